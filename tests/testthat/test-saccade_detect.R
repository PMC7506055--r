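make_recording <- function(x, y = NULL, rate = 60) {
  n <- length(x)
  if (is.null(y)) y <- numeric(n)
  gaze_recording((seq_len(n) - 1) / rate, x, y, x, y, rate_hz = rate)
}

test_that("central-difference kinematics match closed forms", {
  n <- 120; t <- (0:(n - 1)) / 60
  # constant position
  kin <- differentiate(make_recording(rep(3, n)), "left")
  expect_true(all(abs(kin$velocity_x) < 1e-12))
  expect_true(all(abs(kin$acceleration) < 1e-12))
  # linear ramp, 10 deg/s
  kin <- differentiate(make_recording(10 * t), "left")
  expect_equal(kin$velocity_x, rep(10, n), tolerance = 1e-9)
  expect_true(all(abs(kin$acceleration_x[3:(n - 2)]) < 1e-9))
  # quadratic, a = 100 deg/s^2: interior acceleration recovers a exactly
  kin <- differentiate(make_recording(0.5 * 100 * t^2), "left")
  expect_equal(kin$acceleration_x[3:(n - 2)], rep(100, n - 4),
               tolerance = 1e-8)
  expect_error(
    differentiate(make_recording(c(1, 2)), "left"), "3 valid")
})

test_that("adaptive threshold is K times the trailing-window SD", {
  cfg <- detector_config()  # K = 3.4, 60-frame window
  win <- as.numeric(scale(rnorm(60)))       # sample SD exactly 1
  acc <- c(win, rnorm(40))
  thr <- adaptive_threshold(acc, cfg)
  expect_length(thr, 100)
  expect_equal(thr[61], 3.4, tolerance = 1e-9)

  # independent K x SD oracle at SD = 2.5
  win2 <- as.numeric(scale(rnorm(60))) * 2.5
  thr2 <- adaptive_threshold(c(win2, 0), cfg)
  expect_equal(thr2[61], 3.4 * 2.5, tolerance = 1e-9)
  expect_equal(thr2[61], cfg$K * sd(win2), tolerance = 1e-12)

  # warm-up uses the first complete window
  expect_equal(thr[1], thr[60])
  expect_equal(thr[1], 3.4)

  # constant acceleration: zero SD, zero threshold
  thr3 <- adaptive_threshold(rep(5, 80), cfg)
  expect_true(all(thr3 == 0))

  expect_error(adaptive_threshold(rnorm(30), cfg), "shorter")
})

test_that("saccade geometry: amplitude and direction from endpoints", {
  expect_equal(saccade_direction(c(0, 0), c(0, 3)), 90)
  expect_equal(saccade_direction(c(0, 0), c(-2, 0)), 180)
  expect_equal(saccade_direction(c(1, 1), c(2, 2)), 45)
  expect_error(saccade_direction(c(1, 1), c(1, 1)), "undefined")

  # a pure rightward 5-degree step embedded in fixation noise-free drift
  x <- c(rep(0, 100), seq(0, 5, length.out = 4), rep(5, 100))
  det <- detect_saccades(make_recording(x), eyes = "left")
  expect_equal(nrow(det), 1)
  expect_equal(det$amplitude, 5, tolerance = 1e-6)
  expect_equal(det$direction, 0, tolerance = 1e-6)
})

test_that("noiseless smooth drift yields zero saccades", {
  t <- (0:599) / 60
  det <- detect_saccades(make_recording(2 * t, 1 * t))
  expect_equal(nrow(det), 0)
})

test_that("simulated saccades are recovered with accurate onsets", {
  st <- add_saccadic_displacements(generate_random_walk(seed = 21), 2,
                                   seed = 22)
  sim <- simulate_observer(st, observer_profile(), seed = 23)
  det <- detect_saccades(sim$recording)
  gt <- sim$ground_truth
  g <- gt[gt$eye == "left" & gt$amplitude >= 2, ]
  d <- det[det$eye == "left", ]
  hits <- match_events(d$onset_index, g$onset_index, tol = 5)
  expect_gte(hits / nrow(g), 0.9)
  # onset localisation: within the +/-2-frame stencil width of the
  # first-motion frame for matched events
  offs <- vapply(g$onset_index, function(o) {
    dd <- abs(d$onset_index - o)
    min(dd)
  }, numeric(1))
  expect_true(median(offs) <= 3)
})

test_that("detection is translation-invariant and scale-consistent", {
  st <- add_saccadic_displacements(generate_random_walk(seed = 31), 2,
                                   seed = 32)
  sim <- simulate_observer(st, observer_profile(), seed = 33)
  rec <- sim$recording
  shifted <- rec
  shifted$lx <- rec$lx + 7; shifted$ly <- rec$ly - 4
  shifted$rx <- rec$rx + 7; shifted$ry <- rec$ry - 4
  d0 <- detect_saccades(rec)
  d1 <- detect_saccades(shifted)
  expect_equal(d0$onset_index, d1$onset_index)
  expect_equal(d0$amplitude, d1$amplitude, tolerance = 1e-9)

  # scaling positions scales amplitudes/velocities but, because the
  # threshold is data-driven, leaves the detected frames unchanged
  scaled <- rec
  for (f in c("lx", "ly", "rx", "ry")) scaled[[f]] <- 2 * rec[[f]]
  d2 <- detect_saccades(scaled)
  expect_equal(d2$onset_index, d0$onset_index)
  expect_equal(d2$amplitude, 2 * d0$amplitude, tolerance = 1e-9)
  expect_equal(d2$peak_velocity, 2 * d0$peak_velocity, tolerance = 1e-9)
})

test_that("peak velocity respects the mean-speed lower bound", {
  st <- add_saccadic_displacements(generate_random_walk(seed = 41), 2,
                                   seed = 42)
  sim <- simulate_observer(st, observer_profile(), seed = 43)
  det <- detect_saccades(sim$recording)
  det <- det[det$amplitude > 0.5, ]
  dur <- (det$offset_index - det$onset_index + 2) / 60
  expect_true(all(det$peak_velocity >= 0.95 * det$amplitude / dur))
})
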