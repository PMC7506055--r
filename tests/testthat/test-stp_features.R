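test_that("cross-correlogram localises shifts and respects the null", {
  set.seed(1)
  s <- rnorm(1200)
  cg <- velocity_cross_correlogram(s, s, 60, 1)
  expect_equal(max(cg$correlation), 1, tolerance = 1e-12)
  expect_equal(cg$lags[which.max(cg$correlation)], 0)
  expect_true(all(abs(cg$correlation) <= 1 + 1e-12))

  # eye = stimulus delayed by 6 frames: peak at +0.1 s (oracle: brute-force
  # argmax over lags)
  eye <- c(rep(0, 6), s[1:1194])
  cg6 <- velocity_cross_correlogram(eye, s, 60, 1)
  brute <- sapply(-60:60, function(l) {
    if (l >= 0) cor(eye[(1 + l):1200], s[1:(1200 - l)])
    else cor(eye[1:(1200 + l)], s[(1 - l):1200])
  })
  expect_equal(cg6$lags[which.max(cg6$correlation)], 0.1)
  expect_equal(which.max(cg6$correlation), which.max(brute))

  # independent white noise: peak below the 95% null band for max over lags
  set.seed(2)
  noise_peak <- max(abs(velocity_cross_correlogram(rnorm(1200), s,
                                                   60, 1)$correlation))
  expect_lt(noise_peak, (qnorm(1 - 0.025 / 121)) / sqrt(1200))

  expect_error(velocity_cross_correlogram(rep(1, 1200), s, 60, 1),
               "zero-variance")
  expect_error(velocity_cross_correlogram(s, s, 60, 10), "quarter")
})

test_that("lag and temporal uncertainty read out of the correlogram", {
  # symmetric triangular correlogram centred at +0.1 s
  lags <- (-60:60) / 60
  tri <- pmax(0.9 - 3 * abs(lags - 0.1), 0.02)
  cg <- structure(list(lags = lags, correlation = tri, rate_hz = 60),
                  class = "correlogram")
  lu <- lag_and_uncertainty(cg)
  expect_lt(abs(lu$lag - 0.1), 1 / 120)  # within half a frame

  # narrower correlogram gives smaller temporal uncertainty
  gauss_cg <- function(sd) {
    structure(list(lags = lags,
                   correlation = 0.8 * exp(-(lags - 0.1)^2 / (2 * sd^2)),
                   rate_hz = 60), class = "correlogram")
  }
  wide <- lag_and_uncertainty(gauss_cg(0.3))
  narrow <- lag_and_uncertainty(gauss_cg(0.1))
  expect_lt(narrow$uncertainty, wide$uncertainty)
  expect_equal(narrow$uncertainty, 0.1, tolerance = 0.02)
  expect_equal(narrow$lag, 0.1, tolerance = 1e-6)

  flat <- structure(list(lags = lags, correlation = rep(-0.1, 121),
                         rate_hz = 60), class = "correlogram")
  expect_true(is.na(lag_and_uncertainty(flat)$lag))
})

test_that("injected tracking delays are recovered within a frame", {
  st <- generate_random_walk(seed = 50)
  for (lat in c(50, 100, 200)) {
    prof <- observer_profile(latency_ms = lat, drift_noise_sd = 0,
                             pursuit_gain = 1, saccade_trigger_deg = 100)
    sim <- simulate_observer(st, prof, seed = 51)
    f <- axis_features(sim$recording$lx, st$x)
    expect_equal(f[["F1"]], lat / 1000, tolerance = 1 / 60)
  }
  # at default noise: median recovery over 20 seeds within two frames
  rec <- vapply(1:20, function(s) {
    sti <- generate_random_walk(seed = 400 + s)
    prof <- observer_profile(latency_ms = 100, saccade_trigger_deg = 100)
    sim <- simulate_observer(sti, prof, seed = 600 + s)
    axis_features(sim$recording$lx, sti$x)[["F1"]]
  }, numeric(1))
  expect_lte(abs(median(rec) - 0.1), 2 / 60)
})

test_that("positional error features match their constructions", {
  st <- generate_random_walk(seed = 60)
  # constant offset: zero spread, bias equal to the offset
  expect_equal(error_spread(st$x + 2, st$x), 0)
  f <- axis_features(st$x + 2, st$x)
  expect_equal(f[["F6"]], 2, tolerance = 1e-9)
  expect_equal(f[["F3"]], 0, tolerance = 1e-9)

  # known-sigma recovery at n = 1200
  set.seed(61)
  expect_equal(error_spread(st$x + rnorm(1200, 0, 1), st$x), 1,
               tolerance = 0.09)

  # dissimilarity endpoints
  v <- st$x - mean(st$x)
  expect_equal(dissimilarity(v, v, center = FALSE), 0)
  expect_equal(dissimilarity(c(1, 0), c(0, 1), center = FALSE), 1)
  expect_equal(dissimilarity(v, -v, center = FALSE), 2)
  expect_true(is.na(dissimilarity(rep(0, 10), 1:10, center = FALSE)))
})

test_that("extended features behave at their anchors", {
  st <- generate_random_walk(seed = 70)
  perfect <- axis_features(st$x, st$x)
  expect_equal(perfect[["F5"]], 1, tolerance = 1e-9)
  expect_equal(perfect[["F6"]], 0, tolerance = 1e-12)
  expect_equal(perfect[["F7"]], 1, tolerance = 1e-9)
  expect_equal(perfect[["F8"]], 0, tolerance = 1e-12)
  expect_equal(perfect[["F9"]], 1)

  # halved velocity gain
  half <- axis_features(st$x * 0.5, st$x)
  expect_equal(half[["F7"]], 0.5, tolerance = 0.02)

  # Gaussian-tail oracle for the on-target fraction at error sd 3
  set.seed(71)
  noisy <- axis_features(st$x + rnorm(1200, 0, 3), st$x)
  expect_equal(noisy[["F9"]], 2 * pnorm(2 / 3) - 1, tolerance = 0.05)
})

test_that("the STP vector has the 10 x 2 x 2 x 2 structure", {
  sub <- simulate_subject(observer_profile(), seed = 80)
  stp <- extract_stp_vector(sub$recordings, sub$stimuli)
  expect_equal(nrow(stp), 80)
  expect_equal(sum(is.na(stp$value)), 0)
  expect_setequal(unique(stp$feature_id), paste0("F", 1:10))
  expect_setequal(unique(stp$axis), c("H", "V"))
  expect_setequal(unique(stp$eye), c("L", "R"))

  # bounded features stay in range
  expect_true(all(stp$value[stp$feature_id == "F4"] >= 0 &
                    stp$value[stp$feature_id == "F4"] <= 2))
  expect_true(all(stp$value[stp$feature_id == "F5"] >= -1 &
                    stp$value[stp$feature_id == "F5"] <= 1))
  expect_true(all(stp$value[stp$feature_id == "F9"] >= 0 &
                    stp$value[stp$feature_id == "F9"] <= 1))

  # smooth-only input: 40 computed, 40 explicitly missing
  keep <- vapply(sub$stimuli, function(s) s$condition == "smooth",
                 logical(1))
  part <- extract_stp_vector(sub$recordings[keep], sub$stimuli[keep])
  expect_equal(nrow(part), 80)
  expect_equal(sum(is.na(part$value)), 40)
  expect_true(all(is.na(part$value[part$condition == "saccadic"])))

  # determinism: identical observers give identical vectors
  sub2 <- simulate_subject(observer_profile(), seed = 80)
  stp2 <- extract_stp_vector(sub2$recordings, sub2$stimuli)
  expect_identical(stp$value, stp2$value)

  # wide form
  w <- stp_wide(list(a = stp, b = stp2))
  expect_equal(dim(w), c(2, 80))
  expect_identical(w[1, ], w[2, ])
})
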