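fake_saccades <- function(direction, amplitude = 5, peak_velocity = 300,
                          eye = "left") {
  data.frame(eye = eye, direction = direction, amplitude = amplitude,
             peak_velocity = peak_velocity, stringsAsFactors = FALSE)
}

test_that("direction binning uses 12 thirty-degree bins centred on 0..330", {
  prof <- bin_directions(fake_saccades(c(0, 0, 0, 0)))
  expect_equal(nrow(prof), 12)
  expect_equal(unique(diff(prof$bin_center_deg)), 30)
  expect_equal(prof$count[prof$bin_center_deg == 0], 4)
  expect_equal(sum(prof$count), 4)

  # edge tie at +15 degrees goes to the counterclockwise (30-deg) bin
  tie <- bin_directions(fake_saccades(rep(15, 4)))
  expect_equal(tie$count[tie$bin_center_deg == 30], 4)
  # and 345 degrees wraps into the 0-centred bin
  wrap <- bin_directions(fake_saccades(rep(345.1, 4)))
  expect_equal(wrap$count[wrap$bin_center_deg == 0], 4)
})

test_that("uniform directions spread evenly; shares always sum to one", {
  set.seed(5)
  s <- fake_saccades(runif(1200, 0, 360))
  prof <- bin_directions(s)
  expect_equal(sum(prof$share), 1, tolerance = 1e-12)
  # binomial 99.9% band around 1/12
  p <- 1 / 12
  band <- qnorm(0.9995) * sqrt(p * (1 - p) / 1200)
  expect_true(all(abs(prof$share - p) <= band))

  # rotating all directions by one bin width rotates the profile
  rot <- bin_directions(fake_saccades((s$direction + 30) %% 360))
  expect_equal(rot$count, prof$count[c(12, 1:11)])
})

test_that("quartile strata reproduce hand-computed and analytic oracles", {
  expect_equal(quartile_stratify(c(1, 2, 3, 4)), c(1, 2, 3, 4))
  expect_equal(quartile_stratify(rep(7, 10)), rep(7, 10)[1:4])
  expect_error(quartile_stratify(c(1, 2)), "at least 4")

  # analytic truncated-lognormal within-quartile means
  set.seed(6)
  mu <- 1; sig <- 0.5
  x <- rlnorm(1000, mu, sig)
  got <- quartile_stratify(x)
  qb <- qlnorm(c(0, 0.25, 0.5, 0.75, 1), mu, sig)
  analytic <- vapply(1:4, function(k) {
    a <- qb[k]; b <- qb[k + 1]
    exp(mu + sig^2 / 2) *
      (pnorm((log(b) - mu - sig^2) / sig) -
         pnorm((log(a) - mu - sig^2) / sig)) / 0.25
  }, numeric(1))
  expect_equal(got, analytic, tolerance = 0.08)

  # quartile means are non-decreasing wherever defined
  prof <- bin_directions(fake_saccades(runif(500, 0, 360),
                                       amplitude = rlnorm(500, 1, 0.4),
                                       peak_velocity = rlnorm(500, 5, 0.3)))
  amps <- as.matrix(prof[!prof$sparse, paste0("amp_q", 1:4)])
  expect_true(all(t(apply(amps, 1, diff)) >= 0))
})

test_that("profile z-scoring matches the robust-z oracle and keeps NA", {
  set.seed(7)
  norm <- lapply(1:12, function(i) {
    bin_directions(fake_saccades(runif(600, 0, 360),
                                 amplitude = rlnorm(600, 1, 0.3),
                                 peak_velocity = rlnorm(600, 5, 0.2)))
  })
  # a profile equal to the normative per-bin medians scores zero everywhere
  target <- norm[[1]]
  for (col in c("share", paste0("amp_q", 1:4), paste0("vel_q", 1:4))) {
    target[[col]] <- apply(vapply(norm, function(p) p[[col]],
                                  numeric(12)), 1, median)
  }
  z <- normalize_profile(target, norm)
  expect_true(all(abs(z$z_share) < 1e-12))
  expect_true(all(abs(z$z_amp_q2) < 1e-12))

  # Eq-1 style oracle on a single bin
  shares <- vapply(norm, function(p) p$share[1], numeric(1))
  med <- median(shares); mad <- median(abs(shares - med))
  target2 <- norm[[1]]
  target2$share[1] <- med + 1.486 * mad * 2
  z2 <- normalize_profile(target2, norm)
  expect_equal(z2$z_share[1], 2, tolerance = 1e-9)
  expect_true(z2$flag_share[1])

  # sparse bins propagate as missing, never as zero
  sparse_prof <- bin_directions(fake_saccades(c(0, 0, 0, 0, 90)))
  zs <- normalize_profile(sparse_prof, norm)
  expect_true(is.na(zs$z_amp_q1[zs$bin_center_deg == 90]))

  short <- norm[1:5]
  expect_error(normalize_profile(target, short), "at least 10")
  mism <- bin_directions(fake_saccades(runif(100, 0, 360)), n_bins = 6)
  expect_error(normalize_profile(mism, norm), "mismatch")
})

test_that("a left-eye adduction deficit halves that eye's nasal saccade rate
           and shows up as inter-eye asymmetry", {
  healthy <- observer_profile()
  ino <- observer_profile(adduction_deficit = c(left = 0.5, right = 1))

  norm <- lapply(1:30, function(i) {
    subject_direction_profiles(healthy, seed = 1000 + i)
  })
  inos <- lapply(1:20, function(i) {
    subject_direction_profiles(ino, seed = 5000 + i)
  })

  # the left eye's detectable nasal (rightward-hemifield) saccade rate is
  # about halved relative to healthy observers
  rate_ratio <-
    mean(vapply(inos, function(p) nasal_hemifield_count(p$left),
                numeric(1))) /
    mean(vapply(norm, function(p) nasal_hemifield_count(p$left),
                numeric(1)))
  expect_gt(rate_ratio, 0.35)
  expect_lt(rate_ratio, 0.65)

  # dysconjugacy: per-eye frequency normalisation keeps the deficit visible
  # as a left/right nasal-count asymmetry within each subject, which
  # cleanly separates deficit from healthy observers
  lr_ratio <- function(p) {
    nasal_hemifield_count(p$left) / max(nasal_hemifield_count(p$right), 1)
  }
  r_ino <- vapply(inos, lr_ratio, numeric(1))
  r_healthy <- vapply(norm, lr_ratio, numeric(1))
  expect_lt(median(r_ino), 0.7)
  expect_gt(median(r_healthy), 0.85)
  expect_gte(mean(r_ino < 0.8), 0.9)

  # the normalised left-eye nasal-bin share is depressed on average, but
  # binomial direction-sampling noise at protocol-scale saccade counts
  # keeps single-subject |z| >= 2 flags unreliable at this effect size
  z0 <- vapply(inos, function(p) {
    z <- normalize_profile(p$left, lapply(norm, `[[`, "left"))
    z$z_share[z$bin_center_deg == 0]
  }, numeric(1))
  expect_lt(median(z0), 0)
})
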