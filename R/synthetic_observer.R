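#' Parametric oculomotor observer profile
#'
#' Describes a synthetic observer tracking the stimulus: smooth pursuit with
#' a processing delay, a velocity gain and positional drift noise, plus
#' catch-up saccades triggered when the positional error exceeds a
#' threshold. Saccade amplitude is the error times a (possibly direction-
#' and eye-dependent) gain, and the saccadic velocity profile is a symmetric
#' raised cosine whose peak follows the observer's main sequence. Per-eye
#' deficits emulate clinical phenomenology: an adduction deficit (reduced
#' probability of nasally-directed saccades in one eye, as in internuclear
#' ophthalmoplegia) and vertical saccade suppression (omission of
#' vertically-directed catch-up saccades, as in parkinsonian impairment).
#'
#' @param latency_ms Processing delay, ms.
#' @param pursuit_gain Eye velocity / stimulus velocity during pursuit.
#' @param drift_noise_sd Positional noise SD, degrees per frame, per axis.
#' @param saccade_trigger_deg Positional error triggering a catch-up
#'   saccade, degrees.
#' @param saccade_gain Saccade amplitude / positional error. Scalar, or a
#'   length-12 vector (per 30-degree direction bin), or a list with `left`
#'   and `right` entries of either shape (1 orthometric, >1 hypermetric,
#'   <1 hypometric).
#' @param adduction_deficit Named numeric `c(left = , right = )`: probability
#'   multiplier on that eye executing nasally-directed saccades (1 = intact).
#' @param vertical_saccade_suppression Probability of omitting a
#'   vertically-directed catch-up saccade (both eyes).
#' @param main_sequence Named numeric `c(V_max = , A_63 = )` generating
#'   saccadic peak velocities, deg/s and deg.
#' @param pursuit_speed_cap Maximum stimulus speed the pursuit system can
#'   follow, deg/s; target displacements beyond it must be corrected by
#'   saccades.
#' @param refractory_ms Minimum interval between saccade triggers, ms.
#' @return An `observer_profile` list.
#' @export
observer_profile <- function(latency_ms = 100, pursuit_gain = 0.95,
                             drift_noise_sd = 0.05,
                             saccade_trigger_deg = 1.5,
                             saccade_gain = 0.95,
                             adduction_deficit = c(left = 1, right = 1),
                             vertical_saccade_suppression = 0,
                             main_sequence = c(V_max = 500, A_63 = 5),
                             pursuit_speed_cap = 25,
                             refractory_ms = 150) {
  stopifnot(latency_ms >= 0, pursuit_gain >= 0, drift_noise_sd >= 0,
            saccade_trigger_deg > 0,
            vertical_saccade_suppression >= 0,
            vertical_saccade_suppression <= 1,
            all(adduction_deficit >= 0), all(adduction_deficit <= 1),
            main_sequence["V_max"] > 0, main_sequence["A_63"] > 0)
  structure(list(
    latency_ms = latency_ms, pursuit_gain = pursuit_gain,
    drift_noise_sd = drift_noise_sd,
    saccade_trigger_deg = saccade_trigger_deg,
    saccade_gain = saccade_gain,
    adduction_deficit = adduction_deficit,
    vertical_saccade_suppression = vertical_saccade_suppression,
    main_sequence = main_sequence,
    pursuit_speed_cap = pursuit_speed_cap,
    refractory_ms = refractory_ms
  ), class = "observer_profile")
}

# Resolve the saccade gain for a given eye and direction (degrees).
resolve_gain <- function(saccade_gain, eye, direction) {
  g <- saccade_gain
  if (is.list(g)) g <- g[[eye]]
  if (length(g) == 12) {
    bin <- floor(((direction + 15) %% 360) / 30) + 1L
    g <- g[bin]
  }
  as.numeric(g)
}

#' Preset observer profiles
#'
#' Three documented parameter sets: `healthy` (near-unity gains, small
#' latency and noise), `ms_ino_like` (hypermetric saccades with a left-eye
#' adduction deficit, the internuclear-ophthalmoplegia signature) and
#' `pd_like` (longer latency, reduced pursuit gain, hypometric saccades and
#' frequent suppression of vertical catch-up saccades, the parkinsonian
#' signature).
#'
#' @return Named list of [observer_profile()] objects.
#' @export
preset_profiles <- function() {
  list(
    healthy = observer_profile(),
    ms_ino_like = observer_profile(
      latency_ms = 120, drift_noise_sd = 0.06,
      saccade_gain = 1.3,
      adduction_deficit = c(left = 0.5, right = 1)),
    pd_like = observer_profile(
      latency_ms = 220, pursuit_gain = 0.7, drift_noise_sd = 0.08,
      saccade_trigger_deg = 2.0, saccade_gain = 0.7,
      vertical_saccade_suppression = 0.7)
  )
}

#' Simulate a binocular gaze response to a stimulus
#'
#' Per frame, each eye's velocity is `pursuit_gain` times the stimulus
#' velocity delayed by the latency (capped at the pursuit speed limit) plus
#' drift noise. Whenever the cyclopean positional error relative to the
#' delayed target exceeds the trigger threshold (and the refractory period
#' has passed), a catch-up saccade toward the target is emitted: the trigger
#' is conjugate, and each eye corrects its own positional error with
#' amplitude = error x saccade gain and a raised-cosine velocity profile
#' whose peak follows the observer's main sequence. An eye affected by an
#' adduction deficit omits the nasally-directed saccade with the stated
#' probability and re-foveates by a slow glissadic drift instead, so its
#' detectable nasal saccade rate drops accordingly. Deterministic under the
#' seed.
#'
#' @param stimulus A `stimulus_trace`.
#' @param profile An [observer_profile()].
#' @param seed Integer seed.
#' @param trial_id,subject_id,age_years Metadata for the recording.
#' @return List `recording` (a [gaze_recording()]) and `ground_truth`
#'   (data.frame: `eye`, `onset_index`, `amplitude`, `direction`,
#'   `peak_velocity`, one row per executed saccade per eye).
#' @export
simulate_observer <- function(stimulus, profile, seed = 1L,
                              trial_id = 1L, subject_id = "sim",
                              age_years = NA_integer_) {
  stopifnot(inherits(stimulus, "stimulus_trace"),
            inherits(profile, "observer_profile"))
  rate <- stimulus$rate_hz
  n <- length(stimulus$x)
  dt <- 1 / rate
  set.seed(as.integer(seed))

  lagf <- round(profile$latency_ms / 1000 * rate)
  d_idx <- pmax(1L, seq_len(n) - lagf)
  tx <- stimulus$x[d_idx]  # delayed (perceived) target
  ty <- stimulus$y[d_idx]

  # pursuit increments: gain x delayed target increments, magnitude-capped
  dx <- c(0, diff(tx)); dy <- c(0, diff(ty))
  step_mag <- sqrt(dx^2 + dy^2)
  cap <- profile$pursuit_speed_cap * dt
  scale <- ifelse(step_mag > cap, cap / step_mag, 1)
  px <- profile$pursuit_gain * dx * scale
  py <- profile$pursuit_gain * dy * scale

  base <- list()
  for (eye in c("left", "right")) {
    nx <- stats::rnorm(n, 0, profile$drift_noise_sd)
    ny <- stats::rnorm(n, 0, profile$drift_noise_sd)
    nx[1] <- 0; ny[1] <- 0
    base[[eye]] <- list(x = stimulus$x[1] + cumsum(px + nx) - px[1],
                        y = stimulus$y[1] + cumsum(py + ny) - py[1])
  }

  slx <- numeric(n); sly <- numeric(n)
  srx <- numeric(n); sry <- numeric(n)
  bx <- (base$left$x + base$right$x) / 2   # cyclopean pursuit position
  by <- (base$left$y + base$right$y) / 2
  truth_eye <- character(0); truth_onset <- integer(0)
  truth_amp <- numeric(0); truth_dir <- numeric(0); truth_vpk <- numeric(0)
  refractory_frames <- round(profile$refractory_ms / 1000 * rate)
  next_allowed <- lagf + 2L
  clx <- cly <- crx <- cry <- 0
  ms <- profile$main_sequence
  trig <- profile$saccade_trigger_deg

  for (t in seq_len(n)) {
    clx <- clx + slx[t]; cly <- cly + sly[t]
    crx <- crx + srx[t]; cry <- cry + sry[t]
    if (t < next_allowed || t >= n) next
    exl <- tx[t] - (base$left$x[t] + clx)   # per-eye positional errors
    eyl <- ty[t] - (base$left$y[t] + cly)
    exr <- tx[t] - (base$right$x[t] + crx)
    eyr <- ty[t] - (base$right$y[t] + cry)
    ex <- (exl + exr) / 2                   # cyclopean error drives the trigger
    ey <- (eyl + eyr) / 2
    if (ex * ex + ey * ey <= trig * trig) next
    direction <- (atan2(ey, ex) * 180 / pi) %% 360
    if (abs(ey) > abs(ex) && profile$vertical_saccade_suppression > 0 &&
        stats::runif(1) < profile$vertical_saccade_suppression) {
      next_allowed <- t + max(refractory_frames, round(0.5 * rate))
      next
    }
    dur_max <- 2L
    for (eye in c("left", "right")) {
      if (eye == "left") { ex_e <- exl; ey_e <- eyl }
      else               { ex_e <- exr; ey_e <- eyr }
      g <- resolve_gain(profile$saccade_gain, eye, direction)
      ax <- ex_e * g; ay <- ey_e * g
      A <- sqrt(ax^2 + ay^2)
      if (A == 0) next
      nasal <- (eye == "left" && ex_e > 0) || (eye == "right" && ex_e < 0)
      deficit <- profile$adduction_deficit[[eye]]
      omitted <- nasal && deficit < 1 && stats::runif(1) >= deficit
      if (omitted) {
        # slowed adduction: the affected eye re-foveates by a smooth
        # glissadic drift; its duration grows with amplitude so the peak
        # acceleration (pi * 2A / D^2 for a raised cosine) stays near
        # 100 deg/s^2, well under the adaptive detection threshold;
        # triggering is suppressed until the drift completes
        dur <- as.integer(round(max(0.5, sqrt(2 * pi * A / 100)) * rate))
      } else {
        vpk <- ms[["V_max"]] * (1 - exp(-A / ms[["A_63"]]))
        dur <- max(2L, as.integer(round(2 * A / vpk * rate)))
      }
      w <- 1 - cos(2 * pi * (seq_len(dur) - 0.5) / dur)
      wi_all <- w / sum(w)
      dur_max <- max(dur_max, dur)
      idx <- (t + 1L):min(n, t + dur)
      wi <- wi_all[seq_along(idx)]
      if (eye == "left") {
        slx[idx] <- slx[idx] + ax * wi
        sly[idx] <- sly[idx] + ay * wi
      } else {
        srx[idx] <- srx[idx] + ax * wi
        sry[idx] <- sry[idx] + ay * wi
      }
      if (!omitted) {
        truth_eye <- c(truth_eye, eye)
        truth_onset <- c(truth_onset, t + 1L)
        truth_amp <- c(truth_amp, A)
        truth_dir <- c(truth_dir, (atan2(ay, ax) * 180 / pi) %% 360)
        truth_vpk <- c(truth_vpk, A * max(wi_all) * rate)
      }
    }
    next_allowed <- t + dur_max + refractory_frames
  }

  lx <- base$left$x + cumsum(slx)
  ly <- base$left$y + cumsum(sly)
  rx <- base$right$x + cumsum(srx)
  ry <- base$right$y + cumsum(sry)
  rec <- gaze_recording(
    time_s = stimulus$frame_times,
    lx = lx, ly = ly, rx = rx, ry = ry,
    rate_hz = rate, condition = stimulus$condition,
    trial_id = trial_id, subject_id = subject_id, age_years = age_years)
  gt <- data.frame(eye = truth_eye, onset_index = truth_onset,
                   amplitude = truth_amp, direction = truth_dir,
                   peak_velocity = truth_vpk, stringsAsFactors = FALSE)
  list(recording = rec, ground_truth = gt)
}

#' Run the full tracking protocol for one synthetic subject
#'
#' Builds the default 12-trial protocol, simulates every trial with the
#' given observer profile, and returns the recordings, stimuli and pooled
#' ground truth.
#'
#' @param profile An [observer_profile()].
#' @param seed Integer seed (drives protocol and simulation).
#' @param subject_id,age_years Metadata.
#' @param rate_hz Sampling rate (default 60).
#' @return List `recordings`, `stimuli`, `ground_truth`, `schedule`.
#' @export
simulate_subject <- function(profile, seed = 1L, subject_id = "sim",
                             age_years = NA_integer_, rate_hz = 60) {
  sched <- build_protocol(seed = seed)
  stimuli <- realize_protocol(sched, rate_hz = rate_hz)
  recordings <- vector("list", length(stimuli))
  gt <- list()
  for (i in seq_along(stimuli)) {
    sim <- simulate_observer(stimuli[[i]], profile, seed = seed + 37L * i,
                             trial_id = sched$trial_id[i],
                             subject_id = subject_id, age_years = age_years)
    recordings[[i]] <- sim$recording
    if (nrow(sim$ground_truth)) {
      sim$ground_truth$trial_id <- sched$trial_id[i]
      sim$ground_truth$condition <- stimuli[[i]]$condition
      gt[[length(gt) + 1L]] <- sim$ground_truth
    }
  }
  list(recordings = recordings, stimuli = stimuli,
       ground_truth = if (length(gt)) do.call(rbind, gt) else NULL,
       schedule = sched)
}

# Multiplicative lognormal jitter on the positive parameters of a profile.
jitter_profile <- function(profile, sdlog = 0.1) {
  j <- function(v) v * stats::rlnorm(length(v), 0, sdlog)
  p <- profile
  p$latency_ms <- j(p$latency_ms)
  p$pursuit_gain <- min(j(p$pursuit_gain), 1.2)
  p$drift_noise_sd <- j(p$drift_noise_sd)
  p$saccade_trigger_deg <- j(p$saccade_trigger_deg)
  if (is.numeric(p$saccade_gain)) p$saccade_gain <- j(p$saccade_gain)
  p
}

#' Simulate a cohort and extract its feature matrix
#'
#' Runs the full protocol and spatio-temporal feature extraction for every
#' simulated subject, with multiplicative lognormal inter-subject jitter on
#' the positive profile parameters. Default group sizes (50 healthy,
#' 12 MS-like, 9 PD-like) and age ranges (30-79, 40-76, 59-77 years)
#' mirror a typical clinical validation cohort and exercise the
#' age-matched referencing logic.
#'
#' @param n_per_group Named integer vector: subjects per preset.
#' @param presets Named list of [observer_profile()] (default
#'   [preset_profiles()]).
#' @param age_ranges Named list of `c(min, max)` ages per group.
#' @param seed Integer master seed.
#' @param jitter_sdlog Lognormal jitter SD (0 disables jitter).
#' @return List `features` (subjects x 80 matrix), `labels`, `ages`,
#'   `subject_ids`.
#' @export
simulate_cohort <- function(n_per_group = c(healthy = 50, ms_ino_like = 12,
                                            pd_like = 9),
                            presets = preset_profiles(),
                            age_ranges = list(healthy = c(30, 79),
                                              ms_ino_like = c(40, 76),
                                              pd_like = c(59, 77)),
                            seed = 1L, jitter_sdlog = 0.1) {
  stopifnot(all(names(n_per_group) %in% names(presets)))
  set.seed(as.integer(seed))
  subject_seeds <- sample.int(.Machine$integer.max - 1L, sum(n_per_group))
  stp <- list()
  labels <- character(0)
  ages <- numeric(0)
  s <- 0L
  for (grp in names(n_per_group)) {
    rng <- age_ranges[[grp]]
    for (i in seq_len(n_per_group[[grp]])) {
      s <- s + 1L
      sid <- sprintf("%s_%02d", grp, i)
      set.seed(subject_seeds[s])
      age <- round(stats::runif(1, rng[1], rng[2]))
      prof <- if (jitter_sdlog > 0) {
        jitter_profile(presets[[grp]], jitter_sdlog)
      } else {
        presets[[grp]]
      }
      sub <- simulate_subject(prof, seed = subject_seeds[s] %% 100000000L,
                              subject_id = sid, age_years = age)
      stp[[sid]] <- extract_stp_vector(sub$recordings, sub$stimuli)
      labels <- c(labels, grp)
      ages <- c(ages, age)
    }
  }
  list(features = stp_wide(stp), labels = labels, ages = ages,
       subject_ids = names(stp))
}
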