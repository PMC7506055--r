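#' Generate a random-walk tracking stimulus
#'
#' Produces the target trajectory for the continuous-tracking task: a 2-D
#' random walk with i.i.d. Gaussian positional increments per frame, so the
#' velocity signal carries no serial autocorrelation. The walk starts at the
#' screen centre and is kept on screen by reflecting positions at the display
#' bounds (reflection keeps increments unbiased near the edges).
#'
#' @param duration_s Trial duration in seconds (default 20).
#' @param rate_hz Frame rate in Hz (default 60).
#' @param step_sd_deg Standard deviation of the per-frame positional increment,
#'   in degrees of visual angle. The default 0.07 deg/frame gives a median
#'   target speed of about 5 deg/s at 60 Hz. `step_sd_deg = 0` yields a
#'   constant trajectory at the origin.
#' @param bounds Numeric length-2: half-width and half-height of the display
#'   in degrees (default `c(15.4, 9.6)`, a 24-inch widescreen at 60 cm).
#' @param contrast_level `"high"` or `"low"` blob contrast (metadata only).
#' @param seed Integer seed; the trace is deterministic given the seed.
#'
#' @return A `stimulus_trace` object: list with `frame_times`, `x`, `y`
#'   (degrees, screen-centre origin, rightward/upward positive), `rate_hz`,
#'   `condition` (`"smooth"`), `contrast_level`, `displacement_times`
#'   (empty), `bounds` and `seed`.
#' @seealso [add_saccadic_displacements()], [build_protocol()]
#' @export
generate_random_walk <- function(duration_s = 20, rate_hz = 60,
                                 step_sd_deg = 0.07,
                                 bounds = c(15.4, 9.6),
                                 contrast_level = "high",
                                 seed = 1L) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (rate_hz <= 0) stop("rate_hz must be positive")
  if (step_sd_deg < 0) stop("step_sd_deg must be non-negative")
  stopifnot(length(bounds) == 2, all(bounds > 0))
  contrast_level <- match.arg(contrast_level, c("high", "low"))

  n <- round(duration_s * rate_hz)
  set.seed(as.integer(seed))
  if (step_sd_deg == 0) {
    x <- numeric(n)
    y <- numeric(n)
  } else {
    dx <- stats::rnorm(n - 1, 0, step_sd_deg)
    dy <- stats::rnorm(n - 1, 0, step_sd_deg)
    x <- reflect_into(cumsum(c(0, dx)), bounds[1])
    y <- reflect_into(cumsum(c(0, dy)), bounds[2])
  }
  structure(list(
    frame_times = (seq_len(n) - 1) / rate_hz,
    x = x, y = y,
    rate_hz = rate_hz,
    condition = "smooth",
    contrast_level = contrast_level,
    displacement_times = numeric(0),
    bounds = bounds,
    seed = as.integer(seed)
  ), class = "stimulus_trace")
}

# Fold positions into [-b, b] by repeated reflection at the boundaries.
reflect_into <- function(p, b) {
  period <- 4 * b
  q <- (p + b) %% period
  ifelse(q <= 2 * b, q - b, 3 * b - q)
}

#' Add periodic random displacements to a smooth stimulus
#'
#' Converts a smooth random-walk trace into the saccadic condition: at every
#' interior multiple of `interval_s` the target jumps to a uniformly random
#' in-bounds location, and the random walk continues from the displaced
#' position. Displacements occur strictly inside the trial (for a 20-s trial
#' with a 2-s interval: nine events at t = 2, 4, ..., 18 s); neither trial
#' onset nor offset triggers a jump.
#'
#' @param trace A `stimulus_trace` with condition `"smooth"`.
#' @param interval_s Spacing of displacements in seconds (default 2);
#'   must be positive and shorter than the trial.
#' @param seed Integer seed for the displacement targets.
#' @return A `stimulus_trace` with condition `"saccadic"` and
#'   `displacement_times` filled in.
#' @export
add_saccadic_displacements <- function(trace, interval_s = 2, seed = 1L) {
  stopifnot(inherits(trace, "stimulus_trace"))
  if (trace$condition == "saccadic") {
    stop("trace already has saccadic displacements")
  }
  duration <- length(trace$x) / trace$rate_hz
  if (interval_s <= 0 || interval_s >= duration) {
    stop("interval_s must be positive and shorter than the trial duration")
  }
  n <- length(trace$x)
  jump_times <- seq(interval_s, by = interval_s,
                    length.out = floor((duration - 1e-9) / interval_s))
  jump_times <- jump_times[jump_times < duration - 1e-9]
  jump_frames <- round(jump_times * trace$rate_hz) + 1L

  set.seed(as.integer(seed))
  jx <- stats::runif(length(jump_frames), -trace$bounds[1], trace$bounds[1])
  jy <- stats::runif(length(jump_frames), -trace$bounds[2], trace$bounds[2])

  # Rebuild positions from the original increments, restarting the walk at
  # each displacement target and re-reflecting at the bounds.
  x <- trace$x
  y <- trace$y
  dx <- diff(trace$x)
  dy <- diff(trace$y)
  for (k in seq_along(jump_frames)) {
    f <- jump_frames[k]
    to <- if (k < length(jump_frames)) jump_frames[k + 1] - 1L else n
    idx <- f:to
    if (f < to) {
      x[idx] <- reflect_into(jx[k] + cumsum(c(0, dx[f:(to - 1)])), trace$bounds[1])
      y[idx] <- reflect_into(jy[k] + cumsum(c(0, dy[f:(to - 1)])), trace$bounds[2])
    } else {
      x[idx] <- jx[k]
      y[idx] <- jy[k]
    }
  }
  trace$x <- x
  trace$y <- y
  trace$condition <- "saccadic"
  trace$displacement_times <- jump_times
  trace
}

#' Gaussian blob spatial profile
#'
#' The tracking target is a Gaussian luminance blob on a uniform grey
#' background, with a full width at half maximum of 0.83 degrees (about the
#' size-III Goldmann perimetric stimulus). Peak and background luminances are
#' stored as configured constants: high contrast peaks at ~385 cd/m^2, low
#' contrast at ~160 cd/m^2, on a ~140 cd/m^2 background.
#'
#' @param contrast_level `"high"` or `"low"`.
#' @param background_luminance Background in cd/m^2 (default 140).
#' @param fwhm Full width at half maximum in degrees (default 0.83).
#' @return A `blob_profile` object with fields `fwhm`, `peak_luminance`,
#'   `background_luminance`, `contrast_fraction` and `sigma` (the Gaussian SD
#'   implied by the FWHM).
#' @export
blob_profile <- function(contrast_level = c("high", "low"),
                         background_luminance = 140,
                         fwhm = 0.83) {
  contrast_level <- match.arg(contrast_level)
  stopifnot(fwhm > 0)
  peak <- switch(contrast_level, high = 385, low = 160)
  if (peak <= background_luminance) {
    stop("peak luminance must exceed background luminance")
  }
  structure(list(
    fwhm = fwhm,
    peak_luminance = peak,
    background_luminance = background_luminance,
    contrast_fraction = switch(contrast_level, high = 0.5, low = 0.1),
    sigma = fwhm / (2 * sqrt(2 * log(2)))
  ), class = "blob_profile")
}

#' Evaluate a blob profile at radial distances
#'
#' @param blob A [blob_profile()].
#' @param r Radial distance(s) from the blob centre, degrees.
#' @return Luminance in cd/m^2 at each distance.
#' @export
blob_luminance <- function(blob, r) {
  stopifnot(inherits(blob, "blob_profile"))
  blob$background_luminance +
    (blob$peak_luminance - blob$background_luminance) *
      exp(-r^2 / (2 * blob$sigma^2))
}

#' Measure the FWHM of a blob profile numerically
#'
#' Renders the radial luminance profile on a fine grid and returns the
#' separation of the two radial points where the profile crosses
#' background + (peak - background) / 2.
#'
#' @param blob A [blob_profile()].
#' @param grid_step Grid spacing in degrees (default 1e-4).
#' @return Measured full width at half maximum, degrees.
#' @export
measure_fwhm <- function(blob, grid_step = 1e-4) {
  stopifnot(inherits(blob, "blob_profile"))
  r <- seq(-2 * blob$fwhm, 2 * blob$fwhm, by = grid_step)
  lum <- blob_luminance(blob, r)
  half <- blob$background_luminance +
    (blob$peak_luminance - blob$background_luminance) / 2
  above <- which(lum >= half)
  r[max(above)] - r[min(above)]
}

#' Build the default trial protocol
#'
#' The standard protocol is 12 trials of 20 s (4 minutes of tracking):
#' 6 smooth-pursuit trials and 6 saccadic trials (displacement every 2 s),
#' each condition split between high and low blob contrast, conditions
#' interleaved, with a distinct stimulus seed per trial.
#'
#' @param seed Integer master seed; per-trial seeds are derived from it.
#' @param n_per_condition Trials per condition (default 6).
#' @param duration_s Trial duration, seconds (default 20).
#' @return A `protocol_schedule`: data.frame with columns `trial_id`,
#'   `condition`, `duration_s`, `contrast_level`, `seed`.
#' @export
build_protocol <- function(seed = 1L, n_per_condition = 6, duration_s = 20) {
  set.seed(as.integer(seed))
  trial_seeds <- sample.int(.Machine$integer.max - 1L, 2 * n_per_condition)
  contrast <- rep(c("high", "low"), length.out = n_per_condition)
  sched <- data.frame(
    trial_id = seq_len(2 * n_per_condition),
    condition = rep(c("smooth", "saccadic"), n_per_condition),
    duration_s = duration_s,
    contrast_level = rep(contrast, each = 2),
    seed = trial_seeds,
    stringsAsFactors = FALSE
  )
  class(sched) <- c("protocol_schedule", "data.frame")
  sched
}

#' Realise a protocol schedule as stimulus traces
#'
#' @param schedule A [build_protocol()] schedule.
#' @param rate_hz Frame rate in Hz (default 60).
#' @param displacement_interval_s Displacement spacing for saccadic trials.
#' @param ... Passed to [generate_random_walk()].
#' @return List of `stimulus_trace`, one per trial, in schedule order.
#' @export
realize_protocol <- function(schedule, rate_hz = 60,
                             displacement_interval_s = 2, ...) {
  stopifnot(inherits(schedule, "protocol_schedule"))
  lapply(seq_len(nrow(schedule)), function(i) {
    tr <- generate_random_walk(duration_s = schedule$duration_s[i],
                               rate_hz = rate_hz,
                               contrast_level = schedule$contrast_level[i],
                               seed = schedule$seed[i], ...)
    if (schedule$condition[i] == "saccadic") {
      tr <- add_saccadic_displacements(tr, displacement_interval_s,
                                       seed = schedule$seed[i] + 1L)
    }
    tr
  })
}

#' Write a stimulus trace as a delimited table
#'
#' Columns: `frame_index`, `time_s`, `x_deg`, `y_deg`, `condition`,
#' `trial_id`; comma-separated, header row, UTF-8.
#'
#' @param trace A `stimulus_trace`.
#' @param path Output file path.
#' @param trial_id Trial identifier stored in the table (default 1).
#' @export
write_stimulus <- function(trace, path, trial_id = 1L) {
  stopifnot(inherits(trace, "stimulus_trace"))
  df <- data.frame(
    frame_index = seq_along(trace$x) - 1L,
    time_s = trace$frame_times,
    x_deg = trace$x,
    y_deg = trace$y,
    condition = trace$condition,
    trial_id = trial_id
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stimulus trace written by [write_stimulus()]
#'
#' @param path File path.
#' @param rate_hz Declared frame rate (default 60); checked against the
#'   timestamps.
#' @param bounds Display half-extents, degrees.
#' @return A `stimulus_trace`.
#' @export
read_stimulus <- function(path, rate_hz = 60, bounds = c(15.4, 9.6)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", "time_s", "x_deg", "y_deg", "condition")
  if (!all(need %in% names(df))) {
    stop("malformed stimulus file: missing columns ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  structure(list(
    frame_times = df$time_s,
    x = df$x_deg, y = df$y_deg,
    rate_hz = rate_hz,
    condition = df$condition[1],
    contrast_level = "high",
    displacement_times = numeric(0),
    bounds = bounds,
    seed = NA_integer_
  ), class = "stimulus_trace")
}
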