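#' Detector configuration
#'
#' Parameters of the adaptive acceleration-threshold saccade detector. At any
#' frame the threshold equals `K` times the sample standard deviation of the
#' acceleration magnitude over the preceding `window_frames` samples
#' (1 s at 60 Hz by default); frames whose acceleration exceeds the momentary
#' threshold are marked as saccadic. Velocity is deliberately left unfiltered.
#'
#' @param K Threshold multiplier (default 3.4).
#' @param window_frames Trailing window length in frames (default 60).
#' @param rate_hz Sampling rate, Hz (default 60).
#' @param min_duration_frames Shortest supra-threshold run kept as a saccade
#'   (default 2 frames, ~33 ms at 60 Hz).
#' @param merge_gap_frames Runs separated by at most this many frames are
#'   merged (default 1).
#' @param per_axis If `TRUE`, thresholding is applied per axis and combined
#'   by OR; default `FALSE` uses the magnitude of the 2-D acceleration
#'   vector.
#' @return A `detector_config` list.
#' @export
detector_config <- function(K = 3.4, window_frames = 60, rate_hz = 60,
                            min_duration_frames = 2, merge_gap_frames = 1,
                            per_axis = FALSE) {
  stopifnot(K > 0, window_frames >= 2, rate_hz > 0,
            min_duration_frames >= 1, merge_gap_frames >= 0)
  structure(list(K = K, window_frames = as.integer(window_frames),
                 rate_hz = rate_hz,
                 min_duration_frames = as.integer(min_duration_frames),
                 merge_gap_frames = as.integer(merge_gap_frames),
                 per_axis = per_axis),
            class = "detector_config")
}

#' Differentiate one eye's position trace
#'
#' Velocity is obtained by central differences of position (one-sided at the
#' endpoints) and acceleration by central differences of velocity; no
#' temporal filtering is applied to either signal. Invalid frames propagate
#' `NA` through the stencil.
#'
#' @param recording A [gaze_recording()].
#' @param eye `"left"` or `"right"`.
#' @return A `kinematic_trace`: list with `velocity_x`, `velocity_y`, `speed`
#'   (deg/s), `acceleration_x`, `acceleration_y`, `acceleration` (magnitude,
#'   deg/s^2) and `valid`.
#' @export
differentiate <- function(recording, eye = c("left", "right")) {
  stopifnot(inherits(recording, "gaze_recording"))
  eye <- match.arg(eye)
  p <- eye_positions(recording, eye)
  n <- length(p$x)
  if (sum(p$valid) < 3) stop("need at least 3 valid frames to differentiate")
  dt <- 1 / recording$rate_hz
  x <- ifelse(p$valid, p$x, NA_real_)
  y <- ifelse(p$valid, p$y, NA_real_)
  vx <- central_diff(x, dt)
  vy <- central_diff(y, dt)
  ax <- central_diff(vx, dt)
  ay <- central_diff(vy, dt)
  structure(list(
    velocity_x = vx, velocity_y = vy,
    speed = sqrt(vx^2 + vy^2),
    acceleration_x = ax, acceleration_y = ay,
    acceleration = sqrt(ax^2 + ay^2),
    valid = p$valid, interp = p$interp,
    rate_hz = recording$rate_hz, eye = eye
  ), class = "kinematic_trace")
}

central_diff <- function(x, dt) {
  n <- length(x)
  d <- rep(NA_real_, n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Adaptive acceleration threshold
#'
#' `threshold[t] = K * sd(acceleration over the window_frames samples
#' preceding t)`. During warm-up (the first `window_frames` samples) the SD
#' of the first complete window is used, so the output has the same length
#' as the input. `NA` acceleration samples (invalid frames) are ignored
#' within each window.
#'
#' @param acceleration Acceleration magnitude trace, deg/s^2.
#' @param config A [detector_config()].
#' @return Numeric threshold trace, deg/s^2, same length as input.
#' @export
adaptive_threshold <- function(acceleration, config = detector_config()) {
  w <- config$window_frames
  n <- length(acceleration)
  if (n < w) stop("acceleration trace shorter than the detector window")
  a <- acceleration
  ok <- !is.na(a)
  a0 <- ifelse(ok, a, 0)
  # Running trailing-window moments via cumulative sums; window at frame t
  # covers frames (t - w):(t - 1).
  cs <- cumsum(a0)
  cs2 <- cumsum(a0^2)
  ck <- cumsum(as.numeric(ok))
  thr <- rep(NA_real_, n)
  t_idx <- (w + 1L):n
  s <- cs[t_idx - 1L] - c(0, cs)[t_idx - w]
  s2 <- cs2[t_idx - 1L] - c(0, cs2)[t_idx - w]
  k <- ck[t_idx - 1L] - c(0, ck)[t_idx - w]
  v <- ifelse(k >= 2, pmax((s2 - s^2 / k) / (k - 1), 0), NA_real_)
  thr[t_idx] <- config$K * sqrt(v)
  # Warm-up: SD of the first complete window.
  k1 <- sum(ok[1:w])
  thr[1:w] <- if (k1 >= 2) config$K * stats::sd(a[1:w], na.rm = TRUE) else NA_real_
  thr
}

#' Detect saccades in a binocular recording
#'
#' Applies the adaptive acceleration threshold independently to each eye:
#' frames whose acceleration magnitude exceeds the momentary threshold are
#' marked saccadic; marked runs separated by at most `merge_gap_frames` are
#' merged, runs shorter than `min_duration_frames` are discarded, and each
#' surviving run is parameterised by its amplitude (Euclidean start-to-end
#' displacement), peak velocity (maximum speed within the run) and direction
#' (angle of the end-start vector, degrees in \[0, 360), 0 = rightward,
#' 90 = upward). Saccades overlapping invalid or interpolated frames are
#' flagged (`clean = FALSE`).
#'
#' @param recording A [gaze_recording()].
#' @param config A [detector_config()].
#' @param eyes Eyes to process (default both).
#' @return A data.frame with one row per saccade: `eye`, `onset_index`,
#'   `offset_index` (1-based frames), `onset_s`, `offset_s`, `start_x`,
#'   `start_y`, `end_x`, `end_y`, `amplitude`, `peak_velocity`, `direction`,
#'   `clean`, `trial_id`, `condition`. The per-frame saccade mask for each
#'   eye (for back-projection onto the position traces) is attached as
#'   attribute `"marks"`.
#' @export
detect_saccades <- function(recording, config = detector_config(),
                            eyes = c("left", "right")) {
  stopifnot(inherits(recording, "gaze_recording"))
  out <- list()
  marks <- list()
  for (eye in eyes) {
    kin <- differentiate(recording, eye)
    # floor far below any physiological acceleration: keeps floating-point
    # dust on noiseless traces (threshold 0) from marking frames
    floor_dps2 <- 1e-6
    if (config$per_axis) {
      thr_x <- pmax(adaptive_threshold(abs(kin$acceleration_x), config),
                    floor_dps2)
      thr_y <- pmax(adaptive_threshold(abs(kin$acceleration_y), config),
                    floor_dps2)
      above <- (abs(kin$acceleration_x) > thr_x) |
               (abs(kin$acceleration_y) > thr_y)
    } else {
      thr <- pmax(adaptive_threshold(kin$acceleration, config), floor_dps2)
      above <- kin$acceleration > thr
    }
    above[is.na(above)] <- FALSE
    runs <- mask_to_runs(above, config$merge_gap_frames,
                         config$min_duration_frames)
    marks[[eye]] <- runs$mask
    if (nrow(runs$runs) == 0) next
    p <- eye_positions(recording, eye)
    sacc <- do.call(rbind, lapply(seq_len(nrow(runs$runs)), function(i) {
      i0 <- runs$runs$start[i]; i1 <- runs$runs$end[i]
      # endpoints on the position trace: last frame before / first after the
      # supra-threshold run, clipped to the trace
      j0 <- max(1L, i0 - 1L); j1 <- min(length(p$x), i1 + 1L)
      dxy <- c(p$x[j1] - p$x[j0], p$y[j1] - p$y[j0])
      amp <- sqrt(sum(dxy^2))
      idx <- j0:j1
      data.frame(
        eye = eye, onset_index = i0, offset_index = i1,
        onset_s = recording$time_s[i0], offset_s = recording$time_s[i1],
        start_x = p$x[j0], start_y = p$y[j0],
        end_x = p$x[j1], end_y = p$y[j1],
        amplitude = amp,
        peak_velocity = suppressWarnings(max(kin$speed[idx], na.rm = TRUE)),
        direction = if (amp > 0) saccade_direction(c(p$x[j0], p$y[j0]),
                                                   c(p$x[j1], p$y[j1])) else NA_real_,
        clean = !any(!p$valid[idx] | p$interp[idx]),
        stringsAsFactors = FALSE
      )
    }))
    out[[eye]] <- sacc
  }
  res <- if (length(out)) do.call(rbind, out) else empty_saccade_table()
  rownames(res) <- NULL
  if (nrow(res)) {
    res$trial_id <- recording$trial_id
    res$condition <- recording$condition
  }
  attr(res, "marks") <- marks
  res
}

empty_saccade_table <- function() {
  data.frame(eye = character(0), onset_index = integer(0),
             offset_index = integer(0), onset_s = numeric(0),
             offset_s = numeric(0), start_x = numeric(0),
             start_y = numeric(0), end_x = numeric(0), end_y = numeric(0),
             amplitude = numeric(0), peak_velocity = numeric(0),
             direction = numeric(0), clean = logical(0),
             trial_id = integer(0), condition = character(0),
             stringsAsFactors = FALSE)
}

# Merge marked runs separated by <= merge_gap frames, then drop runs shorter
# than min_dur frames. Returns both the run table and the merged mask.
mask_to_runs <- function(mask, merge_gap, min_dur) {
  r <- rle(mask)
  # close short gaps
  if (merge_gap > 0 && length(r$lengths) > 2) {
    interior <- seq_along(r$values)[-c(1, length(r$values))]
    gaps <- interior[!r$values[interior] & r$lengths[interior] <= merge_gap]
    if (length(gaps)) {
      r$values[gaps] <- TRUE
      mask <- inverse.rle(r)
      r <- rle(mask)
    }
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_dur
  # erase too-short runs from the mask
  for (k in which(r$values & r$lengths < min_dur)) {
    mask[starts[k]:ends[k]] <- FALSE
  }
  list(runs = data.frame(start = starts[keep], end = ends[keep]),
       mask = mask)
}

#' Direction of a saccade vector
#'
#' Angle of the end-minus-start displacement, mapped to \[0, 360) degrees
#' with 0 = rightward and 90 = upward.
#'
#' @param start_pos,end_pos Numeric length-2 `(x, y)` positions, degrees.
#' @return Direction in degrees.
#' @export
saccade_direction <- function(start_pos, end_pos) {
  d <- end_pos - start_pos
  if (all(d == 0)) stop("zero displacement: direction undefined")
  (atan2(d[2], d[1]) * 180 / pi) %% 360
}

#' Write a saccade table
#'
#' Delimited output with columns `subject_id`, `trial_id`, `condition`,
#' `eye`, `onset_s`, `offset_s`, `amp_deg`, `pkvel_dps`, `dir_deg`.
#'
#' @param saccades Output of [detect_saccades()].
#' @param path Output path.
#' @param subject_id Subject identifier column value.
#' @export
write_saccades <- function(saccades, path, subject_id = "anon") {
  df <- data.frame(
    subject_id = rep(subject_id, nrow(saccades)),
    trial_id = saccades$trial_id, condition = saccades$condition,
    eye = saccades$eye, onset_s = saccades$onset_s,
    offset_s = saccades$offset_s, amp_deg = saccades$amplitude,
    pkvel_dps = saccades$peak_velocity, dir_deg = saccades$direction
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
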