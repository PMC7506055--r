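#' Construct a binocular gaze recording
#'
#' The core data container: per-frame timestamps plus left/right eye
#' horizontal and vertical gaze position in degrees of visual angle
#' (screen-centre origin, rightward/upward positive) and per-eye validity
#' flags. Invalid frames keep their slot (indices are preserved); their
#' positions are `NA` and they are excluded from every downstream
#' computation.
#'
#' @param time_s Strictly increasing timestamps, seconds from trial onset.
#' @param lx,ly,rx,ry Eye positions, degrees; `NA` on invalid frames.
#' @param valid_l,valid_r Logical per-frame validity (default: non-`NA`
#'   positions).
#' @param rate_hz Declared sampling rate, Hz (default 60). The rate implied
#'   by the timestamps must agree within 1%.
#' @param condition `"smooth"` or `"saccadic"`.
#' @param trial_id Integer trial identifier.
#' @param subject_id Opaque subject identifier.
#' @param age_years Optional subject age.
#' @return A `gaze_recording` object.
#' @export
gaze_recording <- function(time_s, lx, ly, rx, ry,
                           valid_l = NULL, valid_r = NULL,
                           rate_hz = 60, condition = "smooth",
                           trial_id = 1L, subject_id = "anon",
                           age_years = NA_integer_) {
  n <- length(time_s)
  for (v in list(lx, ly, rx, ry)) {
    if (length(v) != n) stop("positional arrays must match frame_times length")
  }
  if (n >= 2) {
    dt <- diff(time_s)
    bad <- which(dt <= 0)
    if (length(bad)) {
      stop(sprintf("timestamps not strictly increasing at row %d", bad[1] + 1L))
    }
    implied <- 1 / stats::median(dt)
    if (abs(implied - rate_hz) / rate_hz > 0.01) {
      stop(sprintf("implied rate %.2f Hz deviates > 1%% from declared %.2f Hz",
                   implied, rate_hz))
    }
  }
  if (is.null(valid_l)) valid_l <- !(is.na(lx) | is.na(ly))
  if (is.null(valid_r)) valid_r <- !(is.na(rx) | is.na(ry))
  valid_l <- valid_l & !(is.na(lx) | is.na(ly))
  valid_r <- valid_r & !(is.na(rx) | is.na(ry))
  structure(list(
    time_s = as.numeric(time_s),
    lx = as.numeric(lx), ly = as.numeric(ly),
    rx = as.numeric(rx), ry = as.numeric(ry),
    valid_l = valid_l, valid_r = valid_r,
    interp_l = logical(n), interp_r = logical(n),
    rate_hz = rate_hz, condition = condition,
    trial_id = as.integer(trial_id), subject_id = subject_id,
    age_years = age_years
  ), class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf(
    "gaze_recording: %d frames at %g Hz, condition %s, trial %d, subject %s\n",
    length(x$time_s), x$rate_hz, x$condition, x$trial_id, x$subject_id))
  cat(sprintf("  valid frames: L %d/%d, R %d/%d\n",
              sum(x$valid_l), length(x$time_s),
              sum(x$valid_r), length(x$time_s)))
  invisible(x)
}

#' Read a gaze recording from a delimited file
#'
#' Schema (comma-separated, mandatory header): `time_s, lx_deg, ly_deg,
#' rx_deg, ry_deg, valid_l, valid_r, condition, trial_id`. Rows with blank or
#' missing samples are kept in place and flagged invalid for the affected eye
#' only; they are never dropped.
#'
#' @param path File path.
#' @param rate_hz Declared sampling rate (default 60).
#' @param subject_id,age_years Optional metadata attached to the recording.
#' @return A [gaze_recording()].
#' @export
read_gaze <- function(path, rate_hz = 60, subject_id = "anon",
                      age_years = NA_integer_) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "lx_deg", "ly_deg", "rx_deg", "ry_deg")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("malformed gaze file header: missing ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- which(duplicated(df$time_s))
  if (length(dup)) {
    stop(sprintf("duplicated timestamp at row %d", dup[1]))
  }
  valid_l <- if ("valid_l" %in% names(df)) as.logical(df$valid_l) else NULL
  valid_r <- if ("valid_r" %in% names(df)) as.logical(df$valid_r) else NULL
  gaze_recording(
    time_s = df$time_s,
    lx = df$lx_deg, ly = df$ly_deg, rx = df$rx_deg, ry = df$ry_deg,
    valid_l = valid_l, valid_r = valid_r,
    rate_hz = rate_hz,
    condition = if ("condition" %in% names(df) && nrow(df)) df$condition[1] else "smooth",
    trial_id = if ("trial_id" %in% names(df) && nrow(df)) df$trial_id[1] else 1L,
    subject_id = subject_id, age_years = age_years
  )
}

#' Write a gaze recording to a delimited file
#'
#' Inverse of [read_gaze()]; positions are printed with enough digits that a
#' round trip reproduces them exactly at >= 6 significant digits. Invalid
#' frames are written with empty position fields (the `NA` sentinel).
#'
#' @param recording A [gaze_recording()].
#' @param path Output path.
#' @export
write_gaze <- function(recording, path) {
  stopifnot(inherits(recording, "gaze_recording"))
  df <- data.frame(
    time_s = recording$time_s,
    lx_deg = recording$lx, ly_deg = recording$ly,
    rx_deg = recording$rx, ry_deg = recording$ry,
    valid_l = recording$valid_l, valid_r = recording$valid_r,
    condition = rep(recording$condition, length(recording$time_s)),
    trial_id = rep(recording$trial_id, length(recording$time_s))
  )
  if (nrow(df) == 0) {
    df <- df[0, , drop = FALSE]
  }
  old <- options(digits = 15)
  on.exit(options(old))
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Check eye-tracker calibration quality
#'
#' Calibration passes when the average error is below 1 degree of visual
#' angle and the maximum error below 2.5 degrees; otherwise the calibration
#' is repeated before recording.
#'
#' @param mean_error_deg Average calibration error, degrees.
#' @param max_error_deg Maximum calibration error, degrees.
#' @return `TRUE` (pass) or `FALSE`.
#' @export
check_calibration <- function(mean_error_deg, max_error_deg) {
  if (mean_error_deg < 0 || max_error_deg < 0) {
    stop("calibration errors must be non-negative")
  }
  mean_error_deg < 1.0 && max_error_deg < 2.5
}

#' Interpolate short gaps in a gaze recording
#'
#' Blink/dropout policy: runs of up to `max_gap` consecutive invalid frames
#' that are bracketed by valid frames are filled by linear interpolation and
#' flagged as interpolated (so saccades overlapping them can be excluded from
#' dynamics statistics); longer gaps stay invalid and split the trace into
#' independently analysed segments.
#'
#' @param recording A [gaze_recording()].
#' @param max_gap Longest gap (frames) to interpolate (default 3).
#' @return The recording with short gaps filled, `interp_l`/`interp_r`
#'   flags set, and validity updated.
#' @export
interpolate_gaps <- function(recording, max_gap = 3) {
  stopifnot(inherits(recording, "gaze_recording"))
  fill <- function(pos_x, pos_y, valid) {
    r <- rle(valid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    interp <- logical(length(valid))
    for (k in seq_along(r$values)) {
      if (r$values[k] || r$lengths[k] > max_gap) next
      if (k == 1 || k == length(r$values)) next  # edge gaps stay invalid
      i0 <- starts[k] - 1L
      i1 <- ends[k] + 1L
      idx <- starts[k]:ends[k]
      w <- (idx - i0) / (i1 - i0)
      pos_x[idx] <- pos_x[i0] + w * (pos_x[i1] - pos_x[i0])
      pos_y[idx] <- pos_y[i0] + w * (pos_y[i1] - pos_y[i0])
      valid[idx] <- TRUE
      interp[idx] <- TRUE
    }
    list(x = pos_x, y = pos_y, valid = valid, interp = interp)
  }
  l <- fill(recording$lx, recording$ly, recording$valid_l)
  r <- fill(recording$rx, recording$ry, recording$valid_r)
  recording$lx <- l$x; recording$ly <- l$y
  recording$valid_l <- l$valid; recording$interp_l <- l$interp
  recording$rx <- r$x; recording$ry <- r$y
  recording$valid_r <- r$valid; recording$interp_r <- r$interp
  recording
}

# Per-eye accessors used throughout the analysis modules.
eye_positions <- function(recording, eye = c("left", "right")) {
  eye <- match.arg(eye)
  if (eye == "left") {
    list(x = recording$lx, y = recording$ly,
         valid = recording$valid_l, interp = recording$interp_l)
  } else {
    list(x = recording$rx, y = recording$ry,
         valid = recording$valid_r, interp = recording$interp_r)
  }
}
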