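#' Velocity cross-correlogram between eye and stimulus
#'
#' Pearson correlation between eye velocity and stimulus velocity at every
#' integer-frame lag in `[-max_lag_s, +max_lag_s]`. A positive lag means the
#' eye follows the stimulus (the eye trace is delayed relative to the
#' stimulus). Frames with `NA` velocity in either trace are dropped pairwise
#' at each lag.
#'
#' @param eye_velocity,stim_velocity Equal-length velocity traces (deg/s) at
#'   the same sampling rate.
#' @param rate_hz Sampling rate, Hz.
#' @param max_lag_s Largest lag, seconds; at most a quarter of the trace
#'   duration.
#' @return A `correlogram`: list with `lags` (seconds) and `correlation`.
#' @export
velocity_cross_correlogram <- function(eye_velocity, stim_velocity,
                                       rate_hz = 60, max_lag_s = 1) {
  n <- length(eye_velocity)
  if (length(stim_velocity) != n) stop("traces must have equal length")
  if (max_lag_s > n / rate_hz / 4) {
    stop("max_lag_s must not exceed a quarter of the trace duration")
  }
  if (stats::sd(eye_velocity, na.rm = TRUE) == 0 ||
      stats::sd(stim_velocity, na.rm = TRUE) == 0) {
    stop("zero-variance input: correlation undefined")
  }
  L <- floor(max_lag_s * rate_hz)
  lags <- (-L):L
  if (!anyNA(eye_velocity) && !anyNA(stim_velocity)) {
    # NA-free fast path: per-lag Pearson from running sums
    ce <- c(0, cumsum(eye_velocity)); ce2 <- c(0, cumsum(eye_velocity^2))
    cs <- c(0, cumsum(stim_velocity)); cs2 <- c(0, cumsum(stim_velocity^2))
    corr <- vapply(lags, function(l) {
      a <- abs(l); m <- n - a
      if (l >= 0) {
        cross <- sum(eye_velocity[(1 + a):n] * stim_velocity[1:m])
        se <- ce[n + 1] - ce[a + 1]; see <- ce2[n + 1] - ce2[a + 1]
        ss <- cs[m + 1]; sss <- cs2[m + 1]
      } else {
        cross <- sum(eye_velocity[1:m] * stim_velocity[(1 + a):n])
        se <- ce[m + 1]; see <- ce2[m + 1]
        ss <- cs[n + 1] - cs[a + 1]; sss <- cs2[n + 1] - cs2[a + 1]
      }
      ve <- see - se^2 / m
      vs <- sss - ss^2 / m
      if (ve <= 0 || vs <= 0) return(NA_real_)
      (cross - se * ss / m) / sqrt(ve * vs)
    }, numeric(1))
  } else {
    corr <- vapply(lags, function(l) {
      if (l >= 0) {
        e <- eye_velocity[(1 + l):n]; s <- stim_velocity[1:(n - l)]
      } else {
        e <- eye_velocity[1:(n + l)]; s <- stim_velocity[(1 - l):n]
      }
      ok <- is.finite(e) & is.finite(s)
      if (sum(ok) < 3 || stats::sd(e[ok]) == 0 || stats::sd(s[ok]) == 0) {
        return(NA_real_)
      }
      stats::cor(e[ok], s[ok])
    }, numeric(1))
  }
  structure(list(lags = lags / rate_hz, correlation = corr,
                 rate_hz = rate_hz),
            class = "correlogram")
}

#' Tracking lag and temporal uncertainty from a correlogram
#'
#' Fits a Gaussian to the cross-correlogram around its (positive) peak: the
#' fitted mean is the tracking lag (feature F1, seconds) and the fitted SD
#' the temporal uncertainty (F2, seconds — the consistency of the
#' eye-to-stimulus velocity coupling). The fit is the closed-form
#' log-quadratic (Caruana) fit to the contiguous lags around the peak where
#' the correlation exceeds half the peak. If fewer than three such points
#' exist or the log-quadratic is not concave, the readout falls back to the
#' discrete argmax and the Gaussian-equivalent half-width at half peak
#' (flagged via `fallback = TRUE`).
#'
#' @param correlogram A [velocity_cross_correlogram()] result.
#' @return List `lag` (F1, s), `uncertainty` (F2, s), `peak` (peak
#'   correlation height, F5) and `fallback`. All `NA` with `peak <= 0`.
#' @export
lag_and_uncertainty <- function(correlogram) {
  l <- correlogram$lags
  r <- correlogram$correlation
  ok <- is.finite(r)
  if (!any(ok) || max(r[ok]) <= 0) {
    return(list(lag = NA_real_, uncertainty = NA_real_, peak = NA_real_,
                fallback = FALSE))
  }
  p <- which.max(ifelse(ok, r, -Inf))
  peak <- r[p]
  # contiguous region around the peak above half height
  above <- ok & r > peak / 2
  i0 <- p; while (i0 > 1 && above[i0 - 1]) i0 <- i0 - 1
  i1 <- p; while (i1 < length(r) && above[i1 + 1]) i1 <- i1 + 1
  idx <- i0:i1
  if (length(idx) >= 3) {
    z <- log(r[idx])
    fit <- stats::lm(z ~ l[idx] + I(l[idx]^2))
    c2 <- unname(stats::coef(fit)[3])
    c1 <- unname(stats::coef(fit)[2])
    if (is.finite(c2) && c2 < 0) {
      mu <- -c1 / (2 * c2)
      s <- sqrt(-1 / (2 * c2))
      if (mu >= min(l) && mu <= max(l)) {
        return(list(lag = mu, uncertainty = s, peak = peak, fallback = FALSE))
      }
    }
  }
  # fallback: discrete argmax + half width at half peak (Gaussian-equivalent SD)
  hwhm <- (l[i1] - l[i0]) / 2
  list(lag = l[p], uncertainty = hwhm / sqrt(2 * log(2)), peak = peak,
       fallback = TRUE)
}

#' Positional error spread (F3)
#'
#' Standard deviation of the per-frame eye-minus-stimulus positional
#' deviation along one axis, over valid frames.
#'
#' @param eye_pos,stim_pos Equal-length position traces, degrees.
#' @return SD of the deviation, degrees; `NA` if fewer than 10 valid frames.
#' @export
error_spread <- function(eye_pos, stim_pos) {
  if (length(eye_pos) != length(stim_pos)) stop("traces must have equal length")
  e <- eye_pos - stim_pos
  e <- e[is.finite(e)]
  if (length(e) < 10) return(NA_real_)
  stats::sd(e)
}

#' Trajectory dissimilarity (F4)
#'
#' One minus the cosine similarity between the eye and stimulus coordinate
#' arrays along one axis; ranges over \[0, 2\] (0 identical direction,
#' 1 orthogonal, 2 anti-aligned). By default the arrays are mean-centred
#' first so a constant screen offset does not dominate.
#'
#' @param eye_coords,stim_coords Equal-length coordinate arrays, degrees.
#' @param center Mean-centre before computing the cosine (default `TRUE`).
#' @return Dissimilarity in \[0, 2\]; `NA` if either centred array has zero
#'   norm.
#' @export
dissimilarity <- function(eye_coords, stim_coords, center = TRUE) {
  if (length(eye_coords) != length(stim_coords)) {
    stop("arrays must have equal length")
  }
  ok <- is.finite(eye_coords) & is.finite(stim_coords)
  e <- eye_coords[ok]; s <- stim_coords[ok]
  if (center) {
    e <- e - mean(e); s <- s - mean(s)
  }
  ne <- sqrt(sum(e^2)); ns <- sqrt(sum(s^2))
  if (ne == 0 || ns == 0) return(NA_real_)
  1 - sum(e * s) / (ne * ns)
}

#' The full per-axis tracking feature set (F1-F10)
#'
#' Computes all ten spatio-temporal tracking features for one eye, one axis
#' and one trial:
#' \describe{
#'   \item{F1 lag (s)}{cross-correlogram Gaussian mean ([lag_and_uncertainty()])}
#'   \item{F2 temporal uncertainty (s)}{cross-correlogram Gaussian SD}
#'   \item{F3 error spread (deg)}{SD of positional error ([error_spread()])}
#'   \item{F4 dissimilarity}{1 - cosine similarity ([dissimilarity()])}
#'   \item{F5 peak correlation}{height of the correlogram peak}
#'   \item{F6 positional bias (deg)}{mean signed eye-minus-stimulus error}
#'   \item{F7 velocity gain}{slope of the eye-on-stimulus velocity
#'     regression, with the eye trace first aligned at the correlogram peak
#'     lag (so a pure tracking delay does not masquerade as low gain)}
#'   \item{F8 RMS error (deg)}{root-mean-square positional error}
#'   \item{F9 on-target fraction}{share of frames with |error| < 2 deg}
#'   \item{F10 error persistence}{lag-1 autocorrelation of the positional error}
#' }
#'
#' @param eye_pos,stim_pos Aligned position traces for one axis, degrees
#'   (`NA` on invalid frames).
#' @param rate_hz Sampling rate, Hz.
#' @param max_lag_s Correlogram half-width, seconds.
#' @param on_target_deg Error magnitude counted as on target for F9
#'   (default 2).
#' @return Named numeric vector `F1` ... `F10` (`NA` where undefined).
#' @export
axis_features <- function(eye_pos, stim_pos, rate_hz = 60, max_lag_s = 1,
                          on_target_deg = 2) {
  dt <- 1 / rate_hz
  ev <- central_diff(eye_pos, dt)
  sv <- central_diff(stim_pos, dt)
  out <- c(F1 = NA_real_, F2 = NA_real_, F3 = NA_real_, F4 = NA_real_,
           F5 = NA_real_, F6 = NA_real_, F7 = NA_real_, F8 = NA_real_,
           F9 = NA_real_, F10 = NA_real_)
  lag_frames <- 0L
  cg <- tryCatch(
    velocity_cross_correlogram(ev, sv, rate_hz, max_lag_s),
    error = function(e) NULL)
  if (!is.null(cg)) {
    lu <- lag_and_uncertainty(cg)
    out["F1"] <- lu$lag
    out["F2"] <- lu$uncertainty
    out["F5"] <- lu$peak
    if (is.finite(lu$peak)) {
      lag_frames <- round(cg$lags[which.max(
        ifelse(is.finite(cg$correlation), cg$correlation, -Inf))] * rate_hz)
    }
  }
  out["F3"] <- error_spread(eye_pos, stim_pos)
  out["F4"] <- dissimilarity(eye_pos, stim_pos)
  err <- eye_pos - stim_pos
  ok <- is.finite(err)
  if (sum(ok) >= 10) {
    e <- err[ok]
    out["F6"] <- mean(e)
    out["F8"] <- sqrt(mean(e^2))
    out["F9"] <- mean(abs(e) < on_target_deg)
    if (stats::sd(e) > 0) {
      out["F10"] <- stats::cor(e[-length(e)], e[-1])
    }
  }
  # align the eye trace at the correlogram peak lag before the gain regression
  n <- length(ev)
  l <- max(min(lag_frames, n - 10L), 0L)
  ea <- if (l > 0) ev[(1 + l):n] else ev
  sa <- if (l > 0) sv[1:(n - l)] else sv
  okv <- is.finite(ea) & is.finite(sa)
  if (sum(okv) >= 10 && stats::var(sa[okv]) > 0) {
    out["F7"] <- stats::cov(ea[okv], sa[okv]) / stats::var(sa[okv])
  }
  out
}

#' Extract the 80-entry spatio-temporal feature vector for one subject
#'
#' Features are computed per trial for every (eye, axis) pair and then
#' aggregated across each condition's trials by the median (robust to a
#' single bad trial), yielding exactly 10 features x 2 axes x 2 conditions
#' x 2 eyes = 80 keyed entries. Conditions with no usable trial carry
#' explicit `NA` entries, never silent zeros.
#'
#' @param recordings List of [gaze_recording()] (one per trial).
#' @param stimuli List of `stimulus_trace` aligned with `recordings`.
#' @param rate_hz Sampling rate, Hz.
#' @param max_lag_s Correlogram half-width, seconds.
#' @return An `stp_vector`: data.frame in long format with columns
#'   `feature_id` (`F1`-`F10`), `axis` (`H`/`V`), `condition`
#'   (`smooth`/`saccadic`), `eye` (`L`/`R`) and `value`; 80 rows.
#' @export
extract_stp_vector <- function(recordings, stimuli, rate_hz = 60,
                               max_lag_s = 1) {
  stopifnot(length(recordings) == length(stimuli), length(recordings) >= 1)
  grid <- expand.grid(feature_id = paste0("F", 1:10),
                      axis = c("H", "V"),
                      condition = c("smooth", "saccadic"),
                      eye = c("L", "R"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  per_trial <- list()
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    stim <- stimuli[[i]]
    for (eye in c("left", "right")) {
      p <- eye_positions(rec, eye)
      ex <- ifelse(p$valid, p$x, NA_real_)
      ey <- ifelse(p$valid, p$y, NA_real_)
      for (axis in c("H", "V")) {
        f <- if (axis == "H") {
          axis_features(ex, stim$x, rate_hz, max_lag_s)
        } else {
          axis_features(ey, stim$y, rate_hz, max_lag_s)
        }
        per_trial[[length(per_trial) + 1L]] <- data.frame(
          feature_id = names(f), axis = axis,
          condition = rec$condition,
          eye = if (eye == "left") "L" else "R",
          value = unname(f), stringsAsFactors = FALSE)
      }
    }
  }
  all_feat <- do.call(rbind, per_trial)
  agg <- stats::aggregate(value ~ feature_id + axis + condition + eye,
                          data = all_feat,
                          FUN = function(v) stats::median(v, na.rm = TRUE),
                          na.action = stats::na.pass)
  out <- merge(grid, agg, all.x = TRUE, sort = FALSE)
  out <- out[order(out$eye, out$condition, out$axis,
                   as.integer(sub("F", "", out$feature_id))), ]
  rownames(out) <- NULL
  out$value[is.nan(out$value)] <- NA_real_
  class(out) <- c("stp_vector", "data.frame")
  out
}

#' Widen STP vectors into a feature matrix
#'
#' @param stp_list Named list of `stp_vector` objects (names = subject ids),
#'   or a single `stp_vector`.
#' @return Matrix with one row per subject and 80 named columns
#'   (`feature.axis.condition.eye`).
#' @export
stp_wide <- function(stp_list) {
  if (inherits(stp_list, "stp_vector")) stp_list <- list(subject = stp_list)
  rows <- lapply(stp_list, function(v) {
    key <- paste(v$feature_id, v$axis, v$condition, v$eye, sep = ".")
    stats::setNames(v$value, key)[order(key)]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(stp_list)
  out
}

#' Write an STP vector as a long-format table
#'
#' @param stp An `stp_vector`.
#' @param path Output path.
#' @param subject_id Subject identifier column.
#' @export
write_stp <- function(stp, path, subject_id = "anon") {
  df <- cbind(subject_id = subject_id, as.data.frame(stp))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
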