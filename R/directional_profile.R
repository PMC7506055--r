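#' Polar-binned saccade profile for one eye
#'
#' Bins saccade directions into `n_bins` sectors (default 12, i.e. 30-degree
#' bins) centred on 0, 30, ..., 330 degrees with edges at +/-15 degrees
#' around each centre; a direction falling exactly on an edge goes to the
#' counterclockwise (higher-centre) bin. For each bin the saccade count, the
#' frequency share (of that eye's saccades, so inter-eye asymmetries such as
#' adduction deficits stay visible), and quartile-stratified amplitude and
#' peak-velocity means are returned. Bins with fewer than `min_per_bin`
#' saccades are marked sparse and carry `NA` dynamics.
#'
#' @param saccades Saccade table ([detect_saccades()]) for one eye (or
#'   pre-filtered as desired); rows with `NA` direction are ignored.
#' @param n_bins Number of direction bins (default 12).
#' @param min_per_bin Minimum saccades for quartile statistics (default 4).
#' @return A `directional_profile`: data.frame with columns `bin_center_deg`,
#'   `count`, `share`, `amp_q1`..`amp_q4`, `vel_q1`..`vel_q4`, `sparse`;
#'   attribute `"eye"` records the eye label when unique.
#' @export
bin_directions <- function(saccades, n_bins = 12, min_per_bin = 4) {
  stopifnot(n_bins >= 2)
  width <- 360 / n_bins
  centers <- (seq_len(n_bins) - 1) * width
  dirs <- saccades$direction
  keep <- is.finite(dirs)
  if (!any(keep)) {
    out <- data.frame(bin_center_deg = centers, count = 0L, share = NA_real_,
                      amp_q1 = NA_real_, amp_q2 = NA_real_,
                      amp_q3 = NA_real_, amp_q4 = NA_real_,
                      vel_q1 = NA_real_, vel_q2 = NA_real_,
                      vel_q3 = NA_real_, vel_q4 = NA_real_,
                      sparse = TRUE)
    attr(out, "empty") <- TRUE
    class(out) <- c("directional_profile", "data.frame")
    return(out)
  }
  s <- saccades[keep, , drop = FALSE]
  # edge ties (e.g. exactly 15 deg) land in the counterclockwise bin
  bin <- floor(((s$direction + width / 2) %% 360) / width) + 1L
  n <- nrow(s)
  rows <- lapply(seq_len(n_bins), function(b) {
    idx <- which(bin == b)
    cnt <- length(idx)
    sparse <- cnt < min_per_bin
    amp_q <- if (sparse) rep(NA_real_, 4) else quartile_stratify(s$amplitude[idx])
    vel_q <- if (sparse) rep(NA_real_, 4) else quartile_stratify(s$peak_velocity[idx])
    data.frame(bin_center_deg = centers[b], count = cnt, share = cnt / n,
               amp_q1 = amp_q[1], amp_q2 = amp_q[2], amp_q3 = amp_q[3],
               amp_q4 = amp_q[4],
               vel_q1 = vel_q[1], vel_q2 = vel_q[2], vel_q3 = vel_q[3],
               vel_q4 = vel_q[4], sparse = sparse)
  })
  out <- do.call(rbind, rows)
  attr(out, "eye") <- if (length(unique(s$eye)) == 1) s$eye[1] else NA_character_
  attr(out, "empty") <- FALSE
  class(out) <- c("directional_profile", "data.frame")
  out
}

#' Quartile-stratified means
#'
#' Splits the values at their 25th/50th/75th percentiles and returns the mean
#' within each quartile, so that each quartile can carry its own normative
#' boundaries downstream.
#'
#' @param values Numeric vector, length >= 4.
#' @return Numeric length-4 vector of within-quartile means (non-decreasing).
#' @export
quartile_stratify <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 4) stop("need at least 4 values for quartile strata")
  if (max(values) == min(values)) return(rep(values[1], 4))
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  grp <- findInterval(values, qs, left.open = TRUE) + 1L
  vapply(1:4, function(g) {
    v <- values[grp == g]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
}

#' Normalise a directional profile against normative profiles
#'
#' Per bin and per statistic (share, quartile amplitudes and velocities), the
#' observation is converted to a modified z-score against the distribution of
#' the same bin/statistic across a set of normative profiles; |z| >= 2 is
#' flagged abnormal. Sparse bins propagate `NA`, never z = 0.
#'
#' @param profile A [bin_directions()] profile.
#' @param normative_profiles List of >= 10 profiles with identical binning.
#' @param cutoff Abnormality cutoff on |z| (default 2).
#' @return The profile with added `z_<stat>` and `flag_<stat>` columns.
#' @export
normalize_profile <- function(profile, normative_profiles, cutoff = 2) {
  stopifnot(inherits(profile, "directional_profile"))
  if (length(normative_profiles) < 10) {
    stop("need at least 10 normative profiles")
  }
  same_bins <- vapply(normative_profiles, function(p) {
    nrow(p) == nrow(profile) &&
      all(p$bin_center_deg == profile$bin_center_deg)
  }, logical(1))
  if (!all(same_bins)) stop("binning mismatch between profile and normative set")
  stats_cols <- c("share", paste0("amp_q", 1:4), paste0("vel_q", 1:4))
  for (col in stats_cols) {
    norm_mat <- vapply(normative_profiles, function(p) p[[col]],
                       numeric(nrow(profile)))
    z <- vapply(seq_len(nrow(profile)), function(b) {
      x <- profile[[col]][b]
      ref <- norm_mat[b, ]
      ref <- ref[is.finite(ref)]
      if (!is.finite(x) || length(ref) < 10) return(NA_real_)
      med <- stats::median(ref)
      mad <- stats::median(abs(ref - med))
      if (mad <= 0) return(NA_real_)
      modified_z(x, med, mad)
    }, numeric(1))
    profile[[paste0("z_", col)]] <- z
    profile[[paste0("flag_", col)]] <- ifelse(is.na(z), NA, abs(z) >= cutoff)
  }
  profile
}
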