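#' Build an age-matched normative reference
#'
#' For each feature (column), the robust location and scale over the control
#' subjects retained by the age filter: the median (MED) and the median
#' absolute deviation from the median (MAD). Together with the consistency
#' constant 1.486 these standardise observations as modified z-scores,
#' robustly to outlying controls. Features whose MAD is zero are flagged
#' unusable. A `scale = "mean_abs"` switch substitutes the mean absolute
#' deviation from the median for the MAD.
#'
#' @param control_features Numeric matrix or data.frame, one row per control
#'   subject, one column per feature.
#' @param ages Optional numeric vector of control ages (years).
#' @param age_min Minimum age retained, years (`NULL` = no filter). Used
#'   e.g. to build an over-50 control subgroup for comparison with older
#'   patient groups.
#' @param group_label Label stored with the reference.
#' @param scale `"mad"` (default, median absolute deviation) or
#'   `"mean_abs"` (mean absolute deviation from the median).
#' @return A `normative_reference`: list with `med`, `mad`, `usable` (named
#'   per feature), `n`, `age_min`, `group_label`, `scale`.
#' @export
build_reference <- function(control_features, ages = NULL, age_min = NULL,
                            group_label = "controls",
                            scale = c("mad", "mean_abs")) {
  scale <- match.arg(scale)
  x <- as.matrix(control_features)
  if (!is.null(age_min)) {
    if (is.null(ages) || length(ages) != nrow(x)) {
      stop("age filtering requires one age per control row")
    }
    x <- x[ages >= age_min, , drop = FALSE]
  }
  if (nrow(x) < 10) stop("need at least 10 controls after age filtering")
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  mad <- apply(x, 2, function(col) {
    dev <- abs(col - stats::median(col, na.rm = TRUE))
    if (scale == "mad") stats::median(dev, na.rm = TRUE)
    else mean(dev, na.rm = TRUE)
  })
  structure(list(med = med, mad = mad, usable = mad > 0,
                 n = nrow(x), age_min = age_min,
                 group_label = group_label, scale = scale),
            class = "normative_reference")
}

#' Modified z-score
#'
#' Robust standardisation of an observation against a normative median and
#' median absolute deviation: `z = (x - MED) / (1.486 * MAD)`. The constant
#' 1.486 makes the denominator a consistent estimate of the Gaussian
#' standard deviation.
#'
#' @param x Observed value(s).
#' @param med Normative median.
#' @param mad Normative median absolute deviation; must be positive.
#' @return Modified z-score(s).
#' @export
modified_z <- function(x, med, mad) {
  if (any(mad <= 0)) stop("MAD must be positive")
  (x - med) / (1.486 * mad)
}

#' Flag abnormal z-scores
#'
#' A feature is abnormal when it deviates by 2 or more (robust) standard
#' deviations from the normative value, i.e. `|z| >= cutoff`.
#'
#' @param z Modified z-score(s).
#' @param cutoff Abnormality cutoff (default 2).
#' @return Logical, `TRUE` where abnormal.
#' @export
flag_abnormal <- function(z, cutoff = 2) {
  abs(z) >= cutoff
}

#' Score a subject's features against a normative reference
#'
#' @param features Named numeric vector (feature -> value), keys matching
#'   the reference.
#' @param reference A [build_reference()] result.
#' @param cutoff Abnormality cutoff on |z| (default 2).
#' @return Data.frame `feature`, `value`, `z`, `abnormal` (`NA` rows where
#'   the feature is missing or the reference MAD is zero).
#' @export
z_score_report <- function(features, reference, cutoff = 2) {
  stopifnot(inherits(reference, "normative_reference"))
  keys <- names(reference$med)
  z <- rep(NA_real_, length(keys))
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(features)) next
    x <- features[[k]]
    if (!is.finite(x) || !reference$usable[[k]]) next
    z[i] <- modified_z(x, reference$med[[k]], reference$mad[[k]])
  }
  data.frame(feature = keys, value = unname(features[keys]), z = z,
             abnormal = ifelse(is.na(z), NA, flag_abnormal(z, cutoff)),
             stringsAsFactors = FALSE)
}

#' One-tailed Welch's t-test
#'
#' Welch's t-test for unequal variances with Welch-Satterthwaite degrees of
#' freedom, one-tailed in the stated direction, at significance level
#' `alpha` (default 0.05). Used for patient-versus-control comparisons where
#' group sizes differ substantially.
#'
#' @param group_a,group_b Numeric samples (each n >= 2).
#' @param direction `"a_less"` (alternative: mean of a < mean of b) or
#'   `"a_greater"`.
#' @param alpha Significance level (default 0.05).
#' @return List `t`, `df`, `p`, `significant`.
#' @export
welch_one_tailed <- function(group_a, group_b,
                             direction = c("a_greater", "a_less"),
                             alpha = 0.05) {
  direction <- match.arg(direction)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    stop("zero variance in both groups")
  }
  ht <- stats::t.test(group_a, group_b,
                      alternative = switch(direction, a_greater = "greater",
                                           a_less = "less"),
                      var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, significant = ht$p.value < alpha)
}

#' Compare patient and control feature matrices feature-by-feature
#'
#' Runs [welch_one_tailed()] per feature column. No multiple-testing
#' correction is applied by default; `adjust = "BH"` switches on
#' Benjamini-Hochberg adjustment of the p-values.
#'
#' @param patients,controls Feature matrices (rows = subjects).
#' @param direction Tail direction, per [welch_one_tailed()]; a single value
#'   or one per feature. The default `"a_greater"` encodes
#'   impairment-increasing features (patients exceed controls on lag,
#'   uncertainty, spread, dissimilarity).
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data.frame `feature`, `t`, `df`, `p`, `significant`.
#' @export
group_comparison <- function(patients, controls, direction = "a_greater",
                             alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  feats <- colnames(patients)
  stopifnot(identical(feats, colnames(controls)))
  direction <- rep(direction, length.out = length(feats))
  rows <- lapply(seq_along(feats), function(i) {
    a <- patients[, i]; b <- controls[, i]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    res <- tryCatch(welch_one_tailed(a, b, direction[i], alpha),
                    error = function(e) list(t = NA_real_, df = NA_real_,
                                             p = NA_real_, significant = NA))
    data.frame(feature = feats[i], t = res$t, df = res$df, p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p) & out$p < alpha
  out
}

#' Serialise a normative reference to JSON
#'
#' @param reference A [build_reference()] result.
#' @param path Output path.
#' @export
write_reference <- function(reference, path) {
  stopifnot(inherits(reference, "normative_reference"))
  obj <- list(
    group_label = reference$group_label,
    n = reference$n,
    age_min = if (is.null(reference$age_min)) NA else reference$age_min,
    scale = reference$scale,
    features = lapply(stats::setNames(names(reference$med),
                                      names(reference$med)), function(k) {
      list(med = reference$med[[k]], mad = reference$mad[[k]],
           usable = reference$usable[[k]])
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
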