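#' Fit the saccadic main sequence
#'
#' Least-squares fit of the saturating-exponential main sequence
#' `V(A) = V_max * (1 - exp(-A / A_63))` relating saccade amplitude `A`
#' (degrees) to peak velocity `V` (deg/s). `A_63` is the amplitude at which
#' velocity reaches 63% of `V_max`. A log-log power-law alternative
#' `V = k * A^b` is available via `form = "power"`.
#'
#' @param saccades Data.frame with columns `amplitude` and `peak_velocity`
#'   (e.g. from [detect_saccades()]), or two numeric vectors via `amplitude`
#'   and `peak_velocity` arguments.
#' @param form `"exponential"` (default) or `"power"`.
#' @return A `main_sequence_fit`: list with `form`, `V_max`, `A_63` (or
#'   `k`, `b`), `sigma` (residual SD on the velocity scale), `n_saccades`,
#'   `boundary` flag (degenerate fit pinned at a parameter bound) and the
#'   data range.
#' @export
fit_main_sequence <- function(saccades, form = c("exponential", "power")) {
  form <- match.arg(form)
  A <- saccades$amplitude
  V <- saccades$peak_velocity
  keep <- is.finite(A) & is.finite(V) & A > 0
  A <- A[keep]; V <- V[keep]
  if (length(A) < 10) stop("need at least 10 saccades with positive amplitude")
  if (stats::sd(A) == 0) stop("degenerate data: all amplitudes identical")

  if (form == "power") {
    lf <- stats::lm(log(V) ~ log(A))
    fit <- list(form = "power",
                k = exp(unname(stats::coef(lf)[1])),
                b = unname(stats::coef(lf)[2]),
                sigma = stats::sd(V - exp(stats::fitted(lf))),
                n_saccades = length(A), boundary = FALSE,
                amplitude_range = range(A))
    class(fit) <- "main_sequence_fit"
    return(fit)
  }

  # Separable least squares: conditional on A_63 the model is linear in
  # V_max (V_max = <V, f> / <f, f> with f = 1 - exp(-A / A_63)), so the fit
  # reduces to a 1-D profile over A_63 — robust where a joint Newton-type
  # search can hit singular gradients (flat or saturated data).
  sse_at <- function(log_a63) {
    f <- 1 - exp(-A / exp(log_a63))
    v <- sum(V * f) / sum(f * f)
    sum((V - v * f)^2)
  }
  lo <- log(min(A) / 100)
  hi <- log(max(A) * 20)
  grid <- seq(lo, hi, length.out = 60)
  sse_grid <- vapply(grid, sse_at, numeric(1))
  g0 <- which.min(sse_grid)
  opt <- stats::optimize(sse_at,
                         c(grid[max(1, g0 - 1)], grid[min(60, g0 + 1)]),
                         tol = 1e-10)
  a63 <- exp(opt$minimum)
  f <- 1 - exp(-A / a63)
  vmax <- sum(V * f) / sum(f * f)
  resid <- V - vmax * f
  fit <- list(form = "exponential",
              V_max = vmax, A_63 = a63,
              sigma = stats::sd(resid),
              n_saccades = length(A),
              boundary = opt$minimum <= lo + 1e-6 ||
                g0 == 1 || g0 == 60,
              amplitude_range = range(A))
  class(fit) <- "main_sequence_fit"
  fit
}

#' Predicted peak velocity under a main-sequence fit
#'
#' @param fit A [fit_main_sequence()] result.
#' @param amplitude Amplitudes, degrees.
#' @return Predicted peak velocities, deg/s.
#' @export
predict_main_sequence <- function(fit, amplitude) {
  stopifnot(inherits(fit, "main_sequence_fit"))
  if (fit$form == "power") {
    fit$k * amplitude^fit$b
  } else {
    fit$V_max * (1 - exp(-amplitude / fit$A_63))
  }
}

#' Pointwise prediction band for new saccades
#'
#' A pointwise prediction interval for the peak velocity of a new saccade at
#' each grid amplitude, from the residual distribution on the velocity scale:
#' Gaussian residuals, by default with amplitude-independent variance
#' (`heteroscedastic = TRUE` scales the residual SD with the fitted value).
#'
#' @param fit A [fit_main_sequence()] result.
#' @param amplitude_grid Amplitudes at which to evaluate the band.
#' @param level Coverage level in (0, 1), default 0.95.
#' @param heteroscedastic If `TRUE`, residual SD proportional to the fitted
#'   velocity (scaled so the average matches `fit$sigma`).
#' @return Data.frame `amplitude`, `fit`, `lower`, `upper`.
#' @export
prediction_interval <- function(fit, amplitude_grid, level = 0.95,
                                heteroscedastic = FALSE) {
  stopifnot(inherits(fit, "main_sequence_fit"))
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  mu <- predict_main_sequence(fit, amplitude_grid)
  df <- max(fit$n_saccades - 2, 1)
  q <- stats::qt(1 - (1 - level) / 2, df)
  s <- if (heteroscedastic) {
    fit$sigma * mu / mean(mu)
  } else {
    rep(fit$sigma, length(mu))
  }
  half <- q * s * sqrt(1 + 1 / fit$n_saccades)
  data.frame(amplitude = amplitude_grid, fit = mu,
             lower = mu - half, upper = mu + half)
}

#' Do two main-sequence prediction bands overlap?
#'
#' Geometric band-intersection criterion: the groups are considered
#' indistinguishable when their prediction bands intersect at every grid
#' amplitude. Also reports the fraction of grid points at which the bands
#' intersect.
#'
#' @param fit_a,fit_b Two [fit_main_sequence()] results.
#' @param amplitude_grid Common amplitude grid; must lie within both fits'
#'   amplitude supports.
#' @param level Band level (default 0.95).
#' @return List `overlap` (logical: all grid points intersect) and
#'   `fraction` (share of grid points with intersection).
#' @export
bands_overlap <- function(fit_a, fit_b, amplitude_grid, level = 0.95) {
  sup_a <- fit_a$amplitude_range
  sup_b <- fit_b$amplitude_range
  lo <- max(sup_a[1], sup_b[1]); hi <- min(sup_a[2], sup_b[2])
  if (lo > hi) stop("disjoint amplitude supports")
  grid <- amplitude_grid[amplitude_grid >= lo & amplitude_grid <= hi]
  if (!length(grid)) stop("amplitude grid does not intersect the common support")
  ba <- prediction_interval(fit_a, grid, level)
  bb <- prediction_interval(fit_b, grid, level)
  inter <- pmax(ba$lower, bb$lower) <= pmin(ba$upper, bb$upper)
  list(overlap = all(inter), fraction = mean(inter))
}
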