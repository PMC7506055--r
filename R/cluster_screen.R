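#' PCA dimensionality reduction to a variance target
#'
#' Principal component analysis of the subject-by-feature matrix, retaining
#' the smallest number of components whose cumulative explained variance
#' reaches the target (default 95%). Features are z-scored per column by
#' default (`standardize = FALSE` keeps raw scales); zero-variance columns
#' are dropped before scaling. Missing entries are median-imputed per column
#' (`impute = "median"`) or subjects with any missing feature dropped
#' (`impute = "complete"`); the choice and the number of imputed cells are
#' recorded on the result.
#'
#' @param feature_matrix Numeric matrix, one row per subject.
#' @param variance_target Cumulative explained-variance target in (0, 1\].
#' @param standardize Z-score columns first (default `TRUE`).
#' @param impute `"median"` (default) or `"complete"`.
#' @return List `components` (retained scores, n x n_retained),
#'   `n_retained`, `variance_explained`, `n_imputed`, `dropped_subjects`,
#'   `sdev` (all component SDs).
#' @export
pca_reduce <- function(feature_matrix, variance_target = 0.95,
                       standardize = TRUE, impute = c("median", "complete")) {
  impute <- match.arg(impute)
  x <- as.matrix(feature_matrix)
  dropped <- character(0)
  n_imputed <- 0L
  if (anyNA(x)) {
    if (impute == "complete") {
      keep <- stats::complete.cases(x)
      dropped <- rownames(x)[!keep]
      x <- x[keep, , drop = FALSE]
    } else {
      for (j in seq_len(ncol(x))) {
        miss <- is.na(x[, j])
        if (any(miss)) {
          x[miss, j] <- stats::median(x[, j], na.rm = TRUE)
          n_imputed <- n_imputed + sum(miss)
        }
      }
    }
  }
  keep_col <- apply(x, 2, function(col) stats::sd(col) > 0)
  x <- x[, keep_col, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  cum <- cumsum(var_frac)
  n_ret <- which(cum >= variance_target - 1e-12)[1]
  if (is.na(n_ret)) n_ret <- length(cum)
  list(components = pc$x[, seq_len(n_ret), drop = FALSE],
       n_retained = n_ret,
       variance_explained = cum[n_ret],
       n_imputed = n_imputed,
       dropped_subjects = dropped,
       sdev = pc$sdev)
}

#' 2-D t-SNE embedding of retained components
#'
#' t-distributed stochastic neighbour embedding of the retained principal
#' components into two dimensions for clustering and display; similar
#' subjects land nearby. Deterministic under the given seed.
#'
#' @param components Numeric matrix (subjects x components).
#' @param seed Integer seed.
#' @param perplexity t-SNE perplexity (default 10, suited to cohorts of
#'   ~70 subjects); requires `nrow >= 3 * perplexity + 1`.
#' @param max_iter Gradient-descent iterations (default 500).
#' @return Numeric matrix (subjects x 2).
#' @export
embed_2d <- function(components, seed = 1L, perplexity = 10,
                     max_iter = 500) {
  n <- nrow(components)
  if (n < 3 * perplexity + 1) {
    stop("too few subjects for this perplexity (need > 3 * perplexity)")
  }
  set.seed(as.integer(seed))
  fit <- Rtsne::Rtsne(as.matrix(components), dims = 2,
                      perplexity = perplexity, pca = FALSE,
                      max_iter = max_iter, verbose = FALSE,
                      check_duplicates = FALSE)
  emb <- fit$Y
  rownames(emb) <- rownames(components)
  emb
}

# k-means++ seeding: first centre uniform, subsequent centres with
# probability proportional to the squared distance to the nearest centre.
kmeanspp_centers <- function(points, k) {
  n <- nrow(points)
  centers <- matrix(NA_real_, k, ncol(points))
  i <- sample.int(n, 1)
  centers[1, ] <- points[i, ]
  if (k == 1) return(centers)
  d2 <- rowSums((points - matrix(centers[1, ], n, ncol(points),
                                 byrow = TRUE))^2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      i <- sample.int(n, 1)
    } else {
      i <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- points[i, ]
    d2 <- pmin(d2, rowSums((points - matrix(centers[j, ], n, ncol(points),
                                            byrow = TRUE))^2))
  }
  centers
}

#' K-means clustering with k-means++ restarts
#'
#' Lloyd's algorithm started from k-means++ centres, best of `restarts` runs
#' by total within-cluster sum of squares; deterministic under the seed.
#'
#' @param points Numeric matrix (subjects x dims).
#' @param k Number of clusters (1 <= k <= n).
#' @param seed Integer seed.
#' @param restarts Number of restarts (default 10).
#' @return List `assignments`, `centroids`, `wss` (total within-cluster sum
#'   of squares).
#' @export
kmeans_cluster <- function(points, k, seed = 1L, restarts = 10) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k > n) stop("k must not exceed the number of points")
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- kmeanspp_centers(points, k)
    init <- init[!duplicated(init), , drop = FALSE]
    km <- suppressWarnings(
      stats::kmeans(points, centers = init, iter.max = 100,
                    algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  list(assignments = best$cluster, centroids = best$centers,
       wss = best$tot.withinss)
}

#' Choose k by the elbow of the WSS curve
#'
#' Computes the within-cluster sum of squares for each candidate k (best of
#' several k-means restarts) and selects the k whose point on the normalised
#' WSS curve lies farthest from the chord joining the curve's endpoints.
#' A degenerate curve (WSS already ~zero at the smallest candidate k, as
#' for coincident points) has no elbow: the smallest candidate is returned
#' with `no_elbow = TRUE`. For structureless but non-degenerate data the
#' WSS still decays roughly as 1/k, so this criterion -- like any WSS-based
#' rule -- cannot attest the absence of cluster structure.
#'
#' @param points Numeric matrix.
#' @param k_range Candidate k values (default 1:10, clipped to n - 1).
#' @param seed Integer seed.
#' @param restarts K-means restarts per k (default 10).
#' @return List `wss_curve` (data.frame `k`, `wss`), `k_selected`,
#'   `no_elbow`.
#' @export
elbow_select_k <- function(points, k_range = 1:10, seed = 1L,
                           restarts = 10) {
  points <- as.matrix(points)
  k_range <- sort(unique(k_range[k_range >= 1 & k_range <= nrow(points) - 1]))
  if (!length(k_range)) stop("empty k range")
  wss <- vapply(seq_along(k_range), function(i) {
    kmeans_cluster(points, k_range[i], seed = seed + i, restarts = restarts)$wss
  }, numeric(1))
  wss <- cummin(wss)  # guard against rare restart non-monotonicity
  tss <- sum(scale(points, scale = FALSE)^2)
  if (length(k_range) < 3 || wss[1] <= 1e-12 * max(tss, 1)) {
    return(list(wss_curve = data.frame(k = k_range, wss = wss),
                k_selected = k_range[1], no_elbow = TRUE))
  }
  # normalised chord distance ("knee" criterion)
  u <- (k_range - k_range[1]) / diff(range(k_range))
  v <- (wss - wss[length(wss)]) / (wss[1] - wss[length(wss)])
  dist <- abs(v - (1 - u)) / sqrt(2)
  list(wss_curve = data.frame(k = k_range, wss = wss),
       k_selected = k_range[which.max(dist)],
       no_elbow = FALSE)
}

#' Unsupervised cohort screening pipeline
#'
#' The full screening chain: per-feature standardised PCA to the
#' explained-variance target, 2-D t-SNE embedding of the retained
#' components, elbow-method choice of k on the within-cluster sum of
#' squares, and k-means clustering of the embedded points. Reproducible
#' from the single top-level seed.
#'
#' @param feature_matrix Subjects x features matrix (e.g. [stp_wide()]).
#' @param variance_target PCA explained-variance target (default 0.95).
#' @param perplexity t-SNE perplexity (default 10).
#' @param k_range Candidate cluster counts (default 1:10).
#' @param k Fixed cluster count; overrides the elbow choice when given.
#' @param seed Integer seed.
#' @param standardize,impute Passed to [pca_reduce()].
#' @return A `screen_result`: list with `n_components_retained`,
#'   `variance_explained`, `embedding`, `wss_curve`, `k_selected`,
#'   `assignments`, `centroids`, `n_imputed`, `dropped_subjects`, `seed`.
#' @export
screen_cohort <- function(feature_matrix, variance_target = 0.95,
                          perplexity = 10, k_range = 1:10, k = NULL,
                          seed = 1L, standardize = TRUE,
                          impute = c("median", "complete")) {
  red <- pca_reduce(feature_matrix, variance_target,
                    standardize = standardize, impute = impute)
  emb <- embed_2d(red$components, seed = seed, perplexity = perplexity)
  sel <- elbow_select_k(emb, k_range = k_range, seed = seed + 1000L)
  k_use <- if (is.null(k)) sel$k_selected else k
  cl <- kmeans_cluster(emb, k_use, seed = seed + 2000L)
  structure(list(
    n_components_retained = red$n_retained,
    variance_explained = red$variance_explained,
    embedding = emb,
    wss_curve = sel$wss_curve,
    k_selected = k_use,
    no_elbow = sel$no_elbow,
    assignments = cl$assignments,
    centroids = cl$centroids,
    n_imputed = red$n_imputed,
    dropped_subjects = red$dropped_subjects,
    seed = as.integer(seed)
  ), class = "screen_result")
}

#' Serialise a screen result to JSON (plus assignment table)
#'
#' @param result A [screen_cohort()] result.
#' @param path JSON output path; an `_assignments.csv` table is written
#'   alongside.
#' @export
write_screen_result <- function(result, path) {
  stopifnot(inherits(result, "screen_result"))
  obj <- list(
    n_components_retained = result$n_components_retained,
    variance_explained = result$variance_explained,
    k_selected = result$k_selected,
    no_elbow = result$no_elbow,
    seed = result$seed,
    wss_curve = result$wss_curve
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  tab <- data.frame(subject_id = rownames(result$embedding),
                    tsne_1 = result$embedding[, 1],
                    tsne_2 = result$embedding[, 2],
                    cluster = result$assignments)
  utils::write.csv(tab, sub("\\.json$", "_assignments.csv", path),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
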