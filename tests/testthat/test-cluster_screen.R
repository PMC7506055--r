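test_that("PCA retains the smallest component set reaching the target", {
  set.seed(1)
  # data lying in a 3-D subspace plus tiny noise
  basis <- matrix(rnorm(30), 10, 3)
  scores <- matrix(rnorm(60 * 3, sd = 5), 60, 3)
  x <- scores %*% t(basis) + matrix(rnorm(600, sd = 1e-4), 60, 10)
  red <- pca_reduce(x, 0.95, standardize = FALSE)
  expect_equal(red$n_retained, 3)
  expect_gte(red$variance_explained, 0.95)

  # target 1 retains the full rank
  full <- pca_reduce(x, 1.0, standardize = FALSE)
  expect_equal(full$n_retained, sum(full$sdev > 1e-8 * full$sdev[1]))

  # duplicating every feature column changes nothing structural
  dup <- pca_reduce(cbind(x, x), 0.95, standardize = FALSE)
  expect_equal(dup$n_retained, red$n_retained)

  # missing-value policies
  xm <- x; xm[3, 2] <- NA
  med <- pca_reduce(xm, 0.95, standardize = FALSE)
  expect_equal(med$n_imputed, 1L)
  rownames(xm) <- paste0("s", 1:60)
  cc <- pca_reduce(xm, 0.95, standardize = FALSE, impute = "complete")
  expect_identical(cc$dropped_subjects, "s3")
})

test_that("t-SNE embedding is seeded, guarded, and separates structure", {
  set.seed(2)
  X <- rbind(matrix(rnorm(30 * 5), 30, 5),
             matrix(rnorm(30 * 5), 30, 5) + 10)  # 10-sigma separation
  e1 <- embed_2d(X, seed = 9, perplexity = 8, max_iter = 300)
  e2 <- embed_2d(X, seed = 9, perplexity = 8, max_iter = 300)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(60, 2))
  # 70 subjects support perplexity 10 but not 30
  X70 <- matrix(rnorm(70 * 3), 70, 3)
  expect_silent(e70 <- embed_2d(X70, seed = 1, perplexity = 10,
                                max_iter = 100))
  expect_error(embed_2d(X70, seed = 1, perplexity = 30), "perplexity")

  sep_ok <- vapply(1:20, function(s) {
    set.seed(s)
    Xs <- rbind(matrix(rnorm(150), 30, 5), matrix(rnorm(150), 30, 5) + 10)
    emb <- embed_2d(Xs, seed = s, perplexity = 8, max_iter = 300)
    d_inter <- sqrt(sum((colMeans(emb[1:30, ]) - colMeans(emb[31:60, ]))^2))
    d_inter > mean(c(apply(emb[1:30, ], 2, sd), apply(emb[31:60, ], 2, sd)))
  }, logical(1))
  expect_gte(sum(sep_ok), 18)
})

test_that("k-means honours its anchors and recovers planted partitions", {
  set.seed(3)
  pts <- matrix(rnorm(80), 40, 2)
  one <- kmeans_cluster(pts, 1, seed = 1)
  expect_equal(as.numeric(one$centroids), colMeans(pts), tolerance = 1e-9)
  expect_equal(one$wss, sum(scale(pts, scale = FALSE)^2), tolerance = 1e-9)
  alln <- kmeans_cluster(pts, nrow(pts), seed = 1)
  expect_equal(alln$wss, 0, tolerance = 1e-9)
  expect_error(kmeans_cluster(pts, 41, seed = 1), "exceed")

  ari <- vapply(1:10, function(s) {
    fx <- planted_clusters(seed = s, k = 3)
    cl <- kmeans_cluster(fx$points, 3, seed = s)
    mclust::adjustedRandIndex(cl$assignments, fx$labels)
  }, numeric(1))
  expect_true(all(ari >= 0.95))
})

test_that("the WSS elbow finds planted structure and degrades gracefully", {
  fx <- planted_clusters(seed = 11, k = 5)
  sel <- elbow_select_k(fx$points, 1:10, seed = 11)
  expect_equal(sel$k_selected, 5)
  expect_true(all(diff(sel$wss_curve$wss) <= 1e-9))
  expect_error(elbow_select_k(fx$points, integer(0)), "empty")

  # coincident points: WSS is zero everywhere, so there is no elbow
  tight <- matrix(1, 50, 2)
  flat <- elbow_select_k(tight, 1:6, seed = 12)
  expect_true(flat$no_elbow)
  expect_equal(flat$k_selected, 1)
})

test_that("the screening pipeline is reproducible end to end", {
  set.seed(4)
  X <- rbind(matrix(rnorm(40 * 8), 40, 8),
             matrix(rnorm(31 * 8), 31, 8) + 6)
  rownames(X) <- paste0("s", 1:71)
  r1 <- screen_cohort(X, seed = 5, perplexity = 10)
  r2 <- screen_cohort(X, seed = 5, perplexity = 10)
  expect_identical(r1$assignments, r2$assignments)
  expect_identical(r1$embedding, r2$embedding)
  expect_gte(r1$variance_explained, 0.95)
  expect_length(r1$assignments, 71)

  # the two planted groups land in distinct clusters
  tab <- table(rep(c("a", "b"), c(40, 31)), r1$assignments)
  purity <- sum(apply(tab, 2, max)) / 71
  expect_gte(purity, 0.9)

  path <- withr::local_tempfile(fileext = ".json")
  write_screen_result(r1, path)
  blob <- jsonlite::read_json(path)
  expect_equal(blob$k_selected, r1$k_selected)
  expect_true(file.exists(sub("\\.json$", "_assignments.csv", path)))
})
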