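test_that("K = 1 reduces to the observed column means", {
  X <- matrix(c(1, 2, NA, 3, 0, 1), 3, 2)
  asg <- kmeans_cluster(X, 1, n_restarts = 2, seed = 1)
  expect_equal(unname(asg$cluster), rep(1L, 3))
  expect_equal(unname(asg$centroids[1, ]),
               c(mean(c(1, 2)), mean(c(3, 0, 1))))
})

test_that("planted partitions are recovered exactly at low noise", {
  labels <- rep(1:4, times = c(40, 30, 20, 10))
  X <- blob_scores(labels, noise_sd = 0.3, seed = 2)
  asg <- kmeans_cluster(X, 4, seed = 9)
  expect_equal(rand_index(asg$cluster, labels), 1)
  expect_equal(sort(asg$sizes), sort(c(40L, 30L, 20L, 10L)))
})

test_that("the Lloyd objective never increases across iterations", {
  set.seed(33)
  for (rep in 1:10) {
    X <- matrix(rnorm(60 * 8), 60, 8)
    X[sample(length(X), 40)] <- NA  # exercise missing-aware distances
    asg <- kmeans_cluster(X, 3, n_restarts = 1, seed = rep)
    expect_true(all(diff(asg$objective_trace) <= 1e-8))
  }
})

test_that("row order does not change the recovered partition", {
  labels <- rep(1:4, each = 15)
  X <- blob_scores(labels, seed = 4)
  asg1 <- kmeans_cluster(X, 4, seed = 5)
  perm <- sample(nrow(X))
  asg2 <- kmeans_cluster(X[perm, ], 4, seed = 5)
  expect_equal(rand_index(asg1$cluster[rownames(X)[perm]], asg2$cluster), 1)
})

test_that("invalid K is rejected", {
  X <- blob_scores(rep(1:4, each = 3))
  expect_error(kmeans_cluster(X, 0), "K must be")
  expect_error(kmeans_cluster(X, nrow(X) + 1), "K must be")
})

test_that("the figure-of-merit curve is nonnegative and zero for constant data", {
  Xc <- matrix(2, 30, 6)
  fc <- fom_curve(Xc, 2:4, seed = 1, n_restarts = 1)
  expect_equal(fc$fom, rep(0, 3))
  X <- matrix(rnorm(30 * 6), 30, 6)
  fc2 <- fom_curve(X, 2:4, seed = 1, n_restarts = 1)
  expect_true(all(fc2$fom >= 0))
})

test_that("the adjusted FOM elbow lands on the planted cluster number", {
  hits <- vapply(1:10, function(s) {
    X <- blob_scores(rep(1:4, each = 25), noise_sd = 0.3, seed = 100 + s)
    fc <- fom_curve(X, 1:6, seed = s, n_restarts = 2, max_iter = 30)
    fom_elbow(fc)
  }, numeric(1))
  expect_gte(sum(hits == 4), 8)
})

test_that("PCA projection behaves on degenerate and full-rank inputs", {
  # points on a line: first component carries essentially all variance
  t <- seq(-3, 3, length.out = 40)
  line <- cbind(t, 2 * t) + matrix(rnorm(80, 0, 1e-6), 40, 2)
  pc <- pca_project(line, 2)
  expect_gte(pc$explained[1], 0.999)
  # projected scores of centered data have zero column means
  expect_lt(max(abs(colMeans(pc$scores))), 1e-10)
  # full-rank reconstruction is exact
  X <- matrix(rnorm(50 * 5), 50, 5)
  pc <- pca_project(X, 5)
  recon <- pc$scores %*% t(pc$rotation) +
    matrix(pc$center, 50, 5, byrow = TRUE)
  expect_lt(max(abs(recon - X)), 1e-8)
})

test_that("cluster names follow severity rank and survive relabelling", {
  labels <- rep(1:2, each = 10)
  X <- rbind(matrix(2.5, 10, 6), matrix(1.0, 10, 6)) +
    matrix(rnorm(120, 0, 0.05), 20, 6)
  rownames(X) <- sprintf("c%02d", 1:20)
  asg <- name_clusters(kmeans_cluster(X, 2, seed = 3), X)
  severe_cluster <- asg$cluster[["c01"]]
  expect_equal(asg$names[severe_cluster], "rank1")

  # K = 4 gets the conventional labels, most to least severe
  labels4 <- rep(1:4, each = 10)
  X4 <- blob_scores(labels4, seed = 6)
  asg4 <- name_clusters(kmeans_cluster(X4, 4, seed = 7), X4)
  sev <- vapply(1:4, function(k)
    mean(X4[asg4$cluster == k, ], na.rm = TRUE), numeric(1))
  expect_equal(asg4$names[order(-sev)],
               c("Language-impaired", "Intermediate", "Moderate", "Mild"))

  # permuting cluster indices keeps names attached to the same case sets
  asg_perm <- asg4
  perm <- c(2L, 3L, 4L, 1L)
  asg_perm$cluster <- stats::setNames(perm[asg4$cluster], names(asg4$cluster))
  asg_perm$names <- NULL
  asg_perm <- name_clusters(asg_perm, X4)
  expect_equal(asg_perm$case_names, asg4$case_names)

  # exact severity ties fall back to cluster-index order
  Xt <- matrix(1, 8, 3)
  asgt <- list(K = 2L, cluster = stats::setNames(rep(1:2, 4), paste0("c", 1:8)))
  class(asgt) <- "subtype_assignment"
  asgt <- name_clusters(asgt, Xt)
  expect_equal(asgt$names, c("rank1", "rank2"))
})
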