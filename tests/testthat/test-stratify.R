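# Classical PCA, ALS-PCA with missing data, Tracy-Widom component
# selection, k-medoids and the Gap statistic, stratification assembly.

test_that("classical PCA basics: rank, trace, translation invariance", {
  set.seed(41)
  u <- rnorm(30); v <- rnorm(8)
  X <- tcrossprod(u, v)
  fit <- classical_pca(X, normalize = FALSE)
  expect_gt(fit$eigenvalues[1], 1e-8)
  expect_lt(fit$eigenvalues[2] / fit$eigenvalues[1], 1e-10)
  X2 <- matrix(rnorm(40 * 6), 40, 6)
  f2 <- classical_pca(X2, normalize = FALSE)
  expect_equal(sum(f2$eigenvalues), sum(apply(X2, 2, var)),
               tolerance = 1e-10)
  f3 <- classical_pca(sweep(X2, 2, rnorm(6)), normalize = FALSE)
  expect_equal(f3$eigenvalues, f2$eigenvalues, tolerance = 1e-10)
  expect_equal(abs(f3$scores), abs(f2$scores), tolerance = 1e-8)
})

test_that("PC1 separates the two populations of an S2 panel", {
  ds <- fx_s2_clean()
  pc <- classical_pca(inference_matrix(ds))
  pop1 <- ds$subject_meta$population == 1
  acc <- max(mean((pc$scores[, 1] > 0) == pop1),
             mean((pc$scores[, 1] < 0) == pop1))
  expect_gte(acc, 0.99)
})

test_that("ALS-PCA matches the SVD on complete data", {
  set.seed(42)
  X <- matrix(rnorm(60 * 15), 60, 15) %*% diag(c(5, rep(1, 14)))
  als <- als_pca(X, K = 1)
  sv <- svd(scale(X, scale = FALSE))
  expect_lt(principal_angle(als$right_vectors[, 1], sv$v[, 1]), 1e-6)
  expect_gt(abs(cor(als$scores[, 1], sv$u[, 1])), 1 - 1e-9)
  expect_true(all(als$converged[1]))
})

test_that("ALS-PCA recovers scores from incomplete rank-2 data", {
  set.seed(43)
  n <- 100; p <- 40
  truth <- matrix(rnorm(n * 2), n, 2) %*% diag(c(6, 4)) %*%
    matrix(rnorm(2 * p), 2, p)
  X <- truth + matrix(rnorm(n * p, sd = 0.2), n, p)
  complete <- als_pca(X, K = 2)
  Xm <- X
  Xm[sample(length(X), round(0.05 * length(X)))] <- NA
  incomplete <- als_pca(Xm, K = 2)
  for (k in 1:2)
    expect_gt(abs(cor(complete$scores[, k], incomplete$scores[, k])),
              0.99)
  # degenerate all-zero input: zero component
  z <- als_pca(matrix(0, 10, 5), K = 1)
  expect_true(all(z$scores == 0))
})

test_that("Tracy-Widom counts match the simulated structure", {
  # pure noise: no significant components in most seeds
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    q <- runif(1000, 0.1, 0.9)
    X <- matrix(rbinom(200 * 1000, 2, rep(q, each = 200)), 200, 1000)
    pc <- classical_pca(X)
    if (tracy_widom_count(pc$eigenvalues, 200, 1000) == 0L)
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
  # two populations: exactly one significant axis
  ds <- fx_s2_clean()
  pc <- classical_pca(inference_matrix(ds))
  expect_equal(tracy_widom_count(pc$eigenvalues, 1000, 2000), 1L)
  # three populations: two significant axes
  ds3 <- fx_s4_clean()
  pc3 <- classical_pca(inference_matrix(ds3))
  expect_equal(tracy_widom_count(pc3$eigenvalues, 1000, 2000), 2L)
  expect_error(tracy_widom_count(c(1, 0.5), 1, 10), "n >= 2")
})

test_that("k-medoids matches exhaustive medoid search on small data", {
  pts <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  fit <- kmedoids(pts, 2)
  expect_equal(fit$membership[1], fit$membership[2])
  expect_equal(fit$membership[3], fit$membership[4])
  expect_false(fit$membership[1] == fit$membership[3])
  # exhaustive oracle over all medoid pairs on 8 random points
  set.seed(44)
  pts2 <- matrix(rnorm(16), 8, 2)
  D <- as.matrix(dist(pts2))
  combos <- utils::combn(8, 2)
  objs <- apply(combos, 2, function(md) sum(pmin(D[, md[1]], D[, md[2]])))
  best <- min(objs)
  fit2 <- kmedoids(pts2, 2)
  expect_equal(fit2$objective, best, tolerance = 1e-10)
  # k = n: every point its own medoid
  fit3 <- kmedoids(pts2, 8)
  expect_equal(fit3$objective, 0)
  expect_error(kmedoids(pts2, 0), "k must be")
  # cross-check against the reference PAM implementation at a size
  # beyond the exhaustive path
  set.seed(45)
  big <- rbind(matrix(rnorm(200), 100, 2),
               matrix(rnorm(200, mean = 7), 100, 2))
  ours <- kmedoids(big, 2)
  ref <- cluster::pam(big, 2, pamonce = 0)
  expect_equal(ours$objective, ref$objective[["swap"]] * 200,
               tolerance = 1e-10)
  expect_true(all(table(ours$membership, ref$clustering) %in%
                    c(0, 100)))
})

test_that("the Gap statistic recovers cluster counts", {
  one <- 0L; two <- 0L
  for (s in 1:10) {
    set.seed(s)
    g1 <- matrix(rnorm(150 * 2), 150, 2)
    if (gap_select(g1, K_max = 4, B = 100)$k == 1L) one <- one + 1L
    g2 <- rbind(matrix(rnorm(75 * 2), 75, 2),
                matrix(rnorm(75 * 2, mean = 10), 75, 2))
    if (gap_select(g2, K_max = 4, B = 100)$k == 2L) two <- two + 1L
  }
  expect_gte(one, 8L)
  expect_gte(two, 9L)
  # degenerate identical points
  expect_equal(gap_select(matrix(1, 20, 2), B = 100)$k, 1L)
})

test_that("build_stratification assembles PCs and clusters", {
  ds <- fx_s4_clean()
  X <- inference_matrix(ds)
  m <- build_stratification(X, B = 100, gap_subsample = 250,
                            seed = 45)
  expect_equal(m$n_components, 2L)
  expect_equal(m$cluster_count, 3L)
  # clusters recover the true populations
  tab <- table(m$memberships, ds$subject_meta$population)
  expect_gte(sum(apply(tab, 2, max)) / 1000, 0.99)
  # no flags behaves like plain PCA
  pc <- classical_pca(X)
  expect_equal(abs(m$pcs), abs(pc$scores[, 1:2]), tolerance = 1e-8)
  expect_error(build_stratification(X, rep(TRUE, nrow(X))),
               "all subjects")
})

test_that("admixed PCs carry the ancestry gradient", {
  ds <- fx_admixed()
  pc <- classical_pca(inference_matrix(ds))
  expect_gte(abs(cor(pc$scores[, 1], ds$subject_meta$ancestry)), 0.9)
})

test_that("removing injected outliers restores the leading axis", {
  clean <- fx_s2_clean()
  cont <- fx_s2_out()
  Xc <- inference_matrix(clean)
  Xo <- inference_matrix(cont)
  pc_clean <- classical_pca(Xc)
  inj <- which(cont$subject_meta$outlier)
  pc_rm <- classical_pca(Xo[-inj, ])
  # compare loadings (subject sets differ after removal)
  expect_lt(principal_angle(pc_clean$loadings[, 1],
                            pc_rm$loadings[, 1]), 0.1)
})
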