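# Projection-pursuit robust PCA and the SD/OD outlier diagnostics.

test_that("CR search equals brute force over the candidate set", {
  X <- matrix(c(0, 0, 1, 0.2, 0.3, 1.1), ncol = 2, byrow = TRUE)
  fit <- pp_pca(X, K = 1, algorithm = "cr")
  # oracle: enumerate the candidate directions by hand
  mu <- apply(X, 2, median)
  Xc <- sweep(X, 2, mu)
  cand <- Xc / sqrt(rowSums(Xc^2))
  scales <- apply(cand, 1, function(a) mad(Xc %*% a))
  best <- cand[which.max(scales), ]
  expect_lt(principal_angle(fit$eigenvectors[, 1], best), 1e-10)
  expect_equal(fit$eigenvalues[1], max(scales)^2, tolerance = 1e-10)
})

test_that("with the sd index robust PCA matches classical PCA", {
  set.seed(21)
  X <- matrix(rnorm(200 * 5), 200, 5) %*% diag(c(3, 2, 1.5, 1, 0.5))
  pc1 <- prcomp(X)$rotation[, 1]
  for (alg in c("cr", "grid")) {
    fit <- pp_pca(X, K = 1, algorithm = alg, pp_index = "sd")
    expect_lt(principal_angle(fit$eigenvectors[, 1], pc1), 0.15)
  }
})

test_that("GRID angle converges to the classical axis as cycles grow", {
  set.seed(22)
  X <- matrix(rnorm(400), 200, 2) %*%
    matrix(c(cos(0.6), sin(0.6), -sin(0.6), cos(0.6)), 2) %*%
    diag(c(3, 1)) # first PC at a known oblique angle
  truth <- prcomp(X)$rotation[, 1]
  coarse <- pp_pca(X, K = 1, algorithm = "grid", pp_index = "sd",
                   max_cycles = 1)
  expect_lt(principal_angle(coarse$eigenvectors[, 1], truth), pi / 10)
  fine <- pp_pca(X, K = 1, algorithm = "grid", pp_index = "sd",
                 max_cycles = 12, tol = 0)
  expect_lt(principal_angle(fine$eigenvectors[, 1], truth), 1e-4)
})

test_that("degenerate rank-1 data yield the line direction and truncation", {
  t <- seq(-2, 2, length.out = 11)
  X <- cbind(t, t)
  expect_warning(fit <- pp_pca(X, K = 2, algorithm = "grid",
                               max_cycles = 25),
                 "no remaining scale")
  expect_equal(length(fit$eigenvalues), 1L)
  expect_lt(principal_angle(fit$eigenvectors[, 1], c(1, 1) / sqrt(2)),
            1e-6)
})

test_that("MAD-index GRID resists contamination that shifts classical PCA", {
  set.seed(23)
  n <- 500; p <- 10
  X <- matrix(rnorm(n * p), n, p) %*% diag(c(4, rep(1, p - 1)))
  Xc <- X
  out <- seq_len(25)
  Xc[out, ] <- matrix(rnorm(25 * p, mean = 0, sd = 0.5), 25, p) +
    matrix(rep(c(0, 25, rep(0, p - 2)), each = 25), 25, p)
  # classical PC1 is captured by the outlier axis (e2); the MAD-index
  # direction stays essentially free of it
  expect_gt(abs(prcomp(Xc)$rotation[2, 1]), 0.9)
  expect_lt(abs(pp_pca(Xc, K = 1, algorithm = "grid")$eigenvectors[2, 1]),
            0.3)
})

test_that("eigenvalues are sorted and row permutation is immaterial", {
  set.seed(24)
  X <- matrix(rnorm(80 * 6), 80, 6)
  fit <- pp_pca(X, K = 3, algorithm = "cr")
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  perm <- sample(nrow(X))
  fit_p <- pp_pca(X[perm, ], K = 3, algorithm = "cr")
  expect_equal(fit_p$eigenvalues, fit$eigenvalues, tolerance = 1e-10)
  for (k in 1:3)
    expect_lt(principal_angle(fit_p$eigenvectors[, k],
                              fit$eigenvectors[, k]), 1e-8)
  # scores reproducible from the returned pieces
  mu <- fit$location
  expect_equal(fit$scores,
               sweep(X, 2, mu) %*% fit$eigenvectors, tolerance = 1e-10)
})

test_that("CR robust PCA is orthogonally equivariant", {
  # with a rotation-equivariant center; the coordinatewise median
  # (robust default) is tied to the coordinate system by construction
  set.seed(25)
  X <- matrix(rnorm(60 * 4), 60, 4)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  f1 <- pp_pca(X, K = 3, algorithm = "cr", center = "mean")
  f2 <- pp_pca(X %*% Q, K = 3, algorithm = "cr", center = "mean")
  expect_equal(f1$eigenvalues, f2$eigenvalues, tolerance = 1e-8)
  s1 <- score_distances(f1); s2 <- score_distances(f2)
  expect_equal(s1$sd, s2$sd, tolerance = 1e-8)
  o1 <- orth_distances(X, f1); o2 <- orth_distances(X %*% Q, f2)
  expect_equal(o1$od, o2$od, tolerance = 1e-8)
  for (k in 1:3)
    expect_lt(principal_angle(Q %*% f2$eigenvectors[, k],
                              f1$eigenvectors[, k]), 1e-6)
})

test_that("CR and GRID agree on clean Gaussian eigenvalues", {
  set.seed(26)
  X <- matrix(rnorm(1000 * 6), 1000, 6) %*% diag(c(4, 3, 2, 1, 1, 1))
  e_cr <- pp_pca(X, K = 3, algorithm = "cr")$eigenvalues
  e_gr <- pp_pca(X, K = 3, algorithm = "grid")$eigenvalues
  expect_true(all(abs(e_cr - e_gr) / e_cr < 0.10))
})

test_that("score distances match the closed form and chi-square cutoff", {
  fit <- structure(list(scores = matrix(c(3, 4), 1),
                        eigenvalues = c(9, 16)), class = "pp_pca")
  s <- score_distances(fit)
  expect_equal(s$sd, sqrt(2), tolerance = 1e-12)
  expect_equal(s$cutoff, sqrt(qchisq(0.975, 2)), tolerance = 1e-12)
  expect_equal(s$cutoff, 2.7162, tolerance = 1e-4)
  # sign flip of an eigenvector/scores leaves SD unchanged
  fit2 <- fit; fit2$scores <- -fit2$scores
  expect_equal(score_distances(fit2)$sd, s$sd)
  fit3 <- fit; fit3$eigenvalues <- c(9, 0)
  expect_error(score_distances(fit3), "truncate")
})

test_that("orthogonal distances vanish on complete subspaces", {
  set.seed(27)
  X <- matrix(rnorm(50 * 3), 50, 3)
  fit <- pp_pca(X, K = 3, algorithm = "cr")
  expect_warning(o <- orth_distances(X, fit), "undefined")
  expect_true(all(o$od < 1e-8))
  # data in a 2-dim subspace through the center (symmetric +/- pairs
  # put the coordinatewise median at the origin): OD ~ 0 with K = 2
  B <- qr.Q(qr(matrix(rnorm(15), 5)))[, 1:2]
  Z <- matrix(rnorm(40 * 2), 40, 2)
  X2 <- rbind(Z, -Z) %*% t(B)
  f2 <- pp_pca(X2, K = 2, algorithm = "cr")
  o2 <- suppressWarnings(orth_distances(X2, f2))
  expect_lt(max(o2$od), 1e-8)
})

test_that("the Wilson-Hilferty OD cutoff is calibrated near 2.5%", {
  set.seed(28)
  od <- sqrt(2 * rchisq(1e4, df = 5))
  z <- od^(2 / 3)
  cutoff <- (median(z) + mad(z) * qnorm(0.975))^(3 / 2)
  exceed <- mean(od > cutoff)
  expect_lt(abs(exceed - 0.025), 3 * sqrt(0.025 * 0.975 / 1e4) + 0.003)
})

test_that("outlier classification partitions the four regions", {
  sd <- c(0, 5, 1, 5)
  od <- c(0, 1, 9, 9)
  lab <- classify_outliers(sd, od, sd_cutoff = 3, od_cutoff = 6)
  expect_equal(as.character(lab), c("regular", "A", "B", "C"))
  removal <- which(lab != "regular")
  expect_equal(length(removal),
               sum(lab == "A") + sum(lab == "B") + sum(lab == "C"))
})

test_that("injected subjects are flagged on the contaminated S4 panel", {
  ds <- fx_s4_out()
  dg <- fx_s4_out_diag()
  inj <- which(ds$subject_meta$outlier)
  clean <- setdiff(seq_len(nrow(ds$genotypes)), inj)
  expect_gte(mean(inj %in% dg$flagged), 0.9)
  expect_lte(mean(clean %in% dg$flagged), 0.02)
})
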