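# Classical PCA on outlier-removed genotypes, Tracy-Widom selection of
# the number of components, alternating-least-squares PCA for missing
# data, and k-medoids clustering with Gap-statistic model selection.

#' Classical principal components of a genotype matrix
#'
#' Columns are centered and, with `normalize = TRUE`, scaled by
#' `sqrt(q (1 - q))` where `q` is the column allele-frequency estimate
#' (mean genotype / 2) — the usual normalization for genotype PCA,
#' which puts eigenvalues on the scale required by the Tracy-Widom
#' test.  Constant columns are dropped with a warning when normalizing.
#'
#' @param X numeric matrix without missing values (route matrices with
#'   missing entries through [als_pca()]).
#' @param K number of score columns to return; `NULL` for all.
#' @param normalize use allele-frequency scaling (default `TRUE`).
#' @return List with `scores` (n x K), `eigenvalues` (variances
#'   `d^2/(n-1)` of all components), `loadings`, `center`, `scale`,
#'   and `kept_cols`.
#' @export
classical_pca <- function(X, K = NULL, normalize = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X))
    stop("X has missing values; use als_pca() for incomplete data")
  n <- nrow(X)
  mu <- colMeans(X)
  if (normalize) {
    q <- mu / 2
    sc <- sqrt(q * (1 - q))
    keep <- sc > 0
    if (!all(keep))
      warning(sprintf("dropping %d constant column(s) before PCA",
                      sum(!keep)))
    Xn <- sweep(X[, keep, drop = FALSE], 2, mu[keep])
    Xn <- sweep(Xn, 2, sc[keep], "/")
  } else {
    keep <- rep(TRUE, ncol(X))
    sc <- rep(1, ncol(X))
    Xn <- sweep(X, 2, mu)
  }
  if (is.null(K)) K <- min(n - 1, ncol(Xn))
  if (K > min(n - 1, ncol(Xn))) stop("K must be <= min(n - 1, p)")
  if (ncol(Xn) > 1.5 * n) {
    # wide matrices: eigendecompose the n x n Gram matrix instead of
    # a full SVD; identical spectrum and scores
    ee <- eigen(tcrossprod(Xn), symmetric = TRUE)
    d <- sqrt(pmax(ee$values, 0))
    ev <- ee$values / (n - 1)
    ev[ev < 0] <- 0
    U <- ee$vectors[, seq_len(K), drop = FALSE]
    scores <- U %*% diag(d[seq_len(K)], K, K)
    pos <- d[seq_len(K)] > 0
    loadings <- crossprod(Xn, U)
    loadings[, pos] <- sweep(loadings[, pos, drop = FALSE], 2,
                             d[seq_len(K)][pos], "/")
  } else {
    sv <- svd(Xn)
    ev <- sv$d^2 / (n - 1)
    scores <- sv$u[, seq_len(K), drop = FALSE] %*%
      diag(sv$d[seq_len(K)], K, K)
    loadings <- sv$v[, seq_len(K), drop = FALSE]
  }
  rownames(scores) <- rownames(X)
  list(scores = scores, eigenvalues = ev, loadings = loadings,
       center = mu, scale = sc, kept_cols = which(keep))
}

#' Alternating-least-squares PCA for matrices with missing entries
#'
#' Extracts components one at a time: starting from an initial right
#' vector, rows of the (column-centered) matrix are regressed on it
#' without intercept over their observed entries, then columns on the
#' resulting left vector, alternating until the relative change of the
#' right vector falls below `tol`.  The fitted rank-one term is
#' subtracted from the observed entries and the procedure repeats for
#' the next component.  On complete data this reproduces the SVD of
#' the centered matrix up to sign.
#'
#' @param X numeric matrix, possibly with `NA` entries; every row and
#'   column must have at least one observed value.
#' @param K number of components.
#' @param tol relative-change convergence tolerance.
#' @param max_iter maximum alternations per component.
#' @return List with `scores` (n x K left vectors scaled by the
#'   component magnitude), `right_vectors` (p x K, unit columns),
#'   `center`, and logical `converged` per component.
#' @export
als_pca <- function(X, K = 2, tol = 1e-8, max_iter = 500) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  M <- !is.na(X)
  if (any(rowSums(M) == 0) || any(colSums(M) == 0))
    stop("every row and column needs at least one observed entry")
  mu <- colMeans(X, na.rm = TRUE)
  Xc <- sweep(X, 2, mu)
  X0 <- Xc
  X0[!M] <- 0
  n <- nrow(X0); p <- ncol(X0)
  U <- matrix(0, n, K)
  V <- matrix(0, p, K)
  conv <- logical(K)
  for (k in seq_len(K)) {
    if (max(abs(X0)) < 1e-14) {      # nothing left to fit
      conv[k] <- TRUE
      break
    }
    v <- rep(1 / sqrt(p), p)
    for (it in seq_len(max_iter)) {
      den_u <- drop(M %*% v^2)
      u <- drop(X0 %*% v) / ifelse(den_u > 0, den_u, 1)
      den_v <- drop(crossprod(M, u^2))
      v_new <- drop(crossprod(X0, u)) / ifelse(den_v > 0, den_v, 1)
      nv <- sqrt(sum(v_new^2))
      if (nv == 0) break
      v_new <- v_new / nv
      delta <- min(sqrt(sum((v_new - v)^2)), sqrt(sum((v_new + v)^2)))
      v <- v_new
      if (delta < tol) { conv[k] <- TRUE; break }
    }
    # final left vector against the converged right vector
    den_u <- drop(M %*% v^2)
    u <- drop(X0 %*% v) / ifelse(den_u > 0, den_u, 1)
    U[, k] <- u
    V[, k] <- v
    fit <- tcrossprod(u, v)
    fit[!M] <- 0
    X0 <- X0 - fit
  }
  list(scores = U, right_vectors = V, center = mu, converged = conv)
}

# Tracy-Widom (beta = 1) upper quantiles; Patterson-style thresholds.
tw_quantile <- function(alpha) {
  tab <- c(`0.05` = 0.9793, `0.01` = 2.0234, `0.001` = 3.2724)
  key <- format(alpha)
  if (!key %in% names(tab))
    stop("alpha must be one of 0.05, 0.01, 0.001")
  tab[[key]]
}

#' Number of significant components by sequential Tracy-Widom tests
#'
#' Standardizes the leading eigenvalue of the normalized genotype PCA
#' via the effective-number-of-markers moment estimator and compares it
#' against the Tracy-Widom (beta = 1) quantile; on rejection the
#' eigenvalue is removed and the next one tested.  The count of
#' consecutive rejections from the top estimates the number of
#' structure axes.
#'
#' @param eigenvalues eigenvalues from [classical_pca()] with
#'   `normalize = TRUE` (positive entries are used).
#' @param n,p data dimensions the eigenvalues came from.
#' @param alpha test level: 0.05 (default), 0.01 or 0.001.
#' @return Integer count of significant components.
#' @export
tracy_widom_count <- function(eigenvalues, n, p, alpha = 0.05) {
  if (n < 2 || p < 2) stop("need n >= 2 and p >= 2")
  crit <- tw_quantile(alpha)
  l <- eigenvalues[eigenvalues > max(eigenvalues) * 1e-12]
  m0 <- length(l)
  count <- 0L
  for (k in seq_len(max(m0 - 2L, 0L))) {
    ev <- l[k:m0]
    m <- length(ev)
    s1 <- sum(ev); s2 <- sum(ev^2)
    denom <- (m - 1) * s2 - s1^2
    if (denom <= 0) break
    n_eff <- (m + 1) * s1^2 / denom
    if (n_eff <= 1) break
    L1 <- m * ev[1] / s1
    mu <- (sqrt(n_eff - 1) + sqrt(m))^2 / n_eff
    sig <- (sqrt(n_eff - 1) + sqrt(m)) / n_eff *
      (1 / sqrt(n_eff - 1) + 1 / sqrt(m))^(1 / 3)
    x <- (L1 - mu) / sig
    if (x > crit) count <- count + 1L else break
  }
  count
}

#' K-medoids clustering (PAM)
#'
#' Partitioning around medoids on Euclidean dissimilarities: cluster
#' centers are observations and the summed dissimilarity to the
#' assigned medoid is minimized.  Small problems (at most 5000 medoid
#' subsets) are solved exactly by enumeration; larger ones use the
#' classical PAM build + swap phases (compiled, with a hard swap cap
#' so termination is guaranteed on ties and duplicated points), which
#' can in principle stop in a local optimum.
#'
#' @param points numeric matrix (or vector) of coordinates.
#' @param k number of clusters (1 <= k <= n).
#' @return List with `membership`, `medoid_idx` and `objective`
#'   (summed distance to assigned medoids).
#' @export
kmedoids <- function(points, k) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k cannot exceed the number of points")
  if (k == 1) {
    d <- sqrt(rowSums(sweep(points, 2, colMeans(points))^2))
    med <- which.min(d)  # most central observation
    dm <- sqrt(rowSums(sweep(points, 2, points[med, ])^2))
    return(list(membership = rep(1L, n), medoid_idx = med,
                objective = sum(dm)))
  }
  if (choose(n, k) <= 5000) {          # exact enumeration
    D <- as.matrix(dist(points))
    combos <- utils::combn(n, k)
    objs <- apply(combos, 2, function(md)
      sum(do.call(pmin, lapply(md, function(j) D[, j]))))
    md <- combos[, which.min(objs)]
    assign_d <- vapply(md, function(j) D[, j], numeric(n))
    memb <- max.col(-assign_d, ties.method = "first")
    return(list(membership = memb, medoid_idx = md,
                objective = min(objs)))
  }
  storage.mode(points) <- "double"
  fit <- .pam_cpp(points, as.integer(k))
  list(membership = as.integer(fit$membership),
       medoid_idx = as.integer(fit$medoids),
       objective = fit$objective)
}

# within-cluster dispersion (Tibshirani's W_k with squared Euclidean
# pairwise distances, computed via centroids)
within_dispersion <- function(points, membership) {
  w <- 0
  for (g in unique(membership)) {
    pg <- points[membership == g, , drop = FALSE]
    if (nrow(pg) > 1)
      w <- w + sum(sweep(pg, 2, colMeans(pg))^2)
  }
  w
}

#' Select the number of clusters by the Gap statistic
#'
#' For each `k` up to `K_max`, compares the log within-cluster
#' dispersion of the k-medoids clustering with its average over `B`
#' reference datasets drawn uniformly over the per-dimension range of
#' the data: `Gap(k) = mean_b log(W*_kb) - log(W_k)`, with
#' `s_k = sd_b(log W*_kb) * sqrt(1 + 1/B)`.  The chosen `k` is the
#' smallest one with `Gap(k) >= Gap(k+1) - s_{k+1}` (falling back to
#' `K_max`).
#'
#' @param points numeric matrix of coordinates (e.g. PC scores).
#' @param K_max largest number of clusters considered.
#' @param B number of uniform reference datasets (1000 reproduces the
#'   published analyses; smaller values are used for quick runs).
#' @param n_sub optional subject subsample size used for the selection
#'   (the clustering returned downstream is still fit to all points);
#'   `NULL` uses every point.
#' @param seed optional integer seed.
#' @return Object of class `gap_curve`: selected `k`, `gap`, `se`,
#'   `logW`, `logW_ref` per candidate `k`.
#' @export
gap_select <- function(points, K_max = 6, B = 1000, n_sub = NULL,
                       seed = NULL) {
  points <- as.matrix(points)
  if (K_max < 1) stop("K_max must be >= 1")
  if (B < 10) stop("B must be >= 10")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(points)
  if (!is.null(n_sub) && n > n_sub)
    points <- points[sample.int(n, n_sub), , drop = FALSE]
  n <- nrow(points)
  K_max <- min(K_max, n - 1L)
  rng <- apply(points, 2, range)
  if (all(rng[2, ] - rng[1, ] < 1e-12))
    return(structure(list(k = 1L, gap = NA_real_, se = NA_real_,
                          logW = NA_real_, logW_ref = NA_real_),
                     class = "gap_curve"))
  eps <- 1e-12
  logW <- vapply(seq_len(K_max), function(k) {
    cl <- kmedoids(points, k)
    log(within_dispersion(points, cl$membership) + eps)
  }, numeric(1))
  logWref <- matrix(NA_real_, B, K_max)
  for (b in seq_len(B)) {
    ref <- vapply(seq_len(ncol(points)),
                  function(j) runif(n, rng[1, j], rng[2, j]),
                  numeric(n))
    ref <- matrix(ref, nrow = n)
    for (k in seq_len(K_max)) {
      cl <- kmedoids(ref, k)
      logWref[b, k] <- log(within_dispersion(ref, cl$membership) + eps)
    }
  }
  gap <- colMeans(logWref) - logW
  se <- apply(logWref, 2, sd) * sqrt(1 + 1 / B)
  k_star <- K_max
  for (k in seq_len(K_max - 1L)) {
    if (gap[k] >= gap[k + 1] - se[k + 1]) { k_star <- k; break }
  }
  structure(list(k = as.integer(k_star), gap = gap, se = se,
                 logW = logW, logW_ref = colMeans(logWref)),
            class = "gap_curve")
}

#' @export
print.gap_curve <- function(x, ...) {
  cat(sprintf("gap_curve: selected k = %d\n", x$k))
  if (!all(is.na(x$gap)))
    print(data.frame(k = seq_along(x$gap), gap = x$gap, se = x$se))
  invisible(x)
}

#' Build a stratification model from genotypes
#'
#' Removes flagged subjects, runs classical PCA on the remainder,
#' selects the number of components by sequential Tracy-Widom tests
#' (unless `K` is given), chooses the number of clusters on the
#' selected PCs by the Gap statistic and assigns memberships by
#' k-medoids.  The result carries everything the adjusted association
#' model needs: PC covariates and cluster indicators.
#'
#' @param X genotype matrix (subjects x SNPs).
#' @param outlier_flags logical vector (or integer indices) of subjects
#'   to remove; `NULL` keeps everyone.
#' @param K `"auto"` for Tracy-Widom selection, or an integer count.
#' @param max_pcs cap on the automatically selected component count.
#' @param K_max_clusters largest number of clusters considered.
#' @param cluster run the Gap/k-medoids step; with `FALSE` the model
#'   carries PCs only (`cluster_count` 1).
#' @param B,gap_subsample Gap-statistic settings (see [gap_select()]).
#' @param normalize allele-frequency scaling for PCA.
#' @param alpha Tracy-Widom test level.
#' @param seed optional integer seed (Gap reference sets).
#' @return Object of class `stratification_model`: `pcs` (scores of
#'   kept subjects), `eigenvalues`, `n_components`, `cluster_count`,
#'   `memberships` (full length n, `NA` for removed subjects),
#'   `medoid_indices` (positions within kept subjects), `gap_curve`,
#'   `removed_subjects`.
#' @export
build_stratification <- function(X, outlier_flags = NULL, K = "auto",
                                 max_pcs = 10, K_max_clusters = 6,
                                 cluster = TRUE, B = 1000,
                                 gap_subsample = NULL,
                                 normalize = TRUE, alpha = 0.05,
                                 seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(outlier_flags)) outlier_flags <- rep(FALSE, n)
  if (is.numeric(outlier_flags))
    outlier_flags <- seq_len(n) %in% outlier_flags
  stopifnot(length(outlier_flags) == n)
  if (all(outlier_flags)) stop("all subjects flagged as outliers")
  keep <- !outlier_flags
  Xk <- X[keep, , drop = FALSE]
  if (anyNA(Xk)) {
    if (identical(K, "auto"))
      stop("automatic component selection needs complete data; ",
           "supply an integer K for matrices with missing entries")
    fit <- als_pca(Xk, K = K)
    scores_all <- fit$scores
    ev <- NULL
    Kc <- K
  } else {
    K_req <- min(if (identical(K, "auto")) max_pcs else K,
                 nrow(Xk) - 1L, ncol(Xk))
    pca <- classical_pca(Xk, K = K_req, normalize = normalize)
    ev <- pca$eigenvalues
    Kc <- if (identical(K, "auto")) {
      min(tracy_widom_count(ev, nrow(Xk), length(pca$kept_cols),
                            alpha = alpha), max_pcs)
    } else K
    scores_all <- pca$scores
  }
  if (Kc > 0 && cluster) {
    pcs <- scores_all[, seq_len(Kc), drop = FALSE]
    gc_fit <- gap_select(pcs, K_max = K_max_clusters, B = B,
                         n_sub = gap_subsample, seed = seed)
    cl <- kmedoids(pcs, gc_fit$k)
    membership_kept <- cl$membership
    medoids <- cl$medoid_idx
  } else if (Kc > 0) {
    pcs <- scores_all[, seq_len(Kc), drop = FALSE]
    gc_fit <- structure(list(k = 1L, gap = NA_real_, se = NA_real_,
                             logW = NA_real_, logW_ref = NA_real_),
                        class = "gap_curve")
    membership_kept <- rep(1L, nrow(Xk))
    medoids <- integer(0)
  } else {
    pcs <- matrix(numeric(0), nrow(Xk), 0)
    gc_fit <- structure(list(k = 1L, gap = NA_real_, se = NA_real_,
                             logW = NA_real_, logW_ref = NA_real_),
                        class = "gap_curve")
    membership_kept <- rep(1L, nrow(Xk))
    medoids <- integer(0)
  }
  memberships <- rep(NA_integer_, n)
  memberships[keep] <- membership_kept
  structure(list(pcs = pcs, eigenvalues = ev, n_components = Kc,
                 cluster_count = gc_fit$k, memberships = memberships,
                 medoid_indices = medoids, gap_curve = gc_fit,
                 removed_subjects = which(outlier_flags)),
            class = "stratification_model")
}

#' @export
print.stratification_model <- function(x, ...) {
  cat(sprintf(
    "stratification_model: %d PC(s), %d cluster(s), %d subject(s) removed\n",
    x$n_components, x$cluster_count, length(x$removed_subjects)))
  invisible(x)
}

#' Write a stratification model to TSV
#'
#' Emits one row per subject (PC scores and cluster membership;
#' removed subjects get NA) plus a companion `<path>.scree.tsv` of
#' eigenvalues.
#'
#' @param model a [build_stratification()] result.
#' @param path output file.
#' @param subjects optional subject identifiers.
#' @export
write_stratification <- function(model, path, subjects = NULL) {
  n <- length(model$memberships)
  if (is.null(subjects)) subjects <- sprintf("subj_%04d", seq_len(n))
  keep <- setdiff(seq_len(n), model$removed_subjects)
  pcs <- matrix(NA_real_, n, model$n_components)
  if (model$n_components > 0) pcs[keep, ] <- model$pcs
  colnames(pcs) <- if (model$n_components > 0)
    sprintf("PC%d", seq_len(model$n_components)) else character(0)
  tab <- data.frame(subject = subjects, pcs,
                    cluster = model$memberships,
                    stringsAsFactors = FALSE)
  writeLines(sprintf("# robustps %s | %d PCs | %d clusters",
                     as.character(utils::packageVersion("robustps")),
                     model$n_components, model$cluster_count), path)
  suppressWarnings(utils::write.table(tab, path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  if (!is.null(model$eigenvalues))
    utils::write.table(
      data.frame(component = seq_along(model$eigenvalues),
                 eigenvalue = model$eigenvalues),
      paste0(path, ".scree.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  invisible(path)
}
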