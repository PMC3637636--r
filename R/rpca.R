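# Projection-pursuit robust PCA (GRID and CR algorithms) and the
# score-distance / orthogonal-distance outlier diagnostics.

scale_index_code <- function(pp_index) {
  switch(pp_index, mad = 0L, sd = 1L,
         stop("pp_index must be 'mad' or 'sd'"))
}

col_medians <- function(X) apply(X, 2, median)

#' Projection-pursuit robust principal components
#'
#' Computes robust principal components sequentially by maximizing a
#' robust scale (the projection-pursuit index) of the projected data
#' over unit directions, instead of the variance used by classical PCA.
#' No covariance matrix is formed, so the method remains usable when
#' the number of SNPs far exceeds the number of subjects.  Data are
#' centered at the coordinatewise median; after each component the data
#' are deflated by the fitted term and the search repeats.
#'
#' Two search algorithms are available.  `"grid"` starts from the best
#' coordinate axis and cycles over coordinate planes, maximizing the
#' index over a grid of angles whose interval is halved at each cycle.
#' `"cr"` (Croux & Ruiz-Gazen) restricts the search to the finite
#' candidate set of normalized centered observations, which is exact on
#' that set but can flag extra observations as outliers when
#' `p >> n` (swamping); `"grid"` is the recommended default for GWA
#' panels.  When `p > n` the computation runs in the
#' rank-reduced row space of the centered data, which leaves all
#' projections, scores and residuals unchanged.
#'
#' @param X numeric matrix (subjects x SNPs); missing entries are
#'   mean-imputed per column when `impute = TRUE`.
#' @param K number of components (default 5).
#' @param algorithm `"grid"` or `"cr"`.
#' @param pp_index projection index: `"mad"` (median absolute
#'   deviation, default) or `"sd"` (classical, for cross-checks).
#' @param grid_points number of angle grid points per plane (GRID).
#' @param max_cycles maximum plane-cycling passes (GRID); the angle
#'   interval is halved after each pass.
#' @param tol direction-change convergence tolerance (GRID).
#' @param center location estimate: `"median"` (coordinatewise median,
#'   robust default) or `"mean"`.  The coordinatewise median is not
#'   rotation-equivariant; use `"mean"` when exact orthogonal
#'   equivariance of the search matters more than robustness of the
#'   center.
#' @param impute mean-impute missing entries before the search.
#' @return Object of class `pp_pca`: `eigenvectors` (p x K, orthonormal
#'   columns), `eigenvalues` (squared index of each projection, sorted
#'   nonincreasing), `scores` (n x K, equal to
#'   `(X - 1 mu') %*% eigenvectors`), `location` (coordinatewise
#'   median), `pp_index`, `algorithm`.
#' @examples
#' X <- matrix(rnorm(600), 100, 6)
#' fit <- pp_pca(X, K = 2)
#' fit$eigenvalues
#' @export
pp_pca <- function(X, K = 5, algorithm = c("grid", "cr"),
                   pp_index = c("mad", "sd"), grid_points = 10,
                   max_cycles = 10, tol = 1e-6,
                   center = c("median", "mean"), impute = TRUE) {
  algorithm <- match.arg(algorithm)
  pp_index <- match.arg(pp_index)
  center <- match.arg(center)
  icode <- scale_index_code(pp_index)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    if (!impute) stop("X contains missing values; set impute = TRUE")
    mu_c <- colMeans(X, na.rm = TRUE)
    nas <- which(is.na(X), arr.ind = TRUE)
    X[nas] <- mu_c[nas[, 2]]
  }
  n <- nrow(X); p <- ncol(X)
  if (K > min(n - 1, p)) stop("K must be <= min(n - 1, p)")

  mu <- if (center == "median") col_medians(X) else colMeans(X)
  Xc <- sweep(X, 2, mu)

  # work in the row space of the centered data when p is large
  if (p > n) {
    sv <- svd(Xc, nu = n, nv = n)
    r <- sum(sv$d > max(sv$d[1], 1) * 1e-12)
    basis <- sv$v[, seq_len(r), drop = FALSE]
    Z <- Xc %*% basis
  } else {
    basis <- NULL
    Z <- Xc
  }
  d <- ncol(Z)

  B <- matrix(0, d, 0)
  lambda <- numeric(0)
  Zk <- Z
  for (k in seq_len(K)) {
    if (algorithm == "grid") {
      res <- .grid_direction_cpp(Zk, as.integer(grid_points),
                                 as.integer(max_cycles), tol, icode)
      b <- res$direction
      s <- res$scale
    } else {
      nrm <- sqrt(rowSums(Zk^2))
      keep <- nrm > 1e-12
      if (!any(keep)) { s <- 0; b <- NULL }
      else {
        C <- Zk[keep, , drop = FALSE] / nrm[keep]
        P <- tcrossprod(Zk, C)          # projections on each candidate
        sc <- .col_scale_cpp(P, icode)
        j <- which.max(sc)              # first-encountered tie-break
        b <- C[j, ]
        s <- sc[j]
      }
    }
    if (is.null(b) || s <= 1e-12 ||
        (length(lambda) > 0 && s^2 <= max(lambda) * 1e-10)) {
      warning(sprintf(
        "deflated data have no remaining scale; returning %d of %d components",
        k - 1L, K))
      break
    }
    # orthogonalize against earlier components (projections unchanged:
    # deflated data are exactly orthogonal to earlier directions)
    if (ncol(B) > 0) {
      b <- b - B %*% crossprod(B, b)
      b <- b / sqrt(sum(b^2))
    }
    y <- drop(Zk %*% b)
    B <- cbind(B, b, deparse.level = 0)
    lambda <- c(lambda, s^2)
    Zk <- Zk - tcrossprod(y, b)
  }
  ord <- order(lambda, decreasing = TRUE)
  B <- B[, ord, drop = FALSE]
  lambda <- lambda[ord]
  vecs <- if (is.null(basis)) B else basis %*% B
  scores <- Xc %*% vecs
  structure(list(eigenvectors = vecs, eigenvalues = lambda,
                 scores = scores, location = mu, pp_index = pp_index,
                 algorithm = algorithm, grid_points = grid_points),
            class = "pp_pca")
}

#' @export
print.pp_pca <- function(x, ...) {
  cat(sprintf("pp_pca (%s algorithm, %s index): %d components\n",
              x$algorithm, x$pp_index, length(x$eigenvalues)))
  cat("eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' Robust score distances
#'
#' Mahalanobis-type distance of each subject within the robust PC
#' subspace: `SD_i = sqrt(sum_j t_ij^2 / l_j)` with robust scores `t`
#' and eigenvalues `l`.  The cutoff is the square root of the 0.975
#' quantile of the chi-square distribution with `k` degrees of freedom.
#'
#' @param fit a [pp_pca()] result; all eigenvalues must be positive
#'   (drop zero-eigenvalue components first).
#' @return List with `sd` (length-n distances), `cutoff`, and `k`.
#' @export
score_distances <- function(fit) {
  l <- fit$eigenvalues
  if (any(l <= 0))
    stop("zero eigenvalue: truncate the result to components with ",
         "positive eigenvalues before computing score distances")
  k <- length(l)
  sd_i <- sqrt(rowSums(sweep(fit$scores^2, 2, l, "/")))
  list(sd = sd_i, cutoff = sqrt(qchisq(0.975, df = k)), k = k)
}

#' Orthogonal distances
#'
#' Euclidean distance from each subject to its projection onto the
#' robust PC subspace, `OD_i = ||x_i - (mu + P t_i)||`.  Squared
#' orthogonal distances are approximately a scaled chi-square,
#' `OD^2 ~ g2 * chisq(g1)`; via the Wilson-Hilferty transformation
#' `OD^(2/3)` is then approximately Gaussian, so the cutoff is
#' `(m + s z_0.975)^(3/2)` with `m` and `s` the median and MAD of
#' `OD^(2/3)`.
#'
#' @param X the data matrix the fit was computed on (same column
#'   order); missing entries are mean-imputed as in [pp_pca()].
#' @param fit a [pp_pca()] result.
#' @return List with `od`, `cutoff`, and the Wilson-Hilferty location
#'   and scale `wh_m`, `wh_s`.  When the components span the full
#'   variable space all distances are zero and the cutoff is `NA` (with
#'   a warning).
#' @export
orth_distances <- function(X, fit) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu_c <- colMeans(X, na.rm = TRUE)
    nas <- which(is.na(X), arr.ind = TRUE)
    X[nas] <- mu_c[nas[, 2]]
  }
  Xc <- sweep(X, 2, fit$location)
  R <- Xc - fit$scores %*% t(fit$eigenvectors)
  od <- sqrt(rowSums(R^2))
  if (max(od) < 1e-8) {
    warning("components span the data: all orthogonal distances are ",
            "zero and the cutoff is undefined")
    return(list(od = od, cutoff = NA_real_, wh_m = NA_real_,
                wh_s = NA_real_))
  }
  z <- od^(2 / 3)
  m <- median(z)
  s <- mad(z)
  list(od = od, cutoff = (m + s * qnorm(0.975))^(3 / 2), wh_m = m,
       wh_s = s)
}

#' Classify subjects by score and orthogonal distance
#'
#' Type `A` outliers exceed only the score-distance cutoff (far within
#' the PC subspace), type `B` exceed only the orthogonal-distance
#' cutoff (far from the subspace), type `C` exceed both; all three
#' types are removed before stratification adjustment.
#'
#' @param sd,od distance vectors of equal length.
#' @param sd_cutoff,od_cutoff the respective cutoffs.
#' @return Factor with levels `regular`, `A`, `B`, `C`.
#' @export
classify_outliers <- function(sd, od, sd_cutoff, od_cutoff) {
  stopifnot(length(sd) == length(od))
  big_sd <- sd > sd_cutoff
  big_od <- if (is.na(od_cutoff)) rep(FALSE, length(od)) else od > od_cutoff
  lab <- ifelse(big_sd & big_od, "C",
                ifelse(big_sd, "A", ifelse(big_od, "B", "regular")))
  factor(lab, levels = c("regular", "A", "B", "C"))
}

#' Robust-PCA outlier diagnostics for a genotype matrix
#'
#' Runs projection-pursuit robust PCA, drops any zero-eigenvalue
#' components, computes score and orthogonal distances with their
#' cutoffs, and labels each subject.  Subjects labelled `A`, `B` or
#' `C` are flagged for removal.
#'
#' @inheritParams pp_pca
#' @param ... further arguments to [pp_pca()].
#' @return Object of class `outlier_diagnostics`: data frame `table`
#'   with columns subject, sd, od, label; `sd_cutoff`, `od_cutoff`;
#'   `flagged` (integer indices of subjects to remove); and the
#'   underlying `fit`.
#' @seealso [plot.outlier_diagnostics()] for the OD-vs-SD diagnostic
#'   plot, [rhm_detect()] for the resampling alternative.
#' @export
rpca_diagnostics <- function(X, K = 5, algorithm = c("grid", "cr"),
                             pp_index = c("mad", "sd"), ...) {
  fit <- pp_pca(X, K = K, algorithm = match.arg(algorithm),
                pp_index = match.arg(pp_index), ...)
  keep <- fit$eigenvalues > 1e-12
  if (!all(keep)) {
    fit$eigenvalues <- fit$eigenvalues[keep]
    fit$eigenvectors <- fit$eigenvectors[, keep, drop = FALSE]
    fit$scores <- fit$scores[, keep, drop = FALSE]
  }
  sdist <- score_distances(fit)
  odist <- orth_distances(X, fit)
  labels <- classify_outliers(sdist$sd, odist$od, sdist$cutoff,
                              odist$cutoff)
  subj <- rownames(X)
  if (is.null(subj)) subj <- sprintf("subj_%04d", seq_len(nrow(X)))
  tab <- data.frame(subject = subj, sd = sdist$sd, od = odist$od,
                    label = labels, stringsAsFactors = FALSE)
  structure(list(table = tab, sd_cutoff = sdist$cutoff,
                 od_cutoff = odist$cutoff,
                 flagged = which(labels != "regular"), fit = fit),
            class = "outlier_diagnostics")
}

#' @export
print.outlier_diagnostics <- function(x, ...) {
  cat(sprintf(
    "outlier_diagnostics: %d subjects, %d flagged (A=%d, B=%d, C=%d)\n",
    nrow(x$table), length(x$flagged), sum(x$table$label == "A"),
    sum(x$table$label == "B"), sum(x$table$label == "C")))
  cat(sprintf("  SD cutoff %.3f, OD cutoff %.3f\n", x$sd_cutoff,
              x$od_cutoff))
  invisible(x)
}

#' Diagnostic plot of orthogonal versus score distances
#'
#' Scatter of each subject's orthogonal distance against its score
#' distance with both cutoff lines; points beyond either line are the
#' flagged outliers (types A, B, C).
#'
#' @param x an [rpca_diagnostics()] result.
#' @param ... passed to [plot()].
#' @export
plot.outlier_diagnostics <- function(x, ...) {
  tab <- x$table
  cols <- c(regular = "grey40", A = "firebrick", B = "dodgerblue3",
            C = "purple3")
  plot(tab$sd, tab$od, col = cols[as.character(tab$label)], pch = 19,
       cex = 0.6, xlab = "Score distance",
       ylab = "Orthogonal distance", ...)
  abline(v = x$sd_cutoff, lty = 2)
  if (!is.na(x$od_cutoff)) abline(h = x$od_cutoff, lty = 2)
  legend("topleft", legend = names(cols), col = cols, pch = 19,
         bty = "n", cex = 0.8)
  invisible(x)
}

#' Write an outlier-diagnostics table to TSV
#'
#' @param x an [rpca_diagnostics()] or [rhm_detect()] result.
#' @param path output file.
#' @export
write_diagnostics <- function(x, path) {
  if (inherits(x, "outlier_diagnostics")) {
    hdr <- sprintf("# robustps %s | SD cutoff %.6g | OD cutoff %.6g",
                   as.character(utils::packageVersion("robustps")),
                   x$sd_cutoff, x$od_cutoff)
    tab <- x$table
  } else if (inherits(x, "rhm_result")) {
    hdr <- sprintf("# robustps %s | RHM cutoff %.6g | nrep %d",
                   as.character(utils::packageVersion("robustps")),
                   x$cutoff, x$nrep)
    tab <- data.frame(subject = x$subject, mean_length = x$mean_lengths,
                      flagged = x$flags, stringsAsFactors = FALSE)
  } else stop("unsupported diagnostics object")
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(tab, path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  invisible(path)
}
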