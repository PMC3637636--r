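# Resampling by half means: multivariate outlier detection that remains
# usable when variables outnumber subjects.

#' Outlier detection by resampling by half means
#'
#' In each of `nrep` replicates, half of the subjects
#' (`floor(n/2)`, sampled without replacement) provide column means and
#' standard deviations (`n/2 - 1` denominator); *all* `n` rows are then
#' standardized by these and their Euclidean lengths recorded.  The
#' per-subject mean length over replicates is compared with the cutoff
#' `median + 3 * MAD` (MAD with the 1.4826 Gaussian consistency
#' factor); subjects above the cutoff are flagged as outliers.  Columns
#' with zero within-half standard deviation contribute nothing to the
#' lengths for that replicate.
#'
#' @param X numeric matrix (subjects x SNPs).
#' @param nrep number of half-sample replicates (default 100).
#' @param seed optional integer seed.
#' @param keep_lengths retain the full n x nrep length matrix.
#' @return Object of class `rhm_result`: `mean_lengths`, `cutoff`,
#'   logical `flags`, `flagged` indices, `nrep`, and optionally
#'   `lengths_matrix`.
#' @examples
#' X <- matrix(rnorm(50 * 20), 50, 20)
#' X[1, ] <- X[1, ] + 8
#' rhm_detect(X, nrep = 50, seed = 1)$flagged
#' @export
rhm_detect <- function(X, nrep = 100, seed = NULL,
                       keep_lengths = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 4) stop("RHM needs at least 4 subjects")
  if (nrep < 1) stop("nrep must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  nh <- floor(n / 2)
  acc <- numeric(n)
  L <- if (keep_lengths) matrix(NA_real_, n, nrep) else NULL
  X2 <- X^2
  for (r in seq_len(nrep)) {
    idx <- sample.int(n, nh)
    m <- colMeans(X[idx, , drop = FALSE])
    s2 <- (colSums(X2[idx, , drop = FALSE]) - nh * m^2) / (nh - 1)
    # squared lengths by expansion: sum_j (x_ij - m_j)^2 / s_j^2,
    # with zero-variance columns excluded (weight 0)
    w <- ifelse(s2 > 0, 1 / s2, 0)
    l2 <- drop(X2 %*% w) - 2 * drop(X %*% (m * w)) + sum(m^2 * w)
    l <- sqrt(pmax(l2, 0))
    acc <- acc + l
    if (keep_lengths) L[, r] <- l
  }
  ml <- acc / nrep
  cutoff <- median(ml) + 3 * mad(ml)
  flags <- ml > cutoff
  subj <- rownames(X)
  if (is.null(subj)) subj <- sprintf("subj_%04d", seq_len(n))
  structure(list(subject = subj, mean_lengths = ml, cutoff = cutoff,
                 flags = flags, flagged = which(flags), nrep = nrep,
                 lengths_matrix = L),
            class = "rhm_result")
}

#' @export
print.rhm_result <- function(x, ...) {
  cat(sprintf("rhm_result: %d subjects, %d flagged (cutoff %.3f, nrep %d)\n",
              length(x$mean_lengths), length(x$flagged), x$cutoff,
              x$nrep))
  invisible(x)
}

#' Plot RHM mean vector lengths
#'
#' Index plot of per-subject mean scaled vector lengths with the
#' `median + 3 * MAD` cutoff line; flagged subjects sit above the line.
#'
#' @param x an [rhm_detect()] result.
#' @param ... passed to [plot()].
#' @export
plot.rhm_result <- function(x, ...) {
  plot(seq_along(x$mean_lengths), x$mean_lengths,
       col = ifelse(x$flags, "firebrick", "grey40"), pch = 19,
       cex = 0.6, xlab = "Subject index", ylab = "Mean vector length",
       ...)
  abline(h = x$cutoff, lty = 2)
  invisible(x)
}
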