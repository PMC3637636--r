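# Empirical false/true positive rates and the scenario x method
# benchmark harness.

#' Empirical rejection rate
#'
#' Percentage of tests with p-value below the nominal level, pooled
#' over all supplied values (datasets are pooled, which equals
#' averaging per-dataset rates when SNP counts are equal).
#'
#' @param p p-values (vector or matrix), in \[0, 1\].
#' @param alpha nominal level (default 0.01).
#' @return Rate in percent.
#' @export
empirical_rates <- function(p, alpha = 0.01) {
  p <- as.numeric(p)
  if (length(p) == 0 || anyNA(p)) stop("p must be nonempty without NA")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  100 * mean(p < alpha)
}

#' Benchmark stratification-correction methods on simulated data
#'
#' For every combination of scenario and outlier setting, simulates
#' `n_datasets` case-control datasets, optionally injects subject
#' outliers via the second-singular-vector perturbation, runs each
#' requested method, and pools the per-SNP p-values into empirical
#' rejection rates per testing-SNP category (false positive rates for
#' random and differentiated SNPs, true positive rates for causal
#' SNPs).
#'
#' Dataset `d` of each cell is simulated after `set.seed(seed + d - 1 +
#' 1000 * cell_index)`, so every cell is reproducible in isolation.
#'
#' @param scenarios character vector from `S1`, `S2`, `S3`, `S4`,
#'   `admixed`.
#' @param outliers logical vector: run without and/or with injected
#'   outliers (default both `FALSE` and `TRUE` runs only `FALSE`).
#' @param methods methods to compare (see [run_method()]).
#' @param n_datasets datasets per cell.
#' @param n_testing_snps testing SNPs per category per dataset.
#' @param n_inference_snps inference-SNP count; `NULL` keeps each
#'   scenario's default (2000 discrete, 20000 admixed).
#' @param outlier_fraction fraction of subjects perturbed when
#'   `outliers` is `TRUE`.
#' @param alpha nominal level.
#' @param seed base integer seed.
#' @param gap_B,gap_subsample,rpca_K,rhm_nrep method settings passed to
#'   [run_method()].
#' @param verbose print progress.
#' @return Data frame of class `benchmark_table`: scenario, outliers,
#'   snp_type, method, rate (percent), n_tests, n_datasets, alpha,
#'   seed.  Cell-level failures are recorded with `NA` rates rather
#'   than aborting the grid.
#' @export
run_benchmark <- function(scenarios = c("S1", "S2", "S3", "S4"),
                          outliers = FALSE,
                          methods = c("trend", "gc", "pca", "mds",
                                      "rpca_rhm", "rpca_pp"),
                          n_datasets = 10, n_testing_snps = 200,
                          n_inference_snps = NULL,
                          outlier_fraction = 0.05, alpha = 0.01,
                          seed = 1, gap_B = 100, gap_subsample = 250,
                          rpca_K = 5, rhm_nrep = 100,
                          verbose = interactive()) {
  grid <- expand.grid(scenario = scenarios, outliers = outliers,
                      stringsAsFactors = FALSE)
  out <- list()
  for (cell in seq_len(nrow(grid))) {
    scn_name <- grid$scenario[cell]
    with_out <- grid$outliers[cell]
    args <- list(name = scn_name, n_testing_snps = n_testing_snps)
    if (!is.null(n_inference_snps))
      args$n_inference_snps <- n_inference_snps
    scn <- do.call(scenario_preset, args)
    pvals <- list()  # [[method]][[role]] pooled p-values
    for (d in seq_len(n_datasets)) {
      set.seed(seed + d - 1 + 1000 * (cell - 1))
      ds <- if (inherits(scn, "admixed_scenario"))
        simulate_admixed(scn) else simulate_discrete(scn)
      if (with_out)
        ds <- inject_outliers(ds, fraction = outlier_fraction)
      for (m in methods) {
        if (verbose)
          message(sprintf("[%s%s] dataset %d/%d method %s", scn_name,
                          if (with_out) "+outliers" else "", d,
                          n_datasets, m))
        res <- tryCatch(
          run_method(ds, m, gap_B = gap_B,
                     gap_subsample = gap_subsample, rpca_K = rpca_K,
                     rhm_nrep = rhm_nrep),
          error = function(e) {
            warning(sprintf("cell %s/%s dataset %d method %s failed: %s",
                            scn_name, with_out, d, m,
                            conditionMessage(e)))
            NULL
          })
        if (is.null(res)) next
        for (r in unique(res$role))
          pvals[[m]][[r]] <- c(pvals[[m]][[r]], res$p[res$role == r])
      }
    }
    for (m in methods) {
      for (r in c("random", "differentiated", "causal")) {
        pv <- pvals[[m]][[r]]
        out[[length(out) + 1]] <- data.frame(
          scenario = scn_name, outliers = with_out, snp_type = r,
          method = m,
          rate = if (length(pv)) empirical_rates(pv, alpha) else NA_real_,
          n_tests = length(pv), n_datasets = n_datasets,
          alpha = alpha, seed = seed, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("benchmark_table", "data.frame")
  res
}

#' Write a benchmark table to TSV
#'
#' Columns are ordered as in the published comparison (Trend, GC, PCA,
#' MDS, RPCA-RHM, RPCA-PP) when reshaped wide.
#'
#' @param table a [run_benchmark()] result.
#' @param path output file.
#' @param wide reshape to one row per (scenario, outliers, snp_type)
#'   with one column per method.
#' @export
write_benchmark <- function(table, path, wide = TRUE) {
  hdr <- sprintf("# robustps %s | alpha %g | %d datasets | seed %d",
                 as.character(utils::packageVersion("robustps")),
                 table$alpha[1], table$n_datasets[1], table$seed[1])
  if (wide) {
    order_methods <- intersect(
      c("trend", "gc", "pca", "mds", "rpca_rhm", "rpca_pp"),
      unique(table$method))
    w <- stats::reshape(
      table[, c("scenario", "outliers", "snp_type", "method", "rate")],
      idvar = c("scenario", "outliers", "snp_type"),
      timevar = "method", direction = "wide")
    names(w) <- sub("^rate\\.", "", names(w))
    w <- w[, c("scenario", "outliers", "snp_type", order_methods)]
    table <- w
  }
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(table, path, sep = "\t",
                                      quote = FALSE, row.names = FALSE,
                                      append = TRUE))
  invisible(path)
}
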