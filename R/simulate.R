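# Simulators for case-control genotype data with population structure:
# discrete subpopulations under the Beta(F_ST) allele-frequency model,
# two-way admixture with ancestry-dependent disease risk, and SVD-based
# subject-outlier injection.

#' Define a discrete-population simulation scenario
#'
#' A scenario bundles all parameters of the discrete-population
#' case-control simulator: the number of subpopulations, the case and
#' control sampling proportions across them, the divergence parameter
#' \eqn{F_{ST}} of the Beta allele-frequency model, and the SNP panel
#' layout.  Per-SNP subpopulation allele frequencies are drawn as
#' \eqn{Beta(p(1-F_{ST})/F_{ST},\,(1-p)(1-F_{ST})/F_{ST})} with the
#' ancestral frequency \eqn{p} uniform on `(freq_low, freq_high)`.
#'
#' @param case_props,control_props numeric vectors of subpopulation
#'   proportions for cases and controls; each must sum to 1.
#' @param fst divergence between subpopulations (default 0.01, typical of
#'   divergent European populations).
#' @param freq_low,freq_high support of the uniform ancestral allele
#'   frequency distribution.
#' @param n_cases,n_controls subject counts.
#' @param n_inference_snps number of null SNPs used for structure
#'   inference and outlier detection.
#' @param n_testing_snps number of testing SNPs *per category* (random,
#'   differentiated, causal).
#' @param relative_risk multiplicative risk `R` per causal allele
#'   (`R >= 1`).
#' @param diff_freqs per-subpopulation allele frequencies of the
#'   differentiated SNPs; default 0.8 for population 1 and 0.2 for the
#'   others.
#' @return An object of class `discrete_scenario`.
#' @seealso [scenario_preset()] for the four standard configurations,
#'   [simulate_discrete()].
#' @export
discrete_scenario <- function(case_props, control_props, fst = 0.01,
                              freq_low = 0.1, freq_high = 0.9,
                              n_cases = 500, n_controls = 500,
                              n_inference_snps = 2000,
                              n_testing_snps = 1000,
                              relative_risk = 1.3,
                              diff_freqs = NULL) {
  n_pops <- length(case_props)
  if (length(control_props) != n_pops)
    stop("case_props and control_props must have the same length")
  if (abs(sum(case_props) - 1) > 1e-12 || abs(sum(control_props) - 1) > 1e-12)
    stop("case_props and control_props must each sum to 1")
  if (any(case_props < 0) || any(control_props < 0))
    stop("proportions must be nonnegative")
  if (fst <= 0 || fst >= 1) stop("fst must lie in (0, 1)")
  if (!(freq_low > 0 && freq_low < freq_high && freq_high < 1))
    stop("need 0 < freq_low < freq_high < 1")
  if (relative_risk < 1) stop("relative_risk must be >= 1")
  if (is.null(diff_freqs)) diff_freqs <- c(0.8, rep(0.2, n_pops - 1))
  if (length(diff_freqs) != n_pops)
    stop("diff_freqs must have one frequency per subpopulation")
  structure(list(n_pops = n_pops, case_props = case_props,
                 control_props = control_props, fst = fst,
                 freq_low = freq_low, freq_high = freq_high,
                 n_cases = n_cases, n_controls = n_controls,
                 n_inference_snps = n_inference_snps,
                 n_testing_snps = n_testing_snps,
                 relative_risk = relative_risk, diff_freqs = diff_freqs),
            class = "discrete_scenario")
}

#' Define an admixed-population simulation scenario
#'
#' Each subject draws an ancestry proportion \eqn{a \sim U(0,1)} from
#' ancestral population 1 and carries allele frequency
#' \eqn{a p_1 + (1-a) p_2} at every SNP.  Disease risk increases with
#' ancestry: \eqn{P(D \mid a) = 0.5 \log(r) r^a / (r - 1)}, which
#' averages to 0.5 over \eqn{a}.
#'
#' @param ancestry_risk ancestry risk ratio `r` (> 1); default 3.
#' @param max_attempts cap on rejection-sampling draws while filling the
#'   case and control quotas.
#' @inheritParams discrete_scenario
#' @return An object of class `admixed_scenario`.
#' @export
admixed_scenario <- function(ancestry_risk = 3, fst = 0.01,
                             freq_low = 0.1, freq_high = 0.9,
                             n_cases = 500, n_controls = 500,
                             n_inference_snps = 20000,
                             n_testing_snps = 1000,
                             relative_risk = 1.3,
                             diff_freqs = c(0.8, 0.2),
                             max_attempts = 1e7) {
  if (ancestry_risk <= 1)
    stop("ancestry_risk must exceed 1 (risk model degenerate at r <= 1)")
  if (fst <= 0 || fst >= 1) stop("fst must lie in (0, 1)")
  if (!(freq_low > 0 && freq_low < freq_high && freq_high < 1))
    stop("need 0 < freq_low < freq_high < 1")
  if (relative_risk < 1) stop("relative_risk must be >= 1")
  if (length(diff_freqs) != 2)
    stop("diff_freqs must give the two ancestral frequencies")
  structure(list(ancestry_risk = ancestry_risk, fst = fst,
                 freq_low = freq_low, freq_high = freq_high,
                 n_cases = n_cases, n_controls = n_controls,
                 n_inference_snps = n_inference_snps,
                 n_testing_snps = n_testing_snps,
                 relative_risk = relative_risk, diff_freqs = diff_freqs,
                 max_attempts = max_attempts),
            class = "admixed_scenario")
}

#' Standard simulation scenarios
#'
#' Returns one of the stock population-stratification configurations:
#' `"S1"` and `"S2"` have two subpopulations with moderate
#' (0.6/0.4 vs 0.4/0.6) and extreme (0.5/0.5 vs 0/1) case-control
#' composition; `"S3"` and `"S4"` are the three-population analogues
#' (0.45/0.35/0.20 vs 0.35/0.20/0.45 and 0.33/0.67/0 vs 0/0.33/0.67);
#' `"admixed"` is the two-way admixture model with ancestry risk 3.
#'
#' @param name scenario label.
#' @param ... overrides passed to [discrete_scenario()] or
#'   [admixed_scenario()] (e.g. `n_testing_snps`).
#' @return A `discrete_scenario` or `admixed_scenario`.
#' @export
scenario_preset <- function(name = c("S1", "S2", "S3", "S4", "admixed"),
                            ...) {
  name <- match.arg(name)
  switch(name,
    S1 = discrete_scenario(c(0.6, 0.4), c(0.4, 0.6), ...),
    S2 = discrete_scenario(c(0.5, 0.5), c(0, 1), ...),
    S3 = discrete_scenario(c(0.45, 0.35, 0.20), c(0.35, 0.20, 0.45), ...),
    S4 = discrete_scenario(c(0.33, 0.67, 0), c(0, 0.33, 0.67), ...),
    admixed = admixed_scenario(...))
}

#' Draw subpopulation allele frequencies from the Beta divergence model
#'
#' Given an ancestral frequency `p_anc` and divergence `fst`, draws
#' independent subpopulation frequencies from
#' `Beta(p_anc (1 - fst) / fst, (1 - p_anc) (1 - fst) / fst)`, whose
#' mean is `p_anc` and variance `fst * p_anc * (1 - p_anc)`.
#'
#' @param p_anc ancestral allele frequency in (0, 1); may be a vector,
#'   in which case one draw per element is made for each population.
#' @param fst divergence coefficient in (0, 1).
#' @param n_pops number of subpopulations.
#' @return If `p_anc` is scalar, a vector of `n_pops` frequencies;
#'   otherwise an `n_pops` x `length(p_anc)` matrix.
#' @export
draw_subpop_freqs <- function(p_anc, fst, n_pops = 2) {
  if (any(p_anc <= 0) || any(p_anc >= 1))
    stop("p_anc must lie strictly in (0, 1)")
  if (fst <= 0 || fst >= 1) stop("fst must lie strictly in (0, 1)")
  a <- p_anc * (1 - fst) / fst
  b <- (1 - p_anc) * (1 - fst) / fst
  m <- length(p_anc)
  out <- matrix(rbeta(n_pops * m, rep(a, each = n_pops),
                      rep(b, each = n_pops)), nrow = n_pops)
  if (m == 1L) drop(out) else out
}

#' Sample control genotypes under Hardy-Weinberg equilibrium
#'
#' Genotypes 0/1/2 are drawn with probabilities `(1-p)^2`, `2p(1-p)`,
#' `p^2` for allele frequency `p`.
#'
#' @param freq allele frequency in \[0, 1\].
#' @param n number of draws.
#' @return Integer vector of genotypes.
#' @export
sample_control_genotypes <- function(freq, n) {
  if (freq < 0 || freq > 1) stop("freq must lie in [0, 1]")
  rbinom(n, 2L, freq)
}

#' Sample case genotypes at a causal SNP
#'
#' Cases at a causal SNP with per-allele relative risk `rr` receive
#' genotype 0/1/2 with relative probabilities `(1-p)^2`,
#' `2 rr p (1-p)`, `rr^2 p^2`, normalized by their sum.  With `rr = 1`
#' this reduces to the Hardy-Weinberg control model.
#'
#' @param freq allele frequency of the subject's population.
#' @param rr per-allele relative risk (>= 1).
#' @param n number of draws.
#' @return Integer vector of genotypes.
#' @export
sample_case_genotypes_causal <- function(freq, rr, n) {
  if (freq < 0 || freq > 1) stop("freq must lie in [0, 1]")
  if (rr < 1) stop("rr must be >= 1")
  pr <- c((1 - freq)^2, 2 * rr * freq * (1 - freq), rr^2 * freq^2)
  pr <- pr / sum(pr)
  u <- runif(n)
  as.integer((u > pr[1]) + (u > pr[1] + pr[2]))
}

# Deterministic largest-remainder apportionment of n subjects to
# populations with target proportions.
apportion <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# genotype draws for an n x p matrix of per-subject frequencies
rbinom_matrix <- function(P) {
  matrix(rbinom(length(P), 2L, P), nrow = nrow(P))
}

# causal-SNP genotypes: HWE for controls, risk-weighted for cases,
# vectorised over an n x p matrix of per-subject frequencies
causal_genotypes <- function(P, case, rr) {
  n <- nrow(P); p <- ncol(P)
  G <- matrix(0L, n, p)
  if (any(!case))
    G[!case, ] <- rbinom_matrix(P[!case, , drop = FALSE])
  if (any(case)) {
    Pc <- P[case, , drop = FALSE]
    p0 <- (1 - Pc)^2
    p1 <- 2 * rr * Pc * (1 - Pc)
    p2 <- rr^2 * Pc^2
    z <- p0 + p1 + p2
    u <- matrix(runif(length(Pc)), nrow(Pc))
    G[case, ] <- (u > p0 / z) + (u > (p0 + p1) / z)
  }
  G
}

make_snp_ids <- function(scn) {
  c(sprintf("inf_%05d", seq_len(scn$n_inference_snps)),
    if (scn$n_testing_snps > 0)
      c(sprintf("rnd_%05d", seq_len(scn$n_testing_snps)),
        sprintf("dif_%05d", seq_len(scn$n_testing_snps)),
        sprintf("cau_%05d", seq_len(scn$n_testing_snps))))
}

make_roles <- function(scn) {
  c(rep("inference", scn$n_inference_snps),
    if (scn$n_testing_snps > 0)
      rep(c("random", "differentiated", "causal"),
          each = scn$n_testing_snps))
}

new_genotype_dataset <- function(genotypes, phenotype, snp_role,
                                 subject_meta, snp_freqs, scenario) {
  structure(list(genotypes = genotypes, phenotype = phenotype,
                 snp_role = snp_role, subject_meta = subject_meta,
                 snp_freqs = snp_freqs, scenario = scenario),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  n <- nrow(x$genotypes); p <- ncol(x$genotypes)
  cat(sprintf("genotype_dataset: %d subjects x %d SNPs\n", n, p))
  cat(sprintf("  cases/controls: %d/%d\n", sum(x$phenotype == 1),
              sum(x$phenotype == 0)))
  cat("  SNP roles: ",
      paste(sprintf("%s=%d", names(table(x$snp_role)),
                    table(x$snp_role)), collapse = ", "), "\n", sep = "")
  if (any(x$subject_meta$outlier))
    cat(sprintf("  injected outliers: %d subjects\n",
                sum(x$subject_meta$outlier)))
  invisible(x)
}

#' Simulate a discrete-population case-control dataset
#'
#' Subjects are apportioned to subpopulations by the scenario's case and
#' control proportion vectors (largest-remainder rounding, so the
#' composition matches the proportions exactly).  Inference and random
#' testing SNPs draw subpopulation frequencies from the Beta divergence
#' model and genotypes under Hardy-Weinberg equilibrium; differentiated
#' SNPs use the fixed `diff_freqs` (default 0.8 vs 0.2); causal SNPs use
#' the relative-risk model of [sample_case_genotypes_causal()] with the
#' subject's own subpopulation frequency.
#'
#' @param scenario a [discrete_scenario()].
#' @param seed optional integer; when given, seeds the session RNG
#'   before simulation.
#' @return A `genotype_dataset`: list with integer matrix `genotypes`
#'   (subjects x SNPs, cases first), binary `phenotype`, `snp_role`
#'   (one of inference/random/differentiated/causal per column),
#'   `subject_meta` (id, phenotype, population, outlier flag) and
#'   `snp_freqs` (true per-population frequencies, populations x SNPs).
#' @export
simulate_discrete <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "discrete_scenario"))
  if (!is.null(seed)) set.seed(seed)
  scn <- scenario
  n <- scn$n_cases + scn$n_controls
  pop <- c(rep(seq_len(scn$n_pops), apportion(scn$n_cases, scn$case_props)),
           rep(seq_len(scn$n_pops), apportion(scn$n_controls,
                                              scn$control_props)))
  phen <- c(rep(1L, scn$n_cases), rep(0L, scn$n_controls))
  case <- phen == 1L

  n_beta <- scn$n_inference_snps +
    if (scn$n_testing_snps > 0) 2L * scn$n_testing_snps else 0L
  # frequency matrix for inference + random + causal SNPs
  p_anc <- runif(n_beta, scn$freq_low, scn$freq_high)
  F <- draw_subpop_freqs(p_anc, scn$fst, scn$n_pops)
  if (is.null(dim(F))) F <- matrix(F, nrow = scn$n_pops)

  nt <- scn$n_testing_snps
  ninf <- scn$n_inference_snps
  blocks <- list()
  freq_blocks <- list()
  # inference + random: HWE draws at the subject's population frequency
  idx_ir <- seq_len(ninf + if (nt > 0) nt else 0L)
  blocks$ir <- rbinom_matrix(F[pop, idx_ir, drop = FALSE])
  freq_blocks$ir <- F[, idx_ir, drop = FALSE]
  if (nt > 0) {
    Fd <- matrix(scn$diff_freqs, scn$n_pops, nt)
    blocks$diff <- rbinom_matrix(Fd[pop, , drop = FALSE])
    freq_blocks$diff <- Fd
    Fc <- F[, ninf + nt + seq_len(nt), drop = FALSE]
    blocks$causal <- causal_genotypes(Fc[pop, , drop = FALSE], case,
                                      scn$relative_risk)
    freq_blocks$causal <- Fc
  }
  G <- do.call(cbind, blocks)
  freqs <- do.call(cbind, freq_blocks)
  ids <- make_snp_ids(scn)
  dimnames(G) <- list(sprintf("subj_%04d", seq_len(n)), ids)
  colnames(freqs) <- ids
  meta <- data.frame(subject = rownames(G), phenotype = phen,
                     population = pop, outlier = FALSE,
                     stringsAsFactors = FALSE)
  new_genotype_dataset(G, phen, make_roles(scn), meta, freqs, scn)
}

#' Simulate an admixed-population case-control dataset
#'
#' Candidate subjects draw an ancestry proportion \eqn{a \sim U(0,1)}
#' and disease status with probability
#' \eqn{0.5\log(r)\,r^a/(r-1)}; rejection sampling continues until the
#' case and control quotas are filled (capped at
#' `scenario$max_attempts` draws).  Every SNP's subject-level allele
#' frequency is the ancestry mixture \eqn{a p_1 + (1-a) p_2} of two
#' ancestral frequencies from the Beta divergence model; differentiated
#' SNPs mix the fixed frequencies 0.8 and 0.2, and causal SNPs apply
#' the relative-risk genotype model at the mixture frequency.
#'
#' @param scenario an [admixed_scenario()].
#' @param seed optional integer seed.
#' @return A `genotype_dataset`; `subject_meta$ancestry` stores each
#'   subject's true ancestry proportion `a`.
#' @export
simulate_admixed <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "admixed_scenario"))
  if (!is.null(seed)) set.seed(seed)
  scn <- scenario
  r <- scn$ancestry_risk

  a_case <- numeric(0); a_ctrl <- numeric(0)
  attempts <- 0
  batch <- max(1000L, 2L * (scn$n_cases + scn$n_controls))
  while ((length(a_case) < scn$n_cases ||
          length(a_ctrl) < scn$n_controls)) {
    if (attempts >= scn$max_attempts)
      stop("admixed sampling failed to fill case/control quotas")
    m <- min(batch, scn$max_attempts - attempts)
    attempts <- attempts + m
    a <- runif(m)
    pd <- 0.5 * log(r) * r^a / (r - 1)
    dis <- runif(m) < pd
    a_case <- c(a_case, a[dis])
    a_ctrl <- c(a_ctrl, a[!dis])
  }
  a <- c(a_case[seq_len(scn$n_cases)], a_ctrl[seq_len(scn$n_controls)])
  phen <- c(rep(1L, scn$n_cases), rep(0L, scn$n_controls))
  case <- phen == 1L
  n <- length(a)

  nt <- scn$n_testing_snps
  ninf <- scn$n_inference_snps
  n_beta <- ninf + if (nt > 0) 2L * nt else 0L
  p_anc <- runif(n_beta, scn$freq_low, scn$freq_high)
  F <- draw_subpop_freqs(p_anc, scn$fst, 2L)
  if (is.null(dim(F))) F <- matrix(F, nrow = 2L)

  mix <- function(cols) outer(a, cols[1, ]) + outer(1 - a, cols[2, ])
  blocks <- list(); freq_blocks <- list()
  idx_ir <- seq_len(ninf + if (nt > 0) nt else 0L)
  blocks$ir <- rbinom_matrix(mix(F[, idx_ir, drop = FALSE]))
  freq_blocks$ir <- F[, idx_ir, drop = FALSE]
  if (nt > 0) {
    Fd <- matrix(scn$diff_freqs, 2L, nt)
    blocks$diff <- rbinom_matrix(mix(Fd))
    freq_blocks$diff <- Fd
    Fc <- F[, ninf + nt + seq_len(nt), drop = FALSE]
    blocks$causal <- causal_genotypes(mix(Fc), case, scn$relative_risk)
    freq_blocks$causal <- Fc
  }
  G <- do.call(cbind, blocks)
  freqs <- do.call(cbind, freq_blocks)
  ids <- make_snp_ids(scn)
  dimnames(G) <- list(sprintf("subj_%04d", seq_len(n)), ids)
  colnames(freqs) <- ids
  meta <- data.frame(subject = rownames(G), phenotype = phen,
                     ancestry = a, outlier = FALSE,
                     stringsAsFactors = FALSE)
  new_genotype_dataset(G, phen, make_roles(scn), meta, freqs, scn)
}

#' Inject subject outliers through a singular-vector perturbation
#'
#' Computes the singular value decomposition \eqn{X = U d V'} of the
#' genotype matrix, replaces a fraction of the entries of the
#' `eigen_index`-th left singular vector (subjects chosen uniformly at
#' random) with values of magnitude `magnitude` and alternating sign,
#' reconstructs \eqn{X_{mod} = U_{mod} d V'}, and clips all entries to
#' `[clip_low, clip_high]`.  Unselected rows change only through
#' clipping (and integer genotypes already lie inside the default
#' bounds).  The reconstructed matrix is real-valued; it is not
#' re-rounded to integers, and downstream methods accept such dosages.
#'
#' The default `magnitude` is 10 times the largest absolute entry of
#' the original singular vector, which produces clearly separated
#' outliers while remaining bounded by the clipping step.
#'
#' @param x a genotype matrix or a `genotype_dataset`.
#' @param fraction proportion of subjects perturbed (default 0.05);
#'   `ceiling(fraction * n)` subjects are selected.
#' @param eigen_index which left singular vector to modify (default 2,
#'   the leading axis of population structure in a raw genotype
#'   matrix).
#' @param magnitude absolute size of the replacement entries; `NULL`
#'   for the default above.
#' @param clip_low,clip_high clipping bounds for reconstructed
#'   genotypes; use `-Inf`/`Inf` to disable clipping.
#' @param seed optional integer seed.
#' @param ... passed between methods.
#' @return For a matrix: list with `genotypes` (modified matrix),
#'   `outlier_idx` (selected subjects) and `magnitude` used.  For a
#'   `genotype_dataset`: the dataset with modified genotypes and
#'   `subject_meta$outlier` flagged.
#' @export
inject_outliers <- function(x, ...) UseMethod("inject_outliers")

#' @rdname inject_outliers
#' @export
inject_outliers.matrix <- function(x, fraction = 0.05, eigen_index = 2,
                                   magnitude = NULL, clip_low = 0,
                                   clip_high = 2, seed = NULL, ...) {
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  if (clip_low >= clip_high) stop("clip_low must be below clip_high")
  if (fraction == 0)
    return(list(genotypes = x, outlier_idx = integer(0), magnitude = 0))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  if (eigen_index < 1 || eigen_index > min(dim(x)))
    stop("eigen_index must lie in 1..min(n, p)")
  m <- ceiling(fraction * n)
  if (ncol(x) > 1.5 * n) {
    # left singular vectors from the n x n Gram matrix (X X') --
    # identical decomposition, much cheaper for wide genotype panels
    ee <- eigen(tcrossprod(x), symmetric = TRUE)
    u <- ee$vectors[, eigen_index]
    d <- sqrt(max(ee$values[eigen_index], 0))
    v <- drop(crossprod(x, u)) / d
  } else {
    sv <- svd(x, nu = eigen_index, nv = eigen_index)
    u <- sv$u[, eigen_index]
    v <- sv$v[, eigen_index]
    d <- sv$d[eigen_index]
  }
  if (is.null(magnitude)) magnitude <- 10 * max(abs(u))
  idx <- sample.int(n, m)
  u_new <- u
  u_new[idx] <- rep_len(c(1, -1), m) * magnitude
  xmod <- x + outer(u_new - u, d * v)
  xmod[xmod < clip_low] <- clip_low
  xmod[xmod > clip_high] <- clip_high
  dimnames(xmod) <- dimnames(x)
  list(genotypes = xmod, outlier_idx = sort(idx), magnitude = magnitude)
}

#' @rdname inject_outliers
#' @export
inject_outliers.genotype_dataset <- function(x, ...) {
  res <- inject_outliers(x$genotypes, ...)
  x$genotypes <- res$genotypes
  x$subject_meta$outlier <- seq_len(nrow(res$genotypes)) %in% res$outlier_idx
  x
}
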