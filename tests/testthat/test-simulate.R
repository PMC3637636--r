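# Simulators: Beta frequency model, HWE genotype sampling, causal risk
# model, discrete and admixed dataset construction, outlier injection.

test_that("subpopulation frequencies follow the Beta divergence model", {
  expect_error(draw_subpop_freqs(0, 0.01), "p_anc")
  expect_error(draw_subpop_freqs(0.5, 1), "fst")
  set.seed(1)
  f <- draw_subpop_freqs(0.5, 0.01, n_pops = 3)
  expect_length(f, 3)
  expect_true(all(f > 0 & f < 1))
  # moments: mean p_anc, variance fst * p * (1 - p)
  n <- 1e5
  draws <- as.numeric(draw_subpop_freqs(rep(0.3, n), 0.01, n_pops = 1))
  se_mean <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - 0.3), 3 * se_mean)
  v_target <- 0.01 * 0.3 * 0.7
  se_var <- var(draws) * sqrt(2 / (n - 1))
  expect_lt(abs(var(draws) - v_target), 3 * se_var)
})

test_that("control genotypes follow Hardy-Weinberg proportions", {
  expect_identical(sample_control_genotypes(0, 50), rep(0L, 50))
  expect_identical(sample_control_genotypes(1, 50), rep(2L, 50))
  set.seed(2)
  g <- sample_control_genotypes(0.5, 1e5)
  pr <- tabulate(g + 1L, 3) / 1e5
  target <- c(0.25, 0.5, 0.25)
  se <- sqrt(target * (1 - target) / 1e5)
  expect_true(all(abs(pr - target) < 3 * se))
})

test_that("causal case genotypes follow the relative-risk model", {
  # R = 1 reduces to HWE
  set.seed(3)
  g1 <- sample_case_genotypes_causal(0.4, 1, 2e5)
  pr1 <- tabulate(g1 + 1L, 3) / 2e5
  hwe <- c(0.36, 0.48, 0.16)
  expect_true(all(abs(pr1 - hwe) < 3 * sqrt(hwe * (1 - hwe) / 2e5)))
  # normalized relative probabilities at p = 0.5, R = 1.3:
  # ((1-p)^2, 2Rp(1-p), R^2 p^2) / Z = (0.1890, 0.4915, 0.3195)
  g2 <- sample_case_genotypes_causal(0.5, 1.3, 2e5)
  pr2 <- tabulate(g2 + 1L, 3) / 2e5
  tgt <- c(0.25, 0.65, 0.4225) / 1.3225
  expect_true(all(abs(pr2 - tgt) < 3 * sqrt(tgt * (1 - tgt) / 2e5)))
  # case allele frequency exceeds the population frequency when R > 1
  expect_gt(mean(g2) / 2, 0.5)
})

test_that("discrete datasets respect the scenario composition", {
  scn <- discrete_scenario(c(0.5, 0.5), c(0, 1), n_cases = 60,
                           n_controls = 40, n_inference_snps = 30,
                           n_testing_snps = 10)
  ds <- simulate_discrete(scn, seed = 5)
  expect_s3_class(ds, "genotype_dataset")
  expect_equal(sum(ds$phenotype), 60)
  # S2 rule: every control from population 2
  expect_true(all(ds$subject_meta$population[ds$phenotype == 0] == 2))
  expect_equal(unname(table(ds$snp_role)[c("inference", "random",
                                           "differentiated", "causal")]),
               c(30L, 10L, 10L, 10L),
               ignore_attr = TRUE)
  expect_true(all(ds$genotypes %in% 0:2))
  # testing SNPs optional
  ds0 <- simulate_discrete(
    discrete_scenario(c(0.5, 0.5), c(0, 1), n_cases = 10,
                      n_controls = 10, n_inference_snps = 20,
                      n_testing_snps = 0), seed = 6)
  expect_true(all(ds0$snp_role == "inference"))
  # reproducibility
  ds_a <- simulate_discrete(scn, seed = 9)
  ds_b <- simulate_discrete(scn, seed = 9)
  expect_identical(ds_a$genotypes, ds_b$genotypes)
})

test_that("differentiated SNPs carry the expected case-control gap", {
  # S1: case mix (0.6, 0.4), control mix (0.4, 0.6), freqs 0.8/0.2
  # => mean allele-frequency difference 0.2 * 0.6 = 0.12
  scn <- discrete_scenario(c(0.6, 0.4), c(0.4, 0.6), n_cases = 500,
                           n_controls = 500, n_inference_snps = 10,
                           n_testing_snps = 300)
  ds <- simulate_discrete(scn, seed = 7)
  G <- ds$genotypes[, ds$snp_role == "differentiated"]
  d <- colMeans(G[ds$phenotype == 1, ]) / 2 -
    colMeans(G[ds$phenotype == 0, ]) / 2
  expect_lt(abs(mean(d) - 0.12), 0.01)
})

test_that("admixed model has calibrated disease risk and ancestry signal", {
  # P(disease | a) = 0.5 log(r) r^a / (r - 1) integrates to 0.5
  for (r in c(1.5, 3, 10)) {
    f <- function(a) 0.5 * log(r) * r^a / (r - 1)
    expect_equal(integrate(f, 0, 1)$value, 0.5, tolerance = 1e-8)
  }
  # endpoint values at r = 3
  expect_equal(0.5 * log(3) / 2, 0.27465, tolerance = 1e-4)
  expect_equal(0.5 * log(3) * 3 / 2, 0.82397, tolerance = 1e-4)
  scn <- admixed_scenario(n_cases = 300, n_controls = 300,
                          n_inference_snps = 60, n_testing_snps = 5)
  ds <- simulate_admixed(scn, seed = 8)
  expect_equal(sum(ds$phenotype), 300)
  a <- ds$subject_meta$ancestry
  expect_gt(mean(a[ds$phenotype == 1]), mean(a[ds$phenotype == 0]))
  expect_error(admixed_scenario(ancestry_risk = 1), "ancestry_risk")
})

test_that("outlier injection perturbs the chosen singular vector only", {
  set.seed(10)
  X <- matrix(rbinom(200 * 80, 2, 0.4), 200, 80)
  # fraction 0 is a no-op
  r0 <- inject_outliers(X, fraction = 0)
  expect_identical(r0$genotypes, X)
  r <- inject_outliers(X, fraction = 0.05, seed = 11)
  expect_length(r$outlier_idx, ceiling(0.05 * 200))
  expect_true(all(r$genotypes >= 0 & r$genotypes <= 2))
  # magnitude 0 zeroes the selected subjects' second-component term
  r2 <- inject_outliers(X, fraction = 0.1, magnitude = 0,
                        clip_low = -Inf, clip_high = Inf, seed = 12)
  sv <- svd(X)
  expected <- X
  expected[r2$outlier_idx, ] <- X[r2$outlier_idx, ] -
    outer(sv$u[r2$outlier_idx, 2], sv$d[2] * sv$v[, 2])
  expect_equal(r2$genotypes, expected, tolerance = 1e-8)
  expect_error(inject_outliers(X, eigen_index = 100), "eigen_index")
})
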