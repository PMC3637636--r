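# Shared simulated fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

fx_s2_clean <- function() fixture("s2_clean", function() {
  simulate_discrete(scenario_preset("S2", n_testing_snps = 0),
                    seed = 101)
})

fx_s2_out <- function() fixture("s2_out", function() {
  inject_outliers(fx_s2_clean(), fraction = 0.05, seed = 102)
})

fx_s4_clean <- function() fixture("s4_clean", function() {
  simulate_discrete(scenario_preset("S4", n_testing_snps = 0),
                    seed = 202)
})

fx_s4_out <- function() fixture("s4_out", function() {
  inject_outliers(fx_s4_clean(), fraction = 0.05, seed = 203)
})

fx_s4_out_diag <- function() fixture("s4_out_diag", function() {
  ds <- fx_s4_out()
  rpca_diagnostics(ds$genotypes[, ds$snp_role == "inference"], K = 5)
})

fx_admixed <- function() fixture("admixed", function() {
  simulate_admixed(scenario_preset("admixed", n_inference_snps = 5000,
                                   n_testing_snps = 0), seed = 404)
})

inference_matrix <- function(ds) {
  ds$genotypes[, ds$snp_role == "inference", drop = FALSE]
}

# angle between two directions, sign-invariant
principal_angle <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(min(1, abs(sum(a * b))))
}

# small dataset for fast association/method tests
fx_tiny <- function() fixture("tiny", function() {
  scn <- discrete_scenario(c(0.5, 0.5), c(0, 1), n_cases = 100,
                           n_controls = 100, n_inference_snps = 300,
                           n_testing_snps = 20)
  simulate_discrete(scn, seed = 777)
})
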