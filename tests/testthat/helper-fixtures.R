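# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

dlbcl_traits <- function() disease_traits("dlbcl")

gbm_traits <- function() disease_traits("gbm")

# a small DLBCL-like cohort reused across endpoint/validation tests
small_cohort <- function(n = 60, seed = 42) {
  cached(sprintf("cohort_%d_%d", n, seed), synthetic_cohort(n, seed))
}

cohort_sims <- function(reg_string, n = 60, seed = 42) {
  cached(paste0("sims_", reg_string, "_", n, "_", seed),
         simulate_cohort(small_cohort(n, seed),
                         reg = parse_regimen(reg_string)))
}

# noise-free observations of a known patient at the sparse study days
observed_days <- c(1, 8, 15, 22, 28)

known_patient_obs <- function(traits, reg, days = observed_days,
                              sigma = 0, seed = NULL) {
  sim <- simulate_patient(traits, reg = reg)
  anc <- anc_at_days(sim, days)
  if (sigma > 0) {
    stopifnot(!is.null(seed))
    set.seed(seed)
    anc <- anc * exp(rnorm(length(anc), 0, sigma))
  }
  data.frame(time_h = 24 * (days - 1), anc = anc)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual / expected - 1) < tol),
              label = sprintf("max rel dev %.3g (tol %.3g)",
                              max(abs(actual / expected - 1)), tol))
}
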