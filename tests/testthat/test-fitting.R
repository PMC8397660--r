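# Objective function and Nelder-Mead parameter regression.

test_that("objective is the weighted sum of absolute normalized differences", {
  sim <- list(times = 24 * (0:28), anc = rep(4.5e9, 29))
  class(sim) <- "anc_series"
  obs <- data.frame(time_h = c(0, 24, 48), anc = c(4.5e9, 4.5e9, 4.5e9))
  expect_equal(anc_objective(sim, obs), 0)

  # one observation 10% below the simulation, unit weight
  obs1 <- data.frame(time_h = 24, anc = 4.5e9 / 1.1)
  expect_equal(anc_objective(sim, obs1), 0.1, tolerance = 1e-12)

  # hand-computed three-point example
  sim2 <- list(times = c(0, 24, 48), anc = c(4.5e9, 3.6e9, 2.2e9))
  class(sim2) <- "anc_series"
  obs2 <- data.frame(time_h = c(0, 24, 48), anc = c(4.5e9, 4.0e9, 2.0e9))
  expect_equal(anc_objective(sim2, obs2), 0.2, tolerance = 1e-12)
  # weights scale the terms
  expect_equal(anc_objective(sim2, obs2, weights = c(1, 2, 1)), 0.3,
               tolerance = 1e-12)
})

test_that("objective skips zero observations and honors censoring", {
  sim <- list(times = c(0, 24, 48), anc = c(4e9, 4e9, 4e9))
  class(sim) <- "anc_series"
  obs <- data.frame(time_h = c(0, 24), anc = c(0, 2e9))
  expect_warning(v <- anc_objective(sim, obs), "zero")
  expect_equal(v, 1)
  obs2 <- data.frame(time_h = c(0, 24, 48), anc = c(4e9, 2e9, 2e9))
  attr(obs2, "censored_after") <- 24
  expect_equal(anc_objective(sim, obs2), 0)   # only t=0 survives
})

test_that("objective is invariant to common rescaling of sim and obs", {
  sim <- list(times = c(0, 24, 48), anc = c(4.5e9, 3.6e9, 2.2e9))
  class(sim) <- "anc_series"
  obs <- data.frame(time_h = c(0, 24, 48), anc = c(4.5e9, 4.0e9, 2.0e9))
  sim2 <- sim; sim2$anc <- sim$anc * 1e-9
  obs2 <- obs; obs2$anc <- obs$anc * 1e-9
  expect_equal(anc_objective(sim, obs), anc_objective(sim2, obs2))
})

test_that("fit specification validates its inputs", {
  expect_error(fit_spec(character(0), c(), c(), c()), "non-empty")
  expect_error(fit_spec("nonsense", c(nonsense = 1), c(nonsense = 2),
                        c(nonsense = 1.5)), "among")
  expect_error(fit_spec("gamma", c(gamma = -1), c(gamma = 1),
                        c(gamma = 0.01)), "finite, positive")
  expect_error(fit_spec("gamma", c(gamma = 0.001), c(gamma = 1),
                        c(gamma = 2)), "outside")
})

test_that("noise-free fit recovers the generating traits", {
  reg <- regimen(3, 5, 2)
  truth <- patient_traits(4.2e9, 2.8, 0.12, 0.012)
  obs <- known_patient_obs(truth, reg)
  fr <- fit_patient(obs, default_fit_spec(), reg, circ0 = truth$circ0)
  expect_lt(abs(fr$par[["ratio_reserv0_circ0"]] / 2.8 - 1), 0.05)
  expect_lt(abs(fr$par[["gamma"]] / 0.012 - 1), 0.05)
  expect_lt(abs(fr$par[["km_fraction"]] / 0.12 - 1), 0.5)
  expect_lt(fr$objective, 1e-3)
  # objective at the solution does not exceed the initial guess
  init_tr <- dlbcl_traits()
  sim_init <- simulate_patient(patient_traits(truth$circ0,
    init_tr$ratio_reserv0_circ0, init_tr$km_fraction, init_tr$gamma),
    reg = reg)
  expect_lte(fr$objective, anc_objective(sim_init, obs))
})

test_that("fit is deterministic and requires enough observations", {
  reg <- regimen(3, 5, 2)
  truth <- patient_traits(4.2e9, 2.6, 0.1, 0.011)
  obs <- known_patient_obs(truth, reg, days = c(8, 15, 22, 28))
  f1 <- fit_patient(obs, default_fit_spec(), reg, circ0 = truth$circ0,
                    maxit = 120)
  f2 <- fit_patient(obs, default_fit_spec(), reg, circ0 = truth$circ0,
                    maxit = 120)
  expect_identical(f1$par, f2$par)
  expect_error(fit_patient(obs[1:2, ], default_fit_spec(), reg),
               "at least 3")
})

test_that("simultaneous multi-group fit recovers one shared parameter set", {
  truth <- patient_traits(4.5e9, 2.7, 0.13, 0.013)
  regs <- list(regimen(3, 28, 0), regimen(6, 5, 2))
  obs_list <- lapply(regs, function(r) known_patient_obs(truth, r))
  fr <- fit_cohort_median(obs_list, default_fit_spec(), regs,
                          circ0s = rep(truth$circ0, 2))
  expect_lt(abs(fr$par[["ratio_reserv0_circ0"]] / 2.7 - 1), 0.02)
  expect_lt(abs(fr$par[["gamma"]] / 0.013 - 1), 0.02)
})

test_that("five-parameter multi-dose fit recovers the PD parameters", {
  # the first-stage workflow fit: PD (EC50, Hill) plus the three traits,
  # regressed simultaneously from several dose groups of one cohort
  truth_tr <- patient_traits(4.5e9, 3, 0.6, 0.02)
  truth_pd <- pd_params(0.9, 15, 2)
  days <- c(1, 4, 8, 11, 15, 18, 22, 25, 28)
  regs <- list(regimen(3, 28, 0), regimen(5, 28, 0), regimen(7, 5, 2))
  obs_list <- lapply(regs, function(r) {
    s <- simulate_patient(truth_tr, pd = truth_pd, reg = r)
    data.frame(time_h = 24 * (days - 1), anc = anc_at_days(s, days))
  })
  spec <- fit_spec(
    free = c("gamma", "ratio_reserv0_circ0", "km_fraction", "ec50", "n_hill"),
    lower = c(gamma = 1e-4, ratio_reserv0_circ0 = 0.5, km_fraction = 0.01,
              ec50 = 2, n_hill = 0.5),
    upper = c(gamma = 2, ratio_reserv0_circ0 = 10, km_fraction = 5,
              ec50 = 100, n_hill = 6),
    init = c(gamma = 0.01, ratio_reserv0_circ0 = 2.5, km_fraction = 0.3,
             ec50 = 25, n_hill = 1.5))
  fr <- fit_cohort_median(obs_list, spec, regs, circ0s = rep(4.5e9, 3),
                          maxit = 600)
  expect_lt(abs(fr$par[["ec50"]] / 15 - 1), 0.1)
  expect_lt(abs(fr$par[["n_hill"]] / 2 - 1), 0.1)
  expect_lt(abs(fr$par[["ratio_reserv0_circ0"]] / 3 - 1), 0.05)
})

test_that("a single-group cohort fit reduces to the patient fit", {
  reg <- regimen(3, 5, 2)
  truth <- patient_traits(4.2e9, 2.8, 0.12, 0.012)
  obs <- known_patient_obs(truth, reg)
  f_pat <- fit_patient(obs, default_fit_spec(), reg, circ0 = truth$circ0,
                       maxit = 150)
  f_coh <- fit_cohort_median(list(obs), default_fit_spec(), list(reg),
                             circ0s = truth$circ0, maxit = 150)
  expect_equal(f_pat$par, f_coh$par, tolerance = 1e-6)
})
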