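# Homeostatic parameter cascade, feedbacks, and the ODE right-hand side.

test_that("homeostatic cascade reproduces the published GBM and DLBCL rates", {
  gbm <- derive_homeostatic_parameters(patient_traits(4.5e9, 3, 0.6, 0.02),
                                       t_half = 30, k_d = 0.001)
  expect_equal(signif(gbm$k_elim, 3), 0.0231)
  expect_equal(signif(gbm$k_out, 2), 0.0077)
  expect_equal(signif(gbm$k_tr4, 3), 0.0261)
  expect_equal(signif(gbm$k_tr3_nominal, 3), 0.0271)
  expect_equal(signif(gbm$k_tr2, 3), 0.0281)
  expect_equal(signif(gbm$k_tr1, 3), 0.0291)
  expect_equal(gbm$k_prol, gbm$k_tr1)
  expect_equal(gbm$reserv0, 1.35e10)
  expect_equal(gbm$k_m, 2.7e9)
  expect_equal(signif(gbm$v_max, 4), 1.952e8)

  dl <- derive_homeostatic_parameters(patient_traits(4.5e9, 2.5, 0.1, 0.01))
  expect_equal(signif(dl$k_out, 2), 0.0092)
  expect_equal(signif(dl$k_tr4, 3), 0.0256)
  expect_equal(dl$k_m, 4.5e8)
  expect_equal(signif(dl$v_max, 4), 1.317e8)

  mm <- derive_homeostatic_parameters(patient_traits(4.5e9, 2.5, 0.45, 0.017))
  expect_equal(signif(mm$v_max, 4), 1.736e8)
})

test_that("cascade satisfies every consistency identity", {
  p <- derive_homeostatic_parameters(patient_traits(3.7e9, 2.2, 0.17, 0.013),
                                     t_half = 24, k_d = 0.002, beta = 15)
  expect_equal(p$k_elim, log(2) / 24)
  expect_equal(p$k_out * p$reserv0, p$k_elim * p$circ_homeostatic)
  expect_equal(p$k_tr4 * p$tran0, (p$k_d + p$k_out) * p$reserv0)
  expect_equal(p$k_tr3_nominal, p$k_tr4 + p$k_d)
  expect_equal(p$k_tr2, p$k_tr3_nominal + p$k_d)
  expect_equal(p$k_tr1, p$k_tr2 + p$k_d)
  expect_equal(p$k_prol, p$k_tr1)
  expect_equal(p$v_max, p$k_tr3_nominal * (p$k_m + p$tran0))
  expect_equal(p$k_m, 0.17 * p$tran0)
})

test_that("zero maturation death and unit ratio collapse all rates to k_elim", {
  p <- derive_homeostatic_parameters(patient_traits(4.5e9, 1, 0.5, 0.01),
                                     k_d = 0)
  rates <- c(p$k_out, p$k_tr4, p$k_tr3_nominal, p$k_tr2, p$k_tr1, p$k_prol)
  expect_equal(rates, rep(p$k_elim, 6))
})

test_that("invalid traits and constants are rejected", {
  expect_error(patient_traits(-1, 2.5, 0.1, 0.01), "circ0")
  expect_error(patient_traits(4.5e9, 0, 0.1, 0.01), "ratio")
  expect_error(patient_traits(4.5e9, 2.5, 0, 0.01), "km_fraction")
  expect_error(patient_traits(4.5e9, 2.5, 0.1, -0.1), "gamma")
  tr <- patient_traits(4.5e9, 2.5, 0.1, 0.01)
  expect_error(derive_homeostatic_parameters(tr, t_half = 0), "t_half")
  expect_error(derive_homeostatic_parameters(tr, k_d = -1), "k_d")
})

test_that("feedback multipliers follow their power-law definitions", {
  # at homeostasis both feedbacks are identity
  expect_equal(feedback_proliferation(3e9, 3e9, 0.7), 1)
  expect_equal(feedback_egress(4.5e9, 4.5e9, 20), 1)
  expect_equal(feedback_egress(1e9, 4.5e9, 0), 1)
  # depletion stimulates, with frozen direct-power expectations
  expect_equal(feedback_proliferation(1.5e9, 3e9, 1), 2)
  expect_equal(feedback_proliferation(1.5e9, 3e9, 0.01), 1.0069556,
               tolerance = 1e-7)
  expect_equal(feedback_egress(0.9 * 4.5e9, 4.5e9, 20), 8.2252,
               tolerance = 1e-4)
  # accumulation above homeostatic damps proliferation
  expect_lt(feedback_proliferation(6e9, 3e9, 0.5), 1)
})

test_that("feedbacks clamp at the 1 cell/L floor with a warning", {
  expect_warning(v <- feedback_egress(0, 4.5e9, 20), "floor")
  expect_equal(v, (4.5e9 / 1)^20)
  expect_warning(feedback_proliferation(-5, 3e9, 0.5), "floor")
})

test_that("rhs vanishes at the homeostatic state and conserves fluxes", {
  p <- derive_homeostatic_parameters(patient_traits(4.5e9, 2.5, 0.1, 0.01))
  y0 <- initial_state(p)
  d0 <- lifecycle_rhs(y0, p, effect = 1)
  expect_true(all(abs(d0) / y0 < 1e-9))

  # flux decomposition at an arbitrary state: inter-compartment transfers
  # cancel pairwise, so the total balance is production minus losses only
  y <- y0 * c(1.2, 0.8, 2.5, 0.6, 0.4, 0.9)
  eff <- 0.4
  d <- lifecycle_rhs(y, p, effect = eff)
  fb_prol <- feedback_proliferation(y[["transit2"]], p$transit2_homeostatic,
                                    p$gamma)
  fb_egr <- feedback_egress(y[["circ"]], p$circ_homeostatic, p$beta)
  production <- p$k_prol * fb_prol * y[["prol"]]
  losses <- p$k_d * (y[["transit1"]] + y[["transit2"]] + y[["transit3"]] +
                       y[["reserv"]]) + p$k_elim * y[["circ"]]
  expect_equal(sum(d), production - losses, tolerance = 1e-12)

  # the Michaelis-Menten flux leaves transit2 and enters transit3 unchanged
  mm <- p$v_max * eff * y[["transit2"]] / (p$k_m + y[["transit2"]])
  expect_equal(d[["transit2"]],
               p$k_tr2 * y[["transit1"]] - mm - p$k_d * y[["transit2"]])
  expect_equal(d[["transit3"]], mm - (p$k_tr4 + p$k_d) * y[["transit3"]])
})

test_that("maturation flux at homeostasis equals the nominal transit rate", {
  p <- derive_homeostatic_parameters(patient_traits(4.5e9, 2.5, 0.1, 0.01))
  y0 <- initial_state(p)
  mm <- p$v_max * 1 * p$tran0 / (p$k_m + p$tran0)
  expect_equal(mm, p$k_tr3_nominal * p$tran0)
  # saturation limit: as transit2 grows the flux tends to effect * v_max
  y_inf <- y0; y_inf[["transit2"]] <- 1e15
  d <- lifecycle_rhs(y_inf, p, effect = 0.1)
  flux_in_t3 <- d[["transit3"]] + (p$k_tr4 + p$k_d) * y_inf[["transit3"]]
  expect_equal(flux_in_t3, 0.1 * p$v_max, tolerance = 1e-5)
})

test_that("effect outside (0, 1] is rejected", {
  p <- derive_homeostatic_parameters(dlbcl_traits())
  y0 <- initial_state(p)
  expect_error(lifecycle_rhs(y0, p, effect = 0), "effect")
  expect_error(lifecycle_rhs(y0, p, effect = 1.5), "effect")
})

test_that("28-day drug-free simulation holds every compartment to 0.1%", {
  s <- simulate_patient(dlbcl_traits(), reg = regimen(0, 5, 2))
  rel <- abs(sweep(s$states, 2, s$states[1, ], "/") - 1)
  expect_lt(max(rel), 1e-3)
})

test_that("stiff solver matches a fixed-step RK4 oracle over 48 h", {
  p <- derive_homeostatic_parameters(dlbcl_traits())
  rk4 <- function(effect) {
    h <- 0.01
    y <- initial_state(p)
    keep <- matrix(NA_real_, 49, 6, dimnames = list(NULL, names(y)))
    keep[1, ] <- y
    for (i in 1:4800) {
      k1 <- lifecycle_rhs(y, p, effect)
      k2 <- lifecycle_rhs(y + h / 2 * k1, p, effect)
      k3 <- lifecycle_rhs(y + h / 2 * k2, p, effect)
      k4 <- lifecycle_rhs(y + h * k3, p, effect)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (i %% 100 == 0) keep[i / 100 + 1, ] <- y
    }
    keep
  }
  for (eff in c(1, 0.5)) {
    tg <- seq(0, 48, by = 1)
    stiff <- neutroqsp:::.integrate_lifecycle(p, tg, rep(eff, length(tg)))
    oracle <- rk4(eff)
    expect_lt(max(abs(stiff / oracle - 1)), 1e-4)
  }
})

test_that("with egress zeroed, circulation decays exponentially at k_elim", {
  p <- derive_homeostatic_parameters(dlbcl_traits())
  p$k_out <- 0
  tg <- seq(0, 96, by = 1)
  states <- neutroqsp:::.integrate_lifecycle(p, tg, rep(1, length(tg)),
                                             rtol = 1e-10, atol = 1e-4)
  expect_rel_equal(states[, "circ"],
                   p$circ_homeostatic * exp(-p$k_elim * tg), 1e-6)
})
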