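# Dosing schedules, two-compartment PK, exposure metrics, PD effect.

test_that("schedule expansion gives the published cycle-1 dose counts", {
  expect_length(dosing_times(regimen(6, 5, 2), 28), 20)
  expect_length(dosing_times(regimen(6, 21, 7), 28), 21)
  expect_length(dosing_times(regimen(6, 28, 0), 28), 28)
  expect_length(dosing_times(regimen(6, 3, 4), 28), 12)
  expect_length(dosing_times(regimen(6, 7, 7), 28), 14)
  expect_length(dosing_times(regimen(6, 14, 14), 28), 14)
})

test_that("dose times are strictly increasing, 24 h apart within runs", {
  dt <- dosing_times(regimen(4, 5, 2), 28)
  expect_true(all(diff(dt) > 0))
  expect_equal(dt[1:5], 24 * (0:4))        # first on-run, daily
  expect_equal(dt[6], 24 * 7)              # next run starts after the break
  dt2 <- dosing_times(regimen(4, 5, 2, dose_hour = 9), 7)
  expect_equal(dt2, 24 * (0:4) + 9)
})

test_that("invalid regimens are rejected", {
  expect_error(regimen(4, 0, 7), "days_on")
  expect_error(regimen(4, 2.5, 4), "days_on")
  expect_error(regimen(4, -1, 7), "days_on")
  expect_error(parse_regimen("0/7"), "parse")
  expect_error(parse_regimen("4mg 0/7"), "schedule")
  expect_error(parse_regimen("4mg 8/7"), "schedule")
})

test_that("regimen strings round-trip", {
  r <- parse_regimen("6mg 5/7")
  expect_equal(r$dose_mg, 6)
  expect_equal(r$days_on, 5L)
  expect_equal(r$days_off, 2L)
  r2 <- parse_regimen("4.5mg 21/28")
  expect_equal(r2$dose_mg, 4.5)
  expect_equal(r2$days_off, 7L)
})

test_that("PK superposition is linear in dose and zero without doses", {
  pk <- default_pk_params()
  tg <- seq(0, 672, by = 1)
  expect_equal(pk_concentration(pk, numeric(0), 4, tg), rep(0, length(tg)))
  expect_equal(pk_concentration(pk, dosing_times(regimen(4, 5, 2), 28), 0, tg),
               rep(0, length(tg)))
  dt <- dosing_times(regimen(4, 5, 2), 28)
  c4 <- pk_concentration(pk, dt, 4, tg)
  c8 <- pk_concentration(pk, dt, 8, tg)
  expect_equal(c8, 2 * c4, tolerance = 1e-12)
  expect_true(all(c4 >= 0))
})

test_that("analytic single-dose solution matches ODE integration to 1e-6", {
  pk <- default_pk_params()
  k10 <- pk$cl_over_f / pk$vc_over_f
  k12 <- pk$q / pk$vc_over_f
  k21 <- pk$q / pk$vp
  dose_mg <- 4
  # amounts in ng; y2 is central amount, concentration = y2 / Vc(mL)
  y0 <- c(gut = dose_mg * 1e6, central = 0, peripheral = 0)
  rhs_amt <- function(t, y, parms) {
    list(c(-pk$ka * y[1],
           pk$ka * y[1] - (k10 + k12) * y[2] + k21 * y[3],
           k12 * y[2] - k21 * y[3]))
  }
  tg <- seq(0, 120, by = 0.5)
  num <- deSolve::ode(y0, tg, rhs_amt, NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-8)
  conc_num <- num[, "central"] / (pk$vc_over_f * 1e3)
  conc_ana <- pk_concentration(pk, 0, dose_mg, tg)
  scale <- max(conc_ana)
  expect_lt(max(abs(conc_ana - conc_num)) / scale, 1e-6)
})

test_that("multi-dose superposition equals direct ODE with dosing events", {
  pk <- default_pk_params()
  k10 <- pk$cl_over_f / pk$vc_over_f
  k12 <- pk$q / pk$vc_over_f
  k21 <- pk$q / pk$vp
  rhs_amt <- function(t, y, parms) {
    list(c(-pk$ka * y[1],
           pk$ka * y[1] - (k10 + k12) * y[2] + k21 * y[3],
           k12 * y[2] - k21 * y[3]))
  }
  dose_times <- c(0, 24, 48)
  tg <- sort(unique(c(seq(0, 96, by = 0.5), dose_times)))
  num <- deSolve::ode(
    c(gut = 0, central = 0, peripheral = 0), tg, rhs_amt, NULL,
    method = "lsoda", rtol = 1e-12, atol = 1e-8,
    events = list(data = data.frame(var = "gut", time = dose_times,
                                    value = 3e6, method = "add")))
  conc_num <- num[, "central"] / (pk$vc_over_f * 1e3)
  conc_ana <- pk_concentration(pk, dose_times, 3, tg)
  expect_lt(max(abs(conc_ana - conc_num)) / max(conc_ana), 1e-6)
})

test_that("exposure metrics: trapezoid AUC, Cmax, and dose linearity", {
  tg <- seq(0, 700, by = 1)
  expect_equal(exposure_metrics(tg, rep(2.5, length(tg)))$auc_cycle1,
               672 * 2.5)
  expect_error(exposure_metrics(numeric(0), numeric(0)), "empty")
  expect_error(exposure_metrics(seq(0, 100), seq(0, 100)), "672")

  pk <- default_pk_params()
  dt <- dosing_times(regimen(1, 5, 2), 28)
  m2 <- exposure_metrics(tg, pk_concentration(pk, dt, 2, tg))
  m4 <- exposure_metrics(tg, pk_concentration(pk, dt, 4, tg))
  expect_equal(m4$auc_cycle1 / m2$auc_cycle1, 2, tolerance = 1e-9)
  expect_equal(m4$cmax / m2$cmax, 2, tolerance = 1e-9)
})

test_that("cycle-1 AUC is proportional to dose x number of doses within 5%", {
  pk <- default_pk_params()
  tg <- seq(0, 672, by = 1)
  auc_per_dose <- vapply(c("3/7", "5/7", "21/28", "28/28"), function(s) {
    reg <- parse_regimen(paste0("4mg ", s))
    dt <- dosing_times(reg, 28)
    exposure_metrics(tg, pk_concentration(pk, dt, 4, tg))$auc_cycle1 /
      (4 * length(dt))
  }, numeric(1))
  expect_lt(diff(range(auc_per_dose)) / mean(auc_per_dose), 0.05)
})

test_that("printed-exposure PK reproduces the published exposure scale", {
  pk <- pk_params_printed_exposure()
  tf <- seq(0, 672, by = 0.05)
  m <- exposure_metrics(
    tf, pk_concentration(pk, dosing_times(regimen(6, 5, 2), 28), 6, tf))
  expect_equal(m$auc_cycle1, 1417, tolerance = 0.02)
  expect_equal(m$cmax, 143, tolerance = 0.02)
})

test_that("PD effect: identity at zero, half-block at EC50, Emax asymptote", {
  pd <- pd_params(emax = 0.9, ec50 = 15, n_hill = 2)
  expect_equal(effect_cc122(0, pd), 1)
  expect_equal(effect_cc122(15, pd), 0.55)
  expect_equal(effect_cc122(1e9, pd), 0.1, tolerance = 1e-6)
  conc <- seq(0, 300, by = 0.5)
  eff <- effect_cc122(conc, pd)
  expect_true(all(diff(eff) < 0))
  expect_true(all(eff > 1 - pd$emax & eff <= 1))
  expect_error(effect_cc122(-1, pd), "non-negative")
  expect_error(pd_params(emax = 1), "emax")
  expect_error(pd_params(ec50 = -2), "ec50")
})
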