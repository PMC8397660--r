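#' Two-compartment oral PK parameters
#'
#' Apparent (dose-normalized, bioavailability-confounded) parameters of a
#' two-compartment disposition model with first-order oral absorption.
#'
#' @param ka First-order absorption rate (1/h).
#' @param cl_over_f Apparent clearance CL/F (L/h).
#' @param vc_over_f Apparent central volume Vc/F (L).
#' @param q Inter-compartmental clearance (L/h).
#' @param vp Peripheral volume (L).
#' @return An object of class `pk_params`.
#' @export
pk_params <- function(ka, cl_over_f, vc_over_f, q, vp) {
  vals <- c(ka = ka, cl_over_f = cl_over_f, vc_over_f = vc_over_f,
            q = q, vp = vp)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all PK parameters must be positive finite numbers")
  structure(as.list(vals), class = "pk_params")
}

#' Inhibitory-Emax PD parameters
#'
#' The PD model maps drug concentration in the central PK compartment to a
#' fractional maturation-flux multiplier in `(1 - emax, 1]`.
#'
#' @param emax Maximal fractional block, in `[0, 1)`. Default 0.9.
#' @param ec50 Half-maximal concentration (ng/mL). Default 15.
#' @param n_hill Hill coefficient, > 0. Default 2.
#' @return An object of class `pd_params`.
#' @export
pd_params <- function(emax = 0.9, ec50 = 15, n_hill = 2) {
  if (!is.finite(emax) || emax < 0 || emax >= 1)
    stop("emax must lie in [0, 1)")
  if (!is.finite(ec50) || ec50 <= 0) stop("ec50 must be > 0")
  if (!is.finite(n_hill) || n_hill <= 0) stop("n_hill must be > 0")
  structure(list(emax = emax, ec50 = ec50, n_hill = n_hill),
            class = "pd_params")
}

#' Dosing regimen
#'
#' A regimen is a dose amount plus an on/off day pattern.  The pattern tiles
#' with period `days_on + days_off`: weekly patterns (3/7, 5/7) repeat every
#' 7 days, 7/14 every 14 days, and the cycle-anchored patterns (14/28,
#' 21/28, 28/28) every 28 days, all anchored at treatment start.
#'
#' @param dose_mg Dose per administration (mg), >= 0.
#' @param days_on Consecutive dosing days per period, integer >= 1.
#' @param days_off Rest days per period, integer >= 0.
#' @param cycle_days Treatment-cycle length in days (default 28).
#' @param n_cycles Number of cycles, integer >= 1.
#' @param dose_hour Hour-of-day offset of each administration (default 0).
#' @return An object of class `regimen`.
#' @examples
#' regimen(6, 5, 2)            # 6 mg on a 5/7 schedule
#' parse_regimen("4mg 21/28")
#' @export
regimen <- function(dose_mg, days_on, days_off, cycle_days = 28,
                    n_cycles = 1, dose_hour = 0) {
  if (!is.finite(dose_mg) || dose_mg < 0) stop("dose_mg must be >= 0")
  if (!is.finite(days_on) || days_on < 1 || days_on != round(days_on))
    stop("invalid regimen: days_on must be an integer >= 1")
  if (!is.finite(days_off) || days_off < 0 || days_off != round(days_off))
    stop("invalid regimen: days_off must be an integer >= 0")
  if (cycle_days < 1 || n_cycles < 1) stop("invalid regimen")
  period <- days_on + days_off
  if (period > cycle_days && period %% cycle_days != 0)
    stop("invalid regimen: pattern period exceeds the cycle length")
  structure(
    list(dose_mg = dose_mg, days_on = as.integer(days_on),
         days_off = as.integer(days_off), cycle_days = as.integer(cycle_days),
         n_cycles = as.integer(n_cycles), dose_hour = dose_hour),
    class = "regimen"
  )
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("Regimen: %g mg, %d/%d schedule, %d x %d-day cycle(s)\n",
              x$dose_mg, x$days_on, x$days_on + x$days_off,
              x$n_cycles, x$cycle_days))
  invisible(x)
}

#' Parse a regimen string such as "6mg 5/7"
#'
#' @param text A string of the form `"<dose>mg <on>/<period>"`, e.g.
#'   `"6mg 5/7"` or `"4mg 21/28"`.  The second number is the pattern period
#'   (days on + days off), matching the field's schedule notation.
#' @param ... Passed to [regimen()] (`cycle_days`, `n_cycles`, `dose_hour`).
#' @return A `regimen` object.
#' @export
parse_regimen <- function(text, ...) {
  m <- regmatches(text, regexec(
    "^\\s*([0-9.]+)\\s*mg\\s+([0-9]+)\\s*/\\s*([0-9]+)\\s*$", text))[[1]]
  if (length(m) != 4)
    stop("cannot parse regimen string: ", text,
         " (expected e.g. \"6mg 5/7\")")
  dose <- as.numeric(m[2]); on <- as.integer(m[3]); period <- as.integer(m[4])
  if (on < 1 || period < on)
    stop("invalid schedule in regimen string: ", text)
  regimen(dose, on, period - on, ...)
}

#' Expand a regimen into dose administration times
#'
#' @param reg A `regimen` object.
#' @param horizon_days Simulation horizon (days), >= 1.
#' @return Strictly increasing numeric vector of dose times (hours from
#'   treatment start); one dose per "on" day.
#' @examples
#' length(dosing_times(regimen(6, 5, 2), 28))   # 20
#' length(dosing_times(regimen(4, 21, 7), 28))  # 21
#' @export
dosing_times <- function(reg, horizon_days) {
  stopifnot(inherits(reg, "regimen"))
  if (horizon_days < 1) stop("horizon_days must be >= 1")
  period <- reg$days_on + reg$days_off
  days <- 0:(ceiling(horizon_days) - 1)
  on <- (days %% period) < reg$days_on
  24 * days[on] + reg$dose_hour
}

# Closed-form central-compartment concentration after a single oral dose of
# a two-compartment model (tri-exponential Bateman form).  t in hours,
# result in ng/mL.
.single_dose_conc <- function(t, pk, dose_mg) {
  k10 <- pk$cl_over_f / pk$vc_over_f
  k12 <- pk$q / pk$vc_over_f
  k21 <- pk$q / pk$vp
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  al <- (s + disc) / 2
  be <- (s - disc) / 2
  ka <- pk$ka
  if (min(abs(ka - al), abs(ka - be)) < 1e-10)
    stop("degenerate PK parameters: ka coincides with a disposition rate")
  # dose_mg [mg] -> ng, vc [L] -> mL
  scale <- dose_mg * 1e6 / (pk$vc_over_f * 1e3) * ka
  cf <- function(tt) {
    scale * ((k21 - al) / ((ka - al) * (be - al)) * exp(-al * tt) +
             (k21 - be) / ((ka - be) * (al - be)) * exp(-be * tt) +
             (k21 - ka) / ((al - ka) * (be - ka)) * exp(-ka * tt))
  }
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- cf(t[pos])
  pmax(out, 0)
}

#' Central-compartment concentration under multiple dosing
#'
#' Linear superposition of identical single-dose tri-exponential responses,
#' one per administration.
#'
#' @param pk A `pk_params` object.
#' @param dose_times Numeric vector of administration times (h).
#' @param dose_mg Dose per administration (mg).
#' @param t_grid Sorted evaluation times (h).
#' @return Numeric vector of concentrations (ng/mL), same length as
#'   `t_grid`.
#' @export
pk_concentration <- function(pk, dose_times, dose_mg, t_grid) {
  stopifnot(inherits(pk, "pk_params"))
  if (is.unsorted(t_grid)) stop("t_grid must be sorted")
  conc <- numeric(length(t_grid))
  if (length(dose_times) == 0 || dose_mg == 0) return(conc)
  for (td in dose_times)
    conc <- conc + .single_dose_conc(t_grid - td, pk, dose_mg)
  conc
}

#' Cycle-1 exposure metrics
#'
#' @param times Evaluation times (h), must span 0 to 672 h (28 days).
#' @param conc Concentrations (ng/mL) on `times`.
#' @return List with `auc_cycle1` (ng/mL*h, trapezoid over 0-672 h) and
#'   `cmax` (ng/mL).
#' @export
exposure_metrics <- function(times, conc) {
  if (length(times) == 0 || length(conc) != length(times))
    stop("empty or mismatched concentration series")
  if (min(times) > 0 || max(times) < 672)
    stop("concentration series must cover 0-672 h (cycle 1)")
  in1 <- times <= 672
  t1 <- times[in1]; c1 <- conc[in1]
  auc <- sum(diff(t1) * (head(c1, -1) + tail(c1, -1)) / 2)
  list(auc_cycle1 = auc, cmax = max(c1))
}

#' Drug effect on the maturation flux
#'
#' Inhibitory Emax (Hill) model:
#' \deqn{Effect = 1 - \frac{E_{max} C^{n}}{EC_{50}^{n} + C^{n}}}
#' The returned multiplier equals 1 at zero concentration, decreases
#' strictly with concentration, and tends to `1 - emax` at saturation.
#'
#' @param conc Concentration (ng/mL), >= 0; vectorized.
#' @param pd A `pd_params` object.
#' @return Effect multiplier in `(1 - emax, 1]`.
#' @examples
#' effect_cc122(c(0, 15, 1e6), pd_params(emax = 0.9, ec50 = 15, n_hill = 2))
#' @export
effect_cc122 <- function(conc, pd) {
  stopifnot(inherits(pd, "pd_params"))
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentration must be non-negative")
  cn <- conc^pd$n_hill
  1 - pd$emax * cn / (pd$ec50^pd$n_hill + cn)
}
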