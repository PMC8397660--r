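#' Patient traits: the four individualized model parameters
#'
#' A virtual or real patient is fully characterized by four quantities:
#' the baseline absolute neutrophil count (ANC) in blood, the ratio of the
#' bone-marrow mature-neutrophil reservoir to circulating neutrophils at
#' homeostasis, the Michaelis constant of the maturation flux expressed as a
#' fraction of the homeostatic transit-2 cell level, and the exponent of the
#' proliferative feedback.
#'
#' @param circ0 Baseline ANC (cells/L), > 0.
#' @param ratio_reserv0_circ0 Homeostatic reservoir-to-circulation ratio
#'   (dimensionless), > 0.
#' @param km_fraction Michaelis constant of the maturation flux as a fraction
#'   of the homeostatic transit-2 level (dimensionless), > 0.
#' @param gamma Exponent of the proliferative feedback (dimensionless), >= 0.
#' @return An object of class `patient_traits`.
#' @examples
#' patient_traits(4.5e9, 2.5, 0.1, 0.01)
#' @export
patient_traits <- function(circ0, ratio_reserv0_circ0, km_fraction, gamma) {
  stopifnot(is.numeric(circ0), is.numeric(ratio_reserv0_circ0),
            is.numeric(km_fraction), is.numeric(gamma))
  if (!is.finite(circ0) || circ0 <= 0)
    stop("invalid patient traits: circ0 must be a positive finite number")
  if (!is.finite(ratio_reserv0_circ0) || ratio_reserv0_circ0 <= 0)
    stop("invalid patient traits: ratio_reserv0_circ0 must be > 0")
  if (!is.finite(km_fraction) || km_fraction <= 0)
    stop("invalid patient traits: km_fraction must be > 0")
  if (!is.finite(gamma) || gamma < 0)
    stop("invalid patient traits: gamma must be >= 0")
  structure(
    list(circ0 = circ0, ratio_reserv0_circ0 = ratio_reserv0_circ0,
         km_fraction = km_fraction, gamma = gamma),
    class = "patient_traits"
  )
}

#' @export
print.patient_traits <- function(x, ...) {
  cat("Patient traits\n")
  cat(sprintf("  baseline ANC (circ0):    %.4g cells/L\n", x$circ0))
  cat(sprintf("  reservoir/circ ratio:    %.4g\n", x$ratio_reserv0_circ0))
  cat(sprintf("  K_M fraction:            %.4g\n", x$km_fraction))
  cat(sprintf("  feedback exponent gamma: %.4g\n", x$gamma))
  invisible(x)
}

#' Derive the full life-cycle parameter set from patient traits
#'
#' Back-calculates every transit/egress rate of the neutrophil life-cycle
#' model under the assumption of homeostasis (constant cell count in every
#' compartment).  The cascade is anchored on the circulating-neutrophil
#' elimination rate `k_elim = ln(2) / t_half` and the fixed maturation
#' apoptosis rate `k_d`:
#'
#' \deqn{k_{out} = k_{elim} Circ_0 / Reserv_0}
#' \deqn{k_{tr4} = (k_d + k_{out}) Reserv_0 / Tran_0}
#' \deqn{k_{tr3} = k_{tr4} + k_d,\quad k_{tr2} = k_{tr3} + k_d,\quad
#'       k_{tr1} = k_{tr2} + k_d,\quad k_{prol} = k_{tr1}}
#'
#' with `Reserv0 = ratio * circ0` and, following the convention of fixing
#' all non-reservoir compartments to the blood baseline,
#' `Tran0 = Prol0 = circ0`.  The Michaelis constant is
#' `K_M = km_fraction * Tran0` and the maximal maturation flux is
#' `V_max = k_tr3 * (K_M + Tran0)`, so that the maturation flux at
#' homeostasis equals `k_tr3 * Tran0`.
#'
#' @param traits A [patient_traits()] object.
#' @param t_half Circulating-neutrophil half-life (hours), > 0. Default 30.
#' @param k_d Maturation apoptosis rate (1/h), >= 0. Default 0.001.
#' @param beta Egress feedback exponent (dimensionless), >= 0. Default 20.
#' @return An object of class `life_cycle_params`: a list with all rate
#'   constants (1/h), `v_max` (cells/L/h), `k_m` (cells/L), the feedback
#'   exponents, and the homeostatic compartment levels.
#' @examples
#' gbm <- derive_homeostatic_parameters(patient_traits(4.5e9, 3, 0.6, 0.02))
#' round(gbm$k_out, 4)   # 0.0077
#' round(gbm$k_tr1, 4)   # 0.0291
#' @export
derive_homeostatic_parameters <- function(traits, t_half = 30, k_d = 0.001,
                                          beta = 20) {
  if (!inherits(traits, "patient_traits"))
    traits <- do.call(patient_traits, as.list(traits))
  if (!is.finite(t_half) || t_half <= 0)
    stop("invalid parameter: t_half must be > 0")
  if (!is.finite(k_d) || k_d < 0)
    stop("invalid parameter: k_d must be >= 0")
  if (!is.finite(beta) || beta < 0)
    stop("invalid parameter: beta must be >= 0")

  circ0   <- traits$circ0
  reserv0 <- traits$ratio_reserv0_circ0 * circ0
  tran0   <- circ0                      # Prol0 = Transit_i,0 = Circ0
  k_elim  <- log(2) / t_half
  k_out   <- k_elim * circ0 / reserv0
  k_tr4   <- (k_d + k_out) * reserv0 / tran0
  k_tr3   <- k_tr4 + k_d
  k_tr2   <- k_tr3 + k_d
  k_tr1   <- k_tr2 + k_d
  k_prol  <- k_tr1
  k_m     <- traits$km_fraction * tran0
  v_max   <- k_tr3 * (k_m + tran0)

  structure(
    list(
      k_prol = k_prol, k_tr1 = k_tr1, k_tr2 = k_tr2,
      k_tr3_nominal = k_tr3, k_tr4 = k_tr4, k_out = k_out,
      k_elim = k_elim, k_d = k_d,
      v_max = v_max, k_m = k_m,
      gamma = traits$gamma, beta = beta,
      prol0 = tran0, tran0 = tran0, reserv0 = reserv0,
      transit2_homeostatic = tran0, circ_homeostatic = circ0,
      t_half_neutrophil = t_half
    ),
    class = "life_cycle_params"
  )
}

#' @export
print.life_cycle_params <- function(x, ...) {
  cat("Neutrophil life-cycle parameters (homeostatic cascade)\n")
  r <- c(k_prol = x$k_prol, k_tr1 = x$k_tr1, k_tr2 = x$k_tr2,
         k_tr3 = x$k_tr3_nominal, k_tr4 = x$k_tr4, k_out = x$k_out,
         k_elim = x$k_elim, k_d = x$k_d)
  cat("  rates (1/h):\n")
  for (nm in names(r)) cat(sprintf("    %-7s %.6g\n", nm, r[[nm]]))
  cat(sprintf("  v_max:   %.6g cells/L/h\n", x$v_max))
  cat(sprintf("  k_m:     %.6g cells/L\n", x$k_m))
  cat(sprintf("  gamma %.4g, beta %.4g\n", x$gamma, x$beta))
  cat(sprintf("  levels:  Circ0 %.4g, Reserv0 %.4g cells/L\n",
              x$circ_homeostatic, x$reserv0))
  invisible(x)
}

#' Homeostatic initial state of the life-cycle model
#'
#' All compartments start at their homeostatic level: proliferation, the
#' three transit stages and circulation at `Circ0`; the reservoir at
#' `ratio * Circ0`.
#'
#' @param params A `life_cycle_params` object.
#' @return Named numeric vector `(prol, transit1, transit2, transit3,
#'   reserv, circ)` in cells/L.
#' @export
initial_state <- function(params) {
  c(prol = params$prol0, transit1 = params$tran0, transit2 = params$tran0,
    transit3 = params$tran0, reserv = params$reserv0,
    circ = params$circ_homeostatic)
}

# Feedback ratios divide by state variables; beta = 20 makes the egress
# feedback explode as circ -> 0, so both feedbacks clamp their argument to a
# 1 cell/L floor.  The floor is far below any physiological level and leaves
# the dynamics untouched at relevant scales.
.STATE_FLOOR <- 1

#' Proliferative feedback multiplier
#'
#' `(transit2_homeostatic / transit2) ^ gamma`: equals 1 at homeostasis,
#' exceeds 1 when the transit-2 pool is depleted (stimulating proliferation),
#' and falls below 1 when maturing cells accumulate upstream of a block.
#'
#' @param transit2 Current transit-2 level (cells/L).
#' @param transit2_homeostatic Homeostatic transit-2 level (cells/L).
#' @param gamma Feedback exponent, >= 0.
#' @return Dimensionless multiplier.
#' @export
feedback_proliferation <- function(transit2, transit2_homeostatic, gamma) {
  if (any(transit2 <= .STATE_FLOOR)) {
    warning("transit2 at or below the 1 cell/L floor; clamping in feedback")
    transit2 <- pmax(transit2, .STATE_FLOOR)
  }
  (transit2_homeostatic / transit2)^gamma
}

#' Egress feedback multiplier
#'
#' `(circ_homeostatic / circ) ^ beta`: accelerates reservoir egress when
#' circulating neutrophils fall below baseline.  The large default exponent
#' (beta = 20) encodes prompt, sustained bone-marrow release that holds ANC
#' near baseline until the reservoir is exhausted.
#'
#' @param circ Current circulating ANC (cells/L).
#' @param circ_homeostatic Homeostatic ANC (cells/L).
#' @param beta Feedback exponent, >= 0.
#' @return Dimensionless multiplier.
#' @export
feedback_egress <- function(circ, circ_homeostatic, beta) {
  if (any(circ <= .STATE_FLOOR)) {
    warning("circ at or below the 1 cell/L floor; clamping in feedback")
    circ <- pmax(circ, .STATE_FLOOR)
  }
  (circ_homeostatic / circ)^beta
}

#' Right-hand side of the neutrophil life-cycle ODE system
#'
#' Reference (pure-R) implementation of the six compartment balances.  The
#' drug effect multiplies the Michaelis-Menten maturation flux
#' `v_max * effect * transit2 / (k_m + transit2)` that leaves transit 2 and
#' enters transit 3; no other rate is drug-modified.
#'
#' @param state Named state vector as returned by [initial_state()].
#' @param params A `life_cycle_params` object.
#' @param effect Drug effect in (0, 1]; 1 means no block.
#' @return Named numeric vector of time derivatives (cells/L/h).
#' @export
lifecycle_rhs <- function(state, params, effect = 1) {
  if (!is.finite(effect) || effect <= 0 || effect > 1)
    stop("effect must lie in (0, 1]")
  p <- params
  fb_prol <- (p$transit2_homeostatic / max(state[["transit2"]], .STATE_FLOOR))^p$gamma
  fb_egr  <- (p$circ_homeostatic / max(state[["circ"]], .STATE_FLOOR))^p$beta
  mm <- p$v_max * effect * state[["transit2"]] / (p$k_m + state[["transit2"]])
  c(
    prol     = p$k_prol * fb_prol * state[["prol"]] - p$k_tr1 * state[["prol"]],
    transit1 = p$k_tr1 * state[["prol"]] - (p$k_tr2 + p$k_d) * state[["transit1"]],
    transit2 = p$k_tr2 * state[["transit1"]] - mm - p$k_d * state[["transit2"]],
    transit3 = mm - (p$k_tr4 + p$k_d) * state[["transit3"]],
    reserv   = p$k_tr4 * state[["transit3"]] -
               (p$k_d + p$k_out * fb_egr) * state[["reserv"]],
    circ     = p$k_out * fb_egr * state[["reserv"]] - p$k_elim * state[["circ"]]
  )
}

# Parameter vector in the order expected by the compiled derivative function.
.lifecycle_parms_vec <- function(params) {
  c(params$k_prol, params$k_tr1, params$k_tr2, params$k_d, params$k_tr4,
    params$k_out, params$k_elim, params$v_max, params$k_m, params$gamma,
    params$beta, params$transit2_homeostatic, params$circ_homeostatic)
}
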