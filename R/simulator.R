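#' Simulate one patient under one regimen
#'
#' Couples the three model layers sequentially, mirroring the one-way
#' drug-to-neutrophil causality: the PK concentration is precomputed
#' analytically on the evaluation grid, mapped through the inhibitory-Emax
#' PD model to a maturation-flux multiplier, and the life-cycle ODE system
#' is integrated consuming the interpolated effect as a forcing function.
#'
#' @param traits A [patient_traits()] object.
#' @param pk A [pk_params()] object (default [default_pk_params()]).
#' @param pd A [pd_params()] object (default [default_pd_params()]).
#' @param reg A [regimen()] object.
#' @param horizon_days Simulation horizon in days (default 28, i.e. cycle 1).
#' @param dt Output/evaluation grid step (hours, default 1).
#' @param t_half,k_d,beta Passed to [derive_homeostatic_parameters()].
#' @param rtol,atol Solver tolerances (stiff-capable `lsoda`; defaults
#'   1e-8 relative, 1 cell/L absolute).
#' @return An object of class `anc_series`: a list with `times` (h from
#'   first dose), `anc` (cells/L, the circulation compartment), `states`
#'   (matrix of all six compartments), `conc` (ng/mL), `effect`,
#'   `censored_after` (NA for simulated series) and the generating objects.
#' @examples
#' \donttest{
#' s <- simulate_patient(disease_traits("dlbcl"), reg = regimen(3, 5, 2))
#' min(s$anc) / s$anc[1]
#' }
#' @export
simulate_patient <- function(traits, pk = default_pk_params(),
                             pd = default_pd_params(), reg,
                             horizon_days = 28, dt = 1,
                             t_half = 30, k_d = 0.001, beta = 20,
                             rtol = 1e-8, atol = 1) {
  stopifnot(inherits(reg, "regimen"))
  params <- derive_homeostatic_parameters(traits, t_half = t_half,
                                          k_d = k_d, beta = beta)
  t_grid <- seq(0, horizon_days * 24, by = dt)
  doses <- dosing_times(reg, horizon_days)
  conc <- pk_concentration(pk, doses, reg$dose_mg, t_grid)
  eff <- effect_cc122(conc, pd)
  states <- .integrate_lifecycle(params, t_grid, eff, rtol, atol)
  structure(
    list(times = t_grid, anc = states[, "circ"], states = states,
         conc = conc, effect = eff, censored_after = NA_real_,
         traits = traits, params = params, regimen = reg),
    class = "anc_series"
  )
}

.integrate_lifecycle <- function(params, t_grid, effect, rtol = 1e-8,
                                 atol = 1) {
  y0 <- initial_state(params)
  forc <- cbind(t_grid, effect)
  out <- try(deSolve::ode(
    y = y0, times = t_grid, func = "lifecycle_derivs", parms =
      .lifecycle_parms_vec(params), dllname = "neutroqsp",
    initfunc = "lifecycle_init", initforc = "lifecycle_forc",
    forcings = forc, method = "lsoda", rtol = rtol, atol = atol
  ), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(t_grid) ||
      anyNA(out[nrow(out), ])) {
    last <- if (inherits(out, "try-error")) y0 else out[max(which(
      stats::complete.cases(out))), ]
    stop(structure(
      class = c("solver_failure", "error", "condition"),
      list(message = "life-cycle ODE integration failed",
           call = sys.call(-1), last_state = last)
    ))
  }
  states <- out[, c("prol", "transit1", "transit2", "transit3",
                    "reserv", "circ"), drop = FALSE]
  rownames(states) <- NULL
  states
}

#' @export
print.anc_series <- function(x, ...) {
  cat(sprintf("ANC series: %d points over %.1f days; baseline %.3g, nadir %.3g cells/L\n",
              length(x$times), max(x$times) / 24, x$anc[1], min(x$anc)))
  invisible(x)
}

#' @export
as.data.frame.anc_series <- function(x, ...) {
  data.frame(time_h = x$times, anc_cells_per_l = x$anc,
             conc_ng_ml = x$conc, effect = x$effect)
}

#' ANC of a simulated series at given study days
#'
#' Study day `d` corresponds to `t = 24 * (d - 1)` hours: day 1 is
#' treatment start.
#'
#' @param series An `anc_series`.
#' @param days Integer study days (1-based).
#' @return Numeric vector of ANC values (cells/L).
#' @export
anc_at_days <- function(series, days) {
  stats::approx(series$times, series$anc, xout = 24 * (days - 1),
                rule = 2)$y
}

#' Simulate a cohort of patients under one regimen
#'
#' Deterministic given the traits: all stochasticity lives in cohort
#' generation. Order-preserving; a failing patient aborts with an error
#' naming the patient index.
#'
#' @param cohort A `virtual_cohort` data frame (see [sample_cohort()]), or a
#'   list of [patient_traits()].
#' @param pk,pd,reg,horizon_days,... Passed to [simulate_patient()].
#' @return List of `anc_series`, one per patient, in cohort order.
#' @export
simulate_cohort <- function(cohort, pk = default_pk_params(),
                            pd = default_pd_params(), reg,
                            horizon_days = 28, ...) {
  traits_list <- as_traits_list(cohort)
  if (length(traits_list) == 0) stop("cohort is empty")
  lapply(seq_along(traits_list), function(i) {
    tryCatch(
      simulate_patient(traits_list[[i]], pk = pk, pd = pd, reg = reg,
                       horizon_days = horizon_days, ...),
      error = function(e) stop("simulation failed for patient ", i, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  })
}

#' Coerce a cohort representation to a list of patient traits
#'
#' @param cohort A `virtual_cohort`/data frame with columns `circ0`,
#'   `ratio_reserv0_circ0`, `km_fraction`, `gamma`, or a list of
#'   [patient_traits()].
#' @return List of `patient_traits`.
#' @export
as_traits_list <- function(cohort) {
  if (is.data.frame(cohort)) {
    need <- c("circ0", "ratio_reserv0_circ0", "km_fraction", "gamma")
    if (!all(need %in% names(cohort)))
      stop("cohort data frame must have columns: ",
           paste(need, collapse = ", "))
    lapply(seq_len(nrow(cohort)), function(i)
      patient_traits(cohort$circ0[i], cohort$ratio_reserv0_circ0[i],
                     cohort$km_fraction[i], cohort$gamma[i]))
  } else if (is.list(cohort)) {
    if (inherits(cohort, "patient_traits")) return(list(cohort))
    stopifnot(all(vapply(cohort, inherits, logical(1), "patient_traits")))
    cohort
  } else stop("unsupported cohort representation")
}
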