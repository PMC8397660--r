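#' Specification of a model fit
#'
#' Declares which parameters are free, their positive finite bounds, and
#' the initial guess.  Free parameters are a subset of the three
#' disease/patient traits (`gamma`, `ratio_reserv0_circ0`, `km_fraction`)
#' and the two PD parameters (`ec50`, `n_hill`).
#'
#' @param free Character vector naming the free parameters (non-empty).
#' @param lower,upper Named numeric bounds (positive, finite) for every
#'   free parameter.
#' @param init Named initial guess within the bounds.
#' @param weights Optional per-observation weights (default: all 1).
#' @return Object of class `fit_spec`.
#' @export
fit_spec <- function(free, lower, upper, init, weights = NULL) {
  allowed <- c("gamma", "ratio_reserv0_circ0", "km_fraction",
               "ec50", "n_hill")
  if (length(free) == 0) stop("free parameter set must be non-empty")
  if (!all(free %in% allowed))
    stop("free parameters must be among: ", paste(allowed, collapse = ", "))
  for (nm in free) {
    lo <- lower[[nm]]; hi <- upper[[nm]]; x0 <- init[[nm]]
    if (is.null(lo) || is.null(hi) || is.null(x0))
      stop("bounds and init required for free parameter ", nm)
    if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || hi <= lo)
      stop("bounds for ", nm, " must be finite, positive and ordered")
    if (x0 < lo || x0 > hi)
      stop("initial guess for ", nm, " outside its bounds")
  }
  structure(list(free = free, lower = lower[free], upper = upper[free],
                 init = init[free], weights = weights),
            class = "fit_spec")
}

#' Default fit specification for the three disease traits
#'
#' Free parameters `gamma`, `ratio_reserv0_circ0`, `km_fraction`,
#' initialized at the median traits of a disease cohort (the workflow
#' starting point for per-patient fits).
#'
#' @param traits A [patient_traits()] supplying the initial guess
#'   (default: DLBCL medians).
#' @return A [fit_spec()].
#' @export
default_fit_spec <- function(traits = disease_traits("dlbcl")) {
  fit_spec(
    free  = c("gamma", "ratio_reserv0_circ0", "km_fraction"),
    lower = c(gamma = 1e-4, ratio_reserv0_circ0 = 0.2, km_fraction = 0.005),
    upper = c(gamma = 2, ratio_reserv0_circ0 = 20, km_fraction = 10),
    init  = c(gamma = traits$gamma,
              ratio_reserv0_circ0 = traits$ratio_reserv0_circ0,
              km_fraction = traits$km_fraction)
  )
}

#' Weighted sum of absolute normalized differences
#'
#' The fitting objective: for each uncensored observation,
#' `w_i * |sim(t_i) - obs_i| / obs_i`, summed.  Simulated values are
#' matched to the observation times by linear interpolation on the
#' simulation grid.  Zero observations cannot be normalized and are
#' skipped with a warning.
#'
#' @param sim An `anc_series` (simulation).
#' @param obs Data frame with columns `time_h` and `anc` (observations),
#'   or an `anc_series`.  A `censored_after` attribute/field excludes all
#'   observations at or after that time.
#' @param weights Optional numeric weights, one per observation row
#'   (default 1).
#' @return Non-negative scalar; zero iff the simulation matches every
#'   uncensored observation exactly.
#' @export
anc_objective <- function(sim, obs, weights = NULL) {
  obs <- .as_obs_df(obs)
  if (is.null(weights)) weights <- rep(1, nrow(obs))
  stopifnot(length(weights) == nrow(obs))
  drop <- obs$anc == 0
  if (any(drop)) {
    warning(sum(drop), " zero-valued observation(s) skipped ",
            "(normalization undefined)")
    obs <- obs[!drop, , drop = FALSE]
    weights <- weights[!drop]
  }
  if (nrow(obs) == 0) return(0)
  simv <- stats::approx(sim$times, sim$anc, xout = obs$time_h, rule = 2)$y
  sum(weights * abs(simv - obs$anc) / obs$anc)
}

.as_obs_df <- function(obs) {
  if (inherits(obs, "anc_series")) {
    df <- data.frame(time_h = obs$times, anc = obs$anc)
    if (is.finite(obs$censored_after))
      df <- df[df$time_h < obs$censored_after, , drop = FALSE]
    return(df)
  }
  stopifnot(is.data.frame(obs), all(c("time_h", "anc") %in% names(obs)))
  ca <- attr(obs, "censored_after")
  if (!is.null(ca) && is.finite(ca))
    obs <- obs[obs$time_h < ca, , drop = FALSE]
  obs
}

# Shared machinery: evaluate the objective for a candidate parameter
# vector (natural scale) against one or more (obs, regimen) groups.
.fit_objective <- function(par, spec, groups, circ0s, pk, pd, fixed,
                           horizon_days) {
  traits_of <- function(circ0) {
    patient_traits(
      circ0 = circ0,
      ratio_reserv0_circ0 = par[["ratio_reserv0_circ0"]] %||%
        groups$base$ratio_reserv0_circ0,
      km_fraction = par[["km_fraction"]] %||% groups$base$km_fraction,
      gamma = par[["gamma"]] %||% groups$base$gamma
    )
  }
  pd_use <- pd_params(
    emax = pd$emax,
    ec50 = par[["ec50"]] %||% pd$ec50,
    n_hill = par[["n_hill"]] %||% pd$n_hill
  )
  total <- 0
  for (g in seq_along(groups$obs)) {
    sim <- simulate_patient(traits_of(circ0s[[g]]), pk = pk, pd = pd_use,
                            reg = groups$regimens[[g]],
                            horizon_days = horizon_days,
                            t_half = fixed$t_half, k_d = fixed$k_d,
                            beta = fixed$beta)
    total <- total + anc_objective(sim, groups$obs[[g]], spec$weights)
  }
  total
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

.run_nelder_mead <- function(spec, fn, maxit, reltol) {
  free <- spec$free
  log_lo <- log(unlist(spec$lower)); log_hi <- log(unlist(spec$upper))
  to_nat <- function(z) {
    x <- exp(pmin(pmax(z, log_lo), log_hi))
    stats::setNames(as.list(x), free)
  }
  penal <- function(z) sum(pmax(0, z - log_hi)^2 + pmax(0, log_lo - z)^2)
  wrapped <- function(z) fn(to_nat(z)) + 1e3 * penal(z)
  z0 <- log(unlist(spec$init))
  if (length(free) == 1) {
    # one free parameter: Nelder-Mead degenerates; use golden-section
    opt <- stats::optimize(function(z) wrapped(z), c(log_lo, log_hi),
                           tol = 1e-10)
    res <- list(par = opt$minimum, value = opt$objective,
                convergence = 0, counts = c(`function` = NA))
  } else {
    res <- stats::optim(z0, wrapped, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    # restart from the incumbent until converged (fminsearch practice):
    # a fresh simplex escapes the degenerate shapes Nelder-Mead collapses to
    for (r in 1:6) {
      res2 <- stats::optim(res$par, wrapped, method = "Nelder-Mead",
                           control = list(maxit = maxit, reltol = reltol))
      res2$counts <- res$counts + res2$counts
      improved <- res2$value < res$value - 1e-8 * (abs(res$value) + 1e-12)
      if (res2$value <= res$value) res <- res2
      if (!improved) break
    }
  }
  list(par = to_nat(res$par), value = fn(to_nat(res$par)),
       convergence = res$convergence, counts = res$counts)
}

#' Fit the model to one patient's ANC observations
#'
#' Nelder-Mead (direct-search) minimization of [anc_objective()] over the
#' free parameters of `spec`.  Positivity is enforced by optimizing in
#' log-space; the finite upper/lower bounds by a smooth penalty outside
#' the log-transformed box.  Deterministic given the initial guess.
#'
#' @param obs Observations: data frame with columns `time_h`, `anc`
#'   (uncensored; see [censor_post_gcsf()] / `censored_after`).
#' @param spec A [fit_spec()].
#' @param reg The [regimen()] the patient received.
#' @param circ0 Baseline ANC (cells/L); defaults to the observation at
#'   the earliest time point.
#' @param pk,pd Fixed PK/PD context.
#' @param fixed Fixed life-cycle constants, see [default_fixed_params()].
#' @param horizon_days Simulation horizon (default 28).
#' @param maxit,reltol Optimizer control.
#' @return Object of class `fit_result`: list with `par` (named fitted
#'   values, natural scale), `objective`, `converged`, `evaluations`,
#'   `residuals` (per observation, relative), `spec`.
#' @export
fit_patient <- function(obs, spec, reg, circ0 = NULL,
                        pk = default_pk_params(), pd = default_pd_params(),
                        fixed = default_fixed_params(), horizon_days = 28,
                        maxit = 400, reltol = 1e-10) {
  stopifnot(inherits(spec, "fit_spec"))
  obs <- .as_obs_df(obs)
  if (nrow(obs) < 3)
    stop("fit requires at least 3 uncensored observations")
  if (is.null(circ0)) circ0 <- obs$anc[which.min(obs$time_h)]
  base <- disease_traits("dlbcl")
  groups <- list(obs = list(obs), regimens = list(reg), base = base)
  fn <- function(par) .fit_objective(par, spec, groups, circ0, pk, pd,
                                     fixed, horizon_days)
  out <- .run_nelder_mead(spec, fn, maxit, reltol)
  sim <- simulate_patient(
    patient_traits(circ0,
                   out$par[["ratio_reserv0_circ0"]] %||% base$ratio_reserv0_circ0,
                   out$par[["km_fraction"]] %||% base$km_fraction,
                   out$par[["gamma"]] %||% base$gamma),
    pk = pk,
    pd = pd_params(pd$emax, out$par[["ec50"]] %||% pd$ec50,
                   out$par[["n_hill"]] %||% pd$n_hill),
    reg = reg, horizon_days = horizon_days,
    t_half = fixed$t_half, k_d = fixed$k_d, beta = fixed$beta)
  simv <- stats::approx(sim$times, sim$anc, xout = obs$time_h, rule = 2)$y
  structure(
    list(par = unlist(out$par), objective = out$value,
         converged = out$convergence == 0,
         evaluations = out$counts[["function"]],
         residuals = (simv - obs$anc) / obs$anc,
         circ0 = circ0, spec = spec),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Model fit (Nelder-Mead direct search)\n")
  for (nm in names(x$par)) cat(sprintf("  %-20s %.6g\n", nm, x$par[[nm]]))
  cat(sprintf("  objective %.6g; converged: %s\n", x$objective,
              x$converged))
  invisible(x)
}

#' Fit a single parameter set to several dose groups simultaneously
#'
#' Minimizes the summed objective across groups, each simulated under its
#' own regimen — the cohort-level fit that regresses one representative
#' parameter set from all dose groups at once.
#'
#' @param obs_list List of observation data frames (one per group).
#' @param spec A [fit_spec()].
#' @param regimens List of [regimen()], parallel to `obs_list`.
#' @param circ0s Optional numeric vector of per-group baselines (default:
#'   earliest observation of each group).
#' @param pk,pd,fixed,horizon_days,maxit,reltol As in [fit_patient()].
#' @return A `fit_result` (no per-observation residuals; `objective` is
#'   the summed objective).
#' @export
fit_cohort_median <- function(obs_list, spec, regimens, circ0s = NULL,
                              pk = default_pk_params(),
                              pd = default_pd_params(),
                              fixed = default_fixed_params(),
                              horizon_days = 28, maxit = 500,
                              reltol = 1e-10) {
  stopifnot(inherits(spec, "fit_spec"))
  if (length(obs_list) < 1) stop("at least one dose group required")
  stopifnot(length(regimens) == length(obs_list))
  obs_list <- lapply(obs_list, .as_obs_df)
  if (is.null(circ0s))
    circ0s <- vapply(obs_list, function(o) o$anc[which.min(o$time_h)],
                     numeric(1))
  base <- disease_traits("dlbcl")
  groups <- list(obs = obs_list, regimens = regimens, base = base)
  fn <- function(par) .fit_objective(par, spec, groups, circ0s, pk, pd,
                                     fixed, horizon_days)
  out <- .run_nelder_mead(spec, fn, maxit, reltol)
  structure(
    list(par = unlist(out$par), objective = out$value,
         converged = out$convergence == 0,
         evaluations = out$counts[["function"]],
         residuals = NULL, circ0 = circ0s, spec = spec),
    class = "fit_result"
  )
}
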