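#' Two-sample Kolmogorov-Smirnov comparison of ANC snapshots
#'
#' Standard two-sample K-S test of the hypothesis that a virtual and a
#' clinical ANC snapshot (taken at the same study day) come from the same
#' distribution.
#'
#' @param sim_values Numeric vector of simulated ANC values (>= 5).
#' @param clin_values Numeric vector of clinical ANC values (>= 5).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `ks_report`: list with `statistic`,
#'   `p_value`, `reject`, `alpha`, `n_sim`, `n_clin`.
#' @export
ks_validate <- function(sim_values, clin_values, alpha = 0.05) {
  if (length(sim_values) < 5 || length(clin_values) < 5)
    stop("K-S comparison requires at least 5 values per sample")
  kt <- suppressWarnings(stats::ks.test(sim_values, clin_values))
  structure(
    list(statistic = unname(kt$statistic), p_value = kt$p.value,
         reject = kt$p.value < alpha, alpha = alpha,
         n_sim = length(sim_values), n_clin = length(clin_values)),
    class = "ks_report"
  )
}

#' @export
print.ks_report <- function(x, ...) {
  cat(sprintf("Two-sample K-S: D = %.4f, p = %.4g (%s at alpha = %g)\n",
              x$statistic, x$p_value,
              if (x$reject) "reject" else "fail to reject", x$alpha))
  invisible(x)
}

#' Validate a virtual cohort against clinical ANC snapshots
#'
#' Takes the virtual ANC distribution at each requested study day from
#' the simulated trajectories and compares it to the clinical ANC values
#' recorded at that day with the two-sample K-S test.
#'
#' @param series_list List of simulated `anc_series` (the virtual
#'   cohort under the clinical regimen).
#' @param clinical Data frame with columns `patient_id`, `day`,
#'   `anc_cells_per_l` (already censored of post-rescue values).
#' @param days Study days to compare (default `c(1, 8, 16, 22, 28)`).
#' @param alpha Significance level (default 0.05).
#' @param obs_noise_sigma Standard deviation of the lognormal measurement
#'   error applied to the virtual snapshots before comparison (default 0:
#'   compare raw simulated ANC).  When the clinical values carry known
#'   multiplicative measurement error, applying the same observation model
#'   to the predictions makes the comparison like-with-like.  Draws come
#'   from the current RNG stream; seed beforehand for reproducibility.
#' @return Data frame with one row per compared day: `day`, `statistic`,
#'   `p_value`, `reject`, `n_sim`, `n_clin`.  Days with fewer than 5
#'   clinical patients are skipped with a warning.
#' @export
validate_cohort <- function(series_list, clinical,
                            days = c(1, 8, 16, 22, 28), alpha = 0.05,
                            obs_noise_sigma = 0) {
  stopifnot(is.data.frame(clinical),
            all(c("day", "anc_cells_per_l") %in% names(clinical)))
  rows <- list()
  for (d in days) {
    clin <- clinical$anc_cells_per_l[clinical$day == d]
    if (length(clin) < 5) {
      warning("day ", d, " skipped: fewer than 5 clinical values")
      next
    }
    simv <- vapply(series_list, anc_at_days, numeric(1), days = d)
    if (obs_noise_sigma > 0)
      simv <- simv * exp(stats::rnorm(length(simv), 0, obs_noise_sigma))
    rep <- ks_validate(simv, clin, alpha)
    rows[[length(rows) + 1]] <- data.frame(
      day = d, statistic = rep$statistic, p_value = rep$p_value,
      reject = rep$reject, n_sim = rep$n_sim, n_clin = rep$n_clin)
  }
  if (length(rows) == 0)
    return(data.frame(day = numeric(0), statistic = numeric(0),
                      p_value = numeric(0), reject = logical(0),
                      n_sim = integer(0), n_clin = integer(0)))
  do.call(rbind, rows)
}

#' Monte Carlo global sensitivity ranking (Latin hypercube + PRCC)
#'
#' Samples the parameter space with a Latin hypercube, evaluates a scalar
#' output metric per sample, and scores each parameter by its partial
#' rank correlation coefficient (PRCC) with the metric, controlling for
#' the remaining parameters.  Parameters are ranked by |PRCC|.
#'
#' @param ranges Named list of length-2 numeric ranges (uniform sampling
#'   bounds), >= 2 parameters.
#' @param n_samples Number of Latin hypercube samples, >= 100.
#' @param seed Integer seed.
#' @param metric Function taking a named numeric vector of parameter
#'   values and returning a scalar output.  Default:
#'   [nadir_metric()] (cycle-1 daily-ANC nadir of a median DLBCL patient
#'   under 4 mg daily dosing, with the sampled traits substituted).
#' @return Object of class `gsa_report`: data frame of `parameter`,
#'   `prcc`, `rank`, with the sample matrix and metric values attached.
#' @examples
#' \donttest{
#' gsa_rank(list(a = c(0, 1), b = c(0, 1)), 200, seed = 1,
#'          metric = function(p) p[["a"]])
#' }
#' @export
gsa_rank <- function(ranges, n_samples = 1000, seed = 1,
                     metric = nadir_metric()) {
  if (length(ranges) < 2) stop("GSA requires at least 2 parameters")
  if (n_samples < 100) stop("GSA requires at least 100 samples")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  k <- length(ranges)
  u <- lhs::randomLHS(n_samples, k)
  x <- sapply(seq_len(k), function(j)
    ranges[[j]][1] + u[, j] * (ranges[[j]][2] - ranges[[j]][1]))
  colnames(x) <- names(ranges)
  y <- apply(x, 1, function(row) metric(row))
  if (stats::sd(y) == 0) {
    warning("degenerate output: metric constant across samples")
    scores <- stats::setNames(rep(0, k), names(ranges))
  } else {
    scores <- stats::setNames(vapply(seq_len(k), function(j)
      .prcc(x[, j], y, x[, -j, drop = FALSE]), numeric(1)), names(ranges))
  }
  tab <- data.frame(parameter = names(ranges), prcc = unname(scores))
  tab <- tab[order(-abs(tab$prcc)), ]
  tab$rank <- seq_len(k)
  rownames(tab) <- NULL
  structure(list(table = tab, samples = x, metric_values = y),
            class = "gsa_report")
}

# Partial rank correlation: correlate the residuals of rank(x_j) and
# rank(y) after regressing each on the ranks of the other parameters.
.prcc <- function(xj, y, others) {
  rx <- rank(xj); ry <- rank(y)
  if (ncol(others) == 0) return(stats::cor(rx, ry))
  ro <- apply(others, 2, rank)
  ex <- stats::lm.fit(cbind(1, ro), rx)$residuals
  ey <- stats::lm.fit(cbind(1, ro), ry)$residuals
  if (stats::sd(ex) == 0 || stats::sd(ey) == 0) return(0)
  stats::cor(ex, ey)
}

#' @export
print.gsa_report <- function(x, ...) {
  cat("Global sensitivity ranking (Latin hypercube / PRCC)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Default GSA exploration ranges
#'
#' Broad ranges for the individualized parameters: about one order of
#' magnitude around the DLBCL median for the multiplicative parameters
#' (`gamma` 0.001-0.3, `km_fraction` 0.02-0.5), the physiological span
#' 1-6 for the reservoir ratio, and the reported clinical baseline range
#' for `circ0`.
#'
#' @return Named list of length-2 ranges.
#' @export
default_gsa_ranges <- function() {
  list(gamma = c(0.001, 0.3), ratio_reserv0_circ0 = c(1, 6),
       km_fraction = c(0.02, 0.5), circ0 = c(2e9, 8e9))
}

#' Default GSA output metric: cycle-1 ANC nadir
#'
#' Returns a closure computing the minimum daily ANC over cycle 1 for a
#' reference patient whose traits are overridden by the sampled
#' parameter values (any of `gamma`, `ratio_reserv0_circ0`,
#' `km_fraction`, `circ0`), under a reference regimen.
#'
#' @param base_traits Reference traits (default DLBCL medians).
#' @param reg Reference regimen (default 4 mg daily).
#' @param pk,pd Model parameter objects.
#' @return Function mapping a named numeric vector to the nadir (cells/L).
#' @export
nadir_metric <- function(base_traits = disease_traits("dlbcl"),
                         reg = regimen(4, 28, 0),
                         pk = default_pk_params(),
                         pd = default_pd_params()) {
  function(par) {
    par <- as.list(par)
    tr <- patient_traits(
      circ0 = par$circ0 %||% base_traits$circ0,
      ratio_reserv0_circ0 = par$ratio_reserv0_circ0 %||%
        base_traits$ratio_reserv0_circ0,
      km_fraction = par$km_fraction %||% base_traits$km_fraction,
      gamma = par$gamma %||% base_traits$gamma)
    min(daily_anc(simulate_patient(tr, pk = pk, pd = pd, reg = reg)))
  }
}
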