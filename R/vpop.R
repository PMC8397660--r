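#' Anderson-Darling normality screen for a fitted-parameter sample
#'
#' Tests the composite null of normality (mean and variance estimated)
#' with the Anderson-Darling statistic.  Parameters whose empirical
#' distribution rejects normality are kept as empirical distributions and
#' smoothed by kernel density estimation rather than replaced by a
#' parametric model.
#'
#' @param samples Numeric vector of fitted parameter values (>= 8).
#' @param alpha Significance level (default 0.05).
#' @return List with `statistic`, `p_value`, `reject` (logical).
#' @export
screen_normality <- function(samples, alpha = 0.05) {
  if (length(samples) < 8)
    stop("normality screen requires at least 8 samples")
  if (any(!is.finite(samples))) stop("samples must be finite")
  if (stats::sd(samples) == 0)
    stop("degenerate input: constant samples")
  ad <- nortest::ad.test(samples)
  list(statistic = unname(ad$statistic), p_value = ad$p.value,
       reject = ad$p.value < alpha)
}

#' Kernel density estimate of a fitted-parameter distribution
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth.  When
#' `positive = TRUE`, draws from the estimate are rejection-resampled to
#' the positive support (all four patient traits are physically
#' positive); the kernel shape away from zero is preserved.
#'
#' @param samples Numeric vector of fitted parameter values (>= 8),
#'   finite; positive when `positive = TRUE`.
#' @param positive Restrict the sampling support to (0, Inf)?  Default
#'   TRUE.
#' @param name Optional parameter name carried in the object.
#' @return Object of class `parameter_distribution`: the sample, the
#'   bandwidth, the support flag, and the normality screen result.
#' @export
estimate_density <- function(samples, positive = TRUE, name = NULL) {
  if (length(samples) < 8)
    stop("density estimation requires at least 8 samples")
  if (any(!is.finite(samples))) stop("samples must be finite")
  if (positive && any(samples <= 0))
    stop("positive-support distribution requires positive samples")
  if (stats::sd(samples) == 0)
    stop("degenerate input: constant samples")
  structure(
    list(name = name, samples = samples,
         bandwidth = stats::bw.nrd0(samples), positive = positive,
         normality = screen_normality(samples)),
    class = "parameter_distribution"
  )
}

#' @export
print.parameter_distribution <- function(x, ...) {
  cat(sprintf("Kernel density estimate%s: n = %d, bandwidth %.4g%s\n",
              if (is.null(x$name)) "" else paste0(" of ", x$name),
              length(x$samples), x$bandwidth,
              if (x$positive) ", positive support" else ""))
  cat(sprintf("  normality (Anderson-Darling): p = %.3g (%s)\n",
              x$normality$p_value,
              if (x$normality$reject) "rejected" else "retained"))
  invisible(x)
}

#' Draw from a kernel density estimate
#'
#' Samples the Gaussian-kernel mixture directly: a resampled data point
#' plus Gaussian noise with the kernel bandwidth.  Non-positive draws are
#' rejection-resampled when the distribution has positive support.
#'
#' @param dist A [estimate_density()] object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(dist, n) {
  stopifnot(inherits(dist, "parameter_distribution"), n >= 1)
  draws <- sample(dist$samples, n, replace = TRUE) +
    stats::rnorm(n, 0, dist$bandwidth)
  if (dist$positive) {
    for (i in 1:100) {
      bad <- draws <= 0
      if (!any(bad)) break
      draws[bad] <- sample(dist$samples, sum(bad), replace = TRUE) +
        stats::rnorm(sum(bad), 0, dist$bandwidth)
    }
    if (any(draws <= 0))
      stop("rejection sampling failed to produce positive draws")
  }
  draws
}

#' Build a virtual patient cohort by independent sampling
#'
#' Draws each of the four patient traits independently from its
#' kernel-density-estimated distribution (trait values are assumed
#' independent: no conditional structure between traits).
#'
#' @param distributions Named list of [estimate_density()] objects with
#'   elements `circ0`, `ratio_reserv0_circ0`, `km_fraction`, `gamma`.
#' @param n Cohort size, >= 1.
#' @param seed Integer seed; the cohort is reproducible given
#'   (distributions, n, seed).
#' @return A `virtual_cohort`: data frame with columns `patient_id`,
#'   `circ0`, `ratio_reserv0_circ0`, `km_fraction`, `gamma`; the seed is
#'   kept as an attribute.
#' @export
sample_cohort <- function(distributions, n, seed) {
  need <- c("circ0", "ratio_reserv0_circ0", "km_fraction", "gamma")
  missing_d <- setdiff(need, names(distributions))
  if (length(missing_d) > 0)
    stop("missing distribution(s): ", paste(missing_d, collapse = ", "))
  if (n < 1) stop("cohort size must be >= 1")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  cols <- lapply(distributions[need], sample_distribution, n = n)
  out <- data.frame(patient_id = seq_len(n), cols)
  names(out) <- c("patient_id", need)
  attr(out, "seed") <- seed
  attr(out, "source") <- vapply(distributions[need], function(d)
    if (is.null(d$name)) "" else d$name, character(1))
  class(out) <- c("virtual_cohort", "data.frame")
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Fitted-trait distributions from a table of per-patient fits
#'
#' Convenience constructor: takes a data frame of per-patient fitted
#' traits (columns `circ0`, `ratio_reserv0_circ0`, `km_fraction`,
#' `gamma`) and returns the four kernel density estimates ready for
#' [sample_cohort()].
#'
#' @param fits Data frame of per-patient fitted trait values.
#' @return Named list of `parameter_distribution` objects.
#' @export
trait_distributions <- function(fits) {
  need <- c("circ0", "ratio_reserv0_circ0", "km_fraction", "gamma")
  stopifnot(all(need %in% names(fits)))
  stats::setNames(
    lapply(need, function(nm) estimate_density(fits[[nm]], name = nm)),
    need)
}
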