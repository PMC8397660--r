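#' Specification of a synthetic ANC study
#'
#' Defines a clinical-trial-like synthetic dataset with known ground
#' truth: trait-generating distributions, the regimen of the (single)
#' dose group, sparse sampling days, a multiplicative lognormal
#' measurement-noise model, and a G-CSF rescue rule whose administration
#' flags downstream censoring.  The defaults emulate the reported trial
#' features: baselines spanning about 2E9-8E9 cells/L, near-weekly
#' sampling (days 1, 8, 15, 22, 28), and rescue once ANC falls below the
#' grade-4 threshold.
#'
#' @param n_patients Number of patients, >= 1.
#' @param reg The dose-group [regimen()] (default 3 mg on 5/7).
#' @param sampling_days Integer study days within cycle 1 (default
#'   `c(1, 8, 15, 22, 28)`).
#' @param noise_sigma Standard deviation of the lognormal multiplicative
#'   measurement error (default 0.15), >= 0.
#' @param traits Trait-generating distributions: a named list with one
#'   entry per trait, each `list(dist = "uniform", min=, max=)` or
#'   `list(dist = "lognormal", meanlog=, sdlog=)`.  Defaults: baseline
#'   uniform on [2E9, 8E9]; ratio, K_M fraction and gamma lognormal
#'   around the DLBCL medians.
#' @param gcsf_trigger ANC threshold (cells/L) below which rescue may be
#'   given (default 5e8); `gcsf_prob` is the per-day rescue probability
#'   once below the trigger (default 0.3).  Set `gcsf_prob = 0` to
#'   disable rescue.
#' @param gcsf_prob See `gcsf_trigger`.
#' @param seed Integer seed.
#' @return Object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(n_patients, reg = regimen(3, 5, 2),
                                 sampling_days = c(1, 8, 15, 22, 28),
                                 noise_sigma = 0.15,
                                 traits = default_trait_generators(),
                                 gcsf_trigger = 5e8, gcsf_prob = 0.3,
                                 seed = 1) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (any(sampling_days < 1 | sampling_days > 28))
    stop("sampling days must lie within cycle 1 (days 1-28)")
  if (gcsf_prob < 0 || gcsf_prob > 1) stop("gcsf_prob must be in [0, 1]")
  stopifnot(inherits(reg, "regimen"))
  structure(
    list(n_patients = as.integer(n_patients), reg = reg,
         sampling_days = sort(unique(as.integer(sampling_days))),
         noise_sigma = noise_sigma, traits = traits,
         gcsf_trigger = gcsf_trigger, gcsf_prob = gcsf_prob,
         seed = as.integer(seed)),
    class = "synthetic_study_spec"
  )
}

#' Default trait-generating distributions for a DLBCL-like study
#'
#' Baseline ANC uniform on the reported clinical range [2E9, 8E9]
#' cells/L; reservoir ratio, K_M fraction and gamma lognormal centred on
#' the DLBCL median values with moderate inter-patient spread.
#'
#' @return Named list of distribution specifications.
#' @export
default_trait_generators <- function() {
  list(
    circ0 = list(dist = "uniform", min = 2e9, max = 8e9),
    ratio_reserv0_circ0 = list(dist = "lognormal", meanlog = log(2.5),
                               sdlog = 0.25),
    km_fraction = list(dist = "lognormal", meanlog = log(0.1), sdlog = 0.5),
    gamma = list(dist = "lognormal", meanlog = log(0.01), sdlog = 0.4)
  )
}

.draw_trait <- function(g, n) {
  switch(g$dist,
         uniform = stats::runif(n, g$min, g$max),
         lognormal = stats::rlnorm(n, g$meanlog, g$sdlog),
         stop("unknown trait distribution: ", g$dist))
}

#' Generate a synthetic clinical-format ANC study
#'
#' Draws patient traits, simulates each patient under the study regimen,
#' samples the trajectory at the sparse study days, applies
#' multiplicative lognormal measurement noise, and applies the G-CSF
#' rescue rule: once the simulated daily ANC drops below the trigger, a
#' rescue is administered with the per-day probability, and every
#' observation from the rescue day onwards carries `gcsf_flag = 1`.
#'
#' @param spec A [synthetic_study_spec()].
#' @param pk,pd Model parameter objects.
#' @return List with `observations` (long-format data frame:
#'   `patient_id`, `day`, `anc_cells_per_l`, `gcsf_flag`) and `truth`
#'   (data frame of generating traits plus `gcsf_day`, NA when no rescue
#'   occurred).  Reproducible given the spec (which carries the seed).
#' @export
generate_study <- function(spec, pk = default_pk_params(),
                           pd = default_pd_params()) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  n <- spec$n_patients
  tr <- data.frame(
    patient_id = seq_len(n),
    circ0 = .draw_trait(spec$traits$circ0, n),
    ratio_reserv0_circ0 = .draw_trait(spec$traits$ratio_reserv0_circ0, n),
    km_fraction = .draw_trait(spec$traits$km_fraction, n),
    gamma = .draw_trait(spec$traits$gamma, n)
  )
  obs <- vector("list", n)
  gcsf_day <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    sim <- simulate_patient(
      patient_traits(tr$circ0[i], tr$ratio_reserv0_circ0[i],
                     tr$km_fraction[i], tr$gamma[i]),
      pk = pk, pd = pd, reg = spec$reg)
    daily <- daily_anc(sim)
    if (spec$gcsf_prob > 0) {
      low_days <- which(daily < spec$gcsf_trigger)
      for (d in low_days) {
        if (stats::runif(1) < spec$gcsf_prob) { gcsf_day[i] <- d; break }
      }
    }
    anc_true <- anc_at_days(sim, spec$sampling_days)
    noise <- if (spec$noise_sigma > 0)
      exp(stats::rnorm(length(anc_true), 0, spec$noise_sigma)) else 1
    obs[[i]] <- data.frame(
      patient_id = i, day = spec$sampling_days,
      anc_cells_per_l = anc_true * noise,
      gcsf_flag = as.integer(!is.na(gcsf_day[i]) &
                               spec$sampling_days >= gcsf_day[i])
    )
  }
  tr$gcsf_day <- gcsf_day
  list(observations = do.call(rbind, obs), truth = tr)
}

#' Censor observations after the first G-CSF rescue
#'
#' For each patient, removes every row at or after the first day whose
#' `gcsf_flag` is set; patients without flags are untouched.  Mirrors the
#' preprocessing that removes post-rescue ANC instead of modeling G-CSF
#' pharmacology.
#'
#' @param table Long-format ANC data frame with columns `patient_id`,
#'   `day`, and `gcsf_flag`.
#' @return The censored table.  A warning names patients left with zero
#'   observations (rescued at their first sample).
#' @export
censor_post_gcsf <- function(table) {
  if (!"gcsf_flag" %in% names(table))
    stop("table has no gcsf_flag column")
  keep <- rep(TRUE, nrow(table))
  for (pid in unique(table$patient_id)) {
    rows <- which(table$patient_id == pid)
    flagged <- rows[table$gcsf_flag[rows] %in% 1]
    if (length(flagged) == 0) next
    first_day <- min(table$day[flagged])
    keep[rows[table$day[rows] >= first_day]] <- FALSE
    if (first_day <= min(table$day[rows]))
      warning("patient ", pid, " rescued at first sample: ",
              "no observations remain")
  }
  table[keep, , drop = FALSE]
}
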