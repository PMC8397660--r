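#' Read a long-format clinical ANC table
#'
#' Expected CSV columns: `patient_id`, `day`, `anc_cells_per_l`, and
#' optionally `gcsf_flag` (0/1 or logical).  Malformed rows (non-finite
#' day or ANC, negative ANC) are rejected with an error listing the
#' offending line numbers.
#'
#' @param path Path to a CSV file.
#' @return Validated data frame; `gcsf_flag` parsed to integer 0/1 when
#'   present.
#' @export
read_anc_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "day", "anc_cells_per_l")
  missing_c <- setdiff(need, names(df))
  if (length(missing_c) > 0)
    stop("ANC table schema error: missing column(s) ",
         paste(missing_c, collapse = ", "))
  day <- suppressWarnings(as.numeric(df$day))
  anc <- suppressWarnings(as.numeric(df$anc_cells_per_l))
  bad <- !is.finite(day) | !is.finite(anc) | anc < 0
  if (any(bad))
    stop("malformed ANC rows (file line numbers, header = line 1): ",
         paste(which(bad) + 1, collapse = ", "))
  df$day <- day
  df$anc_cells_per_l <- anc
  if ("gcsf_flag" %in% names(df)) {
    fl <- df$gcsf_flag
    if (is.logical(fl)) fl <- as.integer(fl)
    fl <- suppressWarnings(as.integer(fl))
    if (any(is.na(fl) | !(fl %in% c(0L, 1L))))
      stop("gcsf_flag must be 0/1 or logical")
    df$gcsf_flag <- fl
  }
  df
}

#' Export simulated trajectories as a long-format table
#'
#' @param series_list List of `anc_series`.
#' @param compartments Include all six compartment columns?  Default
#'   FALSE (ANC only).
#' @return Data frame with `patient_id`, `time_h`, `anc_cells_per_l`
#'   (and compartment columns when requested).
#' @export
trajectories_long <- function(series_list, compartments = FALSE) {
  do.call(rbind, lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    out <- data.frame(patient_id = i, time_h = s$times,
                      anc_cells_per_l = s$anc)
    if (compartments) out <- cbind(out, as.data.frame(s$states))
    out
  }))
}

.write_manifest <- function(out_path, command, config, seed) {
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    package = "neutroqsp",
    package_version = as.character(utils::packageVersion("neutroqsp")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- paste0(out_path, ".manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.check_thresholds <- function(th) {
  if (any(th <= 0) || !(th[["grade4"]] < th[["grade3"]] &&
                        th[["grade3"]] < th[["grade2"]]))
    stop("thresholds must be positive and ordered: grade4 < grade3 < grade2")
  th
}

.opt <- function(...) optparse::make_option(...)

.parse <- function(args, option_list, usage) {
  parser <- optparse::OptionParser(option_list = option_list, usage = usage)
  optparse::parse_args(parser, args = args)
}

#' Run a command-line style subcommand
#'
#' Dispatch for the shell interface.  Subcommands: `synth` (generate a
#' synthetic ANC study), `simulate` (one patient trajectory), `fit`
#' (per-patient fits of an ANC table), `vpop` (KDE cohort sampling from
#' fitted traits), `trial` (dose-by-schedule screen), `endpoints`
#' (toxicity summary of exported trajectories), `validate` (K-S cohort
#' validation), `gsa` (sensitivity ranking).  Every output artifact gets
#' a sibling `*.manifest.json` recording the full configuration, seed
#' and package version, sufficient to replay the run.
#'
#' @param argv Character vector of arguments, subcommand first, e.g.
#'   `c("synth", "--n", "20", "--out", "anc.csv")`.
#' @return Integer exit status, invisibly (0 on success).
#' @export
run_command <- function(argv) {
  if (length(argv) == 0 || argv[1] %in% c("-h", "--help"))
    stop("usage: neutroqsp <synth|simulate|fit|vpop|trial|endpoints|",
         "validate|gsa> [options]", call. = FALSE)
  cmd <- argv[1]
  rest <- argv[-1]
  handler <- switch(cmd,
    synth = .cmd_synth, simulate = .cmd_simulate, fit = .cmd_fit,
    vpop = .cmd_vpop, trial = .cmd_trial, endpoints = .cmd_endpoints,
    validate = .cmd_validate, gsa = .cmd_gsa,
    stop("unknown subcommand: ", cmd, call. = FALSE))
  handler(rest)
  invisible(0L)
}

.cmd_synth <- function(args) {
  o <- .parse(args, list(
    .opt("--n", type = "integer", default = 50),
    .opt("--dose", type = "double", default = 3),
    .opt("--schedule", type = "character", default = "5/7"),
    .opt("--sigma", type = "double", default = 0.15),
    .opt("--seed", type = "integer", default = 1),
    .opt("--out", type = "character", default = "anc.csv"),
    .opt("--truth", type = "character", default = NULL)),
    "neutroqsp synth [options]")
  spec <- synthetic_study_spec(
    o$n, parse_regimen(sprintf("%gmg %s", o$dose, o$schedule)),
    noise_sigma = o$sigma, seed = o$seed)
  study <- generate_study(spec)
  utils::write.csv(study$observations, o$out, row.names = FALSE)
  if (!is.null(o$truth))
    utils::write.csv(study$truth, o$truth, row.names = FALSE)
  .write_manifest(o$out, "synth", o[setdiff(names(o), "help")], o$seed)
}

.cmd_simulate <- function(args) {
  o <- .parse(args, list(
    .opt("--disease", type = "character", default = "dlbcl"),
    .opt("--regimen", type = "character", default = "3mg 5/7"),
    .opt("--horizon", type = "integer", default = 28),
    .opt("--compartments", action = "store_true", default = FALSE),
    .opt("--out", type = "character", default = "trajectory.csv")),
    "neutroqsp simulate [options]")
  s <- simulate_patient(disease_traits(o$disease),
                        reg = parse_regimen(o$regimen),
                        horizon_days = o$horizon)
  utils::write.csv(trajectories_long(list(s), o$compartments), o$out,
                   row.names = FALSE)
  .write_manifest(o$out, "simulate", o[setdiff(names(o), "help")], NA)
}

.cmd_fit <- function(args) {
  o <- .parse(args, list(
    .opt("--anc", type = "character"),
    .opt("--regimen", type = "character", default = "3mg 5/7"),
    .opt("--out", type = "character", default = "fits.json")),
    "neutroqsp fit --anc anc.csv [options]")
  if (is.null(o$anc)) stop("--anc is required")
  tab <- read_anc_table(o$anc)
  if ("gcsf_flag" %in% names(tab)) tab <- censor_post_gcsf(tab)
  reg <- parse_regimen(o$regimen)
  spec <- default_fit_spec()
  fits <- list()
  for (pid in unique(tab$patient_id)) {
    rows <- tab[tab$patient_id == pid, ]
    obs <- data.frame(time_h = 24 * (rows$day - 1),
                      anc = rows$anc_cells_per_l)
    if (nrow(obs) < 3) {
      warning("patient ", pid, " skipped: fewer than 3 observations")
      next
    }
    fr <- fit_patient(obs, spec, reg)
    fits[[as.character(pid)]] <- c(as.list(fr$par),
                                   list(circ0 = fr$circ0,
                                        objective = fr$objective,
                                        converged = fr$converged))
  }
  jsonlite::write_json(fits, o$out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  .write_manifest(o$out, "fit", o[setdiff(names(o), "help")], NA)
}

.cmd_vpop <- function(args) {
  o <- .parse(args, list(
    .opt("--fits", type = "character"),
    .opt("--n", type = "integer", default = 1000),
    .opt("--seed", type = "integer", default = 1),
    .opt("--out", type = "character", default = "cohort.csv")),
    "neutroqsp vpop --fits fits.csv [options]")
  if (is.null(o$fits)) stop("--fits is required (CSV of fitted traits)")
  fits <- utils::read.csv(o$fits)
  cohort <- sample_cohort(trait_distributions(fits), o$n, o$seed)
  utils::write.csv(as.data.frame(cohort), o$out, row.names = FALSE)
  .write_manifest(o$out, "vpop", o[setdiff(names(o), "help")], o$seed)
}

.cmd_trial <- function(args) {
  o <- .parse(args, list(
    .opt("--doses", type = "character", default = "2,3,4,5,6,7,8"),
    .opt("--schedules", type = "character",
         default = "3/7,5/7,7/14,14/28,21/28,28/28"),
    .opt("--cohort", type = "character", default = NULL),
    .opt("--n", type = "integer", default = 1000),
    .opt("--seed", type = "integer", default = 1),
    .opt("--grade3", type = "double", default = 1e9),
    .opt("--grade4", type = "double", default = 5e8),
    .opt("--grade2", type = "double", default = 1.5e9),
    .opt("--out", type = "character", default = "trial.csv")),
    "neutroqsp trial [options]")
  th <- .check_thresholds(c(grade3 = o$grade3, grade4 = o$grade4,
                            grade2 = o$grade2))
  cohort <- if (!is.null(o$cohort)) utils::read.csv(o$cohort)
            else synthetic_cohort(o$n, o$seed)
  doses <- as.numeric(strsplit(o$doses, ",")[[1]])
  schedules <- strsplit(o$schedules, ",")[[1]]
  grid <- scenario_grid(cohort, doses, schedules, thresholds = th)
  utils::write.csv(grid, o$out, row.names = FALSE)
  .write_manifest(o$out, "trial", o[setdiff(names(o), "help")], o$seed)
}

.cmd_endpoints <- function(args) {
  o <- .parse(args, list(
    .opt("--traj", type = "character"),
    .opt("--grade3", type = "double", default = 1e9),
    .opt("--grade4", type = "double", default = 5e8),
    .opt("--grade2", type = "double", default = 1.5e9),
    .opt("--out", type = "character", default = "endpoints.csv")),
    "neutroqsp endpoints --traj trajectories.csv [options]")
  if (is.null(o$traj)) stop("--traj is required")
  th <- .check_thresholds(c(grade3 = o$grade3, grade4 = o$grade4,
                            grade2 = o$grade2))
  tr <- utils::read.csv(o$traj)
  stopifnot(all(c("patient_id", "time_h", "anc_cells_per_l") %in% names(tr)))
  dailies <- lapply(split(tr, tr$patient_id), function(d) {
    n <- floor(max(d$time_h) / 24)
    vapply(seq_len(min(n, 28)), function(day)
      min(d$anc_cells_per_l[d$time_h >= 24 * (day - 1) &
                              d$time_h <= 24 * day]), numeric(1))
  })
  utils::write.csv(as.data.frame(summarize_cohort(dailies, th)), o$out,
                   row.names = FALSE)
  .write_manifest(o$out, "endpoints", o[setdiff(names(o), "help")], NA)
}

.cmd_validate <- function(args) {
  o <- .parse(args, list(
    .opt("--clinical", type = "character"),
    .opt("--days", type = "character", default = "1,8,16,22,28"),
    .opt("--regimen", type = "character", default = "3mg 5/7"),
    .opt("--n", type = "integer", default = 1000),
    .opt("--seed", type = "integer", default = 1),
    .opt("--out", type = "character", default = "validation.csv")),
    "neutroqsp validate --clinical anc.csv [options]")
  if (is.null(o$clinical)) stop("--clinical is required")
  clin <- read_anc_table(o$clinical)
  if ("gcsf_flag" %in% names(clin)) clin <- censor_post_gcsf(clin)
  cohort <- synthetic_cohort(o$n, o$seed)
  sims <- simulate_cohort(cohort, reg = parse_regimen(o$regimen))
  days <- as.numeric(strsplit(o$days, ",")[[1]])
  rep <- validate_cohort(sims, clin, days)
  utils::write.csv(rep, o$out, row.names = FALSE)
  .write_manifest(o$out, "validate", o[setdiff(names(o), "help")], o$seed)
}

.cmd_gsa <- function(args) {
  o <- .parse(args, list(
    .opt("--params", type = "character",
         default = "gamma,ratio_reserv0_circ0,km_fraction"),
    .opt("--n", type = "integer", default = 1000),
    .opt("--seed", type = "integer", default = 1),
    .opt("--out", type = "character", default = "gsa.csv")),
    "neutroqsp gsa [options]")
  default_ranges <- default_gsa_ranges()
  pars <- strsplit(o$params, ",")[[1]]
  unknown <- setdiff(pars, names(default_ranges))
  if (length(unknown) > 0) stop("unknown GSA parameter(s): ",
                                paste(unknown, collapse = ", "))
  rep <- gsa_rank(default_ranges[pars], o$n, o$seed)
  utils::write.csv(rep$table, o$out, row.names = FALSE)
  .write_manifest(o$out, "gsa", o[setdiff(names(o), "help")], o$seed)
}

#' Sample a cohort from the default synthetic trait generators
#'
#' Convenience used by the trial and validation commands when no fitted
#' cohort file is supplied: draws traits from
#' [default_trait_generators()] (the documented synthetic stand-in for
#' the unreleased clinical parameter distributions).
#'
#' @param n Cohort size.
#' @param seed Integer seed.
#' @return A `virtual_cohort` data frame.
#' @export
synthetic_cohort <- function(n, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  g <- default_trait_generators()
  out <- data.frame(
    patient_id = seq_len(n),
    circ0 = .draw_trait(g$circ0, n),
    ratio_reserv0_circ0 = .draw_trait(g$ratio_reserv0_circ0, n),
    km_fraction = .draw_trait(g$km_fraction, n),
    gamma = .draw_trait(g$gamma, n))
  attr(out, "seed") <- seed
  class(out) <- c("virtual_cohort", "data.frame")
  out
}
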