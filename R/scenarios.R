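# Scenario parameter registry and validation.
#
# A simulation setting is fully described by five headline knobs -- the
# misdiagnosis probability p1, the first-line TCS probability p2, the two
# switch probabilities p3 (true AD) and p4 (misdiagnosed CTCL), and the
# Weibull scale lambda of the re-evaluation delay -- plus structural
# constants shared by all settings.

# Sentinel age used for events that never happen within any study window.
.never <- 1e9

# Built-in settings: "main" (A1-A9), "max-use" (B1-B3), "discovery" (C1-C2).
.builtin_grid <- data.frame(
  setting_id = c(paste0("A", 1:9), paste0("B", 1:3), paste0("C", 1:2)),
  scenario = c(rep("main", 9), rep("max-use", 3), rep("discovery", 2)),
  p1 = c(0.25, 0.50, 0.75, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25,
         0.25, 0.50, 0.75, 0.25, 0.25),
  p2 = c(0.95, 0.95, 0.95, 0.99, 0.90, 0.95, 0.95, 0.95, 0.95,
         0.90, 0.90, 0.90, 0.95, 0.95),
  p3 = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.10, 0.20, 0.05, 0.05,
         0.20, 0.20, 0.20, 0.05, 0.05),
  p4 = c(0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.10, 0.40,
         0.40, 0.40, 0.40, 0.25, 0.25),
  lambda_reeval = c(rep(3.5, 12), 1.2, 0.5),
  stringsAsFactors = FALSE
)

#' Default calibration of the atopic-dermatitis onset distribution
#'
#' Lifetime AD risk and onset-age shape are controlled by a three-part
#' mixture: a patient becomes an AD case with probability `case_fraction`;
#' cases draw their onset age either from an exponential childhood component
#' (probability `childhood_weight`, mean `childhood_mean_years`) or uniformly
#' over `adult_onset_range`.  The defaults are solved in closed form so that
#' the cumulative onset risk is 6.6% by age 18 and 10.5% by age 100, with a
#' median onset age among cases of about 5 years.
#'
#' @param case_fraction Lifetime probability of developing AD.
#' @param childhood_weight Mixture weight of the childhood-onset component.
#' @param childhood_mean_years Mean of the exponential childhood component.
#' @param adult_onset_range Two ordered ages bounding the uniform adult
#'   component.
#' @return A list of class `ad_onset_calibration`.
#' @export
ad_onset_calibration <- function(case_fraction = 0.105,
                                 childhood_weight = 0.63,
                                 childhood_mean_years = 3.2,
                                 adult_onset_range = c(18, 100)) {
  stopifnot(is.numeric(case_fraction), length(case_fraction) == 1L,
            case_fraction >= 0, case_fraction <= 1,
            is.numeric(childhood_weight), length(childhood_weight) == 1L,
            childhood_weight >= 0, childhood_weight <= 1,
            is.numeric(childhood_mean_years), childhood_mean_years > 0,
            is.numeric(adult_onset_range), length(adult_onset_range) == 2L,
            adult_onset_range[1] < adult_onset_range[2])
  structure(list(case_fraction = case_fraction,
                 childhood_weight = childhood_weight,
                 childhood_mean_years = childhood_mean_years,
                 adult_onset_range = as.numeric(adult_onset_range)),
            class = "ad_onset_calibration")
}

#' Construct and validate a set of scenario parameters
#'
#' @param setting_id Short identifier of the setting; built-in ids are
#'   `A1`-`A9`, `B1`-`B3`, `C1`-`C2`.
#' @param p1 Probability that a CTCL onset is initially diagnosed correctly.
#' @param p2 Probability of receiving TCS as first-line treatment.
#' @param p3 Probability that a correctly diagnosed AD patient switches from
#'   TCS to tacrolimus.
#' @param p4 Probability that a misdiagnosed CTCL patient switches from TCS
#'   to tacrolimus.
#' @param lambda_reeval Weibull scale (years) of the diagnostic re-evaluation
#'   delay.
#' @param kappa_reeval Weibull shape of the re-evaluation delay.
#' @param n_reeval_draws Number of independent Weibull draws whose maximum is
#'   the per-patient delay.
#' @param lambda_ctcl Constant CTCL onset rate per person-year.
#' @param lambda_ad Nominal AD onset-rate constant retained for reference by
#'   alternative onset samplers; the default sampler uses `ad_calibration`.
#' @param ad_calibration An [ad_onset_calibration()] object.
#' @param p_short_switch Fraction of switchers whose pre-switch TCS duration
#'   is below one year.
#' @param rate_long_switch Exponential rate (per year) of the shifted
#'   long-duration switch component.
#' @param shift_long_switch Shift (years) of the long-duration component.
#' @param base_population Number of patients in one simulated base population.
#' @param study_years Length (years) of the administrative follow-up window.
#' @param inclusion_age_max Upper bound (years) of the uniformly drawn
#'   inclusion age.
#' @param n_replicates Default number of Monte-Carlo replicates.
#' @param alpha Two-sided significance level.
#' @param master_seed Master seed from which per-replicate streams are
#'   derived.
#' @return A list of class `scenario_parameters`.
#' @seealso [builtin_setting()], [load_scenario_config()]
#' @export
scenario_parameters <- function(setting_id = "custom",
                                p1, p2, p3, p4,
                                lambda_reeval,
                                kappa_reeval = 0.9,
                                n_reeval_draws = 2L,
                                lambda_ctcl = 6e-6,
                                lambda_ad = 1.28e-6,
                                ad_calibration = ad_onset_calibration(),
                                p_short_switch = 0.40,
                                rate_long_switch = 3,
                                shift_long_switch = 1,
                                base_population = 4e6,
                                study_years = 12,
                                inclusion_age_max = 100,
                                n_replicates = 1000L,
                                alpha = 0.05,
                                master_seed = 1L) {
  params <- list(setting_id = as.character(setting_id),
                 p1 = p1, p2 = p2, p3 = p3, p4 = p4,
                 lambda_reeval = lambda_reeval,
                 kappa_reeval = kappa_reeval,
                 n_reeval_draws = n_reeval_draws,
                 lambda_ctcl = lambda_ctcl,
                 lambda_ad = lambda_ad,
                 ad_calibration = ad_calibration,
                 p_short_switch = p_short_switch,
                 rate_long_switch = rate_long_switch,
                 shift_long_switch = shift_long_switch,
                 base_population = base_population,
                 study_years = study_years,
                 inclusion_age_max = inclusion_age_max,
                 n_replicates = n_replicates,
                 alpha = alpha,
                 master_seed = master_seed)
  class(params) <- "scenario_parameters"
  validate_scenario_parameters(params)
}

#' @rdname scenario_parameters
#' @param params A `scenario_parameters` object to validate.
#' @export
validate_scenario_parameters <- function(params) {
  chk_prob <- function(name) {
    v <- params[[name]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a probability in [0, 1], got %s",
                   name, format(v)), call. = FALSE)
  }
  chk_pos <- function(name) {
    v <- params[[name]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("'%s' must be strictly positive, got %s",
                   name, format(v)), call. = FALSE)
  }
  chk_count <- function(name) {
    v <- params[[name]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != round(v))
      stop(sprintf("'%s' must be an integer >= 1, got %s",
                   name, format(v)), call. = FALSE)
  }
  for (nm in c("p1", "p2", "p3", "p4", "p_short_switch", "alpha")) chk_prob(nm)
  for (nm in c("lambda_reeval", "kappa_reeval", "lambda_ctcl", "lambda_ad",
               "rate_long_switch", "study_years", "inclusion_age_max"))
    chk_pos(nm)
  for (nm in c("n_reeval_draws", "base_population", "n_replicates"))
    chk_count(nm)
  if (!is.numeric(params$shift_long_switch) || params$shift_long_switch < 0)
    stop("'shift_long_switch' must be non-negative", call. = FALSE)
  if (!inherits(params$ad_calibration, "ad_onset_calibration"))
    params$ad_calibration <- do.call(ad_onset_calibration,
                                     params$ad_calibration)
  for (nm in c("n_reeval_draws", "base_population", "n_replicates",
               "master_seed"))
    params[[nm]] <- as.integer(params[[nm]])
  params
}

#' Retrieve a built-in simulation setting
#'
#' Returns the full parameter set for one of the fourteen registered
#' settings: `A1`-`A9` (main scenario), `B1`-`B3` (maximum-use scenario) and
#' `C1`-`C2` (discovery scenario).
#'
#' @param id Setting identifier.
#' @param ... Further arguments (for example `master_seed`, `base_population`
#'   or `n_replicates`) passed to [scenario_parameters()] to override
#'   structural defaults.
#' @return A `scenario_parameters` object.
#' @examples
#' builtin_setting("A1")
#' @export
builtin_setting <- function(id, ...) {
  row <- .builtin_grid[.builtin_grid$setting_id == id, ]
  if (nrow(row) != 1L)
    stop(sprintf("no such setting '%s'; valid ids: %s", id,
                 paste(.builtin_grid$setting_id, collapse = ", ")),
         call. = FALSE)
  scenario_parameters(setting_id = row$setting_id,
                      p1 = row$p1, p2 = row$p2, p3 = row$p3, p4 = row$p4,
                      lambda_reeval = row$lambda_reeval, ...)
}

#' List the built-in settings
#'
#' @param scenario Optional scenario group filter: `"main"`, `"max-use"` or
#'   `"discovery"`.
#' @return A data frame with one row per setting and columns `setting_id`,
#'   `scenario`, `p1`-`p4` and `lambda_reeval`.
#' @export
list_settings <- function(scenario = NULL) {
  out <- .builtin_grid
  if (!is.null(scenario)) {
    if (!scenario %in% out$scenario)
      stop(sprintf("unknown scenario group '%s'; valid groups: %s", scenario,
                   paste(unique(out$scenario), collapse = ", ")),
           call. = FALSE)
    out <- out[out$scenario == scenario, ]
  }
  rownames(out) <- NULL
  out
}

#' Load scenario parameters from a structured-text configuration
#'
#' The configuration is a YAML mapping.  An optional `base_setting` key names
#' a built-in setting whose parameters are used as defaults; any other key
#' overrides the corresponding field.  Overriding a field of a built-in
#' setting yields a custom setting whose id is derived from the base id
#' unless `setting_id` is given explicitly.
#'
#' @param source Path to a YAML file, or a named list of fields.
#' @return A validated `scenario_parameters` object.
#' @examples
#' params <- load_scenario_config(list(base_setting = "A1", p4 = 0.40))
#' params$p4
#' @export
load_scenario_config <- function(source) {
  cfg <- if (is.character(source) && length(source) == 1L) {
    yaml::read_yaml(source)
  } else if (is.list(source)) {
    source
  } else {
    stop("'source' must be a file path or a named list", call. = FALSE)
  }
  if (is.null(cfg)) cfg <- list()
  base_id <- cfg$base_setting
  cfg$base_setting <- NULL
  known <- names(formals(scenario_parameters))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(base_id)) {
    base <- builtin_setting(base_id)
    overridden <- setdiff(names(cfg), "setting_id")
    args <- unclass(base)
    args[names(cfg)] <- cfg
    if (is.null(cfg$setting_id) && length(overridden))
      args$setting_id <- paste0(base_id, "-custom")
    do.call(scenario_parameters, args)
  } else {
    do.call(scenario_parameters, cfg)
  }
}

#' Serialize scenario parameters to YAML
#'
#' Writing and re-loading a parameter set reproduces an identical tuple,
#' so a run can be reproduced from its manifest alone.
#'
#' @param params A `scenario_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(params, path) {
  stopifnot(inherits(params, "scenario_parameters"))
  x <- unclass(params)
  x$ad_calibration <- unclass(x$ad_calibration)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @export
print.scenario_parameters <- function(x, ...) {
  cat(sprintf("Scenario setting '%s'\n", x$setting_id))
  cat(sprintf("  p1 = %.3g  p2 = %.3g  p3 = %.3g  p4 = %.3g  lambda = %.3g\n",
              x$p1, x$p2, x$p3, x$p4, x$lambda_reeval))
  cat(sprintf("  base population %s, %d replicates, %g-year window\n",
              format(x$base_population, big.mark = ","), x$n_replicates,
              x$study_years))
  invisible(x)
}
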