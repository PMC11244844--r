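# Monte-Carlo replication harness: run one setting many times and
# summarise the sampling distribution of the bias.

#' Run replicate simulations of one setting
#'
#' Each replicate draws a fresh base population, builds the cohort, expands
#' it to counting-process form, fits the time-dependent Cox model and
#' estimates exposure-specific incidence rates.  Replicate streams are
#' derived from `master_seed` up front (two sub-seeds per replicate: one
#' for the population, one for the inclusion ages), so results do not
#' depend on execution order and are reproducible replicate by replicate.
#'
#' @param params A [scenario_parameters()] object.
#' @param n_replicates Number of replicates; defaults to
#'   `params$n_replicates`.
#' @param master_seed Master seed; defaults to `params$master_seed`.
#' @param base_population Base-population size per replicate; defaults to
#'   `params$base_population`.
#' @param progress Print one line per replicate block of 25.
#' @return A data frame with one row per replicate: `setting_id`,
#'   `replicate`, `seed_population`, `seed_cohort`, `n_cohort`, `n_events`,
#'   `log_hr`, `se`, `hr`, `ci_low`, `ci_high`, `p_value`, `converged`,
#'   `significant`, `events_tcs`, `py_tcs`, `ir_tcs`, `events_tacro`,
#'   `py_tacro`, `ir_tacro`.  Replicates whose fit degenerates carry `NA`
#'   estimates rather than aborting the batch.
#' @export
run_setting <- function(params,
                        n_replicates = params$n_replicates,
                        master_seed = params$master_seed,
                        base_population = params$base_population,
                        progress = FALSE) {
  stopifnot(inherits(params, "scenario_parameters"), n_replicates >= 1)
  set.seed(as.integer(master_seed))
  seeds <- matrix(sample.int(2147483646L, 2L * n_replicates),
                  ncol = 2L)
  res <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    res[[r]] <- .run_one_replicate(params, r, seeds[r, 1L], seeds[r, 2L],
                                   base_population)
    if (progress && r %% 25L == 0L)
      message(sprintf("  %s: replicate %d/%d", params$setting_id, r,
                      n_replicates))
  }
  out <- do.call(rbind, res)
  attr(out, "params") <- params
  attr(out, "master_seed") <- as.integer(master_seed)
  attr(out, "base_population") <- as.integer(base_population)
  out
}

.run_one_replicate <- function(params, r, seed_pop, seed_cohort,
                               base_population) {
  pop <- simulate_population(params, seed_pop, n = base_population)
  cohort <- build_cohort(pop, params, seed_cohort)
  rows <- expand_counting_process(cohort)
  base <- data.frame(setting_id = params$setting_id, replicate = r,
                     seed_population = seed_pop, seed_cohort = seed_cohort,
                     n_cohort = nrow(cohort), n_events = sum(cohort$event))
  fit <- tryCatch(fit_cox_td(rows, params$alpha), error = function(e) NULL)
  ir <- estimate_incidence(rows)
  pick <- function(grp, col) {
    v <- ir[[col]][ir$group == grp]
    if (length(v)) v else NA_real_
  }
  if (is.null(fit) || !fit$converged) {
    est <- data.frame(log_hr = NA_real_, se = NA_real_, hr = NA_real_,
                      ci_low = NA_real_, ci_high = NA_real_,
                      p_value = NA_real_, converged = FALSE,
                      significant = NA_integer_)
  } else {
    est <- data.frame(log_hr = fit$log_hr, se = fit$se, hr = fit$hr,
                      ci_low = fit$ci_low, ci_high = fit$ci_high,
                      p_value = fit$p_value, converged = TRUE,
                      significant = wald_significance(fit, params$alpha))
  }
  cbind(base, est,
        data.frame(events_tcs = pick("TCS", "events"),
                   py_tcs = pick("TCS", "person_years"),
                   ir_tcs = pick("TCS", "rate_per_1000py"),
                   events_tacro = pick("tacrolimus", "events"),
                   py_tacro = pick("tacrolimus", "person_years"),
                   ir_tacro = pick("tacrolimus", "rate_per_1000py")))
}

#' Summarise a replicate batch
#'
#' Computes the median, 95% reference interval (2.5th-97.5th percentiles,
#' linear interpolation between order statistics), minimum and maximum of
#' the hazard-ratio point estimates and of each exposure-specific incidence
#' rate, and the percentage of usable replicates with a significant Wald
#' test.  Non-converged replicates are excluded and counted.
#'
#' @param results A [run_setting()] table.
#' @param alpha Significance level for the percentage-significant column.
#' @return A one-row data frame of class `setting_summary`.
#' @export
summarize_setting <- function(results, alpha = 0.05) {
  usable <- results[results$converged %in% TRUE & is.finite(results$hr), ,
                    drop = FALSE]
  if (nrow(usable) < 2L)
    stop("fewer than 2 usable replicates; cannot summarise", call. = FALSE)
  qs <- function(x) {
    q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE, type = 7,
                         na.rm = TRUE)
    c(low = q[1], median = q[2], high = q[3],
      min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE))
  }
  hr <- qs(usable$hr)
  irt <- qs(usable$ir_tacro)
  irc <- qs(usable$ir_tcs)
  params <- attr(results, "params")
  out <- data.frame(
    setting_id = results$setting_id[1L],
    p1 = if (!is.null(params)) params$p1 else NA_real_,
    p2 = if (!is.null(params)) params$p2 else NA_real_,
    p3 = if (!is.null(params)) params$p3 else NA_real_,
    p4 = if (!is.null(params)) params$p4 else NA_real_,
    lambda_reeval = if (!is.null(params)) params$lambda_reeval else NA_real_,
    n_replicates = nrow(results),
    n_excluded = nrow(results) - nrow(usable),
    median_hr = hr["median"], ri_low = hr["low"], ri_high = hr["high"],
    hr_min = hr["min"], hr_max = hr["max"],
    pct_significant = 100 * mean(usable$significant, na.rm = TRUE),
    median_ir_tacro = irt["median"], ir_tacro_ri_low = irt["low"],
    ir_tacro_ri_high = irt["high"], ir_tacro_min = irt["min"],
    ir_tacro_max = irt["max"],
    median_ir_tcs = irc["median"], ir_tcs_ri_low = irc["low"],
    ir_tcs_ri_high = irc["high"], ir_tcs_min = irc["min"],
    ir_tcs_max = irc["max"])
  rownames(out) <- NULL
  class(out) <- c("setting_summary", "data.frame")
  out
}

#' Monte-Carlo standard error of a sample median
#'
#' Large-sample approximation `1.2533 * sd(x) / sqrt(n)`, used to set the
#' tolerance of desk-scale comparisons between replicate medians.
#'
#' @param x Replicate point estimates.
#' @return Standard error of the median.
#' @export
median_mc_se <- function(x) {
  x <- x[is.finite(x)]
  1.2533 * stats::sd(x) / sqrt(length(x))
}
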