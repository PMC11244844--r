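# Registry-style cohort emulation: random administrative windows,
# AD-diagnosis-based inclusion, left truncation, ever-use exposure, and
# counting-process expansion.

#' Build the AD treatment cohort from a latent population
#'
#' Each patient is assigned an administrative window starting at a uniformly
#' drawn inclusion age `r0` on \[0, `inclusion_age_max`\] and running for
#' `study_years`.  A patient enters the cohort at
#' `max(r0, t_ad_obs)` (treatment starts at AD diagnosis) and exits at
#' `min(r0 + study_years, t_cens, t_ctcl_obs)`; only patients with strictly
#' positive at-risk time are included.  The event indicator is 1 when the
#' CTCL diagnosis terminates follow-up (ties with the window end or death
#' count as events).
#'
#' @param pop A [simulate_population()] result.
#' @param params The [scenario_parameters()] the population was simulated
#'   under.
#' @param seed Integer seed for the inclusion-age draws.
#' @return A data frame of class `cohort` with columns `id`, `r0`,
#'   `treat_start`, `entry_age`, `exit_age`, `event`, `switch_age`.
#' @export
build_cohort <- function(pop, params, seed) {
  stopifnot(inherits(params, "scenario_parameters"))
  set.seed(as.integer(seed))
  r0 <- stats::runif(nrow(pop), 0, params$inclusion_age_max)
  window_end <- r0 + params$study_years
  treat_start <- pop$t_ad_obs
  exit_age <- pmin(window_end, pop$t_cens, pop$t_ctcl_obs)
  entry_age <- pmax(r0, treat_start)
  keep <- entry_age < exit_age
  if (!any(keep))
    stop("empty cohort: no patient is diagnosed with AD during an ",
         "administrative window", call. = FALSE)
  event <- as.integer(pop$t_ctcl_obs <= pmin(window_end, pop$t_cens))
  out <- data.frame(id = pop$id[keep],
                    r0 = r0[keep],
                    treat_start = treat_start[keep],
                    entry_age = entry_age[keep],
                    exit_age = exit_age[keep],
                    event = event[keep],
                    switch_age = pop$t_tacro[keep])
  class(out) <- c("cohort", "data.frame")
  out
}

#' Expand a cohort into counting-process form
#'
#' Rewrites each cohort record on the time-since-treatment-initiation scale
#' as one or two half-open `(start, stop]` intervals with an ever-use
#' exposure flag: person-time before the tacrolimus switch is unexposed
#' (`exposed = 0`, first-line/TCS), person-time from the switch onward is
#' exposed (`exposed = 1`) with no return.  A switch at or before study
#' entry yields a single fully exposed row; a switch at or after exit (or
#' never) yields a single unexposed row.  The event flag sits on the last
#' row of an event patient.
#'
#' @param cohort A [build_cohort()] result.
#' @return A data frame with columns `id`, `start`, `stop`, `exposed`,
#'   `event`, ordered by `id` then `start`.
#' @export
expand_counting_process <- function(cohort) {
  ts <- cohort$treat_start
  start0 <- cohort$entry_age - ts
  stop0 <- cohort$exit_age - ts
  sw <- cohort$switch_age - ts

  pre <- sw <= start0                  # exposed for the whole record
  post <- sw >= stop0                  # never exposed during the record
  split <- !pre & !post                # two rows, split at the switch

  one <- !split
  rows1 <- data.frame(id = cohort$id[one],
                      start = start0[one], stop = stop0[one],
                      exposed = as.integer(pre[one]),
                      event = cohort$event[one])
  nsp <- sum(split)
  rows2a <- data.frame(id = cohort$id[split],
                       start = start0[split], stop = sw[split],
                       exposed = rep.int(0L, nsp), event = rep.int(0L, nsp))
  rows2b <- data.frame(id = cohort$id[split],
                       start = sw[split], stop = stop0[split],
                       exposed = rep.int(1L, nsp),
                       event = cohort$event[split])
  out <- rbind(rows1, rows2a, rows2b)
  out <- out[order(out$id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write counting-process rows as a tab-separated file
#'
#' The de-facto standard start/stop survival layout
#' `(id, start, stop, exposed, event)`.
#'
#' @param rows An [expand_counting_process()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counting_process <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
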