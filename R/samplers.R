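# Elementary samplers and deterministic resolvers for the latent event
# times.  All samplers are inverse-transform maps of uniform draws, so the
# whole simulation is a deterministic function of the random stream and the
# closed-form CDFs double as test oracles.
#
# All functions are vectorized over their draw arguments.

#' Sample age at atopic-dermatitis onset
#'
#' Deterministic transform of three uniform draws: `u_case` decides whether
#' the patient ever develops AD, `u_comp` picks the childhood or adult-onset
#' mixture component, and `u_time` is inverted through the component CDF.
#' Non-cases are mapped to the "never" sentinel.
#'
#' @param u_case,u_comp,u_time Uniform(0,1) draws (vectors of equal length).
#' @param calib An [ad_onset_calibration()] object.
#' @return Onset ages in years; `never_age()` for non-cases.
#' @export
sample_ad_onset <- function(u_case, u_comp, u_time,
                            calib = ad_onset_calibration()) {
  .check_unit_open(u_case, "u_case")
  .check_unit_open(u_comp, "u_comp")
  .check_unit_open(u_time, "u_time")
  lo <- calib$adult_onset_range[1]
  hi <- calib$adult_onset_range[2]
  out <- rep.int(.never, length(u_case))
  case <- u_case < calib$case_fraction
  child <- which(case & u_comp < calib$childhood_weight)
  adult <- which(case & u_comp >= calib$childhood_weight)
  out[child] <- -calib$childhood_mean_years * log(u_time[child])
  out[adult] <- lo + u_time[adult] * (hi - lo)
  out
}

#' Sample age at CTCL onset
#'
#' Inverse-CDF draw from the exponential law of a constant incidence rate:
#' `-log(u) / lambda_ctcl`.  With the default rate of 6 per million
#' person-years almost all onsets fall far beyond a human lifespan.
#'
#' @param u Uniform(0,1] draws; `u = 0` is rejected (infinite time).
#' @param lambda_ctcl Onset rate per person-year.
#' @return Onset ages in years.
#' @export
sample_ctcl_onset <- function(u, lambda_ctcl = 6e-6) {
  if (min(u) <= 0 || max(u) > 1) stop("'u' must lie in (0, 1]", call. = FALSE)
  stopifnot(lambda_ctcl > 0)
  -log(u) / lambda_ctcl
}

#' Sample age at death/censoring
#'
#' The censoring age is `(1 - u^2) * 100`, a left-skewed law on \[0, 100\]
#' years with mean 200/3 that mimics general-population mortality in the
#' source registries.
#'
#' @param u Uniform\[0,1\] draws.
#' @return Censoring ages in years, in \[0, 100\].
#' @export
sample_censoring_age <- function(u) {
  if (min(u) < 0 || max(u) > 1) stop("'u' must lie in [0, 1]", call. = FALSE)
  (1 - u^2) * 100
}

#' Resolve the age at (possibly incorrect) AD diagnosis
#'
#' A patient whose AD onset precedes CTCL onset is diagnosed with AD at AD
#' onset.  When CTCL comes first, the patient is either correctly diagnosed
#' (indicator `q = 1`, AD diagnosis at the true AD onset) or misdiagnosed
#' with AD at the CTCL onset age (`q = 0`).
#'
#' @param t_ad,t_ctcl True onset ages (years).
#' @param q 0/1 indicator of a correct initial CTCL diagnosis.
#' @return Age at AD diagnosis in years.
#' @export
resolve_ad_diagnosis <- function(t_ad, t_ctcl, q) {
  stopifnot(all(t_ad >= 0), all(t_ctcl >= 0), all(q %in% c(0, 1)))
  ifelse(t_ad < t_ctcl, t_ad, q * t_ad + (1 - q) * t_ctcl)
}

#' Identify the misdiagnosis pathway
#'
#' TRUE when the CTCL onset strictly precedes AD onset and the initial
#' diagnosis was wrong; exact ties resolve to the AD-first branch.
#'
#' @inheritParams resolve_ad_diagnosis
#' @return Logical vector.
#' @export
is_misdiagnosed <- function(t_ad, t_ctcl, q) {
  t_ctcl < t_ad & q == 0
}

#' Sample the TCS-initiation-to-nonresponse duration
#'
#' Mixture of a short component `1 - u4^2` (strictly below one year, weight
#' `p_short_switch`) and a shifted exponential `e1 + shift` (at or above one
#' year).  `w = 1` marks membership of the long-duration component.
#'
#' @param w 0/1 indicator of the long-duration component.
#' @param u4 Uniform\[0,1\] draws feeding the short component.
#' @param e1 Exponential draws (rate `rate_long_switch`) feeding the long
#'   component.
#' @param shift Shift (years) of the long component.
#' @return Durations in years.
#' @export
sample_tcs_nonresponse_duration <- function(w, u4, e1, shift = 1) {
  stopifnot(all(w %in% c(0, 1)), all(u4 >= 0 & u4 <= 1), all(e1 >= 0))
  ifelse(w == 1, e1 + shift, 1 - u4^2)
}

#' Sample the diagnostic re-evaluation delay
#'
#' The delay between AD (mis)diagnosis and the corrected CTCL diagnosis is
#' the maximum of `n` independent Weibull(shape `kappa`, scale `lambda`)
#' draws, each obtained by inverse transform `lambda * (-log(1 - u))^(1/kappa)`.
#'
#' @param u_draws Uniform\[0,1) draws: a vector of length `n` (one patient)
#'   or a matrix with one row per patient and `n` columns.
#' @param lambda_reeval Weibull scale in years.
#' @param kappa_reeval Weibull shape.
#' @return Delay in years (one value per patient).
#' @export
sample_reevaluation_delay <- function(u_draws, lambda_reeval,
                                      kappa_reeval = 0.9) {
  stopifnot(all(u_draws >= 0 & u_draws < 1), lambda_reeval > 0,
            kappa_reeval > 0)
  x <- lambda_reeval * (-log(1 - u_draws))^(1 / kappa_reeval)
  if (is.matrix(x)) apply(x, 1L, max) else max(x)
}

#' Quantiles of the max-of-n Weibull re-evaluation delay
#'
#' Closed form: the maximum of `n` i.i.d. draws has CDF `F(t)^n`, so the
#' `p`-quantile is `lambda * (-log(1 - p^(1/n)))^(1/kappa)`.  The default
#' median (`lambda = 3.5`, `kappa = 0.9`, `n = 2`) is 4.40 years.
#'
#' @param p Probabilities.
#' @param lambda_reeval,kappa_reeval Weibull scale and shape.
#' @param n_draws Number of draws maximised over.
#' @return Quantiles in years.
#' @export
reevaluation_delay_quantile <- function(p, lambda_reeval = 3.5,
                                        kappa_reeval = 0.9, n_draws = 2L) {
  stopifnot(all(p >= 0 & p <= 1))
  lambda_reeval * (-log(1 - p^(1 / n_draws)))^(1 / kappa_reeval)
}

#' Resolve treatment initiation and switch times
#'
#' First-line assignment: with indicator `s = 1` the patient starts TCS at
#' AD diagnosis, otherwise tacrolimus.  TCS starters switch to tacrolimus
#' after the nonresponse duration `s1` if their pathway-specific switch
#' indicator fires (`p_switch` on the true-AD pathway, `r_switch` on the
#' misdiagnosis pathway); non-switchers keep the censoring age as their
#' never-reached tacrolimus time.
#'
#' @param t_ad_obs Age at AD diagnosis.
#' @param t_ad,t_ctcl True onset ages.
#' @param t_cens Censoring age.
#' @param s 0/1 indicator of TCS as first-line treatment.
#' @param p_switch,r_switch 0/1 switch indicators for the true-AD and
#'   misdiagnosed pathways.
#' @param s1 Nonresponse duration in years.
#' @param q 0/1 indicator of a correct initial CTCL diagnosis (used to
#'   identify the pathway).
#' @return A list with components `t_tcs`, `t_tacro1`, `t_tacro`.
#' @export
resolve_treatment_times <- function(t_ad_obs, t_ad, t_ctcl, t_cens,
                                    s, p_switch, r_switch, s1, q) {
  stopifnot(all(s %in% c(0, 1)), all(p_switch %in% c(0, 1)),
            all(r_switch %in% c(0, 1)))
  t_tcs <- ifelse(s == 1, t_ad_obs, t_cens)
  t_tacro1 <- ifelse(s == 0, t_ad_obs, t_cens)
  misdx <- is_misdiagnosed(t_ad, t_ctcl, q)
  switch_ind <- ifelse(misdx, r_switch, p_switch)
  t_tacro <- ifelse(s == 0, t_tacro1,
                    ifelse(switch_ind == 1, t_tcs + s1, t_cens))
  list(t_tcs = t_tcs, t_tacro1 = t_tacro1, t_tacro = t_tacro)
}

#' Resolve the age at CTCL diagnosis
#'
#' Patients on the misdiagnosis pathway receive the correct diagnosis a
#' re-evaluation delay `s2` after their (incorrect) AD diagnosis; everyone
#' else is diagnosed at the true CTCL onset.
#'
#' @inheritParams resolve_treatment_times
#' @param s2 Re-evaluation delay in years.
#' @return Age at CTCL diagnosis in years.
#' @export
resolve_ctcl_diagnosis <- function(t_ad_obs, t_ad, t_ctcl, s2, q) {
  misdx <- is_misdiagnosed(t_ad, t_ctcl, q)
  ifelse(misdx, t_ad_obs + s2, t_ctcl)
}

#' Sentinel age for events that never occur
#'
#' Strictly greater than any attainable study age
#' (`inclusion_age_max + study_years`).
#'
#' @return A single numeric.
#' @export
never_age <- function() .never

.check_unit_open <- function(u, name) {
  if (min(u) <= 0 || max(u) >= 1)
    stop(sprintf("'%s' must lie strictly in (0, 1)", name), call. = FALSE)
  invisible(u)
}
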