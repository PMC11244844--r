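# Shared fixtures: desk-scale parameter sets and a brute-force partial
# likelihood used as an independent oracle for the Cox fit.

# Small-population variant of a built-in setting for fast replicate runs.
desk_setting <- function(id = "A1", base_population = 4e5, ...) {
  builtin_setting(id, base_population = base_population, ...)
}

# Independent evaluation of the Breslow partial log-likelihood: O(n^2)
# risk-set construction by explicit comparison, no shared code with the
# package's findInterval-based fitter.
brute_partial_loglik <- function(rows, beta) {
  ev <- which(rows$event == 1L)
  vapply(beta, function(b) {
    ll <- 0
    for (i in ev) {
      t_i <- rows$stop[i]
      at_risk <- rows$start < t_i & rows$stop >= t_i
      ll <- ll + b * rows$exposed[i] -
        log(sum(exp(b * rows$exposed[at_risk])))
    }
    ll
  }, numeric(1))
}

# Golden-section maximisation of the brute-force likelihood over
# log HR in [-5, 5].
brute_cox_mle <- function(rows) {
  stats::optimize(function(b) brute_partial_loglik(rows, b),
                  interval = c(-5, 5), maximum = TRUE,
                  tol = 1e-9)$maximum
}

# Random small counting-process dataset with both exposure levels.
random_cp_data <- function(n_patients = 12) {
  repeat {
    entry <- stats::runif(n_patients, 0, 2)
    exit <- entry + stats::runif(n_patients, 0.2, 4)
    sw <- ifelse(stats::runif(n_patients) < 0.5, Inf,
                 stats::runif(n_patients, 0, 5))
    event <- stats::rbinom(n_patients, 1L, 0.5)
    cohort <- data.frame(id = seq_len(n_patients), r0 = entry,
                         treat_start = 0, entry_age = entry,
                         exit_age = exit, event = event, switch_age = sw)
    rows <- expand_counting_process(cohort)
    ev <- rows$event == 1L
    if (sum(ev) >= 2L && length(unique(rows$exposed)) == 2L &&
        length(unique(rows$exposed[ev])) == 2L)
      return(rows)
  }
}

# Kolmogorov-Smirnov distance between a sample and a closed-form CDF.
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}
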