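# Cox partial-likelihood fitter and person-time incidence rates.

toy_rows <- data.frame(id = 1:3, start = 0, stop = c(1, 2, 3),
                       exposed = c(1L, 0L, 1L), event = c(1L, 1L, 0L))

test_that("toy dataset solves the score equation in closed form", {
  # risk sets: at t=1 {1,1,0}, at t=2 {0,1}; score = 0 gives hr = 1/sqrt(2)
  fit <- fit_cox_td(toy_rows)
  expect_true(fit$converged)
  expect_equal(fit$hr, 1 / sqrt(2), tolerance = 1e-8)
  expect_equal(fit$log_hr, -0.5 * log(2), tolerance = 1e-8)
  expect_equal(fit$n_events, 2L)
  expect_lt(fit$ci_low, fit$hr); expect_gt(fit$ci_high, fit$hr)
  # grid confirmation over log HR in [-5, 5]
  grid <- seq(-5, 5, by = 1e-4)
  expect_equal(grid[which.max(cox_partial_loglik(toy_rows, grid))],
               fit$log_hr, tolerance = 1e-3)
})

test_that("degenerate inputs are rejected or flagged, not mis-fit", {
  no_var <- transform(toy_rows, exposed = 0L)
  expect_error(fit_cox_td(no_var), "no variation")
  no_events <- transform(toy_rows, event = 0L)
  expect_error(fit_cox_td(no_events), "no events")
  # monotone separation: the only event is exposed while an unexposed
  # patient shares the risk set, so the likelihood increases without bound
  sep <- data.frame(id = 1:2, start = 0, stop = c(1, 2),
                    exposed = c(1L, 0L), event = c(1L, 0L))
  fit <- fit_cox_td(sep)
  expect_false(fit$converged)
  # single-group risk sets carry no information: flagged, not "converged"
  degen <- data.frame(id = 1:2, start = 0, stop = c(1, 0.5),
                      exposed = c(1L, 0L), event = c(1L, 0L))
  expect_false(fit_cox_td(degen)$converged)
})

test_that("partial likelihood is invariant to cohort duplication and time shifts", {
  fit <- fit_cox_td(toy_rows)
  dup <- rbind(toy_rows, transform(toy_rows, id = id + 10L))
  expect_equal(fit_cox_td(dup)$log_hr, fit$log_hr, tolerance = 1e-8)
  shifted <- transform(toy_rows, start = start + 5, stop = stop + 5)
  expect_equal(fit_cox_td(shifted)$log_hr, fit$log_hr, tolerance = 1e-10)
  scaled <- transform(toy_rows, start = start * 3.7, stop = stop * 3.7)
  expect_equal(fit_cox_td(scaled)$log_hr, fit$log_hr, tolerance = 1e-10)
})

test_that("fitter matches brute-force maximisation on random small datasets", {
  set.seed(4242)
  for (i in 1:100) {
    rows <- random_cp_data(sample(6:20, 1))
    fit <- fit_cox_td(rows)
    if (!fit$converged) next
    expect_equal(fit$log_hr, brute_cox_mle(rows), tolerance = 1e-4,
                 info = paste("dataset", i))
    # the fitter's objective equals the brute-force objective everywhere
    b <- seq(-2, 2, by = 0.5)
    expect_equal(cox_partial_loglik(rows, b), brute_partial_loglik(rows, b),
                 tolerance = 1e-10, info = paste("loglik", i))
  }
})

test_that("fitter agrees with survival::coxph on start/stop data", {
  skip_if_not_installed("survival")
  set.seed(2024)
  for (i in 1:25) {
    rows <- random_cp_data(sample(8:20, 1))
    fit <- fit_cox_td(rows)
    if (!fit$converged) next
    cph <- survival::coxph(
      survival::Surv(start, stop, event) ~ exposed,
      data = rows, ties = "breslow")
    expect_equal(fit$log_hr, unname(coef(cph)), tolerance = 1e-6)
    expect_equal(fit$se, unname(sqrt(vcov(cph)[1, 1])), tolerance = 1e-6)
  }
})

test_that("incidence rates are the closed-form person-time MLE", {
  rows <- data.frame(id = 1:4, start = 0, stop = c(10000, 10000, 5000, 5000),
                     exposed = c(0L, 0L, 1L, 1L), event = c(1L, 1L, 1L, 0L))
  ir <- estimate_incidence(rows)
  expect_equal(ir$rate_per_1000py[ir$group == "TCS"], 1000 * 2 / 20000)
  expect_equal(ir$rate_per_1000py[ir$group == "tacrolimus"],
               1000 * 1 / 10000)
  # zero events give a zero rate
  ir0 <- estimate_incidence(transform(rows, event = 0L))
  expect_equal(ir0$rate_per_1000py, c(0, 0))
  # a missing exposure group is dropped with a warning
  expect_warning(estimate_incidence(rows[rows$exposed == 0L, ]),
                 "omitted")
  # identity with the Poisson-offset GLM estimate
  agg <- data.frame(events = c(2, 1), py = c(20000, 10000), x = c(0, 1))
  glm_fit <- glm(events ~ x + offset(log(py)), family = poisson, data = agg)
  expect_equal(ir$rate_per_1000py,
               1000 * exp(predict(glm_fit,
                                  newdata = transform(agg, py = 1))),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Wald significance follows the normal quantile arithmetic", {
  fit <- fit_cox_td(toy_rows)
  mk <- function(log_hr, se) {
    f <- fit; f$log_hr <- log_hr; f$se <- se
    f$p_value <- 2 * pnorm(-abs(log_hr / se)); f
  }
  expect_equal(wald_significance(mk(1.0, 0.4), 0.05), 1L)   # z = 2.5
  expect_equal(wald_significance(mk(0.5, 0.5), 0.05), 0L)   # z = 1.0
  expect_equal(wald_significance(mk(0, 0.5), 0.2), 0L)
  nc <- fit; nc$converged <- FALSE
  expect_true(is.na(wald_significance(nc)))
})
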