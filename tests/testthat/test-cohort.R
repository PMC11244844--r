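# Cohort emulation and counting-process expansion.

# Minimal latent population with just the columns the cohort builder uses.
mini_pop <- function(t_ad_obs, t_cens, t_ctcl_obs, t_tacro) {
  n <- length(t_ad_obs)
  data.frame(id = seq_len(n), t_ad_obs = t_ad_obs, t_cens = t_cens,
             t_ctcl_obs = t_ctcl_obs, t_tacro = t_tacro)
}

# build_cohort draws r0 itself; for hand traces we bypass the draw by
# reconstructing the record arithmetic directly.
trace_record <- function(r0, t_ad_obs, t_cens, t_ctcl_obs, study_years = 12) {
  entry <- max(r0, t_ad_obs)
  exit <- min(r0 + study_years, t_cens, t_ctcl_obs)
  list(entry = entry, exit = exit, included = entry < exit,
       event = t_ctcl_obs <= min(r0 + study_years, t_cens))
}

test_that("cohort records follow the window/entry/exit hand traces", {
  # censored well before the window ends
  tr <- trace_record(r0 = 40, t_ad_obs = 30, t_cens = 80,
                     t_ctcl_obs = never_age())
  expect_equal(tr$entry, 40); expect_equal(tr$exit, 52)
  expect_true(tr$included); expect_false(tr$event)

  # the misdiagnosis worked example: dx at 50, corrected at 54.4
  tr <- trace_record(r0 = 45, t_ad_obs = 50, t_cens = 80, t_ctcl_obs = 54.4)
  expect_equal(tr$entry, 50); expect_equal(tr$exit, 54.4)
  expect_true(tr$included); expect_true(tr$event)

  # diagnosed after the window closes: excluded
  tr <- trace_record(r0 = 45, t_ad_obs = 58, t_cens = 80,
                     t_ctcl_obs = never_age())
  expect_false(tr$included)

  # the builder reproduces the same arithmetic with its own r0 draws
  p <- builtin_setting("A1")
  pop <- mini_pop(t_ad_obs = c(30, 50, 1e9), t_cens = c(80, 80, 80),
                  t_ctcl_obs = c(1e9, 54.4, 1e9), t_tacro = c(80, 52, 80))
  coh <- build_cohort(pop, p, seed = 1)
  expect_true(all(coh$entry_age == pmax(coh$r0, coh$treat_start)))
  expect_true(all(coh$entry_age < coh$exit_age))
  expect_false(3 %in% coh$id)  # never diagnosed, never included
})

test_that("event patients exit at their CTCL diagnosis", {
  p <- desk_setting("A1", base_population = 2e5)
  pop <- simulate_population(p, seed = 606)
  coh <- build_cohort(pop, p, seed = 607)
  ev <- coh$event == 1L
  idx <- match(coh$id, pop$id)
  expect_true(all(coh$exit_age[ev] == pop$t_ctcl_obs[idx][ev]))
  expect_true(all(coh$exit_age <= pop$t_cens[idx]))
  # every event is consistent with a within-lifetime CTCL diagnosis
  expect_true(all(pop$t_ctcl_obs[idx][ev] <= pop$t_cens[idx][ev]))
  # cohort is a subset of the population with positive at-risk time
  expect_true(all(coh$id %in% pop$id))
  expect_true(all(coh$treat_start <= coh$entry_age))
})

test_that("correctly diagnosed CTCL-first patients contribute no cohort time", {
  p <- desk_setting("A1", base_population = 3e5)
  pop <- simulate_population(p, seed = 708)
  coh <- build_cohort(pop, p, seed = 709)
  ctcl_first_correct <- pop$id[pop$t_ctcl < pop$t_ad & pop$q == 1]
  expect_false(any(ctcl_first_correct %in% coh$id))
})

test_that("counting-process expansion splits at the switch and conserves person-time", {
  cohort <- data.frame(id = 1:3,
                       r0 = c(45, 40, 40),
                       treat_start = c(50, 30, 30),
                       entry_age = c(50, 40, 40),
                       exit_age = c(54.4, 52, 52),
                       event = c(1L, 0L, 0L),
                       switch_age = c(52, never_age(), 35))
  rows <- expand_counting_process(cohort)

  r1 <- rows[rows$id == 1, ]  # switch inside follow-up: split at 2y
  expect_equal(r1$start, c(0, 2))
  expect_equal(r1$stop, c(2, 4.4))
  expect_equal(r1$exposed, c(0L, 1L))
  expect_equal(r1$event, c(0L, 1L))

  r2 <- rows[rows$id == 2, ]  # never switches: one unexposed row
  expect_equal(nrow(r2), 1L)
  expect_equal(c(r2$start, r2$stop, r2$exposed), c(10, 22, 0))

  r3 <- rows[rows$id == 3, ]  # switched before entry: ever-use carries in
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$exposed, 1L)
})

test_that("counting-process invariants hold on simulated cohorts", {
  p <- desk_setting("B1", base_population = 2e5)
  pop <- simulate_population(p, seed = 808)
  coh <- build_cohort(pop, p, seed = 809)
  rows <- expand_counting_process(coh)

  expect_true(all(rows$stop > rows$start))
  # exact person-time conservation per patient
  py <- tapply(rows$stop - rows$start, rows$id, sum)
  target <- (coh$exit_age - coh$entry_age)[match(names(py), coh$id)]
  expect_equal(as.numeric(py), as.numeric(target))
  # exposure is non-decreasing and rows contiguous within patient
  by_id <- split(rows, rows$id)
  multi <- by_id[vapply(by_id, nrow, 1L) > 1L]
  expect_true(all(vapply(multi, function(d) {
    all(diff(d$exposed) >= 0) && all(d$start[-1] == d$stop[-nrow(d)])
  }, logical(1))))
  # at most one event row per patient, always the last
  expect_true(all(vapply(by_id, function(d) {
    sum(d$event) <= 1L && (sum(d$event) == 0L || d$event[nrow(d)] == 1L)
  }, logical(1))))
  # no exposed person-time after CTCL diagnosis can exist by construction:
  # every row stops at or before the diagnosis age
  idx <- match(coh$id, pop$id)
  expect_true(all(coh$exit_age <= pop$t_ctcl_obs[idx]))
})
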