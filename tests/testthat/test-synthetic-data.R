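# The generator: determinism, degenerate hazards, condition age
# profiles, and the behaviour of the planted selection mechanism.

test_that("cohort generation is reproducible given the seed", {
  cfg <- cohort_config(2000, condition_profiles = copd_profile(),
                       seed = 11L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))

  co <- small_cohort()
  s1 <- generate_trial_suite(co, "copd", selection_model(),
                             n_trials = 2, n_per_trial = 100, seed = 5L)
  s2 <- generate_trial_suite(co, "copd", selection_model(),
                             n_trials = 2, n_per_trial = 100, seed = 5L)
  expect_identical(s1$summaries, s2$summaries)
  expect_identical(s1$ipd, s2$ipd)
})

test_that("a zero baseline rate yields zero events for everyone", {
  cfg <- cohort_config(500, condition_profiles = copd_profile(),
                       baseline_rate = 0, seed = 3L)
  co <- generate_cohort(cfg)
  expect_true(all(co$event == 0L))
  expect_true(all(co$time_at_risk == cfg$observation_days))
})

test_that("condition age profiles are respected (COPD: 69.1, sd 11.6)", {
  cfg <- cohort_config(10000, condition_profiles = copd_profile(),
                       seed = 77L)
  co <- generate_cohort(cfg)
  expect_lt(abs(mean(co$age) - 69.1), 0.5)
  expect_lt(abs(sd(co$age) - 11.6), 0.6)
  expect_true(all(co$age >= 18 & co$age <= 100))
})

test_that("cohort invariants hold: event days within risk windows", {
  co <- small_cohort()
  ev <- co[co$event == 1L, ]
  expect_true(all(ev$event_day >= 0 & ev$event_day <= ev$time_at_risk))
  expect_true(all(co$time_at_risk <=
                    attr(co, "config")$observation_days))
})

test_that("configuration validation rejects bad inputs", {
  p <- copd_profile()
  expect_error(cohort_config(0, condition_profiles = p), "positive")
  p2 <- p; p2$prevalence <- 1.5
  expect_error(cohort_config(10, condition_profiles = p2), "prevalence")
  expect_error(cohort_config(10, condition_profiles = p,
                             observation_days = 0), "observation_days")
  expect_error(selection_model(rate_multiplier = 0), "positive")
  expect_error(selection_model(age_lower = 80, age_upper = 60),
               "age_lower")
})

test_that("null selection gives an unbiased subsample of eligibles", {
  co <- small_cohort()
  suite <- generate_trial_suite(co, "copd", selection_model(),
                                n_trials = 10, n_per_trial = 500,
                                seed = 9L)
  ages <- unlist(lapply(suite$ipd, function(d) d$age))
  se <- sd(co$age) / sqrt(length(ages))  # ignores overlap; conservative x3
  expect_lt(abs(mean(ages) - mean(co$age)), 3 * se + 0.2)
  mms <- unlist(lapply(suite$ipd, function(d) d$mm_count))
  expect_lt(abs(mean(mms) - mean(co$mm_count)),
            3 * sd(co$mm_count) / sqrt(length(mms)) + 0.05)
})

test_that("a negative multimorbidity penalty under-samples multimorbidity", {
  co <- small_cohort()
  suite <- generate_trial_suite(co, "copd",
                                selection_model(mm_penalty = -0.5),
                                n_trials = 2, n_per_trial = 1000,
                                seed = 13L)
  mms <- unlist(lapply(suite$ipd, function(d) d$mm_count))
  expect_lt(mean(mms), mean(co$mm_count) -
              2 * sd(co$mm_count) / sqrt(length(mms)))
})

test_that("age-bounded selection respects the bounds and can exclude everyone", {
  co <- small_cohort()
  suite <- generate_trial_suite(co, "copd",
                                selection_model(age_lower = 40,
                                                age_upper = 75),
                                n_trials = 2, n_per_trial = 200,
                                seed = 21L)
  ages <- unlist(lapply(suite$ipd, function(d) d$age))
  expect_true(all(ages >= 40 & ages <= 75))
  expect_error(
    generate_trial_suite(co, "copd",
                         selection_model(age_lower = 101,
                                         age_upper = 110,
                                         label = "impossible"),
                         n_trials = 1, n_per_trial = 10),
    "excludes everyone")
})

test_that("null-selection trial event rates match the cohort hazard", {
  co <- small_cohort()
  suite <- generate_trial_suite(co, "copd", selection_model(),
                                n_trials = 10, n_per_trial = 500,
                                followup_days = 182, seed = 31L)
  obs <- sum(suite$summaries$sae_count)
  # independent truth: per-participant event probability under the
  # generator's exponential hazard
  p <- unlist(lapply(suite$ipd, function(d) {
    hz <- co$true_hazard[match(d$id, co$id)]
    1 - exp(-hz * 182)
  }))
  expect_lt(abs(obs - sum(p)), 3 * sqrt(sum(p * (1 - p))))
})

test_that("the planted rate multiplier scales trial event counts", {
  co <- small_cohort()
  base <- generate_trial_suite(co, "copd", selection_model(),
                               n_trials = 6, n_per_trial = 500,
                               seed = 41L)
  half <- generate_trial_suite(co, "copd",
                               selection_model(rate_multiplier = 0.5),
                               n_trials = 6, n_per_trial = 500,
                               seed = 41L)
  expect_lt(sum(half$summaries$sae_count),
            0.75 * sum(base$summaries$sae_count))
})
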