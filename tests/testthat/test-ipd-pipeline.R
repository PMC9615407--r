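# IPD analyses: the per-sex event filter, association recovery, the
# arm-interaction check, and the paired dual standardization.

make_ipd <- function(n, sex_prob = 0.5, mm_coef = 0.2, base = 2e-3,
                     arm_rr = 1, inter = 0, seed = 1) {
  set.seed(seed)
  age <- round(runif(n, 50, 85))
  sex <- ifelse(runif(n) < sex_prob, "female", "male")
  mm <- rpois(n, 2)
  arm <- sample(rep(c("treatment", "control"), length.out = n))
  trt <- arm == "treatment"
  rate <- base * exp(mm_coef * mm + 0.02 * (age - 65)) *
    ifelse(trt, arm_rr * exp(inter * mm), 1)
  tev <- rexp(n, rate)
  data.frame(trial_id = "sim", condition = "copd", age = age, sex = sex,
             arm = arm, mm_count = mm,
             followup_days = pmin(tev, 182),
             sae_count = as.integer(tev <= 182))
}

test_that("the >= 20 SAEs filter applies per sex, not per trial", {
  set.seed(42)
  # construct a trial with ~19 male events and ample female events
  male <- make_ipd(2000, sex_prob = 0, seed = 5)
  male <- male[c(which(male$sae_count == 1)[1:19],
                 which(male$sae_count == 0)[1:300]), ]
  female <- make_ipd(1500, sex_prob = 1, seed = 6)
  trial <- rbind(male, female)
  expect_message(am <- mm_sae_association(trial, "male"), "excluded")
  expect_null(am)
  af <- mm_sae_association(trial, "female")
  expect_s3_class(af, "mm_association")
  expect_gte(af$n_events, 20)
  # exactly 20 events qualifies
  male20 <- rbind(male, male[male$sae_count == 1, ][1, ])
  expect_s3_class(mm_sae_association(rbind(male20, female), "male",
                                     min_events = 20),
                  "mm_association")
})

test_that("a constant multimorbidity count is skipped as inestimable", {
  d <- make_ipd(2000, seed = 7)
  d$mm_count <- 3L
  expect_message(a <- mm_sae_association(d, "female"), "inestimable")
  expect_null(a)
})

test_that("the multimorbidity coefficient is recovered across trials", {
  tabs <- mm_association_table(
    lapply(1:10, function(i) make_ipd(1200, mm_coef = 0.2, seed = 100 + i)))
  expect_gt(nrow(tabs), 10)
  for (sx in c("male", "female")) {
    d <- tabs[tabs$sex == sx, ]
    m <- meta_analyze(d$coef, d$se)
    expect_lt(abs(m$pooled - 0.2), 2 * m$se + 0.02)
  }
})

test_that("rate ratio curves follow the pooled coefficient", {
  cur <- rate_ratio_curve(log(1.2), 0.05, c(0, 4))
  expect_equal(cur$rr[cur$mm == 0], 1)
  expect_equal(cur$rr[cur$mm == 2], 1.44)
  expect_true(all(cur$lower <= cur$rr & cur$rr <= cur$upper))
  # delta-method band vs Monte-Carlo propagation of the coefficient
  set.seed(3)
  draws <- rnorm(2e5, log(1.2), 0.05)
  mc <- quantile(exp(draws * 3), c(0.025, 0.975))
  expect_lt(abs(cur$lower[cur$mm == 3] - mc[[1]]) / mc[[1]], 0.01)
  expect_lt(abs(cur$upper[cur$mm == 3] - mc[[2]]) / mc[[2]], 0.01)
})

test_that("no arm effect and no interaction pool to the null", {
  res <- mm_treatment_interaction(
    lapply(1:8, function(i) make_ipd(1000, seed = 200 + i)))
  expect_lt(res$interaction$lower, 0)
  expect_gt(res$interaction$upper, 0)
  for (sx in c("male", "female")) {
    ae <- res$arm_effects[[sx]]
    expect_lt(ae$lower, 0); expect_gt(ae$upper, 0)
  }
})

test_that("an arm effect is recovered while the interaction stays null", {
  res <- mm_treatment_interaction(
    lapply(1:8, function(i) make_ipd(1500, arm_rr = 0.7,
                                     seed = 300 + i)))
  pooled_arm <- meta_analyze(
    c(res$arm_effects$male$pooled, res$arm_effects$female$pooled),
    c(res$arm_effects$male$se, res$arm_effects$female$se))
  expect_lt(abs(pooled_arm$pooled - log(0.7)), 2 * pooled_arm$se + 0.05)
  expect_lt(abs(res$interaction$pooled), 0.05)
})

test_that("single-arm trials are skipped with a reason", {
  d <- make_ipd(500, seed = 9)
  d$arm <- "treatment"
  res <- mm_treatment_interaction(list(d))
  expect_null(res$interaction)
  expect_true(any(grepl("single arm", res$skipped$reason)))
})

test_that("dual standardization is a no-op for representative trials", {
  co <- small_cohort()
  models <- small_models()
  models_mm <- list(
    male = fit_rate_model(co, "copd", "male", c("age", "mm_count"),
                          age_powers = 1, mm_powers = 1),
    female = fit_rate_model(co, "copd", "female", c("age", "mm_count"),
                            age_powers = 1, mm_powers = 1))
  suite <- generate_trial_suite(co, "copd", selection_model(),
                                n_trials = 1, n_per_trial = 2000,
                                seed = 51L)
  ds <- dual_standardization(suite$ipd[[1]], models, models_mm,
                             n_draws = 2000, seed = 5L)
  expect_lt(abs(ds$shift), 0.08)
})

test_that("multimorbidity-biased selection shifts the ratio upward", {
  co <- small_cohort()
  models <- small_models()
  models_mm <- list(
    male = fit_rate_model(co, "copd", "male", c("age", "mm_count"),
                          age_powers = 1, mm_powers = 1),
    female = fit_rate_model(co, "copd", "female", c("age", "mm_count"),
                            age_powers = 1, mm_powers = 1))
  suite <- generate_trial_suite(co, "copd",
                                selection_model(mm_penalty = -0.7),
                                n_trials = 1, n_per_trial = 2000,
                                seed = 53L)
  ds <- dual_standardization(suite$ipd[[1]], models, models_mm,
                             n_draws = 2000, seed = 7L)
  expect_gt(ds$table$ratio_age_sex_mm, ds$table$ratio_age_sex)
  expect_lt(ds$table$ratio_age_sex, 1)
})
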