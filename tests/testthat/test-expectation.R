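# Person-time formula, indirect standardization, and its oracles.

test_that("the aggregate person-time formula and its edge cases", {
  expect_equal(aggregate_person_time(100, 182, 0), 18200)
  expect_equal(aggregate_person_time(100, 182, 10), 17290)
  expect_equal(aggregate_person_time(100, 182, 100), 9100)
  expect_warning(pt <- aggregate_person_time(10, 100, 15),
                 "floored")
  expect_equal(pt, 500)
  expect_error(aggregate_person_time(0, 182, 0), "positive")
  expect_error(aggregate_person_time(100, 182, -1), "nonnegative")
})

make_dist <- function(ages, weights, pct_female = 50, id = "t") {
  structure(list(bands = data.frame(age = ages,
                                    weight = weights / sum(weights)),
                 sex_prop = c(female = pct_female / 100,
                              male = 1 - pct_female / 100),
                 flags = character(0), trial_id = id),
            class = "age_sex_distribution")
}

test_that("a constant-rate model collapses standardization to r x PT", {
  r <- 2e-4
  models <- list(male = make_const_model(r, "male"),
                 female = make_const_model(r, "female"))
  d <- make_dist(50:70, runif(21, 0.5, 2))
  e <- expected_events_aggregate(models, d, n = 300, followup_days = 182,
                                 events = 12)
  pt <- aggregate_person_time(300, 182, 12)
  expect_equal(e$expected, r * pt, tolerance = 1e-12)
  expect_equal(e$person_time_days, pt)
})

test_that("aggregate expectation equals brute-force cell enumeration", {
  models <- small_models()
  co <- small_cohort()
  suite <- generate_trial_suite(co, "copd", selection_model(),
                                n_trials = 1, n_per_trial = 400,
                                seed = 23L)
  s <- suite$summaries[1, ]
  d <- reconstruct_age_distribution(s)
  e <- expected_events_aggregate(models, d, s$n_participants,
                                 s$followup_days, s$sae_count)
  # independent oracle: loop over every (sex, band) cell, full
  # person-time first, then the event deficit spread by expected share
  pt <- aggregate_person_time(s$n_participants, s$followup_days,
                              s$sae_count)
  full_pt <- s$n_participants * s$followup_days
  cells <- list()
  for (sx in c("male", "female")) {
    for (i in seq_len(nrow(d$bands))) {
      cells[[length(cells) + 1L]] <- c(
        rate = predict_rate(models[[sx]], d$bands$age[i] + 0.5),
        pt0 = full_pt * unname(d$sex_prop[sx]) * d$bands$weight[i])
    }
  }
  cells <- do.call(rbind, cells)
  share <- cells[, "rate"] * cells[, "pt0"] /
    sum(cells[, "rate"] * cells[, "pt0"])
  brute <- 0
  for (i in seq_len(nrow(cells))) {
    brute <- brute + cells[i, "rate"] *
      (cells[i, "pt0"] - (full_pt - pt) * share[i])
  }
  expect_equal(e$expected, unname(brute), tolerance = 1e-9)
  expect_equal(e$person_time_days, pt)
})

test_that("zero-weight bands do not change the expectation", {
  models <- small_models()
  d1 <- make_dist(c(60, 61, 62), c(0.5, 0.5, 0))
  d2 <- make_dist(c(60, 61), c(0.5, 0.5))
  e1 <- expected_events_aggregate(models, d1, 200, 182, 5)
  e2 <- expected_events_aggregate(models, d2, 200, 182, 5)
  expect_equal(e1$expected, e2$expected, tolerance = 1e-12)
})

test_that("expected counts are linear: pooled trials add up", {
  models <- small_models()
  co <- small_cohort()
  suite <- generate_trial_suite(co, "copd", selection_model(),
                                n_trials = 2, n_per_trial = 300,
                                seed = 29L)
  e1 <- expected_events_ipd(models, suite$ipd[[1]])
  e2 <- expected_events_ipd(models, suite$ipd[[2]])
  both <- rbind(suite$ipd[[1]], suite$ipd[[2]])
  e12 <- expected_events_ipd(models, both)
  expect_equal(e12$expected, e1$expected + e2$expected,
               tolerance = 1e-9)
})

test_that("IPD expectation is rate x exposure, order-invariant", {
  r <- 3e-4
  models <- list(male = make_const_model(r, "male"),
                 female = make_const_model(r, "female"))
  one <- data.frame(trial_id = "t", age = 64, sex = "male",
                    followup_days = 120, sae_count = 0)
  expect_equal(expected_events_ipd(models, one)$expected, r * 120,
               tolerance = 1e-12)
  co <- small_cohort()
  suite <- generate_trial_suite(co, "copd", selection_model(),
                                n_trials = 1, n_per_trial = 200,
                                seed = 31L)
  ipd <- suite$ipd[[1]]
  perm <- ipd[sample(nrow(ipd)), ]
  m <- small_models()
  expect_equal(expected_events_ipd(m, perm)$expected,
               expected_events_ipd(m, ipd)$expected, tolerance = 1e-12)
})

test_that("draw-based expectations centre on the point value", {
  models <- small_models()
  co <- small_cohort()
  suite <- generate_trial_suite(co, "copd", selection_model(),
                                n_trials = 1, n_per_trial = 300,
                                seed = 37L)
  e <- expected_events_ipd(models, suite$ipd[[1]], n_draws = 10000,
                           seed = 7L)
  mc_se <- sd(e$draws) / sqrt(length(e$draws))
  expect_lt(abs(mean(e$draws) - e$expected),
            2 * mc_se + 0.002 * e$expected)
  # point expectation inside the central 99.9% of the draws
  q <- quantile(e$draws, c(0.0005, 0.9995))
  expect_gt(e$expected, q[1])
  expect_lt(e$expected, q[2])
})

test_that("expectation contracts fail loudly", {
  models <- list(male = small_models()$male)  # no female model
  d <- make_dist(60:65, rep(1, 6), pct_female = 40)
  expect_error(expected_events_aggregate(models, d, 100, 182, 0),
               "female")
  ipd <- data.frame(trial_id = "t", age = 60, sex = "male",
                    followup_days = 100, sae_count = 0)
  expect_error(expected_events_ipd(small_models(), ipd,
                                   basis = "age_sex_mm"), "mm_count")
})
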