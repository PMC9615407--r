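# O/E ratios, random-effects Poisson pooling, arm comparisons and
# meta-analysis, each against an independent oracle where one exists.

test_that("the point ratio is observed over expected", {
  r <- oe_ratio(60, 100, n_draws = 500, seed = 1L)
  expect_equal(r$ratio, 0.60)
  expect_error(oe_ratio(5, 0), "zero")
})

test_that("a large balanced count gives an interval containing 1", {
  e <- saerep:::new_expected_count("t", 400, "age_sex",
                                   rep(400, 5000), 1e5)
  r <- oe_ratio(400, e, n_draws = 5000, seed = 2L)
  expect_lt(r$lower, 1)
  expect_gt(r$upper, 1)
})

test_that("observed = 0 gives ratio 0 with a Jeffreys-driven upper limit", {
  E <- 20
  r <- oe_ratio(0, E, n_draws = 1e6, seed = 3L)
  expect_equal(r$ratio, 0)
  expect_gt(r$upper, 0)
  # closed-form oracle: with degenerate expected draws the sampled ratio
  # is Gamma(0.5, 1) / E, so the interval is a scaled gamma quantile
  expect_lt(abs(r$lower - qgamma(0.025, 0.5) / E), 1e-3)
  expect_lt(abs(r$upper - qgamma(0.975, 0.5) / E), 1e-3)
})

test_that("ratios and pooled ratios are scale-equivariant in expected", {
  O <- c(12, 25, 40, 8)
  E <- c(15, 22, 35, 10)
  p1 <- pool_oe(O, E)
  p2 <- pool_oe(O, 2 * E)
  expect_equal(p2$ratio, p1$ratio / 2, tolerance = 1e-5)
  expect_equal(p2$tau, p1$tau, tolerance = 1e-4)
  r1 <- oe_ratio(10, 20, n_draws = 100, seed = 9L)
  r2 <- oe_ratio(10, 40, n_draws = 100, seed = 9L)
  expect_equal(r2$ratio, r1$ratio / 2)
})

test_that("pooling a single trial passes through its ratio", {
  p <- pool_oe(30, 40, condition = "x")
  expect_equal(p$ratio, 0.75)
  expect_equal(p$tau, 0)
  expect_equal(p$k, 1L)
})

test_that("homogeneous null data pool to 1 with negligible heterogeneity", {
  set.seed(11)
  E <- rep(200, 20)
  O <- rpois(20, E)
  p <- pool_oe(O, E)
  expect_lt(p$lower, 1)
  expect_gt(p$upper, 1)
  expect_lt(p$tau, 0.08)
})

# independent oracle: marginal likelihood via stats::integrate on a
# dense (theta, tau) grid, refined to 1e-3 resolution
grid_marginal_loglik <- function(theta, tau, O, E) {
  sum(vapply(seq_along(O), function(i) {
    if (tau <= 0) return(dpois(O[i], E[i] * exp(theta), log = TRUE))
    f <- function(z) dpois(O[i], E[i] * exp(theta + tau * z)) * dnorm(z)
    log(integrate(f, -10, 10, rel.tol = 1e-10)$value)
  }, numeric(1)))
}

test_that("the marginal-likelihood maximum matches a dense grid search", {
  O <- c(5, 10, 20); E <- c(10, 10, 10)
  p <- pool_oe(O, E)
  coarse_t <- seq(-1.2, 0.8, by = 0.02)
  coarse_s <- seq(0.01, 1.2, by = 0.02)
  ll <- outer(coarse_t, coarse_s,
              Vectorize(function(a, b) grid_marginal_loglik(a, b, O, E)))
  ij <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  t0 <- coarse_t[ij[1]]; s0 <- coarse_s[ij[2]]
  fine_t <- seq(t0 - 0.025, t0 + 0.025, by = 1e-3)
  fine_s <- seq(max(s0 - 0.025, 1e-3), s0 + 0.025, by = 1e-3)
  llf <- outer(fine_t, fine_s,
               Vectorize(function(a, b) grid_marginal_loglik(a, b, O, E)))
  ij <- which(llf == max(llf), arr.ind = TRUE)[1, ]
  expect_lt(abs(p$theta - fine_t[ij[1]]), 2e-3)
  expect_lt(abs(p$tau - fine_s[ij[2]]), 2e-3)
  expect_lt(abs(p$loglik - max(llf)), 1e-4)
})

test_that("pooling agrees with an adaptive-quadrature GLMM fit", {
  skip_if_not_installed("lme4")
  set.seed(19)
  E <- round(runif(12, 30, 120))
  O <- rpois(12, E * exp(rnorm(12, log(0.7), 0.25)))
  p <- pool_oe(O, E)
  d <- data.frame(O = O, E = E, trial = factor(seq_along(O)))
  g <- lme4::glmer(O ~ 1 + (1 | trial), offset = log(E),
                   family = poisson(), data = d, nAGQ = 25L)
  expect_lt(abs(p$theta - unname(lme4::fixef(g))), 5e-3)
  expect_lt(abs(p$tau - sqrt(unname(unlist(lme4::VarCorr(g))))), 5e-3)
})

arm_rows <- function(o1, o2, n = 100, fu = 182) {
  data.frame(trial_id = "t", arm = c("a", "b"),
             designation = c("placebo", "experimental"),
             n = c(n, n), sae_count = c(o1, o2),
             followup_days = c(fu, fu))
}

test_that("arm log rate ratios follow the two-group Poisson formula", {
  # equal rates -> 0
  expect_equal(arm_log_rate_ratio(arm_rows(10, 10))$log_rr, 0)
  # rate doubled with equal person-time requires equal event correction;
  # construct counts where O2/PT2 = 2 * O1/PT1 exactly
  a <- arm_rows(10, 20)
  pt1 <- aggregate_person_time(100, 182, 10)
  pt2 <- aggregate_person_time(100, 182, 20)
  cmp <- arm_log_rate_ratio(a)
  expect_equal(cmp$log_rr, log((20 / pt2) / (10 / pt1)))
  expect_equal(cmp$se, sqrt(1 / 10 + 1 / 20))
  expect_equal(cmp$comparison, "placebo")
  expect_error(arm_log_rate_ratio(arm_rows(5, 5)[1, ]), "two arms")
})

test_that("zero counts get a flagged continuity correction", {
  cmp <- arm_log_rate_ratio(arm_rows(0, 5))
  expect_true(cmp$continuity)
  pt1 <- aggregate_person_time(100, 182, 0)
  pt2 <- aggregate_person_time(100, 182, 5)
  expect_equal(cmp$log_rr, log((5.5 / pt2) / (0.5 / pt1)))
  # exact conditional oracle: given the total of 5 events, the split is
  # Binomial(5, pt2/(pt1+pt2)); the corrected point estimate must lie
  # inside the exact conditional 95% interval for the rate ratio
  pbin <- pt2 / (pt1 + pt2)
  ci_p <- binom.test(5, 5, p = pbin)$conf.int
  to_lrr <- function(p) log((p / (1 - p)) / (pt2 / pt1))
  expect_gt(cmp$log_rr, to_lrr(ci_p[1]))
  expect_lt(cmp$log_rr, to_lrr(ci_p[2]) + 1e-9)
})

test_that("trial arm designations select the right comparison", {
  a <- data.frame(trial_id = "t", arm = c("x", "y"),
                  designation = c("active", "experimental"),
                  n = c(50, 50), sae_count = c(4, 8),
                  followup_days = 182)
  expect_equal(arm_log_rate_ratio(a)$comparison, "experimental-vs-active")
  a$designation <- c("active", "active")
  expect_equal(arm_log_rate_ratio(a)$comparison, "same-designation")
})

# restricted log-likelihood for the random-effects model with known
# within-study variances (the REML criterion metafor maximises)
reml_loglik <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

test_that("REML meta-analysis matches a grid search of the criterion", {
  y <- c(0.0, 0.5); v <- c(0.1, 0.1)^2
  m <- meta_analyze(y, sqrt(v))
  grid <- seq(0, 0.5, by = 1e-4)
  ll <- vapply(grid, reml_loglik, numeric(1), y = y, v = v)
  expect_lt(abs(m$tau2 - grid[which.max(ll)]), 1e-3)
  w <- 1 / (v + m$tau2)
  expect_equal(m$pooled, sum(w * y) / sum(w), tolerance = 1e-6)
})

test_that("meta-analysis degenerate cases behave", {
  m <- meta_analyze(rep(0.3, 4), rep(0.1, 4))
  expect_equal(m$pooled, 0.3, tolerance = 1e-8)
  expect_equal(m$tau2, 0, tolerance = 1e-8)
  one <- meta_analyze(0.2, 0.05)
  expect_equal(one$pooled, 0.2)
  expect_true("single_study" %in% one$flags)
  expect_error(meta_analyze(c(0, 1), c(0.1, 0)), "positive")
})
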