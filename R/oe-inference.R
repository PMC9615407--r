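# Observed/expected SAE inference: per-trial ratios with sampling-based
# 95% intervals, condition-level pooling via a random-effects Poisson
# model with a log-expected offset, arm-level log rate ratios, and
# random-effects meta-analysis of (estimate, SE) pairs.

#' Observed/expected SAE ratio with a sampling-based 95% interval
#'
#' The point ratio is `observed / expected`. The interval composes two
#' sources of uncertainty by simulation: the observed count is sampled
#' from its Jeffreys Poisson posterior, `Gamma(observed + 0.5, 1)`, and
#' the expected count from the rate-model coefficient draws carried by
#' the `sae_expected` object (degenerate at the point value when draws
#' are absent). The 2.5th and 97.5th percentiles of the sampled ratios
#' form the interval.
#'
#' @param observed observed SAE count (>= 0).
#' @param expected an `sae_expected` object, or a positive number.
#' @param n_draws number of Monte-Carlo samples (default 10000).
#' @param seed seed for the observed-count draws.
#' @return object of class `oe_ratio`: `observed`, `expected`, `ratio`,
#'   `lower`, `upper`, `n_draws`, `seed`, `basis`, `trial_id`.
#' @export
oe_ratio <- function(observed, expected, n_draws = 10000, seed = NULL) {
  if (is.numeric(expected))
    expected <- new_expected_count(NA_character_, expected, "age_sex",
                                   NULL, NA_real_)
  stopifnot(inherits(expected, "sae_expected"), observed >= 0)
  if (expected$expected <= 0)
    stop("expected count is zero: the observed/expected ratio is undefined; check that the trial has positive person-time and the rate model positive rates",
         call. = FALSE)
  ratio <- observed / expected$expected
  e_draws <- if (length(expected$draws) > 0) {
    if (length(expected$draws) != n_draws)
      sample(expected$draws, n_draws, replace = TRUE)
    else expected$draws
  } else rep(expected$expected, n_draws)
  o_draws <- with_seed(seed, stats::rgamma(n_draws, shape = observed + 0.5,
                                           rate = 1))
  q <- unname(stats::quantile(o_draws / e_draws, c(0.025, 0.975),
                              type = 7))
  structure(list(trial_id = expected$trial_id, observed = observed,
                 expected = expected$expected, ratio = ratio,
                 lower = q[1], upper = q[2], n_draws = n_draws,
                 seed = seed, basis = expected$basis),
            class = "oe_ratio")
}

#' @export
print.oe_ratio <- function(x, ...) {
  cat(sprintf("O/E SAE ratio%s: %d / %.2f = %.3f (95%% CrI %.3f-%.3f)\n",
              if (is.na(x$trial_id)) "" else paste0(" [", x$trial_id, "]"),
              x$observed, x$expected, x$ratio, x$lower, x$upper))
  invisible(x)
}

# ---- random-effects Poisson pooling -----------------------------------

# Negative marginal log-likelihood of O_i ~ Poisson(E_i exp(theta + tau Z)),
# Z ~ N(0,1), by adaptive Gauss-Hermite quadrature: nodes are recentred
# at each trial's conditional mode and rescaled by the local curvature.
# Vectorized over trials (Newton iterations run on all trials at once).
pool_nll <- function(theta, tau, O, E, gh) {
  if (tau <= 0) {
    lam <- E * exp(theta)
    return(-sum(stats::dpois(O, lam, log = TRUE)))
  }
  k <- length(O)
  z <- numeric(k)
  for (it in 1:50) {
    lam <- E * exp(theta + tau * z)
    step <- (tau * (O - lam) - z) / (-tau^2 * lam - 1)
    z <- z - step
    if (max(abs(step)) < 1e-10) break
  }
  shat <- 1 / sqrt(tau^2 * E * exp(theta + tau * z) + 1)
  M <- length(gh$nodes)
  zj <- matrix(z, k, M) + sqrt(2) * shat %o% gh$nodes   # k x M
  lamj <- E * exp(theta + tau * zj)
  hj <- O * log(lamj) - lamj - lgamma(O + 1) +
    stats::dnorm(zj, log = TRUE)
  hj <- hj + matrix(log(gh$weights) + gh$nodes^2, k, M, byrow = TRUE)
  rowmax <- apply(hj, 1L, max)
  lse <- rowmax + log(rowSums(exp(hj - rowmax)))
  -sum(log(sqrt(2) * shat) + lse)
}

#' Pool observed/expected ratios with a random-effects Poisson model
#'
#' Fits `observed_i ~ Poisson(expected_i * exp(theta_i))` with
#' `theta_i ~ N(theta, tau^2)` by maximum marginal likelihood, the
#' integral evaluated by adaptive Gauss--Hermite quadrature. The pooled
#' ratio is `exp(theta_hat)` with a Wald 95% interval on the log scale;
#' a parametric-bootstrap interval is available via `boot`.
#'
#' @param observed,expected equal-length vectors over trials; all
#'   expected counts must be positive.
#' @param condition optional label carried into the result.
#' @param nodes number of quadrature nodes (default 32, minimum 20).
#' @param boot number of parametric-bootstrap replicates for an optional
#'   percentile interval (0 = Wald only).
#' @param seed seed used for the bootstrap.
#' @return object of class `pooled_oe`: `ratio`, `lower`, `upper`,
#'   `theta`, `se_theta`, `tau`, `k`, `loglik`, `convergence`, and
#'   optionally `boot_lower`/`boot_upper`.
#' @export
pool_oe <- function(observed, expected, condition = NULL, nodes = 32,
                    boot = 0, seed = NULL) {
  stopifnot(length(observed) == length(expected), length(observed) >= 1,
            nodes >= 20)
  if (any(expected <= 0))
    stop("all expected counts must be positive", call. = FALSE)
  O <- observed; E <- expected; k <- length(O)
  gh <- gauss_hermite(nodes)
  res <- function(theta, se, tau, ll, conv) {
    out <- list(condition = condition, ratio = exp(theta),
                lower = exp(theta - 1.96 * se),
                upper = exp(theta + 1.96 * se),
                theta = theta, se_theta = se, tau = tau, k = k,
                loglik = ll, convergence = conv)
    class(out) <- "pooled_oe"
    out
  }
  theta0 <- log((sum(O) + 0.5) / sum(E))
  if (k == 1L) {
    se <- 1 / sqrt(max(sum(O), 0.5))
    return(res(log(O / E), se, 0,
               -pool_nll(log(max(O, 0.5) / E), 0, O, E, gh), 0L))
  }
  nll_fixed <- pool_nll(theta0, 0, O, E, gh)
  # tau bounded below at a negligible value; the surface is flat in
  # log(tau) as tau -> 0, so the boundary fit is compared explicitly
  fn <- function(p) pool_nll(p[1], max(exp(p[2]), 1e-6), O, E, gh)
  opt <- stats::optim(c(theta0, log(0.25)), fn, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-12))
  if (opt$convergence != 0L) {
    grad <- vapply(1:2, function(j) {
      h <- 1e-5; ej <- c(0, 0); ej[j] <- h
      (fn(opt$par + ej) - fn(opt$par - ej)) / (2 * h)
    }, numeric(1))
    stop(sprintf(
      "random-effects Poisson fit did not converge (code %d) at theta=%.4f, log tau=%.4f, nll=%.4f, |grad|=%.3g",
      opt$convergence, opt$par[1], opt$par[2], opt$value,
      sqrt(sum(grad^2))), call. = FALSE)
  }
  at_boundary <- exp(opt$par[2]) <= 1e-3
  if (at_boundary || nll_fixed <= opt$value + 1e-8) {
    # tau on the boundary: homogeneous Poisson solution
    out <- res(theta0, 1 / sqrt(max(sum(O), 0.5)), 0, -nll_fixed,
               opt$convergence)
  } else {
    H <- num_hessian(fn, opt$par, h = 1e-4)
    se <- tryCatch(sqrt(solve(H)[1, 1]), error = function(e) NA_real_)
    if (!is.finite(se)) se <- 1 / sqrt(max(sum(O), 0.5))
    out <- res(opt$par[1], se, exp(opt$par[2]), -opt$value,
               opt$convergence)
  }
  if (boot > 0) {
    bs <- with_seed(seed, {
      vapply(seq_len(boot), function(b) {
        th <- stats::rnorm(k, out$theta, out$tau)
        Ob <- stats::rpois(k, E * exp(th))
        log((sum(Ob) + 0.5) / sum(E))  # cheap re-estimate of the mean
      }, numeric(1))
    })
    q <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
    out$boot_lower <- exp(out$theta - (q[2] - mean(bs)))
    out$boot_upper <- exp(out$theta - (q[1] - mean(bs)))
  }
  out
}

#' @export
print.pooled_oe <- function(x, ...) {
  cat(sprintf(
    "pooled O/E SAE ratio%s: %.3f (95%% CI %.3f-%.3f), tau = %.3f, k = %d\n",
    if (is.null(x$condition)) "" else paste0(" [", x$condition, "]"),
    x$ratio, x$lower, x$upper, x$tau, x$k))
  invisible(x)
}

#' Arm-level log SAE rate ratio from aggregate data
#'
#' Classifies the trial comparison (non-placebo vs placebo when a
#' placebo arm exists; experimental vs active when both designations
#' occur; otherwise later arms vs the first arm of the shared
#' designation), computes per-group person-time with
#' [aggregate_person_time()], and returns the two-group Poisson log rate
#' ratio `log((O2/PT2) / (O1/PT1))` with `SE = sqrt(1/O1 + 1/O2)`. A 0.5
#' continuity correction is added to both counts when either is zero
#' (flagged).
#'
#' @param arms per-arm rows of one trial: `arm`, `designation`
#'   (`experimental`/`active`/`placebo`), `n`, `sae_count`,
#'   `followup_days`.
#' @return object of class `arm_comparison`: `comparison`, `log_rr`,
#'   `se`, `lower`, `upper`, `continuity` flag, per-group counts.
#' @export
arm_log_rate_ratio <- function(arms) {
  require_columns(arms, c("arm", "designation", "n", "sae_count",
                          "followup_days"), "arm table")
  if (nrow(arms) < 2L)
    stop("arm comparison undefined: fewer than two arms reported",
         call. = FALSE)
  des <- arms$designation
  if (any(des == "placebo")) {
    comparison <- "placebo"
    grp2 <- des != "placebo"
  } else if (all(c("experimental", "active") %in% des)) {
    comparison <- "experimental-vs-active"
    grp2 <- des == "experimental"
  } else {
    comparison <- "same-designation"
    grp2 <- seq_len(nrow(arms)) != 1L
  }
  if (!any(grp2) || all(grp2))
    stop("arm comparison undefined: all arms fall in one group",
         call. = FALSE)
  tot <- function(g) {
    o <- sum(arms$sae_count[g])
    pt <- sum(mapply(aggregate_person_time, arms$n[g],
                     arms$followup_days[g], arms$sae_count[g]))
    c(o = o, pt = pt)
  }
  g1 <- tot(!grp2); g2 <- tot(grp2)
  continuity <- g1["o"] == 0 || g2["o"] == 0
  o1 <- g1["o"] + 0.5 * continuity
  o2 <- g2["o"] + 0.5 * continuity
  log_rr <- unname(log((o2 / g2["pt"]) / (o1 / g1["pt"])))
  se <- unname(sqrt(1 / o1 + 1 / o2))
  structure(list(trial_id = arms$trial_id[1] %||% NA_character_,
                 comparison = comparison, log_rr = log_rr, se = se,
                 lower = log_rr - 1.96 * se, upper = log_rr + 1.96 * se,
                 continuity = unname(continuity),
                 counts = c(o1 = unname(g1["o"]), o2 = unname(g2["o"])),
                 person_time = c(pt1 = unname(g1["pt"]),
                                 pt2 = unname(g2["pt"]))),
            class = "arm_comparison")
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat(sprintf(
    "arm comparison (%s)%s: log RR = %.3f (SE %.3f)%s\n",
    x$comparison,
    if (is.na(x$trial_id)) "" else paste0(" [", x$trial_id, "]"),
    x$log_rr, x$se, if (x$continuity) " [continuity-corrected]" else ""))
  invisible(x)
}

#' Random-effects meta-analysis of (estimate, SE) pairs
#'
#' REML estimation of the between-study variance with inverse-variance
#' pooling, delegated to [metafor::rma()]. A single study passes
#' through with a flag.
#'
#' @param estimates effect estimates (e.g. log rate ratios or model
#'   coefficients).
#' @param ses their standard errors (all positive).
#' @param method heterogeneity estimator, default `"REML"`.
#' @return object of class `meta_result`: `pooled`, `se`, `lower`,
#'   `upper`, `tau2`, `k`, `flags`.
#' @export
meta_analyze <- function(estimates, ses, method = "REML") {
  stopifnot(length(estimates) == length(ses), length(estimates) >= 1)
  if (any(ses <= 0))
    stop("all standard errors must be positive", call. = FALSE)
  if (length(estimates) == 1L) {
    return(structure(list(pooled = estimates, se = ses,
                          lower = estimates - 1.96 * ses,
                          upper = estimates + 1.96 * ses,
                          tau2 = 0, k = 1L, flags = "single_study"),
                     class = "meta_result"))
  }
  fit <- metafor::rma(yi = estimates, sei = ses, method = method)
  structure(list(pooled = as.numeric(fit$b), se = fit$se,
                 lower = fit$ci.lb, upper = fit$ci.ub,
                 tau2 = fit$tau2, k = fit$k, flags = character(0)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "random-effects meta-analysis: %.3f (95%% CI %.3f-%.3f), tau2 = %.4f, k = %d%s\n",
    x$pooled, x$lower, x$upper, x$tau2, x$k,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}
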