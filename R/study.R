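# Replicated simulation studies over synthetic trial suites: coverage
# calibration, planted-ratio recovery, and the decomposition of
# selection effects by dual standardization. These drive the package's
# validation and are reusable for sensitivity analyses.

#' Replicated O/E studies on synthetic trial suites
#'
#' Draws `n_replicates` independent trial suites from a cohort under one
#' selection model, runs the observed/expected analysis on each (either
#' the aggregate route — reconstruction from summary statistics — or the
#' IPD route), and pools each replicate with [pool_oe()]. The planted
#' `rate_multiplier` of the selection model is the ground truth for
#' coverage and recovery summaries.
#'
#' @param cohort an `sae_cohort`.
#' @param models named `male`/`female` list of age/sex rate models
#'   fitted to that cohort.
#' @param selection a [selection_model()]; its `rate_multiplier` is the
#'   true per-trial ratio.
#' @param n_replicates,n_trials,n_per_trial study dimensions.
#' @param condition index condition (default `"copd"`).
#' @param followup_days trial follow-up (default 182).
#' @param n_draws Monte-Carlo draws per trial interval; 0 skips
#'   per-trial intervals (pooling needs only point expectations).
#' @param route `"aggregate"` (reconstruct age bands from summary
#'   statistics) or `"ipd"` (observed participants).
#' @param seed master seed; replicate r uses `seed + r`.
#' @return list with `trials` (one row per replicate x trial: observed,
#'   expected, ratio, and interval when `n_draws > 0`) and `pooled` (one
#'   row per replicate: pooled ratio, Wald interval, tau).
#' @export
simulate_oe_study <- function(cohort, models, selection,
                              n_replicates, n_trials, n_per_trial,
                              condition = "copd", followup_days = 182,
                              n_draws = 1000,
                              route = c("aggregate", "ipd"),
                              seed = 1L) {
  route <- match.arg(route)
  trials <- vector("list", n_replicates)
  pooled <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    suite <- generate_trial_suite(cohort, condition, selection,
                                  n_trials = n_trials,
                                  n_per_trial = n_per_trial,
                                  followup_days = followup_days,
                                  seed = seed + r)
    rows <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      s <- suite$summaries[i, ]
      if (route == "aggregate") {
        dist <- reconstruct_age_distribution(s)
        e <- expected_events_aggregate(models, dist, s$n_participants,
                                       s$followup_days, s$sae_count,
                                       n_draws = n_draws,
                                       seed = seed + 1000L * r + 2L * i)
      } else {
        e <- expected_events_ipd(models, suite$ipd[[i]],
                                 n_draws = n_draws,
                                 seed = seed + 1000L * r + 2L * i)
      }
      row <- data.frame(replicate = r, trial_id = s$trial_id,
                        observed = s$sae_count, expected = e$expected,
                        ratio = s$sae_count / e$expected,
                        lower = NA_real_, upper = NA_real_,
                        stringsAsFactors = FALSE)
      if (n_draws > 0) {
        oe <- oe_ratio(s$sae_count, e, n_draws = n_draws,
                       seed = seed + 5000000L + 1000L * r + i)
        row$lower <- oe$lower
        row$upper <- oe$upper
      }
      rows[[i]] <- row
    }
    rows <- do.call(rbind, rows)
    p <- pool_oe(rows$observed, rows$expected, condition = condition)
    trials[[r]] <- rows
    pooled[[r]] <- data.frame(replicate = r, ratio = p$ratio,
                              lower = p$lower, upper = p$upper,
                              tau = p$tau, k = p$k)
  }
  list(trials = do.call(rbind, trials),
       pooled = do.call(rbind, pooled),
       truth = selection$rate_multiplier)
}

#' Coverage and recovery summaries of an O/E study
#'
#' @param study result of [simulate_oe_study()].
#' @return list: `pooled_coverage` (fraction of replicates whose pooled
#'   interval covers the truth), `trial_coverage` (fraction of per-trial
#'   intervals covering the truth; NA when intervals were not drawn),
#'   `mean_pooled_ratio`, `exclude_null` (fraction of replicates whose
#'   pooled interval excludes 1).
#' @export
summarize_oe_study <- function(study) {
  tr <- study$truth
  p <- study$pooled
  t <- study$trials
  list(pooled_coverage = mean(p$lower <= tr & tr <= p$upper),
       trial_coverage = if (all(is.na(t$lower))) NA_real_ else
         mean(t$lower <= tr & tr <= t$upper, na.rm = TRUE),
       mean_pooled_ratio = mean(p$ratio),
       exclude_null = mean(p$upper < 1 | p$lower > 1))
}

#' Replicated dual-standardization study
#'
#' For each replicate, draws a trial suite under `selection` and pools
#' the observed/expected ratio twice: expected from age/sex models and
#' from multimorbidity-adjusted models. Summarizes how often the
#' multimorbidity-adjusted pooled ratio exceeds the age/sex one (the
#' decomposition direction when selection under-samples multimorbidity).
#'
#' @param cohort,selection as in [simulate_oe_study()].
#' @param models_age_sex,models_age_sex_mm named `male`/`female` model
#'   lists on the two bases, fitted to the same cohort.
#' @param n_replicates,n_trials,n_per_trial study dimensions.
#' @param condition,followup_days,seed as in [simulate_oe_study()].
#' @return list with `pooled` (per replicate: `ratio_age_sex`,
#'   `ratio_age_sex_mm`), `prop_mm_higher`, `mean_ratio_age_sex`,
#'   `mean_ratio_age_sex_mm`, `truth`.
#' @export
simulate_dual_study <- function(cohort, models_age_sex,
                                models_age_sex_mm, selection,
                                n_replicates, n_trials, n_per_trial,
                                condition = "copd", followup_days = 182,
                                seed = 1L) {
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    suite <- generate_trial_suite(cohort, condition, selection,
                                  n_trials = n_trials,
                                  n_per_trial = n_per_trial,
                                  followup_days = followup_days,
                                  seed = seed + r)
    O <- numeric(n_trials); E1 <- numeric(n_trials)
    E2 <- numeric(n_trials)
    for (i in seq_len(n_trials)) {
      ipd <- suite$ipd[[i]]
      O[i] <- sum(ipd$sae_count > 0)
      E1[i] <- expected_events_ipd(models_age_sex, ipd)$expected
      E2[i] <- expected_events_ipd(models_age_sex_mm, ipd,
                                   basis = "age_sex_mm")$expected
    }
    p1 <- pool_oe(O, E1, condition = condition)
    p2 <- pool_oe(O, E2, condition = condition)
    rows[[r]] <- data.frame(replicate = r,
                            ratio_age_sex = p1$ratio,
                            lower_age_sex = p1$lower,
                            upper_age_sex = p1$upper,
                            ratio_age_sex_mm = p2$ratio,
                            lower_age_sex_mm = p2$lower,
                            upper_age_sex_mm = p2$upper)
  }
  pooled <- do.call(rbind, rows)
  list(pooled = pooled,
       prop_mm_higher = mean(pooled$ratio_age_sex_mm >
                               pooled$ratio_age_sex),
       mean_ratio_age_sex = mean(pooled$ratio_age_sex),
       mean_ratio_age_sex_mm = mean(pooled$ratio_age_sex_mm),
       truth = selection$rate_multiplier)
}

#' Log-scale RMSE of a fitted age-rate curve against the generator truth
#'
#' Compares the fitted sex-specific rate curve with the generating
#' hazard of a synthetic cohort over an age grid.
#'
#' @param model an `sae_rate_model` (age/sex basis) fitted to `cohort`.
#' @param cohort the generating `sae_cohort` (carries the truth
#'   attributes). The truth is the marginal rate at each age for the
#'   model's sex, i.e. the generating hazard averaged over the
#'   age-specific multimorbidity distribution.
#' @param ages age grid (default 40:90).
#' @return RMSE of `log(fitted) - log(true)` over the grid.
#' @export
rate_curve_rmse <- function(model, cohort, ages = 40:90) {
  cfg <- attr(cohort, "config")
  truth <- attr(cohort, "truth")
  if (is.null(cfg) || is.null(truth))
    stop("cohort does not carry generator truth attributes", call. = FALSE)
  # marginal rate at age a: E over mm ~ Poisson(mu(a)) of the hazard
  mu <- pmax(0, cfg$mm_mean + cfg$mm_age_slope * (ages - 50) / 10)
  log_marginal <- truth$log_baseline_per_day +
    truth$age_log_rr_per_decade * (ages - truth$reference_age) / 10 +
    truth$sex_log_rr * (model$sex == "female") +
    mu * (exp(truth$mm_log_rr_per_condition) - 1)
  fitted <- log(predict_rate(model, ages))
  sqrt(mean((fitted - log_marginal)^2))
}
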