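# Synthetic routine-care cohorts and trial suites with known ground
# truth. The generator emulates the statistical structure the analysis
# assumes: exponential event times with a log-linear hazard in age, sex
# and multimorbidity count; age-dependent multimorbidity; and a
# trial-selection mechanism that can under-sample older and
# multimorbid individuals and scale the enrolled hazard by a planted
# observed/expected ratio.

#' Default index-condition profiles
#'
#' Five routine-care condition registers with realistic sizes and age
#' structures (prevalences expressed relative to a 2.3M-person
#' population): COPD, type 2 diabetes, hypertension, asthma and
#' dementia. `category` is the comorbidity category each index condition
#' maps to, excluded from its patients' multimorbidity counts.
#'
#' @return data frame with columns `condition`, `prevalence`,
#'   `age_mean`, `age_sd`, `category`.
#' @export
default_condition_profiles <- function() {
  data.frame(
    condition  = c("copd", "type_2_diabetes", "hypertension", "asthma",
                   "dementia"),
    prevalence = c(57378, 82473, 310691, 191160, 13871) / 2.3e6,
    age_mean   = c(69.1, 65.3, 67.0, 45.6, 82.1),
    age_sd     = c(11.6, 13.0, 12.9, 22.9, 9.0),
    category   = c("asthma_copd", "diabetes_mellitus",
                   "cardiovascular_disease", "asthma_copd", "dementia"),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic routine-care cohort
#'
#' @param n_persons number of persons to generate.
#' @param condition_profiles data frame as in
#'   [default_condition_profiles()]; prevalences must lie in (0, 1] and
#'   set the relative register sizes.
#' @param baseline_rate events per person-year at the reference profile
#'   (age 70, male, multimorbidity 0). May be 0 for degenerate checks.
#' @param age_log_rr_per_decade log rate ratio per 10 years of age.
#' @param sex_log_rr log rate ratio, female vs male.
#' @param mm_log_rr_per_condition log rate ratio per unit multimorbidity
#'   count.
#' @param mm_mean mean multimorbidity count at age 50.
#' @param mm_age_slope increase in mean multimorbidity count per decade
#'   of age (the Poisson mean is floored at 0).
#' @param prop_female proportion female.
#' @param observation_days fixed censoring horizon in days (default 182,
#'   i.e. six months).
#' @param seed integer seed.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_persons,
                          condition_profiles = default_condition_profiles(),
                          baseline_rate = 0.30,
                          age_log_rr_per_decade = log(1.5),
                          sex_log_rr = log(0.85),
                          mm_log_rr_per_condition = 0.2,
                          mm_mean = 1.5,
                          mm_age_slope = 0.4,
                          prop_female = 0.5,
                          observation_days = 182,
                          seed = 1L) {
  if (!is.numeric(n_persons) || length(n_persons) != 1L || n_persons < 1)
    stop("n_persons must be a positive integer", call. = FALSE)
  p <- condition_profiles
  if (!all(c("condition", "prevalence", "age_mean", "age_sd") %in% names(p)))
    stop("condition_profiles needs columns condition, prevalence, age_mean, age_sd",
         call. = FALSE)
  if (any(p$prevalence <= 0 | p$prevalence > 1))
    stop("condition prevalences must lie in (0, 1]", call. = FALSE)
  if (observation_days <= 0)
    stop("observation_days must be positive", call. = FALSE)
  if (baseline_rate < 0)
    stop("baseline_rate must be nonnegative", call. = FALSE)
  if (!"category" %in% names(p)) p$category <- NA_character_
  structure(list(n_persons = as.integer(n_persons),
                 condition_profiles = p,
                 baseline_rate = baseline_rate,
                 age_log_rr_per_decade = age_log_rr_per_decade,
                 sex_log_rr = sex_log_rr,
                 mm_log_rr_per_condition = mm_log_rr_per_condition,
                 mm_mean = mm_mean, mm_age_slope = mm_age_slope,
                 prop_female = prop_female,
                 observation_days = observation_days,
                 reference_age = 70,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# exact truncated-normal sampling on [lo, hi] by CDF inversion
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# per-day hazard implied by the generator's ground truth
true_hazard_fn <- function(config, age, sex, mm) {
  if (config$baseline_rate == 0) return(rep(0, length(age)))
  exp(log(config$baseline_rate / 365.25) +
        config$age_log_rr_per_decade * (age - config$reference_age) / 10 +
        config$sex_log_rr * (sex == "female") +
        config$mm_log_rr_per_condition * mm)
}

#' Generate a synthetic routine-care cohort
#'
#' One row per person: integer age (truncated normal on \[18, 100\] per
#' the person's index condition profile), sex, index-condition flags
#' (`has_<condition>`), multimorbidity count (Poisson with mean linear
#' in age, floored at 0), a synthetic medication-token string consistent
#' with the shipped comorbidity map, and the first-event outcome:
#' exponential event times under the ground-truth hazard, censored at
#' `observation_days`. The `true_hazard` column records the simulation
#' truth (per person-day) for validation work.
#'
#' @param config a [cohort_config()].
#' @return data frame of class `sae_cohort` with attributes `config` and
#'   `truth` (the generating coefficients).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_persons
    p <- config$condition_profiles
    idx <- sample.int(nrow(p), n, replace = TRUE,
                      prob = p$prevalence / sum(p$prevalence))
    age <- round(rtruncnorm(n, p$age_mean[idx], p$age_sd[idx], 18, 100))
    sex <- ifelse(stats::runif(n) < config$prop_female, "female", "male")
    mm_mu <- pmax(0, config$mm_mean +
                    config$mm_age_slope * (age - 50) / 10)
    mm <- pmin(stats::rpois(n, mm_mu), 20L)

    cats <- comorbidity_categories()
    index_cat <- p$category[idx]
    meds <- character(n)
    variant <- sample.int(2L, n, replace = TRUE)
    tric <- stats::runif(n) < 0.10   # excluded token, exercises mapping
    for (i in seq_len(n)) {
      if (mm[i] > 0L) {
        pool <- if (is.na(index_cat[i])) cats else setdiff(cats, index_cat[i])
        chosen <- pool[sample.int(length(pool), mm[i])]
        meds[i] <- paste0("rx_", chosen, "_", variant[i], collapse = ";")
      }
      if (tric[i])
        meds[i] <- paste(c(meds[i][nzchar(meds[i])], "rx_tricyclic"),
                         collapse = ";")
    }

    hz <- true_hazard_fn(config, age, sex, mm)
    tev <- ifelse(hz > 0, stats::rexp(n, rate = pmax(hz, 1e-300)), Inf)
    event <- as.integer(tev <= config$observation_days)
    time_at_risk <- pmin(tev, config$observation_days)
    event_day <- ifelse(event == 1L, tev, NA_real_)

    cohort <- data.frame(id = seq_len(n),
                         condition = p$condition[idx],
                         age = as.integer(age), sex = sex,
                         mm_count = as.integer(mm),
                         medications = meds,
                         time_at_risk = time_at_risk,
                         event = event, event_day = event_day,
                         true_hazard = hz,
                         stringsAsFactors = FALSE)
    for (k in seq_len(nrow(p))) {
      cohort[[paste0("has_", p$condition[k])]] <-
        as.integer(idx == k | stats::runif(n) < p$prevalence[k])
    }
    attr(cohort, "config") <- config
    attr(cohort, "truth") <- list(
      log_baseline_per_day = if (config$baseline_rate > 0)
        log(config$baseline_rate / 365.25) else -Inf,
      reference_age = config$reference_age,
      age_log_rr_per_decade = config$age_log_rr_per_decade,
      sex_log_rr = config$sex_log_rr,
      mm_log_rr_per_condition = config$mm_log_rr_per_condition)
    class(cohort) <- c("sae_cohort", "data.frame")
    cohort
  })
}

#' Trial-selection model
#'
#' Describes how a simulated trial samples from the eligible cohort and
#' how the enrolled hazard differs from routine care. `rate_multiplier`
#' is the planted ground-truth observed/expected ratio ("theta").
#'
#' @param age_lower,age_upper eligibility bounds in years.
#' @param mm_penalty log odds-weight of inclusion per unit multimorbidity
#'   count (negative values under-sample multimorbid persons).
#' @param rate_multiplier multiplicative factor applied to the enrolled
#'   participants' SAE hazard; must be positive.
#' @param label free-text label carried into outputs.
#' @return a `selection_model` list.
#' @export
selection_model <- function(age_lower = 18, age_upper = 100,
                            mm_penalty = 0, rate_multiplier = 1,
                            label = "selection") {
  if (rate_multiplier <= 0)
    stop("rate_multiplier must be positive", call. = FALSE)
  if (age_lower > age_upper)
    stop("age_lower must not exceed age_upper", call. = FALSE)
  structure(list(age_lower = age_lower, age_upper = age_upper,
                 mm_penalty = mm_penalty,
                 rate_multiplier = rate_multiplier, label = label),
            class = "selection_model")
}

#' Generate a suite of synthetic trials from a cohort
#'
#' Samples `n_trials` trials of `n_per_trial` participants each from the
#' cohort members holding the index condition and inside the selection
#' model's age bounds, with inclusion weight `exp(mm_penalty * mm)`.
#' Events are re-simulated over `followup_days` with each participant's
#' ground-truth hazard scaled by `rate_multiplier` (and by
#' `arm_rate_multiplier` in the treatment arm). Aggregate summaries are
#' tallied from the sampled IPD so reconstruction can be validated
#' against truth.
#'
#' @param cohort an `sae_cohort` from [generate_cohort()].
#' @param condition index condition of the trials.
#' @param selection a [selection_model()].
#' @param n_trials,n_per_trial suite dimensions.
#' @param followup_days planned follow-up (default 182 days, the typical
#'   26-week trial horizon).
#' @param arm_rate_multiplier extra hazard multiplier in the treatment
#'   arm (default 1: no arm effect).
#' @param seed integer seed.
#' @return list with `summaries` (one row per trial), `arms` (per-arm
#'   rows: `trial_id`, `arm`, `designation`, `n`, `sae_count`,
#'   `followup_days`) and `ipd` (list of per-trial participant tables).
#' @export
generate_trial_suite <- function(cohort, condition, selection,
                                 n_trials, n_per_trial,
                                 followup_days = 182,
                                 arm_rate_multiplier = 1,
                                 seed = 1L) {
  stopifnot(inherits(selection, "selection_model"), n_trials >= 1,
            n_per_trial >= 1, followup_days > 0)
  flag <- paste0("has_", condition)
  rows <- if (flag %in% names(cohort)) cohort[[flag]] > 0
          else cohort$condition == condition
  elig <- cohort[rows &
                   cohort$age >= selection$age_lower &
                   cohort$age <= selection$age_upper, , drop = FALSE]
  if (nrow(elig) == 0L)
    stop(sprintf(
      "selection '%s' excludes everyone for condition '%s' (age bounds [%s, %s])",
      selection$label, condition, selection$age_lower, selection$age_upper),
      call. = FALSE)
  if (nrow(elig) < n_per_trial)
    stop(sprintf("only %d eligible persons for trials of %d participants",
                 nrow(elig), n_per_trial), call. = FALSE)
  with_seed(seed, {
    w <- exp(selection$mm_penalty * elig$mm_count)
    ipd <- vector("list", n_trials)
    summaries <- vector("list", n_trials)
    arms_tab <- vector("list", n_trials)
    for (tr in seq_len(n_trials)) {
      take <- sample.int(nrow(elig), n_per_trial, prob = w)
      d <- elig[take, , drop = FALSE]
      arm <- ifelse(seq_len(n_per_trial) %% 2L == 0L, "treatment", "control")
      arm <- sample(arm)
      hz <- d$true_hazard * selection$rate_multiplier *
        ifelse(arm == "treatment", arm_rate_multiplier, 1)
      tev <- ifelse(hz > 0, stats::rexp(n_per_trial, pmax(hz, 1e-300)), Inf)
      sae <- as.integer(tev <= followup_days)
      fup <- pmin(tev, followup_days)
      tid <- sprintf("%s_trial_%03d", condition, tr)
      ipd[[tr]] <- data.frame(trial_id = tid, condition = condition,
                              id = d$id, age = d$age, sex = d$sex,
                              arm = arm,
                              medications = d$medications,
                              mm_count = d$mm_count,
                              followup_days = fup, sae_count = sae,
                              stringsAsFactors = FALSE)
      summaries[[tr]] <- data.frame(
        trial_id = tid, condition = condition,
        n_participants = n_per_trial,
        age_mean = mean(d$age), age_sd = stats::sd(d$age),
        age_min = min(d$age), age_max = max(d$age),
        percent_female = 100 * mean(d$sex == "female"),
        followup_days = followup_days,
        sae_count = sum(sae), stringsAsFactors = FALSE)
      arms_tab[[tr]] <- data.frame(
        trial_id = tid,
        arm = c("control", "treatment"),
        designation = c("placebo", "experimental"),
        n = c(sum(arm == "control"), sum(arm == "treatment")),
        sae_count = c(sum(sae[arm == "control"]),
                      sum(sae[arm == "treatment"])),
        followup_days = followup_days, stringsAsFactors = FALSE)
    }
    list(summaries = do.call(rbind, summaries),
         arms = do.call(rbind, arms_tab),
         ipd = ipd)
  })
}
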