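# Shared fixtures, built lazily and cached for the whole test run.

fixture_env <- new.env(parent = emptyenv())

copd_profile <- function() {
  p <- default_condition_profiles()
  p[p$condition == "copd", , drop = FALSE]
}

# single-condition cohort used by most module tests
small_cohort <- function() {
  if (is.null(fixture_env$small)) {
    cfg <- cohort_config(30000, condition_profiles = copd_profile(),
                         seed = 42L)
    fixture_env$small <- generate_cohort(cfg)
  }
  fixture_env$small
}

# age/sex rate models on the small cohort (fixed linear-age powers: the
# generating hazard is log-linear in age)
small_models <- function() {
  if (is.null(fixture_env$small_models)) {
    co <- small_cohort()
    fixture_env$small_models <- list(
      male = fit_rate_model(co, "copd", "male", age_powers = 1),
      female = fit_rate_model(co, "copd", "female", age_powers = 1))
  }
  fixture_env$small_models
}

# the large cohort + models used by the calibration/recovery studies
big_cohort <- function() {
  if (is.null(fixture_env$big)) {
    cfg <- cohort_config(100000, condition_profiles = copd_profile(),
                         seed = 2024L)
    fixture_env$big <- generate_cohort(cfg)
  }
  fixture_env$big
}

big_models <- function() {
  if (is.null(fixture_env$big_models)) {
    co <- big_cohort()
    fixture_env$big_models <- list(
      age_sex = list(
        male = fit_rate_model(co, "copd", "male"),
        female = fit_rate_model(co, "copd", "female")),
      age_sex_mm = list(
        male = fit_rate_model(co, "copd", "male", c("age", "mm_count")),
        female = fit_rate_model(co, "copd", "female", c("age", "mm_count"))))
  }
  fixture_env$big_models
}

# a degenerate rate model with constant rate r per person-day
make_const_model <- function(rate_per_day, sex = "male",
                             basis = c("age_sex", "age_sex_mm")) {
  basis <- match.arg(basis)
  coefs <- if (basis == "age_sex_mm")
    c("(Intercept)" = log(rate_per_day), age_1 = 0, mm_1 = 0)
  else c("(Intercept)" = log(rate_per_day), age_1 = 0)
  p <- length(coefs)
  structure(list(condition = "synthetic", sex = sex, basis = basis,
                 age_fp = list(powers = 1, shift = 0, scale = 10),
                 mm_fp = if (basis == "age_sex_mm")
                   list(powers = 1, shift = 1, scale = 1) else NULL,
                 time_unit = "person-days",
                 coef = coefs,
                 vcov = diag(1e-12, p),
                 age_range = c(18L, 100L), n = 1L, n_events = 1L,
                 person_time_days = 1),
            class = "sae_rate_model")
}

shipped_map_path <- function() {
  system.file("extdata", "comorbidity_map_synthetic.tsv",
              package = "saerep")
}
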