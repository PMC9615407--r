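# IPD analyses: within-trial multimorbidity-SAE associations (per sex,
# >= 20 events per sex), their REML meta-analysis, arm/interaction
# checks, and the paired age/sex vs age/sex/multimorbidity
# standardization.

#' Within-trial multimorbidity--SAE association for one sex
#'
#' Poisson regression of the first-SAE indicator on multimorbidity count
#' adjusted for (linear) age, with `log(follow-up days)` as offset.
#' Strata with fewer than `min_events` SAEs (default 20) are excluded:
#' the filter applies per sex, never per trial. A stratum with constant
#' multimorbidity count is inestimable and skipped.
#'
#' @param ipd one trial's participant table (`age`, `sex`, `mm_count`,
#'   `followup_days`, `sae_count`).
#' @param sex `"male"` or `"female"`.
#' @param min_events per-sex SAE threshold (default 20).
#' @return object of class `mm_association` with `coef`, `se`,
#'   `n_events`, `n`, or `NULL` (with a message) when the stratum is
#'   excluded.
#' @export
mm_sae_association <- function(ipd, sex, min_events = 20) {
  require_columns(ipd, c("age", "sex", "mm_count", "followup_days",
                         "sae_count"), "trial IPD")
  d <- ipd[ipd$sex == sex & ipd$followup_days > 0, , drop = FALSE]
  ev <- as.integer(d$sae_count > 0)
  skip <- function(reason) {
    message(sprintf("stratum excluded (%s, %s): %s",
                    ipd$trial_id[1] %||% "trial", sex, reason))
    NULL
  }
  if (sum(ev) < min_events)
    return(skip(sprintf("%d SAEs < %d required", sum(ev), min_events)))
  if (stats::var(d$mm_count) == 0)
    return(skip("multimorbidity count is constant; coefficient inestimable"))
  fit <- tryCatch(
    stats::glm(ev ~ mm_count + age, family = stats::poisson(),
               offset = log(followup_days), data = d),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged)
    return(skip("Poisson fit failed to converge"))
  sm <- summary(fit)$coefficients
  structure(list(trial_id = ipd$trial_id[1] %||% NA_character_,
                 sex = sex,
                 coef = sm["mm_count", "Estimate"],
                 se = sm["mm_count", "Std. Error"],
                 vcov = stats::vcov(fit),
                 n_events = sum(ev), n = nrow(d)),
            class = "mm_association")
}

#' Multimorbidity associations across an IPD trial suite
#'
#' Applies [mm_sae_association()] per trial and sex and returns the
#' estimable strata as a data frame ready for [meta_analyze()].
#'
#' @param ipd_list list of per-trial IPD tables.
#' @param sexes sexes to fit (default both).
#' @param min_events per-sex SAE threshold.
#' @return data frame: `trial_id`, `sex`, `coef`, `se`, `n_events`.
#' @export
mm_association_table <- function(ipd_list, sexes = c("male", "female"),
                                 min_events = 20) {
  rows <- list()
  for (ipd in ipd_list) for (sx in sexes) {
    a <- suppressMessages(mm_sae_association(ipd, sx, min_events))
    if (!is.null(a))
      rows[[length(rows) + 1L]] <-
        data.frame(trial_id = a$trial_id, sex = a$sex, coef = a$coef,
                   se = a$se, n_events = a$n_events,
                   stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(trial_id = character(0), sex = character(0),
                      coef = numeric(0), se = numeric(0),
                      n_events = integer(0)))
  do.call(rbind, rows)
}

#' Rate-ratio curve over the multimorbidity range
#'
#' `RR(mm) = exp(coef * mm)` relative to a reference count of 0, with a
#' delta-method 95% band from the pooled SE, evaluated over the counts
#' observed in the trials.
#'
#' @param pooled_coef,pooled_se meta-analysed coefficient and SE.
#' @param mm_range integer range of observed counts, e.g. `c(0, 8)`.
#' @return data frame: `mm`, `rr`, `lower`, `upper`.
#' @export
rate_ratio_curve <- function(pooled_coef, pooled_se, mm_range) {
  mm <- seq.int(mm_range[1], mm_range[2])
  data.frame(mm = mm,
             rr = exp(pooled_coef * mm),
             lower = exp((pooled_coef - 1.96 * pooled_se) * mm),
             upper = exp((pooled_coef + 1.96 * pooled_se) * mm))
}

#' Multimorbidity-by-treatment-arm interaction across trials
#'
#' Per trial, fits a Poisson model of the first-SAE indicator on arm,
#' multimorbidity count and their interaction (adjusted for age, sex
#' where both occur; `log(time)` offset); the interaction coefficients
#' are then REML meta-analysed. Arm main effects are estimated per sex
#' from arm-plus-age models and meta-analysed likewise. Single-arm
#' trials are skipped with a reason.
#'
#' @param ipd_list list of per-trial IPD tables with an `arm` column
#'   (`treatment`/`control`).
#' @param min_events minimum SAEs per trial to attempt the fit
#'   (default 10).
#' @return list with `interaction` (a `meta_result` on the log scale),
#'   `interaction_rr` (rate-ratio scale summary), `arm_effects` (named
#'   list of `meta_result` per sex) and `skipped` (data frame of
#'   trial/reason).
#' @export
mm_treatment_interaction <- function(ipd_list, min_events = 10) {
  inter <- list(); arm_eff <- list(male = list(), female = list())
  skipped <- list()
  skip <- function(id, reason)
    skipped[[length(skipped) + 1L]] <<-
      data.frame(trial_id = id, reason = reason, stringsAsFactors = FALSE)
  for (ipd in ipd_list) {
    id <- ipd$trial_id[1] %||% "trial"
    d <- ipd[ipd$followup_days > 0, , drop = FALSE]
    d$ev <- as.integer(d$sae_count > 0)
    if (length(unique(d$arm)) < 2L) { skip(id, "single arm"); next }
    if (sum(d$ev) < min_events) {
      skip(id, sprintf("%d SAEs < %d", sum(d$ev), min_events)); next
    }
    if (stats::var(d$mm_count) == 0) { skip(id, "constant mm count"); next }
    d$trt <- as.integer(d$arm == "treatment")
    form <- if (length(unique(d$sex)) > 1L)
      ev ~ trt * mm_count + age + sex else ev ~ trt * mm_count + age
    fit <- tryCatch(
      suppressWarnings(stats::glm(form, family = stats::poisson(),
                                  offset = log(followup_days), data = d)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      sm <- summary(fit)$coefficients
      if ("trt:mm_count" %in% rownames(sm) &&
          is.finite(sm["trt:mm_count", "Std. Error"]) &&
          sm["trt:mm_count", "Std. Error"] < 10) {
        inter[[length(inter) + 1L]] <-
          c(est = sm["trt:mm_count", "Estimate"],
            se = sm["trt:mm_count", "Std. Error"])
      } else skip(id, "interaction inestimable")
    } else skip(id, "interaction model failed")
    for (sx in c("male", "female")) {
      ds <- d[d$sex == sx, , drop = FALSE]
      if (sum(ds$ev) < min_events || length(unique(ds$trt)) < 2L) next
      fs <- tryCatch(
        suppressWarnings(stats::glm(ev ~ trt + age,
                                    family = stats::poisson(),
                                    offset = log(followup_days),
                                    data = ds)),
        error = function(e) NULL)
      if (is.null(fs) || !fs$converged) next
      sms <- summary(fs)$coefficients
      if (is.finite(sms["trt", "Std. Error"]) &&
          sms["trt", "Std. Error"] < 10)
        arm_eff[[sx]][[length(arm_eff[[sx]]) + 1L]] <-
          c(est = sms["trt", "Estimate"], se = sms["trt", "Std. Error"])
    }
  }
  pool <- function(lst) {
    if (length(lst) == 0L) return(NULL)
    m <- do.call(rbind, lst)
    meta_analyze(m[, "est"], m[, "se"])
  }
  mi <- pool(inter)
  list(interaction = mi,
       interaction_rr = if (!is.null(mi))
         c(rr = exp(mi$pooled), lower = exp(mi$lower),
           upper = exp(mi$upper)) else NULL,
       arm_effects = list(male = pool(arm_eff$male),
                          female = pool(arm_eff$female)),
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(trial_id = character(0), reason = character(0)))
}

#' Paired standardization: age/sex vs age/sex/multimorbidity
#'
#' Computes the observed/expected SAE ratio for one IPD trial twice —
#' expected from age/sex rate models and from multimorbidity-adjusted
#' models fitted to the same cohort — and returns the paired record.
#' `shift` is `ratio_age_sex_mm - ratio_age_sex`; for trials that
#' under-sample multimorbidity relative to routine care the
#' multimorbidity-adjusted ratio is the larger (closer to 1 when the
#' crude ratio is below 1).
#'
#' @param ipd one trial's participant table (with `mm_count`).
#' @param models_age_sex,models_age_sex_mm named `male`/`female` lists
#'   of `sae_rate_model`s on the two bases, fitted to the same cohort.
#' @param n_draws,seed interval-sampling controls (see [oe_ratio()]).
#' @return object of class `dual_standardization`: the two `oe_ratio`
#'   objects, the paired summary row, and `shift`.
#' @export
dual_standardization <- function(ipd, models_age_sex, models_age_sex_mm,
                                 n_draws = 10000, seed = NULL) {
  observed <- sum(ipd$sae_count > 0)
  e1 <- expected_events_ipd(models_age_sex, ipd, basis = "age_sex",
                            n_draws = n_draws, seed = seed)
  e2 <- expected_events_ipd(models_age_sex_mm, ipd, basis = "age_sex_mm",
                            n_draws = n_draws,
                            seed = if (is.null(seed)) NULL else seed + 2L)
  r1 <- oe_ratio(observed, e1, n_draws = n_draws, seed = seed)
  r2 <- oe_ratio(observed, e2, n_draws = n_draws,
                 seed = if (is.null(seed)) NULL else seed + 4L)
  structure(list(trial_id = ipd$trial_id[1] %||% NA_character_,
                 observed = observed,
                 age_sex = r1, age_sex_mm = r2,
                 shift = r2$ratio - r1$ratio,
                 table = data.frame(
                   trial_id = ipd$trial_id[1] %||% NA_character_,
                   observed = observed,
                   expected_age_sex = e1$expected,
                   ratio_age_sex = r1$ratio,
                   lower_age_sex = r1$lower, upper_age_sex = r1$upper,
                   expected_age_sex_mm = e2$expected,
                   ratio_age_sex_mm = r2$ratio,
                   lower_age_sex_mm = r2$lower,
                   upper_age_sex_mm = r2$upper,
                   shift = r2$ratio - r1$ratio,
                   stringsAsFactors = FALSE)),
            class = "dual_standardization")
}

#' @export
print.dual_standardization <- function(x, ...) {
  cat(sprintf(
    "dual standardization [%s]: O/E %.3f (age/sex) vs %.3f (+mm), shift %+.3f\n",
    x$trial_id, x$age_sex$ratio, x$age_sex_mm$ratio, x$shift))
  invisible(x)
}
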