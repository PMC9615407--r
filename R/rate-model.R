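# Sex-stratified Poisson rate models for first urgent hospitalisation or
# death in routine care. Age (and optionally multimorbidity count) enter
# through fractional polynomial terms; log person-days is the offset, so
# fitted rates are per person-day.

rate_model_design <- function(model, age, mm = NULL) {
  Xa <- fp_transform(age, model$age_fp$powers, model$age_fp$shift,
                     model$age_fp$scale)
  colnames(Xa) <- paste0("age_", seq_len(ncol(Xa)))
  if (is.null(model$mm_fp)) {
    if (!is.null(mm))
      stop("multimorbidity count supplied to an age-only rate model",
           call. = FALSE)
    return(Xa)
  }
  if (is.null(mm))
    stop("rate model includes multimorbidity; supply mm counts",
         call. = FALSE)
  Xm <- fp_transform(mm, model$mm_fp$powers, model$mm_fp$shift,
                     model$mm_fp$scale)
  colnames(Xm) <- paste0("mm_", seq_len(ncol(Xm)))
  cbind(Xa, Xm)
}

#' Fit a sex-stratified Poisson SAE rate model
#'
#' Fits first-event (0/1) Poisson regression with `log(person-days)` as
#' offset for one index condition and sex. Age enters through fractional
#' polynomial terms (scaled to decades, `age/10`); optionally the
#' multimorbidity count enters the same way (shifted by +1 so zero counts
#' are in-domain). Powers are selected by [select_fp_powers()] unless
#' supplied.
#'
#' @param cohort a cohort data frame (see [generate_cohort()] /
#'   [read_cohort()]): columns `age`, `sex`, `time_at_risk` (days),
#'   `event`, optionally `mm_count`, and either a `has_<condition>` flag
#'   column or a `condition` column.
#' @param condition index condition name used to subset the cohort.
#' @param sex `"male"` or `"female"`.
#' @param covariates `c("age")` or `c("age", "mm_count")`.
#' @param age_powers,mm_powers optional fixed FP powers; `NULL` selects
#'   them by the closed deviance test.
#' @param select_alpha significance level passed to [select_fp_powers()].
#' @return an object of class `sae_rate_model`: FP specifications,
#'   coefficients, their covariance, the fitted age support, and stratum
#'   totals. Rates are per person-day.
#' @seealso [predict_rate()], [write_rate_model()]
#' @export
fit_rate_model <- function(cohort, condition, sex,
                           covariates = c("age"),
                           age_powers = NULL, mm_powers = NULL,
                           select_alpha = 0.05) {
  stopifnot(sex %in% c("male", "female"))
  covariates <- match.arg(covariates, c("age", "mm_count"), several.ok = TRUE)
  flag <- paste0("has_", condition)
  rows <- if (flag %in% names(cohort)) cohort[[flag]] > 0
          else cohort$condition == condition
  d <- cohort[rows & cohort$sex == sex, , drop = FALSE]
  if (nrow(d) == 0L)
    stop(sprintf("empty stratum: condition '%s', sex '%s'", condition, sex),
         call. = FALSE)
  if (all(d$time_at_risk <= 0))
    stop("no person-time at risk in stratum (all observation censored at day 0)",
         call. = FALSE)
  d <- d[d$time_at_risk > 0, , drop = FALSE]
  if (sum(d$event) == 0L)
    stop(sprintf(
      "zero events in stratum (condition '%s', sex '%s'): rate model is degenerate",
      condition, sex), call. = FALSE)

  use_mm <- "mm_count" %in% covariates
  if (use_mm && !("mm_count" %in% names(d)))
    stop("covariates include mm_count but the cohort has no mm_count column",
         call. = FALSE)

  age_fp <- if (is.null(age_powers)) {
    sel <- select_fp_powers(d$event, d$age, d$time_at_risk,
                            shift = 0, scale = 10, alpha = select_alpha)
    list(powers = sel$powers, shift = 0, scale = 10, selected = TRUE,
         fallback = sel$fallback)
  } else list(powers = sort(age_powers), shift = 0, scale = 10,
              selected = FALSE, fallback = FALSE)

  mm_fp <- NULL
  if (use_mm) {
    mm_fp <- if (is.null(mm_powers)) {
      sel <- select_fp_powers(d$event, d$mm_count + 1, d$time_at_risk,
                              shift = 0, scale = 1, alpha = select_alpha)
      list(powers = sel$powers, shift = 1, scale = 1, selected = TRUE,
           fallback = sel$fallback)
    } else list(powers = sort(mm_powers), shift = 1, scale = 1,
                selected = FALSE, fallback = FALSE)
    # the selector saw mm+1; store shift=1 so callers pass raw counts
  }

  model <- structure(list(condition = condition, sex = sex,
                          basis = if (use_mm) "age_sex_mm" else "age_sex",
                          age_fp = age_fp, mm_fp = mm_fp,
                          time_unit = "person-days"),
                     class = "sae_rate_model")
  X <- rate_model_design(model, d$age,
                         mm = if (use_mm) d$mm_count else NULL)
  fit <- stats::glm(d$event ~ X, family = stats::poisson(),
                    offset = log(d$time_at_risk))
  if (!fit$converged)
    stop("Poisson rate model did not converge", call. = FALSE)
  beta <- stats::coef(fit)
  names(beta) <- c("(Intercept)", colnames(X))
  V <- stats::vcov(fit)
  dimnames(V) <- list(names(beta), names(beta))

  model$coef <- beta
  model$vcov <- V
  model$age_range <- range(d$age)
  model$mm_range <- if (use_mm) range(d$mm_count) else NULL
  model$n <- nrow(d)
  model$n_events <- sum(d$event)
  model$person_time_days <- sum(d$time_at_risk)
  model$deviance <- fit$deviance
  model
}

#' @export
print.sae_rate_model <- function(x, ...) {
  cat(sprintf("SAE rate model (%s): condition '%s', sex %s\n",
              x$basis, x$condition, x$sex))
  cat(sprintf("  age FP powers (%s/10): %s\n",
              "age", paste(x$age_fp$powers, collapse = ", ")))
  if (!is.null(x$mm_fp))
    cat(sprintf("  mm FP powers (mm+1): %s\n",
                paste(x$mm_fp$powers, collapse = ", ")))
  cat(sprintf("  n = %d, events = %d, person-time = %.0f days\n",
              x$n, x$n_events, x$person_time_days))
  cat(sprintf("  fitted ages %d-%d\n", x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' Predict SAE rates from a fitted rate model
#'
#' Evaluates `exp(linear predictor)` at the given ages (and multimorbidity
#' counts, for an `age_sex_mm` model). Ages outside the fitted support
#' extended by 5 years are clamped with a warning. With `draws > 0`, the
#' coefficient vector is sampled from its asymptotic multivariate normal
#' and a matrix of sampled rates is returned alongside the point rates.
#'
#' @param model an `sae_rate_model`.
#' @param age numeric ages in years.
#' @param mm multimorbidity counts (required iff the model includes them).
#' @param draws number of coefficient samples (0 = point prediction only).
#' @param seed optional seed for the coefficient draws.
#' @return rates per person-day: a numeric vector, or when `draws > 0` a
#'   list with `point` and a `length(age) x draws` matrix `draws`.
#' @export
predict_rate <- function(model, age, mm = NULL, draws = 0, seed = NULL) {
  stopifnot(inherits(model, "sae_rate_model"))
  lo <- model$age_range[1] - 5
  hi <- model$age_range[2] + 5
  if (any(age < lo | age > hi)) {
    warning(sprintf(
      "%d age value(s) outside the fitted support [%d, %d] +/- 5y; clamped",
      sum(age < lo | age > hi), model$age_range[1], model$age_range[2]))
    age <- pmin(pmax(age, lo), hi)
  }
  X <- cbind(1, rate_model_design(model, age, mm))
  point <- as.numeric(exp(X %*% model$coef))
  if (draws <= 0) return(point)
  B <- with_seed(seed, rmvnorm_chol(draws, model$coef, model$vcov))
  list(point = point, draws = exp(X %*% t(B)))
}

#' Serialize a rate model to JSON
#'
#' Writes powers, shifts, coefficients, covariance and support range so
#' expectation can run without refitting.
#'
#' @param model an `sae_rate_model`.
#' @param path output file path.
#' @export
write_rate_model <- function(model, path) {
  stopifnot(inherits(model, "sae_rate_model"))
  obj <- unclass(model)
  obj$vcov <- as.vector(model$vcov)
  obj$coef_names <- names(model$coef)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_rate_model
#' @param path path to a JSON file written by [write_rate_model()].
#' @export
read_rate_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(obj$coef_names)
  model <- obj
  model$coef <- stats::setNames(as.numeric(obj$coef), obj$coef_names)
  model$vcov <- matrix(as.numeric(obj$vcov), p, p,
                       dimnames = list(obj$coef_names, obj$coef_names))
  model$coef_names <- NULL
  if (!is.null(model$mm_fp) && length(model$mm_fp) == 0) model$mm_fp <- NULL
  structure(model, class = "sae_rate_model")
}
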