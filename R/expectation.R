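# Expected SAE counts by indirect standardization: routine-care rates
# applied to the trial's age/sex (optionally multimorbidity) structure.

#' Aggregate-trial person-time approximation
#'
#' `followup_days * n - 0.5 * followup_days * events`: each incident
#' event is assumed to occur, on average, halfway through follow-up.
#' When `events > n` the result is floored at half the full person-time
#' with a warning.
#'
#' @param n number of participants (> 0).
#' @param followup_days follow-up duration in days.
#' @param events incident event count (>= 0).
#' @return person-days at risk.
#' @examples
#' aggregate_person_time(100, 182, 10)  # 17290
#' @export
aggregate_person_time <- function(n, followup_days, events) {
  if (n <= 0 || followup_days < 0 || events < 0)
    stop("n must be positive; followup_days and events nonnegative",
         call. = FALSE)
  pt <- followup_days * n - 0.5 * followup_days * events
  floor_pt <- 0.5 * followup_days * n
  if (events > n) {
    warning("more events than participants; person-time floored at half the full follow-up")
    pt <- max(pt, floor_pt)
  }
  pt
}

new_expected_count <- function(trial_id, expected, basis, draws,
                               person_time_days, flags = character(0)) {
  structure(list(trial_id = trial_id, expected = expected, basis = basis,
                 draws = draws, person_time_days = person_time_days,
                 flags = flags),
            class = "sae_expected")
}

#' @export
print.sae_expected <- function(x, ...) {
  cat(sprintf("expected SAEs (%s)%s: %.2f over %.0f person-days%s\n",
              x$basis,
              if (is.na(x$trial_id)) "" else paste0(" for ", x$trial_id),
              x$expected, x$person_time_days,
              if (length(x$draws)) sprintf(" [%d draws]", length(x$draws))
              else ""))
  invisible(x)
}

#' Expected SAE count for an aggregate trial
#'
#' Indirect standardization over reconstructed one-year age bands: each
#' (sex, band) cell contributes `rate(mid-band age, sex) * cell
#' person-time`, and cells are summed. Cell person-time starts from the
#' full follow-up apportioned by cell weight; the event-driven deficit
#' (`0.5 * follow-up * events`, as in [aggregate_person_time()]) is then
#' apportioned across cells proportionally to each cell's expected event
#' share, since high-rate cells lose more exposure to early events than
#' low-rate cells. The cell person-times always sum to the
#' [aggregate_person_time()] total. Uncertainty draws repeat the
#' computation with coefficient-sampled rates.
#'
#' @param models named list with `male` and `female` `sae_rate_model`s
#'   (a missing model is an error only if that sex has positive weight).
#' @param dist an `age_sex_distribution` from
#'   [reconstruct_age_distribution()].
#' @param n,followup_days,events the trial's size, follow-up and
#'   observed SAE count (events enter only through person-time).
#' @param n_draws number of coefficient-sampled expected counts (0 for
#'   none).
#' @param seed seed for the draws.
#' @return an `sae_expected` object.
#' @export
expected_events_aggregate <- function(models, dist, n, followup_days,
                                      events, n_draws = 0, seed = NULL) {
  stopifnot(inherits(dist, "age_sex_distribution"))
  pt_total <- aggregate_person_time(n, followup_days, events)
  deficit <- n * followup_days - pt_total   # 0.5 * FU * events (floored)
  mid <- dist$bands$age + 0.5
  rates <- list(); wts <- list(); rate_draws <- list()
  for (sx in c("female", "male")) {
    prop <- unname(dist$sex_prop[sx])
    if (prop <= 0) next
    model <- models[[sx]]
    if (is.null(model))
      stop(sprintf("no rate model for sex '%s' (proportion %.3f)", sx, prop),
           call. = FALSE)
    if (n_draws > 0) {
      pr <- predict_rate(model, mid, draws = n_draws,
                         seed = if (is.null(seed)) NULL else
                           seed + (sx == "female"))
      rates[[sx]] <- pr$point
      rate_draws[[sx]] <- pr$draws
    } else {
      rates[[sx]] <- predict_rate(model, mid)
    }
    wts[[sx]] <- prop * dist$bands$weight
  }
  r <- unlist(rates, use.names = FALSE)
  w <- unlist(wts, use.names = FALSE)
  pt_naive <- n * followup_days * w
  share <- if (sum(r * pt_naive) > 0) (r * pt_naive) / sum(r * pt_naive)
           else w
  pt_cell <- pt_naive - deficit * share
  expected <- sum(r * pt_cell)
  draws <- NULL
  if (n_draws > 0) {
    D <- do.call(rbind, rate_draws)   # cells x n_draws
    draws <- as.numeric(crossprod(D, pt_cell))
  }
  new_expected_count(dist$trial_id, expected, "age_sex", draws, pt_total)
}

#' Expected SAE count for an IPD trial
#'
#' Sums `rate(age, sex[, mm]) * followup_days_i` over participants:
#' exact individual exposure, so no half-event person-time correction is
#' needed. With `basis = "age_sex_mm"` the models must include
#' multimorbidity and the IPD must carry `mm_count`.
#'
#' @param models named list with `male`/`female` `sae_rate_model`s of
#'   the requested basis.
#' @param ipd participant table: `age`, `sex`, `followup_days`, and
#'   `mm_count` for the multimorbidity basis.
#' @param basis `"age_sex"` or `"age_sex_mm"`.
#' @param n_draws,seed coefficient-sampling controls as in
#'   [expected_events_aggregate()].
#' @return an `sae_expected` object.
#' @export
expected_events_ipd <- function(models, ipd, basis = c("age_sex",
                                                       "age_sex_mm"),
                                n_draws = 0, seed = NULL) {
  basis <- match.arg(basis)
  require_columns(ipd, c("age", "sex", "followup_days"), "trial IPD")
  if (any(ipd$followup_days <= 0))
    stop("all participant follow-up durations must be positive",
         call. = FALSE)
  use_mm <- basis == "age_sex_mm"
  if (use_mm && !"mm_count" %in% names(ipd))
    stop("basis 'age_sex_mm' requested but the IPD has no mm_count column",
         call. = FALSE)
  expected <- 0
  pt_total <- sum(ipd$followup_days)
  draws <- if (n_draws > 0) numeric(n_draws) else NULL
  for (sx in c("female", "male")) {
    d <- ipd[ipd$sex == sx, , drop = FALSE]
    if (nrow(d) == 0L) next
    model <- models[[sx]]
    if (is.null(model))
      stop(sprintf("no rate model for sex '%s' (%d participants)",
                   sx, nrow(d)), call. = FALSE)
    if (use_mm && model$basis != "age_sex_mm")
      stop("basis 'age_sex_mm' requires multimorbidity-adjusted rate models",
           call. = FALSE)
    # aggregate identical (age[, mm]) cells: exposure is additive
    key <- if (use_mm) paste(d$age, d$mm_count) else as.character(d$age)
    t_cell <- tapply(d$followup_days, key, sum)
    first <- d[!duplicated(key), , drop = FALSE]
    ord <- match(names(t_cell),
                 if (use_mm) paste(first$age, first$mm_count)
                 else as.character(first$age))
    first <- first[ord, , drop = FALSE]
    if (n_draws > 0) {
      pr <- predict_rate(model, first$age,
                         mm = if (use_mm) first$mm_count else NULL,
                         draws = n_draws,
                         seed = if (is.null(seed)) NULL else
                           seed + (sx == "female"))
      expected <- expected + sum(pr$point * as.numeric(t_cell))
      draws <- draws + as.numeric(crossprod(pr$draws, as.numeric(t_cell)))
    } else {
      r <- predict_rate(model, first$age,
                        mm = if (use_mm) first$mm_count else NULL)
      expected <- expected + sum(r * as.numeric(t_cell))
    }
  }
  new_expected_count(ipd$trial_id[1] %||% NA_character_, expected, basis,
                     draws, pt_total)
}
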