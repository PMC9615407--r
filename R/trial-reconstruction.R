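# Reconstructing per-sex one-year age-band weights for aggregate trials
# from the four registry statistics (age mean, SD, min, max). A normal
# distribution truncated to the reported bounds is moment-matched to the
# reported mean and SD; band weights are truncated-normal CDF increments.

# mean and sd of N(mu, sigma) truncated to [a, b], computed in log
# space so far-tail truncations (|standardized bound| >> 1) stay stable
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  # far-tail truncation: the conditional law is a truncated exponential
  # with rate |alpha|/sigma to O(1/alpha^2); the direct formulas cancel
  # catastrophically there (mu and sigma*phi/Z are huge and opposite)
  if (al > 30 || be < -30) {
    lam <- if (al > 30) al / sigma else -be / sigma
    L <- b - a
    w <- lam * L
    if (w < 1e-6) {
      m_off <- L / 2
      v <- L^2 / 12
    } else {
      ew <- exp(-w)
      m_off <- 1 / lam - L * ew / (1 - ew)
      v <- 1 / lam^2 - L^2 * ew / (1 - ew)^2
    }
    m <- if (al > 30) a + m_off else b - m_off
    return(c(mean = m, sd = sqrt(max(v, 0))))
  }
  # log Z = log(Phi(be) - Phi(al)), via whichever tail is stable
  logZ <- if (al > 0) {
    lu <- stats::pnorm(al, lower.tail = FALSE, log.p = TRUE)
    lv <- stats::pnorm(be, lower.tail = FALSE, log.p = TRUE)
    lu + log1p(-exp(lv - lu))
  } else {
    lu <- stats::pnorm(be, log.p = TRUE)
    lv <- stats::pnorm(al, log.p = TRUE)
    lu + log1p(-exp(lv - lu))
  }
  if (!is.finite(logZ)) {
    edge <- if (mu < a) a else b
    return(c(mean = edge, sd = 0))
  }
  ha <- exp(stats::dnorm(al, log = TRUE) - logZ)  # phi(al)/Z
  hb <- exp(stats::dnorm(be, log = TRUE) - logZ)
  m <- mu + sigma * (ha - hb)
  v <- sigma^2 * (1 + al * ha - be * hb - (ha - hb)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Solve for the parent normal of a truncated normal with given moments
#'
#' Finds `(mu, sigma)` such that N(mu, sigma) truncated to
#' `[lower, upper]` has the requested mean and standard deviation, to an
#' absolute tolerance of 1e-6 years on both. The supremum of the
#' truncated-normal SD on an interval is the uniform SD,
#' `(upper - lower) / sqrt(12)`; with the mean constrained off-centre the
#' attainable SD is smaller still (the family limits to a tilted
#' exponential). When the requested SD is unattainable (or the solver
#' cannot reach the tolerance) the maximum-entropy fallback — uniform on
#' `[lower, upper]` — is returned with `fallback = TRUE`.
#'
#' @param mean,sd requested moments of the truncated distribution
#'   (`lower <= mean <= upper`, `sd > 0`).
#' @param lower,upper truncation bounds, `lower < upper`.
#' @return list with `mu`, `sigma`, `fallback`, and the achieved
#'   `residual = c(mean error, sd error)` (NA for the fallback).
#' @export
truncated_normal_from_moments <- function(mean, sd, lower, upper) {
  if (!(lower < upper)) stop("need lower < upper", call. = FALSE)
  if (mean < lower || mean > upper)
    stop(sprintf("mean %.3f outside bounds [%.3f, %.3f]", mean, lower, upper),
         call. = FALSE)
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  fallback <- list(mu = NA_real_, sigma = NA_real_, fallback = TRUE,
                   residual = c(NA_real_, NA_real_))
  sd_sup <- (upper - lower) / sqrt(12)
  if (sd >= sd_sup * (1 - 1e-9)) return(fallback)
  # profiled solve: for each sigma, the truncated mean is strictly
  # increasing in mu with range (lower, upper), so mu(sigma) is a 1-D
  # root; the profiled truncated sd then increases in sigma, giving a
  # second 1-D root. This is robust even near the sd supremum, where
  # sigma and |mu| diverge (the tilted-exponential limit).
  mu_for_mean <- function(sigma) {
    f <- function(mu) truncnorm_moments(mu, sigma, lower, upper)["mean"] - mean
    # when sigma >> (b - a) the family acts through the exponential tilt
    # mu / sigma^2, so the bracket must widen like sigma^2
    span <- 10 * sigma + 200 * sigma^2 / (upper - lower) + (upper - lower)
    stats::uniroot(f, c(lower - span, upper + span), tol = 1e-12)$root
  }
  g <- function(sigma)
    truncnorm_moments(mu_for_mean(sigma), sigma, lower, upper)["sd"] - sd
  sig_lo <- sd / 4
  sig_hi <- 200 * (upper - lower)
  if (g(sig_lo) > 0) sig_lo <- sd / 100
  if (g(sig_lo) > 0 || g(sig_hi) < 0) return(fallback)
  sigma <- stats::uniroot(g, c(sig_lo, sig_hi), tol = 1e-12)$root
  mu <- mu_for_mean(sigma)
  got <- truncnorm_moments(mu, sigma, lower, upper)
  resid <- c(got["mean"] - mean, got["sd"] - sd)
  if (any(abs(resid) > 1e-6)) return(fallback)
  list(mu = mu, sigma = sigma, fallback = FALSE, residual = unname(resid))
}

#' Reconstruct a trial's age/sex distribution from summary statistics
#'
#' Converts one aggregate-trial row into per-sex weights over one-year
#' age bands `[a, a+1)`. The same age distribution is used for both
#' sexes (registries report age unstratified by sex), split by
#' `percent_female`. A missing `age_sd` is imputed as
#' `(age_max - age_min) / 4` and flagged. Degenerate bounds
#' (`age_min == age_max`) give a point mass. The reconstruction is
#' deterministic.
#'
#' @param summary one-row data frame or list with `age_mean`, `age_sd`,
#'   `age_min`, `age_max`, `percent_female` (and optionally `trial_id`).
#' @return object of class `age_sex_distribution`: `bands` (data frame
#'   `age`, `weight`, weights summing to 1), `sex_prop` (named vector
#'   female/male), `flags` (character), `trial_id`.
#' @export
reconstruct_age_distribution <- function(summary) {
  s <- as.list(summary)
  for (f in c("age_mean", "age_min", "age_max", "percent_female"))
    if (is.null(s[[f]]) || is.na(s[[f]]))
      stop(sprintf("trial summary is missing '%s'", f), call. = FALSE)
  if (s$age_min > s$age_max)
    stop(sprintf("trial %s: age_min > age_max", s$trial_id %||% "?"),
         call. = FALSE)
  flags <- character(0)
  out <- function(bands) {
    structure(list(bands = bands,
                   sex_prop = c(female = s$percent_female / 100,
                                male = 1 - s$percent_female / 100),
                   flags = flags,
                   trial_id = s$trial_id %||% NA_character_),
              class = "age_sex_distribution")
  }
  if (s$age_min == s$age_max) {
    return(out(data.frame(age = floor(s$age_min), weight = 1)))
  }
  if (is.null(s$age_sd) || is.na(s$age_sd)) {
    s$age_sd <- (s$age_max - s$age_min) / 4
    flags <- c(flags, "sd_imputed")
  }
  sol <- truncated_normal_from_moments(s$age_mean, s$age_sd,
                                       s$age_min, s$age_max)
  ages <- seq.int(floor(s$age_min), ceiling(s$age_max) - 1L)
  if (sol$fallback) {
    flags <- c(flags, "uniform_fallback")
    cdf <- function(x) pmin(pmax((x - s$age_min) / (s$age_max - s$age_min),
                                 0), 1)
  } else {
    Z <- stats::pnorm(s$age_max, sol$mu, sol$sigma) -
      stats::pnorm(s$age_min, sol$mu, sol$sigma)
    cdf <- function(x) {
      x <- pmin(pmax(x, s$age_min), s$age_max)
      (stats::pnorm(x, sol$mu, sol$sigma) -
         stats::pnorm(s$age_min, sol$mu, sol$sigma)) / Z
    }
  }
  w <- cdf(ages + 1) - cdf(ages)
  w <- w / sum(w)
  out(data.frame(age = ages, weight = w))
}

#' @export
print.age_sex_distribution <- function(x, ...) {
  cat(sprintf(
    "age/sex distribution%s: %d band(s) over ages %d-%d, %.1f%% female%s\n",
    if (is.na(x$trial_id)) "" else paste0(" for ", x$trial_id),
    nrow(x$bands), min(x$bands$age), max(x$bands$age),
    100 * x$sex_prop["female"],
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
    else ""))
  invisible(x)
}

#' Reconstruct distributions for a whole aggregate-trial table
#'
#' @param summaries trial summary data frame (one row per trial).
#' @return named list of `age_sex_distribution` objects keyed by
#'   `trial_id`.
#' @export
reconstruct_all <- function(summaries) {
  out <- lapply(seq_len(nrow(summaries)), function(i)
    reconstruct_age_distribution(summaries[i, , drop = FALSE]))
  names(out) <- summaries$trial_id
  out
}
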