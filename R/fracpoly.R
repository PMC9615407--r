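#' Fractional polynomial basis transform
#'
#' Builds the fractional-polynomial (FP) design columns for a positive
#' covariate following the Royston--Altman convention: power `p` maps to
#' `x^p`, power `0` maps to `log(x)`, and a repeated power `p` contributes
#' the pair `(x^p, x^p * log(x))`. The covariate is first shifted and
#' scaled, `z = (x + shift) / scale`, which must leave it strictly
#' positive.
#'
#' @param x numeric vector of covariate values.
#' @param powers numeric vector of length 1 or 2 with entries from
#'   `fp_power_set()`.
#' @param shift value added to `x` before transforming (default 0).
#' @param scale positive divisor applied after shifting (default 1).
#' @return numeric matrix with one column per FP term, named e.g.
#'   `"fp(age)^0.5"`.
#' @examples
#' fp_transform(2, powers = c(2, 2))   # (4, 4 * log 2)
#' @export
fp_transform <- function(x, powers, shift = 0, scale = 1) {
  stopifnot(is.numeric(x), length(powers) %in% 1:2, scale > 0)
  z <- (x + shift) / scale
  if (any(z <= 0, na.rm = TRUE)) {
    need <- -min(x, na.rm = TRUE) + scale * 1e-8
    stop(sprintf(
      "fractional polynomial transform needs a strictly positive argument; smallest value is %.4g (a shift of at least %.4g is required)",
      min(z, na.rm = TRUE) * scale - shift, need), call. = FALSE)
  }
  powers <- sort(powers)
  one <- function(p) if (p == 0) log(z) else z^p
  if (length(powers) == 1L) {
    out <- cbind(one(powers))
    colnames(out) <- sprintf("fp^%g", powers)
  } else if (powers[1] == powers[2]) {
    b <- one(powers[1])
    out <- cbind(b, b * log(z))
    colnames(out) <- sprintf(c("fp^%g", "fp^%g*log"), powers[1])
  } else {
    out <- cbind(one(powers[1]), one(powers[2]))
    colnames(out) <- sprintf("fp^%g", powers)
  }
  out
}

#' Conventional fractional polynomial power set
#'
#' @return the eight candidate powers `{-2, -1, -0.5, 0, 0.5, 1, 2, 3}`.
#' @export
fp_power_set <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

# All FP1 candidates (8) and FP2 candidates (36: 28 distinct pairs + 8
# repeated powers).
fp_candidates <- function(degree) {
  ps <- fp_power_set()
  if (degree == 1L) return(lapply(ps, function(p) p))
  out <- list()
  for (i in seq_along(ps)) for (j in i:length(ps))
    out[[length(out) + 1L]] <- c(ps[i], ps[j])
  out
}

# Deviance of a Poisson fit of events on the FP basis of x with a log
# person-time offset. Returns NA when the fit fails or does not converge.
fp_deviance <- function(y, x, offset, powers, shift, scale) {
  X <- fp_transform(x, powers, shift, scale)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(cbind(1, X), y, offset = offset,
                                    family = stats::poisson())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NA_real_)
  fit$deviance
}

#' Select fractional polynomial powers by a deviance-based closed test
#'
#' Exhaustively fits all degree-1 and degree-2 fractional polynomial
#' Poisson models (log person-time offset) for one covariate and applies a
#' closed testing procedure: the best FP2 is kept if it improves on the
#' best FP1 by a chi-squared test on 2 degrees of freedom at `alpha`;
#' otherwise the best FP1 is kept if it improves on the straight line
#' (power 1) at the same 2-df level; otherwise the linear model is
#' returned. Strata with fewer than `min_events` events fall back to the
#' linear power with a warning.
#'
#' @param events 0/1 (or count) outcome vector.
#' @param x covariate (e.g. age in years).
#' @param person_time exposure per record, in the same unit throughout.
#' @param shift,scale applied to `x` before transforming; defaults keep
#'   `x/scale` strictly positive for ages.
#' @param alpha significance level of the closed test (default 0.05).
#' @param min_events minimum events required to attempt selection
#'   (default 50).
#' @return list with elements `powers`, `shift`, `scale`, `deviance`, and
#'   `fallback` (TRUE when the low-event linear fallback fired).
#' @export
select_fp_powers <- function(events, x, person_time, shift = 0, scale = 1,
                             alpha = 0.05, min_events = 50) {
  stopifnot(length(events) == length(x), length(x) == length(person_time))
  keep <- person_time > 0 & !is.na(events) & !is.na(x)
  events <- events[keep]; x <- x[keep]; person_time <- person_time[keep]
  off <- log(person_time)
  res <- function(p, dev, fb = FALSE)
    list(powers = p, shift = shift, scale = scale, deviance = dev,
         fallback = fb)
  if (sum(events) < min_events) {
    warning(sprintf(
      "only %d events in stratum (< %d); falling back to a linear term",
      sum(events), min_events))
    return(res(1, fp_deviance(events, x, off, 1, shift, scale), fb = TRUE))
  }
  dev1 <- vapply(fp_candidates(1L), function(p)
    fp_deviance(events, x, off, p, shift, scale), numeric(1))
  cands2 <- fp_candidates(2L)
  dev2 <- vapply(cands2, function(p)
    fp_deviance(events, x, off, p, shift, scale), numeric(1))
  if (all(is.na(dev1)) && all(is.na(dev2)))
    stop("no fractional polynomial candidate converged", call. = FALSE)
  dev_lin <- dev1[[which(vapply(fp_candidates(1L), identical, logical(1), 1))]]
  b1 <- which.min(dev1)
  b2 <- which.min(dev2)
  crit <- stats::qchisq(1 - alpha, df = 2)
  if (length(b2) && length(b1) &&
      isTRUE(dev1[b1] - dev2[b2] > crit)) {
    return(res(cands2[[b2]], dev2[b2]))
  }
  if (length(b1) && isTRUE(dev_lin - dev1[b1] > crit)) {
    return(res(fp_candidates(1L)[[b1]], dev1[b1]))
  }
  res(1, dev_lin)
}
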