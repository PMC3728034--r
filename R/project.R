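#' Attributable-risk-deflated baseline hazard
#'
#' The registry incidence rate in each age bin reflects the population mix of
#' risk-factor levels. Multiplying by one minus the attributable risk deflates
#' it to the hazard of a woman with every factor at its reference (lowest
#' risk) level, so that `baseline * rr(x)` recovers a covariate-specific
#' hazard consistent with the population rates.
#'
#' @param bundle A `model_bundle`.
#' @return A [rate_table()] with `rate[j] = incidence_corrected[j] * (1 - AR)`,
#'   still in events per 100,000 person-years.
#' @export
baseline_hazard <- function(bundle) {
  stopifnot(inherits(bundle, "model_bundle"))
  rate_table(bundle$incidence_corrected$age_lo,
             bundle$incidence_corrected$age_hi,
             bundle$incidence_corrected$rate_per_100k *
               (1 - bundle$attributable_risk))
}

# Vectorized piecewise-constant competing-risk projection.
# rr, age_start, age_end are equal-length vectors (or length 1, recycled);
# h10, h2 are per-year hazards per age bin (length = number of bins).
# Returns a list of vectors: absolute_risk, prob_competing_death,
# prob_event_free.
project_many <- function(rr, age_start, age_end, bins, h10, h2) {
  n <- max(length(rr), length(age_start), length(age_end))
  rr <- rep_len(rr, n); a <- rep_len(age_start, n); b <- rep_len(age_end, n)
  if (any(a < bins$age_lo[1] - 1e-9) || any(b > bins$age_hi[nrow(bins)] + 1e-9))
    stop("projection ages must lie within [",
         bins$age_lo[1], ", ", bins$age_hi[nrow(bins)], ")", call. = FALSE)
  if (any(a > b)) stop("age_start must not exceed age_end", call. = FALSE)
  pi1 <- pi2 <- numeric(n)
  surv <- rep(1, n)
  for (j in seq_len(nrow(bins))) {
    d <- pmax(0, pmin(b, bins$age_hi[j]) - pmax(a, bins$age_lo[j]))
    if (all(d == 0)) next
    h1 <- rr * h10[j]
    h <- h1 + h2[j]
    fail <- ifelse(h > 0, -expm1(-h * d), 0)
    frac1 <- ifelse(h > 0, h1 / h, 0)
    pi1 <- pi1 + surv * frac1 * fail
    pi2 <- pi2 + surv * (1 - frac1) * fail
    surv <- surv * exp(-h * d)
  }
  list(absolute_risk = pi1, prob_competing_death = pi2, prob_event_free = surv)
}

#' Project absolute risk over an age interval
#'
#' Computes the probability `pi(a, b)` of developing the bundle's cancer in
#' the age interval `(a, b]`, given the woman is alive and free of that cancer
#' at age `a`. The cause-specific cancer hazard is
#' `h1_j = baseline_j * rr(x)` per 5-year age bin and the competing hazard
#' `h2_j` is the covariate-free competing mortality (plus the organ-removal
#' rate when `include_organ_removal_competing = TRUE`). With piecewise
#' constant hazards the projection is the closed-form sum
#' `pi = sum_j S_j * h1_j/(h1_j+h2_j) * (1 - exp(-(h1_j+h2_j) * d_j))`
#' where `d_j` is the overlap of `[a, b)` with bin j and `S_j` the probability
#' of reaching bin j free of both events. Covariates are held fixed at their
#' baseline values for the whole projection.
#'
#' @param profile A [risk_factor_profile()].
#' @param age_start,age_end Projection interval, `50 <= age_start <
#'   age_end <= 90`; partial 5-year bins are handled by applying the bin's
#'   constant hazards over the partial width.
#' @param bundle A `model_bundle`.
#' @param include_organ_removal_competing If `TRUE` and the bundle carries
#'   organ-removal rates, hysterectomy/oophorectomy is added to the competing
#'   hazard, allowing for loss of the organ at risk during the projection.
#'   Off by default.
#' @return A `projection_result`: `absolute_risk`, `prob_competing_death`,
#'   `prob_event_free` (the three sum to 1), `relative_risk`, and a
#'   `per_interval` data frame decomposing the risk over age bins.
#' @examples
#' b <- beo_bundle("ovarian")
#' p <- risk_factor_profile(current_age = 50, parity = 3)
#' absolute_risk(p, 50, 60, b)
#' @export
absolute_risk <- function(profile, age_start, age_end, bundle,
                          include_organ_removal_competing = FALSE) {
  stopifnot(inherits(bundle, "model_bundle"))
  rr <- relative_risk_levels(encode_levels(profile, bundle$rr_model),
                             bundle$rr_model)
  stopifnot(length(rr) == 1L)
  base <- baseline_hazard(bundle)
  h10 <- hazard_per_year(base)
  h2 <- hazard_per_year(bundle$competing_mortality)
  if (include_organ_removal_competing) {
    if (is.null(bundle$organ_removal_rates))
      stop("bundle carries no organ-removal rates", call. = FALSE)
    h2 <- h2 + hazard_per_year(bundle$organ_removal_rates)
  }
  res <- project_many(rr, age_start, age_end, base, h10, h2)

  d <- bin_overlap(base, age_start, age_end)
  keep <- d > 0
  h1 <- rr * h10
  h <- h1 + h2
  surv_start <- cumprod(c(1, exp(-h * d)))[seq_len(nrow(base))]
  contrib <- surv_start * ifelse(h > 0, h1 / h, 0) * -expm1(-h * d)
  per_interval <- data.frame(
    age_lo = pmax(base$age_lo, age_start)[keep],
    age_hi = pmin(base$age_hi, age_end)[keep],
    hazard_cancer = h1[keep],
    hazard_competing = h2[keep],
    surv_at_start = surv_start[keep],
    contribution = contrib[keep])

  structure(list(cancer = bundle$cancer,
                 age_start = age_start, age_end = age_end,
                 relative_risk = rr,
                 absolute_risk = res$absolute_risk,
                 prob_competing_death = res$prob_competing_death,
                 prob_event_free = res$prob_event_free,
                 per_interval = per_interval),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf(
    "%s cancer risk, ages %g-%g (rr = %.3f)\n", x$cancer, x$age_start,
    x$age_end, x$relative_risk))
  cat(sprintf("  absolute risk        %6.2f%%\n", 100 * x$absolute_risk))
  cat(sprintf("  competing death      %6.2f%%\n", 100 * x$prob_competing_death))
  cat(sprintf("  event-free survival  %6.2f%%\n", 100 * x$prob_event_free))
  invisible(x)
}

#' Attributable risk from a set of relative risks
#'
#' One minus the number of women divided by the sum of their multivariate
#' relative risks: the fraction of incidence attributable to risk-factor
#' levels above the reference. Used to deflate registry incidence rates into
#' reference-profile baseline hazards.
#'
#' @param rr_values Non-empty numeric vector of positive relative risks, one
#'   per woman.
#' @return `1 - length(rr_values) / sum(rr_values)`, a scalar below 1 (zero
#'   when every woman is at reference, negative if risks average below 1).
#' @examples
#' attributable_risk(c(1, 1, 3, 3))
#' @export
attributable_risk <- function(rr_values) {
  if (length(rr_values) == 0L)
    stop("rr_values must be non-empty", call. = FALSE)
  if (any(!is.finite(rr_values)) || any(rr_values <= 0))
    stop("all relative risks must be positive", call. = FALSE)
  1 - length(rr_values) / sum(rr_values)
}
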