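#' Age-binned event rate table
#'
#' A `rate_table` stores event rates per 100,000 person-years on contiguous,
#' non-overlapping, half-open 5-year age intervals covering \[50, 90). The
#' final registry age group "85+" is treated as \[85, 90); projections are
#' capped at age 90. Rates are stored exactly as printed in registry tables;
#' conversion to per-year hazards happens only inside the projection engine.
#'
#' @param age_lo,age_hi Numeric vectors of interval bounds; intervals are
#'   left-closed, right-open.
#' @param rate_per_100k Nonnegative rates in events per 100,000 person-years.
#' @return An object of class `rate_table` (a data frame with columns
#'   `age_lo`, `age_hi`, `rate_per_100k`).
#' @examples
#' rt <- rate_table(seq(50, 85, 5), seq(55, 90, 5), rep(100, 8))
#' hazard_per_year(rt)
#' @export
rate_table <- function(age_lo, age_hi, rate_per_100k) {
  x <- data.frame(age_lo = as.numeric(age_lo),
                  age_hi = as.numeric(age_hi),
                  rate_per_100k = as.numeric(rate_per_100k))
  class(x) <- c("rate_table", "data.frame")
  validate_rate_table(x)
  x
}

validate_rate_table <- function(x, what = "rate table") {
  stopifnot(is.data.frame(x),
            all(c("age_lo", "age_hi", "rate_per_100k") %in% names(x)))
  if (nrow(x) == 0L) stop(what, " is empty", call. = FALSE)
  if (any(x$age_hi <= x$age_lo))
    stop(what, ": intervals must have age_hi > age_lo", call. = FALSE)
  if (is.unsorted(x$age_lo, strictly = TRUE))
    stop(what, ": bins must be in increasing age order", call. = FALSE)
  if (any(abs(x$age_lo[-1] - x$age_hi[-nrow(x)]) > 1e-9))
    stop(what, ": bins must be contiguous (gap or overlap found)", call. = FALSE)
  if (abs(x$age_lo[1] - 50) > 1e-9 || abs(x$age_hi[nrow(x)] - 90) > 1e-9)
    stop(what, ": bins must cover [50, 90)", call. = FALSE)
  if (any(is.na(x$rate_per_100k)) || any(x$rate_per_100k < 0))
    stop(what, ": rates must be nonnegative and non-missing", call. = FALSE)
  invisible(x)
}

#' @rdname rate_table
#' @param x A `rate_table`.
#' @export
hazard_per_year <- function(x) {
  validate_rate_table(x)
  x$rate_per_100k / 1e5
}

#' Intact-organ prevalence table
#'
#' Fraction of women with an intact uterus (endometrial model) or intact
#' ovaries (ovarian model) per 5-year age bin, used to convert whole-population
#' registry incidence to incidence among women still at risk.
#'
#' @param age_lo,age_hi Interval bounds as in [rate_table()].
#' @param proportion_with_organ Values in (0, 1] per bin.
#' @return An object of class `prevalence_table`.
#' @export
prevalence_table <- function(age_lo, age_hi, proportion_with_organ) {
  x <- data.frame(age_lo = as.numeric(age_lo),
                  age_hi = as.numeric(age_hi),
                  proportion_with_organ = as.numeric(proportion_with_organ))
  if (any(is.na(x$proportion_with_organ)) ||
      any(x$proportion_with_organ <= 0) || any(x$proportion_with_organ > 1))
    stop("proportion_with_organ must lie in (0, 1]", call. = FALSE)
  class(x) <- c("prevalence_table", "data.frame")
  x
}

#' Correct registry rates for organ removal prevalence
#'
#' Registry incidence rates for endometrial and ovarian cancer are computed
#' over all women in the population, including women whose uterus or ovaries
#' have been removed and who are no longer at risk. Dividing each age bin's
#' rate by the proportion of women with the organ intact converts the
#' population rate to the rate among women actually at risk.
#'
#' @param raw A [rate_table()] of uncorrected registry rates.
#' @param prevalence A [prevalence_table()] on the same age bins.
#' @return A [rate_table()] with `corrected[j] = raw[j] / proportion[j]`.
#' @examples
#' raw <- rate_table(seq(50, 85, 5), seq(55, 90, 5), rep(77.5, 8))
#' prev <- prevalence_table(seq(50, 85, 5), seq(55, 90, 5), rep(0.6076, 8))
#' correct_rates(raw, prev)
#' @export
correct_rates <- function(raw, prevalence) {
  validate_rate_table(raw, "raw rate table")
  if (!inherits(prevalence, "prevalence_table"))
    stop("prevalence must be a prevalence_table", call. = FALSE)
  if (nrow(raw) != nrow(prevalence) ||
      any(abs(raw$age_lo - prevalence$age_lo) > 1e-9) ||
      any(abs(raw$age_hi - prevalence$age_hi) > 1e-9))
    stop("age bins of raw rates and prevalence table do not match", call. = FALSE)
  rate_table(raw$age_lo, raw$age_hi,
             raw$rate_per_100k / prevalence$proportion_with_organ)
}

# width of overlap of [a, b) with each bin of a rate table
bin_overlap <- function(x, a, b) {
  pmax(0, pmin(b, x$age_hi) - pmax(a, x$age_lo))
}
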