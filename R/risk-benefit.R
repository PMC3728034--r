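#' Risk-benefit arithmetic for an intervention affecting two outcomes
#'
#' For an intervention that multiplies the hazard of outcome A by one factor
#' and outcome B by another (the motivating example is tamoxifen, which
#' roughly halves breast cancer risk while increasing endometrial cancer risk
#' about 4-fold in older women), the change in each absolute risk is
#' `baseline * (multiplier - 1)`, reported in percentage points. The summary
#' compares the magnitudes of the two changes only; it deliberately does not
#' weigh the relative lethality of the outcomes.
#'
#' @param baseline_risk_a,baseline_risk_b Baseline absolute risks in \[0, 1\]
#'   (e.g. 5-year projected risks).
#' @param rr_multiplier_a,rr_multiplier_b Positive multipliers the
#'   intervention applies to each risk.
#' @param label_a,label_b Outcome names used in the summary.
#' @return A list of class `risk_benefit`: `delta_a`, `delta_b` (percentage
#'   points, signed) and a one-line `summary`.
#' @examples
#' # 2.5% breast risk halved vs 0.41% endometrial risk quadrupled
#' risk_benefit(0.025, 0.5, 0.0041, 4)
#' @export
risk_benefit <- function(baseline_risk_a, rr_multiplier_a,
                         baseline_risk_b, rr_multiplier_b,
                         label_a = "outcome A", label_b = "outcome B") {
  stopifnot(baseline_risk_a >= 0, baseline_risk_a <= 1,
            baseline_risk_b >= 0, baseline_risk_b <= 1,
            rr_multiplier_a > 0, rr_multiplier_b > 0)
  delta_a <- 100 * baseline_risk_a * (rr_multiplier_a - 1)
  delta_b <- 100 * baseline_risk_b * (rr_multiplier_b - 1)
  cmp <- if (abs(delta_a) > abs(delta_b)) "exceeds"
         else if (abs(delta_a) < abs(delta_b)) "is exceeded by"
         else "equals"
  summary <- sprintf(
    "%s changes by %+.2f percentage points; its magnitude %s the %+.2f change in %s",
    label_a, delta_a, cmp, delta_b, label_b)
  structure(list(delta_a = delta_a, delta_b = delta_b, summary = summary),
            class = "risk_benefit")
}

#' @export
print.risk_benefit <- function(x, ...) {
  cat(x$summary, "\n")
  invisible(x)
}
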