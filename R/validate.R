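#' Expected number of cases in a cohort
#'
#' Sums each woman's projected probability of the bundle's cancer over her
#' own follow-up interval: `E = sum_i pi(entry_i, exit_i; x_i)`. Follow-up
#' outside the model's age support \[50, 90) is clipped with a warning.
#'
#' @param cohort A data frame of cohort records: columns `entry_age`,
#'   `exit_age`, `event` (logical), plus the risk-factor profile fields of
#'   [risk_factor_profile()].
#' @param bundle A `model_bundle`.
#' @param include_organ_removal_competing Passed through to the projection.
#' @return Nonnegative scalar expected count.
#' @export
expected_cases <- function(cohort, bundle,
                           include_organ_removal_competing = FALSE) {
  if (nrow(cohort) == 0L) return(0)
  ck <- clip_followup(cohort)
  rr <- tryCatch(
    relative_risk_levels(encode_levels(ck, bundle$rr_model), bundle$rr_model),
    error = function(e) stop("cohort profile not encodable: ",
                             conditionMessage(e), call. = FALSE))
  base <- baseline_hazard(bundle)
  h2 <- hazard_per_year(bundle$competing_mortality)
  if (include_organ_removal_competing) {
    if (is.null(bundle$organ_removal_rates))
      stop("bundle carries no organ-removal rates", call. = FALSE)
    h2 <- h2 + hazard_per_year(bundle$organ_removal_rates)
  }
  sum(project_many(rr, ck$entry_age, ck$exit_age, base,
                   hazard_per_year(base), h2)$absolute_risk)
}

clip_followup <- function(cohort) {
  stopifnot(all(c("entry_age", "exit_age") %in% names(cohort)))
  if (any(cohort$entry_age >= cohort$exit_age))
    stop("entry_age must precede exit_age for every record", call. = FALSE)
  lo <- 50; hi <- 90
  if (any(cohort$entry_age < lo) || any(cohort$exit_age > hi)) {
    warning("follow-up outside [50, 90) clipped to the model's age support")
    cohort$entry_age <- pmax(cohort$entry_age, lo)
    cohort$exit_age <- pmin(cohort$exit_age, hi)
    cohort <- cohort[cohort$entry_age < cohort$exit_age, , drop = FALSE]
  }
  cohort
}

#' Expected/observed ratio with Poisson confidence interval
#'
#' Calibration measure: E/O above 1 means the model overestimates risk. The
#' 95% CI uses the normal approximation to the Poisson distribution on the
#' log scale, `(E/O) * exp(+/- 1.96 / sqrt(O))`.
#'
#' @param expected Nonnegative expected case count.
#' @param observed Nonnegative integer observed case count.
#' @return A data frame with `observed`, `expected`, `eo`, `eo_lo`, `eo_hi`.
#'   With `observed = 0` the ratio is undefined; the point estimate columns
#'   are `NA` and a warning is raised.
#' @examples
#' eo_ratio(100, 100)  # 1.00 (0.822, 1.216)
#' @export
eo_ratio <- function(expected, observed) {
  stopifnot(expected >= 0, observed >= 0)
  if (observed == 0) {
    warning("observed = 0: E/O ratio undefined, reporting expected only")
    return(data.frame(observed = 0L, expected = expected,
                      eo = NA_real_, eo_lo = NA_real_, eo_hi = NA_real_))
  }
  eo <- expected / observed
  half <- exp(1.96 / sqrt(observed))
  data.frame(observed = as.integer(observed), expected = expected,
             eo = eo, eo_lo = eo / half, eo_hi = eo * half)
}

#' Calibration table by subgroup
#'
#' Observed and expected counts with E/O ratios per level of a grouping
#' column, mirroring published validation-table layout. Groups partition the
#' cohort, so group observed and expected counts sum to the overall counts.
#'
#' @param cohort Cohort data frame as in [expected_cases()], including an
#'   `event` column and the grouping column.
#' @param bundle A `model_bundle`.
#' @param grouping Name of the column to group by.
#' @return A data frame with one row per group: `group`, `observed`,
#'   `expected`, `eo`, `eo_lo`, `eo_hi`.
#' @export
subgroup_eo <- function(cohort, bundle, grouping) {
  if (!grouping %in% names(cohort))
    stop("unknown grouping column '", grouping, "'", call. = FALSE)
  if (anyNA(cohort[[grouping]]))
    stop("grouping column '", grouping, "' has missing values", call. = FALSE)
  stopifnot(is.logical(cohort$event) || all(cohort$event %in% c(0, 1)))
  groups <- sort(unique(cohort[[grouping]]))
  rows <- lapply(groups, function(g) {
    sub <- cohort[cohort[[grouping]] == g, , drop = FALSE]
    r <- eo_ratio(expected_cases(sub, bundle), sum(sub$event))
    cbind(group = as.character(g), r)
  })
  do.call(rbind, rows)
}

#' Area under the ROC curve with bootstrap confidence interval
#'
#' Discrimination of projected risks: the probability that a randomly chosen
#' case has a higher projected risk than a randomly chosen non-case, ties
#' counting one half. Computed by the mid-rank (rank-sum) formulation, which
#' equals brute-force enumeration over all case/non-case pairs. The 95% CI is
#' a percentile bootstrap over individuals.
#'
#' @param risks Numeric vector of projected risks.
#' @param statuses Logical vector, `TRUE` = case.
#' @param bootstrap_reps Number of bootstrap resamples (0 skips the CI).
#' @param seed Integer seed for the bootstrap; required so every reported CI
#'   is reproducible.
#' @return A data frame with `auc`, `auc_lo`, `auc_hi`, `n_cases`,
#'   `n_controls`.
#' @examples
#' auc_risk(c(0.1, 0.2, 0.3, 0.4), c(FALSE, TRUE, FALSE, TRUE),
#'          bootstrap_reps = 0)
#' @export
auc_risk <- function(risks, statuses, bootstrap_reps = 1000, seed = NULL) {
  statuses <- as.logical(statuses)
  stopifnot(length(risks) == length(statuses), !anyNA(risks), !anyNA(statuses))
  n1 <- sum(statuses); n0 <- sum(!statuses)
  if (n1 == 0L || n0 == 0L)
    stop("AUC needs at least one case and one non-case", call. = FALSE)
  point <- auc_point(risks, statuses)
  lo <- hi <- NA_real_
  if (bootstrap_reps > 0) {
    if (is.null(seed))
      stop("an explicit seed is required for the bootstrap CI", call. = FALSE)
    boot <- with_local_seed(seed, {
      n <- length(risks)
      vapply(seq_len(bootstrap_reps), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        s <- statuses[idx]
        if (!any(s) || all(s)) return(NA_real_)
        auc_point(risks[idx], s)
      }, numeric(1))
    })
    qs <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  data.frame(auc = point, auc_lo = lo, auc_hi = hi,
             n_cases = n1, n_controls = n0)
}

auc_point <- function(risks, statuses) {
  n1 <- sum(statuses); n0 <- sum(!statuses)
  r <- rank(risks)  # mid-ranks give ties weight 1/2
  (sum(r[statuses]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Validate projected risks against cohort outcomes
#'
#' Convenience wrapper producing the full calibration/discrimination report:
#' overall observed and expected counts with E/O ratio, AUC of the
#' individual projected risks with bootstrap CI, and optional subgroup rows.
#'
#' @inheritParams subgroup_eo
#' @param grouping Optional grouping column for subgroup calibration rows.
#' @param bootstrap_reps,seed Passed to [auc_risk()].
#' @return A list of class `validation_report`: `overall` (one-row data
#'   frame with E/O and AUC columns) and `by_group` (or `NULL`).
#' @export
validate_cohort <- function(cohort, bundle, grouping = NULL,
                            bootstrap_reps = 1000, seed = 1L) {
  ck <- clip_followup(cohort)
  rr <- relative_risk_levels(encode_levels(ck, bundle$rr_model),
                             bundle$rr_model)
  base <- baseline_hazard(bundle)
  risks <- project_many(rr, ck$entry_age, ck$exit_age, base,
                        hazard_per_year(base),
                        hazard_per_year(bundle$competing_mortality))$absolute_risk
  overall <- eo_ratio(sum(risks), sum(ck$event))
  auc <- auc_risk(risks, ck$event, bootstrap_reps, seed)
  by_group <- if (!is.null(grouping)) subgroup_eo(ck, bundle, grouping)
  structure(list(overall = cbind(overall, auc), by_group = by_group,
                 cancer = bundle$cancer),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  o <- x$overall
  cat(sprintf("%s cancer validation: O = %d, E = %.1f, E/O = %.2f (%.2f-%.2f)\n",
              x$cancer, o$observed, o$expected, o$eo, o$eo_lo, o$eo_hi))
  cat(sprintf("  AUC = %.3f (%.3f-%.3f)\n", o$auc, o$auc_lo, o$auc_hi))
  if (!is.null(x$by_group)) {
    cat("  by group:\n")
    print(x$by_group, row.names = FALSE)
  }
  invisible(x)
}

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards (no global side effects)
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
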