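#' Categorical factor coding for a multiplicative relative-risk model
#'
#' Each risk factor enters the model through ordered categories with the
#' lowest-risk category as the reference (implied multiplier 1.0). A factor is
#' coded in one of three modes:
#' \describe{
#'   \item{trend}{a single relative risk per one-category increase; a woman at
#'     ordinal level k (0 = reference) contributes `rr^k`.}
#'   \item{per_category}{one multiplier per non-reference category.}
#'   \item{indicator}{a two-level per-category factor (no/yes).}
#' }
#' Factors may additionally carry `special_levels`, labelled multipliers for
#' states outside the ordinal scale (for example "NA/missing" age at menopause
#' for premenopausal women).
#'
#' @param name Factor identifier (must match an encoder rule and a profile
#'   field, e.g. `"bmi"`, `"mht_use"`).
#' @param categories Character vector of ordered category labels, reference
#'   first.
#' @param mode One of `"trend"`, `"per_category"`, `"indicator"`.
#' @param rr For `trend`: one positive multiplier per category increase. For
#'   `per_category`/`indicator`: positive multipliers for the non-reference
#'   categories, in category order.
#' @param special_levels Optional named numeric vector of multipliers for
#'   special levels.
#' @return An object of class `factor_coding`.
#' @export
factor_coding <- function(name, categories, mode, rr, special_levels = NULL) {
  mode <- match.arg(mode, c("trend", "per_category", "indicator"))
  categories <- as.character(categories)
  if (anyDuplicated(categories))
    stop("factor ", name, ": categories must be distinct (non-overlapping)",
         call. = FALSE)
  rr <- as.numeric(rr)
  if (any(!is.finite(rr)) || any(rr <= 0))
    stop("factor ", name, ": all multipliers must be positive", call. = FALSE)
  if (mode == "trend") {
    if (length(categories) < 2L)
      stop("factor ", name, ": trend coding requires >= 2 categories",
           call. = FALSE)
    if (length(rr) != 1L)
      stop("factor ", name, ": trend coding takes a single per-category ",
           "increase multiplier", call. = FALSE)
  } else {
    if (mode == "indicator" && length(categories) != 2L)
      stop("factor ", name, ": indicator coding requires exactly 2 categories",
           call. = FALSE)
    if (length(rr) != length(categories) - 1L)
      stop("factor ", name, ": need one multiplier per non-reference category",
           call. = FALSE)
  }
  if (!is.null(special_levels)) {
    special_levels <- unlist(special_levels)
    if (is.null(names(special_levels)) || any(!nzchar(names(special_levels))))
      stop("factor ", name, ": special_levels must be named", call. = FALSE)
    if (any(special_levels <= 0))
      stop("factor ", name, ": special multipliers must be positive",
           call. = FALSE)
  }
  structure(list(name = name, categories = categories, mode = mode,
                 rr = rr, special_levels = special_levels),
            class = "factor_coding")
}

#' Interaction term between an indicator condition and a trend factor
#'
#' Applied multiplicatively: when `when_factor` is at level `when_level`, the
#' interaction contributes `multiplier^k` where k is the ordinal level of the
#' trend-coded `target_factor`. This encodes a product term between a trend
#' variable and an indicator (e.g. extra menopausal-hormone-therapy risk per
#' duration category among lean women).
#'
#' @param when_factor Name of the conditioning factor.
#' @param when_level Ordinal level (0 = reference) at which the condition holds.
#' @param target_factor Name of a trend-coded factor whose level exponentiates
#'   the multiplier.
#' @param multiplier Positive per-category-increase multiplier.
#' @return An object of class `interaction_term`.
#' @export
interaction_term <- function(when_factor, when_level, target_factor, multiplier) {
  if (!is.finite(multiplier) || multiplier <= 0)
    stop("interaction multiplier must be positive", call. = FALSE)
  structure(list(when_factor = when_factor,
                 when_level = as.integer(when_level),
                 target_factor = target_factor,
                 multiplier = as.numeric(multiplier)),
            class = "interaction_term")
}

#' Multiplicative relative-risk model for one cancer
#'
#' Bundles the factor codings and interaction terms of one cancer's
#' log-linear relative-risk model `rr(x) = exp(beta' x)`: the relative risk of
#' a profile is the product over factors of each factor's contribution, times
#' each satisfied interaction's contribution.
#'
#' @param cancer One of `"breast"`, `"endometrial"`, `"ovarian"`.
#' @param factors List of [factor_coding()] objects with unique names.
#' @param interactions Optional list of [interaction_term()] objects; every
#'   referenced factor must be declared, and targets must be trend-coded.
#' @return An object of class `rr_model`.
#' @export
rr_model <- function(cancer, factors, interactions = list()) {
  cancer <- match.arg(cancer, c("breast", "endometrial", "ovarian"))
  stopifnot(length(factors) > 0L,
            all(vapply(factors, inherits, logical(1), "factor_coding")))
  nm <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("factor names must be unique", call. = FALSE)
  names(factors) <- nm
  for (it in interactions) {
    stopifnot(inherits(it, "interaction_term"))
    if (!(it$when_factor %in% nm) || !(it$target_factor %in% nm))
      stop("interaction references undeclared factor", call. = FALSE)
    if (factors[[it$target_factor]]$mode != "trend")
      stop("interaction target ", it$target_factor, " must be trend-coded",
           call. = FALSE)
  }
  structure(list(cancer = cancer, factors = factors,
                 interactions = interactions),
            class = "rr_model")
}

#' @export
print.rr_model <- function(x, ...) {
  cat("Relative-risk model:", x$cancer, "cancer\n")
  for (f in x$factors) {
    rr_txt <- if (f$mode == "trend")
      sprintf("%.2f per category increase", f$rr)
    else paste(sprintf("%.2f", f$rr), collapse = ", ")
    cat(sprintf("  %-16s %-12s ref=%s  RR %s\n", f$name, f$mode,
                f$categories[1], rr_txt))
    if (!is.null(f$special_levels))
      cat(sprintf("  %-16s special: %s\n", "",
                  paste(names(f$special_levels),
                        sprintf("%.2f", f$special_levels),
                        sep = "=", collapse = ", ")))
  }
  for (it in x$interactions)
    cat(sprintf("  interaction: %s at level %d scales %s by %.2f/category\n",
                it$when_factor, it$when_level, it$target_factor, it$multiplier))
  invisible(x)
}
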