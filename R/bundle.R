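#' Load a complete model parameter bundle
#'
#' A bundle directory holds everything needed to project one cancer's absolute
#' risk: the relative-risk model (`rr_model.yaml`), raw registry incidence
#' rates, competing mortality rates, the attributable-risk constant, and — for
#' the endometrial and ovarian models — the intact-organ prevalence used to
#' correct whole-population incidence to at-risk incidence, plus optional
#' organ-removal rates for the added-competing-risk variant. All tables are
#' plain delimited text with header `age_lo,age_hi,rate_per_100k` (prevalence:
#' `proportion_with_organ`), auditable against their published sources.
#'
#' The corrected incidence table is recomputed at load time with
#' [correct_rates()]; the breast bundle (no organ correction) has
#' `incidence_corrected` identical to `incidence_raw`.
#'
#' @param path Bundle directory containing `config.yaml`, or the parent
#'   directory of several bundles when `cancer` is given.
#' @param cancer Optional cancer name; when supplied, the bundle is read from
#'   `file.path(path, cancer)`.
#' @return An object of class `model_bundle` with fields `cancer`, `rr_model`,
#'   `incidence_raw`, `incidence_corrected`, `competing_mortality`,
#'   `attributable_risk`, `organ_prevalence`, `organ_removal_rates`.
#' @examples
#' b <- load_bundle(system.file("extdata", "bundles", package = "beorisk"),
#'                  "ovarian")
#' b$attributable_risk
#' @export
load_bundle <- function(path, cancer = NULL) {
  if (!is.null(cancer)) path <- file.path(path, cancer)
  cfg_path <- file.path(path, "config.yaml")
  if (!file.exists(cfg_path))
    stop("bundle config not found: ", cfg_path, call. = FALSE)
  cfg <- yaml::read_yaml(cfg_path)
  need <- function(key) {
    f <- file.path(path, cfg$files[[key]])
    if (is.null(cfg$files[[key]]) || !file.exists(f))
      stop("bundle file for '", key, "' missing in ", path, call. = FALSE)
    f
  }
  read_rates <- function(f) {
    d <- utils::read.csv(f)
    rate_table(d$age_lo, d$age_hi, d$rate_per_100k)
  }
  rrm <- read_rr_model_yaml(need("rr_model"))
  if (!identical(rrm$cancer, cfg$cancer))
    stop("rr_model cancer does not match bundle config", call. = FALSE)
  raw <- read_rates(need("incidence_raw"))
  mort <- read_rates(need("competing_mortality"))
  prev <- NULL
  removal <- NULL
  if (!is.null(cfg$files$organ_prevalence)) {
    d <- utils::read.csv(need("organ_prevalence"))
    prev <- prevalence_table(d$age_lo, d$age_hi, d$proportion_with_organ)
  }
  if (!is.null(cfg$files$organ_removal_rates))
    removal <- read_rates(need("organ_removal_rates"))
  corrected <- if (is.null(prev)) raw else correct_rates(raw, prev)
  b <- structure(list(cancer = cfg$cancer,
                      rr_model = rrm,
                      incidence_raw = raw,
                      incidence_corrected = corrected,
                      competing_mortality = mort,
                      attributable_risk = as.numeric(cfg$attributable_risk),
                      organ_prevalence = prev,
                      organ_removal_rates = removal),
                 class = "model_bundle")
  rep <- validate_bundle(b)
  if (!all(rep$passed))
    stop("bundle validation failed: ",
         paste(rep$check[!rep$passed], collapse = ", "), call. = FALSE)
  b
}

read_rr_model_yaml <- function(f) {
  y <- yaml::read_yaml(f)
  factors <- lapply(y$factors, function(fc)
    factor_coding(fc$name, fc$categories, fc$mode, fc$rr, fc$special_levels))
  interactions <- lapply(y$interactions, function(it)
    interaction_term(it$when_factor, it$when_level, it$target_factor,
                     it$multiplier))
  rr_model(y$cancer, factors, interactions)
}

#' Load one of the packaged parameter bundles
#'
#' @param cancer One of `"breast"`, `"endometrial"`, `"ovarian"`.
#' @return A `model_bundle`; see [load_bundle()].
#' @export
beo_bundle <- function(cancer = c("breast", "endometrial", "ovarian")) {
  cancer <- match.arg(cancer)
  load_bundle(system.file("extdata", "bundles", package = "beorisk",
                          mustWork = TRUE), cancer)
}

#' Run all invariant checks on a bundle
#'
#' Reporting only: returns one row per check with its status rather than
#' stopping at the first failure, so a malformed bundle can be diagnosed in
#' one pass.
#'
#' @param bundle A `model_bundle` (possibly hand-built).
#' @return A data frame with columns `check` and `passed`.
#' @export
validate_bundle <- function(bundle) {
  checks <- list()
  add <- function(name, ok) checks[[length(checks) + 1L]] <<- list(name, isTRUE(ok))
  ok_tab <- function(tab) !inherits(try(validate_rate_table(tab), silent = TRUE),
                                    "try-error")
  add("cancer_known", bundle$cancer %in% c("breast", "endometrial", "ovarian"))
  add("rr_model_present", inherits(bundle$rr_model, "rr_model"))
  add("incidence_raw_valid", ok_tab(bundle$incidence_raw))
  add("incidence_corrected_valid", ok_tab(bundle$incidence_corrected))
  add("competing_mortality_valid", ok_tab(bundle$competing_mortality))
  ar <- bundle$attributable_risk
  add("attributable_risk_range", is.numeric(ar) && length(ar) == 1L &&
        ar >= 0 && ar < 1)
  add("corrected_not_below_raw",
      all(bundle$incidence_corrected$rate_per_100k >=
            bundle$incidence_raw$rate_per_100k - 1e-9))
  if (is.null(bundle$organ_prevalence)) {
    add("no_correction_identity",
        isTRUE(all.equal(bundle$incidence_corrected$rate_per_100k,
                         bundle$incidence_raw$rate_per_100k)))
  } else {
    add("prevalence_in_unit_interval",
        all(bundle$organ_prevalence$proportion_with_organ > 0) &&
          all(bundle$organ_prevalence$proportion_with_organ <= 1))
    add("correction_consistent",
        isTRUE(all.equal(
          bundle$incidence_corrected$rate_per_100k,
          bundle$incidence_raw$rate_per_100k /
            bundle$organ_prevalence$proportion_with_organ)))
  }
  if (!is.null(bundle$organ_removal_rates))
    add("organ_removal_rates_valid", ok_tab(bundle$organ_removal_rates))
  data.frame(check = vapply(checks, `[[`, character(1), 1L),
             passed = vapply(checks, `[[`, logical(1), 2L))
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("Model bundle: %s cancer (attributable risk %.2f)\n",
              x$cancer, x$attributable_risk))
  cat(sprintf("  %d age bins covering [%g, %g)\n",
              nrow(x$incidence_raw), x$incidence_raw$age_lo[1],
              x$incidence_raw$age_hi[nrow(x$incidence_raw)]))
  if (!is.null(x$organ_prevalence))
    cat("  incidence corrected for organ-removal prevalence\n")
  print(x$rr_model)
  invisible(x)
}
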