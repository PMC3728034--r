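#' Tabulate absolute risks for a set of profiles
#'
#' One row per profile with the projected absolute risk for each requested
#' cancer and horizon, as percentages rounded to two decimals (set
#' `digits = NULL` for full machine precision). Profiles are assumed
#' organ-present; if the profile table carries a logical `hysterectomy`
#' (resp. `oophorectomy`) column, flagged rows get `NA` in the endometrial
#' (resp. ovarian) cells, since those models do not apply. Per-row encoding
#' failures are collected into `NA` cells with a warning rather than
#' aborting the whole table.
#'
#' @param bundles Named list of `model_bundle`s (default: all three packaged
#'   bundles).
#' @param profiles Data frame of profiles with `current_age` as the
#'   projection start age.
#' @param horizons Projection lengths in years.
#' @param digits Decimal places for the percentage cells (`NULL` = no
#'   rounding).
#' @return A data frame: the input profiles' identifying columns followed by
#'   one `<cancer>_<horizon>y` percentage column per cancer and horizon.
#' @examples
#' profs <- read_profiles(system.file("extdata", "example_profiles.csv",
#'                                    package = "beorisk"))
#' tabulate_profiles(profiles = profs[1:2, ], horizons = 10)
#' @export
tabulate_profiles <- function(bundles = NULL, profiles, horizons = c(10, 20),
                              digits = 2) {
  if (is.null(bundles))
    bundles <- lapply(stats::setNames(nm = c("breast", "endometrial",
                                             "ovarian")), beo_bundle)
  out <- profiles[, intersect(c("profile", "id", "current_age"),
                              names(profiles)), drop = FALSE]
  if (nrow(profiles) == 0L) {
    for (nm in names(bundles)) for (h in horizons)
      out[[paste0(nm, "_", h, "y")]] <- numeric(0)
    return(out)
  }
  skip_flag <- list(endometrial = "hysterectomy", ovarian = "oophorectomy")
  errs <- character(0)
  for (nm in names(bundles)) {
    b <- bundles[[nm]]
    for (h in horizons) {
      col <- paste0(b$cancer, "_", h, "y")
      vals <- rep(NA_real_, nrow(profiles))
      for (i in seq_len(nrow(profiles))) {
        flag <- skip_flag[[b$cancer]]
        if (!is.null(flag) && flag %in% names(profiles) &&
            isTRUE(as.logical(profiles[[flag]][i]))) next
        a0 <- profiles$current_age[i]
        vals[i] <- tryCatch(
          100 * absolute_risk(profiles[i, , drop = FALSE], a0,
                              min(a0 + h, 90), b)$absolute_risk,
          error = function(e) {
            errs <<- c(errs, sprintf("row %d, %s: %s", i, b$cancer,
                                     conditionMessage(e)))
            NA_real_
          })
      }
      out[[col]] <- if (is.null(digits)) vals else round(vals, digits)
    }
  }
  if (length(errs))
    warning("some cells could not be computed:\n  ",
            paste(unique(errs), collapse = "\n  "))
  out
}
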