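profile_columns <- c("current_age", "bmi", "oc_use_years", "mht_use_years",
                     "ep_mht_use_years", "other_mht_use", "parity",
                     "age_first_birth", "menopause_status", "age_at_menopause",
                     "benign_breast_disease", "family_history_breast_ovarian",
                     "alcohol_drinks_per_day", "smoking")

#' Read risk-factor profiles from delimited text
#'
#' One row per woman, comma-delimited with a header; columns are named
#' exactly as the [risk_factor_profile()] fields. Unknown columns are kept
#' (they may serve as identifiers or subgroup labels) with a warning.
#'
#' @param path CSV file path.
#' @return A data frame of profiles.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("profile file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  extra <- setdiff(names(df), c(profile_columns, "id", "profile"))
  if (length(extra))
    warning("ignoring unknown profile column(s): ",
            paste(extra, collapse = ", "))
  df
}

#' Read cohort records from delimited text
#'
#' Cohort files carry `entry_age`, `exit_age`, `event` plus profile columns;
#' `event` is parsed as logical.
#'
#' @param path CSV file path.
#' @return A cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("entry_age", "exit_age", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$event <- as.logical(df$event)
  df
}

#' Write a table as comma-delimited text
#'
#' Plain `write.csv` without row names, so that writing then reading any
#' profile or cohort table is lossless field by field.
#'
#' @param x Data frame.
#' @param path Output path, or `""` for standard output.
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, if (nzchar(path)) path else stdout(), row.names = FALSE,
                   quote = FALSE, na = "NA")
  invisible(x)
}
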