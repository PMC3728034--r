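#' Construct a risk-factor profile
#'
#' Raw risk factors for one woman, prior to any model-specific coding. Fields
#' not used by a given cancer's model are ignored when encoding for it.
#'
#' @param current_age Age in years, in \[50, 90).
#' @param bmi Body mass index in kg/m^2.
#' @param oc_use_years Total years of oral contraceptive use (0 = never).
#' @param mht_use_years Total years of any menopausal hormone therapy use.
#' @param ep_mht_use_years Years of combined estrogen + progestin therapy.
#' @param other_mht_use Logical: any MHT of other/unknown type.
#' @param parity Number of live births.
#' @param age_first_birth Age at first live birth in whole years, `NA` for
#'   nulliparous women.
#' @param menopause_status `"premenopausal"` or `"postmenopausal"`.
#' @param age_at_menopause Age at natural menopause, `NA` if premenopausal or
#'   unknown.
#' @param benign_breast_disease Logical: history of benign breast disease or
#'   breast biopsy.
#' @param family_history_breast_ovarian Logical: any first-degree relative
#'   with breast or ovarian cancer.
#' @param alcohol_drinks_per_day Nonnegative drinks per day.
#' @param smoking `"never"`, `"former"`, or `"current"`.
#' @return A one-row data frame of class `risk_factor_profile`.
#' @examples
#' p <- risk_factor_profile(current_age = 50, bmi = 24, parity = 3,
#'                          age_first_birth = 25)
#' @export
risk_factor_profile <- function(current_age,
                                bmi = NA_real_,
                                oc_use_years = 0,
                                mht_use_years = 0,
                                ep_mht_use_years = 0,
                                other_mht_use = FALSE,
                                parity = 0,
                                age_first_birth = NA_real_,
                                menopause_status = "premenopausal",
                                age_at_menopause = NA_real_,
                                benign_breast_disease = FALSE,
                                family_history_breast_ovarian = FALSE,
                                alcohol_drinks_per_day = 0,
                                smoking = "never") {
  if (current_age < 50 || current_age >= 90)
    stop("current_age must lie in [50, 90)", call. = FALSE)
  if (!is.na(bmi) && bmi <= 0) stop("bmi must be positive", call. = FALSE)
  if (parity < 0) stop("parity must be nonnegative", call. = FALSE)
  if (parity == 0 && !is.na(age_first_birth))
    stop("age_first_birth must be NA for nulliparous women", call. = FALSE)
  x <- data.frame(current_age = current_age, bmi = bmi,
                  oc_use_years = oc_use_years,
                  mht_use_years = mht_use_years,
                  ep_mht_use_years = ep_mht_use_years,
                  other_mht_use = as.logical(other_mht_use),
                  parity = parity, age_first_birth = age_first_birth,
                  menopause_status = menopause_status,
                  age_at_menopause = age_at_menopause,
                  benign_breast_disease = as.logical(benign_breast_disease),
                  family_history_breast_ovarian =
                    as.logical(family_history_breast_ovarian),
                  alcohol_drinks_per_day = alcohol_drinks_per_day,
                  smoking = smoking)
  class(x) <- c("risk_factor_profile", "data.frame")
  x
}

# upper break points implied by ordered interval labels such as
# c("<25", "25-<30", "30-<35", "35+"): the leading number of every
# non-reference label. Intervals are left-closed, right-open.
label_breaks <- function(categories) {
  as.numeric(sub("^[^0-9]*([0-9]+\\.?[0-9]*).*$", "\\1", categories[-1]))
}

# duration in years -> never / <10y / 10+y coded level
duration_level <- function(years) {
  lev <- ifelse(years <= 0, 0L, ifelse(years < 10, 1L, 2L))
  lev[is.na(years)] <- NA_integer_
  lev
}

# Resolve one model factor to ordinal levels for n profiles.
# Returns an integer vector; NA marks the factor's special "NA/missing" level
# (only legal when the coding declares one).
encode_field <- function(coding, df) {
  n <- nrow(df)
  get <- function(col) {
    if (!col %in% names(df))
      stop("profile field '", col, "' required by factor '", coding$name,
           "' is missing", call. = FALSE)
    df[[col]]
  }
  lev <- switch(coding$name,
    bmi = {
      v <- get("bmi")
      findInterval(v, label_breaks(coding$categories))
    },
    oc_use = as.integer(get("oc_use_years") < 1),
    mht_use = duration_level(get("mht_use_years")),
    ep_mht_use = duration_level(get("ep_mht_use_years")),
    other_mht_use = as.integer(get("other_mht_use")),
    age_first_birth = {
      # nulliparous women take the reference level; their elevated risk is
      # carried entirely by the nulliparity term
      v <- get("age_first_birth")
      lev <- ifelse(v < 25, 0L, ifelse(v < 30, 1L, 2L))
      lev[get("parity") == 0] <- 0L
      lev
    },
    parity = {
      p <- get("parity")
      if (identical(coding$categories, c("1+", "0"))) {
        as.integer(p == 0)
      } else {
        ifelse(p >= 3, 0L, ifelse(p >= 1, 1L, 2L))
      }
    },
    age_menopause = {
      v <- get("age_at_menopause")
      pre <- get("menopause_status") == "premenopausal"
      lev <- ifelse(v < 50, 0L, ifelse(v < 55, 1L, 2L))
      lev[pre | is.na(v)] <- NA_integer_   # special "NA/missing" level
      lev
    },
    bbd = as.integer(get("benign_breast_disease")),
    family_history = as.integer(get("family_history_breast_ovarian")),
    alcohol = {
      v <- get("alcohol_drinks_per_day")
      ifelse(v <= 0, 0L, ifelse(v < 1, 1L, 2L))
    },
    smoking = match(get("smoking"), coding$categories) - 1L,
    stop("no encoder rule for factor '", coding$name, "'", call. = FALSE)
  )
  lev <- as.integer(lev)
  if (anyNA(lev) && is.null(coding$special_levels)) {
    bad <- which(is.na(lev))
    stop("factor '", coding$name, "': missing or out-of-range value for ",
         "profile row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         " and no special level is defined", call. = FALSE)
  }
  n_cat <- length(coding$categories)
  if (any(lev < 0L | lev >= n_cat, na.rm = TRUE))
    stop("factor '", coding$name, "': resolved level out of range",
         call. = FALSE)
  lev
}

# level matrix for a data frame of profiles: integer matrix n x p,
# NA = the factor's special "NA/missing" level
encode_levels <- function(df, model) {
  stopifnot(inherits(model, "rr_model"), is.data.frame(df))
  m <- vapply(model$factors, encode_field, integer(nrow(df)), df = df)
  if (nrow(df) == 1L) m <- matrix(m, nrow = 1L,
                                  dimnames = list(NULL, names(model$factors)))
  m
}

#' Resolve a profile's raw factors to model category levels
#'
#' Applies the model's category boundaries (left-closed, right-open intervals;
#' "25 to <30" contains exactly \[25, 30)) to a raw profile. Premenopausal
#' women and women with unknown age at menopause resolve to the model's
#' "NA/missing" special level; nulliparous women resolve to the nulliparity
#' indicator (breast) or the parity-0 level (endometrial/ovarian).
#'
#' @param profile A [risk_factor_profile()] (or any one-row data frame with
#'   the needed fields).
#' @param model An [rr_model()].
#' @return An object of class `encoded_profile`: the cancer and a named list
#'   mapping every model factor to its ordinal level (0 = reference) or
#'   special-level label.
#' @export
encode_profile <- function(profile, model) {
  if (nrow(profile) != 1L)
    stop("encode_profile takes a single profile; see encode_levels for cohorts",
         call. = FALSE)
  m <- encode_levels(profile, model)
  levels <- stats::setNames(vector("list", ncol(m)), colnames(m))
  for (j in seq_len(ncol(m)))
    levels[[j]] <- if (is.na(m[1L, j])) "NA/missing" else unname(m[1L, j])
  structure(list(cancer = model$cancer, level_by_factor = levels),
            class = "encoded_profile")
}

# multiplicative relative risk for a level matrix (vectorized core)
relative_risk_levels <- function(lev, model) {
  rr <- rep(1, nrow(lev))
  for (f in model$factors) {
    k <- unname(lev[, f$name])
    contrib <- if (f$mode == "trend") f$rr^k else c(1, f$rr)[k + 1L]
    if (anyNA(k)) {
      sp <- f$special_levels[["NA/missing"]]
      if (is.null(sp))
        stop("factor '", f$name, "': special level present but undefined",
             call. = FALSE)
      contrib[is.na(k)] <- sp
    }
    rr <- rr * contrib
  }
  for (it in model$interactions) {
    cond <- unname(lev[, it$when_factor])
    tgt <- unname(lev[, it$target_factor])
    hit <- !is.na(cond) & cond == it$when_level & !is.na(tgt)
    rr[hit] <- rr[hit] * it$multiplier^tgt[hit]
  }
  rr
}

#' Multiplicative relative risk of an encoded profile
#'
#' The product over model factors of each factor's contribution (trend:
#' `rr^level`; per-category/indicator: the level's multiplier; special level:
#' its multiplier), times each satisfied interaction's `multiplier^level` of
#' the target factor. A profile with every factor at reference returns
#' exactly 1.
#'
#' @param encoded An `encoded_profile` from [encode_profile()], or a
#'   `risk_factor_profile` (encoded on the fly).
#' @param model The matching [rr_model()].
#' @return A positive scalar.
#' @examples
#' b <- beo_bundle("ovarian")
#' p <- risk_factor_profile(current_age = 50, parity = 3)
#' relative_risk(encode_profile(p, b$rr_model), b$rr_model)
#' @export
relative_risk <- function(encoded, model) {
  if (inherits(encoded, "risk_factor_profile") ||
      (is.data.frame(encoded) && !inherits(encoded, "encoded_profile")))
    return(relative_risk_levels(encode_levels(encoded, model), model))
  stopifnot(inherits(encoded, "encoded_profile"))
  if (!identical(encoded$cancer, model$cancer))
    stop("encoded profile is for the ", encoded$cancer, " model", call. = FALSE)
  lev <- vapply(names(model$factors), function(nm) {
    v <- encoded$level_by_factor[[nm]]
    if (is.null(v))
      stop("encoded profile lacks factor '", nm, "'", call. = FALSE)
    if (is.character(v)) NA_integer_ else as.integer(v)
  }, integer(1))
  relative_risk_levels(matrix(lev, nrow = 1L,
                              dimnames = list(NULL, names(model$factors))),
                       model)
}
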