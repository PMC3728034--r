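#' Covariate sampling distribution for synthetic cohorts
#'
#' Describes how raw risk-factor profiles are drawn: an independent discrete
#' distribution per factor (the default emulates the risk-factor mix of large
#' US cohorts of postmenopausal white women), a discrete entry-age
#' distribution over \[50, 90), and an administrative censoring horizon. A
#' joint table of complete profiles with weights can be supplied instead of
#' independent marginals for correlation studies.
#'
#' @param fields Named list; each element is `list(values = ..., probs = ...)`
#'   for one profile field. Probabilities must sum to 1.
#' @param entry_ages `list(values, probs)` for the age at cohort entry.
#' @param horizon_years Administrative censoring horizon (> 0), years after
#'   entry.
#' @param joint Optional data frame of complete profiles with a `weight`
#'   column; when present, whole rows are sampled and `fields` is ignored.
#' @return An object of class `covariate_distribution`.
#' @export
covariate_distribution <- function(fields = default_covariate_fields(),
                                   entry_ages = list(values = 50:72,
                                                     probs = rep(1 / 23, 23)),
                                   horizon_years = 14,
                                   joint = NULL) {
  if (horizon_years <= 0) stop("horizon_years must be positive", call. = FALSE)
  chk <- function(d, nm) {
    if (length(d$values) != length(d$probs) || any(d$probs < 0) ||
        abs(sum(d$probs) - 1) > 1e-8)
      stop("probabilities for '", nm, "' must be nonnegative and sum to 1",
           call. = FALSE)
  }
  if (is.null(joint)) {
    for (nm in names(fields)) chk(fields[[nm]], nm)
  } else {
    stopifnot(is.data.frame(joint), "weight" %in% names(joint),
              all(joint$weight >= 0), sum(joint$weight) > 0)
  }
  chk(entry_ages, "entry_ages")
  if (any(entry_ages$values < 50) || any(entry_ages$values >= 90))
    stop("entry ages must lie in [50, 90)", call. = FALSE)
  structure(list(fields = fields, entry_ages = entry_ages,
                 horizon_years = horizon_years, joint = joint),
            class = "covariate_distribution")
}

#' @rdname covariate_distribution
#' @export
default_covariate_fields <- function() {
  list(
    bmi = list(values = c(22, 27, 32, 37, 42),
               probs = c(0.45, 0.31, 0.13, 0.07, 0.04)),
    oc_use_years = list(values = c(0, 5, 12), probs = c(0.60, 0.30, 0.10)),
    mht_use_years = list(values = c(0, 5, 12), probs = c(0.40, 0.38, 0.22)),
    parity = list(values = c(0, 1, 2, 3, 4),
                  probs = c(0.12, 0.10, 0.25, 0.35, 0.18)),
    age_first_birth = list(values = c(22, 27, 32),
                           probs = c(0.60, 0.27, 0.13)),
    age_at_menopause = list(values = c(47, 52, 56),
                            probs = c(0.42, 0.47, 0.11)),
    premenopausal = list(values = c(FALSE, TRUE), probs = c(0.95, 0.05)),
    benign_breast_disease = list(values = c(FALSE, TRUE),
                                 probs = c(0.60, 0.40)),
    family_history_breast_ovarian = list(values = c(FALSE, TRUE),
                                         probs = c(0.85, 0.15)),
    alcohol_drinks_per_day = list(values = c(0, 0.5, 1.5),
                                  probs = c(0.25, 0.55, 0.20)),
    smoking = list(values = c("never", "former", "current"),
                   probs = c(0.48, 0.39, 0.13)),
    # share of a woman's MHT use that is combined estrogen + progestin
    ep_share = list(values = c(1, 0), probs = c(0.75, 0.25))
  )
}

#' Draw raw risk-factor profiles
#'
#' Samples `n` profiles independently from the distribution. Structural
#' constraints are enforced after sampling: nulliparous women get
#' `age_first_birth = NA`; premenopausal women get `age_at_menopause = NA`;
#' the estrogen+progestin share splits total MHT duration into combined
#' therapy versus other-type use.
#'
#' @param dist A [covariate_distribution()].
#' @param n Number of profiles (> 0).
#' @param seed Integer seed; all randomness is local to the call.
#' @return A data frame of `n` rows with [risk_factor_profile()] columns.
#' @export
sample_covariates <- function(dist, n, seed) {
  stopifnot(inherits(dist, "covariate_distribution"), n > 0)
  with_local_seed(seed, {
    draw <- function(d) d$values[sample.int(length(d$values), n, replace = TRUE,
                                            prob = d$probs)]
    if (!is.null(dist$joint)) {
      idx <- sample.int(nrow(dist$joint), n, replace = TRUE,
                        prob = dist$joint$weight)
      out <- dist$joint[idx, setdiff(names(dist$joint), "weight"),
                        drop = FALSE]
      rownames(out) <- NULL
      out$current_age <- draw(dist$entry_ages)
      return(out)
    }
    f <- dist$fields
    pre <- draw(f$premenopausal)
    parity <- draw(f$parity)
    mht <- draw(f$mht_use_years)
    ep_share <- draw(f$ep_share)
    out <- data.frame(
      current_age = draw(dist$entry_ages),
      bmi = draw(f$bmi),
      oc_use_years = draw(f$oc_use_years),
      mht_use_years = mht,
      ep_mht_use_years = mht * ep_share,
      other_mht_use = mht > 0 & ep_share == 0,
      parity = parity,
      age_first_birth = ifelse(parity == 0, NA, draw(f$age_first_birth)),
      menopause_status = ifelse(pre, "premenopausal", "postmenopausal"),
      age_at_menopause = ifelse(pre, NA, draw(f$age_at_menopause)),
      benign_breast_disease = draw(f$benign_breast_disease),
      family_history_breast_ovarian = draw(f$family_history_breast_ovarian),
      alcohol_drinks_per_day = draw(f$alcohol_drinks_per_day),
      smoking = draw(f$smoking))
    out
  })
}

#' Simulate competing-risk outcomes for a cohort
#'
#' Draws each woman's outcome from the piecewise-exponential cause-specific
#' hazards implied by the bundle: cancer hazard `h1_j = baseline_j * rr(x)`
#' and competing-mortality hazard `h2_j` per 5-year age bin. Within each bin
#' the waiting time is drawn by exact exponential inversion and attributed to
#' cancer with probability `h1/(h1+h2)`; the first of cancer, death, or
#' administrative censoring (at entry + horizon, capped at age 90) sets the
#' exit age and event flag. No time discretization is involved.
#'
#' @param profiles Data frame of raw profiles (e.g. from
#'   [sample_covariates()]), with `current_age` as the entry age.
#' @param bundle A `model_bundle`.
#' @param dist A [covariate_distribution()] supplying the censoring horizon.
#' @param seed Integer seed; all randomness is local to the call.
#' @param include_organ_removal_competing Add organ-removal rates to the
#'   competing hazard (requires the bundle to carry them).
#' @return A cohort data frame: `id`, `entry_age`, `exit_age`, `event`
#'   (logical, incident cancer of interest), `exit_reason`
#'   (cancer/death/censored), `admin_end_age` (the administrative censoring
#'   age, handy for computing expected counts over the full follow-up window
#'   the way validation studies do), followed by the profile columns.
#' @export
simulate_outcomes <- function(profiles, bundle, dist, seed,
                              include_organ_removal_competing = FALSE) {
  stopifnot(inherits(bundle, "model_bundle"),
            inherits(dist, "covariate_distribution"))
  n <- nrow(profiles)
  rr <- relative_risk_levels(encode_levels(profiles, bundle$rr_model),
                             bundle$rr_model)
  base <- baseline_hazard(bundle)
  h10 <- hazard_per_year(base)
  h2bin <- hazard_per_year(bundle$competing_mortality)
  if (include_organ_removal_competing) {
    if (is.null(bundle$organ_removal_rates))
      stop("bundle carries no organ-removal rates", call. = FALSE)
    h2bin <- h2bin + hazard_per_year(bundle$organ_removal_rates)
  }
  entry <- profiles$current_age
  cap <- pmin(entry + dist$horizon_years, 90)
  with_local_seed(seed, {
    exit <- cap
    reason <- rep("censored", n)
    alive <- rep(TRUE, n)
    for (j in seq_len(nrow(base))) {
      lo <- pmax(entry, base$age_lo[j])
      w <- pmin(cap, base$age_hi[j]) - lo
      act <- alive & w > 0
      if (!any(act)) next
      h1 <- rr[act] * h10[j]
      h <- h1 + h2bin[j]
      t_evt <- ifelse(h > 0, stats::rexp(sum(act)) / h, Inf)
      hit <- t_evt < w[act]
      if (any(hit)) {
        idx <- which(act)[hit]
        is_cancer <- stats::runif(length(idx)) < (h1[hit] / h[hit])
        exit[idx] <- lo[idx] + t_evt[hit]
        reason[idx] <- ifelse(is_cancer, "cancer", "death")
        alive[idx] <- FALSE
      }
    }
    out <- data.frame(id = seq_len(n), entry_age = entry, exit_age = exit,
                      event = reason == "cancer", exit_reason = reason,
                      admin_end_age = cap)
    cbind(out, profiles[setdiff(names(profiles), names(out))])
  })
}
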