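# Shared fixtures: tiny hand-built bundles, reference profiles, an
# independent quadrature oracle, and the published example-profile risks.

bins5 <- function() list(lo = seq(50, 85, 5), hi = seq(55, 90, 5))

flat_rates <- function(rate) {
  b <- bins5()
  rate_table(b$lo, b$hi, rep(rate, 8))
}

# minimal single-factor model: family history doubles the hazard
toy_model <- function(cancer = "ovarian", rr = 2) {
  rr_model(cancer, list(
    factor_coding("family_history", c("no", "yes"), "indicator", rr)))
}

# hand-built bundle with flat hazards (rates per 100,000 person-years)
toy_bundle <- function(incidence = 1000, mortality = 1000, ar = 0,
                       cancer = "ovarian", rr = 2) {
  structure(list(cancer = cancer,
                 rr_model = toy_model(cancer, rr),
                 incidence_raw = flat_rates(incidence),
                 incidence_corrected = flat_rates(incidence),
                 competing_mortality = flat_rates(mortality),
                 attributable_risk = ar,
                 organ_prevalence = NULL,
                 organ_removal_rates = NULL),
            class = "model_bundle")
}

# a profile at every model's reference level (postmenopausal, lean,
# parous at 3+, never user of OC or MHT, current smoker, no alcohol)
reference_profile <- function(age = 50) {
  risk_factor_profile(current_age = age, bmi = 22, oc_use_years = 5,
                      mht_use_years = 0, ep_mht_use_years = 0,
                      other_mht_use = FALSE, parity = 3,
                      age_first_birth = 22,
                      menopause_status = "postmenopausal",
                      age_at_menopause = 48,
                      benign_breast_disease = FALSE,
                      family_history_breast_ovarian = FALSE,
                      alcohol_drinks_per_day = 0, smoking = "current")
}

# independent fine-grid trapezoid quadrature of the competing-risk
# cumulative incidence; shares nothing with the closed-form engine
pi_quadrature <- function(rr, a, b, bundle, step = 0.001) {
  base <- baseline_hazard(bundle)
  h10 <- hazard_per_year(base)
  h2 <- hazard_per_year(bundle$competing_mortality)
  cuts <- base$age_lo[base$age_lo > a & base$age_lo < b]
  edges <- sort(unique(c(a, cuts, b)))
  total <- 0; H0 <- 0
  for (k in seq_len(length(edges) - 1L)) {
    lo <- edges[k]; hi <- edges[k + 1L]
    j <- findInterval(lo + 1e-9, base$age_lo)
    h1 <- rr * h10[j]; h <- h1 + h2[j]
    m <- max(2L, ceiling((hi - lo) / step) + 1L)
    t <- seq(lo, hi, length.out = m)
    f <- h1 * exp(-(H0 + h * (t - lo)))
    total <- total + sum((f[-1] + f[-m]) / 2 * diff(t))
    H0 <- H0 + h * (hi - lo)
  }
  total
}

# random raw profiles with draws over the full category ranges
random_profiles <- function(n, seed) {
  dist <- covariate_distribution()
  sample_covariates(dist, n, seed)
}

packaged_bundles <- function() {
  lapply(stats::setNames(nm = c("breast", "endometrial", "ovarian")),
         beo_bundle)
}

# published 10-/20-year absolute risks (percent) for the 15 example profiles
example_profile_risks <- function() {
  read.csv(text = "profile,breast_10y,breast_20y,endometrial_10y,endometrial_20y,ovarian_10y,ovarian_20y,premenopausal
1,1.83,4.23,0.51,1.36,0.28,0.74,TRUE
2,1.57,3.64,0.51,1.36,0.28,0.74,TRUE
3,1.76,4.07,0.35,0.92,0.28,0.74,TRUE
4,3.09,7.08,0.59,1.59,0.28,0.74,TRUE
5,8.75,19.26,1.17,3.09,0.41,1.09,FALSE
6,9.46,20.71,2.00,5.26,0.41,1.09,FALSE
7,6.84,15.27,4.13,10.67,0.41,1.09,FALSE
8,6.37,14.28,3.42,8.91,0.51,1.34,TRUE
9,2.45,4.35,0.72,1.22,0.52,0.96,FALSE
10,2.94,5.21,1.09,1.85,0.65,1.21,FALSE
11,3.29,5.83,1.09,1.85,0.65,1.21,FALSE
12,4.96,8.71,0.97,1.64,0.65,1.21,FALSE
13,20.27,32.94,2.52,4.25,0.96,1.77,FALSE
14,21.78,35.11,5.18,8.62,0.96,1.77,FALSE
15,16.09,26.73,10.50,17.08,0.96,1.77,FALSE")
}

example_profiles <- function() {
  read_profiles(system.file("extdata", "example_profiles.csv",
                            package = "beorisk"))
}

# printed registry rate table: raw and organ-corrected cells
published_rates <- function() {
  list(
    breast = c(272.42, 338.62, 410.08, 465.29, 499.40, 518.48, 491.45, 408.84),
    endometrial_raw = c(50.50, 77.50, 97.44, 106.50, 109.02, 106.05, 96.76, 69.26),
    endometrial_corrected = c(76.24, 127.55, 174.72, 193.67, 199.96, 196.35, 172.35, 118.09),
    ovarian_raw = c(25.93, 33.50, 43.47, 49.06, 56.15, 60.25, 62.68, 54.61),
    ovarian_corrected = c(32.20, 41.61, 59.28, 70.61, 73.12, 81.59, 85.04, 65.10))
}
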