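test_that("expected cases sum individual projections over follow-up", {
  b <- toy_bundle(incidence = 1000, mortality = 0, rr = 2)
  empty <- data.frame(entry_age = numeric(0), exit_age = numeric(0),
                      event = logical(0))
  expect_equal(expected_cases(empty, b), 0)

  cohort <- data.frame(entry_age = c(50, 60), exit_age = c(55, 70),
                       event = c(FALSE, TRUE),
                       family_history_breast_ovarian = c(FALSE, TRUE))
  # flat hazard 0.01, rr 1 and 2: pi = 1 - exp(-h * t) with h2 = 0
  expect_equal(expected_cases(cohort, b),
               (1 - exp(-0.05)) + (1 - exp(-0.2)), tolerance = 1e-12)
  b0 <- toy_bundle(incidence = 0)
  expect_equal(expected_cases(cohort, b0), 0)
})

test_that("follow-up outside the age support is clipped with a warning", {
  b <- toy_bundle(incidence = 1000, mortality = 0, rr = 2)
  cohort <- data.frame(entry_age = 45, exit_age = 95, event = FALSE,
                       family_history_breast_ovarian = FALSE)
  expect_warning(e <- expected_cases(cohort, b), "clipped")
  expect_equal(e, 1 - exp(-0.01 * 40), tolerance = 1e-12)
})

test_that("E/O ratio uses the log-scale Poisson approximation", {
  r <- eo_ratio(100, 100)
  expect_equal(r$eo, 1)
  expect_equal(r$eo_lo, exp(-1.96 / 10), tolerance = 1e-12)
  expect_equal(r$eo_hi, exp(1.96 / 10), tolerance = 1e-12)
  expect_equal(round(c(r$eo_lo, r$eo_hi), 3), c(0.822, 1.217))

  # published overall breast calibration pair rounds to 1.00 (0.96-1.04)
  r2 <- eo_ratio(2930, 2934)
  expect_equal(round(r2$eo, 2), 1.00)
  expect_equal(round(c(r2$eo_lo, r2$eo_hi), 2), c(0.96, 1.04))

  expect_equal(eo_ratio(50, 25)$eo, 2)
  expect_warning(r0 <- eo_ratio(5, 0), "undefined")
  expect_true(is.na(r0$eo))

  # CI width on the log scale shrinks as 1 / sqrt(observed)
  w <- function(o) log(eo_ratio(o, o)$eo_hi / eo_ratio(o, o)$eo_lo)
  expect_equal(w(400) / w(100), 1 / 2, tolerance = 1e-12)
})

test_that("subgroup calibration partitions observed and expected exactly", {
  b <- toy_bundle(incidence = 2000, mortality = 1000, rr = 2)
  dist <- covariate_distribution()
  profs <- sample_covariates(dist, 400, seed = 9)
  cohort <- simulate_outcomes(profs, b, dist, seed = 10)
  cohort$stratum <- cohort$family_history_breast_ovarian

  overall <- eo_ratio(expected_cases(cohort, b), sum(cohort$event))
  rows <- subgroup_eo(cohort, b, "stratum")
  expect_equal(sum(rows$observed), overall$observed)
  expect_equal(sum(rows$expected), overall$expected, tolerance = 1e-10)

  # a single group reproduces the overall row
  cohort$one <- "all"
  one <- subgroup_eo(cohort, b, "one")
  expect_equal(one$observed, overall$observed)
  expect_equal(one$expected, overall$expected, tolerance = 1e-12)
  expect_equal(one$eo, overall$eo, tolerance = 1e-12)

  expect_error(subgroup_eo(cohort, b, "no_such_column"), "unknown grouping")
})

test_that("AUC equals pairwise concordance with ties counting one half", {
  expect_equal(auc_risk(c(1, 2, 3, 10), c(FALSE, FALSE, FALSE, TRUE),
                        bootstrap_reps = 0)$auc, 1)
  expect_equal(auc_risk(rep(0.3, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
                        bootstrap_reps = 0)$auc, 0.5)
  expect_equal(auc_risk(c(0.1, 0.2, 0.3, 0.4), c(FALSE, TRUE, FALSE, TRUE),
                        bootstrap_reps = 0)$auc, 0.75)
  expect_error(auc_risk(1:3, c(TRUE, TRUE, TRUE), 0), "at least one")
})

test_that("rank-sum AUC matches brute-force pair counting on small inputs", {
  brute <- function(r, s) {
    pairs <- expand.grid(case = which(s), ctrl = which(!s))
    mean(ifelse(r[pairs$case] > r[pairs$ctrl], 1,
                ifelse(r[pairs$case] == r[pairs$ctrl], 0.5, 0)))
  }
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(4:20, 1)
    r <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # many ties
    s <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(s) || all(s)) next
    expect_equal(auc_risk(r, s, bootstrap_reps = 0)$auc, brute(r, s))
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(12)
  r <- runif(60)
  s <- runif(60) < r
  if (!any(s) || all(s)) s[1:2] <- c(TRUE, FALSE)
  a1 <- auc_risk(r, s, bootstrap_reps = 0)$auc
  expect_equal(auc_risk(log(r + 1), s, bootstrap_reps = 0)$auc, a1)
  expect_equal(auc_risk(r^3, s, bootstrap_reps = 0)$auc, a1)
})

test_that("bootstrap CI is reproducible given a seed and brackets the point", {
  set.seed(5)
  r <- runif(150)
  s <- runif(150) < r
  a <- auc_risk(r, s, bootstrap_reps = 200, seed = 77)
  b <- auc_risk(r, s, bootstrap_reps = 200, seed = 77)
  expect_identical(a, b)
  expect_lte(a$auc_lo, a$auc)
  expect_gte(a$auc_hi, a$auc)
  expect_error(auc_risk(r, s, bootstrap_reps = 10), "seed")
  # the bootstrap leaves the caller's RNG stream untouched
  set.seed(5); x1 <- runif(1)
  set.seed(5); invisible(auc_risk(r, s, 50, seed = 3)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("validate_cohort assembles calibration and discrimination", {
  b <- toy_bundle(incidence = 3000, mortality = 1000, rr = 3)
  dist <- covariate_distribution()
  profs <- sample_covariates(dist, 600, seed = 21)
  cohort <- simulate_outcomes(profs, b, dist, seed = 22)
  rep <- validate_cohort(cohort, b,
                         grouping = "family_history_breast_ovarian",
                         bootstrap_reps = 50, seed = 4)
  expect_s3_class(rep, "validation_report")
  expect_equal(rep$overall$observed, sum(cohort$event))
  expect_equal(nrow(rep$by_group), 2L)
  expect_true(rep$overall$auc >= 0 && rep$overall$auc <= 1)
})
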