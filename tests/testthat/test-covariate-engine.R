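bundles <- packaged_bundles()

test_that("interval factors use left-closed right-open category boundaries", {
  breast <- bundles$breast$rr_model
  endo <- bundles$endometrial$rr_model
  lev <- function(p, model) encode_profile(p, model)$level_by_factor
  p <- function(bmi) risk_factor_profile(current_age = 50, bmi = bmi,
                                         parity = 3, age_first_birth = 22)
  expect_equal(lev(p(24), breast)$bmi, 0)
  expect_equal(lev(p(25), breast)$bmi, 1)
  expect_equal(lev(p(34.9), breast)$bmi, 2)
  expect_equal(lev(p(35), breast)$bmi, 3)
  expect_equal(lev(p(50), breast)$bmi, 3)   # open-ended top category
  expect_equal(lev(p(40), endo)$bmi, 4)
  expect_equal(lev(p(39.9), endo)$bmi, 3)

  afb <- function(a) lev(risk_factor_profile(current_age = 50, bmi = 22,
                                             parity = 2, age_first_birth = a),
                         breast)$age_first_birth
  expect_equal(afb(24), 0)
  expect_equal(afb(25), 1)  # "25-29" holds integer ages 25..29
  expect_equal(afb(29), 1)
  expect_equal(afb(30), 2)
})

test_that("duration and count factors resolve to the documented levels", {
  ov <- bundles$ovarian$rr_model
  endo <- bundles$endometrial$rr_model
  lev <- function(p, model) encode_profile(p, model)$level_by_factor
  base <- function(...) risk_factor_profile(current_age = 55, bmi = 30, ...)
  # parity reference is 3+ for endometrial/ovarian; nulliparity is level 2
  expect_equal(lev(base(parity = 0), ov)$parity, 2)
  expect_equal(lev(base(parity = 2, age_first_birth = 25), ov)$parity, 1)
  expect_equal(lev(base(parity = 6, age_first_birth = 25), ov)$parity, 0)
  # MHT duration: 0 -> never, (0,10) -> <10, >=10 -> 10+
  expect_equal(lev(base(mht_use_years = 0), ov)$mht_use, 0)
  expect_equal(lev(base(mht_use_years = 9.5), ov)$mht_use, 1)
  expect_equal(lev(base(mht_use_years = 10), ov)$mht_use, 2)
  # OC under 1 year (including never) is the elevated category
  expect_equal(lev(base(oc_use_years = 0), endo)$oc_use, 1)
  expect_equal(lev(base(oc_use_years = 0.5), endo)$oc_use, 1)
  expect_equal(lev(base(oc_use_years = 1), endo)$oc_use, 0)
  # premenopausal women take the NA/missing menopause level
  expect_equal(lev(base(menopause_status = "premenopausal"),
                   endo)$age_menopause, "NA/missing")
  expect_equal(lev(base(menopause_status = "postmenopausal",
                        age_at_menopause = 52), endo)$age_menopause, 1)
  expect_equal(lev(base(menopause_status = "postmenopausal",
                        age_at_menopause = 55), endo)$age_menopause, 2)
})

test_that("all-reference profiles score a relative risk of exactly 1", {
  for (b in bundles) {
    enc <- encode_profile(reference_profile(), b$rr_model)
    expect_identical(relative_risk(enc, b$rr_model), 1)
  }
})

test_that("relative risk is the product of the published multipliers", {
  ov <- bundles$ovarian$rr_model
  p <- risk_factor_profile(current_age = 50, oc_use_years = 5, parity = 2,
                           age_first_birth = 25, mht_use_years = 3,
                           family_history_breast_ovarian = TRUE)
  expect_equal(relative_risk(p, ov), 1.25 * 1.26 * 1.27)

  endo <- bundles$endometrial$rr_model
  q <- risk_factor_profile(current_age = 55, smoking = "never", bmi = 41,
                           oc_use_years = 2, parity = 1,
                           age_first_birth = 25,
                           menopause_status = "postmenopausal",
                           age_at_menopause = 52, mht_use_years = 4)
  expect_equal(relative_risk(q, endo), 1.47 * 1.72^4 * 1.21 * 1.26 * 1.15)
})

test_that("MHT-by-lean-BMI interaction multiplies per MHT category", {
  endo <- bundles$endometrial$rr_model
  base <- function(bmi, mht) risk_factor_profile(
    current_age = 55, smoking = "current", bmi = bmi, oc_use_years = 2,
    parity = 3, age_first_birth = 25, menopause_status = "postmenopausal",
    age_at_menopause = 48, mht_use_years = mht)
  for (k in 0:2) {
    mht_years <- c(0, 5, 12)[k + 1]
    lean <- relative_risk(base(22, mht_years), endo)
    heavy <- relative_risk(base(27, mht_years), endo)
    # moving BMI to reference changes rr by (1/1.72) * 1.61^k
    expect_equal(lean / heavy, (1 / 1.72) * 1.61^k, tolerance = 1e-12)
    # among lean women the per-category MHT slope is 1.15 * 1.61
    expect_equal(lean, (1.15 * 1.61)^k, tolerance = 1e-12)
  }
})

test_that("nulliparous women get the nulliparity term, reference age at first birth", {
  breast <- bundles$breast$rr_model
  p0 <- risk_factor_profile(current_age = 50, bmi = 22, parity = 0,
                            menopause_status = "postmenopausal",
                            age_at_menopause = 48, smoking = "current",
                            oc_use_years = 5, alcohol_drinks_per_day = 0)
  expect_equal(relative_risk(p0, breast), 1.32)
  enc <- encode_profile(p0, breast)
  expect_equal(enc$level_by_factor$age_first_birth, 0)
})

test_that("profiles agreeing on a model's factors score identically", {
  ov <- bundles$ovarian
  profs <- example_profiles()
  rr <- relative_risk(profs, ov$rr_model)
  expect_equal(rr[1], rr[2])  # profiles 1-4 share all ovarian factors
  expect_equal(rr[1], rr[3])
  expect_equal(rr[1], rr[4])
  expect_equal(rr[5], rr[6])  # profiles 5-7 likewise
  expect_equal(rr[5], rr[7])
  expect_equal(rr[5] / rr[1], 1.25 * 1.26 * 1.27 / 1.36, tolerance = 1e-12)
})

test_that("trend factors never decrease the relative risk", {
  endo <- bundles$endometrial$rr_model
  bmis <- c(22, 27, 32, 37, 42)
  rrs <- vapply(bmis, function(b) relative_risk(
    risk_factor_profile(current_age = 55, bmi = b, smoking = "current",
                        oc_use_years = 2, parity = 3, age_first_birth = 25,
                        menopause_status = "postmenopausal",
                        age_at_menopause = 48), endo), numeric(1))
  expect_true(all(diff(rrs) > 0))
})

test_that("missing required fields without a special level fail loudly", {
  breast <- bundles$breast$rr_model
  p <- reference_profile()
  p$bmi <- NA_real_
  expect_error(relative_risk(p, breast), "bmi")
  p2 <- reference_profile()
  p2$smoking <- "sometimes"
  expect_error(relative_risk(p2, bundles$endometrial$rr_model), "smoking")
})

test_that("model constructors reject malformed codings", {
  expect_error(factor_coding("x", "only-one", "trend", 1.5), ">= 2")
  expect_error(factor_coding("x", c("a", "b"), "per_category", c(1.2, -1)),
               "positive|multiplier")
  expect_error(factor_coding("x", c("a", "b", "b"), "per_category",
                             c(1.2, 1.3)), "distinct")
  expect_error(rr_model("ovarian", list(
    factor_coding("oc_use", c("1+y", "<1y"), "per_category", 1.36)),
    list(interaction_term("bmi", 0, "oc_use", 1.5))), "undeclared")
  expect_error(rr_model("ovarian", list(
    factor_coding("oc_use", c("1+y", "<1y"), "per_category", 1.36)),
    list(interaction_term("oc_use", 0, "oc_use", 1.5))), "trend")
})
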