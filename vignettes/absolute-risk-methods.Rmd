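---
title: "Methods: projecting absolute breast, endometrial, and ovarian cancer risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting absolute breast, endometrial, and ovarian cancer risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beorisk)
```

## The model

beorisk projects the absolute risk $\pi(a, b)$ that a white, non-Hispanic
woman aged 50 or older develops invasive breast, endometrial, or ovarian
cancer in the age interval $(a, b]$, given that she is alive and free of that
cancer at age $a$. Absolute risk accounts for the competing risk of dying of
something else first:

$$\pi(a,b) = \int_a^b \lambda_1(t, x)\,
  \exp\!\Big(-\!\int_a^t \lambda_1(u, x) + \lambda_2(u)\, du\Big)\, dt,$$

where $\lambda_1(t,x) = \lambda_{10}(t)\, \mathrm{rr}(x)$ is the
cause-specific cancer hazard and $\lambda_2$ the covariate-free hazard of
death from other causes. Three ingredients are combined:

1. **Relative risk** $\mathrm{rr}(x) = e^{\beta'x}$, a product of published
   categorical multipliers (one per risk factor, lowest-risk category as
   reference, so the all-reference woman has $\mathrm{rr} = 1$).
2. **Baseline hazard** $\lambda_{10}(t) = \lambda_1^*(t)(1 - \mathrm{AR})$:
   registry age-specific incidence deflated by the attributable risk
   $\mathrm{AR} = 1 - N / \sum_i \mathrm{rr}_i$, the fraction of incidence
   attributable to risk-factor levels above reference in the source cohorts.
   The packaged constants are 0.52 (breast), 0.81 (endometrial), and 0.43
   (ovarian).
3. **Competing mortality** $\lambda_2(t)$ from age-specific death rates for
   causes other than the three cancers.

All hazards are piecewise constant on 5-year age bins covering $[50, 90)$
(the registry's open-ended 85+ group is treated as $[85,90)$, and
projections are capped at 90, where the models' support ends). On that grid
the integral has the closed form implemented in `absolute_risk()`:

$$\pi = \sum_j S_j\, \frac{h_{1j}}{h_{1j}+h_{2j}}
  \left(1 - e^{-(h_{1j}+h_{2j})\Delta_j}\right),
  \qquad S_j = \prod_{k<j} e^{-(h_{1k}+h_{2k})\Delta_k},$$

with $\Delta_j$ the (possibly partial) overlap of the projection interval
with bin $j$. When $a$ or $b$ falls inside a bin, the bin's constant hazards
simply apply over the partial width. Covariates are frozen at their baseline
values for the whole projection — a 50-year-old premenopausal woman is not
aged into menopause mid-projection — matching how the published risk
profiles are defined. `absolute_risk()` also returns
`prob_competing_death` and `prob_event_free`; the three probabilities sum to
one, a decomposition the test suite asserts on every call it makes.

## Parameter bundles

Each cancer's parameters live in a plain-text bundle directory
(`inst/extdata/bundles/<cancer>/`): the relative-risk model as YAML, and all
rate tables as CSV with header `age_lo,age_hi,rate_per_100k`, stored exactly
as printed in their sources so they can be audited cell by cell. Conversion
to per-year hazards (rate / 100,000) happens only inside the projection
engine.

Two registry subtleties are handled at load time:

* **Organ-removal correction.** Registry endometrial and ovarian rates are
  computed over all women, including those who have had a hysterectomy or
  bilateral oophorectomy and are not at risk. `correct_rates()` divides each
  bin's rate by the proportion of women with the organ intact. The packaged
  intact-organ proportions are *derived*: they are back-solved bin-wise from
  the published raw/corrected rate pairs (files named `*_derived.csv`), so
  the corrected table reproduces every published cell by construction —
  which the tests then verify end to end through the loader.
* **Competing mortality.** The packaged competing-mortality table
  (`competing_mortality_synthetic.csv`) is a clearly labelled *synthetic*
  stand-in, constructed from US life-table all-cause mortality for white
  women around the turn of the millennium minus approximate mortality from
  the three modelled cancers. Projected risks at ages 50–70 are insensitive
  to plausible error in this table (the cancer hazards are small relative to
  one, and the mortality deflation over a 10-year window is a few percent);
  20-year projections from age 65 are the most sensitive, at roughly 0.02
  percentage points of ovarian risk per 10% error in mortality.

An optional variant treats hysterectomy/oophorectomy itself as an additional
competing risk (`include_organ_removal_competing = TRUE`), for women who may
lose the organ at risk during the projection. The packaged organ-removal
rates are synthetic too, derived from the intact-organ prevalence curve as a
discrete log-gradient hazard, clamped at zero where prevalence is
non-monotone. The variant is off by default; the published example risks use
prevalence-corrected rates with organ-removal *not* added to the competing
hazard, and so do we.

## Covariate coding

`encode_profile()` maps raw fields to category levels with left-closed,
right-open intervals: "25 to <30" contains exactly $[25, 30)$, "35+" is
$[35, \infty)$, and age at first birth "25–29" holds the integer ages 25–29.
Decisions where the published coding leaves room:

* **Trend factors** contribute $\mathrm{rr}^k$ with $k$ the 0-based ordinal
  distance from the reference (standard Cox trend coding). The ovarian
  example profiles corroborate this: profiles differing only in non-ovarian
  factors score identical ovarian risks, and the high/low profile risk ratio
  matches $1.25 \times 1.26 \times 1.27 / 1.36$.
* **MHT duration** (never, <10, 10+ years) parses years as: 0 → never,
  (0, 10) → <10, ≥10 → 10+. **Oral contraceptive use** under one year
  (including never) is the elevated-risk category for endometrial and
  ovarian cancer; one or more years is the reference.
* **The MHT-by-BMI interaction** (endometrial): among women with BMI <25,
  each MHT duration category multiplies risk by an extra 1.61, i.e. the per
  category MHT slope among lean women is $1.15 \times 1.61$ — a product term
  between a trend variable and an indicator.
* **Nulliparous women** take the breast model's nulliparity multiplier
  (1.32) with age at first birth held at reference, since age at first
  birth is undefined for them; for endometrial/ovarian they occupy the
  parity-0 level (reference 3+).
* **Premenopausal women** (and women with unknown menopause age) take the
  "NA/missing" age-at-menopause multiplier (1.17 breast, 1.29 endometrial).
  The source material also mentions a separate premenopausal indicator whose
  coefficient was not published, so premenopausal breast/endometrial
  projections carry extra uncertainty; our premenopausal example-profile
  risks agree with the published ones to within about 8% relative, versus
  about 4% for postmenopausal profiles, and the acceptance tests check them
  at a correspondingly wider band (20% vs 10% relative; ovarian risks, which
  have no menopause term, are checked at ±0.02 percentage points).

## Validation statistics

Calibration is summarised by the expected/observed ratio. Expected counts
sum each woman's projected risk over her follow-up; in cohort validation the
window runs from entry to administrative end of follow-up, with losses to
death absorbed by the projection itself (the simulator's `admin_end_age`
column supports this convention). The 95% CI uses the normal approximation
to the Poisson distribution on the log scale,
$(E/O)\exp(\pm 1.96/\sqrt{O})$ — the standard form, which reproduces
published CI shapes to rounding; with $O = 0$ the ratio is reported as
undefined rather than approximated. Discrimination is the AUC: the
probability that a random case carries a higher projected risk than a random
non-case, ties counting one half, computed by mid-ranks (provably equal to
brute-force pair counting, which the tests assert on small tied inputs) with
a percentile bootstrap CI over individuals (default 1000 replicates, seed
mandatory).

## The synthetic cohort generator

`sample_covariates()` draws profiles from independent per-factor discrete
marginals; `simulate_outcomes()` then draws each woman's outcome from the
piecewise-exponential cause-specific hazards the bundle implies, by exact
exponential inversion bin by bin (no time discretization), attributing an
event to cancer with probability $h_1/(h_1+h_2)$ and censoring at entry age
plus horizon or age 90. All randomness flows from one explicit seed through
a local RNG scope, leaving the caller's stream untouched.

The default distribution emulates a large US cohort of predominantly
postmenopausal white women: entry ages uniform over 50–72 with a 14-year
administrative horizon (mirroring a mid-1990s-to-2000s follow-up window),
obesity, hormone-use, parity, smoking, and family-history marginals chosen
to resemble the published cohort characteristics (e.g. 45% BMI <25, 60%
never/under-1-year OC use, 40% MHT never-users, 12% nulliparity, 15% family
history, 5% premenopausal at entry). Total MHT duration is split into
combined estrogen+progestin versus other-type use by a 75/25 share, the one
deliberate within-factor coupling; factors are otherwise independent, which
real risk factors are not (BMI and MHT use correlate negatively, for
instance). A joint-table override exists for correlation studies. Passing
calibration on these cohorts therefore demonstrates internal consistency of
the engine — simulated incidence matches projected incidence overall and
within subgroups — not external validity on any real population.

## Numerical choices

* Rates are stored per 100,000 person-years as printed and divided by
  100,000 exactly once, in the engine; no actuarial adjustment is applied.
* `1 - exp(-x)` is computed with `expm1` for accuracy at small hazards; a
  zero total hazard contributes zero risk rather than 0/0.
* The closed-form engine is cross-checked against an independent fine-grid
  trapezoid quadrature of the risk integral (step 0.001 years, segments
  aligned to bin edges) to within $10^{-8}$ absolute on random profiles for
  all three packaged bundles.
* Problem sizes in the test suite were chosen for tight Monte-Carlo error at
  interactive runtimes: 50,000-woman cohorts per bundle for calibration
  closure (binomial 3-SE bands), 100,000 draws for marginal-frequency and
  attributable-risk recovery checks, 100 random profiles per bundle for
  oracle agreement.

## Known limitations

* The models apply to white, non-Hispanic women aged 50–89 without a prior
  diagnosis of the cancer in question and outside known high-risk mutation
  groups (BRCA1/2, Lynch syndrome); no confidence intervals accompany
  projected risks.
* The packaged competing-mortality and organ-removal tables are synthetic
  stand-ins as described above; users with access to registry mortality for
  the matching period and population should drop replacement tables into a
  bundle directory (the loader validates them).
* Premenopausal breast/endometrial projections inherit the menopause-coding
  ambiguity discussed under covariate coding.
* Calibration statements rest on simulated cohorts; no claim is made about
  calibration in contemporary populations, where hormone-therapy use in
  particular differs from the source cohorts' era.
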