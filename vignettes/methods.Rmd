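---
title: "Methods: a nested case-control pipeline for polypharmacy and dementia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a nested case-control pipeline for polypharmacy and dementia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design

`polydem` implements a nested case-control analysis of polypharmacy and
incident dementia in longitudinal health-insurance claims. The study base is
an insured elderly population (aged 65 or older at baseline) followed over
twelve calendar years. Cases are community-dwelling persons newly diagnosed
with dementia (ICD-10 codes F00, F01, F02, F03, F051, G30, G311) during the
case window (2005–2013), after a claim-free washout covering the first study
years, with no inpatient claim of any cause before diagnosis and at least two
outpatient claims by the diagnosis (index) date. Each case is matched 1:1 to
a control sharing age at index, sex, income level and index year; the control
inherits the case's index date and must be alive, enrolled, dementia-free,
community-dwelling and an outpatient-service user at that date.

All exposures are measured over the fixed 730-day look-back window preceding
the index date. Three exposure families are derived:

* **Average daily prescribed drug count.** For every day $d$ of the window,
  $c(d)$ counts the distinct drug codes with an active prescription on $d$
  (a prescription covers `[dispense_date, dispense_date + days_supplied)`);
  combination antihypertensive/antidiabetic products contribute their
  active-ingredient count instead of 1. The exposure is
  $\sum_d c(d) / 730$, computed by an interval sweep (per-code interval
  union, then an ingredient-weighted sum) rather than per-day enumeration;
  the two are provably identical and the test suite checks the identity by
  brute force. Categories are `<1`, `1–<5`, `5–<10`, `≥10` with inclusive
  lower bounds; polypharmacy is an average of ≥ 5 drugs per day.
* **PIM medication possession ratio (MPR).** For each potentially
  inappropriate medication class (benzodiazepines — short/intermediate,
  long-acting, receptor agonists —, anticholinergics, H2-receptor
  antagonists), the MPR is the percentage of window days covered by at least
  one prescription of the class (same-class overlaps count once). MPR is
  reported continuously, binned as `0`, `>0–<50`, `50–100`, and collapsed to
  a binary any-use flag.
* **Comorbidity and Charlson score.** A comorbidity group is flagged when at
  least one claim in the window (index date inclusive, so a case's own
  diagnosis claim is visible) carries a matching ICD-10 code; the Charlson
  score sums the classic 1/2/3/6 weights over the 17 weighted groups.

## Estimation

Crude odds ratios come from univariate logistic regression of case status on
the four-level drug-count category (`<1` as reference); the matched-design
companion, conditional logistic regression on within-pair contrasts, is
provided as well and reduces to the discordant-pair ratio for one binary
exposure. Interactions between the binary polypharmacy flag and each
comorbidity or PIM any-use flag are screened with a likelihood-ratio test
(Wald available behind a flag), at a 0.001 threshold by default.
Comorbidity-subgroup analyses fit the category model separately inside the
with-disease and without-disease strata of each comorbidity and combine the
per-subgroup log-ORs by fixed-effect inverse variance
($\hat\beta = \sum w_i \hat\beta_i / \sum w_i$, $w_i = 1/\mathrm{se}_i^2$).
Multivariable models add covariate blocks stepwise (PIM flags; the
non-interacting comorbidity-group indicator; the interacting-group
indicator), and the interaction models add category-by-factor products, from
which category ORs are reported separately for absence and presence of each
interacting factor (delta-method SEs for the presence stratum). Any cell
with fewer than 5 subjects is suppressed rather than reported.

Numerical choices: 2×2 tables use the cross-product OR with the Woolf SE;
when a zero cell appears, the Haldane–Anscombe correction adds 0.5 to all
four cells and the estimate is flagged; two zero cells in one margin leave
the estimate undefined. Logistic fits use IRLS with a tightened convergence
tolerance (1e-12) so the single-covariate fit agrees with the closed-form
cross-product OR to well below 1e-6; quasi-separation is flagged
(`not_converged`), aliased covariates are dropped with a warning, and no
multiple-testing correction is applied to the interaction screen (raw
p-values against a stringent 0.001 threshold). All confidence intervals are
Wald intervals `exp(log OR ± 1.96 se)` by construction.

## The synthetic-data generator

Real claims databases of this kind are not redistributable, so the package
ships a generator whose output has the statistical structure the analysis
assumes, with known truth:

* **Demographics.** Ages 65–95 at baseline with a geometrically decaying
  weight, 71.8% women (the share reported for the study population the
  design emulates), eleven income levels (level 0 = medical aid, ~8%),
  constant enrollment from the study start, and a 4.5%/year mortality
  hazard.
* **Chronic drug regimens.** Each person draws a negative-binomial number of
  chronic drug "slots" (mean 1.55, size 1.25, capped at 14); 10% of slots
  are combination antihypertensive/antidiabetic codes carrying 2–3
  ingredients. Each slot is realised as back-to-back refill episodes (60–120
  days, 30% of slots refill 10 days early to create same-code overlaps that
  exercise the deduplication rule) covering the whole period from the year
  before exposure windows open until the end of enrollment. Coverage is
  therefore gap-free and the realised look-back drug count equals the latent
  chronic count exactly.
* **PIM use.** Per class, an any-use probability (21/23/5/44/47% for the five
  classes, matching the control-arm any-use range of the emulated study) and
  a small chronic-use probability that produces the 50–100 MPR stratum;
  non-chronic users get a fixed yearly pattern of 1–2 short episodes (7–20
  days), landing in the >0–<50 stratum. Intermittent and acute scripts
  (0.4/year, 7–30 days) add a fractional contribution to the drug count
  that is structurally below one drug, so they can never move a person
  across a category boundary: the configured category remains the exact
  estimand.
* **Comorbidity claims.** Latent group indicators are Bernoulli with
  prevalences inside the control-arm ranges of the emulated population
  (e.g. hypertension 0.55); flagged persons emit Poisson(1.2)/year claims
  with codes chosen to match exactly one group in the default code sets.
  Everybody emits Poisson(3)/year neutral outpatient claims (so the
  outpatient-utilisation rule is almost always met) and 8% get an inpatient
  claim that the community-dwelling rule later excludes.
* **Outcome.** A discrete-time hazard: in each year of the case window an
  at-risk person develops dementia with probability
  `plogis(intercept + Xβ)`, where X holds the polypharmacy category
  (defaults anchored at ORs 1.72 / 2.64 / 3.35 for the three upper
  categories), PIM any-use flags, comorbidity flags, and optional
  polypharmacy-by-covariate products. The default intercept (−6.4) yields a
  cumulative incidence near 15%, the case fraction of the emulated study
  base. Cases receive dementia claims from their index year onward with
  subtype code sets (Alzheimer / other-cause / mixed at 33.1 / 38.5 /
  28.4%); 2% of persons are "prevalent" with dementia claims during the
  washout years, exercising the incident-case rule.

**What the generator does not emulate.** Comorbidities, PIM use and the
chronic drug count are drawn independently, whereas in real claims they are
strongly correlated (comorbidity drives prescribing); there are no secular
trends, no partial enrollment, no dose information, and drug codes are
synthetic tokens rather than a national dictionary. Passing tests therefore
demonstrate that the pipeline recovers known effects under the stated
sampling design — not that real-data confounding is handled beyond what the
matched design and the fitted adjustments provide.

**Recovery study conditions.** The parameter-recovery harness
(`run_recovery_study()`) uses 50 replicate seeds at n = 20,000 persons with
all PIM and comorbidity odds ratios set to 1 and a −4.6 intercept, so the
marginal crude OR coincides with the conditional truth (odds ratios are
non-collapsible; with covariate effects present, the crude OR of a pooled
case-control sample is attenuated even without confounding). Under these
conditions each replicate yields roughly 1,700 matched pairs, and the
configured true ORs fall inside the estimated 95% CI in well over 90% of
replicates for all three categories.

## Open design choices and their resolutions

* *"More than one" qualifying code.* The dementia definition is read as ≥ 1
  qualifying claim by default; `min_dementia_claims` exposes the stricter
  literal reading (≥ 2), with the index date moved to the k-th claim.
* *Washout length.* New diagnosis from 2005 with data starting 2002 is
  operationalised as a 3-year claim-free washout; `washout_years` is a
  parameter.
* *Outpatient utilisation.* "More than once" defaults to
  `min_outpatient_visits = 2`, configurable.
* *Age matching.* Exact integer age at index by default; `age_band` allows
  relaxation.
* *Control reuse.* Controls are sampled without replacement across pairs
  (no reuse), processing cases in index-date order with seeded uniform
  tie-breaking; `allow_control_reuse` switches to reuse. A person may serve
  as a control before later becoming a case (incidence-density sampling);
  controls are required to be dementia-free only through the index date.
* *Subtype codes.* Subtype classification uses all qualifying codes ever
  observed (the mixed definition requires both code families
  "simultaneously" in the person's record, not on one day).
* *Drug window boundary.* The drug window is the half-open
  `[index − 730, index)` — the index date itself is excluded for drugs but
  included for diagnoses, so the case's dementia claim is visible to the
  comorbidity profile (its dementia flag is 100% in cases by construction).
* *Comorbidity dictionaries.* The study-specific ICD-10 lists and the
  national drug dictionary are not public; the package ships a Quan-style
  Charlson mapping (classic weights) and illustrative PIM class pools, and
  treats the YAML config as the per-run source of truth. The delirium
  comorbidity group uses prefix F050 so that F051 stays exclusively a
  dementia-defining code.
* *Interaction models.* The screen uses the binary ≥ 5 flag; the stratified
  multivariable models use category-by-factor products, because reporting
  distinct category ORs for absence/presence of a factor requires products
  with the full category factor.

## Problem sizes used by the shipped validation

The test suite exercises the exposure sweep against per-day enumeration on
1,000 random prescription sets, the logistic/cross-product identity on 100
random tables, pooling against hand-computed closed forms, cohort selection
against a rule-by-rule oracle on 1,000-person panels, interaction-test size
on 1,000 null replicates of n = 2,000, and parameter recovery on 50
replicates of n = 20,000. The acceptance script
(`scripts/acceptance.R`) re-runs the full pipeline at n = 20,000 and the
50-seed recovery study from scratch.

## Known limitations

Fixed-effect pooling only (no random-effects heterogeneity model); no
dose/defined-daily-dose normalisation; no propensity or variable-ratio
matching; unconditional ML for the stratified multivariable models (the
conditional fit is available for the simple category model); the generator's
independence assumptions listed above.
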