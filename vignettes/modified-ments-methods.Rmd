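---
title: "Scoring, ranking and reliability methods in mentsr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, ranking and reliability methods in mentsr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mentsr)
```

## The instrument

`mentsr` implements a modified Medically Necessary Time-Sensitive (MeNTS)
prioritization worksheet for gynecologic surgical services. Sixteen factors,
each scored 1–5, are grouped into Procedure (5), Disease (4) and Patient (7)
components; the total is the sum of the component subtotals and ranges from
16 to 80. The orientation is fixed throughout the package: **1 is the
strongest argument to proceed, 5 the strongest argument to defer**, so lower
totals mean higher surgical priority and queues sort ascending.

The rubric is configuration, not code. It ships as a JSON document
(`system.file("extdata", "modified_ments_rubric.json", package = "mentsr")`)
whose levels are either left-closed numeric intervals `[lower, upper)` (the
top level also includes its upper bound) or category sets over a declared,
risk-ordered domain. `read_rubric()` validates that each factor's criteria
are *exhaustive and mutually exclusive* over its declared domain, so any
complete case record matches exactly one level of every factor; gaps and
overlaps are rejected with the factor and the offending values named. Users
can encode their own instruments the same way.

### Reconstructed cut-points

The instrument's published description fixes the factor list, the 1–5 scale,
the anesthesia ladder (local < MAC < regional < general-LMA < GETA), the
delay strata (3–6 months; more than 6 months), the BMI obesity classes
(<30 / 30–34.9 / 35–39.9 / 40–49.9 / ≥50) and the HbA1c > 8% diabetes
threshold, but not every cell's wording. Where cells are not published the
defaults are reconstructed and labelled as such in the document:

- **OR time** bands ≤30 / 31–60 / 61–120 / 121–180 / >180 min; **LOS**
  outpatient / <24 h / 24–48 h / 2–3 d / >3 d; **ICU need** probability
  bands.
- **Age** bands ≤20 / 21–40 / 41–50 / 51–65 / >65 years, taken from the
  original instrument's anchors.
- **Site/approach** ladder: minor external pelvic or minimally invasive to
  the uterus (hysteroscopy, D&C) < vaginal < laparoscopic/robotic < open
  abdominal < open with upper-abdominal/bowel/aerodigestive involvement (the
  fifth rung is reconstructed).
- **Cardiovascular disease** ladder from none through controlled and
  uncontrolled hypertension to stable CAD/CHF and multiple or uncontrolled
  CV disease.

Three design choices deserve explanation:

- **Smoking and OSA** are published as patient-factor modifications but the
  instrument lists seven patient factors; they are folded into the
  lung-disease factor through a derived `pulmonary_class`, the *worst* of
  the lung-disease grade (none → controlled asthma → uncontrolled asthma →
  COPD → severe COPD), the smoking grade (never → former → current) and the
  OSA grade (none → treated → untreated). The maximum preserves
  monotonicity: worsening any input can never lower the factor score.
- **Diabetes** maps none / diet-controlled / medicated HbA1c ≤ 8 to scores
  1/2/3 and medicated HbA1c > 8 to score 5, with score 4 reserved for
  HbA1c > 8 with *documented absence* of end-organ disease (an optional
  `diabetes_end_organ` field, default `unknown`, which scores
  conservatively at 5). This keeps the five levels a true partition while
  preserving the published threshold.
- **Binary attributes** (immunocompromise: no → 1, yes → 5; COVID status:
  negative → 1, unknown → 3, positive → 5) cannot occupy five levels; the
  unused middle levels carry empty criteria sets, which the validator
  accepts as long as the partition over the declared domain is exact.
  Scoring unknown COVID status at the middle level avoids biasing totals in
  a cohort where almost everyone is untested.

Missing attributes always raise errors naming the factor and attribute;
imputation policy belongs to the caller.

## Ranking and summaries

`rank_cases()` sorts ascending by total. Equal totals are broken by disease
subtotal (ascending — the more time-sensitive disease first) and then by
case id, making queues deterministic and order-independent. When a case is
scored by a rater pair, ranking operates on one sheet set;
`aggregate_sheets()` offers attending-only (default) or mean-of-pair
aggregation. Group summaries report median and range (the midpoint of the
two central values for even group sizes), and `tier_crosswalk()` checks the
expected monotone pattern median(high) ≤ median(intermediate) ≤ median(low)
across a three-tier acuity schema.

## Inter-rater reliability

Reliability between two blinded raters' totals uses the two-way crossed
ANOVA decomposition without replication: with subject mean squares $MS_R$,
rater mean squares $MS_C$ and residual $MS_E$ on $n$ subjects and $k$
raters, the single-rater absolute-agreement ICC (Shrout–Fleiss ICC(2,1)) is

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}.$$

The *agreement* form is used (rather than consistency) because it counts
systematic rater offsets as disagreement and is therefore the more
conservative estimate. The *single-rater* form is the default because a
case in practice is scored by one clinician; the average-measure form
ICC(A,k) is available via `measure = "average"`. Estimates are interpreted
on the Cicchetti bands: poor < 0.40, fair 0.40–0.59, good 0.60–0.74,
excellent ≥ 0.75. A fully constant rating matrix has no defined ICC and
raises an error rather than returning a silent zero.

`per_site_icc()` estimates one ICC per site and a pooled ICC on all sites
stacked into a single ANOVA (stacking, rather than averaging site
estimates, keeps the pooled estimate interpretable as a single agreement
ratio). Cases lacking a complete rater pair are dropped listwise with a
reported count; sites with fewer than two complete pairs are flagged
`insufficient` instead of estimated.

`rank_agreement()` implements the tolerance-based rank-consistency
statistic: the fraction of items whose rank positions under two raters
differ by at most the tolerance (default 2, *inclusive* — a difference of
exactly 2 counts as consistent). Inputs must be true permutations of
`1..n`.

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* of a 392-patient,
three-hospital gynecology surgical waitlist: categorical marginals for
race/ethnicity (293/19/15/12/53 of 392), menopausal status (263/129), lung
disease (43 affected), cardiovascular disease (205), diabetes (54,
including 34 medicated), immunocompromise (19), COVID status (386 unknown;
the 6 remaining patients are assigned negative), surgical indication
(130/77/56/29/26/7/67) and planned approach (56 open / 215 MIS / 121
other), plus continuous anchors age 46 (20–86), BMI 30.7 (17.8–67.3) and
parity 2 (0–8).

Counts are made **exact** by largest-remainder apportionment
(`allocate_counts()`: floor each $n p$, hand remaining units to the largest
fractional parts, ties by declared order) followed by a seeded shuffle, so
every run at any seed reproduces the configured marginals to the unit.
Continuous attributes come from a two-piece sampler whose halves are
triangular densities peaking at the median anchor: all draws stay in
`[min, max]` and the sample median concentrates at the anchor (the source
table reports exactly median and range, so any sampler matching those
anchors is acceptable).

Attributes the source table does not report carry fixed package defaults
chosen once as clinically plausible for this population: smoking never /
former / current = 0.70/0.18/0.12, OSA none/treated/untreated =
0.85/0.09/0.06, severity splits inside the lung (25/10/6/2), CV
(140/40/20/5) and diabetes (20 diet / 34 medicated) totals, HbA1c anchors
5.8/7.6/11.2, and an approximately equal three-site split.

Procedure and disease attributes are filled from indication- and
approach-conditional templates (e.g. AUB planned as MIS → laparoscopic
hysterectomy; prolapse → vaginal repair; cancer → open staging with severe
delay impact), with a small seeded jitter (default probability 0.15 of a
one-step shift) on the four disease levels. Acuity tiers follow the
indication: cancer and adnexal mass are high, AUB and precancer
intermediate, prolapse/contraception/other low.

**What the generator does not emulate.** Joint dependence beyond the
templates: marginals are sampled independently, so real-world correlations
(age with menopausal status, BMI with diabetes) are absent. It makes no
attempt to reproduce the published empirical score distribution or ICC
values, which depend on unreleased per-case rater data. Passing tests
therefore demonstrate that the engine and statistics behave correctly under
the cohort's *marginal* structure, not that the synthetic cohort is a
clinical replica.

### The rater-noise model

`simulate_rater_pair()` scores every case deterministically (the attending
sheet) and derives a trainee sheet by shifting each factor score by ±1 with
a per-factor disagreement probability, plus an optional systematic offset,
clipping to the 1–5 scale. Clipping keeps all sheet invariants intact and
gives the model a closed-form mean and variance for the total disagreement
per case — the tests use exactly that variance decomposition to predict the
resulting ICC and check the simulation against the theory, and the
parameter-recovery test generates continuous subject + rater + noise
ratings with known variance components $(\sigma_s^2, \sigma_r^2,
\sigma_e^2)$ and verifies convergence to
$\sigma_s^2/(\sigma_s^2+\sigma_r^2+\sigma_e^2)$.

## Numerical and interface choices

- Numeric rubric bands are left-closed so published category edges (BMI 30,
  OR time 31 min) land in the intended level; interval arithmetic uses a
  1e-9 tolerance when validating contiguity.
- Queues, summaries and ICC tables are plain tibbles; fitted objects
  (`ments_icc`, `ments_crosswalk`) have `tidy()`/`glance()` methods and the
  crosswalk an `autoplot()`.
- CSV I/O is RFC 4180, UTF-8, "." decimal, with `#` metadata comment
  headers (tool version, rubric version, seed); writes are atomic (a
  temporary file is renamed into place) so failures never leave partial
  outputs. Unparseable cells and missing required columns are reported with
  row and column context.
- All randomness (cohort, jitter, rater noise) is seeded through
  configuration objects; identical configurations produce byte-identical
  data rows.

## Problem sizes used by the test suite

The suite exercises the pipeline at the cohort's natural size where the
check is about calibration (marginal exactness at n = 392; the end-to-end
simulate → score → rank → ICC closure) and at smaller sizes elsewhere:
ICC oracle equivalence on 200 random matrices with n ∈ [3, 10], k ∈ [2, 4]
against an explicit double-loop sum-of-squares oracle (tolerance 1e-10);
parameter recovery at n = 1000, k = 2 over 50 seeds (tolerance 0.03 on the
mean); noise-model theory checks at n = 200–500.

## Known limitations

- The component factor counts (5/4/7, total range 16–80) follow the
  instrument's stated possible range; published per-component subgroup
  ranges elsewhere imply component minima below the structural minimum of
  one point per factor, a discrepancy that cannot be reconciled from the
  published material and is left as-is here.
- Reconstructed cells (ICU bands, CV ladder, immunocompromise gradations,
  the fifth site rung) are package defaults, not published text; they are
  explicitly labelled in the rubric document and editable there.
- The tool scores and ranks; it does not decide. No OR-schedule
  optimization, block-time allocation or clinical recommendation is in
  scope, and confidence intervals for ICC are intentionally not provided.
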