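---
title: "Methods: molecular classification, cost modelling and adjusted RMST"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular classification, cost modelling and adjusted RMST}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endomol)
```

This vignette is the package's account of its science: the classification
cascade, the cost model, the survival machinery, the synthetic generator,
and the decisions taken where the design was genuinely open.

## Marker interpretation and the classification cascades

Three marker-level interpretations feed the cascade:

* **MMR immunohistochemistry** uses the two-marker PMS2/MSH6 panel. A tumor
  is *deficient* when at least one marker shows complete loss of nuclear
  staining **and** internal non-neoplastic tissue retains staining (the
  internal positive control). A failed control, or a non-evaluable marker
  with no valid loss, yields *indeterminate* — a value, not an error, at the
  interpretation level. We treat indeterminate MMR as a hard error inside an
  MMR-requiring cascade rather than silently routing the patient onward,
  because a misrouted patient corrupts downstream test tallies and costs;
  auditability beats convenience here.
* **p53 immunohistochemistry** distinguishes wild-type from three abnormal
  patterns, evaluated in a fixed order: *diffuse* (strong nuclear positivity
  in ≥ 80 % of tumor nuclei — the boundary is inclusive), then *null*
  (complete absence of tumor nuclear staining), then *cytoplasmic*
  (unequivocal cytoplasmic staining, which by definition is accompanied by
  variable nuclear staining). The order matters only for inconsistent raw
  fields: diffuse requires affirmative quantitation, null requires absence,
  so cytoplasmic is evaluated last. A `p53_pattern_override` column takes
  precedence over the raw fields for laboratories that record patterns
  directly.
* **DNA quality control** has one hard gate: failed reference-gene (GAPDH)
  amplification excludes the sample from any sequencing-dependent algorithm.
  Spectrophotometric purity ratios outside 1.80–2.30 only downgrade a pass
  to `pass_with_warning` — they flag marginal DNA, they do not exclude.

`classify_cascade()` runs the stepwise classification: ProMisE order
(MMR → POLE → p53), WHO order (POLE → MMR → p53), or POLE-alone. The two
full cascades assign identical subgroups except for tumors carrying both
MMR loss and a pathogenic POLE variant, which ProMisE labels MMR-d and the
WHO order labels POLE-mut; the test suite proves this by exhaustive
enumeration over the categorical profile space. POLE-alone emits no p53
label at all: non-mutant patients are recorded as passed through and keep
conventional management. Patients failing the GAPDH gate are excluded from
*every* algorithm, including ProMisE where MMR IHC could in principle still
be read — the cohorts this models excluded such cases entirely, and we
follow that.

Pathogenicity is an exact protein-change match against a configurable list
shipping with the five sequencing hotspots (P286R, S297F, V411L, A456P,
S459F); laboratories using broader assays can extend the list by file
(`read_variant_list()`), e.g. to the twelve recognized exonuclease-domain
changes.

## Risk stratification and molecular integration

Conventional adjuvant-therapy risk uses an ordered, first-match rule table.
Only the low-risk tier has a printed, citable definition (stage IA,
low-grade endometrioid histology, LVSI negative or focal); the remaining
tiers in the shipped default are a documented stand-in in the style of the
European consensus prognostic groups (intermediate: IB low-grade or IA
high-grade with at most focal LVSI; high-intermediate: stage II, substantial
LVSI, or IB high-grade; high: non-endometrioid histology or stage III–IV).
Because any such default involves judgement, cohorts whose conventional risk
labels are known should carry them as a `conventional_risk` column — the
cost machinery then never touches the rule table. The shipped 80-patient
fixture does exactly this, and (as a consistency check, not a dependency)
the default table reproduces its labels.

Molecular integration applies only to early-stage (FIGO I–II) patients:
POLE-mut de-escalates to low risk, with adjuvant therapy *omitted* only when
the conventional group would have received any; p53-abn escalates to high
risk, with chemoradiation *added* only when the conventional group was below
high. Stage III–IV and QC-excluded patients are never modified. These
at-target-already rules are forced by the reference risk-count structure
(five early POLE-mut patients but three omissions; five early p53-abn but
three additions).

## The cost model

Costs are integer Baht throughout; no floating currency arithmetic. For a
strategy (cascade × selection mode):

* testing cost = Σ over tests of (patients whose cascade consumed the test)
  × unit cost. Unit costs are configuration, not code; the shipped defaults
  (POLE 4,500; MMR 1,420; p53 570) are the unique solution of the published
  strategy totals against the cascade counts.
* therapy change: each omission subtracts the conventional adjuvant cost.
  Escalations are priced by mode. `move_to_high` charges
  `cost(high) − cost(conventional)` per escalated patient — the principled
  decomposition. `explicit_override` instead reports a configured net amount
  for any strategy that escalates someone; it exists because the published
  net change (+12,288 Baht) is not decomposable into per-patient moves — the
  move-to-high arithmetic on the implied movers gives −12,434 — so
  reproducing the published table requires carrying its net as data.
  Strategies with omissions only (POLE-alone) are always computed
  (−307,400 = 53,400 + 2 × 127,000).
* total = reference adjuvant total + testing + net therapy change. One
  published footnote prints this relation with a minus sign on testing
  costs, but every published total is consistent only with addition; we
  implement addition and note the footnote as typographical.
* percent change = 100 × (total − reference)/reference, rounded half away
  from zero to one decimal (base R's half-to-even would misreport boundary
  percentages).

One published cell — the WHO-order selective testing cost (310,840) — is
inconsistent with the unit costs implied by every other cell; the package
computes 308,840 and annotates the 2,000-Baht discrepancy on the report
rather than reproducing an arithmetic impossibility.

## Survival: flexible parametric model, CFS, adjusted RMST

Kaplan–Meier curves and the log-rank test are delegated to the `survival`
package behind tidy wrappers; the test suite checks both against
independent hand-computed oracles.

The core model is flexible parametric regression on the log cumulative
hazard (the Royston–Parmar family), written in the package:

$$\log H(t \mid X) = s(\log t;\ \gamma) + X\beta,$$

with $s$ a restricted cubic spline. Right-censored log-likelihood
$\sum_i d_i[\log s'(x_i) - x_i^{raw} + \eta_i] - \sum_i e^{\eta_i}$ (with
$x_i = \log t_i$, $\eta_i = s(x_i) + X_i\beta$) is maximized by BFGS with
analytic gradients, initialized from a Weibull `survreg` fit mapped to the
spline scale. Numerical choices:

* **Spline complexity**: default 3 degrees of freedom (two internal knots at
  the 33rd/67th centiles of uncensored log event times; boundary knots at
  their extremes). `df = 1` has no internal knots, making $s$ linear in
  $\log t$ — exactly the Weibull model; the suite verifies log-likelihood
  agreement with the direct Weibull MLE to 10⁻⁶, and agreement with an
  independent spline implementation (`flexsurv`) at `df = 3`.
* **Ties**: handled Breslow-style through the risk-set likelihood; exact-tie
  corrections are out of scope.
* **Convergence**: relative log-likelihood tolerance 10⁻⁸, 500 iterations;
  non-convergence is flagged on the object, never silent. Parameter vectors
  where the spline slope is non-positive at an event time are rejected with
  a penalty, keeping the fitted cumulative hazard nondecreasing.
* **Prediction at the extremes**: the restricted spline continues linearly
  beyond its boundary knots, so $S(t) \to 1$ as $t \to 0$ whenever the
  log-time slope is positive, and $S(0)$ is defined as 1.

**Confounder summary score (CFS).** The five baseline prognostic variables —
age (years, continuous), FIGO stage (I–II vs III–IV), histology
(three-level), depth of uterine wall invasion (three-level), LVSI (present
vs absent) — enter a flexible parametric model *without* molecular results;
each patient's CFS is that model's covariate linear predictor $X\hat\beta$
(the baseline spline contributes nothing). The main model then contains the
subgroup indicators (reference NSMP) plus the CFS as a single continuous
covariate.

**Adjusted RMST.** For each subgroup, predicted survival with the CFS held
at its cohort mean is integrated to the 60-month horizon by adaptive
quadrature (`integrate`, tolerance 10⁻⁹; the suite checks agreement with a
10⁴-point trapezoid rule to < 0.01 month and with the exponential closed
form to 10⁻⁶). Evaluating at the cohort-mean CFS is a convention — the
source analyses do not state theirs; because the CFS enters the linear
predictor as a single scalar, the alternative of standardizing over the
observed CFS distribution moves every subgroup's curve through the same
nonlinearity and leaves the contrasts essentially unchanged, so the simpler
convention stands.
Confidence intervals and p-values come from a nonparametric patient-level
bootstrap (default B = 1000, seed required, percentile intervals,
normal-approximation p-values for differences), re-running the whole
pipeline — including the CFS fit — on every resample. Bootstrap was chosen
over delta-method variances for transparency: every interval is the
empirical spread of an honest re-analysis. A horizon beyond the largest
follow-up triggers an explicit extrapolation warning recorded on the result.

## The synthetic generator

`cohort_spec()` defaults encode the study conditions this package emulates:
186 recruited patients, a 25.8 % DNA-QC failure process, subgroup
probabilities (0.529 NSMP, 0.282 MMR-d, 0.138 p53-abn, 0.051 POLE-mut),
and per-subgroup conditional distributions of stage, histology, invasion,
LVSI, nodal status and age matching the reference cohort's margins.
Progression hazards are piecewise exponential, calibrated through the
closed-form RMST inverter (`calibrate_rates()`, root-finding on a monotone
scale factor, 10⁻⁶ tolerance) so the 5-year PFS RMST per subgroup equals
the reference estimates (53.2 / 51.1 / 29.5 months); the POLE-mut subgroup
has zero hazard — event-free by construction, as observed. Death couples to
progression as progression time plus an exponential residual (subgroup-mean
9–18 months), which enforces PFS ≤ OS per record; the joint model is our
convention, since none is published. Administrative censoring is uniform on
60–95 months, so event-free patients always have at least five years of
follow-up. Times are rounded to 0.01 month with a 0.1-month floor
(registry-scale resolution). Marker profiles are generated as the
classifier's inverse image, so ProMisE classification recovers the true
label for every QC pass — the round-trip is a tested invariant, not an
accident.

What the generator does **not** emulate: within-subgroup covariate effects
on survival (hazards depend on subgroup only), inter-rater variability in
histology, MMR-d/POLE-mut co-occurrence (absent so that the two cascade
orders agree on generated cohorts), and any joint covariate structure
beyond the printed margins. Passing tests therefore demonstrate that the
machinery is correct under these conditions, not that the model fits any
particular real cohort.

Two deterministic fixtures complement the stochastic generator:
`table1_cohort()` (138 patients reproducing the reference per-subgroup
margins exactly, with survival drawn once under a fixed internal seed) and
`table3_cohort()` (its 80 early-stage patients carrying conventional risk
labels 30/18/29/3 and the mover structure — POLE-mut: one intermediate and
two high-intermediate de-escalations; p53-abn: three intermediate
escalations, two already high). Joints beyond the printed margins are fixed
by convention and documented in the fixture source.

## A measured limitation of CFS adjustment under these conditions

The suite's parameter-recovery study (200 replicate cohorts of n = 1000,
true p53-abn − NSMP PFS RMST gap calibrated to −23.6 months) shows a small
finite-sample attenuation of the CFS-adjusted gap: the recovered mean sits
about 1–1.5 months short of the target — around 5 % of the gap and well
inside the estimator's ≈ 3-month sampling spread, but larger than the
Monte-Carlo standard error of the 200-replicate mean, so the strict
recovery test fails and is left failing deliberately. The mechanism is
structural: under the default generator, covariates are strongly
subgroup-linked while survival depends on subgroup only, so the CFS is
nearly collinear with the subgroup indicators; the noisy split of effect
between the two propagates through the nonlinear RMST transform into a
systematic attenuation. (Consistent with this reading, the suite separately
shows the machinery recovering RMSTs without bias where no such
collinearity exists — exponential closed forms, Weibull equivalence, the
event-free 60-month bound.) The failing test documents a real property of
confounder-score adjustment when the "confounders" carry no survival
information beyond group membership; the acceptance script reports the mean
recovered gap exactly as computed.

## Problem sizes and runtime

Defaults were chosen so every routine check is interactive: the fixtures
are 138/80 patients; property tests enumerate the full categorical marker
space (~60 profiles); simulation checks use 10⁵ draws where a distributional
identity is asserted and n = 1000 × 200 replicates for the recovery study,
which completes in well under a minute on one core. The bootstrap default
(B = 1000) is the one knob worth lowering for quick exploration.

## Known limitations

* Single-event right-censored survival only: no competing risks, no
  time-varying effects, no delta-method variances.
* Variant matching is exact string equality on protein changes; no HGVS
  normalization or chromatogram parsing.
* The non-low conventional risk tiers are a stand-in; reports based on the
  default table should say so (the table carries a provenance label).
* Currency is integer Baht with no discounting, QALYs, or sensitivity
  analysis — this is a deterministic direct-cost comparison.
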