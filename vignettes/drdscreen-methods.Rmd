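---
title: "Methods: paired-eye diagnostic accuracy, clustered inference and screening equity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-eye diagnostic accuracy, clustered inference and screening equity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drdscreen)
```

## The analysis problem

Autonomous AI systems that screen for diabetic retinal disease (DRD) are
validated in diagnostic-accuracy trials with a distinctive structure: the
disease is ascertained *per eye* against a prognostic reference standard
(ETDRS severity grading plus macular OCT), but the sampling unit is the
*participant*, who contributes up to two correlated eyes. The AI may also
decline to give a disease-level output (insufficient image quality), which
must be tracked separately from accuracy and folded back in under
worst-case assumptions. Regulatory endpoints are one-sided
non-inferiority tests of sensitivity and specificity, and the equity
question — does a cheaper, more adoptable system identify more true cases
at population scale despite lower sensitivity? — is quantified by
Population Achieved Sensitivity (PAS).

`drdscreen` implements this entire stack: case definitions, eye- and
participant-level confusion tables with diagnosability, worst-case
imputation, participant-clustered bootstrap inference with
disease-spectrum expansion, design power simulation, PAS break-even
ratios, subgroup bias audits, and a calibrated synthetic trial generator
so that every stage is testable without access to proprietary trial data.

## Case definitions

All thresholds compare the integer ETDRS base code only; modifier
letters (35A–35F, 43B, …) are retained for display and stratification
but never enter ordinal logic, because every clinical threshold is
stated as a bare number.

* **DRD-positive** (referable disease): ETDRS base ≥ 35, or DME present.
* **vtDRD** (vision-threatening): ETDRS base ≥ 53, or DME present.
* **CIDME**: OCT central subfield thickness strictly greater than
  300 µm. A missing thickness is indeterminate (`NA`), never silently
  negative.

By construction vtDRD implies DRD (53 ≥ 35 and the DME disjunct is
shared); this is property-tested over the full level set.

### Participant-level aggregation

Published trial reports rarely state the participant-level rule
explicitly, so the package fixes one and documents it:

* **Reference positivity**: worst-eye rule — a participant is positive
  when any eye is positive. This is the standard convention for
  referable disease (the participant is referred if either eye needs
  care).
* **AI output**: `detected` if any *diagnosable* eye is detected;
  `not_detected` if at least one eye is diagnosable and none detected;
  `insufficient_quality` only when every eye is insufficient. The
  single-diagnosable-eye rule is forced by arithmetic: participant-level
  diagnosability (95.8%) exceeds eye-level diagnosability (90.6%), which
  is impossible under a both-eyes-required rule.

## The clustered bootstrap

The primary analysis resamples **whole participants** with replacement
(clusters of one or two eyes stay intact), which respects inter-eye
correlation without modelling it. Per replicate, optionally, the disease
spectrum is **expanded**: whole participants carrying at least one
vtDRD eye are appended (drawn with replacement from the replicate's own
carriers) until the vtDRD share of DRD-positive eyes first reaches the
target (default 20%, the share observed in screening populations). We
interpret the expansion numerator as vtDRD (ETDRS ≥ 53 *or* DME) because
the 20% reference statistic is stated for that composite; appending whole
participants rather than reweighting eyes preserves cluster semantics.

For a metric $p$ (sensitivity or specificity) with non-inferiority
margin $p_0$ (0.75 for sensitivity, 0.775 for specificity), each
replicate recomputes the metric; the package reports

* the **one-sided 97.5% lower confidence bound**: the empirical 2.5th
  percentile of the replicate distribution (inverse-ECDF quantile,
  `type = 1`; the plain percentile method is the simplest estimator
  consistent with a one-sided empirical bound — no BCa correction);
* the **non-inferiority p-value**: the add-one-smoothed bootstrap tail
  probability $(1 + \#\{p^{*b} \le p_0\})/(B + 1)$. The smoothing keeps
  the p-value positive at finite $B$ and makes the test slightly
  conservative.

Study success requires *both* nulls rejected at one-sided α = 0.025; no
multiplicity adjustment is applied to the co-primaries (each must pass on
its own), and secondary endpoints would be tested hierarchically.

Degenerate replicates (an empty metric margin, e.g. a resample with no
positives) are excluded and counted; more than 10% of them aborts the
analysis with diagnostics, since the percentile would no longer be
trustworthy.

Simulation checks at the trial's problem size (567 participants, 400
replicates, 500 simulated trials) show one-sided coverage of ~97.0%
(nominal 97.5%, Monte-Carlo band ±1.4%) and boundary type-I error ~3%
(nominal 2.5%, within the add-one/percentile tolerance). The design
power simulation (200 positive eyes including 20 vtDRD, 140 negative
eyes, true operating point 0.85/0.90) gives study-level power above 0.9.

## Worst-case imputation

Insufficient-quality units are excluded from accuracy cells but never
discarded: the worst-case analysis reassigns every insufficient diseased
unit as a false negative and every insufficient non-diseased unit as a
false positive. This is a pure count transformation
(`fn += insufficient_pos; fp += insufficient_neg`), preserves the total,
and can only lower sensitivity and specificity (property-tested). It is
defined at the eye level, where image quality operates; the same
transformation applied to participant-level tables is available but is an
extension with the analogous semantics.

## Population Achieved Sensitivity

For a screening system with sensitivity $s_c$, diagnosability $d_c$,
access fraction $c$ and prevalences $p_c$ (with access) and
$\hat p_{nc}$ (without),

$$\mathrm{PAS} = \frac{s_c\, c\, p_c\, d_c}{c\,p_c + (1-c)\,\hat p_{nc}}
\;\cong\; s_c\, c\, d_c ,$$

the approximation being exact when the two prevalences agree — the
conservative default (p = 0.2 in both subpopulations). The
**break-even ratio** between a reference and a new system,
PAS(ref)/PAS(new) with the shared access fraction cancelled, is the
adoption multiple above which the new system identifies more true cases.
With participant-level sensitivities 0.872 (reference) and 0.815 (new)
and equal diagnosability, the ratio is 1.07. Uncertainty is propagated
by Monte-Carlo: each sensitivity is drawn from a normal on the
probability scale with standard error inferred from its 95% CI
half-width (truncated to (0,1)), and the 2.5th/97.5th percentiles of the
ratio are reported. This is an interpretation — the propagation scheme
behind published intervals is typically unstated — and is labelled as
such.

A fixed lookup ties each binary output to untreated clinical-outcome
risk (proliferative disease within 3 years, moderate or worse vision
loss at 1 and 3 years) and to the ICD-10 category E11.339x for a
"disease present" output; the percentages are encoded as published, not
re-derived from the source treatment trials.

## Subgroup bias audit

Prespecified contrasts mirror trial practice: male vs female, Black vs
non-Black, Hispanic vs non-Hispanic (unknown/not-reported excluded).
The test statistic is the subgroup metric difference; its null
distribution comes from the same participant-clustered bootstrap
(groups pooled, so group sizes vary as in repeated sampling), and the
two-sided p-value is twice the add-one-smoothed fraction of replicate
differences on the opposite side of zero from the observed difference,
capped at 1 and unadjusted for multiple comparisons. Spectrum expansion
is not applied here: the contrast concerns the realised sample. Null
calibration at the trial's size gives empirical type-I ≈ 4.5% at nominal
5% over 200 simulated trials.

The minimum-subgroup rule is total: any cell below 10 participants
yields a report with *no numeric content at all* (estimates, difference
and p-value are absent, and rendered output prints only
"not reported (n<10)"). Intersectional audits test every pairwise
intersection cell against its complement, with the same suppression.

## The synthetic generator

`generate_trial()` emulates the statistical structure the analysis
assumes, with every default calibrated to a published marginal:

| Quantity | Default | Source of calibration |
|---|---|---|
| ETDRS level weights | empirical 1073-eye distribution | severity table |
| DME given stratum | 36/798 (<35), 0 (35–47), 7/24 (≥53) | forced allocation |
| inter-eye severity correlation ρ | 0.6138 | participant prevalence 0.389 |
| AI operating point | 0.796 / 0.884 | trial accuracy results |
| eye quality-failure rate q | 0.094 | eye diagnosability 0.906 |
| failure clustering γ | 0.3894 | participant diagnosability 0.958 |
| Level II operating point | 0.672 / 0.998 | reading-center accuracy |
| thickness (µm) | N(307,25) DME; N(245,35) DRD+; N(242,22) DRD− | OCT thickness moments |
| dilation rate | 0.155 | dilation fraction |

Both dependence mechanisms are **shared-draw mixtures**: with
probability ρ the two eyes take a single severity draw (otherwise
independent draws), and likewise γ for quality failures. This mechanism
is transparent, seeded, spans independence (0) to comonotonicity (1),
and leaves eye-level marginals untouched. The defaults follow in closed
form: with eye prevalence $p$ and shared-severity participant
positivity $S_1$, participant prevalence is
$\rho S_1 + (1-\rho)(2p - p^2)$, solved for ρ at 0.389; with failure
rate $q$, the both-eyes-fail probability is
$\gamma q + (1-\gamma) q^2$, solved for γ at $1 - 0.958 = 0.042$.

A consequence worth stating plainly: at fixed eye-level failure rate,
*increasing* the failure clustering concentrates failures within
participants and therefore *decreases* participant diagnosability under
the any-diagnosable-eye rule, from $1-q^2 = 0.991$ at independence
towards $1-q = 0.906$ at comonotonicity; the calibrated 0.958 sits
between. The property suite asserts this weak decrease.

DME eyes draw thickness from a component centred at 307 µm so that
center-involvement classification is exercised in both directions; the
true DME thickness distribution is not published, so this is a modelling
choice. Every participant contributes two eyes (the real trial had 61
one-eye participants; one-eye clusters are supported by the container
and the resampler, and are exercised via the reconstructed fixture).
Demographics are drawn independently of disease and of AI accuracy, so
the generator is a *null* model for subgroup bias — which is exactly
what the audit's calibration tests require.

What the generator does **not** emulate: image content and quality
physics, operator and site effects, severity-dependent AI sensitivity
(the operating point is uniform across strata, so spectrum expansion is
unbiased in simulation — on real data it need not be), correlation
between demographics and disease, repeat-imaging dynamics beyond the
attempt counter, and enrollment/attrition processes. Passing calibration
tests therefore demonstrates the correctness of the analysis machinery,
not real-world performance of any device.

## The reconstructed fixture

`paper_fixture()` rebuilds the 1073-eye analyzable set from printed
marginals: the severity table fixes the ETDRS distribution (275 eyes at
≥ 35); reconciling 311 DRD-positive, 60 vtDRD and 43 DME eyes forces the
DME allocation (36 eyes below 35, 7 at ≥ 53, none between); and 567
participants with 221 positive forces 90 both-eyes-positive and 131
one-eye-positive participants. Within-stratum DME placement, the
severity-sorted pairing of eyes into participants, and the demographic
assignment (which matches published counts: 288 male, 259 Hispanic, 98
Black) are synthetic and fixed by a seed. Per-eye AI outputs and
Level II grades were never published and are absent. The same dataset
ships as `inst/extdata/paper_eyes.csv` (clinical columns only) and
exercises the CSV reader.

The worst-case worked examples use the cell counts forced by the
printed worst-case fractions 220/341 and 696/830, implying 65 positive
and 43 negative insufficient-quality eyes. These 108 insufficient eyes
sit in mild tension with the 90.6% diagnosability point estimate
(which implies ~101); the package encodes the forced counts and leaves
the residual rounding tension to this note.

## Numerical and design choices

* Quantiles: inverse ECDF (`type = 1`) for bootstrap percentiles —
  an order statistic, no interpolation between replicates.
* p-values: add-one smoothing everywhere a bootstrap tail is turned
  into a p-value; `p = 1` exactly when an observed difference is zero.
* Empty metric margins give `NA` with a warning, never silent zero;
  missing optional fields are `NA`, never sentinel values.
* Seeds: a single integer seed per public entry point; the pipeline
  splits its global seed deterministically per stage
  (multiplicative-congruential step), so stages can be re-run
  independently and all seeds stay below 2^31.
* The CSV dialect is strict: canonical column names, documented
  vocabularies, malformed values reported with line and column.
* Problem sizes in the shipped test suite: coverage and type-I checks
  run 500 simulated trials of 567 participants at 400 bootstrap
  replicates; power and audit calibration use 200 trials. These sizes
  hold Monte-Carlo error to ~1–2 points, which is what the asserted
  bands require.

## Limitations

* The printed p-values of the motivating trial (0.021, 0.006, …) cannot
  be reproduced: the underlying per-eye data are proprietary and the
  exact p-value mechanics were not published. The package's worked
  examples are exact on printed *counts*; its inferential machinery is
  validated by simulation instead.
* The percentile bound is mildly anti-conservative at this problem size
  (coverage ~97% vs nominal 97.5%); BCa or studentised intervals would
  narrow the gap at substantial complexity cost and are out of scope.
* PAS interval propagation and the subgroup test are documented
  interpretations, not reproductions of any specific published scheme.
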