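---
title: "Age-stratified ROMA: model, design choices and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-stratified ROMA: model, design choices and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(romaP)
```

## The model

ROMA estimates the probability that an adnexal mass is malignant from
two serum markers, HE4 (pmol/l) and CA125 (U/ml). Both markers enter on
the log scale through a linear predictive index,

$$\mathrm{PI} = A + w_{\mathrm{HE4}}\,\ln(\mathrm{HE4})
              + w_{\mathrm{CA125}}\,\ln(\mathrm{CA125}),$$

which the logistic transform maps to a risk on the 0–100 scale,

$$\%\mathrm{ROMA} = \frac{e^{\mathrm{PI}}}{1 + e^{\mathrm{PI}}}
  \times 100 .$$

The *standard* variant switches between two coefficient triples by
menopausal status. The *age-stratified* variant implemented here
replaces that dichotomy with eight triples, one per age interval
(W1: ≤ 20 years, W2–W7: closed decades 21–30 … 71–80, W8: ≥ 81),
constructed by stepwise linear reduction of each coefficient from its
W1 value to its W8 value in seven equal increments:

```{r}
roma_strata()
```

Three modelling assumptions are inherited by anyone using these scores:
both markers act as *stimulants* (positive weights, so risk is strictly
increasing in each marker within every stratum); the age effect on the
marker–risk relationship is monotone and approximately linear across
strata, which is what makes endpoint interpolation sensible; and the
logistic link is taken at face value, so the output is a calibrated-in-
form (not necessarily calibrated-in-fact) probability.

### Published constants versus reconstruction

Scoring always uses the published coefficient table verbatim. The table
shows mixed rounding and truncation — the linear value
$0.063 + (0.732-0.063)/7 = 0.15857$ is printed as 0.158, and
$0.34971$ as 0.349 — so re-deriving coefficients at scoring time would
silently change published results.
`interpolate_coefficients()` therefore exists as a *construction and
verification* tool: rounding its output to the printed precision
reproduces every one of the 24 published values within 0.001, which the
test suite asserts, but the runtime source of truth is the stored
table.

### The printed transform

The source formula for the risk is printed with the denominator
$1 - e^{\mathrm{PI}}$, which is negative for positive indices and
unbounded near zero; no worked numeric example accompanies it. This
package reads it as a typographical slip for the standard logistic
$1 + e^{\mathrm{PI}}$ — the only form that produces the advertised
0–100 % scale and the form every other ROMA implementation uses.

### Boundary and convention choices

Decisions that the published description leaves open, fixed here once:

* **Ages 20 and 81.** The interval labels ("< 20", "21–30", …, "> 81")
  leave the boundary years ambiguous. W1 covers ages up to and
  including 20 and W8 ages from 81 upward; fractional ages floor to
  whole years before lookup (integer-year semantics). This leaves no
  gaps and no overlaps.
* **Score equal to the cutoff.** Classified *high risk* (`>=`
  convention): in a screening context the boundary case should fail
  toward sensitivity. The convention is configurable
  (`equality = "gt"`).
* **Default cutoffs.** 23.5 % for the age-stratified score on the whole
  population; 14.1 % / 25 % for the standard score pre/post. These are
  operating points, not embedded logic — every evaluation function
  accepts other cutoffs.
* **Sub-detection markers.** HE4 below 15 pmol/l or CA125 below
  1 U/ml is scored as-is with a one-shot warning, not clamped: such
  values occur in real cohorts and clamping would alter scores
  invisibly.
* **"ln" is the natural logarithm.** Base-10 would change every
  coefficient's meaning.

## Diagnostic evaluation machinery

`confusion_at_cutoff()` / `confusion_metrics()` implement the
contingency-table metrics (sensitivity, specificity, PPV, NPV, in
percent). A metric whose denominator is empty is reported as `NA`
with a warning — never as zero, which would masquerade as a terrible
but defined result.

`roc_curve()` sweeps every distinct score as a `>=` threshold, grouping
ties at a single threshold. The trapezoidal `roc_auc()` then equals the
Mann–Whitney U-statistic scaled by $n_+ n_-$ with ties counting one
half — the convention DeLong's theory assumes, and the property the
test suite checks exactly against an exhaustive pair-count oracle.

`delong_variance()` and `delong_compare()` use the placement-value
(structural component) estimator in its midrank formulation. The
confidence interval is Wald on the AUC scale, truncated to $[0,1]$;
the logit-scale variant was considered and not adopted because the
plain Wald form is what the common implementations report, and the
truncation contract keeps degenerate cases (perfect separation,
`se = 0`) well-defined. The paired comparison handles two edge cases
explicitly: identical score vectors give $z = 0$, $p = 1$, and a zero
variance estimate with a nonzero AUC difference gives $z = \pm\infty$,
$p = 0$.

`select_cutoff()` maximizes Youden's $J$ = sensitivity + specificity − 1
over the midpoints between consecutive distinct scores (plus the
all-positive cut). Midpoints rather than observed values make the
returned cutoff insensitive to the `>=`/`>` convention and return the
center of the separating gap when the classes are perfectly separated.
Ties in $J$ break toward the higher cutoff, i.e. toward specificity,
matching the intended use as a rule-in threshold. The published cutoff
derivation is described only as "from the ROC curve and the DeLong
method"; Youden's $J$ is the field-standard reading and is documented
as this package's choice.

`mann_whitney()` computes U from midranks; for combined samples of at
most 20 without ties the p-value is exact (the enumeration is the
closed-form null CDF `pwilcox`), otherwise a normal approximation with
tie-corrected variance and continuity correction is used. Two-sided
p-values are the default, matching how such group contrasts are
reported. The contrasts of standard-versus-age-stratified scores on the
same patients would arguably call for a *paired* test; the unpaired
form is implemented because it is the method the evaluation framework
names, and the discrepancy is noted here rather than silently resolved.

## What the synthetic cohort emulates — and what it does not

`default_cohort_spec()` encodes the structure of a 413-patient referral
cohort: 162 malignant / 251 benign; per-stratum age weights
proportional to the observed counts (malignant 0, 3, 7, 28, 47, 43, 25,
9; benign 38, 55, 73, 48, 22, 10, 4, 1 across W1–W8); log-normal HE4
and CA125 per (class, stratum) cell with the observed medians; and a
benign HE4 level that rises with age (the calibrated medians climb from
41.5 pmol/l in W1 to ~70 pmol/l in W7–W8, an increase above the ~40 %
rise such cohorts show between the youngest and oldest patients).

Generator choices, made once:

* **Log-normal markers**, because the observed ranges span 2–3 orders
  of magnitude with strong right skew. The scale is the observed
  median; the dispersion matches the observed min–max to the central
  99 % mass, $\sigma_{\log} = (\ln\max - \ln\min)/(2 \cdot 2.576)$.
* **Empty and unreported cells.** The malignant W1 cell has zero
  weight. The benign W8 cell has weight 1/251 but no reported marker
  row, so it reuses the W7 parameters.
* **Ages** are uniform within the stratum; the open-ended strata use
  finite sampling bounds of 16–20 (W1) and 81–90 (W8), consistent with
  the cohort's 18–90 age range.
* **Menopause** is deterministic: post iff age ≥ 51. The real
  mapping is unreported; 51 reproduces the direction of the observed
  pre/post split.
* **`he4_age_drift`** defaults to 0 because the per-stratum medians
  already embed the age trend; the knob multiplies the benign HE4
  median by $(1+\delta)^{k-1}$ in stratum $k$ for sensitivity
  analyses with flattened medians.
* **No HE4–CA125 correlation within class** by default — the true
  joint structure is unreported. This is the generator's biggest known
  departure from reality: in patients the two markers are positively
  correlated, so synthetic AUCs for the combined scores run somewhat
  higher than real-cohort AUCs. Passing pipeline tests on synthetic
  cohorts therefore demonstrates correctness of the computations and
  plausible discrimination, *not* reproduction of any real cohort's
  performance figures.

## Numerical choices

* The logistic transform goes through `stats::plogis()`; it never
  overflows, and beyond $|\mathrm{PI}| \approx 36$ it saturates at the
  representable 0/100 limits of double precision. All clinically
  reachable indices (markers between assay limits and a few tens of
  thousands) stay far inside the strictly monotone region.
* DeLong placements use the midrank identity rather than the
  $O(n_+ n_-)$ pairwise kernel, so variance estimates are exact (no
  Monte Carlo) and cheap at cohort sizes in the hundreds.
* AUC is computed by trapezoid on the tie-grouped curve; with that
  grouping the trapezoid is *exactly* the tie-adjusted U-statistic, so
  the test-suite comparison against the brute-force pair count uses a
  tolerance of 1e-12, not a statistical band.
* CSV parsing is locale-independent (decimal point only), and invalid
  rows are rejected with row-level reasons rather than repaired.

## Validation strategy and problem sizes

The test suite separates exact oracles from statistical calibration.
Exact checks: the 24-coefficient reconstruction (tolerance 0.001 at
printed precision); pair-count AUC equality on 200 random instances
with up to 15 subjects per class; Youden maximality against an
exhaustive sweep; Mann–Whitney exact p on the separated 3-vs-3 case
(two-sided $2/20$). Statistical checks use fixed seeds: the paired
DeLong test on two pure-noise markers holds its 5 % size within
[0.03, 0.07] over 1000 replicates at 50 + 50 subjects; the 95 % DeLong
interval covers the true binormal AUC in at least 90 % of 1000
replicates at 100 + 100; the Mann–Whitney null rejection rate stays in
[0.035, 0.065] over 2000 replicates at 30 + 30; and the generator's
sample medians converge to specification within 5 % at roughly $10^4$
draws per populous cell. The end-to-end smoke standard is an
age-stratified AUC above 0.85 on a default simulated cohort. These
sizes keep the full suite under half a minute on one CPU while leaving
each calibration check with enough replicates to be meaningfully sharp.

## Known limitations

* Published real-cohort performance tables cannot be reproduced: the
  underlying patient data are not deposited. Synthetic results are
  plausibility checks, not reproductions.
* No assay-platform harmonization: HE4/CA125 values are taken at face
  value regardless of the measuring platform.
* The standard-variant comparator uses the endpoint triples (which
  equal the W1/W8 sets); laboratories using other published standard-
  ROMA coefficient sets will get slightly different comparator scores.
* Binary risk stratification only — no staging, no management
  recommendations, and no alternative indices such as CPH-I.
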