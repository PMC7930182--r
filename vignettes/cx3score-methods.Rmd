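---
title: "Methods behind cx3score: score, diagnostics, survival, repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind cx3score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cx3score)
```

## The problem and the estimand

Static pre-treatment biomarkers for checkpoint blockade (PD-L1 tumor
proportion score, tumor mutational burden) discriminate responders poorly and
need tissue. CX3CR1 marks a late, stably acquired stage of CD8+ T-cell
effector differentiation: once a clone's progeny express it, they keep it,
which makes its frequency in blood a candidate *cumulative* readout of
on-treatment T-cell differentiation. The quantity this package computes — the
CX3CR1 score — is the maximal percent change from baseline of the CX3CR1+
fraction of circulating CD8+ T cells by a landmark week, dichotomized at a
+20% increase.

Two modelling commitments follow from the biology and are hard-coded:

- **Percent change, not absolute change.** Baseline fractions vary an order
  of magnitude between patients (roughly 6–76% of CD8+ T cells), so a fixed
  absolute increment would mean different things in different patients. The
  score is invariant under rescaling a patient's frequencies.
- **Running maximum, not a single visit.** Differentiation is cumulative and
  the visit schedule is irregular; the maximum over all samples up to the
  landmark uses every observation and is monotone non-decreasing in the
  landmark, which the tests enforce as an invariant.

Patients with no post-baseline sample by a landmark are *unevaluable* there
and are excluded from that landmark's diagnostics rather than imputed; this
is why the week-3 analysis of the reference cohort has n = 27 of 36.

## Diagnostic evaluation

`diagnostic_report()` treats the rule as a binary test for objective response
(CR/PR vs SD/PD) and reports:

- **Rates with Jeffreys intervals.** Sensitivity, specificity, PPV, NPV and
  accuracy each get a central Beta(x+½, n−x+½) interval; at x = 0 (x = n) the
  lower (upper) limit is forced to 0 (1). Jeffreys was chosen to match the
  published analysis; its ~95% coverage at n = 36 is verified by simulation
  in the tests.
- **Woolf odds-ratio intervals** with the exact normal quantile (1.959964…);
  using 1.96 changes the reconstructed bounds at the first decimal. Zero
  cells get the Haldane–Anscombe +0.5 on all cells and a flag. The week-9
  upper bound computes to ≈253.77 where the published table prints 253.8 —
  a rounding/method ambiguity we document rather than chase.
- **Fisher's exact test**, two-sided by the standard rule: sum of
  hypergeometric probabilities not exceeding the observed table's (relative
  tolerance 1e-7). Cross-checked against `stats::fisher.test` over a full
  grid of small tables.
- **Empirical ROC/AUC** (pair-counting definition, ties count one half;
  thresholds at observed scores) with the **DeLong** structural-components
  variance and a Wald interval truncated to [0, 1]. Perfect separation gives
  a degenerate, flagged interval.
- **Youden cut-point** over observed scores with the rule `score >= cutoff`.
  J is compared in integer form (tp·n0 + tn·n1) so ties are exact; ties break
  toward the smallest cutoff, i.e. toward sensitivity. The opposite
  convention is available (`tie = "largest"`) because the choice is genuinely
  arbitrary.
- **Logistic fits** use maximum likelihood via IRLS (`stats::glm`). Since the
  fitted probability is monotone in the score, its ROC and AUC equal the raw
  score's — verified numerically — so the empirical ROC is the logistic ROC
  and no probability grid is needed. Separation is detected by disjoint class
  ranges and flagged instead of reporting divergent coefficients.

## Survival

Kaplan–Meier estimation, the log-rank test and its O/E tables come from the
`survival` package behind thin wrappers; the median is extracted explicitly
as the smallest time with S(t) ≤ 0.5 (`NA` if never reached). The hazard
ratio is the Mantel–Haenszel form (O_A/E_A)/(O_B/E_B) with interval
exp(ln HR ± z·√(1/E_A + 1/E_B)) — the log-rank-table HR that mainstream
clinical graphing software reports. A Cox model is deliberately out of scope:
with published results whose method is unstated, the O/E form is the more
reproducible default, and the tests verify it against hand-tabulated
hypergeometric O/E/V tables. At moderate effect sizes it recovers a true
exponential hazard ratio of 0.3 within ±0.05 at n = 2000 (verified), though
the O/E estimator is known to attenuate extreme ratios.

## Repertoire analytics

Clonotypes are keyed by **nucleotide** sequence for diversity and overlap
(matching how rearrangement pipelines count), and aggregated by **amino
acid** for alignment-based analyses. Non-productive rows are dropped first
and frequencies renormalized.

- **Clonality** = 1 − H/ln R (Pielou complement), undefined at R = 1 and
  returned as flagged `NA` rather than 0/0.
- **Overlap**: Morisita–Horn on frequencies by default (the convention of
  repertoire-analysis platforms); the classic count-based Morisita is behind
  `variant = "classic"` because the two are often conflated — the classic
  form slightly exceeds 1 for identical finite samples.
- **Gini/Lorenz**: Gini is the pairwise mean-absolute-difference form,
  computed via the equivalent sorted formula and tied to the Lorenz curve by
  the identity G = 1 − 2·(trapezoidal area), which the tests enforce to
  1e-9.
- **Alignment**: Needleman–Wunsch global alignment under PAM10 with a linear
  gap penalty of 30 per gap position (a single stated penalty implies no
  opening/extension split). PAM10 is a family name, so the package pins one
  canonical 20×20 log-odds matrix, shipped as plain text
  (`inst/extdata/pam10.txt`). Distances are
  d(a,b) = 1 − S(a,b)/√(S(a,a)·S(b,b)): symmetric, zero at identity, and
  allowed to exceed 1 for strongly dissimilar pairs — one of several
  defensible normalizations; this one was chosen for symmetry and exactness
  at identity.
- **Dendrograms**: UPGMA with the midpoint convention (merge at d/2, hence
  ultrametric), deterministic tie-breaking via label-sorted input, leaves
  weighted by clone frequency, Newick export via `ape`. Dominant-motif
  sharing is exact string matching of top-100 amino-acid lists; homology
  clustering beyond exact matching is available only as dendrogram
  inspection, since exact matching is what the headline counts mean.

## The synthetic generators: what they emulate

The cohort generator states a world with the published anchors as defaults:
36 patients, responder fraction 13/36, baseline frequencies logit-normal
rescaled to [6.1, 76.3] with the location solved so the median is 32.3
(closed form, since the logistic CDF is monotone; spread parameter 1 gives
realistic dispersion across the range), visit weeks 0/3/6/9/12 with 25%
week-3 missingness, exponential PFS/OS arms with medians 19.5/5.7 and 40/8.6
months for rule-positive/negative patients (40 stands in for "not reached"
beyond the 35.5-month follow-up horizon), uniform independent censoring on
[0, 35.5].

**Trajectory noise is patient-level by design.** Each patient draws one
multiplicative trajectory factor M, lognormal around the arm center (1.35
responders, 1.05 non-responders by default) with coefficient of variation
`noise_cv`; measurements ramp linearly from baseline to baseline·M at the
last visit, times a small per-visit repeatability jitter
(`visit_jitter_cv = 0.03`, typical of flow-cytometry replicates on ≥10⁴
gated events). The alternative — i.i.d. per-visit noise at cv 0.15 — would
inflate the *maximum* over four visits by roughly one upper-order-statistic
standard deviation (~15 score points), pushing typical non-responder maxima
above +20 and the optimal cutoff near +35, contradicting the world being
emulated (non-responders mostly below +20, optimal cutoffs near +15 to +21).
Flow measurement error at these cell counts is far below 15% cv, so the
dominant variance component is biological, between patients. With
`noise_cv = 0` and zero jitter the generator is exact: every responder's
maximal change equals 100·(1.35−1) and the ≥20% rule recovers the labels
perfectly.

Even so, the empirical Youden cut-point is a noisy statistic: at n = 500 its
replicate-to-replicate spread is ~3 points because J is flat near its
optimum, so a [15, 25] window captures ~84% of replicates rather than ~90%
in our own calibration runs — worth knowing before using the generator to
benchmark cut-point estimators.

The generator does **not** emulate: within-patient serial correlation beyond
the shared trajectory factor, visit-date jitter around nominal weeks (the
caller maps calendar dates to protocol weeks), dependence between PFS and OS
(drawn independently, so OS can be shorter than PFS in a simulated patient),
or any association between PD-L1 TPS and response (TPS is drawn
independently at the cohort's 31/36 high-TPS rate). Green tests on synthetic
cohorts therefore establish correctness of the estimators, not clinical
validity of the biomarker.

The repertoire generator apportions `total_templates` to rank weights
r^(−α) by largest remainder (counts are integers, sum exactly, every clone
keeps ≥1 template), reverse-translates CDR3s with random synonymous codons so
nucleotide keys are unique and consistent with the amino-acid sequences, and
shares the **top** k ranks between paired repertoires — the dominant,
expanded clones are the shared ones, which is the phenomenon of interest
(blood-subset vs tumor-infiltrate sharing). A consequence: under a steep
power law the Morisita–Horn overlap saturates quickly in `shared_fraction`
(most of the mass sits in the first few shared clones); use a flatter
`power_exponent` for a more graded overlap response. Overlap remains 0 at no
sharing, 1 for fully coupled identical specs, and monotone in expectation —
all verified.

## The deterministic reference fixture

`reference_cohort()` reconstructs the 36-patient cohort implied by the
published per-week count fractions: 13 responders, week-3 samples for 27
patients (10 responders), and per-week positivity giving confusion tables
(5,1,5,16), (8,3,5,20), (11,3,2,20), (12,3,1,20) at weeks 3/6/9/12, plus a
PD-L1 TPS ≥50% rule giving (12,19,1,4). Only the margins are published; the
patient-to-indicator assignment is fixed by sorted patient index (earliest
patients turn positive earliest), which is immaterial to every aggregate the
package computes. Measurements are constructed so the *score pipeline*, not
hand-set labels, reproduces the counts: a patient first positive at week w
carries +30% changes from w onward and ±5% before. The fixture's survival
columns are synthetic placeholders so the pipeline runs end to end;
patient-level survival times were never published, and no analysis of the
fixture should interpret them.

## Numerical conventions and degenerate inputs

- Cutoff comparisons are inclusive (`>=`), matching "at least 20%".
- Percent change from a zero baseline is an error, never ±Inf.
- Zero-denominator rates return `NA` for that rate only.
- Youden ties break to the smallest cutoff; UPGMA ties to the smallest
  label; top-clonotype frequency ties break lexicographically.
- All generators are deterministic given `seed`; the JSON report writer is
  byte-stable across runs.
- Percentages live on the 0–100 scale everywhere outside internal
  probability calculations.

## Known limitations

The published survival figures (hazard ratios 0.28/0.24, medians
5.7/8.6/19.5 months) and repertoire overlap/Gini values cannot be reproduced
here because the underlying patient-level data are not public; the survival
and repertoire modules are instead validated against closed-form oracles,
hand tabulations, enumeration, and property checks. The fixture pins only
what the published counts pin. The CLI wrapper is a convenience, not a
stable interface.
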