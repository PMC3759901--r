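---
title: "Intensity-dependent fold-change filtering of longitudinal expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity-dependent fold-change filtering of longitudinal expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maidflow)
```

## The problem

Small longitudinal treatment cohorts — here the motivating setting is six
patients sampled at a baseline and three on-treatment time points, assayed in
parallel for ~650 miRNAs (real-time PCR arrays, Ct values) and ~19,000 mRNAs
(microarray intensities) — do not support well-powered per-feature tests. Two
features of such data drive the design of this package:

1. **Variance depends on intensity.** On the log scale, fold changes of weakly
   expressed features are far noisier than those of highly expressed ones. A
   fixed fold-change cutoff therefore floods the result list with low-intensity
   noise; a fixed t-test threshold is unstable at n = 6.
2. **The patients are their own controls.** Each patient contributes a full
   temporal profile, so within-patient comparisons cancel any per-patient
   scale bias, and significance can be assessed by permuting each patient's
   temporal labels rather than by distributional assumptions.

## The MAID score

For one patient and one comparison (time point $t$ versus baseline $b$), each
feature is placed in MA coordinates,

$$M = \log_2 x_t - \log_2 x_b, \qquad A = \tfrac12(\log_2 x_t + \log_2 x_b),$$

computed on detection-floored values. The intensity-dependent spread of $M$ is
estimated by sorting features into equal-count bins of $A$ (20 by default),
taking the sample standard deviation of $M$ per bin, and fitting the bin
points by constrained nonlinear least squares to the non-increasing
exponential

$$f(A) = a\,e^{-bA} + c, \qquad a, b \ge 0,\; c \ge 10^{-6}.$$

The MAID score of a feature is the spread-adjusted fold change

$$\mathrm{score} = M / f(A).$$

Dividing by $f(A)$ demands a larger fold change of weakly expressed features,
which is the method's premise. A feature is reported per comparison if its
score exceeds a cutoff $C$ in at least $k$ of $n$ patients (up-regulation;
down-regulation analogously with $-C$). The published defaults are $C = 2$
for mRNA intensity data, $C = 1$ for the noisier miRNA Ct data (whose spread
curve runs higher, so the same nominal cutoff is a stricter absolute
requirement), and $k = 4$ of $n = 6$.

Design choices worth stating explicitly, since the score's original
description leaves them open:

* **Ratio form.** The score is $M/f(A)$ rather than, say, $M - C\,f(A)$
  thresholding. The ratio form reproduces both described behaviours: a higher
  fold change is required at low intensity, and a platform with globally
  larger variation (higher curve) justifies a lower cutoff. The form is kept
  behind the single function `maid_score()` so it can be swapped.
* **Curve scope.** One curve is fitted per (patient, comparison) array pair,
  to that pair's own MA cloud, since the variance structure is pair-specific.
  Pooling per platform is a plausible alternative; it was not chosen because
  per-pair clouds are already large (hundreds of usable features) and card- or
  chip-level artefacts are pair-local.
* **Spread estimator.** Per-bin sample SD by default; `robust = TRUE`
  switches to MAD × 1.4826.
* **Degenerate sizes.** With fewer than 5 features per bin the bin count is
  reduced (minimum 3); if every Levenberg–Marquardt start fails, the curve
  falls back to a monotone non-increasing isotonic interpolation of the bin
  spreads, flagged in the diagnostics.
* **Censored features.** A feature undetected on both sides of a comparison
  carries no evidence: it is excluded from curve fitting and scores exactly 0.

## Preprocessing

TaqMan Ct values are handled with the platform's conventions: undetermined
wells are encoded as Ct 45; every well with raw Ct above the detection limit
(38) is censored to the limit and flagged undetected; and values are mapped to
the linear scale as $S = 2^{-\mathrm{Ct}} \times 10^9$, so the detection floor
is $S(38) \approx 0.004$ and one PCR cycle is a two-fold change. (The scale
factor is fixed by the two printed anchor correspondences, Ct 38 → 0.004 and
Ct 20 → 953; a factor of $10^{-9}$ would place them thirteen orders of
magnitude lower.)

Normalization is cyclic (pairwise) loess on log2 values — for every sample
pair within a group, a degree-1 loess of $M$ on $A$ (span 0.7, one full
cycle) is removed half from each side — applied separately per patient and
per card for two-card miRNA sets, or over all samples jointly for a
summarized intensity matrix. Undetected wells never enter the curve fits and
are re-anchored at the detection floor afterwards, so detection counts are
invariant under normalization. Between-patient scale differences are then
removed by multiplying each patient's card by one scalar so that all pooled
95% quantiles agree. The common target is the **geometric mean** of the
per-patient quantiles: it is the multiplicatively symmetric anchor (scaling
patients with quantiles 100 and 400 by 2 and 0.5 to a common 200), keeps the
correction factors balanced around 1, and is invariant to relabelling the
patients. Quantile anchoring changes no within-patient ratio, hence no MAID
score; it exists for cross-patient displays and CV statistics.

Quality is tracked by coefficients of variation (sample SD over mean, per
feature, across all samples on the linear scale, censored wells included at
the floor), whose mean over features should fall after normalization. For
triplicate single-tube PCR assays, `relative_quantify()` implements the
standard workflow: censor, average the triplicate Cts, convert with
$2^{-\mathrm{Ct}}$, divide by the housekeeping miRNA (hsa-miR-191-5p) signal
in the same sample, and scale by 1000.

## The permutation test

The global question — "are this many filtered features surprising?" — is
answered by rearranging each patient's temporal sequence uniformly at random
(independently across patients, identity permitted), re-running the entire
filtering pipeline (MA transforms, curve fits, scores, k-of-n vote) on each
of the 1000 relabelled data sets, and recording the size of the union set
over all post-baseline comparisons. The empirical p-value is the plain
fraction $\#\{\text{null} \ge \text{observed}\}/n_\mathrm{perm}$ (an add-one
estimator is available via `plus_one = TRUE`). The union-set size is used as
the count statistic because the headline result of such a study is the total
number of distinct responsive features.

One structural property of this test deserves emphasis. If planted (or true)
effects are *identical across patients*, a relabelling that happens to align
four or more patients' sequences at the same position reproduces the whole
regulated block in one comparison. The probability of such an alignment
(roughly $4\binom{6}{4}(1/4)^4(3/4)^2 \approx 0.13$ for ≥4-of-6 at some
position of four labels) bounds the attainable p-value from below when the
observed count does not exceed what an aligned relabelling recovers. Real
cohorts sit far from this regime — effect sizes and timing vary across
patients, so aligned relabellings recover only fragments — but perfectly
coherent synthetic cohorts do not, and the package's tests assert tail
position rather than an arbitrarily small p-value in that case.

## The synthetic cohort generator

`simulate_cohort()` generates data with exactly the structure the analysis
assumes, plus known ground truth:

* true log2 abundances $\mu_f \sim N(4, 4^2)$ for expressed features,
  spanning the detectable Ct range (the linear-scale log2 values map to
  Ct $\approx 29.9 - \log_2 S$, i.e. roughly Ct 10–38);
* a fraction `frac_undetected` (default 0.38, matching ~400 of 651 panel
  miRNAs detected per sample) of features absent from the tissue, reported as
  undetermined wells;
* per-sample noise $\varepsilon \sim N(0, s(\mu_f))$ with
  $s(A) = 0.35\,e^{-0.2A} + 0.25$ by default — the same exponential family
  the estimator fits, decaying from ~0.6 at the detection floor to ~0.25 at
  high abundance;
* per-(patient, card) multiplicative biases (log2 SD 0.25 by default),
  emulating card-level offsets such as one patient's systematically shifted
  B-card; features alternate between cards A and B;
* planted effects: `n_up`/`n_down` features shifted by `effect_log2` at
  every post-baseline time point. With the default
  `effect_mode = "spread_multiple"` the shift is `effect_log2` times the
  expected fold-change spread $\sqrt2\,s(\mu_f)$ — i.e. in units of the MAID
  curve's height — so "effect 3" means "three curve heights", the regime the
  filter is designed to catch. The default `effect_ramp = c(0.5, 0.5, 1)`
  halves the effect at the first two on-treatment time points, mimicking a
  dose-titration start; the recovery experiments set `effect_ramp = 1` so
  that the planted effect is at least three curve heights in *every*
  comparison, matching the property being tested.

What the generator does **not** emulate: amplification chemistry (no
per-assay efficiency differences), correlated features (no co-regulated
modules), patient-level biology (no responders/non-responders unless
`patient_effect_sd > 0`), or heavy-tailed noise. Passing tests therefore
demonstrate that the estimator recovers the model it assumes, and that the
pipeline's logic is correct — not that real cohorts meet those assumptions.

Under this model the chance level of the filter can be computed: MAID scores
of null features are approximately $N(0,1)$ after spread normalization, so a
null feature passes one direction of one comparison with probability
$\sum_{j\ge4}\binom{6}{j}p^j(1-p)^{6-j} \approx 0.007$ at $p = P(Z>1) =
0.159$, and the union over three (positively correlated) comparisons and two
directions filters ≈3–4% of features. The test suite asserts this analytic
bound (< 5%); a claim of < 2% would require the score SD to be ~0.8, which
the model does not produce.

## Downstream statistics

Validation comparisons use classical two-sided paired t-tests (per feature,
patients as pairs; zero-variance differences yield an undefined sentinel,
and the α = 0.10 screen is a plain per-feature reporting threshold, not a
multiplicity-corrected test). Cross-platform concordance is Spearman's rho
(mid-ranks on ties). Heat-map layouts use row z-scores for display and
single-linkage hierarchical clustering with $1 - r$ (Pearson) distance for
both rows and columns; constant rows are flagged, given z-score 0, and
appended after the ordered rows. Columns use the same $1 - r$ metric as rows
(the reference description fixes only the row metric).

## Target-network integration

Filtered miRNAs and mRNAs are joined through exported interaction tables: an
edge is kept iff both endpoints were filtered and the pair is experimentally
validated or predicted by at least 5 of 10 algorithms. Validated pairs
survive regardless of their prediction count; pairs that are both are counted
once as edges but appear in both evidence tallies. Isolated filtered features
are not nodes. Identifiers are matched case-insensitively but otherwise
exactly — harmonizing miRNA naming between annotation releases is the
caller's responsibility. Live database queries are deliberately out of scope
(the upstream services are versioned and irreproducible); the module consumes
exported tables and writes SIF/GraphML.

## Numerical choices and problem sizes

* Curve fits use analytic-Jacobian Levenberg–Marquardt with bounds
  ($b \le 50$ guards overflow of $e^{-bA}$ at negative $A$); restarts with
  $b_0 \in \{0.3, 1, 3\}$ are tried only on failure.
* Loess predictions are clamped to the fitted A-range (no extrapolation).
* The permutation test precomputes log2 values once and re-evaluates only
  transforms, fits and votes per relabelling; 200 permutations of a
  651-feature, 6-patient cohort take ~3 s on one core.
* The calibration experiment in the test suite uses 100 independent null
  cohorts at 200 permutations each (~6 minutes); the exhaustive-enumeration
  check uses a 2-patient, 4-time-point, 30-feature instance whose
  $24^2 = 576$ joint relabellings are enumerated exactly and compared with a
  10,000-draw Monte-Carlo estimate.

## Known limitations

* The exponential spread curve is one of several reasonable variance models;
  strongly non-monotone spread (e.g. saturation artefacts at high intensity)
  is only captured by the isotonic fallback.
* The k-of-n vote treats patients symmetrically; systematic subgroups
  (responders vs non-responders) dilute sensitivity.
* The permutation test addresses only the global count, not per-feature
  significance; no FDR is attached to individual features.
* With ≤4 time points per patient the permutation null has at most
  $24^{n_\text{patients}}$ atoms, and p-values are correspondingly discrete.
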