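---
title: "Methods: the lymphomiR diagnostic workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the lymphomiR diagnostic workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphomiR)
```

This vignette is the package's own account of the models and procedures it
implements, the tunable parameters and their defaults, the numerical and
design choices made where the design was genuinely open, and what the
synthetic-data tests do and do not demonstrate about real data.

## 1. Absolute quantification from Ct values

A qPCR threshold cycle falls by one for every doubling of template, so with
copies $q$ per reaction the model is

$$\mathrm{Ct} = b - \log_2 q,$$

equivalently a standard-curve slope of $-\log_2 10 \approx -3.3219$ cycles
per decade at perfect amplification efficiency
($E = 10^{-1/\mathrm{slope}} - 1 = 1$). `fit_standard_curve()` estimates
slope and intercept by least squares on the six-point 10-fold dilution
series and reports $R^2$ and efficiency; a series with $R^2 < 0.95$ is
flagged but not discarded. Copies are interpolated as
$q = 10^{(\mathrm{Ct} - b)/\mathrm{slope}}$ and stored as $\log_2 q$.

Per-sample workflow variation (RNA isolation, RT efficiency) is corrected
with the spike-in wells: each sample's Ct values are shifted by minus the
difference between its mean spike-in Ct and the cohort median of those
means. The applied offsets are cached on the object so the correction is
idempotent while the spike-in wells themselves stay untouched for audit.

Detectability follows the no-template controls: a well is detectable iff
its Ct is strictly below the *lowest* NTC Ct on its plate. "Higher than
the NTCs" is ambiguous with two NTC wells; the strictest reading
(minimum) was chosen as the conservative one. Technical duplicates are
averaged on the Ct scale — the measurement scale, and the qPCR
convention — after per-well detectability calls: a pair with one
detectable member uses that member; a fully undetected pair is masked and
imputed at the plate's detection limit (the copies corresponding to the
minimum NTC Ct). The imputation only provides a fill value for matrix
algebra; the detection filter removes pervasively undetected miRNAs before
any analysis. Whether discordant duplicates (|dCt| > 1) should be excluded
or averaged is not fixed by qPCR practice; they are averaged and flagged
in a QC table.

## 2. Normalization and batch correction

Four transforms, applied in the order the workflow prescribes:

* **Detection filter** (`filter_detection()`): miRNAs undetected in
  *more than* 10% of samples are removed; a miRNA undetected in exactly
  10% is retained. The filter is applied to the discovery cohort only —
  the validation cohort is profiled on the fixed 100-miRNA panel.
* **Global-mean normalization** (`global_mean_normalize()`): subtracts
  each sample's mean log2 expression over all retained miRNAs, the
  genome-scale qPCR analogue of library-size normalization.
* **Z-score standardization** (`zscore_standardize()`): per-miRNA
  centering and scaling with the $n-1$ sample standard deviation.
* **Housekeeping normalization** (`housekeeping_normalize()`): subtracts
  the per-sample mean of the 10-miRNA housekeeping tier; this is what
  makes two cohorts profiled on different panels comparable.

Batch correction (`combat_correct()`) is the parametric empirical-Bayes
location/scale model: per miRNA, standardize under the covariate model,
estimate per-batch additive ($\gamma$) and multiplicative ($\delta^2$)
effects, shrink them across miRNAs via the EB priors, adjust and
back-transform. The adjustment is delegated to `sva::ComBat`; diagnostic
class and tissue site are always protected as covariates, and a
single-batch input is returned unchanged. The report carries naive
(unshrunk) per-batch estimates from the covariate-model residuals, since
the shrunk internals are not exposed by the implementation.

Two numerical facts worth knowing. First, the EB *scale* adjustment
multiplies residuals by a per-batch variance ratio whose sampling noise is
roughly $\sqrt{2/n_\mathrm{batch}}$, so even with identical batch
distributions individual values move by a few hundredths of a log2 unit
(median ≈ 0.04 at 3 × 66 samples with biological sd ≈ 0.55); the package's
tests therefore bound the *typical* (median) change, not the maximum.
Second, covariate protection is only well-posed when every class occurs in
every batch; a confounded design is rejected as rank-deficient.

`merge_cohorts()` fixes the order of operations for combining cohorts:
restrict both to the shared panel (matching by miRNA id, never position),
housekeeping-normalize each, correct the validation cohort across its
three collection sites, then correct across the cohort pair. Site-level
first mirrors the workflow's own sequencing; the cohort-level pass then
absorbs platform drift between panels. Whether to re-standardize the
merged matrix before classification is genuinely open; it is exposed as
`zscore = FALSE` and off by default, because the housekeeping-anchored
scale is already common to both cohorts. The nodal/extranodal tissue site
is appended as a 0/1 feature (extranodal = 1).

## 3. The tiered 100-miRNA panel

Differential testing uses the equal-variance two-sample *t*-test — the
classical "Student" form; Welch is available via `var_equal = FALSE` but
the named Student form is the default. Contrasts are the five one-vs-rest
comparisons and the ten unordered class pairs; pairs are taken in
alphabetical order so that "up" always means higher in the first class,
making direction labels reproducible.

Marker selection takes, per contrast, the 3 most significant up- and 3
most significant down-regulated miRNAs, ranking purely by p-value (no
multiple-testing correction: this is a ranking, not an inference). Since
30 + 60 + 10 must sum to 100 *unique* miRNAs, a candidate already selected
for an earlier contrast is skipped and the next best by p-value is taken;
ties break by larger |t|, then lexicographic id. The housekeeping tier is
the 10 lowest-variance miRNAs outside the marker tiers, ties by id. All
selection is deterministic given the matrix.

Cross-cohort validation (`validate_trends()`) is a strict sign match of
the mean difference for each candidate's source contrast; a zero
difference in either cohort counts as non-concordant.

## 4. Cross-validated classification

Both diagnostic tasks — reactive-vs-lymphoma screening, and 4-way
subtyping of the lymphomas — use the same harness (`run_cv()`):
`n_iterations` repetitions of stratified 4-fold cross-validation; within
each training split, a stratified inner 3-fold grid search tunes the SVM
cost over the integers 1–10 (ties to the smallest cost); the best-tuned
radial-kernel SVM is evaluated on the held-out fold. Multiclass problems
use one-vs-one voting. Tuning and feature ranking only ever see training
folds; the permuted-label tests verify the absence of leakage by
demonstrating chance-level AUC/accuracy.

Fixed choices required for reproducibility:

* Kernel scale $\gamma = 1/(p \cdot \mathrm{Var}(X))$ with $\mathrm{Var}(X)$
  the overall variance of the feature matrix — the common "scale" default;
  only cost is tuned.
* Stratified folds, because the validation cohort's class imbalance would
  otherwise starve folds of the small classes; each fold's class counts
  are within one sample of proportionality.
* Features enter unscaled (`scale = FALSE` in the SVM): the matrix is
  already normalized, and rescaling would distort the 0/1 tissue-site
  indicator.
* Headline metrics pool predictions over all iterations (confusion
  matrix, accuracy, sensitivities); per-iteration accuracies are also
  reported. Binary AUC is computed per iteration from the held-out
  decision scores and summarized as mean with a 2.5/97.5 percentile
  interval over iterations.

Feature ranking (`rank_features()`) uses the mean absolute equal-variance
t-statistic over training folds (multiclass: maximum over one-vs-rest
contrasts) — the original ranking behind the reported small panels is not
recoverable, so this documented statistic stands in. `accuracy_vs_k()`
re-runs the full harness on the top-k features. `two_stage_predict()`
implements the proposed clinical algorithm: subtype only what screens as
lymphoma.

## 5. miRNA set enrichment (miRSEA)

A miRNA is a *member* of a pathway iff it has at least one strong-evidence
target gene in it. Its targeting strength is the upper-tail
hypergeometric probability of its overlap with the pathway within the
target universe. Pathways targeted by fewer than 10 or more than 500
miRNAs are ignored.

The regulation score is a GSEA-style running sum over miRNAs ranked by
descending lymphoma-vs-reactive log2 fold change: members step up by
$w_i/\sum w$, non-members step down by $1/(N - N_\mathrm{mem})$, and the
score is the signed maximum deviation (bounded in $[-1, 1]$). How fold
change and targeting p combine is not fixed by the method's description;
the minimal multiplicative reading
$w_i = (|\mathrm{log2FC}_i| \cdot (-\log_{10} p_i))^{w}$ with exponent
$w = 1$ was chosen and is configurable (`weight_exponent = 0` recovers
the classical unweighted statistic exactly, which the tests exploit). If
every member weight degenerates to zero (all targeting p = 1), unit
weights are substituted rather than dividing by zero.

Significance permutes *miRNA identities* over the ranked list — severing
the fold-change/membership linkage while preserving both marginals — with
a +1 pseudocount to avoid zero p-values. The p-value is one-sided on the
side of the observed score, with the sign-matched null count in the
denominator: $p = (1 + \#\{s^\ast \geq s,\ s^\ast \geq 0\}) /
(1 + \#\{s^\ast \geq 0\})$ for $s \geq 0$ (mirrored for negative scores).
Normalizing by the sign-matched null count, rather than by the total
permutation count, is what makes the p-values uniform under the null —
a property the test suite checks by KS goodness-of-fit over 200 null
pathways. FDR control is GSEA-style against the pooled all-pathway null:
$q(s) = \widehat{F}_\mathrm{null}(s) / \widehat{F}_\mathrm{obs}(s)$ per
sign, clipped to $[0, 1]$, with BH-style monotonicity (a stronger score
takes the running minimum of raw q over weaker scores).

## 6. What the simulator emulates — and what it does not

`simulate_cohort()` reproduces the statistical structure the analysis
assumes, with defaults set once to the study design the workflow targets:

* cohort sizes: discovery 23/21/20/19/17 (SLL/FL/MCL/MZL/RL, n = 100) at
  one site; validation 20/74/22/74/92 (n = 282) across three sites;
* nodal/extranodal tissue assignment per class with the observed
  proportions (e.g. MZL almost entirely extranodal, SLL mostly nodal), so
  batch correction has real covariate structure to protect;
* ~360 assayed miRNAs of which a `dropout_fraction` (default 0.13, ~313
  surviving) sits below the detection floor and fails the >10% filter;
* 12 planted differential miRNAs per one-vs-rest contrast (half up, half
  down) with a 1.5 log2-copy effect;
* per-site additive (sd 0.4) and multiplicative (sd 0.1) batch effects,
  matching the location/scale model ComBat assumes, plus a per-miRNA
  cohort-level shift (sd 0.3) for platform drift;
* per-sample workflow offsets (sd 0.3 Ct) shared with the spike-ins, so
  spike-in correction is well-posed; technical duplicate noise (sd 0.15
  Ct); sporadic per-well amplification failure (2%);
* Ct generation through the perfect-efficiency curve with per-miRNA
  intercept jitter — keeping the inverse mapping analytically checkable —
  and undetected values emitted at or above the NTC level (38).

Values not fixed by the study design (baseline abundance N(10, 1.5) log2
copies, biological sd 0.3–0.8, spike/NTC levels) were chosen once as
typical of FFPE miRNA qPCR panels and are exposed as configuration, not
revisited per analysis.

The simulator deliberately does **not** model: amplification chemistry or
primer behaviour, FFPE degradation kinetics, correlated co-regulation
among miRNAs (markers are independent given class), heavy-tailed or
sample-specific dropout patterns (the real per-miRNA dropout pattern is
unknown), or realistic class overlap. The last point matters most for
interpretation: with 12 independent markers per class at effect 1.5, the
synthetic classes are far more separable than real cohorts, so the
cross-validated accuracies saturate near 100%. Passing tests therefore
demonstrate that the pipeline is correct, leakage-free and calibrated —
not that any particular clinical accuracy would be attained on patient
material.

`simulate_pathway_resources()` emits a strong-evidence style target table
(default 15 targets per miRNA in a 3000-gene universe) and pathway sets of
20–60 genes in which the planted pathways draw 80% of their genes from the
targets of the *lymphoma-up* planted miRNAs — a coherent direction, so the
planted signal concentrates at the top of the fold-change ranking — plus
size-extreme pathways to exercise the 10–500 filter.

## 7. Problem sizes, determinism, degenerate inputs

Everything is deterministic given the configuration seed; the pipeline
derives fixed per-stage seeds from the master seed and records them in the
run manifest. The package's test suite runs the full default discovery
design (100 samples × 360 miRNAs) for the panel worked example, a
200-sample three-site cohort for batch-correction recovery, 20-iteration
CV for the classification properties, and 400–1000 permutations for
enrichment calibration — sizes chosen so the whole suite completes in
about a minute while keeping every estimate's Monte-Carlo error well
inside the asserted tolerances. `scripts/acceptance.R` re-runs the full
default design end to end.

Degenerate inputs are rejected loudly rather than patched: samples
without spike-ins, standard series with fewer than two distinct points,
zero-variance miRNAs under Z-scoring, missing housekeeping ids,
single-sample batches, confounded batch/covariate designs, classes
smaller than the fold count, and tier collisions in panel assembly all
raise errors naming the offending entity.

## 8. Known limitations

* The weighted-KS formula is a declared, configurable reading of a method
  whose exact published form is not reproduced here; equivalence with any
  external implementation is not claimed.
* Duplicate-discordance handling (average + QC flag) and the feature
  ranking statistic are documented substitutes for unstated originals.
* ComBat's scale adjustment makes "no-op under no batch effect" true only
  in the median, not per value (Section 2).
* The simulator's independence assumptions make classification easier
  than reality; use the effect-size and marker-count knobs to study
  harder regimes.
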