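---
title: "Methods: differential methylation and glucocorticoid sensitivity with gcmethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation and glucocorticoid sensitivity with gcmethyl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcmethyl)
```

## Scope and data model

`gcmethyl` analyses cohorts measured on a 450K-style methylation array and
phenotyped with an in-vitro dexamethasone suppression assay. Its inputs are
four tab-separated tables: a probe × sample matrix of beta-values
(β ∈ [0, 1], the methylated share of fluorescence intensity) with optional
per-cell detection p-values; a probe annotation table (gene symbols, genic
region, CpG-island relation, SNP flag); a sample sheet (clinical group,
glucocorticoid subgroup where known, age, BMI, array batch, cell-composition
estimates, eight RAND-36 quality-of-life scores, onset type); and an assay
plate of triplicate optical densities for three culture conditions per
subject. Upstream steps — raw intensity normalisation and cell-composition
deconvolution — are deliberately outside the package: beta-values and cell
proportions arrive already computed.

## Probe filtering

Unreliable probes are removed by a sequential cascade, each probe counted
under the first rule that removes it:

1. **Detection.** A probe whose detection p-value exceeds
   `detection_alpha = 0.01` in any sample is treated as indistinguishable
   from background and removed. Whether a single failing sample should
   disqualify a probe is a genuine design choice; we default to the
   strictest convention (any sample) and expose `max_fail_fraction` for the
   laxer fraction-based variant.
2. **SNP overlap.** Probes flagged as containing a SNP at the interrogated
   CpG or its single-base extension are removed; the flag is an input (the
   dbSNP lookup is upstream of the contract).
3. **Invariance.** Probes with cross-sample mean β ≥ 0.95 or ≤ 0.05 carry
   essentially no usable variation; both bounds are inclusive.
4. **Missingness.** Probes with any remaining `NA` are removed with a
   logged count. This is our convention: array exports differ in how failed
   values are encoded, and an explicit rule keeps the accounting exact
   (input = retained + Σ removals).

Filtering is idempotent — running the cascade on its own output removes
nothing — and the suite asserts this.

## Batch and covariate adjustment

Array batch effects are removed by the parametric empirical-Bayes
location/scale model (ComBat, via the sva package), with the biological
covariates — group, age (years), BMI (kg/m²) and the cell-composition
estimates — protected in the model matrix. Two choices deserve note. First,
adjustment operates directly on the beta scale, and adjusted values are
clipped into [ε, 1 − ε] with ε = 10⁻⁶; a logit-scale variant would also be
defensible, but beta-scale adjustment keeps the downstream effect-size gate
(|Δβ| ≥ 0.05) on its native scale. Second, the clinical group is protected
in the design; without it, a group imbalance across batches would let the
adjustment absorb real signal. Because the cell proportions sum to a
near-constant, the model uses K − 1 of the K composition columns. A
single-batch input is returned unchanged; a batch with one sample is an
error rather than a silent extrapolation.

On synthetic data with a planted logit-scale batch offset of 0.5, the
adjustment removes ≥ 90% of the per-probe batch-mean gap while moving
planted group effects by less than 0.02 β — both asserted in the suite.

## Differential methylation calling

For two groups, each probe gets the signed mean beta-difference
Δβ = mean(β, g₁) − mean(β, g₂) (hypermethylation positive), a two-sided
Wilcoxon rank-sum p-value, and a Benjamini–Hochberg q-value computed once
over all tested probes. The rank-sum test is exact (enumeration) when the
combined sample size is ≤ 12 without ties, and otherwise uses the normal
approximation with tie-corrected variance and continuity correction; the
test suite checks the exact branch against a brute-force enumeration oracle
over every 4-vs-4 partition.

A site is called significant when **all** gates pass: |Δβ| ≥ 0.05
(`diff_min`), nominal p ≤ 0.05 (`p_max`) and q ≤ 0.05 (`q_max`). The
nominal-p gate is redundant when the FDR gate is active; both are applied
literally because the smaller assay-subgroup comparisons use the two-part
variant (`require_q = FALSE`) where the nominal gate does bind. The
effect-size gate uses |Δβ|: hyper- and hypomethylated sites are both
findings, and no one-sided variant is offered.

Direction-of-change composition across genomic context is tested with
Pearson chi-squared statistics (no continuity correction, matching the
plain Pearson form; `correct = TRUE` is available) — a global test over the
category × direction table and pairwise 2×2 contrasts of each category
against a reference (CpG island by default), BH-adjusted within the
pairwise family. The south-shelf-vs-south-shore contrast is included in the
family because the decay of hypermethylation with island distance makes
neighbouring zones the interesting comparison.

## Permutation null

The constructed null asks: how large a mean beta-difference would label
shuffling alone produce at each locus? The implementation shuffles the
group assignment, recomputes Δβ for **every** probe under that shuffle, and
repeats `n_perm = 10,000` times. One shared shuffle sequence serves all
probes — this preserves the inter-probe correlation structure under the
null and mirrors how the assignment, not the probe, is randomised. The
per-locus permutation p is the proportion of null draws with
|Δβ_null| ≥ |Δβ_obs|; equality counts, so a constant probe gets p = 1, and
the estimator can return 0 (an `add_one` option gives the strictly positive
(k + 1)/(n + 1) variant). Sidedness is two-sided on |Δβ| since both
directions are of interest. Shuffles are drawn uniformly with replacement;
an exhaustive mode enumerates all distinct partitions when
C(n, n₁) ≤ 10⁵ and is the oracle the sampled mode is tested against
(agreement within ±0.02 on 5-vs-5 toys; super-uniformity under an
exchangeable null at α ∈ {0.01, 0.05, 0.1}).

Concordance between nominal and permutation calls — the fraction of probes
passing (|Δβ| ≥ 0.05, p ≤ 0.05) whose permutation p is also ≤ 0.05 — is
reported per comparison and is `NA` (not 0/0) when nothing is nominally
significant.

## Glucocorticoid sensitivity

Per subject, the three culture conditions (unstimulated control,
PHA-stimulated, PHA + 10⁻⁶ M dexamethasone) are averaged over their
triplicates (arithmetic mean; the coefficient of variation of each
triplicate is logged and warned about above 0.2, a conventional ELISA
bound) and sensitivity is

Inhibition% = (Stimulated − Suppressed) / Stimulated × 100,

which is scale-invariant in the optical densities and may be negative.

The case distribution of inhibition is bimodal in this setting; the
original stratification was done by eye, which we formalise as a
two-component univariate Gaussian mixture fitted by EM (10 random
restarts, log-likelihood tolerance 10⁻⁸, SD floored at 10⁻³ of the data
SD). Each case is assigned to its maximum-posterior component, ties
breaking toward typical; the higher-mean component is GC-Hypersensitive by
definition. If a fitted component collapses (weight < 2/n), the function
falls back, with a warning, to a fixed threshold at the midpoint of the two
most separated k-means centres; a `fixed_threshold` mode reproduces
hand-drawn splits exactly. The suite cross-checks EM assignments against an
independent mixture implementation (mclust) and requires ≥ 95% recovery of
planted labels.

Group differences use Welch t-tests (the unequal-variance form, since
homoscedasticity is not defensible across strata of different aetiology);
associations of sensitivity with onset type use logistic regression, and
with RAND-36 scores Pearson correlations (per category and against the PC1
summary).

The three comparisons — Hypersensitive vs Typical, Hypersensitive vs
Control, Typical vs Control — are each called with the two-part criteria
plus the permutation gate (perm p ≤ 0.05), and their significant sets are
intersected. Loci in (HvT ∩ HvC) \ TvC track hypersensitivity itself;
(HvC ∩ TvC) \ HvT is the case-wide set; TvC alone is typical-unique.
Whether the sensitivity set should exclude the triple overlap is
ambiguous; the exclusive set is the default and the inclusive one is also
emitted. The headline per-locus magnitude contrasts the hypersensitive
stratum mean against the **unweighted** average of the typical and control
strata, in percentage points — the only pooled-reference definition
consistent with all three published worked-example magnitudes
(14.3 / 13.7 / 12.0).

## Quality of life

The eight RAND-36 categories share a 0–100 scale but not a variance, so
PCA is computed on z-scored categories (correlation PCA; the covariance
variant is a switch). PC1's sign is arbitrary in principle; it is oriented
so that the General Health loading is positive, making "higher PC1 =
better health" deterministic and sample-order invariant.

Regions are (gene symbol, genic region) groups of probes — a multi-gene
probe contributes to each of its genes, but never twice to one region — and
a region is emitted when at least `min_sites = 2` members each have
|Δβ| ≥ 0.05. Region methylation per sample is the unweighted mean of member
betas: the simplest summary consistent with a minimum-two-sites rule, and
the one under which the region beta-difference equals the mean of member
differences. Each region is regressed on PC1 by OLS across the pooled
cohort (cases and controls; their score separation is part of the signal),
with R² = squared correlation, BH-FDR across regions, and descending-R²
ordering. A group-adjusted variant is available but not default. The suite
plants regions at R²_true = 0.22 and requires the mean estimate within
±0.08, and verifies ≤ 5% false region calls under a planted null.

## The synthetic study generator

Every stage is exercised against `simulate_study()`, which emits the full
input contract plus truth tables (planted differentially methylated probes
with signed deltas, planted sensitivity loci, SNP/invariant/failing probes,
true subgroup labels) sufficient to score sensitivity and specificity of
every caller. Defaults are the target study's dimensions: 49 cases / 25
controls, an assay subset of 33 / 24, a 14 / 19 hypersensitive/typical
split, 71.6% of planted case effects hypermethylated, RAND-36 category
means and standard errors from the published cohort demographics (SE
converted to SD by √n of the corresponding group), and 2 array batches.

Generation is additive on the logit scale — baseline + planted effect +
batch offset + N(0, `noise_sd`) noise, mapped back through the inverse
logit — which keeps betas strictly inside (0, 1) without clipping
artefacts. Planted effect sizes are specified as target beta-scale
differences and converted to the logit offset that realises them exactly at
each probe's baseline. `noise_sd` is the one free parameter with no
published analogue: it is calibrated to 0.08 (≈ 0.02 beta-scale SD at
β = 0.5, within the 0.01–0.05 range typical of 450K within-group
dispersion) so that the recovery suite is neither trivial nor hopeless —
Δβ = 0.15 effects are recovered with sensitivity > 0.9 at cohort size
while Δβ = 0.03 effects sit > 4 SD below the 0.05 effect gate and are
never called. Inhibition modes (control 45 ± 7, typical 48 ± 7,
hypersensitive 82 ± 5 %) reproduce the described structure — typical cases
near controls, a clearly separated hypersensitive mode — in the absence of
published numeric parameters. RAND-36 categories share a per-subject latent
health factor (ρ = 0.3) because survey categories correlate within person;
without it the PC1 variance share is implausibly low.

What the generator does **not** emulate: Infinium I/II probe-type chemistry
bias, raw two-channel intensities, genetic polymorphism effects on
hybridisation, spatial plate effects, or realistic linkage between
methylation and the quality-of-life scores (regions associated with PC1
are planted directly when that pathway is tested). Passing tests therefore
demonstrate that the statistical machinery recovers known structure under
the stated noise model — not that the pipeline's biological conclusions
transfer to any particular real cohort.

## Numerical choices and problem sizes

Exact Wilcoxon enumeration switches off above a combined n of 12 or with
ties; the permutation comparison uses a 10⁻¹² absolute tolerance when
counting "equal or more extreme" to keep equality robust to float noise;
EM stops on a 10⁻⁸ log-likelihood change; PCA orthonormality is asserted at
10⁻⁸; beta clipping uses ε = 10⁻⁶. Ties in top-site tables break
lexicographically by probe id so reports are deterministic. All randomness
flows from explicit seeds; two runs of `run_pipeline()` with the same
configuration are byte-identical.

The shipped tests and the acceptance script run at desk scale by choice:
5,000 probes for the sensitivity/null designs, 2,000 probes with 1,000
permutations for the three-comparison overlap, 200 probes for permutation
calibration, 120 planted regions for the R² recovery. These sizes keep the
full suite under a few minutes while leaving every statistical claim
testable; all of them scale linearly if larger runs are wanted.

## Known limitations

Covariates are adjusted once, upstream, rather than modelled per probe; a
per-probe regression framework (as in limma-style pipelines) would handle
covariate-effect heterogeneity better but is out of scope here, matching
the adjusted-then-test design. The permutation machinery permutes labels
freely; restricted (covariate-preserving) permutations are not offered.
The region summary is an unweighted probe mean; inverse-variance or
island-aware weighting is plausible but unspecified in the original
procedure. The mixture subgrouping assumes exactly two case strata; a
model-selection step over the number of components is deliberately not
automated, since the two-group structure is part of the analysis design.
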