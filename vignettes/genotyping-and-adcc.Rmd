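---
title: "Flow-cytometric FcγRIIIa-V158F genotype prediction and ADCC quantification: methods"
author: "fcgrflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow-cytometric FcγRIIIa-V158F genotype prediction and ADCC quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcgrflow)
```

## The problem

The FcγRIIIa (CD16) V158F polymorphism changes the affinity of the receptor
for IgG1 antibodies and with it the strength of NK-cell-mediated
antibody-dependent cellular cytotoxicity (ADCC). Genotyping normally requires
PCR. The assay implemented here infers the genotype (FF, VF, VV) from a
single flow-cytometry staining by exploiting two anti-CD16 antibody clones
with different epitopes:

* **MEM154** binds next to residue 158. It binds V-bearing receptors strongly
  and F-bearing receptors almost not at all, so its signal on NK cells rises
  with V-allele dosage (VV > VF ≫ FF).
* **LNK16** binds a membrane-proximal epitope present in both variants, with
  slightly stronger staining of FF receptors.

Raw MFIs of the two clones are unreliable across donors and staining batches;
the discriminative quantities are the *ratios* of MEM154 to LNK16 binding on
CD56dim CD16+ NK cells, both in intensity (`rMFI_NKdimML`) and in frequency
(`rF_NKdimML`), because a multiplicative staining-intensity factor common to
both CD16 channels cancels in the ratio. The package's classifier formalises
this: feature construction over NK subsets, data-driven feature selection,
and a linear classifier on the selected features.

## The prediction pipeline

`fcgr_fit()` composes four stages, each refit from scratch inside every
cross-validation fold so no selection information leaks:

1. **Conditional permutation-importance ranking.** A random forest
   (`ranger`, 500 trees by default) is fit to the 30 features; each feature
   is scored by the mean per-tree drop in out-of-bag accuracy when it is
   permuted. Permutation is performed within strata of the most correlated
   covariates (|Spearman r| ≥ 0.5, up to two covariates, bins sized so
   strata hold several samples), so a feature correlated with a truly
   predictive one is not credited for the shared signal. Below 12 training
   samples stratification degenerates into singleton cells and is disabled;
   plain permutation importance is also available (`conditional = FALSE`).
2. **Top-5 candidate cut, VIF filter.** The five highest-ranked features are
   candidates (fewer when `n - 2 < 5`, since a variance inflation factor is
   undefined otherwise). Candidates are z-standardised with training-set
   statistics and the highest-VIF candidate is dropped iteratively until all
   VIFs are below 5; ties keep the higher-ranked feature.
3. **Most distinctive survivors.** The `final_k = 2` highest-ranked
   survivors with *positive* importance form the model; a feature whose
   permutation importance is not positive carries no detectable signal and
   is never deemed distinctive. On the synthetic data this almost always
   yields `rMFI_NKdimML` plus one clone-frequency feature.
4. **LDA + multinomial logistic regression.** Linear discriminant axes
   (≤ 2 for three classes) are computed from the standardised selected
   features, and a weakly ridge-penalised multinomial logistic layer
   (`nnet::multinom`, decay `1e-3`) maps the discriminant scores to class
   probabilities. The predicted class is the arg-max, ties broken in the
   fixed order FF < VF < VV.

### Numerical choices

* **Ridge LDA.** The pooled within-class scatter `W` receives a ridge of
  `1e-6 · mean(diag(W))`; when `n - g ≤ p` or `W` is near-singular
  (`rcond < 1e-10`) the ridge grows to `5%` of the mean diagonal. This keeps
  fits defined down to one sample per class (the learning-curve minimum of
  three training samples), where `W` is exactly zero and LDA degenerates
  gracefully into a nearest-centroid rule in z-space. `MASS::lda` is used as
  an independent cross-check on well-conditioned fits in the test suite, not
  as the implementation, precisely because it refuses these degenerate
  designs.
* **Standardisation** uses training means and SDs only; prediction applies
  the stored statistics, which makes predictions invariant to affine
  rescaling of any feature.
* **VIF** is computed by regression (`1/(1 - R²)`), which remains defined
  (infinite) under exact collinearity where inverting the correlation matrix
  fails.

## Gating

Gates are deterministic functions of the event data. Every positivity
threshold is the valley of a kernel density estimate of log-intensity
between the two largest genuine modes. Two robustness rules matter:

* a candidate valley only counts if its density is at most 75% of the lower
  neighbouring peak — sampling jitter on top of a single mode otherwise
  produces spurious "bimodality" and a threshold in the middle of a
  population;
* wide valleys between well-separated modes are nearly flat, so the
  threshold is placed at the centre of the near-minimum plateau rather than
  at the arg-min, whose position is KDE noise.

When a channel is effectively unimodal (e.g. MEM154 on an FF donor), the
threshold falls back to the 99.5th percentile of an internal negative
population (CD3+ T cells for the CD16 clones). The CD56bright/dim split uses
the same valley rule within the NK gate. Doublets are removed by an
FSC-A/FSC-H ratio band (±35% around the singlet diagonal, estimated from
the frame median or supplied explicitly), debris by an FSC-A floor. All
thresholds are overridable.

Frequencies are reported as percentages of the declared parent population
(subset frequencies as % of NK), and the three NK subsets under either
clone partition the NK gate exactly, so their frequencies sum to 100.

## The 30-feature manifest

The feature list is shipped as a versioned CSV
(`inst/extdata/feature_manifest_v1.csv`) and reconstructed as: for each
clone partition c ∈ {M, L} and NK subset s ∈ {bright, dimCD16+, dimCD16−},
the MFI of both clone channels on s (12), the frequency of s as % of NK (6)
and as % of singlets (6); plus per-subset M/L ratios `rMFI_s_ML` and
`rF_s_ML` (6) — 30 in total, containing the two named selected features
verbatim. Features of empty subsets are flagged missing (`NA`), never
imputed; samples missing a selected feature are excluded from fitting with
a warning and flagged unpredictable at prediction time.

## Evaluation

* `kfold_cv()` — stratified 10-fold CV, full pipeline per fold, predictions
  pooled into one confusion matrix; per-class F1, weighted F1 (per-class F1
  weighted by true-class support — the standard definition, chosen because
  the cohort is class-imbalanced), and the count of FF ↔ VF/VV confusions.
* `grouped_loocv()` — leave-one-out in which *all* samples sharing the test
  sample's patient ID are excluded from training, preventing leakage across
  repeated measures (time points C1/C2/C5/C6); reports per time point.
* `learning_curve()` — for each training size and class-composition scheme
  (4:4:2 population prevalence; 1:1:1 balanced; largest-remainder
  allocation), repeated draws from a pool disjoint from the fixed test set.
  By default the feature set is selected once on the full pool and each
  repetition refits standardisation, LDA and the logistic layer
  (`reselect = FALSE`). The curve answers "how many samples are needed to
  rebuild an established model on a new instrument"; re-running forest
  selection inside draws of three to six samples is statistically empty —
  out-of-bag importances are zero or pure noise there — and is available
  behind `reselect = TRUE` for completeness. Repetition seeds derive from
  the master seed via a counter.
* `fit_baseline()` — the naive comparator: axis-aligned regions from a pair
  of MEM154-MFI thresholds (three bands, since MEM binding orders the three
  genotypes) and one LNK16 threshold, each cell assigned its majority
  training class, fitted by exhaustive search over value midpoints with
  ties broken towards the lowest thresholds. A single threshold per axis
  cannot represent three classes on one axis, which the band design fixes.
* `check_acceptance()` — the published rule: weighted F1 ≥ 90% *and* zero
  FF ↔ VF/VV confusions.

## ADCC quantification

`specific_lysis()` implements the LDH formula — after subtracting the mean
medium absorbance from every condition mean,
`(treated − untreated co-culture) / (Triton − target alone) × 100` — and
flags assays whose Triton/target-alone denominator is not positive. Means,
not medians, summarise the technical triplicates (plate-reader practice).
`delta_tumour_facs()` is the flow counterpart,
`(%viable unstimulated − %viable treated) / %viable unstimulated × 100`.

`build_param_table()` expands the 77-parameter readout manifest
(`inst/extdata/adcc_param_manifest_v1.csv`, reconstructed from the panel's
marker × population combinations: tumour viability classes and checkpoint
markers, NK/NK-dim/NK-bright activation markers and CD16, T-cell markers,
monocyte CD40/PDL1) into 154 measures: `Δp = unstimulated − treated` (a
CD16 *down*-regulation is a positive Δ, matching the convention for
treatment-induced decreases) and `FCp = treated / unstimulated` (FC < 1
encodes a decrease; the direction is configurable since only Δ's direction
is fixed by convention). Δ and FC are mutually invertible given the
baseline, which the tests assert to 10⁻¹².

`compare_groups()` applies the two-tailed Mann-Whitney U test (exact for
group sizes ≤ 8 without ties, normal approximation with tie correction
otherwise), the Brunner-Munzel test (in-house implementation of the
rank-based statistic with Welch-type degrees of freedom), or one-way ANOVA
with Tukey's HSD for three groups. P-values are deliberately *unadjusted*:
the 154-measure screen is exploratory and favours sensitivity over
family-wise control, so its type-I rate is the nominal α per parameter —
the test suite verifies a rejection rate of ≈ 5% under the null.
`embed_tsne()` z-scores the measures (zero-variance columns dropped with a
warning) and runs exact-mode tSNE (perplexity 10 by default, suited to
cohorts of ~45 donors) deterministically from a seed.

## The synthetic generator

No event-level data are deposited with the study, so `fcgr_sim_config()` /
`simulate_cohort()` / `simulate_adcc_plate()` generate data with the
statistical structure the method assumes; the generator is first-class,
tested code, and every analysis in the tests and the acceptance script runs
on it.

Marker intensities are log-normal per population: a positive population is
`exp(N(μ, 0.5))` around its location, background sits at `exp(N(1.5, 0.5))`.
Per sample, 10⁵ events (the stained PBMC count) are drawn from T (45%),
monocyte (15%), CD56bright NK (1%), CD56dim NK (9%, of which 90% CD16+) and
other (30%) lineages, with 2% constructed doublets (summed FSC-A, singlet
FSC-H) and 2% debris.

Genotype enters only through the two CD16 clones on CD16+ NK events:

* MEM154 log-locations FF = 1.8, VF = 4.0, VV = 5.0 — FF binding is almost
  abolished (0.3 above background, so the FF "CD16+ by MEM154" gate catches
  only a small tail), and the VF→VV increment reflects the doubled V-allele
  dose;
* LNK16 log-locations FF = 4.8, VF = VV = 4.4 — genotype-tolerant binding,
  slightly stronger on FF.

Donor-level variability has two parts: a clone-specific location jitter
(SD 0.15) and a *shared* staining-brightness offset applied to both CD16
channels (SD 2.2). The shared offset is the core realism ingredient: raw
MFIs inherit it while M/L ratios cancel it. Its default is calibrated so
that the naive MFI-boundary baseline classifies 68% of the default
91-donor cohort correctly — the published baseline failure rate — while
the ratio-based pipeline is unaffected. A `separation_multiplier` scales
all genotype-location differences around their centre; zero makes the
genotypes exactly indistinguishable, which the degradation tests use.

The ADCC generator gives every donor a latent lysis capacity (uniform
0.45–0.95; FF donors scaled to 40% of it, reflecting low-affinity
receptors). The LDH plate model is additive in optical densities (medium
0.10, spontaneous release 0.40, Triton maximum 1.00, effector background
0.15, triplicate noise SD 0.01), with the antibody-induced increment
proportional to the realized lysis — so the computed specific lysis
recovers the latent capacity, and the flow readout (viable-tumour decline)
shares the same latent, making the two readouts correlate as they do in
the assay. Healthy-vs-mCRC effects enter as configurable multipliers:
ADCC reduced by 40%, CD16 downregulation and CD137/CD107a induction
attenuated by 50%, monocyte PDL1 induction reduced by 50%, PD1+ NK
fraction elevated by 10 points; the defaults are sized so the rank tests
detect them at the study arm sizes (10 vs 35).

**What the generator does not emulate:** spectral spillover and
compensation, instrument drift and time effects, per-allele bimodality
within VF donors (VF is one intermediate location, as donor-level shifts
are what the assay reads out), marker correlations beyond lineage
structure, and absolute-count calibration. Passing tests therefore show
that the pipeline recovers the structure it assumes — genotype encoded in
clone-binding ratios under multiplicative staining noise — not that it
would survive every artefact of real acquisitions.

## Problem sizes used in the tests

The unit and acceptance tests run the study-shaped designs at reduced event
counts — typically 6,000 events per sample (2,000–20,000 where a test needs
more or less resolution), 18- to 91-donor cohorts, 40 learning-curve
repetitions, 50-seed degradation sweeps — sizes chosen so the full suite
completes in a few minutes while keeping every statistical structure
intact. The acceptance script (`scripts/acceptance.R`) runs the full
default conditions: 10⁵ events per sample, 39 + 52 donors, 100
learning-curve repetitions.

## Known limitations

* The exact 30-feature and 77-parameter lists are reconstructions (the
  study's appendix enumerations are not public); both are versioned CSVs so
  alternative enumerations drop in without code change.
* With one dominant ratio feature, all other informative features are
  conditionally redundant, so the second selected feature varies across
  seeds among near-tied candidates; rarely a brightness-contaminated raw
  MFI ties its way in and small-training-size accuracy dips by a few
  points.
* The Mann-Whitney exact path is limited to group sizes ≤ 8 (the
  tie-corrected normal approximation is used beyond), and the
  Brunner-Munzel implementation requires ≥ 3 observations per group.
* FCS support covers list-mode float/double files (FCS 3.0/3.1), which is
  what current cytometers export; integer-mode and multi-dataset files are
  out of scope.
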