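---
title: "Methods: ancestry-dependent methylation analysis and co-methylation networks"
author: "methweave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestry-dependent methylation analysis and co-methylation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methweave)
```

## The analysis problem

methweave implements a complete analysis chain for promoter-array DNA
methylation in a two-ancestry neonatal cohort: which CpG sites differ in
methylation between self-reported African-ancestry (AA) and
European-ancestry (EA) newborns, which of those differences replicate in an
independent panel, whether they are enriched for genetic (cis-meQTL)
regulation, and whether maternal micronutrients — chiefly plasma
25-hydroxy vitamin D — modulate the methylome at the level of correlated
CpG networks.

Methylation is measured per CpG as a beta value (methylated fraction in
[0,1]) with an accompanying detection p-value per measurement. All linear
modelling is done on M-values, `M = log2(beta / (1 - beta))`, which
stabilises variance at the extremes of the beta scale.

## Preprocessing

1. **Entry masking.** A measurement with detection p-value >= 0.001 is set
   missing. The comparison is inclusive. Masked entries are never imputed
   for inference; every per-probe model is complete-case.
2. **Probe filters**, applied in order, each probe counted once: probes
   overlapping a common SNP (manifest flag), probes on chromosomes X or Y,
   probes without a gene annotation. A probe-level median-detection rule
   exists but is disabled by default: published probe-level thresholds for
   this design are mutually inconsistent with the 0.001 entry rule, so the
   entry-level mask is the operative QC and the probe rule is a parameter
   the analyst must set deliberately.
3. **Batch correction** (`combat_adjust`) uses the parametric
   empirical-Bayes location/scale model (ComBat, via the sva package):
   per-probe standardisation given protected covariates, normal prior on
   batch locations and inverse-gamma prior on batch scales with
   method-of-moments hyperparameters, and iterative conditional updates.
   Ancestry is protected in the default pipeline so the biological contrast
   survives correction. The default pipeline corrects on the beta scale and
   transforms to M afterwards, matching common array practice; correcting
   on M is supported and statistically cleaner.

Two properties of this correction are worth stating because they are easy
to misread as failures. First, a post-hoc F-test of batch on the corrected
data is *conservative*: the correction subtracts its own batch estimates,
so residual batch signal is of the order of estimation uncertainty and the
rejection fraction falls well below the nominal 5% (typically ~0 with
hundreds of samples), not to it. Second, re-running the correction is only
approximately idempotent: the second pass re-estimates batch parameters
from fresh sampling noise, changing values with RMS of order
sigma/sqrt(n_batch) (about 5e-3 here), not machine zero.

## Cell-type deconvolution

Whole cord blood is a mixture of leukocyte types whose composition differs
between groups, so estimated lymphocyte and granulocyte fractions are
covariates in every site model. Reference-based (Houseman-style)
deconvolution solves, per sample, a least-squares projection of the
sample's beta profile over cell-type-discriminating CpGs onto the
reference profiles, under non-negativity and a sum <= 1 constraint — the
inequality because only two of several leukocyte types are modelled. The
quadratic program is solved exactly by enumerating active sets of the small
constraint system (tolerance 1e-9), so estimates are deterministic.
Discriminating CpGs are chosen per cell type by |t| (with replicate
references) or |delta beta| (without), split evenly between hyper- and
hypomethylated marks. Projection is done on the beta scale because
mixtures are affine in beta, not in M.

## EWAS and multiplicity

`fit_site_models` fits ordinary least squares per probe:
`M ~ ancestry + maternal_age + lymph_frac + gran_frac`, with ancestry coded
as an indicator with the EA group as reference, so coefficients read as
AA minus EA and a negative sign means lower methylation in the
African-ancestry group. Both cell fractions enter despite partial
collinearity; the design condition number is checked and a warning issued
above 1e6. Birth weight is deliberately not a covariate (its influence on
cord-blood methylation is negligible at this scale). Nutrient models swap
the focal predictor for maternal vitamin D or folate, either unadjusted or
with ancestry, maternal age and cell fractions as covariates; samples
missing the nutrient are dropped. False-discovery control is
Benjamini-Hochberg over all tested probes as one family.

## Replication and enrichment

The replication cohort (an independent African/European panel) contributes
per-probe two-sided rank-sum p-values and a direction (sign of the AA-like
minus EA-like group-mean M difference). A probe is called
ancestry-specific when its discovery q-value is <= 0.05, its replication
p-value is <= 0.05 (both inclusive), and the directions agree.

Enrichment of cis-meQTL-flagged probes among the differentially methylated
set uses the upper-tail hypergeometric probability, computed in log space
(`phyper(log.p = TRUE)`), with fold enrichment `k N / (n K)`. The
background defaults to all analysed probes and is configurable: with
published summary counts, the exact tail depends on the choice of
background set, so the result object always carries the exact computed
tail rather than a rounded figure. The same operation accepts any
user-supplied probe set, giving a generic set-enrichment utility.

## Co-methylation network

The network stage follows the weighted correlation network construction:

* unsigned adjacency `a_ij = |cor(x_i, x_j)|^beta` (Pearson, pairwise
  complete observations; probes with > 20% missingness or zero variance
  are dropped), diagonal set to zero so row sums are connectivities;
* the soft power chosen as the smallest one whose scale-free fit index
  (R^2 of log-frequency on log-connectivity over 10 equal-width bins,
  signed by the negative slope) reaches 0.85, falling back to the argmax —
  published powers are data-specific, so none is hard-coded;
* topological overlap
  `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`;
* average-linkage hierarchical clustering of `1 - TOM` with a *static* cut
  (height 0.99, minimum module size 30). The static cut was chosen over the
  dynamic hybrid cut for determinism and testability; both parameters are
  exposed. Surviving modules are labelled Meth1, Meth2, ... by decreasing
  size (ties by smallest contained probe id); everything else is Meth0.

Module eigengenes are first right singular vectors of the standardized
sample-by-probe block, unit norm, sign-oriented to correlate non-negatively
with the module's mean profile — which makes the output a deterministic
function of the input (flipping all values flips the eigengene with it;
no arbitrary SVD sign remains). Intramodular connectivity `kWithin` is the
within-module adjacency sum; hubs are the top members by `kWithin`.

Module-trait analysis is two-stage, as in the source analysis: simple
bivariate regressions of each eigengene on each trait with a Bonferroni
cutoff of 0.05 divided by the number of modules (0.0056 for nine modules,
i.e. the familiar "p <= 0.006 for 9 tests"), then, for modules associated
with both ancestry and vitamin D, a multiple regression on ancestry,
centered vitamin D, and their product. A positive interaction coefficient
with a negative vitamin-D main effect is the signature pattern: a negative
vitamin-D slope confined to the EA group.

## The synthetic cohort generator

All tests run against `simulate_cohort`, which generates the full input
set (beta matrices, detection p-values, manifest, sample sheet, cell
reference profiles) with the statistical structure the analysis assumes.
Defaults are the study conditions:

* **Cohorts**: 112 AA + 91 EA discovery samples, 30 + 30 replication
  samples; 5,000 probes.
* **Baseline betas**: mixture 60% Beta(2,18), 30% Beta(18,2),
  10% Beta(5,5) — the bimodal promoter-array profile.
* **Ancestry effects**: 18% of probes, additive on the M scale,
  magnitudes |N(0.5, 0.2^2)|, 70% with lower methylation in AA; 36% of
  affected probes are "stable" and shared with the replication cohort.
* **Covariates**: per-group normals matching the published participant
  table — maternal age 25.75 (5.03) vs 29.45 (4.50) years; vitamin D
  17.74 (6.03) vs 20.68 (6.23) ng/ml truncated to the observed range
  [9.4, 35.2]; folate 28.30 (18.40) vs 32.84 (12.16) ng/ml truncated to
  [4.84, 109.14]; lymphocyte 38.08 (12.11) vs 42.73 (10.23) percent and
  granulocyte 48.72 (13.01) vs 45.84 (10.51) percent as logit-normals with
  the joint fraction capped at 0.98 (only two of several types modelled,
  so no sum-to-one closure).
* **Cell structure**: 5% of probes are cell-type-specific marks — high in
  exactly one of the two reference types (|delta beta| >= 0.3) over a low
  shared baseline, so the residual leukocyte pool is unmethylated there.
  This is what makes two-type deconvolution well-posed; with an arbitrary
  "other" profile on discriminating probes the projection would be
  misspecified.
* **Batches**: 3 batches with location offsets spread over [-0.1, 0.1] M
  plus per-probe jitter (SD 0.15) and noise-scale multipliers around 1.
* **meQTL flags**: overall rate 333/20595, enriched 2.5-fold among
  affected probes by construction.
* **Planted interaction module**: 200 probes loading (U(1, 1.5)) on a
  latent factor `f = c1 I(AA) + c2 (vitD - vitD_EA_mean) I(EA) + eps`,
  eps ~ N(0, 0.3^2), c1 = 0.25, c2 = -0.035. Centering vitamin D at the EA
  group mean is a reparameterisation that leaves the interaction term
  untouched while keeping the module from dominating the cohort-wide
  mean-M contrast; c1 and c2 were fixed once by a power calculation so the
  planted interaction is detectable at p < 0.01 with roughly 95% power at
  the default sample size, mirroring a clearly significant published
  interaction.
* **Trait-independent co-methylation**: two blocks of 100 probes sharing a
  standard-normal factor with loading sized for within-block r = 0.8.
  Real methylomes organise into many modules unrelated to the traits under
  study; these blocks emulate that and carry the planted-partition network
  recovery checks.
* **Detection failures**: 0.2% of entries get detection p >= 0.001,
  entry-wise independent (no spatial failure model is published).
* **Replication cohort**: a single cell type (no mixture), no batches, no
  nutrient covariates — the replication stage only ever consumes rank-sum
  p-values and directions, mirroring re-use of published statistics.

With these defaults the generator reproduces the qualitative published
structure: the per-sample mean M is significantly lower in the AA group
(driven by the 70/30 direction asymmetry), about 60% of AA mothers fall
below 20 ng/ml vitamin D, and the planted module shows higher methylation
in AA with a negative vitamin-D slope only in EA.

What the generator does **not** emulate: genotypes (meQTL status is a
manifest flag, not a simulated variant), probe chemistry and dye bias,
spatially correlated detection failures, family structure in the
replication panel, admixture within self-reported groups, and missing
nutrient measurements. Passing tests therefore demonstrate correctness of
the statistical machinery under the assumed generative structure, not
robustness to every artefact of real arrays.

## Numerical choices

* Logit transforms clip beta to [1e-6, 1 - 1e-6] so the transform is total;
  the inverse recovers clipped values to 1e-12.
* The deconvolution QP is solved by exhaustive active-set enumeration —
  exact and deterministic for the small cell-type count (tolerance 1e-9).
* The hypergeometric tail is evaluated in log space and is accurate to
  relative 1e-10 against direct pmf summation wherever the latter is
  representable; log10 tails far below -300 remain finite.
* Module detection has no randomness: static cut, size-then-id tie-breaks.
* Scale-free fit bins connectivities into 10 equal-width bins and drops
  empty ones; fewer than 3 usable bins yields NA rather than a fit.
* Problem sizes in the shipped tests: the full default cohort (5,000
  probes, 203 + 60 samples) for parameter-recovery checks, 2,000 probes
  for the network partition and null-calibration checks, 500 probes per
  seed for the 100-seed interaction-detection study. These sizes keep every
  oracle comparison exact while exercising the same code paths as a full
  array.

## Known limitations

* Ancestry is a self-reported binary indicator; no admixture adjustment.
* Only the parametric empirical-Bayes batch model is provided.
* Deconvolution covers two cell classes; six-type references would need
  only a larger reference matrix but are not bundled.
* The meQTL enrichment background is a modelling choice; with summary
  counts from a publication the exact tail can differ from a printed,
  rounded figure depending on that choice, which is why the exact computed
  tail is always reported alongside the fold.
* The pipeline resumes from stored outputs only when the parameter set and
  every output checksum match; there is no per-stage partial resume.
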