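---
title: "Spatial phenotyping of white matter hyperintensities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial phenotyping of white matter hyperintensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhpheno)
```

## The problem

White matter hyperintensities (WMH) are bright lesions on T2-FLAIR MRI and a
core imaging marker of cerebral small vessel disease. Two people with the same
total lesion volume can carry very different spatial configurations —
periventricular caps, deep frontal clouds, posterior occipital involvement —
and those configurations carry different risk profiles and different prognoses.
`wmhpheno` implements a complete, testable pipeline for *discrete* spatial
subtyping of WMH from the 36-region bullseye representation: 9 lobar sectors
(left/right frontal, parietal, occipital, temporal, plus a combined basal
ganglia / thalamus / infratentorial region, "bgit") crossed with 4 depth layers
running from periventricular (layer 1) to juxtacortical (layer 4).

The pipeline has five stages:

1. **Bullseye mapping** — label volumes to a 36-cell regional volume vector.
2. **Feature engineering** — ICV normalisation, relative distributions,
   square-root + min-max features.
3. **Stability-selected clustering** — bootstrap Jaccard stability over a
   range of k, several engines, stable-centroid estimation.
4. **Association** — risk factors regressed on proximity to each centroid.
5. **Progression** — longitudinal labelling at 250 mm³/year and
   gradient-boosted prediction from competing predictor sets.

A synthetic-cohort generator stands in for the large multi-cohort datasets
(tens of thousands of participants across population and clinical studies)
that motivate the design but are access-restricted.

## Depth fields and the bullseye mapper

Layers are defined from the harmonic potential $u$ solving Laplace's equation
on the white-matter domain with $u = 0$ on the ventricular surface and $u = 1$
on the cortical surface, discretised with the standard 4/6-neighbour stencil
and solved by red-black successive over-relaxation (Jacobi is available as a
mode; the contract is the fixed point, not the sweep order). "Equidistant"
layers are equal bins of this normalised map: layer $\ell$ covers
$u \in ((\ell-1)/4,\ \ell/4]$, upper-inclusive, with $u = 0$ joining layer 1.
An alternative reading — normalized streamline length through the potential's
gradient field — is deliberately left as a future mode behind the same
interface; the potential itself was chosen as the default because it is robust
on voxelised domains and has closed-form oracles (linear in 1D, log-radial on
an annulus) that the test suite exploits.

Numerical choices worth knowing:

* The solver stops when the largest per-sweep update falls below `tol`
  (default 1e-6); non-convergence at `max_iter` warns and flags the field
  rather than failing.
* Against the annulus oracle $\ln(r/a)/\ln(b/a)$ the max error is ~0.08 at
  1 mm voxels and shrinks roughly linearly with voxel size (the staircase
  Dirichlet boundary is first order); the suite asserts a stated bound of
  0.1 and a ≤ 0.65 ratio under 2× refinement.
* White-matter voxels unreachable from both boundaries (isolated islands)
  receive the value of their nearest assigned voxel and are counted in
  `n_islands`; they cannot take boundary information from nowhere, and
  flagging beats guessing.
* Regional volumetry uses true voxel dimensions (non-isotropic safe); WMH
  voxels outside lobe/layer coverage go to an `unassigned_mm3` remainder so
  volume is conserved *exactly* — the suite checks this to the last bit.
* The bgit region is treated as a ninth lobe whose layers come from the same
  depth field; its exact construction in the original bullseye formulation is
  under-specified upstream, and this simplification is the package's
  documented choice.

## Features

Total and regional volumes are divided by the participant's baseline
intracranial volume (head-size normalisation that is less atrophy-sensitive
than brain-volume scaling), and rescaled to a common reference — the median
baseline ICV of the fitting dataset — whenever volumetric units are reported.
The clustering features are the 36 regional *proportions* (regional / total,
summing to 1), square-root transformed and min-max scaled per feature to
[0, 1] with extrema learned on the fitting set. Two deliberate choices:

* **Zero-total rows are excluded** from clustering: a relative spatial
  distribution is undefined at zero burden. The exclusion is logged and
  surfaced, never silent.
* **Min-max is per-feature** (the plausible alternative, one global min-max,
  would let a single dominant cell flatten all others); out-of-sample data
  are transformed with the stored extrema and clip to [0, 1] with a counter,
  mirroring the train-derived-parameters convention used for the PCA
  predictors.

## Stability-selected clustering

Four engines sit behind one fit/assign contract: k-means (k-means++-style
seeding, 10 restarts), mini-batch k-means (batch 1024), a full-covariance
Gaussian mixture (EM, 1e-6 diagonal regularisation), and subspace k-means,
which alternates assignment in an m-dimensional projection, centroid updates,
and an eigendecomposition of (within-cluster scatter − total scatter), with m
set to the number of negative eigenvalues. Neural engines (deep embedded
clustering and deep k-means) are out of scope but the contract admits them as
plugins. Assignment is deterministic given a model: nearest centroid
(Euclidean, in the clustered subspace when present), maximum posterior for the
GMM, ties to the lowest index.

Stability of a clustering at a given k is estimated by the bootstrap: fit a
reference model on all n observations; for each of B = 20 resamples (size n,
with replacement) refit and *extend the bootstrap clustering to all
observations* via the assignment rule. Each reference cluster scores the
maximum Jaccard overlap between its member set and any bootstrap cluster's
member set; means over resamples give per-cluster stability, observations
inherit their cluster's score, and the global score is the mean over clusters.
Extending to the full observation set avoids direct centroid mapping, which
becomes unreliable when clusters split or merge across resamples; per-cluster
max matching (rather than a global bipartite matching) tolerates exactly those
splits and merges. The empty set is defined to have Jaccard 1 with itself and
0 with anything else; degenerate bootstrap fits are flagged, not discarded.

The "repetition" layer — the procedure is analogous to 5-fold
cross-validation in spirit — is realised as 5 independent repetitions on
disjoint seed streams, keeping the most stable replicate; the profile records
that replicate's global stability per (algorithm, k), plus the mean over
repeats. A fold-based realisation could replace this without interface change,
and the choice is recorded in run metadata.

The optimal k is the **largest k in 2–7 whose stability strictly exceeds
0.90** (the conventional bar for well-separated clusters; the wording
"exceeds" motivates the strict inequality). If nothing qualifies the selector
says so explicitly and reports the argmax as a suggestion rather than
silently returning it. Centroids are then re-estimated from observations with
stability > 0.90 (clusters with no such observation keep their raw centroid,
flagged), and clusters are reindexed by increasing median total WMH volume so
that "cluster 1" is always the lowest-burden pattern.

## Association and progression

Cross-sectional associations regress **proximity** — literally the inverse
distance $1/(d + \varepsilon)$, $\varepsilon = 10^{-8}$ guarding rows at a
centroid — on one risk factor at a time, adjusted for age, sex and total
baseline WMH volume, with continuous predictors min-max scaled to [0, 1]
(making estimates invariant to affine rescaling of the raw factor) and
categorical factors encoded against fixed reference levels (male, never
smoker, white ethnicity, no diagnosis/medication, zero APOE4 alleles).
Complete-case analysis; the proximity outcome is left unscaled, so effect
sizes read directly on the natural proximity scale.
All (factor × cluster) p-values of one run form a single Benjamini-Hochberg
family; the family scope is logged because other scopings are defensible.

Longitudinally, annualised change in total WMH volume is computed on the
reference-ICV scale and dichotomised at **250 mm³/year, strictly**: boundary
cases are non-progressors ("dichotomise" leaves the boundary open; strict
comparison is the recorded choice). Group comparisons use Mann-Whitney U on
age/sex-residualised continuous variables and Pearson chi-squared (no
continuity correction, matching the hand-computable statistic) on raw
categorical tables — the exact mechanism for removing age/sex effects from
categorical tests is unspecified upstream, so the package residualises only
continuous variables and says so.

Prediction uses gradient-boosted trees over predictor sets (risk factors;
total volume; 36 regional volumes; centroid distances; one-hot clusters;
PCA scores retaining > 80% cumulative variance, basis fitted on training rows
only), tuned over {50, 100, 200} trees × depth {2, 3, 4, 5} by stratified
5-fold cross-validated balanced accuracy with inverse class weights re-derived
within each training fold, evaluated with percentile-bootstrap CIs (1000
resamples) and pairwise McNemar tests (continuity-corrected) under BH. No
boosting library ships in the supported environment, so the base learner is a
weighted least-squares CART in compiled code and the boosting loop uses
logistic loss with Newton leaf steps — deterministic by construction (no
stochastic subsampling), which makes the tuned-hyperparameter determinism and
train/test-isolation guarantees exactly testable.

## The synthetic cohort: what it emulates, and what it does not

`default_cluster_profiles()` plants five spatial subtypes as Dirichlet
distributions over the 36 cells with total concentration 60, log-normal total
burdens with medians 0.9 / 1.5 / 1.9 / 4.4 / 6.4 mL (log-sd 0.55) and mixing
weights 0.25 / 0.20 / 0.25 / 0.17 / 0.13 — three low-burden patterns
emphasising the bgit region, the occipital lobes and symmetric periventricular
involvement, and two high-burden patterns with frontal-deep and
frontal-parietal emphases. Risk-factor baselines sit near the descriptive
medians of large ageing cohorts (e.g. age 66 ± 7, SBP 135 ± 18 mmHg, 4.3%
diabetes, APOE4 0.72/0.25/0.02) and cluster shifts plant an age gradient and
adverse vascular profiles (SBP +8/+10 mmHg, diabetes, smoking) in the
high-burden clusters. Follow-ups add per-cluster annualised change
(means 60–480 mm³/year straddling the 250 threshold) and a small spatial
drift toward the cluster's mean pattern (0.1/year — patterns should be
largely preserved over 18–30 months). ICV is Normal(1.5 × 10⁶, 1.4 × 10⁵) mm³
truncated at zero. Concentration vectors summing above 1e8 are treated as the
deterministic Dirichlet limit, giving tests exact zero-variance worlds.

These numbers were fixed once, from descriptive statistics typical of large
ageing cohorts and the qualitative pattern descriptions the pipeline targets,
before the acceptance tests were run. What a green test
*does* establish: the machinery recovers planted structure of realistic
separation, the selection rule and all formula-level operations are exact, and
the stages compose deterministically. What it does *not* establish: that five
subtypes exist in any particular real cohort, that real stability profiles
look like the synthetic ones (real data carry scanner effects, site
differences and heavier spatial correlation than a Dirichlet can express), or
that prediction accuracies transfer — the generator has no registration
error, no segmentation noise, and cluster-conditional independence of risk
factors.

## Degenerate inputs and tie-breaks, in one place

* Dirichlet draws that underflow to all zeros fall back to uniform.
* k = n is allowed (every point its own cluster, objective 0).
* Duplicate k-means++ seeds (fewer distinct points than k) are jittered.
* Assignment ties break to the lowest cluster index; `ceiling` at layer-bin
  edges carries a 1e-9 slack so converged solver output cannot straddle a bin.
* Empty subKmeans clusters are re-seeded at the farthest point.
* BH is computed by the step-up definition with an explicit running minimum
  and matches `stats::p.adjust(, "BH")` on every tested family.
* All randomness flows through one seeded generator per call (`with_seed`
  saves and restores the session RNG; derived streams use `child_seeds`).

## Known limitations

No site/scanner harmonisation (out of scope by design); no survival-style or
multi-timepoint trajectory modelling (only baseline → one follow-up); the bgit
layer construction is a simplification; the streamline-length depth mode is an
interface, not an implementation; the CLI covers the common paths
(simulate/map/phenotype/transitions), not every workflow permutation.
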