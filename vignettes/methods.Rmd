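---
title: "Methods: DCE-MRI radiomics and frozen-backbone features for SLN prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DCE-MRI radiomics and frozen-backbone features for SLN prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the method: the model and its
assumptions, the parameters that matter, what the synthetic cohort does and
does not emulate, and the numerical and design choices made where the
protocol left them open.

## The prediction problem

The target is the binary sentinel-lymph-node (SLN) status of a breast-cancer
patient, predicted preoperatively from the in-breast tumor as seen in a
five-phase dynamic contrast-enhanced (DCE) MR series plus routine clinical
covariates. Two image-feature families are compared under one identical
downstream protocol: hand-crafted conventional radiomics (CR) and
deep-learning-based (DLB) descriptors taken from a frozen convolutional
network. The central comparison is generalizability: the independent test
cohort is acquired at a different in-plane resolution (0.78 mm vs 0.7 mm),
so a feature family that is less sensitive to pixel-size change should lose
less performance there.

## Kinetic maps

From phases S₀ (pre-contrast), S₁ (first post-contrast) and S₄ (last
post-contrast), three ratio maps in percent:

* wash-in = 100·(S₁−S₀)/S₀ — uptake amplitude;
* wash-out = 100·(S₁−S₄)/S₁ — late signal loss, the malignancy-typical
  kinetic pattern;
* SER = 100·(S₁−S₀)/(S₄−S₀) — the signal enhancement ratio.

The ratios cancel the arbitrary MR signal scale and the TR/TE dependence.
Voxels where any denominator (S₀, S₁, S₄−S₀) is exactly zero are excluded
from the validity mask and carry `NA` downstream; they are excluded from all
ROI statistics rather than imputed, because imputing a ratio at a vanishing
denominator manufactures extreme values. Maps are computed at each cohort's
native resolution — no resampling to a common grid, since the resolution
difference is the point of the test cohort.

## Regions

The intratumoral ROI is the (manually drawn, in the clinical setting) tumor
mask; subjects with fewer than 64 mask voxels are excluded (the boundary is
inclusive: 64 is accepted). The peritumoral region is the 0–4 mm shell
around the mask, motivated by lymphangiogenic and immune-infiltrate signal
in the tissue surrounding the tumor.

Dilation is performed **2D in-plane per slice** by default. With 2 mm slices
a 4 mm 3D dilation would add exactly two whole slices in the through-plane
direction — a large anisotropic step bearing little relation to the 4 mm
intent — whereas in-plane at 0.7/0.78 mm pitch the millimetre semantics are
honoured to sub-pixel accuracy. A `mode = "3d"` switch exists. Membership
uses exact voxel-center Euclidean distance ≤ 4 mm, implemented by dilating
with the explicit offset set of the disk; tests verify it against a
brute-force per-pixel distance scan.

## Conventional radiomics

All texture statistics are computed on maps that are first clipped into
fixed physical windows (absolute resampling) and quantized to 128 grey
levels. The windows (percent units) are region-specific: intratumoral
wash-in 0…640, wash-out −156…100, SER −1280…1280; peritumoral wash-out
−540…100 (the ring reaches non-enhancing tissue, so deeper wash-out values
occur), others as intratumoral. Quantization is floor-based, left-closed,
with the last bin closed: `level(v) = min(L−1, floor((v−lo)/(hi−lo)·L))`.

Texture is computed in 3D — co-occurrence and run accumulation over the 13
unique directions, zones and neighbourhoods 26-connected — matching the
convention of the widely used extraction tools for this feature set; the
distance for co-occurrence is 1 voxel. Where a feature weights by grey
*value* (NGLDM busyness, GLZLM low-grey emphasis), the 1-based level is used
so that level 0 stays finite; the NGLDM coarseness denominator carries an
ε = 10⁻⁶ guard so constant regions return the guarded maximum 10⁶ instead
of infinity. Every matrix family is validated against an exhaustive
brute-force construction on random small ROIs.

Laws features are computed on the **windowed, unquantized** percent maps:
the 25 outer products of the 5-tap kernels L5, E5, S5, W5, R5 (numbered
1…25 row-major in that kernel order — the numbering is a package
convention), applied per slice as zero-padded same-size correlation;
in-ROI responses are pooled across slices and summarised as mean squared
response (Energy_k) and skewness (Skewness_k). Invalid voxels enter the
convolution as 0, like the zero padding.

### The feature catalog

The published model-input counts for this protocol (93 intratumoral
features; 146 for intratumoral + peritumoral) cannot be decomposed into
equal per-map, per-family blocks, and the full per-feature listing lives in
supplementary material that is not machine-readable here. The catalog is
therefore **config-pinned**: the default intratumoral set is 5 shape + the
full first-order/GLCM/NGLDM/GLRLM/GLZLM blocks (72) + 16 Laws features; the
default peritumoral set is the full first-order/GLCM/NGLDM blocks (45) + 8
Laws features. The Laws subsets favour the filters most prominently
reported for this task (Energy_4, Energy_8, Skewness_5, Skewness_7,
Skewness_9 per map) with a fixed deterministic fill. Any other composition
can be passed as a catalog data frame; all counts are checked by tests.

## DLB features

Each ROI-intersecting slice becomes a 224×224×3 tensor: per channel
(wash-in, wash-out, SER) the map is masked to the region, clipped into the
same absolute windows as above, mapped affinely to 0…1 and multiplied
by 255, then cropped at the ROI centroid (ties round toward the lower
index). Note an intentional fidelity choice: masking sets background to 0
*before* the affine mapping, so for channels whose window has a negative
lower bound (wash-out, SER) the background maps to a nonzero constant —
the protocol zeroes first and normalises second, and the package keeps that
order. The backbone consumes the 0–255 values directly; no channel-mean
subtraction is applied by default (a canonical-preprocessing switch would
be trivial to add but is not part of the protocol as described).

The backbone is pluggable behind a single forward-pass contract: frozen
weights, 224×224×3 in, the pre-softmax activations of the last
fully-connected layer (width 1000) out, one vector per slice, averaged
across slices per subject. The default is a **seeded random-weight frozen
convnet** (4×4 average pool → 5×5/stride-2 conv + ReLU → 2×2 max pool →
3×3 conv + ReLU → 2×2 max pool → fully connected to 1000). Random frozen
convolutional features are a legitimate, well-studied feature family in
their own right and make every pipeline property reproducible offline and
seed-exact; the canonical pretrained 16-layer backbone can be substituted
where its weights are available, without touching any other stage. The
package deliberately never fine-tunes: all comparisons are about frozen
descriptors.

## Reduction

Order is fixed: z-score → ADASYN → Mann-Whitney filter → Spearman prune →
optional PCA, with every statistic fitted on the training split only and
reused verbatim for validation and test (asserted by a provenance flag).
Zero-variance training columns are dropped with a warning rather than
erroring, since constant covariates legitimately occur in small synthetic
cohorts.

* **ADASYN** (k = 5 neighbours, β = 1, the method's standard defaults):
  synthetic minority samples allocated by local difficulty (majority
  fraction among the k nearest neighbours), interpolated uniformly toward
  minority-class neighbours. Only the training split is ever rebalanced;
  tests verify every synthetic point lies on a minority–neighbour segment.
* **Mann-Whitney / Spearman statistics** are computed on the rebalanced
  training set (the reduction stage follows rebalancing in the protocol
  order); a switch allows using the originals. Exact p-values for small
  untied samples, normal approximation with tie correction otherwise. The
  correlated-group representative is the member with the smallest
  Mann-Whitney p — the most class-informative — via a greedy pass in
  ascending-p order.
* **Clinical covariates** (11 numbers: quadrant, multifocality, age, grade
  as ordinal, lymphovascular invasion, one-hot pathological type ×2 and
  molecular subtype ×4) are z-scored and carried through the rebalancing,
  but bypass the filter stages and are re-attached before selection, since
  the protocol combines them with the *reduced* image features.
* The (p, ρ, PCA) cell is chosen by the highest mean validation accuracy
  over repeated protocol seeds — the protocol's own criterion. The package
  exposes the full 4×5×6 grid; the shipped analyses search the no-PCA
  p×ρ sub-grid with 5 seeds per cell, a scale documented below.

## Modeling

LASSO-penalised logistic regression (binomial deviance, 100-value lambda
path down to 10⁻⁴·λ_max) with 3-fold cross-validation; the chosen lambda is
the largest within one standard error of the minimum CV error (the 1-SE
rule, with the SE taken across folds). If the active set exceeds 10
features, larger lambdas along the path are taken until the cap holds. The
selected features are refit by unpenalised maximum likelihood, and the
decision threshold maximises the Youden index over the midpoints of
adjacent sorted unique training scores (ties to the lowest threshold). The
whole selection is repeated across seeds with reshuffled folds; the seed
with the highest training accuracy — computed on the rebalanced training
set, which is what the model was fitted to — wins, ties to the lowest seed.

Two numerical policies deserve note. First, complete separation: on small,
strongly-signalled rebalanced training sets the logistic IRLS routinely
hits its iteration cap with divergent coefficients. The scores remain
monotone in the linear predictor, which is all the Youden thresholding and
accuracy computation consume, so the default policy keeps the iteration-cap
fit with a warning (a strict erroring mode exists). Second, empty
selections: under null features the 1-SE rule frequently selects nothing;
the protocol then falls back to the intercept-only model, whose constant
scores make the Youden optimum undefined, so the threshold defaults to 0.5
(majority-class prediction). Both policies are what permit honest null
experiments rather than engineered failures.

Reported metrics per split: rank-based AUC (equivalent to pair counting
with ½ credit for ties), sensitivity, specificity, PPV, NPV, accuracy, YI.
Training-split reports are produced both on the rebalanced set (the basis
of seed selection) and on the original training rows.

## The synthetic cohort

The generator emulates the study conditions: 109 + 54 subjects at 0.7 mm
and 35 at 0.78 mm in-plane (2 mm slices), positive fraction 0.34, and a
planted, recoverable class signal. Per subject, an ellipsoidal tumor
(radii 5–8 mm in-plane, 3–5 mm through-plane, drawn in millimetres so the
test cohort's masks carry ≈ (0.7/0.78)² fewer in-plane voxels) follows a
piecewise-linear enhancement curve: baseline S₀ ≈ 100 arbitrary units,
rise to S₁ = S₀(1 + a·f), linear washout to S₄ = S₁(1 − w·f), with
Gaussian phase noise (SD 5% of baseline) and a smoothed random field f of
unit mean modulating enhancement voxelwise so texture is non-degenerate.

Planted effects (standardized latent shifts for positives, chosen once as
plausible for a moderately separable clinical task and not revisited):
wash-out mean +1.5 SD (the primary kinetic signal), wash-in +0.5 SD,
texture heterogeneity +1.0 SD; clinical log-odds shifts of 2.0 for
lymphovascular invasion (≈ 15% → 57% prevalence) and 1.0 for tumor grade.
The default grid is 48×48×12 voxels — large enough for tumor plus 4 mm
ring, small enough that the full 198-subject cohort extracts in minutes.

What the phantom does **not** emulate: Rician noise (additive Gaussian is
used; at typical SNR the difference is negligible for ratio maps),
irregular tumor boundaries (axis-aligned jittered ellipsoids only), breast
anatomy and fat-suppression artefacts in the background, scanner-specific
intensity non-uniformity, and any spatial correlation between clinical
covariates and image phenotype beyond the shared label. Passing tests on
the phantom therefore demonstrate the pipeline's correctness and its
ability to recover planted multivariate signal — not clinical performance.

## Validation experiments and problem sizes

The test suite runs (sizes chosen to keep the default run inside a few
minutes while preserving the study's structure):

* all texture extractors against exhaustive brute-force oracles on 50
  random ≤ 6³ ROIs per family, plus first-order/Laws direct-summation
  oracles;
* kinetic identities (SER·(S₄−S₀) = 100·(S₁−S₀) = wash-in·S₀) at 1e−9
  relative tolerance on random phantoms; exact quantization boundaries;
* the published performance-table rows as confusion-matrix arithmetic
  (validation and testing rows are fully determined by the printed
  sensitivities/specificities and cohort sizes; training rows are checked
  for the derivable subset, consistent with metrics on the rebalanced
  training set);
* signal recovery at study scale: the default 109/54/35 cohort, reduction
  parameters chosen by the protocol's own validation-accuracy grid search,
  then 20 protocol replicates at 25 seeds each (scaled from 100) —
  requiring lymphovascular invasion plus at least one image-derived
  feature in ≥ 80% of replicates and mean validation AUC ≥ 0.80. Any
  image-derived selection counts as planted signal because the planted
  mechanisms permeate all three maps (wash-out enters wash-out and SER;
  the heterogeneity field modulates texture everywhere), and the null
  control guards against image features being selected spuriously;
* a null control: all planted effects zero, 20 replicates, mean validation
  YI within three standard errors of zero.

## Known limitations

* The 105-feature total quoted for the original extraction cannot be
  reconciled with the published per-model input counts without the
  supplementary listing; the catalog is pinned to the input counts instead
  (see above) and is fully configurable.
* The Laws filter numbering (Energy_8 etc.) is a convention; the original
  in-house ordering is unknown.
* The pretrained 16-layer backbone's weights are not bundled; the default
  frozen random backbone exercises identical plumbing and the backbone is
  swappable behind one function.
* The grid search optimises validation accuracy and the final seed is
  chosen by training accuracy — both faithfully reproduced; neither is a
  nested, unbiased model-selection scheme, so validation metrics retain
  optimism, exactly as in the original protocol.
* Real-data ingestion (NIfTI phases + mask + clinical CSV) validates grids
  and the 64-voxel rule but assumes co-registered phases; registration is
  out of scope.
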