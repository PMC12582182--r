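---
title: "MR-free spatial normalization and Braak-stage SUVR quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MR-free spatial normalization and Braak-stage SUVR quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petnorm)
```

## The problem

Quantifying tau PET uptake requires warping each subject's scan into a
common template space so that template-defined regions of interest (ROIs)
apply to everyone. The classic route needs a paired structural MR image:
the PET is rigidly coregistered to the MR, the MR is nonlinearly
normalized to the template, and the composed transform is applied to the
PET. `petnorm` implements the MR-free alternative: a deformation-prediction
model that maps a PET volume alone to the nonlinear deformation field in a
single forward pass, followed by standardized uptake value ratio (SUVR)
computation over Braak-stage composite ROIs with a cerebellar gray matter
reference, and the validation and clinical-association statistics that a
study of such a pipeline reports.

Everything is testable without external data because the package ships a
synthetic phantom generator with known ground-truth deformations, known
ground-truth SUVR, and cognitive scores stochastically linked to tau
burden.

## The deformation model

A deformation field `u` assigns each template-grid voxel `v` a displacement
in voxels; the warped image is `W[v] = I(v + u(v))` (pull semantics,
trilinear interpolation, zero outside the grid). All fields in the package
map template grid to native coordinates; push-semantics fields are not
accepted anywhere.

The predictor is a two-stage cascade:

* **Coarse stage.** The input volume is mean-normalized and block-averaged
  (factor 2). Each control point of a 1/4-resolution control grid predicts
  its 3-vector displacement as a linear function of the pooled intensities
  in a surrounding neighborhood of blocks plus a bias; the control grid is
  upsampled trilinearly to the full grid.
* **Fine stage.** The input is warped with the coarse field; the same kind
  of locally connected linear layer, reading the coarse-warped volume,
  predicts a residual displacement on a 1/2-resolution control grid.

The composed field is the sum of the two upsampled displacements (additive
residual composition — this convention is fixed and used everywhere). The
heads are *locally connected* rather than fully connected: each control
point only sees its own neighborhood, which is the linear analogue of a
convolutional layer and is what makes the model generalize across subjects
instead of memorizing the training set. Weights are zero-initialized, so an
untrained model predicts the zero field and `normalize()` degenerates to a
resampling of the input.

Training minimizes

```
similarity_loss(warp(input, u), template) + lambda * regularizer(u)
```

jointly over both heads with Adam, backpropagating the similarity gradient
through the trilinear warp (the spatial gradient of the interpolant is the
chain-rule factor). Two conventions matter and are deliberate:

* the fine head's *feature* path (the coarse-warped volume) is treated as a
  constant within each step (stop-gradient); the loss gradient still reaches
  both heads through the composed field;
* the whole run is a pure function of `train_config(seed =)` — minibatch
  order and augmentation draws come from that seed, so histories are
  bit-reproducible on one platform.

### Losses and regularization

The default similarity is `ncc`, one minus the global normalized
cross-correlation: it is invariant to affine intensity rescaling, which is
the right robustness for PET whose global activity scale varies by dose and
scanner. `mse` is available for same-scale images. A constant image has no
correlation defined; its NCC loss is 1 by convention.

The regularizer is a diffusion penalty: for each displacement component the
mean squared forward difference along each axis, summed over axes and
averaged over components. A pure translation costs nothing; a unit shear
(`disp_x = x`) costs exactly 1/3. The default weight `lambda = 0.4` was
calibrated on phantoms by endpoint-error recovery against known fields:
much smaller values let the model "match" the template with physically
wrong fields, much larger values shrink predicted displacements toward
zero (values in 0.3-1 performed within a few percent of each other).

Learning rates default to 1e-3 for training (the reference experiments use
1e-2 with a decay phase; both are exposed) and 10x smaller for fine-tuning.

### Augmentation and transfer learning

`augment()` applies a random rigid transform (uniform translations and
per-axis rotations within configurable ranges) followed by additive
Gaussian noise, all drawn from a seed. `fine_tune()` initializes from a
saved checkpoint — e.g. a model pretrained on amyloid-profile phantoms —
and continues training at a reduced learning rate; a checkpoint stores an
architecture hash and loading refuses a mismatch, so silent
reinitialization cannot happen. `transfer_experiment()` packages the
two-tracer comparison: pretrain on the amyloid profile, fine-tune on tau
phantoms, and compare the final validation loss against training from
scratch at a matched iteration budget over several seeds.

## The classic comparison pipeline

`run_classic()` is a functional stand-in for an SPM-style MR-based
pipeline, *not* a reimplementation of SPM: `rigid_coregister()` maximizes
NCC over the six rigid parameters (deterministic coarse translation search
plus Nelder–Mead refinements), `iterative_normalize()` optimizes the same
NCC + diffusion objective directly over the field, demons-style, with
Gaussian field smoothing at two resolution levels, and the rigid and
nonlinear transforms are composed in world space so the PET is interpolated
exactly once.

## SUVR quantification

`compute_suvr()` divides the mean activity over each ROI's voxels by the
mean over the cerebellar gray voxels, on the template-space PET. Composite
ROIs pool voxels across their member labels (voxel-weighted), never
averaging sub-ROI means. No partial-volume correction is applied. Empty
ROIs yield `NA` with a warning; a non-positive reference mean is an error,
not a silent `Inf`.

## The phantom generator

`make_template()` builds a deterministic synthetic head: nested ellipsoids
for cortical gray, central white matter, ventricles, cerebellum, and a
scalp/skull shell, plus seven ROI blobs carrying the role taxonomy
(Braak I–II, III–IV, V–VI composites, a metatemporal composite, and
entorhinal / inferior-temporal subregions nested inside the early-Braak
sets). A seeded low-frequency intensity texture stands in for gyral/sulcal
detail. Three generator choices deserve explanation because they decide
what the phantom can measure:

* **Internal contrast is information.** A deformation is only observable
  where the image has intensity gradients; in perfectly flat regions *no*
  similarity-driven method can recover it. The texture, ventricles and
  tissue contrast give the interior enough structure that registration is
  well-posed, which real brains provide in abundance.
* **PET tissue contrast.** The painted PET's base activity is a
  piecewise-linear function of the MR-like intensity (gray ≈ 1, white
  ≈ 0.6, CSF ≈ 0.3, scalp ≈ 0.35), emulating the gray/white/CSF contrast
  and off-target scalp uptake of real tau PET. Scanner physics (PSF,
  scatter, attenuation) are deliberately *not* modeled.
* **Eroded reference.** The cerebellar gray label is the one-voxel-eroded
  cerebellum core. Un-eroded edge voxels border low-activity tissue and
  background; under any resampling they mix outside activity into the
  reference mean and bias every SUVR in the study upward. Eroding reference
  regions is standard practice in PET quantification for exactly this
  reason. With this atlas, quantifying phantoms through their *true* fields
  recovers truth with ICC ≈ 0.996 per ROI, so downstream validation
  measures registration quality rather than generator artifacts.

`sample_deformation()` draws Gaussian-smoothed white-noise displacements
plus a small random affine component, rescaled so the peak magnitude equals
the requested amplitude, and rejects/rescales until the minimum
finite-difference Jacobian determinant exceeds 0.1 — every ground-truth
warp is smooth and invertible. `synthesize_subject()` paints stage-dependent
uptake (with per-ROI lognormal jitter standing in for biological
heterogeneity), records the true SUVR from the painted volume *before* any
warping or noise, then resamples PET and MR into native space through the
numerically inverted field and adds Gaussian noise scaled to the mean brain
activity.

Stage uptake profiles (CN ≈ 1.0–1.2, elevated early-Braak uptake in MCI,
global elevation in AD, and a diffuse `amyloid` profile for transfer
experiments) are package defaults chosen to respect the Braak ordering;
they are placeholders in the sense that no published per-stage magnitudes
were fitted.

`make_cohort()` links cognition to tau: MMSE/MoCA are
`baseline − effect × (metatemporal SUVR − 1) + noise` clipped to [0, 30]
(baselines 28.5 / 27.5, consistent with the conventional CN thresholds of
25 and 26); the four episodic-memory probabilities use logistic links, with
recall-from-nondurable-memory given a positive link because that measure
empirically runs *opposite* to the others. Longitudinal visits decline
proportionally to baseline entorhinal/inferior-temporal SUVR. With
`volumes = FALSE` the generator skips volume synthesis and computes each
subject's true SUVR through the exact linear painting map (painting and ROI
averaging are linear in the uptake levels, so this path is identical, not
approximate), which makes 10^4-subject Monte-Carlo oracles and repeated
null-calibration cohorts cheap.

## Validation statistics

* `icc()` computes single-measure intraclass correlation from the two-way
  ANOVA mean squares. The default is absolute agreement (`ICC(A,1)`), which
  penalizes systematic offsets between pipeline and truth; the consistency
  variant (`ICC(C,1)`) is also exposed because reliability studies differ in
  which they report. Confidence intervals use the F-distribution method,
  with Satterthwaite degrees of freedom for the agreement variant.
* `correlate()` is a Pearson correlation with the p-value from the
  t-transform on n−2 degrees of freedom, a one-sided-negative option
  (half the two-sided p when r < 0, `1 − p/2` otherwise), and Bonferroni
  adjustment `min(1, m·p)` for a declared family size.
* `stage_subjects()` labels CN as CDR 0 and CDR > 0.5 as AD; a CDR of 0.5
  is ambiguous between MCI and AD by the usual definitions, so it is
  resolved by an explicit `diagnosis` column when available and otherwise
  labeled `CDR0.5_unresolved` rather than silently assigned.
* `quintile_stratify()` cuts scores at the 20/40/60/80th percentiles
  (type-7 linear interpolation; edge ties fall to the lower bin) and
  reports mean SUVR per quintile, flagging the degenerate all-equal case.
* `change_ratio()` is exactly `(post − pre)/(pre + 0.1)`; the 0.1 is a
  zero-guard for the probability-valued measures and is applied verbatim to
  all measures.
* `longitudinal_analysis()` takes baseline SUVR from the earliest scan,
  matches Pre/Post exams to the earliest/latest scans by minimum absolute
  date difference (ties to the earlier exam), excludes subjects whose
  change-ratio magnitude exceeds 0.5 on any analyzed measure, and
  Bonferroni-corrects over the ROI × measure family. Fewer than three
  surviving subjects yields `NA` correlations with a warning.

## Reference experiments and problem sizes

`mrfree_validation()` is the end-to-end experiment: by default 40 phantom
subjects at 32³ (deformation amplitude 2 voxels, smoothness 4, PET noise 5%
of mean), a 1,000-iteration two-phase training of the cascade (fields predicted
from the PET alone; similarity computed on the warped paired MR against
the MR-like template), MR-free normalization of every
subject, SUVR over the four composite ROI sets, and per-ROI
absolute-agreement ICC against the phantom truth; optionally it evaluates
mean endpoint error on freshly drawn held-out phantoms against the
zero-field baseline. `transfer_experiment()` runs at 24³ with smaller
budgets. The 32³/24³ grid sizes and iteration counts are the package's
demonstration scale — large enough that the ICC and endpoint-error
comparisons are meaningful, small enough to run routinely on a laptop CPU;
the same code runs at any grid divisible by 8.

## What passing phantom tests does and does not show

The phantom cohort shares with real data the structure that matters for
*testing the pipeline's logic*: smooth invertible inter-subject
deformations, tissue-contrasted PET with stage-dependent regional uptake,
noisy scores linked to tau burden, and longitudinal decline. It does not
emulate scanner physics, real anatomy, atrophy, off-target binding
patterns, or the true distribution of cognitive scores; a model trained on
phantoms says nothing about real scans, and the package's validation
numbers are statements about the method's self-consistency under known
ground truth, not clinical performance.

## Numerical choices and degenerate inputs

* Trilinear sampling treats everything outside the input grid as zero;
  displacement-field sampling clamps coordinates instead (a field has no
  meaningful zero outside its grid).
* `invert_field()` iterates the fixed-point equation of the inverse
  displacement; the Jacobian bound of the generator guarantees convergence
  at the amplitudes used.
* NCC of a zero-variance image is defined as loss 1; an SUVR reference mean
  ≤ 0 is an error; an empty ROI is `NA` with a warning; a cohort stage mix
  must sum to 1; training aborts with the iteration index on non-finite
  loss.
* Checkpoints refuse architecture-hash mismatches and unreadable files.

## Known limitations

* The deformation predictor is a locally connected linear cascade — the
  role, interfaces and training objective of the full convolutional
  original, at a fraction of its capacity. It is adequate for the smooth,
  moderate-amplitude phantom deformations it is tested on; large-amplitude
  or high-frequency warps would need the nonlinear original.
* Inverse transformation (template space back to native PET space) is
  intentionally unsupported, matching the forward-only design of the
  pipeline this package models.
* The classic pipeline is a comparator, not an SPM clone; its absolute
  performance should not be read as SPM's.
* Memory probabilities are consumed as given; the hierarchical Bayesian
  memory model that produces them in real studies is out of scope.
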