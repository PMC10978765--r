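---
title: "Automated volumetric assessment of DESH: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated volumetric assessment of DESH: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Disproportionately enlarged subarachnoid-space hydrocephalus (DESH) is the
imaging hallmark of Hakim disease (idiopathic normal-pressure
hydrocephalus): the cerebrospinal fluid is redistributed so that the
ventricles and the Sylvian fissures enlarge while the subarachnoid space
over the high convexities is squeezed. Radiological judgement of DESH is
subjective and experts disagree, so `deshkit` implements a two-step
quantitative assessment from 3D brain MRI:

1. **Volumetric semantic segmentation.** A 3D U-Net labels every voxel as
   background, parenchyma, total ventricles, Sylvian fissure + basal
   cistern, high-convexity subarachnoid space (SAS) or other SAS.
2. **Image classification.** A multimodal convolutional network makes four
   binary determinations — DESH, ventricular dilatation (VD), tightened
   high-convexity sulci (THC), Sylvian fissure dilatation (SFD) — from
   task-specific CSF masks plus age and sex.

Around the networks sit the quantitative core: the volume-ratio indices

$$\mathrm{Venthi} = \frac{V_\mathrm{vent}}{V_\mathrm{hc}}, \qquad
  \mathrm{Sylhi} = \frac{V_\mathrm{syl}}{V_\mathrm{hc}}, \qquad
  \mathrm{DESH~index} = \mathrm{Venthi} + \mathrm{Sylhi}
  = \frac{V_\mathrm{vent} + V_\mathrm{syl}}{V_\mathrm{hc}},$$

ROC analysis with Youden-optimal thresholds for detecting DESH from the
indices, and the landmark rule that carves the high-convexity SAS out of a
total-SAS mask. We compute the DESH index as the *sum* of the other two —
algebraically identical to its ratio definition, and it makes the identity
`desh = venthi + sylhi` exact in floating point.

## The synthetic phantom cohort

The MRI cohorts this method was developed on are not publicly shareable,
so the package ships a first-class synthetic phantom generator; every
statistical claim the tests make is made on these phantoms, and the
generator's defaults *are* the study conditions.

Each phantom is a schematic six-compartment cranial geometry inside a
skull ellipsoid: paired ellipsoidal lateral ventricles plus a midline
third ventricle, two oblique slab-shaped Sylvian fissures joined by a
basal cistern sheet, a vertex sheet of high-convexity SAS (cut by exactly
the same landmark rule the partition module applies), an outer SAS shell,
parenchyma elsewhere. Compartment volumes are drawn from a calibration
table of published per-group means and SDs of automatically segmented
volumes (Hakim disease vs. normal, per contrast); each compartment is then
realized by thresholding a continuous shape field at exactly the voxel
count matching its target, so realized volumes match targets to within one
voxel (the 5% fidelity contract is met with large margin). Two contrast
renderings are supported: CSF-dark (`T1_like`) and CSF-bright (`T2_like`),
plus Gaussian noise (default SD 0.03 on a [0, 1] intensity scale).

Choices worth knowing about:

* **Correlated volume draws.** Within a subject the four compartment
  targets share a latent severity factor (loading 0.9): in the Hakim group
  large ventricles and Sylvian fissures co-occur with a small
  high-convexity space, while in normals a global atrophy factor enlarges
  all CSF spaces together. Independent draws would occasionally produce
  normals with Hakim-like index ratios, which real cohorts — where the
  indices separate the groups almost perfectly — do not show. The marginal
  mean and SD of each compartment still match the calibration table.
* **Targets are floored at 3 mL** (not lower) because one voxel on the
  default grid is 15.6 mm³; far smaller compartments could not meet the
  volume-fidelity contract.
* **Default grid 64×64×64 at 2.5 mm** (160 mm field of view). This is a
  desk-scale grid: phantoms render in ~0.2 s and a full training run fits
  in minutes on one CPU. Finer grids (e.g. 0.9 mm) are supported but not
  default.
* **Phenotype flags.** DESH implies THC and SFD by definition; VD
  accompanies DESH with probability 0.95; isolated VD/THC/SFD occur in
  non-DESH subjects with small probabilities (2–3%), and such an isolated
  flag pulls the corresponding single compartment from the Hakim column so
  the flag is visible in the image. DESH subjects are drawn older
  (normal ~ N(52, 16²), DESH ~ N(75, 7²) years, truncated), mirroring the
  age imbalance of real Hakim cohorts; ages of non-DESH subjects also
  nudge ventricular and outer-SAS volumes upward slightly (0.2 and
  0.4 mL/year) as a mild atrophy effect.

What the phantoms deliberately do **not** emulate: cortical folding,
partial-volume effects, bias fields, k-space artifacts, or any pathology
beyond CSF-space morphometry. Consequently, passing tests show that the
*pipeline machinery* — geometry-faithful segmentation, rule-based
partition, index computation, threshold calibration — is correct and
learnable at realistic effect sizes; they do not certify performance on
clinical MRI.

## The landmark partition of the subarachnoid space

The high-convexity SAS is defined by four anatomical predicates applied in
world millimetres: superior to the top of the lateral-ventricle bodies;
within 30 mm perpendicular distance of the midsagittal plane; posterior to
the coronal plane (perpendicular to the AC–PC line) through the front edge
of the genu of the corpus callosum; anterior to the posterior parts of the
callosomarginal sulci. Landmarks are supplied per subject (by the phantom
generator, or as a JSON sidecar for external data) rather than inferred
from images — automatic landmark detection is out of scope. The posterior
bound is a single coronal level expressed as a signed offset along the
AC–PC axis, and the 30 mm lateral bound is a true Euclidean
point-to-plane distance (the source definition does not say whether the
distance is measured in-slice; the perpendicular reading behaves correctly
on tilted grids). The Sylvian fissure + basal cistern has no algorithmic
definition in the reference workflow (it was delineated manually there),
so the partition grows 26-connected components from supplied seed points —
a documented stand-in, not a reimplementation.

## The networks

No deep-learning framework is available in this toolchain, so both
networks are implemented from first principles: compiled direct-loop 3D
convolutions with an im2col-free backward pass, batch normalization, ReLU,
max-pooling, nearest-neighbour upsampling, squeeze-excitation channel
attention, softmax heads, and Adam — with analytic gradients verified
against finite differences in the test suite.

**Segmenter.** A depth-4 U-Net: per level two conv(3³)+BN+ReLU blocks;
2³ max-pooling between encoder levels; the decoder upsamples, applies an
up-convolution block, concatenates the encoder skip, and refines with two
more blocks; a 1³ convolution produces six category scores. Normalization
uses the statistics of the current volume (batch size is one volume), so
inference is deterministic. Channel widths double from `base_channels = 4`
(4-8-16-32). Width 8 works identically on these phantoms at ~4× the
compute; 4 is the desk-scale default. The loss is the smoothed soft Dice
(ε = 1e-4) averaged over the five foreground categories; ε makes an
all-empty category contribute Dice 1 (no penalty) and the empty∩empty
mask comparison well-defined. Training uses Adam at learning rate 1e-2,
one volume per iteration, with on-the-fly rigid + isotropic-scale
augmentation (rotation ±10° per axis, scale 0.9–1.1, translation ±5 mm —
conventional mild ranges; the method description names the transforms but
not their magnitudes) and percentile intensity normalization (clip to the
0.05/0.95 quantiles, rescale to [0, 1]; quantiles use linear
interpolation between order statistics so tests can pin exact values).
The 1e-2 rate was chosen because at this width and batch size 1e-3
demonstrably under-trains within a 300-iteration desk run: gradients are
correct either way (the finite-difference check passes), but the loss
plateau moves by an order of magnitude. The reference regime of ~1,000
repetitions is reachable via `max_iterations`; desk runs default to 300.

**Classifier.** Four separate small networks, one per task, because each
task sees its own input mask: the whole intracranial CSF space for DESH,
ventricles for VD, high-convexity SAS for THC, Sylvian/basal for SFD —
with the mask min-max normalized to [0, 1]. Three conv+BN+ReLU+attention+
pool blocks (4-8-16 channels), global average pooling, then concatenation
with an embedded covariate vector (age standardized by training-split
mean/SD, sex one-hot) and a fully connected head ending in a two-way
softmax; the decision threshold is fixed at probability 0.5. "Self-
attention" is realized as a squeeze-excitation channel-attention block —
the reference names the mechanism without a formula; the block is small,
differentiable and swappable. Training minimizes cross-entropy per task.

## ROC calibration and statistics

The empirical AUC is computed by the rank statistic (ties counted one
half), which the tests verify against an exhaustive concordant-pair count
and against an independent ROC implementation. Candidate thresholds are
the midpoints between consecutive unique sorted scores plus ±∞ sentinels;
the Youden-optimal threshold maximizes sensitivity + specificity, with
ties broken toward the smaller threshold (higher sensitivity) and a
message emitted when a tie occurs. Confidence intervals are seeded
nonparametric percentile bootstraps over subjects (default 2,000
replicates; degenerate single-class resamples are redrawn). The bootstrap
was chosen over DeLong for uniformity: the same machinery covers the AUC,
the threshold, sensitivity and specificity. Pearson correlations use the
standard product-moment estimator with a Fisher-z 95% CI.

Thresholds are always calibrated on the internal-validation split only
and frozen before external evaluation; a test verifies that permuting
external data cannot move them.

## The end-to-end pipeline

`run_end_to_end()` reproduces the study design at desk scale: generate a
cohort → stratified training/internal/external split (largest-remainder
rounding within each class, so split sizes 110/30/19 are reproduced at
n = 159) → obtain label maps (either through the trained U-Net, or the
*oracle pathway* that uses the phantom ground-truth labels directly,
isolating index/ROC correctness from segmentation quality) → landmark
partition → compartment volumes → indices → optional classifier →
threshold calibration on the internal split → external evaluation →
report tables and a provenance record (config, hash, seed, version).
When the U-Net pathway predicts a degenerate empty high-convexity mask,
the index denominator is floored at one voxel volume and the subject is
flagged in the results table rather than aborting the cohort.

All randomness flows from one top-level seed through named substreams
(phantom, augmentation, training, bootstrap), so every pipeline product is
reproducible from `(config, seed)` and changing one stage's consumption
does not perturb the others.

## Problem sizes used by the tests

The shipped suite exercises: oracle equivalence on masks up to 8³ and
cohorts up to 30 subjects; the partition oracle on grids up to 16³;
phantom fidelity at n = 10 (64³, 2.5 mm); segmentation parameter recovery
with 20 training + 8 held-out phantoms at 64³ and 300 iterations;
end-to-end oracle-pathway discrimination at n = 60; and the classifier at
40 training + 20 held-out subjects (32³ at 5 mm) with a label-shuffle
negative control. These sizes are the package's desk-scale defaults;
everything scales up through the run configuration.

## Known limitations

* Schematic geometry: the acceptance surface is volume, topology and
  landmark consistency, not visual realism.
* Landmarks are inputs, not inferences; the Sylvian seed-growth rule is a
  stand-in for manual delineation.
* THC/SFD severity has no quantitative definition in the literature this
  implements; phantom flags are assigned by construction (volume regime)
  and cannot capture expert visual nuance.
* Training determinism is exact in parameter initialization and data
  order; floating-point reduction order in the compiled kernels is fixed
  single-threaded, so repeated runs on one machine are bit-identical, but
  results may differ in the last bits across compilers.
* The published cohort thresholds (e.g. DESH-index 2.563 on T1) are
  statistics of a private cohort; the package reproduces the calibration
  *procedure* and checks the published group means land on the correct
  side of those thresholds, not the thresholds themselves.
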