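# deshkit

Automated volumetric assessment of **disproportionately enlarged
subarachnoid-space hydrocephalus (DESH)** — the imaging hallmark of Hakim
disease (idiopathic normal-pressure hydrocephalus) — from 3D brain MRI.

DESH means the cerebrospinal fluid is redistributed: the ventricles and
Sylvian fissures enlarge while the subarachnoid space (SAS) over the high
convexities is compressed. Radiologists judge this subjectively and often
disagree. `deshkit` is for neuroimaging researchers who want the
assessment quantitative and reproducible. It implements a two-step
pipeline:

1. **Volumetric semantic segmentation** — a 3D U-Net (conv 3³ + batch
   normalization + ReLU, max-pool 2³, up-convolution, skip concatenation)
   trained with the smoothed Dice loss
   `D_c = (2|X∩Y| + ε) / (|X| + |Y| + ε)`, ε = 1e-4, labels each voxel as
   background, parenchyma, total ventricles, Sylvian fissure + basal
   cistern, high-convexity SAS, or other SAS.
2. **Image classification** — a multimodal CNN (conv blocks with channel
   self-attention, global average pooling, an age/sex covariate embedding,
   two-way softmax) makes four binary determinations: DESH, ventricular
   dilatation (VD), tightened high-convexity sulci (THC), Sylvian fissure
   dilatation (SFD), each from its own CSF mask.

The quantitative core is the three dimensionless volume ratios

    Venthi = V_ventricles / V_high-convexity
    Sylhi  = V_sylvian+basal / V_high-convexity
    DESH index = Venthi + Sylhi

with ROC analysis and Youden-optimal thresholds (maximizing
sensitivity + specificity, bootstrap 95% CIs) for detecting DESH, plus
the deterministic anatomical landmark rule that carves the high-convexity
SAS out of a total-SAS mask (above the lateral-ventricle bodies, within
3 cm of the midline, between the genu coronal plane and the
callosomarginal posterior bound, all in world millimetres).

Because the MRI cohorts behind this method are not shareable, the package
includes a first-class **synthetic phantom generator**: six-compartment
cranial geometries with known volumes calibrated to published per-group
means/SDs, landmark sidecars, demographics and phenotype flags, rendered
as CSF-dark (T1-like) or CSF-bright (T2-like) NIfTI volumes. All tests
and the acceptance script run end to end on these phantoms.

## Worked example

Render one DESH phantom, read off its compartment volumes and indices,
then run the oracle-pathway pipeline (ground-truth labels, landmark
partition, indices, ROC calibration) on a small cohort:

```r
library(deshkit)

ph      <- phenotype_flags(desh = TRUE, vd = TRUE, thc = TRUE, sfd = TRUE)
targets <- phenotype_to_targets(ph, age_years = 76, seed = 42)
subject <- render_phantom(phantom_spec(phenotype = ph, targets = targets,
                                       seed = 42),
                          age_years = 76, sex = "male")
round(unlist(subject$true_volumes), 1)
#>   total_ventricles_ml      sylvian_basal_ml high_convexity_sas_ml
#>                 136.6                  84.8                  14.0
#>          other_sas_ml          total_sas_ml   intracranial_csf_ml
#>                 238.9                 337.7                 474.3

ix <- compute_indices(subject$true_volumes)
sprintf("DESH index %.2f = Venthi %.2f + Sylhi %.2f",
        ix$desh_index, ix$venthi_index, ix$sylhi_index)
#> "DESH index 15.80 = Venthi 9.75 + Sylhi 6.05"
```

The ventricles plus Sylvian fissure are ~16× the high-convexity volume —
far above any plausible DESH cut-off (published thresholds on real T1
cohorts sit near 2.6), exactly what a severe DESH phantom should show.

```r
cfg <- load_run_config(NULL)          # documented defaults
cfg$n_subjects  <- 24L; cfg$desh_fraction <- 0.25
cfg$grid_shape  <- c(32L, 32L, 32L);  cfg$voxel_size_mm <- c(5, 5, 5)
cfg$fractions   <- c(0.5, 0.25, 0.25); cfg$n_boot <- 200L; cfg$seed <- 11L
cfg$output_dir  <- tempfile()
report <- run_end_to_end(cfg)
report$roc_table
#>         index auc auc_lo auc_hi threshold sensitivity specificity
#>    desh_index   1      1      1  8.224432           1           1
#>  venthi_index   1      1      1  4.660437           1           1
#>   sylhi_index   1      1      1  3.742614           1           1
```

All three indices separate DESH from non-DESH phantoms perfectly on this
cohort; the thresholds are calibrated on the internal split only and the
external-split sensitivity/specificity (in `report$external_table`) are
evaluated with those frozen thresholds. Swap `cfg$pathway <- "unet"` to
route the same evaluation through the trained segmenter, and
`cfg$run_classifier <- TRUE` to add the four-task CNN.

A thin command-line front end is installed at `inst/cli/deshkit`
(`deshkit generate|run --config run.yaml`).

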