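largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  extra <- round(sum(raw)) - sum(base)
  if (extra > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  as.integer(base)
}

#' Stratified training / internal / external split
#'
#' Splits subjects into training, internal-validation and external
#' (test) sets, stratified by the DESH flag with largest-remainder
#' rounding applied within each class, so the per-split DESH fraction is
#' within one subject of the cohort fraction.
#'
#' @param manifest Cohort manifest data frame (needs a logical `desh`
#'   column), or a `desh_cohort`.
#' @param fractions Three fractions summing to 1 (default c(0.7, 0.15,
#'   0.15)).
#' @param seed Integer seed for the stratified shuffle.
#' @param allow_single_class Waive the both-classes-per-split requirement.
#' @return List of class `desh_split` with `training_ids`,
#'   `internal_validation_ids`, `external_validation_ids` and per-split
#'   DESH counts.
#' @export
make_split <- function(manifest, fractions = c(0.7, 0.15, 0.15), seed = 1L,
                       allow_single_class = FALSE) {
  if (inherits(manifest, "desh_cohort")) manifest <- manifest$manifest
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  desh_ids <- which(manifest$desh)
  ctrl_ids <- which(!manifest$desh)
  alloc <- function(ids) {
    sizes <- largest_remainder(length(ids), fractions)
    ids <- with_seed(substream_seed(seed, "split"),
                     sample(ids, length(ids)))
    split(ids, rep(1:3, times = sizes))
  }
  a <- alloc(desh_ids); b <- alloc(ctrl_ids)
  take <- function(x, i) if (i <= length(x)) x[[as.character(i)]] else integer(0)
  parts <- lapply(1:3, function(i) sort(c(take(a, i), take(b, i))))
  sizes <- lengths(parts)
  if (any(sizes == 0))
    stop("a split would be empty with n = ", nrow(manifest),
         " and fractions ", paste(fractions, collapse = "/"))
  desh_counts <- vapply(parts, function(p) sum(manifest$desh[p]), 0L)
  if (!allow_single_class && any(desh_counts == 0 | desh_counts == sizes))
    stop("a split would be single-class; enlarge the cohort or waive with ",
         "allow_single_class = TRUE")
  structure(list(training_ids = parts[[1]],
                 internal_validation_ids = parts[[2]],
                 external_validation_ids = parts[[3]],
                 desh_counts = desh_counts, sizes = sizes),
            class = "desh_split")
}

#' Calibrate Youden-optimal index thresholds on the internal split
#'
#' Runs [roc_analysis()] for each of the DESH, Venthi and Sylhi indices on
#' internal-validation subjects only; the resulting thresholds are frozen
#' before any external evaluation.
#'
#' @param indices Data frame with columns `desh_index`, `venthi_index`,
#'   `sylhi_index`.
#' @param flags Logical DESH ground truth, aligned with `indices` rows.
#' @param n_boot,seed Passed to [roc_analysis()].
#' @return Named list of `desh_roc` objects (one per index).
#' @export
calibrate_thresholds <- function(indices, flags, n_boot = 500, seed = 1L) {
  lapply(stats::setNames(nm = c("desh_index", "venthi_index", "sylhi_index")),
         function(ix) roc_analysis(indices[[ix]], flags, n_boot = n_boot,
                                   seed = substream_seed(seed, ix)))
}

# Snap each landmark Sylvian seed to the nearest voxel of `mask` (within
# `radius_mm`); drops seeds with no nearby mask voxel. Needed when the mask
# is a network prediction rather than the generator's own geometry.
snap_seeds_to_mask <- function(seeds_mm, mask, voxel_size_mm,
                               origin_mm = c(0, 0, 0), radius_mm = 15) {
  if (is.null(seeds_mm) || !nrow(seeds_mm) || !any(mask)) return(NULL)
  w <- voxel_world_coords(dim(mask), voxel_size_mm, origin_mm)
  xyz <- cbind(w$x[mask], w$y[mask], w$z[mask])
  out <- lapply(seq_len(nrow(seeds_mm)), function(i) {
    d2 <- colSums((t(xyz) - seeds_mm[i, ])^2)
    j <- which.min(d2)
    if (d2[j] <= radius_mm^2) xyz[j, , drop = FALSE] else NULL
  })
  do.call(rbind, out)
}

# Partition a (possibly predicted) label map with the subject's landmarks
# and return compartment volumes; ventricles are taken from the label map,
# the three SAS compartments from the landmark-rule partition.
volumes_via_partition <- function(labelmap, landmarks) {
  cats <- desh_categories()
  sas <- labelmap$data %in% cats[c("sylvian_basal", "high_convexity_sas",
                                   "other_sas")]
  sas <- array(sas, dim(labelmap$data))
  seeds <- snap_seeds_to_mask(landmarks$sylvian_seed_mm,
                              sas & !high_convexity_mask(sas, landmarks,
                                                         labelmap$voxel_size_mm,
                                                         labelmap$origin_mm),
                              labelmap$voxel_size_mm, labelmap$origin_mm)
  part <- partition_sas(sas, seeds, landmarks, labelmap$voxel_size_mm,
                        labelmap$origin_mm)
  combined <- part$data
  combined[labelmap$data == cats[["ventricles"]]] <- cats[["ventricles"]]
  compartment_volumes(desh_labelmap(combined, labelmap$voxel_size_mm,
                                    labelmap$origin_mm))
}

subject_indices <- function(vols, voxel_size_mm) {
  hc <- vols$high_convexity_sas_ml
  floored <- FALSE
  if (hc <= 0) {  # degenerate segmentation: floor at one voxel volume
    hc <- prod(voxel_size_mm) / 1000
    floored <- TRUE
  }
  ix <- compute_indices(list(total_ventricles_ml = vols$total_ventricles_ml,
                             sylvian_basal_ml = vols$sylvian_basal_ml,
                             high_convexity_sas_ml = hc))
  c(unclass(ix), list(hc_floored = floored))
}

#' Run the full two-step study design end to end at desk scale
#'
#' Generates a synthetic cohort, makes the stratified split, obtains a
#' label map per subject (either through the trained U-Net pathway or the
#' oracle pathway that uses the phantom ground-truth labels directly),
#' partitions the subarachnoid space with the landmark rule, computes
#' compartment volumes and the three DESH indices, optionally trains and
#' evaluates the four-task classifier, calibrates Youden thresholds on the
#' internal split only, and evaluates them on the external split. All
#' tables and a provenance record are written under `config$output_dir`.
#'
#' @param config A [load_run_config()] result (or compatible list).
#' @return List of class `desh_report`: `segmentation_table`,
#'   `volume_table`, `index_table`, `roc_table`, `external_table`,
#'   `classification_table` (NULL unless run), `split`, `config`.
#' @export
run_end_to_end <- function(config = load_run_config()) {
  cfg <- config
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_provenance(cfg$output_dir, cfg)
  cohort <- sample_cohort(cfg$n_subjects, cfg$desh_fraction, cfg$contrast,
                          seed = cfg$seed, grid_shape = cfg$grid_shape,
                          voxel_size_mm = cfg$voxel_size_mm,
                          noise_sd = cfg$noise_sd)
  split <- make_split(cohort$manifest, cfg$fractions, seed = cfg$seed)
  eval_ids <- c(split$internal_validation_ids, split$external_validation_ids)

  segmenter <- NULL
  predicted <- vector("list", cfg$n_subjects)
  if (identical(cfg$pathway, "unet")) {
    ucfg <- unet_config(depth = cfg$unet$depth,
                        base_channels = cfg$unet$base_channels,
                        max_iterations = cfg$unet$iterations,
                        learning_rate = cfg$unet$learning_rate,
                        epsilon = cfg$unet$epsilon,
                        augment = cfg$unet$augment,
                        val_every = cfg$unet$val_every,
                        grid_shape = cfg$grid_shape,
                        seed = substream_seed(cfg$seed, "training"))
    segmenter <- train_segmenter(cohort, ucfg,
                                 train_ids = split$training_ids,
                                 val_ids = split$internal_validation_ids)
    write.csv(segmenter$log, file.path(cfg$output_dir, "training_log.csv"),
              row.names = FALSE)
    for (i in eval_ids)
      predicted[[i]] <- segment_volume(segmenter,
                                       percentile_normalize(cohort$subjects[[i]]$volume))
  } else {
    for (i in eval_ids) predicted[[i]] <- cohort$subjects[[i]]$labelmap
  }

  # segmentation quality + volumes on the evaluated subjects
  seg_rows <- list(); vol_rows <- list(); idx_rows <- list()
  for (i in eval_ids) {
    s <- cohort$subjects[[i]]
    ev <- evaluate_segmentation(predicted[[i]], s$labelmap)
    ev$subject <- i
    seg_rows[[length(seg_rows) + 1]] <- ev
    vols <- volumes_via_partition(predicted[[i]], s$landmarks)
    ix <- subject_indices(vols, cfg$voxel_size_mm)
    vol_rows[[length(vol_rows) + 1]] <- data.frame(
      subject = i, desh = s$phenotype$desh,
      split = if (i %in% split$internal_validation_ids) "internal" else "external",
      auto_ventricles_ml = vols$total_ventricles_ml,
      auto_sylvian_basal_ml = vols$sylvian_basal_ml,
      auto_high_convexity_ml = vols$high_convexity_sas_ml,
      auto_other_sas_ml = vols$other_sas_ml,
      true_ventricles_ml = s$true_volumes$total_ventricles_ml,
      true_sylvian_basal_ml = s$true_volumes$sylvian_basal_ml,
      true_high_convexity_ml = s$true_volumes$high_convexity_sas_ml,
      true_other_sas_ml = s$true_volumes$other_sas_ml)
    idx_rows[[length(idx_rows) + 1]] <- data.frame(
      subject = i, desh = s$phenotype$desh,
      split = vol_rows[[length(vol_rows)]]$split,
      desh_index = ix$desh_index, venthi_index = ix$venthi_index,
      sylhi_index = ix$sylhi_index, hc_floored = ix$hc_floored)
  }
  seg_all <- do.call(rbind, seg_rows)
  vol_table <- do.call(rbind, vol_rows)
  idx_table <- do.call(rbind, idx_rows)

  seg_table <- do.call(rbind, lapply(split(seg_all, seg_all$category),
    function(d) data.frame(category = d$category[1],
                           dice_mean = mean(d$dice), dice_sd = sd(d$dice),
                           precision_mean = mean(d$precision),
                           recall_mean = mean(d$recall),
                           volume_diff_ml_mean = mean(d$volume_diff_ml))))
  # volume agreement r per compartment (auto vs truth over evaluated set)
  r_of <- function(a, b) if (sd(b) > 0 && sd(a) > 0)
    pearson_with_ci(a, b)$r else NA_real_
  seg_table$volume_r <- NA_real_
  pairs <- list(ventricles = c("auto_ventricles_ml", "true_ventricles_ml"),
                sylvian_basal = c("auto_sylvian_basal_ml", "true_sylvian_basal_ml"),
                high_convexity_sas = c("auto_high_convexity_ml", "true_high_convexity_ml"),
                other_sas = c("auto_other_sas_ml", "true_other_sas_ml"))
  for (nm in names(pairs))
    seg_table$volume_r[seg_table$category == nm] <-
      r_of(vol_table[[pairs[[nm]][1]]], vol_table[[pairs[[nm]][2]]])

  # threshold calibration strictly on the internal split
  internal <- idx_table[idx_table$split == "internal", ]
  external <- idx_table[idx_table$split == "external", ]
  rocs <- calibrate_thresholds(internal, internal$desh, n_boot = cfg$n_boot,
                               seed = cfg$seed)
  roc_table <- do.call(rbind, lapply(names(rocs), function(nm) {
    r <- rocs[[nm]]
    data.frame(index = nm, auc = r$auc, auc_lo = r$auc_ci[1],
               auc_hi = r$auc_ci[2], threshold = r$threshold,
               sensitivity = r$sensitivity, specificity = r$specificity)
  }))
  ext_eval <- do.call(rbind, lapply(names(rocs), function(nm) {
    thr <- rocs[[nm]]$threshold
    call_pos <- external[[nm]] >= thr
    data.frame(index = nm, threshold = thr,
               sensitivity = sum(call_pos & external$desh) /
                 max(1, sum(external$desh)),
               specificity = sum(!call_pos & !external$desh) /
                 max(1, sum(!external$desh)))
  }))

  clf_table <- NULL
  if (isTRUE(cfg$run_classifier)) {
    ccfg <- classifier_config(channels = cfg$classifier$channels,
                              iterations = cfg$classifier$iterations,
                              learning_rate = cfg$classifier$learning_rate,
                              embed_dim = cfg$classifier$embed_dim,
                              augment = cfg$classifier$augment,
                              seed = substream_seed(cfg$seed, "classifier"))
    clf <- train_classifier(cohort, ccfg, train_ids = split$training_ids)
    ext_ids <- split$external_validation_ids
    results <- lapply(ext_ids, function(i) {
      s <- cohort$subjects[[i]]
      s$labelmap <- predicted[[i]]
      classify_subject(clf, s)
    })
    clf_eval <- evaluate_classification(results,
                                        cohort$manifest[ext_ids, , drop = FALSE])
    clf_table <- clf_eval$summary
    write.csv(clf_table, file.path(cfg$output_dir, "classification.csv"),
              row.names = FALSE)
  }

  write.csv(seg_table, file.path(cfg$output_dir, "segmentation.csv"),
            row.names = FALSE)
  write.csv(vol_table, file.path(cfg$output_dir, "volumes.csv"),
            row.names = FALSE)
  write.csv(idx_table, file.path(cfg$output_dir, "indices.csv"),
            row.names = FALSE)
  write.csv(roc_table, file.path(cfg$output_dir, "roc.csv"),
            row.names = FALSE)
  write.csv(ext_eval, file.path(cfg$output_dir, "external_thresholds.csv"),
            row.names = FALSE)

  structure(list(segmentation_table = seg_table, volume_table = vol_table,
                 index_table = idx_table, roc_table = roc_table,
                 external_table = ext_eval,
                 classification_table = clf_table, split = split,
                 config = cfg, rocs = rocs),
            class = "desh_report")
}

#' @export
print.desh_report <- function(x, ...) {
  cat("<desh_report>\n-- segmentation --\n")
  print(x$segmentation_table, row.names = FALSE)
  cat("-- ROC (internal calibration) --\n")
  print(x$roc_table, row.names = FALSE)
  cat("-- external thresholds --\n")
  print(x$external_table, row.names = FALSE)
  if (!is.null(x$classification_table)) {
    cat("-- classification (external) --\n")
    print(x$classification_table, row.names = FALSE)
  }
  invisible(x)
}
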