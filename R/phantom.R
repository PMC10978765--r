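#' Phenotype flag set
#'
#' DESH is defined as the simultaneous occurrence of Sylvian fissure
#' dilatation (SFD) and tightened high-convexity sulci (THC), so
#' `desh = TRUE` requires `thc` and `sfd`; ventricular dilatation (VD) is a
#' separate flag.
#'
#' @param desh,vd,thc,sfd Logical flags.
#' @return List of class `desh_phenotype`.
#' @export
phenotype_flags <- function(desh = FALSE, vd = FALSE, thc = FALSE,
                            sfd = FALSE) {
  stopifnot(is.logical(desh), is.logical(vd), is.logical(thc), is.logical(sfd))
  if (desh && !(thc && sfd))
    stop("inconsistent phenotype: DESH requires both THC and SFD")
  structure(list(desh = desh, vd = vd, thc = thc, sfd = sfd),
            class = "desh_phenotype")
}

#' Compartment volume calibration table
#'
#' Built-in means and SDs (mL) of the automatically segmented compartment
#' volumes per phenotype group (Hakim disease vs normal) and contrast. The
#' "other SAS" row is derived as total SAS minus the Sylvian/basal and
#' high-convexity parts, with the total-SAS SD carried over.
#'
#' @return Data frame with columns `group`, `contrast`, `compartment`,
#'   `mean_ml`, `sd_ml`.
#' @export
volume_calibration_table <- function() {
  rbind(
    data.frame(group = "hakim", contrast = "T1_like",
               compartment = c("total_ventricles_ml", "sylvian_basal_ml",
                               "high_convexity_sas_ml", "other_sas_ml"),
               mean_ml = c(129.2, 90.2, 17.9, 331.0 - 90.2 - 17.9),
               sd_ml = c(35.1, 12.0, 3.7, 35.7)),
    data.frame(group = "normal", contrast = "T1_like",
               compartment = c("total_ventricles_ml", "sylvian_basal_ml",
                               "high_convexity_sas_ml", "other_sas_ml"),
               mean_ml = c(26.9, 42.9, 42.5, 280.6 - 42.9 - 42.5),
               sd_ml = c(19.4, 10.3, 12.1, 60.6)),
    data.frame(group = "hakim", contrast = "T2_like",
               compartment = c("total_ventricles_ml", "sylvian_basal_ml",
                               "high_convexity_sas_ml", "other_sas_ml"),
               mean_ml = c(150.3, 88.6, 7.3, 288.4 - 88.6 - 7.3),
               sd_ml = c(45.2, 9.0, 4.2, 53.2)),
    data.frame(group = "normal", contrast = "T2_like",
               compartment = c("total_ventricles_ml", "sylvian_basal_ml",
                               "high_convexity_sas_ml", "other_sas_ml"),
               mean_ml = c(25.5, 37.7, 32.2, 218.9 - 37.7 - 32.2),
               sd_ml = c(9.9, 8.9, 12.8, 57.7))
  )
}

# Minimum compartment target: below ~3 mL a compartment degenerates to a
# handful of voxels on the default 2.5 mm grid.
.target_floor_ml <- 3.0

#' Draw compartment volume targets for a phenotype
#'
#' Samples the four compartment targets from the calibration table: DESH
#' phantoms use the Hakim-group statistics, non-DESH phantoms the
#' normal-group statistics; an isolated positive flag in a non-DESH phantom
#' (VD, THC or SFD without DESH) pulls the corresponding single compartment
#' (ventricles, high-convexity SAS, Sylvian/basal) from the Hakim column.
#' Compartments share a per-subject latent severity factor (correlation
#' 0.9): in the Hakim group large ventricles and Sylvian fissures co-occur
#' with a small high-convexity space, while in normals a global atrophy
#' factor enlarges all CSF spaces together, keeping the ratio indices
#' stable. Samples are truncated below at 3 mL and non-DESH ventricular and
#' outer-SAS volumes drift mildly upward with age.
#'
#' @param phenotype A [phenotype_flags()] set.
#' @param age_years Age covariate.
#' @param seed Integer seed; same (phenotype, age, seed) gives identical
#'   targets.
#' @param contrast `"T1_like"` or `"T2_like"` (selects the calibration
#'   column).
#' @return Named list of class `desh_targets` with the four compartment
#'   targets (mL) plus derived `total_sas_ml`.
#' @export
phenotype_to_targets <- function(phenotype, age_years = 70, seed = 1L,
                                 contrast = c("T1_like", "T2_like")) {
  stopifnot(inherits(phenotype, "desh_phenotype"))
  contrast <- match.arg(contrast)
  tab <- volume_calibration_table()
  grp <- if (phenotype$desh) "hakim" else "normal"
  rows <- tab[tab$contrast == contrast, ]
  comp <- c("total_ventricles_ml", "sylvian_basal_ml",
            "high_convexity_sas_ml", "other_sas_ml")
  src <- rep(grp, 4); names(src) <- comp
  if (!phenotype$desh) {
    if (phenotype$vd) src["total_ventricles_ml"] <- "hakim"
    if (phenotype$sfd) src["sylvian_basal_ml"] <- "hakim"
    if (phenotype$thc) src["high_convexity_sas_ml"] <- "hakim"
  }
  rho <- 0.9
  draw <- with_seed(substream_seed(seed, "targets"), {
    s <- rnorm(1)
    e <- rnorm(4)
    vals <- numeric(4); names(vals) <- comp
    for (i in seq_along(comp)) {
      row <- rows[rows$group == src[comp[i]] & rows$compartment == comp[i], ]
      sgn <- if (src[comp[i]] == "hakim" && comp[i] == "high_convexity_sas_ml")
        -1 else 1
      vals[i] <- row$mean_ml + row$sd_ml * (rho * sgn * s +
                                              sqrt(1 - rho^2) * e[i])
    }
    vals
  })
  if (!phenotype$desh) {
    draw["total_ventricles_ml"] <- draw["total_ventricles_ml"] +
      0.2 * (age_years - 55)
    draw["other_sas_ml"] <- draw["other_sas_ml"] + 0.4 * (age_years - 55)
  }
  draw <- pmax(draw, .target_floor_ml)
  structure(c(as.list(draw), list(total_sas_ml = sum(draw[2:4]))),
            class = "desh_targets")
}

#' Phantom specification
#'
#' @param grid_shape Voxel counts per axis (each at least 32).
#' @param voxel_size_mm Spacing (mm), strictly positive.
#' @param phenotype A [phenotype_flags()] set.
#' @param targets A [phenotype_to_targets()] result (or compatible list).
#' @param contrast `"T1_like"` (CSF dark) or `"T2_like"` (CSF bright).
#' @param noise_sd Gaussian intensity noise SD.
#' @param seed Integer seed for the noise substream.
#' @return List of class `desh_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_size_mm = c(2.5, 2.5, 2.5),
                         phenotype = phenotype_flags(),
                         targets = phenotype_to_targets(phenotype),
                         contrast = c("T1_like", "T2_like"),
                         noise_sd = 0.03, seed = 1L) {
  contrast <- match.arg(contrast)
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(grid_shape < 32L)) stop("grid_shape must be at least 32 per axis")
  if (any(voxel_size_mm <= 0)) stop("voxel size must be positive")
  stopifnot(inherits(phenotype, "desh_phenotype"))
  if (any(unlist(targets[c("total_ventricles_ml", "sylvian_basal_ml",
                           "high_convexity_sas_ml", "other_sas_ml")]) <= 0))
    stop("compartment targets must be strictly positive")
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 phenotype = phenotype, targets = targets,
                 contrast = contrast, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "desh_phantom_spec")
}

# Select the n voxels with the smallest field value among the eligible ones;
# returns a logical array. Fails loudly if fewer than n are eligible.
select_smallest <- function(field, eligible, n, what) {
  if (n < 1) stop("target for ", what, " is below one voxel; unachievable")
  idx <- which(eligible)
  if (length(idx) < n)
    stop("target for ", what, " unachievable within the grid (needs ", n,
         " voxels, ", length(idx), " eligible)")
  sel <- idx[order(field[idx])[seq_len(n)]]
  out <- array(FALSE, dim(field))
  out[sel] <- TRUE
  out
}

#' Render a synthetic cranial phantom
#'
#' Builds a schematic six-compartment cranial geometry: paired ellipsoidal
#' lateral ventricles plus a midline third ventricle, two oblique
#' slab-shaped Sylvian fissures joined by a basal cistern, a vertex sheet of
#' high-convexity SAS within 30 mm of the midsagittal plane (cut by the
#' same landmark rule as [high_convexity_mask()]), an outer SAS shell, and
#' parenchyma elsewhere inside a skull ellipsoid. Each compartment is
#' realized by thresholding a continuous shape field at exactly the voxel
#' count matching its target volume, so realized volumes match targets to
#' within one voxel; unachievable targets raise an error. Intensities are
#' CSF-dark for `T1_like`, CSF-bright for `T2_like`, with seeded Gaussian
#' noise. Landmarks (and Sylvian seed points) consistent with the built
#' geometry are emitted.
#'
#' @param spec A [phantom_spec()].
#' @param age_years,sex Demographic covariates stored on the subject.
#' @return List of class `desh_phantom_subject` with `volume`, `labelmap`,
#'   `landmarks`, `age_years`, `sex`, `phenotype` and `true_volumes`
#'   (computed from the label map).
#' @export
render_phantom <- function(spec, age_years = 70, sex = c("female", "male")) {
  stopifnot(inherits(spec, "desh_phantom_spec"))
  sex <- match.arg(sex)
  dims <- spec$grid_shape
  sp <- spec$voxel_size_mm
  vox_ml <- prod(sp) / 1000
  w <- voxel_world_coords(dims, sp, c(0, 0, 0))
  ctr <- sp * (dims - 1) / 2
  fov <- sp * dims
  ax <- 0.42 * fov[1]; ay <- 0.47 * fov[2]; az <- 0.42 * fov[3]
  xs <- w$x - ctr[1]; ys <- w$y - ctr[2]; zs <- w$z - ctr[3]
  s_skull <- (xs / ax)^2 + (ys / ay)^2 + (zs / az)^2
  interior <- s_skull <= 1

  n_target <- function(ml) max(1L, as.integer(round(ml / vox_ml)))
  tg <- spec$targets

  # --- ventricles: union of three ellipsoids grown by a common factor ----
  qv <- function(cx, cy, cz, a, b, c)
    ((xs - cx) / a)^2 + ((ys - cy) / b)^2 + ((zs - cz) / c)^2
  q_vent <- pmin(qv(-14, 0, -5, 13, 30, 15), qv(14, 0, -5, 13, 30, 15),
                 qv(0, 0, -15, 4, 18, 10))
  vent <- select_smallest(q_vent, interior & s_skull <= 0.55,
                          n_target(tg$total_ventricles_ml), "ventricles")

  # --- Sylvian fissure slabs + basal cistern ----------------------------
  # Slabs kept strictly lateral of the 30 mm midline band so the
  # high-convexity landmark rule can never intersect them.
  slab_dist <- function(side) {
    nrm <- c(side * 0.45, 0, 1); nrm <- nrm / sqrt(sum(nrm^2))
    abs((xs - side * 42) * nrm[1] + (ys - 2) * nrm[2] + (zs - 2) * nrm[3])
  }
  syl_region <- interior & s_skull <= 0.62 & !vent &
    abs(ys) <= 32 & zs >= -18 & zs <= 28 & abs(xs) >= 32
  basal_region <- interior & s_skull <= 0.62 & !vent &
    (xs / 30)^2 + (ys / 28)^2 <= 1 & zs <= -22
  d_syl <- pmin(ifelse(xs < 0, slab_dist(-1), slab_dist(1)), Inf)
  f_syl <- ifelse(syl_region, d_syl,
                  ifelse(basal_region, abs(zs + 32) / 0.8, Inf))
  syl <- select_smallest(f_syl, syl_region | basal_region,
                         n_target(tg$sylvian_basal_ml),
                         "sylvian fissure and basal cistern")

  # --- landmarks from the realized ventricles ---------------------------
  vz <- w$z[vent]; vy <- w$y[vent]
  vent_top_z <- if (length(vz)) max(vz) + 0.5 * sp[3] else ctr[3]
  genu_y <- if (length(vy)) max(vy) + 6 else ctr[2] + 25
  ac <- c(ctr[1], ctr[2] + 12, ctr[3] - 10)
  pc <- c(ctr[1], ctr[2] - 12, ctr[3] - 10)
  # one seed per potentially disconnected Sylvian/basal piece, each snapped
  # to the centroid-nearest realized voxel of that piece
  seed_parts <- list(syl & syl_region & xs < 0, syl & syl_region & xs > 0,
                     syl & basal_region)
  seed_pts <- do.call(rbind, lapply(seed_parts, function(part) {
    if (!any(part)) return(NULL)
    xyz <- cbind(w$x[part], w$y[part], w$z[part])
    ctr_p <- colMeans(xyz)
    xyz[which.min(colSums((t(xyz) - ctr_p)^2)), , drop = FALSE]
  }))
  lm <- desh_landmarks(
    ac_mm = ac, pc_mm = pc,
    midsagittal_point_mm = ctr, midsagittal_normal = c(1, 0, 0),
    genu_front_mm = c(ctr[1], genu_y, ctr[3]),
    ventricle_body_top_z_mm = vent_top_z,
    callosomarginal_posterior_mm = -50,
    sylvian_seed_mm = seed_pts)

  # --- high-convexity SAS: vertex shell cut by the landmark rule --------
  rule <- high_convexity_mask(array(TRUE, dims), lm, sp)
  hc_elig <- interior & rule & !vent & !syl & s_skull >= 0.35
  hc <- select_smallest(-s_skull, hc_elig,
                        n_target(tg$high_convexity_sas_ml),
                        "high-convexity SAS")

  # --- other SAS: outer shell elsewhere ---------------------------------
  oth_elig <- interior & !vent & !syl & !hc & !rule
  oth <- select_smallest(-s_skull, oth_elig, n_target(tg$other_sas_ml),
                         "other SAS")

  cats <- desh_categories()
  lab <- array(cats[["background"]], dims)
  lab[interior] <- cats[["parenchyma"]]
  lab[vent] <- cats[["ventricles"]]
  lab[syl] <- cats[["sylvian_basal"]]
  lab[hc] <- cats[["high_convexity_sas"]]
  lab[oth] <- cats[["other_sas"]]

  base <- if (spec$contrast == "T1_like")
    c(0.05, 0.75, 0.15, 0.15, 0.15, 0.15) else
      c(0.05, 0.35, 0.92, 0.92, 0.92, 0.92)
  img <- array(base[lab + 1L], dims)
  noise <- with_seed(substream_seed(spec$seed, "noise"),
                     rnorm(prod(dims), 0, spec$noise_sd))
  img <- img + array(noise, dims)

  labelmap <- desh_labelmap(lab, sp)
  structure(list(volume = desh_volume(img, sp),
                 labelmap = labelmap,
                 landmarks = lm,
                 age_years = age_years, sex = sex,
                 phenotype = spec$phenotype,
                 true_volumes = compartment_volumes(labelmap),
                 spec = spec),
            class = "desh_phantom_subject")
}

#' @export
print.desh_phantom_subject <- function(x, ...) {
  cat(sprintf("<desh_phantom_subject> %s, age %.0f, DESH=%s; vent %.1f mL, hc %.1f mL\n",
              x$sex, x$age_years, x$phenotype$desh,
              x$true_volumes$total_ventricles_ml,
              x$true_volumes$high_convexity_sas_ml))
  invisible(x)
}

truncnorm1 <- function(mean, sd, lo, hi) {
  u <- runif(1, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Generate a synthetic phantom cohort
#'
#' Draws `n` subjects with approximately `n * desh_fraction` DESH-positive
#' phantoms. DESH subjects are older (mirroring the age imbalance of
#' Hakim cohorts); sex is drawn at a fixed male fraction; VD co-occurs with
#' DESH with high probability and isolated flags are rare in the non-DESH
#' group. Everything is reproducible from the top-level seed.
#'
#' @param n Number of subjects.
#' @param desh_fraction Fraction of DESH-positive subjects in \[0, 1\].
#' @param contrast `"T1_like"` or `"T2_like"`.
#' @param seed Top-level integer seed.
#' @param grid_shape,voxel_size_mm,noise_sd Geometry parameters passed to
#'   [phantom_spec()].
#' @param out_dir Optional directory; when given, per-subject NIfTI volumes
#'   and label maps, landmark JSON sidecars and a cohort manifest CSV are
#'   written there.
#' @return List of class `desh_cohort` with `subjects` (list of
#'   [render_phantom()] results) and `manifest` (data frame).
#' @export
sample_cohort <- function(n, desh_fraction = 0.25,
                          contrast = c("T1_like", "T2_like"), seed = 1L,
                          grid_shape = c(64L, 64L, 64L),
                          voxel_size_mm = c(2.5, 2.5, 2.5),
                          noise_sd = 0.03, out_dir = NULL) {
  contrast <- match.arg(contrast)
  stopifnot(n >= 1, desh_fraction >= 0, desh_fraction <= 1)
  n_desh <- as.integer(round(n * desh_fraction))
  warn <- NULL
  if (n_desh == 0L && desh_fraction > 0)
    warn <- "requested DESH fraction rounds to zero DESH subjects"
  plan <- with_seed(substream_seed(seed, "cohort"), {
    desh <- sample(c(rep(TRUE, n_desh), rep(FALSE, n - n_desh)))
    lapply(seq_len(n), function(i) {
      d <- desh[i]
      age <- if (d) truncnorm1(75, 7, 60, 92) else truncnorm1(52, 16, 22, 88)
      sex <- if (runif(1) < 78 / 180) "male" else "female"
      if (d) {
        ph <- phenotype_flags(desh = TRUE, vd = runif(1) < 0.95, thc = TRUE,
                              sfd = TRUE)
      } else {
        ph <- phenotype_flags(desh = FALSE, vd = runif(1) < 0.02,
                              thc = runif(1) < 0.02, sfd = runif(1) < 0.03)
      }
      list(age = age, sex = sex, phenotype = ph)
    })
  })
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    p <- plan[[i]]
    sseed <- substream_seed(seed, paste0("subject-", i))
    tg <- phenotype_to_targets(p$phenotype, p$age, sseed, contrast)
    sp <- phantom_spec(grid_shape, voxel_size_mm, p$phenotype, tg, contrast,
                       noise_sd, sseed)
    subjects[[i]] <- render_phantom(sp, age_years = p$age, sex = p$sex)
  }
  manifest <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- subjects[[i]]
    data.frame(subject_id = sprintf("sub-%03d", i),
               age_years = s$age_years, sex = s$sex,
               desh = s$phenotype$desh, vd = s$phenotype$vd,
               thc = s$phenotype$thc, sfd = s$phenotype$sfd,
               total_ventricles_ml = s$true_volumes$total_ventricles_ml,
               sylvian_basal_ml = s$true_volumes$sylvian_basal_ml,
               high_convexity_sas_ml = s$true_volumes$high_convexity_sas_ml,
               other_sas_ml = s$true_volumes$other_sas_ml,
               total_sas_ml = s$true_volumes$total_sas_ml,
               intracranial_csf_ml = s$true_volumes$intracranial_csf_ml)
  }))
  if (!is.null(warn)) attr(manifest, "warning") <- warn
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    vol_path <- character(n); lab_path <- character(n); lm_path <- character(n)
    for (i in seq_len(n)) {
      id <- manifest$subject_id[i]
      vol_path[i] <- file.path(out_dir, paste0(id, "_vol.nii.gz"))
      lab_path[i] <- file.path(out_dir, paste0(id, "_labels.nii.gz"))
      lm_path[i] <- file.path(out_dir, paste0(id, "_landmarks.json"))
      write_volume(subjects[[i]]$volume, vol_path[i])
      write_labelmap(subjects[[i]]$labelmap, lab_path[i])
      write_landmarks(subjects[[i]]$landmarks, lm_path[i])
    }
    manifest$volume_path <- vol_path
    manifest$labelmap_path <- lab_path
    manifest$landmarks_path <- lm_path
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    if (!is.null(warn))
      writeLines(warn, file.path(out_dir, "manifest-warnings.txt"))
  }
  structure(list(subjects = subjects, manifest = manifest,
                 contrast = contrast, seed = seed),
            class = "desh_cohort")
}
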