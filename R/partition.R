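#' Anatomical landmark set for the subarachnoid-space partition
#'
#' Landmarks, all in world millimetres, that define the high-convexity
#' subarachnoid space: the anterior/posterior commissures (AC/PC) whose line
#' orients the coronal planes, the midsagittal plane (point + unit normal),
#' the front edge of the genu of the corpus callosum (anterior bound), the
#' axial level of the top of the lateral-ventricle bodies (inferior bound)
#' and the posterior bound at the posterior parts of the callosomarginal
#' sulci, expressed as a signed offset along the AC-PC axis from AC
#' (negative = posterior).
#'
#' @param ac_mm,pc_mm 3D points (mm); must differ.
#' @param midsagittal_point_mm Point on the midsagittal plane.
#' @param midsagittal_normal Plane normal (normalized internally).
#' @param genu_front_mm 3D point at the front edge of the genu.
#' @param ventricle_body_top_z_mm Axial (z) level of the ventricle-body top.
#' @param callosomarginal_posterior_mm Signed AC-PC-axis offset (mm) of the
#'   posterior bound, measured from AC.
#' @param sylvian_seed_mm Optional matrix of seed points (rows, mm) inside
#'   the Sylvian fissure / basal cistern, used by [partition_sas()].
#' @return List of class `desh_landmarks`.
#' @export
desh_landmarks <- function(ac_mm, pc_mm, midsagittal_point_mm,
                           midsagittal_normal, genu_front_mm,
                           ventricle_body_top_z_mm,
                           callosomarginal_posterior_mm,
                           sylvian_seed_mm = NULL) {
  ac_mm <- as.numeric(ac_mm); pc_mm <- as.numeric(pc_mm)
  if (sqrt(sum((ac_mm - pc_mm)^2)) < 1e-9)
    stop("degenerate AC-PC line: AC and PC coincide")
  n <- as.numeric(midsagittal_normal)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("midsagittal normal must be nonzero")
  structure(list(ac_mm = ac_mm, pc_mm = pc_mm,
                 midsagittal_point_mm = as.numeric(midsagittal_point_mm),
                 midsagittal_normal = n / nn,
                 genu_front_mm = as.numeric(genu_front_mm),
                 ventricle_body_top_z_mm = as.numeric(ventricle_body_top_z_mm),
                 callosomarginal_posterior_mm = as.numeric(callosomarginal_posterior_mm),
                 sylvian_seed_mm = sylvian_seed_mm),
            class = "desh_landmarks")
}

#' Write / read landmarks as a JSON sidecar
#'
#' @param lm A [desh_landmarks()] object.
#' @param path JSON file path.
#' @return `path` (write) or the landmarks (read).
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "desh_landmarks"))
  jsonlite::write_json(unclass(lm), path, auto_unbox = FALSE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  desh_landmarks(x$ac_mm, x$pc_mm, x$midsagittal_point_mm,
                 x$midsagittal_normal, x$genu_front_mm,
                 x$ventricle_body_top_z_mm, x$callosomarginal_posterior_mm,
                 if (!is.null(x$sylvian_seed_mm))
                   matrix(unlist(x$sylvian_seed_mm), ncol = 3) else NULL)
}

#' High-convexity subarachnoid-space mask by anatomical rule
#'
#' Keeps the subarachnoid-space voxels that satisfy all four landmark
#' predicates defining the high-convexity SAS: (i) superior to the top of
#' the lateral-ventricle bodies; (ii) within `lateral_mm` (3 cm)
#' perpendicular distance of the midsagittal plane; (iii) on or posterior to
#' the coronal plane, perpendicular to the AC-PC line, through the front
#' edge of the genu of the corpus callosum; and (iv) at or anterior to the
#' posterior bound at the callosomarginal sulci. All distances are computed
#' in world millimetres, so anisotropic grids behave correctly.
#'
#' @param sas Binary 3D mask (logical/0-1 array) of the subarachnoid space.
#' @param lm A [desh_landmarks()] set.
#' @param voxel_size_mm Per-axis spacing (mm).
#' @param origin_mm World position of voxel `(0,0,0)`.
#' @param lateral_mm Lateral bound from the midline (default 30 mm).
#' @return Logical 3D array.
#' @export
high_convexity_mask <- function(sas, lm, voxel_size_mm,
                                origin_mm = c(0, 0, 0), lateral_mm = 30) {
  stopifnot(inherits(lm, "desh_landmarks"))
  dims <- dim(sas)
  if (length(dims) != 3) stop("sas must be a 3D mask")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  w <- voxel_world_coords(dims, voxel_size_mm, origin_mm)
  a_hat <- lm$ac_mm - lm$pc_mm
  a_hat <- a_hat / sqrt(sum(a_hat^2))   # unit vector pointing anterior
  n <- lm$midsagittal_normal
  p0 <- lm$midsagittal_point_mm
  # signed coordinate along the AC-PC axis, measured from AC
  t_axis <- (w$x - lm$ac_mm[1]) * a_hat[1] + (w$y - lm$ac_mm[2]) * a_hat[2] +
    (w$z - lm$ac_mm[3]) * a_hat[3]
  t_genu <- sum((lm$genu_front_mm - lm$ac_mm) * a_hat)
  dist_mid <- abs((w$x - p0[1]) * n[1] + (w$y - p0[2]) * n[2] +
                    (w$z - p0[3]) * n[3])
  keep <- (as.logical(sas)) &
    (w$z >= lm$ventricle_body_top_z_mm) &
    (dist_mid <= lateral_mm) &
    (t_axis <= t_genu) &
    (t_axis >= lm$callosomarginal_posterior_mm)
  array(keep, dims)
}

#' Partition a subarachnoid-space mask into its three compartments
#'
#' The high-convexity part is cut out by [high_convexity_mask()]; the
#' Sylvian fissure + basal cistern is the union of 26-connected components
#' of the remaining SAS that contain at least one seed point; everything
#' else becomes "other SAS". The three outputs are disjoint and their union
#' is the input mask. Seeded component growth stands in for the manual
#' Sylvian delineation of the reference workflow, which gives no
#' algorithmic rule.
#'
#' @param sas Binary 3D SAS mask.
#' @param sylvian_seeds Matrix of seed points (rows, world mm) inside the
#'   Sylvian/basal component; defaults to `lm$sylvian_seed_mm`.
#' @param lm A [desh_landmarks()] set.
#' @param voxel_size_mm Per-axis spacing (mm).
#' @param origin_mm World position of voxel `(0,0,0)`.
#' @return A [desh_labelmap()] with codes `sylvian_basal` (3),
#'   `high_convexity_sas` (4), `other_sas` (5) and background 0.
#' @export
partition_sas <- function(sas, sylvian_seeds = NULL, lm, voxel_size_mm,
                          origin_mm = c(0, 0, 0)) {
  dims <- dim(sas)
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (is.null(sylvian_seeds)) sylvian_seeds <- lm$sylvian_seed_mm
  sas <- array(as.logical(sas), dims)
  cats <- desh_categories()
  out <- array(0L, dims)
  if (any(sas)) {
    hc <- high_convexity_mask(sas, lm, voxel_size_mm, origin_mm)
    rest <- sas & !hc
    syl <- array(FALSE, dims)
    if (!is.null(sylvian_seeds) && nrow(sylvian_seeds) > 0) {
      vox <- t(apply(sylvian_seeds, 1, function(p)
        round((p - origin_mm) / voxel_size_mm) + 1))
      for (s in seq_len(nrow(vox))) {
        v <- vox[s, ]
        if (any(v < 1) || any(v > dims))
          stop("sylvian seed ", s, " lies outside the grid")
        if (!rest[v[1], v[2], v[3]])
          stop("sylvian seed ", s, " at voxel (", paste(v - 1, collapse = ","),
               ") lies outside the SAS mask")
      }
      syl <- array(cpp_flood_select(as.vector(rest), as.integer(dims),
                                    matrix(as.integer(vox), ncol = 3)), dims)
    }
    out[syl] <- cats[["sylvian_basal"]]
    out[hc] <- cats[["high_convexity_sas"]]
    out[rest & !syl] <- cats[["other_sas"]]
  }
  desh_labelmap(out, voxel_size_mm, origin_mm)
}

#' Compartment volumes (mL) from a label map
#'
#' `volume(c) = voxel count(c) x voxel volume (mm^3) / 1000`, plus the
#' derived totals: `total_sas_ml = sylvian + high-convexity + other SAS` and
#' `intracranial_csf_ml = total SAS + ventricles`.
#'
#' @param labels A [desh_labelmap()] (or integer array) with codes from
#'   [desh_categories()].
#' @param voxel_size_mm Spacing; taken from the label map when omitted.
#' @return List of class `desh_compartment_volumes`.
#' @export
compartment_volumes <- function(labels, voxel_size_mm = NULL) {
  if (inherits(labels, "desh_labelmap")) {
    if (is.null(voxel_size_mm)) voxel_size_mm <- labels$voxel_size_mm
    arr <- labels$data
  } else arr <- labels
  if (is.null(voxel_size_mm)) stop("voxel_size_mm required for a bare array")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  cats <- desh_categories()
  bad <- setdiff(unique(as.vector(arr)), as.integer(cats))
  if (length(bad))
    stop("unknown label code(s): ", paste(bad, collapse = ", "))
  vox_ml <- prod(voxel_size_mm) / 1000
  count <- function(code) sum(arr == code) * vox_ml
  vent <- count(cats[["ventricles"]])
  syl <- count(cats[["sylvian_basal"]])
  hc <- count(cats[["high_convexity_sas"]])
  oth <- count(cats[["other_sas"]])
  structure(list(total_ventricles_ml = vent, sylvian_basal_ml = syl,
                 high_convexity_sas_ml = hc, other_sas_ml = oth,
                 total_sas_ml = syl + hc + oth,
                 intracranial_csf_ml = syl + hc + oth + vent),
            class = "desh_compartment_volumes")
}
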