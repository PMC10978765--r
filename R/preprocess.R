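#' Percentile intensity normalization
#'
#' Clips the volume to its `p_lo`/`p_hi` quantiles (linear-interpolation
#' order statistics) and rescales to \[0, 1\]:
#' `clip((v - a) / (b - a), 0, 1)` with `a = quantile(v, p_lo)`,
#' `b = quantile(v, p_hi)`. A constant volume (where `a == b`) maps to all
#' zeros. This is the preprocessing applied before semantic segmentation.
#'
#' @param v A [desh_volume()] or numeric array.
#' @param p_lo,p_hi Lower/upper quantile probabilities (defaults 0.05, 0.95).
#' @return Normalized object of the same type as the input.
#' @export
percentile_normalize <- function(v, p_lo = 0.05, p_hi = 0.95) {
  arr <- if (inherits(v, "desh_volume")) v$data else v
  if (any(!is.finite(arr))) stop("intensities must be finite")
  q <- quantile(arr, c(p_lo, p_hi), names = FALSE, type = 7)
  out <- if (q[2] > q[1]) pmin(pmax((arr - q[1]) / (q[2] - q[1]), 0), 1)
         else array(0, dim(arr))
  out <- array(out, dim(arr))
  if (inherits(v, "desh_volume")) { v$data <- out; v } else out
}

#' Min-max intensity normalization
#'
#' `(v - min) / (max - min)`; a constant volume maps to all zeros. This is
#' the preprocessing applied to classifier input masks.
#'
#' @param v A [desh_volume()] or numeric array.
#' @return Normalized object of the same type as the input.
#' @export
minmax_normalize <- function(v) {
  arr <- if (inherits(v, "desh_volume")) v$data else v
  if (any(!is.finite(arr))) stop("intensities must be finite")
  r <- range(arr)
  out <- if (r[2] > r[1]) (arr - r[1]) / (r[2] - r[1]) else array(0, dim(arr))
  out <- array(out, dim(arr))
  if (inherits(v, "desh_volume")) { v$data <- out; v } else out
}

#' Augmentation parameter set
#'
#' Mild rigid + isotropic-scale augmentation ranges used for both deep
#' learning tasks. Magnitudes are conventional defaults (the source method
#' names rotation, scaling and translation but no ranges).
#'
#' @param rotation_deg_range Per-axis rotation interval in degrees
#'   (length-2, default c(-10, 10)).
#' @param scale_range Isotropic scale interval around 1 (default
#'   c(0.9, 1.1)).
#' @param translation_mm_range Per-axis translation interval in mm (default
#'   c(-5, 5)).
#' @param seed Integer seed; the drawn transform is deterministic per seed.
#' @return List of class `desh_augment_params`.
#' @export
augment_params <- function(rotation_deg_range = c(-10, 10),
                           scale_range = c(0.9, 1.1),
                           translation_mm_range = c(-5, 5),
                           seed = 1L) {
  stopifnot(length(rotation_deg_range) == 2, all(is.finite(rotation_deg_range)),
            length(scale_range) == 2, all(scale_range > 0),
            all(is.finite(scale_range)),
            length(translation_mm_range) == 2,
            all(is.finite(translation_mm_range)))
  structure(list(rotation_deg_range = sort(rotation_deg_range),
                 scale_range = sort(scale_range),
                 translation_mm_range = sort(translation_mm_range),
                 seed = as.integer(seed)),
            class = "desh_augment_params")
}

rotation_matrix <- function(angles_rad) {
  ca <- cos(angles_rad); sa <- sin(angles_rad)
  rx <- rbind(c(1, 0, 0), c(0, ca[1], -sa[1]), c(0, sa[1], ca[1]))
  ry <- rbind(c(ca[2], 0, sa[2]), c(0, 1, 0), c(-sa[2], 0, ca[2]))
  rz <- rbind(c(ca[3], -sa[3], 0), c(sa[3], ca[3], 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# 3x4 voxel map (output 0-based index -> input continuous 0-based index) for
# content rotated by R, scaled by s and translated by t (mm) about the grid
# centre.
affine_voxel_map <- function(dims, spacing, origin, R, s, t) {
  centre <- origin + spacing * (dims - 1) / 2
  A <- diag(1 / spacing) %*% t(R) %*% diag(spacing) / s
  b <- (t(R) %*% (origin - centre - t) / s + centre - origin) / spacing
  cbind(A, as.numeric(b))
}

resample_volume_affine <- function(arr, dims, M, nearest = FALSE, fill = 0) {
  out <- cpp_resample_affine(as.numeric(arr), as.integer(dims), M,
                             as.integer(dims), nearest, fill)
  array(out, dims)
}

#' Apply one random rigid + scale augmentation to a volume/label-map pair
#'
#' Draws per-axis rotations, an isotropic scale and per-axis translations
#' uniformly from the parameter ranges (deterministically per
#' `params$seed`) and applies the same spatial transform to both inputs.
#' Intensities are interpolated trilinearly, labels by nearest neighbour so
#' no new codes can appear; voxels sampled from outside the field of view
#' get zero intensity and the background label.
#'
#' @param v A [desh_volume()].
#' @param m A [desh_labelmap()] on the same grid.
#' @param params An [augment_params()] set.
#' @return List with elements `volume` and `labelmap`.
#' @export
augment_pair <- function(v, m, params = augment_params()) {
  stopifnot(inherits(v, "desh_volume"), inherits(m, "desh_labelmap"))
  if (!identical(dim(v$data), dim(m$data)))
    stop("volume and label map must share the same grid")
  draw <- with_seed(params$seed, list(
    rot = runif(3, params$rotation_deg_range[1], params$rotation_deg_range[2]),
    s = runif(1, params$scale_range[1], params$scale_range[2]),
    t = runif(3, params$translation_mm_range[1], params$translation_mm_range[2])
  ))
  R <- rotation_matrix(draw$rot * pi / 180)
  dims <- dim(v$data)
  M <- affine_voxel_map(dims, v$voxel_size_mm, v$origin_mm, R, draw$s, draw$t)
  v$data <- resample_volume_affine(v$data, dims, M, nearest = FALSE, fill = 0)
  lab <- resample_volume_affine(m$data, dims, M, nearest = TRUE, fill = 0)
  m$data <- array(as.integer(round(lab)), dims)
  list(volume = v, labelmap = m)
}
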