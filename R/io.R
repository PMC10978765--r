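#' Fixed CSF compartment label table
#'
#' Integer codes shared by every label map in the package: background (0),
#' brain parenchyma (1), total ventricles (2), Sylvian fissure and basal
#' cistern (3), high-convexity subarachnoid space (4) and the remaining
#' subarachnoid space (5).
#'
#' @return Named integer vector of the six category codes.
#' @export
desh_categories <- function() {
  c(background = 0L, parenchyma = 1L, ventricles = 2L,
    sylvian_basal = 3L, high_convexity_sas = 4L, other_sas = 5L)
}

#' Construct a scalar 3D volume
#'
#' A volume couples a 3D numeric array with its voxel spacing and the world
#' position (mm, RAS-like axes) of voxel `(0,0,0)` (R index `[1,1,1]`).
#'
#' @param data 3D numeric array of intensities.
#' @param voxel_size_mm Per-axis voxel spacing in mm (length 1 or 3).
#' @param origin_mm World coordinates (mm) of the first voxel.
#' @return Object of class `desh_volume`.
#' @export
desh_volume <- function(data, voxel_size_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " dimensions")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0))
    stop("voxel spacing must be strictly positive and finite")
  if (any(!is.finite(data))) stop("volume intensities must be finite")
  structure(list(data = data, voxel_size_mm = voxel_size_mm,
                 origin_mm = rep_len(as.numeric(origin_mm), 3L)),
            class = "desh_volume")
}

#' Construct a categorical label map
#'
#' @param data 3D array of integer category codes.
#' @param voxel_size_mm Per-axis voxel spacing in mm.
#' @param origin_mm World coordinates (mm) of the first voxel.
#' @param categories Ordered integer code list; defaults to
#'   [desh_categories()].
#' @return Object of class `desh_labelmap`.
#' @export
desh_labelmap <- function(data, voxel_size_mm, origin_mm = c(0, 0, 0),
                          categories = desh_categories()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("label data must be a 3D array, got ", length(dim(data)), " dimensions")
  if (!is.integer(data)) {
    rounded <- round(data)
    if (max(abs(data - rounded)) > 1e-6)
      stop("label values are not integers within tolerance 1e-6")
    data <- array(as.integer(rounded), dim = dim(data))
  }
  bad <- setdiff(unique(as.vector(data)), as.integer(categories))
  if (length(bad))
    stop("label codes outside the category table: ", paste(bad, collapse = ", "))
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0))
    stop("voxel spacing must be strictly positive and finite")
  structure(list(data = data, categories = categories,
                 voxel_size_mm = voxel_size_mm,
                 origin_mm = rep_len(as.numeric(origin_mm), 3L)),
            class = "desh_labelmap")
}

#' @export
print.desh_volume <- function(x, ...) {
  cat("<desh_volume> ", paste(dim(x$data), collapse = "x"),
      " voxels @ ", paste(signif(x$voxel_size_mm, 3), collapse = "x"),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.desh_labelmap <- function(x, ...) {
  cat("<desh_labelmap> ", paste(dim(x$data), collapse = "x"),
      " voxels, categories {", paste(x$categories, collapse = ","),
      "} @ ", paste(signif(x$voxel_size_mm, 3), collapse = "x"), " mm\n",
      sep = "")
  invisible(x)
}

make_affine <- function(voxel_size_mm, origin_mm) {
  aff <- diag(c(voxel_size_mm, 1))
  aff[1:3, 4] <- origin_mm
  aff
}

#' Read a 3D volume from a NIfTI file
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a 3D image.
#' @return A [desh_volume()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D image, file has ", length(d), " dimensions: ", path)
  aff <- RNifti::xform(img)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("file carries no usable voxel spacing: ", path)
  desh_volume(array(as.numeric(img), dim = d), spacing, aff[1:3, 4])
}

#' Write a volume as NIfTI-1
#'
#' @param v A [desh_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "desh_volume"))
  arr <- v$data
  attr(arr, "pixdim") <- v$voxel_size_mm
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(make_affine(v$voxel_size_mm,
                                                      v$origin_mm),
                                          code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label map from a NIfTI file
#'
#' Values must be integers within 1e-6 (they are rounded); anything else is
#' an error.
#'
#' @param path Path to the file.
#' @param categories Accepted code table (default [desh_categories()]).
#' @return A [desh_labelmap()].
#' @export
read_labelmap <- function(path, categories = desh_categories()) {
  v <- read_volume(path)
  desh_labelmap(v$data, v$voxel_size_mm, v$origin_mm, categories)
}

#' Write a label map as NIfTI-1 with an integer datatype
#'
#' @param m A [desh_labelmap()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(m, path) {
  stopifnot(inherits(m, "desh_labelmap"))
  arr <- m$data
  attr(arr, "pixdim") <- m$voxel_size_mm
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(make_affine(m$voxel_size_mm,
                                                      m$origin_mm),
                                          code = 2L))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' World coordinates of every voxel centre
#'
#' @param dims Grid shape (3 integers).
#' @param voxel_size_mm Spacing (mm).
#' @param origin_mm World position of voxel `(0,0,0)`.
#' @return List of three arrays (`x`, `y`, `z`) of world mm coordinates.
#' @keywords internal
voxel_world_coords <- function(dims, voxel_size_mm, origin_mm = c(0, 0, 0)) {
  cx <- origin_mm[1] + (seq_len(dims[1]) - 1) * voxel_size_mm[1]
  cy <- origin_mm[2] + (seq_len(dims[2]) - 1) * voxel_size_mm[2]
  cz <- origin_mm[3] + (seq_len(dims[3]) - 1) * voxel_size_mm[3]
  list(x = array(rep(cx, times = dims[2] * dims[3]), dims),
       y = array(rep(rep(cy, each = dims[1]), times = dims[3]), dims),
       z = array(rep(cz, each = dims[1] * dims[2]), dims))
}

# ---- seed policy -----------------------------------------------------------

#' Derive a named substream seed from a top-level seed
#'
#' All randomness in the package flows from one top-level integer seed;
#' independent stages (phantom geometry, augmentation, training, bootstrap)
#' draw from named substreams so that changing one stage's consumption does
#' not perturb the others.
#'
#' @param seed Top-level integer seed.
#' @param name Substream name, e.g. `"phantom"`.
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(as.character(name)))
    h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- run configuration -----------------------------------------------------

default_run_config <- function() {
  list(
    seed = 1L,
    grid_shape = c(64L, 64L, 64L),
    voxel_size_mm = c(2.5, 2.5, 2.5),
    n_subjects = 60L,
    desh_fraction = 0.25,
    contrast = "T1_like",
    noise_sd = 0.03,
    fractions = c(0.7, 0.15, 0.15),
    pathway = "oracle",
    run_classifier = FALSE,
    unet = list(depth = 4L, base_channels = 4L, iterations = 300L,
                learning_rate = 1e-2, epsilon = 1e-4, augment = TRUE,
                val_every = 25L),
    classifier = list(channels = c(4L, 8L, 16L), iterations = 200L,
                      learning_rate = 1e-3, embed_dim = 8L, augment = TRUE),
    augment = list(rotation_deg = 10, scale = c(0.9, 1.1), translation_mm = 5),
    n_boot = 500L,
    output_dir = "deshkit-run"
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s) ", paste0(path, unknown, collapse = ", "),
         "; accepted keys: ", paste0(path, names(defaults), collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) stop("configuration key ", path, k, " must be a mapping")
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    path = paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) document, fills every omitted key with its
#' documented default, and rejects unknown keys. An empty file yields the
#' full default configuration.
#'
#' @param path Path to the configuration file, or `NULL` for pure defaults.
#' @return Validated configuration list with class `desh_config`.
#' @export
load_run_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  cfg <- merge_config(default_run_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  cfg$grid_shape <- as.integer(rep_len(cfg$grid_shape, 3L))
  cfg$voxel_size_mm <- rep_len(as.numeric(cfg$voxel_size_mm), 3L)
  if (abs(sum(cfg$fractions) - 1) > 1e-8)
    stop("split fractions must sum to 1")
  structure(cfg, class = "desh_config")
}

#' Write a provenance record for a pipeline run
#'
#' Records the configuration, its hash, the seed and the package version as
#' JSON so every run is traceable.
#'
#' @param dir Run directory (created if needed).
#' @param config Configuration list.
#' @return Path of the written record, invisibly.
#' @export
write_provenance <- function(dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  txt <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  rec <- list(
    package = "deshkit",
    version = as.character(packageVersion("deshkit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config_hash = sprintf("%08x", sum(utf8ToInt(txt) *
                                        (seq_along(utf8ToInt(txt)) %% 97 + 1)) %% 4294967291),
    config = unclass(config)
  )
  path <- file.path(dir, "provenance.json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
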