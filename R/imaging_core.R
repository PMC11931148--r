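# Core volumetric data model shared by every pipeline stage.
#
# Conventions (fixed package-wide):
#   * world coordinates are RAS millimetres: +x is anatomical right,
#     +y anterior, +z superior;
#   * voxel indices are 1-based in R but map to world space through the
#     affine using 0-based indices, matching the NIfTI standard;
#   * paired images must share grid shape exactly and affines to <= 1e-4
#     per entry -- there is no implicit resampling.

TISSUES <- c("CSF", "GM", "WM", "LESION", "BACKGROUND")
HEMIS   <- c("LEFT", "RIGHT", "MIDLINE", "NA")

#' Construct a 3D intensity volume
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param affine 4x4 voxel-to-world matrix in RAS millimetres; the upper-left
#'   3x3 block must be invertible.
#' @param modality One of `"T1"`, `"FLAIR"`, `"OTHER"`.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, affine = diag(4), modality = c("OTHER", "T1", "FLAIR")) {
  modality <- match.arg(modality)
  if (length(dim(data)) != 3L || any(dim(data) <= 0L))
    stop("expected 3D volume with positive dimensions")
  affine <- .check_affine(affine)
  structure(list(data = data, affine = affine, modality = modality),
            class = "volume3d")
}

.check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  d <- det(affine[1:3, 1:3])
  if (!is.finite(d) || abs(d) < 1e-12) stop("singular affine")
  affine
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d %s  %s  voxel %.4g mL>\n", x$modality,
              paste(dim(x$data), collapse = "x"), voxel_volume_ml(x)))
  invisible(x)
}

#' Construct a label scheme
#'
#' A label scheme declares the integer ids present in a segmentation, their
#' anatomical names, tissue class and hemisphere tag, plus named id groups
#' used for benchmark-style region grouping (e.g. `deep_gm`, `brainstem`).
#'
#' @param entries data.frame with columns `id` (positive integer, unique),
#'   `name` (character), `tissue` (one of CSF, GM, WM, LESION, BACKGROUND),
#'   `hemisphere` (LEFT, RIGHT, MIDLINE, NA).
#' @param groups Named list of integer id vectors; every member must be a
#'   declared id.
#' @return Object of class `label_scheme`.
#' @export
label_scheme <- function(entries, groups = list()) {
  stopifnot(is.data.frame(entries),
            all(c("id", "name", "tissue", "hemisphere") %in% names(entries)))
  entries$id <- as.integer(entries$id)
  if (any(entries$id <= 0L)) stop("label ids must be positive; 0 is background")
  if (anyDuplicated(entries$id)) stop("label ids must be unique")
  if (!all(entries$tissue %in% TISSUES)) stop("unknown tissue class")
  if (!all(entries$hemisphere %in% HEMIS)) stop("unknown hemisphere tag")
  for (g in names(groups)) {
    groups[[g]] <- as.integer(groups[[g]])
    if (!all(groups[[g]] %in% entries$id))
      stop("group '", g, "' references undeclared ids")
  }
  structure(list(entries = entries, groups = groups), class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat(sprintf("<label_scheme  %d labels, %d groups>\n",
              nrow(x$entries), length(x$groups)))
  invisible(x)
}

scheme_ids <- function(scheme) scheme$entries$id

scheme_lookup <- function(scheme, field) {
  stats::setNames(scheme$entries[[field]], scheme$entries$id)
}

#' Ids of a given tissue class in a scheme
#' @param scheme A `label_scheme`.
#' @param tissue Tissue class name.
#' @return Integer vector of ids.
#' @export
tissue_ids <- function(scheme, tissue) {
  scheme$entries$id[scheme$entries$tissue == tissue]
}

#' Construct a 3D label map
#'
#' @param labels 3D array of non-negative integer labels; every nonzero value
#'   must be declared in `scheme`.
#' @param affine 4x4 voxel-to-world matrix.
#' @param scheme A [label_scheme()].
#' @return Object of class `labelmap3d`.
#' @export
labelmap3d <- function(labels, affine = diag(4), scheme) {
  if (length(dim(labels)) != 3L || any(dim(labels) <= 0L))
    stop("expected 3D label array with positive dimensions")
  affine <- .check_affine(affine)
  if (!inherits(scheme, "label_scheme")) stop("scheme must be a label_scheme")
  if (any(labels < 0)) stop("labels must be non-negative")
  present <- unique(as.vector(labels))
  present <- present[present != 0]
  if (!all(present %in% scheme_ids(scheme)))
    stop("label values not declared in scheme: ",
         paste(setdiff(present, scheme_ids(scheme)), collapse = ", "))
  structure(list(labels = labels, affine = affine, scheme = scheme),
            class = "labelmap3d")
}

#' @export
print.labelmap3d <- function(x, ...) {
  cat(sprintf("<labelmap3d  %s  %d declared labels>\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$scheme$entries)))
  invisible(x)
}

#' Check that two images share a grid
#'
#' Shapes must match exactly and affines entrywise to `tol`; the package never
#' resamples implicitly (inputs are assumed co-registered to a common space).
#'
#' @param a,b `volume3d` or `labelmap3d` objects.
#' @param tol Affine entry tolerance.
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
check_same_grid <- function(a, b, tol = 1e-4) {
  da <- .grid_shape(a); db <- .grid_shape(b)
  if (!all(da == db))
    stop("grid shape mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  if (max(abs(a$affine - b$affine)) > tol)
    stop("affine mismatch beyond tolerance ", tol)
  invisible(TRUE)
}

.grid_shape <- function(x) {
  if (inherits(x, "labelmap3d")) dim(x$labels) else dim(x$data)
}

.image_array <- function(x) {
  if (inherits(x, "labelmap3d")) x$labels else x$data
}

# ---------------------------------------------------------------------------
# I/O

#' Read a NIfTI volume
#'
#' @param path Path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param modality Caller-supplied modality tag.
#' @return A [volume3d()].
#' @export
read_volume <- function(path, modality = c("OTHER", "T1", "FLAIR")) {
  modality <- match.arg(modality)
  r <- read_nifti(path)
  volume3d(r$data, r$affine, modality)
}

#' Read a NIfTI label map
#'
#' @param path Path to a NIfTI-1 file holding integer labels.
#' @param scheme A [label_scheme()] declaring the expected ids.
#' @return A [labelmap3d()].
#' @export
read_labelmap <- function(path, scheme) {
  r <- read_nifti(path)
  labels <- round(r$data)
  if (max(abs(r$data - labels)) > 1e-6)
    stop("file does not contain integer labels: ", path)
  labelmap3d(array(as.integer(labels), dim = dim(labels)), r$affine, scheme)
}

#' Write a volume or label map to NIfTI-1
#'
#' Intensity volumes are stored as float64 (lossless round-trip); label maps
#' as int16, which comfortably holds the 22-structure schemes used here.
#'
#' @param vol A `volume3d` or `labelmap3d`.
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "labelmap3d")) {
    write_nifti(vol$labels, vol$affine, path, "int16")
  } else if (inherits(vol, "volume3d")) {
    write_nifti(vol$data, vol$affine, path, "float64")
  } else stop("vol must be a volume3d or labelmap3d")
  invisible(path)
}

#' Voxel volume in millilitres
#'
#' `|det| / 1000` of the affine's upper-left 3x3 block, i.e. the volume of one
#' voxel in mL; invariant under rotation of the grid.
#'
#' @param vol A `volume3d` or `labelmap3d`.
#' @return Scalar voxel volume in mL.
#' @export
voxel_volume_ml <- function(vol) {
  abs(det(vol$affine[1:3, 1:3])) / 1000
}

# ---------------------------------------------------------------------------
# Label grouping

#' Remap labels into named groups
#'
#' Collapses structure-level ids into coarser regions (the benchmark grouping
#' of CSF / GM / WM / deep GM / brainstem / cerebellum, for example). Output
#' ids are the group indices in `grouping` order; voxels whose id belongs to
#' no group become background (0).
#'
#' @param map A [labelmap3d()].
#' @param grouping Named list of id vectors; groups must be disjoint and every
#'   id must exist in the scheme.
#' @return A [labelmap3d()] whose scheme has one entry per group.
#' @export
remap_labels <- function(map, grouping) {
  stopifnot(inherits(map, "labelmap3d"), length(grouping) >= 1L,
            !is.null(names(grouping)))
  all_ids <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(all_ids)) stop("overlapping groups in grouping")
  if (!all(all_ids %in% scheme_ids(map$scheme)))
    stop("grouping references ids absent from scheme")
  lut <- integer(max(scheme_ids(map$scheme)) + 1L)   # index = id + 1
  tis <- scheme_lookup(map$scheme, "tissue")
  g_tissue <- character(length(grouping))
  for (i in seq_along(grouping)) {
    lut[grouping[[i]] + 1L] <- i
    tt <- unique(tis[as.character(grouping[[i]])])
    g_tissue[i] <- if (length(tt) == 1L) tt else "GM"  # mixed groups default GM
  }
  out <- array(lut[map$labels + 1L], dim = dim(map$labels))
  scheme <- label_scheme(data.frame(
    id = seq_along(grouping), name = names(grouping),
    tissue = g_tissue, hemisphere = "NA", stringsAsFactors = FALSE))
  labelmap3d(out, map$affine, scheme)
}

# ---------------------------------------------------------------------------
# Scheme serialization (JSON; see methods vignette for the format decision)

#' Write a label scheme to JSON
#' @param scheme A [label_scheme()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  jsonlite::write_json(list(entries = scheme$entries, groups = scheme$groups),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a label scheme from JSON
#' @param path Path written by [write_scheme()].
#' @return A [label_scheme()].
#' @export
read_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- lapply(as.list(x$groups), as.integer)
  label_scheme(as.data.frame(x$entries), groups)
}

#' Default label scheme for the uCP pipeline
#'
#' Ships the structures named in the method description (thalamus, caudate,
#' putamen, pallidum, cerebellum, brainstem parts, cortical tissue classes)
#' with the standard groupings: `deep_gm` (thalamus + putamen + caudate +
#' pallidum), `brainstem` (midbrain + pons + medulla), `lenticular`
#' (pallidum + putamen), `cerebellum`, and the six-region benchmark grouping
#' accessor via [benchmark_grouping()]. User-overridable; the full structure
#' inventory of a production model would extend this table.
#'
#' @return A [label_scheme()].
#' @export
default_scheme <- function() {
  e <- data.frame(
    id = 1:16,
    name = c("csf", "cortical_gm", "cerebral_wm",
             "thalamus_left", "thalamus_right",
             "caudate_left", "caudate_right",
             "putamen_left", "putamen_right",
             "pallidum_left", "pallidum_right",
             "cerebellum_left", "cerebellum_right",
             "midbrain", "pons", "medulla"),
    tissue = c("CSF", "GM", "WM",
               rep("GM", 8), "GM", "GM", "WM", "WM", "WM"),
    hemisphere = c("NA", "NA", "NA",
                   rep(c("LEFT", "RIGHT"), 5), "MIDLINE", "MIDLINE", "MIDLINE"),
    stringsAsFactors = FALSE)
  label_scheme(e, groups = list(
    deep_gm = 4:11,
    lenticular = 8:11,
    brainstem = 14:16,
    cerebellum = 12:13))
}

#' Benchmark region grouping
#'
#' The six-region grouping used for quantitative benchmarking: CSF, GM, WM,
#' deep GM (thalamus, putamen, caudate, pallidum), brainstem (midbrain, pons,
#' medulla) and cerebellum.
#'
#' @param scheme A [label_scheme()]; must declare groups `deep_gm`,
#'   `brainstem` and `cerebellum`.
#' @return Named list of id vectors suitable for [remap_labels()].
#' @export
benchmark_grouping <- function(scheme = default_scheme()) {
  need <- c("deep_gm", "brainstem", "cerebellum")
  if (!all(need %in% names(scheme$groups)))
    stop("scheme lacks required groups: ",
         paste(setdiff(need, names(scheme$groups)), collapse = ", "))
  grouped <- c(scheme$groups$deep_gm, scheme$groups$brainstem,
               scheme$groups$cerebellum)
  list(
    csf  = setdiff(tissue_ids(scheme, "CSF"), grouped),
    gm   = setdiff(tissue_ids(scheme, "GM"), grouped),
    wm   = setdiff(tissue_ids(scheme, "WM"), grouped),
    deep_gm = scheme$groups$deep_gm,
    brainstem = scheme$groups$brainstem,
    cerebellum = scheme$groups$cerebellum)
}
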