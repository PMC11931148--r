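# Seeded synthetic brain phantom.
#
# The phantom is a stated world standing in for patient data: three nested
# ellipsoid shells (CSF envelope, cortical GM, cerebral WM core), paired deep
# grey structures, cerebellar hemispheres and a three-part brainstem, imaged
# in T1 and FLAIR with Gaussian tissue noise. Contrast orderings reproduce
# what the lesion model and fusion rules rely on: T1 CSF < GM < WM; FLAIR
# CSF < WM < GM with hyperintense lesions above GM. Lesions are spherical
# blobs of two classes (FLAIR hyperintensity, T1/FLAIR-hypointense cavity)
# placed by rejection sampling inside a target tissue and hemisphere. The
# generator emits paired pre-/post-lesion images (the pre-lesion pair plays
# the role of a lesion-filled representation), exact voxel ground truth,
# analytic ellipsoid volumes and a toy lobar/PLIC atlas.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Default deep-structure geometry (mm, RAS)
#'
#' Centers and semi-axes chosen once so that all structures are pairwise
#' disjoint and fully contained in the outer envelope at the default grids;
#' the generator re-verifies disjointness at voxel level on every run.
#'
#' @return data.frame of structure specs (id, name, hemisphere, center, semi).
#' @export
default_structures <- function() {
  s <- function(id, name, hemi, cx, cy, cz, a, b, c)
    data.frame(id = id, name = name, hemisphere = hemi,
               cx = cx, cy = cy, cz = cz, a = a, b = b, c = c,
               stringsAsFactors = FALSE)
  rbind(
    s(4L,  "thalamus_left",   "LEFT",  -11, -14,   2, 8,   10,  7),
    s(5L,  "thalamus_right",  "RIGHT",  11, -14,   2, 8,   10,  7),
    s(6L,  "caudate_left",    "LEFT",  -13,  12,   6, 4.5, 6.5, 5.5),
    s(7L,  "caudate_right",   "RIGHT",  13,  12,   6, 4.5, 6.5, 5.5),
    s(8L,  "putamen_left",    "LEFT",  -28,   4,   0, 5,   8,   6),
    s(9L,  "putamen_right",   "RIGHT",  28,   4,   0, 5,   8,   6),
    s(10L, "pallidum_left",   "LEFT",  -19,   3,   0, 3.8, 5.2, 4.4),
    s(11L, "pallidum_right",  "RIGHT",  19,   3,   0, 3.8, 5.2, 4.4),
    s(12L, "cerebellum_left", "LEFT",  -15, -36, -20, 11,  9,   8),
    s(13L, "cerebellum_right","RIGHT",  15, -36, -20, 11,  9,   8),
    s(14L, "midbrain",        "MIDLINE", 0, -20, -10, 6,   5,   4),
    s(15L, "pons",            "MIDLINE", 0, -24, -22, 7,   6,   5),
    s(16L, "medulla",         "MIDLINE", 0, -28, -34, 5,   5,   6))
}

#' Default tissue intensity model
#'
#' Gaussian mean/SD per tissue and modality, in arbitrary scanner units.
#' FLAIR hyperintensities sit above cortical GM; cavities take CSF-like
#' intensity in both modalities.
#'
#' @return Named list of intensity parameters.
#' @export
default_intensities <- function() {
  list(
    t1    = c(BACKGROUND = 5, CSF = 30, GM = 70, WM = 100),
    flair = c(BACKGROUND = 5, CSF = 20, GM = 90, WM = 70),
    noise_sd = 3,
    hyper_flair = 115,     # above GM (90)
    hyper_t1_delta = -10,  # mild T1 lowering inside hyperintensities
    lesion_sd = 2)
}

#' Lesion specification
#'
#' @param class `"HYPERINTENSITY"` (FLAIR-bright white-matter lesion, e.g.
#'   periventricular leukomalacia) or `"CAVITY"` (T1/FLAIR-hypointense,
#'   CSF-like defect).
#' @param count Number of lesions to place.
#' @param radius_range Min/max radius in mm.
#' @param target_tissue Tissue class the lesion must lie in entirely.
#' @param hemisphere `"LEFT"` or `"RIGHT"`.
#' @return Object of class `lesion_spec`.
#' @export
lesion_spec <- function(class = c("HYPERINTENSITY", "CAVITY"), count = 1L,
                        radius_range = c(3, 6), target_tissue = "WM",
                        hemisphere = c("LEFT", "RIGHT")) {
  class <- match.arg(class)
  hemisphere <- match.arg(hemisphere)
  stopifnot(count >= 1L, length(radius_range) == 2L,
            radius_range[1] > 0, radius_range[1] <= radius_range[2],
            target_tissue %in% TISSUES)
  structure(list(class = class, count = as.integer(count),
                 radius_range = radius_range, target_tissue = target_tissue,
                 hemisphere = hemisphere),
            class = "lesion_spec")
}

#' Phantom configuration
#'
#' Defaults model a child-sized head in a 128 mm field of view. Two stock
#' grids are used throughout the package: `shape = 64, spacing = 2` (fast
#' tests) and `shape = 128, spacing = 1` (acceptance-quality volumetry);
#' `shape = 32, spacing = 4` gives single-patch training subjects.
#'
#' @param shape Grid size per axis (scalar or length-3).
#' @param spacing Isotropic voxel size in mm.
#' @param shells Semi-axes (mm) of the nested CSF/GM/WM ellipsoid shells.
#' @param structures Deep-structure table, see [default_structures()].
#' @param intensities Intensity model, see [default_intensities()].
#' @param lesions List of [lesion_spec()]s; default: three left-hemisphere WM
#'   FLAIR hyperintensities and one left-hemisphere WM cavity, emulating the
#'   unilateral lesion load of the target population.
#' @param shrink_side,shrink_factor Optional hemispheric volume loss:
#'   structures tagged to `shrink_side` are scaled about their centroids by
#'   `shrink_factor` (0 < factor <= 1) along all axes.
#' @param seed Integer seed; the phantom is fully deterministic given it.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(shape = 64L, spacing = 2,
                           shells = list(csf = c(50, 60, 50),
                                         gm  = c(44, 54, 44),
                                         wm  = c(36, 46, 36)),
                           structures = default_structures(),
                           intensities = default_intensities(),
                           lesions = list(
                             lesion_spec("HYPERINTENSITY", count = 3L,
                                         radius_range = c(3, 6),
                                         target_tissue = "WM",
                                         hemisphere = "LEFT"),
                             lesion_spec("CAVITY", count = 1L,
                                         radius_range = c(4, 7),
                                         target_tissue = "WM",
                                         hemisphere = "LEFT")),
                           shrink_side = NULL, shrink_factor = 1,
                           seed = 1L) {
  if (length(shape) == 1L) shape <- rep(as.integer(shape), 3L)
  stopifnot(length(shape) == 3L, all(shape > 0L), spacing > 0,
            all(c("csf", "gm", "wm") %in% names(shells)),
            shrink_factor > 0, shrink_factor <= 1)
  if (!all(shells$csf > shells$gm) || !all(shells$gm > shells$wm))
    stop("shells must be strictly nested (csf > gm > wm semi-axes)")
  if (!is.null(shrink_side)) shrink_side <- match.arg(shrink_side, c("LEFT", "RIGHT"))
  structure(list(shape = shape, spacing = spacing, shells = shells,
                 structures = structures, intensities = intensities,
                 lesions = lesions, shrink_side = shrink_side,
                 shrink_factor = shrink_factor, seed = as.integer(seed)),
            class = "phantom_config")
}

.phantom_affine <- function(shape, spacing) {
  affine <- diag(c(spacing, spacing, spacing, 1))
  affine[1:3, 4] <- -(shape - 1) / 2 * spacing   # world origin at grid center
  affine
}

.world_axes <- function(shape, spacing) {
  orig <- -(shape - 1) / 2 * spacing
  list(x = orig[1] + spacing * (seq_len(shape[1]) - 1),
       y = orig[2] + spacing * (seq_len(shape[2]) - 1),
       z = orig[3] + spacing * (seq_len(shape[3]) - 1))
}

.ellipsoid_mask <- function(ax, center, semi) {
  nx <- ((ax$x - center[1]) / semi[1])^2
  ny <- ((ax$y - center[2]) / semi[2])^2
  nz <- ((ax$z - center[3]) / semi[3])^2
  outer(outer(nx, ny, "+"), nz, "+") <= 1
}

.structures_effective <- function(config) {
  st <- config$structures
  if (!is.null(config$shrink_side) && config$shrink_factor < 1) {
    sel <- st$hemisphere == config$shrink_side
    st[sel, c("a", "b", "c")] <- st[sel, c("a", "b", "c")] * config$shrink_factor
  }
  st
}

#' Generate a synthetic brain phantom
#'
#' Builds the label map, paired pre-/post-lesion T1 and FLAIR images, lesion
#' masks per class, analytic region volumes and the toy atlas. Deterministic
#' given `config$seed`.
#'
#' @param config A [phantom_config()].
#' @return Object of class `phantom_truth` with fields `t1_prelesion`,
#'   `flair_prelesion`, `t1`, `flair`, `labels`, `lesion_masks`,
#'   `analytic_volumes` (mL), `atlas`, `scheme`, `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  .with_seed(config$seed, {
    shape <- config$shape
    affine <- .phantom_affine(shape, config$spacing)
    ax <- .world_axes(shape, config$spacing)
    scheme <- default_scheme()

    labels <- array(0L, dim = shape)
    labels[.ellipsoid_mask(ax, c(0, 0, 0), config$shells$csf)] <- 1L  # csf
    labels[.ellipsoid_mask(ax, c(0, 0, 0), config$shells$gm)]  <- 2L  # cortical gm
    labels[.ellipsoid_mask(ax, c(0, 0, 0), config$shells$wm)]  <- 3L  # cerebral wm

    st <- .structures_effective(config)
    owner <- array(0L, dim = shape)
    collisions <- character(0)
    for (i in seq_len(nrow(st))) {
      m <- .ellipsoid_mask(ax, c(st$cx[i], st$cy[i], st$cz[i]),
                           c(st$a[i], st$b[i], st$c[i]))
      clash <- unique(owner[m & owner != 0L])
      if (length(clash))
        collisions <- c(collisions, paste0(
          st$name[i], " overlaps ",
          paste(st$name[match(clash, st$id)], collapse = ", ")))
      owner[m] <- st$id[i]
      labels[m] <- st$id[i]
    }
    if (length(collisions))
      stop("overlapping deep structures: ", paste(collisions, collapse = "; "))

    tis_of <- scheme_lookup(scheme, "tissue")
    tissue_vox <- array("BACKGROUND", dim = shape)
    nz <- labels != 0L
    tissue_vox[nz] <- tis_of[as.character(labels[nz])]

    inten <- config$intensities
    t1_mean <- array(inten$t1[tissue_vox], dim = shape)
    fl_mean <- array(inten$flair[tissue_vox], dim = shape)
    n <- prod(shape)
    t1_pre <- t1_mean + array(stats::rnorm(n, 0, inten$noise_sd), dim = shape)
    fl_pre <- fl_mean + array(stats::rnorm(n, 0, inten$noise_sd), dim = shape)

    vol_ml <- function(a, b, c) 4 / 3 * pi * a * b * c / 1000
    analytic <- stats::setNames(vol_ml(st$a, st$b, st$c), st$name)

    phantom <- structure(list(
      t1_prelesion = volume3d(t1_pre, affine, "T1"),
      flair_prelesion = volume3d(fl_pre, affine, "FLAIR"),
      t1 = volume3d(t1_pre, affine, "T1"),
      flair = volume3d(fl_pre, affine, "FLAIR"),
      labels = labelmap3d(labels, affine, scheme),
      lesion_masks = list(),
      analytic_volumes = analytic,
      atlas = NULL, scheme = scheme, config = config), class = "phantom_truth")
    phantom$atlas <- toy_atlas(phantom)
    if (length(config$lesions))
      phantom <- insert_lesions(phantom, config$lesions,
                                seed = config$seed + 104729L)
    phantom
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  nles <- sum(vapply(x$lesion_masks, sum, numeric(1)))
  cat(sprintf("<phantom_truth  %s @ %g mm  %d lesion voxels>\n",
              paste(dim(x$labels$labels), collapse = "x"),
              x$config$spacing, nles))
  invisible(x)
}

.hemi_of_x <- function(wx) {
  ifelse(wx > 0, "RIGHT", ifelse(wx < 0, "LEFT", "MIDLINE"))
}

#' Insert lesions into a phantom
#'
#' Each lesion is a sphere placed by rejection sampling (at most 1000 tries)
#' so that every voxel of the sphere lies in the target tissue and requested
#' hemisphere and is not already lesioned. `HYPERINTENSITY` raises FLAIR
#' intensity above cortical GM and mildly lowers T1; `CAVITY` sets both
#' modalities to CSF-like intensity. Ground-truth structural labels are left
#' unchanged: lesions overlay tissue, and masks are recorded per class.
#'
#' @param phantom A `phantom_truth`.
#' @param specs List of [lesion_spec()]s.
#' @param seed Integer seed for placement and lesion noise.
#' @return The modified `phantom_truth`.
#' @export
insert_lesions <- function(phantom, specs, seed = 1L) {
  stopifnot(inherits(phantom, "phantom_truth"))
  if (inherits(specs, "lesion_spec")) specs <- list(specs)
  .with_seed(seed, {
    shape <- dim(phantom$labels$labels)
    ax <- .world_axes(shape, phantom$config$spacing)
    scheme <- phantom$scheme
    tis_of <- scheme_lookup(scheme, "tissue")
    labels <- phantom$labels$labels
    tissue_vox <- array("BACKGROUND", dim = shape)
    nz <- labels != 0L
    tissue_vox[nz] <- tis_of[as.character(labels[nz])]
    wx <- array(ax$x, dim = shape)   # world x varies along dim 1
    hemi_vox <- .hemi_of_x(wx)

    lesioned <- Reduce(`|`, phantom$lesion_masks,
                       accumulate = FALSE) %||% array(FALSE, dim = shape)
    t1 <- phantom$t1$data
    fl <- phantom$flair$data
    inten <- phantom$config$intensities
    masks <- phantom$lesion_masks

    for (spec in specs) {
      cls <- spec$class
      if (is.null(masks[[cls]])) masks[[cls]] <- array(FALSE, dim = shape)
      eligible0 <- tissue_vox == spec$target_tissue & hemi_vox == spec$hemisphere
      for (k in seq_len(spec$count)) {
        placed <- FALSE
        for (try in seq_len(1000L)) {
          r <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
          cand <- which(eligible0 & !lesioned)
          if (!length(cand)) break
          ctr_idx <- arrayInd(sample(cand, 1L), shape)
          ctr <- c(ax$x[ctr_idx[1]], ax$y[ctr_idx[2]], ax$z[ctr_idx[3]])
          ball <- .ellipsoid_mask(ax, ctr, c(r, r, r))
          if (!any(ball)) next
          if (all(eligible0[ball] & !lesioned[ball])) {
            nb <- sum(ball)
            if (cls == "HYPERINTENSITY") {
              fl[ball] <- inten$hyper_flair +
                stats::rnorm(nb, 0, inten$lesion_sd)
              t1[ball] <- t1[ball] + inten$hyper_t1_delta
            } else {
              t1[ball] <- inten$t1[["CSF"]] + stats::rnorm(nb, 0, inten$lesion_sd)
              fl[ball] <- inten$flair[["CSF"]] + stats::rnorm(nb, 0, inten$lesion_sd)
            }
            masks[[cls]] <- masks[[cls]] | ball
            lesioned <- lesioned | ball
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not place ", cls, " lesion in ", spec$target_tissue,
               " (", spec$hemisphere, ") after 1000 tries")
      }
    }
    phantom$t1$data <- t1
    phantom$flair$data <- fl
    phantom$lesion_masks <- masks
    phantom
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shrink one hemisphere's structures
#'
#' Emulates affected-hemisphere volume loss: structures tagged to `side` are
#' scaled about their centroids by `factor` along all axes, so analytic
#' volumes scale by `factor^3`. The phantom is regenerated from its config
#' with the same seed (midline shells are untouched).
#'
#' @param phantom A `phantom_truth`.
#' @param side `"LEFT"` or `"RIGHT"`.
#' @param factor Scale factor in (0, 1].
#' @return A new `phantom_truth`.
#' @export
shrink_hemisphere <- function(phantom, side = c("LEFT", "RIGHT"), factor) {
  side <- match.arg(side)
  if (factor <= 0 || factor > 1) stop("shrink factor must be in (0, 1]")
  if (factor == 1) return(phantom)
  cfg <- phantom$config
  cfg$shrink_side <- side
  cfg$shrink_factor <- factor
  generate_phantom(cfg)
}

#' Toy lobar/PLIC atlas
#'
#' Splits the brain bounding box into four equal-width slabs per hemisphere
#' along the anterior-posterior axis (frontal, parietal, temporal, occipital
#' from anterior to posterior) and adds a small PLIC box per side spanning
#' the gap between the thalamus and pallidum specs. Territories are disjoint
#' by construction (PLIC is carved out of the slabs) and jointly cover the
#' bounding box, hence every foreground voxel.
#'
#' @param phantom A `phantom_truth`.
#' @return A [labelmap3d()] whose scheme names the ten territories.
#' @export
toy_atlas <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_truth"))
  labels <- phantom$labels$labels
  shape <- dim(labels)
  ax <- .world_axes(shape, phantom$config$spacing)
  fg <- labels != 0L
  fg_idx <- which(fg, arr.ind = TRUE)
  ybounds <- range(ax$y[fg_idx[, 2]])
  # four equal-width slabs, anterior (large y) to posterior
  edges <- seq(ybounds[2], ybounds[1], length.out = 5L)
  lobes <- c("frontal", "parietal", "temporal", "occipital")
  wy <- array(rep(ax$y, each = shape[1]), dim = shape)
  wx <- array(ax$x, dim = shape)
  terr <- array(0L, dim = shape)
  for (i in 1:4) {
    in_slab <- if (i == 1) wy <= edges[1] & wy >= edges[2] else
      wy < edges[i] & wy >= edges[i + 1]
    terr[in_slab & wx < 0] <- i                # left slabs: ids 1..4
    terr[in_slab & wx >= 0] <- i + 4L          # right slabs: ids 5..8
  }
  # PLIC boxes between thalamus and pallidum
  st <- .structures_effective(phantom$config)
  wz <- array(rep(ax$z, each = shape[1] * shape[2]), dim = shape)
  for (side in c("left", "right")) {
    thal <- st[st$name == paste0("thalamus_", side), ]
    pall <- st[st$name == paste0("pallidum_", side), ]
    if (!nrow(thal) || !nrow(pall)) next
    xr <- sort(c(thal$cx, pall$cx))
    yc <- mean(c(thal$cy, pall$cy)); zc <- mean(c(thal$cz, pall$cz))
    box <- wx >= xr[1] & wx <= xr[2] &
      wy >= yc - 4 & wy <= yc + 4 & wz >= zc - 4 & wz <= zc + 4
    terr[box] <- if (side == "left") 9L else 10L
  }
  scheme <- label_scheme(data.frame(
    id = 1:10,
    name = c(paste0(lobes, "_left"), paste0(lobes, "_right"),
             "plic_left", "plic_right"),
    tissue = "WM",
    hemisphere = c(rep("LEFT", 4), rep("RIGHT", 4), "LEFT", "RIGHT"),
    stringsAsFactors = FALSE))
  labelmap3d(terr, phantom$labels$affine, scheme)
}

#' Write a phantom to a directory
#'
#' Emits the NIfTI image set, lesion masks, ground-truth labels, toy atlas,
#' analytic volumes (JSON) and the label scheme (JSON).
#'
#' @param phantom A `phantom_truth`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(phantom$t1, file.path(dir, "t1.nii.gz"))
  write_volume(phantom$flair, file.path(dir, "flair.nii.gz"))
  write_volume(phantom$t1_prelesion, file.path(dir, "t1_prelesion.nii.gz"))
  write_volume(phantom$flair_prelesion, file.path(dir, "flair_prelesion.nii.gz"))
  write_volume(phantom$labels, file.path(dir, "labels.nii.gz"))
  write_volume(phantom$atlas, file.path(dir, "atlas.nii.gz"))
  for (cls in names(phantom$lesion_masks)) {
    m <- labelmap3d(array(as.integer(phantom$lesion_masks[[cls]]),
                          dim = dim(phantom$lesion_masks[[cls]])),
                    phantom$labels$affine, .binary_scheme())
    write_volume(m, file.path(dir, paste0("lesions_", tolower(cls), ".nii.gz")))
  }
  jsonlite::write_json(as.list(phantom$analytic_volumes),
                       file.path(dir, "analytic_volumes.json"),
                       auto_unbox = TRUE, digits = NA)
  write_scheme(phantom$scheme, file.path(dir, "scheme.json"))
  invisible(dir)
}

.binary_scheme <- function() {
  label_scheme(data.frame(id = 1L, name = "mask", tissue = "LESION",
                          hemisphere = "NA", stringsAsFactors = FALSE))
}
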