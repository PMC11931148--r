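# Regional volumetry: total / lesion / lesion-free volumes per region
# (lesion-free = total - lesion, evaluated per region), geometric hemisphere
# splitting, affected-vs-less-affected relative asymmetry, and atlas-guided
# labelling of WM lobes and the PLIC.

#' Hemisphere assignment from the clinical side
#'
#' In unilateral cerebral palsy the affected hemisphere is the one
#' contralateral to the clinical side (the body side with predominant motor
#' impairment).
#'
#' @param clinical_side `"LEFT"` or `"RIGHT"` (body side).
#' @return List with `clinical_side` and `affected_hemisphere`.
#' @export
hemisphere_assignment <- function(clinical_side = c("LEFT", "RIGHT")) {
  clinical_side <- match.arg(clinical_side)
  structure(list(clinical_side = clinical_side,
                 affected_hemisphere = if (clinical_side == "LEFT") "RIGHT" else "LEFT"),
            class = "hemisphere_assignment")
}

#' Per-region volumes in mL
#'
#' Voxel count times voxel volume for every declared label id (regions absent
#' from the image report 0).
#'
#' @param labels A [labelmap3d()].
#' @return Named numeric vector (region name -> mL).
#' @export
region_volumes <- function(labels) {
  stopifnot(inherits(labels, "labelmap3d"))
  vv <- voxel_volume_ml(labels)
  ids <- scheme_ids(labels$scheme)
  counts <- tabulate(labels$labels, nbins = max(ids))[ids]
  stats::setNames(counts * vv, labels$scheme$entries$name)
}

#' Lesion-free volume report
#'
#' For every region: total volume, lesion volume (intersection of the region
#' with the union of the lesion masks) and the lesion-free volume
#' `total - lesion`. Lesion voxels falling on background are excluded from
#' every region with a warning.
#'
#' @param labels A [labelmap3d()].
#' @param lesion_masks Binary 3D array, or list of binary arrays (one per
#'   lesion class), sharing the grid; `NULL` means no lesions.
#' @return A `volume_report` data.frame with columns `region`, `hemisphere`,
#'   `total_ml`, `lesion_ml`, `lesion_free_ml`.
#' @export
lesion_free_volumes <- function(labels, lesion_masks = NULL) {
  stopifnot(inherits(labels, "labelmap3d"))
  vv <- voxel_volume_ml(labels)
  if (is.null(lesion_masks)) {
    union_mask <- array(FALSE, dim = dim(labels$labels))
  } else {
    if (!is.list(lesion_masks)) lesion_masks <- list(lesion_masks)
    lesion_masks <- lapply(lesion_masks, function(m) {
      if (is.list(m) && !is.null(m$labels)) m <- m$labels
      if (!all(dim(m) == dim(labels$labels)))
        stop("lesion mask grid mismatch")
      array(as.logical(m), dim = dim(m))
    })
    union_mask <- Reduce(`|`, lesion_masks)
  }
  if (any(union_mask & labels$labels == 0L))
    warning("lesion voxels on background are excluded from all regions")
  ids <- scheme_ids(labels$scheme)
  nb <- max(ids)
  total <- tabulate(labels$labels, nbins = nb)[ids] * vv
  lesion <- tabulate(labels$labels[union_mask], nbins = nb)[ids] * vv
  rep_ <- data.frame(region = labels$scheme$entries$name,
                     hemisphere = labels$scheme$entries$hemisphere,
                     total_ml = total, lesion_ml = lesion,
                     lesion_free_ml = total - lesion,
                     stringsAsFactors = FALSE)
  class(rep_) <- c("volume_report", "data.frame")
  rep_
}

#' Split bilateral regions into hemispheres
#'
#' Regions whose scheme entry carries no hemisphere tag are split by the sign
#' of each voxel's world x coordinate (x > 0 is anatomical right under the
#' RAS convention); voxels exactly on x = 0 become a MIDLINE region and are
#' counted in neither hemisphere. Structures already tagged LEFT/RIGHT/
#' MIDLINE keep their id and tag.
#'
#' @param labels A [labelmap3d()] with an RAS affine.
#' @return A [labelmap3d()] whose scheme tags every region.
#' @export
split_hemispheres <- function(labels) {
  stopifnot(inherits(labels, "labelmap3d"))
  entries <- labels$scheme$entries
  d <- dim(labels$labels)
  # world x of each voxel center (0-based indices through the affine)
  ii <- arrayInd(seq_len(prod(d)), d) - 1L
  wx <- labels$affine[1, 1] * ii[, 1] + labels$affine[1, 2] * ii[, 2] +
    labels$affine[1, 3] * ii[, 3] + labels$affine[1, 4]
  wx <- array(wx, dim = d)

  next_id <- max(entries$id) + 1L
  out <- labels$labels
  new_entries <- entries[entries$hemisphere != "NA", , drop = FALSE]
  for (k in which(entries$hemisphere == "NA")) {
    id <- entries$id[k]
    sel <- labels$labels == id
    for (side in c("LEFT", "RIGHT", "MIDLINE")) {
      sub <- switch(side, LEFT = sel & wx < 0, RIGHT = sel & wx > 0,
                    MIDLINE = sel & wx == 0)
      out[sub] <- next_id
      new_entries <- rbind(new_entries, data.frame(
        id = next_id,
        name = paste0(entries$name[k], "_", tolower(side)),
        tissue = entries$tissue[k], hemisphere = side,
        stringsAsFactors = FALSE))
      next_id <- next_id + 1L
    }
  }
  new_entries <- new_entries[order(new_entries$id), ]
  labelmap3d(out, labels$affine, label_scheme(new_entries))
}

#' Relative hemispheric asymmetry per region
#'
#' For every region present in both hemispheres, the relative difference
#' between the affected and less-affected lesion-free volumes:
#' `100 * (V_affected - V_less) / mean(V_affected, V_less)` (the symmetric
#' lateralization form, bounded in +/-200%). Negative values mean lower
#' volume in the affected hemisphere. Regions that are zero in both
#' hemispheres report `NA`.
#'
#' @param report A `volume_report` from [lesion_free_volumes()], with
#'   hemisphere-tagged rows (see [split_hemispheres()]).
#' @param assignment A [hemisphere_assignment()].
#' @param denominator `"mean"` (default) or `"less_affected"`.
#' @return data.frame with columns `region`, `affected_ml`,
#'   `less_affected_ml`, `asymmetry_pct`.
#' @export
relative_asymmetry <- function(report, assignment,
                               denominator = c("mean", "less_affected")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(report, "volume_report"),
            inherits(assignment, "hemisphere_assignment"))
  lateral <- report[report$hemisphere %in% c("LEFT", "RIGHT"), , drop = FALSE]
  base <- sub("_(left|right)$", "", lateral$region)
  aff_side <- assignment$affected_hemisphere
  rows <- lapply(unique(base), function(bn) {
    sub <- lateral[base == bn, , drop = FALSE]
    if (!all(c("LEFT", "RIGHT") %in% sub$hemisphere))
      stop("region '", bn, "' is missing one hemisphere")
    va <- sub$lesion_free_ml[sub$hemisphere == aff_side]
    vl <- sub$lesion_free_ml[sub$hemisphere != aff_side]
    den <- if (denominator == "mean") mean(c(va, vl)) else vl
    asym <- if (va == 0 && vl == 0) NA_real_ else 100 * (va - vl) / den
    data.frame(region = bn, affected_ml = va, less_affected_ml = vl,
               asymmetry_pct = asym, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Atlas-guided WM-lobe and PLIC labelling
#'
#' Intersects the WM mask with the atlas territories to produce lobar WM and
#' PLIC labels, and the cortical GM mask with the lobar territories for lobar
#' CGM; voxels of either mask outside every territory keep a generic WM/CGM
#' id. PLIC territories apply to WM only.
#'
#' @param wm_mask,cgm_mask Binary 3D arrays on the atlas grid.
#' @param atlas A [labelmap3d()] whose scheme names lobar territories and
#'   (optionally) `plic_left`/`plic_right` boxes.
#' @return A [labelmap3d()] with `wm_*`, `cgm_*`, `plic_*`, `generic_wm`
#'   and `generic_cgm` regions.
#' @export
atlas_postprocess <- function(wm_mask, cgm_mask, atlas) {
  stopifnot(inherits(atlas, "labelmap3d"))
  if (!all(dim(wm_mask) == dim(atlas$labels)) ||
      !all(dim(cgm_mask) == dim(atlas$labels)))
    stop("mask grid mismatch with atlas")
  wm_mask <- array(as.logical(wm_mask), dim = dim(wm_mask))
  cgm_mask <- array(as.logical(cgm_mask), dim = dim(cgm_mask))
  if (any(wm_mask & cgm_mask)) stop("wm and cgm masks overlap")
  terr <- atlas$scheme$entries
  is_plic <- grepl("^plic", terr$name)

  entries <- list(); out <- array(0L, dim = dim(wm_mask))
  next_id <- 1L
  add_entry <- function(name, tissue, hemi) {
    entries[[length(entries) + 1L]] <<- data.frame(
      id = next_id, name = name, tissue = tissue, hemisphere = hemi,
      stringsAsFactors = FALSE)
    id <- next_id
    next_id <<- next_id + 1L
    id
  }
  for (k in seq_len(nrow(terr))) {
    tmask <- atlas$labels == terr$id[k]
    if (is_plic[k]) {
      id <- add_entry(terr$name[k], "WM", terr$hemisphere[k])
      out[tmask & wm_mask] <- id
    } else {
      idw <- add_entry(paste0("wm_", terr$name[k]), "WM", terr$hemisphere[k])
      out[tmask & wm_mask] <- idw
      idc <- add_entry(paste0("cgm_", terr$name[k]), "GM", terr$hemisphere[k])
      out[tmask & cgm_mask] <- idc
    }
  }
  idw0 <- add_entry("generic_wm", "WM", "NA")
  out[wm_mask & out == 0L] <- idw0
  idc0 <- add_entry("generic_cgm", "GM", "NA")
  out[cgm_mask & out == 0L] <- idc0
  labelmap3d(out, atlas$affine, label_scheme(do.call(rbind, entries)))
}

#' Write a volume report
#'
#' @param report A `volume_report`.
#' @param path Output path; `.csv` or `.json` by extension.
#' @return `path`, invisibly.
#' @export
write_volume_report <- function(report, path) {
  stopifnot(inherits(report, "volume_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}
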