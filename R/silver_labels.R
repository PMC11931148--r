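# Silver ground-truth generation: merge a lesion-affected segmentation and a
# lesion-filled segmentation inside a dilated manual lesion mask, using the
# T1 intensity distribution of CSF to decide which voxels have become
# fluid-like. Three rules, applied per voxel:
#   1. outside the dilated lesion mask: keep the lesion-affected label;
#   2. inside the mask, T1 within the CSF intensity window: label as CSF;
#   3. inside the mask, T1 outside the window: take the lesion-filled label
#      (background there falls back to CSF -- cavity interiors are fluid).

#' Fusion parameters
#'
#' @param dilation_radius_voxels Number of 26-connected dilation passes
#'   applied to the manual lesion mask (default 1).
#' @param csf_low_pct,csf_high_pct Percentile window of CSF T1 intensity
#'   (defaults 1 and 95); the window test is inclusive on both ends.
#' @param csf_fallback_label Label id to use for rule-3 background voxels;
#'   `NULL` picks the first CSF-tissue id of the lesion-affected scheme.
#' @return Object of class `fusion_params`.
#' @export
fusion_params <- function(dilation_radius_voxels = 1L, csf_low_pct = 1,
                          csf_high_pct = 95, csf_fallback_label = NULL) {
  stopifnot(dilation_radius_voxels >= 0L,
            csf_low_pct >= 0, csf_low_pct < csf_high_pct, csf_high_pct <= 100)
  structure(list(dilation_radius_voxels = as.integer(dilation_radius_voxels),
                 csf_low_pct = csf_low_pct, csf_high_pct = csf_high_pct,
                 csf_fallback_label = csf_fallback_label),
            class = "fusion_params")
}

#' Morphological dilation of a binary mask
#'
#' 26-connected (3x3x3 box) dilation applied `radius` times, i.e. the set of
#' voxels within Chebyshev distance `radius` of the input mask. Radius 0
#' returns the mask unchanged.
#'
#' @param mask 3D logical/0-1 array.
#' @param radius Non-negative integer.
#' @return 3D logical array.
#' @export
dilate_mask <- function(mask, radius = 1L) {
  if (is.list(mask) && !is.null(mask$labels)) mask <- mask$labels
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    stop("dilate_mask expects a binary mask")
  m <- array(as.logical(mask), dim = dim(mask))
  if (radius == 0L) return(m)
  d <- dim(m)
  for (r in seq_len(radius)) {
    out <- m
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      sx <- .shift_idx(d[1], dx); sy <- .shift_idx(d[2], dy); sz <- .shift_idx(d[3], dz)
      shifted <- array(FALSE, dim = d)
      shifted[sx$dst, sy$dst, sz$dst] <- m[sx$src, sy$src, sz$src]
      out <- out | shifted
    }
    m <- out
  }
  m
}

.shift_idx <- function(n, delta) {
  # destination/source index ranges for shifting a vector by `delta`
  if (delta >= 0) list(dst = seq(1 + delta, n), src = seq(1, n - delta))
  else list(dst = seq(1, n + delta), src = seq(1 - delta, n))
}

#' CSF intensity window from a lesion-affected segmentation
#'
#' Percentiles (linear interpolation) of T1 intensity over all voxels whose
#' tissue class is CSF in the lesion-affected segmentation.
#'
#' @param t1 A [volume3d()].
#' @param lesion_affected A [labelmap3d()] sharing the grid.
#' @param params [fusion_params()].
#' @return Numeric `c(low, high)`.
#' @export
csf_intensity_range <- function(t1, lesion_affected,
                                params = fusion_params()) {
  check_same_grid(t1, lesion_affected)
  csf_ids <- tissue_ids(lesion_affected$scheme, "CSF")
  sel <- lesion_affected$labels %in% csf_ids
  if (!any(sel)) stop("no CSF voxels in lesion-affected segmentation")
  vals <- t1$data[sel]
  c(low = .pctl(vals, params$csf_low_pct),
    high = .pctl(vals, params$csf_high_pct))
}

#' Fuse a silver ground truth
#'
#' Applies the three fusion rules (see module header) to produce training
#' labels from a lesion-affected segmentation, a lesion-filled segmentation
#' and a manual lesion mask.
#'
#' @param lesion_affected [labelmap3d()] of the lesioned image.
#' @param lesion_filled [labelmap3d()] of the lesion-filled representation.
#' @param lesion_mask Binary 3D array (or binary [labelmap3d()]) of the
#'   manual lesion annotation.
#' @param t1 [volume3d()], the lesioned T1 image.
#' @param params [fusion_params()].
#' @return Fused [labelmap3d()] on the lesion-affected scheme.
#' @export
fuse_silver_gt <- function(lesion_affected, lesion_filled, lesion_mask, t1,
                           params = fusion_params()) {
  check_same_grid(lesion_affected, lesion_filled)
  check_same_grid(lesion_affected, t1)
  if (is.list(lesion_mask) && !is.null(lesion_mask$labels))
    lesion_mask <- lesion_mask$labels
  if (!all(dim(lesion_mask) == dim(lesion_affected$labels)))
    stop("grid shape mismatch between lesion mask and segmentations")
  csf_ids <- tissue_ids(lesion_affected$scheme, "CSF")
  if (!length(csf_ids)) stop("lesion-affected scheme declares no CSF class")
  csf_id <- params$csf_fallback_label %||% csf_ids[1]

  out <- lesion_affected$labels
  if (any(lesion_mask != 0)) {
    dil <- dilate_mask(lesion_mask, params$dilation_radius_voxels)
    rng <- csf_intensity_range(t1, lesion_affected, params)
    inside <- which(dil)
    t1_in <- t1$data[inside]
    is_csf <- t1_in >= rng[1] & t1_in <= rng[2]
    filled <- lesion_filled$labels[inside]
    filled[filled == 0L] <- csf_id
    out[inside] <- ifelse(is_csf, csf_id, filled)
  }
  labelmap3d(array(as.integer(out), dim = dim(out)),
             lesion_affected$affine, lesion_affected$scheme)
}
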