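# Segmentation evaluation: overlap metrics (Dice, 95th-percentile Hausdorff
# surface distance in mm) over the six-region benchmark grouping, and the
# defect-severity / review-status protocol as deterministic classifiers.

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`: 0 for no overlap, 1 for perfect agreement.
#' Two empty masks score 1 by convention; one empty mask scores 0.
#'
#' @param a,b Binary 3D arrays (or binary [labelmap3d()]s) on one grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- .as_binary(a); b <- .as_binary(b)
  if (!all(dim(a) == dim(b))) stop("grid mismatch")
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) return(1.0)
  2 * sum(a & b) / (na + nb)
}

.as_binary <- function(m) {
  if (is.list(m) && !is.null(m$labels)) m <- m$labels
  array(as.logical(m), dim = dim(m))
}

#' Surface voxels of a binary mask
#'
#' Mask voxels with at least one 6-connected background neighbour; voxels on
#' the array boundary count as surface (outside the grid is background).
#'
#' @param mask Binary 3D array.
#' @return Logical 3D array marking the surface.
#' @export
surface_voxels <- function(mask) {
  m <- .as_binary(mask)
  d <- dim(m)
  n_nb <- array(0L, dim = d)
  for (axis in 1:3) for (delta in c(-1L, 1L)) {
    nb <- array(FALSE, dim = d)
    s <- .shift_idx(d[axis], delta)
    if (axis == 1) nb[s$dst, , ] <- m[s$src, , ]
    if (axis == 2) nb[, s$dst, ] <- m[, s$src, ]
    if (axis == 3) nb[, , s$dst] <- m[, , s$src]
    n_nb <- n_nb + nb
  }
  m & n_nb < 6L
}

.surface_coords_mm <- function(mask, spacing) {
  idx <- which(surface_voxels(mask), arr.ind = TRUE)
  sweep(idx, 2, spacing, "*")
}

# directed nearest-surface distances from each row of A to the set B (mm)
.directed_surface_dists <- function(A, B, chunk = 512L) {
  nb2 <- rowSums(B^2)
  out <- numeric(nrow(A))
  for (start in seq(1L, nrow(A), by = chunk)) {
    ii <- start:min(start + chunk - 1L, nrow(A))
    Ac <- A[ii, , drop = FALSE]
    D2 <- outer(rowSums(Ac^2), nb2, "+") - 2 * tcrossprod(Ac, B)
    out[ii] <- sqrt(pmax(0, apply(D2, 1, min)))
  }
  out
}

#' 95th-percentile Hausdorff surface distance
#'
#' Maximum of the two directed distances, each being the 95th percentile
#' (linear interpolation) of Euclidean distances from one mask's surface
#' voxels to the other's surface, in millimetres.
#'
#' @param a,b Non-empty binary 3D arrays on one grid.
#' @param spacing Voxel spacing in mm (scalar or length 3).
#' @param percentile Percentile of the directed distance distribution
#'   (default 95; 100 gives the classical Hausdorff distance).
#' @return Distance in mm.
#' @export
hausdorff95 <- function(a, b, spacing = 1, percentile = 95) {
  a <- .as_binary(a); b <- .as_binary(b)
  if (!all(dim(a) == dim(b))) stop("grid mismatch")
  if (sum(a) == 0 || sum(b) == 0) stop("empty mask")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  Sa <- .surface_coords_mm(a, spacing)
  Sb <- .surface_coords_mm(b, spacing)
  dab <- .pctl(.directed_surface_dists(Sa, Sb), percentile)
  dba <- .pctl(.directed_surface_dists(Sb, Sa), percentile)
  max(dab, dba)
}

#' Benchmark-grouped overlap metrics
#'
#' Remaps prediction and truth with a region grouping (by default the
#' six-region benchmark grouping: CSF, GM, WM, deep GM, brainstem,
#' cerebellum) and reports Dice and HD95 per group. Groups absent from the
#' truth are flagged `missing` with `NA` metrics.
#'
#' @param pred,truth [labelmap3d()]s on one grid with compatible schemes.
#' @param grouping Named list of id vectors (see [benchmark_grouping()]).
#' @return data.frame with columns `region`, `dice`, `hd95_mm`, `missing`.
#' @export
grouped_benchmark_metrics <- function(pred, truth,
                                      grouping = benchmark_grouping(truth$scheme)) {
  check_same_grid(pred, truth)
  rp <- remap_labels(pred, grouping)
  rt <- remap_labels(truth, grouping)
  spacing <- sqrt(colSums(truth$affine[1:3, 1:3]^2))
  rows <- lapply(seq_along(grouping), function(i) {
    tmask <- rt$labels == i
    if (!any(tmask))
      return(data.frame(region = names(grouping)[i], dice = NA_real_,
                        hd95_mm = NA_real_, missing = TRUE))
    pmask <- rp$labels == i
    d <- dice_coefficient(pmask, tmask)
    h <- if (any(pmask)) hausdorff95(pmask, tmask, spacing) else NA_real_
    data.frame(region = names(grouping)[i], dice = d, hd95_mm = h,
               missing = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify a parcellation defect by its volume fraction
#'
#' Defects (unlabeled or erroneously labeled voxels within a region) are
#' minor up to 10% of the region volume, intermediate above 10% and up to
#' 25%, and major above 25%.
#'
#' @param fraction Defect volume fraction in `[0, 1]` (vectorized).
#' @return Character vector: `"MINOR"`, `"INTERMEDIATE"` or `"MAJOR"`.
#' @export
classify_defect <- function(fraction) {
  if (any(fraction < 0 | fraction > 1)) stop("fraction must be in [0, 1]")
  ifelse(fraction <= 0.10, "MINOR",
         ifelse(fraction <= 0.25, "INTERMEDIATE", "MAJOR"))
}

#' Review status from a list of defects
#'
#' Rejected: one or more major defects, or more than three intermediate.
#' Approved with remarks: up to three intermediate defects, or more than
#' three minor. Approved: at most three minor defects and nothing worse.
#'
#' @param severities Character vector of defect severities (possibly empty).
#' @return `"APPROVED"`, `"APPROVED_WITH_REMARKS"` or `"REJECTED"`.
#' @export
review_status <- function(severities) {
  stopifnot(all(severities %in% c("MINOR", "INTERMEDIATE", "MAJOR")))
  n_major <- sum(severities == "MAJOR")
  n_inter <- sum(severities == "INTERMEDIATE")
  n_minor <- sum(severities == "MINOR")
  if (n_major >= 1L || n_inter > 3L) return("REJECTED")
  if (n_inter >= 1L || n_minor > 3L) return("APPROVED_WITH_REMARKS")
  "APPROVED"
}

#' Defect assessment for a region
#'
#' Convenience wrapper: classifies each defect fraction, counts severities
#' and derives the review status.
#'
#' @param region Region name.
#' @param defect_fractions Numeric vector of per-defect volume fractions.
#' @return List with `region`, `severities`, `counts`, `status`.
#' @export
defect_assessment <- function(region, defect_fractions) {
  sev <- if (length(defect_fractions)) classify_defect(defect_fractions)
  else character(0)
  counts <- c(MINOR = sum(sev == "MINOR"),
              INTERMEDIATE = sum(sev == "INTERMEDIATE"),
              MAJOR = sum(sev == "MAJOR"))
  list(region = region, severities = sev, counts = counts,
       status = review_status(sev))
}
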