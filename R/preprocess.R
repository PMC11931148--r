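# Intensity normalization applied before segmentation: percentile clipping
# followed by a robust variant of z-scoring. The combination makes the
# normalized image invariant (to numerical precision) under positive affine
# rescalings of the raw intensities, which is what absorbs scanner-to-scanner
# intensity variability on co-registered data.

#' Normalization parameters
#'
#' @param clip_low_pct,clip_high_pct Clipping percentiles (defaults 1 and 99).
#' @param center_floor_pct The centering statistic is the median of voxels
#'   strictly above this percentile (default 10); using the median rather
#'   than the mean keeps the center robust to residual outliers.
#' @param spread_range Two percentiles bounding the voxels used for the
#'   spread (standard deviation); default `c(5, 95)`, i.e. the central 90%
#'   of intensities. Set to `c(0, 90)` for the "below the 90th percentile"
#'   reading (both are defensible; see the methods vignette).
#' @return Object of class `normalization_params`.
#' @export
normalization_params <- function(clip_low_pct = 1, clip_high_pct = 99,
                                 center_floor_pct = 10,
                                 spread_range = c(5, 95)) {
  stopifnot(clip_low_pct >= 0, clip_low_pct < clip_high_pct,
            clip_high_pct <= 100,
            center_floor_pct >= 0, center_floor_pct <= 100,
            length(spread_range) == 2L,
            spread_range[1] >= 0, spread_range[1] < spread_range[2],
            spread_range[2] <= 100)
  structure(list(clip_low_pct = clip_low_pct, clip_high_pct = clip_high_pct,
                 center_floor_pct = center_floor_pct,
                 spread_range = spread_range),
            class = "normalization_params")
}

# Percentiles are linear interpolation between order statistics throughout
# the package (stats::quantile type 7), fixed so independent oracles agree.
.pctl <- function(x, p) {
  stats::quantile(x, p / 100, type = 7, names = FALSE)
}

#' Clip intensities at low/high percentiles
#'
#' Clamps the volume to its own 1st and 99th percentile values (by default),
#' mitigating the impact of intensity outliers; interior values are unchanged.
#' A constant image is returned unchanged with a warning.
#'
#' @param vol A [volume3d()].
#' @param params [normalization_params()].
#' @return A clipped [volume3d()].
#' @export
clip_intensities <- function(vol, params = normalization_params()) {
  stopifnot(inherits(vol, "volume3d"))
  x <- vol$data
  lo <- .pctl(x, params$clip_low_pct)
  hi <- .pctl(x, params$clip_high_pct)
  if (lo == hi) {
    warning("constant image: percentile clipping is a no-op")
    return(vol)
  }
  vol$data <- array(pmin(pmax(x, lo), hi), dim = dim(x))
  vol
}

#' Robust z-scoring statistics
#'
#' Center `c` = median of voxels strictly above the `center_floor_pct`
#' percentile; spread `s` = standard deviation of voxels inside the
#' `spread_range` percentile band (inclusive).
#'
#' @param x Numeric vector of intensities.
#' @param params [normalization_params()].
#' @return Named list `list(center, spread)`.
#' @export
robust_zscore_stats <- function(x, params = normalization_params()) {
  floor_val <- .pctl(x, params$center_floor_pct)
  above <- x[x > floor_val]
  if (length(above) == 0L) stop("degenerate intensity distribution")
  ctr <- stats::median(above)
  lo <- .pctl(x, params$spread_range[1])
  hi <- .pctl(x, params$spread_range[2])
  band <- x[x >= lo & x <= hi]
  s <- stats::sd(band)
  if (!is.finite(s) || s == 0) stop("degenerate intensity distribution")
  list(center = ctr, spread = s)
}

#' Robust z-score a volume
#'
#' Applies `(x - c) / s` to every voxel, with `c` and `s` from
#' [robust_zscore_stats()]. The transform is monotone and equivariant under
#' positive affine rescaling of the input.
#'
#' @param vol A [volume3d()] (normally already clipped).
#' @param params [normalization_params()].
#' @return Normalized [volume3d()].
#' @export
robust_zscore <- function(vol, params = normalization_params()) {
  stopifnot(inherits(vol, "volume3d"))
  st <- robust_zscore_stats(as.vector(vol$data), params)
  vol$data <- (vol$data - st$center) / st$spread
  vol
}

#' Full intensity normalization
#'
#' Percentile clipping composed with robust z-scoring; modality tag is
#' preserved.
#'
#' @param vol A [volume3d()].
#' @param params [normalization_params()].
#' @return Normalized [volume3d()].
#' @export
normalize_volume <- function(vol, params = normalization_params()) {
  robust_zscore(clip_intensities(vol, params), params)
}
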