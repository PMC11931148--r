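# Shared fixtures and independent oracle implementations used across tests.
# Oracles deliberately use different code paths (explicit sorting, loops,
# full outer-product matrices) from the package implementations they check.

# small phantoms are reused across files; built once per test session
.fixture_env <- new.env(parent = emptyenv())

small_phantom <- function(seed = 1L, lesions = TRUE) {
  key <- paste0("p", seed, "_", lesions)
  if (is.null(.fixture_env[[key]])) {
    cfg <- phantom_config(shape = 32L, spacing = 4, seed = seed,
                          lesions = if (lesions) list(
                            lesion_spec("HYPERINTENSITY", count = 2L,
                                        radius_range = c(4, 7),
                                        hemisphere = "LEFT"),
                            lesion_spec("CAVITY", count = 1L,
                                        radius_range = c(5, 8),
                                        hemisphere = "LEFT")) else list())
    .fixture_env[[key]] <- generate_phantom(cfg)
  }
  .fixture_env[[key]]
}

# percentile by explicit sort + linear interpolation (type-7 convention),
# written independently of stats::quantile
oracle_pctl <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# per-voxel three-branch reference for silver ground-truth fusion
oracle_fuse <- function(affected, filled, lesion_mask, t1, params) {
  dil <- dilate_mask(lesion_mask, params$dilation_radius_voxels)
  csf_ids <- affected$scheme$entries$id[affected$scheme$entries$tissue == "CSF"]
  csf_vals <- t1$data[affected$labels %in% csf_ids]
  lo <- oracle_pctl(csf_vals, params$csf_low_pct)
  hi <- oracle_pctl(csf_vals, params$csf_high_pct)
  csf_id <- csf_ids[1]
  d <- dim(affected$labels)
  out <- array(0L, dim = d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!dil[i, j, k]) {
      out[i, j, k] <- affected$labels[i, j, k]
    } else if (t1$data[i, j, k] >= lo && t1$data[i, j, k] <= hi) {
      out[i, j, k] <- csf_id
    } else {
      v <- filled$labels[i, j, k]
      out[i, j, k] <- if (v == 0L) csf_id else v
    }
  }
  out
}

# all-pairs surface-distance HD via full outer coordinate matrices
oracle_hd95 <- function(a, b, spacing, percentile = 95) {
  surf <- function(m) {
    d <- dim(m)
    out <- array(FALSE, dim = d)
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      if (!m[i, j, k]) next
      nb <- c(
        if (i > 1) m[i - 1, j, k] else FALSE,
        if (i < d[1]) m[i + 1, j, k] else FALSE,
        if (j > 1) m[i, j - 1, k] else FALSE,
        if (j < d[2]) m[i, j + 1, k] else FALSE,
        if (k > 1) m[i, j, k - 1] else FALSE,
        if (k < d[3]) m[i, j, k + 1] else FALSE)
      if (any(!nb)) out[i, j, k] <- TRUE
    }
    out
  }
  A <- which(surf(a), arr.ind = TRUE)
  B <- which(surf(b), arr.ind = TRUE)
  Ax <- A[, 1] * spacing[1]; Ay <- A[, 2] * spacing[2]; Az <- A[, 3] * spacing[3]
  Bx <- B[, 1] * spacing[1]; By <- B[, 2] * spacing[2]; Bz <- B[, 3] * spacing[3]
  D <- sqrt(outer(Ax, Bx, "-")^2 + outer(Ay, By, "-")^2 + outer(Az, Bz, "-")^2)
  dab <- oracle_pctl(apply(D, 1, min), percentile)
  dba <- oracle_pctl(apply(D, 2, min), percentile)
  max(dab, dba)
}

# random blob-ish sparse mask for metric tests
random_mask <- function(shape = c(16L, 16L, 16L), n_seeds = 3L, radius = 3) {
  m <- array(FALSE, dim = shape)
  for (s in seq_len(n_seeds)) {
    ctr <- runif(3, 3, shape - 2)
    r <- runif(1, 1.2, radius)
    for (k in seq_len(shape[3])) for (j in seq_len(shape[2])) {
      i <- seq_len(shape[1])
      m[, j, k] <- m[, j, k] |
        ((i - ctr[1])^2 + (j - ctr[2])^2 + (k - ctr[3])^2 <= r^2)
    }
  }
  m
}

# tissue grouping used to train/test tissue-level models
tissue_grouping <- function(scheme = default_scheme()) {
  list(csf = tissue_ids(scheme, "CSF"),
       gm = tissue_ids(scheme, "GM"),
       wm = tissue_ids(scheme, "WM"))
}
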