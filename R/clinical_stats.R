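# Clinical validation statistics: Spearman rank correlation with bootstrap
# percentile confidence intervals, Mann-Whitney U (min convention, exact null
# distribution for small tie-free samples), Wilcoxon signed-rank, the
# two-way random-effects average-measures absolute-agreement ICC, and
# significance-star tabulation over volume/score tables. Exact null
# distributions are built by dynamic programming; the test suite checks them
# against exhaustive enumeration.

#' Spearman's rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero rank variance: correlation undefined")
  stats::cor(rx, ry)
}

# two-sided p for Spearman via the t approximation (used for tabulation;
# the headline inference object is the bootstrap CI)
.spearman_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Bootstrap percentile confidence interval
#'
#' Resamples rows of `data` with replacement and returns the percentile
#' interval of `stat` over the resamples. Reproducible under `seed`;
#' resamples on which `stat` errors are dropped, and more than 50%
#' undefined is an error.
#'
#' @param stat Function of a data object (same type as `data`) returning a
#'   scalar.
#' @param data data.frame/matrix (resampled by rows) or vector.
#' @param n_boot Number of resamples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(stat, data, n_boot = 10000L, level = 0.95,
                         seed = 1L) {
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  if (n < 3L) stop("need at least 3 rows")
  .with_seed(seed, {
    vals <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      d <- if (is.null(dim(data))) data[idx] else data[idx, , drop = FALSE]
      tryCatch(as.numeric(stat(d)), error = function(e) NA_real_)
    }, numeric(1))
    if (mean(is.na(vals)) > 0.5)
      stop("statistic undefined on more than half of the resamples")
    vals <- vals[!is.na(vals)]
    alpha <- (1 - level) / 2
    c(low = .pctl(vals, 100 * alpha), high = .pctl(vals, 100 * (1 - alpha)))
  })
}

# exact null counts of the Mann-Whitney U_x statistic for sample sizes n, m
# (tie-free): f(n, m, u) = f(n-1, m, u-m) + f(n, m-1, u), memoized
.mwu_null_counts <- local({
  memo <- new.env(parent = emptyenv())
  function(n, m) {
    key <- paste(n, m)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (n == 0L || m == 0L) {
      res <- 1
    } else {
      a <- Recall(n - 1L, m)   # counts over u = 0..(n-1)m
      b <- Recall(n, m - 1L)   # counts over u = 0..n(m-1)
      res <- numeric(n * m + 1L)
      res[(m + 1L):(n * m + 1L)] <- a          # shift by m
      res[seq_along(b)] <- res[seq_along(b)] + b
    }
    memo[[key]] <- res
    res
  }
})

#' Mann-Whitney U test
#'
#' `U_x = sum over pairs [x < y] + 0.5 [x = y]`; the reported U is
#' `min(U_x, U_y)`. The two-sided p-value is exact (dynamic-programming null
#' distribution) when `n_x + n_y <= 12` and there are no ties, otherwise a
#' tie-corrected normal approximation with continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @return List: `U`, `U_x`, `U_y`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y)
  ux <- sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "=="))
  uy <- nx * ny - ux
  U <- min(ux, uy)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (nx + ny <= 12L && !ties) {
    counts <- .mwu_null_counts(nx, ny)
    total <- sum(counts)
    p <- min(1, 2 * sum(counts[seq_len(floor(U) + 1L)]) / total)
    method <- "exact"
  } else {
    N <- nx + ny
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) stop("degenerate data: zero variance")
    z <- (U - nx * ny / 2 + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal_approx"
  }
  list(U = U, U_x = ux, U_y = uy, p_value = p, method = method)
}

# exact null counts of the positive rank sum W+ for n untied ranks:
# f_n(w) = f_{n-1}(w) + f_{n-1}(w - n)
.wsr_null_counts <- local({
  memo <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (n == 0L) {
      res <- 1
    } else {
      a <- Recall(n - 1L)
      res <- numeric(n * (n + 1L) / 2L + 1L)
      res[seq_along(a)] <- a
      res[(n + 1L):(n + length(a))] <- res[(n + 1L):(n + length(a))] + a
    }
    memo[[key]] <- res
    res
  }
})

#' Wilcoxon signed-rank test
#'
#' Zero differences are dropped; absolute differences are mid-ranked; `W` is
#' the smaller of the positive and negative rank sums. Exact two-sided p
#' (dynamic programming over sign assignments) for `n <= 12` without ties in
#' the absolute differences, otherwise tie-corrected normal approximation.
#'
#' @param differences Numeric vector of paired differences.
#' @return List: `W`, `W_pos`, `W_neg`, `n_used`, `p_value`, `method`.
#' @export
wilcoxon_signed_rank <- function(differences) {
  d <- differences[differences != 0]
  if (!length(d)) stop("all differences are zero")
  n <- length(d)
  r <- rank(abs(d), ties.method = "average")
  wpos <- sum(r[d > 0]); wneg <- sum(r[d < 0])
  W <- min(wpos, wneg)
  ties <- anyDuplicated(abs(d)) > 0L
  if (n <= 12L && !ties) {
    counts <- .wsr_null_counts(n)
    p <- min(1, 2 * sum(counts[seq_len(floor(W) + 1L)]) / 2^n)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) stop("degenerate differences: zero variance")
    z <- (W - mu + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal_approx"
  }
  list(W = W, W_pos = wpos, W_neg = wneg, n_used = n, p_value = p,
       method = method)
}

#' Average random raters' intraclass correlation
#'
#' Two-way random-effects, average-measures, absolute-agreement ICC
#' (ICC(2,k) in the Shrout-Fleiss taxonomy), from the two-way ANOVA mean
#' squares: `(MSR - MSE) / (MSR + (MSC - MSE)/n)`.
#'
#' @param ratings Complete numeric matrix, subjects x raters (>= 3 x >= 2).
#' @return ICC estimate.
#' @export
icc_average_random_raters <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings matrix must be complete")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3L || k < 2L) stop("need >= 3 subjects and >= 2 raters")
  grand <- mean(ratings)
  rm_ <- rowMeans(ratings); cm <- colMeans(ratings)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (msc - mse) / n)
}

#' Significance stars
#'
#' `p < 0.001` gives `***`, `p < 0.01` `**`, `p < 0.05` `*`, otherwise empty
#' (strict inequalities).
#'
#' @param p p-value(s) in `[0, 1]` (vectorized).
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Read a subject score table
#'
#' CSV with one row per subject; columns carry regional lesion-free volumes
#' (mL), semi-quantitative lobar lesion scores (0-3, half points allowed),
#' binary structure findings (0/1), and motor/vision scores.
#'
#' @param path CSV path.
#' @return data.frame of class `score_table`.
#' @export
read_score_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  class(x) <- c("score_table", "data.frame")
  x
}

#' Structure-function association table
#'
#' One test per (volume column, score column) pair: Spearman correlation for
#' graded scores, Mann-Whitney U comparing volumes between the binary-score
#' groups for binary findings. Bootstrap percentile CIs are attached to the
#' point estimate and p-values are reported unadjusted (each association is
#' tested individually; no multiplicity correction).
#'
#' @param scores data.frame of subject rows.
#' @param spec List of `list(volume = <column>, score = <column>,
#'   test = "spearman"|"mannwhitney")`.
#' @param n_boot Bootstrap resamples per pair.
#' @param seed Integer seed.
#' @return data.frame with one row per pair: estimate, CI, p-value, n,
#'   stars, and a `note` flag for undefined rows.
#' @export
structure_function_table <- function(scores, spec, n_boot = 2000L, seed = 1L) {
  rows <- lapply(seq_along(spec), function(i) {
    it <- spec[[i]]
    test <- match.arg(it$test, c("spearman", "mannwhitney"))
    if (!all(c(it$volume, it$score) %in% names(scores)))
      stop("unknown column in spec item ", i)
    d <- scores[, c(it$volume, it$score)]
    d <- d[stats::complete.cases(d), , drop = FALSE]
    names(d) <- c("v", "s")
    out <- data.frame(volume = it$volume, score = it$score, test = test,
                      estimate = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_value = NA_real_, n = nrow(d),
                      stars = "", note = "", stringsAsFactors = FALSE)
    if (nrow(d) < 3L) {
      out$note <- "insufficient data"
      return(out)
    }
    if (test == "spearman") {
      if (stats::sd(d$v) == 0 || stats::sd(d$s) == 0) {
        out$note <- "undefined: constant column"
        return(out)
      }
      r <- spearman_r(d$v, d$s)
      ci <- bootstrap_ci(function(dd) spearman_r(dd$v, dd$s), d,
                         n_boot = n_boot, seed = seed + i)
      p <- .spearman_p(r, nrow(d))
      out$estimate <- r
    } else {
      if (!all(d$s %in% c(0, 1)) || length(unique(d$s)) < 2L) {
        out$note <- "undefined: score not binary with both groups"
        return(out)
      }
      mw <- mann_whitney_u(d$v[d$s == 1], d$v[d$s == 0])
      ci <- bootstrap_ci(function(dd) {
        if (length(unique(dd$s)) < 2L) stop("one group")
        mann_whitney_u(dd$v[dd$s == 1], dd$v[dd$s == 0])$U
      }, d, n_boot = n_boot, seed = seed + i)
      p <- mw$p_value
      out$estimate <- mw$U
    }
    out$ci_low <- ci[["low"]]; out$ci_high <- ci[["high"]]
    out$p_value <- p
    out$stars <- significance_stars(p)
    out
  })
  do.call(rbind, rows)
}
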