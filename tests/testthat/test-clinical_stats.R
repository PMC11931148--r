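test_that("Spearman correlation matches a mid-rank oracle and is monotone-invariant", {
  x <- c(1, 3, 2, 5, 4, 8, 7, 6, 10, 9)
  expect_equal(spearman_r(x, x^3), 1.0)            # strictly monotone
  expect_equal(spearman_r(x, -x), -1.0)
  set.seed(51)
  xt <- sample(1:5, 10, TRUE); yt <- sample(1:4, 10, TRUE)  # ties
  # explicit mid-rank + Pearson-formula oracle
  midrank <- function(v) {
    s <- sort(v); r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(s == v[i]))
    r
  }
  rx <- midrank(xt); ry <- midrank(yt)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_r(xt, yt), num / den, tolerance = 1e-12)
  # invariant under strictly monotone transforms (tie-free data)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(spearman_r(exp(a), b), spearman_r(a, b), tolerance = 1e-12)
  expect_error(spearman_r(rep(1, 5), 1:5), "zero rank variance")
  expect_error(spearman_r(1:2, 1:2), "at least 3")
})

test_that("bootstrap CI is seeded, degenerate-safe and error-guarded", {
  set.seed(53)
  d <- cbind(rnorm(20), rnorm(20))
  stat <- function(m) spearman_r(m[, 1], m[, 2])
  ci1 <- bootstrap_ci(stat, d, n_boot = 500, seed = 7)
  ci2 <- bootstrap_ci(stat, d, n_boot = 500, seed = 7)
  expect_identical(ci1, ci2)
  expect_lte(ci1[["low"]], ci1[["high"]])
  # constant statistic -> degenerate interval
  cic <- bootstrap_ci(function(m) 4.2, d, n_boot = 100, seed = 1)
  expect_equal(unname(cic), c(4.2, 4.2))
  # statistic undefined on most resamples -> error
  expect_error(bootstrap_ci(function(m) stop("nope"), d, n_boot = 50, seed = 1),
               "undefined")
})

test_that("bootstrap interval endpoints stabilize with more resamples", {
  set.seed(55)
  n <- 50
  x <- rnorm(n); y <- 0.5 * x + rnorm(n, 0, sqrt(0.75))
  d <- cbind(x, y)
  stat <- function(m) spearman_r(m[, 1], m[, 2])
  ci_a <- bootstrap_ci(stat, d, n_boot = 10000, seed = 3)
  ci_b <- bootstrap_ci(stat, d, n_boot = 40000, seed = 4)
  expect_lt(max(abs(ci_a - ci_b)), 0.01)
})

test_that("Mann-Whitney U matches definitions and the enumeration oracle", {
  # complete separation
  expect_equal(mann_whitney_u(1:4, 11:15)$U, 0)
  # identical multisets
  r <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$U, 4.5)                            # 3*3/2
  # symmetry of the min convention
  set.seed(57)
  x <- rnorm(4); y <- rnorm(5)
  a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
  expect_equal(a$U, b$U); expect_equal(a$p_value, b$p_value)
  expect_equal(a$method, "exact")
  # exhaustive oracle over all C(9,4) labelings of the pooled sample
  pooled <- c(x, y)
  combos <- utils::combn(9, 4)
  u_of <- function(xs, ys) {
    ux <- sum(outer(xs, ys, "<")) + 0.5 * sum(outer(xs, ys, "=="))
    min(ux, length(xs) * length(ys) - ux)
  }
  u_obs <- a$U
  # null distribution of U_x over labelings
  ux_all <- apply(combos, 2, function(ii)
    sum(outer(pooled[ii], pooled[-ii], "<")))
  p_oracle <- min(1, 2 * mean(ux_all <= u_obs))
  expect_equal(a$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(u_of(x, y), u_obs)
  # ties or large n use the corrected normal approximation
  big <- mann_whitney_u(rnorm(10), rnorm(10))
  expect_equal(big$method, "normal_approx")
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact Mann-Whitney is conservative at nominal 0.05", {
  # over the exhaustive null at n=(4,5), P(p <= 0.05) <= 0.05
  combos <- utils::combn(9, 4)
  vals <- 1:9
  ps <- apply(combos, 2, function(ii)
    mann_whitney_u(vals[ii], vals[-ii])$p_value)
  expect_lte(mean(ps <= 0.05), 0.05)
})

test_that("Wilcoxon signed-rank matches definitions and the sign-flip oracle", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 5))$W, 0)   # all positive
  # antisymmetric set: equal rank sums
  r <- wilcoxon_signed_rank(c(-3, -1, 1, 3))
  expect_equal(r$W_pos, r$W_neg)
  # zeros dropped
  expect_equal(wilcoxon_signed_rank(c(0, 0, 2, 3))$n_used, 2)
  set.seed(59)
  d <- round(rnorm(8, 0.3, 1), 3)
  stopifnot(!anyDuplicated(abs(d)))
  res <- wilcoxon_signed_rank(d)
  expect_equal(res$method, "exact")
  # oracle: all 2^8 sign assignments of the observed |d| ranks
  rk <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 8)))
  wpos_all <- signs %*% rk
  p_oracle <- min(1, 2 * mean(wpos_all <= res$W))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")
})

test_that("ICC(2,k) matches an ANOVA-table oracle and penalizes offsets", {
  set.seed(61)
  subj <- rnorm(6, 10, 3)
  ratings <- cbind(subj + rnorm(6, 0, 0.5), subj + rnorm(6, 0, 0.5))
  icc <- icc_average_random_raters(ratings)
  # oracle: mean squares from R's ANOVA machinery
  df <- data.frame(y = as.vector(ratings),
                   subject = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  ms <- anova(stats::aov(y ~ subject + rater, df))$`Mean Sq`
  icc_oracle <- (ms[1] - ms[3]) / (ms[1] + (ms[2] - ms[3]) / 6)
  expect_equal(icc, icc_oracle, tolerance = 1e-9)
  # identical columns with between-subject variance -> 1
  expect_equal(icc_average_random_raters(cbind(subj, subj)), 1.0,
               tolerance = 1e-9)
  # absolute agreement penalizes a constant offset relative to consistency
  off <- cbind(subj, subj + 5)
  icc_abs <- icc_average_random_raters(off)
  # consistency-type ICC on the same data (column-centered)
  icc_cons <- icc_average_random_raters(scale(off, scale = FALSE))
  expect_lt(icc_abs, icc_cons)
  expect_error(icc_average_random_raters(cbind(c(1, NA, 3), 1:3)), "complete")
})

test_that("significance stars follow the strict thresholds", {
  expect_equal(significance_stars(c(0.04, 0.0005, 0.05, 0.009, 0.3)),
               c("*", "***", "", "**", ""))
  expect_error(significance_stars(-0.1), "p must")
})

test_that("structure-function table recovers a generated effect and flags", {
  set.seed(63)
  n <- 30
  score <- sample(0:3, n, TRUE) + sample(c(0, 0.5), n, TRUE)
  vol <- 50 - 6 * score + rnorm(n, 0, 4)      # volumes monotone in the score
  finding <- as.integer(score > 1.5)
  scores <- data.frame(id = 1:n, thalamus_ml = vol, sq_frontal = score,
                       finding = finding, const = 1)
  spec <- list(
    list(volume = "thalamus_ml", score = "sq_frontal", test = "spearman"),
    list(volume = "thalamus_ml", score = "finding", test = "mannwhitney"),
    list(volume = "thalamus_ml", score = "const", test = "spearman"))
  tab <- structure_function_table(scores, spec, n_boot = 300, seed = 5)
  expect_equal(nrow(tab), length(spec))
  expect_lt(tab$estimate[1], 0)                    # negative correlation
  expect_true(tab$stars[1] %in% c("*", "**", "***"))
  expect_true(tab$ci_low[1] <= tab$estimate[1] &
                tab$estimate[1] <= tab$ci_high[1])
  expect_false(is.na(tab$estimate[2]))
  expect_equal(tab$note[3], "undefined: constant column")
  # determinism under seed
  tab2 <- structure_function_table(scores, spec, n_boot = 300, seed = 5)
  expect_identical(tab, tab2)
})

test_that("score tables round-trip through CSV", {
  tmp <- withr::local_tempdir()
  df <- data.frame(id = 1:4, thalamus_ml = c(5.1, 4.2, 6.3, 5.5),
                   sq_parietal = c(0, 1.5, 3, 0.5), plic_finding = c(0, 1, 1, 0))
  p <- file.path(tmp, "scores.csv")
  write.csv(df, p, row.names = FALSE)
  st <- read_score_table(p)
  expect_s3_class(st, "score_table")
  expect_equal(st$thalamus_ml, df$thalamus_ml)
})
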