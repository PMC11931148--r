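bq <- asNamespace("brainquant")

test_that("soft Dice loss matches its definition and a loop oracle", {
  set.seed(31)
  # perfect prediction
  g <- matrix(0, 64, 3); g[cbind(1:64, sample(1:3, 64, TRUE))] <- 1
  expect_lte(soft_dice_loss(g, g), 1e-4)
  # total miss: all mass on a wrong class
  g2 <- matrix(0, 10, 2); g2[, 1] <- 1
  p2 <- matrix(0, 10, 2); p2[, 2] <- 1
  expect_gte(soft_dice_loss(p2, g2), 1 - 1e-3)
  # random tensor vs per-class loop oracle
  z <- matrix(rnorm(64 * 3), 64, 3)
  p <- exp(z) / rowSums(exp(z))
  eps <- 1e-5
  terms <- numeric(0)
  for (k in 2:3) {
    num <- 0; dp <- 0; dg <- 0
    for (i in 1:64) { num <- num + p[i, k] * g[i, k]; dp <- dp + p[i, k]; dg <- dg + g[i, k] }
    terms <- c(terms, (2 * num + eps) / (dp + dg + eps))
  }
  expect_equal(soft_dice_loss(array(p, c(4, 4, 4, 3)), array(g, c(4, 4, 4, 3))),
               1 - mean(terms), tolerance = 1e-6)
})

test_that("weighted categorical cross-entropy matches closed forms", {
  g <- matrix(0, 8, 4); g[cbind(1:8, rep(1:4, 2))] <- 1
  expect_lte(weighted_cce(g * 0.99999 + 0.0000025, g), 1e-4)
  # uniform prediction over K=4 with unit weights -> log 4
  p <- matrix(1 / 4, 8, 4)
  expect_equal(weighted_cce(p, g), log(4), tolerance = 1e-4)
  # hand-expanded 3-voxel toy with weights (2,1,1)
  g3 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  p3 <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.6, 0.3), c(0.25, 0.25, 0.5))
  w <- c(2, 1, 1)
  hand <- -(2 * log(0.7 + 1e-5) + 1 * log(0.6 + 1e-5) + 1 * log(0.5 + 1e-5)) / 3
  expect_equal(weighted_cce(p3, g3, w), hand, tolerance = 1e-12)
  expect_error(weighted_cce(p3, g3, c(-1, 1, 1)), "non-negative")
})

test_that("loss breakdown is linear in its weights", {
  set.seed(33)
  z <- matrix(rnorm(100 * 3), 100, 3)
  p <- exp(z) / rowSums(exp(z))
  g <- matrix(0, 100, 3); g[cbind(1:100, sample(1:3, 100, TRUE))] <- 1
  for (wts in list(c(1, 1), c(2, 0.5), c(0, 3))) {
    lb <- loss_breakdown(p, g, training_config(dice_weight = wts[1],
                                               cce_weight = wts[2]))
    expect_identical(lb$total, wts[1] * lb$soft_dice + wts[2] * lb$weighted_cce)
    expect_gte(lb$soft_dice, 0); expect_lte(lb$soft_dice, 1 + 1e-4)
    expect_gte(lb$weighted_cce, 0)
  }
})

test_that("compiled conv kernels agree with the pure-R reference", {
  set.seed(35)
  sdim <- c(6L, 5L, 4L)
  X <- matrix(rnorm(prod(sdim) * 3), ncol = 3)
  W <- matrix(rnorm(81 * 2), 81, 2); b <- rnorm(2)
  ref <- bq$.conv_fwd(X, W, b, sdim)
  expect_equal(bq$conv3d_fwd_cpp(X, W, b, sdim), ref$Y, tolerance = 1e-12)
  dY <- matrix(rnorm(prod(sdim) * 2), ncol = 2)
  refb <- bq$.conv_bwd(dY, W, ref$Xcol, sdim, 3L)
  cppb <- bq$conv3d_bwd_cpp(X, W, dY, sdim)
  expect_equal(cppb$dX, refb$dX, tolerance = 1e-12)
  expect_equal(cppb$dW, refb$dW, tolerance = 1e-12)
  expect_equal(as.vector(cppb$db), refb$db, tolerance = 1e-12)
})

test_that("backpropagation matches numerical gradients", {
  set.seed(37)
  cfg <- model_config(classes = 3, in_channels = 2, levels = 2,
                      base_channels = 2, patch_size = 8)
  tcfg <- training_config(seed = 1, class_weights = c(1, 2, 1))
  params <- bq$.with_seed(7, bq$.unet_init(cfg))
  # nonzero biases avoid exact-zero ReLU ties where the subgradient is free
  for (nm in names(params))
    params[[nm]]$b <- rnorm(length(params[[nm]]$b), 0, 0.05)
  inp <- array(rnorm(8^3 * 2), dim = c(8, 8, 8, 2))
  lab <- array(sample(0:2, 8^3, TRUE), dim = c(8, 8, 8))
  res <- bq$.subject_loss_and_grads(inp, lab, params, cfg, tcfg)
  f_of <- function(p) bq$.subject_loss_and_grads(inp, lab, p, cfg, tcfg,
                                                 with_grads = FALSE)$loss$total
  eps <- 1e-6
  for (nm in c("enc1_1", "enc2_2", "dec1_1", "out")) {
    for (part in c("W", "b")) {
      pv <- params[[nm]][[part]]
      for (i in sample(length(pv), min(3, length(pv)))) {
        p2 <- params; p2[[nm]][[part]][i] <- p2[[nm]][[part]][i] + eps
        p3 <- params; p3[[nm]][[part]][i] <- p3[[nm]][[part]][i] - eps
        num <- (f_of(p2) - f_of(p3)) / (2 * eps)
        expect_equal(res$grads[[nm]][[part]][i], num,
                     tolerance = 1e-4 * max(1, abs(num)))
      }
    }
  }
})

test_that("training is seeded-deterministic and respects patience", {
  set.seed(39)
  subjects <- lapply(1:4, function(i) {
    inp <- array(rnorm(8^3), dim = c(8, 8, 8))
    lab <- array(as.integer(inp > 0), dim = c(8, 8, 8))
    list(inputs = inp, labels = lab)
  })
  cfg <- model_config(classes = 2, in_channels = 1, levels = 2,
                      base_channels = 2, patch_size = 8)
  tcfg <- training_config(max_epochs = 5, val_subjects = 2, seed = 42)
  f1 <- train_model(subjects, cfg, tcfg)
  f2 <- train_model(subjects, cfg, tcfg)
  expect_equal(f1$history$train_total, f2$history$train_total,
               tolerance = 1e-5)
  expect_equal(f1$history$val_total, f2$history$val_total, tolerance = 1e-5)
  # patience 0: stops right after the first epoch without improvement
  tc0 <- training_config(max_epochs = 50, val_subjects = 2, seed = 42,
                         patience = 0, learning_rate = 10)  # diverges fast
  f0 <- train_model(subjects, cfg, tc0)
  worse <- which(diff(f0$history$val_total) >= -1e-8)
  expect_equal(nrow(f0$history), worse[1] + 1L)
  expect_error(train_model(subjects[1:2], cfg, tcfg), "subjects")
})

test_that("prediction handles padding, channels and argmax ties", {
  cfg <- model_config(classes = 3, in_channels = 1, levels = 2,
                      base_channels = 2, patch_size = 8)
  params <- bq$.with_seed(3, bq$.unet_init(cfg))
  # zero weights: all logits equal, ties break to the lowest class id
  zp <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  inp <- array(rnorm(9 * 10 * 11), dim = c(9, 10, 11))   # not a multiple of 4
  out <- predict_labels(zp, inp, model_cfg = cfg)
  expect_equal(dim(out), c(9, 10, 11))                   # pad-and-crop
  expect_true(all(out == 0L))                            # lowest class id
  expect_error(predict_labels(zp, array(0, c(8, 8, 8, 2)), model_cfg = cfg),
               "channel-count mismatch")
})

test_that("model checkpoints round-trip through save/load", {
  tmp <- withr::local_tempdir()
  set.seed(41)
  subjects <- lapply(1:3, function(i) {
    inp <- array(rnorm(8^3), dim = c(8, 8, 8))
    list(inputs = inp, labels = array(as.integer(inp > 0), dim = c(8, 8, 8)))
  })
  cfg <- model_config(classes = 2, in_channels = 1, levels = 2,
                      base_channels = 2, patch_size = 8)
  fit <- train_model(subjects, cfg, training_config(max_epochs = 2,
                                                    val_subjects = 1, seed = 1))
  save_model(fit, file.path(tmp, "m"))
  re <- load_model(file.path(tmp, "m"))
  expect_equal(re$params, fit$params, tolerance = 1e-12)
  expect_identical(predict_labels(re, subjects[[1]]$inputs),
                   predict_labels(fit, subjects[[1]]$inputs))
})
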