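# Desk-scale trainable 3D U-Net, implemented directly in R.
#
# No deep-learning framework is available in the deployment environment, so
# the network is built from first principles: 3x3x3 convolutions realised as
# im2col gathers + matrix products (with exact manual backpropagation), ReLU,
# 2x2x2 max pooling, nearest-neighbour upsampling with skip concatenation,
# a 1x1x1 output head, and Adam. The default architecture (2 levels, 8 base
# channels, 32^3 patches) is deliberately small: it trains on a CPU in
# minutes and is sufficient for the phantom world; `model_config` exposes
# larger settings.
#
# Activations travel as N x C matrices (N = voxels of the current grid) with
# the spatial dims carried alongside; index maps for conv/pool/upsample are
# cached per grid shape.

#' U-Net model configuration
#'
#' @param classes Number of output classes (including background).
#' @param in_channels Number of input image channels.
#' @param levels Encoder depth (default 2: one skip connection).
#' @param base_channels Channels at the first level (doubled per level).
#' @param patch_size Cubic training patch edge in voxels; must be divisible
#'   by `2^levels`.
#' @param class_labels Label-map values corresponding to each class, in class
#'   order; defaults to `0:(classes-1)`.
#' @return Object of class `model_config`.
#' @export
model_config <- function(classes, in_channels, levels = 2L,
                         base_channels = 8L, patch_size = 32L,
                         class_labels = NULL) {
  stopifnot(classes >= 2L, in_channels >= 1L, levels >= 1L,
            base_channels >= 1L)
  if (patch_size %% (2^levels) != 0L)
    stop("patch_size must be divisible by 2^levels")
  class_labels <- class_labels %||% (0:(classes - 1L))
  stopifnot(length(class_labels) == classes)
  structure(list(classes = as.integer(classes),
                 in_channels = as.integer(in_channels),
                 levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 patch_size = as.integer(patch_size),
                 class_labels = as.integer(class_labels)),
            class = "model_config")
}

#' Training configuration
#'
#' @param dice_weight,cce_weight Non-negative weights of the soft-Dice and
#'   weighted categorical cross-entropy terms of the combined loss.
#' @param class_weights Per-class cross-entropy weights (default all 1).
#' @param learning_rate Adam step size.
#' @param max_epochs Epoch cap.
#' @param patience Epochs without validation-loss improvement before early
#'   stop (default 10); training runs until the validation loss converges.
#' @param val_subjects Number of held-out validation subjects (default 5).
#' @param patches_per_subject Random patches drawn per subject per epoch.
#' @param seed Seed governing the subject shuffle, weight init and patch
#'   sampling; training is fully deterministic given it.
#' @return Object of class `training_config`.
#' @export
training_config <- function(dice_weight = 1, cce_weight = 1,
                            class_weights = NULL, learning_rate = 1e-3,
                            max_epochs = 100L, patience = 10L,
                            val_subjects = 5L, patches_per_subject = 1L,
                            seed = 1L) {
  stopifnot(dice_weight >= 0, cce_weight >= 0,
            dice_weight + cce_weight > 0, learning_rate > 0,
            max_epochs >= 1L, patience >= 0L, val_subjects >= 1L)
  if (!is.null(class_weights) && any(class_weights < 0))
    stop("class weights must be non-negative")
  structure(list(dice_weight = dice_weight, cce_weight = cce_weight,
                 class_weights = class_weights,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_subjects = as.integer(val_subjects),
                 patches_per_subject = as.integer(patches_per_subject),
                 seed = as.integer(seed)),
            class = "training_config")
}

.unet_eps <- 1e-5

# ---------------------------------------------------------------------------
# losses

.as_class_matrix <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) return(as.matrix(x))
  if (length(d) == 4L) return(matrix(x, nrow = prod(d[1:3]), ncol = d[4]))
  stop("expected an N x K matrix or X x Y x Z x K array")
}

#' Soft Dice loss
#'
#' `1 - mean` over foreground classes (all classes but the first) of
#' `(2*sum(p*g) + eps) / (sum(p) + sum(g) + eps)` with `eps = 1e-5`.
#'
#' @param probabilities Per-class probabilities, `N x K` matrix or
#'   `X x Y x Z x K` array; rows must sum to 1.
#' @param one_hot_truth One-hot ground truth of the same shape.
#' @return Scalar loss in `[0, 1]` (up to `eps`).
#' @export
soft_dice_loss <- function(probabilities, one_hot_truth) {
  p <- .as_class_matrix(probabilities); g <- .as_class_matrix(one_hot_truth)
  if (!all(dim(p) == dim(g))) stop("shape mismatch")
  fg <- seq_len(ncol(p))[-1]
  terms <- vapply(fg, function(k) {
    (2 * sum(p[, k] * g[, k]) + .unet_eps) /
      (sum(p[, k]) + sum(g[, k]) + .unet_eps)
  }, numeric(1))
  1 - mean(terms)
}

.soft_dice_grad <- function(p, g) {
  fg <- seq_len(ncol(p))[-1]
  dP <- matrix(0, nrow(p), ncol(p))
  for (k in fg) {
    A <- 2 * sum(p[, k] * g[, k]) + .unet_eps
    B <- sum(p[, k]) + sum(g[, k]) + .unet_eps
    dP[, k] <- -(2 * g[, k] * B - A) / B^2 / length(fg)
  }
  dP
}

#' Weighted categorical cross-entropy
#'
#' `-mean` over voxels of `w[true_class] * log(p[true_class] + eps)`.
#'
#' @param probabilities,one_hot_truth As in [soft_dice_loss()].
#' @param class_weights Per-class non-negative weights (default all 1).
#' @return Scalar loss.
#' @export
weighted_cce <- function(probabilities, one_hot_truth, class_weights = NULL) {
  p <- .as_class_matrix(probabilities); g <- .as_class_matrix(one_hot_truth)
  if (!all(dim(p) == dim(g))) stop("shape mismatch")
  w <- class_weights %||% rep(1, ncol(p))
  if (any(w < 0)) stop("class weights must be non-negative")
  if (length(w) != ncol(p)) stop("class_weights length must equal classes")
  pt <- rowSums(p * g)
  wt <- as.vector(g %*% w)
  -mean(wt * log(pt + .unet_eps))
}

.weighted_cce_grad <- function(p, g, w) {
  pt <- rowSums(p * g)
  wt <- as.vector(g %*% w)
  -(g * (wt / (pt + .unet_eps))) / nrow(p)
}

#' Combined loss breakdown
#'
#' @param probabilities,one_hot_truth As in [soft_dice_loss()].
#' @param train_cfg A [training_config()] carrying the term weights.
#' @return List with `soft_dice`, `weighted_cce`, `total`
#'   (`total = dice_weight*soft_dice + cce_weight*weighted_cce`).
#' @export
loss_breakdown <- function(probabilities, one_hot_truth,
                           train_cfg = training_config()) {
  sd_ <- soft_dice_loss(probabilities, one_hot_truth)
  ce <- weighted_cce(probabilities, one_hot_truth, train_cfg$class_weights)
  list(soft_dice = sd_, weighted_cce = ce,
       total = train_cfg$dice_weight * sd_ + train_cfg$cce_weight * ce)
}

# ---------------------------------------------------------------------------
# index caches

.unet_idx_cache <- new.env(parent = emptyenv())

.conv_idx <- function(sdim) {
  key <- paste0("conv", paste(sdim, collapse = "x"))
  if (!is.null(.unet_idx_cache[[key]])) return(.unet_idx_cache[[key]])
  d1 <- sdim[1]; d2 <- sdim[2]; d3 <- sdim[3]
  dp1 <- d1 + 2L; dp2 <- d2 + 2L
  I <- rep.int(seq_len(d1), d2 * d3)
  J <- rep.int(rep(seq_len(d2), each = d1), d3)
  K <- rep(seq_len(d3), each = d1 * d2)
  base <- (I + 1L) + dp1 * J + dp1 * dp2 * K
  offs <- as.matrix(expand.grid(ox = -1:1, oy = -1:1, oz = -1:1))
  shift <- offs[, 1] + dp1 * offs[, 2] + dp1 * dp2 * offs[, 3]
  idx <- outer(base, shift, "+")
  .unet_idx_cache[[key]] <- idx
  idx
}

.pool_idx <- function(sdim) {
  key <- paste0("pool", paste(sdim, collapse = "x"))
  if (!is.null(.unet_idx_cache[[key]])) return(.unet_idx_cache[[key]])
  h <- sdim %/% 2L
  I <- rep.int(seq_len(h[1]), h[2] * h[3])
  J <- rep.int(rep(seq_len(h[2]), each = h[1]), h[3])
  K <- rep(seq_len(h[3]), each = h[1] * h[2])
  corners <- as.matrix(expand.grid(ox = 0:1, oy = 0:1, oz = 0:1))
  idx <- matrix(0L, length(I), 8L)
  for (q in 1:8) {
    idx[, q] <- (2L * I - 1L + corners[q, 1]) +
      sdim[1] * (2L * J - 2L + corners[q, 2]) +
      sdim[1] * sdim[2] * (2L * K - 2L + corners[q, 3])
  }
  .unet_idx_cache[[key]] <- idx
  idx
}

.up_idx <- function(sdim) {
  # map from output voxel (2x grid) to source voxel (nearest neighbour)
  key <- paste0("up", paste(sdim, collapse = "x"))
  if (!is.null(.unet_idx_cache[[key]])) return(.unet_idx_cache[[key]])
  u <- 2L * sdim
  I <- (rep.int(seq_len(u[1]), u[2] * u[3]) + 1L) %/% 2L
  J <- (rep.int(rep(seq_len(u[2]), each = u[1]), u[3]) + 1L) %/% 2L
  K <- (rep(seq_len(u[3]), each = u[1] * u[2]) + 1L) %/% 2L
  idx <- I + sdim[1] * (J - 1L) + sdim[1] * sdim[2] * (K - 1L)
  .unet_idx_cache[[key]] <- idx
  idx
}

# ---------------------------------------------------------------------------
# layers

.conv_fwd <- function(X, W, b, sdim) {
  N <- nrow(X); Cin <- ncol(X)
  idx <- .conv_idx(sdim)
  dp <- sdim + 2L
  Xcol <- matrix(0, N, 27L * Cin)
  for (c in seq_len(Cin)) {
    pad <- array(0, dim = dp)
    pad[2:(sdim[1] + 1L), 2:(sdim[2] + 1L), 2:(sdim[3] + 1L)] <-
      array(X[, c], dim = sdim)
    flat <- as.vector(pad)
    Xcol[, ((c - 1L) * 27L + 1L):(c * 27L)] <- flat[idx]
  }
  Y <- Xcol %*% W
  Y <- Y + rep(b, each = N)
  list(Y = Y, Xcol = Xcol)
}

.conv_bwd <- function(dY, W, Xcol, sdim, Cin) {
  N <- nrow(dY)
  idx <- .conv_idx(sdim)
  dp <- sdim + 2L
  dW <- crossprod(Xcol, dY)
  db <- colSums(dY)
  dXcol <- tcrossprod(dY, W)
  dX <- matrix(0, N, Cin)
  for (c in seq_len(Cin)) {
    dpad <- numeric(prod(dp))
    block <- dXcol[, ((c - 1L) * 27L + 1L):(c * 27L), drop = FALSE]
    for (o in 1:27) {
      ii <- idx[, o]
      dpad[ii] <- dpad[ii] + block[, o]
    }
    arr <- array(dpad, dim = dp)
    dX[, c] <- as.vector(arr[2:(sdim[1] + 1L), 2:(sdim[2] + 1L),
                             2:(sdim[3] + 1L)])
  }
  list(dX = dX, dW = dW, db = db)
}

.pool_fwd <- function(X, sdim) {
  idx <- .pool_idx(sdim)
  C <- ncol(X)
  N2 <- nrow(idx)
  Y <- matrix(0, N2, C)
  arg <- matrix(0L, N2, C)
  for (c in seq_len(C)) {
    vals <- matrix(X[, c][idx], N2, 8L)
    a <- max.col(vals, ties.method = "first")
    arg[, c] <- a
    Y[, c] <- vals[cbind(seq_len(N2), a)]
  }
  list(Y = Y, arg = arg)
}

.pool_bwd <- function(dY, arg, sdim) {
  idx <- .pool_idx(sdim)
  N <- prod(sdim); C <- ncol(dY); N2 <- nrow(dY)
  dX <- matrix(0, N, C)
  for (c in seq_len(C)) {
    sel <- idx[cbind(seq_len(N2), arg[, c])]
    dX[sel, c] <- dY[, c]
  }
  dX
}

.up_fwd <- function(X, sdim) X[.up_idx(sdim), , drop = FALSE]

.up_bwd <- function(dY, sdim) {
  idx <- .up_idx(sdim)
  rowsum(dY, group = idx, reorder = TRUE)
}

# ---------------------------------------------------------------------------
# network

.unet_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$levels) - 1L)

.he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

.unet_init <- function(cfg) {
  ch <- .unet_channels(cfg)
  params <- list()
  cin <- cfg$in_channels
  for (l in seq_len(cfg$levels)) {
    params[[paste0("enc", l, "_1")]] <- list(W = .he_init(27L * cin, ch[l]), b = numeric(ch[l]))
    params[[paste0("enc", l, "_2")]] <- list(W = .he_init(27L * ch[l], ch[l]), b = numeric(ch[l]))
    cin <- ch[l]
  }
  for (l in rev(seq_len(cfg$levels - 1L))) {
    cin <- ch[l] + ch[l + 1L]
    params[[paste0("dec", l, "_1")]] <- list(W = .he_init(27L * cin, ch[l]), b = numeric(ch[l]))
    params[[paste0("dec", l, "_2")]] <- list(W = .he_init(27L * ch[l], ch[l]), b = numeric(ch[l]))
  }
  params[["out"]] <- list(W = .he_init(ch[1], cfg$classes), b = numeric(cfg$classes))
  params
}

# The network runs on the compiled conv kernels; the pure-R .conv_fwd /
# .conv_bwd above are retained as an independent reference implementation
# for the test suite.
.conv_relu_fwd <- function(X, prm, sdim, cache, name) {
  Y <- conv3d_fwd_cpp(X, prm$W, prm$b, as.integer(sdim))
  mask <- Y > 0
  Y[!mask] <- 0
  cache[[name]] <- list(X = X, mask = mask)
  Y
}

.conv_relu_bwd <- function(dY, prm, sdim, cache, name, grads) {
  info <- cache[[name]]
  dY <- dY * info$mask
  cb <- conv3d_bwd_cpp(info$X, prm$W, dY, as.integer(sdim))
  grads[[name]] <- list(W = cb$dW, b = as.vector(cb$db))
  cb$dX
}

.unet_forward <- function(X, params, cfg, sdim, cache = NULL) {
  train <- !is.null(cache)
  if (!train) cache <- new.env(parent = emptyenv())
  skips <- list(); sdims <- list()
  for (l in seq_len(cfg$levels)) {
    X <- .conv_relu_fwd(X, params[[paste0("enc", l, "_1")]], sdim, cache, paste0("enc", l, "_1"))
    X <- .conv_relu_fwd(X, params[[paste0("enc", l, "_2")]], sdim, cache, paste0("enc", l, "_2"))
    if (l < cfg$levels) {
      skips[[l]] <- X; sdims[[l]] <- sdim
      pf <- .pool_fwd(X, sdim)
      cache[[paste0("pool", l)]] <- pf$arg
      X <- pf$Y
      sdim <- sdim %/% 2L
    }
  }
  for (l in rev(seq_len(cfg$levels - 1L))) {
    X <- .up_fwd(X, sdim)
    sdim <- 2L * sdim
    nup <- ncol(X)
    X <- cbind(X, skips[[l]])
    cache[[paste0("cat", l)]] <- nup
    X <- .conv_relu_fwd(X, params[[paste0("dec", l, "_1")]], sdim, cache, paste0("dec", l, "_1"))
    X <- .conv_relu_fwd(X, params[[paste0("dec", l, "_2")]], sdim, cache, paste0("dec", l, "_2"))
  }
  logits <- X %*% params$out$W + rep(params$out$b, each = nrow(X))
  if (train) cache[["head_in"]] <- X
  logits
}

.softmax <- function(z) {
  m <- Reduce(pmax, lapply(seq_len(ncol(z)), function(k) z[, k]))
  e <- exp(z - m)
  e / rowSums(e)
}

.unet_backward <- function(dlogits, params, cfg, sdim_top, cache) {
  grads <- new.env(parent = emptyenv())
  X <- cache[["head_in"]]
  grads[["out"]] <- list(W = crossprod(X, dlogits), b = colSums(dlogits))
  dX <- tcrossprod(dlogits, params$out$W)
  # walk decoder back (levels-1 .. 1 were applied in reverse; reverse again)
  sdim <- sdim_top
  skip_grads <- list()
  for (l in seq_len(cfg$levels - 1L)) {
    dX <- .conv_relu_bwd(dX, params[[paste0("dec", l, "_2")]], sdim, cache, paste0("dec", l, "_2"), grads)
    dX <- .conv_relu_bwd(dX, params[[paste0("dec", l, "_1")]], sdim, cache, paste0("dec", l, "_1"), grads)
    nup <- cache[[paste0("cat", l)]]
    skip_grads[[l]] <- dX[, (nup + 1L):ncol(dX), drop = FALSE]
    dX <- .up_bwd(dX[, seq_len(nup), drop = FALSE], sdim %/% 2L)
    sdim <- sdim %/% 2L
  }
  for (l in rev(seq_len(cfg$levels))) {
    dX <- .conv_relu_bwd(dX, params[[paste0("enc", l, "_2")]], sdim, cache, paste0("enc", l, "_2"), grads)
    dX <- .conv_relu_bwd(dX, params[[paste0("enc", l, "_1")]], sdim, cache, paste0("enc", l, "_1"), grads)
    if (l > 1L) {
      dX <- .pool_bwd(dX, cache[[paste0("pool", l - 1L)]], sdim * 2L)
      sdim <- sdim * 2L
      dX <- dX + skip_grads[[l - 1L]]
    }
  }
  as.list(grads)
}

# Adam with bias correction
.adam_step <- function(params, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    for (part in c("W", "b")) {
      g <- grads[[nm]][[part]]
      if (is.null(state[[nm]][[part]]))
        state[[nm]][[part]] <- list(m = g * 0, v = g * 0)
      st <- state[[nm]][[part]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      state[[nm]][[part]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[nm]][[part]] <- params[[nm]][[part]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

.one_hot <- function(labels_vec, class_labels) {
  K <- length(class_labels)
  cls <- match(labels_vec, class_labels)
  if (anyNA(cls)) stop("label values outside model class_labels")
  g <- matrix(0, length(cls), K)
  g[cbind(seq_along(cls), cls)] <- 1
  g
}

.as_input_matrix <- function(inputs) {
  d <- dim(inputs)
  if (length(d) == 3L) {
    list(X = matrix(inputs, ncol = 1L), sdim = d)
  } else if (length(d) == 4L) {
    list(X = matrix(inputs, nrow = prod(d[1:3]), ncol = d[4]), sdim = d[1:3])
  } else stop("inputs must be a 3D or 4D array")
}

.sample_patch_corner <- function(sdim, ps) {
  vapply(sdim, function(n) {
    if (n <= ps) 1L else sample.int(n - ps + 1L, 1L)
  }, integer(1))
}

.extract_patch <- function(arr, corner, ps) {
  d <- dim(arr)
  size <- pmin(ps, d[1:3])
  ix <- lapply(1:3, function(a) corner[a]:(corner[a] + size[a] - 1L))
  if (length(d) == 3L) arr[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  else arr[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
}

.subject_loss_and_grads <- function(inputs, labels, params, cfg, tcfg,
                                    with_grads = TRUE) {
  im <- .as_input_matrix(inputs)
  if (ncol(im$X) != cfg$in_channels) stop("channel-count mismatch")
  g <- .one_hot(as.vector(labels), cfg$class_labels)
  cache <- if (with_grads) new.env(parent = emptyenv()) else NULL
  logits <- .unet_forward(im$X, params, cfg, im$sdim, cache)
  p <- .softmax(logits)
  lb <- loss_breakdown(p, g, tcfg)
  if (!with_grads) return(list(loss = lb))
  w <- tcfg$class_weights %||% rep(1, cfg$classes)
  dP <- tcfg$dice_weight * .soft_dice_grad(p, g) +
    tcfg$cce_weight * .weighted_cce_grad(p, g, w)
  dZ <- p * (dP - rowSums(dP * p))
  grads <- .unet_backward(dZ, params, cfg, im$sdim, cache)
  list(loss = lb, grads = grads)
}

#' Train a U-Net model
#'
#' Subjects are shuffled once (seeded); the last `val_subjects` of the
#' shuffle are held out for validation. Each epoch draws
#' `patches_per_subject` random patches per training subject, takes one Adam
#' step per patch, then evaluates the combined loss on the validation
#' subjects. Training stops when the validation loss has not improved for
#' `patience` consecutive epochs, or at `max_epochs`. Fully deterministic
#' given `train_cfg$seed`.
#'
#' @param subjects List of `list(inputs = 3D/4D array, labels = 3D array)`;
#'   inputs are expected normalized, labels carry `class_labels` values.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [training_config()].
#' @return Object of class `unet_fit`: `params`, `history` (per-epoch
#'   train/val loss breakdowns), `model_cfg`, `train_cfg`.
#' @export
train_model <- function(subjects, model_cfg, train_cfg = training_config()) {
  n <- length(subjects)
  if (n < train_cfg$val_subjects + 1L)
    stop("need at least val_subjects + 1 = ", train_cfg$val_subjects + 1L,
         " subjects, got ", n)
  .with_seed(train_cfg$seed, {
    ord <- sample.int(n)
    val_idx <- utils::tail(ord, train_cfg$val_subjects)
    tr_idx <- setdiff(ord, val_idx)
    params <- .unet_init(model_cfg)
    state <- list()
    ps <- model_cfg$patch_size
    t_step <- 0L
    history <- data.frame()
    best_val <- Inf; bad_epochs <- 0L
    for (epoch in seq_len(train_cfg$max_epochs)) {
      tr_losses <- list()
      for (si in tr_idx) {
        sub <- subjects[[si]]
        for (rep_ in seq_len(train_cfg$patches_per_subject)) {
          sdim <- dim(sub$labels)
          corner <- .sample_patch_corner(sdim, ps)
          inp <- .extract_patch(sub$inputs, corner, ps)
          lab <- .extract_patch(sub$labels, corner, ps)
          res <- .subject_loss_and_grads(inp, lab, params, model_cfg, train_cfg)
          t_step <- t_step + 1L
          upd <- .adam_step(params, res$grads, state,
                            train_cfg$learning_rate, t_step)
          params <- upd$params; state <- upd$state
          tr_losses[[length(tr_losses) + 1L]] <- res$loss
        }
      }
      val_losses <- lapply(val_idx, function(si) {
        .subject_loss_and_grads(subjects[[si]]$inputs, subjects[[si]]$labels,
                                params, model_cfg, train_cfg,
                                with_grads = FALSE)$loss
      })
      avg <- function(lst, f) mean(vapply(lst, `[[`, numeric(1), f))
      history <- rbind(history, data.frame(
        epoch = epoch,
        train_soft_dice = avg(tr_losses, "soft_dice"),
        train_weighted_cce = avg(tr_losses, "weighted_cce"),
        train_total = avg(tr_losses, "total"),
        val_soft_dice = avg(val_losses, "soft_dice"),
        val_weighted_cce = avg(val_losses, "weighted_cce"),
        val_total = avg(val_losses, "total")))
      vt <- history$val_total[epoch]
      if (vt < best_val - 1e-8) {
        best_val <- vt; bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs > train_cfg$patience) break
      }
    }
    structure(list(params = params, history = history,
                   model_cfg = model_cfg, train_cfg = train_cfg),
              class = "unet_fit")
  })
}

#' @export
print.unet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<unet_fit  %d classes, %d epochs, final val loss %.4f>\n",
              x$model_cfg$classes, nrow(h), h$val_total[nrow(h)]))
  invisible(x)
}

.pad_to_multiple <- function(arr, mult) {
  d <- dim(arr)
  sdim <- d[1:3]
  target <- as.integer(ceiling(sdim / mult) * mult)
  if (all(target == sdim)) return(list(arr = arr, orig = sdim))
  if (length(d) == 3L) {
    out <- array(0, dim = target)
    out[1:sdim[1], 1:sdim[2], 1:sdim[3]] <- arr
  } else {
    out <- array(0, dim = c(target, d[4]))
    out[1:sdim[1], 1:sdim[2], 1:sdim[3], ] <- arr
  }
  list(arr = out, orig = sdim)
}

#' Predict a label map
#'
#' Runs the fully-convolutional network over the whole grid (padding to a
#' multiple of `2^levels` and cropping back), then takes the per-voxel argmax
#' with ties broken toward the lowest class id.
#'
#' @param fit A `unet_fit` (or bare params list plus `model_cfg`).
#' @param inputs 3D array (single channel) or 4D array `X x Y x Z x C`.
#' @param model_cfg Optional [model_config()] if `fit` is a bare params list.
#' @param affine,scheme If both supplied, the result is a [labelmap3d()];
#'   otherwise a plain integer array of class labels.
#' @return Integer array or [labelmap3d()] of predicted labels.
#' @export
predict_labels <- function(fit, inputs, model_cfg = NULL,
                           affine = NULL, scheme = NULL) {
  if (inherits(fit, "unet_fit")) {
    params <- fit$params; cfg <- fit$model_cfg
  } else {
    params <- fit; cfg <- model_cfg
    if (is.null(cfg)) stop("model_cfg required with bare params")
  }
  pad <- .pad_to_multiple(inputs, 2L^cfg$levels)
  im <- .as_input_matrix(pad$arr)
  if (ncol(im$X) != cfg$in_channels) stop("channel-count mismatch")
  logits <- .unet_forward(im$X, params, cfg, im$sdim)
  cls <- max.col(logits, ties.method = "first")
  lab <- array(cfg$class_labels[cls], dim = im$sdim)
  orig <- pad$orig
  lab <- lab[1:orig[1], 1:orig[2], 1:orig[3], drop = FALSE]
  dim(lab) <- orig
  if (!is.null(affine) && !is.null(scheme))
    labelmap3d(lab, affine, scheme)
  else lab
}

#' Save / load a trained model
#'
#' Weights go to a binary checkpoint (`weights.rds`) with a JSON sidecar
#' describing the architecture.
#'
#' @param fit A `unet_fit`.
#' @param dir Output directory (created if missing).
#' @return `dir` (save) or a `unet_fit` (load).
#' @export
save_model <- function(fit, dir) {
  stopifnot(inherits(fit, "unet_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(fit$params, file.path(dir, "weights.rds"))
  jsonlite::write_json(unclass(fit$model_cfg),
                       file.path(dir, "model_config.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(fit$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfgl <- jsonlite::read_json(file.path(dir, "model_config.json"),
                              simplifyVector = TRUE)
  cfg <- model_config(classes = cfgl$classes, in_channels = cfgl$in_channels,
                      levels = cfgl$levels, base_channels = cfgl$base_channels,
                      patch_size = cfgl$patch_size,
                      class_labels = cfgl$class_labels)
  params <- readRDS(file.path(dir, "weights.rds"))
  history <- if (file.exists(file.path(dir, "history.csv")))
    utils::read.csv(file.path(dir, "history.csv")) else data.frame()
  structure(list(params = params, history = history, model_cfg = cfg,
                 train_cfg = NULL), class = "unet_fit")
}

#' One-hot tissue channels for the lesion model
#'
#' The lesion model consumes T1, FLAIR and the structural tissue map; the
#' tissue map enters as one-hot channels over {background, CSF, GM, WM} to
#' avoid ordinal artifacts.
#'
#' @param labels A [labelmap3d()] of structural labels.
#' @return 4D array `X x Y x Z x 4`.
#' @export
tissue_onehot <- function(labels) {
  stopifnot(inherits(labels, "labelmap3d"))
  tis <- scheme_lookup(labels$scheme, "tissue")
  d <- dim(labels$labels)
  classes <- c("BACKGROUND", "CSF", "GM", "WM")
  tv <- array("BACKGROUND", dim = d)
  nz <- labels$labels != 0L
  tv[nz] <- tis[as.character(labels$labels[nz])]
  out <- array(0, dim = c(d, 4L))
  for (k in seq_along(classes)) out[, , , k] <- as.numeric(tv == classes[k])
  out
}
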