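## Trainable tissue segmenter.
##
## A small nested-skip encoder-decoder (depth 2: two 2x downsamplings, skip
## connections concatenated on the way up, 3x3 convolutions, ReLU, a 1x1
## logit head). Convolutions are evaluated as a sum over the nine kernel
## taps of shifted (HW x Cin) %*% (Cin x Cout) matrix products, which keeps
## both the forward and the hand-derived backward pass inside BLAS. The
## training protocol follows the comparison study: pixel-wise binary cross
## entropy with a positive-class weight, decoupled-weight-decay Adam
## (AdamW), and early stopping on validation F1.

.tap_offsets <- expand.grid(dy = -1:1, dx = -1:1)

## Gather-index cache: for each (H, W, tap) a vector mapping output linear
## indices to input linear indices, with out-of-range pixels sent to a dummy
## zero row (H*W + 1).
.idx_cache <- new.env(parent = emptyenv())

tap_indices <- function(H, W) {
  key <- paste(H, W, sep = "x")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  i <- rep(seq_len(H), W)
  j <- rep(seq_len(W), each = H)
  idx <- lapply(seq_len(9), function(k) {
    dy <- .tap_offsets$dy[k]; dx <- .tap_offsets$dx[k]
    ii <- i + dy; jj <- j + dx
    ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
    out <- rep.int(H * W + 1L, H * W)
    out[ok] <- ii[ok] + (jj[ok] - 1L) * H
    out
  })
  .idx_cache[[key]] <- idx
  idx
}

## tap k -> index of the opposite offset (used in the backward pass)
.tap_inverse <- vapply(seq_len(9), function(k) {
  which(.tap_offsets$dy == -.tap_offsets$dy[k] &
          .tap_offsets$dx == -.tap_offsets$dx[k])
}, integer(1))

a2m <- function(x) { d <- dim(x); dim(x) <- c(d[1] * d[2], d[3]); x }
m2a <- function(m, H, W) { dim(m) <- c(H, W, ncol(m)); m }

conv3_forward <- function(M, layer, idx9) {
  Mz <- rbind(M, 0)
  Z <- matrix(layer$b, nrow(M), length(layer$b), byrow = TRUE)
  for (k in seq_len(9)) Z <- Z + Mz[idx9[[k]], , drop = FALSE] %*% layer$W[[k]]
  Z
}

conv3_backward <- function(dZ, M, layer, idx9) {
  Mz <- rbind(M, 0)
  dW <- vector("list", 9)
  dM <- matrix(0, nrow(M), ncol(M))
  for (k in seq_len(9)) {
    Ms <- Mz[idx9[[k]], , drop = FALSE]
    dW[[k]] <- crossprod(Ms, dZ)
    back <- rbind(dZ %*% t(layer$W[[k]]), 0)
    dM <- dM + back[idx9[[.tap_inverse[k]]], , drop = FALSE]
  }
  list(dW = dW, db = colSums(dZ), dM = dM)
}

conv1_forward <- function(M, layer) {
  sweep(M %*% layer$W[[1]], 2, layer$b, `+`)
}

avgpool2 <- function(x) {
  d <- dim(x)
  (x[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
     x[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
     x[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
     x[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]) / 4
}

avgpool2_backward <- function(dy) {
  d <- dim(dy)
  dy[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE] / 4
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

upsample2_backward <- function(dy) {
  d <- dim(dy)
  (dy[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
     dy[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
     dy[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
     dy[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE])
}

init_conv <- function(cin, cout, k = 3) {
  n_tap <- if (k == 3) 9 else 1
  sd <- sqrt(2 / (n_tap * cin))
  list(W = lapply(seq_len(n_tap),
                  function(i) matrix(rnorm(cin * cout, 0, sd), cin, cout)),
       b = numeric(cout))
}

## Input featurization: raw RGB plus amplified channel differences
## (chroma). Pale, weakly stained tissue is nearly luminance-neutral; its
## signal lives in chroma, and exposing it directly lets a small network
## segment both regimes without trading one off against the other.
featurize <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2], 6))
  out[, , 1:3] <- x
  out[, , 4] <- 5 * (x[, , 1] - x[, , 2])
  out[, , 5] <- 5 * (x[, , 1] - x[, , 3])
  out[, , 6] <- 5 * (x[, , 2] - x[, , 3])
  out
}

init_unet <- function(widths = c(8, 16, 32), in_ch = 6) {
  c1 <- widths[1]; c2 <- widths[2]; c3 <- widths[3]
  list(enc1 = init_conv(in_ch, c1),
       enc2 = init_conv(c1, c2),
       bott = init_conv(c2, c3),
       dec2 = init_conv(c3 + c2, c2),
       dec1 = init_conv(c2 + c1, c1),
       head = init_conv(c1, 1, k = 1))
}

relu <- function(x) { x[x < 0] <- 0; x }

#' Whole-image forward pass of the segmentation network
#'
#' @param params network weights (as stored in a checkpoint).
#' @param x H x W x 3 array, H and W multiples of 4.
#' @param keep_cache retain intermediate activations (for training).
#' @return `list(logits = H x W matrix, cache = ...)`.
#' @keywords internal
unet_forward <- function(params, x, keep_cache = FALSE) {
  if (dim(x)[3] == 3) x <- featurize(x)
  d <- dim(x); H <- d[1]; W <- d[2]
  stopifnot(H %% 4 == 0, W %% 4 == 0)
  i1 <- tap_indices(H, W); i2 <- tap_indices(H / 2, W / 2)
  i3 <- tap_indices(H / 4, W / 4)

  M0 <- a2m(x)
  Z1 <- conv3_forward(M0, params$enc1, i1);  A1 <- relu(Z1)
  P1 <- avgpool2(m2a(A1, H, W))
  Z2 <- conv3_forward(a2m(P1), params$enc2, i2); A2 <- relu(Z2)
  P2 <- avgpool2(m2a(A2, H / 2, W / 2))
  Z3 <- conv3_forward(a2m(P2), params$bott, i3); A3 <- relu(Z3)
  U2 <- upsample2(m2a(A3, H / 4, W / 4))
  C2 <- cbind(a2m(U2), A2)
  Z4 <- conv3_forward(C2, params$dec2, i2); A4 <- relu(Z4)
  U1 <- upsample2(m2a(A4, H / 2, W / 2))
  C1 <- cbind(a2m(U1), A1)
  Z5 <- conv3_forward(C1, params$dec1, i1); A5 <- relu(Z5)
  logits <- conv1_forward(A5, params$head)

  cache <- if (keep_cache)
    list(M0 = M0, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, Z3 = Z3, A3 = A3,
         C2 = C2, Z4 = Z4, A4 = A4, C1 = C1, Z5 = Z5, A5 = A5,
         H = H, W = W, i1 = i1, i2 = i2, i3 = i3)
  list(logits = matrix(logits, H, W), cache = cache)
}

unet_backward <- function(params, cache, dlogits) {
  H <- cache$H; W <- cache$W
  c1w <- ncol(cache$A1); c2w <- ncol(cache$A2)
  g <- list()

  dL <- matrix(as.vector(dlogits), H * W, 1)
  g$head <- list(W = list(crossprod(cache$A5, dL)), b = colSums(dL))
  dA5 <- dL %*% t(params$head$W[[1]])
  dZ5 <- dA5 * (cache$Z5 > 0)
  b5 <- conv3_backward(dZ5, cache$C1, params$dec1, cache$i1)
  g$dec1 <- list(W = b5$dW, b = b5$db)

  dU1 <- b5$dM[, seq_len(ncol(b5$dM) - c1w), drop = FALSE]
  dA1_skip <- b5$dM[, (ncol(b5$dM) - c1w + 1):ncol(b5$dM), drop = FALSE]
  dA4 <- a2m(upsample2_backward(m2a(dU1, H, W)))
  dZ4 <- dA4 * (cache$Z4 > 0)
  b4 <- conv3_backward(dZ4, cache$C2, params$dec2, cache$i2)
  g$dec2 <- list(W = b4$dW, b = b4$db)

  dU2 <- b4$dM[, seq_len(ncol(b4$dM) - c2w), drop = FALSE]
  dA2_skip <- b4$dM[, (ncol(b4$dM) - c2w + 1):ncol(b4$dM), drop = FALSE]
  dA3 <- a2m(upsample2_backward(m2a(dU2, H / 2, W / 2)))
  dZ3 <- dA3 * (cache$Z3 > 0)
  b3 <- conv3_backward(dZ3, a2m(avgpool2(m2a(cache$A2, H / 2, W / 2))),
                       params$bott, cache$i3)
  g$bott <- list(W = b3$dW, b = b3$db)

  dP2 <- b3$dM
  dA2 <- dA2_skip + a2m(avgpool2_backward(m2a(dP2, H / 4, W / 4)))
  dZ2 <- dA2 * (cache$Z2 > 0)
  b2 <- conv3_backward(dZ2, a2m(avgpool2(m2a(cache$A1, H, W))),
                       params$enc2, cache$i2)
  g$enc2 <- list(W = b2$dW, b = b2$db)

  dP1 <- b2$dM
  dA1 <- dA1_skip + a2m(avgpool2_backward(m2a(dP1, H / 2, W / 2)))
  dZ1 <- dA1 * (cache$Z1 > 0)
  b1 <- conv3_backward(dZ1, cache$M0, params$enc1, cache$i1)
  g$enc1 <- list(W = b1$dW, b = b1$db)
  g
}

## Weighted binary cross entropy with logits; returns mean loss and dloss/dz.
bce_with_logits <- function(z, y, pos_weight) {
  sp <- ifelse(z > 0, log1p(exp(-z)) , log1p(exp(z)) - z)   # log(1 + e^-z)
  loss <- (1 - y) * z + (1 + (pos_weight - 1) * y) * sp
  sig <- 1 / (1 + exp(-z))
  grad <- (sig * (1 + (pos_weight - 1) * y) - pos_weight * y) / length(z)
  list(loss = mean(loss), grad = grad)
}

## One AdamW step over the nested parameter tree.
adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-6, weight_decay = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (ly in names(params)) {
    for (k in seq_along(params[[ly]]$W)) {
      gm <- grads[[ly]]$W[[k]]
      state$m[[ly]]$W[[k]] <- beta1 * state$m[[ly]]$W[[k]] + (1 - beta1) * gm
      state$v[[ly]]$W[[k]] <- beta2 * state$v[[ly]]$W[[k]] + (1 - beta2) * gm^2
      params[[ly]]$W[[k]] <- params[[ly]]$W[[k]] -
        lr * (state$m[[ly]]$W[[k]] / bc1) / (sqrt(state$v[[ly]]$W[[k]] / bc2) + eps) -
        lr * weight_decay * params[[ly]]$W[[k]]
    }
    gb <- grads[[ly]]$b
    state$m[[ly]]$b <- beta1 * state$m[[ly]]$b + (1 - beta1) * gb
    state$v[[ly]]$b <- beta2 * state$v[[ly]]$b + (1 - beta2) * gb^2
    params[[ly]]$b <- params[[ly]]$b -
      lr * (state$m[[ly]]$b / bc1) / (sqrt(state$v[[ly]]$b / bc2) + eps)
  }
  list(params = params, state = state)
}

zero_like <- function(params) {
  lapply(params, function(ly) list(
    W = lapply(ly$W, function(w) w * 0), b = ly$b * 0))
}

#' Training configuration for the segmentation network
#'
#' Defaults record the full-scale protocol (learning rate 1e-6, Adam epsilon
#' 1e-6, weight decay 0.01, positive-class weight 5.0, 512-px tiles); desk
#' runs override the learning rate and tile size.
#'
#' @param base_learning_rate AdamW learning rate.
#' @param adam_epsilon AdamW epsilon stabilizer.
#' @param weight_decay decoupled weight decay coefficient.
#' @param positive_class_weight loss weight on tissue pixels.
#' @param tile_size_px training tile edge; must be a multiple of 4 (the
#'   network has two 2x downsamplings).
#' @param patience early-stopping patience in epochs without validation-F1
#'   improvement.
#' @param max_epochs epoch budget (0 returns the initial weights).
#' @param batch_size tiles per optimizer update (gradients are averaged
#'   over the batch).
#' @param lr_schedule `"constant"` or `"cosine"` (cosine anneal of the
#'   learning rate to zero over `max_epochs`).
#' @param seed RNG seed covering initialization, shuffling and augmentation.
#' @param channel_widths encoder widths of the three scales.
#' @return object of class `train_config`.
#' @export
train_config <- function(base_learning_rate = 1e-6, adam_epsilon = 1e-6,
                         weight_decay = 0.01, positive_class_weight = 5.0,
                         tile_size_px = 512L, patience = 5L, max_epochs = 20L,
                         batch_size = 1L,
                         lr_schedule = c("constant", "cosine"), seed = 1L,
                         channel_widths = c(8L, 16L, 32L)) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(base_learning_rate > 0, adam_epsilon > 0, weight_decay >= 0,
            positive_class_weight > 0, tile_size_px %% 4 == 0,
            patience >= 0, max_epochs >= 0, batch_size >= 1,
            length(channel_widths) == 3)
  structure(list(base_learning_rate = base_learning_rate,
                 adam_epsilon = adam_epsilon, weight_decay = weight_decay,
                 positive_class_weight = positive_class_weight,
                 tile_size_px = as.integer(tile_size_px),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 lr_schedule = lr_schedule, seed = as.integer(seed),
                 channel_widths = as.integer(channel_widths)),
            class = "train_config")
}

#' Augmentation policy
#'
#' @param flips random horizontal/vertical flips.
#' @param rotations_90 random multiples of 90 degrees.
#' @param color_jitter_strength in [0, 1]; scales per-channel gain and
#'   brightness jitter.
#' @return object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(flips = TRUE, rotations_90 = TRUE,
                                color_jitter_strength = 0.1) {
  stopifnot(color_jitter_strength >= 0, color_jitter_strength <= 1)
  structure(list(flips = flips, rotations_90 = rotations_90,
                 color_jitter_strength = color_jitter_strength),
            class = "augmentation_policy")
}

rot90a <- function(x, k) {
  k <- k %% 4
  for (i in seq_len(k)) {
    d <- dim(x)
    x <- aperm(x, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  }
  x
}

apply_augmentation <- function(tile, augs) {
  x <- tile$x; y <- tile$y
  y3 <- array(y, c(dim(y), 1))
  if (isTRUE(augs$flips)) {
    if (runif(1) < 0.5) { x <- x[dim(x)[1]:1, , , drop = FALSE]; y3 <- y3[dim(y3)[1]:1, , , drop = FALSE] }
    if (runif(1) < 0.5) { x <- x[, dim(x)[2]:1, , drop = FALSE]; y3 <- y3[, dim(y3)[2]:1, , drop = FALSE] }
  }
  if (isTRUE(augs$rotations_90) && dim(x)[1] == dim(x)[2]) {
    k <- sample(0:3, 1)
    x <- rot90a(x, k); y3 <- rot90a(y3, k)
  }
  s <- augs$color_jitter_strength
  if (s > 0) {
    gain <- 1 + 0.2 * s * runif(3, -1, 1)
    shift <- 0.1 * s * runif(1, -1, 1)
    for (ch in 1:3) x[, , ch] <- pmin(1, pmax(0, x[, , ch] * gain[ch] + shift))
  }
  list(x = x, y = matrix(y3, dim(y3)[1], dim(y3)[2]))
}

## Global-pixel-pool F1 of thresholded predictions over a tile list.
pooled_f1 <- function(params, tiles) {
  tp <- fp <- fn <- 0
  for (t in tiles) {
    pred <- unet_forward(params, t$x)$logits > 0
    y <- t$y > 0.5
    tp <- tp + sum(pred & y); fp <- fp + sum(pred & !y); fn <- fn + sum(!pred & y)
  }
  if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
}

#' Train the segmentation network
#'
#' Optimizes pixel-wise weighted binary cross entropy with AdamW, one tile
#' per update, shuffling tiles each epoch. After every epoch the global
#' pixel-pool F1 on the validation tiles decides early stopping: the
#' checkpoint with the best validation F1 is kept and training stops after
#' `patience` epochs without improvement. Fully seeded.
#'
#' @param train_tiles,val_tiles lists of `list(x = H x W x 3 array,
#'   y = H x W binary matrix)`; the validation list must be non-empty.
#' @param config a [train_config()].
#' @param augs an [augmentation_policy()].
#' @return object of class `seg_checkpoint`: best weights, the config, the
#'   best validation F1 and its epoch, and a per-epoch training log.
#' @export
train_segmenter <- function(train_tiles, val_tiles, config = train_config(),
                            augs = augmentation_policy()) {
  if (length(train_tiles) == 0) td_stop("empty_training_set", "no training tiles")
  if (length(val_tiles) == 0) td_stop("empty_training_set", "no validation tiles")

  with_seed(config$seed, {
    params <- init_unet(config$channel_widths)
    state <- list(m = zero_like(params), v = zero_like(params), t = 0L)
    best <- list(params = params, f1 = pooled_f1(params, val_tiles), epoch = 0L)
    log <- data.frame(epoch = 0L, mean_loss = NA_real_, val_f1 = best$f1)
    since_best <- 0L

    accumulate <- function(acc, g, w) {
      if (is.null(acc)) return(lapply(g, function(ly)
        list(W = lapply(ly$W, `*`, w), b = ly$b * w)))
      for (ly in names(g)) {
        for (k in seq_along(g[[ly]]$W))
          acc[[ly]]$W[[k]] <- acc[[ly]]$W[[k]] + w * g[[ly]]$W[[k]]
        acc[[ly]]$b <- acc[[ly]]$b + w * g[[ly]]$b
      }
      acc
    }

    for (ep in seq_len(config$max_epochs)) {
      lr_ep <- if (identical(config$lr_schedule, "cosine"))
        config$base_learning_rate * 0.5 *
          (1 + cos(pi * (ep - 1) / config$max_epochs))
      else config$base_learning_rate
      losses <- numeric(0)
      order <- sample(length(train_tiles))
      batches <- split(order, ceiling(seq_along(order) / config$batch_size))
      for (batch in batches) {
        acc <- NULL
        for (i in batch) {
          tl <- apply_augmentation(train_tiles[[i]], augs)
          fw <- unet_forward(params, tl$x, keep_cache = TRUE)
          lb <- bce_with_logits(fw$logits, (tl$y > 0.5) * 1,
                                config$positive_class_weight)
          losses <- c(losses, lb$loss)
          grads <- unet_backward(params, fw$cache, lb$grad)
          acc <- accumulate(acc, grads, 1 / length(batch))
        }
        upd <- adamw_step(params, acc, state, lr = lr_ep,
                          eps = config$adam_epsilon,
                          weight_decay = config$weight_decay)
        params <- upd$params; state <- upd$state
      }
      f1 <- pooled_f1(params, val_tiles)
      log <- rbind(log, data.frame(epoch = ep, mean_loss = mean(losses), val_f1 = f1))
      if (f1 > best$f1) {
        best <- list(params = params, f1 = f1, epoch = ep)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience && config$patience > 0) break
      }
    }
    structure(list(weights = best$params, config = config,
                   val_f1 = best$f1, epoch = best$epoch, log = log),
              class = "seg_checkpoint")
  })
}

#' Mirror-pad a raster to a multiple of the tile size
#'
#' Pads reflectively to the smallest multiple of `tile_size` at least the
#' current size, splitting the padding as evenly as possible with the extra
#' pixel on the bottom/right. The top-left offset of the original content is
#' attached as attribute `"offset"` (0-based `c(row, col)`).
#'
#' @param raster matrix or H x W x C array.
#' @param tile_size target multiple.
#' @return padded raster with attribute `offset`.
#' @export
mirror_pad <- function(raster, tile_size) {
  d <- dim(raster)
  H <- d[1]; W <- d[2]
  stopifnot(H >= 1, W >= 1, tile_size >= 1)
  Ph <- ceiling(H / tile_size) * tile_size
  Pw <- ceiling(W / tile_size) * tile_size
  top <- floor((Ph - H) / 2); left <- floor((Pw - W) / 2)
  refl <- function(i, n) {          # half-sample symmetric, any pad width
    i <- i %% (2L * n)
    i[i < 0] <- i[i < 0] + 2L * n
    ifelse(i >= n, 2L * n - 1L - i, i)
  }
  ri <- refl((0:(Ph - 1)) - top, H) + 1L
  ci <- refl((0:(Pw - 1)) - left, W) + 1L
  out <- if (length(d) == 2) raster[ri, ci, drop = FALSE]
  else raster[ri, ci, , drop = FALSE]
  attr(out, "offset") <- c(top, left)
  out
}

#' Kept-region layout of overlap-discard tiling along one axis
#'
#' For a padded extent `extent`, tile edge `tile` and per-edge overlap
#' `overlap` (stride `tile - 2 * overlap`), returns each tile's start and
#' the half-open interval of output pixels it contributes: interiors keep
#' only the central band, border tiles additionally keep their outer margin,
#' so the intervals partition `[0, extent)` exactly.
#'
#' @param extent padded axis length (multiple of `tile`).
#' @param tile tile edge in pixels.
#' @param overlap per-edge overlap in pixels; `tile - 2*overlap` must be a
#'   positive divisor of `tile`.
#' @return data.frame with 0-based columns `start`, `keep_from`, `keep_to`.
#' @export
overlap_discard_regions <- function(extent, tile, overlap) {
  stride <- tile - 2L * overlap
  if (stride <= 0) td_stop("invalid_tiling", "overlap too large: stride must be positive")
  if (tile %% stride != 0)
    td_stop("invalid_tiling", "stride must divide the tile size for exact coverage")
  stopifnot(extent %% tile == 0)
  starts <- seq.int(0L, extent - tile, by = stride)
  keep_from <- pmax(starts, starts + overlap)
  keep_to <- pmin(extent, starts + tile - overlap)
  keep_from[1] <- 0L
  keep_to[length(starts)] <- extent
  data.frame(start = starts, keep_from = keep_from, keep_to = keep_to)
}

#' Predict a tissue mask with overlap-discard tiled inference
#'
#' Operates at the mask resolution: mirror-pads the slide's 8.0 um/px level
#' to a multiple of the tile size, runs the network on tiles spaced
#' `tile - 2*overlap` apart, discards each interior tile's unreliable
#' `overlap`-wide border (image-border margins are kept: no neighbor
#' exists), assembles a mask covering every pixel exactly once, and
#' binarizes probabilities at 0.5 (logit 0).
#'
#' @param slide a `slide_pyramid`.
#' @param checkpoint a `seg_checkpoint` from [train_segmenter()].
#' @param overlap per-edge overlap in pixels; defaults to a quarter of the
#'   tile size (128 for 512-px tiles).
#' @param mask_mpp operating resolution.
#' @return a [tissue_mask()] with `method = "learned"`.
#' @export
predict_mask <- function(slide, checkpoint, overlap = NULL, mask_mpp = 8.0) {
  stopifnot(inherits(checkpoint, "seg_checkpoint"))
  tile <- checkpoint$config$tile_size_px
  overlap <- as.integer(overlap %||% (tile / 4))
  rgb <- get_level(slide, mask_mpp)
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  padded <- mirror_pad(rgb, tile)
  off <- attr(padded, "offset")
  Ph <- dim(padded)[1]; Pw <- dim(padded)[2]
  ry <- overlap_discard_regions(Ph, tile, overlap)
  rx <- overlap_discard_regions(Pw, tile, overlap)
  out <- matrix(FALSE, Ph, Pw)
  for (a in seq_len(nrow(ry))) for (b in seq_len(nrow(rx))) {
    ys <- ry$start[a]; xs <- rx$start[b]
    tl <- padded[(ys + 1):(ys + tile), (xs + 1):(xs + tile), , drop = FALSE]
    pred <- unet_forward(checkpoint$weights, tl)$logits > 0
    kr <- (ry$keep_from[a] + 1):ry$keep_to[a]
    kc <- (rx$keep_from[b] + 1):rx$keep_to[b]
    out[kr, kc] <- pred[kr - ys, kc - xs]
  }
  mask <- out[(off[1] + 1):(off[1] + H), (off[2] + 1):(off[2] + W)]
  tissue_mask(mask, mask_mpp, "learned", slide$slide_id)
}

#' Model selection by sensitivity under a precision floor
#'
#' Picks the candidate with the highest sensitivity among those whose
#' precision is at least 0.90 (precision below 90% is deemed unacceptable).
#' Ties go to the higher precision, then to the earlier candidate.
#'
#' @param candidates list of `c(sensitivity, precision)` pairs or a 2-column
#'   matrix.
#' @param precision_floor minimum acceptable precision.
#' @return index of the selected candidate.
#' @export
select_best_model <- function(candidates, precision_floor = 0.90) {
  if (is.list(candidates)) candidates <- do.call(rbind, candidates)
  stopifnot(is.matrix(candidates), ncol(candidates) == 2, nrow(candidates) >= 1)
  ok <- candidates[, 2] >= precision_floor
  if (!any(ok)) td_stop("no_qualifying_model",
                        "no candidate reaches precision %.2f", precision_floor)
  idx <- which(ok)
  ord <- order(-candidates[idx, 1], -candidates[idx, 2], idx)
  idx[ord[1]]
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds its full configuration; reloading reproduces
#' identical predictions.
#'
#' @param checkpoint a `seg_checkpoint`.
#' @param path file path.
#' @return `load_checkpoint` returns the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "seg_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck, "seg_checkpoint"))
  ck
}

#' @export
print.seg_checkpoint <- function(x, ...) {
  cat(sprintf("<seg_checkpoint> epoch %d, val F1 %.4f, widths %s, tile %d\n",
              x$epoch, x$val_f1, paste(x$config$channel_widths, collapse = "/"),
              x$config$tile_size_px))
  invisible(x)
}
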