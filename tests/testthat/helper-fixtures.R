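# Shared fixtures, memoized so expensive objects (generated slides, the
# trained checkpoint) are built once per test run.

fixtures <- new.env(parent = emptyenv())

fx_manifest <- function() {
  if (is.null(fixtures$man)) fixtures$man <- standard_cohort_manifest()
  fixtures$man
}

# Small bank of generated slides covering the data regimes.
fx_bank <- function() {
  if (is.null(fixtures$bank)) {
    specs <- list(
      lesion2 = synthetic_slide_spec(seed = 101, slide_id = "b1",
                                     lesion = list(isup_grade = 2, area_fraction = 0.35)),
      plain   = synthetic_slide_spec(seed = 102, slide_id = "b2"),
      pale    = synthetic_slide_spec(seed = 103, slide_id = "b3",
                                     color_profile = "pale"),
      debris  = synthetic_slide_spec(seed = 104, slide_id = "b4",
                                     artifacts = "debris"),
      pen     = synthetic_slide_spec(seed = 105, slide_id = "b5",
                                     artifacts = "pen_mark"),
      lesion5 = synthetic_slide_spec(seed = 106, slide_id = "b6",
                                     lesion = list(isup_grade = 5, area_fraction = 0.4)))
    fixtures$bank <- lapply(specs, generate_slide)
  }
  fixtures$bank
}

fx_checkpoint <- function() {
  if (is.null(fixtures$ckpt))
    fixtures$ckpt <- train_standard_segmenter(fx_manifest(), seed = 1L)
  fixtures$ckpt
}

# Independent exhaustive-search oracle for Otsu's threshold: evaluates the
# between-class variance of every cut directly from first principles.
otsu_brute <- function(counts) {
  best_t <- NA_integer_; best_v <- -Inf
  lv <- 0:255
  for (t in 0:254) {
    n0 <- sum(counts[1:(t + 1)]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:(t + 1)] * lv[1:(t + 1)]) / n0
    mu1 <- sum(counts[(t + 2):256] * lv[(t + 2):256]) / n1
    v <- (n0 / sum(counts)) * (n1 / sum(counts)) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# Independently coded direct-formula oracle for quadratic weighted kappa
# (explicit loops over the category grid).
qwk_oracle <- function(ref, pred, categories = 0:5) {
  n <- length(ref)
  num <- 0; den <- 0
  for (i in seq_along(categories)) for (j in seq_along(categories)) {
    w <- (i - j)^2
    o <- sum(ref == categories[i] & pred == categories[j])
    e <- sum(ref == categories[i]) * sum(pred == categories[j]) / n
    num <- num + w * o
    den <- den + w * e
  }
  if (den == 0) 1 else 1 - num / den
}

# Checkpoint whose network is a pure per-pixel function of the red channel
# (threshold at 0.5), routed through the skip connections only.
pixel_local_checkpoint <- function(tile_size = 64L) {
  widths <- c(2L, 2L, 2L)
  zero_conv <- function(cin, cout, k = 3) {
    n <- if (k == 3) 9 else 1
    list(W = lapply(seq_len(n), function(i) matrix(0, cin, cout)),
         b = numeric(cout))
  }
  p <- list(enc1 = zero_conv(6, 2), enc2 = zero_conv(2, 2),
            bott = zero_conv(2, 2), dec2 = zero_conv(4, 2),
            dec1 = zero_conv(4, 2), head = zero_conv(2, 1, k = 1))
  p$enc1$W[[5]][1, 1] <- 1              # center tap: red channel -> feature 1
  p$dec1$W[[5]][3, 1] <- 1              # skip branch (A1 channel 1) -> out 1
  p$head$W[[1]][1, 1] <- 1
  p$head$b <- -0.5
  structure(list(weights = p,
                 config = train_config(tile_size_px = tile_size,
                                       channel_widths = widths),
                 val_f1 = NA_real_, epoch = 0L, log = NULL),
            class = "seg_checkpoint")
}

# Four tiny overfit tiles: a colored disc on a light background.
toy_tiles <- function(n = 4, size = 32L) {
  lapply(seq_len(n), function(k) {
    cx <- 8 + 4 * k; cy <- 10 + 3 * k; r <- 6 + k
    g <- expand.grid(i = seq_len(size), j = seq_len(size))
    disc <- matrix((g$i - cy)^2 + (g$j - cx)^2 <= r^2, size, size)
    x <- array(0.93, c(size, size, 3))
    x[, , 1][disc] <- 0.75; x[, , 2][disc] <- 0.50; x[, , 3][disc] <- 0.68
    list(x = x, y = disc * 1)
  })
}
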