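## Separable Lanczos resampling.
##
## Pyramid levels and grading patches are produced by windowed-sinc (Lanczos)
## resampling, the standard high-quality filter for microscopy downsampling.
## The filter is separable, so a resize is two banded linear operators:
## out = W_rows %*% img %*% t(W_cols). The operators are sparse (support
## ~ 2 * a * scale taps per output pixel), built with Matrix.

lanczos_kernel <- function(x, a = 3) {
  out <- numeric(length(x))
  nz <- abs(x) < a & x != 0
  out[x == 0] <- 1
  xs <- x[nz]
  out[nz] <- a * sin(pi * xs) * sin(pi * xs / a) / (pi^2 * xs^2)
  out
}

## Sparse (n_out x n_in) Lanczos interpolation matrix. For downsampling
## (scale > 1) the kernel is dilated by the scale factor so it acts as a
## proper low-pass filter. Rows are normalized to sum to one, so constants
## are preserved exactly. Source indices are reflected at the borders.
lanczos_matrix <- function(n_in, n_out, a = 3) {
  scale <- n_in / n_out
  s <- max(1, scale)
  support <- a * s
  centers <- (seq_len(n_out) - 0.5) * scale - 0.5   # 0-based source coords
  lo <- floor(centers - support) + 1
  hi <- ceiling(centers + support) - 1
  width <- max(hi - lo) + 1L
  offs <- seq_len(width) - 1L
  src <- outer(lo, offs, `+`)                        # n_out x width, 0-based
  w <- lanczos_kernel((src - centers) / s, a)
  dim(w) <- dim(src)
  w <- w / rowSums(w)
  ## reflect out-of-range source indices (half-sample symmetric)
  refl <- function(i, n) {
    i <- i %% (2L * n)
    i[i < 0] <- i[i < 0] + 2L * n
    ifelse(i >= n, 2L * n - 1L - i, i)
  }
  src <- refl(src, n_in)
  Matrix::sparseMatrix(
    i = rep(seq_len(n_out), times = width),
    j = as.integer(src) + 1L,
    x = as.numeric(w),
    dims = c(n_out, n_in)
  )
}

#' Resize a raster with Lanczos resampling
#'
#' Resamples a grayscale matrix or an H x W x C array to the requested output
#' size using a separable Lanczos-3 windowed-sinc filter. For downsampling the
#' kernel support is widened by the scale factor (anti-aliasing); rows of the
#' operator are normalized so constant images are preserved exactly. Values
#' are clamped to [0, 1].
#'
#' @param img numeric matrix or H x W x C array with values in [0, 1].
#' @param out_h,out_w output height and width in pixels.
#' @param a Lanczos window parameter (default 3).
#' @return resized matrix or array of the same channel count.
#' @export
resize_lanczos <- function(img, out_h, out_w, a = 3) {
  stopifnot(out_h >= 1, out_w >= 1)
  d <- dim(img)
  wr <- lanczos_matrix(d[1], out_h, a)
  wc <- lanczos_matrix(d[2], out_w, a)
  one <- function(m) {
    r <- as.matrix(wr %*% m %*% Matrix::t(wc))
    r[r < 0] <- 0
    r[r > 1] <- 1
    r
  }
  if (length(d) == 2) return(one(img))
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- one(img[, , ch])
  out
}
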