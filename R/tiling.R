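## Grading-model tile extraction: grid construction over the mirror-padded
## slide, tissue-fraction filtering against a segmentation mask held at a
## coarser resolution, and Lanczos extraction of tile rasters from the
## pyramid. Tile coordinates are expressed in the slide frame at the tile
## resolution (border tiles of the padded grid can start at negative
## coordinates).

#' Tiling configuration
#'
#' @param mask_mpp resolution of the segmentation mask (um/px).
#' @param tile_mpp resolution at which tiles are extracted.
#' @param tile_size_px tile edge in pixels at `tile_mpp`.
#' @param train_overlap_px per-edge overlap for training grids (0: abutting).
#' @param infer_overlap_px per-edge overlap for inference grids.
#' @param min_tissue_fraction minimum fraction of tissue pixels (from the
#'   mask) for a tile to be kept; the comparison uses "at least 10%".
#' @return object of class `tiling_config`.
#' @export
tiling_config <- function(mask_mpp = 8.0, tile_mpp = 1.0, tile_size_px = 256L,
                          train_overlap_px = 0L, infer_overlap_px = 128L,
                          min_tissue_fraction = 0.10) {
  scale <- mask_mpp / tile_mpp
  if (scale != round(scale) || scale < 1)
    td_stop("invalid_tiling", "mask_mpp / tile_mpp must be a positive integer")
  if (tile_size_px %% scale != 0)
    td_stop("invalid_tiling", "tile_size_px must be divisible by the mask/tile scale factor")
  stopifnot(min_tissue_fraction >= 0, min_tissue_fraction <= 1,
            train_overlap_px >= 0, infer_overlap_px >= 0)
  structure(list(mask_mpp = mask_mpp, tile_mpp = tile_mpp,
                 tile_size_px = as.integer(tile_size_px),
                 train_overlap_px = as.integer(train_overlap_px),
                 infer_overlap_px = as.integer(infer_overlap_px),
                 min_tissue_fraction = min_tissue_fraction,
                 scale = as.integer(scale)),
            class = "tiling_config")
}

#' Tile grid over the mirror-padded slide extent
#'
#' Training grids abut (stride = tile size); inference grids overlap so the
#' unreliable tile borders can be discarded downstream (stride =
#' tile - 2 * overlap, which must be a positive divisor of the tile size).
#' The grid covers the mirror-padded extent; coordinates are 0-based in the
#' slide frame and sorted row-major.
#'
#' @param slide_dims `c(height, width)` in pixels at the tile resolution.
#' @param config a [tiling_config()].
#' @param mode `"train"` or `"infer"`.
#' @return data.frame with columns `x`, `y`; attributes `padded_dims` and
#'   `offset` describe the padded frame.
#' @export
grid_tiles <- function(slide_dims, config, mode = c("train", "infer")) {
  mode <- match.arg(mode)
  stopifnot(all(slide_dims >= 1))
  tile <- config$tile_size_px
  ov <- if (mode == "train") config$train_overlap_px else config$infer_overlap_px
  stride <- tile - 2L * ov
  if (stride <= 0) td_stop("invalid_tiling", "overlap too large: stride must be positive")
  if (tile %% stride != 0)
    td_stop("invalid_tiling", "stride must divide the tile size for exact coverage")
  pad_dim <- function(d) ceiling(d / tile) * tile
  Ph <- pad_dim(slide_dims[1]); Pw <- pad_dim(slide_dims[2])
  top <- floor((Ph - slide_dims[1]) / 2); left <- floor((Pw - slide_dims[2]) / 2)
  ys <- seq.int(0L, Ph - tile, by = stride) - top
  xs <- seq.int(0L, Pw - tile, by = stride) - left
  out <- data.frame(x = rep(xs, times = length(ys)),
                    y = rep(ys, each = length(xs)))
  attr(out, "padded_dims") <- c(Ph, Pw)
  attr(out, "offset") <- c(top, left)
  out
}

#' Tissue fraction of one tile footprint under a mask
#'
#' The tile footprint is mapped onto the (coarser) mask; the fraction is
#' tissue pixels over the footprint's mask-window area. Footprints reaching
#' outside the mask (padded-grid border tiles) are clipped and the fraction
#' is taken over the clipped area; footprints entirely outside give 0.
#'
#' @param mask a [tissue_mask()] at `config$mask_mpp`.
#' @param tile_coord `c(x, y)` at tile resolution (slide frame, 0-based).
#' @param config a [tiling_config()].
#' @return fraction in [0, 1].
#' @export
tile_tissue_fraction <- function(mask, tile_coord, config) {
  s <- config$scale
  w <- config$tile_size_px %/% s
  x0 <- floor(tile_coord[1] / s); y0 <- floor(tile_coord[2] / s)
  rows <- seq.int(y0, y0 + w - 1L); cols <- seq.int(x0, x0 + w - 1L)
  rows <- rows[rows >= 0 & rows < nrow(mask$raster)]
  cols <- cols[cols >= 0 & cols < ncol(mask$raster)]
  if (!length(rows) || !length(cols)) return(0)
  win <- mask$raster[rows + 1L, cols + 1L, drop = FALSE]
  sum(win) / length(win)
}

#' Filter a tile grid by tissue fraction
#'
#' Keeps tiles whose tissue fraction is at least
#' `config$min_tissue_fraction` (inclusive).
#'
#' @param coords data.frame from [grid_tiles()].
#' @param mask a [tissue_mask()].
#' @param config a [tiling_config()].
#' @param slide_id identifier stored in the result.
#' @return object of class `tile_set` with a `tiles` data.frame
#'   (`x`, `y`, `tissue_fraction`).
#' @export
filter_tiles <- function(coords, mask, config, slide_id = mask$slide_id) {
  fr <- vapply(seq_len(nrow(coords)), function(i)
    tile_tissue_fraction(mask, c(coords$x[i], coords$y[i]), config), numeric(1))
  keep <- fr >= config$min_tissue_fraction
  tiles <- data.frame(x = coords$x[keep], y = coords$y[keep],
                      tissue_fraction = fr[keep])
  structure(list(slide_id = slide_id, tiles = tiles, config = config),
            class = "tile_set")
}

#' Extract one tile raster from the pyramid
#'
#' The source level is the one with the largest resolution value (coarsest)
#' that is still at least as fine as the target; the crop is then Lanczos
#' resampled to the tile size. When the target equals an existing level and
#' the footprint is in bounds the crop is returned bit-exactly. Out-of-range
#' source pixels (padded-grid border tiles) are mirrored.
#'
#' @param slide a `slide_pyramid`.
#' @param coord `c(x, y)` at the tile resolution (slide frame, 0-based).
#' @param config a [tiling_config()].
#' @return `tile_size_px` square H x W x 3 array.
#' @export
extract_tile <- function(slide, coord, config) {
  target <- config$tile_mpp; tile <- config$tile_size_px
  mpps <- vapply(slide$levels, `[[`, numeric(1), "mpp")
  cand <- which(mpps <= target)
  if (!length(cand))
    td_stop("invalid_pyramid", "no pyramid level at or finer than %.3g um/px", target)
  src_i <- cand[which.max(mpps[cand])]
  src <- slide$levels[[src_i]]$raster
  f <- target / mpps[src_i]
  stopifnot(abs(f - round(f)) < 1e-9)
  f <- as.integer(round(f))
  n <- tile * f
  rows <- seq.int(coord[2] * f, length.out = n)
  cols <- seq.int(coord[1] * f, length.out = n)
  refl <- function(i, k) {
    i <- i %% (2L * k); i[i < 0] <- i[i < 0] + 2L * k
    ifelse(i >= k, 2L * k - 1L - i, i)
  }
  crop <- src[refl(rows, nrow(src)) + 1L, refl(cols, ncol(src)) + 1L, , drop = FALSE]
  if (f == 1L) crop else resize_lanczos(crop, tile, tile)
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("<tile_set> %s: %d tiles kept (min fraction %.2f)\n",
              x$slide_id, nrow(x$tiles), x$config$min_tissue_fraction))
  invisible(x)
}
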