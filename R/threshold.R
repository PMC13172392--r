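## Classical tissue detection: global Otsu threshold on a downsampled
## channel transform, followed by a parameterized morphological cleanup
## chain (closing -> opening -> small-object removal -> small-hole fill).
## Everything operates at the mask resolution (8.0 um/px by default); the
## full-resolution image is never thresholded.

#' Parameters of the thresholding segmenter
#'
#' @param channel_mode `"luminance_inverted"` (tissue darker than
#'   background; the default) or `"saturation"` (separates weakly stained,
#'   eosin-only tissue better).
#' @param blur_radius_px Gaussian blur sigma (pixels at mask resolution)
#'   applied before histogramming; 0 disables.
#' @param close_radius_px,open_radius_px disc radii of the morphological
#'   closing and opening; 0 disables either stage.
#' @param min_object_area_px connected components smaller than this are
#'   removed (debris suppression).
#' @param max_hole_area_px interior holes smaller than this are filled.
#' @param preset_name label recorded in mask provenance.
#' @return object of class `threshold_params`.
#' @export
threshold_params <- function(channel_mode = c("luminance_inverted", "saturation"),
                             blur_radius_px = 1L, close_radius_px = 2L,
                             open_radius_px = 2L, min_object_area_px = 120L,
                             max_hole_area_px = 200L,
                             preset_name = "uniform") {
  channel_mode <- match.arg(channel_mode)
  stopifnot(blur_radius_px >= 0, close_radius_px >= 0, open_radius_px >= 0,
            min_object_area_px >= 0, max_hole_area_px >= 0)
  structure(list(channel_mode = channel_mode,
                 blur_radius_px = blur_radius_px,
                 close_radius_px = close_radius_px,
                 open_radius_px = open_radius_px,
                 min_object_area_px = min_object_area_px,
                 max_hole_area_px = max_hole_area_px,
                 preset_name = preset_name),
            class = "threshold_params")
}

#' Load named thresholding presets from a JSON file
#'
#' The file maps preset names to [threshold_params()] fields; missing fields
#' take the defaults. A `"uniform"` preset (the single parameter set applied
#' to every slide in the comparison) ships with the package.
#'
#' @param path JSON file; defaults to the preset file installed with the
#'   package.
#' @return named list of `threshold_params`.
#' @export
load_threshold_presets <- function(path = system.file("extdata",
                                                      "threshold_presets.json",
                                                      package = "tissuedetect")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(stats::setNames(names(raw), names(raw)), function(nm) {
    do.call(threshold_params, c(raw[[nm]], list(preset_name = nm)))
  })
}

#' Otsu's threshold from a 256-bin histogram
#'
#' Returns the gray level t (0..254) maximizing the between-class variance
#' of the split into bins `0..t` and `t+1..255`. Ties are broken towards the
#' smallest level. A histogram with all mass in one bin is degenerate: no
#' split exists, and a classed error (`degenerate_histogram`) is thrown so
#' the caller can record a detection failure instead of a mask.
#'
#' @param counts integer vector of 256 bin counts (levels 0..255).
#' @return integer threshold level.
#' @export
otsu_threshold <- function(counts) {
  stopifnot(length(counts) == 256, all(counts >= 0))
  n <- sum(counts)
  if (n < 1) td_stop("degenerate_histogram", "empty histogram")
  if (sum(counts > 0) < 2)
    td_stop("degenerate_histogram", "all histogram mass in one bin")
  levels <- 0:255
  p <- counts / n
  w0 <- cumsum(p)                       # mass of class {0..t}
  mu <- cumsum(p * levels)              # partial first moment
  mu_t <- mu[256]
  t_all <- 1:255                        # candidate cuts t = 0..254
  w0c <- w0[t_all]
  valid <- w0c > 0 & w0c < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0c[valid] - mu[t_all][valid])^2 /
    (w0c[valid] * (1 - w0c[valid]))
  which.max(sigma_b) - 1L               # which.max takes the first maximum
}

## Channel transform: integer image 0..255 in which tissue is bright.
channel_transform <- function(rgb, mode) {
  if (mode == "luminance_inverted") {
    ch <- 1 - luminance(rgb)
  } else {
    mx <- pmax(rgb[, , 1], rgb[, , 2], rgb[, , 3])
    mn <- pmin(rgb[, , 1], rgb[, , 2], rgb[, , 3])
    ch <- ifelse(mx > 0, (mx - mn) / mx, 0)
  }
  matrix(pmin(255L, pmax(0L, as.integer(round(ch * 255)))), nrow(ch), ncol(ch))
}

## Morphological cleanup chain: closing -> opening -> remove objects smaller
## than min_object_area -> fill holes smaller than max_hole_area.
cleanup_mask <- function(mask, params) {
  m <- EBImage::Image(mask * 1)
  if (params$close_radius_px > 0)
    m <- EBImage::closing(m, EBImage::makeBrush(2L * params$close_radius_px + 1L, "disc"))
  if (params$open_radius_px > 0)
    m <- EBImage::opening(m, EBImage::makeBrush(2L * params$open_radius_px + 1L, "disc"))
  m <- EBImage::imageData(m) > 0.5
  if (params$min_object_area_px > 0 && any(m)) {
    lab <- EBImage::bwlabel(EBImage::Image(m * 1))
    lab <- EBImage::imageData(lab)
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= params$min_object_area_px)
    m <- matrix(lab %in% keep, nrow(m), ncol(m)) & lab > 0
  }
  if (params$max_hole_area_px > 0 && any(!m)) {
    ## holes = background components not touching the image border
    lab <- EBImage::bwlabel(EBImage::Image((!m) * 1))
    lab <- EBImage::imageData(lab)
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    areas <- tabulate(lab[lab > 0])
    fill <- setdiff(which(areas < params$max_hole_area_px), border)
    if (length(fill)) m <- m | matrix(lab %in% fill, nrow(m), ncol(m))
  }
  m
}

#' Construct a tissue mask object
#'
#' @param raster logical matrix (TRUE = tissue).
#' @param mpp mask resolution in um/px.
#' @param method provenance: `"threshold"`, `"learned"` or `"truth"`.
#' @param slide_id slide identifier.
#' @param failure logical detection-failure flag; defaults to "no tissue
#'   pixels".
#' @return object of class `tissue_mask`.
#' @export
tissue_mask <- function(raster, mpp, method = c("threshold", "learned", "truth"),
                        slide_id = "slide", failure = !any(raster)) {
  method <- match.arg(method)
  stopifnot(is.matrix(raster), is.logical(raster))
  structure(list(raster = raster, mpp = mpp, method = method,
                 slide_id = slide_id, failure = failure),
            class = "tissue_mask")
}

#' Otsu + morphology tissue segmentation of a slide
#'
#' Extracts (or derives) the 8.0 um/px pyramid level, applies the configured
#' channel transform and blur, thresholds with [otsu_threshold()] (tissue =
#' strictly above the threshold), then runs the morphological cleanup chain.
#' A degenerate histogram (featureless slide) yields an empty mask with the
#' failure flag set rather than an error, mirroring how detection failures
#' are tallied rather than crashed on.
#'
#' @param slide a `slide_pyramid`.
#' @param params a [threshold_params()].
#' @param mask_mpp operating resolution (default 8.0 um/px).
#' @return a [tissue_mask()] with `method = "threshold"`.
#' @export
segment_threshold <- function(slide, params = threshold_params(),
                              mask_mpp = 8.0) {
  rgb <- get_level(slide, mask_mpp)
  ch <- channel_transform(rgb, params$channel_mode)
  if (params$blur_radius_px > 0) {
    ch <- EBImage::imageData(EBImage::gblur(EBImage::Image(ch / 255),
                                            sigma = params$blur_radius_px))
    ch <- matrix(pmin(255L, pmax(0L, as.integer(round(ch * 255)))),
                 nrow(ch), ncol(ch))
  }
  counts <- tabulate(as.vector(ch) + 1L, nbins = 256)
  lev <- tryCatch(otsu_threshold(counts), degenerate_histogram = function(e) NULL)
  if (is.null(lev)) {
    return(tissue_mask(matrix(FALSE, nrow(ch), ncol(ch)), mask_mpp,
                       "threshold", slide$slide_id, failure = TRUE))
  }
  m <- cleanup_mask(ch > lev, params)
  tissue_mask(m, mask_mpp, "threshold", slide$slide_id)
}

#' Detection-failure predicate
#'
#' A segmentation run fails for a slide when it returns a mask with zero
#' tissue pixels.
#'
#' @param mask a `tissue_mask`.
#' @return logical flag.
#' @export
is_detection_failure <- function(mask) {
  stopifnot(inherits(mask, "tissue_mask"))
  !any(mask$raster)
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %s [%s] %d x %d @ %.1f um/px, %d tissue px%s\n",
              x$slide_id, x$method, nrow(x$raster), ncol(x$raster), x$mpp,
              sum(x$raster), if (is_detection_failure(x)) " (FAILURE)" else ""))
  invisible(x)
}
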