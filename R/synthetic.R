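## Synthetic pyramidal slides with exact ground truth.
##
## The generator emulates H&E-stained core-needle biopsy slides at the scale
## the tissue-detection comparison needs: elongated tissue fragments on a
## bright background, an optional low-contrast ("pale") rendering in which
## tissue differs from background only in chroma (luminance-matched, so a
## grayscale Otsu cut has nothing to work with while a color-aware model
## does), pen-mark and debris artifacts that are background in truth, and an
## optional planted lesion region carrying an ISUP grade. Every slide is a
## pure function of its spec (including the seed), so cohorts are
## reproducible slide-by-slide.

# Palette: background and tissue colors in [0,1] sRGB. The pale tissue color
# is constructed to have exactly the background's luminance; its signal is
# carried by chroma alone. Pixel noise is achromatic (shared across
# channels), mimicking sensor luminance noise, so chroma stays clean.
.td_colors <- list(
  background = c(0.956, 0.956, 0.958),
  tissue     = c(0.800, 0.580, 0.700),
  lesion     = c(0.620, 0.440, 0.640),
  pen        = c(0.100, 0.450, 0.250),
  debris     = c(0.250, 0.220, 0.200)
)

.td_pale_tissue <- function() {
  bg <- .td_colors$background
  dr <- 0.035
  bg + c(dr, -0.299 * dr / 0.587, 0)   # luminance-neutral chroma shift
}

#' Specification of one synthetic slide
#'
#' @param width_um,height_um physical slide extent in microns.
#' @param base_mpp microns per pixel of pyramid level 0.
#' @param n_fragments number of tissue fragments (0 gives an empty slide).
#' @param fragment_scale_um characteristic fragment major-axis scale.
#' @param color_profile `"normal"` (clearly stained) or `"pale"`
#'   (luminance-matched, low contrast).
#' @param artifacts character subset of `c("pen_mark", "debris")`.
#' @param lesion optional `list(isup_grade =, area_fraction =)`: a graded
#'   lesion ellipse planted inside the first fragment, its area the given
#'   fraction of that fragment.
#' @param seed integer RNG seed for this slide.
#' @param slide_id,patient_id identifiers carried through the pipeline.
#' @param pale_fragments integer indices of individual fragments rendered
#'   pale even under the normal profile (used to plant missed-fragment
#'   scenarios).
#' @param separability_delta maximum tissue/background luminance gap the
#'   pale rendering is allowed to have (design guarantee, not a fit).
#' @return object of class `synthetic_slide_spec`.
#' @export
synthetic_slide_spec <- function(width_um = 1024, height_um = 1024,
                                 base_mpp = 1.0, n_fragments = 2,
                                 fragment_scale_um = 500,
                                 color_profile = c("normal", "pale"),
                                 artifacts = character(),
                                 lesion = NULL, seed = 1L,
                                 slide_id = "slide", patient_id = slide_id,
                                 pale_fragments = integer(),
                                 separability_delta = 0.02) {
  color_profile <- match.arg(color_profile)
  if (width_um <= 0 || height_um <= 0)
    td_stop("invalid_spec", "slide physical extent must be positive")
  if (base_mpp <= 0) td_stop("invalid_spec", "base_mpp must be positive")
  if (!is_count(n_fragments)) td_stop("invalid_spec", "n_fragments must be a non-negative integer")
  stopifnot(all(artifacts %in% c("pen_mark", "debris", "none")))
  artifacts <- setdiff(artifacts, "none")
  if (!is.null(lesion)) {
    stopifnot(is.list(lesion), !is.null(lesion$isup_grade), !is.null(lesion$area_fraction))
    if (!(lesion$isup_grade %in% 1:5))
      td_stop("invalid_spec", "lesion isup_grade must be in 1..5")
    if (lesion$area_fraction <= 0 || lesion$area_fraction > 1)
      td_stop("invalid_spec", "lesion area_fraction must be in (0, 1]")
    if (n_fragments == 0)
      td_stop("invalid_spec", "a lesion requires at least one tissue fragment")
  }
  structure(list(
    width_um = width_um, height_um = height_um, base_mpp = base_mpp,
    n_fragments = as.integer(n_fragments),
    fragment_scale_um = fragment_scale_um,
    color_profile = color_profile, artifacts = artifacts, lesion = lesion,
    seed = as.integer(seed), slide_id = slide_id, patient_id = patient_id,
    pale_fragments = as.integer(pale_fragments),
    separability_delta = separability_delta
  ), class = "synthetic_slide_spec")
}

## Sparse box-average matrix (n_out x n_in) with fractional edge weights;
## used for area-majority ground-truth rasterization.
box_matrix <- function(n_in, n_out) {
  r <- n_in / n_out
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (i in seq_len(n_out)) {
    s0 <- (i - 1) * r; s1 <- i * r
    j <- seq(floor(s0), ceiling(s1) - 1)
    w <- pmin(s1, j + 1) - pmax(s0, j)
    rows <- c(rows, rep(i, length(j)))
    cols <- c(cols, as.integer(j) + 1L)
    vals <- c(vals, w / r)
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n_out, n_in))
}

## Area fraction of each coarse pixel covered by a fine binary raster.
occupancy_downsample <- function(mask, out_h, out_w) {
  wr <- box_matrix(nrow(mask), out_h)
  wc <- box_matrix(ncol(mask), out_w)
  as.matrix(wr %*% (mask * 1) %*% Matrix::t(wc))
}

## Membership raster of one deformed ellipse on the pixel grid (microns).
ellipse_member <- function(xg, yg, cx, cy, a, b, theta, amps, phases) {
  dx <- xg - cx; dy <- yg - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  rho <- sqrt(u^2 + v^2)
  if (length(amps)) {
    phi <- atan2(v, u)
    r <- 1
    for (m in seq_along(amps)) r <- r + amps[m] * cos((m + 1) * phi + phases[m])
    rho <= r
  } else rho <= 1
}

#' Generate one synthetic slide with ground truth
#'
#' Renders the slide at level-0 resolution, builds the pyramid by Lanczos
#' downsampling, and rasterizes ground truth at 8.0 um/px by area majority
#' (a coarse pixel is tissue if more than half its footprint is covered by
#' the analytic tissue shape). Deterministic for a fixed spec.
#'
#' @param spec a [synthetic_slide_spec()].
#' @param level_mpps pyramid resolutions (um/px), ascending, starting at
#'   `spec$base_mpp`.
#' @param truth_mpp resolution of the ground-truth masks.
#' @return `list(slide = slide_pyramid, truth = ground_truth)`.
#' @export
generate_slide <- function(spec, level_mpps = spec$base_mpp * c(1, 2, 4, 8),
                           truth_mpp = 8.0) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  H0 <- ceiling(spec$height_um / spec$base_mpp)
  W0 <- ceiling(spec$width_um / spec$base_mpp)
  if (H0 < 1 || W0 < 1) td_stop("invalid_spec", "zero-area slide")

  res <- with_seed(derive_seed(spec$seed, spec$slide_id), {
    xg <- matrix(rep((seq_len(W0) - 0.5) * spec$base_mpp, each = H0), H0, W0)
    yg <- matrix(rep((seq_len(H0) - 0.5) * spec$base_mpp, W0), H0, W0)

    tissue <- matrix(FALSE, H0, W0)
    lesion <- matrix(FALSE, H0, W0)
    frag_members <- vector("list", spec$n_fragments)
    frag_geom <- vector("list", spec$n_fragments)

    ## Fragments lie in separate horizontal bands, roughly parallel and
    ## elongated, the way sectioned core-needle biopsies sit on a slide.
    for (k in seq_len(spec$n_fragments)) {
      cy <- (k - 0.5) / spec$n_fragments * spec$height_um +
        rnorm(1, 0, 0.03 * spec$height_um)
      cx <- spec$width_um / 2 + rnorm(1, 0, 0.08 * spec$width_um)
      a <- spec$fragment_scale_um / 2 * runif(1, 0.9, 1.15)
      b <- a * runif(1, 0.45, 0.7)
      b <- min(b, 0.4 * spec$height_um / spec$n_fragments)
      theta <- runif(1, -0.4, 0.4)
      amps <- rnorm(4, 0, 0.04)
      amps <- amps * min(1, 0.12 / max(sum(abs(amps)), 1e-9))
      phases <- runif(4, 0, 2 * pi)
      m <- ellipse_member(xg, yg, cx, cy, a, b, theta, amps, phases)
      frag_members[[k]] <- m
      frag_geom[[k]] <- list(cx = cx, cy = cy, a = a, b = b, theta = theta)
      tissue <- tissue | m
    }

    if (!is.null(spec$lesion)) {
      g <- frag_geom[[1]]
      s <- sqrt(spec$lesion$area_fraction)
      lesion <- ellipse_member(xg, yg, g$cx, g$cy, g$a * s, g$b * s, g$theta,
                               numeric(0), numeric(0))
      lesion <- lesion & frag_members[[1]]
    }

    ## --- compose the RGB image ---
    noise <- matrix(rnorm(H0 * W0, 0, 0.012), H0, W0)   # achromatic
    img <- array(0, c(H0, W0, 3))
    for (ch in 1:3) img[, , ch] <- .td_colors$background[ch]

    smooth_tex <- resize_lanczos(
      matrix(runif(18 * 18, -1, 1), 18, 18) * 0.5 + 0.5, H0, W0)
    smooth_tex <- (smooth_tex - 0.5) * 0.05              # +-0.025, achromatic

    pale_col <- .td_pale_tissue()
    for (k in seq_len(spec$n_fragments)) {
      m <- frag_members[[k]]
      is_pale <- spec$color_profile == "pale" || k %in% spec$pale_fragments
      col <- if (is_pale) pale_col else .td_colors$tissue
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[m] <- col[ch]
        if (!is_pale) plane[m] <- plane[m] + smooth_tex[m]
        img[, , ch] <- plane
      }
    }
    if (any(lesion) && !(spec$color_profile == "pale" || 1L %in% spec$pale_fragments)) {
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[lesion] <- .td_colors$lesion[ch] + smooth_tex[lesion]
        img[, , ch] <- plane
      }
    }

    if ("pen_mark" %in% spec$artifacts) {
      for (s in seq_len(sample(1:2, 1))) {
        theta <- runif(1, 0, pi)
        px <- runif(1, 0.2, 0.8) * spec$width_um
        py <- runif(1, 0.2, 0.8) * spec$height_um
        d <- abs((xg - px) * sin(theta) - (yg - py) * cos(theta))
        pen <- d <= 30 & !tissue
        for (ch in 1:3) {
          plane <- img[, , ch]; plane[pen] <- .td_colors$pen[ch]; img[, , ch] <- plane
        }
      }
    }
    if ("debris" %in% spec$artifacts) {
      for (s in seq_len(8)) {
        cx <- runif(1, 0, spec$width_um); cy <- runif(1, 0, spec$height_um)
        r <- runif(1, 8, 18)
        speck <- ((xg - cx)^2 + (yg - cy)^2) <= r^2 & !tissue
        for (ch in 1:3) {
          plane <- img[, , ch]; plane[speck] <- .td_colors$debris[ch]; img[, , ch] <- plane
        }
      }
    }

    for (ch in 1:3) img[, , ch] <- pmin(1, pmax(0, img[, , ch] + noise))

    list(img = img, tissue = tissue, lesion = lesion)
  })

  slide <- build_pyramid(res$img, spec$base_mpp, level_mpps,
                         slide_id = spec$slide_id, patient_id = spec$patient_id)

  th <- ceiling(H0 * spec$base_mpp / truth_mpp)
  tw <- ceiling(W0 * spec$base_mpp / truth_mpp)
  tissue_gt <- occupancy_downsample(res$tissue, th, tw) >= 0.5
  lesion_gt <- occupancy_downsample(res$lesion, th, tw) >= 0.5 & tissue_gt
  isup <- if (any(lesion_gt)) spec$lesion$isup_grade else 0L

  truth <- structure(list(
    tissue_mask = tissue_gt, lesion_mask = lesion_gt,
    isup_label = as.integer(isup), mpp = truth_mpp, slide_id = spec$slide_id
  ), class = "ground_truth")

  list(slide = slide, truth = truth)
}

#' Build a resolution pyramid by Lanczos downsampling
#'
#' Each requested level is produced from the closest finer level already
#' built, with dimensions equal to the level-0 dimensions scaled by the
#' resolution ratio (rounded up). Upsampling below the base resolution is
#' refused.
#'
#' @param base_raster H x W x 3 array in [0, 1] (pyramid level 0).
#' @param base_mpp resolution of `base_raster` in um/px.
#' @param target_mpps requested level resolutions, each `>= base_mpp`.
#' @param slide_id,patient_id identifiers.
#' @return object of class `slide_pyramid`.
#' @export
build_pyramid <- function(base_raster, base_mpp, target_mpps,
                          slide_id = "slide", patient_id = slide_id) {
  stopifnot(length(dim(base_raster)) == 3)
  target_mpps <- sort(unique(target_mpps))
  if (any(target_mpps < base_mpp))
    td_stop("invalid_pyramid", "target resolution finer than base (no upsampling)")
  H0 <- dim(base_raster)[1]; W0 <- dim(base_raster)[2]
  levels <- list()
  for (mpp in target_mpps) {
    if (mpp == base_mpp) {
      levels[[length(levels) + 1L]] <- list(mpp = mpp, raster = base_raster)
      next
    }
    built_mpps <- vapply(levels, `[[`, numeric(1), "mpp")
    finer <- c(base_mpp, built_mpps)
    src_mpp <- max(finer[finer <= mpp])
    src <- if (src_mpp == base_mpp) base_raster else
      levels[[which(built_mpps == src_mpp)[1]]]$raster
    h <- ceiling(H0 * base_mpp / mpp); w <- ceiling(W0 * base_mpp / mpp)
    levels[[length(levels) + 1L]] <- list(mpp = mpp,
                                          raster = resize_lanczos(src, h, w))
  }
  structure(list(slide_id = slide_id, patient_id = patient_id,
                 levels = levels), class = "slide_pyramid")
}

#' Fetch (or derive) a pyramid level at a given resolution
#'
#' Returns the stored level at `mpp` if present, otherwise derives it by
#' Lanczos downsampling from the closest finer stored level.
#'
#' @param slide a `slide_pyramid`.
#' @param mpp requested resolution.
#' @return H x W x 3 array.
#' @export
get_level <- function(slide, mpp) {
  mpps <- vapply(slide$levels, `[[`, numeric(1), "mpp")
  hit <- which(mpps == mpp)
  if (length(hit)) return(slide$levels[[hit[1]]]$raster)
  finer <- which(mpps < mpp)
  if (!length(finer))
    td_stop("invalid_pyramid", "no pyramid level at or finer than %.3g um/px", mpp)
  src_i <- finer[which.max(mpps[finer])]
  src <- slide$levels[[src_i]]$raster
  base <- slide$levels[[1]]
  h <- ceiling(dim(base$raster)[1] * base$mpp / mpp)
  w <- ceiling(dim(base$raster)[2] * base$mpp / mpp)
  resize_lanczos(src, h, w)
}

#' Patient-level random partition
#'
#' Splits cases into cells so that all cases of a patient fall in the same
#' cell and cell sizes (in patients) match the requested fractions to within
#' rounding. Used to emulate a 30%/70% validation/evaluation split.
#'
#' @param cases data.frame with a `patient_id` column, or a vector of
#'   patient ids (one per case).
#' @param fractions positive fractions summing to one.
#' @param seed RNG seed.
#' @return list of integer case-index vectors, one per fraction.
#' @export
split_by_patient <- function(cases, fractions, seed = 1L) {
  pid <- if (is.data.frame(cases)) cases$patient_id else cases
  if (length(pid) == 0) td_stop("invalid_split", "empty case list")
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions > 0))
  patients <- unique(pid)
  shuffled <- with_seed(seed, sample(patients))
  bounds <- round(cumsum(fractions) * length(patients))
  bounds[length(bounds)] <- length(patients)
  start <- c(0, bounds[-length(bounds)])
  lapply(seq_along(fractions), function(i) {
    cell_pat <- shuffled[seq.int(start[i] + 1, length.out = bounds[i] - start[i])]
    which(pid %in% cell_pat)
  })
}

#' @export
print.slide_pyramid <- function(x, ...) {
  cat("<slide_pyramid>", x$slide_id, "patient", x$patient_id, "\n")
  for (lv in x$levels)
    cat(sprintf("  %.1f um/px: %d x %d\n", lv$mpp,
                dim(lv$raster)[1], dim(lv$raster)[2]))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s: %d tissue px, %d lesion px, ISUP %d @ %.1f um/px\n",
              x$slide_id, sum(x$tissue_mask), sum(x$lesion_mask),
              x$isup_label, x$mpp))
  invisible(x)
}
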