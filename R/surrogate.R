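## Deterministic stand-in for the downstream Gleason grading model.
##
## The surrogate grades a slide purely from how much of the planted lesion
## the kept tiles cover: full coverage reproduces the reference grade, a
## partially covered lesion drops one grade (a missed piece of a lesion
## reads as a lower-grade case), and an uncovered lesion reads as benign.
## Because it is a pure function of the segmentation mask, any downstream
## disagreement between two arms is attributable to tissue detection alone.

#' Surrogate grader configuration
#'
#' @param full_coverage_threshold lesion coverage at or above which the
#'   reference grade is reproduced.
#' @param partial_coverage_threshold coverage at or above which (but below
#'   the full threshold) the grade drops by one, floored at 1; below it the
#'   slide reads benign.
#' @return object of class `surrogate_grader_config`.
#' @export
surrogate_grader_config <- function(full_coverage_threshold = 0.5,
                                    partial_coverage_threshold = 0.1) {
  stopifnot(full_coverage_threshold > 0, full_coverage_threshold <= 1,
            partial_coverage_threshold > 0,
            partial_coverage_threshold < full_coverage_threshold)
  structure(list(full_coverage_threshold = full_coverage_threshold,
                 partial_coverage_threshold = partial_coverage_threshold),
            class = "surrogate_grader_config")
}

## Binary map (at mask resolution) of pixels covered by any kept tile.
tile_coverage_map <- function(tiles, dims, config) {
  s <- config$scale
  w <- config$tile_size_px %/% s
  covered <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_len(nrow(tiles$tiles))) {
    y0 <- floor(tiles$tiles$y[i] / s); x0 <- floor(tiles$tiles$x[i] / s)
    rows <- seq.int(y0, y0 + w - 1L); cols <- seq.int(x0, x0 + w - 1L)
    rows <- rows[rows >= 0 & rows < dims[1]]
    cols <- cols[cols >= 0 & cols < dims[2]]
    if (length(rows) && length(cols)) covered[rows + 1L, cols + 1L] <- TRUE
  }
  covered
}

#' Grade a slide from lesion coverage of its kept tiles
#'
#' @param truth a `ground_truth` (reference tissue/lesion masks and grade).
#' @param tiles a `tile_set` derived from some segmentation mask of the
#'   same slide.
#' @param config a [surrogate_grader_config()].
#' @return integer grade 0..5.
#' @export
surrogate_grade <- function(truth, tiles, config = surrogate_grader_config()) {
  stopifnot(inherits(truth, "ground_truth"), inherits(tiles, "tile_set"))
  if (!any(truth$lesion_mask)) return(0L)
  covered <- tile_coverage_map(tiles, dim(truth$lesion_mask), tiles$config)
  cov <- sum(truth$lesion_mask & covered) / sum(truth$lesion_mask)
  if (cov >= config$full_coverage_threshold) truth$isup_label
  else if (cov >= config$partial_coverage_threshold) max(truth$isup_label - 1L, 1L)
  else 0L
}

#' Statistics configuration for a comparison run
#'
#' @param replicates bootstrap replicates for kappa confidence intervals.
#' @param seed RNG seed for the bootstrap.
#' @param aggregation_unit resampling unit label recorded with the results.
#' @return list.
#' @export
stats_config <- function(replicates = 1000L, seed = 1L,
                         aggregation_unit = c("slide", "location", "patient")) {
  aggregation_unit <- match.arg(aggregation_unit)
  list(replicates = as.integer(replicates), seed = as.integer(seed),
       aggregation_unit = aggregation_unit)
}

#' Segmenter adaptors for comparison runs
#'
#' A segmenter is a function `(slide, truth) -> tissue_mask`. These
#' adaptors wrap the thresholding pipeline, a trained checkpoint, and the
#' ground-truth mask (the last for oracle/identity checks).
#'
#' @param params a [threshold_params()].
#' @return a segmenter function.
#' @export
threshold_segmenter <- function(params = threshold_params()) {
  function(slide, truth) segment_threshold(slide, params)
}

#' @rdname threshold_segmenter
#' @param checkpoint a `seg_checkpoint`.
#' @param overlap inference overlap passed to [predict_mask()].
#' @export
learned_segmenter <- function(checkpoint, overlap = NULL) {
  function(slide, truth) predict_mask(slide, checkpoint, overlap = overlap)
}

#' @rdname threshold_segmenter
#' @export
truth_segmenter <- function() {
  function(slide, truth)
    tissue_mask(truth$tissue_mask, truth$mpp, "truth", slide$slide_id,
                failure = !any(truth$tissue_mask))
}

#' Run the two-arm downstream grading comparison
#'
#' For every slide in the cohort: segment with both arms, flag detection
#' failures, tile and filter each arm's mask, and grade each arm with the
#' coverage surrogate. Slides where either arm failed to detect tissue are
#' excluded from the grading comparison and tallied in the paired failure
#' table. On the included slides the run reports each arm's quadratic
#' weighted kappa against the reference grades with a bootstrap confidence
#' interval, and the discordance summary between the arms.
#'
#' @param cohort list of `synthetic_slide_spec` objects (slides are
#'   generated on the fly) or of `list(slide =, truth =)` pairs.
#' @param segmenter_A,segmenter_B segmenter functions
#'   (`(slide, truth) -> tissue_mask`); A and B label the arms throughout.
#' @param tiling a [tiling_config()].
#' @param grader a [surrogate_grader_config()].
#' @param stats a [stats_config()].
#' @return object of class `grading_comparison`: per-slide table, per-arm
#'   kappa results, discordance summary, failure table and summary.
#' @export
run_comparison <- function(cohort, segmenter_A, segmenter_B,
                           tiling = tiling_config(infer_overlap_px = 64L),
                           grader = surrogate_grader_config(),
                           stats = stats_config()) {
  if (length(cohort) == 0) td_stop("empty_cohort", "empty cohort")
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    item <- cohort[[i]]
    if (inherits(item, "synthetic_slide_spec")) item <- generate_slide(item)
    slide <- item$slide; truth <- item$truth
    mA <- segmenter_A(slide, truth)
    mB <- segmenter_B(slide, truth)
    fA <- is_detection_failure(mA); fB <- is_detection_failure(mB)
    included <- !fA && !fB
    gA <- gB <- NA_integer_
    if (included) {
      l0 <- slide$levels[[1]]
      dims_tile <- ceiling(dim(l0$raster)[1:2] * l0$mpp / tiling$tile_mpp)
      grid <- grid_tiles(dims_tile, tiling, mode = "infer")
      gA <- surrogate_grade(truth, filter_tiles(grid, mA, tiling), grader)
      gB <- surrogate_grade(truth, filter_tiles(grid, mB, tiling), grader)
    }
    rows[[i]] <- data.frame(slide_id = slide$slide_id,
                            patient_id = slide$patient_id,
                            ref_grade = truth$isup_label,
                            fail_A = fA, fail_B = fB, included = included,
                            grade_A = gA, grade_B = gB)
  }
  per_slide <- do.call(rbind, rows)

  ftab <- paired_failure_table(per_slide$fail_A, per_slide$fail_B,
                               per_slide$slide_id)
  inc <- per_slide[per_slide$included, ]

  kappa_arm <- function(pred, arm_seed) {
    point <- quadratic_weighted_kappa(inc$ref_grade, pred)
    ci <- bootstrap_ci(function(idx) {
      tryCatch(quadratic_weighted_kappa(inc$ref_grade[idx], pred[idx]),
               tissuedetect_error = function(e) NA_real_)
    }, n_cases = nrow(inc), replicates = stats$replicates, seed = arm_seed)
    list(point = point, ci = c(ci$lower, ci$upper),
         replicates = stats$replicates, seed = arm_seed,
         aggregation_unit = stats$aggregation_unit)
  }

  structure(list(
    per_slide = per_slide,
    kappa_A = kappa_arm(inc$grade_A, stats$seed),
    kappa_B = kappa_arm(inc$grade_B, stats$seed + 1L),
    discordance = discordance(inc$grade_A, inc$grade_B, inc$ref_grade),
    failure_table = ftab,
    failure_summary = summarize_failures(ftab),
    n_included = nrow(inc), n_excluded = sum(!per_slide$included)
  ), class = "grading_comparison")
}

#' @export
print.grading_comparison <- function(x, ...) {
  cat(sprintf("<grading_comparison> %d slides: %d included, %d excluded\n",
              nrow(x$per_slide), x$n_included, x$n_excluded))
  cat(sprintf("  QWK arm A: %.3f (%.3f, %.3f)\n", x$kappa_A$point,
              x$kappa_A$ci[1], x$kappa_A$ci[2]))
  cat(sprintf("  QWK arm B: %.3f (%.3f, %.3f)\n", x$kappa_B$point,
              x$kappa_B$ci[1], x$kappa_B$ci[2]))
  cat(sprintf("  discordant: %d/%d\n", x$discordance$n_discordant,
              x$n_included))
  invisible(x)
}
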