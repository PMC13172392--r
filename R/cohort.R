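## The standard synthetic study cohort.
##
## A fixed-composition cohort of synthetic slides emulating the regimes the
## comparison needs: clearly stained slides (most), luminance-matched pale
## slides (the regime where a grayscale threshold has nothing to cut on),
## pen-marked and debris-bearing slides, and planted lesions across ISUP
## grades. Training slides are kept separate; the curated remainder is
## split 30%/70% at patient level into validation and evaluation, the
## split used for early stopping and model selection.

cohort_profiles <- function(n, lesion_every = 3L) {
  ## cycle profiles so every split cell sees each regime
  kinds <- rep(c("normal", "pale", "normal", "pen_mark", "normal", "pale",
                 "normal", "debris"), length.out = n)
  grades <- rep(c(2L, 0L, 4L, 1L, 3L, 5L, 0L, 2L, 1L, 3L), length.out = n)
  data.frame(kind = kinds, grade = grades)
}

#' Manifest of the standard synthetic cohort
#'
#' Builds a reproducible cohort of `n_train` training slides plus
#' `n_curated` curated slides; the curated block is split 30%/70% at
#' patient level (one patient per slide) into validation and evaluation
#' roles. Columns: `slide_id`, `patient_id`, `role`, `color_profile`,
#' `artifacts`, `isup_label`, `seed`.
#'
#' @param seed master cohort seed; every slide derives its own stream.
#' @param n_train,n_curated block sizes (defaults give a 30-slide
#'   evaluation cell).
#' @return data.frame manifest.
#' @export
standard_cohort_manifest <- function(seed = 20240101L, n_train = 24L,
                                     n_curated = 43L) {
  n <- n_train + n_curated
  prof <- cohort_profiles(n)
  man <- data.frame(
    slide_id = sprintf("S%03d", seq_len(n)),
    patient_id = sprintf("P%03d", seq_len(n)),
    role = NA_character_,
    color_profile = ifelse(prof$kind == "pale", "pale", "normal"),
    artifacts = ifelse(prof$kind %in% c("pen_mark", "debris"), prof$kind, ""),
    isup_label = prof$grade,
    seed = vapply(seq_len(n), function(i) derive_seed(seed, sprintf("S%03d", i)),
                  integer(1)),
    stringsAsFactors = FALSE
  )
  man$role[seq_len(n_train)] <- "train"
  curated <- man[(n_train + 1):n, ]
  cells <- split_by_patient(curated, c(0.3, 0.7), seed = seed)
  man$role[n_train + cells[[1]]] <- "val"
  man$role[n_train + cells[[2]]] <- "eval"
  man
}

#' Slide spec for one manifest row
#'
#' @param row one-row data.frame from [standard_cohort_manifest()].
#' @return a [synthetic_slide_spec()].
#' @export
spec_from_manifest <- function(row) {
  lesion <- if (row$isup_label > 0)
    list(isup_grade = row$isup_label, area_fraction = 0.35) else NULL
  synthetic_slide_spec(
    color_profile = row$color_profile,
    artifacts = if (nzchar(row$artifacts)) strsplit(row$artifacts, "\\|")[[1]] else character(),
    lesion = lesion, seed = row$seed,
    slide_id = row$slide_id, patient_id = row$patient_id
  )
}

#' Training/validation tiles for the segmentation network
#'
#' Generates each slide of the requested role, takes its 8.0 um/px level and
#' ground-truth tissue mask, mirror-pads both to a multiple of the tile
#' size and cuts an abutting (training-mode) tile grid.
#'
#' @param manifest cohort manifest.
#' @param role `"train"` or `"val"`.
#' @param tile_size tile edge in pixels at 8.0 um/px.
#' @return list of `list(x = array, y = matrix)` tiles.
#' @export
build_segmentation_tiles <- function(manifest, role = "train", tile_size = 128L) {
  rows <- manifest[manifest$role == role, ]
  tiles <- list()
  for (i in seq_len(nrow(rows))) {
    gen <- generate_slide(spec_from_manifest(rows[i, ]))
    x <- mirror_pad(get_level(gen$slide, 8.0), tile_size)
    y <- mirror_pad(gen$truth$tissue_mask * 1, tile_size)
    nh <- dim(x)[1] %/% tile_size; nw <- dim(x)[2] %/% tile_size
    for (a in seq_len(nh)) for (b in seq_len(nw)) {
      ri <- ((a - 1) * tile_size + 1):(a * tile_size)
      ci <- ((b - 1) * tile_size + 1):(b * tile_size)
      tiles[[length(tiles) + 1L]] <- list(x = x[ri, ci, , drop = FALSE],
                                          y = y[ri, ci])
    }
  }
  tiles
}

#' Desk-scale training configuration
#'
#' The full-scale defaults of [train_config()] (learning rate 1e-6, 512-px
#' tiles) are impractical for the small synthetic slides; this override
#' trains 128-px tiles with a cosine-annealed learning rate while keeping
#' the loss, optimizer family, positive-class weight and
#' best-validation-F1 checkpointing of the protocol.
#'
#' @param seed RNG seed.
#' @param max_epochs epoch budget (the cosine anneal spans it; patience is
#'   set to the budget so checkpoint selection, not early exit, decides).
#' @return a [train_config()].
#' @export
desk_train_config <- function(seed = 1L, max_epochs = 40L) {
  train_config(base_learning_rate = 2e-3, tile_size_px = 128L,
               patience = max_epochs, max_epochs = max_epochs,
               batch_size = 1L, lr_schedule = "cosine", seed = seed,
               channel_widths = c(8L, 16L, 32L))
}

#' Train the desk-scale segmenter on the standard cohort
#'
#' Builds training and validation tiles from the manifest and trains with
#' [desk_train_config()] and mild color jitter.
#'
#' @param manifest cohort manifest from [standard_cohort_manifest()].
#' @param seed training seed.
#' @param max_epochs epoch budget.
#' @return a `seg_checkpoint`.
#' @export
train_standard_segmenter <- function(manifest, seed = 1L, max_epochs = 40L) {
  tr <- build_segmentation_tiles(manifest, "train")
  va <- build_segmentation_tiles(manifest, "val")
  train_segmenter(tr, va, desk_train_config(seed, max_epochs),
                  augmentation_policy(color_jitter_strength = 0.05))
}

#' Per-slide segmentation metrics over a cohort role
#'
#' Generates each slide of the role, applies the segmenter and computes
#' pixel metrics against ground truth plus the detection-failure flag.
#'
#' @param manifest cohort manifest.
#' @param segmenter function `(slide, truth) -> tissue_mask`.
#' @param role cohort role to evaluate.
#' @return data.frame: slide_id, color_profile, artifacts, sensitivity,
#'   precision, undefined_precision_flag, failure.
#' @export
evaluate_segmenter <- function(manifest, segmenter, role = "eval") {
  rows <- manifest[manifest$role == role, ]
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    gen <- generate_slide(spec_from_manifest(rows[i, ]))
    mask <- segmenter(gen$slide, gen$truth)
    ref <- tissue_mask(gen$truth$tissue_mask, gen$truth$mpp, "truth",
                       gen$slide$slide_id)
    pm <- pixel_metrics(mask, ref)
    out[[i]] <- data.frame(slide_id = rows$slide_id[i],
                           color_profile = rows$color_profile[i],
                           artifacts = rows$artifacts[i],
                           sensitivity = pm$sensitivity,
                           precision = pm$precision,
                           undefined_precision_flag = pm$undefined_precision_flag,
                           failure = is_detection_failure(mask))
  }
  do.call(rbind, out)
}
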