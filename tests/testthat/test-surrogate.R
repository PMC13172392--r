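# Hand-built ground truth: 32 x 32 mask at 8 um/px with a 16 x 16 lesion
# block; tiles are 256 px at 1 um/px, so one tile footprint is one 32 x 32
# mask window and quarter-offset footprints cover known lesion fractions.
mk_truth <- function(grade = 3L) {
  tissue <- matrix(TRUE, 32, 32)
  lesion <- matrix(FALSE, 32, 32); lesion[1:16, 1:16] <- TRUE
  structure(list(tissue_mask = tissue, lesion_mask = lesion,
                 isup_label = grade, mpp = 8, slide_id = "hand"),
            class = "ground_truth")
}

mk_tiles <- function(coords) {
  cfg <- tiling_config()
  structure(list(slide_id = "hand",
                 tiles = data.frame(x = vapply(coords, `[`, numeric(1), 1),
                                    y = vapply(coords, `[`, numeric(1), 2),
                                    tissue_fraction = 1),
                 config = cfg), class = "tile_set")
}

test_that("the surrogate grade follows the coverage thresholds", {
  truth <- mk_truth(3L)
  expect_equal(surrogate_grade(truth, mk_tiles(list(c(0, 0)))), 3L)     # full
  expect_equal(surrogate_grade(truth, mk_tiles(list(c(128, 128)))), 0L) # none
  # half-offset tile covers rows 1:16 x cols 9:24 of the mask: 8 of the 16
  # lesion columns, coverage 0.5 -> full-threshold boundary (inclusive)
  expect_equal(surrogate_grade(truth, mk_tiles(list(c(64, 0)))), 3L)
  # three-quarter offset covers 4 of 16 lesion columns: coverage 0.25,
  # between the partial (0.1) and full (0.5) thresholds -> one-grade drop
  expect_equal(surrogate_grade(truth, mk_tiles(list(c(96, 0)))), 2L)
  # benign slides grade 0 regardless of tiles
  benign <- mk_truth(0L); benign$lesion_mask[] <- FALSE
  expect_equal(surrogate_grade(benign, mk_tiles(list(c(0, 0)))), 0L)
  # grade-1 lesions floor at 1 under partial coverage
  g1 <- mk_truth(1L)
  expect_equal(surrogate_grade(g1, mk_tiles(list(c(96, 0)))), 1L)
})

test_that("grader configuration orders its thresholds", {
  expect_error(surrogate_grader_config(0.3, 0.5))
  expect_error(surrogate_grader_config(0.5, 0))
})

test_that("identical ground-truth arms agree perfectly", {
  bank <- fx_bank()
  cohort <- unname(bank)
  cmp <- run_comparison(cohort, truth_segmenter(), truth_segmenter(),
                        stats = stats_config(replicates = 100, seed = 7))
  expect_equal(cmp$n_excluded, 0L)
  expect_equal(cmp$kappa_A$point, 1)
  expect_equal(cmp$kappa_B$point, 1)
  expect_equal(cmp$discordance$n_discordant, 0L)
  expect_true(all(cmp$per_slide$grade_A == cmp$per_slide$ref_grade))
})

test_that("exclusion accounting conserves slides", {
  bank <- fx_bank()
  cohort <- unname(bank)                      # includes one pale slide
  cmp <- run_comparison(cohort, threshold_segmenter(), truth_segmenter(),
                        stats = stats_config(replicates = 50, seed = 3))
  expect_equal(cmp$n_included + cmp$n_excluded, length(cohort))
  expect_equal(cmp$failure_table$a_only + cmp$failure_table$b_only +
                 cmp$failure_table$both, cmp$n_excluded)
  expect_error(run_comparison(list(), truth_segmenter(), truth_segmenter()),
               class = "empty_cohort")
})

test_that("enlarging a mask never lowers the surrogate grade", {
  cfg <- tiling_config(infer_overlap_px = 64L)
  for (nm in c("lesion2", "lesion5")) {
    gen <- fx_bank()[[nm]]
    truth <- gen$truth
    full <- tissue_mask(truth$tissue_mask, 8, "truth", gen$slide$slide_id)
    er <- EBImage::imageData(EBImage::erode(EBImage::Image(truth$tissue_mask * 1),
                                            EBImage::makeBrush(9, "disc"))) > 0.5
    small <- tissue_mask(er, 8, "truth", gen$slide$slide_id)
    dims <- dim(gen$slide$levels[[1]]$raster)[1:2]
    grid <- grid_tiles(dims, cfg, "infer")
    g_small <- surrogate_grade(truth, filter_tiles(grid, small, cfg))
    g_full <- surrogate_grade(truth, filter_tiles(grid, full, cfg))
    expect_gte(g_full, g_small)
    expect_equal(g_full, truth$isup_label)    # full mask reproduces the grade
  }
})
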