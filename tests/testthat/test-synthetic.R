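test_that("empty slides carry empty truth and benign labels", {
  gen <- generate_slide(synthetic_slide_spec(n_fragments = 0, seed = 1,
                                             slide_id = "empty"))
  expect_false(any(gen$truth$tissue_mask))
  expect_false(any(gen$truth$lesion_mask))
  expect_identical(gen$truth$isup_label, 0L)
})

test_that("rasterized ellipse area matches the analytic area", {
  # membership raster at 1 um/px vs pi*a*b, and the 8 um/px area-majority
  # rasterization vs the same area over the 8^2 scale factor
  H <- 800; W <- 800
  xg <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  yg <- matrix(rep(seq_len(H) - 0.5, W), H, W)
  a <- 230; b <- 95
  m <- tissuedetect:::ellipse_member(xg, yg, 400, 400, a, b, 0.6,
                                     numeric(0), numeric(0))
  analytic <- pi * a * b
  expect_lt(abs(sum(m) - analytic) / analytic, 0.02)
  coarse <- tissuedetect:::occupancy_downsample(m, 100, 100) >= 0.5
  expect_lt(abs(sum(coarse) - analytic / 64) / (analytic / 64), 0.02)
})

test_that("generation is bit-reproducible for a fixed spec", {
  spec <- synthetic_slide_spec(seed = 11, slide_id = "rep",
                               artifacts = "debris",
                               lesion = list(isup_grade = 3, area_fraction = 0.3))
  g1 <- generate_slide(spec)
  g2 <- generate_slide(spec)
  expect_identical(g1$truth, g2$truth)
  for (k in seq_along(g1$slide$levels))
    expect_identical(g1$slide$levels[[k]]$raster, g2$slide$levels[[k]]$raster)
})

test_that("generated slides respect truth invariants across seeds", {
  # lesion within tissue, tissue area inside the design band, pale slides
  # luminance-matched below the separability delta
  lum <- function(x) 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  for (s in 1:50) {
    pale <- s %% 3 == 0
    spec <- synthetic_slide_spec(
      width_um = 640, height_um = 640, fragment_scale_um = 320, seed = 500 + s,
      slide_id = paste0("inv", s),
      color_profile = if (pale) "pale" else "normal",
      lesion = if (s %% 2 == 0) list(isup_grade = 1 + s %% 5,
                                     area_fraction = 0.35) else NULL)
    gen <- generate_slide(spec)
    expect_true(all(gen$truth$tissue_mask[gen$truth$lesion_mask]))
    frac <- mean(gen$truth$tissue_mask)
    expect_gt(frac, 0.05); expect_lt(frac, 0.45)
    if (pale) {
      L <- lum(get_level(gen$slide, 8))
      gap <- abs(mean(L[gen$truth$tissue_mask]) - mean(L[!gen$truth$tissue_mask]))
      expect_lt(gap, spec$separability_delta)
    }
  }
})

test_that("pyramid construction follows the closest-finer Lanczos rule", {
  const <- array(0.4, c(30, 20, 3))
  pyr <- build_pyramid(const, 1, c(1, 2, 4))
  expect_identical(pyr$levels[[1]]$raster, const)     # identity at base
  for (lv in pyr$levels) {
    expect_equal(dim(lv$raster)[1:2], ceiling(c(30, 20) / lv$mpp))
    expect_true(all(abs(lv$raster - 0.4) < 1e-12))    # constants preserved
  }
  checker <- array(0, c(2, 2, 3))
  checker[1, 2, ] <- 1; checker[2, 1, ] <- 1
  down <- build_pyramid(checker, 1, 2)$levels[[1]]$raster
  expect_equal(dim(down)[1:2], c(1, 1))
  expect_lt(abs(down[1, 1, 1] * 255 - 127.5), 2)
  expect_error(build_pyramid(const, 2, 1), class = "invalid_pyramid")
})

test_that("patient-level splits keep patients intact and hit the fractions", {
  one <- data.frame(patient_id = rep("P1", 7))
  cells <- split_by_patient(one, c(0.3, 0.7), seed = 3)
  expect_equal(sort(lengths(cells)), c(0L, 7L))       # one patient: one cell

  many <- data.frame(patient_id = rep(sprintf("P%03d", 1:100), each = 2))
  cells <- split_by_patient(many, c(0.3, 0.7), seed = 4)
  pats <- lapply(cells, function(ix) unique(many$patient_id[ix]))
  expect_equal(lengths(pats), c(30L, 70L))            # exact when divisible
  expect_length(intersect(pats[[1]], pats[[2]]), 0)
  expect_equal(sort(unlist(cells)), seq_len(200))     # every case placed once

  expect_identical(split_by_patient(many, c(0.3, 0.7), seed = 4), cells)
  expect_error(split_by_patient(data.frame(patient_id = character()),
                                c(0.5, 0.5)), class = "invalid_split")
})

test_that("slide specs are validated", {
  expect_error(synthetic_slide_spec(width_um = 0), class = "invalid_spec")
  expect_error(synthetic_slide_spec(lesion = list(isup_grade = 6, area_fraction = 0.2)),
               class = "invalid_spec")
  expect_error(synthetic_slide_spec(lesion = list(isup_grade = 2, area_fraction = 0)),
               class = "invalid_spec")
  expect_error(synthetic_slide_spec(n_fragments = 0,
                                    lesion = list(isup_grade = 2, area_fraction = 0.2)),
               class = "invalid_spec")
})
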