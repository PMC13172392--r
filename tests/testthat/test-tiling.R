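test_that("tile grids cover the padded extent in both modes", {
  cfg <- tiling_config()
  g <- grid_tiles(c(256, 256), cfg, "train")
  expect_equal(nrow(g), 1L)
  expect_equal(c(g$x, g$y), c(0L, 0L))

  g <- grid_tiles(c(600, 700), cfg, "train")
  expect_equal(nrow(g), 9L)                         # padded 768 x 768
  expect_equal(attr(g, "padded_dims"), c(768, 768))

  expect_error(grid_tiles(c(512, 512), cfg, "infer"),    # stride 0
               class = "invalid_tiling")
  cfg64 <- tiling_config(infer_overlap_px = 64L)
  g <- grid_tiles(c(512, 512), cfg64, "infer")          # stride 128
  expect_equal(nrow(g), 9L)

  # geometry reconstructs the padded extent: last tile ends at its edge
  for (mode in c("train", "infer")) {
    for (dims in list(c(300, 470), c(512, 512), c(1000, 640))) {
      g <- grid_tiles(dims, cfg64, mode)
      pd <- attr(g, "padded_dims"); off <- attr(g, "offset")
      expect_equal(max(g$x) + cfg64$tile_size_px, pd[2] - off[2])
      expect_equal(max(g$y) + cfg64$tile_size_px, pd[1] - off[1])
      expect_equal(min(g$x), -off[2]); expect_equal(min(g$y), -off[1])
      ord <- order(g$y, g$x)                        # row-major sorted
      expect_identical(ord, seq_len(nrow(g)))
    }
  }
})

test_that("tissue fractions count mask pixels over the footprint", {
  cfg <- tiling_config()
  empty <- tissue_mask(matrix(FALSE, 32, 32), 8, "truth")
  full <- tissue_mask(matrix(TRUE, 32, 32), 8, "truth")
  expect_equal(tile_tissue_fraction(empty, c(0, 0), cfg), 0)
  expect_equal(tile_tissue_fraction(full, c(0, 0), cfg), 1)

  half <- matrix(FALSE, 32, 32); half[1:16, ] <- TRUE   # 512 of 1024 px
  m <- tissue_mask(half, 8, "truth")
  expect_equal(tile_tissue_fraction(m, c(0, 0), cfg), 0.5)
})

test_that("the tissue filter is inclusive at the floor and monotone", {
  # three tiles with fractions 1/16, 1/8, 1/2 against a floor of exactly 1/8
  raster <- matrix(FALSE, 32, 96)
  raster[1:2, 1:32] <- TRUE                          # 64/1024  = 0.0625
  raster[1:4, 33:64] <- TRUE                         # 128/1024 = 0.125
  raster[1:16, 65:96] <- TRUE                        # 512/1024 = 0.5
  m <- tissue_mask(raster, 8, "truth", "frac")
  cfg <- tiling_config(min_tissue_fraction = 0.125)
  coords <- data.frame(x = c(0L, 256L, 512L), y = c(0L, 0L, 0L))
  ts <- filter_tiles(coords, m, cfg)
  expect_equal(nrow(ts$tiles), 2L)                   # 0.125 kept by ">="
  expect_equal(sort(ts$tiles$x), c(256L, 512L))

  expect_equal(nrow(filter_tiles(coords, tissue_mask(matrix(FALSE, 32, 96),
                                                     8, "truth"), cfg)$tiles), 0L)
  all_t <- filter_tiles(coords, tissue_mask(matrix(TRUE, 32, 96), 8, "truth"), cfg)
  expect_equal(nrow(all_t$tiles), 3L)

  # monotone: lowering the floor never drops a kept tile
  set.seed(31)
  rnd <- tissue_mask(matrix(runif(32 * 96) < 0.2, 32, 96), 8, "truth")
  hi <- filter_tiles(coords, rnd, tiling_config(min_tissue_fraction = 0.3))
  lo <- filter_tiles(coords, rnd, tiling_config(min_tissue_fraction = 0.1))
  expect_true(all(hi$tiles$x %in% lo$tiles$x))
})

test_that("mask-resolution fractions match upsampled full-resolution fractions", {
  cfg <- tiling_config(tile_size_px = 64L)
  set.seed(77)
  for (r in 1:10) {
    coarse <- matrix(runif(16 * 16) < 0.4, 16, 16)
    fine <- coarse[rep(1:16, each = 8), rep(1:16, each = 8)]   # nearest 8x
    m <- tissue_mask(coarse, 8, "truth")
    for (coord in list(c(0, 0), c(64, 0), c(0, 64), c(64, 64))) {
      win <- fine[(coord[2] + 1):(coord[2] + 64), (coord[1] + 1):(coord[1] + 64)]
      expect_equal(tile_tissue_fraction(m, coord, cfg), mean(win))
    }
  }
})

test_that("tile extraction picks the closest finer level", {
  gen <- fx_bank()$plain
  cfg <- tiling_config()
  # target equals level 0: bit-exact crop
  tl <- extract_tile(gen$slide, c(128, 256), cfg)
  l0 <- gen$slide$levels[[1]]$raster
  expect_identical(tl, l0[257:512, 129:384, ])

  # levels {1, 4}, target 2: must read from the 1.0 level, not the zeroed 4.0
  base <- gen$slide$levels[[1]]$raster
  py <- build_pyramid(base, 1, c(1, 4), slide_id = "sel")
  py$levels[[2]]$raster[] <- 0
  cfg2 <- tiling_config(mask_mpp = 8, tile_mpp = 2, tile_size_px = 64L)
  tl2 <- extract_tile(py, c(32, 32), cfg2)
  expect_gt(mean(tl2), 0.5)                          # came from real data

  # constant-color region stays constant under resampling
  cpy <- build_pyramid(array(0.25, c(256, 256, 3)), 1, c(1, 2), slide_id = "c")
  tl3 <- extract_tile(cpy, c(16, 16), cfg2)
  expect_true(all(abs(tl3 - 0.25) < 1e-9))

  expect_error(extract_tile(py, c(0, 0), tiling_config(mask_mpp = 4, tile_mpp = 0.5,
                                                       tile_size_px = 64L)),
               class = "invalid_pyramid")
})

test_that("tiling configuration invariants are enforced", {
  expect_error(tiling_config(mask_mpp = 8, tile_mpp = 3), class = "invalid_tiling")
  expect_error(tiling_config(tile_size_px = 100L), class = "invalid_tiling")
})
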