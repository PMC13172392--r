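test_that("mirror padding reaches the tile multiple and round-trips", {
  x <- matrix(runif(64 * 64), 64, 64)
  expect_identical(unname(dim(mirror_pad(x, 64))), c(64L, 64L))

  y <- array(runif(600 * 700 * 3), c(600, 700, 3))
  p <- mirror_pad(y, 512)
  expect_identical(unname(dim(p)[1:2]), c(1024L, 1024L))
  off <- attr(p, "offset")
  expect_identical(p[(off[1] + 1):(off[1] + 600), (off[2] + 1):(off[2] + 700), ],
                   y)

  one <- matrix(0.7, 1, 1)
  p1 <- mirror_pad(one, 4)
  expect_identical(unname(dim(p1)), c(4L, 4L))
  expect_true(all(p1 == 0.7))
})

test_that("the network overfits a toy set and loss trends downward", {
  tiles <- toy_tiles()
  ck <- train_segmenter(tiles, tiles,
                        train_config(base_learning_rate = 1e-3,
                                     tile_size_px = 32L, patience = 60L,
                                     max_epochs = 60L, seed = 5L),
                        augmentation_policy(flips = FALSE, rotations_90 = FALSE,
                                            color_jitter_strength = 0))
  expect_gte(ck$val_f1, 0.99)
  loss <- ck$log$mean_loss[-1]            # epoch 0 has no training loss
  expect_lt(mean(loss[4:6]), mean(loss[1:2]))
})

test_that("a zero-epoch budget returns the initial checkpoint", {
  tiles <- toy_tiles(2)
  ck <- train_segmenter(tiles, tiles,
                        train_config(tile_size_px = 32L, max_epochs = 0L, seed = 2L))
  expect_identical(ck$epoch, 0L)
  expect_true(is.finite(ck$val_f1))
  expect_error(train_segmenter(list(), tiles,
                               train_config(tile_size_px = 32L)),
               class = "empty_training_set")
})

test_that("training is deterministic under a fixed seed", {
  tiles <- toy_tiles(3)
  cfg <- train_config(base_learning_rate = 1e-3, tile_size_px = 32L,
                      patience = 5L, max_epochs = 5L, seed = 77L)
  ck1 <- train_segmenter(tiles, tiles, cfg)
  ck2 <- train_segmenter(tiles, tiles, cfg)
  expect_identical(ck1$epoch, ck2$epoch)
  expect_equal(ck1$val_f1, ck2$val_f1, tolerance = 1e-12)
  expect_identical(ck1$weights$enc1$W[[5]], ck2$weights$enc1$W[[5]])
})

test_that("overlap-discard regions cover every pixel exactly once", {
  cases <- list(c(512, 128, 32), c(1536, 512, 128), c(256, 64, 16),
                c(512, 128, 0))
  for (cs in cases) {
    r <- overlap_discard_regions(cs[1], cs[2], cs[3])
    counts <- integer(cs[1])
    for (i in seq_len(nrow(r)))
      counts[(r$keep_from[i] + 1):r$keep_to[i]] <-
        counts[(r$keep_from[i] + 1):r$keep_to[i]] + 1L
    expect_true(all(counts == 1L))
    expect_true(all(r$keep_from >= r$start & r$keep_to <= r$start + cs[2]))
  }
  expect_error(overlap_discard_regions(512, 128, 64), class = "invalid_tiling")
})

test_that("tiled inference equals whole-image inference for a pixel-local model", {
  ck <- pixel_local_checkpoint(64L)
  gen <- fx_bank()$plain
  tiled <- predict_mask(gen$slide, ck, overlap = 16L)

  raster <- get_level(gen$slide, 8)
  padded <- mirror_pad(raster, 64L)
  off <- attr(padded, "offset")
  whole <- tissuedetect:::unet_forward(ck$weights, padded)$logits > 0
  H <- dim(raster)[1]; W <- dim(raster)[2]
  whole <- whole[(off[1] + 1):(off[1] + H), (off[2] + 1):(off[2] + W)]
  expect_identical(tiled$raster, whole)
  expect_identical(tiled$raster, raster[, , 1] > 0.5)   # per-pixel rule
})

test_that("model selection maximizes sensitivity under the precision floor", {
  expect_identical(select_best_model(list(c(0.99, 0.89), c(0.97, 0.95))), 2L)
  expect_identical(select_best_model(list(c(0.95, 0.95))), 1L)
  expect_identical(select_best_model(list(c(0.97, 0.91), c(0.97, 0.96))), 2L)
  expect_identical(select_best_model(rbind(c(0.98, 0.92), c(0.90, 0.99))), 1L)
  expect_error(select_best_model(list(c(0.99, 0.80), c(0.98, 0.89))),
               class = "no_qualifying_model")
})

test_that("checkpoints round-trip through disk with identical predictions", {
  tiles <- toy_tiles(2)
  ck <- train_segmenter(tiles, tiles,
                        train_config(base_learning_rate = 1e-3,
                                     tile_size_px = 32L, max_epochs = 3L,
                                     patience = 3L, seed = 8L))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  p1 <- tissuedetect:::unet_forward(ck$weights, tiles[[1]]$x)$logits
  p2 <- tissuedetect:::unet_forward(ck2$weights, tiles[[1]]$x)$logits
  expect_identical(p1, p2)
})
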