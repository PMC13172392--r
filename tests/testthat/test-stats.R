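mk_mask <- function(raster, id = "m") tissue_mask(raster, 8, "truth", id)

test_that("pixel metrics follow the TP/FN/FP definitions", {
  a <- matrix(FALSE, 10, 10); a[2:4, 2:5] <- TRUE
  expect_equal(pixel_metrics(mk_mask(a), mk_mask(a))[c("sensitivity", "precision")],
               list(sensitivity = 1, precision = 1))

  truth <- matrix(FALSE, 10, 10); truth[1, 1:10] <- TRUE      # 10 px
  pred <- matrix(FALSE, 10, 10); pred[1, 1:8] <- TRUE; pred[5, 1:2] <- TRUE
  pm <- pixel_metrics(mk_mask(pred), mk_mask(truth))
  expect_equal(pm$sensitivity, 0.8)
  expect_equal(pm$precision, 0.8)

  none <- pixel_metrics(mk_mask(matrix(FALSE, 10, 10)), mk_mask(truth))
  expect_equal(none$sensitivity, 0)
  expect_true(is.na(none$precision))
  expect_true(none$undefined_precision_flag)

  expect_error(pixel_metrics(mk_mask(matrix(FALSE, 5, 5)), mk_mask(truth)),
               class = "dim_mismatch")
})

test_that("Clopper-Pearson intervals bracket the point estimate", {
  ci <- clopper_pearson(0, 10)
  expect_equal(ci$lower, 0)
  set.seed(9)
  for (r in 1:50) {
    n <- sample(1:5000, 1); k <- sample(0:n, 1)
    ci <- clopper_pearson(k, n)
    expect_true(ci$lower <= k / n + 1e-12 && k / n <= ci$upper + 1e-12)
    expect_true(ci$lower >= 0 && ci$upper <= 1)
  }
})

test_that("McNemar p-values match hand computation and the chi-square oracle", {
  expect_equal(mcnemar_exact(1, 5), 14 / 64)         # 2 * P(X <= 1 | n = 6)
  expect_equal(mcnemar_exact(5, 1), 14 / 64)
  expect_equal(mcnemar_exact(0, 0), 1)
  expect_equal(mcnemar_exact(0, 0, "chisq"), 1)
  expect_equal(mcnemar_exact(3, 3), 1)               # capped at 1
  for (bc in list(c(2, 10), c(7, 3), c(15, 30))) {
    tbl <- matrix(c(5, bc[1], bc[2], 5), 2)
    expect_equal(mcnemar_exact(bc[1], bc[2], "chisq"),
                 stats::mcnemar.test(tbl, correct = TRUE)$p.value)
  }
})

test_that("quadratic weighted kappa matches hand and oracle computations", {
  expect_equal(quadratic_weighted_kappa(c(0, 0, 1, 1), c(0, 1, 1, 1),
                                        categories = 0:1), 0.5)
  expect_equal(quadratic_weighted_kappa(c(0, 3, 5, 2), c(0, 3, 5, 2)), 1)
  expect_equal(quadratic_weighted_kappa(c(2, 2, 2), c(2, 2, 2)), 1)  # convention
  expect_error(quadratic_weighted_kappa(1, 1), class = "invalid_kappa")

  set.seed(17)
  for (r in 1:5) {
    ref <- sample(0:5, 200, replace = TRUE)
    pred <- sample(0:5, 200, replace = TRUE)
    k <- quadratic_weighted_kappa(ref, pred)
    expect_equal(k, qwk_oracle(ref, pred), tolerance = 1e-12)
    expect_equal(k, quadratic_weighted_kappa(pred, ref), tolerance = 1e-12)
    perm <- sample(200)
    expect_equal(k, quadratic_weighted_kappa(ref[perm], pred[perm]),
                 tolerance = 1e-12)
  }

  # independent uniform predictions: zero agreement beyond chance
  set.seed(18)
  ks <- replicate(100, quadratic_weighted_kappa(sample(0:5, 200, TRUE),
                                                sample(0:5, 200, TRUE)))
  expect_lt(abs(mean(ks)), 0.03)
})

test_that("bootstrap intervals are seeded, degenerate-safe and calibrated", {
  x <- rep(3.5, 20)
  ci <- bootstrap_ci(function(idx) mean(x[idx]), 20, replicates = 200, seed = 1)
  expect_equal(ci$lower, 3.5); expect_equal(ci$upper, 3.5)

  y <- c(1, 4, 2, 8, 5, 7, 3)
  c1 <- bootstrap_ci(function(idx) mean(y[idx]), 7, seed = 42)
  c2 <- bootstrap_ci(function(idx) mean(y[idx]), 7, seed = 42)
  expect_identical(c1$values, c2$values)

  # NA replicates are redrawn and counted
  flaky <- function(idx) if (idx[1] == 1) NA_real_ else mean(y[idx])
  cf <- bootstrap_ci(flaky, 7, replicates = 100, seed = 3)
  expect_gte(cf$n_redrawn, 1L)
  expect_true(is.finite(cf$lower))

  # Monte-Carlo coverage of the mean of 100 standard-normal draws
  set.seed(101)
  covered <- 0L
  for (r in 1:200) {
    z <- rnorm(100)
    ci <- bootstrap_ci(function(idx) mean(z[idx]), 100, replicates = 1000,
                       seed = 1000 + r)
    if (ci$lower <= 0 && 0 <= ci$upper) covered <- covered + 1L
  }
  expect_gte(covered / 200, 0.91)
  expect_lte(covered / 200, 0.99)
})

test_that("paired failure tables preserve their marginal identities", {
  set.seed(55)
  for (r in 1:20) {
    n <- sample(50:500, 1)
    a <- runif(n) < 0.05; b <- runif(n) < 0.1
    tab <- paired_failure_table(a, b)
    s <- summarize_failures(tab)
    expect_equal(s$a_failures, sum(a))
    expect_equal(s$b_failures, sum(b))
    expect_equal(s$excluded, sum(a | b))
    expect_lte(tab$a_only + tab$b_only + tab$both, tab$total)
  }
  expect_error(paired_failure_table(c(TRUE, FALSE), TRUE),
               class = "mismatched_slides")
  none <- summarize_failures(paired_failure_table(rep(FALSE, 10), rep(FALSE, 10)))
  expect_equal(none$mcnemar_p_exact, 1)
})

test_that("discordance accounting partitions malignant disagreements", {
  same <- discordance(c(1, 2, 0), c(1, 2, 0), c(1, 2, 0))
  expect_equal(same$n_discordant, 0L)
  expect_true(all(same$confusion == 0))

  d <- discordance(c(1, 2, 0), c(1, 3, 2), c(1, 3, 0))
  expect_equal(d$n_discordant, 2L)
  expect_equal(d$n_malignant, 2L)
  expect_equal(d$n_malignant_discordant, 1L)        # case 3 is benign
  expect_equal(d$B_correct_only, 1L)                # case 2: B hits ref 3
  expect_equal(d$A_correct_only, 0L)
  expect_equal(d$confusion["2", "3"], 1L)
  expect_equal(d$confusion["0", "2"], 1L)
  expect_true(all(diag(d$confusion) == 0))

  set.seed(66)
  for (r in 1:20) {
    n <- sample(20:200, 1)
    A <- sample(0:5, n, TRUE); B <- sample(0:5, n, TRUE); ref <- sample(0:5, n, TRUE)
    d <- discordance(A, B, ref)
    expect_equal(d$A_correct_only + d$B_correct_only + d$neither_correct,
                 d$n_malignant_discordant)
    expect_equal(sum(d$confusion), d$n_discordant)
    expect_true(all(diag(d$confusion) == 0))
  }
})

test_that("binary screening metrics flag undefined cohorts", {
  expect_equal(binary_screen_metrics(c(TRUE, FALSE), c(TRUE, FALSE))[1:2],
               list(sensitivity = 1, specificity = 1))
  ref <- c(rep(TRUE, 10), rep(FALSE, 20))
  pred <- c(rep(TRUE, 9), FALSE, rep(FALSE, 18), TRUE, TRUE)
  m <- binary_screen_metrics(ref, pred)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.9)

  allpos <- binary_screen_metrics(rep(TRUE, 5), rep(TRUE, 5))
  expect_true(allpos$specificity_undefined)
  expect_false(allpos$sensitivity_undefined)
})
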