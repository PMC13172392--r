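## Paired statistical evaluation: pixel-wise segmentation metrics, exact
## binomial (Clopper-Pearson) confidence intervals, McNemar's test on
## paired detection failures, quadratic weighted kappa with bootstrap
## confidence intervals, and discordance accounting between two arms of a
## downstream grading comparison.

#' Pixel-wise sensitivity and precision of a predicted mask
#'
#' Sensitivity = TP / (TP + FN), precision = TP / (TP + FP), computed over
#' pixels against a reference mask of identical geometry. A predicted mask
#' with no tissue pixels has undefined precision: the flag is set and such
#' slides are excluded from precision aggregation.
#'
#' @param pred,truth `tissue_mask` objects with equal dims and resolution.
#' @return list with `slide_id`, `sensitivity`, `precision`,
#'   `undefined_precision_flag`.
#' @export
pixel_metrics <- function(pred, truth) {
  stopifnot(inherits(pred, "tissue_mask"), inherits(truth, "tissue_mask"))
  if (!identical(dim(pred$raster), dim(truth$raster)) || pred$mpp != truth$mpp)
    td_stop("dim_mismatch", "prediction and reference masks disagree in geometry")
  tp <- sum(pred$raster & truth$raster)
  fn <- sum(!pred$raster & truth$raster)
  fp <- sum(pred$raster & !truth$raster)
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  undef <- (tp + fp) == 0
  prec <- if (undef) NA_real_ else tp / (tp + fp)
  list(slide_id = pred$slide_id, sensitivity = sens, precision = prec,
       undefined_precision_flag = undef)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Two-sided interval for a proportion from beta quantiles; the same
#' interval `binom.test` reports.
#'
#' @param k successes, `n` trials, `level` confidence level.
#' @param n number of trials.
#' @param level confidence level (default 0.95).
#' @return list with `k`, `n`, `level`, `estimate`, `lower`, `upper`.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  stopifnot(is_count(k), is_count(n), n > 0, k <= n, level > 0, level < 1)
  a <- (1 - level) / 2
  lower <- if (k == 0) 0 else qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else qbeta(1 - a, k + 1, n - k)
  list(k = k, n = n, level = level, estimate = k / n,
       lower = lower, upper = upper)
}

#' McNemar's test on discordant pair counts
#'
#' Primary mode is the exact two-sided binomial test: p = 2 P(X <= min(b,c))
#' for X ~ Binomial(b + c, 1/2), capped at 1. The chi-square variant with
#' continuity correction is provided as a secondary mode. With no discordant
#' pairs the p-value is 1 by convention.
#'
#' @param b,c discordant-pair counts (failures under one method only, and
#'   under the other only).
#' @param mode `"exact"` or `"chisq"`.
#' @return p-value.
#' @export
mcnemar_exact <- function(b, c, mode = c("exact", "chisq")) {
  mode <- match.arg(mode)
  stopifnot(is_count(b), is_count(c))
  n <- b + c
  if (n == 0) return(1)
  if (mode == "exact") {
    min(1, 2 * pbinom(min(b, c), n, 0.5))
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
}

#' Quadratic weighted kappa
#'
#' Chance-corrected agreement for ordered categories with squared-distance
#' disagreement weights: kappa = 1 - sum(W * O) / sum(W * E), where O is the
#' observed cross-table, E the outer product of the marginals divided by n,
#' and W[i, j] = (i - j)^2. Two identical constant vectors (zero expected
#' disagreement) give 1 by convention.
#'
#' @param ref,pred equal-length vectors over `categories`.
#' @param categories ordered category set (default benign + ISUP 1..5).
#' @return kappa in [-1, 1].
#' @export
quadratic_weighted_kappa <- function(ref, pred, categories = 0:5) {
  stopifnot(length(ref) == length(pred))
  if (length(ref) < 2) td_stop("invalid_kappa", "need at least 2 cases")
  if (!all(ref %in% categories) || !all(pred %in% categories))
    td_stop("invalid_kappa", "values outside the category set")
  f <- function(x) factor(x, levels = categories)
  O <- table(f(ref), f(pred))
  n <- length(ref)
  E <- outer(rowSums(O), colSums(O)) / n
  idx <- seq_along(categories)
  W <- outer(idx, idx, function(i, j) (i - j)^2)
  denom <- sum(W * E)
  if (denom == 0) return(1)
  1 - sum(W * O) / denom
}

#' Percentile bootstrap confidence interval
#'
#' Resamples cases (the aggregation unit: slide, location or patient) with
#' replacement and takes the 2.5/97.5 percentiles of the statistic over the
#' replicates. Replicates on which the statistic is undefined (NA; e.g. a
#' constant resample for kappa) are redrawn and counted. Seeded and
#' reproducible.
#'
#' @param statistic_fn function of an index vector into the cases (the
#'   resample), returning a scalar; `NA` marks an undefined replicate.
#' @param n_cases number of cases to resample from.
#' @param replicates bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param level confidence level.
#' @return list with `lower`, `upper`, `replicates`, `seed`, `n_redrawn`,
#'   and the replicate values.
#' @export
bootstrap_ci <- function(statistic_fn, n_cases, replicates = 1000L,
                         seed = 1L, level = 0.95) {
  stopifnot(n_cases >= 1, replicates >= 1)
  a <- (1 - level) / 2
  with_seed(seed, {
    vals <- numeric(replicates)
    redrawn <- 0L
    for (r in seq_len(replicates)) {
      v <- NA_real_
      for (attempt in seq_len(100L)) {
        idx <- sample.int(n_cases, n_cases, replace = TRUE)
        v <- statistic_fn(idx)
        if (!is.na(v)) break
        redrawn <- redrawn + 1L
      }
      if (is.na(v)) td_stop("bootstrap_degenerate",
                            "statistic undefined on 100 consecutive resamples")
      vals[r] <- v
    }
    q <- unname(quantile(vals, c(a, 1 - a)))
    list(lower = q[1], upper = q[2], replicates = replicates, seed = seed,
         n_redrawn = redrawn, values = vals)
  })
}

#' Paired detection-failure table
#'
#' Cross-classifies each slide by whether method A and/or method B failed to
#' detect any tissue.
#'
#' @param a_fail,b_fail logical failure flags, aligned; or use
#'   [failure_table_from_counts()] to build the table from published counts.
#' @param slide_ids optional ids checked for alignment.
#' @return object of class `paired_failure_table` with counts `a_only`,
#'   `b_only`, `both`, `total`.
#' @export
paired_failure_table <- function(a_fail, b_fail, slide_ids = NULL) {
  if (length(a_fail) != length(b_fail))
    td_stop("mismatched_slides", "failure vectors must cover the same slide set")
  structure(list(a_only = sum(a_fail & !b_fail),
                 b_only = sum(!a_fail & b_fail),
                 both = sum(a_fail & b_fail),
                 total = length(a_fail),
                 slide_ids = slide_ids),
            class = "paired_failure_table")
}

#' @rdname paired_failure_table
#' @param a_only,b_only,both,total counts.
#' @export
failure_table_from_counts <- function(a_only, b_only, both, total) {
  stopifnot(is_count(a_only), is_count(b_only), is_count(both), is_count(total),
            a_only + b_only + both <= total)
  structure(list(a_only = a_only, b_only = b_only, both = both, total = total,
                 slide_ids = NULL),
            class = "paired_failure_table")
}

#' Summarize a paired failure table
#'
#' Per-method failure counts and rates with exact binomial confidence
#' intervals, the number of slides excluded from a both-methods comparison
#' (any failure), and McNemar's test on the discordant counts.
#'
#' @param tab a `paired_failure_table`.
#' @param level confidence level for the intervals.
#' @return list with `a_failures`, `b_failures`, `excluded`, `a_ci`, `b_ci`,
#'   `mcnemar_p_exact`, `mcnemar_p_chisq`.
#' @export
summarize_failures <- function(tab, level = 0.95) {
  stopifnot(inherits(tab, "paired_failure_table"))
  a_f <- tab$a_only + tab$both
  b_f <- tab$b_only + tab$both
  list(a_failures = a_f, b_failures = b_f,
       excluded = tab$a_only + tab$b_only + tab$both,
       a_ci = clopper_pearson(a_f, tab$total, level),
       b_ci = clopper_pearson(b_f, tab$total, level),
       mcnemar_p_exact = mcnemar_exact(tab$a_only, tab$b_only, "exact"),
       mcnemar_p_chisq = mcnemar_exact(tab$a_only, tab$b_only, "chisq"))
}

#' Discordance summary between two grading arms
#'
#' Counts slides where the two arms predict different grades; among
#' malignant slides (reference grade >= 1) partitions the discordant ones by
#' which arm matched the reference (A only, B only, neither); and fills the
#' off-diagonal confusion matrix of (A-prediction x B-prediction) grade
#' pairs over all discordant slides.
#'
#' @param preds_A,preds_B,ref_grades aligned grade vectors over
#'   `categories`.
#' @param categories grade set (default 0 = benign, 1..5 = ISUP).
#' @return object of class `discordance_summary`.
#' @export
discordance <- function(preds_A, preds_B, ref_grades, categories = 0:5) {
  stopifnot(length(preds_A) == length(preds_B),
            length(preds_A) == length(ref_grades))
  disc <- preds_A != preds_B
  malignant <- ref_grades >= 1
  md <- disc & malignant
  a_corr <- md & preds_A == ref_grades & preds_B != ref_grades
  b_corr <- md & preds_B == ref_grades & preds_A != ref_grades
  neither <- md & preds_A != ref_grades & preds_B != ref_grades
  f <- function(x) factor(x, levels = categories)
  cm <- table(f(preds_A[disc]), f(preds_B[disc]))
  structure(list(n_total = length(preds_A),
                 n_discordant = sum(disc),
                 n_malignant = sum(malignant),
                 n_malignant_discordant = sum(md),
                 A_correct_only = sum(a_corr),
                 B_correct_only = sum(b_corr),
                 neither_correct = sum(neither),
                 confusion = unclass(cm)),
            class = "discordance_summary")
}

#' Sensitivity and specificity for binary cancer screening
#'
#' Malignant-versus-benign screening metrics. Cohorts without positives
#' (or negatives) have the corresponding metric undefined and flagged, the
#' way all-malignant cohorts report N/A specificity.
#'
#' @param ref_malignant,pred_malignant aligned logical vectors.
#' @return list with `sensitivity`, `specificity` and undefined flags.
#' @export
binary_screen_metrics <- function(ref_malignant, pred_malignant) {
  stopifnot(length(ref_malignant) == length(pred_malignant))
  P <- sum(ref_malignant); N <- sum(!ref_malignant)
  sens <- if (P == 0) NA_real_ else sum(pred_malignant & ref_malignant) / P
  spec <- if (N == 0) NA_real_ else sum(!pred_malignant & !ref_malignant) / N
  list(sensitivity = sens, specificity = spec,
       sensitivity_undefined = P == 0, specificity_undefined = N == 0)
}

#' @export
print.paired_failure_table <- function(x, ...) {
  cat(sprintf("<paired_failure_table> A only %d, B only %d, both %d, of %d slides\n",
              x$a_only, x$b_only, x$both, x$total))
  invisible(x)
}

#' @export
print.discordance_summary <- function(x, ...) {
  cat(sprintf(paste0("<discordance_summary> %d/%d discordant; malignant %d/%d;",
                     " A-only correct %d, B-only correct %d, neither %d\n"),
              x$n_discordant, x$n_total, x$n_malignant_discordant,
              x$n_malignant, x$A_correct_only, x$B_correct_only,
              x$neither_correct))
  invisible(x)
}
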