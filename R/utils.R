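#' @keywords internal
"_PACKAGE"

#' @import stats
#' @import utils
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Classed error helper so callers can distinguish designed error paths
## (degenerate histograms, integrity failures, ...) from programming errors.
td_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "tissuedetect_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards. All package randomness funnels through
## this so cohorts are reproducible slide-by-slide.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## Stable 32-bit sub-seed derived from a master seed and a string tag
## (e.g. a slide id), so per-slide streams are independent of cohort order.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

## sRGB luminance of an H x W x 3 array in [0, 1].
luminance <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
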