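#' @importFrom rlang abort warn %||%
#' @importFrom stats cor qnorm pt sd median rnorm runif rnbinom dist hclust cmdscale cutree kmeans quantile setNames
#' @importFrom utils head
NULL

# rank-based standard-normal quantiles; average ties, strictly inside (0, 1)
rank_inverse_normal <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm(r / (length(x) + 1))
}

check_proportion <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || !lo_ok || !hi_ok) {
    abort(sprintf("`%s` must be a proportion in %s0, 1%s, got %s",
                  name, if (allow_zero) "[" else "(",
                  if (allow_one) "]" else ")", format(x)))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be an integer >= %d, got %s", name, min, format(x)))
  }
  invisible(as.integer(x))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive number, got %s", name, format(x)))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    abort(sprintf("`%s` must be a non-negative number, got %s", name, format(x)))
  }
  invisible(x)
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric gene x sample matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) abort("duplicate gene IDs in `counts`")
  if (anyDuplicated(colnames(counts))) abort("duplicate sample IDs in `counts`")
  if (any(counts < 0)) abort("`counts` contains negative values")
  invisible(counts)
}
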