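# Shared numeric helpers.

#' Z-score a vector, returning zeros when the variance is zero
#'
#' Degenerate (constant) inputs map to all zeros rather than NaN so that
#' silent cells still contribute a well-defined (null) trace.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @keywords internal
zscore_vec <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Row-wise z-score of a matrix (each row over time)
#'
#' Zero-variance rows become all-zero rows.
#'
#' @param m numeric matrix (cells x frames).
#' @return matrix of the same shape.
#' @keywords internal
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  out <- (m - mu) / ifelse(s == 0, 1, s)
  out[s == 0, ] <- 0
  out
}

#' Column-wise z-score of a matrix (each frame over cells)
#' @keywords internal
zscore_cols <- function(m) {
  t(zscore_rows(t(m)))
}

# Mean of x within consecutive bins of `width` elements; trailing partial
# bin dropped. Returns numeric(0) when fewer than `width` elements.
bin_means <- function(x, width) {
  stopifnot(width >= 1)
  n_bins <- length(x) %/% width
  if (n_bins == 0) return(numeric(0))
  colMeans(matrix(x[seq_len(n_bins * width)], nrow = width))
}

# Deterministic per-stage seed derived from a master seed and a label.
# Keeps the result inside 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# Maximal runs of TRUE in a logical vector as (start, end) half-open
# 0-based intervals, returned as a 2-column matrix.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}
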