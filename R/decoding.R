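# Linear-SVM discrimination of neutral vs aversive encoding from
# shared-cell activity vectors, with shuffled-label controls and
# chemotag-fraction decoding.

#' Build a balanced context-decoding dataset
#'
#' Cells active during both encoding sessions are aligned via the match
#' table; all other cells are excluded. The longer session is trimmed from
#' the end so both contexts contribute the same number of frame vectors.
#'
#' @param neutral_enc,aversive_enc `event_matrix` objects.
#' @param neutral_name,aversive_name session identifiers as used in `table`.
#' @param table a `match_table` linking the two encoding sessions.
#' @param bin_s optional bin width in seconds; when given, each activity
#'   vector is the per-cell mean over a bin rather than a single frame
#'   (defaults off: raw frame vectors).
#' @return a `decoding_dataset`: list with `x` (frames x cells numeric
#'   matrix), `y` (factor of context labels), `cell_ids_neutral`,
#'   `cell_ids_aversive`.
#' @export
build_context_dataset <- function(neutral_enc, neutral_name,
                                  aversive_enc, aversive_name, table,
                                  bin_s = NULL) {
  sh <- shared_active_values(neutral_enc, neutral_name,
                             aversive_enc, aversive_name, table)
  va <- sh$a; vb <- sh$b
  if (!is.null(bin_s)) {
    bin_cells <- function(v, w) {
      nb <- ncol(v) %/% w
      vapply(seq_len(nb), function(b) {
        rowMeans(v[, ((b - 1L) * w + 1L):(b * w), drop = FALSE])
      }, numeric(nrow(v)))
    }
    va <- bin_cells(va, as.integer(round(bin_s * neutral_enc$frame_rate)))
    vb <- bin_cells(vb, as.integer(round(bin_s * aversive_enc$frame_rate)))
  }
  n_frames <- min(ncol(va), ncol(vb))
  x <- rbind(t(va[, seq_len(n_frames), drop = FALSE]),
             t(vb[, seq_len(n_frames), drop = FALSE]))
  colnames(x) <- as.character(sh$ids_a)
  y <- factor(rep(c("neutral", "aversive"), each = n_frames))
  structure(list(x = x, y = y, cell_ids_neutral = sh$ids_a,
                 cell_ids_aversive = sh$ids_b),
            class = "decoding_dataset")
}

# One stratified train/test split + linear SVM fit; returns held-out
# accuracy. Labels may be pre-permuted by the caller.
svm_one_repeat <- function(x, y, train_frac, scale_cells) {
  idx_train <- unlist(lapply(levels(y), function(lv) {
    pool <- which(y == lv)
    sample(pool, floor(length(pool) * train_frac))
  }))
  idx_test <- setdiff(seq_along(y), idx_train)
  if (scale_cells) {
    mu <- colMeans(x[idx_train, , drop = FALSE])
    s <- apply(x[idx_train, , drop = FALSE], 2, stats::sd)
    s[s == 0] <- 1
    x <- sweep(sweep(x, 2, mu), 2, s, "/")
  }
  fit <- e1071::svm(x[idx_train, , drop = FALSE], y[idx_train],
                    kernel = "linear", cost = 1, scale = FALSE)
  pred <- stats::predict(fit, x[idx_test, , drop = FALSE])
  mean(pred == y[idx_test])
}

#' Linear-SVM context decoding with repeated random splits
#'
#' Per repeat, a random stratified 50% of frame vectors trains a linear SVM
#' and accuracy is measured on the held-out half. Deterministic under a
#' fixed seed.
#'
#' @param dataset a `decoding_dataset`.
#' @param train_frac training fraction (default 0.5).
#' @param repeats number of random splits (default 50).
#' @param seed RNG seed.
#' @param shuffle_labels if TRUE, labels are randomly permuted independently
#'   per repeat (the shuffled-label control).
#' @param scale_cells per-cell z-scoring using training-split statistics
#'   (default TRUE).
#' @return a `decoding_result`: list with `accuracies`, `mean_accuracy`,
#'   `repeats`, `shuffled`, `cost`.
#' @export
svm_decode <- function(dataset, train_frac = 0.5, repeats = 50, seed = 1,
                       shuffle_labels = FALSE, scale_cells = TRUE) {
  stopifnot(inherits(dataset, "decoding_dataset"))
  if (nlevels(dataset$y) != 2) stop("dataset must have exactly two labels")
  set.seed(seed)
  acc <- vapply(seq_len(repeats), function(r) {
    y <- dataset$y
    if (shuffle_labels) y <- sample(y)
    svm_one_repeat(dataset$x, y, train_frac, scale_cells)
  }, numeric(1))
  structure(list(accuracies = acc, mean_accuracy = mean(acc),
                 repeats = repeats, shuffled = shuffle_labels, cost = 1),
            class = "decoding_result")
}

#' Shuffled-label decoding control
#'
#' Identical to [svm_decode()] with labels randomly permuted independently
#' per repeat; calibrates chance performance for the same data geometry.
#'
#' @inheritParams svm_decode
#' @export
shuffled_control <- function(dataset, train_frac = 0.5, repeats = 50,
                             seed = 1, scale_cells = TRUE) {
  svm_decode(dataset, train_frac, repeats, seed,
             shuffle_labels = TRUE, scale_cells = scale_cells)
}

#' Context decoding by chemotag-responsiveness fifths
#'
#' Dataset cells are split into fifths from most to least responsive on the
#' chemogenetic tagging day and a linear SVM (plus matched shuffled-label
#' control) is trained on each 20% band. Unranked cells rank last; rank
#' ties break by cell id. Bands with fewer than 2 cells are skipped with a
#' warning.
#'
#' @param dataset a `decoding_dataset`.
#' @param chemotag_ranks named numeric vector of chemotag ranks (1 = most
#'   responsive) keyed by the dataset's cell ids.
#' @param n_bands number of rank bands (default 5).
#' @inheritParams svm_decode
#' @return list of per-band lists with elements `decoded` and `shuffled`
#'   (`decoding_result`s), `cells` (band cell ids), named band_1 (most
#'   responsive) .. band_n.
#' @export
decode_by_chemotag_fraction <- function(dataset, chemotag_ranks, n_bands = 5,
                                        train_frac = 0.5, repeats = 50,
                                        seed = 1, scale_cells = TRUE) {
  ids <- colnames(dataset$x)
  rk <- chemotag_ranks[ids]
  rk[is.na(rk)] <- Inf  # unranked cells last
  ord <- order(rk, ids)
  bands <- split(ord, cut(seq_along(ord), n_bands, labels = FALSE))
  out <- list()
  for (b in seq_along(bands)) {
    cols <- bands[[b]]
    nm <- paste0("band_", b)
    if (length(cols) < 2) {
      warning(sprintf("%s has fewer than 2 cells; skipped", nm))
      next
    }
    sub <- structure(list(x = dataset$x[, cols, drop = FALSE],
                          y = dataset$y),
                     class = "decoding_dataset")
    out[[nm]] <- list(
      decoded = svm_decode(sub, train_frac, repeats,
                           seed = derive_seed(seed, paste0(nm, "_d")),
                           scale_cells = scale_cells),
      shuffled = shuffled_control(sub, train_frac, repeats,
                                  seed = derive_seed(seed, paste0(nm, "_s")),
                                  scale_cells = scale_cells),
      cells = ids[cols]
    )
  }
  out
}
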