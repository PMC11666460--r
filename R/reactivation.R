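# Offline reactivation time courses, recall reactivation fractions / index,
# and population-vector correlation analyses.

#' Binned per-ensemble offline activity
#'
#' The offline activity matrix is z-scored along both axes (time, then
#' cells); for each ensemble the activity is averaged across its cells and
#' then averaged within each time bin. The trailing partial bin is dropped.
#'
#' @param matrix an `event_matrix`.
#' @param assignment an `ensemble_assignment`.
#' @param bin_s bin width in seconds (default 60).
#' @param ensembles which ensembles to report; empty ones are omitted.
#' @return numeric matrix, ensembles x bins.
#' @export
offline_ensemble_activity <- function(matrix, assignment, bin_s = 60,
                                      ensembles = c("neutral", "aversive",
                                                    "overlap", "remaining")) {
  check_event_matrix(matrix)
  z <- zscore_cols(zscore_rows(matrix$values))
  width <- as.integer(round(bin_s * matrix$frame_rate))
  if (ncol(z) < width) stop("session shorter than one bin")
  out <- list()
  for (e in ensembles) {
    members <- ensemble_cells(assignment, e)
    if (length(members) == 0) next
    out[[e]] <- bin_means(colMeans(z[members, , drop = FALSE]), width)
  }
  do.call(rbind, out)
}

# Cells of an event matrix that are active (>= 1 event) in the session.
active_cells <- function(matrix) {
  matrix$cell_ids[rowSums(matrix$values > 0) > 0]
}

#' Recall-session ensemble reactivation fractions
#'
#' Among cells active during a recall session, the fraction previously
#' active only during neutral encoding, only during aversive encoding, and
#' during both (the overlap ensemble). Fractions need not sum to 1: recall
#' cells matched to neither encoding session are excluded by definition.
#'
#' @param recall_session an `event_matrix` for the recall (or novel)
#'   exposure.
#' @param recall_name session identifier used in the match tables.
#' @param match_to_neutral_enc,match_to_aversive_enc `match_table`s linking
#'   the recall session to each encoding session.
#' @return named numeric vector (neutral, aversive, overlap) plus attribute
#'   `n_recall_cells`.
#' @export
recall_reactivation_fractions <- function(recall_session, recall_name,
                                          match_to_neutral_enc,
                                          match_to_aversive_enc) {
  check_event_matrix(recall_session)
  act <- active_cells(recall_session)
  if (length(act) == 0) stop("recall session has no active cells")
  ids_n <- if (nrow(match_to_neutral_enc)) {
    match_side(match_to_neutral_enc, recall_name)
  } else integer(0)
  ids_a <- if (nrow(match_to_aversive_enc)) {
    match_side(match_to_aversive_enc, recall_name)
  } else integer(0)
  in_n <- act %in% ids_n
  in_a <- act %in% ids_a
  out <- c(neutral = mean(in_n & !in_a),
           aversive = mean(!in_n & in_a),
           overlap = mean(in_n & in_a))
  attr(out, "n_recall_cells") <- length(act)
  out
}

#' Reactivation index: neutral-recall minus novel-recall reactivation
#'
#' Positive values indicate an ensemble was more reactivated during recall
#' of the familiar neutral context than during exposure to a novel context.
#'
#' @param neutral_recall_fracs,novel_recall_fracs outputs of
#'   [recall_reactivation_fractions()] for the two recall sessions.
#' @return a `reactivation_index`: list with `neutral_recall`,
#'   `novel_recall`, `index` (per-ensemble differences).
#' @export
reactivation_index <- function(neutral_recall_fracs, novel_recall_fracs) {
  ens <- intersect(names(neutral_recall_fracs), names(novel_recall_fracs))
  idx <- neutral_recall_fracs[ens] - novel_recall_fracs[ens]
  structure(list(neutral_recall = neutral_recall_fracs[ens],
                 novel_recall = novel_recall_fracs[ens],
                 index = idx),
            class = "reactivation_index")
}

#' @export
print.reactivation_index <- function(x, ...) {
  cat("<reactivation_index> (neutral recall - novel recall)\n")
  print(round(x$index, 4))
  invisible(x)
}

# Align two event matrices on cells active in both sessions via a match
# table; returns list(a, b): value matrices with rows in matched order.
shared_active_values <- function(mat_a, name_a, mat_b, name_b, table) {
  ids_a <- match_side(table, name_a)
  ids_b <- match_side(table, name_b)
  act_a <- active_cells(mat_a)
  act_b <- active_cells(mat_b)
  keep <- ids_a %in% act_a & ids_b %in% act_b
  ids_a <- ids_a[keep]; ids_b <- ids_b[keep]
  if (length(ids_a) < 2) stop("fewer than 2 shared active cells")
  list(a = mat_a$values[as.character(ids_a), , drop = FALSE],
       b = mat_b$values[as.character(ids_b), , drop = FALSE],
       ids_a = ids_a, ids_b = ids_b)
}

#' Encoding-to-recall population vector correlation (Kendall's tau)
#'
#' Cells active in both sessions are aligned via the match table. The
#' encoding session is summarized by its session-mean population vector;
#' the recall session is broken into `bin_s` bins and the mean population
#' vector of each bin is correlated with the encoding vector using the
#' tie-corrected Kendall's tau (tau-b). The per-bin correlations are
#' averaged.
#'
#' @param encoding_matrix,recall_matrix `event_matrix` objects.
#' @param encoding_name,recall_name session identifiers as used in `table`.
#' @param table a `match_table` linking the two sessions.
#' @param bin_s recall bin width in seconds (default 30).
#' @return list with `mean_tau`, `per_bin_tau`, `n_bins`, `n_cells`.
#' @export
encoding_recall_pv_corr <- function(encoding_matrix, encoding_name,
                                    recall_matrix, recall_name,
                                    table, bin_s = 30) {
  sh <- shared_active_values(encoding_matrix, encoding_name,
                             recall_matrix, recall_name, table)
  enc_vec <- rowMeans(sh$a)
  width <- as.integer(round(bin_s * recall_matrix$frame_rate))
  n_bins <- ncol(sh$b) %/% width
  if (n_bins == 0) stop("recall session shorter than one bin")
  taus <- vapply(seq_len(n_bins), function(b) {
    idx <- ((b - 1L) * width + 1L):(b * width)
    rec_vec <- rowMeans(sh$b[, idx, drop = FALSE])
    suppressWarnings(stats::cor(enc_vec, rec_vec, method = "kendall"))
  }, numeric(1))
  list(mean_tau = mean(taus, na.rm = TRUE), per_bin_tau = taus,
       n_bins = n_bins, n_cells = nrow(sh$a))
}

#' Encoding population-vector correlation matrix (intra vs inter session)
#'
#' Cells active during both encoding sessions are aligned and both sessions
#' binned; the bin x bin correlation matrix over the concatenation yields
#' mean intra-session (diagonal blocks, self-comparisons excluded) and
#' inter-session (off-diagonal block) correlations — a measure of how
#' discriminable the two context representations are.
#'
#' @param neutral_enc,aversive_enc `event_matrix` objects.
#' @param neutral_name,aversive_name session identifiers as used in `table`.
#' @param table a `match_table` linking the sessions.
#' @param bin_s bin width in seconds (default 30).
#' @param method correlation method for the matrix (default "pearson").
#' @return a `pv_correlation_summary`: list with `matrix`, `intra_neutral`,
#'   `intra_aversive`, `inter`, `n_bins_neutral`, `n_bins_aversive`.
#' @export
encoding_pv_matrix <- function(neutral_enc, neutral_name,
                               aversive_enc, aversive_name,
                               table, bin_s = 30, method = "pearson") {
  sh <- shared_active_values(neutral_enc, neutral_name,
                             aversive_enc, aversive_name, table)
  wn <- as.integer(round(bin_s * neutral_enc$frame_rate))
  wa <- as.integer(round(bin_s * aversive_enc$frame_rate))
  bn <- ncol(sh$a) %/% wn
  ba <- ncol(sh$b) %/% wa
  if (bn == 0 || ba == 0) stop("a session is shorter than one bin")
  bin_mat <- function(v, w, nb) {
    vapply(seq_len(nb), function(b) {
      rowMeans(v[, ((b - 1L) * w + 1L):(b * w), drop = FALSE])
    }, numeric(nrow(v)))
  }
  pv <- cbind(bin_mat(sh$a, wn, bn), bin_mat(sh$b, wa, ba))
  cm <- suppressWarnings(stats::cor(pv, method = method))
  idx_n <- seq_len(bn)
  idx_a <- bn + seq_len(ba)
  off_diag_mean <- function(block) {
    if (nrow(block) < 2) return(NA_real_)
    mean(block[upper.tri(block)])
  }
  structure(
    list(matrix = cm,
         intra_neutral = off_diag_mean(cm[idx_n, idx_n, drop = FALSE]),
         intra_aversive = off_diag_mean(cm[idx_a, idx_a, drop = FALSE]),
         inter = mean(cm[idx_n, idx_a]),
         n_bins_neutral = bn, n_bins_aversive = ba),
    class = "pv_correlation_summary"
  )
}
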