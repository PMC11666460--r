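# Chemogenetic tagging: rank cells by CNO-session responsiveness, propagate
# putative-inhibitory labels across sessions, and test ensemble enrichment.

#' Find peaks by topographic prominence
#'
#' Local maxima of a numeric trace filtered by prominence: for each peak the
#' bases are the minima between the peak and the nearest higher point on
#' each side (or the signal edge), and prominence is the peak height minus
#' the higher of the two bases. Peaks closer than `min_distance` samples are
#' thinned keeping the higher peak (ties keep the earlier). Plateaus count
#' once, at their first sample.
#'
#' @param x numeric trace.
#' @param min_prominence minimum prominence to keep a peak.
#' @param min_distance minimum spacing between kept peaks, in samples.
#' @return integer vector of 1-based peak positions.
#' @export
find_prominent_peaks <- function(x, min_prominence = 0, min_distance = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  # candidate local maxima (first sample of any plateau)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) cand <- c(cand, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(p) peak_prominence(x, p), numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) <= 1 || min_distance <= 1) return(cand)
  # thin by distance, keeping higher peaks first (earlier on ties)
  ord <- order(-x[cand], cand)
  selected <- logical(length(cand))
  blocked <- logical(length(cand))
  for (k in ord) {
    if (blocked[k]) next
    selected[k] <- TRUE
    blocked[abs(cand - cand[k]) < min_distance & seq_along(cand) != k] <- TRUE
  }
  sort(cand[selected])
}

# Prominence of the peak at position p: height above the higher of the two
# base minima (minima between the peak and the nearest strictly higher
# sample on each side, or the edge).
peak_prominence <- function(x, p) {
  n <- length(x)
  left_min <- x[p]
  i <- p - 1L
  while (i >= 1L && x[i] <= x[p]) {
    left_min <- min(left_min, x[i])
    i <- i - 1L
  }
  if (i < 1L) left_min <- min(x[seq_len(p)])
  right_min <- x[p]
  i <- p + 1L
  while (i <= n && x[i] <= x[p]) {
    right_min <- min(right_min, x[i])
    i <- i + 1L
  }
  if (i > n) right_min <- min(x[p:n])
  x[p] - max(left_min, right_min)
}

#' Rank cells by prominent-peak count in the CNO response window
#'
#' Each cell's continuous calcium trace is min-max normalized to [0, 1] (so
#' any per-cell affine gain is absorbed) and its prominent peaks are counted
#' within the analysis window, by default minutes 10-40 of the 45-min CNO
#' session. Cells are sorted from most to least responsive; ties break by
#' cell id; the top fraction are flagged as putative inhibitory neurons.
#'
#' @param traces an `event_matrix` holding continuous traces (not
#'   deconvolved events) for the chemotag session.
#' @param window_min analysis window in minutes, half-open (default
#'   `c(10, 40)`).
#' @param min_prominence peak prominence threshold as a fraction of the
#'   normalized range (default 0.3).
#' @param min_distance_s minimum peak spacing in seconds (default 2).
#' @param top_frac fraction of cells flagged putative inhibitory (default
#'   0.10, matching the anatomical inhibitory fraction in CA1).
#' @return a `chemotag_ranking`: data.frame (cell_id, peak_count, rank,
#'   flagged) ordered by rank, with the parameters as attributes.
#' @export
rank_chemotag <- function(traces, window_min = c(10, 40),
                          min_prominence = 0.3, min_distance_s = 2,
                          top_frac = 0.10) {
  stopifnot(inherits(traces, "event_matrix"))
  dur_min <- ncol(traces$values) / traces$frame_rate / 60
  if (dur_min < window_min[2]) {
    stop(sprintf("session is %.1f min; need >= %g min", dur_min,
                 window_min[2]))
  }
  f0 <- as.integer(floor(window_min[1] * 60 * traces$frame_rate)) + 1L
  f1 <- as.integer(floor(window_min[2] * 60 * traces$frame_rate))
  min_dist <- max(1L, as.integer(round(min_distance_s * traces$frame_rate)))
  counts <- vapply(seq_len(nrow(traces$values)), function(i) {
    v <- traces$values[i, ]
    rng <- range(v)
    if (diff(rng) == 0) return(0L)  # flat trace: zero peaks
    v <- (v - rng[1]) / diff(rng)
    length(find_prominent_peaks(v[f0:f1], min_prominence, min_dist))
  }, integer(1))
  ids <- traces$cell_ids
  ord <- order(-counts, ids)
  rk <- integer(length(ids))
  rk[ord] <- seq_along(ids)
  n_flag <- ceiling(top_frac * length(ids))
  out <- data.frame(cell_id = ids, peak_count = counts, rank = rk,
                    flagged = rk <= n_flag, stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- list(window_min = window_min,
                              min_prominence = min_prominence,
                              min_distance_s = min_distance_s,
                              top_frac = top_frac)
  class(out) <- c("chemotag_ranking", "data.frame")
  out
}

#' Propagate chemotag responsiveness to another session
#'
#' Target cells matched to a tag-day cell inherit its peak count; unmatched
#' target cells are treated as having zero activity on tag day (an hM3Dq+
#' cell would have responded to CNO) and rank after all matched cells.
#' Ranks and top-fraction flags are recomputed over the target population.
#'
#' @param ranking a `chemotag_ranking` for the tag session.
#' @param table a `match_table` linking tag session and target session.
#' @param tag_name,target_name session identifiers as used in `table`.
#' @param target_cells cell ids of the target session.
#' @param top_frac fraction flagged in the target population (default taken
#'   from the ranking's parameters).
#' @return a `chemotag_ranking` over `target_cells`.
#' @export
propagate_labels <- function(ranking, table, tag_name, target_name,
                             target_cells, top_frac = NULL) {
  if (is.null(top_frac)) top_frac <- attr(ranking, "params")$top_frac
  counts <- stats::setNames(rep(0L, length(target_cells)),
                            as.character(target_cells))
  if (nrow(table) > 0) {
    ids_tag <- match_side(table, tag_name)
    ids_tgt <- match_side(table, target_name)
    keep <- ids_tgt %in% target_cells & ids_tag %in% ranking$cell_id
    src <- ranking$peak_count[match(ids_tag[keep], ranking$cell_id)]
    counts[as.character(ids_tgt[keep])] <- src
  }
  ord <- order(-counts, target_cells)
  rk <- integer(length(target_cells))
  rk[ord] <- seq_along(target_cells)
  n_flag <- ceiling(top_frac * length(target_cells))
  out <- data.frame(cell_id = target_cells, peak_count = as.integer(counts),
                    rank = rk, flagged = rk <= n_flag,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- c(attr(ranking, "params")["window_min"],
                           list(top_frac = top_frac))
  class(out) <- c("chemotag_ranking", "data.frame")
  out
}

#' Putative-inhibitory composition of the memory ensembles
#'
#' For each ensemble, the fraction of its cells flagged putative inhibitory,
#' with a hypergeometric over-representation test of each ensemble against
#' the whole population.
#'
#' @param assignment an `ensemble_assignment`.
#' @param ranking a `chemotag_ranking` covering the same cells (typically
#'   from [propagate_labels()]).
#' @return data.frame (ensemble, n_cells, n_flagged, fraction, p_enrich);
#'   empty ensembles omitted.
#' @export
ensemble_composition <- function(assignment, ranking) {
  flags <- stats::setNames(ranking$flagged, as.character(ranking$cell_id))
  cells <- names(assignment$labels)
  if (!all(cells %in% names(flags))) {
    stop("ranking does not cover all assigned cells")
  }
  flags <- flags[cells]
  n_total <- length(cells)
  k_total <- sum(flags)
  rows <- list()
  for (e in c("neutral", "aversive", "overlap", "remaining")) {
    members <- ensemble_cells(assignment, e)
    if (length(members) == 0) next
    n <- length(members)
    k <- sum(flags[members])
    # P(X >= k) drawing n cells from n_total with k_total flagged
    p <- stats::phyper(k - 1, k_total, n_total - k_total, n,
                       lower.tail = FALSE)
    rows[[e]] <- data.frame(ensemble = e, n_cells = n, n_flagged = k,
                            fraction = k / n, p_enrich = p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
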