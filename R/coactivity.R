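# Independent vs coincident ensemble participation in bursts and non-burst
# periods, and time-lagged cross-correlations between ensemble mean traces.

TRACKED_ENSEMBLES <- c("neutral", "aversive", "overlap")

#' Z-scored mean activity trace per ensemble
#'
#' For each requested ensemble: per-cell z-score over time, mean across the
#' ensemble's cells, and a final z-score of that mean trace.
#'
#' @param matrix an `event_matrix`.
#' @param assignment an `ensemble_assignment` over the matrix's cells.
#' @param ensembles which ensembles to compute (default neutral, aversive,
#'   overlap). Empty ensembles are omitted with a warning.
#' @return numeric matrix, ensembles x frames.
#' @export
ensemble_mean_traces <- function(matrix, assignment,
                                 ensembles = TRACKED_ENSEMBLES) {
  check_event_matrix(matrix)
  z <- zscore_rows(matrix$values)
  out <- list()
  for (e in ensembles) {
    members <- ensemble_cells(assignment, e)
    if (length(members) == 0) {
      warning(sprintf("ensemble '%s' is empty; trace omitted", e))
      next
    }
    out[[e]] <- zscore_vec(colMeans(z[members, , drop = FALSE]))
  }
  do.call(rbind, out)
}

#' Ensemble participation in burst events
#'
#' An ensemble participates in an event if its z-scored mean trace exceeds
#' the threshold on at least one frame of the event.
#'
#' @param ensemble_traces ensembles x frames matrix from
#'   [ensemble_mean_traces()] (or re-z-scored concatenated traces).
#' @param catalog a `burst_catalog` on the same frame axis.
#' @param threshold_z participation threshold (default 2).
#' @return logical matrix, ensembles x events.
#' @export
ensemble_event_participation <- function(ensemble_traces, catalog,
                                         threshold_z = 2) {
  if (ncol(ensemble_traces) != length(catalog$trace)) {
    stop("ensemble traces and catalog disagree on frame count")
  }
  ev <- catalog$events
  out <- matrix(FALSE, nrow(ensemble_traces), nrow(ev),
                dimnames = list(rownames(ensemble_traces), NULL))
  for (i in seq_len(nrow(ev))) {
    span <- (ev$start[i] + 1L):ev$end[i]
    out[, i] <- apply(ensemble_traces[, span, drop = FALSE], 1, max) >
      threshold_z
  }
  out
}

#' Independent and pairwise co-participation fractions
#'
#' Independent participation of ensemble E: the fraction of events in which
#' E participates and no other tracked ensemble does. Co-participation of a
#' pair: the fraction of events in which both members participate
#' (regardless of the third).
#'
#' @param participation logical ensembles x events matrix from
#'   [ensemble_event_participation()].
#' @return a `coparticipation_summary`: list with `independent` (named
#'   fractions), `pairs` (data.frame ensemble_a, ensemble_b, fraction),
#'   `n_events`, `empty`.
#' @export
coparticipation_fractions <- function(participation) {
  n_events <- ncol(participation)
  if (n_events == 0) {
    return(structure(list(independent = NULL, pairs = NULL, n_events = 0L,
                          empty = TRUE),
                     class = "coparticipation_summary"))
  }
  ens <- rownames(participation)
  n_part <- colSums(participation)
  independent <- vapply(ens, function(e) {
    mean(participation[e, ] & n_part == 1)
  }, numeric(1))
  combs <- utils::combn(ens, 2)
  pairs <- data.frame(
    ensemble_a = combs[1, ], ensemble_b = combs[2, ],
    fraction = apply(combs, 2, function(p) {
      mean(participation[p[1], ] & participation[p[2], ])
    }),
    stringsAsFactors = FALSE
  )
  structure(list(independent = independent, pairs = pairs,
                 n_events = n_events, empty = FALSE),
            class = "coparticipation_summary")
}

# Fraction for one named pair out of a coparticipation_summary.
pair_fraction <- function(summary, a, b) {
  p <- summary$pairs
  hit <- (p$ensemble_a == a & p$ensemble_b == b) |
    (p$ensemble_a == b & p$ensemble_b == a)
  if (!any(hit)) return(NA_real_)
  p$fraction[hit][1]
}

#' Co-participation over non-burst windows
#'
#' Frames outside all burst events are partitioned into contiguous windows
#' whose length equals the median burst duration of the same catalog
#' (remainder frames at the end of each non-burst segment are dropped), and
#' the event-participation rule is applied per window.
#'
#' @inheritParams ensemble_event_participation
#' @return a `coparticipation_summary` over non-burst windows.
#' @export
nonburst_coparticipation <- function(ensemble_traces, catalog,
                                     threshold_z = 2) {
  n_frames <- length(catalog$trace)
  ev <- catalog$events
  if (nrow(ev) == 0) {
    win <- 1L  # no bursts: no duration scale; degenerate single-frame windows
  } else {
    win <- max(1L, as.integer(round(stats::median(ev$end - ev$start))))
  }
  in_burst <- rep(FALSE, n_frames)
  for (i in seq_len(nrow(ev))) {
    in_burst[(ev$start[i] + 1L):ev$end[i]] <- TRUE
  }
  segs <- true_runs(!in_burst)
  windows <- list()
  for (i in seq_len(nrow(segs))) {
    s <- unname(segs[i, "start"]); e <- unname(segs[i, "end"])
    n_win <- (e - s) %/% win
    for (k in seq_len(n_win)) {
      windows[[length(windows) + 1]] <-
        c(start = s + (k - 1L) * win, end = s + k * win)
    }
  }
  if (length(windows) == 0) {
    return(structure(list(independent = NULL, pairs = NULL, n_events = 0L,
                          empty = TRUE),
                     class = "coparticipation_summary"))
  }
  wmat <- do.call(rbind, windows)
  pseudo <- structure(list(events = data.frame(start = wmat[, "start"],
                                               peak = wmat[, "start"],
                                               end = wmat[, "end"]),
                           trace = catalog$trace,
                           threshold_z = catalog$threshold_z),
                      class = "burst_catalog")
  part <- ensemble_event_participation(ensemble_traces, pseudo, threshold_z)
  coparticipation_fractions(part)
}

#' Mean time-lagged cross-correlation between two traces
#'
#' The traces are broken into `bin_s` bins; within each bin the Pearson
#' correlation is computed at every integer lag up to `max_lag_frames`, the
#' maximum (signed) correlation over lags is taken, and the per-bin maxima
#' are averaged. The trailing partial bin is dropped; bins where either
#' trace has zero variance are skipped and counted.
#'
#' @param trace_a,trace_b equal-length numeric traces.
#' @param frame_rate frames per second.
#' @param bin_s bin width in seconds (default 120).
#' @param max_lag_frames maximum lag in frames (default 5, ~160 ms at 30 Hz).
#' @return list with `mean_max_corr`, `per_bin_max`, `n_bins`,
#'   `n_skipped_bins`.
#' @export
lagged_crosscorr <- function(trace_a, trace_b, frame_rate, bin_s = 120,
                             max_lag_frames = 5) {
  if (length(trace_a) != length(trace_b)) stop("traces must have equal length")
  win <- as.integer(round(bin_s * frame_rate))
  n_bins <- length(trace_a) %/% win
  if (n_bins == 0) stop("traces shorter than one bin")
  per_bin <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    idx <- ((b - 1L) * win + 1L):(b * win)
    a <- trace_a[idx]; v <- trace_b[idx]
    if (stats::sd(a) == 0 || stats::sd(v) == 0) next
    best <- -Inf
    for (lag in -max_lag_frames:max_lag_frames) {
      if (lag >= 0) {
        x <- a[seq_len(win - lag)]
        y <- v[(1 + lag):win]
      } else {
        x <- a[(1 - lag):win]
        y <- v[seq_len(win + lag)]
      }
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      best <- max(best, stats::cor(x, y))
    }
    if (is.finite(best)) per_bin[b] <- best
  }
  skipped <- sum(is.na(per_bin))
  list(mean_max_corr = mean(per_bin, na.rm = TRUE), per_bin_max = per_bin,
       n_bins = n_bins, n_skipped_bins = skipped)
}

#' Concatenate per-session ensemble traces into a pseudocontinuous series
#'
#' Mean ensemble activities from several offline recordings are concatenated
#' in temporal order and the concatenated trace is z-scored per ensemble.
#' Session boundaries are recorded so burst detection never returns an event
#' spanning two recordings.
#'
#' @param trace_list list of ensembles x frames matrices (same ensembles in
#'   every session; sessions missing an ensemble are excluded with warning).
#' @return list with `traces` (ensembles x total frames, z-scored),
#'   `boundaries` (0-based start frame of each session after the first).
#' @export
concatenate_offline <- function(trace_list) {
  if (length(trace_list) == 0) stop("empty session list")
  # reference ensembles: those of the first session; later sessions lacking
  # any of them are excluded rather than silently shrinking the set
  ref <- rownames(trace_list[[1]])
  keep <- vapply(trace_list, function(m) all(ref %in% rownames(m)),
                 logical(1))
  if (!all(keep)) {
    warning("sessions missing a reference ensemble were excluded")
    trace_list <- trace_list[keep]
  }
  mats <- lapply(trace_list, function(m) m[ref, , drop = FALSE])
  lens <- vapply(mats, ncol, integer(1))
  concat <- do.call(cbind, mats)
  concat <- zscore_rows(concat)
  boundaries <- cumsum(lens)[-length(lens)]
  list(traces = concat, boundaries = as.integer(boundaries))
}
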