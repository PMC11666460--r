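# Population burst detection and burst participation.

#' Doubly z-scored mean population activity trace
#'
#' Each cell is z-scored along time so no single high-amplitude cell
#' dominates, the mean across cells is taken, and that one-dimensional trace
#' is z-scored again. Zero-variance (silent) cells contribute zeros.
#'
#' @param matrix an `event_matrix`.
#' @return numeric trace, one value per frame.
#' @export
population_trace <- function(matrix) {
  check_event_matrix(matrix)
  v <- matrix$values
  if (ncol(v) < 2 || nrow(v) < 1) stop("need at least 1 cell and 2 frames")
  if (all(v == 0)) {
    warning("all-zero event matrix: population trace is identically zero")
    return(rep(0, ncol(v)))
  }
  zscore_vec(colMeans(zscore_rows(v)))
}

#' Detect population burst events by threshold crossing
#'
#' Each maximal contiguous run of frames with `trace > threshold_z` is one
#' burst event. Runs separated by at least one sub-threshold frame are
#' distinct; there is no merging and no minimum duration. The peak is the
#' frame of maximum trace within the run (earliest on ties). Optional
#' `boundaries` (0-based frame indices of session joins in a concatenated
#' trace) split any run that would straddle a join.
#'
#' @param trace numeric population trace (output of [population_trace()] or
#'   a concatenated ensemble trace).
#' @param threshold_z detection threshold in z units (default 2).
#' @param boundaries optional integer vector of 0-based boundary frames.
#' @return a `burst_catalog`: list with `events` (data.frame start, peak,
#'   end; 0-based, half-open [start, end)), `trace`, `threshold_z`.
#' @export
detect_bursts <- function(trace, threshold_z = 2, boundaries = NULL) {
  above <- trace > threshold_z
  if (!is.null(boundaries) && length(boundaries) > 0) {
    # a frame just before a boundary cannot be contiguous with the frame after
    runs_list <- list()
    cuts <- sort(unique(c(0L, boundaries, length(trace))))
    for (i in seq_len(length(cuts) - 1)) {
      seg <- cuts[i]:(cuts[i + 1] - 1L) + 1L
      r <- true_runs(above[seg])
      if (nrow(r) > 0) {
        r[, "start"] <- r[, "start"] + cuts[i]
        r[, "end"] <- r[, "end"] + cuts[i]
        runs_list[[length(runs_list) + 1]] <- r
      }
    }
    runs <- do.call(rbind, runs_list)
    if (is.null(runs)) runs <- cbind(start = integer(0), end = integer(0))
  } else {
    runs <- true_runs(above)
  }
  if (nrow(runs) > 0) {
    peak <- vapply(seq_len(nrow(runs)), function(i) {
      span <- (runs[i, "start"] + 1L):runs[i, "end"]
      span[which.max(trace[span])] - 1L
    }, integer(1))
    events <- data.frame(start = as.integer(runs[, "start"]),
                         peak = as.integer(peak),
                         end = as.integer(runs[, "end"]))
    events <- events[order(events$start), , drop = FALSE]
    rownames(events) <- NULL
  } else {
    events <- data.frame(start = integer(0), peak = integer(0),
                         end = integer(0))
  }
  structure(list(events = events, trace = trace, threshold_z = threshold_z),
            class = "burst_catalog")
}

#' @export
print.burst_catalog <- function(x, ...) {
  cat(sprintf("<burst_catalog> %d events over %d frames (z > %g)\n",
              nrow(x$events), length(x$trace), x$threshold_z))
  invisible(x)
}

#' Per-cell burst participation
#'
#' A cell participates in a burst event if its z-scored activity exceeds
#' `cell_threshold_z` on at least one frame of the event.
#'
#' @param matrix the `event_matrix` the catalog was computed from.
#' @param catalog a `burst_catalog` on the same frame axis.
#' @param cell_threshold_z per-cell threshold in z units (default 2).
#' @return logical matrix, cells x events.
#' @export
cell_participation <- function(matrix, catalog, cell_threshold_z = 2) {
  check_event_matrix(matrix)
  if (ncol(matrix$values) != length(catalog$trace)) {
    stop("catalog and matrix disagree on frame count")
  }
  z <- zscore_rows(matrix$values)
  ev <- catalog$events
  out <- matrix(FALSE, nrow(matrix$values), nrow(ev),
                dimnames = list(rownames(matrix$values), NULL))
  for (i in seq_len(nrow(ev))) {
    span <- (ev$start[i] + 1L):ev$end[i]
    out[, i] <- matrixStats_rowMaxs(z[, span, drop = FALSE]) > cell_threshold_z
  }
  out
}

# Row maxima without an extra dependency.
matrixStats_rowMaxs <- function(m) {
  if (ncol(m) == 1) return(m[, 1])
  apply(m, 1, max)
}

#' Mean ensemble burst-participation fractions
#'
#' For each ensemble, the fraction of its cells participating in each burst
#' event, averaged across events.
#'
#' @param participation logical cells x events matrix from
#'   [cell_participation()].
#' @param assignment an `ensemble_assignment` covering all cells.
#' @return a `participation_summary`: list with `fractions` (named numeric,
#'   NA for empty ensembles), `per_event` (ensembles x events matrix of
#'   fractions), `n_events`.
#' @export
ensemble_participation <- function(participation, assignment) {
  cells <- rownames(participation)
  if (!setequal(cells, names(assignment$labels))) {
    stop("assignment does not cover the cells of the participation matrix")
  }
  n_events <- ncol(participation)
  if (n_events == 0) {
    return(structure(list(fractions = NULL, per_event = NULL, n_events = 0L,
                          empty = TRUE),
                     class = "participation_summary"))
  }
  ensembles <- c("neutral", "aversive", "overlap", "remaining")
  per_event <- matrix(NA_real_, length(ensembles), n_events,
                      dimnames = list(ensembles, NULL))
  for (e in ensembles) {
    members <- ensemble_cells(assignment, e)
    if (length(members) == 0) next
    sub <- participation[members, , drop = FALSE]
    per_event[e, ] <- colMeans(sub)
  }
  structure(list(fractions = rowMeans(per_event), per_event = per_event,
                 n_events = n_events, empty = FALSE),
            class = "participation_summary")
}

#' Circular-shift shuffle null for burst counts
#'
#' Each shuffle independently rotates every cell's event train by a uniform
#' random offset, preserving per-cell rate and autocorrelation while
#' destroying cross-cell synchrony, then recomputes the population trace and
#' burst detection.
#'
#' @param matrix an `event_matrix`.
#' @param n_shuffles number of surrogates (>= 100 recommended).
#' @param seed RNG seed.
#' @param threshold_z burst threshold passed to [detect_bursts()].
#' @return list with `observed_count`, `observed_peak_z`, `null_counts`,
#'   `null_peak_z` (max trace value per surrogate), `p_value` (add-one
#'   empirical lower tail on the event count) and `p_peak` (add-one upper
#'   tail on the peak z).
#'
#' @details Synchronous bursts concentrate the session's activity into few
#' long, large threshold crossings; destroying synchrony by circular shifts
#' spreads the same events over many brief crossings of a flatter trace.
#' Planted or real synchrony therefore shows up as an observed event count
#' in the *lower* tail of the null (fewer, bigger events than chance) and an
#' observed peak z in the upper tail; both one-sided p-values are returned.
#' @export
shuffle_null <- function(matrix, n_shuffles = 500, seed = 1, threshold_z = 2) {
  check_event_matrix(matrix)
  obs_trace <- suppressWarnings(population_trace(matrix))
  obs <- nrow(detect_bursts(obs_trace, threshold_z)$events)
  v <- matrix$values
  n_frames <- ncol(v)
  null_counts <- integer(n_shuffles)
  null_peak <- numeric(n_shuffles)
  set.seed(seed)
  for (s in seq_len(n_shuffles)) {
    offs <- sample.int(n_frames, nrow(v), replace = TRUE) - 1L
    shifted <- v
    for (i in seq_len(nrow(v))) {
      if (offs[i] > 0) {
        shifted[i, ] <- c(v[i, (n_frames - offs[i] + 1L):n_frames],
                          v[i, seq_len(n_frames - offs[i])])
      }
    }
    sm <- event_matrix(shifted, matrix$frame_rate, matrix$timestamps,
                       matrix$cell_ids)
    tr <- suppressWarnings(population_trace(sm))
    null_counts[s] <- nrow(detect_bursts(tr, threshold_z)$events)
    null_peak[s] <- max(tr)
  }
  list(observed_count = obs, observed_peak_z = max(obs_trace),
       null_counts = null_counts, null_peak_z = null_peak,
       p_value = (1 + sum(null_counts <= obs)) / (n_shuffles + 1),
       p_peak = (1 + sum(null_peak >= max(obs_trace))) / (n_shuffles + 1))
}

#' Peri-burst locomotion traces
#'
#' Extracts the locomotion signal in a window around each burst peak,
#' interpolated onto a regular relative-time grid. Events whose window would
#' extend past either session edge are excluded.
#'
#' @param locomotion numeric locomotion trace.
#' @param locomotion_timestamps its per-sample times in ms.
#' @param catalog a `burst_catalog`.
#' @param frame_timestamps per-frame times of the calcium recording the
#'   catalog indexes into.
#' @param window_s half-window in seconds (default 5).
#' @param grid_hz sampling of the relative-time grid (default 20).
#' @return list with `time_s` (relative grid), `traces` (events x time
#'   matrix), `mean` (mean trace), `n_events_used`, `available`.
#' @export
peri_burst_locomotion <- function(locomotion, locomotion_timestamps, catalog,
                                  frame_timestamps, window_s = 5,
                                  grid_hz = 20) {
  if (is.null(locomotion)) {
    return(list(available = FALSE, n_events_used = 0L,
                time_s = NULL, traces = NULL, mean = NULL))
  }
  grid <- seq(-window_s, window_s, by = 1 / grid_hz)
  t0 <- locomotion_timestamps[1]
  t1 <- locomotion_timestamps[length(locomotion_timestamps)]
  rows <- list()
  for (i in seq_len(nrow(catalog$events))) {
    peak_ms <- frame_timestamps[catalog$events$peak[i] + 1L]
    lo <- peak_ms - window_s * 1000
    hi <- peak_ms + window_s * 1000
    if (lo < t0 || hi > t1) next  # truncated by session edge: drop
    rows[[length(rows) + 1]] <- stats::approx(
      locomotion_timestamps, locomotion, xout = peak_ms + grid * 1000)$y
  }
  if (length(rows) == 0) {
    return(list(available = TRUE, n_events_used = 0L, time_s = grid,
                traces = NULL, mean = NULL))
  }
  traces <- do.call(rbind, rows)
  list(available = TRUE, n_events_used = nrow(traces), time_s = grid,
       traces = traces, mean = colMeans(traces))
}
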