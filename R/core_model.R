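# Data model: event matrices, match tables, ensemble assignment and
# timestamp alignment. Frame indexing is 0-based throughout and intervals
# are half-open [start, end).

#' Construct a deconvolved event matrix
#'
#' The atomic recording unit: a cells x frames matrix of nonnegative
#' deconvolved event amplitudes, with per-frame wall-clock timestamps and the
#' nominal acquisition rate.
#'
#' @param values numeric matrix, cells x frames, nonnegative.
#' @param frame_rate frames per second (30, or 15 for telemetry-paired
#'   recordings).
#' @param timestamps per-frame wall-clock time in ms, strictly increasing.
#'   Defaults to an ideal grid at `frame_rate`.
#' @param cell_ids unique per-session cell identifiers; defaults to
#'   `1:nrow(values)`.
#' @return an object of class `event_matrix`.
#' @export
event_matrix <- function(values, frame_rate,
                         timestamps = NULL, cell_ids = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) {
    stop("event matrix values must be nonnegative")
  }
  if (is.null(timestamps)) {
    timestamps <- (seq_len(ncol(values)) - 1) * 1000 / frame_rate
  }
  if (length(timestamps) != ncol(values)) {
    stop("timestamps length must equal frame count")
  }
  if (ncol(values) > 1 && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (is.null(cell_ids)) cell_ids <- seq_len(nrow(values))
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  rownames(values) <- as.character(cell_ids)
  structure(
    list(values = values, frame_rate = frame_rate,
         timestamps = as.numeric(timestamps), cell_ids = cell_ids),
    class = "event_matrix"
  )
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("<event_matrix> %d cells x %d frames @ %g Hz (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$frame_rate,
              ncol(x$values) / x$frame_rate))
  invisible(x)
}

# Validate that an object is an event_matrix; used by all downstream stages.
check_event_matrix <- function(m) {
  if (!inherits(m, "event_matrix")) stop("expected an event_matrix")
  if (any(m$values < 0)) stop("event matrix contains negative values")
  invisible(m)
}

#' Construct a cross-session cell match table
#'
#' Cross-registration output (e.g. from a spatial-footprint matcher) linking
#' cell identities across two sessions. Matching must be injective: each
#' cell id appears at most once per side.
#'
#' @param session_a,session_b session identifiers.
#' @param cell_id_a,cell_id_b equal-length vectors of matched cell ids.
#' @return an object of class `match_table` (a data.frame).
#' @export
match_table <- function(session_a, session_b, cell_id_a, cell_id_b) {
  if (length(cell_id_a) != length(cell_id_b)) {
    stop("cell_id_a and cell_id_b must have equal length")
  }
  if (anyDuplicated(cell_id_a) || anyDuplicated(cell_id_b)) {
    stop("match table is not injective: a cell id appears more than once")
  }
  structure(
    data.frame(session_a = rep(session_a, length(cell_id_a)),
               session_b = rep(session_b, length(cell_id_b)),
               cell_id_a = cell_id_a, cell_id_b = cell_id_b,
               stringsAsFactors = FALSE),
    class = c("match_table", "data.frame")
  )
}

# Ids in `table` on the side naming `session`; errors if the table does not
# reference the session at all.
match_side <- function(table, session) {
  if (nrow(table) == 0) return(integer(0))
  if (all(table$session_a == session)) return(table$cell_id_a)
  if (all(table$session_b == session)) return(table$cell_id_b)
  stop(sprintf("match table does not reference session '%s'", session))
}

#' Assign offline cells to the four memory ensembles
#'
#' Cells of an offline session are partitioned by their cross-registration
#' with the two encoding sessions: matched only to neutral encoding ->
#' `neutral`; only to aversive -> `aversive`; to both -> `overlap`; to
#' neither -> `remaining`.
#'
#' @param cell_ids cell ids of the offline session.
#' @param session offline session identifier (must appear in both tables,
#'   unless a table is empty).
#' @param match_to_neutral,match_to_aversive `match_table`s linking the
#'   offline session to the neutral and aversive encoding sessions.
#' @return an object of class `ensemble_assignment`: list with `session` and
#'   a named character vector `labels` over all cells.
#' @export
assign_ensembles <- function(cell_ids, session,
                             match_to_neutral, match_to_aversive) {
  ids_n <- if (nrow(match_to_neutral)) match_side(match_to_neutral, session) else integer(0)
  ids_a <- if (nrow(match_to_aversive)) match_side(match_to_aversive, session) else integer(0)
  unknown <- setdiff(c(ids_n, ids_a), cell_ids)
  if (length(unknown) > 0) {
    stop(sprintf("match table references unknown cell id(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  in_n <- cell_ids %in% ids_n
  in_a <- cell_ids %in% ids_a
  labels <- rep("remaining", length(cell_ids))
  labels[in_n & !in_a] <- "neutral"
  labels[!in_n & in_a] <- "aversive"
  labels[in_n & in_a] <- "overlap"
  names(labels) <- as.character(cell_ids)
  structure(list(session = session, labels = labels),
            class = "ensemble_assignment")
}

#' @export
print.ensemble_assignment <- function(x, ...) {
  cat(sprintf("<ensemble_assignment> session '%s': ", x$session))
  print(table(factor(x$labels,
                     levels = c("neutral", "aversive", "overlap", "remaining"))))
  invisible(x)
}

# Cell ids belonging to one ensemble.
ensemble_cells <- function(assignment, ensemble) {
  names(assignment$labels)[assignment$labels == ensemble]
}

#' Align recorded frames to an ideal sampling-rate template
#'
#' Maps each slot of an idealized constant-rate template onto the nearest
#' recorded frame, reporting the maximum displacement. Recordings are
#' expected to sit within four frames of the ideal template; larger
#' displacement triggers a warning, not an error.
#'
#' @param timestamps recorded per-frame times in ms, strictly increasing.
#' @param nominal_rate ideal frames per second.
#' @return an `alignment_map`: list with `target_index` (0-based recorded
#'   frame per template slot), `reuse` (times each recorded frame is used),
#'   `n_template` and `max_displacement_frames`.
#' @export
align_to_template <- function(timestamps, nominal_rate) {
  if (length(timestamps) == 0) stop("empty timestamps")
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  duration_ms <- timestamps[length(timestamps)] - timestamps[1]
  n_template <- round(duration_ms / 1000 * nominal_rate) + 1
  grid <- timestamps[1] + (seq_len(n_template) - 1) * 1000 / nominal_rate
  idx <- nearest_index(timestamps, grid)
  displacement <- abs(timestamps[idx + 1] - grid) * nominal_rate / 1000
  max_disp <- max(displacement)
  if (max_disp > 4) {
    warning(sprintf(
      "recording deviates from ideal template by %.2f frames (> 4)", max_disp))
  }
  structure(
    list(target_index = idx, reuse = tabulate(idx + 1, length(timestamps)),
         n_template = n_template, max_displacement_frames = max_disp),
    class = "alignment_map"
  )
}

# 0-based index of the nearest value in `sorted` for each query; ties go to
# the earlier frame (deterministic, order-independent).
nearest_index <- function(sorted, queries) {
  hi <- findInterval(queries, sorted)        # last sorted <= query (1-based)
  lo <- pmax(hi, 1L)
  hi2 <- pmin(hi + 1L, length(sorted))
  d_lo <- abs(queries - sorted[lo])
  d_hi <- abs(queries - sorted[hi2])
  use_lo <- hi >= 1L & (d_lo <= d_hi | hi2 == hi)
  ifelse(use_lo, lo, hi2) - 1L
}

#' Align calcium frames to target (behaviour) frames with a reuse cap
#'
#' Each target frame receives the nearest calcium frame by wall-clock time.
#' No calcium frame may serve more than two target frames: while the cap is
#' violated, the assignment with the largest time error among the offending
#' frame's targets is greedily moved to its next-nearest calcium frame with
#' remaining capacity.
#'
#' @param calcium_timestamps,target_timestamps strictly increasing ms times.
#' @param max_reuse reuse cap per calcium frame (default 2).
#' @return an `alignment_map`: `target_index` gives the 0-based calcium frame
#'   assigned to each target frame; `reuse` counts uses per calcium frame.
#' @export
align_calcium_to_target <- function(calcium_timestamps, target_timestamps,
                                    max_reuse = 2L) {
  if (length(calcium_timestamps) == 0 || length(target_timestamps) == 0) {
    stop("empty timestamp vector")
  }
  if (length(target_timestamps) > max_reuse * length(calcium_timestamps)) {
    stop("too few calcium frames to cover targets under the reuse cap")
  }
  n_cal <- length(calcium_timestamps)
  assigned <- nearest_index(calcium_timestamps, target_timestamps)
  reuse <- tabulate(assigned + 1L, n_cal)
  err <- abs(target_timestamps - calcium_timestamps[assigned + 1L])
  # Greedy repair: move the worst-error assignment off any over-used frame.
  while (any(reuse > max_reuse)) {
    over <- which(reuse > max_reuse)[1] - 1L
    victims <- which(assigned == over)
    worst <- victims[which.max(err[victims])]
    cand <- which(reuse < max_reuse) - 1L
    cand <- setdiff(cand, over)
    if (length(cand) == 0) stop("cannot satisfy reuse cap")
    d <- abs(target_timestamps[worst] - calcium_timestamps[cand + 1L])
    new <- cand[which.min(d)]
    reuse[over + 1L] <- reuse[over + 1L] - 1L
    reuse[new + 1L] <- reuse[new + 1L] + 1L
    assigned[worst] <- new
    err[worst] <- min(d)
  }
  structure(list(target_index = assigned, reuse = reuse,
                 n_template = length(target_timestamps),
                 max_displacement_frames = NA_real_),
            class = "alignment_map")
}

#' Bundle sessions and match tables into an experiment set
#'
#' @param sessions named list; each element a list with at least `kind` (one
#'   of neutral_encoding, aversive_encoding, offline, recall_aversive,
#'   recall_neutral, recall_novel, chemotag) and `events` (an
#'   `event_matrix`), optionally `locomotion` (list with `trace`,
#'   `timestamps`), `eeg_emg`, `traces` (chemotag continuous traces).
#' @param match_tables list of `match_table`s; both referenced sessions must
#'   be present in `sessions`.
#' @param group_label e.g. "low_shock", "high_shock", "no_shock".
#' @return an object of class `experiment_set`.
#' @export
experiment_set <- function(sessions, match_tables = list(),
                           group_label = NA_character_) {
  kinds <- c("neutral_encoding", "aversive_encoding", "offline",
             "recall_aversive", "recall_neutral", "recall_novel", "chemotag")
  for (nm in names(sessions)) {
    if (!sessions[[nm]]$kind %in% kinds) {
      stop(sprintf("session '%s' has unknown kind '%s'", nm, sessions[[nm]]$kind))
    }
  }
  for (mt in match_tables) {
    ref <- unique(c(mt$session_a, mt$session_b))
    missing <- setdiff(ref, names(sessions))
    if (length(missing) > 0) {
      stop(sprintf("match table references unknown session(s): %s",
                   paste(missing, collapse = ", ")))
    }
  }
  structure(list(sessions = sessions, match_tables = match_tables,
                 group_label = group_label),
            class = "experiment_set")
}

# Retrieve the match table linking two sessions (in either order); NULL when
# absent.
find_match_table <- function(set, sess_x, sess_y) {
  for (mt in set$match_tables) {
    if (nrow(mt) == 0) next
    sa <- mt$session_a[1]; sb <- mt$session_b[1]
    if ((sa == sess_x && sb == sess_y) || (sa == sess_y && sb == sess_x)) {
      return(mt)
    }
  }
  NULL
}
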