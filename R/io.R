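# On-disk formats: long-CSV event matrices with a JSON sidecar, match-table
# CSVs, and the experiment-set manifest.

#' Write an event matrix as long CSV plus JSON sidecar
#'
#' The CSV holds one row per nonzero event (cell_id, frame, value; frames
#' 0-based); the sidecar records frame_rate, timestamps, cell_ids and frame
#' count so silent cells and frames round-trip.
#'
#' @param matrix an `event_matrix`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @export
write_event_matrix <- function(matrix, path) {
  check_event_matrix(matrix)
  nz <- which(matrix$values != 0, arr.ind = TRUE)
  df <- data.frame(cell_id = matrix$cell_ids[nz[, 1]],
                   frame = nz[, 2] - 1L,
                   value = matrix$values[nz])
  df <- df[order(df$cell_id, df$frame), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(frame_rate = matrix$frame_rate,
               n_frames = ncol(matrix$values),
               timestamps = matrix$timestamps,
               cell_ids = matrix$cell_ids)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an event matrix written by [write_event_matrix()]
#'
#' @param path CSV path with its `<path>.json` sidecar.
#' @return an `event_matrix`.
#' @export
read_event_matrix <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  values <- matrix(0, length(side$cell_ids), side$n_frames)
  ri <- match(df$cell_id, side$cell_ids)
  values[cbind(ri, df$frame + 1L)] <- df$value
  event_matrix(values, side$frame_rate, side$timestamps, side$cell_ids)
}

#' Write / read a match table CSV
#'
#' Columns: session_a, session_b, cell_id_a, cell_id_b.
#'
#' @param table a `match_table`.
#' @param path CSV path.
#' @export
write_match_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_match_table
#' @export
read_match_table <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0) {
    return(match_table(character(0), character(0), integer(0), integer(0)))
  }
  match_table(df$session_a[1], df$session_b[1], df$cell_id_a, df$cell_id_b)
}

#' Write an experiment set to a directory with a JSON manifest
#'
#' Each session's event matrix (and chemotag traces / locomotion) is
#' written as CSV; the manifest lists sessions, kinds, file paths, match
#' tables and the group label.
#'
#' @param set an `experiment_set`.
#' @param dir output directory (created if needed).
#' @return the manifest path.
#' @export
write_experiment_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sessions <- list()
  for (nm in names(set$sessions)) {
    s <- set$sessions[[nm]]
    entry <- list(kind = s$kind)
    mat <- if (!is.null(s$events)) s$events else s$traces
    f <- file.path(dir, paste0(nm, "_events.csv"))
    write_event_matrix(mat, f)
    entry$events <- basename(f)
    if (!is.null(s$locomotion)) {
      lf <- file.path(dir, paste0(nm, "_locomotion.csv"))
      utils::write.csv(data.frame(time_ms = s$locomotion$timestamps,
                                  speed = s$locomotion$trace),
                       lf, row.names = FALSE)
      entry$locomotion <- basename(lf)
    }
    sessions[[nm]] <- entry
  }
  tables <- character(0)
  for (i in seq_along(set$match_tables)) {
    tf <- file.path(dir, sprintf("match_%02d.csv", i))
    write_match_table(set$match_tables[[i]], tf)
    tables <- c(tables, basename(tf))
  }
  manifest <- list(group_label = set$group_label, sessions = sessions,
                   match_tables = tables)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  mf
}

#' Read an experiment set from a manifest written by
#' [write_experiment_set()]
#'
#' @param manifest_path path to `manifest.json`.
#' @return an `experiment_set`.
#' @export
read_experiment_set <- function(manifest_path) {
  dir <- dirname(manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  sessions <- list()
  for (nm in names(man$sessions)) {
    e <- man$sessions[[nm]]
    mat <- read_event_matrix(file.path(dir, e$events))
    s <- if (identical(e$kind, "chemotag")) {
      list(kind = e$kind, traces = mat)
    } else {
      list(kind = e$kind, events = mat)
    }
    if (!is.null(e$locomotion)) {
      lf <- utils::read.csv(file.path(dir, e$locomotion))
      s$locomotion <- list(trace = lf$speed, timestamps = lf$time_ms)
    }
    sessions[[nm]] <- s
  }
  tables <- lapply(man$match_tables,
                   function(f) read_match_table(file.path(dir, f)))
  experiment_set(sessions, tables, man$group_label)
}
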