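# Pipeline configuration and the end-to-end driver reproducing the analysis
# flow on one experiment set.

#' Pipeline configuration with the standard analysis parameters
#'
#' Defaults follow the published analysis settings: z = 2 for population
#' bursts and per-cell/per-ensemble participation, 6 s sleep epochs, theta
#' 5-9 Hz and delta 0.5-4 Hz, 120 s cross-correlation bins with a 5-frame
#' maximum lag, 30 s recall bins, 60 s offline-activity bins, 50 SVM repeats
#' at a 50/50 split, chemotag window minutes 10-40 with a top-10% flag.
#'
#' @param burst_z,cell_z,ensemble_z z thresholds.
#' @param epoch_s sleep epoch length (s).
#' @param theta_band,delta_band EEG bands (Hz).
#' @param crosscorr_bin_s,max_lag_frames lagged cross-correlation settings.
#' @param recall_bin_s,offline_bin_s binning for recall PV correlation and
#'   offline ensemble activity (s).
#' @param svm_repeats,train_frac SVM settings.
#' @param chemotag_top_frac,chemotag_window_min chemotag settings.
#' @param peri_burst_window_s peri-burst locomotion half window (s).
#' @param shuffle_n circular-shift surrogates for the burst null.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(burst_z = 2, cell_z = 2, ensemble_z = 2,
                            epoch_s = 6,
                            theta_band = c(5, 9), delta_band = c(0.5, 4),
                            crosscorr_bin_s = 120, max_lag_frames = 5,
                            recall_bin_s = 30, offline_bin_s = 60,
                            svm_repeats = 50, train_frac = 0.5,
                            chemotag_top_frac = 0.10,
                            chemotag_window_min = c(10, 40),
                            peri_burst_window_s = 5,
                            shuffle_n = 500, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(burst_z > 0, cell_z > 0, ensemble_z > 0,
            train_frac > 0, train_frac < 1,
            chemotag_top_frac > 0, chemotag_top_frac <= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full offline co-reactivation analysis on one experiment set
#'
#' Per experiment: ensemble assignment from the match tables, burst
#' detection and participation on offline 2, independent/co-participation
#' during bursts and non-burst periods, time-lagged cross-correlations,
#' offline reactivation time courses, recall reactivation fractions and
#' index, encoding-recall and encoding PV correlations, SVM context
#' decoding with shuffled control, and chemotag ranking/composition when a
#' chemotag session is present. Stages whose required sessions are missing
#' are skipped with a recorded reason.
#'
#' @param set an `experiment_set` (e.g. from [simulate_experiment()] or
#'   [read_experiment_set()]).
#' @param config a `pipeline_config`.
#' @return a `pipeline_result` list of per-stage outputs plus `warnings`
#'   and `skipped` records and the verbatim `config`.
#' @export
run_pipeline <- function(set, config = pipeline_config()) {
  stopifnot(inherits(set, "experiment_set"))
  res <- list(config = config, skipped = character(0),
              warnings = character(0))
  note <- function(msg) res$warnings <<- c(res$warnings, msg)
  sess <- set$sessions
  kinds <- vapply(sess, function(s) s$kind, character(1))
  off_names <- names(sess)[kinds == "offline"]
  offline2 <- if (length(off_names) > 0) off_names[length(off_names)] else NULL
  nm_neutral <- names(sess)[kinds == "neutral_encoding"][1]
  nm_aversive <- names(sess)[kinds == "aversive_encoding"][1]

  if (is.null(offline2) || is.na(nm_neutral) || is.na(nm_aversive)) {
    res$skipped <- c(res$skipped, "offline/encoding sessions missing")
    class(res) <- "pipeline_result"
    return(res)
  }
  off_mat <- sess[[offline2]]$events
  mt_n <- find_match_table(set, offline2, nm_neutral)
  mt_a <- find_match_table(set, offline2, nm_aversive)
  assignment <- assign_ensembles(
    off_mat$cell_ids, offline2,
    if (is.null(mt_n)) match_table(offline2, nm_neutral, integer(0), integer(0)) else mt_n,
    if (is.null(mt_a)) match_table(offline2, nm_aversive, integer(0), integer(0)) else mt_a)
  res$assignment <- assignment

  # bursts + participation
  trace <- population_trace(off_mat)
  catalog <- detect_bursts(trace, config$burst_z)
  res$bursts <- catalog
  part <- cell_participation(off_mat, catalog, config$cell_z)
  res$participation <- ensemble_participation(part, assignment)
  res$shuffle <- shuffle_null(off_mat, config$shuffle_n,
                              seed = derive_seed(config$seed, "shuffle"),
                              threshold_z = config$burst_z)
  loco <- sess[[offline2]]$locomotion
  if (!is.null(loco)) {
    res$peri_burst <- peri_burst_locomotion(
      loco$trace, loco$timestamps, catalog, off_mat$timestamps,
      window_s = config$peri_burst_window_s)
  }

  # co-participation and cross-correlations
  tr <- withCallingHandlers(
    ensemble_mean_traces(off_mat, assignment),
    warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    })
  if (!is.null(tr) && nrow(tr) >= 2) {
    ep <- ensemble_event_participation(tr, catalog, config$ensemble_z)
    res$coparticipation_burst <- coparticipation_fractions(ep)
    res$coparticipation_nonburst <-
      nonburst_coparticipation(tr, catalog, config$ensemble_z)
    if (all(c("overlap", "neutral", "aversive") %in% rownames(tr))) {
      res$crosscorr <- tryCatch(
        list(
          overlap_neutral = lagged_crosscorr(
            tr["overlap", ], tr["neutral", ], off_mat$frame_rate,
            config$crosscorr_bin_s, config$max_lag_frames),
          overlap_aversive = lagged_crosscorr(
            tr["overlap", ], tr["aversive", ], off_mat$frame_rate,
            config$crosscorr_bin_s, config$max_lag_frames)),
        error = function(e) {
          res$skipped <<- c(res$skipped,
                            paste("cross-correlation:", conditionMessage(e)))
          NULL
        })
    }
  } else {
    res$skipped <- c(res$skipped, "co-participation: < 2 nonempty ensembles")
  }

  # sleep-state-resolved co-bursting, when telemetry is present
  eeg <- sess[[offline2]]$eeg_emg
  if (!is.null(eeg) && !is.null(tr) && nrow(tr) >= 2) {
    hyp <- withCallingHandlers(
      score_sleep(eeg, config$epoch_s, config$theta_band, config$delta_band),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      })
    res$hypnogram <- hyp
    res$sleep_features <- sleep_features(hyp)
    frame_states <- assign_states_to_frames(hyp, off_mat$timestamps)
    res$coparticipation_by_state <-
      coparticipation_by_state(tr, catalog, frame_states, config$ensemble_z)
  }

  # offline reactivation time course
  res$offline_activity <- tryCatch(
    offline_ensemble_activity(off_mat, assignment, config$offline_bin_s),
    error = function(e) {
      res$skipped <<- c(res$skipped,
                        paste("offline activity:", conditionMessage(e)))
      NULL
    })

  # recall reactivation fractions + index
  nm_rn <- names(sess)[kinds == "recall_neutral"][1]
  nm_rv <- names(sess)[kinds == "recall_novel"][1]
  react <- function(nm_recall) {
    mtn <- find_match_table(set, nm_recall, nm_neutral)
    mta <- find_match_table(set, nm_recall, nm_aversive)
    recall_reactivation_fractions(
      sess[[nm_recall]]$events, nm_recall,
      if (is.null(mtn)) match_table(nm_recall, nm_neutral, integer(0), integer(0)) else mtn,
      if (is.null(mta)) match_table(nm_recall, nm_aversive, integer(0), integer(0)) else mta)
  }
  if (!is.na(nm_rn) && !is.na(nm_rv)) {
    fr_n <- react(nm_rn)
    fr_v <- react(nm_rv)
    res$reactivation <- reactivation_index(fr_n, fr_v)
    mt_enc <- find_match_table(set, nm_rn, nm_neutral)
    if (!is.null(mt_enc)) {
      res$encoding_recall_pv <- tryCatch(
        encoding_recall_pv_corr(sess[[nm_neutral]]$events, nm_neutral,
                                sess[[nm_rn]]$events, nm_rn,
                                mt_enc, config$recall_bin_s),
        error = function(e) {
          res$skipped <<- c(res$skipped,
                            paste("encoding-recall PV:", conditionMessage(e)))
          NULL
        })
    }
  } else {
    res$skipped <- c(res$skipped, "recall sessions missing")
  }

  # encoding discriminability + decoding
  mt_na <- find_match_table(set, nm_neutral, nm_aversive)
  if (!is.null(mt_na)) {
    res$encoding_pv <- tryCatch(
      encoding_pv_matrix(sess[[nm_neutral]]$events, nm_neutral,
                         sess[[nm_aversive]]$events, nm_aversive,
                         mt_na, config$recall_bin_s),
      error = function(e) NULL)
    ds <- tryCatch(
      build_context_dataset(sess[[nm_neutral]]$events, nm_neutral,
                            sess[[nm_aversive]]$events, nm_aversive, mt_na),
      error = function(e) NULL)
    if (!is.null(ds)) {
      res$decoding <- svm_decode(ds, config$train_frac, config$svm_repeats,
                                 seed = derive_seed(config$seed, "svm"))
      res$decoding_shuffled <- shuffled_control(
        ds, config$train_frac, config$svm_repeats,
        seed = derive_seed(config$seed, "svm_shuffle"))
    }
  } else {
    res$skipped <- c(res$skipped, "encoding match table missing")
  }

  # chemotag
  nm_ct <- names(sess)[kinds == "chemotag"][1]
  if (!is.na(nm_ct)) {
    ranking <- rank_chemotag(sess[[nm_ct]]$traces,
                             window_min = config$chemotag_window_min,
                             top_frac = config$chemotag_top_frac)
    res$chemotag <- ranking
    mt_ct <- find_match_table(set, nm_ct, offline2)
    if (!is.null(mt_ct)) {
      prop <- propagate_labels(ranking, mt_ct, nm_ct, offline2,
                               off_mat$cell_ids)
      res$chemotag_offline <- prop
      res$ensemble_composition <- ensemble_composition(assignment, prop)
    }
  }
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> stages:",
      paste(setdiff(names(x), c("config", "skipped", "warnings")),
            collapse = ", "), "\n")
  if (length(x$skipped)) cat("skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}
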