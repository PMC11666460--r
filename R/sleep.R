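# EEG/EMG sleep scoring, frame-to-state assignment, sleep features, and
# sleep-state-resolved ensemble co-participation.

SLEEP_STATES <- c("wake", "nrem", "rem", "unknown")

#' Construct an EEG/EMG telemetry record
#'
#' @param eeg,emg equal-length numeric traces sampled at `rate_hz`.
#' @param rate_hz sampling rate (fixed at 100 Hz for the telemetry system).
#' @param start_ms wall-clock time of the first sample.
#' @return an `eeg_emg_record`.
#' @export
eeg_emg_record <- function(eeg, emg, rate_hz = 100, start_ms = 0) {
  if (length(eeg) != length(emg)) stop("eeg and emg must have equal length")
  structure(list(eeg = as.numeric(eeg), emg = as.numeric(emg),
                 rate_hz = rate_hz, start_ms = start_ms),
            class = "eeg_emg_record")
}

# Band power per epoch: band-pass filter (4th-order Butterworth, zero-phase)
# then mean squared amplitude within each epoch.
epoch_band_power <- function(x, rate_hz, band, samples_per_epoch) {
  bf <- signal::butter(4, band / (rate_hz / 2), type = "pass")
  filtered <- signal::filtfilt(bf, x)
  n_epochs <- length(x) %/% samples_per_epoch
  vapply(seq_len(n_epochs), function(i) {
    idx <- ((i - 1L) * samples_per_epoch + 1L):(i * samples_per_epoch)
    mean(filtered[idx]^2)
  }, numeric(1))
}

# Two-component 1-D Gaussian mixture classification. Returns a logical
# vector: TRUE where the sample belongs to the higher-mean component, or
# NULL when the fit fails or the components are inseparable.
# (mclustBIC must be imported: Mclust resolves it in the caller's scope.)
#' @importFrom mclust Mclust mclustBIC
gmm2_high <- function(x, min_separation = 0.5) {
  if (length(unique(x)) < 3) return(NULL)
  fit2 <- tryCatch(
    suppressWarnings(Mclust(x, G = 2, modelNames = "V", verbose = FALSE)),
    error = function(e) NULL)
  if (is.null(fit2)) return(NULL)
  # degenerate (unimodal) data: a single Gaussian must not explain the data
  # as well as the two-state model, else the split is arbitrary
  fit1 <- tryCatch(
    suppressWarnings(Mclust(x, G = 1, modelNames = "V", verbose = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit1) && fit2$bic <= fit1$bic) return(NULL)
  mu <- fit2$parameters$mean
  sdv <- sqrt(fit2$parameters$variance$sigmasq)
  sep <- abs(diff(mu)) / max(sdv)
  if (!is.finite(sep) || sep < min_separation) return(NULL)
  high <- which.max(mu)
  fit2$classification == high
}

#' Score sleep states from an EEG/EMG record
#'
#' The record is binned into `epoch_s` epochs (long enough to hold several
#' slow-wave cycles). Per-epoch EMG power is fit with a two-state Gaussian
#' mixture; the lower state is sleep. Within sleep epochs, the EEG
#' theta (5-9 Hz) / delta (0.5-4 Hz) band-power ratio is fit with a second
#' two-state mixture; the higher state is REM, the lower NREM. Mixtures are
#' fit on log power so that a global gain applied jointly to both channels
#' cannot change the scoring. Epochs with missing data become `unknown`.
#'
#' @param record an `eeg_emg_record`.
#' @param epoch_s epoch length in seconds (default 6).
#' @param theta_band,delta_band frequency bands in Hz.
#' @param min_separation minimum mixture-component separation (in pooled SD
#'   units) below which the fit is treated as degenerate.
#' @return a `hypnogram`: list with `states` (per-epoch factor), `epoch_s`,
#'   `epoch_start_ms`.
#' @export
score_sleep <- function(record, epoch_s = 6,
                        theta_band = c(5, 9), delta_band = c(0.5, 4),
                        min_separation = 0.5) {
  stopifnot(inherits(record, "eeg_emg_record"))
  spe <- as.integer(epoch_s * record$rate_hz)
  n_epochs <- length(record$emg) %/% spe
  if (n_epochs < 10) stop("record shorter than 10 epochs")
  emg_pow <- vapply(seq_len(n_epochs), function(i) {
    idx <- ((i - 1L) * spe + 1L):(i * spe)
    mean(record$emg[idx]^2)
  }, numeric(1))
  bad <- vapply(seq_len(n_epochs), function(i) {
    idx <- ((i - 1L) * spe + 1L):(i * spe)
    mean(!is.finite(record$emg[idx]) | !is.finite(record$eeg[idx])) > 0.5
  }, logical(1))
  eeg_clean <- record$eeg
  eeg_clean[!is.finite(eeg_clean)] <- 0
  theta <- epoch_band_power(eeg_clean, record$rate_hz, theta_band, spe)
  delta <- epoch_band_power(eeg_clean, record$rate_hz, delta_band, spe)
  states <- rep("wake", n_epochs)
  ok <- !bad & is.finite(emg_pow) & emg_pow > 0
  wake_high <- gmm2_high(log(emg_pow[ok]), min_separation)
  if (is.null(wake_high)) {
    warning("EMG mixture fit degenerate: scoring all epochs as wake")
    is_sleep <- rep(FALSE, sum(ok))
  } else {
    is_sleep <- !wake_high
  }
  sleep_idx <- which(ok)[is_sleep]
  if (length(sleep_idx) > 0) {
    ratio <- log(theta[sleep_idx] / delta[sleep_idx])
    rem_high <- gmm2_high(ratio, min_separation)
    if (is.null(rem_high)) {
      warning("theta/delta mixture fit degenerate: scoring all sleep as NREM")
      states[sleep_idx] <- "nrem"
    } else {
      states[sleep_idx] <- ifelse(rem_high, "rem", "nrem")
    }
  }
  states[bad] <- "unknown"
  structure(
    list(states = factor(states, levels = SLEEP_STATES),
         epoch_s = epoch_s,
         epoch_start_ms = record$start_ms +
           (seq_len(n_epochs) - 1) * epoch_s * 1000),
    class = "hypnogram"
  )
}

#' Construct a hypnogram directly from per-epoch states
#'
#' @param states character or factor over wake/nrem/rem/unknown.
#' @param epoch_s epoch length in seconds.
#' @param start_ms wall-clock time of the first epoch.
#' @return a `hypnogram`.
#' @export
hypnogram <- function(states, epoch_s = 6, start_ms = 0) {
  structure(
    list(states = factor(as.character(states), levels = SLEEP_STATES),
         epoch_s = epoch_s,
         epoch_start_ms = start_ms + (seq_along(states) - 1) * epoch_s * 1000),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d x %gs epochs: ", length(x$states), x$epoch_s))
  print(table(x$states))
  invisible(x)
}

#' Assign a sleep state to each calcium frame
#'
#' A frame falling inside a scored epoch (half-open `[start, start+epoch)`)
#' takes that epoch's state; frames outside all epochs (dropped or
#' low-quality telemetry) become `unknown` and are excluded from
#' state-specific statistics downstream.
#'
#' @param hyp a `hypnogram`.
#' @param frame_timestamps calcium frame times in ms on the same clock.
#' @return factor of per-frame states.
#' @export
assign_states_to_frames <- function(hyp, frame_timestamps) {
  starts <- hyp$epoch_start_ms
  epoch_ms <- hyp$epoch_s * 1000
  idx <- findInterval(frame_timestamps, starts)
  state <- rep("unknown", length(frame_timestamps))
  inside <- idx >= 1 &
    frame_timestamps < starts[pmax(idx, 1)] + epoch_ms
  state[inside] <- as.character(hyp$states[idx[inside]])
  factor(state, levels = SLEEP_STATES)
}

#' Sleep architecture summary
#'
#' Total sleep time (NREM + REM), time per state, bout lengths (maximal
#' runs of one state) and the transition-count matrix over consecutive
#' epochs. Unknown epochs break bouts and contribute no transitions.
#'
#' @param hyp a `hypnogram`.
#' @return list with `time_s` (named per-state seconds),
#'   `total_sleep_s`, `bouts` (data.frame state, length_epochs),
#'   `transitions` (state x state count matrix).
#' @export
sleep_features <- function(hyp) {
  st <- as.character(hyp$states)
  time_s <- vapply(SLEEP_STATES, function(s) sum(st == s) * hyp$epoch_s,
                   numeric(1))
  r <- rle(st)
  bouts <- data.frame(state = r$values, length_epochs = r$lengths,
                      stringsAsFactors = FALSE)
  bouts <- bouts[bouts$state != "unknown", , drop = FALSE]
  known <- c("wake", "nrem", "rem")
  trans <- matrix(0L, 3, 3, dimnames = list(known, known))
  if (length(st) > 1) {
    from <- st[-length(st)]
    to <- st[-1]
    keep <- from != "unknown" & to != "unknown"
    tt <- table(factor(from[keep], levels = known),
                factor(to[keep], levels = known))
    trans <- trans + unclass(tt)
  }
  list(time_s = time_s,
       total_sleep_s = time_s[["nrem"]] + time_s[["rem"]],
       bouts = bouts, transitions = trans)
}

#' Ensemble co-participation split by sleep state
#'
#' Each burst event is assigned the sleep state of its peak frame and
#' co-participation fractions are computed within each state's events.
#' Events in unknown-state frames are tracked separately so per-state event
#' counts are conserved.
#'
#' @param ensemble_traces ensembles x frames matrix (typically the z-scored
#'   concatenated traces from [concatenate_offline()]).
#' @param catalog a `burst_catalog` on the same frame axis.
#' @param frame_states per-frame factor from [assign_states_to_frames()].
#' @param threshold_z participation threshold (default 2).
#' @return named list (wake, nrem, rem, unknown) of
#'   `coparticipation_summary` objects.
#' @export
coparticipation_by_state <- function(ensemble_traces, catalog, frame_states,
                                     threshold_z = 2) {
  if (length(frame_states) != length(catalog$trace)) {
    stop("frame states and catalog disagree on frame count")
  }
  part <- ensemble_event_participation(ensemble_traces, catalog, threshold_z)
  ev_state <- as.character(frame_states[catalog$events$peak + 1L])
  out <- list()
  for (s in SLEEP_STATES) {
    out[[s]] <- coparticipation_fractions(
      part[, ev_state == s, drop = FALSE])
  }
  out
}
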