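# Synthetic-experiment generator: complete multi-session experiments
# (deconvolved event matrices, match tables, locomotion, EEG/EMG, chemotag
# traces) with planted ensembles, bursts, coincidence structure, hypnograms
# and full ground truth, so every analysis stage is testable without any
# real recording.

#' Simulation configuration
#'
#' All knobs of the synthetic experiment, with defaults emulating a
#' multi-session memory-linking design: neutral and aversive encoding, two
#' offline home-cage periods, neutral/novel recall, and a CNO chemotag
#' session.
#'
#' @param n_cells cells recorded in the offline sessions.
#' @param ensemble_sizes named integer vector (neutral, aversive, overlap,
#'   remaining) for offline 2; must sum to `n_cells`.
#' @param offline_duration_s,encoding_duration_s,recall_duration_s session
#'   durations in seconds.
#' @param frame_rate imaging rate in Hz (30; use 15 for telemetry-paired
#'   designs).
#' @param background_rate_hz per-cell background event rate (events/s).
#' @param burst_rate_per_min population burst rate during offline periods.
#' @param burst_duration_s burst length in seconds (boxcar of elevated event
#'   probability).
#' @param participation named per-ensemble probability that the ensemble
#'   participates in a burst.
#' @param coincidence named list with `overlap_neutral` and
#'   `overlap_aversive`: joint probabilities that overlap co-participates
#'   with that ensemble in the same burst. Must not exceed
#'   `participation["overlap"]`.
#' @param cell_participation_prob probability that a cell of a
#'   participating ensemble fires within a given burst; a scalar, or a named
#'   per-ensemble vector (neutral, aversive, overlap, remaining).
#' @param burst_event_prob per-frame probability that a firing cell emits an
#'   additional event on each frame of the burst (on top of one guaranteed
#'   event), making planted bursts dominate the population trace.
#' @param burst_population_frac baseline fraction of the whole population
#'   recruited into every burst regardless of ensemble flags: a population
#'   burst is a population-level event, with ensemble participation
#'   modulated on top of this floor.
#' @param locomotion_dip_depth,locomotion_dip_pre_s,locomotion_dip_post_s
#'   peri-burst locomotion dip: depth (speed units), onset before the burst
#'   peak and recovery after it, in seconds.
#' @param recall_reactivation named list with per-ensemble probabilities
#'   that an encoding/offline cell is active during neutral recall
#'   (`neutral_recall`) and novel exposure (`novel_recall`).
#' @param encoding_pattern_sd SD of per-cell context-specific rate offsets
#'   (controls SVM separability).
#' @param state_probs,state_dwell_epochs hypnogram Markov model: stationary
#'   entry probabilities and mean dwell (epochs) per state.
#' @param emg_power,eeg_delta_power,eeg_theta_power named per-state signal
#'   powers for the telemetry generator.
#' @param eeg_noise_sd additive Gaussian noise SD on both channels.
#' @param inhibitory_frac fraction of cells that are (ground-truth)
#'   inhibitory.
#' @param cno_peak_rate_per_min prominent-peak rate of responding inhibitory
#'   cells during the CNO window; non-responders emit
#'   `cno_baseline_peak_rate_per_min`.
#' @param chemotag_frame_rate frame rate of the chemotag trace session.
#' @param chemotag_duration_min chemotag session length (>= 45 min design).
#' @param inhibitory_overlap_enrichment odds multiplier concentrating
#'   inhibitory flags in the overlap ensemble.
#' @param seed master RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_cells = 100,
                       ensemble_sizes = c(neutral = 15, aversive = 15,
                                          overlap = 10, remaining = 60),
                       offline_duration_s = 600,
                       encoding_duration_s = 300,
                       recall_duration_s = 120,
                       frame_rate = 30,
                       background_rate_hz = 0.05,
                       burst_rate_per_min = 4,
                       burst_duration_s = 0.5,
                       participation = c(neutral = 0.5, aversive = 0.5,
                                         overlap = 0.9, remaining = 0.1),
                       coincidence = list(overlap_neutral = 0.4,
                                          overlap_aversive = 0.4),
                       cell_participation_prob = 0.8,
                       burst_event_prob = 0.3,
                       burst_population_frac = 0.15,
                       locomotion_dip_depth = 2,
                       locomotion_dip_pre_s = 1,
                       locomotion_dip_post_s = 2,
                       recall_reactivation = list(
                         neutral_recall = c(neutral = 0.5, aversive = 0.2,
                                            overlap = 0.5, remaining = 0.2),
                         novel_recall = c(neutral = 0.2, aversive = 0.2,
                                          overlap = 0.2, remaining = 0.2)),
                       encoding_pattern_sd = 0.03,
                       state_probs = c(wake = 0.4, nrem = 0.45, rem = 0.15),
                       state_dwell_epochs = c(wake = 20, nrem = 15, rem = 5),
                       emg_power = c(wake = 9, nrem = 1, rem = 1),
                       eeg_delta_power = c(wake = 1, nrem = 6, rem = 1),
                       eeg_theta_power = c(wake = 2, nrem = 1, rem = 6),
                       eeg_noise_sd = 0.3,
                       inhibitory_frac = 0.10,
                       cno_peak_rate_per_min = 3,
                       cno_baseline_peak_rate_per_min = 0.2,
                       chemotag_frame_rate = 2,
                       chemotag_duration_min = 45,
                       inhibitory_overlap_enrichment = 1,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(sum(ensemble_sizes) <= n_cells)
  if (sum(ensemble_sizes) != n_cells) {
    cfg$ensemble_sizes["remaining"] <-
      ensemble_sizes["remaining"] + (n_cells - sum(ensemble_sizes))
  }
  probs <- c(participation, cell_participation_prob,
             unlist(coincidence), inhibitory_frac,
             unlist(recall_reactivation))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (coincidence$overlap_neutral > participation[["overlap"]] ||
      coincidence$overlap_aversive > participation[["overlap"]]) {
    stop("coincidence cannot exceed overlap participation probability")
  }
  # note: the joint P(pair & overlap) is honoured exactly; the pair's
  # marginal participation is achieved when the joint law allows it
  # (P(E) must lie in [c, c + 1 - P(O)]) and is clamped to the nearest
  # feasible value otherwise
  class(cfg) <- "sim_config"
  cfg
}

# Draw per-burst ensemble participation flags such that
# P(overlap & neutral) and P(overlap & aversive) equal the configured
# coincidences exactly. Returns an n_bursts x 4 logical matrix.
draw_burst_participation <- function(n_bursts, cfg, use_coincidence = TRUE) {
  p <- cfg$participation
  po <- p[["overlap"]]
  draw_once <- function(k) {
    flags <- matrix(FALSE, k, 4,
                    dimnames = list(NULL, c("neutral", "aversive", "overlap",
                                            "remaining")))
    if (k == 0) return(flags)
    flags[, "overlap"] <- stats::runif(k) < po
    for (pair in c("neutral", "aversive")) {
      if (use_coincidence) {
        c_pair <- cfg$coincidence[[paste0("overlap_", pair)]]
        # conditional probability given overlap so the joint is exactly
        # c_pair; marginal participation kept when feasible
        p_given_o <- if (po > 0) c_pair / po else 0
        p_given_not_o <- if (po < 1) {
          max(0, min(1, (p[[pair]] - c_pair) / (1 - po)))
        } else 0
        u <- stats::runif(k)
        flags[, pair] <- ifelse(flags[, "overlap"],
                                u < p_given_o, u < p_given_not_o)
      } else {
        flags[, pair] <- stats::runif(k) < p[[pair]]
      }
    }
    flags[, "remaining"] <- stats::runif(k) < p[["remaining"]]
    flags
  }
  flags <- draw_once(n_bursts)
  # a population burst with no participating ensemble is not a burst:
  # redraw empty rows so each planted burst is detectable in principle
  # (joint probabilities become conditional on the burst being nonempty)
  if (sum(unlist(p)) > 0) {
    for (iter in 1:100) {
      empty <- !apply(flags, 1, any)
      if (!any(empty)) break
      flags[empty, ] <- draw_once(sum(empty))
    }
  }
  if (n_bursts > 0 && any(!apply(flags, 1, any))) {
    flags[!apply(flags, 1, any), "remaining"] <- TRUE
  }
  flags
}

# Non-overlapping burst start frames for a session.
draw_burst_starts <- function(n_frames, n_bursts, burst_len, margin) {
  if (n_bursts == 0) return(integer(0))
  slots <- seq(margin, n_frames - burst_len - margin, by = burst_len * 4)
  if (length(slots) < n_bursts) {
    stop("session too short for the requested burst count")
  }
  sort(sample(slots, n_bursts)) +
    sample(0:(burst_len * 2), n_bursts, replace = TRUE)
}

# Log-normal event amplitudes.
draw_amplitudes <- function(n) stats::rlnorm(n, meanlog = 0, sdlog = 0.5)

#' Simulate one offline session
#'
#' Background activity is homogeneous per-cell Bernoulli events per frame
#' with log-normal amplitudes. Population bursts are boxcars of elevated
#' event probability in which each participating ensemble's cells emit
#' events with `cell_participation_prob`. The locomotion trace dips starting
#' about a second before each burst peak and recovers a couple of seconds
#' after.
#'
#' @param cfg a `sim_config`.
#' @param labels named per-cell ensemble labels (as in an
#'   `ensemble_assignment`).
#' @param hypnogram optional `hypnogram` covering the session; when given,
#'   together with `wake_only_coincidence = TRUE`, the pairwise coincidence
#'   structure is planted only in bursts whose peak falls in wake.
#' @param wake_only_coincidence plant coincidence only during wake.
#' @param duration_s,frame_rate session geometry (defaults from `cfg`).
#' @return list with `events` (an `event_matrix`), `locomotion` (list
#'   `trace`, `timestamps`), and `truth` (burst starts/peaks/ends, per-burst
#'   participation flags).
#' @export
simulate_offline_session <- function(cfg, labels, hypnogram = NULL,
                                     wake_only_coincidence = FALSE,
                                     duration_s = cfg$offline_duration_s,
                                     frame_rate = cfg$frame_rate) {
  n_cells <- length(labels)
  n_frames <- as.integer(duration_s * frame_rate)
  burst_len <- max(1L, as.integer(round(cfg$burst_duration_s * frame_rate)))
  p_bg <- cfg$background_rate_hz / frame_rate
  values <- matrix(0, n_cells, n_frames)
  bg <- matrix(stats::runif(n_cells * n_frames) < p_bg, n_cells, n_frames)
  values[bg] <- draw_amplitudes(sum(bg))
  n_bursts <- stats::rpois(1, cfg$burst_rate_per_min * duration_s / 60)
  margin <- as.integer(6 * frame_rate)  # keep peri-burst windows in-session
  starts <- draw_burst_starts(n_frames, n_bursts, burst_len, margin)
  timestamps <- (seq_len(n_frames) - 1) * 1000 / frame_rate
  peaks <- starts + burst_len %/% 2L
  if (!is.null(hypnogram)) {
    frame_states <- assign_states_to_frames(hypnogram, timestamps)
    burst_states <- as.character(frame_states[peaks + 1L])
  } else {
    burst_states <- rep("wake", length(starts))
  }
  if (wake_only_coincidence) {
    in_wake <- burst_states == "wake"
    flags <- matrix(FALSE, length(starts), 4,
                    dimnames = list(NULL, c("neutral", "aversive", "overlap",
                                            "remaining")))
    flags[in_wake, ] <- draw_burst_participation(sum(in_wake), cfg,
                                                 use_coincidence = TRUE)
    flags[!in_wake, ] <- draw_burst_participation(sum(!in_wake), cfg,
                                                  use_coincidence = FALSE)
  } else {
    flags <- draw_burst_participation(length(starts), cfg,
                                      use_coincidence = TRUE)
  }
  cpp <- cfg$cell_participation_prob
  for (b in seq_along(starts)) {
    span <- (starts[b] + 1L):(starts[b] + burst_len)
    # baseline population recruitment: the burst is a population-level event
    recruited <- which(stats::runif(n_cells) < cfg$burst_population_frac)
    fire_sets <- list(recruited)
    for (e in colnames(flags)) {
      if (!flags[b, e]) next
      members <- which(labels == e)
      p_cell <- if (length(cpp) > 1) cpp[[e]] else cpp
      fire_sets[[length(fire_sets) + 1]] <-
        members[stats::runif(length(members)) < p_cell]
    }
    for (firing in fire_sets) {
      if (length(firing) == 0) next
      # one guaranteed event per firing cell, plus per-frame extras so the
      # burst stands out of the sparse background
      at <- sample(span, length(firing), replace = TRUE)
      values[cbind(firing, at)] <- values[cbind(firing, at)] +
        draw_amplitudes(length(firing))
      extra <- matrix(stats::runif(length(firing) * burst_len) <
                        cfg$burst_event_prob, length(firing), burst_len)
      idx <- which(extra, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        coords <- cbind(firing[idx[, 1]], span[idx[, 2]])
        values[coords] <- values[coords] + draw_amplitudes(nrow(idx))
      }
    }
  }
  # locomotion: smooth baseline + planted dips around burst peaks
  loco <- 5 + as.numeric(stats::filter(stats::rnorm(n_frames, 0, 0.5),
                                       rep(1 / 15, 15), sides = 2))
  loco[is.na(loco)] <- 5
  t_s <- (seq_len(n_frames) - 1) / frame_rate
  for (b in seq_along(starts)) {
    peak_t <- peaks[b] / frame_rate
    rel <- t_s - peak_t
    dip <- dip_template(rel, cfg$locomotion_dip_pre_s,
                        cfg$locomotion_dip_post_s)
    loco <- loco - cfg$locomotion_dip_depth * dip
  }
  loco <- pmax(loco, 0)
  em <- event_matrix(values, frame_rate, timestamps,
                     cell_ids = seq_len(n_cells))
  list(events = em,
       locomotion = list(trace = loco, timestamps = timestamps),
       truth = list(starts = starts, peaks = peaks,
                    ends = starts + burst_len, flags = flags,
                    burst_states = burst_states))
}

# Raised-cosine slowdown: starts `pre_s` before the burst peak, recovers
# `post_s` after; value in [0, 1].
dip_template <- function(rel_t, pre_s, post_s) {
  out <- numeric(length(rel_t))
  inside <- rel_t >= -pre_s & rel_t <= post_s
  phase <- (rel_t[inside] + pre_s) / (pre_s + post_s)
  out[inside] <- sin(pi * phase)^2
  out
}

# Per-epoch Markov hypnogram with configured dwell times.
simulate_hypnogram <- function(n_epochs, cfg, epoch_s = 6, start_ms = 0) {
  states <- c("wake", "nrem", "rem")
  stay <- 1 - 1 / cfg$state_dwell_epochs[states]
  out <- character(n_epochs)
  out[1] <- sample(states, 1, prob = cfg$state_probs[states])
  for (i in seq_len(n_epochs - 1L)) {
    cur <- out[i]
    if (stats::runif(1) < stay[[cur]]) {
      out[i + 1L] <- cur
    } else {
      others <- setdiff(states, cur)
      # REM is entered from NREM only, as in real sleep architecture
      if (cur == "wake") others <- "nrem"
      pr <- cfg$state_probs[others]
      out[i + 1L] <- sample(others, 1, prob = pr)
    }
  }
  hypnogram(out, epoch_s, start_ms)
}

#' Simulate a 100 Hz EEG/EMG record matching a hypnogram
#'
#' Wake epochs carry high EMG power; NREM low EMG and high delta (0.5-4 Hz)
#' EEG power; REM low EMG and a high theta (5-9 Hz) to delta ratio.
#' Band-limited components are synthesized as frequency-wandering sinusoids
#' plus additive Gaussian noise at the configured SD.
#'
#' @param hyp a `hypnogram`.
#' @param cfg a `sim_config`.
#' @param rate_hz sampling rate (default 100).
#' @param noise_sd overrides `cfg$eeg_noise_sd` when given.
#' @return an `eeg_emg_record`.
#' @export
simulate_eeg_emg <- function(hyp, cfg, rate_hz = 100, noise_sd = NULL) {
  if (is.null(noise_sd)) noise_sd <- cfg$eeg_noise_sd
  spe <- as.integer(hyp$epoch_s * rate_hz)
  n <- length(hyp$states) * spe
  t <- (seq_len(n) - 1) / rate_hz
  delta_osc <- sin(2 * pi * 2 * t + cumsum(stats::rnorm(n, 0, 0.02)))
  theta_osc <- sin(2 * pi * 7 * t + cumsum(stats::rnorm(n, 0, 0.02)))
  st <- as.character(hyp$states)
  st[st == "unknown"] <- "wake"
  amp_d <- rep(sqrt(cfg$eeg_delta_power[st]), each = spe)
  amp_t <- rep(sqrt(cfg$eeg_theta_power[st]), each = spe)
  amp_e <- rep(sqrt(cfg$emg_power[st]), each = spe)
  eeg <- amp_d * delta_osc + amp_t * theta_osc + stats::rnorm(n, 0, noise_sd)
  emg <- amp_e * stats::rnorm(n) + stats::rnorm(n, 0, noise_sd)
  eeg_emg_record(eeg, emg, rate_hz, start_ms = hyp$epoch_start_ms[1])
}

#' Simulate the CNO chemotag session as continuous traces
#'
#' Planted inhibitory cells respond to CNO with frequent high-prominence
#' calcium transients concentrated in minutes 10-40; other cells emit rare
#' baseline transients. Transients are exponential-decay kernels on a slow
#' baseline.
#'
#' @param cfg a `sim_config`.
#' @param inhibitory logical per-cell ground-truth flags.
#' @return an `event_matrix` of continuous traces at
#'   `cfg$chemotag_frame_rate`.
#' @export
simulate_chemotag_session <- function(cfg, inhibitory) {
  fr <- cfg$chemotag_frame_rate
  n_frames <- as.integer(cfg$chemotag_duration_min * 60 * fr)
  n_cells <- length(inhibitory)
  decay <- exp(-(0:as.integer(4 * fr)) / (1.5 * fr))
  window <- c(10, 40) * 60 * fr
  values <- matrix(0, n_cells, n_frames)
  for (i in seq_len(n_cells)) {
    rate <- if (inhibitory[i]) cfg$cno_peak_rate_per_min else
      cfg$cno_baseline_peak_rate_per_min
    n_peaks <- stats::rpois(1, rate * 30)  # within the 30-min window
    trace <- stats::rnorm(n_frames, 0, 0.02)
    # every cell emits at least one spontaneous transient somewhere in the
    # session, so the [0,1] normalization is anchored by a real transient
    # rather than amplifying recorder noise on a silent cell
    p0 <- sample(n_frames - length(decay), 1)
    trace[p0:(p0 + length(decay) - 1L)] <-
      trace[p0:(p0 + length(decay) - 1L)] + stats::runif(1, 0.7, 1.3) * decay
    if (n_peaks > 0) {
      # peaks on a coarse grid so neighbouring transients stay resolvable
      slots <- seq(window[1] + 1, window[2] - length(decay),
                   by = as.integer(8 * fr))
      at <- sort(sample(slots, min(n_peaks, length(slots))))
      for (p in at) {
        amp <- stats::runif(1, 0.7, 1.3)
        span <- p:(p + length(decay) - 1L)
        trace[span] <- trace[span] + amp * decay
      }
    }
    values[i, ] <- trace - min(trace)  # traces are nonnegative fluorescence
  }
  event_matrix(values, fr, cell_ids = seq_len(n_cells))
}

#' Simulate a complete multi-session experiment with ground truth
#'
#' Builds the full multi-session design: neutral and aversive encoding with
#' context-specific activity patterns, offline 1 and offline 2 with planted
#' ensembles/bursts/coincidence, neutral and novel recall with configurable
#' ensemble reactivation, a chemotag CNO session, and all cross-session
#' match tables derived from a global cell registry. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a `sim_config`.
#' @param with_sleep also simulate a hypnogram + EEG/EMG for offline 2 and
#'   plant coincidence only in wake bursts.
#' @return list `set` (an `experiment_set`) and `truth` (planted labels,
#'   burst ground truth per offline session, hypnogram, inhibitory flags,
#'   global id maps).
#' @export
simulate_experiment <- function(cfg, with_sleep = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sizes <- cfg$ensemble_sizes
  n <- cfg$n_cells
  # global registry: offline-2 cells are the reference population
  labels <- rep(names(sizes), sizes)
  names(labels) <- as.character(seq_len(n))
  # inhibitory ground truth, optionally enriched in the overlap ensemble
  w <- rep(1, n)
  w[labels == "overlap"] <- cfg$inhibitory_overlap_enrichment
  n_inhib <- round(cfg$inhibitory_frac * n)
  inhib <- rep(FALSE, n)
  inhib[sample(n, n_inhib, prob = w)] <- TRUE

  hyp <- NULL
  eeg <- NULL
  if (with_sleep) {
    n_epochs <- as.integer(cfg$offline_duration_s / 6)
    hyp <- simulate_hypnogram(n_epochs, cfg, epoch_s = 6)
    eeg <- simulate_eeg_emg(hyp, cfg)
  }
  off2 <- simulate_offline_session(cfg, labels, hypnogram = hyp,
                                   wake_only_coincidence = with_sleep)
  labels1 <- ifelse(labels %in% c("neutral", "overlap"), "neutral",
                    "remaining")
  names(labels1) <- names(labels)
  off1 <- simulate_offline_session(cfg, labels1)

  enc <- simulate_encoding_pair(cfg, labels)
  rec <- simulate_recall_sessions(cfg, labels)
  chem <- simulate_chemotag_session(cfg, inhib)

  sessions <- list(
    neutral_enc = list(kind = "neutral_encoding", events = enc$neutral),
    aversive_enc = list(kind = "aversive_encoding", events = enc$aversive),
    offline1 = list(kind = "offline", events = off1$events,
                    locomotion = off1$locomotion),
    offline2 = list(kind = "offline", events = off2$events,
                    locomotion = off2$locomotion,
                    eeg_emg = eeg),
    recall_neutral = list(kind = "recall_neutral", events = rec$neutral),
    recall_novel = list(kind = "recall_novel", events = rec$novel),
    chemotag = list(kind = "chemotag", traces = chem)
  )
  # match tables from the global registry (all sessions use global ids as
  # local ids, so pairs are identities over the shared active populations)
  mt <- function(sa, sb, ids) match_table(sa, sb, ids, ids)
  enc_n_ids <- enc$active_neutral
  enc_a_ids <- enc$active_aversive
  match_tables <- list(
    mt("offline2", "neutral_enc", enc_n_ids),
    mt("offline2", "aversive_enc", enc_a_ids),
    mt("offline1", "neutral_enc",
       which(labels1 == "neutral")),
    mt("recall_neutral", "neutral_enc",
       intersect(rec$active_neutral_recall, enc_n_ids)),
    mt("recall_neutral", "aversive_enc",
       intersect(rec$active_neutral_recall, enc_a_ids)),
    mt("recall_novel", "neutral_enc",
       intersect(rec$active_novel_recall, enc_n_ids)),
    mt("recall_novel", "aversive_enc",
       intersect(rec$active_novel_recall, enc_a_ids)),
    mt("neutral_enc", "aversive_enc",
       intersect(enc_n_ids, enc_a_ids)),
    mt("chemotag", "offline2", seq_len(n))
  )
  set <- experiment_set(sessions, match_tables,
                        group_label = "synthetic")
  truth <- list(labels = labels, labels_offline1 = labels1,
                bursts_offline2 = off2$truth, bursts_offline1 = off1$truth,
                hypnogram = hyp, inhibitory = inhib,
                active_neutral_enc = enc_n_ids,
                active_aversive_enc = enc_a_ids,
                active_neutral_recall = rec$active_neutral_recall,
                active_novel_recall = rec$active_novel_recall)
  list(set = set, truth = truth)
}

# Encoding sessions: context-specific per-cell rate patterns over the cells
# active in each context (ensemble members by construction). Cell ids are
# global ids.
simulate_encoding_pair <- function(cfg, labels) {
  n <- length(labels)
  active_n <- which(labels %in% c("neutral", "overlap"))
  active_a <- which(labels %in% c("aversive", "overlap"))
  gen <- function(active_ids, duration_s) {
    n_frames <- as.integer(duration_s * cfg$frame_rate)
    base <- cfg$background_rate_hz / cfg$frame_rate
    # context pattern: per-cell rate offsets, truncated at zero
    rates <- pmax(base / 5,
                  base + stats::rnorm(length(active_ids), 0,
                                      cfg$encoding_pattern_sd / cfg$frame_rate))
    values <- matrix(0, length(active_ids), n_frames)
    hit <- matrix(stats::runif(length(active_ids) * n_frames) <
                    rates, length(active_ids), n_frames)
    values[hit] <- draw_amplitudes(sum(hit))
    # guarantee every listed cell is active (>= 1 event)
    silent <- rowSums(values) == 0
    if (any(silent)) {
      at <- sample(n_frames, sum(silent), replace = TRUE)
      values[cbind(which(silent), at)] <- draw_amplitudes(sum(silent))
    }
    event_matrix(values, cfg$frame_rate, cell_ids = active_ids)
  }
  list(neutral = gen(active_n, cfg$encoding_duration_s),
       aversive = gen(active_a, cfg$encoding_duration_s * 0.7),
       active_neutral = active_n, active_aversive = active_a)
}

# Recall sessions: each global cell is active with the per-ensemble
# reactivation probability of its label; active cells carry background
# events. Cell ids are global ids.
simulate_recall_sessions <- function(cfg, labels) {
  n <- length(labels)
  gen <- function(react_probs) {
    p_active <- react_probs[labels]
    active <- which(stats::runif(n) < p_active)
    n_frames <- as.integer(cfg$recall_duration_s * cfg$frame_rate)
    p_bg <- cfg$background_rate_hz / cfg$frame_rate
    values <- matrix(0, length(active), n_frames)
    hit <- matrix(stats::runif(length(active) * n_frames) < p_bg,
                  length(active), n_frames)
    values[hit] <- draw_amplitudes(sum(hit))
    silent <- rowSums(values) == 0
    if (any(silent)) {
      at <- sample(n_frames, sum(silent), replace = TRUE)
      values[cbind(which(silent), at)] <- draw_amplitudes(sum(silent))
    }
    list(events = event_matrix(values, cfg$frame_rate, cell_ids = active),
         active = active)
  }
  rn <- gen(cfg$recall_reactivation$neutral_recall)
  rv <- gen(cfg$recall_reactivation$novel_recall)
  list(neutral = rn$events, novel = rv$events,
       active_neutral_recall = rn$active,
       active_novel_recall = rv$active)
}
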