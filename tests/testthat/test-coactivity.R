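toy_traces <- function(seed = 1, n_frames = 60) {
  set.seed(seed)
  v <- random_toy_matrix(6, n_frames)
  labels <- c("neutral", "neutral", "aversive", "aversive",
              "overlap", "overlap")
  names(labels) <- as.character(1:6)
  list(m = event_matrix(v, 30), labels = labels, v = v)
}

test_that("ensemble_mean_traces equals the brute-force double z-score per ensemble", {
  tt <- toy_traces(5)
  tr <- ensemble_mean_traces(tt$m, as_assignment(tt$labels))
  for (e in c("neutral", "aversive", "overlap")) {
    members <- which(tt$labels == e)
    zm <- t(apply(tt$v[members, ], 1, o_zscore))
    expect_equal(unname(tr[e, ]), o_zscore(colMeans(zm)))
  }
  # one-cell ensemble: trace is the cell's z-score re-standardized
  labels1 <- tt$labels
  labels1[5:6] <- c("overlap", "remaining")
  tr1 <- ensemble_mean_traces(tt$m, as_assignment(labels1))
  expect_equal(unname(tr1["overlap", ]), o_zscore(o_zscore(tt$v[5, ])))
  # empty ensemble warns and is omitted
  labels2 <- tt$labels
  labels2[labels2 == "overlap"] <- "remaining"
  expect_warning(tr2 <- ensemble_mean_traces(tt$m, as_assignment(labels2)),
                 "overlap")
  expect_false("overlap" %in% rownames(tr2))
})

test_that("ensemble_event_participation equals brute force any-frame exceedance", {
  set.seed(6)
  for (rep in 1:20) {
    tr <- rbind(neutral = o_zscore(rnorm(50)), aversive = o_zscore(rnorm(50)),
                overlap = o_zscore(rnorm(50)))
    cat <- detect_bursts(o_zscore(cumsum(rnorm(50))), 1)
    got <- ensemble_event_participation(tr, cat, 1)
    for (e in rownames(tr)) {
      for (i in seq_len(nrow(cat$events))) {
        span <- (cat$events$start[i] + 1):cat$events$end[i]
        expect_equal(unname(got[e, i]), any(tr[e, span] > 1))
      }
    }
  }
  # constant-zero trace participates nowhere
  tr0 <- rbind(neutral = rep(0, 50), aversive = rep(3, 50))
  cat0 <- detect_bursts(c(rep(0, 10), rep(3, 5), rep(0, 35)), 2)
  got0 <- ensemble_event_participation(tr0, cat0, 2)
  expect_false(any(got0["neutral", ]))
  expect_true(all(got0["aversive", ]))
})

test_that("coparticipation fractions: independent vs pairwise definitions", {
  part <- matrix(FALSE, 3, 4,
                 dimnames = list(c("neutral", "aversive", "overlap"), NULL))
  part["overlap", 1] <- TRUE                      # overlap alone
  part[c("overlap", "neutral"), 2] <- TRUE        # pair
  part[, 3] <- TRUE                               # all three
  cp <- coparticipation_fractions(part)
  expect_equal(cp$independent[["overlap"]], 0.25)
  expect_equal(cp$independent[["neutral"]], 0)
  expect_equal(pair_fraction_t(cp, "overlap", "neutral"), 0.5)
  expect_equal(pair_fraction_t(cp, "overlap", "aversive"), 0.25)
  # co-fraction never exceeds either member's total participation
  for (i in seq_len(nrow(cp$pairs))) {
    a <- cp$pairs$ensemble_a[i]; b <- cp$pairs$ensemble_b[i]
    expect_lte(cp$pairs$fraction[i], mean(part[a, ]))
    expect_lte(cp$pairs$fraction[i], mean(part[b, ]))
  }
  # all ensembles in every event: independents 0, pairs 1
  all_part <- matrix(TRUE, 3, 5,
                     dimnames = list(rownames(part), NULL))
  cp_all <- coparticipation_fractions(all_part)
  expect_true(all(cp_all$independent == 0))
  expect_true(all(cp_all$pairs$fraction == 1))
  # zero events: flagged empty
  expect_true(coparticipation_fractions(part[, 0, drop = FALSE])$empty)
})

test_that("planted coincidence ordering is recovered in co-burst fractions", {
  run_arm <- function(seeds, c_on, c_oa) {
    sapply(seeds, function(seed) {
      cfg <- small_config(seed = seed, offline_duration_s = 300,
                          coincidence = list(overlap_neutral = c_on,
                                             overlap_aversive = c_oa))
      labels <- planted_labels(cfg)
      set.seed(cfg$seed)
      off <- simulate_offline_session(cfg, labels)
      tr <- ensemble_mean_traces(off$events, as_assignment(labels))
      cat <- detect_bursts(population_trace(off$events), 2)
      cp <- coparticipation_fractions(
        ensemble_event_participation(tr, cat, 2))
      pair_fraction_t(cp, "overlap", "neutral") >
        pair_fraction_t(cp, "overlap", "aversive")
    })
  }
  high <- run_arm(1:15, 0.8, 0.2)
  expect_gte(mean(high), 14 / 15)
  low <- run_arm(16:30, 0.4, 0.4)
  expect_gt(mean(low), 0.1)   # no systematic preference either way
  expect_lt(mean(low), 0.9)
})

test_that("non-burst windows use the median burst duration and report low fractions on planted data", {
  cfg <- small_config(seed = 71, offline_duration_s = 300)
  labels <- planted_labels(cfg)
  set.seed(cfg$seed)
  off <- simulate_offline_session(cfg, labels)
  tr <- ensemble_mean_traces(off$events, as_assignment(labels))
  cat <- detect_bursts(population_trace(off$events), 2)
  nb <- nonburst_coparticipation(tr, cat, 2)
  expect_false(nb$empty)
  cp <- coparticipation_fractions(ensemble_event_participation(tr, cat, 2))
  # co-bursting is confined to burst periods
  expect_lt(pair_fraction_t(nb, "overlap", "neutral"),
            pair_fraction_t(cp, "overlap", "neutral"))
  # window bookkeeping: windows tile only non-burst segments
  win <- median(cat$events$end - cat$events$start)
  expect_lte(nb$n_events * win, length(cat$trace))
})

test_that("lagged cross-correlation equals the direct-sum oracle and finds planted lags", {
  set.seed(9)
  fr <- 10
  a <- as.numeric(arima.sim(list(ar = 0.8), 400))
  b <- c(rep(0, 3), a[1:397]) + rnorm(400, 0, 0.01)  # b lags a by 3 frames
  # oracle comparison on a 40-frame bin width (bin_s = 4 at 10 Hz)
  got <- lagged_crosscorr(a, b, fr, bin_s = 4, max_lag_frames = 5)
  expect_equal(got$per_bin_max, o_lagged_max_corr(a, b, 40, 5),
               tolerance = 1e-12)
  expect_gt(got$mean_max_corr, 0.95)
  # identity: every bin max is 1 at lag 0
  self <- lagged_crosscorr(a, a, fr, bin_s = 4, max_lag_frames = 5)
  expect_true(all(abs(self$per_bin_max - 1) < 1e-12))
  # symmetry under swapping with a symmetric lag range
  swapped <- lagged_crosscorr(b, a, fr, bin_s = 4, max_lag_frames = 5)
  expect_equal(got$per_bin_max, swapped$per_bin_max, tolerance = 1e-12)
  # widening the lag range never lowers a per-bin maximum
  narrow <- lagged_crosscorr(a, b, fr, bin_s = 4, max_lag_frames = 2)
  expect_true(all(got$per_bin_max - narrow$per_bin_max >= -1e-12))
  # zero-variance bins are skipped and counted
  z <- c(rep(0, 40), rnorm(40))
  got_z <- lagged_crosscorr(z, rnorm(80), fr, bin_s = 4, max_lag_frames = 2)
  expect_equal(got_z$n_skipped_bins, 1)
})

test_that("concatenate_offline z-scores the joined traces and bursts never span joins", {
  set.seed(10)
  mats <- lapply(1:3, function(i) {
    rbind(neutral = rnorm(100, mean = i), overlap = rnorm(100, mean = -i))
  })
  cc <- concatenate_offline(mats)
  expect_equal(ncol(cc$traces), 300)
  expect_equal(cc$boundaries, c(100L, 200L))
  expect_equal(mean(cc$traces["neutral", ]), 0, tolerance = 1e-12)
  expect_equal(sd(cc$traces["neutral", ]), 1, tolerance = 1e-12)
  # a run forced across the boundary is split there
  tr <- rep(0, 300); tr[95:105] <- 5
  cat <- detect_bursts(tr, 2, boundaries = cc$boundaries)
  expect_true(all(cat$events$end <= 100 | cat$events$start >= 100))
  # single session: plain re-z-score
  one <- concatenate_offline(mats[1])
  expect_equal(one$traces["neutral", ], o_zscore(mats[[1]]["neutral", ]))
  expect_error(concatenate_offline(list()), "empty")
  # sessions missing an ensemble are dropped with a warning
  expect_warning(
    cc2 <- concatenate_offline(c(mats, list(rbind(neutral = rnorm(50))))),
    "excluded")
})
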