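test_that("population_trace equals the hand-computed double z-score", {
  set.seed(1)
  v <- matrix(round(runif(30), 2), 3, 10)
  m <- event_matrix(v, 30)
  expect_equal(population_trace(m), o_population_trace(v))
  # nondegenerate output is standardized
  tr <- population_trace(m)
  expect_equal(mean(tr), 0, tolerance = 1e-12)
  expect_equal(sd(tr), 1, tolerance = 1e-12)
})

test_that("constant matrices give a zero trace, all-zero warns", {
  m <- event_matrix(matrix(3, 4, 8), 30)
  expect_equal(population_trace(m), rep(0, 8))
  expect_warning(tr <- population_trace(event_matrix(matrix(0, 2, 5), 30)),
                 "all-zero")
  expect_equal(tr, rep(0, 5))
})

test_that("detect_bursts returns maximal runs above threshold", {
  tr <- rep(0, 50)
  tr[11:15] <- c(2.5, 3, 4, 3, 2.1)
  tr[41:42] <- c(2.2, 2.3)
  cat <- detect_bursts(tr, 2)
  expect_equal(cat$events$start, c(10L, 40L))
  expect_equal(cat$events$end, c(15L, 42L))
  expect_equal(cat$events$peak, c(12L, 41L))
  # sub-threshold trace yields an empty catalog
  expect_equal(nrow(detect_bursts(rep(1.9, 20), 2)$events), 0)
  # strict inequality at the threshold
  expect_equal(nrow(detect_bursts(rep(2, 20), 2)$events), 0)
})

test_that("detect_bursts ties go to the earliest peak and boundaries split runs", {
  tr <- c(0, 3, 3, 3, 0)
  expect_equal(detect_bursts(tr, 2)$events$peak, 1L)
  tr2 <- rep(3, 10)
  cat2 <- detect_bursts(tr2, 2, boundaries = 5L)
  expect_equal(cat2$events$start, c(0L, 5L))
  expect_equal(cat2$events$end, c(5L, 10L))
})

test_that("events at a higher threshold nest inside events at a lower one", {
  # run counts are not monotone in the threshold (lowering it can merge two
  # events across a valley), but supra-threshold time shrinks and every
  # high-threshold event must lie inside some low-threshold event
  set.seed(7)
  for (rep in 1:20) {
    tr <- o_zscore(cumsum(rnorm(200)))
    zs <- c(0.5, 1, 1.5, 2)
    frames_above <- sapply(zs, function(z) sum(tr > z))
    expect_true(all(diff(frames_above) <= 0))
    lo <- detect_bursts(tr, 0.5)$events
    hi <- detect_bursts(tr, 1.5)$events
    for (i in seq_len(nrow(hi))) {
      expect_true(any(lo$start <= hi$start[i] & lo$end >= hi$end[i]))
    }
  }
})

test_that("cell_participation equals brute-force any-frame exceedance", {
  set.seed(2)
  for (rep in 1:20) {
    v <- random_toy_matrix(5, 40)
    m <- event_matrix(v, 30)
    tr <- population_trace(m)
    cat <- detect_bursts(tr, 1)  # lower z so toys have events
    if (nrow(cat$events) == 0) next
    got <- cell_participation(m, cat, 2)
    expect_equal(unname(got), o_cell_participation(v, cat$events, 2))
  }
  # frame-count mismatch is an error
  m <- event_matrix(random_toy_matrix(3, 20), 30)
  cat <- detect_bursts(rep(3, 10), 2)
  expect_error(cell_participation(m, cat), "frame count")
})

test_that("silent cells never participate", {
  v <- random_toy_matrix(4, 30)
  v[2, ] <- 0
  m <- event_matrix(v, 30)
  cat <- detect_bursts(population_trace(m), 1)
  if (nrow(cat$events) > 0) {
    expect_false(any(cell_participation(m, cat)[2, ]))
  }
})

test_that("ensemble_participation averages per-event fractions and is permutation invariant", {
  set.seed(3)
  v <- random_toy_matrix(6, 40)
  m <- event_matrix(v, 30)
  labels <- c(rep("neutral", 3), rep("remaining", 3))
  names(labels) <- as.character(1:6)
  cat <- detect_bursts(population_trace(m), 1)
  part <- cell_participation(m, cat)
  ps <- ensemble_participation(part, as_assignment(labels))
  # all participate => fraction 1
  all_part <- matrix(TRUE, 6, 3, dimnames = list(as.character(1:6), NULL))
  ps_all <- ensemble_participation(all_part, as_assignment(labels))
  expect_equal(ps_all$fractions[["neutral"]], 1)
  expect_equal(ps_all$fractions[["remaining"]], 1)
  # permuting cells leaves fractions unchanged
  perm <- sample(6)
  v2 <- v[perm, ]
  labels2 <- labels[perm]
  names(labels2) <- as.character(1:6)
  m2 <- event_matrix(v2, 30)
  part2 <- cell_participation(m2, detect_bursts(population_trace(m2), 1))
  ps2 <- ensemble_participation(part2, as_assignment(labels2))
  expect_equal(ps$fractions, ps2$fractions)
  # zero events flagged empty
  empty <- ensemble_participation(part[, integer(0), drop = FALSE],
                                  as_assignment(labels))
  expect_true(empty$empty)
})

test_that("planted per-ensemble cell participation is recovered within binomial error", {
  cfg <- small_config(
    seed = 31, burst_rate_per_min = 10,
    participation = c(neutral = 1, aversive = 1, overlap = 1, remaining = 1),
    coincidence = list(overlap_neutral = 1, overlap_aversive = 1),
    burst_population_frac = 0,  # pure ensemble-driven firing for this check
    cell_participation_prob = c(neutral = 0.8, aversive = 0.8,
                                overlap = 0.8, remaining = 0.1))
  labels <- planted_labels(cfg)
  set.seed(cfg$seed)
  off <- simulate_offline_session(cfg, labels)
  m <- off$events
  # evaluate participation on the planted events themselves, so the check
  # isolates the participation statistic from detection granularity
  cat <- detect_bursts(population_trace(m), 2)
  cat$events <- data.frame(start = off$truth$starts,
                           peak = off$truth$peaks,
                           end = off$truth$ends)
  ps <- ensemble_participation(cell_participation(m, cat),
                               as_assignment(labels))
  n_ev <- ps$n_events
  se_av <- sqrt(0.8 * 0.2 / (10 * n_ev))   # 10 aversive cells per event
  se_rm <- sqrt(0.1 * 0.9 / (34 * n_ev))
  expect_lt(abs(ps$fractions[["aversive"]] - 0.8), 3 * se_av + 0.02)
  expect_lt(abs(ps$fractions[["remaining"]] - 0.1), 3 * se_rm + 0.02)
})

test_that("burst detection recovers planted bursts at default SNR", {
  # default burst rate (4/min) over 5 min: ~20 planted bursts occupying a
  # small fraction of the session, as in a real offline recording
  hits <- unlist(lapply(41:43, function(seed) {
    cfg <- small_config(seed = seed, offline_duration_s = 300)
    labels <- planted_labels(cfg)
    set.seed(cfg$seed)
    off <- simulate_offline_session(cfg, labels)
    cat <- detect_bursts(population_trace(off$events), 2)
    half_s_frames <- cfg$frame_rate * 0.5
    sapply(off$truth$peaks, function(p) {
      any(abs(cat$events$peak - p) <= half_s_frames)
    })
  }))
  expect_gte(mean(hits), 0.95)
})

test_that("shuffle null is deterministic and flags planted synchrony", {
  cfg <- small_config(seed = 51, burst_rate_per_min = 10)
  labels <- planted_labels(cfg)
  set.seed(cfg$seed)
  off <- simulate_offline_session(cfg, labels)
  sn1 <- shuffle_null(off$events, n_shuffles = 50, seed = 9)
  sn2 <- shuffle_null(off$events, n_shuffles = 50, seed = 9)
  expect_identical(sn1$null_counts, sn2$null_counts)
  # synchrony concentrates activity into fewer events than any surrogate
  expect_lte(sn1$p_value, 1 / 51)
})

test_that("peri-burst locomotion recovers the planted dip and applies the edge rule", {
  cfg <- small_config(seed = 61, burst_rate_per_min = 8)
  labels <- planted_labels(cfg)
  set.seed(cfg$seed)
  off <- simulate_offline_session(cfg, labels)
  cat <- detect_bursts(population_trace(off$events), 2)
  pb <- peri_burst_locomotion(off$locomotion$trace, off$locomotion$timestamps,
                              cat, off$events$timestamps, window_s = 5)
  expect_true(pb$available)
  expect_gt(pb$n_events_used, 0)
  t_min <- pb$time_s[which.min(pb$mean)]
  # dip template minimum sits (post - pre)/2 = 0.5 s after the peak
  expect_lt(abs(t_min - 0.5), 0.25)
  # constant locomotion -> flat mean
  flat <- peri_burst_locomotion(rep(2, length(off$locomotion$trace)),
                                off$locomotion$timestamps, cat,
                                off$events$timestamps)
  expect_true(all(abs(flat$mean - 2) < 1e-9))
  # event at the session edge is excluded
  edge_cat <- detect_bursts(c(3, rep(0, 299)), 2)
  pb_edge <- peri_burst_locomotion(rep(1, 300), (0:299) * 1000 / 30,
                                   edge_cat, (0:299) * 1000 / 30)
  expect_equal(pb_edge$n_events_used, 0)
  # missing locomotion -> explicit unavailability
  expect_false(peri_burst_locomotion(NULL, NULL, cat,
                                     off$events$timestamps)$available)
})

test_that("burst detection is invariant to cell relabelling", {
  set.seed(8)
  v <- random_toy_matrix(6, 50)
  m1 <- event_matrix(v, 30)
  m2 <- event_matrix(v[sample(6), ], 30)
  expect_equal(detect_bursts(population_trace(m1), 1)$events,
               detect_bursts(population_trace(m2), 1)$events)
})
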