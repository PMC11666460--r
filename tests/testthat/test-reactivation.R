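test_that("offline_ensemble_activity equals the brute-force two-axis z-score and binning", {
  set.seed(12)
  v <- random_toy_matrix(6, 40)
  labels <- c(rep("neutral", 3), rep("remaining", 3))
  names(labels) <- as.character(1:6)
  m <- event_matrix(v, 2)  # 2 Hz so bin_s = 5 -> 10-frame bins
  got <- offline_ensemble_activity(m, as_assignment(labels), bin_s = 5)
  zt <- t(apply(v, 1, o_zscore))
  zc <- apply(zt, 2, o_zscore)
  for (e in c("neutral", "remaining")) {
    cellmean <- colMeans(zc[which(labels == e), ])
    exp_bins <- sapply(1:4, function(b) mean(cellmean[((b - 1) * 10 + 1):(b * 10)]))
    expect_equal(unname(got[e, ]), exp_bins)
  }
  # permutation invariance
  perm <- sample(6)
  m2 <- event_matrix(v[perm, ], 2)
  labels2 <- labels[perm]; names(labels2) <- as.character(1:6)
  expect_equal(offline_ensemble_activity(m2, as_assignment(labels2), 5), got)
})

test_that("recall reactivation fractions follow the cross-registration definition", {
  v <- random_toy_matrix(6, 20); v[v == 0][1] <- 0  # keep as-is
  set.seed(13)
  v <- matrix(1, 6, 20)  # all cells active
  m <- event_matrix(v, 30, cell_ids = 1:6)
  mt_n <- match_table("recall", "n_enc", c(1, 2, 3), c(11, 12, 13))
  mt_a <- match_table("recall", "a_enc", c(3, 4), c(23, 24))
  fr <- recall_reactivation_fractions(m, "recall", mt_n, mt_a)
  expect_equal(fr[["neutral"]], 2 / 6)   # cells 1,2
  expect_equal(fr[["aversive"]], 1 / 6)  # cell 4
  expect_equal(fr[["overlap"]], 1 / 6)   # cell 3
  # no matches -> all zero
  fr0 <- recall_reactivation_fractions(m, "recall",
                                       empty_mt("recall", "n_enc"),
                                       empty_mt("recall", "a_enc"))
  expect_true(all(fr0 == 0))
  # all matched to both -> overlap 1
  mt_nb <- match_table("recall", "n_enc", 1:6, 11:16)
  mt_ab <- match_table("recall", "a_enc", 1:6, 21:26)
  frb <- recall_reactivation_fractions(m, "recall", mt_nb, mt_ab)
  expect_equal(frb[["overlap"]], 1)
  expect_equal(frb[["neutral"]], 0)
})

test_that("reactivation index is the neutral-minus-novel difference and zero on identity", {
  a <- c(neutral = 0.4, aversive = 0.2, overlap = 0.3)
  b <- c(neutral = 0.1, aversive = 0.2, overlap = 0.1)
  ri <- reactivation_index(a, b)
  expect_equal(ri$index[["neutral"]], 0.3)
  expect_equal(ri$index[["overlap"]], 0.2)
  expect_true(all(reactivation_index(a, a)$index == 0))
})

test_that("planted overlap reactivation preference yields positive index; null is centred", {
  run_arm <- function(seeds, p_neutral, p_novel) {
    sapply(seeds, function(seed) {
      rr <- list(
        neutral_recall = c(neutral = 0.5, aversive = 0.2,
                           overlap = p_neutral, remaining = 0.2),
        novel_recall = c(neutral = 0.2, aversive = 0.2,
                         overlap = p_novel, remaining = 0.2))
      cfg <- sim_config(seed = seed, n_cells = 300,
                        ensemble_sizes = c(neutral = 45, aversive = 45,
                                           overlap = 30, remaining = 180),
                        offline_duration_s = 40, encoding_duration_s = 30,
                        recall_duration_s = 40, burst_rate_per_min = 0,
                        recall_reactivation = rr)
      sim <- simulate_experiment(cfg)
      s <- sim$set$sessions
      fn <- recall_reactivation_fractions(
        s$recall_neutral$events, "recall_neutral",
        get_mt(sim$set, "recall_neutral", "neutral_enc"),
        get_mt(sim$set, "recall_neutral", "aversive_enc"))
      fv <- recall_reactivation_fractions(
        s$recall_novel$events, "recall_novel",
        get_mt(sim$set, "recall_novel", "neutral_enc"),
        get_mt(sim$set, "recall_novel", "aversive_enc"))
      reactivation_index(fn, fv)$index[["overlap"]]
    })
  }
  high <- run_arm(1:20, 0.5, 0.15)
  expect_gte(mean(high > 0), 0.95)
  null <- run_arm(21:40, 0.3, 0.3)
  expect_lt(abs(mean(null)), 3 * sd(null) / sqrt(length(null)) + 0.02)
})

test_that("recall fractions recover the generator's ground truth exactly", {
  cfg <- small_config(seed = 77, burst_rate_per_min = 0)
  sim <- simulate_experiment(cfg)
  s <- sim$set$sessions
  fr <- recall_reactivation_fractions(
    s$recall_neutral$events, "recall_neutral",
    get_mt(sim$set, "recall_neutral", "neutral_enc"),
    get_mt(sim$set, "recall_neutral", "aversive_enc"))
  act <- sim$truth$active_neutral_recall
  lab <- sim$truth$labels[as.character(act)]
  expect_equal(fr[["neutral"]], mean(lab == "neutral"))
  expect_equal(fr[["aversive"]], mean(lab == "aversive"))
  expect_equal(fr[["overlap"]], mean(lab == "overlap"))
})

test_that("Kendall tau matches the O(n^2) pair-count oracle, including ties", {
  set.seed(14)
  for (rep in 1:30) {
    x <- sample(0:4, 12, replace = TRUE) + runif(12) * (rep %% 2)
    y <- sample(0:4, 12, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(suppressWarnings(cor(x, y, method = "kendall")),
                 o_kendall_tau_b(x, y), tolerance = 1e-12)
  }
})

test_that("encoding-recall PV correlation behaves as a rank statistic", {
  set.seed(15)
  n_cells <- 8
  enc_v <- random_toy_matrix(n_cells, 60, p = 0.4)
  enc_v[rowSums(enc_v) == 0, 1] <- 1
  enc <- event_matrix(enc_v, 2, cell_ids = 1:n_cells)
  # recall = encoding pattern replicated bin by bin -> tau 1 in every bin
  rec_v <- matrix(rowMeans(enc_v), n_cells, 40)
  rec <- event_matrix(rec_v + 1e-9, 2, cell_ids = 1:n_cells)
  mt <- match_table("enc", "rec", 1:n_cells, 1:n_cells)
  got <- encoding_recall_pv_corr(enc, "enc", rec, "rec", mt, bin_s = 5)
  expect_equal(got$mean_tau, 1)
  # anti-ordered recall -> tau -1 (strictly decreasing transform)
  anti <- event_matrix(max(rec_v) + 1 - rec_v, 2, cell_ids = 1:n_cells)
  got_a <- encoding_recall_pv_corr(enc, "enc", anti, "rec", mt, bin_s = 5)
  expect_equal(got_a$mean_tau, -1)
  # invariance under strictly monotone transform of the encoding vector:
  # constant-column matrices make the session mean equal the column vector
  vvec <- runif(n_cells, 0.1, 2)
  encA <- event_matrix(matrix(vvec, n_cells, 20), 2, cell_ids = 1:n_cells)
  encB <- event_matrix(matrix(exp(vvec), n_cells, 20), 2,
                       cell_ids = 1:n_cells)
  set.seed(16)
  rec2 <- event_matrix(random_toy_matrix(n_cells, 40, 0.4) + 1e-9, 2,
                       cell_ids = 1:n_cells)
  t1 <- encoding_recall_pv_corr(encA, "enc", rec2, "rec", mt, bin_s = 5)
  t2 <- encoding_recall_pv_corr(encB, "enc", rec2, "rec", mt, bin_s = 5)
  expect_equal(t1$per_bin_tau, t2$per_bin_tau)
  # < 2 shared cells errors
  mt1 <- match_table("enc", "rec", 1, 1)
  expect_error(encoding_recall_pv_corr(enc, "enc", rec, "rec", mt1),
               "2 shared")
})

test_that("encoding PV matrix separates planted context patterns", {
  gen_pair <- function(seed, distinct) {
    set.seed(seed)
    n <- 12
    base_a <- runif(n, 0.1, 1)
    base_b <- if (distinct) runif(n, 0.1, 1) else base_a
    mk <- function(base) {
      v <- matrix(rep(base, 50), n, 50) * matrix(rexp(n * 50), n, 50)
      event_matrix(v, 2, cell_ids = 1:n)
    }
    list(a = mk(base_a), b = mk(base_b))
  }
  mt <- match_table("n", "a", 1:12, 1:12)
  res_d <- sapply(1:15, function(s) {
    p <- gen_pair(s, TRUE)
    pv <- encoding_pv_matrix(p$a, "n", p$b, "a", mt, bin_s = 5)
    mean(c(pv$intra_neutral, pv$intra_aversive)) > pv$inter
  })
  expect_gte(mean(res_d), 0.95)
  res_i <- sapply(16:30, function(s) {
    p <- gen_pair(s, FALSE)
    pv <- encoding_pv_matrix(p$a, "n", p$b, "a", mt, bin_s = 5)
    mean(c(pv$intra_neutral, pv$intra_aversive)) - pv$inter
  })
  expect_lt(abs(mean(res_i)), 3 * sd(res_i) / sqrt(length(res_i)) + 0.05)
  # correlation matrix is symmetric with unit diagonal
  p <- gen_pair(31, TRUE)
  pv <- encoding_pv_matrix(p$a, "n", p$b, "a", mt, bin_s = 5)
  expect_equal(pv$matrix, t(pv$matrix))
  expect_equal(unname(diag(pv$matrix)), rep(1, nrow(pv$matrix)))
})
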