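# Independent brute-force reference implementations, written with plain
# loops so they share no code path with the package. Used to freeze expected
# values on small instances.

o_zscore <- function(x) {
  s <- sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# double z-score: per cell over time, mean over cells, z again
o_population_trace <- function(values) {
  zm <- values
  for (i in seq_len(nrow(values))) zm[i, ] <- o_zscore(values[i, ])
  col_mean <- numeric(ncol(values))
  for (j in seq_len(ncol(values))) col_mean[j] <- mean(zm[, j])
  o_zscore(col_mean)
}

# frame-by-frame run scan; 0-based half-open events
o_detect_bursts <- function(trace, z = 2) {
  events <- list()
  in_run <- FALSE
  start <- NA
  for (j in seq_along(trace)) {
    if (trace[j] > z && !in_run) {
      in_run <- TRUE; start <- j
    } else if (trace[j] <= z && in_run) {
      in_run <- FALSE
      run <- start:(j - 1)
      events[[length(events) + 1]] <-
        c(start - 1, run[which.max(trace[run])] - 1, j - 1)
    }
  }
  if (in_run) {
    run <- start:length(trace)
    events[[length(events) + 1]] <-
      c(start - 1, run[which.max(trace[run])] - 1, length(trace))
  }
  if (length(events) == 0) {
    return(data.frame(start = integer(0), peak = integer(0),
                      end = integer(0)))
  }
  m <- do.call(rbind, events)
  data.frame(start = m[, 1], peak = m[, 2], end = m[, 3])
}

# any-frame exceedance of per-cell z within each event
o_cell_participation <- function(values, events, z = 2) {
  zm <- values
  for (i in seq_len(nrow(values))) zm[i, ] <- o_zscore(values[i, ])
  out <- matrix(FALSE, nrow(values), nrow(events))
  for (i in seq_len(nrow(values))) {
    for (e in seq_len(nrow(events))) {
      for (j in (events$start[e] + 1):events$end[e]) {
        if (zm[i, j] > z) { out[i, e] <- TRUE; break }
      }
    }
  }
  out
}

# per-bin max-lag Pearson correlation, direct sums
o_lagged_max_corr <- function(a, b, win, max_lag) {
  n_bins <- length(a) %/% win
  per_bin <- rep(NA_real_, n_bins)
  for (bin in seq_len(n_bins)) {
    ia <- ((bin - 1) * win + 1):(bin * win)
    xa <- a[ia]; xb <- b[ia]
    if (sd(xa) == 0 || sd(xb) == 0) next
    best <- -Inf
    for (lag in -max_lag:max_lag) {
      xs <- c(); ys <- c()
      for (j in seq_len(win)) {
        k <- j + lag
        if (k >= 1 && k <= win) { xs <- c(xs, xa[j]); ys <- c(ys, xb[k]) }
      }
      if (sd(xs) == 0 || sd(ys) == 0) next
      num <- sum((xs - mean(xs)) * (ys - mean(ys)))
      den <- sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
      best <- max(best, num / den)
    }
    if (is.finite(best)) per_bin[bin] <- best
  }
  per_bin
}

# tie-corrected Kendall tau-b by explicit pair counting
o_kendall_tau_b <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx; next }
      if (dx == 0) { tx <- tx + 1; next }
      if (dy == 0) { ty <- ty + 1; next }
      if (dx * dy > 0) conc <- conc + 1 else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# peaks by an O(n^2) scan of the documented definition: local maxima
# (plateau -> first sample), prominence vs nearest higher point per side,
# then greedy height-first distance thinning
o_prominent_peaks <- function(x, min_prom, min_dist) {
  n <- length(x)
  cand <- c()
  for (i in 2:(n - 1)) {
    if (x[i] <= x[i - 1]) next
    k <- i
    while (k < n && x[k + 1] == x[i]) k <- k + 1
    if (k == n || x[k + 1] > x[i]) next
    cand <- c(cand, i)
  }
  if (is.null(cand)) return(integer(0))
  proms <- sapply(cand, function(p) {
    left <- which(x[1:(p - 1)] > x[p])
    lo_l <- if (length(left)) min(x[(max(left) + 1):p]) else min(x[1:p])
    right <- which(x[(p + 1):n] > x[p]) + p
    lo_r <- if (length(right)) min(x[p:(min(right) - 1)]) else min(x[p:n])
    x[p] - max(lo_l, lo_r)
  })
  cand <- cand[proms >= min_prom]
  if (length(cand) <= 1 || min_dist <= 1) return(cand)
  kept <- c()
  for (p in cand[order(-x[cand], cand)]) {
    if (all(abs(kept - p) >= min_dist) || length(kept) == 0) kept <- c(kept, p)
  }
  sort(kept)
}

# nearest-grid alignment by exhaustive search (ties -> earlier frame)
o_nearest <- function(sorted, queries) {
  sapply(queries, function(q) {
    d <- abs(sorted - q)
    which(d == min(d))[1] - 1L
  })
}

# random sparse event matrix for toy comparisons
random_toy_matrix <- function(n_cells, n_frames, p = 0.15) {
  v <- matrix(0, n_cells, n_frames)
  hit <- matrix(runif(n_cells * n_frames) < p, n_cells, n_frames)
  v[hit] <- round(rlnorm(sum(hit), 0, 0.5), 3)
  v
}
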