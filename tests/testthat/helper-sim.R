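# Shared small simulation setups for the test suite.

small_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_cells = 60,
                   ensemble_sizes = c(neutral = 10, aversive = 10,
                                      overlap = 6, remaining = 34),
                   offline_duration_s = 120,
                   encoding_duration_s = 60,
                   recall_duration_s = 60,
                   chemotag_duration_min = 41)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# labels vector for a given config, as planted by simulate_experiment
planted_labels <- function(cfg) {
  labels <- rep(names(cfg$ensemble_sizes), cfg$ensemble_sizes)
  names(labels) <- as.character(seq_len(cfg$n_cells))
  labels
}

as_assignment <- function(labels, session = "offline") {
  structure(list(session = session, labels = labels),
            class = "ensemble_assignment")
}

empty_mt <- function(a, b) match_table(a, b, integer(0), integer(0))

pair_fraction_t <- function(cp, a, b) {
  hit <- (cp$pairs$ensemble_a == a & cp$pairs$ensemble_b == b) |
    (cp$pairs$ensemble_a == b & cp$pairs$ensemble_b == a)
  cp$pairs$fraction[hit]
}

get_mt <- function(set, a, b) {
  m <- ensemblelink:::find_match_table(set, a, b)
  if (is.null(m)) empty_mt(a, b) else m
}
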