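# Shared fixtures built in code. Networks and rasters are small; anything
# expensive is memoised in `.fixture_cache` so several tests can share one
# realization.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, compute) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, compute(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# directed chain 1 -> 2 -> ... -> n
chainNetwork <- function(n) {
  networkFromEdges(seq_len(n - 1L), seq_len(n - 1L) + 1L, n)
}

# star: centre 1 with m out-leaves
starNetwork <- function(m) {
  networkFromEdges(rep(1L, m), seq_len(m) + 1L, m + 1L)
}

# sparse random-regular digraph: every unit has exactly k out-edges to
# distinct random targets; locally tree-like, so the branching-process
# critical point sits at sigma = 1
regularRandomNetwork <- function(n, k, seed = 1L) {
  set.seed(seed)
  from <- rep(seq_len(n), each = k)
  to <- unlist(lapply(seq_len(n), function(i) {
    sample(setdiff(seq_len(n), i), k)
  }))
  networkFromEdges(from, to, n)
}

# small default lattice shared across dynamics tests
smallLattice <- function() {
  fixture("small_lattice", function() buildNetwork(latticeSpec(60, 60),
                                                   seed = 42))
}

# frame-resolution SpikeExperiment from an explicit count matrix
toySpikeExperiment <- function(counts, onsets, tc_ids,
                               tc_per_trial = NULL, positions = NULL) {
  n <- nrow(counts)
  if (is.null(tc_per_trial)) {
    tc_per_trial <- rep(tc_ids, length.out = length(onsets))
  }
  trials <- data.frame(trial_id = seq_along(onsets), tc_id = tc_per_trial,
                       onset_frame = onsets)
  SpikeExperiment(counts, positions = positions,
                  is_tc = seq_len(n) %in% tc_ids, trials = trials,
                  resolution = "frame")
}

# Poisson raster with planted class-dependent responses in the response
# window: unit j responds (extra Poisson) only on trials of target
# `resp_tc[j]` (0 = never)
plantedDecodingSE <- function(n_units = 30, n_tc = 3, n_trials_per_tc = 30,
                              base_rate = 0.2, effect = 3, seed = 1,
                              resp_tc = NULL) {
  set.seed(seed)
  tc_ids <- seq_len(n_tc)
  n_trials <- n_tc * n_trials_per_tc
  tc_seq <- rep(tc_ids, n_trials_per_tc)
  onsets <- 20 + (seq_len(n_trials) - 1L) * 25L
  n_frames <- max(onsets) + 30L
  cts <- matrix(rpois(n_units * n_frames, base_rate), n_units, n_frames)
  if (is.null(resp_tc)) {
    resp_tc <- rep(0L, n_units)
    pool <- setdiff(seq_len(n_units), tc_ids)
    for (tc in tc_ids) {
      resp_tc[pool[(tc - 1) * 5 + 1:5]] <- tc
    }
  }
  for (i in seq_len(n_trials)) {
    idx <- onsets[i] + 0:5
    cts[tc_seq[i], idx] <- cts[tc_seq[i], idx] + rpois(6, 1)
    resp_units <- which(resp_tc == tc_seq[i])
    if (length(resp_units)) {
      cts[resp_units, idx] <- cts[resp_units, idx] +
        matrix(rpois(6 * length(resp_units), effect / 6),
               length(resp_units))
    }
  }
  se <- toySpikeExperiment(cts, onsets, tc_ids, tc_per_trial = tc_seq)
  attr(se, "resp_tc") <- resp_tc
  se
}
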