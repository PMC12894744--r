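## Ground-truth-bearing synthetic fixtures: planted responders, planted
## avalanches and planted power-law trial counts. These emulate the
## structure of stimulation experiments without running the simulator, so
## every analysis stage can be tested against known truth.

#' Specification for a planted-responder bundle
#'
#' Default rates mirror the study conditions the analyses are calibrated
#' for: a low ongoing baseline (0.1 spikes per unit per 132-ms window,
#' i.e. ~0.0167 per frame), about 150 trials per target, and evoked
#' target counts in the experimentally observed 1-7 spikes-per-window
#' range.
#'
#' @param n_units total units (targets included).
#' @param n_tc number of target cells (ids 1..n_tc).
#' @param trials_per_tc stimulation trials per target.
#' @param baseline_rate Poisson baseline, spikes per unit per frame.
#' @param pos_per_tc,neg_per_tc planted positive/suppressed responders per
#'   target.
#' @param pos_effect expected extra spikes per response window for a
#'   positive responder on a successful trial.
#' @param neg_factor multiplicative thinning of a suppressed responder's
#'   response-window counts (0..1).
#' @param tc_success probability a trial successfully drives its target.
#' @param tc_evoked expected evoked target spikes per response window on a
#'   successful trial.
#' @param fov_um side of the square sheet on which units are scattered.
#' @param pos_near_tc_um when set, planted positive responders are placed
#'   within this radius of their target (for spatial analyses).
#' @param seed RNG seed.
#' @return list of class \code{"PlantedResponderSpec"}.
#' @export
plantedResponderSpec <- function(n_units = 200L, n_tc = 2L,
                                 trials_per_tc = 150L,
                                 baseline_rate = 0.1 / 6,
                                 pos_per_tc = 20L, neg_per_tc = 10L,
                                 pos_effect = 2, neg_factor = 0.5,
                                 tc_success = 0.8, tc_evoked = 3,
                                 fov_um = 456, pos_near_tc_um = NULL,
                                 seed = 1L) {
  stopifnot(baseline_rate >= 0, pos_effect >= 0,
            neg_factor >= 0, neg_factor <= 1,
            tc_success >= 0, tc_success <= 1,
            n_units - n_tc >= pos_per_tc + neg_per_tc)
  structure(as.list(environment()), class = "PlantedResponderSpec")
}

#' Generate a planted-responder experiment bundle
#'
#' Builds a frame-resolution raster of independent Poisson baseline
#' counts; on each successful trial the stimulated target gains
#' \code{tc_evoked} expected spikes and its planted positive responders
#' gain independent Poisson(\code{pos_effect}) extra counts in the
#' response window, while planted suppressed responders have their
#' response-window counts binomially thinned by \code{neg_factor}.
#' Responder sets are disjoint across categories within a target.
#'
#' @param spec a [plantedResponderSpec()].
#' @param dir optional directory: writes the bundle
#'   ([writeBundle()]) plus \code{truth.csv}.
#' @return list with \code{se} (a \linkS4class{SpikeExperiment}),
#'   \code{truth} (data.frame: tc_id, unit_id, label, effect) and
#'   \code{spec}.
#' @export
generateResponderBundle <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "PlantedResponderSpec"))
  set.seed(spec$seed)
  n <- spec$n_units
  tc_ids <- seq_len(spec$n_tc)
  pool <- setdiff(seq_len(n), tc_ids)
  truth <- list()
  pos_sets <- list(); neg_sets <- list()
  for (tc in tc_ids) {
    pick <- sample(pool, spec$pos_per_tc + spec$neg_per_tc)
    pos_sets[[tc]] <- pick[seq_len(spec$pos_per_tc)]
    neg_sets[[tc]] <- pick[spec$pos_per_tc + seq_len(spec$neg_per_tc)]
    truth[[tc]] <- rbind(
      data.frame(tc_id = tc, unit_id = pos_sets[[tc]], label = "PosR",
                 effect = spec$pos_effect),
      data.frame(tc_id = tc, unit_id = neg_sets[[tc]], label = "NegR",
                 effect = spec$neg_factor))
  }
  truth <- do.call(rbind, truth)

  ## trial layout: interleaved targets, onsets every 30 frames
  n_trials <- spec$n_tc * spec$trials_per_tc
  seq_tc <- unlist(lapply(seq_len(spec$trials_per_tc),
                          function(i) sample(tc_ids)))
  onset <- 20L + (seq_len(n_trials) - 1L) * 30L
  n_frames <- max(onset) + 30L
  trials <- data.frame(trial_id = seq_len(n_trials), tc_id = seq_tc,
                       onset_frame = onset)

  cts <- matrix(rpois(n * n_frames, spec$baseline_rate), n, n_frames)
  win <- 0:5
  success <- runif(n_trials) < spec$tc_success
  for (i in seq_len(n_trials)) {
    idx <- onset[i] + win
    tc <- seq_tc[i]
    if (success[i]) {
      cts[tc, idx] <- cts[tc, idx] + rpois(6, spec$tc_evoked / 6)
      pu <- pos_sets[[tc]]
      cts[pu, idx] <- cts[pu, idx] +
        matrix(rpois(length(pu) * 6, spec$pos_effect / 6), length(pu))
    }
    nu <- neg_sets[[tc]]
    cts[nu, idx] <- matrix(rbinom(length(nu) * 6, cts[nu, idx],
                                  spec$neg_factor), length(nu))
  }

  pos_xy <- cbind(runif(n, 0, spec$fov_um), runif(n, 0, spec$fov_um))
  if (!is.null(spec$pos_near_tc_um)) {
    for (tc in tc_ids) {
      pu <- pos_sets[[tc]]
      ang <- runif(length(pu), 0, 2 * pi)
      rad <- spec$pos_near_tc_um * sqrt(runif(length(pu)))
      pos_xy[pu, 1] <- pos_xy[tc, 1] + rad * cos(ang)
      pos_xy[pu, 2] <- pos_xy[tc, 2] + rad * sin(ang)
    }
  }

  se <- SpikeExperiment(cts, positions = pos_xy,
                        is_tc = seq_len(n) %in% tc_ids, trials = trials,
                        resolution = "frame",
                        config = list(generator = "planted_responders",
                                      stim_steps = 50L,
                                      seed = spec$seed))
  if (!is.null(dir)) {
    writeBundle(se, dir)
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(se = se, truth = truth, spec = spec)
}

#' Generate a planted-avalanche activity series
#'
#' Concatenates epochs of specified size and duration, separated by runs
#' of zero bins, optionally on a constant noise floor. With no noise and
#' zero threshold, [extractAvalanches()] recovers exactly the planted
#' catalog. Profiles: \code{"parabolic"} (bins follow a discrete
#' \code{i (d + 1 - i)} arc normalized to the requested size, at least one
#' spike per bin) or \code{"flat"} (equal bins).
#'
#' @param sizes,durations equal-length vectors of epoch sizes and
#'   durations; each size must be at least its duration.
#' @param profile \code{"parabolic"} or \code{"flat"}.
#' @param gap_mean mean inter-epoch gap (zero bins); gaps are
#'   \code{1 + Poisson(gap_mean - 1)}.
#' @param noise_floor constant count added to every bin.
#' @param seed RNG seed.
#' @return list with \code{p} (the activity vector) and \code{truth}
#'   (data.frame of planted sizes/durations).
#' @export
generateAvalancheSeries <- function(sizes, durations,
                                    profile = c("parabolic", "flat"),
                                    gap_mean = 3, noise_floor = 0,
                                    seed = 1L) {
  profile <- match.arg(profile)
  stopifnot(length(sizes) == length(durations), all(sizes >= durations),
            all(durations >= 1), gap_mean >= 1)
  set.seed(seed)
  epoch_bins <- function(S, d) {
    w <- if (profile == "parabolic") {
      i <- seq_len(d); i * (d + 1 - i)
    } else rep(1, d)
    base <- rep(1L, d)
    extra <- S - d
    if (extra > 0) {
      ## largest-remainder allocation of the remaining spikes
      q <- extra * w / sum(w)
      fl <- floor(q)
      rem <- extra - sum(fl)
      ord <- order(q - fl, decreasing = TRUE)
      fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
      base <- base + as.integer(fl)
    }
    base
  }
  p <- integer(0)
  for (i in seq_along(sizes)) {
    gap <- 1L + rpois(1, gap_mean - 1)
    p <- c(p, integer(gap), epoch_bins(sizes[i], durations[i]))
  }
  p <- c(p, integer(1L + rpois(1, gap_mean - 1)))
  p <- p + as.integer(noise_floor)
  list(p = p, truth = data.frame(size = sizes, duration = durations))
}

#' Generate planted power-law trial counts
#'
#' Target counts are uniform on \code{1..7} spikes per window; the
#' aggregated category count is log-normal around
#' \code{c0 * count^h_true}. With zero noise the fitted scaling exponent
#' equals \code{h_true} exactly.
#'
#' @param h_true true scaling exponent (>= 0).
#' @param n_trials number of trials.
#' @param noise_sd log-normal noise SD (log scale).
#' @param c0 prefactor.
#' @param seed RNG seed.
#' @return a \linkS4class{TrialCounts} with unit 1 the target and unit 2
#'   the aggregated category; pass
#'   \code{category_units = list("1" = 2)} to [fitResponseScaling()].
#' @export
generateScalingTrials <- function(h_true, n_trials = 150L, noise_sd = 0.1,
                                  c0 = 10, seed = 1L) {
  stopifnot(h_true >= 0, n_trials >= 3)
  set.seed(seed)
  tc <- sample(1:7, n_trials, replace = TRUE)
  y <- c0 * tc^h_true * exp(rnorm(n_trials, 0, noise_sd))
  resp <- cbind(tc, y)
  zero <- matrix(0, n_trials, 2)
  trials <- data.frame(trial_id = seq_len(n_trials), tc_id = 1L,
                       onset_frame = NA_integer_, valid = TRUE)
  units <- data.frame(unit_id = 1:2, x_um = c(0, 10), y_um = c(0, 0),
                      is_tc = c(TRUE, FALSE))
  new("TrialCounts", resp = resp, base = zero, basePrime = zero,
      trials = trials, units = units, windows = unclass(windowSpec()))
}
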