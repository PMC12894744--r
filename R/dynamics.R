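## Three-state excitable dynamics: simulation, calibration, critical point.

#' Simulation configuration
#'
#' @param sigma branching parameter.
#' @param p_poiss per-step, per-unit external drive probability.
#' @param n_steps number of 2-ms simulation steps.
#' @param steps_per_frame steps per imaging frame (default 11, i.e. 22 ms).
#' @param fov_rows,fov_cols size of the central field of view (default
#'   38 x 38, the analysed sub-lattice).
#' @param seed integer RNG seed.
#' @return a list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(sigma = 1.0066, p_poiss = 1e-5,
                             n_steps = 110000L, steps_per_frame = 11L,
                             fov_rows = 38L, fov_cols = 38L, seed = 1L) {
  stopifnot(sigma >= 0, p_poiss >= 0, p_poiss <= 1, n_steps >= 1,
            steps_per_frame >= 1)
  structure(list(sigma = sigma, p_poiss = p_poiss,
                 n_steps = as.integer(n_steps),
                 steps_per_frame = as.integer(steps_per_frame),
                 fov_rows = as.integer(fov_rows),
                 fov_cols = as.integer(fov_cols),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Units of the central field of view
#'
#' Indices of the inner \code{fov_rows x fov_cols} sub-lattice, centred on
#' the lattice. Analyses are restricted to these units to avoid boundary
#' effects, mirroring an imaging window.
#'
#' @param network a \linkS4class{LatticeNetwork}.
#' @param fov_rows,fov_cols field-of-view dimensions.
#' @return integer vector of unit indices.
#' @export
fovIds <- function(network, fov_rows = 38L, fov_cols = 38L) {
  sp <- network@spec
  stopifnot(fov_rows <= sp$n_rows, fov_cols <= sp$n_cols)
  r0 <- (sp$n_rows - fov_rows) %/% 2
  c0 <- (sp$n_cols - fov_cols) %/% 2
  rows <- r0 + seq_len(fov_rows) - 1L
  cols <- c0 + seq_len(fov_cols) - 1L
  as.integer(outer(rows * sp$n_cols, cols, "+") + 1L)
}

#' Advance the dynamics by one step (reference implementation)
#'
#' Pure-R single-step update used as an independent oracle for the compiled
#' stepper. States: 0 resting, 1 active, 2 refractory. A resting unit
#' activates with probability
#' \code{1 - (1 - p_poiss) * (1 - p_stim[stimulated]) * (1 - p_trans)^a},
#' where \code{a} is its number of currently active presynaptic inputs;
#' active units become refractory; refractory units become resting.
#'
#' @param state integer vector of per-unit states (0/1/2).
#' @param network a \linkS4class{LatticeNetwork}.
#' @param p_trans,p_poiss,p_stim probabilities.
#' @param stim_set units receiving extra stimulation drive this step.
#' @return the next state vector.
#' @export
stepDynamics <- function(state, network, p_trans, p_poiss = 0,
                         stim_set = integer(0), p_stim = 0) {
  stopifnot(length(state) == nrow(adjacency(network)))
  active <- state == 1L
  a <- as.numeric(Matrix::crossprod(adjacency(network), active))
  p_act <- 1 - (1 - p_poiss) * (1 - p_trans)^a
  p_act[stim_set] <- 1 - (1 - p_act[stim_set]) * (1 - p_stim)
  nxt <- integer(length(state))
  resting <- state == 0L
  nxt[resting] <- ifelse(runif(sum(resting)) < p_act[resting], 1L, 0L)
  nxt[active] <- 2L
  nxt[state == 2L] <- 0L
  nxt
}

## Low-level wrapper around the compiled simulator. `stim_unit` is a
## per-step vector of 1-based unit indices (NA/0 = none).
simulateSteps <- function(network, p_trans, p_poiss, n_steps,
                          stim_unit = integer(0), p_stim = 0,
                          init_active = integer(0),
                          record_ids = integer(0),
                          steps_per_frame = 11L, record_steps = FALSE,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  su <- rep_len(-1L, n_steps)
  if (length(stim_unit)) {
    stim_unit[is.na(stim_unit)] <- 0L
    su[seq_along(stim_unit)] <- as.integer(stim_unit) - 1L
  }
  cpp_simulate(network@outIndex$row_ptr, network@outIndex$col_idx,
               nrow(adjacency(network)), p_trans, p_poiss,
               as.integer(n_steps), su, p_stim,
               as.integer(init_active) - 1L,
               as.integer(record_ids) - 1L,
               as.integer(steps_per_frame), record_steps)
}

#' Stationary field-of-view rate
#'
#' Simulates the network under constant Poisson drive and returns the mean
#' spike count per unit per frame in the field of view after a burn-in.
#'
#' @param network a \linkS4class{LatticeNetwork}.
#' @param sigma branching parameter.
#' @param p_poiss per-step drive probability.
#' @param n_steps simulation length in steps.
#' @param burn_in steps discarded before averaging.
#' @param config a [simulationConfig()] supplying frame/FoV geometry.
#' @param seed RNG seed.
#' @return mean spikes per unit per frame (scalar).
#' @export
stationaryRate <- function(network, sigma, p_poiss, n_steps = 55000L,
                           burn_in = 11000L, config = simulationConfig(),
                           seed = 1L) {
  p_trans <- transmissionProbability(sigma, meanDegree(network))
  fov <- fovIds(network, config$fov_rows, config$fov_cols)
  res <- simulateSteps(network, p_trans, p_poiss, n_steps,
                       record_ids = fov,
                       steps_per_frame = config$steps_per_frame,
                       seed = seed)
  keep <- seq.int(burn_in + 1L, n_steps)
  mean(res$rec_pop_steps[keep]) / length(fov) * config$steps_per_frame
}

#' Calibrate the external Poisson drive
#'
#' Searches \code{p_poiss} by bisection on a log scale until the stationary
#' field-of-view rate matches \code{target_rate} (spikes per unit per frame)
#' within a relative tolerance.
#'
#' @param network a \linkS4class{LatticeNetwork}.
#' @param sigma branching parameter.
#' @param target_rate target spikes per unit per frame.
#' @param tolerance relative tolerance on the achieved rate.
#' @param config a [simulationConfig()].
#' @param n_steps,burn_in simulation length per evaluation.
#' @param max_iter iteration budget.
#' @param seed RNG seed.
#' @return list with \code{p_poiss}, \code{achieved} rate and the search
#'   \code{trace}.
#' @export
calibratePoissonDrive <- function(network, sigma, target_rate,
                                  tolerance = 0.05,
                                  config = simulationConfig(),
                                  n_steps = 55000L, burn_in = 11000L,
                                  max_iter = 30L, seed = 1L) {
  stopifnot(target_rate >= 0)
  if (target_rate == 0) {
    return(list(p_poiss = 0, achieved = 0, trace = data.frame()))
  }
  spf <- config$steps_per_frame
  ## drive alone gives rate ~ p * spf; propagation only adds, so the
  ## uncalibrated per-step drive is an upper bound (modulo refractoriness)
  lo <- log10(target_rate / spf) - 5
  hi <- log10(min(1, 2 * target_rate / spf))
  trace <- data.frame(log10_p = numeric(0), rate = numeric(0))
  rate_at <- function(lp, it) {
    r <- stationaryRate(network, sigma, 10^lp, n_steps, burn_in, config,
                        seed = seed + it)
    trace[nrow(trace) + 1L, ] <<- c(lp, r)
    r
  }
  r_hi <- rate_at(hi, 0L)
  if (r_hi < target_rate * (1 - tolerance)) {
    stop("calibration failure: target rate unreachable (achieved ",
         signif(r_hi, 3), " at p_poiss = ", signif(10^hi, 3), ")")
  }
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid, it)
    if (abs(r - target_rate) <= tolerance * target_rate) {
      return(list(p_poiss = 10^mid, achieved = r, trace = trace))
    }
    if (r > target_rate) hi <- mid else lo <- mid
  }
  warning("drive calibration did not converge within ", max_iter,
          " iterations; returning closest point")
  best <- trace[which.min(abs(trace$rate - target_rate)), ]
  list(p_poiss = 10^best$log10_p, achieved = best$rate, trace = trace)
}

#' Stimulation protocol
#'
#' @param tc_ids unit indices of the target cells (must lie in the FoV).
#' @param trials_per_tc stimulation trials per target.
#' @param stim_steps stimulation duration in steps (50 = 100 ms).
#' @param iti_steps inter-trial interval in steps (1000 = 2 s).
#' @param p_stim per-step activation probability of the stimulated target.
#' @param ordering \code{"interleaved"} (block-randomized target sequence)
#'   or \code{"blocked"} (all trials of a target consecutively).
#' @return a list of class \code{"StimulusProtocol"}.
#' @export
stimulusProtocol <- function(tc_ids, trials_per_tc = 100L, stim_steps = 50L,
                             iti_steps = 1000L, p_stim = 0.5,
                             ordering = c("interleaved", "blocked")) {
  ordering <- match.arg(ordering)
  stopifnot(length(tc_ids) >= 1, trials_per_tc >= 1, stim_steps >= 1,
            iti_steps >= 0, p_stim >= 0, p_stim <= 1,
            !anyDuplicated(tc_ids))
  structure(list(tc_ids = as.integer(tc_ids),
                 trials_per_tc = as.integer(trials_per_tc),
                 stim_steps = as.integer(stim_steps),
                 iti_steps = as.integer(iti_steps),
                 p_stim = p_stim, ordering = ordering),
            class = "StimulusProtocol")
}

## Trial sequence and onset bookkeeping. Onsets are aligned to frame
## boundaries; the trial period is stim + ITI rounded up to a whole frame.
protocolSchedule <- function(protocol, config) {
  spf <- config$steps_per_frame
  period <- ceiling((protocol$stim_steps + protocol$iti_steps) / spf) * spf
  warmup <- ceiling(max(protocol$iti_steps, 20L * spf) / spf) * spf
  n_tc <- length(protocol$tc_ids)
  seq_tc <- if (protocol$ordering == "interleaved") {
    unlist(lapply(seq_len(protocol$trials_per_tc), function(i) {
      protocol$tc_ids[sample.int(n_tc)]
    }))
  } else {
    rep(protocol$tc_ids, each = protocol$trials_per_tc)
  }
  n_trials <- length(seq_tc)
  onset_step <- warmup + (seq_len(n_trials) - 1L) * period + 1L
  trials <- data.frame(trial_id = seq_len(n_trials), tc_id = seq_tc,
                       onset_step = onset_step,
                       onset_frame = (onset_step - 1L) %/% spf + 1L)
  n_steps <- warmup + n_trials * period + 20L * spf
  list(trials = trials, n_steps = n_steps, period = period)
}

#' Run a stimulation experiment
#'
#' Simulates the full lattice under calibrated Poisson drive while applying
#' the stimulation protocol, and returns the frame-binned raster of the
#' field-of-view units together with the trial table. One target is
#' stimulated per trial for \code{stim_steps} steps; trial onsets are
#' aligned to frame boundaries. Identical inputs and seed reproduce the
#' raster exactly.
#'
#' @param network a \linkS4class{LatticeNetwork}.
#' @param config a [simulationConfig()] (its \code{p_poiss} and
#'   \code{sigma} are used; \code{n_steps} is derived from the protocol).
#' @param protocol a [stimulusProtocol()].
#' @param seed RNG seed.
#' @return a \linkS4class{SpikeExperiment} at frame resolution.
#' @export
runExperiment <- function(network, config, protocol, seed = 1L) {
  fov <- fovIds(network, config$fov_rows, config$fov_cols)
  if (!all(protocol$tc_ids %in% fov)) {
    stop("all target cells must lie inside the field of view")
  }
  set.seed(seed)
  sched <- protocolSchedule(protocol, config)
  stim_unit <- integer(sched$n_steps)
  for (i in seq_len(nrow(sched$trials))) {
    on <- sched$trials$onset_step[i]
    stim_unit[on:(on + protocol$stim_steps - 1L)] <- sched$trials$tc_id[i]
  }
  p_trans <- transmissionProbability(config$sigma, meanDegree(network))
  res <- simulateSteps(network, p_trans, config$p_poiss, sched$n_steps,
                       stim_unit = stim_unit, p_stim = protocol$p_stim,
                       record_ids = fov,
                       steps_per_frame = config$steps_per_frame)
  pos <- positions(network)[fov, , drop = FALSE]
  SpikeExperiment(res$frame_counts,
                  positions = pos,
                  is_tc = fov %in% protocol$tc_ids,
                  trials = sched$trials,
                  resolution = "frame",
                  steps_per_frame = config$steps_per_frame,
                  config = list(sigma = config$sigma,
                                p_poiss = config$p_poiss,
                                p_stim = protocol$p_stim,
                                stim_steps = protocol$stim_steps,
                                iti_steps = protocol$iti_steps,
                                seed = seed),
                  unit_ids = fov)
}

#' Calibrate the stimulation strength
#'
#' Bisects the per-step stimulation probability until the mean target-cell
#' spike count in the 6-frame response window matches
#' \code{target_tc_count} within tolerance. The physical ceiling is one
#' spike every third step (the rest, active, refractory cycle), about 22
#' spikes per 132 ms.
#'
#' @param network a \linkS4class{LatticeNetwork}.
#' @param config a [simulationConfig()] with calibrated \code{p_poiss}.
#' @param target_tc_count target spikes per response window (6 frames).
#' @param tolerance relative tolerance.
#' @param protocol template protocol (its targets and timing are used;
#'   \code{p_stim} is overwritten during the search).
#' @param trials_per_tc trials used per evaluation.
#' @param max_iter iteration budget.
#' @param seed RNG seed.
#' @return list with \code{p_stim}, \code{achieved} count and \code{trace}.
#' @export
calibrateStimulation <- function(network, config, target_tc_count,
                                 tolerance = 0.1, protocol,
                                 trials_per_tc = 20L, max_iter = 12L,
                                 seed = 1L) {
  window_frames <- 6L
  if (target_tc_count == 0) {
    return(list(p_stim = 0, achieved = 0, trace = data.frame()))
  }
  eval_at <- function(p_stim, it) {
    prot <- protocol
    prot$p_stim <- p_stim
    prot$trials_per_tc <- as.integer(trials_per_tc)
    se <- runExperiment(network, config, prot, seed = seed + 1000L * it)
    meanTcResponseCount(se, window_frames)
  }
  trace <- data.frame(p_stim = numeric(0), count = numeric(0))
  lo <- 0; hi <- 1
  achieved_hi <- eval_at(1, 0L)
  trace[1L, ] <- c(1, achieved_hi)
  if (achieved_hi < target_tc_count * (1 - tolerance)) {
    stop("calibration failure: target count ", target_tc_count,
         " exceeds achievable ceiling (", signif(achieved_hi, 3), ")")
  }
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    cnt <- eval_at(mid, it)
    trace[nrow(trace) + 1L, ] <- c(mid, cnt)
    if (abs(cnt - target_tc_count) <= tolerance * target_tc_count) {
      return(list(p_stim = mid, achieved = cnt, trace = trace))
    }
    if (cnt > target_tc_count) hi <- mid else lo <- mid
  }
  best <- trace[which.min(abs(trace$count - target_tc_count)), ]
  list(p_stim = best$p_stim, achieved = best$count, trace = trace)
}

## Mean spike count of the stimulated TC in the first `window_frames`
## frames after each onset.
meanTcResponseCount <- function(se, window_frames = 6L) {
  cts <- spikeCounts(se)
  tr <- trialTable(se)
  ids <- SummarizedExperiment::rowData(se)$unit_id
  counts <- vapply(seq_len(nrow(tr)), function(i) {
    u <- match(tr$tc_id[i], ids)
    f0 <- tr$onset_frame[i]
    sum(cts[u, f0:(f0 + window_frames - 1L)])
  }, 0)
  mean(counts)
}

#' Bin a step-resolution raster into frames
#'
#' Sums contiguous, non-overlapping blocks of \code{steps_per_frame} steps.
#' Total spikes are conserved (trailing steps short of a full frame are
#' dropped).
#'
#' @param x a step-resolution \linkS4class{SpikeExperiment}.
#' @param steps_per_frame steps per frame (defaults to the value stored in
#'   the object).
#' @return a frame-resolution \linkS4class{SpikeExperiment}.
#' @export
binToFrames <- function(x, steps_per_frame = NULL) {
  md <- S4Vectors::metadata(x)
  if (md$resolution != "step") stop("input must be at step resolution")
  spf <- if (is.null(steps_per_frame)) md$steps_per_frame
         else as.integer(steps_per_frame)
  stopifnot(spf >= 1)
  cts <- spikeCounts(x)
  n_frames <- ncol(cts) %/% spf
  idx <- rep(seq_len(n_frames), each = spf)
  binned <- cts[, seq_len(n_frames * spf), drop = FALSE] %*%
    outer(idx, seq_len(n_frames), "==")
  storage.mode(binned) <- "integer"
  rd <- SummarizedExperiment::rowData(x)
  SpikeExperiment(binned, positions = unitPositions(x), is_tc = rd$is_tc,
                  trials = md$trials, resolution = "frame",
                  steps_per_frame = spf, config = md$config,
                  unit_ids = rd$unit_id)
}

#' Descendant ratio of sparsely seeded cascades
#'
#' Seeds a small number of active units in an otherwise quiet network (no
#' external drive), lets the cascade run, and pools children-per-parent
#' counts across steps and repetitions. With sparse seeding the one-step
#' ratio equals the branching parameter by construction; over whole
#' cascades, refractoriness and collisions lower the effective ratio, so
#' the ratio crosses 1 at a branching parameter slightly above 1.
#'
#' @param network a \linkS4class{LatticeNetwork}.
#' @param sigma branching parameter.
#' @param n_seeds active seeds per cascade.
#' @param n_reps number of cascades.
#' @param max_steps cap on cascade length.
#' @param burn_in steps discarded at the start of each cascade before
#'   pooling (0 recovers the seeding-step ratio).
#' @param max_spikes per-cascade spike budget; supercritical cascades are
#'   stopped once they exceed it.
#' @param seed RNG seed.
#' @return list with \code{ratio}, its standard error \code{se}
#'   (ratio-estimator, per-cascade jackknife) and the pooled sums.
#' @export
descendantRatio <- function(network, sigma, n_seeds = 10L, n_reps = 1000L,
                            max_steps = 100L, burn_in = 0L,
                            max_spikes = 10000L, seed = 1L) {
  p_trans <- transmissionProbability(sigma, meanDegree(network))
  set.seed(seed)
  res <- cpp_descendant_ratio(network@outIndex$row_ptr,
                              network@outIndex$col_idx,
                              nrow(adjacency(network)), p_trans,
                              as.integer(n_seeds), as.integer(n_reps),
                              as.integer(max_steps), as.integer(burn_in),
                              as.integer(max_spikes))
  P <- sum(res$parents); C <- sum(res$children)
  if (P == 0) return(list(ratio = NA_real_, se = NA_real_,
                          parents = 0, children = 0))
  ratio <- C / P
  ## ratio-estimator variance across cascades
  n <- length(res$parents)
  pm <- mean(res$parents)
  rv <- (res$children - ratio * res$parents) / pm
  se <- sd(rv) / sqrt(n)
  list(ratio = ratio, se = se, parents = P, children = C)
}

#' Locate the critical branching parameter
#'
#' Bisects the branching parameter until the pooled descendant ratio of
#' sparsely seeded cascades equals 1. Because refractoriness and collisions
#' dissipate activity, the critical value sits slightly above 1. The
#' defaults discard the seeding transient (\code{burn_in = 50} steps) and
#' follow cascades long enough (\code{max_steps = 500}) that the ratio
#' reflects the asymptotic branching of developed cascades — the regime
#' that decides whether activity is self-sustaining — rather than the
#' near-seed growth, which tracks sigma itself.
#'
#' @param network a \linkS4class{LatticeNetwork}.
#' @param sigma_lo,sigma_hi bracket (must straddle the crossing).
#' @param tol absolute tolerance on sigma.
#' @param n_seeds,n_reps,max_steps,burn_in,max_spikes passed to
#'   [descendantRatio()].
#' @param seed RNG seed.
#' @return list with \code{sigma_c}, \code{se} (from the final ratio
#'   uncertainty and local slope) and the bisection \code{trace}.
#' @export
findCriticalPoint <- function(network, sigma_lo = 0.95, sigma_hi = 1.1,
                              tol = 2e-3, n_seeds = 10L, n_reps = 2000L,
                              max_steps = 500L, burn_in = 50L,
                              max_spikes = 50000L, seed = 1L) {
  ratio_at <- function(s, it) {
    descendantRatio(network, s, n_seeds, n_reps, max_steps, burn_in,
                    max_spikes, seed = seed + 7L * it)
  }
  r_lo <- ratio_at(sigma_lo, 0L)
  r_hi <- ratio_at(sigma_hi, 1L)
  trace <- data.frame(sigma = c(sigma_lo, sigma_hi),
                      ratio = c(r_lo$ratio, r_hi$ratio),
                      se = c(r_lo$se, r_hi$se))
  if ((r_lo$ratio - 1) * (r_hi$ratio - 1) > 0) {
    stop("grid too narrow: descendant ratio does not cross 1 in [",
         sigma_lo, ", ", sigma_hi, "]")
  }
  it <- 1L
  while (sigma_hi - sigma_lo > tol) {
    it <- it + 1L
    mid <- (sigma_lo + sigma_hi) / 2
    r <- ratio_at(mid, it)
    trace[nrow(trace) + 1L, ] <- c(mid, r$ratio, r$se)
    if (r$ratio > 1) sigma_hi <- mid else sigma_lo <- mid
  }
  sigma_c <- (sigma_lo + sigma_hi) / 2
  ## local slope of ratio(sigma) from the trace, for an uncertainty
  fit <- try(lm(ratio ~ sigma, data = tail(trace[order(trace$sigma), ], 6)),
             silent = TRUE)
  se <- if (!inherits(fit, "try-error") && abs(coef(fit)[2]) > 0) {
    mean(tail(trace$se, 3)) / abs(coef(fit)[2])
  } else NA_real_
  list(sigma_c = sigma_c, se = unname(se), trace = trace)
}

#' Drive-response sweep
#'
#' Measures the stationary field-of-view rate across a range of external
#' drive probabilities at fixed branching parameter, and fits the log-log
#' slope. Subcritical networks respond linearly (slope 1), critical
#' networks sublinearly (2D directed-percolation exponent 0.285), and
#' supercritical networks saturate (slope near 0).
#'
#' @param network a \linkS4class{LatticeNetwork}.
#' @param sigma branching parameter.
#' @param p_values drive probabilities (per step, per unit).
#' @param n_steps,burn_in simulation length per level.
#' @param config a [simulationConfig()].
#' @param seed RNG seed.
#' @return data.frame with \code{p_poiss} and \code{rate} (spikes per unit
#'   per frame).
#' @export
driveResponseSweep <- function(network, sigma, p_values,
                               n_steps = 110000L, burn_in = 22000L,
                               config = simulationConfig(), seed = 1L) {
  rates <- vapply(seq_along(p_values), function(i) {
    stationaryRate(network, sigma, p_values[i], n_steps, burn_in, config,
                   seed = seed + i)
  }, 0)
  data.frame(p_poiss = p_values, rate = rates)
}

#' @rdname driveResponseSweep
#' @param sweep data.frame from \code{driveResponseSweep}.
#' @return \code{fitDriveResponseSlope}: list with \code{slope}, \code{ci}
#'   (95\%) and the fitted model.
#' @export
fitDriveResponseSlope <- function(sweep) {
  ok <- sweep$rate > 0
  if (sum(ok) < 3) stop("need at least 3 positive rates to fit a slope")
  fit <- lm(log10(rate) ~ log10(p_poiss), data = sweep[ok, ])
  list(slope = unname(coef(fit)[2]),
       ci = unname(confint(fit)[2, ]),
       fit = fit)
}
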