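test_that("window layout is disjoint and equal length", {
  w <- windowSpec()
  expect_equal(w$resp, 0:5)
  expect_equal(w$base, -12:-7)
  expect_equal(w$base_prime, -18:-13)
  expect_equal(length(unique(c(w$resp, w$base, w$base_prime))), 18)
  ## the alternative adjacent-baseline placement is also valid
  w2 <- windowSpec(base_start = -6L)
  expect_equal(w2$base, -6:-1)
  expect_error(windowSpec(base_start = -3L), "overlap")
})

test_that("trial counts match hand-computed sums", {
  ## unit spiking once per frame: base = resp = 6
  cts <- matrix(1L, 2, 60)
  se <- toySpikeExperiment(cts, onsets = c(25, 45), tc_ids = 1)
  counts <- extractTrialCounts(se)
  expect_true(all(respCounts(counts) == 6))
  expect_true(all(baseCounts(counts) == 6))
  expect_true(all(basePrimeCounts(counts) == 6))

  ## empty raster: all zeros
  se0 <- toySpikeExperiment(matrix(0L, 2, 60), c(25, 45), 1)
  expect_true(all(respCounts(extractTrialCounts(se0)) == 0))

  ## random toy raster against an explicit enumeration oracle
  set.seed(5)
  cts <- matrix(rpois(3 * 80, 1), 3, 80)
  se <- toySpikeExperiment(cts, onsets = c(30, 60), tc_ids = 2)
  counts <- extractTrialCounts(se)
  for (i in 1:2) {
    on <- c(30, 60)[i]
    for (j in 1:3) {
      expect_equal(respCounts(counts)[i, j], sum(cts[j, on + 0:5]))
      expect_equal(baseCounts(counts)[i, j], sum(cts[j, on - 12:7]))
    }
  }

  ## trials too close to the recording edge are dropped
  se_edge <- toySpikeExperiment(cts, onsets = c(5, 30), tc_ids = 2)
  expect_message(ce <- extractTrialCounts(se_edge), "dropped")
  expect_equal(nrow(respCounts(ce)), 1)
})

test_that("outlier removal follows the mean + 10 SD rule", {
  cts <- matrix(0L, 2, 400)
  onsets <- 20 + (0:9) * 30
  se <- toySpikeExperiment(cts, onsets, 1)
  counts <- extractTrialCounts(se)

  ## constant counts: nothing removed (strict inequality)
  counts@resp[] <- 5
  out <- removeOutlierTrials(counts)
  expect_equal(sum(is.na(out@resp)), 0)

  ## {1,1,1,1,100}: mean 20.8, SD ~ 44.3, threshold ~ 464 -> kept
  x <- c(1, 1, 1, 1, 100)
  expect_true(max(x) <= mean(x) + 10 * sd(x))
  cc <- counts
  cc@resp <- matrix(rep(x, 2), 5, 2)
  cc@base <- cc@basePrime <- matrix(0, 5, 2)
  cc@trials <- counts@trials[1:5, ]
  out5 <- removeOutlierTrials(cc)
  expect_equal(sum(is.na(out5@resp)), 0)

  ## a genuinely extreme trial among many is removed
  set.seed(1)
  n <- 200
  onsets <- 20 + (0:(n - 1)) * 30
  se <- toySpikeExperiment(matrix(0L, 1, 20 + n * 30), onsets, 1)
  big <- extractTrialCounts(se)
  v <- rpois(n, 1); v[77] <- 1000
  big@resp <- matrix(v, n, 1)
  outb <- removeOutlierTrials(big)
  expect_true(is.na(outb@resp[77, 1]))
  expect_equal(sum(is.na(outb@resp)), 1)

  ## Poisson counts: removal fraction far below 0.1%
  pois <- big
  set.seed(2)
  pois@resp <- matrix(rpois(n, 1), n, 1)
  pois@base <- pois@basePrime <- matrix(rpois(n, 1), n, 1)
  outp <- removeOutlierTrials(pois)
  expect_lt(attr(outp, "removed_fraction"), 0.001)
})

test_that("target retention follows the 91st-percentile rule", {
  set.seed(3)
  n <- 100
  onsets <- 20 + (0:(n - 1)) * 30
  se <- toySpikeExperiment(matrix(0L, 1, 20 + n * 30), onsets, 1)
  counts <- extractTrialCounts(se)

  ## responses all above all baselines: retained
  counts@base <- matrix(rpois(n, 2), n, 1)
  counts@resp <- matrix(20 + rpois(n, 2), n, 1)
  expect_true(selectValidTargets(counts)$retained)

  ## zero responses: excluded
  counts@resp <- matrix(0, n, 1)
  expect_false(selectValidTargets(counts)$retained)

  ## response distribution identical to baseline: typically excluded
  ## (P(count > q91) ~ 9% per trial, far below the 20% criterion)
  counts@resp <- matrix(rpois(n, 2), n, 1)
  expect_false(selectValidTargets(counts)$retained)
})

test_that("z-test classification is calibrated and detects planted shifts", {
  ## planted +3 mean shift against an SD ~ 1 baseline
  n <- 100
  onsets <- 20 + (0:(n - 1)) * 30
  se <- toySpikeExperiment(matrix(0L, 3, 20 + n * 30), onsets, 1)
  counts <- extractTrialCounts(se)
  base <- rep(c(0, 2), n / 2)  # mean 1, sd ~ 1
  counts@base <- cbind(rpois(n, 3), base, base)
  counts@resp <- cbind(rpois(n, 3), base + 3, base)
  cl <- classifyResponders(counts)
  z_planted <- cl$z[cl$unit_id == 2]
  expect_equal(z_planted, 3 / (sd(base) * sqrt(2 / n)), tolerance = 1e-10)
  expect_gt(z_planted, 18)
  expect_equal(cl$label[cl$unit_id == 2], "PosR")
  ## identical draws give z = 0, NonR
  expect_equal(cl$z[cl$unit_id == 3], 0)
  expect_equal(cl$label[cl$unit_id == 3], "NonR")
  ## the target itself is labeled TC
  expect_equal(cl$label[cl$unit_id == 1], "TC")

  ## alternative SE readings rescale z deterministically
  cl2 <- classifyResponders(counts, se_method = "count")
  expect_equal(cl2$z[cl2$unit_id == 2], z_planted * sqrt(2 / n),
               tolerance = 1e-10)
  cl3 <- classifyResponders(counts, se_method = "base_mean")
  expect_equal(cl3$z[cl3$unit_id == 2], z_planted * sqrt(2),
               tolerance = 1e-10)
})

test_that("type-I rate matches alpha and FDR controls nulls", {
  set.seed(7)
  n_units <- 4000; n <- 100
  onsets <- 20 + (0:(n - 1)) * 30
  se <- toySpikeExperiment(matrix(0L, 2, 20 + n * 30), onsets, 1)
  counts <- extractTrialCounts(se)
  counts@units <- data.frame(unit_id = seq_len(n_units + 1),
                             x_um = 0, y_um = 0,
                             is_tc = c(TRUE, rep(FALSE, n_units)))
  counts@base <- cbind(rpois(n, 3),
                       matrix(rpois(n * n_units, 3), n, n_units))
  counts@resp <- cbind(rpois(n, 3),
                       matrix(rpois(n * n_units, 3), n, n_units))
  counts@basePrime <- counts@base
  cl <- classifyResponders(counts, alpha = 0.025)
  fp <- mean(cl$label[cl$unit_id != 1] == "PosR")
  fn <- mean(cl$label[cl$unit_id != 1] == "NegR")
  se3 <- 3 * sqrt(0.025 * 0.975 / n_units)
  ## discreteness of counts makes the test slightly conservative; allow
  ## the binomial band plus a small calibration margin
  expect_lt(abs(fp - 0.025), se3 + 0.012)
  expect_lt(abs(fn - 0.025), se3 + 0.012)
  ## under the global null, BH keeps the discovered fraction below q
  expect_lt(mean(cl$label_fdr[cl$unit_id != 1] %in% c("PosR", "NegR")),
            0.025)
})

test_that("scaling fits recover planted exponents", {
  ## exact power law: slope recovered to machine precision
  tc <- generateScalingTrials(0.3, n_trials = 200, noise_sd = 0, seed = 1)
  fit <- fitResponseScaling(tc, category_units = list("1" = 2))
  expect_equal(fit$exponent, 0.3, tolerance = 1e-10)

  ## flat relation: slope ~ 0
  tc0 <- generateScalingTrials(0, n_trials = 500, noise_sd = 0.05, seed = 2)
  fit0 <- fitResponseScaling(tc0, category_units = list("1" = 2))
  expect_lt(abs(fit0$exponent), 0.05)

  ## unbiased across the exponent range at n = 150 trials
  for (h in c(0.2, 0.3, 0.5, 1.0)) {
    est <- vapply(1:20, function(s) {
      tcs <- generateScalingTrials(h, n_trials = 150, noise_sd = 0.1,
                                   seed = s)
      fitResponseScaling(tcs, category_units = list("1" = 2))$exponent
    }, 0)
    expect_lt(abs(mean(est) - h), 0.02)
  }

  ## insufficient range errors out
  tc1 <- generateScalingTrials(0.3, n_trials = 30, noise_sd = 0, seed = 3)
  tc1@resp[, 1] <- 2
  expect_error(fitResponseScaling(tc1, category_units = list("1" = 2)),
               "insufficient range")
})

test_that("confidence intervals cover the planted exponent", {
  covered <- vapply(1:20, function(s) {
    tcs <- generateScalingTrials(0.285, n_trials = 150, noise_sd = 0.1,
                                 seed = 100 + s)
    f <- fitResponseScaling(tcs, category_units = list("1" = 2))
    f$ci[1] <= 0.285 && 0.285 <= f$ci[2]
  }, TRUE)
  expect_gte(mean(covered), 0.9)
})

test_that("correlations behave on identical, independent and copied series", {
  set.seed(11)
  n <- 10000
  onsets <- 20 + (0:(n - 1)) * 30
  se <- toySpikeExperiment(matrix(0L, 3, 20 + n * 30), onsets, 1)
  counts <- extractTrialCounts(se)
  a <- rpois(n, 2)
  counts@basePrime <- cbind(a, a, rpois(n, 2))
  counts@base <- cbind(a, a, rpois(n, 2))
  counts@resp <- cbind(a, rpois(n, 2), rep(1, n))
  res <- trialCorrelations(counts)
  expect_equal(res$unit_autocorr$r_bprime_base[1], 1)
  expect_equal(res$unit_autocorr$r_bprime_base[2], 1)
  ## independent series: |r| < 3 / sqrt(n)
  expect_lt(abs(res$unit_autocorr$r_bprime_base[3]), 3 / sqrt(n))
  ## zero-variance series: NA
  expect_true(is.na(res$unit_autocorr$r_base_resp[3]))

  ## a fake responder carrying the TC counts has cross-correlation 1
  cl <- data.frame(tc_id = 1, unit_id = 1:3, z = 0, p_up = 1, p_down = 1,
                   label = c("TC", "PosR", "NonR"),
                   label_fdr = c("TC", "PosR", "NonR"), degenerate = FALSE)
  res2 <- trialCorrelations(counts, cl)
  r_pos <- res2$tc_crosscorr$r[res2$tc_crosscorr$category == "PosR" &
                                res2$tc_crosscorr$condition == "base"]
  expect_equal(r_pos, 1)
})

test_that("Fano factors are 1 for Poisson counts and 0 for constants", {
  set.seed(13)
  n <- 2000
  n_frames <- 20 + n * 30
  onsets <- 20 + (0:(n - 1)) * 30
  cts <- matrix(rpois(2 * n_frames, 2 / 6), 2, n_frames)
  se <- toySpikeExperiment(cts, onsets, 1)
  ff <- fanoFactor(se)
  se_ff <- sqrt(2 / n)
  expect_lt(abs(ff$ff_base[2] - 1), 3 * se_ff)
  expect_lt(abs(ff$ff_resp[2] - 1), 3 * se_ff)

  ## constant counts: FF = 0
  cts1 <- matrix(1L, 1, n_frames)
  se1 <- toySpikeExperiment(cts1, onsets, 1)
  ff1 <- fanoFactor(se1)
  expect_equal(ff1$ff_resp[1], 0)

  ## FF is invariant to trial relabeling
  se_shuf <- toySpikeExperiment(cts, sample(onsets), 1)
  ff_s <- fanoFactor(se_shuf)
  expect_equal(sort(ff_s$ff_base), sort(ff$ff_base), tolerance = 1e-12)
})

test_that("rate matching selects the window equalizing mean counts", {
  ## response rate doubled: 3 response frames match 6 baseline frames
  set.seed(17)
  n <- 400
  n_frames <- 20 + n * 30
  onsets <- 20 + (0:(n - 1)) * 30
  cts <- matrix(rpois(n_frames, 0.5), 1, n_frames)
  for (on in onsets) cts[1, on + 0:8] <- rpois(9, 1.0)
  se <- toySpikeExperiment(cts, onsets, 1)
  ffm <- fanoFactor(se, rate_matched = TRUE)
  expect_equal(ffm$matched_window[1], 3, tolerance = 1)
  expect_false(ffm$excluded[1])

  ## a unit with a 10x response cannot be rate-matched and is excluded
  cts2 <- matrix(rpois(n_frames, 0.5), 1, n_frames)
  for (on in onsets) cts2[1, on + 0:8] <- rpois(9, 5)
  se2 <- toySpikeExperiment(cts2, onsets, 1)
  ffm2 <- fanoFactor(se2, rate_matched = TRUE)
  expect_true(ffm2$excluded[1])
  expect_true(is.na(ffm2$ff_resp[1]))
})

test_that("trial stratification partitions as configured", {
  n <- 40
  onsets <- 20 + (0:(n - 1)) * 30
  se <- toySpikeExperiment(matrix(0L, 3, 20 + n * 30), onsets, 1)
  counts <- extractTrialCounts(se)
  ## target baseline counts 0..9 repeating: nearest-rank q91 = 9
  counts@base <- cbind(rep(0:9, 4), rpois(n, 5), rpois(n, 5))
  counts@resp <- cbind(c(rep(5, 10), rep(12, 15), rep(30, 15)),
                       rpois(n, 5), rpois(n, 5))
  st <- stratifyTrials(counts)
  ## low: > 9 and <= 18; high: > 18
  expect_equal(st$tc_split$low, 11:25)
  expect_equal(st$tc_split$high, 26:40)

  ## theta = 0 puts every trial in the HIGH regime
  st0 <- stratifyTrials(counts, theta = 0)
  expect_equal(st0$regime$high, 1:40)
  expect_length(st0$regime$low, 0)

  ## degenerate population baseline: both quartile strata empty
  counts@base[, 2:3] <- 3
  expect_warning(std <- stratifyTrials(counts), "degenerate")
  expect_length(std$pop_split$low, 0)
  expect_length(std$pop_split$high, 0)
})
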