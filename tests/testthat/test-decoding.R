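test_that("feature matrices enumerate window counts and exclude targets", {
  set.seed(1)
  cts <- matrix(rpois(5 * 100, 1), 5, 100)
  se <- toySpikeExperiment(cts, onsets = c(30, 60), tc_ids = c(1, 2),
                           tc_per_trial = c(1, 2))
  fm <- buildFeatures(se, offset = 0, length = 6)
  expect_equal(colnames(fm$X), as.character(3:5))
  for (i in 1:2) {
    on <- c(30, 60)[i]
    expect_equal(unname(fm$X[i, ]), rowSums(cts[3:5, on + 0:5]))
  }
  expect_equal(as.integer(as.character(fm$y)), c(1, 2))
  expect_error(buildFeatures(se, length = 0), "positive")
})

test_that("trial and target filtering follows the spiking criteria", {
  ## 3 classes; TC 3 silent; TC 2 spikes on 60% of trials
  n_per <- 20
  onsets <- 20 + (0:(3 * n_per - 1)) * 20
  tc_seq <- rep(1:3, n_per)
  cts <- matrix(0L, 10, max(onsets) + 30)
  for (i in seq_along(onsets)) {
    tc <- tc_seq[i]
    if (tc == 1) cts[1, onsets[i]] <- 1L
    if (tc == 2 && (i %/% 3) %% 5 < 3) cts[2, onsets[i]] <- 1L
  }
  ## background for features
  set.seed(2)
  cts[4:10, ] <- matrix(rpois(7 * ncol(cts), 0.5), 7)
  se <- toySpikeExperiment(cts, onsets, tc_ids = 1:3,
                           tc_per_trial = tc_seq)
  fm <- buildFeatures(se)
  filt <- filterTrialsAndTargets(fm, se)
  rep_tab <- attr(filt, "class_report")
  expect_false(rep_tab$retained[rep_tab$tc_id == 3])
  expect_true(all(rep_tab$retained[rep_tab$tc_id %in% c(1, 2)]))
  ## class 1 keeps all trials, class 2 only its spiking ones
  expect_equal(sum(filt$y == 1), n_per)
  expect_equal(sum(filt$y == 2),
               sum(cts[2, onsets[tc_seq == 2]] > 0))

  ## every trial spiking: identity
  cts2 <- cts; cts2[1:3, ] <- 1L
  se2 <- toySpikeExperiment(cts2, onsets, 1:3, tc_per_trial = tc_seq)
  fm2 <- buildFeatures(se2)
  expect_equal(nrow(filterTrialsAndTargets(fm2, se2)$X), nrow(fm2$X))
})

test_that("decoders separate planted classes and stay at chance on noise", {
  se <- plantedDecodingSE(seed = 3)
  fm <- buildFeatures(se)
  dec <- trainEvalDecoder(fm, family = "xgb", replicates = 15,
                          nrounds = 25, seed = 4)
  expect_gt(dec$mean_accuracy, 0.85)
  ## micro-accuracy from the pooled confusion matrix is consistent
  expect_equal(sum(diag(dec$confusion)) / sum(dec$confusion),
               mean(dec$accuracy), tolerance = 0.02)

  ## label shuffling collapses to chance (binomial 3-SE band)
  set.seed(5)
  fm_s <- fm
  fm_s$y <- sample(fm$y)
  dec_s <- trainEvalDecoder(fm_s, family = "xgb", replicates = 15,
                            nrounds = 25, seed = 6)
  n_test <- round(0.2 * nrow(fm$X)) * 15
  se3 <- 3 * sqrt(dec_s$chance * (1 - dec_s$chance) / n_test)
  expect_lt(abs(dec_s$mean_accuracy - dec_s$chance), se3 + 0.05)

  ## the random-forest family works through the same surface
  dec_rf <- trainEvalDecoder(fm, family = "rf", replicates = 5,
                             num_trees = 150, seed = 7)
  expect_gt(dec_rf$mean_accuracy, 0.85)
})

test_that("attribution ranks truly informative features first", {
  se <- plantedDecodingSE(seed = 8)
  fm <- buildFeatures(se)
  resp_tc <- attr(se, "resp_tc")
  informative <- as.character(which(resp_tc > 0))
  score <- featureAttribution(fm, "xgb", seed = 9, nrounds = 25)
  top15 <- names(sort(score, decreasing = TRUE))[1:15]
  expect_gte(mean(top15 %in% informative), 0.8)
})

test_that("neuron dropping erodes accuracy to chance", {
  ## one feature encodes the labels perfectly; the rest are noise
  set.seed(10)
  n <- 90
  y <- factor(rep(1:3, 30))
  X <- matrix(rpois(n * 6, 1), n, 6,
              dimnames = list(NULL, as.character(10:15)))
  X[, 3] <- as.integer(y) * 10
  fm <- structure(list(X = X, y = y, trial_id = seq_len(n),
                       window = c(offset = 0, length = 6)),
                  class = "FeatureMatrix")
  dc <- neuronDropCurve(fm, "xgb", replicates = 5, nrounds = 20,
                        posr_ids = "12", seed = 11)
  expect_equal(dc$dropped[1], "12")   # the informative unit goes first
  expect_equal(dc$L[1], 1)
  expect_gt(dc$accuracy[1], 0.9)
  ## after it is gone, accuracy sits at chance
  expect_lt(max(dc$accuracy[-1]), 1 / 3 + 0.15)
  ## the curve runs down to a single feature
  expect_equal(dc$n_features[nrow(dc)], 1)
})

test_that("radius exclusion removes local information", {
  ## informative units only within 40 um of their targets
  se <- plantedDecodingSE(seed = 12)
  resp_tc <- attr(se, "resp_tc")
  n <- nrow(se)
  pos <- cbind(runif(n, 0, 400), runif(n, 0, 400))
  tc_ids <- 1:3
  pos[tc_ids, ] <- cbind(c(100, 300, 200), c(100, 100, 300))
  for (u in which(resp_tc > 0)) {
    ang <- runif(1, 0, 2 * pi); r <- runif(1, 5, 40)
    pos[u, ] <- pos[resp_tc[u], ] + r * c(cos(ang), sin(ang))
  }
  se2 <- SpikeExperiment(spikeCounts(se), positions = pos,
                         is_tc = seq_len(n) %in% tc_ids,
                         trials = trialTable(se), resolution = "frame")
  fm <- buildFeatures(se2)
  feat_pos <- pos[!(seq_len(n) %in% tc_ids), ]
  res <- radiusExclusion(fm, feat_pos, pos[tc_ids, ],
                         radii = c(0, 45, 600), family = "xgb",
                         replicates = 5, nrounds = 25, seed = 13)
  curve <- res$curve
  expect_equal(curve$n_excluded[1], 0)
  expect_gt(curve$accuracy[1], 0.85)
  ## all planted responders excluded by 45 um: chance decoding
  expect_lt(curve$accuracy[curve$r == 45], 1 / 3 + 0.15)
  ## radius beyond the sheet: curve truncated with a message
  expect_lt(nrow(curve), 3)
})

test_that("decoding is above chance only when windows overlap responses", {
  se <- plantedDecodingSE(seed = 14, effect = 4)
  prof <- temporalDecoding(se, offsets = c(-12, 0, 12), window = 6,
                           family = "xgb", replicates = 8, nrounds = 25,
                           seed = 15)
  acc0 <- prof$accuracy[prof$offset == 0]
  expect_gt(acc0, 0.8)
  for (off in c(-12, 12)) {
    expect_lt(prof$accuracy[prof$offset == off], prof$chance[1] + 0.15)
  }
})

test_that("baseline pseudo-trials pick lone-target bins", {
  ## hand-built raster: TC spikes planted in known inter-trial bins
  n_frames <- 400
  cts <- matrix(0L, 5, n_frames)
  onsets <- c(100, 300)
  ## lone spikes of TC 1 in bin starting 151; TC 2 in bin starting 211
  cts[1, 153] <- 1L
  cts[2, 214] <- 1L
  ## a bin where both spike: rejected
  cts[1, 241] <- 1L; cts[2, 244] <- 1L
  se <- toySpikeExperiment(cts, onsets, tc_ids = c(1, 2),
                           tc_per_trial = c(1, 2))
  fm <- baselinePseudoTrials(se, bin_frames = 6, guard_bins = 2)
  expect_equal(sort(as.integer(as.character(fm$y))), c(1, 2))
  expect_equal(nrow(fm$X), 2)
  ## silent targets: nothing qualifies
  cts0 <- matrix(0L, 5, n_frames)
  se0 <- toySpikeExperiment(cts0, onsets, c(1, 2), c(1, 2))
  expect_null(baselinePseudoTrials(se0))
})

test_that("down-sampling caps pseudo-trial class sizes", {
  set.seed(16)
  n_frames <- 2000
  cts <- matrix(0L, 6, n_frames)
  cts[1, sample(seq(300, 1900), 60)] <- 1L
  cts[2, sample(seq(300, 1900), 5)] <- 1L
  se <- toySpikeExperiment(cts, onsets = 50, tc_ids = c(1, 2),
                           tc_per_trial = 1)
  fm <- baselinePseudoTrials(se, match_counts = c("1" = 10, "2" = 10))
  expect_lte(sum(fm$y == 1), 10)
})

test_that("silent-baseline trials are dropped by the control filter", {
  se <- plantedDecodingSE(seed = 17, base_rate = 0.02)
  fm <- buildFeatures(se)
  filt <- dropSilentBaselineTrials(fm, se)
  expect_lt(nrow(filt$X), nrow(fm$X))
  cts <- spikeCounts(se)
  tr <- trialTable(se)
  non_tc <- which(!SummarizedExperiment::rowData(se)$is_tc)
  pop <- vapply(seq_len(nrow(tr)), function(i)
    sum(cts[non_tc, tr$onset_frame[i] - 12:7]), 0)
  expect_equal(sort(filt$trial_id), sort(tr$trial_id[pop > 0]))
})
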