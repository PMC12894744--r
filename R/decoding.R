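## Stimulus-origin decoding: feature construction, classifier evaluation,
## attribution-ranked neuron dropping, radius exclusion, temporal profiles
## and baseline pseudo-trials.

#' Build a trial-by-unit feature matrix
#'
#' One sample per stimulation trial, one feature per non-target unit: the
#' spike count in a window of \code{length} frames placed \code{offset}
#' frames after trial onset. Labels are the stimulated target identities.
#'
#' @param se a frame-resolution \linkS4class{SpikeExperiment}.
#' @param offset window start relative to onset (frames).
#' @param length window length in frames (> 0).
#' @return list of class \code{"FeatureMatrix"}: \code{X} (samples x
#'   features, columns named by unit id), \code{y} (factor of target
#'   ids), \code{trial_id}, \code{window}.
#' @export
buildFeatures <- function(se, offset = 0L, length = 6L) {
  if (length <= 0) stop("window length must be positive")
  cts <- spikeCounts(se)
  tr <- trialTable(se)
  rd <- SummarizedExperiment::rowData(se)
  feat_units <- which(!rd$is_tc)
  ok <- tr$onset_frame + offset >= 1 &
    tr$onset_frame + offset + length - 1L <= ncol(cts)
  tr <- tr[ok, , drop = FALSE]
  X <- matrix(0, nrow(tr), length(feat_units),
              dimnames = list(NULL, rd$unit_id[feat_units]))
  for (i in seq_len(nrow(tr))) {
    idx <- tr$onset_frame[i] + offset + seq_len(length) - 1L
    X[i, ] <- rowSums(cts[feat_units, idx, drop = FALSE])
  }
  structure(list(X = X, y = factor(tr$tc_id), trial_id = tr$trial_id,
                 window = c(offset = offset, length = length)),
            class = "FeatureMatrix")
}

#' Filter trials and targets by stimulation success
#'
#' Keeps only trials on which the stimulated target spiked at least once
#' in the six frames from onset, then keeps only classes (targets) with at
#' least half of their trials surviving.
#'
#' @param features a [buildFeatures()] matrix.
#' @param se the originating \linkS4class{SpikeExperiment} (supplies the
#'   target rasters).
#' @param min_frac minimum surviving-trial fraction per class (0.5).
#' @return the filtered \code{"FeatureMatrix"}; per-class counts are
#'   attached as attribute \code{"class_report"}.
#' @export
filterTrialsAndTargets <- function(features, se, min_frac = 0.5) {
  cts <- spikeCounts(se)
  tr <- trialTable(se)
  ids <- SummarizedExperiment::rowData(se)$unit_id
  tr <- tr[match(features$trial_id, tr$trial_id), , drop = FALSE]
  spiked <- vapply(seq_len(nrow(tr)), function(i) {
    u <- match(tr$tc_id[i], ids)
    idx <- tr$onset_frame[i] + 0:5
    idx <- idx[idx <= ncol(cts)]
    sum(cts[u, idx]) >= 1
  }, TRUE)
  surv_frac <- tapply(spiked, features$y, mean)
  keep_class <- names(surv_frac)[!is.na(surv_frac) & surv_frac >= min_frac]
  keep <- spiked & features$y %in% keep_class
  if (length(keep_class) < 2) stop("decoding impossible: fewer than 2 ",
                                   "classes survive filtering")
  report <- data.frame(tc_id = names(surv_frac),
                       frac_spiking = as.numeric(surv_frac),
                       retained = names(surv_frac) %in% keep_class)
  out <- features
  out$X <- features$X[keep, , drop = FALSE]
  out$y <- droplevels(features$y[keep])
  out$trial_id <- features$trial_id[keep]
  attr(out, "class_report") <- report
  out
}

#' Drop trials with a silent preceding baseline
#'
#' Supercritical-regime control: removes samples whose population
#' (non-target) spike count in the baseline window preceding onset is
#' zero, where decoding would otherwise be trivially driven by the
#' presence of any activity at all.
#'
#' @param features a \code{"FeatureMatrix"}.
#' @param se the originating \linkS4class{SpikeExperiment}.
#' @param windows a [windowSpec()] (its baseline window is used).
#' @return the filtered \code{"FeatureMatrix"}.
#' @export
dropSilentBaselineTrials <- function(features, se,
                                     windows = windowSpec()) {
  cts <- spikeCounts(se)
  tr <- trialTable(se)
  rd <- SummarizedExperiment::rowData(se)
  tr <- tr[match(features$trial_id, tr$trial_id), , drop = FALSE]
  non_tc <- which(!rd$is_tc)
  pop <- vapply(seq_len(nrow(tr)), function(i) {
    idx <- tr$onset_frame[i] + windows$base
    idx <- idx[idx >= 1 & idx <= ncol(cts)]
    sum(cts[non_tc, idx])
  }, 0)
  keep <- pop > 0
  out <- features
  out$X <- features$X[keep, , drop = FALSE]
  out$y <- droplevels(features$y[keep])
  out$trial_id <- features$trial_id[keep]
  out
}

## multiclass boosted-tree fit with library-default hyperparameters,
## single-threaded for reproducibility
fitXgb <- function(X, y, nrounds) {
  dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L,
                                 nthread = 1)
  xgboost::xgb.train(params = list(objective = "multi:softmax",
                                   num_class = nlevels(y), nthread = 1L),
                     data = dtrain, nrounds = nrounds, verbose = 0)
}

## single train/test split evaluation; resamples the split if a class is
## missing from either side
evalSplit <- function(X, y, family, train_frac, nrounds, num_trees) {
  n <- nrow(X)
  for (try_i in 1:20) {
    tr_idx <- sample.int(n, round(train_frac * n))
    if (nlevels(droplevels(y[tr_idx])) == nlevels(y) &&
        length(tr_idx) < n) break
  }
  te_idx <- setdiff(seq_len(n), tr_idx)
  if (family == "xgb") {
    model <- fitXgb(X[tr_idx, , drop = FALSE], y[tr_idx], nrounds)
    pred_idx <- predict(model, xgboost::xgb.DMatrix(
      X[te_idx, , drop = FALSE], nthread = 1))
    pred <- factor(levels(y)[pred_idx + 1L], levels = levels(y))
  } else {
    model <- ranger::ranger(x = X[tr_idx, , drop = FALSE],
                            y = y[tr_idx], num.trees = num_trees,
                            num.threads = 1,
                            seed = sample.int(.Machine$integer.max, 1))
    pred <- predict(model, data = X[te_idx, , drop = FALSE],
                    num.threads = 1)$predictions
  }
  cm <- table(truth = y[te_idx], pred = factor(pred, levels = levels(y)))
  list(confusion = cm, model = model)
}

## per-class F1 from a confusion matrix (truth in rows)
confusionF1 <- function(cm) {
  tp <- diag(cm)
  prec <- tp / pmax(colSums(cm), 1)
  rec <- tp / pmax(rowSums(cm), 1)
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  names(f1) <- rownames(cm)
  f1
}

#' Train and evaluate a stimulus-origin decoder
#'
#' Repeatedly splits the samples into random train/test portions, fits a
#' gradient-boosted-tree or random-forest classifier, and reports overall
#' accuracy and per-class F1 across replicates.
#'
#' @param features a \code{"FeatureMatrix"}.
#' @param family \code{"xgb"} (boosted trees) or \code{"rf"} (random
#'   forest).
#' @param replicates number of random splits (reference protocol: 100).
#' @param train_frac training fraction (0.8).
#' @param seed RNG seed.
#' @param nrounds boosting rounds (xgb).
#' @param num_trees forest size (rf).
#' @return list of class \code{"DecodingResult"}: \code{accuracy} (per
#'   replicate), \code{f1} (replicates x classes), summary means/sds,
#'   pooled \code{confusion}, \code{chance}, and the hyperparameters.
#' @export
trainEvalDecoder <- function(features, family = c("xgb", "rf"),
                             replicates = 100L, train_frac = 0.8,
                             seed = 1L, nrounds = 50L, num_trees = 500L) {
  family <- match.arg(family)
  X <- features$X; y <- features$y
  stopifnot(nlevels(y) >= 2, min(table(y)) >= 2)
  set.seed(seed)
  acc <- numeric(replicates)
  f1 <- matrix(NA_real_, replicates, nlevels(y),
               dimnames = list(NULL, levels(y)))
  pooled <- NULL
  for (r in seq_len(replicates)) {
    ev <- evalSplit(X, y, family, train_frac, nrounds, num_trees)
    acc[r] <- sum(diag(ev$confusion)) / sum(ev$confusion)
    f1[r, ] <- confusionF1(ev$confusion)
    pooled <- if (is.null(pooled)) ev$confusion else pooled + ev$confusion
  }
  structure(list(accuracy = acc, f1 = f1,
                 mean_accuracy = mean(acc), sd_accuracy = sd(acc),
                 mean_f1 = colMeans(f1), confusion = pooled,
                 chance = 1 / nlevels(y), family = family,
                 params = list(replicates = replicates,
                               train_frac = train_frac, nrounds = nrounds,
                               num_trees = num_trees, seed = seed)),
            class = "DecodingResult")
}

#' @export
print.DecodingResult <- function(x, ...) {
  cat("DecodingResult (", x$family, "): accuracy ",
      signif(x$mean_accuracy, 3), " +/- ", signif(x$sd_accuracy, 2),
      " over ", length(x$accuracy), " replicates (chance ",
      signif(x$chance, 3), ")\n", sep = "")
  cat("  per-class F1:", paste(signif(x$mean_f1, 2), collapse = " "), "\n")
  invisible(x)
}

#' Per-feature attribution scores
#'
#' For boosted trees, exact tree-path (Shapley) attributions from the
#' fitted model, averaged as absolute contributions over samples and
#' classes. For random forests, impurity importance is used as the
#' ranking score.
#'
#' @param features a \code{"FeatureMatrix"}.
#' @param family classifier family.
#' @param seed RNG seed.
#' @param nrounds,num_trees hyperparameters as in [trainEvalDecoder()].
#' @return named numeric vector of attribution magnitudes (one per
#'   feature).
#' @export
featureAttribution <- function(features, family = c("xgb", "rf"),
                               seed = 1L, nrounds = 50L, num_trees = 500L) {
  family <- match.arg(family)
  X <- features$X; y <- features$y
  set.seed(seed)
  if (family == "xgb") {
    model <- fitXgb(X, y, nrounds)
    contrib <- predict(model, xgboost::xgb.DMatrix(X, nthread = 1),
                       predcontrib = TRUE)
    ## per-class contributions: samples x classes x (features + bias);
    ## a two-class model may return a plain samples x (features + 1) matrix
    score <- if (length(dim(contrib)) == 3) {
      apply(abs(contrib[, , seq_len(ncol(X)), drop = FALSE]), 3, mean)
    } else {
      colMeans(abs(contrib[, seq_len(ncol(X)), drop = FALSE]))
    }
  } else {
    model <- ranger::ranger(x = X, y = y, num.trees = num_trees,
                            importance = "impurity", num.threads = 1,
                            seed = sample.int(.Machine$integer.max, 1))
    score <- ranger::importance(model)
  }
  names(score) <- colnames(X)
  score
}

#' Attribution-ranked neuron-dropping curve
#'
#' Iteratively removes the most informative features: at each step the
#' classifier is refit, features are ranked by attribution, the top
#' \code{batch} are dropped, and decoding metrics are recorded, until one
#' feature (or fewer than \code{batch}) remains. When positive-responder
#' ids are supplied, the likelihood \code{L} that dropped units are PosR
#' is tracked per step.
#'
#' @param features a \code{"FeatureMatrix"}.
#' @param family classifier family.
#' @param replicates evaluation splits per step.
#' @param batch features removed per step (1 reproduces the reference
#'   procedure; larger batches bound cost).
#' @param posr_ids optional unit ids externally classified as positive
#'   responders.
#' @param recompute recompute attributions on the retrained model each
#'   step (default) or reuse the initial ranking.
#' @param seed RNG seed.
#' @param nrounds,num_trees hyperparameters.
#' @return data.frame of class \code{"DropCurve"}: per step the number
#'   removed, accuracy, mean F1, the dropped unit ids
#'   (comma-separated) and \code{L}.
#' @export
neuronDropCurve <- function(features, family = c("xgb", "rf"),
                            replicates = 10L, batch = 1L,
                            posr_ids = NULL, recompute = TRUE, seed = 1L,
                            nrounds = 50L, num_trees = 500L) {
  family <- match.arg(family)
  cur <- features
  step <- 0L
  rows <- list()
  rank0 <- NULL
  while (ncol(cur$X) >= 1) {
    step <- step + 1L
    ev <- trainEvalDecoder(cur, family, replicates = replicates,
                           seed = seed + step, nrounds = nrounds,
                           num_trees = num_trees)
    if (ncol(cur$X) <= batch) {
      rows[[step]] <- data.frame(step = step,
                                 n_features = ncol(cur$X),
                                 n_removed_total = ncol(features$X) -
                                   ncol(cur$X),
                                 accuracy = ev$mean_accuracy,
                                 mean_f1 = mean(ev$mean_f1),
                                 dropped = "", L = NA_real_)
      break
    }
    score <- if (recompute || is.null(rank0)) {
      featureAttribution(cur, family, seed = seed + step,
                         nrounds = nrounds, num_trees = num_trees)
    } else {
      rank0[names(rank0) %in% colnames(cur$X)]
    }
    if (is.null(rank0)) rank0 <- score
    drop_names <- names(sort(score, decreasing = TRUE))[seq_len(batch)]
    L <- if (is.null(posr_ids)) NA_real_ else
      mean(drop_names %in% as.character(posr_ids))
    rows[[step]] <- data.frame(step = step, n_features = ncol(cur$X),
                               n_removed_total = ncol(features$X) -
                                 ncol(cur$X),
                               accuracy = ev$mean_accuracy,
                               mean_f1 = mean(ev$mean_f1),
                               dropped = paste(drop_names, collapse = ","),
                               L = L)
    keep <- setdiff(colnames(cur$X), drop_names)
    cur$X <- cur$X[, keep, drop = FALSE]
  }
  out <- do.call(rbind, rows)
  class(out) <- c("DropCurve", "data.frame")
  out
}

## Gaussian smoothing with reflecting edges (kernel sd in bins)
gaussSmooth <- function(x, sd_bins = 1) {
  n <- length(x)
  if (n < 2) return(x)
  half <- max(1L, ceiling(3 * sd_bins))
  kern <- exp(-(seq(-half, half))^2 / (2 * sd_bins^2))
  kern <- kern / sum(kern)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[n - seq_len(half) + 1L]))
  as.numeric(stats::filter(xp, kern, sides = 2))[half + seq_len(n)]
}

#' Radius-exclusion decoding
#'
#' Removes all features within radius \code{r} of any target (or of one
#' target in the per-target variant), retrains, and records metrics as a
#' function of \code{r}, the exclusion probability \code{P_ex(r)}
#' (fraction of features removed), and each target's critical radius: the
#' first radius at which the (Gaussian-smoothed, kernel sd 1 bin) drop in
#' its F1-score exceeds three standard deviations below the mean rate of
#' change.
#'
#' @param features a \code{"FeatureMatrix"}.
#' @param positions named matrix/data.frame of feature-unit coordinates
#'   (um), rows matching \code{colnames(features$X)}.
#' @param tc_positions matrix of target coordinates (um), rows named by
#'   target id.
#' @param radii exclusion radii in um (increasing).
#' @param family,replicates,seed,nrounds,num_trees as in
#'   [trainEvalDecoder()].
#' @return list with \code{curve} (r, n_excluded, p_ex, accuracy,
#'   per-class F1 columns) and \code{critical_radii}.
#' @export
radiusExclusion <- function(features, positions, tc_positions, radii,
                            family = c("xgb", "rf"), replicates = 10L,
                            seed = 1L, nrounds = 50L, num_trees = 500L) {
  family <- match.arg(family)
  pos <- as.matrix(positions)
  stopifnot(nrow(pos) == ncol(features$X))
  tcp <- as.matrix(tc_positions)
  ## distance of each feature to its nearest target
  dmin <- apply(pos, 1, function(p) {
    min(sqrt((tcp[, 1] - p[1])^2 + (tcp[, 2] - p[2])^2))
  })
  classes <- levels(features$y)
  rows <- list()
  for (i in seq_along(radii)) {
    r <- radii[i]
    keep <- dmin > r
    if (!any(keep)) {
      message("all features excluded at r = ", r, "; curve truncated")
      break
    }
    sub <- features
    sub$X <- features$X[, keep, drop = FALSE]
    ev <- trainEvalDecoder(sub, family, replicates = replicates,
                           seed = seed + i, nrounds = nrounds,
                           num_trees = num_trees)
    rows[[i]] <- c(r = r, n_excluded = sum(!keep),
                   p_ex = mean(!keep), accuracy = ev$mean_accuracy,
                   setNames(ev$mean_f1, paste0("f1_", classes)))
  }
  curve <- as.data.frame(do.call(rbind, rows))
  crit <- vapply(classes, function(cl) {
    f1 <- gaussSmooth(curve[[paste0("f1_", cl)]], 1)
    if (length(f1) < 3) return(NA_real_)
    d <- diff(f1)
    thr <- mean(d) - 3 * sd(d)
    hit <- which(d < thr)
    if (length(hit)) curve$r[hit[1] + 1L] else NA_real_
  }, 0)
  list(curve = curve,
       critical_radii = data.frame(tc_id = classes, radius = crit))
}

#' Temporal decoding profile
#'
#' Slides the feature window in steps of \code{step} frames relative to
#' stimulus onset and decodes at every offset. Offset 0 is the first
#' window fully overlapping the stimulation.
#'
#' @param se a frame-resolution \linkS4class{SpikeExperiment}.
#' @param offsets vector of window offsets (frames, relative to onset).
#' @param window window length in frames (1 or 6 in the reference
#'   protocol).
#' @param family,replicates,seed,nrounds,num_trees as in
#'   [trainEvalDecoder()].
#' @return data.frame with \code{offset}, \code{accuracy}, \code{sd} and
#'   \code{chance}.
#' @export
temporalDecoding <- function(se, offsets = -10:10, window = 6L,
                             family = c("xgb", "rf"), replicates = 10L,
                             seed = 1L, nrounds = 50L, num_trees = 500L) {
  family <- match.arg(family)
  rows <- lapply(seq_along(offsets), function(i) {
    fm <- buildFeatures(se, offset = offsets[i], length = window)
    if (nrow(fm$X) < 4 || nlevels(droplevels(fm$y)) < 2) return(NULL)
    ev <- trainEvalDecoder(fm, family, replicates = replicates,
                           seed = seed + i, nrounds = nrounds,
                           num_trees = num_trees)
    data.frame(offset = offsets[i], accuracy = ev$mean_accuracy,
               sd = ev$sd_accuracy, chance = ev$chance)
  })
  do.call(rbind, rows)
}

#' Baseline pseudo-trials
#'
#' Finds 6-frame bins in the inter-trial baseline (excluding bins within
#' \code{guard_bins} bins of any stimulation window) in which exactly one
#' of the targets spiked, labels the bin by that target, and down-samples
#' class sizes to match a reference per-class distribution (without
#' replacement, seeded).
#'
#' @param se a frame-resolution \linkS4class{SpikeExperiment}.
#' @param tc_ids target ids to consider (default: all flagged targets).
#' @param bin_frames pseudo-trial bin length (6).
#' @param guard_bins bins excluded on each side of a stimulation window
#'   (2).
#' @param match_counts optional named vector of per-class sample caps
#'   (e.g. \code{table(features$y)} of the stimulation condition).
#' @param seed RNG seed for down-sampling.
#' @return a \code{"FeatureMatrix"} over the non-target units, or
#'   \code{NULL} when no qualifying bin exists.
#' @export
baselinePseudoTrials <- function(se, tc_ids = NULL, bin_frames = 6L,
                                 guard_bins = 2L, match_counts = NULL,
                                 seed = 1L) {
  cts <- spikeCounts(se)
  tr <- trialTable(se)
  rd <- SummarizedExperiment::rowData(se)
  if (is.null(tc_ids)) tc_ids <- rd$unit_id[rd$is_tc]
  md <- S4Vectors::metadata(se)
  stim_frames <- ceiling((md$config$stim_steps %||% 50L) /
                           md$steps_per_frame)
  n_bins <- ncol(cts) %/% bin_frames
  bin_start <- (seq_len(n_bins) - 1L) * bin_frames + 1L
  ## bins overlapping (or adjacent to) any stimulation window are excluded
  bad <- rep(FALSE, n_bins)
  for (i in seq_len(nrow(tr))) {
    s0 <- tr$onset_frame[i] - guard_bins * bin_frames
    s1 <- tr$onset_frame[i] + stim_frames - 1L + guard_bins * bin_frames
    bad <- bad | (bin_start + bin_frames - 1L >= s0 & bin_start <= s1)
  }
  tc_rows <- match(tc_ids, rd$unit_id)
  feat_units <- which(!rd$is_tc)
  keep_bins <- integer(0); labels <- integer(0)
  for (b in which(!bad)) {
    idx <- bin_start[b] + seq_len(bin_frames) - 1L
    tc_counts <- rowSums(cts[tc_rows, idx, drop = FALSE])
    if (sum(tc_counts > 0) == 1L) {
      keep_bins <- c(keep_bins, b)
      labels <- c(labels, tc_ids[which(tc_counts > 0)])
    }
  }
  if (!length(keep_bins)) return(NULL)
  X <- t(vapply(keep_bins, function(b) {
    idx <- bin_start[b] + seq_len(bin_frames) - 1L
    rowSums(cts[feat_units, idx, drop = FALSE])
  }, numeric(length(feat_units))))
  colnames(X) <- rd$unit_id[feat_units]
  y <- factor(labels, levels = sort(unique(labels)))
  if (!is.null(match_counts)) {
    set.seed(seed)
    keep <- unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      cap <- match_counts[[cl]]
      if (is.null(cap) || is.na(cap)) return(idx)
      if (length(idx) > cap) sample(idx, cap) else idx
    }))
    keep <- sort(keep)
    X <- X[keep, , drop = FALSE]
    y <- droplevels(y[keep])
  }
  omitted <- setdiff(as.character(tc_ids), levels(y))
  if (length(omitted)) {
    warning("targets without qualifying baseline bins omitted: ",
            paste(omitted, collapse = ", "))
  }
  structure(list(X = X, y = y, trial_id = keep_bins,
                 window = c(offset = NA, length = bin_frames)),
            class = "FeatureMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
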