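## Perturbation-response analysis: trial-windowed counts, responder
## classification, scaling exponents, correlations, Fano factors, strata.

#' Analysis windows around stimulus onset
#'
#' Three equal-length, non-overlapping windows per trial: the response
#' window starting at onset (6 frames, ~132 ms), the baseline window
#' starting \code{base_start} frames before onset (default 12, ~264 ms
#' before), and the pre-baseline window ("base-prime") ending where the
#' baseline begins.
#'
#' @param len window length in frames.
#' @param resp_start first response frame, relative to onset.
#' @param base_start first baseline frame, relative to onset (negative).
#' @return list of class \code{"WindowSpec"} with \code{resp},
#'   \code{base} and \code{base_prime} frame-offset vectors.
#' @export
windowSpec <- function(len = 6L, resp_start = 0L, base_start = -12L) {
  len <- as.integer(len)
  resp <- resp_start + seq_len(len) - 1L
  base <- base_start + seq_len(len) - 1L
  base_prime <- (base_start - len) + seq_len(len) - 1L
  w <- list(resp = resp, base = base, base_prime = base_prime, len = len)
  all_frames <- c(resp, base, base_prime)
  if (anyDuplicated(all_frames)) stop("windows must not overlap")
  structure(w, class = "WindowSpec")
}

#' Extract per-trial window counts
#'
#' Sums spike counts over the response, baseline and pre-baseline windows
#' for every (trial, unit) pair. Trials whose windows fall outside the
#' recording are dropped (with a message).
#'
#' @param se a frame-resolution \linkS4class{SpikeExperiment} with a trial
#'   table.
#' @param windows a [windowSpec()].
#' @return a \linkS4class{TrialCounts}.
#' @export
extractTrialCounts <- function(se, windows = windowSpec()) {
  stopifnot(S4Vectors::metadata(se)$resolution == "frame")
  cts <- spikeCounts(se)
  tr <- trialTable(se)
  lo <- min(windows$base_prime); hi <- max(windows$resp)
  ok <- tr$onset_frame + lo >= 1 & tr$onset_frame + hi <= ncol(cts)
  if (!all(ok)) {
    message(sum(!ok), " trial(s) too close to the recording edge dropped")
    tr <- tr[ok, , drop = FALSE]
  }
  win_sum <- function(offsets) {
    out <- matrix(0, nrow(tr), nrow(cts))
    for (i in seq_len(nrow(tr))) {
      idx <- tr$onset_frame[i] + offsets
      out[i, ] <- rowSums(cts[, idx, drop = FALSE])
    }
    out
  }
  rd <- SummarizedExperiment::rowData(se)
  units <- data.frame(unit_id = rd$unit_id, x_um = rd$x_um, y_um = rd$y_um,
                      is_tc = rd$is_tc)
  tr$valid <- TRUE
  obj <- new("TrialCounts",
             resp = win_sum(windows$resp),
             base = win_sum(windows$base),
             basePrime = win_sum(windows$base_prime),
             trials = tr, units = units, windows = unclass(windows))
  validObject(obj)
  obj
}

#' @rdname TrialCounts-class
#' @export
setMethod("respCounts", "TrialCounts", function(object) object@resp)

#' @rdname TrialCounts-class
#' @export
setMethod("baseCounts", "TrialCounts", function(object) object@base)

#' @rdname TrialCounts-class
#' @export
setMethod("basePrimeCounts", "TrialCounts",
          function(object) object@basePrime)

#' @rdname TrialCounts-class
#' @export
setMethod("trialInfo", "TrialCounts", function(object) object@trials)

#' @rdname TrialCounts-class
#' @export
setMethod("unitInfo", "TrialCounts", function(object) object@units)

setMethod("show", "TrialCounts", function(object) {
  cat("TrialCounts:", nrow(object@resp), "trials x", ncol(object@resp),
      "units\n")
  cat("  targets:", sum(object@units$is_tc),
      " windows (resp/base/base'):",
      paste(range(object@windows$resp), collapse = ".."), "/",
      paste(range(object@windows$base), collapse = ".."), "/",
      paste(range(object@windows$base_prime), collapse = ".."),
      "frames\n")
  rem <- attr(object, "removed_fraction")
  if (!is.null(rem)) cat("  outlier cells removed:",
                         signif(100 * rem, 3), "%\n")
})

#' Remove outlier trial counts
#'
#' Marks, per unit and per window, trial counts strictly greater than the
#' unit's mean plus 10 standard deviations as missing (an artifact guard;
#' on well-behaved counts far below 0.1\% of cells are affected). Constant
#' counts (zero SD) are never removed.
#'
#' @param counts a \linkS4class{TrialCounts}.
#' @param n_sd removal threshold in standard deviations.
#' @return the \linkS4class{TrialCounts} with outliers set to \code{NA};
#'   the removed fraction is attached as attribute
#'   \code{"removed_fraction"}.
#' @export
removeOutlierTrials <- function(counts, n_sd = 10) {
  stopifnot(nrow(counts@resp) >= 2)
  flag <- function(m) {
    mu <- colMeans(m, na.rm = TRUE)
    s <- apply(m, 2, sd, na.rm = TRUE)
    sweep(m, 2, mu + n_sd * s, ">")
  }
  removed <- 0L; total <- 0L
  for (slot_name in c("resp", "base", "basePrime")) {
    m <- slot(counts, slot_name)
    bad <- flag(m)
    bad[is.na(bad)] <- FALSE
    m[bad] <- NA
    slot(counts, slot_name) <- m
    removed <- removed + sum(bad)
    total <- total + length(bad)
  }
  attr(counts, "removed_fraction") <- removed / total
  counts
}

## nearest-rank percentile (ceiling definition)
nearestRankQuantile <- function(x, p) {
  x <- sort(x[!is.na(x)])
  if (!length(x)) return(NA_real_)
  x[max(1L, ceiling(p * length(x)))]
}

#' Select valid (responsive) targets
#'
#' A target cell is retained if at least \code{min_frac} of its trials
#' evoke a response-window spike count strictly above the
#' \code{percentile} nearest-rank percentile of its own baseline counts.
#'
#' @param counts a \linkS4class{TrialCounts}.
#' @param percentile baseline percentile (default 0.91).
#' @param min_frac minimum fraction of supra-percentile trials (0.2).
#' @return data.frame with \code{tc_id}, \code{frac_above} and
#'   \code{retained}.
#' @export
selectValidTargets <- function(counts, percentile = 0.91, min_frac = 0.2) {
  tr <- counts@trials
  units <- counts@units
  tcs <- unique(tr$tc_id)
  res <- lapply(tcs, function(tc) {
    u <- match(tc, units$unit_id)
    rows <- which(tr$tc_id == tc)
    base <- counts@base[rows, u]
    resp <- counts@resp[rows, u]
    q <- nearestRankQuantile(base, percentile)
    frac <- mean(resp > q, na.rm = TRUE)
    data.frame(tc_id = tc, frac_above = frac, retained = frac >= min_frac)
  })
  do.call(rbind, res)
}

#' Classify responders with a z-test
#'
#' For every (unit, target) pair, compares the mean response-window count
#' of the target's trials with the mean and standard deviation of the
#' baseline counts. The default (\code{se_method = "mean"}) standardizes
#' the difference of the two trial means by its standard error under the
#' baseline variance, \code{sd(base) * sqrt(2 / n)}, which is calibrated
#' under the null (type-I rate = alpha per tail).
#' \code{se_method = "base_mean"} uses \code{sd(base) / sqrt(n)} (the
#' baseline-mean SE only, anti-conservative by sqrt(2)) and
#' \code{se_method = "count"} uses the per-trial-count SD. Units are labeled
#' \code{PosR} when the upper-tail p-value is below \code{alpha},
#' \code{NegR} when the lower-tail p-value is, and \code{NonR} otherwise.
#' Benjamini-Hochberg FDR labels are computed on the upper- and lower-tail
#' p-value sets separately at rate \code{fdr_q}. Target cells themselves
#' are labeled \code{TC} for their own trials and excluded from the
#' feature population.
#'
#' @param counts a \linkS4class{TrialCounts}.
#' @param alpha per-tail significance level (default 0.025).
#' @param fdr_q FDR rate for the adjusted labels (default 0.025).
#' @param se_method \code{"mean"} (SE of the difference of means),
#'   \code{"base_mean"} (SE of the baseline mean only) or \code{"count"}
#'   (per-trial-count SD).
#' @param min_trials minimum valid trials per target (default 10).
#' @return data.frame with one row per (tc_id, unit_id):
#'   \code{z}, \code{p_up}, \code{p_down}, \code{label},
#'   \code{label_fdr}, \code{degenerate}.
#' @export
classifyResponders <- function(counts, alpha = 0.025, fdr_q = 0.025,
                               se_method = c("mean", "base_mean", "count"),
                               min_trials = 10L) {
  se_method <- match.arg(se_method)
  tr <- counts@trials
  units <- counts@units
  tcs <- unique(tr$tc_id)
  out <- lapply(tcs, function(tc) {
    rows <- which(tr$tc_id == tc & tr$valid)
    if (length(rows) < min_trials) {
      stop("fewer than ", min_trials, " valid trials for target ", tc)
    }
    resp <- counts@resp[rows, , drop = FALSE]
    base <- counts@base[rows, , drop = FALSE]
    n_eff <- colSums(!is.na(resp) & !is.na(base))
    mu_r <- colMeans(resp, na.rm = TRUE)
    mu_b <- colMeans(base, na.rm = TRUE)
    sd_b <- apply(base, 2, sd, na.rm = TRUE)
    denom <- switch(se_method,
                    mean = sd_b * sqrt(2 / n_eff),
                    base_mean = sd_b / sqrt(n_eff),
                    count = sd_b)
    z <- (mu_r - mu_b) / denom
    degenerate <- !is.finite(z)
    z[degenerate] <- 0
    p_up <- pnorm(z, lower.tail = FALSE)
    p_down <- pnorm(z)
    label <- rep("NonR", length(z))
    label[p_up < alpha] <- "PosR"
    label[p_down < alpha] <- "NegR"
    label[degenerate] <- "NonR"
    is_tc_unit <- units$unit_id == tc
    label[is_tc_unit] <- "TC"
    q_up <- p.adjust(p_up[!is_tc_unit], method = "BH")
    q_down <- p.adjust(p_down[!is_tc_unit], method = "BH")
    label_fdr <- rep("NonR", length(z))
    label_fdr[!is_tc_unit][q_up < fdr_q] <- "PosR"
    label_fdr[!is_tc_unit][q_down < fdr_q] <- "NegR"
    label_fdr[degenerate] <- "NonR"
    label_fdr[is_tc_unit] <- "TC"
    data.frame(tc_id = tc, unit_id = units$unit_id, z = z,
               p_up = p_up, p_down = p_down, label = label,
               label_fdr = label_fdr, degenerate = degenerate,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Fit the response-scaling exponent
#'
#' Bins trials by the spike count of their stimulated target in the
#' conditioning window (1 to \code{max_bin} spikes per 132 ms), averages
#' the chosen category's count per bin, and fits an ordinary least-squares
#' line to log(mean count) versus log(target count). The slope is the
#' scaling exponent \code{h}.
#'
#' @param counts a \linkS4class{TrialCounts}.
#' @param classification output of [classifyResponders()] (not needed when
#'   \code{category_units} is supplied).
#' @param category category to aggregate (\code{"PosR"}, \code{"NegR"},
#'   \code{"NonR"}).
#' @param mode \code{"population"} (summed category count) or
#'   \code{"per-neuron"} (mean category count).
#' @param condition \code{"stim"} bins by the target's response count and
#'   aggregates response counts; \code{"base"} uses baseline counts.
#' @param max_bin largest target spike count binned (default 7).
#' @param use_fdr use the FDR-adjusted labels.
#' @param category_units optional explicit list (by tc_id) of unit ids to
#'   aggregate, overriding the classification.
#' @return list of class \code{"ScalingFit"}: \code{exponent}, \code{ci},
#'   \code{bins} (data.frame), \code{mode}, \code{condition}, \code{fit}.
#' @export
fitResponseScaling <- function(counts, classification = NULL,
                               category = "PosR",
                               mode = c("population", "per-neuron"),
                               condition = c("stim", "base"),
                               max_bin = 7L, use_fdr = FALSE,
                               category_units = NULL) {
  mode <- match.arg(mode)
  condition <- match.arg(condition)
  tr <- counts@trials
  units <- counts@units
  m <- if (condition == "stim") counts@resp else counts@base
  lab_col <- if (use_fdr) "label_fdr" else "label"
  tc_count <- numeric(nrow(tr))
  cat_count <- numeric(nrow(tr))
  for (tc in unique(tr$tc_id)) {
    rows <- which(tr$tc_id == tc & tr$valid)
    u_tc <- match(tc, units$unit_id)
    if (is.null(category_units)) {
      cl <- classification[classification$tc_id == tc, ]
      sel_units <- cl$unit_id[cl[[lab_col]] == category]
    } else {
      sel_units <- category_units[[as.character(tc)]]
    }
    sel <- match(setdiff(sel_units, units$unit_id[units$is_tc]),
                 units$unit_id)
    sel <- sel[!is.na(sel)]
    tc_count[rows] <- m[rows, u_tc]
    cat_count[rows] <- if (length(sel) == 0) NA else if (mode == "population")
      rowSums(m[rows, sel, drop = FALSE], na.rm = TRUE)
    else rowMeans(m[rows, sel, drop = FALSE], na.rm = TRUE)
  }
  keep <- !is.na(tc_count) & !is.na(cat_count) &
    tc_count >= 1 & tc_count <= max_bin
  bins <- stats::aggregate(cat_count[keep],
                           by = list(tc_count = tc_count[keep]), FUN = mean)
  names(bins)[2] <- "mean_count"
  bins$n_trials <- as.vector(table(factor(tc_count[keep],
                                          levels = bins$tc_count)))
  bins <- bins[bins$mean_count > 0, , drop = FALSE]
  if (nrow(bins) < 3) {
    stop("insufficient range: fewer than 3 usable target-count bins")
  }
  fit <- lm(log(mean_count) ~ log(tc_count), data = bins)
  ci <- tryCatch(suppressWarnings(unname(confint(fit)[2, ])),
                 error = function(e) rep(unname(coef(fit)[2]), 2))
  structure(list(exponent = unname(coef(fit)[2]),
                 ci = ci,
                 bins = bins, mode = mode, condition = condition,
                 category = category, fit = fit),
            class = "ScalingFit")
}

#' @export
print.ScalingFit <- function(x, ...) {
  cat("Response-scaling fit (", x$category, ", ", x$mode, ", ",
      x$condition, "):\n", sep = "")
  cat("  exponent h =", signif(x$exponent, 3),
      " 95% CI [", signif(x$ci[1], 3), ",", signif(x$ci[2], 3), "]\n")
  cat("  bins used:", nrow(x$bins), "\n")
  invisible(x)
}

#' Window auto- and cross-correlations
#'
#' Pearson correlations across trials between temporally lagged window
#' counts: per unit, (base-prime, base) and (base, response); and per
#' target, the cross-correlation between the target's count and each
#' category's population count, separately for baseline and stimulation.
#'
#' @param counts a \linkS4class{TrialCounts}.
#' @param classification output of [classifyResponders()].
#' @return list with \code{unit_autocorr} and \code{tc_crosscorr}
#'   data.frames; zero-variance series give \code{NA}.
#' @export
trialCorrelations <- function(counts, classification = NULL) {
  safe_cor <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])
  }
  units <- counts@units
  n_u <- nrow(units)
  unit_autocorr <- data.frame(
    unit_id = units$unit_id,
    r_bprime_base = vapply(seq_len(n_u), function(j)
      safe_cor(counts@basePrime[, j], counts@base[, j]), 0),
    r_base_resp = vapply(seq_len(n_u), function(j)
      safe_cor(counts@base[, j], counts@resp[, j]), 0))
  tc_crosscorr <- NULL
  if (!is.null(classification)) {
    tr <- counts@trials
    rows_list <- split(seq_len(nrow(tr)), tr$tc_id)
    recs <- list()
    for (tc in names(rows_list)) {
      rows <- rows_list[[tc]]
      u_tc <- match(as.integer(tc), units$unit_id)
      cl <- classification[classification$tc_id == as.integer(tc), ]
      for (cat_lab in c("PosR", "NegR", "NonR")) {
        sel <- match(cl$unit_id[cl$label == cat_lab], units$unit_id)
        sel <- setdiff(sel, which(units$is_tc))
        if (!length(sel)) next
        for (cond in c("base", "stim")) {
          m <- if (cond == "stim") counts@resp else counts@base
          recs[[length(recs) + 1L]] <- data.frame(
            tc_id = as.integer(tc), category = cat_lab, condition = cond,
            r = safe_cor(m[rows, u_tc],
                         rowSums(m[rows, sel, drop = FALSE], na.rm = TRUE)))
        }
      }
    }
    tc_crosscorr <- do.call(rbind, recs)
  }
  list(unit_autocorr = unit_autocorr, tc_crosscorr = tc_crosscorr)
}

#' Fano factors with optional rate matching
#'
#' The Fano factor is the variance-to-mean ratio of trial spike counts.
#' With \code{rate_matched = TRUE} the response window length is varied
#' from 1 to 9 frames (starting at onset) and the length minimizing the
#' normalized rate difference to baseline is used; units whose minimum
#' mismatch exceeds 20\% are excluded.
#'
#' @param se a frame-resolution \linkS4class{SpikeExperiment}.
#' @param windows a [windowSpec()].
#' @param rate_matched logical; match response rate to baseline.
#' @param tc_id restrict to trials of one target (default: all trials).
#' @param max_mismatch exclusion threshold on the normalized rate
#'   difference (0.20).
#' @param min_trials minimum number of trials (10).
#' @return data.frame per unit: \code{ff_base}, \code{ff_resp},
#'   \code{matched_window}, \code{mismatch}, \code{excluded}.
#' @export
fanoFactor <- function(se, windows = windowSpec(), rate_matched = FALSE,
                       tc_id = NULL, max_mismatch = 0.20,
                       min_trials = 10L) {
  cts <- spikeCounts(se)
  tr <- trialTable(se)
  if (!is.null(tc_id)) tr <- tr[tr$tc_id == tc_id, , drop = FALSE]
  stopifnot(nrow(tr) >= min_trials)
  n_u <- nrow(cts)
  win_counts <- function(offsets) {
    out <- matrix(0, nrow(tr), n_u)
    for (i in seq_len(nrow(tr))) {
      idx <- tr$onset_frame[i] + offsets
      idx <- idx[idx >= 1 & idx <= ncol(cts)]
      out[i, ] <- rowSums(cts[, idx, drop = FALSE])
    }
    out
  }
  ff <- function(x) {
    m <- mean(x)
    if (m == 0) NA_real_ else var(x) / m
  }
  base <- win_counts(windows$base)
  mu_base <- colMeans(base)
  ff_base <- apply(base, 2, ff)
  if (!rate_matched) {
    resp <- win_counts(windows$resp)
    res <- data.frame(unit_id = SummarizedExperiment::rowData(se)$unit_id,
                      ff_base = ff_base, ff_resp = apply(resp, 2, ff),
                      matched_window = windows$len, mismatch = NA_real_,
                      excluded = FALSE)
    return(res)
  }
  resp_by_w <- lapply(1:9, function(w) win_counts(seq_len(w) - 1L))
  matched_window <- integer(n_u)
  mismatch <- numeric(n_u)
  ff_resp <- numeric(n_u)
  for (j in seq_len(n_u)) {
    ## choose the response window whose raw mean count best matches the
    ## 6-frame baseline mean
    mm <- vapply(1:9, function(w) {
      mu_w <- mean(resp_by_w[[w]][, j])
      if (mu_base[j] == 0) Inf
      else abs(mu_w - mu_base[j]) / mu_base[j]
    }, 0)
    w_star <- which.min(mm)
    matched_window[j] <- w_star
    mismatch[j] <- mm[w_star]
    ff_resp[j] <- ff(resp_by_w[[w_star]][, j])
  }
  excluded <- !is.finite(mismatch) | mismatch > max_mismatch
  ff_resp[excluded] <- NA_real_
  data.frame(unit_id = SummarizedExperiment::rowData(se)$unit_id,
             ff_base = ff_base, ff_resp = ff_resp,
             matched_window = matched_window, mismatch = mismatch,
             excluded = excluded)
}

#' Stratify trials
#'
#' Partitions trials four ways, for reuse by the other analyses:
#' \itemize{
#' \item \code{tc_split}: per target, "low" trials have a target response
#'   count strictly above the 91st (nearest-rank) percentile of the
#'   target's baseline counts and at most twice that value; "high" trials
#'   exceed twice that value (sub-threshold trials are unassigned).
#' \item \code{pop_split}: trials below the 25th / above the 75th
#'   percentile of the population (non-target) baseline count.
#' \item \code{regime}: LOW/HIGH by comparing the per-unit mean baseline
#'   count against the threshold \code{theta} (spikes per unit per 132 ms).
#' \item \code{early_late}: the two consecutive 6-frame windows centred on
#'   the peak of the targets' mean response (a window definition, returned
#'   as frame offsets relative to onset).
#' }
#' Strata with fewer than \code{min_trials} trials are returned empty.
#'
#' @param counts a \linkS4class{TrialCounts}.
#' @param se the originating \linkS4class{SpikeExperiment} (needed for the
#'   early/late peak estimate; optional).
#' @param theta regime threshold in spikes per unit per window (0.3).
#' @param percentile target-count percentile (0.91).
#' @param min_trials minimum stratum size (5).
#' @return list with \code{tc_split}, \code{pop_split}, \code{regime},
#'   \code{early_late}.
#' @export
stratifyTrials <- function(counts, se = NULL, theta = 0.3,
                           percentile = 0.91, min_trials = 5L) {
  tr <- counts@trials
  units <- counts@units
  non_tc <- which(!units$is_tc)

  check <- function(idx) if (length(idx) < min_trials) integer(0) else idx

  ## per-target split by evoked target count
  lows <- integer(0); highs <- integer(0)
  for (tc in unique(tr$tc_id)) {
    rows <- which(tr$tc_id == tc)
    u <- match(tc, units$unit_id)
    q <- nearestRankQuantile(counts@base[rows, u], percentile)
    cnt <- counts@resp[rows, u]
    lows <- c(lows, rows[!is.na(cnt) & cnt > q & cnt <= 2 * q])
    highs <- c(highs, rows[!is.na(cnt) & cnt > 2 * q])
  }
  tc_split <- list(low = check(sort(lows)), high = check(sort(highs)))
  if (!length(tc_split$low) && !length(tc_split$high)) {
    warning("target-count split degenerate: strata empty")
  }

  pop_base <- rowSums(counts@base[, non_tc, drop = FALSE], na.rm = TRUE)
  q25 <- quantile(pop_base, 0.25); q75 <- quantile(pop_base, 0.75)
  pop_split <- list(low = check(which(pop_base < q25)),
                    high = check(which(pop_base > q75)))
  if (q25 == q75) warning("population-baseline quartiles degenerate")

  rate <- pop_base / length(non_tc)
  regime <- list(low = check(which(rate < theta)),
                 high = check(which(rate >= theta)))

  early_late <- NULL
  if (!is.null(se)) {
    cts <- spikeCounts(se)
    ids <- SummarizedExperiment::rowData(se)$unit_id
    prof <- rep(0, 9)
    for (i in seq_len(nrow(tr))) {
      u <- match(tr$tc_id[i], ids)
      idx <- tr$onset_frame[i] + 0:8
      idx <- idx[idx <= ncol(cts)]
      prof[seq_along(idx)] <- prof[seq_along(idx)] + cts[u, idx]
    }
    peak <- which.max(prof) - 1L  # offset from onset
    early_late <- list(early = (peak - 5L):peak, late = (peak + 1L):(peak + 6L))
  }
  list(tc_split = tc_split, pop_split = pop_split, regime = regime,
       early_late = early_late)
}
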