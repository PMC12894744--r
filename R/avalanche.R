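## Neuronal-avalanche statistics: soft-thresholding, temporal
## coarse-graining, epoch extraction and size-duration scaling.

#' Population activity trace
#'
#' Sums the frame-resolution spike counts over all units except the
#' excluded set (conventionally the target cells).
#'
#' @param se a frame-resolution \linkS4class{SpikeExperiment}, or a
#'   units x time count matrix.
#' @param exclude_ids unit ids excluded from the sum (for a plain matrix,
#'   row indices).
#' @return integer vector \code{p(t)}.
#' @export
populationActivity <- function(se, exclude_ids = integer(0)) {
  if (is(se, "SpikeExperiment")) {
    cts <- spikeCounts(se)
    ids <- SummarizedExperiment::rowData(se)$unit_id
    keep <- !(ids %in% exclude_ids)
  } else {
    cts <- as.matrix(se)
    keep <- !(seq_len(nrow(cts)) %in% exclude_ids)
  }
  as.integer(colSums(cts[keep, , drop = FALSE]))
}

#' Soft-threshold a population trace
#'
#' Subtracts the threshold and zeroes sub-threshold bins:
#' \code{p_T(t) = p(t) - T} where \code{p(t) > T}, else 0.
#'
#' @param p population activity vector.
#' @param theta threshold (>= 0).
#' @return thresholded vector, same length.
#' @export
softThreshold <- function(p, theta) {
  stopifnot(theta >= 0)
  ifelse(p > theta, p - theta, 0)
}

#' Temporal coarse-graining ensemble
#'
#' For factor \code{k}, builds \code{k} offset series, each summing blocks
#' of \code{k} consecutive bins starting at offsets \code{0..k-1}.
#' Incomplete trailing blocks are dropped; \code{k = 1} reproduces the
#' input.
#'
#' @param p_theta thresholded population activity.
#' @param k coarse-graining factor (>= 1).
#' @return list of class \code{"CoarseGrainedEnsemble"} with \code{k} and
#'   \code{series} (list of numeric vectors).
#' @export
coarseGrain <- function(p_theta, k) {
  k <- as.integer(k)
  stopifnot(k >= 1)
  T_len <- length(p_theta)
  series <- lapply(0:(k - 1L), function(j) {
    n_blocks <- (T_len - j) %/% k
    if (n_blocks < 1) return(numeric(0))
    idx <- j + seq_len(n_blocks * k)
    colSums(matrix(p_theta[idx], nrow = k))
  })
  structure(list(k = k, series = series),
            class = "CoarseGrainedEnsemble")
}

## epochs of one series: maximal positive runs strictly bracketed by zeros
extractEpochsOne <- function(x) {
  if (!length(x)) {
    return(data.frame(tau1 = integer(0), tau2 = integer(0),
                      size = numeric(0), duration = integer(0)))
  }
  pos <- x > 0
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values &
                  starts > 1L &       # zero bin before
                  ends < length(x))   # zero bin after
  if (!length(keep)) {
    return(data.frame(tau1 = integer(0), tau2 = integer(0),
                      size = numeric(0), duration = integer(0)))
  }
  tau1 <- starts[keep] - 1L  # bracketing zeros
  tau2 <- ends[keep] + 1L
  size <- vapply(keep, function(i) sum(x[starts[i]:ends[i]]), 0)
  data.frame(tau1 = tau1, tau2 = tau2, size = size,
             duration = tau2 - tau1 - 1L)
}

#' Extract avalanche epochs
#'
#' Finds, in every coarse-grained offset series, maximal runs of positive
#' bins strictly bracketed by zero bins. Each epoch's size is the sum of
#' its bins and its duration the number of positive bins
#' (\code{tau2 - tau1 - 1} with \code{tau1}, \code{tau2} the bracketing
#' zero bins). Epochs from all offsets are pooled.
#'
#' @param ensemble a [coarseGrain()] ensemble, or a plain numeric vector
#'   (treated as \code{k = 1}).
#' @return data.frame of class \code{"AvalancheCatalog"} with \code{k},
#'   \code{offset}, \code{tau1}, \code{tau2}, \code{size},
#'   \code{duration}.
#' @export
extractAvalanches <- function(ensemble) {
  if (is.numeric(ensemble)) ensemble <- coarseGrain(ensemble, 1L)
  out <- lapply(seq_along(ensemble$series), function(j) {
    ep <- extractEpochsOne(ensemble$series[[j]])
    if (nrow(ep)) cbind(k = ensemble$k, offset = j - 1L, ep)
    else cbind(ep, k = integer(0), offset = integer(0))[, c("k", "offset",
                                                            "tau1", "tau2",
                                                            "size",
                                                            "duration")]
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(k = integer(0), offset = integer(0),
                      tau1 = integer(0), tau2 = integer(0),
                      size = numeric(0), duration = integer(0))
  }
  class(res) <- c("AvalancheCatalog", "data.frame")
  res
}

#' Threshold selection from the epoch-count profile
#'
#' Counts epochs \code{N(T)} over a scan of thresholds from one that
#' removes no activity to one that removes all, fits a log-normal shape
#' \code{N(T) = A exp(-(log T - mu)^2 / (2 s^2))} by least squares, and
#' returns the threshold at the fitted location. With
#' \code{location = "median"} (default) the threshold is \code{exp(mu)},
#' the fitted distribution's location expressed in threshold units; with
#' \code{"logmean"} the raw log-space location \code{mu} is returned
#' as-is. If the fit fails, the threshold maximizing \code{N(T)} is used
#' and flagged.
#'
#' @param p population activity vector.
#' @param k coarse-graining factor at which epochs are counted.
#' @param n_scan number of log-spaced thresholds (default 64).
#' @param location interpretation of the fitted location parameter.
#' @return list with \code{theta}, \code{fit} (parameters or \code{NULL}),
#'   \code{scan} (data.frame of \code{theta}, \code{n_epochs}) and
#'   \code{fallback} flag.
#' @export
estimateThreshold <- function(p, k = 1L, n_scan = 64L,
                              location = c("median", "logmean")) {
  location <- match.arg(location)
  pos <- p[p > 0]
  if (!length(pos)) stop("population activity is identically zero")
  ## theta_1 removes nothing (below min positive), theta_2 removes all
  th1 <- min(pos) * 0.5
  th2 <- max(p)
  thetas <- exp(seq(log(th1), log(th2), length.out = n_scan))
  thetas[n_scan] <- th2  # exact endpoint: removes all activity
  n_epochs <- vapply(thetas, function(th) {
    nrow(extractAvalanches(coarseGrain(softThreshold(p, th), k)))
  }, 0L)
  scan <- data.frame(theta = thetas, n_epochs = n_epochs)
  fitThresholdScan(scan, location)
}

## least-squares log-normal fit to an epoch-count profile N(theta);
## factored out so the fitting step can be exercised on synthetic scans
fitThresholdScan <- function(scan, location = c("median", "logmean")) {
  location <- match.arg(location)
  start <- list(A = max(scan$n_epochs),
                mu = log(scan$theta[which.max(scan$n_epochs)]),
                s = diff(range(log(scan$theta))) / 4)
  fit <- try(minpack.lm::nlsLM(
    n_epochs ~ A * exp(-(log(theta) - mu)^2 / (2 * s^2)),
    data = scan, start = start,
    lower = c(A = 0, mu = log(min(scan$theta)) - 5, s = 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    silent = TRUE)
  if (inherits(fit, "try-error") || var(scan$n_epochs) == 0) {
    return(list(theta = scan$theta[which.max(scan$n_epochs)], fit = NULL,
                scan = scan, fallback = TRUE))
  }
  cf <- coef(fit)
  theta <- if (location == "median") exp(cf[["mu"]]) else cf[["mu"]]
  list(theta = unname(theta),
       fit = list(A = cf[["A"]], mu = cf[["mu"]], s = cf[["s"]]),
       scan = scan, fallback = FALSE)
}

#' Mean avalanche size versus duration
#'
#' @param catalog an [extractAvalanches()] catalog.
#' @return data.frame with \code{duration}, \code{mean_size}, \code{n}
#'   and \code{se}.
#' @export
sizeDurationScaling <- function(catalog) {
  stopifnot(nrow(catalog) > 0)
  sp <- split(catalog$size, catalog$duration)
  data.frame(duration = as.numeric(names(sp)),
             mean_size = vapply(sp, mean, 0),
             n = lengths(sp),
             se = vapply(sp, function(x)
               if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_, 0),
             row.names = NULL)
}

#' Fit the double power-law scaling curve
#'
#' Fits, in log space, \code{S(d) = C d^chi_sh /
#' (1 + (d / Phi)^gamma)^((chi_sh - chi_lg) / gamma)}: an initial slope
#' \code{chi_sh} transitioning to \code{chi_lg} around \code{d = Phi},
#' with transition sharpness \code{gamma} fixed at 4. A parabolic initial
#' slope (\code{chi_sh} near 2) is the hallmark of critical cascades. On
#' non-convergence a single power law is fitted and flagged.
#'
#' @param table output of [sizeDurationScaling()].
#' @param gamma transition sharpness (fixed, default 4).
#' @param min_durations minimum distinct durations required (6).
#' @return list of class \code{"ScalingCurveFit"}: \code{C},
#'   \code{chi_sh}, \code{chi_lg}, \code{Phi}, \code{gamma},
#'   \code{residuals}, \code{fallback}.
#' @export
fitDoublePowerLaw <- function(table, gamma = 4, min_durations = 6L) {
  tb <- table[table$mean_size > 0 & table$duration > 0, , drop = FALSE]
  if (nrow(tb) < min_durations) {
    stop("need at least ", min_durations, " distinct durations")
  }
  ld <- log(tb$duration); ls <- log(tb$mean_size)
  ## starting values: slopes of the lower/upper halves
  lower <- ld <= median(ld); upper <- !lower
  s1 <- if (sum(lower) >= 2) unname(coef(lm(ls[lower] ~ ld[lower]))[2]) else 2
  s2 <- if (sum(upper) >= 2) unname(coef(lm(ls[upper] ~ ld[upper]))[2]) else 1
  if (!is.finite(s1)) s1 <- 2
  if (!is.finite(s2)) s2 <- 1
  start <- list(logC = unname(ls[1] - s1 * ld[1]), chi_sh = s1,
                chi_lg = s2, logPhi = median(ld))
  dat <- data.frame(ld = ld, ls = ls)
  fit <- try(minpack.lm::nlsLM(
    ls ~ logC + chi_sh * ld -
      ((chi_sh - chi_lg) / gamma) * log(1 + exp(gamma * (ld - logPhi))),
    data = dat, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500)),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    sf <- lm(ls ~ ld)
    return(structure(list(C = exp(unname(coef(sf)[1])),
                          chi_sh = unname(coef(sf)[2]),
                          chi_lg = unname(coef(sf)[2]),
                          Phi = NA_real_, gamma = gamma,
                          residuals = unname(residuals(sf)),
                          fallback = TRUE),
                     class = "ScalingCurveFit"))
  }
  cf <- coef(fit)
  structure(list(C = exp(cf[["logC"]]), chi_sh = cf[["chi_sh"]],
                 chi_lg = cf[["chi_lg"]], Phi = exp(cf[["logPhi"]]),
                 gamma = gamma, residuals = unname(residuals(fit)),
                 fallback = FALSE),
            class = "ScalingCurveFit")
}

#' @export
print.ScalingCurveFit <- function(x, ...) {
  cat("Size-duration scaling fit:\n")
  cat("  chi_sh =", signif(x$chi_sh, 3), " chi_lg =", signif(x$chi_lg, 3),
      " Phi =", signif(x$Phi, 3), " (gamma fixed at", x$gamma, ")\n")
  if (x$fallback) cat("  [single power-law fallback]\n")
  invisible(x)
}

#' Full avalanche analysis of a population trace
#'
#' Convenience wrapper: estimates the threshold per coarse-graining
#' factor, extracts avalanches and fits the scaling curve on the pooled
#' catalog of each factor.
#'
#' @param p population activity vector.
#' @param k_values coarse-graining factors (default \code{c(1, 2, 4, 8,
#'   16)}).
#' @param theta optional fixed threshold (skips estimation).
#' @return list with per-factor \code{catalogs}, \code{thresholds}, the
#'   pooled \code{scaling} tables and \code{fits}.
#' @export
avalancheAnalysis <- function(p, k_values = c(1L, 2L, 4L, 8L, 16L),
                              theta = NULL) {
  res <- lapply(k_values, function(k) {
    th <- if (is.null(theta)) estimateThreshold(p, k)$theta else theta
    cat_k <- extractAvalanches(coarseGrain(softThreshold(p, th), k))
    list(k = k, theta = th, catalog = cat_k)
  })
  catalogs <- do.call(rbind, lapply(res, `[[`, "catalog"))
  class(catalogs) <- c("AvalancheCatalog", "data.frame")
  fits <- lapply(res, function(r) {
    if (nrow(r$catalog) == 0) return(NULL)
    tab <- sizeDurationScaling(r$catalog)
    if (nrow(tab) >= 6) fitDoublePowerLaw(tab) else NULL
  })
  list(catalogs = catalogs,
       thresholds = vapply(res, `[[`, 0, "theta"),
       k_values = k_values,
       scaling = lapply(res, function(r)
         if (nrow(r$catalog)) sizeDurationScaling(r$catalog) else NULL),
       fits = fits)
}
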