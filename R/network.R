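## Network construction: 2D excitable lattice with distance-dependent
## connectivity, transmission probabilities and structural measures.

#' Lattice specification
#'
#' Describes the geometry of the excitable lattice. The default mirrors the
#' reference configuration: a 300 x 300 torus at 12 um spacing. The
#' connection-probability kernel integrated over an infinite sheet yields a
#' mean degree near 132; a distance cutoff is therefore exposed and, when
#' \code{cutoff_radius = "calibrated"}, solved numerically so that the
#' analytic expected out-degree matches \code{kbar_target} (about 43 by
#' default, reached near a 245 um cutoff).
#'
#' @param n_rows,n_cols lattice dimensions (>= 3).
#' @param spacing lattice spacing in micrometres (> 0).
#' @param periodic logical; use periodic (torus) boundaries.
#' @param cutoff_radius \code{"calibrated"}, \code{"none"}, or a radius in um
#'   beyond which the connection probability is set to zero.
#' @param kbar_target target mean out-degree used when
#'   \code{cutoff_radius = "calibrated"}.
#' @return a named list of class \code{"LatticeSpec"}.
#' @examples
#' sp <- latticeSpec(20, 20)
#' @export
latticeSpec <- function(n_rows = 300L, n_cols = 300L, spacing = 12,
                        periodic = TRUE, cutoff_radius = "calibrated",
                        kbar_target = 43) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 3L, n_cols >= 3L, spacing > 0)
  if (is.character(cutoff_radius)) {
    cutoff_radius <- match.arg(cutoff_radius, c("calibrated", "none"))
  } else {
    stopifnot(is.numeric(cutoff_radius), cutoff_radius > 0)
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, spacing = spacing,
                 periodic = periodic, cutoff_radius = cutoff_radius,
                 kbar_target = kbar_target),
            class = "LatticeSpec")
}

#' Distance-dependent connection probability
#'
#' Probability that an ordered pair of units at distance \code{r} is
#' connected: the sum of a short-range Gaussian component (amplitude 0.05,
#' 100 um characteristic decay) and a long-range exponential component
#' (amplitude 0.03, 290 um characteristic decay). Beyond
#' \code{cutoff_radius} the probability is zero.
#'
#' @param r non-negative distance(s) in micrometres.
#' @param cutoff_radius numeric cutoff in um, or \code{Inf} for none.
#' @return probability vector, same length as \code{r}.
#' @examples
#' connectionProbability(0)    # 0.08
#' connectionProbability(100)
#' @export
connectionProbability <- function(r, cutoff_radius = Inf) {
  if (any(r < 0)) stop("distances must be non-negative")
  p <- 0.05 * exp(-r^2 / (2 * 100^2)) + 0.03 * exp(-r / 290)
  p[r > cutoff_radius] <- 0
  p
}

## Minimal-image offset distances of the lattice, um. Returns the distance
## from a unit to every other unit (one value per non-zero offset).
latticeOffsetDistances <- function(spec) {
  ox <- 0:(spec$n_rows - 1L)
  oy <- 0:(spec$n_cols - 1L)
  if (spec$periodic) {
    mx <- pmin(ox, spec$n_rows - ox)
    my <- pmin(oy, spec$n_cols - oy)
    d <- sqrt(outer(mx^2, my^2, "+")) * spec$spacing
    d[-1L]  # drop the (0, 0) offset
  } else {
    stop("offset distances are only defined for periodic lattices")
  }
}

#' Analytic expected mean out-degree
#'
#' Sums the connection probability over all minimal-image lattice offsets,
#' giving the exact expectation of the out-degree of every unit on a
#' periodic lattice. Serves as the oracle against which realized degrees and
#' the cutoff calibration are checked.
#'
#' @param spec a [latticeSpec()].
#' @param cutoff_radius cutoff in um (\code{Inf} for none).
#' @return expected out-degree (scalar).
#' @export
expectedMeanDegree <- function(spec, cutoff_radius = Inf) {
  d <- latticeOffsetDistances(spec)
  sum(connectionProbability(d, cutoff_radius))
}

#' Calibrate the connectivity cutoff radius
#'
#' Solves for the distance cutoff at which the analytic expected out-degree
#' equals \code{kbar_target}. The expected degree is a decreasing step
#' function of the cutoff over the discrete set of lattice distances; the
#' returned radius is the midpoint between the last included and first
#' excluded distance shell.
#'
#' @param spec a [latticeSpec()].
#' @param kbar_target target mean out-degree.
#' @return cutoff radius in um.
#' @export
calibrateCutoff <- function(spec, kbar_target = spec$kbar_target) {
  d <- sort(latticeOffsetDistances(spec))
  csum <- cumsum(connectionProbability(d))
  if (kbar_target > csum[length(csum)]) {
    stop("kbar_target exceeds the uncut expected degree (",
         round(csum[length(csum)], 1), ")")
  }
  i <- which(csum >= kbar_target)[1L]
  if (i == length(d)) return(d[i])
  (d[i] + d[i + 1L]) / 2
}

resolveCutoff <- function(spec) {
  if (identical(spec$cutoff_radius, "none")) return(Inf)
  if (identical(spec$cutoff_radius, "calibrated")) return(calibrateCutoff(spec))
  spec$cutoff_radius
}

#' Build a lattice network
#'
#' Samples a directed edge for every ordered pair of units independently
#' with probability [connectionProbability()] of their (minimal-image, if
#' periodic) distance. Identical seeds give identical edge sets.
#'
#' @param spec a [latticeSpec()].
#' @param seed integer RNG seed.
#' @param conn_fun optional replacement for the connection-probability
#'   kernel, a function of distance in um returning probabilities (used by
#'   degenerate test constructions; the default kernel is used when
#'   \code{NULL}).
#' @return a \linkS4class{LatticeNetwork}.
#' @examples
#' net <- buildNetwork(latticeSpec(10, 10, cutoff_radius = 30), seed = 1)
#' meanDegree(net)
#' @export
buildNetwork <- function(spec, seed = 1L, conn_fun = NULL) {
  stopifnot(inherits(spec, "LatticeSpec"))
  cutoff <- resolveCutoff(spec)
  n <- spec$n_rows * spec$n_cols
  set.seed(seed)
  if (is.null(conn_fun)) {
    el <- cpp_sample_lattice_edges(spec$n_rows, spec$n_cols, spec$spacing,
                                   spec$periodic, cutoff,
                                   0.05, 100, 0.03, 290)
    from <- el$from; to <- el$to
  } else {
    ## generic (test) path: explicit pairwise sampling in R
    pos <- latticePositions(spec)
    from <- integer(0); to <- integer(0)
    for (i in seq_len(n)) {
      d <- torusDistance(pos[i, 1], pos[i, 2], pos[, 1], pos[, 2], spec)
      p <- conn_fun(d)
      p[i] <- 0
      p[d > cutoff] <- 0
      hit <- which(runif(n) < p)
      from <- c(from, rep.int(i, length(hit)))
      to <- c(to, hit)
    }
  }
  newLatticeNetwork(spec, from, to, seed)
}

latticePositions <- function(spec) {
  idx <- seq_len(spec$n_rows * spec$n_cols) - 1L
  cbind(x_um = (idx %% spec$n_cols) * spec$spacing,
        y_um = (idx %/% spec$n_cols) * spec$spacing)
}

## Pairwise distance honouring periodic minimal-image convention.
torusDistance <- function(x1, y1, x2, y2, spec) {
  dx <- abs(x1 - x2); dy <- abs(y1 - y2)
  if (spec$periodic) {
    wx <- spec$n_cols * spec$spacing
    wy <- spec$n_rows * spec$spacing
    dx <- pmin(dx, wx - dx)
    dy <- pmin(dy, wy - dy)
  }
  sqrt(dx^2 + dy^2)
}

newLatticeNetwork <- function(spec, from, to, seed) {
  n <- spec$n_rows * spec$n_cols
  A <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(n, n))
  ## CSR out-edge index for the compiled stepper (0-based)
  ord <- order(from)
  col_idx <- as.integer(to[ord] - 1L)
  row_ptr <- c(0L, cumsum(tabulate(from, nbins = n)))
  obj <- new("LatticeNetwork",
             adjacency = A,
             positions = latticePositions(spec),
             spec = unclass(spec),
             outIndex = list(row_ptr = as.integer(row_ptr),
                             col_idx = col_idx),
             kbar = length(from) / n,
             seed = as.integer(seed))
  validObject(obj)
  obj
}

#' Build a network from an explicit edge list
#'
#' Constructs a \linkS4class{LatticeNetwork} from given directed edges,
#' bypassing the distance-dependent sampling. Intended for controlled
#' topologies (chains, stars, trees) in analyses and tests; the lattice
#' spec is a nominal 1-row geometry unless positions are supplied.
#'
#' @param from,to integer vectors of edge endpoints (1-based).
#' @param n_units number of units.
#' @param positions optional units x 2 coordinate matrix (um).
#' @return a \linkS4class{LatticeNetwork}.
#' @export
networkFromEdges <- function(from, to, n_units, positions = NULL) {
  stopifnot(length(from) == length(to), all(from >= 1), all(to >= 1),
            all(from <= n_units), all(to <= n_units), all(from != to))
  spec <- list(n_rows = 1L, n_cols = as.integer(n_units), spacing = 1,
               periodic = FALSE, cutoff_radius = "none", kbar_target = NA)
  obj <- newLatticeNetwork(structure(spec, class = "LatticeSpec"),
                           as.integer(from), as.integer(to), 0L)
  if (!is.null(positions)) obj@positions <- as.matrix(positions)
  obj
}

#' Transmission probability from the branching parameter
#'
#' Per-edge spike transmission probability \code{sigma / k_bar}, where
#' \code{sigma} is the branching parameter (the expected number of
#' immediately downstream spikes per spike) and \code{k_bar} the mean
#' out-degree.
#'
#' @param sigma branching parameter (>= 0).
#' @param k_bar mean out-degree (> 0).
#' @return probability in \[0, 1\].
#' @examples
#' transmissionProbability(1.0066, 43)
#' @export
transmissionProbability <- function(sigma, k_bar) {
  stopifnot(sigma >= 0, k_bar > 0)
  p <- sigma / k_bar
  if (p > 1) stop("sigma / k_bar exceeds 1: not a valid probability")
  p
}

#' Structural output strength
#'
#' Expected number of downstream spikes per source spike considering network
#' structure only (no refractoriness or collisions): row sums of the matrix
#' power series \code{sum_{o=1..max_order} (p_trans * A)^o}. Orders above 5
#' contribute negligibly for transmission probabilities of interest.
#'
#' @param network a \linkS4class{LatticeNetwork}.
#' @param p_trans per-edge transmission probability in \[0, 1\].
#' @param max_order highest path order included (>= 1).
#' @return numeric vector of per-unit output strengths.
#' @export
outputStrength <- function(network, p_trans, max_order = 5L) {
  stopifnot(p_trans >= 0, p_trans <= 1, max_order >= 1)
  A <- adjacency(network) * p_trans
  n <- nrow(A)
  ones <- rep(1, n)
  os <- numeric(n)
  v <- ones
  for (o in seq_len(max_order)) {
    v <- as.numeric(A %*% v)  # A^o %*% 1
    os <- os + v
  }
  os
}

## ---- accessors / methods ---------------------------------------------

#' @rdname LatticeNetwork-class
#' @export
setMethod("adjacency", "LatticeNetwork", function(object) object@adjacency)

#' @rdname LatticeNetwork-class
#' @export
setMethod("positions", "LatticeNetwork", function(object) object@positions)

#' @rdname LatticeNetwork-class
#' @export
setMethod("meanDegree", "LatticeNetwork", function(object) object@kbar)

#' @rdname LatticeNetwork-class
#' @export
setMethod("outDegree", "LatticeNetwork", function(object) {
  diff(object@outIndex$row_ptr)
})

setMethod("show", "LatticeNetwork", function(object) {
  sp <- object@spec
  cat("LatticeNetwork:", sp$n_rows, "x", sp$n_cols, "units at",
      sp$spacing, "um spacing",
      if (isTRUE(sp$periodic)) "(periodic)" else "(open)", "\n")
  cat("  edges:", length(object@outIndex$col_idx),
      " mean out-degree:", signif(object@kbar, 4), "\n")
  co <- sp$cutoff_radius
  cat("  cutoff:", if (is.numeric(co)) paste0(signif(co, 4), " um") else co,
      " seed:", object@seed, "\n")
})

## ---- I/O --------------------------------------------------------------

#' Write / read a network as plain-text files
#'
#' Serializes the edge list (\code{edges.csv}: source_id, target_id), unit
#' positions (\code{positions.csv}: unit_id, x_um, y_um) and a JSON header
#' (lattice spec, seed, realized mean degree) into a directory.
#'
#' @param network a \linkS4class{LatticeNetwork}.
#' @param dir output directory (created if missing).
#' @return \code{writeNetwork} returns \code{dir} invisibly;
#'   \code{readNetwork} returns the reconstructed
#'   \linkS4class{LatticeNetwork}.
#' @export
writeNetwork <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  A <- adjacency(network)
  el <- Matrix::summary(A)
  write.csv(data.frame(source_id = el$i, target_id = el$j),
            file.path(dir, "edges.csv"), row.names = FALSE)
  pos <- positions(network)
  write.csv(data.frame(unit_id = seq_len(nrow(pos)),
                       x_um = pos[, 1], y_um = pos[, 2]),
            file.path(dir, "positions.csv"), row.names = FALSE)
  hdr <- list(spec = network@spec, seed = network@seed, kbar = network@kbar)
  jsonlite::write_json(hdr, file.path(dir, "network.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "network.json"),
                             simplifyVector = TRUE)
  spec <- do.call(latticeSpec, hdr$spec[c("n_rows", "n_cols", "spacing",
                                          "periodic", "cutoff_radius",
                                          "kbar_target")])
  el <- read.csv(file.path(dir, "edges.csv"))
  newLatticeNetwork(spec, el$source_id, el$target_id,
                    as.integer(hdr$seed))
}
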