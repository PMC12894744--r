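#' Lattice network with distance-dependent connectivity
#'
#' An S4 container for a directed network of excitable units placed on a 2D
#' lattice. Edges are unweighted; every edge transmits independently with a
#' common probability during simulation. The adjacency matrix is stored
#' sparsely (\code{A[i, j] = 1} for an edge from unit \code{i} to unit
#' \code{j}), together with unit positions in micrometres and the realized
#' mean out-degree.
#'
#' @slot adjacency a \code{\link[Matrix]{dgCMatrix-class}} adjacency matrix,
#'   units x units, zero diagonal.
#' @slot positions numeric matrix (units x 2) of x/y coordinates in um.
#' @slot spec list with the lattice specification (\code{n_rows},
#'   \code{n_cols}, \code{spacing}, \code{periodic}, \code{cutoff_radius}).
#' @slot outIndex list with CSR out-edge index (\code{row_ptr},
#'   \code{col_idx}, both 0-based) used by the compiled stepper.
#' @slot kbar realized mean out-degree (edges / units).
#' @slot seed integer seed used to sample the edge set.
#'
#' @seealso [buildNetwork()], [outputStrength()], [meanDegree()]
#' @export
setClass("LatticeNetwork",
  representation(
    adjacency = "ANY",
    positions = "matrix",
    spec      = "list",
    outIndex  = "list",
    kbar      = "numeric",
    seed      = "integer"
  )
)

setValidity("LatticeNetwork", function(object) {
  A <- object@adjacency
  msg <- character()
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  if (nrow(object@positions) != nrow(A)) {
    msg <- c(msg, "positions must have one row per unit")
  }
  if (any(Matrix::diag(A) != 0)) msg <- c(msg, "self-edges are not allowed")
  if (length(msg)) msg else TRUE
})

#' Spike raster with trial metadata
#'
#' A \code{\link[SummarizedExperiment]{SummarizedExperiment}} subclass
#' holding a units x time matrix of spike counts, either at simulation step
#' resolution (2 ms, binary) or at imaging-frame resolution (22 ms, counts).
#' Row metadata carries unit positions and target-cell flags; the object
#' metadata carries the trial-onset table, the simulation configuration and
#' the time resolution.
#'
#' @seealso [SpikeExperiment()], [runExperiment()], [binToFrames()]
#' @export
setClass("SpikeExperiment", contains = "SummarizedExperiment")

setValidity("SpikeExperiment", function(object) {
  msg <- character()
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
  res <- S4Vectors::metadata(object)$resolution
  if (is.null(res) || !res %in% c("step", "frame")) {
    msg <- c(msg, "metadata()$resolution must be 'step' or 'frame'")
  }
  if (length(msg)) msg else TRUE
})

#' Per-trial baseline and response spike counts
#'
#' Trial-windowed spike counts for every recorded unit: the response window
#' (6 frames from stimulus onset, ~132 ms), the baseline window (6 frames
#' starting 12 frames, ~264 ms, before onset) and the pre-baseline window
#' ("base-prime", the 6 frames ending where the baseline begins). Rows are
#' trials, columns are units. The trial table carries the stimulated
#' target-cell identity per trial and a validity flag updated by
#' [removeOutlierTrials()].
#'
#' @slot resp,base,basePrime integer matrices, trials x units.
#' @slot trials data.frame with \code{trial_id}, \code{tc_id},
#'   \code{onset_frame} and \code{valid}.
#' @slot units data.frame with \code{unit_id}, \code{x_um}, \code{y_um},
#'   \code{is_tc}.
#' @slot windows list describing the three windows (frame offsets).
#'
#' @seealso [extractTrialCounts()], [classifyResponders()],
#'   [fitResponseScaling()]
#' @export
setClass("TrialCounts",
  representation(
    resp      = "matrix",
    base      = "matrix",
    basePrime = "matrix",
    trials    = "data.frame",
    units     = "data.frame",
    windows   = "list"
  )
)

setValidity("TrialCounts", function(object) {
  msg <- character()
  dims <- list(dim(object@resp), dim(object@base), dim(object@basePrime))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1) {
    msg <- c(msg, "resp, base and basePrime must share dimensions")
  }
  if (nrow(object@resp) != nrow(object@trials)) {
    msg <- c(msg, "one trial row per count row required")
  }
  if (ncol(object@resp) != nrow(object@units)) {
    msg <- c(msg, "one unit row per count column required")
  }
  if (any(object@resp < 0) || any(object@base < 0)) {
    msg <- c(msg, "counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})
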