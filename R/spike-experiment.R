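## SpikeExperiment: construction, accessors and experiment-bundle I/O.

#' Construct a SpikeExperiment
#'
#' @param counts units x time matrix of spike counts (step resolution:
#'   binary indicators at 2 ms; frame resolution: counts per imaging frame).
#' @param positions units x 2 matrix of coordinates in um.
#' @param is_tc logical vector flagging target cells.
#' @param trials data.frame with one row per stimulation trial
#'   (\code{trial_id}, \code{tc_id}, \code{onset_frame}, optionally
#'   \code{onset_step}).
#' @param resolution \code{"frame"} or \code{"step"}.
#' @param steps_per_frame simulation steps per imaging frame (11 by
#'   default: 2 ms steps, 22 ms frames).
#' @param config optional list of simulation/configuration metadata.
#' @param unit_ids optional unit identifiers (defaults to row numbers).
#' @return a \linkS4class{SpikeExperiment}.
#' @export
SpikeExperiment <- function(counts, positions = NULL, is_tc = NULL,
                            trials = NULL, resolution = c("frame", "step"),
                            steps_per_frame = 11L, config = list(),
                            unit_ids = NULL) {
  resolution <- match.arg(resolution)
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (is.null(positions)) positions <- cbind(x_um = rep(0, n), y_um = rep(0, n))
  if (is.null(is_tc)) is_tc <- rep(FALSE, n)
  if (is.null(unit_ids)) unit_ids <- seq_len(n)
  if (is.null(trials)) {
    trials <- data.frame(trial_id = integer(0), tc_id = integer(0),
                         onset_frame = integer(0))
  }
  rd <- S4Vectors::DataFrame(unit_id = unit_ids,
                             x_um = positions[, 1], y_um = positions[, 2],
                             is_tc = as.logical(is_tc))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd,
    metadata = list(trials = trials, resolution = resolution,
                    steps_per_frame = as.integer(steps_per_frame),
                    config = config))
  new("SpikeExperiment", se)
}

#' @rdname SpikeExperiment
#' @param object a \linkS4class{SpikeExperiment}
#' @export
setMethod("spikeCounts", "SpikeExperiment", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

#' @rdname SpikeExperiment
#' @export
setMethod("trialTable", "SpikeExperiment", function(object) {
  S4Vectors::metadata(object)$trials
})

#' @rdname SpikeExperiment
#' @export
setMethod("targetIds", "SpikeExperiment", function(object) {
  SummarizedExperiment::rowData(object)$unit_id[
    SummarizedExperiment::rowData(object)$is_tc]
})

setMethod("show", "SpikeExperiment", function(object) {
  md <- S4Vectors::metadata(object)
  cat("SpikeExperiment:", nrow(object), "units x", ncol(object),
      md$resolution, "bins\n")
  cat("  targets:", sum(SummarizedExperiment::rowData(object)$is_tc),
      " trials:", nrow(md$trials), "\n")
  cat("  total spikes:", sum(spikeCounts(object)), "\n")
})

unitPositions <- function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cbind(x_um = rd$x_um, y_um = rd$y_um)
}

#' Write / read an experiment bundle
#'
#' An experiment bundle is a directory of plain-text files:
#' \code{raster.csv} (unit_id in the first column, one column per time bin),
#' \code{trials.csv} (trial_id, tc_id, onset_frame, onset_step),
#' \code{positions.csv} (unit_id, x_um, y_um, is_tc) and \code{meta.json}
#' (resolution, steps per frame, configuration, seeds, calibrations).
#'
#' @param x a \linkS4class{SpikeExperiment}.
#' @param dir bundle directory.
#' @return \code{writeBundle} returns \code{dir} invisibly;
#'   \code{readBundle} the reconstructed \linkS4class{SpikeExperiment}.
#' @export
writeBundle <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rd <- SummarizedExperiment::rowData(x)
  cts <- spikeCounts(x)
  ras <- data.frame(unit_id = rd$unit_id, cts, check.names = FALSE)
  colnames(ras) <- c("unit_id", paste0("t", seq_len(ncol(cts))))
  write.csv(ras, file.path(dir, "raster.csv"), row.names = FALSE)
  write.csv(trialTable(x), file.path(dir, "trials.csv"), row.names = FALSE)
  write.csv(data.frame(unit_id = rd$unit_id, x_um = rd$x_um,
                       y_um = rd$y_um, is_tc = rd$is_tc),
            file.path(dir, "positions.csv"), row.names = FALSE)
  md <- S4Vectors::metadata(x)
  jsonlite::write_json(list(resolution = md$resolution,
                            steps_per_frame = md$steps_per_frame,
                            config = md$config),
                       file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname writeBundle
#' @export
readBundle <- function(dir) {
  md <- jsonlite::read_json(file.path(dir, "meta.json"),
                            simplifyVector = TRUE)
  ras <- read.csv(file.path(dir, "raster.csv"), check.names = FALSE)
  pos <- read.csv(file.path(dir, "positions.csv"))
  trials <- read.csv(file.path(dir, "trials.csv"))
  cts <- as.matrix(ras[, -1, drop = FALSE])
  storage.mode(cts) <- "integer"
  SpikeExperiment(cts,
                  positions = cbind(pos$x_um, pos$y_um),
                  is_tc = pos$is_tc, trials = trials,
                  resolution = md$resolution,
                  steps_per_frame = md$steps_per_frame,
                  config = if (is.null(md$config)) list() else md$config,
                  unit_ids = ras$unit_id)
}
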