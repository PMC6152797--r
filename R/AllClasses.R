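#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
NULL

.tu_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("tuChase_", class), "tuChase_error")))
}

.CHANNELS <- c("decay", "synthesis")

#' SimulationDesign: layout of a simulated 4TU-chase measurement
#'
#' Describes one simulated chase experiment: the chase timepoint grid, the
#' multiplicative lognormal measurement noise, the constant spike-in signal,
#' which channel is observed (the unlabeled flowthrough reporting decay, or
#' the labeled eluate reporting synthesis), and the random seed.
#'
#' @slot timepoints numeric, minutes since the 4TU pulse; strictly
#'   increasing, first element 0.
#' @slot noiseSigma standard deviation of the log of the multiplicative
#'   lognormal noise applied to every measurement (0 = noiseless).
#' @slot spikeLevel constant true signal of the spike-in row, > 0.
#' @slot channel `"decay"` or `"synthesis"`.
#' @slot seed integer seed used for all random draws of the simulation.
#' @slot poissonScale optional counting-noise layer: when > 0, each noisy
#'   signal x is replaced by `rpois(1, x * poissonScale) / poissonScale`.
#'   Default 0 (off).
#'
#' @seealso [simulationDesign()], [simulateDecayTimecourse()]
#' @exportClass SimulationDesign
setClass("SimulationDesign",
  representation(
    timepoints = "numeric",
    noiseSigma = "numeric",
    spikeLevel = "numeric",
    channel = "character",
    seed = "integer",
    poissonScale = "numeric"
  )
)

setValidity("SimulationDesign", function(object) {
  tp <- object@timepoints
  if (length(tp) < 2 || any(!is.finite(tp))) {
    return("timepoints must be at least two finite values")
  }
  if (tp[1] != 0) return("first timepoint must be 0 (the chase start)")
  if (any(diff(tp) <= 0)) return("timepoints must be strictly increasing")
  if (length(object@noiseSigma) != 1 || object@noiseSigma < 0) {
    return("noiseSigma must be a single value >= 0")
  }
  if (length(object@spikeLevel) != 1 || object@spikeLevel <= 0) {
    return("spikeLevel must be a single value > 0")
  }
  if (!(object@channel %in% .CHANNELS)) {
    return("channel must be 'decay' or 'synthesis'")
  }
  if (object@poissonScale < 0) return("poissonScale must be >= 0")
  TRUE
})

#' ChaseExperiment: a 4TU-chase abundance time course
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one chase
#' measurement table: rows are transcripts plus exactly one spike-in row
#' (flagged in `rowData(x)$spike`), columns are chase timepoints (minutes in
#' `colData(x)$timepoint`, strictly increasing, starting at 0). The assay
#' `"signal"` carries the measured abundances; spike-in values must be
#' strictly positive, transcript values non-negative. Channel
#' (decay/synthesis), condition and replicate labels live in `metadata()`.
#'
#' @seealso [ChaseExperiment()] for construction, [spikeNormalize()],
#'   [t0Normalize()], [fitTranscriptome()]
#' @exportClass ChaseExperiment
setClass("ChaseExperiment", contains = "SummarizedExperiment")

setValidity("ChaseExperiment", function(object) {
  if (!("signal" %in% assayNames(object))) {
    return("assay 'signal' is required")
  }
  if (ncol(object) < 3) return("at least 3 timepoints are required")
  cd <- colData(object)
  if (!("timepoint" %in% colnames(cd))) {
    return("colData must contain a 'timepoint' column (minutes)")
  }
  tp <- cd$timepoint
  if (any(!is.finite(tp)) || tp[1] != 0 || any(diff(tp) <= 0)) {
    return("timepoints must be finite, strictly increasing and start at 0")
  }
  rd <- rowData(object)
  if (!("spike" %in% colnames(rd)) || !is.logical(rd$spike)) {
    return("rowData must contain a logical 'spike' column")
  }
  if (sum(rd$spike) != 1) {
    return("exactly one spike-in row is required")
  }
  if (anyDuplicated(rownames(object))) {
    return("transcript ids (rownames) must be unique")
  }
  ch <- metadata(object)$channel
  if (is.null(ch) || !(ch %in% .CHANNELS)) {
    return("metadata()$channel must be 'decay' or 'synthesis'")
  }
  sig <- assay(object, "signal")
  spike_row <- sig[rd$spike, ]
  if (any(!is.finite(spike_row)) || any(spike_row <= 0)) {
    return("spike-in signal must be finite and strictly positive at every timepoint")
  }
  tx <- sig[!rd$spike, , drop = FALSE]
  if (any(is.infinite(tx))) return("transcript signal must not be infinite")
  # NA rows are permitted: they mark transcripts excluded during
  # normalization (zero t = 0 anchor) and are reported unfit downstream.
  if (any(tx < 0, na.rm = TRUE)) {
    return("transcript signal must be non-negative")
  }
  TRUE
})
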