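#' Construct a ChaseExperiment
#'
#' Bundle a transcript-by-timepoint signal matrix, its spike-in row and the
#' chase design into a [ChaseExperiment-class] object. The spike row is an
#' exogenous RNA added in constant amount before extraction; it anchors the
#' absolute scale across timepoints (rcc1(Xl) for decay measurements,
#' srp1a(Hs) for synthesis measurements in the original protocol).
#'
#' @param signal numeric matrix, transcripts x timepoints; rownames are
#'   transcript ids and must include `spikeId`.
#' @param timepoints numeric vector of chase times in minutes; strictly
#'   increasing, first element 0; one per column of `signal`.
#' @param spikeId rowname of the spike-in row.
#' @param channel `"decay"` (unlabeled flowthrough) or `"synthesis"`
#'   (labeled eluate).
#' @param condition,replicate free-text labels stored in `metadata()`.
#' @param rowData optional `DataFrame`/data.frame of per-transcript
#'   annotation (e.g. simulation ground truth), matched to `signal` rows.
#'
#' @return A [ChaseExperiment-class] object.
#' @examples
#' sig <- rbind(ACT1 = c(4, 2, 1), spike = c(1, 1, 1))
#' ce <- ChaseExperiment(sig, timepoints = c(0, 5, 10), spikeId = "spike")
#' timepoints(ce)
#' @export
ChaseExperiment <- function(signal, timepoints, spikeId = "spike",
                            channel = c("decay", "synthesis"),
                            condition = "control", replicate = "rep1",
                            rowData = NULL) {
  channel <- match.arg(channel)
  if (is.null(rownames(signal))) {
    .tu_stop("signal matrix must have transcript ids as rownames", "input")
  }
  if (!(spikeId %in% rownames(signal))) {
    .tu_stop(sprintf("spike-in row '%s' not found in signal matrix", spikeId),
             "missing_spike")
  }
  if (length(timepoints) != ncol(signal)) {
    .tu_stop("one timepoint per signal column is required", "input")
  }
  colnames(signal) <- paste0("t", timepoints)
  rd <- DataFrame(spike = rownames(signal) == spikeId, row.names = rownames(signal))
  if (!is.null(rowData)) {
    rowData <- as(rowData, "DataFrame")
    stopifnot(nrow(rowData) == nrow(signal))
    rd <- cbind(rd, rowData)
  }
  se <- SummarizedExperiment(
    assays = SimpleList(signal = signal),
    rowData = rd,
    colData = DataFrame(timepoint = timepoints, row.names = colnames(signal)),
    metadata = list(channel = channel, condition = condition,
                    replicate = replicate, normalized = character(0))
  )
  new("ChaseExperiment", se)
}

#' Accessors for ChaseExperiment
#'
#' `timepoints()` returns the chase times in minutes; `channel()` the
#' measured channel (`"decay"` or `"synthesis"`); `spikeSignal()` the
#' spike-in row as a numeric vector; `transcriptSignal()` the signal matrix
#' without the spike row; `isSpike()` the logical spike flag per row.
#'
#' @param x a [ChaseExperiment-class]
#' @param ... ignored
#' @return See individual descriptions.
#' @name ChaseExperiment-accessors
#' @aliases timepoints channel spikeSignal transcriptSignal isSpike
NULL

#' @rdname ChaseExperiment-accessors
#' @export
setMethod("timepoints", "ChaseExperiment", function(x, ...) {
  colData(x)$timepoint
})

#' @rdname ChaseExperiment-accessors
#' @export
setMethod("channel", "ChaseExperiment", function(x, ...) {
  metadata(x)$channel
})

#' @rdname ChaseExperiment-accessors
#' @export
setMethod("isSpike", "ChaseExperiment", function(x, ...) {
  rowData(x)$spike
})

#' @rdname ChaseExperiment-accessors
#' @export
setMethod("spikeSignal", "ChaseExperiment", function(x, ...) {
  sig <- assay(x, "signal")
  as.numeric(sig[isSpike(x), ])
})

#' @rdname ChaseExperiment-accessors
#' @export
setMethod("transcriptSignal", "ChaseExperiment", function(x, ...) {
  assay(x, "signal")[!isSpike(x), , drop = FALSE]
})

#' @export
#' @describeIn ChaseExperiment-accessors compact display
setMethod("show", "ChaseExperiment", function(object) {
  md <- metadata(object)
  cat(sprintf(
    "ChaseExperiment: %d transcripts + 1 spike-in, %d timepoints (%s min)\n",
    nrow(object) - 1L, ncol(object),
    paste(timepoints(object), collapse = ", ")
  ))
  cat(sprintf("channel: %s | condition: %s | replicate: %s\n",
              md$channel, md$condition, md$replicate))
  if (length(md$normalized)) {
    cat("normalized:", paste(md$normalized, collapse = " + "), "\n")
  }
  invisible(NULL)
})

#' Construct a SimulationDesign
#'
#' @param timepoints chase times in minutes; strictly increasing, first 0.
#'   The default grid straddles the few-minute half-lives typical of
#'   rapidly dividing yeast.
#' @param noiseSigma log-sd of multiplicative lognormal measurement noise.
#' @param spikeLevel constant spike-in signal (> 0).
#' @param channel `"decay"` or `"synthesis"`.
#' @param seed integer seed for the simulation draws.
#' @param poissonScale optional counting-noise scale; 0 disables (default).
#' @return A [SimulationDesign-class] object.
#' @examples
#' simulationDesign(noiseSigma = 0, channel = "decay")
#' @export
simulationDesign <- function(timepoints = c(0, 2, 4, 8, 16, 32),
                             noiseSigma = 0.05, spikeLevel = 1,
                             channel = c("decay", "synthesis"),
                             seed = 1L, poissonScale = 0) {
  channel <- match.arg(channel)
  new("SimulationDesign", timepoints = as.numeric(timepoints),
      noiseSigma = noiseSigma, spikeLevel = spikeLevel,
      channel = channel, seed = as.integer(seed),
      poissonScale = poissonScale)
}

#' @export
#' @describeIn simulationDesign compact display
setMethod("show", "SimulationDesign", function(object) {
  cat(sprintf(
    "SimulationDesign: %s channel, t = {%s} min, noiseSigma = %g, spike = %g, seed = %d\n",
    object@channel, paste(object@timepoints, collapse = ", "),
    object@noiseSigma, object@spikeLevel, object@seed
  ))
  invisible(NULL)
})
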