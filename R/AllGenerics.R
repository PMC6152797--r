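#' @rdname ChaseExperiment-accessors
#' @export
setGeneric("timepoints", function(x, ...) standardGeneric("timepoints"))

#' @rdname ChaseExperiment-accessors
#' @export
setGeneric("channel", function(x, ...) standardGeneric("channel"))

#' @rdname ChaseExperiment-accessors
#' @export
setGeneric("spikeSignal", function(x, ...) standardGeneric("spikeSignal"))

#' @rdname ChaseExperiment-accessors
#' @export
setGeneric("transcriptSignal", function(x, ...) standardGeneric("transcriptSignal"))

#' @rdname ChaseExperiment-accessors
#' @export
setGeneric("isSpike", function(x, ...) standardGeneric("isSpike"))

#' @rdname spikeNormalize
#' @export
setGeneric("spikeNormalize", function(x, ...) standardGeneric("spikeNormalize"))

#' @rdname t0Normalize
#' @export
setGeneric("t0Normalize", function(x, ...) standardGeneric("t0Normalize"))

#' @rdname fitTranscriptome
#' @export
setGeneric("fitTranscriptome", function(x, ...) standardGeneric("fitTranscriptome"))

#' @rdname bulkHalfLife
#' @export
setGeneric("bulkHalfLife", function(x, ...) standardGeneric("bulkHalfLife"))
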