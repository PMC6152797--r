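#' Spike-in normalization
#'
#' Divides every measurement by the spike-in signal at the same timepoint.
#' The spike RNA is added in constant amount before extraction, so this step
#' removes timepoint-to-timepoint differences in recovery, library depth and
#' measurement scale. Applied to a [ChaseExperiment-class] it rescales every
#' row (the spike row itself becomes all ones); the numeric method normalizes
#' a single series against a spike vector.
#'
#' @param x a [ChaseExperiment-class], or a numeric signal vector.
#' @param spike (numeric method) spike signal, same length as `x`, all > 0.
#' @param ... ignored.
#' @return Same class as `x`, spike-normalized.
#' @examples
#' spikeNormalize(c(4, 4, 4), spike = c(1, 2, 4))
#' @name spikeNormalize
NULL

.check_spike <- function(spike) {
  bad <- which(!is.finite(spike) | spike <= 0)
  if (length(bad)) {
    .tu_stop(sprintf("degenerate spike signal (<= 0 or non-finite) at timepoint index %s",
                     paste(bad, collapse = ", ")), "degenerate_spike")
  }
}

#' @rdname spikeNormalize
#' @export
setMethod("spikeNormalize", "numeric", function(x, spike, ...) {
  if (length(spike) != length(x)) {
    .tu_stop("signal and spike must have the same length", "input")
  }
  .check_spike(spike)
  x / spike
})

#' @rdname spikeNormalize
#' @export
setMethod("spikeNormalize", "ChaseExperiment", function(x, ...) {
  if ("spike" %in% metadata(x)$normalized) return(x)
  sp <- spikeSignal(x)
  .check_spike(sp)
  assay(x, "signal") <- sweep(assay(x, "signal"), 2, sp, "/")
  metadata(x)$normalized <- c(metadata(x)$normalized, "spike")
  validObject(x)
  x
})

#' t0 normalization
#'
#' Rescales a decay-channel series to its value at the chase start, so the
#' fitted model starts at `RNA(0) = 1`. Synthesis-channel experiments pass
#' through unchanged by default: their t = 0 signal is essentially zero (no
#' label before the pulse), so dividing by it is numerically meaningless and
#' the linear synthesis fit absorbs the scale instead. Set `force = TRUE` to
#' apply the division to a synthesis channel anyway.
#'
#' Transcripts whose t = 0 signal is zero cannot be anchored; at the
#' experiment level they are flagged in `rowData(x)$zero_anchor` (their rows
#' become `NA`) and are reported as unfit downstream, while the numeric
#' method raises a zero-anchor error.
#'
#' @param x a [ChaseExperiment-class] or a numeric series (first element is
#'   the t = 0 value).
#' @param force apply to synthesis channel as well (default `FALSE`).
#' @param ... ignored.
#' @return Same class as `x`.
#' @examples
#' t0Normalize(c(4, 2, 1))
#' @name t0Normalize
NULL

#' @rdname t0Normalize
#' @export
setMethod("t0Normalize", "numeric", function(x, ...) {
  if (!is.finite(x[1]) || x[1] <= 0) {
    .tu_stop("t = 0 signal is zero or non-finite; cannot anchor the series",
             "zero_anchor")
  }
  x / x[1]
})

#' @rdname t0Normalize
#' @export
setMethod("t0Normalize", "ChaseExperiment", function(x, force = FALSE, ...) {
  if ("t0" %in% metadata(x)$normalized) return(x)
  if (channel(x) == "synthesis" && !force) return(x)
  sig <- assay(x, "signal")
  anchor <- sig[, 1]
  bad <- !is.finite(anchor) | anchor <= 0
  bad[isSpike(x)] <- FALSE  # spike anchor is guaranteed positive by validity
  out <- sig / anchor
  out[bad, ] <- NA_real_
  rowData(x)$zero_anchor <- bad
  assay(x, "signal") <- out
  metadata(x)$normalized <- c(metadata(x)$normalized, "t0")
  validObject(x)
  x
})
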