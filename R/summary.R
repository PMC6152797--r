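#' Transcriptome-level half-life summary
#'
#' Summarizes a fit table: mean and median half-life over `ok` fits, the
#' mean lifetime implied by the mean half-life, the fractions of transcripts
#' labeled and separated with efficiency above 0.9 and 0.8 (over all rows
#' carrying an efficiency estimate), and the fraction of attempted fits with
#' R-squared above 0.95.
#'
#' @param fits fit table from [fitTranscriptome()] (or any data.frame with
#'   `half_life`, `eff`, `r_squared`, `status`).
#' @return named list: `n_total`, `n_ok`, `mean_half_life`,
#'   `median_half_life`, `mean_lifetime`, `frac_eff_gt_090`,
#'   `frac_eff_gt_080`, `frac_r2_gt_095`.
#' @examples
#' fits <- data.frame(half_life = c(2, 4, 6), eff = c(0.95, 0.85, 0.7),
#'                    r_squared = c(0.99, 0.97, 0.9), status = "ok")
#' summarizeHalfLives(fits)
#' @export
summarizeHalfLives <- function(fits) {
  fits <- as.data.frame(fits)
  if (nrow(fits) == 0) .tu_stop("empty fit table", "empty_summary")
  ok <- fits$status == "ok"
  if (!any(ok)) .tu_stop("no ok fits to summarize", "empty_summary")
  th <- fits$half_life[ok]
  eff <- fits$eff[is.finite(fits$eff)]
  r2 <- fits$r_squared[is.finite(fits$r_squared)]
  list(
    n_total = nrow(fits),
    n_ok = sum(ok),
    mean_half_life = mean(th),
    median_half_life = stats::median(th),
    mean_lifetime = meanLifetime(mean(th)),
    frac_eff_gt_090 = mean(eff > 0.9),
    frac_eff_gt_080 = mean(eff > 0.8),
    frac_r2_gt_095 = mean(r2 > 0.95)
  )
}

#' Mean lifetime of a first-order decaying pool
#'
#' For exponential decay the mean lifetime is `half_life / ln(2)`; a 4.8 min
#' half-life corresponds to a 6.9 min mean lifetime.
#'
#' @param halfLife half-life in minutes, > 0 (vectorized).
#' @return mean lifetime in minutes.
#' @examples
#' meanLifetime(4.8)
#' @export
meanLifetime <- function(halfLife) {
  if (any(!is.finite(halfLife)) || any(halfLife <= 0)) {
    .tu_stop("half-life must be positive", "invalid_parameter")
  }
  halfLife / log(2)
}

#' Bulk-transcriptome half-life
#'
#' Half-life of the abundance-summed mRNA pool: spike-normalized transcript
#' signals are summed per timepoint (preserving abundance weighting), the
#' pooled series is t0-normalized, and the efficiency-modified decay model
#' is fit to it. Because abundant long-lived transcripts dominate the pool,
#' the bulk half-life exceeds the unweighted per-transcript mean.
#'
#' @param x a decay-channel [ChaseExperiment-class].
#' @param config settings from [fitConfig()].
#' @param ... ignored.
#' @return bulk half-life in minutes.
#' @examples
#' p <- sampleTrueParams(20, seed = 1)
#' ce <- simulateDecayTimecourse(p, simulationDesign(noiseSigma = 0, channel = "decay"))
#' bulkHalfLife(ce)
#' @export
setMethod("bulkHalfLife", "ChaseExperiment", function(x, config = fitConfig(), ...) {
  if (channel(x) != "decay") {
    .tu_stop("bulkHalfLife expects a decay-channel experiment", "input")
  }
  xs <- spikeNormalize(x)
  pooled <- colSums(transcriptSignal(xs))
  fit <- fitDecay(t0Normalize(pooled), timepoints(xs),
                  thBounds = config$thBounds, effBounds = config$effBounds,
                  nGrid = config$nGrid)
  fit$half_life
})

#' Replicate agreement of fitted half-lives
#'
#' Pearson correlation of half-lives between two fit tables over transcripts
#' with status `ok` in both. Computed on log10 half-lives by default (the
#' distribution spans more than an order of magnitude, so linear-space
#' correlation is dominated by the long-lived tail); set `log = FALSE` for
#' linear space.
#'
#' @param fitsA,fitsB fit tables from [fitTranscriptome()].
#' @param log correlate log10 half-lives (default) or linear.
#' @return Pearson correlation coefficient.
#' @examples
#' f <- data.frame(transcript_id = c("a", "b", "c"),
#'                 half_life = c(1, 2, 4), status = "ok")
#' replicateAgreement(f, f)
#' @export
replicateAgreement <- function(fitsA, fitsB, log = TRUE) {
  m <- .shared_ok(fitsA, fitsB)
  if (nrow(m) < 3) {
    .tu_stop("fewer than 3 transcripts with ok fits in both tables",
             "insufficient_overlap")
  }
  if (log) stats::cor(log10(m$thA), log10(m$thB)) else stats::cor(m$thA, m$thB)
}

.shared_ok <- function(fitsA, fitsB) {
  fitsA <- as.data.frame(fitsA)
  fitsB <- as.data.frame(fitsB)
  a <- fitsA[fitsA$status == "ok", c("transcript_id", "half_life")]
  b <- fitsB[fitsB$status == "ok", c("transcript_id", "half_life")]
  m <- merge(a, b, by = "transcript_id", suffixes = c("A", "B"))
  names(m) <- c("transcript_id", "thA", "thB")
  m
}

#' Long-lived transcript set
#'
#' Transcripts whose half-life exceeds the mean of `ok` half-lives by more
#' than `k` sample standard deviations (n - 1 denominator).
#'
#' @param fits fit table from [fitTranscriptome()].
#' @param k number of standard deviations above the mean (default 1).
#' @return character vector of transcript ids.
#' @examples
#' fits <- data.frame(transcript_id = letters[1:4],
#'                    half_life = c(1, 1, 1, 10), status = "ok")
#' longLivedSet(fits)
#' @export
longLivedSet <- function(fits, k = 1) {
  fits <- as.data.frame(fits)
  ok <- fits[fits$status == "ok", ]
  if (nrow(ok) < 2) .tu_stop("need at least 2 ok fits", "insufficient_data")
  cut <- mean(ok$half_life) + k * stats::sd(ok$half_life)
  ok$transcript_id[ok$half_life > cut]
}
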