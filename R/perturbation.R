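#' Directional paired test of a mechanistic prediction
#'
#' One-sided paired t-test of treated versus control half-lives under the
#' direction a mechanistic model predicts. For an elongation inhibitor the
#' translation-factor-protection model predicts stabilization
#' (`"stabilize"`, alternative treated > control) while stalled-ribosome-
#' triggered decay predicts destabilization (`"destabilize"`, treated <
#' control); for an initiation inhibitor the protection model predicts
#' destabilization and the stalled-ribosome model makes no clear prediction.
#' The caller maps (perturbation, model) to a direction; p-values below 0.05
#' are taken as supporting the model.
#'
#' When all paired differences are zero the t statistic is 0 and the
#' one-sided p-value is 0.5 by convention.
#'
#' @param control,treated equal-length vectors of paired half-lives
#'   (replicate measurements of one transcript, or per-transcript values
#'   across the transcriptome -- both axes are valid pairings).
#' @param prediction `"stabilize"` or `"destabilize"`.
#' @param log test log-transformed half-lives instead of raw differences
#'   (default `FALSE`, matching per-transcript half-life pair reporting).
#' @return one-sided p-value.
#' @examples
#' pairedModelTest(c(2, 3, 5, 4), c(4, 6, 10, 8), "stabilize")
#' @export
pairedModelTest <- function(control, treated,
                            prediction = c("stabilize", "destabilize"),
                            log = FALSE) {
  prediction <- match.arg(prediction)
  if (length(control) != length(treated)) {
    .tu_stop("control and treated must be paired (equal length)", "input")
  }
  if (length(control) < 2) .tu_stop("need at least 2 pairs", "input")
  if (any(!is.finite(control)) || any(!is.finite(treated)) ||
      any(control <= 0) || any(treated <= 0)) {
    .tu_stop("half-lives must be finite and positive", "input")
  }
  d <- if (log) base::log(treated) - base::log(control) else treated - control
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(0.5)
    up <- mean(d) > 0
    return(if ((up && prediction == "stabilize") ||
               (!up && prediction == "destabilize")) 0 else 1)
  }
  tstat <- mean(d) / (s / sqrt(n))
  if (prediction == "stabilize") {
    stats::pt(tstat, df = n - 1, lower.tail = FALSE)
  } else {
    stats::pt(tstat, df = n - 1, lower.tail = TRUE)
  }
}

# Exact distribution of the Wilcoxon signed-rank statistic with average
# ranks: doubled ranks are integers, so the null distribution of the doubled
# statistic is built by dynamic-programming convolution over sign flips.
.signed_rank_exact_p <- function(W, r) {
  r2 <- as.integer(round(2 * r))
  maxs <- sum(r2)
  probs <- numeric(maxs + 1L)
  probs[1] <- 1
  for (w in r2) {
    shifted <- c(rep(0, w), probs[seq_len(maxs + 1L - w)])
    probs <- (probs + shifted) / 2
  }
  W2 <- round(2 * W)
  p_le <- sum(probs[seq_len(W2 + 1L)])
  p_ge <- sum(probs[seq.int(W2 + 1L, maxs + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Two-sided paired Wilcoxon signed-rank test
#'
#' Transcriptome-wide nonparametric comparison of paired half-lives. Zero
#' differences are dropped (standard signed-rank convention); ties in
#' absolute differences take average ranks. With 25 or fewer informative
#' pairs the p-value is exact, from full enumeration of the sign-flip null
#' distribution; above that a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param control,treated equal-length paired half-life vectors.
#' @return two-sided p-value.
#' @examples
#' wilcoxonPaired(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 7))  # 0.03125
#' @export
wilcoxonPaired <- function(control, treated) {
  if (length(control) != length(treated)) {
    .tu_stop("control and treated must be paired (equal length)", "input")
  }
  d <- treated - control
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n == 0) .tu_stop("all paired differences are zero", "degenerate")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) return(.signed_rank_exact_p(W, r))
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- W - mu
  z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Cumulative half-life distribution
#'
#' Right-continuous empirical cumulative distribution of `ok` half-lives,
#' the representation used to compare a perturbed transcriptome against its
#' control.
#'
#' @param fits fit table from [fitTranscriptome()].
#' @return data.frame with columns `half_life` (sorted unique values) and
#'   `cumulative_frequency` (ending at exactly 1).
#' @examples
#' halfLifeEcdf(data.frame(half_life = c(1, 2, 3), status = "ok"))
#' @export
halfLifeEcdf <- function(fits) {
  fits <- as.data.frame(fits)
  th <- fits$half_life[fits$status == "ok"]
  if (length(th) == 0) .tu_stop("no ok fits", "empty_summary")
  x <- sort(unique(th))
  data.frame(half_life = x,
             cumulative_frequency = stats::ecdf(th)(x))
}

#' Spearman correlation of half-lives across conditions
#'
#' Rank correlation (average-rank ties) of half-lives over transcripts with
#' `ok` fits in both conditions. A high value after a perturbation indicates
#' a global shift in stability rather than a reordering of the stability
#' profile.
#'
#' @param fitsA,fitsB fit tables from [fitTranscriptome()].
#' @return Spearman rho.
#' @examples
#' f <- data.frame(transcript_id = c("a", "b", "c"),
#'                 half_life = c(1, 2, 4), status = "ok")
#' crossConditionSpearman(f, f)
#' @export
crossConditionSpearman <- function(fitsA, fitsB) {
  m <- .shared_ok(fitsA, fitsB)
  if (nrow(m) < 3) {
    .tu_stop("fewer than 3 transcripts with ok fits in both tables",
             "insufficient_overlap")
  }
  stats::cor(m$thA, m$thB, method = "spearman")
}

#' Half-life fold change grouped by a codon-count threshold
#'
#' Splits transcripts by a per-transcript codon count (e.g. histidine plus
#' glycine codons under 3AT-induced starvation) at a threshold and
#' summarizes the half-life fold change (treated / control) in each group.
#' A threshold effect shows as a larger fold increase in the high-count
#' group.
#'
#' @param control,treated paired half-life vectors, matched to `counts`.
#' @param counts non-negative integer codon counts per transcript.
#' @param threshold group boundary: `low` is count <= threshold, `high` is
#'   count > threshold (default 2).
#' @return data.frame with one row per group: `group`, `n`, `mean_fold`,
#'   `median_fold` (NA summaries for an empty group).
#' @examples
#' foldChangeByCount(c(1, 1, 1, 1), c(2, 2, 4, 4), c(0, 1, 3, 5), 2)
#' @export
foldChangeByCount <- function(control, treated, counts, threshold = 2) {
  if (length(control) != length(treated) || length(control) != length(counts)) {
    .tu_stop("control, treated and counts must be matched", "input")
  }
  if (any(counts < 0, na.rm = TRUE)) {
    .tu_stop("counts must be non-negative", "input")
  }
  usable <- is.finite(control) & control > 0 & is.finite(treated) &
    is.finite(counts)
  if (any(!usable)) {
    warning(sum(!usable), " transcript(s) excluded (zero/invalid control half-life)")
  }
  fold <- treated[usable] / control[usable]
  high <- counts[usable] > threshold
  one <- function(sel, label) {
    data.frame(group = label, n = sum(sel),
               mean_fold = if (any(sel)) mean(fold[sel]) else NA_real_,
               median_fold = if (any(sel)) stats::median(fold[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(one(!high, sprintf("count<=%g", threshold)),
        one(high, sprintf("count>%g", threshold)))
}
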