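#' Pairwise Spearman correlation of per-transcript features
#'
#' Rank correlation matrix (average-rank ties) among per-transcript mRNA
#' features such as half-life, translation efficiency, polyA tail length,
#' CAI, nTE, abundance, UTR lengths, GC content and ORF length. Feature
#' tables assembled from heterogeneous external datasets have uneven
#' coverage, so each pair uses its complete observations; a pair sharing
#' fewer than `minOverlap` transcripts is an error naming the pair.
#'
#' @param features data.frame with a `transcript_id` column plus one numeric
#'   column per feature (or a plain numeric matrix/data.frame of features).
#' @param minOverlap minimum shared non-missing transcripts per pair.
#' @return symmetric correlation matrix with unit diagonal.
#' @examples
#' tbl <- data.frame(transcript_id = letters[1:5],
#'                   half_life = c(1, 2, 3, 4, 5), te = c(2, 3, 4, 6, 7))
#' spearmanMatrix(tbl)
#' @export
spearmanMatrix <- function(features, minOverlap = 3) {
  features <- as.data.frame(features)
  if ("transcript_id" %in% names(features)) {
    features <- features[, setdiff(names(features), "transcript_id"),
                         drop = FALSE]
  }
  if (ncol(features) < 2) .tu_stop("need at least 2 features", "input")
  if (anyDuplicated(names(features))) {
    .tu_stop("feature names must be unique", "input")
  }
  X <- as.matrix(features)
  p <- ncol(X)
  rho <- diag(1, p)
  dimnames(rho) <- list(colnames(X), colnames(X))
  for (i in seq_len(p - 1)) {
    for (j in seq.int(i + 1, p)) {
      cc <- stats::complete.cases(X[, i], X[, j])
      if (sum(cc) < minOverlap) {
        .tu_stop(sprintf("features '%s' and '%s' share only %d non-missing transcripts (need >= %d)",
                         colnames(X)[i], colnames(X)[j], sum(cc), minOverlap),
                 "insufficient_overlap")
      }
      rho[i, j] <- rho[j, i] <-
        stats::cor(X[cc, i], X[cc, j], method = "spearman")
    }
  }
  rho
}

#' Hierarchically cluster a feature correlation matrix
#'
#' Agglomerative clustering of features on Euclidean distances between the
#' rows of their correlation matrix, the ordering used to arrange the
#' correlation heatmap. Rows are sorted lexicographically before clustering
#' so equal-height merges resolve deterministically by feature name.
#'
#' @param mat symmetric correlation matrix from [spearmanMatrix()].
#' @param method linkage passed to [stats::hclust()]; average linkage
#'   (UPGMA) by default.
#' @return list with `matrix` (input, in clustered order), `leaf_order`
#'   (feature names), `heights` (merge heights) and the `hclust` object.
#' @examples
#' tbl <- data.frame(a = c(1, 2, 3, 4), b = c(1.1, 2, 3, 3.9), c = c(4, 1, 3, 2))
#' clusterFeatures(spearmanMatrix(tbl))$leaf_order
#' @export
clusterFeatures <- function(mat, method = "average") {
  if (is.null(rownames(mat)) || !isSymmetric(unname(mat), tol = 1e-12)) {
    .tu_stop("input must be a named symmetric correlation matrix", "input")
  }
  ord <- order(rownames(mat))
  mat <- mat[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::dist(mat), method = method)
  leaf_order <- rownames(mat)[hc$order]
  list(matrix = mat[hc$order, hc$order, drop = FALSE],
       leaf_order = leaf_order, heights = hc$height, hclust = hc)
}

#' Correlation heatmap of mRNA features
#'
#' Renders the clustered Spearman matrix as a heatmap with a diverging
#' orange (positive) / blue (negative) palette and the self-correlation
#' diagonal masked in gray. Requires the pheatmap package.
#'
#' @param mat correlation matrix from [spearmanMatrix()].
#' @param filename optional output file (png/pdf by extension).
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plotCorrelationHeatmap <- function(mat, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    .tu_stop("plotCorrelationHeatmap requires the pheatmap package", "input")
  }
  cl <- clusterFeatures(mat)
  shown <- cl$matrix
  diag(shown) <- NA  # self-correlations carry no information; gray them out
  ph <- pheatmap::pheatmap(
    shown,
    cluster_rows = FALSE, cluster_cols = FALSE,
    breaks = seq(-1, 1, length.out = 101),
    color = grDevices::colorRampPalette(c("#2166AC", "white", "#E66101"))(100),
    na_col = "gray70",
    filename = filename, ...)
  invisible(ph)
}
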