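# Canonical table dialect: TSV, UTF-8, '.' decimal separator. Timepoints are
# encoded in the header as t<minutes> (fractional minutes allowed); the
# experiment's channel/condition/replicate/spike id travel as '# key=value'
# comment lines above the header so a counts file is self-describing.

.meta_keys <- c("channel", "condition", "replicate", "spike_id")

#' Read a counts table into a ChaseExperiment
#'
#' Parses the canonical counts TSV: optional `# key=value` comment lines
#' (channel, condition, replicate, spike_id), a header `transcript_id`
#' followed by `t<minutes>` columns, and one row per transcript including
#' exactly one spike-in row. Arguments override the file's comment metadata.
#'
#' @param path file path.
#' @param spikeId,channel,condition,replicate overrides for the file's
#'   metadata lines; `NULL` keeps the file's values.
#' @return A [ChaseExperiment-class].
#' @seealso [writeCounts()]
#' @export
readCounts <- function(path, spikeId = NULL, channel = NULL,
                       condition = NULL, replicate = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines)
  meta <- list(channel = "decay", condition = "control",
               replicate = "rep1", spike_id = "spike")
  for (ml in meta_lines) {
    kv <- regmatches(lines[ml], regexec("^#\\s*([a-z_]+)\\s*=\\s*(.+?)\\s*$",
                                        lines[ml]))[[1]]
    if (length(kv) == 3 && kv[2] %in% .meta_keys) meta[[kv[2]]] <- kv[3]
  }
  if (!is.null(spikeId)) meta$spike_id <- spikeId
  if (!is.null(channel)) meta$channel <- channel
  if (!is.null(condition)) meta$condition <- condition
  if (!is.null(replicate)) meta$replicate <- replicate

  body <- if (length(meta_lines)) lines[-meta_lines] else lines
  tbl <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tbl)[1] != "transcript_id") {
    .tu_stop("first column must be 'transcript_id' (line 1 of the table)", "parse")
  }
  tcols <- names(tbl)[-1]
  if (!all(grepl("^t[0-9.]+$", tcols))) {
    .tu_stop("time columns must be labeled t<minutes> (header line)", "parse")
  }
  tp <- as.numeric(sub("^t", "", tcols))
  if (any(diff(tp) <= 0) || tp[1] != 0) {
    .tu_stop("time columns must be strictly increasing from t0 (header line)",
             "parse")
  }
  dup <- which(duplicated(tbl$transcript_id))
  if (length(dup)) {
    .tu_stop(sprintf("duplicate transcript_id at table line %s",
                     paste(dup + 1L, collapse = ", ")), "parse")
  }
  if (!(meta$spike_id %in% tbl$transcript_id)) {
    .tu_stop(sprintf("spike-in row '%s' missing from counts table", meta$spike_id),
             "missing_spike")
  }
  sig <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(sig) <- tbl$transcript_id
  ChaseExperiment(sig, timepoints = tp, spikeId = meta$spike_id,
                  channel = meta$channel, condition = meta$condition,
                  replicate = meta$replicate)
}

#' Write a ChaseExperiment as a counts TSV
#'
#' @param x a [ChaseExperiment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readCounts()]
#' @export
writeCounts <- function(x, path) {
  md <- metadata(x)
  spike_id <- rownames(x)[isSpike(x)]
  header <- c(sprintf("# channel=%s", md$channel),
              sprintf("# condition=%s", md$condition),
              sprintf("# replicate=%s", md$replicate),
              sprintf("# spike_id=%s", spike_id))
  sig <- assay(x, "signal")
  tbl <- data.frame(transcript_id = rownames(sig), sig,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(tbl) <- c("transcript_id", paste0("t", timepoints(x)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(tbl, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.fit_columns <- c("transcript_id", "half_life", "eff", "r_squared", "status",
                  "high_quality", "n_points", "mean_raw_signal")

#' Read and write fit tables
#'
#' Fit tables are TSV with a fixed column order (`transcript_id`,
#' `half_life`, `eff`, `r_squared`, `status`, `high_quality`, `n_points`,
#' `mean_raw_signal`); bytes are deterministic given identical fits.
#'
#' @param fits fit table from [fitTranscriptome()].
#' @param path file path.
#' @return `writeFits` returns `path` invisibly; `readFits` a data.frame.
#' @export
writeFits <- function(fits, path) {
  fits <- as.data.frame(fits)
  missing <- setdiff(.fit_columns, names(fits))
  if (length(missing)) {
    .tu_stop(paste("fit table is missing columns:",
                   paste(missing, collapse = ", ")), "input")
  }
  utils::write.table(fits[, .fit_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeFits
#' @export
readFits <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a summary or comparison as deterministic JSON
#'
#' Keys are sorted and scalars unboxed so identical inputs produce identical
#' bytes.
#'
#' @param x named list (e.g. from [summarizeHalfLives()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSummaryJson <- function(x, path) {
  x <- x[order(names(x))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Reads a YAML file of fitting settings and merges it over [fitConfig()]
#' defaults; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return config list as from [fitConfig()].
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- fitConfig()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    .tu_stop(paste("unknown config keys:", paste(unknown, collapse = ", ")),
             "parse")
  }
  merged <- utils::modifyList(defaults, user)
  do.call(fitConfig, merged)
}
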