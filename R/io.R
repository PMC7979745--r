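#' Read and write the pipeline's plain-text formats
#'
#' Thin, strict wrappers over the standard formats the pipeline consumes
#' and emits: FASTA (via Biostrings), BED (0-based half-open), bedGraph
#' and TSV. All coordinates are 0-based half-open on disk and in memory;
#' 1-based coordinates appear only in human-readable reports.
#'
#' @param path File path.
#' @param genome Named character vector of sequences.
#' @name io
NULL

#' @rdname io
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' @rdname io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname io
#' @param df Data frame to serialize.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  name <- if ("region_id" %in% names(df)) df$region_id else "."
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  out <- data.frame(df$chrom, df$start, df$end, name, score, strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("malformed BED: fewer than 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "region_id"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  if (ncol(df) >= 6) names(df)[6] <- "strand"
  if (any(df$end <= df$start)) stop("malformed BED: end <= start")
  df
}

#' @rdname io
#' @export
write_bedgraph <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(df)))
  utils::write.table(df[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  if (any(!is.finite(df$value))) stop("malformed bedGraph: non-finite value")
  df
}

#' @rdname io
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
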