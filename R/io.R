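#' Write sequences as 60-column wrapped FASTA
#'
#' @param sequences named character vector or `DNAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector, uppercase.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
}

#' Write reads as FASTQ with uniform quality
#'
#' @param reads named character vector of read sequences.
#' @param path output path.
#' @param quality_char uniform per-base quality character (default "I",
#'   Phred 40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  # records are emitted directly: ultralong reads exceed the per-record
  # buffer of the usual FASTQ serializers
  lines <- character(4L * length(reads))
  lines[seq(1, length(lines), by = 4)] <- paste0("@", names(reads))
  lines[seq(2, length(lines), by = 4)] <- unname(reads)
  lines[seq(3, length(lines), by = 4)] <- "+"
  lines[seq(4, length(lines), by = 4)] <-
    vapply(nchar(reads), function(n) strrep(quality_char, n), "")
  writeLines(lines, path)
  invisible(path)
}

# 0-based half-open interval df (chrom/start/end[, name, score, strand])
# <-> GRanges
df_to_granges <- function(df, seq_lengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start + 1L, df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*")
  if ("name" %in% names(df)) gr$name <- df$name
  if ("score" %in% names(df)) gr$score <- df$score
  if (!is.null(seq_lengths))
    GenomeInfoDb::seqlengths(gr) <- seq_lengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

granges_to_df <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  md <- S4Vectors::mcols(gr)
  for (col in colnames(md)) df[[col]] <- md[[col]]
  st <- as.character(BiocGenerics::strand(gr))
  if (any(st != "*")) df$strand <- st
  df
}

#' Write intervals as BED6
#'
#' `name`/`score`/`strand` columns are used when present (defaults `"."`,
#' 0, `"*"`). Coordinates are already BED-convention 0-based half-open.
#'
#' @param df interval data frame with `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  if (!"name" %in% names(df)) df$name <- "."
  if (!"score" %in% names(df)) df$score <- 0
  rtracklayer::export(df_to_granges(df), path, format = "BED")
  invisible(path)
}

#' Read a BED file as a 0-based half-open interval data frame
#'
#' @param path BED path.
#' @return data frame `chrom`, `start`, `end` (+ `name`, `score`,
#'   `strand` when present).
#' @export
read_bed <- function(path) {
  granges_to_df(rtracklayer::import(path, format = "BED"))
}

#' Write a binned track as bedGraph
#'
#' @param track data frame `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  gr <- df_to_granges(track[, c("chrom", "start", "end")])
  gr$score <- track$value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph as a binned track data frame
#'
#' @param path bedGraph path.
#' @return data frame `chrom`, `start`, `end`, `value` with attribute
#'   `bin_width` inferred from the modal interval width.
#' @export
read_bedgraph <- function(path) {
  df <- granges_to_df(rtracklayer::import(path, format = "bedGraph"))
  names(df)[names(df) == "score"] <- "value"
  w <- df$end - df$start
  attr(df, "bin_width") <- as.integer(names(sort(table(w),
                                                 decreasing = TRUE))[1])
  df
}

#' Write a truth set as BED6
#'
#' Feature kind and label are joined as `kind:label` in the name field;
#' the strand column is carried through.
#'
#' @param truth truth feature data frame from [make_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  df <- truth
  df$name <- paste(df$kind, df$label, sep = ":")
  df$score <- 0
  write_bed(df[, c("chrom", "start", "end", "name", "score", "strand")],
            path)
}
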