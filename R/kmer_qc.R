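#' Canonical k-mers of a sequence
#'
#' Returns the canonical form (lexicographic minimum of a k-mer and its
#' reverse complement) of every k-mer window of `x`, skipping windows that
#' contain an N. Computed without per-window reverse complementation: the
#' reverse complements of all windows of `x` are the reversed windows of
#' `revcomp(x)`.
#'
#' @param x DNA string.
#' @param k k-mer length.
#' @return character vector of canonical k-mers, one per valid window, in
#'   window order.
#' @keywords internal
canonical_kmers <- function(x, k) {
  x <- toupper(x)
  n <- nchar(x)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  fwd <- substring(x, starts, starts + k - 1L)
  rc <- rev(substring(revcomp(x), starts, starts + k - 1L))
  can <- ifelse(fwd <= rc, fwd, rc)
  if (grepl("N", x, fixed = TRUE)) {
    npos <- gregexpr("N", x, fixed = TRUE)[[1]]
    bad <- unique(unlist(lapply(npos, function(p)
      max(1L, p - k + 1L):min(n - k + 1L, p))))
    can <- can[-bad]
  }
  can
}

#' Count canonical k-mers of a sequence set
#'
#' Builds a k-mer database for QV and completeness estimation: a multiset
#' of canonical k-mers (lexicographic minimum of each k-mer and its reverse
#' complement, the standard convention for strand-symmetric counting).
#' Windows containing N are skipped.
#'
#' @param sequences named character vector or `DNAStringSet`.
#' @param k k-mer length (conventionally 21).
#' @param label source label stored in the database.
#' @return object of class `kmer_db`: list with `k`, `counts` (named
#'   integer vector, canonical k-mer -> occurrence count) and `label`.
#' @export
count_kmers <- function(sequences, k, label = "") {
  stopifnot(k >= 1)
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  if (k > max(nchar(sequences))) {
    warning("k exceeds the longest sequence; empty k-mer database")
    return(structure(list(k = as.integer(k), counts = integer(0),
                          label = label), class = "kmer_db"))
  }
  all_k <- unlist(lapply(sequences, canonical_kmers, k = k),
                  use.names = FALSE)
  tab <- table(all_k)
  counts <- setNames(as.integer(tab), names(tab))
  structure(list(k = as.integer(k), counts = counts, label = label),
            class = "kmer_db")
}

#' @export
print.kmer_db <- function(x, ...) {
  cat(sprintf("k-mer database (k = %d): %d distinct, %.0f total instances%s\n",
              x$k, length(x$counts), sum(as.numeric(x$counts)),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Phred-scaled assembly quality value from mapped k-mer counts
#'
#' Converts the count of assembly k-mers absent from a read database into a
#' consensus quality value. With `T` total assembly k-mers of which `E` are
#' unsupported by the reads, the per-base error probability is estimated as
#' `1 - (1 - E/T)^(1/k)` (an error corrupts up to k overlapping k-mers), so
#'
#' \deqn{QV = -10 \log_{10}\left(1 - (1 - E/T)^{1/k}\right)}
#'
#' and accuracy (percent) is `100 - 100 * 10^(-QV/10)`. `E = 0` yields an
#' infinite QV and accuracy 100.
#'
#' @param E assembly k-mer instances missing from the read database.
#' @param T_total total assembly k-mer instances (must be > 0).
#' @param k k-mer length.
#' @return list with `qv` (dB), `accuracy` (percent) and `error_rate`
#'   (per-base error probability).
#' @export
qv_from_counts <- function(E, T_total, k) {
  stop_if_not_scalar_number(E, "E")
  stop_if_not_scalar_number(T_total, "T_total")
  if (T_total <= 0) stop("T_total must be > 0", call. = FALSE)
  if (E < 0 || E > T_total) stop("require 0 <= E <= T_total", call. = FALSE)
  if (E == 0)
    return(list(qv = Inf, accuracy = 100, error_rate = 0))
  err <- 1 - (1 - E / T_total)^(1 / k)
  qv <- -10 * log10(err)
  list(qv = qv, accuracy = 100 - 100 * 10^(qv / -10), error_rate = err)
}

#' Assembly QV against a read k-mer database
#'
#' Evaluates every k-mer instance of the assembly for presence in the read
#' database; instances whose canonical form is absent are counted as
#' base-level errors. Counting is instance-wise (with multiplicity), so the
#' total equals the number of valid k-mer windows in the assembly.
#'
#' @param assembly named character vector or `DNAStringSet` of assembly
#'   sequences.
#' @param read_db a `kmer_db` built from read data (same k).
#' @param k k-mer length; must equal `read_db$k`.
#' @return list with `T` (total assembly k-mer instances), `E` (missing
#'   instances), `k`, `qv`, `accuracy`, `error_rate`.
#' @export
assembly_qv <- function(assembly, read_db, k = read_db$k) {
  stopifnot(inherits(read_db, "kmer_db"))
  if (k != read_db$k)
    stop(sprintf("k mismatch: %d vs database k = %d", k, read_db$k),
         call. = FALSE)
  if (methods::is(assembly, "DNAStringSet"))
    assembly <- as.character(assembly)
  known <- names(read_db$counts)
  T_total <- 0; E <- 0
  for (s in assembly) {
    km <- canonical_kmers(s, k)
    T_total <- T_total + length(km)
    E <- E + sum(!(km %in% known))
  }
  res <- qv_from_counts(E, T_total, k)
  c(list(T = T_total, E = E, k = as.integer(k)), res)
}

#' k-mer completeness of an assembly
#'
#' Fraction of distinct reliable read k-mers (read-database count at least
#' `min_read_count`, suppressing singleton read-error k-mers) present in
#' the assembly database.
#'
#' @param read_db,assembly_db `kmer_db` objects with equal k.
#' @param min_read_count reliability filter on read k-mer counts.
#' @return fraction in `[0, 1]`.
#' @export
kmer_completeness <- function(read_db, assembly_db, min_read_count = 2) {
  stopifnot(inherits(read_db, "kmer_db"), inherits(assembly_db, "kmer_db"))
  if (read_db$k != assembly_db$k) stop("k mismatch", call. = FALSE)
  reliable <- names(read_db$counts)[read_db$counts >= min_read_count]
  if (length(reliable) == 0L)
    stop("no read k-mers pass the reliability filter", call. = FALSE)
  mean(reliable %in% names(assembly_db$counts))
}

#' Write/read a k-mer database as sorted two-column text
#'
#' Plain `kmer<TAB>count` text, sorted by k-mer; `gzfile` connections are
#' handled transparently by R when `path` ends in `.gz`.
#'
#' @param db a `kmer_db`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kmer_db <- function(db, path) {
  stopifnot(inherits(db, "kmer_db"))
  o <- order(names(db$counts))
  writeLines(paste(names(db$counts)[o], db$counts[o], sep = "\t"),
             con = path)
  invisible(path)
}

#' @rdname write_kmer_db
#' @param k k-mer length of the stored database (checked against the data).
#' @param label source label for the restored database.
#' @export
read_kmer_db <- function(path, k = NULL, label = "") {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = c("character", "integer"))
  if (is.null(k)) k <- nchar(tab[[1]][1])
  stopifnot(all(nchar(tab[[1]]) == k))
  structure(list(k = as.integer(k),
                 counts = setNames(tab[[2]], tab[[1]]), label = label),
            class = "kmer_db")
}
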