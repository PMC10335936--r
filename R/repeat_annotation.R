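#' Parse a Tandem Repeats Finder `.dat` table
#'
#' Reads the whitespace-delimited data lines of TRF's `-d` output
#' (`Sequence:` headers delimit chromosomes). Coordinates are converted
#' from TRF's 1-based closed intervals to 0-based half-open.
#'
#' @param path path to a `.dat` file.
#' @return data frame `chrom`, `start`, `end`, `unit_length`,
#'   `copy_number`, `score`, `consensus`.
#' @export
read_trf_dat <- function(path) {
  lines <- readLines(path)
  chrom <- NA_character_
  rows <- list()
  for (ln in lines) {
    if (grepl("^Sequence:", ln)) {
      chrom <- sub("^Sequence:\\s*(\\S+).*$", "\\1", ln)
      next
    }
    if (!grepl("^[0-9]+\\s+[0-9]+\\s", ln)) next
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 14) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom,
      start = as.integer(f[1]) - 1L, end = as.integer(f[2]),
      unit_length = as.integer(f[3]), copy_number = as.numeric(f[4]),
      score = as.numeric(f[8]), consensus = f[14],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), unit_length = integer(),
                      copy_number = numeric(), score = numeric(),
                      consensus = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Classify tandem repeats by unit length
#'
#' Applies the standard post-filter to a tandem-repeat table: records with
#' fewer than five copies are dropped, redundant records (reciprocal
#' overlap > 50%) are resolved by keeping the highest-scoring record
#' (ties: longer interval, then leftmost), and survivors are labeled by
#' unit length — under 10 bp microsatellite, 10-100 bp (inclusive)
#' minisatellite, over 100 bp satellite.
#'
#' @param records tandem-repeat data frame as from [read_trf_dat()].
#' @param min_copies minimum copy number retained (default 5).
#' @return the retained records with an added `class` column.
#' @export
classify_tandem_repeats <- function(records, min_copies = 5) {
  bad <- records$unit_length <= 0
  if (any(bad)) {
    message(sum(bad), " record(s) with nonpositive unit length rejected")
    records <- records[!bad, , drop = FALSE]
  }
  records <- records[records$copy_number >= min_copies, , drop = FALSE]
  # redundancy resolution: greedy by score, then longer, then leftmost
  keep <- logical(nrow(records))
  for (cname in unique(records$chrom)) {
    idx <- which(records$chrom == cname)
    r <- records[idx, , drop = FALSE]
    o <- order(-r$score, -(r$end - r$start), r$start)
    kept_ir <- IRanges::IRanges()
    for (j in o) {
      ir <- IRanges::IRanges(r$start[j] + 1L, r$end[j])
      if (length(kept_ir)) {
        ov <- IRanges::findOverlaps(ir, kept_ir)
        if (length(ov)) {
          w <- BiocGenerics::width(IRanges::pintersect(
            rep(ir, length(ov)), kept_ir[S4Vectors::subjectHits(ov)]))
          recip <- w > 0.5 * BiocGenerics::width(ir) &
            w > 0.5 * BiocGenerics::width(kept_ir[S4Vectors::subjectHits(ov)])
          if (any(recip)) next
        }
      }
      keep[idx[j]] <- TRUE
      kept_ir <- c(kept_ir, ir)
    }
  }
  out <- records[keep, , drop = FALSE]
  out$class <- ifelse(out$unit_length < 10, "microsatellite",
                      ifelse(out$unit_length <= 100, "minisatellite",
                             "satellite"))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sliding-window covered-fraction density of interval hits
#'
#' One value per window start position 0, `step`, 2*`step`, ...; the value
#' is the fraction of window bases covered by (the union of) the hits.
#' Terminal windows truncated by the sequence end use their actual length.
#'
#' @param hits data frame `start`, `end` (0-based half-open) on one
#'   sequence.
#' @param seq_length sequence length in bp.
#' @param window,step window and step sizes in bp, `window >= step > 0`.
#' @return data frame `start`, `end`, `density`.
#' @export
density_track <- function(hits, seq_length, window = 100000, step = 10000) {
  stopifnot(window >= step, step > 0)
  starts <- seq(0L, max(0L, seq_length - 1L), by = step)
  ends <- pmin(starts + window, seq_length)
  hits_ir <- if (nrow(hits)) IRanges::reduce(df_to_iranges(hits))
             else IRanges::IRanges()
  cov <- vapply(seq_along(starts), function(i)
    covered_bases(hits_ir, starts[i], ends[i]), 0L)
  data.frame(start = starts, end = ends,
             density = cov / (ends - starts))
}

#' Call satellite arrays from window densities
#'
#' Windows whose satellite density strictly exceeds `threshold` are
#' selected; overlapping selected windows are merged; each merged interval
#' is then trimmed inward to the outermost satellite hit it contains, so
#' array boundaries are hit-level, not window-level. Windows containing no
#' hit after trimming yield no array.
#'
#' @param density data frame from [density_track()] built from `hits`.
#' @param hits the hit set (`start`, `end`) the density was built from.
#' @param threshold strict density threshold (default 0.10).
#' @param family family name attached to the calls.
#' @return data frame `family`, `start`, `end`, `satellite_bases`,
#'   `density` — one row per array.
#' @export
call_satellite_arrays <- function(density, hits, threshold = 0.10,
                                  family = "satellite") {
  sel <- density$density > threshold
  empty <- data.frame(family = character(), start = integer(),
                      end = integer(), satellite_bases = integer(),
                      density = numeric(), stringsAsFactors = FALSE)
  if (!any(sel)) return(empty)
  merged <- IRanges::reduce(df_to_iranges(density[sel, , drop = FALSE]))
  hits_ir <- IRanges::reduce(df_to_iranges(hits))
  rows <- lapply(seq_along(merged), function(i) {
    inside <- IRanges::intersect(hits_ir, merged[i])
    if (length(inside) == 0L) return(NULL)
    s <- min(BiocGenerics::start(inside)) - 1L
    e <- max(BiocGenerics::end(inside))
    data.frame(family = family, start = s, end = e,
               satellite_bases = sum(BiocGenerics::width(inside)),
               density = sum(BiocGenerics::width(inside)) / (e - s),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Call TE arrays in intergenic space
#'
#' Tiles sliding windows within each intergenic region, selects windows
#' whose TE covered fraction strictly exceeds `threshold`, merges them,
#' discards merged arrays containing any gene, and reports arrays at least
#' `min_length` long (`min_length = 0` reports all; the genome-survey
#' preset uses 700 kb).
#'
#' @param te data frame `start`, `end` of TE intervals on one sequence.
#' @param genes data frame `start`, `end` of gene intervals.
#' @param seq_length sequence length in bp.
#' @param window,step window/step sizes (default 100 kb / 10 kb).
#' @param threshold strict TE-fraction threshold (default 0.95).
#' @param min_length minimum reported array length (default 0).
#' @return data frame `start`, `end`, `length`.
#' @export
call_te_arrays <- function(te, genes, seq_length, window = 100000,
                           step = 10000, threshold = 0.95, min_length = 0) {
  gene_ir <- if (nrow(genes)) IRanges::reduce(df_to_iranges(genes))
             else IRanges::IRanges()
  intergenic <- IRanges::setdiff(IRanges::IRanges(1L, seq_length), gene_ir)
  te_ir <- if (nrow(te)) IRanges::reduce(df_to_iranges(te))
           else IRanges::IRanges()
  selected <- IRanges::IRanges()
  for (i in seq_along(intergenic)) {
    from <- BiocGenerics::start(intergenic[i]) - 1L
    to <- BiocGenerics::end(intergenic[i])
    if (to - from < 1L) next
    starts <- seq(from, to - 1L, by = step)
    ends <- pmin(starts + window, to)
    frac <- vapply(seq_along(starts), function(j)
      covered_bases(te_ir, starts[j], ends[j]) / (ends[j] - starts[j]), 0)
    ok <- frac > threshold
    if (any(ok))
      selected <- c(selected, IRanges::IRanges(starts[ok] + 1L, ends[ok]))
  }
  merged <- IRanges::reduce(selected)
  if (length(gene_ir) && length(merged)) {
    has_gene <- IRanges::overlapsAny(merged, gene_ir)
    merged <- merged[!has_gene]
  }
  merged <- merged[BiocGenerics::width(merged) >= min_length]
  out <- iranges_to_df(merged)
  out$length <- out$end - out$start
  out
}

#' Filter and merge nearly identical segmental duplications
#'
#' Self-alignment pairs with identity strictly over `min_identity` and
#' length strictly over `min_length` are retained (the trivial
#' self-identity diagonal must already be excluded); both intervals of
#' each surviving pair are projected onto the genome and overlapping or
#' book-ended intervals are merged.
#'
#' @param pairs data frame with columns `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`, `identity`, `length`.
#' @param min_identity strict identity threshold (default 0.99; an
#'   alternative survey convention uses 0.98).
#' @param min_length strict length threshold in bp (default 1000).
#' @return data frame `chrom`, `start`, `end` of merged duplication
#'   intervals.
#' @export
merge_segmental_duplications <- function(pairs, min_identity = 0.99,
                                         min_length = 1000) {
  keep <- pairs$identity > min_identity & pairs$length > min_length
  pairs <- pairs[keep, , drop = FALSE]
  iv <- rbind(
    data.frame(chrom = pairs$chrom1, start = pairs$start1, end = pairs$end1),
    data.frame(chrom = pairs$chrom2, start = pairs$start2, end = pairs$end2))
  if (!nrow(iv))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  out <- lapply(split(iv, iv$chrom), function(d) {
    ir <- IRanges::reduce(df_to_iranges(d), min.gapwidth = 1L)
    iranges_to_df(ir, chrom = d$chrom[1])
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
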