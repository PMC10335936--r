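#' Filter alignment records by SAM flag and query coverage
#'
#' Keeps only primary and supplementary alignments (SAM flags 0, 16, 2048,
#' 2064 by default — secondary alignments are dropped regardless of
#' coverage), then retains a read's record set only if the union of its
#' query intervals covers at least `min_query_coverage` of the read length.
#' Each read base counts once even when alignments overlap on the read.
#'
#' @param records alignment record data frame with columns `read_id`,
#'   `read_length`, `flag`, `chrom`, `target_start`, `target_end`,
#'   `query_start`, `query_end`, `strand` (intervals 0-based half-open,
#'   query intervals in read orientation).
#' @param allowed_flags SAM flags to retain.
#' @param min_query_coverage minimum union query coverage in `(0, 1]`.
#' @return list with `retained` (records of retained reads), `coverage`
#'   (per-read union query coverage over all flag-passing records) and
#'   `rejected` (malformed records dropped, with reasons).
#' @export
filter_alignments <- function(records,
                              allowed_flags = c(0L, 16L, 2048L, 2064L),
                              min_query_coverage = 0.85) {
  stopifnot(min_query_coverage > 0, min_query_coverage <= 1)
  bad <- is.na(records$query_start) | is.na(records$query_end) |
    records$query_start < 0 | records$query_end > records$read_length |
    records$query_start >= records$query_end
  rejected <- records[bad, , drop = FALSE]
  if (nrow(rejected))
    rejected$reason <- "malformed query interval"
  records <- records[!bad, , drop = FALSE]
  records <- records[records$flag %in% allowed_flags, , drop = FALSE]
  cov <- query_union_coverage(records)
  keep_ids <- names(cov)[cov >= min_query_coverage]
  list(retained = records[records$read_id %in% keep_ids, , drop = FALSE],
       coverage = cov, rejected = rejected)
}

# union query coverage per read (fraction of read length)
query_union_coverage <- function(records) {
  if (nrow(records) == 0L) return(setNames(numeric(0), character(0)))
  sp <- split(records, records$read_id)
  vapply(sp, function(r) {
    ir <- IRanges::reduce(IRanges::IRanges(r$query_start + 1L, r$query_end))
    sum(BiocGenerics::width(ir)) / r$read_length[1]
  }, 0)
}

# identity between the two halves of a read under reverse complementation:
# fraction of matching bases between half 1 and revcomp(half 2) over the
# shorter half
symmetry_identity <- function(read_seq) {
  n <- nchar(read_seq)
  half <- n %/% 2L
  a <- strsplit(substr(read_seq, 1L, half), "")[[1]]
  b <- revcomp_chars(strsplit(substr(read_seq, n - half + 1L, n), "")[[1]])
  mean(a == b)
}

#' Classify long reads as proper, fused, symmetrical or other
#'
#' Mirrors the assembly-validation criteria used for ultralong-read QC:
#'
#' * `proper` — flag-passing alignments cover >= `min_query_coverage` of
#'   the read and all fall in one genomic neighborhood (single target
#'   sequence, target-interval gaps <= `neighborhood_gap`);
#' * `symmetrical` — the read divides into two parts that are reverse
#'   complements of each other (identity >= `symmetry_identity_min` over
#'   the shorter half) and both parts align to the same genomic region,
#'   with joint query coverage >= `min_query_coverage`;
#' * `fused` — coverage passes but alignments land in two or more distant
#'   genomic regions;
#' * `unmapped_or_other` — everything else (no alignments, or coverage
#'   short of the threshold, e.g. chimeric reads with junk sequence).
#'
#' @param records alignment record data frame (see [filter_alignments()]);
#'   flag filtering is applied internally.
#' @param reads named character vector of read sequences (needed for the
#'   symmetry identity check); reads absent from `records` are classified
#'   `unmapped_or_other`.
#' @param min_query_coverage union query-coverage threshold.
#' @param neighborhood_gap maximum target gap (bp) between split
#'   alignments still considered one genomic neighborhood.
#' @param symmetry_identity_min minimum reverse-complement identity
#'   between the two halves of a symmetrical read.
#' @param allowed_flags SAM flags to retain.
#' @return data frame `read_id`, `class`, `coverage`.
#' @export
classify_reads <- function(records, reads,
                           min_query_coverage = 0.85,
                           neighborhood_gap = 100000,
                           symmetry_identity_min = 0.95,
                           allowed_flags = c(0L, 16L, 2048L, 2064L)) {
  records <- records[records$flag %in% allowed_flags, , drop = FALSE]
  ids <- names(reads)
  cls <- setNames(rep("unmapped_or_other", length(ids)), ids)
  cov_all <- setNames(numeric(length(ids)), ids)
  sp <- split(records, records$read_id)
  for (id in intersect(names(sp), ids)) {
    r <- sp[[id]]
    cov <- query_union_coverage(r)[[1]]
    cov_all[id] <- cov
    if (cov < min_query_coverage) next
    cls[id] <- classify_one(r, reads[[id]], neighborhood_gap,
                            symmetry_identity_min)
  }
  data.frame(read_id = ids, class = unname(cls[ids]),
             coverage = unname(cov_all[ids]), stringsAsFactors = FALSE)
}

classify_one <- function(r, read_seq, neighborhood_gap, sym_min) {
  one_chrom <- length(unique(r$chrom)) == 1L
  if (one_chrom && nrow(r) >= 2L && length(unique(r$strand)) == 2L) {
    # candidate symmetrical: opposite-strand records over one region
    plus <- r[r$strand == "+", , drop = FALSE]
    minus <- r[r$strand == "-", , drop = FALSE]
    ov <- min(max(plus$target_end), max(minus$target_end)) -
      max(min(plus$target_start), min(minus$target_start))
    shorter <- min(max(plus$target_end) - min(plus$target_start),
                   max(minus$target_end) - min(minus$target_start))
    if (ov > 0.5 * shorter && !is.null(read_seq) &&
        symmetry_identity(read_seq) >= sym_min)
      return("symmetrical")
  }
  if (one_chrom) {
    o <- order(r$target_start)
    gaps <- r$target_start[o][-1] - pmax(cummax(r$target_end[o]))[-nrow(r)]
    if (all(gaps <= neighborhood_gap)) return("proper")
  }
  "fused"
}

#' Binned read-depth track from retained alignments
#'
#' Per-base depth is the number of retained target intervals covering the
#' base; bin values are means over the bases in each fixed-width bin, with
#' the terminal partial bin averaged over its actual length.
#'
#' @param records retained alignment records (see [filter_alignments()]).
#' @param seq_lengths named vector of sequence lengths.
#' @param bin_width bin width in bp (default 1 kb).
#' @return binned track data frame (`chrom`, `start`, `end`, `value`) with
#'   attribute `bin_width`.
#' @export
depth_track <- function(records, seq_lengths, bin_width = 1000) {
  stopifnot(bin_width > 0)
  if (nrow(records) &&
      any(records$target_end > seq_lengths[records$chrom] |
          records$target_start < 0)) {
    i <- which(records$target_end > seq_lengths[records$chrom] |
                 records$target_start < 0)[1]
    stop(sprintf("alignment beyond sequence end: read %s on %s [%d, %d)",
                 records$read_id[i], records$chrom[i],
                 records$target_start[i], records$target_end[i]),
         call. = FALSE)
  }
  rows <- lapply(names(seq_lengths), function(cname) {
    L <- as.integer(seq_lengths[[cname]])
    r <- records[records$chrom == cname, , drop = FALSE]
    cov <- IRanges::coverage(
      IRanges::IRanges(r$target_start + 1L, r$target_end), width = L)
    starts <- seq(0L, L - 1L, by = bin_width)
    ends <- pmin(starts + bin_width, L)
    v <- IRanges::Views(cov, start = starts + 1L, end = ends)
    data.frame(chrom = cname, start = starts, end = ends,
               value = IRanges::viewMeans(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bin_width") <- bin_width
  out
}

#' Call low- and high-coverage regions from a binned depth track
#'
#' Bins with depth strictly below `low_threshold` are low-coverage regions
#' (LCRs); bins strictly above `high_threshold` are high-coverage regions
#' (HCRs); adjacent bins of the same kind are merged into maximal
#' intervals. Default thresholds follow the ultralong-ONT profile
#' (100, 250); the HiFi profile uses (20, 105).
#'
#' @param track binned track data frame from [depth_track()].
#' @param low_threshold,high_threshold strict depth thresholds,
#'   `low_threshold < high_threshold`.
#' @param profile convenience preset: `"ont"` sets (100, 250), `"hifi"`
#'   sets (20, 105); explicit thresholds win.
#' @return data frame `chrom`, `start`, `end`, `kind` (`"LCR"`/`"HCR"`).
#' @export
call_coverage_anomalies <- function(track, low_threshold = NULL,
                                    high_threshold = NULL,
                                    profile = c("ont", "hifi")) {
  profile <- match.arg(profile)
  defaults <- if (profile == "ont") c(100, 250) else c(20, 105)
  if (is.null(low_threshold)) low_threshold <- defaults[1]
  if (is.null(high_threshold)) high_threshold <- defaults[2]
  stopifnot(low_threshold < high_threshold)
  out <- lapply(split(track, track$chrom), function(tr) {
    tr <- tr[order(tr$start), , drop = FALSE]
    res <- list()
    for (kind in c("LCR", "HCR")) {
      sel <- if (kind == "LCR") tr$value < low_threshold
             else tr$value > high_threshold
      if (!any(sel)) next
      ir <- IRanges::reduce(df_to_iranges(tr[sel, , drop = FALSE]))
      res[[kind]] <- cbind(iranges_to_df(ir, chrom = tr$chrom[1]),
                           data.frame(kind = kind))
    }
    if (length(res)) do.call(rbind, res) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), kind = character()))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
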