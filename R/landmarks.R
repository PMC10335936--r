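# positions (1-based starts) of a fixed motif in a sequence
motif_starts <- function(seq, motif) {
  m <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# chain motif matches anchored at one terminus, tolerating interruptions
# up to max_interruption bases; returns NULL or list(first, last, copies)
# over 1-based closed match coordinates
terminal_run <- function(starts, motif_len, seq_len, side, max_interruption) {
  if (!length(starts)) return(NULL)
  ends <- starts + motif_len - 1L
  if (side == "end") {
    if (seq_len - ends[length(ends)] > max_interruption) return(NULL)
    i <- length(starts)
    while (i > 1L && starts[i] - ends[i - 1L] - 1L <= max_interruption)
      i <- i - 1L
    list(first = starts[i], last = ends[length(ends)],
         copies = length(starts) - i + 1L)
  } else {
    if (starts[1] - 1L > max_interruption) return(NULL)
    i <- 1L
    while (i < length(starts) && starts[i + 1L] - ends[i] - 1L <= max_interruption)
      i <- i + 1L
    list(first = starts[1], last = ends[i], copies = i)
  }
}

#' Detect telomeres at both ends of each sequence
#'
#' Scans from each terminus for a tandem run of the telomeric motif
#' (default plant telomere TTTAGGG), allowing interruptions up to
#' `max_interruption` bases, and requiring at least `min_copies` motif
#' copies. Correct orientation places the G-rich strand running off the
#' end: the forward motif at the right terminus and its reverse
#' complement (CCCTAAA) at the left. A qualifying run of the
#' wrong-strand motif is still called, with `orientation_ok = FALSE`.
#'
#' @param sequences named character vector (or `DNAStringSet`) of
#'   chromosome sequences.
#' @param motif telomeric repeat motif, G-rich strand (default
#'   `"TTTAGGG"`).
#' @param max_interruption maximum non-motif gap (bp) inside a run and
#'   between the run and the terminus (default 50).
#' @param min_copies minimum motif copies for a call (default 10).
#' @return data frame: `chrom`, `chrom_end` (`"start"`/`"end"`),
#'   `start`, `end` (0-based half-open), `copies`, `length`,
#'   `orientation_ok`. Ends without a qualifying run produce no row.
#' @export
detect_telomeres <- function(sequences, motif = "TTTAGGG",
                             max_interruption = 50, min_copies = 10) {
  stopifnot(nzchar(motif))
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  rc <- revcomp(motif)
  mlen <- nchar(motif)
  rows <- list()
  for (cname in names(sequences)) {
    s <- toupper(sequences[[cname]])
    L <- nchar(s)
    fwd <- motif_starts(s, motif)
    rev_ <- motif_starts(s, rc)
    for (side in c("start", "end")) {
      expected <- if (side == "end") fwd else rev_
      wrong <- if (side == "end") rev_ else fwd
      run <- terminal_run(expected, mlen, L, side, max_interruption)
      ok <- TRUE
      if (is.null(run) || run$copies < min_copies) {
        run <- terminal_run(wrong, mlen, L, side, max_interruption)
        ok <- FALSE
      }
      if (is.null(run) || run$copies < min_copies) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cname, chrom_end = side,
        start = run$first - 1L, end = run$last,
        copies = run$copies, length = run$last - run$first + 1L,
        orientation_ok = ok, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), chrom_end = character(),
                      start = integer(), end = integer(),
                      copies = integer(), length = integer(),
                      orientation_ok = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Call subtelomeres from subtelomeric-repeat hit density
#'
#' From the telomere-proximal side of each chromosome end, grows the
#' subtelomere over fixed windows whose hit density (covered fraction,
#' any family) is at least `min_density`, tolerating low-density gaps up
#' to `max_gap` bases, then trims the call to the outermost hits. Ends
#' without nearby hits yield no call.
#'
#' @param hits data frame `chrom`, `start`, `end`, `family` of
#'   subtelomeric-repeat hits.
#' @param seq_lengths named vector of sequence lengths.
#' @param telomeres data frame from [detect_telomeres()] (anchors the
#'   growth at the inner telomere edge); may be empty, in which case the
#'   terminus itself is the anchor.
#' @param window window width in bp (default 10 kb).
#' @param min_density minimum covered fraction per window (default 0.30).
#' @param max_gap maximum run of sub-threshold sequence tolerated inside
#'   a subtelomere (default 50 kb).
#' @return data frame: `chrom`, `chrom_end`, `start`, `end`, `length`,
#'   plus one `frac_<family>` column per hit family (covered fraction of
#'   the call) and `family_ratio` (first family bases / second family
#'   bases, `NA` when fewer than two families are present).
#' @export
call_subtelomeres <- function(hits, seq_lengths, telomeres = NULL,
                              window = 10000, min_density = 0.30,
                              max_gap = 50000) {
  families <- sort(unique(hits$family))
  rows <- list()
  for (cname in names(seq_lengths)) {
    L <- as.integer(seq_lengths[[cname]])
    h <- hits[hits$chrom == cname, , drop = FALSE]
    if (!nrow(h)) next
    h_ir <- IRanges::reduce(df_to_iranges(h))
    for (side in c("start", "end")) {
      anchor <- if (side == "start") 0L else L
      if (!is.null(telomeres) && nrow(telomeres)) {
        t <- telomeres[telomeres$chrom == cname &
                         telomeres$chrom_end == side, , drop = FALSE]
        if (nrow(t)) anchor <- if (side == "start") t$end[1] else t$start[1]
      }
      # windows marching inward from the anchor
      n_win <- ceiling((if (side == "start") L - anchor else anchor) / window)
      if (n_win < 1L) next
      included_to <- 0L  # distance from anchor up to which we include
      gap_run <- 0L
      for (w in seq_len(n_win)) {
        if (side == "start") {
          from <- anchor + (w - 1L) * window
          to <- min(anchor + w * window, L)
        } else {
          to <- anchor - (w - 1L) * window
          from <- max(anchor - w * window, 0L)
        }
        if (to <= from) break
        dens <- covered_bases(h_ir, from, to) / (to - from)
        if (dens >= min_density) {
          included_to <- if (side == "start") to - anchor else anchor - from
          gap_run <- 0L
        } else {
          gap_run <- gap_run + (to - from)
          if (gap_run > max_gap) break
        }
      }
      if (included_to == 0L) next
      span <- if (side == "start")
        IRanges::IRanges(anchor + 1L, anchor + included_to)
      else IRanges::IRanges(anchor - included_to + 1L, anchor)
      inside <- IRanges::intersect(h_ir, span)
      if (!length(inside)) next
      s <- min(BiocGenerics::start(inside)) - 1L
      e <- max(BiocGenerics::end(inside))
      row <- data.frame(chrom = cname, chrom_end = side, start = s, end = e,
                        length = e - s, stringsAsFactors = FALSE)
      fam_bases <- vapply(families, function(f) {
        f_ir <- df_to_iranges(h[h$family == f, , drop = FALSE])
        covered_bases(IRanges::reduce(f_ir), s, e)
      }, 0L)
      for (f in families)
        row[[paste0("frac_", f)]] <- fam_bases[[f]] / (e - s)
      row$family_ratio <- if (length(families) >= 2L)
        fam_bases[[1]] / fam_bases[[2]] else NA_real_
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), chrom_end = character(),
                      start = integer(), end = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call centromeres from a binned CENH3 enrichment track
#'
#' Bins with enrichment strictly greater than `threshold` are retained;
#' retained bins separated by less than `merge_gap` are merged; merged
#' intervals shorter than `min_length` are dropped (an explicit stand-in
#' for the manual end-point inspection used in genome surveys).
#'
#' @param track binned enrichment track (`chrom`, `start`, `end`,
#'   `value`), conventionally 1 kb bins.
#' @param threshold strict enrichment threshold (default 5).
#' @param merge_gap merge retained bins closer than this (default 1 Mb).
#' @param min_length minimum reported centromere length (default 100 kb).
#' @return data frame `chrom`, `start`, `end`, `length`.
#' @export
call_centromeres <- function(track, threshold = 5, merge_gap = 1e6,
                             min_length = 1e5) {
  out <- lapply(split(track, track$chrom), function(tr) {
    sel <- tr$value > threshold
    if (!any(sel)) return(NULL)
    ir <- IRanges::reduce(df_to_iranges(tr[sel, , drop = FALSE]),
                          min.gapwidth = merge_gap)
    ir <- ir[BiocGenerics::width(ir) >= min_length]
    if (!length(ir)) return(NULL)
    iranges_to_df(ir, chrom = tr$chrom[1])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer()))
  out$length <- out$end - out$start
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Repeat composition and CentC typing of centromere calls
#'
#' Computes, per centromere call, the covered base fraction of each
#' annotated repeat family, and types the centromere `CentC-rich` when
#' CentC-array coverage of the call reaches `rich_threshold`, else
#' `CentC-poor` (satellite-free centromeres type as poor with zero CentC).
#'
#' @param calls centromere calls from [call_centromeres()].
#' @param annotations data frame `chrom`, `start`, `end`, `family` of
#'   repeat annotations (e.g. CentC, CRM, Gypsy).
#' @param centc_arrays data frame `chrom`, `start`, `end` of CentC array
#'   intervals used for typing.
#' @param rich_threshold CentC-array coverage fraction for the rich type
#'   (default 0.50).
#' @return `calls` with one `frac_<family>` column per family, plus
#'   `centc_array_coverage` and `type`.
#' @export
centromere_composition <- function(calls, annotations, centc_arrays,
                                   rich_threshold = 0.50) {
  if (!nrow(calls)) return(calls)
  families <- sort(unique(annotations$family))
  for (f in families) calls[[paste0("frac_", f)]] <- 0
  calls$centc_array_coverage <- 0
  for (i in seq_len(nrow(calls))) {
    w <- calls$end[i] - calls$start[i]
    for (f in families) {
      a <- annotations[annotations$chrom == calls$chrom[i] &
                         annotations$family == f, , drop = FALSE]
      calls[[paste0("frac_", f)]][i] <-
        covered_bases(IRanges::reduce(df_to_iranges(a)),
                      calls$start[i], calls$end[i]) / w
    }
    ca <- centc_arrays[centc_arrays$chrom == calls$chrom[i], , drop = FALSE]
    calls$centc_array_coverage[i] <- if (nrow(ca))
      covered_bases(IRanges::reduce(df_to_iranges(ca)),
                    calls$start[i], calls$end[i]) / w else 0
  }
  calls$type <- ifelse(calls$centc_array_coverage >= rich_threshold,
                       "CentC-rich", "CentC-poor")
  calls
}
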