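#' Simulate long reads with controlled artifact fractions
#'
#' Draws read lengths from a log-normal distribution clipped to
#' `[min_length, shortest chromosome]` (ultralong-read analyses conventionally
#' use reads longer than 10 kb) and assigns each read one of four classes:
#'
#' * `proper` — one contiguous genomic segment, either strand;
#' * `fused` — two segments from distant genomic origins concatenated,
#'   mimicking library fusion artifacts;
#' * `symmetrical` — a segment followed by its own reverse complement,
#'   mimicking in-pore re-reading artifacts;
#' * `chimeric` — a genomic segment followed by junk sequence absent from
#'   the genome.
#'
#' @param genome a `synthetic_genome` or named character vector.
#' @param n_reads number of reads; if `NULL`, derived from `depth` as
#'   `depth * genome length / mean read length`.
#' @param depth target fold-coverage (used only when `n_reads` is `NULL`).
#' @param artifact_rates named fractions for `fused`, `symmetrical`,
#'   `chimeric`; must sum to < 1, the remainder being proper reads.
#' @param length_meanlog,length_sdlog log-normal read-length parameters
#'   (defaults give a ~15 kb median).
#' @param min_length minimum read length (bp).
#' @param min_separation minimum genomic distance between the two origins
#'   of a fused read when both land on one chromosome.
#' @param seed integer RNG seed.
#' @return list with `reads` (named character vector of read sequences) and
#'   `truth`, itself a list of `classes` (read id, class, length) and
#'   `segments` (per genomic segment: read id, segment index, chrom,
#'   0-based half-open target interval, strand, and the 0-based half-open
#'   span on the read). Junk halves of chimeric reads have no segment row.
#' @export
simulate_reads <- function(genome, n_reads = NULL, depth = 20,
                           artifact_rates = c(fused = 0, symmetrical = 0,
                                              chimeric = 0),
                           length_meanlog = log(15000), length_sdlog = 0.3,
                           min_length = 10000, min_separation = 500000,
                           seed = 1L) {
  seqs <- if (inherits(genome, "synthetic_genome")) genome$sequences else genome
  lens <- nchar(seqs)
  rates <- c(fused = 0, symmetrical = 0, chimeric = 0)
  rates[names(artifact_rates)] <- artifact_rates
  if (sum(rates) >= 1) stop("artifact fractions must sum to < 1", call. = FALSE)
  max_len <- min(lens)
  if (min_length > max_len)
    stop("minimum read length exceeds shortest chromosome", call. = FALSE)

  with_seed(seed, {
    if (is.null(n_reads)) {
      mean_len <- exp(length_meanlog + length_sdlog^2 / 2)
      n_reads <- max(1L, round(depth * sum(lens) / mean_len))
    }
    rl <- round(rlnorm(n_reads, length_meanlog, length_sdlog))
    rl <- pmin(pmax(rl, min_length), max_len)
    cls <- sample(c("proper", names(rates)), n_reads, replace = TRUE,
                  prob = c(1 - sum(rates), rates))
    ids <- sprintf("read_%05d", seq_len(n_reads))

    draw_segment <- function(len) {
      ci <- sample(length(seqs), 1L, prob = lens)
      s <- sample(lens[ci] - len + 1L, 1L) - 1L
      list(chrom = names(seqs)[ci], start = s, end = s + len)
    }
    seg_seq <- function(sg, strand) {
      x <- substr(seqs[[sg$chrom]], sg$start + 1L, sg$end)
      if (strand == "-") revcomp(x) else x
    }

    reads <- character(n_reads)
    seg_rows <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      L <- rl[i]
      if (cls[i] == "proper") {
        sg <- draw_segment(L)
        strand <- sample(c("+", "-"), 1L)
        reads[i] <- seg_seq(sg, strand)
        seg_rows[[i]] <- data.frame(read_id = ids[i], segment = 1L,
                                    chrom = sg$chrom, start = sg$start,
                                    end = sg$end, strand = strand,
                                    read_start = 0L, read_end = L,
                                    stringsAsFactors = FALSE)
      } else if (cls[i] == "fused") {
        l1 <- floor(L / 2); l2 <- L - l1
        repeat {
          a <- draw_segment(l1); b <- draw_segment(l2)
          if (a$chrom != b$chrom ||
              max(a$start, b$start) - min(a$end, b$end) >= min_separation)
            break
        }
        sa <- sample(c("+", "-"), 1L); sb <- sample(c("+", "-"), 1L)
        reads[i] <- paste0(seg_seq(a, sa), seg_seq(b, sb))
        seg_rows[[i]] <- data.frame(
          read_id = ids[i], segment = 1:2,
          chrom = c(a$chrom, b$chrom), start = c(a$start, b$start),
          end = c(a$end, b$end), strand = c(sa, sb),
          read_start = c(0L, l1), read_end = c(l1, L),
          stringsAsFactors = FALSE)
      } else if (cls[i] == "symmetrical") {
        half <- floor(L / 2); L <- 2L * half; rl[i] <- L
        sg <- draw_segment(half)
        fwd <- seg_seq(sg, "+")
        reads[i] <- paste0(fwd, revcomp(fwd))
        seg_rows[[i]] <- data.frame(
          read_id = ids[i], segment = 1:2,
          chrom = sg$chrom, start = sg$start, end = sg$end,
          strand = c("+", "-"),
          read_start = c(0L, half), read_end = c(half, L),
          stringsAsFactors = FALSE)
      } else { # chimeric: genomic half + junk half
        l1 <- floor(L / 2)
        sg <- draw_segment(l1)
        strand <- sample(c("+", "-"), 1L)
        reads[i] <- paste0(seg_seq(sg, strand), random_dna(L - l1))
        seg_rows[[i]] <- data.frame(read_id = ids[i], segment = 1L,
                                    chrom = sg$chrom, start = sg$start,
                                    end = sg$end, strand = strand,
                                    read_start = 0L, read_end = l1,
                                    stringsAsFactors = FALSE)
      }
    }
    names(reads) <- ids
    list(reads = reads,
         truth = list(
           classes = data.frame(read_id = ids, class = cls, length = rl,
                                stringsAsFactors = FALSE),
           segments = do.call(rbind, seg_rows)))
  })
}

#' Alignment records from simulated-read truth
#'
#' Converts the truth segments of [simulate_reads()] into the alignment
#' record table consumed by the read-validation module, as an exact-origin
#' placement: each genomic segment becomes one record, the first as the
#' primary alignment (SAM flag 0/16 by strand) and the rest as
#' supplementary alignments (flag 2048/2064). Junk segments of chimeric
#' reads produce no record, so such reads fall below the query-coverage
#' filter exactly as an aligner would leave them.
#'
#' @param read_truth the `truth` element returned by [simulate_reads()].
#' @return data frame of alignment records: `read_id`, `read_length`,
#'   `flag`, `chrom`, `target_start`, `target_end`, `query_start`,
#'   `query_end`, `strand` (intervals 0-based half-open).
#' @export
alignments_from_truth <- function(read_truth) {
  seg <- read_truth$segments
  len <- setNames(read_truth$classes$length, read_truth$classes$read_id)
  flag <- ifelse(seg$segment == 1L,
                 ifelse(seg$strand == "-", 16L, 0L),
                 ifelse(seg$strand == "-", 2064L, 2048L))
  data.frame(read_id = seg$read_id,
             read_length = as.integer(len[seg$read_id]),
             flag = flag, chrom = seg$chrom,
             target_start = seg$start, target_end = seg$end,
             query_start = seg$read_start, query_end = seg$read_end,
             strand = seg$strand, stringsAsFactors = FALSE)
}

#' Simulate a binned enrichment track (e.g. CENH3 ChIP ratio)
#'
#' Bin means are centred on `inside_level` within the given truth intervals
#' and on `outside_level` elsewhere, with Gaussian noise truncated at zero.
#' Bins straddling an interval boundary take the level covering the larger
#' part of the bin.
#'
#' @param genome a `synthetic_genome` or named character vector (only
#'   sequence lengths are used).
#' @param centromere_truth data frame `chrom`, `start`, `end` (0-based
#'   half-open) of enriched intervals; may have zero rows.
#' @param inside_level,outside_level mean enrichment inside/outside the
#'   truth intervals; `inside_level > outside_level >= 0` required.
#' @param noise_sd Gaussian noise standard deviation.
#' @param bin_width bin width in bp (> 0).
#' @param seed integer RNG seed.
#' @return a binned track data frame (`chrom`, `start`, `end`, `value`)
#'   with attribute `bin_width`.
#' @export
simulate_enrichment_track <- function(genome, centromere_truth,
                                      inside_level, outside_level,
                                      noise_sd = 0, bin_width = 1000,
                                      seed = 1L) {
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  if (!(inside_level > outside_level && outside_level >= 0))
    stop("require inside_level > outside_level >= 0", call. = FALSE)
  seqs <- if (inherits(genome, "synthetic_genome")) genome$sequences else genome
  lens <- nchar(seqs)
  with_seed(seed, {
    rows <- lapply(seq_along(lens), function(ci) {
      L <- lens[ci]; cname <- names(lens)[ci]
      starts <- seq(0L, L - 1L, by = bin_width)
      ends <- pmin(starts + bin_width, L)
      level <- rep(outside_level, length(starts))
      ct <- centromere_truth[centromere_truth$chrom == cname, , drop = FALSE]
      if (nrow(ct)) {
        ir <- df_to_iranges(ct)
        ov <- IRanges::findOverlaps(IRanges::IRanges(starts + 1L, ends), ir)
        if (length(ov)) {
          w <- BiocGenerics::width(IRanges::pintersect(
            IRanges::IRanges(starts + 1L, ends)[S4Vectors::queryHits(ov)],
            ir[S4Vectors::subjectHits(ov)]))
          covered <- tapply(w, S4Vectors::queryHits(ov), sum)
          idx <- as.integer(names(covered))
          inside <- idx[covered > (ends - starts)[idx] / 2]
          level[inside] <- inside_level
        }
      }
      value <- level
      if (noise_sd > 0) value <- pmax(0, value + rnorm(length(value), 0, noise_sd))
      data.frame(chrom = cname, start = starts, end = ends, value = value,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "bin_width") <- bin_width
    out
  })
}
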