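#' Configuration for the synthetic miniature genome
#'
#' Describes a miniature genome with planted repeat architecture: satellite
#' arrays (e.g. CentC-, knob180- or TR-1-like), one rDNA-like tandem array
#' with a known genotype mixture and optional inversion block, oriented
#' telomeric repeats, subtelomeric repeat blocks and a synthetic LTR-like
#' transposable-element background. Every planted feature is emitted to a
#' truth set so downstream callers can be scored against a known answer.
#'
#' @param chromosome_lengths numeric vector of chromosome lengths in bp;
#'   names become sequence names (default `chr1`, `chr2`, ...).
#' @param satellite_specs list of satellite array specs, each a list with
#'   `family` (character), `monomer` (DNA string), `copies` (integer),
#'   `mut_rate` (per-base substitution rate per copy, default 0), `chrom`
#'   (index, default 1), `pos` (0-based start offset) and `strand`
#'   (`"+"`/`"-"`, default `"+"`).
#' @param rdna_spec optional rDNA array spec: a list with `chrom`, `pos`,
#'   `unit` (reference unit sequence), `copies`, `haplotypes` (list of
#'   lists with `name`, `snps` = named character vector mapping 1-based
#'   unit positions to alternative bases, and `dels` = list of
#'   `list(pos, len)` deletions), `mixture` (fractions summing to 1, one
#'   per haplotype), `inversion_copies` (optional `c(from, to)` copy index
#'   range placed in inverted orientation), `te_insertions` (count of TE
#'   segments inserted between copies, default 0), `te_length` (default
#'   2000) and `label` (default `"rdna"`).
#' @param telomere_specs optional list with `copies_start` and `copies_end`
#'   (telomeric repeat copy counts per end, recycled across chromosomes).
#'   The repeat motif is the plant telomere TTTAGGG; repeats are oriented
#'   so the G-rich strand runs off each chromosome end.
#' @param subtelomere_specs list of subtelomeric block specs, each a list
#'   with `family`, `motif` (repeat unit sequence), `copies`, `chrom`,
#'   `end` (`"start"` or `"end"`) and `mut_rate` (default 0). Blocks are
#'   placed immediately internal to the telomere of that end.
#' @param te_background_fraction fraction of each chromosome tiled with
#'   motifs from a small synthetic LTR-like pool before planting features.
#' @param seed integer RNG seed; identical config + seed gives
#'   byte-identical output.
#' @return an object of class `synthetic_genome_config`.
#' @export
synthetic_genome_config <- function(chromosome_lengths,
                                    satellite_specs = list(),
                                    rdna_spec = NULL,
                                    telomere_specs = NULL,
                                    subtelomere_specs = list(),
                                    te_background_fraction = 0,
                                    seed = 1L) {
  stopifnot(is.numeric(chromosome_lengths), all(chromosome_lengths > 0))
  if (is.null(names(chromosome_lengths)))
    names(chromosome_lengths) <- paste0("chr", seq_along(chromosome_lengths))
  if (!is.null(rdna_spec)) {
    mix <- rdna_spec$mixture
    if (abs(sum(mix) - 1) > 1e-9)
      stop("rDNA haplotype mixture fractions must sum to 1", call. = FALSE)
    if (length(mix) != length(rdna_spec$haplotypes))
      stop("one mixture fraction per haplotype required", call. = FALSE)
  }
  if (te_background_fraction < 0 || te_background_fraction >= 1)
    stop("te_background_fraction must be in [0, 1)", call. = FALSE)
  structure(list(chromosome_lengths = chromosome_lengths,
                 satellite_specs = satellite_specs,
                 rdna_spec = rdna_spec,
                 telomere_specs = telomere_specs,
                 subtelomere_specs = subtelomere_specs,
                 te_background_fraction = te_background_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_genome_config")
}

# tandem array of `copies` copies of `monomer`, each copy independently hit
# by per-base substitutions at `mut_rate`; returns a character vector of bases
tandem_block_chars <- function(monomer, copies, mut_rate = 0) {
  unit <- strsplit(toupper(monomer), "")[[1]]
  chars <- rep.int(unit, copies)
  if (mut_rate > 0) {
    hit <- which(runif(length(chars)) < mut_rate)
    if (length(hit)) chars[hit] <- substitute_bases(chars[hit])
  }
  chars
}

# synthetic LTR-like motif pool (3-5 motifs, 400-2500 bp)
te_motif_pool <- function(n_motifs = 4L) {
  lens <- round(runif(n_motifs, 400, 2500))
  lapply(lens, function(L) strsplit(random_dna(L), "")[[1]])
}

# build the rDNA array: returns list(chars, copies_df, msa, array_label)
build_rdna_array <- function(spec, chrom_name) {
  unit <- strsplit(toupper(spec$unit), "")[[1]]
  u <- length(unit)
  n <- spec$copies
  hap_names <- vapply(spec$haplotypes, `[[`, "", "name")
  hap_idx <- sample(seq_along(spec$haplotypes), n, replace = TRUE,
                    prob = spec$mixture)
  # gapped rows over the reference unit's column space (deletions only)
  msa <- matrix("", nrow = n, ncol = u)
  for (i in seq_len(n)) {
    hp <- spec$haplotypes[[hap_idx[i]]]
    row <- unit
    if (length(hp$snps)) {
      pos <- as.integer(names(hp$snps))
      row[pos] <- toupper(unname(hp$snps))
    }
    for (d in hp$dels) row[seq(d$pos, length.out = d$len)] <- "-"
    msa[i, ] <- row
  }
  rownames(msa) <- sprintf("copy_%04d", seq_len(n))
  inv <- rep(FALSE, n)
  if (!is.null(spec$inversion_copies)) {
    rng <- spec$inversion_copies
    if (rng[1] < 1 || rng[2] > n || rng[1] > rng[2])
      stop("inversion_copies out of range", call. = FALSE)
    inv[seq(rng[1], rng[2])] <- TRUE
  }
  te_n <- if (is.null(spec$te_insertions)) 0L else spec$te_insertions
  te_len <- if (is.null(spec$te_length)) 2000L else spec$te_length
  te_after <- if (te_n > 0) sort(sample(seq_len(n - 1L), te_n)) else integer()
  # copy order: an inversion block is reversed as a whole
  order_idx <- seq_len(n)
  if (any(inv)) {
    blk <- which(inv)
    order_idx[blk] <- rev(blk)
  }
  chars <- character(0)
  copies_df <- data.frame(copy_id = character(n), chrom = chrom_name,
                          start = NA_integer_, end = NA_integer_,
                          strand = NA_character_, genotype = NA_character_,
                          stringsAsFactors = FALSE)
  offset <- 0L
  te_truth <- list()
  for (slot in seq_len(n)) {
    i <- order_idx[slot]
    seq_i <- msa[i, ][msa[i, ] != "-"]
    if (inv[i]) seq_i <- revcomp_chars(seq_i)
    copies_df$copy_id[i] <- rownames(msa)[i]
    copies_df$start[i] <- offset
    copies_df$end[i] <- offset + length(seq_i)
    copies_df$strand[i] <- if (inv[i]) "-" else "+"
    copies_df$genotype[i] <- hap_names[hap_idx[i]]
    chars <- c(chars, seq_i)
    offset <- offset + length(seq_i)
    if (slot %in% te_after) {
      te_seq <- strsplit(random_dna(te_len), "")[[1]]
      te_truth[[length(te_truth) + 1L]] <- c(offset, offset + te_len)
      chars <- c(chars, te_seq)
      offset <- offset + te_len
    }
  }
  list(chars = chars, copies = copies_df, msa = msa, te_truth = te_truth,
       label = if (is.null(spec$label)) "rdna" else spec$label)
}

#' Generate a synthetic genome with planted truth
#'
#' Builds each chromosome from a random background (optionally tiled with
#' synthetic TE motifs), then plants telomeres, subtelomeric blocks,
#' satellite arrays and the rDNA array at their configured positions.
#' Planted features must not overlap; overlaps raise an error naming the
#' two offending features.
#'
#' @param config a [synthetic_genome_config()].
#' @return a list of class `synthetic_genome` with elements
#'   `sequences` (named character vector of chromosome sequences),
#'   `truth` (data frame of planted features: `chrom`, `start`, `end`
#'   0-based half-open, `kind`, `label`, `strand`, in sorted coordinate
#'   order) and, when an rDNA array was planted, `rdna` (list with the
#'   gapped copy alignment `msa` and the per-copy table `copies`).
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_genome_config"))
  with_seed(config$seed, {
    lens <- config$chromosome_lengths
    sequences <- character(length(lens))
    names(sequences) <- names(lens)
    truth <- list()
    rdna_out <- NULL
    pool <- if (config$te_background_fraction > 0) te_motif_pool() else NULL

    for (ci in seq_along(lens)) {
      L <- as.integer(lens[ci])
      cname <- names(lens)[ci]
      chars <- sample(DNA_BASES, L, replace = TRUE)
      te_iv <- NULL
      if (config$te_background_fraction > 0) {
        target <- config$te_background_fraction * L
        starts <- integer(0); ends <- integer(0); placed <- 0
        while (placed < target) {
          m <- pool[[sample(length(pool), 1L)]]
          w <- min(length(m), L)
          s <- sample(L - w + 1L, 1L) - 1L
          chars[(s + 1L):(s + w)] <- m[seq_len(w)]
          starts <- c(starts, s); ends <- c(ends, s + w)
          placed <- placed + w
        }
        te_iv <- IRanges::reduce(IRanges::IRanges(starts + 1L, ends))
      }

      # assemble planted features for this chromosome
      planted <- list()  # each: list(kind,label,strand,start,chars)
      add_feature <- function(kind, label, strand, start, fchars) {
        planted[[length(planted) + 1L]] <<- list(kind = kind, label = label,
                                                 strand = strand,
                                                 start = as.integer(start),
                                                 chars = fchars)
      }

      tel <- config$telomere_specs
      tel_start_len <- 0L; tel_end_len <- 0L
      if (!is.null(tel)) {
        cs <- rep_len(tel$copies_start, length(lens))[ci]
        ce <- rep_len(tel$copies_end, length(lens))[ci]
        if (cs > 0) {
          fch <- rep.int(strsplit("CCCTAAA", "")[[1]], cs)
          add_feature("telomere", "start", "-", 0L, fch)
          tel_start_len <- length(fch)
        }
        if (ce > 0) {
          fch <- rep.int(strsplit("TTTAGGG", "")[[1]], ce)
          add_feature("telomere", "end", "+", L - length(fch), fch)
          tel_end_len <- length(fch)
        }
      }

      # subtelomeres immediately internal to the telomere of their end;
      # several blocks at one end are stacked inward in spec order
      sub_off_start <- tel_start_len
      sub_off_end <- tel_end_len
      for (sp in config$subtelomere_specs) {
        if ((if (is.null(sp$chrom)) 1L else sp$chrom) != ci) next
        mr <- if (is.null(sp$mut_rate)) 0 else sp$mut_rate
        fch <- tandem_block_chars(sp$motif, sp$copies, mr)
        if (identical(sp$end, "start")) {
          add_feature("subtelomere", sp$family, "+", sub_off_start, fch)
          sub_off_start <- sub_off_start + length(fch)
        } else {
          add_feature("subtelomere", sp$family, "+",
                      L - sub_off_end - length(fch), fch)
          sub_off_end <- sub_off_end + length(fch)
        }
      }

      for (sp in config$satellite_specs) {
        if ((if (is.null(sp$chrom)) 1L else sp$chrom) != ci) next
        mono <- if (identical(sp$strand, "-")) revcomp(sp$monomer) else sp$monomer
        mr <- if (is.null(sp$mut_rate)) 0 else sp$mut_rate
        fch <- tandem_block_chars(mono, sp$copies, mr)
        add_feature("satellite", sp$family,
                    if (is.null(sp$strand)) "+" else sp$strand, sp$pos, fch)
      }

      rd <- config$rdna_spec
      rdna_built <- NULL
      if (!is.null(rd) && (if (is.null(rd$chrom)) 1L else rd$chrom) == ci) {
        rdna_built <- build_rdna_array(rd, cname)
        add_feature("rdna_array", rdna_built$label, "+", rd$pos,
                    rdna_built$chars)
      }

      # overlap check, then overwrite background
      if (length(planted)) {
        st <- vapply(planted, `[[`, 0L, "start")
        en <- st + vapply(planted, function(p) length(p$chars), 0L)
        if (any(st < 0) || any(en > L))
          stop(sprintf("planted feature exceeds bounds of %s", cname),
               call. = FALSE)
        o <- order(st)
        for (j in seq_along(o)[-1]) {
          a <- planted[[o[j - 1]]]; b <- planted[[o[j]]]
          if (st[o[j]] < en[o[j - 1]])
            stop(sprintf(
              "planted features overlap on %s: %s:%s and %s:%s",
              cname, a$kind, a$label, b$kind, b$label), call. = FALSE)
        }
        for (p in planted)
          chars[(p$start + 1L):(p$start + length(p$chars))] <- p$chars
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = cname,
          start = st, end = en,
          kind = vapply(planted, `[[`, "", "kind"),
          label = vapply(planted, `[[`, "", "label"),
          strand = vapply(planted, `[[`, "", "strand"),
          stringsAsFactors = FALSE)
      }

      if (!is.null(rdna_built)) {
        cp <- rdna_built$copies
        cp$start <- cp$start + rd$pos
        cp$end <- cp$end + rd$pos
        rdna_built$copies <- cp
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = cname, start = cp$start, end = cp$end, kind = "rdna_copy",
          label = cp$genotype, strand = cp$strand, stringsAsFactors = FALSE)
        if (length(rdna_built$te_truth))
          truth[[length(truth) + 1L]] <- data.frame(
            chrom = cname,
            start = vapply(rdna_built$te_truth, `[[`, 0, 1) + rd$pos,
            end = vapply(rdna_built$te_truth, `[[`, 0, 2) + rd$pos,
            kind = "te_insertion", label = "rdna_te", strand = "+",
            stringsAsFactors = FALSE)
        rdna_out <- list(msa = rdna_built$msa, copies = cp)
      }

      # TE background truth, minus spans overwritten by planted features
      if (!is.null(te_iv) && length(te_iv)) {
        if (length(planted)) {
          st <- vapply(planted, `[[`, 0L, "start")
          en <- st + vapply(planted, function(p) length(p$chars), 0L)
          te_iv <- IRanges::setdiff(te_iv, IRanges::IRanges(st + 1L, en))
        }
        if (length(te_iv))
          truth[[length(truth) + 1L]] <- data.frame(
            chrom = cname,
            start = BiocGenerics::start(te_iv) - 1L,
            end = BiocGenerics::end(te_iv),
            kind = "te", label = "te_background", strand = "+",
            stringsAsFactors = FALSE)
      }

      sequences[ci] <- paste(chars, collapse = "")
    }

    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 kind = character(), label = character(),
                 strand = character(), stringsAsFactors = FALSE)
    truth_df <- truth_df[order(match(truth_df$chrom, names(lens)),
                               truth_df$start, truth_df$end), , drop = FALSE]
    rownames(truth_df) <- NULL
    structure(list(sequences = sequences, truth = truth_df,
                   rdna = rdna_out, config = config),
              class = "synthetic_genome")
  })
}

#' Introduce a known number of substitutions into an assembly copy
#'
#' Used to plant a controlled base-error rate so that k-mer QV estimation
#' can be checked against ground truth.
#'
#' @param genome a `synthetic_genome` or a named character vector of
#'   sequences.
#' @param substitution_count total substitutions across the genome.
#' @param seed integer RNG seed.
#' @return list with `sequences` (perturbed copy) and `error_truth`
#'   (data frame `chrom`, `pos` 0-based, `ref`, `alt`).
#' @export
perturb_assembly <- function(genome, substitution_count, seed = 1L) {
  seqs <- if (inherits(genome, "synthetic_genome")) genome$sequences else genome
  lens <- nchar(seqs)
  total <- sum(lens)
  if (substitution_count > total)
    stop("substitution_count exceeds genome length", call. = FALSE)
  if (substitution_count == 0)
    return(list(sequences = seqs,
                error_truth = data.frame(chrom = character(),
                                         pos = integer(),
                                         ref = character(),
                                         alt = character(),
                                         stringsAsFactors = FALSE)))
  with_seed(seed, {
    flat <- sample(total, substitution_count)
    cum <- cumsum(lens)
    chrom_i <- findInterval(flat - 1L, c(0L, cum), rightmost.closed = FALSE)
    pos1 <- flat - c(0L, cum)[chrom_i]  # 1-based within chromosome
    err <- data.frame(chrom = names(seqs)[chrom_i], pos = pos1 - 1L,
                      ref = NA_character_, alt = NA_character_,
                      stringsAsFactors = FALSE)
    o <- order(chrom_i, pos1)
    err <- err[o, , drop = FALSE]; chrom_i <- chrom_i[o]; pos1 <- pos1[o]
    out <- seqs
    for (ci in unique(chrom_i)) {
      sel <- chrom_i == ci
      chars <- strsplit(out[ci], "")[[1]]
      err$ref[sel] <- chars[pos1[sel]]
      alt <- substitute_bases(chars[pos1[sel]])
      err$alt[sel] <- alt
      chars[pos1[sel]] <- alt
      out[ci] <- paste(chars, collapse = "")
    }
    rownames(err) <- NULL
    list(sequences = out, error_truth = err)
  })
}
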