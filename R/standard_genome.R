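#' Reciprocal overlap of two intervals
#'
#' @param a,b intervals as `c(start, end)` (0-based half-open).
#' @return minimum of the overlap fraction of each interval (0 when
#'   disjoint).
#' @export
reciprocal_overlap <- function(a, b) {
  ov <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  min(ov / (a[2] - a[1]), ov / (b[2] - b[1]))
}

#' Standard synthetic genome configuration
#'
#' The reference study condition used throughout the test suite and the
#' analysis scripts: a 5 Mb chromosome (`chrA`) carrying oriented
#' 3,700-copy telomeres at both ends (the telomere scale observed in
#' complete plant assemblies), a two-family subtelomeric block stack at
#' the left end and a single-family block at the right end, knob180-,
#' TR-1- and CentC-like satellite arrays (per-copy substitution rate
#' 0.02), and a 2 Mb centromere spanning two large CentC arrays; plus a
#' 1 Mb chromosome (`chrR`) carrying a 200-copy rDNA-like array with a
#' 70/30 two-haplotype mixture over three SNP sites and one 6 bp
#' deletion, a 20-copy inversion block and three TE insertions. The TE
#' background fraction is 0.30.
#'
#' @param seed integer RNG seed; governs both the drawn repeat-unit
#'   sequences and genome construction.
#' @return a [synthetic_genome_config()]; attributes `centromere_truth`
#'   (data frame) and `monomer_lengths` (named vector) carry the planted
#'   centromere interval and the satellite unit lengths.
#' @export
standard_genome_config <- function(seed = 1L) {
  units <- with_seed(seed + 7919L, {
    u <- list(knob180 = random_dna(180), tr1 = random_dna(360),
              centc = random_dna(156), subtel1 = random_dna(629),
              subtel2 = random_dna(532), rdna_unit = random_dna(500))
    # rDNA haplotype 2: three SNPs and one 6 bp deletion vs the reference
    snp_pos <- c(60L, 220L, 410L)
    ref <- strsplit(u$rdna_unit, "")[[1]]
    u$hap2_snps <- setNames(substitute_bases(ref[snp_pos]),
                            as.character(snp_pos))
    u
  })
  cfg <- synthetic_genome_config(
    chromosome_lengths = c(chrA = 5e6, chrR = 1e6),
    telomere_specs = list(copies_start = c(3700L, 0L),
                          copies_end = c(3700L, 0L)),
    subtelomere_specs = list(
      list(family = "subtel1", motif = units$subtel1, copies = 120L,
           chrom = 1L, end = "start"),
      list(family = "subtel2", motif = units$subtel2, copies = 2L,
           chrom = 1L, end = "start"),
      list(family = "subtel1", motif = units$subtel1, copies = 90L,
           chrom = 1L, end = "end")),
    satellite_specs = list(
      list(family = "knob180", monomer = units$knob180, copies = 200L,
           mut_rate = 0.02, chrom = 1L, pos = 500000L, strand = "+"),
      list(family = "tr1", monomer = units$tr1, copies = 70L,
           mut_rate = 0.02, chrom = 1L, pos = 700000L, strand = "+"),
      list(family = "knob180", monomer = units$knob180, copies = 150L,
           mut_rate = 0.02, chrom = 1L, pos = 1200000L, strand = "-"),
      list(family = "centc", monomer = units$centc, copies = 6000L,
           mut_rate = 0.02, chrom = 1L, pos = 2050000L, strand = "+"),
      list(family = "centc", monomer = units$centc, copies = 5000L,
           mut_rate = 0.02, chrom = 1L, pos = 3200000L, strand = "+")),
    rdna_spec = list(
      chrom = 2L, pos = 400000L, unit = units$rdna_unit, copies = 200L,
      haplotypes = list(
        list(name = "hap1", snps = character(0), dels = list()),
        list(name = "hap2", snps = units$hap2_snps,
             dels = list(list(pos = 300L, len = 6L)))),
      mixture = c(0.7, 0.3),
      inversion_copies = c(100L, 119L),
      te_insertions = 3L, te_length = 1500L, label = "rdna5S"),
    te_background_fraction = 0.30,
    seed = seed)
  attr(cfg, "centromere_truth") <- data.frame(
    chrom = "chrA", start = 2000000L, end = 4000000L,
    stringsAsFactors = FALSE)
  attr(cfg, "monomer_lengths") <- c(knob180 = 180L, tr1 = 360L,
                                    centc = 156L, subtel1 = 629L,
                                    subtel2 = 532L)
  cfg
}

#' Synthetic genome configuration for base-accuracy recovery
#'
#' A 1 Mb single-chromosome condition for checking k-mer QV estimation
#' against a planted substitution rate: mostly unique sequence with a
#' 0.30 TE background and two modest satellite arrays (36 kb and 18 kb).
#' Satellite content is kept small on purpose — substitutions inside
#' large, internally similar satellite arrays can recreate k-mers already
#' present elsewhere in the array, which deflates the error k-mer count
#' for any instance-counting QV estimator.
#'
#' @param seed integer RNG seed.
#' @return a [synthetic_genome_config()].
#' @export
qv_genome_config <- function(seed = 1L) {
  units <- with_seed(seed + 104729L,
                     list(knob180 = random_dna(180), tr1 = random_dna(360)))
  synthetic_genome_config(
    chromosome_lengths = c(chrQ = 1e6),
    satellite_specs = list(
      list(family = "knob180", monomer = units$knob180, copies = 200L,
           mut_rate = 0.02, chrom = 1L, pos = 300000L, strand = "+"),
      list(family = "tr1", monomer = units$tr1, copies = 50L,
           mut_rate = 0.02, chrom = 1L, pos = 600000L, strand = "+")),
    te_background_fraction = 0.30,
    seed = seed)
}

#' Per-monomer satellite hits derived from the truth set
#'
#' Splits each planted satellite block into monomer-sized hit intervals
#' labeled with the family, emulating the per-unit homology hits a
#' similarity search would produce (homology search itself is an input
#' contract, not part of the pipeline).
#'
#' @param truth truth feature data frame from [make_genome()].
#' @param monomer_lengths named vector of unit lengths per family.
#' @return data frame `chrom`, `start`, `end`, `family`.
#' @export
satellite_hits_from_truth <- function(truth, monomer_lengths) {
  sat <- truth[truth$kind == "satellite", , drop = FALSE]
  rows <- lapply(seq_len(nrow(sat)), function(i) {
    fam <- sat$label[i]
    u <- monomer_lengths[[fam]]
    starts <- seq(sat$start[i], sat$end[i] - 1L, by = u)
    data.frame(chrom = sat$chrom[i], start = starts,
               end = pmin(starts + u, sat$end[i]), family = fam,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), family = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Subtelomeric-repeat hits derived from the truth set
#'
#' @param truth truth feature data frame from [make_genome()].
#' @return data frame `chrom`, `start`, `end`, `family` (one hit per
#'   planted block).
#' @export
subtelomere_hits_from_truth <- function(truth) {
  st <- truth[truth$kind == "subtelomere", , drop = FALSE]
  data.frame(chrom = st$chrom, start = st$start, end = st$end,
             family = st$label, stringsAsFactors = FALSE)
}
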