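#' Call variant sites across aligned rDNA copies
#'
#' Scans a rectangular alignment of tandem rDNA copies for substitution
#' columns and gap runs (indels). A site is kept only if its minor allele
#' is carried by strictly more than `min_support` of the copies. Two
#' modes mirror the two rDNA classes:
#'
#' * `snp_and_indel` — substitution columns and gap runs of any length
#'   qualify (the 5S-style analysis);
#' * `long_indel` — only gap runs strictly longer than `min_indel_len`
#'   qualify (the 45S-style analysis restricted to large intergenic-spacer
#'   indels).
#'
#' Gap runs are identified by their exact column span: partially
#' overlapping runs are distinct alleles.
#'
#' @param msa character matrix of aligned copies (>= 2 rows).
#' @param mode `"snp_and_indel"` or `"long_indel"`.
#' @param min_support strict minor-allele support fraction (default 0.10).
#' @param min_indel_len gap runs must exceed this length in `long_indel`
#'   mode (default 5, i.e. indels larger than 5 bp).
#' @param region_mask optional integer vector of eligible columns (e.g.
#'   the intergenic spacer); sites outside it are discarded.
#' @return data frame of sites: `column` (start column), `span` (columns
#'   covered), `kind` (`"SNP"`/`"indel"`), `indel_length`, `alleles`
#'   (comma-joined), `support` (comma-joined fractions, same order).
#' @export
call_variant_sites <- function(msa, mode = c("snp_and_indel", "long_indel"),
                               min_support = 0.10, min_indel_len = 5,
                               region_mask = NULL) {
  mode <- match.arg(mode)
  if (is.null(dim(msa)) || nrow(msa) < 2L)
    stop("need at least 2 copies", call. = FALSE)
  n <- nrow(msa)
  sites <- list()

  add_site <- function(column, span, kind, ilen, alleles, support) {
    sites[[length(sites) + 1L]] <<- data.frame(
      column = column, span = span, kind = kind, indel_length = ilen,
      alleles = paste(alleles, collapse = ","),
      support = paste(signif(support, 6), collapse = ","),
      stringsAsFactors = FALSE)
  }

  # indel sites: maximal gap runs per row, keyed by (start, length)
  runs <- list()
  for (i in seq_len(n)) {
    r <- rle(msa[i, ] == "-")
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      key <- paste(starts[j], r$lengths[j], sep = ":")
      runs[[key]] <- c(runs[[key]], i)
    }
  }
  for (key in names(runs)) {
    parts <- as.integer(strsplit(key, ":")[[1]])
    start_col <- parts[1]; len <- parts[2]
    if (mode == "long_indel" && len <= min_indel_len) next
    if (!is.null(region_mask) &&
        !all(seq(start_col, length.out = len) %in% region_mask)) next
    carriers <- length(runs[[key]])
    supp <- carriers / n
    minor <- min(supp, 1 - supp)
    if (minor <= min_support) next
    add_site(start_col, len, "indel", len,
             c("del", "no_del"), c(supp, 1 - supp))
  }

  # SNP sites: substitution columns (gap/N excluded from the tally)
  if (mode == "snp_and_indel") {
    eligible <- if (is.null(region_mask)) seq_len(ncol(msa)) else region_mask
    for (c in eligible) {
      col <- msa[, c]
      bases <- col[col %in% DNA_BASES]
      tab <- sort(table(bases), decreasing = TRUE)
      if (length(tab) < 2L) next
      supp <- as.numeric(tab) / n
      # minor-allele rule: the strongest alternative allele must clear it
      if (supp[2] <= min_support) next
      add_site(c, 1L, "SNP", 0L, names(tab), supp)
    }
  }

  out <- if (length(sites)) do.call(rbind, sites) else
    data.frame(column = integer(), span = integer(), kind = character(),
               indel_length = integer(), alleles = character(),
               support = character(), stringsAsFactors = FALSE)
  out <- out[order(out$column, out$span), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# allele of copy `i` at a site: base at the column for SNPs; for indels,
# "del" iff the copy carries a gap run exactly matching the site span
site_alleles <- function(msa, site) {
  if (site$kind == "SNP") return(msa[, site$column])
  cols <- seq(site$column, length.out = site$span)
  left_ok <- site$column == 1L | msa[, max(1L, site$column - 1L)] != "-"
  right <- site$column + site$span
  right_ok <- right > ncol(msa) | msa[, min(ncol(msa), right)] != "-"
  all_gap <- rowSums(msa[, cols, drop = FALSE] == "-") == site$span
  ifelse(all_gap & left_ok & right_ok, "del", "no_del")
}

#' Assign genotypes to rDNA copies from selected variant sites
#'
#' A copy's genotype is the tuple of its alleles across the selected
#' sites. Genotypes are labeled `type 1`, `type 2`, ... by descending
#' frequency; equal-frequency ties are broken by canonical allele-tuple
#' order, making the labeling stable under permutation of the input
#' copies.
#'
#' @param msa character matrix of aligned copies.
#' @param sites data frame from [call_variant_sites()] on the same
#'   alignment.
#' @return list with `genotypes` (data frame `copy_id`, `allele_tuple`,
#'   `label`) and `frequency` (data frame `label`, `allele_tuple`,
#'   `count`, `frequency`, frequencies summing to 1).
#' @export
assign_genotypes <- function(msa, sites) {
  ids <- rownames(msa)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(msa)))
  if (nrow(sites) == 0L) {
    tuples <- rep("", nrow(msa))
  } else {
    allele_mat <- vapply(seq_len(nrow(sites)), function(s)
      site_alleles(msa, sites[s, ]), character(nrow(msa)))
    tuples <- apply(matrix(allele_mat, nrow = nrow(msa)), 1,
                    paste, collapse = "|")
  }
  tab <- table(tuples)
  freq <- data.frame(allele_tuple = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
  freq <- freq[order(-freq$count, freq$allele_tuple), , drop = FALSE]
  freq$label <- paste("type", seq_len(nrow(freq)))
  freq$frequency <- freq$count / nrow(msa)
  lab <- setNames(freq$label, freq$allele_tuple)
  list(genotypes = data.frame(copy_id = ids, allele_tuple = tuples,
                              label = unname(lab[tuples]),
                              stringsAsFactors = FALSE),
       frequency = freq[, c("label", "allele_tuple", "count", "frequency")])
}

#' Strand-orientation profile and inversion blocks of an rDNA array
#'
#' Reports the fraction of copies transcribed on each strand and the
#' inversion blocks: maximal runs of at least `min_run` consecutive
#' copies on the minority strand, each reported as the genomic interval
#' from the first to the last copy of the run.
#'
#' @param copies data frame of rDNA copies sorted by genomic position:
#'   `copy_id`, `chrom`, `start`, `end`, `strand`.
#' @param min_run minimum run length reported as an inversion block
#'   (default 3).
#' @return list with `strand_fraction` (named fractions for `+`/`-`),
#'   `majority_strand`, and `inversion_blocks` (data frame `chrom`,
#'   `start`, `end`, `n_copies`, `first_copy`, `last_copy`).
#' @export
orientation_profile <- function(copies, min_run = 3) {
  stopifnot(all(copies$strand %in% c("+", "-")))
  copies <- copies[order(copies$chrom, copies$start), , drop = FALSE]
  frac <- c(`+` = mean(copies$strand == "+"),
            `-` = mean(copies$strand == "-"))
  majority <- names(frac)[which.max(frac)]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_copies = integer(),
                      first_copy = character(), last_copy = character(),
                      stringsAsFactors = FALSE)
  blocks <- empty
  for (cname in unique(copies$chrom)) {
    cc <- copies[copies$chrom == cname, , drop = FALSE]
    r <- rle(cc$strand != majority)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_run)) {
      blocks <- rbind(blocks, data.frame(
        chrom = cname, start = cc$start[starts[j]], end = cc$end[ends[j]],
        n_copies = r$lengths[j],
        first_copy = cc$copy_id[starts[j]], last_copy = cc$copy_id[ends[j]],
        stringsAsFactors = FALSE))
    }
  }
  list(strand_fraction = frac, majority_strand = majority,
       inversion_blocks = blocks)
}
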