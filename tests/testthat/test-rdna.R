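test_that("identical copies produce no variant sites and one genotype", {
  m <- do.call(rbind, rep(list(strsplit(strrep("ACGT", 30), "")[[1]]), 20))
  rownames(m) <- sprintf("c%02d", 1:20)
  sites <- call_variant_sites(m)
  expect_equal(nrow(sites), 0L)
  gt <- assign_genotypes(m, sites)
  expect_equal(nrow(gt$frequency), 1L)
  expect_equal(gt$frequency$frequency, 1.0)
  expect_error(call_variant_sites(m[1, , drop = FALSE]), "2 copies")
})

test_that("support thresholds are strict and mode-dependent", {
  base <- strsplit(strrep("ACGT", 25), "")[[1]]  # 100 columns
  n <- 50
  m <- do.call(rbind, rep(list(base), n))
  # a 6 bp deletion carried by 30% of copies
  del_rows <- 1:15
  m[del_rows, 40:45] <- "-"
  # a substitution carried by 8% of copies (below the >10% rule)
  m[1:4, 70] <- "T"
  # a substitution carried by 20%
  m[1:10, 80] <- "G"
  rownames(m) <- sprintf("c%02d", 1:n)

  long <- call_variant_sites(m, mode = "long_indel")
  expect_equal(nrow(long), 1L)
  expect_equal(long$kind, "indel")
  expect_equal(long$column, 40L)
  expect_equal(long$indel_length, 6L)

  both <- call_variant_sites(m, mode = "snp_and_indel")
  expect_setequal(both$kind, c("indel", "SNP"))
  expect_false(70 %in% both$column[both$kind == "SNP"])
  expect_true(80 %in% both$column[both$kind == "SNP"])

  # a 5 bp gap run does not qualify as a long indel ("larger than 5 bp")
  m2 <- do.call(rbind, rep(list(base), n))
  m2[1:20, 40:44] <- "-"
  expect_equal(nrow(call_variant_sites(m2, mode = "long_indel")), 0L)
  expect_equal(nrow(call_variant_sites(m2, mode = "snp_and_indel")), 1L)

  # region mask restricts eligible columns
  masked <- call_variant_sites(m, mode = "long_indel", region_mask = 60:100)
  expect_equal(nrow(masked), 0L)
})

test_that("a planted 70/30 two-haplotype mixture is recovered", {
  g <- std_genome()
  sites <- call_variant_sites(g$rdna$msa, mode = "snp_and_indel")
  expect_equal(nrow(sites), 4L)  # three SNPs and one 6 bp deletion
  gt <- assign_genotypes(g$rdna$msa, sites)
  expect_equal(nrow(gt$frequency), 2L)
  sd3 <- 3 * sqrt(0.7 * 0.3 / 200)
  expect_lt(abs(gt$frequency$frequency[1] - 0.7), sd3)
  expect_lt(abs(gt$frequency$frequency[2] - 0.3), sd3)
  expect_equal(sum(gt$frequency$frequency), 1, tolerance = 1e-9)
  # genotype partition matches the planted haplotype labels exactly
  planted <- g$rdna$copies$genotype
  called <- gt$genotypes$label[match(g$rdna$copies$copy_id,
                                     gt$genotypes$copy_id)]
  expect_equal(length(unique(paste(planted, called))), 2L)
})

test_that("genotype labels rank by abundance and are permutation-stable", {
  base <- strsplit(strrep("ACGT", 10), "")[[1]]
  hap_bases <- c("A", "C", "G", "T", "-")
  counts <- c(40, 25, 20, 10, 5)
  rows <- list()
  for (h in seq_along(counts)) for (i in seq_len(counts[h])) {
    r <- base; r[17] <- hap_bases[h]
    rows[[length(rows) + 1L]] <- r
  }
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("c%03d", seq_len(nrow(m)))
  sites <- call_variant_sites(m)
  gt <- assign_genotypes(m, sites)
  expect_equal(gt$frequency$count, counts)
  expect_equal(gt$frequency$label, paste("type", 1:5))

  perm <- with_seed(2, sample(nrow(m)))
  gt2 <- assign_genotypes(m[perm, ], call_variant_sites(m[perm, ]))
  expect_equal(gt2$frequency, gt$frequency)
  # genotype count bounded by copies and by allele-tuple combinations
  expect_lte(nrow(gt$frequency), nrow(m))
})

test_that("orientation profiling finds minority-strand runs", {
  mk <- function(strands) data.frame(
    copy_id = sprintf("c%03d", seq_along(strands)), chrom = "chrR",
    start = (seq_along(strands) - 1L) * 500L,
    end = seq_along(strands) * 500L, strand = strands,
    stringsAsFactors = FALSE)

  same <- orientation_profile(mk(rep("+", 50)))
  expect_equal(unname(same$strand_fraction["+"]), 1.0)
  expect_equal(nrow(same$inversion_blocks), 0L)

  strands <- rep("+", 100); strands[41:60] <- "-"
  op <- orientation_profile(mk(strands))
  expect_equal(nrow(op$inversion_blocks), 1L)
  expect_equal(op$inversion_blocks$n_copies, 20L)
  expect_equal(op$inversion_blocks$start, 40L * 500L)
  expect_equal(op$inversion_blocks$end, 60L * 500L)

  alt <- orientation_profile(mk(rep(c("+", "+", "-"), 20)))
  expect_equal(nrow(alt$inversion_blocks), 0L)  # runs shorter than min_run
})

test_that("the planted 20-copy inversion block is recovered exactly", {
  g <- std_genome()
  op <- orientation_profile(g$rdna$copies)
  expect_equal(unname(op$strand_fraction["-"]), 0.1)
  expect_equal(nrow(op$inversion_blocks), 1L)
  expect_equal(op$inversion_blocks$n_copies, 20L)
  inv_ids <- sprintf("copy_%04d", 100:119)
  truth_span <- range(c(g$rdna$copies$start[g$rdna$copies$copy_id %in% inv_ids],
                        g$rdna$copies$end[g$rdna$copies$copy_id %in% inv_ids]))
  expect_equal(op$inversion_blocks$start, truth_span[1])
  expect_equal(op$inversion_blocks$end, truth_span[2])
})
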