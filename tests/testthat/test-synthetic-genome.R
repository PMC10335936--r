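test_that("an empty configuration yields bare sequence and empty truth", {
  cfg <- synthetic_genome_config(chromosome_lengths = c(chr1 = 1e5), seed = 3)
  g <- make_genome(cfg)
  expect_equal(nchar(g$sequences), c(chr1 = 100000L))
  expect_equal(nrow(g$truth), 0L)
})

test_that("planted satellite intervals are forced by monomer x copies", {
  cfg <- synthetic_genome_config(
    chromosome_lengths = c(chr1 = 1e5),
    satellite_specs = list(list(family = "knob", monomer = strrep("ACGTA", 36),
                                copies = 200L, pos = 20000L)),
    seed = 7)
  g <- make_genome(cfg)
  sat <- g$truth[g$truth$kind == "satellite", ]
  expect_equal(sat$start, 20000L)
  expect_equal(sat$end, 56000L)  # 200 x 180
})

test_that("per-copy divergence matches the configured mutation rate", {
  monomer <- with_seed(11, random_dna(180))
  cfg <- synthetic_genome_config(
    chromosome_lengths = c(chr1 = 2e5),
    satellite_specs = list(list(family = "f", monomer = monomer,
                                copies = 300L, mut_rate = 0.02,
                                pos = 10000L)),
    seed = 11)
  g <- make_genome(cfg)
  sat <- g$truth[g$truth$kind == "satellite", ]
  block <- substr(g$sequences[["chr1"]], sat$start + 1, sat$end)
  mism <- vapply(seq_len(300), function(i)
    oracle_hamming(substr(block, (i - 1) * 180 + 1, i * 180), monomer), 0)
  n_bases <- 300 * 180
  p_hat <- sum(mism) / n_bases
  se <- sqrt(0.02 * 0.98 / n_bases)
  expect_lt(abs(p_hat - 0.02), 3 * se)
})

test_that("overlapping planted features raise an error naming both", {
  cfg <- synthetic_genome_config(
    chromosome_lengths = c(chr1 = 1e5),
    satellite_specs = list(
      list(family = "a", monomer = strrep("ACGT", 25), copies = 100L,
           pos = 10000L),
      list(family = "b", monomer = strrep("TTGA", 25), copies = 100L,
           pos = 15000L)),
    seed = 1)
  expect_error(make_genome(cfg), "satellite:a.*satellite:b")
})

test_that("identical config and seed give byte-identical output", {
  cfg <- standard_genome_config(5)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(g1$sequences, g2$sequences)
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$rdna, g2$rdna)
})

test_that("rDNA mixture fractions must sum to one", {
  expect_error(synthetic_genome_config(
    chromosome_lengths = c(chr1 = 1e5),
    rdna_spec = list(chrom = 1, pos = 1000, unit = strrep("ACGT", 50),
                     copies = 10,
                     haplotypes = list(list(name = "h1", snps = character(0),
                                            dels = list())),
                     mixture = 0.9)),
    "sum to 1")
})

test_that("truth intervals are valid half-open spans inside the sequence", {
  g <- std_genome()
  lens <- nchar(g$sequences)
  expect_true(all(g$truth$start >= 0))
  expect_true(all(g$truth$end <= lens[g$truth$chrom]))
  expect_true(all(g$truth$end > g$truth$start))
  # sorted coordinate order within chromosome
  for (cn in unique(g$truth$chrom)) {
    s <- g$truth$start[g$truth$chrom == cn]
    expect_true(all(diff(s) >= 0))
  }
})

test_that("perturbation plants exactly the requested substitutions", {
  g <- make_genome(synthetic_genome_config(c(chr1 = 5e4, chr2 = 3e4),
                                           seed = 2))
  p0 <- perturb_assembly(g, 0, seed = 1)
  expect_identical(p0$sequences, g$sequences)
  expect_equal(nrow(p0$error_truth), 0L)

  p <- perturb_assembly(g, 100, seed = 1)
  dist <- sum(vapply(names(g$sequences), function(cn)
    sum(strsplit(g$sequences[[cn]], "")[[1]] !=
          strsplit(p$sequences[[cn]], "")[[1]]), 0))
  expect_equal(dist, 100)
  # recorded positions match the actual differences
  for (i in seq_len(nrow(p$error_truth))) {
    e <- p$error_truth[i, ]
    expect_identical(substr(p$sequences[[e$chrom]], e$pos + 1, e$pos + 1),
                     e$alt)
    expect_identical(substr(g$sequences[[e$chrom]], e$pos + 1, e$pos + 1),
                     e$ref)
  }
  expect_error(perturb_assembly(g, 1e9, seed = 1), "exceeds")
})

test_that("FASTA and truth-BED round trips reproduce in-memory objects", {
  g <- make_genome(synthetic_genome_config(
    chromosome_lengths = c(chr1 = 2e4),
    satellite_specs = list(list(family = "f", monomer = strrep("ACGTG", 20),
                                copies = 50L, pos = 5000L)),
    telomere_specs = list(copies_start = 30L, copies_end = 30L),
    seed = 4))
  fa <- tempfile(fileext = ".fa")
  write_fasta(g$sequences, fa)
  expect_identical(read_fasta(fa), g$sequences)
  bed <- tempfile(fileext = ".bed")
  write_truth_bed(g$truth, bed)
  back <- read_bed(bed)
  expect_equal(back$start, g$truth$start)
  expect_equal(back$end, g$truth$end)
  expect_equal(back$name, paste(g$truth$kind, g$truth$label, sep = ":"))
  expect_equal(back$strand, g$truth$strand)
})
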