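test_that("terminal telomeric runs are counted and oriented", {
  mid <- with_seed(3, random_dna(5000))
  # 100 tandem TTTAGGG at the right end, G-rich strand off the end
  s <- c(chr1 = paste0(mid, strrep("TTTAGGG", 100)))
  tel <- detect_telomeres(s)
  expect_equal(nrow(tel), 1L)
  expect_equal(tel$chrom_end, "end")
  expect_equal(tel$copies, 100L)
  expect_equal(tel$length, 700L)
  expect_true(tel$orientation_ok)

  # the same motif at the start is the wrong strand there
  s2 <- c(chr1 = paste0(strrep("TTTAGGG", 100), mid))
  tel2 <- detect_telomeres(s2)
  expect_equal(tel2$chrom_end, "start")
  expect_false(tel2$orientation_ok)

  # correctly oriented start telomere: CCCTAAA repeats
  s3 <- c(chr1 = paste0(strrep("CCCTAAA", 60), mid))
  tel3 <- detect_telomeres(s3)
  expect_true(tel3$orientation_ok)
  expect_equal(tel3$copies, 60L)

  # interruptions within the tolerance extend the run; beyond it they stop
  s4 <- c(chr1 = paste0(mid, strrep("TTTAGGG", 40), strrep("A", 30),
                        strrep("TTTAGGG", 20)))
  tel4 <- detect_telomeres(s4)
  expect_equal(tel4$copies, 60L)
  s5 <- c(chr1 = paste0(mid, strrep("TTTAGGG", 40), strrep("A", 80),
                        strrep("TTTAGGG", 20)))
  tel5 <- detect_telomeres(s5)
  expect_equal(tel5$copies, 20L)

  # below min_copies there is no call
  s6 <- c(chr1 = paste0(mid, strrep("TTTAGGG", 5)))
  expect_equal(nrow(detect_telomeres(s6)), 0L)
})

test_that("planted standard-genome telomeres are recovered within one copy", {
  g <- std_genome()
  tel <- detect_telomeres(g$sequences)
  tel <- tel[tel$chrom == "chrA", ]
  expect_equal(nrow(tel), 2L)
  expect_true(all(abs(tel$copies - 3700L) <= 1L))
  expect_true(all(tel$orientation_ok))
})

test_that("subtelomeres grow from the telomere and trim to hits", {
  lens <- c(chr1 = 1e6)
  # no hits near an end: no call
  none <- call_subtelomeres(
    data.frame(chrom = character(), start = integer(), end = integer(),
               family = character()), lens)
  expect_equal(nrow(none), 0L)

  # planted 90 kb block adjacent to a 20 kb telomere
  tel <- data.frame(chrom = "chr1", chrom_end = "start", start = 0L,
                    end = 20000L, copies = 2857L, length = 20000L,
                    orientation_ok = TRUE)
  hits <- data.frame(chrom = "chr1", start = 20000L, end = 110000L,
                     family = "subtel1")
  sub <- call_subtelomeres(hits, lens, tel)
  expect_equal(nrow(sub), 1L)
  expect_equal(c(sub$start, sub$end), c(20000L, 110000L))
  expect_equal(sub$frac_subtel1, 1.0)

  # a distal block separated by more than max_gap is not absorbed
  hits2 <- rbind(hits, data.frame(chrom = "chr1", start = 200000L,
                                  end = 250000L, family = "subtel1"))
  sub2 <- call_subtelomeres(hits2, lens, tel)
  sub2 <- sub2[sub2$chrom_end == "start", ]
  expect_equal(sub2$end, 110000L)
})

test_that("centromere calling selects, merges and length-filters bins", {
  flat <- track_from_values(rep(1, 3000))
  expect_equal(nrow(call_centromeres(flat)), 0L)

  # strict threshold: bins exactly at 5 are not retained
  v <- rep(1, 3000); v[1001:1500] <- 5
  expect_equal(nrow(call_centromeres(track_from_values(v))), 0L)

  # two retained blocks 0.5 Mb apart merge into one call
  v <- rep(1, 3000); v[501:700] <- 8; v[1201:1400] <- 8
  cen <- call_centromeres(track_from_values(v))
  expect_equal(nrow(cen), 1L)
  expect_equal(c(cen$start, cen$end), c(500000L, 1400000L))

  # blocks further apart than the merge gap stay separate
  v <- rep(1, 3000); v[1:200] <- 8; v[1501:1700] <- 8
  cen2 <- call_centromeres(track_from_values(v))
  expect_equal(nrow(cen2), 2L)

  # sub-threshold-length calls are dropped
  v <- rep(1, 3000); v[100:150] <- 8
  expect_equal(nrow(call_centromeres(track_from_values(v))), 0L)
})

test_that("raising the enrichment threshold never lengthens the called span", {
  g <- std_genome()
  tr <- simulate_enrichment_track(g, attr(g$config, "centromere_truth"),
                                  inside_level = 8, outside_level = 1,
                                  noise_sd = 0.5, seed = 11)
  spans <- vapply(c(2, 5, 7, 7.9), function(th)
    sum(call_centromeres(tr, threshold = th)$length), 0)
  expect_true(all(diff(spans) <= 0))
})

test_that("centromere typing follows CentC-array coverage", {
  calls <- data.frame(chrom = c("c1", "c2"), start = c(0L, 0L),
                      end = c(1000000L, 1000000L),
                      length = c(1000000L, 1000000L))
  ann <- data.frame(chrom = c("c1", "c1", "c2"),
                    start = c(0L, 970000L, 0L),
                    end = c(970000L, 1000000L, 200000L),
                    family = c("centc", "crm", "centc"))
  arrays <- data.frame(chrom = c("c1", "c2"), start = c(0L, 0L),
                       end = c(970000L, 200000L))
  typed <- centromere_composition(calls, ann, arrays)
  expect_equal(typed$type, c("CentC-rich", "CentC-poor"))
  expect_equal(typed$frac_centc, c(0.97, 0.2))
  # a satellite-free centromere types poor with zero CentC
  no_sat <- centromere_composition(
    data.frame(chrom = "c3", start = 0L, end = 1000000L, length = 1000000L),
    ann, arrays)
  expect_equal(no_sat$type, "CentC-poor")
  expect_equal(no_sat$centc_array_coverage, 0)
})

test_that("telomere and subtelomere calls at one end never overlap", {
  g <- std_genome()
  tel <- detect_telomeres(g$sequences)
  sub <- call_subtelomeres(subtelomere_hits_from_truth(g$truth),
                           nchar(g$sequences), tel)
  for (i in seq_len(nrow(sub))) {
    t <- tel[tel$chrom == sub$chrom[i] & tel$chrom_end == sub$chrom_end[i], ]
    if (!nrow(t)) next
    expect_equal(reciprocal_overlap(c(t$start, t$end),
                                    c(sub$start[i], sub$end[i])), 0)
  }
})
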