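aln_row <- function(read_id, read_length, flag, chrom, ts, te, qs, qe,
                    strand = "+") {
  data.frame(read_id = read_id, read_length = read_length, flag = flag,
             chrom = chrom, target_start = ts, target_end = te,
             query_start = qs, query_end = qe, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("flag and query-coverage filtering follow the retained-set rule", {
  # single primary covering 0.90 of the read: retained
  rec <- aln_row("r1", 1000L, 0L, "c", 0L, 900L, 0L, 900L)
  f <- filter_alignments(rec)
  expect_equal(nrow(f$retained), 1L)

  # secondary alignment (flag 256) dropped regardless of coverage
  rec <- aln_row("r2", 1000L, 256L, "c", 0L, 1000L, 0L, 1000L)
  f <- filter_alignments(rec)
  expect_equal(nrow(f$retained), 0L)

  # union of two supplementary spans [0,0.5) and [0.45,0.88): 0.88 >= 0.85
  rec <- rbind(aln_row("r3", 1000L, 0L, "c", 0L, 500L, 0L, 500L),
               aln_row("r3", 1000L, 2048L, "c", 600L, 1030L, 450L, 880L))
  f <- filter_alignments(rec)
  expect_equal(nrow(f$retained), 2L)
  expect_equal(unname(f$coverage["r3"]), 0.88)

  # union below threshold: whole read unretained
  rec <- aln_row("r4", 1000L, 0L, "c", 0L, 800L, 0L, 800L)
  expect_equal(nrow(filter_alignments(rec)$retained), 0L)

  # malformed query interval rejected at record level
  rec <- aln_row("r5", 1000L, 0L, "c", 0L, 900L, 500L, 200L)
  f <- filter_alignments(rec)
  expect_equal(nrow(f$rejected), 1L)
  expect_match(f$rejected$reason, "malformed")
})

test_that("every read receives exactly one class and counts sum up", {
  g <- std_genome()
  sim <- simulate_reads(g, n_reads = 200,
                        artifact_rates = c(fused = 0.15, symmetrical = 0.1,
                                           chimeric = 0.1), seed = 31)
  cls <- classify_reads(alignments_from_truth(sim$truth), sim$reads)
  expect_equal(nrow(cls), 200L)
  expect_setequal(unique(cls$class),
                  intersect(c("proper", "fused", "symmetrical",
                              "unmapped_or_other"), cls$class))
  expect_equal(sum(table(cls$class)), 200L)
})

test_that("planted artifact classes are recovered from exact placements", {
  g <- std_genome()
  sim <- simulate_reads(g, n_reads = 400,
                        artifact_rates = c(fused = 0.10, symmetrical = 0.05,
                                           chimeric = 0.05), seed = 17)
  cls <- classify_reads(alignments_from_truth(sim$truth), sim$reads)
  truth <- sim$truth$classes$class
  truth[truth == "chimeric"] <- "unmapped_or_other"
  names(truth) <- sim$truth$classes$read_id
  for (k in unique(truth)) {
    ids <- names(truth)[truth == k]
    acc <- mean(cls$class[match(ids, cls$read_id)] == k)
    expect_gte(acc, 0.95)
  }
})

test_that("depth binning averages per-base coverage, partial bins included", {
  lens <- c(c1 = 2500L)
  empty <- depth_track(aln_row("x", 1L, 0L, "c1", 0L, 1L, 0L, 1L)[0, ], lens)
  expect_true(all(empty$value == 0))
  expect_equal(nrow(empty), 3L)  # ceil(2500/1000)

  rec <- aln_row("r1", 3000L, 0L, "c1", 0L, 2500L, 0L, 2500L)
  tr <- depth_track(rec, lens)
  expect_equal(tr$value, c(1, 1, 1))  # terminal bin averaged over 500 bases
  expect_equal(tr$end[3], 2500L)

  rec2 <- rbind(rec, aln_row("r2", 3000L, 0L, "c1", 0L, 500L, 0L, 500L))
  tr2 <- depth_track(rec2, lens)
  expect_equal(tr2$value[1], 1.5)  # 500 bases at depth 2, 500 at 1

  bad <- aln_row("r9", 3000L, 0L, "c1", 2000L, 3000L, 0L, 1000L)
  expect_error(depth_track(bad, lens), "r9")
})

test_that("simulated proper-read depth fluctuates around its expectation", {
  g <- make_genome(synthetic_genome_config(c(chr1 = 3e5), seed = 12))
  sim <- simulate_reads(g, depth = 50, length_meanlog = log(12000),
                        length_sdlog = 0.1, seed = 12)
  f <- filter_alignments(alignments_from_truth(sim$truth))
  tr <- depth_track(f$retained, nchar(g$sequences))
  interior <- tr$value[tr$start > 20000 & tr$end < 280000]
  expect_lt(abs(mean(interior) - 50), 3 * sqrt(50))
})

test_that("coverage-anomaly thresholds are strict and bins merge", {
  tr <- track_from_values(rep(150, 20))
  expect_equal(nrow(call_coverage_anomalies(tr)), 0L)

  # a bin exactly at the low threshold is not an anomaly
  v <- rep(150, 20); v[5] <- 100
  expect_equal(nrow(call_coverage_anomalies(track_from_values(v))), 0L)
  v[5] <- 99.9
  out <- call_coverage_anomalies(track_from_values(v))
  expect_equal(out$kind, "LCR")
  expect_equal(c(out$start, out$end), c(4000L, 5000L))

  # three consecutive low bins merge into one 3 kb LCR
  v <- rep(150, 20); v[7:9] <- 50; v[15] <- 300
  out <- call_coverage_anomalies(track_from_values(v))
  expect_equal(nrow(out), 2L)
  lcr <- out[out$kind == "LCR", ]
  expect_equal(c(lcr$start, lcr$end), c(6000L, 9000L))
  expect_equal(out$kind[out$start == 14000], "HCR")

  # HiFi profile uses the (20, 105) thresholds
  v <- rep(65, 10); v[3] <- 19
  out <- call_coverage_anomalies(track_from_values(v), profile = "hifi")
  expect_equal(out$kind, "LCR")
})

test_that("re-calling anomalies on merged output changes nothing", {
  v <- rep(150, 30); v[5:8] <- 10; v[20:21] <- 400
  tr <- track_from_values(v)
  out1 <- call_coverage_anomalies(tr)
  # re-express the merged intervals as constant bins and re-call
  bins <- do.call(rbind, lapply(seq_len(nrow(out1)), function(i) {
    s <- seq(out1$start[i], out1$end[i] - 1000, by = 1000)
    data.frame(chrom = out1$chrom[i], start = s, end = s + 1000,
               value = if (out1$kind[i] == "LCR") 10 else 400)
  }))
  out2 <- call_coverage_anomalies(bins)
  expect_equal(out2[, c("chrom", "start", "end", "kind")],
               out1[, c("chrom", "start", "end", "kind")])
})
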