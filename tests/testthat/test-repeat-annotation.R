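trf_record <- function(chrom, start, end, unit_length, copy_number, score,
                       consensus = "ACGT") {
  data.frame(chrom = chrom, start = start, end = end,
             unit_length = unit_length, copy_number = copy_number,
             score = score, consensus = consensus, stringsAsFactors = FALSE)
}

test_that("the TRF .dat dialect parses with 0-based half-open coordinates", {
  dat <- c(
    "Tandem Repeats Finder Program",
    "",
    "Sequence: chrT",
    "",
    "Parameters: 2 7 7 80 10 50 500",
    "",
    "471 530 3 20.0 3 100 0 120 0 33 33 32 1.58 TAG TAGTAGTAGTAG",
    "1001 1900 180 5.0 180 95 1 800 25 25 25 25 2.00 ACGTACGT ACGT")
  path <- tempfile(fileext = ".dat")
  writeLines(dat, path)
  tab <- read_trf_dat(path)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$chrom, c("chrT", "chrT"))
  expect_equal(tab$start, c(470L, 1000L))
  expect_equal(tab$end, c(530L, 1900L))
  expect_equal(tab$unit_length, c(3L, 180L))
  expect_equal(tab$score, c(120, 800))
  expect_equal(tab$consensus[1], "TAG")
})

test_that("unit-length classes and the five-copy rule are applied", {
  recs <- rbind(
    trf_record("c", 0, 240, 3, 80, 100),       # TAG-style run
    trf_record("c", 1000, 1828, 180, 4.6, 200),  # below five copies
    trf_record("c", 3000, 4000, 100, 10, 150),   # inclusive upper bound
    trf_record("c", 5000, 5100, 10, 10, 90),     # lower bound inclusive
    trf_record("c", 6000, 8000, 200, 10, 300))
  out <- classify_tandem_repeats(recs)
  expect_equal(nrow(out), 4L)
  expect_false(1000 %in% out$start)
  cls <- setNames(out$class, out$start)
  expect_equal(unname(cls["0"]), "microsatellite")
  expect_equal(unname(cls["3000"]), "minisatellite")
  expect_equal(unname(cls["5000"]), "minisatellite")
  expect_equal(unname(cls["6000"]), "satellite")
})

test_that("redundant reciprocal-overlap records resolve to the best one", {
  recs <- rbind(
    trf_record("c", 0, 1000, 120, 8, 500),
    trf_record("c", 100, 1050, 120, 8, 400),  # >50% reciprocal with above
    trf_record("c", 900, 3000, 150, 12, 300)) # <50% reciprocal: kept
  out <- classify_tandem_repeats(recs)
  expect_equal(sort(out$start), c(0, 900))
  # nonpositive unit length is rejected with a log message
  expect_message(classify_tandem_repeats(
    rbind(recs, trf_record("c", 4000, 4100, 0, 10, 50))), "rejected")
})

test_that("window density equals per-base covered fraction", {
  expect_true(all(density_track(iv(integer(0), integer(0)), 5e5)$density == 0))

  hits <- iv(200000, 300000)
  d <- density_track(hits, 5e5)
  expect_equal(d$density[d$start == 200000], 1.0)
  expect_equal(d$density[d$start == 150000], 0.5)

  # planted 36 kb block: peak density 0.36, and every window agrees with
  # the brute-force per-base count
  hits <- iv(120000, 156000)
  d <- density_track(hits, 4e5)
  expect_equal(max(d$density), 0.36)
  for (i in sample(nrow(d), 25)) {
    expect_equal(d$density[i],
                 oracle_window_density(hits, d$start[i], d$end[i]))
  }
  # terminal windows use their actual length
  expect_equal(d$end[nrow(d)], 400000L)
})

test_that("satellite arrays are called above threshold, merged and trimmed", {
  expect_equal(nrow(call_satellite_arrays(
    data.frame(start = 0, end = 1e5, density = 0.10), iv(0, 5000))), 0L)

  # planted block recovered with hit-level boundaries on a 500 kb sequence
  hits <- iv(seq(210000, 245820, by = 180), seq(210180, 246000, by = 180))
  d <- density_track(hits, 5e5)
  arr <- call_satellite_arrays(d, hits, family = "centc")
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$start, 210000)
  expect_equal(arr$end, 246000)
  expect_equal(arr$satellite_bases, 36000L)

  # two blocks far apart stay two arrays
  hits2 <- rbind(hits, iv(hits$start + 250000, hits$end + 250000))
  d2 <- density_track(hits2, 8e5)
  arr2 <- call_satellite_arrays(d2, hits2)
  expect_equal(nrow(arr2), 2L)
  expect_equal(arr2$start, c(210000, 460000))
})

test_that("raising the density threshold never increases total array length", {
  g <- std_genome()
  hits <- satellite_hits_from_truth(g$truth,
                                    attr(g$config, "monomer_lengths"))
  h <- hits[hits$family == "centc", c("start", "end")]
  d <- density_track(h, nchar(g$sequences[["chrA"]]))
  total <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(th) {
    a <- call_satellite_arrays(d, h, threshold = th)
    sum(a$end - a$start)
  }, 0)
  expect_true(all(diff(total) <= 0))
})

test_that("TE arrays require >95% TE windows and no genes", {
  # TE fraction 0.90 everywhere: nothing called
  te <- iv(seq(0, 9e5, by = 1e5), seq(0, 9e5, by = 1e5) + 90000)
  expect_equal(nrow(call_te_arrays(te, iv(integer(0), integer(0)), 1e6)), 0L)

  # pure 800 kb TE block, no genes: one array longer than 700 kb
  te <- iv(100000, 900000)
  arr <- call_te_arrays(te, iv(integer(0), integer(0)), 1e6,
                        min_length = 700000)
  expect_equal(nrow(arr), 1L)
  expect_gte(arr$length, 700000)

  # the same block with one gene inside is excluded
  arr2 <- call_te_arrays(te, iv(500000, 505000), 1e6, min_length = 0)
  expect_true(all(arr2$start >= 505000 | arr2$end <= 500000))
})

test_that("segmental duplications filter strictly and merge adjacently", {
  pairs <- data.frame(
    chrom1 = "c", start1 = c(0, 0, 10000),
    end1 = c(2000, 5000, 15000),
    chrom2 = "c", start2 = c(2000, 50000, 60000),
    end2 = c(3500, 55000, 65000),
    identity = c(0.995, 0.99, 0.999),
    length = c(2000, 5000, 900))
  out <- merge_segmental_duplications(pairs)
  # row 2 dropped (identity exactly 0.99), row 3 dropped (length <= 1000);
  # the two projections [0,2000) and [2000,3500) merge book-ended
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$start, out$end), c(0, 3500))

  # at the survey convention (0.98) row 2 also passes; its projections
  # absorb the first pair's, leaving [0,5000) and [50000,55000)
  out98 <- merge_segmental_duplications(pairs, min_identity = 0.98)
  expect_equal(nrow(out98), 2L)
  expect_equal(out98$end[1], 5000)
})
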