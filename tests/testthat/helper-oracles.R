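# independent brute-force oracles, deliberately naive and separate from the
# implementations they check

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# enumerate canonical k-mers position by position
oracle_canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  out <- character(0)
  for (i in seq_len(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("N", w, fixed = TRUE)) next
    rc <- oracle_revcomp(w)
    out <- c(out, if (w <= rc) w else rc)
  }
  out
}

# per-column symbol tallies of an alignment matrix, N excluded
oracle_ppm <- function(msa) {
  syms <- c("A", "C", "G", "T", "-")
  sapply(seq_len(ncol(msa)), function(c) {
    col <- msa[, c][msa[, c] != "N"]
    vapply(syms, function(s) sum(col == s) / length(col), 0)
  })
}

oracle_variant_distance <- function(row, msa) {
  ppm <- oracle_ppm(msa)
  total <- 0
  for (c in seq_along(row)) {
    if (row[c] == "N") next
    total <- total + (1 - unname(ppm[row[c], c]))
  }
  total
}

# all-pairs Hamming (gap as symbol, N columns skipped), naive double loop
oracle_pairwise_matrix <- function(msa) {
  n <- nrow(msa)
  D <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- 0
    for (c in seq_len(ncol(msa))) {
      if (msa[i, c] == "N" || msa[j, c] == "N") next
      if (msa[i, c] != msa[j, c]) d <- d + 1
    }
    D[i, j] <- d
  }
  D
}

oracle_group_hors <- function(msa, threshold = 5) {
  D <- oracle_pairwise_matrix(msa)
  ids <- rownames(msa)
  hoods <- lapply(seq_len(nrow(msa)), function(i)
    sort(ids[union(i, which(D[i, ] <= threshold))]))
  unique(hoods[vapply(hoods, length, 0L) >= 2L])
}

# per-base covered fraction of a window
oracle_window_density <- function(hits, from, to) {
  covered <- logical(to - from)
  for (i in seq_len(nrow(hits))) {
    lo <- max(hits$start[i], from); hi <- min(hits$end[i], to)
    if (hi > lo) covered[(lo - from + 1):(hi - from)] <- TRUE
  }
  mean(covered)
}

# Hamming distance between two equal-length sequences
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
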