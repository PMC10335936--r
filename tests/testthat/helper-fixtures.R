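# fixtures built in code; the standard genome is cached across test files
.fixture_cache <- new.env(parent = emptyenv())

std_genome <- function(seed = 1L) {
  key <- paste0("std_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_genome(standard_genome_config(seed))
  .fixture_cache[[key]]
}

# small helper: interval data frame
iv <- function(start, end, chrom = NULL, family = NULL) {
  df <- data.frame(start = start, end = end)
  if (!is.null(chrom)) df <- cbind(data.frame(chrom = chrom), df)
  if (!is.null(family)) df$family <- family
  df
}

# binned track data frame from a vector of bin values
track_from_values <- function(values, bin_width = 1000, chrom = "chrT") {
  n <- length(values)
  data.frame(chrom = chrom, start = (seq_len(n) - 1L) * bin_width,
             end = seq_len(n) * bin_width, value = values,
             stringsAsFactors = FALSE)
}
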