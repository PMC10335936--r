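#' @importFrom stats rbinom rlnorm rnorm runif setNames
#' @importFrom utils head tail read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate code with a private RNG seed
#'
#' Saves the global RNG state, seeds it, runs `code`, and restores the old
#' state on exit, so every stochastic operation in the package owns its seed
#' and never leaks RNG state into the caller's session.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T/N (case-insensitive).
#' @return reverse complement, uppercase.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# reverse complement of a character vector of bases (one base per element)
revcomp_chars <- function(v) {
  rev(chartr("ACGTN", "TGCAN", v))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# draw a different base for each position to be substituted
substitute_bases <- function(bases) {
  vapply(bases, function(b) sample(setdiff(DNA_BASES, b), 1L), "", USE.NAMES = FALSE)
}

#' Convert a 0-based half-open interval data frame to IRanges
#' @keywords internal
df_to_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

iranges_to_df <- function(ir, chrom = NULL) {
  out <- data.frame(start = BiocGenerics::start(ir) - 1L,
                    end = BiocGenerics::end(ir))
  if (!is.null(chrom)) out <- cbind(data.frame(chrom = chrom), out)
  out
}

# total bases of `windows` (0-based half-open df rows) covered by `hits`
covered_bases <- function(hits_ir, from, to) {
  if (length(hits_ir) == 0L) return(0L)
  win <- IRanges::IRanges(from + 1L, to)
  sum(BiocGenerics::width(IRanges::intersect(
    IRanges::reduce(hits_ir), win)))
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
}
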