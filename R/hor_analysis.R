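#' Read an aligned FASTA into a monomer alignment matrix
#'
#' @param path aligned FASTA (rows of equal length; alphabet A/C/G/T/-/N).
#' @return character matrix, one row per monomer, rownames = ids.
#' @export
read_msa_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(ss))
  msa_matrix(rows)
}

#' Build an alignment matrix from gapped sequences
#'
#' @param rows named character vector of equal-length gapped sequences.
#' @return character matrix (rows x columns).
#' @export
msa_matrix <- function(rows) {
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows must have equal length", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(rows), ""))
  rownames(m) <- names(rows)
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "-", "N"))
  if (length(bad))
    stop("alignment contains symbols outside {A,C,G,T,-,N}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  m
}

MSA_SYMBOLS <- c("A", "C", "G", "T", "-")

#' Position probability matrix of a monomer alignment
#'
#' Column c probability of symbol s is the count of s in column c divided
#' by the rows counting toward that column; N is excluded from both
#' numerator and denominator, so each column of the result sums to 1 over
#' `{A, C, G, T, -}` (columns that are all N are left at zero).
#'
#' @param msa character matrix from [msa_matrix()] (>= 2 rows).
#' @return 5 x ncol numeric matrix, rownames `A`, `C`, `G`, `T`, `-`.
#' @export
build_ppm <- function(msa) {
  if (is.null(dim(msa)) || nrow(msa) < 2L)
    stop("alignment must have at least 2 rows", call. = FALSE)
  ppm <- vapply(seq_len(ncol(msa)), function(c) {
    col <- msa[, c]
    col <- col[col != "N"]
    cnt <- tabulate(match(col, MSA_SYMBOLS), nbins = 5L)
    if (length(col)) cnt / length(col) else rep(0, 5)
  }, numeric(5))
  rownames(ppm) <- MSA_SYMBOLS
  ppm
}

#' Variant distance of a monomer to a position probability matrix
#'
#' Sum over alignment positions of the disagreeing probability, one minus
#' the PPM frequency of the monomer's symbol at that position. N positions
#' contribute zero.
#'
#' @param row gapped monomer sequence (string or character vector) of
#'   length equal to the PPM column count.
#' @param ppm matrix from [build_ppm()].
#' @return non-negative score (dimensionless).
#' @export
variant_distance <- function(row, ppm) {
  if (is.character(row) && length(row) == 1L) row <- strsplit(row, "")[[1]]
  row <- toupper(row)
  if (length(row) != ncol(ppm))
    stop("row length does not match PPM column count", call. = FALSE)
  keep <- row != "N"
  sym <- match(row[keep], MSA_SYMBOLS)
  if (anyNA(sym))
    stop("symbol outside {A,C,G,T,-,N} in row", call. = FALSE)
  sum(1 - ppm[cbind(sym, which(keep))])
}

#' Pairwise variant score between two aligned monomers
#'
#' The default (`method = "hamming"`) counts alignment columns where the
#' two monomers carry different symbols, with the gap treated as a fifth
#' symbol; columns where either monomer is N are skipped. With
#' `method = "ppm"` each disagreeing column instead contributes the mean
#' disagreeing probability of the two symbols under the supplied PPM,
#' down-weighting disagreements at poorly conserved positions.
#'
#' @param row_i,row_j gapped monomer sequences of equal length.
#' @param method `"hamming"` (default) or `"ppm"`.
#' @param ppm PPM matrix, required for `method = "ppm"`.
#' @return score (a column count for `"hamming"`).
#' @export
pairwise_variant_score <- function(row_i, row_j,
                                   method = c("hamming", "ppm"),
                                   ppm = NULL) {
  method <- match.arg(method)
  if (is.character(row_i) && length(row_i) == 1L)
    row_i <- strsplit(row_i, "")[[1]]
  if (is.character(row_j) && length(row_j) == 1L)
    row_j <- strsplit(row_j, "")[[1]]
  if (length(row_i) != length(row_j))
    stop("rows must have equal length", call. = FALSE)
  keep <- row_i != "N" & row_j != "N"
  diff <- keep & (row_i != row_j)
  if (method == "hamming") return(sum(diff))
  stopifnot(!is.null(ppm))
  cols <- which(diff)
  if (!length(cols)) return(0)
  pi <- ppm[cbind(match(row_i[cols], MSA_SYMBOLS), cols)]
  pj <- ppm[cbind(match(row_j[cols], MSA_SYMBOLS), cols)]
  sum(((1 - pi) + (1 - pj)) / 2)
}

#' All-pairs variant score matrix
#'
#' @param msa character matrix from [msa_matrix()].
#' @inheritParams pairwise_variant_score
#' @return symmetric numeric matrix of scores with zero diagonal.
#' @export
pairwise_score_matrix <- function(msa, method = c("hamming", "ppm"),
                                  ppm = NULL) {
  method <- match.arg(method)
  n <- nrow(msa)
  valid <- msa != "N"
  D <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  if (method == "hamming") {
    for (i in seq_len(n - 1L)) {
      ri <- msa[i, ]; vi <- valid[i, ]
      js <- (i + 1L):n
      D[i, js] <- vapply(js, function(j)
        sum(vi & valid[j, ] & (ri != msa[j, ])), 0)
    }
  } else {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      D[i, j] <- pairwise_variant_score(msa[i, ], msa[j, ], "ppm", ppm)
  }
  D + t(D)
}

#' Group satellite monomers into higher-order repeat groups
#'
#' Each monomer's neighborhood is the set of monomers within
#' `threshold` pairwise variant score of it (plus itself); the
#' deduplicated neighborhoods with at least two members are the
#' higher-order repeat groups. A monomer may belong to several groups
#' (neighborhooods are not a partition), matching how recurring
#' multi-monomer arrangements share member copies.
#'
#' @param msa character matrix of aligned full-length monomers.
#' @param threshold inclusive score threshold (default 5).
#' @inheritParams pairwise_variant_score
#' @return list of character vectors of monomer ids, ordered by first
#'   member; empty list if no monomer has a neighbor.
#' @export
group_hors <- function(msa, threshold = 5, method = c("hamming", "ppm"),
                       ppm = NULL) {
  method <- match.arg(method)
  if (nrow(msa) < 2L) stop("need at least 2 monomers", call. = FALSE)
  ids <- rownames(msa)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(msa)))
  D <- pairwise_score_matrix(msa, method, ppm)
  hoods <- lapply(seq_len(nrow(msa)), function(i) {
    nb <- which(D[i, ] <= threshold)
    sort(ids[union(i, nb)])
  })
  hoods <- hoods[vapply(hoods, length, 0L) >= 2L]
  unique(hoods)
}

#' Per-monomer variant distances of an alignment
#'
#' Convenience wrapper: builds the PPM from the alignment and scores every
#' row against it.
#'
#' @param msa character matrix from [msa_matrix()].
#' @return named numeric vector of variant distances.
#' @export
msa_variant_distances <- function(msa) {
  ppm <- build_ppm(msa)
  setNames(vapply(seq_len(nrow(msa)), function(i)
    variant_distance(msa[i, ], ppm), 0), rownames(msa))
}

#' Simulate an aligned monomer set with planted families
#'
#' Emits gap-free equal-length monomers (hence trivially aligned): each
#' family has a consensus derived from a shared ancestral sequence by a
#' fixed number of family-defining substitutions, and each monomer
#' deviates from its family consensus at up to `within_diff` random
#' positions.
#'
#' @param n_per_family monomers per family (vector gives per-family
#'   counts).
#' @param n_families number of families.
#' @param monomer_length monomer (alignment) length.
#' @param between_diff substitutions separating each family consensus from
#'   the ancestor (pairwise family distance is up to twice this).
#' @param within_diff maximum substitutions of a monomer from its family
#'   consensus (the actual count is uniform on `0:within_diff`).
#' @param seed integer RNG seed.
#' @return list with `msa` (character matrix) and `family` (named vector
#'   of planted family labels).
#' @export
simulate_monomer_msa <- function(n_per_family = 100, n_families = 2,
                                 monomer_length = 180, between_diff = 6,
                                 within_diff = 2, seed = 1L) {
  with_seed(seed, {
    counts <- rep_len(n_per_family, n_families)
    ancestor <- sample(DNA_BASES, monomer_length, replace = TRUE)
    # family-defining positions are disjoint so family consensus distance
    # is exactly 2 * between_diff for any pair
    pos <- sample(monomer_length, n_families * between_diff)
    consensus <- lapply(seq_len(n_families), function(f) {
      cs <- ancestor
      p <- pos[seq((f - 1) * between_diff + 1, f * between_diff)]
      cs[p] <- substitute_bases(cs[p])
      cs
    })
    rows <- list(); fam <- character(0)
    for (f in seq_len(n_families)) {
      for (i in seq_len(counts[f])) {
        m <- consensus[[f]]
        k <- sample(0:within_diff, 1L)
        if (k > 0) {
          p <- sample(monomer_length, k)
          m[p] <- substitute_bases(m[p])
        }
        rows[[length(rows) + 1L]] <- m
        fam <- c(fam, sprintf("family_%d", f))
      }
    }
    msa <- do.call(rbind, rows)
    rownames(msa) <- sprintf("monomer_%03d", seq_len(nrow(msa)))
    list(msa = msa, family = setNames(fam, rownames(msa)))
  })
}
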