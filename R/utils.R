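## Internal helpers shared across modules.

#' Pairwise mismatch counts between equal-length sequences
#'
#' Counts mismatching positions between every pair of sequences. Positions
#' where either base is `N` always count as mismatches. When quality matrices
#' are supplied, positions where either sequence has quality `<= min_quality`
#' are excluded from the comparison (treated as matching), except that `N`
#' overrides the quality mask.
#'
#' @param seqs character vector of equal-length sequences over `{A,C,G,T,N}`.
#' @param quals optional integer matrix (`length(seqs)` rows) of per-position
#'   Phred qualities aligned with `seqs`.
#' @param min_quality bases with quality at or below this are masked.
#' @return integer distance matrix.
#' @keywords internal
#' @noRd
seq_dist_matrix <- function(seqs, quals = NULL, min_quality = 0L) {
  n <- length(seqs)
  if (n == 0L) return(matrix(0L, 0L, 0L))
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("sequences must be of uniform length (mixed lengths: ",
         paste(len, collapse = ", "), ")")
  M <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = n, byrow = TRUE)
  isN <- M == "N"
  d <- matrix(0L, n, n)
  if (n == 1L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      diff <- M[i, ] != M[j, ]
      anyN <- isN[i, ] | isN[j, ]
      if (!is.null(quals)) {
        low <- quals[i, ] <= min_quality | quals[j, ] <= min_quality
        mism <- (diff & !low) | anyN
      } else {
        mism <- diff | anyN
      }
      d[i, j] <- d[j, i] <- sum(mism)
    }
  }
  d
}

## Single-linkage components of a thresholded distance matrix; returns an
## integer membership vector (1-based, in order of first appearance).
single_linkage <- function(d, threshold) {
  n <- nrow(d)
  if (n == 0L) return(integer(0L))
  adj <- d <= threshold
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  ## renumber so that component ids follow first appearance
  as.integer(factor(memb, levels = unique(memb)))
}

## Phred string (offset 33) -> integer vector.
phred_to_int <- function(x) {
  lapply(x, function(s) as.integer(charCodeAt(s)) - 33L)
}

charCodeAt <- function(s) utf8ToInt(s)

## Integer qualities -> Phred string (offset 33).
int_to_phred <- function(q) intToUtf8(q + 33L, multiple = FALSE)

## Reverse complement for plain character strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
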