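# Shared test helpers: fixture loaders and small constructors.

marker_patterns <- function() {
  x <- read_pattern_tsv(shellmap_fixture("marker_patterns.tsv"))
  x$allele_id <- paste(x$locus_id, x$allele, sep = "_")
  x
}

cross_table <- function() {
  read_shellmap_tsv(shellmap_fixture("cross_phenotypes.tsv"))
}

# Genotype vectors for N offspring realizing given pairwise recombinant
# counts relative to a zero baseline marker.
geno_from_flips <- function(N, flips) {
  # flips: named list marker -> positions at which the call differs from
  # the baseline (all-zero) marker
  base <- rep(0, N)
  rows <- lapply(flips, function(idx) { v <- base; v[idx] <- 1; v })
  do.call(rbind, rows)
}

# Order comparison up to reversal, treating markers with identical observed
# genotype vectors as an unordered block (identical vectors carry no
# ordering information).
same_order_up_to_blocks <- function(est, truth, geno) {
  key <- apply(geno[truth, , drop = FALSE], 1L, paste, collapse = ",")
  block <- as.integer(factor(key, levels = unique(key)))
  names(block) <- truth
  collapse <- function(ord) rle(unname(block[ord]))$values
  est_blocks <- collapse(est)
  identical(est_blocks, collapse(truth)) ||
    identical(est_blocks, rev(collapse(truth)))
}
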