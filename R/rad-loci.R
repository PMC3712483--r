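## De novo RAD locus construction: demultiplexing, within-individual allele
## clustering, PCR-duplicate collapse, cross-individual merging and filters.

SBFI_MOTIF <- "CCTGCAGG"
SBFI_REMNANT <- "TGCAGG"  # residue left on the fragment after SbfI digestion

#' Validate a barcode set
#'
#' Barcodes must be unique, of one length, and pairwise at least two
#' mismatches apart (so a single sequencing error cannot switch individuals).
#'
#' @param barcodes named character vector `individual_id -> barcode`, or a
#'   data.frame with columns `individual_id` and `barcode`.
#' @return named character vector (invisibly validated).
#' @export
barcode_set <- function(barcodes) {
  if (is.data.frame(barcodes))
    barcodes <- setNames(barcodes$barcode, barcodes$individual_id)
  if (is.null(names(barcodes)) || any(names(barcodes) == ""))
    stop("barcodes must be named by individual id")
  if (anyDuplicated(barcodes))
    stop("duplicate barcode in set: ",
         paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
  if (length(unique(nchar(barcodes))) != 1L)
    stop("barcodes must all have the same length")
  if (length(barcodes) > 1L) {
    d <- seq_dist_matrix(unname(barcodes))
    if (any(d[upper.tri(d)] < 2L))
      stop("barcode set violates the minimum pairwise distance of 2")
  }
  barcodes
}

#' Demultiplex barcoded paired reads
#'
#' Assigns each read pair to an individual by the inline barcode at the 5'
#' end of read 1, checks the restriction-site remnant immediately after the
#' barcode, and trims the barcode so that the retained tag (remnant
#' included) is `read length - barcode length` bases (96 for 101-base
#' reads). Reads whose barcode is not an exact member of the set, or whose
#' remnant does not match, are discarded and counted. An optional rescue
#' mode accepts barcodes with a single mismatch when the match is unique
#' (the pairwise distance 2 guarantees uniqueness).
#'
#' @param pairs data.frame with columns `read1`, `read2` and optionally
#'   `qual1`, `qual2` (Phred+33 strings).
#' @param barcodes see [barcode_set()].
#' @param remnant expected restriction-site remnant at the start of the tag.
#' @param max_barcode_mismatch 0 (exact, default) or 1 (rescue mode).
#' @return list with `reads` (data.frame: `individual_id`, `tag`, `tag_qual`,
#'   `read2`, `read2_qual`), `n_input`, `n_assigned` and `discards` (named
#'   counts: `bad_barcode`, `bad_remnant`).
#' @export
demultiplex <- function(pairs, barcodes, remnant = SBFI_REMNANT,
                        max_barcode_mismatch = 0L) {
  barcodes <- barcode_set(barcodes)
  stopifnot(is.data.frame(pairs), all(c("read1", "read2") %in% names(pairs)))
  bl <- nchar(barcodes[[1L]])
  rl <- nchar(remnant)
  bc <- substr(pairs$read1, 1L, bl)
  idx <- match(bc, barcodes)
  if (max_barcode_mismatch >= 1L) {
    miss <- which(is.na(idx))
    if (length(miss)) {
      bcm <- matrix(unlist(strsplit(bc[miss], "", fixed = TRUE)),
                    ncol = bl, byrow = TRUE)
      refm <- matrix(unlist(strsplit(unname(barcodes), "", fixed = TRUE)),
                     ncol = bl, byrow = TRUE)
      for (k in seq_along(miss)) {
        dd <- rowSums(refm != matrix(bcm[k, ], nrow(refm), bl, byrow = TRUE))
        hit <- which(dd <= 1L)
        if (length(hit) == 1L) idx[miss[k]] <- hit
      }
    }
  }
  rem_ok <- substr(pairs$read1, bl + 1L, bl + rl) == remnant
  keep <- !is.na(idx) & rem_ok
  discards <- c(bad_barcode = sum(is.na(idx)),
                bad_remnant = sum(!is.na(idx) & !rem_ok))
  q1 <- pairs$qual1 %||% strrep("I", nchar(pairs$read1))
  q2 <- pairs$qual2 %||% strrep("I", nchar(pairs$read2))
  reads <- data.frame(
    individual_id = names(barcodes)[idx[keep]],
    tag = substr(pairs$read1[keep], bl + 1L, nchar(pairs$read1[keep])),
    tag_qual = substr(q1[keep], bl + 1L, nchar(q1[keep])),
    read2 = pairs$read2[keep],
    read2_qual = q2[keep],
    stringsAsFactors = FALSE)
  list(reads = reads, n_input = nrow(pairs), n_assigned = nrow(reads),
       discards = discards)
}

#' Cluster one individual's tags into candidate loci and alleles
#'
#' Distinct tag sequences with read depth at or above `min_depth` become
#' candidate alleles; alleles are joined into one locus by single linkage
#' whenever their mismatch count over mutually high-quality positions is at
#' most `max_distance`. Positions where either allele has base quality at or
#' below `min_quality` are excluded from the comparison; `N` bases never
#' match. Per-position allele quality is the maximum over the reads carrying
#' the allele. Output ordering is canonical (loci by representative tag,
#' alleles by depth descending then tag), so clustering is invariant to the
#' input read order.
#'
#' @param tags character vector of uniform-length tag sequences (one entry
#'   per read).
#' @param quals optional Phred+33 quality strings aligned with `tags`.
#' @param max_distance maximum mismatches joining two alleles (default 5).
#' @param min_quality bases with quality at or below this are masked
#'   (default 20).
#' @param min_depth minimum read depth for an allele (default 2).
#' @return data.frame with columns `locus` (integer, per-individual), `tag`,
#'   `depth`.
#' @export
cluster_alleles <- function(tags, quals = NULL, max_distance = 5L,
                            min_quality = 20L, min_depth = 2L) {
  if (length(tags) == 0L)
    return(data.frame(locus = integer(0), tag = character(0),
                      depth = integer(0)))
  if (length(unique(nchar(tags))) != 1L)
    stop("tags must be of uniform length; indel-bearing loci are handled ",
         "downstream by rescue_split_loci()")
  u <- sort(unique(tags))
  depth <- tabulate(match(tags, u), nbins = length(u))
  keep <- depth >= min_depth
  u <- u[keep]; depth <- depth[keep]
  if (length(u) == 0L)
    return(data.frame(locus = integer(0), tag = character(0),
                      depth = integer(0)))
  Q <- NULL
  if (!is.null(quals)) {
    len <- nchar(tags[[1L]])
    Q <- matrix(0L, length(u), len)
    qint <- phred_to_int(quals)
    grp <- match(tags, u)
    for (i in seq_along(tags)) {
      g <- grp[i]
      if (!is.na(g)) Q[g, ] <- pmax(Q[g, ], qint[[i]])
    }
  }
  d <- seq_dist_matrix(u, quals = Q, min_quality = if (is.null(Q)) 0L else min_quality)
  memb <- single_linkage(d, max_distance)
  ## canonical order: alleles by depth desc then tag; loci by their
  ## representative (first) allele's tag
  ord <- order(memb, -depth, u)
  u <- u[ord]; depth <- depth[ord]; memb <- memb[ord]
  rep_tag <- tapply(u, memb, function(x) x[[1L]])
  relabel <- rank(rep_tag, ties.method = "first")
  memb <- relabel[as.character(memb)]
  ord2 <- order(memb, -depth, u)
  data.frame(locus = as.integer(memb[ord2]), tag = u[ord2],
             depth = depth[ord2], row.names = NULL)
}

#' Collapse PCR duplicates into fragment counts
#'
#' RAD libraries are PCR-amplified, so read counts overstate the number of
#' template molecules. Because shearing is random, independent template
#' fragments almost surely differ in their second-read (shear-end) sequence,
#' while PCR duplicates are identical. Per allele and individual, the
#' fragment count is the number of distinct second-read sequences.
#'
#' @param reads data.frame with columns `individual_id`, `tag` and `read2`
#'   (as produced by [demultiplex()]); rows with missing `read2` are skipped
#'   and counted.
#' @return list with `counts` (data.frame: `individual_id`, `tag`,
#'   `read_count`, `fragment_count`) and `n_skipped` (pairs lacking a mate).
#' @export
estimate_fragment_counts <- function(reads) {
  stopifnot(all(c("individual_id", "tag", "read2") %in% names(reads)))
  bad <- is.na(reads$read2) | reads$read2 == ""
  n_skipped <- sum(bad)
  reads <- reads[!bad, , drop = FALSE]
  if (nrow(reads) == 0L)
    return(list(counts = data.frame(individual_id = character(0),
                                    tag = character(0),
                                    read_count = integer(0),
                                    fragment_count = integer(0)),
                n_skipped = n_skipped))
  key <- paste(reads$individual_id, reads$tag, sep = "\r")
  sp <- split(reads$read2, key)
  ids <- do.call(rbind, strsplit(names(sp), "\r", fixed = TRUE))
  counts <- data.frame(
    individual_id = ids[, 1L],
    tag = ids[, 2L],
    read_count = lengths(sp),
    fragment_count = vapply(sp, function(x) length(unique(x)), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  counts <- counts[order(counts$individual_id, counts$tag), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts, n_skipped = n_skipped)
}

#' Merge per-individual loci across individuals and apply filters
#'
#' Distinct allele sequences from all individuals are merged into loci by
#' single linkage on pairwise mismatch counts (at most `max_mismatch`, plain
#' Hamming distance over full-quality comparisons). Two filters follow:
#' loci observed in a single individual are discarded, and merged loci with
#' more than `max_alleles` alleles are discarded as presumed repeats (at
#' most four alleles can segregate in a two-parent cross).
#'
#' @param alleles data.frame with columns `individual_id`, `tag`, `depth`
#'   and optionally `read_count`, `fragment_count` — one row per allele per
#'   individual (the per-individual output of [cluster_alleles()] joined
#'   with [estimate_fragment_counts()]).
#' @param max_mismatch maximum mismatches for cross-individual merging
#'   (default 3).
#' @param max_alleles maximum alleles per merged locus (default 4).
#' @param individuals optional character vector fixing the column order of
#'   the presence matrix; defaults to order of first appearance.
#' @return object of class `rad_loci`: list with `alleles` (data.frame:
#'   `locus_id`, `allele_id`, `tag`), `presence` (0/1 matrix, alleles x
#'   individuals), `observations` (the input rows with locus/allele ids
#'   attached), and `dropped` (counts: `single_individual`,
#'   `excess_alleles`).
#' @export
merge_across_individuals <- function(alleles, max_mismatch = 3L,
                                     max_alleles = 4L, individuals = NULL) {
  stopifnot(all(c("individual_id", "tag", "depth") %in% names(alleles)))
  if (nrow(alleles) == 0L) stop("no alleles to merge")
  individuals <- individuals %||% unique(alleles$individual_id)
  seqs <- sort(unique(alleles$tag))
  d <- seq_dist_matrix(seqs)
  memb <- single_linkage(d, max_mismatch)
  ## locus ids ordered by representative tag
  rep_tag <- tapply(seqs, memb, min)
  relabel <- rank(rep_tag, ties.method = "first")
  memb <- relabel[as.character(memb)]
  locus_of_seq <- setNames(memb, seqs)

  obs <- alleles
  obs$locus <- locus_of_seq[obs$tag]

  n_ind <- tapply(obs$individual_id, obs$locus,
                  function(x) length(unique(x)))
  n_all <- tapply(seqs, memb, length)
  keep_loci <- as.integer(names(n_ind))[n_ind >= 2L &
                                          n_all[names(n_ind)] <= max_alleles]
  dropped <- c(single_individual = sum(n_ind < 2L),
               excess_alleles = sum(n_ind >= 2L &
                                      n_all[names(n_ind)] > max_alleles))
  keep_loci <- sort(keep_loci)
  locus_id <- setNames(sprintf("RL%05d", seq_along(keep_loci)),
                       keep_loci)

  seq_keep <- seqs[memb %in% keep_loci]
  memb_keep <- memb[memb %in% keep_loci]
  allele_tbl <- data.frame(locus_id = locus_id[as.character(memb_keep)],
                           tag = seq_keep, stringsAsFactors = FALSE)
  allele_tbl <- allele_tbl[order(allele_tbl$locus_id, allele_tbl$tag), ,
                           drop = FALSE]
  if (nrow(allele_tbl)) {
    idx <- stats::ave(seq_len(nrow(allele_tbl)), allele_tbl$locus_id,
                      FUN = seq_along)
    allele_tbl$allele_id <- paste0(allele_tbl$locus_id, "_a", idx)
  } else {
    allele_tbl$allele_id <- character(0)
  }
  rownames(allele_tbl) <- NULL

  obs <- obs[obs$locus %in% keep_loci, , drop = FALSE]
  obs$locus_id <- locus_id[as.character(obs$locus)]
  obs$allele_id <- allele_tbl$allele_id[match(obs$tag, allele_tbl$tag)]
  obs$locus <- NULL

  presence <- matrix(0L, nrow(allele_tbl), length(individuals),
                     dimnames = list(allele_tbl$allele_id, individuals))
  presence[cbind(match(obs$allele_id, allele_tbl$allele_id),
                 match(obs$individual_id, individuals))] <- 1L

  structure(list(alleles = allele_tbl[, c("locus_id", "allele_id", "tag")],
                 presence = presence, observations = obs, dropped = dropped),
            class = "rad_loci")
}

#' @export
print.rad_loci <- function(x, ...) {
  cat("<rad_loci> ", length(unique(x$alleles$locus_id)), " loci, ",
      nrow(x$alleles), " alleles across ", ncol(x$presence),
      " individuals\n", sep = "")
  cat("  dropped: ", x$dropped[["single_individual"]],
      " single-individual, ", x$dropped[["excess_alleles"]],
      " with excess alleles\n", sep = "")
  invisible(x)
}

#' Serialize a RAD locus set as segregation patterns
#'
#' Converts the presence matrix of a [merge_across_individuals()] /
#' [build_rad_loci()] result into the pattern table consumed by
#' [find_candidates()], with individuals in the stated (panel) order.
#'
#' @param loci a `rad_loci` object.
#' @param individuals column order for the patterns (default: presence
#'   matrix order); typically `panel$individual_id`.
#' @return data.frame with `locus_id`, `allele_id`, `pattern`.
#' @export
presence_patterns <- function(loci, individuals = colnames(loci$presence)) {
  stopifnot(inherits(loci, "rad_loci"),
            all(individuals %in% colnames(loci$presence)))
  P <- loci$presence[, individuals, drop = FALSE]
  data.frame(locus_id = loci$alleles$locus_id,
             allele_id = loci$alleles$allele_id,
             pattern = apply(P, 1L, paste, collapse = ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expected number of RAD loci from genome size and GC content
#'
#' Under an independent-base genome model with the given GC fraction, the
#' expected number of restriction sites is the genome size times the motif
#' probability; each site yields `tags_per_site` RAD loci (one on each
#' flank).
#'
#' @param genome_size_bp genome size in bases (diploid if the library is
#'   built per diploid individual, as here).
#' @param gc_fraction GC content in (0, 1).
#' @param motif recognition sequence (default SbfI, `CCTGCAGG`).
#' @param tags_per_site tags generated per site (default 2).
#' @return expected locus count (real).
#' @examples
#' expected_locus_count(6.6e9, 0.37)  # ~52,500 for SbfI
#' @export
expected_locus_count <- function(genome_size_bp, gc_fraction,
                                 motif = SBFI_MOTIF, tags_per_site = 2) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be in (0, 1)")
  bases <- strsplit(motif, "", fixed = TRUE)[[1L]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("motif must be over {A,C,G,T}")
  p <- ifelse(bases %in% c("G", "C"), gc_fraction / 2, (1 - gc_fraction) / 2)
  genome_size_bp * prod(p) * tags_per_site
}

#' Run the full read-to-locus pipeline
#'
#' Convenience wrapper: demultiplex, cluster alleles per individual, collapse
#' PCR duplicates into fragment counts, merge across individuals and filter.
#'
#' @inheritParams demultiplex
#' @inheritParams cluster_alleles
#' @inheritParams merge_across_individuals
#' @param use_quality use read qualities during clustering (default TRUE
#'   when present).
#' @return list with `loci` (a `rad_loci` object whose `observations` carry
#'   read and fragment counts) and `log` (per-stage record counts).
#' @export
build_rad_loci <- function(pairs, barcodes, remnant = SBFI_REMNANT,
                           max_barcode_mismatch = 0L, max_distance = 5L,
                           min_quality = 20L, min_depth = 2L,
                           max_mismatch = 3L, max_alleles = 4L,
                           use_quality = TRUE) {
  dm <- demultiplex(pairs, barcodes, remnant, max_barcode_mismatch)
  fc <- estimate_fragment_counts(dm$reads)
  per_ind <- split(dm$reads, dm$reads$individual_id)
  clustered <- lapply(names(per_ind), function(id) {
    x <- per_ind[[id]]
    cl <- cluster_alleles(x$tag,
                          quals = if (use_quality) x$tag_qual else NULL,
                          max_distance = max_distance,
                          min_quality = min_quality, min_depth = min_depth)
    if (nrow(cl) == 0L) return(NULL)
    cl$individual_id <- id
    cl
  })
  clustered <- do.call(rbind, clustered)
  if (is.null(clustered) || nrow(clustered) == 0L)
    stop("no alleles passed the depth filter")
  key <- paste(clustered$individual_id, clustered$tag)
  fkey <- paste(fc$counts$individual_id, fc$counts$tag)
  clustered$read_count <- fc$counts$read_count[match(key, fkey)]
  clustered$fragment_count <- fc$counts$fragment_count[match(key, fkey)]
  barcodes <- barcode_set(barcodes)
  loci <- merge_across_individuals(clustered, max_mismatch = max_mismatch,
                                   max_alleles = max_alleles,
                                   individuals = names(barcodes))
  list(loci = loci,
       log = list(n_input = dm$n_input, n_assigned = dm$n_assigned,
                  discards = dm$discards, n_mate_skipped = fc$n_skipped,
                  n_alleles_clustered = nrow(clustered),
                  n_loci = length(unique(loci$alleles$locus_id)),
                  dropped = loci$dropped))
}
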