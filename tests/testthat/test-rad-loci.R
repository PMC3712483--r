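make_pairs <- function(read1, read2 = strrep("G", 101)) {
  data.frame(read1 = read1, read2 = rep_len(read2, length(read1)),
             stringsAsFactors = FALSE)
}

bc <- c(IND1 = "AACCT", IND2 = "GGTTA")
tag96 <- function(body) paste0("TGCAGG", strrep(body, 90 / nchar(body)))

test_that("demultiplexing is exact by default, with conservation of reads", {
  reads <- c(paste0("AACCT", tag96("A")),   # IND1
             paste0("GGTTA", tag96("C")),   # IND2
             paste0("AACCA", tag96("A")),   # 1-mismatch barcode
             paste0("AACCT", "TTTTTT", strrep("A", 90)))  # bad remnant
  dm <- demultiplex(make_pairs(reads), bc)
  expect_equal(dm$n_assigned, 2L)
  expect_equal(unname(dm$discards), c(1L, 1L))
  expect_equal(dm$n_assigned + sum(dm$discards), dm$n_input)
  expect_equal(dm$reads$individual_id, c("IND1", "IND2"))
  expect_equal(unique(nchar(dm$reads$tag)), 96L)
  expect_true(all(startsWith(dm$reads$tag, "TGCAGG")))

  # rescue mode recovers the unique 1-mismatch barcode
  dm2 <- demultiplex(make_pairs(reads), bc, max_barcode_mismatch = 1L)
  expect_equal(dm2$n_assigned, 3L)
})

test_that("barcode sets enforce uniqueness and pairwise distance 2", {
  expect_error(barcode_set(c(A = "AAAAA", B = "AAAAA")), "duplicate")
  expect_error(barcode_set(c(A = "AAAAA", B = "AAAAT")), "distance")
  expect_silent(barcode_set(bc))
  expect_silent(barcode_set(make_barcodes(sprintf("I%02d", 1:26))))
})

test_that("allele clustering joins near-identical tags and drops singletons", {
  t1 <- tag96("A")
  t2 <- t1; substr(t2, 20, 22) <- "CCC"   # 3 mismatches from t1
  t3 <- tag96("C")                        # far from both
  cl <- cluster_alleles(c(rep(t1, 4), rep(t2, 3), rep(t3, 5), tag96("T")))
  expect_equal(nrow(cl), 3L)          # singleton tag dropped
  expect_equal(length(unique(cl$locus)), 2L)
  expect_equal(cl$locus[cl$tag == t1], cl$locus[cl$tag == t2])
  expect_equal(sum(cl$depth), 12L)

  one <- cluster_alleles(rep(t1, 8))
  expect_equal(nrow(one), 1L)
  expect_equal(one$depth, 8L)
})

test_that("allele clustering is invariant to read order", {
  set.seed(42)
  tags <- c(rep(tag96("A"), 5), rep(tag96("C"), 3), rep(tag96("G"), 2))
  a <- cluster_alleles(tags)
  b <- cluster_alleles(sample(tags))
  expect_identical(a, b)
})

test_that("low-quality positions are excluded from clustering distance", {
  t1 <- tag96("A")
  t2 <- t1
  for (p in c(10, 20, 30, 40, 50, 60, 70)) substr(t2, p, p) <- "C"  # 7 diffs
  hi <- strrep("I", 96)
  lo <- hi
  for (p in c(10, 20, 30)) substr(lo, p, p) <- "#"  # quality 2 at 3 sites
  # full quality: 7 mismatches -> two loci
  far <- cluster_alleles(c(rep(t1, 2), rep(t2, 2)), rep(hi, 4))
  expect_equal(length(unique(far$locus)), 2L)
  # masking 3 of the differing sites leaves 4 scored mismatches -> one locus
  near <- cluster_alleles(c(rep(t1, 2), rep(t2, 2)), c(hi, hi, lo, lo))
  expect_equal(length(unique(near$locus)), 1L)
})

test_that("mixed tag lengths are an error at the clustering stage", {
  expect_error(cluster_alleles(c(tag96("A"), substr(tag96("A"), 1, 90))),
               "uniform length")
})

test_that("fragment counts collapse identical shear signatures", {
  reads <- data.frame(individual_id = "I1", tag = tag96("A"),
                      read2 = c(rep("AAA", 4), rep("CCC", 4), rep("GGG", 2)))
  fc <- estimate_fragment_counts(reads)
  expect_equal(fc$counts$read_count, 10L)
  expect_equal(fc$counts$fragment_count, 3L)

  all_same <- estimate_fragment_counts(
    data.frame(individual_id = "I1", tag = tag96("A"), read2 = rep("AAA", 7)))
  expect_equal(all_same$counts$fragment_count, 1L)

  with_na <- estimate_fragment_counts(
    data.frame(individual_id = "I1", tag = tag96("A"),
               read2 = c("AAA", NA, "CCC")))
  expect_equal(with_na$n_skipped, 1L)
  expect_equal(with_na$counts$read_count, 2L)
  expect_true(all(with_na$counts$fragment_count <= with_na$counts$read_count))
})

test_that("cross-individual merging applies the singleton and allele-count filters", {
  t1 <- tag96("A")
  t2 <- t1; substr(t2, 30, 31) <- "CC"    # 2 mismatches: same locus
  lonely <- tag96("C")                    # seen in one individual only
  inds <- c("father", sprintf("O%02d", 1:10))
  shared <- data.frame(individual_id = inds, tag = t1, depth = 5)
  alt <- data.frame(individual_id = "O01", tag = t2, depth = 3)
  single <- data.frame(individual_id = "father", tag = lonely, depth = 9)
  res <- merge_across_individuals(rbind(shared, alt, single))
  expect_equal(length(unique(res$alleles$locus_id)), 1L)
  expect_equal(res$dropped[["single_individual"]], 1L)
  expect_equal(sum(res$presence[res$alleles$allele_id[
    res$alleles$tag == t1], ]), 11)

  # a merged cluster with five alleles is discarded as a presumed repeat
  vars <- vapply(1:5, function(k) {
    tt <- tag96("G"); substr(tt, 10 + k, 10 + k) <- "A"; tt
  }, character(1))
  rep5 <- data.frame(individual_id = rep(c("I1", "I2"), each = 5),
                     tag = rep(vars, 2), depth = 2)
  res5 <- merge_across_individuals(rep5)
  expect_equal(res5$dropped[["excess_alleles"]], 1L)
  expect_equal(nrow(res5$alleles), 0L)
})

test_that("expected locus count follows the independent-base model", {
  expect_equal(expected_locus_count(6.6e9, 0.37),
               6.6e9 * (0.37 / 2)^6 * (0.63 / 2)^2 * 2)
  expect_equal(expected_locus_count(6.6e9, 0.5), 6.6e9 * 0.25^8 * 2)
  expect_equal(expected_locus_count(6.6e9, 0.37, tags_per_site = 0), 0)
  expect_error(expected_locus_count(1e9, 0.37, motif = ""), "non-empty")

  # monotone in genome size; increasing in GC on (0, 0.75) for SbfI
  sizes <- c(1e8, 1e9, 1e10)
  expect_true(all(diff(vapply(sizes, expected_locus_count,
                              0, gc_fraction = 0.37)) > 0))
  gcs <- seq(0.05, 0.74, by = 0.05)
  expect_true(all(diff(vapply(gcs, function(g)
    expected_locus_count(6.6e9, g), 0)) > 0))
})

test_that("error-free reads from a toy genome recover two loci per sampled site", {
  set.seed(5)
  g <- toy_genome(n_sites = 4)
  cfg <- sim_config(seed = 5, n_offspring = 4, coverage_lambda = 15)
  sim <- simulate_reads(g, cfg)  # all monomorphic
  res <- build_rad_loci(sim$pairs[, c("read1", "qual1", "read2", "qual2")],
                        sim$barcodes)
  expect_equal(res$log$n_loci, 8L)   # 2 tags per site, all sampled deeply
  expect_equal(nrow(res$loci$alleles), 8L)
  # every recovered allele sequence occurs in the genome (error rate 0)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(res$loci$alleles$tag)))
  found <- vapply(seq_along(rc), function(i)
    grepl(res$loci$alleles$tag[i], g$sequence, fixed = TRUE) ||
      grepl(rc[i], g$sequence, fixed = TRUE), logical(1))
  expect_true(all(found))
})
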