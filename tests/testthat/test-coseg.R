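panel <- rad_panel()

test_that("expected patterns reproduce the canonical example rows", {
  expect_equal(paste(expected_pattern("banding", "in_phase", panel),
                     collapse = ""), "100000000000001111111111")
  expect_equal(paste(expected_pattern("colour", "in_phase", panel),
                     collapse = ""), "101111111111110000000000")
  expect_equal(paste(expected_pattern("banding", "shared", panel),
                     collapse = ""), strrep("1", 24))
  # the two in-phase expectations differ at all 22 offspring positions,
  # far beyond any combined dropout + recombinant allowance
  d <- sum(expected_pattern("banding", "in_phase", panel) !=
             expected_pattern("colour", "in_phase", panel))
  expect_equal(d, 22L)
})

test_that("pattern scoring counts dropouts and gains as in the marker table", {
  e_band <- expected_pattern("banding", "in_phase", panel)
  e_col <- expected_pattern("colour", "in_phase", panel)
  expect_equal(score_pattern("100000000000001111111111", e_band),
               c(dropouts = 0L, gains = 0L))
  expect_equal(score_pattern("101011111111110000000000", e_col),
               c(dropouts = 1L, gains = 0L))
  expect_equal(score_pattern("100100000000001111111011", e_band),
               c(dropouts = 1L, gains = 1L))
  # 'x' (PCR-confirmed presence) still counts as a dropout during search
  expect_equal(score_pattern("x00000000000001111111111", e_band),
               c(dropouts = 1L, gains = 0L))
  expect_error(score_pattern("101", e_band), "length")
})

test_that("dropouts plus gains equal the Hamming distance to the expectation", {
  set.seed(99)
  e <- expected_pattern("banding", "in_phase", panel)
  for (i in 1:50) {
    obs <- rbinom(24, 1, 0.5)
    s <- score_pattern(obs, e)
    expect_equal(unname(sum(s)), sum(obs != e))
  }
  expect_equal(unname(score_pattern(paste(e, collapse = ""), e)),
               c(0L, 0L))
})

test_that("the eleven assayed markers are all accepted with the correct phases", {
  t3 <- marker_patterns()
  cand <- find_candidates(t3[, c("locus_id", "allele_id", "pattern")], panel)
  expect_equal(nrow(cand), 11L)
  expect_true(all(cand$accepted))
  banding <- paste0("Cne_RAD", c("01", "02", "03", "04", "08", "09", "10"))
  colour <- paste0("Cne_RAD", c("05", "06", "07", "11"))
  expect_setequal(cand$locus_id[cand$phase == "banding"], banding)
  expect_setequal(cand$locus_id[cand$phase == "colour"], colour)
  expect_true(all(cand$dropouts <= 2 & cand$gains <= 2))
})

test_that("alleles exceeding the recombinant allowance are rejected", {
  e <- expected_pattern("banding", "in_phase", panel)
  flip <- which(e == 0)[1:3]
  obs <- e; obs[flip] <- 1L  # 3 gains against banding; far from colour
  pat <- data.frame(locus_id = "L1", allele_id = c("L1_a1", "L1_a2"),
                    pattern = c(paste(obs, collapse = ""), strrep("1", 24)))
  expect_false(find_candidates(pat, panel)$accepted)
})

test_that("a mother-only alternative allele blocks acceptance", {
  set.seed(123)
  inph <- paste(expected_pattern("banding", "in_phase", panel), collapse = "")
  alt <- paste(c(0, 1, rbinom(22, 1, 0.5)), collapse = "")
  pat <- data.frame(locus_id = "L1", allele_id = c("a1", "a2"),
                    pattern = c(inph, alt))
  expect_false(find_candidates(pat, panel)$accepted)
})

test_that("candidate search is monotone in the allowances", {
  set.seed(7)
  pats <- do.call(rbind, lapply(1:60, function(i) {
    data.frame(locus_id = sprintf("L%02d", i),
               allele_id = sprintf("L%02d_a%d", i, 1:2),
               pattern = c(paste(rbinom(24, 1, 0.5), collapse = ""),
                           strrep("1", 24)))
  }))
  base <- find_candidates(pats, panel, coseg_thresholds())
  wide <- find_candidates(pats, panel, coseg_thresholds(
    max_inphase_dropouts = 4, max_putative_recombinants = 4,
    max_alt_dropouts_all = 8, max_alt_dropouts_small = 4))
  expect_true(all(wide$accepted[base$accepted]))
  # no pattern is simultaneously in phase with colour and banding
  expect_false(any(base$accepted &
                     is.na(base$phase)))
})

test_that("split loci are rescued by identity-based regrouping", {
  t1 <- paste0("TGCAGG", strrep("ACGT", 90 / 4))
  # 6 substitutions: beyond the clustering distance, same locus in truth
  t2 <- t1
  for (p in c(10, 22, 34, 46, 58, 70)) substr(t2, p, p) <- "C"
  # unrelated allele at ~55% identity
  t3 <- paste0("TGCAGG", strrep("GGATCCTAA", 10))
  inph <- paste(expected_pattern("banding", "in_phase", panel), collapse = "")
  comp <- paste(expected_pattern("banding", "complement", panel),
                collapse = "")
  pats <- data.frame(
    locus_id = c("L1", "L2", "L3"),
    allele_id = c("a1", "a2", "a3"),
    pattern = c(inph, comp, strrep("1", 24)))
  seqs <- data.frame(allele_id = c("a1", "a2", "a3"), tag = c(t1, t2, t3))
  res <- rescue_split_loci(pats, seqs, panel)
  expect_gte(nrow(res$merged), 1L)
  expect_setequal(c(res$merged$allele_a, res$merged$allele_b), c("a1", "a2"))
  expect_true(all(res$merged$identity >= 0.90))
  regrouped <- res$candidates
  merged_locus <- res$patterns$locus_id[res$patterns$allele_id == "a1"]
  expect_true(regrouped$accepted[regrouped$locus_id == merged_locus])
  expect_equal(regrouped$n_alleles[regrouped$locus_id == merged_locus], 2L)
})

test_that("an allele pair separated by a short indel is regrouped", {
  t1 <- paste0("TGCAGG", strrep("ACGT", 90 / 4))
  t4 <- paste0(substr(t1, 1, 40), substr(t1, 44, 96))  # 3-base deletion
  inph <- paste(expected_pattern("banding", "in_phase", panel), collapse = "")
  pats <- data.frame(locus_id = c("L1", "L2"), allele_id = c("a1", "a4"),
                     pattern = c(inph, strrep("1", 24)))
  seqs <- data.frame(allele_id = c("a1", "a4"), tag = c(t1, t4))
  res <- rescue_split_loci(pats, seqs, panel)
  expect_gte(nrow(res$merged), 1L)
  expect_true(all(res$merged$identity >= 0.90))
  expect_equal(length(unique(res$patterns$locus_id)), 1L)
})

test_that("alleles below the identity threshold are not regrouped", {
  t1 <- paste0("TGCAGG", strrep("ACGT", 90 / 4))
  t2 <- t1
  idx <- seq(7, 96, by = 6)  # ~16% of positions differ -> ~84% identity
  for (p in idx) substr(t2, p, p) <- c(A = "C", C = "G", G = "T",
                                       T = "A")[substr(t1, p, p)]
  inph <- paste(expected_pattern("colour", "in_phase", panel), collapse = "")
  pats <- data.frame(locus_id = c("L1", "L2"), allele_id = c("a1", "a2"),
                     pattern = c(inph, strrep("1", 24)))
  seqs <- data.frame(allele_id = c("a1", "a2"), tag = c(t1, t2))
  res <- rescue_split_loci(pats, seqs, panel)
  expect_equal(nrow(res$merged), 0L)
})

test_that("orientation calls follow shared recombinant individuals", {
  e <- expected_pattern("banding", "in_phase", panel)
  rec_ind <- "YU03"  # flag one yellow-unbanded offspring as recombinant
  ref_pat <- e; ref_pat[panel$individual_id == rec_ind] <- 0L
  recombinants <- data.frame(marker = "REF", individual_id = rec_ind)

  same <- paste(ref_pat, collapse = "")
  other <- e; other[panel$individual_id == "YU05"] <- 0L
  clean <- paste(e, collapse = "")
  cands <- data.frame(
    locus_id = c("same", "opp", "none"),
    phase = "banding",
    pattern = c(same, paste(other, collapse = ""), clean))
  oc <- infer_orientation(cands, recombinants, panel)
  expect_equal(oc$side, c("same_as", "opposite_to", "undetermined"))

  # no recombinant individuals at all -> everything undetermined
  oc2 <- infer_orientation(cands,
                           data.frame(marker = character(0),
                                      individual_id = character(0)), panel)
  expect_true(all(oc2$side == "undetermined"))
})
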