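## Cosegregation search: match RAD allele presence/absence patterns against
## the expectations of a repulsion-phase pseudo-testcross, with explicit
## allowances for allelic dropout and putative recombinants.

#' Define the individual panel for pattern serialization
#'
#' Patterns are ordered binary vectors over a fixed panel: father, mother,
#' then offspring grouped by phenotype class (pink-banded before
#' yellow-unbanded in the canonical repulsion-cross panel). The default is
#' the 24-individual RAD panel of the mapping cross: 2 parents, 12
#' pink-banded and 10 yellow-unbanded offspring.
#'
#' @param n_pink_banded,n_yellow_unbanded offspring counts per class.
#' @param offspring optional data.frame with columns `individual_id` and
#'   `phenotype_class` overriding the two counts (offspring are ordered by
#'   canonical class, preserving input order within class).
#' @return data.frame of class `rad_panel` with columns `individual_id`,
#'   `role` (`father`/`mother`/`offspring`) and `phenotype_class`.
#' @examples
#' p <- rad_panel()
#' nrow(p)  # 24
#' @export
rad_panel <- function(n_pink_banded = 12L, n_yellow_unbanded = 10L,
                      offspring = NULL) {
  if (is.null(offspring)) {
    offspring <- data.frame(
      individual_id = c(sprintf("PB%02d", seq_len(n_pink_banded)),
                        sprintf("YU%02d", seq_len(n_yellow_unbanded))),
      phenotype_class = c(rep("pink-banded", n_pink_banded),
                          rep("yellow-unbanded", n_yellow_unbanded)),
      stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("individual_id", "phenotype_class") %in% names(offspring)))
    ord <- order(match(offspring$phenotype_class, PHENOTYPE_CLASSES))
    offspring <- offspring[ord, c("individual_id", "phenotype_class"),
                           drop = FALSE]
  }
  panel <- rbind(
    data.frame(individual_id = c("father", "mother"),
               phenotype_class = c("pink-unbanded", "yellow-banded"),
               stringsAsFactors = FALSE),
    offspring)
  panel$role <- c("father", "mother", rep("offspring", nrow(offspring)))
  panel <- panel[, c("individual_id", "role", "phenotype_class")]
  rownames(panel) <- NULL
  class(panel) <- c("rad_panel", "data.frame")
  panel
}

.panel_colour <- function(panel)
  grepl("^pink", panel$phenotype_class)
.panel_unbanded <- function(panel)
  grepl("unbanded$", panel$phenotype_class)

#' Expected presence pattern of a RAD allele under linkage
#'
#' In the repulsion-phase mapping cross the doubly heterozygous father
#' carries the dominant colour allele and the dominant banding allele on
#' different haplotypes, so:
#' * an allele in phase with the dominant banding allele (band absence) is
#'   expected in the father and every unbanded offspring;
#' * an allele in phase with the dominant colour allele (pink) is expected
#'   in the father and every pink offspring;
#' * an alternative allele shared by both parents (`"shared"`) is expected
#'   in every individual;
#' * the father-only alternative riding his other haplotype
#'   (`"complement"`) is expected in the father and the offspring class not
#'   carrying the in-phase allele.
#'
#' @param phase `"banding"` or `"colour"`.
#' @param role `"in_phase"`, `"shared"` or `"complement"`.
#' @param panel a [rad_panel()].
#' @return named integer 0/1 vector over the panel.
#' @examples
#' paste(expected_pattern("banding", "in_phase", rad_panel()), collapse = "")
#' @export
expected_pattern <- function(phase = c("banding", "colour"),
                             role = c("in_phase", "shared", "complement"),
                             panel = rad_panel()) {
  phase <- match.arg(phase)
  role <- match.arg(role)
  is_father <- panel$role == "father"
  is_off <- panel$role == "offspring"
  carrier <- if (phase == "banding") .panel_unbanded(panel)
             else .panel_colour(panel)
  pat <- switch(role,
    in_phase = as.integer(is_father | (is_off & carrier)),
    shared = rep(1L, nrow(panel)),
    complement = as.integer(is_father | (is_off & !carrier)))
  setNames(pat, panel$individual_id)
}

#' Parse a pattern string
#'
#' Pattern strings use `1` (allele observed), `0` (absent) and `x` (absent
#' from the sequence data but later confirmed present by PCR; scored as a
#' dropout during the search).
#'
#' @param x a pattern string, e.g. `"100000000000001111111111"`.
#' @return list with `presence` (integer 0/1) and `mask` (logical, `TRUE`
#'   at `x` positions).
#' @export
parse_pattern <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(ch), c("0", "1", "x"))
  if (length(bad))
    stop("pattern contains characters outside {0,1,x}: ",
         paste(bad, collapse = ", "))
  list(presence = as.integer(ch == "1"), mask = ch == "x")
}

#' Score an observed pattern against an expectation
#'
#' Dropouts are positions expected present but observed absent (`x`
#' positions count as dropouts: the allele was sequence-absent at search
#' time); gains — putative recombinants — are positions expected absent but
#' observed present.
#'
#' @param observed a pattern string, a 0/1 vector, or the result of
#'   [parse_pattern()].
#' @param expected a 0/1 vector (see [expected_pattern()]).
#' @return named integer vector `c(dropouts =, gains =)`.
#' @export
score_pattern <- function(observed, expected) {
  if (is.character(observed) && length(observed) == 1L)
    observed <- parse_pattern(observed)
  obs <- if (is.list(observed)) observed$presence else as.integer(observed)
  if (length(obs) != length(expected))
    stop("observed pattern has length ", length(obs),
         " but expected has length ", length(expected))
  c(dropouts = sum(expected == 1L & obs == 0L),
    gains = sum(expected == 0L & obs == 1L))
}

#' Search thresholds for candidate-linked loci
#'
#' The defaults are the search allowances used throughout: at most 2
#' dropouts and 2 putative recombinants for the in-phase allele; for
#' alternative alleles at most 5 dropouts when the allele is expected in all
#' 24 individuals and at most 2 when it is expected in 14 or fewer.
#'
#' @param max_inphase_dropouts,max_putative_recombinants in-phase allowances.
#' @param max_alt_dropouts_all,max_alt_dropouts_small,small_expected_cutoff
#'   alternative-allele allowances.
#' @return named list of class `coseg_thresholds`.
#' @export
coseg_thresholds <- function(max_inphase_dropouts = 2L,
                             max_putative_recombinants = 2L,
                             max_alt_dropouts_all = 5L,
                             max_alt_dropouts_small = 2L,
                             small_expected_cutoff = 14L) {
  th <- list(max_inphase_dropouts = max_inphase_dropouts,
             max_putative_recombinants = max_putative_recombinants,
             max_alt_dropouts_all = max_alt_dropouts_all,
             max_alt_dropouts_small = max_alt_dropouts_small,
             small_expected_cutoff = small_expected_cutoff)
  stopifnot(all(vapply(th, function(x) x >= 0, logical(1))))
  structure(th, class = "coseg_thresholds")
}

## Parse a pattern table into a presence matrix + mask; rows aligned with
## the input data.frame.
.pattern_matrix <- function(patterns, panel) {
  n <- nrow(panel)
  if (any(nchar(patterns$pattern) != n))
    stop("pattern length must equal panel size (", n, "); offending rows: ",
         paste(head(which(nchar(patterns$pattern) != n)), collapse = ", "))
  ch <- matrix(unlist(strsplit(patterns$pattern, "", fixed = TRUE),
                      use.names = FALSE), ncol = n, byrow = TRUE)
  bad <- !(ch %in% c("0", "1", "x"))
  if (any(bad))
    stop("pattern cells outside {0,1,x} in rows: ",
         paste(unique(head(which(rowSums(matrix(bad, nrow(ch))) > 0))),
               collapse = ", "))
  list(P = matrix(as.integer(ch == "1"), nrow(ch)), mask = ch == "x")
}

#' Find RAD loci cosegregating with the supergene
#'
#' A locus is accepted as a candidate when (a) one of its alleles matches
#' the in-phase expectation for colour or banding within the dropout and
#' putative-recombinant allowances, and (b) every other allele is
#' consistent with an alternative-allele expectation: shared by both
#' parents (expected in all individuals; dropout budget
#' `max_alt_dropouts_all`) or father-only on the complementary haplotype
#' (expected in at most `small_expected_cutoff` individuals; dropout budget
#' `max_alt_dropouts_small`, gains capped at `max_putative_recombinants`).
#'
#' @param patterns data.frame with columns `locus_id`, `allele_id`,
#'   `pattern` (strings over `{0,1,x}` in panel order).
#' @param panel a [rad_panel()].
#' @param thresholds a [coseg_thresholds()].
#' @return data.frame with one row per locus: `locus_id`, `accepted`,
#'   `phase` (`"colour"`, `"banding"` or `NA`), `in_phase_allele`,
#'   `dropouts`, `gains`, `n_alleles`, `alt_ok`.
#' @export
find_candidates <- function(patterns, panel = rad_panel(),
                            thresholds = coseg_thresholds()) {
  stopifnot(all(c("locus_id", "allele_id", "pattern") %in% names(patterns)))
  if (nrow(patterns) == 0L)
    return(data.frame(locus_id = character(0), accepted = logical(0),
                      phase = character(0), in_phase_allele = character(0),
                      dropouts = integer(0), gains = integer(0),
                      n_alleles = integer(0), alt_ok = logical(0)))
  pm <- .pattern_matrix(patterns, panel)
  P <- pm$P
  th <- thresholds

  exps <- list(
    band_in = expected_pattern("banding", "in_phase", panel),
    col_in = expected_pattern("colour", "in_phase", panel),
    shared = expected_pattern("banding", "shared", panel),
    band_comp = expected_pattern("banding", "complement", panel),
    col_comp = expected_pattern("colour", "complement", panel))
  drops <- lapply(exps, function(e) as.vector((1L - P) %*% e))
  gains <- lapply(exps, function(e) as.vector(P %*% (1L - e)))

  match_band <- drops$band_in <= th$max_inphase_dropouts &
    gains$band_in <= th$max_putative_recombinants
  match_col <- drops$col_in <= th$max_inphase_dropouts &
    gains$col_in <= th$max_putative_recombinants

  alt_budget <- function(e_name) {
    n_exp <- sum(exps[[e_name]])
    if (n_exp <= th$small_expected_cutoff) th$max_alt_dropouts_small
    else th$max_alt_dropouts_all
  }
  alt_fit <- function(e_name) {
    drops[[e_name]] <= alt_budget(e_name) &
      gains[[e_name]] <= th$max_putative_recombinants
  }
  ## an alternative allele may be the shared allele or, phase-specifically,
  ## the father-only complement allele
  alt_ok_band <- alt_fit("shared") | alt_fit("band_comp")
  alt_ok_col <- alt_fit("shared") | alt_fit("col_comp")

  loci <- unique(patterns$locus_id)
  g <- match(patterns$locus_id, loci)
  per_locus <- function(match_vec, alt_vec) {
    any_m <- tapply(match_vec, g, any)
    all_ok <- tapply(match_vec | alt_vec, g, all)
    unname(any_m & all_ok)
  }
  acc_band <- per_locus(match_band, alt_ok_band)
  acc_col <- per_locus(match_col, alt_ok_col)

  score_in <- ifelse(match_band, drops$band_in + gains$band_in,
                     ifelse(match_col, drops$col_in + gains$col_in, NA))
  out <- data.frame(locus_id = loci,
                    accepted = acc_band | acc_col,
                    phase = ifelse(acc_band, "banding",
                                   ifelse(acc_col, "colour", NA_character_)),
                    in_phase_allele = NA_character_,
                    dropouts = NA_integer_, gains = NA_integer_,
                    n_alleles = as.integer(table(g)[as.character(seq_along(loci))]),
                    alt_ok = unname(tapply(alt_ok_band | alt_ok_col |
                                             match_band | match_col, g, all)),
                    stringsAsFactors = FALSE)
  for (li in which(out$accepted)) {
    rows <- which(g == li)
    use <- if (!is.na(out$phase[li]) && out$phase[li] == "banding")
      rows[match_band[rows]] else rows[match_col[rows]]
    best <- use[which.min(score_in[use])]
    out$in_phase_allele[li] <- patterns$allele_id[best]
    if (out$phase[li] == "banding") {
      out$dropouts[li] <- drops$band_in[best]
      out$gains[li] <- gains$band_in[best]
    } else {
      out$dropouts[li] <- drops$col_in[best]
      out$gains[li] <- gains$col_in[best]
    }
  }
  out
}

#' Rescue candidate loci split by indels or excess polymorphism
#'
#' Hamming-based clustering cannot join alleles separated by an indel or by
#' more substitutions than the clustering distance, so a truly biallelic
#' locus may surface as two single-allele loci. Accepted single-allele
#' candidates are compared against all other alleles with an ends-free
#' (overlap) pairwise alignment; pairs reaching `min_identity` (matches /
#' alignment columns) over at least `min_overlap` columns are regrouped
#' into one locus, and the regrouped set is re-scored.
#'
#' @param patterns pattern data.frame (see [find_candidates()]).
#' @param sequences data.frame with columns `allele_id`, `tag` giving allele
#'   sequences.
#' @param panel a [rad_panel()].
#' @param thresholds a [coseg_thresholds()].
#' @param min_identity minimum alignment identity (default 0.90).
#' @param min_overlap minimum aligned columns for a significant match
#'   (default 50; guards against trivial short overlaps).
#' @return list with `patterns` (regrouped pattern table), `candidates`
#'   (re-scored [find_candidates()] output) and `merged` (data.frame of
#'   regrouped allele pairs with identities).
#' @export
rescue_split_loci <- function(patterns, sequences, panel = rad_panel(),
                              thresholds = coseg_thresholds(),
                              min_identity = 0.90, min_overlap = 50L) {
  cand <- find_candidates(patterns, panel, thresholds)
  n_alleles <- table(patterns$locus_id)
  singles <- cand$locus_id[cand$accepted &
                             n_alleles[cand$locus_id] == 1L]
  merged <- data.frame(allele_a = character(0), allele_b = character(0),
                       identity = numeric(0))
  patterns$new_locus <- patterns$locus_id
  if (length(singles)) {
    seq_of <- setNames(sequences$tag, sequences$allele_id)
    for (lid in singles) {
      a_id <- patterns$allele_id[patterns$locus_id == lid][1L]
      if (is.na(seq_of[a_id])) next
      others <- setdiff(sequences$allele_id, a_id)
      if (!length(others)) next
      aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAStringSet(unname(seq_of[others])),
        subject = Biostrings::DNAString(seq_of[[a_id]]),
        type = "overlap",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1, baseOnly = TRUE),
        gapOpening = 5, gapExtension = 2)
      ## alignment columns = length of the gapped aligned pattern
      ncols <- nchar(as.character(aln))
      ident <- Biostrings::nmatch(aln) / pmax(ncols, 1L)
      hit <- which(ident >= min_identity & ncols >= min_overlap)
      for (h in hit) {
        b_id <- others[h]
        merged <- rbind(merged, data.frame(allele_a = a_id, allele_b = b_id,
                                           identity = ident[h]))
        b_locus <- patterns$new_locus[patterns$allele_id == b_id]
        patterns$new_locus[patterns$new_locus %in% b_locus] <-
          patterns$new_locus[patterns$allele_id == a_id][1L]
      }
    }
  }
  regrouped <- data.frame(locus_id = patterns$new_locus,
                          allele_id = patterns$allele_id,
                          pattern = patterns$pattern,
                          stringsAsFactors = FALSE)
  list(patterns = regrouped,
       candidates = find_candidates(regrouped, panel, thresholds),
       merged = merged)
}

#' Offspring flagged as putative recombinants by a pattern
#'
#' Offspring where the observed pattern deviates from the in-phase
#' expectation of the stated phase, in either direction (an unexpected
#' presence, or an unexpected absence — the latter is ambiguous with
#' allelic dropout and should be PCR-confirmed before use).
#'
#' @param pattern a pattern string.
#' @param phase `"banding"` or `"colour"`.
#' @param panel a [rad_panel()].
#' @return data.frame with `individual_id` and `kind` (`gain`/`loss`).
#' @export
putative_recombinants <- function(pattern, phase, panel = rad_panel()) {
  obs <- parse_pattern(pattern)$presence
  e <- expected_pattern(phase, "in_phase", panel)
  is_off <- panel$role == "offspring"
  gain <- is_off & e == 0L & obs == 1L
  loss <- is_off & e == 1L & obs == 0L
  data.frame(individual_id = panel$individual_id[gain | loss],
             kind = c("gain", "loss")[1L + loss[gain | loss]],
             stringsAsFactors = FALSE)
}

#' Orient unassayed candidates relative to the supergene
#'
#' A candidate whose pattern switches (relative to its in-phase
#' expectation) in the same recombinant offspring as a mapped reference
#' marker lies on the same side of the supergene; a candidate that is
#' parental in the reference's recombinant offspring but switches in other
#' offspring lies on the opposite side; a candidate with no informative
#' switch is undetermined.
#'
#' @param candidates data.frame with columns `locus_id`, `phase`, `pattern`.
#' @param recombinants data.frame with columns `marker`, `individual_id`
#'   listing validated recombinant offspring of the mapped reference
#'   markers (e.g. from [putative_recombinants()] after PCR confirmation).
#' @param panel a [rad_panel()].
#' @return data.frame with `locus_id`, `side` (`"same_as"`,
#'   `"opposite_to"`, `"undetermined"`) and `informative_individuals`.
#' @export
infer_orientation <- function(candidates, recombinants,
                              panel = rad_panel()) {
  ref_inds <- unique(recombinants$individual_id)
  if (!length(ref_inds)) {
    return(data.frame(locus_id = candidates$locus_id, side = "undetermined",
                      informative_individuals = "", stringsAsFactors = FALSE))
  }
  res <- lapply(seq_len(nrow(candidates)), function(i) {
    pr <- putative_recombinants(candidates$pattern[i], candidates$phase[i],
                                panel)
    sw <- pr$individual_id
    side <- if (!length(sw)) "undetermined"
            else if (any(sw %in% ref_inds)) "same_as"
            else "opposite_to"
    data.frame(locus_id = candidates$locus_id[i], side = side,
               informative_individuals = paste(sw, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
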