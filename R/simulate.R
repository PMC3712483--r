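## Synthetic-data generators: crosses with a non-recombining two-locus
## supergene in known phase, RAD markers at known map positions, Poisson
## fragment coverage and depth-driven allelic dropout. All generators draw
## from one seeded RNG stream and attach full ground truth.

#' Simulation configuration
#'
#' Bundles the study-design parameters used by every generator. Defaults
#' emulate the mapping cross: a repulsion-phase doubly heterozygous father
#' crossed to a double homozygous recessive mother, the 13-locus marker map
#' of [default_marker_map()], mean fragment coverage 6.6 per allele per
#' individual, a 66.7% PCR duplicate rate, and presence called at depth 2.
#'
#' @param seed integer seed; every generator reseeds from it, so equal
#'   configs give byte-identical output.
#' @param n_offspring offspring count (22 for the RAD panel).
#' @param markers data.frame with `marker`, `position_cM`, `phase`
#'   (`"colour"`, `"banding"`, `"supergene"` or `"unlinked"`).
#' @param cross an `sg_cross` (default: the repulsion mapping cross).
#' @param coverage_lambda mean fragment depth per allele per individual.
#' @param pcr_duplicate_rate expected proportion of reads that are PCR
#'   duplicates.
#' @param min_depth_for_presence fragment depth at which an allele is
#'   called present.
#' @param error_rate per-base sequencing error rate for read simulation.
#' @param shear_range fragment length range (uniform shear), in bases.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_offspring = 22L,
                       markers = default_marker_map(),
                       cross = study_cross(1),
                       coverage_lambda = 6.6,
                       pcr_duplicate_rate = 0.667,
                       min_depth_for_presence = 2L,
                       error_rate = 0,
                       shear_range = c(300L, 600L)) {
  stopifnot(n_offspring >= 1L,
            all(c("marker", "position_cM", "phase") %in% names(markers)),
            coverage_lambda > 0,
            pcr_duplicate_rate >= 0, pcr_duplicate_rate < 1,
            inherits(cross, "sg_cross"))
  bad <- setdiff(markers$phase, c("colour", "banding", "supergene",
                                  "unlinked"))
  if (length(bad)) stop("unknown marker phase(s): ", paste(bad, collapse = ", "))
  if (any(markers$position_cM < 0 & markers$phase != "unlinked"))
    stop("map positions must be non-negative")
  structure(list(seed = seed, n_offspring = n_offspring, markers = markers,
                 cross = cross, coverage_lambda = coverage_lambda,
                 pcr_duplicate_rate = pcr_duplicate_rate,
                 min_depth_for_presence = min_depth_for_presence,
                 error_rate = error_rate, shear_range = shear_range),
            class = "sim_config")
}

## Which father haplotype (1 or 2) carries the dominant allele anchoring a
## marker phase. Requires a doubly heterozygous informative parent.
.carrier_haplotype <- function(cross, phase) {
  parent <- informative_parent(cross)
  if (is.null(parent))
    stop("cross '", cross$label, "' has no doubly heterozygous parent; ",
         "linked markers cannot be simulated")
  d <- cross[[parent]]
  a1 <- parse_haplotype(d$h1); a2 <- parse_haplotype(d$h2)
  if (phase == "colour") {
    if (a1[["colour"]] == "CP") 1L else 2L
  } else {  # banding
    if (a1[["band"]] == "BO") 1L else 2L
  }
}

## Simulate paternal gametes along the marker map: returns a matrix
## (offspring x positions) of haplotype indices (1/2), with at most one
## crossover per adjacent interval (recombination probability from the
## Kosambi inverse of the interval length).
.sim_gametes <- function(positions, n) {
  ord <- order(positions)
  pos <- positions[ord]
  state <- matrix(0L, n, length(pos))
  state[, 1L] <- sample(1:2, n, replace = TRUE)
  if (length(pos) > 1L) {
    for (k in 2:length(pos)) {
      r <- kosambi_r(pos[k] - pos[k - 1L])
      flip <- runif(n) < r
      state[, k] <- ifelse(flip, 3L - state[, k - 1L], state[, k - 1L])
    }
  }
  state[, order(ord), drop = FALSE]  # back to input order
}

#' Simulate a cross: offspring phenotypes and marker ground truth
#'
#' Each offspring receives one gamete per parent. Crossovers on the
#' informative parent's chromosome are placed per adjacent map interval
#' with probability given by the Kosambi inverse of the interval length (at
#' most one per interval). The supergene is a single non-recombining point
#' carrying both the colour and banding loci. Linked markers ride the
#' informative parent's haplotypes according to their phase; unlinked
#' markers segregate independently.
#'
#' @param config a [sim_config()].
#' @return list with `offspring` (data.frame: `individual_id`,
#'   `phenotype_class`, `supergene_haplotype`), `truth` (list:
#'   `inherit` — offspring x markers logical matrix, TRUE where the
#'   offspring received the in-phase allele; `recombinant` — same shape,
#'   TRUE where that differs from the supergene transmission) and `config`.
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  .sim_cross_impl(config)
}

.sim_cross_impl <- function(config) {
  mk <- config$markers
  cross <- config$cross
  n <- config$n_offspring
  parent <- informative_parent(cross)
  if (is.null(parent) && any(mk$phase %in% c("colour", "banding", "supergene")))
    stop("cross '", cross$label, "' has no doubly heterozygous parent; ",
         "linked markers cannot be simulated")
  sg_pos <- unique(mk$position_cM[mk$phase == "supergene"])
  if (length(sg_pos) > 1L)
    stop("supergene loci must share one map position (non-recombining)")
  if (!length(sg_pos)) sg_pos <- 0
  linked <- mk$phase %in% c("colour", "banding", "supergene")
  positions <- c(sg_pos, mk$position_cM[linked])
  state <- .sim_gametes(positions, n)
  sg_state <- state[, 1L, drop = TRUE]
  mk_state <- state[, -1L, drop = FALSE]

  ## without a doubly heterozygous parent there is no linked-marker
  ## information, but phenotypes still segregate: one gamete per parent
  sim_parent <- parent %||% "father"
  inf <- cross[[sim_parent]]
  other <- cross[[setdiff(c("father", "mother"), sim_parent)]]
  inf_haps <- c(inf$h1, inf$h2)
  other_gam <- sample(c(other$h1, other$h2), n, replace = TRUE)
  pheno <- vapply(seq_len(n), function(i)
    phenotype_class(diplotype(inf_haps[sg_state[i]], other_gam[i])),
    character(1))

  inherit <- matrix(NA, n, nrow(mk),
                    dimnames = list(sprintf("O%03d", seq_len(n)), mk$marker))
  li <- 0L
  col_h <- if (!is.null(parent)) .carrier_haplotype(cross, "colour") else NA
  band_h <- if (!is.null(parent)) .carrier_haplotype(cross, "banding") else NA
  for (j in seq_len(nrow(mk))) {
    ph <- mk$phase[j]
    if (ph == "unlinked") {
      inherit[, j] <- sample(c(TRUE, FALSE), n, replace = TRUE)
    } else {
      li <- li + 1L
      carrier <- switch(ph, colour = col_h, banding = band_h,
                        supergene = NA)
      if (ph == "supergene") {
        ## supergene rows track the dominant colour allele for C and the
        ## dominant banding allele for B, by marker name when available
        carrier <- if (identical(mk$marker[j], "B")) band_h else col_h
      }
      inherit[, j] <- mk_state[, li] == carrier
    }
  }
  sg_col <- sg_state == col_h  # offspring received dominant colour allele
  recomb <- matrix(NA, n, nrow(mk), dimnames = dimnames(inherit))
  for (j in seq_len(nrow(mk))) {
    recomb[, j] <- switch(mk$phase[j],
      colour = inherit[, j] != sg_col,
      banding = inherit[, j] != (sg_state == band_h),
      supergene = FALSE,
      unlinked = NA)
  }

  offspring <- data.frame(individual_id = rownames(inherit),
                          phenotype_class = pheno,
                          supergene_haplotype = sg_state,
                          stringsAsFactors = FALSE)
  list(offspring = offspring,
       truth = list(inherit = inherit, recombinant = recomb),
       config = config)
}

#' Simulate an allele presence/absence matrix with dropout
#'
#' Builds the panel (father, mother, offspring grouped by phenotype class),
#' then for every marker emits a biallelic locus: the in-phase allele
#' (present in the informative parent and the offspring that inherited it)
#' and a shared alternative allele (present in everyone). Observed presence
#' applies depth-driven dropout: each truly present allele draws a Poisson
#' fragment depth with mean `coverage_lambda` and is observed only at depth
#' `min_depth_for_presence` or more. Unlinked markers segregate
#' independently from the informative parent.
#'
#' @param config a [sim_config()].
#' @return list with `patterns` (data.frame: `locus_id`, `allele_id`,
#'   `pattern`), `panel`, `truth` (from [simulate_cross()], plus
#'   `true_presence` and `phase` per locus) and `config`.
#' @export
simulate_presence_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sim <- .sim_cross_impl(config)
  .sim_presence_impl(config, sim)
}

.sim_presence_impl <- function(config, sim) {
  mk <- config$markers
  mk <- mk[mk$phase != "supergene", , drop = FALSE]
  inherit <- sim$truth$inherit[, mk$marker, drop = FALSE]
  ord <- order(match(sim$offspring$phenotype_class, PHENOTYPE_CLASSES))
  panel <- rad_panel(offspring = data.frame(
    individual_id = sim$offspring$individual_id[ord],
    phenotype_class = sim$offspring$phenotype_class[ord],
    stringsAsFactors = FALSE))
  is_off <- panel$role == "offspring"
  off_idx <- match(panel$individual_id[is_off], rownames(inherit))

  observe <- function(true_presence) {
    depth <- rpois(length(true_presence), config$coverage_lambda)
    as.integer(true_presence & depth >= config$min_depth_for_presence)
  }
  rows <- lapply(seq_len(nrow(mk)), function(j) {
    tp_in <- integer(nrow(panel))
    tp_in[panel$role == "father"] <- 1L  # informative parent by convention
    tp_in[is_off] <- as.integer(inherit[off_idx, j])
    tp_alt <- rep(1L, nrow(panel))
    data.frame(
      locus_id = mk$marker[j],
      allele_id = paste0(mk$marker[j], c("_in", "_alt")),
      pattern = c(paste(observe(tp_in), collapse = ""),
                  paste(observe(tp_alt), collapse = "")),
      true_pattern = c(paste(tp_in, collapse = ""),
                       paste(tp_alt, collapse = "")),
      phase = mk$phase[j],
      stringsAsFactors = FALSE)
  })
  patterns <- do.call(rbind, rows)
  list(patterns = patterns[, c("locus_id", "allele_id", "pattern")],
       panel = panel,
       truth = c(sim$truth,
                 list(true_patterns = patterns[, c("locus_id", "allele_id",
                                                   "true_pattern", "phase")],
                      offspring = sim$offspring)),
       config = config)
}

#' Simulate phase-known backcross genotypes for mapping
#'
#' Genotype calls are 1 where the offspring carries the marker's in-phase
#' allele and 0 otherwise (for the supergene loci, 1 where the offspring
#' received the dominant allele); optional missingness is applied at
#' random.
#'
#' @param config a [sim_config()].
#' @param missing_rate probability a call is missing (default 0).
#' @return list with `geno` (markers x offspring 0/1/NA matrix), `truth`
#'   and `config`.
#' @export
simulate_genotypes <- function(config, missing_rate = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sim <- .sim_cross_impl(config)
  geno <- t(sim$truth$inherit) * 1
  if (missing_rate > 0)
    geno[runif(length(geno)) < missing_rate] <- NA
  mk <- config$markers
  anchor <- ifelse(mk$phase == "banding" |
                     (mk$phase == "supergene" & mk$marker == "B"),
                   "BO", "CP")
  anchor[mk$phase == "unlinked"] <- NA
  list(geno = geno, truth = sim$truth,
       anchor = setNames(anchor, mk$marker), config = config)
}

#' Orient dominant-marker genotypes into a common phase
#'
#' A dominant marker is scored as presence of its own in-phase allele, so
#' markers anchored to opposite haplotypes of the informative parent (the
#' colour side versus the banding side, which are in repulsion) yield
#' complementary call vectors even at complete linkage. Before two-point
#' mapping, all markers are flipped into a single orientation using their
#' known phase anchor (from the cosegregation search).
#'
#' @param geno markers x offspring 0/1/NA matrix.
#' @param anchor character vector (named by marker or in row order):
#'   `"CP"` (call 1 = inherited the dominant-colour haplotype) or `"BO"`
#'   (call 1 = inherited the dominant-banding haplotype); `NA` rows are
#'   left as-is.
#' @return matrix with `"BO"`-anchored rows complemented, so every call 1
#'   means "inherited the dominant-colour haplotype".
#' @export
orient_genotypes <- function(geno, anchor) {
  if (!is.null(names(anchor))) anchor <- anchor[rownames(geno)]
  stopifnot(length(anchor) == nrow(geno))
  flip <- !is.na(anchor) & anchor == "BO"
  geno[flip, ] <- 1 - geno[flip, , drop = FALSE]
  geno
}
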