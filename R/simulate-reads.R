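## Read-level library simulation: in-silico SbfI digestion of a toy genome,
## random shearing, Poisson fragment coverage, PCR duplication and inline
## barcodes. Produces paired reads that feed the read-to-locus pipeline.

#' Generate a barcode set
#'
#' Deterministically enumerates 5-base barcodes with pairwise distance at
#' least 2 (positions 1-4 free, fifth base a sum-check over the first
#' four), assigning them to individual ids.
#'
#' @param individual_ids character vector of ids.
#' @return named barcode vector (validated by [barcode_set()]).
#' @export
make_barcodes <- function(individual_ids) {
  n <- length(individual_ids)
  if (n > 256L) stop("barcode enumeration supports up to 256 individuals")
  bases <- c("A", "C", "G", "T")
  codes <- vapply(seq_len(n) - 1L, function(i) {
    d <- c(i %/% 64L %% 4L, i %/% 16L %% 4L, i %/% 4L %% 4L, i %% 4L)
    ## parity check digit: any single substitution in the first four bases
    ## changes it, so pairwise distance is at least 2
    paste(bases[c(d, sum(d) %% 4L) + 1L], collapse = "")
  }, character(1))
  barcode_set(setNames(codes, individual_ids))
}

#' Build a toy genome containing restriction sites
#'
#' Random sequence with `n_sites` copies of the SbfI motif planted at
#' regular spacings; accidental motif occurrences are removed so the
#' digestion pattern is exactly as planted. Uses the current RNG stream.
#'
#' @param n_sites number of restriction sites.
#' @param spacing bases between consecutive sites (default 1500; must
#'   exceed twice the maximum shear length).
#' @param gc_fraction base composition (default 0.37).
#' @return list with `sequence` (character) and `site_positions` (start of
#'   each motif, 1-based).
#' @export
toy_genome <- function(n_sites = 10L, spacing = 1500L, gc_fraction = 0.37) {
  motif <- SBFI_MOTIF
  len <- spacing * (n_sites + 1L)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqv <- sample(names(p), len, replace = TRUE, prob = p)
  genome <- paste(seqv, collapse = "")
  ## scrub accidental motif occurrences (both strands; motif is its own
  ## reverse complement for SbfI)
  repeat {
    hit <- regexpr(motif, genome, fixed = TRUE)
    if (hit < 0) break
    substr(genome, hit, hit) <- "A"  # motif starts with C; breaks the site
  }
  sites <- integer(n_sites)
  for (s in seq_len(n_sites)) {
    pos <- s * spacing
    substr(genome, pos, pos + nchar(motif) - 1L) <- motif
    sites[s] <- pos
  }
  list(sequence = genome, site_positions = sites)
}

## Tag sequences flanking a restriction site. The SbfI cut leaves a TGCAGG
## remnant at the 5' end of each fragment; tags are the 96 bases read
## inward from each cut.
.site_tags <- function(genome, pos, tag_len = 96L) {
  down <- substr(genome, pos + 2L, pos + 1L + tag_len)
  up <- revcomp(substr(genome, pos + 6L - tag_len, pos + 5L))
  c(up = up, down = down)
}

## Inject k substitutions into the variable part of a tag (after the
## remnant), at fixed offsets so variant alleles are deterministic.
.variant_tag <- function(tag, k = 2L) {
  offs <- nchar(SBFI_REMNANT) + c(14L, 40L, 66L, 21L, 53L)[seq_len(k)]
  for (o in offs) {
    base <- substr(tag, o, o)
    substr(tag, o, o) <- c(A = "C", C = "G", G = "T", T = "A", N = "A")[base]
  }
  tag
}

.mutate_reads <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hits <- which(runif(n) < rate)
    for (h in hits) {
      cur <- substr(s, h, h)
      substr(s, h, h) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a barcoded paired-end RAD library from a toy genome
#'
#' Digests the genome at SbfI sites; every site yields two tag loci (one
#' per flank). Site classes define the segregation of a variant downstream
#' tag allele: `"monomorphic"` (reference allele in everyone),
#' `"colour"`/`"banding"` (variant rides the informative parent's
#' dominant-allele haplotype and follows the simulated gametes),
#' `"father_het"`/`"mother_het"` (variant in one parent, transmitted to a
#' random half of offspring). Per individual and allele, fragment depth is
#' Poisson(`coverage_lambda`); each fragment gets a uniform shear length
#' (which determines its second read) and `1 + Geometric` PCR copies tuned
#' so the expected duplicate proportion equals `pcr_duplicate_rate`.
#'
#' @param genome a [toy_genome()] (or list with `sequence`,
#'   `site_positions`).
#' @param config a [sim_config()]; linked site classes use its cross and
#'   marker map positions.
#' @param site_classes character vector, one per site (recycled defaults:
#'   all `"monomorphic"`).
#' @param site_positions_cM map positions for linked sites (matched to
#'   linked `site_classes` in order; defaults to the supergene position,
#'   i.e. complete linkage).
#' @return list with `pairs` (data.frame: `read1`, `qual1`, `read2`,
#'   `qual2`, `individual_id` — the id is ground truth, not used by the
#'   pipeline), `barcodes`, `panel`, `truth` (per-locus data.frame:
#'   `locus_id`, `site`, `side`, `class`, `variant_tag`, `ref_tag`, plus
#'   the cross truth and per-allele true presence matrix), and `config`.
#' @export
simulate_reads <- function(genome, config, site_classes = "monomorphic",
                           site_positions_cM = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sites <- genome$site_positions
  if (!length(sites)) {
    warning("genome contains no restriction sites; empty library")
    return(list(pairs = data.frame(read1 = character(0), qual1 = character(0),
                                   read2 = character(0), qual2 = character(0),
                                   individual_id = character(0)),
                barcodes = character(0), truth = NULL, config = config))
  }
  classes <- rep(site_classes, length.out = length(sites))
  linked_i <- which(classes %in% c("colour", "banding"))
  sg_pos <- unique(config$markers$position_cM[
    config$markers$phase == "supergene"])
  if (!length(sg_pos)) sg_pos <- 0
  pos_cM <- rep(sg_pos[1L], length(linked_i))
  if (!is.null(site_positions_cM))
    pos_cM <- rep(site_positions_cM, length.out = length(linked_i))

  ## simulate the cross once, with one linked pseudo-marker per linked site
  mk <- data.frame(marker = "SG", position_cM = sg_pos[1L],
                   phase = "supergene", stringsAsFactors = FALSE)
  if (length(linked_i))
    mk <- rbind(mk, data.frame(marker = paste0("site", linked_i),
                               position_cM = pos_cM,
                               phase = classes[linked_i],
                               stringsAsFactors = FALSE))
  cfg2 <- config
  cfg2$markers <- mk
  cfg2$seed <- NULL  # stay on the already-seeded stream
  sim <- .sim_cross_impl(cfg2)

  ord <- order(match(sim$offspring$phenotype_class, PHENOTYPE_CLASSES))
  panel <- rad_panel(offspring = data.frame(
    individual_id = sim$offspring$individual_id[ord],
    phenotype_class = sim$offspring$phenotype_class[ord],
    stringsAsFactors = FALSE))
  inds <- panel$individual_id
  n_off <- config$n_offspring
  off_ids <- rownames(sim$truth$inherit)

  ## per-locus allele presence (alleles: ref for every tag; variant for
  ## polymorphic downstream tags)
  truth_rows <- list()
  presence <- list()  # allele key -> named 0/1 over inds
  allele_seq <- list()
  for (si in seq_along(sites)) {
    tags <- .site_tags(genome$sequence, sites[si])
    for (side in c("up", "down")) {
      lid <- sprintf("site%02d_%s", si, side)
      ref <- tags[[side]]
      cls <- if (side == "down") classes[si] else "monomorphic"
      ref_pres <- setNames(rep(1L, length(inds)), inds)
      var_pres <- NULL
      var <- NA_character_
      if (cls != "monomorphic") {
        var <- .variant_tag(ref)
        carried <- switch(cls,
          colour = ,
          banding = {
            inh <- sim$truth$inherit[, paste0("site", si)]
            setNames(as.integer(c(TRUE, FALSE, inh[match(
              setdiff(inds, c("father", "mother")), off_ids)])), inds)
          },
          father_het = setNames(as.integer(c(TRUE, FALSE,
            sample(c(TRUE, FALSE), n_off, TRUE))), inds),
          mother_het = setNames(as.integer(c(FALSE, TRUE,
            sample(c(TRUE, FALSE), n_off, TRUE))), inds))
        var_pres <- carried
        ## ref allele sits on every haplotype that lacks the variant; with
        ## one variant copy in a single parent, every individual keeps at
        ## least one ref copy
        ref_pres <- setNames(rep(1L, length(inds)), inds)
      }
      truth_rows[[lid]] <- data.frame(
        locus_id = lid, site = si, side = side, class = cls,
        ref_tag = ref, variant_tag = var, stringsAsFactors = FALSE)
      presence[[paste0(lid, "_ref")]] <- ref_pres
      allele_seq[[paste0(lid, "_ref")]] <- ref
      if (!is.null(var_pres)) {
        presence[[paste0(lid, "_var")]] <- var_pres
        allele_seq[[paste0(lid, "_var")]] <- var
      }
    }
  }

  barcodes <- make_barcodes(inds)
  shear <- config$shear_range
  qual1 <- strrep("I", 5L + 96L)
  qual2 <- strrep("I", 101L)
  out <- vector("list", length(presence) * length(inds))
  k <- 0L
  glen <- nchar(genome$sequence)
  for (ak in names(presence)) {
    aseq <- allele_seq[[ak]]
    lid <- sub("_(ref|var)$", "", ak)
    tr <- truth_rows[[lid]]
    pos <- sites[tr$site]
    for (ind in inds) {
      if (presence[[ak]][[ind]] == 0L) next
      nfrag <- rpois(1L, config$coverage_lambda)
      if (nfrag == 0L) next
      L <- sample(shear[1L]:shear[2L], nfrag, replace = TRUE)
      if (tr$side == "down") {
        ends <- pmin(pos + 1L + L, glen)
        r2 <- revcomp(substring(genome$sequence, ends - 100L, ends))
      } else {
        starts <- pmax(pos + 6L - L, 1L)
        r2 <- substring(genome$sequence, starts, starts + 100L)
      }
      ncopy <- 1L + rgeom(nfrag, prob = 1 - config$pcr_duplicate_rate)
      rep_i <- rep(seq_len(nfrag), ncopy)
      r1 <- paste0(barcodes[[ind]], aseq)
      k <- k + 1L
      out[[k]] <- data.frame(
        read1 = .mutate_reads(rep(r1, length(rep_i)), config$error_rate),
        qual1 = qual1,
        read2 = .mutate_reads(r2[rep_i], config$error_rate),
        qual2 = qual2,
        individual_id = ind, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, out[seq_len(k)])
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  pres_mat <- do.call(rbind, presence)
  list(pairs = pairs, barcodes = barcodes, panel = panel,
       truth = list(loci = truth, presence = pres_mat,
                    cross = sim$truth, offspring = sim$offspring),
       config = config)
}
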