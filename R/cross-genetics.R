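## Supergene cross genetics: haplotypes, diplotypes, phenotype mapping and
## recombinant counting in pseudo-testcrosses.

#' Canonical phenotype classes
#'
#' The four shell phenotype classes of a colour x banding cross, in the fixed
#' canonical order used throughout the package for count vectors and tables:
#' pink-unbanded, pink-banded, yellow-unbanded, yellow-banded.
#'
#' @export
PHENOTYPE_CLASSES <- c("pink-unbanded", "pink-banded",
                       "yellow-unbanded", "yellow-banded")

.COLOUR_ALLELES <- c("CP", "Cy")  # pink (dominant), yellow (recessive)
.BAND_ALLELES   <- c("BO", "Bb")  # unbanded (dominant), banded (recessive)

#' Construct a two-locus supergene haplotype
#'
#' A haplotype carries one allele at the shell ground colour locus (`CP`,
#' pink, dominant; `Cy`, yellow, recessive) and one at the band presence
#' locus (`BO`, unbanded, dominant; `Bb`, banded, recessive). Haplotypes are
#' represented as `"CP-Bb"`-style strings.
#'
#' @param colour `"CP"` or `"Cy"`.
#' @param band `"BO"` or `"Bb"`.
#' @return a haplotype string, e.g. `"CP-Bb"`.
#' @examples
#' haplotype("CP", "Bb")
#' @export
haplotype <- function(colour, band) {
  colour <- match.arg(colour, .COLOUR_ALLELES)
  band <- match.arg(band, .BAND_ALLELES)
  paste(colour, band, sep = "-")
}

#' @rdname haplotype
#' @param x a haplotype string such as `"CP-Bb"`.
#' @return `parse_haplotype()`: named character vector with elements
#'   `colour` and `band`.
#' @export
parse_haplotype <- function(x) {
  parts <- strsplit(x, "-", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !(parts[1L] %in% .COLOUR_ALLELES) ||
      !(parts[2L] %in% .BAND_ALLELES))
    stop("malformed haplotype token: '", x,
         "' (expected e.g. 'CP-Bb' with colour in {CP,Cy}, band in {BO,Bb})")
  c(colour = parts[1L], band = parts[2L])
}

#' Construct a supergene diplotype
#'
#' A diplotype is an unordered pair of two-locus haplotypes. Phase
#' (coupling/repulsion) is derivable from the pair and never stored
#' separately.
#'
#' @param h1,h2 haplotype strings (see [haplotype()]).
#' @return an object of class `sg_diplotype`.
#' @examples
#' d <- diplotype("CP-Bb", "Cy-BO")
#' phenotype_of(d)
#' phase_of(d)
#' @export
diplotype <- function(h1, h2) {
  parse_haplotype(h1); parse_haplotype(h2)
  structure(list(h1 = h1, h2 = h2), class = "sg_diplotype")
}

#' @export
format.sg_diplotype <- function(x, ...) paste(x$h1, x$h2, sep = " / ")

#' @export
print.sg_diplotype <- function(x, ...) {
  cat("<diplotype>", format(x), "\n")
  invisible(x)
}

#' Shell phenotype implied by a diplotype
#'
#' Shell colour is pink if at least one `CP` allele is present (pink is
#' dominant to yellow) and the shell is unbanded if at least one `BO` allele
#' is present (band absence is dominant to presence).
#'
#' @param d an `sg_diplotype`.
#' @return list with elements `colour` (`"pink"`/`"yellow"`) and `banded`
#'   (logical).
#' @export
phenotype_of <- function(d) {
  stopifnot(inherits(d, "sg_diplotype"))
  a1 <- parse_haplotype(d$h1); a2 <- parse_haplotype(d$h2)
  list(colour = if ("CP" %in% c(a1["colour"], a2["colour"])) "pink" else "yellow",
       banded = !("BO" %in% c(a1["band"], a2["band"])))
}

#' @rdname phenotype_of
#' @return `phenotype_class()`: one of [PHENOTYPE_CLASSES].
#' @export
phenotype_class <- function(d) {
  p <- phenotype_of(d)
  paste0(p$colour, if (p$banded) "-banded" else "-unbanded")
}

#' Phase (coupling/repulsion) of a doubly heterozygous diplotype
#'
#' Repulsion means the dominant alleles (`CP`, `BO`) lie on different
#' haplotypes; coupling means they share a haplotype. Only defined for
#' double heterozygotes; `NA` otherwise.
#'
#' @param d an `sg_diplotype`.
#' @return `"coupling"`, `"repulsion"` or `NA_character_`.
#' @export
phase_of <- function(d) {
  stopifnot(inherits(d, "sg_diplotype"))
  a1 <- parse_haplotype(d$h1); a2 <- parse_haplotype(d$h2)
  if (a1["colour"] == a2["colour"] || a1["band"] == a2["band"])
    return(NA_character_)
  dom1 <- c(a1["colour"] == "CP", a1["band"] == "BO")
  if (all(dom1) || all(!dom1)) "coupling" else "repulsion"
}

#' Gametes of a diplotype, with recombinant flags
#'
#' Enumerates the distinct gamete haplotypes a parent can produce, including
#' those requiring a crossover between the colour and banding loci. A gamete
#' is flagged recombinant only if it cannot be produced without a crossover
#' (i.e. it equals neither parental haplotype).
#'
#' @param d an `sg_diplotype`.
#' @return data.frame with columns `haplotype` and `recombinant`.
#' @export
gametes <- function(d) {
  stopifnot(inherits(d, "sg_diplotype"))
  a1 <- parse_haplotype(d$h1); a2 <- parse_haplotype(d$h2)
  all4 <- c(d$h1, d$h2,
            haplotype(a1[["colour"]], a2[["band"]]),
            haplotype(a2[["colour"]], a1[["band"]]))
  g <- data.frame(haplotype = all4, recombinant = c(FALSE, FALSE, TRUE, TRUE),
                  stringsAsFactors = FALSE)
  ## a crossover product identical to a parental haplotype is not recombinant:
  ## keep the non-recombinant route for duplicated haplotypes
  g <- g[order(g$recombinant), , drop = FALSE]
  g <- g[!duplicated(g$haplotype), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Define a cross between two parents
#'
#' @param father,mother `sg_diplotype` objects (the labels follow the mapping
#'   cross convention where the doubly heterozygous parent is the father; the
#'   genetics is symmetric).
#' @param label free-text identifier.
#' @return object of class `sg_cross`.
#' @examples
#' cr <- cross_design(father = diplotype("CP-Bb", "Cy-BO"),
#'                    mother = diplotype("Cy-Bb", "Cy-Bb"),
#'                    label = "repulsion testcross")
#' infer_offspring_genotypes(cr, "pink-banded")
#' @export
cross_design <- function(father, mother, label = "") {
  stopifnot(inherits(father, "sg_diplotype"), inherits(mother, "sg_diplotype"))
  structure(list(father = father, mother = mother, label = label),
            class = "sg_cross")
}

#' @export
print.sg_cross <- function(x, ...) {
  cat("<cross>", x$label, "\n  father:", format(x$father),
      "\n  mother:", format(x$mother), "\n")
  invisible(x)
}

## The parent (if any) heterozygous at both loci; NULL if none.
informative_parent <- function(cross) {
  for (role in c("father", "mother"))
    if (!is.na(phase_of(cross[[role]]))) return(role)
  NULL
}

#' Offspring diplotypes compatible with an observed phenotype
#'
#' Enumerates all diplotypes formed from one gamete per parent (including
#' recombinant gametes) whose phenotype under dominance matches the observed
#' class, flagging whether each requires at least one recombinant gamete.
#' An empty result signals a phenotype incompatible with the cross
#' (mis-scoring).
#'
#' @param cross an `sg_cross`.
#' @param phenotype one of [PHENOTYPE_CLASSES].
#' @return data.frame with columns `h_father`, `h_mother`,
#'   `requires_recombinant` (logical), one row per distinct compatible
#'   diplotype; zero rows if incompatible.
#' @export
infer_offspring_genotypes <- function(cross, phenotype) {
  stopifnot(inherits(cross, "sg_cross"))
  phenotype <- match.arg(phenotype, PHENOTYPE_CLASSES)
  gf <- gametes(cross$father)
  gm <- gametes(cross$mother)
  combos <- expand.grid(fi = seq_len(nrow(gf)), mi = seq_len(nrow(gm)))
  res <- lapply(seq_len(nrow(combos)), function(k) {
    fi <- combos$fi[k]; mi <- combos$mi[k]
    d <- diplotype(gf$haplotype[fi], gm$haplotype[mi])
    if (phenotype_class(d) != phenotype) return(NULL)
    data.frame(h_father = gf$haplotype[fi], h_mother = gm$haplotype[mi],
               requires_recombinant = gf$recombinant[fi] || gm$recombinant[mi],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(h_father = character(0), h_mother = character(0),
                      requires_recombinant = logical(0)))
  ## same unordered diplotype can arise several ways; keep the least
  ## recombinant route for each
  key <- vapply(seq_len(nrow(out)), function(i)
    paste(sort(c(out$h_father[i], out$h_mother[i])), collapse = "|"),
    character(1))
  ord <- order(key, out$requires_recombinant)
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(key[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a phenotype count vector in canonical class order
#'
#' @param counts numeric vector of length 4 (order of [PHENOTYPE_CLASSES]),
#'   optionally named.
#' @return named numeric vector over the four classes.
#' @export
phenotype_counts <- function(counts) {
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), PHENOTYPE_CLASSES))
      stop("count names must be exactly the four canonical phenotype classes")
    counts <- counts[PHENOTYPE_CLASSES]
  }
  if (length(counts) != 4L || any(is.na(counts)) || any(counts < 0))
    stop("counts must be four non-negative numbers")
  setNames(as.numeric(counts), PHENOTYPE_CLASSES)
}

#' Count recombinant offspring in an informative cross
#'
#' For a cross with one doubly heterozygous parent, each phenotype class is
#' classified as parental or recombinant by [infer_offspring_genotypes()];
#' recombinant classes are those whose every compatible diplotype requires a
#' recombinant gamete. Returns the recombinant count and the number of
#' informative offspring (the total).
#'
#' @param cross an `sg_cross` informative for colour-banding recombination.
#' @param counts phenotype counts (see [phenotype_counts()]).
#' @return list with `n_recombinant`, `n_informative` and
#'   `recombinant_classes`.
#' @export
count_recombinants <- function(cross, counts) {
  counts <- phenotype_counts(counts)
  if (is.null(informative_parent(cross)))
    stop("cross '", cross$label, "' is uninformative for colour-banding ",
         "recombination: no parent is heterozygous at both loci")
  is_rec <- vapply(PHENOTYPE_CLASSES, function(cl) {
    g <- infer_offspring_genotypes(cross, cl)
    if (nrow(g) == 0L) {
      if (counts[[cl]] > 0)
        stop("phenotype class '", cl, "' has count ", counts[[cl]],
             " but is incompatible with cross '", cross$label,
             "' (mis-scoring?)")
      return(NA)
    }
    all(g$requires_recombinant)
  }, logical(1))
  rec_classes <- PHENOTYPE_CLASSES[which(is_rec %in% TRUE)]
  list(n_recombinant = sum(counts[rec_classes]),
       n_informative = sum(counts),
       recombinant_classes = rec_classes)
}
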