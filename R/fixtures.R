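## Packaged study fixtures: the six-cross phenotype table, the 24-individual
## RAD panel, and the segregation patterns of the eleven assayed markers.
## All fixtures are emitted byte-stably by make_study_fixtures(); the copies
## under inst/extdata were written by that function.

.cross_table_data <- function() {
  data.frame(
    cross_id = 1:6,
    phase_label = c(rep("repulsion", 4), "coupling", "colour_only"),
    father_id = c("C100", "C108", "C110", "C112", "C114", "C119"),
    father_h1 = c("CP-Bb", "CP-Bb", "CP-Bb", "CP-Bb", "CP-BO", "CP-Bb"),
    father_h2 = c("Cy-BO", "Cy-BO", "Cy-BO", "Cy-BO", "Cy-Bb", "Cy-Bb"),
    mother_id = c("C101", "C109", "C111", "C113", "C115", "C118"),
    mother_h1 = rep("Cy-Bb", 6),
    mother_h2 = rep("Cy-Bb", 6),
    pink_unbanded = c(0, 0, 0, 0, 18, NA),
    pink_banded = c(56, 27, 17, 56, 0, 37),
    yellow_unbanded = c(47, 23, 10, 53, 0, NA),
    yellow_banded = c(0, 0, 0, 0, 16, 38),
    total = c(103, 50, 27, 109, 34, 75),
    stringsAsFactors = FALSE)
}

.marker_pattern_data <- function() {
  pat <- function(marker, assay_phase, in_phase, alternative, assay) {
    data.frame(marker = marker,
               allele = c(if (assay_phase == "banding") "Unbanded" else "Pink",
                          if (assay_phase == "banding") "Banded" else "Yellow"),
               role = c("in_phase", "alternative"),
               assay_phase = assay_phase,
               pattern = c(in_phase, alternative),
               assay = assay, stringsAsFactors = FALSE)
  }
  rbind(
    pat("Cne_RAD01", "banding", "100000000010011111111111",
        "111111111111111111111111", "CAPS RsaI"),
    pat("Cne_RAD02", "banding", "10000000000000111x111111",
        "11111111111111xxx1111111", "CAPS AvaII"),
    pat("Cne_RAD03", "banding", "100000010000011111111111",
        "111111111111111111111111", "Indel"),
    pat("Cne_RAD04", "banding", "100100000000001111111011",
        "111111111111111111111111", "CAPS MspA1I"),
    pat("Cne_RAD05", "colour", "101011111111110000000000",
        "11x11x11xx1111x111111111", "CAPS AluI"),
    pat("Cne_RAD06", "colour", "101111111101100000000000",
        "11x111111x1x111111111111", "CAPS DdeI"),
    pat("Cne_RAD07", "colour", "101011111111110000000100",
        "111111111111111111111111", "CAPS DraI"),
    pat("Cne_RAD08", "banding", "100000000000001111111111",
        "x11111111111111111111111", "CAPS HinfI"),
    pat("Cne_RAD09", "banding", "100000000000001111111111",
        "111111111x1111x111111111", "CAPS BstUI"),
    pat("Cne_RAD10", "banding", "100000000000001111111111",
        "x1x111111111111111111111", "CAPS DpnII"),
    ## the RAD11 tag polymorphism is in phase with banding, but the assay
    ## SNP (and the pattern printed for it) is in phase with colour
    pat("Cne_RAD11", "colour", "101111111101100000000000",
        "111111111111111111111111", "CAPS BstUI"))
}

#' Write the packaged study fixtures
#'
#' Emits the cross phenotype table (`cross_phenotypes.tsv`), the marker segregation
#' patterns (`marker_patterns.tsv`) and the 24-individual panel definition
#' (`panel.tsv`) in the package's TSV dialect. Output is byte-stable across
#' invocations; the copies shipped under `inst/extdata` were produced by
#' this function.
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
make_study_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(crosses = file.path(dir, "cross_phenotypes.tsv"),
             markers = file.path(dir, "marker_patterns.tsv"),
             panel = file.path(dir, "panel.tsv"))
  write_shellmap_tsv(.cross_table_data(), paths[["crosses"]], comment = c(
    "Six laboratory crosses: parental supergene diplotypes and F1 phenotype",
    "class counts (canonical class order; '-' = class not segregating)."))
  write_shellmap_tsv(.marker_pattern_data(), paths[["markers"]], comment = c(
    "Allele presence/absence patterns of the eleven assayed candidate",
    "markers over the 24-individual panel (father, mother, 12 pink-banded,",
    "10 yellow-unbanded). '1' present, '0' absent, 'x' sequence-absent but",
    "PCR-confirmed. Assay metadata retained as annotation only.",
    "For Cne_RAD11 the printed pattern follows the assay SNP (colour",
    "phase); the tag polymorphism itself is in phase with banding."))
  write_shellmap_tsv(as.data.frame(rad_panel()), paths[["panel"]],
                     comment = "Canonical 24-individual RAD panel order.")
  invisible(paths)
}

#' Path to a shipped fixture
#'
#' @param name fixture file name, e.g. `"marker_patterns.tsv"`.
#' @return absolute path.
#' @export
shellmap_fixture <- function(name) {
  p <- system.file("extdata", name, package = "shellmap")
  if (!nzchar(p)) stop("no packaged fixture named '", name, "'")
  p
}

#' Cross designs of the study
#'
#' Returns the [cross_design()] for one of the six crosses in the packaged
#' cross table.
#'
#' @param cross_id integer 1-6.
#' @param crosses optional cross table (defaults to the packaged one).
#' @return an `sg_cross`.
#' @examples
#' study_cross(1)  # repulsion mapping cross
#' @export
study_cross <- function(cross_id, crosses = .cross_table_data()) {
  row <- crosses[crosses$cross_id == cross_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown cross id: ", cross_id)
  cross_design(
    father = diplotype(row$father_h1, row$father_h2),
    mother = diplotype(row$mother_h1, row$mother_h2),
    label = paste0("cross ", cross_id, " (", row$father_id, " x ",
                   row$mother_id, ", ", row$phase_label, ")"))
}

#' Phenotype counts of a study cross
#'
#' @inheritParams study_cross
#' @return named count vector in canonical class order (`NA` entries for
#'   classes not segregating are returned as zero only when
#'   `zero_missing = TRUE`).
#' @param zero_missing replace non-segregating `NA` classes by zero.
#' @export
study_counts <- function(cross_id, crosses = .cross_table_data(),
                         zero_missing = FALSE) {
  row <- crosses[crosses$cross_id == cross_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown cross id: ", cross_id)
  x <- c(row$pink_unbanded, row$pink_banded, row$yellow_unbanded,
         row$yellow_banded)
  if (zero_missing) x[is.na(x)] <- 0
  setNames(x, PHENOTYPE_CLASSES)
}

#' Canonical simulated marker map
#'
#' The default 13-locus map used by the simulators: eleven RAD-style
#' markers flanking the supergene, with three cosegregating markers 0.98 cM
#' from it and the colour and banding loci at zero distance from each
#' other, for a 35.8 cM total. Phases follow the assayed marker set (four
#' colour-phase, seven banding-phase).
#'
#' @return data.frame with `marker`, `position_cM`, `phase`.
#' @export
default_marker_map <- function() {
  data.frame(
    marker = c("RAD05", "RAD06", "RAD07", "RAD11", "RAD08", "RAD09",
               "RAD10", "C", "B", "RAD01", "RAD02", "RAD03", "RAD04"),
    position_cM = c(0, 6, 11, 16, 20.92, 20.92, 20.92, 21.9, 21.9,
                    26.9, 30.9, 33.9, 35.8),
    phase = c("colour", "colour", "colour", "colour", "banding", "banding",
              "banding", "supergene", "supergene", "banding", "banding",
              "banding", "banding"),
    stringsAsFactors = FALSE)
}
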