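## File formats: headered TSV with '#' comments and '-' for missing values,
## pattern and genotype matrices, barcode maps, and FASTQ via Biostrings.

#' Write a data.frame in the package TSV dialect
#'
#' UTF-8, tab-separated, header row, `#`-prefixed comment lines before the
#' header, `-` for missing values. Output is byte-stable for a given input.
#'
#' @param x data.frame.
#' @param path output path.
#' @param comment optional character vector of comment lines (written
#'   without the leading `#`).
#' @return invisibly, `path`.
#' @export
write_shellmap_tsv <- function(x, path, comment = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con, sep = "\n")
  x2 <- as.data.frame(lapply(x, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- "-"
    col
  }), stringsAsFactors = FALSE)
  names(x2) <- names(x)
  writeLines(paste(names(x2), collapse = "\t"), con, sep = "\n")
  if (nrow(x2))
    writeLines(do.call(paste, c(unname(x2), sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Read a package-dialect TSV
#'
#' @param path input path.
#' @param numeric_cols columns to convert to numeric (default: all columns
#'   that parse cleanly).
#' @return data.frame; `-` cells become `NA`.
#' @export
read_shellmap_tsv <- function(path, numeric_cols = NULL) {
  x <- read.delim(path, comment.char = "#", colClasses = "character",
                  na.strings = "-", check.names = FALSE,
                  stringsAsFactors = FALSE)
  convert <- numeric_cols %||% names(x)
  for (nm in intersect(convert, names(x))) {
    v <- x[[nm]]
    suppressWarnings(num <- as.numeric(v))
    if (!any(is.na(num) & !is.na(v))) x[[nm]] <- num
  }
  x
}

#' Read and validate a segregation-pattern table
#'
#' Expects columns `marker` (or `locus_id`), `allele` (or `allele_id`) and
#' `pattern`; pattern cells must be strings over `{0,1,x}` of one common
#' length. Errors name the offending row.
#'
#' @param path TSV path.
#' @return data.frame with at least `locus_id`, `allele_id`, `pattern`.
#' @export
read_pattern_tsv <- function(path) {
  x <- read_shellmap_tsv(path)
  if ("marker" %in% names(x) && !"locus_id" %in% names(x))
    x$locus_id <- x$marker
  if ("allele" %in% names(x) && !"allele_id" %in% names(x))
    x$allele_id <- x$allele
  need <- c("locus_id", "allele_id", "pattern")
  if (!all(need %in% names(x)))
    stop("pattern table ", path, " lacks columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  x$pattern <- as.character(x$pattern)
  lens <- nchar(x$pattern)
  if (length(unique(lens)) != 1L)
    stop("inconsistent pattern lengths in ", path, " at row(s): ",
         paste(head(which(lens != lens[1L])), collapse = ", "))
  bad <- grepl("[^01x]", x$pattern)
  if (any(bad))
    stop("pattern cells outside {0,1,x} in ", path, " at row(s): ",
         paste(head(which(bad)), collapse = ", "))
  x
}

#' Write a segregation-pattern table
#'
#' @param patterns data.frame with `locus_id`, `allele_id`, `pattern` (extra
#'   columns are preserved).
#' @param path output path.
#' @param comment optional comment lines.
#' @return invisibly, `path`.
#' @export
write_pattern_tsv <- function(patterns, path, comment = NULL) {
  write_shellmap_tsv(patterns, path, comment)
}

#' Read a genotype matrix (markers x offspring)
#'
#' First column = marker id; remaining columns = offspring; cells in
#' `{1, 0, -}` (`-` = missing).
#'
#' @param path TSV path.
#' @return numeric matrix with marker rownames, `NA` for missing.
#' @export
read_genotype_tsv <- function(path) {
  x <- read.delim(path, comment.char = "#", colClasses = "character",
                  check.names = FALSE, stringsAsFactors = FALSE)
  markers <- as.character(x[[1L]])
  m <- as.matrix(x[, -1L, drop = FALSE])
  bad <- !(m %in% c("0", "1", "-") | is.na(m))
  if (any(bad))
    stop("genotype cells outside {0,1,-} in ", path, " at row(s): ",
         paste(head(unique(which(bad, arr.ind = TRUE)[, 1L])),
               collapse = ", "))
  m[m == "-"] <- NA
  mode(m) <- "numeric"
  rownames(m) <- markers
  m
}

#' @rdname read_genotype_tsv
#' @param geno numeric matrix (0/1/NA), markers in rows.
#' @param path output path.
#' @param comment optional comment lines.
#' @export
write_genotype_tsv <- function(geno, path, comment = NULL) {
  df <- data.frame(marker = rownames(geno), as.data.frame(geno),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_shellmap_tsv(df, path, comment)
}

#' Read a barcode map
#'
#' @param path TSV with columns `individual_id`, `barcode`.
#' @return validated named barcode vector (see [barcode_set()]).
#' @export
read_barcode_tsv <- function(path) {
  x <- read_shellmap_tsv(path)
  if (!all(c("individual_id", "barcode") %in% names(x)))
    stop("barcode table ", path,
         " must have columns individual_id and barcode")
  barcode_set(setNames(as.character(x$barcode), x$individual_id))
}

#' Read paired FASTQ files
#'
#' @param file1,file2 paths to the read-1 and read-2 FASTQ files.
#' @return data.frame with `read1`, `qual1`, `read2`, `qual2`.
#' @export
read_fastq_pairs <- function(file1, file2) {
  r1 <- Biostrings::readDNAStringSet(file1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(file2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2)) {
    shorter <- if (length(r1) < length(r2)) file1 else file2
    stop("mate count mismatch: ", length(r1), " vs ", length(r2),
         " reads; shorter file: ", shorter)
  }
  data.frame(read1 = as.character(r1),
             qual1 = as.character(S4Vectors::mcols(r1)$qualities),
             read2 = as.character(r2),
             qual2 = as.character(S4Vectors::mcols(r2)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write paired FASTQ files
#'
#' @param pairs data.frame with `read1`, `qual1`, `read2`, `qual2` and
#'   optionally `id`.
#' @param file1,file2 output paths.
#' @return invisibly, `c(file1, file2)`.
#' @export
write_fastq_pairs <- function(pairs, file1, file2) {
  ids <- pairs$id %||% sprintf("read%06d", seq_len(nrow(pairs)))
  s1 <- Biostrings::DNAStringSet(pairs$read1)
  s2 <- Biostrings::DNAStringSet(pairs$read2)
  names(s1) <- paste0(ids, "/1")
  names(s2) <- paste0(ids, "/2")
  Biostrings::writeXStringSet(s1, file1, format = "fastq",
                              qualities = Biostrings::BStringSet(pairs$qual1))
  Biostrings::writeXStringSet(s2, file2, format = "fastq",
                              qualities = Biostrings::BStringSet(pairs$qual2))
  invisible(c(file1, file2))
}
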