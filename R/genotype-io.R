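#' Read a genotype table
#'
#' Reads a long-format tab-separated genotype table with header columns
#' `strain_id`, `locus`, `length` (one row per allele call) into a
#' [StrainProfileSet-class]. Duplicate rows are collapsed; strain order
#' follows first appearance.
#'
#' @param path Path to a TSV file.
#' @param panel Optional locus panel; calls at loci outside it are an
#'   error. See [readLocusPanel()].
#' @return A [StrainProfileSet-class].
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("strain_id\tlocus\tlength", "a\tC3\t210", "a\tC3\t216",
#'              "b\tC3\t204", "b\tC4\t150"), tf)
#' readGenotypeTable(tf)
readGenotypeTable <- function(path, panel = NULL) {
  df <- .readCallsTsv(path, id_col = "strain_id")
  names(df)[names(df) == "strain_id"] <- "strain_id"
  if (!is.null(panel)) .checkLoci(unique(df$locus), panel)
  StrainProfileSet(df, panel = panel)
}

#' Read query meta-profiles
#'
#' Same TSV format as [readGenotypeTable()] but with a `sample_id` column;
#' each distinct sample id yields one [MetaProfile-class].
#'
#' @inheritParams readGenotypeTable
#' @return A named list of [MetaProfile-class] objects, one per sample, in
#'   order of first appearance.
#' @export
readMetaProfiles <- function(path, panel = NULL) {
  df <- .readCallsTsv(path, id_col = "sample_id")
  if (!is.null(panel)) .checkLoci(unique(df$locus), panel)
  ids <- unique(df$sample_id)
  out <- lapply(ids, function(id) {
    metaProfile(df[df$sample_id == id, c("locus", "length")], id)
  })
  names(out) <- ids
  out
}

.readCallsTsv <- function(path, id_col) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(id_col, "locus", "length")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("genotype table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  len <- suppressWarnings(as.numeric(df$length))
  bad <- which(is.na(len) | len <= 0 | len != floor(len))
  if (length(bad) > 0)
    stop("invalid allele length at line ", bad[1] + 1L, " of ", path,
         " ('", df$length[bad[1]], "'): lengths must be positive integers")
  df$length <- as.integer(len)
  df[, need]
}

#' Write a genotype table
#'
#' @param x A [StrainProfileSet-class] or [MetaProfile-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeGenotypeTable <- function(x, path) {
  if (is(x, "StrainProfileSet")) {
    df <- x@calls
  } else if (is(x, "MetaProfile")) {
    df <- cbind(sample_id = sampleId(x), x@calls)
  } else stop("unsupported object")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a locus panel file
#'
#' One locus name per line; blank lines ignored.
#'
#' @param path Path to the panel file.
#' @return Character vector of locus names.
#' @export
readLocusPanel <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x)]
  if (length(x) == 0) stop("empty locus panel file: ", path)
  if (anyDuplicated(x)) stop("duplicate loci in panel file: ", path)
  x
}
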