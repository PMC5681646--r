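#' @import methods
NULL

#' Default microsatellite locus panel
#'
#' The twelve SSR loci routinely used for multilocus typing of
#' *Saccharomyces cerevisiae* isolates.
#'
#' @return Character vector of locus names.
#' @export
#' @examples
#' ssrPanel()
ssrPanel <- function() {
  c("C3", "C4", "C5", "C6", "C8", "C11", "SCYOR267C", "SCAAT1",
    "SCAAT3", "SCAAT5", "YKL172W", "YPL9")
}

#' Construct a table of allele calls
#'
#' An allele call is one scored PCR fragment length at one SSR locus.
#' Calls behave as a set: duplicates are collapsed and rows are ordered by
#' locus name, then fragment length.
#'
#' @param locus Character vector of locus names (non-empty strings).
#' @param length Integer vector of fragment lengths in base pairs (> 0).
#' @return A `data.frame` with columns `locus` and `length`, unique rows,
#'   sorted by (locus, length).
#' @export
#' @examples
#' alleleCalls(c("C3", "C3", "C4"), c(210, 204, 150))
alleleCalls <- function(locus = character(), length = integer()) {
  locus <- as.character(locus)
  length <- as.integer(length)
  if (anyNA(length) || any(length <= 0L))
    stop("allele lengths must be positive integers")
  if (any(!nzchar(locus)) || anyNA(locus))
    stop("locus names must be non-empty strings")
  df <- unique(data.frame(locus = locus, length = length,
                          stringsAsFactors = FALSE))
  df <- df[order(df$locus, df$length), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.emptyCalls <- function() alleleCalls()

.checkCallsDf <- function(df) {
  if (!is.data.frame(df) || !all(c("locus", "length") %in% names(df)))
    return("calls must be a data.frame with columns 'locus' and 'length'")
  if (nrow(df) > 0) {
    if (!is.numeric(df$length) || any(df$length <= 0))
      return("allele lengths must be positive")
    if (anyDuplicated(paste(df$locus, df$length)))
      return("duplicate (locus, length) calls")
  }
  TRUE
}

#' A reference collection of single-strain SSR profiles
#'
#' Holds the genotypes of a strain collection in long format: one row per
#' (strain, locus, fragment length) allele call. A strain typically carries
#' one (haploid or homozygous) or two (heterozygous diploid) alleles per
#' locus; loci that failed amplification simply contribute no calls.
#'
#' @slot calls `data.frame` with columns `strain_id`, `locus`, `length`.
#' @slot strainIds character vector of strain identifiers, in input order.
#' @slot panel character vector naming the locus panel.
#' @aliases StrainProfileSet
#' @exportClass StrainProfileSet
setClass("StrainProfileSet",
  slots = c(calls = "data.frame", strainIds = "character",
            panel = "character"),
  validity = function(object) {
    df <- object@calls
    if (!all(c("strain_id", "locus", "length") %in% names(df)))
      return("calls must have columns strain_id, locus, length")
    if (nrow(df) > 0 && any(df$length <= 0))
      return("allele lengths must be positive")
    if (anyDuplicated(paste(df$strain_id, df$locus, df$length)))
      return("duplicate (strain, locus, length) rows")
    if (!all(unique(df$strain_id) %in% object@strainIds))
      return("calls contain strain ids missing from strainIds")
    if (anyDuplicated(object@strainIds))
      return("duplicate strain ids")
    if (length(object@panel) > 0 && nrow(df) > 0 &&
        !all(df$locus %in% object@panel))
      return(paste("loci outside the panel:",
                   paste(setdiff(unique(df$locus), object@panel),
                         collapse = ", ")))
    TRUE
  })

#' Create a StrainProfileSet
#'
#' @param calls `data.frame` with columns `strain_id`, `locus`, `length`;
#'   duplicate rows are collapsed.
#' @param panel Optional character vector restricting the locus panel;
#'   calls at loci outside it are an error. Defaults to the loci present.
#' @param strainIds Optional ordering of strain ids; defaults to order of
#'   first appearance.
#' @return A [StrainProfileSet-class] object. Strains with more than two
#'   alleles at a locus trigger a validation warning (multi-allelic calls
#'   are tolerated but unexpected for a haploid/diploid genome).
#' @export
#' @examples
#' df <- data.frame(strain_id = c("a", "a", "b"),
#'                  locus = c("C3", "C3", "C3"),
#'                  length = c(210, 216, 204))
#' StrainProfileSet(df)
StrainProfileSet <- function(calls, panel = NULL, strainIds = NULL) {
  calls <- as.data.frame(calls)
  calls$strain_id <- as.character(calls$strain_id)
  calls$locus <- as.character(calls$locus)
  calls$length <- as.integer(calls$length)
  calls <- unique(calls[, c("strain_id", "locus", "length")])
  if (is.null(strainIds)) strainIds <- unique(calls$strain_id)
  if (is.null(panel)) panel <- sort(unique(calls$locus))
  calls <- calls[order(match(calls$strain_id, strainIds),
                       calls$locus, calls$length), , drop = FALSE]
  rownames(calls) <- NULL
  obj <- new("StrainProfileSet", calls = calls,
             strainIds = as.character(strainIds),
             panel = as.character(panel))
  if (nrow(calls) > 0) {
    cnt <- table(paste(calls$strain_id, calls$locus, sep = "\r"))
    if (any(cnt > 2))
      warning(sum(cnt > 2),
              " strain/locus combination(s) carry more than 2 alleles")
  }
  obj
}

#' A sample meta-profile
#'
#' The set of all SSR alleles observed in one (possibly mixed) sample.
#' Unlike a single-strain profile, the per-locus allele count is unbounded:
#' a pool of several strains can show many alleles at one locus.
#'
#' @slot sampleId sample identifier.
#' @slot calls `data.frame` of allele calls (columns `locus`, `length`).
#' @aliases MetaProfile
#' @exportClass MetaProfile
setClass("MetaProfile",
  slots = c(sampleId = "character", calls = "data.frame"),
  validity = function(object) {
    msg <- .checkCallsDf(object@calls)
    if (!isTRUE(msg)) return(msg)
    if (length(object@sampleId) != 1) return("sampleId must be length 1")
    TRUE
  })

#' Create a MetaProfile
#'
#' @param calls A calls `data.frame` (see [alleleCalls()]) or anything
#'   coercible to one.
#' @param sampleId Sample identifier.
#' @return A [MetaProfile-class].
#' @export
#' @examples
#' metaProfile(alleleCalls(c("C3", "C3"), c(204, 210)), "pool1")
metaProfile <- function(calls, sampleId = "sample") {
  calls <- as.data.frame(calls)
  new("MetaProfile", sampleId = as.character(sampleId),
      calls = alleleCalls(calls$locus, calls$length))
}

#' The allele universe of an analysis
#'
#' The ordered set of distinct alleles over which profiles are encoded as
#' presence/absence vectors. Entries are sorted by locus name then fragment
#' length so that encodings (and hence model fits) are reproducible.
#'
#' @slot entries `data.frame` of distinct calls, deterministically sorted.
#' @aliases AlleleUniverse
#' @exportClass AlleleUniverse
setClass("AlleleUniverse",
  slots = c(entries = "data.frame"),
  validity = function(object) {
    msg <- .checkCallsDf(object@entries)
    if (!isTRUE(msg)) return(msg)
    e <- object@entries
    if (nrow(e) > 1) {
      o <- order(e$locus, e$length)
      if (!identical(o, seq_len(nrow(e))))
        return("universe entries must be sorted by (locus, length)")
    }
    TRUE
  })

#' Result of deconvolving a meta-profile
#'
#' @slot selected strain ids called present (coefficient above threshold).
#' @slot coefficients named non-negative coefficients for all reference
#'   strains at the chosen penalty.
#' @slot lambda chosen L1 penalty.
#' @slot predicted [MetaProfile-class]: union of the selected strains'
#'   profiles.
#' @slot glmError percent of alleles differing between predicted and query
#'   profiles, relative to the predicted profile size.
#' @slot nPredictedAlleles,nDiffAlleles the counts entering the error.
#' @slot degenerate `TRUE` when no strain was selected (the error ratio is
#'   then undefined and reported as 100).
#' @aliases DeconvolutionResult
#' @exportClass DeconvolutionResult
setClass("DeconvolutionResult",
  slots = c(selected = "character", coefficients = "numeric",
            lambda = "numeric", predicted = "MetaProfile",
            glmError = "numeric", nPredictedAlleles = "integer",
            nDiffAlleles = "integer", degenerate = "logical"),
  validity = function(object) {
    if (any(object@coefficients < 0)) return("coefficients must be >= 0")
    if (object@glmError < 0) return("glmError must be >= 0")
    TRUE
  })

#' A pool design: parental strains plus profiles
#'
#' @slot poolId pool identifier.
#' @slot parentalIds ids of the strains pooled to create the sample.
#' @slot expected [MetaProfile-class]: union of the parental profiles.
#' @slot observed [MetaProfile-class]: the profile actually scored (equal
#'   to `expected` for in-silico pools before amplification noise).
#' @aliases PoolDesign
#' @exportClass PoolDesign
setClass("PoolDesign",
  slots = c(poolId = "character", parentalIds = "character",
            expected = "MetaProfile", observed = "MetaProfile"),
  validity = function(object) {
    if (length(object@parentalIds) < 1) return("pool needs parental ids")
    if (anyDuplicated(object@parentalIds)) return("duplicate parental ids")
    TRUE
  })

#' Report of a reference-pruning run
#'
#' @slot kept strain ids retained in the pruned collection.
#' @slot removed `data.frame` with columns `removed_id`,
#'   `representative_id`, `round`.
#' @slot nRounds number of full passes performed.
#' @aliases PruneReport
#' @exportClass PruneReport
setClass("PruneReport",
  slots = c(kept = "character", removed = "data.frame",
            nRounds = "integer"),
  validity = function(object) {
    if (length(intersect(object@kept, object@removed$removed_id)) > 0)
      return("a strain cannot be both kept and removed")
    TRUE
  })
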