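.key <- function(df) paste(df$locus, df$length, sep = "\r")

#' @rdname StrainProfileSet-class
#' @export
setMethod("strainIds", "StrainProfileSet", function(x) x@strainIds)

#' @rdname StrainProfileSet-class
#' @export
setMethod("lociPanel", "StrainProfileSet", function(x) x@panel)

#' @describeIn profileCalls all calls of the collection, or of one strain
#'   when `strain` is given.
#' @param strain optional strain id.
#' @export
setMethod("profileCalls", "StrainProfileSet", function(x, strain = NULL) {
  df <- x@calls
  if (!is.null(strain)) {
    if (!strain %in% x@strainIds) stop("unknown strain id: ", strain)
    df <- df[df$strain_id == strain, c("locus", "length"), drop = FALSE]
    df <- df[order(df$locus, df$length), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
})

#' @describeIn profileCalls the sample's calls.
#' @export
setMethod("profileCalls", "MetaProfile", function(x) x@calls)

#' @describeIn profileCalls the universe entries.
#' @export
setMethod("profileCalls", "AlleleUniverse", function(x) x@entries)

#' @rdname MetaProfile-class
#' @export
setMethod("sampleId", "MetaProfile", function(x) x@sampleId)

#' @rdname DeconvolutionResult-class
#' @export
setMethod("selectedStrains", "DeconvolutionResult", function(x) x@selected)

#' @rdname DeconvolutionResult-class
#' @export
setMethod("strainCoefficients", "DeconvolutionResult",
          function(x) x@coefficients)

#' @rdname PoolDesign-class
#' @export
setMethod("parentalIds", "PoolDesign", function(x) x@parentalIds)

#' Number of strains in a collection
#'
#' @param x a [StrainProfileSet-class].
#' @return Integer count.
#' @export
nStrains <- function(x) length(strainIds(x))

#' Subset a strain collection
#'
#' @param x a [StrainProfileSet-class].
#' @param i strain ids (character) or positional/logical index into
#'   `strainIds(x)`.
#' @param j,drop,... ignored.
#' @return A [StrainProfileSet-class] containing the selected strains, in
#'   the order given.
#' @export
setMethod("[", "StrainProfileSet", function(x, i, j, ..., drop = FALSE) {
  ids <- if (is.character(i)) i else strainIds(x)[i]
  if (!all(ids %in% x@strainIds))
    stop("unknown strain id(s): ",
         paste(setdiff(ids, x@strainIds), collapse = ", "))
  calls <- x@calls[x@calls$strain_id %in% ids, , drop = FALSE]
  StrainProfileSet(calls, panel = x@panel, strainIds = ids)
})

.checkLoci <- function(loci, panel) {
  bad <- setdiff(loci, panel)
  if (length(bad) > 0)
    stop("unknown locus/loci: ", paste(bad, collapse = ", "))
}

#' @rdname restrictLoci
#' @export
setMethod("restrictLoci", "StrainProfileSet", function(x, loci) {
  .checkLoci(loci, x@panel)
  calls <- x@calls[x@calls$locus %in% loci, , drop = FALSE]
  StrainProfileSet(calls, panel = loci, strainIds = x@strainIds)
})

#' @rdname restrictLoci
#' @export
setMethod("restrictLoci", "MetaProfile", function(x, loci) {
  keep <- x@calls$locus %in% loci
  metaProfile(x@calls[keep, , drop = FALSE], sampleId(x))
})

#' @rdname restrictLoci
#' @export
setMethod("restrictLoci", "PoolDesign", function(x, loci) {
  new("PoolDesign", poolId = x@poolId, parentalIds = x@parentalIds,
      expected = restrictLoci(x@expected, loci),
      observed = restrictLoci(x@observed, loci))
})

setMethod("show", "StrainProfileSet", function(object) {
  cat("StrainProfileSet with", length(object@strainIds), "strains,",
      length(object@panel), "loci,", nrow(object@calls), "allele calls\n")
  cat("  panel:", paste(utils::head(object@panel, 6), collapse = ", "),
      if (length(object@panel) > 6) "..." else "", "\n")
})

setMethod("show", "MetaProfile", function(object) {
  cat("MetaProfile", object@sampleId, "with", nrow(object@calls),
      "alleles over", length(unique(object@calls$locus)), "loci\n")
})

setMethod("show", "AlleleUniverse", function(object) {
  cat("AlleleUniverse with", nrow(object@entries), "distinct alleles over",
      length(unique(object@entries$locus)), "loci\n")
})

setMethod("show", "DeconvolutionResult", function(object) {
  cat("DeconvolutionResult:", length(object@selected),
      "strain(s) called at lambda =", signif(object@lambda, 4), "\n")
  if (length(object@selected) > 0)
    cat("  selected:", paste(object@selected, collapse = ", "), "\n")
  cat("  GLM error:", round(object@glmError, 2), "% (",
      object@nDiffAlleles, "of", object@nPredictedAlleles,
      "predicted alleles differ )\n")
  if (object@degenerate) cat("  [degenerate: empty prediction]\n")
})

setMethod("show", "PoolDesign", function(object) {
  cat("PoolDesign", object@poolId, ":", length(object@parentalIds),
      "parental strains,", nrow(object@expected@calls), "expected /",
      nrow(object@observed@calls), "observed alleles\n")
})

setMethod("show", "PruneReport", function(object) {
  cat("PruneReport:", length(object@kept), "kept,",
      nrow(object@removed), "removed in", object@nRounds, "round(s)\n")
})
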