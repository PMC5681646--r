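#' @rdname StrainProfileSet-class
#' @param x,object an object.
#' @export
setGeneric("strainIds", function(x) standardGeneric("strainIds"))

#' @rdname StrainProfileSet-class
#' @export
setGeneric("lociPanel", function(x) standardGeneric("lociPanel"))

#' Extract allele calls
#'
#' @param x a [StrainProfileSet-class], [MetaProfile-class] or
#'   [AlleleUniverse-class].
#' @param ... further arguments (unused).
#' @return A calls `data.frame`.
#' @export
setGeneric("profileCalls", function(x, ...) standardGeneric("profileCalls"))

#' @rdname MetaProfile-class
#' @param x an object.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' Restrict profiles to a subset of loci
#'
#' Drops every allele call outside `loci`. Used to compare the full locus
#' panel against reduced panels that exclude error-prone loci.
#'
#' @param x a [StrainProfileSet-class], [MetaProfile-class] or
#'   [PoolDesign-class].
#' @param loci character vector of locus names to keep; every name must be
#'   a known locus.
#' @return An object of the same class restricted to `loci`.
#' @export
setGeneric("restrictLoci", function(x, loci) standardGeneric("restrictLoci"))

#' GLM error between a predicted and a query profile
#'
#' The percent of alleles differing between the combined profile of the
#' called strains and the query meta-profile, relative to the number of
#' alleles in the predicted profile:
#' `100 * |predicted symmetric-difference query| / |predicted|`.
#'
#' Applied to a [DeconvolutionResult-class] it returns the stored value.
#'
#' @param predicted a [MetaProfile-class] (or calls `data.frame`), or a
#'   [DeconvolutionResult-class].
#' @param query the query [MetaProfile-class] (or calls `data.frame`);
#'   missing in the accessor form.
#' @return Numeric percent, >= 0. When the predicted profile is empty the
#'   ratio is undefined; 100 is returned with attribute `degenerate = TRUE`.
#' @export
setGeneric("glmError", function(predicted, query) standardGeneric("glmError"))

#' @rdname DeconvolutionResult-class
#' @param x an object.
#' @export
setGeneric("selectedStrains", function(x) standardGeneric("selectedStrains"))

#' @rdname DeconvolutionResult-class
#' @export
setGeneric("strainCoefficients",
           function(x) standardGeneric("strainCoefficients"))

#' @rdname PoolDesign-class
#' @param x an object.
#' @export
setGeneric("parentalIds", function(x) standardGeneric("parentalIds"))
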