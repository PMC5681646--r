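#' Create a pool design
#'
#' @param parentalIds Strain ids pooled to create the sample.
#' @param reference [StrainProfileSet-class] providing the parental
#'   profiles (used to derive the expected profile).
#' @param observed Optional observed [MetaProfile-class]; defaults to the
#'   expected (noise-free) profile.
#' @param poolId Pool identifier.
#' @return A [PoolDesign-class] whose `expected` slot is the union of the
#'   parental profiles.
#' @export
poolDesign <- function(parentalIds, reference, observed = NULL,
                       poolId = "pool") {
  expected <- unionProfiles(reference, parentalIds,
                            sampleId = paste0(poolId, ":expected"))
  if (is.null(observed)) {
    observed <- metaProfile(expected@calls, paste0(poolId, ":observed"))
  }
  new("PoolDesign", poolId = as.character(poolId),
      parentalIds = as.character(parentalIds),
      expected = expected, observed = observed)
}

#' Strain-specific alleles at a locus
#'
#' An allele is strain-specific within a pool when exactly one of the
#' parental strains carries it at the locus.
#'
#' @param profiles Named list of parental calls `data.frame`s /
#'   [MetaProfile-class]es, or a [StrainProfileSet-class] together with
#'   `ids`.
#' @param locus Locus name.
#' @param ids Parental strain ids when `profiles` is a collection.
#' @return Named list mapping each strain id that has specific alleles to
#'   the integer vector of its specific fragment lengths.
#' @export
strainSpecificAlleles <- function(profiles, locus, ids = NULL) {
  profiles <- .asProfileList(profiles, ids)
  atLocus <- lapply(profiles, function(df) df$length[df$locus == locus])
  lens <- unlist(atLocus, use.names = FALSE)
  uniq <- as.integer(names(which(table(lens) == 1)))
  out <- lapply(atLocus, function(v) sort(intersect(v, uniq)))
  out[vapply(out, length, 1L) > 0]
}

.asProfileList <- function(profiles, ids = NULL) {
  if (is(profiles, "StrainProfileSet")) {
    if (is.null(ids)) ids <- strainIds(profiles)
    if (!all(ids %in% strainIds(profiles)))
      stop("unknown parental strain id(s): ",
           paste(setdiff(ids, strainIds(profiles)), collapse = ", "))
    out <- lapply(ids, function(id) profileCalls(profiles, id))
    names(out) <- ids
    return(out)
  }
  lapply(profiles, function(p) if (is(p, "MetaProfile")) p@calls else p)
}

#' Discrimination ability of a locus in a pool
#'
#' The fraction of pooled strains that can be recognized at this locus:
#' strains carrying at least one strain-specific allele that is actually
#' present in the pool's observed profile, divided by the number of
#' pooled strains.
#'
#' @param pool A [PoolDesign-class].
#' @param reference [StrainProfileSet-class] with the parental profiles.
#' @param locus Locus name.
#' @return Fraction in \[0, 1\].
#' @export
discriminationAbility <- function(pool, reference, locus) {
  ids <- parentalIds(pool)
  spec <- strainSpecificAlleles(reference, locus, ids = ids)
  obs <- pool@observed@calls
  obsLens <- obs$length[obs$locus == locus]
  identified <- vapply(spec, function(v) any(v %in% obsLens), logical(1))
  sum(identified) / length(ids)
}

#' Average locus error over a set of pools
#'
#' For each pool, the alleles differing between the observed and the
#' expected pooled profile at the locus, divided by the number of expected
#' alleles at that locus; averaged over pools and expressed as a percent.
#' Pools with no expected allele at the locus are excluded (with a
#' warning) and do not count toward the denominator.
#'
#' @param pools List of [PoolDesign-class] objects.
#' @param locus Locus name.
#' @return Percent >= 0, or `NA` if no pool has expected alleles at the
#'   locus.
#' @export
averageLocusError <- function(pools, locus) {
  ratios <- vapply(pools, function(pool) {
    exp <- pool@expected@calls
    obs <- pool@observed@calls
    exp <- exp[exp$locus == locus, , drop = FALSE]
    obs <- obs[obs$locus == locus, , drop = FALSE]
    if (nrow(exp) == 0) return(NA_real_)
    profileDifference(obs, exp)$n_diff / nrow(exp)
  }, numeric(1))
  if (anyNA(ratios)) {
    warning(sum(is.na(ratios)), " pool(s) with no expected allele at ",
            locus, " excluded")
    ratios <- ratios[!is.na(ratios)]
  }
  if (length(ratios) == 0) return(NA_real_)
  100 * mean(ratios)
}

#' Recovery statistics of a deconvolution call
#'
#' @param called Character vector of called strain ids (e.g.
#'   `selectedStrains()` of a [DeconvolutionResult-class]).
#' @param pool The [PoolDesign-class] holding the true parental ids.
#' @return List of class `RecoveryStats` with `tpr` (percent of parental
#'   strains recovered) and `n_false_positives` (called strains that are
#'   not parental).
#' @export
recoveryStats <- function(called, pool) {
  parental <- parentalIds(pool)
  if (length(parental) == 0) stop("pool has no parental strains")
  called <- unique(as.character(called))
  structure(list(
    tpr = 100 * length(intersect(called, parental)) / length(parental),
    n_false_positives = length(setdiff(called, parental))),
    class = "RecoveryStats")
}
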