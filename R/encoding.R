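#' Build the allele universe of an analysis
#'
#' The universe is the ordered union of every distinct allele seen in the
#' reference collection and, optionally, a query meta-profile. Alleles
#' observed only in the query are included: the model must be able to see
#' that the reference cannot explain them.
#'
#' @param reference A [StrainProfileSet-class] (or list of calls
#'   `data.frame`s / [MetaProfile-class]es).
#' @param extra Optional [MetaProfile-class] (typically the query).
#' @return An [AlleleUniverse-class] sorted by (locus, length).
#' @export
buildUniverse <- function(reference, extra = NULL) {
  dfs <- list()
  if (is(reference, "StrainProfileSet")) {
    dfs[[1]] <- reference@calls[, c("locus", "length")]
  } else if (is.list(reference)) {
    dfs <- lapply(reference, function(p) {
      if (is(p, "MetaProfile")) p@calls else as.data.frame(p)
    })
  } else stop("unsupported reference")
  if (!is.null(extra)) {
    dfs <- c(dfs, list(if (is(extra, "MetaProfile")) extra@calls
                       else as.data.frame(extra)))
  }
  all <- do.call(rbind, dfs)
  if (is.null(all) || nrow(all) == 0)
    stop("cannot build an allele universe from empty input")
  new("AlleleUniverse",
      entries = alleleCalls(all$locus, all$length))
}

#' @rdname buildUniverse
#' @param x an [AlleleUniverse-class].
#' @export
setMethod("length", "AlleleUniverse", function(x) nrow(x@entries))

#' Encode a profile over an allele universe
#'
#' @param profile A [MetaProfile-class] or calls `data.frame`.
#' @param universe An [AlleleUniverse-class]; every call of the profile
#'   must belong to it (rebuild the universe otherwise).
#' @return Integer 0/1 vector of length `length(universe)`; entry *i* is 1
#'   iff universe allele *i* is present in the profile.
#' @seealso [decodeProfile()] for the inverse.
#' @export
encodeProfile <- function(profile, universe) {
  calls <- if (is(profile, "MetaProfile")) profile@calls
           else as.data.frame(profile)
  ukeys <- .key(universe@entries)
  idx <- match(.key(calls), ukeys)
  if (anyNA(idx))
    stop("profile contains allele(s) outside the universe; rebuild the ",
         "universe including this profile")
  v <- integer(length(ukeys))
  v[idx] <- 1L
  v
}

#' Decode a presence vector back to allele calls
#'
#' @param v 0/1 vector over the universe.
#' @param universe An [AlleleUniverse-class].
#' @return A calls `data.frame`.
#' @export
decodeProfile <- function(v, universe) {
  stopifnot(length(v) == length(universe))
  df <- universe@entries[v != 0, , drop = FALSE]
  alleleCalls(df$locus, df$length)
}

#' Binary design matrix of a reference collection
#'
#' Rows are universe alleles, columns are strains; entry (i, j) is 1 iff
#' strain j carries allele i. Column sums therefore equal per-strain
#' allele counts.
#'
#' @param reference A [StrainProfileSet-class].
#' @param universe An [AlleleUniverse-class] covering the reference.
#' @return Integer matrix with rownames `locus:length` and colnames the
#'   strain ids.
#' @export
encodeReference <- function(reference, universe) {
  ukeys <- .key(universe@entries)
  m <- matrix(0L, nrow = length(ukeys), ncol = nStrains(reference),
              dimnames = list(paste(universe@entries$locus,
                                    universe@entries$length, sep = ":"),
                              strainIds(reference)))
  df <- reference@calls
  idx <- match(.key(df), ukeys)
  if (anyNA(idx))
    stop("reference contains allele(s) outside the universe")
  m[cbind(idx, match(df$strain_id, strainIds(reference)))] <- 1L
  m
}

#' Union of strain profiles
#'
#' The meta-profile expected from pooling a set of strains: the set union
#' of their allele calls. Commutative, associative and idempotent.
#'
#' @param x A [StrainProfileSet-class], or a list of
#'   [MetaProfile-class]es / calls `data.frame`s.
#' @param ids When `x` is a collection, the strain ids to pool (default:
#'   all).
#' @param sampleId Sample id of the result.
#' @return A [MetaProfile-class].
#' @export
unionProfiles <- function(x, ids = NULL, sampleId = "union") {
  if (is(x, "StrainProfileSet")) {
    if (is.null(ids)) ids <- strainIds(x)
    if (length(ids) == 0) stop("cannot union an empty set of profiles")
    if (!all(ids %in% strainIds(x)))
      stop("unknown strain id(s): ",
           paste(setdiff(ids, strainIds(x)), collapse = ", "))
    df <- x@calls[x@calls$strain_id %in% ids, c("locus", "length")]
  } else if (is.list(x)) {
    if (length(x) == 0) stop("cannot union an empty set of profiles")
    df <- do.call(rbind, lapply(x, function(p) {
      if (is(p, "MetaProfile")) p@calls else as.data.frame(p)
    }))
  } else stop("unsupported input")
  metaProfile(alleleCalls(df$locus, df$length), sampleId)
}

#' Symmetric difference between two profiles
#'
#' @param a,b [MetaProfile-class]es or calls `data.frame`s.
#' @return A list with `n_diff` (size of the symmetric difference of the
#'   allele sets), `n_a` and `n_b` (profile sizes).
#' @export
profileDifference <- function(a, b) {
  ka <- .key(if (is(a, "MetaProfile")) a@calls else as.data.frame(a))
  kb <- .key(if (is(b, "MetaProfile")) b@calls else as.data.frame(b))
  list(n_diff = length(setdiff(ka, kb)) + length(setdiff(kb, ka)),
       n_a = length(ka), n_b = length(kb))
}
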