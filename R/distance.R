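#' Per-strain allele frequencies at a locus
#'
#' A single strain's "allele frequencies" at a locus are taken uniform
#' over its scored alleles: 1 for a homozygous/haploid call, 0.5 each for
#' a heterozygous pair. This convention fixes the scale of the chord
#' distance computed on strain genotypes.
#'
#' @param profile A [MetaProfile-class] or calls `data.frame`.
#' @param locus Locus name.
#' @return Named numeric vector (names = fragment lengths) summing to 1,
#'   or an empty vector when the locus is untyped.
#' @export
locusFrequencies <- function(profile, locus) {
  df <- if (is(profile, "MetaProfile")) profile@calls else profile
  lens <- sort(df$length[df$locus == locus])
  if (length(lens) == 0) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(rep(1 / length(lens), length(lens)),
                  as.character(lens))
}

# upper bound of the per-locus (and hence averaged) chord distance
.chordMax <- function() 2 * sqrt(2) / pi

#' Cavalli-Sforza chord distance between two strain profiles
#'
#' Per locus typed in both strains,
#' `d_l = (2/pi) * sqrt(2 * (1 - sum_a sqrt(f_p(a) * f_q(a))))`
#' with uniform per-strain allele frequencies (see
#' [locusFrequencies()]); the distance is the mean of `d_l` over shared
#' typed loci. Loci untyped in either strain are dropped pairwise.
#'
#' @param p,q [MetaProfile-class]es or calls `data.frame`s.
#' @return Distance in `[0, 2*sqrt(2)/pi]` (about 0.9003, attained when
#'   the profiles share no allele at any locus).
#' @export
#' @examples
#' a <- alleleCalls("C3", 100)
#' b <- alleleCalls(c("C3", "C3"), c(100, 103))
#' chordDistance(a, b)  # (2/pi) * sqrt(2 * (1 - sqrt(0.5))) ~ 0.4872
chordDistance <- function(p, q) {
  dp <- if (is(p, "MetaProfile")) p@calls else p
  dq <- if (is(q, "MetaProfile")) q@calls else q
  shared <- intersect(unique(dp$locus), unique(dq$locus))
  if (length(shared) == 0)
    stop("no locus typed in both profiles")
  d <- vapply(shared, function(l) {
    fp <- locusFrequencies(dp, l)
    fq <- locusFrequencies(dq, l)
    common <- intersect(names(fp), names(fq))
    s <- sum(sqrt(fp[common] * fq[common]))
    (2 / pi) * sqrt(2 * max(0, 1 - s))
  }, numeric(1))
  mean(d)
}

#' Chord distance matrix of a strain collection
#'
#' @param reference A [StrainProfileSet-class].
#' @return A `dist` object labeled with the strain ids.
#' @export
chordDistanceMatrix <- function(reference) {
  ids <- strainIds(reference)
  profs <- lapply(ids, function(id) profileCalls(reference, id))
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- m[j, i] <- chordDistance(profs[[i]], profs[[j]])
      }
    }
  }
  stats::as.dist(m)
}
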