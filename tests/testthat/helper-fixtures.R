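# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# Compact profile-set builder:
#   makeSet(s1 = list(C3 = 100, C4 = c(200, 203)), s2 = ...)
makeSet <- function(..., panel = NULL) {
  strains <- list(...)
  rows <- do.call(rbind, lapply(names(strains), function(id) {
    loci <- strains[[id]]
    do.call(rbind, lapply(names(loci), function(l) {
      data.frame(strain_id = id, locus = l, length = loci[[l]],
                 stringsAsFactors = FALSE)
    }))
  }))
  StrainProfileSet(rows, panel = panel, strainIds = names(strains))
}

# n mutually disjoint strains: strain i carries allele base + i at each
# locus (no allele shared between any two strains)
disjointSet <- function(n, loci = c("L1", "L2"), base = 100L) {
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(strain_id = sprintf("d%02d", i), locus = loci,
               length = base + 10L * seq_along(loci) + i,
               stringsAsFactors = FALSE)
  }))
  StrainProfileSet(rows)
}

# Independent oracle for the deconvolution call: exhaustive search over
# all non-empty strain subsets for the minimum |union(subset) (+) query|
# (symmetric difference). Used only to check the lasso's selection.
exhaustiveBestScore <- function(reference, query) {
  ids <- strainIds(reference)
  stopifnot(length(ids) <= 16)
  u <- buildUniverse(reference, query)
  X <- encodeReference(reference, u) > 0
  y <- encodeProfile(query, u) > 0
  best <- Inf
  for (mask in seq_len(2^length(ids) - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_along(ids) - 1)) > 0)
    un <- rowSums(X[, members, drop = FALSE]) > 0
    score <- sum(xor(un, y))
    if (score < best) best <- score
  }
  best
}

# score of a called set under the same metric
calledScore <- function(reference, called, query) {
  if (length(called) == 0) return(nrow(profileCalls(query)))
  profileDifference(unionProfiles(reference, called), query)$n_diff
}
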