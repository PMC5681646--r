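#' Prune a reference collection for redundancy
#'
#' A reference is usable for deconvolution only if each of its strains
#' self-identifies uniquely. Collections typically contain exact clones
#' and haploid strains whose alleles are subsets of a diploid's, which the
#' model can substitute for one another. This recursive procedure
#' deconvolves every strain's own profile against the current collection;
#' whenever the call is not uniquely the strain itself, a single
#' representative is retained and the redundant strains removed. Two
#' redundancy signatures occur: (i) more than one strain called — the
#' representative is the query strain itself if called, otherwise the
#' called strain with the largest coefficient (ties by input order), and
#' the other called strains are removed; (ii) the call is a single strain
#' other than the query — the solver has collapsed an exact (or
#' dominated) profile onto another column, so the query strain is removed
#' with that strain as representative. Passes repeat, each re-evaluating
#' every surviving strain against the shrunken collection, until a full
#' pass removes nothing.
#'
#' @param reference A [StrainProfileSet-class].
#' @param config A [deconvolutionConfig()]; the seed makes the procedure
#'   deterministic.
#' @return A list with `pruned` (the reduced [StrainProfileSet-class])
#'   and `report` (a [PruneReport-class]).
#' @export
pruneReference <- function(reference, config = deconvolutionConfig()) {
  config <- .asDeconvConfig(config)
  if (!is(reference, "StrainProfileSet") || nStrains(reference) == 0)
    stop("reference must be a non-empty StrainProfileSet")
  current <- strainIds(reference)
  removed <- data.frame(removed_id = character(),
                        representative_id = character(),
                        round = integer(), stringsAsFactors = FALSE)
  round <- 0L
  repeat {
    round <- round + 1L
    if (round > 100L)
      stop("pruning failed to converge within 100 rounds")
    coll <- reference[current]
    callsets <- lapply(current, function(id) {
      res <- deconvolve(coll, metaProfile(profileCalls(coll, id), id),
                        config)
      list(called = selectedStrains(res),
           coefs = strainCoefficients(res))
    })
    names(callsets) <- current
    gone <- character(0)
    for (id in current) {
      if (id %in% gone) next
      called <- setdiff(callsets[[id]]$called, gone)
      if (length(called) == 0) next
      if (identical(called, id)) next
      if (length(called) > 1) {
        if (id %in% called) {
          rep_id <- id
        } else {
          coefs <- callsets[[id]]$coefs[called]
          rep_id <- called[order(-coefs, match(called, current))][1]
        }
        drop <- setdiff(called, rep_id)
      } else {
        # single call that is not the query: the query profile is fully
        # explained by (collapsed onto) another strain
        rep_id <- called
        drop <- id
      }
      gone <- c(gone, drop)
      removed <- rbind(removed,
                       data.frame(removed_id = drop,
                                  representative_id = rep_id,
                                  round = round,
                                  stringsAsFactors = FALSE))
    }
    if (length(gone) == 0) break
    current <- setdiff(current, gone)
  }
  list(pruned = reference[current],
       report = new("PruneReport", kept = current, removed = removed,
                    nRounds = round))
}
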