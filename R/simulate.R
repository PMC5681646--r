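#' Simulation configuration
#'
#' Parameters of the synthetic strain-collection and pooled-sample
#' generator. Defaults emulate a typing study of a few hundred
#' haploid/diploid yeast strains at a 12-locus SSR panel: alleles sit on a
#' trinucleotide-repeat ladder per locus, strains are heterozygous at
#' roughly half their loci, and an optional clonal mode derives
#' near-identical strains from common founders by stepwise single-repeat
#' mutation.
#'
#' @param n_strains Number of strains to simulate (default 292, the size
#'   of a realistic unpruned reference collection).
#' @param loci Locus names (default the 12-locus panel of [ssrPanel()]).
#' @param alleles_per_locus Distinct alleles on each locus ladder
#'   (default 8).
#' @param repeat_unit Base-pair step between adjacent ladder alleles
#'   (default 3).
#' @param base_length Shortest allele length per locus, bp (default 100).
#' @param het_prob Probability a strain is heterozygous (two alleles) at
#'   a locus (default 0.5).
#' @param n_clusters Number of clonal founders. The default (`NULL`) uses
#'   half the number of strains, i.e. clone groups of two on average:
#'   strain collections built from environmental isolates routinely
#'   contain groups of near-identical strains expanded clonally in one
#'   source, and an unstructured collection would make pooled
#'   identification unrealistically easy. Set 0 to draw every strain
#'   independently.
#' @param within_cluster_mut_prob Per-locus probability that a clone
#'   steps one repeat unit away from its founder (default 0.05).
#' @param dropout_by_locus Named numeric vector of per-allele dropout
#'   probabilities in pooled amplification (default: none). See
#'   [dropoutPresets()] for values mimicking the error-prone loci C6 and
#'   C8.
#' @param stutter_prob Probability that an observed pool allele gains a
#'   spurious companion one repeat unit shorter (default 0).
#' @param seed Master RNG seed.
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(n_strains = 292L,
                             loci = ssrPanel(),
                             alleles_per_locus = 8L,
                             repeat_unit = 3L,
                             base_length = 100L,
                             het_prob = 0.5,
                             n_clusters = NULL,
                             within_cluster_mut_prob = 0.05,
                             dropout_by_locus = NULL,
                             stutter_prob = 0,
                             seed = 1L) {
  if (is.null(n_clusters)) n_clusters <- n_strains %/% 2L
  stopifnot(n_strains >= 1, alleles_per_locus >= 2, repeat_unit >= 1,
            base_length >= 1, het_prob >= 0, het_prob <= 1,
            n_clusters >= 0, n_clusters <= n_strains,
            within_cluster_mut_prob >= 0,
            within_cluster_mut_prob <= 1, stutter_prob >= 0,
            stutter_prob <= 1, length(loci) >= 1)
  if (!is.null(dropout_by_locus)) {
    stopifnot(is.numeric(dropout_by_locus),
              !is.null(names(dropout_by_locus)),
              all(dropout_by_locus >= 0), all(dropout_by_locus <= 1))
    bad <- setdiff(names(dropout_by_locus), loci)
    if (length(bad) > 0)
      stop("dropout given for unknown locus/loci: ",
           paste(bad, collapse = ", "))
  }
  structure(list(n_strains = as.integer(n_strains),
                 loci = as.character(loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 repeat_unit = as.integer(repeat_unit),
                 base_length = as.integer(base_length),
                 het_prob = het_prob,
                 n_clusters = as.integer(n_clusters),
                 within_cluster_mut_prob = within_cluster_mut_prob,
                 dropout_by_locus = dropout_by_locus,
                 stutter_prob = stutter_prob,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Dropout presets for error-prone loci
#'
#' Per-allele dropout probabilities of the order observed for the two
#' worst-performing panel loci in pooled amplifications.
#'
#' @return Named numeric vector usable as `dropout_by_locus`.
#' @export
dropoutPresets <- function() c(C6 = 0.09, C8 = 0.046)

.asSimConfig <- function(config) {
  if (is.null(config)) return(simulationConfig())
  if (inherits(config, "SimulationConfig")) return(config)
  do.call(simulationConfig, config)
}

.ladder <- function(config) {
  config$base_length +
    config$repeat_unit * (seq_len(config$alleles_per_locus) - 1L)
}

.drawLocusGenotype <- function(ladder, het_prob) {
  if (stats::runif(1) < het_prob) sample(ladder, 2L) else sample(ladder, 1L)
}

#' Simulate a reference strain collection
#'
#' Each strain draws one or two ladder alleles per locus (per `het_prob`).
#' With `n_clusters > 0`, founders are drawn first and members derive from
#' them by, per locus with probability `within_cluster_mut_prob`, stepping
#' every allele one repeat unit up or down (clamped to the ladder),
#' producing the near-identical clone groups typical of strains expanded
#' clonally in one source.
#'
#' @param config A [simulationConfig()].
#' @return A [StrainProfileSet-class] with ids `S001`, `S002`, ...
#' @export
simulateReference <- function(config = simulationConfig()) {
  config <- .asSimConfig(config)
  if (config$alleles_per_locus < 2 && config$het_prob > 0)
    stop("heterozygous calls need at least 2 alleles per locus")
  ladder <- .ladder(config)
  ids <- sprintf("S%03d", seq_len(config$n_strains))
  withSeed(config$seed, {
    if (config$n_clusters == 0) {
      genos <- lapply(ids, function(id) {
        lapply(config$loci,
               function(l) .drawLocusGenotype(ladder, config$het_prob))
      })
    } else {
      founders <- lapply(seq_len(config$n_clusters), function(i) {
        lapply(config$loci,
               function(l) .drawLocusGenotype(ladder, config$het_prob))
      })
      assign_to <- rep_len(seq_len(config$n_clusters), config$n_strains)
      genos <- lapply(seq_len(config$n_strains), function(i) {
        g <- founders[[assign_to[i]]]
        lapply(g, function(alleles) {
          if (stats::runif(1) < config$within_cluster_mut_prob) {
            step <- sample(c(-1L, 1L), 1) * config$repeat_unit
            alleles <- unique(pmin(max(ladder),
                                   pmax(min(ladder), alleles + step)))
          }
          alleles
        })
      })
    }
    calls <- do.call(rbind, lapply(seq_along(ids), function(i) {
      do.call(rbind, lapply(seq_along(config$loci), function(j) {
        data.frame(strain_id = ids[i], locus = config$loci[j],
                   length = genos[[i]][[j]], stringsAsFactors = FALSE)
      }))
    }))
    StrainProfileSet(calls, panel = config$loci, strainIds = ids)
  })
}

#' Simulate one pooled meta-profile
#'
#' Samples `k` parental strains without replacement; the observed profile
#' equals the expected union (apply [applyAmplificationNoise()] for a
#' corrupted pool).
#'
#' @param collection A [StrainProfileSet-class].
#' @param k Pool size, `2 <= k <= nStrains(collection)`.
#' @param seed RNG seed.
#' @param poolId Pool identifier.
#' @return A [PoolDesign-class].
#' @export
simulatePool <- function(collection, k, seed = 1L, poolId = "pool") {
  if (k < 2 || k > nStrains(collection))
    stop("pool size k must be between 2 and the collection size")
  parents <- withSeed(seed, sample(strainIds(collection), k))
  poolDesign(parents, collection, poolId = poolId)
}

#' Corrupt a pool's observed profile with amplification noise
#'
#' Each observed allele is independently lost with its locus's dropout
#' probability; with probability `stutter_prob` an observed allele gains
#' a spurious companion one repeat unit shorter (the stutter band). The
#' expected profile is left untouched.
#'
#' @param pool A [PoolDesign-class].
#' @param config A [simulationConfig()] providing `dropout_by_locus`,
#'   `stutter_prob` and `repeat_unit`.
#' @param seed RNG seed.
#' @return A [PoolDesign-class] with corrupted `observed`.
#' @export
applyAmplificationNoise <- function(pool, config = simulationConfig(),
                                    seed = 1L) {
  config <- .asSimConfig(config)
  obs <- pool@observed@calls
  if (nrow(obs) == 0) return(pool)
  drop_p <- rep(0, nrow(obs))
  if (!is.null(config$dropout_by_locus)) {
    hit <- match(obs$locus, names(config$dropout_by_locus))
    drop_p[!is.na(hit)] <- config$dropout_by_locus[hit[!is.na(hit)]]
  }
  withSeed(seed, {
    keep <- stats::runif(nrow(obs)) >= drop_p
    stutter <- if (config$stutter_prob > 0) {
      src <- obs[stats::runif(nrow(obs)) < config$stutter_prob, ,
                 drop = FALSE]
      src$length <- src$length - config$repeat_unit
      src[src$length > 0, , drop = FALSE]
    } else obs[0, , drop = FALSE]
    newObs <- rbind(obs[keep, , drop = FALSE], stutter)
    observed <- metaProfile(
      if (nrow(newObs) > 0) alleleCalls(newObs$locus, newObs$length)
      else .emptyCalls(),
      sampleId(pool@observed))
    new("PoolDesign", poolId = pool@poolId,
        parentalIds = pool@parentalIds,
        expected = pool@expected, observed = observed)
  })
}

#' Simulate a full pooling experiment
#'
#' Generates `n_reps` pools for each pool size in `k_values`, optionally
#' restricting all profiles to a locus subset before pooling (to compare
#' a full against a reduced panel). Per-pool seeds are derived from the
#' master seed by a counter, so any single pool can be regenerated in
#' isolation.
#'
#' @param collection A [StrainProfileSet-class].
#' @param k_values Integer vector of pool sizes (default `2:6`).
#' @param n_reps Pools per size (default 1000).
#' @param loci_subset Optional locus names to restrict to.
#' @param config A [simulationConfig()]; supplies the master seed and the
#'   noise model applied to every pool.
#' @return List of [PoolDesign-class] objects with ids like `k2_0001`.
#' @export
simulateExperiment <- function(collection, k_values = 2:6,
                               n_reps = 1000L, loci_subset = NULL,
                               config = simulationConfig()) {
  config <- .asSimConfig(config)
  stopifnot(all(k_values >= 2))
  if (!is.null(loci_subset))
    collection <- restrictLoci(collection, loci_subset)
  counter <- 0L
  pools <- list()
  noisy <- !is.null(config$dropout_by_locus) || config$stutter_prob > 0
  for (k in k_values) {
    for (r in seq_len(n_reps)) {
      counter <- counter + 1L
      s <- .deriveSeed(config$seed, counter)
      pool <- simulatePool(collection, k, seed = s,
                           poolId = sprintf("k%d_%04d", k, r))
      if (noisy)
        pool <- applyAmplificationNoise(pool, config,
                                        seed = .deriveSeed(s, 1L))
      pools[[counter]] <- pool
    }
  }
  pools
}
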