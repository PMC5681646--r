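#' Run a pooled-deconvolution benchmark
#'
#' Deconvolves every pool's observed profile against the reference and
#' aggregates recovery statistics by pool size: the fraction of pools in
#' which all parental strains were identified, the fraction with at least
#' one false positive, mean true-positive rate, mean false-positive
#' count and mean GLM error.
#'
#' @param reference A [StrainProfileSet-class]; must contain every
#'   parental strain.
#' @param pools List of [PoolDesign-class] objects (e.g. from
#'   [simulateExperiment()]).
#' @param config A [deconvolutionConfig()].
#' @param lociSet Label recorded with the results (e.g. `"all.loci"`);
#'   restrict `reference` and pools with [restrictLoci()] beforehand to
#'   benchmark a reduced panel.
#' @return A list of class `BenchmarkSummary` with `summary` (one row per
#'   pool size) and `records` (one row per pool).
#' @export
runBenchmark <- function(reference, pools,
                         config = deconvolutionConfig(),
                         lociSet = "all.loci") {
  config <- .asDeconvConfig(config)
  if (length(pools) == 0) stop("no pools to benchmark")
  missing <- setdiff(unique(unlist(lapply(pools, parentalIds))),
                     strainIds(reference))
  if (length(missing) > 0)
    stop("parental strain(s) absent from the reference: ",
         paste(missing, collapse = ", "))
  t0 <- proc.time()[["elapsed"]]
  n_failed <- 0L
  records <- do.call(rbind, lapply(pools, function(pool) {
    k <- length(parentalIds(pool))
    res <- tryCatch(deconvolve(reference, pool@observed, config),
                    error = function(e) NULL)
    if (is.null(res)) {
      n_failed <<- n_failed + 1L
      return(data.frame(pool_id = pool@poolId, k = k,
                        loci_set = lociSet, tpr = NA_real_,
                        n_false_positives = NA_integer_,
                        all_parental = NA, any_fp = NA,
                        glm_error = NA_real_, lambda = NA_real_,
                        n_selected = NA_integer_,
                        stringsAsFactors = FALSE))
    }
    rs <- recoveryStats(selectedStrains(res), pool)
    data.frame(pool_id = pool@poolId, k = k, loci_set = lociSet,
               tpr = rs$tpr, n_false_positives = rs$n_false_positives,
               all_parental = rs$tpr == 100,
               any_fp = rs$n_false_positives > 0,
               glm_error = glmError(res), lambda = res@lambda,
               n_selected = length(selectedStrains(res)),
               stringsAsFactors = FALSE)
  }))
  ok <- records[!is.na(records$tpr), , drop = FALSE]
  summary <- do.call(rbind, lapply(split(ok, ok$k), function(g) {
    data.frame(k = g$k[1], loci_set = lociSet,
               frac_all_parental = mean(g$all_parental),
               frac_any_fp = mean(g$any_fp),
               mean_tpr = mean(g$tpr),
               mean_fp = mean(g$n_false_positives),
               mean_glm_error = mean(g$glm_error),
               n_reps = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(summary = summary, records = records,
                 n_failed = n_failed,
                 elapsed_sec = proc.time()[["elapsed"]] - t0),
            class = "BenchmarkSummary")
}

#' Combine benchmark summaries
#'
#' Stacks summaries from different locus sets into one.
#'
#' @param ... `BenchmarkSummary` objects.
#' @return A `BenchmarkSummary`.
#' @export
combineBenchmarks <- function(...) {
  parts <- list(...)
  structure(list(
    summary = do.call(rbind, lapply(parts, `[[`, "summary")),
    records = do.call(rbind, lapply(parts, `[[`, "records")),
    n_failed = sum(vapply(parts, `[[`, 1L, "n_failed")),
    elapsed_sec = sum(vapply(parts, `[[`, 1, "elapsed_sec"))),
    class = "BenchmarkSummary")
}

#' Write a benchmark report
#'
#' Writes `<prefix>_summary.tsv` (one row per pool size and locus set,
#' fractions with 3 decimals) and `<prefix>_records.json` (full per-pool
#' records). Output is byte-stable for identical inputs.
#'
#' @param bench A `BenchmarkSummary` from [runBenchmark()].
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
writeSummary <- function(bench, prefix) {
  s <- bench$summary
  fmt <- s
  for (col in c("frac_all_parental", "frac_any_fp"))
    fmt[[col]] <- sprintf("%.3f", s[[col]])
  for (col in c("mean_tpr", "mean_fp", "mean_glm_error"))
    fmt[[col]] <- sprintf("%.4f", s[[col]])
  tsv <- paste0(prefix, "_summary.tsv")
  jsn <- paste0(prefix, "_records.json")
  utils::write.table(fmt, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(summary = s, records = bench$records,
         n_failed = bench$n_failed),
    jsn, dataframe = "rows", digits = NA, pretty = TRUE)
  invisible(c(tsv, jsn))
}

#' Read a benchmark report back
#'
#' @param prefix Path prefix used in [writeSummary()].
#' @return A `BenchmarkSummary`-shaped list.
#' @export
readSummary <- function(prefix) {
  x <- jsonlite::read_json(paste0(prefix, "_records.json"),
                           simplifyVector = TRUE)
  structure(list(summary = x$summary, records = x$records,
                 n_failed = x$n_failed, elapsed_sec = NA_real_),
            class = "BenchmarkSummary")
}

#' @export
print.BenchmarkSummary <- function(x, ...) {
  cat("BenchmarkSummary over", nrow(x$records), "pools",
      if (x$n_failed > 0) paste0("(", x$n_failed, " failed)") else "",
      "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Load a configuration file
#'
#' Reads a YAML (or flat `key: value`) file and splits recognized keys
#' into a [deconvolutionConfig()] and a [simulationConfig()]; unlisted
#' keys keep their defaults, unknown keys are an error.
#'
#' @param path Config file path; `NULL` returns all defaults.
#' @return List with elements `deconvolution` and `simulation`.
#' @export
loadConfig <- function(path = NULL) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  dec_keys <- names(formals(deconvolutionConfig))
  sim_keys <- names(formals(simulationConfig))
  unknown <- setdiff(names(vals), c(dec_keys, sim_keys))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "))
  num_keys <- c("n_folds", "lambda_path_size", "lambda_min_ratio",
                "seed", "coef_epsilon", "max_iter", "tol", "n_strains",
                "alleles_per_locus", "repeat_unit", "base_length",
                "het_prob", "n_clusters", "within_cluster_mut_prob",
                "stutter_prob")
  for (key in intersect(names(vals), num_keys)) {
    if (!is.numeric(vals[[key]]))
      stop("configuration key '", key, "' must be numeric, got '",
           vals[[key]], "'")
  }
  if ("dropout_by_locus" %in% names(vals))
    vals$dropout_by_locus <- unlist(vals$dropout_by_locus)
  list(deconvolution = do.call(deconvolutionConfig,
                               vals[intersect(names(vals), dec_keys)]),
       simulation = do.call(simulationConfig,
                            vals[intersect(names(vals), sim_keys)]))
}
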