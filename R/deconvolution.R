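#' Deconvolution solver configuration
#'
#' Settings for the non-negative, intercept-free L1-penalized binomial GLM
#' that regresses a query meta-profile on the reference strains.
#'
#' @param n_folds Cross-validation folds over universe rows (alleles);
#'   default 10.
#' @param cv_metric Held-out loss minimized to pick the penalty: `"mse"`
#'   (squared error of predicted presence probabilities, default) or
#'   `"deviance"` (binomial deviance).
#' @param lambda_path_size Number of penalty values on the log-spaced path
#'   (default 100).
#' @param lambda_min_ratio Smallest-to-largest penalty ratio (default
#'   1e-4).
#' @param seed RNG seed controlling fold assignment; fixing it makes the
#'   whole fit deterministic.
#' @param coef_epsilon Coefficients above this are "non-zero", i.e. the
#'   strain is called present (default 1e-8).
#' @param standardize Standardize predictor columns inside the solver
#'   (default `TRUE`); coefficients are reported on the original 0/1
#'   scale either way.
#' @param max_iter,tol Solver iteration cap and convergence threshold.
#' @return A list of class `DeconvolutionConfig`.
#' @export
deconvolutionConfig <- function(n_folds = 10L,
                                cv_metric = c("mse", "deviance"),
                                lambda_path_size = 100L,
                                lambda_min_ratio = 1e-4,
                                seed = 1L,
                                coef_epsilon = 1e-8,
                                standardize = TRUE,
                                max_iter = 1e5,
                                tol = 1e-7) {
  cv_metric <- match.arg(cv_metric)
  stopifnot(n_folds >= 2, coef_epsilon > 0,
            lambda_min_ratio > 0, lambda_min_ratio < 1,
            lambda_path_size >= 2, tol > 0, max_iter >= 1)
  structure(list(n_folds = as.integer(n_folds), cv_metric = cv_metric,
                 lambda_path_size = as.integer(lambda_path_size),
                 lambda_min_ratio = lambda_min_ratio,
                 seed = as.integer(seed), coef_epsilon = coef_epsilon,
                 standardize = isTRUE(standardize),
                 max_iter = max_iter, tol = tol),
            class = "DeconvolutionConfig")
}

.asDeconvConfig <- function(config) {
  if (is.null(config)) return(deconvolutionConfig())
  if (inherits(config, "DeconvolutionConfig")) return(config)
  do.call(deconvolutionConfig, config)
}

.checkBinaryResponse <- function(y) {
  if (!is.numeric(y) || anyNA(y) || !all(y %in% c(0, 1)))
    stop("response vector must be binary (0/1)")
}

# glmnet's binomial family refuses a class with < 2 observations. Rows of
# zeros in X carry no information about the (intercept-free) coefficients:
# their linear predictor is 0 whatever beta is, so appending them leaves
# the optimum unchanged while giving the solver the second class it
# requires.
.padDegenerate <- function(X, y) {
  pad_rows <- max(0L, 2L - sum(y == 0))
  if (pad_rows > 0) {
    X <- rbind(X, matrix(0L, pad_rows, ncol(X)))
    y <- c(y, rep(0, pad_rows))
  }
  pad_col <- ncol(X) < 2          # glmnet needs >= 2 predictors
  if (pad_col) X <- cbind(X, `..pad..` = 0L)
  list(X = X, y = y, pad_col = pad_col)
}

.glmnetArgs <- function(config) {
  list(family = "binomial", alpha = 1, intercept = FALSE,
       lower.limits = 0, standardize = config$standardize,
       nlambda = config$lambda_path_size,
       lambda.min.ratio = config$lambda_min_ratio,
       thresh = config$tol, maxit = config$max_iter)
}

#' Fit the penalized regularization path
#'
#' Minimizes, for each penalty lambda on a log-spaced path, the mean
#' binomial negative log-likelihood of the query presence vector `y` given
#' linear predictor `X beta` (no intercept), plus `lambda * sum(beta)`,
#' subject to `beta >= 0`. The path starts at the smallest lambda at which
#' all coefficients vanish.
#'
#' @param X Binary design matrix from [encodeReference()] (rows = universe
#'   alleles, columns = reference strains).
#' @param y 0/1 response from [encodeProfile()] applied to the query.
#' @param config A [deconvolutionConfig()].
#' @return A list of class `PenalizedPath` with elements `lambda`
#'   (decreasing) and `beta` (strains x lambda coefficient matrix).
#' @export
fitPenalizedPath <- function(X, y, config = deconvolutionConfig()) {
  config <- .asDeconvConfig(config)
  .checkBinaryResponse(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (ncol(X) < 1) stop("X must have at least one column")
  if (all(y == 0)) {
    warning("query shares no allele with the universe rows; ",
            "no strain can be called")
    lam <- rev(seq_len(config$lambda_path_size))
    beta <- matrix(0, ncol(X), length(lam),
                   dimnames = list(colnames(X), NULL))
    return(structure(list(lambda = lam, beta = beta),
                     class = "PenalizedPath"))
  }
  p <- .padDegenerate(X, y)
  fit <- do.call(glmnet::glmnet, c(list(x = p$X, y = p$y),
                                   .glmnetArgs(config)))
  beta <- as.matrix(fit$beta)
  if (p$pad_col) beta <- beta[-nrow(beta), , drop = FALSE]
  structure(list(lambda = fit$lambda, beta = beta),
            class = "PenalizedPath")
}

.foldid <- function(n, n_folds, seed) {
  withSeed(seed, sample(rep_len(seq_len(n_folds), n)))
}

#' Choose the penalty by cross-validation
#'
#' Universe rows (alleles) are assigned to folds by a seeded RNG; the
#' penalty minimizing the mean held-out loss (`cv_metric`) is returned.
#' When the response is too unbalanced for fold-wise refits (e.g. almost
#' every universe allele present in the query), the penalty minimizing the
#' full-path deviance is returned with a warning.
#'
#' @inheritParams fitPenalizedPath
#' @return The chosen lambda (numeric scalar).
#' @export
selectLambdaCV <- function(X, y, config = deconvolutionConfig()) {
  .fitCV(X, y, .asDeconvConfig(config))$lambda
}

.fitCV <- function(X, y, config) {
  .checkBinaryResponse(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  p <- .padDegenerate(X, y)
  n <- length(p$y)
  n_folds <- min(config$n_folds, n)
  args <- .glmnetArgs(config)
  cvfit <- NULL
  if (n_folds >= 3 && min(table(p$y)) >= 2) {
    foldid <- .foldid(n, n_folds, config$seed)
    cvfit <- tryCatch(
      suppressWarnings(do.call(glmnet::cv.glmnet,
        c(list(x = p$X, y = p$y, foldid = foldid,
               type.measure = config$cv_metric), args))),
      error = function(e) NULL)
  }
  if (!is.null(cvfit)) {
    lambda <- cvfit$lambda.min
    beta <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[-1, 1]
  } else {
    warning("cross-validation infeasible for this response; ",
            "falling back to full-path deviance minimization")
    fit <- suppressWarnings(do.call(glmnet::glmnet,
                                    c(list(x = p$X, y = p$y), args)))
    dev <- stats::deviance(fit)
    i <- which.min(dev)
    lambda <- fit$lambda[i]
    beta <- as.matrix(fit$beta)[, i]
  }
  if (p$pad_col) beta <- beta[-length(beta)]
  names(beta) <- colnames(X)
  list(lambda = lambda, beta = pmax(beta, 0))
}

#' @rdname glmError
#' @export
setMethod("glmError", signature("MetaProfile", "MetaProfile"),
  function(predicted, query) .glmErrorCalls(predicted@calls, query@calls))

#' @rdname glmError
#' @export
setMethod("glmError", signature("data.frame", "data.frame"),
  function(predicted, query) .glmErrorCalls(predicted, query))

#' @rdname glmError
#' @export
setMethod("glmError", signature("DeconvolutionResult", "missing"),
  function(predicted, query) predicted@glmError)

.glmErrorCalls <- function(predicted, query) {
  d <- profileDifference(predicted, query)
  if (d$n_a == 0) {
    return(structure(100, degenerate = TRUE))
  }
  100 * d$n_diff / d$n_a
}

#' Deconvolve a query meta-profile against a reference collection
#'
#' The central operation: which combination of reference strains best
#' explains the alleles observed in a mixed sample? The query is encoded
#' over the union allele universe and regressed on the reference
#' presence/absence profiles with a non-negative, intercept-free lasso
#' binomial GLM; strains with non-zero coefficients at the
#' cross-validation-selected penalty are called present.
#'
#' @param reference A [StrainProfileSet-class].
#' @param query A [MetaProfile-class].
#' @param config A [deconvolutionConfig()].
#' @return A [DeconvolutionResult-class]. If no strain is selected the
#'   predicted profile is empty and the GLM error is reported as 100 with
#'   `degenerate = TRUE`.
#' @export
#' @examples
#' ref <- StrainProfileSet(data.frame(
#'   strain_id = rep(c("s1", "s2", "s3"), each = 2),
#'   locus = rep(c("C3", "C4"), 3),
#'   length = c(100, 200, 103, 203, 106, 206)))
#' q <- unionProfiles(ref, c("s1", "s2"), sampleId = "mix")
#' deconvolve(ref, q, deconvolutionConfig(seed = 7))
deconvolve <- function(reference, query, config = deconvolutionConfig()) {
  config <- .asDeconvConfig(config)
  if (!is(reference, "StrainProfileSet") || nStrains(reference) == 0)
    stop("reference must be a non-empty StrainProfileSet")
  if (!is(query, "MetaProfile") || nrow(query@calls) == 0)
    stop("query must be a non-empty MetaProfile")
  universe <- buildUniverse(reference, query)
  X <- encodeReference(reference, universe)
  y <- encodeProfile(query, universe)
  fit <- .fitCV(X, y, config)
  selected <- names(fit$beta)[fit$beta > config$coef_epsilon]
  if (length(selected) > 0) {
    predicted <- unionProfiles(reference, selected,
                               sampleId = paste0("predicted:",
                                                 sampleId(query)))
  } else {
    predicted <- metaProfile(.emptyCalls(),
                             paste0("predicted:", sampleId(query)))
  }
  err <- glmError(predicted, query)
  d <- profileDifference(predicted, query)
  new("DeconvolutionResult",
      selected = selected,
      coefficients = fit$beta,
      lambda = fit$lambda,
      predicted = predicted,
      glmError = as.numeric(err),
      nPredictedAlleles = as.integer(d$n_a),
      nDiffAlleles = as.integer(d$n_diff),
      degenerate = isTRUE(attr(err, "degenerate")))
}
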