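# Imputation, transformation and scaling of the feature table into the
# matrix the multivariate model consumes. The fitted parameters (kept
# metabolites, imputation values, centers, scale factors) are returned so
# new samples can be projected through the identical transformation.

#' Preprocessing configuration
#'
#' The default chain -- half-minimum imputation, natural-log transform,
#' autoscaling -- is standard untargeted-metabolomics practice. Filtering
#' by \code{minPresence} precedes imputation; a metabolite is kept only if
#' observed in at least that fraction of samples.
#'
#' @param impute \code{"half_min"} (each metabolite's missing cells replaced
#'   by half its observed minimum) or \code{"none"}.
#' @param transform \code{"log"} (natural log, after imputation) or
#'   \code{"none"}.
#' @param scale \code{"autoscale"} (column mean 0, sample sd 1),
#'   \code{"pareto"} (centered column divided by the square root of its sd)
#'   or \code{"none"}.
#' @param minPresence minimum observed fraction per metabolite, in [0, 1].
#' @return list of class \code{"PreprocessConfig"}.
#' @export
preprocessConfig <- function(impute = c("half_min", "none"),
                             transform = c("log", "none"),
                             scale = c("autoscale", "pareto", "none"),
                             minPresence = 0.5) {
  impute <- match.arg(impute)
  transform <- match.arg(transform)
  scale <- match.arg(scale)
  if (!is.numeric(minPresence) || minPresence < 0 || minPresence > 1)
    validationError("minPresence must be in [0, 1]")
  structure(list(impute = impute, transform = transform, scale = scale,
                 minPresence = minPresence),
            class = "PreprocessConfig")
}

#' Preprocess a feature table for multivariate modelling
#'
#' Applies the presence filter, imputation, transformation and scaling of
#' \code{cfg} and returns both the model-ready matrix and the matrix on
#' the analysis scale: presence-filtered and transformed but neither
#' imputed nor scaled. Univariate tests and group means use the analysis
#' matrix (missing cells stay missing there, so fabricated imputation
#' values cannot distort test statistics); imputation feeds only the
#' multivariate model, which cannot tolerate missing entries.
#'
#' @param table a \linkS4class{FeatureTable}.
#' @param cfg a \code{\link{preprocessConfig}}.
#' @return list with \code{x} (samples x kept metabolites, fully
#'   processed), \code{analysis} (samples x kept metabolites, transformed
#'   only, missing cells retained), \code{kept} (metabolite ids retained)
#'   and \code{params} (everything \code{\link{applyPreprocess}} needs).
#' @examples
#' cohort <- generateCohort(cohortSpec(nMetabolites = 30, nEfficacy = 3,
#'                                     nBias = 3, seed = 2))
#' pp <- preprocessFeatures(cohort$table, preprocessConfig())
#' round(colMeans(pp$x)[1:3], 12)  # autoscaled: zero means
#' @export
preprocessFeatures <- function(table, cfg = preprocessConfig()) {
  stopifnot(methods::is(table, "FeatureTable"))
  if (!inherits(cfg, "PreprocessConfig")) cfg <- do.call(preprocessConfig, cfg)
  x <- t(abundances(table))            # samples x metabolites
  if (nrow(x) == 0L || ncol(x) == 0L)
    validationError("feature table is empty")

  presence <- colMeans(!is.na(x))
  kept <- colnames(x)[presence >= cfg$minPresence & presence > 0]
  if (!length(kept))
    validationError("all metabolites dropped by the presence filter (minPresence = %g)",
                    cfg$minPresence)
  x <- x[, kept, drop = FALSE]

  raw <- x
  halfMin <- rep(NA_real_, length(kept))
  names(halfMin) <- kept
  if (cfg$impute == "half_min") {
    halfMin <- apply(x, 2L, function(v) min(v, na.rm = TRUE) / 2)
    for (j in seq_along(kept)) {
      miss <- is.na(x[, j])
      if (any(miss)) x[miss, j] <- halfMin[j]
    }
  }
  if (cfg$transform == "log") {
    nonpos <- colnames(x)[apply(x, 2L, function(v) any(v <= 0, na.rm = TRUE))]
    if (length(nonpos))
      validationError("log transform requires positive values; offending metabolite(s): %s",
                      paste(utils::head(nonpos, 5L), collapse = ", "))
    x <- log(x)
    analysis <- log(raw)
  } else {
    analysis <- raw
  }

  center <- rep(0, length(kept)); names(center) <- kept
  scaleFactor <- rep(1, length(kept)); names(scaleFactor) <- kept
  if (cfg$scale != "none") {
    center <- colMeans(x, na.rm = TRUE)
    sds <- colSds(x)
    zero <- kept[!is.na(sds) & sds == 0]
    if (length(zero))
      validationError("zero variance under %s scaling; offending metabolite(s): %s",
                      cfg$scale, paste(utils::head(zero, 5L), collapse = ", "))
    scaleFactor <- if (cfg$scale == "autoscale") sds else sqrt(sds)
    x <- sweep(sweep(x, 2L, center, "-"), 2L, scaleFactor, "/")
  }

  params <- list(cfg = cfg, kept = kept, halfMin = halfMin,
                 center = center, scaleFactor = scaleFactor)
  list(x = x, analysis = analysis, kept = kept, params = params)
}

#' Apply stored preprocessing parameters to new samples
#'
#' Projects a table through a previously fitted preprocessing chain:
#' training-set kept metabolites, training-set half-minimum values,
#' transformation and training-set centering/scaling. Applying the stored
#' parameters to the training table reproduces its processed matrix
#' exactly.
#'
#' @param params the \code{params} element returned by
#'   \code{\link{preprocessFeatures}}.
#' @param table a \linkS4class{FeatureTable} containing at least the kept
#'   metabolites.
#' @return matrix, samples x kept metabolites, on the model scale.
#' @export
applyPreprocess <- function(params, table) {
  stopifnot(methods::is(table, "FeatureTable"))
  x <- t(abundances(table))
  missingIds <- setdiff(params$kept, colnames(x))
  if (length(missingIds))
    validationError("table lacks metabolite(s) required by the stored parameters: %s",
                    paste(utils::head(missingIds, 5L), collapse = ", "))
  x <- x[, params$kept, drop = FALSE]
  if (params$cfg$impute == "half_min") {
    for (j in seq_along(params$kept)) {
      miss <- is.na(x[, j])
      if (any(miss)) x[miss, j] <- params$halfMin[j]
    }
  }
  if (params$cfg$transform == "log") x <- log(x)
  if (params$cfg$scale != "none")
    x <- sweep(sweep(x, 2L, params$center, "-"), 2L, params$scaleFactor, "/")
  x
}
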