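#' Age transform specification
#'
#' Chronological ages are mapped onto a "log-like" scale before penalized
#' regression, compressing the sparsely sampled old ages; fitted clocks are
#' reported in years after the inverse map.  Two strictly increasing,
#' invertible families are provided:
#' \describe{
#'   \item{\code{log1p}}{\eqn{f(x) = \log(x + c)} with offset \eqn{c > 0}
#'     (default 1, so \eqn{f(0) = 0}).}
#'   \item{\code{loglinear}}{logarithmic below an adult-age knot \eqn{k} and
#'     affine above it, \eqn{C^1}-matched at the knot:
#'     \eqn{f(x) = \log((x+c)/(k+c))} for \eqn{x \le k} and
#'     \eqn{f(x) = (x-k)/(k+c)} for \eqn{x > k}.  The knot may be a single
#'     value or supplied per species via \code{speciesKnots}.}
#' }
#'
#' @slot name transform family, \code{"log1p"} or \code{"loglinear"}.
#' @slot offset positive offset in years.
#' @slot knot adult-age knot in years (loglinear only).
#' @slot speciesKnots optional named numeric vector of per-species knots.
#' @aliases AgeTransform
#' @exportClass AgeTransform
setClass("AgeTransform",
  representation(name = "character", offset = "numeric", knot = "numeric",
                 speciesKnots = "numeric"),
  prototype(name = "log1p", offset = 1, knot = NA_real_,
            speciesKnots = setNames(numeric(0), character(0))))

setValidity("AgeTransform", function(object) {
  msg <- character(0)
  if (!object@name %in% c("log1p", "loglinear"))
    msg <- c(msg, sprintf("unknown transform name '%s'", object@name))
  if (length(object@offset) != 1L || !is.finite(object@offset) ||
      object@offset <= 0)
    msg <- c(msg, "offset must be a single positive number")
  if (object@name == "loglinear") {
    if (!is.finite(object@knot) || object@knot <= 0)
      msg <- c(msg, "loglinear transform requires a positive knot")
    if (length(object@speciesKnots) &&
        (is.null(names(object@speciesKnots)) ||
         any(object@speciesKnots <= 0)))
      msg <- c(msg, "speciesKnots must be a named vector of positive knots")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted epigenetic clock
#'
#' A sparse linear model on CpG beta values predicting transformed age.
#' Predicted ages in years are recovered through the inverse age transform.
#' Only nonzero coefficients are stored, on the original beta scale
#' (internal predictor standardization is undone by the fitting code).
#'
#' @slot intercept intercept on the transformed-age scale.
#' @slot weights named numeric vector of nonzero CpG coefficients.
#' @slot transform the [AgeTransform-class] used during fitting.
#' @slot trainingMeta list of training metadata: tissue and species filters,
#'   elastic-net mixing \code{alpha}, \code{nSamples}, seed, selected
#'   \code{lambda}, and per-CpG training means (\code{cpgMeans}) used to
#'   impute missing probes at prediction time.
#' @aliases ClockModel
#' @exportClass ClockModel
setClass("ClockModel",
  representation(intercept = "numeric", weights = "numeric",
                 transform = "AgeTransform", trainingMeta = "list"))

setValidity("ClockModel", function(object) {
  msg <- character(0)
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a single finite number")
  w <- object@weights
  if (length(w)) {
    if (is.null(names(w)) || anyDuplicated(names(w)))
      msg <- c(msg, "weights must be uniquely named by CpG id")
    if (any(w == 0)) msg <- c(msg, "weights must not contain explicit zeros")
  }
  if (length(msg)) msg else TRUE
})

#' Methylation experiment container
#'
#' A \linkS4class{SummarizedExperiment} holding a CpG-by-sample beta-value
#' matrix (assay \code{"beta"}, values in [0,1] or \code{NA}) together with
#' the per-sample panel in \code{colData} (\code{species}, \code{tissue},
#' \code{age_years}, \code{sex}, \code{age_known}) and CpG genomic positions
#' in \code{rowData} (\code{chromosome}, \code{position}, 1-based).
#'
#' @aliases MethylExperiment-class
#' @exportClass MethylExperiment
setClass("MethylExperiment", contains = "SummarizedExperiment")

setValidity("MethylExperiment", function(object) {
  msg <- character(0)
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    return("assay 'beta' is required")
  b <- SummarizedExperiment::assay(object, "beta")
  if (any(b < -1e-12 | b > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "beta values must lie in [0, 1]")
  cd <- SummarizedExperiment::colData(object)
  need <- c("species", "tissue", "age_years", "sex", "age_known")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, sprintf("colData misses column(s): %s",
                          paste(miss, collapse = ", ")))
  if ("tissue" %in% colnames(cd) && !all(cd$tissue %in% c("blood", "skin")))
    msg <- c(msg, "tissue must be 'blood' or 'skin'")
  if ("age_years" %in% colnames(cd) && any(cd$age_years < 0, na.rm = TRUE))
    msg <- c(msg, "age_years must be non-negative")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "CpG ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Cross-validation result
#'
#' Per-sample out-of-fold DNA-methylation age predictions plus the accuracy
#' summary the clock literature reports: for leave-one-out CV the Pearson
#' correlation between predicted and observed age and the median absolute
#' error in years; for leave-one-species-out CV the repeated-measures
#' correlation (species as the grouping factor) and the median across species
#' of per-species median absolute errors.
#'
#' @slot scheme \code{"loocv"} or \code{"losocv"}.
#' @slot predictions data.frame with columns sample_id, species, tissue,
#'   observed, predicted (years) and fold.
#' @slot summary named list of summary statistics.
#' @aliases CVResult
#' @exportClass CVResult
setClass("CVResult",
  representation(scheme = "character", predictions = "data.frame",
                 summary = "list"))

#' Simulation scenario for synthetic methylation panels
#'
#' Describes a multi-species, multi-tissue methylation study with planted
#' age- and sex-associated CpGs.  Defaults emulate a consortium-scale
#' cetacean dataset: 13 species sampled in blood and skin at about 42
#' samples per stratum (~1090 samples), per-species maximum lifespans up to
#' the 139-year bowhead bound, and an array-scale CpG universe.
#'
#' @slot maxLifespan named numeric vector of per-species maximum lifespans
#'   (years); its length defines the number of species.
#' @slot tissues tissue types sampled for every species.
#' @slot samplesPerStratum samples per species-tissue stratum.
#' @slot nCpgs,nAgeCpgs,nSexCpgs CpG universe size and planted counts.
#' @slot slopeMean,slopeSd distribution of planted age-slope magnitudes on
#'   the transformed-age scale.
#' @slot sexEffectRange range of planted female-effect magnitudes (beta units).
#' @slot noiseSd i.i.d. Gaussian measurement noise on the beta scale.
#' @slot speciesBaselineSd per-species baseline shift s.d. (beta units).
#' @slot sharedFraction fraction of planted age CpGs whose slope is shared
#'   across species (the remainder get independent per-species slopes).
#' @slot agePower ages are drawn as lifespan * U^agePower; 1 = uniform,
#'   larger values skew sampling toward young animals.
#' @slot transform [AgeTransform-class] defining the transformed-age scale
#'   on which age effects are linear.
#' @slot seed integer seed; generation is fully deterministic given it.
#' @aliases SimulationScenario
#' @exportClass SimulationScenario
setClass("SimulationScenario",
  representation(maxLifespan = "numeric", tissues = "character",
                 samplesPerStratum = "integer", nCpgs = "integer",
                 nAgeCpgs = "integer", nSexCpgs = "integer",
                 slopeMean = "numeric", slopeSd = "numeric",
                 sexEffectRange = "numeric", noiseSd = "numeric",
                 speciesBaselineSd = "numeric", sharedFraction = "numeric",
                 agePower = "numeric", transform = "AgeTransform",
                 seed = "integer"))

setValidity("SimulationScenario", function(object) {
  msg <- character(0)
  if (!length(object@maxLifespan) || any(object@maxLifespan <= 0))
    msg <- c(msg, "maxLifespan must be positive for every species")
  if (is.null(names(object@maxLifespan)))
    msg <- c(msg, "maxLifespan must be named by species")
  if (object@samplesPerStratum < 0) msg <- c(msg, "samplesPerStratum < 0")
  if (object@nCpgs < 0 || object@nAgeCpgs < 0 || object@nSexCpgs < 0)
    msg <- c(msg, "CpG counts must be >= 0")
  if (object@nAgeCpgs + object@nSexCpgs > object@nCpgs)
    msg <- c(msg, "nAgeCpgs + nSexCpgs must not exceed nCpgs")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@sharedFraction < 0 || object@sharedFraction > 1)
    msg <- c(msg, "sharedFraction must be in [0, 1]")
  if (object@agePower < 1) msg <- c(msg, "agePower must be >= 1")
  if (!length(object@seed) || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AgeTransform", function(object) {
  cat("AgeTransform:", object@name, "(offset", object@offset)
  if (object@name == "loglinear") cat(", knot", object@knot)
  cat(")\n")
  if (length(object@speciesKnots))
    cat("  per-species knots for", length(object@speciesKnots), "species\n")
})

setMethod("show", "ClockModel", function(object) {
  tm <- object@trainingMeta
  cat("ClockModel:", length(object@weights), "CpGs,",
      "intercept", signif(object@intercept, 4), "\n")
  cat("  transform:", object@transform@name,
      "| alpha:", tm$alpha %||% NA, "| n:", tm$nSamples %||% NA,
      "| tissue:", tm$tissue %||% "all", "\n")
})

setMethod("show", "CVResult", function(object) {
  s <- object@summary
  cat(sprintf("CVResult (%s): %d samples\n", object@scheme,
              nrow(object@predictions)))
  if (object@scheme == "loocv")
    cat(sprintf("  Pearson r = %.3f, median MAE = %.3f years\n",
                s$r, s$medianMAE))
  else
    cat(sprintf("  repeated-measures r = %.3f, median of per-species median MAE = %.3f years\n",
                s$rmR, s$medianMAE))
})

setMethod("show", "SimulationScenario", function(object) {
  cat(sprintf("SimulationScenario: %d species x %d tissue(s) x %d samples, %d CpGs\n",
              length(object@maxLifespan), length(object@tissues),
              object@samplesPerStratum, object@nCpgs))
  cat(sprintf("  planted: %d age CpGs, %d sex CpGs | noise sd %.3g | seed %d\n",
              object@nAgeCpgs, object@nSexCpgs, object@noiseSd, object@seed))
})
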