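#' @importFrom glmnet cv.glmnet glmnet
NULL

# Resolve (betas, panel) from either a MethylExperiment or an explicit
# samples x CpGs matrix + panel.  Returns samples x CpGs.
resolveInputs <- function(x, panel = NULL) {
  if (is(x, "MethylExperiment"))
    list(betas = t(betaValues(x)), panel = samplePanel(x))
  else {
    if (is.null(panel)) stopf("a sample panel is required with a matrix input")
    list(betas = x[panel$sample_id, , drop = FALSE],
         panel = validateSamplePanel(panel))
  }
}

# Seeded internal CV fold assignment, stratified by species where a species
# contributes >= 2 samples; singletons are pooled and shuffled across folds.
assignFolds <- function(species, nFolds, seed) {
  n <- length(species)
  withSeed(seed, {
    fold <- integer(n)
    tab <- table(species)
    strat <- names(tab)[tab >= 2L]
    for (s in strat) {
      i <- sample(which(species == s))
      fold[i] <- rep_len(sample(nFolds), length(i))
    }
    single <- which(fold == 0L)
    if (length(single))
      fold[single] <- sample(rep_len(sample(nFolds), length(single)))
    fold
  })
}

imputeColMeans <- function(x, means = NULL) {
  if (!anyNA(x)) return(list(x = x, means = means %||% colMeans(x)))
  if (is.null(means)) means <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- means[idx[, 2L]]
  list(x = x, means = means)
}

#' Fit an elastic-net epigenetic clock
#'
#' Fits the regularization path of an elastic net (fixed mixing parameter
#' \code{alpha}, default 0.5, midway between ridge and lasso) to
#' transformed chronological age, choosing the penalty by internal k-fold
#' cross-validation minimizing mean squared error.  Only nonzero
#' coefficients are retained, reported on the original beta scale.
#' Missing probe values are mean-imputed; the training means are stored in
#' the model for prediction-time imputation.
#'
#' @param x a [MethylExperiment-class], or a samples x CpGs beta matrix.
#' @param panel sample panel (ignored when \code{x} is a MethylExperiment).
#' @param transform an [AgeTransform-class] (default log1p).
#' @param alpha elastic-net mixing parameter in [0, 1].
#' @param nFolds internal CV folds (reduced, with a warning, when the
#'   training set is smaller; never below 3).
#' @param seed integer seed controlling fold assignment.
#' @param lambdaRule \code{"min"} (CV-minimizing penalty, default) or
#'   \code{"1se"}.
#' @param nlambda length of the regularization path.
#' @param lambdaMinRatio smallest path penalty as a fraction of the
#'   data-derived maximal penalty.  The path is laid out explicitly so the
#'   CV minimum can be reached even when the signal is strong enough that a
#'   deviance-based early stop would truncate the path first.
#' @return a [ClockModel-class].
#' @export
fitClock <- function(x, panel = NULL, transform = ageTransform(),
                     alpha = 0.5, nFolds = 10L, seed = 1L,
                     lambdaRule = c("min", "1se"), nlambda = 100L,
                     lambdaMinRatio = 1e-5) {
  lambdaRule <- match.arg(lambdaRule)
  inp <- resolveInputs(x, panel)
  betas <- inp$betas; pan <- inp$panel
  n <- nrow(betas)
  if (n < 3L) stopf("need at least 3 samples to fit a clock")
  if (n < nFolds) {
    warnf("reducing internal CV folds from %d to %d (training-set size)",
          nFolds, max(n, 3L))
    nFolds <- max(min(n, nFolds), 3L)
  }
  y <- transformAge(pan$age_years, transform, pan$species)
  if (var(y) == 0) stopf("no age variance in the training set")
  keep <- which(apply(betas, 2L, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0L && any(v != v[1L])
  }))
  if (!length(keep)) stopf("all predictors have zero variance")
  imp <- imputeColMeans(betas[, keep, drop = FALSE])
  foldid <- assignFolds(pan$species, nFolds, seed)
  lmax <- max(glmnet::glmnet(imp$x, y, alpha = alpha, nlambda = 3L)$lambda)
  lam <- exp(seq(log(lmax), log(lmax * lambdaMinRatio),
                 length.out = nlambda))
  # glmnet warns when folds drop below 3 observations and falls back to
  # ungrouped CV error; that fallback is exactly what we want on small
  # training sets, so the notice is muffled
  cv <- withSeed(seed, withCallingHandlers(
    glmnet::cv.glmnet(imp$x, y, alpha = alpha, foldid = foldid,
                      family = "gaussian", lambda = lam),
    warning = function(w) {
      if (grepl("grouped=FALSE", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  s <- if (lambdaRule == "min") cv$lambda.min else cv$lambda.1se
  co <- as.matrix(stats::coef(cv, s = s))[, 1L]
  w <- co[-1L]
  w <- w[w != 0]
  new("ClockModel", intercept = unname(co[1L]), weights = w,
      transform = transform,
      trainingMeta = list(
        tissue = paste(sort(unique(pan$tissue)), collapse = "+"),
        species = paste(sort(unique(pan$species)), collapse = "+"),
        alpha = alpha, nSamples = n, seed = as.integer(seed),
        nFolds = as.integer(nFolds), lambda = s,
        lambdaRule = lambdaRule,
        cpgMeans = imp$means[names(w)]))
}

#' Predict DNA-methylation age in years
#'
#' Linear score of the model's CpG weights on beta values plus intercept,
#' mapped back to years through the inverse age transform.  Model CpGs
#' missing from the input are imputed with their stored training means; a
#' sample missing more than \code{missingThreshold} of the model's CpGs is
#' an error.
#'
#' @param model a [ClockModel-class].
#' @param x a [MethylExperiment-class] or samples x CpGs beta matrix.
#' @param species optional species labels (needed only for per-species
#'   loglinear knots); taken from the MethylExperiment when available.
#' @param missingThreshold maximal tolerated fraction of missing model CpGs
#'   per sample.
#' @return named numeric vector of predicted ages (years).
#' @export
predictAge <- function(model, x, species = NULL, missingThreshold = 0.2) {
  if (is(x, "MethylExperiment")) {
    species <- species %||% samplePanel(x)$species
    x <- t(betaValues(x))
  }
  w <- model@weights
  if (!length(w))
    return(setNames(rep(inverseTransformAge(model@intercept, model@transform),
                        nrow(x)), rownames(x)))
  means <- model@trainingMeta$cpgMeans
  X <- matrix(NA_real_, nrow(x), length(w),
              dimnames = list(rownames(x), names(w)))
  present <- intersect(names(w), colnames(x))
  X[, present] <- x[, present, drop = FALSE]
  missFrac <- rowMeans(is.na(X))
  if (any(missFrac > missingThreshold))
    stopf("more than %.0f%% of model CpGs missing for sample(s): %s",
          100 * missingThreshold,
          paste(rownames(x)[missFrac > missingThreshold], collapse = ", "))
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- means[colnames(X)[idx[, 2L]]]
  }
  score <- drop(X %*% w) + model@intercept
  setNames(inverseTransformAge(score, model@transform, species), rownames(x))
}

#' @rdname betaValues
#' @export
clockWeights <- function(x) x@weights

#' @rdname betaValues
#' @export
clockIntercept <- function(x) x@intercept

#' @rdname betaValues
#' @export
cvPredictions <- function(x) x@predictions

#' @rdname betaValues
#' @export
cvSummary <- function(x) x@summary

#' Leave-one-out cross-validation of a clock
#'
#' Refits the full elastic-net clock once per sample, each time excluding
#' that sample, and predicts its age with the left-out model; the penalty is
#' re-selected within every fold.  Reports the Pearson correlation between
#' predicted and observed ages (years) and the median absolute error.
#'
#' @inheritParams fitClock
#' @return a [CVResult-class] with \code{scheme = "loocv"}.
#' @export
loocv <- function(x, panel = NULL, transform = ageTransform(), alpha = 0.5,
                  nFolds = 10L, seed = 1L, nlambda = 100L) {
  inp <- resolveInputs(x, panel)
  betas <- inp$betas; pan <- inp$panel
  n <- nrow(betas)
  if (n < 10L) stopf("leave-one-out CV needs at least 10 samples")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    m <- tryCatch(
      fitClock(betas[-i, , drop = FALSE], pan[-i, , drop = FALSE],
               transform = transform, alpha = alpha, nFolds = nFolds,
               seed = seed + i, nlambda = nlambda),
      error = function(e)
        stopf("LOO fold for sample '%s' failed: %s",
              pan$sample_id[i], conditionMessage(e)))
    pred[i] <- predictAge(m, betas[i, , drop = FALSE],
                          species = pan$species[i])
  }
  predDf <- data.frame(sample_id = pan$sample_id, species = pan$species,
                       tissue = pan$tissue, observed = pan$age_years,
                       predicted = pred, fold = pan$sample_id,
                       stringsAsFactors = FALSE)
  new("CVResult", scheme = "loocv", predictions = predDf,
      summary = list(n = n, r = cor(pred, pan$age_years),
                     medianMAE = median(abs(pred - pan$age_years))))
}

#' Leave-one-species-out cross-validation of a clock
#'
#' Refits the clock once per species, excluding all of that species'
#' samples, and predicts them with the left-out model.  Summarized by the
#' repeated-measures correlation (species as the repeated-measures grouping
#' factor) and the median across species of per-species median absolute
#' errors, so unequal species sample sizes do not dominate.
#'
#' @inheritParams fitClock
#' @return a [CVResult-class] with \code{scheme = "losocv"}.
#' @export
losocv <- function(x, panel = NULL, transform = ageTransform(), alpha = 0.5,
                   nFolds = 10L, seed = 1L, nlambda = 100L) {
  inp <- resolveInputs(x, panel)
  betas <- inp$betas; pan <- inp$panel
  spAll <- unique(pan$species)
  if (length(spAll) < 3L)
    stopf("leave-one-species-out CV needs at least 3 species")
  pred <- rep(NA_real_, nrow(betas))
  for (k in seq_along(spAll)) {
    s <- spAll[k]
    out <- pan$species == s
    m <- tryCatch(
      fitClock(betas[!out, , drop = FALSE], pan[!out, , drop = FALSE],
               transform = transform, alpha = alpha, nFolds = nFolds,
               seed = seed + k, nlambda = nlambda),
      error = function(e)
        stopf("LOSO fold for species '%s' failed: %s", s,
              conditionMessage(e)))
    pred[out] <- predictAge(m, betas[out, , drop = FALSE],
                            species = pan$species[out])
  }
  predDf <- data.frame(sample_id = pan$sample_id, species = pan$species,
                       tissue = pan$tissue, observed = pan$age_years,
                       predicted = pred, fold = pan$species,
                       stringsAsFactors = FALSE)
  tab <- table(pan$species)
  small <- names(tab)[tab < 2L]
  if (length(small))
    warnf("species with < 2 samples excluded from the repeated-measures correlation: %s",
          paste(small, collapse = ", "))
  keep <- !pan$species %in% small
  rm <- rmCorr(pan$age_years[keep], pred[keep], pan$species[keep])
  perSpecies <- vapply(split(abs(pred - pan$age_years), pan$species),
                       median, numeric(1))
  new("CVResult", scheme = "losocv", predictions = predDf,
      summary = list(n = nrow(betas), rmR = rm$r,
                     medianMAE = median(perSpecies),
                     perSpeciesMAE = perSpecies))
}

#' Repeated-measures correlation
#'
#' The common within-group correlation from the analysis-of-covariance
#' formulation: both variables are centered on their group means and the
#' Pearson correlation of the centered values is returned, its sign that of
#' the common within-group slope.  With a single group this reduces to the
#' ordinary Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param group grouping labels (e.g. species).
#' @return list with elements \code{r} (in [-1, 1]), \code{n} (points
#'   used), \code{k} (groups used) and \code{df} (\code{n - k - 1}).
#' @export
rmCorr <- function(x, y, group) {
  ok <- stats::complete.cases(x, y, group)
  x <- x[ok]; y <- y[ok]; group <- as.character(group[ok])
  tab <- table(group)
  use <- group %in% names(tab)[tab >= 2L]
  if (!any(use)) stopf("all groups are singletons; correlation undefined")
  x <- x[use]; y <- y[use]; group <- group[use]
  xc <- x - stats::ave(x, group)
  yc <- y - stats::ave(y, group)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  k <- length(unique(group))
  list(r = r, n = length(x), k = k, df = length(x) - k - 1L)
}
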