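# Two-sided log-space p from a t statistic, and the matching signed normal
# z-score.  All p-values in this module are natural-log p, so meta-analysis
# of 10^-100-scale associations never underflows.
logPFromT <- function(t, df) log(2) + pt(-abs(t), df = df, log.p = TRUE)

zFromLogP <- function(logP, sign) {
  z <- qnorm(logP - log(2), lower.tail = FALSE, log.p = TRUE)
  sign * z
}

#' Per-stratum EWAS of age (Pearson correlation screening)
#'
#' For a single species-tissue stratum, computes per CpG the Pearson
#' correlation of methylation with age, the corresponding t statistic
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}}, the two-sided p-value from the t
#' distribution (stored as natural-log p) and the signed normal z-score
#' \eqn{z = sign(r)\,\Phi^{-1}(1 - p/2)}, computed via log-space quantiles
#' so extreme associations do not saturate.  Missing betas are handled
#' pairwise-complete; zero-variance CpGs get \code{NA} statistics.
#'
#' @param betas samples x CpGs beta matrix for the stratum.
#' @param age chronological ages (years) for the stratum's samples.
#' @param minN minimum stratum size; smaller strata return \code{NULL} with
#'   a notice (they are skipped, not an error).
#' @param species,tissue stratum labels recorded on the result.
#' @return data.frame (cpg_id, stat, t, logP, z, n) with attributes
#'   \code{species}, \code{tissue}, \code{n}, \code{analysis = "age"}, or
#'   \code{NULL} when the stratum is too small.
#' @export
stratumAgeEwas <- function(betas, age, minN = 15L, species = NA_character_,
                           tissue = NA_character_) {
  n <- nrow(betas)
  if (n < minN) {
    message(sprintf("stratum %s/%s skipped: n = %d < %d",
                    species, tissue, n, minN))
    return(NULL)
  }
  nOk <- colSums(!is.na(betas) & !is.na(age))
  r <- suppressWarnings(as.numeric(cor(age, betas,
                                       use = "pairwise.complete.obs")))
  sds <- apply(betas, 2L, sd, na.rm = TRUE)
  r[!is.na(sds) & sds == 0] <- NA_real_
  df <- nOk - 2
  tt <- r * sqrt(df) / sqrt(pmax(1 - r^2, 0))
  logP <- logPFromT(tt, df)
  z <- zFromLogP(logP, sign(tt))
  z[!is.na(r) & r == 0] <- 0
  out <- data.frame(cpg_id = colnames(betas), stat = r, t = tt,
                    logP = logP, z = z, n = nOk, stringsAsFactors = FALSE)
  structure(out, species = species, tissue = tissue, n = n,
            analysis = "age")
}

# OLS of each CpG on (female, age); returns the female-coefficient t stats.
sexOlsStats <- function(Y, female, age) {
  X <- cbind(1, female, age)
  n <- nrow(X)
  XtXinv <- solve(crossprod(X))
  H <- XtXinv %*% t(X)
  B <- H %*% Y                       # 3 x p coefficients
  R <- Y - X %*% B
  sigma2 <- colSums(R^2) / (n - 3)
  se <- sqrt(sigma2 * XtXinv[2, 2])
  list(est = B[2, ], t = B[2, ] / se, df = n - 3)
}

#' Per-stratum EWAS of sex, adjusted for age
#'
#' Ordinary least squares of each CpG's methylation on a female indicator
#' and chronological age, \code{lm(CpG ~ Female + Age)}; the reported
#' statistic is the female coefficient with its t (df = n - 3), two-sided
#' log-space p and signed z (positive = higher methylation in females).
#' Strata with a single sex, or a rank-deficient design, are skipped with a
#' notice.  Samples of unknown sex must be excluded beforehand.
#'
#' @param betas samples x CpGs beta matrix for the stratum.
#' @param female 0/1 indicator (1 = female).
#' @param age chronological ages in years.
#' @inheritParams stratumAgeEwas
#' @return as [stratumAgeEwas()], with \code{analysis = "sex"} and
#'   \code{stat} the female-coefficient estimate.
#' @export
stratumSexEwas <- function(betas, female, age, minN = 15L,
                           species = NA_character_, tissue = NA_character_) {
  n <- nrow(betas)
  if (n < minN) {
    message(sprintf("stratum %s/%s skipped: n = %d < %d",
                    species, tissue, n, minN))
    return(NULL)
  }
  if (length(unique(female)) < 2L) {
    message(sprintf("stratum %s/%s skipped: single-sex stratum",
                    species, tissue))
    return(NULL)
  }
  if (qr(cbind(1, female, age))$rank < 3L) {
    message(sprintf("stratum %s/%s skipped: collinear sex/age design",
                    species, tissue))
    return(NULL)
  }
  est <- tt <- rep(NA_real_, ncol(betas))
  nOk <- colSums(!is.na(betas))
  dfv <- rep(NA_real_, ncol(betas))
  full <- which(nOk == n)
  if (length(full)) {
    st <- sexOlsStats(betas[, full, drop = FALSE], female, age)
    est[full] <- st$est; tt[full] <- st$t; dfv[full] <- st$df
  }
  for (j in setdiff(seq_len(ncol(betas)), full)) {  # pairwise-complete CpGs
    ok <- !is.na(betas[, j])
    if (sum(ok) < 4L || length(unique(female[ok])) < 2L ||
        qr(cbind(1, female[ok], age[ok]))$rank < 3L) next
    st <- sexOlsStats(betas[ok, j, drop = FALSE], female[ok], age[ok])
    est[j] <- st$est; tt[j] <- st$t; dfv[j] <- st$df
  }
  sds <- apply(betas, 2L, sd, na.rm = TRUE)
  zero <- !is.na(sds) & sds == 0
  est[zero] <- tt[zero] <- NA_real_
  logP <- logPFromT(tt, dfv)
  z <- zFromLogP(logP, sign(tt))
  out <- data.frame(cpg_id = colnames(betas), stat = est, t = tt,
                    logP = logP, z = z, n = nOk, stringsAsFactors = FALSE)
  structure(out, species = species, tissue = tissue, n = n,
            analysis = "sex")
}

#' Run stratified EWAS over all species-tissue strata
#'
#' Splits the experiment into species x tissue strata, runs the per-stratum
#' age or sex EWAS on each stratum with at least \code{minN} samples, and
#' returns the eligible strata.
#'
#' @param x a [MethylExperiment-class].
#' @param analysis \code{"age"} or \code{"sex"} (sex excludes samples of
#'   unknown sex and adjusts for age).
#' @param tissue restrict to \code{"blood"}, \code{"skin"}, or \code{"all"}.
#' @param minN minimum stratum sample size (default 15).
#' @return named list of stratum result data.frames
#'   (names \code{"species|tissue"}).
#' @export
ewasStrata <- function(x, analysis = c("age", "sex"), tissue = "all",
                       minN = 15L) {
  analysis <- match.arg(analysis)
  pan <- samplePanel(x)
  betas <- t(betaValues(x))
  keep <- rep(TRUE, nrow(pan))
  if (tissue != "all") keep <- pan$tissue == tissue
  if (analysis == "sex") keep <- keep & pan$sex %in% c("F", "M")
  pan <- pan[keep, , drop = FALSE]
  betas <- betas[keep, , drop = FALSE]
  out <- list()
  for (s in unique(pan$species)) for (ti in unique(pan$tissue)) {
    i <- pan$species == s & pan$tissue == ti
    if (!any(i)) next
    res <- if (analysis == "age")
      stratumAgeEwas(betas[i, , drop = FALSE], pan$age_years[i],
                     minN = minN, species = s, tissue = ti)
    else
      stratumSexEwas(betas[i, , drop = FALSE],
                     as.numeric(pan$sex[i] == "F"), pan$age_years[i],
                     minN = minN, species = s, tissue = ti)
    if (!is.null(res)) out[[paste(s, ti, sep = "|")]] <- res
  }
  out
}

#' Unweighted Stouffer combination of z-scores
#'
#' \eqn{z_{meta} = \sum_i z_i / \sqrt{k}}; the two-sided meta p-value is
#' computed from the normal tail in log space.
#'
#' @param z finite z-scores (k >= 1).
#' @return list with \code{z}, \code{logP} (natural-log two-sided p) and
#'   \code{k}.
#' @export
stoufferCombine <- function(z) {
  z <- z[is.finite(z)]
  if (!length(z)) stopf("Stouffer combination requires at least one z-score")
  k <- length(z)
  mz <- sum(z) / sqrt(k)
  list(z = mz, logP = log(2) + pnorm(-abs(mz), log.p = TRUE), k = k)
}

# Stouffer-combine columns of a CpG x strata z matrix (NA = unavailable);
# returns per-CpG z and contributing count.
stoufferRows <- function(Z) {
  k <- rowSums(!is.na(Z))
  z <- ifelse(k > 0, rowSums(Z, na.rm = TRUE) / sqrt(pmax(k, 1)), NA_real_)
  list(z = z, k = k)
}

#' Two-step Stouffer meta-analysis across strata
#'
#' For \code{"age-all"} and \code{"sex"}: step 1 combines each species'
#' tissue-stratum z-scores with the unweighted Stouffer method into a
#' species-level z (a species with a single eligible stratum passes its z
#' through unchanged); step 2 combines the species-level z-scores the same
#' way into the meta z.  For \code{"age-blood"} / \code{"age-skin"}: a
#' single Stouffer step across the species strata of that tissue.  A CpG's
#' \code{k} counts only the strata in which its statistic was available;
#' unavailable statistics reduce k rather than being imputed as zero.
#'
#' @param strata list of stratum results from [ewasStrata()].
#' @param analysis \code{"age-all"}, \code{"age-blood"}, \code{"age-skin"}
#'   or \code{"sex"}.
#' @return data.frame (cpg_id, meta_z, logP, k, direction) sorted by
#'   cpg_id; \code{logP} is the natural-log two-sided meta p.
#' @export
twoStepMeta <- function(strata,
                        analysis = c("age-all", "age-blood", "age-skin",
                                     "sex")) {
  analysis <- match.arg(analysis)
  if (!length(strata)) stopf("no eligible strata supplied")
  if (analysis %in% c("age-blood", "age-skin")) {
    want <- sub("age-", "", analysis)
    strata <- Filter(function(s) identical(attr(s, "tissue"), want), strata)
    if (!length(strata)) stopf("no strata for tissue '%s'", want)
  }
  cpgs <- sort(unique(unlist(lapply(strata, `[[`, "cpg_id"))))
  Z <- vapply(strata, function(s) {
    z <- rep(NA_real_, length(cpgs))
    z[match(s$cpg_id, cpgs)] <- s$z
    z
  }, numeric(length(cpgs)))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = length(cpgs))
  avail <- rowSums(!is.na(Z))

  if (analysis %in% c("age-blood", "age-skin")) {
    res <- stoufferRows(Z)
  } else {
    speciesOf <- vapply(strata, function(s) attr(s, "species"), "")
    spZ <- vapply(unique(speciesOf), function(s) {
      stoufferRows(Z[, speciesOf == s, drop = FALSE])$z
    }, numeric(length(cpgs)))
    if (is.null(dim(spZ))) spZ <- matrix(spZ, nrow = length(cpgs))
    res <- stoufferRows(spZ)
  }
  keep <- avail > 0
  mz <- res$z[keep]
  data.frame(cpg_id = cpgs[keep], meta_z = mz,
             logP = log(2) + pnorm(-abs(mz), log.p = TRUE),
             k = avail[keep],
             direction = ifelse(mz >= 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Select top CpGs by meta z-score
#'
#' CpGs with meta z of the requested sign, ordered by |meta z| descending
#' with deterministic tie-breaking (log p ascending, then cpg_id), truncated
#' to \code{n}.
#'
#' @param meta result of [twoStepMeta()].
#' @param n number of CpGs requested (default 1000).
#' @param direction \code{"positive"} or \code{"negative"} association.
#' @return character vector of CpG ids (a warning if fewer than \code{n}
#'   CpGs of that sign exist).
#' @export
selectTop <- function(meta, n = 1000L, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  sub <- meta[!is.na(meta$meta_z) &
              (if (direction == "positive") meta$meta_z > 0
               else meta$meta_z < 0), , drop = FALSE]
  ord <- order(-abs(sub$meta_z), sub$logP, sub$cpg_id)
  sub <- sub[ord, , drop = FALSE]
  if (nrow(sub) < n)
    warnf("only %d CpGs with %s meta z available (requested %d)",
          nrow(sub), direction, n)
  head(sub$cpg_id, n)
}

#' Bonferroni significance threshold
#'
#' @param nTests number of CpGs tested.
#' @param alpha family-wise error rate (default 0.05).
#' @return \code{alpha / nTests} (e.g. 0.05 / 20150 = 2.48e-6, the
#'   roughly 2.5e-6 genome-wide line for the mappable-CpG universe).
#' @export
bonferroniThreshold <- function(nTests, alpha = 0.05) {
  stopifnot(nTests >= 1)
  alpha / nTests
}
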