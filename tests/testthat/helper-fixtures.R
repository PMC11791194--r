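# Shared fixtures. Everything is generated in code; the expensive standard
# multi-species scenario (and its cross-validation runs) is computed once per
# test session and cached.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# The standard parameter-recovery scenario: 6 species x 2 tissues x 40
# samples, 2000 CpGs, 200 planted age CpGs, 50 planted sex CpGs, seed 42.
standardScenario <- function() {
  simulationScenario(
    maxLifespan = c(`hector's dolphin` = 25,
                    `pacific white-sided dolphin` = 40,
                    `common bottlenose dolphin` = 50,
                    `beluga` = 60, `killer whale` = 80,
                    `bowhead whale` = 139),
    samplesPerStratum = 40L, nCpgs = 2000L, nAgeCpgs = 200L,
    nSexCpgs = 50L, seed = 42L)
}

standardFixture <- function() cached("standard", generatePanel(standardScenario()))

standardLoocv <- function() cached("standard_loocv",
  loocv(standardFixture()$experiment, seed = 42L))

standardLosocv <- function() cached("standard_losocv",
  losocv(standardFixture()$experiment, seed = 42L))

standardAgeMeta <- function() cached("standard_meta", {
  strata <- ewasStrata(standardFixture()$experiment, "age")
  twoStepMeta(strata, "age-all")
})

# A small panel for fast clock tests: 3 species, one tissue, low noise.
smallFixture <- function() cached("small", {
  sc <- simulationScenario(maxLifespan = c(a = 25, b = 40, c = 60),
                           tissues = "skin", samplesPerStratum = 14L,
                           nCpgs = 200L, nAgeCpgs = 40L, nSexCpgs = 10L,
                           noiseSd = 0.02, seed = 7L)
  generatePanel(sc)
})

makePanel <- function(n, species = "sp1", tissue = "skin", ages = NULL,
                      sex = NULL, seed = 1) {
  withr::with_seed(seed, {
    data.frame(sample_id = sprintf("s%03d", seq_len(n)),
               species = rep_len(species, n), tissue = rep_len(tissue, n),
               age_years = ages %||% runif(n, 0, 60),
               sex = sex %||% sample(c("F", "M"), n, TRUE),
               age_known = TRUE, stringsAsFactors = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Synthetic stratum-EWAS table carrying given z-scores, for meta tests.
makeStratum <- function(species, tissue, z,
                        cpg = sprintf("cpg%03d", seq_along(z))) {
  structure(data.frame(cpg_id = cpg, stat = z, t = z,
                       logP = log(2) + pnorm(-abs(z), log.p = TRUE),
                       z = z, n = 20L, stringsAsFactors = FALSE),
            species = species, tissue = tissue, n = 20L, analysis = "age")
}

# GRanges from 1-based closed intervals, for enrichment tests.
makeRegionsGr <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, end = end))
}

# Vector of n values with exact sample correlation rho to x (for frozen
# stratum-statistic checks).
withExactCor <- function(x, rho, seed = 1) {
  withr::with_seed(seed, {
    e <- rnorm(length(x))
    e <- residuals(lm(e ~ x))
    zx <- as.numeric(scale(x))
    ze <- as.numeric(scale(e))
    rho * zx + sqrt(1 - rho^2) * ze
  })
}
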