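#' Default per-species maximum lifespans (years)
#'
#' A plausible spread of cetacean maximum lifespans, topped by the
#' 139-year bowhead whale bound, used as the generator default.
#' @keywords internal
defaultLifespans <- function() {
  c(`bowhead whale` = 139, `fin whale` = 90, `humpback whale` = 95,
    `gray whale` = 70, `sperm whale` = 70, `killer whale` = 80,
    `beluga` = 60, `short-finned pilot whale` = 60,
    `common bottlenose dolphin` = 50,
    `indo-pacific bottlenose dolphin` = 45,
    `pacific white-sided dolphin` = 40, `hector's dolphin` = 25,
    `harbor porpoise` = 20)
}

#' Describe a synthetic methylation study
#'
#' See [SimulationScenario-class] for the meaning of each parameter.
#' Defaults emulate a pooled multi-study cetacean panel: 13 species, blood
#' and skin, ~42 samples per stratum (~1090 samples overall), ages spanning
#' 0 to 139 years, and an array-scale universe of 37,000 CpGs of which a few
#' thousand carry age signal.
#'
#' @param maxLifespan named numeric vector of per-species maximum lifespans.
#' @param tissues tissues sampled per species.
#' @param samplesPerStratum samples per species-tissue stratum.
#' @param nCpgs,nAgeCpgs,nSexCpgs universe size and planted CpG counts.
#' @param slopeMean,slopeSd planted age-slope magnitude distribution
#'   (transformed-age scale, beta units per transformed year).
#' @param sexEffectRange magnitude range of planted female effects (beta units).
#' @param noiseSd Gaussian measurement noise s.d. (beta units).
#' @param speciesBaselineSd per-species baseline shift s.d. (beta units).
#' @param sharedFraction fraction of age CpGs with species-shared slopes.
#' @param agePower ages drawn as lifespan * U^agePower (1 = uniform).
#' @param transform [AgeTransform-class] on which age effects are linear.
#' @param seed mandatory integer seed.
#' @return a validated [SimulationScenario-class].
#' @export
simulationScenario <- function(maxLifespan = defaultLifespans(),
                               tissues = c("blood", "skin"),
                               samplesPerStratum = 42L,
                               nCpgs = 37000L, nAgeCpgs = 2000L,
                               nSexCpgs = 200L,
                               slopeMean = 0.08, slopeSd = 0.02,
                               sexEffectRange = c(0.08, 0.2),
                               noiseSd = 0.03, speciesBaselineSd = 0.02,
                               sharedFraction = 1, agePower = 1,
                               transform = ageTransform("log1p"),
                               seed) {
  if (missing(seed)) stopf("seed is mandatory in a simulation scenario")
  if (is.null(names(maxLifespan)))
    names(maxLifespan) <- sprintf("species%02d", seq_along(maxLifespan))
  new("SimulationScenario", maxLifespan = maxLifespan,
      tissues = canonLabel(tissues),
      samplesPerStratum = as.integer(samplesPerStratum),
      nCpgs = as.integer(nCpgs), nAgeCpgs = as.integer(nAgeCpgs),
      nSexCpgs = as.integer(nSexCpgs), slopeMean = slopeMean,
      slopeSd = slopeSd, sexEffectRange = sexEffectRange,
      noiseSd = noiseSd, speciesBaselineSd = speciesBaselineSd,
      sharedFraction = sharedFraction, agePower = agePower,
      transform = transform, seed = as.integer(seed))
}

#' Generate a synthetic multi-species methylation panel
#'
#' Ages are drawn per species on [0, max lifespan] (optionally skewed young
#' via \code{agePower}); a planted age CpG has mean beta
#' \code{squash(b0 + m * f(age))} with \code{f} the scenario's age transform,
#' slope \code{m} shared across species for the shared fraction and redrawn
#' per species otherwise, and \code{b0} a species-shifted baseline; planted
#' sex CpGs add a signed female effect and live on the designated sex
#' chromosome \code{"chrX_sim"}; i.i.d. Gaussian noise is added and values
#' clamped to [0, 1].  Fully deterministic for a fixed scenario seed.
#'
#' @param scenario a [SimulationScenario-class].
#' @return list with elements \code{experiment} (a
#'   [MethylExperiment-class]) and \code{truth} (list: \code{ageCpgs}
#'   data.frame of planted ids/signed slopes/shared flag, \code{sexCpgs}
#'   data.frame of ids/signed female effects, \code{sexChromosome},
#'   \code{ages} named per-sample true ages).
#' @export
generatePanel <- function(scenario) {
  stopifnot(is(scenario, "SimulationScenario"))
  methods::validObject(scenario)
  withSeed(scenario@seed, {
    sp <- names(scenario@maxLifespan)
    nS <- length(sp)
    nPer <- scenario@samplesPerStratum
    tissues <- scenario@tissues
    n <- nS * length(tissues) * nPer
    species <- rep(sp, each = length(tissues) * nPer)
    tissue <- rep(rep(tissues, each = nPer), times = nS)
    life <- scenario@maxLifespan[species]
    age <- as.numeric(life * runif(n) ^ scenario@agePower)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    ids <- sprintf("s%04d", seq_len(n))
    panel <- data.frame(sample_id = ids, species = species, tissue = tissue,
                        age_years = age, sex = sex, age_known = TRUE,
                        stringsAsFactors = FALSE)

    p <- scenario@nCpgs
    cpgIds <- sprintf("cpg%05d", seq_len(p))
    # genomic placement: autosomes chr1..chr20 plus a designated sex
    # chromosome; planted sex CpGs are forced onto it
    chroms <- c(paste0("chr", 1:20), "chrX_sim")
    chrom <- sample(chroms, p, replace = TRUE)
    planted <- sample.int(p, scenario@nAgeCpgs + scenario@nSexCpgs)
    ageIdx <- planted[seq_len(scenario@nAgeCpgs)]
    sexIdx <- planted[-seq_len(scenario@nAgeCpgs)]
    chrom[sexIdx] <- "chrX_sim"
    chrom[ageIdx][chrom[ageIdx] == "chrX_sim"] <- "chr1"
    position <- integer(p)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      position[i] <- sort(sample.int(1e8L, length(i)))
    }
    cpgMap <- data.frame(cpg_id = cpgIds, chromosome = chrom,
                         position = position, stringsAsFactors = FALSE)

    f <- transformAge(age, scenario@transform, species)
    fmax <- max(transformAge(max(scenario@maxLifespan), scenario@transform))

    # baselines and species offsets
    b0 <- runif(p, 0.1, 0.9)
    spOff <- matrix(rnorm(p * nS, 0, scenario@speciesBaselineSd), p, nS,
                    dimnames = list(NULL, sp))

    # planted age effects
    slopeSign <- sample(c(-1, 1), scenario@nAgeCpgs, replace = TRUE)
    slopeMag <- pmax(rnorm(scenario@nAgeCpgs, scenario@slopeMean,
                           scenario@slopeSd), 0.01)
    slope <- slopeSign * slopeMag
    shared <- runif(scenario@nAgeCpgs) <= scenario@sharedFraction
    # species-specific slopes for the unshared fraction
    spSlope <- matrix(rep(slope, nS), scenario@nAgeCpgs, nS,
                      dimnames = list(NULL, sp))
    if (any(!shared)) {
      k <- sum(!shared)
      for (s in sp)
        spSlope[!shared, s] <- sample(c(-1, 1), k, replace = TRUE) *
          pmax(rnorm(k, scenario@slopeMean, scenario@slopeSd), 0.01)
    }
    # keep planted means inside (0,1) across the age range
    b0[ageIdx] <- ifelse(slope > 0,
                         runif(scenario@nAgeCpgs, 0.05,
                               pmax(0.06, 0.95 - slopeMag * fmax)),
                         runif(scenario@nAgeCpgs,
                               pmin(0.94, 0.05 + slopeMag * fmax), 0.95))

    # planted sex effects
    deltaSign <- sample(c(-1, 1), scenario@nSexCpgs, replace = TRUE)
    deltaMag <- runif(scenario@nSexCpgs, scenario@sexEffectRange[1],
                      scenario@sexEffectRange[2])
    delta <- deltaSign * deltaMag
    b0[sexIdx] <- runif(scenario@nSexCpgs, 0.05 + deltaMag,
                        0.95 - deltaMag) # room for +/- delta

    spi <- match(species, sp)
    mu <- matrix(b0, p, n) + spOff[, spi, drop = FALSE]
    if (scenario@nAgeCpgs)
      mu[ageIdx, ] <- mu[ageIdx, , drop = FALSE] +
        spSlope[, spi, drop = FALSE] * rep(f, each = scenario@nAgeCpgs)
    if (scenario@nSexCpgs) {
      fem <- as.numeric(sex == "F")
      mu[sexIdx, ] <- mu[sexIdx, , drop = FALSE] +
        outer(delta, fem)
    }
    mu <- pmin(pmax(mu, 0.001), 0.999)
    beta <- mu + matrix(rnorm(p * n, 0, scenario@noiseSd), p, n)
    beta <- pmin(pmax(beta, 0), 1)
    dimnames(beta) <- list(cpgIds, ids)

    truth <- list(
      ageCpgs = data.frame(cpg_id = cpgIds[ageIdx], slope = slope,
                           shared = shared, stringsAsFactors = FALSE),
      sexCpgs = data.frame(cpg_id = cpgIds[sexIdx], delta = delta,
                           stringsAsFactors = FALSE),
      sexChromosome = "chrX_sim",
      ages = setNames(age, ids))
    list(experiment = MethylExperiment(beta, panel, cpgMap), truth = truth)
  })
}

makeRegions <- function(cpgMap, include, halfWidth = 50L) {
  sub <- cpgMap[match(include, cpgMap$cpg_id), , drop = FALSE]
  GenomicRanges::sort(GenomicRanges::GRanges(
    sub$chromosome,
    IRanges::IRanges(start = pmax(sub$position - halfWidth, 1L),
                     end = sub$position + halfWidth)))
}

#' Generate synthetic annotation region sets
#'
#' Builds mock chromatin-state, transcription-factor peak and polycomb
#' member region sets in which CpGs planted with a positive age slope are
#' included at \code{enrichmentFactor} times the background inclusion rate;
#' every emitted interval is a non-degenerate window covering the CpG it
#' includes.  Deterministic for a fixed seed.
#'
#' @param truth the \code{truth} element from [generatePanel()].
#' @param cpgMap CpG position table of the generated universe.
#' @param enrichmentFactor inclusion-rate multiplier for planted
#'   positive-age CpGs (>= 1; 1 = null fixture).
#' @param seed integer seed.
#' @param backgroundRate baseline inclusion probability per CpG.
#' @return list with named elements \code{states}, \code{tfs}, \code{prc},
#'   each a named list of \code{GRanges}.  The enriched state is
#'   \code{"BivProm_sim"}; the enriched TF is \code{"ZBTB14_sim"}; PRC2
#'   members (EED/SUZ12/EZH2) co-include enriched CpGs so the two-member
#'   rule assigns them to PRC2.
#' @export
generateAnnotationFixture <- function(truth, cpgMap, enrichmentFactor = 5,
                                      seed, backgroundRate = 0.08) {
  if (enrichmentFactor < 1) stopf("enrichmentFactor must be >= 1")
  if (missing(seed)) stopf("seed is mandatory")
  withSeed(seed, {
    ids <- cpgMap$cpg_id
    pos <- truth$ageCpgs$cpg_id[truth$ageCpgs$slope > 0]
    rate <- rep(backgroundRate, length(ids))
    rate[ids %in% pos] <- min(1, enrichmentFactor * backgroundRate)

    draw <- function(r = rate) ids[runif(length(ids)) < r]
    states <- list(
      BivProm_sim = makeRegions(cpgMap, draw()),
      Quies_sim = makeRegions(cpgMap, draw(rep(backgroundRate, length(ids)))),
      TxEnh_sim = makeRegions(cpgMap, draw(rep(backgroundRate, length(ids)))),
      ReprPC_sim = makeRegions(cpgMap, draw(rep(backgroundRate, length(ids)))))

    tfs <- list(
      ZBTB14_sim = makeRegions(cpgMap, draw()),
      CTCF_sim = makeRegions(cpgMap, draw(rep(backgroundRate, length(ids)))),
      REST_sim = makeRegions(cpgMap, draw(rep(backgroundRate, length(ids)))))

    # PRC2 members co-include a common enriched CpG pool (>= 2-member rule);
    # PRC1 members draw independently at background rate
    pool <- draw()
    prcMember <- function(pool) {
      keep <- runif(length(pool)) < 0.9
      makeRegions(cpgMap, pool[keep])
    }
    prc <- list(
      EED = prcMember(pool), SUZ12 = prcMember(pool), EZH2 = prcMember(pool),
      RING1 = makeRegions(cpgMap, draw(rep(backgroundRate, length(ids)))),
      RNF2 = makeRegions(cpgMap, draw(rep(backgroundRate, length(ids)))),
      BMI1 = makeRegions(cpgMap, draw(rep(backgroundRate, length(ids)))))

    list(states = states, tfs = tfs, prc = prc)
  })
}
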