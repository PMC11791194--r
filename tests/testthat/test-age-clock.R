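test_that("a noiseless single-CpG signal is recovered almost exactly", {
  n <- 100L
  pan <- makePanel(n, ages = withr::with_seed(2, runif(n, 0, 139)))
  f <- log1p(pan$age_years)
  b <- withr::with_seed(3, matrix(runif(n * 30, 0.2, 0.8), n, 30))
  b[, 1] <- 0.3 + 0.004 * f
  colnames(b) <- paste0("cg", 1:30)
  rownames(b) <- pan$sample_id
  m <- fitClock(b, pan, seed = 1)
  expect_true("cg1" %in% names(clockWeights(m)))
  pred <- predictAge(m, b)
  expect_gt(cor(pred, pan$age_years), 0.999)
  expect_lt(median(abs(pred - pan$age_years)), 0.1)
})

test_that("degenerate inputs raise the documented errors", {
  pan <- makePanel(20, ages = runif(20, 1, 30))
  const <- matrix(0.5, 20, 5,
                  dimnames = list(pan$sample_id, paste0("cg", 1:5)))
  expect_error(fitClock(const, pan), "zero variance")

  panC <- makePanel(20, ages = rep(7, 20))
  b <- withr::with_seed(1, matrix(runif(100), 20, 5,
       dimnames = list(panC$sample_id, paste0("cg", 1:5))))
  expect_error(fitClock(b, panC), "no age variance")

  expect_warning(
    fitClock(b[1:8, ], pan[1:8, ], nFolds = 10),
    "reducing")
})

test_that("prediction is id-aligned, imputes missing probes, bounds missingness", {
  g <- smallFixture()
  me <- g$experiment
  m <- fitClock(me, seed = 4)
  b <- t(betaValues(me))
  p1 <- predictAge(m, b)
  p2 <- predictAge(m, b[, sample(ncol(b)), drop = FALSE]) # column shuffle
  expect_equal(p1, p2)

  # zero-weight model predicts a constant inverse-transformed intercept
  m0 <- new("ClockModel", intercept = log(11), weights = setNames(numeric(0),
            character(0)), transform = ageTransform(),
            trainingMeta = list())
  expect_equal(unname(predictAge(m0, b)), rep(10, nrow(b)))

  # a missing model CpG falls back to its training mean
  w <- names(clockWeights(m))
  bMiss <- b; bMiss[, w[1]] <- NA
  pm <- predictAge(m, bMiss)
  expect_true(all(is.finite(pm)))
  # too many missing model CpGs is an error naming the sample
  bBad <- b; bBad[2, w] <- NA
  expect_error(predictAge(m, bBad), rownames(b)[2])
})

test_that("an added constant CpG never changes the fitted clock", {
  g <- smallFixture()
  b <- t(betaValues(g$experiment))
  pan <- samplePanel(g$experiment)
  m1 <- fitClock(b, pan, seed = 9)
  b2 <- cbind(b, flat = 0.5)
  m2 <- fitClock(b2, pan, seed = 9)
  expect_equal(clockWeights(m1), clockWeights(m2))
  expect_equal(clockIntercept(m1), clockIntercept(m2))
})

test_that("LOO CV leaves each sample out once and summarizes residuals in years", {
  g <- smallFixture()
  me <- g$experiment
  cv <- loocv(me, seed = 5)
  pred <- cvPredictions(cv)
  expect_equal(nrow(pred), ncol(me))
  expect_equal(pred$fold, pred$sample_id)          # one fold per sample
  s <- cvSummary(cv)
  expect_equal(s$r, cor(pred$predicted, pred$observed))
  expect_equal(s$medianMAE, median(abs(pred$predicted - pred$observed)))
  expect_gt(s$r, 0.9)                              # low-noise fixture
})

test_that("LOSO CV predicts each species from the others and medians per species", {
  g <- smallFixture()
  me <- g$experiment
  cv <- losocv(me, seed = 5)
  pred <- cvPredictions(cv)
  expect_equal(pred$fold, pred$species)
  s <- cvSummary(cv)
  manual <- vapply(split(abs(pred$predicted - pred$observed), pred$species),
                   median, numeric(1))
  expect_equal(s$medianMAE, median(manual))
  expect_equal(s$perSpeciesMAE, manual)

  pan <- samplePanel(me)
  expect_error(losocv(t(betaValues(me))[pan$species == "a", ],
                      pan[pan$species == "a", ], seed = 1),
               "3 species")
})

test_that("a species with unshared effects predicts worse than shared ones", {
  sc <- simulationScenario(maxLifespan = c(a = 40, b = 50, c = 60, d = 45),
                           tissues = "skin", samplesPerStratum = 25L,
                           nCpgs = 400L, nAgeCpgs = 80L, nSexCpgs = 0L,
                           sharedFraction = 0, noiseSd = 0.02, seed = 21L)
  # sharedFraction 0 re-draws every species' slopes independently, so a
  # left-out species carries no transferable signal; the identical design
  # with fully shared slopes transfers well
  scShared <- sc; scShared@sharedFraction <- 1
  cvUnshared <- losocv(generatePanel(sc)$experiment, seed = 2)
  cvShared <- losocv(generatePanel(scShared)$experiment, seed = 2)
  expect_gt(cvSummary(cvUnshared)$medianMAE,
            2 * cvSummary(cvShared)$medianMAE)
  expect_gt(cvSummary(cvShared)$rmR, cvSummary(cvUnshared)$rmR)
})

test_that("repeated-measures correlation matches its ANCOVA oracle", {
  withr::with_seed(8, {
    k <- 5; m <- 12
    group <- rep(letters[1:k], each = m)
    x <- rnorm(k * m) + rep(rnorm(k, sd = 3), each = m)
    y <- 0.6 * x + rnorm(k * m) + rep(rnorm(k, sd = 5), each = m)
  })
  r <- rmCorr(x, y, group)$r
  # oracle: sequential ANOVA of y ~ group + x; r^2 = SSx/(SSx+SSe), sign of
  # the common slope
  fit <- aov(y ~ factor(group) + x)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  rOracle <- sign(coef(fit)[["x"]]) * sqrt(ss[2] / (ss[2] + ss[3]))
  expect_equal(r, rOracle, tolerance = 1e-8)

  # degenerate single group equals the ordinary Pearson correlation
  one <- group == "a"
  expect_equal(rmCorr(x[one], y[one], group[one])$r, cor(x[one], y[one]),
               tolerance = 1e-12)

  # perfect within-group fit across offset groups
  xg <- c(1:5, 1:5); yg <- c(1:5 + 10, 1:5 - 4)
  expect_equal(rmCorr(xg, yg, rep(1:2, each = 5))$r, 1)

  expect_error(rmCorr(1:3, 1:3, c("a", "b", "c")), "singleton")
})
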