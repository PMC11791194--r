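test_that("stratum age EWAS reproduces the t/z statistics of its oracle", {
  withr::with_seed(14, {
    for (n in c(15L, 30L, 100L)) {
      age <- runif(n, 0, 50)
      betas <- matrix(runif(n * 25, 0.2, 0.8), n, 25,
                      dimnames = list(NULL, paste0("cg", 1:25)))
      betas[, 1] <- pmin(pmax(0.3 + 0.006 * age + rnorm(n, 0, 0.05), 0), 1)
      res <- stratumAgeEwas(betas, age, minN = 15L)
      for (j in c(1, 5, 12)) {
        ct <- cor.test(betas[, j], age)
        expect_equal(res$t[j], unname(ct$statistic), tolerance = 1e-8)
        expect_equal(exp(res$logP[j]), ct$p.value, tolerance = 1e-8)
        zO <- sign(ct$estimate) * qnorm(ct$p.value / 2, lower.tail = FALSE)
        expect_equal(res$z[j], unname(zO), tolerance = 1e-8)
      }
    }
  })
})

test_that("stratum statistics honor exact correlations and symmetries", {
  # a CpG exactly uncorrelated with age has z = 0, p = 1
  age <- 0:14
  b0 <- abs(age - 7) / 20 + 0.3
  betas <- cbind(flat0 = b0, rising = 0.2 + age / 40)
  res <- stratumAgeEwas(betas, age)
  expect_equal(res$z[1], 0)
  expect_equal(res$logP[1], 0)

  # an engineered r = 0.5 at n = 15 gives the canonical t, p and z
  y <- withExactCor(age, 0.5)
  y <- (y - min(y)) / (max(y) - min(y)) # into [0,1]; cor is scale-invariant
  res2 <- stratumAgeEwas(cbind(cg = y), age)
  expect_equal(res2$t, 2.0817, tolerance = 1e-4)
  expect_equal(exp(res2$logP), 0.0577, tolerance = 1e-3)
  expect_equal(res2$z, 1.898, tolerance = 1e-3)

  # antisymmetry: flipping methylation direction flips z, keeps p
  resFlip <- stratumAgeEwas(1 - betas, age)
  expect_equal(resFlip$z, -res$z)
  expect_equal(resFlip$logP, res$logP)

  # zero-variance CpGs are marked unavailable, small strata are skipped
  res3 <- stratumAgeEwas(cbind(const = rep(0.5, 15), rising = 0.2 + age / 40),
                         age)
  expect_true(is.na(res3$z[1]))
  expect_message(expect_null(stratumAgeEwas(betas[1:10, ], age[1:10])),
                 "skipped")
})

test_that("sex EWAS matches lm() and skips degenerate designs", {
  withr::with_seed(15, {
    n <- 50L
    female <- rep(c(1, 0), length.out = n)
    age <- runif(n, 0, 40)
    betas <- matrix(runif(n * 10, 0.3, 0.7), n, 10,
                    dimnames = list(NULL, paste0("cg", 1:10)))
    betas[, 1] <- 0.4 + 0.1 * female + rnorm(n, 0, 0.02)
  })
  res <- stratumSexEwas(betas, female, age)
  expect_gt(res$z[1], 3)                       # planted female effect found
  for (j in c(1, 4, 9)) {
    s <- summary(lm(betas[, j] ~ female + age))$coefficients["female", ]
    expect_equal(res$stat[j], unname(s["Estimate"]), tolerance = 1e-8)
    expect_equal(res$t[j], unname(s["t value"]), tolerance = 1e-8)
    expect_equal(exp(res$logP[j]), unname(s["Pr(>|t|)"]), tolerance = 1e-8)
  }
  expect_message(expect_null(
    stratumSexEwas(betas, rep(1, n), age)), "single-sex")
  expect_message(expect_null(
    stratumSexEwas(betas, female, female * 2)), "collinear")
})

test_that("Stouffer combination follows the closed form in log space", {
  expect_error(stoufferCombine(numeric(0)), "at least one")
  expect_equal(stoufferCombine(2)$z, 2)             # k = 1 identity
  expect_equal(stoufferCombine(c(0, 0, 0))$z, 0)
  expect_equal(exp(stoufferCombine(c(0, 0, 0))$logP), 1)
  expect_equal(stoufferCombine(c(1, 2, 3))$z, 6 / sqrt(3), tolerance = 1e-12)
  # log-space p agrees with the direct normal tail where it is computable
  for (z in c(0.5, 2, 8)) {
    s <- stoufferCombine(z)
    expect_equal(exp(s$logP), 2 * pnorm(-abs(z)), tolerance = 1e-10)
  }
  # an |z| = 23 meta-statistic (p ~ 1e-117) computes without underflow
  s <- stoufferCombine(rep(23 / sqrt(4), 4))
  expect_equal(s$z, 23)
  expect_lt(s$logP, -260)
  expect_true(is.finite(s$logP))
})

test_that("two-step meta combines tissues within species, then species", {
  s1 <- makeStratum("beluga", "blood", c(1, 2))
  expect_equal(twoStepMeta(list(s1), "age-all")$meta_z, c(1, 2)) # identity

  strata <- list(makeStratum("beluga", "blood", 1),
                 makeStratum("beluga", "skin", 1),
                 makeStratum("killer whale", "blood", 1),
                 makeStratum("killer whale", "skin", 1))
  m <- twoStepMeta(strata, "age-all")
  expect_equal(m$meta_z, 2)            # species z = sqrt(2); meta = 2
  expect_equal(m$k, 4L)

  # invariant to stratum ordering
  m2 <- twoStepMeta(rev(strata), "age-all")
  expect_equal(m2$meta_z, m$meta_z)

  # tissue-restricted analyses combine in a single step across species
  mb <- twoStepMeta(strata, "age-blood")
  expect_equal(mb$meta_z, 2 / sqrt(2))
  expect_equal(mb$k, 2L)

  # consistent methylation gain with age has positive meta z
  gain <- list(makeStratum("a", "blood", 2.5), makeStratum("b", "skin", 1.5))
  expect_gt(twoStepMeta(gain, "age-all")$meta_z, 0)
  expect_equal(twoStepMeta(gain, "age-all")$direction, "positive")

  # unavailable stratum statistics reduce k instead of imputing zero
  sNA <- makeStratum("b", "skin", c(NA, 1), cpg = c("cpg001", "cpg002"))
  mNA <- twoStepMeta(list(makeStratum("a", "blood", c(1, 1),
                                      cpg = c("cpg001", "cpg002")), sNA),
                     "age-all")
  expect_equal(mNA$k, c(1L, 2L))
  expect_equal(mNA$meta_z[1], 1)       # lone available stratum passes through
})

test_that("meta p stays consistent with meta z deep into log space", {
  strata <- list(makeStratum("a", "blood", c(12, -9, 0.3)),
                 makeStratum("b", "skin", c(11, -8, -0.1)))
  m <- twoStepMeta(strata, "age-all")
  expect_equal(m$logP, log(2) + pnorm(-abs(m$meta_z), log.p = TRUE),
               tolerance = 1e-10)
  expect_true(all(is.finite(m$logP)))
})

test_that("top-CpG selection orders by |z| with deterministic tie-breaks", {
  meta <- data.frame(cpg_id = c("cgA", "cgB", "cgC", "cgD", "cgE"),
                     meta_z = c(5, 2, 7, -3, -3),
                     logP = c(-10, -2, -14, -4, -4),
                     k = 2L, direction = c("positive", "positive",
                                           "positive", "negative",
                                           "negative"))
  expect_equal(selectTop(meta, 2, "positive"), c("cgC", "cgA"))
  expect_warning(all <- selectTop(meta, 10, "positive"), "only 3")
  expect_equal(all, c("cgC", "cgA", "cgB"))
  expect_equal(selectTop(meta, 2, "negative"), c("cgD", "cgE")) # id tie-break
})

test_that("Bonferroni threshold is alpha over the tested CpG count", {
  expect_equal(bonferroniThreshold(1), 0.05)
  expect_equal(bonferroniThreshold(37000), 0.05 / 37000)
  expect_equal(signif(bonferroniThreshold(37000), 3), 1.35e-6)
})

test_that("Stouffer null z-scores stay standard normal across strata counts", {
  withr::with_seed(99, {
    for (k in c(2L, 5L)) {
      Z <- matrix(rnorm(3000 * k), 3000, k)
      mz <- apply(Z, 1, function(z) stoufferCombine(z)$z)
      expect_lt(abs(mean(mz)), 0.05)
      expect_lt(abs(sd(mz) - 1), 0.05)
    }
  })
})
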