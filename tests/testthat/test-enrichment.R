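cpgMap3 <- data.frame(cpg_id = c("cgA", "cgB", "cgC"),
                      chromosome = "chr1",
                      position = c(1000L, 500L, 2000L))

test_that("CpG-region overlap follows half-open buffered interval arithmetic", {
  reg <- makeRegionsGr("chr1", 1151, 1300)   # BED (chr1,1150,1300)
  expect_equal(overlapCpgs(cpgMap3, reg, buffer = 200), "cgA")
  expect_equal(overlapCpgs(cpgMap3, reg, buffer = 0), character(0))
  reg2 <- makeRegionsGr("chr1", 801, 900)    # BED (chr1,800,900)
  expect_false("cgB" %in% overlapCpgs(cpgMap3, reg2, buffer = 200))
  # chromosomes unknown to the map are ignored
  regX <- makeRegionsGr("chr9", 1, 10000)
  expect_equal(overlapCpgs(cpgMap3, regX, buffer = 200), character(0))
})

test_that("overlap grows monotonically with the buffer", {
  withr::with_seed(31, {
    cm <- data.frame(cpg_id = sprintf("cg%03d", 1:150), chromosome = "chr2",
                     position = sort(sample.int(5e4, 150)))
    reg <- makeRegionsGr("chr2", s <- sort(sample.int(5e4, 20)), s + 120)
  })
  prev <- character(0)
  for (b in c(0, 50, 200, 1000)) {
    cur <- overlapCpgs(cm, reg, b)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("hypergeometric rows carry exact tails, FC and odds ratios", {
  bg <- sprintf("c%02d", 1:10)
  row <- hypergeomEnrichment(bg[1:4], bg[1:5], bg, "s")
  expect_equal(row$fc, 2.0)
  expect_equal(exp(row$logP_enrichment), 5 / 210, tolerance = 1e-12)

  sat <- hypergeomEnrichment(bg, bg[1:5], bg)
  expect_equal(sat$fc, 1)
  expect_equal(exp(sat$logP_enrichment), 1, tolerance = 1e-12)

  # zero overlap: enrichment p = 1, depletion p = C(N-K,n)/C(N,n)
  zero <- hypergeomEnrichment(bg[6:9], bg[1:3], bg)
  expect_equal(exp(zero$logP_enrichment), 1, tolerance = 1e-12)
  expect_equal(exp(zero$logP_depletion),
               choose(7, 4) / choose(10, 4), tolerance = 1e-12)
  expect_equal(zero$direction, "depletion")

  expect_error(hypergeomEnrichment(character(0), bg[1:2], bg), "foreground")
  expect_error(hypergeomEnrichment(c("zz"), bg[1:2], bg), "subset")
  deg <- hypergeomEnrichment(bg[1:2], character(0), bg)
  expect_true(deg$degenerate)
  expect_equal(exp(deg$logP), 1)
})

test_that("enrichment and depletion tails are complementary", {
  withr::with_seed(41, {
    for (i in 1:25) {
      N <- sample(5:60, 1); K <- sample.int(N, 1); n <- sample.int(N, 1)
      bg <- sprintf("c%03d", 1:N)
      fg <- sample(bg, n)
      row <- hypergeomEnrichment(fg, bg[1:K], bg)
      expect_equal(exp(row$logP_enrichment) + exp(row$logP_depletion) -
                     dhyper(row$k, K, N - K, n), 1, tolerance = 1e-9)
    }
  })
})

test_that("PRC annotation requires two distinct member TF overlaps", {
  cm <- data.frame(cpg_id = c("cg1", "cg2", "cg3"), chromosome = "chr1",
                   position = c(100L, 5000L, 9000L))
  peak <- function(pos) makeRegionsGr("chr1", pos - 10, pos + 10)
  peaks <- list(EED = peak(100), SUZ12 = peak(100), EZH2 = peak(9000),
                RING1 = c(peak(5000), peak(9000)), BMI1 = peak(9000))
  expect_message(ann <- prcAnnotate(peaks, cm), "RNF2")
  expect_equal(ann$PRC2, "cg1")              # EED + SUZ12
  expect_true("cg3" %in% ann$PRC1)           # RING1 + BMI1
  expect_false("cg2" %in% ann$PRC1)          # RING1 only
  expect_warning(one <- prcAnnotate(peaks["EED"], cm,
                                    list(PRC2 = c("EED", "SUZ12", "EZH2"))),
                 "fewer than 2")
  expect_length(one$PRC2, 0L)
})

test_that("TF enrichment applies the ratio cap, Yamanaka exemption and median rule", {
  withr::with_seed(51, {
    cm <- data.frame(cpg_id = sprintf("cg%03d", 1:200), chromosome = "chr3",
                     position = sort(sample.int(1e6, 200)))
  })
  bg <- cm$cpg_id
  fg <- bg[1:40]
  cover <- function(ids, pad = 10) {
    p <- cm$position[match(ids, cm$cpg_id)]
    makeRegionsGr("chr3", pmax(p - pad, 1), p + pad)
  }
  peaks <- list(
    wide1 = cover(bg[1:130]),          # K/N = 0.65 > cap
    oct1 = cover(bg[1:130]),           # same ratio, Yamanaka-exempt
    tfA1 = cover(bg[1:30]),            # three datasets for TF A with
    tfA2 = cover(bg[1:20]),            # decreasing overlap => ordered p
    tfA3 = cover(bg[1:10]))
  tf <- c("WIDE", "OCT4", "TFA", "TFA", "TFA")
  res <- tfEnrichment(fg, bg, peaks, tf, cm, buffer = 0)
  expect_false("WIDE" %in% res$tf)
  expect_true("OCT4" %in% res$tf)
  expect_equal(res$dataset[res$tf == "TFA"], "tfA2")  # odd count: middle p

  # even dataset count: the more significant of the two middle rows
  res2 <- tfEnrichment(fg, bg, peaks[3:4], c("TFA", "TFA"), cm, buffer = 0)
  expect_equal(res2$dataset, "tfA1")
})

test_that("gene regulatory domains follow the basal-plus-extension rule", {
  lone <- data.frame(gene_id = "g1", chromosome = "chr1",
                     position = 100000L, strand = "+")
  d <- buildGeneDomains(lone)
  expect_equal(c(d$basal_start, d$basal_end), c(95000L, 101000L))
  expect_equal(c(d$ext_start, d$ext_end), c(45000L, 151000L))

  minus <- data.frame(gene_id = "g1", chromosome = "chr1",
                      position = 100000L, strand = "-")
  dm <- buildGeneDomains(minus)
  expect_equal(c(dm$basal_start, dm$basal_end), c(99000L, 105000L))

  # two adjacent genes 8 kb apart clip each other's extensions at the
  # neighbor's basal boundary
  two <- data.frame(gene_id = c("g1", "g2"), chromosome = "chr1",
                    position = c(100000L, 108000L), strand = "+")
  d2 <- buildGeneDomains(two)
  expect_equal(d2$ext_end[d2$gene_id == "g1"],
               d2$basal_start[d2$gene_id == "g2"] - 1L)
  expect_equal(d2$ext_start[d2$gene_id == "g2"],
               d2$basal_end[d2$gene_id == "g1"] + 1L)

  # chromosome-edge clipping and duplicate detection
  edge <- buildGeneDomains(data.frame(gene_id = "g", chromosome = "chr1",
                                      position = 2000L, strand = "+"))
  expect_equal(edge$ext_start, 1L)
  expect_error(buildGeneDomains(rbind(lone, lone)), "duplicate")
})

test_that("gene-set enrichment filters by overlapping genes and p-value", {
  withr::with_seed(61, {
    cm <- data.frame(cpg_id = sprintf("cg%03d", 1:300), chromosome = "chr4",
                     position = sort(sample.int(3e6, 300)))
  })
  bg <- cm$cpg_id
  # genes spaced far apart, each domain covering a block of CpGs
  tss <- data.frame(gene_id = sprintf("g%02d", 1:10), chromosome = "chr4",
                    position = seq(150000L, 3e6L, length.out = 10),
                    strand = "+")
  dom <- buildGeneDomains(tss)
  cpg2gene <- cetClocks:::mapCpgsToGenes(cm, dom)
  gWith <- unique(cpg2gene$gene_id)
  expect_gte(length(gWith), 5)
  # foreground: most CpGs of the first four genes' domains
  fgPool <- cpg2gene$cpg_id[cpg2gene$gene_id %in% gWith[1:4]]
  fg <- unique(fgPool)
  res <- geneSetEnrichment(fg, bg, dom,
                           list(hit = gWith[1:4], miss = gWith[5:6]),
                           cm)
  expect_true("hit" %in% res$set_name)
  expect_false("miss" %in% res$set_name)     # no enrichment signal
  expect_gt(res$fc[res$set_name == "hit"], 1)
  expect_gte(res$n_genes[res$set_name == "hit"], 3)

  # a significant set touching fewer than 3 genes is filtered out
  res2 <- geneSetEnrichment(fg, bg, dom, list(two = gWith[1:2]), cm)
  expect_equal(nrow(res2), 0L)

  expect_equal(nrow(geneSetEnrichment(fg, bg, dom, list(), cm)), 0L)
})
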