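cpgGRanges <- function(cpgMap, buffer = 0L) {
  # a CpG at 1-based position p occupies the half-open interval [p-1, p);
  # buffered by b it becomes [p-1-b, p+b), i.e. 1-based closed [p-b, p+b]
  GenomicRanges::GRanges(
    cpgMap$chromosome,
    IRanges::IRanges(start = pmax(cpgMap$position - buffer, 1L),
                     end = cpgMap$position + buffer))
}

#' CpGs overlapping a region set
#'
#' A CpG is included iff its single-base interval, expanded by
#' \code{buffer} bp on both sides, intersects any interval of the set on
#' the same chromosome.  Chromosomes present in the regions but absent from
#' the CpG map are ignored.
#'
#' @param cpgMap CpG position table (cpg_id, chromosome, position).
#' @param regions a \code{GRanges} region set.
#' @param buffer non-negative buffer in bp (e.g. 200 for TF peak overlap).
#' @return character vector of overlapping CpG ids.
#' @export
overlapCpgs <- function(cpgMap, regions, buffer = 0L) {
  stopifnot(buffer >= 0)
  gr <- cpgGRanges(cpgMap, as.integer(buffer))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, regions))
  unique(cpgMap$cpg_id[S4Vectors::queryHits(hits)])
}

oddsRatio <- function(k, n, K, N) {
  a <- k; b <- n - k; c <- K - k; d <- N - K - n + k
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5
                                 c <- c + 0.5; d <- d + 0.5 }
  (a / b) / (c / d)
}

#' One-sided hypergeometric enrichment of a CpG set
#'
#' Tests whether a foreground CpG set overlaps an annotation's CpG members
#' more (enrichment, FC > 1) or less (depletion, FC < 1) than expected under
#' hypergeometric sampling from the background universe.  Tail
#' probabilities are exact and kept in natural-log space; the fold change is
#' \eqn{FC = k / (n K / N)} and the odds ratio uses the Haldane-Anscombe 0.5
#' correction only when a contingency cell is zero.
#'
#' @param foreground CpG ids of interest (must be a subset of background).
#' @param setMembers CpG ids belonging to the annotation (intersected with
#'   the background before testing).
#' @param background the CpG universe.
#' @param setName label recorded on the output row.
#' @return one-row data.frame: set_name, N, K, n, k, fc, or,
#'   logP_enrichment, logP_depletion, logP and direction (the one-sided p
#'   matching the direction implied by FC vs 1), degenerate flag.
#' @export
hypergeomEnrichment <- function(foreground, setMembers, background,
                                setName = NA_character_) {
  background <- unique(background)
  foreground <- unique(foreground)
  if (!length(foreground)) stopf("empty foreground")
  if (!length(background)) stopf("empty background")
  if (!all(foreground %in% background))
    stopf("foreground must be a subset of the background universe")
  members <- intersect(unique(setMembers), background)
  N <- length(background); K <- length(members); n <- length(foreground)
  k <- length(intersect(foreground, members))
  if (K == 0L) {
    return(data.frame(set_name = setName, N = N, K = 0L, n = n, k = 0L,
                      fc = NA_real_, or = NA_real_, logP_enrichment = 0,
                      logP_depletion = 0, logP = 0, direction = "none",
                      degenerate = TRUE, stringsAsFactors = FALSE))
  }
  fc <- k / (n * K / N)
  logEnr <- phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  logDep <- phyper(k, K, N - K, n, lower.tail = TRUE, log.p = TRUE)
  dir <- if (fc >= 1) "enrichment" else "depletion"
  data.frame(set_name = setName, N = N, K = K, n = n, k = k, fc = fc,
             or = oddsRatio(k, n, K, N),
             logP_enrichment = logEnr, logP_depletion = logDep,
             logP = if (dir == "enrichment") logEnr else logDep,
             direction = dir, degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Enrichment of a foreground across several region sets
#'
#' Maps each region set to its member CpGs (with an optional overlap
#' buffer) and runs [hypergeomEnrichment()] per set; used for chromatin
#' states (buffer 0 by default) and other interval annotations.
#'
#' @param foreground,background CpG id vectors.
#' @param regionSets named list of \code{GRanges}.
#' @param cpgMap CpG position table.
#' @param buffer overlap buffer in bp.
#' @return data.frame of enrichment rows sorted by log p.
#' @export
enrichRegionSets <- function(foreground, background, regionSets, cpgMap,
                             buffer = 0L) {
  rows <- lapply(names(regionSets), function(nm)
    hypergeomEnrichment(foreground,
                        overlapCpgs(cpgMap, regionSets[[nm]], buffer),
                        background, setName = nm))
  out <- do.call(rbind, rows)
  out[order(out$logP_enrichment), , drop = FALSE]
}

#' Polycomb repressive complex CpG annotation
#'
#' A CpG is annotated as PRC1- or PRC2-bound iff it overlaps (no buffer)
#' peaks of at least two distinct member transcription factors of that
#' complex (PRC1: RING1, RNF2, BMI1; PRC2: EED, SUZ12, EZH2).
#'
#' @param memberPeaks named list of \code{GRanges}, one per member TF;
#'   missing members are allowed (logged).
#' @param cpgMap CpG position table.
#' @param complexMembers named list mapping complex name to member TF names.
#' @return named list of CpG id vectors, one per complex (empty, with a
#'   warning, when fewer than two members were supplied).
#' @export
prcAnnotate <- function(memberPeaks, cpgMap,
                        complexMembers = list(
                          PRC1 = c("RING1", "RNF2", "BMI1"),
                          PRC2 = c("EED", "SUZ12", "EZH2"))) {
  lapply(complexMembers, function(members) {
    have <- intersect(members, names(memberPeaks))
    if (length(have) < length(members))
      message(sprintf("missing member peak set(s): %s",
                      paste(setdiff(members, have), collapse = ", ")))
    if (length(have) < 2L) {
      warnf("fewer than 2 member peak sets supplied; complex annotation empty")
      return(character(0))
    }
    hits <- lapply(have, function(m)
      overlapCpgs(cpgMap, memberPeaks[[m]], buffer = 0L))
    counts <- table(unlist(lapply(hits, unique)))
    names(counts)[counts >= 2L]
  })
}

#' Transcription-factor binding-site enrichment
#'
#' Per TF dataset, CpGs within \code{buffer} bp of a peak are the set
#' members and a hypergeometric row is computed against the background.
#' TFs whose member/background ratio K/N exceeds \code{ratioCap} are dropped
#' unless they are one of the \code{alwaysKeep} factors (by default the four
#' Yamanaka factors).  For a TF with several datasets the row with the
#' median enrichment p is reported (even count: the more significant of the
#' two middle rows, so a concrete dataset's full row is returned).
#'
#' @param foreground,background CpG id vectors.
#' @param peakSets named list of \code{GRanges} peak sets (names = dataset
#'   ids).
#' @param tf character vector, same length, giving each dataset's TF name.
#' @param cpgMap CpG position table.
#' @param buffer overlap buffer in bp (default 200).
#' @param ratioCap maximal K/N ratio (default 0.5).
#' @param alwaysKeep TF names exempt from the ratio filter.
#' @return data.frame with one row per retained TF (columns of
#'   [hypergeomEnrichment()] plus \code{tf} and \code{dataset}).
#' @export
tfEnrichment <- function(foreground, background, peakSets,
                         tf = names(peakSets), cpgMap, buffer = 200L,
                         ratioCap = 0.5,
                         alwaysKeep = c("OCT4", "SOX2", "KLF4", "MYC")) {
  stopifnot(length(tf) == length(peakSets))
  rows <- lapply(seq_along(peakSets), function(i) {
    r <- hypergeomEnrichment(
      foreground, overlapCpgs(cpgMap, peakSets[[i]], buffer), background,
      setName = names(peakSets)[i] %||% sprintf("dataset%d", i))
    r$tf <- tf[i]
    r$dataset <- r$set_name
    r
  })
  rows <- do.call(rbind, rows)
  keep <- rows$K / rows$N <= ratioCap | rows$tf %in% alwaysKeep
  rows <- rows[keep, , drop = FALSE]
  out <- lapply(split(rows, rows$tf), function(d) {
    d <- d[order(d$logP_enrichment, d$dataset), , drop = FALSE]
    m <- nrow(d)
    idx <- if (m %% 2L == 1L) (m + 1L) %/% 2L else m %/% 2L
    d[idx, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$logP_enrichment), , drop = FALSE]
}

#' Build GREAT-style gene regulatory domains
#'
#' Each gene gets a strand-aware basal domain (default 5 kb upstream to
#' 1 kb downstream of the TSS) and an extended domain growing each basal
#' flank by at most \code{distalMax} bp, stopping at the nearest neighboring
#' gene's basal domain boundary and clipped at the chromosome start.
#'
#' @param tss data.frame with columns gene_id, chromosome, position (TSS,
#'   1-based), strand (+/-).
#' @param proximalUp,proximalDown basal extent upstream/downstream of the
#'   TSS in bp.
#' @param distalMax maximal extension beyond the basal domain in bp.
#' @return data.frame: gene_id, chromosome, strand, tss, basal_start,
#'   basal_end, ext_start, ext_end (1-based closed).
#' @export
buildGeneDomains <- function(tss, proximalUp = 5000L, proximalDown = 1000L,
                             distalMax = 50000L) {
  if (anyDuplicated(tss$gene_id)) stopf("duplicate gene id(s) in TSS table")
  stopifnot(all(tss$strand %in% c("+", "-")))
  up <- ifelse(tss$strand == "+", proximalUp, proximalDown)
  dn <- ifelse(tss$strand == "+", proximalDown, proximalUp)
  bs <- pmax(tss$position - up, 1L)
  be <- tss$position + dn
  out <- data.frame(gene_id = tss$gene_id, chromosome = tss$chromosome,
                    strand = tss$strand, tss = tss$position,
                    basal_start = bs, basal_end = be,
                    ext_start = pmax(bs - distalMax, 1L),
                    ext_end = be + distalMax, stringsAsFactors = FALSE)
  out <- out[order(out$chromosome, out$basal_start, out$gene_id), ]
  for (ch in unique(out$chromosome)) {
    i <- which(out$chromosome == ch)
    if (length(i) < 2L) next
    for (j in seq_along(i)) {
      idx <- i[j]
      others <- setdiff(i, idx)
      # nearest basal boundaries of neighboring genes on each side
      leftEnds <- out$basal_end[others][out$basal_end[others] <
                                          out$basal_start[idx]]
      if (length(leftEnds))
        out$ext_start[idx] <- max(out$ext_start[idx], max(leftEnds) + 1L)
      rightStarts <- out$basal_start[others][out$basal_start[others] >
                                               out$basal_end[idx]]
      if (length(rightStarts))
        out$ext_end[idx] <- min(out$ext_end[idx], min(rightStarts) - 1L)
    }
  }
  # extension never shrinks below the gene's own basal domain
  out$ext_start <- pmin(out$ext_start, out$basal_start)
  out$ext_end <- pmax(out$ext_end, out$basal_end)
  rownames(out) <- NULL
  out
}

mapCpgsToGenes <- function(cpgMap, geneDomains) {
  gr <- cpgGRanges(cpgMap, 0L)
  dom <- GenomicRanges::GRanges(
    geneDomains$chromosome,
    IRanges::IRanges(start = geneDomains$ext_start,
                     end = geneDomains$ext_end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, dom))
  data.frame(cpg_id = cpgMap$cpg_id[S4Vectors::queryHits(hits)],
             gene_id = geneDomains$gene_id[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' GREAT-style gene-set enrichment of CpGs
#'
#' CpGs are assigned to genes through extended regulatory domains
#' ([buildGeneDomains()]); for each gene set the member CpGs are those
#' assigned to any of its genes, tested hypergeometrically against the
#' array-CpG background.  Only sets with at least \code{minOverlapGenes}
#' genes containing a foreground CpG and enrichment p below \code{pReport}
#' are reported.
#'
#' @param foreground,background CpG id vectors.
#' @param geneDomains output of [buildGeneDomains()].
#' @param geneSets named list of gene id vectors (genes absent from the
#'   domain table are ignored, with a notice).
#' @param cpgMap CpG position table.
#' @param minOverlapGenes minimal foreground-overlapping gene count.
#' @param pReport maximal unadjusted enrichment p-value.
#' @return data.frame of enrichment rows with an \code{n_genes} column.
#' @export
geneSetEnrichment <- function(foreground, background, geneDomains, geneSets,
                              cpgMap, minOverlapGenes = 3L, pReport = 1e-3) {
  if (!length(geneSets)) return(data.frame())
  cpg2gene <- mapCpgsToGenes(cpgMap, geneDomains)
  rows <- lapply(names(geneSets), function(nm) {
    genes <- geneSets[[nm]]
    known <- intersect(genes, geneDomains$gene_id)
    if (length(known) < length(genes))
      message(sprintf("gene set '%s': %d gene(s) absent from domain table ignored",
                      nm, length(genes) - length(known)))
    members <- unique(cpg2gene$cpg_id[cpg2gene$gene_id %in% known])
    r <- hypergeomEnrichment(foreground, members, background, setName = nm)
    fgGenes <- unique(cpg2gene$gene_id[cpg2gene$gene_id %in% known &
                                         cpg2gene$cpg_id %in% foreground])
    r$n_genes <- length(fgGenes)
    r
  })
  out <- do.call(rbind, rows)
  out <- out[!out$degenerate & out$n_genes >= minOverlapGenes &
               out$logP_enrichment < log(pReport), , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$logP_enrichment), , drop = FALSE]
}
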