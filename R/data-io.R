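#' @importFrom data.table fread
#' @importFrom S4Vectors DataFrame metadata metadata<- queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges findOverlaps reduce seqnames start end
#'   sort
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
NULL

sniffSep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

normalizeSex <- function(x) {
  x <- canonLabel(x)
  out <- rep("unknown", length(x))
  out[x %in% c("f", "female")] <- "F"
  out[x %in% c("m", "male")] <- "M"
  out[is.na(x) | x == "" | x == "na"] <- "unknown"
  bad <- !(x %in% c("f", "female", "m", "male", "", "na", "unknown")) & !is.na(x)
  if (any(bad))
    stopf("unrecognized sex value(s): %s",
          paste(unique(x[bad]), collapse = ", "))
  out
}

#' Read and validate a sample sheet
#'
#' Expects a CSV/TSV with columns \code{sample_id}, \code{species},
#' \code{tissue} (blood/skin), \code{age_years}, \code{sex}; optional
#' \code{age_known} (logical, default \code{TRUE}, distinguishing known from
#' estimated chronological ages).  Species and tissue labels are case-folded
#' and whitespace-trimmed; extra columns are preserved untouched.
#'
#' @param path CSV or TSV file path.
#' @return a validated \code{data.frame} (one row per sample).
#' @export
readSamplePanel <- function(path) {
  df <- read.csv(path, sep = sniffSep(path), check.names = FALSE,
                 stringsAsFactors = FALSE)
  validateSamplePanel(df)
}

#' @rdname readSamplePanel
#' @param panel a data.frame to validate/normalize in place of a file.
#' @export
validateSamplePanel <- function(panel) {
  need <- c("sample_id", "species", "tissue", "age_years", "sex")
  miss <- setdiff(need, colnames(panel))
  if (length(miss))
    stopf("sample panel misses required column(s): %s",
          paste(miss, collapse = ", "))
  if (nrow(panel) < 1L) stopf("sample panel must contain at least one row")
  panel$sample_id <- as.character(panel$sample_id)
  if (anyDuplicated(panel$sample_id))
    stopf("duplicate sample_id(s): %s",
          paste(unique(panel$sample_id[duplicated(panel$sample_id)]),
                collapse = ", "))
  panel$species <- canonLabel(panel$species)
  panel$tissue <- canonLabel(panel$tissue)
  bad <- !panel$tissue %in% c("blood", "skin")
  if (any(bad))
    stopf("tissue must be 'blood' or 'skin'; offending sample(s): %s",
          paste(panel$sample_id[bad], collapse = ", "))
  panel$age_years <- as.numeric(panel$age_years)
  neg <- !is.na(panel$age_years) & panel$age_years < 0
  if (any(neg))
    stopf("negative age_years for sample(s): %s",
          paste(panel$sample_id[neg], collapse = ", "))
  panel$sex <- normalizeSex(panel$sex)
  if (is.null(panel$age_known)) panel$age_known <- TRUE
  panel$age_known <- as.logical(panel$age_known)
  rownames(panel) <- panel$sample_id
  panel
}

#' Read a beta-value matrix aligned to a sample panel
#'
#' The file holds samples in rows (first column \code{sample_id}) and CpGs in
#' columns.  Rows are reordered to the panel's sample order; values outside
#' [0,1] by at most 1e-9 are clamped, larger excursions are an error.
#'
#' @param path CSV/TSV path.
#' @param panel a validated sample panel ([readSamplePanel()]).
#' @return numeric matrix, samples x CpGs, rownames = sample ids.
#' @export
readBetaMatrix <- function(path, panel) {
  dt <- data.table::fread(path, sep = "auto", header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stopf("duplicate CpG id(s) in beta matrix")
  miss <- setdiff(panel$sample_id, ids)
  if (length(miss))
    stopf("sample(s) in panel missing from beta matrix: %s",
          paste(miss, collapse = ", "))
  m <- m[panel$sample_id, , drop = FALSE]
  lo <- !is.na(m) & m < 0
  hi <- !is.na(m) & m > 1
  if (any(m[lo] < -1e-9) || any(m[hi] > 1 + 1e-9))
    stopf("beta values outside [0,1] beyond tolerance 1e-9")
  m[lo] <- 0
  m[hi] <- 1
  m
}

#' Read a CpG position table
#'
#' CSV with columns \code{cpg_id}, \code{chromosome}, \code{position}
#' (1-based coordinate of the cytosine).
#'
#' @param path CSV/TSV path.
#' @return data.frame with one row per CpG.
#' @export
readCpgMap <- function(path) {
  df <- read.csv(path, sep = sniffSep(path), stringsAsFactors = FALSE)
  need <- c("cpg_id", "chromosome", "position")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stopf("CpG map misses required column(s): %s", paste(miss, collapse = ", "))
  df$cpg_id <- as.character(df$cpg_id)
  df$position <- as.integer(df$position)
  if (anyDuplicated(df$cpg_id)) stopf("duplicate cpg_id(s) in CpG map")
  if (any(df$position < 1L)) stopf("CpG positions must be >= 1 (1-based)")
  df
}

#' Read a BED file into a genomic region set
#'
#' BED intervals are 0-based half-open on disk and stored 1-based closed in
#' the returned \code{GRanges} (the usual Bioconductor convention), so
#' [writeBed()] round-trips coordinates exactly.  Intervals are canonicalized
#' (sorted within chromosome); overlaps are retained unless \code{merge}.
#'
#' @param path BED path (3+ columns, whitespace-separated).
#' @param setName name of the region set.
#' @param merge union overlapping intervals after load.
#' @param sourceLabel optional provenance label (TF name, dataset id).
#' @return \code{GRanges} with \code{metadata()} fields \code{set_name} and
#'   \code{source_label}.
#' @export
readBed <- function(path, setName = basename(path), merge = FALSE,
                    sourceLabel = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  chrom <- vapply(parts, `[[`, "", 1L)
  s0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(s0) | is.na(e0) | s0 >= e0)
  if (length(bad))
    stopf("malformed BED interval (start >= end or non-numeric) at line %d of %s",
          bad[1L], path)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = s0 + 1, end = e0))
  gr <- GenomicRanges::sort(gr)
  if (merge) gr <- GenomicRanges::reduce(gr)
  S4Vectors::metadata(gr)$set_name <- setName
  S4Vectors::metadata(gr)$source_label <- sourceLabel
  gr
}

#' Write a region set to BED (0-based half-open)
#'
#' @param gr a \code{GRanges}.
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a MethylExperiment
#'
#' Bundles an aligned beta matrix, sample panel and (optionally) CpG
#' positions into a single validated container.  The beta matrix may be
#' given samples x CpGs (as read from file) or CpGs x samples.
#'
#' @param betas numeric beta matrix with dimnames; orientation is inferred
#'   from the panel's sample ids.
#' @param panel validated sample panel data.frame.
#' @param cpgMap optional CpG position table ([readCpgMap()]).
#' @return a [MethylExperiment-class].
#' @export
MethylExperiment <- function(betas, panel, cpgMap = NULL) {
  panel <- validateSamplePanel(panel)
  if (!is.null(rownames(betas)) && all(panel$sample_id %in% rownames(betas)))
    betas <- t(betas[panel$sample_id, , drop = FALSE])
  else if (!is.null(colnames(betas)) && all(panel$sample_id %in% colnames(betas)))
    betas <- betas[, panel$sample_id, drop = FALSE]
  else stopf("beta matrix dimnames do not cover the panel's sample ids")
  rd <- S4Vectors::DataFrame(row.names = rownames(betas))
  if (!is.null(cpgMap)) {
    hit <- match(rownames(betas), cpgMap$cpg_id)
    rd$chromosome <- cpgMap$chromosome[hit]
    rd$position <- cpgMap$position[hit]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = betas),
    colData = S4Vectors::DataFrame(panel, row.names = panel$sample_id),
    rowData = rd)
  new("MethylExperiment", se)
}

#' Accessors for MethylExperiment
#'
#' \code{betaValues} returns the CpG x sample beta matrix; \code{samplePanel}
#' the per-sample metadata as a data.frame; \code{cpgPositions} the CpG map
#' (cpg_id, chromosome, position) when present.
#'
#' @param x a [MethylExperiment-class].
#' @return see Description.
#' @export
betaValues <- function(x) SummarizedExperiment::assay(x, "beta")

#' @rdname betaValues
#' @export
samplePanel <- function(x)
  as.data.frame(SummarizedExperiment::colData(x))

#' @rdname betaValues
#' @export
cpgPositions <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"position" %in% colnames(rd)) return(NULL)
  data.frame(cpg_id = rownames(x), chromosome = rd$chromosome,
             position = rd$position, stringsAsFactors = FALSE)
}

setMethod("show", "MethylExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("MethylExperiment: %d CpGs x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  species: %d | tissues: %s | ages %.1f-%.1f years\n",
              length(unique(cd$species)),
              paste(sort(unique(cd$tissue)), collapse = "/"),
              min(cd$age_years), max(cd$age_years)))
})

#' Serialize / deserialize a fitted clock
#'
#' Clocks are stored as JSON documents carrying the intercept, the sparse
#' CpG weights, the age-transform specification and training metadata;
#' \code{readClockModel(writeClockModel(m))} reproduces \code{m}
#' field-for-field.
#'
#' @param model a [ClockModel-class].
#' @param path JSON file path.
#' @export
writeClockModel <- function(model, path) {
  tm <- model@trainingMeta
  if (!is.null(tm$cpgMeans)) tm$cpgMeans <- as.list(tm$cpgMeans)
  doc <- list(
    format = "cetClocks-clock-1",
    intercept = model@intercept,
    weights = as.list(model@weights),
    transform = transformToList(model@transform),
    training_meta = tm)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeClockModel
#' @return \code{readClockModel}: the restored [ClockModel-class].
#' @export
readClockModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  tr <- transformFromList(doc$transform)
  w <- if (length(doc$weights)) vapply(doc$weights, as.numeric, numeric(1))
       else setNames(numeric(0), character(0))
  tm <- lapply(doc$training_meta, function(x)
    if (is.list(x)) unlist(x) else x)
  if (!is.null(tm$cpgMeans) && !is.null(doc$training_meta$cpgMeans))
    tm$cpgMeans <- unlist(doc$training_meta$cpgMeans)
  new("ClockModel", intercept = as.numeric(doc$intercept),
      weights = w, transform = tr, trainingMeta = tm)
}
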