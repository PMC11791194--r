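writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

pipelineDefaults <- function() {
  list(minN = 15L,       # minimum stratum size for EWAS
       topN = 1000L,     # top CpGs per direction for enrichment
       buffer = 200L,    # TF overlap buffer (bp)
       alpha = 0.5,      # elastic-net mixing
       nFolds = 10L,     # internal CV folds
       loocv = TRUE, losocv = TRUE)
}

#' Run the full simulation-to-enrichment pipeline
#'
#' Drives the stages of the analysis in order: obtain data (either a
#' simulation scenario or input files), fit clocks with cross-validation,
#' run the stratified age and sex meta-EWAS, and (when annotation region
#' sets are available) the chromatin-state enrichment of top age CpGs.
#' All randomness flows from the single config seed through named
#' substreams; outputs are deterministic for a fixed config and seed.
#'
#' @param config named list (or path to a YAML file) with fields:
#'   \describe{
#'     \item{scenario}{list of [simulationScenario()] arguments (exclusive
#'       with \code{input}).}
#'     \item{input}{list with paths \code{samplePanel}, \code{betaMatrix},
#'       optional \code{cpgMap} (exclusive with \code{scenario}).}
#'     \item{seed}{mandatory integer seed.}
#'     \item{outputDir}{output directory (created).}
#'     \item{stages}{optional logical toggles \code{clocks}, \code{ewas},
#'       \code{enrichment}.}
#'     \item{thresholds}{optional overrides of \code{minN}, \code{topN},
#'       \code{buffer}, \code{alpha}, \code{nFolds}, \code{loocv},
#'       \code{losocv}, \code{enrichmentFactor}.}
#'   }
#' @return the run manifest: a list recording package version, seed,
#'   config, and every output file written; also saved as
#'   \code{manifest.json} in the output directory.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stopf("config must carry a seed")
  hasScenario <- !is.null(config$scenario)
  hasInput <- !is.null(config$input)
  if (hasScenario == hasInput)
    stopf("config must carry exactly one of 'scenario' or 'input'")
  outDir <- config$outputDir %||% stopf("config must carry outputDir")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  th <- utils::modifyList(pipelineDefaults(), config$thresholds %||% list())
  stages <- utils::modifyList(list(clocks = TRUE, ewas = TRUE,
                                   enrichment = TRUE),
                              config$stages %||% list())
  seed <- as.integer(config$seed)
  manifest <- list(package = "cetClocks",
                   version = as.character(utils::packageVersion("cetClocks")),
                   seed = seed, thresholds = th, stages = stages,
                   files = list())
  addFile <- function(key, path) manifest$files[[key]] <<- path

  stage <- "data"
  res <- tryCatch({
    if (hasScenario) {
      scArgs <- config$scenario
      scArgs$seed <- scArgs$seed %||% seed
      if (!is.null(scArgs$maxLifespan))
        scArgs$maxLifespan <- unlist(scArgs$maxLifespan)
      sc <- do.call(simulationScenario, scArgs)
      gen <- generatePanel(sc)
      me <- gen$experiment
      truth <- gen$truth
    } else {
      pan <- readSamplePanel(config$input$samplePanel)
      bm <- readBetaMatrix(config$input$betaMatrix, pan)
      cm <- if (!is.null(config$input$cpgMap))
        readCpgMap(config$input$cpgMap) else NULL
      me <- MethylExperiment(bm, pan, cm)
      truth <- NULL
    }

    if (isTRUE(stages$clocks)) {
      stage <- "clocks"
      model <- fitClock(me, alpha = th$alpha, nFolds = th$nFolds,
                        seed = seed)
      addFile("clock_model", writeClockModel(model,
                                             file.path(outDir, "clock_model.json")))
      if (isTRUE(th$loocv)) {
        cv <- loocv(me, alpha = th$alpha, nFolds = th$nFolds, seed = seed)
        addFile("loocv", writeTsv(cvPredictions(cv),
                                  file.path(outDir, "loocv_predictions.tsv")))
        manifest$clock_summary <- c(list(scheme = "loocv"), cvSummary(cv))
      }
      if (isTRUE(th$losocv) &&
          length(unique(samplePanel(me)$species)) >= 3L) {
        lv <- suppressWarnings(losocv(me, alpha = th$alpha,
                                      nFolds = th$nFolds, seed = seed))
        addFile("losocv", writeTsv(cvPredictions(lv),
                                   file.path(outDir, "losocv_predictions.tsv")))
        manifest$losocv_summary <- cvSummary(lv)[c("n", "rmR", "medianMAE")]
      }
    }

    meta <- NULL
    if (isTRUE(stages$ewas)) {
      stage <- "ewas"
      strata <- ewasStrata(me, "age", minN = th$minN)
      if (length(strata)) {
        meta <- twoStepMeta(strata, "age-all")
        addFile("ewas_age_all", writeTsv(meta,
                                         file.path(outDir, "ewas_age_all.tsv")))
        for (ti in intersect(c("blood", "skin"),
                             unique(samplePanel(me)$tissue))) {
          sub <- Filter(function(s) attr(s, "tissue") == ti, strata)
          if (length(sub))
            addFile(paste0("ewas_age_", ti),
                    writeTsv(twoStepMeta(sub, paste0("age-", ti)),
                             file.path(outDir,
                                       sprintf("ewas_age_%s.tsv", ti))))
        }
      }
      sexStrata <- ewasStrata(me, "sex", minN = th$minN)
      if (length(sexStrata))
        addFile("ewas_sex", writeTsv(twoStepMeta(sexStrata, "sex"),
                                     file.path(outDir, "ewas_sex.tsv")))
      manifest$ewas_n_strata <- list(age = length(strata),
                                     sex = length(sexStrata))
      manifest$bonferroni <- bonferroniThreshold(nrow(me))
    }

    if (isTRUE(stages$enrichment) && !is.null(truth) && !is.null(meta) &&
        !is.null(cpgPositions(me))) {
      stage <- "enrichment"
      cm <- cpgPositions(me)
      fix <- generateAnnotationFixture(truth, cm,
                                       th$enrichmentFactor %||% 5,
                                       seed = seed + 1L)
      nPos <- sum(truth$ageCpgs$slope > 0)
      fg <- suppressWarnings(selectTop(meta, n = max(nPos, 1L), "positive"))
      enr <- enrichRegionSets(fg, cm$cpg_id, fix$states, cm, buffer = 0L)
      addFile("enrichment_states",
              writeTsv(enr, file.path(outDir, "enrichment_states.tsv")))
      manifest$top_enrichment <- as.list(enr[1L, c("set_name", "fc", "logP")])
    }

    manifest
  }, error = function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  jsonlite::write_json(res, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  res
}

#' Summarize a completed pipeline run
#'
#' Builds a compact report from a run manifest: clock accuracy (N, r,
#' median MAE), per-analysis counts of CpGs beyond the Bonferroni line, and
#' the top enrichment rows.  Sections whose stage did not run are marked
#' \code{"skipped"}.
#'
#' @param manifest a manifest list from [runPipeline()], or the path to a
#'   \code{manifest.json}.
#' @return named list report.
#' @export
summarizeRun <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  rep <- list()
  rep$clocks <- if (!is.null(manifest$clock_summary)) {
    s <- manifest$clock_summary
    data.frame(scheme = "loocv", N = s$n, r = s$r, medianMAE = s$medianMAE)
  } else "skipped"
  if (!is.null(manifest$losocv_summary)) {
    s <- manifest$losocv_summary
    rep$losocv <- data.frame(scheme = "losocv", N = s$n, rmR = s$rmR,
                             medianMAE = s$medianMAE)
  }
  ewasFiles <- grep("^ewas_", names(manifest$files %||% list()), value = TRUE)
  rep$ewas <- if (length(ewasFiles)) {
    thr <- log(manifest$bonferroni)
    do.call(rbind, lapply(ewasFiles, function(key) {
      df <- read.delim(manifest$files[[key]])
      data.frame(analysis = sub("^ewas_", "", key), n_cpgs = nrow(df),
                 n_significant = sum(df$logP < thr, na.rm = TRUE))
    }))
  } else "skipped"
  rep$enrichment <- if (!is.null(manifest$files$enrichment_states))
    utils::head(read.delim(manifest$files$enrichment_states), 3L)
  else "skipped"
  rep
}
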