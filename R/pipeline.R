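#' @include simulate.R
NULL

pipelineDefaults <- function() {
  list(
    wells = NULL, cells = NULL, platemap = NULL, mask = NULL,
    simulate = FALSE, synthetic = list(), seed = 1L,
    outputDir = NULL,
    quantileP = 0.99, minCells = 0L,
    madConstant = 1.4826, tol = 1e-6, maxIter = 100L,
    k = 2.0, cellCountCut = -2.0, hoechstCut = 2.0,
    toxMode = "both", rankFraction = 0.15,
    callParameters = c("insulin", "pdx1"),
    pool = "error", logLevel = "info")
}

#' Pipeline configuration
#'
#' Assembles and validates the full set of pipeline inputs and tunables.
#' Every tunable defaults to its module default; unknown keys are
#' rejected. Inputs are either file paths (`cells` + `platemap` [+
#' `mask`], or a pre-summarized `wells` + `platemap`) or `simulate = TRUE`
#' with optional [syntheticConfig()] overrides in `synthetic`.
#'
#' `readPipelineConfig()` loads the same structure from a flat YAML file.
#'
#' @param ... Named settings overriding the defaults (see
#'   `pipelineDefaults` in the package source; the names mirror the module
#'   arguments: `quantileP`, `madConstant`, `tol`, `maxIter`, `k`,
#'   `cellCountCut`, `hoechstCut`, `toxMode`, `rankFraction`,
#'   `callParameters`, `pool`, plus inputs `wells`/`cells`/`platemap`/
#'   `mask` or `simulate`/`synthetic`/`seed`, and `outputDir`).
#' @return A validated `PipelineConfig` (classed list).
#' @export
pipelineConfig <- function(...) {
  override <- list(...)
  cfg <- pipelineDefaults()
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown))
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  if (!isTRUE(cfg$simulate)) {
    if (is.null(cfg$platemap))
      stopf("configuration error: platemap path is required unless simulate = TRUE")
    if (is.null(cfg$wells) && is.null(cfg$cells))
      stopf("configuration error: either wells or cells input is required")
  }
  if (!cfg$toxMode %in% c("both", "either", "cell_count_only", "rank"))
    stopf("unknown toxMode: %s", cfg$toxMode)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file path.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stopf("configuration file not found: %s", path)
  vals <- yaml::read_yaml(path)
  do.call(pipelineConfig, vals)
}

logStage <- function(level, name, fmt, ...) {
  if (identical(level, "quiet")) return(invisible())
  message(sprintf("[%s] %s", name, sprintf(fmt, ...)))
}

## stage timings are kept in an environment rather than on the results,
## so stage outputs stay plain objects
stageClock <- new.env(parent = emptyenv())

runStage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  assign(name, proc.time()[["elapsed"]] - t0, envir = stageClock)
  res
}

stageElapsed <- function(name) get0(name, envir = stageClock, ifnotfound = NA_real_)

#' Run the full screening pipeline
#'
#' Orchestrates summarize -> B-score -> aggregate -> cytotoxic exclusion
#' -> band -> hit calling -> bias diagnostics, writing every stage table
#' as CSV plus a resolved configuration echo and a run manifest. The run
#' is a pure composition of the module functions with the configured
#' parameters — calling the stages by hand with the same settings gives
#' identical results — and is idempotent for fixed inputs and seed.
#'
#' Output files in `outDir`: `wells.csv` (when summarized here or
#' simulated), `bscores.csv`, `effects.csv`, `extracts.csv`, `hits.csv`,
#' `bias_report.csv`, `recovery.csv` (simulated inputs only),
#' `config_resolved.yaml`, `manifest.yaml`, and the simulated inputs via
#' [writeScreenData()] when `simulate = TRUE`.
#'
#' @param config A [pipelineConfig()] (or path to its YAML file).
#' @param outDir Output directory; defaults to `config$outputDir`.
#' @return Invisibly, a list with the stage results (`wells`, `layouts`,
#'   `transform`, `bscores`, `aggregates`, `kept`, `excluded`, `bands`,
#'   `hits`, `bias`, `recovery`, `files`).
#' @export
runScreen <- function(config, outDir = config$outputDir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(outDir)) stopf("configuration error: no output directory given")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  lvl <- config$logLevel
  truth <- NULL

  if (isTRUE(config$simulate)) {
    acq <- runStage("simulate", {
      scfg <- do.call(syntheticConfig, config$synthetic)
      sim <- generateWellLevel(scfg, seed = config$seed)
      writeScreenData(sim, outDir)
      sim
    })
    wells <- acq$wells; layouts <- acq$layouts; mask <- acq$mask
    truth <- acq$truth
    logStage(lvl, "simulate", "generated %d wells on %d plates x %d replicates (%.1fs)",
             nrow(wells), length(layouts), acq$config$nReplicates,
             stageElapsed("simulate"))
  } else {
    layouts <- runStage("read-inputs", readPlateMap(config$platemap))
    mask <- if (is.null(config$mask)) NULL else
      runStage("read-inputs", readWellMask(config$mask))
    wells <- runStage("summarize", {
      if (!is.null(config$cells)) {
        cells <- readCellTable(config$cells)
        w <- summarizeScreen(cells, layouts, mask,
                             quantileP = config$quantileP,
                             minCells = config$minCells)
        writeWellTable(w, file.path(outDir, "wells.csv"))
        w
      } else {
        w <- readWellTable(config$wells)
        if (!is.null(mask) && nrow(mask)) {
          mk <- match(paste(w$plate_id, w$replicate_id, w$well),
                      paste(mask$plate_id, mask$replicate_id, mask$well))
          hit <- !is.na(mk)
          w$valid[hit] <- FALSE
          w$reason[hit] <- mask$reason[mk[hit]]
        }
        w
      }
    })
    logStage(lvl, "summarize", "%d well x parameter rows (%.1fs)",
             nrow(wells), stageElapsed("summarize"))
  }

  tr <- runStage("bscore", {
    matrices <- buildPlateMatrices(wells, layouts)
    transformScreen(matrices, madConstant = config$madConstant,
                    maxIter = config$maxIter, tol = config$tol)
  })
  if (nrow(tr$failures))
    warnf("%d plate(s) failed B-score transformation; see the failures table",
          nrow(tr$failures))
  bdf <- bscoreTable(tr$decompositions)
  utils::write.csv(bdf, file.path(outDir, "bscores.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(effectsTable(tr$decompositions),
                   file.path(outDir, "effects.csv"),
                   row.names = FALSE, quote = FALSE)
  logStage(lvl, "bscore", "%d plates transformed, %d failed (%.1fs)",
           length(tr$decompositions), nrow(tr$failures), stageElapsed("bscore"))

  agg <- runStage("aggregate", {
    aggregateReplicates(attachExtracts(bdf, layouts), pool = config$pool)
  })
  logStage(lvl, "aggregate", "%d extract x parameter aggregates (%.1fs)",
           nrow(agg), stageElapsed("aggregate"))

  excl <- runStage("exclude", {
    excludeCytotoxic(agg, cellCountCut = config$cellCountCut,
                     hoechstCut = config$hoechstCut, mode = config$toxMode,
                     rankFraction = config$rankFraction)
  })
  logStage(lvl, "exclude", "%d extracts kept, %d excluded as cytotoxic (%.1fs)",
           length(unique(excl$kept$extract_id)),
           length(unique(excl$excluded$extract_id)), stageElapsed("exclude"))

  bands <- runStage("band", {
    bs <- lapply(config$callParameters, function(p)
      computeBand(excl$kept, p, k = config$k,
                  madConstant = config$madConstant))
    stats::setNames(bs, config$callParameters)
  })

  hits <- runStage("call-hits", {
    callHits(excl$kept, bands, parameters = config$callParameters)
  })
  logStage(lvl, "call-hits", "%d hit calls (%.1fs)", nrow(hits),
           stageElapsed("call-hits"))

  extracts <- agg
  excludedIds <- unique(excl$excluded$extract_id)
  extracts$excluded <- extracts$extract_id %in% excludedIds
  extracts$exclusion_reason <- excl$excluded$exclusion_reason[
    match(extracts$extract_id, excl$excluded$extract_id)]
  utils::write.csv(extracts, file.path(outDir, "extracts.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(hits, file.path(outDir, "hits.csv"),
                   row.names = FALSE, quote = FALSE)

  bias <- runStage("qc", {
    matrices <- buildPlateMatrices(wells, layouts)
    rbind(biasReport(matrices, stage = "raw", mode = "pooled"),
          biasReport(tr$decompositions, stage = "bscore", mode = "pooled"))
  })
  utils::write.csv(bias, file.path(outDir, "bias_report.csv"),
                   row.names = FALSE, quote = FALSE)
  logStage(lvl, "qc", "%d bias diagnostics (%.1fs)", nrow(bias),
           stageElapsed("qc"))

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- evaluateRecovery(hits, truth, excludedIds = excludedIds,
                                 parameters = config$callParameters)
    utils::write.csv(recovery$per_parameter,
                     file.path(outDir, "recovery.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  resolved <- unclass(config)
  # the output location is not part of the analysis configuration: the
  # same inputs, settings and seed give byte-identical artifacts wherever
  # they are written
  resolved$outputDir <- NULL
  resolvedPath <- file.path(outDir, "config_resolved.yaml")
  yaml::write_yaml(resolved, resolvedPath)
  files <- list.files(outDir)
  manifest <- list(
    package = "hcscreen",
    version = as.character(utils::packageVersion("hcscreen")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(resolvedPath)),
    outputs = sort(setdiff(files, "manifest.yaml")))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))

  invisible(list(wells = wells, layouts = layouts, transform = tr,
                 bscores = bdf, aggregates = agg, kept = excl$kept,
                 excluded = excl$excluded, bands = bands, hits = hits,
                 bias = bias, recovery = recovery, truth = truth,
                 files = file.path(outDir, sort(files))))
}
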