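#' @include bias.R
NULL

#' Configuration of a synthetic screen
#'
#' Parameterizes the seeded generator that stands in for raw screen data.
#' The generative model is additive, matching the assumption under which
#' the B-score is exact: for parameter p in well (i, j),
#' `y = mu_p + R_i + C_j + theta * sigma_p + N(0, sigma_p)`, with `R`/`C`
#' a perimeter depression of `perimeterDelta` within-plate standard
#' deviations on the outer rows and columns, `theta` the extract's true
#' effect in sigma units, plus DMSO control wells, artifact-masked wells
#' and toxic extracts (depressed cell count, elevated nuclear-stain
#' intensity).
#'
#' Defaults describe the emulated study design: 1319 extracts on 96-well
#' plates (8 DMSO controls, one per row, alternating between columns 1 and
#' 12 so no plate line is ever fully excluded; 88 sample wells per plate,
#' so 15 plates), 5 replicate screens, 15% cytotoxic extracts (-7 sigma on cell
#' count, +6 sigma on Hoechst: most cells dead, intensely condensed
#' nuclear staining), 0.5% true hits at 4-5 sigma on the
#' reporter channels (one in five a down-hit), 0.5% artifact wells, and a
#' perimeter depression of 2 within-plate SDs. Because the within-plate
#' residual dispersion is the well noise, sigma units coincide (up to MAD
#' estimation error) with B-score units.
#'
#' @param nRows,nCols Plate geometry (default 8 x 12).
#' @param nReplicates Number of replicate screens (default 5).
#' @param nExtracts Library size (default 1319).
#' @param nPlates Plates per replicate; `NULL` (default) derives the
#'   minimum covering all extracts.
#' @param controlWells Labels of the DMSO wells on every plate (default:
#'   one per row, alternating columns 1 and 12).
#' @param baseline Named baseline means `mu_p` (arbitrary fluorescence
#'   units; counts for `cell_count`).
#' @param sigma Named well-noise SDs `sigma_p`.
#' @param perimeterDelta Perimeter depression amplitude, in units of
#'   `sigma_p` (applied to each outer row and column; a corner well is
#'   depressed twice).
#' @param multiplicativeBias If `TRUE`, the row/column bias multiplies the
#'   signal (relative magnitude matched to the additive case) instead of
#'   adding — a robustness option violating the additive model.
#' @param hitFraction Fraction of extracts that are true hits
#'   (default 0.005).
#' @param hitEffectRange Range of |theta| for hits, in sigma units
#'   (default 4 to 5).
#' @param hitDownProb Probability a hit is a down-hit (default 0.2).
#' @param hitChannelProbs Probabilities a hit affects insulin only, pdx1
#'   only, or both (must sum to 1).
#' @param toxicFraction Fraction of cytotoxic extracts (default 0.15).
#' @param toxicCellCountEffect,toxicHoechstEffect Toxicity effects in
#'   sigma units (defaults -7 and +6, sized so that after the plate-MAD
#'   inflation and median-polish absorption a 15% contamination causes,
#'   toxic extracts clear the +/-2 exclusion cutoffs with about a 2-SD
#'   margin).
#' @param artifactRate Per-replicate probability a sample well is masked
#'   as an imaging artifact (default 0.005).
#' @param cellsPerWell Mean cells per well, lambda, for the cell-level
#'   generator (default 50).
#' @param cellSdLog Log-scale SD of the right-skewed (log-normal) per-cell
#'   intensity distribution (default 0.5).
#' @param rngSeed Default seed used by the generators (default 1).
#' @return A validated `SyntheticConfig` (classed list).
#' @export
syntheticConfig <- function(nRows = 8L, nCols = 12L, nReplicates = 5L,
                            nExtracts = 1319L, nPlates = NULL,
                            controlWells = formatWellLabel(0:7, rep(c(0L, 11L), 4)),
                            baseline = c(insulin = 500, pdx1 = 400,
                                         hoechst = 800, cell_count = 50),
                            sigma = c(insulin = 50, pdx1 = 40,
                                      hoechst = 80, cell_count = 7),
                            perimeterDelta = 2, multiplicativeBias = FALSE,
                            hitFraction = 0.005, hitEffectRange = c(4, 5),
                            hitDownProb = 0.2,
                            hitChannelProbs = c(insulin = 0.4, pdx1 = 0.4,
                                                both = 0.2),
                            toxicFraction = 0.15,
                            toxicCellCountEffect = -7,
                            toxicHoechstEffect = 6,
                            artifactRate = 0.005,
                            cellsPerWell = 50, cellSdLog = 0.5,
                            rngSeed = 1L) {
  cfg <- list(nRows = as.integer(nRows), nCols = as.integer(nCols),
              nReplicates = as.integer(nReplicates),
              nExtracts = as.integer(nExtracts),
              controlWells = controlWells, baseline = baseline,
              sigma = sigma, perimeterDelta = perimeterDelta,
              multiplicativeBias = isTRUE(multiplicativeBias),
              hitFraction = hitFraction, hitEffectRange = hitEffectRange,
              hitDownProb = hitDownProb, hitChannelProbs = hitChannelProbs,
              toxicFraction = toxicFraction,
              toxicCellCountEffect = toxicCellCountEffect,
              toxicHoechstEffect = toxicHoechstEffect,
              artifactRate = artifactRate, cellsPerWell = cellsPerWell,
              cellSdLog = cellSdLog, rngSeed = as.integer(rngSeed))
  slots <- cfg$nRows * cfg$nCols - length(controlWells)
  cfg$nPlates <- if (is.null(nPlates)) as.integer(ceiling(cfg$nExtracts / slots))
                 else as.integer(nPlates)
  params <- screenParameters()
  if (!all(params %in% names(cfg$baseline)) || !all(params %in% names(cfg$sigma)))
    stopf("baseline and sigma must be named for all of: %s",
          paste(params, collapse = ", "))
  fr <- c(hitFraction = cfg$hitFraction, toxicFraction = cfg$toxicFraction,
          artifactRate = cfg$artifactRate, hitDownProb = cfg$hitDownProb)
  if (any(fr < 0 | fr > 1))
    stopf("fractions must lie in [0, 1]: %s",
          paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
  if (any(cfg$sigma < 0)) stopf("sigma must be nonnegative")
  if (abs(sum(cfg$hitChannelProbs) - 1) > 1e-8)
    stopf("hitChannelProbs must sum to 1")
  if (cfg$nExtracts > cfg$nPlates * slots)
    stopf("more extracts (%d) than sample wells (%d plates x %d slots)",
          cfg$nExtracts, cfg$nPlates, slots)
  parseWellLabel(controlWells, cfg$nRows, cfg$nCols)
  class(cfg) <- "SyntheticConfig"
  cfg
}

## per-replicate layouts: every replicate screen re-randomizes the
## assignment of extracts to wells (so that a chance cluster of toxic
## extracts along one plate line in one replicate is broken up in the
## others); each replicate's physical plates carry unique ids
syntheticLayouts <- function(cfg, seed, replicate) {
  slots <- allWellLabels(cfg$nRows, cfg$nCols)
  sampleSlots <- setdiff(slots, cfg$controlWells)
  plateIds <- sprintf("R%d-P%02d", replicate, seq_len(cfg$nPlates))
  slotTab <- expand.grid(well = sampleSlots, plate_id = plateIds,
                         stringsAsFactors = FALSE)[, c("plate_id", "well")]
  repSeed <- (childSeed(seed, "assign") + replicate * 7919) %% 2147483629
  ord <- withSeed(repSeed, sample.int(nrow(slotTab)))
  slotTab <- slotTab[ord, , drop = FALSE]
  ids <- sprintf("E%04d", seq_len(cfg$nExtracts))
  slotTab$extract_id <- NA_character_
  slotTab$extract_id[seq_along(ids)] <- ids
  lapply(stats::setNames(plateIds, plateIds), function(pid) {
    d <- slotTab[slotTab$plate_id == pid, , drop = FALSE]
    used <- !is.na(d$extract_id)
    wells <- rbind(
      data.frame(well = cfg$controlWells, role = "control",
                 extract_id = NA_character_, dose_label = "DMSO",
                 stringsAsFactors = FALSE),
      data.frame(well = d$well[used], role = "sample",
                 extract_id = d$extract_id[used],
                 dose_label = "initial", stringsAsFactors = FALSE))
    PlateLayout(pid, wells, cfg$nRows, cfg$nCols)
  })
}

## ground truth: disjoint toxic and hit sets, theta in sigma units
syntheticTruth <- function(cfg, seed) {
  ids <- sprintf("E%04d", seq_len(cfg$nExtracts))
  n <- cfg$nExtracts
  withSeed(childSeed(seed, "effects"), {
    nToxic <- round(cfg$toxicFraction * n)
    nHits <- round(cfg$hitFraction * n)
    pick <- sample(ids, nToxic + nHits)
    toxicIds <- pick[seq_len(nToxic)]
    hitIds <- pick[nToxic + seq_len(nHits)]
    th <- matrix(0, n, 4, dimnames = list(ids, screenParameters()))
    th[toxicIds, "cell_count"] <- cfg$toxicCellCountEffect
    th[toxicIds, "hoechst"] <- cfg$toxicHoechstEffect
    label <- rep("null", n); names(label) <- ids
    label[toxicIds] <- "toxic"
    for (id in hitIds) {
      eff <- stats::runif(1, cfg$hitEffectRange[1], cfg$hitEffectRange[2])
      sgn <- if (stats::runif(1) < cfg$hitDownProb) -1 else 1
      chan <- sample(names(cfg$hitChannelProbs), 1, prob = cfg$hitChannelProbs)
      target <- switch(chan, insulin = "insulin", pdx1 = "pdx1",
                       both = c("insulin", "pdx1"))
      th[id, target] <- sgn * eff
      label[id] <- if (sgn > 0) "hit_up" else "hit_down"
    }
    data.frame(extract_id = ids, label = unname(label),
               theta_insulin = th[, "insulin"], theta_pdx1 = th[, "pdx1"],
               theta_hoechst = th[, "hoechst"],
               theta_cellcount = th[, "cell_count"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

## per-well noiseless targets for one replicate: data.frame with one row
## per non-empty well x parameter, column target (= mu + bias + theta*sigma)
syntheticTargets <- function(cfg, layouts, truth) {
  params <- screenParameters()
  thetas <- as.matrix(truth[, paste0("theta_", sub("cell_count", "cellcount", params))])
  rownames(thetas) <- truth$extract_id
  rows <- list()
  for (pid in names(layouts)) {
    w <- wellRoles(layouts[[pid]])
    w <- w[w$role != "empty", , drop = FALSE]
    idx <- parseWellLabel(w$well, cfg$nRows, cfg$nCols)
    perim <- (idx[, "row"] %in% c(0L, cfg$nRows - 1L)) +
             (idx[, "col"] %in% c(0L, cfg$nCols - 1L))
    for (k in seq_along(params)) {
      p <- params[k]
      mu <- cfg$baseline[[p]]; sg <- cfg$sigma[[p]]
      theta <- thetas[match(w$extract_id, rownames(thetas)), k]
      theta[is.na(theta)] <- 0
      bias <- -cfg$perimeterDelta * sg * perim
      target <- if (cfg$multiplicativeBias)
        (mu + theta * sg) * (1 + bias / mu) else mu + theta * sg + bias
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = pid, well = w$well, role = w$role,
        extract_id = w$extract_id, parameter = p, target = target,
        sigma = sg, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## list of per-replicate layout lists, plus the flat combination
syntheticAllLayouts <- function(cfg, seed) {
  perRep <- lapply(seq_len(cfg$nReplicates), function(rep)
    syntheticLayouts(cfg, seed, rep))
  names(perRep) <- sprintf("R%d", seq_len(cfg$nReplicates))
  list(perRep = perRep, flat = do.call(c, unname(perRep)))
}

syntheticMask <- function(cfg, perRepLayouts, seed) {
  rows <- list()
  withSeed(childSeed(seed, "artifact"), {
    for (rep in seq_len(cfg$nReplicates)) {
      rid <- sprintf("R%d", rep)
      for (pid in names(perRepLayouts[[rid]])) {
        w <- wellRoles(perRepLayouts[[rid]][[pid]])
        sw <- w$well[w$role == "sample"]
        hitMask <- stats::runif(length(sw)) < cfg$artifactRate
        if (any(hitMask))
          rows[[length(rows) + 1L]] <- data.frame(
            plate_id = pid, replicate_id = rid, well = sw[hitMask],
            reason = "artifact", stringsAsFactors = FALSE)
      }
    }
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(plate_id = character(0), replicate_id = character(0),
               well = character(0), reason = character(0))
}

#' Generate a synthetic screen at the well level
#'
#' Draws per-well parameter values for every replicate under the additive
#' model of [syntheticConfig()], producing exactly the structures the rest
#' of the pipeline consumes, plus the ground truth. Deterministic: the same
#' (config, seed) yields identical output, down to the bytes of the CSVs
#' written by [writeScreenData()].
#'
#' @param config A [syntheticConfig()].
#' @param seed Integer seed (default `config$rngSeed`).
#' @return List with `wells` (long well-summary `data.frame` as from
#'   [summarizeScreen()]), `layouts` (named list of [PlateLayout-class]),
#'   `mask` (artifact mask `data.frame`), `truth` (per-extract labels and
#'   effects in sigma units), `config`, `seed`.
#' @export
generateWellLevel <- function(config, seed = config$rngSeed) {
  stopifnot(inherits(config, "SyntheticConfig"))
  lay <- syntheticAllLayouts(config, seed)
  truth <- syntheticTruth(config, seed)
  mask <- syntheticMask(config, lay$perRep, seed)
  maskKey <- paste(mask$plate_id, mask$replicate_id, mask$well)
  rows <- list()
  withSeed(childSeed(seed, "noise"), {
    for (rep in seq_len(config$nReplicates)) {
      rid <- sprintf("R%d", rep)
      d <- syntheticTargets(config, lay$perRep[[rid]], truth)
      d$replicate_id <- rid
      d$value <- d$target + stats::rnorm(nrow(d), 0, d$sigma)
      masked <- paste(d$plate_id, rid, d$well) %in% maskKey
      d$valid <- d$role == "sample" & !masked
      d$reason <- ifelse(masked, "artifact",
                         ifelse(d$role == "control", "control", NA_character_))
      rows[[length(rows) + 1L]] <- d
    }
  })
  wells <- do.call(rbind, rows)
  wells$n_cells <- NA_integer_
  wells <- wells[c("plate_id", "replicate_id", "well", "parameter", "value",
                   "n_cells", "valid", "reason")]
  rownames(wells) <- NULL
  list(wells = wells, layouts = lay$flat, mask = mask, truth = truth,
       config = config, seed = as.integer(seed))
}

#' Generate a synthetic screen at the per-cell level
#'
#' Like [generateWellLevel()] but emits per-cell records: each well's cell
#' count is Poisson with mean `cellsPerWell` scaled by the extract's
#' relative cell-count target (toxic extracts deplete it), and per-cell
#' channel intensities are log-normal — positive and right-skewed, as
#' fluorescence heterogeneity is — with median equal to the well's target
#' value, so that [summarizeWell()] composed with this generator agrees
#' with [generateWellLevel()] in distribution (exactly so as
#' `cellsPerWell` grows).
#'
#' @inheritParams generateWellLevel
#' @return List with `cells` (cell-record `data.frame` in the
#'   [readCellTable()] schema), plus `layouts`, `mask`, `truth`, `config`,
#'   `seed` as in [generateWellLevel()].
#' @export
generateCellLevel <- function(config, seed = config$rngSeed) {
  stopifnot(inherits(config, "SyntheticConfig"))
  lay <- syntheticAllLayouts(config, seed)
  truth <- syntheticTruth(config, seed)
  mask <- syntheticMask(config, lay$perRep, seed)
  channels <- defaultChannelMap()
  muCC <- config$baseline[["cell_count"]]
  rows <- list()
  withSeed(childSeed(seed, "cells"), {
    for (rep in seq_len(config$nReplicates)) {
      rid <- sprintf("R%d", rep)
      targets <- syntheticTargets(config, lay$perRep[[rid]], truth)
      # wide per-well targets, one row per well
      wt <- stats::reshape(targets, idvar = c("plate_id", "well"),
                           timevar = "parameter",
                           v.names = "target", direction = "wide",
                           drop = c("sigma"))
      names(wt) <- sub("^target\\.", "", names(wt))
      for (i in seq_len(nrow(wt))) {
        lambda <- config$cellsPerWell *
          max(0, wt$cell_count[i] / muCC)
        n <- stats::rpois(1, lambda)
        if (n == 0L) next
        rec <- data.frame(plate_id = wt$plate_id[i], replicate_id = rid,
                          well = wt$well[i], object_id = seq_len(n),
                          stringsAsFactors = FALSE)
        for (ch in names(channels)) {
          p <- channels[[ch]]
          med <- max(wt[[p]][i], 0.05 * config$baseline[[p]])
          avg <- stats::rlnorm(n, meanlog = log(med), sdlog = config$cellSdLog)
          area <- stats::rlnorm(n, meanlog = log(100), sdlog = 0.25)
          rec[[paste0(ch, "_avg")]] <- avg
          rec[[paste0(ch, "_total")]] <- avg * area
          rec[[paste0(ch, "_var")]] <- (0.2 * avg)^2 *
            stats::rchisq(n, df = 5) / 5
        }
        rows[[length(rows) + 1L]] <- rec
      }
    }
  })
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  list(cells = cells, layouts = lay$flat, mask = mask, truth = truth,
       config = config, seed = as.integer(seed))
}

#' Write a generated screen to CSV files
#'
#' Emits the pipeline's canonical schemas into a directory:
#' `platemap.csv`, `mask.csv`, `truth.csv`, plus `wells.csv` (well-level
#' output) or `cells.csv` (cell-level output), whichever the generator
#' produced.
#'
#' @param sim Output of [generateWellLevel()] or [generateCellLevel()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
writeScreenData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  f <- file.path(dir, "platemap.csv")
  writePlateMap(sim$layouts, f); files <- c(files, f)
  f <- file.path(dir, "mask.csv")
  writeWellMask(sim$mask, f); files <- c(files, f)
  f <- file.path(dir, "truth.csv")
  utils::write.csv(sim$truth, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)
  if (!is.null(sim$wells)) {
    f <- file.path(dir, "wells.csv")
    writeWellTable(sim$wells, f); files <- c(files, f)
  }
  if (!is.null(sim$cells)) {
    f <- file.path(dir, "cells.csv")
    writeCellTable(sim$cells, f); files <- c(files, f)
  }
  invisible(files)
}

#' Confusion summary of hit calls against ground truth
#'
#' Scores a hit-call table and the cytotoxicity exclusion against the
#' generator's ground truth. A call counts as a true positive only when
#' its direction matches the sign of the true effect.
#'
#' @param hits Hit calls from [callHits()].
#' @param truth Ground-truth `data.frame` from the generators.
#' @param excludedIds Optional character vector of extract ids excluded as
#'   cytotoxic (from [excludeCytotoxic()]).
#' @param parameters Parameters scored (default `insulin`, `pdx1`).
#' @return List: `per_parameter` (`data.frame` with `parameter`,
#'   `n_spiked`, `n_called`, `true_positives`, `false_positives`,
#'   `sensitivity`, `specificity`, `fdr`, `null_call_rate`) and
#'   `exclusion` (`toxic_excluded_rate`, `clean_excluded_rate`, counts;
#'   `NA` when `excludedIds` is not given).
#' @export
evaluateRecovery <- function(hits, truth, excludedIds = NULL,
                             parameters = c("insulin", "pdx1")) {
  badIds <- setdiff(unique(c(hits$extract_id, excludedIds)), truth$extract_id)
  if (length(badIds))
    stopf("extract(s) absent from the ground truth: %s",
          paste(utils::head(badIds, 5), collapse = ", "))
  thetaCol <- function(p) paste0("theta_", sub("cell_count", "cellcount", p))
  perPar <- lapply(parameters, function(p) {
    theta <- stats::setNames(truth[[thetaCol(p)]], truth$extract_id)
    toxic <- truth$label == "toxic"
    spiked <- truth$extract_id[!toxic & theta[truth$extract_id] != 0]
    nulls <- truth$extract_id[!toxic & theta[truth$extract_id] == 0]
    h <- hits[hits$parameter == p, , drop = FALSE]
    dirOk <- (h$direction == "up") == (theta[h$extract_id] > 0)
    tp <- sum(h$extract_id %in% spiked & dirOk)
    fp <- nrow(h) - tp
    nullCalled <- sum(h$extract_id %in% nulls)
    data.frame(parameter = p, n_spiked = length(spiked), n_called = nrow(h),
               true_positives = tp, false_positives = fp,
               sensitivity = if (length(spiked)) tp / length(spiked) else NA_real_,
               specificity = if (length(nulls))
                 1 - nullCalled / length(nulls) else NA_real_,
               fdr = if (nrow(h)) fp / nrow(h) else 0,
               null_call_rate = if (length(nulls))
                 nullCalled / length(nulls) else NA_real_,
               stringsAsFactors = FALSE)
  })
  exclusion <- list(toxic_excluded_rate = NA_real_,
                    clean_excluded_rate = NA_real_,
                    n_toxic = sum(truth$label == "toxic"),
                    n_clean = sum(truth$label != "toxic"))
  if (!is.null(excludedIds)) {
    toxicIds <- truth$extract_id[truth$label == "toxic"]
    cleanIds <- truth$extract_id[truth$label != "toxic"]
    exclusion$toxic_excluded_rate <-
      if (length(toxicIds)) mean(toxicIds %in% excludedIds) else NA_real_
    exclusion$clean_excluded_rate <-
      if (length(cleanIds)) mean(cleanIds %in% excludedIds) else NA_real_
  }
  list(per_parameter = do.call(rbind, perPar), exclusion = exclusion)
}
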