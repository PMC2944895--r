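#' @include medpolish.R
NULL

#' Attach extract identifiers to a B-score table
#'
#' Joins the plate-map roles onto a long B-score table and keeps sample
#' wells, so replicate B-scores can be aggregated per extract.
#'
#' @param bscoreDf Long table from [bscoreTable()].
#' @param layouts A [PlateLayout-class] or named list of them.
#' @return The table with `extract_id` and `role` columns, sample wells
#'   only.
#' @export
attachExtracts <- function(bscoreDf, layouts) {
  if (methods::is(layouts, "PlateLayout"))
    layouts <- stats::setNames(list(layouts), plateId(layouts))
  if (is.null(names(layouts)))
    names(layouts) <- vapply(layouts, plateId, character(1))
  roleTab <- do.call(rbind, lapply(layouts, function(l) {
    w <- wellRoles(l)
    data.frame(plate_id = plateId(l), well = w$well, role = w$role,
               extract_id = w$extract_id, stringsAsFactors = FALSE)
  }))
  out <- merge(bscoreDf, roleTab, by = c("plate_id", "well"), sort = FALSE)
  out[out$role == "sample" & !is.na(out$extract_id), , drop = FALSE]
}

#' Aggregate replicate B-scores per extract
#'
#' Averages each extract's B-scores over replicate screens, per parameter:
#' `mean_bscore` is the plain mean, `sem` the standard error of that mean
#' (sample standard deviation, n-1 denominator, divided by sqrt(n)).
#' Extracts observed in a single replicate have no SEM; they are flagged
#' (`flagged_single`) and later skipped by [callHits()].
#'
#' An extract mapped to several wells within one replicate has no unique
#' replicate value; that is an error unless `pool = "mean"`, which averages
#' the within-replicate wells first.
#'
#' @param bscoreDf Long table with columns `extract_id`, `replicate_id`,
#'   `parameter`, `bscore` (see [attachExtracts()]).
#' @param pool `"error"` (default) or `"mean"`.
#' @return `data.frame`: `extract_id`, `parameter`, `mean_bscore`, `sem`,
#'   `n_replicates`, `flagged_single`.
#' @examples
#' df <- data.frame(extract_id = "X", replicate_id = c("R1", "R2", "R3"),
#'                  parameter = "insulin", bscore = c(1, 2, 3))
#' aggregateReplicates(df)  # mean 2, sem 1/sqrt(3)
#' @export
aggregateReplicates <- function(bscoreDf, pool = c("error", "mean")) {
  pool <- match.arg(pool)
  need <- c("extract_id", "replicate_id", "parameter", "bscore")
  miss <- setdiff(need, names(bscoreDf))
  if (length(miss))
    stopf("bscoreDf is missing column(s): %s", paste(miss, collapse = ", "))
  key <- paste(bscoreDf$extract_id, bscoreDf$replicate_id, bscoreDf$parameter,
               sep = "\r")
  if (anyDuplicated(key)) {
    if (pool == "error") {
      dup <- bscoreDf$extract_id[duplicated(key)]
      stopf("extract(s) mapped to multiple wells within one replicate (set pool = \"mean\" to average): %s",
            paste(unique(dup), collapse = ", "))
    }
    bscoreDf <- stats::aggregate(bscore ~ extract_id + replicate_id + parameter,
                                 data = bscoreDf, FUN = mean)
  }
  agg <- stats::aggregate(bscore ~ extract_id + parameter, data = bscoreDf,
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x),
                                              n = length(x)))
  out <- data.frame(extract_id = agg$extract_id, parameter = agg$parameter,
                    mean_bscore = agg$bscore[, "mean"],
                    sem = agg$bscore[, "sd"] / sqrt(agg$bscore[, "n"]),
                    n_replicates = as.integer(agg$bscore[, "n"]),
                    stringsAsFactors = FALSE)
  out$flagged_single <- out$n_replicates < 2L
  out$sem[out$flagged_single] <- NA_real_
  out <- out[order(out$extract_id, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude cytotoxic extracts before hit calling
#'
#' Cytotoxic extracts kill cells: their wells show a depressed cell count
#' and intense, condensed Hoechst nuclear staining (the apoptotic
#' signature). Such extracts must be removed before the hit band is
#' computed, both because their reporter readouts are uninterpretable and
#' because they would inflate the band.
#'
#' The threshold rule excludes an extract when its mean `cell_count`
#' B-score is at or below `cellCountCut` and/or its mean `hoechst` B-score
#' is at or above `hoechstCut`, combined according to `mode` (`"both"` =
#' conjunction, default; `"either"`; `"cell_count_only"`). The alternative
#' `mode = "rank"` excludes the bottom `rankFraction` of extracts by mean
#' cell-count B-score, reproducing a fixed exclusion rate directly.
#'
#' @param aggregates Output of [aggregateReplicates()]; must carry
#'   `cell_count` and `hoechst` rows for every extract.
#' @param cellCountCut Cell-count B-score cutoff (default -2).
#' @param hoechstCut Hoechst B-score cutoff (default +2).
#' @param mode Combination rule, see above.
#' @param rankFraction Fraction excluded under `mode = "rank"`
#'   (default 0.15).
#' @return List with `kept` and `excluded` (each shaped like `aggregates`,
#'   `excluded` gains an `exclusion_reason` column); the two partition the
#'   input extracts.
#' @export
excludeCytotoxic <- function(aggregates, cellCountCut = -2.0, hoechstCut = 2.0,
                             mode = c("both", "either", "cell_count_only", "rank"),
                             rankFraction = 0.15) {
  mode <- match.arg(mode)
  wideOf <- function(p) {
    d <- aggregates[aggregates$parameter == p, c("extract_id", "mean_bscore")]
    stats::setNames(d$mean_bscore, d$extract_id)
  }
  ids <- unique(aggregates$extract_id)
  cc <- wideOf("cell_count")[ids]
  ho <- wideOf("hoechst")[ids]
  if (anyNA(cc) || anyNA(ho))
    stopf("extract(s) missing a toxicity parameter (cell_count/hoechst): %s",
          paste(ids[is.na(cc) | is.na(ho)], collapse = ", "))
  lowCount <- cc <= cellCountCut
  highHoechst <- ho >= hoechstCut
  toxic <- switch(mode,
    both = lowCount & highHoechst,
    either = lowCount | highHoechst,
    cell_count_only = lowCount,
    rank = rank(cc, ties.method = "first") <= round(rankFraction * length(cc)))
  reason <- ifelse(toxic,
                   switch(mode,
                          both = "low_cell_count+high_hoechst",
                          either = "low_cell_count_or_high_hoechst",
                          cell_count_only = "low_cell_count",
                          rank = "cell_count_rank"),
                   NA_character_)
  toxicIds <- ids[toxic]
  kept <- aggregates[!aggregates$extract_id %in% toxicIds, , drop = FALSE]
  excluded <- aggregates[aggregates$extract_id %in% toxicIds, , drop = FALSE]
  excluded$exclusion_reason <- reason[match(excluded$extract_id, ids)]
  rownames(kept) <- rownames(excluded) <- NULL
  list(kept = kept, excluded = excluded)
}

#' Compute the hit band for one parameter
#'
#' The significance band is centered on the median of the post-exclusion
#' extract means with halfwidth `k * madConstant * median(|mean - center|)`
#' — the robust analogue of a mean +/- k standard deviations band, immune
#' to the hits themselves. A zero raw MAD (possible when a majority of
#' means coincide) gives a degenerate zero-width band and a warning.
#'
#' @param aggregates Kept aggregates from [excludeCytotoxic()].
#' @param parameter Parameter to band (e.g. `"insulin"`).
#' @param k Band halfwidth in scaled-MAD units (default 2).
#' @param madConstant MAD scale constant (default 1.4826, matching the
#'   B-score scaling).
#' @return A [HitBand-class] object.
#' @examples
#' agg <- data.frame(extract_id = letters[1:5], parameter = "insulin",
#'                   mean_bscore = 1:5)
#' computeBand(agg, "insulin", k = 2, madConstant = 1)  # band [1, 5]
#' @export
computeBand <- function(aggregates, parameter, k = 2.0, madConstant = 1.4826) {
  means <- aggregates$mean_bscore[aggregates$parameter == parameter]
  means <- means[!is.na(means)]
  if (length(means) < 3L)
    stopf("need at least 3 extracts to compute a band for %s (got %d)",
          parameter, length(means))
  center <- stats::median(means)
  halfwidth <- k * scaledMad(means, constant = madConstant, center = center)
  degenerate <- halfwidth == 0
  if (degenerate)
    warnf("degenerate band for %s: raw MAD of extract means is zero", parameter)
  methods::new("HitBand", parameter = parameter, center = center,
               halfwidth = halfwidth, lower = center - halfwidth,
               upper = center + halfwidth, k = k, madConstant = madConstant,
               nExtracts = length(means), degenerate = degenerate)
}

#' Call hits by the SEM non-overlap rule
#'
#' An extract is a hit for a parameter when its whole mean +/- SEM interval
#' lies strictly outside the hit band: `mean - sem > upper` (direction
#' `"up"`) or `mean + sem < lower` (direction `"down"`). An interval
#' touching the band line is not a hit. Extracts without a SEM (single
#' replicate) are skipped with a warning; non-hits are absent from the
#' output.
#'
#' @param aggregates Kept aggregates from [excludeCytotoxic()].
#' @param bands Named list of [HitBand-class] objects keyed by parameter
#'   (one per parameter being called), or a single band.
#' @param parameters Parameters to call (default `insulin` and `pdx1`, the
#'   reporter channels).
#' @return `data.frame`: `extract_id`, `parameter`, `direction`,
#'   `mean_bscore`, `sem`, `band_lower`, `band_upper`.
#' @export
callHits <- function(aggregates, bands,
                     parameters = c("insulin", "pdx1")) {
  if (methods::is(bands, "HitBand"))
    bands <- stats::setNames(list(bands), parameterName(bands))
  miss <- setdiff(parameters, names(bands))
  if (length(miss))
    stopf("no band available for parameter(s): %s", paste(miss, collapse = ", "))
  out <- list()
  for (p in parameters) {
    b <- bands[[p]]
    d <- aggregates[aggregates$parameter == p, , drop = FALSE]
    noSem <- is.na(d$sem)
    if (any(noSem)) {
      warnf("skipping %d extract(s) without a SEM for %s (single replicate)",
            sum(noSem), p)
      d <- d[!noSem, , drop = FALSE]
    }
    up <- d$mean_bscore - d$sem > b@upper
    down <- d$mean_bscore + d$sem < b@lower
    hit <- up | down
    if (any(hit)) {
      out[[p]] <- data.frame(
        extract_id = d$extract_id[hit], parameter = p,
        direction = ifelse(up[hit], "up", "down"),
        mean_bscore = d$mean_bscore[hit], sem = d$sem[hit],
        band_lower = b@lower, band_upper = b@upper,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(extract_id = character(0), parameter = character(0),
                      direction = character(0), mean_bscore = numeric(0),
                      sem = numeric(0), band_lower = numeric(0),
                      band_upper = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
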