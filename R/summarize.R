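#' @include io.R
NULL

## long-format rows for one well's summary; values NA when no cells
wellSummaryRows <- function(plate, replicate, well, n, stats, valid, reason) {
  data.frame(plate_id = plate, replicate_id = replicate, well = well,
             parameter = names(stats), value = unname(stats),
             n_cells = n, valid = valid, reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}

summaryParameterNames <- function(channels = defaultChannelMap()) {
  base <- c(unname(channels), "cell_count")
  aux <- c(paste0(unname(channels), "_q99"), paste0(unname(channels), "_var"))
  c(base, aux)
}

#' Summarize one well's cells into per-parameter values
#'
#' Collapses the per-cell measurements of a single well into robust per-well
#' statistics: for each channel the median per-cell average intensity (the
#' headline parameter), the upper quantile (default the 99th, capturing
#' responses confined to a small subpopulation of cells) and the median
#' per-cell intensity variance; plus the object count as the `cell_count`
#' parameter. The median is used because it is insensitive to a few
#' outlying cells, while the upper quantile deliberately is not — that
#' asymmetry is the point of reporting both.
#'
#' @param cells Cell records (see [readCellTable()]) sharing one
#'   (plate_id, replicate_id, well); anything else is an error.
#' @param quantileP Upper-quantile probability (default 0.99), evaluated by
#'   linear interpolation at position `1 + (n - 1) * p`.
#' @param channels Channel-to-parameter mapping, see [defaultChannelMap()].
#' @param minCells Optional floor on cell count; wells below it are flagged
#'   invalid with reason `"few_cells"`. Default 0 (off).
#' @return Long `data.frame` with columns `plate_id`, `replicate_id`,
#'   `well`, `parameter`, `value`, `n_cells`, `valid`, `reason`; one row
#'   per parameter (headline parameters plus `<param>_q99` / `<param>_var`
#'   auxiliaries). With zero cells, intensity values are `NA` and the well
#'   is flagged invalid with reason `"no_cells"`.
#' @examples
#' cells <- data.frame(plate_id = "P1", replicate_id = "R1", well = "B02",
#'                     object_id = 1:3,
#'                     ch1_avg = c(1, 2, 3), ch1_total = 1, ch1_var = 0.1,
#'                     ch2_avg = c(10, 20, 30), ch2_total = 1, ch2_var = 0.1,
#'                     ch3_avg = c(5, 5, 8), ch3_total = 1, ch3_var = 0.1)
#' summarizeWell(cells)
#' @export
summarizeWell <- function(cells, quantileP = 0.99, channels = defaultChannelMap(),
                          minCells = 0L) {
  params <- summaryParameterNames(channels)
  if (nrow(cells) == 0L) {
    stats <- stats::setNames(rep(NA_real_, length(params)), params)
    stats[["cell_count"]] <- 0
    return(wellSummaryRows(NA_character_, NA_character_, NA_character_,
                           0L, stats, FALSE, "no_cells"))
  }
  key <- unique(cells[c("plate_id", "replicate_id", "well")])
  if (nrow(key) != 1L)
    stopf("summarizeWell expects records from one well; got %d distinct (plate, replicate, well) keys",
          nrow(key))
  n <- nrow(cells)
  stats <- numeric(0)
  for (ch in names(channels)) {
    p <- channels[[ch]]
    avg <- cells[[paste0(ch, "_avg")]]
    stats[[p]] <- stats::median(avg)
    stats[[paste0(p, "_q99")]] <- interpQuantile(avg, quantileP)
    stats[[paste0(p, "_var")]] <- stats::median(cells[[paste0(ch, "_var")]])
  }
  stats[["cell_count"]] <- n
  stats <- stats[params]
  valid <- n >= minCells
  wellSummaryRows(key$plate_id, key$replicate_id, key$well, n, stats,
                  valid, if (valid) NA_character_ else "few_cells")
}

#' Summarize a whole screen's cells into per-well values
#'
#' Applies [summarizeWell()] across every non-empty well of every plate and
#' replicate present in `cells`. Control wells and masked wells are carried
#' through with `valid = FALSE` and reason `"control"` / the mask reason,
#' so that downstream plate matrices mark them missing; sample wells with
#' no cell records get `n_cells = 0` and reason `"no_cells"`. The function
#' is pure: identical inputs give identical output.
#'
#' @param cells Cell records (validated as in [readCellTable()]).
#' @param layouts A [PlateLayout-class] or named list of them, keyed by
#'   plate id.
#' @param mask Optional well mask `data.frame` (see [readWellMask()]).
#' @inheritParams summarizeWell
#' @return Long well-summary `data.frame`, one row per well x parameter
#'   (see [summarizeWell()]).
#' @export
summarizeScreen <- function(cells, layouts, mask = NULL, quantileP = 0.99,
                            channels = defaultChannelMap(), minCells = 0L) {
  cells <- validateCellTable(cells, where = "cells")
  if (methods::is(layouts, "PlateLayout"))
    layouts <- stats::setNames(list(layouts), plateId(layouts))
  if (is.null(names(layouts)))
    names(layouts) <- vapply(layouts, plateId, character(1))
  badPlate <- setdiff(unique(cells$plate_id), names(layouts))
  if (length(badPlate))
    stopf("cell records reference plate(s) absent from the layouts: %s",
          paste(badPlate, collapse = ", "))
  for (pid in unique(cells$plate_id)) {
    w <- wellRoles(layouts[[pid]])
    known <- w$well[w$role != "empty"]
    badWell <- setdiff(unique(cells$well[cells$plate_id == pid]), known)
    if (length(badWell))
      stopf("cell records in wells absent from layout of plate %s: %s", pid,
            paste(badWell, collapse = ", "))
  }
  maskKey <- if (!is.null(mask) && nrow(mask))
    paste(mask$plate_id, mask$replicate_id, mask$well) else character(0)
  maskReason <- if (length(maskKey)) stats::setNames(mask$reason, maskKey) else character(0)

  groups <- split(cells, paste(cells$plate_id, cells$replicate_id, sep = "\r"))
  out <- vector("list", 0L)
  for (g in groups) {
    pid <- g$plate_id[1]; rid <- g$replicate_id[1]
    lay <- wellRoles(layouts[[pid]])
    lay <- lay[lay$role != "empty", , drop = FALSE]
    byWell <- split(g, g$well)
    for (i in seq_len(nrow(lay))) {
      wl <- lay$well[i]
      wcells <- byWell[[wl]]
      if (is.null(wcells)) wcells <- g[0, , drop = FALSE]
      s <- summarizeWell(wcells, quantileP = quantileP, channels = channels,
                         minCells = minCells)
      s$plate_id <- pid; s$replicate_id <- rid; s$well <- wl
      mk <- maskReason[paste(pid, rid, wl)]
      if (!is.na(mk) && length(mk)) {
        s$valid <- FALSE; s$reason <- unname(mk)
      } else if (lay$role[i] == "control") {
        s$valid <- FALSE; s$reason <- "control"
      }
      out[[length(out) + 1L]] <- s
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
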