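#' @include wells.R
NULL

cellTableColumns <- function() {
  c("plate_id", "replicate_id", "well", "object_id",
    "ch1_avg", "ch1_total", "ch1_var",
    "ch2_avg", "ch2_total", "ch2_var",
    "ch3_avg", "ch3_total", "ch3_var")
}

validateCellTable <- function(cells, where = "cell table") {
  need <- cellTableColumns()
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stopf("%s is missing required column(s): %s", where, paste(miss, collapse = ", "))
  meas <- grep("^ch[0-9]+_", names(cells), value = TRUE)
  for (cl in meas) {
    v <- cells[[cl]]
    if (!is.numeric(v))
      stopf("%s: column %s must be numeric", where, cl)
    bad <- which(!is.na(v) & v < 0)
    if (length(bad))
      stopf("%s: negative value in column %s at line %s (header is line 1)",
            where, cl, paste(bad + 1L, collapse = ", "))
  }
  key <- paste(cells$plate_id, cells$replicate_id, cells$well, cells$object_id)
  if (anyDuplicated(key))
    stopf("%s: duplicated (plate_id, replicate_id, well, object_id) at line %s",
          where, paste(which(duplicated(key)) + 1L, collapse = ", "))
  cells$plate_id <- as.character(cells$plate_id)
  cells$replicate_id <- as.character(cells$replicate_id)
  cells$well <- as.character(cells$well)
  cells
}

#' Read / write per-cell measurement tables
#'
#' `cells.csv` holds one row per segmented object with per-channel average
#' intensity, total intensity and intensity variance:
#' `plate_id,replicate_id,well,object_id,ch1_avg,ch1_total,ch1_var,ch2_avg,
#' ch2_total,ch2_var,ch3_avg,ch3_total,ch3_var` (UTF-8, header required,
#' "." decimal separator). Invalid rows fail loudly — a negative intensity
#' or a duplicated object key is an error naming the offending line —
#' because silently dropping rows would bias per-well cell counts.
#'
#' @param path CSV file path.
#' @return `readCellTable`: a validated `data.frame` of cell records.
#' @export
readCellTable <- function(path) {
  if (!file.exists(path)) stopf("cell table not found: %s", path)
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateCellTable(cells, where = path)
}

#' @rdname readCellTable
#' @param cells Cell-record `data.frame` with the documented columns.
#' @export
writeCellTable <- function(cells, path) {
  cells <- validateCellTable(cells)
  utils::write.csv(cells[cellTableColumns()], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write plate maps
#'
#' `platemap.csv` has columns `plate_id,well,role,extract_id,dose_label`,
#' one row per listed well; wells not listed default to `empty`. A file may
#' describe several plates; `readPlateMap` then returns a named list of
#' [PlateLayout-class] objects.
#'
#' @param path CSV file path.
#' @param nRows,nCols Plate geometry.
#' @return A [PlateLayout-class] (single plate) or named list of them.
#' @export
readPlateMap <- function(path, nRows = 8L, nCols = 12L) {
  if (!file.exists(path)) stopf("plate map not found: %s", path)
  pm <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = c("NA", ""))
  need <- c("plate_id", "well", "role")
  miss <- setdiff(need, names(pm))
  if (length(miss))
    stopf("%s is missing required column(s): %s", path, paste(miss, collapse = ", "))
  layouts <- lapply(split(pm, pm$plate_id), function(d) {
    dup <- d$well[duplicated(d$well)]
    if (length(dup))
      stopf("%s: duplicate well entry for plate %s: %s", path, d$plate_id[1],
            paste(unique(dup), collapse = ", "))
    PlateLayout(d$plate_id[1], d, nRows = nRows, nCols = nCols)
  })
  if (length(layouts) == 1L) layouts[[1L]] else layouts
}

#' @rdname readPlateMap
#' @param layouts A [PlateLayout-class] or list of them.
#' @export
writePlateMap <- function(layouts, path) {
  if (methods::is(layouts, "PlateLayout")) layouts <- list(layouts)
  rows <- do.call(rbind, lapply(layouts, function(l) {
    w <- wellRoles(l)
    cbind(plate_id = plateId(l), w[c("well", "role", "extract_id", "dose_label")])
  }))
  rows <- rows[rows$role != "empty", , drop = FALSE]  # unlisted wells default to empty
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

maskReasons <- function() c("artifact", "control", "empty", "manual")

#' Read / write well masks
#'
#' `mask.csv` lists wells excluded from analysis, with columns
#' `plate_id,replicate_id,well,reason`; `reason` is one of `artifact`,
#' `control`, `empty`, `manual`. Masked wells appear as missing values in
#' every downstream plate matrix.
#'
#' @param path CSV file path.
#' @return `readWellMask`: a validated `data.frame`.
#' @export
readWellMask <- function(path) {
  if (!file.exists(path)) stopf("well mask not found: %s", path)
  mk <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validateWellMask(mk, where = path)
}

validateWellMask <- function(mask, where = "well mask") {
  need <- c("plate_id", "replicate_id", "well", "reason")
  miss <- setdiff(need, names(mask))
  if (length(miss))
    stopf("%s is missing required column(s): %s", where, paste(miss, collapse = ", "))
  bad <- setdiff(unique(mask$reason), maskReasons())
  if (length(bad))
    stopf("%s: unknown mask reason(s): %s", where, paste(bad, collapse = ", "))
  mask
}

#' @rdname readWellMask
#' @param mask Mask `data.frame` with the documented columns.
#' @export
writeWellMask <- function(mask, path) {
  mask <- validateWellMask(mask)
  utils::write.csv(mask[c("plate_id", "replicate_id", "well", "reason")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write per-well summary tables
#'
#' `wells.csv` is the long-format output of [summarizeScreen()]:
#' `plate_id,replicate_id,well,parameter,value,n_cells,valid,reason`, one
#' row per well x parameter.
#'
#' @param path CSV file path.
#' @return `readWellTable`: a `data.frame` of well summaries.
#' @export
readWellTable <- function(path) {
  if (!file.exists(path)) stopf("well table not found: %s", path)
  w <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  need <- c("plate_id", "replicate_id", "well", "parameter", "value",
            "n_cells", "valid", "reason")
  miss <- setdiff(need, names(w))
  if (length(miss))
    stopf("%s is missing required column(s): %s", path, paste(miss, collapse = ", "))
  w$plate_id <- as.character(w$plate_id)
  w$replicate_id <- as.character(w$replicate_id)
  w$valid <- as.logical(w$valid)
  w
}

#' @rdname readWellTable
#' @param wells Well-summary `data.frame` (see [summarizeScreen()]).
#' @export
writeWellTable <- function(wells, path) {
  cols <- c("plate_id", "replicate_id", "well", "parameter", "value",
            "n_cells", "valid", "reason")
  utils::write.csv(wells[cols], path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
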