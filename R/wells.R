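#' @include AllClasses.R
NULL

#' Parse and format well labels
#'
#' Well labels use the row-letter + column-number convention ("A01", "H12"):
#' rows A-H top to bottom, columns 1-12 left to right on the default
#' 96-well plate. Internal indices are 0-based; `parseWellLabel` and
#' `formatWellLabel` are mutual inverses on every valid label.
#'
#' @param label Character vector of labels (letter plus 1- or 2-digit
#'   column number).
#' @param nRows,nCols Plate geometry the labels must fall inside.
#' @return `parseWellLabel`: a two-column integer matrix (`row`, `col`) of
#'   0-based indices. `formatWellLabel`: a character vector of zero-padded
#'   labels.
#' @examples
#' parseWellLabel("A01")          # row 0, col 0
#' formatWellLabel(7, 11)         # "H12"
#' @export
parseWellLabel <- function(label, nRows = 8L, nCols = 12L) {
  label <- as.character(label)
  ok <- grepl("^[A-Z][0-9]{1,2}$", label)
  if (any(!ok))
    stopf("malformed well label(s): %s", paste(unique(label[!ok]), collapse = ", "))
  row <- match(substr(label, 1L, 1L), LETTERS) - 1L
  col <- as.integer(substr(label, 2L, nchar(label))) - 1L
  bad <- row < 0L | row >= nRows | col < 0L | col >= nCols
  if (any(bad))
    stopf("well label(s) outside the %d x %d plate: %s", nRows, nCols,
          paste(unique(label[bad]), collapse = ", "))
  cbind(row = row, col = col)
}

#' @rdname parseWellLabel
#' @param row,col 0-based row and column indices.
#' @export
formatWellLabel <- function(row, col, nRows = 8L, nCols = 12L) {
  row <- as.integer(row); col <- as.integer(col)
  if (any(row < 0L | row >= nRows | col < 0L | col >= nCols))
    stopf("row/column index outside the %d x %d plate", nRows, nCols)
  sprintf("%s%02d", LETTERS[row + 1L], col + 1L)
}

#' All well labels of a plate, in row-major order
#'
#' @param nRows,nCols Plate geometry.
#' @return Character vector of length `nRows * nCols` ("A01", "A02", ...).
#' @export
allWellLabels <- function(nRows = 8L, nCols = 12L) {
  idx <- expand.grid(col = seq_len(nCols) - 1L, row = seq_len(nRows) - 1L)
  formatWellLabel(idx$row, idx$col, nRows, nCols)
}

#' Construct a PlateLayout
#'
#' Builds a validated [PlateLayout-class] from a well-role table. Wells not
#' listed default to role `"empty"`; the full grid is always represented.
#'
#' @param plateId Plate identifier.
#' @param wells `data.frame` with columns `well`, `role` and optionally
#'   `extract_id`, `dose_label`. May cover a subset of the grid.
#' @param nRows,nCols Plate geometry (defaults: 96-well, 8 x 12).
#' @return A [PlateLayout-class] object.
#' @examples
#' PlateLayout("P1", data.frame(well = c("A01", "A02"),
#'                              role = c("control", "sample"),
#'                              extract_id = c(NA, "X1")))
#' @export
PlateLayout <- function(plateId, wells, nRows = 8L, nCols = 12L) {
  nRows <- as.integer(nRows); nCols <- as.integer(nCols)
  if (!is.data.frame(wells) || !all(c("well", "role") %in% names(wells)))
    stopf("wells must be a data.frame with columns well, role")
  if (anyDuplicated(wells$well))
    stopf("duplicate well entries: %s",
          paste(unique(wells$well[duplicated(wells$well)]), collapse = ", "))
  if (!"extract_id" %in% names(wells)) wells$extract_id <- NA_character_
  if (!"dose_label" %in% names(wells)) wells$dose_label <- NA_character_
  wells$extract_id <- as.character(wells$extract_id)
  wells$extract_id[!is.na(wells$extract_id) & !nzchar(wells$extract_id)] <- NA_character_
  wells$dose_label <- as.character(wells$dose_label)
  smp <- wells$role == "sample"
  if (any(smp & is.na(wells$extract_id)))
    stopf("sample well(s) without extract_id: %s",
          paste(wells$well[smp & is.na(wells$extract_id)], collapse = ", "))
  parseWellLabel(wells$well, nRows, nCols)  # range + format check
  full <- data.frame(well = allWellLabels(nRows, nCols),
                     role = "empty",
                     extract_id = NA_character_,
                     dose_label = NA_character_,
                     stringsAsFactors = FALSE)
  m <- match(wells$well, full$well)
  full$role[m] <- as.character(wells$role)
  full$extract_id[m] <- wells$extract_id
  full$dose_label[m] <- wells$dose_label
  methods::new("PlateLayout", plateId = as.character(plateId),
               nRows = nRows, nCols = nCols, wells = full)
}
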