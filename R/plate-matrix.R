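#' @include summarize.R
NULL

#' Construct a PlateMatrix
#'
#' @param values Numeric matrix (plate rows x columns); `NA` marks missing
#'   wells. Dimnames are set to row letters / column numbers.
#' @param plateId,replicateId,parameter Identifiers.
#' @param masked Optional `data.frame` (`well`, `reason`) documenting why
#'   entries are missing.
#' @return A [PlateMatrix-class] object.
#' @export
PlateMatrix <- function(values, plateId = "plate", replicateId = "rep",
                        parameter = "value",
                        masked = data.frame(well = character(0),
                                            reason = character(0))) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- list(LETTERS[seq_len(nrow(values))],
                           as.character(seq_len(ncol(values))))
  methods::new("PlateMatrix", plateId = as.character(plateId),
               replicateId = as.character(replicateId),
               parameter = as.character(parameter),
               values = values, masked = masked)
}

#' Arrange well summaries into per-plate matrices
#'
#' Pivots a long well-summary table (from [summarizeScreen()] or
#' [generateWellLevel()]) into one [PlateMatrix-class] per
#' (plate, replicate, parameter). Wells flagged invalid (controls,
#' artifact-masked, zero-cell) and wells without a row become explicit
#' missing values, with their reason recorded in the matrix provenance.
#'
#' @param wells Long well-summary `data.frame` with columns `plate_id`,
#'   `replicate_id`, `well`, `parameter`, `value`, `valid`, `reason`.
#' @param layouts A [PlateLayout-class] or named list of them (for
#'   geometry and the empty-well positions).
#' @param parameters Parameters to pivot (default the four headline
#'   screen parameters).
#' @return Named list of [PlateMatrix-class] objects, keyed
#'   `"<plate>|<replicate>|<parameter>"`.
#' @export
buildPlateMatrices <- function(wells, layouts, parameters = screenParameters()) {
  if (methods::is(layouts, "PlateLayout"))
    layouts <- stats::setNames(list(layouts), plateId(layouts))
  if (is.null(names(layouts)))
    names(layouts) <- vapply(layouts, plateId, character(1))
  wells <- wells[wells$parameter %in% parameters, , drop = FALSE]
  out <- list()
  for (grp in split(wells, paste(wells$plate_id, wells$replicate_id, sep = "\r"))) {
    pid <- grp$plate_id[1]; rid <- grp$replicate_id[1]
    lay <- layouts[[pid]]
    if (is.null(lay)) stopf("no layout for plate %s", pid)
    dims <- plateDim(lay)
    roles <- wellRoles(lay)
    for (p in parameters) {
      d <- grp[grp$parameter == p, , drop = FALSE]
      m <- matrix(NA_real_, dims[1], dims[2])
      use <- d$valid & !is.na(d$value)
      if (any(use)) {
        idx <- parseWellLabel(d$well[use], dims[1], dims[2])
        m[idx + 1L] <- d$value[use]
      }
      # provenance: empty wells from the layout, invalid wells from flags
      reasons <- character(0); maskedWells <- character(0)
      if (any(!use)) {
        maskedWells <- d$well[!use]
        reasons <- ifelse(is.na(d$reason[!use]), "invalid", d$reason[!use])
      }
      emp <- roles$well[roles$role == "empty"]
      emp <- setdiff(emp, maskedWells)
      masked <- data.frame(well = c(maskedWells, emp),
                           reason = c(reasons, rep("empty", length(emp))),
                           stringsAsFactors = FALSE)
      key <- paste(pid, rid, p, sep = "|")
      out[[key]] <- PlateMatrix(m, plateId = pid, replicateId = rid,
                                parameter = p, masked = masked)
    }
  }
  out
}
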