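#' @include utils.R
NULL

#' PlateLayout: roles and extract assignments on one multiwell plate
#'
#' An S4 container for one plate's geometry and well roles. Every well of
#' the `nRows` x `nCols` grid carries exactly one role: `"sample"` (with a
#' mandatory extract identifier), `"control"` (e.g. DMSO carrier wells) or
#' `"empty"`. Defaults match the 96-well format (rows A-H top to bottom,
#' columns 1-12 left to right).
#'
#' @slot plateId Plate identifier.
#' @slot nRows,nCols Plate geometry (default 8 x 12).
#' @slot wells `data.frame` with one row per well: `well` (zero-padded
#'   label, "A01" style), `role` (`sample`/`control`/`empty`), `extract_id`
#'   (non-empty for samples, `NA` otherwise), `dose_label` (free text or
#'   `NA`).
#'
#' @seealso [PlateLayout()] for the constructor, [readPlateMap()].
#' @export
setClass("PlateLayout",
  representation(
    plateId = "character",
    nRows   = "integer",
    nCols   = "integer",
    wells   = "data.frame"
  )
)

setValidity("PlateLayout", function(object) {
  msgs <- character()
  if (length(object@plateId) != 1L || is.na(object@plateId) || !nzchar(object@plateId))
    msgs <- c(msgs, "plateId must be a single non-empty string")
  if (object@nRows < 1L || object@nCols < 1L)
    msgs <- c(msgs, "plate geometry must be at least 1 x 1")
  w <- object@wells
  need <- c("well", "role", "extract_id", "dose_label")
  if (!all(need %in% names(w))) {
    msgs <- c(msgs, paste("wells must have columns", paste(need, collapse = ", ")))
    return(if (length(msgs)) msgs else TRUE)
  }
  if (anyDuplicated(w$well))
    msgs <- c(msgs, paste("duplicate well labels:",
                          paste(unique(w$well[duplicated(w$well)]), collapse = ", ")))
  if (nrow(w) != object@nRows * object@nCols)
    msgs <- c(msgs, sprintf("wells must cover all %d wells (got %d rows)",
                            object@nRows * object@nCols, nrow(w)))
  bad <- setdiff(unique(w$role), c("sample", "control", "empty"))
  if (length(bad))
    msgs <- c(msgs, paste("unknown well role(s):", paste(bad, collapse = ", ")))
  idx <- tryCatch(parseWellLabel(w$well, nRows = object@nRows, nCols = object@nCols),
                  error = function(e) conditionMessage(e))
  if (is.character(idx)) msgs <- c(msgs, idx)
  smp <- w$role == "sample"
  if (any(smp & (is.na(w$extract_id) | !nzchar(w$extract_id))))
    msgs <- c(msgs, "sample wells must carry a non-empty extract_id")
  if (any(!smp & !is.na(w$extract_id)))
    msgs <- c(msgs, "extract_id must be absent for non-sample wells")
  if (length(msgs)) msgs else TRUE
})

#' PlateMatrix: one parameter's values on the plate grid
#'
#' One (plate, replicate, parameter) combination's per-well values arranged
#' on the physical grid. Wells excluded from analysis (controls, empty
#' wells, artifact-masked wells, wells with no cells) are explicit `NA`s,
#' never zero-filled; the `masked` slot records which wells are missing and
#' why.
#'
#' @slot plateId,replicateId,parameter Identifiers.
#' @slot values Numeric matrix (rows x columns of the plate) with `NA` for
#'   missing wells; dimnames are row letters and column numbers.
#' @slot masked `data.frame` with columns `well`, `reason` documenting the
#'   provenance of missing entries.
#'
#' @seealso [PlateMatrix()], [buildPlateMatrices()], [medianPolish()].
#' @export
setClass("PlateMatrix",
  representation(
    plateId     = "character",
    replicateId = "character",
    parameter   = "character",
    values      = "matrix",
    masked      = "data.frame"
  )
)

setValidity("PlateMatrix", function(object) {
  msgs <- character()
  if (!is.numeric(object@values))
    msgs <- c(msgs, "values must be a numeric matrix")
  if (any(dim(object@values) < 1L))
    msgs <- c(msgs, "values must have at least one row and column")
  if (!all(c("well", "reason") %in% names(object@masked)))
    msgs <- c(msgs, "masked must have columns well, reason")
  if (length(msgs)) msgs else TRUE
})

#' BScoreDecomposition: median-polish components and B-scores of one plate
#'
#' Result of Tukey's two-way median polish on a [PlateMatrix], optionally
#' with MAD scaling into B-scores. The additive decomposition
#' `value = overall + rowEffect + colEffect + residual` holds exactly at
#' every non-missing cell; B-scores are `residual / mad` where
#' `mad = madConstant * median(|residuals|)`.
#'
#' @slot data The input [PlateMatrix] (for provenance and raw values).
#' @slot overall Grand effect (scalar).
#' @slot rowEffects,colEffects Numeric vectors of row/column effects.
#' @slot residuals Residual grid; `NA` where the input is missing.
#' @slot mad Scaled MAD of the residuals (`NA_real_` before scaling).
#' @slot madConstant The MAD scale constant used (1.4826 by default).
#' @slot bscores B-score grid (`residuals / mad`); all-`NA` before scaling.
#' @slot nIterations Number of full row+column sweep pairs performed.
#' @slot converged Whether the sweep change criterion was met within
#'   `maxIter`.
#'
#' @seealso [medianPolish()], [bscorePlate()].
#' @export
setClass("BScoreDecomposition",
  representation(
    data        = "PlateMatrix",
    overall     = "numeric",
    rowEffects  = "numeric",
    colEffects  = "numeric",
    residuals   = "matrix",
    mad         = "numeric",
    madConstant = "numeric",
    bscores     = "matrix",
    nIterations = "integer",
    converged   = "logical"
  )
)

setValidity("BScoreDecomposition", function(object) {
  msgs <- character()
  v <- object@data@values
  r <- object@residuals
  if (!identical(dim(v), dim(r)))
    msgs <- c(msgs, "residual grid shape must match the input grid")
  if (length(object@rowEffects) != nrow(v) || length(object@colEffects) != ncol(v))
    msgs <- c(msgs, "effect vectors must match the grid dimensions")
  ok <- !is.na(v)
  if (!identical(ok, !is.na(r)))
    msgs <- c(msgs, "missing cells must be missing in the residuals")
  if (any(ok)) {
    fit <- object@overall + outer(object@rowEffects, object@colEffects, "+") + r
    scale <- max(abs(v[ok]), 1)
    if (max(abs(fit[ok] - v[ok])) > 1e-9 * scale)
      msgs <- c(msgs, "overall + row + column + residual must reconstruct the input")
  }
  if (length(msgs)) msgs else TRUE
})

#' HitBand: the median +/- k*MAD significance band for one parameter
#'
#' The hit-calling band computed from post-exclusion extract means:
#' `center = median(means)`, `halfwidth = k * madConstant *
#' median(|means - center|)`, `lower/upper = center -/+ halfwidth`.
#'
#' @slot parameter Parameter the band applies to.
#' @slot center,halfwidth,lower,upper Band geometry.
#' @slot k Multiplier on the MAD (default 2).
#' @slot madConstant MAD scale constant.
#' @slot nExtracts Number of extract means the band was computed from.
#' @slot degenerate `TRUE` when the raw MAD is zero (halfwidth 0).
#'
#' @seealso [computeBand()], [callHits()].
#' @export
setClass("HitBand",
  representation(
    parameter   = "character",
    center      = "numeric",
    halfwidth   = "numeric",
    lower       = "numeric",
    upper       = "numeric",
    k           = "numeric",
    madConstant = "numeric",
    nExtracts   = "integer",
    degenerate  = "logical"
  )
)

setValidity("HitBand", function(object) {
  msgs <- character()
  if (object@halfwidth < 0) msgs <- c(msgs, "halfwidth must be nonnegative")
  if (abs(object@lower - (object@center - object@halfwidth)) > 1e-12 ||
      abs(object@upper - (object@center + object@halfwidth)) > 1e-12)
    msgs <- c(msgs, "lower/upper must equal center -/+ halfwidth")
  if (length(msgs)) msgs else TRUE
})
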