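#' @include AllClasses.R
NULL

#' @name accessors
#' @title Accessors for screen objects
#' @description Slot accessors for [PlateLayout], [PlateMatrix],
#'   [BScoreDecomposition] and [HitBand]; use these rather than `@`.
#' @param object A package S4 object.
#' @return The corresponding component.
NULL

#' @rdname accessors
#' @export
setGeneric("plateId", function(object) standardGeneric("plateId"))
#' @rdname accessors
#' @export
setGeneric("replicateId", function(object) standardGeneric("replicateId"))
#' @rdname accessors
#' @export
setGeneric("parameterName", function(object) standardGeneric("parameterName"))
#' @rdname accessors
#' @export
setGeneric("plateDim", function(object) standardGeneric("plateDim"))
#' @rdname accessors
#' @export
setGeneric("wellRoles", function(object) standardGeneric("wellRoles"))
#' @rdname accessors
#' @export
setGeneric("plateValues", function(object) standardGeneric("plateValues"))
#' @rdname accessors
#' @export
setGeneric("maskedWells", function(object) standardGeneric("maskedWells"))
#' @rdname accessors
#' @export
setGeneric("overallEffect", function(object) standardGeneric("overallEffect"))
#' @rdname accessors
#' @export
setGeneric("rowEffects", function(object) standardGeneric("rowEffects"))
#' @rdname accessors
#' @export
setGeneric("colEffects", function(object) standardGeneric("colEffects"))
#' @rdname accessors
#' @export
setGeneric("polishResiduals", function(object) standardGeneric("polishResiduals"))
#' @rdname accessors
#' @export
setGeneric("madScale", function(object) standardGeneric("madScale"))
#' @rdname accessors
#' @export
setGeneric("bscores", function(object) standardGeneric("bscores"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setMethod("plateId", "PlateLayout", function(object) object@plateId)
#' @rdname accessors
#' @export
setMethod("plateId", "PlateMatrix", function(object) object@plateId)
#' @rdname accessors
#' @export
setMethod("plateId", "BScoreDecomposition", function(object) object@data@plateId)
#' @rdname accessors
#' @export
setMethod("replicateId", "PlateMatrix", function(object) object@replicateId)
#' @rdname accessors
#' @export
setMethod("replicateId", "BScoreDecomposition", function(object) object@data@replicateId)
#' @rdname accessors
#' @export
setMethod("parameterName", "PlateMatrix", function(object) object@parameter)
#' @rdname accessors
#' @export
setMethod("parameterName", "BScoreDecomposition", function(object) object@data@parameter)
#' @rdname accessors
#' @export
setMethod("parameterName", "HitBand", function(object) object@parameter)
#' @rdname accessors
#' @export
setMethod("plateDim", "PlateLayout", function(object) c(object@nRows, object@nCols))
#' @rdname accessors
#' @export
setMethod("plateDim", "PlateMatrix", function(object) dim(object@values))
#' @rdname accessors
#' @export
setMethod("wellRoles", "PlateLayout", function(object) object@wells)
#' @rdname accessors
#' @export
setMethod("plateValues", "PlateMatrix", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("plateValues", "BScoreDecomposition", function(object) object@data@values)
#' @rdname accessors
#' @export
setMethod("maskedWells", "PlateMatrix", function(object) object@masked)
#' @rdname accessors
#' @export
setMethod("overallEffect", "BScoreDecomposition", function(object) object@overall)
#' @rdname accessors
#' @export
setMethod("rowEffects", "BScoreDecomposition", function(object) object@rowEffects)
#' @rdname accessors
#' @export
setMethod("colEffects", "BScoreDecomposition", function(object) object@colEffects)
#' @rdname accessors
#' @export
setMethod("polishResiduals", "BScoreDecomposition", function(object) object@residuals)
#' @rdname accessors
#' @export
setMethod("madScale", "BScoreDecomposition", function(object) object@mad)
#' @rdname accessors
#' @export
setMethod("bscores", "BScoreDecomposition", function(object) object@bscores)
#' @rdname accessors
#' @export
setMethod("isConverged", "BScoreDecomposition", function(object) object@converged)

#' @describeIn accessors Band bounds as a named numeric vector
#'   (`center`, `halfwidth`, `lower`, `upper`).
#' @export
setGeneric("bandBounds", function(object) standardGeneric("bandBounds"))
#' @rdname accessors
#' @export
setMethod("bandBounds", "HitBand", function(object) {
  c(center = object@center, halfwidth = object@halfwidth,
    lower = object@lower, upper = object@upper)
})

setMethod("show", "PlateLayout", function(object) {
  tab <- table(object@wells$role)
  cat(sprintf("PlateLayout '%s': %d x %d (%d wells)\n", object@plateId,
              object@nRows, object@nCols, nrow(object@wells)))
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "PlateMatrix", function(object) {
  v <- object@values
  cat(sprintf("PlateMatrix '%s' replicate '%s' parameter '%s': %d x %d, %d missing\n",
              object@plateId, object@replicateId, object@parameter,
              nrow(v), ncol(v), sum(is.na(v))))
})

setMethod("show", "BScoreDecomposition", function(object) {
  cat(sprintf("BScoreDecomposition [%s / %s / %s]\n", plateId(object),
              replicateId(object), parameterName(object)))
  cat(sprintf("  overall %.4g; %d iterations; converged: %s\n",
              object@overall, object@nIterations, object@converged))
  if (!is.na(object@mad))
    cat(sprintf("  scaled MAD %.4g (constant %.4f)\n", object@mad, object@madConstant))
  else
    cat("  (not yet scaled to B-scores)\n")
})

setMethod("show", "HitBand", function(object) {
  cat(sprintf("HitBand '%s': center %.4g, halfwidth %.4g -> [%.4g, %.4g] (k=%g, n=%d%s)\n",
              object@parameter, object@center, object@halfwidth, object@lower,
              object@upper, object@k, object@nExtracts,
              if (object@degenerate) ", DEGENERATE" else ""))
})
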