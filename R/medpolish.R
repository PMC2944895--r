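#' @include plate-matrix.R
NULL

asPlateMatrix <- function(x) {
  if (methods::is(x, "PlateMatrix")) x else PlateMatrix(x)
}

#' Two-way median polish of a plate
#'
#' Tukey's iterative median polish decomposes the plate grid into
#' `value = overall + rowEffect + colEffect + residual`, using medians so
#' that row/column effect estimates are insensitive to a minority of
#' outlying wells (e.g. hits). Sweeps alternate rows first, then columns;
#' after each sweep the median of the just-updated effect vector is folded
#' into the overall term, so row and column effects each have median zero
#' at convergence. Medians are taken over non-missing wells only, which is
#' how excluded wells (controls, artifacts) are accommodated.
#'
#' Convergence is declared when the sum of absolute residual changes over
#' one full row+column sweep pair falls below
#' `tol * (1 + sum(|values|))`; otherwise the result is returned after
#' `maxIter` sweep pairs with `converged = FALSE`.
#'
#' @param x A [PlateMatrix-class] or plain numeric matrix (at least 2 x 2;
#'   `NA` marks missing wells). A fully missing row or column is an error.
#' @param maxIter Maximum number of row+column sweep pairs (default 100).
#' @param tol Relative convergence tolerance (default 1e-6).
#' @return A [BScoreDecomposition-class] without MAD scaling (`mad` is
#'   `NA`; use [bscorePlate()] for B-scores).
#' @examples
#' medianPolish(matrix(c(1, 3, 2, 4), 2, 2))  # overall 2.5, rows -1/+1
#' @export
medianPolish <- function(x, maxIter = 100L, tol = 1e-6) {
  pm <- asPlateMatrix(x)
  v <- plateValues(pm)
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 2L || nc < 2L)
    stopf("median polish needs at least a 2 x 2 grid (got %d x %d)", nr, nc)
  rowAllNA <- rowSums(!is.na(v)) == 0L
  if (any(rowAllNA))
    stopf("plate %s: row(s) with no usable wells: %s", pm@plateId,
          paste(rownames(v)[rowAllNA], collapse = ", "))
  colAllNA <- colSums(!is.na(v)) == 0L
  if (any(colAllNA))
    stopf("plate %s: column(s) with no usable wells: %s", pm@plateId,
          paste(colnames(v)[colAllNA], collapse = ", "))

  r <- v
  overall <- 0
  re <- numeric(nr)
  ce <- numeric(nc)
  scale <- 1 + sum(abs(v), na.rm = TRUE)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    prev <- r
    rmed <- apply(r, 1L, stats::median, na.rm = TRUE)
    r <- r - rmed            # recycles down columns: subtracts rmed[i] from row i
    re <- re + rmed
    m <- stats::median(re)
    re <- re - m; overall <- overall + m
    cmed <- apply(r, 2L, stats::median, na.rm = TRUE)
    r <- sweep(r, 2L, cmed)
    ce <- ce + cmed
    m <- stats::median(ce)
    ce <- ce - m; overall <- overall + m
    if (sum(abs(r - prev), na.rm = TRUE) < tol * scale) {
      converged <- TRUE
      break
    }
  }
  methods::new("BScoreDecomposition", data = pm, overall = overall,
               rowEffects = stats::setNames(re, rownames(v)),
               colEffects = stats::setNames(ce, colnames(v)),
               residuals = r, mad = NA_real_, madConstant = NA_real_,
               bscores = r * NA_real_, nIterations = iter,
               converged = converged)
}

#' B-score transformation of one plate
#'
#' Runs [medianPolish()] and scales the residual grid by the scaled median
#' absolute deviation of the residuals:
#' `bscore = residual / (madConstant * median(|residuals|))`. The result is
#' location- and scale-invariant: adding a constant to the plate or
#' multiplying it by a positive constant leaves the B-score grid unchanged.
#'
#' A plate whose residuals are all (numerically) zero has no dispersion to
#' scale by; by default that raises a degenerate-plate error naming the
#' plate. Noiseless synthetic fixtures may opt into
#' `onDegenerate = "zero"`, which assigns all-zero B-scores and keeps
#' `mad = 0`.
#'
#' @inheritParams medianPolish
#' @param madConstant MAD scale constant (default 1.4826, the normal-
#'   consistency convention; set 1 for the raw MAD).
#' @param onDegenerate `"error"` (default) or `"zero"`.
#' @return A [BScoreDecomposition-class] with `mad` and `bscores` filled.
#' @export
bscorePlate <- function(x, madConstant = 1.4826, maxIter = 100L, tol = 1e-6,
                        onDegenerate = c("error", "zero")) {
  onDegenerate <- match.arg(onDegenerate)
  dec <- medianPolish(x, maxIter = maxIter, tol = tol)
  r <- dec@residuals
  mad <- madConstant * stats::median(abs(r), na.rm = TRUE)
  # numerically-zero dispersion, relative to the plate's magnitude
  degenerateAt <- 1e-12 * (1 + stats::median(abs(plateValues(dec)), na.rm = TRUE))
  if (mad <= degenerateAt * madConstant) {
    if (onDegenerate == "error")
      stopf("degenerate plate %s (replicate %s, parameter %s): residual MAD is zero",
            dec@data@plateId, dec@data@replicateId, dec@data@parameter)
    dec@mad <- 0
    dec@madConstant <- madConstant
    dec@bscores <- r * 0
    return(dec)
  }
  dec@mad <- mad
  dec@madConstant <- madConstant
  dec@bscores <- r / mad
  dec
}

#' B-score a whole screen of plates
#'
#' Applies [bscorePlate()] independently to each plate matrix. Plates that
#' fail (degenerate MAD, unusable rows) are reported in the `failures`
#' table rather than silently dropped.
#'
#' @param matrices List of [PlateMatrix-class] objects, one per
#'   (plate, replicate, parameter); duplicate keys are an error.
#' @inheritParams bscorePlate
#' @return List with `decompositions` (named list of
#'   [BScoreDecomposition-class]) and `failures` (`data.frame` with
#'   `plate_id`, `replicate_id`, `parameter`, `message`).
#' @export
transformScreen <- function(matrices, madConstant = 1.4826, maxIter = 100L,
                            tol = 1e-6) {
  keys <- vapply(matrices, function(m)
    paste(m@plateId, m@replicateId, m@parameter, sep = "|"), character(1))
  if (anyDuplicated(keys))
    stopf("duplicate (plate, replicate, parameter) keys: %s",
          paste(unique(keys[duplicated(keys)]), collapse = "; "))
  decs <- list()
  fails <- list()
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    res <- tryCatch(
      bscorePlate(m, madConstant = madConstant, maxIter = maxIter, tol = tol),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        plate_id = m@plateId, replicate_id = m@replicateId,
        parameter = m@parameter, message = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      decs[[keys[i]]] <- res
    }
  }
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(plate_id = character(0), replicate_id = character(0),
               parameter = character(0), message = character(0))
  list(decompositions = decs, failures = failures)
}

#' Tidy tables from B-score decompositions
#'
#' `bscoreTable` flattens decompositions into the long `bscores.csv`
#' schema (`plate_id,replicate_id,well,parameter,raw_value,residual,bscore`,
#' non-missing wells only); `effectsTable` emits the fitted components
#' (`plate_id,replicate_id,parameter,component,index,value` with component
#' `overall`/`row`/`col`).
#'
#' @param decompositions List of [BScoreDecomposition-class] (e.g. the
#'   `decompositions` element of [transformScreen()]).
#' @return A `data.frame` in the documented schema.
#' @export
bscoreTable <- function(decompositions) {
  rows <- lapply(decompositions, function(d) {
    v <- plateValues(d)
    ok <- which(!is.na(v), arr.ind = TRUE)
    if (!nrow(ok)) return(NULL)
    data.frame(plate_id = plateId(d), replicateId = replicateId(d),
               well = formatWellLabel(ok[, 1] - 1L, ok[, 2] - 1L,
                                      nrow(v), ncol(v)),
               parameter = parameterName(d),
               raw_value = v[ok], residual = d@residuals[ok],
               bscore = d@bscores[ok], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "replicateId"] <- "replicate_id"
  rownames(out) <- NULL
  out
}

#' @rdname bscoreTable
#' @export
effectsTable <- function(decompositions) {
  rows <- lapply(decompositions, function(d) {
    data.frame(plate_id = plateId(d), replicate_id = replicateId(d),
               parameter = parameterName(d),
               component = c("overall", rep("row", length(d@rowEffects)),
                             rep("col", length(d@colEffects))),
               index = c(NA_character_, names(d@rowEffects), names(d@colEffects)),
               value = c(d@overall, unname(d@rowEffects), unname(d@colEffects)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
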