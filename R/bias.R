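#' @include hits.R
NULL

#' Kruskal-Wallis test of grouped well values
#'
#' Rank-based k-group location test used as the row/column bias
#' diagnostic: values grouped by plate row (or column) should show no
#' systematic location differences on an unbiased (or successfully
#' normalized) plate. The tie-corrected H statistic is referred to a
#' chi-square distribution with `groups - 1` degrees of freedom (the
#' computation is delegated to [stats::kruskal.test()]). Being a rank
#' statistic, H is invariant under any strictly monotone transform of the
#' values.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length (at least 2 nonempty
#'   groups).
#' @param grouping Label recorded in the result (`"row"`, `"column"`, or
#'   free text).
#' @return `data.frame` row: `statistic` (H), `df`, `p_value`, `grouping`,
#'   `n_groups`, `n_values`, `degenerate`. When every value is identical
#'   the statistic is undefined; it is returned as `NA` with
#'   `degenerate = TRUE` rather than as an error.
#' @examples
#' kruskalWallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))  # H = 2.4, df = 1
#' @export
kruskalWallis <- function(values, groups, grouping = "group") {
  values <- as.numeric(values)
  groups <- as.factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2L)
    stopf("Kruskal-Wallis needs at least 2 groups (got %d)", nlevels(groups))
  if (length(values) < 2L)
    stopf("Kruskal-Wallis needs at least 2 values")
  res <- data.frame(statistic = NA_real_, df = nlevels(groups) - 1L,
                    p_value = NA_real_, grouping = grouping,
                    n_groups = nlevels(groups), n_values = length(values),
                    degenerate = FALSE, stringsAsFactors = FALSE)
  if (length(unique(values)) == 1L) {
    res$degenerate <- TRUE
    return(res)
  }
  kt <- stats::kruskal.test(values, groups)
  res$statistic <- unname(kt$statistic)
  res$df <- unname(kt$parameter)
  res$p_value <- kt$p.value
  if (!is.finite(res$statistic)) res$degenerate <- TRUE
  res
}

## well values of one grid with row/column indices, non-missing only
gridLong <- function(v) {
  ok <- which(!is.na(v), arr.ind = TRUE)
  data.frame(row = ok[, 1], col = ok[, 2], value = v[ok])
}

#' Row/column bias report across a screen
#'
#' Runs the Kruskal-Wallis row and column diagnostics per parameter, on
#' the raw plate values (`stage = "raw"`) or on the B-scores of the same
#' plates (`stage = "bscore"`). The default pooled mode concatenates wells
#' across plates within a parameter (the "overall bias" view); per-plate
#' mode tests each plate individually.
#'
#' @param x For `stage = "raw"`: a list of [PlateMatrix-class]. For
#'   `stage = "bscore"`: a list of [BScoreDecomposition-class] (their
#'   B-score grids are tested).
#' @param stage `"raw"` or `"bscore"`.
#' @param mode `"pooled"` (default) or `"per_plate"`.
#' @return `data.frame` with one row per (parameter, grouping[, plate]):
#'   the [kruskalWallis()] columns plus `parameter`, `stage`, `plate_id`,
#'   `replicate_id` (`NA` when pooled).
#' @export
biasReport <- function(x, stage = c("raw", "bscore"),
                       mode = c("pooled", "per_plate")) {
  stage <- match.arg(stage)
  mode <- match.arg(mode)
  if (!length(x)) stopf("empty input to biasReport")
  grids <- lapply(x, function(el) {
    if (stage == "raw") {
      if (!methods::is(el, "PlateMatrix"))
        stopf("stage = \"raw\" expects PlateMatrix objects")
      list(values = plateValues(el), parameter = parameterName(el),
           plate = plateId(el), replicate = replicateId(el))
    } else {
      if (!methods::is(el, "BScoreDecomposition"))
        stopf("stage = \"bscore\" expects BScoreDecomposition objects")
      list(values = bscores(el), parameter = parameterName(el),
           plate = plateId(el), replicate = replicateId(el))
    }
  })
  out <- list()
  addKW <- function(d, grouping, parameter, plate, replicate) {
    g <- if (grouping == "row") d$row else d$col
    kw <- kruskalWallis(d$value, g, grouping = grouping)
    kw$parameter <- parameter; kw$stage <- stage
    kw$plate_id <- plate; kw$replicate_id <- replicate
    out[[length(out) + 1L]] <<- kw
  }
  if (mode == "pooled") {
    params <- unique(vapply(grids, `[[`, character(1), "parameter"))
    for (p in params) {
      d <- do.call(rbind, lapply(grids[vapply(grids, function(g)
        g$parameter == p, logical(1))], function(g) gridLong(g$values)))
      addKW(d, "row", p, NA_character_, NA_character_)
      addKW(d, "column", p, NA_character_, NA_character_)
    }
  } else {
    for (g in grids) {
      d <- gridLong(g$values)
      addKW(d, "row", g$parameter, g$plate, g$replicate)
      addKW(d, "column", g$parameter, g$plate, g$replicate)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Prototypical plate: pooled row/column distribution profile
#'
#' Pools the well values of many plates of one parameter by physical row
#' and by physical column, and summarizes each group with box-plot
#' statistics: median, quartiles (interpolated, same convention as the
#' summarization quantiles), whiskers at the most extreme values within
#' 1.5 x IQR of the quartiles, and the outliers beyond them. Averaged over
#' many plates this exposes systematic geometry effects — e.g. depressed
#' perimeter rows and columns — that single plates show only noisily.
#'
#' @param matrices List of [PlateMatrix-class] of one parameter, sharing
#'   geometry.
#' @return `data.frame`, one row per (axis, index): `parameter`, `axis`
#'   (`"row"`/`"column"`), `index` (1-based), `label`, `median`, `q1`,
#'   `q3`, `whisker_low`, `whisker_high`, `n_values`, `n_outliers`,
#'   `n_plates`; outlier values are attached as the list column
#'   `outliers`.
#' @export
prototypicalPlate <- function(matrices) {
  if (methods::is(matrices, "PlateMatrix")) matrices <- list(matrices)
  if (!length(matrices)) stopf("empty input to prototypicalPlate")
  dims <- lapply(matrices, plateDim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stopf("plate geometry mismatch across matrices")
  par <- unique(vapply(matrices, parameterName, character(1)))
  if (length(par) != 1L)
    stopf("prototypicalPlate expects matrices of a single parameter (got: %s)",
          paste(par, collapse = ", "))
  long <- do.call(rbind, lapply(matrices, function(m) gridLong(plateValues(m))))
  nr <- dims[[1]][1]; nc <- dims[[1]][2]
  profileOf <- function(axis, idx, vals) {
    q1 <- interpQuantile(vals, 0.25); q3 <- interpQuantile(vals, 0.75)
    iqr <- q3 - q1
    inFence <- vals[vals >= q1 - 1.5 * iqr & vals <= q3 + 1.5 * iqr]
    outl <- vals[vals < q1 - 1.5 * iqr | vals > q3 + 1.5 * iqr]
    data.frame(parameter = par, axis = axis, index = idx,
               label = if (axis == "row") LETTERS[idx] else as.character(idx),
               median = stats::median(vals), q1 = q1, q3 = q3,
               whisker_low = min(inFence), whisker_high = max(inFence),
               n_values = length(vals), n_outliers = length(outl),
               n_plates = length(matrices),
               outliers = I(list(outl)), stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nr), function(i)
    profileOf("row", i, long$value[long$row == i]))
  cols <- lapply(seq_len(nc), function(j)
    profileOf("column", j, long$value[long$col == j]))
  res <- do.call(rbind, c(rows, cols))
  rownames(res) <- NULL
  res
}

#' Cross-screen concordance of extract effects
#'
#' Squared Pearson correlation of per-extract mean B-scores between two
#' screens (e.g. a cell-line screen and a primary-tissue screen), per
#' parameter pairing, over the extracts shared by both. Non-shared
#' extracts are dropped pairwise and counted.
#'
#' @param aggA,aggB Aggregates from [aggregateReplicates()] for the two
#'   screens.
#' @param pairing Named character vector mapping a parameter of screen A
#'   to one of screen B (default: same name onto same name for all shared
#'   parameters).
#' @return `data.frame`, one row per pairing: `parameter_a`,
#'   `parameter_b`, `r_squared`, `n_shared`, `degenerate` (`TRUE` with
#'   `r_squared = NA` when either vector has zero variance). Fewer than 3
#'   shared extracts is an error.
#' @export
screenConcordance <- function(aggA, aggB, pairing = NULL) {
  if (is.null(pairing)) {
    shared <- intersect(unique(aggA$parameter), unique(aggB$parameter))
    pairing <- stats::setNames(shared, shared)
  }
  out <- list()
  for (i in seq_along(pairing)) {
    pa <- names(pairing)[i]; pb <- pairing[[i]]
    a <- aggA[aggA$parameter == pa, c("extract_id", "mean_bscore")]
    b <- aggB[aggB$parameter == pb, c("extract_id", "mean_bscore")]
    m <- merge(a, b, by = "extract_id", suffixes = c("_a", "_b"))
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < 3L)
      stopf("fewer than 3 shared extracts for pairing %s ~ %s (got %d)",
            pa, pb, nrow(m))
    degenerate <- stats::sd(m$mean_bscore_a) == 0 || stats::sd(m$mean_bscore_b) == 0
    r2 <- if (degenerate) NA_real_ else
      stats::cor(m$mean_bscore_a, m$mean_bscore_b)^2
    out[[i]] <- data.frame(parameter_a = pa, parameter_b = pb,
                           r_squared = r2, n_shared = nrow(m),
                           degenerate = degenerate, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
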