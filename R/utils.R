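#' @keywords internal
"_PACKAGE"

#' Screen parameter names
#'
#' The four headline per-well parameters of the default screen:
#' `insulin` (GFP reporter, channel 2), `pdx1` (RFP reporter, channel 3),
#' `hoechst` (nuclear stain, channel 1) and `cell_count` (objects per well).
#'
#' @return Character vector of the four parameter names.
#' @export
screenParameters <- function() {
  c("insulin", "pdx1", "hoechst", "cell_count")
}

#' Default channel-to-biology mapping
#'
#' Maps measurement channels to the biological parameter each reports on.
#' The reporter design fixes the default (GFP on the insulin promoter in
#' channel 2, RFP on the pdx1 promoter in channel 3, Hoechst nuclear stain
#' in channel 1), but the mapping is configuration, not hard-coded: pass a
#' modified copy to [summarizeWell()] / [summarizeScreen()] to rebind it.
#'
#' @return Named character vector `c(ch1 = "hoechst", ch2 = "insulin",
#'   ch3 = "pdx1")`.
#' @export
defaultChannelMap <- function() {
  c(ch1 = "hoechst", ch2 = "insulin", ch3 = "pdx1")
}

#' Scaled median absolute deviation
#'
#' `constant * median(|x - median(x)|)`, the robust spread estimate used
#' throughout the pipeline. With the default constant 1.4826 it is a
#' consistent estimator of the standard deviation under normality.
#'
#' @param x Numeric vector; `NA`s are dropped.
#' @param constant Scale factor, default 1.4826.
#' @param center Optional center; defaults to `median(x)`.
#' @return Nonnegative scalar.
#' @export
scaledMad <- function(x, constant = 1.4826, center = stats::median(x, na.rm = TRUE)) {
  constant * stats::median(abs(x - center), na.rm = TRUE)
}

#' Interpolated quantile at position 1 + (n - 1) * p
#'
#' The quantile convention used by all summaries in the package: linear
#' interpolation between order statistics at position `1 + (n - 1) * p`
#' (type 7 in [stats::quantile()]).
#'
#' @param x Numeric vector.
#' @param p Probability in `[0, 1]`.
#' @return Scalar quantile.
#' @export
interpQuantile <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE, na.rm = TRUE))
}

## run `expr` under a temporary RNG state seeded with `seed`; global RNG
## state is untouched so generators never perturb a user's simulation stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## derive a child seed (< 2^31) from a base seed and a stream label
childSeed <- function(seed, stream) {
  offsets <- c(layout = 101L, effects = 211L, assign = 307L, noise = 401L,
               cells = 503L, artifact = 601L)
  off <- offsets[[stream]]
  # double arithmetic keeps the product exact (< 2^53) before the modulus
  as.integer((as.numeric(seed) * 48271 + as.numeric(off)) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
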