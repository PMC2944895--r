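test_that("median polish reproduces hand-worked small cases", {
  # constant matrix: everything in the overall term
  d <- medianPolish(matrix(5, 2, 2))
  expect_equal(overallEffect(d), 5)
  expect_equal(unname(rowEffects(d)), c(0, 0))
  expect_equal(unname(colEffects(d)), c(0, 0))
  expect_equal(max(abs(polishResiduals(d))), 0)

  # rows-first sweeps with fold-in: [[1,2],[3,4]]
  d2 <- medianPolish(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(overallEffect(d2), 2.5)
  expect_equal(unname(rowEffects(d2)), c(-1, 1))
  expect_equal(unname(colEffects(d2)), c(-0.5, 0.5))
  expect_equal(max(abs(polishResiduals(d2))), 0)
  expect_true(isConverged(d2))

  # an exactly additive grid is recovered component-for-component
  R <- c(-2, -1, 0, 0, 0, 0, 1, 2); C <- seq(-2.2, 2.2, length.out = 12)
  C <- C - median(C); R <- R - median(R)
  y <- 10 + outer(R, C, "+")
  d3 <- medianPolish(y, tol = 1e-12)
  expect_equal(overallEffect(d3), 10, tolerance = 1e-9)
  expect_equal(unname(rowEffects(d3)), R, tolerance = 1e-9)
  expect_equal(unname(colEffects(d3)), C, tolerance = 1e-9)
  expect_lt(max(abs(polishResiduals(d3))), 1e-9)
})

test_that("median polish errors on degenerate geometry and all-missing lines", {
  expect_error(medianPolish(matrix(1, 1, 5)), "2 x 2")
  m <- matrix(rnorm(24), 4, 6)
  m[2, ] <- NA
  expect_error(medianPolish(m), "row\\(s\\) with no usable wells: B")
  m2 <- matrix(rnorm(24), 4, 6)
  m2[, 3] <- NA
  expect_error(medianPolish(m2), "column\\(s\\) with no usable wells: 3")
})

test_that("decomposition reconstructs the input and matches stats::medpolish", {
  set.seed(11)
  for (i in 1:20) {
    m <- randomPlate(8, 12, missFrac = if (i %% 2) 0 else 0.15)
    d <- medianPolish(m, tol = 1e-10, maxIter = 300)
    fit <- overallEffect(d) + outer(unname(rowEffects(d)),
                                    unname(colEffects(d)), "+") +
      polishResiduals(d)
    ok <- !is.na(m)
    expect_lt(max(abs(fit[ok] - m[ok])), 1e-9)
    # missing cells stay missing
    expect_identical(unname(is.na(polishResiduals(d))), is.na(m))
    # row/column medians of residuals are driven to zero
    expect_lt(max(abs(apply(polishResiduals(d), 1, median, na.rm = TRUE))), 1e-6)
    expect_lt(max(abs(apply(polishResiduals(d), 2, median, na.rm = TRUE))), 1e-6)
  }
  # independent implementation in base R agrees on complete matrices
  # (medpolish stops on the change in sum(|residual|), a weaker criterion
  # that can halt while individual cells still move ~1e-2, so the
  # cross-check is loose; the brute-force oracle test is the tight one)
  set.seed(12)
  m <- randomPlate(8, 12)
  d <- medianPolish(m, tol = 1e-12, maxIter = 500)
  mp <- stats::medpolish(m, eps = 1e-13, maxiter = 500, trace.iter = FALSE)
  expect_equal(unname(polishResiduals(d)), unname(mp$residuals),
               tolerance = 0.05)
})

test_that("residuals match the brute-force oracle with missing wells", {
  set.seed(13)
  for (i in 1:25) {
    m <- randomPlate(8, 12, missFrac = 0.2)
    d <- medianPolish(m, tol = 1e-12, maxIter = 500)
    o <- oracleMedianPolish(m)
    expect_lt(max(abs(polishResiduals(d) - o$resid), na.rm = TRUE), 1e-9)
  }
})

test_that("polish is location invariant and row-shift equivariant", {
  set.seed(14)
  m <- randomPlate(8, 12, missFrac = 0.1)
  d <- medianPolish(m, tol = 1e-11, maxIter = 300)
  dShift <- medianPolish(m + 7, tol = 1e-11, maxIter = 300)
  expect_equal(overallEffect(dShift), overallEffect(d) + 7, tolerance = 1e-8)
  expect_equal(polishResiduals(dShift), polishResiduals(d), tolerance = 1e-8)

  # noiseless additive input: adding c to one row leaves residuals at zero
  R <- c(-1, 0, 0, 0, 0, 0, 0, 1); C <- c(-1, rep(0, 10), 1)
  y <- 5 + outer(R, C, "+")
  y2 <- y; y2[3, ] <- y2[3, ] + 4
  d2 <- medianPolish(y2, tol = 1e-12)
  expect_lt(max(abs(polishResiduals(d2))), 1e-9)
  expect_equal(unname(rowEffects(d2)[3] - rowEffects(d2)[4]), 4,
               tolerance = 1e-9)
})

test_that("B-scores scale residuals by the scaled MAD and are invariant", {
  set.seed(15)
  m <- randomPlate(8, 12, missFrac = 0.1)
  d <- bscorePlate(m, tol = 1e-10)
  r <- polishResiduals(d)
  expect_equal(madScale(d), 1.4826 * median(abs(r), na.rm = TRUE))
  expect_equal(bscores(d), r / madScale(d))
  # median(|bscores|) = 1/madConstant by construction
  expect_equal(median(abs(bscores(d)), na.rm = TRUE), 1 / 1.4826,
               tolerance = 1e-9)

  # location and positive-scale changes leave the B-score grid unchanged
  dSc <- bscorePlate(3.7 * m + 11, tol = 1e-10)
  expect_equal(bscores(dSc), bscores(d), tolerance = 1e-6)

  # known residuals by construction (zero row/column medians)
  resid <- matrix(c(-1, 1, 0, 1, -1, 0, 2, -2, 0, -2, 2, 0), 3, 4)
  R <- c(-1, 0, 1); C <- c(-2, -1, 1, 2)
  d3 <- bscorePlate(4 + outer(R, C, "+") + resid, tol = 1e-12)
  expect_equal(unname(bscores(d3)),
               unname(polishResiduals(d3)) /
                 (1.4826 * median(abs(polishResiduals(d3)))),
               tolerance = 1e-12)

  # a raw-MAD convention is available
  d1 <- bscorePlate(m, madConstant = 1, tol = 1e-10)
  expect_equal(median(abs(bscores(d1)), na.rm = TRUE), 1, tolerance = 1e-9)
})

test_that("degenerate (zero-dispersion) plates error unless opted out", {
  y <- 5 + outer(c(-1, 0, 1), c(-1, 0, 0, 1), "+")
  expect_error(bscorePlate(y), "degenerate plate")
  dz <- bscorePlate(y, onDegenerate = "zero")
  expect_equal(madScale(dz), 0)
  expect_equal(max(abs(bscores(dz))), 0)
})

test_that("screen transformation reports failures instead of dropping plates", {
  set.seed(16)
  mats <- list()
  for (p in c("P1", "P2")) for (par in screenParameters())
    mats[[paste(p, par)]] <- PlateMatrix(randomPlate(8, 12), plateId = p,
                                         replicateId = "R1", parameter = par)
  tr <- transformScreen(mats)
  expect_length(tr$decompositions, 8L)
  expect_equal(nrow(tr$failures), 0L)

  mats$degen <- PlateMatrix(matrix(5, 8, 12), plateId = "P3",
                            replicateId = "R1", parameter = "insulin")
  tr2 <- transformScreen(mats)
  expect_length(tr2$decompositions, 8L)
  expect_equal(nrow(tr2$failures), 1L)
  expect_match(tr2$failures$message, "degenerate")

  expect_error(transformScreen(c(mats[1], mats[1])), "duplicate")
  empty <- transformScreen(list())
  expect_length(empty$decompositions, 0L)
})

test_that("tidy B-score tables carry raw values, residuals and scores", {
  set.seed(17)
  m <- randomPlate(4, 6, missFrac = 0.2)
  d <- bscorePlate(PlateMatrix(m, "P1", "R1", "insulin"), tol = 1e-10)
  tab <- bscoreTable(list(d))
  expect_equal(nrow(tab), sum(!is.na(m)))
  i <- parseWellLabel(tab$well, 4, 6) + 1L
  expect_equal(tab$raw_value, m[i])
  expect_equal(tab$bscore, bscores(d)[i])
  eff <- effectsTable(list(d))
  expect_equal(sum(eff$component == "row"), 4L)
  expect_equal(sum(eff$component == "col"), 6L)
  expect_equal(eff$value[eff$component == "overall"], overallEffect(d))
})
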