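aggRow <- function(id, p, mean, sem = 0.1, n = 5L) {
  data.frame(extract_id = id, parameter = p, mean_bscore = mean, sem = sem,
             n_replicates = n, flagged_single = n < 2L,
             stringsAsFactors = FALSE)
}

toxAgg <- function(id, cc, ho) {
  rbind(aggRow(id, "cell_count", cc), aggRow(id, "hoechst", ho),
        aggRow(id, "insulin", 0), aggRow(id, "pdx1", 0))
}

test_that("replicate aggregation computes mean, SEM and flags singletons", {
  df <- data.frame(extract_id = "X", replicate_id = paste0("R", 1:3),
                   parameter = "insulin", bscore = c(1, 2, 3))
  a <- aggregateReplicates(df)
  expect_equal(a$mean_bscore, 2)
  expect_equal(a$sem, 1 / sqrt(3))          # sd {1,2,3} = 1
  expect_equal(a$sem, 0.5774, tolerance = 1e-4)
  expect_equal(a$n_replicates, 3L)

  same <- data.frame(extract_id = "X", replicate_id = paste0("R", 1:5),
                     parameter = "insulin", bscore = 2)
  expect_equal(aggregateReplicates(same)$sem, 0)

  single <- df[1, ]
  a1 <- aggregateReplicates(single)
  expect_true(a1$flagged_single)
  expect_true(is.na(a1$sem))

  dup <- rbind(df, df[1, ])                 # two wells in one replicate
  expect_error(aggregateReplicates(dup), "multiple wells")
  pooled <- aggregateReplicates(dup, pool = "mean")
  expect_equal(pooled$mean_bscore, 2)       # within-replicate mean first
})

test_that("cytotoxic exclusion applies threshold rules per mode", {
  agg <- rbind(toxAgg("tox", -5, 3), toxAgg("lowOnly", -5, 0),
               toxAgg("highOnly", 0, 3), toxAgg("clean", 0.2, -0.1))
  both <- excludeCytotoxic(agg, mode = "both")
  expect_setequal(unique(both$excluded$extract_id), "tox")
  expect_setequal(unique(both$kept$extract_id),
                  c("lowOnly", "highOnly", "clean"))
  # partition: kept and excluded are disjoint and cover the input
  expect_equal(sort(c(unique(both$kept$extract_id),
                      unique(both$excluded$extract_id))),
               sort(unique(agg$extract_id)))

  either <- excludeCytotoxic(agg, mode = "either")
  expect_setequal(unique(either$excluded$extract_id),
                  c("tox", "lowOnly", "highOnly"))
  ccOnly <- excludeCytotoxic(agg, mode = "cell_count_only")
  expect_setequal(unique(ccOnly$excluded$extract_id), c("tox", "lowOnly"))

  # boundary is inclusive
  edge <- excludeCytotoxic(toxAgg("e", -2, 2), mode = "both")
  expect_equal(unique(edge$excluded$extract_id), "e")

  # missing toxicity parameter is an error
  expect_error(excludeCytotoxic(aggRow("x", "insulin", 0)), "toxicity")
})

test_that("rank-based exclusion removes the requested fraction", {
  agg <- do.call(rbind, lapply(1:20, function(i)
    toxAgg(sprintf("E%02d", i), cc = -i / 10, ho = 0)))
  r <- excludeCytotoxic(agg, mode = "rank", rankFraction = 0.15)
  expect_equal(length(unique(r$excluded$extract_id)), 3L)  # bottom 15% of 20
  expect_setequal(unique(r$excluded$extract_id), c("E18", "E19", "E20"))
})

test_that("hit bands are the median +/- k * scaled MAD of extract means", {
  agg <- do.call(rbind, lapply(1:5, function(i)
    aggRow(paste0("E", i), "insulin", i)))
  b <- computeBand(agg, "insulin", k = 2, madConstant = 1)
  expect_equal(bandBounds(b),
               c(center = 3, halfwidth = 2, lower = 1, upper = 5))

  # translation equivariance
  agg2 <- agg; agg2$mean_bscore <- agg2$mean_bscore + 10
  b2 <- computeBand(agg2, "insulin", k = 2, madConstant = 1)
  expect_equal(bandBounds(b2)[["center"]], 13)
  expect_equal(bandBounds(b2)[["halfwidth"]], 2)

  # majority at the median: raw MAD 0 -> degenerate warning
  aggDeg <- do.call(rbind, Map(aggRow, paste0("D", 1:5),
                               "insulin", c(-1, 0, 1, 0, 0)))
  expect_warning(bd <- computeBand(aggDeg, "insulin"), "degenerate")
  expect_true(bd@degenerate)
  expect_equal(bandBounds(bd)[["halfwidth"]], 0)

  expect_error(computeBand(agg[1:2, ], "insulin"), "at least 3")
})

test_that("the SEM non-overlap rule decides hits and direction", {
  mkBand <- function(lo, hi, p = "insulin")
    methods::new("HitBand", parameter = p, center = (lo + hi) / 2,
                 halfwidth = (hi - lo) / 2, lower = lo, upper = hi,
                 k = 2, madConstant = 1.4826, nExtracts = 100L,
                 degenerate = FALSE)
  band <- mkBand(-1.40, 1.40)

  # interval entirely above the band: a hit, direction up
  h <- callHits(aggRow("a", "insulin", 1.56, sem = 0.06), band,
                parameters = "insulin")
  expect_equal(h$direction, "up")
  expect_equal(h$extract_id, "a")

  # large SEM reaching back into the band: not a hit despite a big mean
  h2 <- callHits(aggRow("b", "insulin", 2.21, sem = 1.11), band,
                 parameters = "insulin")
  expect_equal(nrow(h2), 0L)

  # a mean at the band center is never a hit
  h3 <- callHits(aggRow("c", "insulin", 0, sem = 0.5), band,
                 parameters = "insulin")
  expect_equal(nrow(h3), 0L)

  # touching the line is not outside (strict inequality)
  h4 <- callHits(aggRow("d", "insulin", 1.90, sem = 0.50), band,
                 parameters = "insulin")
  expect_equal(nrow(h4), 0L)
  h5 <- callHits(aggRow("e", "insulin", 1.91, sem = 0.50), band,
                 parameters = "insulin")
  expect_equal(h5$direction, "up")

  # down-hits mirror
  h6 <- callHits(aggRow("f", "insulin", -2.5, sem = 0.3), band,
                 parameters = "insulin")
  expect_equal(h6$direction, "down")

  # aggregates without a SEM are skipped with a warning
  expect_warning(h7 <- callHits(aggRow("g", "insulin", 5, sem = NA_real_,
                                       n = 1L), band,
                                parameters = "insulin"),
                 "without a SEM")
  expect_equal(nrow(h7), 0L)
})

test_that("hit decisions are monotone in |mean - center| and in SEM", {
  band <- methods::new("HitBand", parameter = "insulin", center = 0,
                       halfwidth = 1.5, lower = -1.5, upper = 1.5, k = 2,
                       madConstant = 1.4826, nExtracts = 50L,
                       degenerate = FALSE)
  isHit <- function(mean, sem)
    nrow(callHits(aggRow("x", "insulin", mean, sem), band,
                  parameters = "insulin")) > 0
  set.seed(20)
  for (i in 1:50) {
    mean <- runif(1, -4, 4); sem <- runif(1, 0, 2)
    if (isHit(mean, sem)) {
      expect_true(isHit(mean * 1.5, sem))      # further out stays a hit
      expect_true(isHit(mean, sem * 0.5))      # tighter SEM stays a hit
    } else {
      expect_false(isHit(mean, sem * 2))       # wider SEM stays a non-hit
    }
  }
})
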