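tinyConfig <- function(...) {
  syntheticConfig(nExtracts = 120L, nReplicates = 3L, ...)
}

test_that("a noiseless null configuration reproduces the baselines exactly", {
  cfg <- tinyConfig(sigma = c(insulin = 0, pdx1 = 0, hoechst = 0,
                              cell_count = 0),
                    perimeterDelta = 0, hitFraction = 0, toxicFraction = 0,
                    artifactRate = 0)
  sim <- generateWellLevel(cfg, seed = 5)
  w <- sim$wells[sim$wells$valid, ]
  for (p in screenParameters())
    expect_equal(unique(w$value[w$parameter == p]),
                 unname(cfg$baseline[[p]]))
  expect_true(all(sim$truth$label == "null"))
})

test_that("generation is deterministic down to CSV bytes", {
  cfg <- tinyConfig()
  a <- generateWellLevel(cfg, seed = 17)
  b <- generateWellLevel(cfg, seed = 17)
  expect_identical(a$wells, b$wells)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$layouts, wellRoles), lapply(b$layouts, wellRoles))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeScreenData(a, d1); writeScreenData(b, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)

  # a different seed moves the data
  c2 <- generateWellLevel(cfg, seed = 18)
  expect_false(identical(a$wells$value, c2$wells$value))
})

test_that("perimeter wells are depressed by the configured amplitude", {
  cfg <- tinyConfig(hitFraction = 0, toxicFraction = 0, artifactRate = 0)
  sim <- generateWellLevel(cfg, seed = 9)
  w <- sim$wells[sim$wells$valid & sim$wells$parameter == "insulin", ]
  idx <- parseWellLabel(w$well)
  edges <- (idx[, "row"] %in% c(0, 7)) + (idx[, "col"] %in% c(0, 11))
  interior <- mean(w$value[edges == 0])
  edge1 <- mean(w$value[edges == 1])
  # depression is perimeterDelta * sigma per edge membership
  expected <- cfg$perimeterDelta * cfg$sigma[["insulin"]]
  expect_equal(interior - edge1, expected, tolerance = 0.15)
  # null well values center on the baseline (3 sigma / sqrt(n) check)
  expect_lt(abs(interior - cfg$baseline[["insulin"]]),
            3 * cfg$sigma[["insulin"]] / sqrt(sum(edges == 0)))
})

test_that("spiked sets are disjoint and truth labels are consistent", {
  cfg <- syntheticConfig(nExtracts = 1319L)
  sim <- generateWellLevel(cfg, seed = 3)
  tr <- sim$truth
  expect_equal(nrow(tr), 1319L)
  expect_equal(sum(tr$label == "toxic"), round(0.15 * 1319))
  expect_equal(sum(tr$label %in% c("hit_up", "hit_down")),
               round(0.005 * 1319))
  hits <- tr[tr$label %in% c("hit_up", "hit_down"), ]
  expect_true(all(hits$theta_cellcount == 0))       # disjoint from toxicity
  expect_true(all((hits$label == "hit_up") ==
                    (pmax(hits$theta_insulin, hits$theta_pdx1) > 0)))
  mag <- abs(hits$theta_insulin) + abs(hits$theta_pdx1)
  expect_true(all(mag >= 4 | hits$theta_insulin != 0 & hits$theta_pdx1 != 0))
  tox <- tr[tr$label == "toxic", ]
  expect_true(all(tox$theta_cellcount == cfg$toxicCellCountEffect))
  expect_true(all(tox$theta_hoechst == cfg$toxicHoechstEffect))
})

test_that("cell-level generation matches count expectations", {
  cfg <- syntheticConfig(nExtracts = 88L, nReplicates = 1L,
                         perimeterDelta = 0, hitFraction = 0,
                         toxicFraction = 0, artifactRate = 0,
                         cellsPerWell = 50)
  sim <- generateCellLevel(cfg, seed = 21)
  # ~ 96 wells x lambda cells, Poisson-variable
  expect_equal(nrow(sim$cells), 96 * 50, tolerance = 0.05)
  expect_true(all(sim$cells$ch1_avg > 0))

  # toxicity multiplies the expected count down via the cell-count target
  cfgTox <- syntheticConfig(nExtracts = 88L, nReplicates = 1L,
                            perimeterDelta = 0, hitFraction = 0,
                            toxicFraction = 0.5, artifactRate = 0,
                            toxicCellCountEffect = -4)
  simT <- generateCellLevel(cfgTox, seed = 22)
  counts <- table(factor(simT$cells$well, levels = allWellLabels()))
  lay <- wellRoles(simT$layouts[[1]])
  toxIds <- simT$truth$extract_id[simT$truth$label == "toxic"]
  toxWells <- lay$well[lay$extract_id %in% toxIds & !is.na(lay$extract_id)]
  cleanWells <- lay$well[lay$role == "sample" & !lay$well %in% toxWells]
  expectedMult <- 1 + cfgTox$toxicCellCountEffect *
    cfgTox$sigma[["cell_count"]] / cfgTox$baseline[["cell_count"]]
  expect_equal(mean(counts[toxWells]) / mean(counts[cleanWells]),
               expectedMult, tolerance = 0.15)
})

test_that("per-cell medians converge to the well target as cells increase", {
  cfg <- syntheticConfig(nExtracts = 20L, nPlates = 1L, nReplicates = 1L,
                         sigma = c(insulin = 0, pdx1 = 0, hoechst = 0,
                                   cell_count = 0),
                         perimeterDelta = 0, hitFraction = 0,
                         toxicFraction = 0, artifactRate = 0,
                         cellsPerWell = 1000)
  sim <- generateCellLevel(cfg, seed = 23)
  med <- tapply(sim$cells$ch2_avg, sim$cells$well, median)
  relErr <- abs(med - 500) / 500
  expect_lt(max(relErr), 0.08)
  expect_lt(mean(relErr), 0.03)
})

test_that("cell-level data flow through summarization unchanged in shape", {
  cfg <- syntheticConfig(nExtracts = 40L, nPlates = 1L, nReplicates = 2L,
                         cellsPerWell = 15)
  sim <- generateCellLevel(cfg, seed = 24)
  s <- summarizeScreen(sim$cells, sim$layouts, sim$mask)
  mats <- buildPlateMatrices(s, sim$layouts)
  expect_equal(length(mats), 2L * 4L)       # 1 plate x 2 replicates x 4 params
  expect_true(all(vapply(mats, function(m) any(!is.na(plateValues(m))),
                         logical(1))))
})

test_that("recovery evaluation scores calls against ground truth", {
  truth <- data.frame(extract_id = paste0("E", 1:10),
                      label = c(rep("null", 7), "hit_up", "hit_down", "toxic"),
                      theta_insulin = c(rep(0, 7), 4.5, -4, 0),
                      theta_pdx1 = 0, theta_hoechst = c(rep(0, 9), 6),
                      theta_cellcount = c(rep(0, 9), -7))
  perfect <- data.frame(extract_id = c("E8", "E9"), parameter = "insulin",
                        direction = c("up", "down"), mean_bscore = c(4, -4),
                        sem = 0.1, band_lower = -1, band_upper = 1)
  r <- evaluateRecovery(perfect, truth, excludedIds = "E10")
  pp <- r$per_parameter[r$per_parameter$parameter == "insulin", ]
  expect_equal(pp$sensitivity, 1)
  expect_equal(pp$fdr, 0)
  expect_equal(pp$specificity, 1)
  expect_equal(r$exclusion$toxic_excluded_rate, 1)
  expect_equal(r$exclusion$clean_excluded_rate, 0)

  none <- perfect[0, ]
  r0 <- evaluateRecovery(none, truth)
  pp0 <- r0$per_parameter[r0$per_parameter$parameter == "insulin", ]
  expect_equal(pp0$sensitivity, 0)
  expect_equal(pp0$specificity, 1)

  # a wrong-direction call is a false positive, not a recovery
  flipped <- transform(perfect, direction = c("down", "up"))
  rf <- evaluateRecovery(flipped, truth)
  expect_equal(rf$per_parameter$sensitivity[1], 0)
  expect_equal(rf$per_parameter$fdr[1], 1)

  expect_error(evaluateRecovery(
    transform(perfect, extract_id = c("E8", "Zn")), truth), "absent")
})

test_that("random calls recover at roughly the call rate", {
  set.seed(25)
  n <- 400
  truth <- data.frame(extract_id = sprintf("E%03d", 1:n),
                      label = "null", theta_insulin = 0, theta_pdx1 = 0,
                      theta_hoechst = 0, theta_cellcount = 0)
  spike <- sample.int(n, 40)
  truth$theta_insulin[spike] <- 4.5
  truth$label[spike] <- "hit_up"
  callRate <- 0.25
  called <- sample.int(n, n * callRate)
  hits <- data.frame(extract_id = truth$extract_id[called],
                     parameter = "insulin", direction = "up",
                     mean_bscore = 3, sem = 0.1,
                     band_lower = -1, band_upper = 1)
  r <- evaluateRecovery(hits, truth)
  expect_equal(r$per_parameter$sensitivity[1], callRate, tolerance = 0.5)
})
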