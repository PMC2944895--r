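# Independent brute-force median-polish oracle: explicit loops, no shared
# code with the package implementation. Sweeps rows then columns until the
# largest single-cell residual change over a full sweep pair is below eps.
oracleMedianPolish <- function(x, maxSweeps = 500L, eps = 1e-12) {
  nr <- nrow(x); nc <- ncol(x)
  resid <- x
  roweff <- rep(0, nr); coleff <- rep(0, nc); grand <- 0
  for (s in seq_len(maxSweeps)) {
    before <- resid
    for (i in seq_len(nr)) {
      m <- median(resid[i, ], na.rm = TRUE)
      resid[i, ] <- resid[i, ] - m
      roweff[i] <- roweff[i] + m
    }
    m <- median(roweff)
    roweff <- roweff - m; grand <- grand + m
    for (j in seq_len(nc)) {
      m <- median(resid[, j], na.rm = TRUE)
      resid[, j] <- resid[, j] - m
      coleff[j] <- coleff[j] + m
    }
    m <- median(coleff)
    coleff <- coleff - m; grand <- grand + m
    if (max(abs(resid - before), na.rm = TRUE) < eps) break
  }
  list(grand = grand, roweff = roweff, coleff = coleff, resid = resid)
}

# random plate with optional missing wells, guaranteed no all-missing line
randomPlate <- function(nr = 8, nc = 12, missFrac = 0) {
  repeat {
    m <- matrix(rnorm(nr * nc), nr, nc)
    if (missFrac > 0)
      m[runif(nr * nc) < missFrac] <- NA
    if (all(rowSums(!is.na(m)) > 0) && all(colSums(!is.na(m)) > 0))
      return(m)
  }
}

# minimal valid cell table for one or more wells
makeCells <- function(well = "A01", n = 3, plate = "P1", rep = "R1",
                      ch1 = NULL, ch2 = NULL, ch3 = NULL) {
  base <- function(x, def) if (is.null(x)) def else x
  data.frame(plate_id = plate, replicate_id = rep, well = well,
             object_id = seq_len(n),
             ch1_avg = base(ch1, rexp(n) + 1), ch1_total = 1, ch1_var = 0.1,
             ch2_avg = base(ch2, rexp(n) + 1), ch2_total = 1, ch2_var = 0.1,
             ch3_avg = base(ch3, rexp(n) + 1), ch3_total = 1, ch3_var = 0.1,
             stringsAsFactors = FALSE)
}

# small complete layout: 96 wells, 8 controls, rest samples
smallLayout <- function(plate = "P1", nControls = 8) {
  wells <- allWellLabels()
  ctrl <- wells[seq_len(nControls)]
  smp <- setdiff(wells, ctrl)
  PlateLayout(plate, data.frame(
    well = c(ctrl, smp),
    role = c(rep("control", length(ctrl)), rep("sample", length(smp))),
    extract_id = c(rep(NA, length(ctrl)), paste0("X", seq_along(smp))),
    stringsAsFactors = FALSE))
}
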