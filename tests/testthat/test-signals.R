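test_that("ROI extraction averages labelled voxels per volume", {
  grid <- array(7, c(3, 3, 2, 5))
  labels <- array(rep(1:2, each = 9), c(3, 3, 2))
  rts <- extractRoiSeries(grid, labels)
  expect_true(all(regionalSeries(rts) == 7))
  # two-voxel region with values 1 and 3 averages to 2
  g2 <- array(0, c(2, 1, 1, 1))
  g2[1, 1, 1, 1] <- 1; g2[2, 1, 1, 1] <- 3
  l2 <- array(1L, c(2, 1, 1))
  expect_equal(as.numeric(regionalSeries(extractRoiSeries(g2, l2))), 2)
  expect_error(extractRoiSeries(grid, array(1L, c(2, 2, 2))),
               "different voxel grids")
  lbad <- labels; lbad[labels == 1] <- 3L
  expect_error(extractRoiSeries(grid, lbad), "zero voxels")
})

test_that("lag shift converts seconds to dropped volumes", {
  s <- matrix(seq_len(40), 20, 2)
  rts <- roiTimeseries(s, tr = 2)
  expect_equal(lagShift(rts, 10)@lagVolumes, 5L)
  expect_equal(lagShift(rts, 8)@lagVolumes, 4L)
  expect_equal(lagShift(rts, 12)@lagVolumes, 6L)
  expect_identical(lagShift(rts, 0), rts)
  expect_equal(nrow(regionalSeries(lagShift(rts, 10))), 15)
  expect_equal(unname(regionalSeries(lagShift(rts, 10))[1, 1]), 6)
  expect_error(lagShift(rts, 7), "multiple of TR")
  expect_error(lagShift(rts, 40), "every volume")
})

test_that("z-scoring and lag-shifting commute on interior volumes", {
  set.seed(2)
  rts <- roiTimeseries(matrix(rnorm(120), 40, 3), tr = 2)
  a <- regionalSeries(lagShift(zscoreSeries(rts), 10))
  b <- regionalSeries(zscoreSeries(lagShift(rts, 10)))
  # same ordering of volumes; values differ only by the per-column affine
  # refit, so correlation per column is exactly 1
  for (j in 1:3) expect_equal(stats::cor(a[, j], b[, j]), 1)
})

test_that("DVARS is zero for constant data and matches hand arithmetic", {
  g <- array(5, c(2, 2, 2, 4))
  dv <- dvars(g)
  expect_true(all(dv$values == 0))
  expect_length(dv$flagged, 0)
  expect_false(dv$exclude)
  # two volumes, voxel diffs 3 and 4 -> sqrt((9 + 16) / 2)
  g2 <- array(0, c(2, 1, 1, 2))
  g2[, 1, 1, 2] <- c(3, 4)
  dv2 <- dvars(g2, normalize = FALSE)
  expect_equal(dv2$values[2], sqrt((9 + 16) / 2))
  # invariant to adding a spatial constant to every volume
  g3 <- array(rnorm(8 * 6), c(2, 2, 2, 6))
  expect_equal(dvars(g3, normalize = FALSE)$values,
               dvars(g3 + 100, normalize = FALSE)$values)
})

test_that("the exclusion predicate fires only above the flagged fraction", {
  base <- array(1000, c(3, 3, 3, 20))
  jump <- function(vols) {
    g <- base
    lvl <- 0
    for (v in 2:20) {
      if (v %in% vols) lvl <- lvl + 60
      g[, , , v] <- 1000 + lvl
    }
    g
  }
  # 3 of 20 volumes (15%) over threshold: no exclusion
  dv15 <- dvars(jump(c(5, 10, 15)))
  expect_equal(length(dv15$flagged), 3)
  expect_false(dv15$exclude)
  # 5 of 20 volumes (25%): excluded
  dv25 <- dvars(jump(c(4, 8, 12, 16, 20)))
  expect_equal(length(dv25$flagged), 5)
  expect_true(dv25$exclude)
})

test_that("motion expansion yields the standard 24 regressors", {
  set.seed(3)
  m <- matrix(rnorm(60), 10, 6)
  out <- expandMotionConfounds(m)
  expect_equal(ncol(out), 24)
  expect_equal(out[, 1:6], m, ignore_attr = TRUE)
  expect_equal(out[, 7:12], m^2, ignore_attr = TRUE)
  expect_true(all(out[1, 13:24] == 0))
  expect_true(all(expandMotionConfounds(matrix(0, 5, 6)) == 0))
  const <- expandMotionConfounds(matrix(2, 5, 6))
  expect_true(all(const[, 13:24] == 0))       # derivatives of a constant
  expect_true(all(const[-1, 7:12] == 4))
  expect_error(expandMotionConfounds(matrix(0, 5, 5)), "6 columns")
})

test_that("design matrices carry the stated regressor counts", {
  d <- generateDesign(runs = 1, seed = 6)
  nv <- ceiling(runDuration(d, 1) / 2)
  Xt <- buildDesignMatrix(d, model = "task", tr = 2, nVolumes = nv)
  expect_equal(sum(attr(Xt, "kind") == "task"), 16)
  Xs <- buildDesignMatrix(d, model = "switch_dimension", tr = 2,
                          nVolumes = nv)
  expect_equal(sum(attr(Xs, "kind") == "task"), 8)
  set.seed(1)
  mo <- matrix(rnorm(nv * 6, sd = 0.01), nv, 6)
  Xm <- buildDesignMatrix(d, model = "task", tr = 2, nVolumes = nv,
                          motion = mo, censor = c(10, 20))
  expect_equal(sum(attr(Xm, "kind") == "motion"), 24)
  expect_equal(sum(attr(Xm, "kind") == "censor"), 2)
  expect_error(buildDesignMatrix(d, nVolumes = 10), "shorter than")
})

test_that("task regressors align with their blocks", {
  d <- generateDesign(runs = 1, seed = 6)
  tr_s <- 2
  nv <- ceiling(runDuration(d, 1) / tr_s)
  X <- buildDesignMatrix(d, model = "task", tr = tr_s, nVolumes = nv)
  lab <- conditionVolumeLabels(d, 1, tr_s, nv)
  for (cn in c("PPP", "UUU")) {
    reg <- X[, paste0("block_", cn)]
    box <- as.numeric(!is.na(lab) & lab == cn)
    cc <- stats::ccf(reg, box, lag.max = 10, plot = FALSE)
    best <- cc$lag[which.max(cc$acf)]
    # HRF delay shifts the peak response a few volumes after the boxcar
    expect_true(best >= 0 && best <= 5)
    expect_gt(max(cc$acf), 0.8)
  }
})

test_that("zero-duration events produce empty regressors", {
  d <- generateDesign(runs = 1, seed = 6)
  d@trials$duration_s[] <- 0
  X <- buildDesignMatrix(d, model = "switch_dimension", tr = 2)
  expect_true(all(abs(X[, attr(X, "kind") == "task"]) < 1e-12))
})

test_that("OLS contrasts recover injected responses and control type I", {
  d <- generateDesign(runs = 1, seed = 6)
  nv <- ceiling(runDuration(d, 1) / 2)
  X <- buildDesignMatrix(d, model = "task", tr = 2, nVolumes = nv)
  set.seed(8)
  target <- X[, "block_PPP"]
  y <- 5 * target + rnorm(nv, sd = 0.1)
  cvec <- as.numeric(colnames(X) == "block_PPP")
  fit <- olsContrast(y, X, cvec)
  expect_gt(fit$t, 20)
  expect_gt(fit$z, 8)
  # contrast orthogonal to the injected signal stays in the null band
  cort <- as.numeric(colnames(X) == "block_UUU")
  set.seed(9)
  tnull <- replicate(200, {
    yy <- 5 * target + rnorm(nv)
    olsContrast(yy, X, cort)$t
  })
  expect_lt(abs(mean(tnull)), 0.2)
  expect_lt(stats::quantile(abs(tnull), 0.5), 1.5)
  # pure-noise responses: empirical type-I close to nominal
  set.seed(10)
  Y <- matrix(rnorm(nv * 1000), nv)
  ft <- olsContrast(Y, X, cvec)
  pvals <- 2 * stats::pt(-abs(ft$t), ft$df)
  expect_gt(mean(pvals < 0.05), 0.03)
  expect_lt(mean(pvals < 0.05), 0.07)
  # rank deficiency is reported with the offending columns
  Xbad <- cbind(X, dup = X[, 1])
  expect_error(olsContrast(y, Xbad, c(cvec, 0)), "rank deficient")
})
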