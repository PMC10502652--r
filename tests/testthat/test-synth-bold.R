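test_that("the double-gamma HRF has canonical shape", {
  expect_equal(hrf(0), 0)
  tt <- seq(0, 30, by = 0.01)
  pk <- tt[which.max(hrf(tt))]
  expect_gte(pk, 5)
  expect_lte(pk, 6)
  expect_gt(sum(hrf(seq(0, 32, 0.01))) * 0.01, 0)  # positive net response
  expect_error(hrf(-1))
})

test_that("coupling specs validate their ground truth", {
  cs <- couplingSpec(i = 1, j = 2, form = "linear", strength = 0.6)
  expect_equal(cs@pairs$mi_nats, -0.5 * log(1 - 0.36))
  suppressWarnings(
    expect_error(couplingSpec(i = 1, j = 2, form = "linear",
                              strength = 1.2), "correlation"))
  expect_s4_class(couplingSpec(), "CouplingSpec")
})

test_that("noise-free uncoupled simulation gives constant series", {
  d <- generateDesign(runs = 1, seed = 2)
  sb <- simulateBold(d, nRegions = 3, betas = 0, noiseSd = 0, seed = 1)
  s <- regionalSeries(sb)
  expect_true(all(apply(s, 2, stats::sd) == 0))
})

test_that("linear coupling reproduces the requested correlation", {
  d <- generateDesign(runs = 1, seed = 2)
  cs <- couplingSpec(i = 1, j = 2, form = "linear", strength = 0.9)
  # pool several independently seeded runs for a tight empirical estimate
  xy <- do.call(rbind, lapply(1:12, function(s) {
    regionalSeries(simulateBold(d, coupling = cs, nRegions = 2,
                                seed = s))[, 1:2]
  }))
  expect_gt(nrow(xy), 4800)
  expect_lt(abs(stats::cor(xy[, 1], xy[, 2]) - 0.9), 0.05)
})

test_that("condition-restricted coupling is absent elsewhere", {
  d <- generateDesign(runs = 1, seed = 4)
  cs <- couplingSpec(i = 1, j = 2, form = "linear", strength = 0.8,
                     conditions = "PPP")
  sb <- simulateBold(d, coupling = cs, nRegions = 2, seed = 3)
  s <- regionalSeries(sb)
  lab <- conditionVolumeLabels(d, 1, 2, nrow(s))
  on <- !is.na(lab) & lab == "PPP"
  off <- !is.na(lab) & lab != "PPP"
  expect_gt(stats::cor(s[on, 1], s[on, 2]), 0.5)
  expect_lt(abs(stats::cor(s[off, 1], s[off, 2])), 0.2)
})

test_that("quadratic coupling is nonlinear: high MI, null correlation", {
  d <- generateDesign(runs = 1, seed = 2)
  cs <- couplingSpec(i = 1, j = 2, form = "quadratic", strength = 0.9)
  xy <- do.call(rbind, lapply(1:12, function(s) {
    regionalSeries(simulateBold(d, coupling = cs, nRegions = 2,
                                seed = 100 + s))[, 1:2]
  }))
  mi <- mutualInformation(xy[, 1], xy[, 2])
  expect_gt(mi@miNats, 0.2)
  # Monte-Carlo null band for |r| at this n from independent pairs
  set.seed(1)
  nullr <- replicate(200, abs(stats::cor(stats::rnorm(nrow(xy)),
                                         stats::rnorm(nrow(xy)))))
  expect_lt(abs(stats::cor(xy[, 1], xy[, 2])), stats::quantile(nullr, 0.999))
})

test_that("voxel grids broadcast regional series faithfully", {
  d <- generateDesign(runs = 1, seed = 2)
  sb <- simulateBold(d, nRegions = 4, gridShape = c(6, 4, 2),
                     voxelNoiseSd = 0, seed = 9)
  rts <- extractRoiSeries(sb@grid, sb@labels, tr = sb@tr)
  expect_equal(unname(regionalSeries(rts)), unname(regionalSeries(sb)),
               tolerance = 1e-12)
  # volume counts agree between grid, series and motion
  expect_equal(dim(sb@grid)[4], nrow(regionalSeries(sb)))
  expect_equal(nrow(sb@motion), nrow(regionalSeries(sb)))
})

test_that("coupling referencing a missing region is rejected", {
  d <- generateDesign(runs = 1, seed = 2)
  cs <- couplingSpec(i = 1, j = 9, form = "linear", strength = 0.5)
  expect_error(simulateBold(d, coupling = cs, nRegions = 4), "region index")
})

test_that("statistic maps place their bumps where requested", {
  one <- simulateStatMap(data.frame(x = 10, y = 12, z = 8, amplitude = 5,
                                    width = 2.5), c(20, 24, 16))
  expect_equal(arrayInd(which.max(one), dim(one)),
               matrix(c(10L, 12L, 8L), 1))
  two <- simulateStatMap(data.frame(x = c(6, 26), y = c(8, 8), z = c(8, 8),
                                    amplitude = c(5, 4), width = c(2, 2)),
                         c(32, 16, 16))
  mx <- local_maxima_oracle(two, 0.5)
  expect_equal(nrow(mx), 2)
  zero <- simulateStatMap(data.frame(x = numeric(0), y = numeric(0),
                                     z = numeric(0), amplitude = numeric(0),
                                     width = numeric(0)), c(5, 5, 5))
  expect_true(all(zero == 0))
  expect_error(simulateStatMap(data.frame(x = 99, y = 1, z = 1,
                                          amplitude = 1, width = 1),
                               c(5, 5, 5)))
})

test_that("motion spikes drive DVARS and clean traces stay quiet", {
  clean <- simulateMotion(40, seed = 3)
  dv0 <- dvars(clean$grid, threshold = 50)
  expect_length(dv0$flagged, 0)
  spiked <- simulateMotion(40, spikeVolumes = c(15, 30), seed = 3)
  dv <- dvars(spiked$grid, threshold = 50)
  # a transient spike disturbs the difference into and out of volume k
  expect_true(which.max(dv$values) %in% c(15, 16))
  expect_setequal(order(dv$values, decreasing = TRUE)[1:4],
                  c(15, 16, 30, 31))
  again <- simulateMotion(40, spikeVolumes = c(15, 30), seed = 3)
  expect_identical(spiked$grid, again$grid)
  expect_identical(spiked$motion, again$motion)
  expect_error(simulateMotion(10, spikeVolumes = 1))
})
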