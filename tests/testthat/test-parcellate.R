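test_that("a single smooth bump yields one region containing its peak", {
  m <- simulateStatMap(data.frame(x = 10, y = 10, z = 8, amplitude = 6,
                                  width = 3), c(20, 20, 16))
  p <- watershedParcellate(m, 1.0)
  labs <- parcelLabels(p)
  expect_equal(max(labs), 1L)
  pk <- arrayInd(which.max(m), dim(m))
  expect_equal(labs[pk], 1L)
})

test_that("well-separated bumps match the components/local-maxima oracle", {
  m <- simulateStatMap(data.frame(x = c(10, 30), y = c(10, 30), z = c(8, 8),
                                  amplitude = c(6, 5), width = c(3, 3)),
                       c(40, 40, 16))
  thr <- 1.0
  p <- watershedParcellate(m, thr)
  labs <- parcelLabels(p)
  # oracle: subthreshold trough separates the bumps into two components,
  # each holding one local maximum
  cc <- cc_oracle(m > thr)
  expect_equal(max(labs), max(cc))
  expect_equal(nrow(local_maxima_oracle(m, thr)), max(labs))
  # labels 1..K in decreasing peak order; each region holds a local max
  mx <- local_maxima_oracle(m, thr)
  for (k in seq_len(max(labs)))
    expect_true(any(labs[mx] == k))
  expect_gte(p@peaks$peak_stat[1], p@peaks$peak_stat[2])
})

test_that("small basins merge into their large neighbour", {
  # hand-built grid: a 500-voxel basin (10x10x5) face-adjacent to a
  # 60-voxel basin (4x5x3), each with an interior gradient to its own peak
  g <- array(0, c(24, 12, 9))
  big_peak <- c(4, 6, 5)
  for (x in 1:10) for (y in 2:11) for (z in 3:7)
    g[x, y, z] <- 5 - 0.05 * sqrt(sum((c(x, y, z) - big_peak)^2))
  small_peak <- c(13, 6, 5)
  for (x in 11:14) for (y in 4:8) for (z in 4:6)
    g[x, y, z] <- 4 - 0.05 * sqrt(sum((c(x, y, z) - small_peak)^2))
  expect_equal(sum(g > 1), 560)
  # with merging disabled both basins survive (boundary voxels contested
  # by winner-takes-all, so the small basin keeps most but not all of its
  # 60 nominal voxels)
  p0 <- watershedParcellate(g, 1, mergeThreshold = 1L)
  expect_equal(max(parcelLabels(p0)), 2L)
  sizes <- sort(as.integer(table(parcelLabels(p0)[parcelLabels(p0) > 0])))
  expect_lt(sizes[1], 100L)
  expect_gte(sizes[1], 40L)
  expect_gt(sizes[2], 100L)
  expect_equal(sum(sizes), 560L)
  # ... at the stated threshold the small basin (< 100) is absorbed
  p1 <- watershedParcellate(g, 1, mergeThreshold = 100L)
  expect_equal(max(parcelLabels(p1)), 1L)
  expect_equal(sum(parcelLabels(p1) == 1L), 560)
})

test_that("labelling is a partition of the suprathreshold set and idempotent", {
  set.seed(4)
  m <- simulateStatMap(data.frame(x = c(8, 20, 30), y = c(10, 25, 8),
                                  z = c(6, 10, 12),
                                  amplitude = c(5, 4, 4.5),
                                  width = c(3, 4, 3)),
                       c(40, 40, 16), noiseSd = 0.15, seed = 4)
  thr <- 0.8
  p <- watershedParcellate(m, thr, mergeThreshold = 50L)
  labs <- parcelLabels(p)
  expect_true(all((labs > 0) == (m > thr)))            # partition
  expect_setequal(unique(labs[labs > 0]), seq_len(max(labs)))  # contiguous
  p2 <- watershedParcellate(m, thr, mergeThreshold = 50L)
  expect_identical(parcelLabels(p2), labs)             # deterministic
  # no small region still touches another region
  sizes <- tabulate(labs[labs > 0])
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  adj <- matrix(FALSE, max(labs), max(labs))
  idx <- which(labs > 0)
  co <- arrayInd(idx, dim(labs))
  for (o in seq_len(nrow(offs))) {
    nc <- sweep(co, 2, as.numeric(offs[o, ]), `+`)
    ok <- nc[, 1] >= 1 & nc[, 1] <= dim(labs)[1] &
      nc[, 2] >= 1 & nc[, 2] <= dim(labs)[2] &
      nc[, 3] >= 1 & nc[, 3] <= dim(labs)[3]
    lin <- nc[ok, 1] + (nc[ok, 2] - 1) * dim(labs)[1] +
      (nc[ok, 3] - 1) * dim(labs)[1] * dim(labs)[2]
    a <- labs[idx[ok]]
    b <- labs[lin]
    keep <- b > 0 & a != b
    adj[cbind(a[keep], b[keep])] <- TRUE
  }
  for (a in seq_len(max(labs)))
    if (sizes[a] < 50 && any(adj[a, ]))
      fail(sprintf("region %d is small (%d voxels) but still adjacent",
                   a, sizes[a]))
  succeed()
})

test_that("empty suprathreshold sets are rejected", {
  m <- array(0, c(5, 5, 5))
  expect_error(watershedParcellate(m, 1), "suprathreshold")
})

test_that("regions inherit the majority atlas labels", {
  m <- simulateStatMap(data.frame(x = c(6, 16), y = c(6, 6), z = c(5, 5),
                                  amplitude = c(6, 6), width = c(2, 2)),
                       c(20, 12, 10))
  p <- watershedParcellate(m, 1, mergeThreshold = 1L)
  expect_equal(max(parcelLabels(p)), 2L)
  lookup <- data.frame(atlas_id = 1:2,
                       anatomical_name = c("insula L", "parietal R"),
                       network_17 = c("SalVentAttnA", "DorsAttnA"),
                       network_7 = c("SalVentAttn", "DorsAttn"))
  # region 1 entirely in atlas parcel 1; region 2 split ~70/30
  atlas <- array(0L, dim(m))
  atlas[1:11, , ] <- 1L
  atlas[12:20, , ] <- 2L
  labs <- parcelLabels(p)
  r2 <- which(labs == labs[16, 6, 5])
  in2 <- mean(atlas[r2] == 2L)
  expect_gt(in2, 0.5)
  tab <- labelToTable(p, m, atlas, lookup)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$network_17[tab$label_id == labs[6, 6, 5]],
               "SalVentAttnA")
  expect_equal(tab$network_17[tab$label_id == labs[16, 6, 5]], "DorsAttnA")
  expect_true(all(tab$n_voxels > 0))
  # region overlapping only atlas background -> unassigned
  atlas0 <- array(0L, dim(m))
  tab0 <- labelToTable(p, m, atlas0, lookup)
  expect_true(all(tab0$network_17 == "unassigned"))
  # grid mismatch rejected
  expect_error(labelToTable(p, m, array(0L, c(4, 4, 4)), lookup),
               "different voxel grids")
})
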