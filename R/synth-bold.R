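#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities: response peaking near 5-6 s and an
#' undershoot peaking near 16 s scaled by `ratio`. The default shape/scale
#' pair (shapes 6 and 16, scale 1, undershoot ratio 1/6) is the widely used
#' canonical parameterisation.
#'
#' @param t time since event onset, seconds (vectorised, t >= 0).
#' @param peakShape,undershootShape gamma shapes of response and undershoot.
#' @param scale common gamma scale, seconds.
#' @param ratio undershoot amplitude ratio.
#' @return HRF amplitude at `t` (0 at t = 0).
#' @examples
#' t <- seq(0, 30, 0.1)
#' t[which.max(hrf(t))]  # ~5 s
#' @export
hrf <- function(t, peakShape = 6, undershootShape = 16, scale = 1,
                ratio = 1 / 6) {
  stopifnot(all(t >= 0))
  stats::dgamma(t, shape = peakShape, scale = scale) -
    ratio * stats::dgamma(t, shape = undershootShape, scale = scale)
}

#' Construct a coupling specification
#'
#' @param i,j region indices of each coupled pair.
#' @param form `"linear"` or `"quadratic"` per pair.
#' @param strength correlation rho in (-1, 1) for linear pairs; scaling of
#'   the centred-square transform for quadratic pairs.
#' @param conditions per pair: `"all"` or a ';'-joined set of condition
#'   triplet labels (see [tripletLabel()]) in which the coupling is active.
#' @return a [CouplingSpec-class]. Linear pairs carry the analytic ground
#'   truth MI of -1/2 log(1 - rho^2) nats; quadratic pairs carry NA (their
#'   ground truth is estimated numerically where needed).
#' @export
couplingSpec <- function(i = integer(0), j = integer(0),
                         form = character(0), strength = numeric(0),
                         conditions = "all") {
  n <- length(i)
  if (n == 0)
    return(new("CouplingSpec", pairs = data.frame(
      i = integer(0), j = integer(0), form = character(0),
      strength = numeric(0), conditions = character(0),
      mi_nats = numeric(0))))
  conditions <- rep_len(conditions, n)
  form <- rep_len(form, n)
  strength <- rep_len(strength, n)
  mi <- ifelse(form == "linear", -0.5 * log(1 - strength^2), NA_real_)
  new("CouplingSpec", pairs = data.frame(
    i = as.integer(i), j = as.integer(j), form = form, strength = strength,
    conditions = conditions, mi_nats = mi, stringsAsFactors = FALSE))
}

#' Condition label of each volume in a run
#'
#' Maps scanner volumes onto the design: a volume whose midpoint falls
#' inside a task block inherits that block's condition triplet label;
#' volumes in rest periods get `NA`.
#'
#' @param design a [TaskDesign-class].
#' @param run run index.
#' @param tr repetition time, seconds.
#' @param nVolumes number of volumes to label.
#' @return character vector of length `nVolumes` (condition label or NA).
#' @export
conditionVolumeLabels <- function(design, run, tr, nVolumes) {
  trd <- design@trials[design@trials$run == run, ]
  mids <- (seq_len(nVolumes) - 0.5) * tr
  out <- rep(NA_character_, nVolumes)
  for (b in unique(trd$block)) {
    blk <- trd[trd$block == b, ]
    t0 <- min(blk$onset_s)
    t1 <- max(blk$onset_s + blk$duration_s)
    out[mids >= t0 & mids < t1] <- blk$condition[1]
  }
  out
}

# coupled noise for one pair over the active volumes: linear pairs share a
# bivariate-normal draw at correlation rho; quadratic pairs pass the first
# region's noise through a centred square normalised to unit variance
apply_coupling <- function(noise, pair, active) {
  x <- noise[active, pair$i]
  eta <- stats::rnorm(length(x))
  if (pair$form == "linear") {
    y <- pair$strength * x + sqrt(1 - pair$strength^2) * eta
  } else {
    y <- pair$strength * (x^2 - 1) / sqrt(2) +
      sqrt(max(0, 1 - pair$strength^2)) * eta
  }
  noise[active, pair$j] <- y
  noise
}

#' Simulate regional BOLD data for one run
#'
#' Each region's series is the sum of HRF-convolved block regressors scaled
#' by `betas` plus Gaussian noise. For coupled region pairs, during the
#' volumes belonging to the pair's active conditions, the noise is drawn
#' with the specified dependence (bivariate normal for linear coupling, a
#' unit-variance centred-square transform for quadratic coupling);
#' elsewhere the regions are independent. When `gridShape` is supplied, a
#' voxel grid is populated by broadcasting each region's series to its
#' labelled voxels plus voxel-level noise, so that region-wise voxel means
#' reproduce the regional series up to that noise.
#'
#' @param design a [TaskDesign-class].
#' @param run which run to simulate.
#' @param coupling a [CouplingSpec-class] (default: none).
#' @param nRegions number of regions (>= 2).
#' @param tr repetition time, seconds.
#' @param betas task-activation amplitude: scalar, per-region vector, or
#'   nRegions x 8 matrix over the condition triplets (columns in
#'   [conditionTriplets()] order). Default 0 (noise-only, exact coupling
#'   ground truth).
#' @param noiseSd regional noise SD.
#' @param voxelNoiseSd voxel-level noise SD on top of the regional signal.
#' @param gridShape length-3 integer vector, or NULL for no voxel grid.
#' @param seed RNG seed.
#' @return a [SyntheticBold-class].
#' @export
simulateBold <- function(design, run = 1L, coupling = couplingSpec(),
                         nRegions = 10L, tr = 2, betas = 0, noiseSd = 1,
                         voxelNoiseSd = 0.5, gridShape = NULL, seed = 1L) {
  stopifnot(nRegions >= 2, tr > 0)
  pr <- coupling@pairs
  if (nrow(pr) && any(c(pr$i, pr$j) > nRegions))
    stop("coupling names a region index larger than nRegions")
  set.seed(as.integer(seed))
  nVolumes <- as.integer(ceiling(runDuration(design, run) / tr))
  vol_cond <- conditionVolumeLabels(design, run, tr, nVolumes)

  # task signal: one HRF-convolved boxcar per condition triplet (skipped
  # entirely for noise-only simulations)
  trips <- conditionTriplets()$condition
  B <- matrix(0, nRegions, length(trips))
  B[] <- betas  # recycles scalar/vector/matrix
  if (any(B != 0)) {
    X <- vapply(trips, function(cn) {
      trd <- design@trials[design@trials$run == run &
                             design@trials$condition == cn, ]
      block_regressor(min(trd$onset_s),
                      max(trd$onset_s + trd$duration_s) - min(trd$onset_s),
                      tr, nVolumes)
    }, numeric(nVolumes))
    signal <- X %*% t(B)
  } else {
    signal <- matrix(0, nVolumes, nRegions)
  }

  noise <- matrix(stats::rnorm(nVolumes * nRegions), nVolumes, nRegions)
  if (nrow(pr)) {
    for (k in seq_len(nrow(pr))) {
      conds <- strsplit(pr$conditions[k], ";", fixed = TRUE)[[1]]
      active <- if (identical(conds, "all")) rep(TRUE, nVolumes)
                else !is.na(vol_cond) & vol_cond %in% conds
      noise <- apply_coupling(noise, pr[k, ], active)
    }
  }
  series <- signal + noiseSd * noise
  colnames(series) <- paste0("R", seq_len(nRegions))

  grid <- array(NA_real_, c(0))
  labels <- array(NA_integer_, c(0))
  if (!is.null(gridShape)) {
    stopifnot(length(gridShape) == 3, prod(gridShape) >= nRegions)
    labels <- array(as.integer(cut(seq_len(prod(gridShape)), nRegions,
                                   labels = FALSE)), dim = gridShape)
    grid <- array(0, c(gridShape, nVolumes))
    lab_vec <- as.vector(labels)
    for (v in seq_len(nVolumes)) {
      grid[, , , v] <- series[v, lab_vec] +
        voxelNoiseSd * stats::rnorm(length(lab_vec))
    }
  }

  motion <- vapply(1:6, function(k) cumsum(stats::rnorm(nVolumes, sd = 0.005)),
                   numeric(nVolumes))
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")

  new("SyntheticBold", series = series, grid = grid, labels = labels,
      motion = motion, tr = tr, design = design, truth = coupling,
      run = as.integer(run))
}

#' Simulate a smooth 3D statistic map
#'
#' Sum of isotropic Gaussian bumps on a voxel grid plus optional noise;
#' the standard fixture for watershed parcellation.
#'
#' @param peaks data.frame with columns `x`, `y`, `z` (voxel centres),
#'   `amplitude`, `width` (Gaussian SD, voxels). Zero rows give an all-zero
#'   map.
#' @param gridShape length-3 integer vector.
#' @param noiseSd additive Gaussian noise SD (0 for a clean map).
#' @param seed RNG seed (used only if `noiseSd > 0`).
#' @return 3D numeric array.
#' @export
simulateStatMap <- function(peaks, gridShape, noiseSd = 0, seed = 1L) {
  vals <- array(0, gridShape)
  if (nrow(peaks)) {
    cx <- slice.index(vals, 1)
    cy <- slice.index(vals, 2)
    cz <- slice.index(vals, 3)
    for (k in seq_len(nrow(peaks))) {
      p <- peaks[k, ]
      stopifnot(p$x >= 1, p$x <= gridShape[1], p$y >= 1, p$y <= gridShape[2],
                p$z >= 1, p$z <= gridShape[3])
      d2 <- (cx - p$x)^2 + (cy - p$y)^2 + (cz - p$z)^2
      vals <- vals + p$amplitude * exp(-d2 / (2 * p$width^2))
    }
  }
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    vals <- vals + array(stats::rnorm(prod(gridShape), sd = noiseSd),
                         gridShape)
  }
  vals
}

#' Simulate a motion trace and a spiked 4D grid
#'
#' Produces a smooth low-amplitude rigid-body drift plus a small 4D grid
#' whose intensity is disrupted at the requested spike volumes - the
#' fixture for DVARS-based QC.
#'
#' @param nVolumes number of volumes.
#' @param spikeVolumes integer volume indices (> 1) receiving a large
#'   intensity disruption.
#' @param gridShape length-3 grid shape.
#' @param spikeAmplitude intensity of the disruption, in units of the
#'   baseline noise SD.
#' @param seed RNG seed.
#' @return list with `motion` (nVolumes x 6) and `grid` (4D array).
#' @export
simulateMotion <- function(nVolumes, spikeVolumes = integer(0),
                           gridShape = c(8, 8, 4), spikeAmplitude = 12,
                           seed = 1L) {
  stopifnot(all(spikeVolumes > 1), all(spikeVolumes <= nVolumes))
  set.seed(as.integer(seed))
  motion <- vapply(1:6, function(k) cumsum(stats::rnorm(nVolumes, sd = 0.004)),
                   numeric(nVolumes))
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  base <- 100
  grid <- array(base + stats::rnorm(prod(gridShape) * nVolumes),
                c(gridShape, nVolumes))
  for (v in spikeVolumes) {
    grid[, , , v] <- grid[, , , v] +
      spikeAmplitude * stats::rnorm(prod(gridShape))
    motion[v, 1:3] <- motion[v, 1:3] + 1.5
  }
  list(motion = motion, grid = grid)
}
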