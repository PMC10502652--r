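# --- regressor construction -------------------------------------------------

# HRF-convolved boxcar sampled at volume midpoints. Stimulus and kernel are
# built on a 0.1 s grid; the convolution is evaluated out to 32 s of HRF.
convolve_boxcar <- function(onsets, durations, tr, nVolumes, dt = 0.1) {
  t_end <- nVolumes * tr
  fine <- seq(0, t_end, by = dt)
  stim <- numeric(length(fine))
  for (k in seq_along(onsets)) {
    on <- fine >= onsets[k] & fine < onsets[k] + durations[k]
    stim[on] <- 1
  }
  kern <- hrf(seq(0, 32, by = dt))
  # zero-padded FFT convolution at a highly composite length
  nfull <- length(stim) + length(kern) - 1L
  nfft <- stats::nextn(nfull, 2)
  conv <- Re(stats::fft(stats::fft(c(stim, numeric(nfft - length(stim)))) *
                          stats::fft(c(kern, numeric(nfft - length(kern)))),
                        inverse = TRUE)) / nfft
  conv <- conv[seq_along(fine)] * dt
  mids <- (seq_len(nVolumes) - 0.5) * tr
  stats::approx(fine, conv, xout = mids, rule = 2)$y
}

block_regressor <- function(onset, duration, tr, nVolumes)
  convolve_boxcar(onset, duration, tr, nVolumes)

# --- ROI extraction and timeseries state ------------------------------------

#' Extract regional mean timeseries from a 4D grid
#'
#' @param grid 4D array (x, y, z, volume).
#' @param labels 3D integer label array on the same grid (0 = background).
#' @param tr repetition time, seconds.
#' @return a [RoiTimeseries-class]: column r is the mean over voxels with
#'   label r at each volume.
#' @export
extractRoiSeries <- function(grid, labels, tr = 2) {
  stopifnot(length(dim(grid)) == 4)
  if (!all(dim(grid)[1:3] == dim(labels)))
    stop("grid and label volume are on different voxel grids")
  lab <- as.integer(labels)
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) stop("label volume contains no labelled voxels")
  miss <- setdiff(seq_len(max(ids)), ids)
  if (length(miss))
    stop("region(s) with zero voxels: ", paste(miss, collapse = ", "))
  nv <- dim(grid)[4]
  mat <- matrix(grid, ncol = nv)
  keep <- lab > 0
  sums <- rowsum(mat[keep, , drop = FALSE], lab[keep])
  counts <- as.vector(table(lab[keep]))
  series <- t(sums / counts)
  colnames(series) <- paste0("R", ids)
  new("RoiTimeseries", series = series, tr = tr, zscored = FALSE,
      lagVolumes = 0L)
}

#' Build a RoiTimeseries from a plain matrix
#'
#' @param series volumes x regions matrix.
#' @param tr repetition time, seconds.
#' @return a [RoiTimeseries-class].
#' @export
roiTimeseries <- function(series, tr = 2) {
  series <- as.matrix(series)
  if (is.null(colnames(series)))
    colnames(series) <- paste0("R", seq_len(ncol(series)))
  new("RoiTimeseries", series = series, tr = tr, zscored = FALSE,
      lagVolumes = 0L)
}

#' Z-score each regional timeseries
#'
#' Centres every column to mean 0 and scales to SD 1.
#'
#' @param rts a [RoiTimeseries-class].
#' @return a z-scored [RoiTimeseries-class].
#' @export
zscoreSeries <- function(rts) {
  s <- scale(rts@series)
  if (any(!is.finite(s))) stop("cannot z-score a constant regional series")
  new("RoiTimeseries", series = s[, , drop = FALSE], tr = rts@tr,
      zscored = TRUE, lagVolumes = rts@lagVolumes)
}

#' Shift a timeseries forward against its design
#'
#' Advances the series by `shiftS` seconds (a whole number of volumes) so
#' that haemodynamically delayed signal aligns with design time: after a
#' shift of k volumes, series row v corresponds to design volume v. The k
#' overhanging volumes are dropped from the front of the series; users of
#' the design must truncate its tail to the new length.
#'
#' @param rts a [RoiTimeseries-class].
#' @param shiftS shift in seconds; must be a non-negative multiple of TR.
#' @return a shifted [RoiTimeseries-class] with `lagVolumes` updated.
#' @export
lagShift <- function(rts, shiftS) {
  if (shiftS < 0) stop("shift must be non-negative")
  k <- shiftS / rts@tr
  if (abs(k - round(k)) > 1e-9)
    stop("shift (", shiftS, " s) is not a multiple of TR (", rts@tr, " s)")
  k <- as.integer(round(k))
  if (k == 0) return(rts)
  n <- nrow(rts@series)
  if (k >= n) stop("shift drops every volume")
  # dropping volumes invalidates exact unit-variance, so the flag is reset;
  # the MI estimator is affine-invariant and unaffected
  new("RoiTimeseries", series = rts@series[(k + 1):n, , drop = FALSE],
      tr = rts@tr, zscored = FALSE,
      lagVolumes = rts@lagVolumes + k)
}

# --- DVARS QC ----------------------------------------------------------------

#' DVARS motion/artefact trace
#'
#' DVARS at volume v is the spatial root mean square of the temporally
#' differenced image, sqrt(mean over voxels of (I_v - I_{v-1})^2), computed
#' after normalising the 4D grid to a grand median of 1000 (the intensity
#' convention under which the default threshold of 50 is meaningful). The
#' first volume has no predecessor and is assigned 0.
#'
#' @param grid 4D array (>= 2 volumes).
#' @param threshold flagging threshold (default 50).
#' @param flagFraction fraction of flagged volumes above which the
#'   participant-exclusion predicate fires (default 0.20).
#' @param normalize median-1000 normalisation (disable for toy grids whose
#'   scale is already meaningful).
#' @return list with `values` (per-volume DVARS), `threshold`, `flagged`
#'   (volume indices), `flaggedFraction`, and `exclude` (logical).
#' @export
dvars <- function(grid, threshold = 50, flagFraction = 0.20,
                  normalize = TRUE) {
  stopifnot(length(dim(grid)) == 4, dim(grid)[4] >= 2)
  nv <- dim(grid)[4]
  mat <- matrix(grid, ncol = nv)
  if (normalize) {
    med <- stats::median(mat)
    if (med != 0) mat <- mat * (1000 / med)
  }
  d <- diff(t(mat))
  vals <- c(0, sqrt(rowMeans(d^2)))
  flagged <- which(vals > threshold)
  frac <- length(flagged) / nv
  list(values = vals, threshold = threshold, flagged = flagged,
       flaggedFraction = frac, exclude = frac > flagFraction)
}

# --- confounds and design matrix ---------------------------------------------

#' Expand 6 rigid-body parameters to the 24-regressor motion set
#'
#' The standard 24-parameter expansion: the six parameters, their squares,
#' their backward-difference temporal derivatives (first row 0), and the
#' squares of those derivatives.
#'
#' @param motion volumes x 6 matrix.
#' @return volumes x 24 matrix.
#' @export
expandMotionConfounds <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6)
    stop("motion must have exactly 6 columns, got ", ncol(motion))
  d <- rbind(0, diff(motion))
  out <- cbind(motion, motion^2, d, d^2)
  base <- c("tx", "ty", "tz", "rx", "ry", "rz")
  colnames(out) <- c(base, paste0(base, "_sq"), paste0(base, "_d"),
                     paste0(base, "_dsq"))
  out
}

#' Build a GLM design matrix for one run
#'
#' The `"task"` model carries, per condition triplet, one block regressor
#' (the whole block boxcar) and one switch-event regressor (the switch
#' trials), 16 task columns in all. The `"switch_dimension"` model carries
#' one switch-event regressor per condition triplet, 8 task columns, from
#' which the per-dimension predictability contrasts (4 predictable vs 4
#' unpredictable conditions) are formed. All task regressors are
#' HRF-convolved boxcars sampled at the TR. Motion parameters, when given,
#' enter through the 24-regressor expansion; censored volumes each get one
#' indicator (spike) column.
#'
#' @param design a [TaskDesign-class].
#' @param run run index.
#' @param model `"task"` or `"switch_dimension"`.
#' @param tr repetition time, seconds.
#' @param nVolumes number of volumes modelled; must cover the design.
#' @param motion optional volumes x 6 motion matrix.
#' @param censor integer indices of censored volumes.
#' @return numeric matrix with an attribute `kind` (one of `"task"`,
#'   `"motion"`, `"censor"` per column).
#' @export
buildDesignMatrix <- function(design, run = 1L,
                              model = c("task", "switch_dimension"),
                              tr = 2, nVolumes = NULL, motion = NULL,
                              censor = integer(0)) {
  model <- match.arg(model)
  trd <- design@trials[design@trials$run == run, ]
  need <- ceiling(max(trd$onset_s + trd$duration_s) / tr)
  if (is.null(nVolumes)) nVolumes <- as.integer(need)
  if (nVolumes < need)
    stop("nVolumes (", nVolumes, ") shorter than the design (", need,
         " volumes)")
  trips <- conditionTriplets()$condition
  cols <- list()
  for (cn in trips) {
    blk <- trd[trd$condition == cn, ]
    sw <- blk[blk$trial_type == "switch", ]
    if (model == "task") {
      cols[[paste0("block_", cn)]] <-
        convolve_boxcar(min(blk$onset_s),
                        max(blk$onset_s + blk$duration_s) - min(blk$onset_s),
                        tr, nVolumes)
    }
    cols[[paste0("switch_", cn)]] <-
      convolve_boxcar(sw$onset_s, sw$duration_s, tr, nVolumes)
  }
  X <- do.call(cbind, cols)
  kind <- rep("task", ncol(X))
  if (!is.null(motion)) {
    mc <- expandMotionConfounds(motion[seq_len(nVolumes), , drop = FALSE])
    X <- cbind(X, mc)
    kind <- c(kind, rep("motion", 24))
  }
  for (v in censor) {
    ind <- numeric(nVolumes)
    ind[v] <- 1
    X <- cbind(X, ind)
    colnames(X)[ncol(X)] <- paste0("censor_", v)
    kind <- c(kind, "censor")
  }
  attr(X, "kind") <- kind
  X
}

#' Ordinary least-squares contrast fit
#'
#' Fits y = X b + e per response column and evaluates the t statistic of a
#' contrast c'b, with its z-score equivalent. The desk-scale stand-in for a
#' full mixed-effects neuroimaging GLM stack.
#'
#' @param y numeric vector or volumes x units matrix of responses.
#' @param X design matrix (see [buildDesignMatrix()]); an intercept column
#'   is appended automatically if absent.
#' @param contrast numeric contrast vector over the columns of `X` (padded
#'   with 0 for the intercept).
#' @return list with `t`, `z`, `df`, `beta` (contrast estimate per unit).
#' @export
olsContrast <- function(y, X, contrast) {
  y <- as.matrix(y)
  X0 <- X
  if (!any(apply(X, 2, function(col) all(col == col[1]))))
    X0 <- cbind(X, intercept = 1)
  if (length(contrast) == ncol(X))
    contrast <- c(contrast, rep(0, ncol(X0) - ncol(X)))
  qrX <- qr(X0)
  if (qrX$rank < ncol(X0)) {
    drop <- colnames(X0)[qrX$pivot[(qrX$rank + 1):ncol(X0)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  n <- nrow(X0)
  df <- n - ncol(X0)
  beta <- qr.coef(qrX, y)
  res <- y - X0 %*% beta
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot)]
  cvar <- drop(t(contrast) %*% XtXinv %*% contrast)
  cb <- drop(t(contrast) %*% beta)
  tval <- cb / sqrt(sigma2 * cvar)
  z <- sign(tval) * stats::qnorm(stats::pt(-abs(tval), df, log.p = TRUE),
                                 log.p = TRUE) * -1
  list(t = tval, z = z, df = df, beta = cb)
}
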