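#' @import methods
NULL

PRED_LEVELS <- c("pred", "unpred")
CATEGORIES <- c("faces", "lines", "rooms", "figures")

#' Factorial switching-task design
#'
#' Holds one session of the 2x2x2 switching paradigm: `runs` runs of
#' `blocksPerRun` blocks, each block carrying one of the eight combinations of
#' sequential, perceptual and spatial predictability and `trialsPerBlock`
#' trials. The trial table records, per trial, the run, block, within-block
#' index, condition levels, trial type (`switch`/`stay`), attended row
#' position (1-4), stimulus category, onset and duration in seconds.
#'
#' @slot trials data.frame of per-trial events.
#' @slot runs,blocksPerRun,trialsPerBlock integer design counts.
#' @slot restS rest period between blocks, seconds.
#' @slot seed integer seed the design was generated from.
#' @exportClass TaskDesign
setClass("TaskDesign",
  representation(trials = "data.frame", runs = "integer",
                 blocksPerRun = "integer", trialsPerBlock = "integer",
                 restS = "numeric", seed = "integer"))

setValidity("TaskDesign", function(object) {
  tr <- object@trials
  need <- c("run", "block", "trial", "onset_s", "duration_s", "trial_type",
            "seq", "perc", "spat", "position", "category")
  if (!all(need %in% names(tr)))
    return(paste("trial table missing columns:",
                 paste(setdiff(need, names(tr)), collapse = ", ")))
  if (!all(tr$trial_type %in% c("switch", "stay")))
    return("trial_type must be 'switch' or 'stay'")
  if (!all(tr$seq %in% PRED_LEVELS) || !all(tr$perc %in% PRED_LEVELS) ||
      !all(tr$spat %in% PRED_LEVELS))
    return("condition levels must be 'pred'/'unpred'")
  for (r in unique(tr$run)) {
    on <- tr$onset_s[tr$run == r]
    if (any(diff(on) <= 0)) return("onsets must be strictly increasing within a run")
    cond <- unique(tr[tr$run == r, c("block", "seq", "perc", "spat")])
    if (nrow(unique(cond[, c("seq", "perc", "spat")])) != 8L)
      return("every condition triplet must appear exactly once per run")
  }
  TRUE
})

#' Ground-truth regional coupling specification
#'
#' Declares which region pairs of a simulated dataset are dependent, through
#' which functional form, at what strength, and in which task conditions.
#' For linear coupling the strength is a correlation rho and the analytic
#' mutual information is -1/2 log(1 - rho^2) nats; for quadratic coupling
#' the strength scales a centred-square transform with unit noise variance.
#'
#' @slot pairs data.frame with columns `i`, `j` (region indices), `form`
#'   (`linear`/`quadratic`), `strength`, `conditions` (';'-joined condition
#'   labels, or `"all"`), `mi_nats` (ground truth where analytic).
#' @exportClass CouplingSpec
setClass("CouplingSpec", representation(pairs = "data.frame"))

setValidity("CouplingSpec", function(object) {
  p <- object@pairs
  if (nrow(p) == 0) return(TRUE)
  need <- c("i", "j", "form", "strength", "conditions", "mi_nats")
  if (!all(need %in% names(p)))
    return(paste("pairs missing columns:",
                 paste(setdiff(need, names(p)), collapse = ", ")))
  if (!all(p$form %in% c("linear", "quadratic")))
    return("form must be 'linear' or 'quadratic'")
  lin <- p$form == "linear"
  if (any(abs(p$strength[lin]) >= 1))
    return("linear coupling strength must be a correlation in (-1, 1)")
  bad <- lin & is.finite(p$mi_nats) &
    abs(p$mi_nats - (-0.5 * log(1 - p$strength^2))) > 1e-8
  if (any(bad))
    return("linear ground-truth MI must equal -1/2 log(1 - rho^2)")
  TRUE
})

#' Simulated BOLD dataset with known ground truth
#'
#' Bundles everything the simulator produced for one run: the regional
#' timeseries (volumes x regions), optionally a voxel grid (4D) whose
#' region-wise means reproduce the series, the region label volume, the
#' rigid-body motion trace, the design and the coupling ground truth.
#'
#' @slot series volumes x regions matrix.
#' @slot grid 4D array (x, y, z, volume) or NULL-like empty array.
#' @slot labels 3D integer region label array (0 = unassigned voxels).
#' @slot motion volumes x 6 matrix (3 translations mm, 3 rotations rad).
#' @slot tr repetition time, seconds.
#' @slot design the [TaskDesign-class] simulated against.
#' @slot truth the [CouplingSpec-class] used.
#' @slot run which run of the design this dataset covers.
#' @exportClass SyntheticBold
setClass("SyntheticBold",
  representation(series = "matrix", grid = "array", labels = "array",
                 motion = "matrix", tr = "numeric", design = "TaskDesign",
                 truth = "CouplingSpec", run = "integer"))

setValidity("SyntheticBold", function(object) {
  if (length(object@grid) > 1 && dim(object@grid)[4] != nrow(object@series))
    return("voxel grid and regional series disagree on volume count")
  if (nrow(object@motion) > 0 && nrow(object@motion) != nrow(object@series))
    return("motion trace and regional series disagree on volume count")
  if (object@tr <= 0) return("TR must be positive")
  TRUE
})

#' Regional BOLD timeseries matrix
#'
#' A volumes x regions matrix with its TR and processing state: whether the
#' columns were z-scored, and how many volumes of haemodynamic lag shift
#' have been applied (volumes dropped from the front so that volume v of the
#' series aligns with design time of volume v).
#'
#' @slot series volumes x regions numeric matrix.
#' @slot tr repetition time, seconds.
#' @slot zscored logical.
#' @slot lagVolumes integer count of volumes the series was advanced by.
#' @exportClass RoiTimeseries
setClass("RoiTimeseries",
  representation(series = "matrix", tr = "numeric", zscored = "logical",
                 lagVolumes = "integer"))

setValidity("RoiTimeseries", function(object) {
  if (object@tr <= 0) return("TR must be positive")
  if (object@zscored && nrow(object@series) > 1) {
    m <- colMeans(object@series)
    s <- apply(object@series, 2, stats::sd)
    if (any(abs(m) > 1e-6) || any(abs(s - 1) > 1e-6))
      return("zscored series must have column mean 0 and SD 1")
  }
  TRUE
})

#' Single-pair mutual information estimate
#'
#' @slot miNats raw mutual information, nats (clipped at 0).
#' @slot miNormalized normalised MI in [0, 1].
#' @slot entropies named vector: Hx, Hy, Hxy (nats, leave-one-out KDE).
#' @slot nSamples sample count used.
#' @slot bandwidth per-dimension kernel bandwidth (SD units).
#' @exportClass MiEstimate
setClass("MiEstimate",
  representation(miNats = "numeric", miNormalized = "numeric",
                 entropies = "numeric", nSamples = "integer",
                 bandwidth = "numeric"))

#' Symmetric miFC matrix
#'
#' Pairwise normalised mutual information between regional timeseries,
#' symmetric with unit diagonal, all cells in [0, 1]. `rawNats` carries the
#' unnormalised estimates alongside.
#'
#' @slot values regions x regions normalised MI.
#' @slot rawNats regions x regions raw MI, nats.
#' @slot condition condition/block label the matrix belongs to ("" if all).
#' @slot shiftVolumes haemodynamic lag applied upstream, volumes.
#' @slot nVolumes number of volumes the estimates used.
#' @exportClass MiFCMatrix
setClass("MiFCMatrix",
  representation(values = "matrix", rawNats = "matrix", condition = "character",
                 shiftVolumes = "integer", nVolumes = "integer"))

setValidity("MiFCMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("miFC matrix must be square")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12)))
    return("miFC matrix must be symmetric")
  offd <- v[row(v) != col(v)]
  offd <- offd[!is.na(offd)]
  if (length(offd) && (min(offd) < 0 || max(offd) > 1))
    return("normalised miFC cells must lie in [0, 1]")
  if (any(diag(v) != 1)) return("diagonal must be 1")
  TRUE
})

#' Intraclass correlation results
#'
#' ICC(A,k): two-way model, absolute agreement, mean of k ratings. `values`
#' holds one ICC per unit (per subject for within-subject reliability, per
#' run for across-subject reliability).
#'
#' @slot values named numeric vector of ICCs.
#' @slot model fixed descriptor string.
#' @slot nTargets,kRaters table dimensions the ICCs were computed on.
#' @exportClass IccResult
setClass("IccResult",
  representation(values = "numeric", model = "character",
                 nTargets = "integer", kRaters = "integer"))

setValidity("IccResult", function(object) {
  if (any(object@values > 1 + 1e-12, na.rm = TRUE)) return("ICC cannot exceed 1")
  TRUE
})

#' Per-edge factorial effect table
#'
#' One row per unordered region pair and effect (3 main effects, 3 two-way
#' and 1 three-way interaction of the predictability factors): F statistic,
#' degrees of freedom, p, BH-FDR q, effect size eta^2, and a direction sign
#' for main effects (+1/-1 from a paired Wilcoxon signed-rank comparison of
#' the marginal levels, 0 when that comparison is not itself significant).
#'
#' @slot effects data.frame with columns region_i, region_j, factor, F, df1,
#'   df2, p, q_fdr, eta_sq, direction.
#' @slot nSubjects cohort size used.
#' @exportClass EdgeEffectTable
setClass("EdgeEffectTable",
  representation(effects = "data.frame", nSubjects = "integer"))

setValidity("EdgeEffectTable", function(object) {
  e <- object@effects
  if (nrow(e) == 0) return(TRUE)
  if (any(e$region_i >= e$region_j))
    return("edges must be stored with region_i < region_j")
  if (any(e$q_fdr + 1e-12 < e$p, na.rm = TRUE)) return("q_fdr must be >= p")
  if (any(e$eta_sq < -1e-12 | e$eta_sq > 1 + 1e-12, na.rm = TRUE))
    return("eta_sq must lie in [0, 1]")
  TRUE
})

#' Network-level significant-edge graph
#'
#' Nodes are functional networks; edges connect network pairs holding at
#' least one FDR-significant region pair for the chosen factor/direction,
#' weighted by the contributing regions or pairs. Within-network
#' (self-loop) edges are kept in the structure and only dropped at display.
#'
#' @slot nodes data.frame: network, degree.
#' @slot edges data.frame: net_a, net_b, weight, n_pairs.
#' @slot factor,direction what the graph summarises.
#' @slot weightMode "regions" (per-side distinct regions) or "pairs".
#' @exportClass NetworkGraph
setClass("NetworkGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 factor = "character", direction = "character",
                 weightMode = "character"))

setValidity("NetworkGraph", function(object) {
  e <- object@edges
  if (nrow(e) && (any(e$weight <= 0) || any(e$weight != round(e$weight))))
    return("edge weights must be positive integers")
  TRUE
})
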