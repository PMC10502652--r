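#' Pipeline configuration
#'
#' Assembles and validates the parameter set for an end-to-end run on a
#' simulated cohort: cohort and design sizes, TR, haemodynamic shift (with
#' its sensitivity set), QC thresholds, watershed parameters, the FDR
#' level, and an optional injected coupling effect whose recovery the run
#' is meant to demonstrate.
#'
#' @param nSubjects,nRegions,runs cohort dimensions.
#' @param tr repetition time, seconds.
#' @param shiftS haemodynamic lag, seconds (multiple of `tr`).
#' @param shiftSensitivity other shifts for [sensitivityShift()].
#' @param dvarsThreshold,flagFraction DVARS QC parameters.
#' @param watershedThreshold,mergeThreshold,seedRadius watershed
#'   parameters (statistic threshold, minimum region voxels, seed radius).
#' @param fdrQ FDR level for edgewise inference.
#' @param minSamples minimum volumes per block for an MI estimate.
#' @param noiseSd regional noise SD in the simulator.
#' @param injected optional list (`i`, `j`, `dimension`, `rhoPred`,
#'   `rhoUnpred`): a region pair whose coupling differs between the
#'   predictable and unpredictable levels of one dimension.
#' @param seed master seed; all stage seeds derive from it.
#' @return validated config list.
#' @export
pipelineConfig <- function(nSubjects = 12, nRegions = 12, runs = 3, tr = 2,
                           shiftS = 10, shiftSensitivity = c(8, 12),
                           dvarsThreshold = 50, flagFraction = 0.20,
                           watershedThreshold = 3.1, mergeThreshold = 100,
                           seedRadius = 5, fdrQ = 0.05, minSamples = 16,
                           noiseSd = 1,
                           injected = list(i = 1, j = 2, dimension = "seq",
                                           rhoPred = 0.7, rhoUnpred = 0.2),
                           seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$tr > 0, cfg$dvarsThreshold > 0, cfg$watershedThreshold > 0,
            cfg$mergeThreshold > 0, cfg$seedRadius > 0, cfg$fdrQ > 0)
  for (s in c(cfg$shiftS, cfg$shiftSensitivity))
    if (abs(s / cfg$tr - round(s / cfg$tr)) > 1e-9)
      stop("shift ", s, " s is not a multiple of TR ", cfg$tr, " s")
  if (!is.null(cfg$injected))
    stopifnot(cfg$injected$i < cfg$injected$j,
              cfg$injected$j <= cfg$nRegions,
              cfg$injected$dimension %in% c("seq", "perc", "spat"))
  cfg
}

# coupling spec realising the injected condition-dependent effect
injected_coupling <- function(injected, baseline = 0) {
  if (is.null(injected)) return(couplingSpec())
  g <- conditionTriplets()
  pred <- g$condition[g[[injected$dimension]] == "pred"]
  unpred <- g$condition[g[[injected$dimension]] == "unpred"]
  couplingSpec(i = c(injected$i, injected$i),
               j = c(injected$j, injected$j),
               form = "linear",
               strength = c(injected$rhoPred, injected$rhoUnpred),
               conditions = c(paste(pred, collapse = ";"),
                              paste(unpred, collapse = ";")))
}

# deterministic per-stage seed derivation, kept well below 2^31
derive_seed <- function(seed, subject, run = 0L)
  (as.integer(seed) %% 100000L) * 10000L + subject * 10L + run

#' Simulate the raw data of a cohort
#'
#' One design and `runs` runs of regional BOLD per subject, with the
#' config's injected coupling.
#'
#' @param config a [pipelineConfig()].
#' @return list over subjects: `design`, `runs` (list of
#'   [RoiTimeseries-class]).
#' @export
simulateCohortData <- function(config) {
  coup <- injected_coupling(config$injected)
  lapply(seq_len(config$nSubjects), function(s) {
    design <- generateDesign(runs = config$runs,
                             seed = derive_seed(config$seed, s))
    runs <- lapply(seq_len(config$runs), function(r) {
      sb <- simulateBold(design, run = r, coupling = coup,
                         nRegions = config$nRegions, tr = config$tr,
                         noiseSd = config$noiseSd,
                         seed = derive_seed(config$seed, s, r))
      roiTimeseries(regionalSeries(sb), tr = config$tr)
    })
    list(design = design, runs = runs)
  })
}

#' miFC stage for a simulated cohort
#'
#' Per subject: per-run per-condition miFC matrices, their across-run
#' condition averages, and a run-level matrix (the mean over the run's
#' eight condition matrices) used for reliability screening.
#'
#' @param cohortData output of [simulateCohortData()].
#' @param shiftS haemodynamic lag, seconds.
#' @param minSamples minimum volumes per block.
#' @return list over subjects: `perRun`, `avg`, `runLevel`.
#' @export
cohortMiFC <- function(cohortData, shiftS = 10, minSamples = 16) {
  lapply(cohortData, function(subj) {
    perRun <- lapply(seq_along(subj$runs), function(r) {
      mifcByCondition(subj$runs[[r]], subj$design, run = r,
                      shiftS = shiftS, minSamples = minSamples)
    })
    runLevel <- lapply(perRun, function(mats) {
      vals <- Reduce(`+`, lapply(mats, mifcValues)) / length(mats)
      raw <- Reduce(`+`, lapply(mats, mifcRawNats)) / length(mats)
      new("MiFCMatrix", values = vals, rawNats = raw, condition = "",
          shiftVolumes = mats[[1]]@shiftVolumes,
          nVolumes = mats[[1]]@nVolumes)
    })
    list(perRun = perRun, avg = conditionAverageMiFC(perRun),
         runLevel = runLevel)
  })
}

#' Run the full pipeline end-to-end on a simulated cohort
#'
#' Simulation, miFC, ICC reliability screen, edgewise 2x2x2 inference with
#' FDR, network graphs for the sequential and perceptual factors, plus a
#' desk-scale parcellation and DVARS QC demonstration. Deterministic given
#' the config seed; when `outDir` is given, all tabular outputs are
#' written as TSV with a JSON manifest (parameters and file hashes).
#'
#' @param config a [pipelineConfig()].
#' @param outDir optional output directory.
#' @return result bundle: `mifc` (per-subject matrices), `icc`,
#'   `screen`, `effects` ([EdgeEffectTable-class]), `graphs`,
#'   `parcels`, `qc`, `config`.
#' @export
runEndToEnd <- function(config, outDir = NULL) {
  cohortData <- simulateCohortData(config)
  mifc <- cohortMiFC(cohortData, config$shiftS, config$minSamples)

  icc <- withinSubjectReliability(lapply(mifc, `[[`, "runLevel"))
  screen <- exclusionScreen(icc)
  keep <- match(screen$retained, names(iccValues(icc)))
  effects <- edgewiseFactorial(lapply(mifc[keep], `[[`, "avg"),
                               alpha = config$fdrQ)

  lookup <- makeNetworkLookup(config$nRegions)
  graphs <- list()
  for (fac in c("seq", "perc")) for (dir in c("+", "-")) {
    g <- buildNetworkGraph(effects, lookup, factor = fac, direction = dir,
                           alpha = config$fdrQ)
    graphs[[paste0(fac, dir)]] <- list(
      subnetworks = g, consolidated = consolidateSubnetworks(g))
  }

  # desk-scale demonstration stages: watershed parcellation of a synthetic
  # statistic map, and DVARS QC of a spiked grid
  peaks <- data.frame(x = c(8, 22), y = c(8, 22), z = c(6, 10),
                      amplitude = c(6, 5), width = c(3, 3))
  statmap <- simulateStatMap(peaks, c(30, 30, 16))
  parcels <- watershedParcellate(statmap, config$watershedThreshold,
                                 config$mergeThreshold, config$seedRadius)
  atlas <- array(0L, dim(statmap))
  atlas[1:15, , ] <- 1L
  atlas[16:30, , ] <- 2L
  atlas_lookup <- data.frame(atlas_id = 1:2,
                             anatomical_name = c("synthetic region L",
                                                 "synthetic region R"),
                             network_17 = c("ContA", "DefaultA"),
                             network_7 = c("Cont", "Default"))
  parcel_table <- labelToTable(parcels, statmap, atlas, atlas_lookup)

  mo <- simulateMotion(60, spikeVolumes = c(20, 40),
                       seed = derive_seed(config$seed, 0L, 9L))
  qc <- dvars(mo$grid, threshold = config$dvarsThreshold,
              flagFraction = config$flagFraction)

  bundle <- list(mifc = mifc, icc = icc, screen = screen,
                 effects = effects, graphs = graphs, parcels = parcels,
                 parcelTable = parcel_table, qc = qc, config = config)
  if (!is.null(outDir)) writeBundle(bundle, outDir)
  bundle
}

# write the bundle's tabular outputs plus a manifest of parameters and
# content hashes (no timestamps, so identical runs are byte-identical)
writeBundle <- function(bundle, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wt <- function(x, name) {
    p <- file.path(outDir, name)
    writeTsv(x, p)
    files <<- c(files, p)
  }
  wt(edgeEffects(bundle$effects), "edge_effects.tsv")
  wt(data.frame(subject = names(iccValues(bundle$icc)),
                icc = unname(iccValues(bundle$icc))), "icc_within.tsv")
  wt(bundle$parcelTable, "parcels.tsv")
  for (nm in names(bundle$graphs)) {
    wt(graphEdges(bundle$graphs[[nm]]$subnetworks),
       paste0("graph_", gsub("[+]", "pos", gsub("-", "neg", nm)), "_edges.tsv"))
    wt(graphNodes(bundle$graphs[[nm]]$consolidated),
       paste0("graph_", gsub("[+]", "pos", gsub("-", "neg", nm)),
              "_macro_nodes.tsv"))
  }
  wt(data.frame(volume = seq_along(bundle$qc$values),
                dvars = bundle$qc$values), "dvars.tsv")
  manifest <- list(
    parameters = bundle$config[setdiff(names(bundle$config), "injected")],
    injected = bundle$config$injected,
    retained = bundle$screen$retained,
    excluded = bundle$screen$excluded,
    files = lapply(stats::setNames(files, basename(files)),
                   function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}

#' Haemodynamic-shift sensitivity analysis
#'
#' Re-runs the miFC and edgewise stages of a simulated cohort at each
#' candidate shift and reports, per shift, the count of FDR-significant
#' edges for the injected dimension and whether the injected edge was
#' recovered (significant with positive direction).
#'
#' @param config a [pipelineConfig()].
#' @param shifts shifts to compare, seconds (default 8, 10 and 12).
#' @return list with `report` (one row per shift) and `effects` (per-shift
#'   [EdgeEffectTable-class]).
#' @export
sensitivityShift <- function(config, shifts = c(8, 10, 12)) {
  cohortData <- simulateCohortData(config)
  fac <- if (is.null(config$injected)) "seq" else config$injected$dimension
  res <- lapply(shifts, function(sh) {
    mifc <- cohortMiFC(cohortData, sh, config$minSamples)
    edgewiseFactorial(lapply(mifc, `[[`, "avg"), alpha = config$fdrQ)
  })
  report <- do.call(rbind, lapply(seq_along(shifts), function(k) {
    e <- edgeEffects(res[[k]])
    e <- e[e$factor == fac, ]
    sig <- e[!is.na(e$q_fdr) & e$q_fdr < config$fdrQ, ]
    rec <- if (is.null(config$injected)) NA else
      any(sig$region_i == config$injected$i &
            sig$region_j == config$injected$j & sig$direction == 1L)
    data.frame(shift_s = shifts[k], n_significant = nrow(sig),
               injected_recovered = rec)
  }))
  list(report = report, effects = stats::setNames(res, paste0("shift", shifts)))
}
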