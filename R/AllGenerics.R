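#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: `designTrials()`
#' returns the per-trial event table of a [TaskDesign-class];
#' `regionalSeries()` the volumes x regions matrix of a timeseries-bearing
#' object; `mifcValues()` the normalised miFC matrix; `iccValues()` the
#' per-unit ICC vector; `edgeEffects()` the per-edge effect table;
#' `graphEdges()`/`graphNodes()` the network-level edge list and node table.
#'
#' @param object an object of the matching class.
#' @return the underlying data (a data.frame, matrix or numeric vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("designTrials", function(object) standardGeneric("designTrials"))

#' @rdname accessors
#' @export
setGeneric("regionalSeries", function(object) standardGeneric("regionalSeries"))

#' @rdname accessors
#' @export
setGeneric("mifcValues", function(object) standardGeneric("mifcValues"))

#' @rdname accessors
#' @export
setGeneric("mifcRawNats", function(object) standardGeneric("mifcRawNats"))

#' @rdname accessors
#' @export
setGeneric("iccValues", function(object) standardGeneric("iccValues"))

#' @rdname accessors
#' @export
setGeneric("edgeEffects", function(object) standardGeneric("edgeEffects"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(object) standardGeneric("graphNodes"))

#' @rdname accessors
#' @export
setMethod("designTrials", "TaskDesign", function(object) object@trials)

#' @rdname accessors
#' @export
setMethod("regionalSeries", "SyntheticBold", function(object) object@series)

#' @rdname accessors
#' @export
setMethod("regionalSeries", "RoiTimeseries", function(object) object@series)

#' @rdname accessors
#' @export
setMethod("mifcValues", "MiFCMatrix", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("mifcRawNats", "MiFCMatrix", function(object) object@rawNats)

#' @rdname accessors
#' @export
setMethod("iccValues", "IccResult", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("edgeEffects", "EdgeEffectTable", function(object) object@effects)

#' @rdname accessors
#' @export
setMethod("graphEdges", "NetworkGraph", function(object) object@edges)

#' @rdname accessors
#' @export
setMethod("graphNodes", "NetworkGraph", function(object) object@nodes)

setMethod("show", "TaskDesign", function(object) {
  cat(sprintf("TaskDesign: %d run(s) x %d blocks x %d trials (seed %d)\n",
              object@runs, object@blocksPerRun, object@trialsPerBlock,
              object@seed))
  sw <- sum(object@trials$trial_type == "switch")
  cat(sprintf("  %d trials (%d switch), rest %.0f s between blocks\n",
              nrow(object@trials), sw, object@restS))
})

setMethod("show", "CouplingSpec", function(object) {
  cat(sprintf("CouplingSpec: %d coupled pair(s)\n", nrow(object@pairs)))
  if (nrow(object@pairs)) print(utils::head(object@pairs, 5))
})

setMethod("show", "SyntheticBold", function(object) {
  cat(sprintf("SyntheticBold: %d volumes x %d regions, TR %.1f s, run %d\n",
              nrow(object@series), ncol(object@series), object@tr, object@run))
  if (length(object@grid) > 1)
    cat(sprintf("  voxel grid %s\n", paste(dim(object@grid), collapse = " x ")))
})

setMethod("show", "RoiTimeseries", function(object) {
  cat(sprintf("RoiTimeseries: %d volumes x %d regions, TR %.1f s%s, lag %d vol\n",
              nrow(object@series), ncol(object@series), object@tr,
              if (object@zscored) ", z-scored" else "", object@lagVolumes))
})

setMethod("show", "MiEstimate", function(object) {
  cat(sprintf("MiEstimate: %.4f nats (normalised %.4f), n = %d, h = %.3f\n",
              object@miNats, object@miNormalized, object@nSamples,
              object@bandwidth))
})

setMethod("show", "MiFCMatrix", function(object) {
  cat(sprintf("MiFCMatrix: %d x %d regions%s, %d volumes, shift %d\n",
              nrow(object@values), ncol(object@values),
              if (nzchar(object@condition))
                paste0(", condition ", object@condition) else "",
              object@nVolumes, object@shiftVolumes))
})

setMethod("show", "IccResult", function(object) {
  cat(sprintf("IccResult [%s]: %d value(s), mean %.3f (sd %.3f)\n",
              object@model, length(object@values),
              mean(object@values), stats::sd(object@values)))
})

setMethod("show", "EdgeEffectTable", function(object) {
  e <- object@effects
  cat(sprintf("EdgeEffectTable: %d edges x %d effects, %d subjects\n",
              length(unique(paste(e$region_i, e$region_j))),
              length(unique(e$factor)), object@nSubjects))
  sig <- e[!is.na(e$q_fdr) & e$q_fdr < 0.05, ]
  if (nrow(sig)) {
    tab <- table(sig$factor)
    cat("  FDR-significant (q < .05): ",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "NetworkGraph", function(object) {
  cat(sprintf("NetworkGraph [%s, %s]: %d node(s), %d edge(s), mode '%s'\n",
              object@factor, object@direction, nrow(object@nodes),
              nrow(object@edges), object@weightMode))
})
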