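#' @include AllClasses.R
NULL

#' Accessors for respclust objects
#'
#' Small generic accessors: `flowSamples()` and `volumeSamples()` return the
#' raw sample vectors, `samplingRate()` the sampling rate in Hz,
#' `subjectId()`, `groupLabel()` and `phaseLabel()` the recording metadata,
#' `nCycles()` the number of respiratory cycles, `durations()` per-element
#' durations in seconds, `references()` and `clusterLabels()` the reference
#' shapes and their symbols, `thresholds()` the per-reference outlier
#' thresholds and `symbols()` the per-cycle combined symbols.
#'
#' @param object an object of the documented classes.
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("flowSamples", function(object) standardGeneric("flowSamples"))
#' @rdname accessors
#' @export
setGeneric("volumeSamples", function(object) standardGeneric("volumeSamples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setGeneric("phaseLabel", function(object) standardGeneric("phaseLabel"))
#' @rdname accessors
#' @export
setGeneric("nCycles", function(object) standardGeneric("nCycles"))
#' @rdname accessors
#' @export
setGeneric("durations", function(object) standardGeneric("durations"))
#' @rdname accessors
#' @export
setGeneric("references", function(object) standardGeneric("references"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("thresholds", function(object) standardGeneric("thresholds"))
#' @rdname accessors
#' @export
setGeneric("symbols", function(object) standardGeneric("symbols"))
#' @rdname accessors
#' @export
setGeneric("rcMatrix", function(object) standardGeneric("rcMatrix"))

#' @rdname accessors
setMethod("flowSamples", "Recording", function(object) object@samples)
#' @rdname accessors
setMethod("samplingRate", "Recording", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "VolumeTrace", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "CycleSegmentation", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "PhaseSet", function(object) object@fs)
#' @rdname accessors
setMethod("samplingRate", "SymbolicRecording", function(object) object@fs)
#' @rdname accessors
setMethod("volumeSamples", "VolumeTrace", function(object) object@samples)
#' @rdname accessors
setMethod("subjectId", "Recording", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectId", "SymbolicRecording", function(object) object@subjectId)
#' @rdname accessors
setMethod("subjectId", "RCDistribution", function(object) object@subjectId)
#' @rdname accessors
setMethod("groupLabel", "Recording", function(object) object@group)
#' @rdname accessors
setMethod("groupLabel", "SymbolicRecording", function(object) object@group)
#' @rdname accessors
setMethod("groupLabel", "RCDistribution", function(object) object@group)
#' @rdname accessors
setMethod("phaseLabel", "Recording", function(object) object@phase)
#' @rdname accessors
setMethod("phaseLabel", "SymbolicRecording", function(object) object@phase)
#' @rdname accessors
setMethod("phaseLabel", "RCDistribution", function(object) object@phase)
#' @rdname accessors
setMethod("nCycles", "CycleSegmentation", function(object) length(object@tIn))
#' @rdname accessors
setMethod("nCycles", "SymbolicRecording", function(object) nrow(object@cycles))
#' @rdname accessors
setMethod("durations", "Recording",
          function(object) length(object@samples) / object@fs)
#' @rdname accessors
setMethod("durations", "PhaseSet",
          function(object) lengths(object@sequences) / object@fs)
#' @rdname accessors
setMethod("references", "ShapeModel", function(object) {
  stats::setNames(object@references, object@labels)
})
#' @rdname accessors
setMethod("clusterLabels", "ShapeModel", function(object) object@labels)
#' @rdname accessors
setMethod("thresholds", "ShapeModel", function(object) {
  stats::setNames(object@thresholds, object@labels)
})
#' @rdname accessors
setMethod("symbols", "SymbolicRecording", function(object) {
  ifelse(object@cycles$outlier, "OUTLIER",
         paste0(object@cycles$insp_symbol, object@cycles$exp_symbol))
})
#' @rdname accessors
setMethod("rcMatrix", "RCDistribution", function(object) object@matrix)

#' @describeIn accessors number of sequences in a PhaseSet.
#' @param x,i a `PhaseSet` and an index, for the subsetting methods.
#' @export
setMethod("length", "PhaseSet", function(x) length(x@sequences))

#' @rdname accessors
#' @export
setMethod("[[", "PhaseSet", function(x, i) x@sequences[[i]])

#' @rdname accessors
#' @export
setMethod("[", "PhaseSet", function(x, i) {
  PhaseSet(x@sequences[i], x@phase, x@startIndex[i], x@sourceId[i], x@fs)
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording '%s' (group %s, phase %s): %d samples at %g Hz (%.1f s)\n",
              object@subjectId, object@group, object@phase,
              length(object@samples), object@fs,
              length(object@samples) / object@fs))
})

setMethod("show", "CycleSegmentation", function(object) {
  cat(sprintf("CycleSegmentation: %d cycles at %g Hz, %d discarded span(s)\n",
              length(object@tIn), object@fs, nrow(object@discarded)))
})

setMethod("show", "PhaseSet", function(object) {
  d <- durations(object)
  cat(sprintf("PhaseSet (%s): %d sequences at %g Hz%s\n", object@phase,
              length(object@sequences), object@fs,
              if (length(d)) sprintf(", durations %.3f-%.3f s", min(d), max(d))
              else ""))
})

setMethod("show", "Barycenter", function(object) {
  tr <- object@objectiveTrace
  cat(sprintf("Barycenter: length %d, objective %.6g -> %.6g over %d epoch(s)\n",
              length(object@samples), tr[1], tr[length(tr)],
              length(tr) - 1L))
})

setMethod("show", "ShapeModel", function(object) {
  cat(sprintf("ShapeModel (%s): %d references [%s], %d training sequences\n",
              object@phase, length(object@references),
              paste(object@labels, collapse = ", "),
              length(object@assignments)))
  if (!is.na(object@alpha))
    cat(sprintf("  outlier thresholds at alpha = %g\n", object@alpha))
})

setMethod("show", "SymbolicRecording", function(object) {
  cyc <- object@cycles
  cat(sprintf("SymbolicRecording '%s' (%s/%s): %d cycles, %.1f%% outliers\n",
              object@subjectId, object@group, object@phase, nrow(cyc),
              if (nrow(cyc)) 100 * mean(cyc$outlier) else 0))
})

setMethod("show", "RCDistribution", function(object) {
  cat(sprintf("RCDistribution '%s' (%s/%s): %dx%d, outlier time %.1f%%\n",
              object@subjectId, object@group, object@phase,
              nrow(object@matrix), ncol(object@matrix),
              100 * object@outlierTimeFraction))
  print(round(object@matrix, 1))
})

setMethod("show", "TestMap", function(object) {
  cat(sprintf("TestMap (%d vs %d subjects, FDR level %g): %d of %d rejected\n",
              object@nA, object@nB, object@level, sum(object@rejected),
              length(object@rejected)))
})

#' Coerce a CycleSegmentation to a data.frame of boundary times
#'
#' @param x a [CycleSegmentation-class].
#' @param ... ignored.
#' @return data.frame with columns `cycle_index`, `t_in_s`, `t_out_s`,
#'   `t_next_in_s`.
#' @export
as.data.frame.CycleSegmentation <- function(x, ...) {
  data.frame(cycle_index = seq_along(x@tIn),
             t_in_s = (x@tIn - 1L) / x@fs,
             t_out_s = (x@tOut - 1L) / x@fs,
             t_next_in_s = (x@tEnd - 1L) / x@fs)
}

#' Coerce a SymbolicRecording to its per-cycle data.frame
#'
#' @param x a [SymbolicRecording-class].
#' @param ... ignored.
#' @return the per-cycle data.frame.
#' @export
as.data.frame.SymbolicRecording <- function(x, ...) x@cycles
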