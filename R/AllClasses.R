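#' @include utils.R
NULL

.PHASES <- c("pre", "post", "unspecified")
.PHASE_KINDS <- c("inspiration", "expiration")

#' Recording: a single-channel airflow trace with metadata
#'
#' Holds a uniformly sampled nasal airflow signal (mL/s, positive during
#' inspiration, negative during expiration) together with its sampling rate
#' and subject-level metadata.
#'
#' @slot samples numeric vector of airflow values in mL/s.
#' @slot fs sampling rate in Hz.
#' @slot subjectId subject identifier.
#' @slot group group label (e.g. genotype).
#' @slot phase experimental phase, one of `"pre"`, `"post"`, `"unspecified"`.
#' @slot t0 acquisition start time in seconds.
#'
#' @seealso [Recording()], [readRecording()], [downsample()]
#' @export
setClass("Recording",
  representation(samples = "numeric", fs = "numeric", subjectId = "character",
                 group = "character", phase = "character", t0 = "numeric"),
  prototype(t0 = 0, group = "unspecified", phase = "unspecified"))

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@samples) == 0L) msg <- c(msg, "samples must be non-empty")
  if (any(!is.finite(object@samples))) msg <- c(msg, "samples must be finite")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a positive scalar")
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    msg <- c(msg, "subjectId must be a non-empty string")
  if (length(object@group) != 1L || !nzchar(object@group))
    msg <- c(msg, "group must be a non-empty string")
  if (length(object@phase) != 1L || !object@phase %in% .PHASES)
    msg <- c(msg, sprintf("phase must be one of: %s",
                          paste(.PHASES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param samples numeric airflow samples in mL/s (positive = inspiration).
#' @param fs sampling rate in Hz.
#' @param subjectId subject identifier.
#' @param group group label (e.g. genotype).
#' @param phase experimental phase: `"pre"`, `"post"` or `"unspecified"`.
#' @param t0 acquisition start time in seconds.
#' @return A [Recording-class] object.
#' @examples
#' rec <- Recording(sin(2 * pi * 3 * seq(0, 1, by = 1 / 250)), fs = 250)
#' rec
#' @export
Recording <- function(samples, fs, subjectId = "subject",
                      group = "unspecified", phase = "unspecified", t0 = 0) {
  new("Recording", samples = as.numeric(samples), fs = as.numeric(fs),
      subjectId = subjectId, group = group, phase = phase,
      t0 = as.numeric(t0))
}

#' VolumeTrace: detrended lung volume derived from airflow
#'
#' The running integral of airflow with its least-squares linear trend
#' removed. As produced by [integrateDetrended()], the samples satisfy
#' `sum(v) == 0` and `sum(t * v) == 0` up to floating-point tolerance; the
#' class itself only enforces shape and finiteness so that traces can also be
#' constructed directly for boundary-detection experiments.
#'
#' @slot samples numeric vector of volume values in mL (arbitrary zero).
#' @slot fs sampling rate in Hz.
#' @seealso [integrateDetrended()], [detectBoundaries()]
#' @export
setClass("VolumeTrace",
  representation(samples = "numeric", fs = "numeric"))

setValidity("VolumeTrace", function(object) {
  msg <- character()
  if (length(object@samples) == 0L) msg <- c(msg, "samples must be non-empty")
  if (any(!is.finite(object@samples))) msg <- c(msg, "samples must be finite")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a VolumeTrace
#' @param samples numeric volume samples (mL).
#' @param fs sampling rate in Hz.
#' @return A [VolumeTrace-class] object.
#' @export
VolumeTrace <- function(samples, fs) {
  new("VolumeTrace", samples = as.numeric(samples), fs = as.numeric(fs))
}

#' CycleSegmentation: inspiration/expiration boundaries of a recording
#'
#' Stores, for each retained respiratory cycle, the 1-based sample index of
#' the inspiration start (`tIn`), the expiration start (`tOut`) and the
#' exclusive cycle end (`tEnd`, the next inspiration start). Cycles removed
#' by the phase-duration bounds are kept as `discarded` spans so that
#' downstream symbolization can mark them as unclassified.
#'
#' @slot tIn integer vector, inspiration start indices.
#' @slot tOut integer vector, expiration start indices.
#' @slot tEnd integer vector, exclusive cycle end indices.
#' @slot fs sampling rate in Hz.
#' @slot discarded data.frame with columns `start`, `end` (sample indices) of
#'   spans whose cycles violated the duration bounds.
#' @seealso [detectBoundaries()], [splitPhases()]
#' @export
setClass("CycleSegmentation",
  representation(tIn = "integer", tOut = "integer", tEnd = "integer",
                 fs = "numeric", discarded = "data.frame"))

setValidity("CycleSegmentation", function(object) {
  msg <- character()
  k <- length(object@tIn)
  if (length(object@tOut) != k || length(object@tEnd) != k)
    msg <- c(msg, "tIn, tOut, tEnd must have equal length")
  if (k > 0 && (length(object@tOut) == k) && (length(object@tEnd) == k)) {
    if (any(object@tIn >= object@tOut) || any(object@tOut >= object@tEnd))
      msg <- c(msg, "alternation tIn < tOut < tEnd violated")
    if (k > 1 && any(object@tEnd[-k] > object@tIn[-1]))
      msg <- c(msg, "cycles must not overlap")
  }
  if (length(msg)) msg else TRUE
})

CycleSegmentation <- function(tIn, tOut, tEnd, fs,
                              discarded = data.frame(start = integer(),
                                                     end = integer())) {
  new("CycleSegmentation", tIn = as.integer(tIn), tOut = as.integer(tOut),
      tEnd = as.integer(tEnd), fs = as.numeric(fs), discarded = discarded)
}

#' PhaseSet: a collection of inspiration or expiration sequences
#'
#' Container for variable-length phase sequences extracted from one or more
#' recordings, with per-sequence provenance (source recording and start
#' index).
#'
#' @slot sequences list of numeric vectors (airflow samples, mL/s).
#' @slot phase `"inspiration"` or `"expiration"`.
#' @slot startIndex integer vector of start sample indices in the source.
#' @slot sourceId character vector of source recording identifiers.
#' @slot fs sampling rate in Hz.
#' @seealso [splitPhases()], [subsampleTraining()]
#' @export
setClass("PhaseSet",
  representation(sequences = "list", phase = "character",
                 startIndex = "integer", sourceId = "character",
                 fs = "numeric"))

setValidity("PhaseSet", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (length(object@startIndex) != n || length(object@sourceId) != n)
    msg <- c(msg, "startIndex and sourceId must match number of sequences")
  if (length(object@phase) != 1L || !object@phase %in% .PHASE_KINDS)
    msg <- c(msg, "phase must be 'inspiration' or 'expiration'")
  if (n > 0 && !all(vapply(object@sequences, is.numeric, logical(1))))
    msg <- c(msg, "sequences must be numeric vectors")
  if (length(msg)) msg else TRUE
})

PhaseSet <- function(sequences, phase, startIndex = rep(NA_integer_,
                     length(sequences)),
                     sourceId = rep("unknown", length(sequences)), fs) {
  new("PhaseSet", sequences = sequences, phase = phase,
      startIndex = as.integer(startIndex), sourceId = as.character(sourceId),
      fs = as.numeric(fs))
}

#' Barycenter: a DTW average sequence
#'
#' The output of [bsDba()]: a fixed-length average shape minimizing (locally)
#' the sum of DTW costs to a set of sequences, with the per-epoch objective
#' values recorded. `objectiveTrace[1]` is the objective of the
#' initialization; the returned iterate is the best one observed, so the
#' final trace value never exceeds the first.
#'
#' @slot samples numeric vector of the average shape.
#' @slot objectiveTrace numeric vector of objective values (initialization
#'   first, then one value per epoch).
#' @slot meta list of provenance (seed, epochs, batch size, step size).
#' @export
setClass("Barycenter",
  representation(samples = "numeric", objectiveTrace = "numeric",
                 meta = "list"),
  prototype(meta = list()))

setValidity("Barycenter", function(object) {
  msg <- character()
  if (length(object@samples) < 2L) msg <- c(msg, "samples must have length >= 2")
  if (length(object@objectiveTrace) >= 1L) {
    tr <- object@objectiveTrace
    if (min(tr) < -1e-12) msg <- c(msg, "objective values must be nonnegative")
    if (tr[length(tr)] > tr[1] + 1e-9 * max(1, tr[1]))
      msg <- c(msg, "final objective must not exceed the initialization")
  }
  if (length(msg)) msg else TRUE
})

#' ShapeModel: DTW K-means reference shapes for one breathing phase
#'
#' A fitted clustering of z-normalized inspiration (or expiration) sequences:
#' the ordered reference shapes (barycenters), training assignments,
#' within-cluster DTW distances, per-cluster mean durations and, once
#' [fitThresholds()] has been applied, the per-reference outlier thresholds.
#' Cluster labels are letters (`A`, `B`, ...) for inspiration and digits
#' (`0`, `1`, ...) for expiration, ordered by increasing mean member
#' duration.
#'
#' @slot phase `"inspiration"` or `"expiration"`.
#' @slot references list of numeric vectors, the reference shapes in label
#'   order.
#' @slot labels character vector of cluster symbols in reference order.
#' @slot assignments integer vector, cluster index (into `labels`) per
#'   training sequence.
#' @slot memberDistances numeric vector, DTW distance of each training
#'   sequence to its own reference.
#' @slot memberDurations numeric vector, duration (s) of each training
#'   sequence.
#' @slot withinDistances list of numeric vectors, `memberDistances` split by
#'   cluster.
#' @slot meanDurations numeric vector, mean member duration (s) per cluster.
#' @slot thresholds numeric vector of per-reference outlier thresholds
#'   (NA before [fitThresholds()]).
#' @slot alpha quantile level used for `thresholds` (NA before fitting).
#' @slot inertiaTrace data.frame with per-iteration inertia bookkeeping.
#' @slot config list of fitting parameters (radius, fs, lSamples, nIter,
#'   seed, batchSize, epochs).
#' @seealso [fitKmeans()], [fitThresholds()], [symbolize()]
#' @export
setClass("ShapeModel",
  representation(phase = "character", references = "list",
                 labels = "character", assignments = "integer",
                 memberDistances = "numeric", memberDurations = "numeric",
                 withinDistances = "list", meanDurations = "numeric",
                 thresholds = "numeric", alpha = "numeric",
                 inertiaTrace = "data.frame", config = "list"),
  prototype(alpha = NA_real_))

setValidity("ShapeModel", function(object) {
  msg <- character()
  K <- length(object@references)
  if (K == 0L) msg <- c(msg, "model must have at least one reference")
  if (length(object@labels) != K) msg <- c(msg, "one label per reference")
  if (anyDuplicated(object@labels)) msg <- c(msg, "labels must be unique")
  if (length(object@phase) != 1L || !object@phase %in% .PHASE_KINDS)
    msg <- c(msg, "phase must be 'inspiration' or 'expiration'")
  if (length(object@meanDurations) == K && K > 1 &&
      any(diff(object@meanDurations) < -1e-12))
    msg <- c(msg, "references must be ordered by non-decreasing mean duration")
  if (length(object@assignments) &&
      (min(object@assignments) < 1L || max(object@assignments) > K))
    msg <- c(msg, "assignments out of range")
  if (length(msg)) msg else TRUE
})

#' SymbolicRecording: per-cycle symbols for one recording
#'
#' The symbolization of a recording: one row per respiratory cycle with its
#' boundaries (seconds), the assigned inspiration letter and expiration
#' digit (or `"OUTLIER"`), the DTW distances to the winning references, and
#' an outlier flag. Spans discarded by the duration bounds at segmentation
#' are included as unclassified (`OUTLIER`) rows so the timeline is fully
#' covered.
#'
#' @slot cycles data.frame with columns `cycle`, `t_in_s`, `t_out_s`,
#'   `t_end_s`, `insp_symbol`, `exp_symbol`, `insp_dist`, `exp_dist`,
#'   `outlier`, `classified`.
#' @slot subjectId,group,phase recording metadata.
#' @slot fs sampling rate in Hz.
#' @slot inspLabels,expLabels the label vocabularies of the models used.
#' @seealso [symbolize()], [rcDistribution()], [barcode()]
#' @export
setClass("SymbolicRecording",
  representation(cycles = "data.frame", subjectId = "character",
                 group = "character", phase = "character", fs = "numeric",
                 inspLabels = "character", expLabels = "character"))

setValidity("SymbolicRecording", function(object) {
  msg <- character()
  cyc <- object@cycles
  need <- c("cycle", "t_in_s", "t_out_s", "t_end_s", "insp_symbol",
            "exp_symbol", "insp_dist", "exp_dist", "outlier", "classified")
  if (!all(need %in% names(cyc)))
    msg <- c(msg, "cycles is missing required columns")
  else if (nrow(cyc) > 1 && any(diff(cyc$t_in_s) <= 0))
    msg <- c(msg, "cycle start times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' RCDistribution: referent-cycle time distribution of one recording
#'
#' A K1 x K2 matrix giving, for each (inspiration letter, expiration digit)
#' referent cycle, the percentage of classified time the recording spends in
#' that class. Entries sum to 100 unless every cycle is an outlier, in which
#' case the matrix is zero and `allOutliers` is set.
#'
#' @slot matrix numeric K1 x K2 matrix (percent), rows = inspiration labels,
#'   columns = expiration labels.
#' @slot outlierTimeFraction fraction of total covered time spent in
#'   outlier/unclassified cycles.
#' @slot allOutliers logical flag.
#' @slot subjectId,group,phase recording metadata.
#' @seealso [rcDistribution()], [marginalProfiles()], [compareGroups()]
#' @export
setClass("RCDistribution",
  representation(matrix = "matrix", outlierTimeFraction = "numeric",
                 allOutliers = "logical", subjectId = "character",
                 group = "character", phase = "character"),
  prototype(allOutliers = FALSE))

setValidity("RCDistribution", function(object) {
  msg <- character()
  m <- object@matrix
  if (any(m < -1e-9)) msg <- c(msg, "entries must be nonnegative")
  s <- sum(m)
  if (!object@allOutliers && abs(s - 100) > 1e-6)
    msg <- c(msg, "entries must sum to 100")
  if (object@allOutliers && abs(s) > 1e-9)
    msg <- c(msg, "all-outlier distribution must be the zero matrix")
  if (length(msg)) msg else TRUE
})

#' TestMap: per-referent-cycle group comparison
#'
#' Raw and FDR-adjusted Mann-Whitney p-values for each referent cycle class,
#' and the rejection map at the chosen level.
#'
#' @slot rawP,adjustedP numeric K1 x K2 matrices of p-values.
#' @slot rejected logical K1 x K2 matrix, `adjustedP <= level`.
#' @slot level FDR level.
#' @slot nA,nB group sizes.
#' @seealso [compareGroups()]
#' @export
setClass("TestMap",
  representation(rawP = "matrix", adjustedP = "matrix", rejected = "matrix",
                 level = "numeric", nA = "integer", nB = "integer"))

setValidity("TestMap", function(object) {
  msg <- character()
  if (!identical(dim(object@rawP), dim(object@adjustedP)) ||
      !identical(dim(object@rawP), dim(object@rejected)))
    msg <- c(msg, "matrices must share dimensions")
  if (any(object@adjustedP < object@rawP - 1e-12))
    msg <- c(msg, "adjusted p-values must be >= raw p-values")
  if (!identical(as.vector(object@rejected),
                 as.vector(object@adjustedP <= object@level)))
    msg <- c(msg, "rejected must equal adjustedP <= level")
  if (length(msg)) msg else TRUE
})

#' CycleArchetype: a parametric synthetic respiratory cycle
#'
#' Describes one synthetic cycle shape used by the generator: an inspiration
#' shape (`half_sine`, `biphasic` with a mid-inspiration gap, or `delayed`
#' with a pre-inspiratory pause), an expiration shape (`half_sine` or
#' `post_insp_pause` with a pause of graded duration), nominal phase
#' durations and a peak amplitude. The expiration amplitude is balanced at
#' render time so each cycle has zero net volume.
#'
#' @slot name symbol name of the archetype.
#' @slot inspShape one of `"half_sine"`, `"biphasic"`, `"delayed"`.
#' @slot expShape one of `"half_sine"`, `"post_insp_pause"`.
#' @slot ti,te nominal inspiration/expiration durations (s).
#' @slot amplitude peak inspiratory flow (mL/s).
#' @slot inspParam gap fraction (biphasic) or pause fraction (delayed).
#' @slot expPause post-inspiratory pause duration (s).
#' @seealso [cycleArchetype()], [generateRecording()]
#' @export
setClass("CycleArchetype",
  representation(name = "character", inspShape = "character",
                 expShape = "character", ti = "numeric", te = "numeric",
                 amplitude = "numeric", inspParam = "numeric",
                 expPause = "numeric"))

setValidity("CycleArchetype", function(object) {
  msg <- character()
  if (!object@inspShape %in% c("half_sine", "biphasic", "delayed"))
    msg <- c(msg, "unknown inspiration shape")
  if (!object@expShape %in% c("half_sine", "post_insp_pause"))
    msg <- c(msg, "unknown expiration shape")
  if (object@ti <= 0 || object@te <= 0) msg <- c(msg, "durations must be > 0")
  if (object@amplitude <= 0) msg <- c(msg, "amplitude must be > 0")
  if (object@inspParam < 0 || object@inspParam >= 1)
    msg <- c(msg, "inspParam must be in [0, 1)")
  if (object@expPause < 0 || object@expPause >= object@te)
    msg <- c(msg, "expPause must be in [0, te)")
  if (length(msg)) msg else TRUE
})
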