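#' @include clustering.R
NULL

#' Fit per-reference outlier thresholds
#'
#' Sets each reference's outlier threshold to the empirical `alpha`-quantile
#' (linear interpolation between order statistics, the R type-7 estimator)
#' of the DTW distances observed within its training cluster. At
#' `alpha = 1` the thresholds are the per-cluster maxima and no training
#' member is gated out.
#'
#' @param model a fitted [ShapeModel-class].
#' @param alpha quantile level in (0, 1]; default 0.95.
#' @return The model with `thresholds` and `alpha` filled in.
#' @seealso [symbolize()]
#' @export
fitThresholds <- function(model, alpha = 0.95) {
  stopifnot(is(model, "ShapeModel"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("parameter error: alpha must be in (0, 1]")
  thr <- vapply(model@withinDistances, function(d) {
    if (length(d) == 0L) return(NA_real_)
    unname(stats::quantile(d, alpha, type = 7))
  }, numeric(1))
  model@thresholds <- thr
  model@alpha <- alpha
  model
}

.nearestReference <- function(z, model) {
  r <- sakoeChibaSamples(model@config$radius, model@config$fs)
  d <- vapply(model@references, function(ref) cpp_dtw_dist(z, ref, r),
              numeric(1))
  k <- which.min(d)
  list(k = k, dist = d[k])
}

#' Symbolize a recording against fitted shape models
#'
#' Segments the recording, z-normalizes every inspiration and expiration
#' sequence and assigns each to its nearest reference by banded DTW (1-NN).
#' A phase whose distance exceeds the winning reference's threshold is
#' marked `OUTLIER`, as is any zero-variance phase; a cycle is an outlier
#' when either of its phases is. Spans discarded by the duration bounds at
#' segmentation are emitted as unclassified outlier rows covering their
#' time, so the symbolic timeline covers the whole recording.
#'
#' @param rec a [Recording-class].
#' @param inspModel,expModel fitted [ShapeModel-class] objects for
#'   inspiration and expiration, with thresholds set (see
#'   [fitThresholds()]; if missing, thresholds at the default
#'   `alpha = 0.95` are fitted on the fly with a message).
#' @param config a [pipelineConfig()] supplying the segmentation
#'   parameters.
#' @return A [SymbolicRecording-class]; empty (zero rows) with a warning if
#'   the recording cannot be segmented.
#' @export
symbolize <- function(rec, inspModel, expModel, config = pipelineConfig()) {
  stopifnot(is(rec, "Recording"), is(inspModel, "ShapeModel"),
            is(expModel, "ShapeModel"))
  if (inspModel@phase != "inspiration" || expModel@phase != "expiration")
    stop("models must be for inspiration and expiration respectively")
  if (is.na(inspModel@alpha)) {
    message("symbolize: fitting thresholds at default alpha = 0.95")
    inspModel <- fitThresholds(inspModel)
  }
  if (is.na(expModel@alpha)) {
    message("symbolize: fitting thresholds at default alpha = 0.95")
    expModel <- fitThresholds(expModel)
  }
  seg <- segmentRecording(rec, config)
  emptyCycles <- data.frame(cycle = integer(), t_in_s = numeric(),
                            t_out_s = numeric(), t_end_s = numeric(),
                            insp_symbol = character(),
                            exp_symbol = character(),
                            insp_dist = numeric(), exp_dist = numeric(),
                            outlier = logical(), classified = logical())
  mk <- function(cycles) {
    new("SymbolicRecording", cycles = cycles, subjectId = rec@subjectId,
        group = rec@group, phase = rec@phase, fs = rec@fs,
        inspLabels = inspModel@labels, expLabels = expModel@labels)
  }
  if (length(seg@tIn) == 0L && nrow(seg@discarded) == 0L) {
    warning("symbolize: recording could not be segmented")
    return(mk(emptyCycles))
  }
  phases <- splitPhases(rec, seg)
  fs <- rec@fs
  classifyPhase <- function(s, model) {
    if (length(s) < 2L || .isDegenerate(s))
      return(list(symbol = "OUTLIER", dist = NA_real_))
    z <- as.numeric(zNormalize(s))
    nn <- .nearestReference(z, model)
    thr <- model@thresholds[nn$k]
    if (!is.na(thr) && nn$dist > thr)
      list(symbol = "OUTLIER", dist = nn$dist)
    else
      list(symbol = model@labels[nn$k], dist = nn$dist)
  }
  k <- length(seg@tIn)
  rows <- vector("list", k + nrow(seg@discarded))
  for (i in seq_len(k)) {
    ci <- classifyPhase(phases$inspiration[[i]], inspModel)
    ce <- classifyPhase(phases$expiration[[i]], expModel)
    rows[[i]] <- data.frame(
      cycle = NA_integer_,
      t_in_s = (seg@tIn[i] - 1L) / fs,
      t_out_s = (seg@tOut[i] - 1L) / fs,
      t_end_s = (seg@tEnd[i] - 1L) / fs,
      insp_symbol = ci$symbol, exp_symbol = ce$symbol,
      insp_dist = ci$dist, exp_dist = ce$dist,
      outlier = ci$symbol == "OUTLIER" || ce$symbol == "OUTLIER",
      classified = TRUE)
  }
  dd <- seg@discarded
  for (j in seq_len(nrow(dd))) {
    rows[[k + j]] <- data.frame(
      cycle = NA_integer_,
      t_in_s = (dd$start[j] - 1L) / fs,
      t_out_s = NA_real_,
      t_end_s = (dd$end[j] - 1L) / fs,
      insp_symbol = "OUTLIER", exp_symbol = "OUTLIER",
      insp_dist = NA_real_, exp_dist = NA_real_,
      outlier = TRUE, classified = FALSE)
  }
  cycles <- do.call(rbind, rows)
  cycles <- cycles[order(cycles$t_in_s), , drop = FALSE]
  cycles$cycle <- seq_len(nrow(cycles))
  rownames(cycles) <- NULL
  mk(cycles)
}

#' Per-cycle ventilation descriptors
#'
#' Computes the classical descriptors from a segmentation: inspiration and
#' expiration durations `Ti`/`Te` (s) and the nasal inspired/expired
#' volumes `NIV`/`NEV` (mL, the rectangle-rule integral of flow over each
#' phase, expired volume reported as a magnitude).
#'
#' @param rec a [Recording-class].
#' @param seg its [CycleSegmentation-class].
#' @return data.frame with columns `cycle`, `Ti`, `Te`, `NIV`, `NEV`.
#' @export
computeDescriptors <- function(rec, seg) {
  stopifnot(is(rec, "Recording"), is(seg, "CycleSegmentation"))
  if (length(seg@tEnd) && max(seg@tEnd) > length(rec@samples) + 1L)
    stop("validation error: segmentation does not match recording")
  fs <- rec@fs
  k <- length(seg@tIn)
  out <- data.frame(cycle = seq_len(k),
                    Ti = (seg@tOut - seg@tIn) / fs,
                    Te = (seg@tEnd - seg@tOut) / fs,
                    NIV = NA_real_, NEV = NA_real_)
  for (i in seq_len(k)) {
    out$NIV[i] <- sum(rec@samples[seg@tIn[i]:(seg@tOut[i] - 1L)]) / fs
    out$NEV[i] <- abs(sum(rec@samples[seg@tOut[i]:(seg@tEnd[i] - 1L)])) / fs
  }
  out
}

#' Write a symbolic recording as CSV
#'
#' `#`-prefixed header lines carry the metadata (subject, group, phase, fs
#' and the label vocabularies); the body is the per-cycle table.
#'
#' @param sym a [SymbolicRecording-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSymbolicRecording <- function(sym, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# subject_id=%s", sym@subjectId),
               sprintf("# group=%s", sym@group),
               sprintf("# phase=%s", sym@phase),
               sprintf("# fs=%.17g", sym@fs),
               sprintf("# insp_labels=%s", paste(sym@inspLabels,
                                                 collapse = "|")),
               sprintf("# exp_labels=%s", paste(sym@expLabels,
                                                collapse = "|"))), con)
  utils::write.csv(sym@cycles, con, row.names = FALSE)
  invisible(path)
}

#' Read a symbolic recording from CSV
#'
#' @param path path written by [writeSymbolicRecording()].
#' @return A [SymbolicRecording-class].
#' @export
readSymbolicRecording <- function(path) {
  meta <- .parseHeaderMeta(path)
  cyc <- utils::read.csv(path, comment.char = "#",
                         colClasses = c(insp_symbol = "character",
                                        exp_symbol = "character"))
  new("SymbolicRecording", cycles = cyc,
      subjectId = meta$subject_id %||% "subject",
      group = meta$group %||% "unspecified",
      phase = meta$phase %||% "unspecified",
      fs = as.numeric(meta$fs %||% NA),
      inspLabels = strsplit(meta$insp_labels %||% "", "|",
                            fixed = TRUE)[[1]],
      expLabels = strsplit(meta$exp_labels %||% "", "|", fixed = TRUE)[[1]])
}
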