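#' @include clustering.R
NULL

#' Write a fitted shape model to JSON
#'
#' Serializes the references, labels, thresholds, per-cluster training
#' distance distributions, durations and fitting configuration so that new
#' recordings can be symbolized without refitting. Numbers are written at
#' full precision, making the file a faithful round-trip of the model.
#'
#' @param model a [ShapeModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeShapeModel <- function(model, path) {
  stopifnot(is(model, "ShapeModel"))
  obj <- list(
    phase = model@phase,
    labels = model@labels,
    references = model@references,
    assignments = model@assignments,
    memberDistances = model@memberDistances,
    memberDurations = model@memberDurations,
    withinDistances = model@withinDistances,
    meanDurations = model@meanDurations,
    thresholds = model@thresholds,
    alpha = model@alpha,
    inertiaTrace = model@inertiaTrace,
    config = model@config)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a shape model from JSON
#'
#' @param path path written by [writeShapeModel()].
#' @return A [ShapeModel-class].
#' @export
readShapeModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  asNum <- function(x) if (is.null(x)) numeric(0) else as.numeric(x)
  within <- obj$withinDistances
  if (is.null(within)) within <- list()
  if (is.matrix(within)) within <- lapply(seq_len(nrow(within)),
                                          function(i) within[i, ])
  if (!is.list(within)) within <- list(within)
  within <- lapply(within, asNum)
  refs <- obj$references
  if (is.matrix(refs)) refs <- lapply(seq_len(nrow(refs)),
                                      function(i) refs[i, ])
  if (!is.list(refs)) refs <- list(asNum(refs))
  refs <- lapply(refs, asNum)
  new("ShapeModel", phase = obj$phase, references = refs,
      labels = as.character(obj$labels),
      assignments = as.integer(obj$assignments %||% integer()),
      memberDistances = asNum(obj$memberDistances),
      memberDurations = asNum(obj$memberDurations),
      withinDistances = unname(within),
      meanDurations = asNum(obj$meanDurations),
      thresholds = asNum(obj$thresholds),
      alpha = as.numeric(obj$alpha %||% NA_real_),
      inertiaTrace = as.data.frame(obj$inertiaTrace %||%
        data.frame(iteration = integer(), beforeReassign = numeric(),
                   afterReassign = numeric())),
      config = as.list(obj$config))
}

#' Write a barycenter to JSON or CSV
#'
#' @param b a [Barycenter-class].
#' @param path output path; extension `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
writeBarycenter <- function(b, path) {
  stopifnot(is(b, "Barycenter"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(samples = b@samples,
                              objectiveTrace = b@objectiveTrace,
                              meta = b@meta[setdiff(names(b@meta),
                                                    "rawTrace")]),
                         path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.csv(data.frame(sample = seq_along(b@samples),
                                value = b@samples), path, row.names = FALSE)
  }
  invisible(path)
}
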