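#' @include stats.R
NULL

.INSP_PALETTE <- c("#A50026", "#D73027", "#F46D43", "#FDAE61", "#FEE08B")
.EXP_PALETTE <- c("#08306B", "#2171B5", "#6BAED6", "#74C476", "#A1D99B")
.OUTLIER_GREY <- "#BDBDBD"

#' Fixed color palettes for inspiration and expiration references
#'
#' Inspiration references use a red-to-yellow ramp and expiration
#' references a blue-to-green ramp, lighter colors corresponding to longer
#' mean durations (labels are duration-ordered). For `K != 5` the fixed
#' 5-step palettes are interpolated.
#'
#' @param K number of references.
#' @return Character vector of `K` hex colors.
#' @export
inspirationPalette <- function(K = 5) {
  if (K == 5) .INSP_PALETTE else colorRampPalette(.INSP_PALETTE)(K)
}

#' @rdname inspirationPalette
#' @export
expirationPalette <- function(K = 5) {
  if (K == 5) .EXP_PALETTE else colorRampPalette(.EXP_PALETTE)(K)
}

#' Referent-cycle map: exemplar cycles for every (letter, digit) class
#'
#' For each pair of an inspiration reference and an expiration reference,
#' selects among the training cycles carrying that combined label the one
#' whose cumulative DTW distance (inspiration distance plus expiration
#' distance to the respective references) is smallest, and arranges the
#' exemplars on a K1 x K2 grid (rows = inspiration letters, columns =
#' expiration digits, both in increasing duration order). Cells with no
#' member are left blank. Exemplars can be displayed as airflow or as the
#' within-cycle volume trace.
#'
#' @param inspModel,expModel fitted [ShapeModel-class] objects trained on
#'   cycle-aligned phase sets (element i of both training sets from the
#'   same cycle).
#' @param inspSet,expSet the training [PhaseSet-class] objects, in the
#'   order used for fitting.
#' @param display `"flow"` or `"volume"`.
#' @return List with `exemplars` (data.frame: `insp_label`, `exp_label`,
#'   `index` of the exemplar cycle, `distance`), `traces` (data.frame of
#'   exemplar samples for plotting) and `plot` (a ggplot object).
#' @export
referentCycleMap <- function(inspModel, expModel, inspSet, expSet,
                             display = c("flow", "volume")) {
  display <- match.arg(display)
  stopifnot(is(inspModel, "ShapeModel"), is(expModel, "ShapeModel"))
  nI <- length(inspModel@assignments)
  if (nI != length(expModel@assignments))
    stop("models must be trained on cycle-aligned sets of equal size")
  keepI <- inspModel@config$keep %||% seq_len(nI)
  keepE <- expModel@config$keep %||% seq_len(nI)
  common <- intersect(keepI, keepE)
  posI <- match(common, keepI)
  posE <- match(common, keepE)
  total <- inspModel@memberDistances[posI] + expModel@memberDistances[posE]
  exem <- expand.grid(insp_label = inspModel@labels,
                      exp_label = expModel@labels,
                      stringsAsFactors = FALSE)
  exem$index <- NA_integer_
  exem$distance <- NA_real_
  for (r in seq_len(nrow(exem))) {
    ki <- match(exem$insp_label[r], inspModel@labels)
    ke <- match(exem$exp_label[r], expModel@labels)
    in_class <- which(inspModel@assignments[posI] == ki &
                      expModel@assignments[posE] == ke)
    if (length(in_class)) {
      best <- in_class[which.min(total[in_class])]
      exem$index[r] <- common[best]
      exem$distance[r] <- total[best]
    }
  }
  fs <- inspSet@fs
  traceRows <- list()
  for (r in which(!is.na(exem$index))) {
    i <- exem$index[r]
    flow <- c(inspSet[[i]], expSet[[i]])
    y <- if (display == "volume") cumsum(flow) / fs else flow
    nIn <- length(inspSet[[i]])
    traceRows[[length(traceRows) + 1L]] <- data.frame(
      insp_label = exem$insp_label[r], exp_label = exem$exp_label[r],
      t = (seq_along(y) - 1L) / fs, value = y,
      segment = rep(c("inspiration", "expiration"),
                    c(nIn, length(y) - nIn)))
  }
  traces <- if (length(traceRows)) do.call(rbind, traceRows) else
    data.frame(insp_label = character(), exp_label = character(),
               t = numeric(), value = numeric(), segment = character())
  pal <- c(inspiration = "#D73027", expiration = "#2171B5")
  p <- ggplot2::ggplot(traces,
                       ggplot2::aes(x = .data$t, y = .data$value,
                                    color = .data$segment)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_color_manual(values = pal) +
    ggplot2::facet_grid(insp_label ~ exp_label) +
    ggplot2::labs(x = "time (s)",
                  y = if (display == "flow") "airflow (mL/s)"
                      else "volume (mL)",
                  title = "Referent cycle map") +
    ggplot2::theme_minimal()
  list(exemplars = exem, traces = traces, plot = p)
}

#' RC heat map of referent-cycle time percentages
#'
#' Displays an RC distribution (or the elementwise average over several) as
#' a heat map with rows = inspiration letters and columns = expiration
#' digits. Display values are truncated at `cap` percent (default 20) so
#' rare classes stay visible; averaging across subjects happens before
#' capping.
#'
#' @param dist an [RCDistribution-class], a matrix, or a list of either
#'   (averaged elementwise).
#' @param cap display cap in percent (default 20).
#' @return A ggplot object; the capped display matrix is attached as
#'   attribute `"displayMatrix"` and the uncapped mean as `"meanMatrix"`.
#' @export
rcHeatmap <- function(dist, cap = 20) {
  assertScalarPositive(cap, "cap")
  mats <- if (is(dist, "RCDistribution")) list(dist@matrix)
          else if (is.matrix(dist)) list(dist)
          else lapply(dist, function(d)
            if (is(d, "RCDistribution")) d@matrix else as.matrix(d))
  m <- Reduce(`+`, mats) / length(mats)
  disp <- pmin(m, cap)
  df <- expand.grid(insp = rownames(m) %||% as.character(seq_len(nrow(m))),
                    expn = colnames(m) %||% as.character(seq_len(ncol(m))),
                    stringsAsFactors = FALSE)
  df$value <- as.vector(disp)
  df$insp <- factor(df$insp, levels = rev(sort(unique(df$insp))))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$expn, y = .data$insp,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, cap),
                                  name = "% time (capped)") +
    ggplot2::labs(x = "expiration reference", y = "inspiration reference",
                  title = "RC map") +
    ggplot2::theme_minimal()
  attr(p, "displayMatrix") <- disp
  attr(p, "meanMatrix") <- m
  p
}

#' Polar profile of marginal reference-time percentages
#'
#' Shows the percentage of time assigned to each reference of one phase as
#' a closed polygon on a polar chart, optionally overlaying two conditions
#' (e.g. before and after a treatment).
#'
#' @param profiles a named list of numeric vectors (one polygon each), all
#'   over the same references; typically the `inspiration` or `expiration`
#'   element of [marginalProfiles()] for one or two conditions.
#' @param title plot title.
#' @return A ggplot object with the polygon data attached as attribute
#'   `"profileData"`.
#' @export
polarProfile <- function(profiles, title = "Reference time profile") {
  if (is.numeric(profiles)) profiles <- list(profile = profiles)
  rows <- list()
  for (nm in names(profiles)) {
    v <- profiles[[nm]]
    rows[[nm]] <- data.frame(condition = nm,
                             reference = names(v) %||%
                               as.character(seq_along(v)),
                             value = as.numeric(v))
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$reference,
                                        y = .data$value,
                                        group = .data$condition,
                                        color = .data$condition,
                                        fill = .data$condition)) +
    ggplot2::geom_polygon(alpha = 0.25) +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "% time", title = title) +
    ggplot2::theme_minimal()
  attr(p, "profileData") <- df
  p
}

#' Respiratory bar code of a symbolized recording
#'
#' Two-track timeline: the upper track shows inspirations and the lower
#' track expirations, one rectangle per phase with width proportional to
#' its duration and color given by its reference; outlier and unclassified
#' spans are light grey across both tracks, and an optional injection
#' interval is left white.
#'
#' @param sym a non-empty [SymbolicRecording-class].
#' @param injectionWindow optional numeric `c(start, end)` in seconds,
#'   blanked out of both tracks.
#' @return A ggplot object with the rectangle data attached as attribute
#'   `"barData"`.
#' @export
barcode <- function(sym, injectionWindow = NULL) {
  stopifnot(is(sym, "SymbolicRecording"))
  cyc <- sym@cycles
  if (nrow(cyc) == 0L) stop("parameter error: empty symbolic recording")
  K1 <- length(sym@inspLabels)
  K2 <- length(sym@expLabels)
  palI <- stats::setNames(inspirationPalette(K1), sym@inspLabels)
  palE <- stats::setNames(expirationPalette(K2), sym@expLabels)
  rows <- list()
  for (i in seq_len(nrow(cyc))) {
    if (!cyc$classified[i] || is.na(cyc$t_out_s[i])) {
      rows[[length(rows) + 1L]] <- data.frame(
        xmin = cyc$t_in_s[i], xmax = cyc$t_end_s[i], ymin = 0, ymax = 2,
        fill = .OUTLIER_GREY, track = "both", symbol = "OUTLIER")
      next
    }
    iCol <- if (cyc$outlier[i] || cyc$insp_symbol[i] == "OUTLIER")
      .OUTLIER_GREY else palI[[cyc$insp_symbol[i]]]
    eCol <- if (cyc$outlier[i] || cyc$exp_symbol[i] == "OUTLIER")
      .OUTLIER_GREY else palE[[cyc$exp_symbol[i]]]
    rows[[length(rows) + 1L]] <- data.frame(
      xmin = cyc$t_in_s[i], xmax = cyc$t_out_s[i], ymin = 1, ymax = 2,
      fill = iCol, track = "inspiration", symbol = cyc$insp_symbol[i])
    rows[[length(rows) + 1L]] <- data.frame(
      xmin = cyc$t_out_s[i], xmax = cyc$t_end_s[i], ymin = 0, ymax = 1,
      fill = eCol, track = "expiration", symbol = cyc$exp_symbol[i])
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  if (!is.null(injectionWindow)) {
    df <- df[df$xmax <= injectionWindow[1] | df$xmin >= injectionWindow[2], ,
             drop = FALSE]
  }
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax),
                       fill = df$fill) +
    ggplot2::scale_y_continuous(breaks = c(0.5, 1.5),
                                labels = c("expiration", "inspiration")) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("Bar code: %s", sym@subjectId)) +
    ggplot2::theme_minimal()
  attr(p, "barData") <- df
  p
}
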