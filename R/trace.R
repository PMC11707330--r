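#' Single-lane electrophoresis trace
#'
#' A trace holds one lane's detector signal sampled over migration time
#' (capillary gel electrophoresis, CGE) or over gel position (agarose gel
#' electrophoresis, AGE, reduced to a 1-D lane profile). The `role` marks how
#' the lane is used downstream: `"sample"` lanes are quantified, `"buffer"`
#' lanes serve as background references, `"alignment_marker"` lanes anchor
#' migration-time positions and `"ladder"` lanes calibrate apparent size.
#'
#' @param lane_id Character scalar, unique lane identifier.
#' @param time Numeric vector of migration times in seconds (or gel position
#'   for AGE profiles); must be strictly increasing with at least 2 samples.
#' @param signal Numeric vector of detector signal (arbitrary units), same
#'   length as `time`; all values finite.
#' @param role One of `"sample"`, `"buffer"`, `"alignment_marker"`,
#'   `"ladder"`.
#' @param meta Named list of optional acquisition metadata. Recognised keys:
#'   `capillary_id`, `injection_time_s`, `concentration_ng_per_uL`,
#'   `prepared_sc_fraction`, `incubation_time_min`, `run_index`,
#'   `replicate_id`.
#' @return An object of class `cge_trace`.
#' @examples
#' tr <- cge_trace("L1", time = 0:10, signal = rep(1, 11))
#' tr
#' @export
cge_trace <- function(lane_id, time, signal, role = "sample", meta = list()) {
  role <- match.arg(role, c("sample", "buffer", "alignment_marker", "ladder"))
  time <- as.numeric(time)
  signal <- as.numeric(signal)
  if (length(time) != length(signal))
    stop("`time` and `signal` must have the same length", call. = FALSE)
  if (length(time) < 2L)
    stop("a trace needs at least 2 samples", call. = FALSE)
  if (anyNA(time) || any(!is.finite(time)))
    stop("`time` must be finite", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("`time` must be strictly increasing", call. = FALSE)
  if (anyNA(signal) || any(!is.finite(signal)))
    stop("`signal` must be finite", call. = FALSE)
  if (!is.list(meta))
    stop("`meta` must be a list", call. = FALSE)
  structure(
    list(lane_id = as.character(lane_id), role = role,
         time = time, signal = signal, meta = meta),
    class = "cge_trace"
  )
}

#' @export
print.cge_trace <- function(x, ...) {
  cat(sprintf("<cge_trace> lane '%s' (%s): %d samples, t = [%g, %g] s\n",
              x$lane_id, x$role, length(x$time),
              min(x$time), max(x$time)))
  invisible(x)
}

#' Batch of traces from one run
#'
#' Bundles traces that share one acquisition (e.g. a 12-channel CGE
#' cartridge) together with the run parameters. Lane ids must be unique and
#' each capillary may contribute at most one buffer lane.
#'
#' @param traces List of [cge_trace] objects.
#' @param run_params Named list of instrument settings (all optional):
#'   `injection_voltage_kV`, `injection_time_s`, `separation_voltage_kV`,
#'   `separation_time_s`.
#' @return An object of class `cge_batch`; traces are stored as a named list
#'   keyed by lane id.
#' @export
cge_batch <- function(traces, run_params = list()) {
  if (!length(traces)) stop("a batch needs at least one trace", call. = FALSE)
  ok <- vapply(traces, inherits, logical(1), what = "cge_trace")
  if (!all(ok)) stop("all elements of `traces` must be cge_trace objects", call. = FALSE)
  ids <- vapply(traces, function(tr) tr$lane_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate lane_id in batch: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  buf <- traces[vapply(traces, function(tr) tr$role == "buffer", logical(1))]
  if (length(buf) > 1L) {
    caps <- vapply(buf, function(tr) {
      cid <- tr$meta$capillary_id
      if (is.null(cid)) "" else as.character(cid)
    }, character(1))
    if (anyDuplicated(caps))
      stop("at most one buffer trace per capillary_id", call. = FALSE)
  }
  names(traces) <- ids
  structure(list(traces = traces, run_params = run_params),
            class = "cge_batch")
}

#' @export
print.cge_batch <- function(x, ...) {
  roles <- table(vapply(x$traces, function(tr) tr$role, character(1)))
  cat(sprintf("<cge_batch> %d lanes (%s)\n", length(x$traces),
              paste(names(roles), roles, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' @export
length.cge_batch <- function(x) length(x$traces)

#' Lane identifiers of a batch
#' @param batch A [cge_batch].
#' @return Character vector of lane ids in batch order.
#' @export
lane_ids <- function(batch) {
  stopifnot(inherits(batch, "cge_batch"))
  names(batch$traces)
}

#' Extract one trace from a batch
#' @param batch A [cge_batch].
#' @param lane_id Lane identifier.
#' @return The [cge_trace] for that lane.
#' @export
get_trace <- function(batch, lane_id) {
  stopifnot(inherits(batch, "cge_batch"))
  tr <- batch$traces[[lane_id]]
  if (is.null(tr)) stop("no lane '", lane_id, "' in batch", call. = FALSE)
  tr
}

#' DNA ladder specification
#'
#' Describes the band composition of a linear DNA ladder used for
#' apparent-size calibration: fragment sizes in base pairs, ordered from
#' smallest (fastest-migrating) to largest.
#'
#' @param size_bp Integer vector of fragment sizes in bp, strictly
#'   increasing.
#' @param label Optional character vector of band labels; defaults to
#'   `"<size> bp"`.
#' @return An object of class `ladder_spec` (a data.frame with columns
#'   `size_bp`, `label`).
#' @export
ladder_spec <- function(size_bp, label = NULL) {
  size_bp <- as.integer(size_bp)
  if (any(size_bp <= 0L)) stop("`size_bp` must be positive", call. = FALSE)
  if (any(diff(size_bp) <= 0L))
    stop("`size_bp` must be strictly increasing", call. = FALSE)
  if (is.null(label)) label <- sprintf("%d bp", size_bp)
  structure(data.frame(size_bp = size_bp, label = as.character(label),
                       stringsAsFactors = FALSE),
            class = c("ladder_spec", "data.frame"))
}

#' Plot a trace
#'
#' Draws the densiogram with optional shaded isoform integration windows.
#'
#' @param x A [cge_trace].
#' @param windows Optional [isoform_windows] to shade.
#' @param ... Passed to [graphics::plot].
#' @export
plot.cge_trace <- function(x, windows = NULL, ...) {
  graphics::plot(x$time, x$signal, type = "l",
                 xlab = "migration time [s]", ylab = "signal [a.u.]",
                 main = x$lane_id, ...)
  if (!is.null(windows)) {
    cols <- c(lin = grDevices::adjustcolor("firebrick", 0.15),
              sc = grDevices::adjustcolor("goldenrod", 0.15),
              oc = grDevices::adjustcolor("forestgreen", 0.15))
    usr <- graphics::par("usr")
    for (nm in c("lin", "sc", "oc")) {
      w <- windows[[nm]]
      graphics::rect(w[1], usr[3], w[2], usr[4], col = cols[[nm]], border = NA)
    }
  }
  invisible(x)
}
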