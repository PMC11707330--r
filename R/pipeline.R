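# Pull a scalar metadata value out of a trace, NA when absent.
meta_value <- function(trace, key) {
  v <- trace$meta[[key]]
  if (is.null(v) || length(v) != 1L) NA else v
}

#' Quantify one background-corrected trace
#'
#' Window integration followed by sum-normalized fraction computation.
#'
#' @param trace A background-corrected [cge_trace].
#' @param windows An [isoform_windows].
#' @param correction Optional [dye_correction] (CGE: `NULL`, no correction).
#' @return List with `integrals` and `fractions`.
#' @export
quantify_trace <- function(trace, windows = default_windows(),
                           correction = NULL) {
  ints <- integrate_windows(trace, windows)
  list(integrals = ints,
       fractions = fractions_from_integrals(ints, correction))
}

#' Run the full quantification pipeline over a batch
#'
#' For every sample lane: background correction (per-lane linear fit with
#' the isoform windows excluded, or subtraction of the batch's buffer
#' lane), trapezoidal window integration, and sum-normalized isoform
#' fractions. Non-sample lanes (buffer, markers, ladders) are used as
#' references but not quantified.
#'
#' @param batch A [cge_batch] of raw traces.
#' @param windows An [isoform_windows] used for integration.
#' @param baseline `"linear"` (per-lane least-squares drift fit) or
#'   `"buffer"` (subtract the buffer lane of the same capillary, falling
#'   back to the batch's single buffer lane).
#' @param correction Optional [dye_correction]; `NULL` applies none (CGE).
#' @param exclusion_windows Windows excluded from the linear baseline fit;
#'   defaults to `windows`.
#' @return Data.frame (class `quant_table`) with one row per sample lane:
#'   `lane_id`, areas (`area_lin`, `area_sc`, `area_oc`, `total_area`),
#'   fractions (`f_lin`, `f_sc`, `f_oc`), a `clipped` flag (any window
#'   clipped at 0), and the lane metadata columns.
#' @export
quantify_batch <- function(batch, windows = default_windows(),
                           baseline = c("linear", "buffer"),
                           correction = NULL,
                           exclusion_windows = windows) {
  stopifnot(inherits(batch, "cge_batch"))
  baseline <- match.arg(baseline)
  buffers <- Filter(function(tr) tr$role == "buffer", batch$traces)
  buffer_for <- function(tr) {
    if (!length(buffers))
      stop("buffer baseline requested but the batch has no buffer lane",
           call. = FALSE)
    cap <- meta_value(tr, "capillary_id")
    for (b in buffers)
      if (!is.na(cap) && identical(meta_value(b, "capillary_id"), cap))
        return(b)
    buffers[[1L]]
  }
  rows <- list()
  for (id in lane_ids(batch)) {
    tr <- get_trace(batch, id)
    if (tr$role != "sample") next
    corrected <- if (baseline == "linear") {
      correct_background(tr, fit_linear_baseline(tr, exclusion_windows))
    } else {
      buf <- buffer_for(tr)
      correct_background(tr, buffer_baseline(buf), buffer = buf)
    }
    ints <- integrate_windows(corrected, windows)
    fr <- fractions_from_integrals(ints, correction)
    rows[[id]] <- data.frame(
      lane_id = id,
      area_lin = ints$lin, area_sc = ints$sc, area_oc = ints$oc,
      total_area = ints$total,
      f_lin = fr$f_lin, f_sc = fr$f_sc, f_oc = fr$f_oc,
      clipped = any(ints$clipped),
      capillary_id = as.character(meta_value(tr, "capillary_id")),
      concentration_ng_per_uL = as.numeric(meta_value(tr, "concentration_ng_per_uL")),
      prepared_sc_fraction = as.numeric(meta_value(tr, "prepared_sc_fraction")),
      incubation_time_min = as.numeric(meta_value(tr, "incubation_time_min")),
      run_index = as.numeric(meta_value(tr, "run_index")),
      replicate_id = as.character(meta_value(tr, "replicate_id")),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("batch contains no sample lanes", call. = FALSE)
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("quant_table", "data.frame")
  out
}
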