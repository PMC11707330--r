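#' Fit a linear baseline outside the peak regions
#'
#' Ordinary least squares of signal on time over all samples that fall
#' outside the exclusion windows (normally the three isoform windows). This
#' models the slow drift of the detector background when no pure-buffer lane
#' is available.
#'
#' @param trace A [cge_trace].
#' @param exclusion_windows An [isoform_windows] or list of `c(start, end)`
#'   intervals whose samples are excluded from the fit.
#' @return A `baseline_model` with `kind = "linear"`, `intercept` (signal
#'   units) and `slope` (signal units per second).
#' @export
fit_linear_baseline <- function(trace, exclusion_windows = list()) {
  stopifnot(inherits(trace, "cge_trace"))
  keep <- !in_any_window(trace$time, exclusion_windows)
  if (sum(keep) < 10L)
    stop("insufficient baseline: fewer than 10 samples outside the ",
         "exclusion windows", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, trace$time[keep]), trace$signal[keep])
  structure(list(kind = "linear",
                 intercept = unname(fit$coefficients[1]),
                 slope = unname(fit$coefficients[2]),
                 buffer_ref = NULL),
            class = "baseline_model")
}

#' Buffer-lane baseline model
#'
#' Marks a pure-buffer lane as the background reference: its signal is
#' subtracted from the sample lane (resampled onto the sample grid if
#' needed).
#'
#' @param buffer A [cge_trace] with role `"buffer"` (role is not enforced, a
#'   sample-free lane works too).
#' @return A `baseline_model` with `kind = "buffer"` and `buffer_ref` set to
#'   the buffer's lane id.
#' @export
buffer_baseline <- function(buffer) {
  stopifnot(inherits(buffer, "cge_trace"))
  structure(list(kind = "buffer", intercept = NA_real_, slope = NA_real_,
                 buffer_ref = buffer$lane_id),
            class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  if (x$kind == "linear")
    cat(sprintf("<baseline_model> linear: %.6g + %.6g * t\n",
                x$intercept, x$slope))
  else
    cat(sprintf("<baseline_model> buffer lane '%s'\n", x$buffer_ref))
  invisible(x)
}

#' Subtract the background from a trace
#'
#' Returns a new trace whose signal is the input minus the predicted
#' background — either the fitted linear drift or the (resampled) signal of a
#' pure-buffer lane. The input trace is left untouched and metadata is
#' preserved.
#'
#' @param trace A [cge_trace].
#' @param model A `baseline_model` from [fit_linear_baseline()] or
#'   [buffer_baseline()].
#' @param buffer The buffer [cge_trace]; required when
#'   `model$kind == "buffer"`. If its grid differs from the trace's it is
#'   resampled by linear interpolation (constant extension at the edges);
#'   non-overlapping grids are an error.
#' @return The background-corrected [cge_trace].
#' @export
correct_background <- function(trace, model, buffer = NULL) {
  stopifnot(inherits(trace, "cge_trace"), inherits(model, "baseline_model"))
  if (model$kind == "linear") {
    pred <- model$intercept + model$slope * trace$time
  } else {
    if (is.null(buffer))
      stop("buffer-mode correction needs the buffer trace", call. = FALSE)
    if (isTRUE(all.equal(buffer$time, trace$time))) {
      pred <- buffer$signal
    } else {
      if (max(buffer$time) < min(trace$time) ||
          min(buffer$time) > max(trace$time))
        stop("alignment error: buffer grid does not overlap trace grid",
             call. = FALSE)
      pred <- stats::approx(buffer$time, buffer$signal, xout = trace$time,
                            rule = 2)$y
    }
  }
  out <- trace
  out$signal <- trace$signal - pred
  out
}

#' Per-window signal-to-noise ratio
#'
#' For each isoform window, SNR = (maximum signal inside the window) divided
#' by a robust noise scale, `sigma = 1.4826 * MAD` of the signal over all
#' samples outside every window. The MAD-based scale is insensitive to any
#' residual peak tails leaking out of the windows. A zero noise estimate
#' yields an `Inf` sentinel rather than `NaN`.
#'
#' @param trace A background-corrected [cge_trace].
#' @param windows An [isoform_windows].
#' @return Named numeric vector `c(lin = , sc = , oc = )`.
#' @export
estimate_snr <- function(trace, windows) {
  stopifnot(inherits(trace, "cge_trace"), inherits(windows, "isoform_windows"))
  outside <- !in_any_window(trace$time, windows)
  if (!any(outside))
    stop("noise estimation error: no samples outside the windows",
         call. = FALSE)
  sigma <- stats::mad(trace$signal[outside])  # 1.4826 * median |x - median|
  vapply(c(lin = "lin", sc = "sc", oc = "oc"), function(nm) {
    w <- windows[[nm]]
    idx <- trace$time >= w[1] & trace$time <= w[2]
    peak <- if (any(idx)) max(trace$signal[idx]) else 0
    if (sigma == 0) {
      if (peak > 0) Inf else 0
    } else peak / sigma
  }, numeric(1))
}

#' Detect detector saturation
#'
#' A lane is flagged saturated when the signal sits at or above `level` for
#' at least `min_run` consecutive samples — the flat-topped plateau clipping
#' produces at high DNA loads.
#'
#' @param trace A [cge_trace] (raw, i.e. before background subtraction, since
#'   clipping happens in the detector).
#' @param level Saturation level in signal units; must be positive. There is
#'   no heuristic default: the instrument's full-scale value must be supplied
#'   explicitly.
#' @param min_run Minimum plateau length in samples.
#' @return Logical scalar.
#' @export
detect_saturation <- function(trace, level, min_run = 5L) {
  stopifnot(inherits(trace, "cge_trace"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0)
    stop("`level` must be a positive number", call. = FALSE)
  r <- rle(trace$signal >= level)
  any(r$values & r$lengths >= min_run)
}

#' Quality-control filter for a quantification batch
#'
#' A sample lane is included only when the worst-window SNR reaches
#' `min_snr`, the total integrated intensity reaches `min_total`, and no
#' saturation plateau is present. Buffer, alignment-marker and ladder lanes
#' pass through untouched. The filter never alters the signal of the lanes
#' it keeps.
#'
#' @param batch A [cge_batch] of background-corrected traces.
#' @param windows An [isoform_windows].
#' @param min_snr Minimum per-window SNR (default 10).
#' @param min_total Minimum total integrated intensity (signal·s).
#' @param level Optional saturation level; when `NULL` saturation is not
#'   tested. `raw_batch` supplies the pre-correction signals for the test.
#' @param min_run Plateau length for [detect_saturation()].
#' @param raw_batch Optional [cge_batch] of the uncorrected traces (same lane
#'   ids) used for the saturation test; defaults to `batch`.
#' @return List with `batch` (the filtered [cge_batch]) and `reports`, a
#'   data.frame with one row per sample lane: per-window SNR, total
#'   intensity, `saturated`, `included` and a `reasons` string
#'   (semicolon-separated; empty when included).
#' @export
qc_filter <- function(batch, windows, min_snr = 10, min_total = 0,
                      level = NULL, min_run = 5L, raw_batch = NULL) {
  stopifnot(inherits(batch, "cge_batch"))
  if (is.null(raw_batch)) raw_batch <- batch
  reports <- list()
  keep <- character(0)
  for (id in lane_ids(batch)) {
    tr <- get_trace(batch, id)
    if (tr$role != "sample") {
      keep <- c(keep, id)
      next
    }
    snr <- estimate_snr(tr, windows)
    ints <- integrate_windows(tr, windows)
    sat <- if (is.null(level)) FALSE else
      detect_saturation(get_trace(raw_batch, id), level, min_run)
    reasons <- character(0)
    if (min(snr) < min_snr) reasons <- c(reasons, "snr")
    if (ints$total < min_total) reasons <- c(reasons, "total_intensity")
    if (sat) reasons <- c(reasons, "saturation")
    included <- length(reasons) == 0L
    if (included) keep <- c(keep, id)
    reports[[id]] <- data.frame(
      lane_id = id, snr_lin = snr[["lin"]], snr_sc = snr[["sc"]],
      snr_oc = snr[["oc"]], total_intensity = ints$total,
      saturated = sat, included = included,
      reasons = paste(reasons, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  reports <- if (length(reports)) do.call(rbind, c(reports, make.row.names = FALSE))
             else data.frame()
  list(batch = cge_batch(batch$traces[keep], run_params = batch$run_params),
       reports = reports)
}
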