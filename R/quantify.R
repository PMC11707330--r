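#' Place isoform windows, optionally anchored to an alignment marker
#'
#' Band positions drift between capillaries, injection times and buffers, so
#' the canonical windows are re-anchored per lane when an alignment-marker
#' trace is available: every window is shifted by the difference between the
#' observed marker apex (argmax of the marker signal) and its reference
#' time. With two reference times (the small and large marker fragments) an
#' affine time map through both apexes is applied instead, correcting
#' stretch as well as shift. With no marker the defaults pass through.
#'
#' @param trace The background-corrected sample [cge_trace] (used only for
#'   validation of the resulting windows against the grid).
#' @param defaults An [isoform_windows]; see [default_windows()].
#' @param marker_trace Optional alignment-marker [cge_trace].
#' @param reference_marker_time Expected apex time (s) of the marker.
#' @param reference_marker_time2 Optional second reference time; when given,
#'   the two largest well-separated marker peaks are matched to the two
#'   references in time order and the windows mapped affinely.
#' @return An [isoform_windows].
#' @export
locate_windows <- function(trace, defaults = default_windows(),
                           marker_trace = NULL,
                           reference_marker_time = NULL,
                           reference_marker_time2 = NULL) {
  stopifnot(inherits(defaults, "isoform_windows"))
  if (is.null(marker_trace) || is.null(reference_marker_time))
    return(defaults)
  stopifnot(inherits(marker_trace, "cge_trace"))
  s <- marker_trace$signal
  sigma <- stats::mad(s)
  height <- max(s) - stats::median(s)
  if (height <= 0 || (sigma > 0 && height <= 5 * sigma))
    stop("marker-not-found: no marker peak above 5x noise", call. = FALSE)
  if (is.null(reference_marker_time2)) {
    apex <- marker_trace$time[which.max(s)]
    shift <- apex - reference_marker_time
    map <- function(t) t + shift
  } else {
    pk <- find_peaks(marker_trace)
    if (length(pk) < 2L)
      stop("marker-not-found: two marker peaks required for affine ",
           "alignment", call. = FALSE)
    obs <- c(min(pk), max(pk))
    ref <- sort(c(reference_marker_time, reference_marker_time2))
    slope <- diff(obs) / diff(ref)
    map <- function(t) obs[1] + slope * (t - ref[1])
  }
  isoform_windows(lin = map(defaults$lin), sc = map(defaults$sc),
                  oc = map(defaults$oc))
}

#' Integrate the signal over the isoform windows
#'
#' Trapezoidal integration of the background-corrected signal over each of
#' the three windows, on the native time grid (no resampling: at ~1 s
#' sampling the trapezoid error for these band widths is negligible).
#' Negative raw areas — possible in near-empty windows after background
#' subtraction — are clipped to 0 and flagged.
#'
#' @param trace A background-corrected [cge_trace].
#' @param windows An [isoform_windows]; every window must lie within the
#'   trace's time grid.
#' @return An `isoform_integrals`: list with `lin`, `sc`, `oc`, `total`
#'   (signal·s) and a named logical `clipped`.
#' @export
integrate_windows <- function(trace, windows) {
  stopifnot(inherits(trace, "cge_trace"), inherits(windows, "isoform_windows"))
  t0 <- min(trace$time); t1 <- max(trace$time)
  res <- list()
  clipped <- c(lin = FALSE, sc = FALSE, oc = FALSE)
  for (nm in c("lin", "sc", "oc")) {
    w <- windows[[nm]]
    if (w[1] < t0 || w[2] > t1)
      stop("range error: window `", nm, "` [", w[1], ", ", w[2],
           "] outside the time grid [", t0, ", ", t1, "]", call. = FALSE)
    idx <- which(trace$time >= w[1] & trace$time <= w[2])
    a <- if (length(idx) >= 2L)
      pracma::trapz(trace$time[idx], trace$signal[idx]) else 0
    if (a < 0) {
      clipped[[nm]] <- TRUE
      a <- 0
    }
    res[[nm]] <- a
  }
  structure(list(lin = res$lin, sc = res$sc, oc = res$oc,
                 total = res$lin + res$sc + res$oc, clipped = clipped),
            class = "isoform_integrals")
}

#' @export
print.isoform_integrals <- function(x, ...) {
  cat(sprintf("<isoform_integrals> lin %.6g  sc %.6g  oc %.6g  (total %.6g)\n",
              x$lin, x$sc, x$oc, x$total))
  invisible(x)
}

#' Dye attachment-efficiency correction factors
#'
#' Fluorescent dyes can bind the compact supercoiled form with a slightly
#' different efficiency than the relaxed forms; for SYBR Gold on agarose
#' gels the SC:OC efficiency ratio is 1.05. Raw band areas are divided by
#' these factors before normalization. For CGE no correction is applied
#' (all-unit efficiencies, the default of [fractions_from_integrals()]).
#'
#' @param sc_efficiency,lin_efficiency,oc_efficiency Positive dimensionless
#'   ratios relative to the OC response.
#' @return A `dye_correction` object.
#' @export
dye_correction <- function(sc_efficiency = 1.05, lin_efficiency = 1.0,
                           oc_efficiency = 1.0) {
  eff <- c(lin = lin_efficiency, sc = sc_efficiency, oc = oc_efficiency)
  if (any(!is.finite(eff)) || any(eff <= 0))
    stop("efficiencies must be positive and finite", call. = FALSE)
  structure(as.list(eff), class = "dye_correction")
}

#' Isoform fractions from integrated areas
#'
#' Divides each area by its dye efficiency and normalizes the corrected
#' amounts to sum to 1 — the sum-normalized SC/OC/Lin percentages reported
#' per measurement. A zero total is an explicit error, never `NaN`.
#'
#' @param integrals An `isoform_integrals` from [integrate_windows()] or
#'   [multipeak_integrals()], or a named numeric `c(lin=, sc=, oc=)`.
#' @param correction Optional [dye_correction]; `NULL` (the default) means
#'   unit efficiencies, appropriate for CGE.
#' @return An `isoform_fractions`: list with `f_lin`, `f_sc`, `f_oc` in
#'   `[0, 1]` summing to 1.
#' @export
fractions_from_integrals <- function(integrals, correction = NULL) {
  a <- c(lin = integrals[["lin"]], sc = integrals[["sc"]],
         oc = integrals[["oc"]])
  if (any(a < 0)) stop("areas must be non-negative", call. = FALSE)
  if (is.null(correction)) correction <- dye_correction(1, 1, 1)
  stopifnot(inherits(correction, "dye_correction"))
  amt <- a / c(correction$lin, correction$sc, correction$oc)
  tot <- sum(amt)
  if (tot <= 0)
    stop("undefined fractions: total integrated area is zero", call. = FALSE)
  f <- amt / tot
  structure(list(f_lin = f[["lin"]], f_sc = f[["sc"]], f_oc = f[["oc"]]),
            class = "isoform_fractions")
}

#' @export
print.isoform_fractions <- function(x, ...) {
  cat(sprintf("<isoform_fractions> lin %.4f  sc %.4f  oc %.4f\n",
              x$f_lin, x$f_sc, x$f_oc))
  invisible(x)
}
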