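#' Isoform integration windows
#'
#' The three migration-time regions assigned to the plasmid isoforms: linear
#' (Lin, sharp, early), supercoiled (SC/CCC, sharp), and open-circular (OC,
#' broad, late). Intervals are closed, in seconds, and must not overlap
#' (shared endpoints are allowed).
#'
#' @param lin,sc,oc Numeric length-2 vectors `c(start, end)` in seconds.
#' @return An object of class `isoform_windows`.
#' @seealso [default_windows()], [matched_windows()], [locate_windows()]
#' @export
isoform_windows <- function(lin, sc, oc) {
  w <- list(lin = as.numeric(lin), sc = as.numeric(sc), oc = as.numeric(oc))
  for (nm in names(w)) {
    if (length(w[[nm]]) != 2L || anyNA(w[[nm]]))
      stop("window `", nm, "` must be c(start, end)", call. = FALSE)
    if (w[[nm]][1] >= w[[nm]][2])
      stop("window `", nm, "` must have start < end", call. = FALSE)
  }
  ord <- order(vapply(w, `[`, numeric(1), 1L))
  sorted <- w[ord]
  for (i in seq_len(2L)) {
    if (sorted[[i]][2] > sorted[[i + 1L]][1])
      stop("windows `", names(sorted)[i], "` and `", names(sorted)[i + 1L],
           "` overlap", call. = FALSE)
  }
  structure(w, class = "isoform_windows")
}

#' @export
print.isoform_windows <- function(x, ...) {
  cat(sprintf("<isoform_windows> lin [%g, %g]  sc [%g, %g]  oc [%g, %g]\n",
              x$lin[1], x$lin[2], x$sc[1], x$sc[2], x$oc[1], x$oc[2]))
  invisible(x)
}

#' Default pUC19 isoform windows
#'
#' Windows around the canonical pUC19 band positions: Lin centred at 400 s
#' (half-width 50 s), SC at 500 s (75 s), OC at 750 s (100 s). Band
#' positions drift between capillaries; use [locate_windows()] with an
#' alignment-marker lane to shift them.
#'
#' @return An [isoform_windows] with lin `[350, 450]`, sc `[450, 600]`,
#'   oc `[650, 850]`.
#' @export
default_windows <- function() {
  isoform_windows(lin = c(350, 450), sc = c(450, 600), oc = c(650, 850))
}

#' Windows matched to a simulation configuration
#'
#' Builds integration windows spanning `k_sigma` standard deviations either
#' side of each configured peak centre. At the default `k_sigma = 6` each
#' Gaussian band is captured up to a relative tail loss of about 2e-9, so
#' window integrals equal the underlying band areas to numerical precision —
#' the right choice for exactness checks against simulated ground truth.
#'
#' @param config A [simulation_config].
#' @param k_sigma Half-width in units of the per-isoform band sigma.
#' @return An [isoform_windows].
#' @export
matched_windows <- function(config, k_sigma = 6) {
  stopifnot(inherits(config, "simulation_config"))
  mk <- function(nm) config$peak_centers[[nm]] +
    c(-1, 1) * k_sigma * config$peak_sigmas[[nm]]
  isoform_windows(lin = mk("lin"), sc = mk("sc"), oc = mk("oc"))
}

# Coerce an isoform_windows object or list of c(start, end) intervals to a
# plain list of intervals.
as_interval_list <- function(windows) {
  if (inherits(windows, "isoform_windows")) return(unclass(windows))
  if (is.numeric(windows) && length(windows) == 2L) return(list(windows))
  as.list(windows)
}

# Logical mask of time points falling inside any of the intervals.
in_any_window <- function(time, windows) {
  iv <- as_interval_list(windows)
  inside <- rep(FALSE, length(time))
  for (w in iv) inside <- inside | (time >= w[1] & time <= w[2])
  inside
}
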