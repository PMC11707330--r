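# Local maxima above 5x the robust noise scale (1.4826 * MAD), returned as
# times sorted by migration time.
find_peaks <- function(trace, noise_mult = 5) {
  ss <- trace$signal
  sigma <- stats::mad(ss)
  cand <- which(diff(sign(diff(ss))) < 0) + 1L
  thr <- noise_mult * sigma
  cand <- cand[ss[cand] > thr]
  trace$time[cand]
}

#' Calibrate apparent size from a DNA ladder lane
#'
#' Detects the ladder band apexes (local maxima above 5x the robust noise
#' level, in time order) and pairs them one-to-one with the ladder
#' specification's fragment sizes. The number of detected peaks must equal
#' the number of specified bands — partial matching would silently
#' mis-assign sizes, so a mismatch is an error.
#'
#' @param ladder_trace A background-corrected ladder [cge_trace].
#' @param spec A [ladder_spec].
#' @return A `size_map`: knots `(migration_time_s, size_bp)` with strictly
#'   increasing times and sizes, interpolated log-linearly by
#'   [apparent_size()].
#' @export
calibrate_size <- function(ladder_trace, spec) {
  stopifnot(inherits(ladder_trace, "cge_trace"), inherits(spec, "ladder_spec"))
  pk <- find_peaks(ladder_trace)
  if (length(pk) != nrow(spec))
    stop("ladder-matching error: detected ", length(pk), " peaks but the ",
         "spec lists ", nrow(spec), " bands", call. = FALSE)
  knots <- data.frame(time = pk, size_bp = spec$size_bp)
  if (any(diff(knots$size_bp) <= 0) || any(diff(knots$time) <= 0))
    stop("ladder-matching error: sizes must increase with migration time",
         call. = FALSE)
  structure(list(knots = knots), class = "size_map")
}

#' @export
print.size_map <- function(x, ...) {
  cat(sprintf("<size_map> %d knots, %g-%g bp over %g-%g s\n",
              nrow(x$knots), min(x$knots$size_bp), max(x$knots$size_bp),
              min(x$knots$time), max(x$knots$time)))
  invisible(x)
}

#' Apparent fragment size at a migration time
#'
#' Interpolates `log(size_bp)` linearly in time between the calibration
#' knots, so the midpoint between two knots maps to their geometric-mean
#' size. Queries outside the knot range are linearly extrapolated (still in
#' log size) and flagged via the `"extrapolated"` attribute.
#'
#' @param map A `size_map` from [calibrate_size()].
#' @param t Numeric vector of migration times (s).
#' @return Numeric vector of apparent sizes in bp, with a logical attribute
#'   `"extrapolated"` marking out-of-range queries.
#' @export
apparent_size <- function(map, t) {
  stopifnot(inherits(map, "size_map"))
  kt <- map$knots$time
  kl <- log(map$knots$size_bp)
  n <- length(kt)
  ls <- numeric(length(t))
  inside <- t >= kt[1] & t <= kt[n]
  if (any(inside))
    ls[inside] <- stats::approx(kt, kl, xout = t[inside])$y
  lo <- t < kt[1]
  if (any(lo))
    ls[lo] <- kl[1] + (t[lo] - kt[1]) * (kl[2] - kl[1]) / (kt[2] - kt[1])
  hi <- t > kt[n]
  if (any(hi))
    ls[hi] <- kl[n] + (t[hi] - kt[n]) * (kl[n] - kl[n - 1]) /
      (kt[n] - kt[n - 1])
  out <- exp(ls)
  attr(out, "extrapolated") <- !inside
  out
}
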