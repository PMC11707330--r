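# Sum-of-Gaussians band model. Peaks are parameterised by (center, sigma,
# area) so a fitted area is directly comparable to a window integral.
gaussian_sum <- function(t, center, sigma, area) {
  y <- numeric(length(t))
  for (i in seq_along(center))
    y <- y + area[i] * stats::dnorm(t, center[i], sigma[i])
  y
}

#' Gaussian peak parameter set
#'
#' @param center Peak centre (seconds, or gel position units for AGE).
#' @param sigma Gaussian standard deviation, same units, `> 0`.
#' @param area Band area (signal · units), `>= 0`.
#' @param label Optional isoform label (`"lin"`, `"sc"`, `"oc"`, ...).
#' @return A one-row data.frame; rbind several to build a multipeak
#'   initialisation.
#' @export
gaussian_peak <- function(center, sigma, area, label = NA_character_) {
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  if (area < 0) stop("`area` must be >= 0", call. = FALSE)
  data.frame(label = label, center = center, sigma = sigma, area = area,
             stringsAsFactors = FALSE)
}

#' Initial peak guesses from a lane profile
#'
#' Seeds the multipeak fit: centres at the `n` largest local maxima, sigma
#' from half the full-width-at-half-maximum of each candidate
#' (`0.5 * FWHM / 2.355`), area from a local trapezoid around the candidate.
#'
#' @param profile A background-corrected [cge_trace].
#' @param n Number of peaks to seed (1–5).
#' @param labels Optional character vector of labels, recycled to `n`.
#' @return Data.frame of peaks, ordered by centre.
#' @export
initial_peaks <- function(profile, n = 3L, labels = NULL) {
  stopifnot(inherits(profile, "cge_trace"), n >= 1L, n <= 5L)
  tt <- profile$time; ss <- profile$signal
  cand <- which(diff(sign(diff(ss))) < 0) + 1L
  if (!length(cand)) cand <- which.max(ss)
  cand <- cand[order(ss[cand], decreasing = TRUE)]
  cand <- cand[seq_len(min(n, length(cand)))]
  peaks <- lapply(cand, function(i) {
    h <- ss[i]
    half <- h / 2
    left <- i; while (left > 1L && ss[left] > half) left <- left - 1L
    right <- i; while (right < length(ss) && ss[right] > half) right <- right + 1L
    fwhm <- max(tt[right] - tt[left], 2 * min(diff(tt)))
    sigma <- 0.5 * fwhm / 2.355
    lo <- max(1L, which.min(abs(tt - (tt[i] - 2 * sigma))))
    hi <- min(length(tt), which.min(abs(tt - (tt[i] + 2 * sigma))))
    area <- if (hi > lo) max(pracma::trapz(tt[lo:hi], ss[lo:hi]), 0) else
      max(h * sigma * sqrt(2 * pi), 0)
    gaussian_peak(tt[i], sigma, area)
  })
  out <- do.call(rbind, peaks)
  out <- out[order(out$center), , drop = FALSE]
  if (!is.null(labels)) out$label <- rep_len(labels, nrow(out))
  rownames(out) <- NULL
  out
}

#' Multipeak Gaussian deconvolution of a lane profile
#'
#' Fits a sum of Gaussians to an (overlapping) band profile by bounded
#' Levenberg–Marquardt nonlinear least squares, returning per-band centre,
#' width and area. This is how overlapping OC/Lin bands on agarose gels are
#' separated when simple window integration would misassign their shared
#' mass.
#'
#' @param profile A background-corrected [cge_trace] (gel lane profile or
#'   densiogram).
#' @param init Initial peaks: a data.frame as from [initial_peaks()] /
#'   [gaussian_peak()], 1 to 5 rows.
#' @param max_iter Maximum optimizer iterations.
#' @return A `multipeak_fit`: list with `peaks` (data.frame `label`,
#'   `center`, `sigma`, `area`, sorted by centre), `residual_rms` (signal
#'   units) and `converged`. On non-convergence the last iterate is
#'   returned with `converged = FALSE`; such fits should not be used
#'   downstream.
#' @export
fit_multipeak <- function(profile, init, max_iter = 200L) {
  stopifnot(inherits(profile, "cge_trace"), is.data.frame(init))
  k <- nrow(init)
  if (k < 1L || k > 5L) stop("1 to 5 initial peaks required", call. = FALSE)
  if (!is.null(init$label) && !all(is.na(init$label)) &&
      anyDuplicated(stats::na.omit(init$label)))
    stop("peak labels must be unique", call. = FALSE)
  tt <- profile$time; ss <- profile$signal
  par0 <- c(init$center, log(pmax(init$sigma, 1e-8)), init$area)
  unpack <- function(p) list(center = p[1:k],
                             sigma = exp(p[(k + 1):(2 * k)]),
                             area = p[(2 * k + 1):(3 * k)])
  resid_fn <- function(p) {
    q <- unpack(p)
    ss - gaussian_sum(tt, q$center, q$sigma, q$area)
  }
  lower <- c(rep(-Inf, k), rep(log(1e-6 * diff(range(tt))), k), rep(0, k))
  upper <- rep(Inf, 3 * k)
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, maxfev = 200L * (3L * k + 1L)))
  q <- unpack(fit$par)
  peaks <- data.frame(
    label = if (!is.null(init$label)) init$label else rep(NA_character_, k),
    center = q$center, sigma = q$sigma, area = q$area,
    stringsAsFactors = FALSE)
  ord <- order(peaks$center)
  peaks <- peaks[ord, , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(peaks = peaks,
                 residual_rms = sqrt(mean(fit$fvec^2)),
                 converged = fit$info %in% 1:4),
            class = "multipeak_fit")
}

#' @export
print.multipeak_fit <- function(x, ...) {
  cat(sprintf("<multipeak_fit> %d peaks, residual RMS %.4g, %s\n",
              nrow(x$peaks), x$residual_rms,
              if (x$converged) "converged" else "NOT converged"))
  print(x$peaks)
  invisible(x)
}

#' Isoform integrals from a multipeak fit
#'
#' Reassembles fitted band areas into the `(lin, sc, oc)` layout expected by
#' [fractions_from_integrals()], using the peak labels. Unlabelled peaks are
#' an error.
#'
#' @param fit A converged `multipeak_fit` whose peaks carry labels among
#'   `"lin"`, `"sc"`, `"oc"`; missing isoforms get area 0.
#' @return An `isoform_integrals`.
#' @export
multipeak_integrals <- function(fit) {
  stopifnot(inherits(fit, "multipeak_fit"))
  if (!fit$converged)
    stop("multipeak fit did not converge; peaks are unusable", call. = FALSE)
  if (anyNA(fit$peaks$label))
    stop("all fitted peaks must carry an isoform label", call. = FALSE)
  a <- c(lin = 0, sc = 0, oc = 0)
  for (i in seq_len(nrow(fit$peaks))) {
    lbl <- fit$peaks$label[i]
    if (!lbl %in% names(a))
      stop("unknown peak label: ", lbl, call. = FALSE)
    a[[lbl]] <- a[[lbl]] + fit$peaks$area[i]
  }
  structure(list(lin = a[["lin"]], sc = a[["sc"]], oc = a[["oc"]],
                 total = sum(a), clipped = c(lin = FALSE, sc = FALSE,
                                             oc = FALSE)),
            class = "isoform_integrals")
}
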