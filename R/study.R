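#' Aggregate replicate fraction measurements
#'
#' Per-isoform arithmetic mean and sample standard deviation (n − 1
#' denominator) over replicate lanes of the same sample. With a single
#' replicate the standard deviation is undefined and reported as `NA` with
#' `sd_defined = FALSE` — never silently as 0.
#'
#' @param fractions_list List of `isoform_fractions` (or anything with
#'   `f_lin`/`f_sc`/`f_oc` fields), length `>= 1`.
#' @param group_key Named list identifying the group (e.g.
#'   `list(prepared_sc = 0.5)`), stored on the summary.
#' @return A `replicate_summary`: `group_key`, `mean_fractions`
#'   (`isoform_fractions`), `sd_fractions` (named numeric), `n`,
#'   `sd_defined`.
#' @export
aggregate_replicates <- function(fractions_list, group_key = list()) {
  n <- length(fractions_list)
  if (n < 1L) stop("empty replicate list", call. = FALSE)
  m <- vapply(fractions_list,
              function(f) c(f$f_lin, f$f_sc, f$f_oc), numeric(3))
  means <- rowMeans(m)
  sds <- if (n > 1L) apply(m, 1L, stats::sd) else rep(NA_real_, 3L)
  structure(list(
    group_key = group_key,
    mean_fractions = structure(list(f_lin = means[1], f_sc = means[2],
                                    f_oc = means[3]),
                               class = "isoform_fractions"),
    sd_fractions = c(lin = sds[1], sc = sds[2], oc = sds[3]),
    n = n, sd_defined = n > 1L),
    class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf(
    "<replicate_summary> n=%d  f_lin %.4f  f_sc %.4f  f_oc %.4f%s\n",
    x$n, x$mean_fractions$f_lin, x$mean_fractions$f_sc,
    x$mean_fractions$f_oc,
    if (x$sd_defined) sprintf("  (sd %.4f/%.4f/%.4f)", x$sd_fractions[1],
                              x$sd_fractions[2], x$sd_fractions[3])
    else "  (single replicate, sd undefined)"))
  invisible(x)
}

#' Group a quantification table into replicate summaries
#'
#' Convenience bridge from a per-lane `quant_table` to the
#' `replicate_summary` lists consumed by [mixture_linearity()]: lanes are
#' grouped by the value of one annotation column and aggregated with
#' [aggregate_replicates()].
#'
#' @param quant A `quant_table` from [quantify_batch()].
#' @param by Name of the grouping column (default
#'   `"prepared_sc_fraction"`).
#' @param key Name under which the group value is stored in each summary's
#'   `group_key` (default `"prepared_sc"`).
#' @return List of `replicate_summary`, ordered by group value.
#' @export
replicate_summaries <- function(quant, by = "prepared_sc_fraction",
                                key = "prepared_sc") {
  stopifnot(is.data.frame(quant), by %in% names(quant))
  vals <- sort(unique(quant[[by]]))
  lapply(vals, function(v) {
    sub <- quant[quant[[by]] == v, , drop = FALSE]
    fr <- lapply(seq_len(nrow(sub)), function(i)
      structure(list(f_lin = sub$f_lin[i], f_sc = sub$f_sc[i],
                     f_oc = sub$f_oc[i]), class = "isoform_fractions"))
    aggregate_replicates(fr, stats::setNames(list(v), key))
  })
}

#' Mixture-linearity regression
#'
#' Tests linearity of the quantified SC content against the prepared SC
#' content of an SC:OC mixture series. Measured mean SC fractions are
#' normalized to the reference level (the mixture prepared without relaxed
#' plasmid, prepared SC = 1), then regressed on the prepared fractions by
#' unweighted ordinary least squares; an ideal instrument gives slope 1,
#' intercept 0, R-squared 1.
#'
#' @param summaries List of `replicate_summary` objects whose `group_key`
#'   carries `prepared_sc`; at least 3 distinct levels.
#' @param reference_level The prepared SC fraction used for normalization
#'   (default 1.0); its mean SC fraction must be positive.
#' @return A `linearity_result`: `slope`, `intercept`, `r_squared`, and
#'   `points` (data.frame `prepared_sc`, `measured_sc_normalized` the fit
#'   was computed from).
#' @export
mixture_linearity <- function(summaries, reference_level = 1.0) {
  lv <- vapply(summaries, function(s) as.numeric(s$group_key$prepared_sc),
               numeric(1))
  if (anyNA(lv))
    stop("every summary needs a `prepared_sc` group key", call. = FALSE)
  if (length(unique(lv)) < 3L)
    stop("insufficient design: fewer than 3 distinct prepared levels",
         call. = FALSE)
  ref <- which(abs(lv - reference_level) < 1e-9)
  if (!length(ref))
    stop("reference level ", reference_level, " missing", call. = FALSE)
  ref_fsc <- summaries[[ref[1L]]]$mean_fractions$f_sc
  if (!is.finite(ref_fsc) || ref_fsc <= 0)
    stop("reference level has non-positive mean SC fraction", call. = FALSE)
  measured <- vapply(summaries, function(s) s$mean_fractions$f_sc,
                     numeric(1)) / ref_fsc
  pts <- data.frame(prepared_sc = lv, measured_sc_normalized = measured)
  pts <- pts[order(pts$prepared_sc), , drop = FALSE]
  rownames(pts) <- NULL
  fit <- stats::lm(measured_sc_normalized ~ prepared_sc, data = pts)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((pts$measured_sc_normalized -
                   mean(pts$measured_sc_normalized))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = 1 - ss_res / ss_tot,
                 points = pts),
            class = "linearity_result")
}

#' @export
print.linearity_result <- function(x, ...) {
  cat(sprintf(paste0("<linearity_result> measured = %.4f * prepared + %.4f",
                     "  (R^2 = %.4f, %d levels)\n"),
              x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Concentration-series check
#'
#' Verifies that sum-normalized fractions are independent of DNA
#' concentration while the total integrated intensity tracks it: reports
#' the spread (max − min) of the mean SC fraction across concentration
#' levels and the Pearson correlation between concentration and mean total
#' intensity.
#'
#' @param summaries_by_level Either a list of entries
#'   `list(concentration_ng_per_uL =, summary = <replicate_summary>,
#'   total_mean =, total_sd =)`, or a `quant_table` data.frame from
#'   [quantify_batch()] with a `concentration_ng_per_uL` column, which is
#'   grouped and summarized internally. At least 3 levels.
#' @return A `concentration_result`: `levels` (data.frame sorted by
#'   concentration: concentration, mean/sd fractions, n, mean/sd total
#'   intensity), `fraction_range`, `intensity_correlation`.
#' @export
concentration_series <- function(summaries_by_level) {
  if (is.data.frame(summaries_by_level)) {
    q <- summaries_by_level
    if (!"concentration_ng_per_uL" %in% names(q))
      stop("quant table lacks `concentration_ng_per_uL`", call. = FALSE)
    levels <- sort(unique(q$concentration_ng_per_uL))
    summaries_by_level <- lapply(levels, function(cc) {
      sub <- q[q$concentration_ng_per_uL == cc, , drop = FALSE]
      fr <- lapply(seq_len(nrow(sub)), function(i)
        structure(list(f_lin = sub$f_lin[i], f_sc = sub$f_sc[i],
                       f_oc = sub$f_oc[i]), class = "isoform_fractions"))
      list(concentration_ng_per_uL = cc,
           summary = aggregate_replicates(fr, list(concentration = cc)),
           total_mean = mean(sub$total_area),
           total_sd = if (nrow(sub) > 1L) stats::sd(sub$total_area)
                      else NA_real_)
    })
  }
  if (length(summaries_by_level) < 3L)
    stop("insufficient design: fewer than 3 concentration levels",
         call. = FALSE)
  lv <- do.call(rbind, lapply(summaries_by_level, function(e) data.frame(
    concentration_ng_per_uL = e$concentration_ng_per_uL,
    f_lin = e$summary$mean_fractions$f_lin,
    f_sc = e$summary$mean_fractions$f_sc,
    f_oc = e$summary$mean_fractions$f_oc,
    n = e$summary$n,
    total_mean = e$total_mean, total_sd = e$total_sd)))
  lv <- lv[order(lv$concentration_ng_per_uL), , drop = FALSE]
  rownames(lv) <- NULL
  structure(list(
    levels = lv,
    fraction_range = max(lv$f_sc) - min(lv$f_sc),
    intensity_correlation = stats::cor(lv$concentration_ng_per_uL,
                                       lv$total_mean)),
    class = "concentration_result")
}

#' @export
print.concentration_result <- function(x, ...) {
  cat(sprintf(paste0("<concentration_result> %d levels, f_sc range %.4g, ",
                     "intensity-concentration r = %.4f\n"),
              nrow(x$levels), x$fraction_range, x$intensity_correlation))
  invisible(x)
}

#' Digestion time-course tabulation
#'
#' Tabulates the quantified isoform fractions of an enzyme digestion
#' experiment per (incubation time, instrument run) and reports the change
#' in linear fraction between the two sequential runs of the same vials.
#' No kinetic model is fitted — the output is the tabulated time course.
#' Lanes with `NA` incubation time are treated as the no-enzyme blind
#' control and reported separately.
#'
#' @param quant A `quant_table` from [quantify_batch()]; every sample lane
#'   must carry `run_index`, and `incubation_time_min` (NA marks the blind
#'   control).
#' @param times,runs Optional named vectors (by `lane_id`) overriding the
#'   table's annotation columns.
#' @return A `kinetics_result`: `rows` (per-lane fractions sorted by
#'   (time, run)), `deltas` (data.frame `incubation_time_min`,
#'   `delta_f_lin` = mean f_lin(run 2) − mean f_lin(run 1) per time), and
#'   `blind` (the control rows).
#' @export
kinetics_timecourse <- function(quant, times = NULL, runs = NULL) {
  stopifnot(is.data.frame(quant))
  q <- as.data.frame(quant)
  if (!is.null(times)) q$incubation_time_min <- unname(times[q$lane_id])
  if (!is.null(runs)) q$run_index <- unname(runs[q$lane_id])
  if (is.null(q$run_index) || anyNA(q$run_index))
    stop("lanes missing run annotation: ",
         paste(q$lane_id[is.null(q$run_index) | is.na(q$run_index)],
               collapse = ", "), call. = FALSE)
  if (is.null(q$incubation_time_min))
    stop("lanes missing incubation-time annotation: ",
         paste(q$lane_id, collapse = ", "), call. = FALSE)
  blind <- q[is.na(q$incubation_time_min), , drop = FALSE]
  rows <- q[!is.na(q$incubation_time_min), , drop = FALSE]
  rows <- rows[order(rows$incubation_time_min, rows$run_index), ,
               drop = FALSE]
  keep <- c("lane_id", "incubation_time_min", "run_index",
            "f_lin", "f_sc", "f_oc")
  rows <- rows[, keep]
  rownames(rows) <- NULL
  blind <- blind[, keep]
  rownames(blind) <- NULL
  tt <- sort(unique(rows$incubation_time_min))
  deltas <- do.call(rbind, lapply(tt, function(t0) {
    r1 <- rows$f_lin[rows$incubation_time_min == t0 & rows$run_index == 1]
    r2 <- rows$f_lin[rows$incubation_time_min == t0 & rows$run_index == 2]
    if (!length(r1) || !length(r2)) return(NULL)
    data.frame(incubation_time_min = t0,
               delta_f_lin = mean(r2) - mean(r1))
  }))
  if (is.null(deltas))
    deltas <- data.frame(incubation_time_min = numeric(0),
                         delta_f_lin = numeric(0))
  structure(list(rows = rows, deltas = deltas, blind = blind),
            class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf("<kinetics_result> %d timepoint lanes, %d blind lanes\n",
              nrow(x$rows), nrow(x$blind)))
  if (nrow(x$deltas))
    cat(sprintf("  run2 - run1 f_lin deltas: %s\n",
                paste(sprintf("%.3f", x$deltas$delta_f_lin),
                      collapse = ", ")))
  invisible(x)
}
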