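# Run expr with a private RNG stream: the caller's .Random.seed is restored
# afterwards, so simulation is reproducible without clobbering user state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed from a base seed and a string tag (lane or
# capillary id), kept inside 32-bit integer range.
derive_seed <- function(seed, tag) {
  h <- 0
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% 2147483629
  as.integer((abs(seed) + h) %% 2147483629)
}

#' Ground truth for a simulated lane
#'
#' The per-isoform DNA amounts (arbitrary mass units) a synthetic lane is
#' generated from. Blank lanes (all zero) are allowed.
#'
#' @param amount_lin,amount_sc,amount_oc Non-negative DNA amounts.
#' @param concentration_ng_per_uL Optional nominal concentration recorded in
#'   the lane metadata.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(amount_lin = 0, amount_sc = 0, amount_oc = 0,
                         concentration_ng_per_uL = NA_real_) {
  amt <- c(lin = amount_lin, sc = amount_sc, oc = amount_oc)
  if (any(!is.finite(amt)) || any(amt < 0))
    stop("amounts must be finite and >= 0", call. = FALSE)
  structure(list(amount_lin = amount_lin, amount_sc = amount_sc,
                 amount_oc = amount_oc,
                 concentration_ng_per_uL = concentration_ng_per_uL),
            class = "ground_truth")
}

#' True isoform fractions of a ground truth
#' @param truth A [ground_truth] with positive total amount.
#' @return An `isoform_fractions`.
#' @export
true_fractions <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  fractions_from_integrals(c(lin = truth$amount_lin, sc = truth$amount_sc,
                             oc = truth$amount_oc))
}

#' Synthetic densiogram generator configuration
#'
#' Generative model for pUC19-like CGE densiograms: three Gaussian bands
#' (sharp Lin near 400 s, sharp tall SC near 500 s, broad low OC near
#' 750 s) on a linear baseline, with additive Gaussian detector noise,
#' per-capillary migration-time jitter, and optional detector clipping.
#' Band area equals `amount * response`, so at equal amounts the narrow SC
#' band is much taller than the broad OC band, as seen on real
#' densiograms.
#'
#' @param seed Integer seed; all randomness of a simulated batch derives
#'   deterministically from it.
#' @param t_min,t_max,dt Time grid in seconds (default 0–1320 s at 1 s).
#' @param peak_centers Named numeric `c(lin=, sc=, oc=)` band centres (s).
#' @param peak_sigmas Named numeric band standard deviations (s), all `> 0`.
#' @param response Detector response per amount unit per isoform
#'   (signal·s per mass unit); unit responses by default.
#' @param baseline `c(intercept, slope)` of the linear background drift
#'   (signal units, signal units/s).
#' @param noise_sd Additive Gaussian noise standard deviation (signal
#'   units), `>= 0`.
#' @param migration_jitter_sd Standard deviation (s) of the per-capillary
#'   migration-time shift applied to all band centres of that capillary.
#' @param clip_level Optional detector full-scale value; signal is clipped
#'   there when set.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, t_min = 0, t_max = 1320, dt = 1,
                              peak_centers = c(lin = 400, sc = 500, oc = 750),
                              peak_sigmas = c(lin = 5, sc = 8, oc = 30),
                              response = c(lin = 1, sc = 1, oc = 1),
                              baseline = c(intercept = 2, slope = 0.01),
                              noise_sd = 0, migration_jitter_sd = 0,
                              clip_level = NULL) {
  stopifnot(dt > 0, t_max > t_min, all(peak_sigmas > 0), noise_sd >= 0,
            migration_jitter_sd >= 0, all(response > 0))
  for (nm in c("lin", "sc", "oc")) {
    if (!nm %in% names(peak_centers) || !nm %in% names(peak_sigmas) ||
        !nm %in% names(response))
      stop("peak_centers, peak_sigmas and response need entries ",
           "named lin/sc/oc", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), t_min = t_min, t_max = t_max,
                 dt = dt, peak_centers = as.list(peak_centers),
                 peak_sigmas = as.list(peak_sigmas),
                 response = as.list(response),
                 baseline = c(intercept = unname(baseline[1]),
                              slope = unname(baseline[2])),
                 noise_sd = noise_sd,
                 migration_jitter_sd = migration_jitter_sd,
                 clip_level = clip_level),
            class = "simulation_config")
}

# Height of the pure-SC band at a given total mass; used to express noise
# levels as a fraction of the dominant peak.
sc_peak_height <- function(config, total_mass = 1000) {
  total_mass * config$response$sc *
    stats::dnorm(0, 0, config$peak_sigmas$sc)
}

#' Simulate one densiogram lane
#'
#' Generates `signal = sum_i amount_i * response_i * N(center_i + jitter,
#' sigma_i) + baseline + noise`, clipped at `clip_level` when configured.
#' The migration jitter is drawn once per `capillary_id` (lanes sharing a
#' capillary share the shift); noise is drawn per lane. Both derive
#' deterministically from `config$seed`, so the same seed reproduces the
#' lane bit for bit.
#'
#' @param truth A [ground_truth].
#' @param config A [simulation_config].
#' @param lane_id,role,capillary_id Lane identity; see [cge_trace].
#' @param meta Extra metadata merged into the trace.
#' @return List with `trace` (the simulated [cge_trace], metadata includes
#'   `capillary_id`) and `truth` (the input, passed through).
#' @export
simulate_trace <- function(truth, config, lane_id = "L1", role = "sample",
                           capillary_id = "C1", meta = list()) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "simulation_config"))
  tt <- seq(config$t_min, config$t_max, by = config$dt)
  jitter <- if (config$migration_jitter_sd > 0)
    with_seed(derive_seed(config$seed, paste0("cap:", capillary_id)),
              stats::rnorm(1, 0, config$migration_jitter_sd)) else 0
  amt <- c(lin = truth$amount_lin, sc = truth$amount_sc, oc = truth$amount_oc)
  ss <- config$baseline[["intercept"]] + config$baseline[["slope"]] * tt
  for (nm in names(amt)) {
    if (amt[[nm]] == 0) next
    ss <- ss + amt[[nm]] * config$response[[nm]] *
      stats::dnorm(tt, config$peak_centers[[nm]] + jitter,
                   config$peak_sigmas[[nm]])
  }
  if (config$noise_sd > 0)
    ss <- ss + with_seed(derive_seed(config$seed, paste0("lane:", lane_id)),
                         stats::rnorm(length(tt), 0, config$noise_sd))
  if (!is.null(config$clip_level)) ss <- pmin(ss, config$clip_level)
  meta$capillary_id <- capillary_id
  if (is.finite(truth$concentration_ng_per_uL) &&
      is.null(meta$concentration_ng_per_uL))
    meta$concentration_ng_per_uL <- truth$concentration_ng_per_uL
  list(trace = cge_trace(lane_id, tt, ss, role = role, meta = meta),
       truth = truth)
}

#' Simulate an SC:OC mixture dilution series
#'
#' Emulates the linearity experiment: pure supercoiled and pure
#' (enzyme-relaxed) open-circular stocks mixed at given SC mass fractions
#' and run together, plus one pure-buffer lane for background reference.
#' Total DNA mass per lane is constant, so truth amounts are
#' `sc = x * total_mass`, `oc = (1 - x) * total_mass`, `lin = 0`.
#'
#' @param levels Numeric vector of prepared SC mass fractions in `[0, 1]`.
#' @param replicates Replicate lanes per level.
#' @param config A [simulation_config].
#' @param total_mass Total DNA mass per lane (arbitrary units).
#' @param capillaries Number of capillaries lanes are cycled over
#'   (jitter is shared within a capillary).
#' @return A [cge_batch]; sample lanes carry `prepared_sc_fraction` and
#'   `replicate_id` metadata, and the batch has a `truth` attribute
#'   (data.frame of per-lane amounts).
#' @export
simulate_mixture_series <- function(levels, replicates = 3L, config,
                                    total_mass = 1000, capillaries = 12L) {
  stopifnot(all(levels >= 0 & levels <= 1), replicates >= 1L,
            inherits(config, "simulation_config"))
  traces <- list()
  truth_rows <- list()
  i <- 0L
  for (li in seq_along(levels)) {
    x <- levels[li]
    for (r in seq_len(replicates)) {
      i <- i + 1L
      id <- sprintf("mix%02d_r%d", li, r)
      cap <- sprintf("C%d", (i - 1L) %% capillaries + 1L)
      tr <- simulate_trace(
        ground_truth(amount_sc = x * total_mass,
                     amount_oc = (1 - x) * total_mass),
        config, lane_id = id, capillary_id = cap,
        meta = list(prepared_sc_fraction = x, replicate_id = r))
      traces[[id]] <- tr$trace
      truth_rows[[id]] <- data.frame(
        lane_id = id, prepared_sc_fraction = x, replicate_id = r,
        amount_lin = 0, amount_sc = x * total_mass,
        amount_oc = (1 - x) * total_mass, stringsAsFactors = FALSE)
    }
  }
  buf <- simulate_trace(ground_truth(), config, lane_id = "buffer",
                        role = "buffer", capillary_id = "C0")
  traces[["buffer"]] <- buf$trace
  batch <- cge_batch(traces)
  attr(batch, "truth") <- do.call(rbind, c(truth_rows,
                                           make.row.names = FALSE))
  batch
}

#' Simulate a restriction-digest time course
#'
#' Emulates a time-resolved linearization experiment: a pure supercoiled
#' stock exposed to a double-strand-cutting enzyme for `times` minutes, with
#' first-order conversion `f_lin(t) = 1 - exp(-k t)` of the initial SC
#' mass. A blind lane (no enzyme) is included. The second instrument run of
#' the same vials is modelled by converting an additional fraction
#' `run_gap_extra` of each lane's remaining SC mass (continued
#' room-temperature digestion between runs); the blind lane, having no
#' enzyme, never converts, and with `k = 0` no conversion occurs in either
#' run.
#'
#' @param k First-order rate constant (per minute), `>= 0`.
#' @param times Numeric vector of incubation times (minutes), `>= 0`.
#' @param run_gap_extra Fraction in `[0, 1)` of remaining SC converted
#'   between run 1 and run 2 (only when `k > 0`).
#' @param config A [simulation_config].
#' @param total_mass Initial SC mass per lane.
#' @param include_blind Include the no-enzyme control lane in both runs.
#' @return A [cge_batch]; sample lanes carry `incubation_time_min` (`NA` for
#'   the blind lane), `run_index` and a `truth` attribute with the per-lane
#'   true amounts.
#' @export
simulate_digestion_series <- function(k, times, run_gap_extra = 0, config,
                                      total_mass = 1000,
                                      include_blind = TRUE) {
  stopifnot(k >= 0, all(times >= 0), run_gap_extra >= 0, run_gap_extra < 1,
            inherits(config, "simulation_config"))
  extra <- if (k > 0) run_gap_extra else 0
  traces <- list()
  truth_rows <- list()
  add_lane <- function(id, t_min, run, flin) {
    sc <- total_mass * (1 - flin)
    lin <- total_mass * flin
    tr <- simulate_trace(
      ground_truth(amount_lin = lin, amount_sc = sc), config,
      lane_id = id, capillary_id = id,
      meta = list(incubation_time_min = t_min, run_index = run))
    traces[[id]] <<- tr$trace
    truth_rows[[id]] <<- data.frame(
      lane_id = id, incubation_time_min = t_min, run_index = run,
      amount_lin = lin, amount_sc = sc, amount_oc = 0,
      stringsAsFactors = FALSE)
  }
  for (run in 1:2) {
    if (include_blind)
      add_lane(sprintf("blind_run%d", run), NA_real_, run, 0)
    for (ti in seq_along(times)) {
      t_min <- times[ti]
      f1 <- 1 - exp(-k * t_min)
      flin <- if (run == 1L) f1 else f1 + extra * (1 - f1)
      add_lane(sprintf("t%02d_run%d", ti, run), t_min, run, flin)
    }
  }
  batch <- cge_batch(traces)
  attr(batch, "truth") <- do.call(rbind, c(truth_rows,
                                           make.row.names = FALSE))
  batch
}

#' Simulate an agarose-gel lane intensity profile
#'
#' Produces a 1-D gel lane profile in position units with Gaussian bands
#' for the SC, Lin and OC isoforms. With `overlap = TRUE` the OC band is
#' placed only 1.5 band-sigmas after the Lin band, reproducing the partial
#' OC/Lin overlap that defeats naive window integration and motivates
#' Gaussian multipeak deconvolution. The SC band intensity is multiplied by
#' the dye attachment efficiency (1.05), so the dye-corrected pipeline
#' recovers the true amounts.
#'
#' @param truth A [ground_truth].
#' @param config A [simulation_config] (supplies `seed` and `noise_sd`;
#'   band geometry on the gel is set by the arguments below).
#' @param overlap Place the OC band 1.5 sigma after Lin (`TRUE`) or well
#'   separated (`FALSE`).
#' @param band_sigma Gaussian band width in position units.
#' @param centers Named `c(sc=, lin=)` band positions; OC is derived.
#' @param sc_efficiency Dye attachment efficiency of SC relative to OC/Lin.
#' @param grid Position grid.
#' @param lane_id Lane identifier.
#' @return A [cge_trace] over gel position, with the band `centers` actually
#'   used stored in its `meta` and the truth as attribute `"truth"`.
#' @export
simulate_age_profile <- function(truth, config, overlap = FALSE,
                                 band_sigma = 8,
                                 centers = c(sc = 30, lin = 60),
                                 sc_efficiency = 1.05,
                                 grid = seq(0, 140, by = 0.25),
                                 lane_id = "gel1") {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "simulation_config"))
  oc_center <- centers[["lin"]] +
    (if (overlap) 1.5 else 5) * band_sigma
  pos <- grid
  ss <- numeric(length(pos))
  amt <- c(sc = truth$amount_sc * sc_efficiency, lin = truth$amount_lin,
           oc = truth$amount_oc)
  ctr <- c(sc = centers[["sc"]], lin = centers[["lin"]], oc = oc_center)
  for (nm in names(amt)) {
    if (amt[[nm]] == 0) next
    ss <- ss + amt[[nm]] * stats::dnorm(pos, ctr[[nm]], band_sigma)
  }
  if (config$noise_sd > 0)
    ss <- ss + with_seed(derive_seed(config$seed, paste0("gel:", lane_id)),
                         stats::rnorm(length(pos), 0, config$noise_sd))
  tr <- cge_trace(lane_id, pos, ss, role = "sample",
                  meta = list(band_centers = ctr, band_sigma = band_sigma,
                              sc_efficiency = sc_efficiency))
  attr(tr, "truth") <- truth
  tr
}
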