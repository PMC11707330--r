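test_that("linear baseline fit recovers drift outside the peak windows", {
  w <- default_windows()
  # flat zero signal
  flat <- fun_trace(function(t) 0 * t)
  m0 <- fit_linear_baseline(flat, w)
  expect_equal(m0$intercept, 0)
  expect_equal(m0$slope, 0)
  # pure drift with the isoform windows excluded: closed-form least squares
  drift <- fun_trace(function(t) 2 + 0.01 * t)
  m <- fit_linear_baseline(drift, w)
  expect_equal(m$intercept, 2, tolerance = 1e-9)
  expect_equal(m$slope, 0.01, tolerance = 1e-9)
  # exclusion covering the whole trace
  expect_error(fit_linear_baseline(drift, list(c(-1, 1001))),
               "insufficient baseline")
})

test_that("background correction removes the modelled component exactly", {
  w <- default_windows()
  peak <- function(t) gauss(t, 500, 8, 1000)
  tr <- fun_trace(function(t) peak(t) + 2 + 0.01 * t)
  m <- fit_linear_baseline(tr, w)
  corrected <- correct_background(tr, m)
  expect_equal(corrected$signal, peak(tr$time), tolerance = 1e-9)
  # original untouched, metadata preserved
  expect_equal(tr$signal, peak(tr$time) + 2 + 0.01 * tr$time)
  # buffer mode: a trace minus itself is identically zero
  self <- correct_background(tr, buffer_baseline(tr), buffer = tr)
  expect_true(all(self$signal == 0))
  # idempotence: refitting on corrected data finds nearly no background left
  m2 <- fit_linear_baseline(corrected, w)
  expect_lt(abs(m2$slope), 1e-12)
  twice <- correct_background(corrected, m2)
  expect_equal(twice$signal, corrected$signal, tolerance = 1e-9)
})

test_that("background correction is linear in the signal", {
  w <- default_windows()
  a <- fun_trace(function(t) gauss(t, 500, 8, 500) + 1 + 0.005 * t)
  b_sig <- function(t) gauss(t, 750, 30, 300)
  ab <- fun_trace(function(t) gauss(t, 500, 8, 500) + 1 + 0.005 * t + b_sig(t))
  m <- fit_linear_baseline(a, w)
  expect_equal(correct_background(ab, m)$signal,
               correct_background(a, m)$signal + b_sig(a$time),
               tolerance = 1e-12)
})

test_that("buffer resampling interpolates; disjoint grids are an error", {
  tr <- fun_trace(function(t) 5 + 0 * t, from = 0, to = 100, by = 1)
  buf <- fun_trace(function(t) 0 * t + 2, from = 0, to = 100, by = 2.5,
                   lane_id = "buf", role = "buffer")
  out <- correct_background(tr, buffer_baseline(buf), buffer = buf)
  expect_equal(out$signal, rep(3, length(tr$time)))
  far <- fun_trace(function(t) 0 * t, from = 5000, to = 5100, by = 1,
                   lane_id = "far", role = "buffer")
  expect_error(correct_background(tr, buffer_baseline(far), buffer = far),
               "alignment error")
})

test_that("SNR uses a robust noise scale and handles zero noise", {
  w <- default_windows()
  clean <- fun_trace(function(t) gauss(t, 500, 8, 1000))
  snr0 <- estimate_snr(clean, w)
  expect_identical(snr0[["sc"]], Inf)
  # known sigma: peak height 100 over N(0, 1) noise
  tt <- seq(0, 1320, by = 1)
  set.seed(42)
  noisy <- cge_trace("n", tt, 100 * exp(-(tt - 500)^2 / (2 * 64)) +
                              rnorm(length(tt)))
  snr <- estimate_snr(noisy, w)
  expect_gt(snr[["sc"]], 80)
  expect_lt(snr[["sc"]], 120)
  # SNR is invariant under positive rescaling of the whole trace
  scaled <- cge_trace("s", tt, 7.3 * noisy$signal)
  expect_equal(estimate_snr(scaled, w), snr, tolerance = 1e-12)
  # windows covering every grid point leave nothing to estimate noise from
  expect_error(estimate_snr(clean, isoform_windows(c(0, 300), c(300.5, 600),
                                                   c(600.5, 1000))),
               "noise estimation")
})

test_that("pure-noise lanes almost never reach SNR 5", {
  w <- default_windows()
  tt <- seq(0, 1320, by = 1)   # > 1000 samples outside the windows
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    tr <- cge_trace("n", tt, rnorm(length(tt)))
    max(estimate_snr(tr, w)) < 5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("saturation detection needs a sustained plateau", {
  tt <- 0:100
  below <- cge_trace("a", tt, rep(9, 101))
  expect_false(detect_saturation(below, level = 10))
  plateau <- cge_trace("b", tt, c(rep(0, 50), rep(10, 5), rep(0, 46)))
  expect_true(detect_saturation(plateau, level = 10, min_run = 5))
  expect_false(detect_saturation(plateau, level = 10, min_run = 6))
  # clipped simulated SC peak (amplitude 2x level) vs unclipped half-amplitude
  cfg <- simulation_config(seed = 3, baseline = c(intercept = 0, slope = 0))
  level <- plasmidcge:::sc_peak_height(cfg, 1000) / 2
  cfg_clip <- simulation_config(seed = 3, clip_level = level,
                                baseline = c(intercept = 0, slope = 0))
  clipped <- simulate_trace(ground_truth(amount_sc = 1000), cfg_clip)$trace
  expect_true(detect_saturation(clipped, level = level, min_run = 5))
  small <- simulate_trace(ground_truth(amount_sc = 250), cfg)$trace
  expect_false(detect_saturation(small, level = level, min_run = 5))
})

test_that("QC includes clean lanes and excludes noisy or clipped ones", {
  w <- default_windows()
  cfg_ok <- simulation_config(seed = 11, noise_sd = 0.05)
  cfg_noisy <- simulation_config(seed = 11, noise_sd = 1.5)  # evaporated-sample regime
  # all three isoforms present: inclusion demands adequate SNR in every window
  truth <- ground_truth(amount_lin = 300, amount_sc = 500, amount_oc = 500)
  good <- simulate_trace(truth, cfg_ok, lane_id = "good")$trace
  noisy <- simulate_trace(truth, cfg_noisy, lane_id = "noisy")$trace
  # instrument full scale: above the clean lanes' peaks, below the overloaded one
  level <- 40
  cfg_clip <- simulation_config(seed = 11, noise_sd = 0.05, clip_level = level)
  sat_raw <- simulate_trace(ground_truth(amount_lin = 300, amount_sc = 2000,
                                         amount_oc = 500),
                            cfg_clip, lane_id = "sat")$trace
  buf <- simulate_trace(ground_truth(), cfg_ok, lane_id = "buf",
                        role = "buffer")$trace
  raw <- cge_batch(list(good, noisy, sat_raw, buf))
  corrected <- cge_batch(lapply(raw$traces, function(tr)
    correct_background(tr, fit_linear_baseline(tr, w))))
  res <- qc_filter(corrected, w, min_snr = 10, level = level, min_run = 5,
                   raw_batch = raw)
  rep <- res$reports
  expect_setequal(rep$lane_id, c("good", "noisy", "sat"))
  expect_true(rep$included[rep$lane_id == "good"])
  expect_identical(rep$reasons[rep$lane_id == "good"], "")
  expect_false(rep$included[rep$lane_id == "noisy"])
  expect_match(rep$reasons[rep$lane_id == "noisy"], "snr")
  expect_false(rep$included[rep$lane_id == "sat"])
  expect_match(rep$reasons[rep$lane_id == "sat"], "saturation")
  # buffer lane passes through, and kept signals are untouched
  expect_true("buf" %in% lane_ids(res$batch))
  expect_identical(get_trace(res$batch, "good")$signal,
                   get_trace(corrected, "good")$signal)
  expect_false(any(rep$included & nzchar(rep$reasons)))
})
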