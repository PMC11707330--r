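test_that("a blank lane is exactly the configured baseline", {
  cfg <- simulation_config(seed = 1, baseline = c(intercept = 2, slope = 0.01))
  tr <- simulate_trace(ground_truth(), cfg)$trace
  expect_equal(tr$signal, 2 + 0.01 * tr$time)
})

test_that("band area equals amount times response", {
  cfg <- simulation_config(seed = 1, baseline = c(intercept = 0, slope = 0))
  A <- 640
  tr <- simulate_trace(ground_truth(amount_sc = A), cfg)$trace
  ints <- integrate_windows(tr, default_windows())
  expect_equal(ints$sc, A * cfg$response$sc, tolerance = 1e-3)
  expect_equal(ints$lin + ints$oc, 0, tolerance = 1e-6 * A)
})

test_that("band morphology: SC is tall and narrow, OC low and broad", {
  cfg <- simulation_config(seed = 1, baseline = c(intercept = 0, slope = 0))
  sc <- simulate_trace(ground_truth(amount_sc = 500), cfg)$trace
  oc <- simulate_trace(ground_truth(amount_oc = 500), cfg)$trace
  expect_gt(max(sc$signal), max(oc$signal))
  expect_lt(cfg$peak_sigmas$sc, cfg$peak_sigmas$oc)
})

test_that("noiseless pipeline round trip recovers any truth to 1e-6", {
  cfg <- simulation_config(seed = 8)
  w <- matched_windows(cfg)
  set.seed(17)
  for (i in 1:8) {
    amt <- runif(3, 0, 1000)
    if (sum(amt) < 1) amt <- amt + 1
    st <- simulate_trace(ground_truth(amt[1], amt[2], amt[3]), cfg)
    corr <- correct_background(st$trace, fit_linear_baseline(st$trace, w))
    got <- fractions_vec(fractions_from_integrals(integrate_windows(corr, w)))
    expect_equal(got, fractions_vec(true_fractions(st$truth)),
                 tolerance = 1e-6)
  }
})

test_that("the same seed reproduces a batch bit for bit", {
  cfg <- simulation_config(seed = 99, noise_sd = 0.4,
                           migration_jitter_sd = 2)
  b1 <- simulate_mixture_series(c(0, 0.5, 1), 2, cfg)
  b2 <- simulate_mixture_series(c(0, 0.5, 1), 2, cfg)
  expect_identical(b1, b2)
  b3 <- simulate_mixture_series(c(0, 0.5, 1), 2,
                                simulation_config(seed = 100, noise_sd = 0.4,
                                                  migration_jitter_sd = 2))
  expect_false(identical(b1, b3))
})

test_that("jitter is shared within a capillary and noise is not", {
  cfg <- simulation_config(seed = 5, noise_sd = 0, migration_jitter_sd = 3)
  truth <- ground_truth(amount_sc = 500)
  a <- simulate_trace(truth, cfg, lane_id = "a", capillary_id = "C1")$trace
  b <- simulate_trace(truth, cfg, lane_id = "b", capillary_id = "C1")$trace
  c2 <- simulate_trace(truth, cfg, lane_id = "c", capillary_id = "C2")$trace
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, c2$signal))
})

test_that("mixture series has the designed lane layout and truths", {
  cfg <- simulation_config(seed = 12)
  batch <- simulate_mixture_series(seq(0, 1, by = 0.1), 3, cfg)
  roles <- vapply(batch$traces, function(tr) tr$role, character(1))
  expect_equal(sum(roles == "sample"), 33L)
  expect_equal(sum(roles == "buffer"), 1L)
  expect_length(batch, 34L)
  truth <- attr(batch, "truth")
  expect_equal(nrow(truth), 33L)
  # equal-mass Mix lane: SC:OC truth ratio exactly 1
  half <- truth[truth$prepared_sc_fraction == 0.5, ]
  expect_equal(half$amount_sc / half$amount_oc, rep(1, nrow(half)))
  # pure SC level quantifies to f_sc = 1
  q <- quantify_batch(batch, windows = matched_windows(cfg))
  pure <- q[q$prepared_sc_fraction == 1, ]
  expect_equal(pure$f_sc, rep(1, nrow(pure)), tolerance = 1e-6)
})

test_that("digestion series follows first-order conversion of the SC stock", {
  cfg <- simulation_config(seed = 13)
  # no enzyme: every lane equals the blind control
  b0 <- simulate_digestion_series(0, c(0, 5, 10), run_gap_extra = 0.3,
                                  config = cfg)
  blind <- get_trace(b0, "blind_run1")$signal
  for (id in lane_ids(b0))
    expect_equal(get_trace(b0, id)$signal, blind)
  # long-time limit converts everything
  b_inf <- simulate_digestion_series(0.1, c(0, 1e6), config = cfg)
  truth <- attr(b_inf, "truth")
  last <- truth[!is.na(truth$incubation_time_min) &
                  truth$incubation_time_min == 1e6 & truth$run_index == 1, ]
  expect_equal(last$amount_lin / (last$amount_lin + last$amount_sc), 1,
               tolerance = 1e-12)
  # between-run conversion strictly increases f_lin wherever SC remains
  b2 <- simulate_digestion_series(0.1, c(0, 6, 12), run_gap_extra = 0.15,
                                  config = cfg)
  tr2 <- attr(b2, "truth")
  tr2 <- tr2[!is.na(tr2$incubation_time_min), ]
  for (t0 in c(0, 6, 12)) {
    r1 <- tr2[tr2$incubation_time_min == t0 & tr2$run_index == 1, ]
    r2 <- tr2[tr2$incubation_time_min == t0 & tr2$run_index == 2, ]
    expect_gt(r2$amount_lin, r1$amount_lin)
  }
})

test_that("total intensity is affine in the loaded DNA amount", {
  cfg <- simulation_config(seed = 14)
  total_of <- function(M) {
    tr <- simulate_trace(ground_truth(amount_sc = M), cfg)$trace
    pracma::trapz(tr$time, tr$signal)
  }
  t0 <- total_of(0); t1 <- total_of(500); t2 <- total_of(1000)
  expect_equal(t2 - t1, t1 - t0, tolerance = 1e-6)
  expect_equal((t1 - t0) / 500, cfg$response$sc, tolerance = 1e-3)
  # intercept is the baseline area
  tt <- seq(cfg$t_min, cfg$t_max, by = cfg$dt)
  expect_equal(t0, pracma::trapz(tt, 2 + 0.01 * tt), tolerance = 1e-9)
})

test_that("gel profiles reproduce the OC/Lin overlap problem", {
  cfg <- simulation_config(seed = 15)
  # zero truth: flat profile
  flat <- simulate_age_profile(ground_truth(), cfg)
  expect_true(all(flat$signal == 0))
  # overlapping bands: window integration misassigns, deconvolution does not
  truth <- ground_truth(amount_lin = 1, amount_oc = 2)
  tr <- simulate_age_profile(truth, cfg, overlap = TRUE)
  ctr <- tr$meta$band_centers
  split <- (ctr[["lin"]] + ctr[["oc"]]) / 2
  w <- isoform_windows(lin = c(ctr[["lin"]] - 20, split),
                       sc = c(0.5, 5),
                       oc = c(split, ctr[["oc"]] + 20))
  naive <- integrate_windows(tr, w)
  # at 1.5 sigma separation the bands swap > 5 % of their mass at the split
  expect_gt(abs(naive$lin - 1), 0.05)
  init <- rbind(gaussian_peak(ctr[["lin"]] - 1, 7, 0.8, "lin"),
                gaussian_peak(ctr[["oc"]] + 1, 7, 1.6, "oc"))
  fit <- fit_multipeak(tr, init)
  expect_true(fit$converged)
  got <- setNames(fit$peaks$area, fit$peaks$label)
  expect_lt(abs(got[["lin"]] - 1), 0.02)
  expect_lt(abs(got[["oc"]] - 2) / 2, 0.02)
})
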