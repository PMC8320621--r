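mk_trace <- function(duration = 60, flux = 0, noise_sd = 0, seed = NULL,
                     a = 0.25, d50 = 100) {
  simulate_trace(cycling_protocol(duration = duration, relative_amplitude = a),
                 film_params(deposition_flux = flux, noise_sd = noise_sd,
                             seed = seed, d50 = d50))
}

test_that("segmentation finds every cycle of a clean sinusoid", {
  tr <- mk_trace(60)
  rng <- segment_cycles(tr)
  expect_equal(nrow(rng), 20)
  expect_true(all(rng$end[-nrow(rng)] == rng$start[-1]))  # contiguous
})

test_that("segmentation is robust to small area jitter", {
  tr <- mk_trace(60)
  set.seed(11)
  jit <- tr
  jit$area_mm2 <- jit$area_mm2 + rnorm(nrow(jit), 0, 0.001 * 18)
  expect_equal(nrow(segment_cycles(jit)), nrow(segment_cycles(tr)))
})

test_that("segmentation rejects a constant-area trace", {
  tr <- data.frame(time_s = seq(0, 10, 0.1), gamma_mN_per_m = 20,
                   area_mm2 = 18)
  expect_error(segment_cycles(tr), class = "segmentation_error")
})

test_that("per-cycle minima equal an exhaustive scan over the cycle samples", {
  tr <- mk_trace(60, flux = 30, noise_sd = 0.3, seed = 5)
  rng <- segment_cycles(tr)
  smry <- summarize_cycles(tr, rng)
  for (i in seq_len(nrow(rng))) {
    idx <- rng$start[i]:(rng$end[i] - 1)
    expect_identical(smry$min_surface_tension[i],
                     min(tr$gamma_mN_per_m[idx]))
    expect_identical(smry$max_area[i], max(tr$area_mm2[idx]))
  }
  expect_error(summarize_cycles(tr, data.frame(cycle = 1, start = 5, end = 6)),
               class = "empty_range_error")
})

test_that("baseline QC applies strict thresholds", {
  mk_sum <- function(minima, comps) {
    data.frame(cycle = seq_along(minima), min_surface_tension = minima,
               time_at_min_s = NA, area_at_min = NA,
               max_area = 18, min_area = 18 * (1 - comps),
               compression_ratio = comps)
  }
  crit <- assay_criteria(n_baseline_cycles = 3)
  ok <- qc_baseline(mk_sum(c(1.5, 2.0, 1.8), c(0.25, 0.24, 0.26)), crit)
  expect_true(ok$passed)
  expect_length(ok$reasons, 0)
  # values exactly at a threshold fail ("below" is strict)
  at_st <- qc_baseline(mk_sum(c(5.0, 5.2, 6.0), c(0.25, 0.25, 0.25)), crit)
  expect_false(at_st$passed)
  expect_true("baseline_min_st_not_below_limit" %in% at_st$reasons)
  at_comp <- qc_baseline(mk_sum(c(2, 2, 2), c(0.30, 0.30, 0.30)), crit)
  expect_false(at_comp$passed)
  expect_true("compression_not_below_limit" %in% at_comp$reasons)
  # just below both thresholds passes
  near <- qc_baseline(mk_sum(c(4.999, 4.999, 4.999), c(0.299, 0.299, 0.299)),
                      crit)
  expect_true(near$passed)
  expect_error(qc_baseline(mk_sum(2, 0.25), crit),
               class = "insufficient_baseline_error")
})

test_that("inhibition detection follows the consecutive-minima rule", {
  expect_false(detect_inhibition(c(2, 3, 2, 4, 3))$inhibited)
  call <- detect_inhibition(c(3, 11, 12, 10.5, 4))
  expect_true(call$inhibited)
  expect_equal(call$onset_cycle, 2L)
  # two runs of length 2 do not qualify
  expect_false(detect_inhibition(c(3, 11, 12, 4, 10, 11))$inhibited)
  # the threshold is inclusive
  call10 <- detect_inhibition(c(10.0, 10.0, 10.0))
  expect_true(call10$inhibited)
  expect_equal(call10$onset_cycle, 1L)
  expect_error(detect_inhibition(c(11, 12)), class = "insufficient_data_error")
})

test_that("detector matches the brute-force window scan on random series", {
  set.seed(2024)
  for (i in 1:2000) {
    minima <- random_minima_series(sample(3:25, 1))
    got <- detect_inhibition(minima)
    want <- brute_force_inhibition(minima)
    expect_identical(got$inhibited, want$inhibited)
    if (want$inhibited) expect_identical(got$onset_cycle, as.integer(want$onset))
  }
})

test_that("replicate aggregation uses the majority rule and flags discordance", {
  expect_true(classify_chemical(c(TRUE, TRUE, TRUE))$inhibitory)
  expect_false(classify_chemical(c(FALSE, FALSE, FALSE, FALSE))$inhibitory)
  tie <- classify_chemical(c(TRUE, FALSE, TRUE, FALSE))
  expect_true(tie$inhibitory)   # >= 0.5 rule
  expect_true(tie$discordant)
  expect_equal(tie$fraction_inhibited, 0.5)
  expect_error(classify_chemical(logical(0)), class = "no_call_error")
  expect_warning(classify_chemical(c(TRUE, TRUE)), "replicates")
})

test_that("inhibitory dose arithmetic and volatility handling", {
  call <- structure(list(inhibited = TRUE, onset_cycle = 5L,
                         onset_time_s = 300), class = "inhibition_call")
  est <- estimate_inhibitory_dose(10, call, mean_drop_area = 50)
  expect_equal(est$dose_per_area_ng_cm2, 50)   # 10 ng/cm2/min x 5 min
  expect_equal(est$total_mass_ng, 25)          # 50 ng/cm2 x 0.50 cm2
  vol <- estimate_inhibitory_dose(10, call, 50, volatile = TRUE)
  expect_false(vol$estimable)
  expect_match(vol$reason, "volatile")
  no_call <- structure(list(inhibited = FALSE), class = "inhibition_call")
  expect_error(estimate_inhibitory_dose(10, no_call, 50),
               class = "no_dose_error")
})

test_that("uninhibited noisy traces are never called inhibited", {
  for (s in 1:8) {
    res <- analyze_trace(mk_trace(60, flux = 0, noise_sd = 0.3, seed = s))
    expect_true(res$qc$passed)
    expect_false(res$call$inhibited)
  }
})

test_that("saturating doses are always detected with onset near the analytic crossing", {
  film <- film_params(deposition_flux = 50, d50 = 50, noise_sd = 0)
  tr <- simulate_trace(cycling_protocol(duration = 120), film)
  res <- analyze_trace(tr)
  expect_true(res$call$inhibited)
  t_cross <- floor_crossing_time(film)   # analytic floor = 10 crossing, s
  expect_lte(abs(res$call$onset_time_s - t_cross), 3)  # one cycle duration
  est <- estimate_inhibitory_dose(50, res$call, 15)
  expect_lte(abs(est$dose_per_area_ng_cm2 - 50 * t_cross / 60), 50 * 3 / 60)
})

test_that("assay_chemical aggregates QC-passing replicates", {
  traces <- lapply(1:4, function(s) mk_trace(90, flux = 50, d50 = 50,
                                             noise_sd = 0.3, seed = s))
  out <- assay_chemical(traces)
  expect_equal(out$n_qc_passed, 4)
  expect_true(out$call$inhibitory)
})
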