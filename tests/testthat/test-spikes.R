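test_that("binning contract: counts, units, and edge handling", {
  cfg <- wt_cfg(duration_h = 600 / 3600, n_electrodes = 2)
  rates <- bin_spikes(gen_spike_trains(cfg), 0.1)
  expect_equal(nrow(rates), 2 * 6000)

  # 4 spikes inside one 100-ms bin -> 40 Hz
  tr <- tibble::tibble(electrode = 1L, time_s = c(0.31, 0.33, 0.36, 0.39))
  attr(tr, "duration_s") <- 1
  r <- bin_spikes(tr, 0.1)
  expect_equal(r$rate_hz[4], 40)
  expect_equal(sum(r$rate_hz > 0), 1)

  # no spikes -> all-zero series, still full length
  tr0 <- tibble::tibble(electrode = integer(), time_s = numeric())
  attr(tr0, "duration_s") <- 10
  attr(tr0, "scn_mask") <- 1L
  expect_equal(bin_spikes(tr0, 1)$rate_hz, rep(0, 10))

  # trailing partial bin dropped
  tr1 <- tibble::tibble(electrode = 1L, time_s = c(0.05, 1.45))
  attr(tr1, "duration_s") <- 1.5
  expect_equal(nrow(bin_spikes(tr1, 1)), 1)

  expect_error(bin_spikes(tr, 0))
})

test_that("bin-ratio distribution sums to 100% and flags supra-threshold bins", {
  set.seed(42)
  for (i in 1:5) {
    rates <- rates_from_vector(rpois(2000, 2) * 10)
    brd <- bin_ratio_distribution(rates)
    expect_equal(sum(tidy(brd)$pct), 100, tolerance = 1e-10)
    expect_equal(brd$frac_above_pct,
                 100 * mean(rates$rate_hz > 35))
  }

  # all-zero series: everything in the lowest class, nothing above 35 Hz
  brd0 <- bin_ratio_distribution(rates_from_vector(rep(0, 500)))
  expect_equal(tidy(brd0)$pct[1], 100)
  expect_equal(brd0$frac_above_pct, 0)

  expect_error(bin_ratio_distribution(rates_from_vector(rep(0, 500)),
                                      window = c(0, 0.05)))
})

test_that("burst detector agrees with a brute-force oracle on random series", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(50:1000, 1)
    x <- pmax(0, rnorm(n, mean = 20, sd = 15))
    gap <- sample(c(0, 0.3, 0.5, 1), 1)
    rates <- rates_from_vector(x)
    cat <- detect_bursts(rates, threshold_hz = 35, merge_gap_s = gap)
    ora <- oracle_bursts(x, 0.1, 35, gap)
    expect_equal(cat$events$start_s, ora$start_s)
    expect_equal(cat$events$end_s, ora$end_s)
    # single electrode: merged catalog must match too
    expect_equal(cat$merged_events$start_s, ora$start_s)
  }
})

test_that("burst detection examples and peak rates", {
  expect_equal(nrow(detect_bursts(rates_from_vector(rep(10, 600)))$events), 0)

  x <- rep(5, 100)
  x[11:15] <- 50; x[41:43] <- 60; x[80] <- 90
  cat <- detect_bursts(rates_from_vector(x), merge_gap_s = 0.5)
  expect_equal(nrow(cat$events), 3)
  expect_equal(cat$events$peak_rate_hz, c(50, 60, 90))
  expect_error(detect_bursts(rates_from_vector(x), threshold_hz = 0))

  # generator schedule: 5 events every 120 s in 600 s, synchronized merge
  cfg <- ko_cfg(duration_h = 600 / 3600, burst_interval_s = c(120, 120),
                n_electrodes = 2)
  rates <- bin_spikes(gen_spike_trains(cfg), 0.1)
  cat2 <- detect_bursts(rates)
  expect_equal(nrow(cat2$merged_events), 5)
  expect_equal(diff(cat2$merged_events$start_s), rep(120, 4))
  expect_equal(glance(cat2)$median_interval_s, 120)
})

test_that("band decomposition separates burst and non-burst minutes", {
  # hand-built: minutes at 5 Hz except minute 4 at 50 Hz, covered by an event
  x60 <- rep(5, 10); x60[4] <- 50
  rates60 <- rates_from_vector(x60, bin_width_s = 60)
  cat <- detect_bursts(rates_from_vector(c(rep(0, 1850), rep(40, 20),
                                           rep(0, 4130))))
  bands <- band_decomposition(rates60, cat)
  expect_equal(bands$mean_burst_band_hz, 50)
  expect_equal(bands$mean_nonburst_band_hz, 5)
  expect_equal(bands$band_gap_hz, 45)

  # wild type: no events, burst band absent (NA, not zero)
  cfg <- wt_cfg(duration_h = 0.5, n_electrodes = 1)
  tr <- gen_spike_trains(cfg)
  bands_wt <- band_decomposition(bin_spikes(tr, 60), detect_bursts(bin_spikes(tr, 0.1)))
  expect_true(is.na(bands_wt$mean_burst_band_hz))
  expect_true(is.na(bands_wt$band_gap_hz))
})

test_that("the band gap is stable from day to day in a stationary burst regime", {
  cfg <- ko_cfg(duration_h = 72, n_electrodes = 1, seed = 5)
  tr <- gen_spike_trains(cfg)
  bands <- band_decomposition(bin_spikes(tr, 60), detect_bursts(bin_spikes(tr, 0.1)))
  expect_equal(nrow(bands), 3)
  rel_spread <- diff(range(bands$band_gap_hz)) / mean(bands$band_gap_hz)
  expect_lt(rel_spread, 0.15)
})

test_that("synchrony matrix: identical, independent, and degenerate series", {
  x <- rpois(600, 5) * 10
  rates <- dplyr::bind_rows(rates_from_vector(x, electrode = 1L),
                            rates_from_vector(x, electrode = 2L),
                            rates_from_vector(x, electrode = 3L))
  attr(rates, "bin_width_s") <- 0.1
  sm <- synchrony_matrix(rates)
  expect_equal(unname(sm$cor), matrix(1, 3, 3))
  expect_equal(sm$mean_offdiag, 1)

  # independent wild-type trains: mean off-diagonal near zero
  md <- vapply(1:20, function(s) {
    cfg <- wt_cfg(duration_h = 600 / 3600, n_electrodes = 4, seed = s)
    synchrony_matrix(bin_spikes(gen_spike_trains(cfg), 0.1))$mean_offdiag
  }, numeric(1))
  expect_lt(abs(mean(md)), 3 / sqrt(6000))

  # zero-variance electrode flagged undefined and excluded from the mean
  rates2 <- dplyr::bind_rows(rates_from_vector(x, electrode = 1L),
                             rates_from_vector(x + rnorm(600), electrode = 2L),
                             rates_from_vector(rep(0, 600), electrode = 3L))
  attr(rates2, "bin_width_s") <- 0.1
  sm2 <- synchrony_matrix(rates2)
  expect_true(is.na(sm2$cor[1, 3]))
  expect_false(is.na(sm2$mean_offdiag))
  expect_error(synchrony_matrix(rates_from_vector(x)))
})

test_that("burst-rich slices are more synchronous than wild type", {
  cfgk <- ko_cfg(duration_h = 600 / 3600, n_electrodes = 4, seed = 21)
  cfgw <- wt_cfg(duration_h = 600 / 3600, n_electrodes = 4, seed = 21)
  mk <- synchrony_matrix(bin_spikes(gen_spike_trains(cfgk), 0.1))$mean_offdiag
  mw <- synchrony_matrix(bin_spikes(gen_spike_trains(cfgw), 0.1))$mean_offdiag
  expect_gt(mk, mw)
  expect_gt(mk, 0.3)
})

test_that("burst phase profile is relative to the daily mean", {
  # two full cycles so every 4-h CT window is observable; all bursts in the
  # CT0 window of each cycle -> profile (6, 0, ..., 0)
  tau_h <- 24
  x <- rep(0, 2 * 86400)
  anchor <- (4 / 24) * 24 * 3600  # per2 peak: CT12 at t = 4 h
  ct0 <- anchor + (0 - 12) / 24 * 86400 + 86400  # first in-record CT0 center
  for (ce in c(ct0, ct0 + 86400)) {
    x[(ce - 200):(ce + 200)] <- 80
  }
  rates <- rates_from_vector(x, bin_width_s = 1)
  cat <- detect_bursts(rates)
  prof <- burst_phase_profile(cat, rates, per2_peak_time_s = anchor, tau_h = tau_h)
  expect_equal(prof$rel_burst_count, c(6, 0, 0, 0, 0, 0))
  expect_equal(mean(prof$rel_burst_count), 1)

  # scale invariance: widening each event (more supra bins, same window)
  # rescales the daily mean and leaves the relative profile unchanged
  x2 <- x
  for (ce in c(ct0, ct0 + 86400)) {
    x2[(ce - 290):(ce - 201)] <- 80
  }
  prof2 <- burst_phase_profile(detect_bursts(rates_from_vector(x2, bin_width_s = 1)),
                               rates_from_vector(x2, bin_width_s = 1),
                               per2_peak_time_s = anchor, tau_h = tau_h)
  expect_equal(prof2$rel_burst_count, c(6, 0, 0, 0, 0, 0))

  # phase-independent generator schedule: profile flat around 1
  cfg <- ko_cfg(duration_h = 72, n_electrodes = 1, seed = 13)
  r100 <- bin_spikes(gen_spike_trains(cfg), 0.1)
  prof3 <- burst_phase_profile(detect_bursts(r100), r100,
                               per2_peak_time_s = per2_peak_time_s(cfg),
                               tau_h = cfg$circadian_period_h)
  expect_equal(mean(prof3$rel_burst_count), 1, tolerance = 1e-9)
  expect_true(all(abs(prof3$rel_burst_count - 1) < 0.6))

  # all-zero counts: flagged via zero daily mean
  prof0 <- burst_phase_profile(cat, rates_from_vector(rep(0, 86400), bin_width_s = 1),
                               per2_peak_time_s = anchor, tau_h = tau_h)
  expect_equal(attr(prof0, "daily_mean"), 0)
  expect_true(all(is.na(prof0$rel_burst_count)))
})
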