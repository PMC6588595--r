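test_that("burst schedule is periodic for a degenerate interval and empty for wt", {
  cfg <- ko_cfg(duration_h = 600 / 3600, burst_interval_s = c(120, 120))
  sch <- gen_burst_schedule(cfg)
  expect_equal(sch$start_s, c(0, 120, 240, 360, 480))
  expect_equal(sch$end_s - sch$start_s, rep(5, 5))

  expect_equal(nrow(gen_burst_schedule(wt_cfg())), 0)

  expect_error(ko_cfg(burst_interval_s = c(3, 2)),
               class = "scnburst_config_error")
  # lower bound below the burst duration
  expect_error(ko_cfg(burst_interval_s = c(4, 10)),
               class = "scnburst_config_error")
})

test_that("burst gaps stay in the configured range with the right mean", {
  cfg <- ko_cfg(duration_h = 24)
  sch <- gen_burst_schedule(cfg)
  gaps <- diff(sch$start_s)
  expect_gt(length(gaps), 500)
  expect_true(all(gaps >= 120 & gaps <= 180))
  expect_gt(mean(gaps), 140)
  expect_lt(mean(gaps), 160)
  expect_true(all(diff(sch$start_s) > 0))
  expect_true(all(sch$end_s[-nrow(sch)] <= sch$start_s[-1]))
})

test_that("burst occurrence is independent of circadian phase", {
  # chi-square uniformity of event counts over six 4-h phase windows,
  # non-significant at alpha = 0.01 in at least 95% of seeds
  ok <- vapply(1:20, function(s) {
    cfg <- ko_cfg(duration_h = 72, seed = s)
    sch <- gen_burst_schedule(cfg)
    phase <- (sch$start_s %% (cfg$circadian_period_h * 3600)) /
      (cfg$circadian_period_h * 3600)
    counts <- tabulate(floor(phase * 6) + 1, nbins = 6)
    suppressWarnings(chisq.test(counts)$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("wild-type spiking honors the absolute refractory ceiling", {
  cfg <- wt_cfg(duration_h = 1, n_electrodes = 1)
  trains <- gen_spike_trains(cfg)
  expect_true(all(diff(trains$time_s) >= 0.035 - 1e-12))
  counts <- tabulate(floor(trains$time_s / 0.1) + 1, nbins = 36000)
  expect_lte(max(counts), 3)  # 30 Hz, below the 35 Hz criterion
})

test_that("intra-burst bins contain exactly burst_rate/10 spikes on every electrode", {
  cfg <- ko_cfg(duration_h = 0.25, burst_interval_s = c(120, 120),
                n_electrodes = 3)
  sch <- gen_burst_schedule(cfg)
  trains <- gen_spike_trains(cfg, sch)
  for (e in 1:3) {
    sp <- trains$time_s[trains$electrode == e]
    # bins fully inside the burst starting at 120 s
    for (b0 in seq(120, 124.9, by = 0.1)) {
      expect_equal(sum(sp >= b0 & sp < b0 + 0.1), 6)
    }
  }
  # the burst spike times are identical across electrodes
  in_burst <- function(e) {
    sp <- trains$time_s[trains$electrode == e]
    sp[sp >= 120 & sp < 125]
  }
  expect_identical(in_burst(1), in_burst(2))
  expect_identical(in_burst(1), in_burst(3))
})

test_that("time-averaged rate over one cycle matches the sinusoid mean", {
  cfg <- wt_cfg(duration_h = 23.86, n_electrodes = 1, seed = 4)
  trains <- gen_spike_trains(cfg)
  realized <- nrow(trains) / (23.86 * 3600)
  expect_lt(abs(realized - (18 + 2) / 2) / 10, 0.02)
})

test_that("a fixed seed reproduces every generator bit-identically", {
  cfg <- ko_cfg(duration_h = 1, seed = 11)
  expect_identical(gen_burst_schedule(cfg), gen_burst_schedule(cfg))
  expect_identical(gen_spike_trains(cfg), gen_spike_trains(cfg))
  expect_identical(gen_calcium_traces(cfg), gen_calcium_traces(cfg))
  cfg2 <- wt_cfg(duration_h = 26, seed = 11, img_dims = c(8, 8))
  expect_identical(gen_image_stack(cfg2)$frames, gen_image_stack(cfg2)$frames)
  expect_identical(gen_actogram(cfg2), gen_actogram(cfg2))
})

test_that("image stack degenerate cases behave as constructed", {
  cfg <- wt_cfg(duration_h = 72, img_phase_sd_h = 0, img_noise_sd = 0,
                img_dims = c(6, 6), img_damping_per_cycle = 1)
  st <- gen_image_stack(cfg)
  # all pixels identical
  expect_equal(max(apply(st$frames, 1, function(f) diff(range(f)))), 0)
  # no damping: first and last cycle amplitudes equal
  px <- st$frames[, 1, 1]
  tau_fr <- cfg$img_period_h * 3600 / cfg$img_frame_interval_s
  c1 <- px[seq_len(floor(tau_fr))]
  c2 <- px[(length(px) - floor(tau_fr) + 1):length(px)]
  expect_equal(diff(range(c1)), diff(range(c2)), tolerance = 0.02)

  expect_error(wt_cfg(img_amplitude = -1), class = "scnburst_config_error")
})

test_that("per-pixel acrophase dispersion is recovered from the stack", {
  cfg <- wt_cfg(duration_h = 72, img_phase_sd_h = 0.5, img_noise_sd = 0,
                img_dims = c(32, 32), seed = 8)
  st <- gen_image_stack(cfg)
  map <- pixel_acrophase_map(st, cfg$img_period_h)
  expect_gte(sum(map$mask), 1000)
  # circular SD from the Rayleigh mean vector length
  r <- acrophase_rayleigh(map)$r
  circ_sd_h <- sqrt(-2 * log(r)) / (2 * pi) * cfg$img_period_h
  expect_equal(circ_sd_h, 0.5, tolerance = 0.1)
})

test_that("calcium transients count and align with the schedule", {
  cfg <- ko_cfg(duration_h = 600 / 3600, burst_interval_s = c(120, 120),
                seed = 2)
  sch <- gen_burst_schedule(cfg)
  ca <- gen_calcium_traces(cfg, sch)
  ev <- detect_ca_spikes(ca)
  expect_equal(unname(table(ev$roi)), rep(5L, cfg$ca_n_rois),
               ignore_attr = TRUE)
  on1 <- sort(ev$onset_s[ev$roi == 1])
  expect_true(all(abs(on1 - sch$start_s) <= cfg$ca_frame_interval_s))

  # wt: empty schedule, no noise -> smooth circadian trace, zero events
  cfgw <- wt_cfg(duration_h = 2, ca_noise_sd = 0)
  evw <- detect_ca_spikes(gen_calcium_traces(cfgw))
  expect_equal(nrow(evw), 0)
})

test_that("actogram onsets follow the configured period and jitter", {
  cfg <- wt_cfg(duration_h = 96, circadian_period_h = 24,
                onset_jitter_min = 0, seed = 3)
  act <- gen_actogram(cfg)
  onsets <- attr(act, "true_onsets_min")
  expect_equal(diff(onsets), rep(24 * 60, length(onsets) - 1))

  cfg2 <- wt_cfg(duration_h = 96, circadian_period_h = 23.5,
                 onset_jitter_min = 0, seed = 3)
  on2 <- attr(gen_actogram(cfg2), "true_onsets_min")
  # a 23.5-h clock advances 0.5 h per 24-h day
  expect_equal(diff(on2), rep(23.5 * 60, length(on2) - 1))
})

test_that("all on-disk formats round-trip", {
  dir <- withr::local_tempdir()
  cfg <- ko_cfg(duration_h = 0.1)
  trains <- gen_spike_trains(cfg)
  p <- file.path(dir, "spikes.tsv")
  write_spike_trains(trains, p)
  back <- read_spike_trains(p)
  expect_equal(back$time_s, trains$time_s)
  expect_equal(attr(back, "duration_s"), attr(trains, "duration_s"))

  cfg2 <- wt_cfg(duration_h = 26, img_dims = c(6, 6))
  st <- gen_image_stack(cfg2)
  pt <- file.path(dir, "stack.tif")
  write_image_stack(st, pt)
  st2 <- read_image_stack(pt)
  expect_equal(st2$frames, st$frames, tolerance = 1e-5)
  expect_equal(st2$frame_interval_s, st$frame_interval_s)

  act <- gen_actogram(wt_cfg(duration_h = 48))
  pa <- file.path(dir, "act.csv")
  write_actogram(act, pa)
  expect_equal(as.data.frame(read_actogram(pa)), as.data.frame(act),
               ignore_attr = TRUE)

  ca <- gen_calcium_traces(cfg)
  pc <- file.path(dir, "ca.csv")
  write_calcium_traces(ca, pc)
  ca2 <- read_calcium_traces(pc)
  expect_equal(ca2$dff, ca$dff)
  expect_equal(attr(ca2, "frame_interval_s"), cfg$ca_frame_interval_s)
})
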