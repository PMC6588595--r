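# Small configurations reused across tests. Durations are kept short; the
# acceptance tests exercise the full-scale study conditions.

wt_cfg <- function(duration_h = 600 / 3600, n_electrodes = 2, seed = 1, ...) {
  gen_config("wt", duration_h = duration_h, n_electrodes = n_electrodes,
             seed = seed, ...)
}

ko_cfg <- function(duration_h = 600 / 3600, n_electrodes = 2, seed = 1,
                   burst_interval_s = c(120, 180), ...) {
  gen_config("gaba_deficient", duration_h = duration_h,
             n_electrodes = n_electrodes, seed = seed,
             burst_interval_s = burst_interval_s, ...)
}

# Rate-series tibble from a bare vector of Hz values (one electrode), as
# bin_spikes() would produce it.
rates_from_vector <- function(rate_hz, bin_width_s = 0.1, electrode = 1L) {
  out <- tibble::tibble(
    electrode = electrode,
    t_s = (seq_along(rate_hz) - 1) * bin_width_s,
    rate_hz = as.numeric(rate_hz)
  )
  attr(out, "bin_width_s") <- bin_width_s
  attr(out, "duration_s") <- length(rate_hz) * bin_width_s
  out
}

# Independent brute-force burst oracle: walk the bins, open an event at each
# supra-threshold bin, close it when the gap to the next supra bin exceeds
# merge_gap_s. Deliberately naive (O(n) scalar loop).
oracle_bursts <- function(rate_hz, bin_width_s, threshold_hz, merge_gap_s) {
  idx <- which(rate_hz > threshold_hz)
  if (!length(idx)) {
    return(data.frame(start_s = numeric(), end_s = numeric()))
  }
  starts <- c(); ends <- c()
  cur_start <- idx[1]; cur_end <- idx[1]
  for (i in idx[-1]) {
    gap_s <- (i - cur_end - 1) * bin_width_s
    if (gap_s <= merge_gap_s + 1e-9) {
      cur_end <- i
    } else {
      starts <- c(starts, cur_start); ends <- c(ends, cur_end)
      cur_start <- i; cur_end <- i
    }
  }
  starts <- c(starts, cur_start); ends <- c(ends, cur_end)
  data.frame(start_s = (starts - 1) * bin_width_s, end_s = ends * bin_width_s)
}

# Noise-free actogram: square-wave nocturnal activity, exact counts.
square_actogram <- function(period_h = 24, n_cycles = 10, rate = 10) {
  period_min <- period_h * 60
  total <- floor(n_cycles * period_min)
  t_min <- seq_len(total) - 1
  active <- (t_min %% period_min) < period_min / 2
  tibble::tibble(t_min = t_min, count = ifelse(active, rate, 0),
                 light_state = "D")
}

# Direct cosine image stack with a chosen per-pixel phase matrix (hours).
phase_stack <- function(phase_h, tau_h = 24, n_frames = 72,
                        frame_interval_s = 3600, mesor = 100, amp = 50) {
  h <- nrow(phase_h); w <- ncol(phase_h)
  tt <- (seq_len(n_frames) - 1) * frame_interval_s
  ang <- outer(tt, as.vector(phase_h) * 3600,
               function(t, p) cos(2 * pi * (t - p) / (tau_h * 3600)))
  image_stack(array(mesor + amp * ang, dim = c(n_frames, h, w)),
              frame_interval_s)
}
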