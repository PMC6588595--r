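#' Configuration for the synthetic SCN recording generator
#'
#' Builds and validates the parameter set from which every synthetic modality
#' (spike trains, bioluminescence image stacks, calcium traces, actograms) is
#' generated. Two presets encode the two genotype conditions the pipeline is
#' designed to contrast:
#'
#' * `"wt"` — wild-type-like firing: a sinusoidal circadian rate between
#'   `trough_rate_hz` and `peak_rate_hz`, an absolute refractory period of
#'   `refractory_ms`, and no bursts. With the 35-ms default refractory no
#'   100-ms bin can ever contain more than 3 spikes (30 Hz), so the 35-Hz
#'   burst criterion is never met.
#' * `"gaba_deficient"` — the same circadian base plus synchronized burst
#'   events: regular spiking at `burst_rate_hz` (35–80 Hz) on all electrodes
#'   for `burst_duration_s` seconds, recurring at intervals drawn uniformly
#'   from `burst_interval_s`, independent of circadian phase.
#'
#' Time is internally seconds from recording start. The firing-rate peak is at
#' t = 0, which corresponds to circadian time CT8 (the phase of highest
#' multiunit activity); the PER2 reporter peak, which defines CT12, therefore
#' falls at t = (4/24) * circadian_period_h hours.
#'
#' @param preset `"wt"` or `"gaba_deficient"`.
#' @param n_electrodes Number of electrodes on the simulated array (default 12,
#'   within the 9–19 per-slice range typical of SCN recordings).
#' @param duration_h Recording length in hours.
#' @param circadian_period_h Circadian period of the firing rhythm in hours.
#'   Defaults: 23.86 (wt), 23.63 (gaba_deficient).
#' @param peak_rate_hz,trough_rate_hz Circadian peak/trough multiunit rate (Hz).
#' @param refractory_ms Absolute refractory period for baseline spiking (ms).
#' @param burst_rate_hz Intra-burst firing rate (Hz); must exceed 35.
#' @param burst_duration_s Duration of each burst event (s).
#' @param burst_interval_s Length-2 numeric: range of the uniform distribution
#'   of burst start-to-start intervals (s). A degenerate range (equal bounds)
#'   gives a strictly periodic schedule.
#' @param ca_frame_interval_s Calcium sampling interval (s); default 3 s
#'   (0.33 fps).
#' @param ca_n_rois Number of calcium ROIs.
#' @param ca_transient_amp,ca_decay_s,ca_noise_sd Calcium transient amplitude
#'   (dF/F), exponential decay constant (s), and additive noise SD. The
#'   transient amplitude must be at least 5 times the noise SD.
#' @param img_period_h,img_phase_sd_h,img_damping_per_cycle,img_noise_sd
#'   Image-stack rhythm parameters: period (h), SD of the wrapped-normal
#'   per-pixel acrophase dispersion (h), amplitude damping factor per cycle,
#'   additive noise SD (intensity units).
#' @param img_mesor,img_amplitude Pixel rhythm mesor and initial amplitude
#'   (intensity units).
#' @param img_dims Length-2 integer: image height and width in pixels.
#' @param img_frame_interval_s Frame interval of the image stack (s); default
#'   3600 (hourly exposures).
#' @param img_pixel_size_um Pixel edge length (micrometres).
#' @param onset_jitter_min SD (minutes) of the Gaussian perturbation applied to
#'   each behavioral activity onset.
#' @param act_night_rate,act_day_rate Mean activity counts per 1-min bin during
#'   the active (subjective night) and rest phases.
#' @param act_light_schedule `"DD"` (constant darkness) or `"LD"` (12:12
#'   light-dark annotation).
#' @param seed Integer seed from which all generator randomness derives.
#'
#' @return A `gen_config` object (named list).
#' @examples
#' cfg <- gen_config("wt", duration_h = 2, n_electrodes = 3)
#' cfg$peak_rate_hz
#' @export
gen_config <- function(preset = c("wt", "gaba_deficient"),
                       n_electrodes = 12,
                       duration_h = 24,
                       circadian_period_h = NULL,
                       peak_rate_hz = 18,
                       trough_rate_hz = 2,
                       refractory_ms = 35,
                       burst_rate_hz = 60,
                       burst_duration_s = 5,
                       burst_interval_s = c(120, 180),
                       ca_frame_interval_s = 3,
                       ca_n_rois = 4,
                       ca_transient_amp = 1,
                       ca_decay_s = 5,
                       ca_noise_sd = 0.05,
                       img_period_h = NULL,
                       img_phase_sd_h = 0.5,
                       img_damping_per_cycle = 0.95,
                       img_noise_sd = 2,
                       img_mesor = 100,
                       img_amplitude = 50,
                       img_dims = c(32, 32),
                       img_frame_interval_s = 3600,
                       img_pixel_size_um = 4.3,
                       onset_jitter_min = 20,
                       act_night_rate = 10,
                       act_day_rate = 0,
                       act_light_schedule = c("DD", "LD"),
                       seed = 1L) {
  preset <- match.arg(preset)
  act_light_schedule <- match.arg(act_light_schedule)
  if (is.null(circadian_period_h)) {
    circadian_period_h <- if (preset == "wt") 23.86 else 23.63
  }
  if (is.null(img_period_h)) img_period_h <- circadian_period_h

  cfg <- list(
    preset = preset,
    n_electrodes = as.integer(n_electrodes),
    duration_h = duration_h,
    circadian_period_h = circadian_period_h,
    peak_rate_hz = peak_rate_hz,
    trough_rate_hz = trough_rate_hz,
    refractory_ms = refractory_ms,
    burst_rate_hz = burst_rate_hz,
    burst_duration_s = burst_duration_s,
    burst_interval_s = as.numeric(burst_interval_s),
    ca_frame_interval_s = ca_frame_interval_s,
    ca_n_rois = as.integer(ca_n_rois),
    ca_transient_amp = ca_transient_amp,
    ca_decay_s = ca_decay_s,
    ca_noise_sd = ca_noise_sd,
    img_period_h = img_period_h,
    img_phase_sd_h = img_phase_sd_h,
    img_damping_per_cycle = img_damping_per_cycle,
    img_noise_sd = img_noise_sd,
    img_mesor = img_mesor,
    img_amplitude = img_amplitude,
    img_dims = as.integer(img_dims),
    img_frame_interval_s = img_frame_interval_s,
    img_pixel_size_um = img_pixel_size_um,
    onset_jitter_min = onset_jitter_min,
    act_night_rate = act_night_rate,
    act_day_rate = act_day_rate,
    act_light_schedule = act_light_schedule,
    seed = as.integer(seed)
  )
  class(cfg) <- "gen_config"
  validate_gen_config(cfg)
  cfg
}

validate_gen_config <- function(cfg) {
  stopifnot(inherits(cfg, "gen_config"))
  if (!is.finite(cfg$duration_h) || cfg$duration_h <= 0) {
    abort("`duration_h` must be positive.", class = "scnburst_config_error")
  }
  if (cfg$n_electrodes < 1) {
    abort("`n_electrodes` must be >= 1.", class = "scnburst_config_error")
  }
  if (cfg$trough_rate_hz > cfg$peak_rate_hz) {
    abort("`trough_rate_hz` must not exceed `peak_rate_hz`.",
          class = "scnburst_config_error")
  }
  if (cfg$trough_rate_hz < 0) {
    abort("Rates must be non-negative.", class = "scnburst_config_error")
  }
  if (cfg$refractory_ms < 0) {
    abort("`refractory_ms` must be non-negative.", class = "scnburst_config_error")
  }
  # the renewal construction needs mean ISI > refractory at the peak rate
  if (cfg$peak_rate_hz > 0 && 1 / cfg$peak_rate_hz <= cfg$refractory_ms / 1000) {
    abort("`peak_rate_hz` incompatible with the refractory period.",
          class = "scnburst_config_error")
  }
  if (cfg$preset == "gaba_deficient") {
    if (cfg$burst_rate_hz <= 35) {
      abort("`burst_rate_hz` must exceed 35 Hz.", class = "scnburst_config_error")
    }
    iv <- cfg$burst_interval_s
    if (length(iv) != 2 || any(!is.finite(iv)) || iv[1] > iv[2]) {
      abort("`burst_interval_s` must be an increasing length-2 range.",
            class = "scnburst_config_error")
    }
    if (iv[1] <= cfg$burst_duration_s) {
      abort("Lower bound of `burst_interval_s` must exceed `burst_duration_s`.",
            class = "scnburst_config_error")
    }
  }
  if (cfg$img_amplitude <= 0 || cfg$img_period_h <= 0) {
    abort("Image rhythm amplitude and period must be positive.",
          class = "scnburst_config_error")
  }
  if (cfg$ca_noise_sd > 0 && cfg$ca_transient_amp < 5 * cfg$ca_noise_sd) {
    abort("`ca_transient_amp` must be at least 5x `ca_noise_sd`.",
          class = "scnburst_config_error")
  }
  invisible(cfg)
}

#' @export
print.gen_config <- function(x, ...) {
  cat("<gen_config>", x$preset, "preset:",
      x$n_electrodes, "electrodes,",
      x$duration_h, "h, period", x$circadian_period_h, "h, seed", x$seed, "\n")
  invisible(x)
}

# Instantaneous multiunit firing rate (Hz) at time t (s): cosine between
# trough and peak, peak at t = 0 (== CT8).
rate_fun <- function(cfg) {
  period_s <- cfg$circadian_period_h * 3600
  force(cfg)
  function(t) {
    cfg$trough_rate_hz +
      (cfg$peak_rate_hz - cfg$trough_rate_hz) * (1 + cos(2 * pi * t / period_s)) / 2
  }
}

#' PER2 peak time implied by a generator configuration
#'
#' Under the generator's phase convention the firing-rate peak is at t = 0,
#' which is CT8; the PER2 reporter peak defines CT12 and therefore falls
#' 4 CT-hours later. This anchor feeds [to_ct()] and
#' [burst_phase_profile()].
#'
#' @param cfg A [gen_config()] object.
#' @return Time of the PER2 peak in seconds from recording start.
#' @export
per2_peak_time_s <- function(cfg) {
  (4 / 24) * cfg$circadian_period_h * 3600
}
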