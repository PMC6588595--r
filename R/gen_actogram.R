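#' Generate a synthetic actogram
#'
#' Emulates passive-infrared locomotor recordings of a nocturnal mouse in
#' 1-min bins: square-wave activity with an active phase of half the circadian
#' period (12 h for a 24-h period), cycle onsets at
#' `k * period + N(0, onset_jitter_min)`, Poisson count noise with mean
#' `act_night_rate` during the active phase and `act_day_rate` otherwise.
#' Under `"LD"` the light annotation is a fixed 12:12 cycle with lights-off at
#' t = 0; under `"DD"` all bins are marked `"D"`.
#'
#' @param cfg A [gen_config()] object; `circadian_period_h` sets the
#'   free-running period of the behavioral rhythm.
#' @return A tibble `t_min` (bin start, minutes from recording start), `count`,
#'   `light_state` (`"L"`/`"D"`), with attribute `true_onsets_min`.
#' @examples
#' cfg <- gen_config("wt", duration_h = 72, onset_jitter_min = 0, seed = 2)
#' act <- gen_actogram(cfg)
#' head(act)
#' @export
gen_actogram <- function(cfg) {
  validate_gen_config(cfg)
  period_min <- cfg$circadian_period_h * 60
  total_min <- floor(cfg$duration_h * 60)
  n_cycles <- ceiling(total_min / period_min) + 1L

  set.seed(split_seed(cfg$seed, 4L))
  onsets <- (seq_len(n_cycles) - 1) * period_min +
    rnorm(n_cycles, 0, cfg$onset_jitter_min)
  active_len <- period_min / 2

  t_min <- seq_len(total_min) - 1
  active <- rep(FALSE, total_min)
  for (k in seq_len(n_cycles)) {
    lo <- onsets[k]; hi <- onsets[k] + active_len
    idx <- t_min >= lo & t_min < hi
    active[idx] <- TRUE
  }
  mu <- ifelse(active, cfg$act_night_rate, cfg$act_day_rate)
  counts <- rpois(total_min, mu)

  light_state <- if (cfg$act_light_schedule == "LD") {
    ifelse((t_min %% 1440) < 720, "D", "L")
  } else {
    rep("D", total_min)
  }

  out <- tibble(t_min = t_min, count = counts, light_state = light_state)
  attr(out, "true_onsets_min") <- onsets[onsets < total_min]
  attr(out, "period_min") <- period_min
  out
}
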