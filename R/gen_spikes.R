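#' Generate the slice-wide burst schedule
#'
#' Burst events in GABA-deficient SCN slices occur synchronously on all
#' electrodes, so a single event schedule is shared by every electrode of a
#' simulated slice. Start-to-start gaps are drawn i.i.d. uniformly from
#' `cfg$burst_interval_s`; each event lasts `cfg$burst_duration_s`. The first
#' event starts at t = 0 and the schedule covers the whole recording, so event
#' timing is tied to elapsed recording time, not to circadian phase.
#'
#' For the `"wt"` preset the schedule is empty (zero rows), which is a valid
#' input everywhere downstream.
#'
#' @param cfg A [gen_config()] object.
#' @return A tibble with columns `start_s`, `end_s` (sorted, non-overlapping).
#' @examples
#' cfg <- gen_config("gaba_deficient", duration_h = 600 / 3600,
#'                   burst_interval_s = c(120, 120))
#' gen_burst_schedule(cfg)$start_s
#' @export
gen_burst_schedule <- function(cfg) {
  validate_gen_config(cfg)
  duration_s <- cfg$duration_h * 3600
  if (cfg$preset == "wt") {
    return(tibble(start_s = numeric(), end_s = numeric()))
  }
  iv <- cfg$burst_interval_s
  set.seed(split_seed(cfg$seed, 1L))
  n_max <- ceiling(duration_s / iv[1]) + 2L
  gaps <- runif(n_max, iv[1], iv[2])
  starts <- c(0, cumsum(gaps))
  starts <- starts[starts < duration_s]
  tibble(
    start_s = starts,
    end_s = pmin(starts + cfg$burst_duration_s, duration_s)
  )
}

# Baseline multiunit spiking for one electrode: a renewal process with an
# absolute refractory period followed by an exponential wait whose hazard is
# refreshed every `seg_s` seconds from the (slowly varying) circadian rate.
# Mean inter-spike interval at local rate r is refractory + 1/hazard = 1/r,
# so the realized rate tracks the target sinusoid while the refractory bound
# caps any 100-ms window at floor(0.1/refractory) + 1 spikes.
sim_renewal_train <- function(duration_s, rate_at, refractory_s, seg_s = 60) {
  n_seg <- ceiling(duration_s / seg_s)
  out <- vector("list", n_seg)
  t_cur <- 0
  for (i in seq_len(n_seg)) {
    s1 <- min(i * seg_s, duration_s)
    if (t_cur >= s1) next
    lam <- rate_at((max(t_cur, (i - 1) * seg_s) + s1) / 2)
    if (lam <= 1e-9) next
    ex_rate <- 1 / (1 / lam - refractory_s)
    span <- s1 - t_cur
    acc <- NULL
    repeat {
      m <- ceiling(span * lam + 4 * sqrt(span * lam) + 10)
      isi <- refractory_s + rexp(m, ex_rate)
      tt <- t_cur + cumsum(isi)
      over <- tt >= s1
      if (any(over)) {
        sp <- tt[!over]
        if (length(sp)) t_cur <- sp[length(sp)]
        acc <- c(acc, sp)
        break
      }
      acc <- c(acc, tt)
      t_cur <- tt[length(tt)]
      span <- s1 - t_cur
    }
    out[[i]] <- acc
  }
  unlist(out) %||% numeric()
}

#' Generate multi-electrode spike trains
#'
#' Simulates one slice recording: per electrode, baseline spiking follows a
#' refractory renewal process whose instantaneous rate is a circadian sinusoid
#' between `trough_rate_hz` and `peak_rate_hz` (peak at t = 0). During each
#' event of the burst schedule, baseline spikes are replaced by regular spiking
#' at `burst_rate_hz` on *all* electrodes simultaneously, so any 100-ms bin
#' fully inside a burst contains exactly `burst_rate_hz / 10` spikes.
#'
#' Each electrode draws from its own seed stream derived from `cfg$seed`, so
#' output is bit-identical for a fixed seed and unchanged for electrode k when
#' more electrodes are added.
#'
#' @param cfg A [gen_config()] object.
#' @param schedule A burst schedule tibble from [gen_burst_schedule()];
#'   defaults to generating one from `cfg`.
#' @return A tibble with columns `electrode` (integer) and `time_s` (sorted
#'   within electrode), with attributes `duration_s`, `scn_mask` (electrode ids
#'   flagged on-SCN; all, by default).
#' @examples
#' cfg <- gen_config("wt", duration_h = 0.1, n_electrodes = 2)
#' trains <- gen_spike_trains(cfg)
#' dplyr::count(trains, electrode)
#' @export
gen_spike_trains <- function(cfg, schedule = gen_burst_schedule(cfg)) {
  validate_gen_config(cfg)
  duration_s <- cfg$duration_h * 3600
  refractory_s <- cfg$refractory_ms / 1000
  rate_at <- rate_fun(cfg)

  burst_times <- NULL
  if (nrow(schedule)) {
    burst_times <- purrr::map(seq_len(nrow(schedule)), function(i) {
      seq(schedule$start_s[i], schedule$end_s[i] - 1e-9, by = 1 / cfg$burst_rate_hz)
    })
    burst_times <- unlist(burst_times)
  }

  per_electrode <- purrr::map(seq_len(cfg$n_electrodes), function(e) {
    set.seed(split_seed(cfg$seed, 100L + e))
    sp <- sim_renewal_train(duration_s, rate_at, refractory_s)
    if (!is.null(burst_times)) {
      in_burst <- rep(FALSE, length(sp))
      for (i in seq_len(nrow(schedule))) {
        in_burst <- in_burst |
          (sp >= schedule$start_s[i] & sp < schedule$end_s[i])
      }
      sp <- sort(c(sp[!in_burst], burst_times))
    }
    tibble(electrode = e, time_s = sp)
  })
  out <- bind_rows(per_electrode)
  attr(out, "duration_s") <- duration_s
  attr(out, "scn_mask") <- seq_len(cfg$n_electrodes)
  out
}

# Recording duration: explicit argument, then attribute, then data range.
train_duration <- function(trains, duration_s = NULL) {
  duration_s %||% attr(trains, "duration_s") %||% max(trains$time_s)
}

scn_electrodes <- function(trains) {
  attr(trains, "scn_mask") %||% sort(unique(trains$electrode))
}
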