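#' Detect activity onsets and cycle-to-cycle variability
#'
#' For each cycle the onset is the earliest minute maximizing a contrast
#' template — mean activity in the following `template_h` hours minus mean
#' activity in the preceding `template_h` hours — searched within
#' `search_h` hours of the expected onset (previous onset + `period_guess_h`;
#' the first cycle is searched globally). Regressing onset time on cycle
#' index gives the free-running period (slope) and the cycle-to-cycle
#' variability (residual SD, minutes). Cycles without activity yield no onset
#' and are excluded from the regression.
#'
#' @param act Actogram tibble with `t_min`, `count` (see [gen_actogram()],
#'   [read_actogram()]).
#' @param period_guess_h Prior estimate of the period (h).
#' @param template_h Half-width of the contrast template (h).
#' @param search_h Search half-window around the expected onset (h).
#' @return An `onset_series`: `onsets` tibble (`cycle`, `onset_h`),
#'   `period_h` (regression slope), `residual_sd_min`, `n_cycles`.
#' @export
detect_onsets <- function(act, period_guess_h = 24, template_h = 6,
                          search_h = 6) {
  counts <- act$count
  n <- length(counts)
  period_min <- period_guess_h * 60
  tpl <- round(template_h * 60)
  srch <- round(search_h * 60)
  n_cycles <- floor(n / period_min)
  if (n_cycles < 2) abort("Need at least 2 cycles of data.")

  cs <- cumsum(c(0, counts))
  wsum <- function(lo, hi) { # sum of counts in bins [lo, hi), 1-based
    lo <- max(1L, lo); hi <- min(n + 1L, hi)
    if (hi <= lo) return(0)
    cs[hi] - cs[lo]
  }
  contrast <- function(i) {
    wsum(i, i + tpl) / tpl - wsum(i - tpl, i) / tpl
  }

  onsets <- rep(NA_real_, n_cycles)
  expected <- NA_real_
  for (k in seq_len(n_cycles)) {
    lo_cycle <- (k - 1) * period_min
    if (is.na(expected)) {
      cand <- seq.int(floor(lo_cycle) + 1L, min(n, floor(lo_cycle + period_min)))
    } else {
      cand <- seq.int(max(1L, floor(expected - srch)),
                      min(n, ceiling(expected + srch)))
    }
    if (!length(cand)) next
    # a cycle with no activity has no onset
    if (wsum(floor(lo_cycle) + 1L, floor(lo_cycle + period_min) + 1L) == 0) {
      expected <- if (is.na(expected)) NA_real_ else expected + period_min
      next
    }
    sc <- vapply(cand, contrast, numeric(1))
    best <- cand[which.max(sc)]  # which.max returns the earliest maximum
    onsets[k] <- best - 1        # bin start, minutes
    expected <- onsets[k] + period_min
  }

  ok <- which(!is.na(onsets))
  tab <- tibble(cycle = ok, onset_h = onsets[ok] / 60)
  if (length(ok) >= 3) {
    fit <- lm(onset_h ~ cycle, data = tab)
    period_h <- unname(coef(fit)[2])
    resid_sd_min <- sqrt(sum(residuals(fit)^2) / (length(ok) - 2)) * 60
  } else {
    period_h <- NA_real_
    resid_sd_min <- NA_real_
  }
  structure(
    list(onsets = tab, period_h = period_h, residual_sd_min = resid_sd_min,
         n_cycles = n_cycles),
    class = "onset_series"
  )
}

#' @export
print.onset_series <- function(x, ...) {
  cat(sprintf("<onset_series> %d onsets; period %.3f h; cycle-to-cycle SD %.1f min\n",
              nrow(x$onsets), x$period_h, x$residual_sd_min))
  invisible(x)
}

#' @rdname detect_onsets
#' @param x An `onset_series`.
#' @param ... Unused.
#' @method tidy onset_series
#' @export
tidy.onset_series <- function(x, ...) x$onsets

#' @rdname detect_onsets
#' @method glance onset_series
#' @export
glance.onset_series <- function(x, ...) {
  tibble(n_onsets = nrow(x$onsets), n_cycles = x$n_cycles,
         period_h = x$period_h, residual_sd_min = x$residual_sd_min)
}

#' Mean daily activity profile
#'
#' Folds the actogram at `fold_period_h`, sums counts into `bin_h`-hour bins
#' per cycle, and averages across cycles, so the profile totals the mean
#' per-cycle activity.
#'
#' @param act Actogram tibble (`t_min`, `count`).
#' @param fold_period_h Folding period (h); must be at least `bin_h`.
#' @param bin_h Profile bin width (h, default 2).
#' @return Tibble `bin_start_h`, `mean_count`.
#' @export
daily_profile <- function(act, fold_period_h = 24, bin_h = 2) {
  if (fold_period_h < bin_h) abort("`fold_period_h` must be at least `bin_h`.")
  period_min <- fold_period_h * 60
  n_bins <- ceiling(fold_period_h / bin_h)
  act |>
    mutate(
      cycle = floor(.data$t_min / period_min),
      bin = pmin(floor((.data$t_min %% period_min) / (bin_h * 60)), n_bins - 1)
    ) |>
    group_by(.data$cycle, .data$bin) |>
    summarise(total = sum(.data$count), .groups = "drop") |>
    group_by(.data$bin) |>
    summarise(mean_count = mean(.data$total), .groups = "drop") |>
    mutate(bin_start_h = .data$bin * bin_h) |>
    select("bin_start_h", "mean_count")
}

#' Activity totals in light vs dark (or subjective day vs night)
#'
#' Under a light-dark annotation (any `"L"` bins), counts are summed per
#' 24-h cycle by light state. Under constant darkness the partition uses the
#' detected (or supplied) onsets: subjective night is the 12 h from each
#' onset, subjective day the remainder of that cycle.
#'
#' @param act Actogram tibble (`t_min`, `count`, `light_state`).
#' @param onsets Optional `onset_series` (required under DD if onsets cannot
#'   be detected with defaults).
#' @param period_h Cycle length used for the DD partition; defaults to the
#'   onset-regression period.
#' @return Tibble `cycle`, `dark_or_night`, `light_or_day`, `difference`.
#' @export
activity_partition <- function(act, onsets = NULL, period_h = NULL) {
  has_ld <- "light_state" %in% names(act) && any(act$light_state == "L")
  if (has_ld) {
    out <- act |>
      mutate(cycle = floor(.data$t_min / 1440) + 1L) |>
      group_by(.data$cycle) |>
      summarise(
        dark_or_night = sum(.data$count[.data$light_state == "D"]),
        light_or_day = sum(.data$count[.data$light_state == "L"]),
        .groups = "drop"
      )
  } else {
    if (is.null(onsets)) onsets <- detect_onsets(act)
    period_h <- period_h %||% onsets$period_h
    if (!is.finite(period_h)) abort("No usable period for the DD partition.")
    tab <- onsets$onsets
    out <- purrr::map(seq_len(nrow(tab)), function(i) {
      on_min <- tab$onset_h[i] * 60
      night <- act$t_min >= on_min & act$t_min < on_min + 720
      day <- act$t_min >= on_min + 720 & act$t_min < on_min + period_h * 60
      tibble(
        cycle = tab$cycle[i],
        dark_or_night = sum(act$count[night]),
        light_or_day = sum(act$count[day])
      )
    })
    out <- bind_rows(out)
  }
  mutate(out, difference = .data$dark_or_night - .data$light_or_day)
}

#' Free-running period of a behavioral rhythm
#'
#' Chi-square periodogram ([chisq_periodogram()]) on the 1-min activity
#' counts of the last `days` days of the record (the convention is 28
#' consecutive days under constant darkness).
#'
#' @param act Actogram tibble (`t_min`, `count`).
#' @param days Number of trailing days to analyze.
#' @param period_range_h,alpha Passed to [chisq_periodogram()].
#' @return A `periodogram` object.
#' @export
behavior_period <- function(act, days = 28, period_range_h = c(20, 28),
                            alpha = 0.01) {
  need <- days * 1440
  if (nrow(act) < need) {
    abort(sprintf("Need %d days of data; actogram has %.1f.", days,
                  nrow(act) / 1440))
  }
  sub <- utils::tail(act[order(act$t_min), ], need)
  chisq_periodogram(sub$count, period_range_h = period_range_h, alpha = alpha,
                    sample_interval_s = 60)
}
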