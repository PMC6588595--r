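#' Bin spike trains into firing-rate series
#'
#' Counts spikes per electrode in left-closed, right-open bins
#' `[k*w, (k+1)*w)` and converts to Hz (`count / w`). A trailing partial bin is
#' dropped, so a 10-min record in 100-ms bins yields exactly 6000 bins.
#'
#' @param trains Tibble with columns `electrode`, `time_s` (e.g. from
#'   [gen_spike_trains()] or [read_spike_trains()]).
#' @param bin_width_s Bin width in seconds (> 0). 0.1 s for burst statistics,
#'   60 s for circadian rhythm analysis.
#' @param duration_s Recording length; defaults to the `duration_s` attribute
#'   of `trains`.
#' @return A tibble `electrode`, `t_s` (bin start), `rate_hz`, with attributes
#'   `bin_width_s`, `duration_s`, `scn_mask`.
#' @examples
#' cfg <- gen_config("wt", duration_h = 600 / 3600, n_electrodes = 2)
#' rates <- bin_spikes(gen_spike_trains(cfg), 0.1)
#' nrow(rates) / 2  # 6000 bins per electrode
#' @export
bin_spikes <- function(trains, bin_width_s, duration_s = NULL) {
  if (bin_width_s <= 0) abort("`bin_width_s` must be positive.")
  electrodes <- sort(unique(trains$electrode))
  if (!length(electrodes)) {
    # an empty spike list is valid when the electrode set is known
    electrodes <- attr(trains, "scn_mask")
    if (!length(electrodes)) abort("No electrodes in `trains`.")
  }
  duration_s <- train_duration(trains, duration_s)
  n_bins <- floor(duration_s / bin_width_s + 1e-9)
  if (n_bins < 1) abort("Recording shorter than one bin.")

  out <- purrr::map(electrodes, function(e) {
    sp <- trains$time_s[trains$electrode == e]
    sp <- sp[sp >= 0 & sp < n_bins * bin_width_s]
    counts <- tabulate(floor(sp / bin_width_s) + 1L, nbins = n_bins)
    tibble(
      electrode = e,
      t_s = (seq_len(n_bins) - 1) * bin_width_s,
      rate_hz = counts / bin_width_s
    )
  })
  out <- bind_rows(out)
  attr(out, "bin_width_s") <- bin_width_s
  attr(out, "duration_s") <- duration_s
  attr(out, "scn_mask") <- attr(trains, "scn_mask") %||% electrodes
  out
}

rate_bin_width <- function(rates) {
  attr(rates, "bin_width_s") %||% min(diff(sort(unique(rates$t_s))))
}

# electrodes included in slice-level statistics
rate_scn <- function(rates) {
  m <- attr(rates, "scn_mask") %||% sort(unique(rates$electrode))
  intersect(sort(unique(rates$electrode)), m)
}

#' Bin-ratio distribution of firing rates
#'
#' Histogram of 100-ms bin firing rates pooled over on-SCN electrodes within a
#' time window, expressed as the percentage of bin numbers to the total — the
#' representation in which GABA-deficient slices show >3% of bins above 35 Hz
#' while wild-type slices never exceed 35 Hz.
#'
#' @param rates Rate series from [bin_spikes()] (100-ms bins by default usage).
#' @param window Length-2 numeric `(start_s, end_s)`; default the full record.
#' @param class_width_hz Width of the frequency classes (Hz).
#' @param threshold_hz Burst criterion used for `frac_above_hz` (default 35).
#' @return A `bin_ratio_distribution` object: tibble of classes via [tidy()],
#'   summary via [glance()]; fields `n_bins_total` and `frac_above_pct`.
#' @export
bin_ratio_distribution <- function(rates, window = NULL, class_width_hz = 5,
                                   threshold_hz = 35) {
  w <- rate_bin_width(rates)
  if (is.null(window)) {
    window <- c(min(rates$t_s), max(rates$t_s) + w)
  }
  if (diff(window) < w) abort("`window` shorter than one bin.")
  keep <- rates$electrode %in% rate_scn(rates) &
    rates$t_s >= window[1] & rates$t_s < window[2]
  x <- rates$rate_hz[keep]
  if (!length(x)) abort("No bins fall inside `window`.")

  hi <- max(threshold_hz + class_width_hz,
            (floor(max(x) / class_width_hz) + 1) * class_width_hz)
  edges <- seq(0, hi, by = class_width_hz)
  cls <- cut(x, breaks = edges, right = FALSE, include.lowest = FALSE,
             labels = FALSE)
  cls[x == 0] <- 1L  # left-closed lowest class
  counts <- tabulate(cls, nbins = length(edges) - 1)
  out <- list(
    table = tibble(
      freq_lo_hz = edges[-length(edges)],
      freq_hi_hz = edges[-1],
      pct = 100 * counts / length(x)
    ),
    n_bins_total = length(x),
    threshold_hz = threshold_hz,
    frac_above_pct = 100 * mean(x > threshold_hz)
  )
  class(out) <- "bin_ratio_distribution"
  out
}

#' @export
print.bin_ratio_distribution <- function(x, ...) {
  cat("<bin_ratio_distribution>", x$n_bins_total, "bins;",
      sprintf("%.3f%%", x$frac_above_pct), "above", x$threshold_hz, "Hz\n")
  invisible(x)
}

#' @rdname bin_ratio_distribution
#' @param x A `bin_ratio_distribution`.
#' @param ... Unused.
#' @method tidy bin_ratio_distribution
#' @export
tidy.bin_ratio_distribution <- function(x, ...) x$table

#' @rdname bin_ratio_distribution
#' @method glance bin_ratio_distribution
#' @export
glance.bin_ratio_distribution <- function(x, ...) {
  tibble(n_bins_total = x$n_bins_total, threshold_hz = x$threshold_hz,
         frac_above_pct = x$frac_above_pct)
}

# maximal runs of TRUE in a logical vector -> (start_idx, end_idx) tibble
runs_true <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(start_idx = starts[r$values], end_idx = ends[r$values])
}

#' Detect burst events from a rate series
#'
#' Applies the operational burst definition — firing rate above `threshold_hz`
#' (35 Hz) in a 100-ms bin — and segments supra-threshold bins into events:
#' maximal runs of supra-threshold bins, with runs separated by no more than
#' `merge_gap_s` fused into one event. Returns per-electrode events and the
#' slice-level union (merged across on-SCN electrodes).
#'
#' @param rates Rate series from [bin_spikes()], binned at 100 ms.
#' @param threshold_hz Burst criterion (Hz, > 0).
#' @param merge_gap_s Sub-event gaps up to this length are bridged
#'   (default 0.5 s: bursts last seconds, so sub-second dips belong to the
#'   same event).
#' @return A `burst_catalog`: list with `events` (tibble `electrode`,
#'   `start_s`, `end_s`, `peak_rate_hz`), `merged_events` (slice level),
#'   `threshold_hz`, `bin_width_s`.
#' @export
detect_bursts <- function(rates, threshold_hz = 35, merge_gap_s = 0.5) {
  if (threshold_hz <= 0) abort("`threshold_hz` must be positive.")
  w <- rate_bin_width(rates)
  electrodes <- rate_scn(rates)

  events_one <- function(e) {
    sub <- rates[rates$electrode == e, ]
    sub <- sub[order(sub$t_s), ]
    flag <- sub$rate_hz > threshold_hz
    if (!any(flag)) {
      return(tibble(electrode = e, start_s = numeric(),
                    end_s = numeric(), peak_rate_hz = numeric()))
    }
    rr <- runs_true(flag)
    st <- sub$t_s[rr$start_idx]
    en <- sub$t_s[rr$end_idx] + w
    # fuse runs separated by <= merge_gap_s
    if (nrow(rr) > 1) {
      gap <- st[-1] - en[-length(en)]
      new_event <- c(TRUE, gap > merge_gap_s + 1e-9)
      grp <- cumsum(new_event)
      st <- tapply(st, grp, min)
      en <- tapply(en, grp, max)
    }
    pk <- vapply(seq_along(st), function(i) {
      max(sub$rate_hz[sub$t_s >= st[i] & sub$t_s < en[i]])
    }, numeric(1))
    tibble(electrode = e, start_s = as.numeric(st),
           end_s = as.numeric(en), peak_rate_hz = pk)
  }

  events <- bind_rows(purrr::map(electrodes, events_one))

  merged <- if (nrow(events)) {
    iv <- events[order(events$start_s), c("start_s", "end_s", "peak_rate_hz")]
    st <- iv$start_s; en <- iv$end_s; pk <- iv$peak_rate_hz
    ms <- st[1]; me <- en[1]; mp <- pk[1]
    out <- list()
    for (i in seq_along(st)[-1]) {
      if (st[i] <= me + merge_gap_s + 1e-9) {
        me <- max(me, en[i]); mp <- max(mp, pk[i])
      } else {
        out[[length(out) + 1]] <- c(ms, me, mp)
        ms <- st[i]; me <- en[i]; mp <- pk[i]
      }
    }
    out[[length(out) + 1]] <- c(ms, me, mp)
    m <- do.call(rbind, out)
    tibble(start_s = m[, 1], end_s = m[, 2], peak_rate_hz = m[, 3])
  } else {
    tibble(start_s = numeric(), end_s = numeric(), peak_rate_hz = numeric())
  }

  structure(
    list(events = events, merged_events = merged,
         threshold_hz = threshold_hz, bin_width_s = w,
         merge_gap_s = merge_gap_s),
    class = "burst_catalog"
  )
}

#' @export
print.burst_catalog <- function(x, ...) {
  cat("<burst_catalog>", nrow(x$events), "per-electrode events,",
      nrow(x$merged_events), "slice-level events ( >", x$threshold_hz, "Hz )\n")
  invisible(x)
}

#' @rdname detect_bursts
#' @param x A `burst_catalog`.
#' @param ... Unused.
#' @method tidy burst_catalog
#' @export
tidy.burst_catalog <- function(x, ...) x$events

#' @rdname detect_bursts
#' @method glance burst_catalog
#' @export
glance.burst_catalog <- function(x, ...) {
  gaps <- diff(x$merged_events$start_s)
  tibble(
    n_events = nrow(x$events),
    n_merged = nrow(x$merged_events),
    threshold_hz = x$threshold_hz,
    median_interval_s = if (length(gaps)) median(gaps) else NA_real_
  )
}

#' Two-band decomposition of the 1-min firing rhythm
#'
#' GABA-deficient slices show two distinct bands in the 1-min firing-rate
#' series: minutes containing burst firings (the high band) and minutes
#' without (the low band). Each 1-min bin of the slice-mean series is
#' classified as burst-containing iff it overlaps a slice-level catalog event;
#' band means and their difference are computed per 24-h segment.
#'
#' @param rates_1min Slice rate series binned at 60 s ([bin_spikes()]).
#' @param catalog A `burst_catalog` from the same recording (100-ms bins).
#' @param day_length_h Segment length for the per-day summary.
#' @return Tibble `day`, `mean_burst_band_hz`, `mean_nonburst_band_hz`,
#'   `band_gap_hz` (NA where a band is absent, e.g. wild type).
#' @export
band_decomposition <- function(rates_1min, catalog, day_length_h = 24) {
  w <- rate_bin_width(rates_1min)
  slice <- rates_1min |>
    filter(.data$electrode %in% rate_scn(rates_1min)) |>
    group_by(.data$t_s) |>
    summarise(rate_hz = mean(.data$rate_hz), .groups = "drop")

  ev <- catalog$merged_events
  in_burst <- rep(FALSE, nrow(slice))
  for (i in seq_len(nrow(ev))) {
    in_burst <- in_burst |
      (slice$t_s < ev$end_s[i] & slice$t_s + w > ev$start_s[i])
  }
  slice$burst_min <- in_burst
  slice$day <- floor(slice$t_s / (day_length_h * 3600)) + 1L

  slice |>
    group_by(.data$day) |>
    summarise(
      mean_burst_band_hz = if (any(.data$burst_min))
        mean(.data$rate_hz[.data$burst_min]) else NA_real_,
      mean_nonburst_band_hz = if (any(!.data$burst_min))
        mean(.data$rate_hz[!.data$burst_min]) else NA_real_,
      band_gap_hz = .data$mean_burst_band_hz - .data$mean_nonburst_band_hz,
      .groups = "drop"
    )
}

#' Pairwise synchrony matrix of electrode rate series
#'
#' Pearson correlation of 100-ms firing-rate series for all pairs of on-SCN
#' electrodes over a time window (the figure convention is 10 min at CT8).
#' Electrodes with zero variance in the window yield undefined pairs, which
#' are excluded from the off-diagonal mean.
#'
#' @param rates Rate series from [bin_spikes()] (100-ms bins).
#' @param window Length-2 numeric `(start_s, end_s)`; default full record.
#' @return A `correlation_matrix`: `cor` (matrix, electrodes x electrodes),
#'   `mean_offdiag`.
#' @export
synchrony_matrix <- function(rates, window = NULL) {
  w <- rate_bin_width(rates)
  if (is.null(window)) window <- c(min(rates$t_s), max(rates$t_s) + w)
  electrodes <- rate_scn(rates)
  if (length(electrodes) < 2) abort("Need at least 2 on-SCN electrodes.")

  sub <- rates[rates$electrode %in% electrodes &
                 rates$t_s >= window[1] & rates$t_s < window[2], ]
  wide <- tidyr::pivot_wider(sub, id_cols = "t_s", names_from = "electrode",
                             values_from = "rate_hz")
  m <- as.matrix(wide[, -1, drop = FALSE])
  keep_var <- apply(m, 2, stats::sd) > 0
  cc <- suppressWarnings(stats::cor(m))
  cc[!keep_var, ] <- NA_real_
  cc[, !keep_var] <- NA_real_
  diag(cc) <- 1
  off <- cc[upper.tri(cc)]
  structure(
    list(cor = cc, electrodes = colnames(m),
         mean_offdiag = mean(off, na.rm = TRUE),
         n_bins = nrow(m), window = window),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix>", length(x$electrodes), "electrodes; mean off-diagonal",
      sprintf("%.3f", x$mean_offdiag), "\n")
  invisible(x)
}

#' @rdname synchrony_matrix
#' @param x A `correlation_matrix`.
#' @param ... Unused.
#' @method tidy correlation_matrix
#' @export
tidy.correlation_matrix <- function(x, ...) {
  cc <- x$cor
  tibble(
    electrode_a = rep(rownames(cc) %||% seq_len(nrow(cc)), times = ncol(cc)),
    electrode_b = rep(colnames(cc) %||% seq_len(ncol(cc)), each = nrow(cc)),
    r = as.vector(cc)
  )
}

#' @rdname synchrony_matrix
#' @method glance correlation_matrix
#' @export
glance.correlation_matrix <- function(x, ...) {
  tibble(n_electrodes = length(x$electrodes), n_bins = x$n_bins,
         mean_offdiag = x$mean_offdiag)
}

#' Circadian phase profile of burst occurrence
#'
#' Counts supra-threshold 100-ms bins in 10-min windows centered at every
#' 4 circadian hours (CT0, 4, ..., 20), averages across cycles, and expresses
#' each window relative to the daily mean count. A flat profile (all values
#' near 1) indicates that bursts occur independently of circadian phase.
#'
#' @param catalog A `burst_catalog` (only `threshold_hz` is used; counting is
#'   done on `rates` so partial windows are handled exactly).
#' @param rates 100-ms rate series from [bin_spikes()].
#' @param per2_peak_time_s Time (s) of the PER2 reporter peak, which anchors
#'   CT12.
#' @param tau_h Circadian period (h) used for the CT axis.
#' @param window_min Window length (minutes) around each CT mark.
#' @param every_ct_h Spacing of the CT marks (h).
#' @return Tibble `ct_h`, `mean_count`, `rel_burst_count`, plus attribute
#'   `daily_mean`. If all counts are zero the profile is all-NA with attribute
#'   `daily_mean = 0`.
#' @export
burst_phase_profile <- function(catalog, rates, per2_peak_time_s, tau_h,
                                window_min = 10, every_ct_h = 4) {
  w <- rate_bin_width(rates)
  electrodes <- rate_scn(rates)
  slice_max <- rates |>
    filter(.data$electrode %in% electrodes) |>
    group_by(.data$t_s) |>
    summarise(rate_hz = max(.data$rate_hz), .groups = "drop")

  duration_s <- max(slice_max$t_s) + w
  tau_s <- tau_h * 3600
  half <- window_min * 60 / 2
  ct_marks <- seq(0, 24 - every_ct_h, by = every_ct_h)

  n_cycles <- floor(duration_s / tau_s)
  counts <- purrr::map(ct_marks, function(ct) {
    # time of CT `ct` in cycle k: anchor CT12 at per2 peak
    centers <- per2_peak_time_s + ((ct - 12) / 24) * tau_s + (0:(n_cycles)) * tau_s
    centers <- centers[centers - half >= 0 & centers + half <= duration_s]
    if (!length(centers)) return(NA_real_)
    per_cycle <- vapply(centers, function(ce) {
      sum(slice_max$rate_hz[slice_max$t_s >= ce - half &
                              slice_max$t_s < ce + half] > catalog$threshold_hz)
    }, numeric(1))
    mean(per_cycle)
  })
  counts <- unlist(counts)
  daily_mean <- mean(counts, na.rm = TRUE)
  rel <- if (is.finite(daily_mean) && daily_mean > 0) counts / daily_mean
         else rep(NA_real_, length(counts))
  out <- tibble(ct_h = ct_marks, mean_count = counts, rel_burst_count = rel)
  attr(out, "daily_mean") <- if (is.finite(daily_mean)) daily_mean else 0
  out
}
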