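#' Chi-square periodogram (Sokolove-Bushell)
#'
#' For each candidate period of P samples the evenly-sampled series is folded
#' into K = floor(N/P) complete cycles and
#' `Qp = N * Var(column means) / Var(series)` (population variances over the
#' N = K*P retained samples). Under the white-noise null Qp is approximately
#' chi-square with P - 1 degrees of freedom, giving the pointwise significance
#' line `qchisq(1 - alpha, P - 1)` (the oblique line of periodogram plots; no
#' multiplicity correction). The best period is chosen among supra-line
#' periods as the argmax of the normalized ratio `Qp / N` — the fraction of
#' variance carried by the folded waveform. Unlike raw Qp, the ratio does not
#' grow with the retained sample count N(P), which otherwise drags the argmax
#' of a broad low-noise peak toward longer periods.
#'
#' @param data Data frame with a time column (`t_s`, seconds) and a value
#'   column (`value`); even sampling required. Alternatively a numeric vector
#'   via `sample_interval_s`.
#' @param value Name of the value column (default `"value"`; `"rate_hz"` and
#'   `"count"` are detected automatically).
#' @param period_range_h Tested period range (h), default 20-28.
#' @param alpha Pointwise significance level (default 0.01).
#' @param sample_interval_s Sampling interval when `data` is a bare numeric
#'   vector.
#' @return A `periodogram` object: `table` (tibble `period_h`, `qp`, `sig`),
#'   `best_period_h` (NA if no supra-line period, with `arrhythmic = TRUE`),
#'   `qp_peak`, `alpha`.
#' @examples
#' t_s <- seq(0, 7 * 86400 - 600, by = 600)
#' x <- data.frame(t_s = t_s, value = cos(2 * pi * t_s / 86400))
#' chisq_periodogram(x)$best_period_h
#' @export
chisq_periodogram <- function(data, value = NULL, period_range_h = c(20, 28),
                              alpha = 0.01, sample_interval_s = NULL) {
  if (is.numeric(data) && is.null(dim(data))) {
    if (is.null(sample_interval_s)) {
      abort("Provide `sample_interval_s` for a bare numeric series.")
    }
    x <- as.numeric(data)
    dt <- sample_interval_s
  } else {
    value <- value %||% intersect(c("value", "rate_hz", "count"), names(data))[1]
    if (is.na(value)) abort("No value column found.")
    data <- data[order(data$t_s), ]
    dts <- diff(data$t_s)
    dt <- stats::median(dts)
    if (max(abs(dts - dt)) > dt * 1e-6) abort("Series must be evenly sampled.")
    x <- as.numeric(data[[value]])
  }
  n <- length(x)
  vx <- mean((x - mean(x))^2)
  p_lo <- ceiling(period_range_h[1] * 3600 / dt)
  p_hi <- floor(period_range_h[2] * 3600 / dt)
  if (p_hi < p_lo) abort("Period grid empty at this sampling interval.")
  if (n < 3 * p_hi) {
    abort("Need at least 3 cycles of data at the longest tested period.")
  }

  ps <- p_lo:p_hi
  if (vx == 0) {
    tab <- tibble(period_h = ps * dt / 3600, qp = 0,
                  sig = qchisq(1 - alpha, ps - 1))
    out <- list(table = tab, best_period_h = NA_real_, qp_peak = NA_real_,
                alpha = alpha, arrhythmic = TRUE, sample_interval_s = dt)
    class(out) <- "periodogram"
    return(out)
  }

  stat <- vapply(ps, function(p) {
    k <- n %/% p
    np <- k * p
    xs <- x[seq_len(np)]
    cm <- rowMeans(matrix(xs, nrow = p))
    ms <- mean(xs)
    ratio <- mean((cm - ms)^2) / mean((xs - ms)^2)
    c(np * ratio, ratio)
  }, numeric(2))
  qp <- stat[1, ]
  sig <- qchisq(1 - alpha, ps - 1)
  tab <- tibble(period_h = ps * dt / 3600, qp = qp, sig = sig)
  supra <- which(qp > sig)
  if (length(supra)) {
    best <- supra[which.max(stat[2, supra])]
    out <- list(table = tab, best_period_h = tab$period_h[best],
                qp_peak = qp[best], alpha = alpha, arrhythmic = FALSE,
                sample_interval_s = dt)
  } else {
    out <- list(table = tab, best_period_h = NA_real_, qp_peak = max(qp),
                alpha = alpha, arrhythmic = TRUE, sample_interval_s = dt)
  }
  class(out) <- "periodogram"
  out
}

#' @export
print.periodogram <- function(x, ...) {
  if (x$arrhythmic) {
    cat("<periodogram> no significant period (alpha =", x$alpha, ")\n")
  } else {
    cat("<periodogram> best period", sprintf("%.2f h", x$best_period_h),
        "Qp =", sprintf("%.1f", x$qp_peak), "\n")
  }
  invisible(x)
}

#' @rdname chisq_periodogram
#' @param x A `periodogram`.
#' @param ... Unused.
#' @method tidy periodogram
#' @export
tidy.periodogram <- function(x, ...) x$table

#' @rdname chisq_periodogram
#' @method glance periodogram
#' @export
glance.periodogram <- function(x, ...) {
  tibble(best_period_h = x$best_period_h, qp_peak = x$qp_peak,
         alpha = x$alpha, arrhythmic = x$arrhythmic)
}

#' Cosinor fit
#'
#' Least-squares fit of `M + A*cos(2*pi*(t - phi)/tau)`. With `tau_h` fixed
#' this is the closed-form linear regression on cosine and sine regressors;
#' with `tau_h = NULL` the period is profiled over `tau_range_h` (coarse grid
#' then golden-section refinement of the residual sum of squares). The
#' acrophase `phi` is the peak time of the fitted curve, wrapped to
#' `[0, tau)` hours.
#'
#' @param data Data frame with `t_s` and a value column, or numeric vector
#'   plus `sample_interval_s`.
#' @param tau_h Fixed period (h), or NULL to estimate.
#' @param value Value column name (auto-detected as in [chisq_periodogram()]).
#' @param tau_range_h Search range when `tau_h` is NULL.
#' @param sample_interval_s Sampling interval for bare numeric input.
#' @return A `cosinor_fit`: `mesor`, `amplitude`, `acrophase_h`, `tau_h`,
#'   `gof` (fraction of variance explained), `n`.
#' @export
cosinor_fit <- function(data, tau_h = NULL, value = NULL,
                        tau_range_h = c(20, 28), sample_interval_s = NULL) {
  if (is.numeric(data) && is.null(dim(data))) {
    if (is.null(sample_interval_s)) {
      abort("Provide `sample_interval_s` for a bare numeric series.")
    }
    t_s <- (seq_along(data) - 1) * sample_interval_s
    x <- as.numeric(data)
  } else {
    value <- value %||% intersect(c("value", "rate_hz", "count", "dff"),
                                  names(data))[1]
    if (is.na(value)) abort("No value column found.")
    t_s <- data$t_s
    x <- as.numeric(data[[value]])
  }
  ok <- is.finite(t_s) & is.finite(x)
  t_s <- t_s[ok]; x <- x[ok]
  if (length(x) < 4) abort("Fewer samples than parameters.")

  fit_at <- function(tau) {
    wt <- 2 * pi * t_s / (tau * 3600)
    X <- cbind(1, cos(wt), sin(wt))
    b <- qr.coef(qr(X), x)
    res <- x - X %*% b
    list(b = b, rss = sum(res^2))
  }

  if (is.null(tau_h)) {
    grid <- seq(tau_range_h[1], tau_range_h[2], by = 0.05)
    rss <- vapply(grid, function(g) fit_at(g)$rss, numeric(1))
    i <- which.min(rss)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- optimize(function(g) fit_at(g)$rss, c(lo, hi))
    tau_h <- opt$minimum
  }
  f <- fit_at(tau_h)
  b <- f$b
  amp <- sqrt(b[2]^2 + b[3]^2)
  # x ~ M + b2*cos(wt) + b3*sin(wt) = M + A*cos(w*(t - phi_s))
  phi_s <- atan2(b[3], b[2]) / (2 * pi) * tau_h * 3600
  tss <- sum((x - mean(x))^2)
  out <- list(
    mesor = unname(b[1]), amplitude = unname(amp),
    acrophase_h = (phi_s / 3600) %% tau_h,
    tau_h = tau_h, gof = if (tss > 0) 1 - f$rss / tss else NA_real_,
    n = length(x)
  )
  class(out) <- "cosinor_fit"
  out
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "<cosinor_fit> mesor %.3g, amplitude %.3g, acrophase %.2f h, tau %.2f h, R2 %.3f\n",
    x$mesor, x$amplitude, x$acrophase_h, x$tau_h, x$gof))
  invisible(x)
}

#' @rdname cosinor_fit
#' @param x A `cosinor_fit`.
#' @param ... Unused.
#' @method tidy cosinor_fit
#' @export
tidy.cosinor_fit <- function(x, ...) {
  tibble(
    term = c("mesor", "amplitude", "acrophase_h", "tau_h"),
    estimate = c(x$mesor, x$amplitude, x$acrophase_h, x$tau_h)
  )
}

#' @rdname cosinor_fit
#' @method glance cosinor_fit
#' @export
glance.cosinor_fit <- function(x, ...) {
  tibble(mesor = x$mesor, amplitude = x$amplitude,
         acrophase_h = x$acrophase_h, tau_h = x$tau_h,
         gof = x$gof, n = x$n)
}

#' Rayleigh circular statistics of a phase sample
#'
#' Maps phases (hours modulo `tau_h`) to angles `theta = 2*pi*phase/tau` and
#' returns the circular mean and the mean vector length
#' `r = |sum(exp(i*theta))| / n`, the standard concentration measure for
#' acrophase maps: r = 1 for perfect synchrony, r near 0 for uniform
#' dispersion.
#'
#' @param phases_h Numeric vector of phases in hours.
#' @param tau_h Period (h) defining the circle.
#' @return A `rayleigh` object: `n`, `mean_angle_h` in `[0, tau)`, `r`.
#' @export
rayleigh_stats <- function(phases_h, tau_h) {
  phases_h <- phases_h[is.finite(phases_h)]
  if (!length(phases_h)) abort("Empty phase sample.")
  theta <- 2 * pi * phases_h / tau_h
  cm <- mean(cos(theta)); sm <- mean(sin(theta))
  r <- sqrt(cm^2 + sm^2)
  mean_angle <- (atan2(sm, cm) / (2 * pi) * tau_h) %% tau_h
  structure(list(n = length(phases_h), mean_angle_h = mean_angle, r = r),
            class = "rayleigh")
}

#' @export
print.rayleigh <- function(x, ...) {
  cat(sprintf("<rayleigh> n = %d, mean angle %.2f h, r = %.3f\n",
              x$n, x$mean_angle_h, x$r))
  invisible(x)
}

#' @rdname rayleigh_stats
#' @param x A `rayleigh` object.
#' @param ... Unused.
#' @method glance rayleigh
#' @export
glance.rayleigh <- function(x, ...) {
  tibble(n = x$n, mean_angle_h = x$mean_angle_h, r = x$r)
}

#' Per-cycle standardized amplitude and damping ratio
#'
#' The series is smoothed with a centered moving average (default 2 h, which
#' removes burst-band contamination without materially shifting circadian
#' phase), cut into consecutive cycles of length `tau_h`, and for each cycle
#' the standardized amplitude `(peak - trough) / peak` is computed from the
#' smoothed values. The damping ratio is the standardized amplitude of cycle
#' `damping_cycles` divided by that of cycle 1 (the first-six-cycles
#' convention gives `damping_cycles = 6`).
#'
#' @param data Data frame with `t_s` and a value column, or numeric vector
#'   plus `sample_interval_s`.
#' @param tau_h Cycle length (h).
#' @param value Value column name.
#' @param smooth_h Moving-average window (h); 0 disables smoothing.
#' @param damping_cycles Cycle whose amplitude is referenced to cycle 1.
#' @param sample_interval_s Sampling interval for bare numeric input.
#' @return An `amplitude_metrics` object: `cycles` tibble (`cycle`, `peak`,
#'   `trough`, `standardized_amplitude`), `damping_ratio` (NA when a needed
#'   cycle is missing or a peak is non-positive, flagged via `undefined`).
#' @export
amplitude_metrics <- function(data, tau_h, value = NULL, smooth_h = 2,
                              damping_cycles = 6, sample_interval_s = NULL) {
  if (is.numeric(data) && is.null(dim(data))) {
    if (is.null(sample_interval_s)) {
      abort("Provide `sample_interval_s` for a bare numeric series.")
    }
    t_s <- (seq_along(data) - 1) * sample_interval_s
    x <- as.numeric(data)
  } else {
    value <- value %||% intersect(c("value", "rate_hz", "count", "dff"),
                                  names(data))[1]
    t_s <- data$t_s
    x <- as.numeric(data[[value]])
    sample_interval_s <- stats::median(diff(sort(t_s)))
  }
  if (smooth_h > 0) {
    k <- max(1L, round(smooth_h * 3600 / sample_interval_s))
    if (k %% 2 == 0) k <- k + 1L
    if (k > 1 && k <= length(x)) {
      sm <- stats::filter(x, rep(1 / k, k), sides = 2)
      # keep edges unsmoothed rather than NA
      x <- ifelse(is.na(sm), x, as.numeric(sm))
    }
  }
  cyc <- floor(t_s / (tau_h * 3600)) + 1L
  cycles <- tibble(t_s = t_s, x = x, cycle = cyc) |>
    group_by(.data$cycle) |>
    summarise(peak = max(.data$x), trough = min(.data$x), .groups = "drop") |>
    mutate(standardized_amplitude = ifelse(
      .data$peak > 0, (.data$peak - .data$trough) / .data$peak, NA_real_))
  # drop a trailing partial cycle
  full <- floor((max(t_s) + sample_interval_s) / (tau_h * 3600))
  cycles <- cycles[cycles$cycle <= full, ]

  sa <- function(k) {
    v <- cycles$standardized_amplitude[cycles$cycle == k]
    if (length(v)) v else NA_real_
  }
  dr <- sa(damping_cycles) / sa(1)
  structure(
    list(cycles = cycles, damping_ratio = unname(dr),
         undefined = !is.finite(dr), tau_h = tau_h),
    class = "amplitude_metrics"
  )
}

#' @export
print.amplitude_metrics <- function(x, ...) {
  cat("<amplitude_metrics>", nrow(x$cycles), "cycles; damping ratio",
      sprintf("%.3f", x$damping_ratio), "\n")
  invisible(x)
}

#' @rdname amplitude_metrics
#' @param x An `amplitude_metrics` object.
#' @param ... Unused.
#' @method tidy amplitude_metrics
#' @export
tidy.amplitude_metrics <- function(x, ...) x$cycles

#' @rdname amplitude_metrics
#' @method glance amplitude_metrics
#' @export
glance.amplitude_metrics <- function(x, ...) {
  tibble(n_cycles = nrow(x$cycles), damping_ratio = x$damping_ratio,
         undefined = x$undefined)
}

#' Convert recording time to circadian time
#'
#' CT12 is anchored at the PER2 reporter peak:
#' `CT(t) = (12 + 24 * (t - per2_peak) / (3600 * tau_h)) %% 24`.
#'
#' @param time_s Time(s) in seconds from recording start.
#' @param per2_peak_time_s PER2 peak anchor (s); must be finite.
#' @param tau_h Circadian period (h).
#' @return CT in hours, in `[0, 24)`.
#' @examples
#' to_ct(3600, 3600, 24)  # the anchor itself is CT12
#' @export
to_ct <- function(time_s, per2_peak_time_s, tau_h) {
  if (is.null(per2_peak_time_s) || !all(is.finite(per2_peak_time_s))) {
    abort("A PER2 peak anchor is required.")
  }
  (12 + 24 * (time_s - per2_peak_time_s) / (3600 * tau_h)) %% 24
}
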