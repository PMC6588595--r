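#' Pixel-level acrophase map of a bioluminescence image stack
#'
#' Fits a fixed-period cosinor to every pixel trace (a single slice-level
#' period stabilizes per-pixel fits), masks pixels whose fit explains less
#' than `gof_min` of the variance, and expresses phases relative to the
#' circular mean acrophase of the masked pixels.
#'
#' @param stack An [image_stack()] spanning at least 2 cycles.
#' @param tau_h Period (h) used for all pixels (slice-level estimate).
#' @param gof_min Minimum fraction of variance explained for a pixel to count
#'   as rhythmic (default 0.1).
#' @return An `acrophase_map`: matrices `acrophase_h`, `gof`, `relative_h`
#'   (signed circular offset from the slice mean, in `(-tau/2, tau/2]`),
#'   logical `mask`, `tau_h`, `mean_phase_h`.
#' @export
pixel_acrophase_map <- function(stack, tau_h, gof_min = 0.1) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  tt <- frame_times(stack)
  if (max(tt) - min(tt) < 2 * tau_h * 3600) {
    abort("Stack must span at least 2 cycles.")
  }
  y <- matrix(stack$frames, nrow = d[1])  # frames x pixels
  wt <- 2 * pi * tt / (tau_h * 3600)
  X <- cbind(1, cos(wt), sin(wt))
  b <- qr.coef(qr(X), y)                 # 3 x pixels
  res <- y - X %*% b
  rss <- colSums(res^2)
  tss <- colSums(sweep(y, 2, colMeans(y))^2)
  gof <- ifelse(tss > 0, 1 - rss / tss, 0)
  phase_h <- (atan2(b[3, ], b[2, ]) / (2 * pi) * tau_h) %% tau_h
  mask <- gof >= gof_min
  if (!any(mask)) abort("All pixels below the goodness-of-fit threshold.")

  mean_phase <- rayleigh_stats(phase_h[mask], tau_h)$mean_angle_h
  rel <- (phase_h - mean_phase + tau_h / 2) %% tau_h - tau_h / 2
  rel[!mask] <- NA_real_
  ph <- phase_h; ph[!mask] <- NA_real_

  structure(
    list(
      acrophase_h = matrix(ph, d[2], d[3]),
      gof = matrix(gof, d[2], d[3]),
      relative_h = matrix(rel, d[2], d[3]),
      mask = matrix(mask, d[2], d[3]),
      tau_h = tau_h, mean_phase_h = mean_phase
    ),
    class = "acrophase_map"
  )
}

#' @export
print.acrophase_map <- function(x, ...) {
  cat("<acrophase_map>", sum(x$mask), "rhythmic pixels of", length(x$mask),
      sprintf("; slice mean phase %.2f h (tau %.2f h)\n", x$mean_phase_h, x$tau_h))
  invisible(x)
}

#' @rdname pixel_acrophase_map
#' @param x An `acrophase_map`.
#' @param ... Unused.
#' @method tidy acrophase_map
#' @export
tidy.acrophase_map <- function(x, ...) {
  d <- dim(x$acrophase_h)
  tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    acrophase_h = as.vector(x$acrophase_h),
    relative_h = as.vector(x$relative_h),
    gof = as.vector(x$gof),
    rhythmic = as.vector(x$mask)
  )
}

#' @rdname pixel_acrophase_map
#' @method glance acrophase_map
#' @export
glance.acrophase_map <- function(x, ...) {
  rs <- rayleigh_stats(x$acrophase_h[x$mask], x$tau_h)
  tibble(n_pixels = length(x$mask), n_rhythmic = sum(x$mask),
         mean_phase_h = x$mean_phase_h, rayleigh_r = rs$r)
}

#' Rayleigh statistics of an acrophase map
#'
#' Convenience wrapper: [rayleigh_stats()] on the rhythmic-pixel phases of an
#' [pixel_acrophase_map()] result, as used for slice-level synchrony (mean
#' vector length r).
#'
#' @param map An `acrophase_map`.
#' @return A `rayleigh` object.
#' @export
acrophase_rayleigh <- function(map) {
  rayleigh_stats(map$acrophase_h[map$mask], map$tau_h)
}

#' Line scan (kymograph) through an image stack
#'
#' Samples intensity along a pixel path for every frame, preserving the path
#' order (dorsal first when the path runs dorsal to ventral, since row 1 is
#' dorsal). With `width > 1` each position averages over a perpendicular band
#' of that many pixels.
#'
#' @param stack An [image_stack()].
#' @param line Two-column matrix or data frame of (row, col) pixel
#'   coordinates, in path order.
#' @param width Band width in pixels (odd; averaged across columns for a
#'   vertical path and across rows otherwise).
#' @return A `kymograph`: `intensity` (position x time matrix), `positions`,
#'   `t_s`.
#' @export
line_scan <- function(stack, line, width = 1) {
  stopifnot(inherits(stack, "image_stack"))
  line <- as.matrix(line)
  d <- dim(stack$frames)
  if (any(line[, 1] < 1 | line[, 1] > d[2] | line[, 2] < 1 | line[, 2] > d[3])) {
    abort("Line path out of image bounds.")
  }
  half <- (width - 1) %/% 2
  vertical <- length(unique(line[, 2])) >= length(unique(line[, 1]))
  mat <- matrix(NA_real_, nrow(line), d[1])
  for (i in seq_len(nrow(line))) {
    r <- line[i, 1]; c <- line[i, 2]
    if (vertical) {
      cs <- max(1, c - half):min(d[3], c + half)
      mat[i, ] <- rowMeans(stack$frames[, r, cs, drop = FALSE])
    } else {
      rs <- max(1, r - half):min(d[2], r + half)
      mat[i, ] <- rowMeans(stack$frames[, rs, c, drop = FALSE])
    }
  }
  structure(
    list(intensity = mat, positions = seq_len(nrow(line)),
         t_s = frame_times(stack), line = line),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  cat("<kymograph>", nrow(x$intensity), "positions x", ncol(x$intensity),
      "frames\n")
  invisible(x)
}

#' @rdname line_scan
#' @param x A `kymograph`.
#' @param ... Unused.
#' @method tidy kymograph
#' @export
tidy.kymograph <- function(x, ...) {
  tibble(
    position = rep(x$positions, times = length(x$t_s)),
    t_s = rep(x$t_s, each = length(x$positions)),
    intensity = as.vector(x$intensity)
  )
}

#' Mean intensity time series over a region of interest
#'
#' @param stack An [image_stack()].
#' @param mask Logical H x W matrix selecting the ROI; default whole frame.
#' @return Tibble `t_s`, `value` (per-frame mean over the mask).
#' @export
roi_series <- function(stack, mask = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  if (is.null(mask)) mask <- matrix(TRUE, d[2], d[3])
  if (!any(mask)) abort("Empty ROI mask.")
  y <- matrix(stack$frames, nrow = d[1])
  tibble(t_s = frame_times(stack), value = rowMeans(y[, as.vector(mask), drop = FALSE]))
}

#' Detect calcium transients in a fluorescence trace
#'
#' Baseline-corrects each trace with a running median (window at least 10x the
#' typical transient duration), flags samples whose residual exceeds
#' `k` times the MAD of the residual, and groups contiguous supra-threshold
#' samples into events. dF/F amplitudes are defined against the running-median
#' baseline.
#'
#' @param traces Tibble with `t_s`, `dff`, optionally `roi` (e.g. from
#'   [gen_calcium_traces()]).
#' @param k Detection threshold in MAD units (default 4).
#' @param baseline_window_s Running-median window (s); default 60.
#' @return Tibble `roi`, `onset_s`, `amplitude_dff`, `duration_s`.
#' @export
detect_ca_spikes <- function(traces, k = 4, baseline_window_s = 60) {
  if (!"roi" %in% names(traces)) traces$roi <- 1L
  dt <- stats::median(diff(sort(unique(traces$t_s))))
  win <- max(3L, round(baseline_window_s / dt))
  if (win %% 2 == 0) win <- win + 1L

  one <- function(sub) {
    sub <- sub[order(sub$t_s), ]
    x <- sub$dff
    if (length(x) < 10) abort("Trace must have at least 10 samples.")
    # reflect-pad so events at the trace edges keep a robust local baseline
    kw <- min(win, if (length(x) %% 2 == 0) length(x) - 1 else length(x))
    pad <- min(kw, length(x) - 1)
    xp <- c(x[(pad + 1):2], x, x[(length(x) - 1):(length(x) - pad)])
    base <- runmed(xp, kw)[(pad + 1):(pad + length(x))]
    resid <- x - base
    # noise scale from first differences: unbiased for iid noise, robust to
    # both the slow baseline and sparse transients (mad(resid) is biased low
    # because the running median absorbs part of each point's own noise).
    # The residual x - median(window) has null SD sigma * sqrt(1 + pi/(2m)),
    # so the k-sigma rule is calibrated against that inflated scale.
    s <- mad(diff(x)) / sqrt(2) * sqrt(1 + pi / (2 * kw))
    if (s == 0) {
      return(tibble(roi = sub$roi[1], onset_s = numeric(),
                    amplitude_dff = numeric(), duration_s = numeric()))
    }
    flag <- resid > k * s
    if (!any(flag)) {
      return(tibble(roi = sub$roi[1], onset_s = numeric(),
                    amplitude_dff = numeric(), duration_s = numeric()))
    }
    rr <- runs_true(flag)
    tibble(
      roi = sub$roi[1],
      onset_s = sub$t_s[rr$start_idx],
      amplitude_dff = vapply(seq_len(nrow(rr)), function(i) {
        max(resid[rr$start_idx[i]:rr$end_idx[i]])
      }, numeric(1)),
      duration_s = (rr$end_idx - rr$start_idx + 1) * dt
    )
  }
  bind_rows(purrr::map(split(traces, traces$roi), one))
}

#' Coincidence between calcium transients and burst events
#'
#' Fraction of calcium-event onsets lying within `tol_s` of a slice-level
#' burst event (start-to-onset distance), and vice versa. Events detected on
#' multiple ROIs are reduced to unique onset times first.
#'
#' @param events Calcium event tibble from [detect_ca_spikes()].
#' @param catalog A `burst_catalog`.
#' @param tol_s Temporal tolerance (s).
#' @return Tibble `frac_ca_near_burst`, `frac_burst_near_ca` (NA when the
#'   corresponding list is empty), `n_ca_events`, `n_burst_events`.
#' @export
burst_ca_coincidence <- function(events, catalog, tol_s = 2) {
  ca_on <- sort(unique(round(events$onset_s, 6)))
  # collapse near-simultaneous multi-ROI detections of the same transient
  if (length(ca_on) > 1) {
    ca_on <- ca_on[c(TRUE, diff(ca_on) > tol_s)]
  }
  bu_on <- catalog$merged_events$start_s
  near <- function(a, b) {
    if (!length(a) || !length(b)) return(NA_real_)
    mean(vapply(a, function(t) any(abs(b - t) <= tol_s), logical(1)))
  }
  tibble(
    frac_ca_near_burst = near(ca_on, bu_on),
    frac_burst_near_ca = near(bu_on, ca_on),
    n_ca_events = length(ca_on),
    n_burst_events = length(bu_on)
  )
}
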