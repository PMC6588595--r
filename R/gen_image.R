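#' Construct an image stack object
#'
#' Light container for a time-ordered stack of raster frames with acquisition
#' metadata. Frames are stored as a numeric array `[frame, row, col]`; row 1
#' is the dorsal edge by convention, which fixes the orientation of line scans.
#'
#' @param frames Numeric array `T x H x W` (T >= 2).
#' @param frame_interval_s Uniform frame interval in seconds.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param t0_s Acquisition time of the first frame (s from recording start).
#' @return An `image_stack` object.
#' @export
image_stack <- function(frames, frame_interval_s, pixel_size_um = NA_real_,
                        t0_s = 0) {
  stopifnot(is.array(frames), length(dim(frames)) == 3, dim(frames)[1] >= 2,
            frame_interval_s > 0)
  structure(
    list(frames = frames, frame_interval_s = frame_interval_s,
         pixel_size_um = pixel_size_um, t0_s = t0_s),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("<image_stack>", d[1], "frames of", d[2], "x", d[3], "px,",
      "frame interval", x$frame_interval_s, "s\n")
  invisible(x)
}

# Frame acquisition times (s)
frame_times <- function(stack) {
  stack$t0_s + (seq_len(dim(stack$frames)[1]) - 1) * stack$frame_interval_s
}

#' @describeIn image_stack Long tibble of pixel intensities
#'   (`frame`, `t_s`, `row`, `col`, `value`).
#' @param x An `image_stack`.
#' @param ... Unused.
#' @method tidy image_stack
#' @export
tidy.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  tibble(
    frame = rep(seq_len(d[1]), times = d[2] * d[3]),
    t_s = rep(frame_times(x), times = d[2] * d[3]),
    row = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    col = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(x$frames)
  )
}

#' Generate a synthetic bioluminescence reporter image stack
#'
#' Emulates pixel-level PER2 reporter rhythms: pixel i emits
#' `M + A * d^(t/tau) * cos(2*pi*(t - phi_i)/tau) + noise`, where the per-pixel
#' acrophase `phi_i` is wrapped-normal around the slice mean phase with SD
#' `img_phase_sd_h`, and `d` is the amplitude damping factor per cycle. The
#' slice mean acrophase is the PER2 peak time implied by the configuration's
#' CT convention (CT12 at t = (4/24) * period).
#'
#' @param cfg A [gen_config()] object.
#' @return An [image_stack()] whose `true_phase_h` attribute carries the
#'   per-pixel acrophases (hours) used in simulation.
#' @export
gen_image_stack <- function(cfg) {
  validate_gen_config(cfg)
  tau_s <- cfg$img_period_h * 3600
  duration_s <- cfg$duration_h * 3600
  if (duration_s < 2 * cfg$img_frame_interval_s) {
    abort("Recording too short for an image stack.", class = "scnburst_config_error")
  }
  n_frames <- floor(duration_s / cfg$img_frame_interval_s)
  tt <- (seq_len(n_frames) - 1) * cfg$img_frame_interval_s
  h <- cfg$img_dims[1]; w <- cfg$img_dims[2]

  set.seed(split_seed(cfg$seed, 2L))
  phi_s <- (per2_peak_time_s(cfg) + rnorm(h * w, 0, cfg$img_phase_sd_h * 3600)) %% tau_s
  damp <- cfg$img_damping_per_cycle ^ (tt / tau_s)
  # frames[t, pixel] built by outer products, then reshaped
  ang <- outer(tt, phi_s, function(t, p) cos(2 * pi * (t - p) / tau_s))
  vals <- cfg$img_mesor + cfg$img_amplitude * damp * ang
  if (cfg$img_noise_sd > 0) {
    vals <- vals + rnorm(length(vals), 0, cfg$img_noise_sd)
  }
  frames <- array(vals, dim = c(n_frames, h, w))
  out <- image_stack(frames, cfg$img_frame_interval_s, cfg$img_pixel_size_um)
  attr(out, "true_phase_h") <- matrix(phi_s / 3600, nrow = h, ncol = w)
  out
}

#' Generate synthetic calcium traces
#'
#' Per-ROI calcium fluorescence (dF/F-like units): a circadian baseline
#' aligned with the firing rhythm plus, for each burst-schedule event, a
#' transient with one-frame rise and exponential decay (`ca_decay_s`), plus
#' Gaussian noise. The transient amplitude is at least 5x the noise SD by
#' configuration, matching the large calcium spikes that accompany bursts.
#'
#' @param cfg A [gen_config()] object.
#' @param schedule Burst schedule from [gen_burst_schedule()] (same slice).
#' @return A tibble `roi`, `t_s`, `dff`, with attribute `frame_interval_s`.
#' @export
gen_calcium_traces <- function(cfg, schedule = gen_burst_schedule(cfg)) {
  validate_gen_config(cfg)
  duration_s <- cfg$duration_h * 3600
  tt <- seq(0, duration_s - cfg$ca_frame_interval_s, by = cfg$ca_frame_interval_s)
  tau_s <- cfg$circadian_period_h * 3600
  baseline <- 1 + 0.3 * cos(2 * pi * tt / tau_s)

  transient <- numeric(length(tt))
  for (i in seq_len(nrow(schedule))) {
    on <- schedule$start_s[i]
    after <- tt >= on
    transient[after] <- transient[after] +
      cfg$ca_transient_amp * exp(-(tt[after] - on) / cfg$ca_decay_s)
  }

  set.seed(split_seed(cfg$seed, 3L))
  out <- purrr::map(seq_len(cfg$ca_n_rois), function(r) {
    noise <- if (cfg$ca_noise_sd > 0) rnorm(length(tt), 0, cfg$ca_noise_sd) else 0
    tibble(roi = r, t_s = tt, dff = baseline + transient + noise)
  })
  out <- bind_rows(out)
  attr(out, "frame_interval_s") <- cfg$ca_frame_interval_s
  out
}
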