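#' Read and write spike trains as tab-separated text
#'
#' The on-disk format is two tab-separated columns, `electrode_id` and
#' `time_s`, with a header row.
#'
#' @param trains Tibble `electrode`, `time_s`.
#' @param path File path.
#' @param duration_s Recording length recorded for round-tripping (written as
#'   a `# duration_s:` comment line).
#' @return `write_spike_trains()` returns `path` invisibly;
#'   `read_spike_trains()` returns the trains tibble with its `duration_s`
#'   attribute restored when present.
#' @export
write_spike_trains <- function(trains, path, duration_s = NULL) {
  duration_s <- duration_s %||% attr(trains, "duration_s")
  df <- tibble(electrode_id = trains$electrode, time_s = trains$time_s)
  if (!is.null(duration_s)) {
    writeLines(sprintf("# duration_s: %.10g", duration_s), path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  first <- readLines(path, n = 1)
  duration_s <- NULL
  if (startsWith(first, "# duration_s:")) {
    duration_s <- as.numeric(sub("# duration_s:", "", first))
  }
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  out <- tibble(electrode = df$electrode_id, time_s = df$time_s)
  if (!is.null(duration_s)) attr(out, "duration_s") <- duration_s
  attr(out, "scn_mask") <- sort(unique(out$electrode))
  out
}

#' Read and write image stacks as multi-frame TIFF with a YAML sidecar
#'
#' Frames are written as 32-bit float TIFF pages scaled to `[0, 1]`; the
#' scaling constants and acquisition metadata (`frame_interval_s`,
#' `pixel_size_um`, `t0_s`) go to `<path>.yml`, so the round trip is exact up
#' to float precision.
#'
#' @param stack An [image_stack()].
#' @param path TIFF path; the sidecar is written next to it.
#' @return `write_image_stack()` returns `path` invisibly;
#'   `read_image_stack()` an [image_stack()].
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  lo <- min(stack$frames); hi <- max(stack$frames)
  scale <- if (hi > lo) hi - lo else 1
  pages <- purrr::map(seq_len(dim(stack$frames)[1]), function(i) {
    (stack$frames[i, , ] - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  yaml::write_yaml(
    list(frame_interval_s = stack$frame_interval_s,
         pixel_size_um = stack$pixel_size_um,
         t0_s = stack$t0_s,
         intensity_offset = lo, intensity_scale = scale),
    paste0(path, ".yml")
  )
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- dim(pages[[1]])
  frames <- array(NA_real_, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) {
    frames[i, , ] <- pages[[i]] * meta$intensity_scale + meta$intensity_offset
  }
  image_stack(frames, meta$frame_interval_s,
              meta$pixel_size_um %||% NA_real_, meta$t0_s %||% 0)
}

#' Read and write actograms as CSV
#'
#' Columns: `t_min`, `count`, `light_state`.
#'
#' @param act Actogram tibble.
#' @param path File path.
#' @return `write_actogram()` returns `path` invisibly; `read_actogram()` the
#'   tibble.
#' @export
write_actogram <- function(act, path) {
  readr::write_csv(act, path)
  invisible(path)
}

#' @rdname write_actogram
#' @export
read_actogram <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read and write calcium traces as CSV
#'
#' Columns: `roi`, `t_s`, `dff`.
#'
#' @param traces Calcium trace tibble.
#' @param path File path.
#' @return `write_calcium_traces()` returns `path` invisibly;
#'   `read_calcium_traces()` the tibble.
#' @export
write_calcium_traces <- function(traces, path) {
  readr::write_csv(traces, path)
  invisible(path)
}

#' @rdname write_calcium_traces
#' @export
read_calcium_traces <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  attr(out, "frame_interval_s") <- stats::median(diff(sort(unique(out$t_s))))
  out
}
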