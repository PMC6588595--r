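#' @importFrom ggplot2 ggplot aes geom_line geom_col geom_tile geom_point
#'   geom_step geom_segment labs scale_fill_viridis_c scale_fill_gradient2
#'   coord_polar theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot a chi-square periodogram
#'
#' Qp against candidate period with the pointwise significance line.
#'
#' @param object A `periodogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot periodogram
#' @export
autoplot.periodogram <- function(object, ...) {
  ggplot(object$table, aes(x = .data$period_h)) +
    geom_line(aes(y = .data$qp)) +
    geom_line(aes(y = .data$sig), colour = "red") +
    labs(x = "Period (h)", y = expression(Q[p]),
         title = if (object$arrhythmic) "No significant period"
                 else sprintf("Best period %.2f h", object$best_period_h)) +
    theme_minimal()
}

#' Plot a bin-ratio distribution
#'
#' Percentage of 100-ms bins per firing-rate class; the 35-Hz burst criterion
#' is marked.
#'
#' @param object A `bin_ratio_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bin_ratio_distribution
#' @export
autoplot.bin_ratio_distribution <- function(object, ...) {
  ggplot(object$table, aes(x = .data$freq_lo_hz, y = .data$pct)) +
    geom_col(width = diff(object$table$freq_lo_hz[1:2]) * 0.9,
             just = 0, fill = "grey30") +
    ggplot2::geom_vline(xintercept = object$threshold_hz,
                        linetype = "dashed", colour = "red") +
    labs(x = "Firing rate (Hz)", y = "Bins (%)",
         subtitle = sprintf("%.2f%% of bins above %g Hz",
                            object$frac_above_pct, object$threshold_hz)) +
    theme_minimal()
}

#' Plot a synchrony matrix
#'
#' Heat map of pairwise Pearson correlations between electrode rate series.
#'
#' @param object A `correlation_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot correlation_matrix
#' @export
autoplot.correlation_matrix <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$electrode_a, y = .data$electrode_b,
                           fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL,
         subtitle = sprintf("Mean off-diagonal r = %.2f", object$mean_offdiag)) +
    theme_minimal()
}

#' Plot an acrophase map
#'
#' Per-pixel acrophase relative to the slice circular mean (pseudocolor);
#' non-rhythmic pixels blank. Row 1 (dorsal) is drawn at the top.
#'
#' @param object An `acrophase_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot acrophase_map
#' @export
autoplot.acrophase_map <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$col, y = -.data$row,
                           fill = .data$relative_h)) +
    geom_tile() +
    scale_fill_gradient2(name = "Phase - mean (h)") +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot a kymograph
#'
#' Position x time intensity map from a line scan.
#'
#' @param object A `kymograph`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kymograph
#' @export
autoplot.kymograph <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$t_s, y = -.data$position,
                           fill = .data$intensity)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "Time (s)", y = "Position (dorsal at top)") +
    theme_minimal()
}

#' Double-plotted actogram
#'
#' Classic raster: each row shows two consecutive days; bar height encodes the
#' 1-min activity count.
#'
#' @param act Actogram tibble (`t_min`, `count`).
#' @param day_h Row length in hours (24 by default; rows show `2 * day_h`).
#' @return A ggplot.
#' @export
plot_actogram <- function(act, day_h = 24) {
  day_min <- day_h * 60
  df <- act |>
    mutate(day = floor(.data$t_min / day_min),
           tod_h = (.data$t_min %% day_min) / 60)
  df2 <- df |> mutate(day = .data$day - 1, tod_h = .data$tod_h + day_h)
  both <- bind_rows(df, df2) |> filter(.data$day >= 0, .data$count > 0)
  ggplot(both, aes(x = .data$tod_h, y = -.data$day, height = 0.8,
                   alpha = .data$count)) +
    geom_tile(fill = "black", width = 1 / 60) +
    ggplot2::scale_alpha_continuous(range = c(0.3, 1), guide = "none") +
    labs(x = "Time (h, double plot)", y = "Day") +
    theme_minimal()
}
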