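#' Plot an axial slice of a voxel grid
#'
#' @param object A [voxel_grid()].
#' @param slice Slice index along the third axis (default: middle).
#' @param ... Unused.
#' @return A ggplot raster of the slice in mm coordinates.
#' @export
autoplot.voxel_grid <- function(object, slice = NULL, ...) {
  d <- dim(object$data)
  slice <- slice %||% ((d[3] + 1) %/% 2)
  df <- tidyr::expand_grid(i = seq_len(d[1]), j = seq_len(d[2])) |>
    dplyr::mutate(x = (.data$i - 1) * object$spacing[1],
                  y = (.data$j - 1) * object$spacing[2],
                  value = as.numeric(object$data[cbind(.data$i, .data$j,
                                                       slice)]))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("slice z = %d", slice))
}

#' Plot a pseudodiffusivity map slice
#'
#' @param object A `pdiff_map`.
#' @param slice Slice index along the third axis (default: middle).
#' @param ... Unused.
#' @return A ggplot raster of voxel D* (mm2/s).
#' @export
autoplot.pdiff_map <- function(object, slice = NULL, ...) {
  g <- voxel_grid(object$d_star, object$spacing)
  autoplot.voxel_grid(g, slice = slice) +
    ggplot2::labs(fill = "D* (mm2/s)", title = "pseudodiffusivity")
}

#' Heatmap of inter-regional MPD correlations
#'
#' @param object A `cbss_cor`.
#' @param ... Unused.
#' @return A ggplot tile plot of the correlation matrix.
#' @export
autoplot.cbss_cor <- function(object, ...) {
  regs <- rownames(object$r)
  df <- tidyr::expand_grid(region1 = regs, region2 = regs) |>
    dplyr::mutate(r = as.numeric(object$r[cbind(
      match(.data$region1, regs), match(.data$region2, regs))]))
  ggplot2::ggplot(df, ggplot2::aes(.data$region1, .data$region2,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r")
}

#' Forest plot of adjusted associations
#'
#' Standardized slopes with 95% confidence bars, marking predictors that
#' survive BH adjustment.
#'
#' @param object A `cbss_association`.
#' @param alpha Significance level on the adjusted p-values.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cbss_association <- function(object, alpha = 0.05, ...) {
  df <- object$results |>
    dplyr::mutate(sig = .data$p_adj < alpha,
                  lo = .data$slope - 1.96 * .data$se,
                  hi = .data$slope + 1.96 * .data$se)
  ggplot2::ggplot(df, ggplot2::aes(.data$slope,
                                   stats::reorder(.data$predictor,
                                                  .data$slope),
                                   color = .data$sig)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = sprintf("standardized slope on %s",
                              df$outcome[1]),
                  y = NULL, color = sprintf("BH p < %g", alpha))
}

#' Ventricular zone MPD profile
#'
#' MPD against distance zone for the lateral and third ventricles, one
#' line per subject, highlighting the gradient away from the start of the
#' third ventricle.
#'
#' @param zone_tables Tibble from [run_cbss()] (`zone_tables`) or a single
#'   [zone_mpd()] table; a `subject` column is optional.
#' @return A ggplot.
#' @export
plot_zone_profile <- function(zone_tables) {
  df <- zone_tables
  if (!"subject" %in% names(df)) df$subject <- 1L
  ggplot2::ggplot(df, ggplot2::aes(.data$zone, .data$mpd,
                                   group = .data$subject)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", linewidth = 1.2,
                          color = "firebrick") +
    ggplot2::facet_wrap(~ .data$ventricle) +
    ggplot2::labs(x = "distance zone", y = "MPD (mm2/s)")
}
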