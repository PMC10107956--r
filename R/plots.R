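#' Tissue map of a phantom layer
#'
#' Plots the element centroids of one z-layer of the hex grid coloured
#' by tissue label — a quick visual check of suture bands, pegs and
#' trabecular core placement.
#'
#' @param mesh a labelled `tet_mesh`.
#' @param z layer height (mm, in flat parametric coordinates); default
#'   mid-thickness.
#' @param thickness layer half-width (mm); default one cell.
#' @return a ggplot object.
#' @export
plot_tissue_map <- function(mesh, z = NULL, thickness = NULL) {
  cen <- element_centroids(mesh, space = "param")
  z <- z %||% stats::median(cen[, 3L])
  thickness <- thickness %||% (diff(range(cen[, 3L])) /
                                 max(1, length(unique(round(cen[, 3L], 6)))))
  keep <- abs(cen[, 3L] - z) <= thickness
  df <- tibble(x = cen[keep, 1L], y = cen[keep, 2L],
               tissue = factor(mesh$tissue[keep], levels = TISSUE_LEVELS))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$tissue)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "tissue",
                  title = sprintf("tissue map, z = %.2f mm", z)) +
    ggplot2::theme_minimal()
}

#' @method autoplot tet_mesh
#' @export
autoplot.tet_mesh <- function(object, ...) plot_tissue_map(object, ...)

#' Principal strain map of a phantom layer
#'
#' @param object a `principal_field`.
#' @param mesh the `tet_mesh` the field was computed on.
#' @param component `"e1"`, `"e3"` or `"ratio"`.
#' @param z layer height (mm, parametric); default the dorsal-most
#'   element layer.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot principal_field
#' @export
autoplot.principal_field <- function(object, mesh, component = "e1",
                                     z = NULL, ...) {
  if (!component %in% c("e1", "e3", "ratio"))
    abort("component must be 'e1', 'e3' or 'ratio'")
  cen <- element_centroids(mesh, space = "param")
  z <- z %||% max(cen[, 3L])
  zs <- sort(unique(round(cen[, 3L], 9)))
  layer_w <- if (length(zs) > 1L) min(diff(zs)) else 1
  keep <- abs(cen[, 3L] - z) <= layer_w
  df <- tibble(x = cen[keep, 1L], y = cen[keep, 2L],
               value = object[[component]][keep])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  colour = if (component == "ratio") "|e1:e3|"
                  else paste0(component, " (µε)")) +
    ggplot2::theme_minimal()
}

#' Gauge comparison plot for a run report
#'
#' Virtual gauge readings by site, variant and load case: the
#' suture-site gauges should move far more between the sutured and
#' fused variants than the parietal-bone analog.
#'
#' @param object a `run_report`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot run_report
#' @export
autoplot.run_report <- function(object, ...) {
  g <- tidy(object)
  ggplot2::ggplot(g, ggplot2::aes(.data$site, .data$e1_mean,
                                  fill = .data$variant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$e1_mean - .data$e1_sd,
                   ymax = .data$e1_mean + .data$e1_sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25) +
    ggplot2::facet_wrap(~.data$load_case) +
    ggplot2::labs(x = "virtual gauge site",
                  y = "first principal strain (µε)") +
    ggplot2::theme_minimal()
}
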