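#' True-scale community scatter
#'
#' Draws a simulated 3-D cell layout projected on the XY plane with cell
#' symbols rendered as circles whose data-space radius equals the cell
#' radius — the same scaling as the spatial axes, so apparent crowding is
#' never exaggerated by marker size. Depth along Z is cued by opacity:
#' alpha proportional to `1 - z / extent`, clipped to \[0.15, 1\], so
#' fainter points sit farther back.
#'
#' @param layout A [generate_layout()] result.
#' @param n_vertices Circle resolution.
#' @return A ggplot object.
#' @export
plot_community <- function(layout, n_vertices = 32) {
  cfg <- attr(layout, "config")
  extent <- if (!is.null(cfg)) cfg$extent_mm else rep(max(layout$z_mm, 1), 3)
  df <- dplyr::mutate(
    tibble::as_tibble(layout),
    id = dplyr::row_number(),
    alpha = pmin(pmax(1 - .data$z_mm / extent[3], 0.15), 1)
  )
  circles <- circle_polygons(df$x_mm, df$y_mm, df$radius_um * 1e-3,
                             df$id, n_vertices)
  circles <- dplyr::left_join(circles, df[, c("id", "taxon", "alpha")], by = "id")
  ggplot2::ggplot(circles,
                  ggplot2::aes(.data$x, .data$y, group = .data$id,
                               fill = .data$taxon, alpha = .data$alpha)) +
    ggplot2::geom_polygon(colour = NA) +
    ggplot2::scale_alpha_identity() +
    ggplot2::coord_equal(xlim = c(0, extent[1]), ylim = c(0, extent[2]),
                         expand = FALSE) +
    ggplot2::labs(x = "X (mm)", y = "Y (mm)", fill = "Taxon") +
    ggplot2::theme_bw()
}

#' Plot an H2O2 concentration profile
#'
#' Concentration against distance from the cell centre, on a log10
#' concentration axis. The pale blue band marks the natural range of
#' seawater \[H2O2\] (1e-9 to 1e-6 M), the orange band the cytotoxic range;
#' black points show dilution alone and red points dilution with decay
#' superimposed. A green vertical line marks the cell surface and a dashed
#' line the threshold radius where the profile meets the seawater
#' background.
#'
#' @param object,x An `h2o2_profile` from [source_profile()] or
#'   [sink_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.h2o2_profile <- function(object, ...) {
  p <- attr(object, "params")
  R <- attr(object, "cell_radius_um")
  thr <- if (object$direction[1] == "source") {
    source_threshold_lambertw(p, R)$r_threshold_um
  } else {
    sink_threshold(p, R)$r_threshold_um
  }
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("conc_dilution_M", "conc_decay_M"),
                              names_to = "series", values_to = "conc_M")
  ggplot2::ggplot(long, ggplot2::aes(.data$r_um, .data$conc_M)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = 1e-9, ymax = 1e-6,
                      fill = "lightblue", alpha = 0.4) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = p$cytotoxic_M[1], ymax = p$cytotoxic_M[2],
                      fill = "orange", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = R, colour = "darkgreen") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$series == "conc_dilution_M"),
                        colour = "black", size = 0.8) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$series == "conc_decay_M"),
                        colour = "red", size = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Distance from cell centre (µm)",
                  y = "[H2O2] (mol L⁻¹)") +
    ggplot2::theme_bw()
}

#' @rdname autoplot.h2o2_profile
#' @export
plot.h2o2_profile <- function(x, ...) print(autoplot.h2o2_profile(x, ...))

#' Sphere-of-influence overlay of a habitat
#'
#' Renders an [overlay_habitat()] scene: each cell's sphere of influence as
#' a translucent disc (pale blue for sources raising local \[H2O2\], red for
#' sinks lowering it) with the cell itself drawn at true scale on top, and
#' the usual depth cue by opacity.
#'
#' @param object,x An `h2o2_scene`.
#' @param n_vertices Circle resolution.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.h2o2_scene <- function(object, n_vertices = 32, ...) {
  cfg <- attr(object, "config")
  extent <- if (!is.null(cfg)) cfg$extent_mm else rep(max(object$z_mm, 1), 3)
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    id = dplyr::row_number(),
    alpha = pmin(pmax(1 - .data$z_mm / extent[3], 0.15), 1)
  )
  spheres <- circle_polygons(df$x_mm, df$y_mm, df$sphere_um * 1e-3,
                             df$id, n_vertices)
  cells <- circle_polygons(df$x_mm, df$y_mm, df$radius_um * 1e-3,
                           df$id, n_vertices)
  meta <- df[, c("id", "direction", "alpha")]
  spheres <- dplyr::left_join(spheres, meta, by = "id")
  cells <- dplyr::left_join(cells, meta, by = "id")
  ggplot2::ggplot(mapping = ggplot2::aes(.data$x, .data$y, group = .data$id)) +
    ggplot2::geom_polygon(data = spheres,
                          ggplot2::aes(fill = .data$direction,
                                       alpha = 0.3 * .data$alpha),
                          colour = NA) +
    ggplot2::geom_polygon(data = cells,
                          ggplot2::aes(alpha = .data$alpha),
                          fill = "darkgreen", colour = NA) +
    ggplot2::scale_fill_manual(values = c(source = "lightblue", sink = "red")) +
    ggplot2::scale_alpha_identity() +
    ggplot2::coord_equal(xlim = c(0, extent[1]), ylim = c(0, extent[2]),
                         expand = FALSE) +
    ggplot2::labs(x = "X (mm)", y = "Y (mm)", fill = NULL) +
    ggplot2::theme_bw()
}

#' @rdname autoplot.h2o2_scene
#' @export
plot.h2o2_scene <- function(x, ...) print(autoplot.h2o2_scene(x, ...))

#' Plot threshold lines of cell-to-cell interaction
#'
#' Critical cell suspension density against cell radius on log-log axes, one
#' line per intracellular:extracellular ratio; combinations above a line
#' maintain overlapping spheres of influence. Community records can be
#' overlaid as points at their (density, radius) coordinates.
#'
#' @param lines One or more [threshold_line()] tibbles, row-bound.
#' @param community Optional community tibble to overlay as points.
#' @return A ggplot object.
#' @export
plot_threshold_lines <- function(lines, community = NULL) {
  p <- ggplot2::ggplot(lines,
                       ggplot2::aes(.data$critical_density_m3, .data$radius_um,
                                    colour = factor(.data$ratio))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Cell suspension density (cells m⁻³)",
                  y = "Cell radius (µm)",
                  colour = "[H2O2] cell:seawater") +
    ggplot2::theme_bw()
  if (!is.null(community)) {
    community <- validate_community(community)
    p <- p + ggplot2::geom_point(
      data = community,
      ggplot2::aes(.data$cells_per_m3, .data$cell_radius_um,
                   shape = .data$habitat),
      colour = "black", inherit.aes = FALSE
    )
  }
  p
}

# polygon vertices for circles drawn in data space (true-scale rendering)
circle_polygons <- function(x0, y0, r, id, n_vertices = 32) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  tibble::tibble(
    id = rep(id, each = n_vertices),
    x = rep(x0, each = n_vertices) + rep(r, each = n_vertices) * cos(theta),
    y = rep(y0, each = n_vertices) + rep(r, each = n_vertices) * sin(theta)
  )
}

#' Render the full figure set for a habitat
#'
#' Produces the package's four figure types for one community/configuration
#' — true-scale layout, gradient profile, sphere-of-influence overlay, and
#' threshold lines — writing each as PNG alongside a sidecar CSV carrying
#' every number shown, so figures are pure views over exported tables and
#' a run is reproducible from (community, params, config) alone.
#'
#' @param outdir Output directory (created if missing).
#' @param community A community tibble.
#' @param params An [h2o2_params()].
#' @param config A [layout_config()].
#' @param source_ratio,sink_ratio Ratios forwarded to [assess_community()].
#' @param line_ratios Ratios for the threshold-line figure.
#' @param width,height,dpi PNG geometry.
#' @return Invisibly, a character vector of the files written.
#' @export
save_figures <- function(outdir, community, params = h2o2_params(),
                         config = layout_config(),
                         source_ratio = 1000, sink_ratio = 0.1,
                         line_ratios = c(10, 100, 1000, 10000),
                         width = 6, height = 5, dpi = 150) {
  community <- validate_community(community)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) abort(paste0("cannot create output dir: ", outdir))

  layout <- generate_layout(community, config)
  assessments <- assess_community(community, source_ratio = source_ratio,
                                  sink_ratio = sink_ratio)
  scene <- overlay_habitat(community, layout, assessments)
  prof_radius <- max(community$cell_radius_um)
  profile <- source_profile(params, prof_radius)
  lines <- dplyr::bind_rows(purrr::map(line_ratios, threshold_line))

  paths <- file.path(outdir, c(
    "layout.csv", "layout.png", "profile.csv", "profile.png",
    "scene.csv", "scene.png", "assessments.csv",
    "threshold_lines.csv", "threshold_lines.png"
  ))
  readr::write_csv(tibble::as_tibble(layout), paths[1], progress = FALSE)
  ggplot2::ggsave(paths[2], plot_community(layout),
                  width = width, height = height, dpi = dpi)
  readr::write_csv(tibble::as_tibble(profile), paths[3], progress = FALSE)
  ggplot2::ggsave(paths[4], autoplot.h2o2_profile(profile),
                  width = width, height = height, dpi = dpi)
  readr::write_csv(tibble::as_tibble(scene), paths[5], progress = FALSE)
  ggplot2::ggsave(paths[6], autoplot.h2o2_scene(scene),
                  width = width, height = height, dpi = dpi)
  readr::write_csv(assessments, paths[7], progress = FALSE)
  readr::write_csv(lines, paths[8], progress = FALSE)
  ggplot2::ggsave(paths[9], plot_threshold_lines(lines, community),
                  width = width, height = height, dpi = dpi)
  invisible(paths)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
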