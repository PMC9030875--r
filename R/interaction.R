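#' Classify cell-to-cell H2O2 interaction potential across a community
#'
#' For every record of a community table, computes the cell-specific sphere
#' of influence (zero-decay source threshold for phototrophs, sink threshold
#' for heterotrophs, parameterised by the intracellular:extracellular
#' concentration ratio) and the mean cell-to-cell spacing at that record's
#' suspension density, then flags the record as interacting when the sphere
#' reaches the spacing criterion. Direct diffusional interaction via H2O2
#' requires the sphere of influence to span the typical gap to the nearest
#' neighbouring cell.
#'
#' @param community A community tibble (see [plankton_taxa()]).
#' @param source_ratio Intracellular:extracellular concentration ratio for
#'   phototrophs (> 1; default 1000, i.e. 1e-6 M over a 1e-9 M background).
#' @param sink_ratio Ratio for heterotrophs (< 1; default 0.1).
#' @param criterion `"spacing"` (sphere reaches the full mean spacing,
#'   the default) or `"half_spacing"` (two like spheres meet halfway).
#' @param convention `"centre"` (sphere radius measured from the cell
#'   centre, the default) or `"surface"` (distance from the cell surface).
#' @param correction Spacing correction constant, see [nn_constant()].
#' @return A tibble with one row per community record: `taxon`, `habitat`,
#'   `metabolism`, `cells_per_m3`, `cell_radius_um`, `ratio`, `sphere_um`,
#'   `spacing_um`, `interacting`.
#' @examples
#' assess_community(plankton_taxa())
#' @export
assess_community <- function(community,
                             source_ratio = 1000,
                             sink_ratio = 0.1,
                             criterion = c("spacing", "half_spacing"),
                             convention = c("centre", "surface"),
                             correction = nn_constant()) {
  community <- validate_community(community)
  criterion <- match.arg(criterion)
  convention <- match.arg(convention)
  if (!is.finite(source_ratio) || source_ratio <= 1) {
    abort("`source_ratio` must be > 1 (intracellular above seawater).")
  }
  if (!is.finite(sink_ratio) || sink_ratio <= 0 || sink_ratio >= 1) {
    abort("`sink_ratio` must be in (0, 1) (intracellular below seawater).")
  }
  if (nrow(community) == 0) {
    return(tibble::tibble(
      taxon = character(), habitat = character(), metabolism = character(),
      cells_per_m3 = numeric(), cell_radius_um = numeric(), ratio = numeric(),
      sphere_um = numeric(), spacing_um = numeric(), interacting = logical()
    ))
  }
  out <- dplyr::mutate(
    community,
    ratio = ifelse(.data$metabolism == "phototroph", source_ratio, sink_ratio),
    sphere_um = sphere_radius(.data$cell_radius_um, .data$ratio, convention),
    spacing_um = mean_cell_spacing(.data$cells_per_m3, correction)$spacing_um,
    interacting = .data$sphere_um >=
      (if (criterion == "half_spacing") .data$spacing_um / 2 else .data$spacing_um)
  )
  dplyr::select(out, "taxon", "habitat", "metabolism", "cells_per_m3",
                "cell_radius_um", "ratio", "sphere_um", "spacing_um",
                "interacting")
}

# sphere-of-influence radius for a concentration ratio; ratios > 1 are
# sources (r * ratio^(1/3)), ratios in (0,1) are sinks (r * ratio^(-1/3));
# surface convention subtracts the cell radius
sphere_radius <- function(cell_radius_um, ratio, convention = "centre") {
  expand <- ifelse(ratio >= 1, ratio^(1 / 3), ratio^(-1 / 3))
  r <- cell_radius_um * expand
  if (convention == "surface") r <- r - cell_radius_um
  r
}

#' Threshold line of critical density versus cell radius
#'
#' For a fixed intracellular:extracellular concentration ratio, computes for
#' each cell radius the suspension density at which the mean cell-to-cell
#' spacing equals the cell-specific sphere of influence. Populations above
#' the line (denser, or larger-celled) maintain overlapping spheres and so
#' can interact cell-to-cell via H2O2; populations below it cannot.
#'
#' @param ratio Intracellular:extracellular ratio; > 1 for sources, in
#'   (0, 1) for sinks.
#' @param cell_radii_um Radii at which to evaluate the line (um).
#' @inheritParams assess_community
#' @return A tibble with columns `ratio`, `radius_um`, `sphere_um`,
#'   `critical_density_m3`, strictly decreasing in `radius_um`.
#' @examples
#' threshold_line(1000, c(0.5, 1, 2.5, 10, 40))
#' @export
threshold_line <- function(ratio, cell_radii_um = 10^seq(-0.6, 1.7, by = 0.1),
                           convention = c("centre", "surface"),
                           correction = nn_constant()) {
  convention <- match.arg(convention)
  if (!is.finite(ratio) || ratio <= 0 || ratio == 1 && convention == "surface") {
    abort("`ratio` must be > 0 (and != 1 under the surface convention).")
  }
  if (any(cell_radii_um <= 0)) abort("`cell_radii_um` must be > 0.")
  sphere <- sphere_radius(cell_radii_um, ratio, convention)
  tibble::tibble(
    ratio = ratio,
    radius_um = cell_radii_um,
    sphere_um = sphere,
    critical_density_m3 = critical_density_for_spacing(sphere, correction)$density_m3
  )
}

#' Build a renderable sphere-of-influence scene for a habitat
#'
#' Joins a simulated cell layout with per-taxon interaction assessments into
#' the per-cell scene consumed by the plotting functions: position, cell
#' radius, sphere-of-influence radius and direction for each cell, plus
#' pairwise sphere-overlap counts (two spheres overlap when the
#' centre-to-centre separation is below the sum of their sphere radii).
#'
#' @param community The community the layout and assessments were built from.
#' @param layout A [generate_layout()] result for `community`.
#' @param assessments An [assess_community()] result for `community`.
#' @return A tibble of class `h2o2_scene` with columns `taxon`, `x_mm`,
#'   `y_mm`, `z_mm`, `radius_um`, `sphere_um`, `direction`, `n_overlaps`
#'   and `overlapping`; attribute `"n_overlap_pairs"` holds the total
#'   pairwise overlap count.
#' @examples
#' colony <- dplyr::filter(plankton_taxa(), taxon == "Phaeocystis")
#' lay <- generate_layout(colony, layout_config(extent_mm = 0.1, seed = 7))
#' scene <- overlay_habitat(colony, lay, assess_community(colony))
#' glance(scene)
#' @export
overlay_habitat <- function(community, layout, assessments) {
  community <- validate_community(community)
  if (!all(unique(layout$taxon) %in% community$taxon) ||
      !all(assessments$taxon %in% community$taxon)) {
    abort("layout/assessments do not match the community (taxon mismatch).")
  }
  key <- dplyr::distinct(
    dplyr::transmute(
      assessments,
      taxon = .data$taxon, cell_radius_um = .data$cell_radius_um,
      sphere_um = .data$sphere_um,
      direction = ifelse(.data$metabolism == "phototroph", "source", "sink")
    )
  )
  scene <- dplyr::inner_join(
    tibble::as_tibble(layout), key,
    by = dplyr::join_by("taxon", "radius_um" == "cell_radius_um"),
    relationship = "many-to-many"
  )
  if (nrow(scene) != nrow(layout)) {
    # duplicate table rows (same taxon, different citations) would fan out
    scene <- dplyr::distinct(scene, .data$x_mm, .data$y_mm, .data$z_mm,
                             .data$taxon, .keep_all = TRUE)
  }
  n <- nrow(scene)
  n_over <- integer(n)
  if (n >= 2) {
    pos <- as.matrix(scene[, c("x_mm", "y_mm", "z_mm")]) * 1e3  # um
    sph <- scene$sphere_um
    block <- 512L
    for (start in seq(1L, n, by = block)) {
      rows <- start:min(start + block - 1L, n)
      d2 <- matrix(0, length(rows), n)
      for (a in 1:3) {
        dx <- outer(pos[rows, a], pos[, a], "-")
        d2 <- d2 + dx * dx
      }
      lim <- outer(sph[rows], sph, "+")
      hit <- d2 < lim * lim
      hit[cbind(seq_along(rows), rows)] <- FALSE
      n_over[rows] <- rowSums(hit)
    }
  }
  scene$n_overlaps <- as.integer(n_over)
  scene$overlapping <- n_over > 0
  attr(scene, "n_overlap_pairs") <- sum(n_over) %/% 2
  attr(scene, "config") <- attr(layout, "config")
  class(scene) <- c("h2o2_scene", class(scene))
  scene
}

#' @rdname overlay_habitat
#' @param x An `h2o2_scene`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.h2o2_scene <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_overlap_pairs = attr(x, "n_overlap_pairs"),
    n_overlapping_cells = sum(x$overlapping),
    frac_overlapping = if (nrow(x) > 0) mean(x$overlapping) else NA_real_
  )
}

#' @rdname overlay_habitat
#' @exportS3Method generics::tidy
tidy.h2o2_scene <- function(x, ...) tibble::as_tibble(x)
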