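#' Nearest-neighbour correction constant
#'
#' Constant relating the mean nearest-neighbour distance of a homogeneous
#' spatial Poisson process of intensity rho to rho^(-1/3): the exact value is
#' Gamma(4/3) * (4 pi / 3)^(-1/3) ~= 0.553960. Evenly spaced cells would give
#' the uncorrected rho^(-1/3) (a maximum spacing, not an average), so mean
#' spacing estimates multiply the reciprocal cube root of density by this
#' constant. The rounded 0.55 commonly quoted in the field is available via
#' `exact = FALSE`.
#'
#' @param exact If `TRUE` (default), the exact Poisson constant; if `FALSE`,
#'   the rounded 0.55.
#' @return A length-1 numeric.
#' @examples
#' nn_constant()
#' nn_constant(exact = FALSE)
#' @export
nn_constant <- function(exact = TRUE) {
  if (isTRUE(exact)) gamma(4 / 3) * (4 * pi / 3)^(-1 / 3) else 0.55
}

#' Mean cell-to-cell spacing from suspension density
#'
#' Estimates the mean distance between randomly located cells from the cell
#' suspension density: spacing (mm) = correction / (density in cells mm^-3)^(1/3),
#' with densities supplied in cells m^-3 (1 cell mm^-3 = 10^9 cells m^-3 =
#' 1 cell uL^-1). The correction constant accounts for complete spatial
#' randomness; see [nn_constant()].
#'
#' @param density_m3 Cell suspension density in cells m^-3 (vectorised).
#' @param correction Dimensionless nearest-neighbour correction constant.
#' @return A tibble with columns `density_m3`, `correction`, `spacing_mm`
#'   and `spacing_um`.
#' @examples
#' mean_cell_spacing(c(1e9, 2.4e13))
#' @export
mean_cell_spacing <- function(density_m3, correction = nn_constant()) {
  if (any(!is.finite(density_m3) | density_m3 <= 0)) {
    abort("`density_m3` must be finite and > 0.")
  }
  density_mm3 <- density_m3 * 1e-9
  spacing_mm <- correction / density_mm3^(1 / 3)
  tibble::tibble(
    density_m3 = density_m3,
    correction = correction,
    spacing_mm = spacing_mm,
    spacing_um = spacing_mm * 1e3
  )
}

#' Critical suspension density for a target spacing
#'
#' Exact algebraic inverse of [mean_cell_spacing()]: the density at which the
#' mean cell-to-cell spacing equals `spacing_um`. Used to place threshold
#' lines of cell-to-cell interaction in density/radius space.
#'
#' @param spacing_um Target mean spacing in micrometres (vectorised).
#' @inheritParams mean_cell_spacing
#' @return A tibble with columns `spacing_um`, `correction` and `density_m3`.
#' @examples
#' critical_density_for_spacing(400)  # ~2.66e9 cells m^-3
#' @export
critical_density_for_spacing <- function(spacing_um, correction = nn_constant()) {
  if (any(!is.finite(spacing_um) | spacing_um <= 0)) {
    abort("`spacing_um` must be finite and > 0.")
  }
  spacing_mm <- spacing_um * 1e-3
  tibble::tibble(
    spacing_um = spacing_um,
    correction = correction,
    density_m3 = (correction / spacing_mm)^3 * 1e9
  )
}
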