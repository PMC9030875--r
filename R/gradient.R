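#' Physical parameters of the H2O2 gradient model
#'
#' Bundles the concentrations and transport/decay constants governing the
#' H2O2 microenvironment around a cell:
#' \describe{
#'   \item{`c_cell`}{homeostatic intracellular \[H2O2\] in mol L^-1. The
#'     phytoplankton default 1e-6 M sits an order of magnitude below the
#'     cytotoxic range; heterotrophic bacterioplankton are usually modelled
#'     at 1/10 of the external concentration instead (a sink).}
#'   \item{`c_seawater`}{background seawater \[H2O2\] in mol L^-1; natural
#'     waters span roughly 1e-9 to 1e-6 M. The default 1e-9 M is the low end,
#'     which maximises a source cell's sphere of influence.}
#'   \item{`diffusion_um2_us`}{H2O2 diffusion coefficient `D`, default 1500
#'     (um^2 per time unit as reported for seawater at ~20 C).}
#'   \item{`decay_per_us`}{pseudo-first-order decay constant `mu` in us^-1
#'     (default 0, i.e. no decay); see [decay_constant_from_lifetime()].}
#'   \item{`cytotoxic_M`}{annotation-only band of acutely toxic \[H2O2\],
#'     default 1e-5 to 1e-4 M, drawn on gradient figures.}
#' }
#'
#' @param c_cell Intracellular concentration (mol L^-1).
#' @param c_seawater Seawater background concentration (mol L^-1).
#' @param diffusion_um2_us Diffusion coefficient (um^2 us^-1).
#' @param decay_per_us Decay constant (us^-1), >= 0.
#' @param cytotoxic_M Length-2 increasing cytotoxic concentration band.
#' @return An `h2o2_params` list.
#' @examples
#' h2o2_params()                           # phytoplankton source defaults
#' h2o2_params(c_cell = 1e-10, c_seawater = 1e-9)  # bacterioplankton sink
#' @export
h2o2_params <- function(c_cell = 1e-6,
                        c_seawater = 1e-9,
                        diffusion_um2_us = 1500,
                        decay_per_us = 0,
                        cytotoxic_M = c(1e-5, 1e-4)) {
  stopifnot(c_cell >= 0, c_seawater >= 0, diffusion_um2_us > 0,
            decay_per_us >= 0, length(cytotoxic_M) == 2,
            cytotoxic_M[1] < cytotoxic_M[2])
  structure(
    list(c_cell = c_cell, c_seawater = c_seawater,
         diffusion_um2_us = diffusion_um2_us, decay_per_us = decay_per_us,
         cytotoxic_M = cytotoxic_M),
    class = "h2o2_params"
  )
}

#' Decay constant from extracellular lifetime
#'
#' Converts an H2O2 extracellular lifetime (hours to days in natural waters)
#' into the pseudo-first-order decay constant `mu` in us^-1, using the
#' e-folding convention `mu = 1 / lifetime`. At the sub-millisecond
#' timescales of the gradient simulation the distinction from a half-life
#' convention is numerically irrelevant (relative effect < 1e-7).
#'
#' @param lifetime_h Lifetime in hours; `Inf` gives 0 (no decay).
#' @return Decay constant in us^-1.
#' @examples
#' decay_constant_from_lifetime(1)    # ~2.78e-10
#' decay_constant_from_lifetime(24)   # ~1.16e-11
#' @export
decay_constant_from_lifetime <- function(lifetime_h) {
  if (any(is.na(lifetime_h) | lifetime_h <= 0)) {
    abort("`lifetime_h` must be > 0 (or Inf for no decay).")
  }
  1 / (lifetime_h * 3.6e9)
}

#' Logarithmic time grid for gradient simulation
#'
#' Builds the simulation time series: exactly 0, then log10-spaced points
#' from `t_min_us` up to `t_max_us`. The default spans 1e-3 to 100 us at 20
#' points per decade, covering displacement fronts out to ~100 um for
#' D = 1500 um^2 us^-1.
#'
#' @param t_min_us First positive time (us).
#' @param t_max_us Last time (us).
#' @param points_per_decade Grid resolution.
#' @return Strictly increasing numeric vector starting at 0.
#' @export
time_grid <- function(t_min_us = 1e-3, t_max_us = 100, points_per_decade = 20) {
  stopifnot(t_min_us > 0, t_max_us > t_min_us, points_per_decade >= 1)
  lo <- log10(t_min_us)
  hi <- log10(t_max_us)
  n <- ceiling((hi - lo) * points_per_decade) + 1
  c(0, 10^seq(lo, hi, length.out = n))
}

#' Diffusional displacement front
#'
#' Net diffusional displacement of H2O2 outward from (or inward toward) the
#' cell surface after time `t`: `r(t) = cell_radius + sqrt(D * t)`, measured
#' from the cell centre.
#'
#' @param cell_radius_um Cell radius (um).
#' @param t_us Elapsed time (us), vectorised, >= 0.
#' @param diffusion_um2_us Diffusion coefficient `D`.
#' @return Radii in um from the cell centre.
#' @export
displacement_radius <- function(cell_radius_um, t_us, diffusion_um2_us = 1500) {
  if (any(t_us < 0)) abort("`t_us` must be >= 0.")
  cell_radius_um + sqrt(diffusion_um2_us * t_us)
}

#' Outward H2O2 gradient from a source cell
#'
#' Simulates \[H2O2\] as H2O2 diffuses outward from a phytoplankton-like
#' source cell that maintains intracellular concentration above the seawater
#' background. At each grid time the displacement front sits at
#' `r(t) = R + sqrt(D t)` and the surface concentration is diluted by the
#' volume ratio `(R / r)^3` (volumetric dilution); a second series
#' superimposes pseudo-first-order decay `exp(-mu t)`. Both series are
#' floored at `c_seawater`: beyond the threshold radius the cell has no
#' local influence and merely contributes to the bulk background.
#'
#' @param params An [h2o2_params()] with `c_cell > c_seawater`.
#' @param cell_radius_um Cell radius (um).
#' @param grid Time grid from [time_grid()] (us; first element 0).
#' @return A tibble of class `h2o2_profile` with columns `t_us`, `r_um`,
#'   `conc_dilution_M`, `conc_decay_M` and `direction = "source"`;
#'   attributes carry `params` and `cell_radius_um`.
#' @examples
#' prof <- source_profile(h2o2_params(), cell_radius_um = 10)
#' @export
source_profile <- function(params = h2o2_params(), cell_radius_um,
                           grid = time_grid()) {
  stopifnot(inherits(params, "h2o2_params"), cell_radius_um > 0)
  if (params$c_cell <= params$c_seawater) {
    abort("c_cell <= c_seawater: source cell has no outward sphere of influence.")
  }
  r <- displacement_radius(cell_radius_um, grid, params$diffusion_um2_us)
  dil <- params$c_cell * (cell_radius_um / r)^3
  dec <- dil * exp(-params$decay_per_us * grid)
  new_profile(
    t_us = grid, r_um = r,
    conc_dilution_M = pmax(dil, params$c_seawater),
    conc_decay_M = pmax(dec, params$c_seawater),
    direction = "source", params = params, cell_radius_um = cell_radius_um
  )
}

#' Inward H2O2 gradient toward a sink cell
#'
#' Simulates \[H2O2\] around a heterotrophic bacterioplankton-like sink cell
#' that maintains intracellular concentration below seawater background.
#' The mirrored dilution heuristic raises concentration from `c_cell` at the
#' cell surface as `(r / R)^3`, capped at `c_seawater`; no decay term is
#' applied because the cell's uptake acts on top of any bulk decay.
#'
#' @param params An [h2o2_params()] with `c_cell < c_seawater`.
#' @inheritParams source_profile
#' @return A tibble of class `h2o2_profile` (both concentration columns
#'   carry the same no-decay series; `direction = "sink"`).
#' @examples
#' sink_profile(h2o2_params(c_cell = 1e-10, c_seawater = 1e-9), 0.5)
#' @export
sink_profile <- function(params, cell_radius_um, grid = time_grid()) {
  stopifnot(inherits(params, "h2o2_params"), cell_radius_um > 0)
  if (params$c_cell >= params$c_seawater) {
    abort("c_cell >= c_seawater: sink cell has no inward sphere of influence.")
  }
  r <- displacement_radius(cell_radius_um, grid, params$diffusion_um2_us)
  conc <- pmin(params$c_cell * (r / cell_radius_um)^3, params$c_seawater)
  new_profile(
    t_us = grid, r_um = r,
    conc_dilution_M = conc, conc_decay_M = conc,
    direction = "sink", params = params, cell_radius_um = cell_radius_um
  )
}

new_profile <- function(t_us, r_um, conc_dilution_M, conc_decay_M,
                        direction, params, cell_radius_um) {
  out <- tibble::tibble(
    t_us = t_us, r_um = r_um,
    conc_dilution_M = conc_dilution_M, conc_decay_M = conc_decay_M,
    direction = direction
  )
  attr(out, "params") <- params
  attr(out, "cell_radius_um") <- cell_radius_um
  class(out) <- c("h2o2_profile", class(out))
  out
}

#' @rdname source_profile
#' @param x An `h2o2_profile`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.h2o2_profile <- function(x, ...) {
  p <- attr(x, "params")
  tibble::tibble(
    direction = x$direction[1],
    cell_radius_um = attr(x, "cell_radius_um"),
    c_cell_M = p$c_cell, c_seawater_M = p$c_seawater,
    diffusion_um2_us = p$diffusion_um2_us, decay_per_us = p$decay_per_us,
    t_max_us = max(x$t_us), r_max_um = max(x$r_um)
  )
}

#' @rdname source_profile
#' @exportS3Method generics::tidy
tidy.h2o2_profile <- function(x, ...) {
  tibble::as_tibble(x)
}
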