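#' Threshold radius of a source cell's sphere of influence (Lambert W)
#'
#' Solves for the time and radius at which \[H2O2\] diffusing outward from a
#' source cell, under volumetric dilution and pseudo-first-order decay,
#' falls to the seawater background. Writing `k = c_seawater / (c_cell R^3)`
#' the threshold condition
#' `c_seawater = c_cell R^3 / (R + sqrt(D t))^3 * exp(-mu t)`
#' is solved on the principal branch of the Lambert W function:
#' `t = W0((k^(-1/3) - R)^2 * (2 mu / 3) / D) / (2 mu / 3)`,
#' followed by a Newton polish on the log-concentration so that the profile
#' evaluated at the returned `(t, r)` recovers `c_seawater` to machine
#' precision. When `mu * t` would be below ~1e-12 the closed-form zero-decay
#' branch is used instead (W0(x)/x is numerically unstable as x -> 0).
#'
#' @param params An [h2o2_params()] with `c_cell > c_seawater`.
#' @param cell_radius_um Cell radius (um).
#' @return A one-row tibble of class `threshold_result` with columns
#'   `direction`, `method`, `cell_radius_um`, `ratio` (c_cell/c_seawater),
#'   `mu_per_us`, `t_threshold_us`, `r_threshold_um` (from the cell centre)
#'   and `dist_surface_um` (= r - R). For the Lambert-W branch the attribute
#'   `"derivation"` carries the intermediates `k`, `w_argument` and `Y`.
#' @examples
#' # diatom-sized source, no decay: 100 um from centre, 90 um from surface
#' source_threshold_lambertw(h2o2_params(), cell_radius_um = 10)
#' @export
source_threshold_lambertw <- function(params = h2o2_params(), cell_radius_um) {
  check_source(params)
  R <- cell_radius_um
  D <- params$diffusion_um2_us
  mu <- params$decay_per_us
  k <- params$c_seawater / (params$c_cell * R^3)
  A <- k^(-1 / 3)                    # zero-decay threshold radius from centre
  t0 <- (A - R)^2 / D                # zero-decay threshold time
  if (mu * t0 < 1e-12) {
    res <- source_threshold_zero_decay(params, R)
    attr(res, "derivation") <- list(k = k, w_argument = NA_real_, Y = NA_real_)
    return(res)
  }
  a <- 2 * mu / 3
  w_arg <- (A - R)^2 * a / D
  stopifnot(w_arg >= -exp(-1))       # provably >= 0 for valid inputs
  Y <- pracma::lambertWp(w_arg)
  t <- Y / a
  # Newton polish of log c(t) - log c_seawater = 0 (the printed closed form
  # factors (R + sqrt(Dt)) e^{mu t/3} approximately; polish removes the
  # O(mu t) residual so the profile round-trips exactly)
  for (i in 1:12) {
    s <- sqrt(D * t)
    f <- log(params$c_cell / params$c_seawater) + 3 * log(R / (R + s)) - mu * t
    fp <- -3 * (D / (2 * s)) / (R + s) - mu
    step <- f / fp
    t <- t - step
    if (abs(step) < 1e-14 * t) break
  }
  r <- R + sqrt(D * t)
  res <- threshold_row("source", "lambertw", R, params$c_cell / params$c_seawater,
                       mu, t, r)
  attr(res, "derivation") <- list(k = k, w_argument = w_arg, Y = Y)
  res
}

#' Zero-decay threshold radius of a source cell
#'
#' Closed form when decay is negligible: dilution alone gives
#' `r = R * (c_cell / c_seawater)^(1/3)` and the front reaches it at
#' `t = (r - R)^2 / D`. Independent of `D` in radius; this is the limit the
#' Lambert-W solution approaches as `mu -> 0`.
#'
#' @inheritParams source_threshold_lambertw
#' @return A one-row `threshold_result` tibble.
#' @export
source_threshold_zero_decay <- function(params = h2o2_params(), cell_radius_um) {
  check_source(params)
  R <- cell_radius_um
  r <- R * (params$c_cell / params$c_seawater)^(1 / 3)
  t <- (r - R)^2 / params$diffusion_um2_us
  threshold_row("source", "closed_form_zero_decay", R,
                params$c_cell / params$c_seawater, 0, t, r)
}

#' Threshold radius from the simulated time grid
#'
#' Grid-scan analogue of [source_threshold_lambertw()]: walks the simulated
#' log10 time series and reports the first grid time at which the
#' decay-inclusive concentration has dropped to (or below) `c_seawater`.
#' Because the crossing is reported at the first grid point past the
#' continuous solution, the result always overshoots it, converging from
#' above as `points_per_decade` grows.
#'
#' @inheritParams source_threshold_lambertw
#' @param grid Time grid from [time_grid()].
#' @return A one-row `threshold_result` tibble (`method = "grid_scan"`).
#' @examples
#' # Prochlorococcus-sized source on the default grid: ~3.0-3.1 um from centre
#' p <- h2o2_params(decay_per_us = decay_constant_from_lifetime(24))
#' source_threshold_grid(p, cell_radius_um = 0.3)
#' @export
source_threshold_grid <- function(params = h2o2_params(), cell_radius_um,
                                  grid = time_grid()) {
  check_source(params)
  R <- cell_radius_um
  r <- displacement_radius(R, grid, params$diffusion_um2_us)
  conc <- params$c_cell * (R / r)^3 * exp(-params$decay_per_us * grid)
  hit <- which(conc <= params$c_seawater)
  if (length(hit) == 0) {
    abort(paste0("concentration never reaches c_seawater within the grid ",
                 "(t_max = ", max(grid), " us); extend the time grid."))
  }
  i <- hit[1]
  threshold_row("source", "grid_scan", R, params$c_cell / params$c_seawater,
                params$decay_per_us, grid[i], r[i])
}

#' Threshold radius of a sink cell's sphere of influence
#'
#' For a heterotrophic sink cell holding intracellular \[H2O2\] below the
#' seawater background, the mirrored dilution model gives the radius at
#' which local concentration recovers to background:
#' `r = R * (c_seawater / c_cell)^(1/3)`, with no time dependence and no
#' decay term (uptake acts on top of bulk decay).
#'
#' @param params An [h2o2_params()] with `c_cell < c_seawater`.
#' @inheritParams source_threshold_lambertw
#' @return A one-row `threshold_result` tibble (`t_threshold_us` is `NA`;
#'   the sink threshold has no time dependence).
#' @examples
#' # bacterioplankton at 1/10 of external: sphere of ~1.08 um around a 0.5 um cell
#' sink_threshold(h2o2_params(c_cell = 1e-10, c_seawater = 1e-9), 0.5)
#' @export
sink_threshold <- function(params, cell_radius_um) {
  stopifnot(inherits(params, "h2o2_params"))
  if (params$c_cell >= params$c_seawater) {
    abort("c_cell >= c_seawater: sink cell has no inward sphere of influence.")
  }
  if (params$c_cell <= 0) abort("sink threshold needs c_cell > 0.")
  R <- cell_radius_um
  r <- R * (params$c_seawater / params$c_cell)^(1 / 3)
  threshold_row("sink", "closed_form_zero_decay", R,
                params$c_cell / params$c_seawater, 0, NA_real_, r)
}

#' Bisection oracle for threshold radii
#'
#' Independent verification route for the analytic thresholds: finds the
#' root of `profile concentration - c_seawater` by bracketed bisection to
#' relative tolerance 1e-12, using only the profile equations (never the
#' Lambert-W or algebraic closed forms). Intended for tests and
#' cross-checks.
#'
#' @inheritParams source_threshold_lambertw
#' @param direction `"source"` (bisection in time on the decay-inclusive
#'   outward profile) or `"sink"` (bisection in radius on the inward
#'   profile).
#' @return A one-row `threshold_result` tibble (`method = "bisection_oracle"`).
#' @export
bisection_oracle <- function(params, cell_radius_um,
                             direction = c("source", "sink")) {
  direction <- match.arg(direction)
  R <- cell_radius_um
  if (direction == "source") {
    check_source(params)
    D <- params$diffusion_um2_us
    mu <- params$decay_per_us
    f <- function(t) {
      params$c_cell * (R / (R + sqrt(D * t)))^3 * exp(-mu * t) - params$c_seawater
    }
    lo <- 0
    # zero-decay threshold time bounds the root; pad it because with mu = 0
    # the bound lands on the root to within rounding
    hi <- 2 * (R * (params$c_cell / params$c_seawater)^(1 / 3) - R)^2 / D
    if (f(hi) > 0) abort("bisection bracket does not straddle the root.")
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
      if ((hi - lo) < 1e-13 * max(hi, 1e-300)) break
    }
    t <- (lo + hi) / 2
    threshold_row("source", "bisection_oracle", R,
                  params$c_cell / params$c_seawater, mu, t,
                  R + sqrt(D * t))
  } else {
    if (params$c_cell >= params$c_seawater || params$c_cell <= 0) {
      abort("sink oracle needs 0 < c_cell < c_seawater.")
    }
    f <- function(r) params$c_cell * (r / R)^3 - params$c_seawater
    lo <- R
    hi <- R * (params$c_seawater / params$c_cell)  # generous upper bracket
    if (f(lo) > 0 || f(hi) < 0) abort("bisection bracket does not straddle the root.")
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
      if ((hi - lo) < 1e-13 * hi) break
    }
    threshold_row("sink", "bisection_oracle", R,
                  params$c_cell / params$c_seawater, 0, NA_real_,
                  (lo + hi) / 2)
  }
}

check_source <- function(params) {
  stopifnot(inherits(params, "h2o2_params"))
  if (params$c_cell <= params$c_seawater) {
    abort("c_cell <= c_seawater: source cell has no outward sphere of influence.")
  }
  invisible(params)
}

threshold_row <- function(direction, method, R, ratio, mu, t, r) {
  out <- tibble::tibble(
    direction = direction, method = method,
    cell_radius_um = R, ratio = ratio, mu_per_us = mu,
    t_threshold_us = t, r_threshold_um = r,
    dist_surface_um = r - R
  )
  class(out) <- c("threshold_result", class(out))
  out
}

#' @rdname source_threshold_lambertw
#' @param x A `threshold_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.threshold_result <- function(x, ...) tibble::as_tibble(x)
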