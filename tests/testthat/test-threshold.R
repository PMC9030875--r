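test_that("zero-decay source threshold is the cube-root dilution radius", {
  # diatom-sized source, ratio 1000: 100 um from centre, 90 um from surface
  res <- source_threshold_zero_decay(h2o2_params(), 10)
  expect_equal(res$r_threshold_um, 100)
  expect_equal(res$dist_surface_um, 90)
  expect_equal(res$t_threshold_us, 90^2 / 1500)

  # cube root of the ratio scales the radius
  expect_equal(source_threshold_zero_decay(
    h2o2_params(c_cell = 8e-9, c_seawater = 1e-9), 1)$r_threshold_um, 2)

  # degenerate limit: ratio -> 1 collapses onto the cell surface
  tiny <- source_threshold_zero_decay(
    h2o2_params(c_cell = 1e-9 * (1 + 1e-9), c_seawater = 1e-9), 2)
  expect_equal(tiny$r_threshold_um, 2, tolerance = 1e-9)
  expect_lt(tiny$t_threshold_us, 1e-15)

  expect_error(source_threshold_zero_decay(
    h2o2_params(c_cell = 1e-9, c_seawater = 1e-9), 1), "no outward sphere")
})

test_that("Lambert-W threshold round-trips the decay-inclusive profile", {
  for (lifetime in c(1, 24)) {
    params <- h2o2_params(decay_per_us = decay_constant_from_lifetime(lifetime))
    for (R in c(0.5, 2.2, 10, 40)) {
      res <- source_threshold_lambertw(params, R)
      # evaluating the profile at (t*, r*) recovers c_seawater
      conc <- params$c_cell * (R / res$r_threshold_um)^3 *
        exp(-params$decay_per_us * res$t_threshold_us)
      expect_equal(conc, params$c_seawater, tolerance = 1e-9)
      expect_equal(res$r_threshold_um,
                   displacement_radius(R, res$t_threshold_us,
                                       params$diffusion_um2_us))
      # decay can only shrink the sphere
      r0 <- source_threshold_zero_decay(params, R)$r_threshold_um
      if (res$method == "lambertw") expect_lt(res$r_threshold_um, r0)
    }
  }

  # the decay deficit vanishes as mu -> 0
  slow <- h2o2_params(decay_per_us = decay_constant_from_lifetime(1e6))
  expect_equal(source_threshold_lambertw(slow, 10)$r_threshold_um, 100,
               tolerance = 1e-9)

  # derivation intermediates: principal-branch argument is non-negative and
  # Y solves Y e^Y = argument
  params <- h2o2_params(decay_per_us = decay_constant_from_lifetime(1))
  res <- source_threshold_lambertw(params, 40)
  der <- attr(res, "derivation")
  expect_equal(der$k, params$c_seawater / (params$c_cell * 40^3))
  expect_gte(der$w_argument, 0)
  expect_equal(der$Y * exp(der$Y), der$w_argument, tolerance = 1e-12)
})

test_that("grid scan brackets the continuous threshold from above", {
  params <- h2o2_params()
  res <- source_threshold_grid(params, 10)
  cont <- source_threshold_zero_decay(params, 10)
  expect_gte(res$r_threshold_um, cont$r_threshold_um)
  # within one step of the default grid
  grid <- time_grid()
  i <- which(grid >= res$t_threshold_us)[1]
  step_ratio <- grid[i] / grid[i - 1]
  expect_lt(res$r_threshold_um / cont$r_threshold_um, sqrt(step_ratio))

  # refining the grid converges toward the continuous solution
  fine <- source_threshold_grid(params, 10, time_grid(points_per_decade = 200))
  expect_lt(fine$r_threshold_um - cont$r_threshold_um,
            res$r_threshold_um - cont$r_threshold_um + 1e-12)

  # Prochlorococcus-sized cell with day-scale decay: crossing in [3.0, 3.2] um
  p24 <- h2o2_params(decay_per_us = decay_constant_from_lifetime(24))
  proc <- source_threshold_grid(p24, 0.3)
  expect_gte(proc$r_threshold_um, 3.0)
  expect_lte(proc$r_threshold_um, 3.2)

  # grid too short to reach background
  expect_error(source_threshold_grid(params, 10, time_grid(t_max_us = 0.01)),
               "extend the time grid")
})

test_that("sink threshold follows the printed algebraic cube root", {
  # bacterioplankton at 1/10 external: 0.5 * 10^(1/3) ~ 1.077 um
  res <- sink_threshold(h2o2_params(c_cell = 1e-10, c_seawater = 1e-9), 0.5)
  expect_equal(res$r_threshold_um, 1.077217345015942)
  expect_true(is.na(res$t_threshold_us))
  expect_equal(res$direction, "sink")

  # ratio 0.01 widens the sphere to 0.5 * 100^(1/3) ~ 2.321 um
  expect_equal(sink_threshold(
    h2o2_params(c_cell = 1e-11, c_seawater = 1e-9), 0.5)$r_threshold_um,
    2.320794416806389)

  # ratio -> 1 collapses onto the cell surface
  expect_equal(sink_threshold(
    h2o2_params(c_cell = 1e-9 * (1 - 1e-12), c_seawater = 1e-9), 0.5)$r_threshold_um,
    0.5, tolerance = 1e-9)

  expect_error(sink_threshold(h2o2_params(), 0.5), "no inward sphere")
})

test_that("thresholds are monotone in radius and ratio, D-free without decay", {
  radii <- c(0.3, 1, 5, 20)
  r_out <- vapply(radii, function(R) {
    source_threshold_zero_decay(h2o2_params(), R)$r_threshold_um
  }, numeric(1))
  expect_true(all(diff(r_out) > 0))

  ratios <- c(10, 100, 1000)
  r_by_ratio <- vapply(ratios, function(q) {
    source_threshold_zero_decay(
      h2o2_params(c_cell = q * 1e-9, c_seawater = 1e-9), 5)$r_threshold_um
  }, numeric(1))
  expect_true(all(diff(r_by_ratio) > 0))

  # radius independent of D when mu = 0
  a <- source_threshold_zero_decay(h2o2_params(diffusion_um2_us = 1500), 5)
  b <- source_threshold_zero_decay(h2o2_params(diffusion_um2_us = 15), 5)
  expect_equal(a$r_threshold_um, b$r_threshold_um)
})

test_that("bisection oracle verifies both analytic threshold routes", {
  # zero-decay closed form to 1e-12
  a <- source_threshold_zero_decay(h2o2_params(), 2.5)
  b <- bisection_oracle(h2o2_params(), 2.5, "source")
  expect_equal(b$t_threshold_us, a$t_threshold_us, tolerance = 1e-12)

  # with decay, Lambert-W route agrees to well under 1e-6
  params <- h2o2_params(decay_per_us = decay_constant_from_lifetime(1))
  lw <- source_threshold_lambertw(params, 10)
  or <- bisection_oracle(params, 10, "source")
  expect_equal(lw$r_threshold_um, or$r_threshold_um, tolerance = 1e-9)

  # sink oracle recovers the algebraic form
  sp <- h2o2_params(c_cell = 1e-10, c_seawater = 1e-9)
  expect_equal(bisection_oracle(sp, 0.5, "sink")$r_threshold_um,
               sink_threshold(sp, 0.5)$r_threshold_um, tolerance = 1e-12)
})
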