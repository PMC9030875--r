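test_that("community assessment compares spheres of influence with spacing", {
  res <- assess_community(plankton_taxa())
  expect_equal(nrow(res), nrow(plankton_taxa()))

  # Phaeocystis within its colony: sphere 22 um exceeds ~19.2 um spacing
  phaeo <- dplyr::filter(res, taxon == "Phaeocystis")
  expect_equal(phaeo$sphere_um, 2.2 * 1000^(1 / 3))
  expect_equal(phaeo$spacing_um, 19.204730227342576)
  expect_true(phaeo$interacting)

  # oligotrophic Prochlorococcus: 3 um sphere against ~165 um spacing
  proc <- dplyr::filter(res, taxon == "Prochlorococcus",
                        habitat == "oligotrophic", cells_per_m3 == 3.8e10)
  expect_equal(proc$sphere_um, 0.3 * 1000^(1 / 3))
  expect_equal(proc$spacing_um, 164.7722577758332)
  expect_false(proc$interacting)

  # heterotrophs get the sink expansion 1/ratio^(1/3)
  bact <- dplyr::filter(res, metabolism == "heterotroph")
  expect_equal(unique(bact$ratio), 0.1)
  expect_equal(bact$sphere_um, bact$cell_radius_um * 10^(1 / 3))
  expect_false(any(bact$interacting))

  # the flag restates the criterion exactly
  expect_equal(res$interacting, res$sphere_um >= res$spacing_um)

  # half-spacing criterion can only add interactions
  half <- assess_community(plankton_taxa(), criterion = "half_spacing")
  expect_true(all(half$interacting >= res$interacting))
  expect_equal(half$interacting, half$sphere_um >= half$spacing_um / 2)
})

test_that("assessment validates inputs and handles the empty community", {
  empty <- assess_community(plankton_taxa()[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("sphere_um", "spacing_um", "interacting") %in% names(empty)))

  expect_error(assess_community(plankton_taxa(), source_ratio = 0.5), "> 1")
  expect_error(assess_community(plankton_taxa(), sink_ratio = 2), "in \\(0, 1\\)")
})

test_that("threshold lines reproduce the critical densities", {
  # 40 um cells at ratio 1000 interact down to ~2.66e9 cells m^-3
  line <- threshold_line(1000, c(0.5, 2.5, 10, 40))
  expect_equal(line$critical_density_m3[line$radius_um == 40],
               2656170203.2242956)
  # small cells need enormous densities; both radius conventions
  expect_equal(line$critical_density_m3[line$radius_um == 0.5],
               1359959144050839.5)
  expect_equal(
    threshold_line(1000, 0.5, convention = "surface")$critical_density_m3,
    1865513229150671.0)

  # monotone decreasing in radius and in ratio
  expect_true(all(diff(line$critical_density_m3) < 0))
  d100 <- threshold_line(100, c(0.5, 2.5, 10, 40))$critical_density_m3
  expect_true(all(line$critical_density_m3 < d100))

  # identity ratio: sphere equals the bare cell radius
  expect_equal(threshold_line(1, 10)$sphere_um, 10)
  # sink ratios invert
  expect_equal(threshold_line(0.1, 0.5)$sphere_um, 0.5 * 10^(1 / 3))

  expect_error(threshold_line(-1, 1), "> 0")
})

test_that("running the assessment at the critical density closes the loop", {
  line <- threshold_line(1000, c(0.5, 1, 2.2, 10, 40))
  for (i in seq_len(nrow(line))) {
    comm <- one_taxon(density = line$critical_density_m3[i],
                      radius = line$radius_um[i])
    res <- assess_community(comm, source_ratio = 1000)
    expect_equal(res$sphere_um, res$spacing_um, tolerance = 1e-9)
    # nudging density across the line flips the flag
    above <- assess_community(
      dplyr::mutate(comm, cells_per_m3 = cells_per_m3 * (1 + 1e-6)),
      source_ratio = 1000)
    below <- assess_community(
      dplyr::mutate(comm, cells_per_m3 = cells_per_m3 * (1 - 1e-6)),
      source_ratio = 1000)
    expect_true(above$interacting)
    expect_false(below$interacting)
  }
})

test_that("scene overlays count pairwise sphere overlaps", {
  comm <- one_taxon(density = 1e9, radius = 2.2)
  assess <- assess_community(comm)  # sphere 22 um

  lay1 <- tibble::tibble(taxon = "TestTaxon", x_mm = 0.5, y_mm = 0.5,
                         z_mm = 0.5, radius_um = 2.2)
  s1 <- overlay_habitat(comm, lay1, assess)
  expect_equal(nrow(s1), 1)
  expect_equal(attr(s1, "n_overlap_pairs"), 0)
  expect_false(s1$overlapping)

  # 30 um apart with 22 um spheres: spheres intersect (30 < 44)
  lay2 <- tibble::tibble(taxon = "TestTaxon", x_mm = c(0.5, 0.53),
                         y_mm = 0.5, z_mm = 0.5, radius_um = 2.2)
  s2 <- overlay_habitat(comm, lay2, assess)
  expect_equal(attr(s2, "n_overlap_pairs"), 1)
  expect_equal(s2$n_overlaps, c(1L, 1L))

  # 50 um apart: no overlap
  lay3 <- tibble::tibble(taxon = "TestTaxon", x_mm = c(0.5, 0.55),
                         y_mm = 0.5, z_mm = 0.5, radius_um = 2.2)
  expect_equal(attr(overlay_habitat(comm, lay3, assess), "n_overlap_pairs"), 0)

  expect_error(overlay_habitat(comm, dplyr::mutate(lay1, taxon = "Other"),
                               assess), "mismatch")
  expect_equal(glance(s2)$frac_overlapping, 1)
})

test_that("colony cells are almost all within reach of a neighbour", {
  colony <- dplyr::filter(plankton_taxa(), taxon == "Phaeocystis")
  assess <- assess_community(colony)
  fracs <- vapply(1:5, function(s) {
    lay <- generate_layout(colony, layout_config(extent_mm = 0.1,
                                                 mode = "uniform_random",
                                                 seed = s))
    glance(overlay_habitat(colony, lay, assess))$frac_overlapping
  }, numeric(1))
  expect_gt(mean(fracs), 0.9)
})

test_that("interaction flags agree with simulated nearest-neighbour geometry", {
  # flagged taxon: mean nn distance below the sphere radius, and vice versa
  cases <- list(
    list(comm = dplyr::filter(plankton_taxa(), taxon == "Phaeocystis"),
         extent = 0.2),
    list(comm = dplyr::filter(plankton_taxa(), taxon == "Synechococcus",
                              habitat == "eutrophic"),
         extent = 2)
  )
  for (cs in cases) {
    assess <- assess_community(cs$comm)
    lay <- generate_layout(cs$comm, layout_config(extent_mm = cs$extent,
                                                  mode = "uniform_random",
                                                  seed = 21))
    nn <- nearest_neighbour_stats(lay, boundary = "periodic")
    geom_flag <- nn$mean_nn * 1e3 <= assess$sphere_um
    expect_equal(geom_flag, assess$interacting)
  }
})
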