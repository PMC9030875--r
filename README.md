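# h2o2sphere

Can one plankton cell directly influence a neighbour by leaking (or
consuming) hydrogen peroxide, or does its H2O2 merely feed the bulk
seawater pool? `h2o2sphere` answers this for marine phytoplankton and
bacterioplankton communities by comparing two lengths:

* the **mean cell-to-cell spacing** implied by a habitat's cell suspension
  density, using the Poisson nearest-neighbour correction

  $$\bar d = \Gamma(4/3)\,(4\pi/3)^{-1/3}\,\rho^{-1/3} \approx 0.554\,\rho^{-1/3},$$

  with $\rho$ in cells mm⁻³ (the "multiply the reciprocal cube root of
  density by 0.55" rule, kept at full precision); and

* the **cell-specific sphere of influence**: the radius at which
  \[H2O2\] diffusing outward from a source cell of radius $R$, diluting
  volumetrically with the displacement front $r(t) = R + \sqrt{Dt}$ and
  decaying pseudo-first-order,

  $$C(t) = C_{cell}\,(R/r(t))^{3}\,e^{-\mu t},$$

  falls back to the seawater background $C_{sea}$. With
  $k = C_{sea}/(C_{cell}R^3)$ the threshold time has the closed form

  $$t^{*} = W_0\!\left((k^{-1/3}-R)^2\,\tfrac{2\mu}{3D}\right)\Big/\tfrac{2\mu}{3},$$

  on the principal branch of the Lambert W function (zero-decay limit
  $r^{*} = R\,(C_{cell}/C_{sea})^{1/3}$). Heterotrophic sink cells holding
  internal \[H2O2\] below background get the mirrored algebraic form
  $r^{*} = R\,(C_{sea}/C_{cell})^{1/3}$.

Where the sphere of influence reaches the mean spacing, direct
cell-to-cell interaction via H2O2 is feasible. The package ships a curated
taxa × habitat table of cell radii and suspension densities
(`plankton_taxa()`), a reproducible 3-D layout simulator (jittered lattice
and uniform-random modes), gradient profiles on a log10 time grid,
threshold solvers with an independent bisection oracle, habitat-level
interaction classification, threshold lines in density–radius space, and
true-scale ggplot2 visualisations. Everything takes and returns tibbles,
so results pipe straight into dplyr/ggplot2.

## Worked example

A diatom-sized source cell (radius 10 µm, intracellular 10⁻⁶ M over a
10⁻⁹ M background):

```r
library(h2o2sphere)
library(dplyr)

source_threshold_zero_decay(h2o2_params(), cell_radius_um = 10)
#> # A tibble: 1 × 8
#>   direction method                 cell_radius_um ratio mu_per_us t_threshold_us
#> 1 source    closed_form_zero_decay             10  1000         0            5.4
#>   r_threshold_um dist_surface_um
#> 1            100              90
```

The sphere of influence extends 100 µm from the cell centre — 90 µm of
seawater beyond the cell surface. Within a *Phaeocystis* colony, cells sit
about 19 µm apart:

```r
mean_cell_spacing(2.4e13)
#> # A tibble: 1 × 4
#>   density_m3 correction spacing_mm spacing_um
#> 1    2.40e13      0.554     0.0192       19.2
```

so their 22 µm spheres overlap neighbouring cells — and that is the only
record in the shipped table for which they do:

```r
assess_community(plankton_taxa()) |> filter(interacting)
#> # A tibble: 1 × 9
#>   taxon       habitat metabolism cells_per_m3 cell_radius_um ratio sphere_um
#> 1 Phaeocystis colony  phototroph      2.40e13            2.2  1000        22
#>   spacing_um interacting
#> 1       19.2 TRUE
```

Threshold lines generalise this: at an intracellular:extracellular ratio
of 1000, 40 µm cells keep overlapping spheres down to ~2.7 × 10⁹ cells
m⁻³, while 0.5 µm cells would need ~10¹⁵ cells m⁻³ — far beyond any marine
habitat:

```r
threshold_line(1000, c(0.5, 2.5, 10, 40))
#> # A tibble: 4 × 4
#>   ratio radius_um sphere_um critical_density_m3
#> 1  1000       0.5         5             1.36e15
#> 2  1000       2.5        25             1.09e13
#> 3  1000      10         100             1.70e11
#> 4  1000      40         400             2.66e 9
```

Figures (true-scale community scatters, gradient profiles with seawater
and cytotoxic bands, sphere-of-influence overlays, threshold-line plots)
render via `plot_community()`, `autoplot()`, `plot_threshold_lines()` and
`save_figures()`, each backed by a sidecar CSV of the plotted numbers.
See the vignette in `vignettes/h2o2-spheres-of-influence.Rmd` for the full
model description, assumptions and numerical choices.

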