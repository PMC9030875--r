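---
title: "Modelling diffusional H2O2 interactions among marine plankton"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling diffusional H2O2 interactions among marine plankton}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h2o2sphere)
library(dplyr)
```

## The question

Marine phytoplankton and bacterioplankton exchange solutes — nutrients,
signals, reactive oxygen species — by diffusion across the water separating
them. Hydrogen peroxide is a particularly tractable case: it crosses cell
membranes readily, persists in seawater for hours to days, and occurs at
documented concentrations both inside cells and in bulk seawater. Whether
one cell can *directly* influence a neighbour via H2O2, rather than merely
contributing to the bulk background, comes down to two lengths:

* the **mean cell-to-cell spacing**, set by the cell suspension density of
  the habitat, and
* the **cell-specific sphere of influence**, the radius out to which a cell
  holding its internal \[H2O2\] above (source) or below (sink) the seawater
  background perturbs the local concentration before dilution returns it to
  background.

Direct interaction is feasible where the sphere of influence reaches the
spacing; otherwise cells only interact through the bulk pool. `h2o2sphere`
implements both lengths, a concentration-gradient simulator connecting
them, and habitat-level classification and visualisation built on a curated
table of cell radii and suspension densities across oligotrophic,
mesotrophic, eutrophic and colonial habitats (`plankton_taxa()`).

## Cell spacing from suspension density

For a density $\rho$ expressed in cells mm$^{-3}$ (equivalently cells
µL$^{-1}$; the package stores densities in cells m$^{-3}$ and converts
internally), the reciprocal cube root $\rho^{-1/3}$ is the pitch of an
evenly spaced lattice — a *maximum* spacing. Randomly located cells sit
closer on average: for a homogeneous Poisson process the mean
nearest-neighbour distance is

$$\bar d = \Gamma(4/3)\left(\tfrac{4\pi}{3}\right)^{-1/3} \rho^{-1/3}
        \approx 0.5540\,\rho^{-1/3},$$

which is the familiar "multiply by 0.55" correction. `mean_cell_spacing()`
defaults to the exact constant (`nn_constant()`), not the rounded 0.55,
because downstream critical densities scale with its cube and the rounded
constant shifts them by ~2%; `nn_constant(exact = FALSE)` restores 0.55 for
comparison with older calculations. `critical_density_for_spacing()` is the
exact algebraic inverse, used for threshold lines.

```{r spacing}
mean_cell_spacing(c(1e9, 4.6e11, 2.4e13))
```

The constant is not taken on faith: `generate_layout()` in
`"uniform_random"` mode simulates complete spatial randomness (Poisson
point counts, i.i.d. uniform coordinates), and
`nearest_neighbour_stats()` with periodic boundaries recovers
$\bar d\,\rho^{1/3} \approx 0.554$ by Monte Carlo — the test suite does
this with ~4,000 points and the acceptance script with >20,000.

## Synthetic community layouts

`generate_layout()` emulates the spatial structure the analysis assumes,
in two modes:

* `"jittered_lattice"` — per taxon, a cubic lattice at the mean-spacing
  pitch, each coordinate perturbed by uniform noise of half-width
  `jitter_fraction × pitch` and clipped to the box. The default
  `jitter_fraction = 0.4` mirrors the conventional jitter amount of
  *factor* × *d*/5 with factor 2 for regularly spaced input; the exact
  half-width affects no computed threshold, only the look of the point
  cloud. This mode is intended for true-scale visualisation.
* `"uniform_random"` — complete spatial randomness, the model under which
  the 0.554 constant is exact. Point counts are Poisson draws with mean
  density × volume rather than deterministic roundings, so small boxes at
  low densities can legitimately come out empty.

Co-occurring taxa are overlaid by concatenating independently generated
patterns. All randomness flows from the single seed in `layout_config()`;
the same config always reproduces the same layout. A configurable cap
(default $10^6$ expected points) refuses accidental colony-density ×
large-box requests.

What the generator does **not** emulate: non-random clustering (e.g.
around marine snow particles), attraction or repulsion between taxa,
bacterial colonization of colonies, advection, or cell motility. Passing
tests therefore validate the mathematics under spatial randomness, not the
full spatial ecology of natural communities.

## Concentration gradients around a cell

The cell is a static sphere of radius $R$ (µm) holding a homeostatic
intracellular concentration $C_{cell}$. After time $t$ (µs) the diffusional
displacement front sits at

$$r(t) = R + \sqrt{D\,t},$$

with $D$ the diffusion coefficient (default 1500, in the µm²/time units in
which the source literature reports it; the zero-decay threshold radius is
independent of $D$, so none of the headline radii depend on this unit
choice — only the nominal times do). For a **source** cell the surface
concentration dilutes into the growing sphere by volume,

$$C(t) = C_{cell}\left(\frac{R}{r(t)}\right)^{3} e^{-\mu t},$$

where $\mu$ is a pseudo-first-order decay constant
(`decay_constant_from_lifetime()`, e-folding convention $\mu = 1/\tau$; at
$t \le 100$ µs and lifetimes of an hour or more, $\mu t < 3\times10^{-8}$,
so decay is negligible for H2O2 — the decay term exists to keep the
machinery general for less stable species). For a **sink** cell the model
is the mirrored heuristic $C(t) = C_{cell}(r/R)^3$ with no decay term,
rising from the depressed surface value back to background; it is a
deliberate heuristic, not a steady-state diffusion solution, and is
implemented as stated.

Both profiles are clamped at the seawater background `c_seawater`
(floor for sources, ceiling for sinks): beyond the threshold the cell has
no *local* influence. The default time grid is $t = 0$ then log10-spaced
from $10^{-3}$ to $100$ µs at 20 points per decade; endpoints are fixed by
the simulated scenario, the resolution is a free choice exposed in
`time_grid()`.

```{r profile}
prof <- source_profile(h2o2_params(), cell_radius_um = 10)
glance(prof)
```

## Threshold radii: the Lambert W closed form

Setting $C(t) = C_{sea}$ and writing $k = C_{sea}/(C_{cell}R^3)$ leads,
after the substitution $Y = \tfrac{2}{3}\mu t$, to $Y e^Y = x$ with

$$x = \left(k^{-1/3} - R\right)^{2}\frac{2\mu}{3D}, \qquad
  t^{*} = \frac{W_0(x)}{2\mu/3},$$

on the principal branch $W_0$ (the argument is non-negative for every
valid input, so the branch is unambiguous). Numerical choices:

* **Newton polish.** The algebra above rests on factoring
  $(R+\sqrt{Dt})e^{\mu t/3}$ approximately; the raw $W_0$ value can miss
  the true root by a relative $O(\mu t\cdot R/r^*)$ (up to ~$10^{-9}$ at
  the corners of the supported parameter range). `source_threshold_lambertw()`
  therefore polishes the $W_0$ start with Newton iterations on the
  log-concentration, so the returned $(t^*, r^*)$ reproduces `c_seawater`
  to machine precision and agrees with an independent bisection root
  (`bisection_oracle()`) to well below $10^{-6}$.
* **Zero-decay branch.** When $\mu t^{*} < 10^{-12}$ the solver falls
  through to the closed form $r^{*} = R\,(C_{cell}/C_{sea})^{1/3}$,
  $t^{*} = (r^{*}-R)^2/D$ (`source_threshold_zero_decay()`), avoiding the
  unstable evaluation of $W_0(x)/x$ as $x \to 0$.
* **Grid scan.** `source_threshold_grid()` reports the first simulated
  grid time past the crossing — always an overshoot of the continuous
  solution, shrinking with `points_per_decade`. On the default grid a
  0.3 µm cell at ratio 1000 lands at ~3.04 µm against the continuous
  3.00 µm; published figures of ~3.1 µm for this scenario are consistent
  with a coarser scan of the same model.
* **Conventions.** Results carry the radius both from the cell centre
  (`r_threshold_um`) and from the surface (`dist_surface_um`), because the
  field quotes both conventions; every function that consumes a sphere
  radius exposes a `convention` argument.

The sink threshold is purely algebraic,
$r^{*} = R\,(C_{sea}/C_{cell})^{1/3}$ (`sink_threshold()`), with no time
dependence.

```{r thresholds}
source_threshold_zero_decay(h2o2_params(), cell_radius_um = 10)
sink_threshold(h2o2_params(c_cell = 1e-10, c_seawater = 1e-9), 0.5)
```

## From thresholds to interaction classification

`assess_community()` composes the two lengths per community record:
phototrophs get the zero-decay source sphere at a configurable
intracellular:extracellular ratio (default 1000, i.e. $10^{-6}$ M over the
$10^{-9}$ M low-end background — the background choice that *maximises*
spheres of influence), heterotrophs the sink sphere (default ratio 0.1),
and each is compared with the mean spacing at that record's density.

Two genuinely open design choices are exposed rather than hidden:

* **Criterion.** The default flags interaction when the sphere reaches the
  *full* mean spacing (centre-to-centre); `criterion = "half_spacing"`
  instead lets two like spheres meet halfway. The full-spacing criterion
  with the centre convention and the exact Poisson constant is the
  combination that reproduces the published critical density for 40 µm
  cells (~2.7 × 10⁹ cells m⁻³) to three figures, so it is the default.
* **Radius convention.** Centre (default) or surface. For small cells the
  two differ materially — a 0.5 µm cell at ratio 1000 has a critical
  density of ~1.4 × 10¹⁵ m⁻³ under the centre convention and
  ~1.9 × 10¹⁵ m⁻³ under the surface convention — and published small-cell
  figures match the surface convention while the 40 µm figure matches the
  centre convention. Both are computed; the default follows the most
  precisely printed number.

`threshold_line()` sweeps cell radius at a fixed ratio and returns the
critical density per radius (the interaction/no-interaction boundary in
density–radius space; defaults of {10, 100, 1000, 10000} for sources and
their inverses for sinks bracket the ratios discussed in the literature),
and `overlay_habitat()` joins a layout with assessments into a per-cell
scene with pairwise sphere-overlap counts.

```{r assess}
assess_community(plankton_taxa()) |>
  filter(interacting)
```

Only the *Phaeocystis* colony record interacts under the defaults: within
colonies, cells sit ~19 µm apart with ~22 µm spheres, while even eutrophic
open-water populations are an order of magnitude too sparse.

## Visualisation

`plot_community()` draws layouts with cell symbols as circles whose
data-space radius equals the cell radius — the same scale as the spatial
axes — deliberately refusing the marker-size exaggeration that makes
plankton cartoons look crowded; depth is cued by opacity
($\alpha \propto 1 - z/\mathrm{extent}$, clipped to $[0.15, 1]$).
`autoplot()` on profiles shows both concentration series against the
seawater and cytotoxic bands; on scenes it overlays translucent spheres of
influence (pale blue sources, red sinks). `plot_threshold_lines()` places
community records in density–radius space against the threshold lines.
`save_figures()` renders the full set with sidecar CSVs carrying every
plotted number, so figures are pure views over exported tables and a run
is reproducible from (community, params, config, seed) alone.

## Problem sizes and test design

The package validates itself at sizes chosen to exercise the mathematics
well: nearest-neighbour code is checked exactly against a brute-force
all-pairs oracle up to 600 points; the Poisson constant is recovered with
~4,000 points in unit tests and >20,000 in the acceptance script (standard
error ~0.0015 on the scaled statistic, comfortably inside the ±0.01
acceptance band); Poisson count calibration uses 1,000 seeds at mean 4.5;
the Lambert-W/bisection cross-check sweeps 8 radii × 3 ratios × 3
lifetimes. Layout generation refuses more than $10^6$ expected points by
default.

## Limitations

* Static cells in still water: no advection, boundary-layer refreshment,
  sinking or motility.
* Homogeneous single-taxon spacing: spacing is computed per record, and
  overlap scenes concatenate independent patterns; joint spacing
  distributions of mixed communities are not modelled.
* The sink profile is a mirrored dilution heuristic, not a steady-state
  reaction–diffusion solution.
* No parameter sets for other reactive oxygen species are shipped; the
  decay machinery accepts arbitrary lifetimes but superoxide-specific
  chemistry (membrane impermeability, dismutation) is out of scope.
* Clustered point processes (colonies aside, which are handled as dense
  boxes) are not generated.
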