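# brute-force all-pairs nearest-neighbour oracle, deliberately naive:
# independent of the blocked search in the package
brute_nn <- function(pos, period = NULL) {
  n <- nrow(pos)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d2 <- 0
      for (a in 1:3) {
        dx <- abs(pos[i, a] - pos[j, a])
        if (!is.null(period)) dx <- min(dx, period[a] - dx)
        d2 <- d2 + dx^2
      }
      best <- min(best, d2)
    }
    out[i] <- sqrt(best)
  }
  out
}

# one-record community helper
one_taxon <- function(taxon = "TestTaxon", habitat = "eutrophic",
                      metabolism = "phototroph", density = 1e9, radius = 1) {
  tibble::tibble(habitat = habitat, taxon = taxon, metabolism = metabolism,
                 cells_per_m3 = density, cell_radius_um = radius,
                 citation = "test")
}

# exact Poisson nearest-neighbour constant, written out independently
poisson_nn_constant <- gamma(4 / 3) * (4 * pi / 3)^(-1 / 3)
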