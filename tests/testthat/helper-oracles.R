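# Independent oracles used to cross-check the package's vectorized
# computations.  These are deliberately written as plain nested loops /
# exhaustive enumeration, sharing no code with the implementation.

# Gain in Occupancy by direct summation over species rows and years.
brute_gain <- function(L, alloc, habitat) {
  years <- L$climate$year
  total <- 0
  for (t in seq_along(years)) {
    a <- L$climate$anomaly[t]
    for (r in seq_len(nrow(L$species))) {
      sp <- L$species[r, ]
      ci <- which(L$cells$cell_id == sp$cell_id)
      ai <- which(alloc$cells$cell_id == sp$cell_id)
      area <- L$cells$farmland_area[ci]
      fh <- if (area > 0) alloc$cells$habitat_ha[ai] / area else 0
      fl <- if (area > 0) alloc$cells$lowyield_ha[ai] / area else 0
      d <- sp[[paste0("delta_", habitat)]]
      occ1 <- min(1, max(0, sp$p0 + d * fh + sp$gamma * fl + sp$beta * a))
      occ0 <- min(1, max(0, sp$p0 + sp$beta * a))
      total <- total + occ1 - occ0
    }
  }
  total / length(years)
}

# Exact optimum of the continuous knapsack
#   maximize sum_i v_i x_i  s.t.  sum_i w_i x_i = B,  0 <= x_i <= cap_i
# by vertex enumeration: every basic optimum has at most one fractional
# coordinate, so enumerate all fully-converted subsets plus one
# fractional cell.  Independent of the greedy implementation.
knapsack_oracle <- function(v, w, cap, B) {
  n <- length(v)
  best <- -Inf
  for (mask in 0:(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    wS <- sum(w[S] * cap[S])
    vS <- sum(v[S] * cap[S])
    resid <- B - wS
    if (abs(resid) <= 1e-9 * max(B, 1)) best <- max(best, vS)
    if (resid > 0) {
      for (j in setdiff(seq_len(n), S)) {
        if (w[j] > 0 && resid / w[j] <= cap[j] + 1e-12)
          best <- max(best, vS + v[j] * resid / w[j])
      }
    }
  }
  best
}

# closed-form annuity factor for a constant unit flow over n years
annuity_factor <- function(rate, n_years)
  (1 - (1 + rate)^(-n_years)) / (1 - (1 + rate)^(-1))

# small seeded landscape for property tests
small_landscape <- function(seed, n_cols = 6, n_rows = 6, n_species = 8)
  generate_landscape(generator_config(
    n_cols = n_cols, n_rows = n_rows, n_species = n_species, seed = seed))

# hand-built landscape from explicit cell yields/areas and species
# response vectors (one row per species x cell, recycled)
make_landscape <- function(yields, areas = rep(100, length(yields)),
                           p0 = 0.2, delta_g = 0.3, delta_w = 0.1,
                           gamma = 0, beta = 0, anomaly_slope = 0,
                           n_species = 1, lowyield_factor = 0.1) {
  n <- length(yields)
  cells <- data.frame(
    cell_id = seq_len(n), col = seq_len(n), row = rep(1L, n),
    farmland_area = areas, yield_rate = yields,
    stratum = rep("lowland", n), kappa = rep(0, n))
  sp <- expand.grid(cell_id = seq_len(n), species_id = seq_len(n_species))
  species <- data.frame(
    species_id = sp$species_id, cell_id = sp$cell_id,
    p0 = rep_len(p0, n * n_species),
    delta_grassland = rep_len(delta_g, n * n_species),
    delta_woodland = rep_len(delta_w, n * n_species),
    gamma = rep_len(gamma, n * n_species),
    beta = rep_len(beta, n * n_species))
  years <- 2020:2060
  climate <- data.frame(year = years,
                        anomaly = anomaly_slope * (years - 2020))
  landscape(cells, species, climate, lowyield_factor)
}

# default seeded study landscape, built once per test run
default_landscape_cache <- new.env(parent = emptyenv())
default_landscape <- function() {
  if (is.null(default_landscape_cache$L))
    default_landscape_cache$L <- generate_landscape(generator_config())
  default_landscape_cache$L
}
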