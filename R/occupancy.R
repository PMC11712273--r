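# Species occupancy under a land-use state, and the Gain-in-Occupancy
# biodiversity metric: per-cell, per-species changes in probability of
# occurrence summed over cells and species and averaged over the horizon.

#' Per-cell species occupancy under a land-use state
#'
#' The occupancy response is linear in the converted fractions and the
#' climate anomaly, clipped to the unit interval:
#' `clip(p0 + delta * f_habitat + gamma * f_lowyield + beta * anomaly, 0, 1)`.
#' All arguments are vectorized and recycled.
#'
#' @param p0 baseline occupancy probability in \[0, 1\].
#' @param delta occupancy change at full conversion of the cell's
#'   farmland to the conservation habitat.
#' @param gamma occupancy change at full conversion to low-yield
#'   agriculture.
#' @param f_habitat,f_lowyield converted fractions of the cell's
#'   farmland, each in \[0, 1\] with sum at most 1.
#' @param beta occupancy change per unit climate anomaly.
#' @param anomaly climate anomaly (0 at the base year).
#' @return occupancy probabilities in \[0, 1\].
#' @examples
#' cell_occupancy(0.1, 0.9, f_habitat = 0.5)  # 0.55
#' @export
cell_occupancy <- function(p0, delta, gamma = 0, f_habitat = 0,
                           f_lowyield = 0, beta = 0, anomaly = 0) {
  if (any(f_habitat < 0 | f_lowyield < 0 | f_habitat + f_lowyield > 1 + 1e-9))
    stop("converted fractions must be in [0, 1] with sum <= 1")
  pmin(1, pmax(0, p0 + delta * f_habitat + gamma * f_lowyield +
                 beta * anomaly))
}

# species table aligned to the landscape cell order, with converted
# fractions attached; shared backbone of the occupancy aggregations
state_fractions <- function(landscape, allocation) {
  cells <- landscape$cells
  pos <- match(allocation$cells$cell_id, cells$cell_id)
  if (anyNA(pos)) stop("allocation references unknown cells")
  f_hab <- f_low <- numeric(nrow(cells))
  area <- cells$farmland_area
  nz <- area > 0
  f_hab[pos[nz]] <- allocation$cells$habitat_ha[nz] / area[pos[nz]]
  f_low[pos[nz]] <- allocation$cells$lowyield_ha[nz] / area[pos[nz]]
  list(f_habitat = f_hab, f_lowyield = f_low)
}

# per-cell sum over species of (scenario - baseline) occupancy,
# averaged over the climate horizon; cells in landscape order
occupancy_gain_cells <- function(landscape, allocation, habitat) {
  habitat <- match.arg(habitat, HABITATS)
  if (!identical(sort(allocation$cells$cell_id),
                 sort(landscape$cells$cell_id)))
    stop("allocation references unknown cells")
  st <- state_fractions(landscape, allocation)
  sp <- landscape$species
  cell_pos <- match(sp$cell_id, landscape$cells$cell_id)
  delta <- sp[[paste0("delta_", habitat)]]
  lin_scen <- sp$p0 + delta * st$f_habitat[cell_pos] +
    sp$gamma * st$f_lowyield[cell_pos]
  lin_base <- sp$p0
  anomalies <- landscape$climate$anomaly
  acc <- numeric(nrow(sp))
  for (a in anomalies) {
    shift <- sp$beta * a
    acc <- acc + pmin(1, pmax(0, lin_scen + shift)) -
      pmin(1, pmax(0, lin_base + shift))
  }
  acc <- acc / length(anomalies)
  sums <- tapply(acc, cell_pos, sum)
  out <- numeric(nrow(landscape$cells))
  out[as.integer(names(sums))] <- as.numeric(sums)
  out
}

#' Gain in Occupancy of a policy allocation
#'
#' The biodiversity headline metric: the change in occupancy relative to
#' the no-policy baseline, summed across all cells and species, computed
#' at each year's climate anomaly over the horizon and averaged over
#' years.  With zero climate sensitivities the climate terms cancel in
#' the difference, and the metric equals the single-year sum.
#'
#' @param landscape a `landscape`.
#' @param allocation an `allocation` over the same cells.
#' @param habitat conservation habitat label; defaults to the
#'   allocation's own habitat.
#' @return a single dimensionless gain (summed occupancy probability).
#' @export
gain_in_occupancy <- function(landscape, allocation,
                              habitat = allocation$habitat)
  sum(occupancy_gain_cells(landscape, allocation, habitat))

#' Per-cell species-richness change map
#'
#' For each grid cell, the change in expected species richness (the sum
#' over species of the occupancy change against the no-policy baseline),
#' averaged over the climate horizon.  Summing the map over cells
#' reproduces [gain_in_occupancy()] exactly.
#'
#' @inheritParams gain_in_occupancy
#' @return data.frame (`cell_id`, `col`, `row`, `value`).
#' @export
richness_change_map <- function(landscape, allocation,
                                habitat = allocation$habitat) {
  vals <- occupancy_gain_cells(landscape, allocation, habitat)
  data.frame(cell_id = landscape$cells$cell_id,
             col = landscape$cells$col, row = landscape$cells$row,
             value = vals)
}
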