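# Allocation rules and strategy-specific stopping conditions.
# Land is divisible: any portion of a cell's farmland can be converted.

#' Construct an allocation result
#'
#' Per-cell hectares converted out of conventional farming, split between
#' the conservation habitat and low-yield agriculture.
#'
#' @param landscape a `landscape`.
#' @param habitat_ha numeric vector, hectares converted to the
#'   conservation habitat, one value per cell in `landscape$cells` order.
#' @param lowyield_ha hectares converted to low-yield agriculture,
#'   same order.
#' @param habitat conservation habitat label, `"grassland"` or
#'   `"woodland"`.
#' @return an object of class `allocation` with a per-cell table and the
#'   area totals (`spared_area`, `habitat_area`, `lowyield_area`).
#' @export
allocation_result <- function(landscape, habitat_ha, lowyield_ha = NULL,
                              habitat = "grassland") {
  habitat <- match.arg(habitat, HABITATS)
  n <- nrow(landscape$cells)
  if (is.null(lowyield_ha)) lowyield_ha <- numeric(n)
  stopifnot(length(habitat_ha) == n, length(lowyield_ha) == n)
  if (any(habitat_ha < -1e-12) || any(lowyield_ha < -1e-12))
    stop("converted areas must be >= 0")
  habitat_ha <- pmax(habitat_ha, 0)
  lowyield_ha <- pmax(lowyield_ha, 0)
  over <- habitat_ha + lowyield_ha - landscape$cells$farmland_area
  if (any(over > 1e-6 * pmax(landscape$cells$farmland_area, 1)))
    stop("converted area exceeds farmland area in cell_id ",
         landscape$cells$cell_id[which.max(over)])
  structure(
    list(cells = data.frame(cell_id = landscape$cells$cell_id,
                            habitat_ha = habitat_ha,
                            lowyield_ha = lowyield_ha),
         habitat = habitat,
         spared_area = sum(habitat_ha) + sum(lowyield_ha),
         habitat_area = sum(habitat_ha),
         lowyield_area = sum(lowyield_ha)),
    class = "allocation")
}

#' Empty allocation (the no-policy baseline land use)
#' @inheritParams allocation_result
#' @export
empty_allocation <- function(landscape, habitat = "grassland")
  allocation_result(landscape, numeric(nrow(landscape$cells)),
                    habitat = habitat)

#' @export
print.allocation <- function(x, ...) {
  cat(sprintf(
    "<allocation> habitat '%s': %.3f ha spared (%.3f habitat + %.3f low-yield) over %d cells\n",
    x$habitat, x$spared_area, x$habitat_area, x$lowyield_area,
    sum(x$cells$habitat_ha + x$cells$lowyield_ha > 0)))
  invisible(x)
}

# per-cell summed habitat response across species, in landscape cell order
cell_delta_sums <- function(landscape, habitat) {
  habitat <- match.arg(habitat, HABITATS)
  col <- paste0("delta_", habitat)
  sums <- tapply(landscape$species[[col]], landscape$species$cell_id, sum)
  as.numeric(sums[as.character(landscape$cells$cell_id)])
}

#' Rank cells for greedy allocation
#'
#' Produces the ordered candidate list each greedy rule walks:
#' * `cost_min`: ascending agricultural output per hectare (yield), the
#'   lowest-subsidy-cost land first;
#' * `biodiv_max` under an area constraint (Sharing): descending
#'   per-hectare occupancy gain, `G_i = sum_s delta_{s,i,habitat} / A_i`,
#'   so converting `x` ha of cell `i` gains `x * G_i`;
#' * `biodiv_max` under the output-neutrality constraint (Sparing):
#'   descending gain per unit of forgone output, `G_i / y_i`;
#' * `equal`: no ranking — cells in `cell_id` order with equal scores
#'   (the quota is divided uniformly instead).
#'
#' Ties are broken by ascending `cell_id`.  Cells without farmland are
#' excluded.
#'
#' @param landscape a `landscape`.
#' @param rule `"equal"`, `"cost_min"` or `"biodiv_max"`.
#' @param habitat conservation habitat (used by `biodiv_max` only).
#' @param objective `"area_constrained"` (Sharing-style area target) or
#'   `"output_constrained"` (Sparing-style output neutrality).
#' @return data.frame (`cell_id`, `score`, `available_area`) in walk order.
#' @export
rank_cells <- function(landscape, rule, habitat = "grassland",
                       objective = c("area_constrained",
                                     "output_constrained")) {
  rule <- match.arg(rule, RULES)
  objective <- match.arg(objective)
  cells <- landscape$cells
  keep <- cells$farmland_area > 0
  ids <- cells$cell_id[keep]
  area <- cells$farmland_area[keep]
  yield <- cells$yield_rate[keep]
  if (rule == "equal") {
    ord <- order(ids)
    return(data.frame(cell_id = ids[ord], score = 0,
                      available_area = area[ord]))
  }
  if (rule == "cost_min") {
    score <- yield
    ord <- order(score, ids)
  } else {
    g_per_ha <- cell_delta_sums(landscape, habitat)[keep] / area
    if (objective == "area_constrained") {
      score <- g_per_ha
    } else {
      if (any(yield == 0))
        stop("output-constrained biodiversity ranking requires positive yields")
      score <- g_per_ha / yield
    }
    ord <- order(-score, ids)
  }
  data.frame(cell_id = ids[ord], score = score[ord],
             available_area = area[ord])
}

# iterative water-filling: divide `target` equally over cells with
# capacities `cap`, filling capped cells and re-dividing the shortfall
water_fill <- function(cap, target) {
  alloc <- numeric(length(cap))
  remaining <- target
  repeat {
    active <- which(cap - alloc > 1e-12)
    if (!length(active) || remaining <= 1e-12 * max(target, 1)) break
    share <- remaining / length(active)
    add <- pmin(share, cap[active] - alloc[active])
    alloc[active] <- alloc[active] + add
    remaining <- remaining - sum(add)
    if (all(add >= share - 1e-15 * share)) break
  }
  alloc
}

#' Area-targeted conservation allocation (Sharing)
#'
#' Converts a fixed total farmland area to the conservation habitat.
#' Under `equal` the target is divided equally across cells by
#' water-filling (cells with less farmland than their share are filled to
#' capacity and the shortfall re-divided among the rest).  Under
#' `cost_min` and `biodiv_max` the ranking from [rank_cells()] is walked,
#' converting whole cells until the residual target is smaller than the
#' next cell's farmland, then converting a fractional area so the total
#' matches the target exactly.
#'
#' @param landscape a `landscape`.
#' @param rule allocation rule.
#' @param target_area total hectares to convert; must not exceed total
#'   farmland.
#' @param habitat conservation habitat label.
#' @return an `allocation` with `habitat_area == target_area` and no
#'   low-yield compartment.
#' @export
allocate_shared_area <- function(landscape, rule, target_area,
                                 habitat = "grassland") {
  rule <- match.arg(rule, RULES)
  habitat <- match.arg(habitat, HABITATS)
  if (target_area < 0) stop("target_area must be >= 0")
  tf <- total_farmland(landscape)
  if (target_area > tf * (1 + 1e-12))
    stop(sprintf("target_area (%.6g ha) exceeds total farmland (%.6g ha)",
                 target_area, tf))
  cells <- landscape$cells
  hab <- numeric(nrow(cells))
  if (rule == "equal") {
    keep <- cells$farmland_area > 0
    hab[keep] <- water_fill(cells$farmland_area[keep], target_area)
  } else {
    rk <- rank_cells(landscape, rule, habitat, "area_constrained")
    pos <- match(rk$cell_id, cells$cell_id)
    remaining <- target_area
    for (k in seq_len(nrow(rk))) {
      if (remaining <= 0) break
      take <- min(rk$available_area[k], remaining)
      hab[pos[k]] <- take
      remaining <- remaining - take
    }
  }
  allocation_result(landscape, hab, habitat = habitat)
}

#' Output-neutral conservation allocation (Sparing)
#'
#' A proportional yield uplift `g` raises output on retained farmland;
#' land is converted to conservation until total food output returns
#' exactly to its pre-uplift baseline.  The converted areas `c_i` solve
#' `sum_i y_i c_i = g / (1 + g) * sum_i y_i A_i`.  Under `equal` this has
#' the closed form of a uniform converted fraction `f = g / (1 + g)` of
#' every cell's farmland (`f < 1`, so capacity caps never bind).  Under
#' `cost_min` and `biodiv_max` (output-constrained ranking) the greedy
#' walk converts whole cells and a fractional final cell so the output
#' identity holds.
#'
#' @param landscape a `landscape`.
#' @param rule allocation rule.
#' @param uplift proportional yield increase `g >= 0`.
#' @param habitat conservation habitat label.
#' @param max_uplift upper bound on `g` (policy cap).
#' @return an `allocation` with no low-yield compartment.
#' @export
allocate_spared <- function(landscape, rule, uplift,
                            habitat = "grassland", max_uplift = 0.05) {
  rule <- match.arg(rule, RULES)
  habitat <- match.arg(habitat, HABITATS)
  if (uplift < 0) stop("uplift must be >= 0")
  if (uplift > max_uplift + 1e-12)
    stop(sprintf("uplift %.4g exceeds the configured maximum %.4g",
                 uplift, max_uplift))
  cells <- landscape$cells
  hab <- numeric(nrow(cells))
  if (uplift == 0)
    return(allocation_result(landscape, hab, habitat = habitat))
  required_output <- uplift / (1 + uplift) * baseline_output(landscape)
  if (rule == "equal") {
    f <- uplift / (1 + uplift)
    hab <- f * cells$farmland_area
  } else {
    rk <- rank_cells(landscape, rule, habitat, "output_constrained")
    pos <- match(rk$cell_id, cells$cell_id)
    yields <- cells$yield_rate[pos]
    remaining <- required_output
    for (k in seq_len(nrow(rk))) {
      if (remaining <= 0) break
      cell_output <- yields[k] * rk$available_area[k]
      if (cell_output <= remaining || yields[k] == 0) {
        hab[pos[k]] <- rk$available_area[k]
        remaining <- remaining - cell_output
      } else {
        hab[pos[k]] <- remaining / yields[k]
        remaining <- 0
      }
    }
  }
  allocation_result(landscape, hab, habitat = habitat)
}

#' Split a spared allocation into three compartments
#'
#' Three-Compartment Sparing keeps the total spared area fixed but
#' reassigns exactly one-third of the spared hectares from natural
#' habitat to low-yield agriculture, choosing the lowest-output hectares
#' first (ascending cell yield, ties by ascending `cell_id`) with a
#' fractional split of the marginal cell.
#'
#' @param landscape a `landscape`.
#' @param spared an `allocation` from [allocate_spared()] (no low-yield
#'   compartment).
#' @return an `allocation` with `lowyield_area == spared_area / 3` and an
#'   unchanged total spared area.
#' @export
split_three_compartment <- function(landscape, spared) {
  stopifnot(inherits(spared, "allocation"))
  if (spared$lowyield_area > 0)
    stop("input allocation already contains low-yield area")
  hab <- spared$cells$habitat_ha
  low <- numeric(length(hab))
  target_low <- spared$spared_area / 3
  if (target_low > 0) {
    cells <- landscape$cells
    idx <- which(hab > 0)
    ord <- idx[order(cells$yield_rate[idx], cells$cell_id[idx])]
    remaining <- target_low
    for (i in ord) {
      if (remaining <= 0) break
      move <- min(hab[i], remaining)
      low[i] <- move
      hab[i] <- hab[i] - move
      remaining <- remaining - move
    }
  }
  allocation_result(landscape, hab, low, habitat = spared$habitat)
}
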