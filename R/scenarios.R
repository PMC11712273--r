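# Compose allocation, occupancy and economics into single policy runs,
# parameter sweeps (one curve per strategy/rule/habitat) and the full
# 3 strategies x 3 rules x 2 habitats factorial.

#' Specify a conservation policy
#'
#' @param strategy `"sharing"` (area target, no uplift), `"sparing"`
#'   (output-neutral yield uplift) or `"sparing3c"` (sparing followed by
#'   the three-compartment split).
#' @param rule allocation rule: `"equal"`, `"cost_min"` or
#'   `"biodiv_max"`.
#' @param habitat conservation habitat: `"grassland"` or `"woodland"`.
#' @param parameter the strategy lever: hectares of conservation for
#'   sharing; the yield-uplift fraction `g` for sparing/sparing3c.
#' @param max_uplift policy cap on the uplift (default 0.05).
#' @return an object of class `policy_spec`.
#' @export
policy_spec <- function(strategy, rule, habitat, parameter,
                        max_uplift = 0.05) {
  strategy <- match.arg(strategy, STRATEGIES)
  rule <- match.arg(rule, RULES)
  habitat <- match.arg(habitat, HABITATS)
  if (parameter < 0) stop("policy parameter must be >= 0")
  if (strategy != "sharing" && parameter > max_uplift + 1e-12)
    stop(sprintf("uplift %.4g exceeds the configured maximum %.4g",
                 parameter, max_uplift))
  structure(list(strategy = strategy, rule = rule, habitat = habitat,
                 parameter = parameter, max_uplift = max_uplift),
            class = "policy_spec")
}

#' Run one policy scenario against the no-policy baseline
#'
#' Builds the allocation the policy implies (area-targeted for sharing;
#' output-neutral for sparing; output-neutral plus the one-third
#' low-yield split for sparing3c), then scores it: Gain in Occupancy,
#' per-year food-output deltas and their NPV, the leakage NPV, the
#' opportunity-cost NPV (forgone output valued at `unit_price`), the
#' per-cell richness-change map and the per-cell selection map (converted
#' fraction of farmland).
#'
#' @param landscape a `landscape`.
#' @param policy a [policy_spec()].
#' @param discount_rate discount rate for all NPVs (default 0.035).
#' @param unit_price currency value of one output unit (default 1).
#' @return an object of class `scenario_outcome`.
#' @export
run_scenario <- function(landscape, policy, discount_rate = 0.035,
                         unit_price = 1) {
  stopifnot(inherits(policy, "policy_spec"))
  if (policy$strategy == "sharing") {
    alloc <- allocate_shared_area(landscape, policy$rule,
                                  policy$parameter, policy$habitat)
    uplift <- 0
  } else {
    alloc <- allocate_spared(landscape, policy$rule, policy$parameter,
                             policy$habitat, policy$max_uplift)
    uplift <- policy$parameter
    if (policy$strategy == "sparing3c")
      alloc <- split_three_compartment(landscape, alloc)
  }
  gain <- gain_in_occupancy(landscape, alloc)
  rich_map <- richness_change_map(landscape, alloc)
  delta <- delta_food_series(landscape, alloc, uplift)
  delta_npv <- npv(delta$delta, discount_rate, delta$year[1],
                   years = delta$year)
  leak <- leakage_indicator(delta, discount_rate)
  cells <- landscape$cells
  conv <- alloc$cells$habitat_ha + alloc$cells$lowyield_ha
  sel <- ifelse(cells$farmland_area > 0, conv / cells$farmland_area, 0)
  structure(
    list(policy = policy, allocation = alloc,
         gain_in_occupancy = gain,
         spared_area_ha = alloc$spared_area,
         habitat_area_ha = alloc$habitat_area,
         lowyield_area_ha = alloc$lowyield_area,
         delta_food = delta, delta_food_npv = delta_npv,
         leakage_npv = leak$npv,
         opportunity_cost_npv = -delta_npv * unit_price,
         richness_map = rich_map,
         selection_map = data.frame(cell_id = cells$cell_id,
                                    col = cells$col, row = cells$row,
                                    value = sel)),
    class = "scenario_outcome")
}

#' @export
print.scenario_outcome <- function(x, ...) {
  p <- x$policy
  cat(sprintf("<scenario_outcome> %s / %s / %s, parameter %.4g\n",
              p$strategy, p$rule, p$habitat, p$parameter))
  cat(sprintf(
    "  spared %.2f ha (habitat %.2f + low-yield %.2f)\n  gain in occupancy %.4f, delta-food NPV %.2f, leakage NPV %.2f\n",
    x$spared_area_ha, x$habitat_area_ha, x$lowyield_area_ha,
    x$gain_in_occupancy, x$delta_food_npv, x$leakage_npv))
  invisible(x)
}

outcome_row <- function(outcome) {
  p <- outcome$policy
  data.frame(strategy = p$strategy, rule = p$rule, habitat = p$habitat,
             parameter = p$parameter,
             spared_area_ha = outcome$spared_area_ha,
             habitat_area_ha = outcome$habitat_area_ha,
             lowyield_area_ha = outcome$lowyield_area_ha,
             gain_in_occupancy = outcome$gain_in_occupancy,
             delta_food_npv = outcome$delta_food_npv,
             leakage_npv = outcome$leakage_npv,
             opportunity_cost_npv = outcome$opportunity_cost_npv,
             stringsAsFactors = FALSE)
}

#' Default sharing sweep grid
#'
#' Area targets from zero to 15% of the landscape's total farmland in 10
#' equal steps — the synthetic analogue of sweeping a national
#' conservation-area target, expressed as a farmland fraction so it is
#' meaningful on any landscape size.
#'
#' @param landscape a `landscape`.
#' @param max_fraction top of the sweep as a fraction of total farmland.
#' @param n number of grid points (including 0).
#' @export
default_sharing_grid <- function(landscape, max_fraction = 0.15, n = 10)
  seq(0, max_fraction, length.out = n) * total_farmland(landscape)

#' Default sparing uplift grid: 1% to 5% yield increases
#' @export
default_uplift_grid <- function() seq(0.01, 0.05, by = 0.01)

#' Sweep one policy over a parameter grid
#'
#' One [run_scenario()] per grid value, summarized as one row each — the
#' machine-readable analogue of one curve in the strategy-comparison
#' figure.
#'
#' @inheritParams run_scenario
#' @param strategy,rule,habitat policy coordinates (see [policy_spec()]).
#' @param grid numeric vector of parameter values (hectares for sharing,
#'   uplift fractions otherwise); defaults to the strategy's default
#'   grid.
#' @return data.frame with columns `strategy`, `rule`, `habitat`,
#'   `parameter`, `spared_area_ha`, `habitat_area_ha`, `lowyield_area_ha`,
#'   `gain_in_occupancy`, `delta_food_npv`, `leakage_npv`,
#'   `opportunity_cost_npv`.
#' @export
sweep_policy <- function(landscape, strategy, rule, habitat, grid = NULL,
                         discount_rate = 0.035, unit_price = 1) {
  strategy <- match.arg(strategy, STRATEGIES)
  if (is.null(grid))
    grid <- if (strategy == "sharing") default_sharing_grid(landscape)
            else default_uplift_grid()
  rows <- lapply(sort(grid), function(par)
    outcome_row(run_scenario(landscape,
                             policy_spec(strategy, rule, habitat, par),
                             discount_rate, unit_price)))
  do.call(rbind, rows)
}

#' Full factorial: 3 strategies x 3 rules x 2 habitats
#'
#' Concatenates the 18 policy sweeps in deterministic lexicographic order
#' (strategy, rule, habitat, parameter).
#'
#' @inheritParams run_scenario
#' @param sharing_grid area-target grid (ha); defaults to
#'   [default_sharing_grid()].
#' @param uplift_grid uplift grid; defaults to [default_uplift_grid()].
#' @return a sweep table (see [sweep_policy()]) with one row per
#'   combination and grid value.
#' @export
factorial_run <- function(landscape, sharing_grid = NULL,
                          uplift_grid = NULL, discount_rate = 0.035,
                          unit_price = 1) {
  if (is.null(sharing_grid)) sharing_grid <- default_sharing_grid(landscape)
  if (is.null(uplift_grid)) uplift_grid <- default_uplift_grid()
  out <- list()
  for (strategy in sort(STRATEGIES))
    for (rule in sort(RULES))
      for (habitat in sort(HABITATS)) {
        grid <- if (strategy == "sharing") sharing_grid else uplift_grid
        out[[length(out) + 1L]] <-
          sweep_policy(landscape, strategy, rule, habitat, grid,
                       discount_rate, unit_price)
      }
  do.call(rbind, out)
}
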