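T4 <- toy_landscape()

test_that("rankings follow the rule definitions on the toy fixture", {
  expect_equal(rank_cells(T4, "cost_min")$cell_id, c(1, 2, 3, 4))
  # per-hectare grassland gains (0.003, 0.010, 0.005, 0.006)
  rk <- rank_cells(T4, "biodiv_max", "grassland", "area_constrained")
  expect_equal(rk$cell_id, c(2, 4, 3, 1))
  expect_equal(rk$score, c(0.010, 0.006, 0.005, 0.003), tolerance = 1e-12)
  # gain per unit forgone output (0.003, 0.005, 0.00125, 0.00075)
  rk2 <- rank_cells(T4, "biodiv_max", "grassland", "output_constrained")
  expect_equal(rk2$cell_id, c(2, 1, 3, 4))
  expect_equal(rk2$score, c(0.005, 0.003, 0.00125, 0.00075),
               tolerance = 1e-12)
  # equal: cell order, flat scores
  expect_equal(rank_cells(T4, "equal")$cell_id, 1:4)
  expect_error(rank_cells(T4, "optimal"), "'arg'")
})

test_that("ranking ties break by ascending cell id", {
  L <- make_landscape(yields = c(3, 3, 3), delta_g = 0.2)
  expect_equal(rank_cells(L, "cost_min")$cell_id, c(1, 2, 3))
  expect_equal(rank_cells(L, "biodiv_max")$cell_id, c(1, 2, 3))
})

test_that("area-targeted sharing places exactly the target", {
  eq <- allocate_shared_area(T4, "equal", 40)
  expect_equal(eq$cells$habitat_ha, rep(10, 4))
  expect_equal(eq$habitat_area, 40)
  expect_equal(eq$lowyield_area, 0)

  # water-filling with a capped cell
  L <- make_landscape(yields = c(1, 1, 1, 1),
                      areas = c(100, 100, 100, 20))
  wf <- allocate_shared_area(L, "equal", 200)
  expect_equal(wf$cells$habitat_ha, c(60, 60, 60, 20), tolerance = 1e-9)

  # greedy with a fractional stop in the first-ranked cell
  bm <- allocate_shared_area(T4, "biodiv_max", 40, "grassland")
  expect_equal(bm$cells$habitat_ha, c(0, 40, 0, 0))

  # greedy spanning several cells
  cm <- allocate_shared_area(T4, "cost_min", 250)
  expect_equal(cm$cells$habitat_ha, c(100, 100, 50, 0))

  expect_error(allocate_shared_area(T4, "equal", 500), "exceeds")
  expect_error(allocate_shared_area(T4, "equal", -1), ">= 0")
})

test_that("output-neutral sparing solves the uplift identity", {
  # closed form under equal allocation: f = g / (1 + g)
  s_eq <- allocate_spared(T4, "equal", 0.05)
  f <- 0.05 / 1.05
  expect_equal(s_eq$cells$habitat_ha, f * rep(100, 4), tolerance = 1e-12)
  expect_equal(s_eq$spared_area, 400 * f, tolerance = 1e-12)

  # greedy cost minimization: all in the lowest-yield cell
  s_cm <- allocate_spared(T4, "cost_min", 0.05)
  expect_equal(s_cm$cells$habitat_ha, c(0.05 / 1.05 * 1500, 0, 0, 0),
               tolerance = 1e-9)
  expect_equal(s_cm$spared_area, 71.428571, tolerance = 1e-6)

  # greedy biodiversity maximization: all in the top-ranked cell 2
  s_bm <- allocate_spared(T4, "biodiv_max", 0.05, "grassland")
  expect_equal(s_bm$cells$habitat_ha, c(0, 71.428571 / 2, 0, 0),
               tolerance = 1e-6)

  # output neutrality by direct recomputation
  for (al in list(s_eq, s_cm, s_bm))
    expect_equal(annual_food_output(T4, al, 0.05, 2020), 1500,
                 tolerance = 1e-12)

  expect_error(allocate_spared(T4, "equal", -0.01), ">= 0")
  expect_error(allocate_spared(T4, "equal", 0.2), "maximum")
  expect_equal(allocate_spared(T4, "equal", 0)$spared_area, 0)
})

test_that("greedy sparing can span multiple cells and stay neutral", {
  L <- make_landscape(yields = c(0.5, 0.6, 4, 6), areas = c(10, 10, 100, 100))
  al <- allocate_spared(L, "cost_min", 0.05)
  required <- 0.05 / 1.05 * baseline_output(L)
  expect_equal(sum(al$cells$habitat_ha * L$cells$yield_rate), required,
               tolerance = 1e-9 * required)
  # first two tiny cells fully converted, remainder fractional
  expect_equal(al$cells$habitat_ha[1:2], c(10, 10))
  expect_equal(annual_food_output(L, al, 0.05, 2020), baseline_output(L),
               tolerance = 1e-9 * baseline_output(L))
})

test_that("three-compartment split moves one-third to low-yield, lowest yield first", {
  s_cm <- allocate_spared(T4, "cost_min", 0.05)
  tc <- split_three_compartment(T4, s_cm)
  expect_equal(tc$spared_area, s_cm$spared_area, tolerance = 1e-12)
  expect_equal(tc$lowyield_area, s_cm$spared_area / 3, tolerance = 1e-9)
  expect_equal(tc$cells$habitat_ha[1], 47.619048, tolerance = 1e-6)
  expect_equal(tc$cells$lowyield_ha[1], 23.809524, tolerance = 1e-6)

  # ascending-yield fill across cells: 60/3 = 20 ha from the yield-2 cell
  L <- make_landscape(yields = c(2, 5))
  sp <- allocation_result(L, habitat_ha = c(30, 30))
  tc2 <- split_three_compartment(L, sp)
  expect_equal(tc2$cells$lowyield_ha, c(20, 0))
  expect_equal(tc2$cells$habitat_ha, c(10, 30))

  # empty in, empty out
  tc3 <- split_three_compartment(T4, empty_allocation(T4))
  expect_equal(tc3$spared_area, 0)

  expect_error(split_three_compartment(T4, tc), "already contains")
})

test_that("no cell is converted beyond its farmland, across rules and seeds", {
  for (seed in c(2, 9, 17)) {
    L <- small_landscape(seed)
    for (rule in c("equal", "cost_min", "biodiv_max")) {
      al <- allocate_shared_area(L, rule, 0.8 * total_farmland(L))
      tot <- al$cells$habitat_ha + al$cells$lowyield_ha
      expect_true(all(tot <= L$cells$farmland_area + 1e-9))
      sp <- allocate_spared(L, rule, 0.05)
      tc <- split_three_compartment(L, sp)
      tot <- tc$cells$habitat_ha + tc$cells$lowyield_ha
      expect_true(all(tot <= L$cells$farmland_area + 1e-9))
    }
  }
})

test_that("cost minimization spares at least as much land as equal allocation", {
  for (seed in c(4, 12, 23)) {
    L <- small_landscape(seed)
    for (g in c(0.01, 0.03, 0.05)) {
      a_cm <- allocate_spared(L, "cost_min", g)
      a_eq <- allocate_spared(L, "equal", g)
      expect_gte(a_cm$spared_area, a_eq$spared_area - 1e-9)
      expect_gte(a_eq$spared_area, 0)
    }
  }
})

test_that("allocation totals stay consistent with their per-cell sums", {
  al <- allocate_spared(T4, "cost_min", 0.03)
  expect_equal(al$habitat_area, sum(al$cells$habitat_ha),
               tolerance = 1e-12)
  tc <- split_three_compartment(T4, al)
  expect_equal(tc$spared_area,
               sum(tc$cells$habitat_ha + tc$cells$lowyield_ha),
               tolerance = 1e-12)
  expect_error(allocation_result(T4, c(200, 0, 0, 0)), "exceeds farmland")
})
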