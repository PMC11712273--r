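T4 <- toy_landscape()

test_that("landscape CSV round-trip is value-identical", {
  dir <- withr::local_tempdir()
  write_landscape(T4, dir)
  expect_setequal(list.files(dir),
                  c("cells.csv", "species.csv", "climate.csv",
                    "header.json"))
  back <- read_landscape(dir)
  expect_equal(back$cells, T4$cells)
  expect_equal(back$species, T4$species)
  expect_equal(back$climate, T4$climate)
  expect_equal(back$lowyield_factor, T4$lowyield_factor)

  # a generated landscape with full-precision doubles survives too
  L <- small_landscape(31)
  dir2 <- withr::local_tempdir()
  write_landscape(L, dir2)
  back2 <- read_landscape(dir2)
  expect_identical(back2$cells$yield_rate, L$cells$yield_rate)
  expect_identical(back2$species$p0, L$species$p0)
})

test_that("readers name schema and range violations precisely", {
  dir <- withr::local_tempdir()
  write_landscape(T4, dir)

  sp <- utils::read.csv(file.path(dir, "species.csv"))
  sp$p0[6] <- 1.2
  utils::write.csv(sp, file.path(dir, "species.csv"), row.names = FALSE)
  err <- tryCatch(read_landscape(dir), error = conditionMessage)
  expect_match(err, "species_id 2")
  expect_match(err, "cell_id 2")

  write_landscape(T4, dir)
  cells <- utils::read.csv(file.path(dir, "cells.csv"))
  cells$yield_rate <- NULL
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  expect_error(read_landscape(dir), "missing column\\(s\\): yield_rate")

  write_landscape(T4, dir)
  cells <- utils::read.csv(file.path(dir, "cells.csv"))
  cells$extra <- 1
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  expect_error(read_landscape(dir), "unexpected column\\(s\\): extra")

  expect_error(read_landscape(withr::local_tempdir()), "missing landscape")
})

test_that("maps export as ESRI ASCII grids and CSV", {
  dir <- withr::local_tempdir()
  cm <- allocate_shared_area(T4, "cost_min", 40)
  sel <- as.numeric(cm$cells$habitat_ha > 0)
  asc <- file.path(dir, "sel.asc")
  write_map(sel, T4, asc, "esri_ascii")
  lines <- readLines(asc)
  expect_equal(lines[1:6],
               c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
                 "cellsize 2000", "NODATA_value -9999"))
  # cell 1 (col 1, row 1) selected; row 1 written first (northernmost)
  expect_equal(lines[7], "1 0")
  expect_equal(lines[8], "0 0")

  write_map(rep(0, 4), T4, asc, "esri_ascii")
  expect_equal(readLines(asc)[7:8], c("0 0", "0 0"))

  csv <- file.path(dir, "sel.csv")
  write_map(richness_change_map(T4, cm), T4, csv, "csv")
  df <- utils::read.csv(csv)
  expect_equal(names(df), c("cell_id", "col", "row", "value"))
  expect_equal(df$value, c(0.12, 0, 0, 0), tolerance = 1e-12)

  # incomplete rectangles are rejected for rasters
  L3 <- T4
  L3$cells <- L3$cells[1:3, ]
  L3$species <- L3$species[L3$species$cell_id %in% 1:3, ]
  L3 <- landscape(L3$cells, L3$species, L3$climate)
  expect_error(write_map(rep(1, 3), L3, asc, "esri_ascii"),
               "rectangular")
  expect_error(write_map(rep(1, 3), T4, asc), "cover all cells")
})

test_that("cli generate is byte-deterministic and validates configs", {
  dir <- withr::local_tempdir()
  gen_cfg <- file.path(dir, "gen.json")
  jsonlite::write_json(list(n_cols = 5, n_rows = 4, n_species = 6,
                            seed = 11),
                       gen_cfg, auto_unbox = TRUE)
  out1 <- file.path(dir, "a"); out2 <- file.path(dir, "b")
  expect_equal(run_cli(c("generate", "--config", gen_cfg, "--out", out1),
                       quiet = TRUE), 0L)
  expect_equal(run_cli(c("generate", "--config", gen_cfg, "--out", out2),
                       quiet = TRUE), 0L)
  expect_identical(readLines(file.path(out1, "cells.csv")),
                   readLines(file.path(out2, "cells.csv")))
  L <- read_landscape(out1)
  expect_equal(nrow(L$cells), 20L)

  # run: sharing target beyond total farmland fails with a clear message
  bad_cfg <- file.path(dir, "bad.json")
  jsonlite::write_json(
    list(landscape = list(path = out1),
         policy = list(strategy = "sharing", rule = "equal",
                       habitat = "grassland", parameter = 1e9)),
    bad_cfg, auto_unbox = TRUE)
  msgs <- capture_messages(
    status <- run_cli(c("run", "--config", bad_cfg, "--out",
                        file.path(dir, "r")), quiet = TRUE))
  expect_equal(status, 1L)
  expect_match(paste(msgs, collapse = " "), "exceeds total farmland")

  expect_equal(suppressMessages(run_cli(c("explode"), quiet = TRUE)), 1L)
})

test_that("cli sweep output matches the sparing closed form", {
  dir <- withr::local_tempdir()
  tdir <- file.path(dir, "toy")
  write_landscape(toy_landscape(), tdir)
  cfg <- file.path(dir, "sweep.json")
  jsonlite::write_json(
    list(landscape = list(path = tdir),
         sweep = list(strategy = "sparing", rule = "equal",
                      habitat = "grassland",
                      grid = seq(0.01, 0.05, by = 0.01))),
    cfg, auto_unbox = TRUE)
  out <- file.path(dir, "sweep_out")
  expect_equal(run_cli(c("sweep", "--config", cfg, "--out", out),
                       quiet = TRUE), 0L)
  tab <- utils::read.csv(file.path(out, "sweep.csv"))
  g <- seq(0.01, 0.05, by = 0.01)
  expect_equal(tab$spared_area_ha, 400 * g / (1 + g), tolerance = 1e-9)
  expect_equal(names(tab),
               c("strategy", "rule", "habitat", "parameter",
                 "spared_area_ha", "habitat_area_ha", "lowyield_area_ha",
                 "gain_in_occupancy", "delta_food_npv", "leakage_npv",
                 "opportunity_cost_npv"))
})

test_that("cli run writes re-readable artifacts with summary metrics", {
  dir <- withr::local_tempdir()
  tdir <- file.path(dir, "toy")
  write_landscape(toy_landscape(), tdir)
  cfg <- file.path(dir, "run.json")
  jsonlite::write_json(
    list(landscape = list(path = tdir),
         policy = list(strategy = "sharing", rule = "cost_min",
                       habitat = "grassland", parameter = 40)),
    cfg, auto_unbox = TRUE)
  out <- file.path(dir, "run_out")
  expect_equal(run_cli(c("run", "--config", cfg, "--out", out),
                       quiet = TRUE), 0L)
  oc <- utils::read.csv(file.path(out, "outcome.csv"))
  expect_equal(oc$gain_in_occupancy, 0.12, tolerance = 1e-9)
  rmap <- utils::read.csv(file.path(out, "richness_map.csv"))
  expect_equal(rmap$value, c(0.12, 0, 0, 0), tolerance = 1e-9)
  expect_true(file.exists(file.path(out, "selection_map.asc")))
  expect_true(file.exists(file.path(out, "delta_food.csv")))
})
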