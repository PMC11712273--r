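# File round-trips (landscape <-> CSV + JSON header), raster/CSV map
# export, run configuration and the command-line entry points.
# All CSVs are comma-separated, dot-decimal, UTF-8, with a header row;
# numeric fields are serialized with 17 significant digits so that
# read(write(x)) is value-identical.

fmt_num <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  # integers print without decoration
  ints <- !is.na(x) & x == round(x) & abs(x) < 2^53
  out[ints] <- sprintf("%.0f", x[ints])
  out
}

write_table_precise <- function(df, path, num_cols) {
  out <- df
  for (col in num_cols) out[[col]] <- fmt_num(df[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Write a landscape to a directory
#'
#' Serializes the landscape as three CSV tables plus a JSON header:
#' `cells.csv` (`cell_id,col,row,farmland_area,yield_rate,stratum,kappa`),
#' `species.csv`
#' (`species_id,cell_id,p0,delta_grassland,delta_woodland,gamma,beta`),
#' `climate.csv` (`year,anomaly`) and `header.json` (`lowyield_factor`,
#' `base_year`, `end_year`).  Numeric fields use decimal text at full
#' double precision, so [read_landscape()] recovers the object exactly.
#'
#' @param landscape a `landscape`.
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  validate_landscape(landscape)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_table_precise(landscape$cells, file.path(path, "cells.csv"),
                      c("cell_id", "col", "row", "farmland_area",
                        "yield_rate", "kappa"))
  write_table_precise(landscape$species, file.path(path, "species.csv"),
                      c("species_id", "cell_id", "p0", "delta_grassland",
                        "delta_woodland", "gamma", "beta"))
  write_table_precise(landscape$climate, file.path(path, "climate.csv"),
                      c("year", "anomaly"))
  header <- list(lowyield_factor = landscape$lowyield_factor,
                 base_year = min(landscape$climate$year),
                 end_year = max(landscape$climate$year))
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_csv_checked <- function(path, expected_cols, colClasses) {
  if (!file.exists(path)) stop("missing landscape file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(expected_cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", basename(path),
                 paste(miss, collapse = ", ")))
  extra <- setdiff(names(df), expected_cols)
  if (length(extra))
    stop(sprintf("%s has unexpected column(s): %s", basename(path),
                 paste(extra, collapse = ", ")))
  df[expected_cols]
}

#' Read a landscape written by [write_landscape()]
#'
#' Validates the schema (missing or extra columns are named in the
#' error), the occupancy ranges and the cell cross-references.
#'
#' @param path directory containing `cells.csv`, `species.csv`,
#'   `climate.csv` and `header.json`.
#' @return a `landscape`.
#' @export
read_landscape <- function(path) {
  header_path <- file.path(path, "header.json")
  if (!file.exists(header_path))
    stop("missing landscape file: ", header_path)
  header <- jsonlite::read_json(header_path, simplifyVector = TRUE)
  cells <- read_csv_checked(
    file.path(path, "cells.csv"),
    c("cell_id", "col", "row", "farmland_area", "yield_rate", "stratum",
      "kappa"))
  species <- read_csv_checked(
    file.path(path, "species.csv"),
    c("species_id", "cell_id", "p0", "delta_grassland", "delta_woodland",
      "gamma", "beta"))
  climate <- read_csv_checked(file.path(path, "climate.csv"),
                              c("year", "anomaly"))
  cells$cell_id <- as.integer(cells$cell_id)
  cells$col <- as.integer(cells$col)
  cells$row <- as.integer(cells$row)
  species$species_id <- as.integer(species$species_id)
  species$cell_id <- as.integer(species$cell_id)
  climate$year <- as.integer(climate$year)
  landscape(cells, species, climate, header$lowyield_factor)
}

#' Export a per-cell map as an ESRI ASCII grid or CSV
#'
#' `esri_ascii` writes the standard six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value -9999`) followed
#' by the value rows; row 1 of the landscape grid is treated as the
#' northernmost and written first.  The cell size defaults to 2000 m,
#' honouring the 2 km grid cells of the national analysis.  `csv` writes
#' `cell_id,col,row,value`.
#'
#' @param values per-cell values: either a numeric vector in landscape
#'   cell order or a data.frame with `cell_id` and `value` columns.
#' @param landscape a `landscape` whose (`col`, `row`) layout defines the
#'   raster; must form a complete rectangle for `esri_ascii`.
#' @param path output file.
#' @param format `"esri_ascii"` or `"csv"`.
#' @param cellsize raster cell size in metres.
#' @return `path`, invisibly.
#' @export
write_map <- function(values, landscape, path,
                      format = c("esri_ascii", "csv"), cellsize = 2000) {
  format <- match.arg(format)
  cells <- landscape$cells
  if (is.data.frame(values)) {
    pos <- match(cells$cell_id, values$cell_id)
    if (anyNA(pos)) stop("values must cover all cells")
    vals <- values$value[pos]
  } else {
    if (length(values) != nrow(cells)) stop("values must cover all cells")
    vals <- as.numeric(values)
  }
  if (format == "csv") {
    write_table_precise(
      data.frame(cell_id = cells$cell_id, col = cells$col,
                 row = cells$row, value = vals),
      path, c("cell_id", "col", "row", "value"))
    return(invisible(path))
  }
  n_cols <- max(cells$col); n_rows <- max(cells$row)
  if (nrow(cells) != n_cols * n_rows ||
      anyDuplicated(cells[c("col", "row")]))
    stop("grid is not rectangular-complete; cannot write esri_ascii")
  m <- matrix(NA_real_, n_rows, n_cols)
  m[cbind(cells$row, cells$col)] <- vals
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", n_cols),
               sprintf("nrows %d", n_rows),
               "xllcorner 0",
               "yllcorner 0",
               sprintf("cellsize %s", fmt_num(cellsize)),
               "NODATA_value -9999"), con)
  for (r in seq_len(n_rows))    # row 1 = northernmost
    writeLines(paste(fmt_num(m[r, ]), collapse = " "), con)
  invisible(path)
}

#' Write a sweep table to CSV
#'
#' Column set is fixed: `strategy, rule, habitat, parameter,
#' spared_area_ha, habitat_area_ha, lowyield_area_ha, gain_in_occupancy,
#' delta_food_npv, leakage_npv, opportunity_cost_npv`.
#'
#' @param sweep a sweep table from [sweep_policy()] or
#'   [factorial_run()].
#' @param path output CSV file.
#' @export
write_sweep <- function(sweep, path) {
  cols <- c("strategy", "rule", "habitat", "parameter", "spared_area_ha",
            "habitat_area_ha", "lowyield_area_ha", "gain_in_occupancy",
            "delta_food_npv", "leakage_npv", "opportunity_cost_npv")
  write_table_precise(sweep[cols], path, setdiff(cols, c("strategy",
                                                         "rule",
                                                         "habitat")))
  invisible(path)
}

resolve_landscape <- function(cfg) {
  if (!is.null(cfg$landscape$path))
    return(read_landscape(cfg$landscape$path))
  if (!is.null(cfg$landscape$generate)) {
    gen <- cfg$landscape$generate
    if (!is.null(cfg$seed) && is.null(gen$seed)) gen$seed <- cfg$seed
    return(generate_landscape(do.call(generator_config, gen)))
  }
  stop("config field 'landscape' must contain 'path' or 'generate'")
}

cli_log <- function(..., quiet = FALSE)
  if (!quiet) message(sprintf(...))

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--"))
      stop("unexpected argument: ", key)
    if (i == length(args)) stop("missing value for option ", key)
    opts[[substring(key, 3)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Thin, scriptable front end over the package functions.  Subcommands:
#' \describe{
#'   \item{`generate`}{`--config gen.json --out dir` — build a synthetic
#'     landscape from a [generator_config()] JSON and write it with
#'     [write_landscape()].}
#'   \item{`run`}{`--config run.json --out dir` — one policy run; writes
#'     `outcome.csv` (one summary row), `delta_food.csv`,
#'     `richness_map.csv`/`.asc` and `selection_map.csv`/`.asc`.}
#'   \item{`sweep`}{`--config run.json --out dir` — one policy sweep;
#'     writes `sweep.csv`.}
#'   \item{`factorial`}{`--config run.json --out dir` — the full
#'     18-combination table as `factorial.csv`.}
#' }
#' The run config JSON holds `landscape` (either `path` or `generate`
#' with [generator_config()] fields), `policy`
#' (`strategy`/`rule`/`habitat`/`parameter`) or `sweep`
#' (`strategy`/`rule`/`habitat` and optional `grid`), `economics`
#' (`discount_rate`, `unit_price`), and `seed`.  Every run logs the
#' resolved configuration, seed, package version and summary metrics.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first), e.g. `commandArgs(trailingOnly = TRUE)`.
#' @param quiet suppress log messages.
#' @return integer exit status, invisibly: 0 on success, 1 on failure
#'   (with a one-line diagnostic message).
#' @export
run_cli <- function(args, quiet = FALSE) {
  status <- tryCatch({
    if (!length(args)) stop("usage: <generate|run|sweep|factorial> --config FILE --out DIR")
    cmd <- args[1]
    if (!cmd %in% c("generate", "run", "sweep", "factorial"))
      stop("unknown subcommand: ", cmd)
    opts <- parse_cli_args(args[-1])
    if (is.null(opts$config)) stop("--config is required")
    if (is.null(opts$out)) stop("--out is required")
    cfg <- jsonlite::read_json(opts$config, simplifyVector = TRUE)
    dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
    ver <- as.character(utils::packageVersion("sparesim"))
    cli_log("sparesim %s | subcommand %s | config %s | seed %s",
            ver, cmd, opts$config,
            if (is.null(cfg$seed)) "none" else cfg$seed, quiet = quiet)

    if (cmd == "generate") {
      gen_args <- cfg
      gen_args$seed <- if (is.null(cfg$seed)) 42L else cfg$seed
      L <- generate_landscape(do.call(generator_config,
                                      gen_args[names(gen_args) %in%
                                               names(formals(generator_config))]))
      write_landscape(L, opts$out)
      cli_log("wrote landscape: %d cells, %d species, total farmland %.1f ha",
              nrow(L$cells), length(unique(L$species$species_id)),
              total_farmland(L), quiet = quiet)
      return(invisible(0L))
    }

    L <- resolve_landscape(cfg)
    rate <- if (is.null(cfg$economics$discount_rate)) 0.035
            else cfg$economics$discount_rate
    price <- if (is.null(cfg$economics$unit_price)) 1
             else cfg$economics$unit_price

    if (cmd == "run") {
      p <- cfg$policy
      if (is.null(p)) stop("config field 'policy' is required for 'run'")
      pol <- policy_spec(p$strategy, p$rule, p$habitat, p$parameter)
      out <- run_scenario(L, pol, rate, price)
      write_sweep(outcome_row(out), file.path(opts$out, "outcome.csv"))
      write_table_precise(out$delta_food,
                          file.path(opts$out, "delta_food.csv"),
                          c("year", "delta"))
      write_map(out$richness_map, L,
                file.path(opts$out, "richness_map.csv"), "csv")
      write_map(out$selection_map, L,
                file.path(opts$out, "selection_map.csv"), "csv")
      write_map(out$richness_map, L,
                file.path(opts$out, "richness_map.asc"), "esri_ascii")
      write_map(out$selection_map, L,
                file.path(opts$out, "selection_map.asc"), "esri_ascii")
      cli_log("gain in occupancy %.6f | spared %.3f ha | leakage NPV %.3f",
              out$gain_in_occupancy, out$spared_area_ha, out$leakage_npv,
              quiet = quiet)
    } else if (cmd == "sweep") {
      s <- cfg$sweep
      if (is.null(s)) stop("config field 'sweep' is required for 'sweep'")
      grid <- if (is.null(s$grid)) NULL else as.numeric(s$grid)
      tab <- sweep_policy(L, s$strategy, s$rule, s$habitat, grid, rate,
                          price)
      write_sweep(tab, file.path(opts$out, "sweep.csv"))
      cli_log("sweep rows: %d | max gain %.6f", nrow(tab),
              max(tab$gain_in_occupancy), quiet = quiet)
    } else {
      tab <- factorial_run(L, discount_rate = rate, unit_price = price)
      write_sweep(tab, file.path(opts$out, "factorial.csv"))
      cli_log("factorial rows: %d", nrow(tab), quiet = quiet)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
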