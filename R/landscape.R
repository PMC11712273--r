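HABITATS <- c("grassland", "woodland")
RULES <- c("biodiv_max", "cost_min", "equal")
STRATEGIES <- c("sharing", "sparing", "sparing3c")

#' Construct a landscape object
#'
#' A landscape bundles the grid-cell table (farmland areas, base-year
#' yields, stratum labels, climate-yield sensitivities), the long
#' species-response table (one row per species x cell), the climate-anomaly
#' trajectory, and the productivity factor of low-yield agriculture.
#' It is the substrate of every policy run.
#'
#' @param cells data.frame with columns `cell_id`, `col`, `row`,
#'   `farmland_area` (ha), `yield_rate` (output units / ha / yr at the base
#'   year), `stratum` (`"upland"` or `"lowland"`), `kappa` (proportional
#'   yield change per unit climate anomaly).
#' @param species data.frame with columns `species_id`, `cell_id`, `p0`
#'   (baseline occupancy probability), `delta_grassland`, `delta_woodland`
#'   (occupancy change at full conversion of the cell's farmland to that
#'   habitat), `gamma` (occupancy change at full conversion to low-yield
#'   agriculture), `beta` (occupancy change per unit climate anomaly).
#' @param climate data.frame with columns `year`, `anomaly`; the anomaly at
#'   the first (base) year must be 0.
#' @param lowyield_factor fraction of conventional yield attained by
#'   low-yield agriculture, in (0, 1].
#' @return an object of class `landscape`.
#' @export
landscape <- function(cells, species, climate, lowyield_factor = 0.1) {
  obj <- structure(
    list(cells = as.data.frame(cells), species = as.data.frame(species),
         climate = as.data.frame(climate),
         lowyield_factor = as.numeric(lowyield_factor)),
    class = "landscape")
  validate_landscape(obj)
  obj
}

#' Validate a landscape object
#'
#' Checks the structural invariants: required columns, unique cell ids,
#' non-negative areas and yields, occupancy parameters within range,
#' complete species x cell coverage, a zero anomaly at the base year, and
#' positive total farmland.
#'
#' @param x a `landscape`.
#' @return `x`, invisibly, if valid; otherwise an error naming the problem.
#' @export
validate_landscape <- function(x) {
  stopifnot(inherits(x, "landscape"))
  cell_cols <- c("cell_id", "col", "row", "farmland_area", "yield_rate",
                 "stratum", "kappa")
  sp_cols <- c("species_id", "cell_id", "p0", "delta_grassland",
               "delta_woodland", "gamma", "beta")
  miss <- setdiff(cell_cols, names(x$cells))
  if (length(miss))
    stop("cells table is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(sp_cols, names(x$species))
  if (length(miss))
    stop("species table is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(c("year", "anomaly"), names(x$climate))
  if (length(miss))
    stop("climate table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$cells$cell_id))
    stop("cell_id values must be unique")
  if (any(x$cells$farmland_area < 0))
    stop("farmland_area must be >= 0")
  if (any(x$cells$yield_rate < 0))
    stop("yield_rate must be >= 0")
  if (!all(x$cells$stratum %in% c("upland", "lowland")))
    stop("stratum must be 'upland' or 'lowland'")
  bad <- x$species$p0 < 0 | x$species$p0 > 1
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "baseline occupancy p0 out of [0,1] for species_id %s, cell_id %s",
      x$species$species_id[i], x$species$cell_id[i]))
  }
  for (col in c("delta_grassland", "delta_woodland", "gamma")) {
    bad <- abs(x$species[[col]]) > 1
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("%s out of [-1,1] for species_id %s, cell_id %s",
                   col, x$species$species_id[i], x$species$cell_id[i]))
    }
  }
  unknown <- setdiff(x$species$cell_id, x$cells$cell_id)
  if (length(unknown))
    stop("species table references unknown cell_id: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  n_sp <- length(unique(x$species$species_id))
  if (nrow(x$species) != n_sp * nrow(x$cells))
    stop("species table must cover every (species, cell) pair exactly once")
  yrs <- x$climate$year
  if (!identical(as.integer(yrs), as.integer(seq(min(yrs), max(yrs)))))
    stop("climate years must be consecutive")
  if (abs(x$climate$anomaly[which.min(yrs)]) > 0)
    stop("climate anomaly must be 0 at the base year")
  if (!(x$lowyield_factor > 0 && x$lowyield_factor <= 1))
    stop("lowyield_factor must be in (0, 1]")
  if (sum(x$cells$farmland_area) <= 0)
    stop("total farmland area must be > 0")
  invisible(x)
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf(
    "<landscape> %d cells (%d x %d grid), %d species, years %d-%d\n",
    nrow(x$cells), max(x$cells$col), max(x$cells$row),
    length(unique(x$species$species_id)),
    min(x$climate$year), max(x$climate$year)))
  cat(sprintf("  total farmland %.1f ha, lowyield_factor %.3g\n",
              sum(x$cells$farmland_area), x$lowyield_factor))
  invisible(x)
}

#' Total farmland area of a landscape, in hectares
#' @param landscape a `landscape`.
#' @export
total_farmland <- function(landscape) sum(landscape$cells$farmland_area)

#' Baseline annual food output at the base year
#'
#' Sum over cells of farmland area times base-year yield, with no policy
#' and no climate forcing.
#'
#' @param landscape a `landscape`.
#' @return total output units per year.
#' @export
baseline_output <- function(landscape)
  sum(landscape$cells$farmland_area * landscape$cells$yield_rate)

#' Deterministic 2x2 toy landscape
#'
#' A four-cell, two-species fixture small enough to verify every policy
#' computation by hand: 100 ha farmland per cell, yields 1, 2, 4, 8
#' (cell 1 upland, others lowland), zero climate sensitivity everywhere.
#' Species 1 has baseline occupancy 0.2 and uniform habitat responses
#' (grassland 0.1, woodland 0.4); species 2 has baseline 0.1, cell-varying
#' grassland responses (0.2, 0.9, 0.4, 0.5), woodland 0.05, and a positive
#' low-yield-agriculture response (0.2).  The anomaly is identically zero
#' over 2020-2060 and low-yield land attains 10% of conventional yield.
#'
#' @return a `landscape`.
#' @examples
#' toy <- toy_landscape()
#' total_farmland(toy)   # 400
#' baseline_output(toy)  # 1500
#' @export
toy_landscape <- function() {
  cells <- data.frame(
    cell_id = 1:4, col = c(1L, 2L, 1L, 2L), row = c(1L, 1L, 2L, 2L),
    farmland_area = rep(100, 4), yield_rate = c(1, 2, 4, 8),
    stratum = c("upland", "lowland", "lowland", "lowland"),
    kappa = rep(0, 4), stringsAsFactors = FALSE)
  species <- data.frame(
    species_id = rep(1:2, each = 4), cell_id = rep(1:4, 2),
    p0 = rep(c(0.2, 0.1), each = 4),
    delta_grassland = c(rep(0.1, 4), 0.2, 0.9, 0.4, 0.5),
    delta_woodland = c(rep(0.4, 4), rep(0.05, 4)),
    gamma = rep(c(0, 0.2), each = 4),
    beta = rep(0, 8))
  climate <- data.frame(year = 2020:2060, anomaly = rep(0, 41))
  landscape(cells, species, climate, lowyield_factor = 0.1)
}

#' Configuration for the synthetic landscape generator
#'
#' Collects the knobs of [generate_landscape()] with defaults that emulate
#' the statistical structure of a national-scale agricultural landscape at
#' desk scale: a 40 x 40 grid of 2 km cells, 100 at-risk species drawn
#' from four response archetypes, a contiguous low-yield upland block
#' covering 30% of the columns, log-normal spatially smoothed yields, and
#' a linear warming trajectory reaching anomaly 1 by 2060.
#'
#' @param n_cols,n_rows grid dimensions (cells).
#' @param n_species number of species.
#' @param upland_fraction fraction of grid columns (leftmost) forming the
#'   contiguous upland stratum.
#' @param yield_meanlog named numeric, log-scale mean yield per stratum
#'   (`upland`, `lowland`); the generated arithmetic stratum means are
#'   pinned to `exp(meanlog + sdlog^2 / 2)` exactly, so the upland mean is
#'   below the lowland mean by construction for every seed.
#' @param yield_sdlog named numeric, log-scale yield spread per stratum.
#' @param smoothing_radius moving-average half-width, in cells, applied to
#'   the log-yield noise field (spatial autocorrelation).
#' @param farmland_range range (ha) of per-cell farmland area, uniform
#'   draws; a 2 km cell holds at most 400 ha.
#' @param archetype_prop named proportions of the four species archetypes
#'   (`woodland`, `grassland`, `farmland`, `generalist`); must sum to 1.
#' @param climate_slope anomaly units gained per year after the base year.
#' @param base_year,end_year horizon (inclusive calendar years).
#' @param lowyield_factor productivity of low-yield agriculture relative
#'   to conventional farmland, in (0, 1].
#' @param seed integer seed; the generator is a pure function of the full
#'   configuration including the seed.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_cols = 40L, n_rows = 40L, n_species = 100L,
                             upland_fraction = 0.3,
                             yield_meanlog = c(upland = log(1.5),
                                               lowland = log(5)),
                             yield_sdlog = c(upland = 0.4, lowland = 0.3),
                             smoothing_radius = 2L,
                             farmland_range = c(200, 380),
                             archetype_prop = c(woodland = 0.3,
                                                grassland = 0.3,
                                                farmland = 0.2,
                                                generalist = 0.2),
                             climate_slope = 0.025,
                             base_year = 2020L, end_year = 2060L,
                             lowyield_factor = 0.1, seed = 42L) {
  cfg <- list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
              n_species = as.integer(n_species),
              upland_fraction = upland_fraction,
              yield_meanlog = yield_meanlog, yield_sdlog = yield_sdlog,
              smoothing_radius = as.integer(smoothing_radius),
              farmland_range = farmland_range,
              archetype_prop = archetype_prop,
              climate_slope = climate_slope,
              base_year = as.integer(base_year),
              end_year = as.integer(end_year),
              lowyield_factor = lowyield_factor, seed = as.integer(seed))
  class(cfg) <- "generator_config"
  if (cfg$n_cols <= 0 || cfg$n_rows <= 0 || cfg$n_species <= 0)
    stop("grid dimensions and n_species must be positive")
  if (abs(sum(cfg$archetype_prop) - 1) > 1e-8)
    stop("archetype_prop must sum to 1")
  if (cfg$upland_fraction < 0 || cfg$upland_fraction > 1)
    stop("upland_fraction must be in [0, 1]")
  cfg
}

# evaluate `expr` under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# moving-average smoothing of a matrix with an odd square kernel;
# edges normalized by the number of cells actually inside the window
smooth_matrix <- function(m, radius) {
  if (radius <= 0) return(m)
  n_r <- nrow(m); n_c <- ncol(m)
  out <- matrix(0, n_r, n_c)
  cnt <- matrix(0, n_r, n_c)
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      src_r <- pmin(pmax(seq_len(n_r) + dr, 1L), n_r)
      src_c <- pmin(pmax(seq_len(n_c) + dc, 1L), n_c)
      valid_r <- seq_len(n_r) + dr >= 1L & seq_len(n_r) + dr <= n_r
      valid_c <- seq_len(n_c) + dc >= 1L & seq_len(n_c) + dc <= n_c
      if (!any(valid_r) || !any(valid_c)) next
      rr <- which(valid_r); cc <- which(valid_c)
      out[rr, cc] <- out[rr, cc] + m[rr + dr, cc + dc]
      cnt[rr, cc] <- cnt[rr, cc] + 1
    }
  }
  out / cnt
}

#' Generate a seeded synthetic landscape
#'
#' Emulates the statistical structure a national gridded land-use analysis
#' assumes, without any real geography: spatially autocorrelated log-normal
#' yields with a contiguous low-yield upland block, per-cell farmland
#' areas, species responses drawn from four archetypes (woodland
#' specialists, grassland specialists, farmland specialists that benefit
#' from low-yield agriculture, and mild generalists) with per-cell
#' heterogeneity, and a linear climate-anomaly trajectory that depresses
#' yields and occupancy.
#'
#' The per-stratum arithmetic mean yields are pinned exactly to their
#' configured targets by a post-hoc per-stratum rescaling, so the upland
#' mean is strictly below the lowland mean for every seed, by
#' construction rather than by rejection.  The generator is a pure
#' function of its configuration: identical configs (including the seed)
#' produce identical landscapes.
#'
#' @param config a [generator_config()].
#' @return a `landscape`.
#' @examples
#' L <- generate_landscape(generator_config(n_cols = 8, n_rows = 8,
#'                                          n_species = 10, seed = 1))
#' nrow(L$cells)
#' @export
generate_landscape <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n_c <- config$n_cols; n_r <- config$n_rows
    n_cells <- n_c * n_r
    grid <- expand.grid(col = seq_len(n_c), row = seq_len(n_r))
    n_upland_cols <- round(config$upland_fraction * n_c)
    stratum <- ifelse(grid$col <= n_upland_cols, "upland", "lowland")

    # smoothed standard-normal noise field, re-standardized so the
    # configured sdlog applies after smoothing
    z <- matrix(stats::rnorm(n_cells), n_r, n_c)
    zs <- smooth_matrix(z, config$smoothing_radius)
    zs <- (zs - mean(zs)) / stats::sd(zs)
    zv <- zs[cbind(grid$row, grid$col)]

    sdlog <- config$yield_sdlog[stratum]
    meanlog <- config$yield_meanlog[stratum]
    yield <- exp(meanlog + sdlog * zv)
    # pin stratum arithmetic means to their log-normal targets
    for (s in unique(stratum)) {
      idx <- stratum == s
      target <- exp(config$yield_meanlog[[s]] + config$yield_sdlog[[s]]^2 / 2)
      yield[idx] <- yield[idx] * target / mean(yield[idx])
    }

    farmland <- stats::runif(n_cells, config$farmland_range[1],
                             config$farmland_range[2])
    # one shared climate-yield sensitivity: a uniform proportional yield
    # response keeps output-neutral sparing neutral in every year, not
    # only at the base year (cell-varying kappa is supported for
    # user-supplied landscapes but breaks exact year-by-year neutrality)
    kappa <- rep(stats::rnorm(1, -0.02, 0.01), n_cells)

    cells <- data.frame(
      cell_id = seq_len(n_cells) - 1L, col = grid$col, row = grid$row,
      farmland_area = farmland, yield_rate = as.numeric(yield),
      stratum = stratum, kappa = kappa, stringsAsFactors = FALSE)

    # species archetypes: deterministic counts from the proportions
    props <- config$archetype_prop
    counts <- floor(props * config$n_species)
    rem <- config$n_species - sum(counts)
    if (rem > 0) {
      extra <- order(props * config$n_species - counts,
                     decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    archetype <- rep(names(props), counts)

    n_sp <- config$n_species
    draw <- function(lo, hi, n = n_sp) stats::runif(n, lo, hi)
    dg <- dw <- gm <- numeric(n_sp)
    for (a in names(props)) {
      idx <- which(archetype == a)
      n_a <- length(idx)
      if (!n_a) next
      if (a == "woodland") {
        dw[idx] <- draw(0.25, 0.5, n_a); dg[idx] <- draw(0.02, 0.08, n_a)
        gm[idx] <- draw(0, 0.02, n_a)
      } else if (a == "grassland") {
        dg[idx] <- draw(0.25, 0.5, n_a); dw[idx] <- draw(0.02, 0.08, n_a)
        gm[idx] <- draw(0, 0.02, n_a)
      } else if (a == "farmland") {
        gm[idx] <- draw(0.15, 0.35, n_a)
        dg[idx] <- draw(0, 0.05, n_a); dw[idx] <- draw(0, 0.05, n_a)
      } else {
        dg[idx] <- draw(0.05, 0.15, n_a); dw[idx] <- draw(0.05, 0.15, n_a)
        gm[idx] <- draw(0, 0.05, n_a)
      }
    }
    p0_sp <- draw(0.05, 0.35)
    beta_sp <- draw(-0.05, 0)

    # per-cell heterogeneity: multiplicative noise on responses,
    # additive noise on baseline occupancy, all clipped to range
    n_pairs <- n_sp * n_cells
    mult <- stats::runif(n_pairs, 0.6, 1.4)
    p0_noise <- stats::rnorm(n_pairs, 0, 0.03)
    sp_idx <- rep(seq_len(n_sp), each = n_cells)
    species <- data.frame(
      species_id = sp_idx,
      cell_id = rep(cells$cell_id, n_sp),
      p0 = pmin(1, pmax(0, p0_sp[sp_idx] + p0_noise)),
      delta_grassland = pmin(1, pmax(-1, dg[sp_idx] * mult)),
      delta_woodland = pmin(1, pmax(-1, dw[sp_idx] * mult)),
      gamma = pmin(1, pmax(-1, gm[sp_idx] * mult)),
      beta = beta_sp[sp_idx])

    years <- config$base_year:config$end_year
    climate <- data.frame(
      year = years, anomaly = config$climate_slope * (years - years[1]))

    landscape(cells, species, climate, config$lowyield_factor)
  })
}
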