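# Food-output accounting, leakage indicator and discounted opportunity
# cost.  Output is in abstract output units / yr; monetization uses a
# configurable unit price (default 1).

#' Annual food output under an allocation and yield uplift
#'
#' Retained conventional farmland produces at the climate-adjusted yield
#' `y_i(year) = y_i * (1 + kappa_i * a(year))` raised by the uplift
#' `(1 + g)`; land converted to low-yield agriculture produces the
#' fraction `lowyield_factor` of that; natural habitat produces nothing.
#' The uplift applies as a step from the base year onwards, to
#' conventional and low-yield farmland alike.
#'
#' @param landscape a `landscape`.
#' @param allocation an `allocation`.
#' @param uplift proportional yield increase `g`.
#' @param year calendar year within the horizon.
#' @return total output units for that year.
#' @export
annual_food_output <- function(landscape, allocation, uplift = 0,
                               year = landscape$climate$year[1]) {
  i <- match(year, landscape$climate$year)
  if (is.na(i)) stop("year ", year, " outside the climate horizon")
  a <- landscape$climate$anomaly[i]
  cells <- landscape$cells
  pos <- match(allocation$cells$cell_id, cells$cell_id)
  hab <- lo <- numeric(nrow(cells))
  hab[pos] <- allocation$cells$habitat_ha
  lo[pos] <- allocation$cells$lowyield_ha
  y_t <- cells$yield_rate * pmax(0, 1 + cells$kappa * a)
  conv <- cells$farmland_area - hab - lo
  sum((conv + lo * landscape$lowyield_factor) * y_t * (1 + uplift))
}

#' Per-year food-output change against the no-policy baseline
#'
#' The baseline is the same landscape with an empty allocation and no
#' uplift.  Sharing (positive target, no uplift) gives strictly negative
#' deltas; pure Sparing gives zero by construction; Three-Compartment
#' Sparing gives non-negative deltas whenever `lowyield_factor > 0`.
#'
#' @inheritParams annual_food_output
#' @return data.frame (`year`, `delta`) over the full horizon.
#' @export
delta_food_series <- function(landscape, allocation, uplift = 0) {
  years <- landscape$climate$year
  base <- empty_allocation(landscape, allocation$habitat)
  delta <- vapply(years, function(yr)
    annual_food_output(landscape, allocation, uplift, yr) -
      annual_food_output(landscape, base, 0, yr), numeric(1))
  data.frame(year = years, delta = delta)
}

#' Net present value of a yearly flow
#'
#' End-of-year discounting with the base-year flow undiscounted:
#' `sum_t flow(t) / (1 + rate)^(t - base_year)`.
#'
#' @param flows numeric vector of per-year values.
#' @param rate discount rate (fraction, > -1); the headline analyses use
#'   the HM Treasury social discount rate of 0.035.
#' @param base_year year of the first flow.
#' @param years calendar years of the flows; defaults to consecutive
#'   years from `base_year`.
#' @return the present value at `base_year`.
#' @examples
#' npv(rep(1, 41), 0.035, 2020)  # 41-year annuity factor
#' @export
npv <- function(flows, rate = 0.035, base_year = 2020,
                years = base_year + seq_along(flows) - 1) {
  if (!length(flows)) stop("empty flow series")
  if (rate <= -1) stop("rate must be > -1")
  stopifnot(length(years) == length(flows))
  sum(flows / (1 + rate)^(years - base_year))
}

#' Leakage indicator of a food-output delta series
#'
#' Leakage is the one-sided shortfall in domestic production that must be
#' met by imports (raising the prospect of biodiversity loss overseas):
#' per-year `max(0, -delta)`, with an NPV-weighted headline value.  It is
#' zero for output-neutral Sparing and for Three-Compartment Sparing, and
#' positive for Sharing at any positive area target.
#'
#' @param delta_series data.frame (`year`, `delta`) from
#'   [delta_food_series()].
#' @param rate discount rate for the headline NPV.
#' @return list with `series` (data.frame `year`, `leakage`) and `npv`.
#' @export
leakage_indicator <- function(delta_series, rate = 0.035) {
  leak <- pmax(0, -delta_series$delta)
  list(series = data.frame(year = delta_series$year, leakage = leak),
       npv = npv(leak, rate, base_year = delta_series$year[1],
                 years = delta_series$year))
}
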