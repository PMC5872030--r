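#' Air demand for a flotation batch
#'
#' Microflotation air requirement scales linearly with the treated
#' volume at a fixed specific rate (laboratory basis: 1 mL of air per
#' minute per litre of water).
#'
#' @param treatment_volume_L batch volume, L (> 0).
#' @param specific_rate_mL_per_min_per_L air per minute per litre
#'   treated (default 1).
#' @return Air demand in L/min.
#' @examples
#' air_demand(24000)  # 24 L/min
#' @export
air_demand <- function(treatment_volume_L, specific_rate_mL_per_min_per_L = 1) {
  if (any(treatment_volume_L <= 0)) stop("volume must be > 0", call. = FALSE)
  as_unit(treatment_volume_L * specific_rate_mL_per_min_per_L,
          "L/min", from = "mL/min")
}

#' Derated compressor delivery at operating pressure
#'
#' A compressor's free-air delivery falls when operating against back
#' pressure; at 3 bar(g) roughly a quarter of the rated flow remains.
#' The derated flow is compared against the air demand to flag whether
#' the design point is feasible.
#'
#' @param rated_flow_L_per_min rated free-air delivery, L/min (> 0).
#' @param fraction derating fraction in `(0, 1]` (default 0.25).
#' @param demand_L_per_min optional air demand for the feasibility
#'   check.
#' @return A list: `flow_L_per_min`, and `feasible` (logical, `NA` when
#'   no demand was given).
#' @examples
#' derated_flow(201, demand_L_per_min = air_demand(24000))
#' @export
derated_flow <- function(rated_flow_L_per_min, fraction = 0.25,
                         demand_L_per_min = NULL) {
  if (rated_flow_L_per_min <= 0) stop("rated flow must be > 0", call. = FALSE)
  if (fraction <= 0 || fraction > 1) {
    stop("derating fraction must lie in (0, 1]", call. = FALSE)
  }
  flow <- rated_flow_L_per_min * fraction
  list(flow_L_per_min = flow,
       feasible = if (is.null(demand_L_per_min)) NA else
         flow >= demand_L_per_min)
}

#' Total batch cycle time
#'
#' @param treat_min flotation treatment time, min.
#' @param fill_min tank fill time, min.
#' @param drain_min tank drain time, min.
#' @return Total minutes per batch.
#' @examples
#' batch_cycle(30, 48, 48)  # 126 min
#' @export
batch_cycle <- function(treat_min, fill_min, drain_min) {
  if (any(c(treat_min, fill_min, drain_min) < 0)) {
    stop("times must be >= 0", call. = FALSE)
  }
  treat_min + fill_min + drain_min
}

#' Electrical energy cost of a duty
#'
#' @param power_kW load, kW.
#' @param duration_min duty time, min.
#' @param tariff_per_kWh electricity price, currency per kWh.
#' @return Cost in currency units.
#' @examples
#' energy_cost(16, 30, 0.15)  # 1.20 per batch for a 16 kW skimmer
#' @export
energy_cost <- function(power_kW, duration_min, tariff_per_kWh) {
  if (any(c(power_kW, duration_min, tariff_per_kWh) < 0)) {
    stop("inputs must be >= 0", call. = FALSE)
  }
  power_kW * (duration_min / 60) * tariff_per_kWh
}

#' Flocculant quantity and cost for a treated volume
#'
#' @param dose_mg_per_L applied dose, mg/L.
#' @param volume_L treated volume, L.
#' @param unit_price_per_kg flocculant price, currency/kg.
#' @return A list: `mass_kg`, `cost`.
#' @examples
#' flocculant_cost(5, 7.5e6, 30)  # 37.5 kg, 1125
#' @export
flocculant_cost <- function(dose_mg_per_L, volume_L, unit_price_per_kg) {
  if (any(c(dose_mg_per_L, volume_L, unit_price_per_kg) < 0)) {
    stop("inputs must be >= 0", call. = FALSE)
  }
  mass_kg <- as_unit(dose_mg_per_L * volume_L, "kg", from = "mg")
  list(mass_kg = mass_kg, cost = mass_kg * unit_price_per_kg)
}

#' Total capital expenditure
#'
#' Sums per-item CAPEX; an item given as a vector of component prices
#' (e.g. two diffusers plus a tank shell) is expanded first.
#'
#' @param items numeric vector, or list of numeric vectors, of item
#'   prices (>= 0).
#' @return Total CAPEX in currency units.
#' @examples
#' capex_total(list(compressor = 200, rotameter = 60, oscillator = 100,
#'                  tank = c(210, 210, 1000), pumps = 1000, skimmer = 1000))
#' @export
capex_total <- function(items) {
  if (length(items) == 0L) return(0)
  vals <- unlist(items, use.names = FALSE)
  if (any(vals < 0)) stop("CAPEX must be >= 0", call. = FALSE)
  sum(vals)
}

#' Whole-treatment cost ledger
#'
#' Scales per-batch operating costs to a full water-body treatment.
#' The batch count `total_volume / batch_volume` is kept fractional for
#' costing (a part-filled final batch costs its pro-rata share); the
#' scheduling view uses the ceiling. Each equipment item needs either a
#' stated per-batch OPEX or a power and duty time from which it is
#' derived at the tariff. A flocculant dose is costed over the whole
#' volume via [flocculant_cost()].
#'
#' @param items data.frame with columns `name`, `capex`,
#'   `opex_per_batch` (NA to derive), `duty_min_per_batch`, and
#'   optionally `power_kW`.
#' @param total_volume_L whole treatment volume, L.
#' @param batch_volume_L volume per batch, L (> 0).
#' @param tariff_per_kWh electricity tariff (default 0.15).
#' @param flocculant optional list `(name, dose_mg_per_L,
#'   unit_price_per_kg)`.
#' @return A `cost_ledger`: per-item full costs, `n_batches`
#'   (fractional), `n_batches_scheduled` (ceiling), `total_opex`,
#'   `total_capex`.
#' @export
treatment_cost <- function(items, total_volume_L, batch_volume_L,
                           tariff_per_kWh = 0.15, flocculant = NULL) {
  if (batch_volume_L <= 0) stop("batch volume must be > 0", call. = FALSE)
  if (total_volume_L < 0) stop("total volume must be >= 0", call. = FALSE)
  n_batches <- total_volume_L / batch_volume_L
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  if (!"power_kW" %in% names(items)) items$power_kW <- NA_real_
  opex <- items$opex_per_batch
  for (i in seq_len(nrow(items))) {
    if (is.na(opex[i])) {
      if (is.na(items$power_kW[i]) || is.na(items$duty_min_per_batch[i])) {
        stop("item '", items$name[i],
             "': no per-batch OPEX and no power/duty to derive it",
             call. = FALSE)
      }
      opex[i] <- energy_cost(items$power_kW[i], items$duty_min_per_batch[i],
                             tariff_per_kWh)
    }
  }
  ledger <- data.frame(name = items$name, capex = items$capex,
                       opex_per_batch = opex,
                       duty_min_per_batch = items$duty_min_per_batch,
                       full_cost = opex * n_batches,
                       stringsAsFactors = FALSE)
  if (!is.null(flocculant)) {
    fc <- flocculant_cost(flocculant$dose_mg_per_L, total_volume_L,
                          flocculant$unit_price_per_kg)
    ledger <- rbind(ledger, data.frame(
      name = flocculant$name, capex = 0,
      opex_per_batch = if (n_batches > 0) fc$cost / n_batches else 0,
      duty_min_per_batch = NA_real_, full_cost = fc$cost,
      stringsAsFactors = FALSE))
  }
  structure(list(items = ledger, n_batches = n_batches,
                 n_batches_scheduled = ceiling(n_batches),
                 tariff_per_kWh = tariff_per_kWh,
                 total_opex = sum(ledger$full_cost),
                 total_capex = sum(ledger$capex)),
            class = "cost_ledger")
}

#' @export
print.cost_ledger <- function(x, ...) {
  cat(sprintf("Cost ledger: %.1f batches (schedule %d)\n",
              x$n_batches, x$n_batches_scheduled))
  df <- x$items
  df$opex_per_batch <- round(df$opex_per_batch, 3)
  df$full_cost <- round(df$full_cost)
  print(df, row.names = FALSE)
  cat(sprintf("Total OPEX: %.2f   Total CAPEX: %.2f\n",
              x$total_opex, x$total_capex))
  invisible(x)
}

#' Solar array sizing for a continuous load
#'
#' Number of panels to carry a continuous electrical load, with an
#' optional performance derate, and the array footprint.
#'
#' @param continuous_load_kW load to supply, kW (> 0).
#' @param panel_rating_W nameplate rating per panel, W (default 250).
#' @param area_per_panel_m2 footprint per panel, m2 (default 1.5).
#' @param derate performance derate in `(0, 1]` (default 1).
#' @return A list: `n_panels`, `array_area_m2`.
#' @examples
#' solar_sizing(1.5)  # 6 panels, 9 m2
#' @export
solar_sizing <- function(continuous_load_kW, panel_rating_W = 250,
                         area_per_panel_m2 = 1.5, derate = 1) {
  if (continuous_load_kW <= 0 || panel_rating_W <= 0 ||
      area_per_panel_m2 <= 0) {
    stop("inputs must be > 0", call. = FALSE)
  }
  if (derate <= 0 || derate > 1) stop("derate must lie in (0, 1]",
                                      call. = FALSE)
  n <- ceiling(continuous_load_kW * 1000 / (panel_rating_W * derate))
  list(n_panels = n, array_area_m2 = n * area_per_panel_m2)
}
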