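#' Standing biomass stock of a bloom
#'
#' Dry biomass mass in a water body from the measured dry-weight
#' concentration and the (uncertain, hence ranged) photic-zone volume:
#' `kg = g/L * 1000 L/m3 * m3 / 1000 g/kg`, i.e. numerically
#' `conc * volume_m3`.
#'
#' @param dry_weight_conc dry weight concentration, g/L (>= 0).
#' @param volume_m3 water volume(s), m3; a length-2 `c(low, high)`
#'   range or a single value.
#' @return Stock in kg, same length as `volume_m3`, named `low`/`high`
#'   for a range.
#' @examples
#' biomass_stock(0.13, c(5000, 10000))  # 650 and 1300 kg
#' @export
biomass_stock <- function(dry_weight_conc, volume_m3) {
  if (dry_weight_conc < 0) stop("dry weight must be >= 0", call. = FALSE)
  if (any(volume_m3 <= 0)) stop("volumes must be > 0", call. = FALSE)
  if (length(volume_m3) == 2L) {
    if (volume_m3[1] > volume_m3[2]) stop("volume range must be low <= high",
                                          call. = FALSE)
    stats::setNames(dry_weight_conc * volume_m3, c("low", "high"))
  } else {
    dry_weight_conc * volume_m3
  }
}

#' Recoverable resource mass
#'
#' Mass of a biomass constituent (lipid, phosphate, protein) recovered
#' by harvesting: `stock * content * efficiency / 100`, kept at full
#' precision (presentation rounding is a separate step). The harvesting
#' efficiency applied is the flotation chlorophyll-a removal, used as a
#' proxy for bulk biomass removal.
#'
#' @param stock_kg dry biomass stock, kg.
#' @param content constituent mass fraction, g per g biomass in
#'   `[0, 1]` (e.g. `0.1037` for 103.7 ug/mg lipid).
#' @param harvesting_efficiency percent in `[0, 100]`.
#' @return Recovered mass, kg.
#' @examples
#' recoverable_mass(650, 0.1037, 91.2)    # 61.5 kg lipid
#' recoverable_mass(650, 0.32545, 91.2)   # 192.9 kg protein
#' @export
recoverable_mass <- function(stock_kg, content, harvesting_efficiency) {
  if (any(content < 0 | content > 1)) {
    stop("content must be a mass fraction in [0, 1]", call. = FALSE)
  }
  if (any(harvesting_efficiency < 0 | harvesting_efficiency > 100)) {
    stop("harvesting efficiency must lie in [0, 100]%", call. = FALSE)
  }
  stock_kg * content * harvesting_efficiency / 100
}

#' Protein content from total nitrogen
#'
#' Converts elemental total nitrogen to estimated protein using a
#' nitrogen-to-protein factor (4.78 for algal biomass, below the
#' classical 6.25 because of non-protein nitrogen).
#'
#' @param total_n total nitrogen mass fraction, g/g in `[0, 1]`.
#' @param factor nitrogen-to-protein conversion factor.
#' @return Protein mass fraction, g/g.
#' @export
protein_from_nitrogen <- function(total_n, factor = 4.78) {
  if (any(total_n < 0 | total_n > 1)) {
    stop("total nitrogen must be a mass fraction in [0, 1]", call. = FALSE)
  }
  p <- factor * total_n
  if (any(p > 1)) {
    stop("derived protein fraction exceeds 1 g/g: impossible composition",
         call. = FALSE)
  }
  p
}

#' Dissolved-nutrient removal efficiency
#'
#' Removal of a dissolved constituent (e.g. phosphate) between the
#' start and end of a flotation run; shares the contract and
#' implementation of [removal_efficiency()].
#'
#' @inheritParams removal_efficiency
#' @return Removal efficiency, percent.
#' @export
dissolved_removal <- function(c0, ct, tol_pp = 0.5) {
  removal_efficiency(c0, ct, tol_pp = tol_pp)
}

#' Resource-recovery mass balance table
#'
#' Full recoverable-resource bookkeeping for a bloom: for each
#' constituent and each harvesting mode, the recovered mass at the low
#' and high end of the volume range.
#'
#' @param dry_weight_conc dry weight, g/L.
#' @param volume_m3 length-2 volume range, m3.
#' @param contents named numeric of mass fractions (g/g), e.g.
#'   `c(lipid = 0.1037, phosphate = 0.00902, protein = 0.32545)`.
#' @param efficiencies named numeric of harvesting efficiencies (%),
#'   e.g. `c(max = 91.2, submax = 75.3)`.
#' @return A data.frame with columns `resource`, `mode`,
#'   `recovered_low_kg`, `recovered_high_kg`.
#' @export
resource_recovery_table <- function(dry_weight_conc, volume_m3, contents,
                                    efficiencies) {
  stock <- biomass_stock(dry_weight_conc, volume_m3)
  grid <- expand.grid(resource = names(contents), mode = names(efficiencies),
                      stringsAsFactors = FALSE)
  grid$recovered_low_kg <- recoverable_mass(
    stock[["low"]], contents[grid$resource], efficiencies[grid$mode])
  grid$recovered_high_kg <- recoverable_mass(
    stock[["high"]], contents[grid$resource], efficiencies[grid$mode])
  rownames(grid) <- NULL
  grid
}
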