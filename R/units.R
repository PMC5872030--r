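#' @title Unit registry and conversion
#' @name units
#'
#' @description
#' A closed registry of the units that occur in bloom-harvesting work:
#' volumes, concentrations, mass fractions (biomass contents), masses,
#' times, powers, airflows, currency and percentages. Each unit carries a
#' fixed multiplicative factor to the canonical unit of its dimension
#' (volume L, concentration mg/L, content g/g, mass kg, time min, power
#' kW, airflow L/min), so every conversion is exact arithmetic and every
#' factor has an inverse.
#'
#' Percentages are stored on the 0--100 scale throughout the package.
NULL

# unit -> (dimension, factor to canonical unit of that dimension)
.unit_registry <- local({
  reg <- rbind(
    data.frame(unit = "L",      dimension = "volume",        factor = 1),
    data.frame(unit = "m3",     dimension = "volume",        factor = 1000),
    data.frame(unit = "mL",     dimension = "volume",        factor = 1e-3),
    data.frame(unit = "mg/L",   dimension = "concentration", factor = 1),
    data.frame(unit = "g/L",    dimension = "concentration", factor = 1000),
    data.frame(unit = "ug/L",   dimension = "concentration", factor = 1e-3),
    data.frame(unit = "g/g",    dimension = "content",       factor = 1),
    data.frame(unit = "mg/g",   dimension = "content",       factor = 1e-3),
    data.frame(unit = "ug/mg",  dimension = "content",       factor = 1e-3),
    data.frame(unit = "kg",     dimension = "mass",          factor = 1),
    data.frame(unit = "g",      dimension = "mass",          factor = 1e-3),
    data.frame(unit = "mg",     dimension = "mass",          factor = 1e-6),
    data.frame(unit = "min",    dimension = "time",          factor = 1),
    data.frame(unit = "h",      dimension = "time",          factor = 60),
    data.frame(unit = "kW",     dimension = "power",         factor = 1),
    data.frame(unit = "W",      dimension = "power",         factor = 1e-3),
    data.frame(unit = "kWh",    dimension = "energy",        factor = 1),
    data.frame(unit = "L/min",  dimension = "airflow",       factor = 1),
    data.frame(unit = "mL/min", dimension = "airflow",       factor = 1e-3),
    data.frame(unit = "cfm",    dimension = "airflow",       factor = 28.3168),
    data.frame(unit = "currency", dimension = "currency",    factor = 1),
    data.frame(unit = "%",      dimension = "fraction_pct",  factor = 1)
  )
  rownames(reg) <- reg$unit
  reg
})

# accept the typographic variants that appear in printed tables
.normalise_unit <- function(unit) {
  u <- gsub("µ|μ", "u", trimws(unit))  # micro sign -> "u"
  u <- gsub("³", "3", u)                    # superscript 3
  aliases <- c(
    "l" = "L", "ml" = "mL", "m^3" = "m3", "ug/ml" = "ug/L",
    "CFM" = "cfm", "l/min" = "L/min", "ml/min" = "mL/min",
    "GBP" = "currency", "£" = "currency", "pct" = "%"
  )
  if (u %in% names(aliases)) u <- aliases[[u]]
  if (!u %in% rownames(.unit_registry)) {
    stop("unknown unit '", unit, "'; registry has: ",
         paste(rownames(.unit_registry), collapse = ", "), call. = FALSE)
  }
  u
}

#' Create a quantity with a registered unit
#'
#' @param value numeric value(s).
#' @param unit a unit name from the registry (e.g. `"mg/L"`, `"m3"`,
#'   `"cfm"`, `"ug/mg"`, `"%"`).
#' @return An object of class `quantity`: a numeric with a `unit`
#'   attribute.
#' @examples
#' quantity(7.1, "cfm")
#' @export
quantity <- function(value, unit) {
  stopifnot(is.numeric(value))
  unit <- .normalise_unit(unit)
  structure(as.numeric(value), unit = unit, class = "quantity")
}

#' @export
print.quantity <- function(x, ...) {
  cat(format(unclass(x)), attr(x, "unit"), "\n")
  invisible(x)
}

#' Convert a quantity between registered units
#'
#' Conversion uses the fixed registry factors, so round trips are exact
#' to floating-point (better than 1e-9 relative). Converting between
#' units of different dimensions (say volume to power) is an error that
#' names both units.
#'
#' @param q a [quantity()], or a bare numeric together with `from`.
#' @param to target unit name.
#' @param from source unit name; required when `q` is a bare numeric.
#' @return A `quantity` in the target unit.
#' @examples
#' convert(quantity(7.1, "cfm"), "L/min")  # 201.05, prints as 201
#' convert(1, "L", from = "m3")            # 1000 L
#' convert(103.7, "g/g", from = "ug/mg")   # 0.1037
#' @export
convert <- function(q, to, from = NULL) {
  if (!inherits(q, "quantity")) {
    if (is.null(from)) stop("`from` unit required for a bare numeric", call. = FALSE)
    q <- quantity(q, from)
  }
  from <- attr(q, "unit")
  to <- .normalise_unit(to)
  reg <- .unit_registry
  if (reg[from, "dimension"] != reg[to, "dimension"]) {
    stop("incompatible dimensions: cannot convert '", from, "' (",
         reg[from, "dimension"], ") to '", to, "' (",
         reg[to, "dimension"], ")", call. = FALSE)
  }
  quantity(unclass(q) * reg[from, "factor"] / reg[to, "factor"], to)
}

#' Numeric value of a quantity in a given unit
#'
#' @inheritParams convert
#' @return A bare numeric in unit `to`.
#' @export
as_unit <- function(q, to, from = NULL) {
  as.numeric(unclass(convert(q, to, from = from)))
}
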