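#' Read a delimited table with a typed schema
#'
#' Reads a UTF-8 delimiter-separated file with a header row. The
#' delimiter (tab or comma) is auto-detected from the header line.
#' Mandatory columns are checked by name; numeric columns are validated
#' cell by cell so a bad value is reported with its row number instead
#' of silently becoming `NA`. Unknown columns are preserved as-is.
#'
#' @param path file path.
#' @param required character vector of column names that must be present.
#' @param numeric_cols character vector of columns that must parse as
#'   numbers (defaults to `required`).
#' @return A `data.frame` with one row per data line.
#' @export
read_table <- function(path, required = character(), numeric_cols = required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L || !nzchar(trimws(header))) {
    stop("empty table file: ", path, call. = FALSE)
  }
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", comment.char = "",
                          quote = "\"", fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(df))) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & nzchar(trimws(df[[col]])))
    if (length(bad) > 0L) {
      stop("non-numeric value '", df[[col]][bad[1L]], "' in column '", col,
           "', row ", bad[1L], " of ", path, call. = FALSE)
    }
    df[[col]] <- vals
  }
  # any remaining all-numeric character columns are converted too
  for (col in setdiff(names(df), numeric_cols)) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    if (!anyNA(vals[nzchar(trimws(df[[col]]))])) df[[col]] <- vals
  }
  df
}

#' Write a table read back identically by [read_table()]
#'
#' @param df a data.frame.
#' @param path output path.
#' @param sep delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a water-sample characterisation file
#'
#' Expects a two-column parameter/value table (optionally with `sd` and
#' `unit` columns) describing the physicochemistry of a bloom water
#' sample: temperature, pH, dissolved oxygen, conductivity, salinity,
#' dry weight, chlorophyll a, and dissolved ion concentrations.
#'
#' @param path path to a parameter/value table.
#' @return A `water_sample` object: a named list with numeric entries
#'   and an `ions` sub-list (mg/L).
#' @export
read_water_sample <- function(path) {
  df <- read_table(path, required = c("parameter", "value"),
                   numeric_cols = "value")
  vals <- stats::setNames(df$value, df$parameter)
  water_sample(vals)
}

#' Construct and validate a water sample
#'
#' @param params named numeric vector or list; recognised names are
#'   `temperature` (deg C), `pH`, `dissolved_oxygen` (mg/L),
#'   `conductivity` (uS/cm), `salinity` (PSU), `dry_weight` (g/L),
#'   `chlorophyll_a` (ug/L) and ion names (`F`, `Cl`, `NO2`, `SO4`,
#'   `Br`, `NO3`, `PO4`, `Na`, `NH4`, `K`, `Mg`, `Ca`; mg/L).
#' @return A `water_sample` list with an `ions` component.
#' @export
water_sample <- function(params) {
  params <- as.list(params)
  ion_names <- c("F", "Cl", "NO2", "SO4", "Br", "NO3", "PO4",
                 "Na", "NH4", "K", "Mg", "Ca")
  ions <- params[names(params) %in% ion_names]
  scalars <- params[!names(params) %in% ion_names]
  if (!is.null(scalars$pH) && (scalars$pH < 0 || scalars$pH > 14)) {
    stop("pH must lie in [0, 14], got ", scalars$pH, call. = FALSE)
  }
  conc <- c(unlist(ions), scalars$dissolved_oxygen, scalars$dry_weight,
            scalars$chlorophyll_a)
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  structure(c(scalars, list(ions = ions)), class = "water_sample")
}

#' @export
print.water_sample <- function(x, ...) {
  cat("Water sample\n")
  for (nm in setdiff(names(x), "ions")) {
    cat(sprintf("  %-15s %s\n", nm, format(x[[nm]])))
  }
  if (length(x$ions) > 0L) {
    cat("  ions (mg/L):   ",
        paste(sprintf("%s=%s", names(x$ions), format(unlist(x$ions))),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a structured parameter/configuration file
#'
#' YAML is used for nested scenario and cost-model parameter files
#' (prices, tariffs, equipment items, scenario volumes).
#'
#' @param path path to a YAML file.
#' @param allowed optional character vector of permitted top-level keys;
#'   an unknown key is rejected by name.
#' @return A named list.
#' @export
read_config <- function(path, allowed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.null(allowed)) {
    unknown <- setdiff(names(cfg), allowed)
    if (length(unknown) > 0L) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  cfg
}
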