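#' Parse a FAME shorthand name
#'
#' Parses the `Cx:y` lipid-number notation used for fatty acid methyl
#' esters: carbon chain length, number of double bonds, optional
#' omega position (`n3` or `n-3`), optional `cis`/`trans` geometry
#' token. Examples from supplier mix sheets: `"C16:0"`, `"C18:1 cis"`,
#' `"C18:3n3"`, `"C20:5 n-3"`.
#'
#' @param name a FAME shorthand string.
#' @return A list: `name` (normalised), `carbons`, `double_bonds`,
#'   `omega` (integer or `NA`), `geometry`
#'   (`"cis"`, `"trans"` or `"unspecified"`).
#' @export
parse_fame <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- regmatches(name, regexec(
    "^C([0-9]+):([0-9]+)(?:\\s?n-?([0-9]+))?(?:\\s(cis|trans))?$",
    trimws(name)))[[1]]
  if (length(m) == 0L) {
    stop("malformed FAME name: '", name,
         "' (expected C<carbons>:<bonds>[n<omega>][ cis|trans])",
         call. = FALSE)
  }
  carbons <- as.integer(m[2]); bonds <- as.integer(m[3])
  omega <- if (nzchar(m[4])) as.integer(m[4]) else NA_integer_
  geometry <- if (nzchar(m[5])) m[5] else "unspecified"
  if (carbons < 2L) stop("FAME must have >= 2 carbons: '", name, "'",
                         call. = FALSE)
  if (!is.na(omega) && bonds == 0L) {
    stop("omega position given for saturated species: '", name, "'",
         call. = FALSE)
  }
  list(name = format_fame(carbons, bonds, omega, geometry),
       carbons = carbons, double_bonds = bonds, omega = omega,
       geometry = geometry)
}

#' Format a FAME shorthand name
#'
#' Inverse of [parse_fame()] on the canonical 37-component-mix naming
#' style.
#'
#' @param carbons,double_bonds integers.
#' @param omega omega position or `NA`.
#' @param geometry `"cis"`, `"trans"` or `"unspecified"`.
#' @return A string such as `"C18:3n3"`.
#' @export
format_fame <- function(carbons, double_bonds, omega = NA,
                        geometry = "unspecified") {
  s <- sprintf("C%d:%d", carbons, double_bonds)
  if (!is.na(omega)) s <- sprintf("%sn%d", s, omega)
  if (geometry %in% c("cis", "trans")) s <- paste(s, geometry)
  s
}

#' Classify a FAME by saturation
#'
#' @param x a FAME name string or a parsed record from [parse_fame()].
#' @return `"SFA"` (0 double bonds), `"MUFA"` (1) or `"PUFA"` (>= 2).
#' @examples
#' classify_saturation("C18:1 cis")  # MUFA
#' @export
classify_saturation <- function(x) {
  if (is.character(x)) x <- parse_fame(x)
  b <- x$double_bonds
  if (b == 0L) "SFA" else if (b == 1L) "MUFA" else "PUFA"
}

#' Filter FAME detections to reproducible hits
#'
#' Keeps only species detected in at least `min_replicates` technical
#' replicates, then averages their yields over the replicates in which
#' they were detected.
#'
#' @param df long-format data.frame with columns `fame_name`,
#'   `yield_mg_per_g`, `replicate_id`.
#' @param min_replicates detection threshold (default 3).
#' @return A data.frame with `fame_name`, `yield_mg_per_g` (mean over
#'   detecting replicates), `n_replicates`.
#' @export
filter_true_hits <- function(df, min_replicates = 3) {
  need <- c("fame_name", "yield_mg_per_g", "replicate_id")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n_rep <- tapply(df$replicate_id, df$fame_name,
                  function(r) length(unique(r)))
  keep <- names(n_rep)[n_rep >= min_replicates]
  means <- tapply(df$yield_mg_per_g, df$fame_name, mean)
  out <- data.frame(fame_name = keep,
                    yield_mg_per_g = as.numeric(means[keep]),
                    n_replicates = as.integer(n_rep[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$fame_name), , drop = FALSE]
}

#' Aggregate FAME yields by saturation group
#'
#' Sums per-species yields (mg per g biomass) into SFA / MUFA / PUFA
#' subtotals and computes each group's share of total FAME mass.
#'
#' @param fame_name character vector of FAME shorthand names (must be
#'   unique: a duplicated species is ambiguous input).
#' @param yield_mg_per_g matching non-negative yields.
#' @return A list with `by_species` (data.frame adding `group`),
#'   `group_totals_mg_per_g` (named numeric, SFA/MUFA/PUFA),
#'   `group_pct` (shares summing to 100) and `total_mg_per_g`.
#' @examples
#' group_yields(c("C14:0", "C16:0", "C18:0"), c(30.29, 28.17, 21.5))
#' @export
group_yields <- function(fame_name, yield_mg_per_g) {
  stopifnot(length(fame_name) == length(yield_mg_per_g))
  if (length(fame_name) == 0L) {
    stop("empty FAME list: relative profile undefined", call. = FALSE)
  }
  if (any(yield_mg_per_g < 0)) stop("yields must be >= 0", call. = FALSE)
  canon <- vapply(fame_name, function(n) parse_fame(n)$name, character(1))
  if (anyDuplicated(canon)) {
    stop("duplicate FAME name(s): ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "),
         call. = FALSE)
  }
  group <- vapply(fame_name, classify_saturation, character(1))
  totals <- vapply(c(SFA = "SFA", MUFA = "MUFA", PUFA = "PUFA"),
                   function(g) sum(yield_mg_per_g[group == g]), numeric(1))
  total <- sum(totals)
  if (total <= 0) stop("total FAME yield is zero: profile undefined",
                       call. = FALSE)
  list(by_species = data.frame(fame_name = unname(canon),
                               yield_mg_per_g = yield_mg_per_g,
                               group = unname(group),
                               stringsAsFactors = FALSE),
       group_totals_mg_per_g = totals,
       group_pct = 100 * totals / total,
       total_mg_per_g = total)
}
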