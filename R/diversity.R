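#' Read a classic OTU table
#'
#' Tab-separated table: an `otu_id` column, one column of counts per
#' sample, and a trailing `taxonomy` column of rank-prefixed,
#' semicolon-delimited lineage strings
#' (`k__Bacteria;p__Cyanobacteria;...;g__Synechococcus`).
#'
#' @param path file path.
#' @return A list: `counts` (integer matrix, OTUs x samples),
#'   `taxonomy` (character vector per OTU).
#' @export
read_otu_table <- function(path) {
  df <- read_table(path, required = c("otu_id", "taxonomy"),
                   numeric_cols = character())
  sample_cols <- setdiff(names(df), c("otu_id", "taxonomy"))
  if (length(sample_cols) == 0L) stop("no sample columns found", call. = FALSE)
  counts <- as.matrix(df[sample_cols])
  storage.mode(counts) <- "numeric"
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative numbers", call. = FALSE)
  }
  rownames(counts) <- df$otu_id
  list(counts = counts, taxonomy = df$taxonomy)
}

.rank_prefixes <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                    family = "f", genus = "g", species = "s")

# extract the name at `rank` from a greengenes-style lineage string;
# "" or missing level -> NA
.taxon_at_rank <- function(taxonomy, rank) {
  prefix <- .rank_prefixes[[rank]]
  vapply(strsplit(taxonomy, ";"), function(levels) {
    levels <- trimws(levels)
    hit <- grep(paste0("^", prefix, "__"), levels, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    nm <- sub(paste0("^", prefix, "__"), "", hit[1])
    if (nzchar(nm)) nm else NA_character_
  }, character(1))
}

#' Relative-abundance aggregation at a taxonomic rank
#'
#' Aggregates OTU counts to a rank, converts to per-sample percentages,
#' and pools rare taxa for display: a taxon is retained if it reaches
#' `min_frac` percent in at least one sample (so it stays visible in
#' every column of a stacked-bar figure), otherwise it is pooled into
#' an `other (<X%)` bucket. OTUs without an assignment at the rank are
#' pooled into `unmatched`. Per-sample percentages sum to 100.
#'
#' @param counts OTU x sample count matrix (rows named by OTU).
#' @param taxonomy lineage string per OTU.
#' @param rank one of kingdom, phylum, class, order, family, genus,
#'   species.
#' @param min_frac display threshold in percent (default 1).
#' @return A taxa x sample percentage matrix.
#' @export
relative_abundance <- function(counts, taxonomy,
                               rank = "genus", min_frac = 1) {
  rank <- match.arg(rank, names(.rank_prefixes))
  stopifnot(nrow(counts) == length(taxonomy))
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stop("empty sample column(s): ",
         paste(colnames(counts)[totals <= 0], collapse = ", "),
         call. = FALSE)
  }
  taxon <- .taxon_at_rank(taxonomy, rank)
  taxon[is.na(taxon)] <- "unmatched"
  agg <- rowsum(counts, group = taxon)
  pct <- sweep(agg, 2, colSums(agg), "/") * 100
  named <- setdiff(rownames(pct), "unmatched")
  keep <- named[apply(pct[named, , drop = FALSE], 1, max) >= min_frac]
  pooled <- setdiff(named, keep)
  out <- pct[keep, , drop = FALSE]
  if (length(pooled) > 0L) {
    other <- colSums(pct[pooled, , drop = FALSE])
    out <- rbind(out, matrix(other, nrow = 1,
                             dimnames = list(sprintf("other (<%g%%)", min_frac),
                                             colnames(pct))))
  }
  if ("unmatched" %in% rownames(pct)) {
    out <- rbind(out, pct["unmatched", , drop = FALSE])
  }
  out[order(-rowMeans(out)), , drop = FALSE]
}

#' Shannon diversity index
#'
#' `H' = -sum(p_i * ln p_i)` over the nonzero relative abundances
#' `p_i = c_i / sum(c)`, natural log. Ranges from 0 (a single taxon) to
#' `ln(S)` (S taxa, perfectly even).
#'
#' @param counts non-negative abundance vector with a positive total,
#'   or a matrix (index computed per column).
#' @return H' (numeric, or named numeric per sample for a matrix).
#' @examples
#' shannon_index(c(50, 30, 20))  # 1.0297
#' @export
shannon_index <- function(counts) {
  if (is.matrix(counts)) return(apply(counts, 2, shannon_index))
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("all counts are zero: H' undefined", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}
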