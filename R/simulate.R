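#' @title Synthetic-data generators
#' @name simulate
#' @description
#' Seeded generators producing inputs with the statistical structure
#' the analysis stages assume: Hill-shaped flocculant dose-response
#' points, first-order flotation time series, Dirichlet-multinomial
#' OTU tables, and truncated-normal biomass composition replicates.
#' The same seed and parameters always reproduce the same output.
NULL

# additive Gaussian noise on the percentage scale, truncated to [0,100]
.pct_noise <- function(x, sd) pmin(pmax(x + stats::rnorm(length(x), 0, sd), 0), 100)

#' Simulate a flocculant dose-response table
#'
#' Saturating Hill curve
#' `E(d) = e_max * d^h / (ec50^h + d^h)` plus optional additive
#' Gaussian noise on the percentage scale, clipped to `[0, 100]`.
#'
#' @param e_max plateau efficiency, percent in `[0, 100]`.
#' @param ec50 dose of half-maximal effect, mg/L (> 0).
#' @param hill_coef Hill steepness coefficient.
#' @param doses dose grid, mg/L (non-empty).
#' @param noise_sd noise standard deviation, pp (0 for the exact curve).
#' @param seed RNG seed.
#' @return data.frame with `dose_mg_per_L`, `efficiency_pct`.
#' @export
simulate_dose_response <- function(e_max, ec50, hill_coef = 2,
                                   doses = c(1, 1.25, 2, 3, 5, 7, 9),
                                   noise_sd = 0, seed = 1) {
  if (length(doses) == 0L) stop("empty dose list", call. = FALSE)
  if (e_max < 0 || e_max > 100) stop("e_max must lie in [0, 100]",
                                     call. = FALSE)
  if (ec50 <= 0) stop("ec50 must be > 0", call. = FALSE)
  eff <- e_max * doses^hill_coef / (ec50^hill_coef + doses^hill_coef)
  if (noise_sd > 0) {
    set.seed(seed)
    eff <- .pct_noise(eff, noise_sd)
  }
  data.frame(dose_mg_per_L = doses, efficiency_pct = eff)
}

#' Simulate a flotation harvesting time series
#'
#' First-order flotation model `E(t) = e_inf * (1 - exp(-k t))` with
#' optional truncated Gaussian noise. The study conditions this
#' defaults to: a high-dose run plateauing near 92% with most of the
#' harvest complete within the first couple of minutes.
#'
#' @param e_inf asymptotic efficiency, percent in `[0, 100]`.
#' @param k first-order rate constant, 1/min (>= 0; must be > 0 when
#'   `e_inf > 0` unless the series is meant to stay at zero).
#' @param times sampling times, min.
#' @param noise_sd noise sd, pp.
#' @param seed RNG seed.
#' @return data.frame with `time_min`, `efficiency_pct`.
#' @export
simulate_flotation <- function(e_inf = 92, k = 0.95,
                               times = seq(2, 10, by = 2),
                               noise_sd = 0, seed = 1) {
  if (e_inf < 0 || e_inf > 100) stop("e_inf must lie in [0, 100]",
                                     call. = FALSE)
  if (k <= 0 && e_inf > 0) {
    stop("non-positive rate constant with nonzero e_inf", call. = FALSE)
  }
  eff <- e_inf * (1 - exp(-k * times))
  if (noise_sd > 0) {
    set.seed(seed)
    eff <- .pct_noise(eff, noise_sd)
  }
  data.frame(time_min = times, efficiency_pct = eff)
}

#' Simulate a Dirichlet-multinomial OTU table
#'
#' Draws per-sample taxon proportions from a Dirichlet distribution
#' whose mean gives the top taxon a chosen share (`dominance`) and
#' splits the remainder evenly, then draws multinomial counts at the
#' given sequencing depth. Emulates a bloom community: high dominance
#' mimics a cyanobacteria-dominated pond, low dominance a recovered,
#' more even community.
#'
#' @param n_taxa number of taxa (>= 2).
#' @param dominance expected share of the top taxon, in
#'   `(1/n_taxa, 1)`; `1/n_taxa` gives a uniform community.
#' @param depth reads per sample (>= n_taxa).
#' @param n_samples number of samples.
#' @param concentration Dirichlet precision (larger = less
#'   sample-to-sample variation); default 100.
#' @param seed RNG seed.
#' @return A list like [read_otu_table()]: `counts` (taxa x samples),
#'   `taxonomy` (synthesised lineage strings to genus rank).
#' @export
simulate_community <- function(n_taxa = 10, dominance = 0.5, depth = 50000,
                               n_samples = 2, concentration = 100,
                               seed = 1) {
  if (n_taxa < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (dominance < 1 / n_taxa || dominance >= 1) {
    stop("dominance must lie in [1/n_taxa, 1)", call. = FALSE)
  }
  if (depth < n_taxa) stop("depth must be >= n_taxa", call. = FALSE)
  set.seed(seed)
  p_mean <- c(dominance, rep((1 - dominance) / (n_taxa - 1), n_taxa - 1))
  alpha <- concentration * p_mean
  counts <- vapply(seq_len(n_samples), function(j) {
    g <- stats::rgamma(n_taxa, shape = alpha)  # Dirichlet via gammas
    stats::rmultinom(1, size = depth, prob = g / sum(g))[, 1]
  }, integer(n_taxa))
  rownames(counts) <- sprintf("OTU_%03d", seq_len(n_taxa))
  colnames(counts) <- sprintf("sample_%d", seq_len(n_samples))
  taxonomy <- sprintf(
    "k__Bacteria;p__Phylum%02d;c__Class%02d;o__Order%02d;f__Family%02d;g__Genus%02d",
    seq_len(n_taxa), seq_len(n_taxa), seq_len(n_taxa), seq_len(n_taxa),
    seq_len(n_taxa))
  list(counts = counts, taxonomy = taxonomy)
}

#' Simulate biomass composition replicates
#'
#' Truncated-normal draws of constituent mass fractions around
#' configured means. Defaults are the bloom-biomass point estimates
#' used throughout the package: lipid 0.1037, phosphate 0.00902,
#' protein 0.32545 g per g dry biomass.
#'
#' @param means named numeric of mass fractions (g/g).
#' @param cv coefficient of variation (0 returns the exact means).
#' @param n_replicates rows to draw.
#' @param seed RNG seed.
#' @return data.frame of replicates, one column per constituent, all
#'   values in `[0, 1]`.
#' @export
simulate_composition <- function(means = c(lipid = 0.1037,
                                           phosphate = 0.00902,
                                           protein = 0.32545),
                                 cv = 0, n_replicates = 3, seed = 1) {
  stopifnot(all(means >= 0 & means <= 1), cv >= 0)
  set.seed(seed)
  out <- lapply(means, function(m) {
    if (cv == 0) return(rep(m, n_replicates))
    x <- stats::rnorm(n_replicates, m, cv * m)
    while (any(x < 0 | x > 1)) {  # rejection keeps fractions physical
      bad <- x < 0 | x > 1
      x[bad] <- stats::rnorm(sum(bad), m, cv * m)
    }
    x
  })
  as.data.frame(out)
}
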