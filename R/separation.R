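#' Removal efficiency from before/after concentrations
#'
#' Percentage of a constituent (chlorophyll a, optical density, a
#' dissolved nutrient) removed by a treatment:
#' `100 * (1 - ct / c0)`. Measurement noise can push the final
#' concentration slightly above the initial one; an overshoot of at
#' most `tol_pp` percentage points is clamped to the valid range, a
#' larger one is an error.
#'
#' @param c0 initial concentration (> 0; any unit, shared with `ct`).
#' @param ct concentration after treatment (>= 0).
#' @param tol_pp clamp tolerance in percentage points (default 0.5).
#' @return Removal efficiency in percent, in `[0, 100]`.
#' @examples
#' removal_efficiency(443.23, 395.7)  # 10.72 %
#' @export
removal_efficiency <- function(c0, ct, tol_pp = 0.5) {
  stopifnot(length(c0) == length(ct))
  if (any(c0 <= 0)) stop("initial concentration c0 must be > 0", call. = FALSE)
  if (any(ct < 0)) stop("final concentration ct must be >= 0", call. = FALSE)
  eff <- 100 * (1 - ct / c0)
  over <- eff < -tol_pp
  if (any(over)) {
    stop("final concentration exceeds initial by more than the ", tol_pp,
         " pp tolerance (efficiency ", format(min(eff)), "%)", call. = FALSE)
  }
  pmin(pmax(eff, 0), 100)
}

#' Build a flocculant dose-response curve
#'
#' Constructs a monotone-by-dose piecewise-linear curve from jar-test
#' points (dose in mg/L, sedimentation efficiency in percent). The
#' measured grid is coarse, so no smoothing or extrapolation is
#' applied: evaluation interpolates linearly between measured doses and
#' refuses doses outside the measured range.
#'
#' @param dose flocculant doses, mg/L (>= 2 distinct values, >= 0).
#' @param efficiency removal efficiencies, percent in `[0, 100]`.
#' @param replicate_sd optional replicate standard deviations (pp).
#' @return A `dose_response` object.
#' @seealso [select_doses()], [predict.dose_response()]
#' @export
build_dose_response <- function(dose, efficiency, replicate_sd = NULL) {
  stopifnot(length(dose) == length(efficiency))
  if (any(dose < 0)) stop("doses must be >= 0", call. = FALSE)
  if (any(efficiency < 0 | efficiency > 100)) {
    stop("efficiencies must lie in [0, 100]", call. = FALSE)
  }
  dup <- duplicated(dose)
  if (any(dup)) {
    for (d in unique(dose[dup])) {
      effs <- unique(efficiency[dose == d])
      if (length(effs) > 1L) {
        stop("conflicting efficiencies at dose ", d, " mg/L: ",
             paste(effs, collapse = " vs "), call. = FALSE)
      }
    }
    keep <- !dup
    dose <- dose[keep]; efficiency <- efficiency[keep]
    if (!is.null(replicate_sd)) replicate_sd <- replicate_sd[keep]
  }
  if (length(dose) < 2L) {
    stop("need at least 2 distinct doses to build a curve", call. = FALSE)
  }
  ord <- order(dose)
  structure(list(dose = dose[ord], efficiency = efficiency[ord],
                 replicate_sd = if (!is.null(replicate_sd)) replicate_sd[ord]),
            class = "dose_response")
}

#' Evaluate a dose-response curve at given doses
#'
#' @param object a `dose_response` curve.
#' @param dose doses to evaluate at; must lie within the measured range.
#' @param ... unused.
#' @return Interpolated efficiencies, percent.
#' @export
predict.dose_response <- function(object, dose, ...) {
  rng <- range(object$dose)
  if (any(dose < rng[1] | dose > rng[2])) {
    stop("dose outside the measured range [", rng[1], ", ", rng[2],
         "] mg/L; no extrapolation", call. = FALSE)
  }
  stats::approx(object$dose, object$efficiency, xout = dose,
                ties = "ordered")$y
}

#' @export
print.dose_response <- function(x, ...) {
  cat("Dose-response curve (", length(x$dose), " doses, ",
      format(min(x$dose)), "-", format(max(x$dose)), " mg/L)\n", sep = "")
  print(data.frame(dose_mg_per_L = x$dose, efficiency_pct = x$efficiency))
  invisible(x)
}

#' Select maximum and sub-maximum operating doses
#'
#' Picks the two flocculant operating points used for flotation trials:
#' the maximum-efficiency dose (`se_max`) is the smallest measured dose
#' whose efficiency lies within `tie_tol_pp` of the curve maximum
#' (replicate scatter makes near-ties indistinguishable), and the
#' sub-maximum dose (`se_submax`) is the measured dose whose efficiency
#' is nearest a reduced target (ties broken towards the lower dose).
#'
#' @param curve a `dose_response` from [build_dose_response()].
#' @param submax_target target efficiency (percent) for the reduced
#'   operating point; must be within the measured efficiency range.
#' @param tie_tol_pp tolerance (pp) for calling a dose maximal.
#' @return A `dose_selection` list: `se_max_dose`, `se_max_efficiency`,
#'   `se_submax_dose`, `se_submax_efficiency`.
#' @examples
#' curve <- build_dose_response(c(1.25, 2.5, 5, 9), c(70, 82, 96, 95))
#' select_doses(curve, submax_target = 70)
#' @export
select_doses <- function(curve, submax_target, tie_tol_pp = 1) {
  stopifnot(inherits(curve, "dose_response"))
  eff <- curve$efficiency; dose <- curve$dose
  if (submax_target < min(eff) - tie_tol_pp || submax_target > max(eff)) {
    stop("submax_target ", submax_target,
         "% outside the achievable range [", format(min(eff)), ", ",
         format(max(eff)), "]%", call. = FALSE)
  }
  near_max <- which(eff >= max(eff) - tie_tol_pp)
  i_max <- near_max[which.min(dose[near_max])]
  gap <- abs(eff - submax_target)
  cand <- which(gap <= min(gap) + 1e-12)
  i_sub <- cand[which.min(dose[cand])]
  structure(list(se_max_dose = dose[i_max], se_max_efficiency = eff[i_max],
                 se_submax_dose = dose[i_sub],
                 se_submax_efficiency = eff[i_sub]),
            class = "dose_selection")
}

#' @export
print.dose_selection <- function(x, ...) {
  cat(sprintf("SE_max:     %g mg/L -> %g%%\n", x$se_max_dose,
              x$se_max_efficiency))
  cat(sprintf("SE_sub-max: %g mg/L -> %g%%\n", x$se_submax_dose,
              x$se_submax_efficiency))
  invisible(x)
}

# exact 2-point solution of E(t) = e_inf (1 - exp(-k t)): eliminate
# e_inf and root-find k on the remaining 1-D equation
.fit_kinetics_2pt <- function(t, e) {
  ord <- order(t); t <- t[ord]; e <- e[ord]
  if (e[2] <= e[1]) {  # flat or declining pair: least-squares constant
    return(list(e_inf = mean(e), k = 0))
  }
  # g(k) = e1 * (1 - exp(-k t2)) - e2 * (1 - exp(-k t1)) = 0
  g <- function(k) e[1] * (1 - exp(-k * t[2])) - e[2] * (1 - exp(-k * t[1]))
  lo <- 1e-8; hi <- 1
  while (g(hi) > 0 && hi < 1e6) hi <- hi * 2
  k <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  list(e_inf = e[2] / (1 - exp(-k * t[2])), k = k)
}

#' Fit first-order flotation kinetics
#'
#' Fits the standard first-order flotation-rate model
#' `E(t) = e_inf * (1 - exp(-k t))` to a time series of harvesting
#' efficiencies by nonlinear least squares. With exactly two points the
#' exact interpolating solution is found by one-dimensional root
#' search. Non-increasing efficiencies beyond `noise_tol_pp` trigger a
#' warning but the fit proceeds.
#'
#' @param time minutes since microbubble introduction; >= 0, strictly
#'   increasing.
#' @param efficiency harvesting efficiencies, percent in `[0, 100]`.
#' @param noise_tol_pp drop (pp) between consecutive points tolerated
#'   without warning.
#' @return A `kinetics_fit` list: `e_inf` (asymptotic efficiency, %),
#'   `k` (rate constant, 1/min), `rss`, `fitted`.
#' @examples
#' ts <- simulate_flotation(e_inf = 90, k = 0.9, times = 1:10)
#' fit_flotation_kinetics(ts$time_min, ts$efficiency_pct)
#' @export
fit_flotation_kinetics <- function(time, efficiency, noise_tol_pp = 2) {
  stopifnot(length(time) == length(efficiency))
  if (length(time) < 2L || anyDuplicated(time)) {
    stop("need >= 2 points with distinct times", call. = FALSE)
  }
  if (any(time < 0)) stop("times must be >= 0", call. = FALSE)
  ord <- order(time); time <- time[ord]; efficiency <- efficiency[ord]
  if (any(diff(efficiency) < -noise_tol_pp)) {
    warning("efficiency decreases by more than ", noise_tol_pp,
            " pp between consecutive times; fitting anyway", call. = FALSE)
  }
  if (all(efficiency == 0)) {
    pars <- list(e_inf = 0, k = 0)
  } else if (length(time) == 2L) {
    pars <- .fit_kinetics_2pt(time, efficiency)
  } else {
    e_start <- max(efficiency)
    k_start <- {  # linearised guess from the earliest informative point
      i <- which(efficiency > 0 & efficiency < e_start)[1]
      if (is.na(i)) 0.5 else -log(1 - efficiency[i] / (e_start * 1.001)) / time[i]
    }
    fit <- minpack.lm::nlsLM(
      efficiency ~ e_inf * (1 - exp(-k * time)),
      start = list(e_inf = e_start, k = max(k_start, 1e-3)),
      lower = c(0, 0), upper = c(100, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14))
    cf <- stats::coef(fit)
    pars <- list(e_inf = unname(cf["e_inf"]), k = unname(cf["k"]))
  }
  fitted <- pars$e_inf * (1 - exp(-pars$k * time))
  structure(list(e_inf = pars$e_inf, k = pars$k,
                 rss = sum((efficiency - fitted)^2),
                 time = time, efficiency = efficiency, fitted = fitted),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("First-order flotation kinetics: E(t) = %.3f * (1 - exp(-%.4f t))\n",
              x$e_inf, x$k))
  cat(sprintf("  RSS = %.4g over %d points\n", x$rss, length(x$time)))
  invisible(x)
}

#' Paired mean comparison (paired t-test)
#'
#' Classical paired t statistic and two-sided p-value from the t
#' distribution, used to test whether paired efficiency measurements
#' (e.g. flocculation with natural vs reduced bacterial load) differ.
#' If every difference is zero the test is degenerate and `p = 1` by
#' convention.
#'
#' @param before,after paired measurements (percent), equal length >= 2.
#' @return A list with `t`, `df` and `p_two_sided`.
#' @examples
#' paired_mean_test(c(0, 0, 0, 0), c(1, 2, 3, 4))
#' @export
paired_mean_test <- function(before, after) {
  if (length(before) != length(after)) {
    stop("before/after must have equal length", call. = FALSE)
  }
  n <- length(before)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- after - before
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1L, p_two_sided = 1))
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p_two_sided = 0))
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, df = n - 1L,
       p_two_sided = 2 * stats::pt(-abs(tstat), df = n - 1L))
}
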