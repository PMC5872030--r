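test_that("removal efficiency is the normalised concentration drop", {
  expect_equal(removal_efficiency(100, 100), 0)
  expect_equal(removal_efficiency(100, 0), 100)
  # day-0 vs day-10 untreated chlorophyll a
  expect_equal(removal_efficiency(443.23, 395.7), 10.72355,
               tolerance = 1e-6)
  expect_error(removal_efficiency(0, 1), "c0")
  expect_error(removal_efficiency(100, -1), "ct")
})

test_that("overshoot is clamped only within tolerance", {
  expect_equal(removal_efficiency(100, 100.3), 0)  # 0.3 pp, clamped
  expect_error(removal_efficiency(100, 101), "tolerance")
  expect_equal(removal_efficiency(100, 101, tol_pp = 2), 0)
})

test_that("removal efficiency is antitone in ct and bounded", {
  ct <- seq(0, 100, by = 5)
  eff <- removal_efficiency(rep(100, length(ct)), ct)
  expect_true(all(diff(eff) < 0))
  expect_true(all(eff >= 0 & eff <= 100))
})

test_that("dose-response curve interpolates without extrapolating", {
  curve <- build_dose_response(c(1.25, 5), c(70, 96))
  expect_equal(predict(curve, 5), 96)
  expect_equal(predict(curve, 1.25), 70)
  lin <- build_dose_response(c(0, 10), c(0, 100))
  expect_equal(predict(lin, 5), 50)
  expect_error(predict(lin, 11), "no extrapolation")
  expect_error(build_dose_response(3, 50), "at least 2")
  expect_error(build_dose_response(c(2, 2), c(50, 60)),
               "conflicting efficiencies at dose 2")
})

test_that("dose selection matches an exhaustive-scan oracle", {
  dose <- c(1.25, 2.5, 5, 9); eff <- c(70, 82, 96, 95)
  sel <- select_doses(build_dose_response(dose, eff), submax_target = 70)
  expect_equal(sel$se_max_dose, 5)
  expect_equal(sel$se_max_efficiency, 96)
  expect_equal(sel$se_submax_dose, 1.25)
  expect_equal(sel$se_submax_efficiency, 70)
  expect_true(sel$se_submax_efficiency <= sel$se_max_efficiency)

  # oracle: brute scan over all points, same tie rules
  scan_oracle <- function(dose, eff, target, tol = 1) {
    ok <- eff >= max(eff) - tol
    i_max <- which(ok & dose == min(dose[ok]))
    gap <- abs(eff - target)
    near <- gap <= min(gap) + 1e-12
    i_sub <- which(near & dose == min(dose[near]))
    c(dose[i_max], dose[i_sub])
  }
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    d <- sort(sample(seq(0.5, 12, by = 0.25), n))
    e <- round(runif(n, 20, 99), 1)
    target <- runif(1, min(e), max(e))
    sel <- select_doses(build_dose_response(d, e), target)
    orc <- scan_oracle(d, e, target)
    expect_equal(c(sel$se_max_dose, sel$se_submax_dose), orc)
  }
})

test_that("dose selection is invariant to point order and breaks ties low", {
  perm <- sample(4)
  dose <- c(1.25, 2.5, 5, 9)[perm]; eff <- c(70, 82, 96, 95)[perm]
  sel <- select_doses(build_dose_response(dose, eff), 70)
  expect_equal(sel$se_max_dose, 5)
  flat <- select_doses(build_dose_response(c(1, 3, 6), c(96, 96, 96)), 96)
  expect_equal(flat$se_max_dose, 1)
  expect_error(select_doses(build_dose_response(c(1, 5), c(60, 90)), 30),
               "achievable range")
})

test_that("kinetics fit recovers noiseless parameters exactly", {
  for (e_inf in c(50, 75.3, 91.2)) {
    for (k in c(0.2, 0.9, 1.5)) {
      ts <- simulate_flotation(e_inf, k, times = 1:10)
      fit <- fit_flotation_kinetics(ts$time_min, ts$efficiency_pct)
      expect_equal(fit$e_inf, e_inf, tolerance = 1e-6)
      expect_equal(fit$k, k, tolerance = 1e-6)
      expect_lt(fit$rss, 1e-10)
    }
  }
})

test_that("two-point kinetics solution matches the bisection oracle", {
  # printed high-dose flotation points: 84.9% at 2 min, 91.2% at 10 min
  fit <- fit_flotation_kinetics(c(2, 10), c(84.9, 91.2))
  g <- function(k) 84.9 * (1 - exp(-10 * k)) - 91.2 * (1 - exp(-2 * k))
  k_oracle <- uniroot(g, c(1e-8, 5), tol = 1e-14)$root
  expect_equal(fit$k, k_oracle, tolerance = 1e-9)
  expect_equal(fit$e_inf, 91.2 / (1 - exp(-10 * k_oracle)),
               tolerance = 1e-9)
  # the fit interpolates both points exactly
  expect_equal(fit$fitted, c(84.9, 91.2), tolerance = 1e-9)
})

test_that("kinetics fit handles degenerate and noisy series", {
  fit0 <- fit_flotation_kinetics(c(1, 5, 10), c(0, 0, 0))
  expect_equal(fit0$e_inf, 0)
  expect_warning(fit_flotation_kinetics(c(1, 2, 3, 4), c(50, 80, 40, 85)),
                 "decreases")
  expect_error(fit_flotation_kinetics(c(1, 1), c(10, 20)), "distinct")

  # noisy recovery: median |e_inf error| < 2 pp at sd = 2 pp, n = 6
  errs <- vapply(1:20, function(s) {
    ts <- simulate_flotation(85, 0.8, times = seq(1, 11, by = 2),
                             noise_sd = 2, seed = s)
    fit <- suppressWarnings(
      fit_flotation_kinetics(ts$time_min, ts$efficiency_pct))
    abs(fit$e_inf - 85)
  }, numeric(1))
  expect_lt(median(errs), 2)
})

test_that("paired comparison matches the t-distribution oracle", {
  res <- paired_mean_test(c(0, 0, 0, 0), c(1, 2, 3, 4))
  expect_equal(res$t, 3.872983, tolerance = 1e-6)
  expect_equal(res$df, 3)
  expect_equal(res$p_two_sided, 0.03046629, tolerance = 1e-6)

  # independent cross-check against the stock implementation
  set.seed(7)
  for (i in 1:10) {
    a <- runif(6, 40, 90); b <- a + rnorm(6, 1, 3)
    res <- paired_mean_test(a, b)
    ref <- t.test(b, a, paired = TRUE)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_two_sided, ref$p.value, tolerance = 1e-10)
  }
})

test_that("paired comparison degenerate conventions", {
  sym <- paired_mean_test(c(0, 0), c(3, -3))
  expect_equal(sym$t, 0)
  expect_equal(sym$p_two_sided, 1)
  same <- paired_mean_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p_two_sided, 1)
  shift <- paired_mean_test(c(1, 2, 3), c(2, 3, 4))  # constant difference
  expect_equal(shift$p_two_sided, 0)
  expect_error(paired_mean_test(1:3, 1:4), "equal length")
  expect_error(paired_mean_test(1, 2), "at least 2")
})
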