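test_that("noiseless dose-response generator equals the Hill curve", {
  tab <- simulate_dose_response(e_max = 96, ec50 = 1, hill_coef = 2,
                                doses = c(0.5, 1, 5), noise_sd = 0)
  expect_equal(tab$efficiency_pct[2], 48)          # midpoint: e_max / 2
  expect_equal(tab$efficiency_pct[3], 96 * 25 / 26, tolerance = 1e-9)
  expect_equal(tab$efficiency_pct[3], 92.30769, tolerance = 1e-4)
  expect_error(simulate_dose_response(96, 1, doses = numeric()), "empty")
  expect_error(simulate_dose_response(120, 1), "\\[0, 100\\]")
  expect_error(simulate_dose_response(96, 0), "> 0")
})

test_that("noiseless flotation generator satisfies the first-order model", {
  ts <- simulate_flotation(e_inf = 92, k = 0.95, times = c(2, 4, 10))
  expect_equal(ts$efficiency_pct, 92 * (1 - exp(-0.95 * c(2, 4, 10))))
  expect_equal(ts$efficiency_pct[1], 78.22, tolerance = 0.01)
  expect_equal(simulate_flotation(0, 0.5, times = 1:3)$efficiency_pct,
               c(0, 0, 0))
  expect_equal(simulate_flotation(90, 1, times = 1000)$efficiency_pct, 90)
  expect_error(simulate_flotation(90, 0), "non-positive rate")
})

test_that("all generators are seed-deterministic", {
  expect_identical(simulate_dose_response(96, 1.5, noise_sd = 3, seed = 42),
                   simulate_dose_response(96, 1.5, noise_sd = 3, seed = 42))
  expect_identical(simulate_flotation(90, 0.9, noise_sd = 2, seed = 42),
                   simulate_flotation(90, 0.9, noise_sd = 2, seed = 42))
  expect_identical(simulate_community(seed = 42),
                   simulate_community(seed = 42))
  expect_identical(simulate_composition(cv = 0.05, seed = 42),
                   simulate_composition(cv = 0.05, seed = 42))
  # different seeds do change noisy output
  expect_false(identical(simulate_flotation(90, 0.9, noise_sd = 2, seed = 1),
                         simulate_flotation(90, 0.9, noise_sd = 2, seed = 2)))
})

test_that("noisy generator output stays on the percentage scale", {
  tab <- simulate_dose_response(99, 0.5, doses = seq(0.5, 9, by = 0.5),
                                noise_sd = 10, seed = 8)
  expect_true(all(tab$efficiency_pct >= 0 & tab$efficiency_pct <= 100))
})

test_that("Hill parameters are recovered from noiseless simulated curves", {
  # least-squares refit of the generating Hill model is the round trip
  for (pars in list(c(90, 1.5, 2), c(96, 1, 3), c(70, 3, 1.5))) {
    tab <- simulate_dose_response(pars[1], pars[2], pars[3],
                                  doses = seq(0.25, 10, by = 0.25))
    fit <- minpack.lm::nlsLM(
      efficiency_pct ~ e_max * dose_mg_per_L^h /
        (ec50^h + dose_mg_per_L^h),
      data = tab, start = list(e_max = 80, ec50 = 2, h = 2),
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15))
    expect_equal(unname(coef(fit)), pars, tolerance = 1e-6)
  }
})

test_that("community generator has the requested dominance structure", {
  com <- simulate_community(n_taxa = 10, dominance = 0.97, depth = 50000,
                            n_samples = 4, seed = 3)
  expect_equal(dim(com$counts), c(10, 4))
  expect_equal(unname(colSums(com$counts)), rep(50000, 4))
  expect_true(all(grepl("g__Genus", com$taxonomy)))
  # expected top-taxon share ~ dominance
  top_share <- mean(com$counts[1, ] / colSums(com$counts))
  expect_equal(top_share, 0.97, tolerance = 0.05)
  # uniform limit: E[H'] near ln(n)
  uni <- simulate_community(n_taxa = 10, dominance = 0.1, depth = 50000,
                            concentration = 1e4, seed = 4)
  expect_equal(mean(shannon_index(uni$counts)), log(10), tolerance = 0.05)
  expect_error(simulate_community(n_taxa = 1), "at least 2")
  expect_error(simulate_community(n_taxa = 10, dominance = 1.2), "dominance")
  expect_error(simulate_community(depth = 5), "depth")
})

test_that("reduced dominance raises mean Shannon diversity", {
  # mirrors the pre/post-harvest community shift: knocking down the
  # dominant bloom taxon increases diversity
  h <- function(dom, seed) {
    com <- simulate_community(n_taxa = 10, dominance = dom, depth = 50000,
                              n_samples = 1, seed = seed)
    shannon_index(com$counts[, 1])
  }
  h_dom <- vapply(1:20, function(s) h(0.97, s), numeric(1))
  h_even <- vapply(1:20, function(s) h(0.30, 1000 + s), numeric(1))
  expect_gt(mean(h_even), mean(h_dom))
})

test_that("composition generator reproduces the configured means", {
  exact <- simulate_composition(cv = 0)
  expect_equal(unique(exact$lipid), 0.1037)
  expect_equal(unique(exact$phosphate), 0.00902)
  expect_equal(unique(exact$protein), 0.32545)
  noisy <- simulate_composition(cv = 0.2, n_replicates = 200, seed = 2)
  expect_true(all(noisy >= 0 & noisy <= 1))
  expect_equal(mean(noisy$lipid), 0.1037, tolerance = 0.01)
})
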