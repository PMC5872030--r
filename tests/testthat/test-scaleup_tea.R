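wrp_items <- function() {
  data.frame(
    name = c("compressor", "rotameter", "oscillator", "tank", "pumps",
             "skimmer"),
    capex = c(200, 60, 100, 1420, 1000, 1000),
    opex_per_batch = c(0.83, 0, 0, 0, NA, NA),
    duty_min_per_batch = c(30, 30, 30, 0, 96, 30),
    power_kW = c(1.1, NA, NA, NA, 0.32, 16))
}

wrp_ledger <- function(volume_L = 7.5e6) {
  treatment_cost(wrp_items(), volume_L, 24000, tariff_per_kWh = 0.15,
                 flocculant = list(name = "chitosan", dose_mg_per_L = 5,
                                   unit_price_per_kg = 30))
}

test_that("air demand scales linearly from the laboratory basis", {
  expect_equal(air_demand(24000), 24)
  expect_equal(air_demand(1), 0.001)       # 1 mL/min for 1 L
  expect_equal(air_demand(0.5), 0.0005)
  expect_error(air_demand(0), "> 0")
})

test_that("compressor derating and the feasibility flag", {
  d <- derated_flow(201, demand_L_per_min = air_demand(24000))
  expect_equal(round(d$flow_L_per_min), 50)
  expect_true(d$feasible)
  expect_equal(derated_flow(201, fraction = 1)$flow_L_per_min, 201)
  # flag flips exactly at demand = derated flow
  expect_true(derated_flow(100, 0.25, demand_L_per_min = 25)$feasible)
  expect_false(derated_flow(100, 0.25, demand_L_per_min = 25.0001)$feasible)
  expect_error(derated_flow(201, fraction = 0), "\\(0, 1\\]")
})

test_that("batch cycle and implied pump rate", {
  expect_equal(batch_cycle(30, 48, 48), 126)
  expect_equal(batch_cycle(0, 0, 0), 0)
  expect_equal(24000 / 48, 500)  # fill rate implied by the 48-min fill
  expect_error(batch_cycle(-1, 0, 0), ">= 0")
})

test_that("energy and flocculant costs match the published per-batch figures", {
  expect_equal(energy_cost(0.32, 96, 0.15), 0.0768)
  expect_equal(round(energy_cost(0.32, 96, 0.15), 3), 0.077)
  expect_equal(energy_cost(16, 30, 0.15), 1.20)
  expect_equal(energy_cost(0, 100, 1), 0)

  fc <- flocculant_cost(5, 7.5e6, 30)
  expect_equal(fc$mass_kg, 37.5)
  expect_equal(fc$cost, 1125)
  expect_equal(flocculant_cost(0, 1e6, 30)$cost, 0)
  small <- flocculant_cost(1, 1000, 30)
  expect_equal(small$mass_kg, 0.001)   # 1 g
  expect_equal(small$cost, 0.03)
})

test_that("CAPEX totals expand composite items", {
  expect_equal(capex_total(list(tank = c(210, 210, 1000))), 1420)
  expect_equal(capex_total(c(200, 60, 100, 1420, 1000, 1000)), 3780)
  expect_equal(capex_total(list()), 0)
})

test_that("treatment ledger reproduces the whole-pond cost column", {
  led <- wrp_ledger()
  expect_equal(led$n_batches, 312.5)
  expect_equal(led$n_batches_scheduled, 313)
  full <- setNames(led$items$full_cost, led$items$name)
  expect_equal(unname(round(full["compressor"], 1)), 259.4)
  expect_equal(unname(full["pumps"]), 24)
  expect_equal(unname(full["skimmer"]), 375)
  expect_equal(unname(full["chitosan"]), 1125)
  expect_equal(led$total_opex, 259.375 + 24 + 375 + 1125)
  expect_lt(led$total_opex, 2000)
  expect_equal(led$total_capex, 3780)
})

test_that("ledger conserves totals and is linear in treated volume", {
  led1 <- wrp_ledger()
  expect_equal(led1$total_opex, sum(led1$items$full_cost), tolerance = 1e-9)
  led2 <- wrp_ledger(volume_L = 1.5e7)
  expect_equal(led2$items$full_cost, 2 * led1$items$full_cost,
               tolerance = 1e-9)
  led0 <- wrp_ledger(volume_L = 0)
  expect_equal(led0$total_opex, 0)
  # an item with neither OPEX nor power/duty is rejected by name
  bad <- wrp_items(); bad$power_kW[5] <- NA
  expect_error(treatment_cost(bad, 1e6, 24000), "pumps")
})

test_that("solar sizing brackets the design study", {
  expect_equal(solar_sizing(1.5)$n_panels, 6)
  expect_equal(solar_sizing(2.0)$n_panels, 8)
  expect_equal(solar_sizing(2.0)$array_area_m2, 12)
  expect_equal(solar_sizing(1.5, area_per_panel_m2 = 1.34)$array_area_m2,
               8.04)
  # derating requires more panels for the same load
  expect_gte(solar_sizing(1.5, derate = 0.8)$n_panels, 6)
  expect_error(solar_sizing(0), "> 0")
})
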