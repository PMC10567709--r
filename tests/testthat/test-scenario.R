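# small, fast scenario settings shared by the blocks below
quiet_world <- function(...) {
  world_config(years = 2000:2009, seed = 3, warming_rate = 0,
               cropland_trend = 0, co2_fertilization = 0,
               temp_noise_sd = 0, gpp_noise_sd = 0, ...)
}

test_that("a trend-free noise-free world yields identical annual records", {
  w <- quiet_world()
  cfg <- scenario_config(w, years = 2000:2003, n_members = 10,
                         ef_dataset = ef_dataset(3.5),
                         climatology_window = 2, seed = 5)
  sc <- run_scenario(cfg)
  s <- sc$series
  for (col in c("mean_tg", "ensemble_sd_tg", "potential_area_km2",
                "actual_area_km2", "biomass_tg")) {
    expect_equal(s[[col]], rep(s[[col]][1], nrow(s)), tolerance = 1e-12)
  }
  expect_gt(s$mean_tg[1], 0)
})

test_that("run_scenario is bit-reproducible from its seed", {
  w <- world_config(years = 2000:2004, seed = 9)
  cfg <- scenario_config(w, n_members = 30, climatology_window = 2, seed = 11)
  s1 <- run_scenario(cfg)$series
  s2 <- run_scenario(cfg)$series
  expect_identical(s1, s2)
})

test_that("variant switches reproduce the biomass-trend contrast", {
  # fertilization-inflating world with simultaneous cropland expansion
  w <- world_config(years = 2000:2020, seed = 7, warming_rate = 0,
                    cropland_trend = 0.05, co2_fertilization = 0.1,
                    temp_noise_sd = 0, gpp_noise_sd = 0)
  ef <- ef_dataset(3.81)
  base <- list(n_members = 2, ef_dataset = ef, climatology_window = 2,
               seed = 13)
  years <- c(2000, 2005, 2010, 2015, 2020)

  ctl <- run_scenario(do.call(scenario_config,
                              c(list(w, years = 2000:2020,
                                     variant = "control"), base)))
  lu <- run_scenario(do.call(scenario_config,
                             c(list(w, years = 2000:2020,
                                    variant = "landuse_density"), base)))
  b_ctl <- ctl$series$biomass_tg[ctl$series$year %in% years]
  b_lu <- lu$series$biomass_tg[lu$series$year %in% years]
  expect_true(all(diff(b_ctl) > 0))   # GPP-responsive biomass rises
  expect_true(all(diff(b_lu) < 0))    # land-use-only biomass falls

  # under a pure cropland trend the actual habitat shrinks too
  act <- lu$series$actual_area_km2
  expect_true(all(diff(act) <= 0))
  expect_lt(act[length(act)], act[1])
})

test_that("prescribed-EF variants have zero ensemble spread", {
  w <- quiet_world()
  cfg <- scenario_config(w, years = 2000:2001, variant = "sanderson_ef",
                         n_members = 8, climatology_window = 1, seed = 2)
  s <- run_scenario(cfg)$series
  expect_true(all(s$ensemble_sd_tg == 0))
})

test_that("decadal statistics and deltas are plain window arithmetic", {
  s <- data.frame(year = 2001:2003, mean_tg = c(5, 5, 5))
  expect_equal(unname(decadal_stats(s, 2001, 2003)[c("mean", "sd")]),
               c(5, 0))
  s2 <- data.frame(year = 2001:2003, mean_tg = c(1, 2, 3))
  expect_equal(unname(decadal_stats(s2, 2001, 2003)[c("mean", "sd")]),
               c(2, 1))
  expect_error(decadal_stats(s2, 1990, 1995), "outside series")
  expect_error(decadal_stats(s2, 2001, 2001), "at least 2")

  expect_equal(scenario_delta(s2, c(2001, 2002), c(2001, 2002)), 0)
  expect_equal(scenario_delta(s2, c(2001, 2002), c(2002, 2003)), 1)
})

test_that("stronger forcing gives a larger end-of-run emission delta", {
  years <- 2000:2019
  mild <- world_config(years = years, seed = 7, warming_rate = 0.1,
                       cropland_trend = 0, co2_fertilization = 0.01,
                       temp_noise_sd = 0, gpp_noise_sd = 0)
  strong <- world_config(years = years, seed = 7, warming_rate = 0.5,
                         cropland_trend = 0, co2_fertilization = 0.1,
                         temp_noise_sd = 0, gpp_noise_sd = 0)
  ef <- ef_dataset(3.81)
  run_one <- function(w) {
    run_scenario(scenario_config(w, n_members = 2, ef_dataset = ef,
                                 climatology_window = 2, seed = 3))
  }
  d_mild <- scenario_delta(run_one(mild), c(2000, 2004), c(2015, 2019))
  d_strong <- scenario_delta(run_one(strong), c(2000, 2004), c(2015, 2019))
  expect_gte(d_mild, 0)
  expect_gt(d_strong, d_mild)

  # the same contrast is wired into the shipped presets
  p_mit <- world_preset("mitigation-like")
  p_high <- world_preset("high-end-like")
  expect_gt(p_high$warming_rate, p_mit$warming_rate)
  expect_gt(p_high$co2_fertilization, p_mit$co2_fertilization)
})

test_that("a warming + fertilization world raises late-window decadal means", {
  w <- world_config(years = 2000:2019, seed = 15, warming_rate = 0.3,
                    cropland_trend = 0.01, co2_fertilization = 0.05)
  sc <- run_scenario(scenario_config(w, n_members = 25,
                                     climatology_window = 3, seed = 21))
  early <- decadal_stats(sc, 2000, 2009)
  late <- decadal_stats(sc, 2010, 2019)
  expect_gt(late[["mean"]], early[["mean"]])
})
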