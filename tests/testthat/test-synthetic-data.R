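test_that("configuration validation names the offending field", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(forest_plots_per_habitat = -1),
               "forest_plots_per_habitat")
  expect_error(sim_config(forest_effects = list(
    inaccessible = list(deadwood_rate = 1.5))), "deadwood_rate")
  expect_error(sim_config(landscape = list(azonal_fraction = 0.9)),
               "landscape fractions")
  expect_error(sim_config(species_pool = c(undescribed = -2, introduced = 1,
                                           native = 1)), "species_pool")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_config(seed = 31)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
  # and sensitive to the seed
  expect_false(identical(simulate_forest_inventory(cfg),
                         simulate_forest_inventory(small_config(seed = 32))))
})

test_that("forest inventory honours configured rates and thresholds", {
  cfg <- sim_config(seed = 5, forest_plots_per_habitat = 300)
  inv <- simulate_forest_inventory(cfg)
  expect_true(all(inv$dbh_cm > 10 / pi))
  expect_true(all(inv$height_m > 0))
  # observed deadwood proportions near the configured Bernoulli rates
  obs <- tapply(inv$status == "dead", inv$habitat, mean)
  expect_lt(abs(obs[["inaccessible"]] - 0.30), 0.03)
  expect_lt(abs(obs[["accessible"]] - 0.05), 0.03)
  # configured habitat contrasts: denser stands of larger trees
  dbh <- tapply(inv$dbh_cm, inv$habitat, mean)
  expect_gt(dbh[["inaccessible"]], dbh[["accessible"]])
  stems <- table(inv$habitat) / 300
  expect_gt(stems[["inaccessible"]], stems[["accessible"]])
  # zero plots: empty inventory, no error
  empty <- simulate_forest_inventory(sim_config(forest_plots_per_habitat = 0))
  expect_equal(nrow(empty), 0)
})

test_that("soil profiles follow the depth-increment scheme", {
  inc <- punacarbon:::depth_increments(15)
  expect_equal(unname(inc[, "top"]), c(0, 5, 10))
  expect_equal(unname(inc[, "bottom"]), c(5, 10, 15))
  expect_equal(nrow(punacarbon:::depth_increments(55)), 6)
  cfg <- small_config(seed = 12)
  soil <- simulate_soil_profiles(cfg)
  for (pid in unique(soil$layers$profile_id)) {
    ly <- soil$layers[soil$layers$profile_id == pid, ]
    expect_equal(ly$top_cm, c(0, ly$bottom_cm[-nrow(ly)]))  # contiguous
    depth <- soil$profiles$total_depth[soil$profiles$profile_id == pid]
    expect_equal(max(ly$bottom_cm), depth)
    expect_true(depth >= 15 && depth <= 90)
    # interior boundaries come from the field increment scheme
    expect_true(all(ly$bottom_cm[-nrow(ly)] %in% c(5, 10, 20, 30, 40)))
  }
})

test_that("soil ground truth matches the package's own accounting", {
  cfg <- small_config(seed = 13)
  soil <- simulate_soil_profiles(cfg)
  st <- soil_profile_stocks(soil$layers)
  j <- dplyr::inner_join(st, soil$profiles, by = "profile_id")
  expect_equal(j$fine_earth_mass, j$true_fine_earth_mass, tolerance = 1e-9)
  expect_equal(j$soc_stock, j$true_soc_stock, tolerance = 1e-9)
  expect_equal(j$root_biomass, j$true_root_biomass, tolerance = 1e-9)
  expect_equal(j$base_saturation, j$true_base_saturation, tolerance = 1e-9)
  expect_equal(j$classification, j$true_class)
})

test_that("grassland soils are more acidic but hold more SOC per area", {
  cfg <- sim_config(seed = 14, soil_profiles_per_habitat = 50)
  soil <- simulate_soil_profiles(cfg)
  bs <- tapply(soil$profiles$true_base_saturation, soil$profiles$vegetation, mean)
  expect_lt(bs[["grassland"]], bs[["forest"]])
  soc <- tapply(soil$profiles$true_soc_stock, soil$profiles$vegetation, mean)
  expect_gt(soc[["grassland"]], soc[["forest"]])
})

test_that("community generator places species groups by accessibility", {
  cfg <- sim_config(seed = 15, community_plots_per_habitat = 60)
  sim <- simulate_community(cfg)
  expect_true(all(sim$comm >= 0 & sim$comm <= 100))
  m <- plot_metrics(sim$comm, sim$species)
  acc <- grepl("^accessible", sim$plots$habitat_type)
  expect_gt(mean(m$undescribed_cover[!acc]), mean(m$undescribed_cover[acc]))
  expect_gt(mean(m$introduced_cover[acc]), mean(m$introduced_cover[!acc]))
  expect_lt(mean(m$richness[!acc]), mean(m$richness[acc]))
  # natives outside, introduced inside the latitudinal-amplitude contrast
  expect_gt(mean(m$native_lat_amplitude[acc], na.rm = TRUE),
            mean(m$native_lat_amplitude[!acc], na.rm = TRUE))

  # zero introduced species: introduced cover is zero in every plot
  cfg0 <- small_config(seed = 16)
  cfg0$species_pool["introduced"] <- 0
  sim0 <- simulate_community(sim_config(
    seed = 16, community_plots_per_habitat = 10,
    species_pool = c(undescribed = 10, introduced = 0, native = 20)))
  m0 <- plot_metrics(sim0$comm, sim0$species)
  expect_true(all(m0$introduced_cover == 0))

  # a species occurring in every plot of exactly one habitat scores 100
  cfgx <- sim_config(
    seed = 17, community_plots_per_habitat = 8,
    species_pool = c(undescribed = 3, introduced = 2, native = 10),
    community_effects = list(occurrence = rbind(
      undescribed = c(inaccessible_forest = 1, inaccessible_grassland = 0,
                      accessible_forest = 0, accessible_grassland = 0),
      introduced = c(0.1, 0.1, 0.5, 0.5),
      native = c(0.3, 0.3, 0.3, 0.3))))
  simx <- simulate_community(cfgx)
  resx <- suppressWarnings(
    indval(simx$comm, simx$plots$habitat_type, n_perm = 49, seed = 1))
  und <- grep("^sp_und", resx$species)
  expect_true(all(resx$indval[und] == 100))
  expect_true(all(resx$best_group[und] == "inaccessible_forest"))
})

test_that("simulated datasets round-trip through plain-text files", {
  cfg <- small_config(seed = 18)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[["soil"]])
  expect_equal(nrow(back), nrow(sim$soil$layers))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$seed, 18)
  expect_equal(nrow(truth$profiles), nrow(sim$soil$profiles))
})
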