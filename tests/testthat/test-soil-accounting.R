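test_that("layer bulk densities and masses evaluate directly", {
  expect_equal(weathered_bulk_density(800, 200, 1000), 1.0)
  expect_equal(weathered_bulk_density(1000, 0, 1000), 1.0)
  expect_equal(weathered_bulk_density(800, 200, 600), 1000 / 600)
  expect_error(weathered_bulk_density(800, 200, 0), "positive")

  expect_equal(layer_weathered_mass(1.0, 100), 100)
  expect_equal(layer_weathered_mass(1.5, 50), 75)
  expect_identical(layer_weathered_mass(1.2, 0), 0)
  expect_error(layer_weathered_mass(1, -5), "non-negative")

  expect_equal(fine_earth_bulk_density(800, 200, 600),
               800 / (600 - 200 / 2.65))
  # rock-free layer: fine-earth density equals weathered density
  expect_equal(fine_earth_bulk_density(700, 0, 1000),
               weathered_bulk_density(700, 0, 1000))
  expect_error(fine_earth_bulk_density(10, 2.65 * 600, 600), "rock volume")
})

test_that("profile fine-earth mass: printed and algebraic forms agree", {
  # single layer with M_w = 100 kg m-2 and 20% rock by mass -> 80 kg m-2
  ly <- make_layers(0, 10, volume = 1000, fine_earth = 800, rock = 200)
  expect_equal(profile_fine_earth_mass(ly, form = "printed"), 80)
  expect_equal(profile_fine_earth_mass(ly, form = "fraction"), 80)
  # rock-free profile: fine-earth mass equals total weathered mass
  rf <- make_layers(c(0, 5), c(5, 10), fine_earth = 900, rock = 0)
  m_w <- sum(900 / 1000 * 50)  # per layer: rho_w * h_mm
  expect_equal(profile_fine_earth_mass(rf), 2 * 900 / 1000 * 50)
  # additivity: two identical layers double the single-layer value
  two <- make_layers(c(0, 10), c(10, 20))
  expect_equal(profile_fine_earth_mass(two), 2 * profile_fine_earth_mass(ly) * 1)
  # property: forms agree to 1e-9 relative on random layers
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:6, 1)
    b <- cumsum(runif(n, 3, 20))
    lyr <- make_layers(c(0, b[-n]), b,
                       volume = runif(n, 500, 1500),
                       fine_earth = runif(n, 200, 1200),
                       rock = runif(n, 1, 600))
    expect_equal(profile_fine_earth_mass(lyr, "printed"),
                 profile_fine_earth_mass(lyr, "fraction"), tolerance = 1e-9)
  }
  # all-rock layer contributes zero under the fraction form
  ar <- make_layers(c(0, 10), c(10, 20), fine_earth = c(800, 0),
                    rock = c(200, 500))
  expect_message(m <- profile_fine_earth_mass(ar), "no fine earth")
  expect_equal(m, 80)
})

test_that("carbon, nitrogen, and root stocks accumulate over layers", {
  ly <- make_layers(0, 10, carbon = 5)  # 80 kg m-2 fine earth
  expect_equal(profile_carbon_stock(ly)$soc_stock, 4.0)
  expect_equal(profile_carbon_stock(make_layers(0, 10, carbon = 0))$soc_stock, 0)
  ly_na <- make_layers(0, 10); ly_na$carbon_pct <- NA
  expect_error(profile_carbon_stock(ly_na), "missing carbon")

  # brute-force per-layer oracle
  set.seed(3)
  n <- 5
  b <- cumsum(runif(n, 4, 15))
  lyr <- make_layers(c(0, b[-n]), b, volume = runif(n, 600, 1400),
                     fine_earth = runif(n, 300, 1100),
                     rock = runif(n, 0, 400), carbon = runif(n, 0.5, 8))
  acc <- 0
  for (i in seq_len(n)) {
    h_mm <- (lyr$bottom_cm[i] - lyr$top_cm[i]) * 10
    m_w <- (lyr$fine_earth_g[i] + lyr$rock_g[i]) / lyr$volume_cm3[i] * h_mm
    m_fe <- m_w * lyr$fine_earth_g[i] / (lyr$fine_earth_g[i] + lyr$rock_g[i])
    acc <- acc + lyr$carbon_pct[i] / 100 * m_fe
  }
  expect_equal(profile_carbon_stock(lyr)$soc_stock, acc, tolerance = 1e-12)

  # roots: 0.2 g in a 20 g subsample over 80 kg m-2 fine earth
  ly_root <- make_layers(0, 10, root_sub_root = 0.2)
  rs <- root_stock(ly_root)
  expect_equal(rs$root_biomass, 0.2 / 20 * 80)
  expect_equal(rs$root_carbon, 0.5 * rs$root_biomass)
  expect_equal(root_stock(make_layers(0, 10, root_sub_root = 0))$root_biomass, 0)
  expect_equal(root_stock(ly_root, carbon_fraction = 0.45)$root_carbon,
               0.45 * 0.8)
  expect_error(root_stock(make_layers(0, 10, root_sub_soil = 0)), "positive")
})

test_that("base saturation arithmetic and degenerate cases", {
  expect_equal(base_saturation(4, 2, 1, 1), 100)          # no acidity
  expect_equal(base_saturation(2, 1, 0.5, 0.5, al = 4), 50)  # bases = acidity
  expect_equal(base_saturation(4, 2, 1, 1, al = 2), 80)
  expect_warning(bs0 <- base_saturation(0, 0, 0, 0), "undefined")
  expect_true(is.na(bs0))
  expect_error(base_saturation(-1, 0, 0, 0), "non-negative")
})

test_that("stocks are invariant to re-slicing a homogeneous layer", {
  whole <- make_layers(0, 20, volume = 1000, fine_earth = 800, rock = 200,
                       carbon = 3, root_sub_root = 0.15)
  split <- make_layers(c(0, 10), c(10, 20), volume = 500, fine_earth = 400,
                       rock = 100, carbon = 3, root_sub_root = 0.15)
  expect_equal(profile_fine_earth_mass(whole), profile_fine_earth_mass(split))
  expect_equal(profile_carbon_stock(whole)$soc_stock,
               profile_carbon_stock(split)$soc_stock)
  expect_equal(root_stock(whole)$root_biomass, root_stock(split)$root_biomass)
})

test_that("profile classification follows the diagnostic rules", {
  # shallow, dark, base-rich, carbon-rich profile -> Mollic Leptosol
  expect_equal(classify_profile(make_layers(c(0, 5, 10), c(5, 10, 15),
                                            carbon = 5, bs = 60)),
               "Mollic Leptosol")
  # shallow but acidic -> plain Leptosol
  expect_equal(classify_profile(make_layers(0, 15, carbon = 5, bs = 30)),
               "Leptosol")
  # deep profiles split on base saturation
  deep <- function(bs) make_layers(c(0, 5, 10, 20, 30, 40),
                                   c(5, 10, 20, 30, 40, 50),
                                   carbon = 2, bs = bs)
  expect_equal(classify_profile(deep(70)), "Phaeozem")
  expect_equal(classify_profile(deep(30)), "Umbrisol")
  # very stony profile takes the Leptosol branch regardless of depth
  stony <- make_layers(c(0, 15), c(15, 30), volume = 1000,
                       fine_earth = 100, rock = 0.85 * 1000 * 2.65,
                       carbon = 2, bs = 30)
  expect_equal(classify_profile(stony), "Leptosol")
  # missing diagnostic inputs -> undetermined with a reason
  incomplete <- make_layers(0, 50)
  incomplete$munsell_value <- NA
  cls <- classify_profile(incomplete)
  expect_equal(as.character(cls), "undetermined")
  expect_match(attr(cls, "reason"), "missing")
})

test_that("profile-level wrapper agrees with scalar operations per profile", {
  set.seed(9)
  cfg <- small_config(seed = 4)
  layers <- simulate_soil_profiles(cfg)$layers
  st <- soil_profile_stocks(layers)
  expect_equal(nrow(st), dplyr::n_distinct(layers$profile_id))
  pid <- st$profile_id[5]
  one <- layers[layers$profile_id == pid, ]
  row <- st[st$profile_id == pid, ]
  expect_equal(row$fine_earth_mass, profile_fine_earth_mass(one))
  expect_equal(row$soc_stock, profile_carbon_stock(one)$soc_stock)
  expect_equal(row$root_carbon, root_stock(one)$root_carbon)
  expect_equal(row$classification, as.character(classify_profile(one)))
  expect_true(all(st$base_saturation >= 0 & st$base_saturation <= 100))
})

test_that("layer table invariants are enforced", {
  bad <- make_layers(c(0, 8), c(10, 20))  # overlapping layers
  expect_error(profile_fine_earth_mass(bad), "overlap")
  expect_error(profile_fine_earth_mass(make_layers(5, 5)), "bottom_cm")
  neg <- make_layers(0, 10); neg$rock_g <- -1
  expect_error(profile_fine_earth_mass(neg), "non-negative")
})
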