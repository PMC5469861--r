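# Synthetic field-data generator.
#
# Emulates the four input tables of the accounting pipeline — tree
# inventories, soil-profile layer samples, plot x species cover matrices
# with species attributes, and landscape area fractions — with the habitat
# contrasts observed between human-accessible and inaccessible high-Andean
# terrain: denser stands of larger trees and more standing deadwood in
# inaccessible forest; grassland soils more acidic (lower base saturation)
# but holding somewhat more SOC per area than forest soils; undescribed
# species concentrated in inaccessible plots and introduced species in
# accessible plots. Ground truth (per-profile stocks and classes) is stored
# alongside the generated tables for parameter-recovery tests.
#
# Distributions: lognormal for sizes and covers, truncated normal for soil
# depth, Bernoulli/binomial for flags and traits (positive-support,
# right-skewed field data). One top-level seed; per-table sub-seeds are
# derived deterministically from it.

# Deterministic per-table sub-seed, kept well below 2^31.
sub_seed <- function(seed, k) {
  (as.integer(seed) %% 190000L) * 10000L + as.integer(k)
}

default_forest_effects <- function() list(
  inaccessible = list(stem_lambda = 70, dbh_meanlog = log(40), dbh_sdlog = 0.40,
                      height_a = 0.33, height_b = 0.5, height_sdlog = 0.12,
                      deadwood_rate = 0.30),
  accessible   = list(stem_lambda = 45, dbh_meanlog = log(30), dbh_sdlog = 0.40,
                      height_a = 0.28, height_b = 0.5, height_sdlog = 0.12,
                      deadwood_rate = 0.05)
)

default_soil_effects <- function() list(
  depth_mean = 55, depth_sd = 18, depth_min = 15, depth_max = 90,
  rock_beta = c(2, 14),                  # layer rock volume fraction ~ Beta
  fe_density_mean = 0.85, fe_density_sd = 0.10,
  carbon_surface = c(forest = 4.0, grassland = 4.4),   # % at 0 cm
  carbon_surface_sd = 0.5, carbon_decay = 0.018,        # per cm depth
  cn_ratio = 12,
  base_saturation_mean = c(forest = 66, grassland = 34),
  base_saturation_sd = 8, layer_bs_sd = 2,
  ecec_meanlog = log(15), ecec_sdlog = 0.3,
  root_density_surface = c(inaccessible_forest = 0.0165,
                           accessible_forest = 0.0150,
                           inaccessible_grassland = 0.0045,
                           accessible_grassland = 0.0045),  # g root / g soil
  root_density_sdlog = 0.35, root_decay = 0.03,
  subsample_soil_g = 20
)

default_community_effects <- function() list(
  # occurrence probability per species group x habitat type
  occurrence = rbind(
    undescribed = c(inaccessible_forest = 0.35, inaccessible_grassland = 0.25,
                    accessible_forest = 0.03, accessible_grassland = 0.02),
    introduced  = c(0.005, 0.005, 0.25, 0.25),
    native      = c(0.10, 0.12, 0.35, 0.40)
  ),
  # cover meanlog (log %) per species group x habitat type
  cover_meanlog = rbind(
    undescribed = log(c(inaccessible_forest = 12, inaccessible_grassland = 10,
                        accessible_forest = 3, accessible_grassland = 3)),
    introduced  = log(c(2, 2, 6, 6)),
    native      = log(c(4, 4, 6, 6))
  ),
  cover_sdlog = 0.9,
  herb_height_cm = c(inaccessible_forest = 25, inaccessible_grassland = 20,
                     accessible_forest = 8, accessible_grassland = 6),
  grazed_mean_pct = c(inaccessible_forest = 8, inaccessible_grassland = 12,
                      accessible_forest = 55, accessible_grassland = 65),
  # trait archetypes: probability of carrying each disturbance-syndrome
  # trait (first half) vs the opposing syndrome (second half)
  archetype_p = c(adapted = 0.85, unadapted = 0.15),
  lat_range_meanlog = c(undescribed = log(120), introduced = log(2500),
                        native = log(1500)),
  lat_range_sdlog = c(undescribed = 0.6, introduced = 0.4, native = 0.5),
  n_traits = 32, n_ordinal = 8
)

default_landscape <- function() list(
  total_area_m2 = 132.66e6,
  zonal_inaccessible_fraction = 0.011,
  zonal_accessible_fraction = 0.569,
  azonal_fraction = 0.420,
  forest_fraction_inaccessible = 0.70,
  forest_fraction_accessible = 0.075
)

#' Simulation configuration
#'
#' Bundles and validates all generator settings. Defaults reproduce the
#' study conditions: 24 forest inventory plots per accessibility class
#' (10 x 10 m), 10 soil profiles per habitat type, 118 community plots
#' (2 x 2 m) per habitat type, a zonal-inaccessible / zonal-accessible /
#' azonal landscape split of 1.1% / 56.9% / 42.0%, and forest-cover
#' fractions of 70% (inaccessible) and 7.5% (accessible). Effect settings
#' are nested lists; supplied values are merged over the defaults, so a
#' partial override such as
#' `forest_effects = list(inaccessible = list(deadwood_rate = 0.4))` works.
#'
#' @param seed Integer seed; identical seeds yield identical output.
#' @param forest_plots_per_habitat Forest inventory plots per accessibility
#'   class.
#' @param soil_profiles_per_habitat Soil profiles per habitat type (4 types).
#' @param community_plots_per_habitat Community plots per habitat type.
#' @param species_pool Named counts of `undescribed`, `introduced`, and
#'   widespread `native` species.
#' @param forest_effects,soil_effects,community_effects,landscape Partial
#'   overrides of the generator settings (see the package vignette for the
#'   meaning and units of every field).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       forest_plots_per_habitat = 24,
                       soil_profiles_per_habitat = 10,
                       community_plots_per_habitat = 118,
                       species_pool = c(undescribed = 40, introduced = 25,
                                        native = 155),
                       forest_effects = list(),
                       soil_effects = list(),
                       community_effects = list(),
                       landscape = list()) {
  config <- list(
    seed = as.integer(seed),
    forest_plots_per_habitat = forest_plots_per_habitat,
    soil_profiles_per_habitat = soil_profiles_per_habitat,
    community_plots_per_habitat = community_plots_per_habitat,
    species_pool = species_pool,
    forest_effects = utils::modifyList(default_forest_effects(), forest_effects),
    soil_effects = utils::modifyList(default_soil_effects(), soil_effects),
    community_effects = utils::modifyList(default_community_effects(),
                                          community_effects),
    landscape = utils::modifyList(default_landscape(), landscape)
  )
  validate_sim_config(config)
  structure(config, class = "sim_config")
}

validate_sim_config <- function(config) {
  err <- function(field) {
    stop("invalid configuration field `", field, "`", call. = FALSE)
  }
  if (is.na(config$seed)) err("seed")
  for (f in c("forest_plots_per_habitat", "soil_profiles_per_habitat",
              "community_plots_per_habitat")) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v != round(v)) err(f)
  }
  if (any(config$species_pool < 0)) err("species_pool")
  for (hab in c("inaccessible", "accessible")) {
    fe <- config$forest_effects[[hab]]
    if (fe$deadwood_rate < 0 || fe$deadwood_rate > 1) {
      err(paste0("forest_effects$", hab, "$deadwood_rate"))
    }
    if (fe$stem_lambda < 0) err(paste0("forest_effects$", hab, "$stem_lambda"))
  }
  ls <- config$landscape
  fr <- c(ls$zonal_inaccessible_fraction, ls$zonal_accessible_fraction,
          ls$azonal_fraction)
  if (any(fr < 0 | fr > 1) || abs(sum(fr) - 1) > 1e-9) err("landscape fractions")
  ff <- c(ls$forest_fraction_inaccessible, ls$forest_fraction_accessible)
  if (any(ff < 0 | ff > 1)) err("landscape forest fractions")
  occ <- config$community_effects$occurrence
  if (any(occ < 0 | occ > 1)) err("community_effects$occurrence")
  invisible(config)
}

#' Simulate a forest inventory
#'
#' One row per stem >= 10 cm circumference in 10 x 10 m plots of
#' inaccessible and accessible forest. Stem counts are Poisson, dbh
#' lognormal with a habitat-specific location, height is a noisy power law
#' of dbh, and standing deadwood is a Bernoulli flag with habitat-specific
#' rate. Inaccessible plots are stochastically denser, with larger trees
#' and more deadwood.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `plot_id`, `habitat`, `habitat_type`,
#'   `species`, `status`, `dbh_cm`, `height_m`.
#' @export
simulate_forest_inventory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 1L))
  n_plots <- config$forest_plots_per_habitat
  rows <- list()
  for (hab in c("inaccessible", "accessible")) {
    fx <- config$forest_effects[[hab]]
    for (p in seq_len(n_plots)) {
      n_stems <- stats::rpois(1, fx$stem_lambda)
      plot_id <- sprintf("%s_forest_p%02d", substr(hab, 1, 3), p)
      if (n_stems == 0) next
      dbh <- stats::rlnorm(n_stems, fx$dbh_meanlog, fx$dbh_sdlog)
      # enforce the inventory threshold (circumference > 10 cm)
      while (any(dbh <= DBH_MIN_CM)) {
        i <- dbh <= DBH_MIN_CM
        dbh[i] <- stats::rlnorm(sum(i), fx$dbh_meanlog, fx$dbh_sdlog)
      }
      height <- exp(fx$height_a + fx$height_b * log(dbh) +
                      stats::rnorm(n_stems, 0, fx$height_sdlog))
      dead <- stats::rbinom(n_stems, 1, fx$deadwood_rate) == 1
      rows[[length(rows) + 1]] <- tibble::tibble(
        plot_id = plot_id,
        habitat = hab,
        habitat_type = paste0(hab, "_forest"),
        species = sample(paste0("Polylepis_sp", 1:3), n_stems, replace = TRUE),
        status = ifelse(dead, "dead", "live"),
        dbh_cm = dbh,
        height_m = height
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(plot_id = character(), habitat = character(),
                          habitat_type = character(), species = character(),
                          status = character(), dbh_cm = double(),
                          height_m = double()))
  }
  dplyr::bind_rows(rows)
}

# Depth increment boundaries for a profile of the given total depth:
# 0-5, 5-10, 10-20, 20-30, 30-40, then >40 cm down to continuous rock.
depth_increments <- function(total_depth) {
  bounds <- c(0, 5, 10, 20, 30, 40)
  tops <- bounds[bounds < total_depth]
  bottoms <- c(tops[-1], total_depth)
  bottoms <- pmin(bottoms, total_depth)
  cbind(top = tops, bottom = bottoms)
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (lo >= hi) return(lo)
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Simulate soil profiles with ground truth
#'
#' Generates layered volumetric soil samples for the four habitat types,
#' following the field depth increments (0-5, 5-10, 10-20, 20-30, 30-40,
#' >40 cm) down to continuous rock at a truncated-normal depth between 15
#' and 90 cm. Grassland profiles carry a lower base saturation and a higher
#' surface carbon concentration (hence more SOC per area) than forest
#' profiles. Ground-truth per-profile stocks and the class implied by the
#' generating fields are recomputed inline by direct summation and returned
#' alongside the layer table for recovery tests.
#'
#' @param config A [sim_config()].
#' @return List with `layers` (one row per layer sample) and `profiles`
#'   (ground truth: `true_fine_earth_mass`, `true_soc_stock`,
#'   `true_root_biomass`, `true_base_saturation`, `true_rock_volume_fraction`,
#'   `true_class`, plus depth and habitat labels).
#' @export
simulate_soil_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 2L))
  sx <- config$soil_effects
  n <- config$soil_profiles_per_habitat
  layer_rows <- list()
  prof_rows <- list()
  for (hab in c("inaccessible", "accessible")) {
    for (veg in c("forest", "grassland")) {
      htype <- paste0(hab, "_", veg)
      for (p in seq_len(n)) {
        profile_id <- sprintf("%s_%s_s%02d", substr(hab, 1, 3),
                              substr(veg, 1, 4), p)
        depth <- rtruncnorm1(sx$depth_mean, sx$depth_sd,
                             sx$depth_min, sx$depth_max)
        inc <- depth_increments(depth)
        nl <- nrow(inc)
        mid <- (inc[, "top"] + inc[, "bottom"]) / 2
        volume <- stats::runif(nl, 900, 1100)
        rock_vol_frac <- stats::rbeta(nl, sx$rock_beta[1], sx$rock_beta[2])
        rho_fe <- pmax(stats::rnorm(nl, sx$fe_density_mean, sx$fe_density_sd), 0.4)
        rock_g <- rock_vol_frac * volume * 2.65
        fine_earth_g <- rho_fe * (volume - rock_vol_frac * volume)
        c_surface <- max(stats::rnorm(1, sx$carbon_surface[[veg]],
                                      sx$carbon_surface_sd), 0.8)
        carbon_pct <- c_surface * exp(-sx$carbon_decay * mid)
        nitrogen_pct <- carbon_pct / sx$cn_ratio
        bs_prof <- min(max(stats::rnorm(1, sx$base_saturation_mean[[veg]],
                                        sx$base_saturation_sd), 2), 98)
        bs_layer <- pmin(pmax(bs_prof + stats::rnorm(nl, 0, sx$layer_bs_sd), 1), 99)
        ecec <- stats::rlnorm(nl, sx$ecec_meanlog, sx$ecec_sdlog)
        bases <- ecec * bs_layer / 100
        acidity <- ecec - bases
        d0 <- stats::rlnorm(1, log(sx$root_density_surface[[htype]]),
                            sx$root_density_sdlog)
        root_density <- d0 * exp(-sx$root_decay * mid)
        layers <- tibble::tibble(
          profile_id = profile_id, habitat = hab, vegetation = veg,
          habitat_type = htype, layer_index = seq_len(nl),
          top_cm = inc[, "top"], bottom_cm = inc[, "bottom"],
          volume_cm3 = volume, fine_earth_g = fine_earth_g, rock_g = rock_g,
          carbon_pct = carbon_pct, nitrogen_pct = nitrogen_pct,
          ph_cacl2 = round(stats::rnorm(nl, if (veg == "forest") 4.8 else 4.3, 0.3), 2),
          ca = bases * 0.60, mg = bases * 0.25, k = bases * 0.10,
          na = bases * 0.05, al = acidity * 0.60, fe = acidity * 0.10,
          mn = acidity * 0.05, h = acidity * 0.25,
          munsell_value = sample(2:3, nl, replace = TRUE),
          munsell_chroma = sample(2:3, nl, replace = TRUE),
          root_subsample_soil_g = sx$subsample_soil_g,
          root_subsample_root_g = root_density * sx$subsample_soil_g
        )
        # ground truth by direct summation over layers
        h_mm <- (layers$bottom_cm - layers$top_cm) * 10
        m_w <- (fine_earth_g + rock_g) / volume * h_mm
        fe_frac <- fine_earth_g / (fine_earth_g + rock_g)
        m_fe_layer <- m_w * fe_frac
        true_m_fe <- sum(m_fe_layer)
        true_soc <- sum(carbon_pct / 100 * m_fe_layer)
        true_root <- sum(root_density * m_fe_layer)
        bs_true <- {
          b <- layers$ca + layers$mg + layers$k + layers$na
          e <- b + layers$al + layers$fe + layers$mn + layers$h
          sum(100 * b / e * m_fe_layer) / sum(m_fe_layer)
        }
        rockvol_true <- sum((rock_g / 2.65) / volume *
                              (layers$bottom_cm - layers$top_cm)) /
          sum(layers$bottom_cm - layers$top_cm)
        soc_w <- sum(carbon_pct * m_fe_layer) / sum(m_fe_layer)
        mollic <- soc_w >= 0.6 && all(layers$munsell_value <= 3) &&
          all(layers$munsell_chroma <= 3) && bs_true >= 50 && depth >= 10
        true_class <- if (depth <= 25 || rockvol_true >= 0.80) {
          if (mollic) "Mollic Leptosol" else "Leptosol"
        } else if (bs_true >= 50) "Phaeozem" else "Umbrisol"
        layer_rows[[length(layer_rows) + 1]] <- layers
        prof_rows[[length(prof_rows) + 1]] <- tibble::tibble(
          profile_id = profile_id, habitat = hab, vegetation = veg,
          habitat_type = htype, total_depth = depth,
          true_fine_earth_mass = true_m_fe, true_soc_stock = true_soc,
          true_root_biomass = true_root, true_base_saturation = bs_true,
          true_rock_volume_fraction = rockvol_true, true_class = true_class
        )
      }
    }
  }
  if (length(layer_rows) == 0) {
    return(list(layers = tibble::tibble(), profiles = tibble::tibble()))
  }
  list(layers = dplyr::bind_rows(layer_rows),
       profiles = dplyr::bind_rows(prof_rows))
}

#' Simulate a community table with species attributes
#'
#' Generates a plots x species percent-cover matrix across the four habitat
#' types, with undescribed species concentrated (and dominant) in
#' inaccessible plots, introduced species in accessible plots, and
#' widespread natives most frequent on accessible terrain. The species
#' attribute table carries status, origin, latitudinal range (minutes) and
#' 32 binary/ordinal disturbance-syndrome traits drawn from two archetypes
#' (grazing/burning-adapted versus not).
#'
#' @param config A [sim_config()].
#' @return List with `comm` (plots x species matrix, percent cover),
#'   `plots` (plot covariates: `habitat_type`, `herb_height_cm`,
#'   `grazed_pct`), and `species` (attribute tibble).
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 3L))
  cx <- config$community_effects
  pool <- config$species_pool
  groups <- rep(c("undescribed", "introduced", "native"), times = pool)
  n_sp <- length(groups)
  species <- sprintf("sp_%s_%03d", substr(groups, 1, 3), seq_len(n_sp))

  # attributes
  n_tr <- cx$n_traits
  half <- n_tr / 2
  archetype <- ifelse(
    groups == "undescribed",
    ifelse(stats::runif(n_sp) < 0.9, "unadapted", "adapted"),
    ifelse(stats::runif(n_sp) < 0.8, "adapted", "unadapted")
  )
  p_hi <- cx$archetype_p[["adapted"]]
  p_lo <- cx$archetype_p[["unadapted"]]
  traits <- matrix(0L, n_sp, n_tr,
                   dimnames = list(species, sprintf("trait_%02d", seq_len(n_tr))))
  for (i in seq_len(n_sp)) {
    p <- if (archetype[i] == "adapted") c(rep(p_hi, half), rep(p_lo, half)) else
      c(rep(p_lo, half), rep(p_hi, half))
    n_bin <- n_tr - cx$n_ordinal
    traits[i, seq_len(n_bin)] <- stats::rbinom(n_bin, 1, p[seq_len(n_bin)])
    traits[i, (n_bin + 1):n_tr] <- stats::rbinom(cx$n_ordinal, 3,
                                                 p[(n_bin + 1):n_tr])
  }
  lat_range <- stats::rlnorm(n_sp, cx$lat_range_meanlog[groups],
                             cx$lat_range_sdlog[groups])
  attributes <- tibble::tibble(
    species = species,
    status = ifelse(groups == "undescribed", "undescribed", "described"),
    origin = ifelse(groups == "introduced", "introduced", "native"),
    archetype = archetype,
    lat_range_min = lat_range
  )
  attributes <- dplyr::bind_cols(attributes, tibble::as_tibble(traits))

  # plots and covers
  n_pl <- config$community_plots_per_habitat
  habs <- rep(HABITAT_TYPES, each = n_pl)
  plot_id <- sprintf("%s_v%03d", habs, rep(seq_len(n_pl), times = length(HABITAT_TYPES)))
  comm <- matrix(0, length(habs), n_sp, dimnames = list(plot_id, species))
  for (r in seq_along(habs)) {
    ht <- habs[r]
    occ_p <- cx$occurrence[groups, ht]
    present <- stats::runif(n_sp) < occ_p
    if (any(present)) {
      ml <- cx$cover_meanlog[cbind(groups[present], ht)]
      comm[r, present] <- pmin(stats::rlnorm(sum(present), ml, cx$cover_sdlog), 100)
    }
  }
  plots <- tibble::tibble(
    plot_id = plot_id,
    habitat_type = habs,
    herb_height_cm = stats::rlnorm(length(habs),
                                   log(cx$herb_height_cm[habs]), 0.3),
    grazed_pct = pmin(pmax(stats::rnorm(length(habs),
                                        cx$grazed_mean_pct[habs], 10), 0), 100)
  )
  list(comm = comm, plots = plots, species = attributes)
}

#' Landscape areas implied by the configuration
#'
#' @param config A [sim_config()].
#' @return A [landscape_areas()] object.
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ls <- config$landscape
  landscape_areas(ls$total_area_m2,
                  ls$zonal_inaccessible_fraction,
                  ls$zonal_accessible_fraction,
                  ls$azonal_fraction,
                  ls$forest_fraction_inaccessible,
                  ls$forest_fraction_accessible)
}

#' Simulate the full input dataset
#'
#' @param config A [sim_config()].
#' @return List with `forest`, `soil` (list of `layers` + ground-truth
#'   `profiles`), `community`, `areas`, and the `config` used.
#' @export
simulate_dataset <- function(config = sim_config()) {
  list(forest = simulate_forest_inventory(config),
       soil = simulate_soil_profiles(config),
       community = simulate_community(config),
       areas = simulate_landscape(config),
       config = config)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the four input tables as CSV plus a JSON ground-truth sidecar
#' (per-profile true stocks and classes, and the landscape areas).
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    forest = file.path(dir, "tree_inventory.csv"),
    soil = file.path(dir, "soil_layers.csv"),
    comm = file.path(dir, "community_matrix.csv"),
    species = file.path(dir, "species_attributes.csv"),
    plots = file.path(dir, "community_plots.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  utils::write.csv(sim$forest, paths["forest"], row.names = FALSE)
  utils::write.csv(sim$soil$layers, paths["soil"], row.names = FALSE)
  comm_df <- data.frame(plot_id = rownames(sim$community$comm),
                        sim$community$comm, check.names = FALSE)
  utils::write.csv(comm_df, paths["comm"], row.names = FALSE)
  utils::write.csv(sim$community$species, paths["species"], row.names = FALSE)
  utils::write.csv(sim$community$plots, paths["plots"], row.names = FALSE)
  jsonlite::write_json(
    list(profiles = sim$soil$profiles, landscape = sim$config$landscape,
         seed = sim$config$seed),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Run the carbon-accounting pipeline end to end
#'
#' Simulates a dataset (or accepts one), computes per-plot stand structure
#' and aboveground tree carbon, per-profile soil and root stocks, habitat
#' stock summaries for the three pools (tree, root, soil), and the
#' actual-versus-potential landscape scenario. Grassland habitat types carry
#' a zero tree pool (treeless by definition).
#'
#' @param config A [sim_config()]; ignored when `sim` is supplied.
#' @param sim Optional pre-built dataset from [simulate_dataset()].
#' @param statistic Summary statistic extrapolated to the landscape
#'   (default `"mean"`).
#' @return List with `simulation`, `stand_summary`, `tree_carbon` (per
#'   plot), `soil_stocks` (per profile), `habitat_summaries`, and `scenario`
#'   (see [carbon_scenario()]).
#' @export
run_carbon_pipeline <- function(config = sim_config(), sim = NULL,
                                statistic = "mean") {
  if (is.null(sim)) sim <- simulate_dataset(config)
  stand <- stand_summary(sim$forest)
  plot_hab <- dplyr::distinct(sim$forest, .data$plot_id, .data$habitat_type)
  tree_pp <- plot_tree_carbon(sim$forest) |>
    dplyr::left_join(plot_hab, by = "plot_id")
  soil_st <- soil_profile_stocks(sim$soil$layers)
  prof_hab <- dplyr::distinct(sim$soil$layers, .data$profile_id, .data$habitat_type)
  soil_st <- dplyr::left_join(soil_st, prof_hab, by = "profile_id")
  per_plot <- dplyr::bind_rows(
    tibble::tibble(habitat_type = tree_pp$habitat_type, pool = "tree",
                   stock = tree_pp$tree_carbon),
    tibble::tibble(habitat_type = c("inaccessible_grassland",
                                    "accessible_grassland"),
                   pool = "tree", stock = 0),
    tibble::tibble(habitat_type = soil_st$habitat_type, pool = "root",
                   stock = soil_st$root_carbon),
    tibble::tibble(habitat_type = soil_st$habitat_type, pool = "soil",
                   stock = soil_st$soc_stock)
  )
  summaries <- summarize_habitat_stocks(per_plot)
  scen <- carbon_scenario(sim$areas, summaries, statistic = statistic)
  list(simulation = sim, stand_summary = stand, tree_carbon = tree_pp,
       soil_stocks = soil_st, habitat_summaries = summaries, scenario = scen)
}
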