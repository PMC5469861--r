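# Shared fixtures: compact configurations and hand-built tables.

small_config <- function(seed = 1,
                         forest_plots_per_habitat = 6,
                         soil_profiles_per_habitat = 4,
                         community_plots_per_habitat = 10,
                         species_pool = c(undescribed = 10, introduced = 6,
                                          native = 30),
                         ...) {
  sim_config(seed = seed,
             forest_plots_per_habitat = forest_plots_per_habitat,
             soil_profiles_per_habitat = soil_profiles_per_habitat,
             community_plots_per_habitat = community_plots_per_habitat,
             species_pool = species_pool,
             ...)
}

# One-profile layer table with sensible defaults for every column the soil
# module can consume; override any field by name.
make_layers <- function(top, bottom, volume = 1000, fine_earth = 800,
                        rock = 200, carbon = 2, bs = 60, ecec = 10,
                        munsell_value = 2, munsell_chroma = 2,
                        root_sub_soil = 20, root_sub_root = 0.1,
                        profile_id = "p1") {
  n <- length(top)
  r <- function(x) rep_len(x, n)
  bases <- r(ecec) * r(bs) / 100
  acid <- r(ecec) - bases
  tibble::tibble(
    profile_id = profile_id, layer_index = seq_len(n),
    top_cm = top, bottom_cm = bottom,
    volume_cm3 = r(volume), fine_earth_g = r(fine_earth), rock_g = r(rock),
    carbon_pct = r(carbon), nitrogen_pct = r(carbon) / 12,
    ca = bases * 0.6, mg = bases * 0.25, k = bases * 0.1, na = bases * 0.05,
    al = acid * 0.6, fe = acid * 0.1, mn = acid * 0.05, h = acid * 0.25,
    munsell_value = r(munsell_value), munsell_chroma = r(munsell_chroma),
    root_subsample_soil_g = r(root_sub_soil),
    root_subsample_root_g = r(root_sub_root)
  )
}

# Habitat stock summaries in which every habitat x pool cell carries the
# same constant per-m2 value (all statistics equal).
flat_summaries <- function(value = 1, pools = c("tree", "root", "soil")) {
  tidyr::expand_grid(
    habitat_type = c("inaccessible_forest", "inaccessible_grassland",
                     "accessible_forest", "accessible_grassland"),
    pool = pools
  ) |>
    dplyr::mutate(min = value, q1 = value, mean = value, q3 = value,
                  max = value, n_plots = 1L)
}
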