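# Soil profile accounting: fine-earth mass with rock-fragment correction,
# bulk densities, SOC / nitrogen / root stocks, base saturation, and
# rule-based WRB-style classification.
#
# A layer table has one row per depth increment with columns
#   profile_id, layer_index, top_cm, bottom_cm, volume_cm3, fine_earth_g,
#   rock_g, carbon_pct, nitrogen_pct, ca, mg, k, na, al, fe, mn, h
#   (exchangeable cations, cmol(+) kg-1), munsell_value, munsell_chroma,
#   root_subsample_soil_g, root_subsample_root_g
# Unit contract throughout: bulk density g cm-3 times layer height in mm
# gives kg m-2 with a numeric factor of exactly 1.

ROCK_DENSITY <- 2.65  # assumed density of rock fragments, g cm-3

#' Bulk density of the weathered pedon
#'
#' Density of the undisturbed volumetric sample, fine earth plus rock
#' fragments: `(fine_earth_g + rock_g) / volume_cm3`, in g cm-3.
#'
#' @param fine_earth_g Oven-dry fine-earth mass, g.
#' @param rock_g Oven-dry rock mass, g.
#' @param volume_cm3 Sample volume, cm3 (> 0).
#' @return Numeric vector, g cm-3.
#' @export
weathered_bulk_density <- function(fine_earth_g, rock_g, volume_cm3) {
  if (any(volume_cm3 <= 0, na.rm = TRUE)) {
    stop("`volume_cm3` must be positive", call. = FALSE)
  }
  (fine_earth_g + rock_g) / volume_cm3
}

#' Areal mass of the weathered pedon in one layer
#'
#' `rho_w * h` with the unit contract g cm-3 x mm => kg m-2 (numeric
#' factor 1).
#'
#' @param rho_w Weathered bulk density, g cm-3.
#' @param h_mm Layer height, mm (>= 0).
#' @return Numeric vector, kg m-2.
#' @export
layer_weathered_mass <- function(rho_w, h_mm) {
  if (any(h_mm < 0, na.rm = TRUE)) {
    stop("layer height `h_mm` must be non-negative", call. = FALSE)
  }
  rho_w * h_mm
}

#' Bulk density of the fine earth
#'
#' Fine-earth mass over the volume remaining after subtracting the rock
#' volume at an assumed rock density of 2.65 g cm-3:
#' `fine_earth_g / (volume_cm3 - rock_g / 2.65)`.
#'
#' @inheritParams weathered_bulk_density
#' @return Numeric vector, g cm-3.
#' @export
fine_earth_bulk_density <- function(fine_earth_g, rock_g, volume_cm3) {
  fe_vol <- volume_cm3 - rock_g / ROCK_DENSITY
  bad <- which(fe_vol <= 0)
  if (length(bad) > 0) {
    stop("rock volume meets or exceeds sample volume in layer(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fine_earth_g / fe_vol
}

# Per-layer fine-earth areal mass (kg m-2): the summand of the profile
# fine-earth mass, i.e. weathered mass scaled by the fine-earth mass fraction.
layer_fine_earth_mass <- function(layers) {
  rho_w <- weathered_bulk_density(layers$fine_earth_g, layers$rock_g,
                                  layers$volume_cm3)
  h_mm <- (layers$bottom_cm - layers$top_cm) * 10
  m_w <- layer_weathered_mass(rho_w, h_mm)
  total <- layers$fine_earth_g + layers$rock_g
  frac <- ifelse(total > 0, layers$fine_earth_g / total, 0)
  m_w * frac
}

#' Fine-earth mass of a whole profile
#'
#' Sums the rock-corrected areal mass of fine earth over all layers of one
#' profile, in kg m-2. Two algebraically equivalent forms are available: the
#' `"printed"` form
#' \deqn{M_{fe} = \sum_i M_{w,i} \cdot 100 / ((W_{r,i}/W_{fe,i}) \cdot 100 + 100)}
#' and its simplification, the `"fraction"` form
#' \deqn{M_{fe} = \sum_i M_{w,i} \cdot W_{fe,i} / (W_{fe,i} + W_{r,i}).}
#' The fraction form is the default; it additionally handles the degenerate
#' all-rock layer (fine earth 0) by contributing zero, which is reported.
#'
#' @param layers Layer table for a single profile (columns `top_cm`,
#'   `bottom_cm`, `volume_cm3`, `fine_earth_g`, `rock_g`).
#' @param form `"fraction"` (default) or `"printed"`.
#' @return Fine-earth mass of the profile, kg m-2 (scalar).
#' @export
profile_fine_earth_mass <- function(layers, form = c("fraction", "printed")) {
  form <- match.arg(form)
  check_layer_table(layers)
  rho_w <- weathered_bulk_density(layers$fine_earth_g, layers$rock_g,
                                  layers$volume_cm3)
  h_mm <- (layers$bottom_cm - layers$top_cm) * 10
  m_w <- layer_weathered_mass(rho_w, h_mm)
  if (form == "printed") {
    sum(m_w * 100 / ((layers$rock_g / layers$fine_earth_g * 100) + 100))
  } else {
    all_rock <- layers$fine_earth_g == 0 & layers$rock_g > 0
    if (any(all_rock)) {
      message(sum(all_rock), " layer(s) with no fine earth contribute zero mass")
    }
    sum(layer_fine_earth_mass(layers))
  }
}

#' Carbon and nitrogen stock of a profile
#'
#' Element concentrations (% of fine earth) are converted to areal stocks by
#' multiplying each layer's concentration by that layer's rock-corrected
#' fine-earth mass and summing: kg element m-2.
#'
#' @param layers Layer table for a single profile; `carbon_pct` required,
#'   `nitrogen_pct` optional.
#' @return Named list with `soc_stock` and (if nitrogen present)
#'   `nitrogen_stock`, kg m-2.
#' @export
profile_carbon_stock <- function(layers) {
  check_layer_table(layers)
  if (!"carbon_pct" %in% names(layers) || anyNA(layers$carbon_pct)) {
    bad <- if ("carbon_pct" %in% names(layers)) which(is.na(layers$carbon_pct)) else "all"
    stop("missing carbon concentration in layer(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m_fe <- layer_fine_earth_mass(layers)
  out <- list(soc_stock = sum(layers$carbon_pct / 100 * m_fe))
  if ("nitrogen_pct" %in% names(layers) && !anyNA(layers$nitrogen_pct)) {
    out$nitrogen_stock <- sum(layers$nitrogen_pct / 100 * m_fe)
  }
  out
}

#' Root biomass and root carbon stock of a profile
#'
#' Roots were washed out of a weighed soil subsample per layer; the
#' subsample root-to-soil mass ratio is scaled up by the layer's fine-earth
#' mass and summed over layers. Live and dead roots are pooled.
#'
#' @param layers Layer table for a single profile; columns
#'   `root_subsample_soil_g` (> 0) and `root_subsample_root_g` required.
#' @param carbon_fraction Carbon content of root dry mass (default 0.5).
#' @return Named list with `root_biomass` and `root_carbon`, kg m-2.
#' @export
root_stock <- function(layers, carbon_fraction = 0.5) {
  check_layer_table(layers)
  if (any(layers$root_subsample_soil_g <= 0, na.rm = TRUE)) {
    stop("`root_subsample_soil_g` must be positive in every layer", call. = FALSE)
  }
  density <- layers$root_subsample_root_g / layers$root_subsample_soil_g
  biomass <- sum(density * layer_fine_earth_mass(layers))
  list(root_biomass = biomass, root_carbon = carbon_fraction * biomass)
}

#' Base saturation from exchangeable cations
#'
#' Share of basic cations (Ca, Mg, K, Na) in the effective cation exchange
#' capacity; the remainder (Al, Fe, Mn, H) is the exchangeable acidity.
#'
#' @param ca,mg,k,na,al,fe,mn,h Exchangeable cation charges, cmol(+) kg-1,
#'   all >= 0. Vectors are recycled by ordinary arithmetic.
#' @return Base saturation in percent; `NA` where the total ECEC is zero.
#' @export
base_saturation <- function(ca, mg, k, na, al = 0, fe = 0, mn = 0, h = 0) {
  vals <- cbind(ca, mg, k, na, al, fe, mn, h)
  if (any(vals < 0, na.rm = TRUE)) {
    stop("exchangeable cation values must be non-negative", call. = FALSE)
  }
  bases <- ca + mg + k + na
  ecec <- bases + al + fe + mn + h
  out <- ifelse(ecec > 0, 100 * bases / ecec, NA_real_)
  if (anyNA(out)) {
    warning("base saturation undefined (zero ECEC) in ", sum(is.na(out)),
            " case(s); flagged NA", call. = FALSE)
  }
  out
}

# Rock volume fraction of a profile: per-layer (rock_g / 2.65) / volume,
# weighted by layer thickness.
profile_rock_volume_fraction <- function(layers) {
  v_r <- (layers$rock_g / ROCK_DENSITY) / layers$volume_cm3
  h <- layers$bottom_cm - layers$top_cm
  sum(v_r * h) / sum(h)
}

# Fine-earth-mass-weighted profile base saturation (percent).
profile_base_saturation <- function(layers) {
  bs <- base_saturation(layers$ca, layers$mg, layers$k, layers$na,
                        layers$al, layers$fe, layers$mn, layers$h)
  w <- layer_fine_earth_mass(layers)
  if (all(is.na(bs)) || sum(w) == 0) return(NA_real_)
  sum(bs * w, na.rm = TRUE) / sum(w[!is.na(bs)])
}

#' Rule-based soil classification of a profile
#'
#' Classifies a single-A-horizon profile over continuous rock into
#' Mollic Leptosol, Leptosol, Phaeozem, or Umbrisol:
#'
#' 1. Shallow (total depth <= 25 cm) or very stony (>= 80% rock by volume)
#'    profiles are Leptosols; they qualify as Mollic Leptosols when the
#'    mollic criteria are met: organic carbon >= 0.6% (fine-earth-mass
#'    weighted), Munsell value and chroma <= 3 in every layer, base
#'    saturation >= 50%, and >= 10 cm thickness over continuous rock. (The
#'    further criterion of a 0.6% carbon excess over parent material cannot
#'    be evaluated without parent-material analyses and is taken as
#'    satisfied.)
#' 2. Deeper profiles with profile base saturation >= 50% are Phaeozems.
#' 3. The remaining (more acidic) profiles are Umbrisols.
#'
#' Profile base saturation is the fine-earth-mass-weighted mean over layers,
#' consistent with the stock accounting.
#'
#' @param layers Layer table for a single profile, including cation, carbon,
#'   and Munsell colour columns.
#' @param total_depth Depth to continuous rock, cm; defaults to the deepest
#'   layer bottom.
#' @return Character scalar: `"Mollic Leptosol"`, `"Leptosol"`,
#'   `"Phaeozem"`, `"Umbrisol"`, or `"undetermined"` (with a `reason`
#'   attribute) when required inputs are missing.
#' @export
classify_profile <- function(layers, total_depth = max(layers$bottom_cm)) {
  check_layer_table(layers)
  needed <- c("carbon_pct", "munsell_value", "munsell_chroma",
              "ca", "mg", "k", "na", "al", "fe", "mn", "h")
  absent <- setdiff(needed, names(layers))
  if (length(absent) > 0 || anyNA(layers[intersect(needed, names(layers))]) ||
      is.na(total_depth)) {
    out <- "undetermined"
    attr(out, "reason") <- paste(
      "missing:", paste(c(absent, if (anyNA(layers[intersect(needed, names(layers))])) "NA values"),
                        collapse = ", "))
    return(out)
  }
  w <- layer_fine_earth_mass(layers)
  soc <- sum(layers$carbon_pct * w) / sum(w)
  bs <- suppressWarnings(profile_base_saturation(layers))
  rock_vol <- profile_rock_volume_fraction(layers)
  mollic <- soc >= 0.6 &&
    all(layers$munsell_value <= 3) && all(layers$munsell_chroma <= 3) &&
    !is.na(bs) && bs >= 50 && total_depth >= 10
  if (total_depth <= 25 || rock_vol >= 0.80) {
    if (mollic) "Mollic Leptosol" else "Leptosol"
  } else if (!is.na(bs) && bs >= 50) {
    "Phaeozem"
  } else {
    "Umbrisol"
  }
}

#' Per-profile soil stocks and classification
#'
#' Applies the full soil accounting to a multi-profile layer table:
#' fine-earth mass, mean bulk densities, rock content, SOC/N stocks, root
#' stocks, base saturation, and classification, one row per profile.
#'
#' @param layers Layer table (see module header) covering one or more
#'   profiles, with `profile_id` and optionally `habitat` / `vegetation`
#'   columns carried through.
#' @param root_carbon_fraction Carbon content of root dry mass (default 0.5).
#' @return Tibble with one row per profile: `fine_earth_mass` (kg m-2),
#'   `soc_stock`, `nitrogen_stock`, `root_biomass`, `root_carbon` (kg m-2),
#'   `rock_volume_fraction`, `mean_bulk_density_weathered`,
#'   `mean_bulk_density_fine_earth` (g cm-3, thickness-weighted),
#'   `base_saturation` (%), `total_depth` (cm), `classification`.
#' @export
soil_profile_stocks <- function(layers, root_carbon_fraction = 0.5) {
  layers <- tibble::as_tibble(layers)
  carry <- intersect(c("habitat", "vegetation"), names(layers))
  one <- function(ly) {
    h <- ly$bottom_cm - ly$top_cm
    rho_w <- weathered_bulk_density(ly$fine_earth_g, ly$rock_g, ly$volume_cm3)
    rho_fe <- fine_earth_bulk_density(ly$fine_earth_g, ly$rock_g, ly$volume_cm3)
    cn <- profile_carbon_stock(ly)
    rs <- root_stock(ly, root_carbon_fraction)
    out <- tibble::tibble(
      fine_earth_mass = profile_fine_earth_mass(ly),
      soc_stock = cn$soc_stock,
      nitrogen_stock = cn$nitrogen_stock %||% NA_real_,
      root_biomass = rs$root_biomass,
      root_carbon = rs$root_carbon,
      rock_volume_fraction = profile_rock_volume_fraction(ly),
      mean_bulk_density_weathered = sum(rho_w * h) / sum(h),
      mean_bulk_density_fine_earth = sum(rho_fe * h) / sum(h),
      base_saturation = suppressWarnings(profile_base_saturation(ly)),
      total_depth = max(ly$bottom_cm),
      classification = as.character(classify_profile(ly))
    )
    for (col in carry) out[[col]] <- ly[[col]][1]
    out
  }
  layers |>
    dplyr::group_by(.data$profile_id) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

# Validate the structural invariants of a single-profile layer table:
# positive volumes, non-negative masses, ordered and non-overlapping depths.
check_layer_table <- function(layers) {
  stopifnot(is.data.frame(layers), nrow(layers) >= 1)
  if (any(layers$bottom_cm <= layers$top_cm)) {
    stop("each layer needs bottom_cm > top_cm", call. = FALSE)
  }
  if (any(layers$volume_cm3 <= 0)) {
    stop("`volume_cm3` must be positive", call. = FALSE)
  }
  if (any(layers$fine_earth_g < 0) || any(layers$rock_g < 0)) {
    stop("masses must be non-negative", call. = FALSE)
  }
  ord <- order(layers$top_cm)
  tops <- layers$top_cm[ord]
  bottoms <- layers$bottom_cm[ord]
  if (nrow(layers) > 1 && any(tops[-1] < bottoms[-nrow(layers)] - 1e-9)) {
    stop("layers overlap within the profile", call. = FALSE)
  }
  invisible(layers)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
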