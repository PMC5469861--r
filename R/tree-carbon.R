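# Aboveground tree carbon from dbh/height allometry.
#
# The allometry was calibrated for Polylepis: dbh is first mapped to bole
# diameter at 50 cm height by a linear regression, then dry biomass is
# predicted from log10(height) and log10(d50). Carbon is taken as a fixed
# fraction (default 50%) of dry biomass.

#' Bole diameter at 50 cm height from dbh
#'
#' Linear calibration `d50 = 1.1613 * dbh + 0.4628` (both in cm).
#'
#' @param dbh Numeric vector, diameter at breast height in cm (>= 0).
#' @return Numeric vector of predicted diameters at 50 cm height, cm.
#' @export
dbh_to_d50 <- function(dbh) {
  stopifnot(is.numeric(dbh))
  if (any(dbh < 0, na.rm = TRUE)) {
    stop("`dbh` must be non-negative", call. = FALSE)
  }
  1.1613 * dbh + 0.4628
}

#' Aboveground dry biomass of a tree
#'
#' `biomass = -16.51 + 40.26 * log10(height) + 9.30 * log10(d50)` with height
#' in m, d50 in cm, and the result in kg dry mass per tree. For very small
#' trees (outside the calibration range) the expression can go negative; such
#' predictions are floored at zero and counted in a warning.
#'
#' @param height Numeric vector, tree height in m (> 0).
#' @param d50 Numeric vector, bole diameter at 50 cm height in cm (> 0).
#' @return Numeric vector of dry biomass, kg per tree.
#' @export
tree_biomass <- function(height, d50) {
  stopifnot(is.numeric(height), is.numeric(d50))
  if (any(height <= 0, na.rm = TRUE) || any(d50 <= 0, na.rm = TRUE)) {
    stop("`height` and `d50` must be positive", call. = FALSE)
  }
  raw <- -16.51 + 40.26 * log10(height) + 9.30 * log10(d50)
  n_neg <- sum(raw < 0, na.rm = TRUE)
  if (n_neg > 0) {
    warning(n_neg, " negative biomass prediction(s) floored at 0 ",
            "(trees below the allometry's calibration range)", call. = FALSE)
  }
  pmax(raw, 0)
}

#' Per-tree carbon records
#'
#' Applies the full allometric chain dbh -> d50 -> biomass -> carbon to an
#' inventory table.
#'
#' @param trees Data frame with columns `plot_id`, `status`, `dbh_cm`,
#'   `height_m`.
#' @param carbon_fraction Carbon content of dry biomass (default 0.5).
#' @return Input tibble with added columns `d50_cm`, `biomass_kg`, `carbon_kg`.
#' @export
tree_carbon_table <- function(trees, carbon_fraction = 0.5) {
  trees <- tibble::as_tibble(trees)
  trees$d50_cm <- dbh_to_d50(trees$dbh_cm)
  trees$biomass_kg <- if (nrow(trees) > 0) {
    tree_biomass(trees$height_m, trees$d50_cm)
  } else double()
  trees$carbon_kg <- carbon_fraction * trees$biomass_kg
  trees
}

#' Plot-level aboveground tree carbon stock
#'
#' Sums per-tree carbon over a plot and scales to kg C m-2. Standing deadwood
#' is excluded from the stock by default and reported separately; set
#' `include_deadwood = TRUE` to pool it.
#'
#' @param trees Data frame of trees (may span several plots); columns
#'   `plot_id`, `status`, `dbh_cm`, `height_m`.
#' @param plot_area Plot area in m2 (default 100).
#' @param carbon_fraction Carbon content of dry biomass (default 0.5).
#' @param include_deadwood Include dead stems in the stock (default FALSE).
#' @return Tibble with one row per plot: `tree_carbon` (kg C m-2, per
#'   `include_deadwood`), `deadwood_carbon` (kg C m-2 in dead stems).
#' @export
plot_tree_carbon <- function(trees, plot_area = 100, carbon_fraction = 0.5,
                             include_deadwood = FALSE) {
  if (plot_area <= 0) stop("`plot_area` must be positive", call. = FALSE)
  if (nrow(trees) == 0) {
    return(tibble::tibble(plot_id = character(), tree_carbon = double(),
                          deadwood_carbon = double()))
  }
  tree_carbon_table(trees, carbon_fraction) |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(
      tree_carbon = if (include_deadwood) {
        sum(.data$carbon_kg) / plot_area
      } else {
        sum(.data$carbon_kg[.data$status == "live"]) / plot_area
      },
      deadwood_carbon = sum(.data$carbon_kg[.data$status == "dead"]) / plot_area,
      .groups = "drop"
    )
}
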