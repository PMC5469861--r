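# Landscape-scale carbon budget: habitat stock summaries and the
# actual-versus-potential land-cover scenario.
#
# The landscape is split into zonal-inaccessible, zonal-accessible and azonal
# area. Zonal area of each accessibility class is divided between forest and
# grassland by that class's forest-cover fraction. The "potential" (pristine)
# scenario applies the inaccessible forest-cover fraction and inaccessible
# per-m2 stocks to all zonal area; azonal habitats (rock, moraine, bogs)
# carry zero stock in both scenarios.

HABITAT_TYPES <- c("inaccessible_forest", "inaccessible_grassland",
                   "accessible_forest", "accessible_grassland")
POOLS <- c("tree", "root", "soil")

#' Landscape area description
#'
#' @param total_area_m2 Total mapped landscape area, m2.
#' @param zonal_inaccessible_fraction,zonal_accessible_fraction,azonal_fraction
#'   Fractions of the mapped area; must sum to 1.
#' @param forest_fraction_inaccessible,forest_fraction_accessible Forest-cover
#'   fraction of the zonal area in each accessibility class, in \[0, 1\].
#' @return A `landscape_areas` list.
#' @export
landscape_areas <- function(total_area_m2,
                            zonal_inaccessible_fraction,
                            zonal_accessible_fraction,
                            azonal_fraction,
                            forest_fraction_inaccessible,
                            forest_fraction_accessible) {
  fr <- c(zonal_inaccessible_fraction, zonal_accessible_fraction, azonal_fraction)
  if (total_area_m2 <= 0) stop("`total_area_m2` must be positive", call. = FALSE)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop("landscape fractions must be non-negative and sum to 1", call. = FALSE)
  }
  ff <- c(forest_fraction_inaccessible, forest_fraction_accessible)
  if (any(ff < 0 | ff > 1)) {
    stop("forest fractions must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    total_area_m2 = total_area_m2,
    zonal_inaccessible_fraction = zonal_inaccessible_fraction,
    zonal_accessible_fraction = zonal_accessible_fraction,
    azonal_fraction = azonal_fraction,
    forest_fraction_inaccessible = forest_fraction_inaccessible,
    forest_fraction_accessible = forest_fraction_accessible
  ), class = "landscape_areas")
}

#' Summarise per-plot carbon stocks by habitat and pool
#'
#' Five-number-plus-mean summary (min, lower quartile, mean, upper quartile,
#' max) of per-m2 stocks for each habitat type x carbon pool cell; these
#' statistics drive the landscape extrapolation and its uncertainty bounds.
#'
#' @param per_plot_stocks Data frame with columns `habitat_type`, `pool`,
#'   `stock` (kg C m-2), one row per plot (or soil profile).
#' @return Tibble with columns `habitat_type`, `pool`, `min`, `q1`, `mean`,
#'   `q3`, `max`, `n_plots`.
#' @export
summarize_habitat_stocks <- function(per_plot_stocks) {
  stopifnot(all(c("habitat_type", "pool", "stock") %in% names(per_plot_stocks)))
  per_plot_stocks |>
    dplyr::group_by(.data$habitat_type, .data$pool) |>
    dplyr::summarise(
      min = min(.data$stock),
      q1 = unname(stats::quantile(.data$stock, 0.25)),
      mean = mean(.data$stock),
      q3 = unname(stats::quantile(.data$stock, 0.75)),
      max = max(.data$stock),
      n_plots = dplyr::n(),
      .groups = "drop"
    )
}

# Habitat areas (m2) under one scenario. Potential land cover applies the
# inaccessible forest fraction (and, by default, inaccessible stocks) to all
# zonal area.
scenario_habitat_areas <- function(areas, scenario = c("actual", "potential"),
                                   potential_source = c("inaccessible", "accessible")) {
  scenario <- match.arg(scenario)
  potential_source <- match.arg(potential_source)
  tot <- areas$total_area_m2
  if (scenario == "actual") {
    a_in <- tot * areas$zonal_inaccessible_fraction
    a_ac <- tot * areas$zonal_accessible_fraction
    tibble::tibble(
      habitat_type = HABITAT_TYPES,
      area_m2 = c(a_in * areas$forest_fraction_inaccessible,
                  a_in * (1 - areas$forest_fraction_inaccessible),
                  a_ac * areas$forest_fraction_accessible,
                  a_ac * (1 - areas$forest_fraction_accessible))
    )
  } else {
    a_z <- tot * (areas$zonal_inaccessible_fraction + areas$zonal_accessible_fraction)
    src <- potential_source
    tibble::tibble(
      habitat_type = paste0(src, c("_forest", "_grassland")),
      area_m2 = c(a_z * areas$forest_fraction_inaccessible,
                  a_z * (1 - areas$forest_fraction_inaccessible))
    )
  }
}

#' Landscape carbon stock per pool under one scenario
#'
#' Multiplies each habitat's area by its per-m2 stock statistic and sums over
#' habitats, per pool. The `"actual"` scenario uses present land cover and
#' habitat-specific stocks; the `"potential"` scenario assumes all zonal area
#' carries the inaccessible forest-grassland proportion with (by default)
#' inaccessible-habitat stocks.
#'
#' @param areas A [landscape_areas()] object.
#' @param summaries Output of [summarize_habitat_stocks()].
#' @param scenario `"actual"` or `"potential"`.
#' @param statistic Which summary statistic to extrapolate:
#'   `"mean"`, `"q1"`, `"q3"`, `"min"`, or `"max"`.
#' @param potential_source Habitat stocks applied in the potential scenario
#'   (`"inaccessible"`, the pristine-proxy default, or `"accessible"` for
#'   sensitivity).
#' @return Tibble with columns `pool` and `stock_kg` (kg C over the mapped
#'   area).
#' @export
landscape_stock <- function(areas, summaries,
                            scenario = c("actual", "potential"),
                            statistic = c("mean", "q1", "q3", "min", "max"),
                            potential_source = "inaccessible") {
  scenario <- match.arg(scenario)
  statistic <- match.arg(statistic)
  stopifnot(inherits(areas, "landscape_areas"))
  hab <- scenario_habitat_areas(areas, scenario, potential_source)
  pools <- unique(summaries$pool)
  needed <- tidyr::expand_grid(habitat_type = hab$habitat_type, pool = pools)
  have <- dplyr::semi_join(needed, summaries, by = c("habitat_type", "pool"))
  if (nrow(have) < nrow(needed)) {
    miss <- dplyr::anti_join(needed, summaries, by = c("habitat_type", "pool"))
    stop("missing stock summary for ",
         paste(miss$habitat_type, miss$pool, sep = " x ", collapse = "; "),
         call. = FALSE)
  }
  summaries |>
    dplyr::inner_join(hab, by = "habitat_type") |>
    dplyr::group_by(.data$pool) |>
    dplyr::summarise(stock_kg = sum(.data$area_m2 * .data[[statistic]]),
                     .groups = "drop")
}

#' Percent change between actual and potential landscape stocks
#'
#' Joins per-pool actual and potential stocks, adds a `"total"` row, and
#' computes `100 * (actual - potential) / potential` (a decrease is
#' negative).
#'
#' @param actual,potential Tibbles from [landscape_stock()] (columns `pool`,
#'   `stock_kg`).
#' @return Tibble with columns `pool`, `actual_kg`, `potential_kg`,
#'   `percent_change`; pools with zero potential stock get `NA` change with a
#'   warning.
#' @export
scenario_change <- function(actual, potential) {
  res <- dplyr::full_join(
    dplyr::rename(actual, actual_kg = "stock_kg"),
    dplyr::rename(potential, potential_kg = "stock_kg"),
    by = "pool"
  )
  res <- dplyr::bind_rows(
    res,
    tibble::tibble(pool = "total",
                   actual_kg = sum(res$actual_kg),
                   potential_kg = sum(res$potential_kg))
  )
  res$percent_change <- ifelse(
    res$potential_kg > 0,
    100 * (res$actual_kg - res$potential_kg) / res$potential_kg,
    NA_real_
  )
  if (anyNA(res$percent_change)) {
    warning("percent change undefined for pool(s) with zero potential stock",
            call. = FALSE)
  }
  res
}

#' Forest-cover loss implied by the accessibility contrast
#'
#' Taking inaccessible terrain as the pristine reference, the fraction of
#' forest cover lost on accessible land is
#' `100 * (1 - forest_fraction_accessible / forest_fraction_inaccessible)`.
#'
#' @param areas A [landscape_areas()] object with
#'   `forest_fraction_inaccessible > 0`.
#' @return Forest-cover loss in percent.
#' @export
forest_cover_loss <- function(areas) {
  stopifnot(inherits(areas, "landscape_areas"))
  if (areas$forest_fraction_inaccessible <= 0) {
    stop("undefined: `forest_fraction_inaccessible` is zero", call. = FALSE)
  }
  100 * (1 - areas$forest_fraction_accessible / areas$forest_fraction_inaccessible)
}

#' Full actual-versus-potential carbon scenario
#'
#' Convenience wrapper: computes actual and potential landscape stocks at a
#' chosen statistic and their percent changes, plus the forest-cover-loss
#' arithmetic.
#'
#' @inheritParams landscape_stock
#' @return List with `stocks` (the [scenario_change()] table) and
#'   `forest_cover_loss_percent`.
#' @export
carbon_scenario <- function(areas, summaries, statistic = "mean",
                            potential_source = "inaccessible") {
  act <- landscape_stock(areas, summaries, "actual", statistic)
  pot <- landscape_stock(areas, summaries, "potential", statistic,
                         potential_source)
  list(stocks = scenario_change(act, pot),
       forest_cover_loss_percent = forest_cover_loss(areas))
}
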