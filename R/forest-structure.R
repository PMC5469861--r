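# Stand-structure metrics from tree inventories: basal area, stem density,
# mean/maximum size, and deadwood proportion per plot.

# Minimum qualifying stem size: circumference > 10 cm at 130 cm height.
DBH_MIN_CM <- 10 / pi

#' Cross-sectional (basal) area of a single stem
#'
#' Converts stem diameter at breast height (dbh, 130 cm) to the
#' cross-sectional area of the bole.
#'
#' Two modes are provided. `"metric"` (the default) returns
#' \eqn{\pi (dbh/200)^2} in m2, the dimensionally consistent form for dbh in
#' cm. `"as_printed"` evaluates \eqn{\pi (dbh/2)^2 / 144}, a US-customary
#' form (144 converts square inches to square feet) that is retained only for
#' fidelity with the source allometry sheet; it is dimensionally inconsistent
#' with metric dbh and should not be used for m2 ha-1 reporting.
#'
#' @param dbh Numeric vector of diameters at breast height, cm. Must be >= 0.
#' @param mode `"metric"` or `"as_printed"`.
#' @return Numeric vector of basal areas (m2 in metric mode).
#' @examples
#' tree_basal_area(20)                 # pi * 0.01 ~ 0.0314 m2
#' tree_basal_area(20, "as_printed")   # pi * 100 / 144
#' @export
tree_basal_area <- function(dbh, mode = c("metric", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(dbh))
  if (any(dbh < 0, na.rm = TRUE)) {
    stop("`dbh` must be non-negative; got negative value(s)", call. = FALSE)
  }
  switch(mode,
    metric     = pi * (dbh / 200)^2,
    as_printed = pi * (dbh / 2)^2 / 144
  )
}

#' Read and filter a tree inventory
#'
#' Reads a one-row-per-tree CSV (columns `plot_id`, `habitat`, `species`,
#' `status`, `dbh_cm`, `height_m`) and drops stems below the inventory
#' threshold of 10 cm circumference at breast height (dbh <= 10/pi cm),
#' reporting the number excluded.
#'
#' @param path Path to a CSV file.
#' @return A tibble of qualifying trees.
#' @export
read_tree_inventory <- function(path) {
  trees <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  required <- c("plot_id", "status", "dbh_cm", "height_m")
  missing <- setdiff(required, names(trees))
  if (length(missing) > 0) {
    stop("inventory is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  keep <- trees$dbh_cm > DBH_MIN_CM
  if (any(!keep)) {
    message(sum(!keep), " stem(s) below the 10 cm circumference threshold excluded")
  }
  trees[keep, , drop = FALSE]
}

#' Per-plot stand-structure summary
#'
#' Computes, for each plot, stand basal area (m2 ha-1), stem density
#' (stems ha-1), mean dbh and height, maximum height, and the proportion of
#' standing deadwood. Means are reported over all stems (live plus deadwood)
#' and, because inventory conventions differ on whether dead stems enter size
#' means, also over live stems only (`mean_dbh_live`, `mean_height_live`).
#'
#' @param trees Data frame with columns `plot_id`, `status` ("live" or
#'   "dead"), `dbh_cm`, `height_m`. May span several plots.
#' @param plot_area Plot area in m2 (default 100, a 10 x 10 m plot).
#' @param mode Basal-area mode passed to [tree_basal_area()].
#' @return A tibble with one row per plot. Plots present in `trees` but with
#'   zero stems yield zero densities and `NA` means.
#' @export
stand_summary <- function(trees, plot_area = 100, mode = "metric") {
  if (plot_area <= 0) stop("`plot_area` must be positive", call. = FALSE)
  trees <- tibble::as_tibble(trees)
  if (nrow(trees) == 0) {
    return(tibble::tibble(
      plot_id = character(), stand_basal_area = double(),
      stem_density = double(), mean_dbh = double(), mean_height = double(),
      mean_dbh_live = double(), mean_height_live = double(),
      max_height = double(), deadwood_proportion = double(),
      n_stems = integer()
    ))
  }
  ha_factor <- 10000 / plot_area
  trees |>
    dplyr::mutate(.ba = tree_basal_area(.data$dbh_cm, mode = mode)) |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(
      stand_basal_area = sum(.data$.ba) * ha_factor,
      stem_density = dplyr::n() * ha_factor,
      mean_dbh = mean(.data$dbh_cm),
      mean_height = mean(.data$height_m),
      mean_dbh_live = mean(.data$dbh_cm[.data$status == "live"]),
      mean_height_live = mean(.data$height_m[.data$status == "live"]),
      max_height = max(.data$height_m),
      deadwood_proportion = mean(.data$status == "dead"),
      n_stems = dplyr::n(),
      .groups = "drop"
    )
}
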