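# Community composition metrics: indicator species analysis (IndVal) with a
# permutation null, per-plot diversity/status metrics, and trait-syndrome
# scoring by principal components.

# Maximum IndVal per species together with the best group.
# comm: plots x species numeric matrix; groups: factor of length nrow(comm).
indval_stat <- function(comm, groups) {
  counts <- as.vector(table(groups))
  # group mean cover: groups x species
  gmean <- rowsum(comm, groups) / counts
  colsum <- colSums(gmean)
  a <- sweep(gmean, 2, ifelse(colsum > 0, colsum, 1), "/")
  b <- rowsum((comm > 0) + 0, groups) / counts
  iv <- 100 * a * b
  best <- apply(iv, 2, which.max)
  list(indval = iv[cbind(best, seq_len(ncol(comm)))],
       best_group = rownames(iv)[best])
}

# All distinct arrangements of a label multiset (used for exact enumeration
# on tiny designs). Returns a matrix with one arrangement per row.
multiset_permutations <- function(labels) {
  labels <- as.character(labels)
  rec <- function(pool) {
    if (length(pool) == 1) return(matrix(pool, 1, 1))
    out <- list()
    for (u in unique(pool)) {
      rest <- pool[-match(u, pool)]
      sub <- rec(rest)
      out[[length(out) + 1]] <- cbind(u, sub, deparse.level = 0)
    }
    do.call(rbind, out)
  }
  rec(labels)
}

#' Indicator species analysis (IndVal)
#'
#' For species \eqn{i} and group \eqn{j}, specificity
#' \eqn{A_{ij}} is the mean cover of the species in group \eqn{j} divided by
#' the sum of its group mean covers, and fidelity \eqn{B_{ij}} is the
#' fraction of plots of group \eqn{j} in which the species occurs
#' (cover > 0). The indicator value is \eqn{100 A_{ij} B_{ij}}; the reported
#' value is the maximum over groups, with significance assessed by random
#' reassignment of plot group labels.
#'
#' The permutation p-value uses the add-one rule
#' \eqn{p = (1 + \#\{ \max IV^{perm} \ge IV^{obs} \}) / (n_{perm} + 1)}.
#' With `exact = TRUE` all distinct label arrangements are enumerated
#' instead (feasible only for very small designs) and the p-value is the
#' exact proportion of arrangements whose maximum indicator value reaches
#' the observed one.
#'
#' @param comm Plots x species numeric matrix (percent cover) with species
#'   as (named) columns, or a data frame of the same shape.
#' @param groups Factor (or coercible) of plot group labels, length
#'   `nrow(comm)`, with >= 2 non-empty levels.
#' @param n_perm Number of random permutations (default 999).
#' @param seed Optional integer seed for the permutation null.
#' @param exact Enumerate all distinct label arrangements instead of random
#'   permutation (guarded to <= 200000 arrangements).
#' @return Tibble with columns `species`, `best_group`, `indval` (0-100),
#'   `p_value`. Species absent from every plot are dropped with a warning.
#' @export
indval <- function(comm, groups, n_perm = 999, seed = NULL, exact = FALSE) {
  comm <- as.matrix(comm)
  groups <- droplevels(as.factor(groups))
  stopifnot(nrow(comm) == length(groups))
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (is.null(colnames(comm))) {
    colnames(comm) <- paste0("sp", seq_len(ncol(comm)))
  }
  absent <- colSums(comm) == 0
  if (any(absent)) {
    warning(sum(absent), " species absent from every plot excluded",
            call. = FALSE)
    comm <- comm[, !absent, drop = FALSE]
  }
  obs <- indval_stat(comm, groups)
  eps <- 1e-12
  if (exact) {
    perms <- multiset_permutations(groups)
    if (nrow(perms) > 200000) {
      stop("too many arrangements for exact enumeration; use random permutation",
           call. = FALSE)
    }
    exceed <- integer(ncol(comm))
    for (r in seq_len(nrow(perms))) {
      pm <- indval_stat(comm, factor(perms[r, ], levels = levels(groups)))
      exceed <- exceed + (pm$indval >= obs$indval - eps)
    }
    p <- exceed / nrow(perms)
  } else {
    if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    exceed <- integer(ncol(comm))
    for (r in seq_len(n_perm)) {
      pm <- indval_stat(comm, sample(groups))
      exceed <- exceed + (pm$indval >= obs$indval - eps)
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  tibble::tibble(species = colnames(comm),
                 best_group = obs$best_group,
                 indval = obs$indval,
                 p_value = p)
}

#' Per-plot composition metrics
#'
#' Species richness, cover and richness-proportion of undescribed and of
#' introduced species, and the mean latitudinal amplitude of the native
#' (non-introduced) species present in each plot.
#'
#' @param comm Plots x species cover matrix with plot ids as rownames and
#'   species as column names.
#' @param attributes Data frame with one row per species: columns `species`,
#'   `status` ("described"/"undescribed"), `origin` ("native"/"introduced"),
#'   `lat_range_min` (latitudinal range in minutes; `NA` allowed).
#' @return Tibble with one row per plot: `plot_id`, `richness`,
#'   `undescribed_cover`, `undescribed_prop`, `introduced_cover`,
#'   `introduced_prop`, `native_lat_amplitude` (`NA` for empty plots or
#'   plots with no range data).
#' @export
plot_metrics <- function(comm, attributes) {
  comm <- as.matrix(comm)
  missing_sp <- setdiff(colnames(comm), attributes$species)
  if (length(missing_sp) > 0) {
    stop("species missing from the attribute table: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  attr_idx <- match(colnames(comm), attributes$species)
  undesc <- attributes$status[attr_idx] == "undescribed"
  introd <- attributes$origin[attr_idx] == "introduced"
  latr <- attributes$lat_range_min[attr_idx]
  pres <- comm > 0
  richness <- rowSums(pres)
  amp <- apply(pres, 1, function(p) {
    v <- latr[p & !introd]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  })
  tibble::tibble(
    plot_id = rownames(comm) %||% as.character(seq_len(nrow(comm))),
    richness = as.integer(richness),
    undescribed_cover = unname(rowSums(comm[, undesc, drop = FALSE])),
    undescribed_prop = unname(ifelse(richness > 0,
                              rowSums(pres[, undesc, drop = FALSE]) / richness, 0)),
    introduced_cover = unname(rowSums(comm[, introd, drop = FALSE])),
    introduced_prop = unname(ifelse(richness > 0,
                             rowSums(pres[, introd, drop = FALSE]) / richness, 0)),
    native_lat_amplitude = unname(as.numeric(amp))
  )
}

#' Trait-syndrome scores per plot
#'
#' Standardises the species x trait matrix, extracts principal components
#' (dropping constant trait columns with a warning), fixes each component's
#' sign so its largest-magnitude loading is positive, and averages the
#' per-species component scores over the species present in each plot
#' (unweighted by default; optionally cover-weighted).
#'
#' @param attributes Species attribute table whose trait columns match
#'   `trait_pattern`.
#' @param comm Plots x species cover matrix (species columns must appear in
#'   `attributes$species`).
#' @param n_components Number of components to score (default 8).
#' @param weighted Weight species by cover instead of presence (default
#'   FALSE).
#' @param trait_pattern Regular expression selecting trait columns (default
#'   `"^trait_"`).
#' @return Tibble of per-plot mean scores (`plot_id`, `PC1`...), with
#'   attributes `var_explained` (cumulative proportion over the scored
#'   components) and `loadings`.
#' @export
trait_syndromes <- function(attributes, comm, n_components = 8,
                            weighted = FALSE, trait_pattern = "^trait_") {
  comm <- as.matrix(comm)
  trait_cols <- grep(trait_pattern, names(attributes), value = TRUE)
  if (length(trait_cols) == 0) stop("no trait columns found", call. = FALSE)
  if (n_components > length(trait_cols)) {
    stop("`n_components` exceeds the number of traits", call. = FALSE)
  }
  traits <- as.matrix(attributes[, trait_cols])
  rownames(traits) <- attributes$species
  constant <- apply(traits, 2, function(x) stats::sd(x) == 0)
  if (any(constant)) {
    warning("dropping constant trait column(s): ",
            paste(trait_cols[constant], collapse = ", "), call. = FALSE)
    traits <- traits[, !constant, drop = FALSE]
  }
  if (ncol(traits) == 0) {
    # no trait variation at all: every species scores zero on every axis
    plot_scores <- matrix(0, nrow(comm), n_components,
                          dimnames = list(rownames(comm),
                                          paste0("PC", seq_len(n_components))))
    out <- tibble::as_tibble(plot_scores)
    out <- tibble::add_column(
      out, plot_id = rownames(comm) %||% as.character(seq_len(nrow(comm))),
      .before = 1)
    attr(out, "var_explained") <- NA_real_
    return(out)
  }
  n_components <- min(n_components, ncol(traits))
  pca <- stats::prcomp(traits, center = TRUE, scale. = TRUE)
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(pca$rotation))) {
    k <- which.max(abs(pca$rotation[, j]))
    if (pca$rotation[k, j] < 0) {
      pca$rotation[, j] <- -pca$rotation[, j]
      pca$x[, j] <- -pca$x[, j]
    }
  }
  scores <- pca$x[, seq_len(n_components), drop = FALSE]
  sp_idx <- match(colnames(comm), rownames(scores))
  if (anyNA(sp_idx)) {
    stop("species missing from the attribute table: ",
         paste(colnames(comm)[is.na(sp_idx)], collapse = ", "), call. = FALSE)
  }
  w <- if (weighted) comm else (comm > 0) + 0
  totals <- rowSums(w)
  plot_scores <- (w %*% scores[sp_idx, , drop = FALSE]) /
    ifelse(totals > 0, totals, 1)
  plot_scores[totals == 0, ] <- NA_real_
  out <- tibble::as_tibble(plot_scores)
  out <- tibble::add_column(
    out, plot_id = rownames(comm) %||% as.character(seq_len(nrow(comm))),
    .before = 1)
  var <- pca$sdev^2 / sum(pca$sdev^2)
  attr(out, "var_explained") <- sum(var[seq_len(n_components)])
  attr(out, "loadings") <- pca$rotation[, seq_len(n_components), drop = FALSE]
  out
}
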