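#' Fit a PCA torsion map on a reference feature set
#'
#' Principal components analysis of the sin/cos feature matrix: columns are
#' centered but not scaled (all features share the natural [-1, 1] scale).
#' The sign of each component is fixed by forcing its largest-magnitude
#' loading to be positive, so maps are reproducible across linear-algebra
#' backends and row orderings.
#'
#' The fitting ("reference") set is an explicit argument of the workflow: a
#' global map is typically fit on all reference-ensemble conformers and other
#' ensembles are projected onto it with [project()].
#'
#' @param features a [to_sincos()] feature matrix; must contain no `NA`
#'   (masked-torsion rows belong in [project()], not in the fitting set).
#' @param K number of components to retain; default full rank.
#' @param fitted_on identifier stored with the map.
#' @return object of class `latent_map`: `center` (column means), `loadings`
#'   (`[2T x K]`, orthonormal columns), `eigenvalues` (component variances,
#'   non-increasing), `explained_fraction`, `total_variance`, `scores` of the
#'   fitting set, and `column_names`.
#' @export
fit_map <- function(features, K = NULL, fitted_on = "reference") {
  x <- feature_values(features)
  if (anyNA(x)) stop("fit_map: fitting set contains NA features; ",
                     "fit on fully defined torsions only")
  n <- nrow(x)
  if (n < 2L) stop("fit_map: need at least 2 conformers")
  total_var <- sum(apply(x, 2L, stats::var))
  if (total_var <= 0) stop("fit_map: zero variance feature matrix")
  rank <- min(n - 1L, ncol(x))
  if (is.null(K)) K <- rank
  if (K < 1L || K > rank) stop("fit_map: K must be in 1..min(n-1, 2T)")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  load <- pc$rotation[, seq_len(K), drop = FALSE]
  scores <- pc$x[, seq_len(K), drop = FALSE]
  # sign fix: largest-magnitude loading of each component positive
  for (j in seq_len(K)) {
    piv <- which.max(abs(load[, j]))
    if (load[piv, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  eig <- pc$sdev[seq_len(K)]^2
  structure(list(center = pc$center,
                 loadings = load,
                 eigenvalues = eig,
                 explained_fraction = eig / total_var,
                 total_variance = total_var,
                 scores = scores,
                 column_names = colnames(x),
                 fitted_on = fitted_on),
            class = "latent_map")
}

feature_values <- function(features) {
  if (inherits(features, "feature_matrix")) features$values
  else as.matrix(features)
}

#' @export
print.latent_map <- function(x, ...) {
  K <- length(x$eigenvalues)
  cat("<latent_map> ", length(x$center), " features -> ", K,
      " components (fitted on: ", x$fitted_on, ")\n", sep = "")
  show <- min(K, 8L)
  cat("  cumulative explained variance:",
      paste0(sprintf("%.1f%%", 100 * cumsum(x$explained_fraction)[seq_len(show)]),
             collapse = " "), if (K > show) "..." else "", "\n")
  invisible(x)
}

#' Project a feature matrix onto a fitted torsion map
#'
#' Scores are `(values - center) %*% loadings`. `NA` features (masked
#' torsions of a molecule lacking some reference torsions) are imputed with
#' the map's center values, i.e. they contribute exactly zero after
#' centering, so such molecules still receive finite coordinates on the
#' full-width map.
#'
#' @param map a [fit_map()] result.
#' @param features a [to_sincos()] feature matrix (or bare matrix) whose
#'   width matches the map.
#' @param group_labels optional per-row origin labels; defaults to the
#'   feature matrix's `origin` metadata when present.
#' @return object of class `latent_coords`: `scores` (`[n x K]`),
#'   `group_labels`, `map_ref`.
#' @export
project <- function(map, features, group_labels = NULL) {
  stopifnot(inherits(map, "latent_map"))
  x <- feature_values(features)
  if (ncol(x) != length(map$center)) {
    stop("project: feature width ", ncol(x), " does not match map width ",
         length(map$center))
  }
  if (anyNA(x)) {
    cm <- matrix(map$center, nrow(x), ncol(x), byrow = TRUE)
    x[is.na(x)] <- cm[is.na(x)]
  }
  scores <- sweep(x, 2L, map$center) %*% map$loadings
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  if (is.null(group_labels) && inherits(features, "feature_matrix")) {
    org <- features$source_meta$origin
    if (!is.null(org) && !all(is.na(org))) group_labels <- as.character(org)
  }
  if (is.null(group_labels)) group_labels <- rep(NA_character_, nrow(scores))
  if (length(group_labels) == 1L) group_labels <- rep(group_labels, nrow(scores))
  structure(list(scores = scores,
                 group_labels = group_labels,
                 map_ref = map$fitted_on),
            class = "latent_coords")
}

#' @export
print.latent_coords <- function(x, ...) {
  cat("<latent_coords> ", nrow(x$scores), " conformers x ",
      ncol(x$scores), " components (map: ", x$map_ref, ")\n", sep = "")
  invisible(x)
}

#' Combine latent coordinates row-wise
#'
#' @param ... `latent_coords` objects projected onto the same map.
#' @return a single `latent_coords`.
#' @export
bind_coords <- function(...) {
  parts <- list(...)
  refs <- unique(vapply(parts, `[[`, character(1), "map_ref"))
  if (length(refs) > 1L) stop("bind_coords: coordinates from different maps")
  structure(list(scores = do.call(rbind, lapply(parts, `[[`, "scores")),
                 group_labels = unlist(lapply(parts, `[[`, "group_labels")),
                 map_ref = refs),
            class = "latent_coords")
}

#' Per-component and cumulative explained variance
#'
#' @param map a [fit_map()] result.
#' @return data.frame with `component`, `eigenvalue`, `fraction`,
#'   `cumulative` (fractions of the total feature variance).
#' @export
explained_variance_table <- function(map) {
  stopifnot(inherits(map, "latent_map"))
  data.frame(component = seq_along(map$eigenvalues),
             eigenvalue = map$eigenvalues,
             fraction = map$explained_fraction,
             cumulative = cumsum(map$explained_fraction))
}

#' 2-D conformer density on the map, per group
#'
#' Kernel density estimate (via [MASS::kde2d()]) of the projected conformers
#' in two chosen components, evaluated on a shared grid and normalized per
#' group so each grid sums to 1. Used for the density-map view of ensemble
#' overlap.
#'
#' @param coords a [project()] result.
#' @param dims pair of component indices (default `c(1, 2)`).
#' @param grid grid resolution per axis.
#' @return named list (one per group) of lists with `x`, `y` grid vectors and
#'   `z` the normalized density matrix.
#' @export
density_map <- function(coords, dims = c(1L, 2L), grid = 64L) {
  stopifnot(inherits(coords, "latent_coords"))
  if (length(dims) != 2L || any(dims > ncol(coords$scores))) {
    stop("density_map: dims must index two available components")
  }
  xy <- coords$scores[, dims, drop = FALSE]
  groups <- coords$group_labels
  lims <- c(range(xy[, 1L]), range(xy[, 2L]))
  pad <- c(-1, 1, -1, 1) * 0.1 * c(diff(lims[1:2]), diff(lims[1:2]),
                                   diff(lims[3:4]), diff(lims[3:4]))
  lims <- lims + pad
  out <- list()
  for (g in unique(groups)) {
    pts <- xy[groups == g, , drop = FALSE]
    if (nrow(pts) < 2L) stop("density_map: degenerate density for group '", g,
                             "' (single point)")
    kd <- MASS::kde2d(pts[, 1L], pts[, 2L], n = grid, lims = lims)
    kd$z <- kd$z / sum(kd$z)
    out[[as.character(g)]] <- kd
  }
  out
}

## ---------------------------------------------------------------------------
## Serialization

#' Serialize a fitted map to a JSON bundle
#'
#' Stores center, loadings, eigenvalues, explained fractions and identifiers;
#' [read_map()] restores a `latent_map` usable for projection (the fitting
#' scores themselves are not stored; re-project the fitting features to
#' recover them).
#'
#' @param map a [fit_map()] result.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "latent_map"))
  obj <- list(fitted_on = map$fitted_on,
              column_names = map$column_names,
              center = unname(map$center),
              eigenvalues = map$eigenvalues,
              explained_fraction = map$explained_fraction,
              total_variance = map$total_variance,
              loadings = apply(unname(map$loadings), 2L, identity,
                               simplify = FALSE))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a map written by [write_map()]
#'
#' @param path `.json` path.
#' @return a `latent_map` (without fitting-set scores).
#' @export
read_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  # loadings were serialized column-wise; simplification yields one row per
  # component
  load <- if (is.list(obj$loadings)) do.call(cbind, obj$loadings)
          else t(obj$loadings)
  center <- as.numeric(obj$center)
  names(center) <- obj$column_names
  rownames(load) <- obj$column_names
  structure(list(center = center,
                 loadings = load,
                 eigenvalues = as.numeric(obj$eigenvalues),
                 explained_fraction = as.numeric(obj$explained_fraction),
                 total_variance = as.numeric(obj$total_variance),
                 scores = NULL,
                 column_names = obj$column_names,
                 fitted_on = obj$fitted_on),
            class = "latent_map")
}

#' Write projected coordinates to CSV
#'
#' @param coords a [project()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(coords, path) {
  df <- as.data.frame(coords$scores)
  df$origin <- coords$group_labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read coordinates written by [write_scores_csv()]
#'
#' @param path CSV path.
#' @param map_ref identifier of the map the scores came from.
#' @return a `latent_coords`.
#' @export
read_scores_csv <- function(path, map_ref = "unknown") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  org <- df$origin
  df$origin <- NULL
  structure(list(scores = as.matrix(df),
                 group_labels = if (is.null(org)) rep(NA_character_, nrow(df))
                                else as.character(org),
                 map_ref = map_ref),
            class = "latent_coords")
}
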