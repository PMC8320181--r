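#' k-means cluster mixing between ensemble origins
#'
#' Clusters the combined projected conformers (leading `n_pcs` components)
#' with k-means and reports, per cluster, its size, the per-origin member
#' counts, whether it is "mixed" (members from at least two origins), and the
#' max/median pairwise circular torsion RMSD of its members. A high fraction
#' of mixed clusters indicates strongly overlapping ensembles; clusters unique
#' to one origin mark regions of torsion space the other ensemble missed.
#'
#' k-means uses `stats::kmeans` with the Hartigan-Wong algorithm, `restarts`
#' random starts and at most `max_iter` iterations; the best partition by
#' within-cluster sum of squares is kept.
#'
#' @param coords a [project()] result carrying at least two origin labels.
#' @param n_pcs number of leading components to cluster on (default 8).
#' @param k number of clusters (default 500).
#' @param restarts random restarts (default 25).
#' @param max_iter maximum iterations (default 1000).
#' @param seed integer RNG seed for the restarts.
#' @param angles optional `[n x T]` matrix of the conformers' torsion angles
#'   (degrees), row-aligned with `coords`; enables the per-cluster RMSD
#'   statistics. Pairwise RMSDs in clusters larger than `rmsd_cap` members
#'   are computed on a random subsample of `rmsd_cap` members.
#' @param rmsd_cap member cap for the quadratic pairwise RMSD (default 2000).
#' @return object of class `cluster_overlap`: `per_cluster` data.frame
#'   (`cluster, size, mixed, max_rmsd, median_rmsd` plus one count column per
#'   origin), `n_clusters`, `n_mixed`, `n_unique_per_origin`,
#'   `overall_max_rmsd` (max of cluster maxima), `overall_median_rmsd`
#'   (median of cluster medians, singleton clusters excluded), `cluster`
#'   (per-row assignments).
#' @export
kmeans_overlap <- function(coords, n_pcs = 8L, k = 500L, restarts = 25L,
                           max_iter = 1000L, seed = NULL, angles = NULL,
                           rmsd_cap = 2000L) {
  stopifnot(inherits(coords, "latent_coords"))
  labels <- coords$group_labels
  if (length(unique(labels)) < 2L) {
    stop("kmeans_overlap: single origin, nothing to mix")
  }
  x <- coords$scores[, seq_len(min(n_pcs, ncol(coords$scores))), drop = FALSE]
  n <- nrow(x)
  if (n < k) stop("kmeans_overlap: fewer conformers (", n, ") than clusters (",
                  k, ")")
  if (!is.null(angles) && nrow(angles) != n) {
    stop("kmeans_overlap: angles not row-aligned with coords")
  }
  km <- with_seed(seed, stats::kmeans(x, centers = k, iter.max = max_iter,
                                      nstart = restarts))
  assign <- km$cluster
  origins <- sort(unique(labels))
  counts <- table(factor(assign, levels = seq_len(k)),
                  factor(labels, levels = origins))
  size <- as.integer(rowSums(counts))
  nonempty <- which(size > 0L)
  mixed <- rowSums(counts > 0L) >= 2L
  max_rmsd <- rep(NA_real_, k)
  med_rmsd <- rep(NA_real_, k)
  if (!is.null(angles)) {
    angles <- as.matrix(angles)
    for (c in nonempty) {
      idx <- which(assign == c)
      if (length(idx) == 1L) {            # singleton: RMSD defined as 0
        max_rmsd[c] <- 0
        med_rmsd[c] <- 0
        next
      }
      if (length(idx) > rmsd_cap) {
        idx <- with_seed(seed, sample(idx, rmsd_cap))
      }
      r <- pairwise_circular_rmsd(angles[idx, , drop = FALSE])
      max_rmsd[c] <- max(r)
      med_rmsd[c] <- stats::median(r)
    }
  }
  per <- data.frame(cluster = seq_len(k), size = size,
                    mixed = as.vector(mixed),
                    max_rmsd = max_rmsd, median_rmsd = med_rmsd)
  for (o in origins) per[[paste0("n_", o)]] <- as.integer(counts[, o])
  per <- per[nonempty, , drop = FALSE]
  singleton <- per$size == 1L
  structure(list(per_cluster = per,
                 n_clusters = length(nonempty),
                 n_mixed = sum(per$mixed),
                 n_unique_per_origin = vapply(origins, function(o) {
                   sum(!per$mixed & per[[paste0("n_", o)]] > 0L)
                 }, integer(1)),
                 overall_max_rmsd = if (is.null(angles)) NA_real_
                                    else max(per$max_rmsd, na.rm = TRUE),
                 overall_median_rmsd = if (is.null(angles) || all(singleton))
                                         NA_real_
                                       else stats::median(
                                         per$median_rmsd[!singleton]),
                 cluster = assign),
            class = "cluster_overlap")
}

#' @export
print.cluster_overlap <- function(x, ...) {
  cat("<cluster_overlap> ", x$n_clusters, " non-empty clusters: ",
      x$n_mixed, " mixed, unique per origin: ",
      paste(names(x$n_unique_per_origin), x$n_unique_per_origin,
            sep = "=", collapse = " "), "\n", sep = "")
  if (!is.na(x$overall_max_rmsd)) {
    cat(sprintf("  torsion RMSD: overall max %.2f deg, overall median %.2f deg\n",
                x$overall_max_rmsd, x$overall_median_rmsd))
  }
  invisible(x)
}

# all-pairs circular torsion RMSD within one cluster, vectorized per torsion;
# computed in radians, returned in degrees
pairwise_circular_rmsd <- function(ang) {
  m <- nrow(ang)
  rad <- deg2rad(ang)
  acc <- matrix(0, m, m)
  used <- matrix(0, m, m)
  for (t in seq_len(ncol(rad))) {
    col <- rad[, t]
    if (all(is.na(col))) next
    d <- outer(col, col, `-`)
    d <- (d + pi) %% (2 * pi) - pi
    acc <- acc + d^2
    used <- used + 1
  }
  pairs <- which(upper.tri(acc))
  rad2deg(sqrt(acc[pairs] / used[pairs]))
}

#' Total and generalized variance vs. latent dimensionality
#'
#' For each requested dimensionality `d`, computes the trace (total variance)
#' and determinant (generalized variance) of the sample covariance of the
#' leading `d` latent columns of each ensemble's projected coordinates. The
#' trace is non-decreasing in `d`; the determinant collapses towards zero once
#' near-zero eigenvalue directions enter, which limits its practical use at
#' high `d`.
#'
#' @param coords_list named list of [project()] results (or a single one).
#' @param dims integer vector of dimensionalities (default `1:K`).
#' @return data.frame with `ensemble`, `d`, `total_variance`,
#'   `generalized_variance` (class `variance_curves`).
#' @export
variance_curves <- function(coords_list, dims = NULL) {
  if (inherits(coords_list, "latent_coords")) {
    coords_list <- list(ensemble = coords_list)
  }
  if (is.null(names(coords_list))) {
    names(coords_list) <- paste0("ensemble", seq_along(coords_list))
  }
  out <- list()
  for (nm in names(coords_list)) {
    sc <- coords_list[[nm]]$scores
    if (nrow(sc) < 2L) stop("variance_curves: ensemble '", nm, "' has < 2 rows")
    dd <- if (is.null(dims)) seq_len(ncol(sc)) else as.integer(dims)
    if (any(dd > ncol(sc))) {
      stop("variance_curves: requested d exceeds available components (",
           ncol(sc), ")")
    }
    S <- stats::cov(sc)
    for (d in dd) {
      sub <- S[seq_len(d), seq_len(d), drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        ensemble = nm, d = d,
        total_variance = sum(diag(sub)),
        generalized_variance = det(sub))
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("variance_curves", class(res))
  res
}

## ---------------------------------------------------------------------------
## Mahalanobis coverage

# inverse of a covariance matrix under a named regularization policy
cov_inverse <- function(S, regularization = c("floor", "pseudoinverse", "fail"),
                        eps = 1e-10) {
  regularization <- match.arg(regularization)
  e <- eigen(S, symmetric = TRUE)
  lam <- e$values
  lmax <- max(lam, 0)
  if (regularization == "fail") {
    if (lmax <= 0 || min(lam) < eps * lmax) {
      stop("covariance is singular (smallest eigenvalue ",
           format(min(lam)), ")")
    }
    inv_lam <- 1 / lam
  } else if (regularization == "floor") {
    if (lmax <= 0) stop("covariance has no positive eigenvalue")
    inv_lam <- 1 / pmax(lam, eps * lmax)
  } else {                                  # pseudoinverse
    inv_lam <- ifelse(lam > eps * max(lmax, .Machine$double.eps),
                      1 / lam, 0)
  }
  e$vectors %*% (inv_lam * t(e$vectors))
}

mahal_dist <- function(x, mu, Sinv) {
  xc <- sweep(x, 2L, mu)
  sqrt(pmax(rowSums((xc %*% Sinv) * xc), 0))
}

#' Mahalanobis-distance coverage curves
#'
#' The coverage metric: the comparison ("training") ensemble defines a local
#' model of torsion space — its latent mean `mu` and covariance `S` over the
#' leading `d` components — and every conformer `x` of both ensembles is
#' scored by the Mahalanobis distance
#' `D_M(x) = sqrt((x - mu)' S^-1 (x - mu))`.
#' If the test ("reference", e.g. MD) ensemble extends beyond the training
#' ensemble, its conformers are outliers of the training model and its max
#' and median distances exceed the training ones. Curves are reported for
#' each `d` in `dims`; within a fixed point the distance is non-decreasing
#' in `d`, but scales at different `d` are not directly comparable.
#'
#' High `d` sub-covariances of near-collinear feature spaces can be rank
#' deficient ("near zero eigenvalues"); the `regularization` policy governs
#' the inverse: `"floor"` (default) floors eigenvalues at `1e-10 * lambda_max`,
#' `"pseudoinverse"` drops null directions, `"fail"` raises an error naming
#' the offending `d`.
#'
#' @param train a [project()] result: the ensemble defining the model
#'   (typically the more restricted, generator-derived one).
#' @param test a [project()] result: the ensemble being checked for excess
#'   coverage (typically the MD-derived reference).
#' @param dims dimensionalities to evaluate (default `2:K`).
#' @param regularization one of `"floor"`, `"pseudoinverse"`, `"fail"`.
#' @return object of class `mahalanobis_curve`: data.frame `curve` with
#'   columns `d, train_max, train_median, test_max, test_median`, plus
#'   `train_label`, `test_label`, and per-point distance lists
#'   `train_distances`, `test_distances` (one numeric vector per `d`).
#' @export
mahalanobis_coverage <- function(train, test, dims = NULL,
                                 regularization = c("floor", "pseudoinverse",
                                                    "fail")) {
  stopifnot(inherits(train, "latent_coords"), inherits(test, "latent_coords"))
  regularization <- match.arg(regularization)
  K <- min(ncol(train$scores), ncol(test$scores))
  if (is.null(dims)) dims <- 2:K
  dims <- as.integer(dims)
  if (any(dims > K)) stop("mahalanobis_coverage: d exceeds available components")
  n_tr <- nrow(train$scores)
  if (any(n_tr < dims + 1L)) {
    stop("mahalanobis_coverage: need at least d + 1 training rows (have ",
         n_tr, ")")
  }
  if (nrow(test$scores) < 1L) stop("mahalanobis_coverage: empty test set")
  rows <- list()
  train_d <- list()
  test_d <- list()
  for (d in dims) {
    tr <- train$scores[, seq_len(d), drop = FALSE]
    te <- test$scores[, seq_len(d), drop = FALSE]
    mu <- colMeans(tr)
    S <- stats::cov(tr)
    Sinv <- tryCatch(cov_inverse(S, regularization),
                     error = function(e) stop("mahalanobis_coverage: d = ", d,
                                              ": ", conditionMessage(e)))
    dtr <- mahal_dist(tr, mu, Sinv)
    dte <- mahal_dist(te, mu, Sinv)
    rows[[length(rows) + 1L]] <- data.frame(
      d = d,
      train_max = max(dtr), train_median = stats::median(dtr),
      test_max = max(dte), test_median = stats::median(dte))
    train_d[[as.character(d)]] <- dtr
    test_d[[as.character(d)]] <- dte
  }
  lab <- function(co, default) {
    u <- unique(co$group_labels)
    if (length(u) == 1L && !is.na(u)) u else default
  }
  structure(list(curve = do.call(rbind, rows),
                 train_label = lab(train, "train"),
                 test_label = lab(test, "test"),
                 train_distances = train_d,
                 test_distances = test_d),
            class = "mahalanobis_curve")
}

#' @export
print.mahalanobis_curve <- function(x, ...) {
  cat("<mahalanobis_curve> train = ", x$train_label, ", test = ",
      x$test_label, "\n", sep = "")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

## ---------------------------------------------------------------------------
## Dispersion permutation test

#' Permutation test for homogeneity of multivariate dispersion
#'
#' Each conformer's dispersion is its Euclidean distance to its group's
#' centroid in the leading `n_pcs` latent components. Group differences in
#' mean distance-to-centroid are tested with a one-way ANOVA F statistic
#' whose null distribution is obtained by randomly permuting group labels;
#' the p-value uses the add-one convention `p = (b + 1) / (n_perm + 1)` where
#' `b` counts permuted statistics `>=` the observed one, so `p` can never
#' fall below `1 / (n_perm + 1)`. Pairwise differences
#' `deltaD = D_group1 - D_group2` come with Tukey HSD confidence intervals
#' computed on the distance values.
#'
#' @param coords a [project()] result with at least two groups of >= 2 rows.
#' @param n_pcs leading components used for the distances (default 8).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return object of class `dispersion_test`: `per_group_mean_distance`
#'   (named vector D per group), `F_statistic`, `permutation_p`, `pairwise`
#'   data.frame (`pair, delta_D, lwr, upr, p_adj`), `distances`, `groups`,
#'   `n_perm`.
#' @export
dispersion_test <- function(coords, n_pcs = 8L, n_perm = 10000L, seed = NULL) {
  stopifnot(inherits(coords, "latent_coords"))
  if (n_perm < 1L) stop("dispersion_test: n_perm must be >= 1")
  g <- factor(coords$group_labels)
  if (nlevels(g) < 2L) stop("dispersion_test: need at least two groups")
  if (any(table(g) < 2L)) {
    stop("dispersion_test: every group needs at least 2 members")
  }
  x <- coords$scores[, seq_len(min(n_pcs, ncol(coords$scores))), drop = FALSE]
  cent <- apply(x, 2L, function(col) tapply(col, g, mean))
  if (is.null(dim(cent))) cent <- matrix(cent, ncol = 1L)
  d <- sqrt(rowSums((x - cent[as.integer(g), , drop = FALSE])^2))
  F_obs <- anova_F(d, g)
  b <- 0L
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      if (anova_F(d, g[sample.int(length(d))]) >= F_obs) b <- b + 1L
    }
  })
  p <- (b + 1L) / (n_perm + 1L)
  fit <- stats::aov(d ~ g, data = data.frame(d = d, g = g))
  tk <- stats::TukeyHSD(fit)$g
  pairwise <- data.frame(pair = rownames(tk),
                         delta_D = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"],
                         row.names = NULL)
  structure(list(per_group_mean_distance = tapply(d, g, mean),
                 F_statistic = F_obs,
                 permutation_p = p,
                 pairwise = pairwise,
                 distances = d,
                 groups = g,
                 n_perm = n_perm),
            class = "dispersion_test")
}

# one-way ANOVA F on a numeric response, minimal and allocation-light
anova_F <- function(y, g) {
  n <- length(y)
  k <- nlevels(g)
  gm <- mean(y)
  means <- tapply(y, g, mean)
  sizes <- tabulate(g, nbins = k)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((y - means[as.integer(g)])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat("<dispersion_test> F = ", format(x$F_statistic, digits = 4),
      ", permutation p = ", format(x$permutation_p, digits = 4),
      " (", x$n_perm, " permutations)\n", sep = "")
  cat("  mean distance-to-centroid:\n")
  print(round(x$per_group_mean_distance, 4))
  cat("  pairwise (Tukey HSD):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

## ---------------------------------------------------------------------------
## Energy binning

#' Zero and bin per-conformer relative energies
#'
#' Within each run, energies are shifted so the lowest conformer sits at
#' zero (MD snapshot energies are only comparable after per-run zeroing).
#' Shifted energies are labelled `low` (< `low`), `mid` (`>= low` and
#' `<= high`), `high` (> `high`); conformers above `discard_above` are
#' flagged `discarded`. Defaults (6, 10, 100 kcal/mol) are the conventional
#' biorelevant-conformation thresholds.
#'
#' @param energies numeric vector, kcal/mol.
#' @param runs per-conformer run labels for the zeroing (single run if NULL).
#' @param low,high bin edges in kcal/mol: `low` exclusive ("< 6.0"), `high`
#'   inclusive ("<= 10.0").
#' @param discard_above filter threshold on the shifted energies.
#' @return data.frame with `energy` (shifted), `bin` (factor
#'   `low`/`mid`/`high`), `discarded` (logical).
#' @export
bin_energies <- function(energies, runs = NULL, low = 6.0, high = 10.0,
                         discard_above = 100.0) {
  if (!length(energies)) stop("bin_energies: empty energy vector")
  if (any(!is.finite(energies))) stop("bin_energies: non-finite energy")
  if (is.null(runs)) runs <- rep("run1", length(energies))
  if (length(runs) != length(energies)) {
    stop("bin_energies: runs length mismatch")
  }
  runs <- factor(runs)
  if (any(tabulate(runs) == 0L)) stop("bin_energies: empty run")
  mins <- tapply(energies, runs, min)
  shifted <- energies - mins[as.integer(runs)]
  bin <- cut(shifted, breaks = c(-Inf, low, high, Inf),
             labels = c("low", "mid", "high"), right = FALSE)
  # boundary semantics: exactly `low` is mid ("< 6.0" excludes it), exactly
  # `high` is mid ("<= 10.0" includes it) -- cut(right = FALSE) handles `low`,
  # fix the `high` boundary explicitly
  bin[shifted == high] <- "mid"
  data.frame(energy = as.numeric(shifted), bin = bin,
             discarded = shifted > discard_above)
}
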