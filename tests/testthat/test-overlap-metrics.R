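test_that("circular RMSD wraps differences and matches a shift oracle", {
  expect_equal(circular_rmsd(c(10, -50), c(10, -50)), 0)
  expect_equal(circular_rmsd(179, -179), 2)
  # brute-force oracle: minimum absolute difference over +/- 360 shifts
  set.seed(2)
  for (i in 1:20) {
    a <- runif(6, -180, 180)
    b <- runif(6, -180, 180)
    d <- vapply(a - b, function(x) min(abs(x + c(-360, 0, 360))), numeric(1))
    expect_equal(circular_rmsd(a, b), sqrt(mean(d^2)), tolerance = 1e-10)
  }
  expect_error(circular_rmsd(1:3, 1:4), "length mismatch")
})

test_that("cluster mixing separates identical from disjoint ensembles", {
  set.seed(6)
  x <- matrix(rnorm(400), 200, 2)
  # identical point sets labelled A and B: every non-singleton cluster mixed
  co <- toy_coords(x, x)
  rep1 <- kmeans_overlap(co, n_pcs = 2, k = 10, seed = 1)
  nonsingleton <- rep1$per_cluster$size > 1
  expect_true(all(rep1$per_cluster$mixed[nonsingleton]))
  expect_true(all(rep1$n_unique_per_origin == 0))
  # two blobs far beyond cluster diameter, k = 2: nothing mixes
  co2 <- toy_coords(x, x + 1000)
  rep2 <- kmeans_overlap(co2, n_pcs = 2, k = 2, seed = 1)
  expect_identical(rep2$n_mixed, 0L)
  # bookkeeping invariants
  expect_equal(sum(rep1$per_cluster$size), 400)
  expect_equal(rep1$n_mixed + sum(rep1$n_unique_per_origin),
               rep1$n_clusters)
  expect_error(kmeans_overlap(co, k = 500), "fewer conformers")
  single <- toy_coords(x, x[0, , drop = FALSE], labels = c("A", "B"))
  expect_error(kmeans_overlap(single, k = 5), "single origin")
})

test_that("per-cluster torsion RMSD statistics follow their definitions", {
  set.seed(9)
  ang_a <- matrix(rep(c(60, -60, 170), each = 50), 50, 3)   # identical rows
  ang_b <- sweep(ang_a, 2, c(120, 40, -80), `+`)
  co <- toy_coords(matrix(0, 50, 2) + rnorm(100, sd = 0.01),
                   matrix(5, 50, 2) + rnorm(100, sd = 0.01))
  rep <- kmeans_overlap(co, n_pcs = 2, k = 2, seed = 3,
                        angles = wrap_angle(rbind(ang_a, ang_b)))
  # clusters of identical conformers have zero internal RMSD
  expect_equal(rep$per_cluster$max_rmsd, c(0, 0))
  expect_equal(rep$overall_max_rmsd, max(rep$per_cluster$max_rmsd))
  expect_equal(rep$overall_median_rmsd, median(rep$per_cluster$median_rmsd))
})

test_that("variance curves reproduce PCA eigenvalue sums on the fitting set", {
  scen <- ensemble_scenario(list(basin_spec(c(55, -65, 175, -20, 90), 6)),
                            150, seed = 51)
  f <- to_sincos(sample_ensemble(scen))
  map <- fit_map(f)
  co <- project(map, f, group_labels = "MD")
  vc <- variance_curves(list(MD = co))
  for (d in vc$d) {
    expect_equal(vc$total_variance[vc$d == d],
                 sum(map$eigenvalues[1:d]), tolerance = 1e-8)
  }
  expect_true(all(diff(vc$total_variance) >= -1e-12))
  expect_true(all(vc$generalized_variance >= -1e-12))
  # a near-zero eigenvalue collapses the generalized variance
  K <- ncol(co$scores)
  gv <- vc$generalized_variance
  expect_lt(gv[K] / gv[5], 1e-6)
  expect_error(variance_curves(list(MD = co), dims = K + 1), "exceeds")
})

test_that("variance curves match sampling expectations on isotropic data", {
  set.seed(33)
  co <- structure(list(scores = matrix(rnorm(3e5), 1e5, 3),
                       group_labels = rep("x", 1e5), map_ref = "iso"),
                  class = "latent_coords")
  vc <- variance_curves(list(iso = co), dims = 3)
  expect_equal(vc$total_variance, 3, tolerance = 0.02)
  expect_equal(vc$generalized_variance, 1, tolerance = 0.02)
})

test_that("Mahalanobis distances match the explicit-inverse oracle", {
  set.seed(17)
  tr <- matrix(rnorm(40, sd = c(2, 0.5)), 20, 2, byrow = TRUE)
  te <- matrix(rnorm(10), 5, 2)
  as_coords <- function(s, lab) {
    structure(list(scores = s, group_labels = rep(lab, nrow(s)),
                   map_ref = "m"), class = "latent_coords")
  }
  mc <- mahalanobis_coverage(as_coords(tr, "t"), as_coords(te, "p"),
                             dims = 2)
  mu <- colMeans(tr)
  Sinv <- solve(cov(tr))
  oracle <- apply(te, 1, function(x) sqrt(t(x - mu) %*% Sinv %*% (x - mu)))
  expect_equal(unname(mc$test_distances[["2"]]), unname(oracle),
               tolerance = 1e-10)
})

test_that("Mahalanobis coverage satisfies its algebraic identities", {
  set.seed(19)
  n <- 60
  tr <- structure(list(scores = matrix(rnorm(n * 6), n, 6),
                       group_labels = rep("train", n), map_ref = "m"),
                  class = "latent_coords")
  te <- structure(list(scores = matrix(rnorm(30), 5, 6),
                       group_labels = rep("test", 5), map_ref = "m"),
                  class = "latent_coords")
  mc <- mahalanobis_coverage(tr, te, dims = 2:6)
  # mean squared train distance equals d (n - 1) / n under the sample covariance
  for (d in 2:6) {
    expect_equal(mean(mc$train_distances[[as.character(d)]]^2),
                 d * (n - 1) / n, tolerance = 1e-8)
  }
  # distance at the training mean is zero
  mu_row <- structure(list(scores = matrix(colMeans(tr$scores), 1),
                           group_labels = "c", map_ref = "m"),
                      class = "latent_coords")
  mc0 <- mahalanobis_coverage(tr, mu_row, dims = c(2, 4))
  expect_equal(unname(mc0$test_distances[["4"]]), 0, tolerance = 1e-10)
  # whitened data (sample covariance = identity): distance equals the
  # Euclidean norm from the mean
  xc <- scale(tr$scores, center = TRUE, scale = FALSE)
  w <- xc %*% solve(chol(cov(xc)))
  white <- tr
  white$scores <- w
  mcw <- mahalanobis_coverage(white, white, dims = 6)
  expect_equal(unname(mcw$test_distances[["6"]]),
               unname(sqrt(rowSums(w^2))), tolerance = 1e-8)
  # monotone non-decreasing in d for every point
  dm <- do.call(cbind, mc$test_distances)
  expect_true(all(diff(t(dm)) >= -1e-8))
})

test_that("rank-deficient covariance honors the regularization policy", {
  set.seed(23)
  base <- matrix(rnorm(60), 30, 2)
  sc <- cbind(base, base[, 1] + base[, 2])     # exactly collinear third axis
  tr <- structure(list(scores = sc, group_labels = rep("t", 30),
                       map_ref = "m"), class = "latent_coords")
  expect_error(mahalanobis_coverage(tr, tr, dims = 3,
                                    regularization = "fail"),
               "d = 3")
  mc <- mahalanobis_coverage(tr, tr, dims = 3, regularization = "floor")
  expect_true(all(is.finite(mc$curve$train_max)))
  mp <- mahalanobis_coverage(tr, tr, dims = 3,
                             regularization = "pseudoinverse")
  expect_true(all(is.finite(mp$curve$train_max)))
})

test_that("dispersion test agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(29)
  a <- matrix(rnorm(60, sd = 1), 30, 2)
  b <- matrix(rnorm(40, sd = 3), 20, 2)
  co <- toy_coords(a, b)
  dt <- dispersion_test(co, n_pcs = 2, n_perm = 99, seed = 4)
  mod <- vegan::betadisper(dist(co$scores), co$group_labels,
                           type = "centroid")
  expect_equal(sort(unname(dt$distances)), sort(unname(mod$distances)),
               tolerance = 1e-10)
  expect_equal(unname(dt$per_group_mean_distance),
               unname(tapply(mod$distances, mod$group, mean)),
               tolerance = 1e-10)
  expect_equal(dt$F_statistic, anova(mod)$`F value`[1], tolerance = 1e-10)
})

test_that("dispersion test is calibrated and degenerates correctly", {
  set.seed(31)
  # same-distribution groups: p typically large
  ps <- vapply(1:20, function(s) {
    x <- matrix(rnorm(120), 60, 2)
    co <- toy_coords(x[1:30, ], x[31:60, ])
    dispersion_test(co, n_pcs = 2, n_perm = 99, seed = s)$permutation_p
  }, numeric(1))
  expect_gt(median(ps), 0.3)
  # identical duplicated groups: zero dispersion difference, CI contains 0
  x <- matrix(rnorm(60), 30, 2)
  dt0 <- dispersion_test(toy_coords(x, x), n_pcs = 2, n_perm = 99, seed = 1)
  expect_equal(dt0$pairwise$delta_D, 0, tolerance = 1e-12)
  expect_true(dt0$pairwise$lwr <= 0 && dt0$pairwise$upr >= 0)
  # errors
  expect_error(dispersion_test(toy_coords(x, x), n_perm = 0), "n_perm")
  expect_error(dispersion_test(toy_coords(x, x[1, , drop = FALSE])),
               "at least 2 members")
})

test_that("energy binning zeroes per run and conserves counts", {
  res <- bin_energies(c(12, 15, 120))
  expect_equal(res$energy, c(0, 3, 108))
  expect_identical(as.character(res$bin), c("low", "low", "high"))
  expect_identical(res$discarded, c(FALSE, FALSE, TRUE))
  # boundary semantics: 6.0 is mid (excluded from "< 6"), 10.0 is mid
  res2 <- bin_energies(c(0, 5.999, 6, 9.2, 10, 10.001))
  expect_identical(as.character(res2$bin),
                   c("low", "low", "mid", "mid", "mid", "high"))
  # per-run zeroing uses each run's own minimum
  res3 <- bin_energies(c(10, 12, 100, 103), runs = c("r1", "r1", "r2", "r2"))
  expect_equal(res3$energy, c(0, 2, 0, 3))
  # count conservation over random inputs
  set.seed(37)
  e <- runif(500, 0, 150)
  r <- sample(c("a", "b", "c"), 500, TRUE)
  res4 <- bin_energies(e, r)
  expect_equal(sum(table(res4$bin)), 500)
  expect_equal(nrow(res4), 500)
  expect_error(bin_energies(numeric(0)), "empty")
})
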