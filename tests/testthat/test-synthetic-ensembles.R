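test_that("sampling is deterministic given the scenario seed", {
  scen <- ensemble_scenario(list(basin_spec(c(60, -120), 15, label = "A"),
                                 basin_spec(c(-60, 120), 15, weight = 0.5,
                                            label = "B")),
                            200, seed = 77)
  e1 <- sample_ensemble(scen)
  e2 <- sample_ensemble(scen)
  expect_identical(e1$angles, e2$angles)
  expect_identical(e1$meta, e2$meta)
})

test_that("von Mises basins honor their concentration parameter", {
  # concentration limit: essentially delta at the mean
  tight <- ensemble_scenario(list(basin_spec(c(33, -147), 1e6)), 200,
                             seed = 5)
  e <- sample_ensemble(tight)
  dev <- wrap_angle(sweep(e$angles, 2, c(33, -147)))
  expect_lt(max(abs(dev)), 0.3)
  # angular spread matches the large-kappa limit sd ~ 1/sqrt(kappa)
  expect_lt(abs(sd(dev * pi / 180) - 1 / sqrt(1e6)) * sqrt(1e6), 0.1)
  # kappa = 0: circular-uniform draws (Rayleigh test non-significant at
  # alpha = 0.01 in at least 18 of 20 seeded replicates)
  rayleigh_p <- function(theta) {
    n <- length(theta)
    r <- sqrt(sum(cos(theta))^2 + sum(sin(theta))^2) / n
    z <- n * r^2
    exp(-z) * (1 + (2 * z - z^2) / (4 * n))
  }
  pass <- 0L
  for (s in 1:20) {
    set.seed(s)
    th <- r_vonmises(1e4, 0, 0) * pi / 180
    if (rayleigh_p(th) > 0.01) pass <- pass + 1L
  }
  expect_gte(pass, 18L)
})

test_that("sample circular means converge to the basin means", {
  set.seed(61)
  mu <- c(45, -100, 170)
  e <- sample_ensemble(ensemble_scenario(list(basin_spec(mu, 8)), 1e4,
                                         seed = 62))
  rad <- e$angles * pi / 180
  circ_mean <- atan2(colMeans(sin(rad)), colMeans(cos(rad))) * 180 / pi
  # rule-of-thumb error bound ~ 3 / (sqrt(kappa) * sqrt(n)) radians
  bound <- 3 / sqrt(8 * 1e4) * 180 / pi
  expect_true(all(abs(wrap_angle(circ_mean - mu)) < 5 * bound + 0.5))
})

test_that("basin occupancies follow the scenario weights", {
  scen <- ensemble_scenario(list(basin_spec(rep(0, 2), 50, weight = 0.7,
                                            label = "A"),
                                 basin_spec(rep(120, 2), 50, weight = 0.3,
                                            label = "B")),
                            1e5, seed = 91)
  e <- sample_ensemble(scen)
  occ <- table(e$meta$start) / nrow(e$angles)
  expect_equal(unname(occ["A"]), 0.7, tolerance = 0.015)
  expect_equal(unname(occ["B"]), 0.3, tolerance = 0.035)
})

test_that("overlap pairs encode their ground-truth basin structure", {
  shared <- list(basin_spec(rep(40, 6), 25, label = "A"))
  extra <- list(basin_spec(rep(-140, 6), 25, weight = 0.4, label = "B"))
  pair <- make_overlap_pair(shared, extra, n_train = 300, n_test = 300,
                            seed = 13)
  expect_identical(unique(pair$train$meta$origin), "generator")
  expect_identical(unique(pair$test$meta$origin), "MD")
  expect_identical(unique(pair$train$meta$start), "A")
  expect_setequal(unique(pair$test$meta$start), c("A", "B"))
  # extra-basin occupancy in the test set tracks its weight
  w_b <- mean(pair$test$meta$start == "B")
  expect_lt(abs(w_b - 0.4 / 1.4), 0.06)
  # a distant extra basin inflates the test Mahalanobis maxima at every d
  pp <- project_pair(pair)
  mc <- mahalanobis_coverage(pp$train, pp$test, dims = 2:6)
  expect_true(all(mc$curve$test_max > mc$curve$train_max))
  expect_error(make_overlap_pair(shared, extra, n_test = 0), "n_test")
  expect_error(make_overlap_pair(list(), extra), "shared")
})

test_that("pairs without extra basins are exchangeable", {
  shared <- list(basin_spec(rep(20, 4), 10, label = "A"),
                 basin_spec(rep(-90, 4), 10, label = "B"))
  ok <- 0L
  for (s in 1:20) {
    pair <- make_overlap_pair(shared, list(), n_train = 150, n_test = 150,
                              seed = s)
    # two-sample test on the first torsion's sin embedding
    p <- suppressWarnings(ks.test(sin(pair$train$angles[, 1] * pi / 180),
                                  sin(pair$test$angles[, 1] * pi / 180)))$p.value
    if (p > 0.01) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("energy models attach zeroable per-conformer energies", {
  scen <- ensemble_scenario(list(basin_spec(rep(0, 2), 30, label = "A"),
                                 basin_spec(rep(100, 2), 30, weight = 1,
                                            label = "B")),
                            400, seed = 15,
                            energy_model = list(basin_offsets = c(0, 8),
                                                gamma_shape = 2,
                                                gamma_rate = 1))
  e <- sample_ensemble(scen)
  expect_length(e$energies, 400)
  expect_true(all(e$energies >= 0))
  bins <- bin_energies(e$energies, e$meta$run)
  expect_equal(min(bins$energy), 0)
  # conformers from the offset basin are biased towards higher bins
  expect_gt(mean(e$energies[e$meta$start == "B"]),
            mean(e$energies[e$meta$start == "A"]))
})

test_that("scenario YAML files round-trip into scenarios", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_conformers: 50",
               "origin_label: demo",
               "seed: 3",
               "basins:",
               "  - label: A", "    weight: 0.6",
               "    mean_angles: [60, -120]", "    concentration: 12",
               "  - label: B", "    weight: 0.4",
               "    mean_angles: [-60, 120]", "    concentration: 12"), path)
  scen <- read_scenario(path)
  expect_s3_class(scen, "ensemble_scenario")
  expect_equal(scen$weights, c(0.6, 0.4))
  e <- sample_ensemble(scen)
  expect_equal(dim(e$angles), c(50L, 2L))
  expect_identical(unique(e$meta$origin), "demo")
})
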