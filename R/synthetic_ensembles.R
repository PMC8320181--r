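#' Von Mises random angles
#'
#' Best-Fisher (1979) rejection sampler for the von Mises distribution, the
#' circular analogue of the Gaussian. `kappa = 0` gives circular-uniform
#' draws; large `kappa` concentrates tightly around the mean direction.
#'
#' @param n number of draws.
#' @param mu mean direction in degrees.
#' @param kappa concentration parameter (>= 0).
#' @return angles in degrees on (-180, 180].
#' @export
r_vonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("r_vonmises: kappa must be >= 0")
  if (kappa < 1e-10) {
    return(wrap_angle(stats::runif(n, -180, 180)))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0L) {
      u3 <- stats::runif(k)
      out[got + seq_len(k)] <- sign(u3 - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      got <- got + k
    }
  }
  wrap_angle(mu + rad2deg(out))
}

#' Specification of one torsional basin
#'
#' A basin is a product of independent von Mises distributions, one per
#' torsion: the minimal circular analogue of a Gaussian energy well. An MD
#' run started from one conformer typically explores a few such basins; a
#' conformer generator may cover only a subset of them.
#'
#' @param mean_angles per-torsion mean directions in degrees (length T).
#' @param concentration per-torsion von Mises kappa (scalar recycled, or
#'   length T); larger = tighter basin.
#' @param weight sampling probability weight (>= 0); normalized within a
#'   scenario.
#' @param label basin name recorded in the sampled conformers' metadata.
#' @return list of class `basin_spec`.
#' @export
basin_spec <- function(mean_angles, concentration = 20, weight = 1,
                       label = "basin") {
  if (weight < 0) stop("basin_spec: weight must be >= 0")
  if (any(concentration < 0)) stop("basin_spec: kappa must be >= 0")
  T <- length(mean_angles)
  concentration <- rep_len(concentration, T)
  structure(list(mean_angles = wrap_angle(mean_angles),
                 concentration = concentration,
                 weight = weight, label = label),
            class = "basin_spec")
}

#' Multi-basin ensemble scenario
#'
#' @param basins list of [basin_spec()] with equal torsion counts; weights
#'   are normalized to sum to 1.
#' @param n_conformers number of conformers to draw.
#' @param origin_label origin tag written into the sampled metadata.
#' @param energy_model optional list with `basin_offsets` (kcal/mol, one per
#'   basin) and `gamma_shape`/`gamma_rate` for the within-basin excess
#'   energy; exists to exercise energy binning, not as a physical claim.
#' @param seed RNG seed.
#' @return list of class `ensemble_scenario`.
#' @export
ensemble_scenario <- function(basins, n_conformers, origin_label = "synthetic",
                              energy_model = NULL, seed = NULL) {
  if (!length(basins)) stop("ensemble_scenario: need at least one basin")
  if (n_conformers < 1L) stop("ensemble_scenario: n_conformers must be >= 1")
  Ts <- vapply(basins, function(b) length(b$mean_angles), integer(1))
  if (length(unique(Ts)) != 1L) {
    stop("ensemble_scenario: basins disagree on torsion count")
  }
  w <- vapply(basins, `[[`, numeric(1), "weight")
  if (sum(w) <= 0) stop("ensemble_scenario: basin weights sum to zero")
  structure(list(basins = basins, weights = w / sum(w),
                 n_conformers = as.integer(n_conformers),
                 origin_label = origin_label,
                 energy_model = energy_model, seed = seed),
            class = "ensemble_scenario")
}

#' Sample a torsional ensemble from a scenario
#'
#' Each conformer picks a basin (categorical by weight), then draws each
#' torsion independently from that basin's von Mises distribution. The basin
#' label is recorded in the metadata (`start` column, mirroring
#' starting-conformer tags), and per-conformer energies are attached when the
#' scenario carries an energy model. Deterministic given the scenario seed.
#'
#' @param scenario an [ensemble_scenario()].
#' @param torsion_names optional labels (default `T1..TT`).
#' @return a [torsion_ensemble()].
#' @export
sample_ensemble <- function(scenario, torsion_names = NULL) {
  stopifnot(inherits(scenario, "ensemble_scenario"))
  T <- length(scenario$basins[[1L]]$mean_angles)
  n <- scenario$n_conformers
  with_seed(scenario$seed, {
    which_basin <- sample.int(length(scenario$basins), n, replace = TRUE,
                              prob = scenario$weights)
    ang <- matrix(NA_real_, n, T)
    for (b in seq_along(scenario$basins)) {
      rows <- which(which_basin == b)
      if (!length(rows)) next
      bs <- scenario$basins[[b]]
      for (t in seq_len(T)) {
        ang[rows, t] <- r_vonmises(length(rows), bs$mean_angles[t],
                                   bs$concentration[t])
      }
    }
    energies <- NULL
    em <- scenario$energy_model
    if (!is.null(em)) {
      offs <- rep_len(em$basin_offsets, length(scenario$basins))
      shape <- if (is.null(em$gamma_shape)) 2 else em$gamma_shape
      rate <- if (is.null(em$gamma_rate)) 0.5 else em$gamma_rate
      energies <- offs[which_basin] + stats::rgamma(n, shape, rate)
    }
    meta <- data.frame(
      origin = scenario$origin_label,
      run = "run1",
      start = vapply(scenario$basins, `[[`, character(1),
                     "label")[which_basin])
    torsion_ensemble(ang, torsion_names, meta, energies)
  })
}

#' Train/test ensemble pair with controlled basin overlap
#'
#' Builds the canonical coverage fixture: a "generator-like" training
#' ensemble drawn from the shared basins only, and an "MD-like" test ensemble
#' drawn from the shared basins plus any extra basins. With extra basins of
#' positive weight the test ensemble provably extends beyond the training
#' one; with none, the two are exchangeable samples of one distribution.
#'
#' @param shared_basins list of [basin_spec()] available to both ensembles.
#' @param extra_basins list of [basin_spec()] available only to the test
#'   ensemble (may be empty).
#' @param n_train,n_test sample sizes (both >= 1).
#' @param seed RNG seed; train and test use derived sub-seeds.
#' @param train_label,test_label origin tags.
#' @return list with `train` and `test` [torsion_ensemble()]s.
#' @export
make_overlap_pair <- function(shared_basins, extra_basins = list(),
                              n_train = 500L, n_test = 500L, seed = 1L,
                              train_label = "generator", test_label = "MD") {
  if (!length(shared_basins)) stop("make_overlap_pair: need a shared basin")
  if (n_train < 1L) stop("make_overlap_pair: n_train must be >= 1")
  if (n_test < 1L) stop("make_overlap_pair: n_test must be >= 1")
  tr_scen <- ensemble_scenario(shared_basins, n_train,
                               origin_label = train_label,
                               seed = seed * 2L + 1L)
  te_scen <- ensemble_scenario(c(shared_basins, extra_basins), n_test,
                               origin_label = test_label,
                               seed = seed * 2L + 2L)
  list(train = sample_ensemble(tr_scen), test = sample_ensemble(te_scen))
}

#' Read an ensemble scenario from YAML
#'
#' Layout: top-level `n_conformers`, `origin_label`, optional `seed` and
#' `energy_model`, and a `basins` list of `{label, weight, mean_angles,
#' concentration}` entries.
#'
#' @param path YAML file path.
#' @return an [ensemble_scenario()].
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  basins <- lapply(y$basins, function(b) {
    basin_spec(as.numeric(b$mean_angles),
               concentration = if (is.null(b$concentration)) 20
                               else as.numeric(b$concentration),
               weight = if (is.null(b$weight)) 1 else b$weight,
               label = if (is.null(b$label)) "basin" else b$label)
  })
  ensemble_scenario(basins, y$n_conformers,
                    origin_label = if (is.null(y$origin_label)) "synthetic"
                                   else y$origin_label,
                    energy_model = y$energy_model,
                    seed = y$seed)
}

#' Hand-built hydrogen-bond test structures
#'
#' Small structures with documented geometry realizing a known IMHB count
#' under the default [hbond_criteria()]:
#' * `one_imhb`: an O-H donor aimed at a carbonyl O, H...O 2.0 A, angle 165.
#' * `zero_imhb`: same motif stretched to H...O 3.2 A.
#' * `two_imhb`: two independent donor/acceptor pairs.
#' * `apolar`: methane-like C/H fragment, no polar atoms.
#'
#' @param kind one of `"one_imhb"`, `"zero_imhb"`, `"two_imhb"`, `"apolar"`.
#' @return a [conformer_structure()].
#' @export
build_hbond_fixture <- function(kind = c("one_imhb", "zero_imhb", "two_imhb",
                                         "apolar")) {
  kind <- match.arg(kind)
  # donor O at origin, H along +x; acceptor placed at distance `d` from H
  # with a D-H...A angle of `ang` degrees (in the xy-plane)
  place_acceptor <- function(h, d_vec_u, d, ang) {
    # u points from H back to the donor; rotate by (180 - ang) in-plane
    th <- deg2rad(ang)
    perp <- c(-d_vec_u[2L], d_vec_u[1L], 0)
    h + d * (cos(th) * d_vec_u + sin(th) * perp)
  }
  if (kind == "apolar") {
    el <- c("C", "H", "H", "H", "H")
    co <- rbind(c(0, 0, 0), c(1.09, 0, 0), c(-0.36, 1.03, 0),
                c(-0.36, -0.51, 0.89), c(-0.36, -0.51, -0.89))
    bonds <- cbind(1L, 2:5)
    return(conformer_structure(el, co, bonds))
  }
  d_ha <- if (kind == "zero_imhb") 3.2 else 2.0
  o1 <- c(0, 0, 0)
  h1 <- c(0.96, 0, 0)
  u1 <- (o1 - h1) / sqrt(sum((o1 - h1)^2))
  a1 <- place_acceptor(h1, u1, d_ha, 165)
  c1 <- a1 + c(0, 1.22, 0)                      # carbonyl C, geometry only
  el <- c("O", "H", "O", "C")
  co <- rbind(o1, h1, a1, c1)
  bonds <- rbind(c(1L, 2L), c(3L, 4L))
  if (kind == "two_imhb") {
    off <- c(0, 0, 8)                            # second motif, well apart
    o2 <- c(0, 0, 0) + off
    h2 <- c(0.96, 0, 0) + off
    u2 <- (o2 - h2) / sqrt(sum((o2 - h2)^2))
    a2 <- place_acceptor(h2, u2, 2.0, 150)
    c2 <- a2 + c(0, 1.22, 0)
    el <- c(el, c("O", "H", "O", "C"))
    co <- rbind(co, o2, h2, a2, c2)
    bonds <- rbind(bonds, c(5L, 6L), c(7L, 8L))
  }
  conformer_structure(el, co, bonds)
}
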