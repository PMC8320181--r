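#' Embed dihedral angles in the continuous sin/cos feature space
#'
#' Raw dihedrals are discontinuous at the -180/+180 cut: two nearly identical
#' conformers with torsions of -178 and +178 degrees are far apart on the raw
#' scale. Mapping each angle theta to the pair (sin theta, cos theta) removes
#' the discontinuity; e.g. 178 degrees becomes (0.035, -0.999) and -178
#' becomes (-0.035, -0.999), adjacent points in feature space.
#'
#' Columns are interleaved as `sin_T1, cos_T1, sin_T2, cos_T2, ...`; the order
#' is fixed and stable across runs. Masked (undefined) torsions yield `fill`
#' in both of their columns; the default `NA` is resolved to the reference
#' column means by [project()] (mean imputation, which contributes zero after
#' centering).
#'
#' @param ensemble a [torsion_ensemble()].
#' @param fill value written into the feature columns of masked torsions.
#' @return object of class `feature_matrix`: list with `values`
#'   (`[n x 2T]` matrix), `column_names`, `torsion_names`, `mask` and
#'   `source_meta` (the ensemble's per-conformer metadata).
#' @examples
#' ens <- torsion_ensemble(matrix(c(178, 0, -90), ncol = 1))
#' round(to_sincos(ens)$values, 3)
#' @export
to_sincos <- function(ensemble, fill = NA_real_) {
  stopifnot(inherits(ensemble, "torsion_ensemble"))
  ang <- ensemble$angles
  n <- nrow(ang)
  T <- ncol(ang)
  if (n < 1L) stop("to_sincos: empty ensemble")
  rad <- deg2rad(ang)
  vals <- matrix(NA_real_, n, 2L * T)
  vals[, seq(1L, 2L * T, by = 2L)] <- sin(rad)
  vals[, seq(2L, 2L * T, by = 2L)] <- cos(rad)
  cn <- as.vector(rbind(paste0("sin_", ensemble$torsion_names),
                        paste0("cos_", ensemble$torsion_names)))
  colnames(vals) <- cn
  masked_cols <- as.vector(rbind(!ensemble$mask, !ensemble$mask))
  vals[, masked_cols] <- fill
  structure(list(values = vals,
                 column_names = cn,
                 torsion_names = ensemble$torsion_names,
                 mask = ensemble$mask,
                 source_meta = ensemble$meta),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " conformers x ",
      ncol(x$values), " sin/cos features\n", sep = "")
  invisible(x)
}

#' Perturb dihedrals with Gaussian angular noise
#'
#' Adds independent normal noise (mean 0, standard deviation `sd` radians) to
#' every defined dihedral and re-wraps into (-180, 180]. Used to probe how
#' much of the high-order latent variance is numerical noise rather than
#' conformational signal: the reference level sd = 2*pi/180 (i.e. 2 degrees)
#' emulates the dihedral precision left after geometry optimization.
#'
#' @param ensemble a [torsion_ensemble()].
#' @param sd noise standard deviation in radians (default `2 * pi / 180`).
#' @param seed integer seed; the perturbation is deterministic given the seed
#'   and leaves the caller's RNG state untouched.
#' @return a new [torsion_ensemble()] with perturbed angles.
#' @export
add_angle_noise <- function(ensemble, sd = 2 * pi / 180, seed = NULL) {
  stopifnot(inherits(ensemble, "torsion_ensemble"))
  if (!is.numeric(sd) || length(sd) != 1L || sd < 0) {
    stop("add_angle_noise: sd must be a single non-negative number (radians)")
  }
  ang <- ensemble$angles
  with_seed(seed, {
    noise <- matrix(stats::rnorm(length(ang), mean = 0, sd = rad2deg(sd)),
                    nrow(ang), ncol(ang))
    ang <- wrap_angle(ang + noise)
  })
  torsion_ensemble(ang, ensemble$torsion_names, ensemble$meta,
                   ensemble$energies, ensemble$mask)
}

#' Write a feature matrix to CSV
#'
#' @param features a [to_sincos()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  df <- as.data.frame(features$values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
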