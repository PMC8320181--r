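#' Wrap angles into the interval (-180, 180]
#'
#' All dihedral angles in the package live on (-180, 180] degrees; readers
#' wrap on ingest so that e.g. 270 is stored as -90 and -180 as +180. A single
#' convention avoids double counting the cut point.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped into (-180, 180].
#' @examples
#' wrap_angle(c(270, 360, -180, 181))
#' @export
wrap_angle <- function(x) {
  y <- x %% 360
  gt <- !is.na(y) & y > 180
  y[gt] <- y[gt] - 360
  y
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Circular root-mean-square deviation between two torsion vectors
#'
#' Per-torsion differences are wrapped into (-180, 180] before squaring, so
#' 179 vs -179 contributes 2 degrees, not 358. Internally the computation is
#' carried out in radians and reported in degrees.
#'
#' @param a,b numeric vectors of torsion angles in degrees, equal length.
#' @param mask optional logical vector; only `TRUE` positions enter the RMSD.
#' @return RMSD in degrees (scalar).
#' @examples
#' circular_rmsd(179, -179)  # 2
#' @export
circular_rmsd <- function(a, b, mask = NULL) {
  if (length(a) != length(b)) {
    stop("circular_rmsd: length mismatch (", length(a), " vs ", length(b), ")")
  }
  if (!is.null(mask)) {
    a <- a[mask]
    b <- b[mask]
  }
  d <- deg2rad(wrap_angle(a - b))
  rad2deg(sqrt(mean(d^2)))
}
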