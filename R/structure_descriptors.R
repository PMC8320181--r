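#' Geometric criteria for intramolecular hydrogen bonds
#'
#' Defaults are deliberately softened relative to textbook values (H...A
#' distance 1.5-2.6 A, D-H...A angle window 110-220 degrees) so that MD
#' snapshots, which are not local minima, are not under-counted. Geometric
#' angles live on [0, 180], so the 220-degree upper bound is vacuous; it is
#' retained in the configuration for fidelity to the published window.
#'
#' @param d_min,d_max H...acceptor distance window in Angstrom.
#' @param angle_min,angle_max donor-H...acceptor angle window in degrees.
#' @param donor_elements heavy-atom elements that donate via an attached H.
#' @param acceptor_elements elements accepted as H-bond acceptors.
#' @return list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(d_min = 1.5, d_max = 2.6,
                           angle_min = 110, angle_max = 220,
                           donor_elements = c("N", "O"),
                           acceptor_elements = c("N", "O")) {
  stopifnot(d_min > 0, d_min < d_max, angle_min < angle_max)
  structure(list(d_min = d_min, d_max = d_max,
                 angle_min = angle_min, angle_max = angle_max,
                 donor_elements = donor_elements,
                 acceptor_elements = acceptor_elements),
            class = "hbond_criteria")
}

#' Count intramolecular hydrogen bonds in one conformer
#'
#' Donors are N/O heavy atoms with an explicitly bonded hydrogen; acceptors
#' are N/O atoms other than the donor itself. A donor-H...acceptor triple
#' counts when the H...acceptor distance falls inside the distance window and
#' the geometric D-H...A angle (on [0, 180]) falls inside the angle window.
#' Each hydrogen is counted at most once, towards its nearest qualifying
#' acceptor, so bifurcated contacts are not double counted.
#'
#' @param structure a [conformer_structure()] with explicit hydrogens and a
#'   bond table.
#' @param criteria a [hbond_criteria()].
#' @return list with `count` and `triples` (data.frame `donor, h, acceptor,
#'   distance, angle`).
#' @export
count_imhb <- function(structure, criteria = hbond_criteria()) {
  stopifnot(inherits(structure, "conformer_structure"))
  el <- structure$elements
  co <- structure$coords
  bonds <- structure$bonds
  donors <- which(el %in% criteria$donor_elements)
  acceptors <- which(el %in% criteria$acceptor_elements)
  if (length(donors) && !any(el == "H")) {
    warning("count_imhb: structure has no explicit hydrogens; ",
            "all donor candidates skipped")
  }
  triples <- list()
  for (dnr in donors) {
    nb <- c(bonds[bonds[, 1L] == dnr, 2L], bonds[bonds[, 2L] == dnr, 1L])
    hs <- nb[el[nb] == "H"]
    for (h in hs) {
      cand <- setdiff(acceptors, c(dnr, h))
      if (!length(cand)) next
      v_ha <- co[cand, , drop = FALSE] -
        matrix(co[h, ], length(cand), 3L, byrow = TRUE)
      dist <- sqrt(rowSums(v_ha^2))
      v_hd <- co[dnr, ] - co[h, ]
      cosang <- (v_ha %*% v_hd) / (dist * sqrt(sum(v_hd^2)))
      ang <- rad2deg(acos(pmin(pmax(cosang, -1), 1)))
      ok <- dist >= criteria$d_min & dist <= criteria$d_max &
        ang >= criteria$angle_min & ang <= criteria$angle_max
      if (!any(ok)) next
      best <- cand[ok][which.min(dist[ok])]
      triples[[length(triples) + 1L]] <- data.frame(
        donor = dnr, h = h, acceptor = best,
        distance = min(dist[ok]),
        angle = ang[ok][which.min(dist[ok])])
    }
  }
  triples <- if (length(triples)) do.call(rbind, triples)
             else data.frame(donor = integer(0), h = integer(0),
                             acceptor = integer(0), distance = numeric(0),
                             angle = numeric(0))
  list(count = nrow(triples), triples = triples)
}

#' IMHB histogram over a set of conformers
#'
#' @param structures list of [conformer_structure()].
#' @param criteria a [hbond_criteria()].
#' @return data.frame with `imhb` (`"0","1","2","3+"`), `n`, `percent`
#'   (percentages sum to 100).
#' @export
imhb_profile <- function(structures, criteria = hbond_criteria()) {
  if (!length(structures)) stop("imhb_profile: no structures")
  counts <- vapply(structures, function(s) count_imhb(s, criteria)$count,
                   integer(1))
  lab <- ifelse(counts >= 3L, "3+", as.character(counts))
  tab <- table(factor(lab, levels = c("0", "1", "2", "3+")))
  data.frame(imhb = names(tab), n = as.integer(tab),
             percent = 100 * as.integer(tab) / length(counts))
}

## ---------------------------------------------------------------------------
## 3D polar surface area

# Bondi van der Waals radii (A)
.bondi_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                  P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

#' Parameters for the 3D polar surface area
#'
#' @param polar_elements heavy elements counted as polar; hydrogens bonded to
#'   a polar heavy atom are included automatically.
#' @param probe_radius solvent probe radius in Angstrom.
#' @param n_sphere_points surface lattice points per atom (>= 96).
#' @param vdw_radii named per-element radius table (A); Bondi by default.
#' @param report_thresholds bin edges (A^2) used only for color-coding
#'   reports; defaults mirror the TPSA-derived oral-absorption cut-offs
#'   95 +/- 17.7 and 145 +/- 21.4 A^2.
#' @return list of class `psa_parameters`.
#' @export
psa_parameters <- function(polar_elements = c("N", "O"),
                           probe_radius = 1.4,
                           n_sphere_points = 960L,
                           vdw_radii = .bondi_radii,
                           report_thresholds = c(95, 145)) {
  stopifnot(probe_radius >= 0, n_sphere_points >= 96L)
  structure(list(polar_elements = polar_elements,
                 probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 vdw_radii = vdw_radii,
                 report_thresholds = report_thresholds),
            class = "psa_parameters")
}

# deterministic, near-uniform unit-sphere lattice (golden spiral)
sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' 3D polar surface area of one conformer
#'
#' Shrake-Rupley style numeric surface integration restricted to polar atoms:
#' for each polar atom (N, O, and hydrogens bonded to them) a deterministic
#' point lattice is placed on the sphere of radius `vdw + probe`; points
#' strictly inside any other atom's solvent-expanded sphere are buried, and
#' the exposed fraction times the sphere area is accumulated. Exactly
#' duplicated atoms (same element and coordinates) are collapsed before the
#' computation so coincident copies do not double count surface.
#'
#' Absolute values are method- and radius-set-dependent; compare only values
#' computed with identical parameters.
#'
#' @param structure a [conformer_structure()].
#' @param params a [psa_parameters()].
#' @return polar surface area in A^2 (scalar).
#' @export
psa_3d <- function(structure, params = psa_parameters()) {
  stopifnot(inherits(structure, "conformer_structure"))
  el <- structure$elements
  co <- structure$coords
  key <- paste(el, co[, 1L], co[, 2L], co[, 3L])
  keep <- !duplicated(key)
  el2 <- el[keep]
  co2 <- co[keep, , drop = FALSE]
  # remap bonds onto the deduplicated atom list
  map <- match(key, key[keep])
  bonds <- structure$bonds
  if (nrow(bonds) > 0L) {
    bonds <- cbind(map[bonds[, 1L]], map[bonds[, 2L]])
    bonds <- bonds[bonds[, 1L] != bonds[, 2L], , drop = FALSE]
  }
  unknown <- setdiff(unique(el2), names(params$vdw_radii))
  if (length(unknown)) {
    stop("psa_3d: no van der Waals radius for element ",
         paste(unknown, collapse = ", "))
  }
  polar_heavy <- which(el2 %in% params$polar_elements)
  polar_h <- integer(0)
  if (nrow(bonds) > 0L) {
    h_atoms <- which(el2 == "H")
    for (h in h_atoms) {
      nb <- c(bonds[bonds[, 1L] == h, 2L], bonds[bonds[, 2L] == h, 1L])
      if (any(nb %in% polar_heavy)) polar_h <- c(polar_h, h)
    }
  }
  polar <- union(polar_heavy, polar_h)
  if (!length(polar)) return(0)
  radii <- params$vdw_radii[el2] + params$probe_radius
  pts <- sphere_lattice(params$n_sphere_points)
  area <- 0
  n <- length(el2)
  for (a in polar) {
    surf <- pts * radii[a] + matrix(co2[a, ], params$n_sphere_points, 3L,
                                    byrow = TRUE)
    exposed <- rep(TRUE, params$n_sphere_points)
    for (b in seq_len(n)) {
      if (b == a) next
      d2 <- rowSums((surf - matrix(co2[b, ], params$n_sphere_points, 3L,
                                   byrow = TRUE))^2)
      exposed <- exposed & d2 >= radii[b]^2
      if (!any(exposed)) break
    }
    area <- area + 4 * pi * radii[a]^2 * mean(exposed)
  }
  unname(area)
}

#' Per-conformer descriptor table
#'
#' Joins IMHB counts, 3D-PSA and (optionally) energy bins for a list of
#' conformers into one table ready for map color-coding.
#'
#' @param structures list of [conformer_structure()].
#' @param criteria a [hbond_criteria()].
#' @param params a [psa_parameters()].
#' @param energies optional energies (kcal/mol) forwarded to [bin_energies()].
#' @param runs optional run labels for energy zeroing.
#' @return data.frame with `conformer`, `imhb`, `psa_3d` and, when energies
#'   are given, `energy`, `energy_bin`, `discarded`.
#' @export
descriptor_table <- function(structures, criteria = hbond_criteria(),
                             params = psa_parameters(), energies = NULL,
                             runs = NULL) {
  df <- data.frame(
    conformer = seq_along(structures),
    imhb = vapply(structures, function(s) count_imhb(s, criteria)$count,
                  integer(1)),
    psa_3d = vapply(structures, function(s) psa_3d(s, params), numeric(1)))
  if (!is.null(energies)) {
    eb <- bin_energies(energies, runs)
    df$energy <- eb$energy
    df$energy_bin <- eb$bin
    df$discarded <- eb$discarded
  }
  df
}
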