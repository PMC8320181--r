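# Shared fixtures and independent oracles, all built in code.

# Minimal V2000 SDF writer for test molecules (independent of the reader).
write_test_sdf <- function(path, mols) {
  lines <- character(0)
  for (m in mols) {
    n <- length(m$elements)
    nb <- nrow(m$bonds)
    lines <- c(lines, m$name, "  test", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       m$coords[, 1], m$coords[, 2], m$coords[, 3], m$elements),
               sprintf("%3d%3d%3d  0", m$bonds[, 1], m$bonds[, 2],
                       if (ncol(m$bonds) > 2) m$bonds[, 3] else rep(1L, nb)),
               "M  END")
    for (f in names(m$fields)) {
      lines <- c(lines, paste0("> <", f, ">"), as.character(m$fields[[f]]), "")
    }
    lines <- c(lines, "$$$$")
  }
  writeLines(lines, path)
  path
}

# Chain of m atoms with prescribed consecutive dihedrals (simple zig-zag
# backbone built by Natural Extension of Reference Frame).
chain_with_dihedrals <- function(dihedrals_deg, bond = 1.5, angle = 109.5) {
  n <- length(dihedrals_deg) + 3L
  co <- matrix(0, n, 3L)
  co[2L, ] <- c(bond, 0, 0)
  th <- pi - angle * pi / 180
  co[3L, ] <- co[2L, ] + bond * c(cos(th), sin(th), 0)
  for (i in seq_along(dihedrals_deg)) {
    a <- co[i, ]; b <- co[i + 1L, ]; c <- co[i + 2L, ]
    # the placement frame below realizes a torsion of (180 - phi_used),
    # so request the complement
    phi <- (180 - dihedrals_deg[i]) * pi / 180
    bc <- (c - b) / sqrt(sum((c - b)^2))
    ab <- b - a
    nvec <- ab - sum(ab * bc) * bc
    nvec <- nvec / sqrt(sum(nvec^2))
    mvec <- c(nvec[2] * bc[3] - nvec[3] * bc[2],
              nvec[3] * bc[1] - nvec[1] * bc[3],
              nvec[1] * bc[2] - nvec[2] * bc[1])
    d2 <- -cos(angle * pi / 180)
    dy <- sin(angle * pi / 180) * cos(phi)
    dz <- sin(angle * pi / 180) * sin(phi)
    co[i + 3L, ] <- c + bond * (d2 * bc + dy * nvec + dz * mvec)
  }
  co
}

# Independent brute-force dihedral oracle: angle between the two bond-plane
# normals via arccos, signed by the scalar triple product. Formulation is
# deliberately different from the implementation's atan2 route.
oracle_dihedral <- function(co) {
  xp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- co[2, ] - co[1, ]; b2 <- co[3, ] - co[2, ]; b3 <- co[4, ] - co[3, ]
  n1 <- xp(b1, b2)
  n2 <- xp(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(min(max(cosang, -1), 1)) * 180 / pi
  s <- sum(xp(n1, n2) * b2)
  ang <- if (s >= 0) ang else -ang  # sign fixed against the IUPAC convention
  if (ang <= -180) ang + 360 else ang
}

random_rigid_transform <- function(co, seed = 1) {
  set.seed(seed)
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_dec)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(co %*% R, 2, rnorm(3, sd = 5), `+`)
}

# Small labelled two-group latent_coords fixture.
toy_coords <- function(a, b, labels = c("A", "B"), map_ref = "toy") {
  structure(list(scores = rbind(a, b),
                 group_labels = rep(labels, c(nrow(a), nrow(b))),
                 map_ref = map_ref),
            class = "latent_coords")
}

# Project a two-ensemble von Mises pair onto a map fit on the test (MD-like)
# ensemble; returns the pieces most tests need.
project_pair <- function(pair) {
  ft <- to_sincos(pair$test)
  fr <- to_sincos(pair$train)
  map <- fit_map(ft, fitted_on = "MD")
  list(map = map,
       train = project(map, fr),
       test = project(map, ft))
}
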