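#' Torsion definitions
#'
#' A torsion definition names an ordered quadruple of atom indices (1-based,
#' into a [conformer_structure()]). Definition order fixes the column order of
#' every dihedral matrix downstream.
#'
#' @param names character vector of unique torsion labels (e.g. `"T1"`).
#' @param atoms integer matrix `[n_torsions x 4]` of 1-based atom indices;
#'   each row must contain four distinct indices.
#' @return object of class `torsion_defs`.
#' @export
torsion_defs <- function(names, atoms) {
  atoms <- as.matrix(atoms)
  if (ncol(atoms) != 4L) stop("torsion_defs: atoms must have 4 columns")
  if (length(names) != nrow(atoms)) stop("torsion_defs: names/atoms length mismatch")
  if (anyDuplicated(names)) stop("torsion_defs: duplicate torsion name")
  if (any(apply(atoms, 1L, function(r) anyDuplicated(r) > 0L))) {
    stop("torsion_defs: a torsion quadruple has repeated atom indices")
  }
  if (any(atoms < 1L)) stop("torsion_defs: atom indices are 1-based (>= 1)")
  structure(list(names = as.character(names),
                 atoms = matrix(as.integer(atoms), ncol = 4L)),
            class = "torsion_defs")
}

#' Read torsion definitions from YAML or CSV
#'
#' YAML layout: a `torsions` list of `{name, atoms: [i, j, k, l]}` entries.
#' CSV layout: columns `name, a1, a2, a3, a4`. Atom indices are 1-based.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` vs `.csv`).
#' @return a [torsion_defs()] object.
#' @export
read_torsion_defs <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    entries <- if (!is.null(y$torsions)) y$torsions else y
    nm <- vapply(entries, function(e) as.character(e$name), character(1))
    at <- t(vapply(entries, function(e) as.integer(e$atoms), integer(4)))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "a1", "a2", "a3", "a4")
    if (!all(need %in% names(df))) {
      stop("read_torsion_defs: CSV needs columns ", paste(need, collapse = ", "))
    }
    nm <- as.character(df$name)
    at <- as.matrix(df[, c("a1", "a2", "a3", "a4")])
  }
  torsion_defs(nm, at)
}

#' Single-conformer 3D structure
#'
#' Minimal carrier of one conformer's geometry for dihedral extraction,
#' intramolecular hydrogen-bond detection and 3D polar surface area.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix `[n_atoms x 3]` of Cartesian coordinates (A).
#' @param bonds integer matrix `[n_bonds x 2]` (or `[n_bonds x 3]` with a bond
#'   order column) of 1-based atom index pairs. May have zero rows.
#' @param formal_charges integer vector, default all zero.
#' @return object of class `conformer_structure`.
#' @export
conformer_structure <- function(elements, coords, bonds = NULL,
                                formal_charges = NULL) {
  coords <- as.matrix(coords)
  n <- length(elements)
  if (nrow(coords) != n || ncol(coords) != 3L) {
    stop("conformer_structure: coords must be [n_atoms x 3]")
  }
  if (!all(is.finite(coords))) stop("conformer_structure: non-finite coordinates")
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2L)
  bonds <- as.matrix(bonds)
  if (nrow(bonds) > 0L && (any(bonds[, 1:2] < 1L) || any(bonds[, 1:2] > n))) {
    stop("conformer_structure: bond atom index out of range")
  }
  if (is.null(formal_charges)) formal_charges <- integer(n)
  structure(list(elements = as.character(elements),
                 coords = unname(coords),
                 bonds = bonds,
                 formal_charges = as.integer(formal_charges)),
            class = "conformer_structure")
}

#' Signed dihedral angle of four atoms
#'
#' Returns the torsion angle in degrees on (-180, 180] with the IUPAC sign
#' convention: looking from the second atom towards the third, a clockwise
#' rotation of the far bond relative to the near bond is positive. A planar
#' cis arrangement gives 0, anti gives 180.
#'
#' @param structure a [conformer_structure()].
#' @param quad integer vector of four distinct 1-based atom indices.
#' @return signed dihedral in degrees.
#' @export
compute_dihedral <- function(structure, quad) {
  quad <- as.integer(quad)
  if (length(quad) != 4L || anyDuplicated(quad)) {
    stop("compute_dihedral: quad must be four distinct atom indices")
  }
  n <- nrow(structure$coords)
  if (any(quad < 1L | quad > n)) {
    stop("compute_dihedral: atom index out of range (n_atoms = ", n, ")")
  }
  p <- structure$coords[quad, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18) {
    stop("compute_dihedral: degenerate dihedral (three collinear atoms)")
  }
  # atan2 of the projection onto (n1, n1 x b2-hat); standard signed torsion
  y <- sum(cross3(n1, b2 / sqrt(sum(b2^2))) * n2)
  x <- sum(n1 * n2)
  wrap_angle(rad2deg(atan2(-y, x)))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## ---------------------------------------------------------------------------
## TorsionEnsemble

#' Labelled matrix of ring dihedrals with per-conformer metadata
#'
#' The central container: one row per conformer, one column per torsion,
#' angles in degrees on (-180, 180]. Metadata records the origin of each
#' conformer (e.g. `"MD"` vs a generator label), run / starting-conformer /
#' solvent / charge tags, and optional relative energies in kcal/mol. A
#' per-torsion `mask` flags torsions that are undefined for this molecule
#' (e.g. a smaller ring lacking four of the reference torsions); masked
#' columns are carried, not dropped, so projection onto a full-width map
#' remains possible.
#'
#' @param angles numeric matrix `[n_conformers x n_torsions]`, degrees.
#'   Values are wrapped into (-180, 180] on construction.
#' @param torsion_names character vector of column labels.
#' @param meta data.frame with `n_conformers` rows; recognised columns are
#'   `origin`, `run`, `start`, `solvent`, `charge`. Missing columns are filled
#'   with `NA`. Extra columns are kept.
#' @param energies optional numeric vector of relative energies (kcal/mol).
#' @param mask logical vector, `TRUE` where the torsion is defined.
#' @return object of class `torsion_ensemble`.
#' @export
torsion_ensemble <- function(angles, torsion_names = NULL, meta = NULL,
                             energies = NULL, mask = NULL) {
  angles <- as.matrix(angles)
  if (nrow(angles) < 1L) stop("torsion_ensemble: no conformers")
  if (is.null(torsion_names)) {
    torsion_names <- colnames(angles)
    if (is.null(torsion_names)) torsion_names <- paste0("T", seq_len(ncol(angles)))
  }
  if (length(torsion_names) != ncol(angles)) {
    stop("torsion_ensemble: torsion_names length != ncol(angles)")
  }
  if (anyDuplicated(torsion_names)) stop("torsion_ensemble: duplicate torsion name")
  if (is.null(mask)) mask <- !apply(angles, 2L, function(c) all(is.na(c)))
  if (length(mask) != ncol(angles)) stop("torsion_ensemble: mask length mismatch")
  defined <- angles[, mask, drop = FALSE]
  if (any(!is.finite(defined))) {
    stop("torsion_ensemble: non-finite angle in a defined torsion column")
  }
  angles <- wrap_angle(angles)
  angles[, !mask] <- NA_real_
  dimnames(angles) <- list(NULL, torsion_names)
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(nrow(angles)))
  meta <- as.data.frame(meta)
  if (nrow(meta) != nrow(angles)) stop("torsion_ensemble: meta row mismatch")
  for (col in c("origin", "run", "start", "solvent", "charge")) {
    if (is.null(meta[[col]])) meta[[col]] <- NA_character_
  }
  if (!is.null(energies)) {
    energies <- as.numeric(energies)
    if (length(energies) != nrow(angles)) {
      stop("torsion_ensemble: energies length mismatch")
    }
    if (any(!is.finite(energies))) stop("torsion_ensemble: non-finite energy")
  }
  structure(list(angles = angles,
                 torsion_names = as.character(torsion_names),
                 meta = meta,
                 energies = energies,
                 mask = as.logical(mask)),
            class = "torsion_ensemble")
}

#' @export
print.torsion_ensemble <- function(x, ...) {
  cat("<torsion_ensemble> ", nrow(x$angles), " conformers x ",
      length(x$torsion_names), " torsions (",
      sum(x$mask), " defined)\n", sep = "")
  org <- table(x$meta$origin, useNA = "ifany")
  cat("  origins:", paste(names(org), org, sep = ":", collapse = "  "), "\n")
  if (!is.null(x$energies)) {
    cat(sprintf("  energies: [%.2f, %.2f] kcal/mol\n",
                min(x$energies), max(x$energies)))
  }
  invisible(x)
}

#' @export
dim.torsion_ensemble <- function(x) dim(x$angles)

#' Combine torsion ensembles row-wise
#'
#' All ensembles must share `torsion_names` and `mask`. Energies are kept only
#' if present in every part.
#'
#' @param ... `torsion_ensemble` objects.
#' @return a single `torsion_ensemble`.
#' @export
bind_ensembles <- function(...) {
  parts <- list(...)
  ref <- parts[[1L]]
  for (p in parts[-1L]) {
    if (!identical(p$torsion_names, ref$torsion_names) ||
        !identical(p$mask, ref$mask)) {
      stop("bind_ensembles: incompatible torsion names or masks")
    }
  }
  ang <- do.call(rbind, lapply(parts, `[[`, "angles"))
  meta_cols <- Reduce(intersect, lapply(parts, function(p) names(p$meta)))
  meta <- do.call(rbind, lapply(parts, function(p) p$meta[, meta_cols, drop = FALSE]))
  rownames(meta) <- NULL
  en <- lapply(parts, `[[`, "energies")
  energies <- if (any(vapply(en, is.null, logical(1)))) NULL else unlist(en)
  torsion_ensemble(ang, ref$torsion_names, meta, energies, ref$mask)
}

## ---------------------------------------------------------------------------
## Readers / writers

# metadata columns recognised in the dihedral CSV dialect, by name prefix
.reserved_prefixes <- c("origin", "run", "start", "solvent", "charge", "energy")

#' Read a dihedral table from CSV
#'
#' Dialect: comma-separated, mandatory header, '.' decimal, UTF-8. One row per
#' conformer. Columns whose names start with `origin`, `run`, `start`,
#' `solvent`, `charge` or `energy` are metadata; every other column is taken
#' as a torsion, and must be numeric. Angles are wrapped into (-180, 180].
#'
#' @param path CSV file path.
#' @param torsion_names optional full set of expected torsion labels; columns
#'   absent from the file get `mask = FALSE` (the undefined-torsion pathway).
#' @return a [torsion_ensemble()].
#' @export
read_dihedral_csv <- function(path, torsion_names = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("read_dihedral_csv: no conformers in ", path)
  if (anyDuplicated(names(df))) {
    stop("read_dihedral_csv: duplicate column name: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  }
  is_meta <- Reduce(`|`, lapply(.reserved_prefixes,
                                function(p) startsWith(names(df), p)))
  tors_cols <- names(df)[!is_meta]
  bad <- tors_cols[!vapply(df[tors_cols], is.numeric, logical(1))]
  if (length(bad)) {
    # locate the first offending cell for the error message
    col <- bad[[1L]]
    row <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
    stop("read_dihedral_csv: non-numeric angle in column '", col,
         "', row ", ifelse(is.na(row), 1L, row),
         " (offending columns: ", paste(bad, collapse = ", "), ")")
  }
  ang <- as.matrix(df[, tors_cols, drop = FALSE])
  meta <- df[, is_meta, drop = FALSE]
  energies <- NULL
  ecol <- names(meta)[startsWith(names(meta), "energy")]
  if (length(ecol)) {
    energies <- as.numeric(meta[[ecol[1L]]])
    meta <- meta[, setdiff(names(meta), ecol), drop = FALSE]
  }
  if (!is.null(torsion_names)) {
    full <- matrix(NA_real_, nrow(ang), length(torsion_names),
                   dimnames = list(NULL, torsion_names))
    known <- intersect(torsion_names, tors_cols)
    full[, known] <- ang[, known]
    extra <- setdiff(tors_cols, torsion_names)
    if (length(extra)) {
      warning("read_dihedral_csv: dropping unknown torsion columns: ",
              paste(extra, collapse = ", "))
    }
    mask <- torsion_names %in% known
    return(torsion_ensemble(full, torsion_names, meta, energies, mask))
  }
  torsion_ensemble(ang, tors_cols, meta, energies)
}

#' Write a torsion ensemble to the dihedral CSV dialect
#'
#' @param ensemble a [torsion_ensemble()]. Masked torsion columns are written
#'   as empty cells.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dihedral_csv <- function(ensemble, path) {
  df <- as.data.frame(ensemble$angles)
  meta <- ensemble$meta[, c("origin", "run", "start", "solvent", "charge"),
                        drop = FALSE]
  keep <- vapply(meta, function(c) !all(is.na(c)), logical(1))
  df <- cbind(df, meta[, keep, drop = FALSE])
  if (!is.null(ensemble$energies)) df$energy <- ensemble$energies
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a multi-record SDF into structures and a torsion ensemble
#'
#' Parses a multi-record V2000 SDF (via ChemmineR), computes each torsion of
#' `defs` for every record with [compute_dihedral()], and collects optional
#' per-record metadata from SDF data fields.
#'
#' @param path SDF file path (V2000 records; V3000 is rejected).
#' @param defs a [torsion_defs()] object.
#' @param meta_fields named character vector mapping metadata slots to SDF
#'   data field names, e.g. `c(origin = "ORIGIN", energy = "ENERGY")`.
#'   Recognised slots: origin, run, start, solvent, charge, energy.
#' @return list with `structures` (list of [conformer_structure()]) and
#'   `ensemble` (a [torsion_ensemble()]).
#' @export
read_ensemble_sdf <- function(path, defs,
                              meta_fields = c(origin = "origin",
                                              energy = "energy")) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("read_ensemble_sdf requires the ChemmineR package")
  }
  if (any(grepl("V3000", readLines(path, warn = FALSE), fixed = TRUE))) {
    stop("read_ensemble_sdf: V3000 records are not supported; ",
         "convert to V2000 first (e.g. with openbabel)")
  }
  sdfset <- ChemmineR::read.SDFset(path)
  n <- length(sdfset)
  if (n == 0L) stop("read_ensemble_sdf: no records in ", path)
  structures <- vector("list", n)
  T <- length(defs$names)
  ang <- matrix(NA_real_, n, T, dimnames = list(NULL, defs$names))
  meta_rows <- vector("list", n)
  energies <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    coords <- ab[, 1:3, drop = FALSE]
    elements <- sub("_.*$", "", rownames(ab))
    bb <- ChemmineR::bondblock(sdf)
    bonds <- if (nrow(bb) > 0L) cbind(as.integer(bb[, 1]), as.integer(bb[, 2]),
                                      as.integer(bb[, 3]))
             else matrix(integer(0), ncol = 3L)
    st <- tryCatch(conformer_structure(elements, coords, bonds),
                   error = function(e) stop("read_ensemble_sdf: malformed record ",
                                            i, ": ", conditionMessage(e)))
    structures[[i]] <- st
    for (t in seq_len(T)) {
      quad <- defs$atoms[t, ]
      if (any(quad > length(elements))) {
        stop("read_ensemble_sdf: atom index out of range for torsion '",
             defs$names[t], "' in record ", i)
      }
      ang[i, t] <- compute_dihedral(st, quad)
    }
    db <- ChemmineR::datablock(sdf)
    row <- list()
    for (slot in names(meta_fields)) {
      val <- if (meta_fields[[slot]] %in% names(db)) db[[meta_fields[[slot]]]] else NA
      if (slot == "energy") {
        energies[i] <- suppressWarnings(as.numeric(val))
      } else {
        row[[slot]] <- as.character(val)
      }
    }
    meta_rows[[i]] <- row
  }
  meta <- do.call(rbind, lapply(meta_rows, function(r) {
    as.data.frame(r[lengths(r) > 0], stringsAsFactors = FALSE)
  }))
  if (is.null(meta) || ncol(meta) == 0L) meta <- NULL
  energies <- if (all(is.na(energies))) NULL else energies
  ens <- torsion_ensemble(ang, defs$names, meta, energies)
  list(structures = structures, ensemble = ens)
}

#' Read an XYZ series (one frame per conformer)
#'
#' Plain multi-frame XYZ: each frame is an atom count line, a comment line,
#' then `element x y z` rows. Bonds are optionally inferred from covalent
#' radii (needed for hydrogen-bond detection on XYZ input, which carries no
#' bond table).
#'
#' @param path XYZ file path.
#' @param infer_bonds logical; connect atom pairs closer than
#'   `scale * (r_cov_i + r_cov_j)`.
#' @param scale bond-inference slack factor.
#' @return list of [conformer_structure()].
#' @export
read_xyz_series <- function(path, infer_bonds = TRUE, scale = 1.2) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("read_xyz_series: expected atom count at line ", i)
    if (i + 1L + nat > length(lines)) stop("read_xyz_series: truncated frame at line ", i)
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    elements <- vapply(parts, `[[`, character(1), 1L)
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    bonds <- if (infer_bonds) infer_bonds_by_distance(elements, coords, scale)
             else NULL
    out[[length(out) + 1L]] <- conformer_structure(elements, coords, bonds)
    i <- i + 2L + nat
  }
  if (!length(out)) stop("read_xyz_series: no frames in ", path)
  out
}

# single-bond covalent radii (A), Cordero-style values for common elements
.covalent_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                     P = 1.07, F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39)

infer_bonds_by_distance <- function(elements, coords, scale = 1.2) {
  r <- .covalent_radii[elements]
  if (any(is.na(r))) {
    stop("bond inference: no covalent radius for element ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  }
  n <- length(elements)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  d <- as.matrix(stats::dist(coords))
  cut <- outer(r, r, `+`) * scale
  hit <- which(d < cut & upper.tri(d), arr.ind = TRUE)
  matrix(c(hit[, 1L], hit[, 2L]), ncol = 2L)
}

#' Extract a torsion ensemble from a list of structures
#'
#' @param structures list of [conformer_structure()].
#' @param defs a [torsion_defs()].
#' @param meta,energies forwarded to [torsion_ensemble()].
#' @return a [torsion_ensemble()].
#' @export
ensemble_from_structures <- function(structures, defs, meta = NULL,
                                     energies = NULL) {
  ang <- t(vapply(structures, function(st) {
    vapply(seq_along(defs$names),
           function(t) compute_dihedral(st, defs$atoms[t, ]), numeric(1))
  }, numeric(length(defs$names))))
  if (length(defs$names) == 1L) ang <- matrix(ang, ncol = 1L)
  torsion_ensemble(ang, defs$names, meta, energies)
}
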