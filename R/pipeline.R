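#' Assemble and validate a pipeline run configuration
#'
#' Defaults follow the published analysis protocol: 8 leading components for
#' clustering and dispersion statistics, 500 clusters with 25 random starts
#' and 1000 iterations, 10000 permutations, energy thresholds 6/10/100
#' kcal/mol, Mahalanobis curves over dimensions 2..K.
#'
#' @param inputs named list of input specifications. Each entry is a list
#'   with `path` (dihedral CSV) and `role` (`"reference"` for the ensemble
#'   the map is fitted on, `"comparison"` otherwise). Exactly one reference
#'   is required. Alternatively each entry may carry an `ensemble` (a
#'   [torsion_ensemble()]) directly.
#' @param out_dir output directory (created if absent).
#' @param torsion_names optional full torsion label set for CSV ingest.
#' @param n_pcs,k,restarts,max_iter,n_perm,energy_low,energy_high,
#'   energy_discard,mahalanobis_dims,seed numeric parameters; see details.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(inputs, out_dir = "confcover_out",
                       torsion_names = NULL,
                       n_pcs = 8L, k = 500L, restarts = 25L,
                       max_iter = 1000L, n_perm = 10000L,
                       energy_low = 6.0, energy_high = 10.0,
                       energy_discard = 100.0,
                       mahalanobis_dims = NULL, seed = 1L) {
  if (!length(inputs)) stop("run_config: no inputs", call. = FALSE)
  roles <- vapply(inputs, function(i) i$role %||% "comparison", character(1))
  if (sum(roles == "reference") != 1L) {
    stop("run_config: exactly one input must have role 'reference'",
         call. = FALSE)
  }
  num <- c(n_pcs = n_pcs, k = k, restarts = restarts, max_iter = max_iter,
           n_perm = n_perm, energy_low = energy_low,
           energy_high = energy_high, energy_discard = energy_discard)
  if (any(num <= 0)) {
    stop("run_config: non-positive parameter: ",
         paste(names(num)[num <= 0], collapse = ", "), call. = FALSE)
  }
  structure(list(inputs = inputs, out_dir = out_dir,
                 torsion_names = torsion_names,
                 n_pcs = as.integer(n_pcs), k = as.integer(k),
                 restarts = as.integer(restarts),
                 max_iter = as.integer(max_iter),
                 n_perm = as.integer(n_perm),
                 energy_low = energy_low, energy_high = energy_high,
                 energy_discard = energy_discard,
                 mahalanobis_dims = mahalanobis_dims,
                 seed = as.integer(seed)),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a run configuration from YAML
#'
#' YAML keys mirror the [run_config()] arguments; `inputs` is a list of
#' `{name, path, role}` entries.
#'
#' @param path YAML file path.
#' @param ... overrides forwarded to [run_config()].
#' @return a `run_config`.
#' @export
load_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  inputs <- y$inputs
  names(inputs) <- vapply(inputs, function(i) i$name %||% i$path, character(1))
  args <- y[setdiff(names(y), c("inputs"))]
  args$inputs <- inputs
  over <- list(...)
  args[names(over)] <- over
  do.call(run_config, args)
}

#' Run the complete ensemble-coverage pipeline
#'
#' Stages: ingest dihedral tables -> sin/cos embedding -> PCA map fit on the
#' reference ensemble -> projection of all ensembles -> cluster mixing,
#' variance curves, Mahalanobis coverage (one curve per comparison ensemble,
#' comparison as training set), dispersion permutation test -> energy bins
#' where energies are present -> serialized reports and a summary JSON.
#' Every output is a pure function of (inputs, config, seed).
#'
#' @param config a [run_config()] (or a YAML path accepted by
#'   [load_run_config()]).
#' @return invisibly, a list with the in-memory results (`map`, `coords`,
#'   `cluster_overlap`, `variance`, `mahalanobis`, `dispersion`, `energy`,
#'   `summary`); files are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ensembles <- stage("ingest", {
    lapply(config$inputs, function(inp) {
      ens <- if (!is.null(inp$ensemble)) inp$ensemble
             else read_dihedral_csv(inp$path, config$torsion_names)
      if (all(is.na(ens$meta$origin))) {
        ens$meta$origin <- inp$name %||% "ensemble"
      }
      ens
    })
  })
  nm <- names(config$inputs)
  if (is.null(nm)) nm <- paste0("ensemble", seq_along(ensembles))
  names(ensembles) <- nm
  roles <- vapply(config$inputs, function(i) i$role %||% "comparison",
                  character(1))
  ref_name <- nm[roles == "reference"]

  features <- stage("embed", lapply(ensembles, to_sincos))
  map <- stage("fit_map", fit_map(features[[ref_name]], fitted_on = ref_name))
  coords <- stage("project", lapply(nm, function(x) {
    project(map, features[[x]], group_labels = x)
  }))
  names(coords) <- nm
  all_coords <- do.call(bind_coords, unname(coords))
  all_angles <- do.call(rbind, lapply(ensembles, `[[`, "angles"))

  k_eff <- min(config$k, nrow(all_coords$scores) %/% 2L)
  clu <- stage("cluster_overlap",
               kmeans_overlap(all_coords, n_pcs = config$n_pcs, k = k_eff,
                              restarts = config$restarts,
                              max_iter = config$max_iter,
                              seed = config$seed, angles = all_angles))
  varc <- stage("variance_curves", variance_curves(coords))
  mah <- stage("mahalanobis", {
    out <- list()
    for (cmp in setdiff(nm, ref_name)) {
      dims <- config$mahalanobis_dims %||%
        seq(2L, min(ncol(coords[[cmp]]$scores),
                    nrow(coords[[cmp]]$scores) - 1L))
      out[[cmp]] <- mahalanobis_coverage(coords[[cmp]], coords[[ref_name]],
                                         dims = dims)
    }
    out
  })
  disp <- stage("dispersion",
                dispersion_test(all_coords, n_pcs = config$n_pcs,
                                n_perm = config$n_perm, seed = config$seed))
  energy <- stage("energy_bins", {
    out <- list()
    for (x in nm) {
      if (!is.null(ensembles[[x]]$energies)) {
        out[[x]] <- bin_energies(ensembles[[x]]$energies,
                                 ensembles[[x]]$meta$run,
                                 low = config$energy_low,
                                 high = config$energy_high,
                                 discard_above = config$energy_discard)
      }
    }
    out
  })

  stage("write_outputs", {
    write_map(map, file.path(config$out_dir, "map.json"))
    for (x in nm) {
      write_scores_csv(coords[[x]], file.path(config$out_dir,
                                              paste0("scores_", x, ".csv")))
    }
    utils::write.csv(clu$per_cluster,
                     file.path(config$out_dir, "cluster_overlap.csv"),
                     row.names = FALSE)
    utils::write.csv(varc, file.path(config$out_dir, "variance_curves.csv"),
                     row.names = FALSE)
    for (cmp in names(mah)) {
      utils::write.csv(mah[[cmp]]$curve,
                       file.path(config$out_dir,
                                 paste0("mahalanobis_", cmp, ".csv")),
                       row.names = FALSE)
    }
  })

  summary <- list(
    parameters = config[c("n_pcs", "k", "restarts", "max_iter", "n_perm",
                          "energy_low", "energy_high", "energy_discard",
                          "seed")],
    inputs = lapply(seq_along(nm), function(i) {
      list(name = nm[i], role = roles[i],
           n_conformers = nrow(ensembles[[i]]$angles))
    }),
    map = list(fitted_on = ref_name,
               n_components = length(map$eigenvalues),
               cumulative_variance = cumsum(map$explained_fraction)),
    cluster_overlap = list(k = k_eff, n_clusters = clu$n_clusters,
                           n_mixed = clu$n_mixed,
                           n_unique_per_origin = as.list(clu$n_unique_per_origin),
                           overall_max_rmsd = clu$overall_max_rmsd,
                           overall_median_rmsd = clu$overall_median_rmsd),
    mahalanobis = lapply(mah, function(m) m$curve),
    dispersion = list(F_statistic = disp$F_statistic,
                      permutation_p = disp$permutation_p,
                      per_group_mean_distance =
                        as.list(disp$per_group_mean_distance),
                      pairwise = disp$pairwise),
    energy_bins = lapply(energy, function(e) as.list(table(e$bin))))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(map = map, coords = coords, cluster_overlap = clu,
                 variance = varc, mahalanobis = mah, dispersion = disp,
                 energy = energy, summary = summary))
}
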