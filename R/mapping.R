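#' Configuration for a topographic mapping run
#'
#' Collects every tunable of the SVR mapping chain with the defaults used at
#' full study scale. `c = NULL` triggers grid optimization over `c_grid`.
#'
#' @param c Fixed SVR cost, or `NULL` to optimize over `c_grid`.
#' @param c_grid Cost grid for optimization (powers of two, 2^-20 .. 2^20).
#' @param folds,repeats Cross-validation layout for cost selection.
#' @param n_permutations Label permutations for voxel p-values (25000 at
#'   full scale).
#' @param q Benjamini-Hochberg FDR level. Default 0.05.
#' @param min_cluster Minimum cluster extent kept (voxels). Default 20.
#' @param connectivity Cluster connectivity (6, 18 or 26). Default 26.
#' @param tail Permutation tail; see [permutation_pmap()].
#' @param kernel `"linear"` (required for voxel-wise inference).
#' @param epsilon SVR epsilon. Default 0.1.
#' @param covariate_strategy See [apply_covariate_control()].
#' @param cv_seed,perm_seed Seeds for fold shuffling and permutations.
#' @return A list of class `mapping_config`.
#' @export
mapping_config <- function(c = NULL, c_grid = 2^(-20:20), folds = 5L,
                           repeats = 5L, n_permutations = 25000L, q = 0.05,
                           min_cluster = 20L, connectivity = 26L,
                           tail = "negative", kernel = "linear",
                           epsilon = 0.1, covariate_strategy = "none",
                           cv_seed = 1L, perm_seed = 1L) {
  cfg <- list(c = c, c_grid = c_grid, folds = as.integer(folds),
              repeats = as.integer(repeats),
              n_permutations = as.integer(n_permutations), q = q,
              min_cluster = as.integer(min_cluster),
              connectivity = as.integer(connectivity), tail = tail,
              kernel = kernel, epsilon = epsilon,
              covariate_strategy = covariate_strategy,
              cv_seed = as.integer(cv_seed), perm_seed = as.integer(perm_seed))
  class(cfg) <- "mapping_config"
  cfg
}

#' Read a mapping configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [mapping_config()]
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `mapping_config`.
#' @export
mapping_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(mapping_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(mapping_config, vals)
}

#' Run the full SVR topographic mapping chain
#'
#' Chains covariate control, cost selection (or a fixed cost), the
#' full-cohort linear SVR fit, permutation p-values, Benjamini-Hochberg FDR
#' selection and minimum-cluster filtering. The binary-lesion variant of the
#' analysis is the same call with a 0/1 feature matrix.
#'
#' @param dataset A [skeleton_dataset] (voxel bookkeeping requires one; a
#'   plain matrix is accepted only with `voxel_index` supplied).
#' @param scores Behavioural scores, one per subject.
#' @param config A [mapping_config()].
#' @param covariate Optional covariate vector (required when the config's
#'   `covariate_strategy` is not `"none"`).
#' @return An object of class `mapping_result`: `weights`, `p_values`,
#'   `p_threshold`, `sig_mask_raw` and `sig_mask_filtered` ([volume]s),
#'   `trace` (a `hyperparameter_trace` or `NULL`), `chosen_c`, `config`,
#'   `voxel_index`, `zero_variance`.
#' @export
run_mapping <- function(dataset, scores, config = mapping_config(),
                        covariate = NULL) {
  stopifnot(inherits(config, "mapping_config"))
  if (!inherits(dataset, "skeleton_dataset"))
    stop("dataset must be a skeleton_dataset (build one with extract_matrix)",
         call. = FALSE)
  if (config$n_permutations < 1L)
    stop("n_permutations must be >= 1", call. = FALSE)
  if (config$kernel != "linear")
    stop("voxel-wise inference requires the linear kernel; ",
         "use fit_svr directly for rbf predictions", call. = FALSE)
  vind <- dataset$voxel_index

  adj <- apply_covariate_control(scores, dataset, covariate,
                                 config$covariate_strategy)
  y <- adj$scores
  if (stats::sd(y) < 1e-12)
    stop("degenerate input: adjusted scores are constant", call. = FALSE)
  X <- adj$features

  trace <- NULL
  chosen_c <- config$c
  if (is.null(chosen_c)) {
    trace <- optimize_c(X, y, config$c_grid, config$folds, config$repeats,
                        seed = config$cv_seed, epsilon = config$epsilon)
    chosen_c <- trace$chosen_c
  }

  perm <- permutation_pmap(X, y, c = chosen_c,
                           n_permutations = config$n_permutations,
                           seed = config$perm_seed, tail = config$tail,
                           epsilon = config$epsilon)
  sel <- fdr_select(perm$p_values, config$q)
  sig_raw <- project_map(as.numeric(sel$significant), vind)
  sig_filt <- filter_clusters(sig_raw, config$min_cluster, config$connectivity)

  structure(list(weights = perm$weights, p_values = perm$p_values,
                 p_threshold = sel$p_threshold, fdr_q = config$q,
                 sig_mask_raw = sig_raw, sig_mask_filtered = sig_filt,
                 trace = trace, chosen_c = chosen_c, config = config,
                 voxel_index = vind, zero_variance = perm$zero_variance),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat("<mapping_result> ", length(x$p_values), " voxels | C = ",
      format(x$chosen_c), " | FDR q = ", x$fdr_q,
      " (p threshold ", format(x$p_threshold), ")\n  significant: ",
      sum(x$sig_mask_raw$data), " raw, ", sum(x$sig_mask_filtered$data),
      " after cluster filter (>= ", x$config$min_cluster, " voxels)\n",
      sep = "")
  invisible(x)
}

#' Write a mapping result to a directory
#'
#' Writes the weight, p-value and raw/filtered significance maps as NIfTI,
#' the hyperparameter trace as TSV (if the cost was optimized), and a JSON
#' run manifest with all seeds and parameters.
#'
#' @param result A [run_mapping()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mapping_result <- function(result, dir) {
  stopifnot(inherits(result, "mapping_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vind <- result$voxel_index
  write_volume(project_map(result$weights, vind),
               file.path(dir, "weights.nii.gz"))
  write_volume(project_map(result$p_values, vind, fill = 1),
               file.path(dir, "p_values.nii.gz"))
  write_volume(result$sig_mask_raw, file.path(dir, "sig_raw.nii.gz"))
  write_volume(result$sig_mask_filtered, file.path(dir, "sig_filtered.nii.gz"))
  if (!is.null(result$trace))
    utils::write.table(result$trace$trace, file.path(dir, "c_trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- result$config
  class(manifest) <- NULL
  manifest$chosen_c <- result$chosen_c
  manifest$p_threshold <- result$p_threshold
  jsonlite::write_json(manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
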