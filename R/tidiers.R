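#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a hyperparameter trace
#'
#' @param x A `hyperparameter_trace`.
#' @param ... Unused.
#' @return The per-cost tibble (`c`, `log2_c`, `fit_r2`,
#'   `reproducibility_r`, `score`).
#' @export
tidy.hyperparameter_trace <- function(x, ...) x$trace

#' @export
glance.hyperparameter_trace <- function(x, ...) {
  at <- x$trace[x$trace$c == x$chosen_c, ]
  tibble::tibble(chosen_c = x$chosen_c, log2_chosen_c = log2(x$chosen_c),
                 fit_r2 = at$fit_r2, reproducibility_r = at$reproducibility_r,
                 folds = x$folds, repeats = x$repeats, cv_seed = x$cv_seed)
}

#' Per-voxel tidy table of a mapping result
#'
#' @param x A `mapping_result`.
#' @param ... Unused.
#' @return Tibble with 0-based voxel coordinates, weight, p-value and
#'   raw/filtered significance flags.
#' @export
tidy.mapping_result <- function(x, ...) {
  co <- x$voxel_index$coords
  lin <- linear_index(co, x$voxel_index$shape)
  tibble::tibble(i = co[, 1], j = co[, 2], k = co[, 3],
                 weight = x$weights, p_value = x$p_values,
                 significant = x$sig_mask_raw$data[lin] != 0,
                 significant_filtered = x$sig_mask_filtered$data[lin] != 0,
                 zero_variance = x$zero_variance)
}

#' @export
glance.mapping_result <- function(x, ...) {
  tibble::tibble(n_voxels = length(x$p_values), chosen_c = x$chosen_c,
                 fdr_q = x$fdr_q, p_threshold = x$p_threshold,
                 n_significant_raw = sum(x$sig_mask_raw$data),
                 n_significant_filtered = sum(x$sig_mask_filtered$data),
                 min_cluster = x$config$min_cluster,
                 n_permutations = x$config$n_permutations,
                 tail = x$config$tail)
}

#' Tidy a disconnection matrix into an edge list
#'
#' @param x A `disconnection_matrix`.
#' @param ... Unused.
#' @return The full edge list from [report_edges()] at `min_count = 0`.
#' @export
tidy.disconnection_matrix <- function(x, ...) report_edges(x, 0L)

#' @export
glance.disconnection_matrix <- function(x, ...) {
  ut <- upper.tri(x$total_counts, diag = TRUE)
  tibble::tibble(n_regions = length(x$labels),
                 n_streamlines = sum(x$total_counts[ut]),
                 n_crossing = sum(x$crossing_counts[ut]),
                 n_unassigned = x$n_unassigned,
                 n_unassigned_crossing = x$n_unassigned_crossing)
}

#' Plot the hyperparameter selection trace
#'
#' Model fit (squared held-out correlation) and feature-weight
#' reproducibility against log2 of the SVR cost, with the chosen cost
#' marked.
#'
#' @param object A `hyperparameter_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hyperparameter_trace <- function(object, ...) {
  tr <- object$trace
  long <- rbind(
    data.frame(log2_c = tr$log2_c, value = tr$fit_r2,
               criterion = "model fit (r²)"),
    data.frame(log2_c = tr$log2_c, value = tr$reproducibility_r,
               criterion = "weight reproducibility (r)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$log2_c, y = .data$value,
                                     colour = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = log2(object$chosen_c),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(log[2] ~ C), y = NULL, colour = NULL,
                  title = "SVR cost selection") +
    ggplot2::theme_minimal()
}

#' Plot the voxel p-value distribution of a mapping result
#'
#' Histogram of permutation p-values with the Benjamini-Hochberg threshold
#' marked; a spike near zero reflects voxels driving the behavioural score.
#'
#' @param object A `mapping_result`.
#' @param bins Histogram bins. Default 40.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mapping_result <- function(object, bins = 40, ...) {
  df <- data.frame(p = object$p_values)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey40") +
    ggplot2::labs(x = "permutation p-value", y = "voxels",
                  title = "Voxel-wise permutation p-values") +
    ggplot2::theme_minimal()
  if (object$p_threshold > 0)
    gg <- gg + ggplot2::geom_vline(xintercept = object$p_threshold,
                                   colour = "red", linetype = "dashed")
  gg
}

#' @importFrom rlang .data
NULL
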