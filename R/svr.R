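#' @importFrom methods new
NULL

as_feature_matrix <- function(dataset) {
  if (inherits(dataset, "skeleton_dataset")) dataset$features
  else as.matrix(dataset)
}

check_scores <- function(scores, n) {
  scores <- as.numeric(scores)
  if (length(scores) != n)
    stop("scores length (", length(scores),
         ") does not match number of subjects (", n, ")", call. = FALSE)
  if (anyNA(scores) || any(!is.finite(scores)))
    stop("scores contain missing or non-finite values", call. = FALSE)
  if (stats::sd(scores) < 1e-12)
    stop("degenerate input: scores are constant", call. = FALSE)
  scores
}

# epsilon-SVR on a precomputed linear Gram matrix; returns the dual
# coefficient vector (alpha_i - alpha_i*) over all subjects and the
# intercept, so that prediction = K[new, ] %*% alpha + intercept.
# kernlab's b is the negative offset (f(x) = sum alpha K - b).
svr_dual <- function(K, y, c, epsilon) {
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "eps-svr",
                     C = c, epsilon = epsilon, scaled = FALSE)
  a <- rep(0, nrow(K))
  a[kernlab::alphaindex(m)] <- kernlab::alpha(m)
  list(alpha = a, intercept = -kernlab::b(m))
}

#' Fit a support vector regression of behaviour on voxel features
#'
#' Fits an epsilon-SVR predicting the behavioural score from the
#' subjects-by-voxels feature matrix. With the linear kernel the primal
#' weight vector `w` (one weight per voxel, the quantity the permutation
#' inference operates on) and intercept `b` are recovered, so that
#' `prediction = X w + b`. With the RBF kernel only predictions are exposed.
#' Binary-lesion mapping is the same call with a 0/1 feature matrix.
#'
#' @param dataset A [skeleton_dataset] or plain numeric matrix
#'   (subjects x voxels).
#' @param scores Numeric behavioural scores, one per subject.
#' @param c SVR cost parameter (> 0). Default 1.
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param epsilon SVR epsilon-tube half-width. Default 0.1.
#' @return An object of class `svr_fit`: `weights` (linear only, else `NA`),
#'   `intercept`, `fitted`, `kernel`, `c`, `epsilon`.
#' @export
fit_svr <- function(dataset, scores, c = 1, kernel = c("linear", "rbf"),
                    epsilon = 0.1) {
  kernel <- match.arg(kernel)
  X <- as_feature_matrix(dataset)
  if (nrow(X) < 3L)
    stop("need at least 3 subjects", call. = FALSE)
  if (c <= 0)
    stop("c must be > 0", call. = FALSE)
  if (anyNA(X) || any(!is.finite(X)))
    stop("feature matrix contains missing or non-finite values", call. = FALSE)
  y <- check_scores(scores, nrow(X))
  if (kernel == "linear") {
    K <- tcrossprod(X)
    fit <- svr_dual(K, y, c, epsilon)
    w <- drop(crossprod(X, fit$alpha))
    fitted <- drop(K %*% fit$alpha) + fit$intercept
    out <- list(weights = w, intercept = fit$intercept, alpha = fit$alpha,
                fitted = fitted, kernel = kernel, c = c, epsilon = epsilon)
  } else {
    m <- kernlab::ksvm(X, y, type = "eps-svr", kernel = "rbfdot",
                       C = c, epsilon = epsilon, scaled = FALSE)
    out <- list(weights = NA, intercept = NA, model = m,
                fitted = as.numeric(kernlab::predict(m, X)),
                kernel = kernel, c = c, epsilon = epsilon)
  }
  class(out) <- "svr_fit"
  out
}

#' @export
print.svr_fit <- function(x, ...) {
  cat("<svr_fit> ", x$kernel, " kernel, C = ", format(x$c),
      ", epsilon = ", x$epsilon, "\n", sep = "")
  invisible(x)
}

#' @export
predict.svr_fit <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  if (object$kernel == "linear")
    drop(X %*% object$weights) + object$intercept
  else
    as.numeric(kernlab::predict(object$model, X))
}

# deterministic fold assignment: repeats x subjects matrix of fold ids
make_folds <- function(n, folds, repeats, seed) {
  set.seed(seed)
  out <- matrix(NA_integer_, repeats, n)
  base <- rep(seq_len(folds), length.out = n)
  for (r in seq_len(repeats)) out[r, ] <- sample(base)
  out
}

#' Cross-validated model fit and feature-weight reproducibility for one C
#'
#' Runs repeated k-fold cross-validation at a fixed cost `c`. Model fit is
#' the mean over all folds of the squared Pearson correlation between
#' held-out predictions and observed scores; reproducibility is the mean
#' Pearson correlation of the training-subset weight vectors over all
#' unordered pairs of the `folds * repeats` models.
#'
#' @inheritParams fit_svr
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeats (default 5).
#' @param seed Seed for the fold shuffling.
#' @return List with `fit_r2`, `reproducibility_r`, `fold_r` (per-fold
#'   held-out correlations), `n_models`.
#' @export
evaluate_c <- function(dataset, scores, c = 1, folds = 5L, repeats = 5L,
                       seed = 1L, epsilon = 0.1) {
  X <- as_feature_matrix(dataset)
  n <- nrow(X)
  if (n < folds)
    stop("need at least as many subjects as folds", call. = FALSE)
  y <- check_scores(scores, n)
  K <- tcrossprod(X)
  fold_ids <- make_folds(n, folds, repeats, seed)
  fold_r <- numeric(0)
  Ws <- list()
  for (r in seq_len(repeats)) {
    for (f in seq_len(folds)) {
      test <- which(fold_ids[r, ] == f)
      train <- setdiff(seq_len(n), test)
      if (stats::sd(y[train]) < 1e-12) {
        warning("fold skipped: constant training scores")
        next
      }
      fit <- svr_dual(K[train, train, drop = FALSE], y[train], c, epsilon)
      Ws[[length(Ws) + 1L]] <- drop(crossprod(X[train, , drop = FALSE],
                                              fit$alpha))
      pred <- drop(K[test, train, drop = FALSE] %*% fit$alpha) + fit$intercept
      if (length(test) >= 2L && stats::sd(y[test]) > 1e-12 &&
          stats::sd(pred) > 1e-12) {
        fold_r <- c(fold_r, stats::cor(pred, y[test]))
      } else {
        warning("fold skipped in fit evaluation: constant held-out scores ",
                "or predictions")
      }
    }
  }
  fit_r2 <- if (length(fold_r)) mean(fold_r^2) else NA_real_
  nm <- length(Ws)
  rep_r <- NA_real_
  if (nm >= 2L) {
    W <- do.call(cbind, Ws)
    sds <- apply(W, 2, stats::sd)
    if (all(sds > 1e-15)) {
      cors <- stats::cor(W)
      rep_r <- mean(cors[upper.tri(cors)])
    }
  }
  list(fit_r2 = fit_r2, reproducibility_r = rep_r, fold_r = fold_r,
       n_models = nm)
}

#' Select the SVR cost by model fit and weight reproducibility
#'
#' Evaluates [evaluate_c()] on every grid value and picks the cost that
#' maximizes the selection rule. The default rule sums the min-max-normalized
#' fit and reproducibility across the grid; ties go to the smaller cost.
#'
#' @inheritParams evaluate_c
#' @param c_grid Cost grid; default powers of two from 2^-20 to 2^20.
#' @param rule `"normalized_sum"` (default), `"fit"` or `"reproducibility"`.
#' @return An object of class `hyperparameter_trace`: tibble `trace`
#'   (`c`, `log2_c`, `fit_r2`, `reproducibility_r`, `score`), `chosen_c`,
#'   `folds`, `repeats`, `cv_seed`.
#' @export
optimize_c <- function(dataset, scores, c_grid = 2^(-20:20), folds = 5L,
                       repeats = 5L, seed = 1L, epsilon = 0.1,
                       rule = c("normalized_sum", "fit", "reproducibility")) {
  rule <- match.arg(rule)
  if (length(c_grid) == 0L)
    stop("c_grid must be nonempty", call. = FALSE)
  c_grid <- sort(as.numeric(c_grid))
  evals <- lapply(c_grid, function(cc)
    evaluate_c(dataset, scores, cc, folds, repeats, seed, epsilon))
  fit <- vapply(evals, `[[`, numeric(1), "fit_r2")
  rep_r <- vapply(evals, `[[`, numeric(1), "reproducibility_r")
  norm01 <- function(x) {
    rng <- range(x, na.rm = TRUE)
    if (!is.finite(rng[1]) || diff(rng) < 1e-15) return(rep(0, length(x)))
    out <- (x - rng[1]) / diff(rng)
    out[is.na(out)] <- 0
    out
  }
  score <- switch(rule,
                  normalized_sum = norm01(fit) + norm01(rep_r),
                  fit = ifelse(is.na(fit), -Inf, fit),
                  reproducibility = ifelse(is.na(rep_r), -Inf, rep_r))
  chosen <- c_grid[which.max(score)]  # which.max takes the first (smallest c) tie
  structure(list(trace = tibble::tibble(c = c_grid, log2_c = log2(c_grid),
                                        fit_r2 = fit,
                                        reproducibility_r = rep_r,
                                        score = score),
                 chosen_c = chosen, folds = as.integer(folds),
                 repeats = as.integer(repeats), cv_seed = as.integer(seed),
                 rule = rule),
            class = "hyperparameter_trace")
}

#' @export
print.hyperparameter_trace <- function(x, ...) {
  cat("<hyperparameter_trace> ", nrow(x$trace), " grid values, chosen C = 2^",
      format(log2(x$chosen_c)), "\n", sep = "")
  invisible(x)
}

# all permutations of 1..n as an n! x n matrix (small n only)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

count_extreme <- function(W_perm, w_obs, tail) {
  # W_perm: voxels x perms; returns per-voxel count of permutation weights
  # at least as extreme as the observed weight. Equality is judged with a
  # small relative tolerance so that genuinely tied weights (e.g. the
  # identity permutation) count as ties regardless of BLAS accumulation
  # order.
  eps <- 1e-8 * (1 + abs(w_obs))
  switch(tail,
         negative = rowSums(W_perm <= w_obs + eps),
         positive = rowSums(W_perm >= w_obs - eps),
         two_sided = rowSums(abs(W_perm) >= abs(w_obs) - eps))
}

#' Permutation p-values for SVR feature weights
#'
#' Computes the observed per-voxel weights once, then refits the SVR on
#' datasets pairing the original features with permuted scores and assigns
#' each voxel the rank-based p-value of its observed weight among the
#' permutation weights. With sampling, add-one smoothing is used:
#' `p = (1 + #extreme) / (n_permutations + 1)`. With `exhaustive = TRUE`
#' all `n!` permutations (identity included) are enumerated and
#' `p = #extreme / n!`.
#'
#' Zero-variance voxels (e.g. FA identically zero across subjects inside
#' lesion cores) are retained in the model but their p-value is reported
#' as 1 and they are flagged.
#'
#' @inheritParams fit_svr
#' @param n_permutations Number of sampled permutations (>= 1); 25000 at the
#'   full scale of a real study.
#' @param seed Seed for the permutation sampling.
#' @param tail `"negative"` (count permutation weights <= observed),
#'   `"positive"` (>=) or `"two_sided"` (|perm| >= |obs|). Default
#'   `"negative"`.
#' @param exhaustive Enumerate all `n!` permutations instead of sampling
#'   (only for small cohorts, `n <= 8`).
#' @param block Permutations per weight-matrix block (memory control).
#' @return List with `p_values`, `weights` (observed), `n_permutations`,
#'   `tail`, `zero_variance` (logical flags), `seed`.
#' @export
permutation_pmap <- function(dataset, scores, c = 1, n_permutations = 25000L,
                             seed = 1L, tail = c("negative", "positive",
                                                 "two_sided"),
                             epsilon = 0.1, exhaustive = FALSE, block = 500L) {
  tail <- match.arg(tail)
  X <- as_feature_matrix(dataset)
  n <- nrow(X)
  y <- check_scores(scores, n)
  if (!exhaustive && n_permutations < 1L)
    stop("n_permutations must be >= 1", call. = FALSE)
  K <- tcrossprod(X)
  obs <- svr_dual(K, y, c, epsilon)
  w_obs <- drop(crossprod(X, obs$alpha))
  zero_var <- apply(X, 2, stats::sd) < 1e-12

  if (exhaustive) {
    if (n > 8L)
      stop("exhaustive enumeration is limited to n <= 8 subjects",
           call. = FALSE)
    P <- all_permutations(n)
    A <- matrix(0, n, nrow(P))
    for (k in seq_len(nrow(P))) {
      fit <- svr_dual(K, y[P[k, ]], c, epsilon)
      A[, k] <- fit$alpha
    }
    W <- crossprod(X, A)
    counts <- count_extreme(W, w_obs, tail)
    p <- counts / nrow(P)
    n_perm <- nrow(P)
  } else {
    set.seed(seed)
    counts <- numeric(ncol(X))
    done <- 0L
    while (done < n_permutations) {
      nb <- min(block, n_permutations - done)
      A <- matrix(0, n, nb)
      for (k in seq_len(nb)) {
        fit <- svr_dual(K, y[sample.int(n)], c, epsilon)
        A[, k] <- fit$alpha
      }
      counts <- counts + count_extreme(crossprod(X, A), w_obs, tail)
      done <- done + nb
    }
    p <- (1 + counts) / (n_permutations + 1)
    n_perm <- n_permutations
  }
  p[zero_var] <- 1
  list(p_values = p, weights = w_obs, n_permutations = n_perm, tail = tail,
       zero_variance = zero_var, seed = if (exhaustive) NA_integer_ else seed)
}

#' Benjamini-Hochberg selection of significant voxels
#'
#' Literal step-up procedure: sort the m p-values ascending, find the largest
#' k with `p_(k) <= k q / m`; the threshold is `p_(k)` (or 0, marking nothing
#' significant, when no such k exists) and all p-values at or below it are
#' flagged.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param q FDR level. Default 0.05.
#' @return List with `p_threshold` and logical `significant`.
#' @export
fdr_select <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L)
    stop("degenerate input: empty p-value vector", call. = FALSE)
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  m <- length(p_values)
  ps <- sort(p_values)
  ok <- which(ps <= seq_len(m) * q / m)
  thr <- if (length(ok)) ps[max(ok)] else 0
  list(p_threshold = thr, significant = p_values <= thr)
}

#' Remove small clusters from a binary volume
#'
#' Labels connected components of the nonzero voxels (26-connectivity by
#' default) and zeroes every component smaller than `min_cluster` voxels.
#' Idempotent.
#'
#' @param sig_volume Binary [volume].
#' @param min_cluster Minimum surviving component size in voxels. Default 20.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (all neighbours).
#' @return A binary [volume] of the surviving components.
#' @export
filter_clusters <- function(sig_volume, min_cluster = 20L, connectivity = 26L) {
  stopifnot(inherits(sig_volume, "volume"))
  stopifnot_binary(sig_volume, "sig_volume")
  shape <- sig_volume$shape
  lin <- which(sig_volume$data != 0)
  out <- array(0, dim = shape)
  if (length(lin) == 0L) return(volume(out, sig_volume$affine))
  offsets <- neighbour_offsets(shape, connectivity)
  pos <- match(seq_len(prod(shape)), lin)  # linear index -> vertex id
  edges <- integer(0)
  for (o in seq_along(offsets$delta)) {
    nb <- lin + offsets$delta[o]
    ok <- valid_neighbours_vec(lin, shape, offsets$d[o, ])
    ok <- ok & nb >= 1L & nb <= prod(shape)
    tgt <- rep(NA_integer_, length(lin))
    tgt[ok] <- pos[nb[ok]]
    has <- which(!is.na(tgt))
    if (length(has))
      edges <- c(edges, rbind(has, tgt[has]))
  }
  g <- igraph::make_empty_graph(n = length(lin), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  keep <- comp$membership %in% which(comp$csize >= min_cluster)
  out[lin[keep]] <- 1
  volume(out, sig_volume$affine)
}

# vectorized edge-validity check for one offset triple
valid_neighbours_vec <- function(lin, shape, d) {
  c0 <- lin - 1L
  i <- c0 %% shape[1]
  j <- (c0 %/% shape[1]) %% shape[2]
  k <- c0 %/% (shape[1] * shape[2])
  ni <- i + d[1]; nj <- j + d[2]; nk <- k + d[3]
  ni >= 0 & ni < shape[1] & nj >= 0 & nj < shape[2] & nk >= 0 & nk < shape[3]
}

#' Covariate control of the behavioural score (and optionally the features)
#'
#' `"residualize_behaviour"` replaces the scores by the residuals of an OLS
#' regression of score on the covariate (with intercept), leaving the
#' features untouched. `"covary_in_model"` additionally residualizes every
#' feature column on the covariate.
#'
#' @param scores Numeric score vector.
#' @param features Subjects x voxels matrix (or [skeleton_dataset]).
#' @param covariate Numeric covariate, one value per subject.
#' @param strategy `"none"`, `"residualize_behaviour"` or `"covary_in_model"`.
#' @return List with adjusted `scores` and `features` (plain matrix).
#' @export
apply_covariate_control <- function(scores, features, covariate = NULL,
                                    strategy = c("none",
                                                 "residualize_behaviour",
                                                 "covary_in_model")) {
  strategy <- match.arg(strategy)
  X <- as_feature_matrix(features)
  scores <- as.numeric(scores)
  if (strategy == "none")
    return(list(scores = scores, features = X))
  if (is.null(covariate))
    stop("covariate is required for strategy '", strategy, "'", call. = FALSE)
  covariate <- as.numeric(covariate)
  if (length(covariate) != length(scores))
    stop("covariate length does not match scores", call. = FALSE)
  if (anyNA(covariate) || any(!is.finite(covariate)))
    stop("covariate contains missing or non-finite values", call. = FALSE)
  if (stats::sd(covariate) < 1e-12)
    stop("degenerate input: covariate is constant", call. = FALSE)
  D <- cbind(1, covariate)
  H <- D %*% solve(crossprod(D), t(D))
  adj_scores <- drop(scores - H %*% scores)
  adj_X <- X
  if (strategy == "covary_in_model")
    adj_X <- X - H %*% X
  list(scores = adj_scores, features = adj_X)
}
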