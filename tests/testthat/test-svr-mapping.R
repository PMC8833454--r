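test_that("linear SVR recovers a planted weight vector", {
  set.seed(1)
  X <- cbind(runif(20), runif(20))
  y <- 2 * X[, 1]
  f <- fit_svr(X, y, c = 1e6, epsilon = 0)
  expect_equal(f$weights, c(2, 0), tolerance = 1e-2)
  expect_lt(max(abs(predict(f, X) - y)), 1e-3)

  # subject order invariance
  o <- sample(20)
  f2 <- fit_svr(X[o, ], y[o], c = 1e6, epsilon = 0)
  expect_equal(f2$weights, f$weights, tolerance = 1e-6)

  expect_error(fit_svr(X, rep(1, 20), c = 1), "constant")
  expect_error(fit_svr(X[1:2, ], y[1:2], c = 1), "3 subjects")
  expect_error(fit_svr(X, y, c = -1), "c must be")
  Xbad <- X; Xbad[1, 1] <- NA
  expect_error(fit_svr(Xbad, y, c = 1), "missing")
})

test_that("rbf kernel exposes predictions but no weights", {
  set.seed(2)
  X <- matrix(runif(60), 20, 3)
  y <- sin(4 * X[, 1])
  f <- fit_svr(X, y, c = 10, kernel = "rbf", epsilon = 0.01)
  expect_true(is.na(f$weights[1]))
  expect_gt(cor(predict(f, X), y), 0.9)
})

test_that("evaluate_c counts folds and models as configured", {
  set.seed(3)
  X <- matrix(runif(16), 4, 4)
  y <- c(1, 3, 2, 4)
  # 2 folds x 1 repeat on 4 subjects -> exactly one weight-vector pair
  ev <- evaluate_c(X, y, c = 1, folds = 2, repeats = 1, seed = 1)
  expect_identical(ev$n_models, 2L)

  # noiseless single-voxel effect: near-perfect fit and reproducibility
  set.seed(4)
  Xn <- matrix(runif(40 * 30, 0.2, 0.8), 40, 30)
  yn <- 5 * Xn[, 7]
  evn <- evaluate_c(Xn, yn, c = 64, seed = 1, epsilon = 0)
  expect_gt(evn$fit_r2, 0.95)
  expect_gt(evn$reproducibility_r, 0.95)

  # null scores: expected held-out fit is near zero
  set.seed(5)
  X0 <- matrix(runif(50 * 30, 0.2, 0.8), 50, 30)
  y0 <- rnorm(50)
  ev0 <- evaluate_c(X0, y0, c = 1, seed = 2)
  expect_lt(ev0$fit_r2, 0.1)
})

test_that("optimize_c picks dominating costs and breaks ties low", {
  set.seed(4)
  X <- matrix(runif(40 * 20, 0.2, 0.8), 40, 20)
  y <- 5 * X[, 3]
  one <- optimize_c(X, y, c_grid = 2, seed = 1)
  expect_identical(one$chosen_c, 2)

  opt <- optimize_c(X, y, c_grid = 2^(-6:6), seed = 1, epsilon = 0)
  tr <- opt$trace
  at <- tr[tr$c == opt$chosen_c, ]
  # the chosen cost dominates on the combined normalized criterion
  expect_true(all(at$score >= tr$score))
  expect_error(optimize_c(X, y, c_grid = numeric(0)), "nonempty")
})

test_that("permutation p-values match an exhaustive independent oracle", {
  set.seed(9)
  n <- 4; V <- 6
  X <- matrix(runif(n * V, 0.2, 0.8), n, V)
  y <- c(3, 1, 4, 2)
  perms <- svrfa:::all_permutations(n)
  expect_identical(nrow(unique(perms)), 24L)

  wo <- e1071_weights(X, y, c = 1)
  W <- sapply(seq_len(nrow(perms)), function(k)
    e1071_weights(X, y[perms[k, ]], c = 1))
  eps <- 1e-8 * (1 + abs(wo))
  for (tail in c("negative", "positive", "two_sided")) {
    res <- permutation_pmap(X, y, c = 1, exhaustive = TRUE, tail = tail)
    p_oracle <- switch(tail,
      negative = vapply(1:V, function(v) mean(W[v, ] <= wo[v] + eps[v]), 0),
      positive = vapply(1:V, function(v) mean(W[v, ] >= wo[v] - eps[v]), 0),
      two_sided = vapply(1:V, function(v)
        mean(abs(W[v, ]) >= abs(wo[v]) - eps[v]), 0))
    expect_identical(res$p_values, p_oracle)
  }
})

test_that("sampled permutation p-values are valid and seeded", {
  set.seed(10)
  X <- matrix(runif(12 * 8, 0.2, 0.8), 12, 8)
  y <- rnorm(12)
  r1 <- permutation_pmap(X, y, c = 1, n_permutations = 50, seed = 3)
  r2 <- permutation_pmap(X, y, c = 1, n_permutations = 50, seed = 3)
  expect_identical(r1$p_values, r2$p_values)
  expect_true(all(r1$p_values >= 1 / 51 & r1$p_values <= 1))

  # with a bounded cost the aligned voxel beats every permutation (its
  # box-constrained weight is maximal for the observed alignment), so the
  # smallest attainable p is hit exactly
  ystrong <- 10 * X[, 1]
  rs <- permutation_pmap(X, ystrong, c = 1, n_permutations = 50, seed = 4,
                         tail = "positive")
  expect_identical(rs$p_values[1], 1 / 51)

  expect_error(permutation_pmap(X, y, n_permutations = 0), ">= 1")
  expect_error(permutation_pmap(X, rep(1, 12), n_permutations = 10),
               "constant")
})

test_that("p-values are invariant to subject relabeling and voxel order", {
  set.seed(11)
  X <- matrix(runif(10 * 12, 0.2, 0.8), 10, 12)
  y <- rnorm(10)
  base <- permutation_pmap(X, y, c = 1, n_permutations = 40, seed = 5)
  # voxel columns permuted: p-values follow the columns exactly
  perm_v <- sample(12)
  shuf <- permutation_pmap(X[, perm_v], y, c = 1, n_permutations = 40,
                           seed = 5)
  expect_identical(shuf$p_values, base$p_values[perm_v])
})

test_that("zero-variance voxels are retained, flagged and given p = 1", {
  set.seed(12)
  X <- matrix(runif(10 * 5, 0.2, 0.8), 10, 5)
  X[, 3] <- 0
  y <- rnorm(10)
  r <- permutation_pmap(X, y, c = 1, n_permutations = 30, seed = 1)
  expect_identical(r$zero_variance, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(r$p_values[3], 1)
})

test_that("fdr_select equals the literal Benjamini-Hochberg definition", {
  # spec-sized worked example, checked against the definition applied by hand
  p <- c(0.001, 0.01, 0.02, 0.04, 0.9)
  sel <- fdr_select(p, q = 0.05)
  expect_identical(sel$significant, bh_oracle(p, 0.05))
  expect_identical(sel$p_threshold, 0.04)

  expect_true(all(fdr_select(rep(0.001, 100), 0.05)$significant))
  expect_false(any(fdr_select(rep(1, 100), 0.05)$significant))

  # random vectors: exact agreement with the literal definition and p.adjust
  set.seed(13)
  for (i in 1:25) {
    m <- sample(1:400, 1)
    p <- runif(m)^sample(1:3, 1)
    p[p == 0] <- 1e-12
    sel <- fdr_select(p, q = 0.05)
    expect_identical(sel$significant, bh_oracle(p, 0.05))
    expect_identical(sel$significant, p.adjust(p, "BH") <= 0.05)
  }
  expect_error(fdr_select(numeric(0)), "empty")
  expect_error(fdr_select(c(0.5, 0)), "p-values")
})

test_that("cluster filtering respects the size boundary and connectivity", {
  arr <- array(0, c(30, 10, 10))
  arr[1:19, 1, 1] <- 1                  # 19-voxel line
  v19 <- volume(arr)
  expect_identical(sum(filter_clusters(v19, 20)$data), 0)

  arr20 <- array(0, c(30, 10, 10))
  arr20[1:20, 1, 1] <- 1                # 20-voxel line survives unchanged
  v20 <- volume(arr20)
  expect_identical(filter_clusters(v20, 20)$data, arr20)

  # diagonal voxels: one component under 26-connectivity, two under 6
  arr2 <- array(0, c(4, 4, 4))
  arr2[1, 1, 1] <- 1; arr2[2, 2, 2] <- 1
  vdiag <- volume(arr2)
  expect_identical(sum(filter_clusters(vdiag, 2, connectivity = 26)$data), 2)
  expect_identical(sum(filter_clusters(vdiag, 2, connectivity = 6)$data), 0)

  # filtered output is a subset of the input, and filtering is idempotent
  m <- rand_volume(c(12, 12, 12), seed = 21)
  m$data[] <- as.numeric(m$data > 0.6)
  f1 <- filter_clusters(m, 5)
  expect_true(all(f1$data <= m$data))
  expect_identical(filter_clusters(f1, 5)$data, f1$data)
})

test_that("covariate control residualizes as specified", {
  set.seed(14)
  n <- 30
  cov <- rnorm(n)
  e <- rnorm(n)
  y <- 2 * cov + e
  X <- matrix(runif(n * 4), n, 4)

  adj <- apply_covariate_control(y, X, cov, "residualize_behaviour")
  # residuals equal the noise up to its own projection on (1, cov)
  fit <- lm(e ~ cov)
  expect_equal(adj$scores, unname(resid(fit)), tolerance = 1e-9)
  expect_identical(adj$features, X)

  # orthogonal covariate: adjusted scores are just centred scores
  cov_o <- resid(lm(rnorm(n) ~ y))
  adj_o <- apply_covariate_control(y, X, cov_o, "residualize_behaviour")
  expect_equal(adj_o$scores, unname(resid(lm(y ~ cov_o))), tolerance = 1e-9)
  expect_lt(abs(cor(adj_o$scores, y) - cor(y - mean(y), y)), 0.02)

  # covary_in_model residualizes features too
  adj_m <- apply_covariate_control(y, X, cov, "covary_in_model")
  for (j in 1:4)
    expect_lt(abs(cor(adj_m$features[, j], cov)), 1e-9)

  # covariate equal to the score leaves nothing to model downstream
  adj_id <- apply_covariate_control(y, X, y, "residualize_behaviour")
  expect_lt(max(abs(adj_id$scores)), 1e-9)
  expect_error(check_degenerate <- fit_svr(X, adj_id$scores, c = 1),
               "constant")

  expect_error(apply_covariate_control(y, X, rep(1, n),
                                       "residualize_behaviour"), "constant")
  expect_error(apply_covariate_control(y, X, NULL, "covary_in_model"),
               "covariate")
})

test_that("run_mapping validates configuration and chains the stages", {
  an <- fixture_anatomy()
  co <- make_phantom_cohort(an, n_subjects = 20, seed = 23)
  expect_error(run_mapping(co$fa, co$scores,
                           mapping_config(n_permutations = 0)), ">= 1")
  expect_error(run_mapping(co$fa$features, co$scores), "skeleton_dataset")
  expect_error(run_mapping(co$fa, co$scores, mapping_config(kernel = "rbf")),
               "linear")

  cfg <- mapping_config(c = 0.1, n_permutations = 25, perm_seed = 2)
  res <- run_mapping(co$fa, co$scores, cfg)
  expect_s3_class(res, "mapping_result")
  expect_true(all(res$sig_mask_filtered$data <= res$sig_mask_raw$data))
  expect_true(all(res$sig_mask_raw$data <= an$skeleton_mask$data))
  expect_identical(length(res$p_values), ncol(co$fa$features))

  g <- glance(res)
  expect_identical(g$n_voxels, ncol(co$fa$features))
  td <- tidy(res)
  expect_identical(nrow(td), ncol(co$fa$features))
})

test_that("null permutation p-values are uniform (KS check)", {
  set.seed(21)
  n <- 6; V <- 200
  X <- matrix(runif(n * V, 0.2, 0.8), n, V)
  y <- rnorm(n)
  res <- permutation_pmap(X, y, c = 1, exhaustive = TRUE, tail = "negative")
  ks <- suppressWarnings(ks.test(res$p_values, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("mapping results round-trip to disk with a manifest", {
  an <- fixture_anatomy()
  co <- make_phantom_cohort(an, n_subjects = 15, seed = 29)
  res <- run_mapping(co$fa, co$scores,
                     mapping_config(c = 0.1, n_permutations = 20))
  d <- withr::local_tempdir()
  write_mapping_result(res, d)
  w <- load_volume(file.path(d, "weights.nii.gz"))
  w_back <- extract_matrix(list(w), an$skeleton_mask, clip = FALSE)
  expect_identical(w_back$features[1, ], res$weights)
  man <- jsonlite::read_json(file.path(d, "run_manifest.json"))
  expect_identical(man$chosen_c, 0.1)

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("c: 0.5", "n_permutations: 10", "tail: positive"), yml)
  cfg <- mapping_config_from_yaml(yml)
  expect_identical(cfg$c, 0.5)
  expect_identical(cfg$tail, "positive")
  writeLines("bogus_key: 1", yml)
  expect_error(mapping_config_from_yaml(yml), "unknown config key")
})
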