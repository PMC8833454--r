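test_that("phantom anatomy is reproducible, parcels labelled, critical sized", {
  an <- fixture_anatomy()
  an2 <- make_phantom_anatomy(c(16L, 16L, 16L), 4L, 0.1, seed = 1L)
  expect_identical(an$skeleton_mask$data, an2$skeleton_mask$data)
  expect_identical(an$parcellation$data, an2$parcellation$data)
  expect_identical(an$critical_mask$data, an2$critical_mask$data)

  labs <- sort(unique(as.vector(an$parcellation$data)))
  expect_identical(labs[labs != 0], 1:4)

  n_skel <- sum(an$skeleton_mask$data)
  n_crit <- sum(an$critical_mask$data)
  expect_gte(n_crit, 0.8 * 0.1 * n_skel)
  expect_lte(n_crit, 1.2 * 0.1 * n_skel)
  # critical region is a subset of the skeleton
  expect_true(all(an$critical_mask$data <= an$skeleton_mask$data))

  expect_error(make_phantom_anatomy(critical_fraction = 0), "critical_fraction")
  expect_error(make_phantom_anatomy(critical_fraction = 1.2),
               "critical_fraction")
  expect_error(make_phantom_anatomy(shape = c(4, 16, 16)), ">= 8")
  expect_error(make_phantom_anatomy(n_parcels = 1), "n_parcels")
})

test_that("critical region is contiguous on the skeleton", {
  an <- fixture_anatomy()
  filtered <- filter_clusters(an$critical_mask,
                              min_cluster = sum(an$critical_mask$data),
                              connectivity = 26L)
  expect_identical(filtered$data, an$critical_mask$data)
})

test_that("subject FA follows the lesion-drop model", {
  an <- fixture_anatomy()
  # noiseless: in-lesion skeleton voxels exactly base - drop, others base
  s <- simulate_subject_fa(an, c(8, 8, 8), 3, base_fa = 0.6,
                           lesion_fa_drop = 0.3, fa_noise_sd = 0, seed = 2)
  vi <- voxel_index(an$skeleton_mask)
  in_lesion <- s$lesion$data[vi$coords + 1L] > 0
  expect_true(any(in_lesion))
  expect_true(all(s$fa_row[in_lesion] == 0.3))
  expect_true(all(s$fa_row[!in_lesion] == 0.6))

  # drop 0: deviations are noise only
  s0 <- simulate_subject_fa(an, c(8, 8, 8), 3, base_fa = 0.6,
                            lesion_fa_drop = 0, fa_noise_sd = 0.01, seed = 3)
  expect_lt(max(abs(s0$fa_row - 0.6)), 0.1)

  # with noise, in-lesion mean is clearly below out-lesion mean
  s1 <- simulate_subject_fa(an, c(8, 8, 8), 4, base_fa = 0.6,
                            lesion_fa_drop = 0.3, fa_noise_sd = 0.05, seed = 4)
  in1 <- s1$lesion$data[vi$coords + 1L] > 0
  expect_lt(mean(s1$fa_row[in1]), mean(s1$fa_row[!in1]))

  expect_error(simulate_subject_fa(an, c(8, 8, 8), -1), "radius")
  expect_error(simulate_subject_fa(an, c(8, 8, 8), 3, base_fa = 0.5,
                                   lesion_fa_drop = 0.6), "lesion_fa_drop")
})

test_that("scores follow the planted critical-region effect", {
  an <- fixture_anatomy()
  co <- make_phantom_cohort(an, n_subjects = 40, fa_noise_sd = 0.02, seed = 7)

  # noiseless scores are an exact affine function of mean critical FA
  sc0 <- simulate_scores(co$fa, an$critical_mask, beta0 = 10, beta1 = 70,
                         noise_sd = 0, seed = 8)
  m <- rowMeans(co$fa$features[, sc0$critical_columns, drop = FALSE])
  fit <- lm(sc0$scores ~ m)
  expect_lt(max(abs(resid(fit))), 1e-9)
  expect_equal(unname(coef(fit)), c(10, 70), tolerance = 1e-6)

  # beta1 = 0, noise 0: all scores equal beta0
  sc1 <- simulate_scores(co$fa, an$critical_mask, beta0 = 5, beta1 = 0,
                         noise_sd = 0, seed = 9)
  expect_true(all(sc1$scores == 5))

  expect_error(simulate_scores(co$fa, an$critical_mask, covariate_rho = 1.5),
               "covariate_rho")
  empty_crit <- volume(array(0, an$shape), an$affine)
  empty_crit$data[1, 1, 1] <- 1  # off-skeleton voxel
  expect_error(simulate_scores(co$fa, empty_crit), "critical mask")
})

test_that("covariate hits the target correlation at large n", {
  an <- fixture_anatomy()
  co <- make_phantom_cohort(an, n_subjects = 200, seed = 31)
  # tolerance from the Fisher-z standard error at n = 200 (about 0.07)
  expect_lt(abs(cor(co$scores, co$covariate) - 0.56), 0.1)
})

test_that("cohorts are pure functions of their seed", {
  an <- fixture_anatomy()
  c1 <- make_phantom_cohort(an, n_subjects = 10, seed = 5)
  c2 <- make_phantom_cohort(an, n_subjects = 10, seed = 5)
  expect_identical(c1$fa$features, c2$fa$features)
  expect_identical(c1$scores, c2$scores)
  expect_identical(c1$covariate, c2$covariate)
})

test_that("larger critical-region lesions give worse scores", {
  an <- fixture_anatomy()
  co <- make_phantom_cohort(an, n_subjects = 80, seed = 17)
  vi <- co$fa$voxel_index
  crit_lin <- which(an$critical_mask$data != 0)
  overlap <- vapply(co$lesions, function(l) sum(l$data[crit_lin]), numeric(1))
  expect_lt(cor(overlap, co$scores), -0.3)
})

test_that("synthetic tractogram plants exact pair counts with known truth", {
  an <- fixture_anatomy()
  pc <- data.frame(region_a = 1, region_b = 2, count = 5)
  tr <- simulate_tractogram(an, pc, waypoint_jitter = 0, seed = 6)
  expect_length(tr$streamlines, 5L)
  asg <- assign_endpoints(tr, an$parcellation)
  expect_true(all(asg$assigned))
  expect_true(all(asg$region_a == 1 & asg$region_b == 2))

  # empty request gives an empty tractogram
  tr0 <- simulate_tractogram(an, data.frame(region_a = integer(0),
                                            region_b = integer(0),
                                            count = integer(0)))
  expect_length(tr0$streamlines, 0L)

  expect_error(simulate_tractogram(an, data.frame(region_a = 1, region_b = 9,
                                                  count = 1)), "unknown")

  # jitter-free assignment reproduces the planted counts exactly
  pc2 <- data.frame(region_a = c(1, 2, 3), region_b = c(2, 3, 3),
                    count = c(7, 4, 2))
  tr2 <- simulate_tractogram(an, pc2, waypoint_jitter = 0, seed = 12)
  asg2 <- assign_endpoints(tr2, an$parcellation)
  got <- table(paste(asg2$region_a, asg2$region_b))
  expect_identical(unname(c(got[["1 2"]], got[["2 3"]], got[["3 3"]])),
                   c(7L, 4L, 2L))
  expect_identical(tr2$ground_truth_pairs[, 1],
                   rep(c(1, 2, 3), c(7, 4, 2)))
})

test_that("cohort directories round-trip through the writers and readers", {
  an <- fixture_anatomy()
  co <- make_phantom_cohort(an, n_subjects = 3, seed = 19)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  mask <- load_volume(file.path(d, "skeleton_mask.nii.gz"))
  expect_identical(mask$data > 0, an$skeleton_mask$data > 0)
  tab <- read_subject_table(file.path(d, "subjects.tsv"))
  expect_identical(nrow(tab), 3L)
  expect_equal(tab$score, co$scores, tolerance = 1e-9)
  fa1 <- load_volume(file.path(d, "fa_001.nii.gz"))
  ds <- extract_matrix(list(fa1), mask)
  expect_equal(ds$features[1, ], co$fa$features[1, ], tolerance = 1e-12)
})
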