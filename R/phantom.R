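#' Synthetic phantom anatomy
#'
#' Builds a small ground-truthed anatomy for end-to-end testing of the
#' mapping and disconnectome pipeline: a thin connected white-matter
#' "skeleton" (two intersecting orthogonal one-voxel-thick slabs), an
#' integer parcellation of axis-aligned blocks separated by one-voxel
#' background gaps (so inter-parcel corridors are maskable), and a
#' contiguous "critical" sub-region of the skeleton whose FA will drive the
#' behavioural score.
#'
#' @param shape Grid dimensions (each >= 8). Default `c(16, 16, 16)`.
#' @param n_parcels Number of parcels (>= 2). Default 4.
#' @param critical_fraction Target fraction of skeleton voxels in the
#'   critical region, in (0, 1). Default 0.1.
#' @param seed Integer seed; the anatomy is a pure function of the arguments.
#' @return An object of class `phantom_anatomy`: `skeleton_mask`,
#'   `parcellation`, `critical_mask` (all [volume]s sharing an identity
#'   1 mm affine), `shape`, `affine`, `seed`.
#' @export
make_phantom_anatomy <- function(shape = c(16L, 16L, 16L), n_parcels = 4L,
                                 critical_fraction = 0.1, seed = 1L) {
  if (length(shape) != 3L || any(shape < 8L))
    stop("shape must have 3 dimensions, each >= 8", call. = FALSE)
  if (n_parcels < 2L)
    stop("n_parcels must be >= 2", call. = FALSE)
  if (critical_fraction <= 0 || critical_fraction >= 1)
    stop("critical_fraction must be in (0, 1)", call. = FALSE)
  shape <- as.integer(shape)
  set.seed(seed)
  affine <- diag(4)

  # skeleton: mid-axial slab plus mid-coronal slab (1 voxel thick, interior
  # margin 1); the slabs intersect, so the structure is connected
  skel <- array(0, dim = shape)
  zmid <- shape[3] %/% 2L + 1L
  ymid <- shape[2] %/% 2L + 1L
  skel[2:(shape[1] - 1L), 2:(shape[2] - 1L), zmid] <- 1
  skel[2:(shape[1] - 1L), ymid, 2:(shape[3] - 1L)] <- 1

  # parcellation: n_parcels x-axis blocks spanning y/z, one-voxel gaps
  width <- (shape[1] - (n_parcels - 1L)) %/% n_parcels
  if (width < 1L)
    stop("grid too small in x for ", n_parcels, " parcels", call. = FALSE)
  parc <- array(0L, dim = shape)
  for (p in seq_len(n_parcels)) {
    x0 <- (p - 1L) * (width + 1L) + 1L
    parc[x0:(x0 + width - 1L), , ] <- p
  }

  # critical region: contiguous skeleton patch grown by breadth-first search
  # from a random skeleton voxel (26-connectivity, deterministic order)
  vind <- voxel_index(volume(skel, affine))
  n_skel <- length(vind)
  target <- max(1L, round(critical_fraction * n_skel))
  lin_all <- linear_index(vind$coords, shape)
  in_skel <- array(FALSE, dim = shape)
  in_skel[lin_all] <- TRUE
  start <- lin_all[sample.int(n_skel, 1L)]
  offsets <- neighbour_offsets(shape, 26L)
  visited <- array(FALSE, dim = shape)
  visited[start] <- TRUE
  queue <- start
  grown <- integer(0)
  while (length(queue) > 0L && length(grown) < target) {
    cur <- queue[1L]; queue <- queue[-1L]
    grown <- c(grown, cur)
    nb <- cur + offsets$delta
    ok <- valid_neighbours(cur, nb, shape, offsets)
    nb <- nb[ok]
    nb <- nb[in_skel[nb] & !visited[nb]]
    if (length(nb)) {
      visited[nb] <- TRUE
      queue <- c(queue, sort(nb))
    }
  }
  crit <- array(0, dim = shape)
  crit[grown] <- 1

  structure(list(shape = shape, affine = affine,
                 skeleton_mask = volume(skel, affine),
                 parcellation = volume(parc, affine),
                 critical_mask = volume(crit, affine),
                 n_parcels = as.integer(n_parcels),
                 critical_fraction = critical_fraction,
                 seed = as.integer(seed)),
            class = "phantom_anatomy")
}

#' @export
print.phantom_anatomy <- function(x, ...) {
  cat("<phantom_anatomy> ", paste(x$shape, collapse = "x"), " grid, ",
      sum(x$skeleton_mask$data), " skeleton voxels (",
      sum(x$critical_mask$data), " critical), ",
      x$n_parcels, " parcels\n", sep = "")
  invisible(x)
}

# linear-index offsets for 6/18/26 neighbourhoods, plus the (di,dj,dk)
# triples needed to reject wrap-around at grid edges
neighbour_offsets <- function(shape, connectivity = 26L) {
  d <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  ord <- rowSums(abs(d))
  keep <- switch(as.character(connectivity),
                 "6"  = ord == 1,
                 "18" = ord <= 2,
                 "26" = rep(TRUE, nrow(d)),
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  d <- d[keep, , drop = FALSE]
  delta <- d[, 1] + shape[1] * (d[, 2] + shape[2] * d[, 3])
  list(d = d, delta = delta)
}

# reject neighbours that fall off the grid (wrap-around through linear
# indexing); cur and nb are 1-based linear indices
valid_neighbours <- function(cur, nb, shape, offsets) {
  c0 <- cur - 1L
  i <- c0 %% shape[1]
  j <- (c0 %/% shape[1]) %% shape[2]
  k <- c0 %/% (shape[1] * shape[2])
  ni <- i + offsets$d[, 1]; nj <- j + offsets$d[, 2]; nk <- k + offsets$d[, 3]
  ni >= 0 & ni < shape[1] & nj >= 0 & nj < shape[2] & nk >= 0 & nk < shape[3]
}

#' Simulate one subject's lesion and skeleton FA row
#'
#' The lesion is a sphere in world millimetres; skeleton voxels inside it
#' have their FA depressed by `lesion_fa_drop`, all skeleton voxels receive
#' i.i.d. Gaussian noise, and the result is clipped to \[0, 1\].
#'
#' @param anatomy A [make_phantom_anatomy()] result.
#' @param lesion_center 0-based voxel triple (converted to world mm through
#'   the anatomy affine).
#' @param lesion_radius Sphere radius in mm (> 0).
#' @param base_fa Baseline FA in (0, 1\]. Default 0.6.
#' @param lesion_fa_drop FA reduction inside the lesion, in \[0, base_fa\].
#'   Default 0.35.
#' @param fa_noise_sd Voxel noise SD. Default 0.02.
#' @param seed Integer seed.
#' @return List with `lesion` (binary [volume] over the full grid) and
#'   `fa_row` (numeric vector over skeleton voxels in [voxel_index] order).
#' @export
simulate_subject_fa <- function(anatomy, lesion_center, lesion_radius,
                                base_fa = 0.6, lesion_fa_drop = 0.35,
                                fa_noise_sd = 0.02, seed = 1L) {
  stopifnot(inherits(anatomy, "phantom_anatomy"))
  if (lesion_radius <= 0)
    stop("lesion_radius must be > 0", call. = FALSE)
  if (base_fa <= 0 || base_fa > 1)
    stop("base_fa must be in (0, 1]", call. = FALSE)
  if (lesion_fa_drop < 0 || lesion_fa_drop > base_fa)
    stop("lesion_fa_drop must be in [0, base_fa]", call. = FALSE)
  set.seed(seed)
  shape <- anatomy$shape
  centre_world <- voxel_to_world(matrix(as.numeric(lesion_center), 1),
                                 anatomy$affine)
  grid <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                                k = 0:(shape[3] - 1)))
  world <- voxel_to_world(grid, anatomy$affine)
  d2 <- (world[, 1] - centre_world[1])^2 + (world[, 2] - centre_world[2])^2 +
    (world[, 3] - centre_world[3])^2
  lesion_arr <- array(0, dim = shape)
  lesion_arr[linear_index(grid, shape)] <- as.numeric(d2 <= lesion_radius^2)
  vind <- voxel_index(anatomy$skeleton_mask)
  lin <- linear_index(vind$coords, shape)
  in_lesion <- lesion_arr[lin] > 0
  fa_row <- base_fa - lesion_fa_drop * in_lesion +
    stats::rnorm(length(lin), 0, fa_noise_sd)
  fa_row <- pmin(pmax(fa_row, 0), 1)
  list(lesion = volume(lesion_arr, anatomy$affine), fa_row = fa_row)
}

#' Simulate behavioural scores with a planted critical-region effect
#'
#' Each subject's score is an affine function of their mean FA over the
#' critical voxels plus Gaussian noise:
#' `score_i = beta0 + beta1 * mean(FA_i over critical) + N(0, noise_sd^2)`.
#' A nuisance covariate is generated by mixing the standardized score with
#' independent noise so that its correlation with the score is approximately
#' `covariate_rho` (only the correlation is targeted, not a mechanism).
#'
#' @param cohort_fa A [skeleton_dataset].
#' @param critical_mask Binary [volume]; must intersect the skeleton.
#' @param beta0,beta1 Intercept and slope of the planted effect.
#' @param noise_sd Score noise SD.
#' @param covariate_rho Target score-covariate correlation in (-1, 1).
#'   Default 0.56.
#' @param seed Integer seed.
#' @return List with `scores`, `covariate` (numeric vectors) and
#'   `critical_columns` (feature-matrix columns inside the critical mask).
#' @export
simulate_scores <- function(cohort_fa, critical_mask, beta0 = 10, beta1 = 70,
                            noise_sd = 1, covariate_rho = 0.56, seed = 1L) {
  stopifnot(inherits(cohort_fa, "skeleton_dataset"))
  if (covariate_rho <= -1 || covariate_rho >= 1)
    stop("covariate_rho must be in (-1, 1)", call. = FALSE)
  vind <- cohort_fa$voxel_index
  crit_lin <- which(critical_mask$data != 0)
  cols <- which(linear_index(vind$coords, vind$shape) %in% crit_lin)
  if (length(cols) == 0L)
    stop("critical mask does not intersect the skeleton", call. = FALSE)
  set.seed(seed)
  m <- rowMeans(cohort_fa$features[, cols, drop = FALSE])
  n <- nrow(cohort_fa$features)
  scores <- beta0 + beta1 * m + stats::rnorm(n, 0, noise_sd)
  zs <- if (stats::sd(scores) > 0) as.numeric(scale(scores)) else rep(0, n)
  covariate <- covariate_rho * zs +
    sqrt(1 - covariate_rho^2) * stats::rnorm(n)
  list(scores = scores, covariate = covariate, critical_columns = cols)
}

#' Simulate a tractogram with known region-pair streamline counts
#'
#' For each requested parcel pair `(a, b)`, emits exactly the requested
#' number of streamlines whose first point lies in parcel `a` and last point
#' in parcel `b`; interior points interpolate the straight line between the
#' endpoints (about 1 mm spacing) with optional Gaussian jitter. The planted
#' pair of each streamline is recorded in `ground_truth_pairs`.
#'
#' @param anatomy A [make_phantom_anatomy()] result.
#' @param pair_counts Data frame with columns `region_a`, `region_b`,
#'   `count` (one row per pair; labels must exist in the parcellation).
#' @param waypoint_jitter SD (mm) of jitter applied to interior points.
#'   Default 0.
#' @param seed Integer seed.
#' @return A [tractogram] with `ground_truth_pairs` set.
#' @export
simulate_tractogram <- function(anatomy, pair_counts, waypoint_jitter = 0,
                                seed = 1L) {
  stopifnot(inherits(anatomy, "phantom_anatomy"))
  pair_counts <- as.data.frame(pair_counts)
  if (nrow(pair_counts) == 0L)
    return(tractogram_allow_empty(list(), anatomy$affine))
  stopifnot(all(c("region_a", "region_b", "count") %in% names(pair_counts)))
  labels <- sort(unique(as.vector(anatomy$parcellation$data)))
  labels <- labels[labels != 0]
  bad <- setdiff(unique(c(pair_counts$region_a, pair_counts$region_b)), labels)
  if (length(bad))
    stop("unknown parcel label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  set.seed(seed)
  parc <- anatomy$parcellation$data
  vox_by_label <- lapply(labels, function(l) which(parc == l, arr.ind = TRUE) - 1L)
  names(vox_by_label) <- as.character(labels)
  streamlines <- list()
  gt <- matrix(integer(0), ncol = 2)
  for (r in seq_len(nrow(pair_counts))) {
    a <- pair_counts$region_a[r]; b <- pair_counts$region_b[r]
    cnt <- pair_counts$count[r]
    va <- vox_by_label[[as.character(a)]]
    vb <- vox_by_label[[as.character(b)]]
    for (s in seq_len(cnt)) {
      p0 <- voxel_to_world(va[sample.int(nrow(va), 1L), , drop = FALSE],
                           anatomy$affine)
      p1 <- voxel_to_world(vb[sample.int(nrow(vb), 1L), , drop = FALSE],
                           anatomy$affine)
      dist <- sqrt(sum((p1 - p0)^2))
      npts <- max(3L, ceiling(dist) + 1L)
      t <- seq(0, 1, length.out = npts)
      pts <- cbind(p0[1] + t * (p1[1] - p0[1]),
                   p0[2] + t * (p1[2] - p0[2]),
                   p0[3] + t * (p1[3] - p0[3]))
      if (waypoint_jitter > 0 && npts > 2L) {
        interior <- 2:(npts - 1L)
        pts[interior, ] <- pts[interior, ] +
          matrix(stats::rnorm(length(interior) * 3, 0, waypoint_jitter),
                 ncol = 3)
      }
      streamlines[[length(streamlines) + 1L]] <- pts
      gt <- rbind(gt, c(a, b))
    }
  }
  tr <- tractogram_allow_empty(streamlines, anatomy$affine)
  tr$ground_truth_pairs <- gt
  tr
}

#' Generate a complete phantom cohort
#'
#' Draws one spherical lesion per subject (centre at a random skeleton voxel,
#' radius uniform in `radius_range`), builds the skeleton FA matrix, and
#' plants the linear critical-region effect with a correlated nuisance
#' covariate. Defaults mirror a chronic left-hemisphere stroke cohort:
#' 101 subjects, FA about 0.6 on intact skeleton dropping by 0.35 inside
#' lesions, behavioural scores on an apraxia-test-like scale, and a
#' covariate correlated with the score at rho = 0.56.
#'
#' @param anatomy A [make_phantom_anatomy()] result.
#' @param n_subjects Number of subjects. Default 101.
#' @param radius_range Lesion radius range in mm. Default `c(2.5, 5.5)`.
#' @param base_fa,lesion_fa_drop,fa_noise_sd See [simulate_subject_fa()].
#' @param beta0,beta1,noise_sd,covariate_rho See [simulate_scores()].
#' @param seed Integer seed; the cohort is a pure function of the arguments.
#' @return An object of class `phantom_cohort`: `anatomy`, `lesions` (list of
#'   binary volumes), `fa` ([skeleton_dataset]), `scores`, `covariate`,
#'   `effect_beta`, `noise_sd`, `seed`.
#' @export
make_phantom_cohort <- function(anatomy, n_subjects = 101L,
                                radius_range = c(2.5, 5.5),
                                base_fa = 0.6, lesion_fa_drop = 0.35,
                                fa_noise_sd = 0.02,
                                beta0 = 10, beta1 = 70, noise_sd = 1,
                                covariate_rho = 0.56, seed = 1L) {
  stopifnot(inherits(anatomy, "phantom_anatomy"))
  set.seed(seed)
  vind <- voxel_index(anatomy$skeleton_mask)
  centres <- vind$coords[sample.int(length(vind), n_subjects, replace = TRUE), ,
                         drop = FALSE]
  radii <- stats::runif(n_subjects, radius_range[1], radius_range[2])
  subj_seeds <- sample.int(.Machine$integer.max %/% 2L, n_subjects)
  lesions <- vector("list", n_subjects)
  fa_rows <- matrix(NA_real_, n_subjects, length(vind))
  for (i in seq_len(n_subjects)) {
    s <- simulate_subject_fa(anatomy, centres[i, ], radii[i], base_fa,
                             lesion_fa_drop, fa_noise_sd, seed = subj_seeds[i])
    lesions[[i]] <- s$lesion
    fa_rows[i, ] <- s$fa_row
  }
  fa <- skeleton_dataset(fa_rows, vind)
  sc <- simulate_scores(fa, anatomy$critical_mask, beta0, beta1, noise_sd,
                        covariate_rho, seed = seed + 1L)
  structure(list(anatomy = anatomy, lesions = lesions, fa = fa,
                 scores = sc$scores, covariate = sc$covariate,
                 critical_columns = sc$critical_columns,
                 effect_beta = beta1, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> ", length(x$lesions), " subjects, ",
      ncol(x$fa$features), " skeleton voxels, planted beta = ",
      x$effect_beta, "\n", sep = "")
  invisible(x)
}

#' Write a phantom cohort to a directory
#'
#' Writes the anatomy volumes and per-subject lesion/FA volumes as NIfTI, a
#' tab-separated subject table (`subject_id`, `score`, `covariate`), and a
#' JSON ground-truth file (planted parameters and critical-voxel columns).
#'
#' @param cohort A [make_phantom_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param tractogram Optional [tractogram] to write as `tractogram.tck`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, tractogram = NULL) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  an <- cohort$anatomy
  write_volume(an$skeleton_mask, file.path(dir, "skeleton_mask.nii.gz"))
  write_volume(an$parcellation, file.path(dir, "parcellation.nii.gz"),
               datatype = "int32")
  write_volume(an$critical_mask, file.path(dir, "critical_mask.nii.gz"))
  vind <- cohort$fa$voxel_index
  for (i in seq_along(cohort$lesions)) {
    write_volume(cohort$lesions[[i]],
                 file.path(dir, sprintf("lesion_%03d.nii.gz", i)))
    write_volume(project_map(cohort$fa$features[i, ], vind),
                 file.path(dir, sprintf("fa_%03d.nii.gz", i)))
  }
  tab <- data.frame(subject_id = cohort$fa$subject_ids,
                    score = cohort$scores, covariate = cohort$covariate)
  utils::write.table(tab, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(effect_beta = cohort$effect_beta, noise_sd = cohort$noise_sd,
                seed = cohort$seed, critical_columns = cohort$critical_columns)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(tractogram))
    write_streamlines(tractogram, file.path(dir, "tractogram.tck"))
  invisible(dir)
}

#' Read a tab-separated subject table
#'
#' Expects a header row with at least `subject_id` and `score` columns;
#' additional columns (e.g. covariates) are kept.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_subject_table <- function(path) {
  if (!file.exists(path))
    stop("subject table does not exist: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("subject_id", "score") %in% names(tab)))
    stop("subject table must have 'subject_id' and 'score' columns",
         call. = FALSE)
  tibble::as_tibble(tab)
}
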