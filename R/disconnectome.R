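#' Streamlines crossing a binary mask
#'
#' A streamline "crosses" the mask iff at least one of its points maps, by
#' nearest-voxel lookup through the mask's affine, to a nonzero mask voxel.
#'
#' @param tract A [tractogram] with coordinates in the mask's world frame.
#' @param mask Binary [volume].
#' @return Integer vector of crossing streamline indices (sorted).
#' @export
streamlines_crossing_mask <- function(tract, mask) {
  stopifnot(inherits(tract, "tractogram"), inherits(mask, "volume"))
  stopifnot_binary(mask)
  if (length(tract$streamlines) == 0L) return(integer(0))
  npts <- vapply(tract$streamlines, nrow, integer(1))
  pts <- do.call(rbind, tract$streamlines)
  ids <- rep.int(seq_along(npts), npts)
  vox <- world_to_voxel(pts, mask$affine)
  shape <- mask$shape
  inside <- vox[, 1] >= 0 & vox[, 1] < shape[1] &
    vox[, 2] >= 0 & vox[, 2] < shape[2] &
    vox[, 3] >= 0 & vox[, 3] < shape[3]
  hit <- logical(nrow(vox))
  hit[inside] <- mask$data[linear_index(vox[inside, , drop = FALSE], shape)] != 0
  sort(unique(ids[hit]))
}

#' Assign streamline endpoints to parcellation regions
#'
#' Each endpoint receives the parcel label at its nearest voxel; endpoints on
#' background are snapped to the nearest labelled voxel within
#' `search_radius_mm` (centre-to-point distance), and streamlines with any
#' unresolvable endpoint are marked unassigned. The pair is stored unordered
#' (`region_a <= region_b`).
#'
#' @param tract A [tractogram].
#' @param parcellation Integer-labelled [volume] (0 = background).
#' @param search_radius_mm Snap radius for background endpoints. Default 3.
#' @return A tibble with columns `streamline`, `region_a`, `region_b`,
#'   `assigned`.
#' @export
assign_endpoints <- function(tract, parcellation, search_radius_mm = 3) {
  stopifnot(inherits(tract, "tractogram"), inherits(parcellation, "volume"))
  n <- length(tract$streamlines)
  if (n == 0L)
    return(tibble::tibble(streamline = integer(0), region_a = integer(0),
                          region_b = integer(0), assigned = logical(0)))
  ends <- do.call(rbind, lapply(tract$streamlines, function(s)
    rbind(s[1, ], s[nrow(s), ])))
  shape <- parcellation$shape
  vox <- world_to_voxel(ends, parcellation$affine)
  lab <- rep(0L, nrow(vox))
  inside <- vox[, 1] >= 0 & vox[, 1] < shape[1] &
    vox[, 2] >= 0 & vox[, 2] < shape[2] &
    vox[, 3] >= 0 & vox[, 3] < shape[3]
  lab[inside] <- as.integer(
    parcellation$data[linear_index(vox[inside, , drop = FALSE], shape)])
  need <- which(lab == 0L)
  if (length(need)) {
    lab_idx <- which(parcellation$data != 0, arr.ind = TRUE) - 1L
    if (nrow(lab_idx)) {
      lab_world <- voxel_to_world(lab_idx, parcellation$affine)
      lab_vals <- as.integer(parcellation$data[linear_index(lab_idx, shape)])
      for (i in need) {
        d2 <- (lab_world[, 1] - ends[i, 1])^2 +
          (lab_world[, 2] - ends[i, 2])^2 + (lab_world[, 3] - ends[i, 3])^2
        j <- which.min(d2)
        if (d2[j] <= search_radius_mm^2) lab[i] <- lab_vals[j]
      }
    }
  }
  a <- lab[seq(1, 2 * n, by = 2)]
  b <- lab[seq(2, 2 * n, by = 2)]
  assigned <- a != 0L & b != 0L
  tibble::tibble(streamline = seq_len(n),
                 region_a = ifelse(assigned, pmin(a, b), NA_integer_),
                 region_b = ifelse(assigned, pmax(a, b), NA_integer_),
                 assigned = assigned)
}

#' Region-pair disconnection matrix
#'
#' Counts assigned streamlines per unordered region pair (`total_counts`),
#' the subset crossing the significance mask (`crossing_counts`), and their
#' ratio (`proportion`, 0 where no streamlines exist). Intra-region
#' streamlines sit on the diagonal and are counted once. Per-region totals
#' sum each region's row (diagonal included once); crossing streamlines with
#' an unassigned endpoint are reported in `n_unassigned_crossing`, not
#' silently dropped.
#'
#' @param tract A [tractogram].
#' @param crossing Integer indices from [streamlines_crossing_mask()].
#' @param assignments Tibble from [assign_endpoints()].
#' @param labels Region labels fixing the matrix order; default the sorted
#'   labels present in the assignments.
#' @return An object of class `disconnection_matrix`: `labels`,
#'   `total_counts`, `crossing_counts`, `proportion`,
#'   `region_total_crossing`, `region_total`, `region_proportion`,
#'   `n_unassigned`, `n_unassigned_crossing`.
#' @export
build_disconnection_matrix <- function(tract, crossing, assignments,
                                       labels = NULL) {
  stopifnot(inherits(tract, "tractogram"))
  asg <- assignments
  if (is.null(labels))
    labels <- sort(unique(c(asg$region_a[asg$assigned],
                            asg$region_b[asg$assigned])))
  labels <- as.integer(labels)
  R <- length(labels)
  total <- matrix(0, R, R, dimnames = list(labels, labels))
  cross <- matrix(0, R, R, dimnames = list(labels, labels))
  is_cross <- asg$streamline %in% crossing
  for (r in which(asg$assigned)) {
    ia <- match(asg$region_a[r], labels)
    ib <- match(asg$region_b[r], labels)
    total[ia, ib] <- total[ia, ib] + 1
    if (ia != ib) total[ib, ia] <- total[ib, ia] + 1
    if (is_cross[r]) {
      cross[ia, ib] <- cross[ia, ib] + 1
      if (ia != ib) cross[ib, ia] <- cross[ib, ia] + 1
    }
  }
  prop <- ifelse(total > 0, cross / pmax(total, 1), 0)
  region_total <- rowSums(total)
  region_cross <- rowSums(cross)
  region_prop <- ifelse(region_total > 0, region_cross / pmax(region_total, 1), 0)
  structure(list(labels = labels, total_counts = total,
                 crossing_counts = cross, proportion = prop,
                 region_total_crossing = region_cross,
                 region_total = region_total,
                 region_proportion = region_prop,
                 n_unassigned = sum(!asg$assigned),
                 n_unassigned_crossing = sum(!asg$assigned & is_cross)),
            class = "disconnection_matrix")
}

#' @export
print.disconnection_matrix <- function(x, ...) {
  cat("<disconnection_matrix> ", length(x$labels), " regions, ",
      sum(x$total_counts[upper.tri(x$total_counts, diag = TRUE)]),
      " streamlines (", sum(x$crossing_counts[upper.tri(x$crossing_counts,
                                                        diag = TRUE)]),
      " crossing the mask, ", x$n_unassigned, " unassigned)\n", sep = "")
  invisible(x)
}

#' Disconnection edge list above a count threshold
#'
#' Unordered region pairs with at least `min_count` crossing streamlines,
#' sorted by crossing count descending, then by label pair.
#'
#' @param matrix A [build_disconnection_matrix()] result.
#' @param min_count Minimum crossing count to report. Default 0 reports all
#'   pairs with nonzero totals.
#' @return Tibble with `region_a`, `region_b`, `crossing`, `total`,
#'   `proportion`.
#' @export
report_edges <- function(matrix, min_count = 0L) {
  stopifnot(inherits(matrix, "disconnection_matrix"))
  labels <- matrix$labels
  R <- length(labels)
  rows <- list()
  for (i in seq_len(R)) for (j in i:R) {
    tot <- matrix$total_counts[i, j]
    crs <- matrix$crossing_counts[i, j]
    if (tot > 0 && crs >= min_count)
      rows[[length(rows) + 1L]] <-
        tibble::tibble(region_a = labels[i], region_b = labels[j],
                       crossing = crs, total = tot,
                       proportion = matrix$proportion[i, j])
  }
  if (length(rows) == 0L)
    return(tibble::tibble(region_a = integer(0), region_b = integer(0),
                          crossing = numeric(0), total = numeric(0),
                          proportion = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(-out$crossing, out$region_a, out$region_b), ]
}

#' Per-region disconnection table
#'
#' One row per region: total crossing streamlines and the crossing
#' proportion over all streamlines touching the region (intra-region
#' streamlines counted once).
#'
#' @param matrix A [build_disconnection_matrix()] result.
#' @param min_crossing Report only regions with at least this many crossing
#'   streamlines. Default 0.
#' @return Tibble with `region`, `n_disconnections`, `n_total`,
#'   `fibre_damage_pct`, sorted by `n_disconnections` descending.
#' @export
report_regions <- function(matrix, min_crossing = 0L) {
  stopifnot(inherits(matrix, "disconnection_matrix"))
  out <- tibble::tibble(region = matrix$labels,
                        n_disconnections = matrix$region_total_crossing,
                        n_total = matrix$region_total,
                        fibre_damage_pct = 100 * matrix$region_proportion)
  out <- out[out$n_disconnections >= min_crossing, ]
  out[order(-out$n_disconnections, out$region), ]
}

#' Write disconnection matrices and tables as TSV
#'
#' @param matrix A [build_disconnection_matrix()] result.
#' @param dir Output directory (created if needed).
#' @param min_count Edge-list threshold passed to [report_edges()].
#' @return `dir`, invisibly.
#' @export
write_disconnection <- function(matrix, dir, min_count = 0L) {
  stopifnot(inherits(matrix, "disconnection_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = TRUE,
                                          col.names = NA)
  wt(matrix$total_counts, "total_counts.tsv")
  wt(matrix$crossing_counts, "crossing_counts.tsv")
  wt(matrix$proportion, "proportion.tsv")
  utils::write.table(report_regions(matrix), file.path(dir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report_edges(matrix, min_count),
                     file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
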