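#' Volumetric image with a world-from-voxel affine
#'
#' A `volume` is the package's minimal container for a 3D image: a numeric or
#' integer array plus a 4x4 affine mapping 0-based voxel indices to world
#' coordinates in millimetres. Binary masks, integer parcellations, FA maps
#' and statistical maps are all volumes.
#'
#' @param data A 3D array (numeric or integer).
#' @param affine A 4x4 invertible matrix; `world = affine %*% c(i, j, k, 1)`
#'   for 0-based voxel `(i, j, k)`. Defaults to the identity (1 mm isotropic
#'   grid anchored at the origin).
#' @return An object of class `volume` with elements `data`, `affine`, `shape`.
#' @examples
#' v <- volume(array(1, c(2, 2, 2)))
#' v$shape
#' @export
volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " dimensions",
         call. = FALSE)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  if (abs(det(affine)) < .Machine$double.eps * 64)
    stop("affine is singular", call. = FALSE)
  structure(list(data = data, affine = affine, shape = dim(data)),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat("<volume> ", paste(x$shape, collapse = " x "),
      " | voxel volume ", format(voxel_volume(x)), " mm^3\n", sep = "")
  invisible(x)
}

#' @export
dim.volume <- function(x) x$shape

is_binary <- function(vol) {
  u <- unique(as.vector(vol$data))
  all(u %in% c(0, 1))
}

stopifnot_binary <- function(vol, what = "mask") {
  if (!is_binary(vol))
    stop(what, " must be binary (values in {0, 1})", call. = FALSE)
  invisible(vol)
}

same_geometry <- function(a, b, tol = 1e-5) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

#' Voxel volume in cubic millimetres
#'
#' Computed from the absolute determinant of the spatial 3x3 block of the
#' affine, so anisotropic and rotated grids are handled.
#'
#' @param vol A [volume].
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume <- function(vol) {
  abs(det(vol$affine[1:3, 1:3]))
}

#' Read a NIfTI-1 volume
#'
#' Reads `.nii` / `.nii.gz` images. Integer-typed images keep their exact
#' labels; the world-from-voxel affine is taken from the image's xform.
#'
#' @param path Path to a 3D NIfTI-1 file.
#' @return A [volume].
#' @export
load_volume <- function(path) {
  if (!file.exists(path))
    stop("cannot read volume: file does not exist: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("cannot read '", path, "' as NIfTI: ",
                         conditionMessage(e), call. = FALSE))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a 3D image, but '", path, "' has ", length(d),
         " dimensions", call. = FALSE)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  arr <- as.array(img)
  attributes(arr) <- list(dim = d)
  volume(arr, aff)
}

#' Write a volume as NIfTI-1
#'
#' @param vol A [volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype On-disk datatype; `"double"` (the default) round-trips
#'   numeric data bitwise, integer arrays are stored as `int32`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = NULL) {
  stopifnot(inherits(vol, "volume"))
  if (is.null(datatype))
    datatype <- if (is.integer(vol$data)) "int32" else "double"
  img <- RNifti::asNifti(vol$data, datatype = datatype)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Ordered index of in-mask voxels
#'
#' Enumerates the nonzero voxels of a binary mask as 0-based integer triples
#' in deterministic lexicographic order (sorted by i, then j, then k). The
#' index fixes the column order of every feature matrix built from the mask.
#'
#' @param mask A binary [volume].
#' @return An object of class `voxel_index`: list with `coords` (n x 3
#'   integer matrix, 0-based), `shape`, `affine`.
#' @export
voxel_index <- function(mask) {
  stopifnot(inherits(mask, "volume"))
  stopifnot_binary(mask)
  idx <- which(mask$data != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("mask is empty: no nonzero voxels", call. = FALSE)
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  coords <- idx - 1L
  storage.mode(coords) <- "integer"
  dimnames(coords) <- NULL
  structure(list(coords = coords, shape = mask$shape, affine = mask$affine),
            class = "voxel_index")
}

#' @export
length.voxel_index <- function(x) nrow(x$coords)

#' @export
print.voxel_index <- function(x, ...) {
  cat("<voxel_index> ", nrow(x$coords), " voxels in a ",
      paste(x$shape, collapse = " x "), " grid\n", sep = "")
  invisible(x)
}

linear_index <- function(coords, shape) {
  # 0-based triples -> 1-based R linear (column-major) indices
  1L + coords[, 1] + shape[1] * (coords[, 2] + shape[2] * coords[, 3])
}

#' Convert 0-based voxel coordinates to world millimetres
#'
#' @param coords n x 3 matrix of 0-based voxel coordinates.
#' @param affine 4x4 world-from-voxel matrix.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(coords, affine) {
  coords <- matrix(coords, ncol = 3)
  h <- cbind(coords, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Map world millimetre points to nearest voxels
#'
#' A world point is assigned to the voxel whose centre is nearest: the affine
#' is inverted and the result rounded half-away-from-zero. Points are not
#' clipped to the grid; out-of-grid triples are returned as-is.
#'
#' @param points n x 3 matrix of world coordinates (mm).
#' @param affine 4x4 world-from-voxel matrix.
#' @return n x 3 integer matrix of 0-based voxel coordinates.
#' @export
world_to_voxel <- function(points, affine) {
  points <- matrix(points, ncol = 3)
  inv <- solve(affine)
  h <- cbind(points, 1) %*% t(inv)
  v <- round_half_away(h[, 1:3, drop = FALSE])
  storage.mode(v) <- "integer"
  v
}

#' Skeleton feature dataset: subjects x in-mask voxels
#'
#' Binds a subjects-by-voxels FA feature matrix to the [voxel_index] that
#' defines its column order. FA values are expected in \[0, 1\]; values
#' outside by more than `1e-6` are clipped with a warning (projection
#' overshoot is common in skeletonization pipelines).
#'
#' @param features Numeric matrix, one row per subject.
#' @param vindex A [voxel_index]; its length must match `ncol(features)`.
#' @param subject_ids Character vector of subject identifiers (default
#'   `"S1"..."Sn"`).
#' @param clip Clip FA values to \[0, 1\]? Default `TRUE`.
#' @return An object of class `skeleton_dataset`.
#' @export
skeleton_dataset <- function(features, vindex, subject_ids = NULL, clip = TRUE) {
  features <- as.matrix(features)
  stopifnot(inherits(vindex, "voxel_index"))
  if (ncol(features) != length(vindex))
    stop("feature matrix has ", ncol(features), " columns but voxel index has ",
         length(vindex), " voxels", call. = FALSE)
  if (anyNA(features) || any(!is.finite(features)))
    stop("feature matrix contains missing or non-finite values", call. = FALSE)
  if (is.null(subject_ids))
    subject_ids <- paste0("S", seq_len(nrow(features)))
  if (length(subject_ids) != nrow(features))
    stop("subject_ids length does not match number of rows", call. = FALSE)
  if (clip) {
    out <- features < -1e-6 | features > 1 + 1e-6
    if (any(out))
      warning(sum(out), " FA values outside [0, 1] were clipped")
    features[features < 0] <- 0
    features[features > 1] <- 1
  }
  dimnames(features) <- NULL
  structure(list(features = features, subject_ids = as.character(subject_ids),
                 voxel_index = vindex),
            class = "skeleton_dataset")
}

#' @export
print.skeleton_dataset <- function(x, ...) {
  cat("<skeleton_dataset> ", nrow(x$features), " subjects x ",
      ncol(x$features), " skeleton voxels\n", sep = "")
  invisible(x)
}

#' Extract a masked feature matrix from per-subject volumes
#'
#' Row i of the result holds subject i's voxel values at the mask voxels, in
#' [voxel_index] order. All volumes must share the mask's geometry.
#'
#' @param volumes List of [volume]s, one per subject.
#' @param mask Binary [volume]; must be nonempty.
#' @param subject_ids Optional subject identifiers.
#' @param clip Passed to [skeleton_dataset()].
#' @return A `skeleton_dataset`.
#' @export
extract_matrix <- function(volumes, mask, subject_ids = NULL, clip = TRUE) {
  stopifnot(inherits(mask, "volume"))
  if (inherits(volumes, "volume")) volumes <- list(volumes)
  vindex <- voxel_index(mask)
  lin <- linear_index(vindex$coords, vindex$shape)
  rows <- lapply(seq_along(volumes), function(i) {
    v <- volumes[[i]]
    if (!inherits(v, "volume"))
      stop("volumes[[", i, "]] is not a volume", call. = FALSE)
    if (!same_geometry(v, mask))
      stop("volume ", i, " does not share shape/affine with the mask",
           call. = FALSE)
    as.numeric(v$data[lin])
  })
  skeleton_dataset(do.call(rbind, rows), vindex, subject_ids, clip = clip)
}

#' Render per-voxel values back into a volume
#'
#' Inverse of [extract_matrix()] for a single map: the indexed voxels receive
#' `values`, everything else receives `fill`.
#'
#' @param values Numeric vector, one value per indexed voxel.
#' @param vindex A [voxel_index].
#' @param fill Value for voxels outside the index (default 0; `NA` is allowed).
#' @return A [volume] with the index's shape and affine.
#' @export
project_map <- function(values, vindex, fill = 0) {
  stopifnot(inherits(vindex, "voxel_index"))
  if (length(values) != length(vindex))
    stop("values length (", length(values), ") does not match voxel index (",
         length(vindex), ")", call. = FALSE)
  arr <- array(fill, dim = vindex$shape)
  arr[linear_index(vindex$coords, vindex$shape)] <- values
  volume(arr, vindex$affine)
}
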