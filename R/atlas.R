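#' Probabilistic tract atlas
#'
#' Named probabilistic tract maps (values in \[0, 1\]) sharing one geometry,
#' each tagged with a fibre category (association, projection, commissural).
#' No atlas is bundled; maps are user-supplied (or fabricated by the phantom
#' tooling for tests).
#'
#' @param maps Named list of [volume]s with values in \[0, 1\].
#' @param categories Character vector, one category per map.
#' @return An object of class `tract_atlas`.
#' @export
tract_atlas <- function(maps, categories) {
  if (is.null(names(maps)) || any(names(maps) == ""))
    stop("atlas maps must be named", call. = FALSE)
  if (length(categories) != length(maps))
    stop("one category per map is required", call. = FALSE)
  ref <- maps[[1]]
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (!inherits(m, "volume"))
      stop("atlas map '", nm, "' is not a volume", call. = FALSE)
    if (!same_geometry(m, ref))
      stop("atlas map '", nm, "' does not share the atlas geometry",
           call. = FALSE)
    if (any(m$data < 0 | m$data > 1))
      stop("atlas map '", nm, "' has probabilities outside [0, 1]",
           call. = FALSE)
  }
  structure(list(maps = maps, categories = as.character(categories)),
            class = "tract_atlas")
}

#' @export
print.tract_atlas <- function(x, ...) {
  cat("<tract_atlas> ", length(x$maps), " tract maps (",
      paste(unique(x$categories), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Binarize a probabilistic map at a probability cutoff
#'
#' The cutoff is inclusive: a voxel is set iff its probability is
#' `>= threshold`.
#'
#' @param prob_map A probabilistic [volume].
#' @param threshold Cutoff in \[0, 1\]. Default 0.4.
#' @return A binary [volume].
#' @export
binarize_map <- function(prob_map, threshold = 0.4) {
  stopifnot(inherits(prob_map, "volume"))
  if (threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]", call. = FALSE)
  volume(array(as.numeric(prob_map$data >= threshold), dim = prob_map$shape),
         prob_map$affine)
}

#' Overlap of a significance mask with probabilistic tract maps
#'
#' Each tract map is binarized at `threshold`; the overlap is the voxel
#' count of the intersection with the significance mask times the voxel
#' volume (mm^3). Tracts overlapping less than `min_volume_mm3` are omitted.
#' Rows are sorted by category, then tract name.
#'
#' @param sig_mask Binary [volume].
#' @param atlas A [tract_atlas].
#' @param min_volume_mm3 Reporting floor in mm^3. Default 20.
#' @param threshold Binarization cutoff. Default 0.4.
#' @return Tibble with `tract`, `category`, `overlap_mm3`.
#' @export
overlap_report <- function(sig_mask, atlas, min_volume_mm3 = 20,
                           threshold = 0.4) {
  stopifnot(inherits(sig_mask, "volume"), inherits(atlas, "tract_atlas"))
  stopifnot_binary(sig_mask, "sig_mask")
  if (!same_geometry(sig_mask, atlas$maps[[1]]))
    stop("significance mask does not share the atlas geometry", call. = FALSE)
  vv <- voxel_volume(sig_mask)
  rows <- lapply(seq_along(atlas$maps), function(i) {
    bin <- binarize_map(atlas$maps[[i]], threshold)
    ov <- sum(sig_mask$data != 0 & bin$data != 0) * vv
    tibble::tibble(tract = names(atlas$maps)[i],
                   category = atlas$categories[i], overlap_mm3 = ov)
  })
  out <- do.call(rbind, rows)
  out <- out[out$overlap_mm3 >= min_volume_mm3, ]
  out[order(out$category, out$tract), ]
}

#' Load a tract atlas from a manifest TSV
#'
#' The manifest has a header row and columns `tract_name`, `category`,
#' `path` (NIfTI paths, relative paths resolved against the manifest's
#' directory).
#'
#' @param path Path to the manifest TSV.
#' @return A [tract_atlas].
#' @export
read_atlas_manifest <- function(path) {
  if (!file.exists(path))
    stop("atlas manifest does not exist: ", path, call. = FALSE)
  man <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("tract_name", "category", "path") %in% names(man)))
    stop("manifest needs columns tract_name, category, path", call. = FALSE)
  base <- dirname(path)
  maps <- lapply(man$path, function(p) {
    if (!file.exists(p) && file.exists(file.path(base, p)))
      p <- file.path(base, p)
    load_volume(p)
  })
  names(maps) <- man$tract_name
  tract_atlas(maps, man$category)
}
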