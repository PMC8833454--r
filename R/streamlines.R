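#' Tractogram: streamlines in world coordinates
#'
#' A thin container for a set of streamlines, each an n x 3 matrix of world
#' (scanner) coordinates in millimetres, together with the affine of the
#' companion voxel grid used for mask intersection.
#'
#' @param streamlines List of numeric matrices with 3 columns and >= 2 rows.
#' @param affine 4x4 world-from-voxel affine of the companion grid.
#' @param ground_truth_pairs Optional integer matrix (n x 2) recording, for
#'   synthetic tractograms, the planted region pair of each streamline.
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(streamlines, affine = diag(4), ground_truth_pairs = NULL) {
  streamlines <- lapply(seq_along(streamlines), function(i) {
    s <- streamlines[[i]]
    s <- matrix(as.numeric(s), ncol = 3)
    if (nrow(s) < 2L)
      stop("streamline ", i, " has fewer than 2 points", call. = FALSE)
    if (any(!is.finite(s)))
      stop("streamline ", i, " contains non-finite coordinates", call. = FALSE)
    s
  })
  structure(list(streamlines = streamlines, affine = as.matrix(affine),
                 ground_truth_pairs = ground_truth_pairs),
            class = "tractogram")
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' @export
print.tractogram <- function(x, ...) {
  np <- vapply(x$streamlines, nrow, integer(1))
  cat("<tractogram> ", length(x$streamlines), " streamlines",
      if (length(np)) paste0(" (", min(np), "-", max(np), " points each)"),
      "\n", sep = "")
  invisible(x)
}

#' Read a streamline file (TCK or TRK)
#'
#' Streamlines are returned in world millimetre coordinates regardless of the
#' on-disk convention: TCK stores world coordinates natively; TRK "voxmm"
#' coordinates are mapped through the header's voxel-to-RAS transform with
#' the half-voxel corner offset.
#'
#' @param path Path to a `.tck` or `.trk` file.
#' @param affine Affine to attach as the companion-grid transform (TCK only;
#'   TRK uses its header transform). Default identity.
#' @return A [tractogram].
#' @export
read_streamlines <- function(path, affine = diag(4)) {
  if (!file.exists(path))
    stop("streamline file does not exist: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tck = read_tck(path, affine),
         trk = read_trk(path),
         stop("unsupported streamline format '.", ext,
              "' (expected .tck or .trk)", call. = FALSE))
}

#' Write a tractogram to TCK or TRK
#'
#' @param tract A [tractogram].
#' @param path Output path; format chosen by extension.
#' @param shape Grid dimensions for the TRK header (required for `.trk`).
#' @return `path`, invisibly.
#' @export
write_streamlines <- function(tract, path, shape = NULL) {
  stopifnot(inherits(tract, "tractogram"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tck = write_tck(tract, path),
         trk = write_trk(tract, path, shape),
         stop("unsupported streamline format '.", ext, "'", call. = FALSE))
  invisible(path)
}

# ---- TCK (MRtrix) ---------------------------------------------------------
# Text header ("mrtrix tracks" magic, key: value lines, END), then float32
# triplets; an NaN triplet separates streamlines and an Inf triplet ends the
# stream.

read_tck <- function(path, affine) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!identical(magic, "mrtrix tracks"))
    stop("'", path, "' is not an MRtrix .tck file (bad magic line)",
         call. = FALSE)
  datatype <- "Float32LE"
  offset <- NA_real_
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop("malformed .tck header: no END line", call. = FALSE)
    if (identical(line, "END")) break
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) {
      key <- trimws(kv[2]); val <- trimws(kv[3])
      if (key == "datatype") datatype <- val
      if (key == "file") offset <- as.numeric(sub("^\\.\\s+", "", val))
    }
  }
  if (is.na(offset))
    stop("malformed .tck header: missing 'file' offset", call. = FALSE)
  endian <- if (grepl("BE$", datatype)) "big" else "little"
  if (!grepl("^Float32", datatype))
    stop("unsupported .tck datatype: ", datatype, call. = FALSE)
  seek(con, where = offset, origin = "start")
  raw <- readBin(con, what = "numeric", size = 4L, n = file.size(path),
                 endian = endian)
  parse_triplet_stream(raw)
}

parse_triplet_stream <- function(raw) {
  if (length(raw) %% 3L != 0L)
    stop("malformed .tck body: point data is not a whole number of triplets",
         call. = FALSE)
  pts <- matrix(raw, ncol = 3, byrow = TRUE)
  is_sep <- rowSums(is.na(pts)) > 0
  is_end <- rowSums(is.infinite(pts)) > 0
  streamlines <- list()
  cur_start <- 1L
  for (r in seq_len(nrow(pts))) {
    if (is_end[r]) break
    if (is_sep[r]) {
      if (r > cur_start)
        streamlines[[length(streamlines) + 1L]] <-
          pts[cur_start:(r - 1L), , drop = FALSE]
      cur_start <- r + 1L
    }
  }
  tractogram_allow_empty(streamlines)
}

tractogram_allow_empty <- function(streamlines, affine = diag(4)) {
  if (length(streamlines) == 0L)
    return(structure(list(streamlines = list(), affine = affine,
                          ground_truth_pairs = NULL),
                     class = "tractogram"))
  tractogram(streamlines, affine)
}

write_tck <- function(tract, path) {
  n <- length(tract$streamlines)
  body_triplets <- sum(vapply(tract$streamlines, nrow, integer(1))) + n + 1L
  header_fixed <- paste0("mrtrix tracks\n",
                         "datatype: Float32LE\n",
                         "count: ", n, "\n")
  # 'file: . <offset>' must state the final byte offset of the binary body;
  # the offset's own digits change the header length, so fix the width first.
  for (width in 2:8) {
    offset <- nchar(header_fixed) + nchar("file: . ") + width + nchar("\nEND\n")
    if (nchar(as.character(offset)) <= width) break
  }
  offset_str <- formatC(offset, width = width, flag = "0")
  header <- paste0(header_fixed, "file: . ", offset_str, "\nEND\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  for (s in tract$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

# ---- TRK (TrackVis) -------------------------------------------------------
# 1000-byte binary header (version 2, with a voxel-to-RAS matrix), then per
# streamline: int32 point count + float32 points in "voxmm" coordinates
# (voxel indices scaled by voxel size, corner-anchored, i.e. the centre of
# voxel (0,0,0) sits at voxel_size/2).

trk_voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", n = 6L)
  if (!identical(rawToChar(id[1:5]), "TRACK"))
    stop("'", path, "' is not a TrackVis .trk file (bad magic)", call. = FALSE)
  dim3 <- readBin(con, "integer", n = 3L, size = 2L, endian = "little")
  voxel_size <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  invisible(readBin(con, "numeric", n = 3L, size = 4L, endian = "little")) # origin
  n_scalars <- readBin(con, "integer", n = 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", n = 200L))
  n_properties <- readBin(con, "integer", n = 1L, size = 2L, endian = "little")
  invisible(readBin(con, "raw", n = 200L))
  vox_to_ras <- matrix(readBin(con, "numeric", n = 16L, size = 4L,
                               endian = "little"), 4, 4, byrow = TRUE)
  invisible(readBin(con, "raw", n = 444L + 4L + 4L + 24L + 2L + 6L))
  n_count <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  version <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (hdr_size != 1000L)
    stop("malformed .trk header (hdr_size = ", hdr_size, ")", call. = FALSE)
  if (version < 2L || all(vox_to_ras == 0))
    vox_to_ras <- diag(c(voxel_size, 1))
  streamlines <- list()
  repeat {
    npts <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(npts) == 0L) break
    vals <- readBin(con, "numeric",
                    n = npts * (3L + n_scalars) + n_properties,
                    size = 4L, endian = "little")
    pts <- matrix(vals[seq_len(npts * (3L + n_scalars))],
                  ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(pts, 2, voxel_size, "/") - 0.5
    world <- voxel_to_world(vox, vox_to_ras)
    streamlines[[length(streamlines) + 1L]] <- world
  }
  out <- tractogram_allow_empty(streamlines, affine = vox_to_ras)
  out
}

write_trk <- function(tract, path, shape = NULL) {
  affine <- tract$affine
  voxel_size <- trk_voxel_size(affine)
  if (is.null(shape)) shape <- c(0L, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0L)), con)
  writeBin(as.integer(shape), con, size = 2L, endian = "little")
  writeBin(as.numeric(voxel_size), con, size = 4L, endian = "little")
  writeBin(numeric(3), con, size = 4L, endian = "little")      # origin
  writeBin(0L, con, size = 2L, endian = "little")              # n_scalars
  writeBin(raw(200L), con)
  writeBin(0L, con, size = 2L, endian = "little")              # n_properties
  writeBin(raw(200L), con)
  writeBin(as.numeric(t(affine)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)
  writeChar("RAS", con, nchars = 3, eos = NULL); writeBin(raw(1L), con)
  writeBin(raw(4L), con)                                       # pad2
  writeBin(numeric(6), con, size = 4L, endian = "little")      # orientation
  writeBin(raw(2L), con)                                       # pad1
  writeBin(raw(6L), con)                                       # invert/swap
  writeBin(length(tract$streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")              # version
  writeBin(1000L, con, size = 4L, endian = "little")
  inv <- solve(affine)
  for (s in tract$streamlines) {
    vox <- cbind(s, 1) %*% t(inv)
    voxmm <- sweep(vox[, 1:3, drop = FALSE] + 0.5, 2, voxel_size, "*")
    writeBin(nrow(s), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(voxmm)), con, size = 4L, endian = "little")
  }
  invisible(path)
}
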