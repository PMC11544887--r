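#' NIfTI volume I/O
#'
#' Thin wrappers over RNifti using the package's spatial convention: the
#' voxel-to-world transform is diagonal in the voxel size with the first
#' voxel center at the origin.
#'
#' @param arr 3D or 4D numeric array.
#' @param voxel_size mm (length 3).
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_nifti_volume <- function(arr, voxel_size, path) {
  nd <- length(dim(arr))
  pd <- c(-1, voxel_size, rep(1, 8 - 1 - length(voxel_size)))
  im <- RNifti::asNifti(arr, list(pixdim = pd))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @return `read_nifti_volume`: list with `data` array and `voxel_size`.
#' @export
read_nifti_volume <- function(path) {
  im <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(im)[1:3]
  list(data = array(as.numeric(im), dim = dim(im)), voxel_size = vs)
}

#' Write / read a DWI dataset (NIfTI + FSL bvals/bvecs + JSON sidecar)
#'
#' `<prefix>.nii.gz`, `<prefix>.bval`, `<prefix>.bvec`, and
#' `<prefix>.json` (generation parameters, when provided).
#' @param dwi a `dwi_volume`.
#' @param prefix path prefix.
#' @param params optional list echoed to the JSON sidecar.
#' @export
write_dwi <- function(dwi, prefix, params = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  write_nifti_volume(dwi$signal, dwi$voxel_size, paste0(prefix, ".nii.gz"))
  write_bvalbvec(dwi$gtab, prefix)
  if (!is.null(params))
    jsonlite::write_json(params, paste0(prefix, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_dwi
#' @export
read_dwi <- function(prefix) {
  vol <- read_nifti_volume(paste0(prefix, ".nii.gz"))
  gtab <- read_bvalbvec(prefix)
  structure(list(signal = vol$data, voxel_size = vol$voxel_size,
                 affine = default_affine(vol$voxel_size), gtab = gtab),
            class = "dwi_volume")
}

#' TrackVis TRK tractogram I/O
#'
#' Binary TRK version 2 with the header's voxel size, dimensions and
#' voxel-to-world matrix populated. Point payloads are float32; coordinates
#' are stored in world mm (the header transform is the package's diagonal
#' convention).
#' @param tracts a `tractogram`.
#' @param path output `.trk` path.
#' @param dims grid dimensions for the header (defaults to the bounding
#'   grid implied by the streamlines).
#' @export
write_trk <- function(tracts, path, dims = NULL) {
  stopifnot(inherits(tracts, "tractogram"))
  if (is.null(dims)) {
    hi <- if (length(tracts$streamlines))
      apply(do.call(rbind, tracts$streamlines), 2, max) else c(0, 0, 0)
    dims <- pmax(1L, as.integer(ceiling(hi / tracts$voxel_size)) + 1L)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5, eos = NULL)
  writeBin(raw(1), con)
  writeBin(as.integer(dims), con, size = 2)
  writeBin(as.numeric(tracts$voxel_size), con, size = 4)
  writeBin(numeric(3), con, size = 4)                   # origin
  writeBin(0L, con, size = 2)                           # n_scalars
  writeBin(raw(200), con)                               # scalar names
  writeBin(0L, con, size = 2)                           # n_properties
  writeBin(raw(200), con)                               # property names
  writeBin(as.numeric(t(tracts$affine)), con, size = 4) # vox_to_ras
  writeBin(raw(444), con)                               # reserved
  writeChar("LPS", con, nchars = 3, eos = NULL)         # voxel_order
  writeBin(raw(1), con)
  writeBin(raw(4), con)                                 # pad2
  writeBin(numeric(6), con, size = 4)                   # image orientation
  writeBin(raw(2), con)                                 # pad1
  writeBin(raw(6), con)                                 # invert/swap flags
  writeBin(length(tracts$streamlines), con, size = 4)   # n_count
  writeBin(2L, con, size = 4)                           # version
  writeBin(1000L, con, size = 4)                        # hdr_size
  for (s in tracts$streamlines) {
    writeBin(nrow(s), con, size = 4)
    writeBin(as.numeric(t(s)), con, size = 4)
  }
  invisible(path)
}

#' @rdname write_trk
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 5, useBytes = TRUE)
  if (magic != "TRACK") stopf("not a TRK file: %s", path)
  readBin(con, raw(), 1)
  dims <- readBin(con, integer(), 3, size = 2)
  voxel_size <- readBin(con, numeric(), 3, size = 4)
  readBin(con, numeric(), 3, size = 4)
  n_scalars <- readBin(con, integer(), 1, size = 2)
  readBin(con, raw(), 200)
  n_props <- readBin(con, integer(), 1, size = 2)
  readBin(con, raw(), 200)
  affine <- matrix(readBin(con, numeric(), 16, size = 4), 4, 4, byrow = TRUE)
  readBin(con, raw(), 444 + 4 + 4 + 24 + 2 + 6)
  n_count <- readBin(con, integer(), 1, size = 4)
  version <- readBin(con, integer(), 1, size = 4)
  readBin(con, integer(), 1, size = 4)
  sl <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, integer(), 1, size = 4)
    pts <- readBin(con, numeric(), np * (3 + n_scalars), size = 4)
    m <- matrix(pts, ncol = 3 + n_scalars, byrow = TRUE)
    sl[[i]] <- m[, 1:3, drop = FALSE]
    if (n_props > 0) readBin(con, numeric(), n_props, size = 4)
  }
  tractogram(sl, voxel_size, affine)
}

#' MRtrix TCK tractogram I/O
#'
#' Float32 little-endian track file: streamlines separated by NaN triplets
#' and terminated by an Inf triplet.
#' @param tracts a `tractogram`.
#' @param path output `.tck` path.
#' @export
write_tck <- function(tracts, path) {
  stopifnot(inherits(tracts, "tractogram"))
  hdr <- c("mrtrix tracks", "datatype: Float32LE",
           sprintf("count: %d", length(tracts$streamlines)))
  # compute the data offset including the 'file' line itself
  base <- sum(nchar(hdr)) + length(hdr) + nchar("END\n")
  off <- base + nchar("file: . ") + 1
  repeat {
    line <- sprintf("file: . %d", off)
    total <- base + nchar(line) + 1
    if (total == off) break
    off <- total
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste(c(hdr, line, "END"), collapse = "\n"), con, eos = NULL)
  writeChar("\n", con, eos = NULL)
  for (s in tracts$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(as.numeric(rep(NaN, 3)), con, size = 4, endian = "little")
  }
  writeBin(as.numeric(rep(Inf, 3)), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_tck
#' @param voxel_size spatial reference to attach on read.
#' @export
read_tck <- function(path, voxel_size = c(1, 1, 1)) {
  raw_all <- readBin(path, raw(), file.size(path))
  hdr_end <- grepRaw("END\n", raw_all, fixed = TRUE)
  hdr <- rawToChar(raw_all[seq_len(hdr_end - 1)])
  if (!grepl("^mrtrix tracks", hdr)) stopf("not a TCK file: %s", path)
  off_line <- regmatches(hdr, regexpr("file: \\. [0-9]+", hdr))
  off <- as.integer(sub("file: \\. ", "", off_line))
  vals <- readBin(raw_all[(off + 1):length(raw_all)], numeric(),
                  (length(raw_all) - off) / 4, size = 4, endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  is_nan <- is.nan(m[, 1])
  is_inf <- is.infinite(m[, 1])
  breaks <- which(is_nan | is_inf)
  sl <- list()
  start <- 1
  for (b in breaks) {
    if (b > start) sl[[length(sl) + 1]] <- m[start:(b - 1), , drop = FALSE]
    start <- b + 1
    if (is_inf[b]) break
  }
  tractogram(sl, voxel_size)
}
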