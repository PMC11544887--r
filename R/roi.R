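#' Tumor region-of-interest mask
#'
#' Wraps a binary mask on the DWI lattice and precomputes its boundary shell
#' (mask voxels with a 6-neighbor outside the mask or on the grid edge),
#' whose world-coordinate centers support signed surface-distance queries:
#' negative inside the mask, positive outside, zero on the boundary shell
#' voxel centers.
#'
#' @param mask logical 3D array (non-empty).
#' @param voxel_size mm.
#' @param affine optional 4x4 voxel-to-world transform.
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(mask, voxel_size, affine = NULL) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  mask <- mask > 0
  if (!any(mask)) stopf("ROI mask is empty")
  dims <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  on_boundary <- rep(FALSE, nrow(idx))
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- idx
      nb[, ax] <- nb[, ax] + s
      outside <- nb[, ax] < 1 | nb[, ax] > dims[ax]
      inb <- !outside
      nbv <- rep(FALSE, nrow(idx))
      nbv[inb] <- mask[nb[inb, , drop = FALSE]]
      on_boundary <- on_boundary | outside | !nbv
    }
  }
  boundary_mm <- sweep(idx[on_boundary, , drop = FALSE] - 1, 2,
                       voxel_size, "*")
  structure(list(mask = mask, voxel_size = voxel_size,
                 affine = affine %||% default_affine(voxel_size),
                 boundary_mm = boundary_mm),
            class = "roi_mask")
}

# nearest-voxel containment of world points (n x 3) in the mask
points_in_roi <- function(roi, points) {
  ijk <- round(sweep(points, 2, roi$voxel_size, "/")) + 1
  dims <- dim(roi$mask)
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
  inside <- rep(FALSE, nrow(points))
  if (any(ok)) inside[ok] <- roi$mask[ijk[ok, , drop = FALSE]]
  inside
}

#' Signed distance from world points to the ROI surface
#'
#' Distance to the nearest boundary-shell voxel center, in mm; negative for
#' points inside the mask.
#' @param roi a `roi_mask`.
#' @param points matrix (n x 3) of mm coordinates.
#' @export
roi_surface_distance <- function(roi, points) {
  b <- roi$boundary_mm
  d <- apply(points, 1, function(p)
    sqrt(min((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2 + (b[, 3] - p[3])^2)))
  ifelse(points_in_roi(roi, points), -d, d)
}

#' Tumor volume of an ROI, cm^3
#' @param roi a `roi_mask`.
#' @export
roi_volume_cm3 <- function(roi) {
  sum(roi$mask) * prod(roi$voxel_size) / 1000
}

#' Select tumor-intersecting streamlines
#'
#' Keeps streamlines with at least one point inside the ROI (nearest-voxel
#' containment after the world-to-voxel transform).
#' @param tracts a `tractogram`.
#' @param roi a `roi_mask` on the same lattice.
#' @return filtered `tractogram`.
#' @export
select_tumor_tracts <- function(tracts, roi) {
  stopifnot(inherits(tracts, "tractogram"), inherits(roi, "roi_mask"))
  if (max(abs(tracts$affine - roi$affine)) > 1e-6)
    stopf("tractogram and ROI affines do not match")
  keep <- vapply(tracts$streamlines,
                 function(s) any(points_in_roi(roi, s)), logical(1))
  tractogram(tracts$streamlines[keep], tracts$voxel_size, tracts$affine,
             labels = if (!is.null(tracts$labels)) tracts$labels[keep])
}

#' Classify a tumor-intersecting streamline as core, shell or projecting
#'
#' `core`: every point inside the ROI. Otherwise let `e` be the maximum
#' surface distance over exterior points: `shell` when `e <= shell_margin`
#' (the tract adheres to the tumor surface), `projecting` when it extends
#' farther outward.
#'
#' @param s streamline point matrix (mm); must intersect the ROI.
#' @param roi a `roi_mask`.
#' @param shell_margin mm; default 3 (about the in-plane voxel diagonal).
#' @return one of `"core"`, `"shell"`, `"projecting"`.
#' @export
classify_tract <- function(s, roi, shell_margin = 3) {
  inside <- points_in_roi(roi, s)
  if (!any(inside)) stopf("streamline does not intersect the ROI")
  if (all(inside)) return("core")
  ext <- s[!inside, , drop = FALSE]
  e <- max(roi_surface_distance(roi, ext))
  if (e <= shell_margin) "shell" else "projecting"
}

#' @rdname classify_tract
#' @param tracts a `tractogram` of tumor-intersecting streamlines.
#' @return factor with levels core, shell, projecting.
#' @export
classify_tracts <- function(tracts, roi, shell_margin = 3) {
  factor(vapply(tracts$streamlines, classify_tract, character(1),
                roi = roi, shell_margin = shell_margin),
         levels = c("core", "shell", "projecting"))
}
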