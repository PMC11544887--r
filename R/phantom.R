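#' Parametric diffusion phantoms
#'
#' A phantom is a voxel grid carrying fiber bundles (tubes around parametric
#' centerlines, each with an axially symmetric diffusion tensor) and an
#' ellipsoidal "tumor" of isotropic diffusivity, embedded in an isotropic
#' background. Phantoms stand in for patient anatomy so the reconstruction,
#' tracking and tract-metric stages can be validated against known truth.
#'
#' @param grid_shape integer 3-vector, voxels.
#' @param voxel_size numeric 3-vector, mm.
#' @param bundles list of bundles from [bundle_straight()] (or any list with
#'   `centerline` (m x 3 mm polyline), `radius` (mm), `eigenvalues`
#'   (3, mm^2/s, descending) and `volume_fraction`).
#' @param tumor `NULL` or list with `center` (mm), `semi_axes` (mm) and
#'   `isotropic_diffusivity` (mm^2/s).
#' @param background_diffusivity isotropic diffusivity outside bundles and
#'   tumor, mm^2/s.
#' @param s0 unweighted signal level.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, voxel_size, bundles = list(),
                         tumor = NULL, background_diffusivity = 1.0e-3,
                         s0 = 100) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0),
            length(voxel_size) == 3, all(voxel_size > 0),
            background_diffusivity > 0, s0 > 0)
  for (b in bundles) {
    stopifnot(is.matrix(b$centerline), ncol(b$centerline) == 3,
              b$radius > 0, length(b$eigenvalues) == 3)
    if (any(b$eigenvalues <= 0) || is.unsorted(rev(b$eigenvalues)))
      stopf("bundle eigenvalues must be positive and sorted descending")
    stopifnot(b$volume_fraction > 0, b$volume_fraction <= 1)
  }
  fov <- grid_shape * voxel_size
  if (!is.null(tumor)) {
    stopifnot(length(tumor$center) == 3, length(tumor$semi_axes) == 3,
              all(tumor$semi_axes > 0), tumor$isotropic_diffusivity > 0)
    lo <- tumor$center - tumor$semi_axes
    hi <- tumor$center + tumor$semi_axes
    if (any(lo < -voxel_size / 2) || any(hi > fov - voxel_size / 2))
      stopf("tumor ellipsoid extends outside the grid")
  }
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 bundles = bundles, tumor = tumor,
                 background_diffusivity = background_diffusivity, s0 = s0),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param from,to endpoints of a straight centerline, mm.
#' @param radius tube radius, mm.
#' @param eigenvalues tensor eigenvalues along/perpendicular to the tube,
#'   mm^2/s, descending.
#' @param volume_fraction intra-bundle signal fraction per voxel.
#' @export
bundle_straight <- function(from, to, radius = 3,
                            eigenvalues = c(1.7, 0.3, 0.3) * 1e-3,
                            volume_fraction = 0.8) {
  n <- max(2, ceiling(vnorm(to - from)))   # ~1 mm sampling
  tt <- seq(0, 1, length.out = n)
  list(centerline = cbind(from[1] + tt * (to[1] - from[1]),
                          from[2] + tt * (to[2] - from[2]),
                          from[3] + tt * (to[3] - from[3])),
       radius = radius, eigenvalues = eigenvalues,
       volume_fraction = volume_fraction)
}

# voxel centers in mm for a grid (origin at first voxel center)
voxel_centers <- function(grid_shape, voxel_size) {
  xs <- (seq_len(grid_shape[1]) - 1) * voxel_size[1]
  ys <- (seq_len(grid_shape[2]) - 1) * voxel_size[2]
  zs <- (seq_len(grid_shape[3]) - 1) * voxel_size[3]
  list(x = xs, y = ys, z = zs,
       grid = as.matrix(expand.grid(x = xs, y = ys, z = zs)))
}

default_affine <- function(voxel_size) {
  a <- diag(c(voxel_size, 1))
  a
}

# distance from points (n x 3) to a polyline, plus tangent at nearest vertex
polyline_distance <- function(points, polyline) {
  m <- nrow(polyline)
  tang <- rbind(polyline[2, , drop = FALSE] - polyline[1, , drop = FALSE],
                (polyline[-(1:2), , drop = FALSE] -
                   polyline[seq_len(m - 2), , drop = FALSE]) / 2,
                polyline[m, , drop = FALSE] - polyline[m - 1, , drop = FALSE])
  if (m == 2) tang <- rbind(tang[1, , drop = FALSE], tang[1, , drop = FALSE])
  tang <- normalize_rows(tang)
  best_d <- rep(Inf, nrow(points))
  best_i <- rep(1L, nrow(points))
  for (i in seq_len(m)) {
    d2 <- (points[, 1] - polyline[i, 1])^2 +
      (points[, 2] - polyline[i, 2])^2 +
      (points[, 3] - polyline[i, 3])^2
    hit <- d2 < best_d
    best_d[hit] <- d2[hit]
    best_i[hit] <- i
  }
  list(distance = sqrt(best_d), tangent = tang[best_i, , drop = FALSE])
}

#' Simulate a diffusion-weighted volume from a phantom
#'
#' Multi-tensor forward model per voxel:
#' \deqn{S(g,b) = S_0 [\sum_k f_k e^{-b g^T D_k g} + f_{free} e^{-b d}]}
#' where the sum runs over bundles containing the voxel (a voxel belongs to a
#' bundle when its center lies within the tube radius of the centerline), and
#' the free compartment uses the tumor's isotropic diffusivity inside the
#' tumor ellipsoid and the background diffusivity elsewhere. Magnitude noise
#' is Rician: two independent Gaussian channels of width `s0/snr` on the
#' complex signal.
#'
#' @param spec a [phantom_spec()].
#' @param gtab a [make_gradient_table()] gradient table.
#' @param snr signal-to-noise ratio defined as `s0 / sigma`; `Inf` for
#'   noise-free signal.
#' @param seed RNG seed for the noise draw.
#' @return list with `dwi` (class `dwi_volume`: 4D `signal`, `voxel_size`,
#'   `affine`, `gtab`) and `truth` (per-voxel fiber directions
#'   `(nx,ny,nz,n_bundles,3)`, logical `bundle_membership`
#'   `(nx,ny,nz,n_bundles)`, logical `tumor` mask, `n_fibers`).
#' @export
simulate_dwi <- function(spec, gtab, snr = Inf, seed = 0) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(gtab, "gradient_table"))
  if (!(snr > 0)) stopf("snr must be positive (possibly Inf)")
  dims <- spec$grid_shape
  vc <- voxel_centers(dims, spec$voxel_size)
  nvox <- nrow(vc$grid)
  ngrad <- length(gtab$bvals)
  nb <- length(spec$bundles)

  # bundle membership and local tangents
  membership <- matrix(FALSE, nvox, max(1, nb))
  tangents <- vector("list", nb)
  for (k in seq_len(nb)) {
    bd <- spec$bundles[[k]]
    pd <- polyline_distance(vc$grid, bd$centerline)
    membership[, k] <- pd$distance <= bd$radius
    tangents[[k]] <- pd$tangent
  }

  tumor_mask <- rep(FALSE, nvox)
  if (!is.null(spec$tumor)) {
    u <- sweep(vc$grid, 2, spec$tumor$center)
    u <- sweep(u, 2, spec$tumor$semi_axes, "/")
    tumor_mask <- rowSums(u^2) <= 1
  }

  b <- gtab$bvals
  g <- gtab$bvecs
  d_free <- ifelse(tumor_mask, spec$tumor$isotropic_diffusivity %||% NA,
                   spec$background_diffusivity)
  if (!is.null(spec$tumor))
    d_free[tumor_mask] <- spec$tumor$isotropic_diffusivity

  # attenuation of a cylindrically parameterised tensor: for eigenvalues
  # (l1,l2,l3) with axis t and a fixed perpendicular frame (e2,e3):
  # g'Dg = l1 (g.t)^2 + l2 (g.e2)^2 + l3 (g.e3)^2
  signal <- matrix(0, nvox, ngrad)
  iso_att <- exp(-outer(d_free, b))          # nvox x ngrad
  fsum <- numeric(nvox)
  if (nb > 0) {
    ftot <- sapply(spec$bundles, function(x) x$volume_fraction)
    raw <- membership %*% diag(ftot, nb, nb)
    fsum <- rowSums(raw)
    scale <- ifelse(fsum > 1, 1 / fsum, 1)   # renormalise overlaps to sum 1
    for (k in seq_len(nb)) {
      idx <- which(membership[, k])
      if (!length(idx)) next
      ev <- spec$bundles[[k]]$eigenvalues
      tk <- tangents[[k]][idx, , drop = FALSE]
      # perpendicular frame per voxel
      ref <- matrix(rep(c(1, 0, 0), each = length(idx)), ncol = 3)
      swap <- abs(tk[, 1]) > 0.9
      ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
      e2 <- ref - tk * rowSums(ref * tk)
      e2 <- normalize_rows(e2)
      e3 <- cbind(tk[, 2] * e2[, 3] - tk[, 3] * e2[, 2],
                  tk[, 3] * e2[, 1] - tk[, 1] * e2[, 3],
                  tk[, 1] * e2[, 2] - tk[, 2] * e2[, 1])
      q <- ev[1] * (tk %*% t(g))^2 + ev[2] * (e2 %*% t(g))^2 +
        ev[3] * (e3 %*% t(g))^2
      att <- exp(-sweep(q, 2, b, "*"))
      fk <- spec$bundles[[k]]$volume_fraction * scale[idx]
      signal[idx, ] <- signal[idx, ] + fk * att
    }
    f_free <- pmax(0, 1 - pmin(fsum, 1))
  } else {
    f_free <- rep(1, nvox)
  }
  signal <- spec$s0 * (signal + f_free * iso_att)

  if (is.finite(snr)) {
    sigma <- spec$s0 / snr
    signal <- with_seed(seed, {
      n1 <- matrix(stats::rnorm(length(signal), sd = sigma), nvox, ngrad)
      n2 <- matrix(stats::rnorm(length(signal), sd = sigma), nvox, ngrad)
      sqrt((signal + n1)^2 + n2^2)
    })
  }

  sig4 <- array(signal, dim = c(dims, ngrad))
  dwi <- structure(list(signal = sig4, voxel_size = spec$voxel_size,
                        affine = default_affine(spec$voxel_size),
                        gtab = gtab),
                   class = "dwi_volume")

  dir_arr <- array(NA_real_, dim = c(dims, max(1, nb), 3))
  mem_arr <- array(membership, dim = c(dims, max(1, nb)))
  for (k in seq_len(nb)) {
    for (cc in 1:3) {
      comp <- rep(NA_real_, nvox)
      comp[membership[, k]] <- tangents[[k]][membership[, k], cc]
      dir_arr[, , , k, cc] <- array(comp, dim = dims)
    }
  }
  truth <- list(fiber_dirs = dir_arr,
                bundle_membership = mem_arr,
                tumor = array(tumor_mask, dim = dims),
                n_fibers = array(rowSums(membership[, seq_len(max(1, nb)),
                                                    drop = FALSE]),
                                 dim = dims))
  list(dwi = dwi, truth = truth)
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("dwi_volume: %d x %d x %d voxels, %d volumes, voxel %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$voxel_size), collapse = " x ")))
  invisible(x)
}

#' Acquisition presets
#'
#' `human64`: b = 1000 s/mm^2, 64 directions, 1.8 x 1.8 x 4.0 mm voxels
#' (clinical 3T add-on protocol). `mouse512`: b = 1200 s/mm^2, 512
#' directions, 0.16 mm isotropic (ex vivo 7T). `human27` mirrors the
#' historical-cohort scheme (27 directions + b0, b = 1200 s/mm^2).
#' @param name preset name.
#' @param seed seed for direction placement.
#' @return list with `gtab` and `voxel_size`.
#' @export
acquisition_preset <- function(name = c("human64", "mouse512", "human27"),
                               seed = 7) {
  name <- match.arg(name)
  switch(name,
    human64 = list(gtab = make_gradient_table(64, 1000, 1, seed),
                   voxel_size = c(1.8, 1.8, 4.0)),
    human27 = list(gtab = make_gradient_table(27, 1200, 1, seed),
                   voxel_size = c(0.86, 0.86, 3.5)),
    mouse512 = list(gtab = make_gradient_table(512, 1200, 1, seed),
                    voxel_size = c(0.16, 0.16, 0.16)))
}
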