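#' Streamline tracking parameters
#'
#' Defaults follow the clinical post-processing protocol: step size 0.3 mm,
#' angular threshold 45 degrees (a turn sharper than this terminates the
#' track), and a 0-300 mm emitted length window. `qa_termination` stops
#' propagation when the interpolated QA falls below it; `max_steps` guards
#' against cycles and defaults to `ceil(max_length / step) + 1` per
#' direction.
#'
#' @param step_size mm.
#' @param angular_threshold degrees in (0, 90).
#' @param length_range `c(min, max)` mm.
#' @param qa_termination QA floor in `[0, 1]`.
#' @param max_steps integer or NULL for the default guard.
#' @export
tracking_params <- function(step_size = 0.3, angular_threshold = 45,
                            length_range = c(0, 300), qa_termination = 0.08,
                            max_steps = NULL) {
  stopifnot(step_size > 0, angular_threshold > 0, angular_threshold < 90,
            length(length_range) == 2, length_range[1] >= 0,
            length_range[1] < length_range[2], qa_termination >= 0)
  if (is.null(max_steps))
    max_steps <- as.integer(ceiling(length_range[2] / step_size) + 1)
  structure(list(step_size = step_size,
                 angular_threshold = angular_threshold,
                 length_range = length_range,
                 qa_termination = qa_termination,
                 max_steps = as.integer(max_steps)),
            class = "tracking_params")
}

#' Seed points for tractography
#'
#' Places `seeds_per_voxel` uniformly jittered points inside each masked
#' voxel's world-coordinate box.
#' @param mask logical 3D array.
#' @param voxel_size mm.
#' @param seeds_per_voxel positive integer.
#' @param seed RNG seed.
#' @return matrix (n x 3) of mm coordinates.
#' @export
seed_points <- function(mask, voxel_size, seeds_per_voxel = 1, seed = 0) {
  stopifnot(seeds_per_voxel >= 1)
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stopf("empty seed mask")
  centers <- sweep(idx - 1, 2, voxel_size, "*")
  centers <- centers[rep(seq_len(nrow(centers)), each = seeds_per_voxel), ,
                     drop = FALSE]
  with_seed(seed, {
    jit <- matrix(stats::runif(length(centers), -0.5, 0.5),
                  nrow(centers), 3)
    centers + sweep(jit, 2, voxel_size, "*")
  })
}

# Tri-linear directional interpolation of a multi-peak field.
# At continuous voxel coordinate v (0-based), each of the 8 neighbor voxels
# contributes its peak best aligned with the incoming direction (sign-flipped
# to agree); contributions are tri-linearly weighted, averaged and
# renormalized. With no incoming direction the strongest-QA peaks are used,
# sign-aligned to the highest-weighted contributor. Returns NULL when no
# neighbor has peaks.
interp_direction <- function(pf, v, incoming = NULL) {
  dims <- pf$dims
  i0 <- floor(v)
  fr <- v - i0
  dsum <- c(0, 0, 0)
  qsum <- 0
  wbest <- -1
  ref <- NULL
  contrib <- NULL
  for (corner in 0:7) {
    di <- c(corner %% 2, (corner %/% 2) %% 2, corner %/% 4)
    ijk <- i0 + di + 1                      # 1-based indices
    if (any(ijk < 1) || any(ijk > dims)) next
    w <- prod(ifelse(di == 1, fr, 1 - fr))
    if (w <= 0) next
    np <- pf$n_peaks[ijk[1], ijk[2], ijk[3]]
    if (np == 0) next
    pd <- matrix(pf$dirs[ijk[1], ijk[2], ijk[3], seq_len(np), ], np, 3)
    pq <- pf$qa[ijk[1], ijk[2], ijk[3], seq_len(np)]
    if (is.null(incoming)) {
      m <- 1L                               # peaks stored QA-descending
      p <- pd[m, ]
      if (w * pq[m] > wbest) { wbest <- w * pq[m]; ref <- p }
    } else {
      dots <- pd %*% incoming
      m <- which.max(abs(dots))
      p <- pd[m, ] * sign(dots[m] + (dots[m] == 0))
    }
    contrib <- rbind(contrib, c(w, p, pq[m]))
  }
  if (is.null(contrib)) return(NULL)
  if (is.null(incoming)) {
    # sign-align all contributions to the dominant one
    sgn <- sign(contrib[, 2:4, drop = FALSE] %*% ref)
    sgn[sgn == 0] <- 1
    contrib[, 2:4] <- contrib[, 2:4, drop = FALSE] * as.vector(sgn)
  }
  w <- contrib[, 1]
  dsum <- colSums(contrib[, 2:4, drop = FALSE] * w)
  qsum <- sum(contrib[, 5] * w)             # empty neighbors pull QA to 0
  n <- vnorm(dsum)
  if (n == 0) return(NULL)
  list(dir = dsum / n, qa = qsum)
}

# one half-track from seed (mm), first step along sense * d0
propagate_half <- function(pf, seed_mm, d0, params) {
  inv_vs <- 1 / pf$voxel_size
  dims <- pf$dims
  pts <- matrix(0, params$max_steps + 1, 3)
  pts[1, ] <- seed_mm
  pos <- seed_mm
  dir_prev <- d0
  n <- 1L
  for (s in seq_len(params$max_steps)) {
    cand <- pos + params$step_size * dir_prev
    v <- cand * inv_vs
    if (any(v < -0.5) || any(v > dims - 0.5)) break   # left the volume
    it <- interp_direction(pf, v, dir_prev)
    if (is.null(it) || it$qa < params$qa_termination) break
    turn <- sum(it$dir * dir_prev)
    if (turn < cos(params$angular_threshold * pi / 180)) break
    n <- n + 1L
    pts[n, ] <- cand
    pos <- cand
    dir_prev <- it$dir
  }
  pts[seq_len(n), , drop = FALSE]
}

#' Track a single streamline
#'
#' Deterministic bidirectional Euler integration over the tri-linearly
#' interpolated peak field. At the seed, the strongest-QA interpolated peak
#' fixes the initial axis and both senses are propagated; each subsequent
#' step follows the interpolated peak direction most aligned with the
#' incoming direction. Propagation terminates on a turn sharper than the
#' angular threshold, interpolated QA below `qa_termination`, leaving the
#' volume, or `max_steps`. The streamline is discarded when its final
#' length falls outside `length_range`.
#'
#' @param pf a `peak_field`.
#' @param seed_mm length-3 world coordinate (mm).
#' @param params a [tracking_params()].
#' @return matrix of mm points (consecutive spacing = step size) or `NULL`.
#' @export
track_streamline <- function(pf, seed_mm, params = tracking_params()) {
  stopifnot(inherits(pf, "peak_field"))
  v <- seed_mm / pf$voxel_size
  if (any(v < -0.5) || any(v > pf$dims - 0.5)) stopf("seed outside volume")
  it <- interp_direction(pf, v, NULL)
  if (is.null(it) || it$qa < params$qa_termination) return(NULL)
  h1 <- propagate_half(pf, seed_mm, it$dir, params)
  h2 <- propagate_half(pf, seed_mm, -it$dir, params)
  pts <- rbind(h2[rev(seq_len(nrow(h2)))[-nrow(h2)], , drop = FALSE], h1)
  if (nrow(pts) < 2) return(NULL)
  len <- streamline_length(pts)
  if (len < params$length_range[1] || len > params$length_range[2])
    return(NULL)
  pts
}

#' Track all seeds into a tractogram
#'
#' @param pf a `peak_field`.
#' @param seeds matrix (n x 3) of mm seed points.
#' @param params a [tracking_params()].
#' @return `tractogram`: list with `streamlines` (list of point matrices),
#'   `affine`, `voxel_size`, optional `labels`.
#' @export
track_all <- function(pf, seeds, params = tracking_params()) {
  sl <- vector("list", nrow(seeds) %||% 0)
  if (!is.null(seeds) && nrow(seeds)) {
    for (i in seq_len(nrow(seeds)))
      sl[[i]] <- track_streamline(pf, seeds[i, ], params)
  }
  sl <- sl[!vapply(sl, is.null, logical(1))]
  tractogram(sl, pf$voxel_size, pf$affine)
}

#' @rdname track_all
#' @param streamlines list of point matrices (mm).
#' @param voxel_size,affine spatial reference.
#' @param labels optional per-streamline labels.
#' @export
tractogram <- function(streamlines, voxel_size, affine = NULL,
                       labels = NULL) {
  if (!is.null(labels) && length(labels) != length(streamlines))
    stopf("labels must cover all streamlines")
  structure(list(streamlines = streamlines, voxel_size = voxel_size,
                 affine = affine %||% default_affine(voxel_size),
                 labels = labels),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  n <- length(x$streamlines)
  if (n) {
    lens <- vapply(x$streamlines, streamline_length, numeric(1))
    cat(sprintf("tractogram: %d streamlines, length %.1f-%.1f mm (mean %.1f)\n",
                n, min(lens), max(lens), mean(lens)))
  } else cat("tractogram: empty\n")
  invisible(x)
}

#' Streamline length
#'
#' Sum of consecutive point distances, mm.
#' @param s matrix (n x 3) of points.
#' @export
streamline_length <- function(s) {
  if (!is.matrix(s) || nrow(s) < 2)
    stopf("streamline needs >= 2 points")
  sum(sqrt(rowSums((s[-1, , drop = FALSE] -
                      s[-nrow(s), , drop = FALSE])^2)))
}
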