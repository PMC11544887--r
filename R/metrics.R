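#' Resample a streamline to a fixed number of points
#'
#' Linear interpolation at equal arc-length spacing; used before streamline
#' distance computation.
#' @param s point matrix (mm).
#' @param n_points number of output points.
#' @export
resample_streamline <- function(s, n_points = 12) {
  stopifnot(nrow(s) >= 2, n_points >= 2)
  seg <- sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  tot <- cum[length(cum)]
  if (tot == 0) return(matrix(rep(s[1, ], n_points), n_points, 3,
                              byrow = TRUE))
  tgt <- seq(0, tot, length.out = n_points)
  out <- matrix(0, n_points, 3)
  for (cc in 1:3) out[, cc] <- stats::approx(cum, s[, cc], xout = tgt,
                                             ties = "ordered")$y
  out
}

#' Minimum average direct-flip (MDF) distance between two streamlines
#'
#' Both inputs must share the same point count (use
#' [resample_streamline()]). The distance is the smaller of the mean
#' pointwise distance taken directly and with one streamline reversed;
#' symmetric, zero on identical curves.
#' @param a,b point matrices (same n x 3).
#' @export
mdf_distance <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  direct <- mean(sqrt(rowSums((a - b)^2)))
  flipped <- mean(sqrt(rowSums((a - b[rev(seq_len(nrow(b))), ])^2)))
  min(direct, flipped)
}

# symmetric mean-closest-point distance between two polylines (smaller of
# the two directed means); insensitive to truncation, unlike MDF
mcp_distance <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  min(mean(sqrt(apply(d2, 1, min))), mean(sqrt(apply(d2, 2, min))))
}

#' Greedy MDF streamline clustering (bundle counting)
#'
#' QuickBundles-style single pass: each streamline (resampled to
#' `n_points`) joins the nearest cluster centroid within
#' `distance_threshold`, flip-aligned before updating the running centroid,
#' or founds a new cluster. Because the direct-flip distance penalises
#' length differences, clusters of truncated streamlines lying inside
#' another cluster's corridor are then merged by a mean-closest-point pass
#' (same threshold), so early-terminating tracks do not inflate the bundle
#' count. Clusters with fewer than `min_members` streamlines are discarded.
#' Deterministic given input order.
#'
#' @param tracts a `tractogram` (or list of point matrices).
#' @param distance_threshold mm MDF threshold for joining a cluster.
#' @param min_members minimum cluster size counted as a bundle.
#' @param n_points resampling point count.
#' @param merge_overlapping logical; run the mean-closest-point merge pass.
#' @return integer bundle count, with attribute `labels` (cluster index per
#'   streamline; NA for streamlines in discarded clusters).
#' @export
count_bundles <- function(tracts, distance_threshold = 8, min_members = 2,
                          n_points = 12, merge_overlapping = TRUE) {
  sl <- if (inherits(tracts, "tractogram")) tracts$streamlines else tracts
  if (!length(sl)) return(structure(0L, labels = integer(0)))
  rs <- lapply(sl, resample_streamline, n_points = n_points)
  centroids <- list()
  sizes <- integer(0)
  labels <- integer(length(rs))
  for (i in seq_along(rs)) {
    s <- rs[[i]]
    best <- 0L; bestd <- Inf
    for (k in seq_along(centroids)) {
      d <- mdf_distance(s, centroids[[k]])
      if (d < bestd) { bestd <- d; best <- k }
    }
    if (best > 0L && bestd <= distance_threshold) {
      cen <- centroids[[best]]
      flip <- mean(sqrt(rowSums((s - cen)^2))) >
        mean(sqrt(rowSums((s[rev(seq_len(nrow(s))), ] - cen)^2)))
      if (flip) s <- s[rev(seq_len(nrow(s))), ]
      centroids[[best]] <- (cen * sizes[best] + s) / (sizes[best] + 1)
      sizes[best] <- sizes[best] + 1L
      labels[i] <- best
    } else {
      centroids[[length(centroids) + 1L]] <- s
      sizes <- c(sizes, 1L)
      labels[i] <- length(centroids)
    }
  }
  if (merge_overlapping && length(centroids) > 1) {
    parent <- seq_along(centroids)
    repeat {
      merged <- FALSE
      ord <- order(-sizes)
      for (ai in seq_along(ord)) {
        a <- ord[ai]
        if (sizes[a] == 0) next
        for (b in ord[-seq_len(ai)]) {
          if (sizes[b] == 0 || a == b) next
          if (mcp_distance(centroids[[a]], centroids[[b]]) <=
              distance_threshold) {
            # absorb the smaller cluster; the larger centroid stands
            labels[labels == b] <- a
            sizes[a] <- sizes[a] + sizes[b]
            sizes[b] <- 0L
            merged <- TRUE
          }
        }
      }
      if (!merged) break
    }
  }
  keep <- which(sizes >= min_members)
  relabel <- rep(NA_integer_, length(sizes))
  relabel[keep] <- seq_along(keep)
  structure(length(keep), labels = relabel[labels])
}

#' Tract-derived prognostic metrics
#'
#' Implements the cohort metrics: mean tract length over all
#' tumor-intersecting tracts; mean projecting tract length over projecting
#' tracts only (full streamline lengths, flagged `NA` when no projecting
#' tract exists); the projecting bundle count; per-class tract counts;
#' tumor volume (cm^3); and intratumoral means of QA, FA, MD and AD over
#' ROI voxels.
#'
#' @param tracts tumor-intersecting `tractogram`.
#' @param classes factor from [classify_tracts()].
#' @param roi a `roi_mask`.
#' @param maps optional `scalar_maps` for FA/MD/AD summaries.
#' @param peaks optional `peak_field` for the QA summary.
#' @param distance_threshold,min_members bundle-count parameters.
#' @return `tract_metrics`: named list.
#' @export
tract_metrics <- function(tracts, classes, roi, maps = NULL, peaks = NULL,
                          distance_threshold = 8, min_members = 2) {
  stopifnot(inherits(tracts, "tractogram"),
            length(classes) == length(tracts$streamlines))
  if (!length(tracts$streamlines))
    stopf("need >= 1 tumor-intersecting tract")
  lens <- vapply(tracts$streamlines, streamline_length, numeric(1))
  proj <- classes == "projecting"
  proj_tracts <- tractogram(tracts$streamlines[proj], tracts$voxel_size,
                            tracts$affine)
  n_bundles <- if (any(proj))
    as.integer(count_bundles(proj_tracts, distance_threshold, min_members))
  else 0L
  roi_idx <- which(roi$mask)
  mean_in_roi <- function(arr) if (is.null(arr)) NA_real_ else
    mean(arr[roi_idx], na.rm = TRUE)
  out <- list(
    mean_tract_length = mean(lens),
    mean_projecting_tract_length = if (any(proj)) mean(lens[proj])
      else NA_real_,
    n_projecting_bundles = n_bundles,
    n_tracts_by_class = table(classes),
    tumor_volume_cm3 = roi_volume_cm3(roi),
    intratumoral_qa = if (!is.null(peaks)) mean_in_roi(qa_map(peaks))
      else NA_real_,
    intratumoral_fa = mean_in_roi(maps$fa),
    intratumoral_md = mean_in_roi(maps$md),
    intratumoral_ad = mean_in_roi(maps$ad))
  class(out) <- "tract_metrics"
  out
}

#' @export
print.tract_metrics <- function(x, ...) {
  cat(sprintf(
    "tract_metrics: mean TL %.1f mm; mean projecting TL %s mm; %d bundles; tumor %.2f cm^3\n",
    x$mean_tract_length,
    if (is.na(x$mean_projecting_tract_length)) "NA"
    else sprintf("%.1f", x$mean_projecting_tract_length),
    x$n_projecting_bundles, x$tumor_volume_cm3))
  print(x$n_tracts_by_class)
  invisible(x)
}
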