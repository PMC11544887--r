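#' End-to-end phantom pipeline: simulate, reconstruct, track, classify, count
#'
#' Builds a phantom with `k` straight fiber bundles piercing a spherical
#' "tumor" and extending well beyond it (arranged on a circle around the
#' tumor center so the tubes do not overlap), simulates the DWI acquisition,
#' reconstructs the orientation field, tracks streamlines seeded over the
#' whole volume, selects tumor-intersecting tracts, classifies them as
#' core/shell/projecting and counts projecting bundles.
#'
#' @param k_bundles number of bundles (1-5).
#' @param preset acquisition preset name (see [acquisition_preset()]).
#' @param snr simulation SNR (Inf for noise-free).
#' @param seed RNG seed for direction placement, noise and seeding.
#' @param tumor_radius tumor sphere radius, mm.
#' @param bundle_extent distance the bundles extend beyond the tumor
#'   surface on each side, mm.
#' @param seeds_per_voxel seed density.
#' @param shell_margin classification margin, mm.
#' @param tracking tracking parameter list; its `qa_termination` is
#'   replaced by the adaptive threshold unless `qa_threshold` is given.
#' @param qa_threshold QA floor/termination threshold; `NULL` (default)
#'   selects it adaptively as the Otsu threshold of the nonzero QA map,
#'   separating the noise floor from fiber peaks.
#' @return list with `metrics` (a `tract_metrics`), `classes`,
#'   `tumor_tracts`, `n_projecting_bundles`, `frac_projecting`, `truth`,
#'   `roi`, and the intermediate `peaks`.
#' @export
run_phantom_pipeline <- function(k_bundles, preset = "human64", snr = 30,
                                 seed = 1, tumor_radius = 14,
                                 bundle_extent = 25, seeds_per_voxel = 1,
                                 shell_margin = 3,
                                 tracking = tracking_params(),
                                 qa_threshold = NULL) {
  stopifnot(k_bundles >= 1, k_bundles <= 5)
  acq <- acquisition_preset(preset, seed = seed)
  vs <- acq$voxel_size

  # world extents: bundles run along x through the tumor center
  half_x <- tumor_radius + bundle_extent + 6
  half_yz <- tumor_radius + 8
  dims <- as.integer(ceiling(c(2 * half_x, 2 * half_yz, 2 * half_yz) / vs))
  center <- (dims - 1) * vs / 2

  offs <- bundle_offsets(k_bundles, radius = if (k_bundles == 1) 0 else 10)
  bundles <- lapply(seq_len(k_bundles), function(k) {
    o <- offs[k, ]
    bundle_straight(
      from = center + c(-(tumor_radius + bundle_extent), o[1], o[2]),
      to = center + c(tumor_radius + bundle_extent, o[1], o[2]),
      radius = 3)
  })
  spec <- phantom_spec(dims, vs, bundles,
                       tumor = list(center = center,
                                    semi_axes = rep(tumor_radius, 3),
                                    isotropic_diffusivity = 1.2e-3))
  sim <- simulate_dwi(spec, acq$gtab, snr = snr, seed = seed)

  odf <- reconstruct_sdf(sim$dwi)
  peaks <- extract_peaks(odf)
  if (is.null(qa_threshold)) {
    qv <- qa_map(peaks)
    qa_threshold <- otsu_threshold(qv[qv > 0])
  }
  peaks <- apply_qa_floor(peaks, qa_threshold)
  tracking$qa_termination <- qa_threshold
  seeds <- seed_points(array(TRUE, dims), vs, seeds_per_voxel, seed = seed)
  tracts <- track_all(peaks, seeds, tracking)

  roi <- roi_mask(sim$truth$tumor, vs)
  tumor_tracts <- select_tumor_tracts(tracts, roi)
  classes <- classify_tracts(tumor_tracts, roi, shell_margin)

  maps <- tensor_metrics(fit_tensor(sim$dwi))
  # bundle support rule: a reported bundle must hold >= 1% of projecting
  # tracts (>= 2), making the count robust to isolated truncated tracks
  min_members <- max(2, ceiling(0.01 * sum(classes == "projecting")))
  metrics <- tract_metrics(tumor_tracts, classes, roi, maps = maps,
                           peaks = peaks, min_members = min_members)
  list(metrics = metrics, classes = classes, tumor_tracts = tumor_tracts,
       n_projecting_bundles = metrics$n_projecting_bundles,
       frac_projecting = mean(classes == "projecting"),
       truth = sim$truth, roi = roi, peaks = peaks, dwi = sim$dwi)
}

# y/z-plane offsets for k parallel bundles: one central, otherwise equally
# spaced on a circle (pairwise separation 2 r sin(pi/k))
bundle_offsets <- function(k, radius = 10) {
  if (k == 1) return(matrix(0, 1, 2))
  ang <- 2 * pi * (seq_len(k) - 1) / k
  cbind(radius * cos(ang), radius * sin(ang))
}
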