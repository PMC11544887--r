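#' Log-linear diffusion tensor fit
#'
#' Fits `ln S = ln S0 - b g' D g` per voxel by unweighted least squares.
#' Measurements with non-positive signal are excluded voxel-wise; a voxel
#' with fewer than 7 usable measurements (6 tensor elements + ln S0) is
#' flagged invalid rather than silently zeroed.
#'
#' @param dwi a `dwi_volume`.
#' @param mask optional logical 3D array; default all voxels.
#' @return `tensor_volume`: list with `tensors` (nx,ny,nz,6; order
#'   xx,yy,zz,xy,xz,yz in mm^2/s), `s0`, logical `valid`, `voxel_size`,
#'   `affine`.
#' @export
fit_tensor <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  gtab <- dwi$gtab
  if (sum(!gtab$b0) < 6 || sum(gtab$b0) < 1)
    stopf("need >= 6 weighted directions and >= 1 b0 volume")
  dims <- dim(dwi$signal)[1:3]
  nvox <- prod(dims)
  ngrad <- length(gtab$bvals)
  if (is.null(mask)) mask <- array(TRUE, dims)
  sig <- matrix(dwi$signal, nvox, ngrad)

  g <- gtab$bvecs; b <- gtab$bvals
  x <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2],
             -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])

  tensors <- matrix(NA_real_, nvox, 6)
  s0 <- rep(NA_real_, nvox)
  valid <- rep(FALSE, nvox)
  midx <- which(as.vector(mask))

  ok_all <- rowSums(sig[midx, , drop = FALSE] <= 0) == 0
  # fast path: all measurements usable -> one shared pseudo-inverse
  if (any(ok_all)) {
    pinv <- solve(crossprod(x), t(x))
    idx <- midx[ok_all]
    theta <- t(pinv %*% t(log(sig[idx, , drop = FALSE])))
    s0[idx] <- exp(theta[, 1])
    tensors[idx, ] <- theta[, 2:7]
    valid[idx] <- TRUE
  }
  for (v in midx[!ok_all]) {
    use <- sig[v, ] > 0
    if (sum(use) < 7) next
    xt <- x[use, , drop = FALSE]
    fit <- tryCatch(stats::lm.fit(xt, log(sig[v, use])), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) next
    s0[v] <- exp(fit$coefficients[1])
    tensors[v, ] <- fit$coefficients[2:7]
    valid[v] <- TRUE
  }
  structure(list(tensors = array(tensors, c(dims, 6)),
                 s0 = array(s0, dims),
                 valid = array(valid, dims),
                 voxel_size = dwi$voxel_size, affine = dwi$affine),
            class = "tensor_volume")
}

#' Tensor-derived scalar maps (FA, MD, AD)
#'
#' Eigen-decomposes each valid tensor and computes mean diffusivity
#' `MD = (l1+l2+l3)/3`, axial diffusivity `AD = l1`, and fractional
#' anisotropy
#' \deqn{FA = \sqrt{3/2}\,\sqrt{\sum_i (\lambda_i - MD)^2} / \sqrt{\sum_i \lambda_i^2}}
#' with FA defined as 0 when all eigenvalues vanish. Negative eigenvalues
#' (possible for noisy log-linear fits) are floored at zero before the
#' formulas — the usual positive-semidefinite projection, which also keeps
#' FA within [0, 1] without clamping the formula itself. Invalid voxels
#' are NaN.
#'
#' @param tv a `tensor_volume`.
#' @return `scalar_maps`: list of 3D arrays `fa`, `md`, `ad`, `evals`
#'   (nx,ny,nz,3 descending), plus grid info.
#' @export
tensor_metrics <- function(tv) {
  stopifnot(inherits(tv, "tensor_volume"))
  dims <- dim(tv$valid)
  nvox <- prod(dims)
  tm <- matrix(tv$tensors, nvox, 6)
  fa <- md <- ad <- rep(NaN, nvox)
  evals <- matrix(NaN, nvox, 3)
  for (v in which(as.vector(tv$valid))) {
    d <- matrix(c(tm[v, 1], tm[v, 4], tm[v, 5],
                  tm[v, 4], tm[v, 2], tm[v, 6],
                  tm[v, 5], tm[v, 6], tm[v, 3]), 3, 3)
    ev <- sort(pmax(0, eigen(d, symmetric = TRUE,
                             only.values = TRUE)$values),
               decreasing = TRUE)
    evals[v, ] <- ev
    md[v] <- mean(ev)
    ad[v] <- ev[1]
    ss <- sum(ev^2)
    fa[v] <- if (ss == 0) 0 else
      sqrt(1.5) * sqrt(sum((ev - md[v])^2)) / sqrt(ss)
  }
  structure(list(fa = array(fa, dims), md = array(md, dims),
                 ad = array(ad, dims), evals = array(evals, c(dims, 3)),
                 voxel_size = tv$voxel_size, affine = tv$affine),
            class = "scalar_maps")
}
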