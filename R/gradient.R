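#' Diffusion gradient tables
#'
#' A gradient table pairs unit gradient directions with diffusion weightings
#' (b-values, s/mm^2) and flags the unweighted (b0) volumes. Directions for
#' the weighted volumes are spread over the sphere by electrostatic repulsion
#' with antipodal symmetry, emulating the near-uniform vendor schemes used on
#' clinical and preclinical scanners.
#'
#' @param n_directions number of diffusion-weighted directions (>= 6; a
#'   tensor fit is underdetermined below six).
#' @param bvalue diffusion weighting for the weighted volumes, s/mm^2.
#' @param n_b0 number of unweighted (b = 0) volumes, placed first.
#' @param seed integer seed for the repulsion initialisation.
#' @param n_iter repulsion iterations (fixed-count scheme).
#' @return object of class `gradient_table`: list with `bvals` (length
#'   n_b0 + n_directions), `bvecs` (matrix, rows unit vectors; zero rows for
#'   b0 entries) and `b0` (logical).
#' @examples
#' gtab <- make_gradient_table(64, 1000, n_b0 = 1, seed = 7)
#' range(sqrt(rowSums(gtab$bvecs[!gtab$b0, ]^2)))
#' @export
make_gradient_table <- function(n_directions, bvalue, n_b0 = 1, seed = 0,
                                n_iter = 1000) {
  if (n_directions < 6)
    stopf("n_directions must be >= 6 (tensor fit underdetermined): got %d",
          n_directions)
  stopifnot(bvalue >= 0, n_b0 >= 0)
  key <- paste(n_directions, seed, n_iter, sep = "|")
  dirs <- .gradient_cache[[key]]
  if (is.null(dirs)) {
    dirs <- repulsion_directions(n_directions, seed, n_iter)
    .gradient_cache[[key]] <- dirs
  }
  bvecs <- rbind(matrix(0, n_b0, 3), dirs)
  gtab <- list(
    bvals = c(rep(0, n_b0), rep(bvalue, n_directions)),
    bvecs = bvecs,
    b0 = c(rep(TRUE, n_b0), rep(FALSE, n_directions)))
  class(gtab) <- "gradient_table"
  validate_gradient_table(gtab)
  gtab
}

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("gradient_table: %d volumes (%d b0), b = %s s/mm^2\n",
              length(x$bvals), sum(x$b0),
              paste(unique(x$bvals[!x$b0]), collapse = ", ")))
  invisible(x)
}

validate_gradient_table <- function(gtab) {
  stopifnot(length(gtab$bvals) == nrow(gtab$bvecs),
            length(gtab$b0) == length(gtab$bvals))
  if (!any(gtab$b0)) stopf("gradient table must contain at least one b0 entry")
  if (any(gtab$bvals < 0)) stopf("b-values must be non-negative")
  nrm <- sqrt(rowSums(gtab$bvecs[!gtab$b0, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-9))
    stopf("weighted gradient directions must be unit length")
  invisible(gtab)
}

# Electrostatic (Thomson-like) repulsion on the sphere with antipodal
# symmetry: each point repels every other point and every antipode with an
# inverse-square force; a fixed number of decaying tangent-projected steps.
repulsion_directions <- function(n, seed, n_iter = 1000) {
  with_seed(seed, {
    p <- normalize_rows(matrix(stats::rnorm(n * 3), n, 3))
    step0 <- 0.05
    decay <- exp(log(0.01) / max(1, n_iter))   # step shrinks 100x over run
    eps <- 1e-12
    for (it in seq_len(n_iter)) {
      fx <- numeric(n); fy <- numeric(n); fz <- numeric(n)
      dx <- outer(p[, 1], p[, 1], "-")
      dy <- outer(p[, 2], p[, 2], "-")
      dz <- outer(p[, 3], p[, 3], "-")
      inv <- (dx * dx + dy * dy + dz * dz + eps)^(-1.5)
      diag(inv) <- 0
      fx <- rowSums(dx * inv); fy <- rowSums(dy * inv); fz <- rowSums(dz * inv)
      sx <- outer(p[, 1], p[, 1], "+")
      sy <- outer(p[, 2], p[, 2], "+")
      sz <- outer(p[, 3], p[, 3], "+")
      invp <- (sx * sx + sy * sy + sz * sz + eps)^(-1.5)
      fx <- fx + rowSums(sx * invp)
      fy <- fy + rowSums(sy * invp)
      fz <- fz + rowSums(sz * invp)
      f <- cbind(fx, fy, fz)
      # tangent projection, then unit-normalised displacement
      f <- f - p * rowSums(f * p)
      fn <- sqrt(rowSums(f^2))
      fn[fn == 0] <- 1
      p <- normalize_rows(p + (step0 * decay^it) * (f / fn))
    }
    dimnames(p) <- NULL
    p
  })
}

.gradient_cache <- new.env(parent = emptyenv())

#' Minimum pairwise (axial) angle of a direction set
#'
#' Angular spread diagnostic: the smallest sign-free angle between any two
#' directions, in degrees. Higher is better for an antipodally symmetric
#' sampling scheme.
#' @param dirs matrix of unit row vectors.
#' @export
min_pairwise_angle <- function(dirs) {
  g <- abs(tcrossprod(dirs))
  diag(g) <- 0
  acos(min(1, max(g[upper.tri(g) | lower.tri(g)]))) * 180 / pi
}

#' Write / read FSL-style bvals and bvecs files
#'
#' `bvals` is a single row of b-values; `bvecs` has three rows (x, y, z
#' components), one column per volume.
#' @param gtab a `gradient_table`.
#' @param prefix path prefix; files `<prefix>.bval` and `<prefix>.bvec`.
#' @return `write_bvalbvec` the prefix invisibly; `read_bvalbvec` a
#'   `gradient_table`.
#' @export
write_bvalbvec <- function(gtab, prefix) {
  writeLines(paste(format(gtab$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "),
             paste0(prefix, ".bval"))
  vec <- t(gtab$bvecs)
  lines <- apply(vec, 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " "))
  writeLines(lines, paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' @rdname write_bvalbvec
#' @param b0_max b-values at or below this are flagged b0.
#' @export
read_bvalbvec <- function(prefix, b0_max = 0) {
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  vec <- as.matrix(utils::read.table(paste0(prefix, ".bvec")))
  stopifnot(nrow(vec) == 3)
  gtab <- list(bvals = bvals, bvecs = t(unname(vec)), b0 = bvals <= b0_max)
  class(gtab) <- "gradient_table"
  validate_gradient_table(gtab)
  gtab
}
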