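# Shared fixtures, all generated in code.

# single-voxel-style phantom: one straight bundle filling the grid
single_fiber_phantom <- function(dims = c(3, 3, 3), voxel_size = c(1, 1, 1),
                                 axis = c(1, 0, 0), f = 1,
                                 eigenvalues = c(1.7, 0.3, 0.3) * 1e-3) {
  fov <- dims * voxel_size
  center <- (dims - 1) * voxel_size / 2
  span <- 3 * max(fov)
  phantom_spec(dims, voxel_size,
               bundles = list(bundle_straight(center - span * axis,
                                              center + span * axis,
                                              radius = 2 * max(fov),
                                              eigenvalues = eigenvalues,
                                              volume_fraction = f)))
}

# uniform single-peak field pointing along `axis`
uniform_peak_field <- function(dims = c(20, 20, 20), voxel_size = c(1, 1, 1),
                               axis = c(1, 0, 0), qa = 1) {
  m <- 1
  dirs <- array(NA_real_, c(dims, m, 3))
  for (cc in 1:3) dirs[, , , 1, cc] <- axis[cc]
  qa_arr <- array(qa, c(dims, m))
  peak_field(dirs, qa_arr, voxel_size)
}

# expected FA by direct evaluation of the eigenvalue formula
fa_closed_form <- function(ev) {
  md <- mean(ev)
  ss <- sum(ev^2)
  if (ss == 0) return(0)
  sqrt(1.5) * sqrt(sum((ev - md)^2)) / sqrt(ss)
}

# analytic mean of a Rician(nu, sigma) variable
rician_mean <- function(nu, sigma) {
  x <- nu^2 / (2 * sigma^2)
  sigma * sqrt(pi / 2) * exp(-x / 2) *
    ((1 + x) * besselI(x / 2, 0) + x * besselI(x / 2, 1))
}

# independently coded two-group log-rank via hypergeometric increments
logrank_oracle_2group <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1], t2[e2])))
  o_minus_e <- 0
  v <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d1 <- sum(t1 == tt & e1); d2 <- sum(t2 == tt & e2); d <- d1 + d2
    if (n < 2 || d == 0) next
    e_d1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e_d1)
    v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi2 <- o_minus_e^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}
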