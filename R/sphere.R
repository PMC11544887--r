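#' Subdivided icosahedral sphere tessellation
#'
#' Builds an antipodally symmetric tessellation of the unit sphere by
#' recursive midpoint subdivision of the icosahedron, used as the sampling
#' grid for the per-voxel orientation distribution function. The vertex set
#' is closed under negation, so any even function of direction is exactly
#' antipodally symmetric on it.
#'
#' @param order tessellation order; `order - 1` midpoint subdivisions are
#'   applied, giving `10 * 4^(order-1) + 2` vertices (order 4: 642).
#' @return list with `vertices` (n x 3 unit rows), `faces` (m x 3 indices)
#'   and `adjacency` (list of neighbor index vectors per vertex).
#' @export
icosphere <- function(order = 4) {
  stopifnot(order >= 1)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- normalize_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(6, 5, 10), c(12, 3, 5), c(11, 7, 3), c(8, 9, 7), c(2, 10, 9))

  for (lev in seq_len(order - 1)) {
    cache <- new.env(hash = TRUE, parent = emptyenv())
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / vnorm(m)
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      cache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(t - 1) * 4 + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- nf
  }

  edges <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  adj <- vector("list", nrow(v))
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  list(vertices = v, faces = f, adjacency = adj)
}
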