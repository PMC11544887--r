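#' @keywords internal
"_PACKAGE"

# Run `expr` with a private RNG stream; the caller's .Random.seed is restored.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

vnorm <- function(x) sqrt(sum(x^2))

normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

# angle between two unit vectors, degrees
angle_deg <- function(a, b) {
  d <- sum(a * b)
  acos(max(-1, min(1, d))) * 180 / pi
}

# axial (sign-free) angle between unit vectors, degrees
axial_angle_deg <- function(a, b) {
  d <- abs(sum(a * b))
  acos(min(1, d)) * 180 / pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
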