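#' @keywords internal
"_PACKAGE"

#' @useDynLib airwayplug, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

vol_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L)
    stop("expected a 3-D array (z, y, x)")
  as.integer(d)
}

stopifnot_same_shape <- function(a, b, what = "volumes") {
  if (!identical(vol_dims(a), vol_dims(b)))
    stop(sprintf("%s have mismatching shapes", what))
}

# linear (column-major) index for 1-based (z, y, x) coordinates
lin_index <- function(z, y, x, dims) {
  as.integer(z + dims[1L] * ((y - 1L) + dims[2L] * (x - 1L)))
}

lin_to_zyx <- function(i, dims) {
  i0 <- i - 1L
  z <- i0 %% dims[1L]
  r <- i0 %/% dims[1L]
  cbind(z = z + 1L, y = r %% dims[2L] + 1L, x = r %/% dims[2L] + 1L)
}

# integer offsets of a digital ball of the given radius (voxels)
offsets_ball <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero direction vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# deterministic orthonormal basis (u, v) of the plane orthogonal to unit d
plane_basis <- function(d) {
  ref <- diag(3)[, which.min(abs(d))]
  u <- unit3(cross3(ref, d))
  v <- cross3(d, u)
  list(u = u, v = v)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

LOBE_CODES <- c("RUL", "RML", "RLL", "RCL", "LL")
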