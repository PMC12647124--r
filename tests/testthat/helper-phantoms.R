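# Shared fixture builders.  Everything is generated in code at test time;
# sizes are kept small so the whole suite stays well inside its budget.

# brute-force digital disc: integer grid points with centre distance < r
disc_count <- function(r, centre = c(0, 0)) {
  g <- expand.grid(y = floor(centre[1] - r - 1):ceiling(centre[1] + r + 1),
                   x = floor(centre[2] - r - 1):ceiling(centre[2] + r + 1))
  sum((g$y - centre[1])^2 + (g$x - centre[2])^2 < r^2)
}

# independent flood fill (R implementation, no package C++ involved)
flood_count_components <- function(mask) {
  dims <- dim(mask)
  visited <- array(FALSE, dims)
  shifts <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  shifts <- shifts[rowSums(abs(shifts)) > 0, ]
  ncomp <- 0L
  repeat {
    start <- which(mask & !visited)
    if (!length(start)) break
    ncomp <- ncomp + 1L
    frontier <- array(FALSE, dims)
    frontier[start[1]] <- TRUE
    visited <- visited | frontier
    repeat {
      grown <- frontier
      for (k in seq_len(nrow(shifts))) {
        sh <- shift_mask(frontier, shifts$dz[k], shifts$dy[k], shifts$dx[k])
        grown <- grown | sh
      }
      grown <- grown & mask & !visited
      if (!any(grown)) break
      visited <- visited | grown
      frontier <- grown
    }
  }
  ncomp
}

shift_mask <- function(m, dz, dy, dx) {
  d <- dim(m)
  out <- array(FALSE, d)
  zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
  out[zs, ys, xs] <- m[zs - dz, ys - dy, xs - dx]
  out
}

std_cylinder <- function(radius = 10, length = 60, margin = 8) {
  side <- 2 * ceiling(radius) + 2 * margin
  spec <- phantom_cylinder_spec(radius, length, origin = c(margin, side / 2, side / 2))
  build_tree_volume(spec, c(length + 2 * margin, side, side), 1)
}

std_two_branch <- function(radius = 9, length = 80) {
  spec <- phantom_two_branch_spec(radius, length, origin = c(8, 26, 40))
  build_tree_volume(spec, c(96, 80, 80), 1)
}

two_branch_markers <- function() {
  marker_set(data.frame(z = c(12, 3, 93), y = c(26, 3, 77), x = c(40, 3, 77),
                        role = c("lumen", "background", "background")))
}

thick_deposits <- function() {
  deposit_spec(data.frame(branch_id = c(1L, 2L), span_lo = c(0.3, 0.4),
                          span_hi = c(0.7, 0.8), kind = c("crescent", "plug"),
                          fill_fraction = c(0.5, 1), angular_coverage = c(180, NA)))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
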