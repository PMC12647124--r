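# Lumen and mucus segmentation.
#
# The lumen segmenter follows the marked-watershed idea: user-placed seed
# markers constrain a priority flood on the (Gaussian-smoothed) intensity.
# Air-filled lumen is dark, tissue bright, mucus intermediate, so the flood
# from lumen seeds is additionally capped by an intensity barrier estimated
# from the data (background level minus a noise margin); this keeps the
# flood from spilling through the bright airway wall while still claiming
# the intermediate-gray mucus, which belongs to the airway interior.  The
# proprietary branch decomposition of the original tooling is approximated
# functionally: skeletonise the mask, split the skeleton at branch points,
# merge the best-aligned segment pair at each junction (monopodial trunks
# continue straight through), and assign every mask voxel to its nearest
# skeleton branch.

#' Seed markers for lumen segmentation
#'
#' @param markers data.frame with columns `z, y, x` (1-based voxel
#'   coordinates) and `role` (`"lumen"` or `"background"`); a `marker_id`
#'   column is added if absent.
#' @return validated `marker_set` data.table.
#' @export
marker_set <- function(markers) {
  m <- as.data.table(markers)
  need <- c("z", "y", "x", "role")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("marker_set is missing columns: ", paste(miss, collapse = ", "))
  if (!"marker_id" %in% names(m)) m[, marker_id := seq_len(.N)]
  if (!all(m$role %in% c("lumen", "background")))
    stop("marker role must be 'lumen' or 'background'")
  if (!any(m$role == "lumen")) stop("at least one lumen seed marker is required")
  class(m) <- c("marker_set", class(m))
  m
}

# robust noise estimate: sd of (raw - smoothed) residual
estimate_noise_sd <- function(vol, smoothed) {
  r <- as.vector(vol) - as.vector(smoothed)
  1.4826 * mad(r, center = 0)
}

patch_median <- function(vol, m, dims, r = 2L) {
  vals <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    zi <- max(1L, m$z[i] - r):min(dims[1], m$z[i] + r)
    yi <- max(1L, m$y[i] - r):min(dims[2], m$y[i] + r)
    xi <- max(1L, m$x[i] - r):min(dims[3], m$x[i] + r)
    vals[i] <- median(vol[zi, yi, xi])
  }
  median(vals)
}

#' Segment the airway lumen into branch-labelled regions
#'
#' Marker-constrained watershed (priority flood on the smoothed intensity,
#' lumen flooding capped at an automatic intensity barrier) followed by a
#' raw-intensity refinement, hole filling, seed-connected component
#' selection and skeleton-based monopodial branch decomposition.
#'
#' @param volume a [volume3d()] with dark lumen / bright tissue contrast.
#' @param markers a [marker_set()] with at least one lumen seed.
#' @param sigma Gaussian pre-smoothing sd in voxels (default 1).
#' @param barrier intensity above which lumen flooding stops; `"auto"`
#'   estimates background level minus 3 estimated noise sd.
#' @param cut raw-intensity threshold for the refinement step; `"auto"`
#'   estimates background level minus 2.5 noise sd.
#' @param prune_vox terminal skeleton spurs shorter than this are pruned
#'   before branch decomposition.
#' @param max_fraction error if the flooded region exceeds this fraction of
#'   the volume (runaway flood, markers need revision).
#' @return a `lumen_segmentation` list: `labels` (integer array, one label
#'   per branch, 0 background), `mask` (labels > 0), `adjacency`
#'   (data.table `parent, child`), `skeleton` (a `skeleton_graph`), `root`
#'   (root branch label) and `params`.
#' @export
segment_lumen <- function(volume, markers, sigma = 1, barrier = "auto",
                          cut = "auto", prune_vox = 8L, max_fraction = 0.5) {
  markers <- marker_set(markers)
  dims <- vol_dims(volume)
  if (any(markers$z < 1 | markers$z > dims[1] | markers$y < 1 | markers$y > dims[2] |
          markers$x < 1 | markers$x > dims[3]))
    stop("marker coordinates outside the volume")
  raw <- unclass(volume)
  sm <- array(cpp_gauss3(as.double(raw), dims, sigma), dims)
  lum <- markers[markers$role == "lumen"]
  bg <- markers[markers$role == "background"]
  noise_sd <- estimate_noise_sd(raw, sm)
  lum_level <- patch_median(sm, lum, dims)
  bg_level <- if (nrow(bg)) patch_median(sm, bg, dims) else median(sm)
  if (bg_level <= lum_level)
    stop("background level not brighter than lumen level; check markers")
  # barrier: low enough to stop at the bright wall, high enough to claim
  # wall-adjacent mucus whose smoothed value is pulled towards tissue
  if (identical(barrier, "auto")) barrier <- bg_level - 2 * noise_sd
  if (identical(cut, "auto")) cut <- bg_level - 2.5 * noise_sd
  seeds <- lin_index(markers$z, markers$y, markers$x, dims)
  seed_lab <- ifelse(markers$role == "lumen", 1L, 2L)
  barriers <- c(barrier, Inf)[seq_len(max(seed_lab))]
  ws <- cpp_watershed(as.double(sm), dims, seeds, as.integer(seed_lab), as.double(barriers))
  mask <- array(ws == 1L, dims)
  frac <- sum(mask) / prod(dims)
  if (frac > max_fraction)
    stop(sprintf(paste("watershed flooded %.0f%% of the volume; revise markers",
                       "(add background seeds or lower the barrier)"), 100 * frac))
  # refinement on the raw intensity: the smoothed flood overshoots the wall
  # by up to a voxel; raw thresholding restores the voxel-accurate boundary
  mask <- mask & (raw < cut)
  # fill interior holes (background components not connected to the border)
  inv <- cpp_label_components(as.logical(!mask), dims, 6L)
  inv_a <- array(inv, dims)
  border_labs <- unique(c(inv_a[1, , ], inv_a[dims[1], , ], inv_a[, 1, ],
                          inv_a[, dims[2], ], inv_a[, , 1], inv_a[, , dims[3]]))
  border_labs <- setdiff(border_labs, 0L)
  mask <- mask | (inv_a != 0L & !(inv_a %in% border_labs))
  mask <- array(mask, dims)
  # keep only components containing a lumen seed
  cc <- array(cpp_label_components(as.logical(mask), dims, 26L), dims)
  seed_cc <- setdiff(unique(cc[lin_index(lum$z, lum$y, lum$x, dims)]), 0L)
  if (!length(seed_cc)) stop("no lumen seed lies inside the segmented mask; revise markers")
  mask <- array(cc %in% seed_cc, dims)
  if (nrow(bg)) {
    if (any(mask[lin_index(bg$z, bg$y, bg$x, dims)]))
      stop("a background seed ended up inside the airway mask; revise markers")
  }
  skel <- skeletonize(mask, prune_vox = prune_vox)
  lab <- label_mask_by_skeleton(mask, skel)
  root_node <- nearest_node(skel, c(lum$z[1], lum$y[1], lum$x[1]))
  adj <- orient_adjacency(skel, root = skel$nodes$branch_id[root_node])
  structure(list(labels = lab, mask = mask, adjacency = adj, skeleton = skel,
                 root = skel$nodes$branch_id[root_node],
                 params = list(sigma = sigma, barrier = barrier, cut = cut,
                               noise_sd = noise_sd, prune_vox = prune_vox)),
            class = "lumen_segmentation")
}

#' @export
print.lumen_segmentation <- function(x, ...) {
  cat(sprintf("lumen_segmentation: %d voxels, %d branches (root %d)\n",
              sum(x$mask), length(setdiff(unique(as.vector(x$labels)), 0L)), x$root))
  invisible(x)
}

# assign every mask voxel the branch id of the nearest skeleton voxel
label_mask_by_skeleton <- function(mask, skel) {
  dims <- vol_dims(mask)
  src <- lin_index(skel$nodes$z, skel$nodes$y, skel$nodes$x, dims)
  g <- cpp_geodesic(as.logical(mask), dims, src, as.integer(skel$nodes$branch_id),
                    numeric(0))
  array(g$label, dims)
}

nearest_node <- function(skel, zyx) {
  d <- (skel$nodes$z - zyx[1])^2 + (skel$nodes$y - zyx[2])^2 + (skel$nodes$x - zyx[3])^2
  which.min(d)
}

# orient the undirected branch adjacency from the root by BFS
orient_adjacency <- function(skel, root) {
  und <- skel$branch_adjacency
  if (!nrow(und)) return(data.table(parent = integer(), child = integer()))
  out <- list()
  visited <- root
  frontier <- root
  while (length(frontier)) {
    nxt <- integer(0)
    for (b in frontier) {
      nb <- setdiff(c(und$a[und$b == b], und$b[und$a == b]), visited)
      for (cdd in nb) out[[length(out) + 1L]] <- data.table(parent = b, child = cdd)
      nxt <- c(nxt, nb)
      visited <- c(visited, nb)
    }
    frontier <- unique(nxt)
  }
  if (length(out)) rbindlist(out) else data.table(parent = integer(), child = integer())
}

#' Mucus segmentation parameters
#'
#' @param threshold_mode `"otsu"` (data-driven threshold inside the airway
#'   interior, with a bimodality guard that returns an empty mask when no
#'   mucus-level class is present) or `"fixed"` (use the gray band
#'   `(band_lo, band_hi)`).
#' @param band_lo,band_hi fixed gray band (only for `threshold_mode =
#'   "fixed"`).
#' @param opening_radius,closing_radius radii (voxels) of the morphological
#'   opening/closing ball; 0 disables the step.
#' @param min_component_size 26-connected components smaller than this are
#'   removed (>= 1).
#' @export
mucus_params <- function(threshold_mode = c("otsu", "fixed"), band_lo = NA,
                         band_hi = NA, opening_radius = 1, closing_radius = 2,
                         min_component_size = 27L) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed" && (is.na(band_lo) || is.na(band_hi)))
    stop("fixed threshold mode needs band_lo and band_hi")
  if (opening_radius < 0 || closing_radius < 0) stop("morphology radii must be >= 0")
  if (min_component_size < 1L) stop("min_component_size must be >= 1")
  list(threshold_mode = threshold_mode, band_lo = band_lo, band_hi = band_hi,
       opening_radius = opening_radius, closing_radius = closing_radius,
       min_component_size = as.integer(min_component_size))
}

otsu_threshold <- function(x, nbins = 256L) {
  h <- tabulate(pmin(nbins, pmax(1L, as.integer(ceiling((x - min(x)) /
                 (max(x) - min(x) + 1e-12) * nbins)))), nbins)
  edges <- min(x) + (seq_len(nbins) - 0.5) / nbins * (max(x) - min(x))
  w <- cumsum(h); tot <- w[nbins]
  mu <- cumsum(h * edges); mut <- mu[nbins]
  w1 <- w[-nbins]; w2 <- tot - w1
  ok <- w1 > 0 & w2 > 0
  bc <- rep(-Inf, nbins - 1L)
  bc[ok] <- (mut / tot * w1[ok] - mu[-nbins][ok])^2 / (w1[ok] * w2[ok])
  k <- which.max(bc)
  edges[k]
}

#' Segment intraluminal mucus by banded thresholding and morphology
#'
#' Mucus is sought inside the airway interior only: intermediate-gray voxels
#' are selected (Otsu threshold within the region, or a fixed band), then
#' cleaned by morphological opening, closing, and small-component removal.
#'
#' @param volume a [volume3d()].
#' @param region logical array: the airway-interior mask (air + mucus).
#' @param params a [mucus_params()] list.
#' @return logical mucus mask, a subset of `region`.
#' @export
segment_mucus <- function(volume, region, params = mucus_params()) {
  dims <- vol_dims(volume)
  stopifnot_same_shape(volume, region, "volume and region")
  if (!any(region)) stop("empty lumen region; segment the airway first")
  raw <- unclass(volume)
  vals <- raw[region]
  if (params$threshold_mode == "fixed") {
    sel <- region & raw > params$band_lo & raw < params$band_hi
  } else {
    thr <- otsu_threshold(vals)
    lo <- vals[vals <= thr]; hi <- vals[vals > thr]
    if (length(lo) < 2L || length(hi) < 2L) return(array(FALSE, dims))
    # bimodality guard: an Otsu split of unimodal noise yields class means
    # ~1.6 sd apart; genuine air/mucus classes are separated far wider
    sep <- (mean(hi) - mean(lo)) / max(min(sd(lo), sd(hi)), 1e-9)
    if (sep < 4) return(array(FALSE, dims))
    sel <- region & raw > thr
  }
  sel <- array(sel, dims)
  if (params$opening_radius > 0) {
    off <- offsets_ball(params$opening_radius)
    sel <- array(cpp_morph(as.logical(array(cpp_morph(as.logical(sel), dims, off, FALSE),
                                            dims)), dims, off, TRUE), dims)
  }
  if (params$closing_radius > 0) {
    off <- offsets_ball(params$closing_radius)
    sel <- array(cpp_morph(as.logical(array(cpp_morph(as.logical(sel), dims, off, TRUE),
                                            dims)), dims, off, FALSE), dims)
  }
  sel <- sel & region
  if (params$min_component_size > 1L) {
    cc <- cpp_label_components(as.logical(sel), dims, 26L)
    sizes <- tabulate(cc)
    keep <- which(sizes >= params$min_component_size)
    sel <- array(cc %in% keep, dims)
  }
  array(sel, dims)
}

#' Split a mask into the seed-connected part and the excluded rest
#'
#' Components 26-connected to the seed region are retained; everything else
#' goes to the excluded mask (rendered blue in ratio maps and contributing no
#' downstream ratio records).  The two outputs partition the input exactly.
#'
#' @param mask logical array.
#' @param seed_region logical array (or vector of linear indices)
#'   intersecting the mask.
#' @return list `connected`, `excluded` (logical arrays).
#' @export
exclude_unconnected <- function(mask, seed_region) {
  dims <- vol_dims(mask)
  seeds <- if (is.logical(seed_region)) which(seed_region) else as.integer(seed_region)
  seeds <- seeds[mask[seeds]]
  if (!length(seeds)) stop("seed region is disjoint from the mask")
  cc <- cpp_label_components(as.logical(mask), dims, 26L)
  keep <- setdiff(unique(cc[seeds]), 0L)
  connected <- array(cc %in% keep, dims)
  list(connected = connected, excluded = mask & !connected)
}
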