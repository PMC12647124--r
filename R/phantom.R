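#' Airway tree specification
#'
#' Describes a branching airway tree as a table of straight cylindrical
#' branches.  Murine airways branch monopodially: small daughters bud off a
#' continuing trunk, so a "branch" here is one straight segment of lumen.
#'
#' @param branches data.frame with columns `branch_id` (integer, unique),
#'   `parent_id` (integer or `NA` for the single root), `oz`, `oy`, `ox`
#'   (origin, 1-based voxel coordinates), `dz`, `dy`, `dx` (direction,
#'   normalised internally), `length_um`, `radius_um` (> 0), `generation`
#'   (integer 1-11) and `lobe` (one of RUL, RML, RLL, RCL, LL).
#' @return a `tree_spec` object (validated data.table).
#' @export
tree_spec <- function(branches) {
  need <- c("branch_id", "parent_id", "oz", "oy", "ox", "dz", "dy", "dx",
            "length_um", "radius_um", "generation", "lobe")
  b <- as.data.table(branches)
  miss <- setdiff(need, names(b))
  if (length(miss)) stop("tree_spec is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(b) == 0L) {
    out <- b[, need, with = FALSE]
    class(out) <- c("tree_spec", class(out))
    return(out)
  }
  if (anyDuplicated(b$branch_id)) stop("branch_ids must be unique")
  if (sum(is.na(b$parent_id)) != 1L) stop("exactly one root branch (parent_id = NA) required")
  if (any(b$radius_um <= 0)) stop("radii must be positive")
  if (any(b$length_um <= 0)) stop("lengths must be positive")
  if (!all(b$generation %in% 1:11)) stop("generation must be an integer in 1..11")
  if (!all(b$lobe %in% LOBE_CODES))
    stop("lobe must be one of ", paste(LOBE_CODES, collapse = ", "))
  # normalise directions
  n <- sqrt(b$dz^2 + b$dy^2 + b$dx^2)
  if (any(n == 0)) stop("zero direction vector")
  b[, c("dz", "dy", "dx") := .(dz / n, dy / n, dx / n)]
  # parent linkage: child origin on parent axis, generation increments
  for (i in seq_len(nrow(b))) {
    pid <- b$parent_id[i]
    if (is.na(pid)) next
    p <- b[b$branch_id == pid]
    if (nrow(p) != 1L) stop(sprintf("branch %d references unknown parent %d", b$branch_id[i], pid))
    if (b$generation[i] != p$generation + 1L)
      stop(sprintf("branch %d: generation must be parent's + 1", b$branch_id[i]))
    ov <- c(b$oz[i] - p$oz, b$oy[i] - p$oy, b$ox[i] - p$ox)
    d <- c(p$dz, p$dy, p$dx)
    t <- sum(ov * d)
    off <- sqrt(max(0, sum(ov^2) - t^2))
    if (off > 0.51 || t < -0.51)
      stop(sprintf("branch %d: origin does not lie on parent axis", b$branch_id[i]))
  }
  out <- b[, need, with = FALSE]
  class(out) <- c("tree_spec", class(out))
  out
}

#' @export
print.tree_spec <- function(x, ...) {
  cat(sprintf("tree_spec: %d branches, generations %s, lobes %s\n", nrow(x),
              if (nrow(x)) paste(range(x$generation), collapse = "-") else "-",
              paste(unique(x$lobe), collapse = ",")))
  invisible(x)
}

#' Single straight cylinder specification
#'
#' @param radius_um,length_um cylinder radius and length (micrometres).
#' @param origin 1-based `(z, y, x)` voxel coordinates of the proximal end.
#' @param direction direction vector `(dz, dy, dx)`; default along +z.
#' @param lobe,generation nomenclature attributes of the branch.
#' @return a [tree_spec()] with one branch.
#' @export
phantom_cylinder_spec <- function(radius_um, length_um, origin, direction = c(1, 0, 0),
                                  lobe = "LL", generation = 1L) {
  tree_spec(data.frame(branch_id = 1L, parent_id = NA_integer_,
                       oz = origin[1], oy = origin[2], ox = origin[3],
                       dz = direction[1], dy = direction[2], dx = direction[3],
                       length_um = length_um, radius_um = radius_um,
                       generation = generation, lobe = lobe))
}

#' Two-branch monopodial tree (trunk plus one oblique daughter)
#'
#' @param radius_um trunk radius; the daughter gets `child_frac * radius_um`.
#' @param length_um trunk length; daughter length is `child_length_um`.
#' @param origin trunk origin `(z, y, x)`.
#' @param branch_at fractional position along the trunk where the daughter
#'   buds (default mid-trunk).
#' @param child_angle_deg angle between trunk and daughter (default 45).
#' @param child_frac daughter/trunk radius ratio.
#' @param child_length_um daughter length.
#' @return a [tree_spec()] with two branches.
#' @export
phantom_two_branch_spec <- function(radius_um, length_um, origin,
                                    branch_at = 0.5, child_angle_deg = 45,
                                    child_frac = 0.7,
                                    child_length_um = 0.4 * length_um) {
  a <- child_angle_deg * pi / 180
  o2 <- c(origin[1] + branch_at * length_um, origin[2], origin[3])
  tree_spec(data.frame(
    branch_id = c(1L, 2L), parent_id = c(NA_integer_, 1L),
    oz = c(origin[1], o2[1]), oy = c(origin[2], o2[2]), ox = c(origin[3], o2[3]),
    dz = c(1, cos(a)), dy = c(0, sin(a)), dx = c(0, 0),
    length_um = c(length_um, child_length_um),
    radius_um = c(radius_um, child_frac * radius_um),
    generation = c(1L, 2L), lobe = "LL"))
}

#' Monopodial demonstration tree
#'
#' A trunk with several oblique daughters, emulating the monopodial murine
#' anatomy at toy scale.  Used by the pipeline demos and tests.
#'
#' @param trunk_radius_um,trunk_length_um trunk geometry.
#' @param origin trunk origin `(z, y, x)` in voxels.
#' @param n_laterals number of daughter branches budding off the trunk.
#' @return a [tree_spec()].
#' @export
phantom_demo_tree <- function(trunk_radius_um = 10, trunk_length_um = 90,
                              origin = c(8, 40, 40), n_laterals = 3L) {
  rows <- list(data.frame(
    branch_id = 1L, parent_id = NA_integer_, oz = origin[1], oy = origin[2],
    ox = origin[3], dz = 1, dy = 0, dx = 0, length_um = trunk_length_um,
    radius_um = trunk_radius_um, generation = 1L, lobe = "LL"))
  for (k in seq_len(n_laterals)) {
    at <- k / (n_laterals + 1)
    phi <- (k - 1) * 2 * pi / n_laterals
    a <- 50 * pi / 180
    d <- c(cos(a), sin(a) * cos(phi), sin(a) * sin(phi))
    rows[[k + 1L]] <- data.frame(
      branch_id = k + 1L, parent_id = 1L,
      oz = origin[1] + at * trunk_length_um, oy = origin[2], ox = origin[3],
      dz = d[1], dy = d[2], dx = d[3],
      length_um = 0.35 * trunk_length_um, radius_um = 0.55 * trunk_radius_um,
      generation = 2L, lobe = "LL")
  }
  tree_spec(do.call(rbind, rows))
}

# per-branch geometry in voxel units
branch_geom <- function(spec, voxel_size) {
  lapply(seq_len(nrow(spec)), function(i) {
    d <- unit3(c(spec$dz[i], spec$dy[i], spec$dx[i]))
    list(id = spec$branch_id[i],
         o = c(spec$oz[i], spec$oy[i], spec$ox[i]),
         d = d,
         L = spec$length_um[i] / voxel_size,
         r = spec$radius_um[i] / voxel_size,
         basis = plane_basis(d))
  })
}

#' Voxelise an airway tree into lumen mask, branch labels and centerline
#'
#' A voxel belongs to the lumen iff its centre lies strictly within the
#' radius of some branch axis segment (voxel-centre membership, no
#' anti-aliasing, so exact counting oracles apply).  Each lumen voxel is
#' labelled with the branch whose axis is nearest.
#'
#' @param spec a [tree_spec()].
#' @param volume_shape integer `(nz, ny, nx)`.
#' @param voxel_size_um isotropic voxel size; branch lengths/radii in
#'   micrometres are divided by it.
#' @param seed unused (the construction is deterministic); accepted so all
#'   generators share one signature.
#' @return an `airway_phantom` list: `lumen` (logical array), `labels`
#'   (integer array, 0 = background), `station` (integer array, 1-based
#'   axial station of each lumen voxel along its branch), `centerline`
#'   (data.table `branch_id, station, z, y, x`), plus `spec`, `dims`,
#'   `voxel_size_um`.
#' @export
build_tree_volume <- function(spec, volume_shape, voxel_size_um = 1, seed = NULL) {
  dims <- as.integer(volume_shape)
  if (length(dims) != 3L || any(dims <= 0)) stop("volume_shape must be 3 positive integers")
  if (voxel_size_um <= 0) stop("voxel_size_um must be positive")
  lumen <- array(FALSE, dims)
  labels <- array(0L, dims)
  station <- array(0L, dims)
  bestd <- array(Inf, dims)
  cl <- list()
  if (nrow(spec) > 0L) {
    geoms <- branch_geom(spec, voxel_size_um)
    parent_of <- spec$parent_id
    names(parent_of) <- as.character(spec$branch_id)
    overlap_pairs <- character(0)
    for (g in geoms) {
      p0 <- g$o; p1 <- g$o + g$L * g$d
      ext <- g$r * sqrt(pmax(0, 1 - g$d^2))
      lo <- pmin(p0, p1) - ext
      hi <- pmax(p0, p1) + ext
      if (any(lo < 0.5) || any(hi > dims + 0.5))
        stop(sprintf("branch %d does not fit inside the volume", g$id))
      zi <- max(1L, floor(lo[1])):min(dims[1], ceiling(hi[1]))
      yi <- max(1L, floor(lo[2])):min(dims[2], ceiling(hi[2]))
      xi <- max(1L, floor(lo[3])):min(dims[3], ceiling(hi[3]))
      nz <- length(zi); ny <- length(yi); nx <- length(xi)
      Z <- rep(zi, times = ny * nx)
      Y <- rep(rep(yi, each = nz), times = nx)
      X <- rep(xi, each = nz * ny)
      vz <- Z - g$o[1]; vy <- Y - g$o[2]; vx <- X - g$o[3]
      t <- vz * g$d[1] + vy * g$d[2] + vx * g$d[3]
      d2 <- vz^2 + vy^2 + vx^2 - t^2
      inside <- t >= 0 & t <= g$L & d2 < g$r^2
      if (!any(inside)) next
      li <- lin_index(Z[inside], Y[inside], X[inside], dims)
      daxis <- sqrt(pmax(0, d2[inside]))
      prev <- labels[li]
      pid <- parent_of[[as.character(g$id)]]
      clash <- prev != 0L & prev != g$id &
        prev != (if (is.na(pid)) -1L else pid) &
        parent_of[as.character(prev)] != g$id
      clash[is.na(clash)] <- FALSE
      if (any(clash))
        overlap_pairs <- union(overlap_pairs,
                               paste(pmin(prev[clash], g$id), pmax(prev[clash], g$id), sep = "-"))
      upd <- daxis < bestd[li]
      if (any(upd)) {
        liu <- li[upd]
        labels[liu] <- g$id
        bestd[liu] <- daxis[upd]
        station[liu] <- as.integer(floor(t[inside][upd])) + 1L
      }
      lumen[li] <- TRUE
      ns <- max(1L, ceiling(g$L))
      s <- seq_len(ns)
      pt <- outer(pmin(s - 0.5, g$L), g$d) # ns x 3
      cl[[length(cl) + 1L]] <- data.table(
        branch_id = g$id, station = s,
        z = g$o[1] + pt[, 1], y = g$o[2] + pt[, 2], x = g$o[3] + pt[, 3])
    }
    if (length(overlap_pairs))
      warning("overlapping non-adjacent branches: ", paste(overlap_pairs, collapse = ", "))
  }
  structure(list(lumen = lumen, labels = labels, station = station,
                 centerline = if (length(cl)) rbindlist(cl) else
                   data.table(branch_id = integer(), station = integer(),
                              z = numeric(), y = numeric(), x = numeric()),
                 spec = spec, dims = dims, voxel_size_um = voxel_size_um),
            class = "airway_phantom")
}

#' Mucus deposit specification
#'
#' Deposit morphologies are an artifact convention for emulating the range of
#' plugs seen in muco-obstructive airways: `plug` (full occlusion),
#' `annulus` (wall-lining ring of given radial thickness) and `crescent`
#' (partial wall coverage).  A crescent takes a target wall coverage
#' (`angular_coverage`, degrees) and either a radial `thickness_vox` or a
#' target `fill_fraction` of the cross-section area; when the requested fill
#' exceeds what a full-thickness wedge provides, a concentric core is added
#' (the union area is solved in closed form), so fill fraction and
#' wall-contact fraction are programmable independently within the
#' geometrically feasible region (full occlusion forces full contact).
#'
#' @param deposits data.frame with columns `branch_id`, `span_lo`, `span_hi`
#'   (fractional axial positions in `[0, 1]`), `kind`
#'   (plug/crescent/annulus), and optionally `fill_fraction`,
#'   `angular_coverage` (degrees), `thickness_vox`.
#' @return validated `deposit_spec` data.table.
#' @export
deposit_spec <- function(deposits) {
  d <- as.data.table(deposits)
  need <- c("branch_id", "span_lo", "span_hi", "kind")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("deposit_spec is missing columns: ", paste(miss, collapse = ", "))
  for (col in c("fill_fraction", "angular_coverage", "thickness_vox")) {
    if (!col %in% names(d)) d[, (col) := NA_real_]
    else d[, (col) := as.numeric(get(col))]
  }
  if (nrow(d)) {
    if (!all(d$kind %in% c("plug", "crescent", "annulus")))
      stop("kind must be plug, crescent or annulus")
    if (any(d$span_lo < 0 | d$span_hi > 1 | d$span_lo >= d$span_hi))
      stop("axial span must satisfy 0 <= span_lo < span_hi <= 1")
    d[kind == "plug", `:=`(fill_fraction = 1, angular_coverage = 360)]
    d[kind == "annulus", angular_coverage := 360]
    if (any(d$kind == "annulus" & is.na(d$thickness_vox)))
      stop("annulus deposits need thickness_vox")
    if (any(d$kind == "crescent" & is.na(d$angular_coverage)))
      stop("crescent deposits need angular_coverage")
    if (any(d$kind == "crescent" & is.na(d$fill_fraction) & is.na(d$thickness_vox)))
      stop("crescent deposits need fill_fraction or thickness_vox")
    bad <- !is.na(d$fill_fraction) & (d$fill_fraction < 0 | d$fill_fraction > 1)
    if (any(bad)) stop("fill_fraction must be in [0, 1]")
    bad <- !is.na(d$angular_coverage) & (d$angular_coverage < 0 | d$angular_coverage > 360)
    if (any(bad)) stop("angular_coverage must be in [0, 360] degrees")
    infeas <- d$kind == "crescent" & !is.na(d$fill_fraction) &
      d$fill_fraction >= 1 & d$angular_coverage < 360
    if (any(infeas))
      stop("full occlusion (fill_fraction 1) forces full wall contact; use kind = 'plug'")
  }
  class(d) <- c("deposit_spec", class(d))
  d
}

#' Carve mucus deposits into a phantom and compute exact ground truth
#'
#' Ground truth is obtained by exact voxel counting per axial station of each
#' branch: area ratio = mucus / lumen voxels of the station, contact ratio =
#' mucus-occupied perimeter voxels / all perimeter voxels, with the perimeter
#' defined as lumen voxels having a 6-neighbour outside the lumen (identical
#' to the metric module's wall definition).
#'
#' @param phantom result of [build_tree_volume()].
#' @param deposits a [deposit_spec()].
#' @param seed unused (deterministic); kept for signature uniformity.
#' @return list with `mucus` (logical array, subset of the lumen) and
#'   `ground_truth` (data.table `branch_id, station, true_area_ratio,
#'   true_contact_ratio, n_lumen, n_perimeter`).
#' @export
carve_mucus <- function(phantom, deposits, seed = NULL) {
  deposits <- deposit_spec(deposits)
  dims <- phantom$dims
  mucus <- array(FALSE, dims)
  if (nrow(deposits)) {
    unknown <- setdiff(deposits$branch_id, phantom$spec$branch_id)
    if (length(unknown))
      stop("deposit references unknown branch_id: ", paste(unknown, collapse = ", "))
    geoms <- branch_geom(phantom$spec, phantom$voxel_size_um)
    names(geoms) <- as.character(phantom$spec$branch_id)
    for (i in seq_len(nrow(deposits))) {
      dep <- deposits[i]
      g <- geoms[[as.character(dep$branch_id)]]
      li <- which(phantom$labels == dep$branch_id)
      if (!length(li)) next
      co <- lin_to_zyx(li, dims)
      vz <- co[, 1] - g$o[1]; vy <- co[, 2] - g$o[2]; vx <- co[, 3] - g$o[3]
      t <- vz * g$d[1] + vy * g$d[2] + vx * g$d[3]
      frac <- t / g$L
      insp <- frac >= dep$span_lo & frac <= dep$span_hi
      rz <- vz - t * g$d[1]; ry <- vy - t * g$d[2]; rx <- vx - t * g$d[3]
      rad <- sqrt(rz^2 + ry^2 + rx^2)
      sel <- insp
      if (dep$kind == "annulus") {
        sel <- insp & rad > g$r - dep$thickness_vox
      } else if (dep$kind == "crescent") {
        pu <- rz * g$basis$u[1] + ry * g$basis$u[2] + rx * g$basis$u[3]
        pv <- rz * g$basis$v[1] + ry * g$basis$v[2] + rx * g$basis$v[3]
        ang <- atan2(pv, pu) * 180 / pi            # (-180, 180]
        half <- dep$angular_coverage / 2
        inwin <- abs(ang) <= half
        cfrac <- dep$angular_coverage / 360
        if (is.na(dep$fill_fraction)) {
          sel <- insp & inwin & rad > g$r - dep$thickness_vox
        } else if (dep$fill_fraction <= cfrac) {
          tt <- g$r * (1 - sqrt(1 - dep$fill_fraction / cfrac))
          sel <- insp & inwin & rad > g$r - tt
        } else {
          rc <- g$r * sqrt((dep$fill_fraction - cfrac) / (1 - cfrac))
          sel <- insp & (inwin | rad < rc)
        }
      }
      mucus[li[sel]] <- TRUE
    }
  }
  per <- array(cpp_boundary6(as.logical(phantom$lumen), dims), dims)
  li <- which(phantom$lumen)
  gt <- data.table(branch_id = phantom$labels[li], station = phantom$station[li],
                   muc = mucus[li], per = per[li])
  gt <- gt[, .(n_lumen = .N, n_mucus = sum(muc), n_perimeter = sum(per),
               n_perimeter_mucus = sum(per & muc)),
           by = .(branch_id, station)]
  gt[, true_area_ratio := n_mucus / n_lumen]
  gt[, true_contact_ratio := ifelse(n_perimeter > 0, n_perimeter_mucus / n_perimeter, 0)]
  setorder(gt, branch_id, station)
  list(mucus = mucus,
       ground_truth = gt[, .(branch_id, station, true_area_ratio, true_contact_ratio,
                             n_lumen, n_perimeter)])
}

#' Render a phantom into an osmium-stain style intensity volume
#'
#' Emulates the contrast of osmium-stained, agarose-embedded lung: bright
#' tissue (0.85), dark air-filled lumen (0.10), intermediate mucus (0.60) on
#' a unit gray scale, plus additive Gaussian noise clipped to `[0, 1]`.
#' The gray triple is an artifact constant chosen so threshold-based
#' separation works up to noise sd ~0.1.
#'
#' @param lumen,mucus logical arrays of equal shape; `mucus` must be a subset
#'   of `lumen`.
#' @param noise_sd Gaussian noise standard deviation in gray-level units.
#' @param seed integer seed; the output is bit-identical for identical seeds.
#' @param voxel_size_um voxel size recorded on the returned [volume3d()].
#' @param levels named numeric: gray levels for `air`, `mucus`, `tissue`.
#' @export
render_intensity <- function(lumen, mucus, noise_sd = 0.05, seed = 1L,
                             voxel_size_um = 1,
                             levels = c(air = 0.10, mucus = 0.60, tissue = 0.85)) {
  stopifnot_same_shape(lumen, mucus, "lumen and mucus masks")
  if (any(mucus & !lumen)) stop("mucus mask must be a subset of the lumen mask")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  vol <- array(levels[["tissue"]], dim(lumen))
  vol[lumen] <- levels[["air"]]
  vol[mucus] <- levels[["mucus"]]
  if (noise_sd > 0) {
    noise <- withr::with_seed(as.integer(seed), rnorm(length(vol), 0, noise_sd))
    vol <- clamp(vol + noise, 0, 1)
  }
  volume3d(array(vol, dim(lumen)), voxel_size_um)
}

#' Synthetic cohort of per-sample mean ratio pairs
#'
#' Draws per-sample mean area ratios uniformly and generates mean contact
#' ratios from the linear wall-adherence model `y = slope * x + intercept +
#' N(0, noise_sd)`.  The defaults are the regression coefficients and the
#' observed range of mean area ratios of the study this package emulates
#' (slope 3.204, intercept 7.243 percentage points, x in 0.7-15.5 %).
#'
#' @param n_samples number of samples (>= 2).
#' @param slope,intercept linear model coefficients (percent scale).
#' @param noise_sd Gaussian noise sd in percentage points (>= 0).
#' @param x_range range of mean area ratios in percent, within `[0, 100]`.
#' @param seed integer seed.
#' @return data.table `sample_id, mean_area_ratio, mean_contact_ratio`
#'   (percent).
#' @export
generate_cohort_ratio_table <- function(n_samples, slope = 3.204, intercept = 7.243,
                                        noise_sd = 5, x_range = c(0.7, 15.5),
                                        seed = 1L) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (x_range[1] < 0 || x_range[2] > 100 || x_range[1] >= x_range[2])
    stop("x_range must be an increasing pair within [0, 100]")
  withr::with_seed(as.integer(seed), {
    x <- runif(n_samples, x_range[1], x_range[2])
    y <- slope * x + intercept + rnorm(n_samples, 0, noise_sd)
  })
  data.table(sample_id = sprintf("S%03d", seq_len(n_samples)),
             mean_area_ratio = x, mean_contact_ratio = y)
}

#' Synthetic ordinal mucus-score table
#'
#' One score per catalog segment per animal, drawn independently from the
#' probability triple of the segment's generation and the animal's group.
#'
#' @param catalog a nomenclature catalog ([default_catalog()]).
#' @param group_probs data.frame with columns `genotype`, `age_group`,
#'   `generation`, `p0`, `p1`, `p2`; every (group, generation) needed by the
#'   catalog must be present and each triple must sum to 1 (tolerance 1e-9).
#' @param n_animals animals per group.
#' @param seed integer seed.
#' @return data.table with columns `animal_id, genotype, age_group,
#'   segment_label, lobe, generation, score`.
#' @export
generate_score_table <- function(catalog, group_probs, n_animals, seed = 1L) {
  gp <- as.data.table(group_probs)
  need <- c("genotype", "age_group", "generation", "p0", "p1", "p2")
  miss <- setdiff(need, names(gp))
  if (length(miss)) stop("group_probs is missing columns: ", paste(miss, collapse = ", "))
  s <- gp$p0 + gp$p1 + gp$p2
  if (any(abs(s - 1) > 1e-9)) stop("probability triples must sum to 1")
  if (any(gp$p0 < 0 | gp$p1 < 0 | gp$p2 < 0)) stop("probabilities must be non-negative")
  cat_dt <- as.data.table(catalog)
  groups <- unique(gp[, .(genotype, age_group)])
  rows <- withr::with_seed(as.integer(seed), {
    out <- vector("list", nrow(groups) * n_animals)
    k <- 0L
    for (gi in seq_len(nrow(groups))) {
      gt <- groups$genotype[gi]; ag <- groups$age_group[gi]
      probs <- gp[genotype == gt & age_group == ag]
      pr <- merge(cat_dt[, .(segment_label, lobe, generation)],
                  probs[, .(generation, p0, p1, p2)],
                  by = "generation", all.x = TRUE, sort = FALSE)
      if (anyNA(pr$p0))
        stop(sprintf("group_probs lacks generation(s) %s for group %s/%s",
                     paste(sort(unique(pr$generation[is.na(pr$p0)])), collapse = ","), gt, ag))
      for (a in seq_len(n_animals)) {
        u <- runif(nrow(pr))
        score <- ifelse(u < pr$p0, 0L, ifelse(u < pr$p0 + pr$p1, 1L, 2L))
        k <- k + 1L
        out[[k]] <- data.table(
          animal_id = sprintf("%s_%s_%02d", gt, ag, a), genotype = gt, age_group = ag,
          segment_label = pr$segment_label, lobe = pr$lobe,
          generation = pr$generation, score = score)
      }
    }
    out
  })
  res <- rbindlist(rows)
  setattr(res, "catalog", cat_dt)
  res[]
}

#' Write a phantom bundle to disk
#'
#' Writes the rendered intensity volume (NRRD), branch label map (NRRD),
#' mucus mask (NRRD, 0/1), exact ground-truth table (CSV) and the tree
#' specification (CSV) into a directory.
#'
#' @param phantom result of [build_tree_volume()].
#' @param carved result of [carve_mucus()].
#' @param dir output directory (created if needed).
#' @param noise_sd,seed rendering parameters, see [render_intensity()].
#' @param force overwrite existing files.
#' @return invisibly, the named vector of written paths.
#' @export
write_phantom_bundle <- function(phantom, carved, dir, noise_sd = 0.05, seed = 1L,
                                 force = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vol <- render_intensity(phantom$lumen, carved$mucus, noise_sd = noise_sd, seed = seed,
                          voxel_size_um = phantom$voxel_size_um)
  paths <- c(intensity = file.path(dir, "intensity.nrrd"),
             labels = file.path(dir, "labels.nrrd"),
             mucus = file.path(dir, "mucus.nrrd"),
             ground_truth = file.path(dir, "ground_truth.csv"),
             tree = file.path(dir, "tree_spec.csv"))
  write_volume(vol, paths[["intensity"]], force = force)
  write_volume(volume3d(phantom$labels, phantom$voxel_size_um), paths[["labels"]], force = force)
  write_volume(volume3d(array(as.integer(carved$mucus), phantom$dims),
                        phantom$voxel_size_um), paths[["mucus"]], force = force)
  if (!force && file.exists(paths[["ground_truth"]]))
    stop("output exists; use force = TRUE to overwrite")
  write.csv(carved$ground_truth, paths[["ground_truth"]], row.names = FALSE)
  write.csv(as.data.frame(phantom$spec), paths[["tree"]], row.names = FALSE)
  invisible(paths)
}
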