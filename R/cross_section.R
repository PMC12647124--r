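# Airway cross-section extraction by three methods: slice (original z-planes),
# skeleton (planes orthogonal to the centerline tangent) and geodesic (level
# sets of the geodesic distance transform).  All methods emit comparable
# records with integer voxel counts so ratios stay oracle-checkable.

cs_record_cols <- c("method", "branch_id", "station", "n_lumen", "n_perimeter",
                    "n_mucus", "n_perimeter_mucus", "planar", "voxels")

empty_cs_records <- function() {
  out <- data.table(method = character(), branch_id = integer(), station = integer(),
                    n_lumen = integer(), n_perimeter = integer(), n_mucus = integer(),
                    n_perimeter_mucus = integer(), planar = logical(), voxels = list())
  class(out) <- c("cs_records", class(out))
  out
}

as_cs_records <- function(dt) {
  stopifnot(all(cs_record_cols %in% names(dt)))
  if (any(dt$n_lumen < 1L)) stop("cross-section records must have non-empty lumen")
  if (any(dt$n_mucus > dt$n_lumen)) stop("mucus count exceeds lumen count")
  class(dt) <- unique(c("cs_records", class(dt)))
  dt
}

labels_of <- function(x) {
  if (inherits(x, "lumen_segmentation")) x$labels
  else if (is.logical(x)) array(as.integer(x), dim(x))
  else x
}

#' Skeletonise an airway mask into a centerline graph
#'
#' Topology-preserving distance-ordered thinning produces a unit-width curve
#' skeleton; descending end tails (a known thinning artifact at blunt tube
#' caps) are trimmed using the chamfer distance map, terminal spurs shorter
#' than `prune_vox` are pruned, and the skeleton is decomposed into branches
#' by splitting at junction clusters and re-merging the best-aligned segment
#' pair at each junction (a monopodial trunk continues straight through).
#' Local tangents are central differences over a 5-node window (one-sided at
#' branch ends).
#'
#' @param mask non-empty logical array.
#' @param prune_vox prune terminal spurs shorter than this many nodes.
#' @param trim_tails trim end tails that descend the distance map.
#' @return a `skeleton_graph`: `nodes` (data.table `node_id, z, y, x,
#'   branch_id, degree, is_junction, station, tz, ty, tx`), `edges`,
#'   `branch_adjacency` (undirected pairs `a, b`), `dims`.
#' @export
skeletonize <- function(mask, prune_vox = 8L, trim_tails = TRUE) {
  dims <- vol_dims(mask)
  if (!any(mask)) stop("cannot skeletonise an empty mask")
  sk <- array(cpp_thin(as.logical(mask), dims), dims)
  distmap <- array(cpp_dist_to_bg(as.logical(mask), dims), dims)
  keep <- which(sk)
  g <- build_skel_graph(keep, dims)
  if (trim_tails) {
    repeat {
      drop <- trim_tail_nodes(g, distmap)
      if (!length(drop)) break
      keep <- setdiff(keep, drop)
      g <- build_skel_graph(keep, dims)
    }
  }
  if (prune_vox > 0L) {
    repeat {
      drop <- spur_nodes(g, prune_vox, distmap)
      if (!length(drop)) break
      keep <- setdiff(keep, drop)
      g <- build_skel_graph(keep, dims)
    }
  }
  sg <- finalize_skeleton(g, dims)
  # drop redundant branches: a decomposition "branch" whose nodes all lie
  # inside the tube of other branches covers no territory of its own and is
  # a thinning artifact of junction widening
  for (pass in 1:3) {
    drop_ids <- redundant_branches(sg, distmap)
    if (!length(drop_ids)) break
    nd <- sg$nodes
    keep <- lin_index(nd$z, nd$y, nd$x, dims)[!(nd$branch_id %in% drop_ids & !nd$is_junction)]
    g <- build_skel_graph(keep, dims)
    sg <- finalize_skeleton(g, dims)
  }
  sg
}

redundant_branches <- function(sg, distmap) {
  nd <- sg$nodes
  ids <- unique(nd$branch_id)
  if (length(ids) <= 1L) return(integer(0))
  sizes <- table(nd$branch_id)
  main <- as.integer(names(sizes)[which.max(sizes)])
  drop <- integer(0)
  for (b in setdiff(ids, main)) {
    own <- nd[nd$branch_id == b & !nd$is_junction]
    if (!nrow(own)) next
    oth <- nd[nd$branch_id != b]
    d2 <- outer(own$z, oth$z, "-")^2 + outer(own$y, oth$y, "-")^2 +
      outer(own$x, oth$x, "-")^2
    nearest <- apply(d2, 1L, which.min)
    dn <- sqrt(d2[cbind(seq_len(nrow(own)), nearest)])
    rloc <- distmap[lin_index(oth$z[nearest], oth$y[nearest], oth$x[nearest], sg$dims)]
    if (mean(dn < rloc + 2) > 0.85) drop <- c(drop, b)
  }
  drop
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton_graph: %d nodes, %d branches, %d junction voxels\n",
              nrow(x$nodes), length(unique(x$nodes$branch_id)), sum(x$nodes$is_junction)))
  invisible(x)
}

# adjacency among skeleton voxels given their linear indices
build_skel_graph <- function(idx, dims) {
  idx <- sort(idx)
  co <- lin_to_zyx(idx, dims)
  pos <- seq_along(idx)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[offs[, "dz"] > 0 | (offs[, "dz"] == 0 & offs[, "dy"] > 0) |
                 (offs[, "dz"] == 0 & offs[, "dy"] == 0 & offs[, "dx"] > 0), , drop = FALSE]
  ef <- integer(0); et <- integer(0)
  for (k in seq_len(nrow(offs))) {
    z2 <- co[, "z"] + offs[k, "dz"]; y2 <- co[, "y"] + offs[k, "dy"]; x2 <- co[, "x"] + offs[k, "dx"]
    ok <- z2 >= 1 & z2 <= dims[1] & y2 >= 1 & y2 <= dims[2] & x2 >= 1 & x2 <= dims[3]
    tgt <- rep(NA_integer_, length(idx))
    tgt[ok] <- match(lin_index(z2[ok], y2[ok], x2[ok], dims), idx)
    hit <- which(!is.na(tgt))
    ef <- c(ef, pos[hit]); et <- c(et, tgt[hit])
  }
  deg <- tabulate(c(ef, et), nbins = length(idx))
  adj <- vector("list", length(idx))
  for (i in seq_along(ef)) {
    adj[[ef[i]]] <- c(adj[[ef[i]]], et[i])
    adj[[et[i]]] <- c(adj[[et[i]]], ef[i])
  }
  list(idx = idx, co = co, ef = ef, et = et, deg = deg, adj = adj, dims = dims)
}

# segments = connected components after removing junction (deg >= 3) nodes;
# tiny (<= 2 node) segments bridging junction voxels are junction material
segment_membership <- function(g) {
  n <- length(g$idx)
  isj <- g$deg >= 3L
  repeat {
    sm <- segment_membership_raw(g, isj)
    bridge <- logical(n)
    for (s in seq_len(sm$nseg)) {
      members <- which(sm$seg == s)
      if (length(members) > 2L) next
      if (all(vapply(members, function(p) any(isj[g$adj[[p]]]), logical(1))) &&
          sum(isj) > 0L)
        bridge[members] <- TRUE
    }
    if (!any(bridge)) return(sm)
    isj <- isj | bridge
  }
}

segment_membership_raw <- function(g, isj) {
  n <- length(g$idx)
  seg <- integer(n)
  nseg <- 0L
  for (s in seq_len(n)) {
    if (isj[s] || seg[s] != 0L) next
    nseg <- nseg + 1L
    stack <- s; seg[s] <- nseg
    while (length(stack)) {
      c0 <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (nb in g$adj[[c0]]) {
        if (!isj[nb] && seg[nb] == 0L) {
          seg[nb] <- nseg
          stack <- c(stack, nb)
        }
      }
    }
  }
  list(seg = seg, isj = isj, nseg = nseg)
}

# ordered node positions of one segment (a path); returns positions in order
order_segment <- function(g, members) {
  if (length(members) == 1L) return(members)
  memset <- members
  degs <- vapply(members, function(p) sum(g$adj[[p]] %in% memset), integer(1))
  start <- members[degs <= 1L]
  start <- if (length(start)) min(start) else min(members)
  ord <- integer(0)
  visited <- logical(length(g$idx))
  cur <- start
  repeat {
    ord <- c(ord, cur)
    visited[cur] <- TRUE
    nxt <- setdiff(g$adj[[cur]][g$adj[[cur]] %in% memset], which(visited))
    nxt <- nxt[!visited[nxt]]
    if (!length(nxt)) break
    cur <- nxt[1]
  }
  if (length(ord) < length(members)) ord <- c(ord, setdiff(members, ord))
  ord
}

# nodes to drop: tail ends whose distance-to-background strictly descends
# towards a free endpoint (cap artifact of thinning)
trim_tail_nodes <- function(g, distmap) {
  sm <- segment_membership(g)
  drop <- integer(0)
  for (s in seq_len(sm$nseg)) {
    members <- which(sm$seg == s)
    if (length(members) < 3L) next
    ord <- order_segment(g, members)
    dvals <- distmap[g$idx[ord]]
    for (endside in c("head", "tail")) {
      o <- if (endside == "head") ord else rev(ord)
      dv <- if (endside == "head") dvals else rev(dvals)
      # free end only (endpoint not attached to a junction)
      if (any(sm$isj[g$adj[[o[1]]]])) next
      k <- 0L
      while (k + 1L < length(o) - 2L && dv[k + 1L] < dv[k + 2L] - 1e-9) k <- k + 1L
      if (k > 0L) drop <- c(drop, o[seq_len(k)])
    }
  }
  unique(g$idx[drop])
}

# terminal segments attached to a junction that are shorter than the spur
# threshold: the fixed prune_vox, or the local tube radius at the junction
# plus a margin (junction bulges shed skeleton spurs up to ~radius long)
spur_nodes <- function(g, prune_vox, distmap = NULL) {
  sm <- segment_membership(g)
  if (sm$nseg <= 1L) return(integer(0))
  drop <- integer(0)
  for (s in seq_len(sm$nseg)) {
    members <- which(sm$seg == s)
    touches_j <- vapply(members, function(p) any(sm$isj[g$adj[[p]]]), logical(1))
    free_end <- vapply(members, function(p) sum(g$adj[[p]] %in% members) <= 1L &&
                         !any(sm$isj[g$adj[[p]]]), logical(1))
    if (!any(touches_j) || !any(free_end)) next
    thr <- prune_vox
    if (!is.null(distmap)) {
      # junction bulges shed spurs up to ~local radius long
      jn <- unlist(lapply(members[touches_j], function(p) g$adj[[p]][sm$isj[g$adj[[p]]]]))
      if (length(jn))
        thr <- max(thr, max(distmap[g$idx[jn]]) + 3)
    }
    if (length(members) < thr) drop <- c(drop, members)
  }
  unique(g$idx[drop])
}

finalize_skeleton <- function(g, dims) {
  n <- length(g$idx)
  sm <- segment_membership(g)
  # junction clusters (26-connected groups of junction nodes)
  jclust <- integer(n); njc <- 0L
  for (s in which(sm$isj)) {
    if (jclust[s] != 0L) next
    njc <- njc + 1L
    stack <- s; jclust[s] <- njc
    while (length(stack)) {
      c0 <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (nb in g$adj[[c0]]) if (sm$isj[nb] && jclust[nb] == 0L) {
        jclust[nb] <- njc
        stack <- c(stack, nb)
      }
    }
  }
  # union-find over segments for straight-through merging
  parent <- seq_len(max(sm$nseg, 1L))
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  seg_ord <- lapply(seq_len(sm$nseg), function(s) order_segment(g, which(sm$seg == s)))
  seg_dir_at <- function(s, jnodes) {
    ord <- seg_ord[[s]]
    # orient so that ord[1] is the end adjacent to this junction cluster
    touches_first <- any(g$adj[[ord[1]]] %in% jnodes)
    touches_last <- any(g$adj[[ord[length(ord)]]] %in% jnodes)
    if (!touches_first && touches_last) ord <- rev(ord)
    k <- min(5L, length(ord))
    v <- g$co[ord[k], ] - g$co[ord[1], ]
    if (all(v == 0)) return(NULL)
    unit3(as.numeric(v))
  }
  jassign <- integer(n)  # branch segment assigned to junction nodes
  adj_pairs <- list()
  for (jc in seq_len(njc)) {
    jnodes <- which(jclust == jc)
    inc <- unique(unlist(lapply(jnodes, function(p) sm$seg[g$adj[[p]]])))
    inc <- setdiff(inc, 0L)
    if (length(inc) >= 2L) {
      dirs <- lapply(inc, seg_dir_at, jnodes = jnodes)
      ok <- !vapply(dirs, is.null, logical(1))
      inc2 <- inc[ok]; dirs <- dirs[ok]
      best <- NULL; bestdot <- Inf
      if (length(inc2) >= 2L) {
        for (i in seq_len(length(inc2) - 1L)) for (j in (i + 1L):length(inc2)) {
          dt_ <- sum(dirs[[i]] * dirs[[j]])
          if (dt_ < bestdot) { bestdot <- dt_; best <- c(inc2[i], inc2[j]) }
        }
      }
      if (!is.null(best) && bestdot < -0.5)
        parent[findp(best[2])] <- findp(best[1])
      jassign[jnodes] <- if (!is.null(best)) best[1] else inc[1]
      if (length(inc) >= 2L)
        for (i in seq_len(length(inc) - 1L)) for (j in (i + 1L):length(inc))
          adj_pairs[[length(adj_pairs) + 1L]] <- c(inc[i], inc[j])
    } else if (length(inc) == 1L) {
      jassign[jnodes] <- inc[1]
    }
  }
  seg_root <- vapply(seq_len(max(sm$nseg, 1L)), findp, integer(1))
  # contiguous branch ids
  node_seg <- ifelse(sm$isj, jassign, sm$seg)
  node_seg[node_seg == 0L] <- if (sm$nseg > 0L) 1L else 1L
  node_branch_raw <- seg_root[node_seg]
  ids <- sort(unique(node_branch_raw))
  branch_id <- match(node_branch_raw, ids)
  # branch adjacency on merged ids
  ba <- unique(rbindlist(lapply(adj_pairs, function(p) {
    a <- match(seg_root[p[1]], ids); b <- match(seg_root[p[2]], ids)
    if (a == b) NULL else data.table(a = min(a, b), b = max(a, b))
  })))
  if (is.null(ba) || !nrow(ba)) ba <- data.table(a = integer(), b = integer())
  # order nodes along each branch, compute stations and tangents
  station <- integer(n); tz <- rep(NA_real_, n); ty <- rep(NA_real_, n); tx <- rep(NA_real_, n)
  for (b in sort(unique(branch_id))) {
    members <- which(branch_id == b)
    ord <- order_segment(g, members)
    station[ord] <- seq_along(ord)
    if (length(ord) >= 2L) {
      for (i in seq_along(ord)) {
        lo <- max(1L, i - 2L); hi <- min(length(ord), i + 2L)
        v <- g$co[ord[hi], ] - g$co[ord[lo], ]
        if (any(v != 0)) {
          u <- unit3(as.numeric(v))
          tz[ord[i]] <- u[1]; ty[ord[i]] <- u[2]; tx[ord[i]] <- u[3]
        }
      }
    }
  }
  nodes <- data.table(node_id = seq_len(n), z = g$co[, "z"], y = g$co[, "y"],
                      x = g$co[, "x"], branch_id = branch_id, degree = g$deg,
                      is_junction = sm$isj, station = station,
                      tz = tz, ty = ty, tx = tx)
  edges <- data.table(from = g$ef, to = g$et)
  structure(list(nodes = nodes, edges = edges, branch_adjacency = ba, dims = dims),
            class = "skeleton_graph")
}

#' Slice-method cross-sections (original z-planes)
#'
#' One record per (z-plane, branch label) present; the lumen set is the
#' label's voxels in that plane, with no resampling.  Fast, exact for
#' z-aligned branches, but smears oblique ones (the lumen area of a branch
#' tilted by angle a inflates by 1/cos a).
#'
#' @param x branch label array (or a `lumen_segmentation`).
#' @param mucus logical mucus mask, congruent with `x`.
#' @return a `cs_records` data.table.
#' @export
slice_cross_sections <- function(x, mucus) {
  labels <- labels_of(x)
  dims <- vol_dims(labels)
  stopifnot_same_shape(labels, mucus, "label map and mucus mask")
  li <- which(labels > 0L)
  if (!length(li)) return(empty_cs_records())
  mask <- array(labels > 0L, dims)
  per <- array(cpp_boundary6(as.logical(mask), dims), dims)
  co_z <- (li - 1L) %% dims[1L] + 1L
  dt <- data.table(idx = li, z = co_z, branch_id = labels[li],
                   muc = mucus[li], per = per[li])
  rec <- dt[, .(n_lumen = .N, n_mucus = sum(muc), n_perimeter = sum(per),
                n_perimeter_mucus = sum(per & muc), voxels = list(idx)),
            by = .(branch_id, station = z)]
  rec[, `:=`(method = "slice", planar = TRUE)]
  setorder(rec, branch_id, station)
  as_cs_records(rec[, cs_record_cols, with = FALSE])
}

#' Skeleton-method cross-sections (planes orthogonal to the centerline)
#'
#' At every non-junction skeleton node the plane orthogonal to the local
#' tangent is sampled on a voxel-pitch grid (nearest-neighbour lookup, no
#' interpolation); the record's lumen set is the 4-connected in-plane region
#' containing the node, which prevents capturing nearby branches.  Junction
#' nodes emit no record (topology there is unreliable); nodes without a
#' tangent are skipped with a logged count.
#'
#' @param x branch label array or `lumen_segmentation` (the airway mask is
#'   `x > 0`).
#' @param skel a [skeletonize()] result derived from the same mask.
#' @param mucus logical mucus mask.
#' @param max_extent maximum in-plane half-extent in voxels.
#' @return a `cs_records` data.table.
#' @export
skeleton_cross_sections <- function(x, skel, mucus, max_extent = 96L) {
  labels <- labels_of(x)
  dims <- vol_dims(labels)
  stopifnot_same_shape(labels, mucus, "label map and mucus mask")
  mask <- labels > 0L
  nodes <- skel$nodes[!skel$nodes$is_junction]
  skipped <- 0L
  out <- vector("list", nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    nd <- nodes[i]
    if (is.na(nd$tz)) { skipped <- skipped + 1L; next }
    t <- c(nd$tz, nd$ty, nd$tx)
    bas <- plane_basis(t)
    p0 <- c(nd$z, nd$y, nd$x)
    L <- 8L
    repeat {
      ij <- -L:L
      gi <- rep(ij, times = length(ij)); gj <- rep(ij, each = length(ij))
      pz <- p0[1] + gi * bas$u[1] + gj * bas$v[1]
      py <- p0[2] + gi * bas$u[2] + gj * bas$v[2]
      px <- p0[3] + gi * bas$u[3] + gj * bas$v[3]
      vz <- as.integer(round(pz)); vy <- as.integer(round(py)); vx <- as.integer(round(px))
      ok <- vz >= 1L & vz <= dims[1] & vy >= 1L & vy <= dims[2] & vx >= 1L & vx <= dims[3]
      inm <- logical(length(gi))
      vox <- rep(NA_integer_, length(gi))
      vox[ok] <- lin_index(vz[ok], vy[ok], vx[ok], dims)
      inm[ok] <- mask[vox[ok]]
      side <- 2L * L + 1L
      cc <- cpp_label_components(as.logical(inm), c(1L, side, side), 6L)
      centre <- (length(gi) + 1L) %/% 2L + 1L - 1L  # centre cell index
      centre <- L * side + L + 1L
      if (cc[centre] == 0L) { skipped <- skipped + 1L; comp <- NULL; break }
      comp <- cc == cc[centre]
      m <- matrix(comp, side, side)
      touches <- any(m[1, ]) || any(m[side, ]) || any(m[, 1]) || any(m[, side])
      if (!touches || L >= max_extent) break
      L <- min(max_extent, L * 2L)
    }
    if (is.null(comp)) next
    m <- matrix(comp, side, side)
    # 4-neighbour perimeter within the plane
    up <- rbind(FALSE, m[-side, ]); dn <- rbind(m[-1, ], FALSE)
    lf <- cbind(FALSE, m[, -side]); rt <- cbind(m[, -1], FALSE)
    perim <- m & !(up & dn & lf & rt)
    muc <- comp & !is.na(vox) & mucus[ifelse(is.na(vox), 1L, vox)]
    out[[i]] <- data.table(
      method = "skeleton", branch_id = nd$branch_id, station = nd$station,
      n_lumen = sum(comp), n_perimeter = sum(perim),
      n_mucus = sum(muc), n_perimeter_mucus = sum(muc & as.vector(perim)),
      planar = TRUE, voxels = list(unique(vox[comp])))
  }
  if (skipped > 0L)
    message(sprintf("skeleton_cross_sections: skipped %d node(s) without usable tangent/plane", skipped))
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_cs_records())
  rec <- rbindlist(out)
  setorder(rec, branch_id, station)
  as_cs_records(rec[, cs_record_cols, with = FALSE])
}

#' Geodesic-method cross-sections (level sets of the geodesic distance)
#'
#' Chamfer-weighted (1 / sqrt 2 / sqrt 3) geodesic distance is computed
#' inside the airway mask from a seed slice (by default the lowest z-plane
#' containing the largest branch), voxels are binned by
#' `floor(distance / bin_width)`, and each (branch, bin) pair becomes one
#' record.  Bins are generally non-planar, so the "area" ratio is the mucus
#' volume fraction of the bin.  Mask components unreachable from the seed
#' form the excluded set (no records; rendered blue on maps).
#'
#' @param x branch label array or `lumen_segmentation`.
#' @param mucus logical mucus mask.
#' @param bin_width level-set bin width in voxels (default 1).
#' @param seed seed region: `NULL` (auto), a logical array, or linear voxel
#'   indices.
#' @return list: `records` (`cs_records`), `excluded` (logical array of
#'   unreachable mask voxels).
#' @export
geodesic_cross_sections <- function(x, mucus, bin_width = 1, seed = NULL) {
  labels <- labels_of(x)
  dims <- vol_dims(labels)
  stopifnot_same_shape(labels, mucus, "label map and mucus mask")
  if (bin_width <= 0) stop("bin_width must be positive")
  mask <- array(labels > 0L, dims)
  if (!any(mask)) return(list(records = empty_cs_records(), excluded = array(FALSE, dims)))
  if (is.null(seed)) {
    counts <- tabulate(labels[labels > 0L])
    main <- which.max(counts)
    main_idx <- which(labels == main)
    zmain <- (main_idx - 1L) %% dims[1L] + 1L
    z0 <- min(zmain)
    seed_idx <- main_idx[zmain == z0]
  } else if (is.logical(seed)) {
    seed_idx <- which(seed)
  } else seed_idx <- as.integer(seed)
  seed_idx <- seed_idx[mask[seed_idx]]
  if (!length(seed_idx)) stop("seed region is disjoint from the mask")
  g <- cpp_geodesic(as.logical(mask), dims, seed_idx, rep(1L, length(seed_idx)),
                    numeric(0))
  dist <- g$dist
  reached <- is.finite(dist) & as.vector(mask)
  excluded <- array(as.vector(mask) & !reached, dims)
  li <- which(reached)
  per <- cpp_boundary6(as.logical(mask), dims)
  dt <- data.table(idx = li, branch_id = labels[li],
                   station = as.integer(floor(dist[li] / bin_width)) + 1L,
                   muc = mucus[li], per = per[li])
  rec <- dt[, .(n_lumen = .N, n_mucus = sum(muc), n_perimeter = sum(per),
                n_perimeter_mucus = sum(per & muc), voxels = list(idx)),
            by = .(branch_id, station)]
  rec[, `:=`(method = "geodesic", planar = FALSE)]
  setorder(rec, branch_id, station)
  list(records = as_cs_records(rec[, cs_record_cols, with = FALSE]),
       excluded = excluded)
}

# per-voxel record index volume (for ratio map rendering)
station_label_volume <- function(records, dims) {
  out <- array(0L, dims)
  for (i in seq_len(nrow(records))) out[records$voxels[[i]]] <- i
  out
}
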