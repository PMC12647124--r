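test_that("skeleton of a straight cylinder is a single path on the axis", {
  ph <- std_cylinder(radius = 8, length = 50)
  sk <- skeletonize(ph$lumen)
  expect_identical(length(unique(sk$nodes$branch_id)), 1L)
  ctr <- (dim(ph$lumen)[2] + 1) / 2
  off_axis <- sqrt((sk$nodes$y - ctr)^2 + (sk$nodes$x - ctr)^2)
  expect_lte(max(off_axis), 1)
  expect_true(all(sk$nodes$degree <= 2))
  # tangents are unit vectors along z
  tg <- sk$nodes[!is.na(sk$nodes$tz), ]
  expect_equal(sqrt(tg$tz^2 + tg$ty^2 + tg$tx^2), rep(1, nrow(tg)), tolerance = 1e-9)
  expect_true(all(abs(tg$tz) > 0.95))
})

test_that("degenerate and disjoint masks skeletonise sanely", {
  d <- c(21, 21, 21)
  ctr <- 11
  ball <- array(FALSE, d)
  g <- expand.grid(z = 1:21, y = 1:21, x = 1:21)
  ball[as.matrix(g[(g$z - ctr)^2 + (g$y - ctr)^2 + (g$x - ctr)^2 < 64, ])] <- TRUE
  sk <- skeletonize(ball, prune_vox = 0, trim_tails = FALSE)
  expect_gt(nrow(sk$nodes), 0L)
  expect_true(all(ball[cbind(sk$nodes$z, sk$nodes$y, sk$nodes$x)]))
  two <- array(FALSE, c(40, 24, 24))
  two[5:35, 4:10, 4:10] <- TRUE
  two[5:35, 15:21, 15:21] <- TRUE
  sk2 <- skeletonize(two)
  expect_gte(length(unique(sk2$nodes$branch_id)), 2L)
  expect_error(skeletonize(array(FALSE, c(4, 4, 4))), "empty")
})

test_that("slice method equals the digital-disc oracle on a z-aligned cylinder", {
  ph <- std_cylinder(radius = 10, length = 40)
  cs <- slice_cross_sections(ph$labels, array(FALSE, dim(ph$lumen)))
  oracle <- disc_count(10)
  expect_true(all(cs$n_lumen == oracle))
  n_planes <- length(unique(which(ph$lumen, arr.ind = TRUE)[, 1]))
  expect_identical(nrow(cs), n_planes)   # one record per z-plane with lumen
  expect_true(all(cs$planar))
  empty <- slice_cross_sections(array(0L, c(4, 4, 4)), array(FALSE, c(4, 4, 4)))
  expect_identical(nrow(empty), 0L)
})

test_that("45-degree tilt smears the slice method by about sqrt(2)", {
  d <- c(1, 1, 0) / sqrt(2)
  spec <- phantom_cylinder_spec(10, 80, origin = c(10, 10, 25), direction = d)
  ph <- build_tree_volume(spec, c(90, 90, 50), 1)
  cs <- slice_cross_sections(ph$labels, array(FALSE, dim(ph$lumen)))
  ratio <- median(cs$n_lumen) / disc_count(10)
  expect_gt(ratio, 1.30)
  expect_lt(ratio, 1.55)
})

test_that("skeleton method matches slice counts on z-aligned, resists tilt", {
  ph <- std_cylinder(radius = 10, length = 40)
  mucus <- array(FALSE, dim(ph$lumen))
  sk <- skeletonize(ph$lumen)
  kc <- skeleton_cross_sections(ph$labels, sk, mucus)
  expect_true(all(kc$n_lumen == disc_count(10)))
  # tilted: no smear, within 8 % of pi R^2
  d <- c(1, 1, 0) / sqrt(2)
  spec <- phantom_cylinder_spec(10, 80, origin = c(10, 10, 25), direction = d)
  ph2 <- build_tree_volume(spec, c(90, 90, 50), 1)
  sk2 <- skeletonize(ph2$lumen)
  kc2 <- skeleton_cross_sections(ph2$labels, sk2, array(FALSE, dim(ph2$lumen)))
  expect_lt(abs(median(kc2$n_lumen) - pi * 100) / (pi * 100), 0.08)
  # rotation robustness: median changes by <= 10 % between aligned and tilted
  expect_lt(abs(median(kc2$n_lumen) - median(kc$n_lumen)) / median(kc$n_lumen), 0.10)
})

test_that("junction nodes emit no skeleton-method record", {
  ph <- std_two_branch()
  sk <- skeletonize(ph$lumen)
  kc <- skeleton_cross_sections(ph$labels, sk, array(FALSE, dim(ph$lumen)))
  jn <- sk$nodes[sk$nodes$is_junction, c("branch_id", "station")]
  if (nrow(jn)) {
    hits <- merge(as.data.frame(kc)[, c("branch_id", "station")], jn,
                  by = c("branch_id", "station"))
    expect_identical(nrow(hits), 0L)
  }
  expect_gt(nrow(kc), 0L)
})

test_that("geodesic bins coincide with z-slices on a straight cylinder", {
  ph <- std_cylinder(radius = 9, length = 40, margin = 8)
  deps <- deposit_spec(data.frame(branch_id = 1L, span_lo = 0.25, span_hi = 0.75,
                                  kind = "annulus", thickness_vox = 3))
  cv <- carve_mucus(ph, deps)
  sl <- compute_ratios(slice_cross_sections(ph$labels, cv$mucus))
  gx <- geodesic_cross_sections(ph$labels, cv$mucus, bin_width = 1)
  gg <- compute_ratios(gx$records)
  # bins partition the reachable mask
  expect_identical(sum(gx$records$n_lumen), sum(ph$lumen))
  expect_identical(sum(gx$excluded), 0L)
  # station s of the geodesic method maps to slice z0 + s - 1; compare area
  # ratios allowing a one-station offset
  z0 <- min(sl$station)
  for (s in unique(gg$station)) {
    g_a <- gg$area_ratio[gg$station == s]
    near <- sl$area_ratio[abs(sl$station - (z0 + s - 1)) <= 1]
    expect_lte(min(abs(near - g_a)), 0.03 + 1e-9)
  }
})

test_that("geodesic method excludes detached components and honours trivial seeds", {
  ph <- std_cylinder(radius = 7, length = 30)
  labels <- ph$labels
  d <- dim(labels)
  labels[5:10, 2:5, 2:5] <- 99L      # detached blob
  mucus <- array(FALSE, d)
  gx <- geodesic_cross_sections(labels, mucus)
  expect_false(99L %in% gx$records$branch_id)
  expect_identical(sum(gx$excluded), length(which(labels == 99L)))
  # seed covering the whole mask: one bin per branch containing every voxel
  gx2 <- geodesic_cross_sections(ph$labels, mucus, seed = array(ph$labels > 0L, d))
  expect_identical(unique(gx2$records$station), 1L)
  expect_identical(sum(gx2$records$n_lumen), sum(ph$lumen))
  expect_error(geodesic_cross_sections(ph$labels, mucus, seed = array(FALSE, d)),
               "disjoint")
})

test_that("record invariants hold across methods", {
  ph <- std_two_branch()
  cv <- carve_mucus(ph, thick_deposits())
  sk <- skeletonize(ph$lumen)
  all_recs <- rbind(slice_cross_sections(ph$labels, cv$mucus),
                    skeleton_cross_sections(ph$labels, sk, cv$mucus),
                    geodesic_cross_sections(ph$labels, cv$mucus)$records)
  expect_true(all(all_recs$n_lumen >= 1L))
  expect_true(all(all_recs$n_mucus <= all_recs$n_lumen))
  expect_true(all(all_recs$n_perimeter <= all_recs$n_lumen))
  expect_true(all(all_recs$n_perimeter_mucus <= all_recs$n_perimeter))
})
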