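test_that("empty tree spec builds empty volumes", {
  spec <- tree_spec(data.frame(branch_id = integer(), parent_id = integer(),
                               oz = numeric(), oy = numeric(), ox = numeric(),
                               dz = numeric(), dy = numeric(), dx = numeric(),
                               length_um = numeric(), radius_um = numeric(),
                               generation = integer(), lobe = character()))
  ph <- build_tree_volume(spec, c(10, 10, 10), 1)
  expect_false(any(ph$lumen))
  expect_true(all(ph$labels == 0L))
  expect_equal(nrow(ph$centerline), 0L)
})

test_that("tree spec validation catches broken invariants", {
  base <- data.frame(branch_id = 1L, parent_id = NA_integer_, oz = 5, oy = 10, ox = 10,
                     dz = 1, dy = 0, dx = 0, length_um = 20, radius_um = 4,
                     generation = 1L, lobe = "LL")
  expect_s3_class(tree_spec(base), "tree_spec")
  expect_error(tree_spec(rbind(base, base)), "unique")
  expect_error(tree_spec(transform(base, radius_um = 0)), "positive")
  expect_error(tree_spec(transform(base, lobe = "XX")), "lobe")
  child_off <- rbind(base, data.frame(branch_id = 2L, parent_id = 1L, oz = 10, oy = 14,
                                      ox = 10, dz = 0, dy = 1, dx = 0, length_um = 10,
                                      radius_um = 2, generation = 2L, lobe = "LL"))
  expect_error(tree_spec(child_off), "parent axis")
})

test_that("digitised cylinder matches the digital-disc oracle", {
  ph <- std_cylinder(radius = 10, length = 40)
  oracle <- disc_count(10)
  zs <- 9:47
  counts <- vapply(zs, function(z) sum(ph$lumen[z, , ]), integer(1))
  expect_true(all(counts == oracle))
  # digitised area within 5 % of pi R^2 for R >= 8
  for (r in c(8, 10, 13)) {
    expect_lt(abs(disc_count(r) - pi * r^2) / (pi * r^2), 0.05)
  }
})

test_that("two-branch tree: 2 labels, one 26-connected component (flood-fill oracle)", {
  spec <- phantom_two_branch_spec(7, 36, origin = c(5, 14, 20))
  ph <- build_tree_volume(spec, c(48, 44, 40), 1)
  expect_setequal(setdiff(unique(as.vector(ph$labels)), 0L), c(1L, 2L))
  expect_identical(flood_count_components(ph$lumen), 1L)
})

test_that("branch outside the volume errors with the branch named", {
  spec <- phantom_cylinder_spec(10, 80, origin = c(5, 9, 12))
  expect_error(build_tree_volume(spec, c(90, 24, 24), 1), "branch 1")
})

test_that("plug deposit gives unit ratios on covered stations, zero elsewhere", {
  ph <- std_cylinder(radius = 8, length = 50)
  deps <- deposit_spec(data.frame(branch_id = 1L, span_lo = 0.1, span_hi = 0.2,
                                  kind = "plug"))
  cv <- carve_mucus(ph, deps)
  gt <- cv$ground_truth
  covered <- gt$station >= ceiling(0.1 * 50) + 1 & gt$station <= floor(0.2 * 50)
  expect_true(all(gt$true_area_ratio[covered] == 1))
  expect_true(all(gt$true_contact_ratio[covered] == 1))
  outside <- gt$station > 0.25 * 50
  expect_true(all(gt$true_area_ratio[outside] == 0))
  expect_true(all(gt$true_contact_ratio[outside] == 0))
  expect_false(any(cv$mucus & !ph$lumen))  # mucus subset of lumen
})

test_that("180-degree crescent: contact ratio 0.5 within voxelisation tolerance", {
  ph <- std_cylinder(radius = 12, length = 40)
  deps <- deposit_spec(data.frame(branch_id = 1L, span_lo = 0, span_hi = 1,
                                  kind = "crescent", angular_coverage = 180,
                                  thickness_vox = 3))
  cv <- carve_mucus(ph, deps)
  mid <- cv$ground_truth[cv$ground_truth$station %in% 10:30, ]
  expect_true(all(abs(mid$true_contact_ratio - 0.5) <= 0.06))
  # brute-force oracle on one station: classify perimeter voxels by polar angle
  z <- 8 + 20  # station 21
  sl <- ph$lumen[z, , ]
  ctr <- (dim(sl) + 1) / 2
  idx <- which(sl, arr.ind = TRUE)
  is_per <- vapply(seq_len(nrow(idx)), function(i) {
    y <- idx[i, 1]; x <- idx[i, 2]
    !(sl[y - 1, x] && sl[y + 1, x] && sl[y, x - 1] && sl[y, x + 1])
  }, logical(1))
  ang <- atan2(idx[is_per, 2] - ctr[2], idx[is_per, 1] - ctr[1])
  # crescent window is half the circle about the deterministic basis; the
  # oracle checks only the fraction, not the orientation
  muc_sl <- cv$mucus[z, , ]
  on_per_muc <- vapply(which(is_per), function(i) muc_sl[idx[i, 1], idx[i, 2]], logical(1))
  expect_equal(mean(on_per_muc), 0.5, tolerance = 0.12)
})

test_that("empty deposit spec yields zero ratios; unknown branch errors", {
  ph <- std_cylinder(radius = 8, length = 30)
  cv <- carve_mucus(ph, deposit_spec(data.frame(branch_id = integer(), span_lo = numeric(),
                                                span_hi = numeric(), kind = character())))
  expect_true(all(cv$ground_truth$true_area_ratio == 0))
  expect_true(all(cv$ground_truth$true_contact_ratio == 0))
  expect_error(carve_mucus(ph, deposit_spec(data.frame(branch_id = 9L, span_lo = 0,
                                                       span_hi = 1, kind = "plug"))),
               "unknown branch")
})

test_that("programmable fill and coverage reproduce target ratios (wedge and wedge+core)", {
  ph <- std_cylinder(radius = 14, length = 40)
  for (tc in list(c(a = 0.25, c = 0.5), c(a = 0.6, c = 0.25))) {
    deps <- deposit_spec(data.frame(branch_id = 1L, span_lo = 0, span_hi = 1,
                                    kind = "crescent", fill_fraction = tc[["a"]],
                                    angular_coverage = 360 * tc[["c"]]))
    cv <- carve_mucus(ph, deps)
    mid <- cv$ground_truth[cv$ground_truth$station %in% 10:30, ]
    expect_equal(mean(mid$true_area_ratio), tc[["a"]], tolerance = 0.05)
    expect_equal(mean(mid$true_contact_ratio), tc[["c"]], tolerance = 0.07)
  }
  expect_error(deposit_spec(data.frame(branch_id = 1L, span_lo = 0, span_hi = 1,
                                       kind = "crescent", fill_fraction = 1,
                                       angular_coverage = 180)),
               "full occlusion")
})

test_that("render_intensity: levels, determinism, subset contract, noise means", {
  ph <- std_cylinder(radius = 12, length = 70)
  deps <- deposit_spec(data.frame(branch_id = 1L, span_lo = 0.2, span_hi = 0.8,
                                  kind = "plug"))
  cv <- carve_mucus(ph, deps)
  v0 <- render_intensity(ph$lumen, cv$mucus, noise_sd = 0)
  expect_setequal(unique(as.vector(unclass(v0))), c(0.10, 0.60, 0.85))
  v1 <- render_intensity(ph$lumen, cv$mucus, noise_sd = 0.05, seed = 42)
  v2 <- render_intensity(ph$lumen, cv$mucus, noise_sd = 0.05, seed = 42)
  expect_identical(unclass(v1), unclass(v2))
  air <- ph$lumen & !cv$mucus
  expect_gt(sum(air), 1e4)
  expect_lt(abs(mean(unclass(v1)[air]) - 0.10), 0.01)
  expect_gt(sum(cv$mucus), 1e4)
  expect_lt(abs(mean(unclass(v1)[cv$mucus]) - 0.60), 0.01)
  tissue <- !ph$lumen
  expect_lt(abs(mean(unclass(v1)[tissue]) - 0.85), 0.01)
  bad <- array(TRUE, dim(ph$lumen))
  expect_error(render_intensity(ph$lumen, bad, 0), "subset")
})

test_that("cohort generator: noiseless line recovered exactly, contracts enforced", {
  tab <- generate_cohort_ratio_table(20, slope = 2.5, intercept = -1, noise_sd = 0,
                                     x_range = c(5, 50), seed = 3)
  fit <- simple_linreg(tab$mean_area_ratio, tab$mean_contact_ratio)
  expect_equal(fit$slope, 2.5, tolerance = 1e-12)
  expect_equal(fit$intercept, -1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(generate_cohort_ratio_table(1), "n_samples")
  expect_error(generate_cohort_ratio_table(5, noise_sd = -1), "noise_sd")
  expect_identical(generate_cohort_ratio_table(5, seed = 7),
                   generate_cohort_ratio_table(5, seed = 7))
})

test_that("score table generator: degenerate triples and determinism", {
  cat_dt <- default_catalog()
  gp_all0 <- data.frame(genotype = "wt", age_group = "adult", generation = 1:11,
                        p0 = 1, p1 = 0, p2 = 0)
  t0 <- generate_score_table(cat_dt, gp_all0, n_animals = 2, seed = 1)
  expect_true(all(t0$score == 0L))
  expect_true(all(aggregate_scores(t0, "whole")$mean_score == 0))
  gp_all2 <- transform(gp_all0, p0 = 0, p2 = 1)
  t2 <- generate_score_table(cat_dt, gp_all2, n_animals = 2, seed = 1)
  expect_true(all(aggregate_scores(t2, "whole")$mean_score == 2))
  gp_mix <- transform(gp_all0, p0 = 0.5, p1 = 0.3, p2 = 0.2)
  expect_identical(generate_score_table(cat_dt, gp_mix, 3, seed = 9),
                   generate_score_table(cat_dt, gp_mix, 3, seed = 9))
  expect_error(generate_score_table(cat_dt, transform(gp_all0, p0 = 0.9), 1, 1),
               "sum to 1")
})
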