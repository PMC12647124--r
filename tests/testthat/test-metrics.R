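fake_rec <- function(n_lumen, n_mucus, n_per, n_per_muc, station = 1L,
                     method = "slice", branch = 1L) {
  data.table::data.table(method = method, branch_id = branch, station = station,
                         n_lumen = n_lumen, n_perimeter = n_per, n_mucus = n_mucus,
                         n_perimeter_mucus = n_per_muc, planar = TRUE,
                         voxels = list(integer()))
}

test_that("ratio arithmetic and degenerate contracts", {
  expect_equal(area_ratio(fake_rec(148L, 37L, 40L, 10L)), 0.25)
  expect_equal(area_ratio(fake_rec(100L, 100L, 30L, 30L)), 1)   # full plug
  expect_equal(area_ratio(fake_rec(100L, 0L, 30L, 0L)), 0)
  expect_equal(contact_ratio(fake_rec(100L, 40L, 30L, 30L)), 1) # full annulus
  expect_equal(contact_ratio(fake_rec(100L, 0L, 30L, 0L)), 0)
  expect_error(area_ratio(fake_rec(0L, 0L, 0L, 0L)), "empty lumen")
  expect_error(contact_ratio(fake_rec(10L, 0L, 0L, 0L)), "empty perimeter")
})

test_that("ratios agree with a brute-force voxel-counting oracle on phantoms", {
  ph <- std_cylinder(radius = 9, length = 30)
  cv <- carve_mucus(ph, deposit_spec(data.frame(branch_id = 1L, span_lo = 0.2,
                                                span_hi = 0.8, kind = "crescent",
                                                fill_fraction = 0.35,
                                                angular_coverage = 200)))
  cs <- slice_cross_sections(ph$labels, cv$mucus)
  r <- compute_ratios(cs)
  d <- dim(ph$lumen)
  for (i in sample.int(nrow(r), 6)) {
    z <- r$station[i]
    lum <- ph$lumen[z, , ]
    muc <- cv$mucus[z, , ]
    # oracle: count voxels directly; perimeter via 6-neighbourhood in 3-D
    n_lum <- sum(lum)
    per <- matrix(FALSE, d[2], d[3])
    for (y in 2:(d[2] - 1)) for (x in 2:(d[3] - 1)) if (lum[y, x]) {
      per[y, x] <- !(lum[y - 1, x] && lum[y + 1, x] && lum[y, x - 1] && lum[y, x + 1] &&
                       ph$lumen[z - 1, y, x] && ph$lumen[z + 1, y, x])
    }
    expect_equal(r$area_ratio[i], sum(muc) / n_lum)
    expect_equal(r$contact_ratio[i], sum(per & muc) / sum(per))
  }
})

test_that("monotonicity: adding mucus never decreases either ratio", {
  base <- fake_rec(200L, 40L, 60L, 10L)
  for (k in 1:20) {
    more <- fake_rec(200L, 40L + k, 60L, min(60L, 10L + k))
    expect_gte(area_ratio(more), area_ratio(base))
    expect_gte(contact_ratio(more), contact_ratio(base))
  }
})

test_that("branch profile: plug in the middle third, ordering and gaps", {
  ph <- std_cylinder(radius = 8, length = 45, margin = 6)
  cv <- carve_mucus(ph, deposit_spec(data.frame(branch_id = 1L, span_lo = 1 / 3,
                                                span_hi = 2 / 3, kind = "plug")))
  r <- compute_ratios(slice_cross_sections(ph$labels, cv$mucus))
  prof <- branch_profile(r)
  thirds <- cut(seq_len(nrow(prof)), 3, labels = FALSE)
  expect_lt(mean(prof$area_ratio[thirds == 1]), 0.1)
  expect_gt(mean(prof$area_ratio[thirds == 2]), 0.85)
  expect_lt(mean(prof$area_ratio[thirds == 3]), 0.1)
  # shuffled input comes back sorted; missing stations appear as NA
  shuffled <- r[sample.int(nrow(r)), ]
  gap <- shuffled[shuffled$station != min(shuffled$station) + 3, ]
  p2 <- branch_profile(gap)
  expect_true(!is.unsorted(p2$station))
  expect_true(is.na(p2$area_ratio[p2$station == min(shuffled$station) + 3]))
  expect_identical(nrow(branch_profile(compute_ratios(
    slice_cross_sections(array(0L, c(3, 3, 3)), array(FALSE, c(3, 3, 3)))))), 0L)
  expect_error(branch_profile(rbind(r, transform(r, method = "geodesic"))),
               "single method")
})

test_that("sample summaries average records and report percent", {
  r <- compute_ratios(rbind(fake_rec(100L, 10L, 40L, 4L, station = 1L),
                            fake_rec(100L, 30L, 40L, 12L, station = 2L)))
  s <- sample_summary(r, "demo")
  expect_equal(s$mean_area_ratio, 20)
  expect_equal(s$mean_contact_ratio, 20)
  expect_identical(s$n_cross_sections, 2L)
  zero <- compute_ratios(fake_rec(50L, 0L, 20L, 0L))
  s0 <- sample_summary(zero, "z")
  expect_equal(c(s0$mean_area_ratio, s0$mean_contact_ratio), c(0, 0))
  expect_error(sample_summary(r[0, ], "x"), "zero")
})

test_that("summary recovery of a programmed uniform deposit", {
  ph <- std_cylinder(radius = 10, length = 40)
  cv <- carve_mucus(ph, deposit_spec(data.frame(branch_id = 1L, span_lo = 0,
                                                span_hi = 1, kind = "crescent",
                                                fill_fraction = 0.25,
                                                angular_coverage = 360)))
  # skeleton-method estimate vs exact voxel-counted ground truth
  sk <- skeletonize(ph$lumen)
  r <- compute_ratios(skeleton_cross_sections(ph$labels, sk, cv$mucus))
  s <- sample_summary(r, "u")
  truth <- 100 * mean(cv$ground_truth$true_area_ratio)
  expect_lt(abs(s$mean_area_ratio - truth), 3)
})

test_that("correlate_summaries: exact recovery, errors, anticorrelation", {
  tab <- generate_cohort_ratio_table(8, slope = 3.204, intercept = 7.243,
                                     noise_sd = 0, seed = 2)
  s <- data.table::data.table(sample_id = tab$sample_id, method = "slice",
                              mean_area_ratio = tab$mean_area_ratio,
                              mean_contact_ratio = tab$mean_contact_ratio,
                              n_cross_sections = 1L)
  cc <- correlate_summaries(s)
  expect_equal(cc$slope, 3.204, tolerance = 1e-10)
  expect_equal(cc$intercept, 7.243, tolerance = 1e-9)
  expect_equal(cc$r_squared, 1, tolerance = 1e-12)
  anti <- data.table::data.table(sample_id = c("a", "b", "c"), method = "slice",
                                 mean_area_ratio = c(0, 5, 10),
                                 mean_contact_ratio = c(10, 5, 0),
                                 n_cross_sections = 1L)
  expect_equal(correlate_summaries(anti)$r, -1)
  const <- data.table::copy(anti)[, mean_area_ratio := 5]
  expect_error(correlate_summaries(const), "constant")
  expect_error(correlate_summaries(s[1:2, ]), ">= 3")
})
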