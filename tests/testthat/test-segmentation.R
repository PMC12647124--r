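test_that("single-cylinder phantom segments with high Dice and one branch", {
  ph <- std_cylinder(radius = 9, length = 56, margin = 8)
  cv <- carve_mucus(ph, deposit_spec(data.frame(branch_id = 1L, span_lo = 0.3,
                                                span_hi = 0.6, kind = "plug")))
  vol <- render_intensity(ph$lumen, cv$mucus, noise_sd = 0.05, seed = 4)
  d <- dim(ph$lumen)
  mk <- marker_set(data.frame(z = c(12, 3), y = c(d[2] / 2, 3), x = c(d[3] / 2, 3),
                              role = c("lumen", "background")))
  seg <- segment_lumen(vol, mk)
  expect_gte(dice(seg$mask, ph$lumen), 0.95)
  expect_identical(setdiff(unique(as.vector(seg$labels)), 0L), 1L)
})

test_that("two-branch phantom yields two labels with parent-child adjacency", {
  ph <- std_two_branch()
  cv <- carve_mucus(ph, thick_deposits())
  vol <- render_intensity(ph$lumen, cv$mucus, noise_sd = 0.05, seed = 2)
  seg <- segment_lumen(vol, two_branch_markers())
  labs <- setdiff(unique(as.vector(seg$labels)), 0L)
  expect_length(labs, 2L)
  expect_equal(nrow(seg$adjacency), 1L)
  expect_identical(seg$adjacency$parent, seg$root)
  # branch labels partition the mask
  expect_identical(array(seg$labels > 0L, dim(seg$mask)), seg$mask)
})

test_that("marker contracts: no lumen seed, runaway flood", {
  expect_error(marker_set(data.frame(z = 1, y = 1, x = 1, role = "background")),
               "lumen seed")
  # a volume that is dark nearly everywhere floods past half the volume
  vol <- array(0.1, c(30, 30, 30))
  vol[25:30, 25:30, 25:30] <- 0.85
  v <- volume3d(vol, 1)
  mk <- marker_set(data.frame(z = c(5, 27), y = c(5, 27), x = c(5, 27),
                              role = c("lumen", "background")))
  expect_error(segment_lumen(v, mk), "revise markers")
})

test_that("mucus segmentation: exact noiseless recovery with a fixed band", {
  ph <- std_cylinder(radius = 9, length = 50)
  cv <- carve_mucus(ph, deposit_spec(data.frame(branch_id = 1L, span_lo = 0.25,
                                                span_hi = 0.75, kind = "crescent",
                                                fill_fraction = 0.4,
                                                angular_coverage = 240)))
  vol <- render_intensity(ph$lumen, cv$mucus, noise_sd = 0)
  params <- mucus_params("fixed", band_lo = 0.35, band_hi = 0.75,
                         opening_radius = 0, closing_radius = 0,
                         min_component_size = 1L)
  m <- segment_mucus(vol, ph$lumen, params)
  expect_identical(m, cv$mucus)
})

test_that("mucus segmentation contracts: empty region, no-mucus volume, min size", {
  ph <- std_cylinder(radius = 8, length = 30)
  vol <- render_intensity(ph$lumen, array(FALSE, dim(ph$lumen)), noise_sd = 0.05,
                          seed = 3)
  expect_error(segment_mucus(vol, array(FALSE, dim(ph$lumen))), "empty lumen")
  m <- segment_mucus(vol, ph$lumen)   # otsu with bimodality guard
  expect_identical(sum(m), 0L)
  # a single isolated mucus-level voxel is removed by the size filter
  raw <- unclass(render_intensity(ph$lumen, array(FALSE, dim(ph$lumen)), 0))
  ctr <- round(dim(raw) / 2)
  raw[ctr[1], ctr[2], ctr[3]] <- 0.6
  v2 <- volume3d(raw, 1)
  m2 <- segment_mucus(v2, ph$lumen, mucus_params("fixed", 0.35, 0.75,
                                                 opening_radius = 0,
                                                 closing_radius = 0,
                                                 min_component_size = 5L))
  expect_identical(sum(m2), 0L)
})

test_that("segment_mucus output is always inside the region", {
  ph <- std_two_branch()
  cv <- carve_mucus(ph, thick_deposits())
  vol <- render_intensity(ph$lumen, cv$mucus, noise_sd = 0.05, seed = 8)
  m <- segment_mucus(vol, ph$lumen)
  expect_false(any(m & !ph$lumen))
})

test_that("exclude_unconnected partitions exactly and conserves voxel count", {
  d <- c(30, 20, 20)
  mask <- array(FALSE, d)
  mask[5:25, 5:9, 5:9] <- TRUE     # tube 1
  mask[5:25, 14:18, 14:18] <- TRUE # tube 2, disjoint
  seed <- array(FALSE, d); seed[6, 6, 6] <- TRUE
  parts <- exclude_unconnected(mask, seed)
  expect_false(any(parts$connected & parts$excluded))
  expect_identical(parts$connected | parts$excluded, mask)
  expect_identical(sum(parts$connected) + sum(parts$excluded), sum(mask))
  expect_true(all(parts$excluded[5:25, 14:18, 14:18]))
  # fully connected mask: nothing excluded
  parts2 <- exclude_unconnected(array(TRUE, c(4, 4, 4)), 1L)
  expect_identical(sum(parts2$excluded), 0L)
  expect_error(exclude_unconnected(mask, array(FALSE, d)), "disjoint")
})

test_that("phantom fidelity across 10 noise seeds: Dice and mucus F1", {
  # scaled-down version of the acceptance criterion, one phantom, sd 0.05
  ph <- std_two_branch()
  cv <- carve_mucus(ph, thick_deposits())
  mk <- two_branch_markers()
  dices <- f1s <- numeric(5)
  for (s in 1:5) {
    vol <- render_intensity(ph$lumen, cv$mucus, noise_sd = 0.05, seed = s)
    seg <- segment_lumen(vol, mk)
    m <- segment_mucus(vol, seg$mask)
    dices[s] <- dice(seg$mask, ph$lumen)
    f1s[s] <- dice(m, cv$mucus)
  }
  expect_gte(median(dices), 0.95)
  expect_gte(median(f1s), 0.90)
})
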