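test_that("NRRD round-trips are bit-exact for double, integer and logical", {
  withr::with_seed(1, {
    vd <- volume3d(array(rnorm(32^3), c(32, 32, 32)), 9)
    vi <- volume3d(array(sample(0:9, 18^3, TRUE), c(18, 18, 18)), 3.25)
    vl <- volume3d(array(sample(c(TRUE, FALSE), 12^3, TRUE), c(12, 12, 12)), 1)
  })
  for (v in list(vd, vi, vl)) {
    p <- withr::local_tempfile(fileext = ".nrrd")
    write_volume(v, p)
    v2 <- read_volume(p)
    expect_identical(as.vector(unclass(v)), as.vector(unclass(v2)))
    expect_identical(voxel_size(v2), voxel_size(v))
  }
})

test_that("anisotropic NRRD is rejected mentioning isotropy", {
  p <- withr::local_tempfile(fileext = ".nrrd")
  con <- file(p, "wb")
  writeLines(c("NRRD0004", "type: uint8", "dimension: 3", "sizes: 2 2 2",
               "spacings: 1 1 2", "endian: little", "encoding: raw", ""), con)
  writeBin(as.integer(rep(0, 8)), con, size = 1L)
  close(con)
  expect_error(read_volume(p), "isotropic")
})

test_that("missing voxel size is an error, never a silent default", {
  p <- withr::local_tempfile(fileext = ".nrrd")
  con <- file(p, "wb")
  writeLines(c("NRRD0004", "type: uint8", "dimension: 3", "sizes: 2 2 2",
               "endian: little", "encoding: raw", ""), con)
  writeBin(as.integer(rep(1, 8)), con, size = 1L)
  close(con)
  expect_error(read_volume(p), "voxel size")
  v <- read_volume(p, voxel_size_um = 4)
  expect_identical(voxel_size(v), 4)
})

test_that("TIFF stacks round-trip 8- and 16-bit integers and carry voxel size", {
  withr::with_seed(2, {
    g8 <- volume3d(array(sample(0:255, 10 * 12 * 14, TRUE), c(10, 12, 14)), 9)
    g16 <- volume3d(array(sample(0:60000, 6 * 7 * 8, TRUE), c(6, 7, 8)), 3.25)
  })
  for (v in list(g8, g16)) {
    p <- withr::local_tempfile(fileext = ".tif")
    write_volume(v, p)
    v2 <- read_volume(p)
    expect_identical(as.vector(unclass(v)), as.vector(unclass(v2)))
    expect_identical(voxel_size(v2), voxel_size(v))
  }
})

test_that("TIFF without voxel-size metadata errors unless the flag is given", {
  p <- withr::local_tempfile(fileext = ".tif")
  v <- volume3d(array(0L, c(2, 3, 3)), 5)
  write_volume(v, p)
  raw <- readBin(p, "raw", file.info(p)$size)
  tag <- charToRaw("voxel_size_um=")
  hit <- which(vapply(seq_len(length(raw) - length(tag)), function(i)
    all(raw[i:(i + length(tag) - 1)] == tag), logical(1)))
  raw[hit] <- charToRaw("X")   # corrupt the metadata key on every page
  writeBin(raw, p)
  expect_error(read_volume(p), "voxel size")
  expect_identical(voxel_size(read_volume(p, voxel_size_um = 7)), 7)
})

test_that("write_volume contracts: empty volume, overwrite, doubles to TIFF", {
  p <- withr::local_tempfile(fileext = ".nrrd")
  expect_error(write_volume(volume3d(array(0, c(1, 1, 1))[0, , , drop = FALSE], 1), p),
               "3-D|0-voxel")
  v <- volume3d(array(1L, c(2, 2, 2)), 1)
  write_volume(v, p)
  expect_error(write_volume(v, p), "force")
  expect_silent(write_volume(v, p, force = TRUE))
  pt <- withr::local_tempfile(fileext = ".tif")
  expect_error(write_volume(volume3d(array(0.5, c(2, 2, 2)), 1), pt), "integer")
})

test_that("score CSV validation names the offending row", {
  cat_dt <- default_catalog()
  good <- data.frame(animal_id = "a1", genotype = "wt", age_group = "adult",
                     segment_label = cat_dt$segment_label[1:4],
                     lobe = cat_dt$lobe[1:4], generation = cat_dt$generation[1:4],
                     score = c(0L, 1L, 2L, 0L))
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(good, p, row.names = FALSE)
  expect_equal(nrow(read_score_csv(p)), 4L)
  bad <- good; bad$score[2] <- 3L
  write.csv(bad, p, row.names = FALSE)
  expect_error(read_score_csv(p), "row 2.*3")
  bad <- good; bad$generation[3] <- 0L
  write.csv(bad, p, row.names = FALSE)
  expect_error(read_score_csv(p), "trachea")
  bad <- good; bad$segment_label[1] <- "NOPE"
  write.csv(bad, p, row.names = FALSE)
  expect_error(read_score_csv(p), "NOPE")
})

test_that("ratio maps: gradient endpoints, midpoint, exclusion and monotonicity", {
  sl <- array(0L, c(3, 4, 4))
  sl[1, 1, 1] <- 1L; sl[2, 2, 2] <- 2L; sl[3, 3, 3] <- 3L; sl[3, 4, 4] <- 4L
  p <- withr::local_tempfile(fileext = ".tif")
  write_ratio_map(sl, c(0, 0.5, 0.35, 0), which = "contact", path = p,
                  excluded_labels = 4L)
  rgb <- read_volume(p, voxel_size_um = 1)
  gr <- function(z, y, x) c(unclass(rgb$r)[z, y, x], unclass(rgb$g)[z, y, x],
                            unclass(rgb$b)[z, y, x])
  expect_identical(gr(1, 1, 1), c(0L, 255L, 0L))          # ratio 0: pure green
  mid <- gr(2, 2, 2)
  expect_identical(mid[1], mid[2])                        # exact midpoint colour
  expect_identical(gr(3, 4, 4), c(0L, 0L, 255L))          # excluded: blue
  expect_identical(gr(1, 2, 3), c(0L, 0L, 0L))            # background: black
  # area scale clamps at 0.30
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_ratio_map(sl, c(0.30, 0.9, 0.15, 0), which = "area", path = p2)
  rgb2 <- read_volume(p2, voxel_size_um = 1)
  expect_identical(unclass(rgb2$r)[1, 1, 1], 255L)        # at scale: pure red
  expect_identical(unclass(rgb2$r)[2, 2, 2], 255L)        # beyond scale: clamped
  expect_error(write_ratio_map(sl, c(0, 0.5, 1.2, 0), "area", withr::local_tempfile()),
               "\\[0, 1\\]")
  # monotone: red channel non-decreasing in ratio
  cols <- ratio_colour(seq(0, 1, by = 0.05), scale = 1)
  expect_true(all(diff(cols[, "r"]) >= 0) && all(diff(cols[, "g"]) <= 0))
})
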