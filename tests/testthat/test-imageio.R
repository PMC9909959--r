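test_that("NIfTI volume round-trip is lossless for integer HU", {
  withr::local_seed(201)
  vol <- ct_volume(array(sample(-1024:2000, 8 * 7 * 6, TRUE), c(8, 7, 6)),
                   spacing_mm = c(0.625, 0.625, 1.25))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_identical(back$data, vol$data)
  expect_equal(back$spacing_mm, vol$spacing_mm, tolerance = 1e-6)
})

test_that("mask round-trip preserves geometry", {
  m <- array(FALSE, c(6, 6, 4)); m[2:4, 2:4, 2:3] <- TRUE
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(m, path, spacing_mm = c(1, 1, 1))
  expect_identical(read_mask(path), m)
})

test_that("ct_volume validates dimensionality and the HU floor", {
  expect_error(ct_volume(matrix(0, 3, 3), c(1, 1, 1)), "3D")
  expect_error(ct_volume(array(-2000, c(3, 3, 3)), c(1, 1, 1)), "-1024")
  expect_error(ct_volume(array(0, c(3, 3, 3)), c(0, 1, 1)))
})

test_that("a DICOM series rescales stored values to HU", {
  withr::local_seed(202)
  dir <- withr::local_tempdir()
  hu <- array(sample(-1000:1500, 5 * 4 * 3, TRUE), c(5, 4, 3))
  write_dicom_series(dir, hu, slice_pitch = 0.625, pixel_spacing = c(0.7, 0.5),
                     slope = 1, intercept = -1024)
  vol <- read_volume(dir)
  expect_identical(vol$data, array(as.integer(hu), dim(hu)))
  # stored value 1424 with slope 1, intercept -1024 reads back as 400 HU
  hu2 <- array(400L, c(4, 4, 2))
  dir2 <- withr::local_tempdir()
  write_dicom_series(dir2, hu2, slope = 1, intercept = -1024)
  expect_true(all(read_volume(dir2)$data == 400L))
})

test_that("DICOM slice pitch becomes the z spacing", {
  dir <- withr::local_tempdir()
  write_dicom_series(dir, array(100L, c(4, 4, 3)), slice_pitch = 0.625,
                     pixel_spacing = c(0.7, 0.5))
  vol <- read_volume(dir)
  expect_equal(vol$spacing_mm, c(0.5, 0.7, 0.625))  # (x, y, z)
})

test_that("defective DICOM series are rejected with a named defect", {
  dir <- withr::local_tempdir()
  write_dicom_series(dir, array(0L, c(4, 4, 2)), uid = "1.1")
  write_dicom_slice(file.path(dir, "zz_other.dcm"), matrix(0L, 4, 4), z = 9,
                    uid = "2.2")
  expect_error(read_volume(dir), "mixed DICOM series")
  one <- withr::local_tempdir()
  write_dicom_slice(file.path(one, "s1.dcm"), matrix(0L, 4, 4), z = 0)
  expect_error(read_volume(one), "2D")
})

test_that("%BTV profiles are written with the twelve printed row labels", {
  lab <- array(c(rep(1L, 30), rep(12L, 10)), c(40, 1, 1))
  prof <- btv_profile(lab, c(1, 1, 1), bone = "tibial_plateau", side = "left")
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  df <- read.csv(path)
  expect_identical(nrow(df), 12L)
  expect_identical(df$density_hu[1], "100-200")
  expect_identical(df$density_hu[12], "1201-maximum")
  expect_equal(df$pct_btv[1], 75)
})

test_that("an empty frequency table writes a header-only CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(data.frame(region = integer(), count = integer()), path)
  lines <- readLines(path)
  expect_length(lines, 1)
  expect_match(lines, "region")
})

test_that("density maps round-trip through CSV", {
  withr::local_seed(203)
  map <- make_test_map(9, 7, base = 500, spacing = c(0.625, 0.625))
  map$values[2, 3] <- 1234
  map$footprint[5, 5] <- FALSE; map$values[5, 5] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_map_csv(map, path)
  back <- read_map_csv(path, pixel_spacing_mm = c(0.625, 0.625))
  expect_equal(back$values, map$values, tolerance = 1e-6)
  expect_identical(back$footprint, map$footprint)
})

test_that("pseudo-colour PNG export writes a readable image", {
  map <- add_disc(make_test_map(12, 12), 6, 6, 3, 950)
  path <- withr::local_tempfile(fileext = ".png")
  write_map_png(map, path)
  img <- png::readPNG(path)
  expect_identical(dim(img)[1:2], c(12L, 12L))
  expect_gt(max(img), 0)
})

test_that("2D NIfTI input is rejected", {
  path <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(matrix(0L, 5, 5))
  RNifti::writeNifti(img, path)
  expect_error(read_volume(path), "3D")
})
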