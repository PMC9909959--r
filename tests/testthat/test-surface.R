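test_that("projection reproduces a single-voxel-thick shell and column maxima", {
  # depth-1 shell: the map equals the shell values
  d <- array(-1024L, c(6, 6, 4))
  shell <- matrix(sample(100:900, 36, replace = TRUE), 6, 6)
  d[, , 2] <- shell
  vol <- ct_volume(d, c(1, 1, 1))
  m <- array(FALSE, dim(d)); m[, , 2] <- TRUE
  map <- project_density(vol, m)
  expect_equal(map$values, shell + 0)
  # column with HU {300, 950, 420} projects to 950
  d2 <- array(-1024L, c(1, 1, 3))
  d2[1, 1, ] <- c(300L, 950L, 420L)
  map2 <- project_density(ct_volume(d2, c(1, 1, 1)), array(TRUE, c(1, 1, 3)))
  expect_equal(map2$values[1, 1], 950)
})

test_that("projection matches a per-column brute-force maximum oracle", {
  withr::local_seed(11)
  for (rep in 1:5) {
    dims <- sample(5:10, 3, replace = TRUE)
    vol <- random_volume(dims, lo = 100, hi = 1500)
    mask <- random_mask3d(dims, 0.5)
    if (!any(mask)) next
    map <- project_density(vol, mask)
    expect_equal(map$values, oracle_project(vol, mask))
  }
})

test_that("projection is monotone: raising a ROI voxel never lowers the map", {
  withr::local_seed(12)
  dims <- c(8, 8, 6)
  vol <- random_volume(dims, lo = 100, hi = 1000)
  mask <- random_mask3d(dims, 0.6)
  m1 <- project_density(vol, mask)$values
  idx <- which(mask)[sample(sum(mask), 10)]
  v2 <- vol$data; v2[idx] <- v2[idx] + 500L
  m2 <- project_density(ct_volume(v2, vol$spacing_mm), mask)$values
  expect_true(all(m2 >= m1, na.rm = TRUE))
})

test_that("nine regions partition a square footprint into equal thirds", {
  map <- make_test_map(30, 30)
  rg <- nine_regions(map)
  counts <- table(rg$region_of_pixel)
  expect_length(counts, 9)
  expect_true(all(counts == 100))
  # every footprint pixel has exactly one region (pixel-count conservation)
  expect_identical(sum(!is.na(rg$region_of_pixel)), sum(map$footprint))
  # the footprint centroid is in the central region 5
  expect_identical(rg$region_of_pixel[15, 15], 5L)
})

test_that("region numbering mirrors anatomically between left and right", {
  withr::local_seed(13)
  map <- make_test_map(17, 23)  # widths not divisible by 3
  rg_r <- nine_regions(map)
  # mirroring the image while keeping the side swaps columns 1<->3
  rg_m <- nine_regions(mirror_map(map, flip_side = FALSE))
  mirrored <- rg_r$region_of_pixel[rev(seq_len(17)), ]
  swap <- c(3L, 2L, 1L, 6L, 5L, 4L, 9L, 8L, 7L)
  expect_identical(rg_m$region_of_pixel, array(swap[mirrored], dim(mirrored)))
  # mirroring image *and* side flag keeps anatomical labels at mirrored pixels
  rg_lr <- nine_regions(mirror_map(map, flip_side = TRUE))
  expect_identical(rg_lr$region_of_pixel, mirrored)
})

test_that("degenerate footprints are rejected", {
  expect_error(nine_regions(make_test_map(2, 30)), "degenerate")
  m <- density_map(matrix(NA_real_, 5, 5), matrix(FALSE, 5, 5), c(1, 1),
                   "distal_femur", "right")
  expect_error(nine_regions(m), "degenerate")
})

test_that("high-density detection finds discs with area and regions", {
  map <- make_test_map(30, 30)
  expect_length(detect_high_density(map)$components, 0)  # nothing >= 901
  # one disc inside the medial central cell (region 4): x band 1, central row
  map2 <- add_disc(map, cx = 5, cy = 15, r = 4, value = 950)
  areas <- detect_high_density(map2)
  expect_length(areas$components, 1)
  expect_identical(areas$components[[1]]$regions, 4L)
  expect_equal(areas$components[[1]]$area_mm2, sum((outer((1:30) - 5, (1:30) - 15,
    function(a, b) a^2 + b^2) <= 16) & TRUE))
  # an undersized disc is filtered by min_area_mm2
  map3 <- add_disc(map, cx = 15, cy = 15, r = 2, value = 950)
  expect_length(detect_high_density(map3, min_area_mm2 = 25)$components, 0)
  expect_length(detect_high_density(map3, min_area_mm2 = 5)$components, 1)
})

test_that("component labelling matches an independent two-pass oracle", {
  withr::local_seed(14)
  for (rep in 1:6) {
    nx <- sample(12:20, 1); ny <- sample(12:20, 1)
    map <- make_test_map(nx, ny)
    vals <- matrix(sample(c(300, 950), nx * ny, TRUE, prob = c(0.8, 0.2)), nx, ny)
    map$values <- vals
    areas <- detect_high_density(map, min_area_mm2 = 0.5)
    oc <- oracle_cc2d(vals >= 901)
    expect_identical(length(areas$components), length(oc))
    expect_setequal(vapply(areas$components, function(cp) nrow(cp$pixels), 0),
                    vapply(oc, nrow, 0))
  }
})

test_that("region frequencies reproduce the printed count-to-percent pairs", {
  expect_identical(percent_integer(24, 30), 80L)
  expect_identical(percent_integer(28, 30), 93L)
  cohort <- c(
    replicate(24, stub_areas(list(4L)), simplify = FALSE),
    replicate(4, stub_areas(list(c(5L, 6L))), simplify = FALSE),
    replicate(2, stub_areas(list()), simplify = FALSE)
  )
  freq <- region_frequency(cohort, 30)
  expect_identical(freq$count, c(0L, 0L, 0L, 24L, 4L, 4L, 0L, 0L, 0L))
  expect_identical(freq$percent[4], 80L)
  expect_identical(freq$percent[5], 13L)
  # a knee with several components touching one region is counted once
  one <- region_frequency(list(stub_areas(list(1L, c(1L, 2L)))), 1)
  expect_identical(one$count[1], 1L)
  expect_identical(region_frequency(list(stub_areas(list())), 1)$percent,
                   rep(0L, 9))
})
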