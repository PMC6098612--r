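test_that("section indices are evenly spaced inside the 5% exclusion band", {
  vol <- binary_volume(solid_array(c(100, 20, 20)), 1)
  vol[, 5:15, 5:15] <- FALSE
  secs <- extract_sections(binary_volume(unclass(vol), 1), n_sections = 5)
  idx0 <- vapply(secs, `[[`, 1L, "index") - 1L   # 0-based within full-depth VOI
  expect_true(all(idx0 >= 5 & idx0 <= 94))
  expect_equal(idx0, round(seq(5, 94, length.out = 5)))
  one <- extract_sections(binary_volume(unclass(vol), 1), n_sections = 1)
  expect_equal(one[[1]]$index - 1L, round((5 + 94) / 2))
  expect_error(extract_sections(binary_volume(unclass(vol), 1),
                                n_sections = 200), "thinner")
})

test_that("sphere sections follow the chord relation", {
  ph <- sphere_phantom(diameter = 30, grid = 48)
  secs <- extract_sections(ph$volume, n_sections = 5)
  for (sec in secs) {
    z <- sec$index - 24   # offset from the sphere center plane
    if (abs(z) >= 14) next
    chord <- 2 * sqrt(15^2 - z^2)
    prs <- label_pores_2d(sec, "keep")
    expect_equal(length(prs$regions), 1)
    aecd <- area_equivalent_circle_diameter(prs$regions[[1]])
    expect_close(aecd, chord, 2)
  }
})

test_that("pore labeling follows 8-connectivity and the border policy", {
  m <- matrix(FALSE, 20, 20)
  m[3:6, 3:6] <- TRUE
  m[12:15, 12:15] <- TRUE
  prs <- label_pores_2d(m, "keep", voxel_size = 1)
  expect_equal(length(prs$regions), 2)
  diagonal <- matrix(FALSE, 10, 10)
  for (i in 2:8) diagonal[i, i] <- TRUE
  expect_equal(length(label_pores_2d(diagonal, "keep", voxel_size = 1)$regions), 1)
  half <- matrix(FALSE, 20, 20)
  half[1:5, 8:12] <- TRUE                 # touches the image border
  expect_equal(length(label_pores_2d(half, "exclude", voxel_size = 1)$regions), 0)
  expect_equal(length(label_pores_2d(half, "keep", voxel_size = 1)$regions), 1)
})

test_that("major diameter equals the all-pairs brute force on random blobs", {
  for (seed in 1:30) {
    reg <- blob_region(seed)
    md <- major_diameter(reg)
    pts <- reg$coords
    brute <- if (nrow(pts) == 1) 0 else max(dist(pts))
    expect_equal(md, (brute + 1) * reg$voxel_size, tolerance = 1e-12)
  }
})

test_that("planar parameters recover the rectangle", {
  reg <- shape_region("rectangle", width = 60, height = 20)
  expect_close(major_diameter(reg), sqrt(20^2 + 60^2), 1)
  expect_close(biggest_inner_circle_diameter(reg), 20, 1)
  expect_close(area_equivalent_circle_diameter(reg), 2 * sqrt(1200 / pi), 1)
  mt <- mean_thickness_2d(reg)
  expect_close(mt, 20, 2)
  expect_lt(mt, biggest_inner_circle_diameter(reg) + 1e-9)
})

test_that("planar parameters agree on a disk", {
  reg <- shape_region("circle", diameter = 40)
  expect_close(major_diameter(reg), 40, 2)
  expect_close(biggest_inner_circle_diameter(reg), 40, 1)
  expect_close(area_equivalent_circle_diameter(reg), 40, 1)
  expect_close(mean_thickness_2d(reg), 40, 2)
})

test_that("single-pixel regions measure one pixel pitch", {
  m <- matrix(FALSE, 9, 9)
  m[5, 5] <- TRUE
  reg <- pore_region(m, 4.5)
  expect_equal(major_diameter(reg), 4.5)
  expect_equal(area_equivalent_circle_diameter(reg), 2 * sqrt(1 / pi) * 4.5)
})

test_that("the biggest inner circle ignores narrow necks", {
  reg <- shape_region("lobulated", voxel = 0.5, lobe_diameter = 40,
                      neck_width = 6, center_distance = 50)
  expect_close(biggest_inner_circle_diameter(reg), 40, 1)
})

test_that("mean thickness tracks the brute-force circle-fitting oracle", {
  for (seed in c(2, 9, 17)) {
    reg <- blob_region(seed, n = 30)
    m <- poremetry:::region_mask(reg)
    a3 <- array(m, dim = c(1, dim(m)))
    bf <- poremetry:::thickness_bruteforce_cpp(as.logical(a3),
                                               as.integer(dim(a3)), TRUE)
    oracle <- mean(bf[a3]) * reg$voxel_size
    mt <- mean_thickness_2d(reg)
    expect_gte(mt, oracle - 1e-9)
    expect_lte(mt, oracle + 1)
  }
})

test_that("AECD adds in quadrature over disjoint regions", {
  m <- matrix(FALSE, 40, 40)
  m[5:12, 5:12] <- TRUE
  a1 <- area_equivalent_circle_diameter(pore_region(m, 1))
  m2 <- matrix(FALSE, 40, 40)
  m2[25:36, 25:30] <- TRUE
  a2 <- area_equivalent_circle_diameter(pore_region(m2, 1))
  both <- area_equivalent_circle_diameter(pore_region(m | m2, 1))
  expect_equal(both, sqrt(a1^2 + a2^2), tolerance = 1e-12)
})

test_that("merging regions can only raise MD and AECD", {
  m <- matrix(FALSE, 40, 40)
  m[5:12, 5:12] <- TRUE
  m2 <- matrix(FALSE, 40, 40)
  m2[25:36, 25:30] <- TRUE
  for (fn in c(major_diameter, area_equivalent_circle_diameter)) {
    single <- max(fn(pore_region(m, 1)), fn(pore_region(m2, 1)))
    expect_gte(fn(pore_region(m | m2, 1)), single)
  }
})

test_that("every parameter scales linearly with pixel size", {
  reg1 <- blob_region(4, voxel = 1)
  reg3 <- reg1
  reg3$voxel_size <- 3
  for (fn in c(major_diameter, biggest_inner_circle_diameter,
               area_equivalent_circle_diameter, mean_thickness_2d)) {
    expect_equal(fn(reg3), 3 * fn(reg1), tolerance = 1e-12)
  }
})

test_that("the isodiametric chain holds on irregular regions", {
  for (seed in 1:50) {
    reg <- blob_region(seed, n = 36)
    mt <- mean_thickness_2d(reg)
    bicd <- biggest_inner_circle_diameter(reg)
    aecd <- area_equivalent_circle_diameter(reg)
    md <- major_diameter(reg)
    expect_lte(mt, bicd + 2)
    expect_lte(bicd, aecd + 2)
    expect_lte(aecd, md + 2)
  }
})

test_that("per-region sampling pools sections with exact bookkeeping", {
  m <- matrix(FALSE, 30, 30)
  m[10:20, 10:20] <- TRUE
  a <- array(rep(!m, each = 5), dim = c(5, 30, 30))
  # five identical sections of one square pore
  vol <- binary_volume(a, 1)
  secs <- extract_sections(vol, n_sections = 5)
  s <- size_sample_2d(secs, "AECD", "keep")
  expect_equal(length(s), 5)
  expect_equal(length(unique(s$values)), 1)
  expect_error(size_sample_2d(secs, "BICD", "exclude", merge_regions = FALSE),
               NA)
  empty <- binary_volume(solid_array(c(10, 30, 30)), 1)
  expect_error(size_sample_2d(extract_sections(empty, n_sections = 2), "MD"),
               "no pore regions")
})

test_that("parameter divergence grows with shape irregularity", {
  spread <- function(reg) {
    vals <- c(mean_thickness_2d(reg), major_diameter(reg),
              biggest_inner_circle_diameter(reg),
              area_equivalent_circle_diameter(reg))
    (max(vals) - min(vals)) / mean(vals)
  }
  s_circle <- spread(shape_region("circle", diameter = 40))
  s_ellipse <- spread(shape_region("ellipse", axis_a = 40, axis_b = 60))
  s_lob <- spread(shape_region("lobulated", voxel = 0.5, lobe_diameter = 40,
                               neck_width = 6, center_distance = 50))
  expect_lt(s_circle, s_ellipse)
  expect_lt(s_ellipse, s_lob)
})
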