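test_that("single-sphere phantom matches its analytic porosity", {
  ph <- make_single_sphere(phantom_spec("single_sphere", c(64, 64, 64), 1,
                                        list(diameter = 30)))
  measured <- mean(!unclass(ph$volume))
  analytic <- (4 / 3) * pi * 15^3 / 64^3
  expect_equal(ph$truth$porosity, analytic, tolerance = 1e-6)
  # one-voxel-shell tolerance: surface area x one voxel
  shell <- 4 * pi * 15^2 / 64^3
  expect_close(measured, analytic, shell)
  expect_equal(ph$truth$diameters, 30)
})

test_that("degenerate or oversized spheres are rejected", {
  expect_error(make_single_sphere(phantom_spec("single_sphere", c(64, 64, 64),
                                               1, list(diameter = 0))),
               "positive")
  expect_error(make_single_sphere(phantom_spec("single_sphere", c(64, 64, 64),
                                               1, list(diameter = 70))),
               "does not fit")
})

test_that("packed-sphere foam hits its porosity target and records diameters", {
  ph <- make_packed_sphere_foam(phantom_spec(
    "packed_spheres", c(64, 64, 64), 2,
    list(mean_diameter = 60, sd_diameter = 0, target_porosity = 0.30),
    seed = 7))
  expect_close(ph$truth$porosity, 0.30, 0.02)
  expect_true(all(ph$truth$diameters == 60))
  expect_equal(ph$truth$porosity, mean(!unclass(ph$volume)))
})

test_that("foam generation is bit-identical under a fixed seed", {
  spec <- phantom_spec("packed_spheres", c(48, 48, 48), 2,
                       list(mean_diameter = 60, sd_diameter = 0,
                            target_porosity = 0.30), seed = 7)
  a <- make_packed_sphere_foam(spec)
  b <- make_packed_sphere_foam(spec)
  expect_identical(unclass(a$volume), unclass(b$volume))
  expect_identical(a$truth$diameters, b$truth$diameters)
})

test_that("foam pore sizes recover the sampled diameter distribution", {
  # moderate-overlap regime: the voxel-weighted thickness median sits near
  # the nominal sphere diameter
  ph <- make_packed_sphere_foam(phantom_spec(
    "packed_spheres", c(80, 80, 80), 2,
    list(mean_diameter = 60, sd_diameter = 10, target_porosity = 0.5),
    seed = 1))
  tf <- local_thickness_3d(ph$volume)
  med <- median(tf[tf > 0])
  expect_close(med, 60, 0.15 * 60)
})

test_that("random foam porosity is controlled by the threshold quantile", {
  ph <- make_random_foam(phantom_spec("random_foam", c(48, 48, 48), 2,
                                      list(target_porosity = 0.7,
                                           correlation_length = 12), seed = 3))
  expect_gte(ph$truth$porosity, 0.68)
  expect_lte(ph$truth$porosity, 0.72)
  ph2 <- make_random_foam(phantom_spec("random_foam", c(48, 48, 48), 2,
                                       list(target_porosity = 0.7,
                                            correlation_length = 12), seed = 4))
  expect_false(identical(unclass(ph$volume), unclass(ph2$volume)))
  expect_error(make_random_foam(phantom_spec("random_foam", c(48, 48, 48), 2,
                                             list(target_porosity = 0.7,
                                                  correlation_length = 3))),
               "correlation_length")
})

test_that("anisotropic stretch shows up as a section-orientation effect", {
  # structure stretched along the section axis: sections cut perpendicular
  # to the stretch see the narrow transverse scale, sections containing the
  # stretch axis see coarser structure
  ph <- make_random_foam(phantom_spec("random_foam", c(60, 60, 60), 2,
                                      list(target_porosity = 0.6,
                                           correlation_length = 10,
                                           anisotropy = 2), seed = 11))
  vol <- ph$volume
  mt_mean <- function(v) {
    mean(size_sample_2d(extract_sections(v, n_sections = 3), "MT",
                        "keep")$values)
  }
  perp <- mt_mean(vol)
  along <- mt_mean(binary_volume(aperm(unclass(vol), c(2, 1, 3)),
                                 voxel_size(vol)))
  expect_gt(along, perp)
})

test_that("2D shapes carry closed-form ground truth", {
  circ <- make_shape_2d(phantom_spec("shape2d", NULL, 1,
                                     list(shape = "circle", diameter = 40)))
  expect_equal(unlist(circ$truth$analytic), c(MD = 40, BICD = 40, AECD = 40,
                                              MT = 40))
  rect <- make_shape_2d(phantom_spec("shape2d", NULL, 1,
                                     list(shape = "rectangle", width = 60,
                                          height = 20)))
  expect_equal(rect$truth$analytic$MD, sqrt(20^2 + 60^2))
  expect_equal(rect$truth$analytic$BICD, 20)
  expect_equal(rect$truth$analytic$AECD, 2 * sqrt(1200 / pi))
  # corners lower the mean inscribed-circle diameter slightly below the width
  expect_close(rect$truth$analytic$MT, 20, 2)
  expect_lt(rect$truth$analytic$MT, 20)
  expect_error(make_shape_2d(phantom_spec("shape2d", NULL, 1,
                                          list(shape = "pentagon",
                                               diameter = 40))),
               "unknown shape")
})

test_that("shape ground truth respects the isodiametric chain", {
  shapes <- list(
    make_shape_2d(phantom_spec("shape2d", NULL, 1,
                               list(shape = "circle", diameter = 40))),
    make_shape_2d(phantom_spec("shape2d", NULL, 1,
                               list(shape = "rectangle", width = 60,
                                    height = 20))),
    make_shape_2d(phantom_spec("shape2d", NULL, 1,
                               list(shape = "ellipse", axis_a = 30,
                                    axis_b = 70))),
    make_shape_2d(phantom_spec("shape2d", NULL, 0.5,
                               list(shape = "lobulated", lobe_diameter = 40,
                                    neck_width = 6, center_distance = 50))))
  for (s in shapes) {
    a <- s$truth$analytic
    expect_lte(a$MT, a$BICD + 1e-9)
    expect_lte(a$BICD, a$AECD + 1e-9)
    expect_lte(a$AECD, a$MD + 1e-9)
  }
})

test_that("noise-free rendering round-trips through binarization", {
  vol <- foam_volume(seed = 2, grid = 40)
  gray <- render_grayscale(vol)
  expect_identical(unclass(binarize_adaptive(gray, 2, 0)) > 0,
                   unclass(vol) > 0)
  # a different window radius must round-trip too
  expect_identical(unclass(binarize_adaptive(gray, 4, 0)) > 0,
                   unclass(vol) > 0)
})

test_that("speckles are isolated single voxels at the requested rate", {
  vol <- foam_volume(seed = 2, grid = 40)
  gray <- render_grayscale(vol, speckle_rate = 0.01, seed = 5)
  n_spk <- attr(gray, "speckle_count")
  solidified <- binarize_adaptive(gray, 2, 0)
  lab <- poremetry:::label_components(unclass(solidified), 26)
  singletons <- sum(tabulate(lab) == 1)
  expect_equal(singletons, n_spk)
  # count within a Poisson-like band of rate x eligible pore voxels
  n_eligible <- attr(gray, "speckle_eligible")
  expect_gt(n_eligible, 0)
  expected <- 0.01 * n_eligible
  expect_gt(n_spk, expected - 4 * sqrt(expected) - 1)
  expect_lt(n_spk, expected + 4 * sqrt(expected) + 1)
  expect_error(render_grayscale(vol, speckle_rate = 0.2), "speckle_rate")
})

test_that("rendering is deterministic under a fixed seed", {
  vol <- foam_volume(seed = 2, grid = 32)
  g1 <- render_grayscale(vol, blur_sigma = 2, noise_sd = 0.05,
                         speckle_rate = 0.01, seed = 9)
  g2 <- render_grayscale(vol, blur_sigma = 2, noise_sd = 0.05,
                         speckle_rate = 0.01, seed = 9)
  expect_identical(unclass(g1), unclass(g2))
})

test_that("partial-volume blur pulls thin-wall voxels below the midpoint", {
  # a 6 um wall between two wide pores, blurred at a sigma comparable to the
  # wall half-width: the wall loses apparent density
  a <- solid_array(c(30, 30, 30), FALSE)
  a[, 15:20, ] <- TRUE   # 6-voxel wall
  vol <- binary_volume(a, 1)
  gray <- render_grayscale(vol, blur_sigma = 4)
  wall_vals <- unclass(gray)[15, 15:20, 15]
  expect_true(any(wall_vals < 0.5))
  # an unblurred rendering keeps the wall at full intensity
  crisp <- render_grayscale(vol)
  expect_true(all(unclass(crisp)[15, 15:20, 15] == 0.75))
})
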