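test_that("polygon_area matches closed forms", {
  sq <- polygon2d(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
  expect_equal(polygon_area(sq), 100)

  tri <- polygon2d(cbind(c(0, 40, 0), c(0, 0, 30)))
  expect_equal(polygon_area(tri), 600)

  # regular 64-gon, circumradius 10: A = n/2 * r^2 * sin(2*pi/n)
  hexacontatetragon <- polygon2d(regular_polygon(64, 10))
  expect_equal(polygon_area(hexacontatetragon),
               0.5 * 64 * 100 * sin(2 * pi / 64), tolerance = 1e-10)
  expect_equal(polygon_area(hexacontatetragon), 313.65, tolerance = 0.01 / 313)

  # orientation must not matter
  expect_equal(polygon_area(polygon2d(cbind(c(0, 0, 10, 10), c(0, 10, 10, 0)))),
               100)
})

test_that("non-convex contours get their true enclosed area (signed fan)", {
  # L-shape: area 3 * 1 = 75 - hull would be 100
  lshape <- polygon2d(cbind(c(0, 10, 10, 5, 5, 0), c(0, 0, 5, 5, 10, 10)))
  expect_equal(polygon_area(lshape), 75)
  # star with deep concavities
  set.seed(42)
  v <- star_polygon(40, 10, 0.6)
  expect_equal(polygon_area(polygon2d(v)), raster_area(v, 0.05),
               tolerance = 0.02)
})

test_that("construction collapses duplicates and flags degenerate contours", {
  with_dup <- polygon2d(rbind(c(0, 0), c(0, 0), c(10, 0), c(10, 10), c(0, 0)))
  expect_equal(nrow(with_dup$vertices), 3L)
  expect_equal(polygon_area(with_dup), 50)

  expect_error(polygon2d(rbind(c(0, 0), c(1, 1))), "at least 3")
  expect_error(polygon2d(rbind(c(0, 0), c(1, NA), c(2, 0))), "finite")

  collinear <- polygon2d(rbind(c(0, 0), c(1, 1), c(2, 2)))
  expect_equal(polygon_area(collinear), 0)
  expect_equal(unname(principal_axis_lengths(collinear)), c(0, 0))

  collapsed <- polygon2d(rbind(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(polygon_area(collapsed), 0)
})

test_that("principal axes match uniform-shape covariance closed forms", {
  # disk radius 10: covariance r^2/4, axis = 2r = diameter
  disk <- polygon2d(regular_polygon(256, 10))
  ax <- principal_axis_lengths(disk)
  expect_equal(unname(ax), c(20, 20), tolerance = 0.005)

  # ellipse semi-axes 30, 10: axes (60, 20)
  ell <- polygon2d(ellipse_polygon(30, 10, 256))
  ax <- principal_axis_lengths(ell)
  expect_equal(unname(ax), c(60, 20), tolerance = 0.005)

  # square side 10: variance w^2/12 each way, axis 4w/sqrt(12)
  sq <- polygon2d(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
  ax <- principal_axis_lengths(sq)
  expect_equal(unname(ax), rep(40 / sqrt(12), 2), tolerance = 1e-6)

  expect_true(all(ax["major"] >= ax["minor"]))
})

test_that("lesion_volume is exactly 2/3 * surface * minor axis", {
  expect_equal(lesion_volume(pi * 100, 20), 4188.79, tolerance = 0.01 / 4188)
  expect_equal(lesion_volume(0, 5), 0)
  expect_equal(lesion_volume(100, 3), 200)
  expect_error(lesion_volume(-1, 2), ">= 0")
  expect_error(lesion_volume(10, -2), ">= 0")

  f <- shape_features(polygon2d(ellipse_polygon(12, 7)))
  expect_identical(f$volume, (2 / 3) * f$surface * f$minor_axis)
})

test_that("n-gon phantom volume converges to the sphere volume", {
  r <- 10
  for (n in c(128, 256, 512)) {
    f <- shape_features(polygon2d(regular_polygon(n, r)))
    expect_equal(f$volume, (4 / 3) * pi * r^3, tolerance = 0.01)
  }
  # error shrinks with n
  err <- sapply(c(32, 128, 512), function(n) {
    abs(shape_features(polygon2d(regular_polygon(n, r)))$volume -
          (4 / 3) * pi * r^3)
  })
  expect_true(all(diff(err) < 0))
})

test_that("equivalent_sphere_diameter inverts the sphere volume", {
  expect_equal(equivalent_sphere_diameter((4 / 3) * pi * 0.5^3), 1.0)
  expect_equal(equivalent_sphere_diameter(0), 0)
  expect_error(equivalent_sphere_diameter(-1), ">= 0")
  d <- equivalent_sphere_diameter(90)
  expect_equal((4 / 3) * pi * (d / 2)^3, 90, tolerance = 1e-12)
})

test_that("features scale correctly and are rigid-motion invariant", {
  set.seed(101)
  for (rep in 1:10) {
    v <- star_polygon(sample(16:48, 1), runif(1, 5, 20), runif(1, 0, 0.5))
    f <- shape_features(polygon2d(v))
    expect_gte(f$major_axis, f$minor_axis)
    for (s in c(0.5, 2, 10)) {
      fs <- shape_features(polygon2d(v * s))
      expect_equal(fs$surface, f$surface * s^2, tolerance = 1e-12)
      expect_equal(fs$major_axis, f$major_axis * s, tolerance = 1e-12)
      expect_equal(fs$minor_axis, f$minor_axis * s, tolerance = 1e-12)
      expect_equal(fs$volume, f$volume * s^3, tolerance = 1e-12)
    }
    ang <- runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    vt <- sweep(v %*% rot, 2, runif(2, -100, 100), `+`)
    ft <- shape_features(polygon2d(vt))
    expect_equal(ft$surface, f$surface, tolerance = 1e-9)
    expect_equal(ft$major_axis, f$major_axis, tolerance = 1e-9)
    expect_equal(ft$minor_axis, f$minor_axis, tolerance = 1e-9)
  }
})

test_that("area agrees with the pixel-counting oracle", {
  set.seed(7)
  for (rep in 1:10) {
    v <- star_polygon(sample(20:60, 1), runif(1, 5, 15), runif(1, 0, 0.4))
    expect_equal(polygon_area(polygon2d(v)), raster_area(v, 0.1),
                 tolerance = 0.02)
  }
})

test_that("inclusion rules drop small nodes and micronodules only", {
  tab <- six_lesion_fixture()
  kept <- filter_lesions(tab)
  expect_equal(nrow(kept), 4L)
  expect_setequal(kept$lesion_id, c("L3", "L4", "L5", "L6"))
  expect_equal(attr(kept, "n_dropped"), c(lymph_node = 1L, lung = 1L))

  # thresholds are strict: exactly-at-threshold lesions are dropped
  node10 <- shape_features(polygon2d(ellipse_polygon(8, 5)))  # minor 10.0
  lung3 <- shape_features(polygon2d(ellipse_polygon(1.5, 1)))  # major 3.0
  edge <- data.frame(
    patient_id = "P", timepoint = "baseline", lesion_id = c("N", "G"),
    organ = c("lymph_node", "lung"),
    surface = c(node10$surface, lung3$surface),
    major_axis = c(node10$major_axis, lung3$major_axis),
    minor_axis = c(node10$minor_axis, lung3$minor_axis),
    volume = c(node10$volume, lung3$volume), stringsAsFactors = FALSE)
  # the 256-gon minor/major sit a hair under the nominal diameter, so both
  # lesions are at/below threshold and must go
  expect_equal(nrow(filter_lesions(edge)), 0L)
  # just above threshold is retained
  node11 <- ellipse_polygon(8, 5.6)
  f <- shape_features(polygon2d(node11))
  edge$minor_axis[1] <- f$minor_axis
  expect_equal(nrow(filter_lesions(edge)), 1L)
  expect_equal(filter_lesions(edge)$lesion_id, "N")
})

test_that("lesion_features drops degenerate contours with a warning", {
  good <- lesion_annotation("P1", "baseline", "L1", "liver",
                            polygon2d(regular_polygon(16, 5)))
  flat <- lesion_annotation("P1", "baseline", "L2", "liver",
                            polygon2d(rbind(c(0, 0), c(5, 5), c(10, 10))))
  expect_warning(tab <- lesion_features(list(good, flat)), "degenerate")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$lesion_id, "L1")
})
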