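# Synthetic prosthesis generators and their ground truth.

test_that("superellipse exponent solve reproduces the target areas", {
  for (j in 1:3) {
    h <- c(5.7, 5.7, 5.8)[j]; l <- c(6.8, 6.0, 6.8)[j]
    a <- c(33.1, 28.5, 33.2)[j]
    p <- superellipse_exponent(h, l, a)
    expect_gt(p, 2)  # fuller than an ellipse
    expect_equal(fpdconnect:::superellipse_area(h, l, p), a,
                 tolerance = 1e-9)
  }
  expect_error(superellipse_exponent(2, 2, 4.5), "between")
  expect_error(superellipse_exponent(2, 2, 1.5), "between")
})

test_that("default-spec FPD has the nominal overall extents", {
  fpd <- coarse_fpd(0.3)
  ext <- apply(fpd$mesh$vertices, 2, function(x) diff(range(x)))
  expect_equal(ext, c(32.5, 11.7, 9.0), tolerance = 0.05 * 32.5)
  expect_lt(abs(ext[1] - 32.5) / 32.5, 0.05)
  expect_lt(abs(ext[2] - 11.7) / 11.7, 0.05)
  expect_lt(abs(ext[3] - 9.0) / 9.0, 0.05)
  expect_true(is_watertight(fpd$mesh))
  expect_identical(fpd$mesh$provenance, "synthetic")
})

test_that("ground truth has one record per connector", {
  fpd2 <- generate_fpd(fpd_spec(n_units = 2, neck_heights = 5.7,
                                neck_lengths = 6.0, neck_areas = 28.5,
                                total_length = 16, pitch = 0.3))
  expect_equal(nrow(fpd2$ground_truth), 1L)
  fpd5 <- fpd_spec(n_units = 5, pitch = 0.3)
  expect_equal(length(fpd5$neck_stations), 4L)
  expect_true(all(diff(fpd5$neck_stations) > 0))
})

test_that("middle connector section matches its construction target", {
  fpd <- coarse_fpd(0.3)
  site <- manual_site(fpd$ground_truth$station[2])
  a <- section_area_at(fpd$mesh, site)
  expect_equal(a, 28.5, tolerance = 0.1 * 28.5)
})

test_that("generation is bit-reproducible without jitter", {
  a <- generate_fpd(fpd_spec(pitch = 0.35))
  b <- generate_fpd(fpd_spec(pitch = 0.35))
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
  # jitter changes geometry but deterministically for a fixed seed
  j1 <- generate_fpd(fpd_spec(pitch = 0.35, jitter = 0.01, seed = 3))
  j2 <- generate_fpd(fpd_spec(pitch = 0.35, jitter = 0.01, seed = 3))
  expect_identical(j1$mesh$vertices, j2$mesh$vertices)
  expect_false(identical(a$mesh$vertices, j1$mesh$vertices))
})

test_that("spec guards reject unresolvable parameters", {
  expect_error(fpd_spec(pitch = 2), "too coarse")
  expect_error(fpd_spec(n_units = 1), "at least 2")
  expect_error(fpd_spec(neck_heights = 10), "smaller than the crown")
})

test_that("dumbbell and cylinder fixtures match closed forms", {
  db <- generate_dumbbell(radius = 5, neck_radius = 2, pitch = 0.3)
  expect_true(is_watertight(db$mesh))
  expect_equal(db$ground_truth$station, 10)  # length/2
  expect_equal(db$ground_truth$area, pi * 4)
  site <- manual_site(10)
  expect_equal(section_area_at(db$mesh, site), pi * 4, tolerance = 0.05 * pi * 4)
  expect_error(generate_dumbbell(radius = 2, neck_radius = 3), "exceed")

  cyl <- generate_cylinder(radius = 2, length = 20, pitch = 0.3)
  expect_true(is_watertight(cyl))
  expect_equal(section_area_at(cyl, manual_site(7)), pi * 4,
               tolerance = 0.02 * pi * 4)
  expect_equal(mesh_volume(cyl), pi * 4 * 20, tolerance = 0.01 * pi * 80)
  expect_error(generate_cylinder(radius = -1), "positive")
})

test_that("revolve_profile enforces its profile contract", {
  expect_error(revolve_profile(c(0, 1, 0.5), c(1, 1, 1)), "increasing")
  expect_error(revolve_profile(c(0, 1, 2), c(1, -1, 1)), "non-negative")
  expect_error(revolve_profile(c(0, 1, 2), c(1, 0, 1)), "ends")
  m <- revolve_profile(seq(0, 2, 0.1), rep(1, 21), n_theta = 40)
  expect_true(is_watertight(m))
})
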