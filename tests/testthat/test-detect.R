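# Connector detection: slice profiles, rectangle split, minima, sites.

test_that("cylinder slice profiles carry the closed-form rectangle areas", {
  cyl <- generate_cylinder(radius = 2, length = 20, pitch = 0.25)
  box <- fit_oriented_box(cyl)
  prof <- slice_profiles(cyl, box, n_planes = 40)
  expect_length(prof, 40L)
  a_occ <- vapply(prof, `[[`, 0, "a_occ")
  a_gin <- vapply(prof, `[[`, 0, "a_gin")
  # every profile: one circular loop; split rectangle 4 x 2 both sides
  expect_true(all(vapply(prof, function(p) length(p$curves), 0L) == 1L))
  expect_equal(a_occ, rep(8, 40), tolerance = 0.02)
  expect_equal(a_gin, rep(8, 40), tolerance = 0.02)
  expect_error(slice_profiles(cyl, box, n_planes = 5), "at least 10")
})

test_that("rectangle split clips the full bounding rectangle at E_mid", {
  box <- fit_oriented_box(cuboid_mesh(20, 10, 10, origin = c(0, -5, -5)))
  th <- (seq_len(100) - 1) / 100 * 2 * pi
  mk <- function(dy, dz, w = 4, h = 6)
    list(cbind(10, dy + w / 2 * cos(th), dz + h / 2 * sin(th)))
  # symmetric 4 x 6 section centred on E_mid
  r <- split_rectangles(mk(0, 0), box)
  expect_equal(r$a_occ, 12, tolerance = 1e-6)
  expect_equal(r$a_gin, 12, tolerance = 1e-6)
  # shifted 1 mm occlusally
  r2 <- split_rectangles(mk(0, 1), box)
  expect_equal(r2$a_occ, 16, tolerance = 1e-6)
  expect_equal(r2$a_gin, 8, tolerance = 1e-6)
  # entirely occlusal of E_mid
  r3 <- split_rectangles(mk(0, 4), box)
  expect_equal(r3$a_gin, 0)
  expect_equal(r3$a_occ, 24, tolerance = 1e-6)
  # empty input
  expect_equal(split_rectangles(list(), box)$a_occ, 0)
})

test_that("minima detection matches the worked series and a brute-force oracle", {
  s <- c(5, 4, 3, 4, 5, 4, 3, 4, 5, 6)
  m <- find_connector_minima(list(a_occ = s, a_gin = s), smooth_window = 1)
  expect_equal(m$alpha, c(3L, 7L))
  expect_equal(m$beta, c(3L, 7L))
  # monotone series: no minima
  mono <- as.numeric(1:20)
  expect_equal(nrow(find_connector_minima(list(a_occ = mono, a_gin = mono),
                                          smooth_window = 1)), 0L)
  # property: with zero prominence threshold, detection equals the
  # brute-force interior scan on random rough series
  withr::local_seed(42)
  for (rep in 1:20) {
    x <- cumsum(rnorm(60))
    got <- find_connector_minima(list(a_occ = x, a_gin = x),
                                 smooth_window = 1, prominence = 0,
                                 pairing_window = 0)
    expect_equal(got$alpha, brute_minima(x))
  }
})

test_that("unpaired minima are dropped with a warning", {
  a <- c(5, 4, 3, 4, 5, 5, 5, 5, 5, 5)       # minimum at 3
  g <- c(5, 5, 5, 5, 5, 5, 5, 4, 3, 4, 5, 5) # minimum at 9, too far
  w <- testthat::capture_warnings(
    m <- find_connector_minima(list(a_occ = c(a, 5, 5),
                                    a_gin = g),
                               smooth_window = 1, pairing_window = 2))
  expect_true(length(w) >= 1)
  expect_match(w, "unpaired", all = TRUE)
  expect_equal(nrow(m), 0L)
})

test_that("dumbbell yields one connector with the circle-area oracle", {
  db <- generate_dumbbell(radius = 5, neck_radius = 2, pitch = 0.25)
  det <- detect_connectors(db$mesh)
  expect_length(det$sites, 1L)
  s <- det$sites[[1]]
  expect_equal(s$a0, pi * 4, tolerance = 0.05 * pi * 4)
  expect_lt(abs(s$station - db$ground_truth$station), 0.5)
  # the neck is a flat-bottomed waist, so the paired minima may sit a few
  # slices apart inside the plateau; the plane stays nearly perpendicular
  expect_lt(s$obliquity_deg, 5)
  # A0 equals an independent re-slice at the connector plane
  expect_equal(s$a0, section_area_at(db$mesh, s), tolerance = 1e-9)
  # an exactly-paired (alpha = beta) site has its plane parallel to L1
  det2 <- detect_connectors(db$mesh)
  prof <- slice_profiles(db$mesh, det2$box)
  site_sym <- build_connector_site(db$mesh, prof,
                                   c(s$alpha, s$alpha), det2$box)
  expect_lt(site_sym$obliquity_deg, 1e-6)
})

test_that("capsule (no neck) and cylinder produce zero sites", {
  cap <- generate_dumbbell(radius = 4, neck_radius = 4, pitch = 0.3)
  expect_length(detect_connectors(cap$mesh)$sites, 0L)
  cyl <- generate_cylinder(radius = 2, length = 20, pitch = 0.3)
  expect_length(detect_connectors(cyl)$sites, 0L)
})

test_that("synthetic 4-unit FPD: 3 sites at the constructed necks", {
  fpd <- coarse_fpd(0.3)
  det <- detect_connectors(fpd$mesh)
  expect_length(det$sites, 3L)
  st <- vapply(det$sites, `[[`, 0, "station")
  a0 <- vapply(det$sites, `[[`, 0, "a0")
  expect_true(all(abs(st - fpd$ground_truth$station) <= 0.5))
  expect_true(all(abs(a0 - fpd$ground_truth$area) / fpd$ground_truth$area
                  <= 0.1))
  # middle connector near its 28.5 mm^2 construction target
  expect_equal(a0[2], 28.5, tolerance = 0.1 * 28.5)
  # sum rule: occlusal + gingival rectangle areas = full rectangle area
  for (p in det$profiles[c(10, 150, 290)]) {
    full <- (p$rect$og_max - p$rect$og_min) * (p$rect$lb_max - p$rect$lb_min)
    expect_equal(p$a_occ + p$a_gin, full, tolerance = 1e-9)
  }
})

test_that("detection is invariant under rigid transformation", {
  fpd <- coarse_fpd(0.35)
  det1 <- detect_connectors(fpd$mesh)
  R <- rotmat(c(2, -1, 0.5), 40 * pi / 180)
  moved <- transform_mesh(fpd$mesh, rotation = R, translation = c(10, 4, -7))
  hints <- orientation_hints(occlusal = R %*% c(0, 0, 1),
                             mesial = R %*% c(1, 0, 0),
                             buccal = R %*% c(0, 1, 0))
  det2 <- detect_connectors(moved, hints = hints)
  expect_length(det2$sites, length(det1$sites))
  a1 <- vapply(det1$sites, `[[`, 0, "a0")
  a2 <- vapply(det2$sites, `[[`, 0, "a0")
  expect_lt(max(abs(a1 - a2)), 1e-3)
})

test_that("connector site frame satisfies its geometric contract", {
  fpd <- coarse_fpd(0.35)
  det <- detect_connectors(fpd$mesh)
  box <- det$box
  for (s in det$sites) {
    fr <- s$frame
    # orthonormal right-handed
    A <- cbind(fr$x, fr$y, fr$z)
    expect_equal(t(A) %*% A, diag(3), tolerance = 1e-9)
    expect_equal(det(A), 1, tolerance = 1e-9)
    # origin on E_mid, E_mid2 and E_midCon
    expect_lt(abs(plane_dist_test(box$e_mid, fr$origin)), 1e-6)
    expect_lt(abs(plane_dist_test(box$e_mid2, fr$origin)), 1e-6)
    expect_lt(abs(plane_dist_test(s$e_midcon, fr$origin)), 1e-6)
    # L_o and L_g lie in E_midCon
    for (p in list(s$l_o[1, ], s$l_o[2, ], s$l_g[1, ], s$l_g[2, ]))
      expect_lt(abs(plane_dist_test(s$e_midcon, p)), 1e-6)
    expect_gt(s$a0, 0)
  }
})
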