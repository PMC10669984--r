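# Bezier falloff, displacement law, point selection and the k-solver.

test_that("bezier weight matches hand-evaluated closed forms", {
  # B(0) = w^4, B(w) = 0, B(w/2, 1) = 0.125 + 0.3375 + 0.0375 = 0.5
  for (w in c(0.5, 1, 2)) {
    expect_identical(bezier_weight(0, w), w^4)
    expect_identical(bezier_weight(w, w), 0)
  }
  expect_identical(bezier_weight(0.5, 1), 0.5)
  expect_error(bezier_weight(0.1, 0), "positive")
  # out-of-range arguments clamp to the endpoint values
  expect_identical(bezier_weight(-1, 1), 1)
  expect_identical(bezier_weight(2, 1), 0)
})

test_that("bezier weight is strictly decreasing on [0, w]", {
  t <- seq(0, 1, length.out = 1000)
  b <- bezier_weight(t, 1)
  expect_true(all(diff(b) < 0))
})

test_that("displacement law reproduces direct substitution", {
  # single occlusal vertex: x = 2, d_xy = 0, w = 1, k = 0.1
  # x_new = 2 - 0.1 * 2 * B(0) * 2 = 1.6
  pts <- structure(list(indices = 1L, x = 2, y = 0.3, z = 0,
                        occlusal = TRUE, gingival = FALSE,
                        buccal = TRUE, lingual = FALSE, w = 1),
                   class = "connector_points")
  upd <- apply_displacement(pts, k = 0.1, w = 1, direction = "occlusal")
  expect_equal(upd$x, 1.6)
  expect_identical(upd$y, 0.3)
  # k = 0 identity is bit-exact
  upd0 <- apply_displacement(pts, k = 0, w = 1, direction = "iso")
  expect_identical(upd0$x, pts$x)
  expect_identical(upd0$y, pts$y)
  # x = 0 vertex never moves (zero distance to the y-z plane, zero factor)
  pts2 <- structure(list(indices = 1:2, x = c(0, 1), y = c(1, -1),
                         z = c(0, 0),
                         occlusal = c(FALSE, TRUE),
                         gingival = c(FALSE, FALSE),
                         buccal = c(TRUE, FALSE),
                         lingual = c(FALSE, TRUE), w = 1),
                    class = "connector_points")
  u2 <- apply_displacement(pts2, k = 0.2, w = 1, direction = "occlusal")
  expect_identical(u2$x[1], 0)
  # displacement vanishes continuously at the selection boundary d_xy -> w
  pts3 <- structure(list(indices = 1L, x = 2, y = 0, z = 1 - 1e-9,
                         occlusal = TRUE, gingival = FALSE,
                         buccal = FALSE, lingual = FALSE, w = 1),
                    class = "connector_points")
  u3 <- apply_displacement(pts3, k = 0.2, w = 1, direction = "occlusal")
  expect_lt(abs(u3$x - 2), 1e-8)
  # fold-over guard
  expect_error(apply_displacement(pts, k = 10, w = 1,
                                  direction = "occlusal"), "k_max")
})

test_that("occlusal and gingival laws are mirror images", {
  withr::local_seed(8)
  n <- 200
  x <- runif(n, 0.1, 3)
  y <- runif(n, -2, 2)
  z <- runif(n, -0.99, 0.99)
  mk <- function(xv) structure(
    list(indices = seq_len(n), x = xv, y = y, z = z,
         occlusal = xv > 0, gingival = xv < 0,
         buccal = y > 0, lingual = y < 0, w = 1),
    class = "connector_points")
  up_occ <- apply_displacement(mk(x), 0.05, 1, "occlusal")
  up_gin <- apply_displacement(mk(-x), 0.05, 1, "gingival")
  expect_equal(up_gin$x, -up_occ$x, tolerance = 1e-12)
})

test_that("select_points picks exactly the vertices within w of the plane", {
  cyl <- generate_cylinder(radius = 2, length = 20, pitch = 0.3)
  site <- manual_site(10)
  pts <- select_points(cyl, site, w = 1)
  # direct distance-scan oracle
  d <- abs(cyl$vertices[, 1] - 10)
  expect_setequal(pts$indices, which(d < 1))
  # subsets partition by sign
  expect_true(all(xor(pts$occlusal, pts$gingival) |
                    (pts$x == 0)))
  expect_true(all(abs(pts$z) < 1))
  # w larger than the mesh: everything selected
  pts_all <- select_points(cyl, site, w = 100)
  expect_equal(length(pts_all$indices), nrow(cyl$vertices))
  # strict inequality at exactly w
  flat <- fpd_mesh(rbind(c(9, 0, 0), c(11, 1, 0), c(10, 0, 1)),
                   matrix(1:3, 1), validate = FALSE)
  p2 <- select_points(flat, site, w = 1)
  expect_false(1L %in% p2$indices)  # vertex at distance exactly w excluded
  expect_false(2L %in% p2$indices)
  expect_true(3L %in% p2$indices)
  expect_error(select_points(flat, manual_site(3), w = 0.5), "no vertices")
})

test_that("section area decreases monotonically in k", {
  cyl <- generate_cylinder(radius = 2, length = 12, pitch = 0.3)
  site <- manual_site(6)
  pts <- select_points(cyl, site, w = 1)
  for (dir in c("iso", "gingival", "buccal")) {
    kmax <- fpdconnect:::k_max(pts, dir, 1)
    ks <- seq(0, kmax, length.out = 50)
    # area measured along the solver's own path (unchecked shoelace): at
    # extreme k the crushed section may self-touch, which the simplicity
    # check would reject, but the measured area must still be monotone
    areas <- vapply(ks, function(k) {
      upd <- apply_displacement(pts, k, 1, dir)
      m <- rebuild_vertices(cyl, site, pts, upd)
      fpdconnect:::site_section_area(m$vertices, m$faces, site)
    }, 0)
    expect_true(all(diff(areas) <= 1e-9))
    expect_equal(areas[1], pi * 4, tolerance = 0.02)
  }
})

test_that("solver meets the area tolerance and the locality contract", {
  cyl <- generate_cylinder(radius = 2, length = 12, pitch = 0.25)
  site <- manual_site(6)
  a0 <- section_area_at(cyl, site)
  spec <- adjustment_spec(direction = "iso", target_area = 0.8 * a0)
  adj <- adjust_connector(cyl, site, spec)
  expect_lte(adj$result$achieved, 0.001)
  expect_lt(adj$result$a_final, a0)
  expect_equal(adj$result$a_final, 0.8 * a0, tolerance = 0.002)
  # faces untouched; vertices beyond w bit-identical
  expect_identical(adj$mesh$faces, cyl$faces)
  far <- abs(cyl$vertices[, 1] - 6) >= 1
  expect_identical(adj$mesh$vertices[far, ], cyl$vertices[far, ])
  # independent re-slice of the adjusted mesh agrees with the solver
  expect_equal(section_area_at(adj$mesh, site), adj$result$a_final,
               tolerance = 1e-6)
  # identity target: zero iterations, bit-identical mesh
  adj0 <- adjust_connector(cyl, site,
                           adjustment_spec(direction = "iso",
                                           target_area = a0))
  expect_identical(adj0$mesh$vertices, cyl$vertices)
  expect_equal(adj0$result$k, 0)
  # unreachable target reports the minimum achievable area
  expect_error(adjust_connector(cyl, site,
                                adjustment_spec(direction = "gingival",
                                                target_area = 0.01 * a0)),
               "unreachable")
})

test_that("occ/gin adjustment leaves local y and z coordinates bit-identical", {
  cyl <- generate_cylinder(radius = 2, length = 12, pitch = 0.3)
  site <- manual_site(6)
  pts <- select_points(cyl, site, w = 1)
  upd <- apply_displacement(pts, 0.05, 1, "gingival")
  expect_identical(upd$y, pts$y)
  # occlusal-subset coordinates untouched by the gingival law
  expect_identical(upd$x[pts$occlusal], pts$x[pts$occlusal])
})

test_that("sequential adjustment of distant connectors does not interfere", {
  fpd <- coarse_fpd(0.35)
  det <- detect_connectors(fpd$mesh)
  s1 <- det$sites[[1]]; s3 <- det$sites[[3]]
  a3_before <- section_area_at(fpd$mesh, s3)
  adj1 <- adjust_connector(fpd$mesh, s1,
                           adjustment_spec(direction = "iso",
                                           reduction = 0.2, a0 = s1$a0))
  a3_after <- section_area_at(adj1$mesh, s3)
  expect_lt(abs(a3_after - a3_before), 0.001 * s3$a0)
  adj3 <- adjust_connector(adj1$mesh, s3,
                           adjustment_spec(direction = "iso",
                                           reduction = 0.2, a0 = s3$a0))
  expect_lte(adj1$result$achieved, 0.001)
  expect_lte(adj3$result$achieved, 0.001)
})

test_that("adjustment_spec validates its inputs", {
  expect_error(adjustment_spec(direction = "iso"), "exactly one")
  expect_error(adjustment_spec(direction = "iso", target_area = 1,
                               reduction = 0.1), "exactly one")
  expect_error(adjustment_spec(direction = "iso", reduction = 1.2, a0 = 10),
               "in \\(0, 1\\)")
  expect_error(adjustment_spec(direction = "iso", target_area = 12, a0 = 10),
               "in \\(0, A0")
  expect_error(adjustment_spec(direction = "iso", target_area = 5, a0 = 10,
                               w = -1), "positive")
  s <- adjustment_spec(direction = "gingival", reduction = 0.1, a0 = 10)
  expect_equal(s$target_area, 9)
})
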