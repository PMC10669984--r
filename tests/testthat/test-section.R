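# Planar cross-sections: loop extraction, shoelace area, metrics.

test_that("cube mid-plane section is a unit square loop", {
  m <- cuboid_mesh()
  loops <- intersect_plane(m, list(point = c(0.5, 0.5, 0.5),
                                   normal = c(0, 0, 1)))
  expect_length(loops, 1L)
  expect_equal(polygon_area(loops[[1]]), 1, tolerance = 1e-9)
  expect_equal(nrow(loops[[1]]$vertices), 4L)  # collinear points cleaned
})

test_that("slice topology matches analytic expectations", {
  # torus through the hole axis: two loops of area ~ pi r^2
  tor <- torus_mesh(R = 2, r = 0.5)
  loops <- intersect_plane(tor, list(point = c(0, 0, 0),
                                     normal = c(1, 0, 0)))
  expect_length(loops, 2L)
  for (l in loops)
    expect_equal(polygon_area(l), pi * 0.25, tolerance = 0.01)
  # equatorial slice: two concentric loops
  loops2 <- intersect_plane(tor, list(point = c(0, 0, 0),
                                      normal = c(0, 0, 1)))
  expect_length(loops2, 2L)
  # plane outside the mesh: empty
  expect_length(intersect_plane(tor, list(point = c(0, 0, 5),
                                          normal = c(0, 0, 1))), 0L)
})

test_that("shoelace area matches closed forms", {
  rect <- planar_polygon(rbind(c(0, 0), c(3, 0), c(3, 2), c(0, 2)))
  expect_identical(polygon_area(rect), 6)
  n <- 360
  th <- (seq_len(n) - 1) / n * 2 * pi
  ngon <- planar_polygon(cbind(cos(th), sin(th)))
  expect_equal(polygon_area(ngon), 0.5 * n * sin(2 * pi / n),
               tolerance = 1e-12)
  expect_error(planar_polygon(rbind(c(0, 0), c(1, 1))), "at least 3")
  bowtie <- planar_polygon(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)))
  expect_error(polygon_area(bowtie), "self-intersecting")
})

test_that("area agrees with a Monte-Carlo point-in-polygon oracle", {
  withr::local_seed(99)
  for (rep in 1:3) {
    # random star-shaped simple polygon
    nv <- 40
    th <- sort(runif(nv, 0, 2 * pi))
    rr <- runif(nv, 0.5, 1.5)
    uv <- cbind(rr * cos(th), rr * sin(th))
    poly <- planar_polygon(uv)
    a <- polygon_area(poly)
    ns <- 40000
    px <- runif(ns, -1.6, 1.6); py <- runif(ns, -1.6, 1.6)
    # ray-crossing point-in-polygon (independent oracle)
    x <- poly$vertices[, 1]; y <- poly$vertices[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    inside <- rep(FALSE, ns)
    for (e in seq_along(x)) {
      crosses <- (y[e] > py) != (yn[e] > py)
      xi <- x[e] + (py - y[e]) / (yn[e] - y[e]) * (xn[e] - x[e])
      inside <- xor(inside, crosses & px < xi)
    }
    mc <- mean(inside) * 3.2^2
    expect_equal(a, mc, tolerance = 0.05)
  }
})

test_that("section metrics match rectangle and circle closed forms", {
  # chart: x = length axis (buccal), y = height axis (occlusal)
  rect <- planar_polygon(rbind(c(0, 0), c(3, 0), c(3, 2), c(0, 2)))
  sm <- section_metrics(rect)
  expect_equal(sm$area, 6)
  expect_equal(sm$height, 2)
  expect_equal(sm$length, 3)
  expect_equal(sm$centroid, c(1.5, 1))
  expect_equal(min(sm$principal_moments), 3 * 2^3 / 12, tolerance = 1e-12)
  expect_equal(max(sm$principal_moments), 2 * 3^3 / 12, tolerance = 1e-12)

  n <- 1000
  th <- (seq_len(n) - 1) / n * 2 * pi
  circ <- planar_polygon(cbind(cos(th), sin(th)))
  sm2 <- section_metrics(circ)
  expect_equal(sm2$principal_moments[1], pi / 4, tolerance = 1e-3 * pi / 4)
  expect_equal(sm2$centroid, c(0, 0), tolerance = 1e-12)
})

test_that("area is invariant under in-plane chart rotation", {
  withr::local_seed(5)
  th <- sort(runif(25, 0, 2 * pi))
  uv <- cbind((1 + 0.3 * cos(3 * th)) * cos(th),
              (1 + 0.3 * cos(3 * th)) * sin(th))
  a0 <- polygon_area(planar_polygon(uv))
  for (ang in c(0.3, 1.1, 2.7)) {
    Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    expect_equal(polygon_area(planar_polygon(uv %*% Rm)), a0,
                 tolerance = 1e-12)
  }
})

test_that("connector loop selection picks the nearest loop and guards empties", {
  one <- planar_polygon(rbind(c(-0.5, -0.5), c(0.5, -0.5), c(0.5, 0.5),
                              c(-0.5, 0.5)))
  far <- planar_polygon(rbind(c(9, 9), c(11, 9), c(11, 11), c(9, 11)))
  expect_identical(select_connector_loop(list(one)), one)
  pick <- select_connector_loop(list(far, one))
  expect_equal(polygon_area(pick), 1)
  expect_error(select_connector_loop(list()), "no section loop")
})
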