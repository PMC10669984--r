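# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write.

# axis-aligned cuboid mesh (12 triangles, outward normals)
cuboid_mesh <- function(lx = 1, ly = 1, lz = 1, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(x = c(0, lx), y = c(0, ly), z = c(0, lz)))
  v <- sweep(v, 2, origin, "+")
  f <- rbind(c(1, 3, 4), c(1, 4, 2),   # z = 0
             c(5, 6, 8), c(5, 8, 7),   # z = lz
             c(1, 2, 6), c(1, 6, 5),   # y = 0
             c(3, 7, 8), c(3, 8, 4),   # y = ly
             c(1, 5, 7), c(1, 7, 3),   # x = 0
             c(2, 4, 8), c(2, 8, 6))   # x = lx
  m <- fpd_mesh(v, f, validate = FALSE)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# parametric torus: tube radius r around a circle of radius R in the
# xy-plane, centred at the origin
torus_mesh <- function(R = 2, r = 0.5, nu = 64, nv = 32) {
  u <- (seq_len(nu) - 1) / nu * 2 * pi
  v <- (seq_len(nv) - 1) / nv * 2 * pi
  g <- expand.grid(vi = seq_len(nv), ui = seq_len(nu))
  uu <- u[g$ui]; vv <- v[g$vi]
  pts <- cbind((R + r * cos(vv)) * cos(uu),
               (R + r * cos(vv)) * sin(uu),
               r * sin(vv))
  idx <- function(ui, vi) (ui - 1) * nv + vi
  ui <- g$ui; vi <- g$vi
  ui2 <- ifelse(ui == nu, 1L, ui + 1L)
  vi2 <- ifelse(vi == nv, 1L, vi + 1L)
  f <- rbind(cbind(idx(ui, vi), idx(ui2, vi), idx(ui2, vi2)),
             cbind(idx(ui, vi), idx(ui2, vi2), idx(ui, vi2)))
  m <- fpd_mesh(pts, f, validate = FALSE)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# two-triangle flat square patch in the z = 0 plane
square_patch <- function(side = 1) {
  fpd_mesh(rbind(c(0, 0, 0), c(side, 0, 0), c(side, side, 0), c(0, side, 0)),
           rbind(c(1, 2, 3), c(1, 3, 4)), validate = FALSE)
}

# Rodrigues rotation matrix
rotmat <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# minimal ASCII STL of the unit cube, 12 facets (written by the tests)
write_cube_ascii_stl <- function(path) {
  m <- cuboid_mesh()
  write_mesh(m, path, dialect = "ascii")
  path
}

# hand-built connector site on a mesh whose connector plane is x = x0 with
# occlusal = +z, buccal = +y (used where a detected frame's roll about the
# long axis would be arbitrary, e.g. on surfaces of revolution)
manual_site <- function(x0) {
  xhat <- c(0, 0, 1); yhat <- c(0, 1, 0)
  zhat <- c(xhat[2] * yhat[3] - xhat[3] * yhat[2],
            xhat[3] * yhat[1] - xhat[1] * yhat[3],
            xhat[1] * yhat[2] - xhat[2] * yhat[1])
  structure(list(ordinal = 1L, alpha = NA, beta = NA,
                 e_midcon = list(point = c(x0, 0, 0), normal = c(1, 0, 0)),
                 frame = list(origin = c(x0, 0, 0),
                              x = xhat, y = yhat, z = zhat),
                 station = x0, a0 = NA_real_),
            class = "connector_site")
}

# connector-chart section area of a mesh at a manual site (independent
# re-slicing path used as the area oracle in adjustment tests)
section_area_at <- function(mesh, site) {
  loops <- intersect_plane(mesh, site$e_midcon,
                           chart = list(origin = site$frame$origin,
                                        ex = site$frame$y,
                                        ey = site$frame$x))
  polygon_area(select_connector_loop(loops))
}

# signed distance of a point to a (point, normal) plane
plane_dist_test <- function(plane, p) {
  sum((p - plane$point) * plane$normal)
}

# brute-force interior strict local minima (independent oracle)
brute_minima <- function(x) {
  n <- length(x)
  which(vapply(2:(n - 1), function(i)
    x[i] < x[i - 1] && x[i] < x[i + 1], TRUE)) + 1L
}

# rebuild world vertices from displaced local coordinates of a point set
rebuild_vertices <- function(mesh, site, pts, upd) {
  v <- mesh$vertices
  fr <- site$frame
  v[pts$indices, ] <- rep(fr$origin, each = length(pts$indices)) +
    outer(upd$x, fr$x) + outer(upd$y, fr$y) + outer(pts$z, fr$z)
  m <- mesh
  m$vertices <- v
  m
}

# small default synthetic FPD variants used across tests (coarser pitch
# keeps unit tests quick; the acceptance suite uses the default spec)
coarse_fpd <- function(pitch = 0.3) generate_fpd(fpd_spec(pitch = pitch))
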