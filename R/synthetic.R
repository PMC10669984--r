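# Parametric synthetic prosthesis meshes with exact connector ground
# truth.  An n-unit FPD is modelled as a generalized cylinder swept along
# the mesial-distal axis: wide, tall superellipse sections at the crowns,
# narrow oval superellipse sections at the connector necks, blended with
# C1 smoothstep profiles so each neck is a true local waist exactly at its
# construction station.  The superellipse exponent at each neck is solved
# so the section area equals the requested connector area, which makes the
# ground truth exact up to mesh discretisation.

#' Solve the superellipse exponent for a target area
#'
#' A superellipse `|u/a|^p + |v/b|^p = 1` has area
#' `4ab * gamma(1+1/p)^2 / gamma(1+2/p)`.  Given the full section height
#' `2a`, length `2b` and a target area, returns the exponent `p` that
#' matches the area (dental connectors are "oval" with fuller shoulders
#' than an ellipse, i.e. p > 2 typically).
#'
#' @param height,length full extents of the section (mm).
#' @param area target area (mm^2); must lie strictly between the rhombus
#'   (p = 1) and rectangle (p -> infinity) areas.
#' @return exponent `p`.
#' @export
superellipse_exponent <- function(height, length, area) {
  fill <- area / (height * length)
  if (fill <= 0.5 || fill >= 1)
    stop("area must be between the rhombus (0.5*h*l) and rectangle (h*l)")
  g <- function(p) gamma(1 + 1 / p)^2 / gamma(1 + 2 / p)
  uniroot(function(p) g(p) - fill, c(1.001, 200),
          tol = 1e-12)$root
}

superellipse_area <- function(height, length, p) {
  height * length * gamma(1 + 1 / p)^2 / gamma(1 + 2 / p)
}

# superellipse ring: u = half-width*sgn(cos)|cos|^(2/p), v = half-height*...
superellipse_ring <- function(theta, half_len, half_hgt, p) {
  e <- 2 / p
  cbind(half_len * sign(cos(theta)) * abs(cos(theta))^e,
        half_hgt * sign(sin(theta)) * abs(sin(theta))^e)
}

#' Synthetic FPD specification
#'
#' Defaults emulate a 4-unit posterior bridge of overall extent
#' 32.5 x 11.7 x 9.0 mm whose three connector necks are irregular ovals
#' with heights 5.7/5.7/5.8 mm, lengths 6.8/6.0/6.8 mm and cross-sectional
#' areas 33.1/28.5/33.2 mm^2.
#'
#' @param n_units number of crown/pontic units (default 4; `n-1` necks).
#' @param total_length,total_width,total_height overall extents, mm.
#' @param neck_heights,neck_lengths,neck_areas per-connector section
#'   construction targets (recycled to `n_units - 1`).
#' @param crown_exponent superellipse exponent of the crown sections
#'   (default 3: squarish occlusal table).
#' @param blend_plateau fraction of each crown-to-neck span held at the
#'   crown section before blending (default 0.3; larger = flatter crowns,
#'   sharper necks).
#' @param pitch target mesh edge pitch, mm (default 0.15); must resolve
#'   the smallest neck dimension with at least 6 elements.
#' @param jitter vertex jitter amplitude, mm (default 0 = bit-reproducible).
#' @param seed RNG seed for jitter.
#' @return an `fpd_spec` list (also carries solved neck exponents).
#' @export
fpd_spec <- function(n_units = 4L,
                     total_length = 32.5,
                     total_width = 11.7,
                     total_height = 9.0,
                     neck_heights = c(5.7, 5.7, 5.8),
                     neck_lengths = c(6.8, 6.0, 6.8),
                     neck_areas = c(33.1, 28.5, 33.2),
                     crown_exponent = 3.0,
                     blend_plateau = 0.3,
                     pitch = 0.15,
                     jitter = 0,
                     seed = 42L) {
  n_units <- as.integer(n_units)
  if (n_units < 2L) stop("`n_units` must be at least 2")
  ncon <- n_units - 1L
  neck_heights <- rep_len(neck_heights, ncon)
  neck_lengths <- rep_len(neck_lengths, ncon)
  neck_areas <- rep_len(neck_areas, ncon)
  if (pitch >= min(neck_heights, neck_lengths) / 6)
    stop("`pitch` too coarse to resolve the smallest neck dimension")
  if (any(neck_heights >= total_height) || any(neck_lengths >= total_width))
    stop("neck sections must be smaller than the crown envelope")
  unit <- total_length / n_units
  crown_stations <- (seq_len(n_units) - 0.5) * unit
  neck_stations <- seq_len(ncon) * unit
  p_neck <- vapply(seq_len(ncon), function(j)
    superellipse_exponent(neck_heights[j], neck_lengths[j], neck_areas[j]), 0)
  structure(list(n_units = n_units, total_length = total_length,
                 total_width = total_width, total_height = total_height,
                 crown_stations = crown_stations,
                 neck_stations = neck_stations,
                 neck_heights = neck_heights, neck_lengths = neck_lengths,
                 neck_areas = neck_areas, neck_exponents = p_neck,
                 crown_exponent = crown_exponent,
                 blend_plateau = blend_plateau,
                 pitch = pitch, jitter = jitter, seed = as.integer(seed)),
            class = "fpd_spec")
}

# smoothstep with zero slope at both ends (keeps necks true local minima
# exactly at their construction stations)
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# profile value at stations s, blending crown value -> neck value -> crown
fpd_profile <- function(s, spec, crown_value, neck_values) {
  cs <- spec$crown_stations
  ns <- spec$neck_stations
  rho <- spec$blend_plateau
  n <- spec$n_units
  out <- numeric(length(s))
  for (i in seq_along(s)) {
    si <- s[i]
    if (si <= cs[1] || si >= cs[n]) { out[i] <- crown_value; next }
    seg <- findInterval(si, cs)           # between cs[seg] and cs[seg+1]
    m <- ns[seg]
    if (si <= m) {
      a <- cs[seg] + rho * (m - cs[seg])  # plateau end
      u <- (si - a) / (m - a)
      out[i] <- crown_value +
        (neck_values[seg] - crown_value) * smoothstep(u)
    } else {
      b <- cs[seg + 1] - rho * (cs[seg + 1] - m)
      u <- (b - si) / (b - m)
      out[i] <- crown_value +
        (neck_values[seg] - crown_value) * smoothstep(u)
    }
  }
  out
}

#' Generate a synthetic n-unit FPD mesh with ground truth
#'
#' @param spec an [fpd_spec()].
#' @return list with `mesh` (watertight [fpd_mesh], provenance
#'   `"synthetic"`) and `ground_truth` (data frame: `connector`, `station`
#'   mm, `height`, `length` mm, `area` mm^2, `exponent`).  The mesh long
#'   axis is +X (mesial), height +Z (occlusal), width +Y (buccal), centred
#'   at the origin in Y and Z with X from 0 to `total_length`.
#' @export
generate_fpd <- function(spec = fpd_spec()) {
  L <- spec$total_length
  ns_ax <- max(64L, ceiling(L / spec$pitch) + 1L)
  s <- seq(0, L, length.out = ns_ax)
  # blended section parameters along the sweep
  hh <- fpd_profile(s, spec, spec$total_height, spec$neck_heights) / 2
  hw <- fpd_profile(s, spec, spec$total_width, spec$neck_lengths) / 2
  pp <- fpd_profile(s, spec, spec$crown_exponent, spec$neck_exponents)

  per <- pi * (3 * (spec$total_width / 2 + spec$total_height / 2) -
                 sqrt((3 * spec$total_width / 2 + spec$total_height / 2) *
                        (spec$total_width / 2 + 3 * spec$total_height / 2)))
  nt <- max(48L, ceiling(per / spec$pitch))
  theta <- (seq_len(nt) - 1) / nt * 2 * pi

  nv <- ns_ax * nt
  v <- matrix(0, nv + 2L, 3)
  for (i in seq_len(ns_ax)) {
    ring <- superellipse_ring(theta, hw[i], hh[i], pp[i])
    rows <- (i - 1L) * nt + seq_len(nt)
    v[rows, 1] <- s[i]
    v[rows, 2] <- ring[, 1]
    v[rows, 3] <- ring[, 2]
  }
  # cap centre vertices
  v[nv + 1L, ] <- c(0, 0, 0)
  v[nv + 2L, ] <- c(L, 0, 0)

  f <- sweep_faces(ns_ax, nt, cap_start = nv + 1L, cap_end = nv + 2L)
  mesh <- finalize_synthetic(v, f, spec$jitter, spec$seed)
  gt <- data.frame(connector = seq_len(spec$n_units - 1L),
                   station = spec$neck_stations,
                   height = spec$neck_heights,
                   length = spec$neck_lengths,
                   area = spec$neck_areas,
                   exponent = spec$neck_exponents)
  list(mesh = mesh, ground_truth = gt)
}

# quad strip faces between consecutive rings plus end fans
sweep_faces <- function(ns_ax, nt, cap_start, cap_end) {
  ring <- function(i) (i - 1L) * nt + seq_len(nt)
  nxt <- c(seq_len(nt - 1L) + 1L, 1L)
  side <- vector("list", ns_ax - 1L)
  for (i in seq_len(ns_ax - 1L)) {
    a <- ring(i); b <- ring(i + 1L)
    side[[i]] <- rbind(cbind(a, b[nxt], b), cbind(a, a[nxt], b[nxt]))
  }
  r1 <- ring(1L); rn <- ring(ns_ax)
  caps <- rbind(cbind(cap_start, r1[nxt], r1),
                cbind(cap_end, rn, rn[nxt]))
  f <- rbind(do.call(rbind, side), caps)
  storage.mode(f) <- "integer"
  f
}

finalize_synthetic <- function(v, f, jitter, seed) {
  mesh <- fpd_mesh(v, f, provenance = "synthetic", validate = TRUE)
  if (mesh_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1, 3, 2)]
  if (jitter > 0) {
    n_like <- with_local_seed(seed, function()
      matrix(rnorm(length(mesh$vertices), sd = jitter), ncol = 3))
    mesh$vertices <- mesh$vertices + n_like
  }
  mesh
}

#' Generate a dumbbell fixture (two spheres joined by a cylindrical neck)
#'
#' Minimal one-connector detection fixture: a surface of revolution whose
#' radius profile is the maximum of two sphere caps and a neck cylinder.
#' Ground truth: one connector at `length / 2` with circular section area
#' `pi * neck_radius^2`.
#'
#' @param radius sphere radius, mm.
#' @param neck_radius neck radius, mm (< `radius`).
#' @param length end-to-end length, mm (default `4 * radius`).
#' @param pitch target mesh pitch, mm.
#' @return list with `mesh` and `ground_truth` (one-row data frame).
#' @export
generate_dumbbell <- function(radius = 5, neck_radius = 2,
                              length = 4 * radius, pitch = 0.2) {
  if (neck_radius > radius) stop("`neck_radius` must not exceed `radius`")
  c1 <- radius; c2 <- length - radius
  if (c2 <= c1) stop("`length` too short for the two spheres")
  s <- seq(0, length, length.out = max(64L, ceiling(length / pitch) + 1L))
  sph <- function(c0) sqrt(pmax(0, radius^2 - (s - c0)^2))
  rneck <- ifelse(s >= c1 & s <= c2, neck_radius, 0)
  r <- pmax(sph(c1), sph(c2), rneck)
  mesh <- revolve_profile(s, r, pitch = pitch)
  gt <- data.frame(connector = 1L, station = length / 2,
                   height = 2 * neck_radius, length = 2 * neck_radius,
                   area = pi * neck_radius^2, exponent = 2)
  list(mesh = mesh, ground_truth = gt)
}

#' Generate a capped cylinder (null fixture: no connectors)
#'
#' @param radius,length cylinder dimensions, mm.
#' @param pitch target mesh pitch, mm.
#' @return a watertight [fpd_mesh] with its axis along +X.
#' @export
generate_cylinder <- function(radius = 2, length = 20, pitch = 0.2) {
  if (radius <= 0 || length <= 0) stop("dimensions must be positive")
  s <- seq(0, length, length.out = max(16L, ceiling(length / pitch) + 1L))
  revolve_profile(s, rep(radius, length(s)), pitch = pitch)
}

#' Surface of revolution about the x axis
#'
#' Builds a watertight triangle mesh from a radius profile `r(s)`.
#' Zero radius is allowed only at the two ends (poles); non-zero ends are
#' closed with flat cap fans.
#'
#' @param s strictly increasing stations along x (mm).
#' @param r radii at the stations (mm, >= 0).
#' @param n_theta number of angular samples (default from `pitch`).
#' @param pitch target pitch used to derive `n_theta` when not given.
#' @return a watertight [fpd_mesh], provenance `"synthetic"`.
#' @export
revolve_profile <- function(s, r, n_theta = NULL, pitch = 0.2) {
  if (any(diff(s) <= 0)) stop("`s` must be strictly increasing")
  if (any(r < 0)) stop("radii must be non-negative")
  interior_zero <- r[-c(1, length(r))] <= 0
  if (any(interior_zero)) stop("zero radius allowed only at the ends")
  if (is.null(n_theta))
    n_theta <- max(24L, ceiling(2 * pi * max(r) / pitch))
  theta <- (seq_len(n_theta) - 1) / n_theta * 2 * pi

  ring_ids <- which(r > 0)
  nr <- length(ring_ids)
  v <- matrix(0, nr * n_theta, 3)
  for (k in seq_len(nr)) {
    i <- ring_ids[k]
    rows <- (k - 1L) * n_theta + seq_len(n_theta)
    v[rows, 1] <- s[i]
    v[rows, 2] <- r[i] * cos(theta)
    v[rows, 3] <- r[i] * sin(theta)
  }
  extra <- NULL
  nxt <- c(seq_len(n_theta - 1L) + 1L, 1L)
  ring <- function(k) (k - 1L) * n_theta + seq_len(n_theta)
  side <- vector("list", nr - 1L)
  for (k in seq_len(nr - 1L)) {
    a <- ring(k); b <- ring(k + 1L)
    side[[k]] <- rbind(cbind(a, b[nxt], b), cbind(a, a[nxt], b[nxt]))
  }
  f <- do.call(rbind, side)
  nv <- nr * n_theta
  # a zero-radius end gets a cone fan to the pole point; a non-zero end a
  # flat cap fan -- both are a centre vertex joined to the terminal ring
  extra <- rbind(extra, c(s[1], 0, 0))
  pid <- nv + nrow(extra)
  a <- ring(1L)
  f <- rbind(f, cbind(pid, a[nxt], a))
  extra <- rbind(extra, c(s[length(s)], 0, 0))
  pid <- nv + nrow(extra)
  a <- ring(nr)
  f <- rbind(f, cbind(pid, a, a[nxt]))
  v <- rbind(v, extra)
  storage.mode(f) <- "integer"
  finalize_synthetic(v, f, jitter = 0, seed = 1L)
}

#' UV sphere mesh (test fixture)
#'
#' @param radius sphere radius, mm.
#' @param center length-3 centre.
#' @param n_theta angular resolution (default 48).
#' @return a watertight [fpd_mesh].
#' @export
generate_sphere <- function(radius = 1, center = c(0, 0, 0), n_theta = 48L) {
  ns <- max(8L, n_theta %/% 2L)
  s <- seq(-radius, radius, length.out = ns)
  r <- sqrt(pmax(0, radius^2 - s^2))
  m <- revolve_profile(s - s[1], r, n_theta = n_theta)
  m$vertices[, 1] <- m$vertices[, 1] + s[1]
  m$vertices <- sweep(m$vertices, 2, center, "+")
  m
}
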