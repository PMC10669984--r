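# Connector remodelling: Bezier-weighted localized vertex displacement with
# a bisection solve for the scale parameter k so the connector section hits
# a prescribed cross-sectional area.

#' Bezier-type falloff weight
#'
#' The cubic falloff that tapers vertex displacement from full effect at
#' the connector mid-plane to zero at distance `w`:
#' \deqn{B(t) = (w-t)^3 w + 3 t (w-t)^2 \cdot 0.9 w + 3 t^2 (w-t) \cdot 0.1 w}
#' which is \eqn{w^4} times the cubic Bernstein combination with control
#' values (1, 0.9, 0.1, 0) at \eqn{s = t/w}: strictly decreasing, equal to
#' \eqn{w^4} at \eqn{t = 0} and 0 at \eqn{t = w}.
#'
#' @param t distance to the connector mid-plane, mm (vectorised).
#' @param w falloff width, mm.
#' @return weight value(s), scale mm^4.
#' @export
bezier_weight <- function(t, w) {
  if (w <= 0) stop("`w` must be positive")
  out_of_range <- t < 0 | t > w
  if (any(out_of_range)) t <- pmin(pmax(t, 0), w)
  (w - t)^3 * w + 3 * t * (w - t)^2 * 0.9 * w + 3 * t^2 * (w - t) * 0.1 * w
}

#' Adjustment specification for one connector
#'
#' @param direction one of `"occlusal"`, `"gingival"`, `"lingual"`,
#'   `"buccal"`, `"iso"` (iso = all four simultaneously with one shared k).
#' @param target_area absolute target cross-sectional area `A_input`
#'   (mm^2); exactly one of `target_area` / `reduction` must be given.
#' @param reduction fractional reduction of the initial area (e.g. 0.1
#'   for a 10 percent smaller section); resolved to an absolute target at
#'   spec creation against `a0`.
#' @param a0 initial connector area (required with `reduction`, and used
#'   to validate `target_area`).
#' @param w falloff width, mm (default 1.0).
#' @param tolerance area matching tolerance, mm^2 (default 0.001).
#' @return an `adjustment_spec` list.
#' @export
adjustment_spec <- function(direction = c("iso", "occlusal", "gingival",
                                          "lingual", "buccal"),
                            target_area = NULL, reduction = NULL,
                            a0 = NULL, w = 1.0, tolerance = 0.001) {
  direction <- match.arg(direction)
  if (is.null(target_area) == is.null(reduction))
    stop("give exactly one of `target_area` or `reduction`")
  if (!is.null(reduction)) {
    if (is.null(a0)) stop("`reduction` needs `a0` to resolve the target")
    if (reduction <= 0 || reduction >= 1)
      stop("`reduction` must be in (0, 1)")
    target_area <- (1 - reduction) * a0
  }
  if (!is.null(a0) && (target_area <= 0 || target_area > a0))
    stop("`target_area` must be in (0, A0]")
  if (w <= 0) stop("`w` must be positive")
  if (tolerance <= 0) stop("`tolerance` must be positive")
  structure(list(direction = direction, target_area = target_area,
                 w = w, tolerance = tolerance),
            class = "adjustment_spec")
}

#' Select the connector point set
#'
#' All mesh vertices strictly closer than `w` to the connector mid-plane,
#' with their local-frame coordinates and directional subsets: occlusal
#' (x > 0), gingival (x < 0), buccal (y > 0), lingual (y < 0).  The
#' distance to the mid-plane is `|z|` in the local frame.
#'
#' @param mesh an [fpd_mesh].
#' @param site a `connector_site`.
#' @param w falloff width, mm.
#' @return a `connector_points` list: `indices` (vertex rows), local
#'   coordinates `x`, `y`, `z`, subsets `occlusal`, `gingival`, `buccal`,
#'   `lingual` (logical over the selection), and `w`.
#' @export
select_points <- function(mesh, site, w = 1.0) {
  if (w <= 0) stop("`w` must be positive")
  fr <- site$frame
  rel <- sweep(mesh$vertices, 2, fr$origin)
  z <- as.vector(rel %*% fr$z)
  sel <- which(abs(z) < w)
  if (length(sel) == 0L)
    stop("no vertices within w of the connector plane (w too small?)")
  rels <- rel[sel, , drop = FALSE]
  x <- as.vector(rels %*% fr$x)
  y <- as.vector(rels %*% fr$y)
  structure(list(indices = sel, x = x, y = y, z = z[sel],
                 occlusal = x > 0, gingival = x < 0,
                 buccal = y > 0, lingual = y < 0, w = w),
            class = "connector_points")
}

#' Apply the displacement law to local coordinates
#'
#' The occlusal law moves each selected occlusal-side vertex toward the
#' occluso-gingival mid-plane:
#' \deqn{x_{new} = x - k \, d_{yz} \, B(d_{xy}) \, x}
#' with \eqn{d_{yz} = |x|} (distance to the y-z plane) and
#' \eqn{d_{xy} = |z|} (distance to the connector mid-plane).  The gingival
#' law is the same formula on the gingival subset (the \eqn{|x|} factor
#' makes it sign-symmetric); lingual/buccal exchange the roles of x and y
#' (\eqn{d_{xz} = |y|} replacing \eqn{d_{yz}}); `iso` applies all four
#' with the same k.  Coordinates of vertices outside the addressed subset
#' are returned bit-identical.
#'
#' @param points a `connector_points` set from [select_points()].
#' @param k displacement scale, `0 <= k <= k_max(points, direction)`.
#' @param w falloff width, mm (defaults to the selection width).
#' @param direction adjustment direction (see [adjustment_spec()]).
#' @return list with updated local coordinate vectors `x` and `y`.
#' @export
apply_displacement <- function(points, k,
                               w = points$w,
                               direction = c("iso", "occlusal", "gingival",
                                             "lingual", "buccal")) {
  direction <- match.arg(direction)
  if (k < 0) stop("`k` must be non-negative")
  kmax <- k_max(points, direction, w)
  if (k > kmax)
    stop(sprintf("k = %g exceeds fold-over bound k_max = %g", k, kmax))
  x <- points$x; y <- points$y
  if (k == 0) return(list(x = x, y = y))
  B <- bezier_weight(abs(points$z), w)
  mx <- switch(direction,
               occlusal = points$occlusal,
               gingival = points$gingival,
               iso = rep(TRUE, length(x)),
               rep(FALSE, length(x)))
  my <- switch(direction,
               buccal = points$buccal,
               lingual = points$lingual,
               iso = rep(TRUE, length(y)),
               rep(FALSE, length(y)))
  if (any(mx))
    x[mx] <- x[mx] - k * abs(x[mx]) * B[mx] * x[mx]
  if (any(my))
    y[my] <- y[my] - k * abs(y[my]) * B[my] * y[my]
  list(x = x, y = y)
}

# Fold-over guard: the in-slice map x -> x (1 - k |x| B) must stay
# injective, i.e. its derivative 1 - 2 k |x| B must stay positive for every
# addressed coordinate.  (Mere positivity of the shrink factor is not
# enough: beyond half this bound the map folds the section onto itself.)
k_max <- function(points, direction, w = points$w) {
  B <- bezier_weight(abs(points$z), w)
  den <- 0
  if (direction %in% c("occlusal", "gingival", "iso")) {
    mx <- if (direction == "iso") rep(TRUE, length(points$x))
          else points[[direction]]
    if (any(mx)) den <- max(den, max(abs(points$x[mx]) * B[mx]))
  }
  if (direction %in% c("buccal", "lingual", "iso")) {
    my <- if (direction == "iso") rep(TRUE, length(points$y))
          else points[[direction]]
    if (any(my)) den <- max(den, max(abs(points$y[my]) * B[my]))
  }
  if (den <= 0) return(Inf)
  0.99 / (2 * den)
}

# Displaced copy of the full vertex matrix for a given k.
displaced_vertices <- function(mesh, site, points, k, w, direction) {
  v <- mesh$vertices
  if (k == 0) return(v)
  upd <- apply_displacement(points, k, w, direction)
  moved <- upd$x != points$x | upd$y != points$y
  if (!any(moved)) return(v)
  fr <- site$frame
  idx <- points$indices[moved]
  v[idx, ] <- rep(fr$origin, each = length(idx)) +
    outer(upd$x[moved], fr$x) + outer(upd$y[moved], fr$y) +
    outer(points$z[moved], fr$z)
  v
}

# Section area of (possibly displaced) vertices at the site's original
# mid-plane, connector loop only.
site_section_area <- function(vertices, faces, site) {
  loops <- plane_section_loops3d(vertices, faces, site$e_midcon,
                                 warn_open = FALSE)
  if (length(loops) == 0L)
    stop("no section loop at the connector plane (connector vanished?)")
  fr <- site$frame
  polys <- lapply(loops, function(m) {
    rel <- sweep(m, 2, fr$origin)
    planar_polygon(cbind(rel %*% fr$y, rel %*% fr$x),
                   plane = site$e_midcon,
                   chart = list(origin = fr$origin, ex = fr$y, ey = fr$x))
  })
  loop <- suppressWarnings(select_connector_loop(polys))
  polygon_area(loop, check = FALSE)
}

#' Solve the displacement scale k for a target area
#'
#' Bisection on the monotone map from k to the connector cross-sectional
#' area (measured at the site's *original* mid-plane), terminating when
#' the measured area is within `spec$tolerance` of the target
#' (default 0.001 mm^2).  The area decreases monotonically in k, so
#' deterministic bracketed root-finding replaces any stochastic optimiser.
#'
#' @param mesh an [fpd_mesh].
#' @param site a `connector_site` detected on this mesh.
#' @param spec an [adjustment_spec()].
#' @param max_iter maximum bisection iterations (default 200).
#' @return an `adjustment_result`: list with `k`, `a_initial`, `a_final`,
#'   `iterations`, `achieved` (mm^2, `<= tolerance` on success),
#'   `displaced_count`, `direction`, `target_area`.
#' @export
solve_k <- function(mesh, site, spec, max_iter = 200L) {
  target <- spec$target_area
  w <- spec$w
  tol <- spec$tolerance
  f <- mesh$faces
  a0 <- site_section_area(mesh$vertices, f, site)
  if (target > a0 + tol)
    stop(sprintf("target area %.3f exceeds initial area %.3f", target, a0))
  points <- select_points(mesh, site, w)
  if (abs(a0 - target) <= tol)
    return(adjustment_result(0, a0, a0, 0L, abs(a0 - target), 0L, spec))

  khi <- k_max(points, spec$direction, w)
  if (!is.finite(khi))
    stop("no displaceable vertices for this direction")
  area_at <- function(k)
    site_section_area(displaced_vertices(mesh, site, points, k, w,
                                         spec$direction), f, site)
  a_hi <- area_at(khi)
  if (a_hi > target + tol)
    stop(sprintf(
      "target %.3f mm^2 unreachable: minimum achievable area is %.3f mm^2",
      target, a_hi))
  if (a_hi > a0)
    stop("non-monotone area response (pathological mesh)")

  lo <- 0; hi <- khi
  it <- 0L
  k <- NA_real_; a_k <- NA_real_
  repeat {
    it <- it + 1L
    k <- (lo + hi) / 2
    a_k <- area_at(k)
    if (abs(a_k - target) <= tol) break
    if (a_k > target) lo <- k else hi <- k
    if (it >= max_iter)
      stop(sprintf("bisection did not reach tolerance %.2g after %d iterations",
                   tol, max_iter))
  }
  upd <- apply_displacement(points, k, w, spec$direction)
  moved <- sum(upd$x != points$x | upd$y != points$y)
  adjustment_result(k, a0, a_k, it, abs(a_k - target), moved, spec)
}

adjustment_result <- function(k, a0, a2, iterations, achieved, moved, spec) {
  structure(list(k = k, a_initial = a0, a_final = a2,
                 iterations = iterations, achieved = achieved,
                 displaced_count = as.integer(moved),
                 direction = spec$direction,
                 target_area = spec$target_area,
                 tolerance = spec$tolerance, w = spec$w),
            class = "adjustment_result")
}

#' @export
print.adjustment_result <- function(x, ...) {
  cat(sprintf(
    paste0("<adjustment_result: %s, A %.3f -> %.3f mm^2 (target %.3f), ",
           "k = %.6g, %d iterations, |dA| = %.2g mm^2>\n"),
    x$direction, x$a_initial, x$a_final, x$target_area, x$k,
    x$iterations, x$achieved))
  invisible(x)
}

#' Adjust one connector of a mesh
#'
#' Solves for k (see [solve_k()]) and reconstructs the mesh with the
#' displaced vertices.  Face connectivity is untouched: adjustment moves
#' vertices only, and vertices farther than `w` from the connector plane
#' are bit-identical to the input.
#'
#' @param mesh an [fpd_mesh].
#' @param site a `connector_site` detected on this mesh.
#' @param spec an [adjustment_spec()].
#' @return list with `mesh` (provenance `"adjusted"`) and `result`
#'   (`adjustment_result`).
#' @export
adjust_connector <- function(mesh, site, spec) {
  res <- solve_k(mesh, site, spec)
  v <- if (res$k == 0) mesh$vertices else {
    points <- select_points(mesh, site, spec$w)
    displaced_vertices(mesh, site, points, res$k, spec$w, spec$direction)
  }
  out <- structure(list(vertices = v, faces = mesh$faces,
                        provenance = "adjusted"),
                   class = "fpd_mesh")
  list(mesh = out, result = res)
}
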