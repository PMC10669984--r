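# Planar cross-sections: mesh/plane intersection loops, in-plane charts,
# shoelace area, centroid, extents and second moments.  This module is the
# area oracle used both by connector detection and by the k-solver.

# Raw mesh/plane intersection: returns a list of closed loops, each an
# n x 3 matrix of 3-D points, plus open chains (normally none on a
# watertight mesh).  Vertices lying exactly on the plane are nudged to the
# positive side by `eps` so every crossing triangle contributes exactly one
# well-defined segment.
plane_section_loops3d <- function(vertices, faces, plane, eps = 1e-9,
                                  warn_open = TRUE) {
  d <- plane_signed_dist(plane, vertices)
  d[abs(d) < eps] <- eps
  s <- matrix(d[faces], ncol = 3)
  neg <- s < 0
  nneg <- rowSums(neg)
  cross <- nneg == 1L | nneg == 2L
  if (!any(cross)) return(list())
  f <- faces[cross, , drop = FALSE]
  sc <- s[cross, , drop = FALSE]

  seg_from <- matrix(0, nrow(f), 3)
  seg_to <- matrix(0, nrow(f), 3)
  got_first <- rep(FALSE, nrow(f))
  pair <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  for (e in 1:3) {
    i <- pair[[e]][1]; j <- pair[[e]][2]
    hit <- sc[, i] * sc[, j] < 0
    if (!any(hit)) next
    t <- sc[hit, i] / (sc[hit, i] - sc[hit, j])
    va <- vertices[f[hit, i], , drop = FALSE]
    vb <- vertices[f[hit, j], , drop = FALSE]
    p <- va + t * (vb - va)
    firsts <- hit & !got_first
    seconds <- hit & got_first
    if (any(firsts)) seg_from[firsts, ] <- p[!got_first[hit], , drop = FALSE]
    if (any(seconds)) seg_to[seconds, ] <- p[got_first[hit], , drop = FALSE]
    got_first[hit] <- TRUE
  }

  chain_segments(seg_from, seg_to, warn_open = warn_open)
}

# Chain a segment soup into closed loops by endpoint matching.  Endpoints
# are matched by a hashed rounding grid with neighbour-cell fallback, so a
# match never fails because two nearly-identical points straddle a rounding
# boundary (which happens when a slicing plane passes exactly through a
# vertex ring).  Degenerate (near-zero-length) segments are dropped first.
chain_segments <- function(seg_from, seg_to, match_tol = 1e-6,
                           warn_open = TRUE) {
  if (nrow(seg_from) == 0L) return(list())
  keep <- rowSums((seg_from - seg_to)^2) > 1e-14
  seg_from <- seg_from[keep, , drop = FALSE]
  seg_to <- seg_to[keep, , drop = FALSE]
  n <- nrow(seg_from)
  if (n == 0L) return(list())

  mkkey <- function(P) paste(round(P[, 1] / match_tol),
                             round(P[, 2] / match_tol),
                             round(P[, 3] / match_tol))
  kf <- mkkey(seg_from)
  kt <- mkkey(seg_to)
  ends <- new.env(hash = TRUE, parent = emptyenv())
  kk <- c(kf, kt)
  ii <- rep(seq_len(n), 2L)
  for (i in seq_along(kk)) {
    prev <- get0(kk[i], envir = ends)
    assign(kk[i], c(prev, ii[i]), envir = ends)
  }
  neigh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  neigh <- neigh[rowSums(abs(neigh)) > 0, , drop = FALSE]
  lookup <- function(key, p) {
    ids <- get0(key, envir = ends)
    # fall back to the 26 neighbouring rounding cells only when the exact
    # cell has no unused candidate (points straddling a cell boundary)
    if (is.null(ids) || all(used[ids])) {
      base <- round(p / match_tol)
      for (r in seq_len(26)) {
        v <- get0(paste(base[1] + neigh[r, 1], base[2] + neigh[r, 2],
                        base[3] + neigh[r, 3]), envir = ends)
        if (!is.null(v)) ids <- c(ids, v)
      }
    }
    unique(ids)
  }

  used <- rep(FALSE, n)
  loops <- list()
  n_open <- 0L
  close_tol2 <- (2 * match_tol)^2
  for (s0 in seq_len(n)) {
    if (used[s0]) next
    used[s0] <- TRUE
    loop_pts <- list(seg_from[s0, ], seg_to[s0, ])
    start <- seg_from[s0, ]
    cur <- seg_to[s0, ]
    cur_key <- kt[s0]
    closed <- FALSE
    repeat {
      if (sum((cur - start)^2) <= close_tol2) { closed <- TRUE; break }
      cand <- lookup(cur_key, cur)
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break
      df <- rowSums((seg_from[cand, , drop = FALSE] -
                       matrix(cur, length(cand), 3, byrow = TRUE))^2)
      dt <- rowSums((seg_to[cand, , drop = FALSE] -
                       matrix(cur, length(cand), 3, byrow = TRUE))^2)
      dmin <- pmin(df, dt)
      best <- which.min(dmin)
      if (dmin[best] > close_tol2) break
      nxt <- cand[best]
      used[nxt] <- TRUE
      if (df[best] <= dt[best]) {
        loop_pts[[length(loop_pts) + 1]] <- seg_to[nxt, ]
        cur <- seg_to[nxt, ]
        cur_key <- kt[nxt]
      } else {
        loop_pts[[length(loop_pts) + 1]] <- seg_from[nxt, ]
        cur <- seg_from[nxt, ]
        cur_key <- kf[nxt]
      }
    }
    if (closed) {
      m <- do.call(rbind, loop_pts[-length(loop_pts)])  # drop repeated start
      if (nrow(m) >= 3L) loops[[length(loops) + 1]] <- m
    } else {
      n_open <- n_open + 1L
    }
  }
  if (n_open > 0L && warn_open)
    warning(sprintf("%d open intersection chain(s) dropped (non-watertight?)",
                    n_open))
  loops
}

#' Intersect a mesh with a plane
#'
#' Computes all closed intersection loops of the mesh surface with a plane
#' and projects each into an in-plane 2-D chart.  On a watertight mesh the
#' intersection consists of closed loops only; open chains (from boundary
#' edges) are dropped with a warning.
#'
#' @param mesh an [fpd_mesh].
#' @param plane a plane as `list(point=, normal=)` with unit normal
#'   (see `new_plane`).
#' @param chart optional list with `origin`, `ex`, `ey`: in-plane chart.
#'   `ex` and `ey` must be orthonormal in-plane axes; chart coordinates are
#'   `(u, v) = ((p - origin).ex, (p - origin).ey)`.  Defaults to an
#'   arbitrary orthonormal in-plane pair through the plane point.
#' @return list of [planar_polygon] objects (possibly empty).
#' @export
intersect_plane <- function(mesh, plane, chart = NULL) {
  plane <- new_plane(plane$point, plane$normal)
  loops <- plane_section_loops3d(mesh$vertices, mesh$faces, plane)
  if (is.null(chart)) {
    ref <- if (abs(plane$normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ex <- unitize(cross3(plane$normal, ref))
    ey <- cross3(plane$normal, ex)
    chart <- list(origin = plane$point, ex = ex, ey = ey)
  }
  lapply(loops, function(m) {
    rel <- sweep(m, 2, chart$origin)
    uv <- cbind(rel %*% chart$ex, rel %*% chart$ey)
    planar_polygon(uv, plane = plane, chart = chart)
  })
}

#' Planar polygon in an in-plane chart
#'
#' A closed simple polygon living in a 3-D plane, stored as ordered 2-D
#' chart coordinates.  Nearly-collinear chains are cleaned up and the
#' orientation is normalised counter-clockwise.
#'
#' @param uv 2-column matrix of chart coordinates (mm).
#' @param plane owning plane `list(point=, normal=)`.
#' @param chart chart `list(origin=, ex=, ey=)`.
#' @param cleanup_tol collinear-point cleanup tolerance (default 1e-9 mm).
#' @return an object of class `planar_polygon`.
#' @export
planar_polygon <- function(uv, plane = NULL, chart = NULL,
                           cleanup_tol = 1e-9) {
  uv <- as.matrix(uv)
  if (ncol(uv) != 2L) stop("`uv` must have two columns")
  uv <- dedup_consecutive(uv, 1e-7)
  uv <- drop_collinear(uv, cleanup_tol)
  if (nrow(uv) < 3L) stop("polygon must have at least 3 vertices")
  if (shoelace(uv) < 0) uv <- uv[rev(seq_len(nrow(uv))), , drop = FALSE]
  structure(list(plane = plane, chart = chart, vertices = uv, closed = TRUE),
            class = "planar_polygon")
}

# merge runs of (cyclically) consecutive near-identical points
dedup_consecutive <- function(uv, tol) {
  n <- nrow(uv)
  if (n < 2L) return(uv)
  keep <- c(TRUE, rowSums(diff(uv)^2) > tol^2)
  uv <- uv[keep, , drop = FALSE]
  n <- nrow(uv)
  if (n >= 2L && sum((uv[1, ] - uv[n, ])^2) <= tol^2)
    uv <- uv[-n, , drop = FALSE]
  uv
}

drop_collinear <- function(uv, tol) {
  n <- nrow(uv)
  if (n < 4L) return(uv)
  prev <- uv[c(n, seq_len(n - 1L)), , drop = FALSE]
  nxt <- uv[c(seq_len(n - 1L) + 1L, 1L), , drop = FALSE]
  a <- uv - prev
  b <- nxt - uv
  cr <- abs(a[, 1] * b[, 2] - a[, 2] * b[, 1])
  keep <- cr > tol | (abs(a[, 1]) + abs(a[, 2]) < tol / 10)
  # always keep at least a triangle
  if (sum(keep) < 3L) return(uv)
  uv[keep, , drop = FALSE]
}

shoelace <- function(uv) {
  x <- uv[, 1]; y <- uv[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

is_simple_polygon <- function(uv) {
  n <- nrow(uv)
  if (n < 3L) return(FALSE)
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), n)
  sel <- j > i + 1L & !(i == 1L & j == n)
  i <- i[sel]; j <- j[sel]
  nxt <- function(k) ifelse(k == n, 1L, k + 1L)
  p1 <- uv[i, , drop = FALSE]; p2 <- uv[nxt(i), , drop = FALSE]
  p3 <- uv[j, , drop = FALSE]; p4 <- uv[nxt(j), , drop = FALSE]
  d1 <- p2 - p1; d2 <- p4 - p3
  den <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  dx <- p3 - p1
  t <- (dx[, 1] * d2[, 2] - dx[, 2] * d2[, 1]) / den
  u <- (dx[, 1] * d1[, 2] - dx[, 2] * d1[, 1]) / den
  hit <- is.finite(t) & is.finite(u) &
    t > 1e-12 & t < 1 - 1e-12 & u > 1e-12 & u < 1 - 1e-12
  !any(hit)
}

#' Polygon area (shoelace)
#'
#' @param poly a [planar_polygon].
#' @param check verify the polygon is simple (non-self-intersecting) first
#'   (default `TRUE`; the internal solver loop skips the check).
#' @return area in mm^2 (positive).
#' @export
polygon_area <- function(poly, check = TRUE) {
  uv <- poly$vertices
  if (check && !is_simple_polygon(uv))
    stop("polygon is self-intersecting")
  abs(shoelace(uv))
}

#' Cross-section metrics of a planar polygon
#'
#' Area, centroid, chart-axis extents and principal second moments of area
#' by the standard polygon moment formulas.  With the connector chart
#' convention (`ex` = buccal, `ey` = occlusal), `height` is the
#' occluso-gingival extent and `length` the bucco-lingual extent, matching
#' the usual clinical descriptors of a connector section.
#'
#' @param poly a [planar_polygon].
#' @return a `section_metrics` list: `area` (mm^2), `centroid` (chart mm),
#'   `height`, `length` (mm), `principal_moments` (mm^4, ascending).
#' @export
section_metrics <- function(poly) {
  uv <- poly$vertices
  if (!is_simple_polygon(uv)) stop("polygon is self-intersecting")
  x <- uv[, 1]; y <- uv[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- 0.5 * sum(cr)
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  # second moments about the origin
  ixx <- sum((y^2 + y * yn + yn^2) * cr) / 12
  iyy <- sum((x^2 + x * xn + xn^2) * cr) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  # parallel-axis shift to the centroid
  ixx <- ixx - A * cy^2
  iyy <- iyy - A * cx^2
  ixy <- ixy - A * cx * cy
  pm <- sort(eigen(matrix(c(ixx, -ixy, -ixy, iyy), 2, 2),
                   symmetric = TRUE)$values)
  structure(list(area = abs(A),
                 centroid = c(cx, cy),
                 length = diff(range(x)),
                 height = diff(range(y)),
                 principal_moments = pm),
            class = "section_metrics")
}

#' @export
print.section_metrics <- function(x, ...) {
  cat(sprintf(
    "<section_metrics: area %.3f mm^2, height %.2f mm, length %.2f mm>\n",
    x$area, x$height, x$length))
  invisible(x)
}

#' Select the connector loop among section loops
#'
#' The connector section is the loop whose centroid lies nearest the
#' connector frame origin; distant artifact loops (e.g. a neighbouring
#' unit grazed by the plane) are rejected.
#'
#' @param loops list of [planar_polygon] (chart coordinates centred on the
#'   connector frame origin).
#' @param site optional `connector_site`; reserved for future tie-breaks.
#' @return the selected [planar_polygon].
#' @export
select_connector_loop <- function(loops, site = NULL) {
  if (length(loops) == 0L)
    stop("no section loop at the connector plane (connector vanished?)")
  if (length(loops) == 1L) return(loops[[1]])
  d <- vapply(loops, function(p) {
    m <- section_metrics_basic(p$vertices)
    sqrt(sum(m$centroid^2))
  }, 0)
  o <- order(d)
  if (length(loops) > 1L && d[o[2]] - d[o[1]] < 1)
    warning("multiple section loops within 1 mm of the connector origin")
  loops[[o[1]]]
}

# centroid/area without simplicity checks (internal fast path)
section_metrics_basic <- function(uv) {
  x <- uv[, 1]; y <- uv[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- 0.5 * sum(cr)
  if (abs(A) < 1e-14) return(list(area = 0, centroid = colMeans(uv)))
  list(area = abs(A),
       centroid = c(sum((x + xn) * cr) / (6 * A),
                    sum((y + yn) * cr) / (6 * A)))
}
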