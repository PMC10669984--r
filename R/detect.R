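# Automatic connector detection: slice the prosthesis with equally spaced
# planes perpendicular to the mid axis L1, bound each intersection in a
# box-aligned rectangle split at the occlusal/gingival mid-plane, and take
# the paired local minima of the two rectangle-area series as connector
# stations.

#' Slice profiles along the mid axis
#'
#' Generates `n_planes` equally spaced planes perpendicular to the mid
#' axis (endpoints excluded by a half-spacing margin), intersects each
#' with the mesh, and bounds the intersection curves with a rectangle
#' whose sides are parallel to the box axes, split by the mid-plane
#' `E_mid` into an occlusal and a gingival sub-rectangle.
#'
#' @param mesh an [fpd_mesh].
#' @param box an `oriented_box` from [fit_oriented_box()].
#' @param n_planes number of slicing planes (default 300, minimum 10).
#' @return list of `slice_profile` records with elements `index` (1-based),
#'   `station` (mm along the mid axis from the distal face), `plane`,
#'   `curves` (list of n x 3 loop matrices), `rect` (named in-plane bounds),
#'   `a_occ`, `a_gin` (mm^2).
#' @export
slice_profiles <- function(mesh, box, n_planes = 300L) {
  if (n_planes < 10L) stop("`n_planes` must be at least 10")
  ax <- mid_axis(box)
  L <- ax$length
  stations <- (seq_len(n_planes) - 0.5) / n_planes * L
  v <- mesh$vertices
  md <- as.vector(v %*% box$axis_md)
  md0 <- sum(ax$start * box$axis_md)
  og <- as.vector(v %*% box$axis_og)
  lb <- as.vector(v %*% box$axis_lb)
  og_mid <- sum(box$center * box$axis_og)
  lb_mid <- sum(box$center * box$axis_lb)

  f <- mesh$faces
  eps <- 1e-9
  out <- vector("list", n_planes)
  empty_interior <- 0L
  for (i in seq_len(n_planes)) {
    st <- stations[i]
    d <- md - (md0 + st)
    d[abs(d) < eps] <- eps
    s <- matrix(d[f], ncol = 3)
    nneg <- rowSums(s < 0)
    cross <- nneg == 1L | nneg == 2L
    plane <- new_plane(ax$start + st * box$axis_md, box$axis_md)
    if (!any(cross)) {
      out[[i]] <- structure(list(index = i, station = st, plane = plane,
                                 curves = list(), rect = NULL,
                                 a_occ = 0, a_gin = 0),
                            class = "slice_profile")
      empty_interior <- empty_interior + 1L
      next
    }
    loops <- plane_section_segments(v, f[cross, , drop = FALSE],
                                    s[cross, , drop = FALSE])
    if (length(loops) == 0L) {
      # e.g. a plane grazing the surface tangentially
      out[[i]] <- structure(list(index = i, station = st, plane = plane,
                                 curves = list(), rect = NULL,
                                 a_occ = 0, a_gin = 0),
                            class = "slice_profile")
      next
    }
    rect <- split_rectangles_from_coords(loops, box, og_mid, lb_mid)
    out[[i]] <- structure(list(index = i, station = st, plane = plane,
                               curves = loops, rect = rect$rect,
                               a_occ = rect$a_occ, a_gin = rect$a_gin),
                          class = "slice_profile")
  }
  if (empty_interior > 0L)
    warning(sprintf("%d plane(s) missed the mesh (open or undersized input?)",
                    empty_interior))
  out
}

# segment extraction + chaining given precomputed signed distances
plane_section_segments <- function(vertices, f, sc) {
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
    firsts_local <- !got_first[hit]
    tmp_from <- seg_from[hit, , drop = FALSE]
    tmp_to <- seg_to[hit, , drop = FALSE]
    tmp_from[firsts_local, ] <- p[firsts_local, , drop = FALSE]
    tmp_to[!firsts_local, ] <- p[!firsts_local, , drop = FALSE]
    seg_from[hit, ] <- tmp_from
    seg_to[hit, ] <- tmp_to
    got_first[hit] <- TRUE
  }
  chain_segments(seg_from, seg_to, warn_open = FALSE)
}

# rectangle split given in-plane scalar coordinates of the loop points
split_rectangles_from_coords <- function(loops, box, og_mid, lb_mid) {
  pts <- do.call(rbind, loops)
  og <- as.vector(pts %*% box$axis_og)
  lb <- as.vector(pts %*% box$axis_lb)
  og_rng <- range(og); lb_rng <- range(lb)
  width <- diff(lb_rng)
  h_occ <- max(0, og_rng[2] - max(og_rng[1], og_mid))
  h_gin <- max(0, min(og_rng[2], og_mid) - og_rng[1])
  list(rect = list(og_min = og_rng[1], og_max = og_rng[2],
                   lb_min = lb_rng[1], lb_max = lb_rng[2],
                   og_mid = og_mid, lb_mid = lb_mid),
       a_occ = width * h_occ,
       a_gin = width * h_gin)
}

#' Split the bounding rectangle of slice curves at the mid-plane
#'
#' Bounds planar intersection curves with a rectangle whose sides are
#' parallel to the lingual-buccal and occlusal-gingival box axes, then
#' clips that full rectangle by the mid-plane `E_mid` into occlusal and
#' gingival sub-rectangles.  The two sub-rectangles share their boundary on
#' `E_mid` and their full lingual-buccal extent, so their areas always sum
#' to the full rectangle area.
#'
#' @param curves list of n x 3 matrices (closed loops in one slicing plane).
#' @param box an `oriented_box`.
#' @return list with `rect` (scalar in-plane bounds), `a_occ` and `a_gin`
#'   (mm^2); zero areas for empty input.
#' @export
split_rectangles <- function(curves, box) {
  if (length(curves) == 0L)
    return(list(rect = NULL, a_occ = 0, a_gin = 0))
  split_rectangles_from_coords(curves, box,
                               og_mid = sum(box$center * box$axis_og),
                               lb_mid = sum(box$center * box$axis_lb))
}

#' Paired local minima of the occlusal/gingival area series
#'
#' Finds interior local minima of the (optionally smoothed) occlusal
#' rectangle-area series and of the gingival series separately, keeps those
#' with prominence at least `prominence` times the series range, and pairs
#' occlusal with gingival minima by nearest slice index within
#' `pairing_window`.  Separate minima allow oblique connectors (the
#' occlusal and gingival waists need not lie in the same slice).
#'
#' @param profiles list of `slice_profile` from [slice_profiles()], or a
#'   list with numeric vectors `a_occ`, `a_gin`.
#' @param smooth_window centred moving-average window in slices (default 5;
#'   1 disables smoothing).
#' @param prominence minimum prominence as a fraction of the series range
#'   (default 0.05).
#' @param pairing_window maximum index separation when pairing occlusal
#'   and gingival minima (default 15 slices).
#' @return data frame with columns `alpha` (occlusal minimum slice index,
#'   1-based), `beta` (gingival), ordered distal to mesial; zero rows when
#'   no connector is found.
#' @export
find_connector_minima <- function(profiles, smooth_window = 5L,
                                  prominence = 0.05,
                                  pairing_window = 15L) {
  if (!is.null(profiles$a_occ)) {
    a_occ <- profiles$a_occ
    a_gin <- profiles$a_gin
  } else {
    a_occ <- vapply(profiles, `[[`, 0, "a_occ")
    a_gin <- vapply(profiles, `[[`, 0, "a_gin")
  }
  if (length(a_occ) < 10L) stop("need at least 10 profiles")
  so <- moving_average(a_occ, smooth_window)
  sg <- moving_average(a_gin, smooth_window)
  alpha <- prominent_minima(so, prominence)
  beta <- prominent_minima(sg, prominence)

  if (length(alpha) == 0L || length(beta) == 0L)
    return(data.frame(alpha = integer(0), beta = integer(0)))

  # greedy nearest-index pairing
  pairs <- list()
  bfree <- rep(TRUE, length(beta))
  for (a in alpha) {
    d <- abs(beta - a)
    d[!bfree] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= pairing_window) {
      bfree[j] <- FALSE
      pairs[[length(pairs) + 1]] <- c(a, beta[j])
    } else {
      warning(sprintf("unpaired occlusal minimum at slice %d dropped", a))
    }
  }
  if (any(bfree) && length(beta[bfree]) > 0L && length(pairs) < length(beta))
    for (b in beta[bfree])
      warning(sprintf("unpaired gingival minimum at slice %d dropped", b))
  if (length(pairs) == 0L)
    return(data.frame(alpha = integer(0), beta = integer(0)))
  m <- do.call(rbind, pairs)
  m <- m[order(m[, 1]), , drop = FALSE]
  data.frame(alpha = m[, 1], beta = m[, 2])
}

moving_average <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  h <- window %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# interior strict local minima with prominence filter; an absolute floor of
# 1e-9 mm^2 (relative to series scale) rejects float-noise minima on flat
# series
prominent_minima <- function(x, prom_frac) {
  n <- length(x)
  rng <- diff(range(x))
  floor_abs <- max(1e-9, 1e-9 * max(abs(x)))
  if (rng <= floor_abs) return(integer(0))
  idx <- which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] < x[3:n]) + 1L
  if (length(idx) == 0L) return(integer(0))
  keep <- vapply(idx, function(i) {
    v <- x[i]
    left <- x[seq_len(i - 1)]
    right <- x[seq(i + 1, n)]
    lower_l <- which(left < v)
    lower_r <- which(right < v)
    lmax <- if (length(lower_l) == 0L) max(left) else {
      span <- left[seq(max(lower_l) + 1L, i - 1L)]
      if (length(span) == 0L) v else max(span)
    }
    rmax <- if (length(lower_r) == 0L) max(right) else {
      span <- right[seq_len(min(lower_r) - 1L)]
      if (length(span) == 0L) v else max(span)
    }
    min(lmax, rmax) - v >= max(prom_frac * rng, floor_abs)
  }, TRUE)
  idx[keep]
}

#' Build a connector site from a minima pair
#'
#' Constructs the connector reference geometry: `L_o`, the occlusal edge
#' of the occlusal rectangle at the occlusal minimum; `L_g`, the gingival
#' edge of the gingival rectangle at the gingival minimum; the connector
#' mid-plane `E_midCon` containing both; and the local right-handed frame
#' whose origin is the intersection of `E_mid`, `E_mid2` and `E_midCon`,
#' with x toward occlusal (through `E_mid2` crossing `L_o`), y along the
#' buccal axis inside `E_midCon`, and z = x cross y (the plane normal).
#' The initial cross-sectional area `A0` and section loop are measured at
#' `E_midCon`.
#'
#' @param mesh an [fpd_mesh].
#' @param profiles list of `slice_profile` from [slice_profiles()].
#' @param pair numeric length-2 `(alpha, beta)` slice indices (1-based).
#' @param box the `oriented_box` used for slicing.
#' @param ordinal connector ordinal (distal to mesial), for reporting.
#' @return a `connector_site`: list with `ordinal`, `alpha`, `beta`,
#'   `l_o`, `l_g` (each two 3-D endpoints), `e_midcon`, `frame`
#'   (`origin`, `x`, `y`, `z`), `station` (mm), `a0` (mm^2),
#'   `section_loop` ([planar_polygon]) and `obliquity_deg`.
#' @export
build_connector_site <- function(mesh, profiles, pair, box, ordinal = 1L) {
  a <- as.integer(pair[1]); b <- as.integer(pair[2])
  pa <- profiles[[a]]; pb <- profiles[[b]]
  if (is.null(pa$rect) || is.null(pb$rect))
    stop("empty slice at the connector station")

  md <- box$axis_md; og <- box$axis_og; lb <- box$axis_lb
  md_a <- sum(pa$plane$point * md)
  md_b <- sum(pb$plane$point * md)
  # reconstruct 3-D edge segments from scalar coordinates in the box basis
  p3 <- function(mdc, ogc, lbc) mdc * md + ogc * og + lbc * lb
  l_o <- rbind(p3(md_a, pa$rect$og_max, pa$rect$lb_min),
               p3(md_a, pa$rect$og_max, pa$rect$lb_max))
  l_g <- rbind(p3(md_b, pb$rect$og_min, pb$rect$lb_min),
               p3(md_b, pb$rect$og_min, pb$rect$lb_max))

  po <- (l_o[1, ] + l_o[2, ]) / 2
  pg <- (l_g[1, ] + l_g[2, ]) / 2
  dvec <- pg - po
  nrm <- cross3(lb, dvec)
  if (sqrt(sum(nrm^2)) < 1e-9) {
    warning("L_o and L_g collinear; falling back to a plane perpendicular to L1")
    nrm <- md
  }
  nrm <- unitize(nrm)
  if (sum(nrm * md) < 0) nrm <- -nrm
  e_midcon <- new_plane((po + pg) / 2, nrm)

  # frame origin: E_mid (og level) and E_mid2 (lb level) fix two
  # coordinates; E_midCon fixes the station along md
  og_mid <- sum(box$center * og)
  lb_mid <- sum(box$center * lb)
  base <- og_mid * og + lb_mid * lb
  denom <- sum(e_midcon$normal * md)
  if (abs(denom) < 1e-9) stop("degenerate connector plane")
  t0 <- (sum(e_midcon$normal * e_midcon$point) -
           sum(e_midcon$normal * base)) / denom
  origin <- base + t0 * md

  # x axis: toward the point where E_mid2 crosses L_o
  q <- p3(md_a, pa$rect$og_max, lb_mid)
  xhat <- unitize(q - origin)
  yhat <- lb
  zhat <- cross3(xhat, yhat)
  frame <- list(origin = origin, x = xhat, y = yhat, z = zhat)

  loops <- intersect_plane(mesh, e_midcon,
                           chart = list(origin = origin, ex = yhat, ey = xhat))
  loop <- select_connector_loop(loops)
  a0 <- polygon_area(loop, check = FALSE)
  obl <- acos(min(1, abs(sum(e_midcon$normal * md)))) * 180 / pi

  structure(list(ordinal = as.integer(ordinal), alpha = a, beta = b,
                 l_o = l_o, l_g = l_g, e_midcon = e_midcon, frame = frame,
                 station = sum(origin * md) - sum(mid_axis(box)$start * md),
                 a0 = a0, section_loop = loop, obliquity_deg = obl),
            class = "connector_site")
}

#' @export
print.connector_site <- function(x, ...) {
  cat(sprintf(
    "<connector_site %d: station %.2f mm, A0 %.2f mm^2, obliquity %.1f deg>\n",
    x$ordinal, x$station, x$a0, x$obliquity_deg))
  invisible(x)
}

#' Detect all connectors of an FPD mesh
#'
#' Full detection pipeline: oriented-box framing, mid-axis slicing,
#' rectangle-area series, paired prominent minima, and connector-site
#' construction.
#'
#' @param mesh an [fpd_mesh].
#' @param hints an [orientation_hints] list.
#' @param n_planes number of slicing planes (default 300).
#' @param smooth_window,prominence,pairing_window see
#'   [find_connector_minima()].
#' @return a `connector_detection`: list with `box`, `profiles`, `series`
#'   (data frame `index`, `station`, `a_occ`, `a_gin`), `minima` and
#'   `sites` (list of `connector_site`, distal to mesial).
#' @export
detect_connectors <- function(mesh, hints = orientation_hints(),
                              n_planes = 300L, smooth_window = 5L,
                              prominence = 0.05, pairing_window = 15L) {
  box <- fit_oriented_box(mesh, hints)
  profiles <- slice_profiles(mesh, box, n_planes)
  series <- data.frame(
    index = vapply(profiles, `[[`, 0L, "index"),
    station = vapply(profiles, `[[`, 0, "station"),
    a_occ = vapply(profiles, `[[`, 0, "a_occ"),
    a_gin = vapply(profiles, `[[`, 0, "a_gin"))
  minima <- find_connector_minima(profiles, smooth_window, prominence,
                                  pairing_window)
  sites <- vector("list", nrow(minima))
  for (j in seq_len(nrow(minima)))
    sites[[j]] <- build_connector_site(mesh, profiles,
                                       c(minima$alpha[j], minima$beta[j]),
                                       box, ordinal = j)
  structure(list(box = box, profiles = profiles, series = series,
                 minima = minima, sites = sites),
            class = "connector_detection")
}

#' @export
print.connector_detection <- function(x, ...) {
  cat(sprintf("<connector_detection: %d site(s)>\n", length(x$sites)))
  for (s in x$sites) print(s)
  invisible(x)
}
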