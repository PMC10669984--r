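# Oriented bounding box with anatomical face labels, and the mid axis L1.

new_plane <- function(point, normal) {
  normal <- normal / sqrt(sum(normal^2))
  list(point = as.numeric(point), normal = as.numeric(normal))
}

plane_signed_dist <- function(plane, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  as.vector(pts %*% plane$normal) - sum(plane$point * plane$normal)
}

unitize <- function(x) x / sqrt(sum(x^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rot_about <- function(axis, theta) {
  # Rodrigues rotation matrix
  a <- unitize(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Default anatomical orientation hints
#'
#' The minimum-volume box alone cannot name anatomical faces, so labeling
#' uses hint vectors: approximate occlusal (biting surface) direction,
#' approximate mesial direction, and approximate buccal direction.
#' Defaults assume the common scan convention occlusal = +Z, mesial = +X,
#' buccal = +Y.
#'
#' @param occlusal,mesial,buccal length-3 numeric hint vectors.
#' @return a named list of unit hint vectors.
#' @export
orientation_hints <- function(occlusal = c(0, 0, 1),
                              mesial = c(1, 0, 0),
                              buccal = c(0, 1, 0)) {
  list(occlusal = unitize(occlusal), mesial = unitize(mesial),
       buccal = unitize(buccal))
}

# Deterministic "extreme point" subset: farthest vertex along each of a
# fixed fan of directions (golden-spiral sphere), plus axis extremes.
extreme_points <- function(v, ndir = 600L) {
  i <- seq_len(ndir) - 0.5
  phi <- acos(1 - 2 * i / ndir)
  theta <- pi * (1 + sqrt(5)) * i
  D <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  s <- v %*% t(D)
  idx <- unique(c(apply(s, 2, which.max),
                  apply(v, 2, which.max), apply(v, 2, which.min)))
  v[idx, , drop = FALSE]
}

obb_volume <- function(axes, pts) {
  s <- pts %*% axes
  prod(apply(s, 2, function(x) diff(range(x))))
}

#' Fit a labeled minimum-volume oriented bounding box
#'
#' Approximates the smallest oriented bounding box of the mesh by a
#' deterministic rotation search (coordinate descent over the three
#' rotation angles, 1 degree scan refined to below 1e-4 degree, started
#' from the principal axes of a deterministic extreme-point subset), then
#' labels the box faces anatomically from the orientation hints:
#' the axis of largest extent is mesial-distal; of the remaining two, the
#' axis best aligned with the occlusal hint is occlusal-gingival; the last
#' is lingual-buccal.  Also derives the mid-planes `E_mid` (normal =
#' occlusal axis) and `E_mid2` (normal = lingual-buccal axis) through the
#' box centre.
#'
#' @param mesh an [fpd_mesh].
#' @param hints an [orientation_hints] list.
#' @return an `oriented_box`: list with `center`, unit axes `axis_md`,
#'   `axis_og`, `axis_lb` (mesial, occlusal and buccal positive), and
#'   `half_extents` (same order), plus mid-planes `e_mid`, `e_mid2`.
#' @export
fit_oriented_box <- function(mesh, hints = orientation_hints()) {
  if (!inherits(mesh, "fpd_mesh")) stop("`mesh` must be an fpd_mesh")
  v <- mesh$vertices
  ep <- extreme_points(v)
  cv <- stats::cov(ep)
  axes <- eigen(cv, symmetric = TRUE)$vectors
  if (det(axes) < 0) axes[, 3] <- -axes[, 3]
  if (min(apply(ep %*% axes, 2, function(x) diff(range(x)))) < 1e-9)
    stop("degenerate (flat or linear) geometry: cannot fit an oriented box")

  best <- obb_volume(axes, ep)
  for (sweep in 1:4) {
    improved <- FALSE
    for (ax in 1:3) {
      # scan rotation about current axis `ax`
      span <- pi / 4
      step <- pi / 180
      center_th <- 0
      for (level in 1:7) {
        th <- seq(center_th - span, center_th + span, by = step)
        vols <- vapply(th, function(t) {
          obb_volume(axes %*% rot_about_local(ax, t), ep)
        }, 0)
        j <- which.min(vols)
        center_th <- th[j]
        if (vols[j] < best - 1e-14) improved <- TRUE
        best <- min(best, vols[j])
        span <- step
        step <- step / 5
      }
      axes <- axes %*% rot_about_local(ax, center_th)
      # re-orthonormalise drift
      axes <- qr.Q(qr(axes))
    }
    if (!improved) break
  }

  # extents from the full vertex set so every vertex is inside the box
  s <- v %*% axes
  lo <- apply(s, 2, min); hi <- apply(s, 2, max)
  half <- (hi - lo) / 2
  center_local <- (hi + lo) / 2
  center <- as.vector(axes %*% center_local)

  # label axes
  ord <- order(half, decreasing = TRUE)
  a_md <- axes[, ord[1]]
  rem <- ord[2:3]
  og_pick <- rem[which.max(abs(c(sum(axes[, rem[1]] * hints$occlusal),
                                 sum(axes[, rem[2]] * hints$occlusal))))]
  lb_pick <- setdiff(rem, og_pick)
  a_og <- axes[, og_pick]
  a_lb <- axes[, lb_pick]
  if (sum(a_md * hints$mesial) < 0) a_md <- -a_md
  if (sum(a_og * hints$occlusal) < 0) a_og <- -a_og
  if (sum(a_lb * hints$buccal) < 0) a_lb <- -a_lb
  h <- c(half[ord[1]], half[og_pick], half[lb_pick])

  structure(list(center = center,
                 axis_md = a_md, axis_og = a_og, axis_lb = a_lb,
                 half_extents = h,
                 e_mid = new_plane(center, a_og),
                 e_mid2 = new_plane(center, a_lb)),
            class = "oriented_box")
}

# rotation acting in the box's local axis frame
rot_about_local <- function(ax, theta) {
  idx <- switch(ax, c(2, 3), c(3, 1), c(1, 2))
  R <- diag(3)
  R[idx[1], idx[1]] <- cos(theta); R[idx[2], idx[2]] <- cos(theta)
  R[idx[1], idx[2]] <- -sin(theta); R[idx[2], idx[1]] <- sin(theta)
  R
}

#' @export
print.oriented_box <- function(x, ...) {
  cat(sprintf(
    "<oriented_box: extents %.3f (md) x %.3f (og) x %.3f (lb) mm>\n",
    2 * x$half_extents[1], 2 * x$half_extents[2], 2 * x$half_extents[3]))
  invisible(x)
}

#' Mid axis of the prosthesis (the line L1)
#'
#' The segment joining the centres of the two smallest box faces (distal
#' and mesial); slicing planes are placed perpendicular to it.
#'
#' @param box an `oriented_box` from [fit_oriented_box()].
#' @return a `mid_axis`: list with `start` (distal face centre), `end`
#'   (mesial face centre), unit `direction` and `length` (mm).
#' @export
mid_axis <- function(box) {
  start <- box$center - box$axis_md * box$half_extents[1]
  end <- box$center + box$axis_md * box$half_extents[1]
  structure(list(start = start, end = end,
                 direction = box$axis_md,
                 length = 2 * box$half_extents[1]),
            class = "mid_axis")
}
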