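#' Triangle surface mesh
#'
#' The central container of the package: an indexed triangle mesh with
#' vertices in millimetres.  All geometry in this package is interpreted in
#' mm (STL itself carries no units).
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param provenance one of `"original"`, `"remeshed"`, `"adjusted"`,
#'   `"synthetic"`.
#' @param validate merge duplicate vertices and drop degenerate faces
#'   before constructing (default `TRUE`).
#' @param merge_tol vertex merge tolerance in mm (default `1e-6`).
#'
#' @return An object of class `fpd_mesh`: a list with elements `vertices`,
#'   `faces` and `provenance`.
#' @export
fpd_mesh <- function(vertices, faces,
                     provenance = "original",
                     validate = TRUE,
                     merge_tol = 1e-6) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must have 3 columns")
  if (ncol(faces) != 3L) stop("`faces` must have 3 columns")
  if (nrow(faces) == 0L || nrow(vertices) == 0L)
    stop("empty mesh: no vertices or no faces")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of vertex range")

  m <- structure(list(vertices = vertices, faces = faces,
                      provenance = provenance),
                 class = "fpd_mesh")
  if (validate) m <- clean_mesh(m, merge_tol = merge_tol)
  m
}

#' @export
print.fpd_mesh <- function(x, ...) {
  e <- apply(x$vertices, 2, range)
  cat(sprintf("<fpd_mesh: %d vertices, %d faces, provenance '%s'>\n",
              nrow(x$vertices), nrow(x$faces), x$provenance))
  cat(sprintf("  extent: %.3f x %.3f x %.3f mm\n",
              e[2, 1] - e[1, 1], e[2, 2] - e[1, 2], e[2, 3] - e[1, 3]))
  invisible(x)
}

# Merge duplicate vertices (within tol) and drop degenerate faces.
clean_mesh <- function(mesh, merge_tol = 1e-6) {
  v <- mesh$vertices
  f <- mesh$faces
  key <- paste(round(v[, 1] / merge_tol), round(v[, 2] / merge_tol),
               round(v[, 3] / merge_tol))
  first <- !duplicated(key)
  remap <- match(key, key[first])
  v <- v[first, , drop = FALSE]
  f[] <- remap[f]
  # faces with a repeated index are degenerate
  keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[keep, , drop = FALSE]
  # zero-area faces
  if (nrow(f) > 0L) {
    a <- face_areas(v, f)
    f <- f[a > 1e-14, , drop = FALSE]
  }
  if (nrow(f) == 0L) stop("mesh has no non-degenerate faces after validation")
  # drop unreferenced vertices
  used <- sort(unique(as.vector(f)))
  remap2 <- integer(nrow(v))
  remap2[used] <- seq_along(used)
  structure(list(vertices = v[used, , drop = FALSE],
                 faces = matrix(remap2[f], ncol = 3L),
                 provenance = mesh$provenance),
            class = "fpd_mesh")
}

face_areas <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

face_normals <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Total surface area of a mesh (mm^2)
#' @param mesh an [fpd_mesh].
#' @return scalar surface area in mm^2.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh$vertices, mesh$faces))

#' Signed enclosed volume of a mesh (mm^3)
#'
#' Positive for a watertight mesh with outward-facing normals.
#' @param mesh an [fpd_mesh].
#' @return scalar volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

mesh_edges <- function(f) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Is a mesh watertight?
#'
#' A mesh is watertight (closed, 2-manifold along edges) when every
#' undirected edge is shared by exactly two faces.  Well-defined section
#' loops require watertightness.
#'
#' @param mesh an [fpd_mesh].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  e <- mesh_edges(mesh$faces)
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2L)
}

# number of boundary (single-face) edges
boundary_edge_count <- function(f) {
  e <- mesh_edges(f)
  key <- paste(e[, 1], e[, 2])
  sum(table(key) == 1L)
}

# Rigid transform helper used by tests and orientation handling.
#' Apply a rigid transform to a mesh
#' @param mesh an [fpd_mesh].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric.
#' @return transformed [fpd_mesh].
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  structure(list(vertices = v, faces = mesh$faces,
                 provenance = mesh$provenance),
            class = "fpd_mesh")
}
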