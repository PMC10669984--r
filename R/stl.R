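#' Read an STL file
#'
#' Reads binary or ASCII STL (auto-detected) into an [fpd_mesh].  STL files
#' carry no units; coordinates are interpreted as millimetres.  Duplicate
#' vertices within `merge_tol` are merged so the surface is edge-connected,
#' and degenerate facets are dropped.
#'
#' @param path path to an STL file.
#' @param merge_tol vertex merge tolerance in mm (default `1e-6`).
#' @return an [fpd_mesh] with provenance `"original"`.
#' @export
read_mesh <- function(path, merge_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop("not a valid STL file (too short): ", path)

  con <- file(path, "rb")
  head84 <- readBin(con, "raw", n = min(84, sz))
  close(con)

  is_binary <- FALSE
  if (sz >= 84) {
    nfac <- readBin(head84[81:84], "integer", size = 4, endian = "little")
    if (!is.na(nfac) && nfac >= 0 && sz == 84 + 50 * as.numeric(nfac))
      is_binary <- TRUE
  }
  tri <- if (is_binary) read_stl_binary(path) else read_stl_ascii(path)
  if (nrow(tri) == 0L) stop("STL file contains no facets: ", path)

  nf <- nrow(tri) / 3L
  fpd_mesh(tri, matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE),
           provenance = "original", merge_tol = merge_tol)
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80))
  nfac <- readBin(con, "integer", size = 4, endian = "little")
  if (sz < 84 + 50 * as.numeric(nfac)) stop("truncated binary STL: ", path)
  body <- readBin(con, "raw", n = 50 * nfac)
  body <- matrix(body, nrow = 50)
  # facet record: 12 bytes normal, 36 bytes vertices, 2 bytes attribute
  vraw <- as.raw(body[13:48, ])
  vals <- readBin(vraw, "numeric", size = 4, n = 9 * nfac, endian = "little")
  # vals: per facet v1x v1y v1z v2x ... -> one vertex per row
  matrix(vals, ncol = 3, byrow = TRUE)
}

read_stl_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vl <- grep("vertex", txt, fixed = TRUE, value = TRUE)
  if (length(vl) == 0L) stop("STL file contains no facets: ", path)
  if (length(vl) %% 3L != 0L) stop("malformed ASCII STL (vertex count): ", path)
  toks <- strsplit(trimws(vl), "\\s+")
  bad <- vapply(toks, length, 1L) != 4L
  if (any(bad)) stop("malformed ASCII STL vertex line: ", path)
  vals <- suppressWarnings(
    as.numeric(unlist(lapply(toks, `[`, 2:4), use.names = FALSE)))
  if (anyNA(vals)) stop("malformed ASCII STL vertex coordinates: ", path)
  matrix(vals, ncol = 3, byrow = TRUE)
}

#' Write an STL file
#'
#' Writes an [fpd_mesh] as binary (default) or ASCII STL.  Facet normals
#' are recomputed from the vertex winding; coordinates are written as
#' 32-bit floats in the binary dialect (the STL standard), so a round trip
#' is faithful to about 1e-7 relative precision.
#'
#' @param mesh an [fpd_mesh].
#' @param path output path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  if (!inherits(mesh, "fpd_mesh")) stop("`mesh` must be an fpd_mesh")
  if (nrow(mesh$faces) == 0L) stop("refusing to write an empty mesh")
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(v, f)
  nf <- nrow(f)

  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    # 12 floats per facet: n, v1, v2, v3
    dat <- t(cbind(n, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
                   v[f[, 3], , drop = FALSE]))
    fraw <- writeBin(as.vector(dat), raw(), size = 4, endian = "little")
    fraw <- matrix(fraw, nrow = 48)
    out <- rbind(fraw, matrix(as.raw(0), nrow = 2, ncol = nf))
    writeBin(as.vector(out), con)
  } else {
    fmt <- function(x) sprintf("%.9g", x)
    lines <- character(7 * nf + 2)
    lines[1] <- "solid fpdconnect"
    idx <- seq_len(nf)
    lines[7 * (idx - 1) + 2] <-
      paste("facet normal", fmt(n[, 1]), fmt(n[, 2]), fmt(n[, 3]))
    lines[7 * (idx - 1) + 3] <- "  outer loop"
    for (k in 1:3) {
      vk <- v[f[, k], , drop = FALSE]
      lines[7 * (idx - 1) + 3 + k] <-
        paste("    vertex", fmt(vk[, 1]), fmt(vk[, 2]), fmt(vk[, 3]))
    }
    lines[7 * (idx - 1) + 7] <- "  endloop"
    lines[7 * (idx - 1) + 8] <- "endfacet"
    lines[7 * nf + 2] <- "endsolid fpdconnect"
    writeLines(lines, path)
  }
  invisible(path)
}
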