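# Incremental isotropic triangle remeshing (split / collapse / flip /
# tangential smooth + back-projection), in the spirit of the standard
# edge-length-equalisation remeshers.  Stands in for proprietary quad
# remeshing; fidelity is enforced by the same Hausdorff QC that the
# detection pipeline uses.

#' Isotropic remeshing to a target triangle count
#'
#' Iteratively splits long edges, collapses short edges, flips edges toward
#' regular vertex valence, and relaxes vertices tangentially with
#' back-projection onto the *input* surface, until the triangle count is
#' near `target_element_count` and edge lengths are near-uniform.  Vertices
#' always lie on the input surface, so the geometric deviation is bounded
#' by the chord error of the new triangulation.
#'
#' @param mesh an [fpd_mesh]; should be closed and edge-connected (an open
#'   mesh with a large boundary triggers a warning, boundary vertices are
#'   kept fixed).
#' @param target_element_count desired number of triangles (default 120000,
#'   i.e. about 60000 quads split into triangle pairs; must be >= 100).
#' @param passes maximum remeshing passes (default 10).
#' @return an [fpd_mesh] with provenance `"remeshed"` whose face count is
#'   within about 20 percent of the target.
#' @export
remesh_uniform <- function(mesh, target_element_count = 120000L, passes = 10L) {
  if (target_element_count < 100)
    stop("`target_element_count` must be at least 100")
  orig <- mesh
  nb <- boundary_edge_count(mesh$faces)
  if (nb > 0L)
    warning(sprintf("mesh is not closed (%d boundary edges); proceeding", nb))

  area <- mesh_area(mesh)
  l <- sqrt(4 * area / (sqrt(3) * target_element_count))
  v <- mesh$vertices
  f <- mesh$faces
  for (pass in seq_len(passes)) {
    r <- rm_split_long(v, f, 4 / 3 * l); v <- r$v; f <- r$f
    r <- rm_collapse_short(v, f, 4 / 5 * l, 4 / 3 * l); v <- r$v; f <- r$f
    f <- rm_flip_valence(v, f)
    v <- rm_smooth_project(v, f, orig, iters = 2L)
    nf <- nrow(f)
    if (abs(nf - target_element_count) / target_element_count < 0.15 &&
        pass >= 2L)
      break
    # re-aim the edge length at the observed count
    l <- l * sqrt(nf / target_element_count)
  }
  out <- fpd_mesh(v, f, provenance = "remeshed", validate = TRUE)
  nf <- nrow(out$faces)
  if (abs(nf - target_element_count) / target_element_count > 0.2)
    warning(sprintf("remesh count %d outside 20%% of target %d",
                    nf, target_element_count))
  out
}

# --- edge split ------------------------------------------------------------

rm_split_long <- function(v, f, lmax) {
  for (it in 1:12) {
    ed <- mesh_edges(f)
    key <- paste(ed[, 1], ed[, 2])
    ue <- !duplicated(key)
    e1 <- ed[ue, 1]; e2 <- ed[ue, 2]
    len <- sqrt(rowSums((v[e1, , drop = FALSE] - v[e2, , drop = FALSE])^2))
    long <- len > lmax
    if (!any(long)) break
    mid <- (v[e1[long], , drop = FALSE] + v[e2[long], , drop = FALSE]) / 2
    midx <- nrow(v) + seq_len(sum(long))
    v <- rbind(v, mid)
    midmap <- integer(0)
    lkey <- paste(e1[long], e2[long])
    # per-face long-edge pattern; edges in order (1,2),(2,3),(3,1)
    fk1 <- paste(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2]))
    fk2 <- paste(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3]))
    fk3 <- paste(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1]))
    m1 <- midx[match(fk1, lkey)]
    m2 <- midx[match(fk2, lkey)]
    m3 <- midx[match(fk3, lkey)]
    pat <- (!is.na(m1)) + 2L * (!is.na(m2)) + 4L * (!is.na(m3))

    pieces <- vector("list", 8)
    pieces[[1]] <- f[pat == 0L, , drop = FALSE]
    # rotate faces so the split pattern is canonical
    rot <- function(ff, mm1, mm2, mm3, k) {
      # rotate vertex order left k times; edges rotate the same way
      if (k == 1L) list(f = ff[, c(2, 3, 1), drop = FALSE],
                        m = cbind(mm2, mm3, mm1))
      else if (k == 2L) list(f = ff[, c(3, 1, 2), drop = FALSE],
                             m = cbind(mm3, mm1, mm2))
      else list(f = ff, m = cbind(mm1, mm2, mm3))
    }
    out <- list(pieces[[1]])
    for (p in 1:7) {
      sel <- pat == p
      if (!any(sel)) next
      ff <- f[sel, , drop = FALSE]
      mm <- cbind(m1[sel], m2[sel], m3[sel])
      k <- switch(p, 0L, 1L, 0L, 2L, 2L, 1L, 0L)
      # after rotation: p in {1,2,4} -> long edge is e1; {3,6,5} -> e1,e2;
      # 7 -> all three
      r <- rot(ff, mm[, 1], mm[, 2], mm[, 3], k)
      ff <- r$f; mm <- r$m
      if (p %in% c(1L, 2L, 4L)) {
        new <- rbind(cbind(ff[, 1], mm[, 1], ff[, 3]),
                     cbind(mm[, 1], ff[, 2], ff[, 3]))
      } else if (p %in% c(3L, 6L, 5L)) {
        new <- rbind(cbind(ff[, 1], mm[, 1], mm[, 2]),
                     cbind(ff[, 1], mm[, 2], ff[, 3]),
                     cbind(mm[, 1], ff[, 2], mm[, 2]))
      } else {
        new <- rbind(cbind(ff[, 1], mm[, 1], mm[, 3]),
                     cbind(ff[, 2], mm[, 2], mm[, 1]),
                     cbind(ff[, 3], mm[, 3], mm[, 2]),
                     cbind(mm[, 1], mm[, 2], mm[, 3]))
      }
      out[[length(out) + 1]] <- new
    }
    f <- do.call(rbind, out)
    storage.mode(f) <- "integer"
  }
  list(v = v, f = f)
}

# --- edge collapse ---------------------------------------------------------

rm_collapse_short <- function(v, f, lmin, lmax) {
  ed <- mesh_edges(f)
  key <- paste(ed[, 1], ed[, 2])
  ue <- which(!duplicated(key))
  e1 <- ed[ue, 1]; e2 <- ed[ue, 2]
  len <- sqrt(rowSums((v[e1, , drop = FALSE] - v[e2, , drop = FALSE])^2))
  cand <- order(len)
  cand <- cand[len[cand] < lmin]
  if (length(cand) == 0L) return(list(v = v, f = f))

  # adjacency lists and boundary vertices
  nv <- nrow(v)
  adj <- vector("list", nv)
  tab <- table(key)
  bnd_keys <- names(tab)[tab == 1L]
  bnd <- rep(FALSE, nv)
  if (length(bnd_keys) > 0) {
    bi <- do.call(rbind, strsplit(bnd_keys, " "))
    bnd[as.integer(bi)] <- TRUE
  }
  allpairs <- rbind(cbind(e1, e2), cbind(e2, e1))
  adjsplit <- split(allpairs[, 2], allpairs[, 1])
  adj[as.integer(names(adjsplit))] <- adjsplit

  touched <- rep(FALSE, nv)
  mapto <- seq_len(nv)
  newpos <- v
  lmax2 <- lmax^2
  for (ci in cand) {
    a <- e1[ci]; b <- e2[ci]
    if (touched[a] || touched[b] || bnd[a] || bnd[b]) next
    na <- adj[[a]]; nb_ <- adj[[b]]
    common <- na[match(na, nb_, nomatch = 0L) > 0L]
    if (length(common) != 2L) next       # link condition
    mid <- (v[a, ] + v[b, ]) / 2
    ring <- unique(c(na, nb_))
    ring <- ring[ring != a & ring != b]
    d2 <- (v[ring, 1] - mid[1])^2 + (v[ring, 2] - mid[2])^2 +
      (v[ring, 3] - mid[3])^2
    if (any(d2 > lmax2)) next            # would create a long edge
    touched[a] <- TRUE; touched[b] <- TRUE
    touched[ring] <- TRUE
    mapto[b] <- a
    newpos[a, ] <- mid
  }
  f[] <- mapto[f]
  keep <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[keep, , drop = FALSE]
  # drop duplicated faces (same vertex set), a rare artifact of collapses
  fk <- apply(f, 1, function(r) paste(sort(r), collapse = " "))
  f <- f[!duplicated(fk), , drop = FALSE]
  list(v = newpos, f = f)
}

# --- valence flips ---------------------------------------------------------

rm_flip_valence <- function(v, f) {
  nf <- nrow(f)
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fid <- rep(seq_len(nf), 3)
  opp <- c(f[, 3], f[, 1], f[, 2])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  o <- order(key)
  key <- key[o]; ed <- ed[o, , drop = FALSE]; fid <- fid[o]; opp <- opp[o]
  first <- !duplicated(key)
  idx1 <- which(first)
  # interior edges appear exactly twice consecutively after sorting
  has2 <- idx1 + 1L <= length(key) & c(key[-1], "") [idx1] == key[idx1]
  idx1 <- idx1[has2]
  i2 <- idx1 + 1L
  a <- ed[idx1, 1]; b <- ed[idx1, 2]
  cc <- opp[idx1]; dd <- opp[i2]
  f1 <- fid[idx1]; f2 <- fid[i2]

  val <- tabulate(f, nbins = nrow(v))
  dev_now <- abs(val[a] - 6) + abs(val[b] - 6) + abs(val[cc] - 6) +
    abs(val[dd] - 6)
  # after a flip, a and b lose an edge and c, d gain one
  dev_new <- abs(val[a] - 1 - 6) + abs(val[b] - 1 - 6) +
    abs(val[cc] + 1 - 6) + abs(val[dd] + 1 - 6)
  want <- dev_new < dev_now & cc != dd

  if (any(want)) {
    # geometric guard: both new triangles must keep the old orientation
    n_old <- face_normals(v, rbind(cbind(a, b, cc), cbind(b, a, dd)))
    navg <- n_old[seq_along(a), , drop = FALSE] +
      n_old[length(a) + seq_along(a), , drop = FALSE]
    tri1 <- cbind(a, dd, cc)
    tri2 <- cbind(dd, b, cc)
    n1 <- face_normals(v, tri1); n2 <- face_normals(v, tri2)
    ok <- rowSums(n1 * navg) > 1e-3 & rowSums(n2 * navg) > 1e-3
    want <- want & ok
  }
  if (!any(want)) return(f)

  # greedy independent set over faces
  used <- rep(FALSE, nf)
  for (i in which(want)) {
    if (used[f1[i]] || used[f2[i]]) next
    used[f1[i]] <- TRUE; used[f2[i]] <- TRUE
    f[f1[i], ] <- c(a[i], dd[i], cc[i])
    f[f2[i], ] <- c(dd[i], b[i], cc[i])
  }
  f
}

# --- tangential smoothing with back-projection -----------------------------

rm_smooth_project <- function(v, f, orig, iters = 2L, lambda = 0.5) {
  nv <- nrow(v)
  ed <- mesh_edges(f)
  key <- paste(ed[, 1], ed[, 2])
  ue <- !duplicated(key)
  e <- ed[ue, , drop = FALSE]
  tab <- table(key)
  bnd <- rep(FALSE, nv)
  bk <- names(tab)[tab == 1L]
  if (length(bk) > 0) bnd[as.integer(unlist(strsplit(bk, " ")))] <- TRUE
  both <- rbind(e, e[, c(2, 1)])
  deg <- tabulate(both[, 1], nbins = nv)
  deg[deg == 0] <- 1
  for (it in seq_len(iters)) {
    # vertex normals (area-weighted face normal accumulation)
    fn <- face_normals(v, f)
    fa <- face_areas(v, f)
    vn <- matrix(0, nv, 3)
    for (k in 1:3) {
      idx <- f[, k]
      vn[, 1] <- vn[, 1] + as.vector(tapply_add(fn[, 1] * fa, idx, nv))
      vn[, 2] <- vn[, 2] + as.vector(tapply_add(fn[, 2] * fa, idx, nv))
      vn[, 3] <- vn[, 3] + as.vector(tapply_add(fn[, 3] * fa, idx, nv))
    }
    nl <- sqrt(rowSums(vn^2)); nl[nl == 0] <- 1
    vn <- vn / nl
    # neighbour centroid
    cen <- matrix(0, nv, 3)
    for (c3 in 1:3) {
      s <- tapply_add(v[both[, 2], c3], both[, 1], nv)
      cen[, c3] <- s / deg
    }
    g <- cen - v
    gn <- rowSums(g * vn)
    gt <- g - vn * gn
    move <- !bnd & deg > 0
    v[move, ] <- v[move, ] + lambda * gt[move, ]
    v[move, ] <- project_points(v[move, , drop = FALSE], orig)
  }
  v
}

# sum `x` into bins 1..nv given index vector
tapply_add <- function(x, idx, nv) {
  out <- numeric(nv)
  s <- rowsum(x, idx, reorder = TRUE)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}
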