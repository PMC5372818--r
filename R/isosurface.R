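#' Triangulated isosurface of the tissue foreground
#'
#' Builds the outer surface of the tissue (all non-background voxels) as a
#' triangular mesh, used as the projection target for surface vertices. The
#' binary mask is first smoothed by a small separable box filter, then
#' contoured at level 0.5 by marching tetrahedra (each voxel cube split into
#' six tetrahedra, crossings placed by linear interpolation), which avoids
#' the ambiguous cube cases of plain marching cubes. Coordinates are world
#' micrometres.
#'
#' @param image a `segmented_image` with at least one foreground voxel
#' @param smoothing number of box-smoothing passes applied to the binary mask
#'   (width-3 kernel per axis); 2 gives surface areas close to the continuum
#'   limit while keeping the surface within a voxel of the mask boundary
#' @return list with `vertices` (n x 3) and `triangles` (m x 3 vertex
#'   indices), class `iso_surface`
#' @export
binary_isosurface <- function(image, smoothing = 2) {
  mask <- (image$labels != image$background_label) * 1
  if (sum(mask) == 0) stop("empty foreground: no tissue voxels")
  f <- mask
  for (i in seq_len(smoothing)) f <- box_smooth3(f)
  surf <- marching_tetrahedra(f, level = 0.5, voxel_size = image$voxel_size)
  structure(surf, class = "iso_surface")
}

box_smooth3 <- function(a) {
  # separable width-3 box filter with zero padding (outside = background)
  d <- dim(a)
  sh <- function(a, ax, by) {
    out <- array(0, d)
    n <- d[ax]
    if (by == 0) return(a)
    src <- if (by > 0) 1:(n - by) else (1 - by):n
    dst <- if (by > 0) (1 + by):n else 1:(n + by)
    if (ax == 1) out[dst, , ] <- a[src, , ]
    if (ax == 2) out[, dst, ] <- a[, src, ]
    if (ax == 3) out[, , dst] <- a[, , src]
    out
  }
  for (ax in 1:3) a <- (sh(a, ax, -1) + a + sh(a, ax, 1)) / 3
  a
}

# 6-tetrahedron decomposition of the unit cube (corners numbered 1..8 as
# (0,0,0),(1,0,0),(0,1,0),(1,1,0),(0,0,1),(1,0,1),(0,1,1),(1,1,1)), all
# sharing the main diagonal 1-8
TET_DECOMP <- matrix(c(1, 2, 4, 8,
                       1, 2, 6, 8,
                       1, 3, 4, 8,
                       1, 3, 7, 8,
                       1, 5, 6, 8,
                       1, 5, 7, 8), ncol = 4, byrow = TRUE)

CUBE_OFFSETS <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 1, 0,
                         0, 0, 1, 1, 0, 1, 0, 1, 1, 1, 1, 1),
                       ncol = 3, byrow = TRUE)

marching_tetrahedra <- function(f, level, voxel_size) {
  d <- dim(f)
  nc <- d - 1
  corner <- function(k) {
    o <- CUBE_OFFSETS[k, ]
    as.vector(f[(1:nc[1]) + o[1], (1:nc[2]) + o[2], (1:nc[3]) + o[3]])
  }
  vals <- sapply(1:8, corner)                     # ncubes x 8
  above <- vals > level
  active <- which(rowSums(above) > 0 & rowSums(above) < 8)
  if (length(active) == 0) stop("no isosurface crossing at this level")
  low <- arrayInd(active, nc)                     # 1-based low corner index

  # global linear voxel index of each cube corner, for shared-vertex keys
  lin <- function(idx) (idx[, 3] - 1) * d[1] * d[2] + (idx[, 2] - 1) * d[1] + idx[, 1]
  corner_lin <- sapply(1:8, function(k)
    lin(sweep(low, 2, CUBE_OFFSETS[k, ], `+`)))
  vals <- vals[active, , drop = FALSE]
  if (length(active) == 1) corner_lin <- matrix(corner_lin, nrow = 1)

  seg_a <- integer(0); seg_b <- integer(0)        # global corner ids per crossing
  tri_of <- list()
  for (t in seq_len(nrow(TET_DECOMP))) {
    cid <- TET_DECOMP[t, ]
    v <- vals[, cid, drop = FALSE]
    g <- corner_lin[, cid, drop = FALSE]
    ab <- v > level
    nab <- rowSums(ab)
    # one corner separated from the other three: one triangle
    for (lone_above in c(TRUE, FALSE)) {
      rows <- which(if (lone_above) nab == 1 else nab == 3)
      if (length(rows) == 0) next
      lone <- apply(ab[rows, , drop = FALSE], 1, function(x)
        which(x == lone_above))
      others <- t(vapply(lone, function(i) setdiff(1:4, i), integer(3)))
      ii <- cbind(rows, lone)
      e1 <- cbind(g[ii], g[cbind(rows, others[, 1])])
      e2 <- cbind(g[ii], g[cbind(rows, others[, 2])])
      e3 <- cbind(g[ii], g[cbind(rows, others[, 3])])
      tri_of[[length(tri_of) + 1]] <- cbind(e1, e2, e3)
    }
    # two against two: quad split into two triangles
    rows <- which(nab == 2)
    if (length(rows) > 0) {
      hi <- t(apply(ab[rows, , drop = FALSE], 1, function(x) which(x)))
      lo <- t(apply(ab[rows, , drop = FALSE], 1, function(x) which(!x)))
      gi <- function(cidx) g[cbind(rows, cidx)]
      e_ik <- cbind(gi(hi[, 1]), gi(lo[, 1]))
      e_il <- cbind(gi(hi[, 1]), gi(lo[, 2]))
      e_jk <- cbind(gi(hi[, 2]), gi(lo[, 1]))
      e_jl <- cbind(gi(hi[, 2]), gi(lo[, 2]))
      tri_of[[length(tri_of) + 1]] <- cbind(e_ik, e_il, e_jk)
      tri_of[[length(tri_of) + 1]] <- cbind(e_il, e_jl, e_jk)
    }
  }
  tri6 <- do.call(rbind, tri_of)   # each row: 3 edges as (ga, gb)
  # canonical edge keys
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "_")
  k1 <- ekey(tri6[, 1], tri6[, 2])
  k2 <- ekey(tri6[, 3], tri6[, 4])
  k3 <- ekey(tri6[, 5], tri6[, 6])
  all_keys <- unique(c(k1, k2, k3))
  tri <- cbind(match(k1, all_keys), match(k2, all_keys), match(k3, all_keys))
  tri <- tri[tri[, 1] != tri[, 2] & tri[, 1] != tri[, 3] &
               tri[, 2] != tri[, 3], , drop = FALSE]

  # interpolated vertex position per unique crossing edge
  parts <- matrix(as.numeric(unlist(strsplit(all_keys, "_", fixed = TRUE))),
                  ncol = 2, byrow = TRUE)
  pa <- lin_to_world(parts[, 1], d, voxel_size)
  pb <- lin_to_world(parts[, 2], d, voxel_size)
  fa <- f[parts[, 1]]; fb <- f[parts[, 2]]
  tt <- (level - fa) / (fb - fa)
  tt[!is.finite(tt)] <- 0.5
  verts <- pa + (pb - pa) * tt
  list(vertices = verts, triangles = tri)
}

lin_to_world <- function(lin, d, vs) {
  lin0 <- lin - 1
  i <- lin0 %% d[1]
  j <- (lin0 %/% d[1]) %% d[2]
  k <- lin0 %/% (d[1] * d[2])
  cbind((i + 0.5) * vs[1], (j + 0.5) * vs[2], (k + 0.5) * vs[3])
}

#' Total area of a triangulated surface
#' @param surface list with `vertices` and `triangles`
#' @return numeric (square micrometres)
#' @export
surface_area <- function(surface) {
  sum(triangle_areas(surface$vertices, surface$triangles))
}

triangle_areas <- function(vertices, triangles) {
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  p2 <- vertices[triangles[, 2], , drop = FALSE]
  p3 <- vertices[triangles[, 3], , drop = FALSE]
  cr <- cross3(p2 - p1, p3 - p1)
  0.5 * sqrt(rowSums(cr^2))
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Nearest points on a triangulated surface
#'
#' For each query point, finds the nearest surface vertex through a uniform
#' spatial grid and refines the answer by exact closest-point projection onto
#' the triangles incident to that vertex (and its one-ring neighbours).
#'
#' @param points n x 3 query matrix
#' @param surface an `iso_surface` (or any `vertices`/`triangles` list)
#' @return n x 3 matrix of closest surface points
#' @export
project_to_surface <- function(points, surface) {
  points <- matrix(points, ncol = 3)
  nn <- nearest_vertex(points, surface$vertices)
  # triangles incident to each surface vertex
  tri <- surface$triangles
  inc <- split(rep(seq_len(nrow(tri)), 3), as.vector(tri))
  out <- points
  for (q in seq_len(nrow(points))) {
    v <- nn[q]
    cand <- inc[[as.character(v)]]
    if (is.null(cand)) { out[q, ] <- surface$vertices[v, ]; next }
    ring <- unique(as.vector(tri[cand, ]))
    cand <- unique(unlist(inc[as.character(ring)]))
    best <- surface$vertices[v, ]
    bestd <- sum((points[q, ] - best)^2)
    for (ti in cand) {
      cp <- closest_point_triangle(points[q, ], surface$vertices[tri[ti, 1], ],
                                   surface$vertices[tri[ti, 2], ],
                                   surface$vertices[tri[ti, 3], ])
      dd <- sum((points[q, ] - cp)^2)
      if (dd < bestd) { bestd <- dd; best <- cp }
    }
    out[q, ] <- best
  }
  out
}

nearest_vertex <- function(points, verts) {
  h <- max(apply(verts, 2, function(x) diff(range(x)))) / 20 + 1e-9
  key <- function(p) paste(floor(p[, 1] / h), floor(p[, 2] / h),
                           floor(p[, 3] / h), sep = ",")
  buckets <- split(seq_len(nrow(verts)), key(verts))
  out <- integer(nrow(points))
  for (q in seq_len(nrow(points))) {
    p <- points[q, ]
    r <- 1
    cand <- integer(0)
    while (length(cand) == 0 && r < 100) {
      cells <- expand.grid(x = floor(p[1] / h) + (-r:r),
                           y = floor(p[2] / h) + (-r:r),
                           z = floor(p[3] / h) + (-r:r))
      keys <- paste(cells$x, cells$y, cells$z, sep = ",")
      cand <- unlist(buckets[keys], use.names = FALSE)
      r <- r * 2
    }
    if (length(cand) == 0) cand <- seq_len(nrow(verts))
    dd <- rowSums((verts[cand, , drop = FALSE] -
                     matrix(p, length(cand), 3, byrow = TRUE))^2)
    out[q] <- cand[which.min(dd)]
  }
  out
}

closest_point_triangle <- function(p, a, b, c) {
  # Ericson-style closest point on triangle abc to point p
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + ab * d1 / (d1 - d3))
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + ac * d2 / (d2 - d6))
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + (c - b) * (d4 - d3) / ((d4 - d3) + (d5 - d6)))
  denom <- 1 / (va + vb + vc)
  a + ab * vb * denom + ac * vc * denom
}
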