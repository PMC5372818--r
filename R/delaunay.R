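#' Circumsphere centre of a tetrahedron
#'
#' The unique point equidistant from the four vertices, obtained by solving
#' the 3x3 linear system of equidistance conditions. This is where a cell
#' corner is placed when dualizing an adjacency tetrahedron, exactly as
#' Voronoi vertices are circumcentres of Delaunay tetrahedra.
#'
#' @param tet 4 x 3 matrix of vertex coordinates
#' @param tol relative volume tolerance below which the tetrahedron is
#'   treated as degenerate
#' @return numeric length-3 centre
#' @export
circumsphere_center <- function(tet, tol = 1e-12) {
  tet <- matrix(tet, 4, 3)
  A <- 2 * sweep(tet[2:4, , drop = FALSE], 2, tet[1, ], `-`)
  scale <- max(abs(A)) + 1e-300
  if (abs(det(A / scale)) < tol)
    stop("degenerate tetrahedron: no unique circumsphere centre")
  b <- rowSums(tet[2:4, , drop = FALSE]^2) - sum(tet[1, ]^2)
  as.numeric(solve(A, b))
}

tet_volume <- function(tet) {
  tet <- matrix(tet, 4, 3)
  abs(det(rbind(tet[2, ] - tet[1, ], tet[3, ] - tet[1, ],
                tet[4, ] - tet[1, ]))) / 6
}

tet_edge_lengths <- function(tet) {
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  sqrt(rowSums((tet[idx[, 1], ] - tet[idx[, 2], ])^2))
}

tet_radius_edge_ratio <- function(tet) {
  cc <- tryCatch(circumsphere_center(tet), error = function(e) NULL)
  if (is.null(cc)) return(Inf)
  r <- sqrt(sum((tet[1, ] - cc)^2))
  r / min(tet_edge_lengths(tet))
}

tet_min_dihedral <- function(tet) {
  # dihedral angle at each of the 6 edges, via face normals
  faces <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  normals <- t(apply(faces, 1, function(f) {
    n <- crossv(tet[f[2], ] - tet[f[1], ], tet[f[3], ] - tet[f[1], ])
    n / (sqrt(sum(n^2)) + 1e-300)
  }))
  # edge (i,j) is shared by the two faces containing both i and j
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  ang <- apply(pairs, 1, function(e) {
    fs <- which(apply(faces, 1, function(f) all(e %in% f)))
    c <- sum(normals[fs[1], ] * normals[fs[2], ])
    acos(pmin(1, pmax(-1, abs(c))))
  })
  min(ang) * 180 / pi
}

crossv <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Constrain a point into a tetrahedron
#'
#' Returns `p` unchanged when all its barycentric coordinates are at least
#' `margin`; otherwise projects it to the closest point of the tetrahedron
#' shrunk by that barycentric margin. Used to keep dual cell-corner vertices
#' inside their adjacency tetrahedron, avoiding face intersections when the
#' optimized complex no longer satisfies the Delaunay property.
#'
#' @param p length-3 point
#' @param tet 4 x 3 vertex matrix (non-degenerate)
#' @param margin barycentric margin in `[0, 0.25)`, default 0.05
#' @return length-3 point
#' @export
constrain_into_tetrahedron <- function(p, tet, margin = 0.05) {
  tet <- matrix(tet, 4, 3)
  b <- barycentric_coords(p, tet)
  if (all(b >= margin - 1e-12)) return(as.numeric(p))
  # vertices of the shrunk tetrahedron {x : all barycentric >= margin}
  shrunk <- t(apply(diag(4), 1, function(e) {
    w <- (1 - 4 * margin) * e + margin
    as.numeric(w %*% tet)
  }))
  bs <- barycentric_coords(p, shrunk)
  if (all(bs >= -1e-12)) return(as.numeric(p))
  faces <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  best <- NULL; bestd <- Inf
  for (f in seq_len(4)) {
    cp <- closest_point_triangle(as.numeric(p), shrunk[faces[f, 1], ],
                                 shrunk[faces[f, 2], ], shrunk[faces[f, 3], ])
    dd <- sum((p - cp)^2)
    if (dd < bestd) { bestd <- dd; best <- cp }
  }
  as.numeric(best)
}

barycentric_coords <- function(p, tet) {
  M <- rbind(t(tet), rep(1, 4))
  as.numeric(solve(M, c(p, 1)))
}

#' Delaunay adjacency complex of cell barycenters
#'
#' Computes the 3D Delaunay tetrahedrization of the cell centre points by
#' incremental insertion (Bowyer-Watson). Its tetrahedra are the starting
#' adjacency simplices of the dual reconstruction: the dual of this complex
#' is the Voronoi diagram of the barycenters, a first approximation of the
#' tissue geometry that the subsequent optimization corrects.
#'
#' @param barycenters n x 3 coordinate matrix with rownames = cell labels
#'   (n >= 4, not all coplanar)
#' @return a simplicial `incidence_complex` whose vertex ids are the cell
#'   labels and whose vertex positions are the barycenters
#' @export
delaunay_adjacency <- function(barycenters) {
  pts <- as.matrix(barycenters)
  if (nrow(pts) < 4) stop("need at least 4 points for a tetrahedrization")
  labs <- as.integer(rownames(pts))
  if (length(labs) == 0 || any(is.na(labs)))
    labs <- seq_len(nrow(pts))
  tets_idx <- delaunay_tets(pts)
  if (nrow(tets_idx) == 0)
    stop("degenerate input: points are coplanar, no tetrahedrization exists")
  tets <- matrix(labs[tets_idx], ncol = 4)
  pos <- pts
  rownames(pos) <- labs
  simplicial_from_tets(tets, positions = pos)
}

delaunay_tets <- function(pts) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  R <- sqrt(max(rowSums(sweep(pts, 2, ctr, `-`)^2))) + 1
  K <- 64
  super <- rbind(ctr + K * R * c(1, 1, 1), ctr + K * R * c(-1, -1, 1),
                 ctr + K * R * c(-1, 1, -1), ctr + K * R * c(1, -1, -1))
  P <- rbind(pts, super)
  tets <- matrix(n + 1:4, 1, 4)
  cc <- matrix(circumsphere_center(P[tets[1, ], ]), 1, 3)
  r2 <- sum((P[tets[1, 1], ] - cc[1, ])^2)
  for (ip in seq_len(n)) {
    p <- P[ip, ]
    d2 <- rowSums(sweep(cc, 2, p, `-`)^2)
    bad <- which(d2 <= r2 * (1 + 1e-10))
    if (length(bad) == 0) {
      # numerical fallback: point outside every circumsphere, take nearest
      bad <- which.min(d2 - r2)
    }
    faces <- do.call(rbind, lapply(bad, function(t) {
      tt <- tets[t, ]
      rbind(tt[c(1, 2, 3)], tt[c(1, 2, 4)], tt[c(1, 3, 4)], tt[c(2, 3, 4)])
    }))
    faces <- t(apply(faces, 1, sort))
    fk <- apply(faces, 1, paste, collapse = "-")
    keep <- names(which(table(fk) == 1))
    boundary <- faces[match(keep, fk), , drop = FALSE]
    tets <- tets[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    r2 <- r2[-bad]
    for (f in seq_len(nrow(boundary))) {
      newt <- c(boundary[f, ], ip)
      ccn <- tryCatch(circumsphere_center(P[newt, ]), error = function(e) NULL)
      if (is.null(ccn)) next
      tets <- rbind(tets, newt)
      cc <- rbind(cc, ccn)
      r2 <- c(r2, sum((P[newt[1], ] - ccn)^2))
    }
  }
  keep <- rowSums(tets > n) == 0
  tets <- tets[keep, , drop = FALSE]
  rownames(tets) <- NULL
  tets
}
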