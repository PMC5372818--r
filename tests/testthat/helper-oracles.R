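# Independent geometric oracles used to validate the package's own
# computations. These deliberately use brute force / enumeration instead of
# the implementation paths they check.

# circumcentres of every 4-subset of points, vectorized (cofactor inverse)
brute_circumcenters <- function(pts, subsets) {
  a <- pts[subsets[, 1], , drop = FALSE]
  b <- pts[subsets[, 2], , drop = FALSE]
  c <- pts[subsets[, 3], , drop = FALSE]
  d <- pts[subsets[, 4], , drop = FALSE]
  A1 <- 2 * (b - a); A2 <- 2 * (c - a); A3 <- 2 * (d - a)
  r1 <- rowSums(b^2) - rowSums(a^2)
  r2 <- rowSums(c^2) - rowSums(a^2)
  r3 <- rowSums(d^2) - rowSums(a^2)
  det3 <- A1[, 1] * (A2[, 2] * A3[, 3] - A2[, 3] * A3[, 2]) -
    A1[, 2] * (A2[, 1] * A3[, 3] - A2[, 3] * A3[, 1]) +
    A1[, 3] * (A2[, 1] * A3[, 2] - A2[, 2] * A3[, 1])
  cx <- r1 * (A2[, 2] * A3[, 3] - A2[, 3] * A3[, 2]) -
    A1[, 2] * (r2 * A3[, 3] - A2[, 3] * r3) +
    A1[, 3] * (r2 * A3[, 2] - A2[, 2] * r3)
  cy <- A1[, 1] * (r2 * A3[, 3] - A2[, 3] * r3) -
    r1 * (A2[, 1] * A3[, 3] - A2[, 3] * A3[, 1]) +
    A1[, 3] * (A2[, 1] * r3 - r2 * A3[, 1])
  cz <- A1[, 1] * (A2[, 2] * r3 - r2 * A3[, 2]) -
    A1[, 2] * (A2[, 1] * r3 - r2 * A3[, 1]) +
    r1 * (A2[, 1] * A3[, 2] - A2[, 2] * A3[, 1])
  cbind(cx, cy, cz) / det3
}

# Voronoi vertices of a point set by exhaustive 4-subset enumeration:
# keep circumcentres whose sphere contains no other point
brute_voronoi_vertices <- function(pts) {
  n <- nrow(pts)
  subsets <- t(utils::combn(n, 4))
  cc <- brute_circumcenters(pts, subsets)
  ok <- is.finite(rowSums(cc))
  subsets <- subsets[ok, , drop = FALSE]
  cc <- cc[ok, , drop = FALSE]
  r2 <- rowSums((pts[subsets[, 1], , drop = FALSE] - cc)^2)
  d2 <- outer(rowSums(cc^2), rep(1, n)) - 2 * cc %*% t(pts) +
    outer(rep(1, nrow(cc)), rowSums(pts^2))
  empty <- rowSums(d2 < r2 * (1 - 1e-9)) == 0
  list(subsets = subsets[empty, , drop = FALSE],
       centers = cc[empty, , drop = FALSE])
}

# generalized winding test: is a point inside a closed oriented surface?
winding_inside <- function(points, vertices, triangles) {
  out <- numeric(nrow(points))
  for (q in seq_len(nrow(points))) {
    p <- points[q, ]
    a <- sweep(vertices[triangles[, 1], , drop = FALSE], 2, p)
    b <- sweep(vertices[triangles[, 2], , drop = FALSE], 2, p)
    c <- sweep(vertices[triangles[, 3], , drop = FALSE], 2, p)
    la <- sqrt(rowSums(a^2)); lb <- sqrt(rowSums(b^2)); lc <- sqrt(rowSums(c^2))
    num <- a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])
    den <- la * lb * lc + rowSums(a * b) * lc + rowSums(a * c) * lb +
      rowSums(b * c) * la
    out[q] <- sum(2 * atan2(num, den)) / (4 * pi)
  }
  abs(out) > 0.5
}

jaccard_keys <- function(a, b) length(intersect(a, b)) / length(union(a, b))

edge_keys_of <- function(m) apply(m, 1, function(r) paste(sort(r), collapse = "-"))

# 26-connectivity component count of a voxel set
n_components_26 <- function(vox) {
  n <- nrow(vox)
  if (n == 0) return(0)
  key <- paste(vox[, 1], vox[, 2], vox[, 3])
  index <- stats::setNames(seq_len(n), key)
  seen <- rep(FALSE, n)
  comp <- 0
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- comp + 1
    queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- sweep(offs, 2, as.numeric(vox[cur, ]), `+`)
      hits <- index[paste(nb[, 1], nb[, 2], nb[, 3])]
      hits <- hits[!is.na(hits)]
      new <- hits[!seen[hits]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
  }
  comp
}
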