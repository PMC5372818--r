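test_that("four non-coplanar points give one tetrahedron, coplanar fail", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  rownames(pts) <- 1:4
  cx <- delaunay_adjacency(pts)
  expect_equal(nrow(complex_simplices(cx, 3)), 1)

  flat <- cbind(matrix(runif(10), 5, 2), 0)
  rownames(flat) <- 1:5
  expect_error(delaunay_adjacency(flat), "coplanar|degenerate")
  expect_error(delaunay_adjacency(pts[1:3, , drop = FALSE]), "at least 4")
})

test_that("a regular tetrahedron with its centroid splits into four", {
  pts <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  pts <- rbind(pts, colMeans(pts))
  rownames(pts) <- 1:5
  cx <- delaunay_adjacency(pts)
  got <- complex_simplices(cx, 3)
  expect_equal(nrow(got), 4)
  # oracle: enumerate all 4-subsets with an empty circumsphere
  oracle <- brute_voronoi_vertices(pts)
  expect_setequal(edge_keys_of(got), edge_keys_of(oracle$subsets))
})

test_that("all Delaunay tetrahedra satisfy the empty-circumsphere property", {
  set.seed(42)
  pts <- matrix(runif(90, 0, 10), 30, 3)
  rownames(pts) <- 1:30
  cx <- delaunay_adjacency(pts)
  tets <- complex_simplices(cx, 3)
  for (i in seq_len(nrow(tets))) {
    tv <- pts[as.character(tets[i, ]), ]
    cc <- circumsphere_center(tv)
    r2 <- sum((tv[1, ] - cc)^2)
    d2 <- rowSums(sweep(pts, 2, cc)^2)
    expect_equal(sum(d2 < r2 * (1 - 1e-9)), 0)
  }
  # and they exactly match the brute-force enumeration
  oracle <- brute_voronoi_vertices(pts)
  expect_setequal(edge_keys_of(tets), edge_keys_of(oracle$subsets))
})

test_that("circumsphere centres are equidistant points", {
  expect_equal(circumsphere_center(rbind(c(0, 0, 0), c(1, 0, 0),
                                         c(0, 1, 0), c(0, 0, 1))),
               c(0.5, 0.5, 0.5))
  # regular tetrahedron: centre at the centroid by symmetry
  reg <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(circumsphere_center(reg), c(0, 0, 0))
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_error(circumsphere_center(flat), "degenerate")
})

test_that("constrain_into_tetrahedron matches a dense sampling oracle", {
  tet <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4))
  # interior points are unchanged
  expect_equal(constrain_into_tetrahedron(colMeans(tet), tet), colMeans(tet))
  # zero margin keeps a point lying exactly on a face
  on_face <- c(1, 1, 0)
  expect_equal(constrain_into_tetrahedron(on_face, tet, margin = 0), on_face)
  # far outside points land on the shrunk tetrahedron, at the position a
  # dense barycentric sampling of it finds closest
  set.seed(3)
  w <- matrix(rexp(4 * 20000), ncol = 4)
  w <- w / rowSums(w)
  margin <- 0.05
  w <- w * (1 - 4 * margin) + margin
  cloud <- w %*% tet
  for (p in list(c(10, 10, 10), c(-3, 2, 2), c(2, -5, 9))) {
    got <- constrain_into_tetrahedron(p, tet, margin)
    d_got <- sum((p - got)^2)
    d_oracle <- min(rowSums(sweep(cloud, 2, p)^2))
    expect_lte(d_got, d_oracle + 1e-6)
    # the result respects the margin
    b <- tissuemesh:::barycentric_coords(got, tet)
    expect_true(all(b >= margin - 1e-6))
  }
})
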