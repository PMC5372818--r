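test_that("a single adjacency tetrahedron dualizes to one corner with four cells", {
  cx <- simplicial_from_tets(matrix(1:4, 1))
  expect_equal(element_counts(cx), c(4L, 6L, 4L, 1L))
  dd <- dualize(cx)
  expect_equal(element_counts(dd$complex), c(1L, 4L, 6L, 4L))
  # the dual map records the dimension swap and reuses ids
  expect_true(all(dd$dual_map$dual_dimension == 3 - dd$dual_map$dimension))
  expect_true(all(dd$dual_map$dual_id == dd$dual_map$id))
})

test_that("dualization is an involution and swaps element counts", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    pts <- matrix(runif(3 * n), n, 3)
    rownames(pts) <- seq_len(n)
    cx <- delaunay_adjacency(pts)
    dd <- dualize(cx)
    expect_equal(element_counts(dd$complex), rev(element_counts(cx)))
    back <- dualize(dd$complex)
    expect_true(complex_identical_structure(cx, back$complex))
  }
})

test_that("incidence reversal holds between a complex and its dual", {
  cx <- simplicial_from_tets(rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))
  dd <- dualize(cx)$complex
  # a (dim 2, triangle) bounds b (dim 3, tet)  <=>  dual(b) bounds dual(a)
  for (tet in cx$ids[[4]]) {
    for (tri in boundary_of(cx, 3, tet)) {
      expect_true(tet %in% boundary_of(dd, 1, tri))
    }
  }
})

test_that("validate_complex reports structural violations with element ids", {
  cx <- simplicial_from_tets(matrix(1:4, 1))
  expect_equal(nrow(validate_complex(cx, simplicial = TRUE)), 0)

  broken <- cx
  broken$bnd[[1]][["1"]] <- broken$bnd[[1]][["1"]][1]   # edge with 1 vertex
  rep1 <- validate_complex(broken)
  expect_true(any(rep1$dimension == 1 & rep1$id == 1))

  four_edges <- cx
  four_edges$bnd[[2]][["1"]] <- c(four_edges$bnd[[2]][["1"]], 5L)
  rep2 <- validate_complex(four_edges, simplicial = TRUE)
  expect_true(any(rep2$dimension == 2 & rep2$id == 1))

  missing_ref <- cx
  missing_ref$bnd[[3]][["1"]] <- c(1L, 2L, 3L, 99L)
  rep3 <- validate_complex(missing_ref)
  expect_true(any(grepl("missing", rep3$problem)))
})

test_that("boundary, coboundary and neighbour queries have set semantics", {
  cx <- simplicial_from_tets(rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))
  # an edge bounds exactly two vertices
  e1 <- cx$ids[[2]][1]
  expect_length(boundary_of(cx, 1, e1), 2)
  # the shared interior triangle {2,3,4} has both tetrahedra as coboundary
  tris <- complex_simplices(cx, 2)
  shared <- which(apply(tris, 1, function(r) all(r == c(2, 3, 4))))
  expect_equal(coboundary_of(cx, 2, shared), c(1L, 2L))
  # the two 3-cells are neighbours through it
  expect_equal(neighbors_of(cx, 3, 1L), 2L)
  expect_equal(neighbors_of(cx, 3, 2L), 1L)
  expect_error(boundary_of(cx, 2, 999), "no element")
})

test_that("complexes built from tetrahedra satisfy boundary closure", {
  set.seed(7)
  pts <- matrix(runif(24), 8, 3)
  rownames(pts) <- 1:8
  cx <- delaunay_adjacency(pts)
  # every face of every simplex is present: validate checks references,
  # and each triangle has 3 edges all present
  expect_equal(nrow(validate_complex(cx, simplicial = TRUE)), 0)
})
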