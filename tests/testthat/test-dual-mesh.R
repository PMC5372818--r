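test_that("the dual of a pristine Delaunay complex is the Voronoi diagram", {
  set.seed(12)
  pts <- matrix(runif(60, 0, 10), 20, 3)
  rownames(pts) <- 1:20
  cx <- delaunay_adjacency(pts)
  geom <- dual_geometry(cx)
  tets <- complex_simplices(cx, 3)
  oracle <- brute_voronoi_vertices(pts)
  okeys <- apply(oracle$subsets, 1, function(r) paste(sort(r), collapse = "-"))
  for (t in seq_len(nrow(tets))) {
    hit <- match(paste(sort(tets[t, ]), collapse = "-"), okeys)
    expect_false(is.na(hit))
    expect_lt(max(abs(geom$positions[t, ] - oracle$centers[hit, ]) /
                    pmax(abs(oracle$centers[hit, ]), 1)), 1e-9)
  }
})

test_that("a single tetrahedron dualizes to one interior corner and 4 capped cells", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  rownames(pos) <- 1:4
  cx <- simplicial_from_tets(matrix(1:4, 1), positions = pos)
  geom <- dual_geometry(cx)
  # 1 interior vertex (circumcentre) + 4 surface vertices
  expect_equal(element_counts(geom)[1], 5L)
  expect_equal(unname(geom$positions[1, ]), c(0.5, 0.5, 0.5))
  expect_equal(length(geom$ids[[4]]), 4)
  mesh <- star_triangulate(geom)
  for (cl in mesh_cells(mesh)) expect_true(cell_boundary_closed(mesh, cl))
  # interior corner touches exactly 4 cells, surface corners 3 + exterior
  cells0 <- geom$properties[["0"]]$cells
  expect_equal(length(cells0[["1"]]), 4)
  expect_true(all(vapply(cells0[as.character(2:5)], function(s)
    0 %in% s && length(s) == 4, logical(1))))
})

test_that("star triangulation fans one triangle per interface boundary edge", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  rownames(pos) <- 1:4
  geom <- dual_geometry(simplicial_from_tets(matrix(1:4, 1), positions = pos))
  mesh <- star_triangulate(geom)
  n_edges_per_face <- lengths(geom$bnd[[2]])
  expect_equal(nrow(mesh$triangles), sum(n_edges_per_face))
  # one added centre vertex per face
  expect_equal(nrow(mesh$vertices),
               nrow(geom$positions) + length(geom$ids[[3]]))
})

test_that("split refinement multiplies triangles and conserves area exactly", {
  m <- unit_cube_mesh()
  m1 <- split_refine(m, 1)
  expect_equal(nrow(m1$triangles), 4 * nrow(m$triangles))
  m2 <- split_refine(m, 2)
  expect_equal(nrow(m2$triangles), 16 * nrow(m$triangles))
  a0 <- sum(tissuemesh:::triangle_areas(m$vertices, m$triangles))
  a2 <- sum(tissuemesh:::triangle_areas(m2$vertices, m2$triangles))
  expect_equal(a2, a0)
  expect_true(cell_boundary_closed(m2, 5))
  # a lone triangle: 4 triangles on 6 vertices after one round
  tri <- tissue_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                     matrix(1:3, 1), matrix(c(0L, 2L), 1))
  tri1 <- split_refine(tri, 1)
  expect_equal(nrow(tri1$triangles), 4)
  expect_equal(nrow(tri1$vertices), 6)
})

test_that("watertightness detects a punctured cell", {
  m <- unit_cube_mesh()
  expect_true(cell_boundary_closed(m, 5))
  holed <- m
  holed$triangles <- m$triangles[-1, , drop = FALSE]
  holed$interface <- m$interface[-1, , drop = FALSE]
  expect_false(cell_boundary_closed(holed, 5))
  expect_error(cell_boundary_closed(m, 99), "unknown cell")
})

test_that("every cell of a reconstructed tissue mesh is watertight", {
  tm <- tiny_mesh()
  mesh <- tm$mesh
  for (cl in mesh_cells(mesh)) expect_true(cell_boundary_closed(mesh, cl))
  # interior junction corners join exactly 4 cells by construction
  interior <- which(vapply(mesh$corner_cells, function(s)
    !is.null(s) && !(0 %in% s), logical(1)))
  expect_true(all(lengths(mesh$corner_cells[interior]) == 4))
  # the mesh converts to a valid incidence complex
  cx <- as_incidence_complex(mesh)
  expect_equal(nrow(validate_complex(cx)), 0)
})
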