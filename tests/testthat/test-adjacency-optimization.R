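test_that("adjacency energy vanishes in its designed zero cases", {
  tt <- tiny_tissue()
  adj <- tt$adj
  cx <- delaunay_adjacency(cell_barycenters(tt$tis$image))
  zero_w <- energy_weights(0, 0, 0)
  expect_equal(adjacency_energy(cx, adj, zero_w)$total, 0)

  # a complex made of exactly the image simplices has zero image energy
  quads <- tissuemesh:::image_cell_quads(adj)
  img_cx <- simplicial_from_tets(quads,
                                 positions = cell_barycenters(tt$tis$image))
  en <- adjacency_energy(img_cx, adj, energy_weights())
  # edges may include a handful of pairs only seen in higher simplices
  expect_lt(en$e_image, 0.15)

  # equilateral tetrahedra carry zero elongation
  reg <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(tissuemesh:::tet_elongation(reg), 0)

  expect_error(adjacency_energy(simplicial_from_tets(matrix(900:903, 1)),
                                adj), "not present")
})

test_that("exterior cleaning is idempotent and can empty a complex", {
  # cleaning its own output changes nothing
  tt <- tiny_tissue()
  td <- tiny_adj_optim()
  again <- clean_exterior(td$cleaned, tt$adj)
  expect_identical(complex_simplices(again, 3),
                   complex_simplices(td$cleaned, 3))

  # one tetrahedron with a huge edge is removed, emptying the complex
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 40))
  rownames(pts) <- c(2, 3, 4, 5)
  lone <- delaunay_adjacency(pts)
  expect_error(clean_exterior(lone, tt$adj, max_edge_factor = 2),
               "every tetrahedron")
})

test_that("exterior cleaning removes hull tents over a concave tissue", {
  fx <- get_fixture("dome_small", function() {
    dome <- generate_layered_dome(14, 10, 6, resolution = 48, rng_seed = 9)
    list(dome = dome, adj = extract_adjacencies(dome$image))
  })
  dc <- delaunay_adjacency(cell_barycenters(fx$dome$image))
  cl <- clean_exterior(dc, fx$adj)
  n0 <- nrow(complex_simplices(dc, 3))
  n1 <- nrow(complex_simplices(cl, 3))
  expect_lt(n1, n0)
  # cleaning must improve agreement with the true adjacency
  tk <- edge_keys_of(fx$dome$true_adjacency)
  j0 <- jaccard_keys(edge_keys_of(complex_simplices(dc, 1)), tk)
  j1 <- jaccard_keys(edge_keys_of(complex_simplices(cl, 1)), tk)
  expect_gte(j1, j0)
})

test_that("adjacency optimization is deterministic and structurally sound", {
  td <- tiny_adj_optim()
  tt <- tiny_tissue()
  opt2 <- optimize_adjacency(td$cleaned, tt$adj,
                             schedule = annealing_schedule(rng_seed = 11,
                                                           cycles = 2,
                                                           steps_per_cycle = 15))
  expect_identical(complex_simplices(td$optimized, 3),
                   complex_simplices(opt2, 3))
  expect_equal(nrow(validate_complex(td$optimized, simplicial = TRUE)), 0)
  # every triangle belongs to at most two tetrahedra
  fk <- tissuemesh:::tet_face_keys(complex_simplices(td$optimized, 3))
  expect_lte(max(table(fk)), 2)
})

test_that("optimization improves adjacency recovery over Delaunay", {
  td <- tiny_adj_optim()
  tt <- tiny_tissue()
  tk <- edge_keys_of(tt$tis$true_adjacency)
  j_del <- jaccard_keys(edge_keys_of(complex_simplices(td$delaunay, 1)), tk)
  j_opt <- jaccard_keys(edge_keys_of(complex_simplices(td$optimized, 1)), tk)
  expect_gt(j_opt, j_del)
  # energy log: quench phase is non-increasing, final <= initial
  log <- attr(td$optimized, "energy_log")
  qe <- log$energy[log$phase == "quench"]
  expect_true(all(diff(qe) <= 1e-9))
  expect_lte(log$energy[nrow(log)], log$energy[1] + 1e-9)
})

test_that("layer tetra weights follow wall support and distance", {
  fx <- get_fixture("dome_small", function() {
    dome <- generate_layered_dome(14, 10, 6, resolution = 48, rng_seed = 9)
    list(dome = dome, adj = extract_adjacencies(dome$image))
  })
  adj <- fx$adj
  quads <- tissuemesh:::image_cell_quads(adj)
  q <- quads[1, ]
  w1 <- layer_tetra_weight(q, adj)
  expect_gt(w1, 0)
  # invariant under label permutation
  expect_equal(layer_tetra_weight(rev(q), adj), w1)
  # a quadruple with a non-adjacent pair scores zero
  e <- adjacency_edges(adj)
  labs <- as.integer(rownames(adj$barycenters))
  non_adj <- NULL
  for (a in labs) {
    for (b in labs) {
      if (a < b && !(paste(a, b, sep = "-") %in% edge_keys_of(e))) {
        non_adj <- c(a, b); break
      }
    }
    if (!is.null(non_adj)) break
  }
  others <- setdiff(labs, non_adj)[1:2]
  expect_equal(layer_tetra_weight(c(non_adj, others), adj), 0)
  expect_error(layer_tetra_weight(c(1000, 1001, 1002, 1003), adj),
               "not present")
})

test_that("layer aggregation reconstructs L1/L2 and the epidermal surface", {
  fx <- get_fixture("dome_small", function() {
    dome <- generate_layered_dome(14, 10, 6, resolution = 48, rng_seed = 9)
    list(dome = dome, adj = extract_adjacencies(dome$image))
  })
  adj <- fx$adj
  l12 <- aggregate_layer_complex(adj, "L1L2")
  expect_equal(nrow(validate_complex(l12, simplicial = TRUE)), 0)
  # every L1 and L2 cell appears as a vertex
  want <- as.integer(names(adj$layers)[adj$layers %in% c("L1", "L2")])
  expect_true(all(want %in% l12$ids[[1]]))
  # only L1/L2 labels participate
  expect_true(all(adj$layers[as.character(l12$ids[[1]])] %in% c("L1", "L2")))

  l1 <- aggregate_layer_complex(adj, "L1-surface")
  expect_equal(nrow(complex_simplices(l1, 3)), 0)
  expect_gt(nrow(complex_simplices(l1, 2)), 0)
  expect_true(all(adj$layers[as.character(l1$ids[[1]])] == "L1"))
  # its dual is a 2.5D polygonal mesh with one face per participating cell
  dd <- dualize(l1, top_dim = 2)$complex
  expect_equal(length(dd$ids[[3]]), length(l1$ids[[1]]))
})

test_that("conflicting equal-weight candidates resolve deterministically", {
  # two tetrahedra over the same base triangle with apexes on the same
  # side: geometrically overlapping, equal weight by symmetric wall areas
  bar <- rbind(a = c(0, 0, 0), b = c(2, 0, 0), c = c(1, 2, 0),
               d = c(1, 0.7, 1), e = c(1, 0.7, 2))
  rownames(bar) <- 2:6
  walls <- c("2-3" = 1, "2-4" = 1, "3-4" = 1, "2-5" = 1, "3-5" = 1,
             "4-5" = 1, "2-6" = 1, "3-6" = 1, "4-6" = 1)
  # scale the second apex walls so both candidate weights are equal
  d25 <- sqrt(sum((bar["5", ] - bar["2", ])^2))
  adj <- structure(list(
    barycenters = bar,
    edges = tissuemesh:::key_to_matrix(names(walls), 2),
    triangles = matrix(integer(0), 0, 3),
    tetrahedra = rbind(c(2, 3, 4, 5), c(2, 3, 4, 6)),
    wall_areas = walls, surface_cells = integer(0),
    layers = c("2" = "L1", "3" = "L1", "4" = "L1", "5" = "L2", "6" = "L2"),
    corner_points = list(keys = matrix(integer(0), 0, 4),
                         points = matrix(numeric(0), 0, 3)),
    background_label = 1L, voxel_size = c(1, 1, 1)),
    class = "image_adjacencies")
  w1 <- layer_tetra_weight(c(2, 3, 4, 5), adj)
  w2 <- layer_tetra_weight(c(2, 3, 4, 6), adj)
  expect_gt(w1, 0); expect_gt(w2, 0)
  out <- aggregate_layer_complex(adj, "L1L2")
  tets <- complex_simplices(out, 3)
  expect_equal(nrow(tets), 1)
  # the better-supported candidate (higher weight; here the nearer apex) wins
  expect_equal(sort(tets[1, ]), c(2, 3, 4, 5))
})
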