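test_that("intrinsic estimators score exactly 1 on ideal constructions", {
  hp <- hex_patch_mesh()
  sc <- intrinsic_scores(hp)
  expect_equal(sc$triangle_area_deviation, 1)
  expect_equal(sc$triangle_eccentricity, 1)
  expect_equal(sc$vertex_valence, 1)
})

test_that("degenerate triangles have eccentricity 1", {
  V <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  ecc <- tissuemesh:::triangle_eccentricity(V, matrix(1:3, 1))
  expect_equal(ecc, 1)
})

test_that("a convex cell has convexity 1 and ideal junctions score 1", {
  m <- unit_cube_mesh()
  expect_equal(prior_scores(m)$cell_convexity, 1)
  s <- icosphere_mesh(r = 2, subdiv = 1)
  expect_equal(prior_scores(s)$cell_convexity, 1, tolerance = 0.02)
})

test_that("voxelization reproduces an axis-aligned box exactly", {
  img <- segmented_image(array(1L, c(8, 8, 8)), c(0.25, 0.25, 0.25))
  m <- unit_cube_mesh(origin = c(0.3, 0.3, 0.3), size = 1)
  vx <- voxelize_mesh(m, img)
  centers <- voxel_centers(which(array(TRUE, c(8, 8, 8)), arr.ind = TRUE),
                           img)
  inside <- apply(centers, 1, function(p) all(p > 0.3 & p < 1.3))
  expect_equal(as.vector(vx$labels == 5L), unname(inside))
})

test_that("parity voxelization agrees with a winding-number oracle", {
  img <- segmented_image(array(1L, c(16, 16, 16)), c(0.5, 0.5, 0.5))
  s <- icosphere_mesh(r = 2.6, subdiv = 1)
  s$vertices <- sweep(s$vertices, 2, c(4, 4, 4), `+`)
  vx <- voxelize_mesh(s, img)
  centers <- voxel_centers(which(array(TRUE, dim(img$labels)),
                                 arr.ind = TRUE), img)
  tt <- tissuemesh:::orient_consistently(s$triangles)
  oracle <- winding_inside(centers, s$vertices, tt)
  expect_equal(as.vector(vx$labels == 2L), oracle)
})

test_that("image scores hit 1 on a voxel-faithful two-cell mesh", {
  a <- array(1L, c(8, 8, 8))
  a[3:6, 3:6, 3:4] <- 2L
  a[3:6, 3:6, 5:6] <- 3L
  img <- segmented_image(a)
  adj <- extract_adjacencies(img)
  # two stacked boxes in world coordinates [2,6]x[2,6]x[2,4]/[4,6],
  # sharing the middle wall (vertices 5..8) as their 2|3 interface
  V <- rbind(c(2, 2, 2), c(6, 2, 2), c(2, 6, 2), c(6, 6, 2),
             c(2, 2, 4), c(6, 2, 4), c(2, 6, 4), c(6, 6, 4),
             c(2, 2, 6), c(6, 2, 6), c(2, 6, 6), c(6, 6, 6))
  lower_ext <- rbind(c(1, 2, 3), c(2, 4, 3), c(1, 3, 5), c(3, 7, 5),
                     c(2, 6, 4), c(4, 6, 8), c(1, 5, 2), c(2, 5, 6),
                     c(3, 4, 7), c(4, 8, 7))
  upper_ext <- lower_ext + 4L
  upper_ext[1:2, ] <- rbind(c(9, 11, 10), c(10, 11, 12))
  wall <- rbind(c(5, 6, 7), c(6, 8, 7))
  mesh <- tissue_mesh(V, rbind(lower_ext, upper_ext, wall),
                      rbind(matrix(c(0L, 2L), 10, 2, byrow = TRUE),
                            matrix(c(0L, 3L), 10, 2, byrow = TRUE),
                            matrix(c(2L, 3L), 2, 2, byrow = TRUE)))
  sc <- image_scores(mesh, img, adj)
  expect_equal(sc$image_accuracy, 1)
  expect_equal(sc$cell_2adjacency, 1)
})

test_that("vertex distance is 1 at zero mean distance and missing without corners", {
  tm <- tiny_mesh()
  tt <- tiny_tissue()
  sc <- image_scores(tm$mesh, tt$tis$image, tt$adj,
                     voxelized = segmented_image(tt$tis$image$labels,
                                                 tt$tis$image$voxel_size))
  # pinned corners are at their image points; the mean distance only
  # reflects unmatched corners, so the score is high but defined
  expect_true(is.finite(sc$vertex_distance))
  # no corners at all -> missing, not zero
  cube <- unit_cube_mesh()
  a <- array(1L, c(4, 4, 4)); a[2:3, 2:3, 2:3] <- 5L
  img <- segmented_image(a)
  adj0 <- extract_adjacencies(img)
  sc0 <- image_scores(cube, img, adj0, voxelized = voxelize_mesh(cube, img))
  expect_true(is.na(sc0$vertex_distance))
})

test_that("mesh complexity is the reciprocal of triangles per cell", {
  fake <- function(n_tri_per_cell) {
    # interface table alone drives the estimator
    tissue_mesh(matrix(runif(9), 3), matrix(rep(1:3, n_tri_per_cell),
                                            ncol = 3, byrow = TRUE),
                matrix(c(0L, 2L), n_tri_per_cell, 2, byrow = TRUE))
  }
  expect_equal(complexity_score(fake(152))$mesh_complexity, 1)
  expect_equal(complexity_score(fake(304))$mesh_complexity, 0.5)
  expect_equal(complexity_score(fake(10))$mesh_complexity, 1)
})

test_that("the full quality report is complete, bounded and reproducible", {
  tm <- tiny_mesh()
  tt <- tiny_tissue()
  rep1 <- quality_report(tm$mesh, tt$tis$image, tt$adj)
  expect_length(rep1$scores, 10)
  ok <- !is.na(rep1$scores)
  expect_true(all(rep1$scores[ok] >= 0 & rep1$scores[ok] <= 1))
  expect_equal(rep1$average_quality, mean(rep1$scores, na.rm = TRUE))
  rep2 <- quality_report(tm$mesh, tt$tis$image, tt$adj)
  expect_identical(rep1$scores, rep2$scores)
})

test_that("tissue properties recover analytic volumes, areas and curvature", {
  m <- unit_cube_mesh()
  tp <- tissue_properties(m)
  expect_equal(unname(tp$cell_volumes["5"]), 1)
  expect_equal(sum(tp$interface_areas), 6)

  r <- 2.5
  s <- icosphere_mesh(r = r, subdiv = 2)
  tps <- tissue_properties(s)
  expect_lt(abs(mean(tps$surface_curvature$gaussian) - 1 / r^2) / (1 / r^2),
            0.1)
  expect_lt(abs(mean(tps$surface_curvature$mean) - 1 / r) / (1 / r), 0.1)
  # principal curvatures bracket the mean curvature
  expect_true(all(tps$surface_curvature$k1 >= tps$surface_curvature$k2))

  # a flat exterior patch has near-zero Gaussian curvature inside
  flat <- hex_patch_mesh(label_pair = c(0L, 2L))
  tpf <- tissuemesh:::surface_curvature(flat)
  if (nrow(tpf) > 0) expect_lt(max(abs(tpf$gaussian)), 1e-6)

  holed <- m
  holed$triangles <- m$triangles[-1, , drop = FALSE]
  holed$interface <- m$interface[-1, , drop = FALSE]
  expect_error(tissue_properties(holed), "open")
})
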