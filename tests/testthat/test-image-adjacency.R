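make_image <- function(a, vs = c(1, 1, 1), bg = 1L) {
  segmented_image(a, voxel_size = vs, background_label = bg)
}

# an image whose interior is filled by one value, border = background
framed <- function(n, fill) {
  a <- array(1L, c(n, n, n))
  a[2:(n - 1), 2:(n - 1), 2:(n - 1)] <- fill
  a
}

test_that("cell barycenters are voxel-centre means in world coordinates", {
  a <- array(1L, c(6, 6, 6))
  a[2:5, 2:5, 2:5] <- 7L                     # 4^3 cube at index 2..5
  img <- make_image(a)
  b <- cell_barycenters(img)
  expect_equal(unname(b["7", ]), c(3, 3, 3))
  # anisotropic voxels scale the world coordinates
  img2 <- make_image(a, vs = c(2, 1, 0.5))
  expect_equal(unname(cell_barycenters(img2)["7", ]), c(6, 3, 1.5))
})

test_that("two half-volumes have mirror-symmetric barycenters", {
  a <- framed(8, 2L)
  a[5:7, 2:7, 2:7] <- 3L
  b <- cell_barycenters(make_image(a))
  mid <- mean(b[, 1])
  expect_equal(unname(b["2", 2:3]), unname(b["3", 2:3]))
  expect_equal(unname(abs(b["2", 1] - mid)), unname(abs(b["3", 1] - mid)))
})

test_that("a uniform image yields no adjacencies and a two-label plane one wall", {
  img1 <- make_image(framed(6, 2L))
  adj1 <- extract_adjacencies(img1)
  expect_equal(nrow(adjacency_edges(adj1)), 0)

  a <- framed(8, 2L)
  a[5:7, 2:7, 2:7] <- 3L
  adj <- extract_adjacencies(make_image(a))
  e <- adjacency_edges(adj)
  expect_equal(e, matrix(c(2L, 3L), 1))
  # the wall is a full 6x6 plane of voxel faces
  expect_equal(unname(adj$wall_areas["2-3"]), 36)
})

test_that("a pure four-quadrant line contact is treated as an ambiguous junction", {
  # four quadrant columns meet only along the central lattice line: the
  # diagonal pairs share no wall, so the co-occurring triples and the
  # quadruple are corner-touch ambiguities and are filtered out
  a <- array(1L, c(6, 6, 6))
  a[2:3, 2:3, 2:5] <- 2L
  a[4:5, 2:3, 2:5] <- 3L
  a[2:3, 4:5, 2:5] <- 4L
  a[4:5, 4:5, 2:5] <- 5L
  adj <- extract_adjacencies(make_image(a))
  e <- adjacency_edges(adj)
  expect_equal(nrow(e), 4)                 # only the wall-sharing pairs
  expect_false("2-5" %in% edge_keys_of(e))
  expect_false("3-4" %in% edge_keys_of(e))
  expect_equal(sum(rowSums(adj$triangles == 1L) == 0), 0)
  expect_equal(sum(rowSums(adj$tetrahedra == 1L) == 0), 0)
})

test_that("a generic four-cell corner is extracted at the meeting point", {
  # two cells below split along x, two above split along y: all six pairs
  # share a wall and the four labels co-occur in exactly one voxel block
  a <- array(1L, c(6, 6, 6))
  a[2:3, 2:5, 2:3] <- 2L
  a[4:5, 2:5, 2:3] <- 3L
  a[2:5, 2:3, 4:5] <- 4L
  a[2:5, 4:5, 4:5] <- 5L
  adj <- extract_adjacencies(make_image(a))
  e <- adjacency_edges(adj)
  expect_equal(nrow(e), 6)
  tris_cells <- adj$triangles[rowSums(adj$triangles == 1L) == 0, ,
                              drop = FALSE]
  expect_equal(nrow(tris_cells), 4)
  quads_cells <- adj$tetrahedra[rowSums(adj$tetrahedra == 1L) == 0, ,
                                drop = FALSE]
  expect_equal(nrow(quads_cells), 1)
  expect_equal(sort(quads_cells[1, ]), 2:5)
  cp <- adj$corner_points
  hit <- match("2-3-4-5", apply(cp$keys, 1, paste, collapse = "-"))
  expect_false(is.na(hit))
  expect_equal(unname(cp$points[hit, ]), c(3, 3, 3))
})

test_that("corner points are empty for a two-label image", {
  a <- framed(8, 2L)
  a[5:7, 2:7, 2:7] <- 3L
  cp <- cell_corner_points(make_image(a))
  expect_equal(nrow(cp$keys), 0)
})

test_that("layer assignment separates an enclosed cell from its shell", {
  a <- array(1L, c(8, 8, 8))
  a[2:7, 2:7, 2:7] <- 2L     # outer shell touches the background
  a[3:6, 3:6, 3:5] <- 3L     # inner cell touches only the shell
  adj <- extract_adjacencies(make_image(a))
  expect_equal(unname(adj$layers["2"]), "L1")
  expect_equal(unname(adj$layers["3"]), "L2")

  single <- extract_adjacencies(make_image(framed(6, 4L)))
  expect_equal(unname(single$layers["4"]), "L1")
})

test_that("extracted simplices are closed over their faces", {
  tt <- tiny_tissue()
  adj <- tt$adj
  ek <- edge_keys_of(adj$edges)
  tk <- edge_keys_of(adj$triangles)
  for (i in seq_len(nrow(adj$triangles))) {
    tr <- adj$triangles[i, ]
    prs <- rbind(tr[c(1, 2)], tr[c(1, 3)], tr[c(2, 3)])
    expect_true(all(edge_keys_of(prs) %in% ek))
  }
  for (i in seq_len(nrow(adj$tetrahedra))) {
    q <- adj$tetrahedra[i, ]
    faces <- rbind(q[c(1, 2, 3)], q[c(1, 2, 4)], q[c(1, 3, 4)], q[c(2, 3, 4)])
    expect_true(all(edge_keys_of(faces) %in% tk))
  }
})

test_that("rasterized contacts cover the exact adjacency of a Voronoi tissue", {
  tt <- tiny_tissue()
  truth <- edge_keys_of(tt$tis$true_adjacency)
  found <- edge_keys_of(adjacency_edges(tt$adj))
  # voxelization may add corner-touch contacts but misses at most a facet
  # smaller than a voxel
  expect_lte(sum(!(truth %in% found)), ceiling(0.02 * length(truth)))
  # and every barycenter lies inside its own cell region
  b <- cell_barycenters(tt$tis$image)
  idx <- floor(b) + 1L
  labs <- as.integer(rownames(b))
  at <- tt$tis$image$labels[cbind(idx[, 1], idx[, 2], idx[, 3])]
  expect_gte(mean(at == labs), 0.9)
})

test_that("the binary isosurface of a ball has the analytic sphere area", {
  n <- 28; r <- 10
  ctr <- c(n / 2, n / 2, n / 2)
  grid <- as.matrix(expand.grid(1:n, 1:n, 1:n)) - 0.5
  a <- array(1L, c(n, n, n))
  inside <- rowSums(sweep(grid, 2, ctr)^2) <= r^2
  a[inside] <- 2L
  img <- make_image(a)
  iso <- binary_isosurface(img)
  expect_lt(abs(surface_area(iso) - 4 * pi * r^2) / (4 * pi * r^2), 0.1)
  # all isosurface vertices stay within a voxel of the mask boundary
  d_ctr <- sqrt(rowSums(sweep(iso$vertices, 2, ctr)^2))
  expect_lt(max(abs(d_ctr - r)), 1.8)
})

test_that("an empty foreground is rejected", {
  a <- array(1L, c(6, 6, 6))
  expect_error(binary_isosurface(make_image(a)), "empty foreground")
})
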