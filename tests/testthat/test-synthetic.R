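test_that("generators are deterministic under a fixed seed", {
  a <- generate_voronoi_tissue(8, "box", resolution = 32, rng_seed = 3)
  b <- generate_voronoi_tissue(8, "box", resolution = 32, rng_seed = 3)
  expect_identical(a$image$labels, b$image$labels)
  expect_identical(a$true_adjacency, b$true_adjacency)
  c <- generate_voronoi_tissue(8, "box", resolution = 32, rng_seed = 4)
  expect_false(identical(a$image$labels, c$image$labels))
})

test_that("tissue generation validates its inputs and labels", {
  expect_error(generate_voronoi_tissue(3, "box"), "n_cells")
  tis <- generate_voronoi_tissue(8, "box", resolution = 32, rng_seed = 3)
  expect_equal(image_labels(tis$image), 2:9)
  expect_length(validate_image(tis$image), 0)
})

test_that("isotropic ground truth matches the clipped Delaunay of the seeds", {
  tt <- tiny_tissue()
  tis <- tt$tis
  # every true adjacency is a Delaunay edge of the seeds
  dc <- delaunay_adjacency(tis$seeds)
  dk <- edge_keys_of(complex_simplices(dc, 1))
  expect_true(all(edge_keys_of(tis$true_adjacency) %in% dk))
  # true corners are empty-circumsphere subsets inside the domain
  oracle <- brute_voronoi_vertices(tis$seeds)
  labs <- as.integer(rownames(tis$seeds))
  okeys <- apply(oracle$subsets, 1, function(r)
    paste(sort(labs[r]), collapse = "-"))
  ckeys <- apply(tis$true_corners$keys, 1, paste, collapse = "-")
  expect_true(all(ckeys %in% okeys))
})

test_that("the layered dome reproduces the meristem layer organisation", {
  fx <- get_fixture("dome_small", function() {
    dome <- generate_layered_dome(14, 10, 6, resolution = 48, rng_seed = 9)
    list(dome = dome, adj = extract_adjacencies(dome$image))
  })
  dome <- fx$dome; adj <- fx$adj
  la <- layer_assignment(adj)
  expect_identical(unname(la[names(dome$layer_truth)]),
                   unname(dome$layer_truth))
  l1 <- names(dome$layer_truth)[dome$layer_truth == "L1"]
  expect_true(all(l1 %in% as.character(adj$surface_cells)))
  # dome cap: background above the tissue along the central axis
  d <- dim(dome$image$labels)
  column <- dome$image$labels[d[1] %/% 2, d[2] %/% 2, ]
  top <- max(which(column != 1))
  expect_true(all(column[(top + 1):d[3]] == 1))
  expect_true(top < d[3])
})

test_that("degradation perturbs boundaries but preserves labels and regions", {
  tis <- generate_voronoi_tissue(8, "box", resolution = 32, rng_seed = 3)
  expect_identical(degrade(tis$image, 0), tis$image)
  deg <- degrade(tis$image, 0.05, rng_seed = 1)
  expect_setequal(unique(as.vector(deg$labels)),
                  unique(as.vector(tis$image$labels)))
  changed <- sum(deg$labels != tis$image$labels)
  expect_gt(changed, 0)
  # regions stay 26-connected
  for (lab in image_labels(deg)) {
    vox <- which(deg$labels == lab, arr.ind = TRUE)
    expect_equal(n_components_26(vox), 1)
  }
})
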