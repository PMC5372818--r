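test_that("surface projection never increases the distance to the surface", {
  tm <- tiny_mesh()
  tt <- tiny_tissue()
  mesh <- tm$mesh
  # re-projecting an already projected mesh moves nothing
  again <- project_surface_vertices(mesh, tm$iso)
  expect_equal(again$vertices, mesh$vertices, tolerance = 1e-10)
  # from jittered positions, every move is distance non-increasing
  jit <- mesh
  set.seed(4)
  sel <- which(jit$is_surface & !jit$pinned)
  jit$vertices[sel, ] <- jit$vertices[sel, ] + matrix(rnorm(3 * length(sel),
                                                            0, 0.4),
                                                      ncol = 3)
  proj <- project_surface_vertices(jit, tm$iso)
  d_before <- sqrt(rowSums((jit$vertices[sel, ] - mesh$vertices[sel, ])^2))
  d_after <- sqrt(rowSums((proj$vertices[sel, ] - jit$vertices[sel, ])^2))
  # the projection target is within the jitter distance of the start
  expect_true(all(d_after <= d_before + 1e-8))
})

test_that("corner pinning matches image corners by label set", {
  tm <- tiny_mesh()
  tt <- tiny_tissue()
  mesh <- tm$mesh
  expect_gt(sum(mesh$pinned), 0)
  # pinned corner vertices sit exactly at their image corner point
  cp <- tt$adj$corner_points
  keys <- cp$keys; keys[keys == 1L] <- 0L
  ikeys <- apply(t(apply(keys, 1, sort)), 1, paste, collapse = "-")
  for (v in which(mesh$pinned)) {
    k <- paste(sort(mesh$corner_cells[[v]]), collapse = "-")
    hit <- match(k, ikeys)
    expect_false(is.na(hit))
    expect_equal(unname(mesh$vertices[v, ]), unname(cp$points[hit, ]))
  }
  # most interior corners of the fixture find their image counterpart
  interior <- which(vapply(mesh$corner_cells, function(s)
    !is.null(s) && !(0 %in% s), logical(1)))
  expect_gte(mean(mesh$pinned[interior]), 0.9)
  # a corner with an unobserved label set stays unpinned and is reported
  fake <- mesh
  fake$corner_cells[[interior[1]]] <- c(9991L, 9992L, 9993L, 9994L)
  fake$pinned[] <- FALSE
  out <- pin_cell_corners(fake, tt$adj$corner_points, background_label = 1L)
  expect_false(out$pinned[interior[1]])
  expect_true("9991-9992-9993-9994" %in% attr(out, "unmatched"))
})

test_that("mesh energy vanishes in its designed zero cases", {
  m <- unit_cube_mesh(origin = c(1, 1, 1), size = 4)
  img <- segmented_image(array(1L, c(6, 6, 6)))
  img$labels[2:5, 2:5, 2:5] <- 5L
  expect_equal(mesh_energy(m, img, mesh_weights(0, 0, 0))$total, 0)
  # perfectly planar interfaces have zero flatness energy
  expect_equal(tissuemesh:::interface_flatness(
    hex_patch_mesh(), tissuemesh:::interface_planes(hex_patch_mesh())), 0)
  # equilateral valence-6 interiors have zero regularity contributions
  hp <- hex_patch_mesh()
  ecc <- tissuemesh:::triangle_eccentricity(hp$vertices, hp$triangles)
  expect_equal(max(ecc), 0, tolerance = 1e-10)
  expect_equal(tissuemesh:::valence_deviation(hp), 0)
})

test_that("isotropic remeshing reaches the target length and guards budget", {
  m <- unit_cube_mesh(size = 10)
  out <- isotropic_remesh(m, target_length = 3, iterations = 4)
  med <- stats::median(tissuemesh:::mesh_edge_lengths(out)$len)
  expect_lt(abs(med - 3) / 3, 0.25)
  expect_true(cell_boundary_closed(out, 5))
  expect_identical(mesh_adjacency_edges(out), mesh_adjacency_edges(m))
  expect_error(isotropic_remesh(m, 0.01, max_elements = 20),
               "element budget")
})

test_that("already-uniform meshes pass through remeshing essentially unchanged", {
  hp <- hex_patch_mesh()
  med <- stats::median(tissuemesh:::mesh_edge_lengths(hp)$len)
  out <- isotropic_remesh(hp, target_length = med, iterations = 2)
  expect_equal(nrow(out$triangles), nrow(hp$triangles))
})

test_that("mesh optimization is deterministic, adjacency- and shape-safe", {
  tm <- get_fixture("tiny_mesh_optim", function() {
    tm0 <- tiny_mesh()
    tt <- tiny_tissue()
    sw <- mesh_weights(schedule = annealing_schedule(rng_seed = 11,
                                                     cycles = 1,
                                                     steps_per_cycle = 5))
    m1 <- optimize_mesh(tm0$mesh, tt$tis$image, sw, isosurface = tm0$iso)
    m2 <- optimize_mesh(tm0$mesh, tt$tis$image, sw, isosurface = tm0$iso)
    list(before = tm0$mesh, m1 = m1, m2 = m2)
  })
  expect_identical(tm$m1$vertices, tm$m2$vertices)
  expect_identical(tm$m1$triangles, tm$m2$triangles)
  expect_identical(mesh_adjacency_edges(tm$m1),
                   mesh_adjacency_edges(tm$before))
  for (cl in mesh_cells(tm$m1)) expect_true(cell_boundary_closed(tm$m1, cl))
  # energy accounting: quench monotone, final <= initial
  log <- attr(tm$m1, "energy_log")
  qe <- log$energy[log$phase == "quench"]
  expect_true(all(diff(qe) <= 1e-9))
  expect_lte(log$energy[nrow(log)], log$energy[1] + 1e-9)
  # per-cell volumes change by less than 10%
  v0 <- tissue_properties(tm$before)$cell_volumes
  v1 <- tissue_properties(tm$m1)$cell_volumes
  expect_lt(max(abs(v1 - v0) / v0), 0.10)
})
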