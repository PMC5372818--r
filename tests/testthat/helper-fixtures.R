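# Shared fixtures, built once per test session (the cache environment
# persists across test files within one run).

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# small isotropic box tissue for fast unit tests
tiny_tissue <- function() get_fixture("tiny", function() {
  tis <- generate_voronoi_tissue(15, "box", resolution = 48, rng_seed = 11)
  adj <- extract_adjacencies(tis$image)
  list(tis = tis, adj = adj)
})

tiny_adj_optim <- function() get_fixture("tiny_adj_optim", function() {
  tt <- tiny_tissue()
  dc <- delaunay_adjacency(cell_barycenters(tt$tis$image))
  cl <- clean_exterior(dc, tt$adj)
  opt <- optimize_adjacency(cl, tt$adj,
                            schedule = annealing_schedule(rng_seed = 11,
                                                          cycles = 2,
                                                          steps_per_cycle = 15))
  list(delaunay = dc, cleaned = cl, optimized = opt)
})

tiny_mesh <- function() get_fixture("tiny_mesh", function() {
  tt <- tiny_tissue()
  td <- tiny_adj_optim()
  iso <- binary_isosurface(tt$tis$image)
  mesh <- star_triangulate(dual_geometry(td$optimized, tt$adj,
                                         isosurface = iso))
  mesh <- project_surface_vertices(mesh, iso)
  mesh <- pin_cell_corners(mesh, tt$adj$corner_points,
                           background_label = 1L)
  list(mesh = mesh, iso = iso)
})

# closed unit-cube cell mesh (12 triangles), cell label 5
unit_cube_mesh <- function(origin = c(0, 0, 0), size = 1, label = 5L) {
  V <- as.matrix(expand.grid(0:1, 0:1, 0:1))[, 3:1] * size
  V <- sweep(V, 2, origin, `+`)
  tris <- rbind(c(1, 2, 3), c(2, 4, 3), c(5, 7, 6), c(6, 7, 8),
                c(1, 3, 5), c(3, 7, 5), c(2, 6, 4), c(4, 6, 8),
                c(1, 5, 2), c(2, 5, 6), c(3, 4, 7), c(4, 8, 7))
  tissue_mesh(V, tris, matrix(c(0L, label), 12, 2, byrow = TRUE))
}

# icosphere of radius r as a single closed cell, by midpoint subdivision
icosphere_mesh <- function(r = 1, subdiv = 2, label = 2L) {
  phi <- (1 + sqrt(5)) / 2
  iv <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
              c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
              c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7),
             c(8, 2, 9), c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9),
             c(4, 9, 10), c(5, 10, 6), c(3, 5, 12), c(7, 3, 11),
             c(9, 7, 8), c(10, 9, 2))
  V <- iv / sqrt(rowSums(iv^2)) * r
  for (s in seq_len(subdiv)) {
    m <- tissue_mesh(V, f, matrix(c(0L, label), nrow(f), 2, byrow = TRUE))
    m <- split_refine(m, 1)
    V <- m$vertices / sqrt(rowSums(m$vertices^2)) * r
    f <- m$triangles
  }
  tissue_mesh(V, f, matrix(c(0L, label), nrow(f), 2, byrow = TRUE))
}

# regular triangular grid patch (all equilateral, interior valence 6)
hex_patch_mesh <- function(n = 6, label_pair = c(2L, 3L)) {
  pts <- list(); id <- function(i, j) paste(i, j)
  idx <- new.env(parent = emptyenv())
  V <- NULL; k <- 0
  for (j in 0:n) for (i in 0:n) {
    k <- k + 1
    idx[[id(i, j)]] <- k
    V <- rbind(V, c(i + j / 2, j * sqrt(3) / 2, 0))
  }
  tris <- list()
  for (j in 0:(n - 1)) for (i in 0:(n - 1)) {
    tris[[length(tris) + 1]] <- c(idx[[id(i, j)]], idx[[id(i + 1, j)]],
                                  idx[[id(i, j + 1)]])
    tris[[length(tris) + 1]] <- c(idx[[id(i + 1, j)]],
                                  idx[[id(i + 1, j + 1)]],
                                  idx[[id(i, j + 1)]])
  }
  tt <- do.call(rbind, tris)
  tissue_mesh(V, tt, matrix(label_pair, nrow(tt), 2, byrow = TRUE))
}
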