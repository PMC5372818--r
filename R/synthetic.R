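#' Synthetic segmented tissues with known ground truth
#'
#' Meristematic tissue closely resembles a (locally anisotropic) Voronoi
#' tessellation of the cell centres, which makes Voronoi-type generators a
#' natural source of test tissues: every stage of the reconstruction can be
#' validated against the exact generator geometry without any external data.
#' [generate_voronoi_tissue()] rasterizes an anisotropic-metric Voronoi
#' tessellation of Poisson-disc seeds in a box or dome domain;
#' [generate_layered_dome()] emulates the layered organisation of the shoot
#' apical meristem (single-cell-thick L1 and L2 layers over an inner bulk);
#' [degrade()] perturbs region boundaries to emulate segmentation noise.
#'
#' All generators are deterministic given `rng_seed` and return a
#' `synthetic_tissue` carrying the image plus the exact (non-rasterized)
#' ground truth: seed positions, true adjacency (contacts of the exact
#' diagram clipped to the domain), true corner points (Voronoi vertices) and
#' per-cell layer truth.
#'
#' @param n_cells number of cells (>= 5)
#' @param domain `"box"` or `"dome"` (hemispherical cap)
#' @param resolution voxels per axis (>= 32)
#' @param anisotropy 3 positive metric scale factors; label assignment uses
#'   the axis-scaled Euclidean distance, so a factor of 2 along x produces
#'   cells elongated 2x along x, the failure mode that breaks the plain
#'   Voronoi/Delaunay approximation
#' @param jitter in `[0, 1)`: 0 = maximally even Poisson-disc packing, larger
#'   values allow closer seed pairs
#' @param voxel_size physical voxel edge (micrometres)
#' @param rng_seed integer seed
#' @return an object of class `synthetic_tissue`: list with `image`
#'   (`segmented_image`), `seeds` (matrix, rownames = labels),
#'   `true_adjacency` (n x 2 label matrix), `true_corners` (list `keys`,
#'   `points`), `layer_truth` (named character), `rng_seed`.
#' @export
generate_voronoi_tissue <- function(n_cells, domain = c("box", "dome"),
                                    resolution = 64,
                                    anisotropy = c(1, 1, 1), jitter = 0.3,
                                    voxel_size = 1, rng_seed = 1) {
  domain <- match.arg(domain)
  stopifnot(n_cells >= 5, resolution >= 32, all(anisotropy > 0))
  S <- resolution * voxel_size
  margin <- 2.5 * voxel_size
  inside <- domain_predicate(domain, S, margin)
  seeds <- with_seed(rng_seed, {
    poisson_disc(n_cells, inside, S, jitter)
  })
  labels <- 2:(n_cells + 1)
  rownames(seeds) <- labels
  img <- rasterize_voronoi(seeds, inside, resolution, anisotropy, voxel_size)
  if (length(unique(as.vector(img$labels))) - 1 < n_cells)
    stop("resolution too low to separate the seeds: a cell has no voxel")
  truth <- exact_adjacency(seeds, inside, anisotropy, S)
  structure(list(image = img, seeds = seeds,
                 true_adjacency = truth$edges, true_corners = truth$corners,
                 layer_truth = NULL, rng_seed = rng_seed),
            class = "synthetic_tissue")
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  cat(sprintf("<synthetic_tissue> %d cells, %d true adjacencies, seed %d\n",
              nrow(x$seeds), nrow(x$true_adjacency), x$rng_seed))
  print(x$image)
  invisible(x)
}

#' Layered dome tissue emulating the meristem L1/L2 organisation
#'
#' The dome is stratified into three concentric shells, reproducing the
#' anticlinal layering of the meristem: a single-cell-thick epidermal shell
#' (L1, every cell touches the background), a subepidermal shell underneath
#' (L2, touching L1 but never the background) and an inner bulk. Each voxel
#' is assigned to the shell its depth falls in and then to the nearest seed
#' of that shell, so the layer organisation holds by construction for any
#' cell counts. Ground-truth adjacency is extracted from a rasterization of
#' the same tessellation at twice the resolution (contacts of one voxel
#' face at double resolution are discarded as corner-touch ambiguities);
#' ground-truth corner points are the corner points of that tessellation.
#'
#' @param n_L1,n_L2,n_inner cell counts per compartment (>= 3 each)
#' @param resolution voxels per axis
#' @param voxel_size physical voxel edge (micrometres)
#' @param rng_seed integer seed
#' @return a `synthetic_tissue` with `layer_truth` filled in
#' @export
generate_layered_dome <- function(n_L1 = 24, n_L2 = 16, n_inner = 12,
                                  resolution = 64, voxel_size = 1,
                                  rng_seed = 1) {
  stopifnot(n_L1 >= 3, n_L2 >= 3, n_inner >= 3)
  S <- resolution * voxel_size
  margin <- 2.5 * voxel_size
  dome <- dome_geometry(S, margin)
  # depth below the tissue boundary (curved cap or flat base)
  bdist <- function(p) pmin(dome$R - sqrt(rowSums(sweep(p, 2, dome$center, `-`)^2)),
                            p[, 3] - dome$z0)
  t1 <- 0.18 * dome$R
  t2 <- 0.18 * dome$R
  if (t1 < 1.5 * voxel_size)
    stop("shell spacing below the voxel size: increase the resolution")
  inside <- function(p) bdist(p) >= 0
  layer_of_point <- function(p) {
    d <- bdist(p)
    ifelse(d < t1, 1L, ifelse(d < t1 + t2, 2L, 3L))
  }
  seeds <- with_seed(rng_seed, {
    s1 <- poisson_disc(n_L1, function(p) {
      d <- bdist(p); d >= 0.25 * t1 & d < 0.75 * t1
    }, S, 0.3)
    s2 <- poisson_disc(n_L2, function(p) {
      d <- bdist(p); d >= t1 + 0.25 * t2 & d < t1 + 0.75 * t2
    }, S, 0.3)
    s3 <- poisson_disc(n_inner, function(p) bdist(p) >= t1 + 1.25 * t2, S, 0.3)
    rbind(s1, s2, s3)
  })
  labels <- 2:(nrow(seeds) + 1)
  rownames(seeds) <- labels
  seed_layer <- rep(1:3, c(n_L1, n_L2, n_inner))
  layer_truth <- stats::setNames(c("L1", "L2", "deeper")[seed_layer], labels)
  img <- rasterize_voronoi(seeds, inside, resolution, c(1, 1, 1), voxel_size,
                           seed_layer = seed_layer,
                           layer_of_point = layer_of_point)
  if (length(unique(as.vector(img$labels))) - 1 < nrow(seeds))
    stop("resolution too low to separate the seeds: a cell has no voxel")
  fine <- rasterize_voronoi(seeds, inside, 2L * resolution, c(1, 1, 1),
                            voxel_size / 2, seed_layer = seed_layer,
                            layer_of_point = layer_of_point)
  edges <- raster_cell_edges(fine$labels, 1L, min_faces = 2)
  corners <- cell_corner_points(fine)
  structure(list(image = img, seeds = seeds,
                 true_adjacency = edges, true_corners = corners,
                 layer_truth = layer_truth, rng_seed = rng_seed),
            class = "synthetic_tissue")
}

#' Degrade a segmented image by boundary voxel swaps
#'
#' Reassigns a random fraction of inter-region boundary voxels to the label
#' of one of their face neighbours, emulating local segmentation errors.
#' Swaps that would locally disconnect a region (the voxel's same-label face
#' neighbours no longer mutually connected inside its 3x3x3 neighbourhood)
#' are rejected, so region connectivity is preserved.
#'
#' @param image a `segmented_image`
#' @param swap_fraction fraction of boundary voxels to perturb, in `[0, 0.1)`
#' @param rng_seed integer seed
#' @return a `segmented_image`
#' @export
degrade <- function(image, swap_fraction, rng_seed = 1) {
  stopifnot(swap_fraction >= 0, swap_fraction < 0.1)
  if (swap_fraction == 0) return(image)
  a <- image$labels
  d <- dim(a)
  bnd <- boundary_voxels(a)
  n_swap <- floor(nrow(bnd) * swap_fraction)
  with_seed(rng_seed, {
    pick <- bnd[sample.int(nrow(bnd), n_swap), , drop = FALSE]
    for (q in seq_len(nrow(pick))) {
      v <- pick[q, ]
      lab <- a[v[1], v[2], v[3]]
      nb <- face_neighbors(v, d)
      nlabs <- a[nb]
      alt <- setdiff(unique(nlabs), lab)
      if (length(alt) == 0) next
      new_lab <- alt[sample.int(length(alt), 1)]
      if (is_simple_swap(a, v, lab)) a[v[1], v[2], v[3]] <- new_lab
    }
  })
  segmented_image(a, image$voxel_size, image$background_label)
}

# ---- internals ---------------------------------------------------------

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

domain_predicate <- function(domain, S, margin) {
  if (domain == "box") {
    function(p) p[, 1] >= margin & p[, 1] <= S - margin &
      p[, 2] >= margin & p[, 2] <= S - margin &
      p[, 3] >= margin & p[, 3] <= S - margin
  } else {
    g <- dome_geometry(S, margin)
    function(p) p[, 3] >= g$z0 &
      rowSums(sweep(p, 2, g$center, `-`)^2) <= g$R^2
  }
}

dome_geometry <- function(S, margin) {
  # hemispherical cap resting slightly above the bottom image border
  z0 <- margin
  R <- (S - 2 * margin) / 2
  list(center = c(S / 2, S / 2, z0), R = R, z0 = z0)
}

poisson_disc <- function(n, inside, S, jitter) {
  # dart throwing with a shrinking exclusion radius until n seeds are placed
  vol_guess <- S^3
  rmin <- (1 - jitter) * 0.7 * (vol_guess / n)^(1 / 3)
  pts <- matrix(numeric(0), 0, 3)
  attempts <- 0
  while (nrow(pts) < n) {
    cand <- matrix(stats::runif(3, 0, S), 1, 3)
    attempts <- attempts + 1
    if (attempts > 2000) { rmin <- rmin * 0.9; attempts <- 0 }
    if (!inside(cand)) next
    if (nrow(pts) > 0 &&
        min(rowSums(sweep(pts, 2, cand[1, ], `-`)^2)) < rmin^2) next
    pts <- rbind(pts, cand)
  }
  pts
}

rasterize_voronoi <- function(seeds, inside, resolution, anisotropy,
                              voxel_size, seed_layer = NULL,
                              layer_of_point = NULL) {
  d <- rep(resolution, 3)
  ax <- lapply(1:3, function(k) ((1:d[k]) - 0.5) * voxel_size)
  grid <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  lab <- rep(1L, nrow(grid))
  keep <- inside(grid)
  scaled_seeds <- sweep(seeds, 2, anisotropy, `/`)
  scaled_grid <- sweep(grid[keep, , drop = FALSE], 2, anisotropy, `/`)
  grid_layer <- if (is.null(layer_of_point)) NULL else
    layer_of_point(grid[keep, , drop = FALSE])
  # nearest (layer-compatible) seed under the scaled metric, chunked to
  # bound memory
  n <- nrow(scaled_grid)
  nearest <- integer(n)
  chunk <- 20000
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    block <- scaled_grid[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rep(1, nrow(scaled_seeds))) -
      2 * block %*% t(scaled_seeds) +
      outer(rep(1, nrow(block)), rowSums(scaled_seeds^2))
    if (!is.null(grid_layer)) {
      mism <- outer(grid_layer[s:e], seed_layer, `!=`)
      d2[mism] <- Inf
    }
    nearest[s:e] <- max.col(-d2, ties.method = "first")
  }
  lab[keep] <- as.integer(rownames(seeds))[nearest]
  segmented_image(array(lab, d), rep(voxel_size, 3), 1L)
}

raster_cell_edges <- function(labels, bg, min_faces = 1) {
  # fast 6-connectivity contact pairs between non-background regions
  d <- dim(labels)
  keys <- character(0)
  for (ax in 1:3) {
    n <- d[ax]
    A <- labels[slice_index(d, ax, 1:(n - 1))]
    B <- labels[slice_index(d, ax, 2:n)]
    m <- A != B & A != bg & B != bg
    if (any(m)) keys <- c(keys, paste(pmin(A[m], B[m]), pmax(A[m], B[m]),
                                      sep = "-"))
  }
  tb <- table(keys)
  key_to_matrix(names(tb)[tb >= min_faces], 2)
}

exact_adjacency <- function(seeds, inside, anisotropy, S, n_facet_samples = 600) {
  # in the axis-scaled space the diagram is an ordinary Voronoi diagram: two
  # cells are truly adjacent within the domain iff the Voronoi facet of their
  # Delaunay edge intersects the domain. The facet of an edge is the convex
  # hull of the circumcentres of the tetrahedra around that edge (plus, for
  # convex-hull edges, rays along the outward normals of the boundary
  # triangles); it is sampled densely by convex combinations.
  scaled <- sweep(seeds, 2, anisotropy, `/`)
  labs <- as.integer(rownames(seeds))
  dc <- delaunay_tets(scaled)
  ccs <- t(apply(dc, 1, function(t)
    tryCatch(circumsphere_center(scaled[t, ]),
             error = function(e) colMeans(scaled[t, ]))))
  ek <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "-")
  facet_pts <- new.env(parent = emptyenv())
  add_pt <- function(key, p) {
    facet_pts[[key]] <- rbind(facet_pts[[key]], p)
  }
  tet_edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (t in seq_len(nrow(dc))) {
    for (e in seq_len(6)) {
      i <- dc[t, tet_edges[e, 1]]; j <- dc[t, tet_edges[e, 2]]
      add_pt(ek(i, j), ccs[t, ])
    }
  }
  # unbounded facet directions from boundary triangles
  tri_rows <- do.call(rbind, lapply(seq_len(nrow(dc)), function(t)
    cbind(rbind(sort(dc[t, c(1, 2, 3)]), sort(dc[t, c(1, 2, 4)]),
                sort(dc[t, c(1, 3, 4)]), sort(dc[t, c(2, 3, 4)])), t)))
  tk <- paste(tri_rows[, 1], tri_rows[, 2], tri_rows[, 3], sep = "-")
  single <- names(which(table(tk) == 1))
  D <- 4 * S
  for (row in which(tk %in% single)) {
    tri <- tri_rows[row, 1:3]; t <- tri_rows[row, 4]
    apex <- setdiff(dc[t, ], tri)
    n <- crossv(scaled[tri[2], ] - scaled[tri[1], ],
                scaled[tri[3], ] - scaled[tri[1], ])
    n <- n / sqrt(sum(n^2))
    if (sum(n * (scaled[apex, ] - scaled[tri[1], ])) > 0) n <- -n
    ext <- ccs[t, ] + D * n
    add_pt(ek(tri[1], tri[2]), ext)
    add_pt(ek(tri[1], tri[3]), ext)
    add_pt(ek(tri[2], tri[3]), ext)
  }
  keys <- ls(facet_pts)
  keep <- with_seed(972341L, vapply(keys, function(k) {
    verts <- facet_pts[[k]]
    pts <- verts
    if (nrow(verts) > 1) {
      w <- matrix(stats::rexp(n_facet_samples * nrow(verts)),
                  n_facet_samples)
      pts <- rbind(pts, (w / rowSums(w)) %*% verts)
    }
    any(inside(sweep(pts, 2, anisotropy, `*`)))
  }, logical(1)))
  pairs <- key_to_matrix(keys[keep], 2)
  edges <- matrix(labs[pairs], ncol = 2)
  edges <- t(apply(edges, 1, sort))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  # Voronoi vertices: circumcentres of scaled Delaunay tets inside the domain
  world_cc <- sweep(ccs, 2, anisotropy, `*`)
  ok <- inside(world_cc)
  ckeys <- matrix(labs[dc[ok, , drop = FALSE]], ncol = 4)
  if (nrow(ckeys) > 0) ckeys <- t(apply(ckeys, 1, sort))
  list(edges = edges,
       corners = list(keys = ckeys, points = world_cc[ok, , drop = FALSE]))
}

boundary_voxels <- function(a) {
  d <- dim(a)
  inner <- a[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)]
  diff_any <- (inner != a[1:(d[1] - 2), 2:(d[2] - 1), 2:(d[3] - 1)]) |
    (inner != a[3:d[1], 2:(d[2] - 1), 2:(d[3] - 1)]) |
    (inner != a[2:(d[1] - 1), 1:(d[2] - 2), 2:(d[3] - 1)]) |
    (inner != a[2:(d[1] - 1), 3:d[2], 2:(d[3] - 1)]) |
    (inner != a[2:(d[1] - 1), 2:(d[2] - 1), 1:(d[3] - 2)]) |
    (inner != a[2:(d[1] - 1), 2:(d[2] - 1), 3:d[3]])
  idx <- which(diff_any, arr.ind = TRUE)
  idx + 1L
}

face_neighbors <- function(v, d) {
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  nb <- sweep(offs, 2, v, `+`)
  nb[nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
       nb[, 3] >= 1 & nb[, 3] <= d[3], , drop = FALSE]
}

is_simple_swap <- function(a, v, lab) {
  # local sufficient condition: the same-label face neighbours of v stay
  # 26-connected inside the 3x3x3 neighbourhood with v removed
  d <- dim(a)
  rng <- lapply(1:3, function(k) max(1, v[k] - 1):min(d[k], v[k] + 1))
  cube <- a[rng[[1]], rng[[2]], rng[[3]]]
  center <- c(match(v[1], rng[[1]]), match(v[2], rng[[2]]),
              match(v[3], rng[[3]]))
  same <- which(cube == lab, arr.ind = TRUE)
  same <- same[!(same[, 1] == center[1] & same[, 2] == center[2] &
                   same[, 3] == center[3]), , drop = FALSE]
  faces <- same[rowSums(abs(sweep(same, 2, center, `-`))) == 1, , drop = FALSE]
  if (nrow(faces) <= 1) return(nrow(faces) == 1)
  # BFS over 26-connectivity among `same`
  visited <- rep(FALSE, nrow(same))
  key <- apply(same, 1, paste, collapse = ",")
  start <- which(key == paste(faces[1, ], collapse = ","))
  queue <- start
  visited[start] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    adj <- which(!visited &
                   apply(abs(sweep(same, 2, same[cur, ], `-`)), 1, max) == 1)
    visited[adj] <- TRUE
    queue <- c(queue, adj)
  }
  fkeys <- apply(faces, 1, paste, collapse = ",")
  all(fkeys %in% key[visited])
}
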