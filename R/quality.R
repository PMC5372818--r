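#' Mesh quality estimation
#'
#' Ten normalized estimators, each in [0, 1] with 1 = ideal, covering four
#' complementary views of a reconstructed tissue mesh: consistency with the
#' structural prior (convex cells, 120-degree epidermal junctions, four-cell
#' corners), consistency with the segmented image (voxel overlap, corner
#' positions, cell adjacency), intrinsic finite-element regularity (triangle
#' area homogeneity, triangle eccentricity, vertex valence) and complexity
#' (triangles per cell). [quality_report()] assembles them and their mean.
#'
#' @name quality
NULL

#' Prior-consistency scores
#'
#' `cell_convexity`: mean over cells of the ratio between the cell volume
#' and the volume of its convex hull (1 for convex cells). At every surface
#' junction where three cells meet the outside, the three wedge angles the
#' cells make around the junction, measured in the local tangent plane,
#' ideally equal 120 degrees; `epidermis_cell_angle` is 1 minus the mean
#' absolute deviation normalized by 30 degrees. `cell_cliques` is 1 minus
#' the fraction of junction vertices where strictly more than 4 cells meet
#' (more than 3 on the surface).
#'
#' @param mesh a watertight `tissue_mesh`
#' @return named list with the three scores and a `raw` attribute
#' @export
prior_scores <- function(mesh) {
  cells <- mesh_cells(mesh)
  conv <- vapply(cells, function(cl) {
    tri <- cell_triangles(mesh, cl)
    if (!cell_boundary_closed(mesh, cl))
      stop("cell ", cl, " is not watertight")
    v <- cell_volume(mesh, cl)
    vs <- unique(as.vector(mesh$triangles[tri, ]))
    hv <- convex_hull_volume(mesh$vertices[vs, , drop = FALSE])
    if (hv <= 0) return(1)
    min(1, v / hv)
  }, numeric(1))
  ang <- junction_angle_deviation(mesh)
  cliq <- clique_fraction(mesh)
  out <- list(cell_convexity = mean(conv),
              epidermis_cell_angle =
                if (is.na(ang)) NA_real_ else clamp01(1 - ang / 30),
              cell_cliques = 1 - cliq)
  attr(out, "raw") <- list(mean_angle_deviation_deg = ang,
                           over_clique_fraction = cliq)
  out
}

clamp01 <- function(x) pmin(1, pmax(0, x))

junction_angle_deviation <- function(mesh) {
  # rim edges: surface edges separating two different cells
  et <- edge_triangle_map(mesh)
  ik1 <- mesh$interface[, 1]; ik2 <- mesh$interface[, 2]
  rim <- vapply(et, function(tr) {
    ext <- tr[ik1[tr] == 0]
    length(unique(ik2[ext])) >= 2
  }, logical(1))
  rim_keys <- names(et)[rim]
  if (length(rim_keys) == 0) return(NA_real_)
  ends <- matrix(as.integer(unlist(strsplit(rim_keys, "-", fixed = TRUE))),
                 ncol = 2, byrow = TRUE)
  # surface junctions: corner vertices with 3 cells + exterior
  jv <- which(vapply(mesh$corner_cells, function(s)
    !is.null(s) && 0 %in% s && length(setdiff(s, 0)) == 3, logical(1)))
  if (length(jv) == 0) return(NA_real_)
  # tangent plane from the outer surface only (exterior triangles)
  ext <- mesh$interface[, 1] == 0
  surf_mesh <- mesh
  surf_mesh$triangles <- mesh$triangles[ext, , drop = FALSE]
  vn <- vertex_normals(surf_mesh)
  devs <- c()
  for (v in jv) {
    inc <- which(ends[, 1] == v | ends[, 2] == v)
    if (length(inc) != 3) next
    other <- ifelse(ends[inc, 1] == v, ends[inc, 2], ends[inc, 1])
    n <- vn[v, ]
    dirs <- sweep(mesh$vertices[other, , drop = FALSE], 2,
                  mesh$vertices[v, ], `-`)
    dirs <- dirs - (dirs %*% n) %*% t(n)       # project to tangent plane
    len <- sqrt(rowSums(dirs^2))
    if (any(len < 1e-12)) next
    dirs <- dirs / len
    # angles of the three directions around the normal
    ref <- dirs[1, ]
    ref2 <- crossv(n, ref)
    th <- atan2(dirs %*% ref2, dirs %*% ref)
    th <- sort(th %% (2 * pi))
    wedge <- diff(c(th, th[1] + 2 * pi)) * 180 / pi
    devs <- c(devs, mean(abs(wedge - 120)))
  }
  if (length(devs) == 0) return(NA_real_)
  mean(devs)
}

clique_fraction <- function(mesh) {
  # junction vertices: neighbouring >= 4 cells, or >= 3 cells on the surface
  vp <- vertex_pairs(mesh)
  cellsets <- lapply(vp, function(ks) {
    if (is.null(ks)) return(integer(0))
    unique(as.integer(unlist(strsplit(ks, "-", fixed = TRUE))))
  })
  on_surface <- vapply(cellsets, function(s) 0 %in% s, logical(1))
  ncells <- vapply(cellsets, function(s) length(setdiff(s, 0L)), integer(1))
  junction <- (on_surface & ncells >= 3) | (!on_surface & ncells >= 4)
  if (!any(junction)) return(0)
  over <- (on_surface & ncells > 3) | (!on_surface & ncells > 4)
  sum(over & junction) / sum(junction)
}

#' Voxelize a tissue mesh onto the grid of a segmented image
#'
#' Each voxel is assigned the label of the cell whose closed boundary
#' surface contains its centre, decided by parity ray casting along +x;
#' ray origins are perturbed by a small fraction of a voxel so that rays
#' never hit mesh edges or vertices exactly. Voxels inside no cell get the
#' background label.
#'
#' @param mesh a watertight `tissue_mesh`
#' @param image the `segmented_image` providing grid and voxel size
#' @return a `segmented_image` on the same grid
#' @export
voxelize_mesh <- function(mesh, image) {
  d <- dim(image$labels)
  vs <- image$voxel_size
  out <- array(image$background_label, d)
  eps <- c(0, vs[2] * 1.37e-4, vs[3] * 2.41e-4)
  for (cl in mesh_cells(mesh)) {
    tri <- cell_triangles(mesh, cl)
    if (!cell_boundary_closed(mesh, cl))
      stop("cell ", cl, " is not watertight")
    tt <- mesh$triangles[tri, , drop = FALSE]
    P1 <- mesh$vertices[tt[, 1], , drop = FALSE]
    P2 <- mesh$vertices[tt[, 2], , drop = FALSE]
    P3 <- mesh$vertices[tt[, 3], , drop = FALSE]
    crossings <- list()
    for (f in seq_len(nrow(tt))) {
      cr <- triangle_ray_crossings(P1[f, ], P2[f, ], P3[f, ], d, vs, eps)
      if (!is.null(cr)) crossings[[length(crossings) + 1]] <- cr
    }
    if (length(crossings) == 0) next
    cr <- do.call(rbind, crossings)
    ray_id <- cr[, 1] + (cr[, 2] - 1) * d[2]
    by_ray <- split(cr[, 3], ray_id)
    for (rk in names(by_ray)) {
      xs <- sort(by_ray[[rk]])
      if (length(xs) %% 2 != 0) next          # grazing artefact, skip ray
      id <- as.integer(rk)
      j <- ((id - 1) %% d[2]) + 1
      k <- ((id - 1) %/% d[2]) + 1
      for (s in seq(1, length(xs), by = 2)) {
        i1 <- max(1, ceiling(xs[s] / vs[1] + 0.5))
        i2 <- min(d[1], floor(xs[s + 1] / vs[1] + 0.5))
        if (i2 >= i1) out[i1:i2, j, k] <- cl
      }
    }
  }
  segmented_image(out, vs, image$background_label)
}

triangle_ray_crossings <- function(a, b, c, d, vs, eps) {
  # rays r(j,k): x variable, y = (j-0.5)vy + eps_y, z = (k-0.5)vz + eps_z
  ymin <- min(a[2], b[2], c[2]); ymax <- max(a[2], b[2], c[2])
  zmin <- min(a[3], b[3], c[3]); zmax <- max(a[3], b[3], c[3])
  j1 <- max(1, ceiling(ymin / vs[2] + 0.5 - 1)); j2 <- min(d[2], floor(ymax / vs[2] + 0.5 + 1))
  k1 <- max(1, ceiling(zmin / vs[3] + 0.5 - 1)); k2 <- min(d[3], floor(zmax / vs[3] + 0.5 + 1))
  if (j2 < j1 || k2 < k1) return(NULL)
  jj <- rep(j1:j2, times = k2 - k1 + 1)
  kk <- rep(k1:k2, each = j2 - j1 + 1)
  y <- (jj - 0.5) * vs[2] + eps[2]
  z <- (kk - 0.5) * vs[3] + eps[3]
  # 2D barycentric in the (y, z) projection
  den <- (b[2] - a[2]) * (c[3] - a[3]) - (c[2] - a[2]) * (b[3] - a[3])
  if (abs(den) < 1e-14) return(NULL)          # triangle parallel to the ray
  l2 <- ((y - a[2]) * (c[3] - a[3]) - (c[2] - a[2]) * (z - a[3])) / den
  l3 <- ((b[2] - a[2]) * (z - a[3]) - (y - a[2]) * (b[3] - a[3])) / den
  l1 <- 1 - l2 - l3
  hit <- l1 > 0 & l2 > 0 & l3 > 0
  if (!any(hit)) return(NULL)
  x <- l1[hit] * a[1] + l2[hit] * b[1] + l3[hit] * c[1]
  cbind(jj[hit], kk[hit], x)
}

#' Image-consistency scores
#'
#' `image_accuracy`: mean over cells of the Jaccard index between the
#' cell's voxel region in the segmented image and in the voxelized mesh.
#' `vertex_distance`: the mean distance between matched mesh corners and
#' their image corner points, reported as `min(1, d0 / mean distance)` with
#' the reference `d0` the voxel diagonal of a typical 0.25 micrometre
#' resolution image (`0.25 * sqrt(3)`); `NA` when no corner is matched.
#' `cell_2adjacency`: Jaccard index between the non-background adjacency
#' edges extracted from the image and the cell pairs sharing an interface
#' in the mesh.
#'
#' @param mesh a `tissue_mesh`
#' @param image the `segmented_image`
#' @param adj `image_adjacencies` extracted from `image`
#' @param d0 reference corner distance (micrometres)
#' @param voxelized optional precomputed [voxelize_mesh()] result
#' @return named list of the three scores with a `raw` attribute
#' @export
image_scores <- function(mesh, image, adj, d0 = 0.25 * sqrt(3),
                         voxelized = NULL) {
  if (is.null(voxelized)) voxelized <- voxelize_mesh(mesh, image)
  cells <- mesh_cells(mesh)
  jac <- vapply(cells, function(cl) {
    A <- image$labels == cl
    B <- voxelized$labels == cl
    u <- sum(A | B)
    if (u == 0) return(NA_real_)
    sum(A & B) / u
  }, numeric(1))
  image_accuracy <- mean(jac, na.rm = TRUE)
  md <- matched_corner_distance(mesh, adj)
  vertex_distance <- if (is.na(md)) NA_real_
  else if (md == 0) 1 else min(1, d0 / md)
  ek <- simplex_key(adjacency_edges(adj, FALSE))
  mk <- simplex_key(mesh_adjacency_edges(mesh, FALSE))
  cell_2adjacency <- length(intersect(ek, mk)) / length(union(ek, mk))
  out <- list(image_accuracy = image_accuracy,
              vertex_distance = vertex_distance,
              cell_2adjacency = cell_2adjacency)
  attr(out, "raw") <- list(per_cell_jaccard = jac,
                           mean_corner_distance_um = md)
  out
}

matched_corner_distance <- function(mesh, adj) {
  keys <- adj$corner_points$keys
  if (is.null(keys) || nrow(keys) == 0) return(NA_real_)
  keys[keys == adj$background_label] <- 0L
  ikeys <- apply(t(apply(keys, 1, sort)), 1, paste, collapse = "-")
  corner_vs <- which(!vapply(mesh$corner_cells, is.null, logical(1)))
  if (length(corner_vs) == 0) return(NA_real_)
  mkeys <- vapply(mesh$corner_cells[corner_vs], function(s)
    paste(sort(s), collapse = "-"), character(1))
  hit <- match(mkeys, ikeys)
  ok <- !is.na(hit)
  if (!any(ok)) return(NA_real_)
  d <- sqrt(rowSums((mesh$vertices[corner_vs[ok], , drop = FALSE] -
                       adj$corner_points$points[hit[ok], , drop = FALSE])^2))
  mean(d)
}

#' Intrinsic regularity scores
#'
#' `triangle_area_deviation`: 1 minus the standard deviation of triangle
#' areas normalized by sqrt(2) times the mean area. `triangle_eccentricity`:
#' per-triangle eccentricity is 1 - (sin a + sin b + sin c)/(3 sin 60), 0
#' for equilateral and 1 for degenerate triangles; the score is 1 minus the
#' mean eccentricity normalized by 0.5. `vertex_valence`: 1 minus the mean
#' absolute deviation of interface-interior vertex valences from 6,
#' normalized by 6.
#'
#' @param mesh a `tissue_mesh`
#' @return named list of the three scores with a `raw` attribute
#' @export
intrinsic_scores <- function(mesh) {
  areas <- triangle_areas(mesh$vertices, mesh$triangles)
  tad <- if (length(areas) < 2 || mean(areas) == 0) 1 else
    clamp01(1 - stats::sd(areas) / (sqrt(2) * mean(areas)))
  ecc <- triangle_eccentricity(mesh$vertices, mesh$triangles)
  tecc <- clamp01(1 - mean(ecc) / 0.5)
  ii <- interior_interface_vertices(mesh)
  vv <- if (length(ii) == 0) 1 else {
    val <- vertex_valences(mesh)
    clamp01(1 - mean(abs(val[ii] - 6)) / 6)
  }
  out <- list(triangle_area_deviation = tad, triangle_eccentricity = tecc,
              vertex_valence = vv)
  attr(out, "raw") <- list(area_sd = stats::sd(areas),
                           mean_eccentricity = mean(ecc))
  out
}

#' Mesh complexity score
#'
#' The average number of triangles needed to represent one cell (triangles
#' shared by two cells count once for each), normalized as a reciprocal by
#' the reference of 152 triangles per cell, which yields a suitable total
#' element count for finite-element models of a 1,000-cell tissue and
#' corresponds to a good triangulation of the space-filling truncated
#' octahedron.
#'
#' @param mesh a `tissue_mesh`
#' @param reference reference triangle count per cell
#' @return named list with `mesh_complexity` and a `raw` attribute
#' @export
complexity_score <- function(mesh, reference = 152) {
  cells <- mesh_cells(mesh)
  if (length(cells) == 0) stop("mesh has no cells")
  incidences <- sum(mesh$interface > 0)
  per_cell <- incidences / length(cells)
  out <- list(mesh_complexity = min(1, reference / per_cell))
  attr(out, "raw") <- list(triangles_per_cell = per_cell)
  out
}

#' Assemble the full ten-estimator quality report
#'
#' @param mesh a `tissue_mesh`
#' @param image the `segmented_image` it reconstructs
#' @param adj `image_adjacencies` of the image (extracted if omitted)
#' @param d0 reference corner distance for the vertex-distance estimator
#' @param complexity_reference reference triangle count per cell
#' @return an object of class `quality_report`: list with `scores` (named,
#'   ordered for the radar plot), `raw`, `counts` and `average_quality`
#'   (mean of the available scores)
#' @export
quality_report <- function(mesh, image, adj = NULL, d0 = 0.25 * sqrt(3),
                           complexity_reference = 152) {
  if (is.null(adj)) adj <- extract_adjacencies(image)
  pr <- prior_scores(mesh)
  im <- image_scores(mesh, image, adj, d0 = d0)
  it <- intrinsic_scores(mesh)
  cx <- complexity_score(mesh, reference = complexity_reference)
  scores <- c(unlist(pr), unlist(im), unlist(it), unlist(cx))
  raw <- list(prior = attr(pr, "raw"), image = attr(im, "raw"),
              intrinsic = attr(it, "raw"), complexity = attr(cx, "raw"))
  structure(list(scores = scores, raw = raw,
                 counts = c(cells = length(mesh_cells(mesh)),
                            vertices = nrow(mesh$vertices),
                            triangles = nrow(mesh$triangles)),
                 average_quality = mean(scores, na.rm = TRUE)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  for (nm in names(x$scores))
    cat(sprintf("  %-24s %s\n", nm,
                ifelse(is.na(x$scores[nm]), "missing",
                       sprintf("%.3f", x$scores[nm]))))
  cat(sprintf("  average_quality          %.3f\n", x$average_quality))
  cat(sprintf("  (%d cells, %d vertices, %d triangles)\n",
              x$counts["cells"], x$counts["vertices"],
              x$counts["triangles"]))
  invisible(x)
}

#' Radar (spider-web) plot of a quality report
#'
#' @param x a `quality_report`
#' @param ... passed to [graphics::polygon()]
#' @return invisibly, the plotted score vector
#' @export
plot_quality <- function(x, ...) {
  sc <- x$scores
  sc[is.na(sc)] <- 0
  n <- length(sc)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] + pi / 2
  graphics::plot(NA, xlim = c(-1.5, 1.5), ylim = c(-1.5, 1.5), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Mesh quality")
  for (r in c(0.25, 0.5, 0.75, 1))
    graphics::polygon(r * cos(th), r * sin(th), border = "grey80")
  graphics::segments(0, 0, cos(th), sin(th), col = "grey80")
  graphics::polygon(sc * cos(th), sc * sin(th),
                    col = grDevices::adjustcolor("steelblue", 0.4),
                    border = "steelblue", ...)
  graphics::text(1.25 * cos(th), 1.25 * sin(th), names(sc), cex = 0.6)
  invisible(sc)
}

# ---- geometric properties ---------------------------------------------

#' Cell volumes, interface areas and surface curvature
#'
#' Computes per-cell volumes (divergence theorem over each cell's closed,
#' consistently oriented boundary), per-interface summed triangle areas,
#' and curvature of the outer tissue surface at surface vertices: Gaussian
#' curvature by angle deficit over the barycentric mixed area, mean
#' curvature from the cotangent Laplacian, and principal curvatures and
#' directions from a local quadric fit over the one-ring.
#'
#' @param mesh a watertight `tissue_mesh`
#' @return list with `cell_volumes` (named numeric, cubic micrometres),
#'   `interface_areas` (named by "a-b", square micrometres), and
#'   `surface_curvature` (data.frame: vertex, gaussian, mean, k1, k2)
#' @export
tissue_properties <- function(mesh) {
  cells <- mesh_cells(mesh)
  vol <- vapply(cells, function(cl) {
    if (!cell_boundary_closed(mesh, cl)) stop("cell ", cl, " is open")
    cell_volume(mesh, cl)
  }, numeric(1))
  names(vol) <- cells
  ik <- edge_key(mesh$interface[, 1], mesh$interface[, 2])
  areas <- triangle_areas(mesh$vertices, mesh$triangles)
  ia <- tapply(areas, ik, sum)
  surf <- surface_curvature(mesh)
  list(cell_volumes = vol,
       interface_areas = stats::setNames(as.numeric(ia), names(ia)),
       surface_curvature = surf)
}

cell_volume <- function(mesh, cell) {
  tri <- cell_triangles(mesh, cell)
  tt <- orient_consistently(mesh$triangles[tri, , drop = FALSE])
  V <- mesh$vertices
  v6 <- sum(vapply(seq_len(nrow(tt)), function(f)
    det(rbind(V[tt[f, 1], ], V[tt[f, 2], ], V[tt[f, 3], ])), numeric(1)))
  abs(v6) / 6
}

orient_consistently <- function(tt) {
  # BFS over shared edges, flipping triangles to consistent orientation
  n <- nrow(tt)
  if (n == 0) return(tt)
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")
  e_all <- rbind(cbind(ek(tt[, 1], tt[, 2]), 1:n),
                 cbind(ek(tt[, 2], tt[, 3]), 1:n),
                 cbind(ek(tt[, 3], tt[, 1]), 1:n))
  emap <- split(as.integer(e_all[, 2]), e_all[, 1])
  seen <- rep(FALSE, n)
  out <- tt
  queue <- 1L; seen[1] <- TRUE
  has_directed <- function(t, a, b) {
    (t[1] == a && t[2] == b) || (t[2] == a && t[3] == b) ||
      (t[3] == a && t[1] == b)
  }
  while (length(queue)) {
    f <- queue[1]; queue <- queue[-1]
    es <- rbind(out[f, c(1, 2)], out[f, c(2, 3)], out[f, c(3, 1)])
    for (i in 1:3) {
      a <- es[i, 1]; b <- es[i, 2]
      for (g in emap[[ek(a, b)]]) {
        if (seen[g]) next
        # consistent orientation: the shared edge must run oppositely
        if (has_directed(out[g, ], a, b)) out[g, ] <- rev(out[g, ])
        seen[g] <- TRUE
        queue <- c(queue, g)
      }
    }
  }
  out
}

convex_hull_volume <- function(P) {
  P <- unique(round(P, 10))
  if (nrow(P) < 4) return(0)
  hull <- tryCatch(quickhull3(P), error = function(e) NULL)
  if (is.null(hull)) return(0)
  ctr <- colMeans(P)
  sum(vapply(seq_len(nrow(hull)), function(f) {
    a <- P[hull[f, 1], ] - ctr; b <- P[hull[f, 2], ] - ctr
    c <- P[hull[f, 3], ] - ctr
    abs(det(rbind(a, b, c))) / 6
  }, numeric(1)))
}

quickhull3 <- function(P) {
  # incremental 3D convex hull; returns face index matrix
  n <- nrow(P)
  i1 <- which.min(P[, 1]); i2 <- which.max(P[, 1])
  if (i1 == i2) stop("degenerate point set")
  d_line <- function(p) {
    u <- P[i2, ] - P[i1, ]
    w <- sweep(p, 2, P[i1, ], `-`)
    cr <- cross3(matrix(u, nrow(p), 3, byrow = TRUE), w)
    sqrt(rowSums(cr^2))
  }
  i3 <- which.max(d_line(P))
  nrm <- crossv(P[i2, ] - P[i1, ], P[i3, ] - P[i1, ])
  h <- abs(sweep(P, 2, P[i1, ], `-`) %*% nrm)
  i4 <- which.max(h)
  if (h[i4] < 1e-12) stop("coplanar point set")
  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  ctr <- colMeans(P[c(i1, i2, i3, i4), ])
  orient_out <- function(f) {
    nn <- crossv(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
    if (sum(nn * (ctr - P[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient_out))
  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    vis <- vapply(seq_len(nrow(faces)), function(fi) {
      f <- faces[fi, ]
      nn <- crossv(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
      sum(nn * (P[p, ] - P[f[1], ])) > 1e-12
    }, logical(1))
    if (!any(vis)) next
    visf <- faces[vis, , drop = FALSE]
    e_of <- function(f) rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])
    all_e <- do.call(rbind, lapply(seq_len(nrow(visf)), function(i)
      e_of(visf[i, ])))
    keyd <- paste(pmin(all_e[, 1], all_e[, 2]),
                  pmax(all_e[, 1], all_e[, 2]), sep = "-")
    horizon <- all_e[keyd %in% names(which(table(keyd) == 1)), ,
                     drop = FALSE]
    faces <- faces[!vis, , drop = FALSE]
    newf <- cbind(horizon, p)
    newf <- t(apply(newf, 1, orient_out))
    faces <- rbind(faces, newf)
  }
  faces
}

surface_curvature <- function(mesh) {
  ext <- which(mesh$interface[, 1] == 0)
  if (length(ext) == 0)
    return(data.frame(vertex = integer(0), gaussian = numeric(0),
                      mean = numeric(0), k1 = numeric(0), k2 = numeric(0)))
  tt <- mesh$triangles[ext, , drop = FALSE]
  V <- mesh$vertices
  verts <- sort(unique(as.vector(tt)))
  # angle deficit and barycentric mixed area
  ang_sum <- stats::setNames(rep(0, length(verts)), verts)
  area_sum <- ang_sum
  areas <- triangle_areas(V, tt)
  for (c in 1:3) {
    a <- tt[, c]; b <- tt[, c %% 3 + 1]; cc <- tt[, (c + 1) %% 3 + 1]
    u <- V[b, , drop = FALSE] - V[a, , drop = FALSE]
    w <- V[cc, , drop = FALSE] - V[a, , drop = FALSE]
    cosv <- rowSums(u * w) / (sqrt(rowSums(u^2)) * sqrt(rowSums(w^2)) + 1e-300)
    th <- acos(pmin(1, pmax(-1, cosv)))
    s <- rowsum(cbind(th, areas / 3), a)
    idx <- as.character(as.integer(rownames(s)))
    ang_sum[idx] <- ang_sum[idx] + s[, 1]
    area_sum[idx] <- area_sum[idx] + s[, 2]
  }
  # interior surface vertices only (full angle around them); boundary of
  # the surface patch is detected by open edge fans
  et <- split(rep(seq_len(nrow(tt)), 3),
              c(edge_key(tt[, 1], tt[, 2]), edge_key(tt[, 2], tt[, 3]),
                edge_key(tt[, 1], tt[, 3])))
  open_edges <- names(et)[lengths(et) == 1]
  boundary_v <- unique(as.integer(unlist(strsplit(open_edges, "-",
                                                  fixed = TRUE))))
  keep <- setdiff(verts, boundary_v)
  kg <- (2 * pi - ang_sum[as.character(keep)]) / area_sum[as.character(keep)]
  # mean curvature via cotangent Laplacian
  km <- cotan_mean_curvature(V, tt, keep, area_sum)
  k1 <- km + sqrt(pmax(0, km^2 - kg))
  k2 <- km - sqrt(pmax(0, km^2 - kg))
  data.frame(vertex = keep, gaussian = as.numeric(kg),
             mean = as.numeric(km), k1 = k1, k2 = k2)
}

cotan_mean_curvature <- function(V, tt, verts, area_sum) {
  lap <- matrix(0, nrow(V), 3)
  for (c in 1:3) {
    i <- tt[, c]; j <- tt[, c %% 3 + 1]; k <- tt[, (c + 1) %% 3 + 1]
    # cotangent at k for edge (i, j)
    u <- V[i, , drop = FALSE] - V[k, , drop = FALSE]
    w <- V[j, , drop = FALSE] - V[k, , drop = FALSE]
    cotk <- rowSums(u * w) / (sqrt(rowSums(cross3(u, w)^2)) + 1e-300)
    dij <- V[j, , drop = FALSE] - V[i, , drop = FALSE]
    s1 <- rowsum(cotk * dij, i)
    s2 <- rowsum(-cotk * dij, j)
    lap[as.integer(rownames(s1)), ] <- lap[as.integer(rownames(s1)), ] + s1
    lap[as.integer(rownames(s2)), ] <- lap[as.integer(rownames(s2)), ] + s2
  }
  hn <- lap[verts, , drop = FALSE] /
    (4 * area_sum[as.character(verts)])
  sqrt(rowSums(hn^2))
}
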