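#' Weights and schedule for tissue mesh enhancement
#'
#' The mesh optimization minimizes an energy of the same three-part form as
#' the adjacency optimization: an image attachment term tying vertices to
#' the actual cell interfaces observed in the segmented image, a shape prior
#' term producing flat polygonal cell walls, and a regularization term
#' keeping triangles regular and vertex neighbourhoods isotropic.
#'
#' @param w_image,w_prior,w_regularity nonnegative weights
#' @param shift_radius radius (micrometres) of the sphere in which vertices
#'   are relocated; `NULL` = half the median edge length, shrinking by 0.9
#'   per temperature cycle
#' @param deadband distance (micrometres) below which a vertex counts as
#'   lying on its image interface; the wall-plane attachment is smooth, so
#'   the default is 0 (no deadband).
#' @param schedule an [annealing_schedule()]
#' @return list of class `mesh_weights`
#' @export
mesh_weights <- function(w_image = 1.0, w_prior = 0.5, w_regularity = 0.5,
                         shift_radius = NULL, deadband = NULL,
                         schedule = annealing_schedule()) {
  stopifnot(w_image >= 0, w_prior >= 0, w_regularity >= 0,
            is.null(shift_radius) || shift_radius > 0,
            is.null(deadband) || deadband >= 0)
  structure(list(w_image = w_image, w_prior = w_prior,
                 w_regularity = w_regularity, shift_radius = shift_radius,
                 deadband = deadband, schedule = schedule),
            class = "mesh_weights")
}

#' Uniform triangle split refinement
#'
#' Each round replaces every triangle by four via its edge midpoints;
#' midpoints are shared across adjacent triangles, including across
#' interfaces at junction edges, so cells stay watertight. Interface labels
#' are inherited and the total interface area is conserved exactly.
#'
#' @param mesh a `tissue_mesh`
#' @param rounds number of refinement rounds (triangle count x4 per round)
#' @return a refined `tissue_mesh`
#' @export
split_refine <- function(mesh, rounds = 1) {
  for (r in seq_len(rounds)) mesh <- split_once(mesh)
  mesh
}

split_once <- function(mesh) {
  tt <- mesh$triangles
  nv <- nrow(mesh$vertices)
  ek <- cbind(edge_key(tt[, 1], tt[, 2]), edge_key(tt[, 2], tt[, 3]),
              edge_key(tt[, 1], tt[, 3]))
  keys <- unique(as.vector(ek))
  mid_id <- stats::setNames(nv + seq_along(keys), keys)
  emat <- matrix(as.integer(unlist(strsplit(keys, "-", fixed = TRUE))),
                 ncol = 2, byrow = TRUE)
  mids <- (mesh$vertices[emat[, 1], , drop = FALSE] +
             mesh$vertices[emat[, 2], , drop = FALSE]) / 2
  # an edge lies on the outer surface when one of its triangles is exterior
  ext_tri <- mesh$interface[, 1] == 0
  edge_surface <- tapply(rep(ext_tri, 3), as.vector(ek), any)[keys]
  m12 <- mid_id[ek[, 1]]; m23 <- mid_id[ek[, 2]]; m13 <- mid_id[ek[, 3]]
  new_tris <- rbind(cbind(tt[, 1], m12, m13),
                    cbind(tt[, 2], m23, m12),
                    cbind(tt[, 3], m13, m23),
                    cbind(m12, m23, m13))
  new_int <- rbind(mesh$interface, mesh$interface, mesh$interface,
                   mesh$interface)
  tissue_mesh(rbind(mesh$vertices, mids), new_tris, new_int,
              is_surface = c(mesh$is_surface, unname(edge_surface)),
              is_corner = c(mesh$is_corner, rep(FALSE, length(keys))),
              pinned = c(mesh$pinned, rep(FALSE, length(keys))),
              corner_cells = c(mesh$corner_cells,
                               vector("list", length(keys))))
}

#' Isotropic remeshing towards a target edge length
#'
#' The classic split-long / collapse-short / tangential-smoothing loop,
#' restricted so that cell structure is preserved: junction edges (edges
#' whose incident triangles carry more than one interface label), corner
#' vertices and pinned vertices are never collapsed away, and smoothing
#' moves a vertex within the tangent plane of its one-ring only when the
#' vertex is interior to a single interface. Edges longer than 4/3 of the
#' target are split, edges shorter than 4/5 collapsed.
#'
#' @param mesh a `tissue_mesh`
#' @param target_length target edge length (micrometres)
#' @param iterations remeshing passes
#' @param max_elements guard against absurd refinement (error if a pass
#'   would exceed this many triangles)
#' @return a `tissue_mesh`
#' @export
isotropic_remesh <- function(mesh, target_length, iterations = 3,
                             max_elements = 200000) {
  stopifnot(target_length > 0)
  for (it in seq_len(iterations)) {
    el <- mesh_edge_lengths(mesh)
    n_split <- sum(el$len > 4 / 3 * target_length)
    if (nrow(mesh$triangles) + 2 * n_split > max_elements)
      stop("target length too small: element budget exceeded")
    mesh <- remesh_split_long(mesh, 4 / 3 * target_length)
    mesh <- remesh_collapse_short(mesh, 4 / 5 * target_length)
    mesh <- remesh_smooth(mesh)
  }
  mesh
}

mesh_edge_lengths <- function(mesh) {
  tt <- mesh$triangles
  ek <- c(edge_key(tt[, 1], tt[, 2]), edge_key(tt[, 2], tt[, 3]),
          edge_key(tt[, 1], tt[, 3]))
  keys <- unique(ek)
  emat <- matrix(as.integer(unlist(strsplit(keys, "-", fixed = TRUE))),
                 ncol = 2, byrow = TRUE)
  len <- sqrt(rowSums((mesh$vertices[emat[, 1], , drop = FALSE] -
                         mesh$vertices[emat[, 2], , drop = FALSE])^2))
  list(keys = keys, ends = emat, len = len)
}

edge_triangle_map <- function(mesh) {
  tt <- mesh$triangles
  ek <- c(edge_key(tt[, 1], tt[, 2]), edge_key(tt[, 2], tt[, 3]),
          edge_key(tt[, 1], tt[, 3]))
  split(rep(seq_len(nrow(tt)), 3), ek)
}

feature_edges <- function(mesh) {
  # edges whose incident triangles carry more than one interface label
  et <- edge_triangle_map(mesh)
  ik <- paste(mesh$interface[, 1], mesh$interface[, 2], sep = "-")
  vapply(et, function(tr) length(unique(ik[tr])) > 1 || length(tr) != 2,
         logical(1))
}

remesh_split_long <- function(mesh, limit) {
  el <- mesh_edge_lengths(mesh)
  long <- el$keys[el$len > limit]
  if (length(long) == 0) return(mesh)
  et <- edge_triangle_map(mesh)
  ext_tri <- mesh$interface[, 1] == 0
  V <- mesh$vertices; tris <- mesh$triangles; int <- mesh$interface
  surf <- mesh$is_surface; corn <- mesh$is_corner; pin <- mesh$pinned
  cc <- mesh$corner_cells
  dead <- rep(FALSE, nrow(tris))
  add_t <- list(); add_i <- list()
  for (k in long) {
    rows <- et[[k]]
    # split only edges whose incident triangles are all untouched in this
    # pass: splitting against an already-replaced triangle would leave a
    # non-conforming T-junction
    if (any(dead[rows])) next
    ab <- as.integer(strsplit(k, "-", fixed = TRUE)[[1]])
    V <- rbind(V, (V[ab[1], ] + V[ab[2], ]) / 2)
    mid <- nrow(V)
    surf <- c(surf, any(ext_tri[rows]))
    corn <- c(corn, FALSE); pin <- c(pin, FALSE); cc <- c(cc, list(NULL))
    for (r in rows) {
      tr <- tris[r, ]
      other <- setdiff(tr, ab)
      dead[r] <- TRUE
      add_t[[length(add_t) + 1]] <- rbind(c(ab[1], mid, other),
                                          c(ab[2], mid, other))
      add_i[[length(add_i) + 1]] <- rbind(int[r, ], int[r, ])
    }
  }
  tris <- rbind(tris[!dead, , drop = FALSE], do.call(rbind, add_t))
  int <- rbind(int[!dead, , drop = FALSE], do.call(rbind, add_i))
  tissue_mesh(V, tris, int, surf, corn, pin, cc)
}

remesh_collapse_short <- function(mesh, limit) {
  el <- mesh_edge_lengths(mesh)
  feat <- feature_edges(mesh)
  short <- el$keys[el$len < limit & !feat[el$keys]]
  if (length(short) == 0) return(mesh)
  # protected vertices: corners, pinned, and vertices on feature edges
  featv <- unique(as.integer(unlist(strsplit(names(feat)[feat], "-",
                                             fixed = TRUE))))
  protected <- mesh$is_corner | mesh$pinned
  protected[featv] <- TRUE
  tris <- mesh$triangles
  remap <- seq_len(nrow(mesh$vertices))
  gone <- rep(FALSE, nrow(mesh$vertices))
  alive_tri <- rep(TRUE, nrow(tris))
  cur <- tris
  tri_keys <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(tris)))
    tri_keys[[paste(sort(tris[r, ]), collapse = "-")]] <- r
  vtris <- split(rep(seq_len(nrow(tris)), 3), as.vector(tris))
  touched <- rep(FALSE, nrow(mesh$vertices))
  for (k in short) {
    ab <- as.integer(strsplit(k, "-", fixed = TRUE)[[1]])
    a <- remap[ab[1]]; b <- remap[ab[2]]
    if (a == b || gone[a] || gone[b]) next
    # one collapse per vertex and pass: edge lengths are only recomputed
    # between passes, chained collapses would overshoot the target
    if (touched[a] || touched[b]) next
    if (protected[a] && protected[b]) next
    keep <- if (protected[a]) a else b
    drop <- if (keep == a) b else a
    # simulate: collapsing must not duplicate a surviving triangle
    inc <- vtris[[as.character(drop)]]
    inc <- inc[alive_tri[inc]]
    ok <- TRUE
    new_rows <- list()
    new_keys <- character(0)
    for (r in inc) {
      tr <- cur[r, ]
      tr[tr == drop] <- keep
      if (length(unique(tr)) < 3) next
      key <- paste(sort(tr), collapse = "-")
      hit <- tri_keys[[key]]
      if (!is.null(hit) && alive_tri[hit] && !(hit %in% inc)) { ok <- FALSE; break }
      new_keys <- c(new_keys, key)
      new_rows[[as.character(r)]] <- tr
    }
    if (!ok || anyDuplicated(new_keys)) next
    for (r in inc) {
      old_key <- paste(sort(cur[r, ]), collapse = "-")
      if (!is.null(tri_keys[[old_key]]) && tri_keys[[old_key]] == r)
        rm(list = old_key, envir = tri_keys)
      tr <- new_rows[[as.character(r)]]
      if (is.null(tr)) { alive_tri[r] <- FALSE; next }
      cur[r, ] <- tr
      tri_keys[[paste(sort(tr), collapse = "-")]] <- r
      vtris[[as.character(keep)]] <- c(vtris[[as.character(keep)]], r)
    }
    remap[remap == drop] <- keep
    gone[drop] <- TRUE
    touched[c(a, b)] <- TRUE
  }
  tt <- cur[alive_tri, , drop = FALSE]
  int <- mesh$interface[alive_tri, , drop = FALSE]
  degen <- tt[, 1] == tt[, 2] | tt[, 1] == tt[, 3] | tt[, 2] == tt[, 3]
  tt <- tt[!degen, , drop = FALSE]
  int <- int[!degen, , drop = FALSE]
  live <- sort(unique(as.vector(tt)))
  new_id <- integer(nrow(mesh$vertices)); new_id[live] <- seq_along(live)
  tissue_mesh(mesh$vertices[live, , drop = FALSE],
              matrix(new_id[tt], ncol = 3), int,
              mesh$is_surface[live], mesh$is_corner[live],
              mesh$pinned[live], mesh$corner_cells[live])
}

remesh_smooth <- function(mesh, lambda = 0.5) {
  feat <- feature_edges(mesh)
  featv <- unique(as.integer(unlist(strsplit(names(feat)[feat], "-",
                                             fixed = TRUE))))
  fixed <- mesh$is_corner | mesh$pinned
  fixed[featv] <- TRUE
  tt <- mesh$triangles
  nb_from <- c(tt[, 1], tt[, 2], tt[, 1], tt[, 3], tt[, 2], tt[, 3])
  nb_to <- c(tt[, 2], tt[, 1], tt[, 3], tt[, 1], tt[, 3], tt[, 2])
  V <- mesh$vertices
  cen_sum <- rowsum(V[nb_to, , drop = FALSE], nb_from)
  cnt <- as.vector(rowsum(rep(1, length(nb_from)), nb_from))
  cen <- cen_sum / cnt
  idx <- as.integer(rownames(cen_sum))
  # move within the tangent plane of the one-ring (area-weighted normal)
  vn <- vertex_normals(mesh)
  for (i in seq_along(idx)) {
    v <- idx[i]
    if (fixed[v]) next
    d <- lambda * (cen[i, ] - V[v, ])
    n <- vn[v, ]
    d <- d - sum(d * n) * n
    V[v, ] <- V[v, ] + d
  }
  mesh$vertices <- V
  mesh
}

vertex_normals <- function(mesh) {
  tt <- mesh$triangles
  V <- mesh$vertices
  n <- cross3(V[tt[, 2], , drop = FALSE] - V[tt[, 1], , drop = FALSE],
              V[tt[, 3], , drop = FALSE] - V[tt[, 1], , drop = FALSE])
  acc <- matrix(0, nrow(V), 3)
  for (c in 1:3) {
    s <- rowsum(n, tt[, c])
    idx <- as.integer(rownames(s))
    acc[idx, ] <- acc[idx, ] + s
  }
  len <- sqrt(rowSums(acc^2))
  len[len == 0] <- 1
  acc / len
}

#' Project surface vertices onto the tissue isosurface
#'
#' Moves every vertex flagged as surface (and not pinned) to its nearest
#' point on the binary isosurface of the image foreground, anchoring the
#' mesh's outer boundary to the observed tissue surface.
#'
#' @param mesh a `tissue_mesh`
#' @param isosurface an `iso_surface` from [binary_isosurface()]
#' @return a `tissue_mesh`
#' @export
project_surface_vertices <- function(mesh, isosurface) {
  sel <- which(mesh$is_surface & !mesh$pinned)
  if (length(sel) == 0) return(mesh)
  mesh$vertices[sel, ] <- project_to_surface(mesh$vertices[sel, , drop = FALSE],
                                             isosurface)
  mesh
}

#' Pin mesh cell corners to their observed image positions
#'
#' Every mesh corner vertex (incident to at least four cells, or three plus
#' the exterior) is matched to the image corner point with the same
#' incident cell label set; matched vertices are moved to the image point
#' and marked as pinned (immovable during optimization). When two mesh
#' vertices match the same image corner the nearest is kept and the other
#' left unpinned; unmatched corners are reported in the `unmatched`
#' attribute.
#'
#' @param mesh a `tissue_mesh`
#' @param corner_points list with `keys` (n x 4 label matrix) and `points`
#'   (n x 3), as produced by [cell_corner_points()]
#' @param background_label image background label, mapped to the mesh
#'   exterior label 0
#' @param tolerance maximum move distance (micrometres); farther matches
#'   are left unpinned
#' @return a `tissue_mesh` with attribute `unmatched` (corner label keys of
#'   mesh corners without an image match)
#' @export
pin_cell_corners <- function(mesh, corner_points, background_label = 1L,
                             tolerance = Inf) {
  keys <- corner_points$keys
  keys[keys == background_label] <- 0L
  keys <- t(apply(keys, 1, sort))
  ikeys <- apply(keys, 1, paste, collapse = "-")
  corner_vs <- which(!vapply(mesh$corner_cells, is.null, logical(1)))
  mkeys <- vapply(mesh$corner_cells[corner_vs], function(s)
    paste(sort(s), collapse = "-"), character(1))
  unmatched <- character(0)
  used <- rep(NA_integer_, length(ikeys))   # image corner -> chosen vertex
  for (i in seq_along(corner_vs)) {
    hit <- match(mkeys[i], ikeys)
    if (is.na(hit)) { unmatched <- c(unmatched, mkeys[i]); next }
    v <- corner_vs[i]
    d <- sqrt(sum((mesh$vertices[v, ] - corner_points$points[hit, ])^2))
    if (d > tolerance) { unmatched <- c(unmatched, mkeys[i]); next }
    if (!is.na(used[hit])) {
      prev <- used[hit]
      dprev <- sqrt(sum((mesh$vertices[prev, ] -
                           corner_points$points[hit, ])^2))
      if (d >= dprev) { unmatched <- c(unmatched, mkeys[i]); next }
      mesh$pinned[prev] <- FALSE
    }
    used[hit] <- v
    mesh$vertices[v, ] <- corner_points$points[hit, ]
    mesh$pinned[v] <- TRUE
  }
  attr(mesh, "unmatched") <- unmatched
  mesh
}

#' Mesh energy against image, shape prior and regularity criteria
#'
#' `e_image` is the mean, over non-pinned vertices, of the squared distance
#' to the nearest inter-label boundary point of the image compatible with
#' the vertex's incident interfaces. `e_prior` is the mean over cell-cell
#' interfaces of the mean squared distance of the interface's vertices to
#' its best-fit plane (flat polygonal walls; the curved outer surface is
#' not penalized). `e_regularity` is the mean triangle eccentricity plus
#' the mean squared relative valence deviation from 6 of interface-interior
#' vertices.
#'
#' @param mesh a `tissue_mesh`
#' @param image a `segmented_image`
#' @param w a `mesh_weights`
#' @return an `energy_breakdown`
#' @export
mesh_energy <- function(mesh, image, w = mesh_weights(),
                        isosurface = NULL) {
  wplanes <- wall_plane_index(image)
  planes <- interface_planes(mesh)
  db <- if (is.null(w$deadband)) 0 else w$deadband
  if (is.null(isosurface)) isosurface <- binary_isosurface(image)
  parts <- mesh_energy_parts(mesh, wplanes, planes, db, isosurface)
  total <- w$w_image * parts$e_image + w$w_prior * parts$e_prior +
    w$w_regularity * parts$e_regularity
  structure(c(parts, list(total = total)), class = "energy_breakdown")
}

mesh_energy_parts <- function(mesh, wplanes, planes, deadband = 0,
                              isosurface = NULL) {
  vp <- vertex_pairs(mesh)
  sel <- which(!mesh$pinned)
  ext_d2 <- rep(NA_real_, nrow(mesh$vertices))
  wpts <- attr(wplanes, "exterior_points")
  for (v in sel) {
    ks <- vp[[v]]
    ext <- ks[startsWith(ks, "0-")]
    if (length(ext) == 0) next
    best <- Inf
    for (k in ext) {
      pts <- wpts[[k]]
      if (is.null(pts)) next
      p <- mesh$vertices[v, ]
      best <- min(best, min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 +
                              (pts[, 3] - p[3])^2))
    }
    ext_d2[v] <- best
  }
  d2 <- vapply(sel, function(v)
    deadband_d2(vertex_image_dist2(mesh$vertices[v, ], vp[[v]], wplanes,
                                   ext_d2[v]), deadband), numeric(1))
  e_image <- if (length(d2)) mean(d2[is.finite(d2)]) else 0
  e_prior <- interface_flatness(mesh, planes)
  ecc <- triangle_eccentricity(mesh$vertices, mesh$triangles)
  vd <- valence_deviation(mesh)
  list(e_image = e_image, e_prior = e_prior,
       e_regularity = mean(ecc) + vd)
}

wall_plane_index <- function(image) {
  # local planar fit of each observed cell wall: midpoints of the voxel
  # faces separating two labels are reduced to a best-fit plane per label
  # pair (walls of this tissue are flat); tiny walls with too few face
  # points keep the raw points. Background is mapped to the exterior
  # label 0; exterior "walls" are curved and handled through the
  # isosurface instead.
  wp <- wall_point_index(image)
  out <- new.env(parent = emptyenv())
  ext <- new.env(parent = emptyenv())
  for (k in ls(wp)) {
    pts <- wp[[k]]
    if (startsWith(k, "0-")) {
      ext[[k]] <- pts
      next
    }
    if (nrow(pts) >= 3) {
      ctr <- colMeans(pts)
      sv <- svd(sweep(pts, 2, ctr, `-`), nu = 0, nv = 3)
      out[[k]] <- list(center = ctr, normal = sv$v[, 3])
    } else {
      out[[k]] <- list(points = pts)
    }
  }
  attr(out, "exterior_points") <- ext
  out
}

wall_point_index <- function(image) {
  # midpoints of voxel faces separating two labels, indexed by pair key
  # (background mapped to the exterior label 0)
  a <- image$labels
  d <- dim(a)
  bg <- image$background_label
  vs <- image$voxel_size
  pts <- list(); keys <- list()
  for (ax in 1:3) {
    n <- d[ax]
    i1 <- slice_index(d, ax, 1:(n - 1)); i2 <- slice_index(d, ax, 2:n)
    A <- a[i1]; B <- a[i2]
    m <- which(A != B)
    if (length(m) == 0) next
    idx <- which(i1, arr.ind = TRUE)[m, , drop = FALSE]
    ctr <- voxel_centers(idx, image)
    ctr[, ax] <- ctr[, ax] + vs[ax] / 2
    la <- A[m]; lb <- B[m]
    la[la == bg] <- 0L; lb[lb == bg] <- 0L
    pts[[length(pts) + 1]] <- ctr
    keys[[length(keys) + 1]] <- edge_key(la, lb)
  }
  pts <- do.call(rbind, pts)
  keys <- unlist(keys)
  out <- new.env(parent = emptyenv())
  for (k in unique(keys)) out[[k]] <- pts[keys == k, , drop = FALSE]
  out
}

vertex_pairs <- function(mesh) {
  ik <- edge_key(mesh$interface[, 1], mesh$interface[, 2])
  tt <- mesh$triangles
  out <- vector("list", nrow(mesh$vertices))
  for (c in 1:3) {
    sp <- split(ik, tt[, c])
    for (v in names(sp)) {
      vi <- as.integer(v)
      out[[vi]] <- c(out[[vi]], sp[[v]])
    }
  }
  lapply(out, unique)
}

deadband_d2 <- function(d2, db) {
  if (db <= 0 || !is.finite(d2)) return(d2)
  max(0, sqrt(d2) - db)^2
}

vertex_image_dist2 <- function(p, pairs, wplanes, ext_d2 = NA_real_) {
  # mean squared distance to the observed wall surfaces compatible with
  # the vertex: cell-cell pairs use their fitted wall plane (so junction
  # and corner vertices are pulled to the intersection of their walls);
  # exterior pairs use the distance to the cell's own exposed boundary
  # points, which anchors surface vertices laterally on the curved
  # epidermis where no plane fit applies
  acc <- 0; n <- 0L
  for (k in pairs) {
    if (startsWith(k, "0-")) {
      if (is.finite(ext_d2)) { acc <- acc + ext_d2; n <- n + 1L }
      next
    }
    pl <- wplanes[[k]]
    if (is.null(pl)) next
    if (!is.null(pl$center)) {
      d <- sum((p - pl$center) * pl$normal)
      acc <- acc + d * d
    } else {
      acc <- acc + min((pl$points[, 1] - p[1])^2 +
                         (pl$points[, 2] - p[2])^2 +
                         (pl$points[, 3] - p[3])^2)
    }
    n <- n + 1L
  }
  if (n == 0L) return(if (is.finite(ext_d2)) ext_d2 else NA_real_)
  acc / n
}

interface_planes <- function(mesh) {
  # best-fit plane per cell-cell interface (centroid + unit normal)
  ik <- edge_key(mesh$interface[, 1], mesh$interface[, 2])
  cellcell <- mesh$interface[, 1] > 0
  out <- new.env(parent = emptyenv())
  for (k in unique(ik[cellcell])) {
    vs <- unique(as.vector(mesh$triangles[ik == k, , drop = FALSE]))
    P <- mesh$vertices[vs, , drop = FALSE]
    ctr <- colMeans(P)
    if (nrow(P) >= 3) {
      sv <- svd(sweep(P, 2, ctr, `-`), nu = 0, nv = 3)
      out[[k]] <- list(center = ctr, normal = sv$v[, 3], verts = vs)
    } else {
      out[[k]] <- list(center = ctr, normal = c(0, 0, 1), verts = vs)
    }
  }
  out
}

interface_flatness <- function(mesh, planes) {
  ks <- ls(planes)
  if (length(ks) == 0) return(0)
  mean(vapply(ks, function(k) {
    pl <- planes[[k]]
    d <- sweep(mesh$vertices[pl$verts, , drop = FALSE], 2, pl$center,
               `-`) %*% pl$normal
    mean(d^2)
  }, numeric(1)))
}

triangle_eccentricity <- function(vertices, triangles) {
  # 1 - (sin a + sin b + sin c) / (3 sin 60): 0 for equilateral, 1 for
  # degenerate triangles
  p1 <- vertices[triangles[, 1], , drop = FALSE]
  p2 <- vertices[triangles[, 2], , drop = FALSE]
  p3 <- vertices[triangles[, 3], , drop = FALSE]
  ang <- function(a, b, c) {
    u <- b - a; v <- c - a
    cosv <- rowSums(u * v) /
      (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)) + 1e-300)
    acos(pmin(1, pmax(-1, cosv)))
  }
  s <- sin(ang(p1, p2, p3)) + sin(ang(p2, p3, p1)) + sin(ang(p3, p1, p2))
  pmin(1, pmax(0, 1 - s / (3 * sin(pi / 3))))
}

interior_interface_vertices <- function(mesh) {
  # vertices strictly interior to a single interface: all incident
  # triangles share one label pair and no incident edge lies on the
  # interface boundary (junction lines, surface rims, open patch borders)
  vp <- vertex_pairs(mesh)
  single <- lengths(vp) == 1
  feat <- feature_edges(mesh)
  featv <- unique(as.integer(unlist(strsplit(names(feat)[feat], "-",
                                             fixed = TRUE))))
  single[featv] <- FALSE
  which(single)
}

valence_deviation <- function(mesh) {
  ii <- interior_interface_vertices(mesh)
  if (length(ii) == 0) return(0)
  val <- vertex_valences(mesh)
  mean(((val[ii] - 6) / 6)^2)
}

vertex_valences <- function(mesh) {
  tt <- mesh$triangles
  ek <- unique(c(edge_key(tt[, 1], tt[, 2]), edge_key(tt[, 2], tt[, 3]),
                 edge_key(tt[, 1], tt[, 3])))
  ends <- matrix(as.integer(unlist(strsplit(ek, "-", fixed = TRUE))),
                 ncol = 2, byrow = TRUE)
  tab <- table(factor(as.vector(ends), levels = seq_len(nrow(mesh$vertices))))
  as.integer(tab)
}

#' Optimize a tissue mesh by annealed vertex shifts and edge flips
#'
#' Minimizes [mesh_energy()] by simulated annealing with two local moves:
#' relocation of a vertex within a small sphere around its current position
#' (pinned vertices excluded; surface vertices are re-projected onto the
#' tissue isosurface after each shift) and flips of edges strictly interior
#' to a single interface. Flips never cross interfaces, so the dual cell
#' adjacency of the mesh is preserved exactly; moves that would create a
#' degenerate or fold-over triangle are filtered. Interface planes for the
#' flatness prior are refit between temperature cycles and frozen within a
#' cycle, so energy changes are computed exactly. With the default
#' `t_start = NULL` the temperature is zero throughout (descent cycles
#' with plane refits and a shrinking shift radius): the continuous
#' relocation landscape needs no uphill moves from a structurally correct
#' input; an explicit `t_start` enables Metropolis annealing. The final
#' state is the best state seen, quenched at zero temperature, and is
#' returned only if its full energy does not exceed the input's (otherwise
#' the input mesh is returned unchanged). Deterministic given the
#' schedule's seed.
#'
#' @param mesh a `tissue_mesh`
#' @param image the `segmented_image` the mesh reconstructs
#' @param w a `mesh_weights` (with the annealing schedule inside)
#' @param isosurface optional precomputed [binary_isosurface()] of `image`
#' @return an optimized `tissue_mesh` with attributes `energy_log`
#'   (data.frame) and `energy` (final `energy_breakdown`)
#' @export
optimize_mesh <- function(mesh, image, w = mesh_weights(),
                          isosurface = NULL) {
  if (is.null(isosurface)) isosurface <- binary_isosurface(image)
  wp <- wall_plane_index(image)
  if (is.null(w$deadband)) w$deadband <- 0
  schedule <- w$schedule
  e_init_full <- mesh_energy(mesh, image, w, isosurface)
  out <- with_seed(schedule$rng_seed,
                   mesh_anneal(mesh, image, w, wp, isosurface, schedule))
  e_out_full <- mesh_energy(out$mesh, image, w, isosurface)
  if (e_out_full$total > e_init_full$total + 1e-12) {
    out$mesh <- mesh
    e_out_full <- e_init_full
  }
  attr(out$mesh, "energy_log") <- out$log
  attr(out$mesh, "energy") <- e_out_full
  out$mesh
}

mesh_anneal <- function(mesh, image, w, wp, isosurface, schedule) {
  radius0 <- w$shift_radius
  if (is.null(radius0))
    radius0 <- 0.5 * stats::median(mesh_edge_lengths(mesh)$len)
  st <- mesh_state_init(mesh, w, wp)
  build_local_caches(st, isosurface, radius0)
  log <- list()
  note <- function(phase, sweep, temp, e)
    log[[length(log) + 1]] <<- data.frame(phase = phase, sweep = sweep,
                                          temperature = temp, energy = e)
  e_cur <- mesh_state_energy(st)
  note("init", 0L, NA_real_, e_cur)
  best <- mesh_state_current(st); e_best <- e_cur
  # the default temperature is zero: unlike the discrete adjacency
  # optimization, the vertex-relocation landscape is smooth and the input
  # mesh is already structurally correct, so uphill moves only trade cell
  # shape for voxel-scale detail; explicit temperatures enable annealing
  t_start <- schedule$t_start
  if (is.null(t_start)) t_start <- 0
  t_end <- if (is.null(schedule$t_end) || t_start == 0) t_start / 200
  else schedule$t_end
  sweep_no <- 0L
  for (cyc in seq_len(schedule$cycles)) {
    temp <- t_start
    radius <- radius0 * 0.9^(cyc - 1)
    for (s in seq_len(schedule$steps_per_cycle)) {
      e_cur <- mesh_sweep(st, temp, radius, isosurface)
      sweep_no <- sweep_no + 1L
      if (e_cur < e_best) { e_best <- e_cur; best <- mesh_state_current(st) }
      note("anneal", sweep_no, temp, e_cur)
      temp <- max(temp * schedule$cooling_factor, t_end)
    }
    # refit the interface planes and local search caches between cycles
    mesh_state_refit(st)
    build_local_caches(st, isosurface, radius0)
    e_cur <- mesh_state_energy(st)
  }
  st <- mesh_state_init(best, w, wp)
  build_local_caches(st, isosurface, radius0)
  e_cur <- mesh_state_energy(st)
  for (qs in seq_len(6)) {
    e_new <- mesh_sweep(st, 0, radius0 * 0.9^schedule$cycles, isosurface)
    sweep_no <- sweep_no + 1L
    note("quench", sweep_no, 0, e_new)
    if (e_new >= e_cur - max(1e-12, 1e-5 * abs(e_cur))) { e_cur <- min(e_cur, e_new); break }
    e_cur <- e_new
  }
  list(mesh = mesh_state_current(st), log = do.call(rbind, log))
}

mesh_probe_scale <- function(st, radius) {
  # typical |dE| of a random vertex shift, to set the temperature scale
  w <- st$w
  n_mov <- length(st$movable)
  probe <- st$movable[seq_len(min(60, n_mov))]
  deltas <- c()
  n_ifaces <- length(ls(st$plane_stats))
  for (v in probe) {
    dirn <- stats::rnorm(3); dirn <- dirn / sqrt(sum(dirn^2))
    p_new <- st$V[v, ] + dirn * radius * 0.5
    d2_new <- deadband_d2(
      vertex_image_dist2(p_new, st$vpairs[[v]], st$wp,
                         local_ext_d2(st, v, p_new)), st$db)
    dE <- 0
    if (is.finite(st$d2[v]) && is.finite(d2_new))
      dE <- dE + w$w_image * (d2_new - st$d2[v]) / n_mov
    pd_old <- plane_dist2(st, v, st$V[v, ])
    pd_new <- plane_dist2(st, v, p_new)
    ks <- st$vpairs[[v]]
    for (i in seq_along(ks)) {
      ps <- st$plane_stats[[ks[i]]]
      if (is.null(ps) || is.na(pd_new[i])) next
      dE <- dE + w$w_prior * (pd_new[i] - pd_old[i]) / ps$n / n_ifaces
    }
    deltas <- c(deltas, abs(dE))
  }
  if (length(deltas) == 0) return(1e-9)
  stats::median(deltas)
}

mesh_state_init <- function(mesh, w, wp) {
  st <- new.env(parent = emptyenv())
  st$mesh <- mesh
  st$w <- w
  st$wp <- wp
  st$db <- if (is.null(w$deadband)) 0 else w$deadband
  st$V <- mesh$vertices
  st$T <- mesh$triangles
  st$ik <- edge_key(mesh$interface[, 1], mesh$interface[, 2])
  st$int <- mesh$interface
  st$pinned <- mesh$pinned
  st$surface <- mesh$is_surface
  st$vtris <- split(rep(seq_len(nrow(st$T)), 3), as.vector(st$T))
  ek_all <- c(edge_key(st$T[, 1], st$T[, 2]), edge_key(st$T[, 2], st$T[, 3]),
              edge_key(st$T[, 1], st$T[, 3]))
  st$edge_tris <- list2env(split(rep(seq_len(nrow(st$T)), 3), ek_all),
                           envir = new.env(parent = emptyenv()))
  st$vpairs <- vertex_pairs(mesh)
  st$movable <- which(!st$pinned)
  st$planes <- interface_planes(mesh)
  # caches
  st$extpts <- attr(wp, "exterior_points")
  st$d2 <- rep(NA_real_, nrow(st$V))
  for (v in st$movable)
    st$d2[v] <- deadband_d2(
      vertex_image_dist2(st$V[v, ], st$vpairs[[v]], wp,
                         global_ext_d2(st, v, st$V[v, ])), st$db)
  st$local_surf <- vector("list", nrow(st$V))
  st$local_ext <- vector("list", nrow(st$V))
  st$iso <- NULL
  st$ecc <- triangle_eccentricity(st$V, st$T)
  st$val <- vertex_valences(mesh)
  st$interior <- rep(FALSE, nrow(st$V))
  st$interior[lengths(st$vpairs) == 1] <- TRUE
  st$plane_stats <- plane_dist_stats(st)
  st
}

plane_dist_stats <- function(st) {
  out <- new.env(parent = emptyenv())
  for (k in ls(st$planes)) {
    pl <- st$planes[[k]]
    d <- sweep(st$V[pl$verts, , drop = FALSE], 2, pl$center, `-`) %*%
      pl$normal
    out[[k]] <- list(sum = sum(d^2), n = length(pl$verts))
  }
  out
}

build_local_caches <- function(st, isosurface, radius0) {
  # restrict the image-attachment and surface-projection searches of every
  # movable vertex to candidates near its current position; the caches are
  # rebuilt whenever the interface planes are refit, so the localization
  # stays valid while vertices drift
  st$iso <- isosurface
  if (is.null(st$iso_inc))
    st$iso_inc <- split(rep(seq_len(nrow(isosurface$triangles)), 3),
                        as.vector(isosurface$triangles))
  surf_v <- st$movable[st$surface[st$movable]]
  nv <- if (length(surf_v))
    nearest_vertex(st$V[surf_v, , drop = FALSE], isosurface$vertices)
  else integer(0)
  for (i in seq_along(surf_v)) {
    v <- surf_v[i]
    # triangles within two rings of the nearest isosurface vertex
    t1 <- st$iso_inc[[as.character(nv[i])]]
    ring <- unique(as.vector(isosurface$triangles[t1, , drop = FALSE]))
    st$local_surf[[v]] <- unique(unlist(st$iso_inc[as.character(ring)],
                                        use.names = FALSE))
  }
  for (v in st$movable) {
    p <- st$V[v, ]
    ext <- st$vpairs[[v]][startsWith(st$vpairs[[v]], "0-")]
    if (length(ext) > 0) {
      r <- sqrt(max(st$d2[v], 1, na.rm = TRUE)) + 4 * radius0
      cand <- list()
      for (k in ext) {
        pts <- st$extpts[[k]]
        if (is.null(pts)) next
        d2p <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 +
          (pts[, 3] - p[3])^2
        near <- d2p <= r^2
        if (!any(near)) near <- which.min(d2p)
        cand[[length(cand) + 1]] <- pts[near, , drop = FALSE]
      }
      st$local_ext[v] <- list(if (length(cand)) do.call(rbind, cand))
    }
  }
  invisible(st)
}

global_ext_d2 <- function(st, v, p) {
  ks <- st$vpairs[[v]]
  ext <- ks[startsWith(ks, "0-")]
  if (length(ext) == 0) return(NA_real_)
  best <- Inf
  for (k in ext) {
    pts <- st$extpts[[k]]
    if (is.null(pts)) next
    best <- min(best, min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 +
                            (pts[, 3] - p[3])^2))
  }
  best
}

local_ext_d2 <- function(st, v, p) {
  pts <- st$local_ext[[v]]
  if (is.null(pts)) return(NA_real_)
  min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 + (pts[, 3] - p[3])^2)
}

local_surface_project <- function(st, v, p) {
  tris <- st$local_surf[[v]]
  if (is.null(tris)) return(p)
  best <- p; bestd <- Inf
  iv <- st$iso$vertices; it <- st$iso$triangles
  for (ti in tris) {
    cp <- closest_point_triangle(p, iv[it[ti, 1], ], iv[it[ti, 2], ],
                                 iv[it[ti, 3], ])
    dd <- sum((p - cp)^2)
    if (dd < bestd) { bestd <- dd; best <- cp }
  }
  best
}

mesh_state_refit <- function(st) {
  st$planes <- interface_planes(mesh_state_current(st))
  st$plane_stats <- plane_dist_stats(st)
}

mesh_state_current <- function(st) {
  tissue_mesh(st$V, st$T, st$int, st$mesh$is_surface, st$mesh$is_corner,
              st$mesh$pinned, st$mesh$corner_cells)
}

mesh_state_energy <- function(st) {
  w <- st$w
  d2 <- st$d2[st$movable]
  e_image <- if (length(d2)) mean(d2[is.finite(d2)]) else 0
  ks <- ls(st$plane_stats)
  e_prior <- if (length(ks) == 0) 0 else
    mean(vapply(ks, function(k) {
      s <- st$plane_stats[[k]]; s$sum / s$n
    }, numeric(1)))
  e_reg <- mean(st$ecc) +
    (if (any(st$interior))
      mean(((st$val[st$interior] - 6) / 6)^2) else 0)
  w$w_image * e_image + w$w_prior * e_prior + w$w_regularity * e_reg
}

plane_dist2 <- function(st, v, p) {
  vapply(st$vpairs[[v]], function(k) {
    pl <- st$planes[[k]]
    if (is.null(pl)) return(NA_real_)
    as.numeric((sum((p - pl$center) * pl$normal))^2)
  }, numeric(1))
}

mesh_sweep <- function(st, temp, radius, isosurface) {
  n_mov <- length(st$movable)
  w <- st$w
  n_int_v <- sum(st$interior)
  n_ifaces <- length(ls(st$plane_stats))
  for (v in st$movable[sample.int(n_mov)]) {
    # uniform random point in the shift sphere
    dirn <- stats::rnorm(3)
    dirn <- dirn / sqrt(sum(dirn^2))
    p_new <- st$V[v, ] + dirn * radius * stats::runif(1)^(1 / 3)
    if (st$surface[v])
      p_new <- local_surface_project(st, v, p_new)
    tris <- st$vtris[[as.character(v)]]
    tt_loc <- st$T[tris, , drop = FALSE]
    vids <- unique(as.vector(tt_loc))
    Vloc <- st$V[vids, , drop = FALSE]
    Vloc[vids == v, ] <- rep(p_new, each = sum(vids == v))
    tt_idx <- matrix(match(tt_loc, vids), ncol = 3)
    ecc_new <- triangle_eccentricity(Vloc, tt_idx)
    if (any(!is.finite(ecc_new))) next
    # fold-over filter: no incident triangle may flip its orientation
    n_old <- cross3(st$V[tt_loc[, 2], , drop = FALSE] -
                      st$V[tt_loc[, 1], , drop = FALSE],
                    st$V[tt_loc[, 3], , drop = FALSE] -
                      st$V[tt_loc[, 1], , drop = FALSE])
    n_new <- cross3(Vloc[tt_idx[, 2], , drop = FALSE] -
                      Vloc[tt_idx[, 1], , drop = FALSE],
                    Vloc[tt_idx[, 3], , drop = FALSE] -
                      Vloc[tt_idx[, 1], , drop = FALSE])
    if (any(rowSums(n_old * n_new) <= 0)) next
    d2_new <- deadband_d2(
      vertex_image_dist2(p_new, st$vpairs[[v]], st$wp,
                         local_ext_d2(st, v, p_new)), st$db)
    pd_old <- plane_dist2(st, v, st$V[v, ])
    pd_new <- plane_dist2(st, v, p_new)
    dE <- 0
    if (is.finite(st$d2[v]) && is.finite(d2_new))
      dE <- dE + w$w_image * (d2_new - st$d2[v]) / n_mov
    ks <- st$vpairs[[v]]
    for (i in seq_along(ks)) {
      ps <- st$plane_stats[[ks[i]]]
      if (is.null(ps) || is.na(pd_new[i])) next
      dE <- dE + w$w_prior * (pd_new[i] - pd_old[i]) / ps$n / n_ifaces
    }
    dE <- dE + w$w_regularity *
      (sum(ecc_new) - sum(st$ecc[tris])) / nrow(st$T)
    if (dE <= 0 || (temp > 0 && stats::runif(1) < exp(-dE / temp))) {
      st$V[v, ] <- p_new
      st$ecc[tris] <- ecc_new
      st$d2[v] <- d2_new
      for (i in seq_along(ks)) {
        ps <- st$plane_stats[[ks[i]]]
        if (is.null(ps) || is.na(pd_new[i])) next
        ps$sum <- ps$sum + pd_new[i] - pd_old[i]
        st$plane_stats[[ks[i]]] <- ps
      }
    }
  }
  # interface-interior edge flips
  flips <- flip_candidates(st)
  if (length(flips) > 0) {
    for (fi in flips[sample.int(length(flips),
                                min(length(flips), n_mov %/% 4 + 1))]) {
      e_flip <- try_flip(st, fi, temp)
    }
  }
  mesh_state_energy(st)
}

flip_candidates <- function(st) {
  keys <- ls(st$edge_tris)
  keep <- vapply(keys, function(k) {
    tr <- st$edge_tris[[k]]
    length(tr) == 2 && st$ik[tr[1]] == st$ik[tr[2]]
  }, logical(1))
  keys[keep]
}

try_flip <- function(st, ekey, temp) {
  tt <- st$T
  ab <- as.integer(strsplit(ekey, "-", fixed = TRUE)[[1]])
  rows <- st$edge_tris[[ekey]]
  if (is.null(rows) || length(rows) != 2) return(invisible(NULL))
  if (st$ik[rows[1]] != st$ik[rows[2]]) return(invisible(NULL))
  c1 <- setdiff(tt[rows[1], ], ab)
  c2 <- setdiff(tt[rows[2], ], ab)
  if (length(c1) != 1 || length(c2) != 1 || c1 == c2) return(invisible(NULL))
  # the new diagonal must not already exist
  new_key <- edge_key(c1, c2)
  if (!is.null(st$edge_tris[[new_key]])) return(invisible(NULL))
  newt <- rbind(c(c1, c2, ab[1]), c(c1, c2, ab[2]))
  ecc_new <- triangle_eccentricity(st$V, newt)
  if (any(ecc_new > 0.999)) return(invisible(NULL))
  # fold-over filter: keep the new normals on the side of the old ones
  n_old <- colSums(cross3(st$V[tt[rows, 2], , drop = FALSE] -
                            st$V[tt[rows, 1], , drop = FALSE],
                          st$V[tt[rows, 3], , drop = FALSE] -
                            st$V[tt[rows, 1], , drop = FALSE]))
  n_new <- cross3(st$V[newt[, 2], , drop = FALSE] -
                    st$V[newt[, 1], , drop = FALSE],
                  st$V[newt[, 3], , drop = FALSE] -
                    st$V[newt[, 1], , drop = FALSE])
  if (any(n_new %*% n_old < 0)) return(invisible(NULL))
  w <- st$w
  dE <- w$w_regularity * (sum(ecc_new) - sum(st$ecc[rows])) / nrow(tt)
  # valence changes: ab lose one neighbour, c1/c2 gain one
  val_delta <- 0
  n_int_v <- sum(st$interior)
  if (n_int_v > 0) {
    for (v in c(ab, c1, c2)) {
      if (!st$interior[v]) next
      old <- ((st$val[v] - 6) / 6)^2
      newv <- st$val[v] + if (v %in% ab) -1L else 1L
      val_delta <- val_delta + (((newv - 6) / 6)^2 - old) / n_int_v
    }
  }
  dE <- dE + w$w_regularity * val_delta
  if (dE <= 0 || (temp > 0 && stats::runif(1) < exp(-dE / temp))) {
    old_rows <- tt[rows, ]
    st$T[rows[1], ] <- newt[1, ]
    st$T[rows[2], ] <- newt[2, ]
    st$ecc[rows] <- ecc_new
    for (v in ab) st$val[v] <- st$val[v] - 1L
    for (v in c(c1, c2)) st$val[v] <- st$val[v] + 1L
    # update vertex-triangle incidence for the four corners
    for (v in unique(as.vector(old_rows)))
      st$vtris[[as.character(v)]] <- setdiff(st$vtris[[as.character(v)]],
                                             rows)
    for (r in rows) for (v in st$T[r, ])
      st$vtris[[as.character(v)]] <- c(st$vtris[[as.character(v)]], r)
    # update the edge-triangle map: the diagonal flips, two quad edges
    # change their incident triangle row
    rm(list = ekey, envir = st$edge_tris)
    st$edge_tris[[new_key]] <- rows
    k_bc1 <- edge_key(ab[2], c1)
    st$edge_tris[[k_bc1]] <-
      c(setdiff(st$edge_tris[[k_bc1]], rows[1]), rows[2])
    k_ac2 <- edge_key(ab[1], c2)
    st$edge_tris[[k_ac2]] <-
      c(setdiff(st$edge_tris[[k_ac2]], rows[2]), rows[1])
  }
  invisible(NULL)
}
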