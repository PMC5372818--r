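#' Cell barycenters of a segmented image
#'
#' Per-label unweighted mean of the voxel-centre world coordinates, the
#' natural placement of a cell's adjacency vertex. Background voxels are
#' excluded.
#'
#' @param image a `segmented_image`
#' @return numeric matrix (n_cells x 3, micrometres), rownames = cell labels
#' @export
cell_barycenters <- function(image) {
  a <- image$labels
  keep <- a != image$background_label
  idx <- which(keep, arr.ind = TRUE)
  labs <- a[keep]
  pts <- voxel_centers(idx, image)
  sums <- rowsum(pts, labs)
  cnt <- as.vector(rowsum(rep(1, length(labs)), labs))
  out <- sums / cnt
  rownames(out) <- rownames(sums)
  out[order(as.integer(rownames(out))), , drop = FALSE]
}

#' Extract all cell adjacency information from a segmented image
#'
#' Adjacency edges are unordered pairs of distinct labels meeting across a
#' voxel face (6-connectivity); wall areas count those face contacts times
#' the physical face area. Adjacency triangles and tetrahedra are label
#' triples and quadruples co-occurring in some 2x2x2 voxel cube, the 3D
#' generalization of pixel squares containing at least three labels; cubes
#' with five or more labels contribute all their subsets, deferring the
#' disambiguation of such junctions to the adjacency optimization. Triples
#' and quadruples are closed over the lower-dimensional adjacencies: a triple
#' is kept only if its three pairs are face-adjacent somewhere in the image
#' (and likewise quadruples over triples), which discards pure corner-touch
#' contacts and guarantees the simplex-closure invariant of the result.
#'
#' The background label participates (flagged through `background_label` and
#' `surface_cells`), so surface corners (three cells plus outside) are
#' captured alongside interior corners where four cells meet.
#'
#' @param image a `segmented_image`
#' @return an object of class `image_adjacencies` with fields `barycenters`,
#'   `edges` (E x 2), `triangles` (T x 3), `tetrahedra` (Q x 4, sorted label
#'   rows), `wall_areas` (named by "a-b"), `surface_cells`, `layers`,
#'   `corner_points` (list with `keys` Q x 4 and `points` Q x 3),
#'   `background_label`, `voxel_size`.
#' @export
extract_adjacencies <- function(image) {
  a <- image$labels
  d <- dim(a)
  bg <- image$background_label
  vs <- image$voxel_size
  face_area <- c(vs[2] * vs[3], vs[1] * vs[3], vs[1] * vs[2])

  pair_tab <- list()
  for (ax in 1:3) {
    n <- d[ax]
    i1 <- slice_index(d, ax, 1:(n - 1))
    i2 <- slice_index(d, ax, 2:n)
    A <- a[i1]; B <- a[i2]
    m <- A != B
    if (!any(m)) next
    p <- cbind(pmin(A[m], B[m]), pmax(A[m], B[m]))
    key <- paste(p[, 1], p[, 2], sep = "-")
    tb <- table(key)
    pair_tab[[ax]] <- data.frame(key = names(tb),
                                 area = as.vector(tb) * face_area[ax],
                                 stringsAsFactors = FALSE)
  }
  ptab <- do.call(rbind, pair_tab)
  wall <- if (is.null(ptab)) numeric(0) else
    tapply(ptab$area, ptab$key, sum)
  wall_areas <- as.numeric(wall)
  names(wall_areas) <- names(wall)
  edges <- key_to_matrix(names(wall_areas), 2)

  # 2x2x2 cube label co-occurrences
  cubes <- cube_label_sets(a)
  tris <- unique_subsets(cubes$sets, 3)
  quads <- unique_subsets(cubes$sets, 4)
  ekey <- simplex_key(edges)
  if (nrow(tris) > 0) {
    ok <- apply(tris, 1, function(t)
      all(simplex_key(rbind(t[c(1, 2)], t[c(1, 3)], t[c(2, 3)])) %in% ekey))
    tris <- tris[ok, , drop = FALSE]
  }
  tkey <- simplex_key(tris)
  if (nrow(quads) > 0) {
    ok <- apply(quads, 1, function(q)
      all(simplex_key(rbind(q[c(1, 2, 3)], q[c(1, 2, 4)], q[c(1, 3, 4)],
                            q[c(2, 3, 4)])) %in% tkey))
    quads <- quads[ok, , drop = FALSE]
  }

  # corner points: mean of the centres of all cubes containing the quadruple
  cp <- corner_points_from_cubes(cubes, quads, bg, vs)

  surface <- sort(unique(c(edges[edges[, 1] == bg, 2],
                           edges[edges[, 2] == bg, 1])))
  surface <- setdiff(surface, bg)

  adj <- structure(list(
    barycenters = cell_barycenters(image),
    edges = edges, triangles = tris, tetrahedra = quads,
    wall_areas = wall_areas, surface_cells = surface,
    layers = NULL, corner_points = cp,
    background_label = bg, voxel_size = vs,
    background_mask = a == bg),
    class = "image_adjacencies")
  adj$layers <- layer_assignment(adj)
  adj
}

#' @export
print.image_adjacencies <- function(x, ...) {
  cat(sprintf("<image_adjacencies> %d cells, %d edges, %d triangles, %d tetrahedra, %d corner points\n",
              nrow(x$barycenters), nrow(x$edges), nrow(x$triangles),
              nrow(x$tetrahedra), nrow(x$corner_points$keys)))
  invisible(x)
}

slice_index <- function(d, ax, range) {
  # logical index array selecting a sub-block along one axis
  idx <- array(FALSE, d)
  if (ax == 1) idx[range, , ] <- TRUE
  if (ax == 2) idx[, range, ] <- TRUE
  if (ax == 3) idx[, , range] <- TRUE
  idx
}

key_to_matrix <- function(keys, k) {
  if (length(keys) == 0) return(matrix(integer(0), ncol = k))
  m <- matrix(as.integer(unlist(strsplit(keys, "-", fixed = TRUE))),
              ncol = k, byrow = TRUE)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

cube_label_sets <- function(a) {
  d <- dim(a)
  nc <- (d - 1)
  # the 8 corner values of every 2x2x2 cube, cubes indexed by their low corner
  corner <- function(dx, dy, dz)
    as.vector(a[(1:nc[1]) + dx, (1:nc[2]) + dy, (1:nc[3]) + dz])
  labs8 <- cbind(corner(0, 0, 0), corner(1, 0, 0), corner(0, 1, 0),
                 corner(1, 1, 0), corner(0, 0, 1), corner(1, 0, 1),
                 corner(0, 1, 1), corner(1, 1, 1))
  mixed <- rowSums(labs8 != labs8[, 1]) > 0
  which_mixed <- which(mixed)
  sets <- lapply(which_mixed, function(i) sort.int(unique(labs8[i, ])))
  centers_idx <- arrayInd(which_mixed, nc)   # low-corner 1-based index
  list(sets = sets, centers_idx = centers_idx, dims = nc)
}

unique_subsets <- function(sets, k) {
  nlab <- lengths(sets)
  keep <- sets[nlab >= k]
  if (length(keep) == 0) return(matrix(integer(0), ncol = k))
  subs <- lapply(keep, function(s) {
    if (length(s) == k) matrix(s, ncol = k)
    else t(utils::combn(s, k))
  })
  m <- unique(do.call(rbind, subs))
  m[do.call(order, as.data.frame(m)), , drop = FALSE]
}

corner_points_from_cubes <- function(cubes, quads, bg, vs) {
  # keep interior corners (4 cells) and surface corners (3 cells + background)
  if (nrow(quads) > 0) {
    nbg <- rowSums(quads == bg)
    quads <- quads[nbg <= 1, , drop = FALSE]
  }
  if (nrow(quads) == 0)
    return(list(keys = matrix(integer(0), ncol = 4),
                points = matrix(numeric(0), ncol = 3)))
  qkey <- simplex_key(quads)
  nlab <- lengths(cubes$sets)
  rich <- which(nlab >= 4)
  acc_sum <- matrix(0, nrow(quads), 3)
  acc_n <- numeric(nrow(quads))
  for (i in rich) {
    s <- cubes$sets[[i]]
    sub <- if (length(s) == 4) matrix(s, ncol = 4) else t(utils::combn(s, 4))
    hit <- match(simplex_key(sub), qkey)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0) next
    ctr <- cubes$centers_idx[i, ] * vs   # cube centre = shared voxel corner
    acc_sum[hit, ] <- acc_sum[hit, , drop = FALSE] +
      matrix(ctr, length(hit), 3, byrow = TRUE)
    acc_n[hit] <- acc_n[hit] + 1
  }
  ok <- acc_n > 0
  list(keys = quads[ok, , drop = FALSE],
       points = acc_sum[ok, , drop = FALSE] / acc_n[ok])
}

#' Assign cells to tissue layers L1/L2/deeper
#'
#' The epidermal layer L1 is the set of cells adjacent to the background; L2
#' the cells adjacent to some L1 cell but not to the background; everything
#' else is deeper. In layered meristematic tissue L1 and L2 are anticlinally
#' separated and form independent sets of cells, which the layer
#' reconstruction exploits.
#'
#' @param adj an `image_adjacencies`
#' @return named character vector label -> "L1" / "L2" / "deeper"
#' @export
layer_assignment <- function(adj) {
  bg <- adj$background_label
  labs <- as.integer(rownames(adj$barycenters))
  l1 <- adj$surface_cells
  if (length(l1) == 0)
    stop("no cell is adjacent to the background: tissue fills the image")
  e <- adj$edges
  e <- e[e[, 1] != bg & e[, 2] != bg, , drop = FALSE]
  touch_l1 <- unique(c(e[e[, 1] %in% l1, 2], e[e[, 2] %in% l1, 1]))
  l2 <- setdiff(touch_l1, c(l1, bg))
  out <- stats::setNames(rep("deeper", length(labs)), labs)
  out[as.character(l2)] <- "L2"
  out[as.character(l1)] <- "L1"
  out
}

#' Cell corner points observed in the image
#'
#' Interior cell corners are points where exactly four cells meet; surface
#' corners where three cells meet the outside. Each corner is located at the
#' mean of the centres of all 2x2x2 voxel cubes in which its label set
#' co-occurs, in world coordinates. Used to pin mesh corner vertices to their
#' observed positions.
#'
#' @param image a `segmented_image`
#' @return list with `keys` (n x 4 sorted label matrix, background allowed
#'   once per row) and `points` (n x 3, micrometres)
#' @export
cell_corner_points <- function(image) {
  extract_adjacencies(image)$corner_points
}

#' Adjacency edges as a label-pair matrix
#' @param adj an `image_adjacencies`
#' @param include_background keep pairs involving the background label?
#' @return integer matrix (n x 2), rows sorted
#' @export
adjacency_edges <- function(adj, include_background = FALSE) {
  e <- adj$edges
  if (!include_background) {
    bg <- adj$background_label
    e <- e[e[, 1] != bg & e[, 2] != bg, , drop = FALSE]
  }
  e
}
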