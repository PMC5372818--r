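#' Non-manifold triangular tissue mesh
#'
#' A triangular mesh whose triangles carry an interface label: the unordered
#' pair of tissue cells they separate (0 stands for the exterior). The mesh
#' is non-manifold at cell junction edges, where three or more interfaces
#' meet; each individual cell boundary is a closed (watertight) surface.
#'
#' @param vertices n x 3 coordinate matrix (micrometres)
#' @param triangles m x 3 integer matrix of vertex indices
#' @param interface m x 2 integer matrix of cell labels per triangle (0 =
#'   exterior), rows sorted ascending
#' @param is_surface,is_corner,pinned logical per-vertex flags
#' @param corner_cells list per vertex: incident cell label set of corner
#'   vertices (with 0 for the exterior), or NULL
#' @return an object of class `tissue_mesh`
#' @export
tissue_mesh <- function(vertices, triangles, interface,
                        is_surface = rep(FALSE, nrow(vertices)),
                        is_corner = rep(FALSE, nrow(vertices)),
                        pinned = rep(FALSE, nrow(vertices)),
                        corner_cells = vector("list", nrow(vertices))) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  interface <- matrix(as.integer(interface), ncol = 2)
  interface <- cbind(pmin(interface[, 1], interface[, 2]),
                     pmax(interface[, 1], interface[, 2]))
  stopifnot(nrow(triangles) == nrow(interface),
            max(triangles) <= nrow(vertices))
  structure(list(vertices = vertices, triangles = triangles,
                 interface = interface, is_surface = is_surface,
                 is_corner = is_corner, pinned = pinned,
                 corner_cells = corner_cells),
            class = "tissue_mesh")
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat(sprintf("<tissue_mesh> %d vertices, %d triangles, %d cells (%d surface triangles)\n",
              nrow(x$vertices), nrow(x$triangles), length(mesh_cells(x)),
              sum(x$interface[, 1] == 0)))
  invisible(x)
}

#' Cell labels present in a tissue mesh
#' @param mesh a `tissue_mesh`
#' @return sorted integer vector (exterior label 0 excluded)
#' @export
mesh_cells <- function(mesh) {
  sort(setdiff(unique(as.vector(mesh$interface)), 0L))
}

#' Cell adjacency edges of a tissue mesh
#'
#' The dual adjacency of the mesh: unordered pairs of cells sharing at least
#' one interface triangle.
#'
#' @param mesh a `tissue_mesh`
#' @param include_exterior keep pairs (0, cell)?
#' @return integer matrix (n x 2)
#' @export
mesh_adjacency_edges <- function(mesh, include_exterior = FALSE) {
  e <- unique(mesh$interface)
  if (!include_exterior) e <- e[e[, 1] != 0, , drop = FALSE]
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Is a cell's boundary surface closed?
#'
#' A cell is watertight when every edge of its boundary triangles belongs to
#' exactly two of those triangles. Watertightness of every cell is what
#' makes the mesh usable for finite elements and voxelizable.
#'
#' @param mesh a `tissue_mesh`
#' @param cell cell label
#' @return logical
#' @export
cell_boundary_closed <- function(mesh, cell) {
  tri <- cell_triangles(mesh, cell)
  if (length(tri) == 0) stop("unknown cell: ", cell)
  ek <- cell_edge_keys(mesh, tri)
  all(table(ek) == 2)
}

cell_triangles <- function(mesh, cell) {
  which(mesh$interface[, 1] == cell | mesh$interface[, 2] == cell)
}

cell_edge_keys <- function(mesh, tri_rows) {
  tt <- mesh$triangles[tri_rows, , drop = FALSE]
  c(edge_key(tt[, 1], tt[, 2]), edge_key(tt[, 1], tt[, 3]),
    edge_key(tt[, 2], tt[, 3]))
}

#' Convert a tissue mesh to an incidence complex
#'
#' Builds the full incidence graph (vertices, edges, triangles, cells) of
#' the mesh, suitable for [validate_complex()] and [dualize()].
#'
#' @param mesh a `tissue_mesh`
#' @return an `incidence_complex`
#' @export
as_incidence_complex <- function(mesh) {
  tt <- mesh$triangles
  ekeys_all <- c(edge_key(tt[, 1], tt[, 2]), edge_key(tt[, 1], tt[, 3]),
                 edge_key(tt[, 2], tt[, 3]))
  ekeys <- unique(ekeys_all)
  eid <- stats::setNames(seq_along(ekeys), ekeys)
  nF <- nrow(tt)
  bnd2 <- lapply(seq_len(nF), function(f)
    as.integer(eid[ekeys_all[c(f, f + nF, f + 2 * nF)]]))
  emat <- key_to_matrix(ekeys, 2)
  # key_to_matrix sorts rows; rebuild in id order
  emat <- matrix(as.integer(unlist(strsplit(ekeys, "-", fixed = TRUE))),
                 ncol = 2, byrow = TRUE)
  bnd1 <- lapply(seq_along(ekeys), function(e) emat[e, ])
  cells <- mesh_cells(mesh)
  bnd3 <- lapply(cells, function(cl) as.integer(cell_triangles(mesh, cl)))
  pos <- mesh$vertices
  rownames(pos) <- seq_len(nrow(pos))
  incidence_complex(
    ids = list(seq_len(nrow(pos)), seq_along(ekeys), seq_len(nF),
               as.integer(cells)),
    bnd = list(stats::setNames(bnd1, seq_along(ekeys)),
               stats::setNames(bnd2, seq_len(nF)),
               stats::setNames(bnd3, cells)),
    positions = pos)
}

#' Star-triangulate a polyhedral cell complex into a tissue mesh
#'
#' Each polygonal interface of the dual geometry is fanned into triangles
#' from an added vertex at the mean of its boundary vertices, producing as
#' many triangles as the interface has boundary edges. Interface labels are
#' inherited; the original dual vertices keep their cell-corner flags and
#' the added centre vertices of exterior caps are flagged as surface
#' vertices.
#'
#' @param cellcomplex a `cell_complex` from [dual_geometry()]
#' @return a `tissue_mesh`
#' @export
star_triangulate <- function(cellcomplex) {
  cx <- cellcomplex
  vpos <- cx$positions
  n0 <- nrow(vpos)
  vsurf <- cx$properties[["0"]]$surface
  vcells <- cx$properties[["0"]]$cells
  lab1 <- cx$properties[["2"]]$label1
  lab2 <- cx$properties[["2"]]$label2
  faces <- cx$ids[[3]]
  verts <- vpos
  is_surface <- as.logical(vsurf[as.character(seq_len(n0))])
  is_corner <- rep(TRUE, n0)
  corner_cells <- unname(vcells[as.character(seq_len(n0))])
  tri <- list(); tri_lab <- list()
  for (f in faces) {
    fb <- cx$bnd[[2]][[as.character(f)]]
    if (length(fb) < 3)
      stop("interface ", f, " has fewer than 3 boundary edges")
    ctr_ids <- unique(unlist(cx$bnd[[1]][as.character(fb)]))
    ctr <- colMeans(vpos[as.character(ctr_ids), , drop = FALSE])
    verts <- rbind(verts, ctr)
    cvid <- nrow(verts)
    exterior <- lab1[as.character(f)] == 0 || lab2[as.character(f)] == 0
    is_surface <- c(is_surface, exterior)
    is_corner <- c(is_corner, FALSE)
    corner_cells <- c(corner_cells, list(NULL))
    for (e in fb) {
      ev <- cx$bnd[[1]][[as.character(e)]]
      tri[[length(tri) + 1]] <- c(ev[1], ev[2], cvid)
      tri_lab[[length(tri_lab) + 1]] <- c(lab1[as.character(f)],
                                          lab2[as.character(f)])
    }
  }
  tissue_mesh(verts, do.call(rbind, tri), do.call(rbind, tri_lab),
              is_surface = is_surface, is_corner = is_corner,
              corner_cells = corner_cells)
}
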