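#' Polyhedral cell geometry dual to an adjacency complex
#'
#' Dualizes an optimized adjacency simplicial complex into a polyhedral
#' tissue geometry. Topologically this is the incidence-graph flip of
#' [dualize()]; geometrically, every adjacency tetrahedron becomes a cell
#' corner placed at the centre of its circumscribed sphere, as in a Voronoi
#' diagram. When a tetrahedron violates the empty-circumsphere property
#' (which happens once the complex has been optimized away from Delaunay),
#' its circumcentre may drift arbitrarily far and is constrained back inside
#' the tetrahedron by projection onto its nearest face
#' ([constrain_into_tetrahedron()]); circumcentres of tetrahedra that still
#' satisfy the Delaunay property are genuine Voronoi vertices and are left
#' untouched, so the dual of a pristine Delaunay complex is exactly the
#' Voronoi diagram of its vertices.
#'
#' Boundary ("infinite") cell interfaces are truncated: every boundary
#' triangle of the adjacency complex contributes an extra surface vertex at
#' the centre of its circumscribed circle, projected onto the tissue
#' isosurface when one is supplied, and each surface cell is closed by a cap
#' face through these vertices.
#'
#' When image adjacencies are supplied, cell corners whose label set was
#' observed as a corner in the segmented image (four cells meeting, or
#' three cells and the background) are placed directly at their observed
#' image position, which anchors the dual geometry to the image;
#' circumcentres are the fallback for corners the image does not resolve.
#'
#' @param complex valid simplicial `incidence_complex` with vertex positions
#' @param adj optional `image_adjacencies` providing observed corner
#'   positions
#' @param isosurface optional `iso_surface` (from [binary_isosurface()])
#'   onto which surface vertices are projected
#' @param constrain `"auto"` (constrain only circumcentres of tetrahedra
#'   violating the empty-circumsphere property), `"always"`, or `"never"`
#' @param margin barycentric margin used when constraining
#' @return an `incidence_complex` of class `c("cell_complex",
#'   "incidence_complex")`: 0-cell properties `surface` (logical) and
#'   `cells` (list of incident cell label sets, background = 0); 2-cell
#'   properties `label1`/`label2` (interface cell pair, 0 = exterior);
#'   3-cell ids are the tissue cell labels.
#' @export
dual_geometry <- function(complex, adj = NULL, isosurface = NULL,
                          constrain = c("auto", "always", "never"),
                          margin = 0.05) {
  constrain <- match.arg(constrain)
  img_corner <- NULL
  if (!is.null(adj) && !is.null(adj$corner_points) &&
      nrow(adj$corner_points$keys) > 0) {
    ck <- adj$corner_points$keys
    img_corner <- stats::setNames(
      lapply(seq_len(nrow(ck)), function(i) adj$corner_points$points[i, ]),
      apply(ck, 1, function(r) paste(sort(r), collapse = "-")))
  }
  bg <- if (!is.null(adj)) adj$background_label else NA_integer_
  tets <- complex_simplices(complex, 3)
  if (nrow(tets) == 0) stop("adjacency complex has no tetrahedra")
  pos <- complex$positions
  labs <- complex$ids[[1]]
  nT <- nrow(tets)

  tri_all <- rbind(tets[, c(1, 2, 3), drop = FALSE],
                   tets[, c(1, 2, 4), drop = FALSE],
                   tets[, c(1, 3, 4), drop = FALSE],
                   tets[, c(2, 3, 4), drop = FALSE])
  tri_tet <- rep(seq_len(nT), 4)
  tri_key <- simplex_key(tri_all)
  tri_groups <- split(tri_tet, tri_key)
  tri_keys <- names(tri_groups)
  nF <- length(tri_keys)
  tri_mat <- matrix(as.integer(unlist(strsplit(tri_keys, "-", fixed = TRUE))),
                    ncol = 3, byrow = TRUE)
  rownames(tri_mat) <- tri_keys
  cof <- tri_groups[tri_keys]
  n_cof <- lengths(cof)
  if (any(n_cof > 2))
    stop("triangle shared by more than two tetrahedra: ",
         tri_keys[which(n_cof > 2)[1]])
  boundary_tri <- which(n_cof == 1)
  nB <- length(boundary_tri)
  b_index <- stats::setNames(seq_len(nB), tri_keys[boundary_tri])

  # --- dual vertex positions ------------------------------------------
  vpos <- matrix(0, nT + nB, 3)
  for (t in seq_len(nT)) {
    tp <- pos[as.character(tets[t, ]), ]
    if (!is.null(img_corner)) {
      hit <- img_corner[[paste(sort(tets[t, ]), collapse = "-")]]
      if (!is.null(hit)) { vpos[t, ] <- hit; next }
    }
    cc <- tryCatch(circumsphere_center(tp), error = function(e) NULL)
    if (is.null(cc)) { vpos[t, ] <- colMeans(tp); next }
    do_constrain <- switch(constrain,
      never = FALSE,
      always = TRUE,
      auto = {
        r2 <- sum((tp[1, ] - cc)^2)
        others <- pos[!(rownames(pos) %in% as.character(tets[t, ])), ,
                      drop = FALSE]
        nrow(others) > 0 &&
          any(rowSums(sweep(others, 2, cc, `-`)^2) < r2 * (1 - 1e-9))
      })
    vpos[t, ] <- if (do_constrain)
      constrain_into_tetrahedron(cc, tp, margin) else cc
  }
  if (nB > 0) {
    # surface corner fallback: circumcircle centre of the three cell
    # centres (exact for a Voronoi hull facet); with image adjacencies the
    # centroid is used instead, which stays near the junction even for
    # strongly irregular cells
    bpos <- t(vapply(boundary_tri, function(f) {
      P <- pos[as.character(tri_mat[f, ]), ]
      if (is.null(adj)) circumcircle_center(P) else colMeans(P)
    }, numeric(3)))
    if (!is.null(isosurface)) {
      # project onto the tissue surface, but only for genuine surface
      # corners: pseudo-boundary triangles deep in the tissue (interior
      # gaps of the adjacency complex) must not be dragged to the surface
      proj <- rep(TRUE, nB)
      if (!is.null(adj))
        proj <- vapply(seq_len(nB), function(i)
          all(tri_mat[boundary_tri[i], ] %in% adj$surface_cells),
          logical(1))
      if (any(proj))
        bpos[proj, ] <- project_to_surface(bpos[proj, , drop = FALSE],
                                           isosurface)
    }
    if (!is.null(img_corner)) {
      for (i in seq_len(nB)) {
        key <- paste(sort(c(bg, tri_mat[boundary_tri[i], ])),
                     collapse = "-")
        hit <- img_corner[[key]]
        if (!is.null(hit)) bpos[i, ] <- hit
      }
    }
    vpos[nT + seq_len(nB), ] <- bpos
  }

  # --- dual edges: one per primal triangle, plus surface rim edges ----
  e_bnd <- vector("list", nF)
  for (f in seq_len(nF)) {
    e_bnd[[f]] <- if (n_cof[f] == 2) as.integer(cof[[f]])
    else as.integer(c(cof[[f]], nT + b_index[[tri_keys[f]]]))
  }
  # boundary edges of the complex and their two boundary triangles
  edges_all <- unique(rbind(tri_mat[, c(1, 2)], tri_mat[, c(1, 3)],
                            tri_mat[, c(2, 3)]))
  edge_keys <- simplex_key(edges_all)
  edge_tris <- split(rep(seq_len(nF), 3),
                     c(simplex_key(tri_mat[, c(1, 2), drop = FALSE]),
                       simplex_key(tri_mat[, c(1, 3), drop = FALSE]),
                       simplex_key(tri_mat[, c(2, 3), drop = FALSE])))
  rim_of_edge <- list()
  nE_dual <- nF
  rim_verts <- list()
  for (k in edge_keys) {
    btris <- intersect(edge_tris[[k]], boundary_tri)
    if (length(btris) == 0) next
    if (length(btris) != 2)
      stop("non-manifold tissue boundary at adjacency edge ", k)
    nE_dual <- nE_dual + 1L
    rim_of_edge[[k]] <- nE_dual
    rim_verts[[length(rim_verts) + 1]] <-
      as.integer(nT + b_index[tri_keys[btris]])
    e_bnd[[nE_dual]] <- rim_verts[[length(rim_verts)]]
  }

  # --- dual faces: one per primal edge, plus caps per surface cell ----
  f_bnd <- list()
  lab1 <- integer(0); lab2 <- integer(0)
  for (i in seq_along(edge_keys)) {
    k <- edge_keys[i]
    bd <- as.integer(edge_tris[[k]])
    if (!is.null(rim_of_edge[[k]])) bd <- c(bd, rim_of_edge[[k]])
    f_bnd[[length(f_bnd) + 1]] <- bd
    lab1 <- c(lab1, edges_all[i, 1]); lab2 <- c(lab2, edges_all[i, 2])
  }
  face_of_edge <- stats::setNames(seq_along(edge_keys), edge_keys)
  surface_cells <- sort(unique(as.vector(tri_mat[boundary_tri, ])))
  cap_of_cell <- list()
  for (v in surface_cells) {
    bkeys <- edge_keys[vapply(strsplit(edge_keys, "-", fixed = TRUE),
                              function(p) v %in% as.integer(p), logical(1))]
    rims <- unlist(rim_of_edge[bkeys])
    if (length(rims) < 3)
      stop("surface cell ", v, " has a degenerate boundary cap")
    f_bnd[[length(f_bnd) + 1]] <- as.integer(rims)
    lab1 <- c(lab1, 0L); lab2 <- c(lab2, v)
    cap_of_cell[[as.character(v)]] <- length(f_bnd)
  }

  # --- dual cells: one per primal vertex ------------------------------
  c_bnd <- list()
  for (v in labs) {
    vkeys <- edge_keys[vapply(strsplit(edge_keys, "-", fixed = TRUE),
                              function(p) v %in% as.integer(p), logical(1))]
    bd <- as.integer(face_of_edge[vkeys])
    if (!is.null(cap_of_cell[[as.character(v)]]))
      bd <- c(bd, cap_of_cell[[as.character(v)]])
    c_bnd[[as.character(v)]] <- bd
  }

  ids <- list(seq_len(nT + nB), seq_len(nE_dual), seq_along(f_bnd),
              as.integer(labs))
  rownames(vpos) <- ids[[1]]
  # incident cell label set of every dual vertex (4 cells at interior
  # corners, 3 cells + background 0 at surface corners)
  vcells <- c(lapply(seq_len(nT), function(t) sort(tets[t, ])),
              lapply(boundary_tri, function(f)
                c(0L, sort(tri_mat[f, ]))))
  cx <- incidence_complex(
    ids = ids,
    bnd = list(stats::setNames(e_bnd, as.character(seq_len(nE_dual))),
               stats::setNames(f_bnd, as.character(seq_along(f_bnd))),
               stats::setNames(c_bnd, as.character(labs))),
    positions = vpos,
    properties = list(
      "0" = list(surface = stats::setNames(c(rep(FALSE, nT), rep(TRUE, nB)),
                                           ids[[1]]),
                 cells = stats::setNames(vcells, ids[[1]])),
      "2" = list(label1 = stats::setNames(lab1, seq_along(f_bnd)),
                 label2 = stats::setNames(lab2, seq_along(f_bnd)))))
  class(cx) <- c("cell_complex", class(cx))
  cx
}

circumcircle_center <- function(tri) {
  # centre of the circle through three points in 3-space
  a <- tri[1, ]; b <- tri[2, ]; c <- tri[3, ]
  ab <- b - a; ac <- c - a
  n <- crossv(ab, ac)
  n2 <- sum(n^2)
  if (n2 < 1e-24) return(colMeans(tri))
  ab2 <- sum(ab^2); ac2 <- sum(ac^2)
  a + crossv(ab2 * ac - ac2 * ab, n) / (2 * n2)
}
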