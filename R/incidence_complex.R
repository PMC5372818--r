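#' Incidence-graph representation of cellular complexes
#'
#' A cellular complex of top dimension up to 3 (vertices, edges, faces,
#' 3-cells) stored as an incidence graph: every element is a node identified
#' by its dimension and an integer id, and boundary links connect elements of
#' consecutive dimensions only. The same structure represents triangular
#' tissue meshes, polyhedral cell complexes and simplicial adjacency
#' complexes; the adjacency complex of a tissue is the dual of its geometry
#' complex and dualization is a pure graph flip (see [dualize()]).
#'
#' @param ids list of 4 integer vectors: element ids per dimension 0..3
#'   (unused dimensions may be empty). Ids are opaque; they need only be
#'   unique within their dimension.
#' @param bnd list of 3 named lists; `bnd[[d]]` maps the id (as character) of
#'   each d-cell to the integer ids of its (d-1)-dimensional boundary
#'   elements.
#' @param positions optional numeric matrix (one row per 0-cell, rownames =
#'   ids, 3 columns) of vertex coordinates in micrometres. Pure-topology
#'   complexes may omit it.
#' @param properties optional nested list `properties[[as.character(dim)]][[name]]`
#'   of named per-element value vectors, so that e.g. "volume" on 3-cells and
#'   "area" on 2-cells coexist.
#' @return an object of class `incidence_complex`.
#' @export
incidence_complex <- function(ids, bnd, positions = NULL, properties = list()) {
  stopifnot(length(ids) == 4, length(bnd) == 3)
  ids <- lapply(ids, as.integer)
  for (d in 1:3) {
    if (length(ids[[d + 1]]) > 0) {
      stopifnot(!is.null(names(bnd[[d]])),
                setequal(names(bnd[[d]]), as.character(ids[[d + 1]])))
    }
  }
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    stopifnot(ncol(positions) == 3, !is.null(rownames(positions)))
  }
  structure(list(ids = ids, bnd = bnd, positions = positions,
                 properties = properties),
            class = "incidence_complex")
}

#' @export
print.incidence_complex <- function(x, ...) {
  n <- vapply(x$ids, length, integer(1))
  cat(sprintf("<incidence_complex> %d vertices, %d edges, %d faces, %d 3-cells\n",
              n[1], n[2], n[3], n[4]))
  if (!is.null(x$positions)) cat("  with vertex positions (um)\n")
  invisible(x)
}

#' Number of elements per dimension
#' @param complex an `incidence_complex`
#' @return integer vector of length 4 (counts for dimensions 0..3)
#' @export
element_counts <- function(complex) {
  vapply(complex$ids, length, integer(1))
}

top_dimension <- function(complex) {
  n <- element_counts(complex)
  max(c(0L, which(n > 0) - 1L))
}

#' Boundary, coboundary and same-dimension neighbours of an element
#'
#' `boundary_of()` returns the ids of the incident elements one dimension
#' down, `coboundary_of()` one dimension up, and `neighbors_of()` the
#' same-dimension elements sharing at least one boundary element. All three
#' have set semantics: the result is a sorted integer vector.
#'
#' @param complex an `incidence_complex`
#' @param dim dimension of the query element (0..3)
#' @param id element id
#' @return sorted integer vector of element ids
#' @export
boundary_of <- function(complex, dim, id) {
  check_element(complex, dim, id)
  if (dim == 0) return(integer(0))
  sort(unique(complex$bnd[[dim]][[as.character(id)]]))
}

#' @rdname boundary_of
#' @export
coboundary_of <- function(complex, dim, id) {
  check_element(complex, dim, id)
  if (dim >= 3 || length(complex$ids[[dim + 2]]) == 0) return(integer(0))
  up <- complex$bnd[[dim + 1]]
  hit <- vapply(up, function(b) any(b == id), logical(1))
  sort(as.integer(names(up)[hit]))
}

#' @rdname boundary_of
#' @export
neighbors_of <- function(complex, dim, id) {
  check_element(complex, dim, id)
  if (dim == 0) {
    # vertices are neighbours when they share an edge
    cob <- coboundary_of(complex, 0, id)
    nb <- unlist(lapply(cob, function(e) boundary_of(complex, 1, e)))
  } else {
    bd <- boundary_of(complex, dim, id)
    nb <- unlist(lapply(bd, function(b) coboundary_of(complex, dim - 1, b)))
  }
  sort(setdiff(unique(as.integer(nb)), id))
}

check_element <- function(complex, dim, id) {
  if (dim < 0 || dim > 3 || !(id %in% complex$ids[[dim + 1]]))
    stop(sprintf("no element of dimension %d with id %s in complex", dim, id))
  invisible(TRUE)
}

#' Structural validation of an incidence complex
#'
#' Checks the incidence-graph invariants: boundary links only between
#' consecutive dimensions referencing existing elements (the cellular-complex
#' axiom that the boundary of every n-cell lies in the complex), every edge
#' incident to exactly two distinct vertices, every triangle of a triangular
#' complex incident to exactly three edges, every tetrahedron of a simplicial
#' complex incident to exactly four faces, and no dangling n-cell (n >= 1)
#' with an empty boundary.
#'
#' Complexes with a topological boundary that have been dualized may carry
#' "infinite interface" edges incident to a single vertex (the dual of a
#' boundary triangle); set `strict = FALSE` to allow these and check only the
#' structural axioms (existing references, no dangling elements).
#'
#' @param complex an `incidence_complex`
#' @param simplicial if `TRUE`, additionally require 3 boundary edges per
#'   2-cell and 4 boundary faces per 3-cell.
#' @param strict enforce the cardinality invariants (2 vertices per edge)?
#' @return a data.frame with columns `dimension`, `id`, `problem`; zero rows
#'   iff the complex is valid.
#' @export
validate_complex <- function(complex, simplicial = FALSE, strict = TRUE) {
  bad <- list()
  note <- function(dim, id, problem)
    bad[[length(bad) + 1]] <<- data.frame(dimension = dim, id = id,
                                          problem = problem)
  for (d in 1:3) {
    ids_d <- complex$ids[[d + 1]]
    if (length(ids_d) == 0) next
    lower <- complex$ids[[d]]
    for (id in ids_d) {
      b <- complex$bnd[[d]][[as.character(id)]]
      if (length(b) == 0) note(d, id, "empty boundary (dangling element)")
      if (!all(b %in% lower))
        note(d, id, "boundary references missing lower-dimensional element")
      if (strict && d == 1 && length(unique(b)) != 2)
        note(d, id, "edge not incident to exactly two distinct vertices")
      if (simplicial && d == 2 && length(unique(b)) != 3)
        note(d, id, "triangle not incident to exactly three edges")
      if (simplicial && d == 3 && length(unique(b)) != 4)
        note(d, id, "tetrahedron not incident to exactly four faces")
    }
  }
  if (length(bad) == 0)
    data.frame(dimension = integer(0), id = integer(0),
               problem = character(0))
  else do.call(rbind, bad)
}

#' Dualize an incidence complex by flipping its incidence graph
#'
#' Duality exchanges dimensions: every n-cell becomes a (top_dim - n)-cell of
#' the dual and all boundary links are reversed, so that tissue cells map to
#' adjacency vertices, cell interfaces to adjacency edges, interface edges to
#' adjacency triangles and cell corners to adjacency tetrahedra (and back).
#' Element ids are reused, so the returned dual map is the identity on ids;
#' it is still recorded explicitly for API stability. The dual carries no
#' vertex positions: dual geometry is assigned separately (see
#' [dual_geometry()]).
#'
#' @param complex a valid `incidence_complex`
#' @param top_dim top dimension of the complex (2 or 3)
#' @return a list with components `complex` (the dual `incidence_complex`)
#'   and `dual_map` (data.frame `dimension`, `id`, `dual_dimension`,
#'   `dual_id`).
#' @export
dualize <- function(complex, top_dim = top_dimension(complex)) {
  rep_ok <- validate_complex(complex, strict = FALSE)
  if (nrow(rep_ok) > 0)
    stop(sprintf("invalid complex: %s (dimension %d, id %d)",
                 rep_ok$problem[1], rep_ok$dimension[1], rep_ok$id[1]))
  stopifnot(top_dim %in% 2:3)
  dual_ids <- vector("list", 4)
  for (n in 0:3) dual_ids[[n + 1]] <- integer(0)
  for (n in 0:top_dim) dual_ids[[top_dim - n + 1]] <- complex$ids[[n + 1]]
  dual_bnd <- rep(list(list()), 3)
  # dual d'-cells come from primal (top_dim - d')-cells; their dual boundary
  # is the primal coboundary, obtained by inverting each incidence relation
  for (dp in 1:top_dim) {
    n <- top_dim - dp                       # primal dimension of dual dp-cells
    up <- complex$bnd[[n + 1]]              # primal (n+1)-cells -> n-cells
    inv <- invert_incidence(up, complex$ids[[n + 1]])
    dual_bnd[[dp]] <- inv
  }
  dm <- do.call(rbind, lapply(0:top_dim, function(n) {
    ids_n <- complex$ids[[n + 1]]
    if (length(ids_n) == 0) return(NULL)
    data.frame(dimension = n, id = ids_n, dual_dimension = top_dim - n,
               dual_id = ids_n)
  }))
  list(complex = incidence_complex(dual_ids, dual_bnd), dual_map = dm)
}

invert_incidence <- function(bnd_list, lower_ids) {
  # bnd_list: named list upper id -> lower ids; returns lower id -> upper ids
  if (length(bnd_list) == 0)
    return(stats::setNames(rep(list(integer(0)), length(lower_ids)),
                           as.character(lower_ids)))
  upper <- rep(as.integer(names(bnd_list)), lengths(bnd_list))
  lower <- unlist(bnd_list, use.names = FALSE)
  out <- split(upper, factor(as.character(lower), levels = as.character(lower_ids)))
  lapply(out, as.integer)
}

#' Test whether two complexes are isomorphic under an id-preserving map
#'
#' Used to check that dualization is an involution: dualizing twice must give
#' back a complex with identical element ids and identical boundary sets.
#'
#' @param a,b `incidence_complex` objects
#' @return logical
#' @export
complex_identical_structure <- function(a, b) {
  for (d in 0:3) {
    if (!setequal(a$ids[[d + 1]], b$ids[[d + 1]])) return(FALSE)
  }
  for (d in 1:3) {
    for (id in as.character(a$ids[[d + 1]])) {
      if (!setequal(a$bnd[[d]][[id]], b$bnd[[d]][[id]])) return(FALSE)
    }
  }
  TRUE
}

#' Build a simplicial 3-complex from a tetrahedron list
#'
#' Vertices are identified by arbitrary integer labels (typically tissue cell
#' labels); edges, triangles and tetrahedra get consecutive ids. All faces of
#' every simplex are included, so the result satisfies the cellular-complex
#' closure axiom by construction.
#'
#' @param tets integer matrix (n x 4) of vertex labels, one tetrahedron per row
#' @param positions optional matrix of vertex coordinates with rownames =
#'   vertex labels
#' @return an `incidence_complex` with an attribute `simplices` holding the
#'   vertex-label matrices of edges (n x 2), triangles (n x 3) and tetrahedra
#'   (n x 4), rows ordered by element id.
#' @export
simplicial_from_tets <- function(tets, positions = NULL) {
  tets <- matrix(as.integer(tets), ncol = 4)
  tets <- t(apply(tets, 1, sort))
  tets <- unique(tets)
  tris <- unique(rbind(tets[, c(1, 2, 3), drop = FALSE],
                       tets[, c(1, 2, 4), drop = FALSE],
                       tets[, c(1, 3, 4), drop = FALSE],
                       tets[, c(2, 3, 4), drop = FALSE]))
  edges <- unique(rbind(tris[, c(1, 2), drop = FALSE],
                        tris[, c(1, 3), drop = FALSE],
                        tris[, c(2, 3), drop = FALSE]))
  simplicial_from_parts(edges, tris, tets, positions)
}

#' Build a simplicial complex from explicit simplex tables
#'
#' Lower-dimensional faces implied by higher simplices are added
#' automatically. Pass `tets = NULL` for a pure triangulated surface complex.
#'
#' @param edges,tris,tets vertex-label matrices (2/3/4 columns) or NULL
#' @param positions optional vertex coordinate matrix (rownames = labels)
#' @return an `incidence_complex` (see [simplicial_from_tets()])
#' @export
simplicial_from_parts <- function(edges = NULL, tris = NULL, tets = NULL,
                                  positions = NULL) {
  norm <- function(m, k) {
    if (is.null(m) || nrow(m) == 0) return(matrix(integer(0), ncol = k))
    unique(t(apply(matrix(as.integer(m), ncol = k), 1, sort)))
  }
  tets <- norm(tets, 4)
  tris <- norm(rbind(tris,
                     if (nrow(tets)) rbind(tets[, c(1, 2, 3), drop = FALSE],
                                           tets[, c(1, 2, 4), drop = FALSE],
                                           tets[, c(1, 3, 4), drop = FALSE],
                                           tets[, c(2, 3, 4), drop = FALSE])),
               3)
  edges <- norm(rbind(edges,
                      if (nrow(tris)) rbind(tris[, c(1, 2), drop = FALSE],
                                            tris[, c(1, 3), drop = FALSE],
                                            tris[, c(2, 3), drop = FALSE])),
                2)
  verts <- sort(unique(c(edges, tris, tets)))
  ekey <- simplex_key(edges)
  fkey <- simplex_key(tris)
  bnd1 <- stats::setNames(lapply(seq_len(nrow(edges)), function(i)
    edges[i, ]), as.character(seq_len(nrow(edges))))
  bnd2 <- stats::setNames(lapply(seq_len(nrow(tris)), function(i) {
    tr <- tris[i, ]
    as.integer(match(simplex_key(rbind(tr[c(1, 2)], tr[c(1, 3)], tr[c(2, 3)])),
                     ekey))
  }), as.character(seq_len(nrow(tris))))
  bnd3 <- stats::setNames(lapply(seq_len(nrow(tets)), function(i) {
    tt <- tets[i, ]
    as.integer(match(simplex_key(rbind(tt[c(1, 2, 3)], tt[c(1, 2, 4)],
                                       tt[c(1, 3, 4)], tt[c(2, 3, 4)])),
                     fkey))
  }), as.character(seq_len(nrow(tets))))
  if (!is.null(positions)) {
    positions <- as.matrix(positions)[as.character(verts), , drop = FALSE]
  }
  cx <- incidence_complex(
    ids = list(verts, seq_len(nrow(edges)), seq_len(nrow(tris)),
               seq_len(nrow(tets))),
    bnd = list(bnd1, bnd2, bnd3),
    positions = positions)
  attr(cx, "simplices") <- list(edges = edges, tris = tris, tets = tets)
  cx
}

simplex_key <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(character(0))
  apply(m, 1, function(r) paste(sort(r), collapse = "-"))
}

#' Vertex-label matrix of the simplices of a simplicial complex
#' @param complex an `incidence_complex` built by [simplicial_from_tets()] or
#'   [simplicial_from_parts()]
#' @param dim simplex dimension (1, 2 or 3)
#' @return integer matrix, rows ordered by element id
#' @export
complex_simplices <- function(complex, dim) {
  s <- attr(complex, "simplices")
  if (is.null(s)) stop("complex does not carry simplex tables")
  switch(dim, s$edges, s$tris, s$tets)
}
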