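#' Energy weights for adjacency complex optimization
#'
#' The adjacency complex is scored by a three-term energy: an image term
#' (mismatch with the adjacencies extracted from the segmented image), a
#' prior term (deviation of per-cell neighbour counts from the expected
#' count for tissue cells) and a regularity term (tetrahedron elongation,
#' preventing distant cells from ending up as neighbours). Each component is
#' weighted so its relative influence can be tuned.
#'
#' @param w_image,w_prior,w_regularity nonnegative weights; the image term
#'   dominates by default
#' @param target_neighbors expected neighbour count of an interior cell
#'   (around 13-14 for space-filling polyhedral tissue)
#' @return list of class `energy_weights`
#' @export
energy_weights <- function(w_image = 1.0, w_prior = 0.1,
                           w_regularity = 0.1, target_neighbors = 13.2) {
  stopifnot(w_image >= 0, w_prior >= 0, w_regularity >= 0)
  structure(list(w_image = w_image, w_prior = w_prior,
                 w_regularity = w_regularity,
                 target_neighbors = target_neighbors),
            class = "energy_weights")
}

#' Simulated annealing schedule
#'
#' Successive temperature cycles: each cycle starts hot (allowing
#' non-optimal transformations to escape local minima) and cools
#' geometrically; a final zero-temperature quench from the best state seen
#' guarantees the returned energy never exceeds the initial one. With
#' `t_start = NULL` the starting temperature is calibrated from the energy
#' scale of the problem (twice the mean absolute energy change of a probe of
#' random candidate moves), so that early sweeps accept most moves and late
#' sweeps almost none.
#'
#' @param t_start starting temperature of each cycle, or NULL to calibrate
#' @param t_end final temperature (> 0)
#' @param cycles number of reheating cycles
#' @param steps_per_cycle sweeps per cycle (one proposed move per element
#'   and sweep)
#' @param cooling_factor geometric cooling per sweep, in (0, 1)
#' @param rng_seed integer seed; runs are deterministic given the seed
#' @return list of class `annealing_schedule`
#' @export
annealing_schedule <- function(t_start = NULL, t_end = NULL, cycles = 3,
                               steps_per_cycle = 30, cooling_factor = 0.85,
                               rng_seed = 1) {
  stopifnot(cycles >= 1, steps_per_cycle >= 1,
            cooling_factor > 0, cooling_factor < 1)
  if (!is.null(t_start) && !is.null(t_end)) stopifnot(t_start > t_end, t_end > 0)
  structure(list(t_start = t_start, t_end = t_end, cycles = cycles,
                 steps_per_cycle = steps_per_cycle,
                 cooling_factor = cooling_factor,
                 rng_seed = as.integer(rng_seed)),
            class = "annealing_schedule")
}

#' Adjacency energy of a simplicial complex against image adjacencies
#'
#' `e_image` measures how far the complex is from the adjacency simplices
#' extracted from the segmented image: the mean of the normalized symmetric
#' differences of the edge sets (complex edges against non-background image
#' adjacency pairs) and of the tetrahedron sets (complex tetrahedra against
#' image corner quadruples), so that a complex containing exactly the
#' image-extracted simplices has zero image energy. `e_prior` is the mean
#' squared relative deviation of per-vertex neighbour counts from the target
#' count. `e_regularity` is the mean tetrahedron elongation (max edge / min
#' edge - 1). The total is the weighted sum.
#'
#' @param complex simplicial `incidence_complex` with vertex ids equal to
#'   cell labels present in the image
#' @param adj an `image_adjacencies`
#' @param w an `energy_weights`
#' @return list of class `energy_breakdown` with `e_image`, `e_prior`,
#'   `e_regularity`, `total`
#' @export
adjacency_energy <- function(complex, adj, w = energy_weights()) {
  labs <- complex$ids[[1]]
  img_labels <- as.integer(rownames(adj$barycenters))
  if (!all(labs %in% img_labels))
    stop("complex vertex not present in the image: ",
         paste(setdiff(labs, img_labels), collapse = ", "))
  edges <- complex_simplices(complex, 1)
  tets <- complex_simplices(complex, 3)
  pos <- complex$positions
  breakdown_from_parts(edges, tets, pos, labs, adj, w)
}

breakdown_from_parts <- function(edges, tets, pos, labs, adj, w) {
  img_keys <- simplex_key(adjacency_edges(adj, include_background = FALSE))
  t_keys <- simplex_key(edges)
  n_img <- length(img_keys)
  e_edge <- (sum(!(t_keys %in% img_keys)) + sum(!(img_keys %in% t_keys))) /
    max(1, n_img)
  qimg <- image_cell_quads(adj)
  qi_keys <- simplex_key(qimg)
  tt_keys <- simplex_key(tets)
  e_quad <- if (length(qi_keys) == 0) 0 else
    (sum(!(tt_keys %in% qi_keys)) + sum(!(qi_keys %in% tt_keys))) /
    length(qi_keys)
  si_keys <- image_surface_triples(adj)
  bt_keys <- boundary_triple_keys(tets)
  e_surf <- if (length(si_keys) == 0) 0 else
    (sum(!(bt_keys %in% si_keys)) + sum(!(si_keys %in% bt_keys))) /
    length(si_keys)
  e_image <- (e_edge + e_quad + e_surf) / 3
  deg <- degree_from_edges(edges, labs)
  e_prior <- mean(((deg - w$target_neighbors) / w$target_neighbors)^2)
  e_reg <- if (nrow(tets) == 0) 0 else
    mean(apply(tets, 1, function(t) tet_elongation(pos[as.character(t), ])))
  total <- w$w_image * e_image + w$w_prior * e_prior +
    w$w_regularity * e_reg
  structure(list(e_image = e_image, e_prior = e_prior, e_regularity = e_reg,
                 total = total), class = "energy_breakdown")
}

image_cell_quads <- function(adj) {
  quads <- adj$tetrahedra
  if (is.null(quads) || nrow(quads) == 0) return(matrix(integer(0), 0, 4))
  quads[rowSums(quads == adj$background_label) == 0, , drop = FALSE]
}

image_surface_triples <- function(adj) {
  # cell triples observed as surface corners (three cells + background)
  quads <- adj$tetrahedra
  if (is.null(quads) || nrow(quads) == 0) return(character(0))
  bg <- adj$background_label
  surf <- quads[rowSums(quads == bg) == 1, , drop = FALSE]
  if (nrow(surf) == 0) return(character(0))
  unique(vapply(seq_len(nrow(surf)), function(i)
    paste(sort(setdiff(surf[i, ], bg)), collapse = "-"), character(1)))
}

boundary_triple_keys <- function(tets) {
  fk <- tet_face_keys(tets)
  tb <- table(fk)
  names(tb)[tb == 1]
}

degree_from_edges <- function(edges, labs) {
  deg <- stats::setNames(rep(0L, length(labs)), labs)
  if (nrow(edges) > 0) {
    tb <- table(factor(as.character(c(edges[, 1], edges[, 2])),
                       levels = as.character(labs)))
    deg[] <- as.integer(tb)
  }
  deg
}

tet_elongation <- function(tet) {
  el <- tet_edge_lengths(matrix(tet, 4, 3))
  max(el) / min(el) - 1
}

#' Remove misleading exterior tetrahedra from a Delaunay adjacency complex
#'
#' The convexity of the Delaunay complex creates exterior tetrahedra that do
#' not correspond to tissue structure: tetrahedra bridging a concave part of
#' the tissue surface through the background, tetrahedra with overly long
#' edges, and flat slivers. These are peeled off iteratively from the
#' complex boundary until stable.
#'
#' A boundary tetrahedron (one with a face not shared by two tetrahedra) is
#' removed when (a) it links two cells that are not adjacent in the image
#' and whose barycenter segment crosses background voxels, (b) one of its
#' edges exceeds `max_edge_factor` times the median edge length of the
#' initial complex, or (c) it is a sliver (minimal dihedral angle below
#' `sliver_min_dihedral` degrees or circumradius/shortest-edge ratio above
#' `sliver_radius_edge`).
#'
#' @param complex simplicial `incidence_complex` (typically Delaunay)
#' @param adj `image_adjacencies` extracted from the same image
#' @param max_edge_factor long-edge threshold (default 3 medians)
#' @param sliver_min_dihedral degrees (default 5)
#' @param sliver_radius_edge radius-edge ratio threshold (default 4)
#' @return the cleaned simplicial `incidence_complex`
#' @export
clean_exterior <- function(complex, adj, max_edge_factor = 3,
                           sliver_min_dihedral = 5, sliver_radius_edge = 4) {
  pos <- complex$positions
  edges <- complex_simplices(complex, 1)
  med <- stats::median(sqrt(rowSums((pos[as.character(edges[, 1]), , drop = FALSE] -
                                       pos[as.character(edges[, 2]), , drop = FALSE])^2)))
  img_keys <- simplex_key(adjacency_edges(adj, include_background = FALSE))
  st <- adj_state_init(complex, adj, energy_weights())
  st$enforce_surface_boundary <- FALSE   # peeling must reach the tissue shape
  no_add <- matrix(integer(0), 0, 4)
  offending <- function(t) {
    tt <- st$tets[t, ]
    tp <- pos[as.character(tt), ]
    if (max(tet_edge_lengths(tp)) > max_edge_factor * med) return(TRUE)
    if (tet_min_dihedral(tp) < sliver_min_dihedral ||
        tet_radius_edge_ratio(tp) > sliver_radius_edge) return(TRUE)
    prs <- utils::combn(sort(tt), 2)
    for (cidx in seq_len(ncol(prs))) {
      pr <- prs[, cidx]
      if (paste(pr, collapse = "-") %in% img_keys) next
      if (segment_crosses_background(pos[as.character(pr[1]), ],
                                     pos[as.character(pr[2]), ], adj))
        return(TRUE)
    }
    FALSE
  }
  repeat {
    removed_any <- FALSE
    for (t in which(st$alive)) {
      if (!st$alive[t]) next
      tt <- st$tets[t, ]
      on_boundary <- any(vapply(simplex_key(tet_tris(tt)), function(k)
        st$tri_count[[k]] == 1L, logical(1)))
      if (!on_boundary) next
      if (!offending(t)) next
      if (st$n_alive <= 1L)
        stop("exterior cleaning removed every tetrahedron")
      # removal must keep the boundary surface an edge-manifold, or the
      # dual cells could not be closed; blocked removals are retried after
      # their neighbourhood has been peeled
      if (!move_valid(st, remove = t, add = no_add)) next
      state_apply_tets(st, t, no_add)
      removed_any <- TRUE
    }
    if (!removed_any) break
  }
  simplicial_from_tets(state_snapshot(st), positions = pos)
}

tet_face_keys <- function(tets) {
  simplex_key(rbind(tets[, c(1, 2, 3), drop = FALSE],
                    tets[, c(1, 2, 4), drop = FALSE],
                    tets[, c(1, 3, 4), drop = FALSE],
                    tets[, c(2, 3, 4), drop = FALSE]))
}

segment_crosses_background <- function(p, q, adj) {
  if (is.null(adj$background_mask)) return(FALSE)
  vs <- adj$voxel_size
  len <- sqrt(sum((q - p)^2))
  n <- max(2, ceiling(len / (0.5 * min(vs))))
  tt <- seq(0, 1, length.out = n)
  pts <- outer(1 - tt, p) + outer(tt, q)
  idx <- floor(sweep(pts, 2, vs, `/`)) + 1
  d <- dim(adj$background_mask)
  idx[, 1] <- pmin(pmax(idx[, 1], 1), d[1])
  idx[, 2] <- pmin(pmax(idx[, 2], 1), d[2])
  idx[, 3] <- pmin(pmax(idx[, 3], 1), d[3])
  any(adj$background_mask[idx])
}

# ---- annealed topological optimization --------------------------------

#' Optimize an adjacency complex against image adjacencies
#'
#' Minimizes the [adjacency_energy()] by simulated annealing over local
#' topological operations: 2-3 and 3-2 bistellar flips (triangle swaps) and
#' removal of an edge surrounded by its ring of tetrahedra (the cavity is
#' retetrahedrized as a fan, or as a bipyramid for boundary edges). Each
#' sweep proposes, besides random exploratory moves, targeted repairs: for
#' every image adjacency missing from the complex the flip that would create
#' it, and for every excess adjacency the removal of its edge. A move is
#' accepted with probability 1 when it lowers the energy and `exp(-dE/t)`
#' otherwise; moves that would break the simplicial-complex structure (a
#' triangle shared by more than two tetrahedra, a duplicate tetrahedron) are
#' filtered out. After the temperature cycles the best state seen is
#' restored and quenched at zero temperature, so the final energy never
#' exceeds the initial one. Deterministic given the schedule's seed.
#'
#' @param complex valid simplicial `incidence_complex` (typically the
#'   cleaned Delaunay complex)
#' @param adj an `image_adjacencies`
#' @param w an `energy_weights`
#' @param schedule an `annealing_schedule`
#' @return the optimized simplicial `incidence_complex`, with attribute
#'   `energy_log` (data.frame of per-sweep energies) and `energy`
#'   (final `energy_breakdown`)
#' @export
optimize_adjacency <- function(complex, adj, w = energy_weights(),
                               schedule = annealing_schedule()) {
  st <- adj_state_init(complex, adj, w)
  log <- with_seed(schedule$rng_seed, adj_anneal(st, schedule))
  out <- simplicial_from_tets(state_snapshot(st),
                              positions = complex$positions)
  attr(out, "energy_log") <- log
  attr(out, "energy") <- adjacency_energy(out, adj, w)
  out
}

adj_state_init <- function(complex, adj, w) {
  st <- new.env(parent = emptyenv())
  st$pos <- complex$positions
  st$w <- w
  st$tets <- complex_simplices(complex, 3)
  st$alive <- rep(TRUE, nrow(st$tets))
  st$labs <- complex$ids[[1]]
  st$img_keys <- simplex_key(adjacency_edges(adj, FALSE))
  st$n_img <- length(st$img_keys)
  # image-extracted candidate tetrahedra indexed by the cell pairs they link
  st$pair_quads <- new.env(parent = emptyenv())
  quads <- adj$tetrahedra
  st$img_quad_keys <- character(0)
  if (!is.null(quads) && nrow(quads) > 0) {
    quads <- quads[rowSums(quads == adj$background_label) == 0, , drop = FALSE]
    st$img_quad_keys <- simplex_key(quads)
    for (i in seq_len(nrow(quads))) {
      q <- quads[i, ]
      for (k in simplex_key(tet_edges6(q)))
        st$pair_quads[[k]] <- rbind(st$pair_quads[[k]], q)
    }
  }
  st$surface_cells <- adj$surface_cells
  # when set, moves may not expose interior cells on the complex boundary
  st$enforce_surface_boundary <- TRUE
  st$tri_count <- new.env(parent = emptyenv())
  st$edge_tets <- new.env(parent = emptyenv())   # edge key -> alive rows
  st$vert_tets <- new.env(parent = emptyenv())   # label -> alive rows
  st$tet_rows <- new.env(parent = emptyenv())    # tet key -> row
  st$deg <- stats::setNames(rep(0L, length(st$labs)), st$labs)
  st$n_match <- 0L; st$n_extra <- 0L
  st$n_qmatch <- 0L; st$n_qextra <- 0L
  st$n_img_quads <- length(st$img_quad_keys)
  st$img_surf_keys <- image_surface_triples(adj)
  st$n_img_surf <- length(st$img_surf_keys)
  st$n_smatch <- 0L; st$n_sextra <- 0L
  st$elong <- numeric(nrow(st$tets))
  st$sum_elong <- 0; st$n_alive <- 0L
  for (t in seq_len(nrow(st$tets))) state_add_tet_counts(st, t)
  st
}

tet_tris <- function(tt) {
  tt <- sort(tt)
  rbind(tt[c(1, 2, 3)], tt[c(1, 2, 4)], tt[c(1, 3, 4)], tt[c(2, 3, 4)])
}

tet_edges6 <- function(tt) {
  tt <- sort(tt)
  rbind(tt[c(1, 2)], tt[c(1, 3)], tt[c(1, 4)], tt[c(2, 3)], tt[c(2, 4)],
        tt[c(3, 4)])
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")

state_add_tet_counts <- function(st, t) {
  tt <- sort(st$tets[t, ])
  st$tets[t, ] <- tt
  for (k in simplex_key(tet_tris(tt))) {
    old <- if (is.null(st$tri_count[[k]])) 0L else st$tri_count[[k]]
    st$tri_count[[k]] <- old + 1L
    if (old == 1L) state_boundary_tri(st, k, -1L)
    if (old == 0L) state_boundary_tri(st, k, +1L)
  }
  e6 <- tet_edges6(tt)
  for (i in seq_len(6)) {
    k <- paste(e6[i, ], collapse = "-")
    rows <- st$edge_tets[[k]]
    if (is.null(rows) || length(rows) == 0) state_edge_appeared(st, e6[i, ], k)
    st$edge_tets[[k]] <- c(rows, t)
  }
  for (v in as.character(tt)) st$vert_tets[[v]] <- c(st$vert_tets[[v]], t)
  tk <- paste(tt, collapse = "-")
  st$tet_rows[[tk]] <- t
  if (tk %in% st$img_quad_keys) st$n_qmatch <- st$n_qmatch + 1L
  else st$n_qextra <- st$n_qextra + 1L
  st$elong[t] <- tet_elongation(st$pos[as.character(tt), ])
  st$sum_elong <- st$sum_elong + st$elong[t]
  st$n_alive <- st$n_alive + 1L
}

state_boundary_tri <- function(st, k, by) {
  # a triangle entered (+1) or left (-1) the complex boundary
  if (st$n_img_surf == 0) return(invisible(NULL))
  if (k %in% st$img_surf_keys) st$n_smatch <- st$n_smatch + by
  else st$n_sextra <- st$n_sextra + by
}

state_remove_tet_counts <- function(st, t) {
  tt <- st$tets[t, ]
  for (k in simplex_key(tet_tris(tt))) {
    old <- st$tri_count[[k]]
    st$tri_count[[k]] <- old - 1L
    if (old == 2L) state_boundary_tri(st, k, +1L)
    if (old == 1L) state_boundary_tri(st, k, -1L)
  }
  e6 <- tet_edges6(tt)
  for (i in seq_len(6)) {
    k <- paste(e6[i, ], collapse = "-")
    rows <- setdiff(st$edge_tets[[k]], t)
    st$edge_tets[[k]] <- rows
    if (length(rows) == 0) state_edge_vanished(st, e6[i, ], k)
  }
  for (v in as.character(tt))
    st$vert_tets[[v]] <- setdiff(st$vert_tets[[v]], t)
  tk <- paste(tt, collapse = "-")
  rm(list = tk, envir = st$tet_rows)
  if (tk %in% st$img_quad_keys) st$n_qmatch <- st$n_qmatch - 1L
  else st$n_qextra <- st$n_qextra - 1L
  st$sum_elong <- st$sum_elong - st$elong[t]
  st$n_alive <- st$n_alive - 1L
}

state_edge_appeared <- function(st, e, k) {
  st$deg[as.character(e)] <- st$deg[as.character(e)] + 1L
  if (k %in% st$img_keys) st$n_match <- st$n_match + 1L
  else st$n_extra <- st$n_extra + 1L
}

state_edge_vanished <- function(st, e, k) {
  st$deg[as.character(e)] <- st$deg[as.character(e)] - 1L
  if (k %in% st$img_keys) st$n_match <- st$n_match - 1L
  else st$n_extra <- st$n_extra - 1L
}

state_energy <- function(st) {
  w <- st$w
  e_edge <- (st$n_img - st$n_match + st$n_extra) / max(1, st$n_img)
  e_quad <- if (st$n_img_quads == 0) 0 else
    (st$n_img_quads - st$n_qmatch + st$n_qextra) / st$n_img_quads
  e_surf <- if (st$n_img_surf == 0) 0 else
    (st$n_img_surf - st$n_smatch + st$n_sextra) / st$n_img_surf
  e_image <- (e_edge + e_quad + e_surf) / 3
  e_prior <- mean(((st$deg - w$target_neighbors) / w$target_neighbors)^2)
  e_reg <- if (st$n_alive == 0) 0 else st$sum_elong / st$n_alive
  w$w_image * e_image + w$w_prior * e_prior + w$w_regularity * e_reg
}

state_snapshot <- function(st) {
  tt <- st$tets[st$alive, , drop = FALSE]
  tt[order(tt[, 1], tt[, 2], tt[, 3], tt[, 4]), , drop = FALSE]
}

state_restore <- function(st, tets) {
  for (t in which(st$alive)) {
    state_remove_tet_counts(st, t)
    st$alive[t] <- FALSE
  }
  st$tets <- tets
  st$alive <- rep(TRUE, nrow(tets))
  st$elong <- numeric(nrow(tets))
  for (t in seq_len(nrow(tets))) state_add_tet_counts(st, t)
}

state_apply_tets <- function(st, remove_rows, add_tets) {
  for (t in remove_rows) {
    state_remove_tet_counts(st, t)
    st$alive[t] <- FALSE
  }
  new_rows <- integer(nrow(add_tets))
  free <- which(!st$alive)
  fi <- 1
  for (i in seq_len(nrow(add_tets))) {
    if (fi <= length(free)) {
      r <- free[fi]; fi <- fi + 1
      st$tets[r, ] <- add_tets[i, ]
    } else {
      st$tets <- rbind(st$tets, add_tets[i, ])
      st$elong <- c(st$elong, 0)
      st$alive <- c(st$alive, FALSE)
      r <- nrow(st$tets)
    }
    st$alive[r] <- TRUE
    new_rows[i] <- r
    state_add_tet_counts(st, r)
  }
  new_rows
}

state_try_move <- function(st, mv, temp, e_cur) {
  # returns the new current energy (unchanged if rejected)
  removed <- st$tets[mv$remove, , drop = FALSE]
  new_rows <- state_apply_tets(st, mv$remove, mv$add)
  e_new <- state_energy(st)
  dE <- e_new - e_cur
  if (dE <= 0 || (temp > 0 && stats::runif(1) < exp(-dE / temp)))
    return(e_new)
  state_apply_tets(st, new_rows, removed)
  e_cur
}

adj_anneal <- function(st, schedule) {
  e_cur <- state_energy(st)
  e_init <- e_cur
  best <- state_snapshot(st); e_best <- e_cur
  t_start <- schedule$t_start
  if (is.null(t_start)) t_start <- max(2 * probe_move_scale(st), 1e-8)
  t_end <- if (is.null(schedule$t_end)) t_start / 200 else schedule$t_end
  log <- list()
  note <- function(phase, sweep, temp, e)
    log[[length(log) + 1]] <<- data.frame(phase = phase, sweep = sweep,
                                          temperature = temp, energy = e)
  note("init", 0L, NA_real_, e_cur)
  sweep_no <- 0L
  for (cyc in seq_len(schedule$cycles)) {
    temp <- t_start
    for (s in seq_len(schedule$steps_per_cycle)) {
      e_cur <- adj_sweep(st, temp, e_cur)
      sweep_no <- sweep_no + 1L
      if (e_cur < e_best) { e_best <- e_cur; best <- state_snapshot(st) }
      note("anneal", sweep_no, temp, e_cur)
      temp <- max(temp * schedule$cooling_factor, t_end)
    }
  }
  # quench from the best state seen: zero temperature, descents only
  state_restore(st, best)
  e_cur <- state_energy(st)
  repeat {
    e_new <- adj_sweep(st, 0, e_cur)
    sweep_no <- sweep_no + 1L
    note("quench", sweep_no, 0, e_new)
    if (e_new >= e_cur - 1e-12) break
    e_cur <- e_new
  }
  stopifnot(e_cur <= e_init + 1e-9)
  do.call(rbind, log)
}

probe_move_scale <- function(st) {
  rows <- which(st$alive)
  rows <- rows[seq_len(min(40, length(rows)))]
  deltas <- c()
  e0 <- state_energy(st)
  for (t in rows) {
    if (!st$alive[t]) next
    mv <- propose_flip23(st, t, which_face = 1L)
    if (is.null(mv)) next
    removed <- st$tets[mv$remove, , drop = FALSE]
    new_rows <- state_apply_tets(st, mv$remove, mv$add)
    deltas <- c(deltas, abs(state_energy(st) - e0))
    state_apply_tets(st, new_rows, removed)   # undo
  }
  if (length(deltas) == 0) return(1e-4)
  stats::median(deltas)
}

adj_sweep <- function(st, temp, e_cur) {
  t_keys <- ls(st$edge_tets)
  t_keys <- t_keys[vapply(t_keys, function(k) length(st$edge_tets[[k]]) > 0,
                          logical(1))]
  extra <- setdiff(t_keys, st$img_keys)
  missing <- setdiff(st$img_keys, t_keys)
  # targeted repairs: remove excess adjacencies ...
  for (k in extra[sample.int(length(extra))]) {
    mv <- propose_remove_edge_key(st, k)
    if (!is.null(mv)) e_cur <- state_try_move(st, mv, temp, e_cur)
  }
  # ... and create missing ones
  for (k in missing[sample.int(length(missing))]) {
    mv <- propose_create_edge_key(st, k)
    if (!is.null(mv)) e_cur <- state_try_move(st, mv, temp, e_cur)
  }
  # include image-extracted tetrahedra not yet in the complex
  absent <- setdiff(st$img_quad_keys, ls(st$tet_rows))
  for (k in absent[sample.int(length(absent))]) {
    q <- matrix(as.integer(strsplit(k, "-", fixed = TRUE)[[1]]), 1, 4)
    if (!move_valid(st, remove = integer(0), add = q)) next
    e_cur <- state_try_move(st, list(remove = integer(0), add = q),
                            temp, e_cur)
  }
  # exploratory random moves
  rows <- which(st$alive)
  n_rand <- max(1L, length(rows) %/% 4L)
  for (t in rows[sample.int(length(rows), n_rand)]) {
    if (!st$alive[t]) next
    mv <- switch(sample.int(2L, 1L),
                 propose_flip23(st, t, sample.int(4L, 1L)),
                 propose_remove_edge_key(
                   st, paste(tet_edges6(st$tets[t, ])[sample.int(6L, 1L), ],
                             collapse = "-")))
    if (!is.null(mv)) e_cur <- state_try_move(st, mv, temp, e_cur)
  }
  e_cur
}

propose_flip23 <- function(st, t, which_face) {
  tt <- st$tets[t, ]
  tri <- tet_tris(tt)[which_face, ]
  k <- paste(tri, collapse = "-")
  if (is.null(st$tri_count[[k]]) || st$tri_count[[k]] != 2L) return(NULL)
  shared <- intersect(intersect(st$edge_tets[[edge_key(tri[1], tri[2])]],
                                st$edge_tets[[edge_key(tri[1], tri[3])]]),
                      st$edge_tets[[edge_key(tri[2], tri[3])]])
  shared <- shared[vapply(shared, function(r)
    sum(st$tets[r, ] %in% tri) == 3, logical(1))]
  other <- setdiff(shared, t)
  if (length(other) != 1) return(NULL)
  d <- setdiff(tt, tri)
  e <- setdiff(st$tets[other, ], tri)
  if (d == e) return(NULL)
  flip23_move(st, tri, d, e, c(t, other))
}

flip23_move <- function(st, tri, d, e, remove) {
  add <- rbind(sort(c(tri[1], tri[2], d, e)),
               sort(c(tri[1], tri[3], d, e)),
               sort(c(tri[2], tri[3], d, e)))
  if (!move_valid(st, remove = remove, add = add)) return(NULL)
  list(remove = remove, add = add)
}

propose_create_edge_key <- function(st, k) {
  # find a triangle tri with both tets tri+a and tri+b present, then 2-3 flip
  ab <- as.integer(strsplit(k, "-", fixed = TRUE)[[1]])
  a <- ab[1]; b <- ab[2]
  rows_a <- st$vert_tets[[as.character(a)]]
  if (is.null(rows_a)) return(NULL)
  for (t in rows_a) {
    tt <- st$tets[t, ]
    if (b %in% tt) next
    # the flip joins the apexes of two tets sharing the face opposite to a
    tri <- setdiff(tt, a)
    other_key <- paste(sort(c(tri, b)), collapse = "-")
    other <- st$tet_rows[[other_key]]
    if (is.null(other)) next
    mv <- flip23_move(st, sort(tri), a, b, c(t, other))
    if (!is.null(mv)) return(mv)
  }
  # no flip available: try inserting an image-extracted tetrahedron
  cand <- st$pair_quads[[k]]
  if (!is.null(cand)) {
    for (i in seq_len(nrow(cand))) {
      q <- matrix(sort(cand[i, ]), 1, 4)
      if (!is.null(st$tet_rows[[paste(q, collapse = "-")]])) next
      if (move_valid(st, remove = integer(0), add = q))
        return(list(remove = integer(0), add = q))
    }
  }
  NULL
}

propose_delete_tet <- function(st, t) {
  # deletion of a boundary tetrahedron that carries a non-image adjacency;
  # tetrahedra all of whose edges are image adjacencies represent plausible
  # corner structure and are never deleted (flips and edge removals are the
  # only moves that may rearrange them)
  tt <- st$tets[t, ]
  if (st$n_alive <= 1L) return(NULL)
  on_boundary <- any(vapply(simplex_key(tet_tris(tt)), function(k)
    st$tri_count[[k]] == 1L, logical(1)))
  if (!on_boundary) return(NULL)
  if (all(simplex_key(tet_edges6(tt)) %in% st$img_keys)) return(NULL)
  mv <- list(remove = t, add = matrix(integer(0), 0, 4))
  if (!move_valid(st, mv$remove, mv$add)) return(NULL)
  mv
}

propose_remove_edge_key <- function(st, k) {
  rows <- st$edge_tets[[k]]
  if (is.null(rows) || length(rows) == 0) return(NULL)
  e <- as.integer(strsplit(k, "-", fixed = TRUE)[[1]])
  if (length(rows) == 3) {
    mv <- propose_flip32_ring(st, e, rows)
    if (!is.null(mv)) return(mv)
  }
  link <- link_vertices(st, rows, e)
  if (!is.null(link)) {
    mv <- if (link$closed) propose_ring_removal(st, e, rows, link$cycle)
    else propose_boundary_edge_removal(st, e, rows, link$cycle)
    if (!is.null(mv)) return(mv)
  }
  # fall back to deleting one boundary tetrahedron carrying the edge
  for (t in rows) {
    mv <- propose_delete_tet(st, t)
    if (!is.null(mv)) return(mv)
  }
  NULL
}

propose_flip32_ring <- function(st, e, ring) {
  apexes <- unique(unlist(lapply(ring, function(r) setdiff(st$tets[r, ], e))))
  if (length(apexes) != 3) return(NULL)
  # only when the three tets really close around the edge
  lk <- link_vertices(st, ring, e)
  if (is.null(lk) || !lk$closed) return(NULL)
  add <- rbind(sort(c(apexes, e[1])), sort(c(apexes, e[2])))
  if (!move_valid(st, remove = ring, add = add)) return(NULL)
  list(remove = ring, add = add)
}

propose_ring_removal <- function(st, e, ring, cyc) {
  m <- length(cyc)
  if (m < 4) return(NULL)
  for (shift in 0:(m - 1)) {
    link <- c(cyc[(shift %% m) + 1], cyc[((seq_len(m - 1) + shift - 1) %% m) + 1])
    a <- 1
    fan <- lapply(2:(m - 1), function(i) c(link[1], link[i], link[i + 1]))
    add <- do.call(rbind, lapply(fan, function(tr)
      rbind(sort(c(tr, e[1])), sort(c(tr, e[2])))))
    if (anyDuplicated(add)) next
    if (!move_valid(st, remove = ring, add = add)) next
    return(list(remove = ring, add = add))
  }
  NULL
}

propose_boundary_edge_removal <- function(st, e, rows, path) {
  m <- length(path)
  if (m < 3) return(NULL)
  # fill the cavity with the bipyramid over the link path
  for (a in seq_len(m)) {
    fan <- list()
    for (i in seq_len(m - 1)) {
      tr <- c(path[a], path[i], path[i + 1])
      if (length(unique(tr)) != 3) next
      fan[[length(fan) + 1]] <- tr
    }
    if (length(fan) != m - 2) next
    add <- do.call(rbind, lapply(fan, function(tr)
      rbind(sort(c(tr, e[1])), sort(c(tr, e[2])))))
    if (anyDuplicated(add)) next
    if (!move_valid(st, remove = rows, add = add)) next
    return(list(remove = rows, add = add))
  }
  NULL
}

link_vertices <- function(st, ring, e) {
  # order the link of edge e (one vertex pair per surrounding tet) into a
  # cycle (interior edge) or a path (boundary edge)
  pairs <- lapply(ring, function(r) setdiff(st$tets[r, ], e))
  if (any(lengths(pairs) != 2)) return(NULL)
  adjm <- do.call(rbind, pairs)
  verts <- unique(as.vector(adjm))
  nxt <- list()
  for (i in seq_len(nrow(adjm))) {
    a <- as.character(adjm[i, 1]); b <- as.character(adjm[i, 2])
    nxt[[a]] <- c(nxt[[a]], adjm[i, 2])
    nxt[[b]] <- c(nxt[[b]], adjm[i, 1])
  }
  degs <- vapply(nxt, length, integer(1))
  if (any(degs > 2)) return(NULL)
  ends <- names(degs)[degs == 1]
  closed <- length(ends) == 0
  if (!closed && length(ends) != 2) return(NULL)
  start <- if (closed) verts[1] else as.integer(ends[1])
  cyc <- start
  prev <- NA
  repeat {
    cur <- cyc[length(cyc)]
    cand <- setdiff(nxt[[as.character(cur)]], prev)
    if (length(cand) == 0) break
    nxt_v <- cand[1]
    if (closed && nxt_v == cyc[1]) break
    cyc <- c(cyc, nxt_v)
    prev <- cur
    if (length(cyc) > length(verts)) return(NULL)
  }
  if (length(cyc) != length(verts)) return(NULL)
  if (closed && length(cyc) != length(ring)) return(NULL)
  if (!closed && length(cyc) != length(ring) + 1) return(NULL)
  list(cycle = cyc, closed = closed)
}

move_valid <- function(st, remove, add) {
  # simulate triangle counts: no triangle may end up in more than 2 tets
  delta <- new.env(parent = emptyenv())
  bump <- function(k, by)
    delta[[k]] <- (if (is.null(delta[[k]])) 0L else delta[[k]]) + by
  for (r in remove) for (k in simplex_key(tet_tris(st$tets[r, ]))) bump(k, -1L)
  for (i in seq_len(nrow(add))) {
    if (length(unique(add[i, ])) != 4) return(FALSE)
    for (k in simplex_key(tet_tris(add[i, ]))) bump(k, 1L)
  }
  post_count <- function(k) {
    cur <- if (is.null(st$tri_count[[k]])) 0L else st$tri_count[[k]]
    d <- if (is.null(delta[[k]])) 0L else delta[[k]]
    cur + d
  }
  for (k in ls(delta)) {
    pc <- post_count(k)
    if (pc > 2L) return(FALSE)
    if (st$enforce_surface_boundary && pc == 1L) {
      cur <- if (is.null(st$tri_count[[k]])) 0L else st$tri_count[[k]]
      if (cur != 1L) {
        # newly exposed boundary triangle: the tissue boundary is
        # anticlinal, interior cells must stay covered
        labs3 <- as.integer(strsplit(k, "-", fixed = TRUE)[[1]])
        if (!all(labs3 %in% st$surface_cells)) return(FALSE)
      }
    }
  }
  # no duplicate tetrahedra
  add_keys <- if (nrow(add) == 0) character(0) else
    vapply(seq_len(nrow(add)), function(i)
      paste(sort(add[i, ]), collapse = "-"), character(1))
  if (anyDuplicated(add_keys)) return(FALSE)
  removed_keys <- vapply(remove, function(r)
    paste(sort(st$tets[r, ]), collapse = "-"), character(1))
  for (k in add_keys) {
    if (!is.null(st$tet_rows[[k]]) && !(k %in% removed_keys)) return(FALSE)
  }
  # every cell must keep at least one tetrahedron, or it would disappear
  # from the reconstruction
  if (length(remove) > 0) {
    rem_verts <- unique(as.vector(st$tets[remove, , drop = FALSE]))
    for (v in rem_verts) {
      n_after <- length(setdiff(st$vert_tets[[as.character(v)]], remove))
      if (nrow(add)) n_after <- n_after + sum(rowSums(matrix(add == v,
                                                             ncol = 4)) > 0)
      if (n_after == 0L) return(FALSE)
    }
  }
  # the tissue boundary must stay an edge-manifold surface: every affected
  # adjacency edge must afterwards lie in 0 or 2 boundary triangles, or the
  # dual cells around it could not be closed
  aff <- unique(c(unlist(lapply(remove, function(r)
    simplex_key(tet_edges6(st$tets[r, ])))),
    if (nrow(add)) unlist(lapply(seq_len(nrow(add)), function(i)
      simplex_key(tet_edges6(add[i, ]))))))
  for (k in aff) {
    ab <- as.integer(strsplit(k, "-", fixed = TRUE)[[1]])
    rows_after <- setdiff(st$edge_tets[[k]], remove)
    tets_after <- if (length(rows_after))
      st$tets[rows_after, , drop = FALSE] else matrix(integer(0), 0, 4)
    if (nrow(add)) {
      inc <- rowSums(matrix(add %in% ab, ncol = 4)) == 2
      tets_after <- rbind(tets_after, add[inc, , drop = FALSE])
    }
    if (nrow(tets_after) == 0) next
    tris_on_e <- unique(unlist(lapply(seq_len(nrow(tets_after)), function(i) {
      others <- setdiff(tets_after[i, ], ab)
      c(paste(sort(c(ab, others[1])), collapse = "-"),
        paste(sort(c(ab, others[2])), collapse = "-"))
    })))
    nb <- sum(vapply(tris_on_e, post_count, integer(1)) == 1L)
    if (!(nb %in% c(0L, 2L))) return(FALSE)
  }
  TRUE
}

# ---- layer reconstruction by weighted aggregation ----------------------

#' Weight of a candidate adjacency tetrahedron
#'
#' Candidate tetrahedra extracted from the image are ranked by how strongly
#' the image supports them: the sum over their six cell pairs of shared wall
#' area divided by barycenter distance. A tetrahedron containing a pair of
#' cells that share no wall gets weight zero.
#'
#' @param tet integer vector of 4 cell labels present in `adj`
#' @param adj an `image_adjacencies`
#' @return nonnegative numeric weight (square micrometres per micrometre)
#' @export
layer_tetra_weight <- function(tet, adj) {
  labs <- rownames(adj$barycenters)
  if (!all(as.character(tet) %in% labs))
    stop("label not present in adjacencies: ",
         paste(setdiff(as.character(tet), labs), collapse = ", "))
  prs <- utils::combn(sort(tet), 2)
  w <- 0
  for (i in seq_len(ncol(prs))) {
    k <- paste(prs[, i], collapse = "-")
    wa <- adj$wall_areas[k]
    if (is.na(wa) || wa <= 0) return(0)
    d <- sqrt(sum((adj$barycenters[as.character(prs[1, i]), ] -
                     adj$barycenters[as.character(prs[2, i]), ])^2))
    w <- w + wa / d
  }
  unname(w)
}

#' Reconstruct the outer tissue layers by tetrahedron aggregation
#'
#' The epidermal (L1) and subepidermal (L2) layers are anticlinally
#' separated, so the adjacency complex between them contains only
#' tetrahedra made of a triangle of L1 cells and one L2 cell, a triangle of
#' L2 cells and one L1 cell, or two cells of each layer. This strong prior
#' allows building a valid simplicial complex directly from the candidate
#' tetrahedra extracted from the image: starting from the best-weighted
#' candidate (see [layer_tetra_weight()]), neighbours are added greedily in
#' decreasing weight order, skipping any candidate that would geometrically
#' intersect an accepted simplex (in the barycentric embedding) or create a
#' non-manifold face; ties are broken by lexicographic label order. In
#' `"L1-surface"` mode the same aggregation runs on triangles of L1 cells
#' and produces a triangulated surface whose dual is a 2.5D polygonal mesh
#' of the epidermal layer.
#'
#' @param adj an `image_adjacencies` (with layers assigned)
#' @param mode `"L1L2"` (layer pair volume) or `"L1-surface"`
#' @return a simplicial `incidence_complex` with vertex positions at the
#'   cell barycenters
#' @export
aggregate_layer_complex <- function(adj, mode = c("L1L2", "L1-surface")) {
  mode <- match.arg(mode)
  layers <- adj$layers
  pos <- adj$barycenters
  if (mode == "L1L2") {
    cand <- image_cell_quads(adj)
    if (nrow(cand) > 0) {
      nl1 <- matrix(layers[as.character(cand)] == "L1", ncol = 4)
      nl2 <- matrix(layers[as.character(cand)] == "L2", ncol = 4)
      nl1[is.na(nl1)] <- FALSE; nl2[is.na(nl2)] <- FALSE
      ok <- rowSums(nl1) + rowSums(nl2) == 4 & rowSums(nl1) >= 1 &
        rowSums(nl2) >= 1
      cand <- cand[ok, , drop = FALSE]
    }
    if (nrow(cand) == 0) stop("no candidate L1/L2 tetrahedra in the image")
    aggregate_simplices(cand, adj, dim = 3)
  } else {
    cand <- adj$triangles
    if (nrow(cand) > 0) {
      all_l1 <- matrix(layers[as.character(cand)] == "L1", ncol = 3)
      all_l1[is.na(all_l1)] <- FALSE
      cand <- cand[rowSums(all_l1) == 3, , drop = FALSE]
    }
    if (nrow(cand) == 0) stop("no candidate L1 triangles in the image")
    aggregate_simplices(cand, adj, dim = 2)
  }
}

aggregate_simplices <- function(cand, adj, dim) {
  pos <- adj$barycenters
  k <- dim + 1
  wts <- apply(cand, 1, function(s) layer_tetra_weight_any(s, adj))
  keep <- wts > 0
  cand <- cand[keep, , drop = FALSE]
  wts <- wts[keep]
  if (nrow(cand) == 0) stop("no positively weighted candidate simplices")
  ckeys <- simplex_key(cand)
  ord_pref <- order(-wts, ckeys)         # weight desc, lexicographic ties
  rank <- integer(nrow(cand)); rank[ord_pref] <- seq_len(nrow(cand))
  accepted <- integer(0)
  acc_face_count <- new.env(parent = emptyenv())
  seed_i <- ord_pref[1]
  in_queue <- rep(FALSE, nrow(cand))
  queue <- seed_i; in_queue[seed_i] <- TRUE
  faces_of <- function(s) {
    if (dim == 3) simplex_key(tet_tris(s)) else
      simplex_key(rbind(sort(s)[c(1, 2)], sort(s)[c(1, 3)], sort(s)[c(2, 3)]))
  }
  while (length(queue) > 0) {
    qi <- queue[which.min(rank[queue])]
    queue <- setdiff(queue, qi)
    s <- cand[qi, ]
    fks <- faces_of(s)
    manifold_ok <- all(vapply(fks, function(fk) {
      cnt <- acc_face_count[[fk]]
      is.null(cnt) || cnt < 2L
    }, logical(1)))
    if (manifold_ok &&
        !simplex_intersects_any(s, cand[accepted, , drop = FALSE], pos, dim)) {
      accepted <- c(accepted, qi)
      for (fk in fks)
        acc_face_count[[fk]] <- (if (is.null(acc_face_count[[fk]])) 0L
                                 else acc_face_count[[fk]]) + 1L
      # enqueue unvisited candidates sharing a face
      share <- which(!in_queue & !(seq_len(nrow(cand)) %in% accepted) &
                       rowSums(matrix(cand %in% s, ncol = k)) >= dim)
      queue <- c(queue, share)
      in_queue[share] <- TRUE
    }
  }
  acc <- cand[accepted, , drop = FALSE]
  if (dim == 3) simplicial_from_tets(acc, positions = pos)
  else simplicial_from_parts(tris = acc, positions = pos)
}

layer_tetra_weight_any <- function(s, adj) {
  prs <- utils::combn(sort(s), 2)
  w <- 0
  for (i in seq_len(ncol(prs))) {
    kk <- paste(prs[, i], collapse = "-")
    wa <- adj$wall_areas[kk]
    if (is.na(wa) || wa <= 0) return(0)
    d <- sqrt(sum((adj$barycenters[as.character(prs[1, i]), ] -
                     adj$barycenters[as.character(prs[2, i]), ])^2))
    w <- w + wa / d
  }
  unname(w)
}

simplex_intersects_any <- function(s, accepted, pos, dim) {
  if (nrow(accepted) == 0) return(FALSE)
  sp <- pos[as.character(sort(s)), , drop = FALSE]
  for (i in seq_len(nrow(accepted))) {
    a <- sort(accepted[i, ])
    shared <- intersect(s, a)
    if (length(shared) == length(s)) return(TRUE)   # duplicate
    ap <- pos[as.character(a), , drop = FALSE]
    if (dim == 3) {
      if (tets_overlap(sp, ap, length(shared))) return(TRUE)
    } else {
      if (tris_overlap(sp, ap, length(shared))) return(TRUE)
    }
  }
  FALSE
}

tets_overlap <- function(A, B, n_shared) {
  # interior overlap test between two tetrahedra that may legitimately
  # share a vertex, edge or face: probe interior points of each against
  # the other
  probes <- function(P) {
    rbind(colMeans(P),
          (P[1, ] + P[2, ] + P[3, ] + 3 * P[4, ]) / 6,
          (P[1, ] + P[2, ] + 3 * P[3, ] + P[4, ]) / 6,
          (P[1, ] + 3 * P[2, ] + P[3, ] + P[4, ]) / 6,
          (3 * P[1, ] + P[2, ] + P[3, ] + P[4, ]) / 6)
  }
  inside <- function(p, P) {
    b <- tryCatch(barycentric_coords(p, P), error = function(e) NULL)
    !is.null(b) && all(b > 1e-7)
  }
  any(apply(probes(A), 1, inside, P = B)) ||
    any(apply(probes(B), 1, inside, P = A))
}

tris_overlap <- function(A, B, n_shared) {
  # segment-triangle crossings between non-shared edges and the other
  # triangle
  edges <- list(c(1, 2), c(1, 3), c(2, 3))
  for (e in edges) {
    if (segment_hits_triangle(A[e[1], ], A[e[2], ], B)) return(TRUE)
    if (segment_hits_triangle(B[e[1], ], B[e[2], ], A)) return(TRUE)
  }
  FALSE
}

segment_hits_triangle <- function(p, q, tri) {
  # Moeller-Trumbore with strict interior hit
  d <- q - p
  e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
  h <- crossv(d, e2)
  a <- sum(e1 * h)
  if (abs(a) < 1e-12) return(FALSE)
  f <- 1 / a
  s <- p - tri[1, ]
  u <- f * sum(s * h)
  if (u < 1e-7 || u > 1 - 1e-7) return(FALSE)
  qv <- crossv(s, e1)
  v <- f * sum(d * qv)
  if (v < 1e-7 || u + v > 1 - 1e-7) return(FALSE)
  t <- f * sum(e2 * qv)
  t > 1e-7 && t < 1 - 1e-7
}
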