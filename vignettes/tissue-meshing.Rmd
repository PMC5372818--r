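---
title: "Reconstructing cell-resolution tissue meshes from segmented 3D images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing cell-resolution tissue meshes from segmented 3D images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Confocal imaging of membrane-marked plant tissue, followed by 3D
segmentation, yields a label image: an integer per voxel, one connected
region per cell, a designated background label outside the tissue. Many
downstream applications — above all finite-element (FEM) simulation of
tissue mechanics — need a different representation: a triangular mesh of
the cell *interfaces*, non-manifold at the junction lines where three or
more walls meet, with every cell bounded by a closed (watertight) surface
and with triangles regular enough for stable numerics. Standard isosurface
extraction cannot produce this: marching cubes separates each pair of
cells independently and never forms junctions of more than two cells.

This package reconstructs such meshes by working in the *dual* domain.
Tissue geometry (cells, walls, wall edges, cell corners) and tissue
adjacency (cell centre points, adjacency links, adjacency triangles,
adjacency tetrahedra) are two incidence-graded complexes that carry the
same topological information: a corner where four cells meet corresponds
to an adjacency tetrahedron on those four cells; a wall between two cells
corresponds to an adjacency link. Dualizing an incidence graph is a pure
graph flip (`dualize()`): dimensions are exchanged, boundary links
reversed. The reconstruction problem therefore becomes: *build a valid
simplicial complex of adjacencies that matches the adjacencies observed in
the image, then dualize it and assign geometry.*

## Pipeline

1. **Adjacency extraction** (`extract_adjacencies()`). Cell barycenters;
   adjacency links from 6-connected voxel face contacts (with wall areas);
   adjacency triangles and tetrahedra from label triples/quadruples
   co-occurring in 2×2×2 voxel blocks; cell corner points as the mean
   position of the blocks where a quadruple co-occurs; epidermal layer
   assignment (L1 = touches background, L2 = touches L1 only). Triples are
   kept only when all three pairs are face contacts (and quadruples only
   when all triples survive), which discards pure corner-touch artefacts
   and guarantees that the extracted simplices are closed under taking
   faces. Raw face-count wall areas are reported without staircase
   correction.

2. **Initial adjacency complex** (`delaunay_adjacency()` +
   `clean_exterior()`). The Delaunay tetrahedrization of the barycenters
   (computed by incremental Bowyer–Watson insertion; no external geometry
   library is used) is a valid starting complex whose dual is the Voronoi
   diagram — a fair first approximation of meristematic tissue, but wrong
   wherever cells are anisotropic and wrong along concave parts of the
   tissue surface, where Delaunay convexity spans the background. Cleaning
   iteratively peels boundary tetrahedra that bridge non-adjacent cells
   through background voxels, have an edge longer than 3 median edge
   lengths, or are slivers (minimal dihedral angle < 5°, or
   circumradius/shortest-edge ratio > 4).

3. **Annealed topological optimization** (`optimize_adjacency()`). The
   energy is
   `E = w_image·E_image + w_prior·E_prior + w_regularity·E_regularity`
   with defaults (1.0, 0.1, 0.1): the image term is the mean of three
   normalized symmetric differences between the complex and the image
   extraction — adjacency edges, cell tetrahedra vs. observed corner
   quadruples, and boundary triangles vs. observed surface-corner
   triples — so a complex consisting of exactly the image-extracted
   simplices has zero image energy; the prior term is the mean squared
   relative deviation of per-cell neighbour counts from 13.2 (a
   space-filling polyhedral packing); the regularity term is the mean
   tetrahedron elongation (max/min edge − 1). Moves are 2–3 and 3–2
   bistellar flips, removal of an edge with retetrahedrization of its
   cavity (fan for interior edges, bipyramid for boundary edges),
   insertion of image-extracted tetrahedra, and deletion of boundary
   tetrahedra that carry a non-image adjacency. Every sweep also proposes
   *targeted* repairs: for each image adjacency missing from the complex,
   the specific flip or insertion that creates it; for each excess
   adjacency, the removal of its edge. A move is filtered out if it would
   leave a triangle with more than two cofacets, duplicate a tetrahedron,
   break the edge-manifoldness of the complex boundary, or newly expose an
   interior cell on the boundary (the tissue boundary is anticlinal: only
   background-adjacent cells may carry boundary triangles). Acceptance is
   by the Metropolis rule over reheated geometric cooling cycles; the
   starting temperature is calibrated to twice the median |ΔE| of probe
   moves, because the energy quantum of a single adjacency change
   (≈ 1/|edges|) is far below 1 and a fixed t=1 would randomize the
   complex. A final zero-temperature quench from the best state seen
   guarantees that the returned energy never exceeds the initial one.

4. **Dual geometry** (`dual_geometry()` + `star_triangulate()`). The
   optimized complex is flipped into a polyhedral cell complex. Cell
   corners dual to a tetrahedron whose label set was observed as a corner
   in the image are placed at the observed corner position; others at the
   centre of the circumscribed sphere, constrained into the tetrahedron by
   projection on its nearest face when (and only when) the tetrahedron
   violates the empty-circumsphere property — for a pristine Delaunay
   complex nothing is constrained and the dual is exactly the Voronoi
   diagram. Boundary ("infinite") interfaces are truncated: each boundary
   triangle contributes a surface vertex (image corner if observed, else
   the cell-centre centroid projected onto the tissue isosurface), and
   every surface cell is closed by a cap face, so all cells are watertight
   by construction. Star triangulation fans every polygonal interface from
   a vertex at the mean of its boundary vertices. The tissue isosurface
   itself is extracted by marching tetrahedra on a box-smoothed binary
   foreground mask — the smoothing (two width-3 passes) removes the
   voxel staircase so that surface areas and projections approach the
   continuum surface.

5. **Mesh enhancement** (`split_refine()`, `isotropic_remesh()`,
   `project_surface_vertices()`, `pin_cell_corners()`, `optimize_mesh()`).
   Optional refinement (midpoint splitting and/or isotropic remeshing with
   split-long/collapse-short/tangential smoothing, both restricted so
   junction lines and corners are preserved), projection of surface
   vertices onto the isosurface, and pinning of corner vertices to their
   observed image positions. The optimization then anneals vertex shifts
   (inside a sphere of half the median edge length, shrinking by 0.9 per
   cycle; pinned vertices immobile, surface vertices re-projected after
   each shift) and edge flips strictly interior to a single interface —
   so the dual cell adjacency is preserved exactly. Its energy has the
   same three-part form, defaults (1.0, 0.5, 0.5): the image term
   attaches each vertex to the observed wall surfaces compatible with its
   incident interfaces — a fitted plane per cell–cell wall (walls of this
   tissue are flat, and a plane fit is immune to voxel staircase noise;
   junction and corner vertices are attracted to the intersection of
   their walls) and the nearest exposed-boundary point for exterior
   interfaces (lateral anchoring on the curved epidermis); the prior term
   is the mean squared distance of interface vertices to their
   interface's best-fit plane (flat polygonal walls; the curved outer
   surface is not penalized); the regularity term is the mean triangle
   eccentricity (1 − Σsin/(3 sin 60°)) plus the mean squared relative
   valence deviation from 6 over interface-interior vertices. Interface
   planes are refit between temperature cycles and frozen within one, so
   per-move energy changes are exact; shifts that would fold a triangle
   over (normal reversal) are filtered, as are flips. The default
   temperature is zero — descent cycles with plane refits and shrinking
   radius — because, unlike the discrete adjacency optimization, the
   continuous relocation landscape needs no uphill moves from a
   structurally correct input and any hot phase does shape damage the
   final quench cannot recover; passing an explicit `t_start` enables true
   Metropolis annealing. Best-state tracking and a capped final quench
   guarantee the returned energy never exceeds the input's; if it somehow
   would, the input mesh is returned unchanged.

6. **Quality estimation** (`quality_report()`). Ten normalized estimators
   in [0, 1] (1 = ideal): cell convexity (volume over convex-hull volume,
   hull by an in-package incremental 3D hull); epidermis cell angle
   (1 − mean |wedge − 120°|/30° over surface three-cell junctions, wedges
   measured between rim directions projected into the tangent plane of
   the outer surface); cell cliques (1 − fraction of junctions where more
   than 4 cells — 3 on the surface — meet); image accuracy (mean per-cell
   voxel Jaccard between the segmented image and the parity-ray-cast
   voxelized mesh); vertex distance (min(1, d₀/mean corner displacement)
   with d₀ = 0.25·√3 µm, the voxel diagonal at a typical 0.25 µm
   resolution); cell 2-adjacency (Jaccard of image vs. mesh adjacency
   edges); triangle area deviation (1 − sd/(√2·mean)); triangle
   eccentricity (1 − mean ecc/0.5); vertex valence (1 − mean |valence −
   6|/6 over interface-interior vertices); mesh complexity (min(1,
   152/triangle-incidences-per-cell), 152 being a good triangulation of
   the space-filling truncated octahedron). "Measured as a reciprocal"
   estimators are capped at 1, all scores are clamped to [0, 1], and the
   report's average is the mean of the available scores (vertex distance
   is reported as missing, not zero, when no corner is matched).
   `plot_quality()` draws the radar plot; `tissue_properties()` computes
   per-cell volumes (divergence theorem over consistently oriented
   boundaries), per-interface areas, and surface curvature (angle-deficit
   Gaussian curvature, cotangent-Laplacian mean curvature, principal
   curvatures from the two).

## Synthetic study tissues

No external dataset is required: `generate_voronoi_tissue()` rasterizes an
anisotropic-metric Voronoi tessellation of Poisson-disc seeds in a box or
dome (the axis-scaled metric is the simplest model of the elongated-cell
anisotropy that breaks the plain Voronoi approximation), and returns the
exact ground truth — seed positions, the adjacency of the exact diagram
clipped to the domain (candidate pairs are scaled-space Delaunay edges,
kept when dense sampling of their Voronoi facet, the convex hull of the
circumcentres around the Delaunay edge with ray extensions on the hull,
intersects the domain), and the Voronoi vertices as true corners.
`generate_layered_dome()` emulates the shoot apical meristem's anticlinal
layering: voxels are assigned to a depth shell first (single-cell L1 and
L2 shells of thickness 0.18·R over an inner bulk) and then to the nearest
seed of that shell, so L1 cells touch the background and L2 cells touch
only L1 by construction, for any cell counts; its ground-truth adjacency
comes from a rasterization of the same tessellation at twice the
resolution (the stratified diagram has no closed-form facet test), with
single-face contacts discarded as corner ambiguities. `degrade()` flips
boundary voxels to neighbouring labels under a local connectivity guard to
emulate segmentation noise.

What these tissues do *not* emulate: curved cell walls (all generator
walls are planar or spherical-shell pieces), the mechanical 120°
equilibrium of real epidermal junctions (Poisson-disc Voronoi junctions
deviate substantially from 120°, so the epidermis-angle score of a perfect
reconstruction of these tissues is far below what real meristem data
would give), intensity noise, and segmentation errors beyond label
swaps. Passing the test suite therefore demonstrates correct topology
recovery, watertightness, determinism and score computation — not
biological realism of the score values themselves.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run on tissues of 10–60 cells
at 40³–64³ voxels, with 1–3 annealing cycles of 8–30 sweeps — sizes at
which the full pipeline completes in a few minutes in plain R while still
exhibiting every structural property of interest (hundreds of tetrahedra,
thousands of triangles). All coordinates are micrometres with the
voxel-centre convention ((i+0.5)·v for 0-based index i). Degenerate
tetrahedra fall back to centroid dual vertices; voxelization perturbs ray
origins by ~10⁻⁴ voxel to avoid edge-exact hits; circumsphere solves
reject tetrahedra with relative volume below 10⁻¹²; ties in the greedy
layer aggregation are broken by lexicographic label order; equal-energy
moves are accepted (ΔE ≤ 0) to allow plateau drift.

## Known limitations

- The adjacency optimizer reaches the image's corner structure only up to
  moves that keep the complex valid at every step; a few observed
  quadruples may stay unreachable, leaving their corners at fallback
  circumcentre positions.
- The wall-plane image attachment assumes flat walls; on tissues with
  strongly curved internal walls it flattens them (the prior does the
  same, by design).
- Mesh optimization improves the energy, which is a proxy for the quality
  estimators, not the estimators themselves. Its optimum sits at the
  tissue's *image-truthful* shape statistics: a noisy-boundary mesh gains
  convexity as vertices return to the walls, while an idealized flat-fan
  mesh that overshoots the tissue's real (curved-shell) convexity loses a
  little of it for the same reason — the optimizer converges to the
  truthful value from either side.
- The 2.5D epidermal surface product (`aggregate_layer_complex(adj,
  "L1-surface")` + `dualize()`) is topological; no dedicated surface
  geometry embedding is provided beyond the cell barycenters.
- Exact-arithmetic predicates are not used; the Bowyer–Watson insertion
  relies on double precision with tolerances, which is ample for the
  barycenter clouds of segmented tissues but not for adversarial inputs.
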