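# tissuemesh

Reconstructs **FEM-ready, non-manifold triangular meshes of multicellular
tissue at cell resolution** from segmented 3D label images — the
representation needed to simulate the mechanics of a growing shoot apical
meristem (and similar layered plant tissues), where every cell must be a
closed surface of well-shaped triangles and three or more cell walls meet
along shared junction lines.

## The method

A segmented image easily yields *adjacency* information, while the
*geometry* (walls, corners) is hard to abstract from voxels. The two are
dual: cells ↔ adjacency vertices, walls ↔ adjacency links, wall edges ↔
adjacency triangles, cell corners ↔ adjacency tetrahedra (exactly four
cells meet at a generic corner). The package therefore

1. extracts adjacency simplices from voxel neighbourhoods (face contacts,
   label triples/quadruples in 2×2×2 blocks, observed corner positions);
2. builds a first valid adjacency complex — the Delaunay tetrahedrization
   of the cell barycenters, whose dual is the Voronoi diagram — and peels
   off the exterior tetrahedra that Delaunay convexity creates across
   concave tissue surface;
3. optimizes the complex by simulated annealing over local topological
   moves (bistellar flips, edge removals, image-guided insertions and
   deletions), minimizing

   `E(T,S) = w_img·E_image(T,S) + w_prior·E_prior(T) + w_reg·E_regularity(T)`

   where `E_image` is the normalized symmetric difference between the
   complex's simplices and those extracted from the image `S`, `E_prior`
   penalizes deviations of per-cell neighbour counts from ~13, and
   `E_regularity` penalizes elongated tetrahedra;
4. dualizes the optimized complex into polyhedral cells: corners at their
   observed image positions (circumsphere centres where unobserved,
   exactly the Voronoi construction for a Delaunay complex), surface cells
   truncated against the tissue isosurface and closed by cap faces — every
   cell watertight by construction;
5. star-triangulates the interfaces and enhances the mesh: optional
   refinement, surface projection, corner pinning, and a second
   optimization over vertex shifts and intra-interface edge flips with an
   image attachment (fitted wall planes), a flat-wall shape prior and a
   triangle-regularity term — preserving the cell adjacency exactly;
6. scores the result with ten normalized estimators (cell convexity,
   epidermal 120° junction angles, four-cell corners, voxel overlap,
   corner distance, adjacency Jaccard, triangle area/eccentricity/valence
   regularity, triangles per cell) and computes cell volumes, wall areas
   and surface curvature.

The layered organisation of the meristem is exploited in a second mode:
`aggregate_layer_complex()` reconstructs the epidermal layers alone (L1/L2
tetrahedra, or an L1 triangle complex dualizing to a 2.5D surface mesh) by
greedy aggregation of image-extracted simplices weighted by shared wall
area over cell distance.

Synthetic tissues with exact ground truth (`generate_voronoi_tissue()`,
`generate_layered_dome()`, `degrade()`) make the whole pipeline testable
without any imaging data.

## Worked example

```r
library(tissuemesh)

# an anisotropic synthetic tissue (cells elongated 2x along x) where the
# plain Voronoi/Delaunay approximation fails
tis <- generate_voronoi_tissue(20, "box", resolution = 48,
                               anisotropy = c(2, 1, 1), rng_seed = 7)

cfg <- default_config(rng_seed = 7)
cfg$adj_cycles <- 2L; cfg$adj_steps_per_cycle <- 15L
cfg$mesh_cycles  <- 1L; cfg$mesh_steps_per_cycle  <- 5L
res <- reconstruct_tissue_mesh(tis$image, cfg, verbose = TRUE)
#> extracting adjacencies ...
#>   20 cells, 72 adjacency edges
#> Delaunay complex: 56 tetrahedra
#> cleaned: 51 tetrahedra
#> optimized adjacency: 39 tetrahedra, energy 0.2363 (image 0.1372)
#> star mesh: 170 vertices, 450 triangles
#> optimized mesh energy 1.4535
#> average quality: 0.693

res$report
#> <quality_report>
#>   cell_convexity           0.852
#>   epidermis_cell_angle     0.000
#>   cell_cliques             1.000
#>   image_accuracy           0.569
#>   vertex_distance          1.000
#>   cell_2adjacency          0.947
#>   triangle_area_deviation  0.241
#>   triangle_eccentricity    0.568
#>   vertex_valence           0.749
#>   mesh_complexity          1.000
#>   average_quality          0.693
#>   (20 cells, 170 vertices, 450 triangles)
```

Reading the scores: every cell is closed and convex to 85%, every interior
junction joins exactly four cells (`cell_cliques = 1`), corners sit at
their observed image positions (`vertex_distance = 1`), and 95% of the
cell adjacencies agree with the image (`cell_2adjacency = 0.947`; against
the generator's exact ground truth the recovered adjacency Jaccard is
0.934, versus 0.739 for the raw Delaunay guess on this fixture).
The intrinsic regularity scores are low because this example skips
refinement: star triangulation alone fans large uneven triangles; add
`cfg$split_rounds <- 1` or an `isotropic_remesh()` pass before judging
FEM-readiness. The epidermis-angle score reflects the synthetic tissue
itself: Poisson-disc Voronoi junctions deviate far from the 120°
mechanical equilibrium of real epidermis, so this axis is only
informative on real data. `write_mesh(res$mesh, "tissue.ply")` exports
the mesh with interface labels; `plot_quality(res$report)` draws the
radar plot; a command-line launcher is installed at
`inst/scripts/tissuemesh` (subcommands `synth`, `extract`, `pipeline`,
`quality`).

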