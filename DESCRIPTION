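Package: tissuemesh
Title: FEM-Ready Triangular Meshes of Segmented Plant Tissue at Cell Resolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs non-manifold, finite-element-ready 3D triangular
    meshes of multicellular tissue (shoot apical meristem and similar layered
    tissues) from 3D segmented label images. Cell adjacencies extracted from
    voxel neighbourhoods are assembled into a simplicial complex, optimized by
    simulated annealing against image, prior and regularity energies, and
    dualized into a polyhedral cell geometry whose interfaces are then
    triangulated and enhanced by a second annealed optimization. Includes ten
    normalized mesh-quality estimators, geometric property computation
    (volumes, interface areas, surface curvature), synthetic tissue generators
    with ground-truth adjacency for validation, and readers/writers for
    labeled TIFF/INR images and PLY/OBJ/VTK meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
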