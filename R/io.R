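#' Read a segmented label image
#'
#' Supports multi-page TIFF (one page per z-slice, 8/16/32-bit integer
#' samples) and INR volumes. The label array is stored in (x, y, z) axis
#' order. TIFF files do not carry the physical voxel size, so it must be
#' supplied; INR headers include it (an explicit `voxel_size` overrides).
#'
#' @param path file path (`.tif`, `.tiff` or `.inr`)
#' @param voxel_size numeric length-3 (micrometres per axis) or NULL
#' @param background_label background label (default 1)
#' @return a `segmented_image`
#' @export
read_labeled_image <- function(path, voxel_size = NULL,
                               background_label = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (any(vapply(pages, function(p) is.double(p) &&
                     any(p != round(p)), logical(1))))
      stop("non-integer pixel type: labels must be integer-valued")
    nz <- length(pages)
    ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
    a <- array(0L, c(nx, ny, nz))
    for (k in seq_len(nz)) a[, , k] <- as.integer(t(pages[[k]]))
    if (is.null(voxel_size))
      stop("voxel size missing: TIFF carries no physical spacing, ",
           "supply voxel_size")
    segmented_image(a, voxel_size, background_label)
  } else if (ext == "inr") {
    read_inr(path, voxel_size, background_label)
  } else stop("unsupported image format: .", ext)
}

#' Write a segmented label image
#'
#' TIFF output is written as 16-bit multi-page grayscale (one page per z
#' slice); labels must fit in 16 bits. INR output stores the voxel size in
#' its header. Round trip through either format reproduces the label array
#' exactly.
#'
#' @param image a `segmented_image`
#' @param path destination (`.tif`, `.tiff` or `.inr`)
#' @return invisibly, `path`
#' @export
write_labeled_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  a <- image$labels
  if (ext %in% c("tif", "tiff")) {
    if (max(a) > 65535) stop("labels exceed 16-bit TIFF range")
    d <- dim(a)
    pages <- lapply(seq_len(d[3]), function(k)
      t(a[, , k]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                    compression = "none")
  } else if (ext == "inr") {
    write_inr(image, path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

read_inr <- function(path, voxel_size, background_label) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 256))
  get <- function(key, default = NA) {
    m <- regmatches(header, regexec(paste0(key, "=([^\n]+)"), header))[[1]]
    if (length(m) < 2) default else m[2]
  }
  d <- as.integer(c(get("XDIM"), get("YDIM"), get("ZDIM")))
  bits <- as.integer(sub(" .*", "", get("PIXSIZE", "16")))
  vx <- as.numeric(c(get("VX", 1), get("VY", 1), get("VZ", 1)))
  if (!is.null(voxel_size)) vx <- voxel_size
  type <- get("TYPE", "unsigned fixed")
  if (grepl("float", type)) stop("non-integer pixel type in INR volume")
  vals <- readBin(con, "integer", n = prod(d), size = bits / 8,
                  signed = bits > 16, endian = "little")
  segmented_image(array(as.integer(vals), d), vx, background_label)
}

write_inr <- function(image, path) {
  d <- dim(image$labels)
  vs <- image$voxel_size
  head <- sprintf(paste0(
    "#INRIMAGE-4#{\nXDIM=%d\nYDIM=%d\nZDIM=%d\nVDIM=1\n",
    "TYPE=unsigned fixed\nPIXSIZE=32 bits\nSCALE=2**0\nCPU=decm\n",
    "VX=%g\nVY=%g\nVZ=%g\n"), d[1], d[2], d[3], vs[1], vs[2], vs[3])
  pad <- 256 - nchar(head) - 4
  head <- paste0(head, strrep("\n", pad), "##}\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(head), con)
  writeBin(as.integer(image$labels), con, size = 4, endian = "little")
  invisible(path)
}

#' Write a tissue mesh to PLY, OBJ or VTK
#'
#' PLY (ascii) and VTK (legacy ascii) store the per-triangle interface
#' labels (two integer cell ids, 0 = exterior) and the per-vertex surface /
#' corner / pinned flags in native property channels; PLY round-trips
#' through [read_mesh()] with topology, labels and coordinates intact. OBJ
#' cannot carry labels and drops them with a warning.
#'
#' @param mesh a `tissue_mesh`
#' @param path destination file
#' @param format `"ply"`, `"obj"` or `"vtk"` (default from extension)
#' @return invisibly, `path`
#' @export
write_mesh <- function(mesh, path,
                       format = tolower(tools::file_ext(path))) {
  format <- match.arg(format, c("ply", "obj", "vtk"))
  switch(format,
         ply = write_ply(mesh, path),
         obj = write_obj(mesh, path),
         vtk = write_vtk(mesh, path))
  invisible(path)
}

#' Read a tissue mesh written by [write_mesh()]
#' @param path a PLY file
#' @return a `tissue_mesh`
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext != "ply")
    stop("only PLY meshes can be read back; got .", ext)
  read_ply(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

write_ply <- function(mesh, path) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    "comment non-manifold cell tissue mesh (coordinates in um)",
    sprintf("element vertex %d", n),
    "property double x", "property double y", "property double z",
    "property uchar is_surface", "property uchar is_corner",
    "property uchar pinned",
    sprintf("element face %d", m),
    "property list uchar int vertex_indices",
    "property int label1", "property int label2",
    "end_header"), con)
  writeLines(paste(fmt_num(mesh$vertices[, 1]), fmt_num(mesh$vertices[, 2]),
                   fmt_num(mesh$vertices[, 3]),
                   as.integer(mesh$is_surface), as.integer(mesh$is_corner),
                   as.integer(mesh$pinned)), con)
  writeLines(paste(3, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L,
                   mesh$interface[, 1], mesh$interface[, 2]), con)
}

read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)))
  vl <- lines[end + seq_len(nv)]
  fl <- lines[end + nv + seq_len(nf)]
  vm <- matrix(as.numeric(unlist(strsplit(vl, " ", fixed = TRUE))),
               nrow = nv, byrow = TRUE)
  fm <- matrix(as.numeric(unlist(strsplit(fl, " ", fixed = TRUE))),
               nrow = nf, byrow = TRUE)
  tissue_mesh(vm[, 1:3], fm[, 2:4] + 1L, fm[, 5:6],
              is_surface = vm[, 4] > 0, is_corner = vm[, 5] > 0,
              pinned = vm[, 6] > 0)
}

write_obj <- function(mesh, path) {
  warning("OBJ cannot store interface labels; they are dropped ",
          "(use PLY or VTK to keep them)")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cell tissue mesh (labels dropped, coordinates in um)", con)
  writeLines(paste("v", fmt_num(mesh$vertices[, 1]),
                   fmt_num(mesh$vertices[, 2]),
                   fmt_num(mesh$vertices[, 3])), con)
  writeLines(paste("f", mesh$triangles[, 1], mesh$triangles[, 2],
                   mesh$triangles[, 3]), con)
}

write_vtk <- function(mesh, path) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "cell tissue mesh (um)", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  writeLines(paste(fmt_num(mesh$vertices[, 1]), fmt_num(mesh$vertices[, 2]),
                   fmt_num(mesh$vertices[, 3])), con)
  writeLines(sprintf("POLYGONS %d %d", m, 4 * m), con)
  writeLines(paste(3, mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                   mesh$triangles[, 3] - 1L), con)
  writeLines(c(sprintf("CELL_DATA %d", m),
               "SCALARS label1 int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$interface[, 1]), con)
  writeLines(c("SCALARS label2 int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$interface[, 2]), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS is_surface int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(mesh$is_surface)), con)
}

# ---- pipeline configuration -------------------------------------------

#' Default pipeline configuration
#'
#' A flat list of every tunable of the reconstruction pipeline, suitable
#' for JSON serialization; [load_config()] and [save_config()] round-trip
#' it exactly. All defaults match the corresponding function defaults.
#'
#' @param rng_seed integer seed used for every stochastic stage
#' @return named list of class `pipeline_config`
#' @export
default_config <- function(rng_seed = 1L) {
  structure(list(
    background_label = 1L,
    voxel_size = c(1, 1, 1),
    layers = "none",                 # none | L1L2 | L1
    adj_w_image = 1.0, adj_w_prior = 0.1, adj_w_regularity = 0.1,
    adj_target_neighbors = 13.2,
    adj_cycles = 3L, adj_steps_per_cycle = 30L,
    adj_cooling = 0.85,
    max_edge_factor = 3, sliver_min_dihedral = 5, sliver_radius_edge = 4,
    mesh_optim_enabled = TRUE,
    mesh_w_image = 1.0, mesh_w_prior = 0.5, mesh_w_regularity = 0.5,
    mesh_cycles = 2L, mesh_steps_per_cycle = 10L, mesh_cooling = 0.85,
    split_rounds = 0L, remesh_target_length = 0,
    project_surface = TRUE, pin_corners = TRUE,
    d0 = 0.25 * sqrt(3), complexity_reference = 152,
    angle_reference = 30,
    rng_seed = as.integer(rng_seed)), class = c("pipeline_config", "list"))
}

#' @rdname default_config
#' @param config a `pipeline_config`
#' @param path JSON file path
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname default_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  ints <- c("background_label", "adj_cycles", "adj_steps_per_cycle",
            "mesh_cycles", "mesh_steps_per_cycle", "split_rounds",
            "rng_seed")
  for (nm in ints) cfg[[nm]] <- as.integer(cfg[[nm]])
  cfg
}

#' Run the full reconstruction pipeline on a segmented image
#'
#' extract adjacencies -> Delaunay -> exterior cleaning -> annealed
#' adjacency optimization (or layer aggregation) -> dual geometry -> star
#' triangulation -> optional refinement, surface projection and corner
#' pinning -> annealed mesh optimization -> quality report. Deterministic
#' given `config$rng_seed`.
#'
#' @param image a `segmented_image`
#' @param config a `pipeline_config`
#' @param verbose print stage progress and energies
#' @return list with `mesh` (`tissue_mesh`), `report` (`quality_report`),
#'   `complex` (optimized adjacency complex) and `adjacencies`
#' @export
reconstruct_tissue_mesh <- function(image, config = default_config(),
                                    verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stopifnot(length(validate_image(image)) == 0)
  say("extracting adjacencies ...")
  adj <- extract_adjacencies(image)
  say("  %d cells, %d adjacency edges", nrow(adj$barycenters),
      nrow(adjacency_edges(adj)))
  if (config$layers == "none") {
    dc <- delaunay_adjacency(cell_barycenters(image))
    say("Delaunay complex: %d tetrahedra", nrow(complex_simplices(dc, 3)))
    cl <- clean_exterior(dc, adj,
                         max_edge_factor = config$max_edge_factor,
                         sliver_min_dihedral = config$sliver_min_dihedral,
                         sliver_radius_edge = config$sliver_radius_edge)
    say("cleaned: %d tetrahedra", nrow(complex_simplices(cl, 3)))
    w <- energy_weights(config$adj_w_image, config$adj_w_prior,
                        config$adj_w_regularity,
                        config$adj_target_neighbors)
    sch <- annealing_schedule(cycles = config$adj_cycles,
                              steps_per_cycle = config$adj_steps_per_cycle,
                              cooling_factor = config$adj_cooling,
                              rng_seed = config$rng_seed)
    opt <- optimize_adjacency(cl, adj, w, sch)
    en <- attr(opt, "energy")
    say("optimized adjacency: %d tetrahedra, energy %.4f (image %.4f)",
        nrow(complex_simplices(opt, 3)), en$total, en$e_image)
  } else if (config$layers == "L1L2") {
    opt <- aggregate_layer_complex(adj, "L1L2")
    say("L1/L2 aggregation: %d tetrahedra", nrow(complex_simplices(opt, 3)))
  } else {
    # the 2.5D epidermal surface mesh is a different product; it is built
    # through aggregate_layer_complex(adj, "L1-surface") + dualize()
    stop("layers must be 'none' or 'L1L2' for the volumetric pipeline")
  }
  iso <- binary_isosurface(image)
  geom <- dual_geometry(opt, adj, isosurface = iso)
  mesh <- star_triangulate(geom)
  say("star mesh: %d vertices, %d triangles", nrow(mesh$vertices),
      nrow(mesh$triangles))
  if (config$split_rounds > 0) mesh <- split_refine(mesh, config$split_rounds)
  if (config$remesh_target_length > 0)
    mesh <- isotropic_remesh(mesh, config$remesh_target_length)
  if (config$project_surface) mesh <- project_surface_vertices(mesh, iso)
  if (config$pin_corners)
    mesh <- pin_cell_corners(mesh, adj$corner_points,
                             background_label = adj$background_label)
  if (config$mesh_optim_enabled) {
    sw <- mesh_weights(config$mesh_w_image, config$mesh_w_prior,
                       config$mesh_w_regularity,
                       schedule = annealing_schedule(
                         cycles = config$mesh_cycles,
                         steps_per_cycle = config$mesh_steps_per_cycle,
                         cooling_factor = config$mesh_cooling,
                         rng_seed = config$rng_seed))
    mesh <- optimize_mesh(mesh, image, sw, isosurface = iso)
    en <- attr(mesh, "energy")
    say("optimized mesh energy %.4f", en$total)
  }
  report <- quality_report(mesh, image, adj, d0 = config$d0,
                           complexity_reference = config$complexity_reference)
  say("average quality: %.3f", report$average_quality)
  list(mesh = mesh, report = report, complex = opt, adjacencies = adj)
}

#' Command-line interface
#'
#' Subcommands: `synth` (generate a synthetic tissue image), `extract`
#' (adjacency summary), `pipeline` (full reconstruction to mesh + report),
#' `quality` (score an existing mesh against an image). Run from a shell as
#' `Rscript -e 'tissuemesh::cli_main()' -- <subcommand> ...` or through the
#' installed `inst/scripts/tissuemesh` launcher.
#'
#' @param argv character vector of arguments (default: command line)
#' @return exit code, invisibly (0 on success)
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(argv) == 0) stop(cli_usage(), call. = FALSE)
    cmd <- argv[1]
    args <- cli_parse(argv[-1])
    switch(cmd,
           synth = cli_synth(args),
           extract = cli_extract(args),
           pipeline = cli_pipeline(args),
           quality = cli_quality(args),
           stop(cli_usage(), call. = FALSE))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

cli_usage <- function() {
  paste("usage: tissuemesh <synth|extract|pipeline|quality> [--key value ...]",
        "  synth    --cells N --resolution N --seed N [--anisotropy x,y,z] --out img.tif",
        "  extract  --input img.tif [--voxel-size x,y,z] [--background N]",
        "  pipeline --input img.tif [--config cfg.json] [--voxel-size x,y,z]",
        "           [--layers none|L1L2] --out mesh.ply [--report report.json]",
        "  quality  --mesh mesh.ply --input img.tif [--voxel-size x,y,z]",
        "           [--report report.json]", sep = "\n")
}

cli_parse <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("unexpected argument: ", args[i], "\n", cli_usage(), call. = FALSE)
    key <- sub("^--", "", args[i])
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop("missing value for --", key, call. = FALSE)
    out[[key]] <- args[i + 1]
    i <- i + 2
  }
  out
}

cli_num3 <- function(s) as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])

cli_read_image <- function(args) {
  if (is.null(args$input)) stop("--input is required", call. = FALSE)
  vs <- if (!is.null(args$`voxel-size`)) cli_num3(args$`voxel-size`) else
    c(1, 1, 1)
  bg <- if (!is.null(args$background)) as.integer(args$background) else 1L
  read_labeled_image(args$input, voxel_size = vs, background_label = bg)
}

cli_synth <- function(args) {
  n <- as.integer(args$cells %||% 60)
  res <- as.integer(args$resolution %||% 64)
  seed <- as.integer(args$seed %||% 1)
  aniso <- if (!is.null(args$anisotropy)) cli_num3(args$anisotropy) else
    c(1, 1, 1)
  if (is.null(args$out)) stop("--out is required", call. = FALSE)
  tis <- generate_voronoi_tissue(n, "box", resolution = res,
                                 anisotropy = aniso, rng_seed = seed)
  write_labeled_image(tis$image, args$out)
  truth_path <- paste0(tools::file_path_sans_ext(args$out), "_truth.json")
  jsonlite::write_json(list(
    seeds = cbind(label = as.integer(rownames(tis$seeds)), tis$seeds),
    true_adjacency = tis$true_adjacency, rng_seed = seed),
    truth_path, digits = NA)
  message("wrote ", args$out, " and ", truth_path)
}

cli_extract <- function(args) {
  img <- cli_read_image(args)
  adj <- extract_adjacencies(img)
  print(adj)
  layers <- table(adj$layers)
  message("layers: ", paste(names(layers), layers, collapse = ", "))
}

cli_pipeline <- function(args) {
  img <- cli_read_image(args)
  cfg <- if (!is.null(args$config)) load_config(args$config) else
    default_config()
  if (!is.null(args$seed)) cfg$rng_seed <- as.integer(args$seed)
  if (!is.null(args$layers)) cfg$layers <- args$layers
  if (is.null(args$out)) stop("--out is required", call. = FALSE)
  res <- reconstruct_tissue_mesh(img, cfg, verbose = TRUE)
  write_mesh(res$mesh, args$out)
  if (!is.null(args$report)) write_report(res$report, args$report)
  message("wrote ", args$out)
}

cli_quality <- function(args) {
  if (is.null(args$mesh)) stop("--mesh is required", call. = FALSE)
  img <- cli_read_image(args)
  mesh <- read_mesh(args$mesh)
  rep <- quality_report(mesh, img)
  print(rep)
  if (!is.null(args$report)) write_report(rep, args$report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a quality report as JSON (and its radar axes as CSV)
#'
#' @param report a `quality_report`
#' @param path JSON destination; a sibling `.csv` with (axis, score) rows
#'   is written alongside
#' @return invisibly, `path`
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(list(scores = as.list(report$scores),
                            average_quality = report$average_quality,
                            counts = as.list(report$counts)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  csv <- paste0(tools::file_path_sans_ext(path), ".csv")
  utils::write.csv(data.frame(axis = names(report$scores),
                              score = as.numeric(report$scores)),
                   csv, row.names = FALSE)
  invisible(path)
}
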