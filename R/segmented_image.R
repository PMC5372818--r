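#' Segmented 3D label image
#'
#' Wraps a 3D integer label lattice with its physical voxel size and the
#' designated background label. Axes are stored in (x, y, z) order; world
#' coordinates are micrometres with the voxel-centre convention: the voxel at
#' 0-based index (i, j, k) has its centre at ((i + 0.5) vx, (j + 0.5) vy,
#' (k + 0.5) vz). The tissue must not touch the image border (the border is
#' background) and every non-background label is expected to form a single
#' connected region.
#'
#' @param labels 3D integer array (x, y, z)
#' @param voxel_size numeric length-3 (micrometres per axis, x/y/z)
#' @param background_label integer; voxels carrying it are outside the
#'   tissue. Defaults to 1, the common convention in meristem segmentation
#'   pipelines.
#' @return an object of class `segmented_image`
#' @export
segmented_image <- function(labels, voxel_size = c(1, 1, 1),
                            background_label = 1L) {
  stopifnot(length(dim(labels)) == 3, length(voxel_size) == 3,
            all(voxel_size > 0))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size),
                 background_label = as.integer(background_label)),
            class = "segmented_image")
}

#' @export
print.segmented_image <- function(x, ...) {
  d <- dim(x$labels)
  labs <- image_labels(x)
  cat(sprintf("<segmented_image> %dx%dx%d voxels (%.3g x %.3g x %.3g um), %d cells, background=%d\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], length(labs), x$background_label))
  invisible(x)
}

#' Non-background labels present in the image
#' @param image a `segmented_image`
#' @return sorted integer vector of cell labels
#' @export
image_labels <- function(image) {
  sort(setdiff(unique(as.vector(image$labels)), image$background_label))
}

#' Structural validation of a segmented image
#'
#' Checks that all labels are >= the background label >= 0 and that the
#' image border consists of background only (the tissue does not touch the
#' boundary of the stack).
#'
#' @param image a `segmented_image`
#' @return character vector of problems; empty iff valid
#' @export
validate_image <- function(image) {
  a <- image$labels
  d <- dim(a)
  bad <- character(0)
  if (image$background_label < 0) bad <- c(bad, "background label < 0")
  if (min(a) < image$background_label)
    bad <- c(bad, "labels below the background label")
  border <- c(a[1, , ], a[d[1], , ], a[, 1, ], a[, d[2], ], a[, , 1],
              a[, , d[3]])
  if (any(border != image$background_label))
    bad <- c(bad, "tissue touches the image border")
  bad
}

#' World coordinates of voxel centres
#' @param idx integer matrix (n x 3) of 1-based voxel indices (x, y, z)
#' @param image a `segmented_image`
#' @return numeric matrix (n x 3) in micrometres
#' @export
voxel_centers <- function(idx, image) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(idx - 0.5, 2, image$voxel_size, `*`)
}
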