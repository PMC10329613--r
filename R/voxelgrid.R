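#' 3D scalar volume with physical geometry
#'
#' A `VoxelGrid` stores a 3D array of scalar intensities (arbitrary CBCT
#' gray-value units) together with its physical geometry: voxel spacing in mm,
#' the physical position of voxel (0,0,0), and a direction-cosine matrix.
#' Physical coordinates follow the LPS convention common to medical-imaging
#' headers; a voxel's physical position is the position of its center, and
#' voxel indices are 0-based in all geometry computations.
#'
#' @param values numeric 3D array (or vector with `dims`).
#' @param spacing positive numeric length-3, mm per axis.
#' @param origin numeric length-3, mm position of the center of voxel (0,0,0).
#' @param direction 3x3 direction-cosine matrix, orthonormal with det +1.
#' @param dims integer length-3, required when `values` is not an array.
#' @return an object of class `VoxelGrid`.
#' @export
voxel_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       direction = diag(3), dims = NULL) {
  if (is.null(dim(values))) {
    if (is.null(dims)) stop("`dims` required when `values` is not an array")
    values <- array(as.numeric(values), dim = dims)
  }
  g <- structure(list(
    dims = as.integer(dim(values)),
    spacing = as.numeric(spacing),
    origin = as.numeric(origin),
    direction = matrix(as.numeric(direction), 3, 3),
    values = values
  ), class = "VoxelGrid")
  validate_grid(g)
  g
}

validate_grid <- function(g) {
  stopifnot(length(g$dims) == 3, all(g$dims >= 1))
  if (any(g$spacing <= 0)) stop("spacing components must be positive")
  D <- g$direction
  if (max(abs(crossprod(D) - diag(3))) > 1e-6)
    stop("direction matrix is not orthonormal")
  if (det(D) < 0) stop("direction matrix must have determinant +1")
  if (length(g$values) != prod(g$dims))
    stop("number of values does not match dims")
  invisible(g)
}

#' Integer-coded segmentation sharing a grid's geometry
#'
#' A `LabelMap` carries one nonnegative integer code per voxel on the same
#' geometry as its parent [voxel_grid()]. Code 0 is reserved for
#' unlabeled/background; every nonzero code present must appear in the legend.
#'
#' @param codes integer 3D array (or vector with geometry from `geometry`).
#' @param geometry a `VoxelGrid` (or `LabelMap`) providing the geometry.
#' @param legend named integer vector mapping semantic names to codes,
#'   e.g. `c(bone = 1, background = 2)`.
#' @return an object of class `LabelMap`.
#' @export
label_map <- function(codes, geometry, legend = NULL) {
  if (is.null(dim(codes))) codes <- array(as.integer(codes), dim = geometry$dims)
  storage.mode(codes) <- "integer"
  if (!identical(as.integer(dim(codes)), as.integer(geometry$dims)))
    stop("codes dims do not match geometry dims")
  present <- sort(unique(as.integer(codes)))
  present <- present[present != 0L]
  if (is.null(legend)) {
    legend <- stats::setNames(present, if (length(present))
      paste0("label", present) else character(0))
  }
  if (any(as.integer(codes) < 0L)) stop("label codes must be nonnegative")
  if (!all(present %in% legend))
    stop("codes present but missing from legend: ",
         paste(setdiff(present, legend), collapse = ", "))
  structure(list(
    dims = geometry$dims, spacing = geometry$spacing, origin = geometry$origin,
    direction = geometry$direction, codes = codes,
    legend = stats::setNames(as.integer(legend), names(legend))
  ), class = "LabelMap")
}

#' @export
print.VoxelGrid <- function(x, ...) {
  cat("VoxelGrid", paste(x$dims, collapse = " x "),
      "| spacing (mm):", paste(signif(x$spacing, 6), collapse = ", "),
      "| range:", paste(signif(range(x$values), 6), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
print.LabelMap <- function(x, ...) {
  cat("LabelMap", paste(x$dims, collapse = " x "),
      "| codes:", paste(sort(unique(as.vector(x$codes))), collapse = ", "), "\n")
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(as.integer(a$dims), as.integer(b$dims)) &&
    max(abs(a$spacing - b$spacing)) <= tol * max(1, max(abs(a$spacing))) &&
    max(abs(a$origin - b$origin)) <= tol * max(1, max(abs(a$origin))) &&
    max(abs(a$direction - b$direction)) <= 1e-9
}

#' Volume of a single voxel in cubic millimetres
#'
#' The product of the three spacing components; invariant to origin and
#' orientation. At the 0.25 mm isotropic spacing typical of high-resolution
#' dental CBCT this is 0.015625 mm^3.
#'
#' @param grid a `VoxelGrid` or `LabelMap`.
#' @return voxel volume in mm^3.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

## index (0-based, columns of a 3xN matrix) -> physical mm
index_to_physical <- function(grid, idx) {
  idx <- matrix(idx, nrow = 3)
  grid$direction %*% (idx * grid$spacing) + grid$origin
}

## physical mm -> continuous 0-based index
physical_to_index <- function(grid, pts) {
  pts <- matrix(pts, nrow = 3)
  (t(grid$direction) %*% (pts - grid$origin)) / grid$spacing
}

## affine (3x4) mapping this grid's 0-based indices to physical mm
index_affine <- function(grid) {
  cbind(grid$direction %*% diag(grid$spacing, 3), grid$origin)
}

grid_center <- function(grid) {
  as.numeric(index_to_physical(grid, (grid$dims - 1) / 2))
}

#' Resample a label map onto a reference grid
#'
#' Nearest-neighbor resampling of integer codes onto the geometry of
#' `reference`, through a rigid transform mapping reference physical space
#' into the label map's physical space (the transform returned by
#' [register_rigid()] when `reference` was the fixed image). Labels are never
#' interpolated; voxels mapping outside the input domain receive code 0.
#'
#' @param labels a `LabelMap`.
#' @param reference a `VoxelGrid` or `LabelMap` supplying the output geometry.
#' @param transform a rigid transform from [rigid_transform()]; identity by
#'   default.
#' @return a `LabelMap` on the reference geometry.
#' @export
resample_labels <- function(labels, reference, transform = rigid_identity()) {
  A <- resample_index_map(labels, reference, transform)
  out <- cpp_resample_nn(as.vector(labels$codes), labels$dims,
                         reference$dims, A)
  label_map(array(out, dim = reference$dims), reference, legend = labels$legend)
}

#' Resample an intensity volume onto a reference grid (trilinear)
#'
#' @inheritParams resample_labels
#' @param grid a `VoxelGrid`.
#' @param outside value assigned outside the input domain.
#' @return a `VoxelGrid` on the reference geometry.
#' @export
resample_intensity <- function(grid, reference, transform = rigid_identity(),
                               outside = 0) {
  A <- resample_index_map(grid, reference, transform)
  out <- cpp_resample_trilinear(as.vector(grid$values), grid$dims,
                                reference$dims, A, outside)
  voxel_grid(array(out, dim = reference$dims), reference$spacing,
             reference$origin, reference$direction)
}

## full chain: reference index -> reference phys -> transform -> input index
resample_index_map <- function(input, reference, transform) {
  Aref <- index_affine(reference)          # ref idx -> phys
  R <- transform$rotation
  cvec <- transform$center
  tvec <- transform$translation
  ## p' = R (p - c) + c + t
  M <- R %*% Aref[, 1:3]
  b <- R %*% (Aref[, 4] - cvec) + cvec + tvec
  ## input phys -> input idx
  Din <- t(input$direction) / input$spacing  # rows scaled
  Mi <- Din %*% M
  bi <- Din %*% (b - input$origin)
  cbind(Mi, as.numeric(bi))
}
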