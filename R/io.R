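#' Read a 3D volume (NRRD or NIfTI-1)
#'
#' Geometry (spacing, origin, direction cosines) is taken from the file
#' header and expressed in LPS physical coordinates. NIfTI headers, which are
#' RAS by convention, are converted on the fly.
#'
#' @param path path to a `.nrrd`, `.nii` or `.nii.gz` file.
#' @return a [voxel_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "nrrd") return(read_nrrd(path))
  if (ext == "nii") return(read_nifti_grid(path))
  stop("unsupported volume format: ", path)
}

#' Write a 3D volume or label map (NRRD or NIfTI-1)
#'
#' Label maps are stored with an integer voxel type so that codes round-trip
#' exactly; intensity volumes are stored as double (NRRD) or float64 (NIfTI).
#'
#' @param grid a `VoxelGrid` or `LabelMap`.
#' @param path output path ending in `.nrrd`, `.nii` or `.nii.gz`.
#' @export
write_volume <- function(grid, path) {
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  is_labels <- inherits(grid, "LabelMap")
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "nrrd") {
    write_nrrd(grid, path, integer_type = is_labels)
  } else if (ext == "nii") {
    write_nifti_grid(grid, path, integer_type = is_labels)
  } else stop("unsupported volume format: ", path)
  invisible(path)
}

#' Read a label map written by [write_volume()]
#'
#' @param path volume file path.
#' @param legend optional named code vector; defaults to auto-generated names.
#' @return a [label_map()].
#' @export
read_labels <- function(path, legend = NULL) {
  g <- read_volume(path)
  codes <- round(g$values)
  if (max(abs(codes - g$values)) > 1e-6)
    stop("volume does not contain integer codes: ", path)
  label_map(array(as.integer(codes), dim = g$dims), g, legend = legend)
}

## ---- NRRD (subset: 3D, raw/text encodings, little endian) ----

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD000[1-5]$", magic)) stop("not a NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated NRRD header: ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  dims <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(dims) != 3) stop("only 3D NRRD supported: ", path)
  type <- fields$type
  enc <- tolower(fields$encoding)
  n <- prod(dims)
  if (enc == "raw") {
    endian <- if (!is.null(fields$endian)) fields$endian else "little"
    rb <- function(what, size) readBin(con, what, n = n, size = size,
                                       endian = endian)
    vals <- switch(type,
      "double" = rb("double", 8), "float" = rb("double", 4),
      "int" = , "int32" = , "signed int" = rb("integer", 4),
      "short" = , "int16" = , "signed short" = rb("integer", 2),
      "uchar" = , "uint8" = , "unsigned char" = as.numeric(rb("integer", 1)),
      stop("unsupported NRRD type: ", type))
  } else if (enc %in% c("txt", "text", "ascii")) {
    vals <- scan(con, what = numeric(), n = n, quiet = TRUE)
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("truncated NRRD data: ", path)

  spacing <- c(1, 1, 1); direction <- diag(3); origin <- c(0, 0, 0)
  if (!is.null(fields[["space directions"]])) {
    vecs <- parse_nrrd_vectors(fields[["space directions"]])
    M <- do.call(cbind, vecs)
    spacing <- sqrt(colSums(M^2))
    direction <- sweep(M, 2, spacing, "/")
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  }
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("non-orthonormal direction matrix in ", path)
  voxel_grid(array(as.numeric(vals), dim = dims), spacing, origin, direction)
}

parse_nrrd_vectors <- function(s) {
  m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(m, function(v) as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
}

write_nrrd <- function(grid, path, integer_type = FALSE) {
  M <- grid$direction %*% diag(grid$spacing, 3)
  fmt_vec <- function(v) sprintf("(%.17g,%.17g,%.17g)", v[1], v[2], v[3])
  vals <- if (inherits(grid, "LabelMap")) grid$codes else grid$values
  hdr <- c("NRRD0004",
           paste0("type: ", if (integer_type) "int32" else "double"),
           "dimension: 3",
           paste0("sizes: ", paste(grid$dims, collapse = " ")),
           "space: left-posterior-superior",
           paste0("space directions: ", paste(apply(M, 2, fmt_vec),
                                              collapse = " ")),
           paste0("space origin: ", fmt_vec(grid$origin)),
           "kinds: domain domain domain",
           "endian: little",
           "encoding: raw",
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (integer_type) {
    writeBin(as.integer(vals), con, size = 4, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = 8, endian = "little")
  }
  invisible(path)
}

## ---- NIfTI-1 via RNifti (RAS <-> LPS conversion) ----

read_nifti_grid <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), class = NULL)  # index -> RAS mm
  aff_lps <- diag(c(-1, -1, 1, 1)) %*% aff
  M <- aff_lps[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  direction <- sweep(M, 2, spacing, "/")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6 || det(direction) < 0)
    stop("non-orthonormal direction matrix in ", path)
  vals <- array(as.numeric(img), dim = dim(img))
  voxel_grid(vals, spacing, as.numeric(aff_lps[1:3, 4]), direction)
}

write_nifti_grid <- function(grid, path, integer_type = FALSE) {
  vals <- if (inherits(grid, "LabelMap")) grid$codes else grid$values
  img <- RNifti::asNifti(array(as.numeric(vals), dim = grid$dims))
  ## NIfTI stores voxel scale in pixdim; the quaternion qform carries only
  ## rotation and origin, so set both
  RNifti::pixdim(img) <- grid$spacing
  aff_lps <- rbind(cbind(grid$direction %*% diag(grid$spacing, 3),
                         grid$origin), c(0, 0, 0, 1))
  aff_ras <- diag(c(-1, -1, 1, 1)) %*% aff_lps
  RNifti::qform(img) <- structure(aff_ras, code = 2L)
  RNifti::sform(img) <- structure(aff_ras, code = 2L)
  RNifti::writeNifti(img, path,
                     datatype = if (integer_type) "int32" else "double")
  invisible(path)
}

## ---- surface meshes ----

#' Surface mesh container
#'
#' Vertices in physical mm coordinates and 1-based triangle indices.
#'
#' @param vertices N x 3 numeric matrix (mm).
#' @param triangles M x 3 integer matrix of vertex indices (1-based).
#' @param scalars optional per-vertex numeric attribute (e.g. signed
#'   surface distance for colormap rendering).
#' @return an object of class `SurfaceMesh`.
#' @export
surface_mesh <- function(vertices, triangles, scalars = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1 || max(triangles) > nrow(vertices)))
    stop("triangle references an out-of-range vertex")
  structure(list(vertices = vertices, triangles = triangles,
                 scalars = scalars), class = "SurfaceMesh")
}

#' @export
print.SurfaceMesh <- function(x, ...) {
  cat("SurfaceMesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  invisible(x)
}

#' Write a surface mesh to STL (binary) or PLY (ASCII)
#'
#' PLY output carries the mesh's per-vertex scalar attribute (if any) as a
#' `quality` property, the conventional slot for colormap scalars.
#'
#' @param mesh a `SurfaceMesh`.
#' @param path output path ending in `.stl` or `.ply`.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") write_stl_binary(mesh, path)
  else if (ext == "ply") write_ply_ascii(mesh, path)
  else stop("unsupported mesh format: ", path)
  invisible(path)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(formatC("cbctvol binary STL", width = 80, flag = "-"))
  writeBin(hdr[1:80], con)
  nt <- nrow(mesh$triangles)
  writeBin(as.integer(nt), con, size = 4, endian = "little")
  V <- mesh$vertices
  for (r in seq_len(nt)) {
    p <- V[mesh$triangles[r, ], , drop = FALSE]
    nrm <- pracma_cross(p[2, ] - p[1, ], p[3, ] - p[1, ])
    nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
    writeBin(as.numeric(c(nrm, t(p))), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

write_ply_ascii <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  has_q <- !is.null(mesh$scalars)
  hdr <- c("ply", "format ascii 1.0", "comment cbctvol surface",
           paste("element vertex", nv),
           "property float x", "property float y", "property float z",
           if (has_q) "property float quality",
           paste("element face", nt),
           "property list uchar int vertex_indices", "end_header")
  vlines <- if (has_q) {
    paste(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
          mesh$scalars)
  } else {
    paste(mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  }
  flines <- paste(3, mesh$triangles[, 1] - 1, mesh$triangles[, 2] - 1,
                  mesh$triangles[, 3] - 1)
  writeLines(c(hdr, vlines, flines), path)
  invisible(path)
}
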