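#' Extract a closed triangulated isosurface of a label code
#'
#' Marching tetrahedra on the binary indicator of `code` at the 0.5
#' iso-level. The field is zero-padded by one voxel so surfaces touching the
#' grid boundary close properly. Vertices are returned in physical (mm)
#' coordinates; triangles are consistently oriented with outward normals, so
#' [mesh_volume()] integrates the enclosed volume.
#'
#' @param labels a [label_map()].
#' @param code integer code to surface.
#' @return a [surface_mesh()]; empty (with a warning) when the code is absent.
#' @export
extract_surface <- function(labels, code) {
  if (!code %in% labels$legend && !code %in% labels$codes) {
    warning("code ", code, " absent from label map; returning empty mesh")
    return(surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  }
  mask <- array(0L, dim = labels$dims + 2L)
  mask[2:(labels$dims[1] + 1), 2:(labels$dims[2] + 1),
       2:(labels$dims[3] + 1)] <- (labels$codes == code) * 1L
  if (!any(mask != 0L)) {
    warning("code ", code, " has no voxels; returning empty mesh")
    return(surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  }
  res <- cpp_marching_tetra(as.vector(mask), dim(mask), offset = -1)
  V <- res$vertices                      # continuous 0-based index coords
  P <- t(index_to_physical(labels, t(V)))
  surface_mesh(P, res$triangles)
}

#' Enclosed volume of a closed oriented mesh (mm^3)
#'
#' Divergence-theorem integral over the oriented triangles; the absolute
#' value is returned so either global orientation yields the volume.
#'
#' @param mesh a `SurfaceMesh`.
#' @return enclosed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  if (nrow(mesh$triangles) == 0) return(0)
  V <- mesh$vertices
  p0 <- V[mesh$triangles[, 1], , drop = FALSE]
  p1 <- V[mesh$triangles[, 2], , drop = FALSE]
  p2 <- V[mesh$triangles[, 3], , drop = FALSE]
  cx <- p1[, 2] * p2[, 3] - p1[, 3] * p2[, 2]
  cy <- p1[, 3] * p2[, 1] - p1[, 1] * p2[, 3]
  cz <- p1[, 1] * p2[, 2] - p1[, 2] * p2[, 1]
  abs(sum(p0[, 1] * cx + p0[, 2] * cy + p0[, 3] * cz) / 6)
}

#' Number of connected components of a mesh
#'
#' Union-find over shared vertices (the isosurfacer deduplicates vertices, so
#' topologically connected sheets share vertex indices).
#'
#' @param mesh a `SurfaceMesh`.
#' @return integer component count.
#' @export
mesh_components <- function(mesh) {
  nv <- nrow(mesh$vertices)
  if (nv == 0) return(0L)
  parent <- seq_len(nv)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(mesh$triangles))) {
    tr <- mesh$triangles[r, ]
    a <- find(tr[1]); b <- find(tr[2]); c <- find(tr[3])
    if (b != a) parent[b] <- a
    c2 <- find(tr[3])
    if (c2 != a) parent[c2] <- a
  }
  roots <- vapply(seq_len(nv), find, integer(1))
  length(unique(roots[unique(as.vector(mesh$triangles))]))
}
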