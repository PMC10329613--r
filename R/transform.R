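#' Rigid transforms in physical (mm) space
#'
#' A rigid transform maps a physical point p to `R (p - c) + c + t`, where
#' `R` is a rotation matrix, `c` the rotation center and `t` a translation.
#' Registration returns the transform taking fixed-image physical points into
#' moving-image physical space.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation numeric length-3, mm.
#' @param center numeric length-3, mm rotation center.
#' @return an object of class `RigidTransform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0) stop("rotation must be proper (det +1)")
  structure(list(rotation = rotation,
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "RigidTransform")
}

#' @rdname rigid_transform
#' @export
rigid_identity <- function() rigid_transform()

#' Rotation matrix from Euler angles (degrees)
#'
#' Angles are applied as `Rz %*% Ry %*% Rx` (extrinsic x-y-z order).
#'
#' @param rx,ry,rz rotation about each axis in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_rotation <- function(rx = 0, ry = 0, rz = 0) {
  a <- rx * pi / 180; b <- ry * pi / 180; g <- rz * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Apply a rigid transform to points
#'
#' @param t a `RigidTransform`.
#' @param p numeric length-3 point or 3xN matrix of points (mm).
#' @return transformed point(s), same shape as `p`.
#' @export
apply_point <- function(t, p) {
  was_vec <- is.null(dim(p))
  p <- matrix(p, nrow = 3)
  out <- t$rotation %*% (p - t$center) + t$center + t$translation
  if (was_vec) as.numeric(out) else out
}

#' Compose and invert rigid transforms
#'
#' `compose_rigid(a, b)` is the transform applying `b` first, then `a`:
#' `apply_point(compose_rigid(a, b), p) == apply_point(a, apply_point(b, p))`.
#'
#' @param a,b,t `RigidTransform` objects.
#' @return a `RigidTransform`.
#' @export
compose_rigid <- function(a, b) {
  ## write each as p -> R p + d with d = c + t - R c
  Ra <- a$rotation; da <- a$center + a$translation - Ra %*% a$center
  Rb <- b$rotation; db <- b$center + b$translation - Rb %*% b$center
  R <- Ra %*% Rb
  d <- as.numeric(Ra %*% db + da)
  rigid_transform(R, translation = d, center = c(0, 0, 0))
}

#' @rdname compose_rigid
#' @export
invert_rigid <- function(t) {
  R <- t$rotation; d <- t$center + t$translation - R %*% t$center
  Ri <- t(R)
  rigid_transform(Ri, translation = as.numeric(-Ri %*% d), center = c(0, 0, 0))
}

## decompose a rotation matrix into its angle (degrees) for error reporting
rotation_angle_deg <- function(R) {
  cosang <- (sum(diag(R)) - 1) / 2
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

## effective translation comparing two transforms at a reference point
transform_param_distance <- function(a, b, at = c(0, 0, 0)) {
  dR <- t(a$rotation) %*% b$rotation
  ang <- rotation_angle_deg(dR)
  dt <- apply_point(a, at) - apply_point(b, at)
  list(angle_deg = ang, translation_mm = sqrt(sum(dt^2)))
}

#' Serialize / read a rigid transform as JSON
#'
#' @param t a `RigidTransform`; `path` a file path.
#' @param path file path.
#' @param extra named list of extra fields (e.g. metric, convergence report).
#' @export
write_transform_json <- function(t, path, extra = list()) {
  obj <- c(list(rotation = unname(apply(t$rotation, 1, as.numeric, simplify = FALSE)),
                translation = t$translation, center = t$center), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  R <- if (is.matrix(obj$rotation)) {
    matrix(as.numeric(obj$rotation), 3, 3)   # rows already rows
  } else {
    t(matrix(unlist(obj$rotation), 3, 3))    # list of row vectors
  }
  rigid_transform(R, obj$translation, obj$center)
}
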