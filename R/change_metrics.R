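#' Logical-operator subtraction of two label maps
#'
#' Output code 1 exactly where `a` carries `code` and `b` does not — the
#' "new hard tissue" model obtained by subtracting the baseline segmentation
#' from a follow-up segmentation after both live on the same (baseline) grid.
#'
#' @param a,b `LabelMap`s on identical geometry.
#' @param code label code compared (default 1).
#' @return a `LabelMap` with codes {0, 1}.
#' @export
label_difference <- function(a, b, code = 1L) {
  if (!same_geometry(a, b)) stop("label map geometry mismatch")
  out <- (a$codes == code) & (b$codes != code)
  label_map(array(as.integer(out), dim = a$dims), a,
            legend = c(difference = 1L))
}

#' Logical intersection of two label maps
#'
#' @inheritParams label_difference
#' @return a `LabelMap` with codes {0, 1}.
#' @export
label_intersection <- function(a, b, code = 1L) {
  if (!same_geometry(a, b)) stop("label map geometry mismatch")
  out <- (a$codes == code) & (b$codes == code)
  label_map(array(as.integer(out), dim = a$dims), a,
            legend = c(intersection = 1L))
}

#' Labeled volume in cubic centimetres
#'
#' Voxel count times voxel volume, reported in cm^3 as in volumetric
#' hard-tissue outcome tables.
#'
#' @param labels a `LabelMap`.
#' @param code label code counted (default 1).
#' @return volume in cm^3.
#' @export
volume_cm3 <- function(labels, code = 1L) {
  sum(labels$codes == code) * voxel_volume(labels) / 1000
}

#' T3/T2 volume-stability ratio (percent)
#'
#' The share of the hard-tissue volume newly present at the early follow-up
#' (T2) that is still present at the late follow-up (T3): `100 * vT3 / vT2`.
#'
#' @param v_t3,v_t2 volumes in cm^3; `v_t2` must be positive.
#' @return ratio in percent.
#' @export
stability_ratio <- function(v_t3, v_t2) {
  if (v_t2 <= 0) stop("stability ratio undefined: T2 volume is not positive")
  100 * v_t3 / v_t2
}

#' Dice similarity coefficient between two label maps
#'
#' `2 |A intersect B| / (|A| + |B|)` over the voxel sets carrying `code`.
#' When both sets are empty the coefficient is defined as 1 (the two models
#' agree that there is nothing).
#'
#' @param a,b `LabelMap`s on identical geometry.
#' @param code label code compared (default 1).
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b, code = 1L) {
  if (!same_geometry(a, b)) stop("label map geometry mismatch")
  na <- sum(a$codes == code)
  nb <- sum(b$codes == code)
  if (na + nb == 0) return(1)
  2 * sum(a$codes == code & b$codes == code) / (na + nb)
}

#' Signed surface distances for colormap rendering
#'
#' For every vertex of the reference label's isosurface, the Euclidean
#' distance (mm) to the comparison label's surface, signed negative where
#' the comparison has receded relative to the reference (hard-tissue loss,
#' rendered red) and positive where it extends beyond it (gain, blue).
#' Distances come from interpolating the comparison label's signed distance
#' field at the reference vertices.
#'
#' @param reference,comparison `LabelMap`s on identical geometry; the
#'   reference must be nonempty.
#' @param code label code compared (default 1).
#' @return a [surface_mesh()] of the reference with per-vertex signed
#'   distances in `$scalars`.
#' @export
signed_surface_distances <- function(reference, comparison, code = 1L) {
  if (!same_geometry(reference, comparison)) stop("geometry mismatch")
  if (!any(reference$codes == code)) stop("reference label is empty")
  mesh <- extract_surface(reference, code)
  cmp <- as.integer(comparison$codes == code)
  if (!any(cmp != 0L)) {
    warning("comparison label is empty; distances measure to nothing ",
            "and are reported as -Inf")
    mesh$scalars <- rep(-Inf, nrow(mesh$vertices))
    return(mesh)
  }
  d_out <- sqrt(cpp_edt_sq(cmp, reference$dims, reference$spacing))
  d_in <- sqrt(cpp_edt_sq(1L - cmp, reference$dims, reference$spacing))
  sd_field <- d_in - d_out   # positive inside the comparison, negative outside
  pts <- t(physical_to_index(reference, t(mesh$vertices)))
  mesh$scalars <- cpp_sample_points(sd_field, reference$dims, pts)
  mesh
}

#' Implantation-site specification for linear ridge measurements
#'
#' @param site_id site identifier (FDI tooth position, e.g. 11).
#' @param crest_point mm coordinates of the crest reference point.
#' @param buccolingual_axis unit vector of the buccolingual direction (mm
#'   space); normalized internally.
#' @param vertical_axis unit vector of the vertical (apicocoronal)
#'   direction; defaults to +z.
#' @param reference_offset mm from the crest point down to the vertical
#'   reference plane used for height measurement.
#' @param depths mm below the crest at which horizontal widths are taken
#'   (positive ascending; default 1, 3, 5 mm).
#' @return an object of class `SiteSpec`.
#' @export
site_spec <- function(site_id, crest_point, buccolingual_axis,
                      vertical_axis = c(0, 0, 1), reference_offset = 10,
                      depths = c(1, 3, 5)) {
  if (any(diff(depths) <= 0) || any(depths <= 0))
    stop("depths must be positive and ascending")
  nb <- sqrt(sum(buccolingual_axis^2)); nv <- sqrt(sum(vertical_axis^2))
  structure(list(site_id = site_id, crest_point = as.numeric(crest_point),
                 buccolingual_axis = as.numeric(buccolingual_axis) / nb,
                 vertical_axis = as.numeric(vertical_axis) / nv,
                 reference_offset = reference_offset,
                 depths = as.numeric(depths)),
            class = "SiteSpec")
}

#' Linear ridge dimensions at an implantation site
#'
#' On the cross-sectional plane through the crest reference point spanned by
#' the buccolingual and vertical axes: the horizontal width at each depth is
#' the bone-covered chord length along the buccolingual axis at that depth
#' below the crest; the vertical height is the distance from the reference
#' plane (`reference_offset` mm below the crest point) to the most coronal
#' bone sample along the vertical line through the crest point.
#'
#' @param bone a `LabelMap` of the (hard-tissue) bone.
#' @param site a [site_spec()].
#' @param code bone code (default 1).
#' @param step sampling step along measurement lines in mm (default half the
#'   smallest spacing).
#' @return list with `widths_mm` (named by depth), `height_mm`, `site_id`.
#' @export
ridge_linear_measurements <- function(bone, site, code = 1L, step = NULL) {
  if (is.null(step)) step <- min(bone$spacing) / 2
  half_range <- sum(bone$dims * bone$spacing)  # generous scan range
  ts <- seq(-half_range / 2, half_range / 2, by = step)
  inside <- function(pts) {
    idx <- physical_to_index(bone, pts)
    ii <- round(idx) + 1
    ok <- ii[1, ] >= 1 & ii[1, ] <= bone$dims[1] &
      ii[2, ] >= 1 & ii[2, ] <= bone$dims[2] &
      ii[3, ] >= 1 & ii[3, ] <= bone$dims[3]
    res <- logical(ncol(pts))
    if (any(ok)) {
      lin <- ii[1, ok] + bone$dims[1] * ((ii[2, ok] - 1) +
                                           bone$dims[2] * (ii[3, ok] - 1))
      res[ok] <- bone$codes[lin] == code
    }
    res
  }
  widths <- vapply(site$depths, function(d) {
    p0 <- site$crest_point - d * site$vertical_axis
    pts <- p0 + outer(site$buccolingual_axis, ts)
    hit <- inside(pts)
    if (!any(hit)) return(0)
    sum(hit) * step
  }, numeric(1))
  if (all(widths == 0))
    warning("measurement plane misses the bone label at site ", site$site_id)
  ## vertical height: scan up from the reference plane along the vertical axis
  hs <- seq(0, site$reference_offset + half_range / 2, by = step)
  pref <- site$crest_point - site$reference_offset * site$vertical_axis
  ptsv <- pref + outer(site$vertical_axis, hs)
  hitv <- inside(ptsv)
  height <- if (any(hitv)) max(hs[hitv]) else 0
  list(site_id = site$site_id,
       widths_mm = stats::setNames(widths, paste0("depth_", site$depths, "mm")),
       height_mm = height)
}
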