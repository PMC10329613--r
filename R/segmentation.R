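#' Seed sets for semi-automatic segmentation
#'
#' A seed set lists labeled voxel indices (0-based triples) from which
#' region growing or watershed flooding starts, mirroring seed points placed
#' on the planar views of a CBCT dataset.
#'
#' @param index N x 3 integer matrix of 0-based voxel indices.
#' @param label integer code per seed (0 is not a valid seed code).
#' @param names optional semantic name per distinct label.
#' @return an object of class `SeedSet`.
#' @export
seed_set <- function(index, label, names = NULL) {
  index <- matrix(as.integer(index), ncol = 3)
  label <- as.integer(label)
  if (nrow(index) != length(label)) stop("one label per seed index required")
  if (any(label <= 0)) stop("seed labels must be positive")
  key <- paste(index[, 1], index[, 2], index[, 3])
  dup <- duplicated(key)
  if (any(dup)) {
    for (k in unique(key[dup])) {
      if (length(unique(label[key == k])) > 1)
        stop("seed index assigned two different codes: ", k)
    }
  }
  lev <- sort(unique(label))
  if (is.null(names)) names <- paste0("label", lev)
  structure(list(index = index, label = label,
                 legend = stats::setNames(lev, names)),
            class = "SeedSet")
}

#' Read seeds from a JSON annotation file
#'
#' Format: `[{"index": [i,j,k], "label": n, "name": "bone"}, ...]` with
#' 0-based indices.
#'
#' @param path JSON file path.
#' @return a [seed_set()].
#' @export
read_seeds_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  idx <- t(vapply(obj, function(e) as.integer(unlist(e$index)), integer(3)))
  lab <- vapply(obj, function(e) as.integer(e$label), integer(1))
  nm <- vapply(obj, function(e) if (is.null(e$name)) NA_character_
               else as.character(e$name), character(1))
  lev <- sort(unique(lab))
  names <- vapply(lev, function(l) {
    n <- nm[lab == l & !is.na(nm)]
    if (length(n)) n[1] else paste0("label", l)
  }, character(1))
  seed_set(idx, lab, names)
}

#' @rdname read_seeds_json
#' @param seeds a `SeedSet`.
#' @export
write_seeds_json <- function(seeds, path) {
  nm <- names(seeds$legend)[match(seeds$label, seeds$legend)]
  obj <- lapply(seq_along(seeds$label), function(r)
    list(index = seeds$index[r, ], label = seeds$label[r], name = nm[r]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

check_seeds_in_grid <- function(seeds, grid) {
  ok <- seeds$index[, 1] >= 0 & seeds$index[, 1] < grid$dims[1] &
    seeds$index[, 2] >= 0 & seeds$index[, 2] < grid$dims[2] &
    seeds$index[, 3] >= 0 & seeds$index[, 3] < grid$dims[3]
  if (!all(ok)) stop("seed outside grid at row(s): ",
                     paste(which(!ok), collapse = ", "))
  ## 0-based linear indices
  seeds$index[, 1] + grid$dims[1] *
    (seeds$index[, 2] + grid$dims[2] * seeds$index[, 3])
}

#' Intensity gate (gray-value window)
#'
#' @param lo,hi inclusive gray-value bounds, `lo <= hi`.
#' @return an object of class `IntensityGate`.
#' @export
intensity_gate <- function(lo, hi) {
  if (lo > hi) stop("gate lo must be <= hi")
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi)),
            class = "IntensityGate")
}

#' Competitive seeded region growing
#'
#' Every voxel is assigned to exactly one of the seeded labels. Each seed
#' grows its own region, so a label may be represented by several competing
#' regions (e.g. trabecular and cortical bone seeds both carrying the bone
#' code, or soft-tissue plus per-tooth seeds all carrying the background
#' code) — this keeps a region's mean from being polluted by a second
#' tissue compartment of the same label. Unlabeled voxels are claimed
#' through a priority queue keyed by the absolute difference between the
#' voxel intensity and the claiming region's reference mean; intensity ties
#' fall back to geodesic step count, then to (smaller label code,
#' lexicographic voxel index). Growth uses 6-connectivity and is
#' deterministic and independent of the order in which seeds are listed.
#'
#' Two reference-mean modes are available. `"frozen"` (default) fixes each
#' region's mean to the mean intensity of a small ball around its seed —
#' the tissue sample the rater clicked on. Two regions then compete for a
#' boundary voxel exactly at the midpoint of their seed intensities, so the
#' segmented surface is an iso-intensity surface that is reproducible
#' across serial scans of the same anatomy. `"running"` updates each
#' region's mean with every voxel it absorbs; it adapts to drifting
#' intensities but couples the boundary position to the claiming history,
#' which can shift boundaries between scans.
#'
#' @param grid a [voxel_grid()].
#' @param seeds a [seed_set()] with at least two distinct labels.
#' @param means `"frozen"` or `"running"` (see Details).
#' @param sample_radius_mm radius of the seed sample ball for frozen means.
#' @return a [label_map()] partitioning the grid into the seeded codes.
#' @export
grow_from_seeds <- function(grid, seeds, means = c("frozen", "running"),
                            sample_radius_mm = 1) {
  means <- match.arg(means)
  if (!inherits(seeds, "SeedSet") || nrow(seeds$index) == 0)
    stop("a non-empty SeedSet is required")
  if (length(unique(seeds$label)) < 2)
    stop("region growing needs >= 2 distinct seed labels ",
         "(competition is undefined otherwise)")
  lin <- check_seeds_in_grid(seeds, grid)
  ## canonical seed order (label, then index) -> result cannot depend on
  ## how the rater happened to list the seeds
  ord <- order(seeds$label, lin)
  fixed_means <- if (means == "frozen") {
    vapply(ord, function(s) seed_ball_mean(grid, seeds$index[s, ],
                                           sample_radius_mm), numeric(1))
  } else numeric(0)
  out <- cpp_region_grow(as.vector(grid$values), grid$dims,
                         as.integer(lin[ord]), seeds$label[ord], fixed_means)
  label_map(array(out, dim = grid$dims), grid,
            legend = seeds$legend)
}

## mean intensity of the ball of radius r_mm around a 0-based voxel index
seed_ball_mean <- function(grid, idx0, r_mm) {
  r_vox <- pmax(0L, as.integer(floor(r_mm / grid$spacing)))
  lo <- pmax(idx0 - r_vox, 0L) + 1L
  hi <- pmin(idx0 + r_vox, grid$dims - 1L) + 1L
  sub <- grid$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  xs <- (lo[1]:hi[1] - 1L - idx0[1]) * grid$spacing[1]
  ys <- (lo[2]:hi[2] - 1L - idx0[2]) * grid$spacing[2]
  zs <- (lo[3]:hi[3] - 1L - idx0[3]) * grid$spacing[3]
  D2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  mean(sub[D2 <= r_mm^2])
}

#' Seeded watershed segmentation within an intensity gate
#'
#' Voxels outside `[gate$lo, gate$hi]` receive code 0. Gated voxels are
#' flooded from the seeds over the gradient-magnitude landscape of the
#' (optionally Gaussian-smoothed) intensity volume, so boundaries form along
#' gradient ridges — one code per seed label, used to separate individual
#' teeth sharing the enamel/dentin intensity window.
#'
#' @param grid a [voxel_grid()].
#' @param seeds a [seed_set()]; every seed must lie inside the gate.
#' @param gate an [intensity_gate()].
#' @param sigma_vox Gaussian pre-smoothing in voxels (default 1) applied
#'   before the gradient; 0 disables smoothing.
#' @return a [label_map()].
#' @export
watershed_from_seeds <- function(grid, seeds, gate, sigma_vox = 1) {
  if (!inherits(seeds, "SeedSet") || nrow(seeds$index) == 0)
    stop("a non-empty SeedSet is required")
  lin <- check_seeds_in_grid(seeds, grid)
  sv <- grid$values[lin + 1]
  bad <- sv < gate$lo | sv > gate$hi
  if (any(bad))
    stop("seed(s) outside the intensity gate at row(s): ",
         paste(which(bad), collapse = ", "),
         " (values ", paste(signif(sv[bad], 6), collapse = ", "), ")")
  sm <- if (sigma_vox > 0) {
    cpp_gaussian_blur(as.vector(grid$values), grid$dims, rep(sigma_vox, 3))
  } else as.vector(grid$values)
  landscape <- cpp_gradient_magnitude(sm, grid$dims, grid$spacing)
  gatemask <- as.integer(grid$values >= gate$lo & grid$values <= gate$hi)
  out <- cpp_watershed_flood(landscape, grid$dims, as.integer(lin),
                             seeds$label, gatemask)
  label_map(array(out, dim = grid$dims), grid, legend = seeds$legend)
}

#' Global thresholding segmentation
#'
#' Labels every voxel whose intensity falls inside the gate with code 1,
#' optionally intersected with a region-of-interest label map. This is the
#' fully automatic comparator to the semi-automatic (seeded) routes.
#'
#' @param grid a [voxel_grid()].
#' @param gate an [intensity_gate()].
#' @param roi optional `LabelMap`; only voxels with a nonzero roi code are
#'   eligible.
#' @return a [label_map()] with codes {0, 1}.
#' @export
global_threshold <- function(grid, gate, roi = NULL) {
  m <- grid$values >= gate$lo & grid$values <= gate$hi
  if (!is.null(roi)) {
    if (!same_geometry(grid, roi)) stop("roi geometry mismatch")
    m <- m & (roi$codes != 0L)
  }
  label_map(array(as.integer(m), dim = grid$dims), grid,
            legend = c(inside = 1L))
}

#' Apply a manual label edit (e.g. screw-head exclusion)
#'
#' Sets every voxel where `mask` is nonzero to `new_code`, leaving all other
#' voxels untouched. Serial graft imaging uses this to exclude the heads of
#' osteosynthesis screws from the bone label while keeping the screw bodies.
#'
#' @param labels a [label_map()] to edit.
#' @param mask a `LabelMap` on the same geometry; nonzero marks edited voxels.
#' @param new_code integer code written into the masked voxels.
#' @return the edited `LabelMap`.
#' @export
apply_label_edit <- function(labels, mask, new_code) {
  if (!same_geometry(labels, mask)) stop("mask geometry mismatch")
  codes <- labels$codes
  codes[mask$codes != 0L] <- as.integer(new_code)
  legend <- labels$legend
  if (new_code != 0 && !new_code %in% legend) {
    legend <- c(legend, stats::setNames(as.integer(new_code),
                                        paste0("label", new_code)))
  }
  label_map(codes, labels, legend = legend)
}

#' Morphological opening of a label's nonzero set
#'
#' Erosion followed by dilation with a Euclidean ball of `radius_mm`,
#' computed via distance transforms. Removes sheets and speckle thinner
#' than the ball while leaving bulky structures (up to slight edge
#' rounding) intact — used to suppress the one-voxel boundary crust that
#' nearest-neighbor label resampling can leave in difference models.
#'
#' @param labels a `LabelMap`.
#' @param radius_mm opening radius in mm; 0 disables.
#' @return the opened `LabelMap` (codes collapsed to {0, 1}).
#' @export
morphological_opening <- function(labels, radius_mm) {
  if (radius_mm <= 0) return(labels)
  mask <- as.integer(labels$codes != 0L)
  d_in <- cpp_edt_sq(1L - mask, labels$dims, labels$spacing)
  eroded <- as.integer(d_in > radius_mm^2)
  d_er <- cpp_edt_sq(eroded, labels$dims, labels$spacing)
  opened <- as.integer(d_er <= radius_mm^2)
  label_map(array(opened, labels$dims), labels, legend = c(kept = 1L))
}

#' Half-height refinement of a segmented bone boundary
#'
#' Reassigns voxels in a narrow band around the label's boundary by a local
#' half-height rule, the standard for bone boundaries in quantitative CBCT:
#' a band voxel belongs to bone when its intensity exceeds the midpoint
#' between the local mean of the nearby label interior and the local mean
#' of the nearby exterior. Both references are computed from voxels at
#' least `deep_mm` away from the boundary (excluding the partial-volume
#' ramp) with Gaussian locality `sigma_mm`, and intensities at or above
#' `cap` (metal, enamel) are excluded from the interior reference so
#' screws and tooth rims cannot inflate it. The refined surface is the
#' local half-height iso-surface of each bone/soft-tissue interface —
#' unbiased against partial-volume blur and, crucially for longitudinal
#' subtraction, reproducible across serial scans of the same anatomy
#' regardless of how the seeded growth happened to claim the
#' partial-volume band. The rule assumes bone is brighter than its
#' surroundings, so brighter non-bone structures (teeth, screw heads) must
#' be excluded separately — as the pipeline does with the watershed tooth
#' label and the screw-head mask.
#'
#' @param grid the intensity [voxel_grid()].
#' @param labels a `LabelMap` whose code-1 set is refined (other codes are
#'   treated as exterior).
#' @param band_mm half-width of the refitted boundary band, mm.
#' @param deep_mm minimum distance from the boundary for reference voxels.
#' @param sigma_mm Gaussian locality of the reference means, mm.
#' @param cap gray value at or above which voxels are excluded from the
#'   interior reference (e.g. the tooth gate's lower bound); `Inf` disables.
#' @return the refined `LabelMap` (codes {0, 1}).
#' @export
refine_boundary <- function(grid, labels, band_mm = NULL, deep_mm = NULL,
                            sigma_mm = 0.45, cap = Inf, metal_thr = Inf,
                            metal_halo_mm = 0.6) {
  r <- boundary_references(grid, labels, band_mm, deep_mm, sigma_mm, cap)
  to_bone <- r$v >= (r$m_in + r$m_out) / 2
  if (is.finite(metal_thr) && any(r$v >= metal_thr)) {
    ## partial-volume halo of metal: the intensity is dominated by the
    ## titanium, so classify by context — whichever deep tissue reference
    ## (bone vs background) dominates the neighborhood
    metal <- r$v >= metal_thr
    d_metal <- sqrt(cpp_edt_sq(as.integer(metal), grid$dims, grid$spacing))
    halo <- !metal & d_metal <= metal_halo_mm
    ## require clear bone dominance: a falsely "hard" halo ring around an
    ## exposed screw costs far more than a conservative call inside bone,
    ## where the surrounding label carries the voxel anyway
    to_bone[halo] <- r$den_in[halo] > 3 * r$den_out[halo]
  }
  codes <- as.integer(r$mask)
  codes[r$band] <- as.integer(to_bone[r$band])
  label_map(array(codes, grid$dims), grid, legend = c(bone = 1L))
}

## shared machinery of refine_boundary / bone_fraction_map: local deep-tissue
## reference means around the label boundary
boundary_references <- function(grid, labels, band_mm = NULL, deep_mm = NULL,
                                sigma_mm = 0.45, cap = Inf) {
  sp <- grid$spacing
  if (is.null(band_mm)) band_mm <- 1.6 * max(sp)
  if (is.null(deep_mm)) deep_mm <- 1.9 * max(sp)
  mask <- labels$codes == 1L
  d_in <- sqrt(cpp_edt_sq(as.integer(!mask), grid$dims, sp))
  d_out <- sqrt(cpp_edt_sq(as.integer(mask), grid$dims, sp))
  v <- as.vector(grid$values)
  sig_vox <- sigma_mm / sp
  loc_mean <- function(w) {
    num <- cpp_gaussian_blur(v * w, grid$dims, sig_vox)
    den <- cpp_gaussian_blur(w, grid$dims, sig_vox)
    list(m = num / pmax(den, 1e-12), den = den)
  }
  lin_ <- loc_mean(as.numeric(mask & d_in > deep_mm & v < cap))
  lout <- loc_mean(as.numeric(!mask & d_out > deep_mm))
  band <- ((mask & d_in <= band_mm) | (!mask & d_out <= band_mm)) &
    lin_$den > 1e-3 & lout$den > 1e-3
  list(mask = mask, band = band, v = v, m_in = lin_$m, m_out = lout$m,
       den_in = lin_$den, den_out = lout$den)
}

#' Fractional (partial-volume) bone map
#'
#' Estimates, for every voxel, the fraction of its volume occupied by bone:
#' 1 deep inside the refined label, 0 well outside, and, across the
#' partial-volume band at the boundary, the intensity unmixing
#' `(v - m_out) / (m_in - m_out)` clamped to [0, 1], where `m_in`/`m_out`
#' are the local deep-tissue reference means of [refine_boundary()]. The
#' fractional map carries subvoxel surface information that binary labels
#' quantize away, which makes longitudinal volume differences insensitive
#' to how each scan's grid happens to sample the anatomy.
#'
#' Band voxels adjacent to metal (intensities at or above `metal_thr`,
#' e.g. titanium screws) are unmixed against the mean metal intensity
#' instead of the local bone reference, so the bright partial-volume halo
#' around exposed screw surfaces is counted at its true (small) metal
#' fraction rather than mistaken for near-solid bone.
#'
#' @inheritParams refine_boundary
#' @param metal_thr gray value at or above which a voxel counts as metal;
#'   `Inf` disables metal-aware unmixing.
#' @param metal_halo_mm reach of a metal voxel's partial-volume halo, mm.
#' @return a numeric array (same dims as the grid) of bone fractions.
#' @export
bone_fraction_map <- function(grid, labels, band_mm = NULL, deep_mm = NULL,
                              sigma_mm = 0.45, cap = Inf, metal_thr = Inf,
                              metal_halo_mm = 0.6) {
  r <- boundary_references(grid, labels, band_mm, deep_mm, sigma_mm, cap)
  f <- as.numeric(r$mask)
  m_in <- r$m_in
  halo_bone <- halo_soft <- rep(FALSE, length(f))
  if (is.finite(metal_thr) && any(r$v >= metal_thr)) {
    metal <- r$v >= metal_thr
    d_metal <- sqrt(cpp_edt_sq(as.integer(metal), grid$dims, grid$spacing))
    halo <- !metal & d_metal <= metal_halo_mm
    ## halo voxels surrounded by bone are a metal+bone mix (fully hard);
    ## halo voxels surrounded by background carry only their metal fraction
    halo_bone <- halo & r$den_in > 3 * r$den_out
    halo_soft <- halo & !halo_bone
    m_in[halo_soft] <- mean(r$v[metal])
  }
  contrast <- m_in - r$m_out
  ok <- r$band & contrast > 1e-9
  f[ok] <- pmin(1, pmax(0, (r$v[ok] - r$m_out[ok]) / contrast[ok]))
  f[r$band & halo_bone] <- 1
  array(f, grid$dims)
}

#' Remove connected components smaller than a voxel count
#'
#' 26-connectivity components of the nonzero voxels; components with fewer
#' than `min_voxels` voxels are set to 0. Used to suppress registration and
#' segmentation speckle in difference labels before volumetry.
#'
#' @param labels a `LabelMap`.
#' @param min_voxels minimum component size kept (default 20).
#' @return the cleaned `LabelMap`.
#' @export
remove_small_components <- function(labels, min_voxels = 20) {
  if (min_voxels <= 1) return(labels)
  cc <- cpp_connected_components(as.integer(labels$codes != 0L),
                                 labels$dims, 26L)
  if (cc$n == 0) return(labels)
  sizes <- tabulate(cc$labels, nbins = cc$n)
  drop <- which(sizes < min_voxels)
  if (!length(drop)) return(labels)
  codes <- labels$codes
  codes[array(cc$labels %in% drop, dim = labels$dims)] <- 0L
  label_map(codes, labels, legend = labels$legend)
}
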