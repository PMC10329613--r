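## run `code` under a temporarily seeded RNG, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Parameters of a serial-CBCT ridge-and-graft phantom
#'
#' Describes a synthetic study case: an atrophied alveolar ridge at baseline
#' (T1), the ridge plus a buccally grafted bone block fixed with two
#' osteosynthesis screws at the 2-month follow-up (T2), and the same block
#' after partial, buccally/crestally biased resorption at the 6-month
#' follow-up (T3). Scans carry tissue-specific intensity texture,
#' partial-volume Gaussian blur, additive scanner noise and a known rigid
#' inter-scan misalignment; all ground truth (labels, transforms, volumes)
#' is emitted alongside. Follow-up scans are rendered directly in their own
#' (misaligned) frame, so all three scans share an identical point-spread
#' function — no interpolation blur distinguishes them.
#'
#' Defaults mirror the study conditions the pipeline is meant for: 0.25 mm
#' isotropic voxels, a ~0.75 cm^3 block and ~32% resorption between T2 and
#' T3 with the loss concentrated on the buccal/crestal aspect.
#'
#' @param dims grid size (voxels per axis; recycled to length 3).
#' @param spacing mm per voxel (recycled to length 3).
#' @param crest_height ridge height above its base, mm.
#' @param basal_width,crest_width buccolingual ridge width at base and
#'   crest, mm (parabolic taper between them).
#' @param block_volume_cm3 target graft volume at T2, cm^3.
#' @param block_footprint mm (mesiodistal, vertical) footprint of the block
#'   on the buccal ridge face; the buccal protrusion is solved to match the
#'   target volume.
#' @param resorption_fraction fraction of the T2 block volume lost by T3,
#'   in [0, 1).
#' @param resorption_bias named weights (buccal, crestal, lingual, apical)
#'   controlling how deep each aspect of the block recedes.
#' @param intensities named gray-value means for background, trabecular,
#'   graft, cortical, tooth, screw (must be ordered background < trabecular
#'   < graft <= cortical < tooth < screw).
#' @param tissue_sd named intra-tissue intensity SDs (texture).
#' @param blur_sigma_mm partial-volume blur, mm.
#' @param noise_sd additive scanner noise SD, gray values.
#' @param misalignment_t2,misalignment_t3 true rigid motion of each
#'   follow-up scan: list(rx, ry, rz) degrees and `t` mm.
#' @param seed integer RNG seed; the case is bitwise reproducible.
#' @return an object of class `PhantomSpec`.
#' @export
phantom_spec <- function(dims = c(128, 128, 128), spacing = c(0.25, 0.25, 0.25),
                         crest_height = 14, basal_width = 10, crest_width = 3,
                         block_volume_cm3 = 0.75,
                         block_footprint = c(12, 10),
                         resorption_fraction = 0.32,
                         resorption_bias = c(buccal = 3, crestal = 2,
                                             lingual = 0.7, apical = 0.3),
                         intensities = c(background = 50, trabecular = 600,
                                         graft = 700, cortical = 1200,
                                         tooth = 1600, screw = 3000),
                         tissue_sd = c(background = 10, trabecular = 30,
                                       graft = 30, cortical = 30,
                                       tooth = 25, screw = 20),
                         blur_sigma_mm = 0.25, noise_sd = 50,
                         misalignment_t2 = list(rx = 0, ry = 0, rz = 5,
                                                t = c(2.0, -1.5, 1.0)),
                         misalignment_t3 = list(rx = 2, ry = -3, rz = 0,
                                                t = c(-1.5, 1.0, -2.0)),
                         seed = 1L) {
  dims <- rep_len(as.integer(dims), 3)
  spacing <- rep_len(as.numeric(spacing), 3)
  if (resorption_fraction < 0 || resorption_fraction >= 1)
    stop("resorption fraction must lie in [0, 1)")
  iv <- intensities
  if (!(iv["background"] < iv["trabecular"] && iv["trabecular"] < iv["graft"] &&
        iv["graft"] <= iv["cortical"] && iv["cortical"] < iv["tooth"] &&
        iv["tooth"] < iv["screw"]))
    stop("intensities must be ordered background < trabecular < graft <= ",
         "cortical < tooth < screw")
  if (blur_sigma_mm < 0) stop("blur sigma must be >= 0")
  structure(list(dims = dims, spacing = spacing, crest_height = crest_height,
                 basal_width = basal_width, crest_width = crest_width,
                 block_volume_cm3 = block_volume_cm3,
                 block_footprint = block_footprint,
                 resorption_fraction = resorption_fraction,
                 resorption_bias = resorption_bias,
                 intensities = intensities, tissue_sd = tissue_sd,
                 blur_sigma_mm = blur_sigma_mm, noise_sd = noise_sd,
                 misalignment_t2 = misalignment_t2,
                 misalignment_t3 = misalignment_t3,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

## scene layout constants relative to the physical extent. Axis-aligned
## planar faces are snapped to voxel edges: a plane through voxel centers
## makes the voxelized ground truth ambiguous by half a voxel over the
## whole face, whereas a plane on voxel edges voxelizes exactly.
phantom_layout <- function(spec) {
  ext <- spec$dims * spec$spacing
  snap_edge <- function(x, s) (round(x / s - 0.5) + 0.5) * s
  list(ext = ext,
       x0 = 10 / 32 * ext[1],            # lingual-shifted ridge axis
       z0 = snap_edge(2 / 32 * ext[3], spec$spacing[3]),  # ridge base height
       y_ridge = snap_edge(c(4, 28) / 32 * ext[2], spec$spacing[2]),
       tooth_y = c(7, 25) / 32 * ext[2],
       tooth_radius = 1.8, tooth_halfheight = 4,
       screw_dy = 3, screw_body_radius = 0.45, screw_head_radius = 0.95,
       screw_head_length = 0.8, screw_anchor = 2)
}

ridge_halfwidth <- function(spec, z, lay) {
  u <- (z - lay$z0) / spec$crest_height
  hw <- 0.5 * (spec$crest_width +
                 (spec$basal_width - spec$crest_width) * (1 - u^2))
  hw[u < 0 | u > 1] <- -1
  hw
}

## physical-coordinate arrays of the voxel centers of the phantom grid
phantom_coords <- function(spec) {
  d <- spec$dims; s <- spec$spacing
  xs <- (seq_len(d[1]) - 1) * s[1]
  ys <- (seq_len(d[2]) - 1) * s[2]
  zs <- (seq_len(d[3]) - 1) * s[3]
  list(X = array(rep.int(xs, d[2] * d[3]), d),
       Y = array(rep.int(rep(ys, each = d[1]), d[3]), d),
       Z = array(rep(zs, each = d[1] * d[2]), d))
}

## smooth, direction-biased recession-depth criterion for resorption.
## Returns a continuous "keep" field K (mm) on the block's grid: a point of
## the block survives iff K > 0, where K = interior depth - tau * local
## recession weight. tau is solved so the removed voxel fraction matches.
resorption_keep_field <- function(mask, fraction, bias, seed, spacing,
                                  protect = NULL, noise_sigma_mm = 1.5,
                                  noise_sd = 0.35) {
  dims <- dim(mask)
  d_in <- sqrt(cpp_edt_sq(as.integer(!mask), dims, spacing))
  d_in[!mask] <- 0
  ## outward normal ~ -grad(interior depth)
  g <- -array(cpp_gradient_magnitude_vec(d_in, dims, spacing), c(dims, 3))
  nx <- g[, , , 1]; ny <- g[, , , 2]; nz <- g[, , , 3]
  nn <- sqrt(nx^2 + ny^2 + nz^2); nn[nn == 0] <- 1
  nx <- nx / nn; ny <- ny / nn; nz <- nz / nn
  w_md <- mean(bias[c("buccal", "lingual", "crestal", "apical")])
  w <- bias[["buccal"]] * pmax(nx, 0) + bias[["lingual"]] * pmax(-nx, 0) +
    bias[["crestal"]] * pmax(nz, 0) + bias[["apical"]] * pmax(-nz, 0) +
    w_md * abs(ny)
  w <- w / mean(bias[c("buccal", "lingual", "crestal", "apical")])
  eps <- with_seed(seed, {
    e <- array(stats::rnorm(prod(dims)), dims)
    e <- cpp_gaussian_blur(as.vector(e), dims, noise_sigma_mm / spacing)
    e <- array(e, dims)
    (e - mean(e)) / stats::sd(e) * noise_sd
  })
  depth_scale <- w * pmax(1 + eps, 0.1)
  n0 <- sum(mask)
  target <- round(fraction * n0)
  removable <- mask & !(if (is.null(protect)) FALSE else protect)
  removed_at <- function(tau) sum(removable & d_in <= tau * depth_scale)
  lo <- 0; hi <- max(d_in) / max(stats::quantile(depth_scale[mask], 0.05), 1e-6)
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (removed_at(mid) < target) lo <- mid else hi <- mid
  }
  tau <- hi
  K <- d_in - tau * depth_scale
  if (!is.null(protect)) K[protect] <- pmax(K[protect], min(spacing) / 2)
  K
}

#' Simulate biased surface resorption of a graft block
#'
#' Erodes the block by a smooth, direction-biased recession-depth field: a
#' voxel survives when its interior depth exceeds a locally varying
#' recession depth, which is larger on aspects facing the weighted
#' directions (buccal/crestal by default) and modulated by a smooth random
#' field — emulating the spatially coherent, buccally/crestally dominant
#' resorption pattern of onlay grafts. The global recession scale is solved
#' so the removed volume fraction matches `fraction`; the result is
#' reproducible for a fixed seed and stays connected for convex blocks.
#'
#' @param block a `LabelMap` (nonzero = graft) or logical array.
#' @param fraction volume fraction to remove, in [0, 1).
#' @param bias named weights for aspects facing `buccal` (+x), `lingual`
#'   (-x), `crestal` (+z), `apical` (-z); mesiodistal aspects get the mean
#'   weight.
#' @param seed RNG seed for the smooth modulation field.
#' @param protect optional logical array of voxels that never resorb
#'   (e.g. titanium screw bodies).
#' @param spacing mm per voxel; taken from the label map when `block` is one.
#' @return same type as `block`, with the eroded mask.
#' @export
simulate_resorption <- function(block, fraction,
                                bias = c(buccal = 3, crestal = 2,
                                         lingual = 0.7, apical = 0.3),
                                seed = 1L, protect = NULL, spacing = NULL) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  was_labels <- inherits(block, "LabelMap")
  mask <- if (was_labels) block$codes != 0L else block
  if (is.null(spacing)) spacing <- if (was_labels) block$spacing else c(1, 1, 1)
  if (fraction == 0) return(block)
  K <- resorption_keep_field(mask, fraction, bias, seed, spacing,
                             protect = protect)
  out <- mask & (K > 0)
  if (was_labels) {
    label_map(array(as.integer(out), dim(mask)), block, legend = block$legend)
  } else out
}

## Scene model: analytic predicates + T1-frame voxel fields, so follow-up
## scans can be rasterized directly in their own (rigidly moved) frame.
phantom_scene <- function(spec) {
  lay <- phantom_layout(spec)
  co <- phantom_coords(spec)
  vox <- prod(spec$spacing)
  crest_z <- lay$z0 + spec$crest_height
  fp <- spec$block_footprint
  ## snap the block's planar faces to voxel edges: a face through voxel
  ## centers makes the voxelized ground-truth volume ambiguous by half a
  ## voxel per face, whereas a face on voxel edges voxelizes exactly
  snap_edge <- function(x, s) (round(x / s - 0.5) + 0.5) * s
  yb <- snap_edge(mean(lay$y_ridge) + c(-fp[1] / 2, fp[1] / 2), spec$spacing[2])
  zb <- snap_edge(c(crest_z - fp[2], crest_z), spec$spacing[3])

  preds <- local({
    tooth_pred <- function(X, Y, Z) {
      out <- array(FALSE, dim(X))
      for (ty in lay$tooth_y)
        out <- out | ((X - lay$x0)^2 + (Y - ty)^2 <= lay$tooth_radius^2 &
                        Z >= crest_z - lay$tooth_halfheight &
                        Z <= crest_z + lay$tooth_halfheight)
      out
    }
    bone_pred <- function(X, Y, Z) {
      hw <- ridge_halfwidth(spec, Z, lay)
      hw >= 0 & abs(X - lay$x0) <= hw &
        Y >= lay$y_ridge[1] & Y <= lay$y_ridge[2] & !tooth_pred(X, Y, Z)
    }
    block_pred <- function(X, Y, Z, p) {
      hw <- ridge_halfwidth(spec, Z, lay)
      dxa <- X - lay$x0
      hw >= 0 & dxa > hw & dxa <= hw + p &
        Y >= pmax(lay$y_ridge[1], yb[1]) & Y <= pmin(lay$y_ridge[2], yb[2]) &
        Z >= zb[1] & Z <= zb[2] & !tooth_pred(X, Y, Z)
    }
    list(tooth = tooth_pred, bone = bone_pred, block = block_pred)
  })

  ## calibrate the buccal protrusion to the target volume on the T1 grid
  target_mm3 <- spec$block_volume_cm3 * 1000
  zs_ <- mean(zb)
  p_max <- lay$ext[1] - lay$x0 - max(ridge_halfwidth(spec, zb[1], lay), 0) -
    lay$screw_head_length - 1.5
  count_at <- function(p) sum(preds$block(co$X, co$Y, co$Z, p))
  if (count_at(p_max) * vox < target_mm3 * 0.98)
    stop("block footprint exceeds the grid: target volume ",
         spec$block_volume_cm3, " cm^3 does not fit")
  lo <- 0.2; hi <- p_max
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (count_at(mid) * vox < target_mm3) lo <- mid else hi <- mid
  }
  p <- (lo + hi) / 2

  screw_preds <- local({
    hw_s <- ridge_halfwidth(spec, zs_, lay)
    face <- lay$x0 + hw_s + p
    screw_y <- mean(lay$y_ridge) + c(-lay$screw_dy, lay$screw_dy)
    body <- function(X, Y, Z, hard) {
      out <- array(FALSE, dim(X))
      for (sy in screw_y)
        out <- out | ((Y - sy)^2 + (Z - zs_)^2 <= lay$screw_body_radius^2 &
                        X >= lay$x0 - lay$screw_anchor & X <= face)
      out & hard   # titanium replacing hard tissue only
    }
    head <- function(X, Y, Z) {
      out <- array(FALSE, dim(X))
      for (sy in screw_y)
        out <- out | ((Y - sy)^2 + (Z - zs_)^2 <= lay$screw_head_radius^2 &
                        X > face & X <= face + lay$screw_head_length)
      out
    }
    list(body = body, head = head)
  })

  ## T1-frame masks and voxel fields
  bone_t1 <- preds$bone(co$X, co$Y, co$Z)
  block_t1 <- preds$block(co$X, co$Y, co$Z, p)
  body_t1 <- screw_preds$body(co$X, co$Y, co$Z, bone_t1 | block_t1)
  bone_depth <- sqrt(cpp_edt_sq(as.integer(!bone_t1), spec$dims, spec$spacing))
  keep_field <- if (spec$resorption_fraction > 0) {
    resorption_keep_field(block_t1, spec$resorption_fraction,
                          spec$resorption_bias, spec$seed + 1303L,
                          spec$spacing, protect = body_t1)
  } else NULL

  ## evaluate every mask at arbitrary physical points (scan-frame rendering)
  eval_masks <- function(X, Y, Z) {
    dims_out <- dim(X)
    pts_idx <- cbind(as.vector(X) / spec$spacing[1],
                     as.vector(Y) / spec$spacing[2],
                     as.vector(Z) / spec$spacing[3])
    sample_field <- function(fld)
      array(cpp_sample_points(as.vector(fld), spec$dims, pts_idx), dims_out)
    bone <- preds$bone(X, Y, Z)
    cortical <- bone & sample_field(bone_depth) <= 1.0
    block <- preds$block(X, Y, Z, p)
    graft_t3 <- if (is.null(keep_field)) block else
      block & sample_field(keep_field) > 0
    teeth <- vector("list", length(lay$tooth_y))
    for (t in seq_along(lay$tooth_y)) {
      ty <- lay$tooth_y[t]
      teeth[[t]] <- ((X - lay$x0)^2 + (Y - ty)^2 <= lay$tooth_radius^2 &
                       Z >= crest_z - lay$tooth_halfheight &
                       Z <= crest_z + lay$tooth_halfheight)
    }
    body <- screw_preds$body(X, Y, Z, bone | block)
    head <- screw_preds$head(X, Y, Z)
    list(bone = bone, cortical = cortical, graft_t2 = block,
         graft_t3 = graft_t3, teeth = teeth, screw_body = body,
         screw_head = head)
  }
  list(eval_masks = eval_masks, protrusion = p, layout = lay)
}

#' Generate one serial-CBCT phantom case
#'
#' Rasterizes the T1/T2/T3 scenes described by a [phantom_spec()] — each
#' follow-up directly in its own rigidly misaligned frame — applies tissue
#' texture, partial-volume blur and additive noise, and returns the three
#' volumes together with the full ground truth: label masks in the baseline
#' frame and in each scan's own frame, the true rigid transforms, the
#' screw-head exclusion masks, and the true graft volumes at T2 and T3.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `PhantomCase` with elements `volumes` (T1/T2/
#'   T3 `VoxelGrid`s), `truth` (ground-truth labels, transforms, volumes),
#'   `spec`.
#' @export
generate_case <- function(spec = phantom_spec()) {
  sc <- phantom_scene(spec)
  vox <- prod(spec$spacing)
  geo <- voxel_grid(array(0, spec$dims), spec$spacing)
  iv <- spec$intensities; sdv <- spec$tissue_sd
  co <- phantom_coords(spec)
  mis <- function(ms) rigid_transform(
    euler_rotation(ms$rx, ms$ry, ms$rz), translation = ms$t,
    center = grid_center(geo))
  tr2 <- mis(spec$misalignment_t2)
  tr3 <- mis(spec$misalignment_t3)

  frame_masks <- function(transform) {
    if (is.null(transform)) return(sc$eval_masks(co$X, co$Y, co$Z))
    ti <- invert_rigid(transform)
    P <- apply_point(ti, rbind(as.vector(co$X), as.vector(co$Y),
                               as.vector(co$Z)))
    sc$eval_masks(array(P[1, ], spec$dims), array(P[2, ], spec$dims),
                  array(P[3, ], spec$dims))
  }
  rasterize <- function(m, graft, tp_seed) {
    with_seed(spec$seed + tp_seed, {
      img <- array(iv["background"] +
                     stats::rnorm(prod(spec$dims), 0, sdv["background"]),
                   spec$dims)
      paint <- function(img, mask, mean, sd) {
        img[mask] <- mean + stats::rnorm(sum(mask), 0, sd)
        img
      }
      img <- paint(img, m$bone, iv["trabecular"], sdv["trabecular"])
      img <- paint(img, m$cortical, iv["cortical"], sdv["cortical"])
      for (tt in m$teeth) img <- paint(img, tt, iv["tooth"], sdv["tooth"])
      if (!is.null(graft)) {
        img <- paint(img, graft, iv["graft"], sdv["graft"])
        img <- paint(img, m$screw_body | m$screw_head, iv["screw"],
                     sdv["screw"])
      }
      img
    })
  }
  finish <- function(img, noise_seed) {
    v <- if (spec$blur_sigma_mm > 0) {
      cpp_gaussian_blur(as.vector(img), spec$dims,
                        spec$blur_sigma_mm / spec$spacing)
    } else as.vector(img)
    g <- voxel_grid(array(v, spec$dims), spec$spacing)
    if (spec$noise_sd > 0) {
      g$values <- g$values + with_seed(spec$seed + noise_seed,
        array(stats::rnorm(prod(spec$dims), 0, spec$noise_sd), spec$dims))
    }
    g
  }
  m1 <- frame_masks(NULL)
  m2 <- frame_masks(tr2)
  m3 <- frame_masks(tr3)
  t1 <- finish(rasterize(m1, NULL, 11L), 101L)
  t2 <- finish(rasterize(m2, m2$graft_t2, 12L), 102L)
  t3 <- finish(rasterize(m3, m3$graft_t3, 13L), 103L)

  lm <- function(mask, name) label_map(array(as.integer(mask), spec$dims), geo,
                                       legend = stats::setNames(1L, name))
  teeth_lab <- function(m) {
    codes <- array(0L, spec$dims)
    for (t in seq_along(m$teeth)) codes[m$teeth[[t]]] <- t
    label_map(codes, geo,
              legend = stats::setNames(seq_along(m$teeth),
                                       paste0("tooth", seq_along(m$teeth))))
  }
  truth_t1frame <- list(
    bone = lm(m1$bone, "bone"),
    hard_t1 = lm(m1$bone, "hard"),
    hard_t2 = lm(m1$bone | m1$graft_t2 | m1$screw_body, "hard"),
    hard_t3 = lm(m1$bone | m1$graft_t3 | m1$screw_body, "hard"),
    graft_t2 = lm(m1$graft_t2, "graft"), graft_t3 = lm(m1$graft_t3, "graft"),
    teeth = teeth_lab(m1),
    screw_body = lm(m1$screw_body, "screw_body"),
    screw_head = lm(m1$screw_head, "screw_head"))
  scan_frame <- list(
    t1 = list(hard = truth_t1frame$hard_t1, teeth = truth_t1frame$teeth,
              graft = lm(array(FALSE, spec$dims), "graft"),
              screw_head = lm(array(FALSE, spec$dims), "screw_head")),
    t2 = list(hard = lm(m2$bone | m2$graft_t2 | m2$screw_body, "hard"),
              teeth = teeth_lab(m2), graft = lm(m2$graft_t2, "graft"),
              screw_head = lm(m2$screw_head, "screw_head")),
    t3 = list(hard = lm(m3$bone | m3$graft_t3 | m3$screw_body, "hard"),
              teeth = teeth_lab(m3), graft = lm(m3$graft_t3, "graft"),
              screw_head = lm(m3$screw_head, "screw_head")))
  v_t2 <- sum(m1$graft_t2) * vox / 1000
  v_t3 <- sum(m1$graft_t3) * vox / 1000
  structure(list(
    volumes = list(t1 = t1, t2 = t2, t3 = t3),
    truth = list(t1frame = truth_t1frame, scan_frame = scan_frame,
                 transforms = list(t2 = tr2, t3 = tr3),
                 volumes = list(v_t2_cm3 = v_t2, v_t3_cm3 = v_t3,
                                ratio_pct = 100 * v_t3 / v_t2,
                                dsc = dice_coefficient(truth_t1frame$graft_t2,
                                                       truth_t1frame$graft_t3)),
                 protrusion_mm = sc$protrusion),
    spec = spec), class = "PhantomCase")
}

#' Deterministic segmentation seeds from phantom ground truth
#'
#' Picks, for each requested label, the interior voxel of the scan-frame
#' truth mask farthest from the mask boundary (ties resolved by
#' lexicographic index), treating the volume edge as boundary — emulating a
#' rater clicking well inside each structure. Bone receives two seeds, one
#' deep in the trabecular core and one mid-cortex (at the shell's 90th
#' intensity percentile, robust against titanium), mirroring how a rater
#' seeds both bone compartments; the background receives a soft-tissue
#' seed plus one seed inside each tooth.
#'
#' @param case a `PhantomCase`.
#' @param timepoint "t1", "t2" or "t3".
#' @return list with `bone_bg` (a [seed_set()] with bone = 1, background = 2)
#'   and `teeth` (one seed per tooth, codes 1..n).
#' @export
phantom_seeds <- function(case, timepoint = c("t1", "t2", "t3")) {
  timepoint <- match.arg(timepoint)
  sf <- case$truth$scan_frame[[timepoint]]
  vol <- case$volumes[[timepoint]]
  dims <- sf$hard$dims
  depth_mm <- function(mask) {
    ## pad so the volume edge counts as boundary
    pm <- array(0L, dims + 2L)
    pm[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- mask * 1L
    d <- sqrt(cpp_edt_sq(as.integer(pm == 0L), dims + 2L, sf$hard$spacing))
    array(d, dims + 2L)[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)]
  }
  lin_to_idx <- function(l) {
    l <- l - 1L
    c(l %% dims[1], (l %/% dims[1]) %% dims[2], l %/% (dims[1] * dims[2]))
  }
  interior_point <- function(mask) lin_to_idx(which.max(depth_mm(mask)))
  hard <- sf$hard$codes != 0L
  teeth_any <- sf$teeth$codes != 0L
  soft <- !(hard | teeth_any)
  d_hard <- depth_mm(hard)
  bone_core <- lin_to_idx(which.max(d_hard))
  ## mid-cortex: scan voxel ~0.6 mm below the hard-tissue surface whose
  ## intensity sits at the 90th percentile of that shell — bright enough to
  ## be cortical, robust against landing on a titanium screw
  shell <- which(hard & abs(d_hard - 0.6) <= max(0.31, min(vol$spacing)))
  q90 <- stats::quantile(vol$values[shell], 0.9, names = FALSE)
  bone_cortex <- lin_to_idx(shell[which.min(abs(vol$values[shell] - q90))])
  bone_seeds <- rbind(bone_core, bone_cortex)
  bg_seeds <- rbind(interior_point(soft),
                    do.call(rbind, lapply(sort(unique(sf$teeth$codes[teeth_any])),
                      function(tc) interior_point(sf$teeth$codes == tc))))
  bone_bg <- seed_set(rbind(bone_seeds, bg_seeds),
                      c(rep(1L, nrow(bone_seeds)), rep(2L, nrow(bg_seeds))),
                      names = c("bone", "background"))
  tcodes <- sort(unique(sf$teeth$codes[teeth_any]))
  teeth <- if (length(tcodes)) {
    seed_set(do.call(rbind, lapply(tcodes, function(tc)
      interior_point(sf$teeth$codes == tc))), tcodes,
      names = paste0("tooth", tcodes))
  } else NULL
  list(bone_bg = bone_bg, teeth = teeth)
}

#' Tooth intensity gate implied by a phantom spec
#'
#' Midway between the cortical and tooth means up to midway between the
#' tooth and screw means — the gray-value window a rater would read off the
#' histogram.
#'
#' @param spec a `PhantomSpec`.
#' @return an [intensity_gate()].
#' @export
phantom_tooth_gate <- function(spec) {
  iv <- spec$intensities
  intensity_gate((iv[["cortical"]] + iv[["tooth"]]) / 2,
                 (iv[["tooth"]] + iv[["screw"]]) / 2)
}

#' Draw a phantom cohort
#'
#' Per-case T2 graft volumes are drawn from a lognormal distribution and
#' resorption fractions from a beta distribution, reproducing the spread of
#' graft sizes and resorption seen across patients. With `render = FALSE`
#' (the default) only the per-case specs and the ground-truth table are
#' produced; with `render = TRUE` every case is fully rasterized.
#'
#' @param n_cases number of cases (>= 1).
#' @param volume_meanlog,volume_sdlog lognormal parameters of the T2 graft
#'   volume in cm^3 (defaults calibrated to mean 0.75, sd 0.57 cm^3).
#' @param resorption_shape1,resorption_shape2 beta parameters of the
#'   resorption fraction (defaults calibrated to mean 0.32, sd ~0.19).
#' @param seed cohort RNG seed.
#' @param render rasterize full volumes for each case?
#' @param base_spec template [phantom_spec()] whose geometry and imaging
#'   parameters each case inherits.
#' @return list with `truth` (data.frame: case, v_t2_cm3, v_t3_cm3,
#'   ratio_pct), `specs`, and (if rendered) `cases`.
#' @export
make_cohort <- function(n_cases = 23, volume_meanlog = log(0.75) - 0.456 / 2,
                        volume_sdlog = 0.675, resorption_shape1 = 1.7,
                        resorption_shape2 = 3.6, seed = 1L, render = FALSE,
                        base_spec = phantom_spec()) {
  stopifnot(n_cases >= 1)
  draws <- with_seed(seed, list(
    vol = stats::rlnorm(n_cases, volume_meanlog, volume_sdlog),
    res = stats::rbeta(n_cases, resorption_shape1, resorption_shape2)))
  specs <- lapply(seq_len(n_cases), function(i) {
    sp <- base_spec
    sp$block_volume_cm3 <- draws$vol[i]
    sp$resorption_fraction <- draws$res[i]
    sp$seed <- base_spec$seed + 1000L * i
    sp
  })
  truth <- data.frame(case = seq_len(n_cases),
                      v_t2_cm3 = draws$vol,
                      v_t3_cm3 = draws$vol * (1 - draws$res),
                      ratio_pct = 100 * (1 - draws$res))
  out <- list(truth = truth, specs = specs)
  if (render) {
    out$cases <- lapply(specs, generate_case)
    out$truth$v_t2_cm3 <- vapply(out$cases, function(cs)
      cs$truth$volumes$v_t2_cm3, numeric(1))
    out$truth$v_t3_cm3 <- vapply(out$cases, function(cs)
      cs$truth$volumes$v_t3_cm3, numeric(1))
    out$truth$ratio_pct <- 100 * out$truth$v_t3_cm3 / out$truth$v_t2_cm3
  }
  out
}

#' Write a cohort ground-truth table as CSV
#'
#' @param cohort result of [make_cohort()].
#' @param path output CSV path.
#' @export
write_cohort_truth <- function(cohort, path) {
  utils::write.csv(cohort$truth, path, row.names = FALSE)
  invisible(path)
}
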