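#' Per-case analysis of serial CBCT scans
#'
#' Runs the full evaluation chain on one case: seeded region-growing
#' segmentation of bone vs background per timepoint, watershed tooth
#' segmentation (when tooth seeds are given), screw-head exclusion, rigid
#' intensity-based registration of the follow-ups to baseline, logical
#' subtraction on the baseline grid, small-component cleanup, and all
#' outcome metrics: new hard-tissue volumes at T2 and T3, the T3/T2
#' stability ratio, the Dice coefficient between the two new-tissue models,
#' the signed-surface-distance colormap, and linear ridge dimensions at the
#' configured implantation sites.
#'
#' `volumes`, `seeds` and `head_masks` are named lists with entries `t1`,
#' `t2`, `t3` (head masks may be NULL, e.g. at baseline).
#'
#' @param volumes list of three `VoxelGrid`s.
#' @param seeds list of three bone/background [seed_set()]s (bone code 1,
#'   background code 2).
#' @param teeth_seeds optional list of per-timepoint tooth seed sets.
#' @param tooth_gate [intensity_gate()] for the watershed (required when
#'   `teeth_seeds` given).
#' @param head_masks optional list of per-timepoint screw-head `LabelMap`s.
#' @param reg_cfg a [registration_config()]; its `fixed_mask` is replaced by
#'   the dilated baseline bone label.
#' @param cleanup_min_voxels difference-label components smaller than this
#'   are discarded (default 20).
#' @param bone_opening_mm radius (mm) of the morphological opening applied
#'   to each scan's bone label before comparison; defaults to just over one
#'   voxel, removing one-voxel partial-volume shells that competitive
#'   growth can attach to high-gradient surfaces.
#' @param cleanup_opening_mm radius (mm) of an optional morphological
#'   opening of the difference labels before volumetry (default 0 = off;
#'   the component-size cleanup usually suffices once the bone labels are
#'   opened per scan).
#' @param teeth_exclusion_mm dilation radius (mm) of the watershed tooth
#'   label excluded from the bone label (the partial-volume rim of enamel
#'   reaches bone-like gray values; excluding it consistently at every
#'   timepoint keeps tooth rims out of the difference models). Used only
#'   when tooth seeds are supplied.
#' @param head_carve_mm dilation (mm) applied to the screw-head masks
#'   before exclusion, so the head's partial-volume halo is carved with it.
#' @param sites optional list of [site_spec()]s for linear measurements.
#' @param case_id identifier carried into the report.
#' @param out_dir optional directory; when given, labels, meshes and the
#'   report JSON are written beneath it.
#' @return a `ChangeReport` list: volumes (cm^3), `stability_ratio_pct`,
#'   `dsc`, `linear`, `registration` diagnostics, `log` of every parameter
#'   used, and artifact paths (when written).
#' @export
run_case <- function(volumes, seeds, teeth_seeds = NULL, tooth_gate = NULL,
                     head_masks = NULL, reg_cfg = registration_config(),
                     cleanup_min_voxels = 20, bone_opening_mm = 0,
                     cleanup_opening_mm = 0, teeth_exclusion_mm = NULL,
                     head_carve_mm = NULL, sites = NULL,
                     case_id = "case", out_dir = NULL) {
  tps <- c("t1", "t2", "t3")
  stopifnot(all(tps %in% names(volumes)), all(tps %in% names(seeds)))
  report <- list(case_id = case_id, failed = FALSE, failed_stage = NULL)
  log <- list(cleanup_min_voxels = cleanup_min_voxels,
              bone_opening_mm = bone_opening_mm,
              cleanup_opening_mm = cleanup_opening_mm,
              teeth_exclusion_mm = teeth_exclusion_mm %||%
                (2.6 * max(volumes$t1$spacing)),
              head_carve_mm = head_carve_mm %||%
                (1.05 * max(volumes$t1$spacing)),
              registration = list(metric = reg_cfg$metric,
                                  shrink_factors = reg_cfg$shrink_factors,
                                  smoothing_sigmas = reg_cfg$smoothing_sigmas,
                                  maxit = reg_cfg$maxit, tol = reg_cfg$tol,
                                  seed = reg_cfg$seed),
              tooth_gate = if (!is.null(tooth_gate))
                c(lo = tooth_gate$lo, hi = tooth_gate$hi))
  stage <- "segmentation"
  res <- try({
    excl_mm <- teeth_exclusion_mm %||% (2.6 * max(volumes$t1$spacing))
    cap <- if (!is.null(tooth_gate)) tooth_gate$lo else Inf
    bone <- list(); teeth <- list(); bfrac <- list()
    for (tp in tps) {
      lab <- grow_from_seeds(volumes[[tp]], seeds[[tp]])
      lab <- label_map(array(as.integer(lab$codes == 1L), lab$dims), lab,
                       legend = c(bone = 1L))
      lab <- refine_boundary(volumes[[tp]], lab, cap = cap,
                             metal_thr = if (!is.null(tooth_gate))
                               tooth_gate$hi else Inf)
      if (bone_opening_mm > 0) lab <- morphological_opening(lab, bone_opening_mm)
      fr <- bone_fraction_map(volumes[[tp]], lab, cap = cap,
                              metal_thr = if (!is.null(tooth_gate))
                                tooth_gate$hi else Inf)
      if (!is.null(teeth_seeds[[tp]])) {
        teeth[[tp]] <- watershed_from_seeds(volumes[[tp]], teeth_seeds[[tp]],
                                            tooth_gate)
        if (excl_mm > 0) {
          tz <- label_map(array(as.integer(teeth[[tp]]$codes != 0L),
                                lab$dims), lab, legend = c(teeth = 1L))
          tz <- dilate_mask(tz, 1L, excl_mm)
          lab <- apply_label_edit(lab, tz, 0L)
          fr[tz$codes != 0L] <- 0
        }
      }
      if (!is.null(head_masks[[tp]])) {
        ## carve the head's partial-volume halo with the head itself
        carve <- head_carve_mm %||% (1.05 * max(lab$spacing))
        hm <- if (carve > 0) {
          dilate_mask(head_masks[[tp]], 1L, carve)
        } else head_masks[[tp]]
        lab <- apply_label_edit(lab, hm, 0L)
        fr[hm$codes != 0L] <- 0
      }
      bone[[tp]] <- lab
      bfrac[[tp]] <- fr
    }

    stage <- "registration"
    reg_mask <- dilate_mask(bone$t1, 1L, 2.0)
    reg <- list(t2 = NULL, t3 = NULL)
    for (tp in c("t2", "t3")) {
      cfg <- reg_cfg
      cfg$fixed_mask <- reg_mask
      reg[[tp]] <- register_rigid(volumes$t1, volumes[[tp]], cfg)
      if (!reg[[tp]]$converged)
        stop("registration failed for ", tp)
    }

    stage <- "subtraction"
    bone_on_t1 <- list(t1 = bone$t1)
    frac_on_t1 <- list(t1 = bfrac$t1)
    for (tp in c("t2", "t3")) {
      bone_on_t1[[tp]] <- resample_mask_soft(bone[[tp]], volumes$t1,
                                             reg[[tp]]$transform)
      A <- resample_index_map(volumes[[tp]], volumes$t1, reg[[tp]]$transform)
      frac_on_t1[[tp]] <- array(
        cpp_resample_trilinear(as.vector(bfrac[[tp]]), volumes[[tp]]$dims,
                               volumes$t1$dims, A, 0), volumes$t1$dims)
    }
    clean <- function(lab) remove_small_components(
      morphological_opening(lab, cleanup_opening_mm), cleanup_min_voxels)
    geo1 <- volumes$t1
    ## trilinear resampling smooths the follow-up fraction fields by the
    ## interpolation kernel (average variance 1/6 voxel^2 per axis, but
    ## spatially varying). Smoothing the resampled fields by a matching
    ## Gaussian and the baseline by its sqrt(2)-wider counterpart makes the
    ## residual kernel mismatch second-order, so the subtraction compares
    ## like-for-like surface profiles
    for (tp in c("t2", "t3"))
      frac_on_t1[[tp]] <- array(
        cpp_gaussian_blur(as.vector(frac_on_t1[[tp]]), geo1$dims,
                          rep(sqrt(1 / 6), 3)), geo1$dims)
    f1_cmp <- array(cpp_gaussian_blur(as.vector(frac_on_t1$t1), geo1$dims,
                                      rep(sqrt(2 / 6), 3)), geo1$dims)
    frac_diff <- function(tp) {
      signed <- frac_on_t1[[tp]] - f1_cmp
      fd <- pmax(signed, 0)
      ## surfaces present in both scans whose fraction difference is below
      ## the deadband are grid-sampling jitter, not tissue change (the
      ## method's resolution limit)
      bilateral <- f1_cmp > 0.05 & frac_on_t1[[tp]] > 0.05 & abs(signed) < 0.2
      fd[bilateral] <- 0
      lab <- clean(label_map(array(as.integer(fd >= 0.5), geo1$dims), geo1,
                             legend = c(difference = 1L)))
      ## volume: *signed* fraction difference over the kept components plus
      ## their subvoxel partial-volume shell. Bilateral-stable voxels are
      ## excluded in the outer shell (jitter on unchanged surfaces must not
      ## bleed into the sum) but kept immediately next to the change, where
      ## their small signed values are part of its partial-volume
      ## bookkeeping
      inner <- dilate_mask(lab, 1L, 2.1 * max(geo1$spacing))$codes != 0L
      ## the outer shell must cover the full smoothed partial-volume spread
      ## (~3 sigma of edge PSF + matching kernels), about 0.8 mm at 0.25 mm
      ## voxels
      outer <- dilate_mask(lab, 1L, 3.2 * max(geo1$spacing))$codes != 0L
      support <- outer & (inner | !bilateral)
      vol <- sum(signed[support]) * voxel_volume(geo1) / 1000
      list(label = lab, volume_cm3 = max(vol, 0),
           signed = signed, support = support)
    }
    d2 <- frac_diff("t2"); d3 <- frac_diff("t3")
    new2 <- d2$label; new3 <- d3$label

    stage <- "metrics"
    v2 <- d2$volume_cm3; v3 <- d3$volume_cm3
    report$new_volume_t2_cm3 <- v2
    report$new_volume_t3_cm3 <- v3
    report$stability_ratio_pct <- if (v2 > 0) stability_ratio(v3, v2) else NA
    report$dsc <- dice_coefficient(new2, new3)
    cmap <- if (any(new2$codes != 0L)) {
      signed_surface_distances(new2, new3)
    } else NULL
    report$linear <- if (!is.null(sites)) {
      lapply(sites, function(s) {
        lapply(tps, function(tp) ridge_linear_measurements(bone_on_t1[[tp]], s))
      })
    } else NULL
    report$registration <- lapply(reg, function(r)
      list(metric = r$metric, converged = r$converged))
    list(bone = bone, bone_on_t1 = bone_on_t1, teeth = teeth,
         new2 = new2, new3 = new3, cmap = cmap, reg = reg,
         diff2 = d2, diff3 = d3)
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    report$failed <- TRUE
    report$failed_stage <- stage
    report$error <- attr(res, "condition")$message
    return(report)
  }
  report$log <- log
  if (!is.null(out_dir)) {
    report$artifacts <- write_case_artifacts(res, report, out_dir)
  }
  attr(report, "data") <- res
  class(report) <- "ChangeReport"
  report
}

## subvoxel-accurate binary-mask resampling: trilinear interpolation of the
## indicator, thresholded at 0.5 (labels stay binary; the surface is placed
## with subvoxel accuracy instead of nearest-neighbor staircase jitter)
resample_mask_soft <- function(labels, reference, transform) {
  A <- resample_index_map(labels, reference, transform)
  v <- cpp_resample_trilinear(as.numeric(labels$codes != 0L), labels$dims,
                              reference$dims, A, 0)
  label_map(array(as.integer(v >= 0.5), reference$dims), reference,
            legend = labels$legend)
}

## dilate a label's nonzero set by a physical radius (mm)
dilate_mask <- function(labels, code, radius_mm) {
  d <- cpp_edt_sq(as.integer(labels$codes == code), labels$dims,
                  labels$spacing)
  label_map(array(as.integer(d <= radius_mm^2), labels$dims), labels,
            legend = c(mask = 1L))
}

write_case_artifacts <- function(res, report, out_dir) {
  dir.create(file.path(out_dir, "labels"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "meshes"), showWarnings = FALSE)
  paths <- list()
  paths$new_t2 <- file.path(out_dir, "labels", "new_tissue_t2.nrrd")
  paths$new_t3 <- file.path(out_dir, "labels", "new_tissue_t3.nrrd")
  write_volume(res$new2, paths$new_t2)
  write_volume(res$new3, paths$new_t3)
  for (tp in c("t2", "t3")) {
    paths[[paste0("transform_", tp)]] <-
      file.path(out_dir, paste0("transform_", tp, ".json"))
    write_transform_json(res$reg[[tp]]$transform,
                         paths[[paste0("transform_", tp)]],
                         extra = list(metric = res$reg[[tp]]$metric))
  }
  if (!is.null(res$cmap)) {
    paths$colormap <- file.path(out_dir, "meshes", "new_t2_vs_t3.ply")
    write_mesh(res$cmap, paths$colormap)
  }
  paths$report <- file.path(out_dir, "report.json")
  write_change_report(report, paths$report)
  paths
}

#' Write a change report as JSON
#'
#' @param report a `ChangeReport`.
#' @param path output JSON path.
#' @export
write_change_report <- function(report, path) {
  out <- unclass(report)
  attr(out, "data") <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

#' Run a full phantom case through the pipeline
#'
#' Derives seeds, the tooth gate and the screw-head masks from the phantom's
#' ground truth and calls [run_case()] — the standard harness for validating
#' the pipeline against known truth.
#'
#' @param case a `PhantomCase` from [generate_case()].
#' @param ... passed on to [run_case()].
#' @return a `ChangeReport`.
#' @export
run_phantom_case <- function(case, ...) {
  seeds <- list(); teeth_seeds <- list(); head_masks <- list()
  for (tp in c("t1", "t2", "t3")) {
    ps <- phantom_seeds(case, tp)
    seeds[[tp]] <- ps$bone_bg
    teeth_seeds[[tp]] <- ps$teeth
    hm <- case$truth$scan_frame[[tp]]$screw_head
    head_masks[[tp]] <- if (any(hm$codes != 0L)) hm else NULL
  }
  run_case(case$volumes, seeds, teeth_seeds = teeth_seeds,
           tooth_gate = phantom_tooth_gate(case$spec),
           head_masks = head_masks, ...)
}

#' Cohort-level analysis
#'
#' Aggregates per-case change reports into the standard outcome battery:
#' descriptive statistics (mean, sd, median, min, max) for the new volumes,
#' the T3/T2 ratio and the DSC; the Wilcoxon matched-pairs signed-rank test
#' of vT2 vs vT3; and the Spearman rank correlation between the T3/T2 ratio
#' and the DSC. Failed cases are excluded and listed.
#'
#' @param reports list of `ChangeReport`s from [run_case()].
#' @param out_csv optional path for a flat per-case CSV.
#' @return list with `per_case` (data.frame), `descriptives`, `wilcoxon_v2_v3`,
#'   `spearman_ratio_dsc`, `excluded`.
#' @export
run_cohort <- function(reports, out_csv = NULL) {
  ok <- vapply(reports, function(r) isFALSE(r$failed), logical(1))
  excluded <- vapply(reports[!ok], function(r)
    paste0(r$case_id, " (", r$failed_stage, ")"), character(1))
  reports <- reports[ok]
  if (!length(reports)) stop("no successful cases")
  per_case <- data.frame(
    case_id = vapply(reports, function(r) as.character(r$case_id),
                     character(1)),
    v_t2_cm3 = vapply(reports, function(r) r$new_volume_t2_cm3, numeric(1)),
    v_t3_cm3 = vapply(reports, function(r) r$new_volume_t3_cm3, numeric(1)),
    ratio_pct = vapply(reports, function(r) r$stability_ratio_pct, numeric(1)),
    dsc = vapply(reports, function(r) r$dsc, numeric(1)))
  res <- list(
    per_case = per_case,
    descriptives = list(v_t2_cm3 = descriptive(per_case$v_t2_cm3),
                        v_t3_cm3 = descriptive(per_case$v_t3_cm3),
                        ratio_pct = descriptive(per_case$ratio_pct),
                        dsc = descriptive(per_case$dsc)),
    wilcoxon_v2_v3 = if (nrow(per_case) >= 2)
      wilcoxon_signed_rank(per_case$v_t2_cm3, per_case$v_t3_cm3),
    spearman_ratio_dsc = if (nrow(per_case) >= 3 &&
                               stats::sd(per_case$ratio_pct) > 0 &&
                               stats::sd(per_case$dsc) > 0)
      spearman_rho(per_case$ratio_pct, per_case$dsc),
    excluded = excluded)
  if (!is.null(out_csv)) utils::write.csv(per_case, out_csv, row.names = FALSE)
  res
}

#' Read a case configuration (YAML or JSON) and run it
#'
#' The configuration lists the three volume paths, per-timepoint seed JSON
#' files, the tooth gate, optional screw-head mask volumes, registration
#' settings, cleanup size and an output directory; see the package vignette
#' for the schema.
#'
#' @param path YAML or JSON case configuration.
#' @return a `ChangeReport`.
#' @export
run_case_config <- function(path) {
  cfg <- if (tolower(tools::file_ext(path)) %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p)) NULL else {
    if (file.exists(p)) p else file.path(base, p)
  }
  tps <- c("t1", "t2", "t3")
  volumes <- lapply(cfg$volumes[tps], function(p) read_volume(resolve(p)))
  seeds <- lapply(cfg$seeds[tps], function(p) read_seeds_json(resolve(p)))
  teeth_seeds <- if (!is.null(cfg$teeth_seeds))
    lapply(cfg$teeth_seeds[tps], function(p)
      if (is.null(p)) NULL else read_seeds_json(resolve(p)))
  head_masks <- if (!is.null(cfg$head_masks))
    lapply(cfg$head_masks[tps], function(p)
      if (is.null(p)) NULL else read_labels(resolve(p)))
  gate <- if (!is.null(cfg$tooth_gate))
    intensity_gate(cfg$tooth_gate$lo, cfg$tooth_gate$hi)
  reg_cfg <- do.call(registration_config,
                     c(cfg$registration, list()))
  run_case(volumes, seeds, teeth_seeds = teeth_seeds, tooth_gate = gate,
           head_masks = head_masks, reg_cfg = reg_cfg,
           cleanup_min_voxels = cfg$cleanup_min_voxels %||% 20,
           case_id = cfg$case_id %||% basename(path),
           out_dir = resolve(cfg$out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
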