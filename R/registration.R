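#' Configuration for rigid intensity-based registration
#'
#' Defaults follow a same-modality serial-CBCT setting: normalized
#' cross-correlation metric, a 3-level multiresolution pyramid (shrink
#' factors 4/2/1 with matched Gaussian smoothing), and a derivative-free
#' simplex optimizer over the 6-parameter Euler-angle + translation space.
#'
#' @param metric "ncc" (normalized cross-correlation; default) or "mi"
#'   (histogram mutual information).
#' @param shrink_factors integer vector, coarse to fine (one pyramid level
#'   per entry).
#' @param smoothing_sigmas Gaussian sigma in voxels per level (defaults to
#'   shrink/2).
#' @param maxit optimizer iteration cap per level.
#' @param tol convergence tolerance on the metric.
#' @param fixed_mask optional `LabelMap`; the metric is evaluated only over
#'   its nonzero voxels (e.g. the baseline bone label).
#' @param centroid_init initialize translation by aligning intensity
#'   centroids (default TRUE).
#' @param mi_bins histogram bins per axis for the "mi" metric.
#' @param seed integer kept for interface stability; the optimizer and both
#'   metrics are deterministic, so it does not influence the result.
#' @return an object of class `RegistrationConfig`.
#' @export
registration_config <- function(metric = c("ncc", "mi"),
                                shrink_factors = c(4, 2, 1),
                                smoothing_sigmas = NULL,
                                maxit = c(300, 200, 100),
                                tol = 1e-7,
                                fixed_mask = NULL,
                                centroid_init = TRUE,
                                mi_bins = 32,
                                seed = 0L) {
  metric <- match.arg(metric)
  if (length(shrink_factors) < 1) stopifnot(FALSE)
  if (is.null(smoothing_sigmas)) smoothing_sigmas <- pmax(shrink_factors / 2, 0)
  if (tol <= 0) stop("tolerance must be > 0")
  maxit <- rep_len(maxit, length(shrink_factors))
  structure(list(metric = metric, shrink_factors = as.integer(shrink_factors),
                 smoothing_sigmas = smoothing_sigmas, maxit = maxit, tol = tol,
                 fixed_mask = fixed_mask, centroid_init = centroid_init,
                 mi_bins = as.integer(mi_bins), seed = as.integer(seed)),
            class = "RegistrationConfig")
}

## downsample a grid by an integer factor (after blur), voxel centers kept
## at the retained input voxel positions so geometry stays exact
downsample_grid <- function(grid, factor, sigma_vox) {
  if (factor == 1 && sigma_vox <= 0) return(grid)
  vals <- if (sigma_vox > 0) {
    cpp_gaussian_blur(as.vector(grid$values), grid$dims, rep(sigma_vox, 3))
  } else as.vector(grid$values)
  vals <- array(vals, dim = grid$dims)
  if (factor > 1) {
    ix <- seq(1, grid$dims[1], by = factor)
    iy <- seq(1, grid$dims[2], by = factor)
    iz <- seq(1, grid$dims[3], by = factor)
    vals <- vals[ix, iy, iz, drop = FALSE]
  }
  voxel_grid(vals, grid$spacing * factor, grid$origin, grid$direction)
}

downsample_mask <- function(mask, factor) {
  if (factor == 1) return(mask$codes != 0L)
  ix <- seq(1, mask$dims[1], by = factor)
  iy <- seq(1, mask$dims[2], by = factor)
  iz <- seq(1, mask$dims[3], by = factor)
  (mask$codes != 0L)[ix, iy, iz, drop = FALSE]
}

intensity_centroid <- function(grid) {
  w <- pmax(as.vector(grid$values) - stats::median(grid$values), 0)
  s <- sum(w)
  if (s <= 0) return(grid_center(grid))
  d <- grid$dims
  i <- rep.int(seq_len(d[1]) - 1, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  idx <- c(sum(w * i), sum(w * j), sum(w * k)) / s
  as.numeric(index_to_physical(grid, idx))
}

mask_centroid <- function(grid, mask_arr) {
  w <- as.numeric(mask_arr != 0)
  s <- sum(w)
  if (s <= 0) return(grid_center(grid))
  d <- grid$dims
  i <- rep.int(seq_len(d[1]) - 1, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  idx <- c(sum(w * i), sum(w * j), sum(w * k)) / s
  as.numeric(index_to_physical(grid, idx))
}

## metric for a parameter vector at one pyramid level; returns similarity
## (higher is better) or NA when the overlap is degenerate
level_metric <- function(par, fx, mv, mask_int, center, cfg) {
  tr <- params_to_transform(par, center)
  A <- resample_index_map(mv, fx, tr)
  if (cfg$metric == "ncc") {
    r <- cpp_ncc_affine(as.vector(fx$values), fx$dims, mask_int,
                        as.vector(mv$values), mv$dims, A)
    if (is.na(r$ncc) || r$n < 32) return(NA_real_)
    r$ncc
  } else {
    vals <- cpp_resample_trilinear(as.vector(mv$values), mv$dims, fx$dims, A,
                                   NA_real_)
    f <- as.vector(fx$values)
    if (length(mask_int) > 1) {
      keep <- mask_int != 0L & !is.na(vals)
    } else keep <- !is.na(vals)
    if (sum(keep) < 32) return(NA_real_)
    mutual_information(f[keep], vals[keep], cfg$mi_bins)
  }
}

mutual_information <- function(x, y, bins) {
  bx <- cut(x, breaks = bins, labels = FALSE)
  by <- cut(y, breaks = bins, labels = FALSE)
  joint <- table(bx, by) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

params_to_transform <- function(par, center) {
  rigid_transform(euler_rotation(par[1], par[2], par[3]),
                  translation = par[4:6], center = center)
}

#' Rigid intensity-based registration of two volumes
#'
#' Aligns `moving` to `fixed` by maximizing an intensity-similarity metric
#' (normalized cross-correlation by default) over rotations and translations,
#' using a multiresolution pyramid. The returned transform maps fixed-image
#' physical points into moving-image physical space, i.e. it is directly
#' usable by [resample_labels()] / [resample_intensity()] with `fixed` as the
#' reference. If the optimum does not improve on the identity alignment, the
#' result is flagged `converged = FALSE` and carries the identity transform.
#'
#' @param fixed,moving `VoxelGrid`s with overlapping fields of view.
#' @param cfg a [registration_config()].
#' @return list with `transform` (`RigidTransform`), `metric` (achieved
#'   similarity), `converged` (logical), `levels` (per-level convergence
#'   report).
#' @export
register_rigid <- function(fixed, moving, cfg = registration_config()) {
  if (stats::sd(fixed$values) == 0 || stats::sd(moving$values) == 0)
    stop("registration requires non-constant intensities")
  center <- if (!is.null(cfg$fixed_mask)) {
    mask_centroid(fixed, cfg$fixed_mask$codes)
  } else grid_center(fixed)
  par <- c(0, 0, 0, 0, 0, 0)
  if (cfg$centroid_init) {
    cf <- if (!is.null(cfg$fixed_mask)) center else intensity_centroid(fixed)
    cm <- intensity_centroid(moving)
    par[4:6] <- cm - cf
  }
  report <- list()
  for (lev in seq_along(cfg$shrink_factors)) {
    f <- cfg$shrink_factors[lev]
    fx <- downsample_grid(fixed, f, cfg$smoothing_sigmas[lev])
    mv <- downsample_grid(moving, f, cfg$smoothing_sigmas[lev])
    mask_int <- if (!is.null(cfg$fixed_mask)) {
      as.integer(downsample_mask(cfg$fixed_mask, f))
    } else 0L
    obj <- function(p) {
      m <- level_metric(p, fx, mv, mask_int, center, cfg)
      if (is.na(m)) 1e6 else -m
    }
    opt <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = cfg$maxit[lev],
                                       reltol = cfg$tol,
                                       parscale = c(1, 1, 1, 1, 1, 1) *
                                         c(rep(0.5, 3), rep(0.5, 3))))
    par <- opt$par
    report[[lev]] <- list(shrink = f, metric = -opt$value,
                          evaluations = unname(opt$counts[1]))
  }
  final <- level_metric(par, fixed, moving,
                        if (!is.null(cfg$fixed_mask))
                          as.integer(cfg$fixed_mask$codes != 0L) else 0L,
                        center, cfg)
  id_metric <- level_metric(c(0, 0, 0, 0, 0, 0), fixed, moving,
                            if (!is.null(cfg$fixed_mask))
                              as.integer(cfg$fixed_mask$codes != 0L) else 0L,
                            center, cfg)
  if (is.na(final) || (!is.na(id_metric) && final < id_metric - 1e-9)) {
    warning("registration failed to improve over identity; ",
            "returning flagged identity transform")
    return(list(transform = rigid_identity(), metric = id_metric,
                converged = FALSE, levels = report))
  }
  list(transform = params_to_transform(par, center), metric = final,
       converged = TRUE, levels = report)
}
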