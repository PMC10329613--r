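test_that("uniform-intensity growth splits the grid by geodesic distance", {
  g <- voxel_grid(array(100, c(6, 6, 6)))
  s <- seed_set(rbind(c(0, 0, 0), c(5, 5, 5)), c(1, 2),
                c("bone", "background"))
  lab <- grow_from_seeds(g, s)
  ## brute-force oracle: 6-connected geodesic = Manhattan distance on a
  ## full grid; ties go to the smaller label code
  oracle <- array(0L, c(6, 6, 6))
  for (k in 0:5) for (j in 0:5) for (i in 0:5) {
    d1 <- i + j + k
    d2 <- (5 - i) + (5 - j) + (5 - k)
    oracle[i + 1, j + 1, k + 1] <- if (d1 <= d2) 1L else 2L
  }
  expect_identical(lab$codes, oracle)
})

test_that("two-intensity step volume splits exactly at the step", {
  v <- array(100, c(10, 10, 10)); v[6:10, , ] <- 1000
  g <- voxel_grid(v)
  lab <- grow_from_seeds(g, seed_set(rbind(c(1, 5, 5), c(8, 5, 5)), c(1, 2)))
  expected <- array(2L, c(10, 10, 10)); expected[1:5, , ] <- 1L
  expect_identical(lab$codes, expected)
})

test_that("growth is invariant to seed listing order", {
  set.seed(7)
  v <- array(rnorm(10^3, 500, 120), c(10, 10, 10))
  g <- voxel_grid(v)
  idx <- rbind(c(1, 1, 1), c(8, 8, 8), c(2, 7, 3))
  a <- grow_from_seeds(g, seed_set(idx, c(1, 2, 2)))
  b <- grow_from_seeds(g, seed_set(idx[c(3, 1, 2), ], c(2, 1, 2)))
  expect_identical(a$codes, b$codes)
})

test_that("growth yields a partition with codes drawn from the seeds", {
  set.seed(8)
  for (rep in 1:5) {
    v <- array(rnorm(8^3, 100, 50) + rep(c(0, 400), each = 256), c(8, 8, 8))
    g <- voxel_grid(v)
    lab <- grow_from_seeds(g, seed_set(rbind(c(0, 0, 0), c(7, 7, 7)), c(3, 5)))
    expect_true(all(lab$codes %in% c(3L, 5L)))      # every voxel labeled
    expect_identical(lab$codes[1, 1, 1], 3L)        # seeds keep their codes
    expect_identical(lab$codes[8, 8, 8], 5L)
  }
})

test_that("growth rejects degenerate seed sets", {
  g <- voxel_grid(array(0, c(4, 4, 4)))
  expect_error(grow_from_seeds(g, seed_set(rbind(c(0, 0, 0)), 1L)),
               "distinct seed labels")
  expect_error(seed_set(matrix(numeric(0), 0, 3), integer(0)))
  expect_error(seed_set(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 2)),
               "two different codes")
})

test_that("watershed recovers two gated spheres exactly", {
  d <- c(24, 12, 12)
  v <- array(0, d)
  co <- as.matrix(expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3]))
  s1 <- (co[, 1] - 6)^2 + (co[, 2] - 6)^2 + (co[, 3] - 6)^2 <= 9
  s2 <- (co[, 1] - 18)^2 + (co[, 2] - 6)^2 + (co[, 3] - 6)^2 <= 9
  v[co[s1, ]] <- 1000; v[co[s2, ]] <- 1000
  g <- voxel_grid(v)
  lab <- watershed_from_seeds(g, seed_set(rbind(c(5, 5, 5), c(17, 5, 5)),
                                          c(1, 2)),
                              intensity_gate(500, 1500))
  ## oracle: gated connected components
  m1 <- array(FALSE, d); m1[co[s1, ]] <- TRUE
  m2 <- array(FALSE, d); m2[co[s2, ]] <- TRUE
  expect_identical(lab$codes == 1L, m1)
  expect_identical(lab$codes == 2L, m2)
})

test_that("watershed floods a constant gradient-free volume from one seed", {
  g <- voxel_grid(array(500, c(6, 6, 6)))
  lab <- watershed_from_seeds(g, seed_set(rbind(c(3, 3, 3)), 4L),
                              intensity_gate(0, 1000))
  expect_true(all(lab$codes == 4L))
})

test_that("watershed rejects seeds outside the gate and keeps labels connected", {
  v <- array(100, c(8, 8, 8)); v[3:6, 3:6, 3:6] <- 900
  g <- voxel_grid(v)
  expect_error(watershed_from_seeds(g, seed_set(rbind(c(0, 0, 0)), 1L),
                                    intensity_gate(500, 1000)),
               "outside the intensity gate")
  lab <- watershed_from_seeds(g, seed_set(rbind(c(3, 3, 3)), 1L),
                              intensity_gate(500, 1000))
  cc <- cbctvol:::cpp_connected_components(as.integer(lab$codes == 1L),
                                           lab$dims, 26L)
  expect_identical(cc$n, 1L)
  expect_identical(lab$codes[4, 4, 4], 1L)   # contains its seed
})

test_that("watershed separates touching spheres near the intensity valley", {
  ## two bright blobs overlapping slightly, valley at the contact plane x=12.5
  d <- c(24, 12, 12)
  co <- as.matrix(expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3]))
  f <- function(cx) pmax(0, 1 - ((co[, 1] - cx)^2 + (co[, 2] - 6)^2 +
                                   (co[, 3] - 6)^2) / 36)
  v <- array(1000 * pmax(f(8), f(17)), d)
  g <- voxel_grid(v)
  lab <- watershed_from_seeds(g, seed_set(rbind(c(7, 5, 5), c(16, 5, 5)),
                                          c(1, 2)),
                              intensity_gate(200, 1100), sigma_vox = 0)
  idx1 <- which(lab$codes == 1L, arr.ind = TRUE)
  idx2 <- which(lab$codes == 2L, arr.ind = TRUE)
  ## watershed line within 1 voxel of the valley plane between the centers
  expect_lte(max(idx1[, 1]), 14)
  expect_gte(min(idx2[, 1]), 12)
})

test_that("global threshold labels exactly the gated voxels", {
  g <- voxel_grid(array(c(0, 500, 1500), c(3, 1, 1)))
  expect_identical(as.vector(global_threshold(g, intensity_gate(400, 1000))$codes),
                   c(0L, 1L, 0L))
  expect_true(all(global_threshold(g, intensity_gate(-1, 2000))$codes == 1L))
})

test_that("threshold voxel count grows monotonically with the gate", {
  set.seed(9)
  g <- voxel_grid(array(rnorm(6^3, 500, 200), c(6, 6, 6)))
  widths <- seq(50, 800, by = 150)
  counts <- vapply(widths, function(w)
    sum(global_threshold(g, intensity_gate(500 - w, 500 + w))$codes),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("threshold respects a region-of-interest mask", {
  g <- voxel_grid(array(700, c(4, 4, 4)))
  roi <- label_map(array(c(1L, 0L), c(4, 4, 4)), g)
  out <- global_threshold(g, intensity_gate(600, 800), roi)
  expect_identical(out$codes != 0L, roi$codes != 0L)
})

test_that("label edits replace exactly the masked voxels", {
  g <- voxel_grid(array(0, c(8, 8, 8)), spacing = c(0.5, 0.5, 0.5))
  bone <- label_map(array(1L, c(8, 8, 8)), g)
  empty_mask <- label_map(array(0L, c(8, 8, 8)), g)
  expect_identical(apply_label_edit(bone, empty_mask, 0L)$codes, bone$codes)
  head_codes <- array(0L, c(8, 8, 8)); head_codes[3:5, 3:5, 3:5] <- 1L
  head <- label_map(head_codes, g)
  edited <- apply_label_edit(bone, head, 0L)
  expect_equal(sum(bone$codes == 1L) - sum(edited$codes == 1L), 27)
  expect_equal(volume_cm3(bone) - volume_cm3(edited),
               27 * voxel_volume(g) / 1000)
  all_mask <- label_map(array(1L, c(8, 8, 8)), g)
  expect_true(all(apply_label_edit(bone, all_mask, 0L)$codes == 0L))
  g2 <- voxel_grid(array(0, c(4, 4, 4)))
  expect_error(apply_label_edit(bone, label_map(array(0L, c(4, 4, 4)), g2), 0L),
               "mismatch")
})

test_that("small-component cleanup removes speckle but keeps bulk", {
  d <- c(16, 16, 16)
  codes <- array(0L, d)
  codes[2:9, 2:9, 2:9] <- 1L     # 512-voxel bulk
  codes[14, 14, 14] <- 1L        # isolated speckle
  lm <- label_map(codes, voxel_grid(array(0, d)))
  out <- remove_small_components(lm, 20)
  expect_equal(sum(out$codes), 512)
})

test_that("morphological opening removes thin sheets, keeps thick slabs", {
  d <- c(20, 20, 20)
  codes <- array(0L, d)
  codes[4:15, 4:15, 4:9] <- 1L   # 6-voxel-thick slab
  codes[4:15, 4:15, 15] <- 1L    # 1-voxel sheet
  lm <- label_map(codes, voxel_grid(array(0, d)))
  out <- morphological_opening(lm, 1.05)
  expect_equal(sum(out$codes[, , 15]), 0)
  ## edge rounding of the opening costs ~12% of a 12x12x6 slab
  expect_gt(sum(out$codes[, , 4:9]), 0.85 * 12 * 12 * 6)
})

test_that("all three segmentation routes agree on a blur-free phantom", {
  ## without partial-volume blur or scanner noise every tissue boundary is
  ## sharp, so region growing, gated watershed and global thresholding must
  ## all recover the baseline hard tissue almost perfectly
  sp <- coarse_spec(seed = 61L)
  sp$blur_sigma_mm <- 0
  sp$noise_sd <- 0
  cs <- generate_case(sp)
  truth <- cs$truth$scan_frame$t1$hard$codes != 0L
  iv <- sp$intensities
  gate <- intensity_gate((iv[["background"]] + iv[["trabecular"]]) / 2,
                         (iv[["cortical"]] + iv[["tooth"]]) / 2)
  dice_vs_truth <- function(mask) 2 * sum(mask & truth) /
    (sum(mask) + sum(truth))
  ps <- phantom_seeds(cs, "t1")
  grown <- grow_from_seeds(cs$volumes$t1, ps$bone_bg)
  expect_gte(dice_vs_truth(grown$codes == 1L), 0.99)
  thr <- global_threshold(cs$volumes$t1, gate)
  expect_gte(dice_vs_truth(thr$codes == 1L), 0.99)
  bone_seed <- ps$bone_bg$index[ps$bone_bg$label == 1L, , drop = FALSE][1, ,
                                                                drop = FALSE]
  ws <- watershed_from_seeds(cs$volumes$t1, seed_set(bone_seed, 1L), gate)
  expect_gte(dice_vs_truth(ws$codes == 1L), 0.99)
})

test_that("seeded growth recovers phantom bone under realistic noise", {
  ## default noise is ~10% of the bone/soft-tissue contrast
  cs <- cached_case(coarse_spec(noise_sd = 50, seed = 31L))
  ps <- phantom_seeds(cs, "t1")
  grown <- grow_from_seeds(cs$volumes$t1, ps$bone_bg)
  truth <- cs$truth$scan_frame$t1$hard$codes != 0L
  dice <- 2 * sum(grown$codes == 1L & truth) /
    (sum(grown$codes == 1L) + sum(truth))
  expect_gte(dice, 0.95)
})
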