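grid8 <- voxel_grid(array(0, c(8, 8, 8)))

lm8 <- function(idx_expr) {
  codes <- array(0L, c(8, 8, 8))
  codes[idx_expr] <- 1L
  label_map(codes, grid8)
}

test_that("label_difference implements the logical subtraction", {
  a <- lm8(cbind(1:8, 4, 4))
  expect_true(all(label_difference(a, a)$codes == 0L))
  b <- lm8(cbind(1:4, 4, 4))          # left 4 voxels of the 8-voxel bar
  d <- label_difference(a, b)
  expect_identical(which(d$codes != 0L),
                   which(lm8(cbind(5:8, 4, 4))$codes != 0L))
  empty <- lm8(cbind(integer(0), integer(0), integer(0)))
  expect_identical(label_difference(a, empty)$codes != 0L, a$codes != 0L)
  expect_error(label_difference(a, lm8(cbind(1, 1, 1))[]), NA)
})

test_that("difference and intersection partition the minuend exactly", {
  set.seed(11)
  for (rep in 1:20) {
    a <- random_label8(); b <- random_label8()
    expect_identical(sum(label_difference(a, b)$codes) +
                       sum(label_intersection(a, b)$codes),
                     sum(a$codes == 1L))
  }
})

test_that("volume_cm3 counts voxels times voxel volume", {
  d <- c(10, 10, 10)
  g1 <- voxel_grid(array(0, d), spacing = c(1, 1, 1))
  expect_equal(volume_cm3(label_map(array(1L, d), g1)), 1.0)
  ## 48,000 voxels at 0.25 mm spacing -> 0.75 cm^3, a typical graft volume
  g2 <- voxel_grid(array(0, c(40, 40, 30)), spacing = c(0.25, 0.25, 0.25))
  expect_equal(volume_cm3(label_map(array(1L, c(40, 40, 30)), g2)), 0.75)
  expect_equal(volume_cm3(label_map(array(0L, d), g1)), 0)
})

test_that("stability ratio is the T3/T2 percentage with guarded zero", {
  expect_equal(stability_ratio(1, 1), 100)
  expect_equal(stability_ratio(0.52, 0.75), 69.33, tolerance = 1e-3)
  expect_equal(stability_ratio(0, 0.5), 0)
  expect_error(stability_ratio(0.5, 0), "undefined")
})

test_that("mean of per-case ratios differs from ratio of means in general", {
  v2 <- c(1.0, 0.2); v3 <- c(0.9, 0.04)
  per_case <- mean(mapply(stability_ratio, v3, v2))
  of_means <- stability_ratio(mean(v3), mean(v2))
  expect_false(isTRUE(all.equal(per_case, of_means)))
})

test_that("dice coefficient matches its definition and edge cases", {
  a <- lm8(cbind(1:8, 1, 1))
  expect_equal(dice_coefficient(a, a), 1)
  b <- lm8(cbind(1:8, 8, 8))
  expect_equal(dice_coefficient(a, b), 0)
  a2 <- lm8(cbind(1:8, 1, 1))
  b2 <- lm8(cbind(c(1:4), 1, c(1, 1, 1, 1)))
  ## |A| = 8, |B| = 4, overlap 4 -> 2*4/12
  expect_equal(dice_coefficient(a2, b2), 2 * 4 / 12)
  empty <- lm8(cbind(integer(0), integer(0), integer(0)))
  expect_equal(dice_coefficient(empty, empty), 1)  # both agree: nothing there
})

test_that("dice equals the brute-force voxel-set oracle on 100 random pairs", {
  set.seed(12)
  for (rep in 1:100) {
    a <- random_label8(stats::runif(1, 0.1, 0.9))
    b <- random_label8(stats::runif(1, 0.1, 0.9))
    expect_identical(dice_coefficient(a, b), dice_oracle(a, b))
    expect_identical(dice_coefficient(a, b), dice_coefficient(b, a))
    expect_true(dice_coefficient(a, b) >= 0 && dice_coefficient(a, b) <= 1)
  }
})

test_that("nested labels give non-positive distances and the analytic dice", {
  d <- c(16, 16, 16)
  g <- voxel_grid(array(0, d), spacing = c(1, 1, 1))
  A <- array(0L, d); A[3:12, 3:12, 3:12] <- 1L
  B <- array(0L, d); B[5:10, 5:10, 5:10] <- 1L
  la <- label_map(A, g); lb <- label_map(B, g)
  expect_equal(dice_coefficient(la, lb), 2 * sum(B) / (sum(A) + sum(B)))
  msh <- signed_surface_distances(la, lb)
  expect_true(all(msh$scalars <= 1e-9))
})

test_that("signed surface distances read out erosion and dilation depths", {
  d <- c(20, 20, 20)
  g <- voxel_grid(array(0, d), spacing = c(1, 1, 1))
  A <- array(0L, d); A[5:16, 5:16, 5:16] <- 1L
  la <- label_map(A, g)
  same <- signed_surface_distances(la, la)
  expect_lt(max(abs(same$scalars)), 1 + 1e-9)
  expect_lt(mean(abs(same$scalars)), 0.51)
  ## erode two voxels off the +x face only
  B <- A; B[15:16, , ] <- 0L
  ero <- signed_surface_distances(la, label_map(B, g))
  face <- ero$vertices[, 1] > max(ero$vertices[, 1]) - 0.3
  expect_equal(mean(ero$scalars[face]), -2, tolerance = 1)
  expect_lt(max(ero$scalars), 1e-6 + 1)
  ## dilate one voxel everywhere (box dilation: face distances 1 mm,
  ## corner distances up to sqrt(3) mm)
  C <- array(0L, d); C[4:17, 4:17, 4:17] <- 1L
  dil <- signed_surface_distances(la, label_map(C, g))
  expect_true(all(dil$scalars > 1 - 1e-6))
  expect_true(all(dil$scalars < sqrt(3) + 0.51))
  expect_equal(mean(dil$scalars), 1, tolerance = 0.75)
})

test_that("empty comparison flags distances to nothing", {
  d <- c(8, 8, 8)
  g <- voxel_grid(array(0, d))
  A <- array(0L, d); A[3:6, 3:6, 3:6] <- 1L
  empty <- label_map(array(0L, d), g)
  expect_warning(msh <- signed_surface_distances(label_map(A, g), empty),
                 "empty")
  expect_true(all(msh$scalars == -Inf))
})

test_that("monotonicity: enlarging the T3 model never lowers ratio or dice", {
  set.seed(13)
  a <- random_label8(0.5)
  small <- label_map(array(as.integer(a$codes == 1L &
                                        as.vector(stats::runif(512) < 0.5)),
                           c(8, 8, 8)), grid8)
  grown <- label_map(array(pmax(small$codes, a$codes), c(8, 8, 8)), grid8)
  v2 <- 0.5
  expect_gte(stability_ratio(volume_cm3(grown), v2),
             stability_ratio(volume_cm3(small), v2))
  expect_gte(dice_coefficient(a, grown), dice_coefficient(a, small))
})

test_that("linear measurements recover a rectangular ridge block", {
  d <- c(40, 20, 50)
  g <- voxel_grid(array(0, d), spacing = c(0.5, 0.5, 0.5))
  codes <- array(0L, d)
  ## block 6 mm wide (x), 10 mm tall (z): x in [8,13.5] mm, z in [5,14.5] mm
  codes[17:28, 5:16, 11:30] <- 1L
  bone <- label_map(codes, g)
  site <- site_spec(11, crest_point = c(11, 5, 14.75),
                    buccolingual_axis = c(1, 0, 0),
                    reference_offset = 10, depths = c(1, 3, 5))
  res <- ridge_linear_measurements(bone, site)
  expect_equal(unname(res$widths_mm), c(6, 6, 6), tolerance = 0.3)
  expect_equal(res$height_mm, 10, tolerance = 0.3)
})

test_that("a plane missing the bone yields zero widths and a warning", {
  d <- c(10, 10, 10)
  g <- voxel_grid(array(0, d))
  bone <- label_map(array(0L, d), g)
  bone$codes[2, 2, 2] <- 1L
  site <- site_spec(21, crest_point = c(50, 50, 50),
                    buccolingual_axis = c(1, 0, 0), depths = c(1, 2, 3))
  expect_warning(res <- ridge_linear_measurements(bone, site), "misses")
  expect_true(all(res$widths_mm == 0))
})

test_that("site specs validate their depth schedule", {
  expect_error(site_spec(11, c(0, 0, 0), c(1, 0, 0), depths = c(3, 1)),
               "ascending")
  expect_error(site_spec(11, c(0, 0, 0), c(1, 0, 0), depths = c(-1, 1)))
})
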