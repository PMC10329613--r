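test_that("phantom generation is bitwise deterministic for a fixed seed", {
  sp <- coarse_spec(noise_sd = 30, seed = 9L)
  a <- generate_case(sp)
  b <- generate_case(sp)
  expect_identical(a$volumes$t1$values, b$volumes$t1$values)
  expect_identical(a$volumes$t3$values, b$volumes$t3$values)
  expect_identical(a$truth$t1frame$graft_t3$codes, b$truth$t1frame$graft_t3$codes)
})

test_that("graft truth hits the target volume and the resorption fraction", {
  cs <- cached_case(coarse_spec())
  tv <- cs$truth$volumes
  expect_lt(abs(tv$v_t2_cm3 - 0.75) / 0.75, 0.05)
  ## ratio equals 1 - resorption fraction within voxelization error
  expect_lt(abs(tv$ratio_pct - 100 * (1 - 0.32)), 2)
})

test_that("resorbed graft is always a subset of the original graft", {
  cs <- cached_case(coarse_spec())
  expect_true(all(cs$truth$t1frame$graft_t3$codes <=
                    cs$truth$t1frame$graft_t2$codes))
})

test_that("zero resorption leaves the block untouched", {
  d <- c(20, 20, 20)
  block <- array(FALSE, d); block[5:16, 5:16, 5:16] <- TRUE
  expect_identical(simulate_resorption(block, 0, seed = 1), block)
})

test_that("uniform-bias resorption removes the requested fraction of a cube", {
  d <- c(28, 28, 28)
  block <- array(FALSE, d); block[5:24, 5:24, 5:24] <- TRUE
  out <- simulate_resorption(block, 0.5,
                             bias = c(buccal = 1, crestal = 1,
                                      lingual = 1, apical = 1), seed = 3)
  expect_lt(abs(sum(out) / sum(block) - 0.5), 0.02)
  expect_true(all(out <= block))
  ## connectivity preserved for a convex block
  cc <- cbctvol:::cpp_connected_components(as.integer(out), d, 26L)
  expect_identical(cc$n, 1L)
})

test_that("buccal-dominant bias erodes the buccal face deeper", {
  d <- c(30, 30, 30)
  g <- voxel_grid(array(0, d), spacing = c(1, 1, 1))
  block <- array(FALSE, d); block[6:25, 6:25, 6:25] <- TRUE
  out <- simulate_resorption(block, 0.3,
                             bias = c(buccal = 6, crestal = 1,
                                      lingual = 0.2, apical = 0.2), seed = 4)
  ref <- label_map(array(as.integer(block), d), g)
  cmp <- label_map(array(as.integer(out), d), g)
  msh <- signed_surface_distances(ref, cmp)
  buccal <- msh$vertices[, 1] > max(msh$vertices[, 1]) - 0.6
  lingual <- msh$vertices[, 1] < min(msh$vertices[, 1]) + 0.6
  expect_lt(mean(msh$scalars[buccal]), mean(msh$scalars[lingual]) - 1)
})

test_that("resorption rejects impossible fractions, protects marked voxels", {
  d <- c(12, 12, 12)
  block <- array(FALSE, d); block[3:10, 3:10, 3:10] <- TRUE
  expect_error(simulate_resorption(block, 1), "fraction")
  protect <- array(FALSE, d); protect[6, 6, 6] <- TRUE
  out <- simulate_resorption(block, 0.6, seed = 5, protect = protect)
  expect_true(out[6, 6, 6])
})

test_that("infeasible block volumes raise a clear error", {
  expect_error(generate_case(coarse_spec(block_volume_cm3 = 50)),
               "does not fit")
})

test_that("phantom cohorts draw reproducibly and carry a consistent truth table", {
  a <- make_cohort(n_cases = 23, seed = 42)
  b <- make_cohort(n_cases = 23, seed = 42)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$truth), 23)
  expect_equal(a$truth$ratio_pct,
               100 * a$truth$v_t3_cm3 / a$truth$v_t2_cm3, tolerance = 1e-12)
  single <- make_cohort(n_cases = 1, seed = 1)
  expect_equal(nrow(single$truth), 1)
  ## calibration: mean T2 volume near 0.75 cm^3 within sampling error
  big <- make_cohort(n_cases = 400, seed = 7)
  expect_lt(abs(mean(big$truth$v_t2_cm3) - 0.75), 0.08)
  expect_lt(abs(mean(1 - big$truth$ratio_pct / 100) - 0.32), 0.04)
})

test_that("cohort truth table writes as CSV", {
  co <- make_cohort(n_cases = 3, seed = 2)
  p <- withr::local_tempfile(fileext = ".csv")
  write_cohort_truth(co, p)
  back <- utils::read.csv(p)
  expect_equal(back$v_t2_cm3, co$truth$v_t2_cm3, tolerance = 1e-9)
})

test_that("phantom seeds land inside their structures with valid labels", {
  cs <- cached_case(coarse_spec())
  for (tp in c("t1", "t2", "t3")) {
    ps <- phantom_seeds(cs, tp)
    sf <- cs$truth$scan_frame[[tp]]
    idx <- ps$bone_bg$index
    lin <- idx[, 1] + dim(sf$hard$codes)[1] *
      (idx[, 2] + dim(sf$hard$codes)[2] * idx[, 3]) + 1
    hard <- sf$hard$codes != 0L
    expect_true(all(hard[lin[ps$bone_bg$label == 1L]]))
    expect_true(all(!hard[lin[ps$bone_bg$label == 2L]]))
    expect_equal(length(unique(ps$teeth$label)), 2)  # one seed per tooth
  }
})
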