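test_that("registering a volume to itself recovers the identity", {
  cs <- cached_case(coarse_spec())
  fx <- cs$volumes$t1
  reg <- register_rigid(fx, fx, registration_config(maxit = c(120, 80, 40)))
  err <- cbctvol:::transform_param_distance(reg$transform, rigid_identity(),
                                            at = cbctvol:::grid_center(fx))
  expect_lt(err$angle_deg, 1e-2)
  expect_lt(err$translation_mm, 1e-2)
  expect_gt(reg$metric, 0.999)
  expect_true(reg$converged)
})

test_that("the NCC metric attains its optimum of 1 at perfect alignment", {
  cs <- cached_case(coarse_spec())
  fx <- cs$volumes$t1
  m <- cbctvol:::level_metric(rep(0, 6), fx, fx, 0L,
                              cbctvol:::grid_center(fx),
                              registration_config())
  expect_equal(m, 1, tolerance = 1e-12)
})

test_that("a known coarse-phantom misalignment is recovered accurately", {
  ## the coarse grid halves the resolution of the full-scale setting, so
  ## the applicable bounds are those of the degraded (noisy) class; the
  ## acceptance suite checks the tight bounds at full resolution
  cs <- cached_case(coarse_spec())
  reg <- register_rigid(cs$volumes$t1, cs$volumes$t2)
  err <- cbctvol:::transform_param_distance(
    reg$transform, cs$truth$transforms$t2,
    at = cbctvol:::grid_center(cs$volumes$t1))
  expect_lt(err$angle_deg, 1.0)
  expect_lt(err$translation_mm, 0.5)
})

test_that("NCC registration is invariant to affine intensity rescaling", {
  cs <- cached_case(coarse_spec())
  mv <- cs$volumes$t2
  mv2 <- mv
  mv2$values <- 3.7 * mv$values + 250
  r1 <- register_rigid(cs$volumes$t1, mv)
  r2 <- register_rigid(cs$volumes$t1, mv2)
  d <- cbctvol:::transform_param_distance(r1$transform, r2$transform,
                                          at = cbctvol:::grid_center(mv))
  expect_lt(d$angle_deg, 0.1)
  expect_lt(d$translation_mm, 0.05)
})

test_that("finer pyramids do not degrade the achieved similarity", {
  cs <- cached_case(coarse_spec())
  fx <- cs$volumes$t1; mv <- cs$volumes$t2
  ## register_rigid reports its final metric at full resolution, so the
  ## two pyramids are compared on the same footing
  r2 <- register_rigid(fx, mv, registration_config(shrink_factors = c(4, 2),
                                                   maxit = c(300, 200)))
  r3 <- register_rigid(fx, mv, registration_config(shrink_factors = c(4, 2, 1)))
  expect_gte(r3$metric, r2$metric - 1e-6)
  ## and the finer pyramid's alignment is tighter in displacement terms
  truth <- cs$truth$transforms$t2
  at <- cbctvol:::grid_center(fx)
  e3 <- cbctvol:::transform_param_distance(r3$transform, truth, at = at)
  expect_lt(e3$translation_mm, 0.5)
})

test_that("registration requires non-constant intensities", {
  g <- voxel_grid(array(1, c(16, 16, 16)))
  expect_error(register_rigid(g, g), "non-constant")
})

test_that("mutual-information metric also aligns the coarse phantom", {
  ## smoke test of the optional metric: it must remove most of the 5-degree
  ## / several-mm misalignment, though NCC remains the accurate default
  cs <- cached_case(coarse_spec())
  reg <- register_rigid(cs$volumes$t1, cs$volumes$t2,
                        registration_config(metric = "mi",
                                            maxit = c(200, 120, 40)))
  expect_true(reg$converged)
  err <- cbctvol:::transform_param_distance(
    reg$transform, cs$truth$transforms$t2,
    at = cbctvol:::grid_center(cs$volumes$t1))
  expect_lt(err$angle_deg, 4)
  expect_lt(err$translation_mm, 1.5)
})
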