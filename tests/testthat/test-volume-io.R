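test_that("NRRD round-trip preserves geometry and values losslessly", {
  set.seed(1)
  g <- voxel_grid(array(rnorm(6 * 5 * 4), c(6, 5, 4)),
                  spacing = c(0.25, 0.25, 0.5), origin = c(1.5, -2, 3))
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(g, p)
  g2 <- read_volume(p)
  expect_identical(g2$dims, g$dims)
  expect_equal(g2$values, g$values, tolerance = 0)
  expect_equal(g2$spacing, g$spacing, tolerance = 1e-9)
  expect_equal(g2$origin, g$origin, tolerance = 1e-9)
  expect_equal(g2$direction, g$direction, tolerance = 1e-9)
})

test_that("NIfTI round-trip preserves geometry through the RAS conversion", {
  set.seed(2)
  g <- voxel_grid(array(rnorm(5 * 4 * 3), c(5, 4, 3)),
                  spacing = c(0.25, 0.5, 0.75), origin = c(-4, 7, 1))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(g, p)
  g2 <- read_volume(p)
  expect_equal(g2$values, g$values, tolerance = 1e-12)
  expect_equal(g2$spacing, g$spacing, tolerance = 1e-6)
  expect_equal(g2$origin, g$origin, tolerance = 1e-4)
  expect_equal(g2$direction, g$direction, tolerance = 1e-6)
})

test_that("label maps round-trip as exact integers, no float coercion", {
  g <- voxel_grid(array(0, c(4, 4, 4)), spacing = c(0.25, 0.25, 0.25))
  lm <- label_map(array(sample(0:2, 64, TRUE), c(4, 4, 4)), g,
                  legend = c(bone = 1L, background = 2L))
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(lm, p)
  l2 <- read_labels(p, legend = lm$legend)
  expect_identical(l2$codes, lm$codes)
  expect_setequal(unique(as.vector(l2$codes)), unique(as.vector(lm$codes)))
})

test_that("header spacing survives to full precision, including anisotropy", {
  g <- voxel_grid(array(1.0, c(2, 2, 2)), spacing = c(0.25, 0.25, 0.5))
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(g, p)
  expect_identical(read_volume(p)$spacing, c(0.25, 0.25, 0.5))
})

test_that("degenerate 1x1x1 volume reads back", {
  g <- voxel_grid(array(7, c(1, 1, 1)), spacing = c(0.25, 0.25, 0.25))
  p <- withr::local_tempfile(fileext = ".nrrd")
  write_volume(g, p)
  g2 <- read_volume(p)
  expect_identical(g2$dims, c(1L, 1L, 1L))
  expect_equal(as.numeric(g2$values), 7)
})

test_that("reader rejects missing files and unknown formats", {
  expect_error(read_volume("no/such/file.nrrd"), "no such file")
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines("junk", p)
  expect_error(read_volume(p), "unsupported")
})

test_that("voxel_volume is the spacing product, invariant to pose", {
  g1 <- voxel_grid(array(0, c(3, 3, 3)), spacing = c(0.25, 0.25, 0.25))
  expect_equal(voxel_volume(g1), 0.015625)
  g2 <- voxel_grid(array(0, c(3, 3, 3)), spacing = c(0.5, 0.25, 2.0),
                   origin = c(10, -5, 2),
                   direction = euler_rotation(0, 0, 90))
  expect_equal(voxel_volume(g2), 0.25)
  expect_equal(voxel_volume(voxel_grid(array(0, c(2, 2, 2)))), 1)
})

test_that("grid validation enforces the geometric invariants", {
  expect_error(voxel_grid(array(0, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "positive")
  bad_dir <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 2), 3, 3)
  expect_error(voxel_grid(array(0, c(2, 2, 2)), direction = bad_dir),
               "orthonormal")
  expect_error(label_map(array(-1L, c(2, 2, 2)),
                         voxel_grid(array(0, c(2, 2, 2)))),
               "nonnegative")
})

test_that("mesh writers produce parseable STL and PLY files", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tri <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  mesh <- surface_mesh(v, tri, scalars = c(-1, 0, 0.5, 2))
  ply <- withr::local_tempfile(fileext = ".ply")
  write_mesh(mesh, ply)
  lines <- readLines(ply)
  expect_identical(lines[1], "ply")
  expect_true(any(grepl("element vertex 4", lines)))
  expect_true(any(grepl("element face 4", lines)))
  expect_true(any(grepl("property float quality", lines)))
  stl <- withr::local_tempfile(fileext = ".stl")
  write_mesh(mesh, stl)
  con <- file(stl, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  expect_identical(readBin(con, "integer", 1, size = 4, endian = "little"), 4L)
})
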