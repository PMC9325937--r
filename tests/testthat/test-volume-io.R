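test_that("volumes round-trip losslessly through every supported format", {
  vol <- image_volume(array(as.double(sample.int(4096, 4 * 5 * 6, TRUE)),
                            c(4, 5, 6)),
                      spacing = c(50, 50, 200))
  for (ext in c(".nii.gz", ".mhd", ".tif")) {
    path <- file.path(withr::local_tempdir(), paste0("vol", ext))
    write_volume(vol, path)
    back <- read_volume(path)
    expect_identical(dim(back$data), dim(vol$data))
    expect_identical(back$spacing, vol$spacing)          # bit-exact spacing
    if (ext == ".tif") {
      # float32 container: single-precision round trip
      expect_lt(max(abs(back$data - vol$data)) / max(abs(vol$data)), 1e-6)
    } else {
      expect_identical(as.vector(back$data), as.vector(vol$data))
    }
  }
})

test_that("constant 4x4x4 volume round-trips identically", {
  vol <- image_volume(array(7, c(4, 4, 4)), spacing = 35)
  path <- file.path(withr::local_tempdir(), "const.nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_identical(as.vector(back$data), as.vector(vol$data))
  expect_identical(back$spacing, c(35, 35, 35))
})

test_that("TIFF stacks carry spacing through the YAML sidecar", {
  vol <- image_volume(array(runif(8 * 8 * 10), c(8, 8, 10)), spacing = 50)
  path <- file.path(withr::local_tempdir(), "stack.tif")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_identical(dim(back$data)[3], 10L)
  expect_identical(back$spacing, c(50, 50, 50))
  # missing sidecar and no override is an explicit error naming the file
  file.remove(trabmorph:::sidecar_path(path))
  expect_error(read_volume(path), "stack.tif")
  expect_silent(read_volume(path, spacing = c(10, 10, 10)))
})

test_that("invalid headers and files are rejected", {
  expect_error(read_volume("no/such/file.nii"), "exist")
  hdr <- file.path(withr::local_tempdir(), "bad.mhd")
  writeLines(c("ObjectType = Image", "NDims = 3", "DimSize = 2 2 2",
               "ElementSpacing = 0 0 0", "ElementType = MET_DOUBLE",
               "ElementDataFile = bad.raw"), hdr)
  writeBin(rep(0, 8), file.path(dirname(hdr), "bad.raw"))
  expect_error(read_volume(hdr), "ElementSpacing")
  expect_error(image_volume(array(1, c(2, 2, 2)), spacing = c(50, -1, 50)))
})

test_that("resampling matches extent arithmetic and reproduces smooth fields", {
  # 60^3 at (15,15,50) um -> 50 um iso covers 900x900x3000 um: dims 18x18x60
  vol <- image_volume(array(rnorm(60^3), c(60, 60, 60)), c(15, 15, 50))
  out <- resample_isotropic(vol, 50)
  expect_identical(dim(out$data), c(18L, 18L, 60L))
  expect_identical(out$spacing, c(50, 50, 50))

  # constant volume stays constant at any spacing
  const <- image_volume(array(3.5, c(12, 10, 8)), c(30, 40, 70))
  rc <- resample_isotropic(const, 55)
  expect_equal(max(abs(rc$data - 3.5)), 0, tolerance = 1e-12)

  # linear ramp reproduced at the new sample points (interior, away from
  # mirror boundary)
  ramp <- image_volume(array(rep(seq_len(40), times = 40 * 40), c(40, 40, 40)),
                       c(25, 25, 25))
  rr <- resample_isotropic(ramp, 40)
  xs <- ((seq_len(dim(rr$data)[1]) - 0.5) * 40) / 25 + 0.5
  expected <- array(rep(xs, times = prod(dim(rr$data)[2:3])), dim(rr$data))
  interior <- 3:(dim(rr$data)[1] - 2)
  expect_lt(max(abs(rr$data - expected)[interior, , ] /
                  abs(expected[interior, , ])), 1e-9)

  expect_error(resample_isotropic(vol, -5), "positive")
  expect_error(resample_isotropic(image_volume(array(1, c(2, 2, 2)), 10), 1e5),
               "coarser")
})

test_that("round-trip resampling of a band-limited volume is accurate", {
  n <- 32
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  # smooth central bump, flat near the faces so the mirror boundary is benign
  smooth <- array(exp(-((g$x - 16.5)^2 + (g$y - 16.5)^2 + (g$z - 16.5)^2) /
                        (2 * (n / 6)^2)), c(n, n, n))
  vol <- image_volume(smooth + 2, 60)
  down <- resample_isotropic(vol, 40)
  back <- resample_isotropic(down, 60)
  rel_rms <- sqrt(mean((back$data - vol$data)^2)) /
    sqrt(mean(vol$data^2))
  expect_lt(rel_rms, 1e-3)
  # mean intensity conserved within 0.1%
  expect_lt(abs(mean(down$data) - mean(vol$data)) / abs(mean(vol$data)), 1e-3)
})

test_that("rigid transforms resample onto the reference grid", {
  vol <- image_volume(array(rnorm(20^3), c(20, 20, 20)), 50)
  ident <- rigid_transform()
  out <- apply_rigid_transform(vol, ident, vol, order = 0L)
  expect_equal(out$data, vol$data, tolerance = 0)
  out1 <- apply_rigid_transform(vol, ident, vol, order = 1L)
  expect_equal(out1$data, vol$data, tolerance = 1e-12)

  # pure one-voxel translation with nearest neighbour shifts the grid by one
  tr <- rigid_transform(diag(3), c(50, 0, 0))
  sh <- apply_rigid_transform(vol, tr, vol, order = 0L)
  expect_equal(sh$data[2:20, , ], vol$data[1:19, , ], tolerance = 0)

  # 90 degree rotation about z maps an x-aligned bar onto the y axis
  bar <- array(0, c(21, 21, 21))
  bar[5:17, 11, 11] <- 1000
  # rotate about the volume centre: x_ref = R (x - c) + c
  R <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  centre <- c(10, 10, 10) * 50
  tr90 <- rigid_transform(R, centre - as.vector(R %*% centre))
  barv <- image_volume(bar, 50)
  rot <- apply_rigid_transform(barv, tr90, barv, order = 0L)
  expect_lt(abs(sum(rot$data > 500) - sum(bar > 500)) / sum(bar > 500), 0.01)
  expect_true(all(rot$data[11, 5:17, 11] > 500))

  expect_error(rigid_transform(matrix(2 * diag(3), 3, 3)), "orthonormal")
})

test_that("transform JSON round-trips", {
  th <- 0.3
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tr <- rigid_transform(R, c(12.5, -3, 40))
  path <- file.path(withr::local_tempdir(), "t.json")
  write_transform(tr, path)
  back <- read_transform(path)
  expect_equal(back$rotation, tr$rotation, tolerance = 1e-12)
  expect_equal(back$translation_um, tr$translation_um, tolerance = 1e-12)
})
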