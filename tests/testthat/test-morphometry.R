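test_that("bvtv is exact voxel counting", {
  full <- binary_mask(array(TRUE, c(5, 5, 5)), 50)
  expect_identical(bvtv(full), 1)
  m <- array(FALSE, c(10, 10, 10))
  m[seq_len(90)] <- TRUE
  expect_identical(bvtv(binary_mask(m, 50)), 0.09)
  r <- random_salt_mask(c(12, 12, 12), 0.3, seed = 2)
  expect_identical(bvtv(r), sum(r$data) / 12^3)
})

test_that("local thickness follows the sphere-fitting convention", {
  # digitized ball of radius 5 voxels at 50 um: max map value 0.5 mm +- 1 voxel
  dims <- c(17, 17, 17)
  g <- expand.grid(x = 1:17, y = 1:17, z = 1:17)
  ball <- array(sqrt((g$x - 9)^2 + (g$y - 9)^2 + (g$z - 9)^2) <= 5, dims)
  map <- local_thickness(binary_mask(ball, 50))
  expect_lt(abs(max(map$values, na.rm = TRUE) - 0.5), 0.05 + 1e-9)

  # slab spanning x/y, 3 voxels thick in z: uniform interior thickness 3 vox
  slab <- array(FALSE, c(20, 20, 20))
  slab[, , 9:11] <- TRUE
  mval <- local_thickness(binary_mask(slab, 50))$values
  expect_equal(unique(as.vector(mval[, , 9:11])), 0.2, tolerance = 1e-12)

  # a 2-voxel plate reads 2 voxel widths (0.1 mm at 50 um)
  plate <- array(FALSE, c(20, 20, 20))
  plate[, , 10:11] <- TRUE
  pv <- local_thickness(binary_mask(plate, 50))$values
  expect_equal(unique(as.vector(pv[, , 10:11])), 0.1, tolerance = 1e-12)

  # single isolated voxel: smallest representable sphere
  iso <- array(FALSE, c(9, 9, 9)); iso[5, 5, 5] <- TRUE
  expect_equal(local_thickness(binary_mask(iso, 50))$values[5, 5, 5], 0.1,
               tolerance = 1e-12)

  expect_error(local_thickness(binary_mask(array(TRUE, c(4, 4, 4)),
                                           c(50, 50, 200))), "isotropic")
  expect_error(local_thickness(binary_mask(array(FALSE, c(4, 4, 4)), 50)),
               "empty")
})

test_that("local thickness matches the brute-force oracle on random masks", {
  # smaller companion of the dedicated acceptance suite: a handful of masks
  for (case in 1:10) {
    m <- random_blob_mask(c(12, 12, 12), fill = runif(1, 0.2, 0.6),
                          sigma = runif(1, 0.8, 1.8), seed = 100 + case)
    if (!any(m$data) || all(m$data)) next
    got <- local_thickness(m)$values
    want <- oracle_local_thickness_vox(m$data) * 50 / 1000
    expect_lt(max(abs(got - want), na.rm = TRUE), 1e-9)
  }
})

test_that("map statistics are population moments over the support", {
  mk_map <- function(vals, supp) {
    structure(list(values = vals, support = supp, spacing = rep(50, 3)),
              class = "local_map")
  }
  supp <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  vals <- array(c(0.1, 0.3, NA, NA), c(2, 2, 1))
  st <- tb_th_stats(mk_map(vals, supp))
  expect_equal(unname(st), c(0.2, 0.1), tolerance = 1e-12)
  const <- mk_map(array(0.25, c(2, 2, 1)), array(TRUE, c(2, 2, 1)))
  expect_equal(unname(tb_th_stats(const)), c(0.25, 0), tolerance = 1e-12)
  expect_error(tb_th_stats(mk_map(vals, array(FALSE, c(2, 2, 1)))), "empty")
})

test_that("tb_sp is local thickness of the complement, by construction", {
  m <- random_blob_mask(c(14, 14, 14), 0.4, 1.2, seed = 9)
  sp <- tb_sp(m)
  inv <- binary_mask(!m$data, m$spacing)
  direct <- local_thickness(inv)
  expect_identical(sp$map$values, direct$values)
  expect_error(tb_sp(binary_mask(array(TRUE, c(3, 3, 3)), 50)), "background")
})

test_that("tb_sc warns when no neighbouring midline exists", {
  bar <- array(FALSE, c(12, 12, 12))
  bar[3:10, 6, 6] <- TRUE
  m <- binary_mask(bar, 50)
  expect_warning(tb_sc(m), "domain")
})

test_that("tb_nd divides node voxels by the analysed volume", {
  sk <- skeletonize(line_mask())           # 9^3 at 50 um = 0.091125 mm^3
  expect_identical(tb_nd(sk), 0)
  skp <- skeletonize(plus_mask())
  expect_equal(tb_nd(skp), 1 / (9 * 0.05)^3, tolerance = 1e-12)
  expect_equal(tb_nd(skp, domain_volume_mm3 = 2), 0.5, tolerance = 1e-12)
  expect_error(tb_nd(skp, domain_volume_mm3 = -1), "positive")
})

test_that("cnr implements the skeleton-sampled contrast formula", {
  dims <- c(10, 10, 10)
  bone <- array(FALSE, dims); bone[3, , 5] <- TRUE
  water <- array(FALSE, dims); water[8, , 5] <- TRUE
  vals <- array(0, dims)
  vals[3, , 5] <- 1000
  vals[8, , 5] <- withr::with_seed(1, rnorm(10, 0, 500))
  vol <- image_volume(vals, 50)
  bs <- as_skeleton3d(bone, 50); ws <- as_skeleton3d(water, 50)
  got <- cnr(vol, bs, ws)
  bgv <- vals[8, , 5]
  expect_equal(got, (1000 - mean(bgv)) / sd(bgv), tolerance = 1e-12)
  # identical means give zero
  vals2 <- vals; vals2[3, , 5] <- mean(bgv)
  expect_equal(cnr(image_volume(vals2, 50), bs, ws), 0, tolerance = 1e-12)
  # halving the background noise doubles CNR
  vals3 <- vals; vals3[8, , 5] <- bgv / 2
  expect_equal(cnr(image_volume(vals3, 50), bs, ws) /
                 ((1000 - mean(bgv) / 2) / (sd(bgv) / 2)), 1, tolerance = 1e-9)
  expect_error(cnr(vol, bs, as_skeleton3d(array(FALSE, dims), 50)), "non-empty")
})

test_that("scale equivariance: spacing scales lengths by k and tb_nd by k^-3", {
  m <- random_blob_mask(c(14, 14, 14), 0.35, 1.4, seed = 21, spacing = 50)
  m2 <- binary_mask(m$data, spacing = 100)
  th1 <- tb_th_stats(local_thickness(m))
  th2 <- tb_th_stats(local_thickness(m2))
  expect_equal(unname(th2), 2 * unname(th1), tolerance = 1e-12)
  sk1 <- skeletonize(m); sk2 <- skeletonize(m2)
  expect_equal(tb_nd(sk2), tb_nd(sk1) / 8, tolerance = 1e-12)
})

test_that("measure_volume composes the standalone operations", {
  m <- random_blob_mask(c(16, 16, 16), 0.35, 1.4, seed = 5)
  vol <- image_volume(array(1000 * m$data +
                              withr::with_seed(6, rnorm(16^3, 0, 60)),
                            dim(m$data)), 50)
  sk <- skeletonize(m)
  res <- measure_volume(vol, m, sk)
  expect_identical(res$bvtv, bvtv(m))
  expect_equal(res$tb_th, unname(tb_th_stats(local_thickness(m))["mean"]))
  expect_equal(res$tb_sp, tb_sp(m)$mean)
  expect_equal(res$tb_nd, tb_nd(sk))
  water <- skeletonize(binary_mask(!m$data, m$spacing))
  expect_equal(res$cnr, cnr(vol, sk, water))
  expect_error(measure_volume(vol, binary_mask(array(FALSE, dim(m$data)), 50)),
               "empty")
})

test_that("local map rendering hits the stated colour anchors", {
  vals <- array(NA_real_, c(3, 1, 1))
  vals[, 1, 1] <- c(0.1, 0.2, 0.3)
  map <- structure(list(values = vals, support = array(TRUE, c(3, 1, 1)),
                        spacing = rep(50, 3)), class = "local_map")
  rgb <- render_local_map(map)
  expect_equal(rgb[1, 1, 1, ], c(0, 0, 1), tolerance = 1e-12)  # min: blue
  expect_equal(rgb[2, 1, 1, ], c(0, 1, 0), tolerance = 1e-12)  # mid: green
  expect_equal(rgb[3, 1, 1, ], c(1, 0, 0), tolerance = 1e-12)  # max: red
  const <- structure(list(values = array(0.2, c(2, 1, 1)),
                          support = array(TRUE, c(2, 1, 1)),
                          spacing = rep(50, 3)), class = "local_map")
  expect_warning(rc <- render_local_map(const), "green")
  expect_equal(rc[1, 1, 1, ], c(0, 1, 0), tolerance = 1e-12)
})
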