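test_that("plate phantoms carry exact closed-form truth", {
  p <- make_plate_phantom(0.1, 0.4, domain_mm = 2, voxel_um = 50)
  expect_equal(p$truth$bvtv, 0.2, tolerance = 1e-12)
  expect_equal(p$truth$tb_sc, 0.5, tolerance = 1e-12)
  expect_equal(bvtv(p$mask), 0.2, tolerance = 1e-12)
  sym <- make_plate_phantom(0.25, 0.25, domain_mm = 2, voxel_um = 50)
  expect_equal(bvtv(sym$mask), 0.5, tolerance = 1e-12)
  expect_error(make_plate_phantom(2, 2, domain_mm = 1), "domain")
})

test_that("measured plate parameters match the analytic truth within a voxel", {
  p <- make_plate_phantom(0.1, 0.4, domain_mm = 2, voxel_um = 50)
  res <- measure_volume(NULL, p$mask)
  vox <- 0.05
  expect_lt(abs(res$tb_th - p$truth$tb_th), vox + 1e-9)
  expect_lt(abs(res$tb_sp - p$truth$tb_sp), vox + 1e-9)
  expect_lt(abs(res$tb_sc - p$truth$tb_sc), vox + 1e-9)
  expect_identical(res$tb_nd, 0)
})

test_that("rod lattices know their junction geometry", {
  rl <- make_rod_lattice(pitch_mm = 1, radius_mm = 0.1, domain_mm = 5,
                         voxel_um = 50)
  expect_identical(rl$truth$n_junctions, 125)
  expect_equal(rl$truth$tb_nd, 1, tolerance = 1e-12)
  # doubling the pitch at fixed domain divides junction count by 8
  rl2 <- make_rod_lattice(pitch_mm = 2, radius_mm = 0.1, domain_mm = 5,
                          voxel_um = 50)
  expect_identical(rl2$truth$n_junctions, 8)
  expect_error(make_rod_lattice(pitch_mm = 0.3, radius_mm = 0.2), "overlap")
})

test_that("gaussian-field phantoms hit the target bone fraction and seed", {
  g <- make_gaussian_field_phantom(0.09, domain_mm = 2, voxel_um = 35,
                                   seed = 3)
  expect_lt(abs(bvtv(g) - 0.09), 0.005)
  g2 <- make_gaussian_field_phantom(0.09, domain_mm = 2, voxel_um = 35,
                                    seed = 3)
  expect_identical(g$data, g2$data)
  g3 <- make_gaussian_field_phantom(0.09, domain_mm = 2, voxel_um = 35,
                                    seed = 4)
  expect_false(identical(g$data, g3$data))
  # larger correlation length -> thicker structures (monotone over 3 settings)
  th <- vapply(c(0.08, 0.12, 0.18), function(cl) {
    m <- make_gaussian_field_phantom(0.2, cl, domain_mm = 2, voxel_um = 35,
                                     seed = 11)
    unname(tb_th_stats(local_thickness(m))["mean"])
  }, numeric(1))
  expect_true(all(diff(th) > 0))
  expect_error(make_gaussian_field_phantom(0.1, corr_length_mm = 0.01,
                                           voxel_um = 35), "2 voxels")
})

test_that("a delta-PSF identity acquisition returns calibrated truth exactly", {
  p <- make_plate_phantom(0.1, 0.4, domain_mm = 1.5, voxel_um = 50)
  prof <- scanner_profile("ident", 50, 50, 50, psf_sigma_um = c(0, 0, 0),
                          noise_sd = 0, bone_value = 800, water_value = -200)
  sc <- simulate_scan(p$mask, prof, seed = 1)
  expect_identical(dim(sc$data), dim(p$mask$data))
  expect_equal(max(abs(sc$data - (-200 + 1000 * p$mask$data))), 0,
               tolerance = 1e-9)
})

test_that("simulated scans are reproducible and blur conserves mass", {
  g <- make_gaussian_field_phantom(0.12, domain_mm = 1.5, voxel_um = 35,
                                   seed = 5)
  prof <- scanner_presets()$pcd
  s1 <- simulate_scan(g, prof, seed = 9)
  s2 <- simulate_scan(g, prof, seed = 9)
  expect_identical(s1$data, s2$data)
  expect_false(identical(s1$data, simulate_scan(g, prof, seed = 10)$data))
  expect_identical(s1$spacing, c(50, 50, 50))
  # unit-sum blur kernel conserves the mean density before sampling
  # (checked on a compactly supported structure so no mass reaches the faces)
  gr <- expand.grid(x = 1:43, y = 1:43, z = 1:43)
  ball <- array(1000 * (sqrt((gr$x - 22)^2 + (gr$y - 22)^2 +
                               (gr$z - 22)^2) <= 9), c(43, 43, 43))
  blurred <- trabmorph:::.gauss_blur_cpp(as.double(ball), dim(ball),
                                         c(2.1, 2.1, 2.9))
  expect_lt(abs(mean(blurred) - mean(ball)) / mean(ball), 1e-3)
  expect_error(simulate_scan(g, scanner_profile("huge", 5000, 5000, 5000)),
               "coarser")
})

test_that("coarser acquisition thickens the measured structure", {
  p <- make_plate_phantom(0.15, 0.45, domain_mm = 1.8, voxel_um = 30)
  pcd <- simulate_scan(p$mask, scanner_presets()$pcd, seed = 2)
  eid <- simulate_scan(p$mask, scanner_presets()$eid, seed = 2)
  th_p <- analyze_scan(pcd, method = "arg",
                       config = arg_config(smooth_sigma_vox = 0.6))$result$tb_th
  th_e <- analyze_scan(eid, method = "arg",
                       config = arg_config(smooth_sigma_vox = 0.6))$result$tb_th
  expect_gt(th_e, th_p)
  expect_gt(th_p, 0.15 - 0.03)
})

test_that("cohorts are reproducible with spread-out target fractions", {
  cohort <- make_specimen_cohort(n = 4, seed = 8, domain_mm = 1.5)
  cohort2 <- make_specimen_cohort(n = 4, seed = 8, domain_mm = 1.5)
  expect_identical(lapply(cohort, function(s) s$truth$data),
                   lapply(cohort2, function(s) s$truth$data))
  expect_identical(names(cohort[[1]]$scans), c("micro", "pcd", "eid"))
  targets <- vapply(cohort, `[[`, numeric(1), "target_bvtv")
  expect_true(all(targets >= 0.05 & targets <= 0.15))
  measured <- vapply(cohort, function(s) bvtv(s$truth), numeric(1))
  expect_equal(measured, targets, tolerance = 0.01)
  expect_error(make_specimen_cohort(n = 2), "at least 3")
  expect_error(make_specimen_cohort(n = 4, bvtv_range = c(0.5, 0.1)),
               "interval")
})
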