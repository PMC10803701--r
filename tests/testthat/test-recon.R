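test_that("OS-EM conserves counts on matched noiseless data", {
  m <- tiny_sphere_maps(dims = c(32L, 32L, 16L), sphere_d = 50, conc = 2)
  acq <- tiny_acq()
  ps <- forward_project(m$activity, m$mu, acq)
  rec <- osem_reconstruct(ps, m$mu, recon_config(TRUE, iterations = 16))
  # total reconstructed counts (per the system model) match the data
  scale <- acq$sensitivity_cps_MBq * acq$time_per_projection_s * voxel_mL(rec)
  ps_rec <- forward_project(rec, m$mu, acq)
  expect_rel_equal(sum(ps_rec$counts), sum(ps$counts), 0.01)
  # and total activity is conserved within 1%
  expect_rel_equal(sum(rec$values) * voxel_mL(rec), m$total_MBq, 0.01)
})

test_that("all-zero projections give a zero image with a warning", {
  m <- tiny_sphere_maps()
  acq <- tiny_acq(n_projections = 10)
  ps <- forward_project(m$activity, m$mu, acq)
  ps$counts[] <- 0
  expect_warning(rec <- osem_reconstruct(ps, m$mu, recon_config(TRUE)),
                 "zero")
  expect_true(all(rec$values == 0))
})

test_that("resolution recovery sharpens and stays non-negative", {
  dims <- c(32L, 32L, 16L)
  vox <- 4.42
  origin <- -(dims - 1) / 2 * vox
  act <- array(0, dims); act[16, 16, 8] <- 10
  av <- voxel_volume(act, vox, origin, "activity")
  mu0 <- voxel_volume(array(0, dims), vox, origin, "attenuation")
  acq <- tiny_acq()
  ps <- forward_project(av, mu0, acq)
  rec_rr <- osem_reconstruct(ps, mu0, recon_config(TRUE, iterations = 8))
  rec_nr <- osem_reconstruct(ps, mu0, recon_config(FALSE, iterations = 8))
  expect_gt(max(rec_rr$values), max(rec_nr$values))
  expect_true(all(rec_rr$values >= 0))
  expect_true(all(rec_nr$values >= 0))
})

test_that("subset count must divide projections", {
  m <- tiny_sphere_maps()
  ps <- forward_project(m$activity, m$mu, tiny_acq(n_projections = 21))
  expect_error(osem_reconstruct(ps, m$mu, recon_config(TRUE, subsets = 10L)),
               "divide")
})

test_that("matched-model fidelity: uniform cylinder interior within 2%", {
  # >= 500 mL uniform cylinder (diameter 110 mm, height 60 mm = 570 mL)
  dims <- c(36L, 36L, 20L)
  vox <- 4.42
  origin <- -(dims - 1) / 2 * vox
  xs <- origin[1] + (seq_len(dims[1]) - 1) * vox
  zs <- origin[3] + (seq_len(dims[3]) - 1) * vox
  incyl <- outer(outer(xs^2, xs^2, "+") <= 55^2, abs(zs) <= 30, "&")
  act <- array(0, dims); act[incyl] <- 1.5
  mu <- array(0, dims); mu[incyl] <- 0.154
  av <- voxel_volume(act, vox, origin, "activity")
  mv <- voxel_volume(mu, vox, origin, "attenuation")
  acq <- tiny_acq(n_projections = 30, orbit = 160)
  ps <- forward_project(av, mv, acq)
  rec <- osem_reconstruct(ps, mv, recon_config(TRUE))
  interior <- outer(outer(xs^2, xs^2, "+") <= (55 - 2 * vox)^2,
                    abs(zs) <= 30 - 2 * vox, "&")
  expect_rel_equal(mean(rec$values[interior]), 1.5, 0.02)
})

test_that("RR reconstruction of a sphere shows edge ringing", {
  m <- tiny_sphere_maps(dims = c(34L, 34L, 18L), sphere_d = 40, conc = 2)
  acq <- tiny_acq(n_projections = 20)
  ps <- forward_project(m$activity, m$mu, acq)
  rec <- osem_reconstruct(ps, m$mu, recon_config(TRUE, iterations = 16))
  voi_in <- sphere_voi(rec, c(0, 0, 0), 20)        # deep interior
  expect_gt(max(rec$values), 1.02 * mean(rec$values[voi_in]))
})

test_that("gaussian_postfilter preserves totals and hits its FWHM", {
  dims <- c(31L, 31L, 31L)
  vox <- 2
  origin <- -(dims - 1) / 2 * vox
  delta <- array(0, dims); delta[16, 16, 16] <- 1
  dv <- voxel_volume(delta, vox, origin, "counts")
  f <- gaussian_postfilter(dv, 8.8)
  expect_rel_equal(sum(f$values), 1, 0.001)
  # measured FWHM along x within 5%
  prof <- f$values[, 16, 16]
  half <- max(prof) / 2
  above <- which(prof >= half)
  # linear interpolation at the half-maximum crossings
  lo <- min(above); hi <- max(above)
  xl <- lo - 1 + (prof[lo - 1] - half) / (prof[lo - 1] - prof[lo])
  xr <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  expect_rel_equal((xr - xl) * vox, 8.8, 0.05)
  # uniform input stays uniform in the interior
  u <- voxel_volume(array(3, dims), vox, origin, "counts")
  fu <- gaussian_postfilter(u, 8.8)
  expect_rel_equal(mean(fu$values[10:22, 10:22, 10:22]), 3, 0.001)
  # tiny FWHM is the identity (with a warning)
  expect_warning(f0 <- gaussian_postfilter(dv, 0.5), "identity")
  expect_equal(f0$values, dv$values, tolerance = 1e-6)
})

test_that("calibration factor is self-consistent and scales with sensitivity", {
  acq <- tiny_acq(n_projections = 20)
  cfg <- recon_config(TRUE, iterations = 8)
  cal <- simulate_calibration(acq, cfg, concentration_MBq_mL = 0.2,
                              cylinder_mm = c(100, 80), voxel_size_mm = 4.42)
  expect_gt(cal, 0)
  # factor near unity because the forward model carries absolute units
  expect_rel_equal(cal, 1, 0.05)
  acq2 <- tiny_acq(n_projections = 20)
  acq2$sensitivity_cps_MBq <- 2 * acq$sensitivity_cps_MBq
  cal2 <- simulate_calibration(acq2, cfg, concentration_MBq_mL = 0.2,
                               cylinder_mm = c(100, 80), voxel_size_mm = 4.42)
  # output already normalizes by the modelled sensitivity, so the factor is
  # sensitivity-independent in the noiseless limit
  expect_rel_equal(cal2, cal, 0.01)
  expect_error(simulate_calibration(acq, cfg, concentration_MBq_mL = 0),
               "activity")
})

test_that("to_activity_concentration validates and scales", {
  vv <- voxel_volume(array(2, c(4, 4, 4)), 4.42, c(0, 0, 0), "activity")
  out <- to_activity_concentration(vv, 0.5)
  expect_equal(out$values[1], 4)
  expect_error(to_activity_concentration(vv, NULL), "calibration")
})
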