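test_that("psf_fwhm combines intrinsic and distance terms", {
  col <- list(intrinsic_fwhm_mm = 3.9, resolution_slope = 0.0633)
  expect_equal(psf_fwhm(0, col), 3.9)
  expect_equal(psf_fwhm(100, col), sqrt(3.9^2 + 6.33^2))
  expect_rel_equal(psf_fwhm(100, col), 7.4, 0.01)   # typical LEHR at 10 cm
  col2 <- col; col2$resolution_slope <- 2 * col$resolution_slope
  expect_rel_equal(psf_fwhm(5000, col2) / psf_fwhm(5000, col), 2, 0.02)
  expect_error(psf_fwhm(-1, col), "distance")
})

test_that("projector conserves counts for a centred source without attenuation", {
  dims <- c(33L, 33L, 21L)
  vox <- 4.42
  origin <- -(dims - 1) / 2 * vox
  act <- array(0, dims)
  act[17, 17, 11] <- 3                      # voxel at the rotation centre
  av <- voxel_volume(act, vox, origin, "activity")
  # cardinal angles: the rotation is exact, so a single voxel is conserved
  acq4 <- tiny_acq(n_projections = 4)
  ps <- forward_project(av, NULL, acq4, use_psf = FALSE, use_atten = FALSE)
  expected <- 3 * vox^3 / 1000 * acq4$sensitivity_cps_MBq *
    acq4$time_per_projection_s
  for (i in 1:4)
    expect_rel_equal(sum(ps$counts[, , i]), expected, 1e-6)
  # oblique angles: conservation holds for smooth sources (the bilinear
  # rotation is second-order accurate); use a centred Gaussian blob
  xs <- origin[1] + (seq_len(dims[1]) - 1) * vox
  zs <- origin[3] + (seq_len(dims[3]) - 1) * vox
  blob <- array(exp(-outer(xs^2, xs^2, "+") / (2 * 15^2)), dims) *
    rep(exp(-zs^2 / (2 * 12^2)), each = dims[1] * dims[2])
  bv <- voxel_volume(blob, vox, origin, "activity")
  acq <- tiny_acq(n_projections = 20)
  for (psf in c(FALSE, TRUE)) {
    psb <- forward_project(bv, NULL, acq, use_psf = psf, use_atten = FALSE)
    totals <- apply(psb$counts, 3, sum)
    expect_lt(max(abs(totals - mean(totals))) / mean(totals), 0.005)
    expect_rel_equal(mean(totals),
                     sum(blob) * vox^3 / 1000 * acq$sensitivity_cps_MBq *
                       acq$time_per_projection_s, 0.005)
  }
})

test_that("attenuation follows Beer-Lambert for a known depth", {
  dims <- c(33L, 33L, 11L)
  vox <- 2
  origin <- -(dims - 1) / 2 * vox
  act <- array(0, dims); act[17, 17, 6] <- 1
  mu_val <- 0.154
  mu <- array(mu_val, dims)
  av <- voxel_volume(act, vox, origin, "activity")
  mv <- voxel_volume(mu, vox, origin, "attenuation")
  acq <- tiny_acq(n_projections = 1, orbit = 100)
  ps <- forward_project(av, mv, acq, use_psf = FALSE, use_atten = TRUE)
  ps0 <- forward_project(av, mv, acq, use_psf = FALSE, use_atten = FALSE)
  # depth from the centre voxel to the +y exit face: 16.5 voxels minus the
  # half-voxel self-attenuation offset
  depth_cm <- (16.5 - 0.5 + 0.5) * vox / 10  # cumulative rule: 16 above + half self
  expect_rel_equal(sum(ps$counts) / sum(ps0$counts),
                   exp(-mu_val * (16 + 0.5) * vox / 10), 0.01)
})

test_that("forward and back projectors are exact adjoints", {
  set.seed(11)
  dims <- c(32L, 32L, 32L)
  x <- array(runif(prod(dims)), dims)
  mu <- array(runif(prod(dims)) * 0.15, dims)
  y <- matrix(runif(dims[1] * dims[3]), dims[1], dims[3])
  args <- list(dims = dims, vox = 4.42, orbit = 250,
               si = 3.9 / 2.3548, ss = 0.0633 / 2.3548)
  for (th in c(0, 18.2, 45, 77.7, 133)) {
    for (psf in c(TRUE, FALSE)) {
      Px <- gridspect:::cpp_fp_angle(x, mu, dims, th, args$vox, args$orbit,
                                     args$si, args$ss, psf, TRUE)
      Pty <- gridspect:::cpp_bp_angle(y, mu, dims, th, args$vox, args$orbit,
                                      args$si, args$ss, psf, TRUE)
      lhs <- sum(Px * y); rhs <- sum(x * Pty)
      expect_lt(abs(lhs - rhs) / abs(lhs), 1e-5)
    }
  }
})

test_that("rotational consistency: rotating phantom shifts the sinogram", {
  # an off-centre smooth blob projected at angle 0 equals the same blob
  # rotated by the inter-projection angle and projected at the next index
  dims <- c(48L, 48L, 12L)
  vox <- 4
  origin <- -(dims - 1) / 2 * vox
  xs <- origin[1] + (seq_len(dims[1]) - 1) * vox
  zs <- origin[3] + (seq_len(dims[3]) - 1) * vox
  blob <- function(cx, cy) {
    dx2 <- outer((xs - cx)^2, (xs - cy)^2, "+")
    array(exp(-dx2 / (2 * 15^2)), dims) *
      rep(exp(-zs^2 / (2 * 10^2)), each = dims[1] * dims[2])
  }
  acq <- tiny_acq(n_projections = 12, orbit = 160)
  dtheta <- 360 / 12
  a1 <- voxel_volume(blob(30, 0), vox, origin, "activity")
  phi <- dtheta * pi / 180
  a2 <- voxel_volume(blob(30 * cos(phi), 30 * sin(phi)), vox, origin, "activity")
  p1 <- forward_project(a1, NULL, acq, use_psf = FALSE, use_atten = FALSE)
  p2 <- forward_project(a2, NULL, acq, use_psf = FALSE, use_atten = FALSE)
  # p2 at angle index i+1 should match p1 at angle index i
  for (i in 1:10)
    expect_rel_equal(sum(abs(p2$counts[, , i + 1] - p1$counts[, , i])) /
                       sum(p1$counts[, , i]) + 1, 1, 0.015)
})

test_that("add_poisson is seed-deterministic with the right mean", {
  dims <- c(8L, 8L, 4L)
  counts <- array(50, c(8, 4, 10))
  ps <- gridspect:::new_projection_set(counts, seq(0, 324, by = 36),
                                       "expected", tiny_acq(10))
  n1 <- add_poisson(ps, 42)
  n2 <- add_poisson(ps, 42)
  expect_identical(n1$counts, n2$counts)
  expect_equal(n1$rng_seed, 42)
  expect_true(all(n1$counts == floor(n1$counts)))
  # mean over many bins: 8*4*10 = 320 draws at mean 50
  expect_lt(abs(mean(n1$counts) - 50), 3 * sqrt(50 / 320) * 3)
  # zero expectation stays zero
  z <- ps; z$counts[] <- 0
  expect_true(all(add_poisson(z, 1)$counts == 0))
  bad <- ps; bad$counts[1] <- -1
  expect_error(add_poisson(bad, 1), "non-negative")
})

test_that("orbit radius and lattice mismatches are rejected", {
  m <- tiny_sphere_maps()
  acq_small <- tiny_acq(orbit = 10)
  expect_error(forward_project(m$activity, m$mu, acq_small), "orbit")
  mu_bad <- voxel_volume(array(0, c(4, 4, 4)), 4.42, c(0, 0, 0), "attenuation")
  expect_error(forward_project(m$activity, mu_bad, tiny_acq()), "lattice")
})
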