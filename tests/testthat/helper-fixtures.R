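# Shared fixtures: small, fast acquisition/phantom setups used across tests.
# Everything is generated in code; nothing is read from disk.

# small-matrix acquisition for fast projector/recon tests
tiny_acq <- function(n_projections = 20, time_s = 10, orbit = 160,
                     psf = list(intrinsic_fwhm_mm = 3.9,
                                resolution_slope = 0.0633)) {
  acquisition_config(n_projections = n_projections, matrix_size = 32,
                     time_per_projection_s = time_s, orbit_radius_mm = orbit,
                     collimator = psf, sensitivity_cps_MBq = 90,
                     nuclide = "tc99m", mu_water_cm = 0.154)
}

# uniform sphere activity/mu maps on a small lattice centred in a water
# cylinder; returns list(activity, mu, total_MBq)
tiny_sphere_maps <- function(dims = c(32L, 32L, 20L), vox = 4.42,
                             sphere_d = 40, conc = 2, mu_w = 0.154,
                             cyl_d = NULL, cyl_h = NULL) {
  origin <- -(dims - 1) / 2 * vox
  xs <- origin[1] + (seq_len(dims[1]) - 1) * vox
  ys <- origin[2] + (seq_len(dims[2]) - 1) * vox
  zs <- origin[3] + (seq_len(dims[3]) - 1) * vox
  r2 <- outer(outer(xs^2, ys^2, "+"), zs^2, "+")
  act <- array(0, dims)
  act[r2 <= (sphere_d / 2)^2] <- conc
  if (is.null(cyl_d)) cyl_d <- (dims[1] - 4) * vox
  if (is.null(cyl_h)) cyl_h <- (dims[3] - 2) * vox
  incyl <- outer(outer(xs^2, ys^2, "+") <= (cyl_d / 2)^2,
                 abs(zs) <= cyl_h / 2, "&")
  mu <- array(0, dims)
  mu[incyl] <- mu_w
  list(activity = voxel_volume(act, vox, origin, "activity"),
       mu = voxel_volume(mu, vox, origin, "attenuation"),
       total_MBq = sum(act) * vox^3 / 1000)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
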