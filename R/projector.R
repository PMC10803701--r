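#' SPECT acquisition configuration and collimator presets
#'
#' The forward model is a rotation-based parallel-beam projector with
#' attenuation, a distance-dependent Gaussian collimator-detector response
#' (CDR), a global photopeak sensitivity, and scaling to activity x time.
#' Presets bundle typical collimator/nuclide combinations; the true system
#' constants of a given camera are not public, so the preset values are
#' chosen to reproduce typical clinical system resolutions and count
#' densities and are freely overridable.
#'
#' @param n_projections number of evenly spaced angles over `arc_deg`.
#' @param arc_deg orbit arc in degrees (default 360).
#' @param matrix_size detector matrix (default 128).
#' @param pixel_size_mm detector pixel (default 4.42 mm).
#' @param time_per_projection_s acquisition time per angle.
#' @param orbit_radius_mm circular orbit radius (collimator face to axis).
#' @param collimator list with `intrinsic_fwhm_mm` and `resolution_slope`
#'   (mm FWHM per mm distance).
#' @param sensitivity_cps_MBq photopeak system sensitivity.
#' @param nuclide `"tc99m"` or `"lu177"`.
#' @param mu_water_cm water attenuation at the photopeak energy.
#' @return An `acquisition_config`.
#' @export
acquisition_config <- function(n_projections = 60, arc_deg = 360,
                               matrix_size = 128, pixel_size_mm = 4.42,
                               time_per_projection_s = 45,
                               orbit_radius_mm = 180,
                               collimator = list(intrinsic_fwhm_mm = 3.9,
                                                 resolution_slope = 0.0633),
                               sensitivity_cps_MBq = 90,
                               nuclide = c("tc99m", "lu177"),
                               mu_water_cm = 0.154) {
  nuclide <- match.arg(nuclide)
  if (n_projections < 1) stop("need at least one projection")
  if (pixel_size_mm <= 0) stop("pixel size must be > 0")
  if (sensitivity_cps_MBq <= 0) stop("sensitivity must be > 0")
  structure(list(n_projections = as.integer(n_projections), arc_deg = arc_deg,
                 matrix_size = as.integer(matrix_size),
                 pixel_size_mm = pixel_size_mm,
                 time_per_projection_s = time_per_projection_s,
                 orbit_radius_mm = orbit_radius_mm,
                 collimator = collimator,
                 sensitivity_cps_MBq = sensitivity_cps_MBq,
                 nuclide = nuclide, mu_water_cm = mu_water_cm),
            class = "acquisition_config")
}

#' @rdname acquisition_config
#' @param preset `"tc99m_lehr"` (LEHR, 140.5 keV) or `"lu177_megp"`
#'   (MEGP, 208 keV photopeak).
#' @param ... overrides passed to [acquisition_config()].
#' @export
acq_preset <- function(preset = c("tc99m_lehr", "lu177_megp"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    tc99m_lehr = list(collimator = list(intrinsic_fwhm_mm = 3.9,
                                        resolution_slope = 0.0633),
                      sensitivity_cps_MBq = 90, nuclide = "tc99m",
                      mu_water_cm = 0.154, time_per_projection_s = 45,
                      orbit_radius_mm = 180),
    lu177_megp = list(collimator = list(intrinsic_fwhm_mm = 4.0,
                                        resolution_slope = 0.085),
                      sensitivity_cps_MBq = 10, nuclide = "lu177",
                      mu_water_cm = 0.137, time_per_projection_s = 90,
                      orbit_radius_mm = 180))
  args <- utils::modifyList(base, list(...))
  do.call(acquisition_config, args)
}

#' Collimator-detector response FWHM at a distance
#'
#' @param distance_mm source-to-collimator distance, >= 0.
#' @param collimator list with `intrinsic_fwhm_mm` and `resolution_slope`.
#' @return FWHM in mm: `sqrt(intrinsic^2 + (slope * distance)^2)`.
#' @export
psf_fwhm <- function(distance_mm, collimator) {
  if (any(distance_mm < 0)) stop("distance must be >= 0")
  sqrt(collimator$intrinsic_fwhm_mm^2 +
         (collimator$resolution_slope * distance_mm)^2)
}

new_projection_set <- function(counts, angles, kind, acq, seed = NULL) {
  structure(list(counts = counts, angles_deg = angles, kind = kind,
                 acquisition = acq, rng_seed = seed),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<projection_set> %d angles of %d x %d bins (%s), total %.4g counts\n",
              d[3], d[1], d[2], x$kind, sum(x$counts)))
  invisible(x)
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))  # 1/2.3548

#' Forward-project an activity map
#'
#' For each angle the volume is rotated so the detector sits at +y, each
#' depth slab is attenuated by `exp(-integral mu dl)` toward the detector
#' (half-voxel self-attenuation offset), blurred with the depth-dependent
#' CDR, and summed; expected counts are the ray sums scaled by
#' `sensitivity x time x voxel volume`.  Scatter is not simulated: the model
#' corresponds to primary photons with ideal scatter rejection.
#'
#' @param activity activity `voxel_volume` (MBq/mL), isotropic voxels.
#' @param mu attenuation `voxel_volume` (1/cm) on the same lattice.
#' @param acq an [acquisition_config()].
#' @param use_psf include the CDR blur (default TRUE).
#' @param use_atten include attenuation (default TRUE).
#' @return A `projection_set` of expected (real-valued) counts.
#' @export
forward_project <- function(activity, mu, acq, use_psf = TRUE,
                            use_atten = TRUE) {
  stopifnot(inherits(activity, "voxel_volume"))
  d <- dim(activity$values)
  if (!is.null(mu) && !identical(dim(mu$values), d))
    stop("activity and mu lattices differ")
  vox <- activity$voxel_size_mm[1]
  if (any(abs(activity$voxel_size_mm - vox) > 1e-9))
    stop("projector requires isotropic voxels")
  half_extent <- max(d[1], d[2]) / 2 * vox
  if (acq$orbit_radius_mm < half_extent * 0.999)
    stop("orbit radius smaller than the transaxial phantom extent")
  angles <- acq$arc_deg * (seq_len(acq$n_projections) - 1) / acq$n_projections
  muv <- if (is.null(mu)) numeric(prod(d)) else mu$values
  scale <- acq$sensitivity_cps_MBq * acq$time_per_projection_s * voxel_mL(activity)
  sig_int <- acq$collimator$intrinsic_fwhm_mm * FWHM_TO_SIGMA
  sig_slope <- acq$collimator$resolution_slope * FWHM_TO_SIGMA
  counts <- array(0, dim = c(d[1], d[3], acq$n_projections))
  for (i in seq_along(angles)) {
    counts[, , i] <- cpp_fp_angle(activity$values, muv, d, angles[i], vox,
                                  acq$orbit_radius_mm, sig_int, sig_slope,
                                  use_psf, use_atten) * scale
  }
  new_projection_set(counts, angles, "expected", acq)
}

#' Add Poisson counting noise to expected projections
#'
#' @param expected a `projection_set` of kind `"expected"`.
#' @param seed integer RNG seed (recorded in the result).
#' @return A `projection_set` of kind `"noisy"` with integer counts.
#' @export
add_poisson <- function(expected, seed) {
  stopifnot(inherits(expected, "projection_set"))
  if (expected$kind != "expected") stop("input must be expected counts")
  if (any(expected$counts < 0)) stop("expected counts must be non-negative")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  noisy <- array(rpois(length(expected$counts), expected$counts),
                 dim = dim(expected$counts))
  new_projection_set(noisy, expected$angles_deg, "noisy",
                     expected$acquisition, seed)
}

# backproject a stack of projections (subset of angles); exact adjoint of
# forward_project restricted to those angles.
backproject <- function(counts, angle_idx, angles, mu, dims, vox, acq,
                        use_psf, use_atten) {
  muv <- if (is.null(mu)) numeric(prod(dims)) else mu$values
  sig_int <- acq$collimator$intrinsic_fwhm_mm * FWHM_TO_SIGMA
  sig_slope <- acq$collimator$resolution_slope * FWHM_TO_SIGMA
  out <- array(0, dim = dims)
  for (i in angle_idx) {
    out <- out + cpp_bp_angle(counts[, , i], muv, dims, angles[i], vox,
                              acq$orbit_radius_mm, sig_int, sig_slope,
                              use_psf, use_atten)
  }
  out
}

#' Simulate the image calibration factor
#'
#' Simulates and reconstructs a large uniform cylinder of known activity
#' concentration with the given acquisition/reconstruction settings; the
#' calibration factor is the mean reconstructed voxel value in a central
#' eroded VOI divided by the true concentration (reconstructed-value units
#' per MBq/mL).
#'
#' @param acq an [acquisition_config()].
#' @param recon_cfg a [recon_config()] (the factor is
#'   reconstruction-setting specific).
#' @param concentration_MBq_mL uniform concentration (> 0).
#' @param cylinder_mm calibration cylinder c(diameter, height).
#' @param voxel_size_mm reconstruction voxel.
#' @return Calibration factor (> 0).
#' @export
simulate_calibration <- function(acq, recon_cfg,
                                 concentration_MBq_mL = 0.1,
                                 cylinder_mm = c(160, 160),
                                 voxel_size_mm = 4.42) {
  if (concentration_MBq_mL <= 0) stop("calibration activity must be > 0")
  cyl <- container_cylinder(cylinder_mm[1], cylinder_mm[2])
  nxy <- as.integer(ceiling(cylinder_mm[1] / voxel_size_mm)) + 8L
  nz <- as.integer(ceiling(cylinder_mm[2] / voxel_size_mm)) + 4L
  dims <- c(nxy, nxy, nz)
  origin <- -(dims - 1) / 2 * voxel_size_mm
  xs <- origin[1] + (seq_len(dims[1]) - 1) * voxel_size_mm
  ys <- origin[2] + (seq_len(dims[2]) - 1) * voxel_size_mm
  zs <- origin[3] + (seq_len(dims[3]) - 1) * voxel_size_mm
  inc <- cyl$mask_fn(xs, ys, zs)
  act <- voxel_volume(inc * concentration_MBq_mL, voxel_size_mm, origin, "activity")
  mu <- voxel_volume(inc * acq$mu_water_cm, voxel_size_mm, origin, "attenuation")
  ps <- forward_project(act, mu, acq)
  rec <- osem_reconstruct(ps, mu, recon_cfg)
  # central VOI: erode radially by 3 voxels, half height
  r_in <- cyl$radius - 3 * voxel_size_mm
  voi <- cyl$mask_fn(xs, ys, zs) &
    outer(outer(xs^2, ys^2, "+"), rep(0, length(zs)), "+") <= r_in^2 &
    outer(array(TRUE, dims[1:2]), abs(zs) <= cylinder_mm[2] / 4)
  mean(rec$values[voi]) / concentration_MBq_mL
}
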