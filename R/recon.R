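#' Reconstruction configuration
#'
#' OS-EM settings.  With resolution recovery (RR) the depth-dependent CDR is
#' part of the system model in both the forward and back steps; the usual
#' operating points are 16 iterations x 10 subsets with RR and 4 x 10
#' without (optionally followed by a Gaussian post-filter).
#'
#' @param resolution_recovery logical; model the CDR in reconstruction.
#' @param iterations full OS-EM iterations (default 16 with RR, 4 without).
#' @param subsets number of angle-interleaved subsets (default 10).
#' @param post_filter_fwhm_mm optional 3D Gaussian post-filter FWHM.
#' @param voxel_size_mm reconstruction voxel (default 4.42 mm isotropic).
#' @param calibration optional calibration factor from
#'   [simulate_calibration()].
#' @return A `recon_config`.
#' @export
recon_config <- function(resolution_recovery = TRUE,
                         iterations = if (resolution_recovery) 16L else 4L,
                         subsets = 10L, post_filter_fwhm_mm = NULL,
                         voxel_size_mm = 4.42, calibration = NULL) {
  if (iterations < 1) stop("need at least one iteration")
  structure(list(resolution_recovery = resolution_recovery,
                 iterations = as.integer(iterations),
                 subsets = as.integer(subsets),
                 post_filter_fwhm_mm = post_filter_fwhm_mm,
                 voxel_size_mm = voxel_size_mm,
                 calibration = calibration),
            class = "recon_config")
}

#' OS-EM reconstruction with attenuation compensation
#'
#' Standard multiplicative OS-EM update
#' `x <- x * Pt_s(y_s / P_s x) / Pt_s 1` cycling over angle-interleaved
#' subsets.  The system model always includes attenuation; the CDR is
#' included only when `resolution_recovery` is on.  Initialization is
#' uniform inside the circular field of view; voxels with negligible subset
#' sensitivity are frozen at zero.  Because the forward model includes the
#' sensitivity x time x voxel-volume scaling, the reconstruction converges
#' to activity concentration (MBq/mL) up to the calibration factor.
#'
#' @param projections a `projection_set`.
#' @param mu attenuation `voxel_volume` on the reconstruction grid.
#' @param cfg a [recon_config()].
#' @return A `voxel_volume` of reconstructed values.
#' @export
osem_reconstruct <- function(projections, mu, cfg) {
  stopifnot(inherits(projections, "projection_set"),
            inherits(cfg, "recon_config"))
  acq <- projections$acquisition
  y <- projections$counts
  nang <- dim(y)[3]
  if (nang %% cfg$subsets != 0)
    stop("subsets must divide the number of projections")
  dims <- dim(mu$values)
  if (!identical(dim(y)[1:2], c(dims[1], dims[3])))
    stop("projection bins inconsistent with the mu lattice")
  vox <- mu$voxel_size_mm[1]
  angles <- projections$angles_deg
  use_psf <- cfg$resolution_recovery
  if (sum(y) == 0) {
    warning("all-zero projection data; returning a zero volume")
    return(voxel_volume(array(0, dims), mu$voxel_size_mm, mu$origin_mm, "activity"))
  }
  subsets <- lapply(seq_len(cfg$subsets), function(s)
    seq(s, nang, by = cfg$subsets))
  scale <- acq$sensitivity_cps_MBq * acq$time_per_projection_s * vox^3 / 1000
  muv <- mu$values
  sig_int <- acq$collimator$intrinsic_fwhm_mm * FWHM_TO_SIGMA
  sig_slope <- acq$collimator$resolution_slope * FWHM_TO_SIGMA
  # the outer backprojection scale cancels between numerator and
  # sensitivity image, so both are kept unscaled
  ones <- matrix(1, dims[1], dims[3])
  sens <- lapply(subsets, function(idx) {
    s <- array(0, dims)
    for (i in idx)
      s <- s + cpp_bp_angle(ones, muv, dims, angles[i], vox,
                            acq$orbit_radius_mm, sig_int, sig_slope,
                            use_psf, TRUE)
    s
  })
  sens_floor <- 1e-8 * max(vapply(sens, max, numeric(1)))
  # uniform start inside the inscribed circular FOV
  cx <- (dims[1] - 1) / 2; cy <- (dims[2] - 1) / 2
  rad2 <- (min(dims[1], dims[2]) / 2)^2
  fov <- outer((seq_len(dims[1]) - 1 - cx)^2,
               (seq_len(dims[2]) - 1 - cy)^2, "+") <= rad2
  x <- array(as.numeric(fov), dims)
  for (it in seq_len(cfg$iterations)) {
    for (s in seq_len(cfg$subsets)) {
      num <- array(0, dims)
      for (i in subsets[[s]]) {
        num <- num + cpp_osem_angle(x, y[, , i], muv, dims, angles[i], vox,
                                    acq$orbit_radius_mm, sig_int, sig_slope,
                                    use_psf, scale)
      }
      ok <- sens[[s]] > sens_floor
      x[ok] <- x[ok] * num[ok] / sens[[s]][ok]
      x[!ok] <- 0
    }
  }
  out <- voxel_volume(x, mu$voxel_size_mm, mu$origin_mm, "activity")
  if (!is.null(cfg$post_filter_fwhm_mm))
    out <- gaussian_postfilter(out, cfg$post_filter_fwhm_mm)
  out
}

#' 3D Gaussian post-reconstruction filter
#'
#' @param vol a `voxel_volume` with isotropic voxels.
#' @param fwhm_mm filter full width at half maximum (default 8.8 mm).
#' @return Filtered `voxel_volume`; the total sum is preserved away from the
#'   boundary.
#' @export
gaussian_postfilter <- function(vol, fwhm_mm = 8.8) {
  stopifnot(inherits(vol, "voxel_volume"))
  vox <- vol$voxel_size_mm
  if (fwhm_mm < min(vox) / 2)
    warning("filter FWHM below half a voxel: near-identity")
  sigma_px <- fwhm_mm * FWHM_TO_SIGMA / vox
  out <- cpp_gauss3(vol$values, dim(vol$values), sigma_px)
  voxel_volume(out, vox, vol$origin_mm, vol$value_kind)
}

#' Convert a reconstruction to activity concentration
#'
#' Divides by the calibration factor determined with
#' [simulate_calibration()] under the same acquisition and reconstruction
#' settings.
#'
#' @param vol reconstructed `voxel_volume`.
#' @param calibration calibration factor (> 0).
#' @return `voxel_volume` in MBq/mL.
#' @export
to_activity_concentration <- function(vol, calibration) {
  if (is.null(calibration) || !is.numeric(calibration) || calibration <= 0)
    stop("a positive calibration factor is required")
  voxel_volume(vol$values / calibration, vol$voxel_size_mm, vol$origin_mm,
               "activity")
}
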