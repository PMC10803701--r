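# Quantitative evaluation: modulation contrast, FVF-contrast regression,
# activity recovery, threshold-volume segmentation curves, profiles, MIPs.

#' Spherical volume of interest on an image grid
#'
#' VOI with the physical volume of the object: voxels whose centres lie
#' within the sphere of the given diameter around `center_mm`.
#'
#' @param image a `voxel_volume`.
#' @param center_mm sphere centre (mm).
#' @param diameter_mm sphere diameter (mm); alternatively give `volume_mL`.
#' @param volume_mL sphere volume in mL (used if `diameter_mm` missing).
#' @return Logical array matching the image lattice.
#' @export
sphere_voi <- function(image, center_mm = c(0, 0, 0), diameter_mm = NULL,
                       volume_mL = NULL) {
  if (is.null(diameter_mm)) {
    if (is.null(volume_mL)) stop("give diameter_mm or volume_mL")
    diameter_mm <- 2 * (volume_mL * 1000 * 3 / (4 * pi))^(1 / 3)
  }
  r2 <- (diameter_mm / 2)^2
  xs <- voxel_coords(image, 1) - center_mm[1]
  ys <- voxel_coords(image, 2) - center_mm[2]
  zs <- voxel_coords(image, 3) - center_mm[3]
  outer(outer(xs^2, ys^2, "+"), zs^2, "+") <= r2
}

#' Modulation contrast between a grid object and its grid-free reference
#'
#' `C_M = mean(image in grid VOI) / mean(reference image in reference VOI)`.
#' Both VOIs are drawn at the physical object volume; resolution-induced
#' spill-out is assumed equal for the two objects and cancels in the ratio.
#'
#' @param image image of the grid-filled object.
#' @param voi_grid logical VOI for the grid object.
#' @param reference image of the grid-free object (may be the same image).
#' @param voi_reference logical VOI for the reference object.
#' @return `C_M` (dimensionless).
#' @export
modulation_contrast <- function(image, voi_grid, reference = image,
                                voi_reference) {
  if (!any(voi_grid) || !any(voi_reference)) stop("VOIs must be non-empty")
  ref <- mean(reference$values[voi_reference])
  if (ref == 0) stop("zero reference signal: contrast undefined")
  mean(image$values[voi_grid]) / ref
}

#' Ordinary least-squares fit of modulation contrast versus FVF
#'
#' @param fvf fillable-volume fractions (>= 3 points, non-degenerate).
#' @param cm modulation contrasts.
#' @return A `fit_result` with slope, intercept, their standard deviations,
#'   Pearson r and the number of points.
#' @export
fit_cm_vs_fvf <- function(fvf, cm) {
  n <- length(fvf)
  if (n < 3 || length(cm) != n) stop("need >= 3 matched points")
  if (sd(fvf) < 1e-12) stop("degenerate FVF range")
  mx <- mean(fvf); my <- mean(cm)
  sxx <- sum((fvf - mx)^2)
  slope <- sum((fvf - mx) * (cm - my)) / sxx
  intercept <- my - slope * mx
  res <- cm - intercept - slope * fvf
  s2 <- sum(res^2) / max(n - 2, 1)
  r <- if (sd(cm) < 1e-15) 1 else sum((fvf - mx) * (cm - my)) /
    sqrt(sxx * sum((cm - my)^2))
  structure(list(slope = slope, intercept = intercept,
                 pearson_r = r,
                 slope_sd = sqrt(s2 / sxx),
                 intercept_sd = sqrt(s2 * (1 / n + mx^2 / sxx)),
                 n_points = n),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> C_M = %.4f FVF %+.4f (n = %d), r = %.5f\n",
              x$slope, x$intercept, x$n_points, x$pearson_r))
  cat(sprintf("  sd(slope) = %.4f, sd(intercept) = %.4f\n",
              x$slope_sd, x$intercept_sd))
  invisible(x)
}

#' Activity recovery coefficient
#'
#' `R = A_SPECT / A`: image-derived activity in a VOI (sum of calibrated
#' voxel concentrations times voxel volume) divided by the true activity.
#'
#' @param image calibrated image in MBq/mL.
#' @param voi logical VOI on the image lattice.
#' @param true_activity_MBq reference activity (> 0).
#' @return Recovery coefficient.
#' @export
recovery <- function(image, voi, true_activity_MBq) {
  if (true_activity_MBq <= 0) stop("true activity must be > 0")
  sum(image$values[voi]) * voxel_mL(image) / true_activity_MBq
}

#' Threshold-volume segmentation curve
#'
#' The threshold is varied in `steps` equal fractions of the image maximum;
#' for each threshold the segmented volume is the number of voxels at or
#' above the threshold times the voxel volume.
#'
#' @param image a `voxel_volume` with positive maximum.
#' @param steps number of threshold steps (default 100).
#' @param mask optional logical restriction (e.g. one phantom's half of the
#'   field of view).
#' @return A `threshold_volume_curve` with `thresholds` (absolute image
#'   units), `volumes_mL` and `max_value`.
#' @export
threshold_volume_curve <- function(image, steps = 100, mask = NULL) {
  vals <- if (is.null(mask)) image$values else image$values[mask]
  mx <- max(vals)
  if (mx <= 0) stop("image maximum must be positive")
  thresholds <- mx * seq_len(steps) / steps
  vm <- voxel_mL(image)
  volumes <- vapply(thresholds, function(th) sum(vals >= th) * vm, numeric(1))
  structure(list(thresholds = thresholds, volumes_mL = volumes,
                 max_value = mx),
            class = "threshold_volume_curve")
}

#' Threshold yielding a given true volume
#'
#' Linearly interpolates the threshold-volume curve at `V_true` and returns
#' the threshold as a fraction of the image maximum.
#'
#' @param curve a [threshold_volume_curve()].
#' @param V_true_mL true object volume (> 0).
#' @return Fraction of the maximum in (0, 1).
#' @export
threshold_for_true_volume <- function(curve, V_true_mL) {
  if (V_true_mL <= 0) stop("true volume must be > 0")
  v <- curve$volumes_mL
  th <- curve$thresholds
  if (V_true_mL > v[1])
    stop("true volume exceeds the segmented volume at the lowest threshold")
  # volumes are non-increasing in threshold: find the bracketing pair
  i <- max(which(v >= V_true_mL))
  if (i == length(v)) return(th[i] / curve$max_value)
  frac <- if (v[i] == v[i + 1]) 0 else (v[i] - V_true_mL) / (v[i] - v[i + 1])
  (th[i] + frac * (th[i + 1] - th[i])) / curve$max_value
}

#' Mean Euclidean distance between two threshold-volume curves
#'
#' Mean over sample points of the absolute volume difference between curves
#' sampled at the same relative thresholds.
#'
#' @param c1,c2 [threshold_volume_curve()] objects with identical sampling.
#' @return Mean distance in mL.
#' @export
mean_euclidean_distance <- function(c1, c2) {
  if (length(c1$volumes_mL) != length(c2$volumes_mL))
    stop("curves sampled at different numbers of thresholds")
  mean(abs(c1$volumes_mL - c2$volumes_mL))
}

#' Averaged coronal profile through an image
#'
#' Averages the `n_slices` central coronal (constant-y) slices and extracts
#' the profile along x at a given axial position.
#'
#' @param image a `voxel_volume`, at least `n_slices` thick along y.
#' @param z_mm axial position of the profile line (mm; default centre).
#' @param n_slices number of central coronal slices to average (default 3).
#' @return `data.frame(pos_mm, value)` along the x axis.
#' @export
coronal_profile <- function(image, z_mm = NULL, n_slices = 3) {
  d <- dim(image$values)
  if (d[2] < n_slices) stop("image thinner than n_slices along y")
  iy0 <- floor((d[2] - n_slices) / 2) + 1L
  zs <- voxel_coords(image, 3)
  iz <- if (is.null(z_mm)) which.min(abs(zs - mean(range(zs))))
        else which.min(abs(zs - z_mm))
  slab <- image$values[, iy0:(iy0 + n_slices - 1L), iz, drop = FALSE]
  data.frame(pos_mm = voxel_coords(image, 1),
             value = rowMeans(slab[, , 1, drop = TRUE]))
}

#' Maximum-intensity projection
#'
#' @param image a `voxel_volume`.
#' @param axis projection axis (1, 2 or 3).
#' @return 2D matrix of per-ray maxima.
#' @export
mip <- function(image, axis = 2) {
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  apply(image$values, setdiff(1:3, axis), max)
}
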