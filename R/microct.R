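# Synthetic micro-CT verification of printed grids.
#
# The printing process leaves excess material preferentially at sharp wall
# crossings and may thicken walls globally; a micro-CT scan of the printed
# object, segmented and compared against the design, quantifies both.  This
# module synthesizes micro-CT-like volumes with controllable defects and
# implements the segmentation chain: moment-preserving threshold,
# 3x3x3 morphological opening/closing, and shell exclusion by fitting an
# analytic sphere to the outer mask boundary.

#' Printing-defect model for synthetic micro-CT
#'
#' @param edge_excess_mm extra material (dilation radius, mm) applied at
#'   wall crossings, where two or more wall families meet.
#' @param uniform_scale fractional global wall thickening (0.1 = walls grow
#'   by 10 percent of their thickness, split over both sides).
#' @param noise_sd additive Gaussian noise sd in image-value units.
#' @param blur_fwhm_mm scanner PSF FWHM (mm).
#' @return A `defect_model`.
#' @export
defect_model <- function(edge_excess_mm = 0, uniform_scale = 0,
                         noise_sd = 0, blur_fwhm_mm = 0) {
  if (edge_excess_mm < 0) stop("edge excess must be >= 0")
  if (blur_fwhm_mm < 0) stop("blur FWHM must be >= 0")
  structure(list(edge_excess_mm = edge_excess_mm,
                 uniform_scale = uniform_scale,
                 noise_sd = noise_sd, blur_fwhm_mm = blur_fwhm_mm),
            class = "defect_model")
}

#' Synthesize a micro-CT-like volume of a printed grid
#'
#' Starts from the design labels (solid / fillable / outside), applies the
#' defects, then the scanner blur and noise.  Deterministic for a given
#' seed.
#'
#' @param labels label `voxel_volume` from [rasterize_grid()]; the attached
#'   `grid_spec` is needed when `edge_excess_mm > 0`.
#' @param defects a [defect_model()].
#' @param solid_value,air_value the two image levels (HU-like).
#' @param seed RNG seed for the noise.
#' @return An HU-like `voxel_volume`.
#' @export
synth_microct <- function(labels, defects = defect_model(),
                          solid_value = 1000, air_value = 0, seed = 1) {
  stopifnot(inherits(labels, "voxel_volume"))
  vox <- labels$voxel_size_mm[1]
  spec <- attr(labels, "grid_spec")
  if (!is.null(spec)) {
    wall_px <- spec$wall_thickness_mm / vox
    if (wall_px < 4)
      stop("wall under-resolved: need >= 4 voxels across a wall")
  }
  solid <- labels$values == GRID_LABELS[["solid"]]
  d <- dim(solid)
  if (defects$uniform_scale > 0) {
    if (is.null(spec)) stop("uniform_scale requires an attached grid_spec")
    n_dil <- round(defects$uniform_scale * spec$wall_thickness_mm / 2 / vox)
    m <- array(as.integer(solid), d)
    for (i in seq_len(n_dil)) m <- cpp_morph3(m, d, TRUE)
    solid <- m == 1L
  }
  if (defects$edge_excess_mm > 0) {
    if (is.null(spec)) stop("edge_excess requires an attached grid_spec")
    xs <- voxel_coords(labels, 1); ys <- voxel_coords(labels, 2)
    zs <- voxel_coords(labels, 3)
    p <- spec$wall_thickness_mm + spec$gap_mm
    inwall <- function(v, ph) ((v - ph) %% p) < spec$wall_thickness_mm
    w <- list(x = if ("x" %in% spec$wall_axes) inwall(xs, spec$phase_mm[1]) else rep(FALSE, d[1]),
              y = if ("y" %in% spec$wall_axes) inwall(ys, spec$phase_mm[2]) else rep(FALSE, d[2]),
              z = if ("z" %in% spec$wall_axes) inwall(zs, spec$phase_mm[3]) else rep(FALSE, d[3]))
    nfam <- outer(outer(as.integer(w$x), as.integer(w$y), "+"),
                  as.integer(w$z), "+")
    cross <- (nfam >= 2) & (labels$values != GRID_LABELS[["outside"]])
    n_dil <- round(defects$edge_excess_mm / vox)
    m <- array(as.integer(cross), d)
    for (i in seq_len(n_dil)) m <- cpp_morph3(m, d, TRUE)
    inside <- labels$values != GRID_LABELS[["outside"]]
    solid <- solid | (m == 1L & inside)
  }
  img <- array(air_value, d)
  img[solid] <- solid_value
  if (defects$blur_fwhm_mm > 0) {
    sigma_px <- defects$blur_fwhm_mm * FWHM_TO_SIGMA / labels$voxel_size_mm
    img <- cpp_gauss3(img, d, sigma_px)
  }
  if (defects$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    img <- img + array(rnorm(length(img), sd = defects$noise_sd), d)
  }
  out <- voxel_volume(img, labels$voxel_size_mm, labels$origin_mm, "hu")
  attr(out, "grid_spec") <- spec
  attr(out, "container") <- attr(labels, "container")
  out
}

#' Moment-preserving (Tsai) threshold
#'
#' Chooses the threshold so that the binarized image preserves the first
#' three empirical gray-level moments: the two representative levels and
#' the below-fraction follow in closed form from the moments, and the
#' threshold is the corresponding image quantile.
#'
#' @param image a `voxel_volume` or numeric array with non-zero variance.
#' @return Threshold value in image units.
#' @export
moment_preserving_threshold <- function(image) {
  v <- if (inherits(image, "voxel_volume")) as.numeric(image$values)
       else as.numeric(image)
  m1 <- mean(v); m2 <- mean(v^2); m3 <- mean(v^3)
  cd <- m2 - m1^2
  if (cd < 1e-12 * max(m2, 1)) stop("degenerate histogram: zero variance")
  c0 <- (m1 * m3 - m2^2) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- sqrt(max(c1^2 - 4 * c0, 0))
  z0 <- (-c1 - disc) / 2
  z1 <- (-c1 + disc) / 2
  p0 <- (z1 - m1) / (z1 - z0)     # fraction of voxels at the low level
  p0 <- min(max(p0, 0), 1)
  quantile(v, p0, names = FALSE)
}

#' Morphological cleanup of a binary mask
#'
#' Opening followed by closing, both with a full 3x3x3 structuring element;
#' removes isolated voxels and fills single-voxel holes, and is idempotent
#' on a second application.
#'
#' @param mask logical/0-1 3D array or a label `voxel_volume`.
#' @return Object of the same type with a cleaned mask.
#' @export
clean_mask <- function(mask) {
  vv <- inherits(mask, "voxel_volume")
  m <- if (vv) mask$values else mask
  d <- dim(m)
  mi <- array(as.integer(m != 0), d)
  mi <- cpp_morph3(cpp_morph3(mi, d, FALSE), d, TRUE)   # opening
  mi <- cpp_morph3(cpp_morph3(mi, d, TRUE), d, FALSE)   # closing
  out <- array(mi == 1L, d)
  if (vv) { mask$values <- out; mask } else out
}

#' Exclude the container shell from a segmented grid mask
#'
#' Fits an analytic sphere (centre and radius, algebraic least squares) to
#' the outer boundary of the mask -- the mask voxels adjacent to air that is
#' connected to the volume border -- and removes everything outside the
#' fitted radius minus the shell thickness and a safety margin.
#'
#' @param mask binary 3D array or `voxel_volume` containing an
#'   approximately spherical outer shell.
#' @param voxel_size_mm voxel size (taken from the volume if omitted).
#' @param shell_thickness_mm nominal shell wall thickness (default 1.5 mm).
#' @param margin_vox extra margin inside the shell, in voxels (default 2).
#' @return List with `mask` (interior grid only), `center_mm`, `radius_mm`
#'   and the boundary-fit RMS residual.
#' @export
exclude_shell <- function(mask, voxel_size_mm = NULL,
                          shell_thickness_mm = 1.5, margin_vox = 2) {
  vv <- inherits(mask, "voxel_volume")
  m <- if (vv) mask$values != 0 else mask != 0
  if (is.null(voxel_size_mm))
    voxel_size_mm <- if (vv) mask$voxel_size_mm[1] else 1
  d <- dim(m)
  mi <- array(as.integer(m), d)
  outside <- cpp_outside_air(mi, d) == 1L
  # boundary: mask voxels 6-adjacent to outside air
  nb <- array(FALSE, d)
  sh <- function(a, ax, by) {
    out <- array(FALSE, dim(a))
    n <- dim(a)[ax]
    idx <- lapply(dim(a), seq_len)
    src <- idx; src[[ax]] <- pmin(pmax(seq_len(n) + by, 1L), n)
    do.call(`[`, c(list(a), src))
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) nb <- nb | sh(outside, ax, by)
  boundary <- m & nb
  if (sum(boundary) < 100) stop("no shell found: too few outer boundary voxels")
  idx <- which(boundary, arr.ind = TRUE)
  org <- if (vv) mask$origin_mm else c(0, 0, 0)
  P <- sweep(sweep(idx - 1, 2, rep(voxel_size_mm, 3), "*"), 2, org, "+")
  # algebraic sphere fit: |p|^2 = 2 a.p + b
  A <- cbind(2 * P, 1)
  rhs <- rowSums(P^2)
  sol <- unname(qr.solve(A, rhs))
  ctr <- sol[1:3]
  r <- sqrt(sol[4] + sum(ctr^2))
  resid <- sqrt(mean((sqrt(rowSums(sweep(P, 2, ctr)^2)) - r)^2))
  if (resid > 0.15 * r)
    stop(sprintf("shell fit failed: RMS residual %.2f mm for radius %.2f mm",
                 resid, r))
  # occupancy near the fitted radius should be shell-like (near 1)
  xs <- org[1] + (seq_len(d[1]) - 1) * voxel_size_mm - ctr[1]
  ys <- org[2] + (seq_len(d[2]) - 1) * voxel_size_mm - ctr[2]
  zs <- org[3] + (seq_len(d[3]) - 1) * voxel_size_mm - ctr[3]
  dist <- sqrt(outer(outer(xs^2, ys^2, "+"), zs^2, "+"))
  shell_band <- dist <= (r - 0.5 * voxel_size_mm) &
                dist >= (r - shell_thickness_mm + 0.5 * voxel_size_mm)
  occ <- mean(m[shell_band])
  if (is.nan(occ) || occ < 0.9)
    stop(sprintf("no shell present: occupancy %.2f at the fitted radius", occ))
  r_cut <- r - shell_thickness_mm - margin_vox * voxel_size_mm
  keep <- m & (dist < r_cut)
  out <- if (vv) { mask$values <- keep; mask } else keep
  list(mask = out, center_mm = ctr, radius_mm = r, rms_residual_mm = resid)
}

#' Grid volume from a segmented micro-CT mask
#'
#' @param mask cleaned, shell-excluded binary array or `voxel_volume`.
#' @param voxel_size_mm voxel size (taken from the volume if omitted).
#' @return Solid volume in mL (zero with a warning for an empty mask).
#' @export
grid_volume_from_ct <- function(mask, voxel_size_mm = NULL) {
  vv <- inherits(mask, "voxel_volume")
  m <- if (vv) mask$values != 0 else mask != 0
  if (is.null(voxel_size_mm))
    voxel_size_mm <- if (vv) mask$voxel_size_mm[1] else 1
  n <- sum(m)
  if (n == 0) warning("empty mask: zero grid volume")
  n * voxel_size_mm^3 / 1000
}

#' Central-to-peripheral void-area ratio of a grid slice
#'
#' On the transversal slice through the sphere centre, five central ROIs
#' (a plus pattern around the centre) and four peripheral ROIs (diagonals at
#' 70 percent of the interior radius) measure the mean open (void) area;
#' their ratio is unity for a uniformly printed grid.
#'
#' @param mask solid-grid binary array or `voxel_volume` (shell excluded).
#' @param spec the design [grid_spec()] (sets the ROI side to 3 periods).
#' @param interior_radius_mm radius of the grid interior (mm).
#' @param voxel_size_mm voxel size (taken from the volume if omitted).
#' @param slice_index transversal (z) slice; default the central slice.
#' @return Ratio of mean central to mean peripheral void area.
#' @export
central_peripheral_ratio <- function(mask, spec, interior_radius_mm,
                                     voxel_size_mm = NULL, slice_index = NULL) {
  vv <- inherits(mask, "voxel_volume")
  m <- if (vv) mask$values != 0 else mask != 0
  if (is.null(voxel_size_mm))
    voxel_size_mm <- if (vv) mask$voxel_size_mm[1] else 1
  d <- dim(m)
  if (is.null(slice_index)) slice_index <- (d[3] + 1L) %/% 2L
  sl <- m[, , slice_index]
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  side_px <- 3 * (spec$wall_thickness_mm + spec$gap_mm) / voxel_size_mm
  h <- side_px / 2
  r70 <- 0.7 * interior_radius_mm / voxel_size_mm
  sqrt2 <- sqrt(2)
  centers <- rbind(c(0, 0), c(side_px, 0), c(-side_px, 0), c(0, side_px),
                   c(0, -side_px),
                   c(r70 / sqrt2, r70 / sqrt2), c(-r70 / sqrt2, r70 / sqrt2),
                   c(r70 / sqrt2, -r70 / sqrt2), c(-r70 / sqrt2, -r70 / sqrt2))
  corner_r <- sqrt((abs(centers[, 1]) + h)^2 + (abs(centers[, 2]) + h)^2)
  if (any(corner_r > interior_radius_mm / voxel_size_mm))
    stop("ROI layout extends outside the grid interior")
  area <- function(k) {
    ix <- round(cx + centers[k, 1]) + (-floor(h):floor(h))
    iy <- round(cy + centers[k, 2]) + (-floor(h):floor(h))
    sum(!sl[ix, iy]) * voxel_size_mm^2
  }
  areas <- vapply(1:9, area, numeric(1))
  mean(areas[1:5]) / mean(areas[6:9])
}
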