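#' Parametric grid specification
#'
#' A grid is a periodic arrangement of flat solid walls inside a container.
#' Along each axis listed in `wall_axes` a family of walls of thickness `t`
#' repeats with period `t + g`, where `g` is the gap (the fillable channel
#' width).  With `k` orthogonal wall families the analytic fillable-volume
#' fraction is `(g / (t + g))^k`.
#'
#' @param wall_thickness_mm wall thickness `t` in mm, > 0.
#' @param gap_mm wall-to-wall distance `g` in mm, > 0.
#' @param wall_axes character subset of `c("x","y","z")`: the normals along
#'   which wall families repeat.  Two families (default) leave square
#'   channels open along the remaining axis, which permits draining and
#'   cleaning of a printed grid.
#' @param phase_mm per-axis offset of the wall pattern (mm), default 0.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(wall_thickness_mm, gap_mm, wall_axes = c("x", "y"),
                      phase_mm = c(0, 0, 0)) {
  if (!is.numeric(wall_thickness_mm) || wall_thickness_mm <= 0)
    stop("wall thickness must be > 0")
  if (!is.numeric(gap_mm) || gap_mm <= 0)
    stop("gap must be > 0")
  wall_axes <- match.arg(wall_axes, c("x", "y", "z"), several.ok = TRUE)
  wall_axes <- unique(wall_axes)
  structure(list(wall_thickness_mm = as.numeric(wall_thickness_mm),
                 gap_mm = as.numeric(gap_mm),
                 wall_axes = wall_axes,
                 phase_mm = rep_len(as.numeric(phase_mm), 3L)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> t = %g mm, g = %g mm, walls along {%s}, FVF = %.4f\n",
              x$wall_thickness_mm, x$gap_mm,
              paste(x$wall_axes, collapse = ","), analytic_fvf(x)))
  invisible(x)
}

#' Analytic fillable-volume fraction of a grid
#'
#' @param spec a [grid_spec()].
#' @return `(g/(t+g))^k` with `k` the number of wall families; in (0, 1),
#'   independent of the phase offsets.
#' @export
analytic_fvf <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  k <- length(spec$wall_axes)
  (spec$gap_mm / (spec$wall_thickness_mm + spec$gap_mm))^k
}

#' Solve the wall gap for a target fillable-volume fraction
#'
#' Uniform scaling of both `t` and `g` leaves the FVF unchanged, so FVF
#' targeting holds the wall thickness fixed and solves the gap analytically:
#' `g = t q / (1 - q)` with `q = target^(1/k)`.
#'
#' @param target_fvf desired FVF, strictly in (0, 1).
#' @param wall_thickness_mm wall thickness to preserve (mm).
#' @param wall_axes wall families, as in [grid_spec()].
#' @return A [grid_spec()] whose [analytic_fvf()] equals `target_fvf`.
#' @export
solve_gap_for_fvf <- function(target_fvf, wall_thickness_mm = 2,
                              wall_axes = c("x", "y")) {
  if (!is.numeric(target_fvf) || target_fvf <= 0 || target_fvf >= 1)
    stop("target FVF must lie strictly in (0, 1)")
  k <- length(unique(match.arg(wall_axes, c("x", "y", "z"), several.ok = TRUE)))
  q <- target_fvf^(1 / k)
  grid_spec(wall_thickness_mm, wall_thickness_mm * q / (1 - q), wall_axes)
}

## ---- containers ------------------------------------------------------------

#' Container shapes
#'
#' Containers carry a vectorised membership test evaluated on the separable
#' voxel-centre coordinates and the nominal (design) volume `V_no_grid` in mL.
#'
#' @param diameter_mm,height_mm,side_mm dimensions in mm.
#' @param center_mm length-3 centre in mm.
#' @return A `container` object with fields `kind`, `volume_mL`, `bbox`
#'   (2 x 3 matrix of mm extents) and a mask generator.
#' @export
container_sphere <- function(diameter_mm, center_mm = c(0, 0, 0)) {
  r <- diameter_mm / 2
  structure(list(
    kind = "sphere", center = center_mm, radius = r,
    volume_mL = 4 / 3 * pi * r^3 / 1000,
    bbox = rbind(center_mm - r, center_mm + r),
    mask_fn = function(xs, ys, zs) {
      dx2 <- (xs - center_mm[1])^2
      dy2 <- (ys - center_mm[2])^2
      dz2 <- (zs - center_mm[3])^2
      outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
    },
    sdf_fn = function(xs, ys, zs) {
      dx2 <- (xs - center_mm[1])^2
      dy2 <- (ys - center_mm[2])^2
      dz2 <- (zs - center_mm[3])^2
      r - sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    }), class = "container")
}

#' @rdname container_sphere
#' @export
container_cylinder <- function(diameter_mm, height_mm, center_mm = c(0, 0, 0)) {
  r <- diameter_mm / 2
  h2 <- height_mm / 2
  structure(list(
    kind = "cylinder", center = center_mm, radius = r, height = height_mm,
    volume_mL = pi * r^2 * height_mm / 1000,
    bbox = rbind(center_mm - c(r, r, h2), center_mm + c(r, r, h2)),
    mask_fn = function(xs, ys, zs) {
      dx2 <- (xs - center_mm[1])^2
      dy2 <- (ys - center_mm[2])^2
      inz <- abs(zs - center_mm[3]) <= h2
      outer(outer(dx2, dy2, "+") <= r^2, inz, "&")
    },
    sdf_fn = function(xs, ys, zs) {
      dr <- r - sqrt(outer(outer((xs - center_mm[1])^2,
                                 (ys - center_mm[2])^2, "+"),
                           rep(0, length(zs)), "+"))
      dz <- h2 - abs(zs - center_mm[3])
      pmin(dr, rep(dz, each = length(xs) * length(ys)))
    }), class = "container")
}

#' @rdname container_sphere
#' @export
container_box <- function(side_mm, center_mm = c(0, 0, 0)) {
  side_mm <- rep_len(side_mm, 3L)
  h <- side_mm / 2
  structure(list(
    kind = "box", center = center_mm, side = side_mm,
    volume_mL = prod(side_mm) / 1000,
    bbox = rbind(center_mm - h, center_mm + h),
    mask_fn = function(xs, ys, zs) {
      inx <- abs(xs - center_mm[1]) <= h[1]
      iny <- abs(ys - center_mm[2]) <= h[2]
      inz <- abs(zs - center_mm[3]) <= h[3]
      outer(outer(inx, iny, "&"), inz, "&")
    }), class = "container")
}

## ---- rasterization ---------------------------------------------------------

#' Label codes used by rasterized grids
#' @export
GRID_LABELS <- c(outside = 0L, fillable = 1L, solid = 2L)

#' Rasterize a grid inside a container
#'
#' Voxelizes the periodic wall pattern (by voxel-centre membership) inside
#' the container.  Voxels are labelled `outside` (0), `fillable` (1) or
#' `solid` (2).  Pass `spec = NULL` for a grid-free (empty) container.
#'
#' @param spec a [grid_spec()] or `NULL`.
#' @param container a container object.
#' @param voxel_size_mm isotropic voxel size; must satisfy
#'   `voxel_size <= min(t, g) / 2` for adequate sampling.
#' @param margin_mm padding added around the container bounding box.
#' @return A label `voxel_volume` with attribute `grid_spec`.
#' @export
rasterize_grid <- function(spec, container, voxel_size_mm, margin_mm = 0) {
  stopifnot(inherits(container, "container"))
  if (!is.null(spec)) {
    m <- min(spec$wall_thickness_mm, spec$gap_mm)
    if (voxel_size_mm > m / 2)
      stop(sprintf(
        "voxel size %g mm too coarse: must be <= min(t, g)/2 = %g mm",
        voxel_size_mm, m / 2))
  }
  lo <- container$bbox[1, ] - margin_mm - voxel_size_mm / 2
  hi <- container$bbox[2, ] + margin_mm + voxel_size_mm / 2
  n <- pmax(1L, as.integer(ceiling((hi - lo) / voxel_size_mm)))
  origin <- (lo + hi) / 2 - (n - 1) / 2 * voxel_size_mm
  xs <- origin[1] + (seq_len(n[1]) - 1) * voxel_size_mm
  ys <- origin[2] + (seq_len(n[2]) - 1) * voxel_size_mm
  zs <- origin[3] + (seq_len(n[3]) - 1) * voxel_size_mm
  inside <- container$mask_fn(xs, ys, zs)
  labels <- array(GRID_LABELS[["outside"]], dim = n)
  labels[inside] <- GRID_LABELS[["fillable"]]
  if (!is.null(spec)) {
    solid <- grid_solid_mask(spec, xs, ys, zs)
    labels[inside & solid] <- GRID_LABELS[["solid"]]
  }
  out <- voxel_volume(labels, voxel_size_mm, origin, "label")
  attr(out, "grid_spec") <- spec
  attr(out, "container") <- container
  out
}

# Periodic wall membership on separable coordinates; returns a 3D logical.
grid_solid_mask <- function(spec, xs, ys, zs) {
  p <- spec$wall_thickness_mm + spec$gap_mm
  inwall <- function(v, ph) ((v - ph) %% p) < spec$wall_thickness_mm
  wx <- if ("x" %in% spec$wall_axes) inwall(xs, spec$phase_mm[1]) else rep(FALSE, length(xs))
  wy <- if ("y" %in% spec$wall_axes) inwall(ys, spec$phase_mm[2]) else rep(FALSE, length(ys))
  wz <- if ("z" %in% spec$wall_axes) inwall(zs, spec$phase_mm[3]) else rep(FALSE, length(zs))
  outer(outer(wx, wy, "|"), wz, "|")
}

#' Fillable-volume fraction from a label volume
#'
#' `FVF = 1 - V_grid / V_no_grid`, with both volumes obtained by voxel
#' counting over the container interior.
#'
#' @param labels a label `voxel_volume` from [rasterize_grid()].
#' @return FVF in `[0, 1]`.
#' @export
fvf_from_labels <- function(labels) {
  v <- labels$values
  n_solid <- sum(v == GRID_LABELS[["solid"]])
  n_fill <- sum(v == GRID_LABELS[["fillable"]])
  if (n_solid + n_fill == 0L)
    stop("label volume contains no container voxels")
  1 - n_solid / (n_solid + n_fill)
}

#' Fillable-volume fraction from grid mass (weighing emulation)
#'
#' The grid volume is taken as `m_grid / rho`, emulating the determination of
#' the printed-grid volume from its mass and the cured-resin density.
#'
#' @param m_grid_g grid mass in g (>= 0).
#' @param rho_g_cm3 material density in g/cm3, default the cured clear-resin
#'   value 1.192.
#' @param V_no_grid_mL container volume without grid, in mL.
#' @return List with `fvf` and logical `consistent`; an FVF outside `[0, 1]`
#'   is reported as-is with `consistent = FALSE` and a warning.
#' @export
fvf_from_mass <- function(m_grid_g, rho_g_cm3 = 1.192, V_no_grid_mL) {
  if (m_grid_g < 0) stop("grid mass must be >= 0")
  if (rho_g_cm3 <= 0) stop("density must be > 0")
  if (V_no_grid_mL <= 0) stop("container volume must be > 0")
  fvf <- 1 - (m_grid_g / rho_g_cm3) / V_no_grid_mL
  consistent <- fvf >= 0 && fvf <= 1
  if (!consistent)
    warning(sprintf("mass-derived grid volume (%.3g mL) inconsistent with container (%.3g mL)",
                    m_grid_g / rho_g_cm3, V_no_grid_mL))
  list(fvf = fvf, consistent = consistent)
}

#' Relative volume deviation from a reference measurement
#'
#' `delta_V = 1 - V_design / V_measured`; the measured volume is the
#' reference, and negative values (design larger than measured) are allowed.
#'
#' @param V_design_mL design volume (mL).
#' @param V_measured_mL measured reference volume (mL), > 0.
#' @return Signed fraction.
#' @export
delta_v <- function(V_design_mL, V_measured_mL) {
  if (V_measured_mL <= 0) stop("measured volume must be > 0")
  1 - V_design_mL / V_measured_mL
}
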