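test_that("analytic FVF follows (g/(t+g))^k and validates inputs", {
  expect_equal(analytic_fvf(grid_spec(2, 2, c("x", "y"))), 0.25)
  expect_equal(analytic_fvf(grid_spec(2, 2, "x")), 0.5)
  expect_equal(analytic_fvf(grid_spec(1e-9, 5)), 1.0, tolerance = 1e-6)
  expect_equal(analytic_fvf(grid_spec(2, 2, c("x", "y", "z"))), 0.125)
  # independent of phase
  expect_equal(analytic_fvf(grid_spec(2, 3, phase_mm = c(1, 2, 0))),
               analytic_fvf(grid_spec(2, 3)))
  expect_error(grid_spec(0, 2), "thickness")
  expect_error(grid_spec(2, -1), "gap")
})

test_that("solve_gap_for_fvf inverts analytic_fvf", {
  s <- solve_gap_for_fvf(0.25, 2, c("x", "y"))
  expect_equal(s$gap_mm, 2)
  expect_equal(solve_gap_for_fvf(0.5, 3, "x")$gap_mm, 3)
  # closed form for k = 2
  s48 <- solve_gap_for_fvf(0.48, 2)
  expect_equal(s48$gap_mm, 2 * sqrt(0.48) / (1 - sqrt(0.48)), tolerance = 1e-9)
  # mutual inverse property over a sweep
  for (f in c(0.05, 0.28, 0.44, 0.6, 0.65, 0.9)) {
    for (ax in list("x", c("x", "y"), c("x", "y", "z"))) {
      expect_equal(analytic_fvf(solve_gap_for_fvf(f, 2, ax)), f,
                   tolerance = 1e-9)
    }
  }
  expect_error(solve_gap_for_fvf(0, 2), "FVF")
  expect_error(solve_gap_for_fvf(1, 2), "FVF")
})

test_that("solve_gap_for_fvf(0.48) confirmed by voxel-counting oracle", {
  # independent oracle: count fillable voxel centres over whole periods
  s <- solve_gap_for_fvf(0.48, 2)
  p <- s$wall_thickness_mm + s$gap_mm
  box <- container_box(2 * p)         # two periods per axis, exact tiling
  lab <- rasterize_grid(s, box, 0.1)
  expect_equal(fvf_from_labels(lab), 0.48, tolerance = 0.01)
})

test_that("rasterize_grid labels and degenerate cases", {
  sph <- container_sphere(40)
  lab0 <- rasterize_grid(NULL, sph, 0.5)
  expect_equal(sum(lab0$values == GRID_LABELS[["solid"]]), 0)
  vol_fill <- sum(lab0$values == GRID_LABELS[["fillable"]]) * voxel_mL(lab0)
  expect_rel_equal(vol_fill, 4 / 3 * pi * 2^3, 0.01)   # 33.51 mL
  lab <- rasterize_grid(grid_spec(2, 2), container_box(40.07), 0.5)
  expect_lt(abs(fvf_from_labels(lab) - 0.25), 0.01)
  expect_error(rasterize_grid(grid_spec(2, 2), sph, 1.5), "min\\(t, g\\)")
})

test_that("rasterized FVF is phase- and axis-permutation invariant", {
  # box side incommensurate with the voxel grid so that no wall boundary
  # falls exactly on a voxel centre (a measure-zero knife edge)
  box <- container_box(40.07)
  base <- fvf_from_labels(rasterize_grid(grid_spec(2, 3), box, 0.25))
  shifted <- fvf_from_labels(rasterize_grid(
    grid_spec(2, 3, phase_mm = c(2.5, 2.5, 0)), box, 0.25))
  expect_equal(shifted, base, tolerance = 1e-3)
  perm <- fvf_from_labels(rasterize_grid(grid_spec(2, 3, c("y", "z")), box, 0.25))
  expect_equal(perm, base, tolerance = 1e-3)
})

test_that("voxelized FVF converges to analytic FVF at first order", {
  spec <- grid_spec(2, 2.8)
  box <- container_box(38.4)  # 8 periods
  target <- analytic_fvf(spec)
  errs <- vapply(c(0.4, 0.2, 0.1), function(v)
    abs(fvf_from_labels(rasterize_grid(spec, box, v)) - target), numeric(1))
  expect_lt(errs[3], errs[1])          # error decreases with voxel size
  # halving voxel size roughly halves the error (first order, +/- 50%)
  expect_gt(errs[1] / errs[3], 2)      # two halvings: factor in [2, 8]
  expect_lt(errs[1] / errs[3], 8)
})

test_that("fvf_from_labels edge cases", {
  lab <- rasterize_grid(NULL, container_box(10), 0.5)
  expect_equal(fvf_from_labels(lab), 1.0)
  lab$values[lab$values == GRID_LABELS[["fillable"]]] <- GRID_LABELS[["solid"]]
  expect_equal(fvf_from_labels(lab), 0.0)
  lab$values[] <- GRID_LABELS[["outside"]]
  expect_error(fvf_from_labels(lab), "no container")
})

test_that("fvf_from_mass implements 1 - (m/rho)/V with consistency flag", {
  expect_equal(fvf_from_mass(0, 1.192, 33.51)$fvf, 1.0)
  expect_equal(fvf_from_mass(1.192 * 33.51, 1.192, 33.51)$fvf, 0.0)
  r <- fvf_from_mass(0.72 * 1.192 * 33.51, 1.192, 33.51)
  expect_equal(r$fvf, 0.28, tolerance = 1e-12)
  expect_true(r$consistent)
  expect_warning(bad <- fvf_from_mass(2 * 1.192 * 33.51, 1.192, 33.51),
                 "inconsistent")
  expect_false(bad$consistent)
  expect_lt(bad$fvf, 0)               # reported as-is, not clipped
  expect_error(fvf_from_mass(-1, 1.192, 33.51))
})

test_that("delta_v is the signed relative deviation", {
  expect_equal(delta_v(100, 100), 0)
  expect_equal(delta_v(85, 100), 0.15)
  expect_equal(delta_v(110, 100), -0.1)
  expect_error(delta_v(100, 0), "measured")
})

test_that("MetaImage round trip preserves values and geometry", {
  vv <- voxel_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)), c(1, 2, 3),
                     c(-1, 0, 2.5), "attenuation")
  f <- tempfile(fileext = ".mha")
  write_mha(vv, f)
  back <- read_mha(f)
  expect_equal(back$values, vv$values)
  expect_equal(back$voxel_size_mm, vv$voxel_size_mm)
  expect_equal(back$origin_mm, vv$origin_mm)
  expect_equal(back$value_kind, "attenuation")
  unlink(f)
})
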