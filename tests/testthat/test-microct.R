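# Synthetic micro-CT fixtures: a sphere shell with an internal grid,
# generated at test time.  Voxel sizes are chosen so walls span >= 4 voxels.

shelled_grid <- function(sphere_d = 24, t = 2, g = 2, vox = 0.2,
                         shell = 1.5) {
  spec <- grid_spec(t, g)
  inner <- container_sphere(sphere_d)
  lab <- rasterize_grid(spec, inner, vox, margin_mm = shell + 1)
  xs <- voxel_coords(lab, 1); ys <- voxel_coords(lab, 2)
  zs <- voxel_coords(lab, 3)
  r <- sqrt(outer(outer(xs^2, ys^2, "+"), zs^2, "+"))
  in_shell <- r > sphere_d / 2 & r <= sphere_d / 2 + shell
  v <- lab$values
  v[in_shell] <- GRID_LABELS[["solid"]]
  lab$values <- v
  lab
}

test_that("synth_microct produces a deterministic two-level image", {
  spec <- grid_spec(2, 2)
  lab <- rasterize_grid(spec, container_box(12.1), 0.25)
  img0 <- synth_microct(lab, defect_model())
  expect_setequal(unique(as.numeric(img0$values)), c(0, 1000))
  expect_equal(img0$values == 1000, lab$values == GRID_LABELS[["solid"]])
  n1 <- synth_microct(lab, defect_model(noise_sd = 5), seed = 3)
  n2 <- synth_microct(lab, defect_model(noise_sd = 5), seed = 3)
  expect_identical(n1$values, n2$values)
  coarse <- rasterize_grid(grid_spec(2, 2), container_box(12.1), 0.9)
  expect_error(synth_microct(coarse, defect_model()), "under-resolved")
})

test_that("uniform thickening grows the solid volume as designed", {
  # analytic oracle: with t = 2, g = 2 and 10% thickening (0.1 mm per side,
  # exactly 1 voxel at 0.1 mm), solid fraction goes from 1-(g/p)^2 with
  # t = 2 to t' = 2.2 at fixed period
  spec <- grid_spec(2, 2)
  lab <- rasterize_grid(spec, container_box(12.05), 0.1)
  img <- synth_microct(lab, defect_model(uniform_scale = 0.1))
  inside <- lab$values != GRID_LABELS[["outside"]]
  frac <- sum(img$values[inside] == 1000) / sum(inside)
  frac0 <- 1 - (2 / 4)^2
  frac1 <- 1 - ((4 - 2.2) / 4)^2
  expect_gt(frac, frac0)
  expect_rel_equal(frac, frac1, 0.02)
})

test_that("moment-preserving threshold matches the two-level oracle", {
  set.seed(9)
  v <- c(rep(10, 3000), rep(50, 7000))
  th <- moment_preserving_threshold(array(v, c(10, 10, 100)))
  expect_gt(th, 10); expect_lt(th, 50)
  expect_equal(mean(v >= th), 0.700, tolerance = 0.001)
  # robust to moderate noise over several seeds
  for (s in 1:10) {
    set.seed(s)
    vn <- v + rnorm(length(v), 0, 2)
    thn <- moment_preserving_threshold(vn)
    expect_equal(mean(vn >= thn), 0.70, tolerance = 0.01)
  }
  # translation equivariance
  expect_equal(moment_preserving_threshold(v + 17.3),
               moment_preserving_threshold(v) + 17.3, tolerance = 1e-6)
  expect_error(moment_preserving_threshold(rep(5, 100)), "variance")
})

test_that("clean_mask removes specks, fills holes, and is idempotent", {
  m <- array(FALSE, c(20, 20, 20))
  m[5:15, 5:15, 5:15] <- TRUE
  m[10, 10, 10] <- FALSE     # single-voxel hole
  m[2, 2, 2] <- TRUE         # isolated voxel
  cl <- clean_mask(m)
  expect_false(cl[2, 2, 2])
  expect_true(cl[10, 10, 10])
  expect_identical(clean_mask(cl), cl)
  # a defect-free grid with walls >= 3 voxels across passes unchanged
  lab <- rasterize_grid(grid_spec(2, 2), container_box(12.1), 0.5)
  g <- lab$values == GRID_LABELS[["solid"]]
  # interior comparison (the box boundary voxels see the padded border)
  cg <- clean_mask(g)
  i <- 3:(dim(g)[1] - 2)
  expect_identical(cg[i, i, i], g[i, i, i])
})

test_that("exclude_shell fits the sphere and isolates the grid", {
  lab <- shelled_grid()
  mask <- lab$values == GRID_LABELS[["solid"]]
  res <- exclude_shell(voxel_volume(array(mask, dim(mask)) + 0,
                                    lab$voxel_size_mm, lab$origin_mm, "label"),
                       shell_thickness_mm = 1.5)
  expect_equal(res$radius_mm, 12 + 1.5, tolerance = 0.1)
  expect_equal(res$center_mm, c(0, 0, 0), tolerance = 0.2)
  # interior voxel count close to the grid-only rasterization
  spec <- grid_spec(2, 2)
  r_cut <- res$radius_mm - 1.5 - 2 * 0.2
  ref <- rasterize_grid(spec, container_sphere(2 * r_cut), 0.2)
  n_ref <- sum(ref$values == GRID_LABELS[["solid"]])
  expect_rel_equal(sum(res$mask$values != 0), n_ref, 0.02)
  # a grid without a shell is rejected
  bare <- rasterize_grid(spec, container_sphere(24), 0.2)
  expect_error(exclude_shell(bare$values == GRID_LABELS[["solid"]],
                             voxel_size_mm = 0.2), "shell")
})

test_that("full pipeline recovers the designed grid volume within 2%", {
  lab <- shelled_grid(sphere_d = 24, vox = 0.1)
  img <- synth_microct(lab, defect_model(blur_fwhm_mm = 0.15, noise_sd = 60),
                       seed = 4)
  th <- moment_preserving_threshold(img)
  mask <- clean_mask(img$values >= th)
  res <- exclude_shell(voxel_volume(mask + 0, img$voxel_size_mm,
                                    img$origin_mm, "label"),
                       shell_thickness_mm = 1.5)
  vol <- grid_volume_from_ct(res$mask)
  r_cut <- res$radius_mm - 1.5 - 2 * 0.1
  design <- rasterize_grid(grid_spec(2, 2), container_sphere(2 * r_cut), 0.1)
  v_design <- sum(design$values == GRID_LABELS[["solid"]]) * voxel_mL(design)
  expect_rel_equal(vol, v_design, 0.02)
})

test_that("central-peripheral ratio is unity for uniform grids and shifts for local defects", {
  spec <- grid_spec(1, 1)
  lab <- rasterize_grid(spec, container_sphere(32), 0.2)
  mask <- lab$values == GRID_LABELS[["solid"]]
  vv <- voxel_volume(mask + 0, lab$voxel_size_mm, lab$origin_mm, "label")
  ratio <- central_peripheral_ratio(vv, spec, interior_radius_mm = 16)
  expect_equal(ratio, 1.00, tolerance = 0.02)
  # a uniformly applied defect keeps the ratio at unity
  img_u <- synth_microct(rasterize_grid(grid_spec(1, 1), container_sphere(32),
                                        0.2),
                         defect_model(uniform_scale = 0.2))
  vu <- voxel_volume((img_u$values > 500) + 0, img_u$voxel_size_mm,
                     img_u$origin_mm, "label")
  ratio_u <- central_peripheral_ratio(vu, spec, interior_radius_mm = 16)
  expect_equal(ratio_u, 1.00, tolerance = 0.02)
  # thicken only central walls: central voids shrink, ratio < 1
  d <- dim(mask)
  ctr <- lapply(d, function(n) seq(round(n * 0.35), round(n * 0.65)))
  m2 <- array(as.integer(mask), d)
  sub <- m2[ctr[[1]], ctr[[2]], ctr[[3]]]
  sub <- gridspect:::cpp_morph3(sub, dim(sub), TRUE)
  m2[ctr[[1]], ctr[[2]], ctr[[3]]] <- sub
  m2[!(lab$values != GRID_LABELS[["outside"]])] <- 0L
  v2 <- voxel_volume(m2, lab$voxel_size_mm, lab$origin_mm, "label")
  ratio_c <- central_peripheral_ratio(v2, spec, interior_radius_mm = 16)
  expect_lt(ratio_c, 0.98)
  expect_error(central_peripheral_ratio(vv, spec, interior_radius_mm = 3),
               "ROI")
})
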