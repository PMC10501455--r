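test_that("shape spec enforces the geometry constraints", {
  expect_error(sim_shape_spec(-0.1, 0.2), class = "dentamorph_parameter_error")
  expect_error(sim_shape_spec(0.2, 0.05, length_mm = 40),
               class = "dentamorph_parameter_error")  # < 3 periods
  expect_error(sim_shape_spec(6, 0.2, height_mm = 10),
               class = "dentamorph_parameter_error")  # 2A >= height
  expect_warning(sim_shape_spec(0.1, 0.2, voxel_mm = 0.2), "sub-voxel")
})

test_that("a zero-amplitude spec yields a plain cuboid with a flat face", {
  spec <- sim_shape_spec(0, 0.2)
  m <- simulate_dentated_cuboid(spec)
  sil <- extract_silhouette(m, dentamorph_config(), seed = 3)
  # flat face: silhouette variation within one fine voxel
  expect_lt(diff(range(sil$y_mm)), 0.2 + 1e-9)
})

test_that("the voxelized volume matches the analytic volume integral", {
  # the sinusoid is mean-zero so the displaced-face solid still encloses
  # length * width * height; allow one voxel-layer of discretization error
  spec <- sim_shape_spec(0.3, 0.15, phase_rad = 0.8)
  m <- simulate_dentated_cuboid(spec, grid_offset_mm = c(0.05, 0.09, 0.03))
  vol_mm3 <- sum(m) * vol_spacing(m)^3
  surface_area <- 2 * (40 * 20 + 40 * 10 + 20 * 10)
  expect_lt(abs(vol_mm3 - 40 * 20 * 10), surface_area * vol_spacing(m))
})

test_that("the inferior envelope follows the analytic sinusoid", {
  # column-wise most-inferior foreground voxel vs the analytic face, for
  # several (A, F) cells; RMS must stay below one voxel
  for (cell in list(c(0.3, 0.2), c(0.4, 0.1), c(0.2, 0.25))) {
    spec <- sim_shape_spec(cell[1], cell[2], phase_rad = 1.2)
    m <- simulate_dentated_cuboid(spec, grid_offset_mm = c(0.07, 0.0, 0.11))
    arr <- unclass(m) > 0
    h <- vol_spacing(m)
    jmid <- round(dim(arr)[2] / 2)
    xs <- voxel_centers(m, 1)
    zs <- voxel_centers(m, 3)
    env <- apply(arr[, jmid, ], 1, function(col) {
      if (!any(col)) NA_real_ else zs[which(col)[1]]  # lowest z = inferior
    })
    keep <- !is.na(env) & xs > 2 & xs < 38
    resid <- env[keep] - analytic_inferior_face(spec, xs[keep])
    resid <- resid - mean(resid)  # half-voxel offset is systematic
    expect_lt(sqrt(mean(resid^2)), h)
  }
})

test_that("the expected number of bump periods fits along the shape", {
  spec <- sim_shape_spec(0.4, 0.25, length_mm = 40)
  m <- simulate_dentated_cuboid(spec)
  fit <- fit_sinusoid_sa(extract_silhouette(m, dentamorph_config(), seed = 2),
                         seed = 2)
  expect_equal(fit$f_bpm * 40, 10, tolerance = 0.02)
})

test_that("simulation is deterministic and degradation is seed-reproducible", {
  spec <- sim_shape_spec(0.2, 0.2)
  expect_identical(unclass(simulate_dentated_cuboid(spec)),
                   unclass(simulate_dentated_cuboid(spec)))
  m <- simulate_dentated_cuboid(spec)
  d1 <- degrade_to_probability_map(m, 1, 0.5, 0.05, seed = 9)
  d2 <- degrade_to_probability_map(m, 1, 0.5, 0.05, seed = 9)
  expect_identical(unclass(d1), unclass(d2))
  i1 <- companion_intensity_image(m, noise_sd = 5, seed = 4)
  i2 <- companion_intensity_image(m, noise_sd = 5, seed = 4)
  expect_identical(unclass(i1), unclass(i2))
})

test_that("degradation in the identity limit returns the mask itself", {
  spec <- sim_shape_spec(0.2, 0.2)
  m <- simulate_dentated_cuboid(spec)
  p <- degrade_to_probability_map(m, vol_spacing(m), blur_sigma_mm = 0,
                                  noise_sd = 0, seed = 1)
  expect_equal(unclass(p), unclass(m), ignore_attr = TRUE)
  expect_error(degrade_to_probability_map(m, 0.1),
               class = "dentamorph_parameter_error")
})

test_that("the 0.5 level of the degraded map stays close to the truth", {
  spec <- sim_shape_spec(0.3, 0.125, phase_rad = 0.5)
  m <- simulate_dentated_cuboid(spec)
  p <- degrade_to_probability_map(m, 1, 0.5, 0, seed = 1)
  # oracle: direct box-downsample + threshold of the truth
  down <- degrade_to_probability_map(m, 1, blur_sigma_mm = 0, noise_sd = 0,
                                     seed = 1)
  expect_gt(overlap_metrics(threshold_mask(p), threshold_mask(down))$dsc, 0.9)
})

test_that("the companion image is two-valued before blurring and its LoG
           zero-crossing sits on the true surface", {
  spec <- sim_shape_spec(0, 0.2)
  m <- simulate_dentated_cuboid(spec)
  raw <- companion_intensity_image(m, fg_mean = 120, bg_mean = 40,
                                   noise_sd = 0, psf_sigma_mm = 0)
  expect_setequal(unique(as.numeric(raw)), c(40, 120))
  expect_error(companion_intensity_image(m, fg_mean = 50, bg_mean = 50),
               class = "dentamorph_parameter_error")

  img <- companion_intensity_image(m, noise_sd = 0, psf_sigma_mm = 0.3)
  h <- vol_spacing(img)
  lg <- array(dentamorph:::.cpp_laplacian(as.numeric(unclass(img)),
                                          dim(img), h), dim(img))
  # walk down a central column: LoG changes sign within 1 voxel of the flat
  # inferior face at z = 0 (oracle: the shape's analytic face position)
  i <- round(dim(img)[1] / 2)
  j <- round(dim(img)[2] / 2)
  zs <- voxel_centers(img, 3)
  prof <- lg[i, j, ]
  sgn <- which(diff(sign(prof)) != 0)
  mids <- (zs[sgn] + zs[sgn + 1]) / 2
  crossing <- mids[which.min(abs(mids))]
  expect_lt(abs(crossing - 0), h)
})
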