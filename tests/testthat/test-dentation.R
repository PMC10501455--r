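test_that("rejection sampling draws uniform interior points", {
  ball <- make_ball_mask(10, n = 26)
  cloud <- sample_point_cloud(ball, n = 50000, seed = 3)
  # every point lies in a foreground voxel
  idx <- round(cbind(cloud$x_mm, cloud$y_mm, cloud$z_mm) / 1) + 1
  expect_true(all(unclass(ball)[idx] > 0))
  # centroid of the ball sample ~ ball centre within 3 standard errors
  ctr_true <- (dim(ball) - 1) / 2
  se <- 10 / sqrt(5) / sqrt(50000)  # sd of a coordinate in a ball = R/sqrt(5)
  ctr_est <- colMeans(cbind(cloud$x_mm, cloud$y_mm, cloud$z_mm))
  expect_true(all(abs(ctr_est - ctr_true) < 3 * se + 0.05))
  # determinism
  cloud2 <- sample_point_cloud(ball, n = 50000, seed = 3)
  expect_identical(cloud$x_mm, cloud2$x_mm)
})

test_that("cuboid samples pass an octant uniformity chi-square test", {
  m <- make_cuboid_mask(c(16, 12, 8), pad = 3)
  cloud <- sample_point_cloud(m, n = 40000, seed = 11)
  pts <- cbind(cloud$x_mm, cloud$y_mm, cloud$z_mm)
  # exact centre in mm: cells span [pad - 0.5, pad - 0.5 + dims]
  med <- c(2.5 + 16 / 2, 2.5 + 12 / 2, 2.5 + 8 / 2)
  oct <- 1 + (pts[, 1] > med[1]) + 2 * (pts[, 2] > med[2]) +
    4 * (pts[, 3] > med[3])
  expect_gt(stats::chisq.test(tabulate(oct, 8))$p.value, 0.01)
})

test_that("the PCA frame recovers the axes of a cuboid", {
  spec <- sim_shape_spec(0, 0.2)  # 40 x 20 x 10 mm
  m <- simulate_dentated_cuboid(spec)
  cloud <- sample_point_cloud(m, n = 60000, seed = 5)
  fr <- pca_frame(cloud)
  ang <- function(v, w) acos(abs(sum(v * w))) * 180 / pi
  expect_lt(ang(fr$eigvecs[, 1], c(1, 0, 0)), 2)
  expect_lt(ang(fr$eigvecs[, 2], c(0, 1, 0)), 2)
  expect_lt(ang(fr$eigvecs[, 3], c(0, 0, 1)), 2)
  # oracle: analytic eigenvalues of a uniform cuboid, L^2/12 etc.
  expect_equal(fr$eigvals, c(40^2, 20^2, 10^2) / 12, tolerance = 0.02)
  # sign conventions: e3 inferior (-z), e1 anterior (+x), right-handed
  expect_gt(sum(fr$eigvecs[, 3] * c(0, 0, -1)), 0)
  expect_gt(sum(fr$eigvecs[, 1] * c(1, 0, 0)), 0)
  cross <- c(fr$eigvecs[2, 3] * fr$eigvecs[3, 1] -
               fr$eigvecs[3, 3] * fr$eigvecs[2, 1],
             fr$eigvecs[3, 3] * fr$eigvecs[1, 1] -
               fr$eigvecs[1, 3] * fr$eigvecs[3, 1],
             fr$eigvecs[1, 3] * fr$eigvecs[2, 1] -
               fr$eigvecs[2, 3] * fr$eigvecs[1, 1])
  expect_equal(as.numeric(fr$eigvecs[, 2]), unname(cross), tolerance = 1e-8)
  expect_equal(crossprod(fr$eigvecs), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("a near-isotropic cloud triggers the degenerate warning path", {
  ball <- make_ball_mask(10, n = 26)
  cloud <- sample_point_cloud(ball, n = 20000, seed = 7)
  expect_warning(pca_frame(cloud), "isotropic")
  flat <- tibble::tibble(x_mm = runif(100), y_mm = runif(100), z_mm = 0)
  class(flat) <- c("point_cloud", class(flat))
  attr(flat, "axes") <- c("AP", "LR", "SI")
  expect_error(pca_frame(flat), class = "dentamorph_degenerate_error")
})

test_that("the PCA frame is equivariant under rigid rotation", {
  spec <- sim_shape_spec(0, 0.2)
  m <- simulate_dentated_cuboid(spec)
  cloud <- sample_point_cloud(m, n = 40000, seed = 5)
  R <- rotation_matrix(c(1, 2, 0.5), 0.4)
  pts <- as.matrix(cloud[, 1:3])
  ctr <- colMeans(pts)
  rot <- sweep(sweep(pts, 2, ctr) %*% t(R), 2, ctr, "+")
  cloud_r <- tibble::tibble(x_mm = rot[, 1], y_mm = rot[, 2], z_mm = rot[, 3])
  class(cloud_r) <- c("point_cloud", class(cloud_r))
  fr <- pca_frame(cloud, inferior_hint = c(0, 0, -1),
                  anterior_hint = c(1, 0, 0))
  fr_r <- pca_frame(cloud_r, inferior_hint = as.numeric(R %*% c(0, 0, -1)),
                    anterior_hint = as.numeric(R %*% c(1, 0, 0)))
  # oracle: the rotated frame equals R applied to the unrotated frame
  expect_equal(fr_r$eigvecs, R %*% fr$eigvecs, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fr_r$eigvals, fr$eigvals, tolerance = 1e-8)
})

test_that("plane projection is an in-plane identity and a contraction", {
  pts <- withr::with_seed(1, matrix(rnorm(300), ncol = 3))
  cloud <- tibble::tibble(x_mm = pts[, 1], y_mm = pts[, 2], z_mm = pts[, 3])
  class(cloud) <- c("point_cloud", class(cloud))
  fr <- pca_frame(cloud, inferior_hint = c(0, 0, 1))
  pr <- project_to_plane(cloud, fr)
  # pairwise distances never grow under orthogonal projection
  d3 <- dist(pts)
  d2 <- dist(cbind(pr$u_mm, pr$v_mm))
  expect_true(all(d2 <= d3 + 1e-12))
  # points already in the e1-e3 plane are unchanged
  inplane <- sweep(outer(pr$u_mm, fr$eigvecs[, 1]) +
                     outer(pr$v_mm, fr$eigvecs[, 3]), 2, fr$mean_mm, "+")
  cloud2 <- tibble::tibble(x_mm = inplane[, 1], y_mm = inplane[, 2],
                           z_mm = inplane[, 3])
  class(cloud2) <- c("point_cloud", class(cloud2))
  fr2 <- fr
  fr2$mean_mm <- colMeans(inplane)
  pr2 <- project_to_plane(cloud2, fr2)
  ctr_u <- pr$u_mm - mean(pr$u_mm)
  ctr_v <- pr$v_mm - mean(pr$v_mm)
  expect_equal(pr2$u_mm, ctr_u, tolerance = 1e-8)
  expect_equal(pr2$v_mm, ctr_v, tolerance = 1e-8)
})

test_that("projected extents of the cuboid cloud match the analytic body", {
  spec <- sim_shape_spec(0, 0.2)
  m <- simulate_dentated_cuboid(spec)
  cloud <- sample_point_cloud(m, n = 40000, seed = 13)
  pr <- project_to_plane(cloud, pca_frame(cloud))
  expect_equal(diff(range(pr$u_mm)), 40, tolerance = 0.03)
  expect_equal(diff(range(pr$v_mm)), 10, tolerance = 0.03)
})

test_that("silhouette extraction matches the analytic face of a simulated
           shape", {
  spec <- sim_shape_spec(0.3, 0.2, phase_rad = 0.9)
  m <- simulate_dentated_cuboid(spec, grid_offset_mm = c(0.06, 0.1, 0.14))
  cfg <- dentamorph_config()
  sil <- extract_silhouette(m, cfg, seed = 21)
  # v grows toward inferior, so the analytic envelope is -face(x) + const;
  # x is centred by the PCA frame, so allow a phase shift via LS alignment
  w <- 2 * pi * 0.2
  X <- cbind(sin(w * sil$x_mm), cos(w * sil$x_mm), 1)
  cf <- qr.solve(X, sil$y_mm)
  resid <- sil$y_mm - X %*% cf
  expect_lt(sqrt(mean(resid^2)), vol_spacing(m))
  expect_equal(sqrt(cf[1]^2 + cf[2]^2), 0.3, tolerance = 0.15)
})

test_that("trimming removes the stated share of the x-range", {
  spec <- sim_shape_spec(0.3, 0.2)
  m <- simulate_dentated_cuboid(spec)
  cloud <- sample_point_cloud(m, n = 50000, seed = 2)
  pr <- project_to_plane(cloud, pca_frame(cloud))
  sil <- inferior_silhouette(pr, bin_width_mm = 0.2, trim_fraction = 0.4)
  expect_lt(diff(range(sil$x_mm)), 0.2 * 40 + 0.5)
  expect_gte(nrow(sil), 10)
  expect_error(inferior_silhouette(pr, bin_width_mm = 8, trim_fraction = 0.4),
               class = "dentamorph_parameter_error")
})

test_that("mask-to-silhouette is reproducible and sampling-mode agrees with
           the deterministic mode", {
  spec <- sim_shape_spec(0.3, 0.15, phase_rad = 0.4)
  m <- simulate_dentated_cuboid(spec, grid_offset_mm = c(0.03, 0.08, 0.12))
  cfg <- dentamorph_config()
  s1 <- extract_silhouette(m, cfg, seed = 8)
  s2 <- extract_silhouette(m, cfg, seed = 8)
  expect_identical(s1$y_mm, s2$y_mm)
  f_s <- fit_sinusoid_sa(s1, seed = 8)
  f_d <- fit_sinusoid_sa(extract_silhouette(m, cfg, deterministic = TRUE),
                         seed = 8)
  expect_lt(abs(f_s$A_mm - f_d$A_mm) / f_d$A_mm, 0.02)
  expect_lt(abs(f_s$f_bpm - f_d$f_bpm) / f_d$f_bpm, 0.02)
})
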