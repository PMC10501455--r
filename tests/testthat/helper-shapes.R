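# fixtures are generated in code at test time; nothing is stored on disk

options(dentamorph.quiet = TRUE)

# digital ball mask: voxel centres within radius r (voxels) of ctr
make_ball_mask <- function(r, n = 2 * ceiling(r) + 11, spacing = 1,
                           ctr = rep((n - 1) / 2, 3)) {
  arr <- array(FALSE, c(n, n, n))
  for (k in seq_len(n)) {
    arr[, , k] <- outer((seq_len(n) - 1 - ctr[1])^2,
                        (seq_len(n) - 1 - ctr[2])^2, "+") +
      (k - 1 - ctr[3])^2 <= r^2
  }
  binary_mask(arr, spacing, axes = c("AP", "LR", "SI"))
}

make_cuboid_mask <- function(dims_vox = c(20, 10, 6), pad = 4, spacing = 1) {
  n <- dims_vox + 2 * pad
  arr <- array(FALSE, n)
  arr[pad + seq_len(dims_vox[1]), pad + seq_len(dims_vox[2]),
      pad + seq_len(dims_vox[3])] <- TRUE
  binary_mask(arr, spacing, axes = c("AP", "LR", "SI"))
}

rand_mask <- function(seed, n = 12, p = 0.4, spacing = 1) {
  arr <- withr::with_seed(seed, array(runif(n^3) < p, c(n, n, n)))
  # guarantee non-empty
  arr[n %/% 2, n %/% 2, n %/% 2] <- TRUE
  binary_mask(arr, spacing, axes = c("AP", "LR", "SI"))
}

# rotation matrix about a (unit) axis by angle rad
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# rigidly rotate a binary mask about its foreground centroid (nearest-
# neighbour resampling on a grid large enough to hold the rotated shape)
rotate_mask <- function(mask, R) {
  arr <- unclass(mask) > 0
  h <- vol_spacing(mask)
  fg <- which(arr, arr.ind = TRUE)
  ctr_mm <- vol_origin(mask) + (colMeans(fg) - 1) * h
  # rotated bounding box from the 8 corners
  corners <- as.matrix(expand.grid(range(fg[, 1]), range(fg[, 2]),
                                   range(fg[, 3])))
  corners_mm <- sweep((corners - 1) * h, 2, vol_origin(mask), "+")
  centered <- sweep(corners_mm, 2, ctr_mm, "-")
  rot_corners <- centered %*% t(R)
  lo <- apply(rot_corners, 2, min) - 3 * h
  hi <- apply(rot_corners, 2, max) + 3 * h
  nvox <- ceiling((hi - lo) / h) + 1
  # target voxel centres, rotated back into the source frame
  xs <- lo[1] + (seq_len(nvox[1]) - 1) * h
  ys <- lo[2] + (seq_len(nvox[2]) - 1) * h
  zs <- lo[3] + (seq_len(nvox[3]) - 1) * h
  pts <- as.matrix(expand.grid(xs, ys, zs))
  src <- pts %*% R  # R^-1 = t(R); pts are row vectors so %*% R applies t(R)
  src <- sweep(src, 2, ctr_mm, "+")
  idx <- sweep(src, 2, vol_origin(mask)) / h
  ijk <- round(idx) + 1
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= dim(arr)[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= dim(arr)[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= dim(arr)[3]
  vals <- logical(nrow(ijk))
  vals[ok] <- arr[ijk[ok, , drop = FALSE]]
  out <- array(vals, nvox)
  binary_mask(out, h, origin_mm = ctr_mm + lo, axes = vol_axes(mask))
}

# degrade + refine one simulated cell, returning masks aligned to the truth
refine_cell <- function(A, F, seed, cfg = dentamorph_config()) {
  draws <- withr::with_seed(seed, list(ph = runif(1, 0, 2 * pi),
                                       off = runif(3, 0, 0.2)))
  spec <- suppressWarnings(sim_shape_spec(A, F, phase_rad = draws$ph))
  truth <- suppressWarnings(simulate_dentated_cuboid(spec,
                                                     grid_offset_mm = draws$off))
  prob <- degrade_to_probability_map(truth, 1, 0.5, 0.05, seed = seed)
  img <- companion_intensity_image(truth, noise_sd = 4, out_spacing_mm = 1,
                                   seed = seed + 1L)
  img <- resample_to_grid(img, prob, mode = "nearest", outside = 40)
  fine <- fine_scale_segment(img, prob, cfg)
  list(truth = truth,
       prob = prob,
       fine = fine,
       fine_on_truth = threshold_mask(
         resample_to_grid(fine, truth, mode = "nearest")),
       native_on_truth = threshold_mask(
         resample_to_grid(threshold_mask(prob, 0.5), truth,
                          mode = "nearest")))
}

# brute-force all-pairs directed Hausdorff (oracle for the EDT-based path)
brute_hausdorff <- function(a, b, spacing) {
  pa <- which(unclass(a) > 0, arr.ind = TRUE)
  pb <- which(unclass(b) > 0, arr.ind = TRUE)
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2 +
    outer(pa[, 3], pb[, 3], "-")^2
  list(ab = sqrt(apply(d2, 1, min)) * spacing,
       ba = sqrt(apply(d2, 2, min)) * spacing)
}

# least-squares sinusoid fit by dense frequency grid search (independent
# oracle for the annealing optimizer)
grid_search_fit <- function(sil, f_lo = 0.02, f_hi = 0.5, n_f = 2000) {
  fs <- exp(seq(log(f_lo), log(f_hi), length.out = n_f))
  best <- NULL
  best_cost <- Inf
  for (f in fs) {
    w <- 2 * pi * f
    X <- cbind(sin(w * sil$x_mm), cos(w * sil$x_mm), 1)
    cf <- tryCatch(qr.solve(X, sil$y_mm), error = function(e) NULL)
    if (is.null(cf)) next
    cost <- mean((sil$y_mm - X %*% cf)^2)
    if (cost < best_cost) {
      best_cost <- cost
      best <- list(A = sqrt(cf[1]^2 + cf[2]^2), f = f,
                   phi = atan2(cf[2], cf[1]) %% (2 * pi), b = cf[3],
                   cost = cost)
    }
  }
  best
}

# analytic silhouette samples (no voxelization)
analytic_sil <- function(A, f, phi = 0, b = 0, x = seq(0, 40, by = 0.2),
                         noise_sd = 0, seed = 1) {
  y <- A * sin(2 * pi * f * x + phi) + b
  if (noise_sd > 0) {
    y <- y + withr::with_seed(seed, rnorm(length(x), sd = noise_sd))
  }
  sil <- tibble::tibble(x_mm = x, y_mm = y, n_in_bin = 1L)
  class(sil) <- c("silhouette", class(sil))
  sil
}
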