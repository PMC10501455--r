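#' Sample uniform interior points from a binary mask
#'
#' Rejection sampling: points are drawn uniformly in the foreground bounding
#' box (world mm) and kept iff the voxel containing them is foreground,
#' yielding a uniform sample of the shape's interior. Deterministic given
#' the seed.
#'
#' @param mask A non-empty [binary_mask()].
#' @param n Number of points to draw.
#' @param seed Integer seed.
#' @return A `point_cloud` tibble with columns `x_mm`, `y_mm`, `z_mm`
#'   (world coordinates in grid-axis order) and attributes `seed` and
#'   `axes`.
#' @export
sample_point_cloud <- function(mask, n = 200000L, seed = 1L) {
  stopifnot(inherits(mask, "binary_mask"), n >= 1)
  arr <- as_plain_array(mask) > 0
  fg <- which(arr, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    abort("mask is empty.", class = "dentamorph_parameter_error")
  }
  h <- vol_spacing(mask)
  org <- vol_origin(mask)
  # bounding box of foreground voxel cells, in mm
  lo <- (apply(fg, 2, min) - 1.5) * h + org
  hi <- (apply(fg, 2, max) - 0.5) * h + org
  frac <- nrow(fg) * h^3 / prod(hi - lo)
  if (frac < 1e-6) {
    abort(paste0("foreground occupies < 1e-6 of its bounding box; use ",
                 "point_cloud_from_voxels() instead."),
          class = "dentamorph_parameter_error")
  }
  pts <- withr::with_seed(as.integer(seed), {
    acc <- matrix(numeric(0), 0, 3)
    while (nrow(acc) < n) {
      m <- ceiling((n - nrow(acc)) / max(frac, 1e-3) * 1.2)
      m <- min(m, 5e6)
      cand <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]),
                    runif(m, lo[3], hi[3]))
      idx <- sweep(cand, 2, org, "-") / h
      ijk <- floor(idx + 0.5) + 1  # voxel cell containing the point
      ok <- ijk[, 1] >= 1 & ijk[, 1] <= dim(arr)[1] &
            ijk[, 2] >= 1 & ijk[, 2] <= dim(arr)[2] &
            ijk[, 3] >= 1 & ijk[, 3] <= dim(arr)[3]
      ijk <- ijk[ok, , drop = FALSE]
      cand <- cand[ok, , drop = FALSE]
      keep <- arr[ijk]
      acc <- rbind(acc, cand[keep, , drop = FALSE])
    }
    acc[seq_len(n), , drop = FALSE]
  })
  out <- tibble(x_mm = pts[, 1], y_mm = pts[, 2], z_mm = pts[, 3])
  class(out) <- c("point_cloud", class(out))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "axes") <- vol_axes(mask)
  out
}

#' @rdname sample_point_cloud
#' @details `point_cloud_from_voxels()` is the deterministic alternative:
#'   it returns every foreground voxel centre instead of sampling.
#' @export
point_cloud_from_voxels <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  fg <- which(as_plain_array(mask) > 0, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    abort("mask is empty.", class = "dentamorph_parameter_error")
  }
  h <- vol_spacing(mask)
  org <- vol_origin(mask)
  out <- tibble(x_mm = (fg[, 1] - 1) * h + org[1],
                y_mm = (fg[, 2] - 1) * h + org[2],
                z_mm = (fg[, 3] - 1) * h + org[3])
  class(out) <- c("point_cloud", class(out))
  attr(out, "seed") <- NA_integer_
  attr(out, "axes") <- vol_axes(mask)
  out
}

#' Principal-axis frame of a point cloud
#'
#' Eigendecomposition of the point covariance. For a hippocampus-like
#' elongated shape the first eigenvector is approximately the
#' anterior-posterior axis, the second the left-right axis and the third
#' perpendicular to the "sheet" of the structure. Signs are fixed so that
#' `e3` points toward the anatomical inferior direction
#' (`e3 . inferior_hint > 0`), `e1` toward anterior when a hint is
#' available, and `e2 = e3 x e1` completes a right-handed frame.
#'
#' @param cloud A `point_cloud` tibble (N >= 4 non-coplanar points).
#' @param inferior_hint World-space vector pointing inferior; defaults to
#'   the direction implied by the cloud's axis labels.
#' @param anterior_hint Optional world-space vector pointing anterior.
#' @return A `pca_frame` list with `mean_mm`, `eigvecs` (columns e1, e2,
#'   e3), `eigvals` (descending).
#' @export
pca_frame <- function(cloud, inferior_hint = NULL, anterior_hint = NULL) {
  pts <- as.matrix(cloud[, c("x_mm", "y_mm", "z_mm")])
  if (nrow(pts) < 4) {
    abort("need at least 4 points for a PCA frame.",
          class = "dentamorph_parameter_error")
  }
  axes <- attr(cloud, "axes")
  if (is.null(inferior_hint)) {
    if (is.null(axes)) {
      abort("no axis labels on the cloud; supply `inferior_hint`.",
            class = "dentamorph_parameter_error")
    }
    ax <- match("SI", axes)
    inferior_hint <- c(0, 0, 0)
    inferior_hint[ax] <- -1
  }
  if (is.null(anterior_hint) && !is.null(axes) && "AP" %in% axes) {
    ax <- match("AP", axes)
    anterior_hint <- c(0, 0, 0)
    anterior_hint[ax] <- 1
  }
  ctr <- colMeans(pts)
  cv <- stats::cov(pts)
  eg <- eigen(cv, symmetric = TRUE)
  vals <- eg$values
  vecs <- eg$vectors
  if (vals[3] < 1e-10 * max(vals[1], 1)) {
    abort("degenerate (coplanar) point cloud: rank-deficient covariance.",
          class = "dentamorph_degenerate_error")
  }
  if (vals[1] - vals[3] < 0.05 * vals[1]) {
    warn(paste0("nearly isotropic point cloud: principal axes are ",
                "ill-determined."))
  }
  e1 <- vecs[, 1]
  e3 <- vecs[, 3]
  if (sum(e3 * inferior_hint) < 0) e3 <- -e3
  if (!is.null(anterior_hint) && sum(e1 * anterior_hint) < 0) e1 <- -e1
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  structure(list(mean_mm = ctr,
                 eigvecs = cbind(e1 = e1, e2 = e2, e3 = e3),
                 eigvals = vals),
            class = "pca_frame")
}

#' @export
print.pca_frame <- function(x, ...) {
  cat("<pca_frame>\n  eigenvalues:", sprintf("%.4g", x$eigvals), "\n")
  cat("  e1:", sprintf("% .3f", x$eigvecs[, 1]), "\n")
  cat("  e2:", sprintf("% .3f", x$eigvecs[, 2]), "\n")
  cat("  e3:", sprintf("% .3f", x$eigvecs[, 3]), "\n")
  invisible(x)
}

#' Project a point cloud onto the e1-e3 principal plane
#'
#' Each point maps to `u = (x - mean) . e1` (position along the long axis)
#' and `v = (x - mean) . e3` (height; increasing toward inferior, given the
#' frame's sign convention). The `e2` (lateral) component is discarded, so
#' the dentations of the inferior surface appear as undulations of the
#' lower envelope of the projected set.
#'
#' @param cloud A `point_cloud`.
#' @param frame A [pca_frame()].
#' @return A tibble with columns `u_mm`, `v_mm`.
#' @export
project_to_plane <- function(cloud, frame) {
  pts <- as.matrix(cloud[, c("x_mm", "y_mm", "z_mm")])
  ctd <- sweep(pts, 2, frame$mean_mm)
  tibble(u_mm = as.numeric(ctd %*% frame$eigvecs[, 1]),
         v_mm = as.numeric(ctd %*% frame$eigvecs[, 3]))
}

#' Inferior silhouette of a projected point set
#'
#' Partitions the long axis into bins of `bin_width_mm`; each bin
#' contributes its most inferior point (the maximum `v`, since `v`
#' increases toward inferior under the frame convention; a robust
#' percentile mode is available for noisy masks). Bins with fewer than
#' `min_per_bin` points are dropped and the first and last `trim_fraction`
#' of the x-range are removed, excluding the curved head/tail of a real
#' hippocampus.
#'
#' @param points2d Tibble with `u_mm`, `v_mm` from [project_to_plane()].
#' @param bin_width_mm Bin width, mm (default: the 0.2 mm fine voxel).
#' @param trim_fraction Fraction of the x-range removed per end, \[0, 0.5).
#' @param min_per_bin Minimum points for a bin to be kept.
#' @param stat `"extreme"` (per-bin most-inferior point) or `"percentile"`
#'   (robust envelope).
#' @param probs Percentile used when `stat = "percentile"`.
#' @return A `silhouette` tibble with columns `x_mm` (bin centre, strictly
#'   increasing), `y_mm` (inferior height) and `n_in_bin`.
#' @export
inferior_silhouette <- function(points2d, bin_width_mm = 0.2,
                                trim_fraction = 0.1, min_per_bin = 5L,
                                stat = c("extreme", "percentile"),
                                probs = 0.95) {
  stat <- match.arg(stat)
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    abort("`trim_fraction` must lie in [0, 0.5).",
          class = "dentamorph_parameter_error")
  }
  u <- points2d$u_mm
  v <- points2d$v_mm
  rng <- range(u)
  keep <- u >= rng[1] + trim_fraction * diff(rng) &
          u <= rng[2] - trim_fraction * diff(rng)
  u <- u[keep]
  v <- v[keep]
  u0 <- min(u)
  env <- tibble(bin = floor((u - u0) / bin_width_mm), v = v) %>%
    group_by(.data$bin) %>%
    summarise(y_mm = if (stat == "extreme") max(.data$v)
                     else as.numeric(quantile(.data$v, probs)),
              n_in_bin = dplyr::n(), .groups = "drop") %>%
    mutate(x_mm = u0 + (.data$bin + 0.5) * bin_width_mm)
  # a sliver bin at the far edge spans only part of the bin width and its
  # envelope is unreliable; keep complete bins only
  env <- env[(env$bin + 1) * bin_width_mm <= (max(u) - u0) + 1e-9, ]
  env <- env[env$n_in_bin >= min_per_bin, c("x_mm", "y_mm", "n_in_bin")]
  env <- env[order(env$x_mm), ]
  if (nrow(env) < 10) {
    abort(sprintf(paste0("only %d usable bins (width %g mm, %d points): too ",
                         "few for a silhouette (need >= 10)."),
                  nrow(env), bin_width_mm, length(u)),
          class = "dentamorph_parameter_error")
  }
  class(env) <- c("silhouette", class(env))
  attr(env, "bin_width_mm") <- bin_width_mm
  attr(env, "n_raw_points") <- nrow(points2d)
  env
}

#' One-call silhouette extraction from a fine-scale mask
#'
#' Convenience composition sample -> PCA -> projection -> silhouette used by
#' the study runner and per-subject pipeline.
#'
#' @param mask Fine-scale [binary_mask()].
#' @param cfg A [dentamorph_config()] supplying `n_points`, `bin_width_mm`,
#'   `trim_fraction`.
#' @param seed Seed for the point sampling (default: `cfg$seed`).
#' @param deterministic Use every voxel centre instead of sampling.
#' @return A `silhouette` tibble.
#' @export
extract_silhouette <- function(mask, cfg = dentamorph_config(), seed = NULL,
                               deterministic = FALSE) {
  cloud <- if (deterministic) point_cloud_from_voxels(mask)
           else sample_point_cloud(mask, cfg$n_points, seed %||% cfg$seed)
  frame <- pca_frame(cloud)
  proj <- project_to_plane(cloud, frame)
  inferior_silhouette(proj, bin_width_mm = cfg$bin_width_mm,
                      trim_fraction = cfg$trim_fraction)
}
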