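#' Upsample a probability map by an integer factor
#'
#' Cubic-spline (Catmull-Rom) interpolation onto a grid with spacing
#' `spacing / H` covering the same physical extent (the fine nodes include
#' every coarse node); values are clipped back to \[0, 1\].
#'
#' @param M A [probability_map()] (or any [scalar_volume()]).
#' @param H Positive integer upsampling factor; `H = 5` takes a 1 mm native
#'   map to the 0.2 mm fine scale.
#' @return The upsampled volume (same class as the input).
#' @export
upsample_probability <- function(M, H) {
  if (length(H) != 1 || H < 1 || H != round(H)) {
    abort("`H` must be a positive integer.",
          class = "dentamorph_parameter_error")
  }
  H <- as.integer(H)
  if (H == 1L) return(M)
  arr <- as_plain_array(M)
  for (ax in 1:3) {
    new_n <- (dim(arr)[ax] - 1L) * H + 1L
    arr <- array(.cpp_resample_axis(as.numeric(arr), dim(arr), ax - 1L,
                                    new_n, 1 / H, 0, 0L),
                 dim = replace(dim(arr), ax, new_n))
  }
  is_prob <- inherits(M, "probability_map")
  if (is_prob) arr <- pmin(pmax(arr, 0), 1)
  out <- scalar_volume(arr, vol_spacing(M) / H, vol_origin(M), vol_axes(M))
  if (is_prob) class(out) <- c("probability_map", class(out))
  out
}

#' Crop a volume to the region of interest around the foreground
#'
#' Axis-aligned bounding box of `{M > threshold}`, padded by `margin_mm` and
#' clipped to the grid; the origin is updated so world coordinates are
#' preserved. Restricting the fine-scale computation to this ROI is what
#' keeps sub-millimetre refinement tractable.
#'
#' @param M A [probability_map()] (or any volume).
#' @param threshold Probability threshold defining the foreground.
#' @param margin_mm Padding added around the bounding box, mm.
#' @return The cropped volume, with the index ranges used stored in
#'   attribute `"roi_box"` (a 2x3 matrix of first/last indices).
#' @export
crop_roi <- function(M, threshold = 0.2, margin_mm = 3) {
  fg <- which(as_plain_array(M) > threshold, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    abort(sprintf("no foreground at threshold %g.", threshold),
          class = "dentamorph_parameter_error")
  }
  pad <- ceiling(margin_mm / vol_spacing(M))
  lo <- pmax(apply(fg, 2, min) - pad, 1L)
  hi <- pmin(apply(fg, 2, max) + pad, dim(M))
  box <- rbind(lo, hi)
  out <- crop_to_box(M, box)
  attr(out, "roi_box") <- box
  out
}

#' @rdname crop_roi
#' @param vol Volume to crop.
#' @param box 2x3 matrix of first/last voxel indices (as produced by
#'   `crop_roi()`'s `"roi_box"` attribute).
#' @export
crop_to_box <- function(vol, box) {
  arr <- as_plain_array(vol)[box[1, 1]:box[2, 1],
                             box[1, 2]:box[2, 2],
                             box[1, 3]:box[2, 3], drop = FALSE]
  origin <- vol_origin(vol) + (box[1, ] - 1) * vol_spacing(vol)
  kind <- if (inherits(vol, "binary_mask")) "binary"
          else if (inherits(vol, "probability_map")) "probability"
          else "scalar"
  f <- switch(kind, binary = binary_mask, probability = probability_map,
              scalar = scalar_volume)
  f(arr, vol_spacing(vol), origin, vol_axes(vol))
}

#' High-confidence initial region
#'
#' Thresholds the upsampled probability map at `eta` and keeps the largest
#' 6-connected component (ties broken toward the component with the highest
#' mean probability). This strict region initializes the level-set surface,
#' which then relaxes outward/inward under image evidence.
#'
#' @param Mup Upsampled [probability_map()].
#' @param eta Confidence threshold in \[0, 1\]; higher values mark voxels
#'   that belong to the structure with higher confidence.
#' @return A [binary_mask()].
#' @export
init_high_confidence <- function(Mup, eta = 0.5) {
  if (eta < 0 || eta > 1) {
    abort("`eta` must lie in [0, 1].", class = "dentamorph_parameter_error")
  }
  arr <- as_plain_array(Mup)
  fg <- arr > eta
  if (!any(fg)) {
    abort(sprintf(paste0("no voxels exceed eta = %g (map maximum %.3g); ",
                         "lower eta."), eta, max(arr)),
          class = "dentamorph_parameter_error")
  }
  lab <- array(.cpp_label6(as.logical(fg), dim(Mup)), dim = dim(Mup))
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) > 1L) {
    biggest <- which(sizes == max(sizes))
    if (length(biggest) > 1L) {
      mean_p <- vapply(biggest, function(l) mean(arr[lab == l]), numeric(1))
      keep <- biggest[which.max(mean_p)]
    } else {
      keep <- biggest
    }
    dm_inform(sprintf(
      "init_high_confidence: discarded %d smaller component(s) (%d voxels).",
      length(sizes) - 1L, sum(sizes) - sizes[keep]))
    fg <- lab == keep
  }
  binary_mask(fg, vol_spacing(Mup), vol_origin(Mup), vol_axes(Mup))
}

#' Level-set evolution parameters
#'
#' @param alpha Non-negative regional (probability) force weight.
#' @param beta Non-negative mean-curvature force weight. The curvature
#'   convention is the divergence of the outward unit normal, i.e. the sum
#'   of the principal curvatures (2/R for a sphere of radius R).
#' @param log_sigma_mm Laplacian-of-Gaussian scale, mm.
#' @param dt_cfl CFL fraction in (0, 1] for the time step.
#' @param max_iters Iteration cap.
#' @param converge_tol Relative volume change defining convergence.
#' @param converge_window Number of iterations over which `converge_tol` is
#'   assessed.
#' @param band_halfwidth_mm Narrow-band half-width, mm (default 6 voxels).
#' @param reinit_every Signed-distance reinitialization period, iterations.
#' @return An `evolve_params` list.
#' @export
evolve_params <- function(alpha = 0.3, beta = 0.1, log_sigma_mm = 0.5,
                          dt_cfl = 0.45, max_iters = 200L,
                          converge_tol = 5e-4, converge_window = 10L,
                          band_halfwidth_mm = NULL, reinit_every = 20L) {
  if (alpha < 0 || beta < 0) {
    abort("`alpha` and `beta` must be non-negative.",
          class = "dentamorph_parameter_error")
  }
  if (dt_cfl <= 0 || dt_cfl > 1) {
    abort("`dt_cfl` must lie in (0, 1].", class = "dentamorph_parameter_error")
  }
  structure(list(alpha = alpha, beta = beta, log_sigma_mm = log_sigma_mm,
                 dt_cfl = dt_cfl, max_iters = as.integer(max_iters),
                 converge_tol = converge_tol,
                 converge_window = as.integer(converge_window),
                 band_halfwidth_mm = band_halfwidth_mm,
                 reinit_every = as.integer(reinit_every)),
            class = "evolve_params")
}

#' Evolve the segmentation surface by a narrow-band level set
#'
#' The zero level set of a signed-distance field (negative inside) moves
#' with normal speed `LoG(image) - alpha * M + beta * kappa` along the
#' inward unit normal, where `LoG` is the Laplacian-of-Gaussian edge
#' response of the upsampled intensity image (rescaled to \[-1, 1\] per
#' volume so `alpha`, `beta` are comparable across images), `M` the
#' upsampled probability map and `kappa` the mean curvature. The regional
#' term `-alpha * M` drives outward growth where the probability is high;
#' the edge term locks the surface onto intensity edges; the curvature term
#' regularizes. Evolution stops when the relative volume change over
#' `converge_window` iterations falls below `converge_tol` or at
#' `max_iters`. Fully deterministic.
#'
#' @param Mup Upsampled [probability_map()].
#' @param image_up Upsampled intensity [scalar_volume()] on the same grid,
#'   or `NULL` to disable the edge force.
#' @param init Non-empty [binary_mask()] initializing the surface.
#' @param params An [evolve_params()].
#' @return A [binary_mask()] of the evolved region, with attributes
#'   `iterations`, `volumes` (voxel counts per iteration), `energies`
#'   (discrete region + area energy per iteration), `converged` and
#'   `last_volume_mm3`.
#' @export
evolve_surface <- function(Mup, image_up = NULL, init, params = evolve_params()) {
  check_same_grid(Mup, init, "probability map and init mask")
  if (!is.null(image_up)) check_same_grid(Mup, image_up,
                                          "probability map and image")
  if (!any(init > 0)) {
    abort("`init` mask is empty.", class = "dentamorph_parameter_error")
  }
  h <- vol_spacing(Mup)
  n3 <- dim(Mup)
  if (is.null(image_up)) {
    log_term <- numeric(prod(n3))
  } else {
    blurred <- .cpp_gaussian_blur(as.numeric(as_plain_array(image_up)), n3,
                                  params$log_sigma_mm / h)
    log_term <- .cpp_laplacian(blurred, n3, h)
    mx <- max(abs(log_term))
    if (mx > 0) log_term <- log_term / mx
  }
  Mnum <- as.numeric(as_plain_array(Mup))
  band <- params$band_halfwidth_mm %||% (6 * h)
  phi0 <- ifelse(as.logical(as_plain_array(init) > 0), -1, 1)
  res <- .cpp_levelset_evolve(phi0, log_term, Mnum, params$alpha, n3, h,
                              params$beta, params$dt_cfl, params$max_iters,
                              params$converge_tol, params$converge_window,
                              band, params$reinit_every)
  inside <- array(res$phi < 0, n3)
  if (!any(inside)) {
    abort(sprintf(paste0("surface collapsed to empty at iteration %d; ",
                         "reduce beta or revisit the forces."),
                  res$iterations),
          class = "dentamorph_collapse_error")
  }
  out <- binary_mask(inside, h, vol_origin(Mup), vol_axes(Mup))
  attr(out, "iterations") <- res$iterations
  attr(out, "volumes") <- res$volumes
  attr(out, "energies") <- res$energies
  attr(out, "converged") <- res$converged
  attr(out, "last_volume_mm3") <- sum(inside) * h^3
  out
}

#' Full sub-voxel refinement of a coarse probability map
#'
#' Composition of the fine-scale stages: crop the ROI around the foreground,
#' upsample the probability map and intensity image by the configured
#' factor, threshold the high-confidence region, and evolve the level-set
#' surface. The output mask lives on the fine grid with world coordinates
#' preserved.
#'
#' @param image Intensity [scalar_volume()] at native resolution (or `NULL`
#'   to refine without the edge force).
#' @param M [probability_map()] at native resolution on the same grid.
#' @param cfg A [dentamorph_config()].
#' @param crop_threshold,margin_mm ROI cropping controls.
#' @param evolve Optional [evolve_params()]; defaults are drawn from `cfg`.
#' @return Fine-scale [binary_mask()] (attributes as in [evolve_surface()]).
#' @export
fine_scale_segment <- function(image, M, cfg = dentamorph_config(),
                               crop_threshold = 0.2, margin_mm = 3,
                               evolve = NULL) {
  if (!is.null(image)) check_same_grid(M, image, "image and probability map")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)),
            class = class(e)[1])
    })
  }
  Mc <- stage("crop", crop_roi(M, crop_threshold, margin_mm))
  box <- attr(Mc, "roi_box")
  img_c <- if (is.null(image)) NULL else stage("crop", crop_to_box(image, box))
  Mup <- stage("upsample", upsample_probability(Mc, cfg$upsample_factor))
  img_up <- if (is.null(img_c)) NULL else
    stage("upsample", upsample_probability(img_c, cfg$upsample_factor))
  init <- stage("init", init_high_confidence(Mup, cfg$eta))
  pars <- evolve %||% evolve_params(alpha = cfg$alpha, beta = cfg$beta,
                                    log_sigma_mm = cfg$log_sigma_mm)
  stage("evolve", evolve_surface(Mup, img_up, init, pars))
}
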