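#' Specification of a simulated dentated shape
#'
#' Describes a cuboid body whose inferior face carries a sinusoidal
#' dentation pattern: the face is displaced by `A * sin(2*pi*F*x + phase)`
#' along the height axis, where `x` runs along the length (anterior -
#' posterior) axis. This is the synthetic ground truth used to validate the
#' dentation analysis: amplitude `A` (mm) is half the bump height and
#' frequency `F` (bumps per mm) the reciprocal of the bump width.
#'
#' @param amplitude_mm Non-negative dentation amplitude `A` in mm.
#' @param frequency_bpm Positive dentation frequency `F` in bumps per mm.
#' @param length_mm,width_mm,height_mm Cuboid body dimensions in mm. The
#'   default 40 x 20 x 10 mm body fits at least 4 bump periods at the lowest
#'   studied frequency (0.1 bump/mm).
#' @param phase_rad Phase of the sinusoidal displacement, radians.
#' @param voxel_mm Fine grid spacing in mm (default 0.2).
#' @return A `sim_shape_spec` list.
#' @export
sim_shape_spec <- function(amplitude_mm, frequency_bpm, length_mm = 40,
                           width_mm = 20, height_mm = 10, phase_rad = 0,
                           voxel_mm = 0.2) {
  if (amplitude_mm < 0) {
    abort("`amplitude_mm` must be non-negative.",
          class = "dentamorph_parameter_error")
  }
  if (frequency_bpm <= 0) {
    abort("`frequency_bpm` must be positive.",
          class = "dentamorph_parameter_error")
  }
  if (length_mm <= 0 || width_mm <= 0 || height_mm <= 0 || voxel_mm <= 0) {
    abort("cuboid dimensions and voxel size must be positive.",
          class = "dentamorph_parameter_error")
  }
  if (length_mm * frequency_bpm < 3) {
    abort(sprintf(paste0("length_mm * frequency_bpm = %.3g < 3: at least 3 ",
                         "full bump periods must fit along the shape."),
                  length_mm * frequency_bpm),
          class = "dentamorph_parameter_error")
  }
  if (2 * amplitude_mm >= height_mm) {
    abort("2 * amplitude_mm must be smaller than height_mm.",
          class = "dentamorph_parameter_error")
  }
  if (amplitude_mm > 0 && voxel_mm > amplitude_mm) {
    warn(sprintf(paste0("voxel_mm (%g) exceeds amplitude_mm (%g): bumps are ",
                        "sub-voxel and will be poorly resolved."),
                 voxel_mm, amplitude_mm))
  }
  structure(list(amplitude_mm = amplitude_mm, frequency_bpm = frequency_bpm,
                 length_mm = length_mm, width_mm = width_mm,
                 height_mm = height_mm, phase_rad = phase_rad,
                 voxel_mm = voxel_mm),
            class = "sim_shape_spec")
}

#' Voxelize a dentated cuboid at fine resolution
#'
#' Generates the binary ground-truth mask of a cuboid whose inferior face is
#' displaced by `A * sin(2*pi*F*x + phase)`; the superior face stays flat. A
#' voxel is foreground iff its centre lies inside the continuous shape. The
#' grid axes are labelled so the length axis is anterior-posterior and the
#' bump axis superior-inferior, and a 2-voxel background margin surrounds
#' the shape. Deterministic: no randomness is involved.
#'
#' @param spec A [sim_shape_spec()].
#' @param grid_offset_mm Length-3 sub-voxel translation of the voxel grid
#'   relative to the shape (mm); used by the study runner to decouple
#'   recovery statistics from the voxel lattice.
#' @param margin_vox Background margin in voxels around the shape.
#' @return A [binary_mask()] with axes `c("AP", "LR", "SI")`, carrying the
#'   generating `spec` as attribute `"sim_spec"`.
#' @export
simulate_dentated_cuboid <- function(spec, grid_offset_mm = c(0, 0, 0),
                                     margin_vox = 2L) {
  stopifnot(inherits(spec, "sim_shape_spec"))
  h <- spec$voxel_mm
  A <- spec$amplitude_mm
  m <- margin_vox * h
  # shape in world mm: x in [0, L], y in [0, W], z from A*sin(...) up to H
  lo <- c(-m, -m, -A - m) + grid_offset_mm
  hi <- c(spec$length_mm + m, spec$width_mm + m, spec$height_mm + m)
  nvox <- ceiling((hi - lo) / h) + 1L
  xs <- lo[1] + (seq_len(nvox[1]) - 1) * h
  ys <- lo[2] + (seq_len(nvox[2]) - 1) * h
  zs <- lo[3] + (seq_len(nvox[3]) - 1) * h
  zfloor <- A * sin(2 * pi * spec$frequency_bpm * xs + spec$phase_rad)
  inx <- xs >= 0 & xs <= spec$length_mm
  iny <- ys >= 0 & ys <= spec$width_mm
  # mask[i, j, k] = inx[i] & iny[j] & z_k >= zfloor[i] & z_k <= height
  zin <- outer(zfloor, zs, function(f, z) z >= f & z <= spec$height_mm)
  mask <- array(FALSE, nvox)
  xz <- zin & inx  # recycles inx down columns: (i, k)
  jy <- which(iny)
  for (j in jy) mask[, j, ] <- xz
  out <- binary_mask(mask, h, origin_mm = lo, axes = c("AP", "LR", "SI"))
  attr(out, "sim_spec") <- spec
  out
}

#' Degrade a fine mask into a coarse probability map
#'
#' Synthetic stand-in for the output of a coarse-resolution segmentation
#' model: the fine binary mask is box-averaged to the coarse spacing
#' (yielding partial-volume probabilities), Gaussian-blurred, optionally
#' perturbed with clipped Gaussian noise, and clipped to \[0, 1\].
#'
#' @param mask Fine-resolution [binary_mask()].
#' @param coarse_spacing_mm Target spacing, an (approximate) integer multiple
#'   of the mask spacing and not finer than it.
#' @param blur_sigma_mm Gaussian blur sigma in mm (0 disables).
#' @param noise_sd Standard deviation of additive Gaussian noise (0 disables).
#' @param seed Integer seed for the noise.
#' @return A [probability_map()] at the coarse spacing.
#' @export
degrade_to_probability_map <- function(mask, coarse_spacing_mm = 1,
                                       blur_sigma_mm = 0.5, noise_sd = 0.05,
                                       seed = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  hf <- vol_spacing(mask)
  if (coarse_spacing_mm < hf - 1e-9) {
    abort("`coarse_spacing_mm` must not be finer than the mask spacing.",
          class = "dentamorph_parameter_error")
  }
  k <- round(coarse_spacing_mm / hf)
  if (abs(coarse_spacing_mm / hf - k) > 1e-6) {
    abort("`coarse_spacing_mm` must be an integer multiple of the mask spacing.",
          class = "dentamorph_parameter_error")
  }
  arr <- as_plain_array(mask)
  if (k > 1L) {
    # zero-pad at the high end so dims divide by k
    pad <- (k - dim(arr) %% k) %% k
    if (any(pad > 0)) {
      padded <- array(0, dim(arr) + pad)
      padded[seq_len(dim(arr)[1]), seq_len(dim(arr)[2]),
             seq_len(dim(arr)[3])] <- arr
      arr <- padded
    }
    coarse <- array(.cpp_box_average(as.numeric(arr), dim(arr), as.integer(k)),
                    dim = dim(arr) %/% k)
  } else {
    coarse <- arr
  }
  hc <- hf * k
  origin <- vol_origin(mask) + (k - 1) / 2 * hf
  if (blur_sigma_mm > 0) {
    coarse <- array(.cpp_gaussian_blur(as.numeric(coarse), dim(coarse),
                                       blur_sigma_mm / hc), dim = dim(coarse))
  }
  if (noise_sd > 0) {
    noise <- withr::with_seed(as.integer(seed), {
      rnorm(length(coarse), sd = noise_sd)
    })
    noise <- pmin(pmax(noise, -3 * noise_sd), 3 * noise_sd)
    coarse <- coarse + array(noise, dim(coarse))
  }
  coarse <- pmin(pmax(coarse, 0), 1)
  probability_map(coarse, hc, origin, vol_axes(mask))
}

#' Synthetic grayscale companion image for a mask
#'
#' Builds the intensity image whose Laplacian-of-Gaussian supplies the edge
#' force during surface refinement: piecewise-constant (foreground
#' `fg_mean`, background `bg_mean`), smoothed by a small point-spread
#' function so the intensity gradient is maximal at the true surface, plus
#' optional Gaussian noise. Optionally box-averaged down to a coarser
#' acquisition spacing.
#'
#' @param mask [binary_mask()] defining the object.
#' @param fg_mean,bg_mean Foreground/background intensities (must differ).
#' @param noise_sd Additive Gaussian noise SD (0 disables).
#' @param psf_sigma_mm Point-spread sigma in mm.
#' @param out_spacing_mm Optional coarser output spacing (integer multiple of
#'   the mask spacing); mimics acquisition at native resolution.
#' @param seed Integer seed for the noise.
#' @return A [scalar_volume()].
#' @export
companion_intensity_image <- function(mask, fg_mean = 120, bg_mean = 40,
                                      noise_sd = 0, psf_sigma_mm = 0.3,
                                      out_spacing_mm = NULL, seed = 1L) {
  stopifnot(inherits(mask, "binary_mask"))
  if (fg_mean == bg_mean) {
    abort("`fg_mean` and `bg_mean` must differ.",
          class = "dentamorph_parameter_error")
  }
  hf <- vol_spacing(mask)
  arr <- bg_mean + (fg_mean - bg_mean) * as_plain_array(mask)
  if (psf_sigma_mm > 0) {
    arr <- array(.cpp_gaussian_blur(as.numeric(arr), dim(arr),
                                    psf_sigma_mm / hf), dim = dim(arr))
  }
  origin <- vol_origin(mask)
  spacing <- hf
  if (!is.null(out_spacing_mm) && out_spacing_mm > hf + 1e-9) {
    k <- round(out_spacing_mm / hf)
    if (abs(out_spacing_mm / hf - k) > 1e-6) {
      abort("`out_spacing_mm` must be an integer multiple of the mask spacing.",
            class = "dentamorph_parameter_error")
    }
    pad <- (k - dim(arr) %% k) %% k
    if (any(pad > 0)) {
      padded <- array(bg_mean, dim(arr) + pad)
      padded[seq_len(dim(arr)[1]), seq_len(dim(arr)[2]),
             seq_len(dim(arr)[3])] <- arr
      arr <- padded
    }
    arr <- array(.cpp_box_average(as.numeric(arr), dim(arr), as.integer(k)),
                 dim = dim(arr) %/% k)
    origin <- origin + (k - 1) / 2 * hf
    spacing <- hf * k
  }
  if (noise_sd > 0) {
    noise <- withr::with_seed(as.integer(seed),
                              rnorm(length(arr), sd = noise_sd))
    arr <- arr + array(noise, dim(arr))
  }
  scalar_volume(arr, spacing, origin, vol_axes(mask))
}

#' Analytic inferior face of a simulated shape
#'
#' Returns the continuous inferior envelope `z(x) = A*sin(2*pi*F*x + phase)`
#' of a [sim_shape_spec()] at given positions; the reference against which
#' extracted silhouettes are validated.
#'
#' @param spec A [sim_shape_spec()].
#' @param x_mm Positions along the length axis, mm.
#' @return Numeric vector of face heights (mm, superior-positive).
#' @export
analytic_inferior_face <- function(spec, x_mm) {
  spec$amplitude_mm * sin(2 * pi * spec$frequency_bpm * x_mm + spec$phase_rad)
}
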