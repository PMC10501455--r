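#' Scalar volumes, probability maps and binary masks
#'
#' A `scalar_volume` is a 3D numeric array with an isotropic voxel spacing
#' (mm), a world-space origin (the mm coordinate of voxel `[1,1,1]`'s centre)
#' and anatomical axis labels. World coordinates follow the RAS-style
#' convention: along the axis labelled `"LR"` the index increases toward the
#' right, along `"AP"` toward anterior and along `"SI"` toward superior, so
#' the inferior anatomical direction is the negative of the `"SI"` axis. All
#' geometry in the package is carried out in world millimetres,
#' `world = origin + (index - 1) * spacing`.
#'
#' `probability_map()` and `binary_mask()` are constrained sub-classes with
#' values in \[0, 1\] and \{0, 1\} respectively.
#'
#' @param data 3D numeric array (a `binary_mask` also accepts logical).
#' @param spacing_mm Positive isotropic voxel spacing in mm.
#' @param origin_mm Numeric length-3 world coordinate of the first voxel
#'   centre, in mm.
#' @param axes Character permutation of `c("LR", "AP", "SI")` naming the
#'   anatomical direction of each grid axis.
#' @return An object of class `scalar_volume` (and possibly
#'   `probability_map` or `binary_mask`).
#' @examples
#' v <- scalar_volume(array(0, c(4, 4, 4)), spacing_mm = 1)
#' vol_dim(v)
#' @export
scalar_volume <- function(data, spacing_mm, origin_mm = c(0, 0, 0),
                          axes = c("AP", "LR", "SI")) {
  if (is.logical(data)) {
    storage.mode(data) <- "double"
  }
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.", class = "dentamorph_format_error")
  }
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L ||
      !is.finite(spacing_mm) || spacing_mm <= 0) {
    abort("`spacing_mm` must be a single positive number.",
          class = "dentamorph_parameter_error")
  }
  if (length(origin_mm) != 3L || !all(is.finite(origin_mm))) {
    abort("`origin_mm` must be a finite length-3 vector.",
          class = "dentamorph_parameter_error")
  }
  if (!setequal(axes, c("LR", "AP", "SI")) || length(axes) != 3L) {
    abort("`axes` must be a permutation of c(\"LR\", \"AP\", \"SI\").",
          class = "dentamorph_parameter_error")
  }
  if (anyNA(data) || !all(is.finite(data))) {
    abort("volume data must be finite everywhere.",
          class = "dentamorph_format_error")
  }
  structure(data,
            spacing_mm = as.numeric(spacing_mm),
            origin_mm = as.numeric(origin_mm),
            axes = as.character(axes),
            class = c("scalar_volume", "array"))
}

#' @rdname scalar_volume
#' @export
probability_map <- function(data, spacing_mm, origin_mm = c(0, 0, 0),
                            axes = c("AP", "LR", "SI")) {
  v <- scalar_volume(data, spacing_mm, origin_mm, axes)
  rng <- range(v)
  if (rng[1] < 0 || rng[2] > 1) {
    abort("probability map values must lie in [0, 1].",
          class = "dentamorph_format_error")
  }
  class(v) <- c("probability_map", class(v))
  v
}

#' @rdname scalar_volume
#' @export
binary_mask <- function(data, spacing_mm, origin_mm = c(0, 0, 0),
                        axes = c("AP", "LR", "SI")) {
  v <- scalar_volume(data, spacing_mm, origin_mm, axes)
  if (!all(v == 0 | v == 1)) {
    abort("binary mask values must be exactly 0 or 1.",
          class = "dentamorph_format_error")
  }
  class(v) <- c("binary_mask", "probability_map", class(v))
  v
}

#' @export
print.scalar_volume <- function(x, ...) {
  kind <- class(x)[1]
  cat(sprintf("<%s> %s voxels, spacing %.4g mm, axes [%s]\n",
              kind, paste(dim(x), collapse = " x "),
              attr(x, "spacing_mm"), paste(attr(x, "axes"), collapse = ", ")))
  cat(sprintf("  origin (mm): %s   value range: [%.4g, %.4g]\n",
              paste(sprintf("%.3g", attr(x, "origin_mm")), collapse = ", "),
              min(x), max(x)))
  invisible(x)
}

#' Volume geometry accessors
#'
#' @param vol A [scalar_volume()].
#' @return `vol_spacing()`, `vol_origin()`, `vol_axes()` and `vol_dim()`
#'   return the corresponding geometry attributes; `voxel_centers()` the
#'   world-mm coordinates of the voxel centres along one grid axis;
#'   `anatomical_direction()` a world-space unit vector.
#' @export
vol_spacing <- function(vol) attr(vol, "spacing_mm")

#' @rdname vol_spacing
#' @export
vol_origin <- function(vol) attr(vol, "origin_mm")

#' @rdname vol_spacing
#' @export
vol_axes <- function(vol) attr(vol, "axes")

#' @rdname vol_spacing
#' @export
vol_dim <- function(vol) dim(vol)

#' @rdname vol_spacing
#' @param axis Grid axis index (1-3).
#' @export
voxel_centers <- function(vol, axis) {
  vol_origin(vol)[axis] + (seq_len(dim(vol)[axis]) - 1) * vol_spacing(vol)
}

#' @rdname vol_spacing
#' @param label One of `"LR"`, `"AP"`, `"SI"`, `"inferior"`, `"anterior"`.
#'   `"inferior"` is the negative of the `"SI"` grid axis, `"anterior"` the
#'   positive `"AP"` axis.
#' @export
anatomical_direction <- function(vol, label) {
  axes <- vol_axes(vol)
  flip <- 1
  if (label == "inferior") {
    label <- "SI"
    flip <- -1
  } else if (label == "anterior") {
    label <- "AP"
  }
  ax <- match(label, axes)
  if (is.na(ax)) {
    abort(sprintf("volume has no axis labelled '%s'.", label),
          class = "dentamorph_parameter_error")
  }
  v <- c(0, 0, 0)
  v[ax] <- flip
  v
}

# strip volume classes/attrs down to a plain array
as_plain_array <- function(vol) {
  a <- unclass(vol)
  attributes(a) <- list(dim = dim(vol))
  a
}

# rebuild a volume like `template` but with new data (same geometry)
vol_like <- function(data, template, kind = c("scalar", "probability",
                                              "binary")) {
  kind <- match.arg(kind)
  f <- switch(kind, scalar = scalar_volume, probability = probability_map,
              binary = binary_mask)
  f(data, vol_spacing(template), vol_origin(template), vol_axes(template))
}

#' Resample a volume onto the grid of a reference volume
#'
#' Nearest-neighbour (masks) or cubic (intensities) resampling in world
#' coordinates, used to compare volumes defined on different grids.
#'
#' @param vol Volume to resample.
#' @param ref Reference volume supplying the target grid.
#' @param mode `"nearest"` or `"cubic"`.
#' @param outside Fill value for target voxels outside `vol`'s grid.
#' @return A volume on `ref`'s grid carrying `vol`'s values.
#' @export
resample_to_grid <- function(vol, ref, mode = c("nearest", "cubic"),
                             outside = 0) {
  mode <- match.arg(mode)
  if (!identical(vol_axes(vol), vol_axes(ref))) {
    abort("volumes must share axis labels to be resampled onto each other.",
          class = "dentamorph_geometry_error")
  }
  arr <- as_plain_array(vol)
  d <- dim(arr)
  out <- arr
  # per-axis mapping: target index j -> source index position
  for (ax in 1:3) {
    src_n <- dim(out)[ax]
    # source index position (1-based fractional) of each ref node
    pos <- (voxel_centers(ref, ax) - vol_origin(vol)[ax]) / vol_spacing(vol)
    new_n <- length(pos)
    scale <- if (new_n > 1) (pos[new_n] - pos[1]) / (new_n - 1) else 0
    out <- array(.cpp_resample_axis(as.numeric(out), dim(out), ax - 1L,
                                    as.integer(new_n), scale, pos[1],
                                    if (mode == "nearest") 1L else 0L),
                 dim = replace(dim(out), ax, new_n))
  }
  # mask out-of-extent voxels
  for (ax in 1:3) {
    pos <- (voxel_centers(ref, ax) - vol_origin(vol)[ax]) / vol_spacing(vol)
    bad <- pos < -0.5 | pos > d[ax] - 0.5
    if (any(bad)) {
      idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
      idx[[ax]] <- which(bad)
      out <- do.call(`[<-`, c(list(out), idx, list(value = outside)))
    }
  }
  kind <- if (inherits(vol, "binary_mask")) "binary"
          else if (inherits(vol, "probability_map")) "probability"
          else "scalar"
  if (kind == "probability") out <- pmin(pmax(out, 0), 1)
  vol_like(out, ref, kind)
}

#' Threshold a volume into a binary mask
#'
#' @param vol A [scalar_volume()] or [probability_map()].
#' @param level Threshold; voxels strictly above it become foreground.
#' @return A [binary_mask()] on the same grid.
#' @export
threshold_mask <- function(vol, level = 0.5) {
  binary_mask(as_plain_array(vol) > level, vol_spacing(vol), vol_origin(vol),
              vol_axes(vol))
}

# check two volumes share grid geometry
check_same_grid <- function(a, b, what = "volumes") {
  ok <- identical(dim(a), dim(b)) &&
    isTRUE(all.equal(vol_spacing(a), vol_spacing(b))) &&
    isTRUE(all.equal(vol_origin(a), vol_origin(b), tolerance = 1e-8))
  if (!ok) {
    abort(sprintf("%s are defined on different grids.", what),
          class = "dentamorph_geometry_error")
  }
  invisible(TRUE)
}
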