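#' Read a 3D volume from a NIfTI-1 file
#'
#' Reads a `.nii`/`.nii.gz` file into a [scalar_volume()]. The image is
#' reoriented in memory to the RAS convention (indices increase toward
#' right / anterior / superior) so axis labels are always
#' `c("LR", "AP", "SI")` in grid order. Anisotropic images are resampled to
#' isotropic spacing equal to the smallest header spacing (cubic for
#' intensities, nearest-neighbour when `kind = "mask"`); the resampling is
#' reported via a message.
#'
#' @param path Path to a NIfTI-1 file.
#' @param kind `"scalar"`, `"probability"` or `"mask"`; controls validation
#'   and the interpolation used if isotropic resampling is needed.
#' @param axes Optional explicit axis labels overriding the header
#'   orientation (needed for synthetic volumes without anatomical headers).
#' @return A [scalar_volume()] (or subclass per `kind`).
#' @export
read_volume <- function(path, kind = c("scalar", "probability", "mask"),
                        axes = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "dentamorph_io_error")
  }
  img <- tryCatch(RNifti::readNifti(path, internal = FALSE),
                  error = function(e) {
                    abort(sprintf("cannot read NIfTI file %s: %s", path,
                                  conditionMessage(e)),
                          class = "dentamorph_io_error")
                  })
  if (length(dim(img)) != 3L) {
    abort(sprintf("expected a 3D scalar image, got %dD.", length(dim(img))),
          class = "dentamorph_format_error")
  }
  ornt <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (is.null(axes)) {
    if (is.na(ornt) || !nzchar(ornt)) {
      abort(paste0("cannot determine anatomical orientation from the header ",
                   "of ", path, "; pass `axes` explicitly."),
            class = "dentamorph_format_error")
    }
    RNifti::orientation(img) <- "RAS"
    axes <- c("LR", "AP", "SI")
  }
  spac <- RNifti::pixdim(img)[1:3]
  origin <- as.numeric(RNifti::voxelToWorld(c(1, 1, 1), img))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))

  target <- min(spac)
  if (max(abs(spac - target)) > 1e-6) {
    dm_inform(sprintf(
      "read_volume: anisotropic spacing (%s) mm resampled to isotropic %g mm.",
      paste(sprintf("%g", spac), collapse = ", "), target))
    mode <- if (kind == "mask") 1L else 0L
    for (ax in 1:3) {
      if (abs(spac[ax] - target) <= 1e-12) next
      extent <- (dim(arr)[ax] - 1) * spac[ax]
      new_n <- as.integer(floor(extent / target)) + 1L
      scale <- target / spac[ax]
      arr <- array(.cpp_resample_axis(as.numeric(arr), dim(arr), ax - 1L,
                                      new_n, scale, 0, mode),
                   dim = replace(dim(arr), ax, new_n))
    }
    spac <- rep(target, 3)
  }
  switch(kind,
         scalar = scalar_volume(arr, target, origin, axes),
         probability = probability_map(pmin(pmax(arr, 0), 1), target, origin,
                                       axes),
         mask = binary_mask(round(arr) != 0, target, origin, axes))
}

#' Write a volume to a NIfTI-1 file
#'
#' Spacing, origin and RAS orientation are stored in the qform/sform so that
#' `read_volume(write_volume(v))` reproduces `v` exactly for binary masks and
#' to better than 1e-6 for real-valued volumes.
#'
#' @param vol A [scalar_volume()].
#' @param path Output `.nii` or `.nii.gz` path; the parent directory must
#'   exist and be writable.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0) {
    abort(sprintf("cannot write to directory: %s", dir),
          class = "dentamorph_io_error")
  }
  s <- vol_spacing(vol)
  # data axes are stored as-is; the affine encodes world placement. Axis
  # labels other than the RAS default are recorded by permuting the affine
  # columns so LR/AP/SI land on world x/y/z.
  perm <- match(c("LR", "AP", "SI"), vol_axes(vol))
  rot <- matrix(0, 3, 3)
  for (w in 1:3) rot[w, perm[w]] <- s
  origin_world <- numeric(3)
  origin_world[1:3] <- vol_origin(vol)[perm]
  affine <- rbind(cbind(rot, origin_world), c(0, 0, 0, 1))
  h <- RNifti::niftiHeader(list(pixdim = c(-1, rep(s, 3), 0, 0, 0, 0)))
  dt <- if (inherits(vol, "binary_mask")) "uint8" else "double"
  arr <- as_plain_array(vol)
  img <- RNifti::asNifti(arr, reference = h, datatype = dt)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
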