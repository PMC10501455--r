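#' Voxel-overlap segmentation scores
#'
#' True/false positives and negatives are counted voxel-wise on identical
#' grids and combined into `Recall = TP/(TP+FN)`, `Precision = TP/(TP+FP)`,
#' `DSC = 2TP/(2TP+FP+FN)` and `Jaccard = TP/(TP+FP+FN)`. Two empty masks
#' score DSC = 1 by convention (reported via a message).
#'
#' @param pred,truth [binary_mask()]s on the same grid.
#' @return One-row tibble with `dsc`, `jaccard`, `recall`, `precision`.
#' @export
overlap_metrics <- function(pred, truth) {
  check_same_grid(pred, truth, "pred and truth masks")
  p <- as_plain_array(pred) > 0
  t <- as_plain_array(truth) > 0
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  if (tp + fp + fn == 0) {
    dm_inform("overlap_metrics: both masks empty; DSC defined as 1.")
    return(tibble(dsc = 1, jaccard = 1, recall = 1, precision = 1))
  }
  tibble(dsc = 2 * tp / (2 * tp + fp + fn),
         jaccard = tp / (tp + fp + fn),
         recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

# directed boundary distances (mm) from each boundary voxel of `a` to the
# nearest boundary voxel of `b`, via an exact Euclidean distance transform
directed_boundary_distances <- function(a, b, dims, spacing) {
  d2 <- .cpp_edt_sq(as.logical(b), dims)
  sqrt(d2[as.logical(a)]) * spacing
}

#' Hausdorff boundary distances
#'
#' Boundary voxels are foreground voxels with at least one face-adjacent
#' background neighbour (6-connectivity). Directed distances are
#' spacing-aware nearest-neighbour distances between boundary voxel
#' centres; `HD` is the max of the two directed maxima, and `HD95` the max
#' of the two directed 95th percentiles (linear interpolation between order
#' statistics).
#'
#' @param pred,truth Non-empty [binary_mask()]s with identical spacing and
#'   grids.
#' @return One-row tibble with `hd_mm` and `hd95_mm`.
#' @export
hausdorff_metrics <- function(pred, truth) {
  check_same_grid(pred, truth, "pred and truth masks")
  p <- as_plain_array(pred) > 0
  t <- as_plain_array(truth) > 0
  if (!any(p) || !any(t)) {
    abort("Hausdorff distance undefined for an empty mask.",
          class = "dentamorph_parameter_error")
  }
  h <- vol_spacing(pred)
  bp <- .cpp_boundary6(as.logical(p), dim(pred))
  bt <- .cpp_boundary6(as.logical(t), dim(truth))
  d_pt <- directed_boundary_distances(bp, bt, dim(pred), h)
  d_tp <- directed_boundary_distances(bt, bp, dim(pred), h)
  tibble(hd_mm = max(max(d_pt), max(d_tp)),
         hd95_mm = max(quantile(d_pt, 0.95, names = FALSE),
                       quantile(d_tp, 0.95, names = FALSE)))
}

#' All segmentation scores at once
#'
#' @inheritParams hausdorff_metrics
#' @return One-row tibble combining [overlap_metrics()] and
#'   [hausdorff_metrics()].
#' @export
evaluate_segmentation <- function(pred, truth) {
  dplyr::bind_cols(overlap_metrics(pred, truth),
                   hausdorff_metrics(pred, truth))
}

#' Characteristic sagittal slice
#'
#' The slice perpendicular to the left-right axis with the largest
#' foreground area: the view in which the dentation profile of an elongated
#' structure is most visible.
#'
#' @param mask A [binary_mask()].
#' @param axis_label Anatomical label of the slicing axis.
#' @return Integer slice index along that grid axis.
#' @export
characteristic_slice <- function(mask, axis_label = "LR") {
  ax <- match(axis_label, vol_axes(mask))
  if (is.na(ax)) {
    abort(sprintf("mask has no '%s' axis.", axis_label),
          class = "dentamorph_parameter_error")
  }
  areas <- apply(as_plain_array(mask) > 0, ax, sum)
  idx <- which.max(areas)
  dm_inform(sprintf(
    "characteristic_slice: axis %s slice %d (area %d voxels).",
    axis_label, idx, areas[idx]))
  idx
}

extract_slice <- function(mask, ax, idx) {
  arr <- as_plain_array(mask) > 0
  if (idx < 1 || idx > dim(arr)[ax]) {
    abort(sprintf("slice index %d out of range on axis %d.", idx, ax),
          class = "dentamorph_parameter_error")
  }
  sl <- switch(ax, arr[idx, , ], arr[, idx, ], arr[, , idx])
  matrix(sl, nrow = dim(arr)[setdiff(1:3, ax)][1])
}

boundary_2d <- function(sl) {
  n1 <- nrow(sl)
  n2 <- ncol(sl)
  pad <- matrix(FALSE, n1 + 2, n2 + 2)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- sl
  inner <- pad[2:(n1 + 1), 2:(n2 + 1)]
  nb <- pad[1:n1, 2:(n2 + 1)] & pad[3:(n1 + 2), 2:(n2 + 1)] &
        pad[2:(n1 + 1), 1:n2] & pad[2:(n1 + 1), 3:(n2 + 2)]
  which(inner & !nb, arr.ind = TRUE)
}

#' Slice-wise 2D Hausdorff distance
#'
#' Extracts one slice from both masks, computes the 2D boundary contours
#' (4-connectivity) and returns the full two-sided Hausdorff distance in mm
#' between the contour point sets. When `slice_index` is `NULL` the
#' characteristic sagittal slice of `truth` is used.
#'
#' @param pred,truth [binary_mask()]s with identical spacing and grids.
#' @param axis_label Anatomical label of the slicing axis.
#' @param slice_index Slice to compare (default: [characteristic_slice()]
#'   of `truth`).
#' @return 2D Hausdorff distance in mm.
#' @export
hausdorff_2d <- function(pred, truth, axis_label = "LR", slice_index = NULL) {
  check_same_grid(pred, truth, "pred and truth masks")
  ax <- match(axis_label, vol_axes(truth))
  if (is.na(ax)) {
    abort(sprintf("mask has no '%s' axis.", axis_label),
          class = "dentamorph_parameter_error")
  }
  idx <- slice_index %||% characteristic_slice(truth, axis_label)
  sp <- extract_slice(pred, ax, idx)
  st <- extract_slice(truth, ax, idx)
  if (!any(sp) || !any(st)) {
    abort(sprintf("slice %d is empty in one of the masks.", idx),
          class = "dentamorph_parameter_error")
  }
  h <- vol_spacing(pred)
  cp <- boundary_2d(sp) * h
  ct <- boundary_2d(st) * h
  # pairwise squared distances (contours are small point sets)
  d2 <- outer(cp[, 1], ct[, 1], "-")^2 + outer(cp[, 2], ct[, 2], "-")^2
  max(max(sqrt(apply(d2, 1, min))), max(sqrt(apply(d2, 2, min))))
}
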