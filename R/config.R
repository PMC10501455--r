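#' Pipeline configuration
#'
#' Bundles every tunable parameter of the refinement + dentation pipeline.
#' Defaults (documented in the README table) are: 5x upsampling to 0.2 mm
#' from a 1 mm native grid, high-confidence threshold `eta = 0.5`, regional
#' force weight `alpha = 0.3`, curvature weight `beta = 0.1`, LoG scale
#' `log_sigma_mm = 0.5`, 200,000 interior sample points, silhouette bin
#' width equal to the fine voxel size and 10% trimming per end. The point
#' count is chosen so the expected gap between the deepest sample in a bin
#' and the true surface (column height x number of bins / n) stays well
#' below the fine voxel size; sparser clouds leave envelope noise
#' comparable to the shallowest dentations.
#'
#' @param upsample_factor Positive integer upsampling factor `H`.
#' @param eta High-confidence probability threshold in \[0, 1\].
#' @param alpha Non-negative regional (probability) force weight.
#' @param beta Non-negative mean-curvature force weight.
#' @param log_sigma_mm Positive Laplacian-of-Gaussian scale in mm (at the
#'   fine spacing).
#' @param sa_schedule Simulated-annealing schedule, see [sa_schedule()].
#' @param n_points Number of interior points sampled for the PCA projection.
#' @param bin_width_mm Silhouette bin width in mm.
#' @param trim_fraction Fraction of the silhouette x-range trimmed from each
#'   end, in \[0, 0.5).
#' @param seed Integer seed governing all stochastic steps.
#' @return A `dentamorph_config` list.
#' @export
dentamorph_config <- function(upsample_factor = 5L,
                              eta = 0.5,
                              alpha = 0.3,
                              beta = 0.1,
                              log_sigma_mm = 0.5,
                              sa_schedule = NULL,
                              n_points = 200000L,
                              bin_width_mm = 0.2,
                              trim_fraction = 0.1,
                              seed = 1L) {
  if (is.null(sa_schedule)) sa_schedule <- dentamorph::sa_schedule()
  stopifnot(upsample_factor >= 1, upsample_factor == round(upsample_factor))
  if (eta < 0 || eta > 1) {
    abort("`eta` must lie in [0, 1].", class = "dentamorph_parameter_error")
  }
  if (alpha < 0 || beta < 0) {
    abort("`alpha` and `beta` must be non-negative.",
          class = "dentamorph_parameter_error")
  }
  if (log_sigma_mm <= 0) {
    abort("`log_sigma_mm` must be positive.",
          class = "dentamorph_parameter_error")
  }
  if (n_points < 1) {
    abort("`n_points` must be positive.",
          class = "dentamorph_parameter_error")
  }
  if (bin_width_mm <= 0) {
    abort("`bin_width_mm` must be positive.",
          class = "dentamorph_parameter_error")
  }
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    abort("`trim_fraction` must lie in [0, 0.5).",
          class = "dentamorph_parameter_error")
  }
  structure(list(upsample_factor = as.integer(upsample_factor),
                 eta = eta, alpha = alpha, beta = beta,
                 log_sigma_mm = log_sigma_mm,
                 sa_schedule = sa_schedule,
                 n_points = as.integer(n_points),
                 bin_width_mm = bin_width_mm,
                 trim_fraction = trim_fraction,
                 seed = as.integer(seed)),
            class = "dentamorph_config")
}

#' @rdname dentamorph_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "dentamorph_io_error")
  }
  raw <- yaml::read_yaml(path)
  sched <- do.call(sa_schedule, raw$sa_schedule %||% list())
  raw$sa_schedule <- sched
  do.call(dentamorph_config, raw)
}

#' @rdname dentamorph_config
#' @param config A `dentamorph_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$sa_schedule <- unclass(x$sa_schedule)
  yaml::write_yaml(x, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dentamorph_config <- function(x, ...) {
  cat("<dentamorph_config>\n")
  cat(sprintf("  upsample_factor: %d  eta: %g  alpha: %g  beta: %g\n",
              x$upsample_factor, x$eta, x$alpha, x$beta))
  cat(sprintf("  log_sigma_mm: %g  n_points: %d  bin_width_mm: %g  trim: %g\n",
              x$log_sigma_mm, x$n_points, x$bin_width_mm, x$trim_fraction))
  cat(sprintf("  seed: %d  SA: T0=%g cool=%g iters=%d Tmin=%g restarts=%d\n",
              x$seed, x$sa_schedule$T0, x$sa_schedule$cooling,
              x$sa_schedule$iters_per_temp, x$sa_schedule$T_min,
              x$sa_schedule$restarts))
  invisible(x)
}
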