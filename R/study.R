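#' Dentation recovery study on simulated shapes
#'
#' Runs the simulation-based validation: for every combination of true
#' amplitude and frequency, dentated cuboids are generated with randomized
#' phase and sub-voxel grid offset per replicate, the dentation analysis is
#' applied, and the fitted amplitude/frequency are compared against the
#' ground truth. Three modes:
#' * `"silhouette"` - analyse the fine-resolution ground-truth mask
#'   directly (validates the shape-analysis chain in isolation);
#' * `"full"` - degrade the mask to a coarse probability map and companion
#'   intensity image, refine back to fine scale with the level set, then
#'   analyse (validates the whole pipeline);
#' * `"analytic"` - sample the continuous sinusoid directly, bypassing
#'   voxelization (noiseless identifiability check).
#'
#' @param amplitudes True amplitudes in mm.
#' @param frequencies True frequencies in bumps/mm.
#' @param replicates Replicates per (A, F) cell.
#' @param mode `"silhouette"`, `"full"` or `"analytic"`.
#' @param seed Master seed; every replicate derives its own sub-seed.
#' @param cfg A [dentamorph_config()].
#' @param shape Base shape parameters as a named list
#'   (`length_mm`, `width_mm`, `height_mm`, `voxel_mm`).
#' @param coarse_spacing_mm,blur_sigma_mm,noise_sd Degradation settings for
#'   `"full"` mode.
#' @return A `recovery_table`: list with `records` (one row per replicate),
#'   `cells` (per-cell mean fitted values), `margins_A` / `margins_F`
#'   (marginal MAEs recomputed from the cell means) and `summary` (global
#'   relative-error figures).
#' @export
run_recovery_study <- function(amplitudes = c(0.1, 0.2, 0.3, 0.4),
                               frequencies = c(0.1, 0.125, 0.2, 0.25),
                               replicates = 5L,
                               mode = c("silhouette", "full", "analytic"),
                               seed = 1L,
                               cfg = dentamorph_config(),
                               shape = list(length_mm = 40, width_mm = 20,
                                            height_mm = 10, voxel_mm = 0.2),
                               coarse_spacing_mm = 1, blur_sigma_mm = 0.5,
                               noise_sd = 0.05) {
  mode <- match.arg(mode)
  if (length(amplitudes) == 0 || length(frequencies) == 0 || replicates < 1) {
    abort("need non-empty parameter lists and replicates >= 1.",
          class = "dentamorph_parameter_error")
  }
  grid <- tidyr::expand_grid(true_A = amplitudes, true_F = frequencies,
                             rep = seq_len(replicates))
  seeds <- derive_seeds(seed, nrow(grid))
  records <- purrr::pmap(list(grid$true_A, grid$true_F, grid$rep, seeds),
    function(A, F, rep, rseed) {
      tryCatch({
        fit <- recover_one(A, F, rseed, mode, cfg, shape,
                           coarse_spacing_mm, blur_sigma_mm, noise_sd)
        tibble(true_A = A, true_F = F, rep = rep, seed = rseed,
               A_hat = fit$A_mm, f_hat = fit$f_bpm, phi_hat = fit$phi_rad,
               b_hat = fit$b_mm, cost = fit$cost_J,
               converged = fit$converged, error = NA_character_)
      }, error = function(e) {
        tibble(true_A = A, true_F = F, rep = rep, seed = rseed,
               A_hat = NA_real_, f_hat = NA_real_, phi_hat = NA_real_,
               b_hat = NA_real_, cost = NA_real_, converged = "error",
               error = conditionMessage(e))
      })
    }) %>% bind_rows()
  if (all(!is.na(records$error))) {
    abort("every replicate of the recovery study failed.",
          class = "dentamorph_study_error")
  }
  build_recovery_table(records, mode = mode, seed = seed)
}

# one replicate of the recovery study; phase and grid offset drawn from the
# replicate seed
recover_one <- function(A, F, rseed, mode, cfg, shape, coarse_spacing_mm,
                        blur_sigma_mm, noise_sd) {
  draws <- withr::with_seed(as.integer(rseed), {
    list(phase = runif(1, 0, 2 * pi), offset = runif(3, 0, shape$voxel_mm))
  })
  if (mode == "analytic") {
    x <- seq(shape$length_mm * cfg$trim_fraction,
             shape$length_mm * (1 - cfg$trim_fraction),
             by = cfg$bin_width_mm)
    sil <- tibble(x_mm = x,
                  y_mm = A * sin(2 * pi * F * x + draws$phase),
                  n_in_bin = 1L)
    class(sil) <- c("silhouette", class(sil))
    return(fit_sinusoid_sa(sil, schedule = cfg$sa_schedule, seed = rseed))
  }
  spec <- sim_shape_spec(amplitude_mm = A, frequency_bpm = F,
                         length_mm = shape$length_mm,
                         width_mm = shape$width_mm,
                         height_mm = shape$height_mm,
                         phase_rad = draws$phase, voxel_mm = shape$voxel_mm)
  truth <- simulate_dentated_cuboid(spec, grid_offset_mm = draws$offset)
  mask <- truth
  if (mode == "full") {
    prob <- degrade_to_probability_map(truth, coarse_spacing_mm,
                                       blur_sigma_mm, noise_sd, seed = rseed)
    img <- companion_intensity_image(truth, noise_sd = noise_sd * 80,
                                     out_spacing_mm = coarse_spacing_mm,
                                     seed = rseed + 1L)
    img <- resample_to_grid(img, prob, mode = "nearest", outside = 40)
    mask <- fine_scale_segment(img, prob, cfg)
  }
  sil <- extract_silhouette(mask, cfg, seed = rseed)
  fit_sinusoid_sa(sil, schedule = cfg$sa_schedule, seed = rseed)
}

build_recovery_table <- function(records, mode, seed) {
  ok <- records %>% filter(is.na(.data$error))
  cells <- ok %>%
    group_by(.data$true_A, .data$true_F) %>%
    summarise(mean_A_hat = mean(.data$A_hat), mean_f_hat = mean(.data$f_hat),
              n_reps = dplyr::n(), .groups = "drop")
  margins_A <- cells %>%
    group_by(.data$true_A) %>%
    summarise(mae_A = mean(abs(.data$mean_A_hat - .data$true_A)),
              .groups = "drop")
  margins_F <- cells %>%
    group_by(.data$true_F) %>%
    summarise(mae_F = mean(abs(.data$mean_f_hat - .data$true_F)),
              .groups = "drop")
  summary <- tibble(
    mode = mode,
    n_fits = nrow(ok),
    n_failed = sum(!is.na(records$error)),
    rel_f_err_pct = 100 * mean(abs(ok$f_hat - ok$true_F) / ok$true_F),
    rel_A_err_pct = 100 * mean(abs(ok$A_hat - ok$true_A) / ok$true_A),
    max_mae_A = max(margins_A$mae_A),
    max_mae_F = max(margins_F$mae_F))
  structure(list(records = records, cells = cells, margins_A = margins_A,
                 margins_F = margins_F, summary = summary, seed = seed),
            class = "recovery_table")
}

#' @export
print.recovery_table <- function(x, ...) {
  cat(sprintf("<recovery_table> %s mode, %d fits (%d failed), seed %d\n",
              x$summary$mode, x$summary$n_fits, x$summary$n_failed, x$seed))
  wide <- tidyr::pivot_wider(x$cells[, c("true_F", "true_A", "mean_A_hat",
                                         "mean_f_hat")],
                             names_from = "true_A",
                             values_from = c("mean_A_hat", "mean_f_hat"))
  print(as.data.frame(wide), digits = 3)
  cat(sprintf("MAE(A) by level: %s\n",
              paste(sprintf("%.3g=%.4f", x$margins_A$true_A,
                            x$margins_A$mae_A), collapse = "  ")))
  cat(sprintf("MAE(F) by level: %s\n",
              paste(sprintf("%.3g=%.4f", x$margins_F$true_F,
                            x$margins_F$mae_F), collapse = "  ")))
  cat(sprintf("mean relative frequency error: %.3f%%\n",
              x$summary$rel_f_err_pct))
  invisible(x)
}

#' @method tidy recovery_table
#' @export
tidy.recovery_table <- function(x, ...) x$cells

#' @method glance recovery_table
#' @export
glance.recovery_table <- function(x, ...) x$summary

#' Write a recovery table to CSV files
#'
#' @param x A `recovery_table`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recovery_table <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(x$records, file.path(dir, "recovery_records.csv"),
            row.names = FALSE)
  write.csv(x$cells, file.path(dir, "recovery_table.csv"), row.names = FALSE)
  write.csv(x$margins_A, file.path(dir, "recovery_margins_A.csv"),
            row.names = FALSE)
  write.csv(x$margins_F, file.path(dir, "recovery_margins_F.csv"),
            row.names = FALSE)
  jsonlite::write_json(as.list(x$summary), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Pairwise group comparison of dentation measures
#'
#' Welch two-sided t-tests between every pair of groups, separately per
#' side and measure, with significance tiers at 0.05 / 0.005 / 0.001 (no
#' multiple-testing correction: tiers mirror raw thresholds, as recorded in
#' the output metadata). Groups with fewer than 2 records are excluded
#' with a warning. Box-plot summary statistics (median, quartiles, 1.5 IQR
#' whiskers) are computed per group.
#'
#' @param records Tibble with columns `subject`, `side`, `group` and the
#'   measure columns (default `A_mm`, `f_bpm`).
#' @param measures Measure column names to test.
#' @return A `group_comparison`: list with `tests`, `summary`, `meta`.
#' @export
compare_groups <- function(records, measures = c("A_mm", "f_bpm")) {
  stopifnot(all(c("group", "side") %in% names(records)),
            all(measures %in% names(records)))
  counts <- records %>% group_by(.data$group) %>%
    summarise(n = dplyr::n(), .groups = "drop")
  small <- counts$group[counts$n < 2]
  if (length(small) > 0) {
    warn(sprintf("excluding group(s) with < 2 records: %s",
                 paste(small, collapse = ", ")))
    records <- records %>% filter(!(.data$group %in% small))
  }
  groups <- sort(unique(records$group))
  if (length(groups) < 2) {
    abort("need at least two groups with >= 2 records each.",
          class = "dentamorph_parameter_error")
  }
  pairs <- utils::combn(as.character(groups), 2)
  tests <- purrr::map(unique(records$side), function(sd) {
    purrr::map(measures, function(ms) {
      purrr::map(seq_len(ncol(pairs)), function(pi) {
        g1 <- pairs[1, pi]
        g2 <- pairs[2, pi]
        x <- records[records$side == sd & records$group == g1, ][[ms]]
        y <- records[records$side == sd & records$group == g2, ][[ms]]
        if (length(x) < 2 || length(y) < 2) return(NULL)
        tt <- t.test(x, y)
        tibble(side = sd, measure = ms, group1 = g1, group2 = g2,
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value,
               tier = significance_tier(tt$p.value))
      }) %>% bind_rows()
    }) %>% bind_rows()
  }) %>% bind_rows()
  summary <- records %>%
    tidyr::pivot_longer(dplyr::all_of(measures), names_to = "measure",
                        values_to = "value") %>%
    group_by(.data$side, .data$measure, .data$group) %>%
    summarise(n = dplyr::n(), median = median(.data$value),
              q1 = quantile(.data$value, 0.25, names = FALSE),
              q3 = quantile(.data$value, 0.75, names = FALSE),
              .groups = "drop") %>%
    mutate(whisker_lo = .data$q1 - 1.5 * (.data$q3 - .data$q1),
           whisker_hi = .data$q3 + 1.5 * (.data$q3 - .data$q1))
  structure(list(tests = tests, summary = summary,
                 meta = list(test = "Welch two-sided t-test",
                             correction = "none (raw-threshold tiers)",
                             tiers = c(`*` = 0.05, `**` = 0.005,
                                       `***` = 0.001))),
            class = "group_comparison")
}

significance_tier <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.005 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", nrow(x$tests), "pairwise Welch t-tests\n")
  print(as.data.frame(x$tests), digits = 3)
  invisible(x)
}

#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$tests

#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(n_tests = nrow(x$tests),
         n_significant = sum(x$tests$tier != "ns"),
         min_p = min(x$tests$p_value))
}

#' Per-subject dentation record
#'
#' Runs refine -> extract -> fit for each hippocampus side of one subject
#' and returns one tidy row per side. Per-side failures are recorded and
#' flagged rather than aborting the subject.
#'
#' @param subject Subject identifier.
#' @param sides Named list (e.g. `left`, `right`); each element a list with
#'   `image` (or `NULL`) and either `prob` (native probability map, to be
#'   refined) or `mask` (already-fine binary mask).
#' @param cfg A [dentamorph_config()].
#' @return Tibble with one row per side: fit fields, derived H/L, seed,
#'   config hash and an `ok` flag.
#' @export
run_subject <- function(subject, sides, cfg = dentamorph_config()) {
  cfg_hash <- rlang::hash(unclass(cfg))
  purrr::imap(sides, function(inp, side) {
    tryCatch({
      mask <- if (!is.null(inp$mask)) inp$mask
              else fine_scale_segment(inp$image, inp$prob, cfg)
      sil <- extract_silhouette(mask, cfg, seed = cfg$seed)
      fit <- fit_sinusoid_sa(sil, schedule = cfg$sa_schedule, seed = cfg$seed)
      tibble(subject = subject, side = side, A_mm = fit$A_mm,
             f_bpm = fit$f_bpm, H_mm = fit$H_mm, L_mm = fit$L_mm,
             cost_J = fit$cost_J, seed = cfg$seed, config_hash = cfg_hash,
             ok = TRUE, note = NA_character_)
    }, error = function(e) {
      tibble(subject = subject, side = side, A_mm = NA_real_,
             f_bpm = NA_real_, H_mm = NA_real_, L_mm = NA_real_,
             cost_J = NA_real_, seed = cfg$seed, config_hash = cfg_hash,
             ok = FALSE, note = conditionMessage(e))
    })
  }) %>% bind_rows()
}
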