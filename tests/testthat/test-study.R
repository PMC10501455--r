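test_that("the recovery grid covers every requested cell and its margins
           recompute from the cells", {
  rt <- suppressWarnings(run_recovery_study(
    amplitudes = c(0.2, 0.4), frequencies = c(0.1, 0.2), replicates = 2,
    mode = "analytic", seed = 3))
  expect_equal(nrow(rt$cells), 4)
  expect_true(all(rt$cells$n_reps == 2))
  # margins must equal recomputation from the cell means
  recompute_A <- dplyr::summarise(dplyr::group_by(rt$cells, true_A),
                                  mae = mean(abs(mean_A_hat - true_A)))
  expect_equal(rt$margins_A$mae_A, recompute_A$mae)
  recompute_F <- dplyr::summarise(dplyr::group_by(rt$cells, true_F),
                                  mae = mean(abs(mean_f_hat - true_F)))
  expect_equal(rt$margins_F$mae_F, recompute_F$mae)
  expect_error(run_recovery_study(amplitudes = numeric(0)),
               class = "dentamorph_parameter_error")
})

test_that("analytic-mode recovery is essentially exact (noiseless
           identifiability)", {
  rt <- run_recovery_study(replicates = 1, mode = "analytic", seed = 7)
  err_A <- abs(rt$cells$mean_A_hat - rt$cells$true_A)
  err_f <- abs(rt$cells$mean_f_hat - rt$cells$true_F)
  expect_lt(max(err_A), 1e-3)
  expect_lt(max(err_f), 1e-3)
})

test_that("full-pipeline and direct-silhouette modes agree on frequency", {
  cfg <- dentamorph_config()
  direct <- suppressWarnings(run_recovery_study(
    amplitudes = 0.3, frequencies = 0.2, replicates = 1,
    mode = "silhouette", seed = 5, cfg = cfg))
  full <- suppressWarnings(run_recovery_study(
    amplitudes = 0.3, frequencies = 0.2, replicates = 1,
    mode = "full", seed = 5, cfg = cfg))
  expect_lt(abs(full$cells$mean_f_hat - direct$cells$mean_f_hat) /
              direct$cells$mean_f_hat, 0.02)
})

test_that("study runs are reproducible and robust to per-cell failure", {
  r1 <- run_recovery_study(amplitudes = 0.2, frequencies = c(0.1, 0.2),
                           replicates = 2, mode = "analytic", seed = 11)
  r2 <- run_recovery_study(amplitudes = 0.2, frequencies = c(0.1, 0.2),
                           replicates = 2, mode = "analytic", seed = 11)
  expect_identical(r1$records$A_hat, r2$records$A_hat)
  expect_identical(r1$records$seed, r2$records$seed)
})

test_that("identical groups show no significant difference", {
  rec <- tibble::tibble(subject = rep(1:10, 2), side = "left",
                        group = rep(c("g1", "g2"), each = 10),
                        A_mm = rep(seq(0.1, 0.2, length.out = 10), 2),
                        f_bpm = rep(seq(0.1, 0.15, length.out = 10), 2))
  gc <- compare_groups(rec)
  expect_equal(nrow(gc$tests), 2)  # one pair x two measures
  expect_true(all(abs(gc$tests$statistic) < 1e-10))
  expect_true(all(gc$tests$p_value > 0.999))
  expect_true(all(gc$tests$tier == "ns"))
})

test_that("three groups yield all pairwise tests and tiny groups are
           dropped with a warning", {
  rec <- withr::with_seed(4, tibble::tibble(
    subject = rep(1:30, 2),
    side = rep(c("left", "right"), each = 30),
    group = rep(rep(c("20s", "30s", "40s"), each = 10), 2),
    A_mm = rnorm(60, 0.15, 0.03),
    f_bpm = rnorm(60, 0.13, 0.02)))
  gc <- compare_groups(rec)
  expect_equal(nrow(gc$tests), 3 * 2 * 2)  # 3 pairs x 2 measures x 2 sides
  expect_true(all(gc$tests$p_value >= 0 & gc$tests$p_value <= 1))
  rec_small <- dplyr::bind_rows(rec, tibble::tibble(
    subject = 99, side = "left", group = "50s", A_mm = 0.2, f_bpm = 0.1))
  expect_warning(gc2 <- compare_groups(rec_small), "excluding")
  expect_false("50s" %in% c(gc2$tests$group1, gc2$tests$group2))
})

test_that("two-sample rejection rates match closed-form power", {
  n <- 90
  delta <- 0.03
  sdv <- 0.03
  reject <- withr::with_seed(202, vapply(1:200, function(i) {
    x <- rnorm(n, 0.12, sdv)
    y <- rnorm(n, 0.15, sdv)
    t.test(x, y)$p.value < 0.05
  }, logical(1)))
  theory <- power.t.test(n = n, delta = delta, sd = sdv,
                         sig.level = 0.05)$power
  expect_lt(abs(mean(reject) - theory), 0.05)
  # null calibration: size close to the nominal 5%
  reject0 <- withr::with_seed(303, vapply(1:400, function(i) {
    t.test(rnorm(n, 0.12, sdv), rnorm(n, 0.12, sdv))$p.value < 0.05
  }, logical(1)))
  expect_lt(abs(mean(reject0) - 0.05), 0.04)
})

test_that("per-subject records carry fits and flag failing sides", {
  spec <- sim_shape_spec(0.3, 0.2, phase_rad = 0.3)
  m <- simulate_dentated_cuboid(spec, grid_offset_mm = c(0.04, 0.1, 0.06))
  cfg <- dentamorph_config(seed = 5L)
  rec <- run_subject("phantom-01", list(left = list(mask = m)), cfg)
  expect_true(rec$ok)
  expect_lt(abs(rec$A_mm - 0.3), 0.05)  # within the recovery error envelope
  expect_equal(rec$H_mm, 2 * rec$A_mm)
  # one missing side: flagged, the other intact
  rec2 <- run_subject("phantom-02",
                      list(left = list(mask = m),
                           right = list(image = NULL, prob = NULL)), cfg)
  expect_equal(rec2$ok, c(TRUE, FALSE))
  expect_false(is.na(rec2$note[2]))
  # determinism
  rec3 <- run_subject("phantom-01", list(left = list(mask = m)), cfg)
  expect_identical(rec$A_mm, rec3$A_mm)
})
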