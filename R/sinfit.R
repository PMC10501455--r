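#' Sinusoid fitting objective
#'
#' Mean squared residual between the silhouette and the four-parameter
#' model `y(x) = A * sin(w * x + phi) + b`:
#' `J(A, w, phi, b) = mean( (y - (A sin(w x + phi) + b))^2 )`. The
#' continuous least-squares integral is discretized as the mean over the
#' silhouette samples.
#'
#' @param params Numeric vector `c(A, w, phi, b)` (amplitude mm, angular
#'   frequency rad/mm, phase rad, bias mm).
#' @param sil A `silhouette` tibble (columns `x_mm`, `y_mm`) from
#'   [inferior_silhouette()].
#' @return Non-negative scalar cost.
#' @export
sin_objective <- function(params, sil) {
  r <- sil$y_mm - (params[1] * sin(params[2] * sil$x_mm + params[3]) +
                     params[4])
  mean(r * r)
}

#' Simulated-annealing schedule
#'
#' @param T0 Initial temperature (costs are pre-normalized by the
#'   silhouette variance, so 1 is a natural scale).
#' @param cooling Geometric cooling factor in (0, 1).
#' @param iters_per_temp Proposals evaluated at each temperature.
#' @param T_min Final temperature.
#' @param restarts Independent annealing runs; the best-ever solution is
#'   kept across all of them.
#' @param proposal_scales Per-parameter Gaussian step scales for
#'   `(A, log f, phi, b)`; frequency is proposed in log-space so octaves
#'   are explored evenly. Steps shrink with `sqrt(T / T0)`.
#' @return An `sa_schedule` list.
#' @export
sa_schedule <- function(T0 = 1.0, cooling = 0.95, iters_per_temp = 50L,
                        T_min = 1e-4, restarts = 4L,
                        proposal_scales = c(A = 0.25, logf = 0.35,
                                            phi = 0.8, b = 0.25)) {
  if (T0 <= 0 || T_min <= 0 || cooling <= 0 || cooling >= 1) {
    abort("require T0 > 0, T_min > 0 and cooling in (0, 1).",
          class = "dentamorph_parameter_error")
  }
  if (iters_per_temp < 1 || restarts < 1) {
    abort("`iters_per_temp` and `restarts` must be positive.",
          class = "dentamorph_parameter_error")
  }
  structure(list(T0 = T0, cooling = cooling,
                 iters_per_temp = as.integer(iters_per_temp),
                 T_min = T_min, restarts = as.integer(restarts),
                 proposal_scales = proposal_scales),
            class = "sa_schedule")
}

# least-squares amplitude/phase/bias for a fixed frequency (linear in the
# sin/cos basis); used for the informed restart and by tests as an oracle
# component
ls_fixed_freq <- function(sil, f) {
  w <- 2 * pi * f
  X <- cbind(sin(w * sil$x_mm), cos(w * sil$x_mm), 1)
  cf <- tryCatch(qr.solve(X, sil$y_mm), error = function(e) c(0, 0, mean(sil$y_mm)))
  A <- sqrt(cf[1]^2 + cf[2]^2)
  phi <- atan2(cf[2], cf[1])  # A sin(wx + phi) = cf1 sin + cf2 cos
  r <- sil$y_mm - X %*% cf
  list(A = A, phi = phi %% (2 * pi), b = cf[3], cost = mean(r^2))
}

#' Fit a sinusoid to a silhouette by simulated annealing
#'
#' Minimizes [sin_objective()] over amplitude, frequency, phase and bias.
#' A worse proposal with cost increase `dD` at temperature `T` is accepted
#' iff `exp(-dD / T) > u` with `u ~ U(0, 1)`; temperatures cool
#' geometrically, the best-ever parameters are kept across restarts, and a
#' derivative-free Nelder-Mead polish refines the final solution. One
#' restart is initialized from a coarse frequency sweep (least squares in
#' the remaining parameters), the others from random feasible points. The
#' reported amplitude is non-negative (a negative amplitude is absorbed
#' into the phase) and the phase lies in `[0, 2 pi)`.
#'
#' @param sil A `silhouette` tibble (>= 10 samples).
#' @param bounds List with elements `A` and `f`, each `c(lo, hi)`:
#'   feasible amplitude (mm) and frequency (bumps/mm) ranges. The bias is
#'   constrained to the silhouette's y-range widened by 2 mm.
#' @param schedule An [sa_schedule()].
#' @param seed Integer seed (the fit is bit-reproducible given it).
#' @return A `sinusoid_fit` object: fields `A_mm`, `w_rad_per_mm`,
#'   `phi_rad`, `b_mm`, derived `f_bpm = w / 2 pi`, `H_mm = 2 A`,
#'   `L_mm = 1 / f`, residual `cost_J`, `n_samples`, `seed`, `converged`.
#' @export
fit_sinusoid_sa <- function(sil,
                            bounds = list(A = c(0, 2), f = c(0.02, 0.5)),
                            schedule = sa_schedule(), seed = 1L) {
  if (nrow(sil) < 10) {
    abort("silhouette has fewer than 10 samples.",
          class = "dentamorph_parameter_error")
  }
  if (bounds$A[1] > bounds$A[2] || bounds$f[1] > bounds$f[2] ||
      bounds$f[1] <= 0) {
    abort("infeasible bounds.", class = "dentamorph_parameter_error")
  }
  y <- sil$y_mm
  vy <- var(y)
  if (vy < 1e-10) {
    # flat silhouette: no dentation signal
    return(new_sinusoid_fit(A = 0, f = bounds$f[1], phi = 0, b = mean(y),
                            cost = mean((y - mean(y))^2), n = nrow(sil),
                            seed = seed, converged = "flat"))
  }
  b_rng <- range(y) + c(-2, 2)
  lb <- c(bounds$A[1], log(bounds$f[1]), -Inf, b_rng[1])
  ub <- c(bounds$A[2], log(bounds$f[2]), Inf, b_rng[2])
  # cost in units of the silhouette variance so T0 ~ 1 is meaningful
  costf <- function(p) {
    sin_objective(c(p[1], 2 * pi * exp(p[2]), p[3], p[4]), sil) / vy
  }
  clamp <- function(p) pmin(pmax(p, lb), ub)

  sch <- schedule
  n_temps <- max(1L, ceiling(log(sch$T_min / sch$T0) / log(sch$cooling)))
  scales <- sch$proposal_scales

  run <- withr::with_seed(as.integer(seed), {
    best <- NULL
    best_cost <- Inf
    # informed start: log-spaced frequency sweep + LS in (A, phi, b); the
    # grid must be denser than the likelihood peak (half-width ~ 1/(2 x
    # record length)) or a weak fundamental can lose to its own harmonics
    fgrid <- exp(seq(log(bounds$f[1]), log(bounds$f[2]), length.out = 240))
    sweep_fit <- purrr::map(fgrid, ls_fixed_freq, sil = sil)
    i0 <- which.min(purrr::map_dbl(sweep_fit, "cost"))
    starts <- list(c(min(max(sweep_fit[[i0]]$A, bounds$A[1]), bounds$A[2]),
                     log(fgrid[i0]), sweep_fit[[i0]]$phi,
                     min(max(sweep_fit[[i0]]$b, b_rng[1]), b_rng[2])))
    for (r in seq_len(sch$restarts - 1)) {
      starts[[r + 1]] <- c(runif(1, bounds$A[1], bounds$A[2]),
                           runif(1, log(bounds$f[1]), log(bounds$f[2])),
                           runif(1, 0, 2 * pi),
                           runif(1, b_rng[1], b_rng[2]))
    }
    for (start in starts) {
      cur <- clamp(start)
      cur_cost <- costf(cur)
      if (cur_cost < best_cost) {
        best <- cur
        best_cost <- cur_cost
      }
      Tt <- sch$T0
      for (tstep in seq_len(n_temps)) {
        step <- scales * sqrt(Tt / sch$T0)
        for (it in seq_len(sch$iters_per_temp)) {
          prop <- clamp(cur + rnorm(4) * step)
          pc <- costf(prop)
          dD <- pc - cur_cost
          if (dD < 0 || exp(-dD / Tt) > runif(1)) {
            cur <- prop
            cur_cost <- pc
            if (pc < best_cost) {
              best <- prop
              best_cost <- pc
            }
          }
        }
        Tt <- Tt * sch$cooling
        if (Tt < sch$T_min) break
      }
    }
    # derivative-free local polish
    pol <- optim(best, function(p) costf(clamp(p)), method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12))
    pol_par <- clamp(pol$par)
    if (pol$value <= best_cost) {
      best <- pol_par
      best_cost <- pol$value
    }
    list(par = best, cost = best_cost, polished = pol$convergence == 0)
  })

  A <- run$par[1]
  f <- exp(run$par[2])
  phi <- run$par[3]
  b <- run$par[4]
  if (A < 0) {
    A <- -A
    phi <- phi + pi
  }
  phi <- phi %% (2 * pi)
  new_sinusoid_fit(A = A, f = f, phi = phi, b = b,
                   cost = run$cost * vy, n = nrow(sil), seed = seed,
                   converged = if (run$polished) "ok" else "max-iterations")
}

new_sinusoid_fit <- function(A, f, phi, b, cost, n, seed, converged) {
  A <- unname(A); f <- unname(f); phi <- unname(phi); b <- unname(b)
  cost <- unname(cost)
  structure(list(A_mm = A, w_rad_per_mm = 2 * pi * f, phi_rad = phi,
                 b_mm = b, f_bpm = f, H_mm = 2 * A,
                 L_mm = if (f > 0) 1 / f else NA_real_,
                 cost_J = cost, n_samples = as.integer(n),
                 seed = as.integer(seed), converged = converged),
            class = "sinusoid_fit")
}

#' Dentation height and width from a fit
#'
#' The bump height is twice the amplitude, `H = 2A`, and the bump width is
#' the reciprocal frequency, `L = 1/f`.
#'
#' @param fit A `sinusoid_fit`.
#' @return Tibble with `H_mm` and `L_mm`.
#' @export
derived_measures <- function(fit) {
  if (fit$f_bpm <= 0) {
    abort("frequency is zero: bump width L = 1/f is undefined.",
          class = "dentamorph_parameter_error")
  }
  tibble(H_mm = 2 * fit$A_mm, L_mm = 1 / fit$f_bpm)
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat("<sinusoid_fit>\n")
  cat(sprintf("  A = %.4g mm   f = %.4g bump/mm   phi = %.3f rad   b = %.4g mm\n",
              x$A_mm, x$f_bpm, x$phi_rad, x$b_mm))
  cat(sprintf("  H = 2A = %.4g mm   L = 1/f = %.4g mm\n", x$H_mm, x$L_mm))
  cat(sprintf("  cost J = %.4g (n = %d, seed = %d, %s)\n",
              x$cost_J, x$n_samples, x$seed, x$converged))
  invisible(x)
}

#' @rdname fit_sinusoid_sa
#' @param x A `sinusoid_fit`.
#' @param ... Unused.
#' @method tidy sinusoid_fit
#' @export
tidy.sinusoid_fit <- function(x, ...) {
  tibble(term = c("A_mm", "f_bpm", "phi_rad", "b_mm"),
         estimate = c(x$A_mm, x$f_bpm, x$phi_rad, x$b_mm))
}

#' @rdname fit_sinusoid_sa
#' @method glance sinusoid_fit
#' @export
glance.sinusoid_fit <- function(x, ...) {
  tibble(A_mm = x$A_mm, f_bpm = x$f_bpm, phi_rad = x$phi_rad, b_mm = x$b_mm,
         H_mm = x$H_mm, L_mm = x$L_mm, cost_J = x$cost_J,
         n_samples = x$n_samples, seed = x$seed, converged = x$converged)
}

#' Predicted silhouette from a fit
#'
#' @param object A `sinusoid_fit`.
#' @param newdata Optional tibble with `x_mm`.
#' @param ... Unused.
#' @export
predict.sinusoid_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    abort("supply `newdata` with an `x_mm` column.",
          class = "dentamorph_parameter_error")
  }
  object$A_mm * sin(object$w_rad_per_mm * newdata$x_mm + object$phi_rad) +
    object$b_mm
}
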