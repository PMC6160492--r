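## The classed model object tying the modules together: construct once from
## a parameter set, then query with the standard modelling verbs.

#' Navel lint accretion model
#'
#' Builds the full model from a physical parameter set: the per-fiber force
#' balance, the phase and cycle-averaged sliding velocities, the
#' single-fiber mass, the fill time and the initial density profile. The
#' returned object supports `print`, `summary`, `coef`, `predict`,
#' `simulate` and `plot`.
#'
#' @param params A `lint_params` object; see [default_params()].
#' @param n0 Initial [density_profile()]; default constant at
#'   `params$transport$n0_level` on \[0, L\].
#' @return An object of class `lint_model`.
#' @examples
#' m <- lint_model()
#' summary(m)
#' predict(m, times = c(3600, 36000))
#' @export
lint_model <- function(params = default_params(), n0 = NULL) {
  stopifnot(inherits(params, "lint_params"))
  if (is.null(n0))
    n0 <- density_profile("constant", level = params$transport$n0_level,
                          L = params$transport$L)
  stopifnot(inherits(n0, "density_profile"))
  structure(list(
    params = params,
    n0 = n0,
    forces = force_balance(params),
    velocity = mean_velocity(params),
    m_L = fiber_mass(params$geometry),
    fill_time = params$transport$L / mean_velocity(params)$u_bar
  ), class = "lint_model")
}

#' @export
print.lint_model <- function(x, ...) {
  cat("Navel lint accretion model (friction-ratchet transport)\n")
  cat(sprintf("  drift velocity u_bar  %.4g m/s (%.4g m per %g s breath)\n",
              x$velocity$u_bar, x$velocity$dx_cycle, x$params$transport$T))
  cat(sprintf("  fill time L/u_bar     %.4g s (%.2f hr)\n",
              x$fill_time, x$fill_time / 3600))
  cat(sprintf("  fiber mass m_L        %.4g kg\n", x$m_L))
  cat(sprintf("  initial profile       %s, %.4g fibers total\n",
              x$n0$kind, profile_total(x$n0)))
  invisible(x)
}

#' @export
summary.lint_model <- function(object, t_long = 36000, ...) {
  out <- list(model = object,
              report = reproduce_paper(object$params, t_long = t_long))
  class(out) <- "summary.lint_model"
  out
}

#' @export
print.summary.lint_model <- function(x, ...) {
  print(x$model)
  cat("\n")
  print(x$report)
  invisible(x)
}

#' @export
coef.lint_model <- function(object, ...) {
  params_flat(object$params)
}

#' Predict accreted lint over time
#'
#' Evaluates the analytic accretion law at the requested times: the density
#' at the navel, the cumulative accreted fiber count, the accreted mass,
#' and which asymptotic regime each time falls in (`"short"` before the
#' fill time, where the initial fibers still contribute; `"long"` after,
#' where only the source term grows).
#'
#' @param object A [lint_model()].
#' @param times Times, s (>= 0).
#' @param A Source-rate override, fibers m^-1 s^-1.
#' @param ... Unused.
#' @return A data frame with columns `t_s`, `n_at_navel_per_m`,
#'   `N_B_fibers`, `m_B_kg`, `regime`.
#' @export
predict.lint_model <- function(object, times = NULL, A = NULL, ...) {
  if (is.null(times))
    times <- seq(0, 10 * 3600, length.out = 101L)
  if (is.null(A)) A <- object$params$transport$A
  u_bar <- object$velocity$u_bar
  L <- object$params$transport$L
  n_navel <- concentration(rep(L, length(times)), times, A, u_bar, object$n0)
  N_B <- accreted_count(times, A, u_bar, object$n0)
  data.frame(
    t_s = times,
    n_at_navel_per_m = n_navel,
    N_B_fibers = N_B,
    m_B_kg = object$m_L * N_B,
    regime = ifelse(times < object$fill_time, "short", "long")
  )
}

#' Simulate the discrete-fiber ratchet from a model
#'
#' Thin wrapper around [run_sim()]: `nsim` replicates of the stochastic
#' per-breathing-cycle simulator under the model's parameters.
#'
#' @param object A [lint_model()].
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param n_cycles Number of breathing cycles; default enough to reach the
#'   fill time.
#' @param ... Passed to [sim_config()] (`source_mode`, `initial_mode`,
#'   `track`).
#' @return A `lint_sim` object; see [run_sim()].
#' @export
simulate.lint_model <- function(object, nsim = 1L, seed = 1L,
                                n_cycles = NULL, ...) {
  if (is.null(n_cycles))
    n_cycles <- ceiling(object$fill_time / object$params$transport$T)
  run_sim(sim_config(object$params, n_cycles = n_cycles,
                     n_replicates = nsim, seed = seed, n0 = object$n0, ...))
}

#' Plot the accretion law
#'
#' Accreted mass against time with the short-time (linear, initial-fiber)
#' and long-time (quadratic, source-dominated) asymptotes.
#'
#' @param x A [lint_model()].
#' @param t_max Plot horizon, s (default 10 hours).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lint_model <- function(x, t_max = 36000, ...) {
  t <- seq(0, t_max, length.out = 400L)
  m <- accreted_mass(t, x$params, n0 = x$n0)
  graphics::plot(t / 3600, m * 1e6, type = "l", lwd = 2,
                 xlab = "time (hr)", ylab = "accreted lint mass (mg)", ...)
  graphics::lines(t / 3600, longtime_mass(t, x$params) * 1e6,
                  lty = 2, col = "grey40")
  graphics::lines(t / 3600, shorttime_mass(t, x$params) * 1e6,
                  lty = 3, col = "grey40")
  graphics::abline(v = x$fill_time / 3600, lty = 3, col = "red")
  graphics::legend("topleft",
                   c("exact", "long-time t^2 law", "short-time linear law",
                     "fill time"),
                   lty = c(1, 2, 3, 3),
                   col = c("black", "grey40", "grey40", "red"), bty = "n")
  invisible(x)
}
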