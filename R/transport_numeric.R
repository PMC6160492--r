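## Finite-volume upwind solver for the 1-D conservation law
## dn/dt + d(u n)/dx = S(x, t) with one-signed (rightward) velocity.
##
## First-order explicit upwind is deliberate: the model's velocity is
## uniform and the analytic answer exists, so the solver's job is
## independent verification, where provable positivity and exact discrete
## conservation matter more than order of accuracy.

#' Discretization contract for the numeric transport solver
#'
#' @param n_cells Number of finite-volume cells (>= 8).
#' @param cfl Courant number in (0, 1]; the time step is
#'   `cfl * dx / max(u)`. At `cfl = 1` with constant u the scheme is an
#'   exact shift.
#' @param t_end End time, s (> 0).
#' @param output_stride Record a density snapshot every this many steps
#'   (the final state is always recorded).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_cells = 512, cfl = 0.9, t_end, output_stride = 50L) {
  stopifnot(n_cells >= 8, cfl > 0, cfl <= 1, t_end > 0, output_stride >= 1)
  structure(list(n_cells = as.integer(n_cells), cfl = cfl, t_end = t_end,
                 output_stride = as.integer(output_stride)),
            class = "grid_spec")
}

#' Solve the lint transport equation numerically
#'
#' Explicit first-order finite-volume upwind scheme on \[0, L\]. The inflow
#' boundary at x = 0 carries zero density; the outflow flux u * n at x = L
#' is accumulated each step into the numeric accreted count `N_B`. The
#' source is integrated by forward Euler within the same step. Velocity
#' must be non-negative everywhere sampled (rightward transport only).
#'
#' @param params A `lint_params` object; supplies L and the defaults for
#'   `u` (the cycle-averaged drift) and `S` (the constant source A).
#' @param n0 Initial [density_profile()]; default constant at
#'   `params$transport$n0_level`.
#' @param u Velocity field: a single number or a `function(x, t)`,
#'   m/s (>= 0).
#' @param S Source field: a single number or a `function(x, t)`,
#'   fibers m^-1 s^-1.
#' @param grid A [grid_spec()].
#' @param inflow Chest-end (x = 0) ghost density. `"source_consistent"`
#'   (default) sets it to `S(0, t) * t`, the value the characteristics
#'   solution takes at x = 0 when the source also acts on the hairy region
#'   upstream of the modeled window -- required for the numeric solution to
#'   match the closed form beyond the fill time. `"zero"` seals the chest
#'   end (no inflow at all), which matches the closed form only up to the
#'   fill time. A `function(t)` may be supplied directly.
#' @return An object of class `transport_numeric` with fields
#'   `cell_centers`, `dx`, `snapshots` (list of `(t, n)`), `times`,
#'   `N_B` (accumulated outflow count per recorded time), `total_in_domain`,
#'   `source_injected`, `inflow_injected`, `initial_total` and
#'   `conservation_residual` (total + N_B - source - inflow - initial;
#'   at round-off for every recorded step).
#' @examples
#' p <- default_params()
#' sol <- solve_transport(p, grid = grid_spec(128, t_end = 600))
#' utils::tail(sol$N_B, 1)
#' @export
solve_transport <- function(params, n0 = NULL, u = NULL, S = NULL, grid,
                            inflow = c("source_consistent", "zero")) {
  stopifnot(inherits(params, "lint_params"), inherits(grid, "grid_spec"))
  L <- params$transport$L
  if (is.null(n0))
    n0 <- density_profile("constant", level = params$transport$n0_level,
                          L = L)
  stopifnot(abs(n0$L - L) < 1e-12)
  if (is.null(u)) u <- mean_velocity(params)$u_bar
  if (is.null(S)) S <- params$transport$A
  u_fun <- if (is.function(u)) u else function(x, t) rep(u, length(x))
  S_fun <- if (is.function(S)) S else function(x, t) rep(S, length(x))
  if (is.function(inflow)) {
    ghost_fun <- inflow
  } else {
    inflow <- match.arg(inflow)
    ghost_fun <- if (inflow == "zero") function(t) 0
                 else function(t) S_fun(0, t)[1] * t
  }

  nc <- grid$n_cells
  dx <- L / nc
  centers <- (seq_len(nc) - 0.5) * dx
  faces <- seq(0, L, length.out = nc + 1L)

  n <- profile_eval(n0, centers)
  initial_total <- sum(n) * dx

  t <- 0
  N_B <- 0
  source_injected <- 0
  inflow_injected <- 0
  times <- 0
  N_B_series <- 0
  total_series <- initial_total
  residual <- 0
  snapshots <- list(list(t = 0, n = n))
  step <- 0L

  while (t < grid$t_end - 1e-12 * grid$t_end) {
    u_f <- u_fun(faces, t)
    if (any(u_f < 0))
      stop("unsupported regime: negative velocity sampled (rightward transport only)",
           call. = FALSE)
    umax <- max(u_f)
    dt <- if (umax > 0) grid$cfl * dx / umax else grid$t_end - t
    dt <- min(dt, grid$t_end - t)

    # upwind interface fluxes; the ghost cell feeds the inflow face
    flux <- u_f * c(ghost_fun(t), n)
    s_cells <- S_fun(centers, t)
    n <- n + dt / dx * (flux[seq_len(nc)] - flux[-1L]) + dt * s_cells
    N_B <- N_B + flux[nc + 1L] * dt
    source_injected <- source_injected + sum(s_cells) * dx * dt
    inflow_injected <- inflow_injected + flux[1L] * dt
    t <- t + dt
    step <- step + 1L

    total <- sum(n) * dx
    times <- c(times, t)
    N_B_series <- c(N_B_series, N_B)
    total_series <- c(total_series, total)
    residual <- c(residual,
                  total + N_B - source_injected - inflow_injected -
                    initial_total)
    if (step %% grid$output_stride == 0L || t >= grid$t_end * (1 - 1e-12))
      snapshots[[length(snapshots) + 1L]] <- list(t = t, n = n)
  }

  structure(list(
    cell_centers = centers, dx = dx, snapshots = snapshots,
    times = times, N_B = N_B_series, total_in_domain = total_series,
    source_injected = source_injected, inflow_injected = inflow_injected,
    initial_total = initial_total,
    conservation_residual = residual, grid = grid
  ), class = "transport_numeric")
}

#' @export
print.transport_numeric <- function(x, ...) {
  cat(sprintf("Upwind transport solution: %d cells, t_end = %g s\n",
              x$grid$n_cells, x$grid$t_end))
  cat(sprintf("  accreted count N_B = %.6g fibers\n", utils::tail(x$N_B, 1)))
  cat(sprintf("  max |conservation residual| = %.3g fibers\n",
              max(abs(x$conservation_residual))))
  invisible(x)
}

#' Grid-refinement convergence study
#'
#' Runs the upwind solver on a sequence of grids (each doubling the cell
#' count), measures the L1 error of the final density against the
#' characteristics solution, and reports the observed convergence order
#' between consecutive grids. First-order upwind should give observed
#' orders near 1 for smooth initial profiles.
#'
#' @param params A `lint_params` object.
#' @param n0 Initial [density_profile()] (smooth profiles recommended).
#' @param n_cells_seq Increasing integer vector of cell counts, each double
#'   the previous, length >= 3.
#' @param cfl Courant number (shared by all runs).
#' @param t_end End time, s.
#' @return A data frame with columns `n_cells`, `l1_error`, `order`
#'   (`NA` for the first grid), plus attribute `"mean_order"`.
#' @export
convergence_study <- function(params, n0, n_cells_seq = c(128L, 256L, 512L),
                              cfl = 0.9, t_end = NULL) {
  stopifnot(length(n_cells_seq) >= 3)
  if (any(diff(log2(n_cells_seq)) != 1))
    stop("n_cells_seq must double at each refinement", call. = FALSE)
  u_bar <- mean_velocity(params)$u_bar
  A <- params$transport$A
  if (is.null(t_end)) t_end <- 0.25 * fill_time(params)
  err <- vapply(n_cells_seq, function(nc) {
    sol <- solve_transport(params, n0 = n0,
                           grid = grid_spec(nc, cfl = cfl, t_end = t_end))
    fin <- sol$snapshots[[length(sol$snapshots)]]
    exact <- concentration(sol$cell_centers, fin$t, A, u_bar, n0)
    sum(abs(fin$n - exact)) * sol$dx
  }, numeric(1))
  order <- c(NA, log2(utils::head(err, -1) / utils::tail(err, -1)))
  out <- data.frame(n_cells = n_cells_seq, l1_error = err, order = order)
  attr(out, "mean_order") <- mean(order, na.rm = TRUE)
  out
}
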