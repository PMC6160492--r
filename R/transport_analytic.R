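## Closed-form solution of the lint transport equation and the navel
## accretion law.
##
## With a uniform drift u_bar and constant source A, the number density
## obeys dn/dt + u_bar dn/dx = A, whose characteristics solution is
## n(x, t) = A t + n0(x - u_bar t) with n0 zero-extended for negative
## arguments. The navel (x = L) absorbs at rate n(L, t) * u_bar, so the
## accreted count is N_B(t) = A u_bar t^2 / 2 + integral of n0 over
## [L - u_bar t, L], and the accreted mass is m_L * N_B(t).

#' Fiber number density n(x, t)
#'
#' Characteristics solution of the advection equation with constant source:
#' `A * t + n0(x - u_bar * t)`, the initial profile translating toward the
#' navel at speed `u_bar` on top of a uniformly growing source background.
#'
#' @param x Position(s), m; must lie in \[0, L\].
#' @param t Time(s), s (>= 0).
#' @param A Source rate, fibers m^-1 s^-1.
#' @param u_bar Drift velocity, m/s.
#' @param n0 Initial [density_profile()] (zero-extended outside \[0, L\]).
#' @return Density, fibers/m; vectorized over `x` or `t`.
#' @export
concentration <- function(x, t, A, u_bar, n0) {
  stopifnot(inherits(n0, "density_profile"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (any(x < 0 | x > n0$L))
    stop("x must lie within [0, L]", call. = FALSE)
  A * t + profile_eval(n0, x - u_bar * t)
}

#' Cumulative fiber count accreted at the navel
#'
#' N_B(t) = A u_bar t^2 / 2 + integral of n0 over \[L - u_bar t, L\]
#' (zero-extension of n0 unifies the pre- and post-fill branches). For a
#' constant profile the closed form A u_bar t^2 / 2 + u_bar n0 t (t < L /
#' u_bar) or + n0 L (t >= L / u_bar) is used unless
#' `method = "quadrature"` forces the integral path.
#'
#' @param t Time(s), s (>= 0).
#' @param A Source rate, fibers m^-1 s^-1.
#' @param u_bar Drift velocity, m/s (>= 0).
#' @param n0 Initial [density_profile()].
#' @param method `"auto"` (closed form where available), `"closed"`, or
#'   `"quadrature"`.
#' @return Accreted fiber count(s).
#' @examples
#' p <- default_params()
#' vp <- mean_velocity(p)
#' n0 <- density_profile("constant", level = 100, L = 0.1)
#' accreted_count(3680, A = 0, u_bar = vp$u_bar, n0 = n0)  # the 10 initial fibers
#' @export
accreted_count <- function(t, A, u_bar, n0,
                           method = c("auto", "closed", "quadrature")) {
  stopifnot(inherits(n0, "density_profile"))
  method <- match.arg(method)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (u_bar < 0) stop("u_bar must be >= 0", call. = FALSE)
  L <- n0$L
  source_part <- A * u_bar * t^2 / 2
  use_closed <- method == "closed" ||
    (method == "auto" && n0$kind %in% c("constant", "zero"))
  if (use_closed) {
    if (!n0$kind %in% c("constant", "zero"))
      stop("closed form only available for constant/zero profiles",
           call. = FALSE)
    lvl <- n0$level
    init_part <- ifelse(u_bar * t < L, u_bar * lvl * t, lvl * L)
  } else {
    int_method <- if (method == "quadrature") "quadrature" else "auto"
    init_part <- vapply(t, function(ti)
      profile_integral(n0, L - u_bar * ti, L, method = int_method),
      numeric(1))
  }
  source_part + init_part
}

#' Accreted lint mass m_B(t)
#'
#' The accreted mass is the single-fiber mass times the accreted count:
#' m_B(t) = m_L * N_B(t).
#'
#' @param t Time(s), s (>= 0).
#' @param params A `lint_params` object (supplies A, the drift velocity and
#'   the fiber mass).
#' @param n0 Initial [density_profile()]; default constant at
#'   `params$transport$n0_level`.
#' @param A Source rate override, fibers m^-1 s^-1; default
#'   `params$transport$A`.
#' @return Mass, kg.
#' @export
accreted_mass <- function(t, params, n0 = NULL, A = NULL) {
  stopifnot(inherits(params, "lint_params"))
  if (is.null(n0))
    n0 <- density_profile("constant", level = params$transport$n0_level,
                          L = params$transport$L)
  if (is.null(A)) A <- params$transport$A
  u_bar <- mean_velocity(params)$u_bar
  fiber_mass(params$geometry) * accreted_count(t, A, u_bar, n0)
}

#' Long-time (source-dominated) accreted mass
#'
#' For large t the parabolic source term dominates and
#' m_B(t) = m_L * A * u_bar * t^2 / 2: the initial fibers contribute a
#' constant that becomes negligible, which is why accumulated lint matches
#' the shirt worn rather than the towel.
#'
#' @inheritParams accreted_mass
#' @return Mass, kg.
#' @examples
#' longtime_mass(36000, default_params())   # ~6.2e-7 kg ~ 1 mg after 10 h
#' @export
longtime_mass <- function(t, params, A = NULL) {
  stopifnot(inherits(params, "lint_params"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (is.null(A)) A <- params$transport$A
  u_bar <- mean_velocity(params)$u_bar
  fiber_mass(params$geometry) * A * u_bar * t^2 / 2
}

#' Short-time (initial-population) accreted mass
#'
#' For small t the linear term dominates: m_B(t) = m_L * u_bar * n0 * t
#' (constant initial profile). Even at the fill time this is only of order
#' 0.1 ug -- the towel-deposited population is a negligible contributor.
#'
#' @inheritParams accreted_mass
#' @param n0_level Constant initial density override, fibers/m.
#' @return Mass, kg.
#' @export
shorttime_mass <- function(t, params, n0_level = NULL) {
  stopifnot(inherits(params, "lint_params"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (is.null(n0_level)) n0_level <- params$transport$n0_level
  u_bar <- mean_velocity(params)$u_bar
  fiber_mass(params$geometry) * u_bar * n0_level * t
}

#' Domain fill time L / u_bar
#'
#' Time for the whole initial fiber population to translate into the navel;
#' beyond it only the source term adds fibers. About an hour at nominal
#' parameters.
#'
#' @param params A `lint_params` object.
#' @return Time, s.
#' @export
fill_time <- function(params) {
  stopifnot(inherits(params, "lint_params"))
  u_bar <- mean_velocity(params)$u_bar
  if (u_bar <= 0) stop("fill time undefined: u_bar <= 0", call. = FALSE)
  params$transport$L / u_bar
}

#' Order of magnitude of a positive value
#'
#' Operationalizes "~" statements: returns the power of ten nearest to the
#' value, or the power of ten below it.
#'
#' @param value Positive number(s).
#' @param convention `"nearest"` (10^round(log10 v)) or `"floor"`
#'   (10^floor(log10 v)).
#' @return Power(s) of ten.
#' @examples
#' order_of_magnitude(0.62, "nearest")  # 1
#' order_of_magnitude(0.35, "floor")    # 0.1
#' @export
order_of_magnitude <- function(value, convention = c("nearest", "floor")) {
  convention <- match.arg(convention)
  if (any(value <= 0)) stop("value must be > 0", call. = FALSE)
  e <- switch(convention, nearest = round(log10(value)),
              floor = floor(log10(value)))
  10^e
}
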