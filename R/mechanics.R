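## Per-fiber force balance and sliding velocities.
##
## A lint fiber sandwiched between the shirt and a body hair feels equal
## normal forces F_N at both contacts. Shirt-side friction mu_SL*F_N drags
## it along the shirt's motion; hair-side friction mu_HL*F_N resists. The
## net traction is balanced against Stokes-scale air drag eta*l*U, which
## sets the sliding speed of each breathing-cycle phase. All "~" scaling
## relations are treated as equalities with proportionality constant 1, so
## every output is an order-of-magnitude estimate, not a precision value.

#' Fabric tension from skin pressure (Laplace relation)
#'
#' A garment exerting pressure p on a body wall of radius of curvature R
#' must carry a line tension gamma = p * R, by the same force balance that
#' gives the pressure jump across a curved fluid interface (hoop stress in
#' a thin shell).
#'
#' @param p Skin pressure, Pa (>= 0).
#' @param R Radius of curvature, m (> 0).
#' @return Fabric tension, N/m.
#' @examples
#' fabric_tension(100, 0.47)  # ~47 N/m for everyday clothing
#' @export
fabric_tension <- function(p, R) {
  if (any(R <= 0)) stop("R must be > 0", call. = FALSE)
  if (any(p < 0)) stop("p must be >= 0", call. = FALSE)
  p * R
}

#' Skin pressure from fabric tension
#'
#' Exact inverse of [fabric_tension()]: p = gamma / R. A larger belly has a
#' smaller radius of curvature, so the same fabric tension produces a higher
#' skin pressure -- and hence faster lint transport.
#'
#' @param gamma Fabric line tension, N/m (>= 0).
#' @param R Radius of curvature, m (> 0).
#' @return Skin pressure, Pa.
#' @export
skin_pressure <- function(gamma, R) {
  if (any(R <= 0)) stop("R must be > 0", call. = FALSE)
  if (any(gamma < 0)) stop("gamma must be >= 0", call. = FALSE)
  gamma / R
}

#' Interfacial normal force on a sandwiched fiber
#'
#' The real contact area between fiber and fabric is a small fraction alpha
#' of the projected area d*l, so F_N = p * alpha * d * l.
#'
#' @param p Skin pressure, Pa.
#' @param geometry A [fiber_geometry()].
#' @param alpha Real-contact-area fraction (0 < alpha <= 1); taken from
#'   `geometry`'s companion [garment_skin()] in normal use.
#' @return Normal force in N, with the contact area `A_c` (m^2) attached as
#'   attribute `"A_c"`.
#' @export
normal_force <- function(p, geometry, alpha) {
  stopifnot(inherits(geometry, "fiber_geometry"))
  A_c <- alpha * geometry$d * geometry$l
  structure(p * A_c, A_c = A_c)
}

#' Phase sliding velocity of a lint fiber
#'
#' Balancing the net traction (mu_SL - mu_HL) * F_N against Stokes-scale
#' air drag eta * l * U gives U = (mu_SL - mu_HL) * F_N / (eta * l). The
#' drag scaling is used as an equality with prefactor 1 (slender-cylinder
#' logarithmic corrections are dropped). If the hair-side friction exceeds
#' the shirt-side friction the fiber cannot be dragged at all; the raw
#' negative value is clamped to zero and a `lintflux_no_slip` warning is
#' signalled.
#'
#' @param mu_SL Shirt--lint friction coefficient.
#' @param mu_HL_dir Hair--lint friction coefficient for the phase direction
#'   (`mu_HL_plus` during exhale, `mu_HL_minus` during inhale).
#' @param F_N Normal force, N (>= 0).
#' @param eta Air viscosity, Pa s (> 0).
#' @param l Fiber length, m (> 0).
#' @return Sliding speed, m/s (>= 0).
#' @export
phase_velocity <- function(mu_SL, mu_HL_dir, F_N, eta, l) {
  stopifnot(eta > 0, l > 0, all(F_N >= 0))
  u <- (mu_SL - mu_HL_dir) * F_N / (eta * l)
  if (any(u < 0)) {
    warning(structure(
      class = c("lintflux_no_slip", "warning", "condition"),
      list(message = "no-slip phase: hair-side friction exceeds shirt-side friction; velocity clamped to 0",
           call = sys.call())))
    u <- pmax(u, 0)
  }
  u
}

#' Cycle-averaged fiber velocity and per-phase speeds
#'
#' During exhale the shirt moves root-to-tip (low hair friction), giving the
#' faster phase speed U+; during inhale it moves tip-to-root (against the
#' cuticle scale edges), giving the slower U-. With equal phase durations
#' the cycle-averaged drift toward the navel is u_bar = (U+ - U-) / 2 =
#' (mu_HL_minus - mu_HL_plus) * F_N / (2 * eta * l), independent of the
#' shirt--lint coefficient, which cancels between the phases.
#'
#' @param params A `lint_params` object.
#' @return An object of class `velocity_pair` with fields `U_plus`,
#'   `U_minus`, `u_bar` (m/s) and `dx_cycle = u_bar * T` (m), the net
#'   ratchet advance per breathing cycle.
#' @examples
#' mean_velocity(default_params())$u_bar   # ~2.7e-5 m/s
#' @export
mean_velocity <- function(params) {
  stopifnot(inherits(params, "lint_params"))
  fr <- params$friction; g <- params$garment
  F_N <- as.numeric(normal_force(g$p, params$geometry, g$alpha))
  U_plus <- phase_velocity(fr$mu_SL, fr$mu_HL_plus, F_N, g$eta,
                           params$geometry$l)
  U_minus <- phase_velocity(fr$mu_SL, fr$mu_HL_minus, F_N, g$eta,
                            params$geometry$l)
  u_bar <- (U_plus - U_minus) / 2
  if (u_bar < 0)
    stop("u_bar < 0: lint would migrate away from the navel (mu_HL_minus < mu_HL_plus)",
         call. = FALSE)
  structure(list(U_plus = U_plus, U_minus = U_minus, u_bar = u_bar,
                 dx_cycle = u_bar * params$transport$T),
            class = "velocity_pair")
}

#' @export
print.velocity_pair <- function(x, ...) {
  cat(sprintf("Phase velocities: U+ = %.4g m/s, U- = %.4g m/s\n",
              x$U_plus, x$U_minus))
  cat(sprintf("Cycle average:    u_bar = %.4g m/s (%.4g m per cycle)\n",
              x$u_bar, x$dx_cycle))
  invisible(x)
}

#' Mass of a single lint fiber
#'
#' Treats the fiber as a solid cylinder: m_L = rho * pi * d^2 * l / 4.
#'
#' @param geometry A [fiber_geometry()], or any list with `d`, `l`, `rho`.
#' @return Fiber mass, kg.
#' @examples
#' fiber_mass(fiber_geometry())  # ~3.5e-11 kg
#' @export
fiber_mass <- function(geometry) {
  geometry$rho * pi * geometry$d^2 * geometry$l / 4
}

#' Full force balance on a sandwiched lint fiber
#'
#' Collects the interfacial normal force, both directional friction forces
#' and net tractions, the real contact area, the fabric tension and the
#' drag coefficient eta * l into one object.
#'
#' @param params A `lint_params` object.
#' @return An object of class `force_balance` with fields `F_N`, `F_S`,
#'   `F_H_plus`, `F_H_minus`, `F_T_plus`, `F_T_minus` (N), `A_c` (m^2),
#'   `gamma` (N/m) and `drag_coef` (= eta * l, N s/m).
#' @export
force_balance <- function(params) {
  stopifnot(inherits(params, "lint_params"))
  g <- params$garment; fr <- params$friction
  F_N <- normal_force(g$p, params$geometry, g$alpha)
  A_c <- attr(F_N, "A_c"); F_N <- as.numeric(F_N)
  F_S <- fr$mu_SL * F_N
  F_H_plus <- fr$mu_HL_plus * F_N
  F_H_minus <- fr$mu_HL_minus * F_N
  structure(list(
    F_N = F_N, F_S = F_S,
    F_H_plus = F_H_plus, F_H_minus = F_H_minus,
    F_T_plus = F_S - F_H_plus, F_T_minus = F_S - F_H_minus,
    A_c = A_c, gamma = fabric_tension(g$p, g$R),
    drag_coef = g$eta * params$geometry$l
  ), class = "force_balance")
}

#' @export
print.force_balance <- function(x, ...) {
  cat("Per-fiber force balance\n")
  cat(sprintf("  normal force F_N          %.4g N (contact area %.4g m^2)\n",
              x$F_N, x$A_c))
  cat(sprintf("  shirt friction F_S        %.4g N\n", x$F_S))
  cat(sprintf("  hair friction F_H (+/-)   %.4g / %.4g N\n",
              x$F_H_plus, x$F_H_minus))
  cat(sprintf("  net traction F_T (+/-)    %.4g / %.4g N\n",
              x$F_T_plus, x$F_T_minus))
  cat(sprintf("  fabric tension gamma      %.4g N/m\n", x$gamma))
  cat(sprintf("  drag coefficient eta*l    %.4g N s/m\n", x$drag_coef))
  invisible(x)
}
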