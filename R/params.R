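## Physical parameter set: construction, validation, unit-aware config I/O.
## Internal representation is strict SI throughout.

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}

chk_scalar <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(field, "must be a single finite number")
  invisible(x)
}

#' Lint fiber geometry
#'
#' Width, length and material density of a single lint fiber. Fibers are
#' slender cylinders dislodged from worn fabric; the default material is
#' cotton.
#'
#' @param d Fiber width (diameter), m. Default `1e-5` (10 um, typical of
#'   lint fibers seen in electron micrographs of navel fluff).
#' @param l Fiber length, m. Default `1e-3` (individual fibers are at least
#'   about a millimetre long).
#' @param rho Mass density of the fiber material, kg/m^3. Default 450
#'   (cotton).
#' @return An object of class `fiber_geometry`.
#' @examples
#' fiber_geometry()
#' @export
fiber_geometry <- function(d = 1e-5, l = 1e-3, rho = 450) {
  chk_scalar(d, "d"); chk_scalar(l, "l"); chk_scalar(rho, "rho")
  if (d <= 0) stop_invalid("d", "must be > 0")
  if (l <= 0) stop_invalid("l", "must be > 0")
  if (rho <= 0) stop_invalid("rho", "must be > 0")
  if (d >= l) stop_invalid("d", "fibers are slender: require d < l")
  structure(list(d = d, l = l, rho = rho), class = "fiber_geometry")
}

#' Kinetic friction coefficients
#'
#' The shirt--lint coefficient and the two directional hair--lint
#' coefficients. The overlapping cuticle scales of body hair run root-to-tip,
#' so sliding tip-to-root (against the scale edges) sees markedly higher
#' friction than sliding root-to-tip; this asymmetry is what rectifies the
#' breathing oscillation into net transport.
#'
#' @param mu_SL Shirt--lint kinetic friction coefficient. Must exceed
#'   `mu_HL_plus` or the shirt cannot drag the fiber forward at all.
#' @param mu_HL_plus Hair--lint coefficient, root-to-tip (low-friction)
#'   direction.
#' @param mu_HL_minus Hair--lint coefficient, tip-to-root (high-friction)
#'   direction; must be >= `mu_HL_plus`.
#' @return An object of class `friction_set`.
#' @export
friction_set <- function(mu_SL = 0.3, mu_HL_plus = 0.1, mu_HL_minus = 0.2) {
  chk_scalar(mu_SL, "mu_SL"); chk_scalar(mu_HL_plus, "mu_HL_plus")
  chk_scalar(mu_HL_minus, "mu_HL_minus")
  if (mu_SL < 0 || mu_HL_plus < 0 || mu_HL_minus < 0)
    stop_invalid("friction", "all coefficients must be >= 0")
  if (mu_HL_minus < mu_HL_plus)
    stop_invalid("mu_HL_minus",
                 "directional asymmetry requires mu_HL_minus >= mu_HL_plus")
  if (mu_SL <= mu_HL_plus)
    stop_invalid("mu_SL",
                 "forward sliding requires mu_SL > mu_HL_plus (else U+ = 0)")
  structure(list(mu_SL = mu_SL, mu_HL_plus = mu_HL_plus,
                 mu_HL_minus = mu_HL_minus), class = "friction_set")
}

#' Garment, skin and ambient-air parameters
#'
#' @param p Skin pressure exerted by the worn garment, Pa. Even loose
#'   clothing exerts of order 0.1 kPa during daytime activity.
#' @param R Longitudinal radius of curvature of the abdominal wall, m
#'   (about 0.47 m from MRI measurements). Links `p` to the fabric tension
#'   via the Laplace relation p = gamma / R.
#' @param alpha Ratio of real to projected lint--fabric contact area,
#'   dimensionless in (0, 1]. Real contact between rough surfaces is a tiny
#'   fraction of the apparent area; default `1e-5`.
#' @param eta Dynamic viscosity of air, Pa s.
#' @return An object of class `garment_skin`.
#' @export
garment_skin <- function(p = 100, R = 0.47, alpha = 1e-5, eta = 1.84e-5) {
  chk_scalar(p, "p"); chk_scalar(R, "R"); chk_scalar(alpha, "alpha")
  chk_scalar(eta, "eta")
  if (p <= 0) stop_invalid("p", "must be > 0")
  if (R <= 0) stop_invalid("R", "must be > 0")
  if (alpha <= 0 || alpha > 1) stop_invalid("alpha", "must satisfy 0 < alpha <= 1")
  if (eta <= 0) stop_invalid("eta", "must be > 0")
  structure(list(p = p, R = R, alpha = alpha, eta = eta),
            class = "garment_skin")
}

#' Transport-domain parameters
#'
#' The 1-D domain runs along the midline from the chest (x = 0) to the navel
#' (x = L); positive x is the root-to-tip hair direction, i.e. toward the
#' navel.
#'
#' @param L Domain length, m (default 0.1 m = 10 cm).
#' @param T Breathing-cycle period, s (default 6 s).
#' @param A Constant lint-fiber source rate, fibers m^-1 s^-1 (default 1;
#'   equivalently about one fiber added to the 10 cm domain every breath).
#' @param n0_level Constant initial fiber number density, fibers/m (default
#'   100, i.e. roughly one pre-existing fiber per body hair).
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(L = 0.1, T = 6, A = 1, n0_level = 100) {
  chk_scalar(L, "L"); chk_scalar(T, "T"); chk_scalar(A, "A")
  chk_scalar(n0_level, "n0_level")
  if (L <= 0) stop_invalid("L", "must be > 0")
  if (T <= 0) stop_invalid("T", "must be > 0")
  if (A < 0) stop_invalid("A", "must be >= 0")
  if (n0_level < 0) stop_invalid("n0_level", "must be >= 0")
  structure(list(L = L, T = T, A = A, n0_level = n0_level),
            class = "transport_params")
}

#' Full model parameter set
#'
#' Composition of [fiber_geometry()], [friction_set()], [garment_skin()] and
#' [transport_params()]. All values are SI.
#'
#' @param geometry A `fiber_geometry`.
#' @param friction A `friction_set`.
#' @param garment A `garment_skin`.
#' @param transport A `transport_params`.
#' @return An object of class `lint_params`.
#' @seealso [default_params()], [load_params()], [save_params()]
#' @export
lint_params <- function(geometry = fiber_geometry(),
                        friction = friction_set(),
                        garment = garment_skin(),
                        transport = transport_params()) {
  stopifnot(inherits(geometry, "fiber_geometry"),
            inherits(friction, "friction_set"),
            inherits(garment, "garment_skin"),
            inherits(transport, "transport_params"))
  structure(list(geometry = geometry, friction = friction,
                 garment = garment, transport = transport),
            class = "lint_params")
}

#' Nominal parameter values
#'
#' The reference parameter set in SI units: source rate A = 1 m^-1 s^-1,
#' fiber width 1e-5 m, fiber length 1e-3 m, domain L = 0.1 m, initial
#' density 100 m^-1, skin pressure 100 Pa, breathing period 6 s, contact
#' fraction 1e-5, air viscosity 1.84e-5 Pa s, root-to-tip hair--lint
#' friction 0.1, cotton density 450 kg/m^3; plus mu_HL_minus = 0.2 (twice
#' the root-to-tip value, reflecting the measured cuticle asymmetry),
#' mu_SL = 0.3 (cotton on hair) and abdominal radius of curvature
#' R = 0.47 m.
#'
#' @return A `lint_params` object.
#' @examples
#' p <- default_params()
#' p$garment$p      # 100 Pa
#' p$transport$T    # 6 s
#' @export
default_params <- function() {
  lint_params(
    geometry  = fiber_geometry(d = 1e-5, l = 1e-3, rho = 450),
    friction  = friction_set(mu_SL = 0.3, mu_HL_plus = 0.1, mu_HL_minus = 0.2),
    garment   = garment_skin(p = 100, R = 0.47, alpha = 1e-5, eta = 1.84e-5),
    transport = transport_params(L = 0.1, T = 6, A = 1, n0_level = 100)
  )
}

## field name -> parameter group, for flat config files
.param_field_map <- c(
  d = "geometry", l = "geometry", rho = "geometry",
  mu_SL = "friction", mu_HL_plus = "friction", mu_HL_minus = "friction",
  p = "garment", R = "garment", alpha = "garment", eta = "garment",
  L = "transport", T = "transport", A = "transport", n0_level = "transport"
)

## multiplicative SI conversion factors for units accepted in config files
.unit_factors <- c(
  "Pa" = 1, "kPa" = 1e3, "MPa" = 1e6,
  "m" = 1, "cm" = 1e-2, "mm" = 1e-3, "um" = 1e-6, "µm" = 1e-6,
  "s" = 1, "min" = 60, "hr" = 3600, "h" = 3600,
  "Pa.s" = 1, "Pa s" = 1, "Ns/m2" = 1, "N s/m^2" = 1,
  "kg/m3" = 1, "kg/m^3" = 1,
  "N/m" = 1, "1/m" = 1, "/m" = 1, "1/(m s)" = 1, "1/m/s" = 1
)

#' Parse a numeric value with an optional unit suffix
#'
#' Accepts plain numbers (taken as SI) or strings like `"0.1 kPa"`,
#' `"10 cm"`, `"6 s"`. Only fixed multiplicative units are supported.
#'
#' @param x A number, or a string `"<number> <unit>"`.
#' @param field Field name, used in error messages.
#' @return The value in SI units.
#' @keywords internal
parse_quantity <- function(x, field = "value") {
  if (is.numeric(x)) {
    chk_scalar(x, field)
    return(as.numeric(x))
  }
  if (!is.character(x) || length(x) != 1L)
    stop_invalid(field, "must be a number or a '<number> <unit>' string")
  s <- trimws(x)
  m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*(.*)$", s))[[1]]
  if (length(m) != 3L || is.na(suppressWarnings(val <- as.numeric(m[2]))))
    stop_invalid(field, sprintf("cannot parse quantity '%s'", x))
  unit <- trimws(m[3])
  if (!nzchar(unit)) return(val)
  if (!unit %in% names(.unit_factors))
    stop_invalid(field, sprintf("unknown unit '%s'", unit))
  val * unname(.unit_factors[unit])
}

#' Load a parameter set from a flat config file
#'
#' Reads a flat YAML file whose keys are exactly the parameter field names
#' (`d`, `l`, `rho`, `mu_SL`, `mu_HL_plus`, `mu_HL_minus`, `p`, `R`,
#' `alpha`, `eta`, `L`, `T`, `A`, `n0_level`). Values may be plain SI
#' numbers or strings carrying a unit (e.g. `p: 0.1 kPa`, `L: 10 cm`).
#' Precedence is defaults < file < `overrides`. The merged set is validated
#' against every type invariant.
#'
#' @param path Path to the config file. An empty file yields
#'   [default_params()].
#' @param overrides Named list of field overrides (numbers or unit strings),
#'   applied after the file.
#' @return A validated `lint_params` object.
#' @export
load_params <- function(path, overrides = list()) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must be a flat key/value mapping",
                          call. = FALSE)
  merge_fields(raw, overrides)
}

## merge flat key/value sets onto defaults and rebuild (validating)
merge_fields <- function(...) {
  vals <- list(
    d = 1e-5, l = 1e-3, rho = 450,
    mu_SL = 0.3, mu_HL_plus = 0.1, mu_HL_minus = 0.2,
    p = 100, R = 0.47, alpha = 1e-5, eta = 1.84e-5,
    L = 0.1, T = 6, A = 1, n0_level = 100
  )
  for (layer in list(...)) {
    if (length(layer) == 0L) next
    if (is.null(names(layer)) || any(!nzchar(names(layer))))
      stop("all config entries must be named", call. = FALSE)
    for (key in names(layer)) {
      if (!key %in% names(.param_field_map))
        stop(sprintf("unknown parameter key '%s'", key), call. = FALSE)
      vals[[key]] <- parse_quantity(layer[[key]], key)
    }
  }
  lint_params(
    geometry  = fiber_geometry(vals$d, vals$l, vals$rho),
    friction  = friction_set(vals$mu_SL, vals$mu_HL_plus, vals$mu_HL_minus),
    garment   = garment_skin(vals$p, vals$R, vals$alpha, vals$eta),
    transport = transport_params(vals$L, vals$T, vals$A, vals$n0_level)
  )
}

#' Flatten a parameter set to a named SI vector
#'
#' @param params A `lint_params` object.
#' @return Named numeric vector of the 14 SI parameter values.
#' @export
params_flat <- function(params) {
  stopifnot(inherits(params, "lint_params"))
  c(d = params$geometry$d, l = params$geometry$l, rho = params$geometry$rho,
    mu_SL = params$friction$mu_SL, mu_HL_plus = params$friction$mu_HL_plus,
    mu_HL_minus = params$friction$mu_HL_minus,
    p = params$garment$p, R = params$garment$R,
    alpha = params$garment$alpha, eta = params$garment$eta,
    L = params$transport$L, T = params$transport$T, A = params$transport$A,
    n0_level = params$transport$n0_level)
}

#' Save a parameter set to a flat config file
#'
#' Writes the resolved SI values as flat `key: value` YAML. Values are
#' written with 17 significant digits so a save/load round trip reproduces
#' every field bit-exactly.
#'
#' @param params A `lint_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_params <- function(params, path) {
  v <- params_flat(params)
  lines <- sprintf("%s: %.17g", names(v), v)
  writeLines(lines, path)
  invisible(path)
}

#' JSON dump of the resolved SI parameter set
#'
#' @param params A `lint_params` object.
#' @return A JSON string (flat object, SI values).
#' @export
params_json <- function(params) {
  jsonlite::toJSON(as.list(params_flat(params)), auto_unbox = TRUE,
                   digits = NA)
}

#' @export
print.lint_params <- function(x, ...) {
  cat("Lint transport model parameters (SI)\n")
  v <- params_flat(x)
  cat(paste(sprintf("  %-12s %g", names(v), v), collapse = "\n"), "\n")
  invisible(x)
}
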