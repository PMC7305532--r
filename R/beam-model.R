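# Simply-supported-beam model of the second sequential loop.
#
# The archwire segment between the two anchorage teeth is an Euler-Bernoulli
# beam on simple supports, loaded by a point force P at the bracket of the
# target tooth (x = a, measured from the distal support). The orthodontic
# force F on the tooth is the reaction to P. Deflections are negative
# root-ward in the math; forces are reported as magnitudes.

#' Bending moment of the loaded second sequential loop
#'
#' Piecewise-linear bending moment of a simply supported beam with a point
#' load P at `x = a`: `M(x) = (P b / l) x` for `0 <= x <= a` and
#' `M(x) = (P b / l) x - P (x - a)` for `a <= x <= l`. Both branches agree at
#' `x = a` and the moment vanishes at both supports.
#'
#' @param x_mm Position(s) along the beam in mm, measured from the distal
#'   anchorage support; must lie in `[0, l]`.
#' @param P Applied load in N.
#' @param geometry A [loop_geometry()].
#' @return Bending moment in N.m (same length as `x_mm`).
#' @export
bending_moment <- function(x_mm, P, geometry) {
  stopifnot(inherits(geometry, "loop_geometry"))
  x <- mm_to_m(x_mm)
  l <- geometry$l; a <- geometry$a; b <- geometry$b
  if (any(x < -1e-12 | x > l + 1e-12))
    stop_domain("domain error: x must lie in [0, l]")
  x <- pmin(pmax(x, 0), l)
  ifelse(x <= a, P * b / l * x, P * b / l * x - P * (x - a))
}

#' Deflection and slope profile of the loaded archwire
#'
#' Evaluates the closed-form deflection of the simply supported beam,
#' `v(x) = -(P b x / (6 E Iz l)) (l^2 - x^2 - b^2)` on `[0, a]` and
#' `v(x) = -(P b / (6 E Iz l)) [ (l/b)(x-a)^3 + (l^2 - b^2) x - x^3 ]` on
#' `[a, l]`, together with the slope (its derivative). The integration
#' constants are `C1 = C2 = -(P b / l)(l^2 - b^2) / (6 E Iz)` and
#' `D1 = D2 = 0`, fixed by `v(0) = v(l) = 0` and continuity at `x = a`.
#'
#' Exactly one of `P` or `d_mm` must be given; with `d_mm` the load is the one
#' producing a load-point deflection of `d_mm` under the profile itself, i.e.
#' the `"rederived"` stiffness of [theoretical_force()].
#'
#' @param spec An [archwire_spec()].
#' @param P Applied load in N.
#' @param d_mm Load-point deflection in mm (alternative to `P`).
#' @param n_points Number of evaluation positions over `[0, l]`.
#' @return A data frame of class `deflection_profile` with columns `x_mm`,
#'   `v_mm` (deflection, negative root-ward) and `theta` (slope, rad), with
#'   the integration constants in attribute `"constants"`.
#' @export
deflection_profile <- function(spec, P = NULL, d_mm = NULL, n_points = 201L) {
  stopifnot(inherits(spec, "archwire_spec"))
  if (is.null(P) == is.null(d_mm))
    stop_domain("give exactly one of 'P' (N) or 'd_mm' (mm)")
  if (is.null(P))
    P <- theoretical_force(spec, d_mm, variant = "rederived")
  g <- spec$geometry
  E <- spec$material$elastic_modulus
  Iz <- second_moment(spec$section)
  l <- g$l; a <- g$a; b <- g$b
  x <- seq(0, l, length.out = n_points)
  k <- P * b / (6 * E * Iz * l)
  v <- ifelse(x <= a,
              -k * x * (l^2 - x^2 - b^2),
              -k * ((l / b) * (x - a)^3 + (l^2 - b^2) * x - x^3))
  theta <- ifelse(x <= a,
                  -k * (l^2 - 3 * x^2 - b^2),
                  -k * (3 * (l / b) * (x - a)^2 + (l^2 - b^2) - 3 * x^2))
  out <- data.frame(x_mm = m_to_mm(x), v_mm = m_to_mm(v), theta = theta)
  attr(out, "constants") <- c(C = -(P * b / l) * (l^2 - b^2) / (6 * E * Iz), D = 0)
  attr(out, "load_N") <- P
  class(out) <- c("deflection_profile", "data.frame")
  out
}

#' Write a deflection profile as two-column CSV
#'
#' @param profile A [deflection_profile()].
#' @param path Output CSV path (columns `x_mm`, `v_mm`).
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "deflection_profile"))
  utils::write.csv(profile[, c("x_mm", "v_mm")], path, row.names = FALSE)
}

#' Theoretical (uncorrected) orthodontic force
#'
#' Force exerted by the archwire on the target tooth when the bracket is
#' displaced by `d`, from the simply-supported-beam model. Two variants are
#' provided:
#'
#' * `"printed"` (default): `F = 6 E Iz d / (a (l^2 - a^2 - b^2))`, the form
#'   used as the baseline of the published correction-factor calibration.
#' * `"rederived"`: `F = 3 E Iz l d / (a^2 b^2)`, the load-point stiffness
#'   implied by the deflection profile itself. The printed form drops a factor
#'   `b / l` when passing from the deflection equation to the load-point
#'   relation, so the two differ by `l / b` (a factor 2 when `a = b`); both
#'   are exposed and calibration records which one it used.
#'
#' Since `b = l - a`, the denominator term `l^2 - a^2 - b^2` equals `2 a b`
#' and is positive on the whole valid domain. F is linear in `d`, `E` and
#' `Iz`.
#'
#' @param spec An [archwire_spec()].
#' @param d_mm Displacement(s) of the bracket in mm (`d >= 0`).
#' @param variant `"printed"` or `"rederived"`.
#' @return Force(s) in N, same length as `d_mm`.
#' @examples
#' theoretical_force(parse_code("S16162010"), 1.0)
#' @export
theoretical_force <- function(spec, d_mm, variant = c("printed", "rederived")) {
  stopifnot(inherits(spec, "archwire_spec"))
  variant <- match.arg(variant)
  if (any(d_mm < 0)) stop_domain("domain error: displacement d must be >= 0")
  g <- spec$geometry
  E <- spec$material$elastic_modulus
  Iz <- second_moment(spec$section)
  d <- mm_to_m(d_mm)
  denom <- g$l^2 - g$a^2 - g$b^2   # = 2ab > 0 for 0 < a < l
  if (denom <= 0) stop_domain("degenerate geometry: l^2 - a^2 - b^2 <= 0")
  if (variant == "printed") {
    6 * E * Iz * d / (g$a * denom)
  } else {
    3 * E * Iz * g$l * d / (g$a^2 * g$b^2)
  }
}
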