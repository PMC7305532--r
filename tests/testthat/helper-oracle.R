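# Independent beam oracle: double numerical integration of v'' = M(x)/(E Iz)
# with v(0) = v(l) = 0 (trapezoidal cumulative integration on a fine grid).
# Used to cross-check the closed-form deflection profile and load-point
# stiffness; deliberately shares no code with deflection_profile().

cumtrapz_vec <- function(y, x) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

beam_oracle_deflection <- function(spec, P, n = 4001) {
  l <- spec$geometry$l
  x <- seq(0, l, length.out = n)
  EI <- spec$material$elastic_modulus * second_moment(spec$section)
  M <- bending_moment(x * 1000, P, spec$geometry)
  slope <- cumtrapz_vec(M / EI, x)    # v' up to an additive constant
  v <- cumtrapz_vec(slope, x)         # v up to a linear term
  v <- v - x * v[n] / l               # enforce v(l) = 0 (v(0) = 0 already)
  list(x = x, v = v)
}

# load-point compliance |v(a)| per unit load, by the oracle
beam_oracle_compliance <- function(spec, n = 4001) {
  o <- beam_oracle_deflection(spec, P = 1, n = n)
  abs(stats::approx(o$x, o$v, xout = spec$geometry$a)$y)
}

# random valid archwire spec for property tests
random_spec <- function() {
  l <- stats::runif(1, 12, 30)
  a <- stats::runif(1, 0.15, 0.85) * l
  geom <- loop_geometry(l, a)
  section <- if (stats::runif(1) < 0.5) {
    cross_section("round", diameter_mm = stats::runif(1, 0.3, 0.6))
  } else {
    cross_section("rectangular", depth_mm = stats::runif(1, 0.3, 0.6),
                  width_mm = stats::runif(1, 0.3, 0.7))
  }
  mat <- material("test alloy", stats::runif(1, 0.8e11, 2.2e11))
  archwire_spec("TEST00000", mat, section, geom)
}
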