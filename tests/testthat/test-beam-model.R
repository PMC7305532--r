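test_that("bending moment vanishes at the supports and is continuous at the load", {
  geom <- loop_geometry(20, 10)
  expect_equal(bending_moment(0, 1, geom), 0)
  expect_equal(bending_moment(20, 1, geom), 0)
  # P = 1 N, l = 20 mm, a = b = 10 mm, x = 10 mm -> (1 * 0.01 / 0.02) * 0.01
  expect_equal(bending_moment(10, 1, geom), 0.005)
  expect_error(bending_moment(21, 1, geom), "domain")
  set.seed(21)
  for (i in 1:10) {
    spec <- random_spec()
    a_mm <- spec$geometry$a * 1000
    left <- bending_moment(a_mm - 1e-9, 2.5, spec$geometry)
    right <- bending_moment(a_mm + 1e-9, 2.5, spec$geometry)
    expect_equal(left, right, tolerance = 1e-6)
    expect_true(bending_moment(a_mm, 2.5, spec$geometry) > 0)
  }
})

test_that("deflection satisfies boundary conditions and the load-point closed form", {
  spec <- parse_code("S16162010")
  prof <- deflection_profile(spec, P = 1, n_points = 1001)
  expect_equal(prof$v_mm[1], 0)
  expect_equal(prof$v_mm[nrow(prof)], 0, tolerance = 1e-12)
  # |v(a)| = P a^2 b^2 / (3 E Iz l), frozen from direct evaluation: 4.096e-4 m
  E <- spec$material$elastic_modulus; Iz <- second_moment(spec$section)
  g <- spec$geometry
  v_a <- approx(prof$x_mm, prof$v_mm, xout = g$a * 1000)$y / 1000
  expect_equal(abs(v_a), g$a^2 * g$b^2 / (3 * E * Iz * g$l), tolerance = 1e-6)
  expect_equal(abs(v_a), 4.096e-4, tolerance = 1e-3)
  expect_true(all(prof$v_mm[2:(nrow(prof) - 1)] < 0))  # root-ward sag
})

test_that("the two deflection branches agree at the load point for any valid case", {
  set.seed(31)
  for (i in 1:10) {
    spec <- random_spec()
    a_mm <- spec$geometry$a * 1000
    prof <- deflection_profile(spec, P = 1, n_points = 11)
    # evaluate both branch formulas directly at x = a
    E <- spec$material$elastic_modulus; Iz <- second_moment(spec$section)
    g <- spec$geometry
    k <- 1 * g$b / (6 * E * Iz * g$l)
    v1 <- -k * g$a * (g$l^2 - g$a^2 - g$b^2)
    v2 <- -k * ((g$l / g$b) * 0^3 + (g$l^2 - g$b^2) * g$a - g$a^3)
    expect_equal(v1, v2, tolerance = 1e-12)
  }
})

test_that("theoretical force matches its frozen reference values and is linear", {
  spec <- parse_code("S16162010")
  # frozen from direct SI evaluation of the two closed forms at d = 1 mm
  expect_equal(theoretical_force(spec, 1.0, "printed"), 1.2208, tolerance = 1e-4)
  expect_equal(theoretical_force(spec, 1.0, "rederived"), 2.4415, tolerance = 1e-4)
  expect_equal(theoretical_force(spec, 0), 0)
  # superposition and variant ratio l/b
  set.seed(41)
  for (i in 1:10) {
    s <- random_spec()
    d1 <- runif(1, 0.1, 3); d2 <- runif(1, 0.1, 3)
    expect_equal(theoretical_force(s, d1 + d2),
                 theoretical_force(s, d1) + theoretical_force(s, d2))
    expect_equal(theoretical_force(s, d1, "rederived") /
                   theoretical_force(s, d1, "printed"),
                 s$geometry$l / s$geometry$b)
  }
})

test_that("force decreases with anchorage distance and increases with stiffness", {
  base <- parse_code("S16162010")
  f <- function(l_mm) {
    geom <- loop_geometry(l_mm, l_mm / 2)  # fixed a/l ratio
    theoretical_force(archwire_spec("X", base$material, base$section, geom), 1)
  }
  ls <- seq(16, 30, by = 2)
  expect_true(all(diff(sapply(ls, f)) < 0))
  stiffer <- archwire_spec("X", material("stiff", 2.5e11), base$section, base$geometry)
  expect_gt(theoretical_force(stiffer, 1), theoretical_force(base, 1))
  thicker <- archwire_spec("X", base$material,
                           cross_section("rectangular", depth_mm = 0.5, width_mm = 0.5),
                           base$geometry)
  expect_gt(theoretical_force(thicker, 1), theoretical_force(base, 1))
})

test_that("closed-form profile and stiffness agree with double numerical integration", {
  set.seed(51)
  for (i in 1:12) {
    spec <- random_spec()
    P <- runif(1, 0.5, 5)
    oracle <- beam_oracle_deflection(spec, P)
    prof <- deflection_profile(spec, P = P, n_points = length(oracle$x))
    scale <- max(abs(oracle$v))
    expect_lt(max(abs(prof$v_mm / 1000 - oracle$v)) / scale, 0.005)
    # load recovered from an imposed displacement matches the rederived stiffness
    d_mm <- runif(1, 0.5, 5)
    load_from_oracle <- (d_mm / 1000) / beam_oracle_compliance(spec)
    expect_equal(load_from_oracle,
                 theoretical_force(spec, d_mm, "rederived"),
                 tolerance = 0.005)
  }
})

test_that("a deflection profile exports as two-column CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile(deflection_profile(parse_code("S16162010"), d_mm = 1), path)
  out <- read.csv(path)
  expect_identical(names(out), c("x_mm", "v_mm"))
  expect_equal(nrow(out), 201)
})
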