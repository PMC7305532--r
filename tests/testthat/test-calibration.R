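test_that("deviation and correction rates follow their definitions", {
  spec <- parse_code("S16162010")
  d <- c(1, 2, 3)
  f_theo <- theoretical_force(spec, d, "printed")
  # measured exactly half the theoretical force: deviation -100%, correction -50%
  tab <- measurement_table(d, list(S16162010 = f_theo / 2))
  rec <- correction_rates(tab, "printed")
  expect_equal(rec$deviation_rate, rep(-100, 3))
  expect_equal(rec$correction_rate, rep(-50, 3))
  # measured equal to theory: both rates zero
  tab0 <- measurement_table(d, list(S16162010 = f_theo))
  rec0 <- correction_rates(tab0, "printed")
  expect_equal(rec0$deviation_rate, rep(0, 3))
  expect_equal(rec0$correction_rate, rep(0, 3))
})

test_that("zero-force cells are excluded from the rate records", {
  spec <- parse_code("S16162010")
  d <- c(0, 1, 2)
  tab <- measurement_table(d, list(S16162010 = c(0, 0.5, 1.0)))
  expect_message(rec <- correction_rates(tab), "excluding 1")
  expect_equal(nrow(rec), 2)
  expect_true(all(rec$displacement_mm > 0))
})

test_that("correction and deviation rates satisfy their algebraic identity", {
  rec <- correction_rates(builtin_table1(), "printed")
  expect_equal((1 + rec$correction_rate / 100) * (1 - rec$deviation_rate / 100),
               rep(1, nrow(rec)))
})

test_that("the published correction functions evaluate to their frozen values", {
  pc <- printed_coefficients()
  # frozen from direct arithmetic on the published coefficients
  expect_equal(eval_K(pc, "l", 20), 1.18071, tolerance = 1e-6)
  expect_equal(eval_K(pc, "a", 10), 1.19121, tolerance = 1e-6)
  expect_equal(eval_K(pc, "S", 2.2733e-15), 1.2373101, tolerance = 1e-6)
  expect_equal(eval_K(pc, "M", 1.79e11), 1.1865818, tolerance = 1e-6)
  # root of the anchorage percent line
  expect_equal(eval_K(pc, "l", 62.561 / 2.2245), 1)
  expect_error(eval_K(pc, "S", -1e-15), "positive")
})

test_that("fitting a noiseless in-class table recovers the coefficients exactly", {
  truth <- default_true_coefficients()
  tab <- exact_table(truth)
  fit <- fit_correction_functions(tab, variant = truth$variant)
  for (part in c("kfl", "kfa", "kfs", "kfm")) {
    expect_equal(fit[[part]], truth[[part]], tolerance = 1e-8)
  }
  # material group: 2 points, 2 parameters -> exactly determined, zero residual
  diag <- fit$diagnostics$fit
  expect_equal(diag$resid_sd[diag$group == "material"], 0)
})

test_that("group classification reproduces the published comparison design", {
  fit <- suppressMessages(fit_correction_functions(builtin_table1()))
  groups <- fit$diagnostics$groups
  expect_setequal(groups$anchorage,
                  c("S16162010", "S16162210", "S16162410", "S16162610"))
  expect_setequal(groups$offset,
                  c("S16162010", "S16162009", "S16162008", "S20102007"))
  expect_setequal(groups$section, c("S16162010", "S18252010", "S00162010"))
  expect_setequal(groups$material, c("S16162010", "A16162010"))
  # measured forces fall with anchorage distance faster than the beam model:
  # the fitted anchorage correction decreases in l
  expect_lt(fit$kfl[["l"]], 0)
})

test_that("a missing comparison group fails with the group named", {
  tab <- builtin_table1()
  no_section <- tab[, !names(tab) %in% c("S18252010", "S00162010")]
  class(no_section) <- class(tab)
  expect_error(suppressMessages(fit_correction_functions(no_section)), "section group")
  no_material <- tab[, names(tab) != "A16162010"]
  class(no_material) <- class(tab)
  expect_error(suppressMessages(fit_correction_functions(no_material)), "material group")
})

test_that("the composed factor reduces to K_Fl(l_ref) at the reference archwire", {
  ref <- parse_code("S16162010")
  pc <- printed_coefficients()
  expect_equal(compose_KF(ref, pc), unname(eval_K(pc, "l", 20)))
  expect_equal(compose_KF(ref, pc), 1.18071, tolerance = 1e-6)
  fit <- suppressMessages(fit_correction_functions(builtin_table1()))
  expect_equal(compose_KF(parse_code("S16162010"), fit),
               unname(eval_K(fit, "l", 20)))
})

test_that("a material-only change composes as a ratio of K_FM values", {
  pc <- printed_coefficients()
  aus <- parse_code("A16162010")
  expect_equal(compose_KF(aus, pc),
               unname(eval_K(pc, "l", 20) *
                        eval_K(pc, "M", 1.57e11) / eval_K(pc, "M", 1.79e11)))
})

test_that("coefficients serialize to JSON and back unchanged", {
  fit <- suppressMessages(fit_correction_functions(builtin_table1()))
  path <- withr::local_tempfile(fileext = ".json")
  write_coefficients(fit, path)
  back <- read_coefficients(path)
  for (part in c("kfl", "kfa", "kfs", "kfm", "base")) {
    expect_equal(back[[part]], fit[[part]])
  }
  expect_identical(back$variant, fit$variant)
  expect_identical(back$convention, fit$convention)
  spec <- parse_code("S16162210")
  expect_equal(compose_KF(spec, back), compose_KF(spec, fit))
})

test_that("composition warns when extrapolating beyond the fitted ranges", {
  fit <- suppressMessages(fit_correction_functions(builtin_table1()))
  wide <- parse_code("S16163010")  # l = 30 mm, beyond the 20-26 mm fit range
  expect_warning(compose_KF(wide, fit), "extrapolating")
  expect_silent(compose_KF(parse_code("S16162210"), fit))
})
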