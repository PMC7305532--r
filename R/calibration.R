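# Empirical correction-factor calibration.
#
# The beam model systematically misses the measured forces (bracket friction,
# residual bending stress, ligation). The correction factor K_F reconciles
# them: per-archwire correction rates (percent excess of measured over
# theoretical force) are fitted, one comparison group at a time, as functions
# of the anchorage distance (linear), offset distance (quadratic), section
# second moment (linear in log) and elastic modulus (linear), then composed
# multiplicatively with base normalization at the reference archwire:
#   K_F = K_Fl(l) * K_Fa(a)/K_Fa0 * K_FS(Iz)/K_FS0 * K_FM(E)/K_FM0.

#' Per-point deviation and correction rates
#'
#' For every (archwire, displacement) cell, compares the measured force with
#' the uncorrected theoretical force and reports the deviation rate
#' `100 (F_exp - F_theo) / F_exp` and the correction rate
#' `100 (F_exp - F_theo) / F_theo`. Cells where either force is zero (e.g.
#' `d = 0`) are excluded with a message.
#'
#' @param table A [measurement_table()] whose column names are parseable
#'   archwire codes.
#' @param variant Theoretical baseline variant, see [theoretical_force()].
#' @param materials Material library for [parse_code()].
#' @return Data frame with columns `code`, `displacement_mm`, `f_theo`,
#'   `f_exp`, `deviation_rate`, `correction_rate` (rates in percent).
#' @export
correction_rates <- function(table, variant = c("printed", "rederived"),
                             materials = default_materials()) {
  validate_table(table)
  variant <- match.arg(variant)
  codes <- table_codes(table)
  records <- do.call(rbind, lapply(codes, function(code) {
    spec <- parse_code(code, materials)
    data.frame(code = code,
               displacement_mm = table$displacement_mm,
               f_theo = theoretical_force(spec, table$displacement_mm, variant),
               f_exp = table[[code]])
  }))
  bad <- records$f_theo <= 0 | records$f_exp <= 0
  if (any(bad)) {
    message("excluding ", sum(bad),
            " cell(s) with zero force (rates undefined there)")
    records <- records[!bad, ]
  }
  records$deviation_rate <- 100 * (records$f_exp - records$f_theo) / records$f_exp
  records$correction_rate <- 100 * (records$f_exp - records$f_theo) / records$f_theo
  rownames(records) <- NULL
  records
}

new_correction_coefficients <- function(variant, convention, kfl, kfa, kfs, kfm,
                                        base, reference, ranges = NULL,
                                        diagnostics = NULL, source = "fitted",
                                        aggregate = "mean") {
  structure(
    list(variant = variant, convention = convention,
         kfl = kfl, kfa = kfa, kfs = kfs, kfm = kfm,
         base = base, reference = reference, ranges = ranges,
         diagnostics = diagnostics, source = source, aggregate = aggregate),
    class = "correction_coefficients"
  )
}

#' @export
print.correction_coefficients <- function(x, ...) {
  cat(sprintf("<correction_coefficients> source: %s, baseline variant: %s, convention: %s\n",
              x$source, x$variant, x$convention))
  cat(sprintf("  K_Fl(l mm)      = 1 + (%+.5g l %+.5g)/100\n", x$kfl[["l"]], x$kfl[["intercept"]]))
  cat(sprintf("  K_Fa(a mm)      = 1 + (%+.5g a^2 %+.5g a %+.5g)/100\n",
              x$kfa[["a2"]], x$kfa[["a"]], x$kfa[["intercept"]]))
  cat(sprintf("  K_FS(Iz m^4)    = 1 + (%+.5g ln(Iz*1e15) %+.5g)/100\n",
              x$kfs[["lnI"]], x$kfs[["intercept"]]))
  cat(sprintf("  K_FM(E Pa)      = 1 + (%+.5g E*1e-10 %+.5g)/100\n",
              x$kfm[["E10"]], x$kfm[["intercept"]]))
  cat(sprintf("  base (%s): K_Fa0 = %.5f, K_FS0 = %.5f, K_FM0 = %.5f\n",
              x$reference$code, x$base[["kfa0"]], x$base[["kfs0"]], x$base[["kfm0"]]))
  invisible(x)
}

#' Evaluate one correction-coefficient function
#'
#' Evaluates a single-parameter correction function `K = 1 + percent/100` at
#' a raw parameter value. Unit conventions: `l` and `a` in mm; `S` takes the
#' second moment Iz in m^4 (transformed internally to `ln(Iz * 1e15)`); `M`
#' takes the elastic modulus E in Pa (scaled internally by `1e-10`).
#'
#' @param coeffs A `correction_coefficients` object (fitted via
#'   [fit_correction_functions()] or the published set via
#'   [printed_coefficients()]).
#' @param parameter One of `"l"`, `"a"`, `"S"`, `"M"`.
#' @param value Parameter value(s) in the units above.
#' @return Dimensionless K value(s).
#' @examples
#' eval_K(printed_coefficients(), "l", 20)
#' @export
eval_K <- function(coeffs, parameter = c("l", "a", "S", "M"), value) {
  stopifnot(inherits(coeffs, "correction_coefficients"))
  parameter <- match.arg(parameter)
  pct <- switch(parameter,
    l = coeffs$kfl[["intercept"]] + coeffs$kfl[["l"]] * value,
    a = coeffs$kfa[["intercept"]] + coeffs$kfa[["a"]] * value +
        coeffs$kfa[["a2"]] * value^2,
    S = {
      if (any(value <= 0)) stop_domain("domain error: Iz must be positive")
      coeffs$kfs[["intercept"]] + coeffs$kfs[["lnI"]] * log(value * 1e15)
    },
    M = coeffs$kfm[["intercept"]] + coeffs$kfm[["E10"]] * value * 1e-10
  )
  1 + pct / 100
}

reference_parameters <- function(spec) {
  list(code = spec$code,
       l_mm = m_to_mm(spec$geometry$l),
       a_mm = m_to_mm(spec$geometry$a),
       Iz = second_moment(spec$section),
       E = spec$material$elastic_modulus)
}

compute_base <- function(coeffs, reference) {
  c(kfa0 = unname(eval_K(coeffs, "a", reference$a_mm)),
    kfs0 = unname(eval_K(coeffs, "S", reference$Iz)),
    kfm0 = unname(eval_K(coeffs, "M", reference$E)))
}

#' The published correction coefficients
#'
#' The correction-coefficient functions exactly as published:
#' `K_Fl = 1 + (-2.2245 l + 62.561)/100` (l in mm),
#' `K_Fa = 1 + (8.555 a^2 - 153.941 a + 703.031)/100` (a in mm),
#' `K_FS = 1 + (-36.5 ln(Iz * 1e15) + 53.706)/100` (Iz in m^4),
#' `K_FM = 1 + (-0.1068 E * 1e-10 + 20.5699)/100` (E in Pa),
#' with base values evaluated at the reference archwire S16162010 under
#' `materials`. They are provided as published, for arithmetic on the printed
#' functions; the elastic moduli and baseline conventions behind them are not
#' stated in the source, so refitting via [fit_correction_functions()] is the
#' normative calibration path.
#'
#' @param materials Material library for the reference archwire.
#' @return A `correction_coefficients` object with `source = "printed"`.
#' @export
printed_coefficients <- function(materials = default_materials()) {
  reference <- reference_parameters(parse_code("S16162010", materials))
  out <- new_correction_coefficients(
    variant = "printed", convention = "multiply",
    kfl = c(intercept = 62.561, l = -2.2245),
    kfa = c(intercept = 703.031, a = -153.941, a2 = 8.555),
    kfs = c(intercept = 53.706, lnI = -36.5),
    kfm = c(intercept = 20.5699, E10 = -0.1068),
    base = c(kfa0 = NA_real_, kfs0 = NA_real_, kfm0 = NA_real_),
    reference = reference, source = "printed")
  out$base <- compute_base(out, reference)
  out
}

# Classify each archwire of a panel into the single-parameter comparison group
# it belongs to, relative to the reference archwire. Priority when several
# parameters differ (the published S20102007 differs in both offset and
# section): anchorage, then offset, then section, then material.
classify_groups <- function(specs, reference_code) {
  ref <- specs[[reference_code]]
  groups <- list(anchorage = reference_code, offset = reference_code,
                 section = reference_code, material = reference_code)
  # relative comparison: parameter magnitudes range from 1e-15 (Iz) to 1e11 (E)
  eq <- function(x, y) abs(x - y) <= 1e-9 * max(abs(x), abs(y))
  for (code in setdiff(names(specs), reference_code)) {
    s <- specs[[code]]
    same_l <- eq(s$geometry$l, ref$geometry$l)
    same_a <- eq(s$geometry$a, ref$geometry$a)
    same_I <- eq(second_moment(s$section), second_moment(ref$section))
    same_E <- eq(s$material$elastic_modulus, ref$material$elastic_modulus)
    g <- if (!same_l) "anchorage" else if (!same_a) "offset"
         else if (!same_I) "section" else if (!same_E) "material" else NA
    if (is.na(g)) {
      message("archwire ", code, " does not differ from the reference; left out of all groups")
      next
    }
    mixed <- sum(!c(same_l, same_a, same_I, same_E)) > 1L
    if (mixed)
      message("archwire ", code, " differs from the reference in more than one ",
              "parameter; assigned to the ", g, " group")
    groups[[g]] <- c(groups[[g]], code)
  }
  groups
}

fit_group <- function(rates, x, formula_terms, group, n_params) {
  if (length(x) < n_params)
    stop_domain("fit error: ", group, " group has ", length(x),
                " archwire(s) but the ", group, " function needs ", n_params,
                " coefficients")
  df <- data.frame(rate = rates, x = x)
  fit <- stats::lm(stats::as.formula(paste("rate ~", formula_terms)), data = df)
  dof <- length(x) - n_params
  list(coef = stats::coef(fit),
       resid_sd = if (dof > 0) sqrt(sum(stats::resid(fit)^2) / dof) else 0,
       n = length(x))
}

#' Fit the four correction-coefficient functions to a measurement table
#'
#' Computes per-archwire summary correction rates against the chosen
#' theoretical baseline, splits the panel into the four single-parameter
#' comparison groups relative to the reference archwire, and fits by ordinary
#' least squares: rate vs anchorage distance l (linear, mm), vs offset
#' distance a (quadratic, mm), vs `ln(Iz * 1e15)` (linear), and vs `E * 1e-10`
#' (linear). Base values are the fitted functions evaluated at the reference
#' archwire's parameters.
#'
#' @param table A [measurement_table()] containing the reference archwire and
#'   at least enough archwires per group to determine each fit.
#' @param variant Theoretical baseline, see [theoretical_force()]; stored with
#'   the coefficients ([validate_model()] refuses to mix variants).
#' @param materials Material library.
#' @param reference_code Code of the reference archwire used for base
#'   normalization (default `"S16162010"`).
#' @param aggregate Per-archwire summary of the per-displacement correction
#'   rates: `"mean"` (default) or `"median"`.
#' @param groups Optional explicit group assignment: named list with elements
#'   `anchorage`, `offset`, `section`, `material`, each a character vector of
#'   codes (the reference is included automatically). Default: automatic
#'   classification by which single parameter differs from the reference.
#' @param convention How the composed factor is applied by
#'   [corrected_force()]: `"multiply"` (default; consistent with the
#'   correction-rate definition) or `"divide"`.
#' @return A `correction_coefficients` object carrying the fitted
#'   coefficients, base values, parameter ranges of the fit, per-group
#'   diagnostics (n, residual sd) and per-archwire summary rates.
#' @examples
#' fit_correction_functions(builtin_table1())
#' @export
fit_correction_functions <- function(table, variant = c("printed", "rederived"),
                                     materials = default_materials(),
                                     reference_code = "S16162010",
                                     aggregate = c("mean", "median"),
                                     groups = NULL,
                                     convention = c("multiply", "divide")) {
  validate_table(table)
  variant <- match.arg(variant)
  aggregate <- match.arg(aggregate)
  convention <- match.arg(convention)
  codes <- table_codes(table)
  if (!reference_code %in% codes)
    stop_domain("fit error: reference archwire ", reference_code,
                " is not a column of the table")
  specs <- lapply(codes, parse_code, materials = materials)
  names(specs) <- codes

  records <- correction_rates(table, variant, materials)
  agg_fun <- if (aggregate == "mean") mean else stats::median
  rate_by_code <- tapply(records$correction_rate, records$code, agg_fun)

  if (is.null(groups)) {
    groups <- classify_groups(specs, reference_code)
  } else {
    if (!all(c("anchorage", "offset", "section", "material") %in% names(groups)))
      stop_domain("fit error: explicit 'groups' must name anchorage, offset, section and material")
    groups <- lapply(groups, function(g) union(reference_code, g))
  }
  missing <- setdiff(unique(unlist(groups)), codes)
  if (length(missing) > 0)
    stop_domain("fit error: group archwires not in table: ",
                paste(missing, collapse = ", "))

  par_of <- function(code_set, f) vapply(specs[code_set], f, numeric(1))
  l_mm <- par_of(groups$anchorage, function(s) m_to_mm(s$geometry$l))
  a_mm <- par_of(groups$offset, function(s) m_to_mm(s$geometry$a))
  lnI  <- par_of(groups$section, function(s) log(second_moment(s$section) * 1e15))
  E10  <- par_of(groups$material, function(s) s$material$elastic_modulus * 1e-10)

  fl <- fit_group(rate_by_code[groups$anchorage], l_mm, "x", "anchorage", 2L)
  fa <- fit_group(rate_by_code[groups$offset], a_mm, "x + I(x^2)", "offset", 3L)
  fs <- fit_group(rate_by_code[groups$section], lnI, "x", "section", 2L)
  fm <- fit_group(rate_by_code[groups$material], E10, "x", "material", 2L)

  reference <- reference_parameters(specs[[reference_code]])
  out <- new_correction_coefficients(
    variant = variant, convention = convention,
    kfl = c(intercept = unname(fl$coef[1]), l = unname(fl$coef[2])),
    kfa = c(intercept = unname(fa$coef[1]), a = unname(fa$coef[2]),
            a2 = unname(fa$coef[3])),
    kfs = c(intercept = unname(fs$coef[1]), lnI = unname(fs$coef[2])),
    kfm = c(intercept = unname(fm$coef[1]), E10 = unname(fm$coef[2])),
    base = c(kfa0 = NA_real_, kfs0 = NA_real_, kfm0 = NA_real_),
    reference = reference,
    ranges = list(l_mm = range(l_mm), a_mm = range(a_mm),
                  Iz = range(exp(lnI) * 1e-15), E = range(E10 * 1e10)),
    diagnostics = list(
      groups = groups,
      fit = data.frame(group = c("anchorage", "offset", "section", "material"),
                       n = c(fl$n, fa$n, fs$n, fm$n),
                       resid_sd = c(fl$resid_sd, fa$resid_sd, fs$resid_sd,
                                    fm$resid_sd)),
      rates = data.frame(code = names(rate_by_code),
                         rate = as.numeric(rate_by_code))),
    source = "fitted", aggregate = aggregate)
  out$base <- compute_base(out, reference)
  out
}

#' Compose the overall correction factor K_F for an archwire
#'
#' `K_F = K_Fl(l) * K_Fa(a)/K_Fa0 * K_FS(Iz)/K_FS0 * K_FM(E)/K_FM0`, where
#' the base values are the single-parameter functions evaluated at the
#' reference archwire. At the reference archwire itself the three ratios
#' cancel and `K_F = K_Fl(l_ref)`.
#'
#' @param spec An [archwire_spec()].
#' @param coeffs A `correction_coefficients` object.
#' @param warn_extrapolation Warn when a parameter of `spec` falls outside the
#'   range the coefficients were fitted on (only when ranges are recorded).
#' @return Dimensionless composed correction factor.
#' @export
compose_KF <- function(spec, coeffs, warn_extrapolation = TRUE) {
  stopifnot(inherits(spec, "archwire_spec"),
            inherits(coeffs, "correction_coefficients"))
  p <- reference_parameters(spec)
  if (warn_extrapolation && !is.null(coeffs$ranges)) {
    chk <- function(value, range, what) {
      if (value < range[1] - 1e-9 || value > range[2] + 1e-9)
        warning("extrapolating ", what, " = ", signif(value, 6),
                " beyond the fitted range [", signif(range[1], 6), ", ",
                signif(range[2], 6), "]", call. = FALSE)
    }
    chk(p$l_mm, coeffs$ranges$l_mm, "anchorage distance (mm)")
    chk(p$a_mm, coeffs$ranges$a_mm, "offset distance (mm)")
    chk(p$Iz, coeffs$ranges$Iz, "second moment (m^4)")
    chk(p$E, coeffs$ranges$E, "elastic modulus (Pa)")
  }
  unname(eval_K(coeffs, "l", p$l_mm) *
         eval_K(coeffs, "a", p$a_mm) / coeffs$base[["kfa0"]] *
         eval_K(coeffs, "S", p$Iz) / coeffs$base[["kfs0"]] *
         eval_K(coeffs, "M", p$E) / coeffs$base[["kfm0"]])
}

#' Serialize correction coefficients to JSON
#'
#' @param coeffs A `correction_coefficients` object.
#' @param path Output JSON path.
#' @seealso [read_coefficients()]
#' @export
write_coefficients <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "correction_coefficients"))
  jsonlite::write_json(coefficients_as_list(coeffs), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

# named coefficient vectors as JSON objects (jsonlite drops names of
# atomic vectors when writing arrays)
coefficients_as_list <- function(coeffs) {
  out <- unclass(coeffs)
  for (part in c("kfl", "kfa", "kfs", "kfm", "base"))
    out[[part]] <- as.list(out[[part]])
  out
}

#' Read correction coefficients from JSON
#'
#' @param path JSON path written by [write_coefficients()].
#' @return A `correction_coefficients` object.
#' @export
read_coefficients <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  diag <- raw$diagnostics
  if (!is.null(diag) && !is.null(diag$groups))
    diag$groups <- lapply(diag$groups, as.character)
  new_correction_coefficients(
    variant = raw$variant, convention = raw$convention,
    kfl = unlist(raw$kfl), kfa = unlist(raw$kfa),
    kfs = unlist(raw$kfs), kfm = unlist(raw$kfm),
    base = unlist(raw$base), reference = raw$reference,
    ranges = raw$ranges, diagnostics = diag,
    source = raw$source, aggregate = raw$aggregate %||% "mean")
}
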