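# Corrected prediction and error-rate validation.

#' Corrected orthodontic force prediction
#'
#' Applies the composed correction factor to the theoretical beam-model
#' force: `F = K_F(spec) * F_theo(spec, d)` under the `"multiply"` convention
#' (default; consistent with the correction-rate definition, under which
#' `F_theo * (1 + rate/100)` matches the measurement pointwise), or
#' `F = F_theo / K_F` under `"divide"`, exposed for fidelity experiments. The
#' theoretical baseline variant is the one stored in `coeffs`.
#'
#' @param spec An [archwire_spec()].
#' @param d_mm Displacement(s) in mm.
#' @param coeffs A `correction_coefficients` object.
#' @param warn_extrapolation Passed to [compose_KF()].
#' @return Predicted force(s) in N.
#' @examples
#' coeffs <- fit_correction_functions(builtin_table1())
#' corrected_force(parse_code("S16162010"), 2.5, coeffs)
#' @export
corrected_force <- function(spec, d_mm, coeffs, warn_extrapolation = TRUE) {
  stopifnot(inherits(coeffs, "correction_coefficients"))
  kf <- compose_KF(spec, coeffs, warn_extrapolation)
  f_theo <- theoretical_force(spec, d_mm, coeffs$variant)
  if (identical(coeffs$convention, "divide")) f_theo / kf else kf * f_theo
}

#' Relative error of a prediction, in percent
#'
#' `100 * |F_pred - F_exp| / F_exp`.
#'
#' @param f_pred Predicted force(s), N.
#' @param f_exp Measured force(s), N; must be positive.
#' @return Percent relative error(s).
#' @export
relative_error <- function(f_pred, f_exp) {
  if (any(f_exp <= 0)) stop_domain("domain error: measured force must be > 0")
  100 * abs(f_pred - f_exp) / f_exp
}

#' Validate corrected predictions against a measurement table
#'
#' Computes per-point percent relative errors of [corrected_force()] against
#' every cell of the table, per-archwire means over displacements, and the
#' min/max of those means across archwires. Rows with zero displacement are
#' skipped. Note that validating on the same table the coefficients were
#' fitted from (the published protocol; there is no holdout) measures
#' in-sample goodness of fit, not out-of-sample accuracy; the report records
#' this.
#'
#' @param table A [measurement_table()].
#' @param coeffs A `correction_coefficients` object.
#' @param materials Material library.
#' @param variant If given, must equal `coeffs$variant`; guards against
#'   accidentally mixing baselines.
#' @return An object of class `validation_report`: list with `per_point`
#'   (data frame `code`, `displacement_mm`, `f_exp`, `f_pred`, `rel_error`),
#'   `per_archwire` (data frame `code`, `mean_rel_error`), `min_mean_error`,
#'   `max_mean_error`, `min_point_error`, `max_point_error`, `coefficients`,
#'   and `in_sample` flag.
#' @examples
#' tab <- builtin_table1()
#' validate_model(tab, fit_correction_functions(tab))
#' @export
validate_model <- function(table, coeffs, materials = default_materials(),
                           variant = NULL) {
  validate_table(table)
  stopifnot(inherits(coeffs, "correction_coefficients"))
  if (!is.null(variant) && !identical(variant, coeffs$variant))
    stop_domain("variant mismatch: coefficients were calibrated against the '",
                coeffs$variant, "' baseline, not '", variant, "'")
  keep <- table$displacement_mm > 0
  if (!any(keep)) stop_domain("validation error: table has no nonzero displacements")
  codes <- table_codes(table)
  if (length(codes) == 0L) stop_domain("validation error: empty table")
  per_point <- do.call(rbind, lapply(codes, function(code) {
    spec <- parse_code(code, materials)
    f_pred <- corrected_force(spec, table$displacement_mm[keep], coeffs)
    f_exp <- table[[code]][keep]
    data.frame(code = code, displacement_mm = table$displacement_mm[keep],
               f_exp = f_exp, f_pred = f_pred,
               rel_error = relative_error(f_pred, f_exp))
  }))
  rownames(per_point) <- NULL
  means <- tapply(per_point$rel_error, per_point$code, mean)
  per_archwire <- data.frame(code = codes,
                             mean_rel_error = as.numeric(means[codes]))
  structure(
    list(per_point = per_point, per_archwire = per_archwire,
         min_mean_error = min(per_archwire$mean_rel_error),
         max_mean_error = max(per_archwire$mean_rel_error),
         min_point_error = min(per_point$rel_error),
         max_point_error = max(per_point$rel_error),
         coefficients = coeffs,
         in_sample = TRUE),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, digits = 3, ...) {
  cat("<validation_report>",
      if (isTRUE(x$in_sample)) "(in-sample: validated on the calibration data; no holdout)",
      "\n")
  cat(sprintf("  baseline variant: %s, convention: %s\n",
              x$coefficients$variant, x$coefficients$convention))
  df <- x$per_archwire
  df$mean_rel_error <- round(df$mean_rel_error, digits)
  print(df, row.names = FALSE)
  cat(sprintf("  per-archwire mean relative error: min %.*f%%, max %.*f%%\n",
              digits, x$min_mean_error, digits, x$max_mean_error))
  cat(sprintf("  per-point relative error:         min %.*f%%, max %.*f%%\n",
              digits, x$min_point_error, digits, x$max_point_error))
  invisible(x)
}

#' Export a validation report
#'
#' @param report A [validate_model()] report.
#' @param json_path Optional path for the full report as JSON.
#' @param csv_path Optional path for the per-point errors as CSV.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  if (!is.null(json_path)) {
    out <- unclass(report)
    out$coefficients <- coefficients_as_list(out$coefficients)
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
  }
  if (!is.null(csv_path))
    utils::write.csv(report$per_point, csv_path, row.names = FALSE)
  invisible(report)
}
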