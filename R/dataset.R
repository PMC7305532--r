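# Measurement tables: displacement x archwire grids of measured forces.

#' Construct a measurement table
#'
#' A displacement-by-archwire grid of measured orthodontic forces: one row
#' per displacement (mm, strictly increasing), one column per archwire naming
#' code, forces in N.
#'
#' @param displacement_mm Strictly increasing numeric vector of displacements.
#' @param forces Data frame or named list of numeric force vectors (N), one
#'   per archwire code, each the same length as `displacement_mm`.
#' @param replicate Optional single replicate index.
#' @return A data frame of class `measurement_table` with first column
#'   `displacement_mm`.
#' @export
measurement_table <- function(displacement_mm, forces, replicate = NULL) {
  forces <- as.data.frame(forces, check.names = FALSE, optional = TRUE)
  out <- cbind(data.frame(displacement_mm = displacement_mm), forces)
  attr(out, "replicate") <- replicate
  class(out) <- c("measurement_table", "data.frame")
  validate_table(out)
  out
}

validate_table <- function(table) {
  if (!is.data.frame(table) || ncol(table) < 2L || nrow(table) < 1L)
    stop_domain("format error: a measurement table needs a displacement column and at least one force column")
  if (names(table)[1] != "displacement_mm")
    stop_domain("format error: first column must be 'displacement_mm'")
  d <- table$displacement_mm
  if (!is.numeric(d) || anyNA(d) || any(diff(d) <= 0))
    stop_domain("format error: displacements must be numeric and strictly increasing")
  for (code in names(table)[-1]) {
    f <- table[[code]]
    if (!is.numeric(f) || anyNA(f))
      stop_domain("format error: non-numeric force cell in column '", code, "'")
    if (any(f < 0))
      stop_domain("format error: negative force in column '", code, "'")
  }
  invisible(table)
}

#' Archwire codes of a measurement table
#' @param table A [measurement_table()].
#' @return Character vector of column codes.
#' @export
table_codes <- function(table) setdiff(names(table), c("displacement_mm", "replicate"))

#' @export
print.measurement_table <- function(x, ...) {
  rep <- attr(x, "replicate")
  cat(sprintf("<measurement_table> %d displacements x %d archwires%s\n",
              nrow(x), length(table_codes(x)),
              if (is.null(rep)) "" else sprintf(" (replicate %s)", rep)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Read a measurement table from CSV
#'
#' Expects a comma-separated, dot-decimal file with header
#' `displacement_mm,<code1>,<code2>,...` and optionally a `replicate` column.
#' When a `replicate` column is present a list of per-replicate
#' `measurement_table`s is returned (in replicate order); otherwise a single
#' table.
#'
#' @param path CSV file path.
#' @return A [measurement_table()] or a list of them (one per replicate).
#' @export
load_table <- function(path) {
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop_domain("format error reading '", path, "': ",
                                    conditionMessage(e)))
  if (nrow(raw) == 0L || !"displacement_mm" %in% names(raw))
    stop_domain("format error: '", path,
                "' must have a 'displacement_mm' header column and data rows")
  for (j in seq_along(raw)) {
    if (!is.numeric(raw[[j]]))
      stop_domain("format error: non-numeric cell in column '", names(raw)[j],
                  "' of '", path, "'")
  }
  if ("replicate" %in% names(raw)) {
    reps <- split(raw, raw$replicate)
    lapply(reps, function(chunk) {
      if (anyDuplicated(chunk$displacement_mm))
        stop_domain("format error: duplicated displacement within replicate ",
                    chunk$replicate[1])
      chunk <- chunk[order(chunk$displacement_mm), ]
      measurement_table(chunk$displacement_mm,
                        chunk[setdiff(names(chunk), c("displacement_mm", "replicate"))],
                        replicate = chunk$replicate[1])
    })
  } else {
    if (anyDuplicated(raw$displacement_mm))
      stop_domain("format error: duplicated displacement in '", path, "'")
    measurement_table(raw$displacement_mm,
                      raw[setdiff(names(raw), "displacement_mm")])
  }
}

#' Write a measurement table to CSV
#'
#' @param table A [measurement_table()].
#' @param path Output path.
#' @param digits Optional number of decimal places to format force and
#'   displacement cells with (e.g. `2` reproduces the fixture formatting
#'   bit-identically); `NULL` writes full precision.
#' @export
write_table <- function(table, path, digits = NULL) {
  validate_table(table)
  out <- as.data.frame(table)
  if (!is.null(digits)) {
    out[] <- lapply(out, function(col) formatC(col, format = "f", digits = digits))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' The packaged 10 x 10 measured force table
#'
#' The published unidirectional orthodontic-force measurements of ten second
#' sequential loops: displacements 0.5 to 5.0 mm in steps of 0.5 mm, one
#' column per archwire code (each cell already the average of three repeated
#' measurements). Column order follows the published single-parameter
#' comparison design: anchorage-distance group S16162010/S16162210/S16162410/
#' S16162610, offset-distance group S16162009/S16162008/S20102007,
#' cross-section group S18252010/S00162010, material group A16162010.
#'
#' @return A [measurement_table()], 10 displacements x 10 archwires.
#' @export
builtin_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "archforce",
                      mustWork = TRUE)
  load_table(path)
}

#' Average replicate measurement tables
#'
#' Element-wise arithmetic mean of force grids measured on identical
#' displacement grids and archwire panels.
#'
#' @param tables List of [measurement_table()]s with identical shape.
#' @return A [measurement_table()] of means (no replicate index).
#' @export
average_replicates <- function(tables) {
  if (!is.list(tables) || length(tables) < 1L)
    stop_domain("shape error: 'tables' must be a non-empty list of measurement tables")
  ref <- tables[[1]]
  validate_table(ref)
  codes <- table_codes(ref)
  for (t in tables[-1]) {
    validate_table(t)
    if (!identical(table_codes(t), codes) ||
        !isTRUE(all.equal(t$displacement_mm, ref$displacement_mm)))
      stop_domain("shape error: replicate tables must share displacements and archwire columns")
  }
  mean_forces <- lapply(codes, function(code)
    rowMeans(sapply(tables, function(t) t[[code]])))
  names(mean_forces) <- codes
  measurement_table(ref$displacement_mm, mean_forces)
}
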