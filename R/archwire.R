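#' Archwire material
#'
#' A named elastic material for an orthodontic archwire. Only the elastic
#' modulus enters the beam model; Poisson's ratio is carried for completeness
#' (no implemented equation consumes it).
#'
#' @param name Human-readable material name.
#' @param elastic_modulus Young's modulus E in Pa. Must be positive.
#' @param poisson Poisson's ratio, in `[0, 0.5)`.
#' @return An object of class `archwire_material`.
#' @examples
#' material("stainless steel", 1.79e11)
#' @export
material <- function(name, elastic_modulus, poisson = 0.3) {
  if (!is.character(name) || length(name) != 1L)
    stop_domain("material 'name' must be a single string")
  if (!is_scalar_number(elastic_modulus) || elastic_modulus <= 0)
    stop_domain("elastic modulus must be a positive number (Pa)")
  if (!is_scalar_number(poisson) || poisson < 0 || poisson >= 0.5)
    stop_domain("Poisson's ratio must lie in [0, 0.5)")
  structure(
    list(name = name, elastic_modulus = elastic_modulus, poisson = poisson),
    class = "archwire_material"
  )
}

#' @export
print.archwire_material <- function(x, ...) {
  cat(sprintf("<material> %s: E = %.4g GPa, nu = %.2f\n",
              x$name, x$elastic_modulus / 1e9, x$poisson))
  invisible(x)
}

#' Default material library
#'
#' Materials keyed by the single-letter prefix of the archwire naming code:
#' `S` for stainless steel (E = 179 GPa, a standard orthodontic value) and `A`
#' for Australian wire (E = 157 GPa). Both values are overridable via
#' [read_material_library()].
#'
#' @return Named list of [material()] objects keyed by code letter.
#' @export
default_materials <- function() {
  list(
    S = material("stainless steel", 1.79e11, 0.3),
    A = material("Australian wire", 1.57e11, 0.3)
  )
}

#' Read a material library from JSON
#'
#' The file maps code letters to objects with fields `name`, `E_Pa` and
#' optionally `poisson`, e.g. `{"S": {"name": "stainless steel", "E_Pa":
#' 1.79e11, "poisson": 0.3}}`.
#'
#' @param path Path to a JSON file.
#' @return Named list of [material()] objects keyed by code letter.
#' @export
read_material_library <- function(path) {
  raw <- jsonlite::read_json(path)
  if (length(raw) == 0L || is.null(names(raw)))
    stop_domain("material library must be a JSON object keyed by code letter")
  lapply(raw, function(entry) {
    material(entry$name, entry$E_Pa, entry$poisson %||% 0.3)
  })
}

#' Archwire cross-section
#'
#' Round or rectangular wire cross-section. For rectangular sections the
#' `depth` is the dimension in the deflection (occlusal-gingival) direction
#' and is the one cubed in the second moment of area; `width` is the
#' perpendicular side.
#'
#' @param kind `"round"` or `"rectangular"`.
#' @param diameter_mm Diameter in mm (round sections only).
#' @param depth_mm Deflection-direction side length in mm (rectangular only).
#' @param width_mm Perpendicular side length in mm (rectangular only).
#' @return An object of class `cross_section` with dimensions stored in metres.
#' @seealso [second_moment()], [section_area()]
#' @examples
#' cross_section("round", diameter_mm = 0.4064)
#' cross_section("rectangular", depth_mm = 0.4064, width_mm = 0.4064)
#' @export
cross_section <- function(kind = c("round", "rectangular"),
                          diameter_mm = NULL, depth_mm = NULL, width_mm = NULL) {
  kind <- match.arg(kind)
  if (kind == "round") {
    if (!is_scalar_number(diameter_mm) || diameter_mm <= 0)
      stop_domain("round section needs a positive 'diameter_mm'")
    dims <- list(diameter = mm_to_m(diameter_mm))
  } else {
    if (!is_scalar_number(depth_mm) || depth_mm <= 0 ||
        !is_scalar_number(width_mm) || width_mm <= 0)
      stop_domain("rectangular section needs positive 'depth_mm' and 'width_mm'")
    dims <- list(depth = mm_to_m(depth_mm), width = mm_to_m(width_mm))
  }
  structure(c(list(kind = kind), dims), class = "cross_section")
}

#' Second moment of area of a cross-section
#'
#' `pi * d^4 / 64` for round sections and `width * depth^3 / 12` for
#' rectangular sections, with the depth taken in the bending (deflection)
#' direction.
#'
#' @param section A [cross_section()].
#' @return Second moment of area I_z in m^4.
#' @examples
#' second_moment(cross_section("round", diameter_mm = 0.4064))
#' @export
second_moment <- function(section) {
  stopifnot(inherits(section, "cross_section"))
  if (section$kind == "round") {
    pi * section$diameter^4 / 64
  } else {
    section$width * section$depth^3 / 12
  }
}

#' Cross-sectional area
#'
#' Carried for completeness; the beam model only consumes [second_moment()].
#'
#' @param section A [cross_section()].
#' @return Area in m^2.
#' @export
section_area <- function(section) {
  stopifnot(inherits(section, "cross_section"))
  if (section$kind == "round") pi * section$diameter^2 / 4
  else section$width * section$depth
}

#' @export
print.cross_section <- function(x, ...) {
  if (x$kind == "round") {
    cat(sprintf("<cross_section> round, d = %.4f mm, Iz = %.4e m^4\n",
                m_to_mm(x$diameter), second_moment(x)))
  } else {
    cat(sprintf("<cross_section> rectangular, depth = %.4f mm (bending), width = %.4f mm, Iz = %.4e m^4\n",
                m_to_mm(x$depth), m_to_mm(x$width), second_moment(x)))
  }
  invisible(x)
}

#' Loop geometry of the second sequential loop
#'
#' `l` is the anchorage distance (archwire length between the two anchorage
#' teeth), `a` the offset distance from the target tooth to the distal
#' anchorage tooth, and `b = l - a` the distance to the mesial anchorage.
#'
#' @param anchorage_mm Anchorage distance l in mm.
#' @param offset_mm Offset distance a in mm; must satisfy `0 < a < l`.
#' @return An object of class `loop_geometry` with fields `l`, `a`, `b` in m.
#' @export
loop_geometry <- function(anchorage_mm, offset_mm) {
  if (!is_scalar_number(anchorage_mm) || anchorage_mm <= 0)
    stop_domain("anchorage distance must be a positive number (mm)")
  if (!is_scalar_number(offset_mm) || offset_mm <= 0 || offset_mm >= anchorage_mm)
    stop_domain("geometry error: offset distance must satisfy 0 < a < l (got a = ",
                offset_mm, " mm, l = ", anchorage_mm, " mm)")
  structure(
    list(l = mm_to_m(anchorage_mm), a = mm_to_m(offset_mm),
         b = mm_to_m(anchorage_mm - offset_mm)),
    class = "loop_geometry"
  )
}

#' @export
print.loop_geometry <- function(x, ...) {
  cat(sprintf("<loop_geometry> l = %g mm, a = %g mm, b = %g mm\n",
              m_to_mm(x$l), m_to_mm(x$a), m_to_mm(x$b)))
  invisible(x)
}

#' Archwire specification
#'
#' Bundles the naming code with its material, cross-section and loop geometry.
#' Usually produced by [parse_code()] rather than called directly.
#'
#' @param code Archwire naming code (see [parse_code()]).
#' @param material An [material()].
#' @param section A [cross_section()].
#' @param geometry A [loop_geometry()].
#' @return An object of class `archwire_spec`.
#' @export
archwire_spec <- function(code, material, section, geometry) {
  stopifnot(inherits(material, "archwire_material"),
            inherits(section, "cross_section"),
            inherits(geometry, "loop_geometry"))
  structure(
    list(code = code, material = material, section = section,
         geometry = geometry),
    class = "archwire_spec"
  )
}

#' @export
print.archwire_spec <- function(x, ...) {
  cat(sprintf("<archwire_spec> %s\n", x$code))
  print(x$material); print(x$section); print(x$geometry)
  invisible(x)
}

#' Parse an archwire naming code
#'
#' The code grammar is `M D1D1 D2D2 LL AA`: a material letter, two section
#' dimension pairs in thousandths of an inch, the anchorage distance in mm and
#' the offset distance in mm. `S16162010` is a stainless-steel square
#' 0.016 x 0.016 inch wire with l = 20 mm, a = 10 mm. A leading dimension pair
#' of `"00"` denotes a round wire whose diameter is the second pair
#' (`S00162010` is round, 0.016 inch). For rectangular wires the FIRST pair is
#' taken as the deflection-direction (occlusal-gingival) dimension, the one
#' cubed in the second moment of area.
#'
#' @param code A 9-character code string.
#' @param materials Material library, a named list keyed by code letter
#'   (default [default_materials()]).
#' @param reinterpret_s20102007 The code `S20102007` reads literally as a
#'   0.020 x 0.010 inch section; set `TRUE` to re-interpret its section as
#'   0.016 x 0.016 inch (same offset geometry), for sensitivity analyses of
#'   the offset-distance comparison group.
#' @return An [archwire_spec()].
#' @examples
#' parse_code("S16162010")
#' parse_code("S00162010")$section$kind
#' @export
parse_code <- function(code, materials = default_materials(),
                       reinterpret_s20102007 = FALSE) {
  if (!is.character(code) || length(code) != 1L || !grepl("^[A-Za-z][0-9]{8}$", code))
    stop_domain("parse error: code '", code,
                "' does not match the grammar <letter><8 digits>")
  letter <- substr(code, 1, 1)
  if (!letter %in% names(materials))
    stop_domain("lookup error: unknown material letter '", letter,
                "' (library has: ", paste(names(materials), collapse = ", "), ")")
  d1 <- as.numeric(substr(code, 2, 3))
  d2 <- as.numeric(substr(code, 4, 5))
  l_mm <- as.numeric(substr(code, 6, 7))
  a_mm <- as.numeric(substr(code, 8, 9))
  if (isTRUE(reinterpret_s20102007) && identical(code, "S20102007")) {
    d1 <- 16; d2 <- 16
  }
  if (d2 == 0)
    stop_domain("parse error: second section dimension pair of '", code, "' is 00")
  section <- if (d1 == 0) {
    cross_section("round", diameter_mm = m_to_mm(mil_to_m(d2)))
  } else {
    cross_section("rectangular",
                  depth_mm = m_to_mm(mil_to_m(d1)),
                  width_mm = m_to_mm(mil_to_m(d2)))
  }
  if (l_mm == 0)
    stop_domain("parse error: anchorage distance of '", code, "' is 00 mm")
  if (a_mm >= l_mm || a_mm == 0)
    stop_domain("geometry error: code '", code, "' has offset a = ", a_mm,
                " mm outside (0, l = ", l_mm, " mm)")
  archwire_spec(code, materials[[letter]], section,
                loop_geometry(l_mm, a_mm))
}

#' Render an archwire specification back to its naming code
#'
#' Inverse of [parse_code()]: `parse_code(render_code(spec))` reproduces
#' `spec` for any spec whose dimensions are representable in the code grammar.
#'
#' @param spec An [archwire_spec()].
#' @param materials Material library used to recover the code letter.
#' @return The 9-character code string.
#' @export
render_code <- function(spec, materials = default_materials()) {
  stopifnot(inherits(spec, "archwire_spec"))
  letter <- names(materials)[vapply(materials, function(m)
    identical(m$name, spec$material$name), logical(1))]
  if (length(letter) != 1L)
    stop_domain("render error: material '", spec$material$name,
                "' has no unique letter in the library")
  to_mil <- function(m) round(m / M_PER_INCH * 1000)
  if (spec$section$kind == "round") {
    d1 <- 0; d2 <- to_mil(spec$section$diameter)
  } else {
    d1 <- to_mil(spec$section$depth); d2 <- to_mil(spec$section$width)
  }
  sprintf("%s%02d%02d%02d%02d", letter, d1, d2,
          round(m_to_mm(spec$geometry$l)), round(m_to_mm(spec$geometry$a)))
}
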