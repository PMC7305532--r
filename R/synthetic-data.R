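# Synthetic measurement tables with the statistical structure the calibration
# assumes: force = K_F(spec) * F_theo(spec, d) times multiplicative
# measurement noise, on a single-parameter comparison panel, with averaged
# replicates.

#' Default synthetic archwire panel
#'
#' Ten codes forming four clean single-parameter comparison groups around the
#' reference S16162010: anchorage distances 20/22/24/26 mm, offset distances
#' 10/9/8/7 mm (the offset group uses S16162007, so that — unlike the
#' published panel's S20102007 — only the offset varies within the group),
#' sections 0.016 square / 0.018 x 0.025 / round 0.016, and stainless vs
#' Australian material.
#'
#' @return Character vector of ten archwire codes.
#' @export
default_panel <- function() {
  c("S16162010", "S16162210", "S16162410", "S16162610",
    "S16162009", "S16162008", "S16162007",
    "S18252010", "S00162010", "A16162010")
}

#' Rescale correction coefficients into the self-consistent class
#'
#' Coefficients are identifiable from composed forces only up to one scale
#' per group: multiplying `K_Fa` by a constant `c` (i.e. mapping its percent
#' polynomial `p` to `c p + 100 (c - 1)`) leaves `K_Fa(a)/K_Fa0` — and hence
#' every prediction — unchanged, and likewise for `K_FS` and `K_FM`.
#' Refitting noiseless data therefore recovers coefficients exactly only in
#' the representative of that family which a fit itself produces: the one
#' with `K_Fa0 = K_FS0 = K_FM0 = K_Fl(l_ref)`. This function maps any
#' coefficient set to that representative (predictions are unchanged).
#'
#' @param coeffs A `correction_coefficients` object.
#' @return An equivalent `correction_coefficients` object with all base
#'   values equal to `K_Fl(l_ref)`.
#' @export
self_consistent_coefficients <- function(coeffs) {
  stopifnot(inherits(coeffs, "correction_coefficients"))
  target <- unname(eval_K(coeffs, "l", coeffs$reference$l_mm))
  rescale <- function(pct_coef, current) {
    cc <- target / current
    out <- cc * pct_coef
    out[["intercept"]] <- out[["intercept"]] + 100 * (cc - 1)
    out
  }
  coeffs$kfa <- rescale(coeffs$kfa, coeffs$base[["kfa0"]])
  coeffs$kfs <- rescale(coeffs$kfs, coeffs$base[["kfs0"]])
  coeffs$kfm <- rescale(coeffs$kfm, coeffs$base[["kfm0"]])
  coeffs$base <- compute_base(coeffs, coeffs$reference)
  coeffs$source <- paste0(coeffs$source, " (self-consistent form)")
  coeffs
}

#' Default true coefficients for simulation
#'
#' The published coefficient set ([printed_coefficients()]) mapped to the
#' self-consistent class by [self_consistent_coefficients()], so that exact
#' parameter recovery from noiseless synthetic data is well defined.
#'
#' @param materials Material library.
#' @return A `correction_coefficients` object.
#' @export
default_true_coefficients <- function(materials = default_materials()) {
  self_consistent_coefficients(printed_coefficients(materials))
}

#' Simulation configuration
#'
#' Study conditions for [generate_table()]: the archwire panel, the 10-point
#' 0.5-5.0 mm displacement grid, the true correction coefficients, the
#' fractional multiplicative noise level (default 0.02, inside the < 5 percent
#' manual measurement error of the measuring protocol the generator
#' emulates), the number of repeated measurements to average (default 3),
#' and the RNG seed.
#'
#' @param codes Archwire codes of the panel.
#' @param displacement_mm Displacement grid in mm.
#' @param coefficients True `correction_coefficients` generating the data.
#' @param sigma Fractional standard deviation of the multiplicative noise
#'   (truncated normal, truncated so forces stay positive).
#' @param replicates Number of replicate tables (`>= 1`).
#' @param seed Integer RNG seed.
#' @param materials Material library.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(codes = default_panel(),
                              displacement_mm = seq(0.5, 5, by = 0.5),
                              coefficients = default_true_coefficients(materials),
                              sigma = 0.02, replicates = 3L, seed = 1L,
                              materials = default_materials()) {
  if (!is_scalar_number(sigma) || sigma < 0)
    stop_domain("sigma must be a non-negative number")
  if (!is_scalar_number(replicates) || replicates < 1)
    stop_domain("replicates must be >= 1")
  stopifnot(inherits(coefficients, "correction_coefficients"))
  structure(
    list(codes = codes, displacement_mm = displacement_mm,
         coefficients = coefficients, sigma = sigma,
         replicates = as.integer(replicates), seed = as.integer(seed),
         materials = materials),
    class = "simulation_config"
  )
}

#' Read a simulation configuration from JSON
#'
#' Recognised fields: `codes`, `displacement_mm`, `sigma`, `replicates`,
#' `seed`, and optionally `coefficients_path` (JSON written by
#' [write_coefficients()]); omitted fields take the [simulation_config()]
#' defaults.
#'
#' @param path JSON file path.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  coeffs <- if (!is.null(raw$coefficients_path))
    read_coefficients(raw$coefficients_path) else default_true_coefficients()
  simulation_config(
    codes = raw$codes %||% default_panel(),
    displacement_mm = raw$displacement_mm %||% seq(0.5, 5, by = 0.5),
    coefficients = coeffs,
    sigma = raw$sigma %||% 0.02,
    replicates = raw$replicates %||% 3L,
    seed = raw$seed %||% 1L)
}

# truncated multiplicative noise factor: 1 + eps, eps ~ N(0, sigma) redrawn
# while 1 + eps <= 0 so forces stay positive
draw_noise <- function(n, sigma) {
  eps <- stats::rnorm(n, 0, sigma)
  while (any(eps <= -1)) {
    bad <- eps <= -1
    eps[bad] <- stats::rnorm(sum(bad), 0, sigma)
  }
  eps
}

#' Generate a synthetic measurement table
#'
#' Every cell is `K_F(spec) * F_theo(spec, d) * (1 + eps)`, with `eps` drawn
#' per replicate from a truncated normal with standard deviation
#' `config$sigma`. The same seed always produces bit-identical output.
#'
#' @param config A [simulation_config()].
#' @return List with `replicates` (list of [measurement_table()]s, one per
#'   replicate), `average` (their [average_replicates()] mean) and `config`.
#' @examples
#' sim <- generate_table(simulation_config(sigma = 0, seed = 42))
#' sim$average
#' @export
generate_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  specs <- lapply(config$codes, parse_code, materials = config$materials)
  names(specs) <- config$codes
  truth <- vapply(specs, function(spec) {
    compose_KF(spec, config$coefficients, warn_extrapolation = FALSE) *
      theoretical_force(spec, config$displacement_mm,
                        config$coefficients$variant)
  }, numeric(length(config$displacement_mm)))
  truth <- matrix(truth, nrow = length(config$displacement_mm),
                  dimnames = list(NULL, config$codes))
  set.seed(config$seed)
  reps <- lapply(seq_len(config$replicates), function(r) {
    noisy <- truth * (1 + draw_noise(length(truth), config$sigma))
    measurement_table(config$displacement_mm,
                      as.data.frame(noisy, check.names = FALSE),
                      replicate = r)
  })
  list(replicates = reps, average = average_replicates(reps), config = config)
}

coefficient_vector <- function(coeffs) {
  c(kfl_intercept = coeffs$kfl[["intercept"]], kfl_l = coeffs$kfl[["l"]],
    kfa_intercept = coeffs$kfa[["intercept"]], kfa_a = coeffs$kfa[["a"]],
    kfa_a2 = coeffs$kfa[["a2"]],
    kfs_intercept = coeffs$kfs[["intercept"]], kfs_lnI = coeffs$kfs[["lnI"]],
    kfm_intercept = coeffs$kfm[["intercept"]], kfm_E10 = coeffs$kfm[["E10"]])
}

#' Parameter-recovery experiment
#'
#' Generates `n_seeds` synthetic tables (seeds `config$seed`,
#' `config$seed + 1`, ...), refits the correction functions on each averaged
#' table, and summarises the relative estimation error of every coefficient
#' across seeds.
#'
#' @param config A [simulation_config()]; its coefficients are the truth.
#' @param n_seeds Number of independent tables (`>= 2`).
#' @return Data frame with one row per coefficient: `coefficient`, `true`,
#'   `bias` (mean relative error) and `rmse` (root-mean-square relative
#'   error).
#' @export
recovery_experiment <- function(config, n_seeds = 50L) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_seeds < 2) stop_domain("n_seeds must be >= 2")
  truth <- coefficient_vector(config$coefficients)
  rel_errors <- vapply(seq_len(n_seeds), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    sim <- generate_table(cfg)
    fit <- fit_correction_functions(sim$average,
                                    variant = config$coefficients$variant,
                                    materials = config$materials)
    (coefficient_vector(fit) - truth) / abs(truth)
  }, numeric(length(truth)))
  data.frame(coefficient = names(truth), true = unname(truth),
             bias = rowMeans(rel_errors),
             rmse = sqrt(rowMeans(rel_errors^2)))
}
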