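# Model constants for the surface-dose system. Every fitted coefficient of
# the dose rules lives here so an alternative fit can be swapped in from a
# config file without touching code.

#' Model coefficients for the skin-dose system
#'
#' Builds the full set of constants used by the dose rules: the in-field and
#' near-field entrance-dose line fits for megavoltage and cobalt beams, the
#' exit backscatter-deficit factor, the tangential (90-degree obliquity)
#' fraction, the shielding-block transmission, the distance clamp of the
#' surface-to-depth ratio, and the legacy cobalt tray-to-skin separation
#' power law. Defaults are the published fits; any subset can be overridden.
#'
#' @param ... named overrides of individual coefficients (see Details).
#'
#' @details Coefficient names and defaults:
#' \describe{
#'   \item{mv_infield_intercept (6.63), mv_infield_slope (0.926)}{megavoltage
#'     in-field entrance dose, percent of Dmax per cm of equivalent square.}
#'   \item{mv_tray_slope (0.5)}{additional percent per cm when a block tray is
#'     present (megavoltage only; the tray factor term).}
#'   \item{co_infield_intercept (12.9), co_infield_slope (1.85)}{cobalt
#'     in-field entrance dose; a tray has no effect for cobalt.}
#'   \item{mv_near_intercept (-0.686), mv_near_slope (0.557),
#'     mv_near_tray_slope (0.27)}{megavoltage entrance dose 2 cm outside the
#'     field edge.}
#'   \item{co_near_intercept (-1.17), co_near_slope (0.894)}{cobalt entrance
#'     dose 2 cm outside the field edge.}
#'   \item{exit_backscatter_deficit (0.85)}{multiplier on the percent depth
#'     dose at an exit surface, accounting for missing backscatter.}
#'   \item{tangential_fraction (65)}{percent of Dmax assigned to a surface
#'     tangential to the beam (90-degree obliquity), both beam classes.}
#'   \item{block_transmission (0.08)}{fraction of Dmax transmitted through a
#'     shielding block, as dose in full phantom.}
#'   \item{ratio_distance_clamp (12)}{distance from the field edge (cm) beyond
#'     which the surface-to-depth ratio is held constant.}
#'   \item{tray_eq_coeff (0.25), tray_eq_h_exp (-0.44), tray_eq_r_exp
#'     (0.72)}{legacy cobalt power law for skin dose versus tray-to-skin
#'     separation h and equivalent circular field radius r.}
#' }
#'
#' @return An object of class \code{skindose_coefficients}: a validated named
#'   list of numeric constants.
#' @seealso [read_coefficients()] to load overrides from a YAML/JSON file.
#' @export
#' @examples
#' coeffs <- model_coefficients()
#' coeffs$tangential_fraction
#' model_coefficients(tangential_fraction = 60)$tangential_fraction
model_coefficients <- function(...) {
  defaults <- list(
    mv_infield_intercept = 6.63,
    mv_infield_slope = 0.926,
    mv_tray_slope = 0.5,
    co_infield_intercept = 12.9,
    co_infield_slope = 1.85,
    mv_near_intercept = -0.686,
    mv_near_slope = 0.557,
    mv_near_tray_slope = 0.27,
    co_near_intercept = -1.17,
    co_near_slope = 0.894,
    exit_backscatter_deficit = 0.85,
    tangential_fraction = 65,
    block_transmission = 0.08,
    ratio_distance_clamp = 12,
    tray_eq_coeff = 0.25,
    tray_eq_h_exp = -0.44,
    tray_eq_r_exp = 0.72
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1L]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1L]]
  }
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      stop_skindose(
        sprintf("unknown coefficient name(s): %s", paste(bad, collapse = ", ")),
        "skindose_config_error"
      )
    }
    for (nm in names(overrides)) {
      val <- overrides[[nm]]
      if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
        stop_skindose(
          sprintf("coefficient '%s' must be a single finite number", nm),
          "skindose_config_error"
        )
      }
      defaults[[nm]] <- as.numeric(val)
    }
  }
  validate_coefficients(structure(defaults, class = "skindose_coefficients"))
}

validate_coefficients <- function(coeffs) {
  with(coeffs, {
    if (mv_infield_slope < 0 || co_infield_slope < 0 ||
        mv_near_slope < 0 || co_near_slope < 0 ||
        mv_tray_slope < 0 || mv_near_tray_slope < 0) {
      stop_skindose("entrance-dose slopes must be non-negative",
                    "skindose_config_error")
    }
    if (exit_backscatter_deficit <= 0 || exit_backscatter_deficit > 1) {
      stop_skindose("exit_backscatter_deficit must lie in (0, 1]",
                    "skindose_config_error")
    }
    if (block_transmission <= 0 || block_transmission >= 1) {
      stop_skindose("block_transmission must lie in (0, 1)",
                    "skindose_config_error")
    }
    if (tangential_fraction < 0 || tangential_fraction > 100) {
      stop_skindose("tangential_fraction must lie in [0, 100]",
                    "skindose_config_error")
    }
    if (ratio_distance_clamp <= 0) {
      stop_skindose("ratio_distance_clamp must be positive",
                    "skindose_config_error")
    }
  })
  coeffs
}

#' Load coefficient overrides from a config file
#'
#' Reads a flat key/value YAML or JSON file and returns a full coefficient
#' set with the listed keys replaced. Keys must match the names documented in
#' [model_coefficients()].
#'
#' @param path path to a YAML (.yaml/.yml) or JSON (.json) file.
#' @return A \code{skindose_coefficients} object.
#' @export
read_coefficients <- function(path) {
  overrides <- read_config_file(path)
  if (!is.list(overrides)) {
    stop_skindose("coefficient file must contain a flat key/value mapping",
                  "skindose_config_error")
  }
  do.call(model_coefficients, overrides)
}

#' @export
print.skindose_coefficients <- function(x, ...) {
  cat("Skin-dose model coefficients:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %g\n", nm, x[[nm]]))
  invisible(x)
}

# Shared reader for YAML/JSON config files (dialect chosen by extension;
# YAML parses JSON too, so unknown extensions fall back to yaml).
read_config_file <- function(path) {
  if (!file.exists(path)) {
    stop_skindose(sprintf("config file not found: %s", path),
                  "skindose_config_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

stop_skindose <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "skindose_error"),
                      call = call))
}
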