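# The dose-rule core. Every rule returns surface dose as percent of the
# Dmax dose (fraction for the legacy tray-separation law), computed at full
# floating-point precision; rounding to reporting precision happens only in
# the reporting layer (report_round).

#' Normalize a beam class label
#'
#' Maps any nominal megavoltage energy label (e.g. "6MV", "18 MV", "mv") to
#' \code{"megavoltage"} and cobalt labels ("cobalt", "co", "co60", "co-60")
#' to \code{"cobalt"}: surface dose varies little across MV energies, so the
#' model distinguishes only the two classes.
#'
#' @param beam_class a character label.
#' @return \code{"megavoltage"} or \code{"cobalt"}.
#' @export
beam_class <- function(beam_class) {
  x <- tolower(trimws(as.character(beam_class)))
  if (x %in% c("megavoltage", "mv", "linac", "x") ||
      grepl("^[0-9]+(\\.[0-9]+)?\\s*(mv|x)$", x)) {
    return("megavoltage")
  }
  if (x %in% c("cobalt", "co", "co60", "co-60", "cobalt-60", "cobalt60")) {
    return("cobalt")
  }
  stop_skindose(
    sprintf("unrecognized beam class '%s' (expected megavoltage or cobalt)",
            beam_class),
    "skindose_invalid_input"
  )
}

check_field_size <- function(fs) {
  if (!is.numeric(fs) || any(!is.finite(fs)) || any(fs <= 0)) {
    stop_skindose("field size must be finite and positive",
                  "skindose_invalid_geometry")
  }
  if (any(fs > 40)) {
    warning("field size exceeds 40 cm: outside the fitted range, ",
            "result extrapolated", call. = FALSE)
  }
  invisible(fs)
}

# clamp a percent into [lo, hi], recording whether any clamp fired in the
# "clamped" attribute; exceeding 100% warns rather than errors
clamp_percent <- function(x, lo = 0, hi = 100) {
  clamped <- x < lo | x > hi
  if (any(x > hi)) {
    warning(sprintf("surface dose %.4g%% exceeds %g%% of Dmax; capped",
                    max(x), hi), call. = FALSE)
  }
  out <- pmin(pmax(x, lo), hi)
  attr(out, "clamped") <- clamped
  out
}

#' In-field entrance surface dose
#'
#' Skin dose on the entrance surface inside the open (unblocked) treatment
#' field, as percent of Dmax. For megavoltage beams
#' \eqn{D_s = 6.63 + 0.926 \cdot FS + 0.5 \cdot FS \cdot TF} where TF is 1
#' with a block tray and 0 without; for cobalt
#' \eqn{D_s = 12.9 + 1.85 \cdot FS} and the tray has no effect.
#'
#' @param beam \code{"megavoltage"} or \code{"cobalt"} (any alias accepted by
#'   [beam_class()]).
#' @param fs equivalent square field size in cm at the isocenter plane
#'   (fitted range up to 40 cm; larger values warn).
#' @param tray logical, block tray present.
#' @param coeffs a [model_coefficients()] object.
#' @return Percent of Dmax, clamped to [0, 100] (attribute \code{clamped}
#'   records whether the clamp fired).
#' @export
#' @examples
#' entrance_infield("megavoltage", 30, tray = TRUE)  # 49.41
#' entrance_infield("cobalt", 15)                    # 40.65
entrance_infield <- function(beam, fs, tray = FALSE,
                             coeffs = model_coefficients()) {
  beam <- beam_class(beam)
  check_field_size(fs)
  tf <- as.numeric(isTRUE(tray))
  pct <- if (beam == "megavoltage") {
    coeffs$mv_infield_intercept + coeffs$mv_infield_slope * fs +
      coeffs$mv_tray_slope * fs * tf
  } else {
    # cobalt: tray has no effect on surface dose
    coeffs$co_infield_intercept + coeffs$co_infield_slope * fs
  }
  clamp_percent(pct)
}

#' Entrance surface dose 2 cm outside the field edge
#'
#' Near-field entrance dose at the reference distance of 2 cm outside the
#' jaw-defined field edge. Megavoltage:
#' \eqn{D_s = -0.686 + 0.557 \cdot FS + 0.27 \cdot FS \cdot TF}; cobalt:
#' \eqn{D_s = -1.17 + 0.894 \cdot FS}. The fitted lines have negative
#' intercepts, so predictions for very small fields clamp at zero.
#'
#' @inheritParams entrance_infield
#' @return Percent of Dmax, clamped below at 0.
#' @export
#' @examples
#' nearfield_2cm("megavoltage", 30, tray = TRUE)  # 24.124
#' nearfield_2cm("cobalt", 15)                    # 12.24
nearfield_2cm <- function(beam, fs, tray = FALSE,
                          coeffs = model_coefficients()) {
  beam <- beam_class(beam)
  check_field_size(fs)
  tf <- as.numeric(isTRUE(tray))
  pct <- if (beam == "megavoltage") {
    coeffs$mv_near_intercept + coeffs$mv_near_slope * fs +
      coeffs$mv_near_tray_slope * fs * tf
  } else {
    coeffs$co_near_intercept + coeffs$co_near_slope * fs
  }
  clamp_percent(pct)
}

#' Entrance surface dose under a shielding block
#'
#' A point inside the collimator opening but shielded by a block receives a
#' dose similar to that 2 cm outside the treatment field, so this rule is
#' identical to [nearfield_2cm()] evaluated with the unblocked jaw-defined
#' field size.
#'
#' @inheritParams entrance_infield
#' @return Percent of Dmax.
#' @export
under_block_entrance <- function(beam, fs, tray = FALSE,
                                 coeffs = model_coefficients()) {
  nearfield_2cm(beam, fs, tray = tray, coeffs = coeffs)
}

#' Surface-to-depth dose ratio outside the treatment field
#'
#' Beyond ~2 cm from the field edge the surface dose is elevated relative to
#' the out-of-field dose a few cm below the surface. The ratio grows with
#' field size and with distance from the edge up to 12 cm, beyond which it
#' is constant. Megavoltage: \eqn{(FS+10)\chi/150 + FS/100 + 1}; cobalt:
#' \eqn{FS\,\chi/85 + (FS-3)/10 + 1}, with \eqn{\chi = \min(distance, 12)}.
#'
#' @inheritParams entrance_infield
#' @param distance distance from the field edge in cm (clamped internally at
#'   \code{coeffs$ratio_distance_clamp}).
#' @return Dimensionless ratio, at least 1.
#' @export
#' @examples
#' surface_to_depth_ratio("megavoltage", 40, 12)  # 5.4
#' surface_to_depth_ratio("cobalt", 15, 10)       # 3.9647
surface_to_depth_ratio <- function(beam, fs, distance,
                                   coeffs = model_coefficients()) {
  beam <- beam_class(beam)
  check_field_size(fs)
  x <- clamp_distance(distance, coeffs$ratio_distance_clamp)
  ratio <- if (beam == "megavoltage") {
    (fs + 10) * (x / 150) + fs / 100 + 1
  } else {
    fs * x / 85 + (fs - 3) / 10 + 1
  }
  # the cobalt fit dips below 1 for fields under 3 cm; physically the
  # surface cannot receive less than the dose at depth in this regime
  pmax(ratio, 1)
}

#' Far out-of-field entrance surface dose
#'
#' Entrance dose at distances beyond 2 cm from the field edge: the
#' out-of-field dose at depth is scaled up by the surface-to-depth ratio.
#'
#' @inheritParams surface_to_depth_ratio
#' @param dose_at_depth out-of-field dose at depth at this distance, percent
#'   of Dmax (from [oof_dose_at_depth()] or user data).
#' @return Percent of Dmax.
#' @export
#' @examples
#' farfield_surface("cobalt", 15, 10, dose_at_depth = 2.0)  # 7.929
farfield_surface <- function(beam, fs, distance, dose_at_depth,
                             coeffs = model_coefficients()) {
  if (any(distance <= 2)) {
    stop_skindose(
      "farfield_surface applies beyond 2 cm from the field edge; use nearfield_2cm or edge_interpolate within 2 cm",
      "skindose_wrong_rule"
    )
  }
  if (any(!is.finite(dose_at_depth)) || any(dose_at_depth < 0)) {
    stop_skindose("dose_at_depth must be finite and non-negative",
                  "skindose_invalid_input")
  }
  ratio <- surface_to_depth_ratio(beam, fs, distance, coeffs)
  clamp_percent(ratio * dose_at_depth)
}

#' In-field exit surface dose
#'
#' Skin dose where the beam exits the patient: the percent depth dose at the
#' exit surface reduced by the backscatter deficit factor (0.85, i.e. the
#' ~15% relative reduction from missing backscatter material).
#'
#' @param pdd_at_exit percent depth dose at the exit depth, percent of Dmax.
#' @param coeffs a [model_coefficients()] object.
#' @return Percent of Dmax; never exceeds \code{pdd_at_exit}.
#' @export
#' @examples
#' exit_surface(46)  # 39.1
exit_surface <- function(pdd_at_exit, coeffs = model_coefficients()) {
  if (any(!is.finite(pdd_at_exit)) || any(pdd_at_exit < 0) ||
      any(pdd_at_exit > 100)) {
    stop_skindose("pdd_at_exit must lie in [0, 100] percent of Dmax",
                  "skindose_invalid_input")
  }
  coeffs$exit_backscatter_deficit * pdd_at_exit
}

#' Exit surface dose under a shielding block
#'
#' Dose at an exit surface shielded by a block: block transmission (dose in
#' full phantom) times the Dmax dose, reduced by the backscatter deficit.
#' With default coefficients, 100 x 0.08 x 0.85 = 6.8% of Dmax, independent
#' of depth and field size.
#'
#' @param coeffs a [model_coefficients()] object.
#' @return Percent of Dmax.
#' @export
exit_under_block <- function(coeffs = model_coefficients()) {
  100 * coeffs$block_transmission * coeffs$exit_backscatter_deficit
}

#' Tangential (90-degree obliquity) surface dose
#'
#' A surface lateral to the beam (grazing incidence) is assigned a flat 65%
#' of the Dmax dose for both megavoltage and cobalt beams. The model treats
#' obliquity as binary (normal vs tangential); intermediate angles are not
#' approximated.
#'
#' @param coeffs a [model_coefficients()] object.
#' @return Percent of Dmax (\code{coeffs$tangential_fraction}).
#' @export
tangential_dose <- function(coeffs = model_coefficients()) {
  coeffs$tangential_fraction
}

#' Exit dose on the diverged field edge
#'
#' A point lying exactly on the diverged edge of an exit-side field receives
#' half the in-field exit dose: \eqn{0.5 \times PDD \times 0.85}.
#'
#' @inheritParams exit_surface
#' @return Percent of Dmax.
#' @export
exit_edge_divergence <- function(pdd_at_exit, coeffs = model_coefficients()) {
  0.5 * exit_surface(pdd_at_exit, coeffs)
}

#' Legacy cobalt skin dose versus tray-to-skin separation
#'
#' Power law for the skin dose (as a fraction of Dmax) contributed by
#' electron contamination from a cobalt block tray at separation \code{h}
#' from the skin: \eqn{D = 0.25 \, h^{-0.44} \, r^{0.72}}, with \code{r} the
#' radius of the equivalent circular field ([equivalent_circle_radius()]).
#' Retained for historical cobalt units with variable tray position; modern
#' fixed-tray treatments do not use it.
#'
#' @param h tray-to-skin separation in cm (> 0).
#' @param r equivalent circular field radius in cm (> 0).
#' @param coeffs a [model_coefficients()] object.
#' @return Fraction of the Dmax dose; decreasing in \code{h}, increasing in
#'   \code{r}.
#' @export
#' @examples
#' cobalt_tray_separation_dose(1, 1)  # 0.25
cobalt_tray_separation_dose <- function(h, r,
                                        coeffs = model_coefficients()) {
  if (any(!is.finite(h)) || any(h <= 0) || any(!is.finite(r)) || any(r <= 0)) {
    stop_skindose("h and r must be finite and positive",
                  "skindose_invalid_input")
  }
  coeffs$tray_eq_coeff * h^coeffs$tray_eq_h_exp * r^coeffs$tray_eq_r_exp
}

#' Entrance dose between the field edge and 2 cm outside
#'
#' Within the first 2 cm outside the field edge the entrance dose is
#' interpolated linearly between the in-field value at the edge (distance 0)
#' and the 2-cm near-field value (distance 2).
#'
#' @inheritParams entrance_infield
#' @param distance distance from the field edge in cm, in [0, 2].
#' @return Percent of Dmax.
#' @export
#' @examples
#' edge_interpolate("megavoltage", 30, tray = TRUE, distance = 1)  # 36.77
edge_interpolate <- function(beam, fs, tray = FALSE, distance,
                             coeffs = model_coefficients()) {
  if (any(!is.finite(distance)) || any(distance < 0) || any(distance > 2)) {
    stop_skindose(
      "edge_interpolate applies for distances in [0, 2] cm from the field edge",
      "skindose_wrong_rule"
    )
  }
  at_edge <- entrance_infield(beam, fs, tray = tray, coeffs = coeffs)
  at_2cm <- nearfield_2cm(beam, fs, tray = tray, coeffs = coeffs)
  w <- distance / 2
  clamp_percent(as.numeric((1 - w) * at_edge + w * at_2cm))
}
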