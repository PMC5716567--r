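# Field-size reduction and surface-point description. All distances are in
# cm at the isocenter plane; the field edge is the jaw projection, not the
# penumbra.

#' Equivalent square of a rectangular field
#'
#' Reduces a rectangular jaw-defined field to the side of the dosimetrically
#' equivalent square via the Sterling 4*Area/Perimeter rule,
#' \eqn{FS = 2 x y / (x + y)}.
#'
#' @param jaw_x,jaw_y field dimensions in cm at the isocenter plane.
#' @return Equivalent square side in cm. Symmetric in its arguments and
#'   bounded by \code{min(jaw_x, jaw_y)} and \code{max(jaw_x, jaw_y)}.
#' @export
#' @examples
#' equivalent_square(10, 10)  # 10
#' equivalent_square(5, 20)   # 8
equivalent_square <- function(jaw_x, jaw_y) {
  check_positive(jaw_x, "jaw_x", "skindose_invalid_geometry")
  check_positive(jaw_y, "jaw_y", "skindose_invalid_geometry")
  2 * jaw_x * jaw_y / (jaw_x + jaw_y)
}

#' Radius of the equivalent circular field
#'
#' Converts an equivalent-square side to the radius of the equivalent
#' circle, used only by the legacy cobalt tray-to-skin separation law
#' ([cobalt_tray_separation_dose()]).
#'
#' @param side equivalent square side in cm.
#' @param convention \code{"equal_area"} (default, \eqn{r = s/\sqrt{\pi}}) or
#'   \code{"equal_perimeter"} (\eqn{r = 2s/\pi}).
#' @return Radius in cm.
#' @export
#' @examples
#' equivalent_circle_radius(10)  # 5.6419
equivalent_circle_radius <- function(side,
                                     convention = c("equal_area",
                                                    "equal_perimeter")) {
  check_positive(side, "side", "skindose_invalid_geometry")
  convention <- match.arg(convention)
  switch(convention,
         equal_area = side / sqrt(pi),
         equal_perimeter = 2 * side / pi)
}

#' Clamp a distance from the field edge at 12 cm
#'
#' The surface-to-depth dose ratio is approximately constant beyond 12 cm
#' from the field edge, so distances entering the ratio formulas are capped
#' there. Idempotent and monotone non-decreasing.
#'
#' @param distance_from_edge distance in cm, non-negative.
#' @param clamp clamp value in cm (default 12).
#' @return \code{min(distance_from_edge, clamp)}.
#' @export
clamp_distance <- function(distance_from_edge, clamp = 12) {
  if (any(!is.finite(distance_from_edge)) || any(distance_from_edge < 0)) {
    stop_skindose("distance_from_edge must be finite and non-negative",
                  "skindose_invalid_location")
  }
  pmin(distance_from_edge, clamp)
}

#' Field geometry of one beam
#'
#' Describes the jaw-defined field and its equivalent square. Either both jaw
#' dimensions or the equivalent square side directly may be given. For
#' blocked fields the relevant size is the unblocked jaw-defined field.
#'
#' @param jaw_x,jaw_y jaw openings in cm at the isocenter plane.
#' @param equivalent_square_side equivalent square side in cm, if supplied
#'   directly instead of jaws.
#' @return An object of class \code{skindose_field} with elements
#'   \code{jaw_x}, \code{jaw_y} (NA when the square side was supplied
#'   directly) and \code{equivalent_square_side}.
#' @export
field_geometry <- function(jaw_x = NULL, jaw_y = NULL,
                           equivalent_square_side = NULL) {
  if (!is.null(equivalent_square_side)) {
    check_positive(equivalent_square_side, "equivalent_square_side",
                   "skindose_invalid_geometry")
    fs <- equivalent_square_side
    if (is.null(jaw_x)) jaw_x <- NA_real_
    if (is.null(jaw_y)) jaw_y <- NA_real_
  } else {
    if (is.null(jaw_x) || is.null(jaw_y)) {
      stop_skindose(
        "supply either both jaw dimensions or equivalent_square_side",
        "skindose_invalid_geometry"
      )
    }
    fs <- equivalent_square(jaw_x, jaw_y)
  }
  structure(
    list(jaw_x = jaw_x, jaw_y = jaw_y, equivalent_square_side = fs),
    class = "skindose_field"
  )
}

#' Location of a surface point relative to one beam
#'
#' Classifies where a surface point sits with respect to a single beam. The
#' region determines which dose rule applies; the caller supplies per-beam
#' locations because beam divergence can place the same physical point in
#' different regions of the entrance- and exit-side fields.
#'
#' @param region one of \code{"in_field"}, \code{"under_block"},
#'   \code{"near_field"} (within 2 cm of the field edge),
#'   \code{"out_of_field"} (more than 2 cm from the edge), or
#'   \code{"tangential"} (surface grazed at 90-degree obliquity).
#' @param side \code{"entrance"} or \code{"exit"}.
#' @param distance_cm distance from the jaw-projected field edge in cm;
#'   required (and only allowed) for \code{near_field} and
#'   \code{out_of_field} regions.
#' @param depth_cm depth along the beam axis to the point in cm; required on
#'   the exit side for \code{in_field} and \code{under_block} points (for the
#'   percent-depth-dose lookup) and for diverged-edge points.
#' @param diverged_edge logical; set for a point lying on the diverged field
#'   edge of an exit-side beam, where the dose is half the in-field exit
#'   dose.
#' @return An object of class \code{skindose_location}.
#' @export
point_location <- function(region = c("in_field", "under_block", "near_field",
                                      "out_of_field", "tangential"),
                           side = c("entrance", "exit"),
                           distance_cm = NULL,
                           depth_cm = NULL,
                           diverged_edge = FALSE) {
  region <- match.arg(region)
  side <- match.arg(side)
  needs_distance <- region %in% c("near_field", "out_of_field")
  if (needs_distance) {
    if (is.null(distance_cm)) {
      stop_skindose(
        sprintf("distance_cm is required for region '%s'", region),
        "skindose_invalid_location"
      )
    }
    if (!is.finite(distance_cm) || distance_cm < 0) {
      stop_skindose("distance_cm must be finite and non-negative",
                    "skindose_invalid_location")
    }
    if (region == "near_field" && distance_cm > 2) {
      stop_skindose("near_field requires distance_cm <= 2 (beyond 2 cm use out_of_field)",
                    "skindose_invalid_location")
    }
    if (region == "out_of_field" && distance_cm <= 2) {
      stop_skindose("out_of_field requires distance_cm > 2 (within 2 cm use near_field)",
                    "skindose_invalid_location")
    }
  } else if (!is.null(distance_cm)) {
    stop_skindose(
      sprintf("distance_cm is not meaningful for region '%s'", region),
      "skindose_invalid_location"
    )
  }
  needs_depth <- side == "exit" &&
    (region %in% c("in_field", "under_block") || isTRUE(diverged_edge))
  if (needs_depth && region != "under_block") {
    # under_block exit dose is depth-independent (block transmission rule),
    # so depth is accepted there but not required
    if (is.null(depth_cm) || !is.finite(depth_cm) || depth_cm <= 0) {
      stop_skindose(
        "depth_cm > 0 is required for exit-side in-field and diverged-edge points",
        "skindose_invalid_location"
      )
    }
  }
  structure(
    list(region = region, side = side,
         distance_cm = if (needs_distance) distance_cm else NULL,
         depth_cm = depth_cm,
         diverged_edge = isTRUE(diverged_edge)),
    class = "skindose_location"
  )
}

check_positive <- function(x, name, class) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_skindose(sprintf("%s must be finite and positive", name), class)
  }
  invisible(x)
}
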