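# Plan-level dispatch: route each (beam, point) pair to the correct dose
# rule, convert percent of Dmax to absolute dose, and sum over beams.

#' Specify one treatment beam
#'
#' @param label beam identifier used to match point locations.
#' @param beam beam class (any alias accepted by [beam_class()]).
#' @param jaw_x,jaw_y,equivalent_square field geometry in cm at the
#'   isocenter plane; give either both jaws or the equivalent square side
#'   (see [field_geometry()]). For blocked fields use the unblocked
#'   jaw-defined size.
#' @param tray logical, block tray present.
#' @param dmax_dose_gy Dmax dose (historically the "given dose") delivered
#'   by this beam, in Gy.
#' @param exit_thickness_cm optional patient thickness along the beam axis,
#'   used as the default exit depth for in-field exit points that do not
#'   carry their own \code{depth_cm}.
#' @return An object of class \code{skindose_beam}.
#' @export
beam_spec <- function(label, beam, jaw_x = NULL, jaw_y = NULL,
                      equivalent_square = NULL, tray = FALSE,
                      dmax_dose_gy = 1, exit_thickness_cm = NULL) {
  if (!is.numeric(dmax_dose_gy) || length(dmax_dose_gy) != 1L ||
      !is.finite(dmax_dose_gy) || dmax_dose_gy < 0) {
    stop_skindose("dmax_dose_gy must be a single non-negative number",
                  "skindose_invalid_input")
  }
  geom <- field_geometry(jaw_x = jaw_x, jaw_y = jaw_y,
                         equivalent_square_side = equivalent_square)
  structure(
    list(label = as.character(label), beam = beam_class(beam),
         geometry = geom, tray = isTRUE(tray),
         dmax_dose_gy = dmax_dose_gy,
         exit_thickness_cm = exit_thickness_cm),
    class = "skindose_beam"
  )
}

#' Specify one surface point of interest
#'
#' A surface point is described once per beam: because of beam divergence
#' and entrance/exit geometry, the same physical point generally sits in a
#' different region of each field, so region assignments are explicit
#' per-beam inputs rather than derived from 3D geometry.
#'
#' @param name point identifier.
#' @param ... named [point_location()] objects, one per beam label.
#' @return An object of class \code{skindose_point}.
#' @export
#' @examples
#' point_spec("chest_center",
#'   ant = point_location("in_field", "entrance"),
#'   post = point_location("in_field", "exit", depth_cm = 18))
point_spec <- function(name, ...) {
  locations <- list(...)
  if (length(locations) == 1L && is.null(names(locations)) &&
      is.list(locations[[1L]]) &&
      !inherits(locations[[1L]], "skindose_location")) {
    locations <- locations[[1L]]
  }
  if (!length(locations) || is.null(names(locations)) ||
      any(!nzchar(names(locations)))) {
    stop_skindose("point_spec needs named per-beam locations",
                  "skindose_invalid_location")
  }
  ok <- vapply(locations, inherits, logical(1), "skindose_location")
  if (!all(ok)) {
    stop_skindose("each location must be built with point_location()",
                  "skindose_invalid_location")
  }
  structure(list(name = as.character(name), locations = locations),
            class = "skindose_point")
}

skin_dose_result <- function(percent, rule, clamped = FALSE) {
  structure(
    list(percent_of_dmax = as.numeric(percent), rule = rule,
         clamped = isTRUE(clamped)),
    class = "skindose_result"
  )
}

#' @export
print.skindose_result <- function(x, ...) {
  cat(sprintf("%s%% of Dmax  [rule: %s%s]\n",
              format(report_round(x$percent_of_dmax)), x$rule,
              if (x$clamped) ", clamped" else ""))
  invisible(x)
}

#' Surface dose at one point from one beam
#'
#' Dispatches a (beam, location) pair to the dose rule the region and side
#' select:
#' \tabular{ll}{
#'   in_field / entrance \tab [entrance_infield()] \cr
#'   in_field / exit \tab [exit_surface()] of the PDD at the exit depth \cr
#'   under_block / entrance \tab [under_block_entrance()] \cr
#'   under_block / exit \tab [exit_under_block()] \cr
#'   near_field / entrance \tab [edge_interpolate()] at the point's distance \cr
#'   out_of_field / entrance \tab [farfield_surface()] of the out-of-field
#'     dose at depth \cr
#'   near/out_of_field / exit \tab 0.85 x out-of-field dose at depth, or
#'     [exit_edge_divergence()] for a flagged diverged-edge point \cr
#'   tangential (either side) \tab [tangential_dose()] \cr
#' }
#'
#' @param beam a [beam_spec()].
#' @param loc a [point_location()].
#' @param coeffs a [model_coefficients()] object.
#' @param pdd a [pdd_table()] for this beam; required for exit-side in-field
#'   and diverged-edge points.
#' @param oof an [oof_model()]; required for out-of-field points.
#' @return A \code{skindose_result} with the percent of Dmax, the name of
#'   the rule applied, and a clamp flag.
#' @export
point_dose <- function(beam, loc, coeffs = model_coefficients(),
                       pdd = NULL, oof = NULL) {
  stopifnot(inherits(beam, "skindose_beam"),
            inherits(loc, "skindose_location"))
  fs <- beam$geometry$equivalent_square_side
  need_pdd <- function(what) {
    if (is.null(pdd)) {
      stop_skindose(
        sprintf("no PDD table supplied for beam '%s' but %s requires one",
                beam$label, what),
        "skindose_dispatch_error"
      )
    }
  }
  need_oof <- function(what) {
    if (is.null(oof)) {
      stop_skindose(
        sprintf("no out-of-field depth-dose model supplied for beam '%s' but %s requires one",
                beam$label, what),
        "skindose_dispatch_error"
      )
    }
  }
  exit_depth <- function() {
    depth <- loc$depth_cm
    if (is.null(depth)) depth <- beam$exit_thickness_cm
    if (is.null(depth)) {
      stop_skindose(
        sprintf("exit-side point on beam '%s' needs depth_cm or the beam's exit_thickness_cm",
                beam$label),
        "skindose_dispatch_error"
      )
    }
    depth
  }

  if (loc$region == "tangential") {
    return(skin_dose_result(tangential_dose(coeffs), "tangential"))
  }
  if (loc$region == "in_field") {
    if (loc$side == "entrance") {
      pct <- entrance_infield(beam$beam, fs, tray = beam$tray, coeffs = coeffs)
      return(skin_dose_result(pct, "entrance_infield",
                              any(attr(pct, "clamped"))))
    }
    need_pdd("an in-field exit point")
    pct <- exit_surface(pdd_lookup(pdd, exit_depth()), coeffs)
    return(skin_dose_result(pct, "exit_surface"))
  }
  if (loc$region == "under_block") {
    if (loc$side == "entrance") {
      pct <- under_block_entrance(beam$beam, fs, tray = beam$tray,
                                  coeffs = coeffs)
      return(skin_dose_result(pct, "under_block_entrance",
                              any(attr(pct, "clamped"))))
    }
    return(skin_dose_result(exit_under_block(coeffs), "exit_under_block"))
  }
  # near_field / out_of_field
  if (loc$side == "entrance") {
    if (loc$region == "near_field") {
      pct <- edge_interpolate(beam$beam, fs, tray = beam$tray,
                              distance = loc$distance_cm, coeffs = coeffs)
      return(skin_dose_result(pct, "edge_interpolate",
                              any(attr(pct, "clamped"))))
    }
    need_oof("a far out-of-field entrance point")
    dd <- oof_dose_at_depth(oof, loc$distance_cm)
    pct <- farfield_surface(beam$beam, fs, loc$distance_cm, dd, coeffs)
    return(skin_dose_result(pct, "farfield_surface",
                            any(attr(pct, "clamped"))))
  }
  # exit side, outside the field
  if (loc$diverged_edge) {
    need_pdd("a diverged-edge exit point")
    pct <- exit_edge_divergence(pdd_lookup(pdd, exit_depth()), coeffs)
    return(skin_dose_result(pct, "exit_edge_divergence"))
  }
  need_oof("an out-of-field exit point")
  dd <- oof_dose_at_depth(oof, loc$distance_cm)
  pct <- coeffs$exit_backscatter_deficit * dd
  skin_dose_result(pct, "exit_out_of_field")
}

#' Surface doses for a full treatment plan
#'
#' Evaluates every surface point against every beam, converts percent of
#' Dmax to absolute dose (\code{percent/100 x dmax_dose_gy}) and sums the
#' per-beam contributions per point. Output row order is deterministic
#' (points, then beams, in input order).
#'
#' @param beams list of [beam_spec()] objects with unique labels.
#' @param points list of [point_spec()] objects; each must name a location
#'   for every beam label in the plan.
#' @param coeffs a [model_coefficients()] object.
#' @param pdd a single [pdd_table()] used for all beams, or a named list of
#'   tables keyed by beam label.
#' @param oof a single [oof_model()] or a named list keyed by beam label;
#'   defaults to the exponential fallback.
#' @return An object of class \code{skindose_plan_result}: a list with
#'   \code{doses} (data.frame: point, beam, rule, percent_of_dmax, dose_gy,
#'   clamped) and \code{totals} (data.frame: point, total_gy).
#' @export
plan_dose <- function(beams, points, coeffs = model_coefficients(),
                      pdd = NULL, oof = oof_model()) {
  if (inherits(beams, "skindose_beam")) beams <- list(beams)
  if (inherits(points, "skindose_point")) points <- list(points)
  labels <- vapply(beams, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop_skindose("beam labels must be unique", "skindose_config_error")
  }
  pick <- function(x, label) {
    if (is.null(x) || inherits(x, c("skindose_pdd", "skindose_oof"))) {
      return(x)
    }
    x[[label]]
  }
  rows <- list()
  for (pt in points) {
    missing <- setdiff(labels, names(pt$locations))
    if (length(missing)) {
      stop_skindose(
        sprintf("point '%s' has no location for beam(s): %s",
                pt$name, paste(missing, collapse = ", ")),
        "skindose_config_error"
      )
    }
    for (i in seq_along(beams)) {
      bm <- beams[[i]]
      res <- point_dose(bm, pt$locations[[bm$label]], coeffs = coeffs,
                        pdd = pick(pdd, bm$label), oof = pick(oof, bm$label))
      rows[[length(rows) + 1L]] <- data.frame(
        point = pt$name, beam = bm$label, rule = res$rule,
        percent_of_dmax = res$percent_of_dmax,
        dose_gy = res$percent_of_dmax / 100 * bm$dmax_dose_gy,
        clamped = res$clamped, stringsAsFactors = FALSE
      )
    }
  }
  doses <- do.call(rbind, rows)
  totals <- stats::aggregate(dose_gy ~ point, data = doses, FUN = sum)
  names(totals)[2] <- "total_gy"
  totals <- totals[match(unique(doses$point), totals$point), , drop = FALSE]
  rownames(totals) <- NULL
  structure(list(doses = doses, totals = totals),
            class = "skindose_plan_result")
}

#' @export
print.skindose_plan_result <- function(x, ...) {
  cat("Per-beam surface doses:\n")
  shown <- x$doses
  shown$percent_of_dmax <- report_round(shown$percent_of_dmax)
  print(shown, row.names = FALSE)
  cat("\nTotals per point (Gy):\n")
  print(x$totals, row.names = FALSE)
  invisible(x)
}

#' Agreement between calculated and measured surface doses
#'
#' Summarizes a set of calculated/measured pairs (both as percent of Dmax)
#' by the mean magnitude of the local difference,
#' \eqn{\mathrm{mean}(|c-m|/m \times 100)}, and the mean absolute
#' difference in percent of Dmax, \eqn{\mathrm{mean}(|c-m|)}. The local
#' difference weights small doses heavily; the absolute difference
#' downplays large relative errors in small doses.
#'
#' @param calc,meas equal-length numeric vectors, percent of Dmax; measured
#'   values must be positive.
#' @return A list with \code{mean_local_pct} and \code{mean_absolute_pct}.
#' @export
validation_summary <- function(calc, meas) {
  if (length(calc) != length(meas) || !length(calc)) {
    stop_skindose("calc and meas must be non-empty and the same length",
                  "skindose_invalid_input")
  }
  if (any(!is.finite(calc)) || any(!is.finite(meas)) || any(meas <= 0)) {
    stop_skindose("measured doses must be finite and positive",
                  "skindose_invalid_input")
  }
  list(
    mean_local_pct = mean(abs(calc - meas) / meas * 100),
    mean_absolute_pct = mean(abs(calc - meas))
  )
}

#' Round to reporting precision
#'
#' Dose percentages are reported the way the validation tables print them:
#' values of 10 or more to the nearest integer, values below 10 to one
#' decimal place (half away from zero). Internal computation always keeps
#' full precision; use this only at the reporting boundary.
#'
#' @param x numeric vector of percentages.
#' @return Rounded vector.
#' @export
#' @examples
#' report_round(c(49.41, 6.8, 7.929))  # 49, 6.8, 7.9
report_round <- function(x) {
  half_up <- function(v, digits) {
    f <- 10^digits
    sign(v) * floor(abs(v) * f + 0.5) / f
  }
  ifelse(abs(x) >= 10, half_up(x, 0), half_up(x, 1))
}
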