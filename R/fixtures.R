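# Machine-readable encodings of the two phantom validation scenarios: a
# pediatric phantom in a 15 x 15 cm cobalt field, and an adult phantom in
# opposed 30 x 30 cm 6 MV mantle fields with lung blocks. Both carry the
# published measured doses and the published calculated doses as reference
# columns; the measured values are data only and never enter a computation.
#
# The PDD and out-of-field depth-dose tables these scenarios need are not
# part of the dose model: they come from machine commissioning data and
# generic peripheral-dose compilations. The tables shipped under
# inst/extdata are synthetic illustrative stand-ins calibrated so that the
# scenarios reproduce the published calculated values; they are not
# measured beam data (see the package vignette).

ref_row <- function(point, beam, calculated, measured, depth_dependent) {
  data.frame(point = point, beam = beam, printed_calculated = calculated,
             measured = measured, depth_dependent = depth_dependent,
             stringsAsFactors = FALSE)
}

#' Validation scenario: pediatric phantom, 15 x 15 cm cobalt field
#'
#' Opposed anterior/posterior cobalt-60 beams, 15 x 15 cm at isocenter,
#' block tray in the machine head, six measurement locations (in-field
#' anterior and posterior, under the block, tangential lateral surface, and
#' 2 and 10 cm outside the anterior field). Because of beam divergence the
#' point 2 cm outside the anterior field lies on the edge of the posterior
#' field and is flagged as a diverged-edge exit point.
#'
#' @return A list with \code{beams}, \code{points}, \code{pdd} (synthetic
#'   cobalt PDD table), \code{oof} (synthetic out-of-field dose-at-depth
#'   table) and \code{reference}, a data.frame of the published calculated
#'   and measured doses per (point, beam) with a \code{depth_dependent}
#'   flag marking cells that require a depth model.
#' @seealso [run_validation()]
#' @export
fixture_table3 <- function() {
  beams <- list(
    beam_spec("ant", "cobalt", equivalent_square = 15, tray = TRUE,
              dmax_dose_gy = 1, exit_thickness_cm = 16),
    beam_spec("post", "cobalt", equivalent_square = 15, tray = TRUE,
              dmax_dose_gy = 1, exit_thickness_cm = 16)
  )
  points <- list(
    point_spec("anterior_infield",
      ant = point_location("in_field", "entrance"),
      post = point_location("in_field", "exit", depth_cm = 16)),
    point_spec("under_block",
      ant = point_location("under_block", "entrance"),
      post = point_location("under_block", "exit", depth_cm = 16)),
    point_spec("edge_2cm",
      ant = point_location("near_field", "entrance", distance_cm = 2),
      post = point_location("near_field", "exit", distance_cm = 0,
                            depth_cm = 16.5, diverged_edge = TRUE)),
    point_spec("outside_10cm",
      ant = point_location("out_of_field", "entrance", distance_cm = 10),
      post = point_location("out_of_field", "exit", distance_cm = 10)),
    point_spec("lateral_infield",
      ant = point_location("tangential", "entrance"),
      post = point_location("tangential", "entrance")),
    point_spec("posterior_infield",
      ant = point_location("in_field", "exit", depth_cm = 16),
      post = point_location("in_field", "entrance"))
  )
  reference <- rbind(
    ref_row("anterior_infield", "ant", 41, 40, FALSE),
    ref_row("anterior_infield", "post", 39, 37, TRUE),
    ref_row("under_block", "ant", 12, 14, FALSE),
    ref_row("under_block", "post", 6.8, 9.7, FALSE),
    ref_row("edge_2cm", "ant", 12, 10, FALSE),
    ref_row("edge_2cm", "post", 19, 16, TRUE),
    ref_row("outside_10cm", "ant", 7.9, 4.2, TRUE),
    ref_row("outside_10cm", "post", 1.7, 1.1, TRUE),
    ref_row("lateral_infield", "ant", 65, 59, FALSE),
    ref_row("lateral_infield", "post", 65, 66, FALSE),
    ref_row("posterior_infield", "ant", 39, 35, TRUE),
    ref_row("posterior_infield", "post", 41, 45, FALSE)
  )
  list(
    beams = beams, points = points,
    pdd = read_pdd_table(skindose_extdata("pdd_cobalt60_synthetic.tsv"),
                         beam = "cobalt"),
    oof = read_oof_table(skindose_extdata("oof_cobalt_synthetic.tsv")),
    reference = reference
  )
}

#' Validation scenario: adult phantom, 30 x 30 cm 6 MV mantle fields
#'
#' Opposed anterior/posterior 6 MV mantle fields, 30 x 30 cm with lung
#' blocks on a block tray, nine measurement locations (in-field anterior
#' and posterior, two under-block points, two tangential lateral points,
#' and points 2, 5, and 15 cm outside the field edge). The equivalent
#' square is the unblocked jaw-defined 30 cm field. Per-beam distances and
#' depths encode the divergence of the opposed fields at each surface.
#'
#' @return Same structure as [fixture_table3()], with synthetic 6 MV PDD
#'   and out-of-field tables.
#' @export
fixture_table4 <- function() {
  beams <- list(
    beam_spec("ant", "megavoltage", jaw_x = 30, jaw_y = 30, tray = TRUE,
              dmax_dose_gy = 1, exit_thickness_cm = 22),
    beam_spec("post", "megavoltage", jaw_x = 30, jaw_y = 30, tray = TRUE,
              dmax_dose_gy = 1, exit_thickness_cm = 22)
  )
  points <- list(
    point_spec("anterior_infield",
      ant = point_location("in_field", "entrance"),
      post = point_location("in_field", "exit", depth_cm = 22)),
    point_spec("under_block_1",
      ant = point_location("under_block", "entrance"),
      post = point_location("under_block", "exit", depth_cm = 22)),
    point_spec("under_block_2",
      ant = point_location("under_block", "entrance"),
      post = point_location("under_block", "exit", depth_cm = 22)),
    point_spec("edge_2cm",
      ant = point_location("near_field", "entrance", distance_cm = 2),
      post = point_location("near_field", "exit", distance_cm = 0,
                            depth_cm = 21.5, diverged_edge = TRUE)),
    point_spec("outside_5cm",
      ant = point_location("out_of_field", "entrance", distance_cm = 5),
      post = point_location("out_of_field", "exit", distance_cm = 4.6)),
    point_spec("outside_15cm",
      ant = point_location("out_of_field", "entrance", distance_cm = 15),
      post = point_location("out_of_field", "exit", distance_cm = 15.4)),
    point_spec("lateral_infield_1",
      ant = point_location("tangential", "entrance"),
      post = point_location("tangential", "entrance")),
    point_spec("lateral_infield_2",
      ant = point_location("tangential", "entrance"),
      post = point_location("tangential", "entrance")),
    point_spec("posterior_infield",
      ant = point_location("in_field", "exit", depth_cm = 18),
      post = point_location("in_field", "entrance"))
  )
  reference <- rbind(
    ref_row("anterior_infield", "ant", 49, 48, FALSE),
    ref_row("anterior_infield", "post", 35, 28, TRUE),
    ref_row("under_block_1", "ant", 24, 26, FALSE),
    ref_row("under_block_1", "post", 6.8, 8.5, FALSE),
    ref_row("under_block_2", "ant", 24, 20, FALSE),
    ref_row("under_block_2", "post", 6.8, 10.2, FALSE),
    ref_row("edge_2cm", "ant", 24, 20, FALSE),
    ref_row("edge_2cm", "post", 18, 24, TRUE),
    ref_row("outside_5cm", "ant", 16, 10, TRUE),
    ref_row("outside_5cm", "post", 5.5, 4.0, TRUE),
    ref_row("outside_15cm", "ant", 5.0, 4.4, TRUE),
    ref_row("outside_15cm", "post", 0.9, 0.8, TRUE),
    ref_row("lateral_infield_1", "ant", 65, 56, FALSE),
    ref_row("lateral_infield_1", "post", 65, 66, FALSE),
    ref_row("lateral_infield_2", "ant", 65, 46, FALSE),
    ref_row("lateral_infield_2", "post", 65, 59, FALSE),
    ref_row("posterior_infield", "ant", 44, 42, TRUE),
    ref_row("posterior_infield", "post", 49, 61, FALSE)
  )
  list(
    beams = beams, points = points,
    pdd = read_pdd_table(skindose_extdata("pdd_mv6_synthetic.tsv"),
                         beam = "megavoltage"),
    oof = read_oof_table(skindose_extdata("oof_mv_synthetic.tsv")),
    reference = reference
  )
}

skindose_extdata <- function(file) {
  path <- system.file("extdata", file, package = "skindose")
  if (!nzchar(path)) {
    stop_skindose(sprintf("bundled data file not found: %s", file),
                  "skindose_invalid_input")
  }
  path
}

#' Run a validation scenario and compare against measurements
#'
#' Recomputes every (point, beam) dose of a validation scenario with the
#' current model, rounds to reporting precision, and summarizes agreement
#' with the measured doses as mean local and mean absolute difference.
#'
#' @param scenario \code{"table3"} (pediatric cobalt) or \code{"table4"}
#'   (adult 6 MV mantle), or a fixture list of the same structure.
#' @param coeffs a [model_coefficients()] object.
#' @return A list with \code{table} (data.frame: point, beam, rule,
#'   calculated, printed_calculated, measured, local_diff_pct,
#'   depth_dependent), \code{summary} (validation_summary of the
#'   recomputed doses against measurements) and \code{printed_summary}
#'   (same statistics for the published calculated column).
#' @export
#' @examples
#' v <- run_validation("table3")
#' v$summary$mean_local_pct
run_validation <- function(scenario = c("table3", "table4"),
                           coeffs = model_coefficients()) {
  fx <- if (is.list(scenario) && !is.null(scenario$beams)) {
    scenario
  } else {
    switch(match.arg(scenario),
           table3 = fixture_table3(),
           table4 = fixture_table4())
  }
  res <- plan_dose(fx$beams, fx$points, coeffs = coeffs,
                   pdd = fx$pdd, oof = fx$oof)
  tab <- merge(res$doses, fx$reference, by = c("point", "beam"),
               sort = FALSE)
  # merge keeps the left order (points, then beams) because both frames
  # were built in that order
  tab$calculated <- report_round(tab$percent_of_dmax)
  tab$local_diff_pct <- (tab$calculated - tab$measured) / tab$measured * 100
  tab <- tab[, c("point", "beam", "rule", "calculated",
                 "printed_calculated", "measured", "local_diff_pct",
                 "depth_dependent")]
  list(
    table = tab,
    summary = validation_summary(tab$calculated, tab$measured),
    printed_summary = validation_summary(tab$printed_calculated,
                                         tab$measured)
  )
}
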