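# Plan configs in YAML/JSON and result export in CSV/JSON.

#' Read a treatment-plan configuration
#'
#' Loads a plan from a structured YAML or JSON file. Expected layout:
#' \preformatted{
#' beams:
#'   - label: ant
#'     class: megavoltage        # or cobalt / 6MV / co60 ...
#'     field: {x: 30, y: 30}     # or {equivalent_square: 15}
#'     tray: true
#'     dmax_dose_gy: 2.0
#'     exit_thickness_cm: 22     # optional
#' points:
#'   - name: chest_center
#'     beams:
#'       ant:  {region: in_field, side: entrance}
#'       post: {region: in_field, side: exit, depth_cm: 22}
#' model:                        # optional coefficient overrides
#'   tangential_fraction: 65
#' depth_models:                 # optional
#'   pdd: pdd.tsv                # single path, or {ant: a.tsv, post: b.tsv}
#'   oof: oof.tsv                # path, or "fallback" (the default)
#' }
#' Relative table paths are resolved against the plan file's directory.
#'
#' @param path path to the plan file.
#' @return A list with \code{beams}, \code{points}, \code{coeffs},
#'   \code{pdd} and \code{oof}, ready for [plan_dose()].
#' @export
read_plan <- function(path) {
  cfg <- read_config_file(path)
  if (is.null(cfg$beams) || is.null(cfg$points)) {
    stop_skindose("plan config needs 'beams' and 'points' sections",
                  "skindose_config_error")
  }
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base_dir, p)
  }

  beams <- lapply(cfg$beams, function(b) {
    if (is.null(b$label) || is.null(b$class) || is.null(b$field)) {
      stop_skindose("each beam needs label, class and field",
                    "skindose_config_error")
    }
    beam_spec(
      label = b$label, beam = b$class,
      jaw_x = b$field$x, jaw_y = b$field$y,
      equivalent_square = b$field$equivalent_square,
      tray = isTRUE(b$tray),
      dmax_dose_gy = if (is.null(b$dmax_dose_gy)) 1 else b$dmax_dose_gy,
      exit_thickness_cm = b$exit_thickness_cm
    )
  })
  labels <- vapply(beams, `[[`, character(1), "label")

  points <- lapply(cfg$points, function(p) {
    if (is.null(p$name) || is.null(p$beams)) {
      stop_skindose("each point needs a name and per-beam locations",
                    "skindose_config_error")
    }
    locs <- lapply(p$beams, function(l) {
      point_location(
        region = l$region,
        side = if (is.null(l$side)) "entrance" else l$side,
        distance_cm = l$distance_cm,
        depth_cm = l$depth_cm,
        diverged_edge = isTRUE(l$diverged_edge)
      )
    })
    point_spec(p$name, locs)
  })

  coeffs <- if (is.null(cfg$model)) {
    model_coefficients()
  } else {
    do.call(model_coefficients, cfg$model)
  }

  class_of <- function(label) beams[[match(label, labels)]]$beam
  pdd <- NULL
  oof <- oof_model()
  dm <- cfg$depth_models
  if (!is.null(dm)) {
    if (!is.null(dm$pdd)) {
      pdd <- if (is.character(dm$pdd)) {
        # one table shared by all beams; beam class taken from the first beam
        read_pdd_table(resolve(dm$pdd), beam = beams[[1L]]$beam)
      } else {
        stats::setNames(
          lapply(names(dm$pdd), function(lb) {
            read_pdd_table(resolve(dm$pdd[[lb]]), beam = class_of(lb))
          }),
          names(dm$pdd)
        )
      }
    }
    if (!is.null(dm$oof) && !identical(dm$oof, "fallback")) {
      oof <- if (is.character(dm$oof)) {
        read_oof_table(resolve(dm$oof))
      } else {
        lapply(dm$oof, function(p) read_oof_table(resolve(p)))
      }
    }
  }
  list(beams = beams, points = points, coeffs = coeffs, pdd = pdd,
       oof = oof)
}

#' Compute a plan from a config file
#'
#' Convenience wrapper: [read_plan()] then [plan_dose()].
#'
#' @param path plan file path.
#' @return A \code{skindose_plan_result}.
#' @export
compute_plan <- function(path) {
  plan <- read_plan(path)
  plan_dose(plan$beams, plan$points, coeffs = plan$coeffs,
            pdd = plan$pdd, oof = plan$oof)
}

#' Flatten a plan result to one table
#'
#' Joins per-point totals onto the per-beam rows, giving the columns
#' \code{point, beam, rule, percent_of_dmax, dose_gy, total_gy}; percent
#' values are at reporting precision ([report_round()]).
#'
#' @param result a \code{skindose_plan_result}.
#' @return A data.frame in deterministic (input) row order.
#' @export
plan_result_table <- function(result) {
  stopifnot(inherits(result, "skindose_plan_result"))
  out <- merge(result$doses, result$totals, by = "point", sort = FALSE)
  out <- out[, c("point", "beam", "rule", "percent_of_dmax", "dose_gy",
                 "total_gy")]
  out$percent_of_dmax <- report_round(out$percent_of_dmax)
  out
}

#' Write a plan result to CSV and/or JSON
#'
#' @param result a \code{skindose_plan_result}.
#' @param csv,json output paths; either may be NULL.
#' @return The flattened table, invisibly.
#' @export
write_plan_result <- function(result, csv = NULL, json = NULL) {
  tab <- plan_result_table(result)
  if (!is.null(csv)) {
    utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(doses = tab, totals = result$totals), json,
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(tab)
}
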