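# Depth-dose inputs the surface rules need but do not define: percent depth
# dose (PDD) at the exit surface, and out-of-field dose at depth. Both come
# from user tables; the out-of-field model also has an exponential fallback
# anchored to two general published dose levels.

#' Percent-depth-dose table
#'
#' Builds a PDD table for one beam class from paired depths and values.
#' Depths must be strictly increasing and values within [0, 100] percent of
#' Dmax.
#'
#' @param depths depths in cm along the beam axis, strictly increasing, at
#'   least two.
#' @param values percent of Dmax at each depth.
#' @param beam \code{"megavoltage"} or \code{"cobalt"}.
#' @return An object of class \code{skindose_pdd}.
#' @seealso [read_pdd_table()], [pdd_lookup()]
#' @export
pdd_table <- function(depths, values, beam = "megavoltage") {
  beam <- beam_class(beam)
  if (length(depths) < 2L || length(depths) != length(values)) {
    stop_skindose("a PDD table needs at least 2 depth/value pairs",
                  "skindose_invalid_input")
  }
  if (any(!is.finite(depths)) || any(diff(depths) <= 0)) {
    stop_skindose("PDD depths must be finite and strictly increasing",
                  "skindose_invalid_input")
  }
  if (any(!is.finite(values)) || any(values < 0) || any(values > 100)) {
    stop_skindose("PDD values must lie in [0, 100] percent of Dmax",
                  "skindose_invalid_input")
  }
  structure(
    list(beam = beam, depths = as.numeric(depths),
         values = as.numeric(values)),
    class = "skindose_pdd"
  )
}

#' Read a PDD table from a delimited text file
#'
#' Expects two whitespace- or tab-delimited columns with header
#' \code{depth_cm} and \code{value_pct}; lines starting with \code{#} are
#' comments.
#'
#' @param path file path.
#' @param beam beam class of the table.
#' @return A \code{skindose_pdd} object.
#' @export
read_pdd_table <- function(path, beam = "megavoltage") {
  df <- read_two_column(path, c("depth_cm", "value_pct"))
  pdd_table(df$depth_cm, df$value_pct, beam = beam)
}

#' Interpolate a PDD table at a depth
#'
#' Linear interpolation between the bracketing rows; exact on table nodes.
#' Depths outside the tabulated range are an error (no extrapolation).
#'
#' @param table a [pdd_table()].
#' @param depth depth in cm.
#' @return Percent of Dmax at \code{depth}.
#' @export
pdd_lookup <- function(table, depth) {
  stopifnot(inherits(table, "skindose_pdd"))
  rng <- range(table$depths)
  if (any(!is.finite(depth)) || any(depth < rng[1]) || any(depth > rng[2])) {
    stop_skindose(
      sprintf("depth outside the tabulated PDD range [%g, %g] cm",
              rng[1], rng[2]),
      "skindose_out_of_range"
    )
  }
  stats::approx(table$depths, table$values, xout = depth,
                method = "linear", ties = "ordered")$y
}

#' Out-of-field dose-at-depth model
#'
#' The far out-of-field surface rule scales the dose at depth (a few cm
#' below the surface, where dose is roughly constant with depth) at a given
#' distance from the field edge. That dose at depth comes from generic
#' out-of-field photon dose data. Two modes:
#' \describe{
#'   \item{exponential_fallback}{\eqn{A e^{-b\chi}} with \code{A} and
#'     \code{b} solved from two general anchor levels: ~1% of Dmax at 10 cm
#'     from the field edge and ~0.05% at 50 cm, giving
#'     \eqn{b = \ln(20)/40 \approx 0.0749\ \mathrm{cm}^{-1}} and
#'     \eqn{A = 20^{1/4} \approx 2.115}. Carries no field-size dependence.}
#'   \item{user_table}{linear interpolation of a user-supplied
#'     distance/value table (strictly decreasing values), e.g. digitized
#'     general peripheral-dose compilations for a specific field size.}
#' }
#'
#' @param table optional data.frame with columns \code{distance_cm} and
#'   \code{value_pct}; supplying it selects \code{user_table} mode.
#' @param amplitude,decay fallback parameters; defaults solve the two-anchor
#'   system above.
#' @return An object of class \code{skindose_oof}.
#' @export
#' @examples
#' m <- oof_model()
#' oof_dose_at_depth(m, 10)  # 1
#' oof_dose_at_depth(m, 50)  # 0.05
oof_model <- function(table = NULL,
                      amplitude = 20^(1 / 4),
                      decay = log(20) / 40) {
  if (!is.null(table)) {
    if (!all(c("distance_cm", "value_pct") %in% names(table))) {
      stop_skindose(
        "out-of-field table needs columns distance_cm and value_pct",
        "skindose_invalid_input"
      )
    }
    d <- as.numeric(table$distance_cm)
    v <- as.numeric(table$value_pct)
    if (length(d) < 2L || any(!is.finite(d)) || any(diff(d) <= 0)) {
      stop_skindose("out-of-field distances must be strictly increasing",
                    "skindose_invalid_input")
    }
    if (any(!is.finite(v)) || any(v < 0) || any(diff(v) >= 0)) {
      stop_skindose("out-of-field doses must be strictly decreasing in distance",
                    "skindose_invalid_input")
    }
    return(structure(list(mode = "user_table", distance_cm = d,
                          value_pct = v),
                     class = "skindose_oof"))
  }
  if (amplitude <= 0 || decay <= 0) {
    stop_skindose("amplitude and decay must be positive",
                  "skindose_invalid_input")
  }
  structure(list(mode = "exponential_fallback", amplitude = amplitude,
                 decay = decay),
            class = "skindose_oof")
}

#' Read an out-of-field dose-at-depth table
#'
#' Two delimited columns with header \code{distance_cm} and
#' \code{value_pct}; \code{#} comments allowed. Returns a user-table
#' [oof_model()].
#'
#' @param path file path.
#' @return A \code{skindose_oof} object in \code{user_table} mode.
#' @export
read_oof_table <- function(path) {
  oof_model(table = read_two_column(path, c("distance_cm", "value_pct")))
}

#' Out-of-field dose at depth at a distance from the field edge
#'
#' @param model an [oof_model()].
#' @param distance distance from the field edge in cm. The exponential
#'   fallback is anchored only beyond the near-field region and refuses
#'   distances of 2 cm or less; a user table is interpolated over its own
#'   range.
#' @return Percent of Dmax.
#' @export
oof_dose_at_depth <- function(model, distance) {
  stopifnot(inherits(model, "skindose_oof"))
  if (any(!is.finite(distance)) || any(distance < 0)) {
    stop_skindose("distance must be finite and non-negative",
                  "skindose_invalid_input")
  }
  if (model$mode == "exponential_fallback") {
    if (any(distance <= 2)) {
      stop_skindose(
        "the exponential out-of-field fallback applies beyond 2 cm from the field edge; supply a user table for nearer points",
        "skindose_wrong_rule"
      )
    }
    return(model$amplitude * exp(-model$decay * distance))
  }
  rng <- range(model$distance_cm)
  if (any(distance < rng[1]) || any(distance > rng[2])) {
    stop_skindose(
      sprintf("distance outside the tabulated out-of-field range [%g, %g] cm",
              rng[1], rng[2]),
      "skindose_out_of_range"
    )
  }
  stats::approx(model$distance_cm, model$value_pct, xout = distance,
                method = "linear", ties = "ordered")$y
}

# strict two-column reader shared by the PDD and out-of-field tables
read_two_column <- function(path, expected) {
  if (!file.exists(path)) {
    stop_skindose(sprintf("table file not found: %s", path),
                  "skindose_invalid_input")
  }
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!identical(names(df), expected)) {
    stop_skindose(
      sprintf("expected header '%s' in %s, found '%s'",
              paste(expected, collapse = " "), path,
              paste(names(df), collapse = " ")),
      "skindose_invalid_input"
    )
  }
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop_skindose(sprintf("non-numeric entries in %s", path),
                  "skindose_invalid_input")
  }
  df
}
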