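#' Cage geometry for a divided-cohabitation recording
#'
#' Describes the recording arena in image coordinates (origin top-left, y
#' increasing downward) together with the physical scale. The divider runs
#' vertically through the cage; each animal occupies one compartment
#' (`"left"` or `"right"` of the divider).
#'
#' @param cage_length_cm Cage length along the divided axis (default 48.3).
#' @param cage_width_cm Cage width (default 25.4).
#' @param px_per_cm Pixel scale (> 0).
#' @param frame_rate_hz Acquisition frame rate in Hz (> 0).
#' @param x_min,y_min Pixel coordinates of the cage's top-left corner.
#' @return An object of class `cage_geometry`: a list with the cage pixel
#'   rectangle, `divider_x` (the divider's pixel abscissa, at the cage
#'   center), and the scale fields.
#' @examples
#' geom <- cage_geometry(px_per_cm = 10, frame_rate_hz = 20)
#' geom$divider_x
#' @export
cage_geometry <- function(cage_length_cm = 48.3, cage_width_cm = 25.4,
                          px_per_cm = 10, frame_rate_hz = 20,
                          x_min = 0, y_min = 0) {
  stopifnot(px_per_cm > 0, frame_rate_hz > 0,
            cage_length_cm > 0, cage_width_cm > 0)
  x_max <- x_min + cage_length_cm * px_per_cm
  y_max <- y_min + cage_width_cm * px_per_cm
  structure(list(
    x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
    divider_x = x_min + cage_length_cm * px_per_cm / 2,
    px_per_cm = px_per_cm, frame_rate_hz = frame_rate_hz,
    cage_length_cm = cage_length_cm, cage_width_cm = cage_width_cm
  ), class = "cage_geometry")
}

#' @export
print.cage_geometry <- function(x, ...) {
  cat(sprintf("cage_geometry: %.1f x %.1f cm, %.1f px/cm, %g Hz, divider_x = %.1f px\n",
              x$cage_length_cm, x$cage_width_cm, x$px_per_cm,
              x$frame_rate_hz, x$divider_x))
  invisible(x)
}

#' Per-animal compartment of a divided cage
#'
#' @param geometry A [cage_geometry()].
#' @param side `"left"` or `"right"` of the divider.
#' @return A `cage_geometry` restricted to one compartment, with
#'   `compartment_box` (x_min, y_min, x_max, y_max) and `normal_sign`
#'   (+1 if the divider lies toward increasing x from the compartment,
#'   -1 otherwise). The divider normal used by the decomposition points
#'   from the compartment toward the divider.
#' @export
compartment <- function(geometry, side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(inherits(geometry, "cage_geometry"))
  g <- geometry
  if (side == "left") {
    g$compartment_box <- c(x_min = geometry$x_min, y_min = geometry$y_min,
                           x_max = geometry$divider_x, y_max = geometry$y_max)
    g$normal_sign <- 1
  } else {
    g$compartment_box <- c(x_min = geometry$divider_x, y_min = geometry$y_min,
                           x_max = geometry$x_max, y_max = geometry$y_max)
    g$normal_sign <- -1
  }
  g$side <- side
  g
}

#' Dyad record: conditions, subtype, and dyad type
#'
#' Each dyad pairs one male and one female, each raised under control (`Ctrl`)
#' or early-life sleep disruption (`ELSD`) conditions. The subtype names the
#' male condition first; the dyad type is `matched` when both conditions are
#' equal and `mixed` otherwise, and is always derived, never stored.
#'
#' @param dyad_id Identifier.
#' @param male_condition,female_condition `"Ctrl"` or `"ELSD"`.
#' @return A `dyad_record` list with `subtype` (e.g. `"Ctrl-ELSD"`) and
#'   `dyad_type` (`"matched"` or `"mixed"`).
#' @export
dyad_record <- function(dyad_id, male_condition, female_condition) {
  male_condition <- match.arg(male_condition, c("Ctrl", "ELSD"))
  female_condition <- match.arg(female_condition, c("Ctrl", "ELSD"))
  structure(list(
    dyad_id = as.character(dyad_id),
    male_condition = male_condition,
    female_condition = female_condition,
    subtype = paste(male_condition, female_condition, sep = "-"),
    dyad_type = if (male_condition == female_condition) "matched" else "mixed"
  ), class = "dyad_record")
}

#' @export
print.dyad_record <- function(x, ...) {
  cat(sprintf("dyad %s: %s (%s)\n", x$dyad_id, x$subtype, x$dyad_type))
  invisible(x)
}

#' Default cohort of dyad records
#'
#' Builds the study's default cohort: subtype counts for
#' Ctrl-Ctrl, ELSD-ELSD, Ctrl-ELSD, ELSD-Ctrl (male condition first),
#' defaulting to 7, 8, 7, 6 for a total of 28 dyads (15 matched, 13 mixed).
#'
#' @param n_per_subtype Integer vector of length 4.
#' @return List of [dyad_record()] objects.
#' @export
cohort_records <- function(n_per_subtype = c(7L, 8L, 7L, 6L)) {
  stopifnot(length(n_per_subtype) == 4, all(n_per_subtype >= 0))
  subtypes <- list(c("Ctrl", "Ctrl"), c("ELSD", "ELSD"),
                   c("Ctrl", "ELSD"), c("ELSD", "Ctrl"))
  recs <- list()
  k <- 0L
  for (i in seq_along(subtypes)) {
    for (j in seq_len(n_per_subtype[i])) {
      k <- k + 1L
      recs[[k]] <- dyad_record(sprintf("dyad%02d", k),
                               subtypes[[i]][1], subtypes[[i]][2])
    }
  }
  recs
}
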