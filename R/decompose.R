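#' @importFrom stats na.omit
NULL

new_variable_series <- function(track, value, variable) {
  df <- data.frame(frame = track$frame, clock_s = track$clock_s,
                   value = value, missing = is.na(value))
  structure(df, animal_id = attr(track, "animal_id"), variable = variable,
            class = c("variable_series", "data.frame"))
}

#' Animal center from keypoints
#'
#' The animal center is the centroid of the three spine keypoints (robust to
#' nose/tail occlusion); `method = "all"` uses all seven keypoints instead.
#'
#' @param track A `keypoint_track`.
#' @param method `"spine"` (default) or `"all"`.
#' @return Two-column matrix (x, y) in pixels, NA where keypoints are missing.
#' @export
animal_center <- function(track, method = c("spine", "all")) {
  method <- match.arg(method)
  bp <- if (method == "spine") c("spine1", "spine2", "spine3") else keypoint_names()
  xs <- as.matrix(as.data.frame(track)[paste0(bp, "_x")])
  ys <- as.matrix(as.data.frame(track)[paste0(bp, "_y")])
  cbind(x = rowMeans(xs), y = rowMeans(ys))
}

heading_vectors <- function(track) {
  df <- as.data.frame(track)
  cbind(x = df$nose_x - df$tail_base_x, y = df$nose_y - df$tail_base_y)
}

# unsigned angle (radians, [0, pi]) between heading rows and a unit normal;
# NA for zero-length headings
unsigned_angle <- function(h, n) {
  len <- sqrt(rowSums(h^2))
  nlen <- sqrt(rowSums(n^2))
  cosphi <- rowSums(h * n) / (len * nlen)
  phi <- acos(pmin(1, pmax(-1, cosphi)))
  phi[len == 0 | !is.finite(len)] <- NA_real_
  phi
}

# linear (default) or cosine rescaling of the unsigned angle to [-1, 1]
angle_score <- function(phi, scaling = c("linear", "cosine")) {
  scaling <- match.arg(scaling)
  if (scaling == "linear") 1 - phi / (pi / 2) else cos(phi)
}

#' Body direction to the divider
#'
#' Per frame, a line is fit through the body extremes (tail base to nose) and
#' compared with the unit normal pointing from the animal's compartment
#' toward the divider. The unsigned angle between the two (0-180 degrees) is
#' rescaled to a score: +1 facing the divider, 0 parallel to it, -1 facing
#' away. Clockwise and counterclockwise rotations are treated equally: the
#' score depends only on the unsigned angle. The default rescaling is linear
#' in the angle (`1 - angle/90`, degrees); `scaling = "cosine"` uses the
#' cosine instead.
#'
#' Frames with a zero-length body axis (nose coincides with tail base) or
#' missing extremes yield missing values.
#'
#' @param track A `keypoint_track`.
#' @param geometry A [compartment()] (supplies the divider normal direction).
#' @param scaling `"linear"` (default) or `"cosine"`.
#' @return A `variable_series` with values in \[-1, 1\].
#' @export
direction_to_divider <- function(track, geometry = attr(track, "geometry"),
                                 scaling = c("linear", "cosine")) {
  stopifnot(!is.null(geometry), !is.null(geometry$normal_sign))
  h <- heading_vectors(track)
  n <- cbind(rep(geometry$normal_sign, nrow(h)), 0)
  phi <- unsigned_angle(h, n)
  n_zero <- sum(is.na(phi) & !is.na(h[, 1]))
  if (n_zero > 0) {
    message(n_zero, " frame(s) with zero-length body axis set to missing")
  }
  new_variable_series(track, angle_score(phi, scaling), "direction_to_divider")
}

#' Distance to the divider
#'
#' Horizontal distance (cm) between the animal center and the divider line,
#' regardless of position along the vertical axis.
#'
#' @inheritParams direction_to_divider
#' @param center_method Passed to [animal_center()].
#' @return A `variable_series` with non-negative values in cm.
#' @export
distance_to_divider <- function(track, geometry = attr(track, "geometry"),
                                center_method = "spine") {
  stopifnot(!is.null(geometry))
  ctr <- animal_center(track, center_method)
  box <- geometry$compartment_box
  if (!is.null(box)) {
    outside <- sum(ctr[, "x"] < box["x_min"] | ctr[, "x"] > box["x_max"], na.rm = TRUE)
    if (outside > 0) {
      warning(outside, " frame(s) with animal center outside its compartment")
    }
  }
  val <- abs(ctr[, "x"] - geometry$divider_x) / geometry$px_per_cm
  new_variable_series(track, unname(val), "distance_to_divider")
}

#' Locomotion speed
#'
#' Per consecutive frame pair, the displacement hypotenuse of the animal
#' center converted to cm and multiplied by the frame rate, giving cm/s.
#' The value is assigned to the later frame; the first frame is missing.
#'
#' @inheritParams distance_to_divider
#' @return A `variable_series` with non-negative values in cm/s.
#' @export
locomotion_speed <- function(track, geometry = attr(track, "geometry"),
                             center_method = "spine") {
  stopifnot(!is.null(geometry), nrow(track) >= 2)
  ctr <- animal_center(track, center_method)
  d <- sqrt(diff(ctr[, "x"])^2 + diff(ctr[, "y"])^2) / geometry$px_per_cm
  val <- c(NA_real_, d * geometry$frame_rate_hz)
  new_variable_series(track, val, "locomotion_speed")
}

#' Dyad-level mutual variables
#'
#' Mutual distance is the center-to-center distance between the two animals
#' in cm. Mutual direction scores each animal's heading against the unit
#' vector pointing at its partner's center (same rescaling as
#' [direction_to_divider()]) and averages the two, so +1 means both animals
#' face each other and -1 both face away.
#'
#' @param track_m,track_f Synchronized `keypoint_track`s (same frames).
#' @param geometry A [cage_geometry()].
#' @param scaling Angle rescaling, as in [direction_to_divider()].
#' @return A list with `mutual_distance` and `mutual_direction`
#'   `variable_series` (attached to the male track's frame axis).
#' @export
dyad_mutual_variables <- function(track_m, track_f,
                                  geometry = attr(track_m, "geometry"),
                                  scaling = "linear") {
  if (nrow(track_m) != nrow(track_f) || any(track_m$frame != track_f$frame)) {
    stop("alignment error: dyad tracks are not frame-synchronized")
  }
  cm <- animal_center(track_m)
  cf <- animal_center(track_f)
  sep <- cf - cm
  dist_cm <- sqrt(rowSums(sep^2)) / geometry$px_per_cm
  score_m <- angle_score(unsigned_angle(heading_vectors(track_m), sep), scaling)
  score_f <- angle_score(unsigned_angle(heading_vectors(track_f), -sep), scaling)
  list(
    mutual_distance = new_variable_series(track_m, unname(dist_cm), "mutual_distance"),
    mutual_direction = new_variable_series(track_m, (score_m + score_f) / 2,
                                           "mutual_direction")
  )
}

#' Decompose a keypoint track into the three divided-cage variables
#'
#' Convenience wrapper computing direction to divider, distance to divider,
#' and locomotion speed, and optionally writing the standard per-animal
#' decomposition table (`frame,clock_s,direction,distance_cm,speed_cms,missing`).
#'
#' @inheritParams direction_to_divider
#' @param path Optional output CSV path.
#' @return Named list of three `variable_series`.
#' @export
decompose_track <- function(track, geometry = attr(track, "geometry"),
                            path = NULL) {
  out <- list(
    direction = direction_to_divider(track, geometry),
    distance = distance_to_divider(track, geometry),
    speed = locomotion_speed(track, geometry)
  )
  if (!is.null(path)) {
    df <- data.frame(frame = out$direction$frame,
                     clock_s = out$direction$clock_s,
                     direction = out$direction$value,
                     distance_cm = out$distance$value,
                     speed_cms = out$speed$value)
    df$missing <- is.na(df$direction) | is.na(df$distance_cm)
    data.table::fwrite(df, path)
  }
  out
}
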