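#' @importFrom data.table fread fwrite as.data.table :=
#' @importFrom stats approx
NULL

kp_columns <- function() {
  bp <- keypoint_names()
  as.vector(t(outer(bp, c("x", "y", "conf"), paste, sep = "_")))
}

new_keypoint_track <- function(df, animal_id, geometry = NULL, clock_start = 0) {
  df <- as.data.frame(df)
  structure(df, animal_id = animal_id, geometry = geometry,
            clock_start = clock_start,
            class = c("keypoint_track", "data.frame"))
}

#' Read a per-frame keypoint table
#'
#' Reads the comma-separated keypoint dialect written by pose trackers and by
#' [generate_divided_cohort()]: one header row, columns `frame` and
#' `<bodypart>_x`, `<bodypart>_y`, `<bodypart>_conf` for each of the seven
#' body parts (nose, ear_left, ear_right, spine1, spine2, spine3, tail_base).
#' A two-level header (`bodypart,coordinate`) as exported by some trackers is
#' also accepted and flattened.
#'
#' Rows with missing coordinates are flagged in the `incomplete` column, not
#' dropped; low-confidence handling is a separate, explicit step
#' ([interpolate_low_confidence()]).
#'
#' @param path File path.
#' @param geometry Optional [cage_geometry()] (typically a [compartment()]);
#'   attached to the track and used for the clock axis.
#' @param animal_id Identifier stored on the track.
#' @param clock_start Seconds between session start and this file's first
#'   frame (from the sidecar metadata, not the filename).
#' @return A `keypoint_track` data frame with `frame`, `clock_s`, the 21
#'   keypoint columns, and `incomplete`.
#' @export
read_keypoint_table <- function(path, geometry = NULL, animal_id = basename(path),
                                clock_start = 0) {
  if (!file.exists(path)) stop("keypoint file not found: ", path)
  hdr <- readLines(path, n = 2L)
  # a letter anywhere in line 2 means line 2 is a header line too
  if (length(hdr) == 2L && grepl("[a-zA-Z]", hdr[2])) {
    # two-level header: line 1 = bodypart (first cell "frame"),
    # line 2 = coordinate (x / y / conf or likelihood)
    bps <- strsplit(hdr[1], ",")[[1]]
    coords <- strsplit(hdr[2], ",")[[1]]
    length(coords) <- length(bps)
    df <- fread(path, skip = 2L, header = FALSE, data.table = FALSE)
    names(df) <- ifelse(coords %in% c("x", "y", "conf", "likelihood"),
                        paste(bps, sub("likelihood", "conf", coords), sep = "_"),
                        bps)
  } else {
    df <- fread(path, header = TRUE, data.table = FALSE)
  }
  validate_keypoint_frame(df, path)
  rate <- if (!is.null(geometry)) geometry$frame_rate_hz else attr(df, "frame_rate_hz")
  if (is.null(rate)) rate <- 20
  df <- df[, c("frame", kp_columns())]
  coord_cols <- grep("_(x|y)$", names(df), value = TRUE)
  df$incomplete <- rowSums(is.na(df[coord_cols])) > 0
  df <- cbind(df[, "frame", drop = FALSE],
              clock_s = clock_start + (df$frame - df$frame[1]) / rate,
              df[, -match("frame", names(df))])
  new_keypoint_track(df, animal_id, geometry, clock_start)
}

validate_keypoint_frame <- function(df, path = "<data>") {
  missing_cols <- setdiff(c("frame", kp_columns()), names(df))
  if (length(missing_cols)) {
    bp <- unique(sub("_(x|y|conf)$", "", missing_cols))
    stop("keypoint format error in ", path, ": missing column(s) for ",
         paste(bp, collapse = ", "), " (", paste(missing_cols, collapse = ", "), ")")
  }
  if (nrow(df) > 1 && any(diff(df$frame) <= 0)) {
    stop("keypoint data error in ", path, ": frame index not strictly increasing")
  }
  conf <- as.matrix(df[grep("_conf$", names(df))])
  if (any(conf < 0 | conf > 1, na.rm = TRUE)) {
    stop("keypoint data error in ", path, ": confidence outside [0, 1]")
  }
  invisible(TRUE)
}

#' Write a keypoint table
#'
#' Inverse of [read_keypoint_table()]; `clock_s` and `incomplete` are derived
#' columns and are not written.
#'
#' @param track A `keypoint_track`.
#' @param path Output path.
#' @export
write_keypoint_table <- function(track, path) {
  fwrite(as.data.frame(track)[, c("frame", kp_columns())], path)
  invisible(path)
}

#' Interpolate low-confidence keypoints
#'
#' Frames where a keypoint's confidence falls below `threshold` have that
#' keypoint's coordinates replaced by linear interpolation from the nearest
#' confident neighbors, for gaps up to `max_gap_s`; longer gaps are left as
#' missing (NA) so they become missing bin contributions downstream.
#'
#' @param track A `keypoint_track`.
#' @param threshold Confidence threshold (default 0.6).
#' @param max_gap_s Maximum gap bridged by interpolation, seconds (default 1).
#' @return The track with interpolated coordinates; interpolated or dropped
#'   frames are reflected in the `incomplete` flag.
#' @export
interpolate_low_confidence <- function(track, threshold = 0.6, max_gap_s = 1) {
  geom <- attr(track, "geometry")
  rate <- if (!is.null(geom)) geom$frame_rate_hz else 20
  max_gap <- max(1L, round(max_gap_s * rate))
  df <- as.data.frame(track)
  for (bp in keypoint_names()) {
    conf <- df[[paste0(bp, "_conf")]]
    bad <- is.na(conf) | conf < threshold
    if (!any(bad)) next
    runs <- rle(bad)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      idx <- starts[k]:ends[k]
      for (ax in c("_x", "_y")) {
        col <- paste0(bp, ax)
        if (runs$lengths[k] <= max_gap && starts[k] > 1 && ends[k] < nrow(df)) {
          df[idx, col] <- approx(x = c(starts[k] - 1L, ends[k] + 1L),
                                 y = df[c(starts[k] - 1L, ends[k] + 1L), col],
                                 xout = idx)$y
        } else {
          df[idx, col] <- NA_real_
        }
      }
    }
  }
  coord_cols <- grep("_(x|y)$", names(df), value = TRUE)
  df$incomplete <- rowSums(is.na(df[coord_cols])) > 0
  new_keypoint_track(df, attr(track, "animal_id"), geom, attr(track, "clock_start"))
}

#' Align multi-segment recordings on a common clock axis
#'
#' Long sessions are acquired as consecutive files (e.g., twelve 6-h files
#' for a 72-h session), each with a short safety margin at both ends.
#' `align_segments` trims `margin_s` from each end of every segment and
#' concatenates them on a clock axis that starts at session start and is
#' never reset, so every frame has a unique temporal identifier.
#'
#' Segment order and start times come from each track's `clock_start`
#' attribute (set from the sidecar metadata at read time). Overlap after
#' trimming is an error; gaps larger than `gap_tolerance_s` are retained as
#' missing time (a warning is issued) and surface as missing bins downstream.
#'
#' @param segments List of `keypoint_track` objects, any order.
#' @param margin_s Margin trimmed from both ends of each segment (default 2).
#' @param gap_tolerance_s Gap size above which a warning is issued (default 1).
#' @return One concatenated `keypoint_track`; `clock_s` strictly increasing.
#' @export
align_segments <- function(segments, margin_s = 2, gap_tolerance_s = 1) {
  stopifnot(length(segments) >= 1, margin_s >= 0)
  geom <- attr(segments[[1]], "geometry")
  rate <- if (!is.null(geom)) geom$frame_rate_hz else 20
  starts <- vapply(segments, function(s) attr(s, "clock_start"), numeric(1))
  segments <- segments[order(starts)]
  margin_frames <- round(margin_s * rate)
  trimmed <- lapply(segments, function(s) {
    df <- as.data.frame(s)
    n <- nrow(df)
    if (n <= 2 * margin_frames) stop("alignment error: segment shorter than its margins")
    df[(margin_frames + 1):(n - margin_frames), , drop = FALSE]
  })
  session_start <- min(vapply(trimmed, function(d) d$clock_s[1], numeric(1)))
  prev_end <- -Inf
  for (d in trimmed) {
    if (d$clock_s[1] <= prev_end) {
      stop("alignment error: segments overlap after margin trimming")
    }
    gap <- d$clock_s[1] - prev_end - 1 / rate
    if (is.finite(prev_end) && gap > gap_tolerance_s) {
      warning(sprintf("gap of %.2f s between segments retained as missing time", gap))
    }
    prev_end <- d$clock_s[nrow(d)]
  }
  out <- do.call(rbind, trimmed)
  out$clock_s <- out$clock_s - session_start
  out$frame <- as.integer(round(out$clock_s * rate))
  rownames(out) <- NULL
  new_keypoint_track(out, attr(segments[[1]], "animal_id"), geom, 0)
}

#' Read / write per-frame behavior score tables
#'
#' Score tables hold, per frame, one likelihood column per raw classifier
#' category (see [raw_categories()]), each on a 0-1 scale. Values outside
#' the unit interval are rejected with the offending frame index.
#'
#' @param path File path.
#' @param animal_id Identifier stored on the table.
#' @param categories Expected category columns (default [raw_categories()];
#'   consolidated tables use [working_categories()]).
#' @return A `behavior_scores` data frame (`frame` + one column per category).
#' @export
read_behavior_scores <- function(path, animal_id = basename(path),
                                 categories = raw_categories()) {
  if (!file.exists(path)) stop("score file not found: ", path)
  df <- fread(path, header = TRUE, data.table = FALSE)
  missing_cols <- setdiff(c("frame", categories), names(df))
  if (length(missing_cols)) {
    stop("score format error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, c("frame", categories)]
  m <- as.matrix(df[categories])
  bad <- which(m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("score data error in ", path, ": likelihood outside [0, 1] at frame ",
         df$frame[bad[1, 1]])
  }
  structure(df, animal_id = animal_id, categories = categories,
            class = c("behavior_scores", "data.frame"))
}

#' @rdname read_behavior_scores
#' @param scores A `behavior_scores` table.
#' @export
write_behavior_scores <- function(scores, path) {
  fwrite(as.data.frame(scores), path)
  invisible(path)
}

#' Read / write attack annotation tracks
#'
#' Annotation tracks carry the manually validated aggression channel: per
#' frame, binary `attacking` and `being_attacked` flags. The two flags can
#' never both be set for the same animal-frame.
#'
#' @param path File path.
#' @param animal_id Identifier stored on the track.
#' @return An `annotation_track` data frame (`frame`, `attacking`,
#'   `being_attacked`, logical).
#' @export
read_annotation_track <- function(path, animal_id = basename(path)) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- fread(path, header = TRUE, data.table = FALSE)
  need <- c("frame", "attacking", "being_attacked")
  if (length(setdiff(need, names(df)))) {
    stop("annotation format error in ", path, ": need columns ",
         paste(need, collapse = ", "))
  }
  for (col in c("attacking", "being_attacked")) {
    if (!all(df[[col]] %in% c(0, 1, TRUE, FALSE))) {
      stop("annotation data error in ", path, ": ", col, " not binary")
    }
    df[[col]] <- as.logical(df[[col]])
  }
  both <- which(df$attacking & df$being_attacked)
  if (length(both)) {
    stop("annotation data error in ", path,
         ": attacking and being_attacked both set at frame ", df$frame[both[1]])
  }
  structure(df[, need], animal_id = animal_id,
            class = c("annotation_track", "data.frame"))
}

#' @rdname read_annotation_track
#' @param annotations An `annotation_track`.
#' @export
write_annotation_track <- function(annotations, path) {
  df <- as.data.frame(annotations)
  df$attacking <- as.integer(df$attacking)
  df$being_attacked <- as.integer(df$being_attacked)
  fwrite(df, path)
  invisible(path)
}

#' Read / write per-dyad frame-level label streams
#'
#' Label streams are written as `frame,label_m,label_f` with a `#`-prefixed
#' header line recording the vocabulary, so a file is self-describing.
#'
#' @param path File path.
#' @return A `dyad_labels` data frame with a `vocabulary` attribute.
#' @export
read_dyad_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  first <- readLines(path, n = 1L)
  vocab <- NULL
  if (startsWith(first, "#")) {
    vocab <- strsplit(sub("^#\\s*vocabulary=", "", first), ",")[[1]]
  }
  df <- fread(path, header = TRUE, skip = if (is.null(vocab)) 0L else 1L,
              data.table = FALSE)
  if (is.null(vocab)) vocab <- label_vocabulary()
  bad <- setdiff(unique(c(df$label_m, df$label_f)), c(vocab, NA))
  if (length(bad)) stop("label data error in ", path, ": labels outside vocabulary: ",
                        paste(bad, collapse = ", "))
  structure(df, vocabulary = vocab, class = c("dyad_labels", "data.frame"))
}

#' @rdname read_dyad_labels
#' @param labels A `dyad_labels` data frame (columns `frame,label_m,label_f`).
#' @param vocabulary Category vocabulary recorded in the header.
#' @export
write_dyad_labels <- function(labels, path, vocabulary = attr(labels, "vocabulary")) {
  if (is.null(vocabulary)) vocabulary <- label_vocabulary()
  writeLines(paste0("# vocabulary=", paste(vocabulary, collapse = ",")), path)
  fwrite(as.data.frame(labels), path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read / write cohort sidecar metadata
#'
#' Clock and design metadata live in a YAML sidecar, not in filenames:
#' recording geometry, session start, per-file segment order and start
#' offsets, and the dyad records (conditions per animal).
#'
#' @param path YAML file path.
#' @return A list with `geometry` (a [cage_geometry()]), `records`
#'   (list of [dyad_record()]), and any further fields present.
#' @export
read_cohort_metadata <- function(path) {
  meta <- yaml::read_yaml(path)
  g <- meta$geometry
  meta$geometry <- cage_geometry(g$cage_length_cm, g$cage_width_cm,
                                 g$px_per_cm, g$frame_rate_hz)
  meta$records <- lapply(meta$records, function(r) {
    dyad_record(r$dyad_id, r$male_condition, r$female_condition)
  })
  meta
}

#' @rdname read_cohort_metadata
#' @param meta Metadata list (as returned by the generators).
#' @export
write_cohort_metadata <- function(meta, path) {
  m <- meta
  g <- m$geometry
  m$geometry <- list(cage_length_cm = g$cage_length_cm,
                     cage_width_cm = g$cage_width_cm,
                     px_per_cm = g$px_per_cm,
                     frame_rate_hz = g$frame_rate_hz)
  m$records <- lapply(m$records, function(r) {
    list(dyad_id = r$dyad_id, male_condition = r$male_condition,
         female_condition = r$female_condition)
  })
  yaml::write_yaml(m, path)
  invisible(path)
}
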