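#' Behavior vocabularies
#'
#' Category sets used across the pipeline, in their fixed analysis order.
#'
#' * `raw_categories()` — the nine per-frame classifier output categories.
#'   The classifier's `aggression` output is ignored downstream (aggression
#'   is taken from manual attack annotations instead).
#' * `working_categories()` — the consolidated score-table columns after
#'   [consolidate_categories()]: focal categories first, mirror roles last.
#' * `analysis_categories()` — the five analysis labels (chasing, attacking,
#'   pointing, behaving_alone, huddling); `attacking` enters only through
#'   the annotation overlay, never through classifier scores.
#' * `mirror_categories()` — recipient-role labels retained as metadata.
#' * `orientation_categories()` — the four divided-cage occupancy classes
#'   used for transition analysis.
#'
#' Ties in winner-takes-all steps are broken by position in these vectors,
#' so their order is part of the pipeline's contract.
#'
#' @return Character vector of category names.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
raw_categories <- function() {
  c("aggression", "chasing", "being_chased", "approaching", "sniffing",
    "being_sniffed", "moving_alone", "idling_alone", "huddling")
}

#' @rdname vocabularies
#' @export
working_categories <- function() {
  c("chasing", "pointing", "behaving_alone", "huddling",
    "being_chased", "being_pointed_at")
}

#' @rdname vocabularies
#' @export
analysis_categories <- function() {
  c("chasing", "attacking", "pointing", "behaving_alone", "huddling")
}

#' @rdname vocabularies
#' @export
mirror_categories <- function() {
  c("being_chased", "being_attacked", "being_pointed_at")
}

#' @rdname vocabularies
#' @export
label_vocabulary <- function() {
  c(analysis_categories(), mirror_categories())
}

#' @rdname vocabularies
#' @export
orientation_categories <- function() {
  c("toward-near", "opposite-near", "toward-away", "opposite-away")
}

# keypoint names in fixed column order
keypoint_names <- function() {
  c("nose", "ear_left", "ear_right", "spine1", "spine2", "spine3", "tail_base")
}
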