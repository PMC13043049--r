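#' Consolidate raw classifier categories into the working set
#'
#' Applies the category adaptations used for analysis:
#' * `pointing` = max likelihood over the sniffing variants and
#'   `approaching` (sniffing-type behaviors and the freezing-like
#'   orientation toward the partner are analyzed as one category);
#'   `being_pointed_at` mirrors `being_sniffed`.
#' * `behaving_alone` = max over `moving_alone` and `idling_alone`.
#' * the classifier's `aggression` column is dropped: aggression enters the
#'   pipeline only through manual attack annotations ([labelize()]).
#' * `chasing`, `being_chased`, `huddling` pass through unchanged.
#'
#' The merge operator is max, so likelihoods stay in \[0, 1\].
#'
#' @param scores A `behavior_scores` table over [raw_categories()].
#' @return A `behavior_scores` table over [working_categories()].
#' @export
consolidate_categories <- function(scores) {
  df <- as.data.frame(scores)
  unknown <- setdiff(attr(scores, "categories"), raw_categories())
  if (length(unknown)) {
    stop("mapping error: unknown raw category ", paste(unknown, collapse = ", "))
  }
  missing_cols <- setdiff(raw_categories(), names(df))
  if (length(missing_cols)) {
    stop("mapping error: raw category column(s) absent: ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    frame = df$frame,
    chasing = df$chasing,
    pointing = pmax(df$sniffing, df$approaching),
    behaving_alone = pmax(df$moving_alone, df$idling_alone),
    huddling = df$huddling,
    being_chased = df$being_chased,
    being_pointed_at = df$being_sniffed
  )
  structure(out, animal_id = attr(scores, "animal_id"),
            categories = working_categories(),
            class = c("behavior_scores", "data.frame"))
}

# row-wise argmax over the category columns, ties broken by column order;
# all-NA rows give NA; returns integer index into `categories`
score_argmax <- function(df, categories) {
  m <- as.matrix(df[categories])
  idx <- apply(m, 1L, function(r) {
    if (all(is.na(r))) NA_integer_ else which.max(r)
  })
  as.integer(idx)
}

#' Apply dyad-level labeling rules
#'
#' Enforces that `behaving_alone` and `huddling` are full-dyad categories,
#' and corrects the identity-merge failure mode of close-contact tracking:
#'
#' * If only one animal's winning category in a frame is `behaving_alone`,
#'   that animal's `behaving_alone` likelihood is set to zero for the frame
#'   (same rule for `huddling`).
#' * Identity merge: frames where one animal's scores are entirely missing
#'   (single detection) while the partner's winning category is
#'   `behaving_alone`, and the last fully-labeled dyad state was mutual
#'   huddling, are re-classified as huddling for both animals.
#'
#' @param scores_m,scores_f Consolidated `behavior_scores`
#'   ([working_categories()]), frame-synchronized.
#' @return List with elements `m` and `f`, the corrected tables.
#' @export
apply_dyad_rules <- function(scores_m, scores_f) {
  dm <- as.data.frame(scores_m)
  df_ <- as.data.frame(scores_f)
  if (nrow(dm) != nrow(df_) || any(dm$frame != df_$frame)) {
    stop("alignment error: dyad score tables are not frame-synchronized")
  }
  cats <- working_categories()
  am <- score_argmax(dm, cats)
  af <- score_argmax(df_, cats)
  i_alone <- match("behaving_alone", cats)
  i_hud <- match("huddling", cats)

  # identity-merge correction first (it can restore mutual huddling that the
  # full-dyad rule would otherwise zero out)
  merged_m <- is.na(am)
  merged_f <- is.na(af)
  prev_hud <- FALSE
  for (t in seq_len(nrow(dm))) {
    if (!is.na(am[t]) && !is.na(af[t])) {
      prev_hud <- am[t] == i_hud && af[t] == i_hud
    } else if (prev_hud) {
      solo_alone <- (merged_m[t] && !is.na(af[t]) && af[t] == i_alone) ||
                    (merged_f[t] && !is.na(am[t]) && am[t] == i_alone)
      if (solo_alone) {
        one_hot <- as.numeric(cats == "huddling")
        dm[t, cats] <- one_hot
        df_[t, cats] <- one_hot
        am[t] <- i_hud
        af[t] <- i_hud
      }
    }
  }

  for (idx in c(i_alone, i_hud)) {
    only_m <- !is.na(am) & am == idx & (is.na(af) | af != idx)
    only_f <- !is.na(af) & af == idx & (is.na(am) | am != idx)
    dm[only_m, cats[idx]] <- 0
    df_[only_f, cats[idx]] <- 0
  }

  list(
    m = structure(dm, animal_id = attr(scores_m, "animal_id"),
                  categories = cats, class = class(scores_m)),
    f = structure(df_, animal_id = attr(scores_f, "animal_id"),
                  categories = cats, class = class(scores_f))
  )
}

#' Winner-takes-all labeling with attack-annotation overlay
#'
#' Converts per-frame likelihoods into a single label per frame: the
#' highest-likelihood category, with ties broken by the fixed vocabulary
#' order (tie occurrences are reported). Frames flagged in the annotation
#' track as `attacking` or `being_attacked` then overwrite the label —
#' manual aggression annotations take precedence over everything.
#'
#' @param scores A consolidated, dyad-rule-processed `behavior_scores` table.
#' @param annotations Optional `annotation_track`, frame-synchronized.
#' @return A `label_stream` data frame (`frame`, `label`) whose labels come
#'   from [label_vocabulary()]; all-missing score rows give NA labels.
#' @export
labelize <- function(scores, annotations = NULL) {
  df <- as.data.frame(scores)
  cats <- attr(scores, "categories")
  m <- as.matrix(df[cats])
  idx <- score_argmax(df, cats)
  row_max <- suppressWarnings(apply(m, 1L, max, na.rm = TRUE))
  n_tie <- sum(rowSums(m == row_max, na.rm = TRUE) > 1, na.rm = TRUE)
  if (n_tie > 0) {
    message(n_tie, " tied frame(s) resolved by vocabulary order")
  }
  label <- cats[idx]
  if (!is.null(annotations)) {
    ann <- as.data.frame(annotations)
    if (nrow(ann) != nrow(df) || any(ann$frame != df$frame)) {
      stop("alignment error: annotations are not frame-synchronized with scores")
    }
    label[ann$attacking] <- "attacking"
    label[ann$being_attacked] <- "being_attacked"
  }
  structure(data.frame(frame = df$frame, label = label),
            animal_id = attr(scores, "animal_id"),
            vocabulary = label_vocabulary(),
            class = c("label_stream", "data.frame"))
}

#' Full frame-level categorization for one dyad
#'
#' Runs [consolidate_categories()], [apply_dyad_rules()] and [labelize()]
#' for both animals and optionally writes the per-dyad label file.
#'
#' @param raw_m,raw_f Raw `behavior_scores` tables.
#' @param ann_m,ann_f Optional `annotation_track`s.
#' @param path Optional output path for [write_dyad_labels()].
#' @return List with `m` and `f` `label_stream`s.
#' @export
categorize_dyad <- function(raw_m, raw_f, ann_m = NULL, ann_f = NULL,
                            path = NULL) {
  fixed <- apply_dyad_rules(consolidate_categories(raw_m),
                            consolidate_categories(raw_f))
  lm_ <- labelize(fixed$m, ann_m)
  lf_ <- labelize(fixed$f, ann_f)
  if (!is.null(path)) {
    write_dyad_labels(data.frame(frame = lm_$frame, label_m = lm_$label,
                                 label_f = lf_$label), path)
  }
  list(m = lm_, f = lf_)
}
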