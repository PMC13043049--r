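#' @importFrom stats cor cor.test
NULL

profile_variables <- function() {
  c("direction_to_divider", "distance_to_divider", "locomotion_speed",
    analysis_categories())
}

#' Cross-experiment per-animal behavioral profiles
#'
#' For each animal present in both experiments, the eight session averages:
#' direction to divider, distance to divider and locomotion speed from the
#' divided cohabitation, and the five analysis-category probabilities
#' (fraction of labeled frames; mirror roles counted toward their focal
#' interaction category) from the undivided cohabitation. Missing frames
#' are ignored in the averages. Animals missing either experiment are
#' excluded with a message.
#'
#' @param exp1 Named list (by animal id) of lists of the three
#'   `variable_series` as returned by [decompose_track()].
#' @param exp2 Named list (by animal id) of frame-level `label_stream`s.
#' @param records List of [dyad_record()]s; animal ids are expected as
#'   `<dyad_id>_M` and `<dyad_id>_F`.
#' @return Data frame: `animal_id`, `sex`, `dyad_type`, and the eight
#'   profile variables.
#' @export
build_profiles <- function(exp1, exp2, records) {
  ids <- intersect(names(exp1), names(exp2))
  dropped <- setdiff(union(names(exp1), names(exp2)), ids)
  if (length(dropped)) {
    message("excluding ", length(dropped),
            " animal(s) missing one experiment: ",
            paste(dropped, collapse = ", "))
  }
  rec_by_id <- setNames(records, vapply(records, `[[`, "", "dyad_id"))
  rows <- lapply(ids, function(id) {
    dyad <- sub("_[MF]$", "", id)
    sex <- if (grepl("_M$", id)) "male" else "female"
    rec <- rec_by_id[[dyad]]
    dd <- exp1[[id]]
    lab <- collapse_roles(exp2[[id]])$label
    probs <- vapply(analysis_categories(), function(cc) {
      mean(lab == cc, na.rm = TRUE)
    }, numeric(1))
    data.frame(animal_id = id, sex = sex,
               dyad_type = if (is.null(rec)) NA_character_ else rec$dyad_type,
               direction_to_divider = mean(dd$direction$value, na.rm = TRUE),
               distance_to_divider = mean(dd$distance$value, na.rm = TRUE),
               locomotion_speed = mean(dd$speed$value, na.rm = TRUE),
               as.list(probs))
  })
  do.call(rbind, rows)
}

#' Group-wise correlation matrices across the eight profile variables
#'
#' Within each sex x dyad-type group, the 8x8 Pearson correlation matrix of
#' the profile variables, the matching two-sided P values, and the list of
#' significant pairs with their sign. Variables with zero variance in a
#' group leave their pairs undefined (NA). P values are reported per pair
#' without multiple-testing correction, matching the per-pair reporting the
#' analysis is designed around; `adjust = "BH"` applies a
#' Benjamini-Hochberg correction to the off-diagonal P values instead.
#'
#' @param profiles Output of [build_profiles()].
#' @param alpha Significance highlight threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @param min_n Minimum animals per group (default 3).
#' @return Named list (one element per group) of lists with `R`, `P`, `n`,
#'   and `significant` (long data frame `var1`, `var2`, `R`, `P`, `sign`).
#' @export
group_correlations <- function(profiles, alpha = 0.05,
                               adjust = c("none", "BH"), min_n = 3) {
  adjust <- match.arg(adjust)
  vars <- profile_variables()
  groups <- split(profiles, interaction(profiles$sex, profiles$dyad_type,
                                        sep = "_", drop = TRUE))
  lapply(groups, function(g) {
    if (nrow(g) < min_n) stop("fewer than ", min_n, " animals in group")
    m <- as.matrix(g[vars])
    k <- length(vars)
    R <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
    P <- R
    diag(R) <- 1
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (sd(m[, i]) == 0 || sd(m[, j]) == 0) next
        ct <- cor.test(m[, i], m[, j])
        R[i, j] <- R[j, i] <- unname(ct$estimate)
        P[i, j] <- P[j, i] <- ct$p.value
      }
    }
    if (adjust == "BH") {
      up <- upper.tri(P)
      P[up] <- stats::p.adjust(P[up], "BH")
      P[lower.tri(P)] <- t(P)[lower.tri(P)]
    }
    idx <- which(upper.tri(P) & !is.na(P) & P < alpha, arr.ind = TRUE)
    sig <- data.frame(var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
                      R = R[idx], P = P[idx],
                      sign = ifelse(R[idx] > 0, "positive", "negative"))
    list(R = R, P = P, n = nrow(g), significant = sig)
  })
}

#' Write per-group correlation matrices
#'
#' @param correlations Output of [group_correlations()].
#' @param dir Output directory; writes `<group>_R.csv`, `<group>_P.csv`,
#'   and a combined `significant_pairs.csv`.
#' @export
write_correlations <- function(correlations, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- list()
  for (gname in names(correlations)) {
    gg <- correlations[[gname]]
    utils::write.csv(gg$R, file.path(dir, paste0(gname, "_R.csv")))
    utils::write.csv(gg$P, file.path(dir, paste0(gname, "_P.csv")))
    if (nrow(gg$significant)) {
      sig[[gname]] <- cbind(group = gname, gg$significant)
    }
  }
  sig_df <- if (length(sig)) do.call(rbind, sig) else
    data.frame(group = character(), var1 = character(), var2 = character(),
               R = numeric(), P = numeric(), sign = character())
  utils::write.csv(sig_df, file.path(dir, "significant_pairs.csv"),
                   row.names = FALSE)
  invisible(dir)
}
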