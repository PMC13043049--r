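pkg_version <- function() {
  as.character(utils::packageVersion("voledyads"))
}

# small stable config hash (FNV-1a over the deparsed config)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the two simulator configs, the
#' binning/smoothing parameters (defaults: 1-h bins for the divided session,
#' 3-min bins for the undivided one, 6-bin moving mean), the 1-s transition
#' discretization thresholds, and the significance level. A single seed
#' drives both simulators.
#'
#' @param divided [divided_sim_config()] (or NULL to skip that arm).
#' @param undivided [undivided_sim_config()] (or NULL to skip).
#' @param bin_width_exp1_s,bin_width_exp2_s Bin widths, seconds.
#' @param smooth_window_bins Moving-mean window (default 6).
#' @param direction_threshold,alpha See [discretize_exp1()], [rm_anova()].
#' @param transition_window_fraction Fraction of the divided session used
#'   for transition analysis (default 1/6: the initial 12 h of 72 h).
#' @param seed Seed applied to both simulator configs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(divided = divided_sim_config(),
                            undivided = undivided_sim_config(),
                            bin_width_exp1_s = 3600,
                            bin_width_exp2_s = 180,
                            smooth_window_bins = 6,
                            direction_threshold = 0,
                            alpha = 0.05,
                            transition_window_fraction = 1 / 6,
                            seed = 1L) {
  if (!is.null(divided)) divided$seed <- seed
  if (!is.null(undivided)) undivided$seed <- seed + 1L
  structure(list(divided = divided, undivided = undivided,
                 bin_width_exp1_s = bin_width_exp1_s,
                 bin_width_exp2_s = bin_width_exp2_s,
                 smooth_window_bins = smooth_window_bins,
                 direction_threshold = direction_threshold,
                 alpha = alpha,
                 transition_window_fraction = transition_window_fraction,
                 seed = seed),
            class = "pipeline_config")
}

#' Run the full simulate-analyze pipeline
#'
#' Executes every stage in order — simulate both cohabitation arms,
#' decompose keypoints, categorize behavior scores, time-binned group
#' statistics (sex within dyad, repeated-measures ANOVA with per-bin Tukey
#' tests), cross-experiment correlations, and sex-directional transition
#' analysis — writing all tables under `outdir` plus a YAML run report
#' (package version, seed, config hash, per-stage row counts, warnings).
#' Idempotent: the same config and seed reproduce identical tables.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @return Invisibly, a list of in-memory results per stage plus
#'   `report_path`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(tool = "voledyads", version = pkg_version(),
                 seed = config$seed, config_hash = config_hash(config),
                 stages = list(), warnings = character())
  note <- function(stage, ...) {
    report$stages[[stage]] <<- list(...)
  }
  results <- list()
  stage <- "start"
  tryCatch({
    ## --- simulate -------------------------------------------------------
    stage <- "simulate_divided"
    div <- generate_divided_cohort(config$divided,
                                   file.path(outdir, "sim_divided"))
    note(stage, n_files = length(div$files))
    stage <- "simulate_undivided"
    und <- generate_undivided_cohort(config$undivided,
                                     file.path(outdir, "sim_undivided"))
    note(stage, n_dyads = length(und$files))

    ## --- decompose ------------------------------------------------------
    stage <- "decompose"
    geom <- div$geometry
    dec_dir <- file.path(outdir, "decomposition")
    dir.create(dec_dir, showWarnings = FALSE)
    decomp <- list()
    for (id in names(div$files)) {
      side <- if (grepl("_M$", id)) "left" else "right"
      tr <- read_keypoint_table(div$files[[id]], compartment(geom, side),
                                animal_id = id)
      tr <- interpolate_low_confidence(tr)
      decomp[[id]] <- decompose_track(tr, path = file.path(dec_dir,
                                                           paste0(id, ".csv")))
    }
    note(stage, n_animals = length(decomp),
         n_frames = nrow(decomp[[1]]$direction))

    ## --- categorize -----------------------------------------------------
    stage <- "categorize"
    lab_dir <- file.path(outdir, "labels")
    dir.create(lab_dir, showWarnings = FALSE)
    labels <- list()
    for (id in names(und$files)) {
      f <- und$files[[id]]
      ld <- categorize_dyad(
        read_behavior_scores(f$scores_m, paste0(id, "_M")),
        read_behavior_scores(f$scores_f, paste0(id, "_F")),
        read_annotation_track(f$annotations_m, paste0(id, "_M")),
        read_annotation_track(f$annotations_f, paste0(id, "_F")),
        path = file.path(lab_dir, paste0(id, ".csv")))
      labels[[paste0(id, "_M")]] <- ld$m
      labels[[paste0(id, "_F")]] <- ld$f
    }
    note(stage, n_animals = length(labels))

    ## --- time-series statistics ----------------------------------------
    stage <- "timeseries"
    stats_dir <- file.path(outdir, "stats")
    dir.create(stats_dir, showWarnings = FALSE)
    hdr <- sprintf("voledyads %s seed=%d config=%s", pkg_version(),
                   config$seed, report$config_hash)
    anovas <- list()
    rate1 <- config$divided$frame_rate_hz
    for (var in c("direction", "distance", "speed")) {
      long <- do.call(rbind, lapply(names(decomp), function(id) {
        bs <- bin_and_smooth(decomp[[id]][[var]], config$bin_width_exp1_s,
                             rate1, config$smooth_window_bins)
        data.frame(subject = sub("_[MF]$", "", id),
                   group = if (grepl("_M$", id)) "male" else "female",
                   bin = factor(seq_along(bs$values)), value = bs$values)
      }))
      fit <- rm_anova(long, design = "within")
      ph <- tukey_per_bin(long, alpha = config$alpha)
      write_anova_table(fit, file.path(stats_dir, paste0("exp1_", var, "_anova.csv")),
                        header = hdr)
      data.table::fwrite(ph, file.path(stats_dir, paste0("exp1_", var, "_posthoc.csv")))
      anovas[[paste0("exp1_", var)]] <- list(anova = fit, posthoc = ph)
    }
    rate2 <- config$undivided$frame_rate_hz
    probs <- lapply(labels, function(l) {
      label_probabilities(collapse_roles(l), config$bin_width_exp2_s, rate2,
                          vocabulary = analysis_categories(),
                          window_bins = config$smooth_window_bins,
                          smooth = TRUE)
    })
    for (cat_ in analysis_categories()) {
      long <- do.call(rbind, lapply(names(probs), function(id) {
        v <- probs[[id]][, cat_]
        data.frame(subject = sub("_[MF]$", "", id),
                   group = if (grepl("_M$", id)) "male" else "female",
                   bin = factor(seq_along(v)), value = v)
      }))
      fit <- rm_anova(long, design = "within")
      write_anova_table(fit, file.path(stats_dir, paste0("exp2_", cat_, "_anova.csv")),
                        header = hdr)
      anovas[[paste0("exp2_", cat_)]] <- list(anova = fit)
    }
    note(stage, n_tables = length(anovas))

    ## --- correlations ---------------------------------------------------
    stage <- "correlate"
    profiles <- build_profiles(decomp, labels, und$records)
    correlations <- group_correlations(profiles, alpha = config$alpha)
    write_correlations(correlations, file.path(outdir, "correlations"))
    data.table::fwrite(profiles, file.path(outdir, "correlations", "profiles.csv"))
    note(stage, n_profiles = nrow(profiles), n_groups = length(correlations))

    ## --- transitions ----------------------------------------------------
    stage <- "transitions"
    tr_dir <- file.path(outdir, "transitions")
    dir.create(tr_dir, showWarnings = FALSE)
    win_s <- config$divided$duration_s * config$transition_window_fraction
    tms <- list(exp1 = list(male_to_female = list(), female_to_male = list()),
                exp2 = list(male_to_female = list(), female_to_male = list()))
    dyad_types <- vapply(und$records, `[[`, "", "dyad_type")
    names(dyad_types) <- vapply(und$records, `[[`, "", "dyad_id")
    for (rec in und$records) {
      id <- rec$dyad_id
      d1 <- lapply(c(M = "M", F = "F"), function(sx) {
        dd <- decomp[[paste0(id, "_", sx)]]
        discretize_exp1(dd$direction, dd$distance,
                        compartment(geom, if (sx == "M") "left" else "right"),
                        direction_threshold = config$direction_threshold,
                        frame_rate_hz = rate1, window_s = win_s)
      })
      d2 <- lapply(c(M = "M", F = "F"), function(sx) {
        binned_labels_exp2(labels[[paste0(id, "_", sx)]], rate2)
      })
      tms$exp1$male_to_female[[id]] <- transition_matrix(d1$M, d1$F, "male_to_female", id)
      tms$exp1$female_to_male[[id]] <- transition_matrix(d1$F, d1$M, "female_to_male", id)
      tms$exp2$male_to_female[[id]] <- transition_matrix(d2$M, d2$F, "male_to_female", id)
      tms$exp2$female_to_male[[id]] <- transition_matrix(d2$F, d2$M, "female_to_male", id)
    }
    comparisons <- list()
    for (exp_ in names(tms)) {
      for (dir_ in names(tms[[exp_]])) {
        mats <- tms[[exp_]][[dir_]]
        for (dt in c("matched", "mixed")) {
          grp <- mats[dyad_types[names(mats)] == dt]
          ag <- average_graph(grp)
          utils::write.csv(ag$mean_probs,
                           file.path(tr_dir, sprintf("%s_%s_%s_mean.csv", exp_, dir_, dt)))
          write_graph_exports(ag,
            graphml_path = file.path(tr_dir, sprintf("%s_%s_%s.graphml", exp_, dir_, dt)),
            edges_path = file.path(tr_dir, sprintf("%s_%s_%s_edges.csv", exp_, dir_, dt)))
        }
        cmp <- compare_transitions(mats, dyad_types[names(mats)],
                                   alpha = config$alpha)
        write_anova_table(cmp$anova,
                          file.path(tr_dir, sprintf("%s_%s_comparison.csv", exp_, dir_)),
                          header = hdr)
        comparisons[[paste0(exp_, "_", dir_)]] <- cmp
      }
    }
    note(stage, n_matrices = sum(lengths(unlist(tms, recursive = FALSE))),
         n_comparisons = length(comparisons))

    results <- list(divided = div, undivided = und, decomposition = decomp,
                    labels = labels, anovas = anovas, profiles = profiles,
                    correlations = correlations, transition_matrices = tms,
                    transition_comparisons = comparisons)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  report_path <- file.path(outdir, "run_report.yaml")
  yaml::write_yaml(report, report_path)
  results$report_path <- report_path
  invisible(results)
}
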