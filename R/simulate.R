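#' @importFrom stats rnorm runif
NULL

# fold a free trajectory into [lo, hi] by reflection (triangular wave);
# pathwise construction of a reflected random walk
fold_reflect <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

# reflected AR(1) on [-1, 1] with target mean b, persistence rho,
# stationary sd sigma (reflection at the boundaries pulls the realized
# mean slightly toward the interior; the realized mean is stored in the
# ground truth)
reflected_ar1 <- function(n, b, rho, sigma) {
  innov_sd <- sigma * sqrt(1 - rho^2)
  e <- rnorm(n, 0, innov_sd)
  out <- numeric(n)
  s <- b + rnorm(1, 0, sigma)
  for (i in seq_len(n)) {
    s <- b + rho * (s - b) + e[i]
    if (s > 1) s <- 2 - s else if (s < -1) s <- -2 - s
    if (s > 1) s <- 1 else if (s < -1) s <- -1  # guard for huge innovations
    out[i] <- s
  }
  out
}

#' Configuration for the divided-cohabitation simulator
#'
#' Defines the study conditions the generator emulates: a divided cage
#' (48.3 x 25.4 cm, divider at center) recorded from overhead, with a male
#' orientation bias toward the divider (stronger in mixed dyads) and
#' elevated activity during an initial period that then decays.
#'
#' Durations and frame rate default to a scaled-down session (2 h at 5 Hz)
#' so cohorts are cheap to simulate; the full study scale is 72 h at 20 Hz.
#'
#' @param n_dyads_per_subtype Dyads per subtype (Ctrl-Ctrl, ELSD-ELSD,
#'   Ctrl-ELSD, ELSD-Ctrl); default `c(7, 8, 7, 6)`.
#' @param duration_s Session length, seconds (default 7200; full 259200).
#' @param frame_rate_hz Frames per second (default 5; full 20).
#' @param orientation_bias Named numeric: target mean direction-to-divider
#'   per sex x dyad type (`male_matched`, `male_mixed`, `female_matched`,
#'   `female_mixed`), each in \[-1, 1\].
#' @param bias_sd Between-animal SD of the realized bias (default 0.1).
#' @param direction_sd Stationary SD of the per-frame direction score
#'   (default 0.5).
#' @param heading_persistence AR(1) coefficient of the direction process,
#'   in \[0, 1) (default 0.95).
#' @param heading_flip_rate Per-frame probability that the rotation sense
#'   (clockwise vs counterclockwise) flips (default 0.01).
#' @param speed_scale_cms Locomotion scale, cm/s (default 3).
#' @param activity_amp Extra activity multiplier at session start
#'   (default 1.5: initial activity is 2.5x basal).
#' @param activity_decay_s Exponential decay constant of the initial-activity
#'   envelope (default `duration_s / 6`, i.e., the first sixth of the
#'   session is elevated — 12 h of a 72-h session).
#' @param circadian Optional sinusoidal (14:10 light/dark) activity
#'   multiplier (default FALSE; meaningful only at full durations).
#' @param kp_jitter_cm Isotropic keypoint jitter SD, cm (default 0.05).
#' @param conf_dropout Per-keypoint-frame probability of a low-confidence
#'   dropout (default 0.02).
#' @param body_length_cm Nose-to-tail-base distance (default 3.6).
#' @param px_per_cm,cage_length_cm,cage_width_cm Geometry (see
#'   [cage_geometry()]).
#' @param seed Global RNG seed; per-dyad substreams are derived
#'   deterministically from it, so cohorts are reproducible and
#'   order-independent.
#' @return A validated `divided_sim_config` list.
#' @export
divided_sim_config <- function(n_dyads_per_subtype = c(7L, 8L, 7L, 6L),
                               duration_s = 7200, frame_rate_hz = 5,
                               orientation_bias = c(male_matched = 0.4,
                                                    male_mixed = 0.55,
                                                    female_matched = 0,
                                                    female_mixed = 0),
                               bias_sd = 0.1, direction_sd = 0.5,
                               heading_persistence = 0.95,
                               heading_flip_rate = 0.01,
                               speed_scale_cms = 3, activity_amp = 1.5,
                               activity_decay_s = duration_s / 6,
                               circadian = FALSE,
                               kp_jitter_cm = 0.05, conf_dropout = 0.02,
                               body_length_cm = 3.6,
                               px_per_cm = 10, cage_length_cm = 48.3,
                               cage_width_cm = 25.4, seed = 1L) {
  stopifnot(length(n_dyads_per_subtype) == 4,
            duration_s > 0, frame_rate_hz > 0,
            all(orientation_bias >= -1 & orientation_bias <= 1),
            all(c("male_matched", "male_mixed", "female_matched",
                  "female_mixed") %in% names(orientation_bias)),
            bias_sd >= 0, direction_sd >= 0,
            heading_persistence >= 0, heading_persistence < 1,
            heading_flip_rate >= 0, heading_flip_rate <= 1,
            speed_scale_cms > 0, activity_amp >= 0, activity_decay_s > 0,
            kp_jitter_cm >= 0, conf_dropout >= 0, conf_dropout < 1)
  if (orientation_bias["male_matched"] < orientation_bias["female_matched"] ||
      orientation_bias["male_mixed"] < orientation_bias["female_mixed"]) {
    stop("default scenario requires male orientation bias >= female bias")
  }
  if (cage_length_cm / 2 <= body_length_cm) {
    stop("config error: compartment smaller than body length")
  }
  structure(as.list(environment()), class = "divided_sim_config")
}

# per-dyad reproducible substream
dyad_seed <- function(seed, i) (as.integer(seed) + 10007L * as.integer(i)) %% .Machine$integer.max

simulate_divided_animal <- function(cfg, geom_animal, bias) {
  n <- round(cfg$duration_s * cfg$frame_rate_hz)
  t_s <- (seq_len(n) - 1) / cfg$frame_rate_hz
  px <- cfg$px_per_cm

  score <- reflected_ar1(n, bias, cfg$heading_persistence, cfg$direction_sd)
  phi <- (1 - score) * pi / 2
  flips <- cumsum(runif(n) < cfg$heading_flip_rate)
  xi <- ifelse(flips %% 2 == 0, 1, -1)
  # heading angle measured from the divider normal, in image coordinates
  theta <- xi * phi
  nx <- geom_animal$normal_sign
  hx <- nx * cos(theta)
  hy <- sin(theta)

  act <- 1 + cfg$activity_amp * exp(-t_s / cfg$activity_decay_s)
  if (isTRUE(cfg$circadian)) {
    act <- act * (1 + 0.5 * sin(2 * pi * t_s / 86400))
  }
  step_sd <- cfg$speed_scale_cms / cfg$frame_rate_hz / sqrt(2) * act * px
  box <- geom_animal$compartment_box
  # keep the whole skeleton (half body + ear offset + jitter) inside the box
  margin <- (cfg$body_length_cm / 2 + 0.8) * px
  cx <- fold_reflect(mean(box[c("x_min", "x_max")]) + cumsum(rnorm(n, 0, step_sd)),
                     box["x_min"] + margin, box["x_max"] - margin)
  cy <- fold_reflect(mean(box[c("y_min", "y_max")]) + cumsum(rnorm(n, 0, step_sd)),
                     box["y_min"] + margin, box["y_max"] - margin)

  half <- cfg$body_length_cm / 2
  along <- c(nose = half, ear_left = half * 2 / 3, ear_right = half * 2 / 3,
             spine1 = half / 3, spine2 = 0, spine3 = -half / 3,
             tail_base = -half)
  across <- c(nose = 0, ear_left = 0.5, ear_right = -0.5, spine1 = 0,
              spine2 = 0, spine3 = 0, tail_base = 0)
  out <- data.frame(frame = seq_len(n) - 1L)
  for (bp in keypoint_names()) {
    jx <- rnorm(n, 0, cfg$kp_jitter_cm)
    jy <- rnorm(n, 0, cfg$kp_jitter_cm)
    out[[paste0(bp, "_x")]] <- cx + (along[bp] * hx - across[bp] * hy + jx) * px
    out[[paste0(bp, "_y")]] <- cy + (along[bp] * hy + across[bp] * hx + jy) * px
    conf <- 1 - runif(n) * 0.05
    drop <- runif(n) < cfg$conf_dropout
    conf[drop] <- runif(sum(drop)) * 0.5
    out[[paste0(bp, "_conf")]] <- conf
  }
  list(table = out, realized_bias = mean(score))
}

#' Generate a divided-cohabitation cohort
#'
#' Writes, per animal, a keypoint table in the standard dialect
#' ([read_keypoint_table()]): the animal center follows a reflected random
#' walk inside its compartment with an activity envelope elevated at session
#' start; the heading follows a reflected autoregressive process on the
#' direction-score scale targeting the configured per-sex orientation bias;
#' the seven keypoints are laid along the body axis (nose ahead of spine
#' ahead of tail base) with isotropic jitter and near-1 confidences subject
#' to a dropout rate. Deterministic given the config seed.
#'
#' @param cfg A [divided_sim_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list: `files` (named keypoint paths), `metadata`
#'   (path to the YAML sidecar), `ground_truth` (per-animal configured and
#'   realized biases, plus config), `records`.
#' @export
generate_divided_cohort <- function(cfg, dir) {
  stopifnot(inherits(cfg, "divided_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geom <- cage_geometry(cfg$cage_length_cm, cfg$cage_width_cm,
                        cfg$px_per_cm, cfg$frame_rate_hz)
  records <- cohort_records(cfg$n_dyads_per_subtype)
  files <- character()
  truth <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    set.seed(dyad_seed(cfg$seed, i))
    for (sex in c("M", "F")) {
      side <- if (sex == "M") "left" else "right"
      base <- cfg$orientation_bias[paste0(if (sex == "M") "male" else "female",
                                          "_", rec$dyad_type)]
      bias <- fold_reflect(rnorm(1, base, cfg$bias_sd), -1, 1)
      sim <- simulate_divided_animal(cfg, compartment(geom, side), bias)
      id <- paste0(rec$dyad_id, "_", sex)
      path <- file.path(dir, paste0(id, "_keypoints.csv"))
      data.table::fwrite(sim$table, path)
      files[[id]] <- path
      truth[[id]] <- list(configured_bias = unname(base),
                          realized_bias = unname(bias),
                          realized_mean_score = sim$realized_bias,
                          sex = if (sex == "M") "male" else "female",
                          dyad_type = rec$dyad_type)
    }
  }
  meta <- list(experiment = "divided", geometry = geom, records = records,
               duration_s = cfg$duration_s, frame_rate_hz = cfg$frame_rate_hz,
               seed = cfg$seed, session_start_s = 0)
  meta_path <- file.path(dir, "metadata.yaml")
  write_cohort_metadata(meta, meta_path)
  gt <- list(animals = truth,
             config = list(orientation_bias = as.list(cfg$orientation_bias),
                           activity_amp = cfg$activity_amp,
                           activity_decay_s = cfg$activity_decay_s,
                           seed = cfg$seed))
  yaml::write_yaml(gt, file.path(dir, "groundtruth.yaml"))
  invisible(list(files = files, metadata = meta_path, ground_truth = gt,
                 records = records, geometry = geom))
}

## ---------------------------------------------------------------- undivided

joint_states <- function() {
  c("huddle", "alone", "chase_mf", "chase_fm", "attack_mf", "attack_fm",
    "point_mf", "point_fm")
}

# per-animal role labels implied by each joint state
state_labels <- function() {
  list(
    huddle = c(m = "huddling", f = "huddling"),
    alone = c(m = "behaving_alone", f = "behaving_alone"),
    chase_mf = c(m = "chasing", f = "being_chased"),
    chase_fm = c(m = "being_chased", f = "chasing"),
    attack_mf = c(m = "attacking", f = "being_attacked"),
    attack_fm = c(m = "being_attacked", f = "attacking"),
    point_mf = c(m = "pointing", f = "being_pointed_at"),
    point_fm = c(m = "being_pointed_at", f = "pointing")
  )
}

#' Configuration for the undivided-cohabitation simulator
#'
#' A dyad-level semi-Markov chain over joint states at a 1-s step. The
#' joint-state construction enforces the pipeline's labeling constraints by
#' design: huddling and behaving-alone are mutual; chasing, attacking and
#' pointing are role pairs (one actor, one recipient). Dwell times are
#' geometric per 1-s step (per-state exit probabilities). Entry hazards are
#' time-modulated: aggression (chasing, attacking) decays with a
#' configurable half-life, huddling entry rises toward its full weight.
#' Female-initiated aggression hazards carry a multiplier in mixed dyads.
#'
#' @param n_dyads_per_subtype As in [divided_sim_config()].
#' @param duration_s Session length, seconds (default 14400 = 4 h).
#' @param frame_rate_hz Emitted frames per second (default 5; full 20).
#' @param exit_prob Named per-second exit probabilities per state family
#'   (`huddle`, `alone`, `chase`, `attack`, `point`).
#' @param entry_weight Named entry hazards toward each joint state
#'   (`alone`, `huddle`, `point_mf`, `point_fm`, `chase_mf`, `chase_fm`,
#'   `attack_mf`, `attack_fm`); female-initiated aggression defaults higher
#'   than male-initiated.
#' @param mixed_female_aggression_multiplier Multiplier (> 1) on the
#'   `chase_fm` and `attack_fm` hazards in mixed dyads (default 3).
#' @param aggression_half_life_s Half-life of the chase/attack hazard decay
#'   (default 3600; `Inf` disables the modulation).
#' @param huddling_half_life_s Half-life of the huddling-entry rise
#'   (default 3600; `Inf` disables the modulation).
#' @param huddling_floor Initial fraction of the full huddling hazard
#'   (default 0.2).
#' @param label_noise Per-frame probability that the emitted one-hot score
#'   is flipped to a random other category (default 0.01), in \[0, 1).
#' @param merge_glitch_prob Per-second probability, inside a sustained
#'   huddle, of an identity-merge glitch: one animal's scores go missing
#'   while the partner is scored as idling alone (default 0.01).
#' @param seed Global RNG seed (per-dyad substreams derived from it).
#' @return A validated `undivided_sim_config` list.
#' @export
undivided_sim_config <- function(n_dyads_per_subtype = c(7L, 8L, 7L, 6L),
                                 duration_s = 14400, frame_rate_hz = 5,
                                 exit_prob = c(huddle = 0.02, alone = 0.05,
                                               chase = 0.30, attack = 0.40,
                                               point = 0.20),
                                 entry_weight = c(alone = 1.0, huddle = 0.6,
                                                  point_mf = 0.25,
                                                  point_fm = 0.25,
                                                  chase_mf = 0.04,
                                                  chase_fm = 0.08,
                                                  attack_mf = 0.02,
                                                  attack_fm = 0.05),
                                 mixed_female_aggression_multiplier = 3,
                                 aggression_half_life_s = 3600,
                                 huddling_half_life_s = 3600,
                                 huddling_floor = 0.2,
                                 label_noise = 0.01,
                                 merge_glitch_prob = 0.01,
                                 seed = 1L) {
  stopifnot(length(n_dyads_per_subtype) == 4, duration_s > 0,
            frame_rate_hz > 0, frame_rate_hz == round(frame_rate_hz),
            all(exit_prob >= 0 & exit_prob <= 1),
            all(c("huddle", "alone", "chase", "attack", "point") %in%
                  names(exit_prob)),
            all(entry_weight >= 0),
            all(c("alone", "huddle", "point_mf", "point_fm", "chase_mf",
                  "chase_fm", "attack_mf", "attack_fm") %in%
                  names(entry_weight)),
            mixed_female_aggression_multiplier > 0,
            aggression_half_life_s > 0, huddling_half_life_s > 0,
            huddling_floor >= 0, huddling_floor <= 1,
            label_noise >= 0, label_noise < 1,
            merge_glitch_prob >= 0, merge_glitch_prob <= 1)
  structure(as.list(environment()), class = "undivided_sim_config")
}

# entry hazards toward every joint state for one dyad type, unmodulated
base_entry_weights <- function(cfg, dyad_type) {
  w <- cfg$entry_weight[c("huddle", "alone", "chase_mf", "chase_fm",
                          "attack_mf", "attack_fm", "point_mf", "point_fm")]
  names(w) <- joint_states()
  if (dyad_type == "mixed") {
    w[c("chase_fm", "attack_fm")] <-
      w[c("chase_fm", "attack_fm")] * cfg$mixed_female_aggression_multiplier
  }
  w
}

state_family <- function(states = joint_states()) {
  sub("_(mf|fm)$", "", states)
}

# time-modulation factors per target state at time t (seconds)
modulation <- function(cfg, states, t_s) {
  fam <- state_family(states)
  f <- rep(1, length(states))
  if (is.finite(cfg$aggression_half_life_s)) {
    agg <- fam %in% c("chase", "attack")
    f[agg] <- 2^(-t_s / cfg$aggression_half_life_s)
  }
  if (is.finite(cfg$huddling_half_life_s)) {
    hud <- fam == "huddle"
    f[hud] <- cfg$huddling_floor +
      (1 - cfg$huddling_floor) * (1 - 2^(-t_s / cfg$huddling_half_life_s))
  }
  f
}

#' One-step joint-state transition matrix of the simulator
#'
#' The row-stochastic transition matrix of the dyad-level chain at time
#' `t_s` (default 0 with modulation disabled, i.e., the time-homogeneous
#' matrix the chain follows when both half-lives are `Inf`). Useful as an
#' analytic oracle for transition-recovery tests.
#'
#' @param cfg An [undivided_sim_config()].
#' @param dyad_type `"matched"` or `"mixed"`.
#' @param t_s Time (seconds) at which modulation factors are evaluated;
#'   `NULL` (default) disables modulation.
#' @return Row-stochastic matrix over [joint_states()].
#' @export
joint_transition_matrix <- function(cfg, dyad_type = "matched", t_s = NULL) {
  states <- joint_states()
  w0 <- base_entry_weights(cfg, dyad_type)
  f <- if (is.null(t_s)) rep(1, length(states)) else modulation(cfg, states, t_s)
  w <- w0 * f
  P <- matrix(0, length(states), length(states),
              dimnames = list(states, states))
  ex <- cfg$exit_prob[state_family(states)]
  for (i in seq_along(states)) {
    wi <- w
    wi[i] <- 0
    if (sum(wi) > 0) {
      P[i, ] <- ex[i] * wi / sum(wi)
      P[i, i] <- 1 - ex[i]
    } else {
      P[i, i] <- 1
    }
  }
  P
}

#' Directional category-transition matrix implied by a joint chain
#'
#' For a time-homogeneous joint chain with transition matrix `P`, the
#' long-run probability that the reactor is in category j at t+1 given the
#' actor is in category i at t: the quantity a directional
#' [transition_matrix()] estimated from an infinitely long recording
#' converges to. Categories are the five analysis labels with mirror roles
#' collapsed, so both directionalities share this limit under the default
#' role mapping.
#'
#' @param P Joint transition matrix ([joint_transition_matrix()]).
#' @return Row-stochastic 5x5 matrix over [analysis_categories()].
#' @export
implied_directional_matrix <- function(P) {
  states <- rownames(P)
  fam <- state_family(states)
  cat_of <- c(huddle = "huddling", alone = "behaving_alone",
              chase = "chasing", attack = "attacking", point = "pointing")
  cats <- analysis_categories()
  sc <- cat_of[fam]
  # stationary distribution
  ev <- eigen(t(P))
  i1 <- which.min(abs(ev$values - 1))
  pi_ <- Re(ev$vectors[, i1])
  pi_ <- pi_ / sum(pi_)
  out <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  for (ci in cats) {
    rows <- which(sc == ci)
    wrow <- pi_[rows] / sum(pi_[rows])
    trans <- colSums(P[rows, , drop = FALSE] * wrow)
    for (cj in cats) {
      out[ci, cj] <- sum(trans[sc == cj])
    }
  }
  out
}

simulate_joint_chain <- function(cfg, dyad_type, n_s) {
  states <- joint_states()
  w0 <- base_entry_weights(cfg, dyad_type)
  ex <- cfg$exit_prob[state_family(states)]
  fam <- state_family(states)
  agg_idx <- fam %in% c("chase", "attack")
  hud_idx <- fam == "huddle"
  s <- match("alone", states)
  out <- integer(n_s)
  u_exit <- runif(n_s)
  agg_hl <- cfg$aggression_half_life_s
  hud_hl <- cfg$huddling_half_life_s
  for (t in seq_len(n_s)) {
    if (u_exit[t] < ex[s]) {
      w <- w0
      if (is.finite(agg_hl)) w[agg_idx] <- w[agg_idx] * 2^(-(t - 1) / agg_hl)
      if (is.finite(hud_hl)) {
        w[hud_idx] <- w[hud_idx] * (cfg$huddling_floor +
          (1 - cfg$huddling_floor) * (1 - 2^(-(t - 1) / hud_hl)))
      }
      w[s] <- 0
      if (sum(w) > 0) s <- sample.int(length(states), 1L, prob = w)
    }
    out[t] <- s
  }
  stopifnot(!any(out == 0))
  states[out]
}

# raw one-hot emission column for each working label
emission_raw_category <- function(label, moving) {
  switch(label,
    chasing = "chasing",
    being_chased = "being_chased",
    pointing = "sniffing",
    being_pointed_at = "being_sniffed",
    behaving_alone = if (moving) "moving_alone" else "idling_alone",
    huddling = "huddling",
    attacking = "sniffing",
    being_attacked = "being_sniffed"
  )
}

emit_animal <- function(cfg, labels_s, glitch_s) {
  # labels_s: per-second role label; glitch_s: logical, this animal's scores
  # missing that second
  rate <- cfg$frame_rate_hz
  n_s <- length(labels_s)
  moving <- runif(n_s) < 0.5
  raw_s <- vapply(seq_len(n_s),
                  function(i) emission_raw_category(labels_s[i], moving[i]),
                  character(1))
  frames_raw <- rep(raw_s, each = rate)
  n <- length(frames_raw)
  cats <- raw_categories()
  noise_cats <- setdiff(cats, "aggression")
  flip <- runif(n) < cfg$label_noise
  frames_raw[flip] <- sample(noise_cats, sum(flip), replace = TRUE)
  m <- matrix(0, n, length(cats), dimnames = list(NULL, cats))
  m[cbind(seq_len(n), match(frames_raw, cats))] <- 1
  glitch_f <- rep(glitch_s, each = rate)
  m[glitch_f, ] <- NA_real_
  scores <- data.frame(frame = seq_len(n) - 1L, m, check.names = FALSE)
  lab_f <- rep(labels_s, each = rate)
  ann <- data.frame(frame = seq_len(n) - 1L,
                    attacking = as.integer(lab_f == "attacking" & !glitch_f),
                    being_attacked = as.integer(lab_f == "being_attacked" & !glitch_f))
  list(scores = scores, annotations = ann)
}

#' Generate an undivided-cohabitation cohort
#'
#' Simulates each dyad's joint behavior chain at a 1-s step (see
#' [undivided_sim_config()]), derives per-animal role labels, and emits
#' per-animal per-frame one-hot behavior scores with label noise, plus
#' attack annotation tracks (aggression is never in the score table's
#' active set, mirroring a manually annotated aggression channel).
#' Identity-merge glitches (one animal missing, partner scored idling
#' alone) are injected only inside sustained huddles. Deterministic given
#' the config seed.
#'
#' @param cfg An [undivided_sim_config()].
#' @param dir Output directory.
#' @return Invisibly, a list: `files` (per dyad: `scores_m`, `scores_f`,
#'   `annotations_m`, `annotations_f`, `truth`), `metadata`, `ground_truth`
#'   (per dyad: the per-second joint-state and per-animal label streams,
#'   the unmodulated joint transition matrix, and its implied directional
#'   category matrix), `records`.
#' @export
generate_undivided_cohort <- function(cfg, dir) {
  stopifnot(inherits(cfg, "undivided_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- cohort_records(cfg$n_dyads_per_subtype)
  n_s <- round(cfg$duration_s)
  slabs <- state_labels()
  files <- list()
  truth <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    set.seed(dyad_seed(cfg$seed, i))
    chain <- simulate_joint_chain(cfg, rec$dyad_type, n_s)
    lab_m <- unname(vapply(slabs[chain], `[[`, "", "m"))
    lab_f <- unname(vapply(slabs[chain], `[[`, "", "f"))
    # identity-merge glitches: only after >= 1 s of sustained huddling
    in_hud <- chain == "huddle"
    sustained <- in_hud & c(FALSE, in_hud[-n_s])
    glitch <- sustained & runif(n_s) < cfg$merge_glitch_prob
    glitch_m <- glitch & runif(n_s) < 0.5
    glitch_f <- glitch & !glitch_m
    em <- emit_animal(cfg, lab_m, glitch_m)
    ef <- emit_animal(cfg, lab_f, glitch_f)
    # partner of a glitched animal is scored idling alone that second
    fix_partner <- function(e, partner_glitch) {
      gf <- rep(partner_glitch, each = cfg$frame_rate_hz)
      m <- as.matrix(e$scores[raw_categories()])
      m[gf, ] <- 0
      m[gf, "idling_alone"] <- 1
      e$scores[raw_categories()] <- m
      e$annotations$attacking[gf] <- 0L
      e$annotations$being_attacked[gf] <- 0L
      e
    }
    em <- fix_partner(em, glitch_f)
    ef <- fix_partner(ef, glitch_m)
    id <- rec$dyad_id
    f <- list(
      scores_m = file.path(dir, paste0(id, "_M_scores.csv")),
      scores_f = file.path(dir, paste0(id, "_F_scores.csv")),
      annotations_m = file.path(dir, paste0(id, "_M_annotations.csv")),
      annotations_f = file.path(dir, paste0(id, "_F_annotations.csv")),
      truth = file.path(dir, paste0(id, "_truth.csv"))
    )
    data.table::fwrite(em$scores, f$scores_m)
    data.table::fwrite(ef$scores, f$scores_f)
    data.table::fwrite(em$annotations, f$annotations_m)
    data.table::fwrite(ef$annotations, f$annotations_f)
    data.table::fwrite(data.frame(second = seq_len(n_s) - 1L, state = chain,
                                  label_m = lab_m, label_f = lab_f),
                       f$truth)
    files[[id]] <- f
    P <- joint_transition_matrix(cfg, rec$dyad_type)
    truth[[id]] <- list(dyad_type = rec$dyad_type, states = chain,
                        label_m = lab_m, label_f = lab_f,
                        joint_matrix = P,
                        implied_matrix = implied_directional_matrix(P),
                        n_glitch_s = sum(glitch))
  }
  meta <- list(experiment = "undivided",
               geometry = cage_geometry(frame_rate_hz = cfg$frame_rate_hz),
               records = records, duration_s = cfg$duration_s,
               frame_rate_hz = cfg$frame_rate_hz, seed = cfg$seed,
               session_start_s = 0)
  meta_path <- file.path(dir, "metadata.yaml")
  write_cohort_metadata(meta, meta_path)
  yaml::write_yaml(list(seed = cfg$seed,
                        mixed_female_aggression_multiplier =
                          cfg$mixed_female_aggression_multiplier,
                        exit_prob = as.list(cfg$exit_prob),
                        entry_weight = as.list(cfg$entry_weight)),
                   file.path(dir, "groundtruth.yaml"))
  invisible(list(files = files, metadata = meta_path, ground_truth = truth,
                 records = records))
}
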