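# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; no data files.

# --- keypoint fixtures -------------------------------------------------------

# write a toy keypoint CSV where all seven keypoints lie on the nose->tail
# line (ears offset perpendicular); nose/tail are n x 2 matrices in px
write_toy_keypoints <- function(nose, tail, path = tempfile(fileext = ".csv"),
                                conf = 1) {
  n <- nrow(nose)
  df <- data.frame(frame = seq_len(n) - 1L)
  u <- nose - tail
  len <- sqrt(rowSums(u^2))
  ux <- ifelse(len > 0, u[, 1] / len, 0)
  uy <- ifelse(len > 0, u[, 2] / len, 0)
  frac <- c(nose = 1, ear_left = 0.85, ear_right = 0.85, spine1 = 0.65,
            spine2 = 0.5, spine3 = 0.35, tail_base = 0)
  perp <- c(nose = 0, ear_left = 2, ear_right = -2, spine1 = 0, spine2 = 0,
            spine3 = 0, tail_base = 0)
  for (bp in names(frac)) {
    df[[paste0(bp, "_x")]] <- tail[, 1] + frac[bp] * u[, 1] - perp[bp] * uy
    df[[paste0(bp, "_y")]] <- tail[, 2] + frac[bp] * u[, 2] + perp[bp] * ux
    df[[paste0(bp, "_conf")]] <- rep(conf, n)
  }
  data.table::fwrite(df, path)
  path
}

toy_track <- function(nose, tail, geometry, clock_start = 0, conf = 1) {
  read_keypoint_table(write_toy_keypoints(nose, tail, conf = conf), geometry,
                      animal_id = "toy", clock_start = clock_start)
}

left_geom <- function(px_per_cm = 10, frame_rate_hz = 20) {
  compartment(cage_geometry(px_per_cm = px_per_cm,
                            frame_rate_hz = frame_rate_hz), "left")
}

# --- behavior-score fixtures -------------------------------------------------

# behavior_scores table from a matrix of likelihoods (via the file dialect,
# so the reading path is exercised too)
scores_from_matrix <- function(m, categories = raw_categories()) {
  df <- data.frame(frame = seq_len(nrow(m)) - 1L, m)
  names(df) <- c("frame", categories)
  path <- tempfile(fileext = ".csv")
  data.table::fwrite(df, path)
  read_behavior_scores(path, animal_id = "fix", categories = categories)
}

# one-hot raw score table from a vector of working labels (the generator's
# emission convention: pointing -> sniffing, behaving_alone -> idling_alone)
onehot_raw <- function(labels) {
  map <- c(chasing = "chasing", being_chased = "being_chased",
           pointing = "sniffing", being_pointed_at = "being_sniffed",
           behaving_alone = "idling_alone", huddling = "huddling",
           attacking = "sniffing", being_attacked = "being_sniffed")
  m <- matrix(0, length(labels), length(raw_categories()),
              dimnames = list(NULL, raw_categories()))
  m[cbind(seq_along(labels), match(map[labels], raw_categories()))] <- 1
  scores_from_matrix(m)
}

annotations_from_labels <- function(labels) {
  df <- data.frame(frame = seq_along(labels) - 1L,
                   attacking = as.integer(labels == "attacking"),
                   being_attacked = as.integer(labels == "being_attacked"))
  path <- tempfile(fileext = ".csv")
  data.table::fwrite(df, path)
  read_annotation_track(path, "fix")
}

# discretized stream directly from labels (bypasses binning)
stream_from_labels <- function(labels, vocabulary = analysis_categories()) {
  structure(list(labels = as.character(labels), vocabulary = vocabulary,
                 animal_id = "fix", bin_width_s = 1),
            class = "discretized_stream")
}

# --- independent oracles -----------------------------------------------------

# brute-force shrinking-window moving mean (window: k/2 before, k/2-1 after)
movmean_oracle <- function(x, k) {
  n <- length(x)
  sapply(seq_len(n), function(i) {
    idx <- max(1, i - floor(k / 2)):min(n, i + ceiling(k / 2) - 1)
    v <- x[idx]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
}

# brute-force run-length bout counter
bout_oracle <- function(labels) {
  counts <- list()
  prev <- NA_character_
  for (l in labels) {
    if (is.na(l)) { prev <- NA_character_; next }
    if (is.na(prev) || l != prev) {
      counts[[l]] <- c(counts[[l]], 1L)
    } else {
      k <- length(counts[[l]])
      counts[[l]][k] <- counts[[l]][k] + 1L
    }
    prev <- l
  }
  counts
}

# textbook sums-of-squares oracle for the balanced fully-within two-way
# repeated-measures ANOVA (a = group levels, b = bins, n = subjects)
anova_within_oracle <- function(d) {
  y <- tapply(d$value, list(d$group, d$bin, d$subject), mean)
  a <- dim(y)[1]; b <- dim(y)[2]; n <- dim(y)[3]
  g <- mean(y)
  ya <- apply(y, 1, mean); yb <- apply(y, 2, mean); ys <- apply(y, 3, mean)
  yas <- apply(y, c(1, 3), mean); ybs <- apply(y, c(2, 3), mean)
  yab <- apply(y, c(1, 2), mean)
  ss_a <- n * b * sum((ya - g)^2)
  ss_b <- n * a * sum((yb - g)^2)
  ss_ab <- n * sum((sweep(sweep(yab, 1, ya), 2, yb) + g)^2)
  ss_as <- b * sum((sweep(sweep(yas, 1, ya), 2, ys) + g)^2)
  ss_bs <- a * sum((sweep(sweep(ybs, 1, yb), 2, ys) + g)^2)
  ss_tot <- sum((y - g)^2)
  ss_s <- a * b * sum((ys - g)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs
  list(
    F_group = (ss_a / (a - 1)) / (ss_as / ((a - 1) * (n - 1))),
    F_time = (ss_b / (b - 1)) / (ss_bs / ((b - 1) * (n - 1))),
    F_inter = (ss_ab / ((a - 1) * (b - 1))) / (ss_abs / ((a - 1) * (b - 1) * (n - 1)))
  )
}

# textbook SS oracle for the balanced mixed design (group between, bin within)
anova_mixed_oracle <- function(d) {
  y <- tapply(d$value, list(d$subject, d$bin), mean)
  grp <- tapply(as.character(d$group), d$subject, function(v) v[1])
  grp <- grp[rownames(y)]
  b <- ncol(y); N <- nrow(y); glev <- unique(grp); a <- length(glev)
  g <- mean(y)
  ys <- rowMeans(y); yb <- colMeans(y)
  ya <- sapply(glev, function(gg) mean(y[grp == gg, ]))
  ng <- as.numeric(table(grp)[glev])
  ss_a <- b * sum(ng * (ya - g)^2)
  ss_sw <- b * sum((ys - ya[match(grp, glev)])^2)
  ss_b <- N * sum((yb - g)^2)
  yab <- t(sapply(glev, function(gg) colMeans(y[grp == gg, , drop = FALSE])))
  ss_ab <- sum(ng * (sweep(sweep(yab, 1, ya), 2, yb) + g)^2)
  ss_tot <- sum((y - g)^2)
  ss_res <- ss_tot - ss_a - ss_sw - ss_b - ss_ab
  list(
    F_group = (ss_a / (a - 1)) / (ss_sw / (N - a)),
    F_time = (ss_b / (b - 1)) / (ss_res / ((b - 1) * (N - a))),
    F_inter = (ss_ab / ((a - 1) * (b - 1))) / (ss_res / ((b - 1) * (N - a)))
  )
}

# unit-vector dot-product / arccos oracle for the direction score
direction_oracle <- function(hx, hy, normal_sign) {
  phi <- acos(pmin(1, pmax(-1, (hx * normal_sign) / sqrt(hx^2 + hy^2))))
  1 - phi / (pi / 2)
}

# small cached cohorts shared by several tests (generated once per run)
cohort_cache <- new.env()
cached_divided <- function() {
  if (is.null(cohort_cache$div)) {
    cfg <- divided_sim_config(n_dyads_per_subtype = c(1, 1, 1, 1),
                              duration_s = 600, frame_rate_hz = 5, seed = 42)
    cohort_cache$div <- generate_divided_cohort(cfg, tempfile("divcache"))
    cohort_cache$div_cfg <- cfg
  }
  cohort_cache$div
}
cached_undivided <- function() {
  if (is.null(cohort_cache$und)) {
    cfg <- undivided_sim_config(n_dyads_per_subtype = c(1, 1, 1, 1),
                                duration_s = 900, frame_rate_hz = 5,
                                label_noise = 0, seed = 42)
    cohort_cache$und <- generate_undivided_cohort(cfg, tempfile("undcache"))
    cohort_cache$und_cfg <- cfg
  }
  cohort_cache$und
}
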