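test_that("generators are deterministic: same seed, byte-identical files", {
  cfg <- divided_sim_config(n_dyads_per_subtype = c(1, 0, 1, 0),
                            duration_s = 120, frame_rate_hz = 5, seed = 17)
  o1 <- generate_divided_cohort(cfg, tempfile("det1"))
  o2 <- generate_divided_cohort(cfg, tempfile("det2"))
  for (id in names(o1$files)) {
    expect_identical(readLines(o1$files[[id]]), readLines(o2$files[[id]]))
  }
  ucfg <- undivided_sim_config(n_dyads_per_subtype = c(1, 0, 0, 1),
                               duration_s = 120, frame_rate_hz = 5, seed = 17)
  u1 <- generate_undivided_cohort(ucfg, tempfile("det3"))
  u2 <- generate_undivided_cohort(ucfg, tempfile("det4"))
  for (id in names(u1$files)) {
    for (ff in names(u1$files[[id]])) {
      expect_identical(readLines(u1$files[[id]][[ff]]),
                       readLines(u2$files[[id]][[ff]]))
    }
  }
  # and the generated score files round-trip losslessly through the readers
  sc <- read_behavior_scores(u1$files$dyad01$scores_m)
  p <- tempfile(fileext = ".csv")
  write_behavior_scores(sc, p)
  expect_identical(readLines(p), readLines(u1$files$dyad01$scores_m))
})

test_that("generated keypoints stay inside the compartment box", {
  for (seed in c(3, 4)) {
    cfg <- divided_sim_config(n_dyads_per_subtype = c(1, 1, 0, 0),
                              duration_s = 300, frame_rate_hz = 5,
                              speed_scale_cms = 8, seed = seed)
    out <- generate_divided_cohort(cfg, tempfile("box"))
    for (id in names(out$files)) {
      side <- if (grepl("_M$", id)) "left" else "right"
      box <- compartment(out$geometry, side)$compartment_box
      df <- data.table::fread(out$files[[id]])
      xs <- as.matrix(df[, grep("_x$", names(df)), with = FALSE])
      ys <- as.matrix(df[, grep("_y$", names(df)), with = FALSE])
      expect_true(all(xs >= box["x_min"] - 1 & xs <= box["x_max"] + 1))
      expect_true(all(ys >= box["y_min"] - 1 & ys <= box["y_max"] + 1))
    }
  }
})

test_that("track length and clock match the configured session", {
  out <- cached_divided()
  cfg <- divided_sim_config(n_dyads_per_subtype = c(1, 1, 1, 1),
                            duration_s = 600, frame_rate_hz = 5, seed = 42)
  tr <- read_keypoint_table(out$files[[1]],
                            compartment(out$geometry, "left"))
  expect_equal(nrow(tr), cfg$duration_s * cfg$frame_rate_hz)
  expect_equal(max(tr$clock_s), (cfg$duration_s * cfg$frame_rate_hz - 1) / 5)
})

test_that("a degenerate orientation config saturates the direction score", {
  cfg <- divided_sim_config(n_dyads_per_subtype = c(1, 0, 0, 0),
                            duration_s = 120, frame_rate_hz = 5,
                            orientation_bias = c(male_matched = 1,
                                                 male_mixed = 1,
                                                 female_matched = 1,
                                                 female_mixed = 1),
                            bias_sd = 0, direction_sd = 0,
                            heading_persistence = 0.99,
                            kp_jitter_cm = 0, conf_dropout = 0, seed = 2)
  out <- generate_divided_cohort(cfg, tempfile("sat"))
  for (id in names(out$files)) {
    side <- if (grepl("_M$", id)) "left" else "right"
    tr <- read_keypoint_table(out$files[[id]], compartment(out$geometry, side))
    ser <- direction_to_divider(tr)
    bs <- bin_and_smooth(ser, 10, 5, smooth = FALSE)
    expect_equal(bs$values, rep(1, 12), tolerance = 1e-9)
  }
})

test_that("invalid simulator configs are rejected", {
  expect_error(divided_sim_config(cage_length_cm = 6, body_length_cm = 3.6),
               "config error")
  expect_error(divided_sim_config(heading_persistence = 1))
  expect_error(divided_sim_config(orientation_bias = c(male_matched = 2,
                                                       male_mixed = 0.5,
                                                       female_matched = 0,
                                                       female_mixed = 0)))
  expect_error(divided_sim_config(orientation_bias = c(male_matched = -0.5,
                                                       male_mixed = 0.5,
                                                       female_matched = 0,
                                                       female_mixed = 0)),
               "male orientation bias")
  expect_error(undivided_sim_config(label_noise = 1))
  expect_error(undivided_sim_config(exit_prob = c(huddle = 1.4, alone = 0.05,
                                                  chase = 0.3, attack = 0.4,
                                                  point = 0.2)))
})

test_that("joint-state constraints hold in every generated frame", {
  allowed <- list(huddling = "huddling", behaving_alone = "behaving_alone",
                  chasing = "being_chased", being_chased = "chasing",
                  attacking = "being_attacked", being_attacked = "attacking",
                  pointing = "being_pointed_at",
                  being_pointed_at = "pointing")
  for (seed in c(5, 6)) {
    cfg <- undivided_sim_config(n_dyads_per_subtype = c(1, 0, 0, 1),
                                duration_s = 400, frame_rate_hz = 5,
                                label_noise = stats::runif(1, 0, 0.05),
                                seed = seed)
    out <- generate_undivided_cohort(cfg, tempfile("joint"))
    for (id in names(out$files)) {
      gt <- out$ground_truth[[id]]
      # the partner label is always the mirror of the focal label
      expect_equal(unname(unlist(allowed[gt$label_m])), gt$label_f)
      # never two focal attackers at once, never one-sided huddling
      expect_false(any(gt$label_m == "attacking" & gt$label_f == "attacking"))
      expect_equal(gt$label_m == "huddling", gt$label_f == "huddling")
      # attack annotations mirror across the dyad, frame-synchronized
      am <- read_annotation_track(out$files[[id]]$annotations_m)
      af <- read_annotation_track(out$files[[id]]$annotations_f)
      expect_equal(am$attacking, af$being_attacked)
      expect_equal(am$being_attacked, af$attacking)
    }
  }
})

test_that("with only huddling enabled the dyad converges to mutual huddling", {
  cfg <- undivided_sim_config(n_dyads_per_subtype = c(1, 0, 0, 0),
                              duration_s = 400, frame_rate_hz = 5,
                              exit_prob = c(huddle = 0, alone = 0.5,
                                            chase = 0.5, attack = 0.5,
                                            point = 0.5),
                              entry_weight = c(alone = 0, huddle = 1,
                                               point_mf = 0, point_fm = 0,
                                               chase_mf = 0, chase_fm = 0,
                                               attack_mf = 0, attack_fm = 0),
                              label_noise = 0, merge_glitch_prob = 0, seed = 8)
  out <- generate_undivided_cohort(cfg, tempfile("hud"))
  gt <- out$ground_truth$dyad01
  expect_equal(gt$label_m[400], "huddling")
  first <- match("huddling", gt$label_m)
  expect_true(all(gt$label_m[first:400] == "huddling"))
  expect_equal(gt$label_m == "huddling", gt$label_f == "huddling")
})

test_that("the mixed-dyad female aggression multiplier is recovered", {
  # female attacking occupancy is higher in mixed than matched dyads in
  # every one of several seeds (full Monte-Carlo power is exercised in the
  # acceptance suite)
  for (seed in c(31, 32, 33)) {
    cfg <- undivided_sim_config(n_dyads_per_subtype = c(2, 2, 2, 2),
                                duration_s = 900, frame_rate_hz = 2,
                                seed = seed)
    out <- generate_undivided_cohort(cfg, tempfile("mult"))
    occ <- vapply(out$ground_truth, function(gt) {
      mean(gt$label_f == "attacking")
    }, numeric(1))
    types <- vapply(out$ground_truth, `[[`, "", "dyad_type")
    expect_gt(mean(occ[types == "mixed"]), mean(occ[types == "matched"]))
  }
})
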