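test_that("divided-cage discretization applies strict thresholds", {
  mk_series <- function(v) {
    structure(data.frame(frame = seq_along(v) - 1, clock_s = seq_along(v) - 1,
                         value = v, missing = is.na(v)),
              class = c("variable_series", "data.frame"))
  }
  # direction +1 at distance 0 -> toward-near
  ds <- discretize_exp1(mk_series(1), mk_series(0), distance_threshold = 12,
                        frame_rate_hz = 1)
  expect_equal(ds$labels, "toward-near")
  expect_equal(ds$vocabulary, orientation_categories())
  # direction exactly at the threshold is opposite (strict inequality)
  expect_equal(discretize_exp1(mk_series(0), mk_series(20),
                               distance_threshold = 12,
                               frame_rate_hz = 1)$labels, "opposite-away")
  # sweep: category counts equal a brute-force thresholding oracle
  set.seed(91)
  dirv <- runif(500, -1, 1)
  dstv <- runif(500, 0, 24)
  ds2 <- discretize_exp1(mk_series(dirv), mk_series(dstv),
                         distance_threshold = 12, frame_rate_hz = 1)
  orc <- paste0(ifelse(dirv > 0, "toward", "opposite"), "-",
                ifelse(dstv < 12, "near", "away"))
  expect_equal(ds2$labels, orc)
  # the default distance threshold is the compartment midpoint
  geom <- left_geom(px_per_cm = 10)
  ds3 <- discretize_exp1(mk_series(0.5), mk_series(12.2), geom,
                         frame_rate_hz = 1)
  expect_equal(ds3$labels, "toward-away")  # threshold = 24.15 / 2 = 12.075
  # missing bins give missing labels
  ds4 <- discretize_exp1(mk_series(c(1, NA)), mk_series(c(0, 3)),
                         distance_threshold = 12, frame_rate_hz = 1)
  expect_true(is.na(ds4$labels[2]))
})

test_that("1-s modal labels follow majority, tie order, and role collapse", {
  mk_lab <- function(v) {
    structure(data.frame(frame = seq_along(v) - 1, label = v),
              vocabulary = label_vocabulary(),
              class = c("label_stream", "data.frame"))
  }
  # 20 frames all huddling at 20 Hz -> one huddling bin
  b1 <- binned_labels_exp2(mk_lab(rep("huddling", 20)), 20)
  expect_equal(b1$labels, "huddling")
  # 11 pointing + 9 chasing -> pointing
  b2 <- binned_labels_exp2(mk_lab(c(rep("pointing", 11), rep("chasing", 9))), 20)
  expect_equal(b2$labels, "pointing")
  # 10-10 tie resolves to chasing (earlier in the vocabulary)
  expect_message(
    b3 <- binned_labels_exp2(mk_lab(c(rep("pointing", 10), rep("chasing", 10))), 20),
    "tie")
  expect_equal(b3$labels, "chasing")
  # mirror roles collapse onto the interaction category
  b4 <- binned_labels_exp2(mk_lab(rep("being_attacked", 5)), 5)
  expect_equal(b4$labels, "attacking")
  # random stream: modal labels equal a brute-force counting oracle
  set.seed(92)
  vocab <- analysis_categories()
  x <- sample(vocab, 400, replace = TRUE)
  b5 <- binned_labels_exp2(mk_lab(x), 8)
  orc <- vapply(seq_len(50), function(i) {
    tab <- table(factor(x[(8 * (i - 1) + 1):(8 * i)], levels = vocab))
    vocab[which.max(tab)]
  }, character(1))
  expect_equal(suppressMessages(b5$labels), orc)
})

test_that("transition matrices count actor-then-reactor pairs correctly", {
  # constant actor A, constant reactor B: single cell with probability 1
  a <- stream_from_labels(rep("chasing", 10))
  b <- stream_from_labels(rep("huddling", 10))
  tm <- transition_matrix(a, b)
  expect_equal(unname(tm$probs["chasing", "huddling"]), 1)
  expect_equal(sum(tm$counts), 9)
  expect_equal(dim(tm$probs), c(5, 5))  # five-category vocabulary -> 5 x 5
  expect_setequal(tm$unvisited, setdiff(analysis_categories(), "chasing"))

  # deterministic periodic streams reproduce the exact hand-computed matrix
  a2 <- stream_from_labels(rep(c("toward-near", "opposite-near"), 6),
                           orientation_categories())
  b2 <- stream_from_labels(rep(c("toward-away", "opposite-away"), 6),
                           orientation_categories())
  tm2 <- transition_matrix(a2, b2)
  expect_equal(dim(tm2$probs), c(4, 4))
  # actor toward-near at odd t is always followed by reactor opposite-away
  expect_equal(unname(tm2$probs["toward-near", "opposite-away"]), 1)
  expect_equal(unname(tm2$probs["opposite-near", "toward-away"]), 1)

  # missing labels drop the touching pairs; counts = n - 1 - dropped
  a3 <- stream_from_labels(c("chasing", NA, "pointing", "huddling"))
  b3 <- stream_from_labels(c("huddling", "pointing", "chasing", "chasing"))
  tm3 <- transition_matrix(a3, b3)
  expect_equal(sum(tm3$counts), 2)

  # directionality is asymmetric: swapping actor and reactor on a
  # constructed fixture is not a transposition
  a4 <- stream_from_labels(c("chasing", "pointing", "chasing", "huddling",
                             "pointing", "chasing"))
  b4 <- stream_from_labels(c("huddling", "huddling", "pointing", "chasing",
                             "chasing", "pointing"))
  f <- transition_matrix(a4, b4)
  r <- transition_matrix(b4, a4)
  expect_false(isTRUE(all.equal(f$probs, t(r$probs))))

  # fewer than 2 valid bins is an empty-matrix error
  expect_error(transition_matrix(stream_from_labels("chasing"),
                                 stream_from_labels("huddling")),
               "empty-matrix")
  # vocabulary mismatch is an error
  expect_error(transition_matrix(a2, b3), "vocabular")
})

test_that("probability rows are stochastic to 1e-12 on simulated dyads", {
  out <- cached_undivided()
  for (id in names(out$files)) {
    gt <- out$ground_truth[[id]]
    am <- stream_from_labels(collapse_roles(gt$label_m))
    af <- stream_from_labels(collapse_roles(gt$label_f))
    for (tm in list(transition_matrix(am, af), transition_matrix(af, am))) {
      visited <- setdiff(tm$vocabulary, tm$unvisited)
      expect_equal(unname(rowSums(tm$probs[visited, , drop = FALSE])),
                   rep(1, length(visited)), tolerance = 1e-12)
      # generating joint matrices stored in the ground truth are stochastic
      expect_equal(unname(rowSums(gt$joint_matrix)), rep(1, 8),
                   tolerance = 1e-12)
    }
  }
})

test_that("estimated matrices approach the generating chain as duration grows", {
  base <- list(duration_s = NA, frame_rate_hz = 2, label_noise = 0,
               merge_glitch_prob = 0,
               aggression_half_life_s = Inf, huddling_half_life_s = Inf,
               seed = 9)
  est_dev <- function(dur) {
    cfg <- do.call(undivided_sim_config,
                   c(list(n_dyads_per_subtype = c(1, 0, 0, 0),
                          duration_s = dur,
                          exit_prob = c(huddle = 0.3, alone = 0.3, chase = 0.3,
                                        attack = 0.3, point = 0.3),
                          entry_weight = c(alone = 0.5, huddle = 0.5,
                                           point_mf = 0.5, point_fm = 0.5,
                                           chase_mf = 0.5, chase_fm = 0.5,
                                           attack_mf = 0.5, attack_fm = 0.5)),
                     base[-1]))
    out <- generate_undivided_cohort(cfg, tempfile("conv"))
    gt <- out$ground_truth$dyad01
    tm <- transition_matrix(stream_from_labels(collapse_roles(gt$label_m)),
                            stream_from_labels(collapse_roles(gt$label_f)))
    max(abs(tm$probs - gt$implied_matrix))
  }
  short <- est_dev(3000)
  long <- est_dev(30000)
  expect_lt(long, short)
  expect_lt(long, 0.05)
})

test_that("averaged graphs are element-wise means with self-loops retained", {
  a <- stream_from_labels(rep(c("chasing", "huddling", "huddling"), 20))
  b <- stream_from_labels(rep(c("huddling", "huddling", "chasing"), 20))
  t1 <- transition_matrix(a, b)
  t2 <- transition_matrix(b, a)
  # single matrix: graph weights equal that matrix
  g1 <- average_graph(list(t1))
  expect_equal(g1$mean_probs, t1$probs)
  # two matrices: arithmetic mean per edge
  g2 <- average_graph(list(t1, t2))
  expect_equal(g2$mean_probs, (t1$probs + t2$probs) / 2)
  expect_true(all(g2$edges$weight >= 0 & g2$edges$weight <= 1))
  # self-loops are present in the edge list
  expect_true(any(g2$edges$source == g2$edges$target))
  # mixed vocabularies are an error
  t3 <- transition_matrix(
    stream_from_labels(rep(c("toward-near", "opposite-near"), 10),
                       orientation_categories()),
    stream_from_labels(rep(c("toward-near", "toward-away"), 10),
                       orientation_categories()))
  expect_error(average_graph(list(t1, t3)), "mixed vocabularies")
  # GraphML and edge-list exports materialize
  gml <- tempfile(fileext = ".graphml")
  edg <- tempfile(fileext = ".csv")
  write_graph_exports(g2, gml, edg)
  expect_true(file.size(gml) > 0)
  expect_equal(nrow(data.table::fread(edg)), nrow(g2$edges))
})

test_that("dyad-type comparison uses off-diagonal pairs as repeated measures", {
  set.seed(93)
  mk_tm <- function(vocab, bump = 0) {
    k <- length(vocab)
    n <- 2000
    lab <- sample(vocab, n, replace = TRUE)
    lab2 <- sample(vocab, n, replace = TRUE,
                   prob = (seq_len(k) + bump) / sum(seq_len(k) + bump))
    transition_matrix(stream_from_labels(lab, vocab),
                      stream_from_labels(lab2, vocab))
  }
  # 4-category vocabulary: 12 pairs, interaction numerator df 11
  m4 <- lapply(1:8, function(i) mk_tm(orientation_categories(),
                                      bump = (i > 4) * 2))
  cmp4 <- suppressMessages(compare_transitions(m4, rep(c("matched", "mixed"),
                                                       each = 4)))
  expect_length(cmp4$pairs, 12)
  expect_equal(cmp4$anova$table$df_num[3], 11)
  expect_equal(cmp4$anova$table$df_den[1], 6)
  # 5-category vocabulary: 20 pairs, interaction numerator df 19
  m5 <- lapply(1:8, function(i) mk_tm(analysis_categories()))
  cmp5 <- suppressMessages(compare_transitions(m5, rep(c("matched", "mixed"),
                                                       each = 4)))
  expect_length(cmp5$pairs, 20)
  expect_equal(cmp5$anova$table$df_num[3], 19)
  # group means and SD are reported per pair for both dyad types
  expect_setequal(names(cmp5$pair_means),
                  c("pair", "mean_matched", "sd_matched", "mean_mixed",
                    "sd_mixed"))
})
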