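test_that("binning reproduces the study's bin counts and smoothing is exact", {
  # a constant series is a fixed point of bin + smooth
  bs <- bin_and_smooth(rep(3.7, 600), bin_width_s = 10, frame_rate_hz = 2)
  expect_equal(bs$values, rep(3.7, 30))

  # 72 h at 1-h bins -> exactly 72 bins; 4 h at 3-min bins -> exactly 80
  x72 <- rnorm(72 * 3600 * 0.01)  # 72 h at 0.01 Hz
  expect_length(bin_and_smooth(x72, 3600, 0.01)$values, 72)
  x4 <- rnorm(4 * 3600 * 0.5)     # 4 h at 0.5 Hz
  expect_length(bin_and_smooth(x4, 180, 0.5)$values, 80)

  # impulse smoothing equals the brute-force shrinking-window oracle
  imp <- c(rep(0, 10), 1, rep(0, 9))
  got <- bin_and_smooth(imp, 1, 1, window_bins = 6)$values
  expect_equal(got, movmean_oracle(imp, 6))
  for (k in c(2, 3, 5, 6)) {
    set.seed(k)
    x <- rnorm(40)
    x[sample(40, 5)] <- NA
    expect_equal(bin_and_smooth(x, 1, 1, window_bins = k)$values,
                 movmean_oracle(x, k))
  }

  # unsmoothed binned mean of a constant equals the constant exactly
  expect_equal(bin_and_smooth(rep(1.25, 100), 5, 2, smooth = FALSE)$values,
               rep(1.25, 10))

  # trailing partial bin is dropped with a warning
  expect_warning(bp <- bin_and_smooth(rnorm(25), 10, 1, smooth = FALSE),
                 "partial bin")
  expect_length(bp$values, 2)

  # all-missing bins stay missing (unsmoothed)
  x <- rep(c(1, NA), each = 10)
  expect_equal(bin_and_smooth(x, 10, 1, smooth = FALSE)$values, c(1, NA))
})

test_that("repeated-measures ANOVA df match their closed forms", {
  # property: within design df are (1, n-1) and (b-1, (b-1)(n-1));
  # mixed design df are (1, N-2) and (b-1, (b-1)(N-2))
  set.seed(51)
  for (n in c(3, 6)) {
    for (b in c(4, 9)) {
      d <- expand.grid(subject = factor(seq_len(n)),
                       group = factor(c("m", "f")), bin = factor(seq_len(b)))
      d$value <- rnorm(nrow(d))
      fit <- rm_anova(d, design = "within")
      expect_equal(fit$table$df_num, c(1, b - 1, b - 1))
      expect_equal(fit$table$df_den, c(n - 1, (b - 1) * (n - 1),
                                       (b - 1) * (n - 1)))

      d2 <- expand.grid(subject = factor(seq_len(2 * n)),
                        bin = factor(seq_len(b)))
      d2$group <- factor(rep(c("matched", "mixed"), each = n))[
        as.integer(d2$subject)]
      d2$value <- rnorm(nrow(d2))
      fit2 <- rm_anova(d2, design = "mixed")
      expect_equal(fit2$table$df_num, c(1, b - 1, b - 1))
      expect_equal(fit2$table$df_den, c(2 * n - 2, (b - 1) * (2 * n - 2),
                                        (b - 1) * (2 * n - 2)))
    }
  }
})

test_that("ANOVA F statistics agree with hand-computed sums of squares", {
  set.seed(52)
  d <- expand.grid(subject = factor(1:5), group = factor(c("m", "f")),
                   bin = factor(1:4))
  d$value <- rnorm(nrow(d), mean = as.integer(d$group))
  fit <- rm_anova(d, design = "within")
  orc <- anova_within_oracle(d)
  expect_equal(fit$table$F, unname(unlist(orc)), tolerance = 1e-10)

  d2 <- expand.grid(subject = factor(1:8), bin = factor(1:5))
  d2$group <- factor(rep(c("a", "b"), each = 4))[as.integer(d2$subject)]
  d2$value <- rnorm(nrow(d2), mean = (d2$group == "b") * 0.5)
  fit2 <- rm_anova(d2, design = "mixed")
  orc2 <- anova_mixed_oracle(d2)
  expect_equal(fit2$table$F, unname(unlist(orc2)), tolerance = 1e-10)
})

test_that("degenerate and incomplete ANOVA inputs are handled, not crashed", {
  # identical values everywhere: zero residual variance, flagged
  d <- expand.grid(subject = factor(1:2), group = factor(c("m", "f")),
                   bin = factor(1:2))
  d$value <- 1
  fit <- rm_anova(d, design = "within")
  expect_true(fit$degenerate)
  expect_true(all(is.na(fit$table$F)))

  # a subject with a missing cell is dropped listwise, df shrink accordingly
  d2 <- expand.grid(subject = factor(1:5), group = factor(c("m", "f")),
                    bin = factor(1:3))
  d2$value <- rnorm(nrow(d2))
  d2$value[d2$subject == "2" & d2$group == "m" & d2$bin == "1"] <- NA
  expect_message(fit2 <- rm_anova(d2, design = "within"), "dropping 1")
  expect_equal(fit2$table$df_den[1], 3)

  # fewer than 2 subjects per group is an error
  d3 <- expand.grid(subject = factor(1:3), bin = factor(1:3))
  d3$group <- factor(c("a", "a", "b"))[as.integer(d3$subject)]
  d3$value <- rnorm(nrow(d3))
  expect_error(rm_anova(d3, design = "mixed"), "insufficient")
})

test_that("per-bin Tukey tests localize a known group difference", {
  set.seed(53)
  n <- 8; b <- 12
  d <- expand.grid(subject = factor(seq_len(2 * n)), bin = factor(seq_len(b)))
  d$group <- factor(rep(c("g1", "g2"), each = n))[as.integer(d$subject)]
  # strong difference confined to the first 4 bins
  d$value <- rnorm(nrow(d), sd = 0.5) +
    ifelse(d$group == "g2" & as.integer(d$bin) <= 4, 3, 0)
  ph <- tukey_per_bin(d)
  expect_true(all(ph$significant[1:4]))
  expect_lt(sum(ph$significant[5:12]), 3)

  # identical groups: empty mask
  d0 <- d
  d0$value <- rep(rnorm(b), each = 2 * n)[order(rep(seq_len(b), 2 * n))]
  d0$value <- ave(d0$value, d0$bin)  # equal within bins
  ph0 <- tukey_per_bin(d0)
  expect_true(all(ph0$degenerate | !ph0$significant))

  # zero pooled variance with unequal means: degenerate flag, not a crash
  d1 <- data.frame(subject = factor(1:4), group = factor(c("a", "a", "b", "b")),
                   bin = factor(1), value = c(1, 1, 2, 2))
  ph1 <- tukey_per_bin(d1)
  expect_true(ph1$degenerate[1])
  expect_true(is.na(ph1$significant[1]))
})

test_that("KS normality report is calibrated and has power", {
  # large normal samples pass at alpha = 0.05 in >= 90% of seeds
  passes <- vapply(1:20, function(s) {
    set.seed(s)
    d <- data.frame(bin = factor(1), value = rnorm(300))
    ks_normality(d)$pass[1]
  }, logical(1))
  expect_gte(mean(passes), 0.9)

  # a uniform(0, 1) sample of n = 500 fails
  set.seed(7)
  du <- data.frame(bin = factor(1), value = runif(500))
  expect_false(ks_normality(du)$pass[1])

  # constant or tiny samples are skipped with a note, not tested
  dc <- data.frame(bin = factor(c(1, 1, 1, 2, 2)),
                   value = c(5, 5, 5, 1, 2))
  rep_ <- ks_normality(dc)
  expect_true(all(rep_$skipped))
})

test_that("bout statistics equal the brute-force run-length oracle", {
  # AABBA: three bouts, A(2), B(2), A(1)
  tab <- bout_statistics(c("A", "A", "B", "B", "A"), bin_width_s = 1)
  expect_equal(sum(tab$n_bouts), 3)
  expect_equal(tab$n_bouts[tab$category == "A"], 2)
  expect_equal(tab$mean_duration_s[tab$category == "A"], 1.5)

  # a single-category stream of k bins is one bout of length k
  tab1 <- bout_statistics(rep("huddling", 17), bin_width_s = 2)
  expect_equal(tab1$n_bouts, 1)
  expect_equal(tab1$mean_duration_s, 34)

  # random streams (with missing bins) match the oracle exactly
  set.seed(61)
  for (rep_i in 1:5) {
    x <- sample(c("a", "b", "c", NA), 200, replace = TRUE,
                prob = c(0.4, 0.3, 0.2, 0.1))
    tab <- bout_statistics(x, bin_width_s = 1)
    orc <- bout_oracle(x)
    for (cc in names(orc)) {
      expect_equal(tab$n_bouts[tab$category == cc], length(orc[[cc]]))
      expect_equal(tab$mean_duration_s[tab$category == cc], mean(orc[[cc]]))
      expect_equal(tab$total_s[tab$category == cc], sum(orc[[cc]]))
    }
  }

  # an empty stream gives an empty table; a minimum-duration filter applies
  expect_equal(nrow(bout_statistics(character())), 0)
  tabf <- bout_statistics(c("a", "b", "b", "a"), min_bins = 2)
  expect_equal(tabf$category, "b")
})

test_that("label probabilities per bin sum to one before role collapsing", {
  out <- cached_undivided()
  f <- out$files[[1]]
  lab <- suppressMessages(categorize_dyad(
    read_behavior_scores(f$scores_m), read_behavior_scores(f$scores_f),
    read_annotation_track(f$annotations_m),
    read_annotation_track(f$annotations_f)))
  pr <- label_probabilities(lab$m, bin_width_s = 30, frame_rate_hz = 5)
  sums <- rowSums(pr)
  expect_equal(unname(sums[!is.na(sums)]),
               rep(1, sum(!is.na(sums))))
})
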