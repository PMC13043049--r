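#' @importFrom stats aov TukeyHSD ks.test sd setNames
NULL

# moving mean with shrinking edge windows; for even k the window covers
# k/2 elements before and k/2 - 1 after the current one (plus itself),
# matching the convention of the numeric environment the original analyses
# used; NAs are ignored within each window
moving_mean <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  lo <- pmax(1L, seq_len(n) - floor(k / 2))
  hi <- pmin(n, seq_len(n) + ceiling(k / 2) - 1L)
  v <- ifelse(is.na(x), 0, x)
  cnt <- as.numeric(!is.na(x))
  cs <- c(0, cumsum(v))
  cc <- c(0, cumsum(cnt))
  num <- cs[hi + 1L] - cs[lo]
  den <- cc[hi + 1L] - cc[lo]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

new_binned_series <- function(values, bin_width_s, variable, animal_id,
                              smoothed) {
  structure(list(values = values, bin_width_s = bin_width_s,
                 variable = variable, animal_id = animal_id,
                 smoothed = smoothed),
            class = "binned_series")
}

#' @export
print.binned_series <- function(x, ...) {
  cat(sprintf("binned_series '%s': %d bins of %g s%s\n", x$variable,
              length(x$values), x$bin_width_s,
              if (x$smoothed) ", smoothed" else ""))
  invisible(x)
}

#' Bin a per-frame series and apply a moving-mean window
#'
#' Frames are averaged into fixed-width time bins (missing frames ignored;
#' an all-missing bin stays missing), then smoothed with a centered
#' `window_bins`-bin moving mean whose windows shrink at the edges.
#' A trailing partial bin is dropped with a warning. The defaults reproduce
#' the study's processing: 72-h sessions at 1-h bins give 72 bins, 4-h
#' sessions at 3-min bins give 80 bins, both followed by a 6-bin window.
#'
#' @param series A `variable_series` (or a numeric vector plus
#'   `frame_rate_hz`).
#' @param bin_width_s Bin width in seconds.
#' @param frame_rate_hz Frames per second (taken from the series' clock axis
#'   when available).
#' @param window_bins Moving-mean window (default 6); `smooth = FALSE` or
#'   `window_bins = 1` disables smoothing.
#' @param smooth Apply the moving mean (default TRUE).
#' @return A `binned_series`.
#' @export
bin_and_smooth <- function(series, bin_width_s, frame_rate_hz = NULL,
                           window_bins = 6, smooth = TRUE) {
  if (inherits(series, "variable_series")) {
    x <- series$value
    clock <- series$clock_s
    variable <- attr(series, "variable")
    animal_id <- attr(series, "animal_id")
    if (is.null(frame_rate_hz)) {
      dt <- diff(clock)
      frame_rate_hz <- 1 / min(dt[dt > 0])
    }
  } else {
    x <- as.numeric(series)
    stopifnot(!is.null(frame_rate_hz))
    clock <- (seq_along(x) - 1) / frame_rate_hz
    variable <- "series"
    animal_id <- NA_character_
  }
  frames_per_bin <- bin_width_s * frame_rate_hz
  duration_s <- (length(x)) / frame_rate_hz
  n_bins <- floor(duration_s / bin_width_s + 1e-9)
  if (n_bins < 1) stop("bin width exceeds session duration")
  bin_of <- floor(clock / bin_width_s) + 1L
  keep <- bin_of <= n_bins
  if (any(!keep)) {
    warning("trailing partial bin dropped (", sum(!keep), " frame(s))")
  }
  sums <- tapply(x[keep], bin_of[keep], function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  vals <- rep(NA_real_, n_bins)
  vals[as.integer(names(sums))] <- unname(sums)
  if (smooth && window_bins > 1) vals <- moving_mean(vals, window_bins)
  new_binned_series(vals, bin_width_s, variable, animal_id,
                    smoothed = smooth && window_bins > 1)
}

#' Per-bin category probabilities from a frame-level label stream
#'
#' For each time bin and category, the fraction of non-missing frames in the
#' bin carrying that label. Before role collapsing, the probabilities of a
#' bin sum to 1. Optionally smoothed like [bin_and_smooth()].
#'
#' @param labels A `label_stream`.
#' @param bin_width_s Bin width in seconds.
#' @param frame_rate_hz Frames per second.
#' @param vocabulary Categories to report (default the stream's vocabulary).
#' @param window_bins,smooth As in [bin_and_smooth()] (default unsmoothed).
#' @return A bins x categories numeric matrix.
#' @export
label_probabilities <- function(labels, bin_width_s, frame_rate_hz,
                                vocabulary = attr(labels, "vocabulary"),
                                window_bins = 6, smooth = FALSE) {
  x <- labels$label
  n_bins <- floor(length(x) / (bin_width_s * frame_rate_hz) + 1e-9)
  bin_of <- floor((seq_along(x) - 1) / (bin_width_s * frame_rate_hz)) + 1L
  keep <- bin_of <= n_bins
  out <- matrix(NA_real_, n_bins, length(vocabulary),
                dimnames = list(NULL, vocabulary))
  tab <- table(factor(bin_of[keep], levels = seq_len(n_bins)),
               factor(x[keep], levels = vocabulary), useNA = "no")
  denom <- tapply(!is.na(x[keep]), bin_of[keep], sum)
  den <- rep(0, n_bins)
  den[as.integer(names(denom))] <- denom
  out[] <- sweep(unclass(tab), 1, ifelse(den == 0, NA, den), "/")
  if (smooth && window_bins > 1) {
    out <- apply(out, 2, moving_mean, k = window_bins)
  }
  out
}

#' Two-way ANOVA with repeated measures
#'
#' The study's workhorse test, fit with base `aov()` error strata and
#' reported with uncorrected (sphericity-unadjusted) degrees of freedom:
#'
#' * `design = "within"`: both factors vary within subject. The subject is
#'   the dyad; `group` is typically sex (male and female of the same dyad)
#'   and `time` the repeated bins. With n subjects, 2 group levels and b
#'   bins: group df (1, n-1); time and interaction df (b-1, (b-1)(n-1)).
#' * `design = "mixed"`: `group` is between-subject (e.g., matched vs mixed
#'   dyad type), `time` within. With N subjects total: group df (1, N-2);
#'   time and interaction df (b-1, (b-1)(N-2)).
#'
#' Subjects with incomplete cells are dropped listwise (with a message).
#' A stratum with zero residual variance is reported with `degenerate = TRUE`
#' rather than an error.
#'
#' @param data Long data frame with columns `subject`, `group`, `bin`,
#'   `value` (names configurable).
#' @param design `"within"` or `"mixed"`.
#' @param dv,subject,group,time Column names.
#' @param gg_correction Apply a Greenhouse-Geisser epsilon correction to the
#'   within-factor P values (default FALSE: reported df match the classic
#'   uncorrected forms).
#' @return An object of class `rm_anova`: a data frame of effects
#'   (`effect`, `df_num`, `df_den`, `F`, `P`) plus design metadata.
#' @examples
#' d <- expand.grid(subject = factor(1:6), group = factor(c("m", "f")),
#'                  bin = factor(1:4))
#' d$value <- rnorm(nrow(d))
#' rm_anova(d, design = "within")
#' @export
rm_anova <- function(data, design = c("within", "mixed"), dv = "value",
                     subject = "subject", group = "group", time = "bin",
                     gg_correction = FALSE) {
  design <- match.arg(design)
  d <- data.frame(subject = factor(data[[subject]]),
                  group = factor(data[[group]]),
                  bin = factor(data[[time]]),
                  value = as.numeric(data[[dv]]))
  if (nlevels(d$group) != 2) stop("group factor must have exactly 2 levels")
  # listwise deletion of subjects with any missing cell
  bad_subj <- unique(d$subject[is.na(d$value)])
  expected <- if (design == "within") nlevels(d$group) * nlevels(d$bin) else nlevels(d$bin)
  counts <- table(d$subject[!is.na(d$value)])
  short <- names(counts)[counts < expected]
  drop_subj <- union(as.character(bad_subj), short)
  if (length(drop_subj)) {
    message("dropping ", length(drop_subj), " subject(s) with incomplete cells")
    d <- droplevels(d[!(as.character(d$subject) %in% drop_subj), ])
  }
  n_subj <- nlevels(d$subject)
  if (design == "mixed") {
    per_group <- table(unique(d[c("subject", "group")])$group)
    if (any(per_group < 2)) stop("insufficient data: fewer than 2 subjects per group")
  } else if (n_subj < 2) {
    stop("insufficient data: fewer than 2 subjects")
  }

  if (design == "within") {
    fit <- aov(value ~ group * bin + Error(subject / (group * bin)), data = d)
    strata <- list(group = "Error: subject:group",
                   bin = "Error: subject:bin",
                   `group:bin` = "Error: subject:group:bin")
  } else {
    fit <- aov(value ~ group * bin + Error(subject), data = d)
    strata <- list(group = "Error: subject",
                   bin = "Error: Within",
                   `group:bin` = "Error: Within")
  }
  s <- summary(fit)
  tab <- data.frame(effect = c("group", "time", "interaction"),
                    df_num = NA_real_, df_den = NA_real_,
                    F = NA_real_, P = NA_real_)
  degenerate <- FALSE
  effs <- c("group", "bin", "group:bin")
  for (i in seq_along(effs)) {
    st <- s[[strata[[effs[i]]]]][[1]]
    rn <- trimws(rownames(st))
    row <- match(effs[i], rn)
    res <- match("Residuals", rn)
    tab$df_num[i] <- st$Df[row]
    tab$df_den[i] <- st$Df[res]
    ms_res <- st$`Mean Sq`[res]
    # scale-aware zero: an all-constant response leaves rounding dust only
    ms_floor <- 1e-20 * mean(d$value^2)
    if (!is.finite(ms_res) || ms_res <= ms_floor) {
      degenerate <- TRUE
      tab$F[i] <- NA_real_
      tab$P[i] <- NA_real_
    } else {
      tab$F[i] <- st$`F value`[row]
      tab$P[i] <- st$`Pr(>F)`[row]
    }
  }
  eps <- NA_real_
  if (gg_correction) {
    eps <- gg_epsilon(d)
    for (i in 2:3) {
      if (is.finite(tab$F[i])) {
        tab$P[i] <- stats::pf(tab$F[i], eps * tab$df_num[i],
                              eps * tab$df_den[i], lower.tail = FALSE)
      }
    }
  }
  structure(list(table = tab, design = design, n_subjects = n_subj,
                 n_bins = nlevels(d$bin), group_levels = levels(d$group),
                 degenerate = degenerate, gg_epsilon = eps,
                 data = d),
            class = "rm_anova")
}

# Greenhouse-Geisser epsilon from the within-subject (bin) covariance
gg_epsilon <- function(d) {
  m <- tapply(d$value, list(d$subject, d$bin), mean)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  S <- stats::cov(m)
  k <- ncol(S)
  dc <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) +
    mean(S)
  sum(diag(dc))^2 / ((k - 1) * sum(dc^2))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA (%s design): %d subjects, %d bins\n",
              x$design, x$n_subjects, x$n_bins))
  if (x$degenerate) cat("NOTE: degenerate stratum (zero residual variance)\n")
  tab <- x$table
  tab$F <- round(tab$F, 2)
  tab$P <- signif(tab$P, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.rm_anova <- function(object, alpha = 0.05, ...) {
  tab <- object$table
  tab$significant_0.05 <- !is.na(tab$P) & tab$P < alpha
  tab$significant_0.01 <- !is.na(tab$P) & tab$P < 0.01
  tab
}

#' Per-bin Tukey post-hoc tests
#'
#' Honestly-significant-difference comparison between the two groups inside
#' every time bin, as the follow-up to [rm_anova()]. Bins with fewer than two
#' values per group are excluded; bins with zero pooled variance but unequal
#' means are flagged degenerate instead of crashing.
#'
#' @param data Long data frame (same layout as [rm_anova()]).
#' @param alpha Significance level (default 0.05).
#' @param dv,group,time Column names.
#' @return Data frame `bin`, `diff`, `p`, `significant`, `degenerate`.
#' @export
tukey_per_bin <- function(data, alpha = 0.05, dv = "value", group = "group",
                          time = "bin") {
  bins <- unique(data[[time]])
  out <- data.frame(bin = bins, diff = NA_real_, p = NA_real_,
                    significant = NA, degenerate = FALSE)
  for (i in seq_along(bins)) {
    d <- data.frame(value = as.numeric(data[[dv]][data[[time]] == bins[i]]),
                    group = factor(data[[group]][data[[time]] == bins[i]]))
    d <- d[!is.na(d$value), ]
    if (nlevels(droplevels(d$group)) < 2 || min(table(droplevels(d$group))) < 2) next
    vars <- tapply(d$value, d$group, stats::var)
    means <- tapply(d$value, d$group, mean)
    if (all(vars == 0, na.rm = TRUE)) {
      out$degenerate[i] <- TRUE
      out$diff[i] <- diff(means)
      out$significant[i] <- NA
      next
    }
    th <- TukeyHSD(aov(value ~ group, data = d), conf.level = 1 - alpha)$group
    out$diff[i] <- th[1, "diff"]
    out$p[i] <- th[1, "p adj"]
    out$significant[i] <- th[1, "p adj"] < alpha
  }
  out
}

#' Kolmogorov-Smirnov normality report per repeated measure
#'
#' One-sample KS test of each repeated measure (each bin's distribution
#' across subjects) against a normal with that measure's sample mean and SD.
#' This mirrors the study's normality reporting: it is a report only and
#' does not gate the ANOVA. Measures with fewer than 3 values or zero SD
#' are skipped with a note.
#'
#' @param data Long data frame (same layout as [rm_anova()]).
#' @param alpha Significance level (default 0.05).
#' @param dv,time Column names.
#' @return Data frame `bin`, `n`, `D`, `p`, `pass`, `skipped`.
#' @export
ks_normality <- function(data, alpha = 0.05, dv = "value", time = "bin") {
  bins <- unique(data[[time]])
  out <- data.frame(bin = bins, n = NA_integer_, D = NA_real_, p = NA_real_,
                    pass = NA, skipped = FALSE)
  for (i in seq_along(bins)) {
    v <- as.numeric(data[[dv]][data[[time]] == bins[i]])
    v <- v[!is.na(v)]
    out$n[i] <- length(v)
    if (length(v) < 3 || sd(v) == 0) {
      out$skipped[i] <- TRUE
      next
    }
    kt <- suppressWarnings(ks.test(v, "pnorm", mean(v), sd(v)))
    out$D[i] <- unname(kt$statistic)
    out$p[i] <- kt$p.value
    out$pass[i] <- kt$p.value >= alpha
  }
  out
}

#' Bout statistics of a categorical stream
#'
#' A bout is a maximal run of consecutive identical labels. Per category the
#' table reports bout count, mean and median duration (seconds), total time,
#' and bout rate per hour. Bouts shorter than `min_bins` are excluded.
#'
#' @param labels Character/factor vector of per-bin labels (NA = missing),
#'   or a `label_stream`.
#' @param bin_width_s Width of one bin in seconds (default 1).
#' @param min_bins Minimum bout length in bins (default 1).
#' @return Data frame `category`, `n_bouts`, `mean_duration_s`,
#'   `median_duration_s`, `total_s`, `rate_per_h`.
#' @export
bout_statistics <- function(labels, bin_width_s = 1, min_bins = 1) {
  if (inherits(labels, "label_stream")) labels <- labels$label
  x <- as.character(labels)
  if (length(x) == 0) {
    return(data.frame(category = character(), n_bouts = integer(),
                      mean_duration_s = numeric(), median_duration_s = numeric(),
                      total_s = numeric(), rate_per_h = numeric()))
  }
  r <- rle(x)
  keep <- !is.na(r$values) & r$lengths >= min_bins
  cat_ <- r$values[keep]
  len <- r$lengths[keep]
  session_h <- length(x) * bin_width_s / 3600
  cats <- unique(cat_)
  out <- data.frame(
    category = cats,
    n_bouts = vapply(cats, function(cc) sum(cat_ == cc), integer(1)),
    mean_duration_s = vapply(cats, function(cc) mean(len[cat_ == cc]) * bin_width_s, numeric(1)),
    median_duration_s = vapply(cats, function(cc) stats::median(len[cat_ == cc]) * bin_width_s, numeric(1)),
    total_s = vapply(cats, function(cc) sum(len[cat_ == cc]) * bin_width_s, numeric(1))
  )
  out$rate_per_h <- out$n_bouts / session_h
  rownames(out) <- NULL
  out
}

#' Write an ANOVA table as comma-separated text
#'
#' Layout mirrors the study's statistics tables: one row per effect with
#' numerator/denominator df, F and P; significance is marked at both the
#' 0.05 and 0.01 thresholds.
#'
#' @param x An `rm_anova` object.
#' @param path Output path.
#' @param header Optional `#`-prefixed provenance lines written first.
#' @export
write_anova_table <- function(x, path, header = NULL) {
  tab <- summary(x)
  if (!is.null(header)) writeLines(paste0("# ", header), path)
  data.table::fwrite(tab, path, append = !is.null(header), col.names = TRUE)
  invisible(path)
}
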