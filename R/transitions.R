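#' Collapse mirror roles into their interaction categories
#'
#' Maps recipient-role labels onto their interaction category
#' (`being_chased` to `chasing`, `being_attacked` to `attacking`,
#' `being_pointed_at` to `pointing`), so an interaction occupies the same
#' category for both animals; the original roles remain available in the
#' frame-level stream. The mapping is configurable.
#'
#' @param labels A `label_stream` (or character vector).
#' @param mapping Named character vector mirror -> target.
#' @return A `label_stream` over [analysis_categories()].
#' @export
collapse_roles <- function(labels,
                           mapping = c(being_chased = "chasing",
                                       being_attacked = "attacking",
                                       being_pointed_at = "pointing")) {
  vec <- if (inherits(labels, "label_stream")) labels$label else as.character(labels)
  hit <- vec %in% names(mapping)
  vec[hit] <- unname(mapping[vec[hit]])
  if (inherits(labels, "label_stream")) {
    out <- labels
    out$label <- vec
    attr(out, "vocabulary") <- analysis_categories()
    out
  } else {
    vec
  }
}

new_discretized_stream <- function(labels, vocabulary, animal_id,
                                   bin_width_s = 1) {
  structure(list(labels = labels, vocabulary = vocabulary,
                 animal_id = animal_id, bin_width_s = bin_width_s),
            class = "discretized_stream")
}

#' @export
print.discretized_stream <- function(x, ...) {
  cat(sprintf("discretized_stream (%s): %d bins of %g s, %d categories\n",
              x$animal_id, length(x$labels), x$bin_width_s,
              length(x$vocabulary)))
  invisible(x)
}

#' Discretize divided-cage variables into four occupancy categories
#'
#' Direction and distance to divider are first averaged into 1-s bins, then
#' thresholded: `toward` iff binned direction exceeds `direction_threshold`
#' (strictly; a bin exactly at the threshold is `opposite`), `near` iff
#' binned distance is strictly below `distance_threshold`. The combined
#' vocabulary is `toward-near`, `opposite-near`, `toward-away`,
#' `opposite-away`. Bins missing either variable give missing labels.
#'
#' @param direction,distance `variable_series` from [decompose_track()].
#' @param geometry [compartment()] used to default the distance threshold to
#'   the midpoint of the compartment's usable range along the divided axis.
#' @param direction_threshold Default 0.
#' @param distance_threshold Default half the compartment length in cm.
#' @param bin_width_s Default 1.
#' @param frame_rate_hz Frames per second (from the series clock if absent).
#' @param window_s Restrict to the first `window_s` seconds (e.g. the first
#'   12 h of a 72-h session); NULL (default) uses the whole series.
#' @return A `discretized_stream` over [orientation_categories()].
#' @export
discretize_exp1 <- function(direction, distance, geometry = NULL,
                            direction_threshold = 0,
                            distance_threshold = NULL,
                            bin_width_s = 1, frame_rate_hz = NULL,
                            window_s = NULL) {
  if (is.null(distance_threshold)) {
    if (is.null(geometry) || is.null(geometry$compartment_box)) {
      stop("distance_threshold or a compartment geometry is required")
    }
    box <- geometry$compartment_box
    distance_threshold <-
      unname(box["x_max"] - box["x_min"]) / geometry$px_per_cm / 2
  }
  if (!is.null(window_s)) {
    keep <- direction$clock_s < window_s
    direction <- direction[keep, ]
    class(direction) <- c("variable_series", "data.frame")
    distance <- distance[keep, ]
    class(distance) <- c("variable_series", "data.frame")
  }
  bd <- bin_and_smooth(direction, bin_width_s, frame_rate_hz, smooth = FALSE)
  bx <- bin_and_smooth(distance, bin_width_s, frame_rate_hz, smooth = FALSE)
  toward <- bd$values > direction_threshold
  near <- bx$values < distance_threshold
  lab <- ifelse(is.na(toward) | is.na(near), NA_character_,
                paste0(ifelse(toward, "toward", "opposite"), "-",
                       ifelse(near, "near", "away")))
  new_discretized_stream(lab, orientation_categories(),
                         attr(direction, "animal_id"), bin_width_s)
}

#' 1-s modal labels from a frame-level label stream
#'
#' Mirror roles are collapsed onto their interaction categories
#' ([collapse_roles()]), then each 1-s bin receives its most frequent label
#' (winner-takes-all); ties are broken by vocabulary order and reported.
#' Bins with no labeled frames are missing.
#'
#' @param labels A frame-level `label_stream`.
#' @param frame_rate_hz Frames per second.
#' @param bin_width_s Default 1.
#' @param collapse Collapse mirror roles first (default TRUE).
#' @return A `discretized_stream` over [analysis_categories()].
#' @export
binned_labels_exp2 <- function(labels, frame_rate_hz, bin_width_s = 1,
                               collapse = TRUE) {
  if (collapse) labels <- collapse_roles(labels)
  vocab <- analysis_categories()
  x <- factor(labels$label, levels = vocab)
  fpb <- bin_width_s * frame_rate_hz
  n_bins <- floor(length(x) / fpb + 1e-9)
  bin_of <- floor((seq_along(x) - 1) / fpb) + 1L
  keep <- bin_of <= n_bins
  counts <- table(factor(bin_of[keep], levels = seq_len(n_bins)), x[keep])
  top <- apply(unclass(counts), 1L, function(r) {
    if (sum(r) == 0) NA_integer_ else which.max(r)
  })
  n_ties <- sum(apply(unclass(counts), 1L, function(r) {
    sum(r == max(r)) > 1 && sum(r) > 0
  }))
  if (n_ties > 0) message(n_ties, " tied bin(s) resolved by vocabulary order")
  new_discretized_stream(vocab[top], vocab, attr(labels, "animal_id"),
                         bin_width_s)
}

#' Directional behavior-transition matrix for a dyad
#'
#' Counts transitions from the actor animal's category at time t to the
#' reactor animal's category at time t+1, over all bin pairs where both
#' labels are present, and row-normalizes to probabilities. Computed once
#' per sex directionality (male-to-female and female-to-male); the two are
#' not transposes of each other. Rows never visited are all-zero and listed
#' in `unvisited`.
#'
#' @param actor,reactor `discretized_stream`s of equal length and shared
#'   vocabulary.
#' @param directionality Label stored on the result (e.g.
#'   `"male_to_female"`).
#' @param dyad_id Identifier stored on the result.
#' @return An object of class `transition_matrix` with `counts`, `probs`
#'   (row-stochastic over visited rows), `vocabulary`, `n_transitions`,
#'   `unvisited`.
#' @export
transition_matrix <- function(actor, reactor, directionality = NA_character_,
                              dyad_id = NA_character_) {
  stopifnot(inherits(actor, "discretized_stream"),
            inherits(reactor, "discretized_stream"))
  if (!identical(actor$vocabulary, reactor$vocabulary)) {
    stop("actor and reactor vocabularies differ")
  }
  if (length(actor$labels) != length(reactor$labels)) {
    stop("actor and reactor streams differ in length")
  }
  vocab <- actor$vocabulary
  a <- factor(actor$labels[-length(actor$labels)], levels = vocab)
  r <- factor(reactor$labels[-1], levels = vocab)
  ok <- !is.na(a) & !is.na(r)
  if (sum(ok) < 1) stop("empty-matrix error: fewer than 2 valid bins")
  counts <- unclass(table(a[ok], r[ok]))
  dimnames(counts) <- list(vocab, vocab)
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, probs = probs, vocabulary = vocab,
                 directionality = directionality, dyad_id = dyad_id,
                 n_transitions = sum(ok), unvisited = vocab[rs == 0]),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("transition_matrix %s (%s): %d x %d, %d transitions\n",
              x$dyad_id, x$directionality, nrow(x$probs), ncol(x$probs),
              x$n_transitions))
  print(round(x$probs, digits))
  if (length(x$unvisited)) {
    cat("unvisited rows:", paste(x$unvisited, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Average a group of transition matrices into a directed graph
#'
#' Element-wise mean of the probability matrices of a group of dyads,
#' returned with a weighted directed `igraph` graph (self-loops included)
#' and its edge list, ready for plotting or GraphML export.
#'
#' @param matrices List of `transition_matrix` objects, shared vocabulary.
#' @return List with `mean_probs`, `graph` (igraph), and `edges`
#'   (`source`, `target`, `weight` in \[0, 1\]).
#' @export
average_graph <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  vocab <- matrices[[1]]$vocabulary
  for (m in matrices) {
    if (!identical(m$vocabulary, vocab)) stop("mixed vocabularies in group")
  }
  arr <- simplify2array(lapply(matrices, `[[`, "probs"))
  mean_probs <- apply(arr, c(1, 2), mean)
  dimnames(mean_probs) <- list(vocab, vocab)
  g <- igraph::graph_from_adjacency_matrix(mean_probs, mode = "directed",
                                           weighted = TRUE, diag = TRUE)
  el <- igraph::as_data_frame(g, what = "edges")
  names(el) <- c("source", "target", "weight")
  list(mean_probs = mean_probs, graph = g, edges = el)
}

#' Export an averaged transition graph
#'
#' @param graph Output of [average_graph()].
#' @param graphml_path,edges_path Output paths (either may be NULL).
#' @export
write_graph_exports <- function(graph, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(graph$graph, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    data.table::fwrite(graph$edges, edges_path)
  }
  invisible(graph)
}

# reshape one dyad's probability matrix into the off-diagonal pair vector,
# pairs ordered row-major; unvisited rows contribute NA pairs
pair_vector <- function(tm) {
  p <- tm$probs
  p[tm$unvisited, ] <- NA_real_
  k <- nrow(p)
  idx <- which(row(p) != col(p), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  setNames(p[idx],
           paste(tm$vocabulary[idx[, 1]], tm$vocabulary[idx[, 2]], sep = "->"))
}

#' Compare transition probabilities between dyad types
#'
#' For one sex directionality: self-loops are dropped, leaving k(k-1)
#' behavior pairs per dyad (12 for the four-category divided-cage
#' vocabulary, 20 for the five-category undivided vocabulary). The
#' dyad x pair probabilities are compared with a mixed two-way ANOVA (dyad
#' type between, behavior pair as the repeated measure), followed by a
#' Tukey test per pair. Probabilities, not counts, are the compared
#' quantity; a dyad's unvisited rows yield missing pairs and drop that dyad
#' listwise from the ANOVA.
#'
#' @param matrices List of `transition_matrix`, one per dyad.
#' @param dyad_type Character vector (`"matched"`/`"mixed"`) parallel to
#'   `matrices`.
#' @param alpha Post-hoc significance level (default 0.05).
#' @return List of class `transition_comparison`: `anova` ([rm_anova()]),
#'   `posthoc` (per-pair Tukey table), `pair_means` (group means and SD per
#'   pair), `pairs` (pair names), `directionality`.
#' @export
compare_transitions <- function(matrices, dyad_type, alpha = 0.05) {
  stopifnot(length(matrices) == length(dyad_type))
  vecs <- lapply(matrices, pair_vector)
  pairs <- names(vecs[[1]])
  long <- do.call(rbind, lapply(seq_along(vecs), function(i) {
    data.frame(subject = sprintf("dyad%03d", i),
               group = unname(dyad_type[i]),
               bin = factor(pairs, levels = pairs),
               value = unname(vecs[[i]]))
  }))
  fit <- rm_anova(long, design = "mixed")
  ph <- tukey_per_bin(long, alpha = alpha)
  names(ph)[names(ph) == "bin"] <- "pair"
  agg_mean <- tapply(long$value, list(long$bin, long$group), mean, na.rm = TRUE)
  agg_sd <- tapply(long$value, list(long$bin, long$group), sd, na.rm = TRUE)
  pm <- data.frame(pair = rownames(agg_mean))
  for (g in colnames(agg_mean)) {
    pm[[paste0("mean_", g)]] <- agg_mean[, g]
    pm[[paste0("sd_", g)]] <- agg_sd[, g]
  }
  rownames(pm) <- NULL
  structure(list(anova = fit, posthoc = ph, pair_means = pm, pairs = pairs,
                 directionality = matrices[[1]]$directionality),
            class = "transition_comparison")
}

#' @export
print.transition_comparison <- function(x, ...) {
  cat("Transition comparison (", length(x$pairs), " behavior pairs, ",
      x$directionality, ")\n", sep = "")
  print(x$anova)
  sig <- x$posthoc[!is.na(x$posthoc$significant) & x$posthoc$significant, ]
  if (nrow(sig)) {
    cat("post-hoc significant pairs:\n")
    print(sig[c("pair", "diff", "p")], row.names = FALSE)
  } else {
    cat("no post-hoc significant pairs\n")
  }
  invisible(x)
}
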