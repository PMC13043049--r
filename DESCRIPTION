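Package: voledyads
Title: Dyadic Social-Behavior Analysis for Opposite-Sex Rodent Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for long-duration recordings of opposite-sex
    rodent dyads. Converts pose-tracker keypoint tables into behavioral
    decomposition variables (body direction to a cage divider, distance to
    divider, locomotion speed), consolidates per-frame behavior-classifier
    likelihoods into an analysis ethogram (chasing, attacking, pointing,
    behaving alone, huddling) with dyad-level labeling rules and manual
    aggression-annotation overlay, and provides time-binned group statistics
    (repeated-measures two-way ANOVA with per-bin Tukey post-hocs),
    cross-experiment correlation matrices, bout statistics, and
    sex-directional behavior-transition matrices with directed-graph export.
    Includes a synthetic dyad cohort generator (reflected random-walk
    keypoints for divided cohabitation; a coupled semi-Markov ethogram for
    undivided cohabitation) with stored ground truth, so every stage is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
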