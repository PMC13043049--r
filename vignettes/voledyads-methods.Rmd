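---
title: "Methods: models, parameters, and design choices in voledyads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in voledyads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voledyads)
```

This vignette documents the scientific and numerical decisions behind the
package: what each stage computes, why the defaults are what they are, what
the synthetic cohorts do and do not emulate, and where the design was
genuinely open.

## The measurement model

### Divided cohabitation

A male and a female occupy the two compartments of a cage
(48.3 × 25.4 cm by default) separated by a central divider, filmed from
overhead at a nominal 20 Hz. A pose tracker supplies seven keypoints per
animal per frame — nose, left/right ear, three spine points, tail base —
in image coordinates (origin top-left, y downward). Three per-frame
variables are derived:

* **Direction to divider.** The body axis is the line from tail base to
  nose. With φ the unsigned angle between that axis and the unit normal
  pointing from the animal's compartment toward the divider
  (φ ∈ [0°, 180°]), the score is `1 − φ/90`: +1 facing the divider, 0
  parallel, −1 facing away. The rescaling is *linear in angle*, not a
  cosine: a linear map places "parallel" exactly at 0 and weighs all
  angular excursions equally, which matches how the variable is described
  and plotted in this literature; a cosine variant is available via
  `scaling = "cosine"`. Clockwise and counterclockwise rotations are
  treated identically because only the unsigned angle enters.
* **Distance to divider.** `|x_center − x_divider| / px_per_cm`, by
  construction independent of the position along the cage's width. The
  *animal center* is the centroid of the three spine keypoints: the spine
  is the part of the skeleton least often occluded (the nose disappears
  against the mesh, the tail base under bedding); a full-7-keypoint
  centroid is available via `center_method = "all"`.
* **Locomotion speed.** The hypotenuse of the center displacement between
  consecutive frames, converted to cm and multiplied by the frame rate.
  The multiplication is explicit so the reported unit is cm/s rather than
  cm/frame; the value is assigned to the later frame and the first frame
  is missing.

Low-confidence keypoints (confidence < 0.6 by default) are linearly
interpolated across gaps of up to 1 s; longer gaps stay missing and
propagate into missing bins — never into zeros, which would bias binned
means toward the cage origin.

Multi-segment sessions (e.g., twelve 6-h files for a 72-h session) are
aligned on one never-resetting clock axis. Each segment's start offset
comes from a YAML sidecar rather than from filename parsing, because
acquisition-software naming schemes are not standardized. A configurable
margin (default 2 s) is trimmed from both ends of every segment; after
trimming, overlaps are an error and gaps are kept as missing time.

### Undivided cohabitation

The same dyads interact freely while a behavior classifier emits per-frame
likelihoods in [0, 1] over nine raw categories (aggression, chasing,
being chased, approaching, three sniffing-type behaviors reported as one
`sniffing` channel, moving alone, idling alone, huddling). The analysis
ethogram is built in three steps:

1. **Consolidation** (`consolidate_categories`). `pointing` is the max of
   the sniffing and approaching likelihoods (sniffing-type behaviors and
   the freezing-like orientation toward the partner that classifiers
   confuse with sniffing are analyzed as one category); `behaving_alone`
   is the max of moving alone and idling alone. Max, not sum, is the merge
   operator so likelihoods stay probabilities. The classifier's
   `aggression` output is dropped entirely: aggression enters only through
   the manually validated annotation channel.
2. **Dyad rules** (`apply_dyad_rules`). Huddling and behaving-alone are
   full-dyad categories: if only one animal's winning category is one of
   them in a frame, that likelihood is zeroed. During sustained body
   contact multi-animal trackers sometimes merge the two identities into
   one, which surfaces as one animal's scores missing while the partner is
   scored "idling alone"; such frames, when the last fully-labeled state
   was mutual huddling, are re-classified as huddling for both. The
   detector (missing scores + partner behaving-alone + prior huddle) is a
   package choice — the failure mode is well known but no canonical
   detector exists.
3. **Labeling** (`labelize`). Winner-takes-all per frame; argmax ties are
   broken by the fixed vocabulary order (chasing, attacking, pointing,
   behaving alone, huddling, then mirror roles) and counted in a message,
   so the tie rule is deterministic and auditable. Attack annotations then
   overwrite the label unconditionally.

Recipient roles (being chased / attacked / pointed at) are preserved at
frame level and collapsed onto their interaction category only where an
analysis needs one category per animal (profiles, 1-s transition labels).
Under the default collapse a chase occupies "chasing" bins for *both*
animals; this is the main interpretive caveat of the transition analysis
and the mapping is therefore configurable in `collapse_roles()`.

## Statistics

* **Binning and smoothing** (`bin_and_smooth`). Per-animal bin means
  ignoring missing frames, then a 6-bin moving mean. The moving window
  shrinks at the series edges, and for an even window covers k/2 bins
  before and k/2 − 1 after the current bin — the convention of the
  numeric environment these analyses traditionally use, reproduced so
  binned curves match published ones bin-for-bin. Defaults: 1-h bins over
  72 h (72 bins) and 3-min bins over 4 h (80 bins).
* **Repeated-measures ANOVA** (`rm_anova`). Fit with base `aov()` error
  strata. Two designs: *within* (sex × time, the dyad is the subject —
  the only subject definition consistent with a sex-effect error df of
  n_dyads − 1) and *mixed* (dyad type between, time within). No
  sphericity correction by default — the reported df are the classic
  uncorrected closed forms, which is what published tables print — with a
  Greenhouse-Geisser option behind `gg_correction = TRUE`. Subjects with
  incomplete cells are dropped listwise with a message. An all-constant
  response is reported as degenerate (F, P missing) rather than an error,
  using a scale-aware zero threshold on the residual mean square.
* **Post-hocs** (`tukey_per_bin`). Tukey's honestly-significant-difference
  test between the two groups inside each bin, α = 0.05 by default; bins
  with under two values per group are excluded, and zero-pooled-variance
  bins are flagged degenerate.
* **Normality** (`ks_normality`). One-sample Kolmogorov-Smirnov per
  repeated measure against a normal with the sample's mean and SD. It is
  a report, not a gate: the ANOVA runs regardless, as is conventional.
* **Bouts** (`bout_statistics`). Maximal runs of identical labels; counts,
  durations, and rates per category with a configurable minimum duration.
* **Correlations** (`group_correlations`). Eight session averages per
  animal (three divided-cage variables, five category probabilities),
  Pearson R and two-sided P per pair within each sex × dyad-type group.
  P values are reported per pair without multiple-testing correction,
  matching per-pair reporting practice in this literature; a
  Benjamini-Hochberg option exists and is flagged in the output when used.
* **Transitions** (`transition_matrix`, `compare_transitions`). Streams
  are discretized to 1-s bins (bin means thresholded for the divided cage:
  *toward* iff direction > 0 strictly, *near* iff distance below the
  compartment midpoint, both thresholds configurable because no canonical
  values exist; modal labels for the undivided cage). The directional
  matrix counts actor category at t against partner category at t + 1 and
  row-normalizes; probabilities, not counts, are the compared quantity.
  Rows never visited yield missing pairs, and a dyad with missing pairs
  drops listwise from the pair-wise ANOVA. Self-loops are excluded from
  comparisons, leaving k(k−1) behavior pairs (12 for the 4-category
  divided vocabulary, 20 for the 5-category undivided one) treated as
  repeated measures. Divided-cage transition analysis defaults to the
  initial sixth of the session (the first 12 h of 72), when activity is
  highest.

## The synthetic cohorts

The generators define the study conditions every test runs under; they are
tested code, not fixtures.

**Divided** (`generate_divided_cohort`). Default cohort 7/8/7/6 dyads per
subtype (28 dyads: 15 matched, 13 mixed). The heading process is generated
directly on the direction-score scale as a reflected AR(1) (persistence
0.95 per frame, stationary SD 0.5) whose target mean is the configured
orientation bias — male +0.4 in matched and +0.55 in mixed dyads, females
0, with a between-animal SD of 0.1. These magnitudes are package
calibration choices: the source literature reports test statistics on real
data, not effect sizes, so the defaults were set once to values a
behavioral scientist would call a clear but not saturating orientation
preference, and are not tuned thereafter. Reflection at ±1 pulls realized
means slightly toward the interior, so the per-animal realized mean is
stored in the ground truth alongside the configured target. The center
follows a reflected random walk (speed scale 3 cm/s) modulated by an
activity envelope `1 + 1.5·exp(−t/τ)` with τ one sixth of the session —
the elevated initial activity that motivates restricting transition
analysis to the early session. An optional 14:10 circadian multiplier is
off by default because it is meaningless at scaled-down durations.
Keypoints are laid along the body axis with 0.05-cm isotropic jitter and
a 2% low-confidence dropout rate.

**Undivided** (`generate_undivided_cohort`). A dyad-level semi-Markov
chain over eight joint states (mutual huddle, mutual alone, and
actor-recipient pairs for chase, attack, point in both directions) at a
1-s step, which enforces the labeling constraints *by construction*:
huddling and behaving-alone are always mutual, and two simultaneous focal
attackers are impossible rather than merely checked. Dwell times are
geometric (per-state exit probabilities; defaults give huddles of ~50 s,
attacks of ~2.5 s). Entry hazards default to female-initiated aggression
above male-initiated (0.08 vs 0.04 chase, 0.05 vs 0.02 attack — aggression
in newly formed opposite-sex dyads of this species is predominantly
female-initiated), multiplied by 3 for female aggression in mixed dyads.
Aggression hazards decay with a 1-h half-life and the huddling entry
hazard rises from 20% toward its full weight with a 1-h half-life,
emulating the transition from high-arousal interaction to consolidated
huddling; `Inf` disables either modulation, which also makes the chain
time-homogeneous so that `joint_transition_matrix()` and
`implied_directional_matrix()` provide exact analytic targets for
recovery tests. Emission is one-hot per frame with a configurable label
noise (default 1%); attack states emit sniffing-type scores while the
attack itself is written to the annotation channel, mirroring pipelines
in which aggression is annotated manually rather than scored by the
classifier. Identity-merge glitches are injected only after at least one
second of sustained huddling (the realistic regime, and the regime the
correction is defined for).

What the generators do *not* emulate: posture and kinematic realism,
estrous or reproductive state, circadian structure at scaled-down
durations, classifier confusion structure beyond uniform label noise, and
more than two animals. Passing tests therefore demonstrate that the
pipeline's logic, statistics, and recovery behavior are correct under a
controlled generative model — not that any biological effect exists in
real animals.

## Numerical choices and degenerate inputs

* Argmax and modal ties break by vocabulary order and are counted in
  messages.
* Probability rows of transition matrices are exact row-normalizations;
  tests assert row sums to 1 within 1e−12.
* Missing data propagate as missing bins and listwise-deleted subjects,
  never as zeros; every deletion is reported.
* Degenerate statistical inputs (zero residual variance, zero pooled
  variance, constant samples, unvisited matrix rows) are flagged in the
  output objects instead of raising errors, so batch runs survive
  pathological dyads.
* Per-dyad RNG substreams are derived deterministically from the global
  seed, making cohorts reproducible and independent of generation order;
  identical configs and seeds produce byte-identical files.

## Problem sizes

The shipped test-suite and acceptance runs use scaled-down sessions chosen
to exercise every code path at desk scale: cohorts of 4-28 dyads, divided
sessions of 10 min - 72 h at 0.05-5 Hz, undivided sessions of 5 min - 4 h
at 1-5 Hz, 500 null-calibration cohorts, and 20-seed recovery runs. Full
published scale (72 h at 20 Hz) is a configuration change, not a code
change.

## Interface

The package's interface is its exported functions plus the
`run_pipeline()` orchestrator and this vignette; the workflow is an R
analysis, not a shell tool, so no command-line wrapper is provided.
`run_pipeline()` executes simulate → decompose → categorize → statistics →
correlations → transitions, writes every table with a seeded provenance
header, and emits a YAML run report (version, seed, config hash, per-stage
counts).

## Known limitations

* The mirror-role collapse makes the two sex directionalities coincide
  exactly under the generator (both animals share a category each second);
  real classifier output, where roles and labels disagree across a dyad,
  produces genuinely asymmetric directional matrices. The collapse mapping
  is configurable for this reason.
* The identity-merge detector assumes the glitch begins strictly inside a
  huddle; a merge at the very first huddle second is not corrected.
* The linear angle rescaling and the strict discretization thresholds are
  conventions; results near category boundaries can shift under the cosine
  or threshold alternatives, which is why both are exposed as options.
* `aov()`-based repeated-measures fits require listwise-complete subjects;
  heavily missing designs lose subjects rather than borrowing strength
  across cells (a mixed-effects alternative is out of scope).
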