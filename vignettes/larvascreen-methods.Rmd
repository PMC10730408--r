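---
title: "Models and methods behind larvascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind larvascreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvascreen)
```

# Scope

`larvascreen` implements a high-throughput behavioral phenotyping pipeline
for 6 dpf larval zebrafish arrayed in 9 mm wells of a 100-well plate, and
the screening statistics used to compare homozygous mutants against their
siblings across a battery of 94 kinematic metrics. The pipeline has five
stages — stimulus protocol, tracking, kinematics, metrics, screen — plus a
synthetic cohort simulator that generates ground-truth-annotated data so
the whole chain can be exercised and validated without recorded video.

# The stimulus paradigm

`build_default_protocol()` encodes a two-hour paradigm of four blocks, in
order:

* **VMR** (visual motor response): 10 min lights-off (unrecorded), then
  8 min lights-on and 8 min lights-off recorded continuously at 20 fps.
* **LF** (light flash): 15 white-light flashes of 500 ms at 30 s ISI;
  500 ms recorded post-stimulus at 500 fps.
* **DF** (dark flash): 5 min lights-on adaptation, then five blocks of 14
  one-second dark flashes (30 s ISI in block 1, 10 s thereafter); blocks
  1, 3 and 5 recorded for 1 s post-stimulus at 500 fps.
* **ASR** (acoustic startle): 10 low- and 10 medium-intensity stimuli at
  20 s ISI; ten repetitions of the prepulse pattern PPI1–PPI2–PPI3–PPI4–High
  at 20 s ISI (prepulse intensity low/medium crossed with 50/300 ms lead;
  "High" has no prepulse); then a habituation train of 30 high-intensity
  stimuli at 1 s ISI. 200 ms recorded post-stimulus at 500 fps.

Three conventions are worth stating because the source description leaves
them open. ISIs are interpreted onset-to-onset, the standard in the startle
literature, which also makes the 1 s-ISI train well defined. Unrecorded
segments are kept in the timeline with `recorded = FALSE` rather than
omitted, so stimulus indices used in habituation bookkeeping are
unambiguous. Acoustic intensities are modeled as ordinal levels (low,
medium, high) because physical intensities are not part of the paradigm
description; the sensitivity index is therefore reported in arbitrary
units.

# Tracking

`segment_frame()` background-subtracts, Gaussian-blurs and thresholds each
frame, then takes the intensity-weighted center of the largest connected
component as the centroid (ties broken deterministically by raster order).
Blur sigma (1.2 px) and threshold (20 intensity units) are configuration
parameters tuned on the package's rendered fixtures; real rigs will need
their own values. `fit_tail_points()` walks five points caudally from the
centroid at a fixed arc step (6.5 px, about 1/5 of a tail at the default
10 px/mm scale), each point being the intensity-weighted mean of mask
pixels in an annulus ahead of the previous step. Orientation is the angle
of the vector from the first body point to the centroid; curvature is the
sum of unsigned angles between successive body segments (centroid plus the
five tail points). Unsigned angles are used because all classification
rules are one-sided magnitude thresholds; the bend direction only affects
the sign of orientation change, which is reported as a magnitude.

Frames with no supra-threshold pixels are recorded as gaps rather than
errors; a response window with more than 20% missing frames (configurable)
is excluded from event extraction, since no dropout policy is printed in
the source description.

# Kinematics

A swim bout starts at the first of at least two consecutive frames whose
centroid displacement exceeds 0.7 px and ends at the frame preceding the
first of two consecutive frames at or below that threshold; single-frame
excursions in either direction do not change state. Centroid movement is
accumulated only within bouts. The same criterion, applied at the block
frame rate, defines movement onset inside a response window — the only
movement definition the assay needs.

Classification uses strict inequalities exactly as published, so equality
at a boundary falls to the lower class:

| assay | rule |
|---|---|
| DF | `too_early` if latency ≤ 15 ms; `obend` if peak curvature > 1.75 rad; `react` if > 0.5 rad |
| LF | `too_early` if latency ≤ 15 ms; `react` if > 0.5 rad (no O-bend class) |
| ASR | `slc` if > 0.8 rad and latency < 20 ms; `llc` if > 0.8 rad otherwise; `react` if 0.5–0.8 rad |

An ASR latency of exactly 20 ms (possible at 500 fps) is an LLC because
the SLC rule demands strictly less than 20 ms. The too-early gate is
published only for the visual assays; a configuration flag
(`kinematic_thresholds(asr_too_early = TRUE)`) extends it to acoustic
responses for users who want symmetric gating.

# Metrics

The registry holds 94 metrics: 60 VMR (10 base metrics across six bins —
first minute, last minute and full span of each lit and dark phase), 9 LF
event summaries, 11 DF (summaries plus O-bend frequency and habituation)
and 14 ASR (summaries plus SLC/LLC frequency, sensitivity index, PPI and
habituation). Decisions taken where the metric definitions leave room:

* **Habituation and PPI** are computed as `1 - late/early`, the standard
  definition under which complete suppression gives exactly 1. The
  published formula text reads literally as `(1 - late)/early`, which does
  not have that property when the baseline is below 1; we treat that as a
  typesetting ambiguity but expose `habituation_mode = "literal"` to
  reproduce it verbatim.
* **DF habituation** compares the first and last *recorded* 14-flash
  blocks (blocks 1 and 5); unrecorded blocks cannot contribute events.
* The nine **ASR summaries** are computed over the ten high-intensity
  20 s-ISI stimuli (the no-prepulse pulses of the PPI pattern), matching
  the baseline-versus-train structure of the habituation formula.
* Feature averages (latency, bend, angular velocity, ...) are taken over
  all events passing the movement and latency gates, not only classified
  responders.
* The **outer rim** of the well is radial distance beyond 2/3 of the well
  radius (configurable); no boundary is printed.
* The **sensitivity index** integrates SLC frequency over ordinal
  intensities 1, 2, 3 by the trapezoidal rule.
* Missing values (e.g. mean latency with zero responses, habituation with
  a zero baseline) propagate as missing — never zero-filled — into the
  screen, where deletion is pairwise per metric.

# Screening statistics

For each line: per-metric two-tailed pooled-variance (Student's) t tests
of homozygous mutants against siblings in each of two independent
experiments; metrics with p < 0.05 in both are *reproducible*. Values are
then normalized within experiment by the mean sibling value (so the
normalized sibling mean is exactly 1 per experiment), pooled, and
re-tested with a Bonferroni threshold of 0.05/94 — the divisor stays 94
even when metrics are missing for a line. A metric is *called* when it is
reproducible and survives the pooled correction. "Sibling" defaults to all
non-homozygous-mutant larvae (wild types plus heterozygotes); for lines
with gross homozygous morphology the contrast can be switched to
heterozygotes versus wild types. Lines assayed once use a flagged
single-experiment path that skips the reproducibility filter.

Heatmap cells are the pooled normalized mutant mean minus sibling mean in
units of the pooled sibling SD (negative = lower in the mutant), masked by
the called flag. Computing SD differences on pooled normalized data (rather
than raw first-experiment data) matches the pooling narrative; this is an
interpretive choice. One-way ANOVA (`multi_group_anova()`) serves the
single-figure and double-mutant contrasts; with two groups its F equals
the squared pooled t, which the tests assert.

# The synthetic cohort model

The simulator is the package's test bed: it draws cohorts (default 50
larvae, Mendelian 1:2:1 from a heterozygote incross) with per-genotype
parameters, and every latent it draws is retained as ground truth.

* Per-stimulus responses are Bernoulli with probability
  `p · (1 - h)^(k - 1)` within a habituating train (the 30-stimulus 1 s-ISI
  acoustic train; within each dark-flash block, resetting between blocks)
  and `p · (1 - ppi_strength)` when a prepulse leads the pulse. Geometric
  decay is chosen for closed-form checks; the habituation metric only
  requires monotone decay.
* Acoustic responses are SLC-like with probability `slc_fraction`, else
  LLC-like. Latency and peak curvature are clamped normal draws whose
  defaults keep SLC latencies below 20 ms and LLC above, so latency-based
  classification recovers the latent class with accuracy above 0.99.
* The curvature time course of a response is a raised-cosine pulse peaking
  at the drawn amplitude — smooth, peak-parameterized and integrable.
  Centroid motion during a response uses a constant-speed two-leg path
  whose path length and chord reproduce the drawn distance and net
  displacement; constant speed makes movement-onset latency recoverable to
  within one or two frames, which a raised-cosine speed profile would not.
* Spontaneous VMR bouts are a Poisson process per lit/dark phase thinned
  by a refractory rule (a bout cannot start before the previous one ends
  plus two frames); the closed-form expectation used in parameter recovery
  is the renewal-thinned rate `r/(1 + r·τ)`. Well positions follow a
  per-bout random walk with radial reflection at the 9 mm wall; the
  position process is deliberately decoupled from the bout kinematic
  latents, so trajectory-extracted bout distances are not forced to equal
  the latent draws (as with real tracking, the trajectory is what the
  kinematics path measures).
* Responses preempt spontaneous bouts by construction: response windows
  and the VMR block do not overlap, keeping ground truth unambiguous.
* Pixel scale is fixed at 10 px/mm; all thresholds are in pixels, so the
  scale matters only for well geometry and rendering.

Two output modes share this generative model. `"events"` materializes the
latent records directly and is fast enough for repeated whole-screen
simulation; `"kinematic"` integrates the same latents into per-frame
trajectories (20 fps VMR, 500 fps response windows) that the extraction
path re-analyzes. Tests assert that both modes agree on labels and
frequencies.

`render_frames()` draws a larva as a bright head blob, a short straight
rostral section and a tapered tail along a uniform-curvature polyline
whose vertices are the ground-truth tail points, translated so the body's
intensity center of mass lands on the pose centroid — the quantity a
centroid tracker estimates. Renderer brightness and geometry defaults were
chosen so the default tracker settings resolve the body; they are fixture
parameters, not claims about any particular camera.

## What the simulator does and does not emulate

It reproduces the statistical structure the metrics and the screen assume:
genotype-dependent response probabilities, habituation and prepulse
modulation, latency/curvature class separation, Poisson-like spontaneous
locomotion, and binomial sampling noise at the published stimulus counts.
It does not emulate biophysically realistic swimming, multi-larva
occlusion, tracking artifacts of real video (reflections, meniscus
shadows), circadian drift, or between-larva parameter heterogeneity beyond
genotype. Passing tests therefore demonstrate that the analysis recovers
the parameters of data generated under its own assumptions — a necessary
check of the code and formulas, not evidence about any real mutant line.

# Validation conditions and problem sizes

The test suite validates, at the study's scale: bout detection against a
brute-force oracle on 10,000 random series; the classification decision
table on a dense curvature-latency grid; recovery of habituation 0.5 and
PPI 0.6 within ±0.05 of their closed-form expectations from 200 simulated
larvae; family-wise false-positive calibration of the full two-experiment
screen over 200 null screens of 50 larvae, with a planted three-sibling-SD
effect on one metric detected and masked on the heatmap; and tracker
centroid error below 1 px with curvature error below 0.2 rad on rendered,
noise-free larvae. The planted effect size is derived in closed form from
the binomial SD of the O-bend frequency over 42 recorded flashes, not
fitted to the data. A small per-larva ratio bias (about 0.03–0.04) is
expected in the PPI estimate because each larva's PPI is a ratio of
frequencies estimated from ten stimuli each; it sits well inside the
validation band and vanishes as stimulus counts grow.

# Known limitations

* Tail-point fitting assumes a single larva per well ROI and bends up to
  roughly 2.5 rad; tighter curls can defeat the annulus walk and are
  reported as degenerate postures (gaps), not errors.
* The tracker's blur, threshold and step parameters must be retuned for
  imaging conditions other than the rendered fixtures.
* DF habituation in the simulator resets between blocks, so the
  first-versus-last-block metric centers on zero unless a cross-block
  decay is configured through per-genotype parameters.
* The screen implements exactly the published procedure (Student's t,
  Bonferroni 94, two-experiment reproducibility); FDR-based alternatives
  and mixed-effects models are out of scope.
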