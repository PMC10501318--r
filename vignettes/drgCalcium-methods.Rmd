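---
title: "Methods: responder analysis for sacral DRG calcium imaging"
author: "drgCalcium authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: responder analysis for sacral DRG calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgCalcium)
```

# The experimental design the package models

A sacral dorsal root ganglion expressing GCaMP6f is imaged in seven
consecutive 40-s episodes sampled at 5 Hz (200 frames per episode). Each
episode opens with an 8-s (40-frame) pre-stimulus baseline, after which one
mechanical stimulus is applied: an air puff, a gentle brush or a pinch on
the perineal skin (the *external* site), or a soft brush inserted into /
extracted from the colon, or a colonic balloon inserted / inflated (the
*internal* site). Recording pauses between episodes while the next stimulus
is prepared; analyses therefore treat episode boundaries as markers, never
as recorded frames. `generateSchedule()` encodes these constants and
nothing downstream hard-codes them.

The timing of stimulus onset *within* an episode is not fixed by the
acquisition protocol beyond the existence of the 8-s baseline. The package
adopts onset at the first post-baseline frame (frame 41 of 200) as a
convention, and the response window runs from onset to the episode's last
frame — the most permissive window consistent with "a response follows the
stimulus". Both are schedule fields, not constants, so other conventions
are a config edit away.

# Trace extraction and annulus correction

A cell's raw trace is the mean intensity over its ROI footprint per frame.
Contamination from out-of-focus tissue and neighbours is removed by
subtracting the mean over a donut-shaped annulus surrounding the ROI:

* annulus of cell *k* = pixels whose Euclidean distance *d* to the
  footprint satisfies `gap < d <= gap + width`, **minus every labeled
  pixel of any cell**, so a neighbouring soma can never leak into a
  background estimate;
* defaults `gap = 1` px, `width = 3` px on the default 4-px-radius
  footprints — wide enough to average ~60 pixels of neuropil, narrow
  enough to stay local. No published annulus geometry exists for this
  preparation, so both are exposed parameters;
* subtraction is direct (scale 1.0). The correction is exact for any
  spatially uniform additive background; that exactness is a tested
  invariant (to 1e-9) rather than an approximation claim.

The distance-threshold construction was chosen over binary morphological
dilation because it is isotropic at small radii and makes the geometry
independently checkable by a brute-force per-pixel loop, which the test
suite does on small stacks.

Correction precedes ΔF/F. The alternative order (ΔF/F first, then
subtract a neuropil ΔF/F) is not equivalent; correcting fluorescence first
keeps `F0` a physically meaningful cell fluorescence and makes the
uniform-background cancellation exact.

# Percent ΔF/F

Within each episode, `ΔF/F(t) = 100 · (F(t) − F0) / F0`, where `F0` is the
mean corrected fluorescence over that episode's baseline frames,
re-estimated per episode. Per-episode baselines are the only reading
consistent with concatenating episodes recorded minutes apart with
independent focus and bleaching states. A cell-episode with `F0 <= 0`
cannot be normalized; it is set to `NA`, recorded in
`metadata(dff)$unusable` and reported with a warning — never silently
zeroed. The per-episode baseline means are kept in
`metadata(dff)$baselineF0` because the persistence rule (below) needs
them.

# Responder calls, exclusions, categories

**Threshold.** A cell responds to an episode when its peak ΔF/F over the
response window strictly exceeds θ = 5 % (`peak > 5`, not `>=`). The
strictness matters only on a set of measure zero, but it is pinned down and
tested so that the boundary case is deterministic.

**Exclusions**, applied before categorisation, with the fixed precedence
overlap → spontaneous → persistent:

* *Overlapping ROIs* — footprints sharing any pixel, known from the ROI
  construction record (a flat label image cannot represent overlap, so the
  record travels in the `RoiSet`).
* *Spontaneous* — ΔF/F above θ for at least 3 consecutive baseline frames
  (0.6 s at 5 Hz) in any episode up to and including the cell's first
  responding episode. "Rare cells with spontaneous activity" is otherwise
  unquantified; 3 frames rejects single-frame noise spikes while catching
  any genuine transient, whose decay lasts several frames at these
  kinetics. Restricting the scan to episodes up to the first response
  prevents a persistently active cell's elevated later baselines from
  being double-counted as spontaneous activity.
* *Persistent* — after the first responding episode, activity above θ in
  at least 80 % of all remaining frames of the session. Because ΔF/F is
  re-baselined per episode, a sustained plateau would be invisible in
  later episodes' own ΔF/F; the rule therefore re-references later frames
  to the baseline of the first responding episode (reconstructing `F` from
  the stored `baselineF0`). When that metadata is absent — e.g. traces
  imported from a bare CSV — the per-episode values are used as-is, which
  can only under-flag.

**Categories.** Cells responding to at least one internal and one external
episode are excluded as mixed responders (stimulation at the anal margin
can mechanically co-activate both territories, so such cells are
uninterpretable). Remaining responders: *Internal* if all responding
episodes are colonic; *External gentle* if any puff or skin-brush
response, a pinch response in addition notwithstanding; *External noxious*
when pinch is the only external response. The gentle-over-noxious
precedence is the category definition, not an inference. Everything else
is a non-responder. The eight categories partition the ROI set — a tested
invariant.

**Proportions and comparison.** Included responders are pooled as 100 %;
excluded cells and non-responders enter neither numerator nor denominator.
Groups are compared with a Pearson chi-square test on the 2 × 3 count
table, no continuity correction, giving 2 degrees of freedom; a category
empty in both groups is dropped with a warning and the dof reduced. The
implementation calls `stats::chisq.test(correct = FALSE)`; the test suite
checks it against a direct Σ(O−E)²/E computation on random small tables.

# Activity maps and heatmap layout

`sdMap()` computes, per pixel, the population standard deviation
(ddof = 0; no estimator is implied by the visualisation purpose) over all
frames of all episodes of one site, pooled. Pooling across a site's
episodes is the default because the map answers "which pixels moved during
this class of stimuli"; single-episode maps are available through
`episodesUsed`.

The heatmap layout replaces what is inherently a manual sorting with a
deterministic rule: category blocks in the order internal → external
gentle → external noxious, rows within a block in descending session-peak
ΔF/F, ties broken by ascending cell id. Excluded cells and non-responders
are omitted. Episode boundaries are carried as gap markers and drawn as
white lines.

# The synthetic session generator

The generator exists so that every stage can be tested against planted
ground truth. It emulates:

* disk footprints (default radius 4 px on a 256 × 256 field; tests use
  smaller fields, 32–96 px, since every property checked is independent of
  field size) placed without unplanted overlap, plus an optional planted
  overlapping pair to exercise that exclusion;
* seven planted response classes mirroring the downstream categories and
  exclusion cases (internal-only, external-gentle, pinch-only, both-site,
  silent, spontaneous, persistent);
* GCaMP6f-like transients: instantaneous rise at stimulus onset,
  exponential decay with τ = 1 s by default. The kernel peaks at exactly 1
  so the planted amplitude (default 20 % ΔF/F) is realised exactly — the
  pipeline recovers it to 1e-6 relative tolerance in the noise-free tests.
  Spontaneous cells fire within the first episode's baseline; persistent
  cells jump at their first response and stay elevated to the final frame;
* a spatially uniform additive background (default level 100) with
  sinusoidal drift (default amplitude 10, period 60 s). Uniformity is
  deliberate: it makes annulus correction exactly invertible, turning
  "correction works" into a machine-precision test. An optional Gaussian
  halo (`haloSigma`) blurs each cell's weight image to emulate local
  contamination instead;
* i.i.d. Gaussian sensor noise (default sd 2), added last and clipped at
  zero.

It does **not** emulate motion (inputs are assumed registered, as
registration is a separate preprocessing step), photobleaching, Poisson
photon statistics, vascular artifacts or optics. Passing tests therefore
demonstrate correctness of the analysis logic under the stated signal
model, not robustness to every artifact of real recordings — which is
exactly what a desk-scale harness can honestly claim.

Default cell counts (24 per session, most of them responders) sit inside
the tens-of-neurons-per-ganglion range typical of this preparation.
Quantification fixtures (`generateQuantFixtures()`) plant their ratios at
generation time — stomach signal shares, stool water fractions, exact
nerve-pixel counts — so each ratio function can be checked to 1e-9 against
stored truth.

# Numerical and interface choices

* Frames and pixels are 1-based, following R convention; the response
  window is the inclusive frame range onset…episode-end. All containers
  are S4 (`TraceMatrix` extends `SummarizedExperiment`), with accessors
  rather than slot access.
* TIFF output uses 32-bit pages normalized to the stack maximum with a
  JSON sidecar carrying the scale and acquisition metadata (label images
  use exact 16-bit storage), because float TIFF storage outside [0, 1] is
  not portable through the available writer.
* Tolerances in tests: 1e-9 where a computation is algebraically exact
  (annulus cancellation, brute-force oracle agreement), 1e-6 relative for
  amplitude recovery through the whole pipeline, exact equality for
  protocol constants and determinism (MD5-identical report bundles).
* Degenerate inputs error early and name the offending entities: empty
  footprints, empty annuli (with the remediation hint to widen the
  annulus), `F0 <= 0` cell-episodes, empty responder denominators,
  zero-total gut signals, dry > wet stool weights.
* `runPipeline()` seeds cell placement and the renderer separately from
  one master seed, writes no timestamps, and records MD5 checksums in its
  manifest, so a bundle is reproducible bit-for-bit from its own
  `config.yaml`.

A note on the group-comparison statistic: for a 2 × 3 contingency table
the chi-square degrees of freedom are 2 by construction; the package
always reports the dof actually used by the test, alongside the statistic
and p-value.

# Known limitations

* The annulus estimate assumes contamination is additive and locally
  uniform at the annulus scale; strong spatial gradients across a soma are
  not corrected (the halo option exists to study this failure mode).
* Exclusion thresholds (3 consecutive frames; 80 % of subsequent frames)
  quantify qualitative criteria; both are parameters, and sessions near
  those boundaries should be inspected rather than trusted blindly.
* ROI segmentation and movie registration are out of scope: ROIs are
  inputs, movies are assumed registered.
* The chi-square comparison is the pipeline's terminal statistic; no
  per-animal random effects are modelled, matching the pooled-cell design
  it serves.
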