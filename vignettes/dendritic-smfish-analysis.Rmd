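---
title: "Spatial statistics for dendritic mRNA imaging: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial statistics for dendritic mRNA imaging: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrofish)
```

## The analysis problem

Single-molecule FISH detects individual mRNAs in cultured neurons as
diffraction-limited spots; combined immunofluorescence marks dendritic
spines (PSD95 centroids) or nascent peptides at translating mRNAs
(SunTag-type reporters). Spot-detection software exports, per channel and
cell, a table of x/y/z coordinates and integrated intensities. dendrofish
starts from those tables and asks the downstream questions: where along
the neuron is each mRNA, is its association with spines or with a second
mRNA species more than chance, is it being translated and by how many
ribosomes, and how aggregated is a co-expressed folding reporter.

The central difficulty is that dendritic mRNA density is strongly
distance-dependent: most transcripts sit in the proximal dendrite. Any
colocalization statistic compared against a fully uniform null would
"detect" enrichment that is nothing but this density gradient. The
package's null model therefore preserves the observed density profile at
25 µm resolution.

## Geometry and binning

A neuron is a closed soma polygon plus dendrite branches, each a skeleton
polyline ordered from the soma outward with a half-width. All internal
computation is in nm; masks are rasterized at the image pixel size
(default 107.5 nm). A spot is somatic if it falls inside the soma
polygon, dendritic if it lies within half-width of a branch skeleton
(nearest branch wins; exact ties go to the lower branch index), otherwise
"outside" — excluded from statistics and counted for QC, since
mis-assignment in dense cultures is a real failure mode.

Distance from the soma is the *path* distance: the arc length along the
skeleton from the soma attachment to the spot's orthogonal projection.
For transported mRNAs the along-dendrite travel distance is the
meaningful coordinate; on straight branches it coincides with Euclidean
distance to within one pixel (a tested invariant). Dendrites are divided
into half-open 25 µm bins, `bin k = [25k, 25(k+1))` µm, so bin 0 is the
first 25 µm of shaft. Per-branch bin masks partition the branch mask
exactly; pixels at the rounded distal cap project to exactly the branch
length and open one extra one-pixel-deep bin, which is kept with its true
(small) mask area rather than length-normalized away.

Compartment assignment takes an optional membership `slack`: spine
centers derived from PSD95 sit at or just beyond the shaft edge, so spine
channels are assigned with `slack = spine_radius` (600 nm) while mRNA
channels use strict membership.

## The count-preserving Monte-Carlo null

For each repeat and each branch × bin cell, the model draws as many mask
pixels (uniformly, without replacement within the repeat) as real mRNAs
were observed there, adds uniform sub-pixel jitter, and recomputes the
statistic; 100 repeats are averaged by default. Every repeat reproduces
the observed per-bin counts exactly, so the simulated concentration
profile along the dendrite matches the real one and only the *within-bin*
arrangement is randomized. Spine positions (or a fixed reference channel)
are never moved.

Two details matter numerically:

* **Sub-pixel jitter.** Drawing bare pixel centers quantizes pairwise
  distances at 107.5 nm, which distorts sharp-radius statistics; the
  jitter removes the artifact at no cost.
* **Simulated z.** The pixel draw is 2D, but observed distances are 3D.
  Giving every simulated spot the bin's median observed z makes simulated
  pairs systematically *closer* in z than real slab-distributed pairs and
  inflates null proximity — we measured this directly during development.
  The default therefore resamples (bootstraps) the observed z values of
  the same branch × bin, which preserves the z marginal and keeps the
  observed-vs-null comparison calibrated; `z_mode = "median"` and a pure
  2D `z_mode = "zero"` remain available.

Observed-vs-null comparison follows the figure-legend convention of the
field: a two-sided Welch unequal-variance t-test of observed per-unit
values (units are dendrites or neurons) against per-repeat simulated
values, plus the empirical rank of the observed mean within the ensemble.
Identical constant groups are defined to give t = 0, p = 1.

Calibration and power were verified in the test suite: across 200
synthetic neurons with uniform placement the per-bin rejection rate at
α = 0.05 falls inside the 95% binomial interval around 0.05, and a 3×
spine-proximal enrichment (six 25 µm dendrites, 0.5 spines/µm, 60
mRNAs/dendrite) is detected at p < 0.05 in ≥ 80 of 100 runs. Those
problem sizes were chosen to give the calibration estimate ≥ 300 tests
and the power experiment ~12 spines per dendrite — enough spine-level
averaging for a branch-level Welch test with n = 6 to be meaningful.

## Proximity, coexistence and their conventions

* "Within r" is closed (≤ r) everywhere: at 600 nm a spot at exactly
  600 nm counts. For continuous positions the convention is
  measure-zero, but it must be fixed once.
* Spine occupancy anchors on spines: each spine's bin is its own
  path-distance bin and each spine is evaluated independently, so one
  mRNA may count toward two nearby spines. Reported per bin: the
  frequencies of spines with 0, 1, and ≥ 2 mRNAs within 600 nm (they sum
  to 1 per bin).
* Coexistence anchors on the reference channel: per reference mRNA the
  3D nearest-partner distance, coexisting iff ≤ 700 nm (the neuronal
  granule diameter scale), with per-bin fractions and mean
  nearest-neighbor distances; the null simulates the partner channel
  while the reference stays fixed.
* Observed pairwise distances are 3D (spots carry z); whether the
  original analyses were 2D or 3D is not determinable from published
  descriptions, and 3D is the stricter choice given that both channels
  are detected in 3D.

## Translation calling

The unit single-peptide intensity is the median intensity of *free*
peptide spots — those farther than the pairing threshold from any mRNA,
i.e. mature proteins that diffused away; the median resists bright
aggregates. Each peptide is provisionally assigned to its nearest mRNA
and kept iff the 3D distance is ≤ 200 nm plus the magnitude of the
residual chromatic registration error (the mean inter-channel offset is
subtracted first; both are measured with multi-fluorophore beads in
practice, so the configuration carries an offset vector and a scalar
residual). Per mRNA, surviving candidates are deduplicated
brightest-first, ties by distance, then by id for determinism — the
published rule is garbled in its source ("the brightest … and then the
closest"), and brightest-then-closest is our reading of it. Ribosome
loads are intensity/unit rounded to the nearest integer with a floor of
1: a kept colocalized signal implies at least one nascent chain. The
pairing equals exhaustive enumeration on all instances with ≤ 8 + 8
spots (1000 random instances tested) and is exactly invariant to a
chromatic offset that is declared to the caller.

Somatic translation percentages are computed but should be interpreted
cautiously: dense somatic signal degrades single-molecule pairing, which
is why per-dendrite scope exists.

## Transcription sites and localization summaries

The unit single-mRNA intensity is the median of candidate single spots
(robust to transcription-site contamination). A spot is a transcription
site if it exceeds 1.5× the unit and lies in the nucleus polygon when
one is supplied; without a nucleus mask no spatial restriction is
applied. Nascent transcript counts are intensity/unit rounded, floored
at 2 — by definition a transcription site exceeds a single mRNA. The
1.5× factor and the median are implementation choices; published
figures show transcription sites only as bright nuclear spots and state
no formula.

The dendrite-to-soma ratio is computed on per-pixel densities, not raw
counts, so unequal compartment sizes cannot masquerade as localization;
fold enrichments between conditions likewise use densities.

## Granularity readout

For a folding-reporter (FLUC-GFP type) channel the proteostasis readout
is the coefficient of variation — sample SD over mean of ROI pixel
intensities on the maximum projection. It is 0 for a diffuse reporter,
√2 for all intensity in half the pixels, and invariant to intensity
scaling. Aggregates are segmented as 8-connected components above
mean + 2·SD of the ROI; the threshold is ROI-relative, so additive
background does not change the segmentation. The thresholding rule is
this package's choice (no published rule exists for the aggregate-size
figures), so absolute aggregate sizes are comparable only within
analyses using the same rule.

## The synthetic-data generator

The generator exists so that every stage can be validated against known
ground truth without microscopy data. Its defaults emulate the imaging
regime the pipeline targets: four 150 µm dendrites (1 µm half-width) on
a 10 µm soma, ~100 dendritic mRNAs per dendrite for an abundant species
and ~5 for a rare partner (the observed abundance span of dendritic HSP
chaperone mRNAs), spine density 1 µm⁻¹, 107.5 nm pixels, 30 nm
localization error per axis, spots in a 0–800 nm z slab, 10% intensity
noise, two nuclear transcription sites, and 30% of mRNAs translating
with geometric ribosome loads (mean 3, truncated at 30 — a generator
convenience, not a biological claim). Dendritic density decays
exponentially with path distance (τ = 60 µm) to mimic
proximally-weighted distributions; `decay_tau_um = Inf` gives uniform
placement for calibration experiments. Enrichment dials plant extra
density within 600 nm of spines (ρ) or a fraction κ of partner spots
within 700 nm of reference spots.

What it does **not** emulate: point-spread-function blur and detection
failures (spots are given, as in the real pipeline, which starts after
detection), crossing or branching dendrites, spine morphology, axons,
within-cell intensity gradients, and z-dependent aberrations beyond a
fixed offset. Passing tests therefore validate the statistics given
correct spot tables; they say nothing about detection quality upstream.

## Numerical and reproducibility choices

* One root seed; per-stage streams are derived with a fixed linear rule,
  so the order in which neurons or channels are processed cannot change
  results. Identical seeds give byte-identical outputs for every CLI
  subcommand (tested via file hashes).
* Without-replacement pixel draws fail loudly if a bin holds more
  observed spots than pixels rather than silently double-placing.
* Degenerate inputs are defined, not crashed on: empty partner channels
  flag distances as undefined; zero-area compartments flag densities;
  zero-mean ROIs flag the CV; constant Welch groups give t = 0, p = 1.
* Results CSVs store reals at 15 significant digits so integer counts
  round-trip exactly and reals to numerical precision; the JSON manifest
  records configuration, seed and package version, and contains no
  timestamps (outputs must be byte-reproducible).

## Known limitations

Branch masks near the soma can overlap for closely spaced dendrites; the
lowest-index tie-break is deterministic but arbitrary. Path distance for
spots near a branch's attachment saturates at 0 rather than going
negative. The Welch comparison treats dendrites as independent units,
pooling dendrites within and across neurons as the field's figure
legends do; a nested random-effects model is out of scope. The
granularity module quantifies single ROIs and performs no soma-level
aggregation.
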