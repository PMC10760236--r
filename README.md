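# dendrofish

Spatial statistics for single-molecule RNA imaging in neurons.

Single-molecule FISH (smFISH) resolves individual mRNAs in cultured
neurons as diffraction-limited spots; paired immunofluorescence marks
dendritic spines (PSD95) or nascent peptides at translating mRNAs
(SunTag-type reporters). Spot-detection tools such as FISH-quant export
per-channel tables of spot coordinates and integrated intensities —
dendrofish is the post-detection layer that turns those tables into
biology: where each mRNA sits along the neuron, whether its association
with spines or with a second mRNA species exceeds chance, whether it is
being translated and by how many ribosomes, and how aggregated a
co-expressed folding reporter is. It is written for labs quantifying
dendritic mRNA transport, local translation, and proteostasis.

## What it computes

**Compartments and bins.** Spots are assigned to soma, dendrite or
outside on a polygon/skeleton model of the neuron. Dendritic spots get
the *path distance* $d$ along the branch skeleton from the soma and a bin
index $k = \lfloor d / 25\,\mu m \rfloor$. Summaries report per-compartment
counts, per-pixel densities, and the localization readout
$\rho = (N_{dend}/A_{dend}) / (N_{soma}/A_{soma})$.

**Count-preserving Monte-Carlo null.** The key statistic engine: for each
of 100 repeats and each branch × bin, draw as many mask pixels (uniform,
without replacement) as mRNAs were observed there. Every repeat
reproduces the observed per-bin counts exactly, so the null keeps the
real proximal-to-distal density profile and randomizes only the
within-bin arrangement. Spine positions or a fixed reference channel are
never moved. Observed and simulated statistics are compared per bin with
Welch's unequal-variance *t*-test plus the empirical rank in the
ensemble.

**Spine proximity.** Per spine, the number of mRNAs within 600 nm of the
PSD95 center (closed boundary, 3D); per bin, the frequencies of spines
with 0 / 1 / ≥ 2 mRNAs, against the null.

**Coexistence.** Per reference mRNA, the 3D nearest-neighbor distance to
a partner species; coexisting iff ≤ 700 nm (the neuronal-granule scale);
per-bin fractions and mean shortest distances against a null that
simulates the partner channel only.

**Translation calling.** Unit peptide intensity = median of free peptide
spots; each peptide pairs to its nearest mRNA iff within 200 nm plus the
residual chromatic aberration (after mean-offset correction); per-mRNA
dedupe keeps the brightest, then the closest peptide. Ribosome load =
intensity/unit rounded (min 1); percent translating = 100 ×
translating/total per cell or dendrite.

**Granularity.** Proteostasis readout of a folding reporter: CV = SD/mean
of ROI pixels on the max projection, plus aggregate sizes as 8-connected
components above mean + 2·SD.

**Synthetic data.** A first-class generator emits neurons, spines and
multi-channel spot tables with ground truth (density decay, spine and
coexistence enrichment dials, ribosome loads, chromatic offset), so every
stage is testable without microscopy data.

## Worked example

```r
library(dendrofish)

cfg <- synthetic_config(spine_enrichment = 1)   # paper-like neuron, no planted enrichment
ds  <- simulate_dataset(cfg, seed = 42)
geom <- ds$neuron$geometry

mrna   <- assign_spots(ds$mrna$spots, geom)
spines <- assign_spots(ds$neuron$spines, geom, slack = 600)
summarize_localization(mrna, geom)
#> Localization summary
#>   soma: 144 spots / 27160 px (density 0.005302)
#>   dendrite: 384 spots / 101016 px (density 0.003801)
#>   dendrite/soma density ratio: 0.717
#>   outside (QC): 2
#>   per-bin counts: 132 111 48 37 34 22
```

Four 150 µm dendrites hold ~100 mRNAs each, concentrated proximally
(bins are 25 µm); the density ratio says dendrites are ~0.7× as crowded
per pixel as the soma.

```r
occ <- spine_occupancy(mrna, spines, radius = 600)
occ
#> Spine occupancy within 600 nm (639 spines, 0 dropped as non-dendritic)
#>  bin n_spines     freq0      freq1  freq2plus
#>    0       99 0.7878788 0.19191919 0.02020202
#>    1      110 0.8363636 0.13636364 0.02727273
#>    2      105 0.8761905 0.12380952 0.00000000
#>    3       98 0.9387755 0.06122449 0.00000000
#>    4      109 0.9174312 0.08256881 0.00000000
#>    5      118 0.9406780 0.05932203 0.00000000

ens <- simulate_null(mrna, geom,
                     stat_spine_frequency(spines, 600, bins = 0:2),
                     n_sim = 100, seed = 43)
ens
#> Monte-Carlo null ensemble: 100 repeats, seed 43
#>   statistic mean (sd) per bin:
#>     bin0: 0.2181 (0.04166)
#>     bin1: 0.1962 (0.04515)
#>     bin2: 0.08467 (0.03197)
```

~21% of proximal-bin spines hold at least one mRNA; the null (same
per-bin counts, random within-bin positions) gives 21.8 ± 4.2% — as
expected with no planted enrichment, chance explains the contiguity.
With data across several dendrites, `compare_to_null()` runs the per-bin
Welch test.

```r
unit  <- estimate_unit_intensity(ds$peptide$spots, ds$mrna$spots, 200, min_free = 10)
calls <- assign_peptides(ds$mrna$spots, ds$peptide$spots, unit = unit)
calls
#> Translation calls: 163/530 mRNAs translating (threshold 200 nm)
#>   nascent peptide counts:
#>  1  2  3  4  5  6  7  8  9 10 11 12 13 14 17 18
#> 42 40 20 18 13  8  5  2  6  2  2  1  1  1  1  1
percent_translating(calls)
#> [1] 30.75472
```

The generator's ground truth was 30% translating with geometric ribosome
loads of mean 3; the pipeline recovers 30.8% and the monosome-heavy load
histogram.

A command-line front end wraps the same functions
(`inst/cli/dendrofish.R`, subcommands `simulate`, `assign`, `localize`,
`proximity`, `coexist`, `translate`, `granularity`; all outputs are plain
text and byte-reproducible under a fixed `--seed`).

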