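---
title: "Methods: image-based steatosis screening analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based steatosis screening analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steatoscreen)
```

## The assay being modeled

`steatoscreen` implements the analysis chain of a phenotypic high-content
screen for inhibitors of ER-stress-induced lipid accumulation in
hepatocyte-like cells. The biological readout is simple: cells challenged
with free fatty acids plus an ER-stress inducer accumulate neutral-lipid
droplets, visible as bright cytoplasmic spots in a lipophilic-dye channel,
while a nuclear stain provides the cell count. A compound that lowers the
per-cell **integrated spot signal (ISS)** without depressing the valid
cell count is a candidate anti-steatotic.

The chain has six computational stages, each a package module:

1. **Synthetic data** — seeded generators for fields, plates, dose
   series, compound sets and Cq tables, all with ground truth attached.
2. **Imaging** — nucleus detection, validity filtering, cytoplasm ring
   construction, spot detection, per-cell and per-well aggregation.
3. **Plate statistics** — Z′, robust Z′, signal-to-background, %CV,
   percent inhibition, hit/cytotoxicity calls.
4. **Dose-response** — 4PL fitting, IC50/pIC50, potency/selectivity
   triage.
5. **Chemical profiling** — Tanimoto distances, Ward linkage, flat cuts,
   pXC50 target profiles.
6. **Expression** — ΔΔCq relative quantification, DEG filtering, 3-set
   Venn arithmetic.

Because the original screening images and compound structures are not
public, every stage is validated against synthetic data whose ground
truth is known by construction. That is a deliberate design: the tests
prove the *algorithms* recover what was planted, not that the original
campaign's numbers reappear.

## The synthetic-data model

`generate_field()` renders a two-channel field. Nuclei are
Gaussian-tapered disks (profile $I\,e^{-d^2/2\sigma^2}$ with
$\sigma = r/2$, truncated at radius $r$) at dart-thrown centers with a
minimum separation; lipid droplets are small uniform disks confined to an
annulus of the configured ring width around their owner nucleus, so the
downstream cytoplasm ring captures them by construction. Droplets of one
cell are kept mutually separated and at least 1.5 px inside the outer
ring edge, so that in the noiseless limit each droplet is its own
connected spot and detection can be *exact*. Noise is optional Poisson
shot noise plus additive Gaussian read noise per channel.

Conventions: matrices are indexed 1-based as `(row, col)`, intensities
are non-negative arbitrary units, the default field is 1080×1080 px with
6 fields per well (acquisition setups for this assay family report
either six or eight fields per well; six is the default and both are
configurable).

Per-cell droplet counts are Poisson with mean
`steatosis × droplets_per_cell`; the count is drawn by inverse-CDF from a
per-cell substream, so raising the steatosis level only appends droplets
and the total planted signal is monotone in the level — a property the
tests assert.

`generate_plate()` has two modes sharing one set of generative means. A
well's effective lipid load is $s = s_0 + (1-s_0)(1-\text{inhibition})$
with $s_0 = 0.05$ the residual load of neutral-control wells (stimulator
wells sit at load 1). In *summary mode* the per-well mean ISS is the
analytic per-cell expectation (droplet rate × expected discrete rendered
droplet signal, the latter integrated over the radius distribution and
sub-pixel placement) times lognormal well-to-well noise (default CV 8%
for intensities, 6% for cell counts — typical well-level spreads for a
well-behaved 384-well cell assay, and values that reproduce Z′ ≈ 0.73 at
the defaults, inside the 0.43–0.78 band reported for assays of this
kind). *Image mode* renders every well's fields; the test suite checks
that quantified image-mode well means agree with the summary-mode means
within Monte-Carlo error. Summary mode exists so that multi-plate
campaigns simulate in seconds; image mode is for small demonstrations
and the imaging tests.

What the generator does **not** emulate: optics (PSF, chromatic
aberration), illumination gradients, well edge effects (only a hook for a
constant row/column bias exists), cell-shape heterogeneity, debris, and
out-of-focus fields. Passing tests therefore demonstrate algorithmic
correctness under idealized imaging, not robustness to every real-world
artifact.

## Imaging: how each step is computed

**Nucleus detection** (`find_nuclei`). The raster is Gaussian-smoothed
(σ = 2 px) and seeded at a robust noise floor: pixels above
`median + seed_k·MAD` of the smoothed image (`seed_k = 6`). We
deliberately use this noise-floor threshold rather than a global Otsu
split: Otsu assumes a bimodal histogram and silently loses small dim
objects (exactly the fragmented nuclei the validity filter is supposed to
see and reject), while the noise floor degrades gracefully to "above
background" on clean input, making noiseless detection exact. Touching
objects are split by a watershed on the distance transform. Each seed is
then *refined*: the object mask is regrown on the raw raster at a
per-object threshold of 10% of its background-subtracted peak. For the
tapered nuclei the 10% level lies beyond the truncation radius, so the
refined mask recovers the full object support exactly in the noiseless
case. Under noise the refined mask is regularized by a small binary
opening/closing plus hole filling (the regularization radius shrinks for
tiny objects so fragments are not erased).

**Shape features.** Perimeter uses the two-direction Cauchy–Crofton
estimate (π/4 × boundary pixel faces), which is asymptotically exact for
smooth convex boundaries — a discrete disk gets perimeter ≈ 2πr and
roundness ≈ 1. Blocky shapes are overestimated, so roundness is clamped
at 1.05; the roundness criterion is a lower bound, so the clamp is
harmless.

**Validity.** A nucleus is valid iff it satisfies every configured
interval (area, roundness, mean intensity) and, by default, does not
touch the field border (truncated cells would get truncated rings).
Screens of this kind apply size/shape/brightness criteria without
publishing numeric thresholds; the package's defaults (area 40–3000 px²,
roundness ≥ 0.5) are declared package defaults tuned to the generator's
scale, not values taken from any protocol.

**Cytoplasm rings** (`select_cell_region`). Every pixel outside all
nuclei and within `ring_width` (default 15 px) of a valid nucleus is
assigned to its *nearest* nucleus by exact Euclidean distance (per-object
distance transforms on padded crops); ties go to the lower label. The
contract is verified against a brute-force per-pixel oracle.

**Spot detection** (`find_spots`). The lipid channel is flattened by a
grayscale white top-hat (square structuring element of half-width 7 px,
larger than any droplet; implemented as separable running min/max since
the installed image library only provides binary morphology). Spot pixels
are top-hat responses above `spot_k = 6` robust noise SDs (MAD over
cytoplasm pixels) inside cytoplasm regions. The threshold is *relative*,
so scaling the channel by any c > 0 leaves the detection mask unchanged
and scales every integrated signal by exactly c. Connected components
below 2 px² are dropped; spots whose centers lie closer than 2 px
(Euclidean — the merge metric is not specified anywhere authoritative,
so center-to-center distance is the declared choice) are merged with
pixel-union semantics. Spot integrated intensity is the top-hat (i.e.
background-corrected) signal summed over the spot's pixels; in the
noiseless case this equals the planted signal exactly. Under noise the
background correction leaves a small positive bias that is largest,
in relative terms, in low-signal wells — visible in the image-level
demonstration script.

**Aggregation.** Valid-cell features are pooled across a well's fields
(cells pooled, not field means averaged), the valid cell count is the
pooled count, and wells under the configurable 600-cell target are
flagged. Zero-cell wells yield flagged `NA` averages, not errors.

## Plate statistics

Z′ is computed exactly as printed for this assay family:
$Z' = 1 - 3\,( \mathrm{SD}_s + \mathrm{SD}_n ) / |\mu_s - \mu_n|$,
with the absolute value added in the denominator (without it the sign
would depend on arbitrary group ordering). The robust variant substitutes
medians and 1.4826·MAD — "robust Z′" has no single standard definition,
so the conventional robust location/scale pair is the declared choice. %CV is 100·SD/mean per control group, and
percent inhibition is `100·(value − AVEneg)/(AVEpos − AVEneg)` with the
neutral (no lipid) control as AVEpos.

Hit calling: a compound well is **cytotoxic** if its valid cell count is
≤ 40% of the control-well average (cytotoxicity takes precedence),
a **hit** if ISS inhibition ≥ 50%, spot-count inhibition ≥ 50%, and cell
count > 60%, else **no effect**. Two readings of the primary hit rule
are in circulation — ISS inhibition alone, or ISS plus spot-count
inhibition — so `require_spot_inh` toggles between them and defaults to
the stricter reading. Control placement (stimulator column 11, neutral
column 12 by default) is pure configuration and never hard-coded. No multiple-testing correction is applied — hit
calling is threshold-based by design, as in the assay being modeled.

## Dose-response

`fit_4pl` fits $y = b + (t-b)/(1+(x/\mathrm{IC}_{50})^h)$ to all
replicate points jointly by Levenberg–Marquardt in log10(IC50) space.
Initialization is deterministic (asymptotes from response extremes, IC50
from the half-response bracket, Hill ±1 by trend), IC50 is bounded in
`[min conc/100, max conc·100]`, and there is no randomness, so fits are
reproducible. Parameters are canonicalized to `bottom ≤ top` with the raw
Hill slope retained. Degenerate data produce a flagged non-converged fit.
A fitted IC50 above the top tested concentration is reported as
right-censored with the top concentration as bound — the "> max tested"
convention — and triage uses the bound as a conservative selectivity
denominator. Activity means IC50 ≤ 10 µM (a stricter 5 µM confirmation
mode is a parameter), selectivity means viability/activity ≥ 5.

Both reported dose layouts are provided (`conc_series("10pt")` half-log
from 10 µM; `"6pt"` log-spaced 10 → 0.625 µM) and neither is privileged.

## Chemical profiling

Distances are Tanimoto on binary fingerprints (two empty fingerprints
have distance 0 by convention). The Ward linkage is implemented in the
package via the Lance–Williams recurrence on squared dissimilarities with
distance-scaled heights (two singletons merge at their distance), because
the deterministic tie-break — lexicographically smallest leaf pair among
minimal-objective merges — is part of the module's contract. Heights are
asserted non-decreasing on every run. The tests compare the linkage
against two independent references: an exhaustive from-scratch
error-sum-of-squares greedy oracle on all matrices up to size 8, and
`stats::hclust(method = "ward.D2")`. Ward's criterion is derived for
Euclidean geometry; applying it to Tanimoto dissimilarities is the
conventional practice for fingerprint data and is inherited here with
that caveat. Flat cuts delegate to `stats::cutree` on the package-built
linkage; dendrograms export as Newick.

Activity profiles aggregate repeated pXC50 records per compound–target
pair as *median within a (source, endpoint) stratum, maximum across
strata*, reconciling the two aggregation conventions in use for pooled
bioactivity annotations (median conversion per endpoint; highest value
reported across repeated measurements); bare records without source
metadata reduce by the maximum. The 7.0 cutoff masks, but does not delete, weaker entries.
ECFP-style circular fingerprints are not computable with the installed
toolkits, so the first-class input path is precomputed bitstrings (CSV or
the synthetic generator); `fingerprints_from_smiles()` exists as an
optional OpenBabel FP2 path with an explicit caveat that FP2 is a
path-based surrogate.

## Expression

ΔCq subtracts the arithmetic Cq mean of the reference genes (HPRT1 and/or
GAPDH — named alternatives without a combination rule, so averaging on
the Cq scale is the declared choice) from each target Cq per sample;
ΔΔCq subtracts the control-group mean; fold change is exactly
$2^{-\Delta\Delta Cq}$ with amplification efficiency fixed at 2. The
construction makes fold changes invariant to any per-sample additive Cq
offset, which the tests assert. Group comparison uses a t-test for two
groups and one-way ANOVA with Tukey contrasts against control for three
or more. The DEG filter keeps genes with fold change ≥ 3 in either
direction and p < 0.05 (both configurable) and is monotone in both
thresholds; `venn3` produces the seven disjoint region counts.

## Pipeline and reproducibility

`run_screen()` executes simulate → QC → call → retest → dose-response →
cluster → profile from a single validated config (`run_config()`, which
rejects unknown keys), writes each stage as CSV, and emits a manifest
with the config echo, stage counts, file checksums and package version.
The confirmation rule operationalizes "active at both concentrations" as
≥ 50% inhibition at 10 µM in at least 2/3 replicates plus ≥ 20% at 1 µM;
the 20% floor is declared configuration, not an inferred constant. All
randomness flows from one seed through per-stage substreams, so a rerun
with the same config is checksum-identical.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script run at deliberately modest
scales chosen for tight feedback loops: imaging checks use 384²–680² px
fields with 8–30 nuclei (20 seeds for the noisy recall/precision check at
SNR 10), plate checks use full 16×24 plates in summary mode (20–50
seeds), dose-response recovery uses 100 simulations of a 10-point
triplicate series at 10% CV, the Ward oracle covers all random matrices
up to size 8 over 50 seeds, and the end-to-end campaign is 4 plates with
1.2% planted actives. Exactness assertions (noiseless recovery, formula
oracles) use tolerances at machine precision; stochastic recovery
assertions use the rates stated above their tests (e.g. recall/precision
≥ 0.95, pIC50 within ±0.15 in ≥ 90% of fits).

## Known limitations

* The imaging model is idealized; no optics, illumination or edge-effect
  simulation, and the spatial-bias correction is only a configuration
  hook (off by default).
* Spot integrated intensity carries a small positive noise bias in
  low-signal wells (background-corrected sums over threshold-selected
  pixels are not unbiased).
* Ward-on-Tanimoto inherits the usual non-Euclidean caveat.
* The headline counts of any real campaign (hit numbers, confirmation
  rates, Z′ ranges) depend on unreleased screening data; the package
  reproduces the *procedures* and validates them on ground-truthed
  synthetic data instead.
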