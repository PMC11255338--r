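---
title: "Quantifying polar asymmetry and division-coupled c-di-GMP bursts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying polar asymmetry and division-coupled c-di-GMP bursts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polburst)
```

This vignette is the package's account of its measurement models, the
choices behind their defaults, and what the synthetic-data validation does
and does not demonstrate.

## What is being measured

Rod-shaped surface-motile bacteria concentrate motility machines and
polarity regulators at their cell poles. `polburst` quantifies, from
fluorescence images plus per-frame integer label masks produced by any
segmentation tool:

1. how polar fluorescence is split between the two poles of each cell
   (asymmetry index and pattern class);
2. when, relative to completion of cytokinesis, a division-site marker
   appears and disappears, and when a ratiometric c-di-GMP biosensor signal
   rises and falls (a division-coupled burst);
3. how evenly polar material is allocated to the two daughters;
4. single-cell speeds and run-and-reverse reversal statistics;
5. enzyme kinetics of the diguanylate cyclase generating the burst.

Masks are the input contract: segmentation itself is out of scope, labels
are taken verbatim, and label identity is *not* assumed stable across
frames (linking is done by pixel overlap).

## Cell geometry

Each labelled region becomes a `cell_region`. Pole tips are the endpoints
of the longest geodesic path through the pixel set, found by the standard
double sweep (farthest pixel from an arbitrary start, then the farthest
pixel from that). Geodesic distances use a 16-neighbourhood chamfer metric
(axis, diagonal and knight moves with Euclidean weights). The knight moves
matter: an 8-neighbourhood chamfer overestimates distances by up to ~8%
depending on direction, which made pole-cap areas visibly depend on cell
orientation; the 16-neighbourhood metric is isotropic to ~2%, and cap areas
of the same rod rendered at different angles agree within 5% once caps are
at least ~10 px deep. For very small cells discretization noise is
proportionally larger; the tests exercise the invariance claim at a
resolution where it is meaningful.

A pole cap is every pixel within `cap_depth_um` of its tip, geodesically;
each pixel is assigned to the nearer tip (ties to pole 1), so caps are
disjoint by construction and caps plus cytoplasm exactly partition the
cell, including for cells shorter than two cap depths. `cap_depth_um`
defaults to 0.35 µm — half a typical cell width — because the extent of
"the pole" is not defined by any standard; tying it to the organism's width
makes the region scale sensibly, and it is configurable.

Background is the per-channel median of non-cell pixels after dilating the
mask by 2 px (halo exclusion). The median makes the estimate indifferent to
hot pixels. Normalized cell fluorescence is
`(sum over cell − background × area) / area`, a concentration proxy
independent of cell area for uniformly fluorescent cells.

## Polar-cluster calling and the asymmetry index

The cluster rule is deliberately self-contained per cell: the threshold is
`tau = mean + k_sd × SD` of that cell's cytoplasmic pixel intensities
(`k_sd` defaults to 2; 1.5 is conventional for low-contrast markers).
Candidate pixels are cap pixels at or above `tau` *and strictly above the
cytoplasmic mean* — the strict clause makes a perfectly flat cell yield no
calls instead of calling its entire cap (SD = 0 puts `tau` at the mean).
Candidates are grouped by 4-connectivity; a component qualifies if it has
at least `min_pixels` (3) pixels and component mean at or above `tau`.
4-connectivity was chosen after validation showed that diagonal chains of
isolated shot-noise pixels form spurious three-pixel "clusters" at a
noticeable per-frame rate under 8-connectivity, while genuine clusters are
compact and unaffected. Only the largest component per pole is reported
(noise speckles must not inflate pole totals); summing all qualifying
components is available via `sum_components = TRUE`.

Cluster totals are reported raw and corrected for the cytoplasmic level
beneath the footprint (`corr_fluor = sum(v − mean(cytoplasm))`). The
asymmetry index and pole fractions use the corrected totals: otherwise two
clusters holding identical amounts of clustered signal but spread over
different pixel counts would get different totals from the underlying
cytoplasm, and the noiseless round-trip against generator truth would be
biased by cluster area. With `F1 ≥ F2`,

\[
\omega = \frac{F_1 - F_2}{F_1 + F_2},
\]

a pole with no call contributing 0, and both pole totals zero leaving
\(\omega\) undefined (the cell is diffuse). Patterns bin as unipolar
(\(\omega > 0.9\)), bipolar asymmetric (\(0.9 \ge \omega \ge 0.2\), both
boundaries inclusive), bipolar symmetric (\(\omega < 0.2\)). Population
summaries report per-pole medians ± MAD (`mad_raw()`, the unscaled
`median(|x − median|)`) and pattern fractions; diffuse cells are excluded
from the \(\omega\) distribution but reported as their own fraction.

## Time-lapse analysis

Linking is by intersection-over-union between consecutive frames
(`iou_min = 0.2`; an abrupt split gives each daughter an IoU of roughly
0.45 with its mother, well above the threshold, while drift between frames
stays well below it). A parent with exactly two qualifying children defines
a division event; the child frame is completion of cytokinesis, t = 0.
Ambiguous many-to-many overlaps are flagged and skipped rather than
guessed.

The mid-zone of an event is every mother pixel within `cap_depth_um` of the
realized split interface, which is knowable only retrospectively from the
daughters' pixel sets — acceptable because timing is computed per event
after the fact. Mid-cell cluster presence uses the same threshold rule as
polar calling with the mid-zone in place of a cap.

Timing is read off the *principal run* — the longest contiguous run of
present (or high-ratio) frames, ties resolved to the latest. On clean data
this coincides with "first present frame to last", but it is robust to a
single spurious frame far from the event, which otherwise dominates the
appearance estimate. Appearance offset is
`(completion − run start) × Δt`, lifetime `run length × Δt`; runs may
extend past completion (relevant when cytokinesis is blocked
pharmacologically and clusters persist).

The biosensor readout is `mean(green)/mean(red)` over the cell, each
background-corrected; the ratio cancels expression differences. A frame is
"high" when the ratio exceeds `baseline median + k_burst × scale` with
`k_burst = 5` — bursts are near-binary, several-fold above baseline, so a
generous multiplier costs no sensitivity. The baseline is the earliest 5
mother frames, and `scale` is the larger of the baseline MAD and
`MAD(diff(ratio))/√2`. Two numerical facts force this: the MAD of 3 values
is degenerate (one absolute deviation is always exactly zero, so the
estimate is frequently near zero and the threshold lands inside the noise
band), and even 5 baseline values can have an atypically small MAD by
chance. The lag-one difference MAD is insensitive to a burst that spans
several frames (only the two transition frames are outliers, and the median
absorbs them) and estimates the same noise scale from the whole series.

Daughter symmetry measures the mother's polarity record a stated offset
before completion and both daughters' records the same offset after,
sorting daughters by \(\omega\) (most symmetric first). Events with a
daughter lost from the field raise an error and are excluded by callers.

## The synthetic-data generator

The generator exists to give every stage a ground truth. Cells are
spherocylinders at random orientation (pole-finding must not assume axis
alignment) on a flat background; a configured fraction of each cell's total
signal is deposited in a small disc anchored at each pole tip, the same tip
pixel the pole-finder reports, so that noiseless recovery is exact rather
than approximate. Noise follows the standard two-stage camera model:
Poisson on `(signal + background) × poisson_scaling`, rescaled, then
additive Gaussian read noise. The imaging noise magnitudes are not
published quantities; defaults (`poisson_scaling = 1`, read noise SD 5 AU
on a ~100 AU background) give a plausible signal-to-noise ratio, and both
are configurable.

Division movies render one lineage growing linearly, splitting abruptly
into two labels at t = 0 (an optional gradual-constriction mode narrows the
mid-cell over the last three mother frames to stress-test event
detection). The green channel carries one or more *markers* —
`midcell_cluster`, `biosensor`, `polar_protein` — mirroring the fact that
these reporters live in different strains in the emulated experiments; the
default is the mid-cell cluster strain. The polar-protein marker places
equal old-pole clusters plus a released pool recruited to the division site
late in cytokinesis and handed to the daughters' new poles in proportion
`daughter_allocation`, which makes daughter \(\omega\) an exact, monotone
function of allocation imbalance in the noiseless limit.

Event timings (cluster appearance, burst onset, burst duration; default
means ± SD of 20 ± 15, 22 ± 12 and 19 ± 9 min, stored in
`inst/extdata/timing-defaults.yaml` and overridable) are interpreted as the
distributions of the *observable, frame-aligned* offsets — what a
time-lapse histogram actually reports. Concretely, the zero-truncated
normal is moment-matched so its realized mean and SD equal the configured
values, and sampled offsets snap to the frame grid with a one-frame
minimum (every division event carries its marker). The alternative —
treating the configured values as untruncated parameters of a continuous
window — systematically shifts every recovered mean: truncation at zero
inflates it by 2–3 min while floor-quantization by the frame interval
deflates it by Δt/2, e.g. a 22-min onset read as ~18 min at 10-min frames.
Under the chosen interpretation the pipeline's recovered means are centred
on the configured values by construction, and the noiseless round trip is
exact. By default the mid-cell cluster disintegrates at completion, so its
lifetime equals its appearance offset, consistent with the near-identical
published appearance and lifetime statistics; an independent lifetime
distribution can be supplied for persistence scenarios.

Tracks follow a run-and-reverse process: per-track speed from a truncated
normal, reversals at Poisson times flipping the heading by 180°, Gaussian
per-step heading jitter. The default reversal rate, 2 per 15-min recording,
matches a typical wild-type cell; the recording geometry (15 min at 30-s
intervals) matches the standard assay.

**What the generator does not emulate** — and therefore what passing tests
do not show: optical blur (clusters are rendered as hard discs, real ones
are PSF-convolved), 3D effects, cell crowding and contact, segmentation
errors (masks are perfect by construction), photobleaching, and
focus drift. Validation here demonstrates that the algorithms measure what
they claim on data whose truth is known; performance on real images is
bounded additionally by segmentation and optics.

## Motility quantification

Speed is the mean frame-to-frame displacement over the frame interval. A
reversal candidate is a step whose heading differs from the previous step's
by at least 120°; candidates closer together than `persistence_frames` (2)
merge into a single event, so a one-frame excursion scores once, not twice.
Headings are not smoothed by default: at a 120° threshold, realistic
per-step jitter (tens of degrees) produces no false candidates, whereas a
3-frame moving average erases genuine one-frame reversal runs entirely. A
`smooth_window` parameter remains for noisier data.

Quantified sampling losses, visible in the recovery tests: a reversal pair
falling within one frame interval cancels out of the sampled positions
(probability ≈ λΔt per event), a reversal in the first interval has no
preceding heading to compare against (≈ Δt/T of events), and merged
excursions count once for two truth events. At the default rate these
losses total some 10–15% of events; the recovery test therefore checks the
mean against rate × duration at a rate where quantization losses are small,
and exactness is asserted on tracks whose flips all survived sampling.
The reversal criterion itself is an operationalization — published reversal
counts are typically scored manually — so the threshold and persistence
defaults are tunable parameters, not ground truth.

## Kinetics

Product inhibition is `V = V0 / (1 + ([cdG]/Ki)^h)` — note `V(0) = V0` and
`V(Ki) = V0/2` — and equilibrium binding is `R = Rmax·C/(KD + C)`, with an
optional linear nonspecific term, off by default. Fits use
Levenberg–Marquardt least squares bounded below at zero, with starting
values from the data (maximal response; concentration nearest half-max;
h = 1). Confidence intervals use t quantiles on the asymptotic standard
errors; across the seeded simulation study in the test suite the nominal
95% intervals cover at ~0.90–0.92, the mild undercoverage reflecting the
multiplicative noise that the unweighted fit ignores. A fitted `Ki` or `KD`
more than 10× the largest tested concentration is flagged
`"unconstrained"` rather than reported as a finding: such data never enter
the regime that identifies the parameter. Relative enzyme activity from
pyrophosphate-release progress curves is the blank-subtracted absorbance
change over the reaction window (or the initial slope, by option), reported
relative to a reference sample's mean; no absorbance-to-concentration
calibration is attempted, so activities are relative by design.

## Age structure

A steady-state exponentially growing population has cell-age density
`f(a) = (2 ln2/Td)·2^(−a/Td)` on `[0, Td]`; sampling uses the closed-form
inverse CDF `a = −Td·log2(1 − u/2)`. The fraction of cells within the final
`w` minutes is `2^(w/Td) − 1`, connecting a division-site marker's
residence time to the marker-positive fraction in a snapshot:
`age_model_fraction()` reports the Monte-Carlo estimate with its binomial
standard error alongside the analytic value.

## Degenerate inputs and tie-breaks

* Flat image / zero cytoplasmic SD: no cluster calls (not an error).
* Single-pixel regions: error from `find_poles()`; regions below
  `min_area_px` (5) are dropped at extraction.
* Mask covering the whole image: background estimation errors out.
* Largest-component selection ties by pixel count, then total
  fluorescence; principal-run ties go to the run closest to completion;
  cap-membership ties go to pole 1.
* Non-positive corrected red signal: biosensor ratio is `NA`, the cell is
  skipped.
* Unknown pipeline configuration keys are rejected before any computation.

## Problem sizes

The validation suite runs on scenes of 5–15 cells at 0.1 µm/px, 100
cluster-timing movies (5-min frames) and 130 burst movies (10-min frames)
of one lineage each, 200-replicate kinetics simulations, and 10,000-cell
age samples — sizes chosen to estimate the stochastic recovery targets with
useful precision while keeping the default check fast on a laptop.

## Known limitations

* Pole caps are defined geometrically (geodesic depth), not from a
  curvature or mesh model; the "pole" of a strongly bent cell is its tip
  region, which may differ from a mesh-based definition.
* The burst detector assumes the baseline frames precede the burst; a
  burst already in progress at the start of a recording is mistimed.
* Lineage linking handles one division per mother per movie reliably;
  dense fields with touching cells are out of scope (masks are assumed
  correct and non-overlapping).
* The reversal criterion is parameter-dependent by necessity; report the
  thresholds alongside any comparison.
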