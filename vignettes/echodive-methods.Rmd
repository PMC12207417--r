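---
title: "Detecting air-breathing predator dives in fishing-vessel echosounder data"
author: "echodive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting air-breathing predator dives in fishing-vessel echosounder data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echodive)
```

## The problem

Krill fishing vessels run downward-looking echosounders continuously while
fishing. Besides krill swarms, the echograms record the air-breathing
predators that dive beneath the hull to feed on the same swarms: penguins
and Antarctic fur seals release air during ascent and leave comet-like,
ascending bubble streaks no more than about 2 m high, while baleen whale
bodies (3-6 m in diameter, with air-filled lungs) return intense, compact
echoes 3 to more than 20 m high. Counting the seconds such signals spend
under the vessel and normalizing by observation effort yields a
*predator-vessel encounter rate* (minutes of predator presence per hour of
echogram), a direct, low-cost index of spatial overlap between the fishery
and krill predators.

`echodive` implements that measurement chain end to end: standardization
of raw backscatter into fixed-format echograms, five-class pixel
segmentation (background, seafloor, krill swarm, whale, bubble trail),
conversion of predator segments into discrete dive events with duration
and acoustic height, and normalization into encounter rates over time,
spatial grids, and colony buffer zones. Because curated acoustic archives
are large and access-restricted, the package also ships a synthetic scene
generator with exact pixel-level ground truth; every stage of the pipeline
is validated against scenes whose content is known by construction.

## The synthetic scene generator

`simulateScene()` draws Gaussian background noise in Sv dB (default mean
-85 dB, sd 3 dB, a plausible open-water noise floor at 120/200 kHz) on the
standard 1 s x 0.5 m grid and plants parametric objects:

* **krill swarms** - elliptical diffuse blobs, default intensity around
  -62 dB;
* **bubble trails** - linearly ascending streaks with a base width of 1-3
  pixels and a linear intensity fade along the trail (the "comet" look).
  Rasterization covers the ascent line within each column, and the
  admissible ascent rate is capped so that no column of the streak ever
  exceeds 4 pixels (2 m) - the physical height bound for seal and penguin
  signals on this grid;
* **whale dives** - compact intense ellipses at least 3 m high, around
  -33 dB;
* **seafloor** - a strong band with gentle sinusoidal relief.

Overlapping objects are resolved by scatterer strength
(whale > bubble trail > krill swarm > seafloor > background), matching how
a stronger target dominates the recorded echo. Every planted predator also
yields a ground-truth event row (class, time span, duration, height), and
the mask/event tables stay consistent by construction.

`corpusSceneConfig()` calibrates random scenes to the class mix of the
annotated training corpus used for the full-scale model - about 87%
background, 10% krill swarm and 1% bubble trail pixels, with whales and
seafloor in the small remainder - so that synthetic training exercises the
same class imbalance the real corpus shows. Because roughly 1% bubble
coverage cannot be reached by temporally non-overlapping trails in a
10-min window, corpus-type scenes allow predator footprints to overlap
(precedence applies). For event-level validation that is the wrong
regime - two crossing trails merge into one connected component, exactly
as they would in a real echogram - so `recoverySceneConfig()` (noise-free)
and the pipeline's `"demo"` scene type (noisy) place predators with
pairwise disjoint, padded bounding boxes instead.

What the generator deliberately does **not** emulate: sonar-equation
physics (beam pattern, time-varied gain, absorption), multi-frequency dB
differencing, vessel noise bursts, or the complex seafloor topography that
causes most real false positives. Intensities are phenomenological
calibration knobs - published dB ranges for these signal classes do not
exist - chosen to be separable in the same qualitative order as real
targets (whale and seafloor strongest, trails strong, krill diffuse,
noise weak). Passing tests on synthetic scenes therefore demonstrate the
correctness of the measurement chain, not field-grade detector skill.

## Standardization

Raw records hold Sv (dB) over irregular ping times and a regular depth
axis. `regridSv()` resamples time to 1-s instants - values at original
ping instants are preserved, longer gaps are filled by linear
interpolation *in dB* along time (the simplest reading of the processing
convention; interpolating in linear backscatter would change the values by
under a quantization step at these gap lengths) - and assigns depths to
0.5-m bins by nearest bin centre. Interpolation is uncapped by default;
columns inside gaps longer than 10 s are flagged, and a `maxGapS`
parameter can force long gaps to stay missing.

`windowEchograms()` cuts consecutive non-overlapping 10-min windows
anchored at the record start, pads depth/time to 500 m x 10 min with a
reserved missing marker (`NA`, *not* 0: padding must never masquerade as
quiet water at -90 dB), and records the padded fraction.
`svToGrayscale()` maps Sv affinely from the fixed -90..-20 dB range to
[0, 1] with clipping; the range deliberately saturates strong targets so
krill and predator signals occupy most of the dynamic range. Pixel
conventions are half-open: column *c* covers [c-1, c) seconds, row *r*
covers [0.5(r-1), 0.5r) metres, so a whale planted from 40 to 50 m spans
exactly 20 rows = 10 m.

## Segmentation

Two segmenters sit behind one interface.

**Trainable U-Net.** `buildSegmenter()` constructs a classic U-Net: per
encoder level two 3x3 convolutions (ReLU) and 2x2 max pooling, a
two-convolution bridge, and a mirrored decoder with nearest-neighbour
upsampling and skip concatenation, closed by a 1x1 convolution onto the
five class logits. The default configuration mirrors the published
training recipe (4 levels, 256 x 256 tiles, five classes, Adam, 100
epochs, batch 20, categorical cross-entropy with whale pixels weighted
10:1 against all other classes); reduced configurations (2 levels, 64 x 64
tiles, 6-8 base filters) train in minutes on one CPU. The implementation
is the package's own: forward/backward passes over im2col convolutions run
in compiled code (`src/conv.cpp`) with BLAS matrix products, and the
backward pass is verified against finite differences in the test suite.
We implement the classic U-Net rather than a MultiRes variant: at the
reduced scales used here the extra residual-path parameters showed no
benefit on synthetic scenes, and the published parameter count is not a
reproduction target. The `bridgeWidth` knob (default 512) stands in for
the bridge width of the full-scale architecture.

Training samples `tilesPerImage` tiles per echogram per epoch: half
centred on a predator pixel, a quarter on any foreground pixel, a quarter
uniform. Without this bias a 64-pixel tile of a 600 x 1000 echogram would
almost never contain the ~1% bubble-trail and ~0.1% whale pixels and the
weighted loss alone cannot rescue classes the sampler never shows.
Validation loss is computed each epoch on a fixed tile set and the
best-validation parameters are returned ("best network stored").
Non-finite loss aborts with a diagnostic rather than silently continuing.

`predictAndThreshold()` tiles an echogram (at inference time with blocks
up to 640 pixels - fully convolutional networks are size-agnostic, and
fewer, larger blocks are much faster than many training-size tiles),
averages probabilities where blocks overlap, and labels each pixel with
the highest-probability class among those exceeding their per-class
threshold; if none passes, background. Exact ties resolve by rarity
priority (whale > bubble trail > krill > seafloor > background),
protecting the classes the loss up-weights; with all thresholds zero the
rule degenerates to argmax. Per-class optimal thresholds are the
F1-maximizers of `evaluateSegmentation()`'s precision-recall sweep on
validation data (the sweep grid is 0.05..0.95 in steps of 0.05).

**Rule-based reference segmenter.** `referenceSegmenter()` is a
deterministic, training-free segmenter used as an independent oracle in
tests and as a production fallback: pixels above a strong cut (default
-55 dB) form seafloor/predator candidates, a weaker band (default -72 dB)
forms krill candidates. A strong component spanning at least 80% of the
observed columns in the lower half of the window is seafloor; a component
at most 4 pixels (2 m) high in every column and descending in row index
over time (ascending in depth) is a bubble trail; a component at least
6 rows (3 m) high is a whale; everything else falls back to krill.
Components under `minPx` (default 6) pixels are discarded - at
N(-85, 3) dB noise the strong cut is never reached and the weak cut only
by a handful of isolated pixels per window, which this floor removes.

## Dive events

`extractDivePolygons()` takes 8-connected components per predator class
(diagonal thin trails would shatter under 4-connectivity; the
4-connected labeller underneath is extended by a union-find merge across
diagonal label contacts) and drops components under `minPixels`.
`measureDives()` applies the inclusive-span conventions: duration =
(col_max - col_min + 1) x 1 s, acoustic height = (row_max - row_min + 1)
x 0.5 m, so a single-pixel detection still measures 1 s x 0.5 m. Events
keep the window-start-plus-offset timestamp, a position interpolated from
the vessel track, and a window-boundary flag; events spanning adjacent
10-min windows are *not* merged (windows are processed independently) and
the flag lets users post-merge if they wish.

`classifyMammalDive()` encodes the acoustic-height taxonomy for
whale-class polygons: below 2 m a signal is consistent with a fur seal
(body length about 2 m), at 3 m or more with a baleen whale (body
diameter 3-6 m, more when diving at an angle), and the 2-3 m band is
declared ambiguous rather than forced either way. Bubble trails are not
split into penguin versus fur seal: the acoustic signature alone does not
distinguish them, so the class is reported as `bubble_trail` with taxon
`unclassified`.

`applyQc()` mirrors the manual false-positive screening step: control
plots per detection, a flag table marking removals, and removed events
retained in the table (`qc_flag = "removed"`) but excluded from every
downstream rate.

## Encounter rates

Activity classification uses the inclusive 0.3-5 kn speed window
(`classifyActivityBySpeed()`): below it the vessel is stationary (port,
offloading), above it steaming; externally supplied status labels take
precedence, and the speed rule is the fallback for vessels without such
labels. Bound inclusivity at exactly 0.3 and 5 kn is our choice; the
window itself treats boundary speeds as fishing. `filterToFishing()`
assigns events and ledger rows to activity periods by their start
timestamp and removes non-fishing periods from numerator and denominator
together - an excluded minute can never contribute observation effort.

`rateTimeseries()` and `rateGrid()` sum kept-event predator minutes and
observation hours per 7-day bin (the bin width is configurable; weekly is
a readable default for multi-season series) or per half-open grid cell
anchored at integer multiples of the cell size (0.04, 0.03 and 0.075
degrees are the published per-region resolutions; origins are not
published, so cells anchor at zero by default). Rates are
minutes-per-hour with `log10(rate + 1)` alongside (the +1 keeps
zero-encounter bins on the log scale); bins or cells with observations
but no events report rate 0, while bins with no observations report a
*missing* rate - absence of effort is not absence of predators.

`vrzExposure()` labels events and effort by membership in radial colony
buffers (default 30 km, the voluntary restricted-zone radius chosen as
the approximate maximum penguin foraging range) and by before/after the
July 2018 management cutoff, reporting per-stratum rates and the share of
encounters within 15 km of the nearest colony. True coastline buffering
is out of scope; the radial simplification is pluggable.
`penguinConsumptionEquivalent()` converts penguin counts to krill demand
at 100 kg per bird per season. `medianIntervesselDistance()` (fleet
synchrony) and `coverageByHour()` (diel coverage) reproduce the standard
fleet diagnostics. All great-circle distances are haversine on
R = 6371 km and are cross-checked in the tests against the spherical law
of cosines and an independent geodesy library.

## Numerical choices and degenerate inputs

* Regridding requires at least 2 pings and strictly increasing times;
  single-ping records are refused by name.
* Probability maps must be simplex-valued (checked by class validity).
* F1 uses the 0/0 -> 0 convention.
* Empty scenes, empty event tables, empty flag tables, and all-padding
  echograms all produce well-defined empty or background outputs.
* All randomness flows through explicitly passed integer seeds; identical
  configuration gives bit-identical scenes, splits, augmentations and
  pipeline outputs.

## Problem sizes used in the validation suite

The test suite and the acceptance script validate the chain at desk
scale: 50 noise-free scenes for event-level recovery; a reduced U-Net
(2 levels, 6 base filters, 64-pixel tiles) trained for up to 15 epochs on
200 corpus-type scenes and evaluated on 50 held-out scenes for the
learning check, with per-class thresholds selected on separate validation
scenes; and a 20-scene end-to-end pipeline run for rate recovery. These
sizes are the package's validation design; the full-scale recipe remains
available through the same configuration objects.

## Known limitations

* Synthetic realism is deliberately limited (see above); reported F1 on
  synthetic scenes exceeds what any segmenter achieves on real echograms,
  where noise bursts and rugged seafloor dominate the error budget.
* Overlapping predator signals merge into single events - a property of
  the echogram itself, not just of this implementation - so dense
  aggregations undercount individual dives; corpus-type scenes exhibit
  this, and the event-level validation uses disjoint placements.
* The taxon split of bubble trails requires regional context (e.g. which
  predator dominates a fishing ground) and is intentionally left to the
  user.
* VRZ geometry is a radial buffer around colony points, not a coastline
  buffer.
* No hypothesis testing is attached to before/after comparisons; the
  package reports stratified rates descriptively.
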