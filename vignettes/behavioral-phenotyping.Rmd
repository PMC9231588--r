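---
title: "Behavioral phenotyping of zebrafish from tracking trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral phenotyping of zebrafish from tracking trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zebratrax)
```

## What this package computes

`zebratrax` turns per-frame 2-D tracking coordinates of zebrafish into the
behavioral statistics used to phenotype mutant lines against wild-type
controls, and compares genotypes with the statistical scheme standard in
this literature. Five readouts are covered:

* **Locomotor activity** — distance moved per 30-s bin; "general activity"
  is the mean over the first 15 min of a recording in constant light.
* **Visual motor response** — at every light-to-dark (or dark-to-light)
  transition, the ratio of mean swimming speed in the 30 s after to the 30 s
  before the switch, averaged over the three same-direction transitions of
  the standard protocol. Larvae startle at abrupt illumination changes; an
  exaggerated response is read as an anxiety-like phenotype.
* **Thigmotaxis** — the fraction of time (or path length) spent in the
  peripheral half of an open-field tank. "Wall-hugging" is a conserved
  anxiety index; values near 0.5 are neutral under an equal-area split.
* **Social preference index (SPI)** — `(C - E) / (C + E)` where `C` and `E`
  are dwell time (or in-sector path length) in the sector adjacent to
  conspecifics and in the opposite empty sector. SPI is +1 for a fish glued
  to its conspecifics, 0 for indifference, -1 for avoidance.
* **Shoaling cohesion** — the mean inter-individual distance (IID) of a
  group: per frame, the mean over all n(n-1)/2 pairwise distances; then the
  mean over frames.

Because the raw recordings behind published phenotyping studies are
generally not deposited, the package includes a trajectory simulator whose
genotype presets reproduce the qualitative effect structure of a
loss-of-function autism-model line (see below). Every metric is therefore
testable end to end: simulate a cohort, compute metrics, compare genotypes.

## Protocol geometry and schedules

All coordinates are arena-local millimetres: rectangular arenas have the
origin at the lower-left corner, circular wells at the centre, y upward.
Shipped presets encode the standard apparatus:

| Preset | Geometry | Zones |
|---|---|---|
| `preset_larval_well()` | 16-mm circular well (24-well plate) | — |
| `preset_open_field()` | 300 x 300 mm tank | equal-area concentric `center` / `periphery` |
| `preset_juvenile_social()` | 22-mm circular well (12-well plate) | chord bands beyond ±¼ diameter: `conspecific` (+y) / `empty` (−y) |
| `preset_adult_social()` | 105 x 110 mm half of a mating tank | two equal rectangles: `conspecific` (at the divider) / `empty` |
| `preset_shoal_tank()` | 240 x 150 mm novel-tank footprint | — |

The well diameters (16 mm, 22 mm) are nominal plate-well dimensions; the
protocols only state the plate formats, so both are configurable arguments.
The shoaling tank is likewise a typical novel-tank footprint. Points exactly
on a zone boundary belong to the first zone listed in the partition — a
deterministic, documented tie-break.

Two open geometric choices deserve note:

* **"Peripheral half" is an equal-area split.** For a square of side *s*
  the central zone is the concentric square of side *s*/√2. The alternative
  (equal border width) would make the null expectation of the thigmotaxis
  ratio differ from 0.5 and entangle the metric with arena size. The split
  is configurable through an explicit partition.
* **Juvenile sectors are chord bands.** The well is cut by two chords
  perpendicular to the social axis at ±¼ diameter from the centre; the band
  nearest the conspecific well is the conspecific sector, the opposite band
  the empty sector, and the middle half of the well belongs to neither (it
  never enters the SPI denominator).

The default larval illumination schedule is 45 min at 25 fps: a 15-min
light period, split for reporting into `baseline` (10 min) and `L0` (5 min),
followed by three 5-min dark / 5-min light cycles (`D1, L1, D2, L2, D3,
L3`); 100 lx in light, 0 lx in dark. Lights-off transitions fall at 900,
1500 and 2100 s, lights-on at 1200, 1800 and 2400 s.

## Metric conventions

* Speed is step length x frame rate, boxcar-averaged over each window; no
  additional smoothing.
* Bins are anchored at the recording start; only complete bins are
  reported. A trajectory of *n* frames carries *n − 1* steps, each
  attributed to the bin (and zone) of its starting frame. Summed bin
  distances therefore equal total path length exactly when the duration is
  a whole number of bins.
* The **"velocity change"** at a transition is implemented as the
  after/before speed **ratio** — a dimensionless quantity that is invariant
  under spatial rescaling, matching how the response is plotted in this
  literature. The per-fish mean over the three same-direction transitions is
  taken before any cross-fish statistics. (Published numeric values of this
  quantity are not always internally consistent — e.g. medians outside
  their own confidence intervals — so no attempt is made to reverse-engineer
  a different formula; the ratio convention is documented and tested.) A
  transition with zero pre-transition speed yields an undefined ratio,
  which is flagged and excluded from the per-fish mean.
* **Tracking dropouts** (frames with `valid = 0`) are bridged by linear
  interpolation when the gap is at most 1 s; longer gaps are excluded from
  both time and distance accrual, and any 30-s bin missing more than 20% of
  its frames is flagged. Commercial trackers drop frames; published methods
  rarely say how they were handled, so the policy is explicit and
  conservative.
* The tracker's device-level detection threshold is an acquisition setting,
  not reproduced in software.

## The trajectory simulator

`simulate_fish()` is a discrete-time correlated random walk at `1/fps`
steps (default 1/25 s):

* **Speed** follows Euler-discretized mean reversion around
  `mu_speed x m(t)` with fluctuation scale `sigma_speed` and relaxation
  time `tau_speed` (2 s default), clamped at zero. The modulation `m(t)` is
  `g_dark` during dark epochs, times `1 + startle_gain x exp(-dt/tau_startle)`
  after each illumination transition (both directions; `tau_startle` = 10 s).
* **Heading** gains wrapped-Gaussian noise with persistence
  `kappa_heading` (the mean resultant length per frame; 0.98 ≈ heading
  decorrelation over roughly a second at 25 fps) plus turn biases, each of
  the form `dt x kappa x sin(bearing - heading)`: toward the nearest wall
  (`kappa_wall`), toward the conspecific side (`kappa_social`, active only
  in test periods of social trials), and toward the centroid of the other
  shoal members (`kappa_cohesion`).
* **Walls reflect specularly** (radial mirror on circular wells); positions
  never leave the arena.
* **Randomness** is fully seeded; group simulations give fish *i* the
  stream `seed + i`, drawn before the coupled loop, so an uncoupled shoal
  is bit-identical to the same fish simulated independently.

With all biases at zero the walk's stationary occupancy is approximately
area-proportional: the equal-area peripheral fraction sits near 0.5 (the
tests hold it within ±0.05 over 20 half-hour runs; heading persistence plus
specular reflection produces a small wall-following excess, which is why
the tolerance is a band rather than an exact value).

### Genotype presets

The study the package emulates reports effect *directions* for a
homozygous mutant (`HOM`) against wild-type (`WT`), with heterozygotes
(`HET`) intermediate: hypoactivity, stronger visual motor response,
enhanced thigmotaxis, reduced social preference, looser shoals. (One figure
legend states the shoaling direction inconsistently with the text; the
package follows the text: mutant shoals are looser, i.e. larger IID.)
Absolute parameter magnitudes are unconstrained by the literature, so the
presets are documented constants chosen once, before the test suite was
frozen:

* `mu_speed` anchors to the printed group-mean activities (mm per 30 s
  divided by 30): larvae 2.72 / 2.13 / 1.83 mm/s, adults 5.17 / 4.60 /
  4.11 mm/s for WT / HET / HOM.
* `kappa_wall` (0.18 / 0.22 / 0.28 rad/s for adults) was placed on a
  Monte-Carlo dose-response curve of the open-field time ratio so that WT
  and HOM land near the reported thigmotaxis ratios (≈0.83 and ≈0.92).
  Larval values are nominal (0.02–0.05): larval thigmotaxis is not assayed.
* `g_dark` (1.5 / 1.7 / 2.0) and `startle_gain` (1.0 / 1.5 / 2.5) give all
  genotypes the well-known dark hyperactivity and lights-off startle, with
  the mutant's response exaggerated.
* `kappa_social` (0.35 / 0.18 / 0.07 rad/s) spans test-period SPIs from
  roughly 0.5 (WT) down to near 0.1 (HOM) in the juvenile paradigm;
  `kappa_cohesion` (0.60 / 0.30 / 0.05 rad/s) spans mean IIDs from roughly
  25 mm (WT) to near the uncoupled value (HOM).

What the simulator deliberately does **not** model: burst-and-glide
swimming, freezing bouts, depth (it is 2-D), body shape, hydrodynamic
interactions, habituation over the session, and the post-dark suppression
of light-phase activity seen in real larvae. Passing tests therefore show
that the *metrics and statistics* recover the effect structure the
generator encodes — they are not evidence about real recordings, which
enter only through the documented CSV reader.

## Statistical layer

The dispatch mirrors the field's reporting convention: Shapiro-Wilk per
group at α = 0.05 (any rejection, or a zero-variance group, routes to the
nonparametric family); then Student's t (two groups) or one-way ANOVA with
Dunnett's comparisons against wild-type (three groups) for normal data, and
Mann-Whitney U or Kruskal-Wallis with Dunn's comparisons otherwise; paired
designs use the paired t-test. All tests are two-tailed. The literature
states the parametric/nonparametric split without a decision rule; the
per-group Shapiro-Wilk gate is this package's documented choice. The
two-group nonparametric fallback (Mann-Whitney) is likewise an extension
the reports flag explicitly.

Numerical notes:

* Dunnett p-values come from `multcomp`; its quasi-Monte-Carlo
  multivariate-t quadrature runs under a locally fixed RNG state so
  repeated calls are identical. Cross-implementation agreement for Dunnett
  is asserted at 1e-3 (the quadrature's precision); all closed-form tests
  (t, paired t, exact Mann-Whitney, Kruskal-Wallis, Dunn z) are asserted
  against independently computed reference values at 1e-6.
* Dunn's comparisons use the tie-corrected pooled-variance z statistic with
  Bonferroni adjustment over the comparisons against the reference; no
  ready-made implementation exists in the installed stack, so it is
  implemented directly and checked against frozen cross-implementation
  values.
* Parametric summaries are mean ± SEM; nonparametric summaries are median
  with a seeded percentile-bootstrap 95% CI (10<sup>4</sup> resamples).
* Count tables render as `n/N (p%)` with half-up rounding to one decimal
  (integer percentages print without a decimal), reproducing the published
  early-development table from its printed numerators and denominators.

## Problem sizes used in validation

The test-suite and acceptance experiments use the study's group sizes where
stated — 17/17 fish for juvenile social preference, 25/33 for open
field and thigmotaxis, 10/14 for adult social preference, 9/10 shoals of
6 — and 20/20 larvae for the light/dark assay (the study pooled hundreds of
larvae across batches; 20 per genotype gives the simulated effect sizes
ample power and keeps a full validation run in the order of a minute).
Monte-Carlo checks of simulator calibration use 20–50 seeds per condition;
the type-I-error check of the two-group branch uses 10<sup>4</sup> null
simulations at n = 20 per group.

## Known limitations

* The simulator's effect magnitudes are calibrated constants, not fitted to
  data; only effect directions are claimed, and the acceptance experiment
  reports its own computed values rather than published ones.
* SPI sector geometry for the juvenile well is an interpretation of a
  protocol described only in words; alternative sector shapes can be
  supplied as explicit partitions.
* The reader ingests one CSV dialect (with a column-mapping option);
  proprietary tracker formats must be exported to it.
* Thigmotaxis assumes a rectangular arena for its default split; other
  shapes need a user-supplied partition.
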