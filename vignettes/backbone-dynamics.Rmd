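---
title: "Models and methods: BI/BII backbone dynamics of B-DNA duplexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: BI/BII backbone dynamics of B-DNA duplexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnaBII)
```

## The physical picture

The phosphodiester linkage of B-DNA populates two conformational
substates, distinguished by the ε and ζ backbone torsions: BI
(ε *trans*, ζ *gauche−*) and BII (ε *gauche−*, ζ *trans*). The two
torsions move in a correlated way, so the single pseudo-angle (ε−ζ),
wrapped into [−180°, 180°), separates the states: the BI mode sits near
−90°, the BII mode near +100°. Exchange between the states is fast
(nano- to picosecond), so any per-phosphate property observed in solution
is an ensemble average over the two states. In a duplex, each
complementary dinucleotide NpN•NpN carries two *facing* phosphates, one
per strand, whose joint state (BI•BI, BI•BII, BII•BI, BII•BII) couples to
the inter base-pair parameters slide, roll and twist. Because BI•BII and
BII•BI are equivalent for most mechanical purposes, the package pools them
into a hybrid category BI•BII|BII•BI throughout, while keeping the ordered
labels available.

The package implements the full analysis chain on per-frame torsion and
helical-parameter tables — the derived output of any MD post-processor —
and on ³¹P chemical-shift tables, plus a synthetic generator that
reproduces the statistical structure the analyses assume.

## State classification

* **Cutoff rule.** A frame is BII exactly when (ε−ζ) strictly exceeds the
  cutoff; a frame exactly at the cutoff is BI. For continuous data the
  choice of strict versus non-strict inequality is immaterial, but it is
  fixed and documented so that counts are reproducible. Two presets are
  provided: 0° (`"parm-like"`, the conventional divide, appropriate when
  the distribution has no clear minimum between the modes) and +30°
  (`"charmm-like"`, for force fields whose (ε−ζ) histogram dips at +30°).
* **Torsion windows.** The staggered conformer windows are gauche plus
  60±40°, trans 180±40°, gauche minus 300±40°, edges inclusive; anything
  outside is `other`. Frames with both ε and ζ in *trans* fall between the
  two modes and are flagged as an ambiguous region; they still receive a
  BI/BII label from the cutoff rule, and the flag lets users quantify how
  much probability mass is affected.
* **Pucker categories.** The sugar pseudorotation phase is categorised as
  north (300° through 0° to 50°), east (50–120°), south (120–220°);
  220–300° belongs to no category and is labelled `other`. Note the north
  range: descriptions of the same data sometimes state north as 0–50°
  only, but the range crossing 0° is the physically meaningful one and is
  what the package uses — a deliberate, documented choice.
* **Cutoff suggestion.** `suggest_cutoff()` histograms (ε−ζ) with 5° bins
  (configurable), smooths with a 3-bin circular moving average, finds the
  two largest modes and locates the minimum between them. The valley must
  be "clear": the smaller mode's smoothed peak must exceed the valley
  height by a factor of 1.5 (configurable), otherwise the suggestion is
  `ambiguous` with a fallback of 0°. No published numeric rule exists for
  this step; the defaults are stated here so that they can be criticised
  and overridden.

## The synthetic generator

The generator's role is to produce data with *known* statistical structure
so that every analysis stage can be validated against ground truth.

* **Latent dynamics.** Each phosphate follows a two-state discrete-time
  Markov chain parameterised by its stationary BII probability `p` and a
  persistence `a` in [0, 1): per frame, the chain refreshes with
  probability 1−a and then redraws its state as Bernoulli(p), giving
  transition probabilities q(BI→BII) = (1−a)p and q(BII→BI) = (1−a)(1−p)
  and mean sojourns 1/((1−a)p) and 1/((1−a)(1−p)) frames. The default
  a = 0.99 at 1 ps frames yields dwell times of order a nanosecond,
  consistent with the fast exchange regime observed in solution. No
  kinetic model is claimed beyond this: it is the simplest chain with
  independently controllable marginals and dwell times.
* **Cross-strand coupling.** With coupling κ ≠ 0, the per-frame joint law
  of the two facing phosphates is the unique 2×2 table with the requested
  marginals and odds ratio e^κ (the Plackett closed form; iterative
  proportional fitting of the same table gives the identical result).
  Sampling uses per-phosphate Gibbs refreshes from the conditionals of
  that table, each with probability 1−a per frame, which leaves the joint
  law stationary and reduces exactly to independent chains at κ = 0.
  Because the chains refresh independently, simultaneous two-phosphate
  transitions are rare at high persistence — of order (1−a)² — matching
  the behaviour the transition census is designed to detect.
* **Torsion emissions.** Defaults: BI ε ~ N(185°, 8°), ζ ~ N(275°, 8°);
  BII ε ~ N(260°, 8°), ζ ~ N(160°, 8°), centring (ε−ζ) at −90° and +100°.
  At these widths the modes are ~8 combined SDs from the 0° cutoff, so
  classification recovers the latent states with error ≪ 1%; all
  parameters are configurable, and widening the SDs is the intended way to
  study classification robustness.
* **Sugar phases.** Mixtures over {north, east, south} per state, with
  components N(20°, 12°), N(85°, 15°), N(160°, 20°). BII frames draw 5′
  south only (weight 1), reflecting the strict association of BII with 5′
  south puckers; BI frames default to 0.1/0.1/0.8. These weights shape
  marginal displays only — no analysis depends on them quantitatively.
* **Helical emissions.** Per pooled combination, the six parameters are
  Gaussian. Slide/roll/twist defaults come from pooled MD conditionals
  reported for two modern force-field families (selectable as `"P"` or
  `"C"`); shift and tilt are combination-invariant and centred at 0; rise
  is 3.3 Å with combination offsets capped at 0.2 Å. The two hybrid
  combinations share one conditional, as the analyses pool them.
* **Chemical shifts.** δP = (100p − 621)/143 plus optional Gaussian noise,
  the exact inversion of the conversion equation, so zero-noise tables
  round-trip to the generating probabilities.
* **Seeding.** Every generator function takes a `seed`; the pipeline
  driver derives stage substreams (seed, seed+1) so stages are
  individually reproducible.

What the generator does *not* emulate: sequence-dependent kinetics beyond
user-supplied per-step targets, correlations between neighbouring steps
along the helix, skewed or heavy-tailed torsion distributions, the
trans/trans bridge population between the modes (absent by default),
terminal fraying, and any atomic-level structure. Tests passing on
generated data therefore validate the *estimators* — counting, censusing,
factorisation, conditioning — not the realism of any force field.

## The independence framework

For facing phosphates i, j the counting identity
P(hybrid) + 2 P(BII•BII) = P_i(BII) + P_j(BII) follows from the
definitions alone and is checked exactly (on integer counts) on every
labelled series. Under independence the pair law factorises,
P(BII•BII) = p_i p_j and P(hybrid) = p_i + p_j − 2 p_i p_j. The
diagnostic compares frame-counted populations against these predictions
computed from the *empirical* marginals, and summarises agreement across
steps by one Pearson correlation per pooled category — the construction
used to establish independence from trajectory data. Both coefficients
are reported separately rather than as a single figure.

Two design safeguards are added and clearly labelled advisory:

* a per-step 2×2 odds ratio with the Haldane–Anscombe 0.5 correction for
  empty cells, and
* a significance note whose standard error is inflated by the state
  autocorrelation: consecutive frames are far from independent, so the
  effective sample size is estimated as n(1−ρ)/(1+ρ) from the lag-1
  autocorrelation of the two state chains (the larger ρ of the two).

Steps with degenerate marginals (p = 0 or 1) carry no information about
association and are excluded from the correlations, and reported.
Transitions are counted between consecutive saved frames with no
minimum-dwell filtering; the frame interval is carried as metadata so
users can coarsen the sampling themselves.

## The NMR bridge

BII(%) = 143 δP + 621 is empirical and can leave [0, 100]; values are
clamped, and the raw value is kept alongside. A tolerance band of ±10
percentage points (configurable) acknowledges the conversion's
assumptions: the shifts of pure-BI and pure-BII endpoints are taken as
sequence independent, which is an approximation. One numerical remark:
with the stated conversion, δP = −4.20 ppm gives 20.4%, while an often
co-quoted rounded average of "19%" corresponds to a slightly more negative
unrounded mean shift; the package always reports the raw arithmetic.

Combination populations inferred from shifts apply the factorisation to
the converted probabilities, with intervals obtained as extrema of each
population over the rectangle of the two tolerance bands. BII•BII and
BI•BI are monotone in each argument, so their extrema sit at corners; the
hybrid population is not (∂/∂p_i changes sign at p_j = 0.5), so interior
edge points at p = 0.5 are included among the candidates. Widening a band
therefore widens every interval — a monotonicity that is tested.

Comparison statistics between simulated and experimental BII sets use the
Pearson (linear) correlation coefficient and Δ_av, defined here as the
mean of absolute per-phosphate differences with its SD across phosphates
(the definition matters and is stated because "average difference" alone
is ambiguous; the SD is computed across phosphates, not across duplexes).
The fraction of phosphates agreeing within the tolerance band is reported
alongside.

## Helical coupling

Conditional means and SDs are computed per pooled combination, either
pooling frames across all complementary steps or per step; frames are
weighted equally within a combination (no per-sojourn averaging).
Combinations with fewer than 100 frames (configurable) are suppressed —
an SD over a handful of autocorrelated frames is noise. The headline
couple is the difference of conditional means between the two homogeneous
extremes, BII•BII − BI•BI; the variability question (is BI•BI softer?) is
answered per step and summarised per parameter as a majority verdict over
eligible steps. Only descriptive statistics are reported, deliberately:
with strongly autocorrelated frames, hypothesis tests on these quantities
would be decoration.

## Topology conventions

Bases are numbered continuously: strand 1 is 1..L (5′→3′), strand 2 is
L+1..2L (also written 5′→3′), base j pairing base 2L+1−j. A step is
identified by its strand and the number of its 5′ base; the facing step of
a strand-1 step at base i starts at base 2L−i, and the facing map is an
involution whose step types are reverse complements (CpA ↔ TpG; CpG is
self-complementary). Terminal steps are excluded by default — terminal
base pairs fray in unrestrained simulations and their phosphates are not
comparable — leaving the central L−3 complementary steps of an L-mer
(9 for a dodecamer; 36 across the four shipped dodecamers). Analyses that
need a narrower window (for example dropping the penultimate steps as
well) pass an explicit step subset. Only unmodified, fully complementary
ACGT duplexes are supported.

## Validation scale and reproducibility

The validation suite exercises the pipeline at 10⁵ frames per trajectory
and 36 complementary steps — enough that Monte-Carlo error on the
factorisation checks is a fraction of a percentage point, while the whole
suite runs in about a minute. The stationary probabilities of the 36
validation steps span 0.05–0.8 on both strands, with the strand-2 ladder
assigned by a fixed stride permutation so the steps cover diverse
(p_i, p_j) combinations, as heterogeneous real duplexes do; an
anti-correlated assignment would make p_i + p_j nearly constant and
collapse the across-step spread that the correlation diagnostic
summarises. At persistence 0.99 each chain contributes an effective
sample of roughly n/199 frames, and the observed correlations (~0.99)
and simultaneous-transition fractions (~0.2%) are stable across seeds.

Degenerate inputs are rejected rather than repaired: ragged frame counts,
missing angles, steps absent from the topology, empty series. No missing
frames are imputed, because transition statistics are only defined on an
uninterrupted frame sequence.

## Known limitations

* The ambiguous trans/trans region is flagged, not modelled; data sets
  with substantial mass between the modes deserve a mixture treatment the
  package does not attempt.
* The effective-sample-size correction is a first-order AR(1) heuristic;
  it makes the association flags conservative, not exact.
* The NMR conversion's sequence-independence assumption is inherited,
  softened only by the tolerance band.
* Helical parameters are consumed, never computed: coordinate-level
  analysis belongs to the dedicated helicoidal tools whose tables the
  readers ingest.
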