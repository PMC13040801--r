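---
title: "ecosoc: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ecosoc: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecosoc)
```

This vignette is the package's own account of the science it implements:
the statistics, the movement model behind the synthetic-data generator, the
parameters that matter, the numerical conventions, and what the test suite
does and does not establish about real data.

## The habitat and the raw observable

The habitat is a ring of four compartments joined by tubular corridors,
with an RFID antenna at each end of every corridor. The only observable is
the stream of antenna reads: `(time, antenna, animal tag)`. A completed
crossing normally produces two reads, one per corridor end; reads can be
lost (dropout), and a mouse lingering at a compartment entrance can
re-trigger the same antenna repeatedly. Time is represented in seconds
since session start at millisecond resolution, and every interval in the
package is half-open `[start, end)`, so tracks concatenate without double
counting.

## Occupancy reconstruction

`reconstruct_occupancy()` assigns a location to the gap between each pair
of consecutive reads of one animal:

1. same antenna twice: the antenna's *home* compartment. Repeated
   same-antenna reads are overwhelmingly a mouse at the entrance, not in
   the corridor; fixing this convention keeps the machine deterministic.
2. the two antennas of one corridor within `max_transit_s`: `CORRIDOR`.
3. antennas of two different corridors that flank the same compartment:
   that compartment.
4. anything else — including rule 2's pattern with too long a gap, which
   indicates a missed read rather than a slow crossing: `UNKNOWN`.

`max_transit_s` defaults to 30 s: one to two orders of magnitude above a
physical corridor crossing (~2 s) and far below typical compartment dwell
times (minutes), so the classification is insensitive to its exact value.
Time before the first and after the last read is `UNKNOWN`. `UNKNOWN` time
is excluded from every downstream numerator *and* denominator, never
imputed; this is unbiased when dropout is ignorable (independent of
location), which holds in the simulator by construction and is a documented
limitation otherwise. Ties in event time are ordered by `(antenna, tag)`
purely to make the machine a total order.

## In-cohort sociability

For a pair *(i, j)* within one phase window, with both animals'
step-function tracks intersected on their common refinement:

- `T_ij` — pair-analyzable time: both animals compartment-located;
- `O_ij` — time both are in the *same* compartment;
- `p_i(c)` — animal *i*'s occupancy fractions, estimated **on the same
  pair-analyzable base** `T_ij`, so that the expectation
  `E_ij = T_ij · Σ_c p_i(c) p_j(c)` sees exactly the data the observation
  sees. Mixing bases would bias `O − E` wherever dropout differs between
  animals.

The statistic `s_ij = (O_ij − E_ij) / T_ij` is dimensionless in `[−1, 1]`.
The underlying quantity is a time difference; we divide by `T_ij` so that
values are invariant to phase length and comparable to the ±0.2 scale on
which such matrices are conventionally displayed. `s_ij` measures
co-occupancy *beyond* what the two animals' individual preferences explain:
two animals pinned to the same compartment all phase have `s = 0`, because
perfectly concentrated preferences already predict their togetherness. The
statistic detects *correlated movement*, not mere co-location.

Undefined pairs (`T_ij = 0`) propagate as missing, never as 0 — a 0 is a
substantive claim of independence, which absent data cannot support.

The per-mouse summary is a two-stage mean — over defined partners within a
phase, then over phases in which the mouse is defined (default assessment
phases: the dark phases of days 3–5; days 1–2 are adaptation, during which
group structure is still forming). The odor-approach measure is a ratio of
smoothed stimulus/neutral occupancy ratios between the test dark phase
(default `dark6`) and the preceding baseline (`dark5`):
`[(t_s + ε)/(t_n + ε)]_test / [(t_s + ε)/(t_n + ε)]_base` with `ε = 1` s.
The underlying description ("proportion of time relative to the
corresponding period") does not fix a zero-handling rule or whether the
contrast is a ratio or difference; we declare the ratio-of-ratios with
additive smoothing as this package's convention (`ε` configurable), since
it is self-calibrating (identical behavior gives exactly 1) and defined
when a compartment was never entered.

## The movement simulator

No quantitative movement model is published for this class of habitat; the
simulator's dynamics are entirely this package's own and exist to make the
pipeline falsifiable against planted ground truth.

It is a continuous-time Markov chain over the joint state of all mice.
Mouse *i* in compartment *c* leaves with hazard

`λ_phase · exp(−κ_stay · Σ_j a_ij · 1[j co-located])`

and moves to ring neighbour *c′* with probability proportional to

`exp(pref_i(c′) + κ_dest · Σ_j a_ij · 1[j in c′])`.

Leaving is preference-neutral (preferences act on destination choice only),
so with zero affinity the embedded chain is a preference-weighted random
walk. Between state changes all hazards are constant, so sampling is exact
Gillespie: total rate, exponential waiting time, categorical
mover/destination. A move emits the origin-side antenna read at departure
and the destination-side read `transit_s` later; each read is dropped
independently with probability `p_miss`. Mice in transit exert and feel no
affinity (co-location is compartment-defined) and arrivals are
deterministic scheduled events; the exponential redraw after each event is
valid by memorylessness.

Defaults, chosen once as plausible for nocturnal group-housed mice and not
revisited: `leave_rate_dark = 1/300` s⁻¹, `leave_rate_light = 1/900` s⁻¹
(dark-phase activity dominance), `transit_s = 2` s, `κ_stay = κ_dest = 1`,
`p_miss = 0`, 12 mice, six 12 h/12 h days. These are simulator
conventions, not claims about any published cohort.

Two regimes of the affinity model deserve note. The leaving hazard falls
exponentially in the summed affinity of co-located partners, so a clique of
*g* mice with pairwise affinity *a* has per-mouse escape hazard
`λ·exp(−a(g−1))`: at `a = 1.5` a group of six effectively freezes
(`e^{−7.5} ≈ 5·10⁻⁴`), emitting almost no events, while a group of three
stays mobile. Structure-recovery analyses therefore use two groups of
three; the demo pipeline scales within-group affinity as `3/(g−1)` so the
total co-located coupling is comparable at any cohort size. An odor phase
adds a per-mouse increment `δ_i` to the preference for the stimulus
compartment during that phase only; because leaving is preference-neutral,
occupancy shifts through destination choice and saturates well below 1 on
a ring — the recovery tests compare biased against unbiased animals rather
than against an absolute occupancy level.

What the generator does **not** emulate: realistic circadian activity
curves (rates switch discretely at phase boundaries), body-contact
interactions, within-compartment spatial structure, tag-read collisions, or
location-dependent dropout. Tests passing on simulated data therefore
validate the estimators' *arithmetic and statistical* behavior (null
centering, parameter recovery, graceful degradation), not the biological
fidelity of any particular cohort.

## Assays and the composite score

The closed-form measures are literal: `SI = (TS − TNS)/(TS + TNS)`;
percent correct = first nosepokes on the reward side over visits to the
rewarded corner in a session; sucrose preference = reward-bottle licks over
total licks; ΔΔCt fold change = `2^(−ΔΔCt)` with technical replicates
averaged on the Ct scale (the least surprising convention; efficiency
correction is out of scope). Marble counts enter as raw integers 0–12; the
two-thirds-buried judgment is an upstream manual measurement.

The composite score min-max standardizes four parameters —
sociability, odor approach, preference index, marbles — across the supplied
cohort, averages the two social-interest measures so the three domains
(social interaction, social interest, repetitive behavior) weigh equally,
inverts the prosocial domains (`1 − x`), and sums:
`score = (1 − std_soc) + (1 − std_interest) + std_marbles ∈ [0, 3]`.
Two choices are exposed rather than hard-coded:

- **the standardization cohort is exactly the set of profiles passed in** —
  whether scores are standardized within one sex, one genotype or the whole
  experiment changes the meaning of the extremes and belongs to the caller;
- **a degenerate (constant) parameter maps to 0.5 for every animal**, with
  a logged warning: the score stays defined while that domain contributes
  no discrimination, which is exactly what a constant column carries.

Animals with any missing parameter are excluded from standardization and
output (a min-max over a partially observed column would redefine the
extremes for everyone else).

## Gene-set filtering and overlap

Significance is strict on both sides — `|log2FC| > 1` and adjusted
`p < 0.05` — matching the usual printed criteria literally; boundary
behavior is unit-tested. Missing adjusted p-values are non-significant
(the convention of independent-filtering pipelines, which emit `NA` for
untestable genes). The universe size `N` is a required argument with no
default: enrichment against an unstated universe is meaningless, and a
silent default would fabricate it. The worked example's `N = 17,516` is the
arithmetic inversion of a published 6.9-fold representation factor with
`k = 31`, `n_a = 77`, `n_b = 1022`; it is used in examples and tests only,
never as a default.

The upper-tail hypergeometric probability
`P(X ≥ k) = Σ_{i=k}^{min(n_a,n_b)} C(n_a,i) C(N−n_a, n_b−i) / C(N, n_b)`
is computed from log-gamma terms combined by log-sum-exp and kept in
natural-log space end-to-end, because overlaps of realistic DEG sets
produce probabilities (1e-19 and far below) that underflow naive summation.
The implementation is cross-checked in the suite against both
`stats::phyper(log.p = TRUE)` and exhaustive subset enumeration for every
configuration with `N ≤ 15`. Benjamini–Hochberg adjustment is validated
against a hand-written textbook step-up; the exported `bh_adjust()`
delegates the computation to `stats::p.adjust(method = "BH")` after
validation.

The paired-table generator plants a shared true-DE module: null genes get
uniform p-values and `N(0, 0.25)` log fold changes; true-DE genes get
`p ~ Beta(α, 1)` with `α = 1/(1 + effect²)` drawn by inverse CDF — so a
saturating effect size drives p-values to exact 0 and the planted overlap
is recovered deterministically — and `|log2FC| ~ N(effect, 0.25)` with
random signs, concordant between tables for shared genes (a shared module
perturbs expression in the same direction in both models; overlap counts
are direction-agnostic, so this affects realism, not recovery).

## Numerical conventions and problem sizes

- Event times are written as integer milliseconds; simulator output is
  rounded to the same resolution so files round-trip exactly.
- Pair statistics are computed by exact interval sweeps on the common
  refinement of two tracks, not by discretization. The suite's independent
  grid oracle evaluates tracks whose boundaries were snapped to whole
  seconds, on which a 1-s tally is an exact integral, making the comparison
  meaningful at 1e-6 relative tolerance.
- The null-centering property of the sociability statistic is asserted on
  the *mean of signed* `s` over pairs and phases (|mean| < 0.01 under the
  default independent 12-mouse, 6-day configuration). Individual pair
  values carry sampling noise of order `sqrt(dwell/phase) ≈ 0.03`, which is
  intrinsic to a 12 h window and ~300 s dwell times, so the mean of
  *absolute* values is not a null-centering diagnostic.
- Suite problem sizes: null and tracking-agreement checks use the full
  12-mouse/6-day default; structure recovery uses 10 seeds of two groups of
  three on the 6-day protocol; grid-equivalence checks use single-dark-day
  sessions. These sizes give comfortable statistical margins while keeping
  the whole suite around a minute.
- All simulators take explicit integer seeds; identical configuration and
  seed give byte-identical output files.

## Known limitations

- Reconstruction is validated against the package's own simulator, not
  against any vendor tracking library; rule 1 (same-antenna reads →
  home compartment) is a convention that a mouse idling *inside* a corridor
  would violate.
- Under non-ignorable dropout (for example, a failing antenna), excluding
  `UNKNOWN` time biases occupancy fractions toward the working antennas'
  compartments; the package reports analyzable-time denominators so such
  cases are visible, but does not correct them.
- The sociability statistic's plug-in expectation uses preferences
  estimated from the same window, which slightly attenuates extreme values
  in short windows; the suite's null check bounds the net effect.
- The composite score is cohort-relative by construction: scores are not
  comparable across cohorts standardized separately.
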