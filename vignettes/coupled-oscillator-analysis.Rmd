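---
title: "Methods: coupling analysis of fast and slow bursting oscillators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupling analysis of fast and slow bursting oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstcoupling)
```

This vignette documents the models, estimators and numerical choices
behind `burstcoupling`, in the spirit of a statistical methods section:
what is computed, under which assumptions, which defaults matter and why,
and what the synthetic data generator does and does not emulate.

## The biological setting

Two motor rhythms coexist in the crustacean stomatogastric ganglion: a
fast pyloric rhythm (~1 s period at 11 °C, indexed by PD neuron bursts)
and a slow gastric mill rhythm (~6–25 pyloric cycles per period, indexed
by LG bursts). The LG neuron fires when rhythmic disinhibition, timed by
the pyloric pacemaker, lets it cross threshold, so its burst onsets are
tied to a particular phase of the fast cycle and its period is built from
whole fast cycles — *integer coupling*. A third neuron, DG, bursts on the
gastric timescale but is not directly coupled to the pacemaker and serves
as a natural negative control. Both rhythms speed up with temperature;
the scientific question the pipeline addresses is whether their
coordination survives that joint speed-up.

## Burst detection

Bursts are defined purely from inter-spike intervals (ISIs): a maximal
run of spikes whose internal ISIs are all `<= gap_threshold` is a burst
candidate, and candidates with fewer than `min_spikes` spikes are
discarded entirely (their spikes belong to no burst). Burst period is
start-to-start between consecutive *retained* bursts; this is forced by
the duty-cycle definition duration/period, which must stay below 1. The
last burst of an epoch has no defined period and is excluded from
frequency summaries. Bursts are never merged across epoch boundaries.

Defaults: slow units (LG, DG, and unrecognized labels) use a 1 s gap and
`min_spikes = 5`; fast pacemaker units (PD, AB) use `min_spikes = 2` and a
0.2 s gap. The 1 s slow-unit gap is the field's standard for
gastric-timescale neurons. **The fast-unit gap is a package decision**:
a 1 s gap would merge consecutive pacemaker bursts, whose whole period is
about 1 s at 11 °C and shorter when warm; 0.2 s sits between the
within-burst ISI (~0.06 s at the defaults) and the shortest inter-burst
gap in the supported temperature range. If your fast unit's period is far
from ~1 s, set `gap_threshold` explicitly.

A boundary ISI exactly equal to the gap counts as *within* the burst
(the partition rule is `ISI > gap` separates bursts), matching the
convention that an inter-burst interval must be *longer than* the gap.

## Thermal scaling (Q10)

For each group, the mean burst frequency at temperature $T$ is
$f_T = \mathrm{mean}(1/P_i)$ over bursts with defined period $P_i$
(`frequency = "mean_rate"`). The alternative $1/\mathrm{mean}(P_i)$ is
available via `frequency = "inverse_mean_period"` because "mean burst
frequency" is ambiguous between the two conventions; the mean of
reciprocals is the default since the frequency of each cycle, not of the
average cycle, is the quantity being rescaled by temperature.

The temperature coefficient is
$Q_{10} = (f_T/f_{\mathrm{ref}})^{10/(T-T_{\mathrm{ref}})}$, undefined at
the reference temperature itself. Two reductions to a single summary per
group are implemented:

* `method = "mean"` (default): the arithmetic mean of per-temperature
  Q10s. Simple and interpretable, but temperatures close to the reference
  amplify frequency noise through the exponent $10/(T-T_{\mathrm{ref}})$.
* `method = "log_regression"`: least squares of
  $\log(f_T/f_{\mathrm{ref}})$ on $(T-T_{\mathrm{ref}})/10$ through the
  origin, returning `exp(slope)`. More robust when many temperatures are
  available; the origin constraint reflects that $f_{T_{\mathrm{ref}}} =
  f_{\mathrm{ref}}$ by definition.

Both are exposed because the single-number-per-preparation reduction is a
genuinely open design choice; the default is the mean per step.
`compare_q10()` applies a paired t test to per-preparation Q10s of the two
rhythms so each animal contributes equally; zero-variance differences are
flagged (`degenerate = TRUE`) with `t = 0, p = 1` for identical groups
and an infinite `t` otherwise, rather than erroring.

## Integer coupling

For each slow burst period (window $[s_i, s_{i+1})$, half-open so a fast
burst starting exactly at a slow burst start belongs to the window it
opens), the mean period of fast bursts starting inside the window — and
having a defined period themselves — forms one period pair. The
significand of the ratio clusters near 0/1 under integer coupling.

The coupling statistic is the unsigned area $\int_0^1 |F(x) - x|\,dx$
between the empirical significand c.d.f. and the diagonal, computed in
closed form from the staircase, never from a grid. The unsigned integrand
is required: perfect coupling splits mass between 0 and just below 1, and
a signed integral would cancel those two halves to 0 instead of the
maximal 0.25. The cost of the unsigned definition, documented here as a
metric limitation, is that one-sided clustering at 0 alone scores 0.5 and
symmetric clustering at 0.5 also scores 0.25; the c.d.f. plot and the KS
test disambiguate these shapes.

Uncertainty and significance:

* A pointwise percentile bootstrap band (default 1000 resamples, level
  0.95, evaluated on a 1001-point grid) accompanies the c.d.f. The band
  level is a package default — configurable because it is a presentation
  choice, not part of the statistic.
* The null is generated by permuting the slow-period list against the
  fast-period-mean list: this destroys coupling while preserving both
  marginal distributions. A one-sample test against the exact uniform is
  deliberately avoided — ratios of randomly paired periods from bounded
  ranges need not have uniform significands.
* The two-sample Kolmogorov–Smirnov test compares observed significands
  with the significands of one designated shuffle (the first), keeping
  the two sample sizes equal so test power is comparable across
  temperatures; the remaining shuffles only populate the null area band.
  Pooling many shuffles into the null sample would inflate the apparent
  precision of the null c.d.f. and is not done.
* Tests are run per temperature, pooling preparations; the significance
  threshold is Bonferroni-corrected, $\alpha$ divided by the number of
  temperature steps analysed.

A Spearman rank correlation of ratio against temperature (midranks for
the tied, discrete protocol temperatures) checks whether the *number* of
fast cycles per slow cycle trends with temperature; constant ratios make
the correlation undefined and are flagged rather than scored.

## Phase locking

Phase within the fast cycle is linear by assumption:
$\phi(t) = (t - s_k)/P_k$ for $t \in [s_k, s_{k+1})$. Times before the
first or at/after the last fast burst start have undefined phase and are
excluded by callers (with counts logged). Phases live in cycle units
$[0, 1)$ at every interface and are converted to radians only inside the
circular mathematics, so axes and configured lock phases read directly in
fractions of the fast cycle.

Per (preparation, temperature) unit, only the **first 40** slow burst
starts with defined phase enter the analysis; units with fewer are
excluded entirely. The cap equalizes each unit's weight and avoids
time-dependent confounds (e.g. rhythm slow-down within a hold); applying
it before pooling is essential, otherwise long recordings dominate.

Circular summaries: mean direction from the resultant vector, mean
resultant length $R \in [0,1]$, circular SD $\sqrt{-2\ln R}$ (back in
cycles). $R$ numerically zero (antipodal configurations) flags the mean
as undefined. The Rayleigh statistic is $z = nR^2$ with the classical
small-sample closed-form p
$\exp\{\sqrt{1 + 4n + 4(n^2 - R_n^2)} - (1 + 2n)\}$, $R_n = nR$ — the
same approximation used by the standard circular-statistics toolboxes.
The test suite cross-checks it against a Monte-Carlo permutation null at
$n = 8$ rather than against another library.

Burst-aligned rasters re-plot fast spikes in a ±3 s window around each
slow burst start, normalizing time by the mean period of fast bursts
whose starts fall inside *that row's* window (edge ties included); rows
with no in-window fast burst are dropped with a logged count. Phase
histograms default to 25 bins — fine enough to resolve a lock-phase peak
at the typical 40–400 burst starts per group without leaving most bins
empty; the count is configurable since no principled default exists.

## The synthetic generator

The generator emulates exactly the structure the estimators assume:

* **Pacemaker**: renewal process with mean period
  $P(T) = P_{\mathrm{ref}} \cdot Q_{10}^{-(T-T_{\mathrm{ref}})/10}$
  (defaults $P_{\mathrm{ref}} = 1$ s at 11 °C, $Q_{10} = 2$), constant
  duty cycle 0.3 across temperature, 6 spikes per burst, multiplicative
  log-normal period jitter (CV 0.02) so periods stay positive.
* **Coupled slow unit**: each burst starts at lock phase 0.5 (Gaussian
  jitter SD 0.02 cycles, wrapped) of the pacemaker cycle exactly $k$
  cycles after the previous burst's anchor, $k$ resampled uniformly on
  5–25 per burst. Building the slow period from whole pacemaker cycles —
  rather than drawing a period and snapping it — mirrors the biological
  mechanism (pacemaker-timed disinhibition) and guarantees the integer
  structure the analysis is meant to detect. Burst duration is 0.4 of the
  slow period, spikes at 20 Hz; ground truth (k sequence, anchor cycles,
  realized phases) is returned alongside. Excessive lock jitter that
  would reorder bursts raises an error instead of producing a
  non-monotone train.
* **Uncoupled slow unit**: renewal process with mean period
  $\bar k \cdot P(T)$ (same timescale as the coupled unit), period CV
  0.1, independent of any pacemaker; an optional per-cycle slow-down
  factor models rhythm non-stationarity and defaults to 0.

Defaults are the study conditions where the biology pins them down
(reference 11 °C, ~1 s fast period, Q10 ≈ 2, k spanning 5–25, lock phase
≈ 0.5, constant pacemaker duty cycle) and field-plausible round numbers
elsewhere (duty cycles, 20 Hz intra-burst rate, jitter CVs chosen small
enough that construction tests are sharp but nonzero so nothing is
degenerate). The slow units' period jitter in particular is not fitted
to any dataset — no quantitative value is published — so recovery
tolerances on jittered data are properties of these chosen CVs, not of
real recordings.

What the generator does *not* emulate: membrane-potential dynamics,
temperature transients between holds (temperature changes take effect
instantly at step boundaries; analyses only use data within holds),
rhythm drop-out at temperature extremes, epoch-to-epoch variability in
coupling strength, and recording artifacts (lost spikes, unit confusion).
Passing recovery tests therefore demonstrates estimator correctness under
the assumed data-generating process, not robustness to everything real
recordings do.

Determinism: every generator takes a seed (sub-seeds with fixed offsets
separate the three units' streams, so the uncoupled unit is genuinely
independent of the pacemaker), and identical configuration plus seed
yields byte-identical spike tables. The pipeline derives per-stage seeds
from one top-level seed by fixed offsets so stages can be rerun
independently.

## Numerical choices and degenerate inputs

* Spike times are full-precision doubles; tables are written with 17
  significant digits so read(write(x)) is exact.
* Duplicate spike times are physically impossible and collapse to one
  spike with a warning; unsorted input is sorted with a warning.
* Empty trains yield empty burst sequences, not errors; groups with a
  single burst (no defined period) are flagged missing and skipped by
  Q10, not averaged.
* The area integral, KS statistic and circular statistics are exact
  given their samples; the only grid in the package is the (cosmetic)
  c.d.f. band evaluation grid.
* Asymptotic two-sample KS p values are used (per-temperature pooled
  samples are large); ties across the two significand samples are
  theoretically null events and tolerated silently.

## Problem sizes

Scales used by the shipped tests and the reproduction script, chosen as
the package's own benchmark conditions:

* Construction and oracle tests run on trains of tens to hundreds of
  bursts (epochs of 100–3500 s); Monte-Carlo calibration loops use 50–100
  seeded replicates.
* Q10 recovery runs the full pipeline on a 7–21 °C protocol (steps 7, 11,
  15, 19, 21 °C, 300 s holds). Because the coupled unit's cycles-per-burst
  spans 5–25, a single preparation yields only ~15–40 slow periods per
  temperature and a per-preparation Q10 with double-digit relative spread;
  the benchmark therefore pools bursts from 100 simulated preparations per
  temperature before computing frequencies — the same
  pooling-across-preparations the per-temperature coupling statistics use
  — which brings the Monte-Carlo spread of the summary Q10 to about 1%.
* The worked example in the README uses 10 preparations, which is enough
  for the per-temperature KS tests (140–400 pairs per temperature) but
  not for a tight slow-unit Q10 from any single preparation.

## Known limitations

* The area metric cannot distinguish symmetric 0/1 clustering from
  clustering at 0.5 (both 0.25); inspect the c.d.f.
* The ISI rule is threshold-based by design; neurons whose within-burst
  ISIs overlap their inter-burst gaps need a different detector
  (model-based detection is out of scope).
* Q10 assumes a single exponential scaling regime across the analysed
  range; it will average over, not detect, a break point (e.g. a rhythm
  "crashing" at high temperature).
* The two-sample KS test conditions on one designated shuffle; its p
  value inherits that shuffle's sampling noise (small for the pooled
  sample sizes the pipeline targets).
* Phases require at least two fast bursts per epoch and are undefined in
  the final (open) fast cycle; slow events there are dropped, which
  slightly under-samples the end of every epoch.
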