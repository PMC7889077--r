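# burstcoupling

Analysis of coordination between a fast and a slow bursting neuronal
oscillator recorded across temperature, modelled on the pyloric (~1 Hz,
indexed by PD neuron bursts) and gastric mill (~0.1 Hz, indexed by LG
neuron bursts) rhythms of the crustacean stomatogastric ganglion. The
package is aimed at circuit electrophysiologists who have spike-sorted
recordings of two coupled central pattern generators — or want to prototype
such an analysis on simulated data — and need to answer three questions:

1. **Thermal scaling.** How does each rhythm's burst frequency scale with
   temperature? Quantified by the temperature coefficient
   `Q10 = (f_T / f_ref)^(10 / (T − T_ref))`, the factor by which the mean
   burst frequency `f` changes per 10 °C, relative to a reference
   temperature (default 11 °C).
2. **Integer coupling.** Does the slow rhythm's period stay an integer
   multiple of the fast rhythm's period? For each slow burst period `P_slow`
   and the mean fast period `P̄_fast` within it, the *significand*
   `s = P_slow/P̄_fast − ⌊P_slow/P̄_fast⌋` clusters near 0 and 1 under
   integer coupling. The degree of coupling is the unsigned area
   `∫₀¹ |F(s) − s| ds` between the empirical c.d.f. of significands and
   the diagonal: 0.25 for perfect integer coupling, ~0 for uniform
   significands, computed exactly from the staircase. Significance comes
   from a two-sample Kolmogorov–Smirnov test against significands of
   shuffled period pairings (Bonferroni-corrected across temperature
   steps), with bootstrap confidence bands on the c.d.f.
3. **Phase locking.** At what phase of the fast cycle does the slow unit
   start bursting, and is that phase distribution non-uniform? Burst-start
   phases (first 40 per preparation and temperature, to avoid
   time-dependent confounds) are summarized by circular statistics —
   circular mean, resultant length `R`, circular SD — and tested with the
   Rayleigh statistic `z = nR²`.

A synthetic spike-train generator produces a temperature-scaled pacemaker,
an integer-coupled slow unit (built from whole pacemaker cycles, with a
configurable lock phase) and an uncoupled slow unit of the same timescale,
with ground-truth labels, so the entire pipeline can be exercised and
calibrated without raw recordings.

## Worked example

Simulate ten preparations over a 7–21 °C step protocol (300 s holds),
detect bursts, and run all three analyses:

```r
library(burstcoupling)

protocol <- temperature_protocol(c(7, 11, 15, 19, 21), duration = 300)
recs <- lapply(1:10, function(i)
  generate_recording(generator_config(seed = 42L), protocol,
                     preparation_id = sprintf("prep%02d", i),
                     seed = 42L + 10L * i))
seqs   <- unlist(lapply(recs, detect_bursts_all), recursive = FALSE)
bursts <- bursts_tbl(seqs)

## Q10 of burst frequency, per preparation, then fast vs slow rhythm
scaling <- preparation_q10(bursts, reference_temperature = 11)
q_pd <- scaling$summary$q10[scaling$summary$neuron == "PD"]
q_lg <- scaling$summary$q10[scaling$summary$neuron == "LG"]
compare_q10(q_lg, q_pd, paired = TRUE)
#> $t [1] -0.577   $p [1] 0.578   $df [1] 9   $n [1] 10
```

Both rhythms scale with a Q10 near the configured 2, and the paired t test
finds no difference between them — temperature speeds both rhythms up
together.

```r
## integer coupling of the coupled slow unit (LG) to the pacemaker
fast <- Filter(function(s) s$neuron == "PD", seqs)
lg_pairs <- pair_periods_all(Filter(function(s) s$neuron == "LG", seqs), fast)
integer_coupling_analysis(lg_pairs, n_boot = 500, n_shuffle = 500, seed = 42)
#> <coupling_analysis> 5 temperature(s), threshold p < 0.01
#> <coupling_result>  7 degC: n = 144, area = 0.2263 (null mean 0.1582), D = 0.319, p = 8.3e-07 *
#> <coupling_result> 11 degC: n = 188, area = 0.2256 (null mean 0.1429), D = 0.319, p = 9.66e-09 *
#> <coupling_result> 15 degC: n = 240, area = 0.2239 (null mean 0.1588), D = 0.304, p = 4.55e-10 *
#> <coupling_result> 19 degC: n = 330, area = 0.2261 (null mean 0.1635), D = 0.294, p = 8.29e-13 *
#> <coupling_result> 21 degC: n = 392, area = 0.2245 (null mean 0.1625), D = 0.306, p = 2.22e-16 *
#> ratio vs temperature: Spearman rho = 0.004, p = 0.893 (n = 1294)
```

The coupled unit's significand c.d.f. area sits near the 0.25 ceiling and
clears the shuffled null at every temperature (`*` marks p below the
Bonferroni threshold 0.05/5). The number of fast cycles per slow cycle
shows no trend with temperature (Spearman p = 0.89): coupling is
maintained, not renegotiated, as both rhythms speed up. Running the same
analysis on the uncoupled unit (DG) gives areas of 0.015–0.038 inside the
null band and no significant temperature (p ≥ 0.61).

```r
## phase locking at 11 degC
samp <- burst_start_phases(
  Filter(function(s) s$neuron == "LG" && s$temperature == 11, seqs),
  Filter(function(s) s$temperature == 11, fast), first_n = 40)
phase_stats(samp)
#> <phase_stats> n = 40: mean phase 0.500, R = 0.995, circ sd 0.016,
#>               Rayleigh z = 39.59, p = 2.26e-29
```

The slow unit starts bursting at phase 0.5 of the pacemaker cycle — the
generator's configured lock phase — with near-maximal concentration.

`run_all(run_config(...))` chains all stages (simulate/load → bursts → Q10
→ coupling → phase) and writes tidy tables, JSON summaries and a manifest
of file hashes; `inst/scripts/oscillation_pipeline.R` exposes the same
stages as shell subcommands.

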