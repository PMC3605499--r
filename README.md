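# phasereplay

Associative memory for **phase-coded spike patterns** in a recurrent leaky
integrate-and-fire (spike-response) network.

Many brain circuits appear to store information in *phase-of-spike* codes:
periodic spatiotemporal patterns in which what matters is the precise
relative phase of each neuron's spike within a collective oscillation.
`phasereplay` implements, simulates, and analyses a network model in which
several such patterns are stored in the recurrent connectivity through a
spike-timing-dependent plasticity (STDP) rule, each becoming an attractor of
the dynamics: a brief cue of a few spikes selectively ignites a
self-sustained, possibly time-compressed, replay of one stored pattern. The
package is for computational neuroscientists who want to reproduce,
perturb, or extend this class of models: it provides the learning rule, the
network simulator (Rcpp core), the overlap order parameter used to score
replay, and the experiment harness for storage capacity, regime, and
robustness analyses.

## Model

*Patterns.* Pattern `μ` assigns each of `N` neurons a phase
`φ_i^μ ~ U[0, 2π)` and a storing frequency `ν^μ`; neuron `i` spikes at times
`φ_i^μ/(2πν^μ) + n/ν^μ` — one spike per cycle.

*Learning.* Each ordered pair contributes through the asymmetric STDP window

```
A(τ) = a_p e^{-τ/T_p} − a_D e^{-ητ/T_p}     (τ > 0)
A(τ) = a_p e^{ητ/T_D} − a_D e^{τ/T_D}       (τ < 0)
```

with `a_p = γ[1/T_p + η/T_D]⁻¹`, `a_D = γ[η/T_p + 1/T_D]⁻¹`
(`T_p = 10.2 ms`, `T_D = 28.6 ms`, `η = 4`, `γ = 0.42`), which integrates to
zero — the origin of the network's excitation/inhibition balance. The learned
weight from `j` to `i` is the periodic pairwise sum
`J_ij = Σ_μ Σ_n A(t_i^μ − t_j^μ + nT^μ)`, with no self-connections.

*Dynamics.* Spike-response formulation of the leaky IF neuron: the membrane
potential is `h_i(t) = Σ_j J_ij Σ_{t̂_j > t̂_i} ε(t − t̂_j)` with the
peak-normalised double-exponential kernel
`ε(t) = K(e^{-t/τ_m} − e^{-t/τ_s})Θ(t)` (`τ_m = 10 ms`, `τ_s = 5 ms`,
`K = 4`). Crossing the threshold `θ_th` emits a spike and resets the unit,
discarding its input memory. Optional Poissonian input noise and
heterogeneous per-unit thresholds.

*Scoring.* The overlap order parameter

```
|m^μ(t)| = |(1/N) Σ_j e^{-i2πt_j*/T*} e^{iφ_j^μ}|
```

(`t_j*` the most recent spike of `j`, `T*` the estimated collective period)
is 1 for a perfect phase-aligned replay at *any* time scale and of order
`1/√N` for unrelated activity. Runs are classified as *retrieval*,
*spurious*, or *silent*.

## Worked example

Store five patterns at 3 Hz in an `N = 3000` network, cue the first, and
score the replay:

```r
library(phasereplay)

pats <- generate_pattern_set(5, n_units = 3000, frequency_hz = 3, seed = 1)
J    <- build_connectivity(pats)
cue  <- make_cue(pats[[1]])            # M = N/10 spikes, T_stim = 50 ms
tr   <- simulate_network(J, theta = 70, duration = 1000, cue = cue)

classify_regime(tr, patterns = pats)
#> <retrieval_result> retrieval of pattern 1 (|m| = 0.998), replay 15.0 Hz,
#>   1.00 spikes/cycle, S_tot = 44948
```

The cued pattern is replayed with overlap `|m^1| ≈ 0.998` while the other
stored patterns stay at the `1/√N` floor (`|m^2| ≈ 0.011`): the 3 Hz pattern
is replayed time-compressed at ~15 Hz, phase relationships intact. Raising
`theta` slows the replay until, near `θ ≈ 90` (for one stored pattern), the
network can only answer the cue with a brief transient; lowering it
accelerates replay toward ~30 Hz and eventually (at very low `theta`, or
with more patterns than the capacity) tips the network into spurious
activity uncorrelated with every stored pattern:

```r
autoplot(tr, sort_by = pats[[1]])           # raster, units sorted by phase
autoplot(overlap_series(tr, pats))          # |m^mu(t)| trajectories
persistence_sweep(seq(60, 120, 5), 3, 3000) # P(S_tot > n), theta_crit
```

## Package layout

- `R/patterns.R` — phase patterns, sampling, spike-time generation
- `R/plasticity.R` — STDP window, periodic pairwise sums, connectivity
- `R/dynamics.R` — kernel, cue, noise, heterogeneity, network simulation
- `R/analysis.R` — period estimation, overlaps, regimes, per-unit rhythms
- `R/experiments.R` — retrieval/capacity/persistence/frequency sweeps
- `R/io.R`, `R/cli.R` — file formats, manifests, `inst/cli/phasereplay`
- `src/core.cpp` — Rcpp inner loops (weight sums, grid-stepped simulation)
- `vignettes/phase-coded-memory.Rmd` — methods and design notes
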