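---
title: "Storing and replaying phase-coded spike patterns: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Storing and replaying phase-coded spike patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasereplay)
```

## The model

`phasereplay` implements an associative memory whose items are *phase-coded
periodic spike patterns*: pattern $\mu$ assigns each of $N$ neurons one phase
$\phi_i^\mu$ drawn uniformly on $[0, 2\pi)$ and a storing frequency
$\nu^\mu$, so that neuron $i$ spikes once per cycle at
$t_i^\mu = \phi_i^\mu/(2\pi\nu^\mu) \pmod{1/\nu^\mu}$. Information lives in
the *relative* phases; the absolute time scale is free, which is what makes
time-compressed replay possible.

### Learning

During a (conceptual) learning stage, every ordered pair of spikes
contributes to the connection $j \to i$ through an asymmetric STDP window
$A(\tau)$ with $\tau$ the post-minus-pre lag:

$$A(\tau) = \begin{cases}
a_p e^{-\tau/T_p} - a_D e^{-\eta\tau/T_p} & \tau > 0\\
a_p e^{\eta\tau/T_D} - a_D e^{\tau/T_D}   & \tau < 0
\end{cases}$$

with $a_p = \gamma[1/T_p + \eta/T_D]^{-1}$,
$a_D = \gamma[\eta/T_p + 1/T_D]^{-1}$ and defaults $T_p = 10.2$ ms,
$T_D = 28.6$ ms, $\eta = 4$, $\gamma = 0.42$ (a fit to hippocampal-culture
pairing experiments). With these amplitudes $\int A = 0$ *exactly* — the
balance condition. For periodic patterns the pairwise contributions collapse
into the periodic sum

$$J_{ij} = \sum_{\mu=1}^P \sum_{n} A\!\left(t_i^\mu - t_j^\mu + nT^\mu\right),$$

implemented in `pairwise_weight()` / `build_connectivity()`. Two remarks on
conventions that are easy to get wrong:

* **Lag orientation.** The weight from pre $j$ to post $i$ uses the
  post-minus-pre lag $t_i - t_j$. The opposite orientation produces a
  network that replays every pattern *time-reversed* (we verified this
  directly: the replay then has overlap $\approx 0.99$ with the
  phase-conjugated pattern and $\approx 0.1$ with the stored one), so the
  orientation is fixed by requiring forward replay.
* **$A(0)$.** Both branches share the limit $a_p - a_D$ at $\tau = 0$; we
  define $A(0)$ as that common value. Self-pairs never arise because the
  diagonal of $J$ is identically zero ($N(N-1)$ connections).

The infinite $n$-sum is truncated to every term whose window argument is at
most $50\,T_D$ in magnitude (plus one period of slack); the neglected tails
are below $10^{-12}$ and the truncation is tested against a brute-force
$n \in [-1000, 1000]$ oracle at $10^{-10}$.

*Learning-duration normalisation.* The underlying rate-based formulation
carries a factor $T/t_\mathrm{learn}$; it is absorbed into the per-pattern
sum above (equivalently, into $\gamma$), so no symbol for the learning
duration appears at runtime. Scaling $\gamma$ scales every weight exactly
linearly, and — because the dynamics below is threshold-linear — scaling all
weights is equivalent to scaling all thresholds down by the same factor.

### Excitation/inhibition balance

Because $\int A = 0$ and phases are uniform, each presynaptic neuron's
summed outgoing excitation $(1/N)\sum_i \max(J_{ij}, 0)$ and inhibition
$(1/N)\sum_i \min(J_{ij}, 0)$ are $O(1)$ in $N$ and cancel up to a
per-neuron residual that vanishes as $1/\sqrt N$ (a mean of $N$ zero-mean
terms). `balance_statistics()` reports exactly these per-neuron quantities.
The *whole-matrix* sums normalised by a single factor of $N$ — a tempting
alternative definition — do **not** decay with $N$ (the double sum is a
U-statistic whose fluctuations grow like $N$); we measured a log–log slope
of $\approx -0.08$ for that variant versus $-0.49$ for the per-neuron one,
and therefore adopted the per-neuron definition.

### Dynamics

Neurons follow the spike-response formulation of the leaky
integrate-and-fire model:

$$h_i(t) = \eta_i(t) + \sum_j J_{ij} \sum_{\hat t_j > \hat t_i}
\varepsilon(t - \hat t_j), \qquad
\varepsilon(t) = K\left(e^{-t/\tau_m} - e^{-t/\tau_s}\right)\Theta(t)$$

with $\tau_m = 10$ ms, $\tau_s = 5$ ms and $K$ fixed by
$\max_t \varepsilon = 1$ ($K = 4$ exactly at the defaults, peak at
$10\ln 2 \approx 6.93$ ms); thresholds are therefore measured in units of
the unitary PSP peak. When $h_i \ge \theta_i$ the unit fires and resets:
its entire presynaptic memory is discarded (the inner sum restarts at the
unit's own last spike, and arrivals at exactly that time are excluded as not
*strictly* later). A unit exactly at threshold fires.

Numerical scheme (`simulate_network()`, C++ core):

* **Fixed grid, default `dt = 0.1` ms.** Exact event-driven integration is
  a performance optimisation, not part of the model; a fixed grid makes runs
  bit-reproducible and trivially testable. The kernel is propagated by two
  exponential state variables per neuron, so cost per step is $O(N)$ plus
  $O(N)$ per spike.
* **One-step transmission.** Spikes emitted at step $t$ reach other units
  from $t + dt$ (automatic, since $\varepsilon(0) = 0$); units crossing
  together in one step all fire in that step. No unit can fire twice within
  a step.
* **Convergence.** The discretisation error manifests as a coherent phase
  drift of the whole replay wave, first order in `dt` (mean drift over the
  first 100 ms at $N = 300$: 1.55 ms for $dt: 0.2 \to 0.1$, 0.83 ms for
  $0.1 \to 0.05$); the collective period is step-independent to well under
  2% at the default step. A per-spike "no time moves by more than one coarse
  step" contract cannot hold along a limit cycle and is not claimed.
* **Cue.** `make_cue()` imposes $M = N/10$ spikes at times
  $T_\mathrm{stim}\phi_i/(2\pi)$ on the $M$ lowest-phase units of the
  pattern, so the whole stimulation spans about $T_\mathrm{stim}/10$ (5 ms
  at the defaults) — a brief, phase-ordered nudge (random unit selection is
  available). Cue events are imposed output spikes: they reset the cued
  unit and propagate through $J$.
* **Noise.** Input noise $\eta_i(t)$ injects external arrivals through the
  same kernel with i.i.d. Gaussian strengths
  $(\bar J_\mathrm{noise}, \sigma)$. The printed form of the interval
  density in the source material implies a per-unit mean interval of
  $N\tau_\mathrm{noise}$ (half a minute per neuron at $N = 3000$) — far too
  sparse to produce the documented spontaneous activity or to threaten
  retrieval at $\sigma = 30$. We read it as a typo and default to per-unit
  exponential intervals with mean $\tau_\mathrm{noise} = 10$ ms (100 Hz per
  neuron); `mean_interval_ms` exposes the literal reading. Under this
  default the documented ladder is reproduced quantitatively: retrieval
  survives $\sigma = 10$ and $20$ and collapses at $\sigma = 30$.
* **Heterogeneity.** $\theta_i = (1 + z\zeta_i)\theta$,
  $\zeta_i \sim U[-1, 1]$; $z \ge 1$ is rejected (non-positive thresholds).

### Scoring replay

The overlap order parameter

$$|m^\mu(t)| = \left|\frac{1}{N}\sum_{j\,:\,t_j^* \in (t - T^*,\, t]}
e^{-i 2\pi t_j^*/T^*} e^{i\phi_j^\mu}\right|$$

compares the phase of each unit's most recent spike against the stored
phase; the prefactor stays $1/N$ however many units contribute. It is 1 for
perfect phase-aligned replay at any time scale (tested under 2× compression
and dilation) and $O(1/\sqrt N)$ for unrelated activity.

$T^*$ is estimated by default as the median inter-spike interval over units
with at least two spikes in the analysis window; a grid search maximising
the overlap over candidate periods (default 5–500 ms) is available for
short or non-periodic trains. The source description does not fix the
estimator; the two agree within 2% on clean replays and the median-ISI
variant is the default for its robustness and speed.

Runs are classified (`classify_regime()`) as **silent** (no network spikes
after $\bar t = 600$ ms), **retrieval** (mean steady-state overlap with some
pattern above 0.5), or **spurious** (persistent but all overlaps at the
noise floor). Steady-state overlaps concentrate near 1 or near $1/\sqrt N$,
so the 0.5 threshold is uncritical; it is a named parameter, not a magic
number. Response size $S_\mathrm{tot}$ counts network spikes after the cue
ends.

Because low thresholds legitimately produce more than one spike per
collective cycle (a doublet or burst per cycle — the rate/phase
dissociation that is one of the model's points), per-unit rhythm analyses
(`unit_oscillation_periods()`) group spikes closer than $T^*/2$ into one
burst and measure the interval between burst onsets. In the heterogeneity
experiments at $z = 0.5$ (thresholds in $[40, 120]$ around $\theta = 80$),
all units whose individual thresholds lie inside the retrieval region lock
to a single collective period within well under 5%; units drawn *beyond*
the silent transition ($\theta_i \gtrsim 90$–$95$; one unit in 3000 in our
seeded run, at $\theta_i = 115.9$) may skip cycles and are outside the
uniform-frequency claim, exactly as too-large $z$ degrades retrieval
altogether.

## Experiments

`retrieval_success()` runs seeded realisations that cue pattern 1 and
averages the steady-state overlap $|m^1|$ at $t > \bar t = 600$ ms; success
means the average exceeds 0.5. With frozen weights and no noise a single
run is deterministic, so the run-average is an average over *pattern
realisations*: each run after the first redraws the patterns from its own
seed stream. `storage_capacity()` ascends $P$ (fresh patterns each $P$) and
stops at the first failure — the success/failure transition in $P$ is
sharp, so the first failure ends the search (a full sweep would only waste
the budget). Testing the cued pattern with fresh patterns per $P$ is
statistically equivalent to testing each stored pattern, by exchangeability
of i.i.d. patterns.

`persistence_sweep()` reports, per threshold, the fraction of realisations
whose response size exceeds $n \in \{0, N/2, N\}$ and whose activity
persists past $\bar t$; the critical threshold is the largest value with a
persistent majority. `frequency_vs_threshold()` maps replay frequency and
spikes per cycle across the retrieval region, flagging (not erroring on)
non-retrieval cells.

### Problem sizes and presets

The full protocol (50 runs per condition, fine grids) reproduces the
complete capacity surface and is cluster-scale; it is available through
`capacity_protocol()`. The shipped desk-scale presets (`desk_protocol()`,
5 runs, 5-unit threshold steps, 1000 ms runs with $\bar t = 600$ ms) are
what the test-suite and `scripts/acceptance.R` use: $N = 3000$ for the
regime boundary, robustness, and overlap measurements, $N = 1000$ for the
size-scaling replay-frequency check, $N \in \{250, 1000, 4000\}$ with 20
seeds for the balance-scaling fit, and $N \in \{100, 600\}$ toys for
end-to-end and selectivity unit tests. Persistent replay at 3 Hz needs
$N \gtrsim 200$ (at $N = 100$ the ~3 spikes per kernel window cannot
sustain the wave; the $N = 100$ toy therefore stores an 8 Hz pattern).

### The replay/storage time-scale crossing

Replay is time-compressed (faster than storage) for low stored frequencies;
the compression shrinks as the stored frequency grows. At the *top* of the
retrieval threshold range the replay is slowest, so the stored frequency at
which replay can first run at the storage time scale is where that minimal
replay frequency meets the identity line — in our desk-scale measurement
between 20 and 30 Hz (interpolated crossing near 24–26 Hz depending on
seed). For the size comparison at $N = 1000$, thresholds are matched across
network sizes at equal $\theta/N$ (the quantity the frequency actually
depends on), using the standard operating ratio $\theta/N = 0.025$ of the
$N = 3000$ examples.

## What the generator emulates — and what it does not

All inputs are synthetic by construction (the model's "data" are random
phase patterns): uniform independent phases, one spike per cycle, a common
stored frequency per pattern. Real recordings differ in ways the model
deliberately abstracts away: phases correlated across neurons and across
patterns, jittered and missing spikes during storage, heterogeneous firing
rates, conduction delays, and adaptation. Passing tests therefore
demonstrate the internal consistency and the claimed collective phenomena
of the model (attractor replay, capacity, compression, robustness), not
goodness-of-fit to any recorded dataset.

## Known limitations

* Dense $N \times N$ double-precision weights: $N = 10^4$ takes ~800 MB;
  beyond that a sparse or single-precision variant would be needed.
* The capacity surface at full fidelity (50 runs × fine grid × growing $P$)
  is cluster-scale; desk-scale runs use reduced presets and report them in
  their outputs.
* No conduction delays, refractory mechanisms beyond reset, or adaptation;
  online plasticity during retrieval is out of scope (weights are frozen
  after learning).
* The median-ISI period estimator assumes a dominant collective rhythm; for
  fragmented, strongly non-periodic trains use the overlap-maximising
  estimator.
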