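---
title: "Correcting Hodgkin-Huxley model error with reservoir-surrogate hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting Hodgkin-Huxley model error with reservoir-surrogate hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`reservoirHH`: the neuron model and its integration, the stimulus
generator, the reservoir and hybrid architectures, the training
conventions, the benchmark harness, and the known limitations.  Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The neuron model

The reference neuron is a single-compartment Hodgkin-Huxley model with
sodium (activation `m`, inactivation `h`), potassium (activation `n`) and
leak currents.  Gate kinetics use the tanh parameterisation: a sigmoidal
steady state `0.5 (1 + tanh((V - v_half) / dv))` (a negative `dv` encodes
inactivation — the same expression serves both gate directions) and a
bell-shaped relaxation time
`tau0 + eps_tau (1 - tanh^2((V - v_half) / dvt))` ranging from `tau0` far
from threshold to `tau0 + eps_tau` at threshold.

Units form a self-consistent point-neuron set: mV, ms, uF/cm^2, mS/cm^2,
uA/cm^2.  The shipped defaults (`default_neuron_params()`) are squid-like:
`gNa = 120`, `gK = 36`, `gL = 0.3`, `ENa = 50`, `EK = -77`, `EL = -54.4`,
`C = 1`, with relaxation times spanning 0.1–0.5 ms (`m`), 1–8 ms (`h`) and
1–6 ms (`n`).  They produce tonic spiking for step currents a few uA/cm^2
above rheobase and rest near −66.5 mV.  Every value is overridable through
the YAML configuration; no behavioural contract in the package depends on
these exact numbers.

A *surrogate* is produced by `detune()`: `gNa <- gNa (1 + eps_g)` (an
error entering the membrane equation linearly), `v_half` of the `m` gate
scaled by `(1 + eps_v)` and the whole `tau_m(V)` curve scaled by
`(1 + eps_tau)` (both nonlinear errors).  Scaling the whole `tau_m` curve
— rather than only one of its two constituents — follows from reading "the
recovery time" as the voltage-dependent function itself.  `eps_g <= -1` is
rejected (non-physical conductance).

### Integration

The disparate relaxation times make the system stiff enough that
fixed-step integration occasionally bifurcates onto spurious trajectories,
so all integration uses the embedded Cash-Karp 4(5) pair with standard
proportional step control: safety factor 0.9, growth capped at 5x,
shrinkage at 10x, step capped at the sampling interval and floored at
`1e-6` of it (a floor hit is reported; a non-finite state aborts reference
integration with a diagnostic, and is flagged — never thrown — during
closed-loop prediction).  Default tolerances are `rtol = 1e-8`,
`atol = 1e-10`.  The injected current is held constant across each
sampling interval (zero-order hold), which represents step protocols
exactly.  Gates are clamped to `[0, 1]` after every accepted step; clamp
events are counted on the returned trajectory.  The test suite checks the
integrator against an independent fixed-step classical RK4 oracle and
against `deSolve::lsoda` on the same vector field.

The resting state is found by root-finding on the steady-state current
balance; for heavily detuned surrogates that lose the hyperpolarised
equilibrium (depolarisation block) a grid scan locates the most
hyperpolarised remaining root.

## Stimulus design

Identifiability demands a drive that elicits both sub- and supra-threshold
behaviour and carries power across the gate relaxation rates; training on
either regime alone leaves gate kinetics (and readout weights)
unconstrained.  `mixed_protocol()` therefore interleaves two regimes at
exponentially distributed switch times (memoryless "random switching" with
configurable mean, default 50 ms): the `x` component of a Lorenz-63 system
(`alpha = 10`, `rho = 28`, `beta = 8/3`, initial condition `(1,1,1)`) and
a train of uniform random steps.  The concatenated series is rescaled by a
single affine map — preserving relative amplitudes across regimes — into
the target current range, `(-2, 22)` uA/cm^2 by default, chosen so the
default neuron spends substantial time on both sides of threshold
(verified in the tests by spike counts and subthreshold fractions).

The Lorenz time scale (ms per Lorenz time unit, default 25) sets where the
chaotic power sits.  Much faster chaos (a few ms per unit) concentrates
power near and above the fastest gate rate and produces a drive that no
trained predictor tracks through its own feedback loop; 25 ms/unit places
the dominant oscillations on the tens-of-ms scale of the slow gates while
step edges supply broadband content.  `protocol_bandwidth_check()` reports
the central-95% power band and flags (with a factor-of-two slack at each
edge, since spectra roll off smoothly) whether it spans
`[1/(2 pi tau_max), 1/(2 pi tau_min)]` at rest.

What the generator does *not* emulate about real recordings: measurement
noise on the voltage, electrode artefacts, channel noise, slow adaptation
currents, or temperature drift.  Passing benchmarks on these synthetic
data therefore demonstrates correction of *structural parameter error*
under clean observations, not robustness to observational noise.

## Reservoir and hybrids

The echo-state reservoir follows the driven-oscillator design: a random
regular graph (every node exactly degree `D`; built with
`igraph::sample_degseq`, one node dropping to `D - 1` when `N_R D` is odd)
with 0/1 weights, rescaled globally so the largest eigenvalue equals the
spectral radius `rho`; a two-channel one-hot input layer (first half of
the nodes wired to the current, second half to the voltage, unit weights);
`r(t+dt) = tanh(A r + W_in v_in)` from `r(0) = 0`.  Stand-alone defaults:
`N_R = 1000`, `D = 6`, `rho = 1.25`, `sigma = 0.4`, `beta = 1e-4`.  The
hybrids use `D = 8`, `rho = 1`, `sigma = 0.8`, `beta = 1e-3` — a longer
memory-retention configuration, which matters because reconstructing an
`n`-dimensional hidden state from one observable requires on the order of
`2n + 1` delayed samples (`embedding_count(4) = 9`).

The six hybrid variants cross the state scope (TVH: model voltage only;
ASVH: `V, m, h, n`) with the injection site (IH: input layer; OH: readout;
FH: both).  A fraction `gamma` (default 0.5) of nodes is allocated to the
model channels, floor-rounded with the remainder on the last listed
channel; OH variants keep the stand-alone input split.  During training
the embedded surrogate is teacher-forced: each step its voltage is
overwritten by the observed voltage while its gates persist, and it is
integrated one sampling interval ahead.  In closed loop the readout
voltage takes the observed voltage's place in both the reservoir feedback
channel and the surrogate step — this is precisely what turns the
surrogate's gate trajectories into the corrected hidden-state estimate.

Two input-scaling conventions deserve comment:

* **Data channels.**  The voltage and current are re-centred on their
  training-window means and scaled so their *oscillation range* maps into
  `[-sigma, +sigma]` (`fit_scaler(method = "range")`).  An alternative
  reading scales to RMS-deviation `sigma` (`method = "rms"`); it is
  provided, but with spiky voltage traces it puts action-potential peaks
  at ~9 standard deviations, which tanh-saturates every voltage-input node
  — spike-shape information is lost and the closed-loop feedback gain
  rises enough to destabilise the stand-alone reservoir.  The range
  reading keeps the voltage channel in the tanh linear zone and is the
  package default.

* **Model channels.**  The model state enters the input layer *raw*: the
  voltage in mV (which tanh-saturates its nodes into near-binary spike
  indicators) and the gates as bare fractions in `[0, 1]`.  Scaling the
  model voltage like the data channels was tried and rejected: it lets a
  badly detuned model inject large fluctuations into the recurrent pool,
  destabilising the IH/FH variants, whereas saturated raw injection gates
  that pathway off.  It also keeps the model-channel allocation `gamma`
  from dominating the pool dynamics (`size_and_gamma_study()` quantifies
  the dependence).

### Readout training

The readout is the ridge solution on standardised regressors,
`W = Y H' (H H' + beta I)^{-1}`, computed by Cholesky on the summed Gram
matrix with the Tikhonov constant added to the diagonal (an SVD-based
independent solve verifies it to 1e-8 in the tests).  Each regressor
(reservoir node, and for OH/FH the appended model outputs) is centred and
scaled by its own RMS deviation; regressors with (near-)zero spread get
weight zero; with collinear regressors and `beta = 0` the solve fails with
advice to regularise.  Because the regression runs on centred variables
and the bias is composed as `w_out = <V> - W_out <r>`, the training-window
mean of predictions matches the target mean exactly (verified to 1e-9).
Prediction starts warm: the reservoir and surrogate states continue from
the end of the training window, with the initial feedback voltage taken
from the readout of the final training regressor.  Fed-back voltages are
clipped to ±150 mV before re-entering the loop; outputs beyond that, or
non-finite readouts, set a `saturated` flag on the returned prediction —
saturation is reported, never thrown, because it is itself a finding about
a configuration.

### The sampling step

The reservoir, surrogate and readout all operate on the trajectory
sampling grid.  The default benchmark uses `dt = 0.25` ms.  At a 10x finer
step (25 us) the one-step prediction task degenerates: the target is
nearly identical to the fed-back input, the nine-sample embedding window
spans only 0.2 ms — far less than the 1–8 ms gate memory the hybrid must
exploit — and the trained loop is either unstable (weak shrinkage) or
badly damped (strong shrinkage).  At 0.25 ms the embedding window spans
2 ms, comparable to the slow-gate time constants, and the architecture
comparisons in the test suite behave as designed.  The step is a plain
configuration value (`windows.dt_ms`); nothing in the package assumes a
particular grid.

## Benchmark harness

`benchmark_config("reduced")` is the default study: 312.5 ms training
window (1251 samples at 0.25 ms), 2500 ms held-out prediction under a
protocol generated from a disjoint sub-seed, 300-node reservoirs, RMSE
evaluated in 312.5 ms windows (8 windows), medians over 5 replicate seeds.
`benchmark_config("paper")` restores the full-scale setting (1250 ms
training, 5500 ms prediction, 1000 nodes, 1250 ms windows) for users with
more patience; the reduced scale exists so that the complete sweep suite
runs in minutes on one core.  All orderings asserted in the tests are
asserted at the reduced scale.

`sweep_model_error()` shares one reference trajectory and protocol pair
per seed across all detunings and systems (the stand-alone reservoir,
being detuning-independent, is trained once per seed).  Failed or
saturated runs enter the tables flagged, with their RMSE computed as-is —
no silent exclusion, since saturation is one of the phenomena under study.
Medians (with interquartile ranges) summarise windows and seeds
throughout; means would be dominated by the occasional saturated window.

## Known limitations

* **Large detunings.**  The ASVH-FH closed loop is reliable on the default
  benchmark up to roughly 100% sodium-conductance detuning (where it still
  roughly halves the raw surrogate's error on most seeds, see the README
  example) but becomes seed-dependent there and unstable beyond: at
  `eps_g >= 10` the gate input channels — whose fast `m` component slaves
  to the fed-back voltage within a step — form a high-gain feedback path,
  and the summed-Gram ridge (whose relative shrinkage falls as
  `beta / (T sigma^2)` with window length `T`) lets readout weights grow
  until the loop saturates.  Larger training windows make this *worse*,
  not better.  The corresponding acceptance checks are left failing rather
  than patched, and the sweep tables flag the saturated cells.

* **Threshold-type error.**  Detuning the sodium activation threshold
  (`eps_v`) is the severest error type; the correction range on the
  default benchmark ends around a few percent, well below the
  conductance-error range.

* **Clean observations only.**  No observation noise is modelled (see the
  stimulus section); with the near-identity one-step structure of the
  task, even sub-mV feedback noise measurably degrades subthreshold
  precision.

* **Single compartment, three currents.**  Multi-compartment or
  multi-channel models, temperature dependence, and the classic
  alpha/beta rate parameterisation are out of scope.
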