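---
title: "The two-field model: methods, calibration and scope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-field model: methods, calibration and scope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dendrofield)
```

## The model

`dendrofield` simulates a patch of cortex as two overlaid two-dimensional
lattices tiling the same sheet (default 5 mm x 5 mm, the scale of rat primary
visual cortex), with periodic boundaries:

* a **somatic field** of adaptive quadratic spiking units (the Izhikevich
  model),
* a **dendritic field** of slow Morris-Lecar units producing all-or-none
  plateau potentials,
* one **global inhibitory unit** integrating every somatic spike and feeding
  back a uniform conductance.

Each somatic unit `i` follows

$$\dot v_i = 0.04 v_i^2 + 5 v_i + 140 - u_i + I_{D,i} + I_{ext,i}
  - G_{inh}\,(v_i - E_{inh}), \qquad \dot u_i = a (b v_i - u_i),$$

with the reset `v <- c`, `u <- u + d` at `v_peak`. The adaptation current
`u` is the model's *somatic K+ current*: it builds up with every spike and
decays with `1/a = 50` ms, and its spatial distribution is what
distinguishes a moving from a stationary activity bump.

Each dendritic unit follows Morris-Lecar dynamics driven by a first-order
synaptic drive `S` (one unit increment per presynaptic somatic spike, decay
`tau_syn`):

$$C_d \dot V = -g_{Ca} m_\infty(V)(V - V_{Ca}) - g_K w (V - V_K)
  - g_L (V - V_L) + g_{syn} S (E_{syn} - \kappa V),$$
$$\dot w = \lambda(V)\, (w_\infty(V) - w) / \tau_d ,$$

with the usual tanh/cosh gating curves. Two deliberate modifications adapt
the Morris-Lecar unit to its role as a *dendritic plateau* generator:

1. **Truncated after-hyperpolarization.** Whenever `V` falls below the
   resting potential it is clamped back to `V_rest` and the gate is reset to
   `w_inf(V_rest)`. Without the gate reset, residual K+ conductance would
   immediately re-hyperpolarize the unit on the next step, defeating the
   truncation. Real dendrites show no deep post-plateau hyperpolarization.
2. **Rescaled output.** Wherever the dendritic potential drives a current —
   the synaptic term above and the dendro-somatic current — it enters as
   `kappa * V` with `kappa = 0.73`, moderating the plateau's downstream
   effect.

The dendro-somatic current is one-way (no back-propagation into the
dendritic field):

$$I_{D,i} = g_{ds} \sum_{j \in \mathrm{branches}(i)} (\kappa V_j - v_i).$$

The two fields are wired by two independent Bernoulli samples with Gaussian
distance kernels on the torus: soma-to-dendrite ("axon") edges and
dendrite-to-soma ("branch") edges, fixed once per seed before simulation.
Soma-to-soma coupling is the composition of the two samples through a shared
dendritic unit — each dendritic unit represents the co-located branches of
all nearby neurons, in the spirit of neural field models.

The inhibitory unit is rate-based: `V_I` jumps by `drive_gain` per somatic
spike anywhere, decays with `tau_I`, and feeds back
`G_inh = g_I max(V_I, 0)` to every soma. A rectified-linear transfer is the
minimal non-spiking choice for a unit that stands for a pooled population.

Integration is classical RK4 at `dt = 0.1` ms (a step-halving convergence
test is part of the suite). Within a step the external currents — including
the white-noise current, held constant over the step with per-sample
variance `sigma^2/dt`, so injected noise power is step-size invariant — and
the inhibitory conductance are frozen; spike resets, synaptic increments,
inhibitory increments and dendritic truncation are applied at step
boundaries. Spikes detected at a boundary increment `S` from the next step
on; at `dt <= 0.25` ms this event ordering is inconsequential.

## Parameters and calibration

None of the numerical constants of the original formulation were available
to this implementation, so all defaults are either canonical parameter sets
or were calibrated once against qualitative targets and then frozen in
`inst/extdata/config-defaults.yaml` (`dendrofield_defaults()`); they are not
revisited per analysis.

* **Soma**: the standard regular-spiking Izhikevich set (`a = 0.02`,
  `b = 0.2`, `c = -65`, `d = 8`, `v_peak = 30`), giving an adaptation decay
  of 50 ms — "several tens of milliseconds", the natural scale for the
  transient-inhibition switching protocol. `E_inh = -75` mV is a standard
  GABA-A reversal.
* **Dendrite**: the canonical Morris-Lecar conductance set (`g_Ca = 4.4`,
  `g_K = 8`, `g_L = 2`, `V_Ca = 120`, `V_K = -84`, `V_L = -60`, `V1 = -1.2`,
  `V2 = 18`, `V3 = 2`, `V4 = 30`, `C_d = 20`). `tau_d` is the one swept
  parameter: the gate rate `lambda(V)/tau_d` makes plateau duration grow
  monotonically from ~9 ms (`tau_d = 5`) to ~210 ms (`tau_d = 500`) for a
  brief suprathreshold pulse, while the amplitude stays all-or-none.
  `tau_d = 200` ms is the slow-dendrite default, `tau_d = 5` ms the fast
  control. `V_rest` is located by root finding at construction and verified
  by a relaxation run.
* **Synapse**: `tau_syn = 5` ms, `g_syn = 2`, `E_syn = 0` mV. With these, a
  single dendritic unit needs roughly five near-coincident presynaptic
  spikes to ignite a plateau, so isolated background spikes do not trigger
  plateaus but coordinated local activity does.
* **Connectivity**: kernel width 0.42 mm for both directions, amplitude 0.3,
  giving a mean degree near 30 on the default 48 x 48 lattice and an
  effective soma-to-soma footprint of about 5-6 lattice spacings — the
  regime in which a single bump several units wide self-organizes.
* **Coupling and inhibition**: `g_ds = 0.0125` makes the tonic
  dendro-somatic current at rest (~11 pA across ~30 branches) comparable to
  the somatic rheobase while a fully plateaued neighborhood delivers ~40 pA;
  `g_I = 0.02`, `tau_I = 10` ms caps total network activity at a single
  compact bump without driving global on/off oscillations.
* **Stimulus anchors**: constant background drive 2 pA; white-noise variance
  anchors 4 / 25 / 150 pA^2 ms for the weak / moderate / strong regimes
  (just-spiking, bump-preserving, bump-degrading); the global inhibitory
  amplitude 100 pA silences a tonically driven test network within
  milliseconds.

## Measures

* **Snapshots**: per-soma spike counts in 10-ms windows, smoothed with a
  periodic Gaussian filter (`filter_sigma = 2` lattice units, mass
  conserving). The window of 10 ms is fixed by the definition of the
  measure; the snapshot hop (default 10 ms, non-overlapping) and the filter
  width are exposed parameters.
* **Lag-dependent inner product**: elementwise-product sums of snapshot
  pairs separated by a lag, averaged over reference times (only meaningful
  under stationarity; `average = FALSE` anchors at one reference time for
  protocols with distinct phases). The chance level is the cross-trial
  baseline — the average product of snapshots from *different* trials —
  subtracted before the peak is normalized to one. The decay constant
  `tau_decay` is fitted as `A exp(-lag/tau)` on the linear scale by
  profiling `A` and optimizing `tau` in 1-D; negative curve values, which
  arise from small normalization errors, are excluded. Linear-scale fitting
  is used (not log-linear) precisely because those near-zero and negative
  late-lag values would dominate a log fit.
* **Clustering index**: the field is divided into square cells (4 x 4 somata
  by default); the coefficient of variation (population SD over mean) of
  per-cell activity is computed per time bin and averaged over bins. Bins
  with zero mean are skipped — the CV is undefined there, and an
  epsilon-regularized alternative was checked to change intact-bump values
  by well under the classification margin. Count mode counts distinct
  spiking somata per cell; sum mode min-max normalizes a field series to
  [0, 1] and sums per cell.
* **Core and skewness**: a field (e.g. the somatic adaptation current) is
  smoothed, rescaled to [0, 1], and thresholded at 0.5; the surviving region
  is the core. Its value-weighted centroid uses circular means on the torus,
  its principal axes come from the value-weighted spatial covariance of
  wrapped displacements, and the value-weighted third standardized moment of
  positions projected on an axis measures the directional bias — the
  trailing adaptation tail of a moving bump. Gaussian-kernel smoothing
  replaces kriging here: the downstream statistics depend only on
  smoothness, not on the interpolator.
* **Trajectory and speed**: per-snapshot core centroids, unwrapped across
  the periodic boundary by accumulating signed minimal-image steps; frames
  without a core are gap-marked, never interpolated. Because each centroid
  carries sampling jitter from the finite spike count per window, the speed
  estimator differences positions `stride` frames apart (default 1; the
  experiment runner uses 5, i.e. 50 ms) — jitter shrinks with the effective
  interval while genuine drift does not.
* **Immobilization score**: the decay-constant curve and the clustering
  curve over a common noise grid, each min-max scaled to [0, 1], multiplied
  pointwise; an interior peak marks noise that immobilizes without
  destroying.

## The synthetic fixture generator

`generate_blob_raster()` emits an inhomogeneous Poisson raster whose rate is
a Gaussian profile translating at a known speed on the torus, plus the
ground-truth trajectory. It emulates exactly the features the metrics
consume — a localized blob, known motion, Poisson sampling noise — and none
of the features of real network activity (no refractoriness, no spike-count
correlations, no background activity, no bump shape dynamics). Metric
validation on these fixtures therefore demonstrates estimator correctness
(speed recovery, `tau_decay` proportional to inverse speed, oracle equality
of the inner product), not that the network simulation itself behaves like
cortex.

## Numerical choices and degenerate inputs

* `dt` must be at most 0.25 ms (stability guard); divergence (`|v| > 1000`
  mV) raises an error naming the step size.
* An all-zero snapshot has no core (`dendrofield_no_core` condition);
  trajectory frames without a core become gaps. A constant positive field
  is all core, with the uniform-torus covariance.
* Zero-mean clustering bins are skipped; an all-constant positive field
  yields index 0 exactly.
* Degenerate normalization (zero-lag value equal to the baseline) and
  all-negative decay curves raise errors rather than returning numbers.
* Equal-eigenvalue cores are flagged `degenerate`; their axes are arbitrary.

## Experiment scale

All experiment defaults target a 48 x 48 lattice (the full 120 x 120 of the
original formulation is available by configuration). The phenomena under
study are local — one bump a few lattice units wide — and the mechanism has
no intrinsic scale, but the reduced field, durations of 1-2 simulated
seconds, and 2 trials per condition in the standard analyses are deliberate
desk-scale choices, recorded in each run's manifest. Classification
thresholds (`clustering_broken = 3.0`, `speed_immobile = 0.03` units/ms)
were calibrated once on labeled extreme configurations — a noiseless
constant-drive mobile bump versus strong-noise fast-dendrite breakup — and
frozen.

## Known limitations

With the calibrated defaults the simulator robustly reproduces: all-or-none
plateaus whose duration is set by `tau_d`; a self-organized traveling bump
under noiseless constant drive; slower decay of pattern similarity
(`tau_decay` rising) under moderate noise when dendrites are slow, with the
clustering index falling as noise grows; breakup of the bump under the same
noise when dendrites are fast; and the extension of the spatio-temporal
integration window by slow plateaus.

It does **not**, in any parameter regime found during calibration, reproduce
full noise-induced immobilization — a noise-born bump whose centroid speed
drops several-fold below the noiseless case — nor, consequently,
mobile/immobile bistability or the transient-inhibition mode switch (after
the inhibitory pulse the bump is reborn several core radii from its
pre-pulse location and resumes drifting). In this implementation the bump's
motion is carried by fresh plateau ignition at its leading edge (it survives
even with somatic adaptation disabled), and noise was never observed to
block front ignition while sparing in-place re-ignition. Two related
signatures differ from the target phenomenology for the same reason: at the
noise level where `tau_decay` peaks the clustering index has already fallen
below the broken-regime floor, and the dendritic gate field `w` of a
traveling bump is strongly skewed along the motion axis (its slow wake
trails the bump), not only the somatic adaptation field. The protocol
constructors for the switching experiments are provided and tested
structurally; the corresponding dynamical assertions in the acceptance suite
document these gaps rather than hiding them.

Further simplifications shared with the underlying formulation: one global
inhibitory unit (no interneuron dynamics), no backpropagating action
potentials or soma-to-dendrite currents, unstructured Gaussian connectivity,
and no synaptic plasticity.
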