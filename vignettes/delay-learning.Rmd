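---
title: "Supervised delay learning for spiking neurons: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised delay learning for spiking neurons: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A single spiking neuron receives spike trains from $N_I$ input synapses and
should learn to emit a *desired* output spike train. Classical supervised
rules for spiking neurons adjust only the synaptic weights $w_i$; biology,
however, also modulates conduction *delays* $d_i$. This package implements a
supervised learning algorithm in which both the weight and the delay of every
synapse are adapted by gradient-descent-style rules derived from spike-train
kernels, together with the simulator and the benchmark harness needed to
study it.

## Neuron model

The neuron is a short-term-memory Spike Response Model. Its membrane
potential at time $t$ is

$$u(t) \;=\; \sum_{i=1}^{N_I} \sum_{f} w_i\,
  \varepsilon\!\left(t - t_i^f - d_i\right) \;+\; \eta\!\left(t - t_o^{l}\right),$$

where $t_i^f$ are the input spike times of synapse $i$, $t_o^l$ is the most
recent output spike (only the last one contributes — the "short-term memory"
of the model), the postsynaptic potential is the alpha-shaped

$$\varepsilon(s) = \frac{s}{\tau}\, e^{1 - s/\tau} \quad (s > 0,\ \text{else } 0),$$

normalized to peak at 1 when $s = \tau$, and the refractoriness is

$$\eta(s) = -\theta\, e^{-s/\tau_R} \quad (s > 0,\ \text{else } 0).$$

The neuron fires when $u(t)$ reaches the threshold $\theta$ and a hard
absolute refractory period $t_{abs}$ has elapsed since the last output spike.

Defaults (the reference benchmark conditions used throughout):
$\tau = 2$ ms, $\tau_R = 50$ ms, $\theta = 1$, $t_{abs} = 1$ ms, interval
$\Gamma = [0, 200]$ ms, clock-driven simulation with step $dt = 0.1$ ms.

## Spike-train kernels and the learning rules

A spike train $s(t)$ is turned into a continuous signal by convolving it
with a kernel, $f_s(t) = \sum_f \kappa(t - t^f)$. The learning rules use the
Laplacian kernel $\kappa(s) = e^{-|s|/\tau_\kappa}$ with scale
$\tau_\kappa = 10$ ms (distinct from the PSP constant). Writing $t_d^g$,
$t_o^h$, $t_i^f$ for desired, actual and input spikes, each epoch updates

$$\Delta w_i = \eta \left[ \sum_g \sum_f \kappa(t_d^g - t_i^f - d_i)
  - \sum_h \sum_f \kappa(t_o^h - t_i^f - d_i) \right],$$

$$\Delta d_i = \frac{\alpha\, w_i}{\tau_\kappa} \left[ \sum_g \sum_f
  \kappa(t_d^g - t_i^f - d_i) - \sum_h \sum_f \kappa(t_o^h - t_i^f - d_i)
  \right].$$

Both rules share the same bracket; identical desired and actual trains
cancel it exactly, so a perfectly reproduced train is a fixed point of the
learning dynamics. The closed double sums are taken as *definitional* (they
are not a quadrature of the underlying error integral: for a Laplacian
kernel the exact integral of a kernel product is $(\tau_\kappa +
|\Delta|)e^{-|\Delta|/\tau_\kappa}$, not $\kappa(\Delta)$; the package
implements the printed double-sum form).

Two points in the delay rule deserve emphasis:

* **The unsigned bracket.** The derivative of $|x|$ that arises when
  differentiating the Laplacian kernel with respect to the delay carries a
  sign that the closed-form rule drops; the default implementation follows
  that unsigned form exactly. An experimental `signed_delay_rule` /
  `signed = TRUE` option restores the $\mathrm{sign}(x)$ factor for
  comparison; it is off by default and not used by any benchmark.
* **Other kernels.** For a Gaussian learning kernel the generic rule is
  used, replacing $\kappa/\tau_\kappa$ by the kernel's delay derivative
  $(x/\sigma^2)\,\kappa(x)$.

### Adaptive learning rate

The weight learning rate adapts to the output firing rate $r$ (spike count
divided by duration, in Hz). Given a referenced band $[r_{min}, r_{max}]$,
a scaling factor $\beta$ is 1 inside the band,
$(r_{min}-r)/(r_{max}-r_{min})$ below it and
$(r-r_{max})/(r_{max}-r_{min})$ above it, and

$$\eta = \begin{cases} (1+\beta)\,\eta^* & r < r_{min} \\
  \eta^* & r_{min} \le r \le r_{max} \\ \eta^*/(1+\beta) & r > r_{max}.
  \end{cases}$$

The band has no single canonical value; the
package defaults to $[0.8\,r_{out},\ 1.2\,r_{out}]$ of the current task
(40–60 Hz at the benchmark), configurable via `r_band_factors`. A silent
neuron ($r = 0$) falls in the below-band branch, as written. The delay rate
$\alpha$ is not adapted.

### Bounds on delays and weights

Delays are clamped into $[d_{min}, d_{max}]$ (default $[0, 15]$ ms) after
every update: the upper bound is the *maximum allowed synaptic delay* of
the model, and delays are also initialized uniformly on this interval.

Weights are initialized uniformly on $[w_{min}, w_{max}]$ (default
$[0, 0.5]$) and, by default, **clamped into that interval during
learning**. This was a genuinely open design point: the bounds could be
read as an initialization range only. We adopted the clamped reading for
three reasons: the bounds are named minimum/maximum synaptic weights,
symmetric with the enforced delay bounds; unbounded weights let the
weight-only (static-delay) network overshoot the accuracy of the full
algorithm, inverting the ablation ordering that motivates delay learning
(static/static < static-w/dynamic-d < dynamic-w/static-d <
dynamic/dynamic), which the clamped variant restores; and clamping keeps
synapses excitatory, consistent with the excitatory-synapse assumption
behind the linear kernel-signal relation used in the derivation. Pass
`clamp_weights = FALSE` to get the unbounded variant.

## Training loop

One epoch: (1) simulate the actual output train with the current state;
(2) record the accuracy $C$ (below); (3) compute $r$ and the adaptive
$\eta$; (4) compute all $\Delta w_i$ and $\Delta d_i$ from the same
snapshot; (5) apply them simultaneously (batch update), clamping delays
(and weights, by default). Training stops at zero network error — the
actual and desired spike sequences coincide on the $dt$ grid — or after
`max_epochs` (default 500) epochs. A disabled channel (`adapt_weights` or
`adapt_delays` `FALSE`) contributes zero deltas; if an epoch leaves the
state bit-identical, the remaining epochs are filled without re-simulating
(the dynamics are deterministic), which makes the untrained baseline cheap
without changing its semantics.

## The accuracy measure C

$C$ is the normalized inner product of the Gaussian-filtered desired and
actual trains,
$C = \langle f_{s_d}, f_{s_o}\rangle / (\lVert f_{s_d}\rVert\,
\lVert f_{s_o}\rVert)$, evaluated on the simulation grid; $C = 1$ for
identical trains, near 0 for unrelated ones. Degenerate conventions: both
trains empty gives 1, exactly one empty gives 0, so "identical $\Rightarrow
C = 1$" extends to the empty case. Normalization makes the value
insensitive to the grid step.

The filter width is a free parameter of the measure; the package
default is $\sigma = 5$ ms, on the order of the PSP/interspike scale, and
it is exposed as `metric_scale`. Note that the *absolute* value of $C$
depends materially on $\sigma$ (a wider filter forgives larger spike-time
errors and inflates $C$ for loosely related trains); comparisons across
configurations are meaningful at fixed $\sigma$.

## Numerical choices

* Spike times are continuous reals; only the neuron simulation and the $C$
  grid discretize time (step $dt = 0.1$ ms). Delayed arrivals
  $t_i^f + d_i$ are *not* rounded to the grid.
* Threshold crossing is detected as $u \ge \theta$ at a grid point (ties
  fire), with a $10^{-9}$ absolute tolerance so that exact-tie cases —
  e.g. a lone PSP peaking exactly at $\theta$ — are robust to round-off;
  the spike time is the grid time.
* Before the first output spike the refractoriness term is exactly 0
  (last spike at $-\infty$); no potential reset is applied beyond $\eta$
  and the absolute refractory window.
* PSP contributions are accumulated event-wise with a cutoff
  $10\,\tau$ (2 ms PSPs → 20 ms window) after each arrival, beyond which
  the neglected contribution is below $1.3\times10^{-3}$; the cutoff is
  configurable (`psp_cutoff`) and the test suite disables it when
  comparing against the exact reference simulator.
* Inside the grid accumulation the exponential decay is advanced
  recursively (one `exp` per spike event), which is what keeps
  500-synapse, 500-epoch training runs at desk scale.
* The kernel-space error $E = \tfrac12 \int (f_{s_o}-f_{s_d})^2\,dt$ is
  available for diagnostics (`spike_train_error()`, trapezoidal rule) but
  plays no role in the updates.

## The synthetic benchmark and what it shows

All benchmark inputs are synthetic: every input train is homogeneous
Poisson at $r_{in} = 20$ Hz, the desired train homogeneous Poisson at
$r_{out} = 50$ Hz, both on 200 ms. This emulates irregular, stationary
spiking with a fixed target pattern. It does **not** emulate rate
modulation, bursting, correlations between input channels, or any
structured stimulus code, so passing benchmarks demonstrates the learning
rules' capacity to bind random spatio-temporal patterns, not performance
on structured real recordings.

The harness runs repeated seeded trials (trial $k$ uses `seed_base + k`;
each trial draws its inputs, desired train and initial state from that
seed in a fixed order) and reports the sample mean and sample standard
deviation ($n-1$) of the per-trial **best** $C$ and of the **first** epoch
at which the maximum is attained (both first-attainment and the final $C$
are recorded). Mode flags (static vs dynamic weights/delays) change
nothing about a trial's data or initialization, so comparisons are paired
by construction. Aggregates at reduced trial counts (typically 20 per
configuration here, versus 100 in the reference protocol) carry
correspondingly wider sampling error, and single sweep points should be
read with the reported standard deviations in mind.

Problem sizes used by the shipped tests and the acceptance script: 20
seeded trials per benchmark configuration (50 for the untrained baseline,
which costs one epoch per trial), chosen as the smallest aggregates at
which the reported means are meaningfully reproducible.

## Known limitations

* Single neuron, single layer, excitatory synapses; no multilayer or
  recurrent extension.
* At the default benchmark conditions the weight channel dominates: the
  weights-only (static-delay) network already reaches a mean best $C$
  close to the full algorithm's, so the measured benefit of delay
  plasticity is a small paired improvement that can be washed out by
  trial noise at modest trial counts. The width of the $C$ filter
  contributes to this compression (at $\sigma = 5$ ms, spike-time errors
  of a millisecond or two barely lower $C$); a narrower $\sigma$
  discriminates the two networks more sharply.
* The unsigned delay rule is followed as printed; its gradient sign is
  known to be dropped, and the provided signed variant is experimental.
* Exact-convergence detection (spike sequences equal on the grid) is
  strict; trials typically run to the epoch limit with $C$ slightly below
  1 rather than formally converging.
* The homogeneous-Poisson generator is the only built-in stimulus source
  (no inhomogeneous or bursting processes).
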