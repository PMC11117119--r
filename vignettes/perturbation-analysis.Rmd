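---
title: "Perturbative analysis of network dynamics on connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbative analysis of network dynamics on connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbflow)
```

## Overview

`perturbflow` quantifies *network-dynamical* interactions: instead of
reading centrality off the static wiring of a structural connectome, it
runs node dynamics on the network, perturbs one region at a time, and
measures how the perturbation propagates. Two node models span a wide
range of dynamical complexity:

* the **linear stochastic model (LSM)**,
  $\dot x_i = -x_i + G \sum_j C_{ij} x_j + \sigma\eta_i(t)$ — an
  Ornstein–Uhlenbeck-like process whose noiseless version contracts to the
  zero steady state for $G < G_{stable} = 1/\lambda_{max}(C)$ and diverges
  above it;
* the **dynamic mean-field model (MFM)**, a reduced Wong–Wang population
  model with one NMDA gating variable per node,
  $\dot S_i = -S_i/\tau_S + (1-S_i)\,\gamma H(x_i)$,
  $x_i = wJS_i + GJ\sum_j C_{ij}S_j + I_0$, with the firing-rate function
  $H(x) = (ax-b)/(1-e^{-d(ax-b)})$. The MFM supports a stable low-activity
  state at weak coupling, a bistable window at intermediate coupling, and
  loss of the low state beyond it.

Both are integrated with a fixed-step forward-Euler scheme at
$dt = 1\,\mathrm{ms}$ (milliseconds are the internal time unit
everywhere); stochastic runs add Euler–Maruyama increments
$\sigma\sqrt{dt}\,\eta$. At $dt = 1$ this is numerically identical to
adding $\sigma\eta$ per step, so the two common readings of "additive
noise per step" coincide at the protocol's resolution; the
$\sqrt{dt}$ scaling keeps noise statistics step-size-invariant if $dt$ is
changed. Clamped and frozen nodes are reset to their held values after
every Euler step, which is how perturbation sources and functional lesions
are realized; because the scheme with per-step resets *is* the protocol,
the integrator is implemented in compiled code in this package rather than
delegated to a general ODE solver.

## The perturbation protocol

1. **Settle.** From uniform $[0,1]$ initial conditions, evolve noiselessly
   for 60 s. The residual $\max_i |\dot x_i|$ must fall below
   $10^{-8}/\mathrm{ms}$, otherwise a "not settled" error is raised — the
   protocol's fixed durations are thereby turned into a checkable
   contract.
2. **Perturb.** For each source $n$, clamp it at
   $\tilde x_n = (1+\alpha)x_n$ with $\alpha = -0.1$ (negative, so the
   perturbation cannot push the system toward an unstable regime),
   initialize every other node at its steady state, evolve noiselessly for
   5 s, and verify settling again.
3. **Measure.** $R_{mn} = (\tilde x_m - x_m)/(\alpha x_m)$, with
   $R_{nn} = 0$. Column sums give total responses $Z_n$; net influence is
   $I_i = \sum_m R_{mi} - \sum_m R_{im}$, which sums to zero exactly
   (the two double sums are the same set of entries).

### Trivial steady states and the $10^{-60}$ floor

Below its stability threshold the LSM relaxes to exactly zero, making the
relative response 0/0. The protocol substitutes a tiny positive floor
($10^{-60}$) for trivial steady-state values *where they are divided by or
used to seed the source clamp*: the clamp becomes
$(1+\alpha)\cdot 10^{-60}$ and the denominator $\alpha \cdot 10^{-60}$,
while initial conditions, frozen-node values and the numerator difference
keep the true steady state. Two candidate readings exist — substituting
the floor *everywhere* versus only as a division guard — and they are not
interchangeable: under the everywhere-reading an *uncoupled* node acquires
the spurious response $-1/\alpha$ (its floored value decays to zero and
the difference is attributed to the perturbation), isolated nodes gain
nonzero response rows, and lesion-based flow orderings invert. Under the
division-guard reading implemented here, uncoupled nodes respond zero, an
isolated node has a zero response row and column, severing the only path
between two nodes zeroes their lesioned response, and freezing the middle
of a three-node chain removes *all* end-to-end transfer (flow exactly 1).
Net influence is identical under both readings (the additive offset
cancels in the column–row difference), so the choice affects the
bookkeeping of $R$, not the influencer–follower structure. For the
subcritical LSM the resulting responses are
$R_{mn} = (1+\alpha)\,g_{mn}/\alpha$, where $g_{mn}$ is the steady state
of node $m$ when node $n$ alone is clamped at one — an algebraic solve the
test suite uses as an entrywise oracle for the simulated matrix.

### Functional lesions: exact and approximate

Freezing node $i$ at its unperturbed steady value removes it from the
dynamics without changing anyone's baseline (the fixed point is
unchanged). The exact route reruns the whole protocol with $i$ frozen
($N+1$ settles per lesion); the cheap route uses the composition
approximation $R^{i}_{mn} \approx R_{mn} - R_{mi}R_{in}$, which needs only
the unlesioned matrix. Flow is then
$F^i = \operatorname{mean}_n (Z_n - Z^{i}_n)/Z_n$ over admissible sources
$n \neq i$; a frozen node cannot itself be a source, so the average runs
over the $N-1$ others (a uniform rescaling relative to averaging over all
$N$, leaving rankings untouched), and sources with $|Z_n| < 10^{-12}$ are
excluded from the mean — their flow fraction is 0/0 — and reported.

**Validity of the approximation.** The composition formula is a
small-perturbation expansion around a *nondegenerate* steady state. Two
caveats follow, both verified numerically in this package's tests:

* Near a nonzero steady state (the MFM), the exact-vs-approximate
  discrepancy is small (on a weakly coupled 10-node instance, below
  $10^{-3}$ entrywise, with identical flow rankings), but its limit as
  $\alpha \to 0$ is an $\alpha$-independent *network composition* term —
  the formula treats the paths $n \to i \to m$ as if they composed
  multiplicatively, which is exact on trees but not on graphs with cycles.
  The error therefore plateaus rather than vanishing as the perturbation
  shrinks.
* Around the *trivial* (floored) steady state of the subcritical LSM the
  premise fails outright: $R$ itself scales as $1/\alpha$, so the product
  $R_{mi}R_{in}$ scales as $1/\alpha^2$ while the exact lesioned response
  scales as $1/\alpha$ — the approximation error *grows* as the
  perturbation shrinks, and the approximate flow becomes an
  order-reversing transform of the exact flow. For the LSM below
  threshold, use `lesion = "exact"`; the approximation is trustworthy for
  dynamics with nondegenerate steady states.

## Fitting the coupling

The forward BOLD pipeline mirrors the standard model-fitting protocol:
simulate the stochastic dynamics (for the LSM, with the noise rule
$\sigma = G_{stable} - G$, which keeps noise from kicking the system into
the divergent regime as $G$ approaches threshold), pass the activity
through a Balloon–Windkessel filter at the neural resolution, discard the
first 12 s of BOLD as transient, downsample to the repetition time by
taking every $(TR/dt)$-th sample (no anti-alias filter — matching the
stated simplicity of the pipeline), z-score per node, and correlate. The
fit objective is $FCD = \frac1N \sum_{ij} (FC^{emp}_{ij} - FC^{sim}_{ij})^2$,
exactly as printed — the double sum divided by $N$ (not $N^2$) and without
a square root; since the argmin over $G$ is invariant under monotone
transforms, the unconventional normalization is harmless. `sweep_coupling()`
evaluates a trial-averaged $FCD$ per grid point (defaults: 96 s
simulations, 12 s transient, $TR = 0.6$ s, 30 trials) and returns the
minimizing $G^*$, breaking ties toward smaller $G$; grid points where all
trials diverge are reported and excluded.

The Balloon–Windkessel equations and constants are not free parameters of
this package's analyses; the canonical form is used
($\kappa = 0.65\,/\mathrm{s}$, $\gamma_f = 0.41\,/\mathrm{s}$,
$\tau = 0.98\,\mathrm{s}$, $\alpha_{bw} = 0.32$, $\rho = 0.34$,
$V_0 = 0.02$, $k_1 = 7\rho$, $k_2 = 2$, $k_3 = 2\rho - 0.2$), with rest
($s, f, v, q) = (0, 1, 1, 1)$ as its fixed point and a positivity floor on
$f, v, q$ for numerical safety.

## The synthetic connectome generator

`synthetic_connectome()` emulates group-averaged, log-transformed
tract-count networks: undirected, nonnegative, zero diagonal, connected,
with lognormal-like edge weights. Node $i$ receives a propensity
$e^{h z_i}$ ($z_i \sim N(0,1)$); edge weights are propensity products
times lognormal edge noise on a topology backbone (complete, modular with
a guaranteed inter-module path, or ring lattice). The heterogeneity knob
$h$ is calibrated so that the default $h = 0.3$ gives a node-strength
coefficient of variation of roughly 0.25–0.35 — comparable to what the log
transform leaves in tract-count connectomes, whose raw strength
distributions are far heavier-tailed. Under a fixed seed the random draws
are identical across $h$, so the knob moves strength dispersion without
reshuffling topology.

What the generator does *not* emulate: spatial embedding and
distance-dependent connection probability, hemispheric symmetry,
community structure aligned with functional systems, and the specific
degree–weight correlations of tractography. Passing tests on these
fixtures therefore demonstrates the correctness of the formalism and its
qualitative behaviors (hierarchy, nulls, mediation), not quantitative
agreement with any empirical connectome. The synthetic RSN partition is a
shuffled round-robin assignment — it provides coverage of the seven
canonical labels for exercising the summaries, not anatomically meaningful
membership.

At the default calibration the influencer–follower hierarchy is strong:
net influence rank-correlates with node strength above 0.8 on subcritical
LSM runs (the acceptance checks compute this afresh). At extreme
heterogeneity ($h \to 1$, strength CV near 1) the correlation degrades —
dominant hubs saturate the spectral structure — which is one reason the
default sits at the empirically plausible moderate value.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | −0.1 | relative | perturbation size; negative to stay in the stable regime |
| `t_settle` / `t_perturb` | 60 000 / 5 000 | ms | settling horizons, residual-checked at $10^{-8}$/ms |
| `trivial_floor` | $10^{-60}$ | activity | division guard for trivial steady states |
| `z_floor` | $10^{-12}$ | response | excludes vanishing-$Z$ sources from flow averages |
| `dt` | 1 | ms | Euler step; BOLD filter shares it |
| MFM `w, J, I0` | 0.9, 0.2609, 0.3 | –, nA, nA | local recurrence, synaptic coupling, drive |
| MFM `gamma, tauS` | 0.641/1000, 100 | /ms, ms | gating kinetics |
| MFM `a, b, d` | 270, 108, 0.154 | n/C, Hz, s | firing-rate gain, threshold, shape |
| MFM `sigma` | 0.001 | activity | noise amplitude for stochastic runs |
| LSM `sigma` | $G_{stable} - G$ | activity | sweep noise rule |
| sweep | 96 s, 12 s, 0.6 s, 30 | s, s, s, trials | duration, transient, TR, trials per $G$ |

The firing-rate singularity at $ax = b$ is removable (limit $1/d \approx
6.4935$ Hz) and is evaluated by series expansion within $|ax - b| <
10^{-6}$, keeping $H$ continuous, positive, and nondecreasing. The
*linear* firing-rate variant replaces $H$ by its chord between the inputs
attained at the gating bounds $S = 0$ and $S = 1$ under local drive
($x = I_0$ and $x = wJ + I_0$); the exact calibration of this variant is
genuinely open, so slope and intercept are configurable with that chord as
the default.

Other deliberate choices: natural log for the tract-count transform (the
base only rescales weights, which the coupling $G$ absorbs); zero raw
counts stay zero and sub-unit counts are removed rather than mapped to
negative weights, preserving sparsity; top-fraction node sets use
$\lceil fN \rceil$ with ties broken by node index; nodes selected into the
top influence decile whose influence sign contradicts the class label are
flagged rather than silently included; strength profiles use quantile bins
so heavy-tailed strengths do not empty bins; Fisher-z FC averaging clips
$|r|$ at $1 - 10^{-15}$ before `atanh` and thresholds negative averages to
zero after `tanh`.

## Problem sizes and determinism

The shipped tests and the acceptance script run on 2–30-node synthetic
networks: large enough to expose heterogeneity, modularity and cycles,
small enough that every protocol (including exact all-node lesioning,
which costs $O(N^2)$ settles) completes in seconds to a couple of minutes.
All stochastic elements — connectome generation, initial conditions, noise
streams — are seeded, and the seeded generators restore the caller's RNG
state, so identical calls are bitwise reproducible.

## Known limitations

* Fixed-step Euler is first order; the matrix-exponential cross-check in
  the tests confirms $O(dt)$ convergence, but stiff parameter regimes
  would need a smaller `dt` (the LSM's unit decay rate per ms makes
  `dt = 1` the coarsest sensible choice).
* The simulated stability threshold resolves $G_{stable}$ to its grid step
  and detects divergence within a finite horizon; thresholds for networks
  with very small $\lambda_{max} \cdot$ step need a longer `t_test`.
* The composition lesion approximation is unreliable for trivial-steady
  state dynamics (see above); exact lesioning is quadratic in $N$.
* No delays, no inhibitory populations, no higher-order integrators, and
  no anatomical rendering — all outside the package's scope.
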