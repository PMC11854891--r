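---
title: "Ordinal transition entropy at sentinel nodes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal transition entropy at sentinel nodes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optews)
```

## The problem

Explosive synchronization (ES) is a first-order-like transition in networks
of coupled oscillators: as the coupling strength `d` grows, the phase order
parameter

\[ R = \left\langle \frac{1}{N}\Big|\sum_j e^{i\theta_j(t)}\Big| \right\rangle_t \]

stays near its incoherent value and then jumps abruptly to ~1, typically
with hysteresis between the forward (synchronization) and backward
(desynchronization) branches. Because the global observable is silent until
the jump, classical early-warning statistics applied to it give little
advance notice. This package implements a *local* early-warning signal: the
ordinal pattern transition (OPT) entropy of scalar time series recorded at
single nodes, with highly connected "sentinel" nodes being the informative
ones.

## Ordinal symbolization and the two entropies

A scalar series is cut into blocks of `D` samples taken `tau` apart; each
block is mapped to the lexicographic rank of the permutation that sorts it
ascending (ties broken in temporal order — the dominant convention in the
ordinal literature). Two conventions for block placement are supported:

* **disjoint** (the default): blocks advance by `tau * D` samples, giving
  `L = floor(T / (tau * D))` symbols from `T` samples;
* **overlapping**: the standard Bandt–Pompe stride of one sample,
  `L = T - (D - 1) * tau` symbols, provided for cross-checks against other
  implementations. For long stationary series the two give the same pattern
  distribution; the disjoint mode has fewer, independent blocks.

From the symbol stream we form:

* the **permutation entropy** `H`: the Shannon entropy (natural log) of the
  pattern distribution, normalized by `log(D!)` so that `H` is 0 for a
  single repeated pattern and 1 for the uniform distribution;
* the **OPT entropy** `HT`: for each pattern, the normalized Shannon entropy
  of its successor distribution in the pattern-to-pattern transition matrix
  (rows are conditional distributions; rows of never-observed patterns are
  zero); `HT` is the plain average of these `D!` local entropies, *including*
  the zeros of unobserved patterns. This deliberately deflates `HT` for
  series that visit few patterns — a periodic signal has `HT = 0` even
  though its few observed rows are deterministic anyway.

Throughout we use `D = 3`, `tau = 1` and series of `T = 2000` symbols as the
reference conditions. A guard warns when `L < 10 * D!`, below which pattern
statistics are unreliable. All entropies use natural logarithms and the
`0 log 0 = 0` convention.

For oscillatory or spiking signals the series fed to the symbolizer is
often a Poincaré reduction: the sequence of strict local extrema
(three-point comparison; plateaus yield no extremum; an optional amplitude
threshold isolates, e.g., spikes with `x > 0.5`).

## The three model families

All simulators use fixed-step integration so that "sample every 200
integration steps" is well defined, and are deterministic given a seed.
Randomness enters only through initial conditions and quenched parameter
disorder — no noise is injected into the dynamics.

* **Kuramoto phase oscillators**
  `dtheta_i/dt = omega_i + d * sum_j a_ij sin(theta_j - theta_i)`,
  integrated with RK4 at `dt = 0.01`. The per-node observable is the
  instantaneous frequency (the right-hand side evaluated at the retained
  instants, avoiding differentiation noise), sampled every 200 steps
  (2 time units). Star of `N = 31`: hub frequency 1.3, leaves
  `1 + 0.005 * U(0, 1)`.
* **Chialvo neural maps**
  `x' = x^2 exp(y - x) + I + d * sum_j a_ij (x_j - x_i)`,
  `y' = 0.89 y - 0.6 x + 0.28` (periodic/quasi-periodic spiking). The
  observable is the sequence of spike maxima (`x > 0.5`); spike times also
  define a phase that advances `2 pi` per spike with linear interpolation.
  Star: hub `I = 0.050`, leaves `0.049 + 1e-4 * U(0, 1)`; scale-free:
  `I = 0.049 + 3e-5 * k`.
* **Rössler oscillators** coupled through `y`
  (`a = 0.165, b = 0.4, c = 8.5`, phase-coherent chaos), RK4 at
  `dt = 0.01`. The observable is the Poincaré section of `y` minima; the
  phase is `atan2(y, x)`. Degree–frequency correlation
  `w = 1.06 + 2.73e-4 * k`; star leaves get an extra `U(0, 1e-4)` jitter so
  the backward branch can desynchronize — the value is a package choice (the
  magnitude is only described as "very small" in the ES literature for this
  setup) and is exposed in the configuration.

Coupling is normalized per link; `d = sigma / k_max` relates it to a global
coupling strength. Scale-free graphs come from a configuration-model draw of
a truncated power law (`gamma = 2.25`, mean degree 4 by choice of `k_min`),
simplified and reduced to the giant component. The degree cap is the
natural cutoff `N^(1/(gamma-1))` rather than the structural cutoff
`sqrt(N <k>)`: the structural cutoff would exclude precisely the
high-degree classes whose sentinel behaviour is under study, and it also
bends the degree CCDF away from a power law over the fitted range.

Default transients are 500 time units (flows) and 5000 iterations (map);
these are package choices, reported in every output.

## Sweep protocol

`run_sweep()` performs the adiabatic continuation: the stationary state at
one grid point seeds the next. Forward sweeps ascend from random initial
conditions; backward sweeps descend from an aligned state at the largest
coupling. Per grid point and node we record `H`, `HT`, the fluctuation
standard deviation `sigma_f` (population SD; the literature formula prints
the variance but names the standard deviation — we implement the SD) and
the lag-1 autocorrelation `AC(1)` in its *uncentered* printed form (a
centered variant sits behind a flag), all on the same observable series
used for the entropies, plus the order parameter `R` over the same window.

`critical_coupling()` operationalizes "abrupt": the first grid step whose
change in `R` (in the sweep's direction) exceeds 0.4 marks the jump;
otherwise the sweep is flagged non-explosive and the largest step is
reported. Hysteresis width is the floored difference of the forward and
backward critical couplings. The multistability that makes the transition
explosive also makes individual sweeps protocol-dependent (grid spacing,
relaxation time and disorder realization shift the jump by a few grid
points); all such quantities are therefore reported as realization
averages.

## Early-warning analysis

Nodes of equal degree are statistically equivalent, so per-node quantities
are averaged within degree classes (`k_class_average()`); the N_k-weighted
mean of the class averages recovers the global mean exactly. The
early-warning statistic is the difference between the most- and
least-connected classes,
`Delta(d) = <HT>_hub - <HT>_ref`, with the reference class the
minimum-degree class (on scale-free graphs this is the modal low-degree
class, which averages many nodes and so has low variance).

`ews_alarm()` turns the trace into an alarm: a baseline mean and SD are
estimated from the lowest-coupling grid points (default 3 — using the
lowest *couplings* rather than an uncoupled recording keeps the rule
applicable to experimental data), and the alarm fires at the first coupling
where `Delta` exceeds `mean + 3 SD` for two consecutive grid points (the
persistence requirement suppresses single-point noise). The multiplier,
baseline width and persistence are parameters; "rises noticeably" has no
canonical operationalization, so the alarm report always states the rule it
applied.

`degree_cutoff()` compares two degree-class profiles (far from and near the
transition) and returns the smallest degree above which the near profile
exceeds the far one by a margin (default 0.05, a configuration value) for
all larger observed classes.

## What reproduces, and what does not

These statements summarize what the package's own acceptance checks
compute; none of them are imported numbers.

* **Chialvo (star and scale-free)**: the full published phenomenology
  emerges — an explosive forward transition with a clear hysteresis loop on
  the star, and a hub-class OPT entropy that rises by ~0.5–0.7 while the
  order parameter is still flat, with low-degree classes moving much less.
* **Kuramoto star**: the hub-leaf entropy divergence is a small systematic
  effect (~0.03–0.08 in `HT`) on top of realization noise of comparable
  size. With ensemble averaging at the reference statistics (≥ 1500
  samples, ~8 disorder realizations) the hub class rises from about one
  third of the critical coupling, the leaf class stays flat, and the
  3-sigma alarm fires near `0.35 * d_c`. Single realizations or short
  series do not resolve the effect.
* **Rössler**: in our integrations the sentinel entropy *departs from
  baseline early but downward*: the nearly coherent mean field of the leaf
  ensemble (or of a hub's neighborhood in the scale-free graph) entrains
  the sentinel's chaotic amplitude dynamics and makes its Poincaré sequence
  more regular, so `<HT>_hub` falls from ~0.43 toward ~0.05 well before the
  jump while leaf classes stay flat. The direction is opposite to the rise
  reported for this system in the literature this package models; we probed
  integration step, transient length, disorder width, topology and system
  size without recovering a rise. The *magnitude and earliness* of the
  departure still single out high-degree nodes as sentinels, and the
  package reports the signed and absolute departures. Consequently the
  margin-rule degree cutoff (which presumes an upward excess) returns
  "none" on our scale-free profiles; the departure-onset degree based on
  the absolute difference is reported alongside.

The synthetic experiments emulate quenched parameter disorder and
deterministic dynamics only. Real recordings add measurement noise,
component tolerances and drift; ordinal methods are robust to moderate
amounts of these, but a passing synthetic suite does not by itself
establish performance on noisy experimental data. The circuit-dataset
reader ingests externally recorded voltage series arranged in a documented
plain-text layout (`dataset.yaml` plus one CSV per coupling step); the
published electronic-circuit deposit must be converted by the user into
this layout, and the package's own fixture is a clearly labelled synthetic
stand-in generated from a short six-node Rössler star run.

## Numerical choices and degenerate inputs

* Tie-breaking in blocks: stable (earlier sample ranks lower); plateaus in
  Poincaré sections yield no extremum (strict comparisons).
* Transition-matrix rows of unobserved patterns are zero, their local
  entropy is 0 by the `0 log 0` convention, and source counts exclude the
  final symbol.
* Empty Poincaré sections, too-short reduced series (`H`/`HT` become `NA`),
  constant series (`sigma_f = 0`), zero-norm autocorrelation windows
  (`NA` with a warning) and zero-length sweep grids (empty result) are all
  non-fatal.
* `R` from spike phases uses the common window between every node's first
  and last spike; it is `NA` when some node spikes fewer than twice.
* Grids are floored at representable couplings only; jump detection breaks
  ties at the first index.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run scaled versions of the
reference conditions, chosen to keep the full suite in the tens of minutes
on a single core: Kuramoto star 20 grid points × 8 realizations × 1500
samples in the tests, and the full 10 realizations × 2000 samples in the
acceptance script; Chialvo star 15 points × 3 realizations ×
1000–1200 spike maxima, scale-free `N = 100` single realization; Rössler
star 12 points × 2 realizations × 300–400 minima, scale-free `N = 200` and
two couplings instead of `N = 500` × 64 realizations. The scale-free
Rössler experiment at full published size is far beyond a desktop budget;
the scaled version preserves the degree-resolved contrast it is meant to
show.
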