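---
title: "Sentinel-node early warning signals for multi-stage transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sentinel-node early warning signals for multi-stage transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Each node $i$ of an undirected, unweighted network carries a state $x_i$
governed by a coupled double-well stochastic differential equation

$$\frac{dx_i}{dt} = -(x_i - r_1)(x_i - r_2)(x_i - r_3)
  + D \sum_{j=1}^N a_{ij} x_j + u + s\,\xi_i ,$$

where $a_{ij}$ is the adjacency matrix, $r_1 < r_2 < r_3$ place the lower
stable, unstable and upper stable equilibria of an isolated node (defaults
$(1, 4, 7)$, all in state units), $D \ge 0$ is the coupling strength, $u$
is a uniform stressor (state units per time unit, default 0) and $s\,\xi_i$
is independent Gaussian white noise of standard-deviation parameter $s$
(default 0.05). The cubic term derives from a quartic double-well
potential; the coupling term pushes a node towards its neighbours' states.
On a heterogeneous network the upward transition is typically
*multi-stage*: hubs and nodes adjacent to already-tipped neighbours tip at
smaller $D$ than peripheral nodes, so the equilibrium composition changes
in several discrete jumps as $D$ grows.

A node's *macro state* is classified against the critical points of the
cubic term, the roots of
$\tfrac{d}{dx}\left[-(x - r_1)(x - r_2)(x - r_3)\right] = 0$:

$$x = \frac{(r_1+r_2+r_3) \pm \sqrt{(r_1+r_2+r_3)^2
  - 3(r_1 r_2 + r_1 r_3 + r_2 r_3)}}{3}.$$

For $(1, 4, 7)$ these are $4 \mp \sqrt 3 \approx 2.268$ and $5.732$. In
lower-start sweeps a node with $x_i < 2.268$ is in the lower state; in
upper-start sweeps the boundary is $5.732$. The measure-zero boundary value
itself is assigned to the upper state (the strict inequality is applied to
the lower side only).

## Simulation protocol

`run_sweep()` performs a quasi-static sweep of a bifurcation parameter
($D$, or $u$ with $D$ held fixed). At each parameter value the state is
reset to the initial condition ($x_i = r_1$ everywhere for lower-start
sweeps; $x_i = r_3$ with $u = -15$ for the upper-start protocol),
integrated by Euler–Maruyama with step $\Delta t = 0.01$ TU for 50 TU of
relaxation, and sampled for a further 25 TU at 0.1 TU intervals, giving
$M = 250$ samples per node. The parameter then moves by $\pm 0.005$ and
the procedure repeats until more than 90% of nodes have left their
original macro state. Because every value is re-equilibrated from scratch,
the sampled fluctuations are stationary by construction and no detrending
is applied.

Numerical choices worth stating:

* The noise term is discretized as $s\sqrt{\Delta t}\,Z$ with independent
  standard-normal draws per node per step, the increment the
  Euler–Maruyama scheme presupposes. The integrator is fixed-step; no
  adaptivity.
* Draws come from R's RNG in node order, so a single seed makes the whole
  pipeline bitwise reproducible. One child seed per parameter value is
  derived from the sweep seed up front, which makes each block's noise
  independent of how far the sweep eventually runs (truncating the sweep
  never rewrites earlier blocks).
* Equilibrium macro-state classification uses each node's mean over the
  $M$ samples against the threshold, which is robust to noise jitter near
  the boundary; the instantaneous state at the end of relaxation
  ($t = 50$ TU) defines lower/upper-state *membership* for node-set
  selection. Both instants are defensible readings of "state at
  equilibrium"; the package makes the choice explicit rather than
  implicit.
* A non-finite state aborts integration with an error naming the step; a
  sweep that fails to reach the stopping fraction within `max_values`
  parameter values errors rather than looping.

## Early warning signals and node sets

From each block's $M \times N$ sample matrix, `sweep_signals()` computes
five signals of critical slowing down for every requested node set: the
dominant eigenvalue of the node-set covariance matrix, and the maximum and
mean of the per-node standard deviation and lag-1 autocorrelation. The
autocorrelation estimator shares a single mean across numerator and
denominator,
$\sum_{m=1}^{M-1}(x_m - \bar x)(x_{m+1} - \bar x) / \sum_{m=1}^{M}(x_m - \bar x)^2$;
a constant series yields a missing value rather than a fabricated 0, and
missing values propagate (they are excluded from aggregates and from
scoring). Sample statistics use the conventional $M - 1$ denominator.

Nine node-set rules are re-evaluated at every parameter value: all nodes;
the lower- and upper-state sets; the top/bottom-$n$ *available* nodes
(still in their original macro state) by the input score
$R_i = \sum_j a_{ij} \bar x_j$ (High/Low Input); available lower-state
nodes with $R_i$ strictly below the median (Lower Half); $n$ uniformly
random nodes; and two structure-free alternatives that rank available
nodes by the correlation score $R'_i = \sum_{j \ne i} cor(x_i, x_j) \bar x_j$
(Large Correlation) or by the sample standard deviation (Large s.d.). The
default $n = 5$. Design points where the definitions left room:

* Ranking ties are broken by lowest node index, for determinism.
* Large s.d. and Large Correlation are restricted to available nodes,
  consistent with their role as structure-free stand-ins for High Input;
  Random draws from all nodes.
* "Below the median" is read strictly, with the median taken over the
  available lower-state nodes.
* `membership_samples` optionally restricts the *selection* scores (means,
  standard deviations, correlations) to the first few samples while the
  signals still use all $M$ — useful for asking how much monitoring data
  node-set selection itself needs.

## Scoring

A *stable range* is a maximal run of consecutive parameter values with a
constant equilibrium macro-state count; a range qualifies for scoring when
it has at least 15 unique values. Within each qualifying range,
`score_sweep()` computes the tie-corrected Kendall rank correlation
(tau-b) between the parameter and each signal and averages over ranges; a
range contributes to a combination only when at least 15 defined signal
values remain after dropping missing ones. Signed tau is reported: in
upper-start sweeps a strongly negative tau is the signature of critical
slowing down as the parameter decreases. `per_transition_tau()` attributes
each count change to the stable range immediately preceding it, which
shows whether a signal anticipated *each* stage of a multi-stage
transition rather than performing well only on average. No
multiple-testing correction is applied — tau is a performance score here,
not a test statistic.

## What the synthetic networks emulate — and what they do not

The bundled generators (configuration-model power law, Erdős–Rényi,
planted communities) reproduce the two features that drive multi-stage
transitions: degree heterogeneity and community structure. Defaults are
$N = 100$, exponent 3, minimum degree 2, matching the order-100-node scale
at which the phenomenon is commonly studied; disconnected remainders are
dropped (the coupling term is meaningless across components), so the
realized $N$ can be slightly below the request. These synthetic networks
are not calibrated to any particular empirical system: real networks carry
degree correlations, clustering and motif structure the generators do not
produce, so passing tests demonstrate that the method behaves as designed
under controlled heterogeneity, not that any given empirical network will
yield equally strong signals. Users with their own networks can supply
them as edge lists or GraphML via `read_network()`.

One consequence of the exponent-3 default is worth knowing: hubs are
moderate (maximum degree near $\sqrt N$), so the first node transition
occurs relatively late in the sweep and the first stable range is long and
mostly far from any bifurcation. The noisy maximum-statistics
(`max_ac` especially, a maximum of ~100 estimates each with sampling error
$\sim 1/\sqrt M$) then average a weaker trend over that range than the
mean- and variance-based signals, and their average tau can fall slightly
below what more heterogeneous networks with earlier first transitions
produce. The variance-based signals and the sentinel sets are robust to
this.

## Problem sizes in the tests

The unit tests run short sweeps (a few TU of sampling) on graphs of 2–20
nodes so that every protocol branch is exercised quickly; the end-to-end
acceptance checks run the full protocol once — a 100-node power-law
network, $\Delta t = 0.01$, 50 + 25 TU, $M = 250$, $\Delta D = 0.005$,
roughly 230 parameter values — which takes a few tens of seconds with the
compiled integrator. The Ornstein–Uhlenbeck checks use a single node for
1000 TU: linearized about $x = r_1$ the restoring rate is
$(r_2 - r_1)(r_3 - r_1) = 18$, so the stationary standard deviation is
$s/\sqrt{36}$ and the lag-1 autocorrelation at 0.1 TU spacing is
$e^{-1.8} \approx 0.165$. The Euler–Maruyama discretization at
$\Delta t = 0.01$ biases that autocorrelation to
$(1 - 0.18)^{10} \approx 0.137$, which the test tolerance accommodates.

## Known limitations

* Dynamics are homogeneous across nodes (one $(r_1, r_2, r_3, u, s)$ for
  all); weighted, directed or bipartite networks are out of scope.
* Only the two one-directional protocols are automated; hysteresis loops
  must be composed by the user.
* The per-value child-seed policy means noise is independent across
  parameter values; this matches the reset-and-re-equilibrate protocol but
  differs from a single continuous noise path.
* Node indices are 1-based inside R; file I/O accepts arbitrary labels
  (numeric labels are ordered numerically on read, so write/read
  round-trips preserve the adjacency exactly).
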