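---
title: "Three-threshold learning in recurrent attractor networks: model and methods"
author: "tlrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-threshold learning in recurrent attractor networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlrnet)
```

# The model

`tlrnet` simulates a fully connected network of $N$ binary (McCulloch–Pitts)
excitatory neurons, $s_i \in \{0,1\}$, with plastic non-negative recurrent
weights $w_{ij} \ge 0$, $w_{ii} = 0$ (Dale's principle for excitatory
synapses), plus a single aggregated, non-plastic inhibitory feedback unit.
Updates are synchronous and deterministic:

$$ s_i' \;=\; \Theta(v_i - \theta), \qquad
   v_i \;=\; \sum_j w_{ij}\, s_j + x_i - I(\mathbf{x}, \mathbf{s}), $$

with the strict Heaviside convention $\Theta(0) = 0$, a neuronal threshold
$\theta = (N-1)\psi$, binary external fields $x_i \in \{0, X\}$, and the
global inhibition

$$ I(\mathbf{x}, \mathbf{s}) \;=\;
   H_0 \;+\; H_1\, \mathbf 1[\mathbf{x} \ne 0]
       \;+\; \lambda \Big(\sum_i s_i - f N\Big). $$

$f$ is the target activity level (and the coding level of the memory
patterns), $\lambda$ the inhibitory feedback slope, $H_0$ the basal
inhibition and $H_1$ the inhibitory reaction to the external input. With

$$ H_0 = (N-1)(f\bar w - \psi) + H^{-1}(f)\sqrt{(N-1)f}\;\sigma_w,
   \qquad H_1 = f\gamma\sqrt{N-1}, \qquad \lambda = \bar w, $$

where $H(x) = \tfrac12\,\mathrm{erfc}(x/\sqrt2)$ and $\bar w$, $\sigma_w$
are the mean and standard deviation of the weights, the quiescent network
self-stabilizes at activity $f$: the $H^{-1}(f)$ term places $\theta$ at the
$f$-quantile of the recurrent field distribution (it vanishes exactly in the
dense regime $f = 0.5$). Weights are initialized as rectified
$\mathcal N(1,1)$ draws, giving $\bar w = \Phi(1)+\phi(1) = 1.0833$ and
$\sigma_w = 0.8667$.

In the sparse regime, activities below $f$ can flow into the quiescent
(all-off) state; self-stabilization holds for initial activities at or above
$f$, which is the operating range of all protocols here (retrieval always
starts near a pattern).

## External-field strength and the inhibitory reaction

A memory pattern $\boldsymbol\xi$ is imposed as $x_i = X\xi_i$. Two design
choices make the presentation geometry exact at every coding level:

* the inhibitory reaction engages at its calibrated magnitude $H_1$
  whenever a stimulus is present. $H_1$ is the design value of the
  response to a pattern at coding level $f$; tying the reaction to the
  realized per-pattern activity instead would shift the clamped fields by
  $O(\gamma\sqrt{f(1-f)}\,z_\mu)$ for a pattern whose active count deviates
  by $z_\mu$ standard deviations — Bernoulli coding would then misalign the
  learning thresholds pattern by pattern, and the zero-margin
  ($\varepsilon = 0$) protocol could never store anything at finite $N$;
* the field strength is $X = 2H_1 = 2f\gamma\sqrt{N-1}$, equal to the
  dense-regime form $\gamma\sqrt N$ up to $O(1/N)$. A presented pattern
  then shifts the stimulated population by $X - H_1 = +H_1$ and the
  unstimulated population by $-H_1$: symmetric shifts of the same
  magnitude at every coding level, which is what the learning thresholds
  below assume (with an asymmetric split the potentiation window could
  never be reached at $f < 0.5$). The distance between the two bumps of
  the clamped field distribution is $X$.

# The three-threshold rule

Training presents the $p$ patterns sequentially in a fresh random
permutation per sweep. For each pattern: (1) the external field is applied
and one synchronous update is performed — for $\gamma$ large enough this
clamps the state to the pattern; (2) the local fields are recomputed in the
clamped condition and every synapse from an active presynaptic neuron is
updated according to the postsynaptic field:

$$ w_{ij} \leftarrow
   \begin{cases}
     w_{ij} - \eta\, s_j & \theta_0 < v_i < \theta \quad (\text{depression})\\
     w_{ij} + \eta\, s_j & \theta < v_i < \theta_1 \quad (\text{potentiation})\\
     w_{ij} & \text{otherwise (no plasticity)},
   \end{cases} $$

with open intervals (a field exactly at a threshold changes nothing),
elementwise clipping at zero after depression, and

$$ \theta_{0,1} \;=\; \theta \mp \big(H_1 + \varepsilon f \sqrt N\big)
   \;=\; \theta \mp (\gamma + \varepsilon) f \sqrt N + O(1/\sqrt N). $$

Because the clamped fields are the free fields shifted by exactly
$\pm H_1$, a field outside $(\theta_0, \theta_1)$ during presentation
corresponds exactly — for every pattern — to a free field beyond the robust
margin $\pm \varepsilon f\sqrt N$ around $\theta$: the rule is the
supervised perceptron rule with the "error signal" read off the local field
itself.
The robustness parameter $\varepsilon \ge 0$ widens the enforced margin,
trading storage capacity for basin size. At strong drive the mapping is
exact: `train3TLR()` and `trainPLR()` produce bit-identical weight
trajectories under shared randomness at $\gamma = 12$, $f = 0.5$ — a
property the test suite asserts as an oracle. At moderate $\gamma$ the two
field bumps overlap slightly; the rule occasionally misreads the desired
output (depressing where it should potentiate), which is also the mechanism
behind the sharp capacity collapse when $\gamma$ is lowered too far.

## Stopping rule

After each sweep the robust fixed-point condition is checked for every
pattern with zero external field: ON units need
$v_i > \theta + \varepsilon f\sqrt N$, OFF units
$v_i < \theta - \varepsilon f\sqrt N$ (strict inequalities; this is the
condition the learning thresholds enforce, since the clamped-field shifts
are exactly $\pm H_1$). Training stops at the first sweep with zero
violations; `countViolations()` exposes the same count for any weight
matrix. Convergence therefore certifies every pattern as a fixed point with
an ON/OFF field gap of at least $2 f \varepsilon \sqrt N$.

Defaults follow the simulation protocol: $\eta = 0.01$ with a 1000-sweep
budget, switching to $\eta = 0.001$ and 10000 sweeps at $\varepsilon = 0$;
$\psi = 0.35$; $\gamma = 6$ dense, $\gamma = 12$ sparse; 50 retrieval trials.

## Recalibration away from the dense regime

$H_0$ contains a $\sigma_w$ quantile term that vanishes at $f = 0.5$ but
moves as learning reshapes the weight distribution; at $f \ne 0.5$ this term
is recomputed after every sweep (and once more before retrieval,
`recalibratedParams()`). Only the quantile term adapts: the mean-weight
anchor inside $H_0$, and $\lambda$, stay at their initial calibration. The
fixed anchor is essential — it pins the mean weight near its initial value
(the constraints force $\sum_j w_{ij}\xi_j \approx \theta + H_0$), which is
why $\bar w \approx 1.08$ is stable under training. Letting the anchor chase
the current mean un-pins $\bar w$, which then drifts downward and inflates
the effective robustness $K = \varepsilon/\bar w$ until the problem becomes
unsatisfiable; we verified this failure mode explicitly before fixing the
anchor.

# Measurement protocols

**Retrieval and basins.** A pattern set is successfully stored at basin
fraction $b$ if every pattern is retrieved in at least 90% of trials, where
a trial resamples a random fraction $b$ of the units Bernoulli($f$)
(expected normalized Hamming distance $2f(1-f)b$, i.e. $b/2$ at $f=0.5$)
and runs free dynamics for at most 30 synchronous steps; retrieval means
ending within normalized distance 0.01 of the pattern. Defaults: 50 trials
per pattern, $b$-grid resolution 0.05. A period-2 oscillation is reported
as non-convergence.

**Capacity.** `storageSuccess()` composes pattern generation, weight
initialization, training and the basin criterion under one master seed;
`capacityCurve()` estimates the success probability over a load grid
(default 10 replicates) and interpolates the 0.5 crossing;
`optimizeOverEps()` maximizes that crossing over a robustness grid at fixed
basin size; `gammaSweep()` and `compareRules()` implement the field-strength
sweep and the matched-randomness rule comparison.

**Baseline.** The Hopfield baseline stores $\pm1$-coded patterns with the
Hebbian outer-product rule and its own sign dynamics at threshold zero.
Its breakdown load is located by initializing at each stored pattern and
sweeping the load on a 0.005 grid until the mean final overlap drops below
0.95; at $N = 500$ this lands near 0.14, consistent with the known
$0.138\,N$ asymptotic capacity. For capacity-ratio comparisons the Hebbian
network is scored with the identical basin criterion as the
three-threshold network.

# Replica-symmetric theory

Each neuron solves an independent perceptron problem with non-negative
weights. Rescaling $W_j = w_j/\bar w - 1 \in [-1,\infty)$ turns the robust
margin into $K = \varepsilon/\bar w$. The quenched entropy of the solution
volume is evaluated under the replica-symmetric ansatz; extremization gives
six coupled saddle equations in the order parameters $(Q, q, M)$ and their
conjugates. We re-derived the quenched average from the constraint
$\sigma^\mu(\sum_j W_j \xi_j^\mu - T\sqrt{Q}\sqrt N) > fK\sqrt N$ from first
principles, normalizing the Gaussian field by its standard deviation
$\sqrt{f(1-f)NQ}$; this fixes the reduced margin $\kappa = K\sqrt{f/(1-f)}$
and threshold coefficient $H^{-1}(f)/\sqrt{1-f}$ entering the solver. At
$f = 0.5$ the normalization is invisible ($\kappa = K$, $T = 0$), so every
dense-regime result is independent of it.

Two independent solvers are implemented and cross-checked:

* `entropySaddle()` solves the full six-equation system below capacity
  (damped Newton with numerical Jacobian, 201-node Gauss–Hermite
  quadrature, residuals scaled per equation because the conjugate
  parameters diverge as $\Delta Q = Q - q \to 0$, continuation in the load
  near capacity);
* `criticalCapacity()` solves the critical system obtained in the
  $\Delta Q \to 0$ limit, where the conjugates diverge as
  $\hat q = C/\Delta Q^2$, $\Delta\hat Q = A/\Delta Q$,
  $\hat M = B\sqrt C/\Delta Q$. Taking this limit ourselves resolves the
  ambiguities a naive reading of the critical equations leaves open: the
  system closes with $u_c = B - A/\sqrt C$, $A = H(u_c)$,
  $0 = (\sqrt C/A)(G(u_c) - BA) - (1-A)$ and
  $Q = (1-A) + [C(1+B^2)A - (BC + A\sqrt C)G(u_c)]/A^2$.

The two routes agree: extrapolating $\Delta Q \to 0$ linearly from loads at
0.97–0.995 of the critical value reproduces `criticalCapacity()`'s
$\alpha_c$ to better than $10^{-3}$ across $K$ (a test asserts this at
$K = 0.5$).

At $K = 0$ the system has a degenerate branch ($Q \to 0$) on which the
weight scale can shrink until the non-negativity boundary is irrelevant: the
capacity equals the unconstrained Gardner value
$\alpha_c = 1/\langle \mathcal B(\sigma a)\rangle_\sigma$ with
$\mathcal B(\tau) = (1+\tau^2)H(\tau) - \tau G(\tau)$ and the offset $a$
solving $\langle\sigma(G - \tau H)\rangle_\sigma = 0$ — exactly 2 at
$f = 0.5$, and larger at sparser coding (2.668 at $f = 0.2$). For $K > 0$
the solver reduces the system to three unknowns $(Q, M, \alpha)$, uses
multistart damped Newton with continuation in $K$, demands residuals below
$10^{-8}$, and raises an error rather than returning an unconverged value.

All Gaussian functions ($G$, $H$, the inverse Mills ratio $G/H$) are
evaluated in log space via `dnorm`/`pnorm`, stable to arguments of
magnitude $\sim 40$.

# What the synthetic patterns do and do not emulate

Patterns are Bernoulli($f$) per entry — independent entries, fluctuating
per-pattern activity — optionally organized into $L$ categories by copying
each prototype entry with probability $c$ and resampling it otherwise
(pattern–prototype Pearson correlation exactly $c$, within-category pair
correlation $c^2$). This matches the generative assumptions of the model
and theory but not several features of real neural activity: no
spatiotemporal structure, no heavy-tailed rate distributions, no
correlation between pattern statistics and connectivity.

Bernoulli coding makes the per-pattern active count fluctuate by
$\sqrt{Nf(1-f)}$; the engaged-at-calibrated-magnitude inhibitory reaction
(see above) keeps the learning geometry exact despite these fluctuations.
What remains is the ordinary finite-size statistics of the constraint
problem itself: desk-scale networks reach a visibly smaller fraction of
the theoretical capacity than $N = 1001$ runs, and per-pattern activity
fluctuations enter the inhibition only through the $\lambda$ feedback term,
which both training and retrieval share.

# Problem sizes and numerical choices

The test suite runs everything at desk scale: networks of $N = 101$–501,
loads to a few hundred patterns, 20–50 retrieval trials, sweep budgets
capped at 300–600 where a run near capacity would otherwise use the full
budget. The headline full-scale protocols ($N = 1001$: zero-basin capacity
near 1.6, the $\gamma \approx 2.4$ collapse, the sparse regime at 70% of
theory, the $\ge 11\times$ Hopfield ratio) take hours of single-core CPU
and are shipped as ready-to-run configurations (`fullScaleTargets()`,
dispatchable through `runExperiment()` or the command-line script in
`inst/scripts/`).

Deterministic choices worth knowing: ties at thresholds never potentiate,
depress, or activate (strict inequalities everywhere, $\Theta(0)=0$);
seeds spawn per-pattern and per-trial sub-streams through a fixed integer
mixing function, so pattern sets are extendable and experiments replayable
bit for bit; the training loop consumes randomness only for the
presentation permutations, which is what makes the matched-randomness
3TLR/PLR comparison exact; all weight clipping produces exact zeros, so
the silent-synapse fraction uses an exact-zero test by default.

# Known limitations

* Synchronous deterministic dynamics only; no asynchronous updates, no
  neuronal noise, no dilution of the connectivity.
* The inhibitory population is a single linear feedback unit; no explicit
  inhibitory neurons.
* Replica symmetry is assumed in the theory (exact for continuous-weight
  perceptrons at these margins, but corrections beyond it are not
  implemented), and finite-$N$ corrections to the theory are not computed —
  simulated capacities at desk scale sit visibly below $\alpha_c$.
* Palimpsest (sequential forgetting) protocols are out of scope.
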