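---
title: "An adaptive frequency-modulated oscillator model of whole-brain dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An adaptive frequency-modulated oscillator model of whole-brain dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainsl)
```

## The model and its assumptions

`brainsl` models every cortical region as a Stuart–Landau oscillator — the
normal form of a supercritical Hopf bifurcation, and the simplest dynamical
system with both amplitude and phase dynamics. Region $j$ carries a complex
state $z_j = r e^{i\theta}$ and a free-running angular frequency $\omega_j$:

$$
\dot z_j = (a_j + i\omega_j - |z_j|^2)\, z_j
         + G \sum_i C_{ij}\,(z_i - z_j) + \beta\,\eta_j ,
\qquad
\dot\omega_j = \omega^0_j - \lambda\,\omega_j + m\,\psi_j ,
$$

with $\psi_j = \sum_i C_{ij}\,\theta_i$ the connectivity-weighted *net phase
of the neighbour ensemble*, and $\theta_i$ the **two-quadrant** arctangent of
$\mathrm{Im}\,z_i/\mathrm{Re}\,z_i$ on $[-\pi/2, \pi/2]$. For $a_j < 0$ the
origin is stable and the region produces noise-driven fluctuations; for
$a_j > 0$ a limit cycle of radius $\sqrt{a_j}$ emerges. The real part of
$z$ is interpreted as the measurable BOLD-like signal; the imaginary part is
a hidden state.

The second equation is the model's distinctive ingredient: the free-running
frequency is not fixed but *adapts*. It relaxes toward $\omega^0_j/\lambda$
with rate $\lambda$ (the frequency "lethargy") and is pushed around by the
net phase of structurally connected neighbours with gain $m$. Setting
$m = 0$ recovers the classic coupled Stuart–Landau model with static
frequencies, which serves as the comparison model throughout (including in
the AIC comparison, where the adaptive model has $k = 4$ fitted parameters
and the classic one $k = 2$).

Two phase conventions coexist deliberately. *Inside the model*, $\theta$ is
the two-quadrant arctangent above. *On signals* (simulated or reference),
instantaneous phases are the four-quadrant argument of the analytic signal
(FFT-based Hilbert transform of the demeaned series). Both are implemented
exactly where they belong; they are not interchangeable.

## Numerical integration

The coupled stochastic system is integrated by Euler–Maruyama in compiled
code. Choices, and why:

* **Step size** `dt = 0.01` s by default; `dt` is snapped to the nearest
  exact divisor of the output interval `tr` so recorded instants fall on
  integration steps. Euler–Maruyama is first-order; the test suite verifies
  the noise-free radial solution against its closed form
  ($r(t)^2 = a r_0^2 e^{2at}/(a - r_0^2 + r_0^2 e^{2at})$) and the $O(dt)$
  convergence under step halving. A known artefact of explicit Euler on
  rotating systems is a radial inflation of order $dt\,\omega^2/2$; at
  default settings this is $\sim 10^{-3}$ relative and is accounted for in
  the amplitude tests.
* **Noise** enters the real and imaginary components independently, each as
  $\beta\sqrt{dt}\,\mathcal N(0,1)$ per step ($\beta = 0.02$ by default).
  Draws come from R's RNG, so a single `set.seed` makes whole trajectories
  bitwise reproducible.
* **Initial conditions**: $z_j(0)$ uniform on the complex disk of radius
  $\max(\sqrt{\max(a_j, 0)}, 0.1)$ and $\omega_j(0) = \omega^0_j/\lambda$ —
  the attracting set of the deterministic skeleton — so burn-in can be short
  (60 s by default; recordings mimic a resting-state run of 1190 samples at
  `tr` = 0.72 s).
* **Degenerate phases**: at $\mathrm{Re}\,z = 0$ the two-quadrant phase is
  $\pm\pi/2$ by sign of the imaginary part, and 0 at $z = 0$.
* **Blow-up** (non-finite state or $|z| > 10^6$) aborts with the offending
  step index; the grid search flags such cells as degenerate rather than
  failing the whole sweep.

## Observables and the fitting target

Model and reference signals are summarized identically: static FC
(product-moment correlations; Fisher-z group averaging), Newman modularity
over the *fixed* functional-system partition (negative FC weights clipped at
zero, the double sum running over all ordered pairs with $w_{ii} = 0$),
instantaneous phase-coherence FC $1 - |\sin\Delta\theta|$, the distribution
of cosine similarities between half-vectorized instantaneous FC matrices
across time-point pairs (exhaustive up to 250{,}000 pairs, seeded subsample
beyond), the Kuramoto order parameter with synchrony (time mean) and
metastability (time SD), and in-band Welch spectral peaks for intrinsic
frequencies (Hann window, segment length $\min(256, T/2)$, 50% overlap — a
standard resolution/variance trade-off). The first and last 5% of time
points are dropped from phase-based metrics to avoid analytic-signal edge
effects (configurable).

A candidate working point is scored by five distances: $(1 - r_{FC})/2$,
$|Q - Q_{ref}|$, the two-sample Kolmogorov–Smirnov statistic between dFC
similarity distributions, and absolute synchrony and metastability
differences. Each distance is unity-normalized across the whole grid (the
full grid, not per-slice, is the normalization basin) and averaged; the
argmin cell is the fitted working point. Every cell is simulated with one
common seed so that cell-to-cell differences reflect parameters, not noise
realizations; degenerate cells receive the worst normalized distance on
every metric. The modularity distance targets the reference value rather
than "as high as possible" — the conservative reading when the goal is to
match, not idealize, a reference network.

## The synthetic study generator

The generator stands in for an empirical resting-state + tractography study
and fixes the study conditions: 68 regions in six functional systems,
0.72 s sampling, 1190 time points, a 0.02–0.12 Hz band, and 20 subjects at
desk scale. Structural connectomes are modular (within-system edge
probability four times the between-system one), with log-normal template
weights, per-subject multiplicative weight jitter and 20% per-subject edge
dropout. The group connectome keeps edges nonzero in at least 60% of
subjects — averaging over *all* subjects including zeros, which preserves
the streamline-density scale — and is then rank-mapped onto Gaussian
quantiles $\Phi^{-1}(k/(M+1))\cdot 0.15 + 0.5$ (the $k/(M+1)$ plotting
position keeps the extremes finite; ties break by stable edge index).

Ground-truth dynamics default to the fitted working point of the reference
analysis ($a = 0.038$, $G = 0.01$, $\lambda = 0.4$, $m = 0.14$,
$\beta = 0.02$). Per-node spectral peaks are drawn uniformly in the band and
the intrinsic drive is set to $\omega^0 = \lambda \cdot 2\pi f$ so the
*post-relaxation* frequency $\omega^0/\lambda$ sits at the drawn peak (when
fitting real reference data, `estimate_intrinsic_frequencies` returns the
angular peak verbatim; `scale_omega0_by_lambda` opts into the rescaling).
Observation noise is white Gaussian on $\mathrm{Re}\,z$ — the simplest
stand-in for scanner noise. The generator does **not** emulate hemodynamics,
motion, physiological noise spectra, or spatially correlated noise, so
passing closed-loop tests demonstrates internal consistency of the pipeline,
not fidelity to any particular dataset.

One consequence of the adaptive term worth knowing: with $m > 0$ the
neighbour-phase drive shifts each region's realized spectral peak away from
$\omega^0/\lambda$ (by roughly $m\,\psi/\lambda$). In the classic $m = 0$
regime the generator's peaks are recovered within one Welch bin for ≥90% of
regions; under the adaptive defaults the recovered peaks still track the
ground truth closely (rank correlation > 0.9) but only within a few bins.
This is a property of the model, not an estimator defect — the adaptive
model's whole point is that realized frequencies are network-dependent.

## The lesion suite

A lesion sets a region's bifurcation parameter to $a = -2$, moving it from
the oscillatory into the noise-driven regime while leaving the anatomy
untouched. The suite runs one baseline and one lesion simulation per region,
all with the *same* noise seed, so differences are attributable to the
lesion (independent seeds are a flag). Vulnerability maps average positive
and negative relative changes separately: nodal maps from FC strength (raw
signed row sums, diagonal excluded), link maps from inter-system mean FC.
Hazard mapping builds a 13-dimensional static feature vector per set (global
efficiency and per-system local efficiency of the binarized FC, both
normalized by degree-preserving double-edge-swap null models with 20
realizations and 10 swaps per edge; per-system segregation as the Chan-style
within-vs-between contrast) plus a 3-dimensional phase vector (dFC
coordinate entering as the KS distance to baseline, synchrony,
metastability). Features are unity-normalized across the $N+1$ sets
(undefined segregation values are imputed with the across-set median and
logged), Euclidean distances from baseline are computed separately in the
two spaces, unity-normalized across the lesions (lesions only, not the
baseline, form the basin for this final normalization), and summed into the
hazard score in $[0, 2]$. Null-model seeds are derived per *feature*, not
per set, so identical FC matrices always yield identical features and a
no-op lesion scores exactly zero.

Robustness curves lesion $\lfloor fN \rfloor$ regions simultaneously —
randomly (averaged over seeded repetitions; 100 by default, 2000 in the
reference analysis) or in descending hub-score order, where the hub score is
the mean of unity-normalized strength, betweenness and closeness computed on
the *structural* connectome (path lengths use $1/\text{weight}$, the
standard transform for streamline densities). The binarized-FC giant
component (undirected connected component; "strongly connected" would be
vacuous for symmetric FC) is reported relative to the unperturbed run, so
$f = 0$ is exactly 1.

### A known limitation: entrained lesions at small $f$

Because the diffusive coupling keeps driving a lesioned region, a
high-strength hub lesioned to $a = -2$ is passively entrained by its
neighbours with amplitude $\approx G\,s_j\,r/|a_{lesion}|$. When that
exceeds the FC binarization noise floor, lesioned hubs *stay attached* to
the giant component, whereas randomly lesioned low-strength regions drop
out. At desk scale this makes targeted attacks marginally *less* damaging
than random failures for small lesion fractions ($f \approx 0.2$), while for
$f \gtrsim 0.35$ targeted attacks fragment the network far faster, as
expected for hub-dominated topologies. The corresponding acceptance test
asserts the strict ordering at every $f \ge 0.2$ and therefore documents
this regime honestly rather than passing it.

## Threshold selection

To choose FC binarization thresholds, simulated and reference FC are
binarized at 100 thresholds spanning $[0, 1]$; with the reference edges as
ground truth, accuracy and precision are computed over unordered
off-diagonal pairs (thresholds with no positive predictions are excluded
from the fit). A least-squares cubic is fitted to precision versus
threshold; the knee (maximal curvature $|y''|/(1+y'^2)^{3/2}$ of the fit)
gives a restrictive threshold and the crossing of accuracy with the fitted
precision (linear interpolation, ties toward the smaller threshold) a
liberal one. In the reference analysis these landed at 0.27 and 0.08; the
lesion-suite defaults use the liberal value.

## Problem sizes and determinism

The shipped tests run everything at desk scale: 4–24-node systems for unit
checks, a 16-node / 1190-sample closed loop for parameter recovery (exact
argmin recovery with $\beta = 0$ on a 5×5 grid; within one grid step in
≥8/10 seeds at $\beta = 0.02$ with a 3-subject averaged reference), and a
68-node preferential-attachment connectome with 50 random-failure
repetitions for the robustness experiment. Grid axes in the reference
analysis were far larger (71 × 15 × 5 × 11 cells); the implementation is the
same, only the axes differ. Every stochastic stage draws its seed
deterministically from a master seed via a counter-based derivation
(`derive_seed`), and the whole pipeline — generator, fit, lesion suite,
hazard map, robustness curves — is bitwise reproducible under a fixed master
seed.

## Known limitations

* No hemodynamic (Balloon–Windkessel) forward model: $\mathrm{Re}\,z$ is the
  signal. No coupling delays.
* The limit cycle has radius $\sqrt a$ (as the radial equation dictates);
  descriptions of the cycle as having "radius $a$" are reconciled in favour
  of the equations.
* One common bifurcation parameter is fitted for all regions — deliberate,
  to keep the lesion protocol interpretable — so region-specific spectral
  power profiles are out of reach.
* FC-level fragmentation under lesioning depends on the entrainment effect
  described above; conclusions about hub criticality at small lesion
  fractions should use the restrictive threshold and larger $f$.
* Efficiency features are computed on binarized FC (weighted variants are
  out of scope); whether a weighted or binary reading is preferable for
  local efficiency is genuinely open, and binary is the default.
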