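---
title: "Equivalent-source interpolation of bad EEG channels: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent-source interpolation of bad EEG channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resit)
```

## The recording model

Scalp EEG referenced to an ideal neutral point at infinity is modeled as
the forward projection of a dense layer of equivalent current dipoles
through a spherical volume conductor:

$$V_\infty = L\,S,$$

with $L$ the $N \times M$ lead field of the montage and $S$ the $M
\times T$ equivalent-source amplitudes. Two facts make this model useful
for channel repair. First, any reference montage is a known linear
transform of $V_\infty$: subtracting a scalp electrode's row gives a
point-referenced recording, subtracting the channel mean gives the
average reference, and both transforms apply equally to the lead field.
Second, the equivalent-source layer is dense enough that the field of
any configuration of brain sources can be represented on it, so a
recording with $k$ bad channels still constrains $S$ through its
remaining $N-k$ rows.

RESIT exploits both: restrict $L$ to the good channels, express it in
the recording's own reference, estimate $\hat S = \tilde
L^{+}_\mathrm{ref}\, \tilde V_\mathrm{ref}$ with the Moore–Penrose
pseudoinverse, and project forward through the full, infinity-referenced
$L$. The result reconstructs every channel (the bad ones included) and
simultaneously standardizes the reference to infinity; with $k = 0$ it
is exactly the REST reference transform. The two baselines ignore the
physics: neighbor interpolation (NI) replaces a bad channel by the
unweighted mean of its $m$ nearest good channels on the unit sphere, and
spherical-spline interpolation (SSI) fits a smooth function of the
electrode positions built from the Legendre kernel
$g(x) = \frac{1}{4\pi}\sum_{n\ge 1} \frac{2n+1}{n^m (n+1)^m} P_n(x)$
with a zero-sum constraint on the spline coefficients.

## The volume conductor and its forward solution

The head is three concentric spheres — brain, skull, scalp — with radii
0.87, 0.92 and 1.0 (normalized by the head radius) and relative
conductivities 1.0, 0.0125 and 1.0, the classical configuration for a
normalized human head. For a dipole with moment $p$ at position $r_0$
($b = |r_0|$) and an electrode at unit vector $e$ the surface potential
is the Legendre series

$$V = \frac{1}{4\pi\sigma_\mathrm{brain}} \sum_{n\ge 1} b^{\,n-1} g_n
\left[\, n\,(p \cdot \hat r_0)\, P_n(\cos\gamma) + \big(p \cdot (e -
\cos\gamma\, \hat r_0)\big)\, P_n'(\cos\gamma) \right],$$

where $\cos\gamma = \hat r_0 \cdot e$ and $g_n$ is a per-degree transfer
coefficient of the shell geometry. Rather than transcribing a closed
form, `resit` derives $g_n$ from the boundary conditions directly: in
each shell the degree-$n$ radial solution is $A r^n + B r^{-(n+1)}$,
with a unit source term in the brain compartment, continuity of
potential and radial current at the two interfaces, and zero radial
current at the scalp. The unknowns are eliminated from the outside in,
which stays well conditioned at high degree (a naive 5x5 solve becomes
numerically singular near degree 150 because $r^{n}$ and $r^{-(n+1)}$
span 25 orders of magnitude). In the homogeneous limit $g_n =
(2n+1)/n$ and the series sums analytically to the classical
single-sphere closed form; the test suite checks this limit to a
relative error below $10^{-6}$, and the implementation was additionally
cross-validated against an independent multilayer-sphere EEG forward
solver to a relative difference of a few times $10^{-3}$ (that solver's
own series acceleration accounts for the residual).

**Series truncation.** The series is truncated when the largest term
falls below `seriesRtol` ($10^{-12}$) of the largest accumulated entry
for three consecutive degrees — the three-in-a-row guard exists because
$P_n(\cos\gamma)$ has zeros that can make a single term small without
convergence. The default ceiling is `nTermsMax = 300`: cap sources sit
at eccentricity 0.869, and their series reaches $10^{-12}$ at the
nearest electrodes only around degree 280 (the tail decays like
$b^{\,n} n^2$). A ceiling of 200, sometimes seen for deeper sources,
would truncate the default grid at a relative accuracy of only about
$10^{-10}$ and trigger the non-convergence warning on every run.

## The equivalent-source layer

The default grid closes a surface around the brain sources with 3000
dipoles: 2600 radially oriented on the spherical cap of radius 0.869 and
400 oriented along $+z$ on the transverse plane at $z = -0.076$.
Counts and geometry are fixed; the *placement* on those surfaces is this
package's choice, since only the counts are standard: a Fibonacci
(golden-angle) lattice, equal-area in $z$, on the cap, and a sunflower
layout on the disk. Both are deterministic, near-equal-area, exact in
the requested counts, and contain no random numbers — the physics core
is fully reproducible without a seed. The test suite verifies the
uniformity (coefficient of variation of nearest-neighbor geodesic
spacing below 0.25 at $n = 500$; the lattice achieves about 0.01).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `rBrain`, `rSkull`, `rScalp` | 0.87, 0.92, 1.0 | shell radii, head-radius units |
| `sigmaBrain`, `sigmaSkull`, `sigmaScalp` | 1, 0.0125, 1 | relative conductivities |
| `nTermsMax`, `seriesRtol` | 300, 1e-12 | forward-series truncation |
| `nCap`, `nPlane` | 2600, 400 | equivalent-dipole counts |
| `capRadius`, `planeZ` | 0.869, -0.076 | source-layer geometry |
| `pinvRtol` | 1e-8 | relative singular-value cutoff of the pseudoinverse |
| `orderM`, `nLegendre` | 4, 50 | spline stiffness and kernel series length |
| `mNeighbors` | 4 | good channels averaged by NI |

The pseudoinverse cutoff is relative to the largest singular value; the
effective rank actually used is stored in the output metadata
(`resitRank`) so ill-conditioned solves are diagnosable. For the
62-channel montage the referenced good-channel lead field has a benign
spectrum (about 1.4 decades from first to last nonzero singular value
plus one exact null direction from average-referencing), so the default
cutoff keeps everything but the null space. The spline defaults are the
de facto standard order-4, 50-term configuration; the $1/4\pi$ kernel
prefactor cancels in the constrained solve. NI uses 4 neighbors, the
count typically assessed in practice (field folklore says 4–6);
neighbors are recomputed among good channels only, and angular-distance
ties are broken by channel-label lexicographic order so the operator is
deterministic.

## Numerical choices

* **SSI solve.** The zero-sum constraint is imposed through a bordered
  (augmented) system $\bigl[\begin{smallmatrix} G & \mathbf 1 \\
  \mathbf 1^\top & 0\end{smallmatrix}\bigr]$ factorized once for all $T$
  time points; the constraint then holds to solver precision rather
  than approximately.
* **Reference transforms.** Average-referencing data or lead fields is
  an exact projection (applying it twice equals applying it once);
  point-referencing zeroes the reference row exactly. The declared
  average reference is checked at construction (channel means below
  $10^{-6}$ of the data RMS) but deliberately *not* re-checked on
  interpolator outputs: an NI or SSI output carries its input's
  convention while the replaced channels are approximations, so exact
  centering cannot be a class invariant.
* **Degenerate inputs.** Dipoles at or outside the brain radius,
  coincident good electrodes (spline angles undefined), all-bad or
  $k = N - 1$ masks, zero-source zero-noise simulations and
  out-of-range bad fractions are rejected with specific errors; a
  zero-variance truth channel has no defined correlation and is
  excluded from the mean with a warning rather than poisoning it.
* **Bad-set sizes.** $k = \operatorname{round}(fN)$, clamped below to
  1; fractions leaving fewer than 3 good channels are rejected. At
  $N = 62$, 10% gives $k = 6$.
* **Relative absolute error.** Defined as summed absolute error over
  summed absolute truth on the bad channels — scale-free, so jointly
  scaling truth and estimate leaves it (and the correlation) unchanged
  while the mean absolute error scales. Correlations are averaged
  per-channel without a Fisher transform, matching how mean Pearson
  correlations are conventionally reported for this protocol.
* **Adjacent bad sets.** Grown from a uniformly drawn seed channel by
  repeatedly adding the non-member nearest (single-linkage, angular
  distance) to the current set; this yields compact contiguous patches,
  and the suite verifies connectivity in the montage's 4-NN graph by
  brute-force traversal.

## What the simulator emulates — and what it does not

`simulateEEG()` generates data through the same physics family as the
inverse model (random dipoles in a three-sphere head) but with sources
that are *not* grid nodes by default, so benchmark recoveries are not
inverse crimes; an explicit `inverseCrime = TRUE` flag places sources
exactly on grid nodes for the exact-recovery tests. Three signal models
cover the protocol's two data types: 1–30 Hz band-limited noise
(resting-state-like), 10 Hz oscillations with random phase, and epoched
ERP-like waveforms (a negative deflection at 175 ms and a dominant
positive one at 350 ms over a −200…800 ms window at 500 Hz — minimal
P300-like morphology). Clean sensor signals are scaled to 10 µV RMS and
white sensor noise is added per channel; `snr` is the clean-RMS over
noise-SD ratio. Defaults (10 sources, eccentricity ≤ 0.8, SNR 5) are
desk-scale choices of plausible difficulty, not fits to any recording:
real EEG adds correlated physiological noise, artifacts, non-spherical
anatomy and electrode-position error, none of which are modeled. Passing
benchmarks on this simulator therefore demonstrates correctness of the
algorithms and the expected *ordering* of methods under dipolar data,
not error magnitudes to be expected on clinical recordings.

The montage fixtures are built geometrically from the 10-20/10-10
construction (circumferential ring at polar 72°, 18° midline steps,
equal-arc row subdivision) rather than copied from a digitized cap; the
62-channel layout includes the lower-temporal pair FT9/FT10 and omits
FCz, the customary recording-reference site.

## Known limitations

* **Inverse-crime recovery is not exact for $k > 0$.** With grid-node
  sources and no noise, the good channels are reproduced essentially
  exactly (the data lie in the column space of the referenced lead
  field), but extrapolation to held-out channels is not: the true
  sparse source vector has a component in the null space of the
  good-channel lead field that the bad-channel rows can see. At 10%
  scattered bad channels the worst-channel correlation is typically
  0.95–0.99 and can drop further when a superficial cap source sits
  directly under a boundary electrode; only the $k = 0$ (REST) case is
  exact. Truncating the pseudoinverse harder does not repair this.
* **Per-seed superiority saturates at the noise floor.** On synthetic
  dipolar data RESIT has the lowest mean absolute error in every
  benchmark cell, and beats SSI in essentially every seed. Against NI
  at *small scattered* fractions the per-seed margin is thin: the
  truth's own sensor noise bounds every method from below, and NI's
  4-channel averaging halves its prediction noise, so at 10% scattered
  bad channels and SNR 5 NI wins a sizeable minority of seeds even
  though RESIT is better on average. From 25% upward RESIT dominates
  both baselines almost seed-for-seed, in both scattered and adjacent
  cases.
* The spherical head model has no individual anatomy; realistic BEM/FEM
  conductors and MEG are out of scope.

## Problem sizes used by the shipped tests

The suite exercises the full default configuration (62 channels x 3000
sources; the lead field is computed once and memoized). The method
benchmark uses 62 channels x 500 samples (1 s at 500 Hz), 10 sources at
SNR 5, 20 seeds, scattered fractions {0.1, 0.25, 0.5} and adjacent
fractions {0.02, 0.1, 0.25, 0.5, 0.85}; the REST-equivalence check uses
62 x 5000 samples. These sizes were chosen as the smallest at which the
protocol's trends are stable across seeds.
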