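---
title: "Kurtosis fractional anisotropy and its two-shell proxy: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kurtosis fractional anisotropy and its two-shell proxy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DKImetrics)
```

## The model

Diffusion kurtosis imaging retains the $b^2$ term of the cumulant
expansion of the diffusion-weighted log-signal,

$$\ln S(b,\hat n) = \ln S_0 - b\, n_i n_j D_{ij}
  + \tfrac{b^2}{6}\, \mathrm{MD}^2\, n_i n_j n_k n_l W_{ijkl},$$

parameterized by the symmetric rank-2 diffusion tensor $D$ (units
$\mu m^2/ms$; 6 unique components) and the fully symmetric rank-4
kurtosis tensor $W$ (dimensionless; 15 unique components). The package
stores both tensors compactly and performs every contraction and norm
with explicit multiplicity weights (1 for $xxxx$-type, 4 for
$xxxy$-type, 6 for $xxyy$-type, 12 for $xxyz$-type components), so all
scalar outputs equal what a brute-force sum over the 81 Cartesian
components would give; the test suite verifies this equivalence against
independent index-loop oracles at $10^{-10}$.

The scalar metrics are MD and FA from the eigenvalues of $D$; the
spherical mean $\bar W$ of the quartic contraction of $W$; the mean
kurtosis MK as the spherical average of the apparent kurtosis
$K(\hat n) = (\mathrm{MD}^2/D(\hat n)^2)\, n_i n_j n_k n_l W_{ijkl}$;
and the kurtosis fractional anisotropy

$$\mathrm{KFA} = \frac{\lVert W - \bar W\, I^{(4)}\rVert_F}
                      {\lVert W\rVert_F} \in [0, 1],$$

with $I^{(4)}_{ijkl} = (\delta_{ij}\delta_{kl} + \delta_{ik}\delta_{jl}
+ \delta_{il}\delta_{jk})/3$. KFA is invariant to rotations and to
rescaling of $W$, and — unlike FA — does not vanish for orthogonal
fiber crossings, because the quartic form retains angular structure
that the quadratic form cannot.

Conventions worth stating explicitly:

* FA uses the population-normalized std/rms reading (divide by $n = 3$,
  no small-sample correction), with the standard $\sqrt{3/2}$ factor.
* KFA is defined as 0 when $\lVert W\rVert_F = 0$, so vanishing-kurtosis
  voxels do not poison maps with NaNs.
* Eigenvalues are never clipped before FA; fits with $\lambda_3 < 0$ are
  flagged in a QC channel rather than rejected.

## Estimation

`fitDki()` normalizes signals to the mean $b = 0$ image and minimizes
squared residuals of the normalized signal with Levenberg–Marquardt
(analytic Jacobian; relative step/function tolerances $10^{-10}$, at
most 500 iterations), initialized from the exact linear log-domain
solution. The parameterization is $1 + 6 + 15 = 22$ unknowns, with the
quartic block fitted as $V = \mathrm{MD}^2 W$ and $W$ recovered by
dividing by $\mathrm{MD}^2$ from the same fit; this mirrors the
expansion's structure and keeps the linear initializer exact. A
weighted linear log-domain fit (`method = "wls"`, weights equal to the
squared predicted signal from an OLS first pass) is provided as a fast
fallback for large sweeps. Designs are rejected ahead of fitting when
they have fewer than 22 measurements, fewer than three distinct
b-values including $b = 0$, or a rank-deficient design matrix.
No positivity or directional-kurtosis constraints are imposed; QC flags
mark $\lambda_3 < 0$ and $K(\hat n) < -3/7$.

The two-shell inversion `twoShellDK()` solves the expansion exactly on
one direction from $(S_0, S_1, S_2)$ at $0 < b_1 < b_2$. Equal shells
are a hard error (the inversion is singular); non-positive signals or
non-positive apparent diffusivity mask the direction rather than void
the voxel, which keeps low-SNR proxy maps usable. The proxy itself is
$\mathrm{std}(K)/\mathrm{rms}(K)$ over valid directions with population
normalization; negative $K$ values are retained (discarding them would
bias the proxy upward). By construction the proxy never exceeds 1. No
calibration mapping from proxy to KFA is applied: none is defined, and
the two ranges are not expected to coincide.

## What the simulator emulates

The synthetic ground truth is built from Gaussian mixtures because they
have *analytically exact* DKI cumulants: for compartments with tensors
$D^{(c)}$ and fractions $f_c$,

$$D = \textstyle\sum_c f_c D^{(c)}, \qquad
W_{ijkl} = \frac{3}{\mathrm{MD}^2}\,\mathrm{Sym}\Big[
\textstyle\sum_c f_c D^{(c)}_{ij} D^{(c)}_{kl} - D_{ij} D_{kl}\Big].$$

Exactness is what makes oracle testing possible — every simulated voxel
carries its true $(D, W)$ — and matters more for this artifact than
biophysical fidelity. The per-direction identity
$K(\hat n) = 3(\sum_c f_c D_c(\hat n)^2 - D(\hat n)^2)/D(\hat n)^2$ is
verified in the tests.

The brain-like voxel population (`syntheticPopulation()`) stands in for
tensors fitted to an in-vivo, CSF-suppressed human acquisition, since no
such data are distributed with the package. Its design went through
three deliberate choices:

* **Fibers are intra/extra-axonal pairs.** A "fiber" is two coaxial
  compartments (axial diffusivity ~1.9–2.3, radial ~0.01–0.04 vs
  ~0.65–0.85 $\mu m^2/ms$). A single Gaussian compartment has zero
  kurtosis; real white matter has large, anisotropic kurtosis from
  exactly this kind of radial heterogeneity. With single-Gaussian
  fibers, crossing two bundles *creates* kurtosis out of nothing and
  KFA rises with crossing — opposite to tissue, where the single-fiber
  $W$ is already large and crossings redistribute it.
* **A fast isotropic pool is the KFA lever.** Each voxel carries a slow
  (~0.35–0.75) and a fast (~1.2–2.2 $\mu m^2/ms$) isotropic pool; the
  fast-pool fraction adds isotropic kurtosis and moves KFA smoothly
  downwards from the single-fiber ceiling. The fast pool is capped near
  2.2 $\mu m^2/ms$ because the emulated acquisition suppresses CSF — a
  free-water pool at 3 $\mu m^2/ms$ would push second-shell signals at
  $b = 5\ ms/\mu m^2$ under the Rician noise floor, a regime the target
  system does not occupy.
* **Profiles are calibrated to the FA segmentation bands.** The
  `wm_like` profile places ~99 % of voxels in the 0.6 < FA < 1 band,
  `gm_like` ~84 % in 0.1 < FA < 0.3; the mixed population spans KFA
  roughly 0.1–0.9 with standard deviation ~0.22. These are generator
  contracts, fixed before any correlation experiment and tested as
  such.

What the generator does **not** emulate: exchange between compartments,
restricted (non-Gaussian) compartments, axonal dispersion continua,
imaging artifacts, or anything driven by gradient strength and diffusion
timing beyond the b-value. Passing tests therefore demonstrate the
estimators' and the proxy's behavior *under the DKI signal model with
Rician noise*, not their robustness to real-scanner confounds.

The 3×3 orthogonal-bundle phantom (`orthogonalPhantom()`) emulates a
plant-stem phantom: nine single-fiber bundles, three per axis, in free
water. Bundle voxels use a plant-like kernel ($d_\parallel = 1.2$,
$d_\perp = 0.25$, 30 % isotropic at 0.6 $\mu m^2/ms$; single-fiber FA
about 0.59) and the default acquisition is $b = 0, 0.5, 1.0, 1.8, 2.5,
3.5\ ms/\mu m^2$ along 15 directions. With brain-level diffusivities the
DKI truncation bias of fitting orientation-averaged multi-Gaussian
signals at $b \le 3.5$ pushes the averaged-fit MD off by almost 4 %;
with the plant-like kernel the deviation stays under 2 %, consistent
with MD's expected constancy under signal averaging (a linear
operation). Mixture-sweep and phantom signals are generated from the
exact multi-Gaussian compartment signal, not the DKI truncation, so the
fits face realistic model error.

The fiber-mixing experiment (`mixtureSweep()`) mixes three orthogonal
single-fiber signal sets as $(1-2\alpha)S_x + \alpha S_y + \alpha S_z$
over $\alpha \in [0, 1/3]$ and tabulates fitted metrics against the
volume-fraction index VI (the FA analogue on the fraction tensor). The
default grid runs 0 to 0.33 in steps of 0.03 *plus* the exact equal
mixture $\alpha = 1/3$, so the VI = 0 endpoint is evaluated exactly.
Its default kernel is the WM-like reference voxel
(`defaultFiberVoxel()`: $d_\parallel = 2.0$, $d_\perp = 0.4$ plus 30 %
isotropic at 1.0 $\mu m^2/ms$), which yields a single-fiber FA of about
0.59 — high enough that the FA collapse at VI = 0 (fitted FA < 1 % of
its maximum) is unambiguous.

## Monte-Carlo design

Rician noise replaces each signal by
$\sqrt{(S+\sigma g_1)^2 + (\sigma g_2)^2}$ with
$\sigma = S_0/\mathrm{SNR}$. One experiment seed drives a private RNG
stream; the realization index advances a counter, so any single
realization is reproducible in isolation and repeated runs are
bit-identical. Infinite SNR is a genuine no-noise code path, not a large
number.

The sweep procedures (`directionSnrSweep()`, `bvalueGridSearch()`)
simulate two-shell signals *through the DKI forward model* from each
voxel's exact tensors — matching how such evaluations are done when the
ground truth is itself a tensor fit — then add noise, build the proxy
map, and correlate against true KFA across voxels. Correlations are
averaged as the mean of per-realization Pearson $r$, never pooled
across realizations. Grid cells with $b_1 \ge b_2$ are masked
(the inversion is singular at $b_1 = b_2$), and cells where more than
half of the voxels fail are flagged.

Problem sizes used by the packaged experiments: the acceptance script
uses 1000 voxels and 100 noise realizations per condition; the test
suite uses 150–1000 voxels and 10–100 realizations depending on the
property under test. At these sizes cell means are stable to well under
0.01.

## Numerical choices

* **Frobenius norms** over $W$ are computed from the 15 unique
  components with multiplicity weights; this equals the 81-term sum to
  machine precision and keeps KFA basis-independent.
* **MK quadrature.** MK averages $K(\hat n)$ over a deterministic
  4096-point Fibonacci sphere lattice. With anisotropic $D$ the
  integrand is a rational function of $\hat n$, and ~256-point uniform
  sets leave quadrature errors of a few $10^{-3}$ — larger than the
  $10^{-3}$ rotation-invariance tolerance the package promises — while
  the 4096-point lattice keeps them near $10^{-4}$. The packaged
  electrostatic-repulsion sets (3–256 directions, generated with a
  seeded antipodally-symmetric Coulomb optimizer) are used for
  *acquisition* simulation, where small counts are the point.
* **Degenerate inputs.** $D(\hat n) \le 10^{-12}$ is a hard error in
  `apparentDK()` (an explicit request for an undefined quantity) but a
  masked direction in the two-shell pipeline (routine at low SNR).
  `kfaProxy()` requires at least three valid directions and returns 0
  for all-equal or all-zero $K$.
* **Unit conventions.** Internally $b$ is in $ms/\mu m^2$ and $D$ in
  $\mu m^2/ms$ everywhere; b-value files in $s/mm^2$ are detected
  (max > 100) and converted only at the I/O boundary. Gradient
  directions follow the FSL bvec convention.

## Known limitations

* The proxy confounds diffusion and kurtosis anisotropy: the
  $\mathrm{MD}^2/D(\hat n)^2$ factor makes $K(\hat n)$ vary with
  direction even for isotropic $W$. Across brain-like populations this
  largely co-varies with true KFA; in populations where KFA varies
  independently of fiber architecture the correlation degrades. This is
  a property of the statistic, not of the implementation.
* Estimation at $b_2 > 3\ ms/\mu m^2$ inside the sweeps inherits the
  DKI truncation's unphysical high-b behavior for high-kurtosis voxels;
  real tissue would add higher-order terms there.
* The nonlinear fit is unweighted on normalized signals and performs no
  outlier rejection; heteroscedasticity at very low SNR is only
  partially addressed by the WLS fallback.
* `fa_segmentation` bands (0.1–0.3 and 0.6–1) are conventions for
  tissue-class summaries, not a tissue classifier.
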