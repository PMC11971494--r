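---
title: "Basis-function compression for MRI field-probe monitoring"
author: "fieldcompress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Basis-function compression for MRI field-probe monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldcompress)
```

## The problem

NMR field probes record the local magnetic-field phase during an MRI
acquisition. With probe positions $r_p$ and a real solid-harmonic basis
$h_i(r)$ (degree-$l$ polynomial solutions of Laplace's equation, scaling as
$r^l$), the accrued probe phase is separable in space and time,

$$\phi = P\,k, \qquad P_{pi} = h_i(r_p),$$

where $\phi$ is the $N_p \times N_t$ phase matrix, $P$ the "probing matrix"
and $k$ the $N_b \times N_t$ matrix of *k-coefficients* (row $i$ in
rad/m$^{l_i}$). A 16-probe array determines at most 16 basis functions —
a third-order expansion. On head-only gradient systems, and whenever probes
sit far from isocenter, eddy-current fields carry significant content above
third order; fitting such data with a low-order basis aliases ("projects")
the missing orders into the low orders that matter most for image
reconstruction.

The package implements a data-driven remedy: learn, from a multi-position
*calibration* scan with many effective probe positions, a low-rank basis for
the high-order dynamics, and fit routine 16-probe data in that compressed
basis.

## The compression model

Let $\Gamma$ be the diagonal order weighting $\Gamma_{ii} = 0.1^{\,l_i}$,
which expresses row $l$ in rad/dm$^l$ and thereby equalises the scale of the
orders over a 10-cm-radius volume. Splitting off the zeroth- and first-order
rows (which every gradient system produces by design and which are never
compressed), the calibration coefficients' high-order block is decomposed by
an economy SVD,

$$\Gamma^{high}\,k^{high}_{calib} = U \Sigma V^T,$$

and the first $L$ left-singular vectors form $C^{high}$. The full
compression matrix is block diagonal with a $4\times4$ identity,

$$C = \begin{pmatrix} I & 0 \\ 0 & C^{high}\end{pmatrix},
\qquad
\Gamma = \begin{pmatrix} I & 0 \\ 0 & \Gamma^{high}\end{pmatrix},$$

giving the compression and (approximate) decompression maps
$\hat k = C^T \Gamma k$ and $k \approx \Gamma^{-1} C \hat k$, the compressed
probing matrix $\hat P = P\,\Gamma^{-1} C$, and the compressed fit
$\hat k = \hat P^+ \phi$. With per-probe weights $W$, $P$ is replaced by
$WP$ throughout, i.e. $k = (P^T W^2 P)^{-1} P^T W^2 \phi$. Because
$C^T C = I$, the round trip $\Gamma^{-1} C C^T \Gamma$ is the
$\Gamma$-metric orthogonal projector onto the retained subspace — both
identities are enforced by tests at $10^{-10}$/$10^{-8}$.

A deterministic sign convention (largest-magnitude entry of each singular
vector made positive) keeps models reproducible across runs and LAPACK
builds. When $L$ exceeds the numerical rank of the weighted high-order
block, the model warns and clamps; calibrations shorter than $N_b - 4$
samples are allowed but flagged as rank-limited.

## Choosing the truncation

The number of retained singular vectors $L$ trades off two error sources:
too few discards basis functions the acquisition needs; too many brings the
total parameter count close to the probe count and degrades the conditioning
of $\hat P$. The RMSE-versus-$L$ curve is therefore U-shaped, and its
minimum moves right as probes are added. `sweepSingularValues()` rebuilds
the model at each candidate $L$ and reports the curve and its argmin against
a supplied ground truth; `sweepProbeCount()` does the analogous experiment
over electrostatically spread probe subsets. The package deliberately keeps
truncation selection explicit (user-supplied $L$ or a ground-truth sweep)
rather than automatic.

## Error metric

`kRMSE()` evaluates, per volume (segment), the order-weighted error

$$\mathrm{RMSE} = \sqrt{\sum_{i=1}^{9}\frac{1}{N_t}\sum_{j=1}^{N_t}
\left(\Gamma_{ii}\,(k_{ij} - k^{GT}_{ij})\right)^2},$$

over the first nine basis functions (orders 0–2, where fitting errors harm
image reconstruction most; the weighting starts at order 0 here), then
reports the mean and SD across volumes. The closed form is tested: an
offset $\delta$ on a single order-$l$ row gives exactly $0.1^l\,|\delta|$.

## Concomitant fields

Concomitant (Maxwell) terms accompany any linear gradient and scale as
$1/B_0$. The package uses the standard lowest-order expression for a
symmetric gradient system,

$$B_c = \frac{1}{2B_0}\Big(G_x^2 z^2 + G_y^2 z^2 +
G_z^2\,\tfrac{x^2+y^2}{4} - G_x G_z\,xz - G_y G_z\,yz\Big),$$

applied self-consistently: the simulator can add the accumulated
concomitant phase to probe data, and `concomitantRefit()` removes it by
iterating (fit → derive gradients from the first-order rows → subtract
$\gamma\int B_c\,dt$ → refit), with the integral restarting at each volume.
Two iterations are the default, with an early exit when the relative
coefficient change falls below $10^{-6}$; in the synthetic closed loop the
first iteration already removes essentially all of the bias because the
linear rows are dominated by the true gradient phase.

## What the synthetic-data generator emulates

No probe data accompany the method, so the generator produces the study
conditions in code:

* **Waveforms.** Slew-limited Archimedean spiral and EPI readouts, PGSE and
  OGSE diffusion encodings scaled numerically to a requested b-value
  (defaults b = 1000 s/mm² for PGSE, b = 400 s/mm² at 40 Hz for OGSE), and
  chirped calibration pulses — all under 80 mT/m and 400 T/m/s limits, the
  regime of a high-performance head gradient. Spin-echo waveforms store the
  physically played-out (same-sign) lobes, which is what drives eddy
  currents, while `bValue()` reverses the effective sign after the recorded
  refocusing time.
* **Eddy currents.** Linear time-invariant per-(basis, axis) responses: each
  mode convolves the negative slew of one gradient axis with
  $A e^{-t/\tau}$ and integrates to phase-coefficient units. The discrete
  convolution treats gradient increments as an impulse train and integrates
  the exponential exactly between samples, so a rectangular gradient step
  reproduces $\gamma A \Delta g\,\tau(1-e^{-t/\tau})$ to machine precision.
  The default scene spreads six spatial modes (plus a rotationally covariant
  $l=2, m=\pm1$ pair) over orders 2–5 with $\tau$ from 0.1 to 100 ms —
  few dominant spatial modes, which is precisely what makes the dynamics
  compressible. Mode amplitudes are scaled deterministically so high-order
  phase is about 7 % of the linear phase at 14 cm from isocenter, the
  regime of probes mounted well outside the specified imaging volume.
* **Probe geometry.** A 16-probe helmet-style base array (radii 0.121–0.149
  m, mean 0.135 m) and a calibration array built from 3 z-positions (5 cm
  apart) × 3 equiangular z-rotations, filtered to 16 cm Euclidean and 14 cm
  per-axis distance — 106 retained positions out of 144 candidates with the
  default layout.
* **Scans.** A diffusion "scan" is a list of scenes sharing the readout
  while the diffusion direction rotates through an
  electrostatic-repulsion-uniform set (defaults: 30 directions plus 2
  b = 0 volumes); Gaussian phase noise of 0.05 rad SD is added per sample,
  under a mandatory seed.

What the generator does *not* model: physiological field fluctuations,
probe signal decay and damping, gradient nonlinearity, synchronisation
delay, or mechanically induced vibration modes. Passing tests therefore
demonstrate the estimator's algebra and its behaviour under the LTI
eddy-current model — not performance on any particular scanner.

## Numerical choices

* Fits go through QR after an SVD condition check; condition numbers above
  $10^{10}$ raise an ill-posed-fit error that names the deficient columns.
* Harmonic convention: real regular solid harmonics, Racah-style
  normalisation, ordered by ascending $l$ and $m = -l..l$ (so row 1 is the
  constant and rows 2–4 are $y, z, x$); `axisRows()` maps gradient axes to
  rows. Any self-consistent real convention would do — the same evaluation
  is used for simulation, calibration and fitting.
* The harmonicity test uses a central finite-difference Laplacian with a
  1 mm step, comparing the residual against the natural curvature scale
  $\max|f|/h^2$ at $10^{-6}$.
* OGSE lobes are separated by an integer number of oscillation periods so
  the two lobes stay spectrally coherent and the waveform's periodogram
  peaks at the nominal frequency.
* Direction sets descend the antipodally symmetric $1/d$ repulsion energy
  with an adaptive step and a 1000-iteration cap.

## Desk-scale study sizes

The simulation studies in the test suite and the acceptance script run the
full pipeline at reduced size: a 2.6 mm spiral readout at a 2 × 10⁻⁵ s
raster, 6 diffusion directions + 1 b = 0 volume for the recovery study and
3 + 1 for the sweep and transfer studies, with medians over 25–50 seeds.
Six directions is the point beyond which calibration quality was found to
saturate, so the reduced protocols preserve the phenomenology (U-shaped
truncation trade-off, probe-count behaviour, narrowband-calibration
transfer penalty) while keeping each study in the minutes range. The
generator's own defaults remain the full-size protocol (1.3 mm readout,
10⁻⁵ s raster, 30 directions + 2 b = 0).

## Known limitations

* The eddy model is single-exponential per mode; real systems superpose
  many time constants per spatial mode (the mode table accepts multiple
  rows per basis function for exactly this reason).
* Probe weighting $W$ enters all fitting operations but not the SVD
  calibration step; the calibration is assumed to come from a
  well-conditioned many-probe fit.
* The compressed basis is global per calibration; per-scan retrospective
  sub-selection of basis functions and singular-value-weighted fitting are
  out of scope.
* Absolute RMSE values from the synthetic scenes are not comparable to any
  particular scanner; only relative orderings between fitting strategies
  are meaningful, and those are what the tests assert.
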