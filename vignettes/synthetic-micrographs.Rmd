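---
title: "Simulating mother-machine micrographs with exact ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating mother-machine micrographs with exact ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 3)
library(trenchsim)
library(ggplot2)
```

## Why synthesise micrographs?

Segmentation networks for bacterial time-lapse imaging need training data
with accurate per-pixel ground truth, but bacteria are of the same size as
the microscope's point spread function (PSF): the image of a 1 um cell is
corrupted enough that neither a human annotator nor a classical pipeline
can label the *true* pixels. `trenchsim` sidesteps annotation entirely: it
simulates cells growing in a mother-machine trench, renders the physically
meaningful intermediate — an optical-path-length (OPL) image — and only
then corrupts it with a parametric microscope and camera model. The masks
are taken from the geometry *before* the optics, so they are exact by
construction, and any change in optics or camera produces new images with
bit-identical ground truth.

The pipeline has five stages, each an exported module surface:

1. **Growth simulation** — an agent-based model of rod-shaped cells in a
   rigid dead-end trench.
2. **Rendering** — analytic chord-length projection of each
   spherocylindrical cell into a super-sampled OPL image plus a label
   image.
3. **Optics** — Airy / obscured-Airy PSF generation, apodisation, defocus,
   convolution at super-resolution, block-average down to camera pixels.
4. **Camera** — Poisson shot noise, Gaussian read noise, gain, offset,
   quantisation; plus histogram / Fourier-spectrum matching against a real
   reference image.
5. **Export & evaluation** — training-sample dialects (binary masks with
   U-net border weightmaps, or labelled instances in multi-trench tiles)
   and label-free quality statistics (sawtooth identification error,
   Jaccard-optimal thresholding, seeded watershed, quadratic-residual
   precision).

## The growth model

Cells are spherocylinders of length $l$ and diameter $2r$ confined to the
trench axis (origin at the closed end, coordinates in um, time in
minutes). Each step applies, in order: exponential elongation
$l' = l e^{\lambda\,\Delta t}$; division when the cell's size-regulation
rule fires; Bernoulli lysis with probability `p_lyse`; and collision
resolution. The three classic size-regulation modes are available:

* **adder** — divide after adding a per-cell threshold $\Delta$ since
  birth;
* **sizer** — divide on reaching a per-cell length threshold $L_d$;
* **timer** — divide at a per-cell age threshold $\tau$.

Thresholds are drawn once per cell at birth from normal distributions
truncated to keep $l \ge 2r$ and $\tau > 0$. The configuration specifies
the mean and SD of the *division length*; in adder mode the added-length
threshold is drawn with mean `division_mean / 2` so the steady-state
division size agrees with the sizer parameterisation — the model input is
a division-size distribution either way, which is what a microscopist
measures. The growth law itself is a modelling choice: exponential
single-cell elongation is the standard for steadily growing bacteria and
produces the expected sawtooth in the mother-cell trace.

Division splits the mother's footprint symmetrically (asymmetry
configurable) minus a septum gap (default 0.1 um). Daughters draw fresh
widths, thresholds and bend amplitudes; widths are constant over each
cell's lifetime.

**Collisions.** A mother-machine trench is quasi-1-D, so a full rigid-body
engine is unnecessary: the solver sorts cells along the axis and sweeps
once from the rigid closed wall outward, displacing each cell toward the
open end just enough to clear its inner neighbour. This is exact (residual
overlap 0), order-preserving, and deterministic; the contract still allows
a residual overlap up to 0.01 um and a convergence check guards the loop.
Cells whose centroid crosses the open end are removed and logged as washed
out. A length audit closes the books every run: founder length plus summed
growth increments equals in-trench length plus removed length plus one
septum gap per division, to floating-point precision.

```{r sim, fig.alt = "sawtooth mother trace"}
sim <- run_simulation(sim_config(n_timepoints = 150, seed = 1),
                      trench_geometry())
glance(sim)
autoplot(sim)
```

## Rendering: analytic OPL projection

A spherocylinder revolved about its major axis has, at perpendicular
distance $d$ from the medial axis, a chord of length $2\sqrt{r^2 - d^2}$
along the optical axis. The renderer evaluates this chord at every
(super-sampled) pixel centre instead of voxelising and projecting — the
same mathematical object, exact at much lower cost. Consequences that the
tests exploit:

* the patch integrates to the spherocylinder volume
  $V = \pi r^2 (l - \tfrac{2}{3} r)$ to better than 1%;
* the label footprint is exactly the analytic hull support (`chord > 0`),
  and because chords are evaluated at absolute pixel centres, footprints of
  touching cells are disjoint whenever the physics says the hulls are;
* bending is a single-arc bow of the medial axis whose arc length is
  renormalised to the straight length, so the integrated OPL (cell mass)
  is conserved to well within 2%.

The scene composes, in fixed order: media everywhere at intensity `I_m`,
the device (closed-end cap and side walls) at `I_t`, then each cell's
chord projection added at `I_c` per unit path length. These three
empirical intensities absorb the OPL-to-refractive-index scaling; physical
units are deliberately not reconstructed. For agar-pad style backgrounds a
2-D gradient (Perlin) noise field is provided; no installed R package
offers one, so it is implemented in-package (lattice gradients, quintic
smoothstep), centred to zero mean with an autocorrelation length that
grows with its `scale` parameter.

## Optics

Kernels are rendered at the OPL pitch (default camera pixel 65 nm in
object space, 3x super-sampled) on a grid of six first-zero radii:

* **fluorescence**: Airy intensity $[2 J_1(v)/v]^2$,
  $v = 2\pi \mathrm{NA}\rho/\lambda$; first zero at
  $0.61\lambda/\mathrm{NA}$;
* **phase contrast**: obscured-Airy intensity with annular amplitude
  $A(v) = \frac{2}{1-\varepsilon^2}\left[\frac{J_1(v)}{v} -
  \varepsilon^2 \frac{J_1(\varepsilon v)}{\varepsilon v}\right]$, where
  $\varepsilon$ is the ratio of the phase annulus radii (both radii are
  accepted in the configuration; only the ratio enters);
* **simplified 3-D fluorescence**: a stack of defocused 2-D planes
  (Gaussian broadening with SD $\theta |z|$) — a deliberate simplification
  of a full vectorial axial model, and flagged as such.

Apodisation multiplies by a centred Gaussian and renormalises; defocus
convolves with a Gaussian of width proportional to $|z|$ (the literature
gives no universal formula; monotone FWHM growth is the contract).
Convolution happens at super-resolution — sub-resolution ring structure of
the PSF must reach the image before resampling — with symmetric-reflection
boundaries, then a block average returns to camera pixels. The FFT path is
pinned to a direct sliding-window implementation to 1e-8 in the tests.

**The phase-contrast signature.** Phase contrast renders optically dense
objects dark with a bright halo. A non-negative intensity kernel convolved
with an additive OPL scene can only brighten cells, so the package
provides `phase_contrast_micrograph()`: a linearised positive
phase-contrast composition
$\mathrm{out} = (1+c)\,(K \ast \mathrm{opl}) - c\,\mathrm{opl}$,
which leaves flat regions untouched, darkens bodies wherever the blurred
OPL falls below $c/(1+c)$ of the local OPL, and spills the kernel's ring
energy outside the cell as the halo. The kernel's small uniform
`halo_offset` (renormalised) spreads weight into a wide pedestal and is
the knob for shade-off strength. The obscured-Airy kernel itself keeps
exactly the contract above.

```{r psf, fig.height = 4, fig.alt = "phase contrast PSF"}
autoplot(make_psf(psf_config(mode = "phase_contrast")))
```

## Camera and reference matching

Capture follows the standard photon-transfer model:
`DN = clip(round(gain * (Poisson(photon_scale * I) + N(0, sigma_r)) +
baseline))` at 8/12/16-bit depth. The tests recover the gain from the
variance-vs-mean slope of flat fields (within 10%) and the read noise from
dark frames (within 5%).

Matching a synthetic image to a real reference uses three advisory tools:
exact histogram matching (monotone rank mapping; idempotent), rotational
Fourier-spectrum matching (per-radial-bin amplitude substitution with
synthetic phases retained), and a per-region error report (relative mean
and variance errors over cell / device / media masks). Black-box
similarity optimisers are deliberately not provided — the error landscape
between a synthetic and a real micrograph is noisy and no closed-form
objective exists — so the report is advisory and manual intensity
corrections stay user-supplied.

## Training-set export

Imaging parameters (intensities, apodisation, defocus, halo offset,
photon scale, read noise, gain) are re-drawn for every exported sample,
by default uniformly within ±5% of their matched values. This emulates
mechanistic drift of the imaging system rather than transforming images
after the fact, so the object-image relation is never corrupted; the
manifest records every draw. Masks come from the physics alone: two
jitters of the same frame have pixel-identical ground truth.

Two mask dialects are produced. `binary_weightmap` separates touching
labels by minimal erosion at contact interfaces and adds a U-net style
border weightmap
$w = w_\mathrm{class} + w_0 \exp\left(-\frac{(d_1+d_2)^2}{2\sigma_w^2}\right)$
(defaults $w_0 = 10$, $\sigma_w = 5$ px; the border form is the standard
choice for "close to touching" emphasis, and class balancing is an
optional flag since its exact weighting is a trainer-side convention).
`instances_tiled` keeps touching labelled instances and can tile many
trenches side by side (40 is the conventional tile) with ids re-indexed to
stay unique. Frames can be sampled with probability inversely proportional
to their cell count, which makes every frame contribute the same expected
number of cells to the training set regardless of how crowded its regime
is — without it, small-cell conditions flood the set. Files are plain
16-bit TIFF (images, instance labels), 8-bit PNG (binary masks) and
max-normalised 32-bit float TIFF (weightmaps, with the scale recorded in
the manifest); integer artefacts round-trip exactly, float fields to
single precision.

## Label-free evaluation

Without real ground truth, quality is scored from structure the biology
guarantees:

* **Identification error.** The mother-cell length trace is a sawtooth;
  mis-segmentation shows up as a sharp drop-then-rise (or rise-then-drop)
  in the derivative that is not a division. A drop is division-compatible
  when $l_{t+1}/l_t \in [0.4, 0.6]$ (configurable); steps smaller than 10%
  are ordinary growth. The rate is flagged timepoints over total
  timepoints. The detector's two parameters were calibrated once on the
  simulator's own clean traces (zero false positives with ~5% growth per
  frame and ~0.49 division ratios) and are not claimed to match any other
  implementation.
* **Jaccard-optimal thresholding.** Network probability maps are scanned
  over a 0.50–0.995 grid in 0.005 steps (lowest argmax on ties); the
  alternative statistic — cumulative intersection of per-cell length and
  width histograms, 50 bins over the pooled range — is reported alongside.
* **Seeded watershed.** Components above `t_seed` (default 0.999) seed a
  region growing over the `t_opt` foreground, splitting masks that merge
  at the lower threshold.
* **Precision.** Stationary-phase cells barely grow, so a per-segment
  quadratic absorbs any slow drift and the SD of the pooled residuals is
  the measurement precision.
* **Mask geometry.** Per label: length is the extent along the major
  principal axis; width is $4\,\overline{|v|}$ over the cylindrical
  mid-section (central half of the axial extent), using the fact that
  transverse offsets are uniform across a rectangular cross-section —
  this estimator is rotation-invariant to about a pixel, where a thin-slice
  max-minus-min underestimates rotated masks.

## Numerical choices and degenerate inputs

* Truncated normals are drawn by inverse-CDF so one uniform draw per value
  keeps the RNG stream simple; a single seed drives a whole pipeline run,
  with per-stage seeds derived deterministically (and kept below $2^{31}$).
* Kernels must span at least three first-zero radii (constructor-enforced)
  so unit-sum normalisation is meaningful; all normalised kernels sum to
  1 ± 1e-6.
* Probability maps are validated against [0, 1] with a 1e-9 slack and then
  clamped — FFT round-off otherwise produces spurious rejections.
* Empty frames render as device + media; empty regions in the error
  report are flagged, not fatal; an all-zero probability map is an error
  (no threshold yields foreground); segments shorter than 4 points are
  skipped by the precision estimator with a warning.
* Label images use 16-bit storage; a trench simulation cannot plausibly
  exceed 65535 ids.

## What the synthetic data does and does not show

The generator reproduces the features that matter for segmentation
training: realistic geometry and crowding of linear colonies, diffraction
blur with correct first-zero scaling, phase-contrast halo/shade-off,
photon-limited noise, and parameter drift. It does not model sub-cellular
intensity structure, refractive-index gradients within cells, 2-D colony
mechanics (the 1-D trench solver is the physics core), nutrient-dependent
growth modulation, or time-dependent fluorescence dynamics (a hook field
exists on the cell state but no dynamics are implemented). Passing tests
therefore certify the pipeline's internal consistency and its contracts —
not that any specific real microscope is matched; that step is the
reference-matching workflow, which is intentionally manual.

Problem sizes used by the test-suite checks were chosen to estimate each
statistic stably: 500-step physics sweeps, ~1000 divisions for regression
slopes, $10^5$ pixels per flat field, $10^3$ points for the precision
estimator, $10^4$ jitter draws.
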