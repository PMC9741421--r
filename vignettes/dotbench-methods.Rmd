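---
title: "dotbench: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dotbench: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific model behind `dotbench`, the parameter
choices that matter, the numerical conventions, and what the test suite does
and does not establish. It states no empirical result that the tests or the
acceptance script do not themselves compute.

## 1. Forward model

Near-infrared light in high-scattering tissue is modelled by the
frequency-domain photon diffusion equation

$$\nabla \cdot D \nabla \Phi(r,\omega) - \Big(\mu_a + \tfrac{i\omega}{c}\Big)\Phi(r,\omega) = -S_0(r,\omega),
\qquad D = \frac{1}{3(\mu_s' + \mu_a)},$$

with photon density $\Phi$, absorption $\mu_a$ (mm⁻¹), reduced scattering
$\mu_s'$ (mm⁻¹), modulation angular frequency $\omega$ and medium wave speed
$c$. Two equally valid time conventions exist, differing only by complex
conjugation of $\Phi$; `dotbench` uses $e^{-i\omega t}$, under which the term
is $+i\omega/c$ and the **phase lag** is $-\mathrm{Arg}\,\Phi \ge 0$, growing
with source–detector distance. (Under the opposite convention the same
physics prints as $\mu_a - i\omega/c$.)

Discretization is Galerkin FEM with linear triangles on a structured disk
mesh: ring $k$ of $n$ carries $6k$ equally spaced vertices, giving
$3n^2+3n+1$ nodes and $6n^2$ triangles; $n = 32$ reproduces the
3169-node / 6144-element geometry of the reference system. Element
coefficients are the means of the nodal values, which keeps the Jacobian
assembly exact and cheap.

Choices the literature leaves open, fixed here:

| Parameter | Value | Rationale |
|---|---|---|
| Boundary condition | Robin, $\Phi + 2AD\,\partial\Phi/\partial n = 0$, $A = 1$ | index-matched boundary; the standard diffusion boundary model |
| Wave speed | $c = 299.792458/n_r$ mm/ns, $n_r = 1.4$ | typical soft-tissue refractive index |
| Source model | unit isotropic point source at depth $1/\mu_s'$ inside the boundary | standard diffusion-theory replacement of a collimated source |
| Detector readout | field value at the detector fiber's boundary node | consistent with fitting log-magnitude/phase data |
| Units | mm, mm⁻¹, MHz; $\omega$ in rad/ns internally | keeps matrix entries near unity |

The complex system is solved as an equivalent real $2N \times 2N$ sparse
block system (the Matrix package has no complex sparse solver), one
factorization per assembly serving all 16 sources and all 16 adjoint loads.

**Analytic oracle.** The FEM is validated against the planar infinite-medium
Green's function $K_0(kr)/(2\pi D)$, $k = \sqrt{(\mu_a + i\omega/c)/D}$,
implemented for complex argument (power series for $|z| \le 8$, asymptotic
expansion beyond, checked against `besselK` on the real axis). The familiar
3-D kernel $e^{-kr}/(4\pi D r)$ is *not* the right oracle for a 2-D solver —
it differs by an order of magnitude at 10 mm — so the 2-D kernel is used.
The oracle test places the source at the disk center (a fiber source sits
one mean free path from the boundary, where the boundary dominates the
field and no infinite-medium comparison is meaningful).

**Reciprocity.** Adjoint reciprocity of the symmetric discrete system,
$b_i^\top A^{-1} b_j = b_j^\top A^{-1} b_i$, holds to solver precision and is
tested at $10^{-6}$. The naive statement "source $i$ read at fiber $j$ equals
source $j$ read at fiber $i$" mixes two different functionals (interior point
source, boundary-node readout) and holds only up to discretization error on
a mesh with 6-fold symmetry, so it is not the tested form.

## 2. Synthetic phantoms and datasets

The generator emulates the breast-like design space of the reference
ring-scanning system: circular phantoms 60–150 mm in diameter, modulation
10–100 MHz, background $\mu_a \in [0.005, 0.03]$, $\mu_s' \in [0.5, 3]$ mm⁻¹,
0–2 circular inclusions of radius 4–17 mm with independent absorption and
scattering contrasts in $[1.5, 8]$, inclusion-count partition 1% / 44% / 55%.
All scalars are uniform on their ranges. Design choices:

- **Containment margin.** Inclusions satisfy
  $r_{oc} + r \le 0.95 \cdot d/2$, keeping them clear of the source ring;
  placement is resampled (≤ 100 attempts) on violation, and two inclusions
  are resampled until disjoint.
- **Exact partition.** Inclusion counts are allocated by largest-remainder
  stratification, so 10,000 samples contain exactly 100 / 4400 / 5500 cases
  and the 80/20 split is exactly 8000/2000; a seeded shuffle assigns labels.
- **Noise.** The instrument noise magnitude is not quantified in the source
  material; defaults are 1% multiplicative Gaussian amplitude noise (applied
  in linear amplitude, re-logged) and 0.5° additive Gaussian phase noise —
  typical FD instrument performance — and are configurable.
- **Truth images.** Ground truth is rasterized analytically (exact discs at
  pixel-center resolution) on the 64 × 64 grid spanning $[-d/2, d/2]^2$, row
  1 at minimum $y$; pixels outside the inscribed circle are masked to 0.
  Contrast targets are normalized as $(\mu/\mu_0 - 1)/(c_{\max} - 1)$ with
  $c_{\max} = 8$, so they lie in $[0, 1]$ regardless of the sample
  (per-sample normalization would discard the contrast magnitude).
- **Container.** Datasets are stored as RDS plus a JSON parameter sidecar
  and a phantom CSV; no HDF5 binding is assumed to exist offline.
- **Calibration.** Experimental data are mapped onto the simulation scale by
  the standard homogeneous-reference scheme,
  $\text{cal} = (\text{inhomog} - \text{homog}) + \text{reference}$, applied
  in the log-amplitude/phase domain, which cancels per-channel instrument
  gains exactly.

What a green generator test establishes: range containment, exact partition,
determinism, interpolation exactness. What it does not: that synthetic
measurements reproduce any particular laboratory instrument — real data
carry fiber-coupling variations, phantom fabrication errors and model
mismatch that only the calibration step addresses, and only partially.

## 3. Tikhonov (TR) inversion

The misfit $\chi^2 = \sum_i (\Phi^C_i - \Phi^M_i)^2$ is summed over all
log-amplitude and phase components (phase differences wrapped to
$(-\pi,\pi]$). Sensitivities are assembled by the adjoint method: with
symmetric $A$, $\partial y/\partial p = -\Psi^\top (\partial A/\partial p)\Phi$,
where $\Psi$ solves the system with a unit load at the detector node; one
factorization yields all 480 measurement sensitivities. Rows are converted to
$\mathrm{d}\ln|y| = \mathrm{Re}(\mathrm{d}y/y)$ and
$\mathrm{d(lag)} = -\mathrm{Im}(\mathrm{d}y/y)$; columns stack
$[\Delta D \,|\, \Delta\mu_a]$.

The update solves $(J^\top J + \lambda\,\mathrm{diag}(J^\top J))\,\Delta X
= J^\top \Delta\Phi$. The Marquardt (diagonal) damping was chosen over
$\lambda I$ because the $D$ and $\mu_a$ blocks differ by orders of magnitude
in scale. Schedule: $\lambda_0 = 10$, ×0.5 per accepted step (floor
$10^{-4}$), ×10 on rejection (a step that increases $\chi^2$), at most 6
rejections before returning the best iterate with a warning flag. Stopping:
relative $\chi^2$ change below $10^{-3}$ or 20 iterations. Updates are
computed in $(D, \mu_a)$, converted to $\mu_s'$ through the diffusion
relation and clamped to $\mu_a \in [10^{-4}, 0.1]$,
$\mu_s' \in [0.05, 5]$ mm⁻¹.

## 4. The sensor-to-image network

The network maps the $16 \times 15 \times 2$ measurement tensor (flattened to
a 240-long, 2-channel sequence, detector index fastest) plus two auxiliary
scalars (modulation frequency, phantom diameter) to a 64 × 64 × 2 contrast
image and two background coefficients; final images are contrast ×
background. Both paths open with a convolution of stride $N_d$ — one stride
per source activation, collapsing each source's 15-detector block into one
feature vector.

- **Background path (block B):** conv1d(stride $N_d$) → ReLU → conv1d(16
  maps) → ReLU → global average pooling to exactly 16 units → concat aux →
  two dense layers → softplus. The softplus output is multiplied by a fixed
  per-channel scale (0.02, 2) mm⁻¹ so both coefficients start and move on
  their physical scales; without this, the ~100× scale gap between μa and
  μs′ makes the absorption head unlearnable in short runs (the same gap
  motivates the $w_a = 100^2$ loss weight).
- **Contrast path (block A):** two conv+BN+ELU stages at width 16, a
  conv+BN+LeakyReLU stage to width 64, the strided collapse, then a 1-D
  encoder–decoder whose bottleneck is gated multiplicatively (per channel)
  by a dense embedding of the aux scalars ($2\sigma(\cdot)$, mean ≈ 1), a
  skip connection around it, and a conv back to 16 maps — 16 × N_s features.
  Two dense layers form the initial 64 × 64 × 2 image, which is circularly
  masked, refined by a 3-level U-net (widths 32-64-128 by default) with an
  additive input–output skip, passed through a sigmoid (contrast ∈ [0, 1])
  and masked again.
- **Initialization:** seeded Glorot-uniform; the image-forming dense bias is
  initialized at −2 so the initial contrast (~0.12 after sigmoid) matches the
  mostly-background truth prior rather than 0.5.
- **Unstated hyperparameters** (kernel sizes 3, U-net depth 3, dense widths,
  gate form) are free design choices exposed in `network_config()`. The
  `"scaled"` preset (widths 8/16, embedding 32, dense 256, U-net 4-8-16) is
  the CPU-budget variant used by the desk-scale tests; it preserves every
  shape contract of the full architecture. Its widths shrink the U-net
  hardest and keep proportionally more of the fully connected
  domain-transform stage, which is where the full design concentrates its
  parameters and which costs almost nothing on CPU; desk-scale localization
  is sensitive to exactly this stage.
- **Two-path variant.** The shared U-net tends to give both coefficient
  images the same contour (they differ mainly by scale); `two_path = TRUE`
  gives each channel its own U-net. Off by default, matching the reference
  architecture.
- **Training:** Adam ($\beta_1 = 0.5$, lr $2 \cdot 10^{-4}$, batch 32);
  inputs standardized per feature with training-split statistics stored in
  the model; aux scalars min-max scaled by their design ranges. The tested
  weights come from the epoch with the lowest validation Q — automating the
  manual early-epoch selection used against overfitting. All layers and
  their backpropagation are implemented in the package; the only compiled
  code is an im2col + BLAS kernel for the 2-D convolutions (`src/conv.cpp`),
  kept bit-consistent with a pure-R reference (`conv2d_ref`) that the tests
  check against.

What the scaled-down training test establishes: the full pipeline
(generation → training → inference) learns — validation Q beats the
predict-the-mean baseline — and localizes high-contrast inclusions from
measurements alone. What it does not: the image quality of the reference
10,000-sample / 200-epoch GPU training, or performance on laboratory data.

## 5. CSD resolution metrics

For each coefficient image, with inclusion regions taken from the true
discs and background taken ≥ 2 pixels away from every inclusion:

- **Contrast:** robust Weber contrast $C = (P_{90}^{incl} - P_{10}^{back})/
  P_{10}^{back}$ (percentiles replace max/min against outliers; per-inclusion
  $P_{90}$ averaged over inclusions); $Ro_{cont} = C_{recon}/C_{truth}$,
  folded to $R_{cont} = 2 - Ro$ when $Ro > 1$ — negative values signal
  overestimation beyond 2×.
- **Size:** $Ro_{size} = 1 - \mathrm{RMSE}_{incl}(recon, truth)/
  \mathrm{RMSE}_{incl}(truth, baseline)$ with the flat background as
  baseline.
- **Compositions:** although the defining relations can be read as plain
  products, every self-consistent worked table row satisfies the
  geometric-mean forms $R_{size} = \sqrt{R_{cont} \cdot Ro_{size}}$ and
  $R_{csd} = \sqrt{R_{cont} \cdot R_{size}}$ to printed rounding, so those
  are implemented. On negative branches the *unfolded* contrast
  $2 - R_{cont}$ is substituted and the result carries a negative sign —
  the only rule consistent with the worked negative rows. Two printed rows
  are arithmetically inconsistent with their own factors (one scattering row
  and one whole case) and are excluded from the property tests.
- **Classification:** raw ratio above/at/below $1/c_{\max}$ ⇒ normal / no
  contrast / abnormal; the reference threshold $T = 0.3$ flags whether at
  least 30% of the original contrast-size detail is recovered.

Degenerate inputs: a homogeneous phantom has no contrast to resolve — the
report flags the case instead of dividing by zero; a flat reconstruction
scores exactly 0 on size and CSD.

## 6. Numerical conventions and degenerate cases

- Phase lags are folded to $[0, 2\pi)$; inverse-solver residuals wrap phase
  differences to $(-\pi, \pi]$, so calibration and misfits are insensitive
  to the fold.
- Pixels inside the circular mask but outside the polygonal mesh hull (a
  sliver of width $O(R/n^2)$) interpolate from the nearest element with
  clamped barycentric weights; linear interpolation is exact for affine
  fields on the hull interior and never overshoots nodal bounds.
- Percentiles use linear interpolation (R type 7).
- The normal-equation diagonal is floored at $10^{-12}$ of its maximum to
  keep zero-sensitivity parameters (e.g. phase columns at DC) from producing
  singular systems.
- Noise draws that would make a linear amplitude nonpositive (beyond 100
  sigma at the default level) are floored at $10^{-6}$.

## 7. Known limitations

- 2-D circular geometry only; no oval or breast-shaped profiles, no 3-D.
- The forward model is the diffusion approximation: it degrades near sources
  and for low-scattering media ($\mu_s' \lesssim 10\,\mu_a$).
- The network presets are desk-scale; reproducing reference-quality
  reconstructions requires the full-width configuration, ~10⁴ samples and
  GPU-scale training.
- The TR solver reconstructs $(D, \mu_a)$; short runs show μa/μs′ cross-talk
  (overestimated scattering contrast), visible as negative size/CSD
  resolutions in the README example.
- Laboratory measurement sets are not shipped; the calibration path is
  exercised on synthetic stand-ins constructed in the tests.
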