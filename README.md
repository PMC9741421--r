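# dotbench — a frequency-domain diffuse optical tomography workbench

Diffuse optical tomography (DOT) reconstructs the absorption (μa) and reduced
scattering (μs′) coefficients of soft tissue — most prominently the breast —
from measurements of multiply scattered near-infrared light on the tissue
boundary. In a frequency-domain (FD) ring-scanning system, 16 fibers sit on a
circle around the tissue; each fiber in turn injects intensity-modulated
light while the other 15 record the logarithmic amplitude attenuation and
phase lag, giving a 16 × 15 × 2 measurement set per scan. The inverse problem
(measurements → coefficient images) is nonlinear, ill-posed and
ill-conditioned.

`dotbench` implements the full workbench for this problem on circular,
breast-like phantoms with 0–2 circular inclusions:

- **Forward model.** Linear-triangle FEM solution of the FD photon diffusion
  equation ∇·D∇Φ − (μa + iω/c)Φ = −S₀ with D = 1/(3(μs′ + μa)), a Robin
  boundary condition Φ + 2AD ∂Φ/∂n = 0, and isotropic point sources placed one
  transport mean free path inside the boundary. The structured disk mesh at
  32 rings has exactly 3169 nodes and 6144 elements.
- **Synthetic data.** A phantom sampler over the design ranges (diameter
  60–150 mm, 10–100 MHz, μa 0.005–0.03 mm⁻¹, μs′ 0.5–3 mm⁻¹, inclusion radius
  4–17 mm, contrast 1.5–8; inclusion-count partition 1% / 44% / 55%), a noise
  model, 64 × 64 ground-truth rasterization, and a dataset builder with an
  exact 80/20 train/validation split. A homogeneous-reference calibration
  maps experimental measurement pairs onto the simulation scale.
- **Tikhonov (TR) reconstruction.** Adjoint-method Jacobian
  J = [∂Φ/∂D ∂Φ/∂μa] and damped normal equations
  (JᵀJ + λ·diag(JᵀJ)) ΔX = Jᵀ ΔΦ, iterated with step acceptance on the χ²
  misfit.
- **Sensor-to-image neural network.** A branching convolutional network: a
  background-predictor path (strided 1-D convolutions, global average
  pooling to 16 units, softplus) and a contrast-image path (1-D convolutional
  domain transform with an aux-gated encoder–decoder bottleneck, fully
  connected layers to a circularly masked 64 × 64 × 2 initial image, and a
  residual U-net). Outputs are contrast images in [0, 1] multiplied by the
  predicted background coefficients. Trained with the weighted loss
  Q = w_ima·MSE(c_a) + w_ims·MSE(c_s′) + w_a·MSE(μa0) + w_s·MSE(μs′0),
  w_a = 100², others 1 (Adam, β₁ = 0.5, lr 2·10⁻⁴, batch 32). Layers and
  backpropagation are implemented in the package (R + a small C++ im2col
  kernel); no deep-learning framework is required.
- **CSD image quality metrics.** Robust Weber-contrast resolution (90th/10th
  percentiles), size resolution from inclusion-region RMSE, and the composed
  contrast-size-detail (CSD) score with the folding convention where values
  above 1 reflect to 2 − R and negative values flag overestimation;
  classification against the 1/c detectability bound and the T = 0.3
  reference threshold.

## Worked example

```r
library(dotbench)
set.seed(1)

# a 90 mm phantom with one 15 mm inclusion, 4x absorption contrast
ph <- phantom(90, 50, 0.01, 1.0,
              list(inclusion(15, 18, 45, 4, 2)), margin = 0.95)
mesh  <- build_disk_mesh(16, ph$diameter_mm)
probe <- probe_geometry()               # 16 fibers, 15 detectors each
meas  <- forward_measure(ph, mesh, probe)
dim(meas$log_amplitude)                 # 16 x 15

init <- list(mu_a = rep(0.01, 817), mu_s = rep(1, 817))
class(init) <- "dot_coeffs"
res <- reconstruct_tr(meas, mesh, probe, init, recon_options(max_iterations = 8))
res
#> <dot_recon_result> 8 iteration(s), chi2 553.8 -> 0.6574, converged=FALSE

img <- list(mu_a_grid = interpolate_to_grid(res$coefficients$mu_a, mesh),
            mu_s_grid = interpolate_to_grid(res$coefficients$mu_s, mesh),
            mask = image_grid(64, 90)$mask, kind = "absolute",
            diameter_mm = 90, mu_a0 = 0.01, mu_s0 = 1)
class(img) <- "dot_image"
evaluate_sample(img, phantom = ph)
#> <dot_resolution_report> (T = 0.3 )
#>  coefficient  Ro_cont     R_cont    Ro_size     R_size      R_csd classification pass_T
#>         mu_a 1.234363  0.7656372  0.2100604  0.4010363  0.5541194         normal   TRUE
#>         mu_s 3.990088 -1.9900878 -0.6324293 -1.5885366 -2.5176180         normal  FALSE
```

The χ² misfit drops from 554 to 0.66 over eight accepted Tikhonov steps. The
report reads: the absorption image slightly overestimates the true inclusion
contrast (raw ratio `Ro_cont` 1.23, folded to `R_cont` 0.77) and recovers
enough size detail for a combined CSD score of 0.55 — above the T = 0.3
reference, so the μa inclusion counts as recovered. The scattering image is
grossly overestimated (raw contrast ratio ≈ 4), which the folding convention
turns into negative resolutions — the characteristic signature of μa/μs′
cross-talk in a short TR run — so its CSD score fails the threshold.

The neural route mirrors the iterative one:

```r
ds <- generate_dataset(500, seed = 1, n_rings = 16)     # ~20 s
model <- assemble_network(network_config(preset = "scaled"), seed = 1)
trained <- train_network(model, ds, training_config(epochs = 40, seed = 1))
img_nn <- reconstruct_nn(trained, meas)                 # 64 x 64 x 2 image
```

A command-line front end covers the same workflow
(`inst/cli/dotbench generate|train|reconstruct|evaluate|demo`); every run
writes a JSON manifest with the resolved configuration and seeds.

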