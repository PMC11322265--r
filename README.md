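# deastrain

Machine-learning strain-field customization for a bioreactor driven by a
9 × 9 array of dielectric elastomer actuators (DEAs).

## The problem

Mechanobiology experiments need bioreactors that stretch cells with
*spatially structured* strain — annular fields mimicking vessel walls,
unidirectional gradients for migration assays, or the 2-D outline of a
tumour–stroma interface as an in-vitro cancer testbed. A 9 × 9 DEA array on
a prestretched elastomer membrane can shape such fields, but the actuation is
nonlinear and the pixels are mechanically coupled, so no analytical map links
the 81 drive voltages to the resulting strain image. `deastrain` solves both
directions of that map by image regression, for the engineers and
mechanobiologists building or simulating such devices:

* **inverse control** — target strain image → 81-channel voltage array;
* **forward control** — voltage array → strain-field image (a fast surrogate
  for simulation), with an optional adversarial super-resolution stage
  (60 × 60 → 480 × 480).

## The model

A single pixel follows a dual-Gaussian voltage–strain calibration

    eps(V) = a1 exp(-((V - b1)/c1)^2) + a2 exp(-((V - b2)/c2)^2),

strictly increasing on the 0–7.1 kV operating range (defaults
a1 = 7.756e15, b1 = 24.1, c1 = 2.964, a2 = 47.69, b2 = 10.18, c2 = 4.401).
The membrane is prestretched 100% (engineering), i.e. ln 2 = 69.31% true
strain. A closed-form surrogate simulator (calibration + anisotropic
inter-pixel coupling + clamped-boundary taper) stands in for finite-element
analysis when generating training data. Training sets are sampled by drawing
per-pixel *strains* uniformly and inverting the calibration, so the fields
cover all strain levels evenly. The inverse controller is a 3600 → 180
(tanh) → 81 perceptron trained with SGD (lr 0.001); the forward controller
maps 81 → 7200 (both axes' low-resolution images) and a SRGAN-style
generator upscales ×8. Image quality is scored with the Gaussian-window
(11-point, sigma 1.5) structural similarity index

    SSIM(x, y) = [luminance] x [contrast] x [structure],  C3 = C2/2,

averaged over the local SSIM map. See the methods vignette
(`vignettes/strain-field-customization.Rmd`) for assumptions, parameter
rationale and design decisions.

## Worked example

```r
library(deastrain)

config <- dea_config()           # 9x9 array, 0-7.1 kV, 60/480 px images
curve  <- dea_curve()            # dual-Gaussian calibration
reachable_strain_range(curve)
#> [1]  0.2263305 69.3223296

# surrogate dataset: uniform-strain sampling, 1000 train / 50 test
ds  <- build_dataset(1000, 50, sampling_scheme("uniform_strain", seed = 42))

# inverse control: strain image -> voltages
inv <- train_inverse(ds, axis = "x", inverse_config(epochs = 20, seed = 1))
ev  <- evaluate_inverse(inv, ds)
#> held-out voltage error: RMSE 0.066 kV (MSE 0.0044 kV^2) over 50 samples

# reproduce demonstration targets through the closed loop
reproduce(target_spec("gradient", direction = "horizontal"), inv)$report$mean_ssim
#> [1] 0.9280          # horizontal-gradient reproduction SSIM
reproduce(target_spec("annuli"), inv)$report$mean_ssim
#> [1] 0.8011          # concentric-annuli reproduction SSIM

# forward control: voltages -> strain image
fwd <- train_forward_lr(ds, forward_config(epochs = 5, seed = 1))
evaluate_forward_lr(fwd, ds, "x")$mean_ssim
#> [1] 0.9978          # held-out SSIM vs surrogate ground truth
```

The RMSE is the held-out voltage-prediction error in kV (range 0–7.1 kV);
the SSIM values compare preprocessed 60 × 60 grayscale strain images, 1
being pixel-perfect structural agreement. At the reference scale (10,000
training samples) the errors tighten further; see `scripts/acceptance.R`.

## Command line

A thin CLI ships in `inst/cli/deastrain`
(`simulate`, `generate`, `train-inverse`, `evaluate`, `evaluate-ssim`,
`reproduce`); images are stored as 16-bit PGM with JSON sidecars, voltage
arrays as CSV (`v00..v88`, row-major).
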