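---
title: "Customizing strain fields in a DEA-array bioreactor: models, surrogate and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Customizing strain fields in a DEA-array bioreactor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deastrain)
```

## The problem

Cell-stretching bioreactors apply mechanical stimuli to cultured cells or
tissues. Conventional designs deliver only uniaxial or biaxial stretch; a
9 × 9 array of independently addressable dielectric elastomer actuators
(DEAs) on one prestretched 100 mm × 100 mm membrane can instead shape an
almost arbitrary 2-D strain field — an annular field mimicking a vessel wall,
a strain gradient for migration assays, or the outline of a tumour–stroma
interface. Two control problems arise:

* **inverse control** — given a target strain image, find the 81 drive
  voltages that reproduce it;
* **forward control** — given 81 voltages, predict the strain field the
  device will produce, orders of magnitude faster than a finite-element
  simulation.

Both are solved here by image regression: multilayer perceptrons trained on a
large synthetic dataset of (voltage array, strain image) pairs, with an
adversarial super-resolution stage upscaling the forward prediction. The
package implements the full pipeline — virtual device, dataset generation,
both controllers, SSIM evaluation, demonstration targets — as tested code.

## The virtual device

### Calibration

A single actuated pixel follows a dual-Gaussian calibration of strain against
voltage,

$$\epsilon(V) = a_1 e^{-((V-b_1)/c_1)^2} + a_2 e^{-((V-b_2)/c_2)^2},$$

with default constants `r paste(unlist(dea_curve()), collapse = ", ")`
(for $a_1, b_1, c_1, a_2, b_2, c_2$). Both Gaussian centres lie above the
7.1 kV operating maximum, so the curve is strictly increasing on the
operating range — a property asserted by the test suite on a $10^4$-point
grid. The units of $\epsilon$ are treated as an abstract calibrated display
scale (the reachable range is about 0.23 to 69.3, and the grayscale display
range defaults to $[0, 70]$): the calibration source does not state whether
the scale is percent actuation strain or includes prestretch, so the package
takes the curve at face value and never interprets its units physically.

The membrane is biaxially prestretched by 100% engineering strain before
actuation, i.e. a true strain of $\ln 2 = 69.31\%$. Prestretch keeps the
membrane planar but is applied before cells are seeded, so it enters reports
only through `engineering_to_true_strain()` and the device configuration.

### Surrogate simulator

The training-data source in the original workflow is a finite-element model
(a coupled electromechanical analysis with a custom user element,
neo-Hookean membrane, $C_{10} = 0.207$, $D_1 = 0.05$ — recorded here for
documentation only). The learning method, however, needs a data source with
the right *structure* — per-pixel nonlinearity, inter-pixel coupling,
clamped boundaries — not finite-element fidelity. `dea_simulate()` therefore
replaces the FEA with a closed-form surrogate:

1. per-pixel commanded strains $\epsilon_k = \epsilon(V_k)$;
2. a piecewise-constant map painted over the 9 × 9 pixel footprints
   (nearest-boundary rasterization: each image pixel belongs to the device
   pixel containing its centre);
3. convolution with an anisotropic Gaussian coupling kernel, truncated and
   renormalized at the image border;
4. multiplication by a smoothstep taper that ramps to the undeformed clamped
   frame over `boundary_margin` of the field width.

**Kernel orientation.** For the X-strain field the kernel is elongated
*along* x, for the Y field along y. This follows the membrane mechanics: the
actuators in a row are mechanically in series along the loading direction of
the X strain, and a clamped, prestretched membrane redistributes strain along
that direction. It also reproduces the device's observed asymmetry — a
horizontal strain gradient in the X field renders smoothly (the broad
along-axis smoothing turns the commanded 9-step staircase into a near-ramp),
while a vertical gradient in the X field stays a sharp staircase and scores
visibly lower. The test suite asserts this ordering.

**Kernel scale.** Defaults are $\sigma_\parallel = 0.2$ and
$\sigma_\perp = 0.07$ device-pixel units. These are deliberately sub-pixel:
the own-pixel kernel weight at a pixel centre is $\ge 0.98$, so centre-point
strains remain essentially the commanded strains. This is not a free choice:
the reference device's own uniformity measurements (std-of-probabilities
0.015, entropy 1.94 ≈ ln 7 over 7 bins at 810 pooled centre strains) sit at
the statistical limit of *exactly* uniform sampling, which tolerates at most
about 1% cross-pixel mixing at the centres. A kernel wide enough to dominate
pixel centres (e.g. $\sigma \approx 2$ pixels) is mathematically incompatible
with those numbers — and would also invert the gradient asymmetry above, since
broad cross-axis smoothing turns the *hard* direction into the easy one.
Coupling in this device blurs pixel *boundaries*, not pixel centres.

**Rasterization.** 480/9 is not an integer, so pixel footprints cannot align
with the image grid. Nearest-boundary rasterization keeps painting exact and
order-preserving; its price is that the few low-resolution pixels straddling
a device-pixel boundary differ between a directly rendered 60 × 60 field and
an area-downsampled 480 × 480 field by up to one commanded-strain step. The
agreement contract is therefore stated in the mean (≤ 2% of the display
range), not the maximum.

The simulator is deterministic, monotone (voltage order implies pointwise
field order, since the kernel is non-negative and the calibration increasing)
and transpose-covariant (transposing the voltage matrix transposes and swaps
the two fields); all three are property-tested.

## Sampling and the training set

The calibration curve is shallow at low voltage and steep near the maximum,
so drive voltages drawn uniformly produce strain histograms piled up at low
strain. `sampling_scheme("uniform_strain")` instead draws per-pixel *strains*
uniformly over the reachable interval and maps them through the inverse
calibration (`voltage_from_strain()`, a vectorized bisection accurate to
~1e-12 kV) — inverse-CDF sampling through the nonlinear calibration. Datasets
(`build_dataset()`) default to the reference protocol of 10,000 training and
100 test samples.

Uniformity is quantified by `strain_distribution_metrics()`: pooled
centre-pixel strains of 10 simulated fields (810 values), a 7-bin equal-width
histogram over the reachable range, the sample standard deviation of the 7
bin probabilities, and the Shannon entropy in natural log. The 7-bin/natural
log convention is pinned down by the reference value 1.94: it equals
$\ln 7 = 1.9459$ to printed precision under near-uniform occupancy. Note two
small-sample facts, established analytically and visible in the tests: at
$n = 810$ even perfect uniformity yields an expected probability-std of
$\approx 0.012$ and an expected plugin entropy of $\ln 7 - 6/(2 \cdot 810)
\approx 1.942$; the acceptance thresholds (≤ 0.015, ≥ 1.94) therefore sit
within a couple of millinats of the theoretical optimum, and the entropy
reading fluctuates by roughly ±0.002 across seeds.

## Inverse control

The inverse model is a single-hidden-layer perceptron, 3600 → 180 (tanh) →
81, trained per axis by mini-batch stochastic gradient descent at learning
rate 0.001 on mean squared error. Inputs are preprocessed images: the
boundary-taper margin is cropped, the active region resized to 60 × 60 by
area interpolation, intensities clipped to $[0, 1]$ and flattened row-major.
Voltage targets are standardized per pixel during optimization and
de-standardized (and clipped to $[0, 7.1]$ kV) at prediction.

### Why initialization is the crux

With generic random initialization this architecture stalls: the hidden units
receive dense mixtures of all 3600 pixels and must first *learn* to localize
on pixel footprints before they can represent the steep inverse calibration
(near zero strain, $dV/d\epsilon \approx 4$ kV per display unit). At learning
rate 0.001 the plateau sits near 0.7 kV RMSE after hundreds of epochs —
regardless of optimizer — an order of magnitude above what the architecture
can actually express.

The package therefore initializes the network from its own physics:

* a 2-term tanh fit of the scalar inverse calibration
  $V \approx w_0 + \sum_j w_j \tanh(a_j \epsilon + c_j)$ (variable-projection
  least squares; residual ≈ 0.026 kV over the reachable range);
* two hidden units per actuator pixel whose input weights are that fit
  applied to a bilinear centre-extraction filter on the preprocessed grid;
* a block-local output layer wiring each pixel's units only to its own
  voltage output, with the remaining 18 units started near zero.

SGD then refines all weights jointly and learns the coupling corrections. A
dense least-squares output initialization was evaluated and rejected: the
per-pixel tanh pairs are nearly collinear, the resulting solution carries
large mutually cancelling coefficients, and although it scores slightly
better in distribution it mispredicts smooth out-of-distribution targets by
more than a kilovolt. Block-local wiring keeps the model robust on exactly
the demonstration targets the controller exists for.

Training uses momentum 0.9 (the optimizer is stated only as "SGD, lr 0.001";
momentum is exposed in `inverse_config()`), a 5% validation split and
early stopping that retains the best-validation weights — which also guards
against the occasional instability of momentum SGD near an already-good
initialization. Epoch and batch defaults (60, 32) reach the loss plateau on
one CPU.

The held-out error is reported both as MSE in kV² and as RMSE in kV
(`evaluate_inverse()`), because the reference figure "MSE of 0.189 kV" is
dimensionally ambiguous; the package's acceptance bound holds for the
stricter RMSE-in-kV reading. The 9 × 9 mean-absolute-error grid uses MAE per
pixel. Edge pixels consistently score better than interior ones — with fewer
coupled neighbours (and a truncation-renormalized kernel raising their
own-centre weight) their characteristics are easier to learn — matching the
reference observation and asserted as a property test.

## Forward control

Stage 1 maps the 81 voltages to the concatenated X/Y preprocessed image pair
(7200 outputs) with one MLP (81 → 180 tanh → 7200, same optimizer settings).
Initialization mirrors the inverse model on the forward side: per-pixel tanh
units encode the forward calibration, and the output layer is wired through
an 81-feature least-squares estimate of the per-actuator image operator (how
each actuator's strain spreads into the image — footprint, coupling and
taper). Because the 81 calibrated-strain features are well conditioned, this
estimate is bounded and stable; it reproduces both held-out fields (SSIM >
0.99 on the surrogate) and out-of-distribution constant drives (interior
plateau within ~1% of the calibration) before SGD refinement even begins.
Direct 81 → 480² regression is deliberately absent: flattened
high-resolution images would multiply memory and training cost for no
benefit, which is the reason the two-stage design exists.

Stage 2 is an adversarial super-resolution generator/discriminator pair
(`train_super_resolution()`): residual blocks (conv-LeakyReLU-conv with
skip), three ×2 pixel-shuffle upsampling blocks realizing the ×8 scale
(60 → 480), and a discriminator of strided convolution blocks with LeakyReLU
and batch normalization, trained with binary cross-entropy (Adam, generator
2.5e-4, discriminator 1e-4, batch 8, 50 epochs at full scale). Design
choices:

* the generator predicts a residual on top of a fixed bicubic upscale, so
  training starts at bicubic parity and short CPU runs improve monotonically
  on that baseline;
* pixel-shuffle convolutions use ICNR-style initialization (the four channels
  of each shuffle group start identical), eliminating checkerboard artifacts
  that otherwise depress SSIM early in training;
* batch normalization is used only in the discriminator, where it is
  specified; in the generator it was measured to hurt held-out SSIM at small
  scale (train/eval statistics drift) and is omitted, consistent with modern
  super-resolution practice;
* the adversarial weight is calibrated on the first batch so the adversarial
  term contributes ~1% of the content (pixel MSE) loss;
* the content/adversarial losses, learning-rate split, batch size and epoch
  budget follow the reference configuration at full scale. The desk-scale
  preset (`sr_config_desk()`: 8 channels, 2 residual blocks, 8–12 epochs on
  ~100 reduced-size images, e.g. 10 → 80 at the same ×8 scale) has ~500×
  fewer optimizer steps than the full schedule and raises the Adam rates
  accordingly (0.005 / 0.002); it exists so the adversarial stage is
  exercised end-to-end in continuous integration, where it must — and does —
  beat the bicubic baseline on held-out SSIM.

## Evaluation: SSIM

`local_ssim_map()` implements the windowed structural-similarity index: an
11-point Gaussian window ($\sigma = 1.5$, the standard choice for this window
size; the width is configurable) slides over both images; within each window
the weighted mean luminance, variance and covariance enter the luminance ×
contrast × structure product with stabilization constants
$C_1 = (0.01 L)^2$, $C_2 = (0.03 L)^2$, $C_3 = C_2/2$ for data range $L$.
With $C_3 = C_2/2$ the three-term product collapses algebraically to the
common two-term form; both code paths exist and agree to ~1e-15, which is
tested. The local map is computed on fully valid windows only (no padding),
because the untextured taper frame behaves differently from the deformed
interior; the overall score is the plain mean of the local map. The
implementation agrees with scikit-image's `structural_similarity`
(Gaussian weights, population covariance) to better than 1e-4 on frozen
fixture pairs.

## Demonstration targets

`make_target()` renders three families on the display-gray scale: concentric
annuli (default boundaries at radius fractions 0.15/0.30/0.45 with levels
65/45/25 inner to outer over a background at the reachable minimum), linear
gradients spanning the reachable strain range, and tumour–stroma-like
interfaces (Fourier-perturbed ellipses with seeded harmonics; three canonical
seeds stand in for the three digitized interface shapes, which are not
redistributable — all interface fixtures here are synthetic emulations).

Discrete-level targets are softened at their boundaries with a Gaussian of
0.5 device pixels (half the actuator pitch). Strain fields are continuous;
a strain discontinuity is not producible by any voltage pattern, and scoring
the controller against one measures the device's resolution limit (a hard-
edged annuli target caps at SSIM ≈ 0.54 for *any* controller, including an
oracle that reads off the exact centre strains). The softening width was
fixed from the device geometry before any controller was evaluated.

`reproduce()` runs the closed loop — predict voltages, simulate, score
SSIM between the preprocessed target and reproduction — and returns the
voltage array, the reproduced field, and the SSIM report with its local map.
Because the original demonstration images are unpublished, reproduction
scores on these emulated targets are compared against the reference values
as bounds, not equalities.

## Scaled-down budgets

The reference protocol (10,000/100 dataset; 50-epoch 480 × 480 adversarial
training) is implemented in full but exercised at reduced scale where a CPU
budget demands it, with thresholds never relaxed: the test suite trains on
2,000/100 (acceptance criteria) and 300/30 (property tests);
`scripts/acceptance.R` defaults to 4,000/100 and accepts `--full` for the
complete run; the super-resolution stage is tested with the desk preset.

## What a green test does and does not establish

The synthetic world reproduces the *structure* of the device data — the
nonlinear calibration, sub-pixel anisotropic coupling, clamped boundaries,
uniform strain coverage — and every learning-stage claim is tested against
it. It does not emulate finite-element mechanics (no strain redistribution
constraints, no out-of-plane effects), fabrication noise or drift,
viscoelasticity (the reference analysis is quasi-static), or electrical
isolation gaps between pixels. Green tests therefore establish that the
control method works as specified on a device with these structural
properties, not that the surrogate matches any physical device's absolute
strain values.

Other known limitations: the inverse model's accuracy deteriorates near the
steep low-voltage end of the calibration (the error grids are dominated by
pixels commanded close to 0 kV); the printed "prediction accuracy"
percentages of the reference workflow have no stated definition and are
deliberately not implemented — MSE/RMSE and error grids are the reported
metrics; and the nearest-boundary rasterization makes single boundary pixels
resolution-dependent, as described above.
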