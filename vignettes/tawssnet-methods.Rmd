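---
title: "Methods: surrogate TAWSS fields and the point-cloud U-Net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate TAWSS fields and the point-cloud U-Net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tawssnet` is a self-contained pipeline for studying whether a compact
convolutional network can replace a transient CFD solve as a predictor of
time-averaged wall shear stress (TAWSS) on idealized left-coronary
bifurcations. This vignette documents the models, the numerical choices
behind them, and the limits of what the package's own experiments can show.

## The morphological population

A bifurcation is described by five parameters: the LM, LCx and LAD
diameters and two angles — `gamma`, the LM–LAD bend (180° means the LAD
continues the LM axis) and `alpha`, the LAD–LCx opening. Defaults cover the
healthy adult ranges used to build the training population:
`d_lm` 2.18–4.18 mm, `d_lcx` and `d_lad` 1.5–3.5 mm, `gamma`
112.75–172.75°, `alpha` 15–130°.

How the published population of 1800 models was distributed over these
ranges is not recoverable from the ranges alone, so `sample_morphologies()`
offers two declared modes: seeded independent uniform draws per parameter
(the default) and a Latin hypercube (`method = "lhs"`, via the **lhs**
package). Neither is asserted to be the original design; uniform sampling
is the default because it covers the box without committing to a factorial
structure.

Splits follow the batch-wise protocol: the ordered id list is cut into
consecutive batches (300 at full scale) and a fixed quota (60) is drawn
uniformly at random from each, giving the 360-model test set; 10% of the
remaining pool, rounded half to even, forms the validation set (144 of
1440, leaving 1296 for training).

## Geometry

Centerlines are analytic primitives in a canonical frame: the LM is a
straight segment along +x ending at the origin; each daughter leaves the
origin in the z = 0 plane and follows a circular arc (default bend radius
20 mm; `Inf` gives straight rays) so the daughters curve apart. Vessel
lengths are 8 `d_lm` for the LM and 10 `max(d_lad, d_lcx)` for the
daughters — declared defaults, not reconstructions; the published figures
do not state them. The CFD-style upstream flow extension (seven diameters)
is a solver construct and is not part of the sampled surface.

The surface is the zero level set of a smooth-min (log-sum-exp) union of
the three tube distance fields with blend parameter `k = 0.4 d_lm`, which
yields a C¹ fillet at the junction without a CAD kernel. The structured
cloud has `rows x cols` points (64 x 64 = 4096 by default): rows are axial
stations with a fixed quota (16 LM / 24 LAD / 24 LCx at 64 rows,
proportional to path lengths), columns are equispaced circumferential
angles measured from the bifurcation-plane normal (+z). Each point is
obtained by radial bisection of the implicit function to |F| below 1e-9 mm,
so stations away from the junction are exact circles of the vessel
diameter, and points whose two smallest tube fields differ by less than
`4k` are labeled `JUNCTION`.

Within the printed parameter ranges the two daughters can never fold back
onto the LM (the LCx stays more than 55° away from the upstream axis), but
the builder still refuses configurations within 30° as a guard for
hand-written parameter sets.

## The surrogate wall-shear field

The package replaces the transient CFD solve with an analytic surrogate
whose role is to give the network a physically structured, pulsatile,
morphology-dependent label — not to reproduce any particular simulation.
Its components:

- **Rheology.** Carreau–Yasuda viscosity
  `mu = (mu0 - mu_inf) (1 + (lambda g)^a)^((m-1)/a) + mu_inf` with the
  standard blood constants (`mu0` 0.056 Pa s, `mu_inf` 0.0035 Pa s,
  `lambda` 1.902 s, `m` 0.22, `a` 1.25). The index is printed under the
  heading "n" in some sources; it is the same exponent as `m` here.
- **Flow.** A two-lobe raised-cosine waveform (period 0.8 s, diastolic
  lobe twice the systolic amplitude, baseline 0.2) rescaled analytically to
  cycle mean 1 stands in for a measured coronary inlet wave. Mean inlet
  flow is `v_mean * pi d_lm^2 / 4`; branch flows follow Murray's cube law,
  the usual stand-in for pressure outlets that let flow apportion itself.
- **Base stress.** Per vessel, the Poiseuille wall shear rate
  `32 Q_v(t) / (pi D_v^3)` with viscosity evaluated at that rate (one shot,
  no fixed point: the map stays smooth and monotone in `Q/D^3`). Points mix
  the three vessel stresses with softmin weights in the tube fields
  (softness `1.0 d_lm`), so the stress is continuous across the junction.
- **Modulators.** Multiplicative, time-independent: an apex amplification
  `1 + A_a exp(-d^2/2 sigma_a^2)` centered on the flow-divider tip
  (`A_a = 1`, `sigma_a = 0.5 d_lm`), a lateral-wall reduction
  (`A_l = 0.4`, `sigma_l = 1.0 d_lm`) on the outer junction wall, and a
  circumferential factor `1 + A_c cos(phi)` producing the front/back
  asymmetry seen on curved daughters. `A_c` is set from the target
  front/back mean ratio `r` as `A_c = (r-1)/(r+1) * pi/2` — the half-circle
  mean of `cos` is `2/pi`, so this makes the measured front-half to
  back-half mean ratio exactly `r` (default 1.25, i.e. the front view is
  ~25% higher). An optional `alpha_apex_gain` lets the apex amplitude grow
  with the opening angle; it is off by default because the underlying trend
  is only known qualitatively.
- **TAWSS.** The trapezoidal time average of |WSS| over one period, on 65
  samples by default. The waveform's lobes have zero endpoint slope, so
  the trapezoid is accurate to O(h^4); a 16x finer grid changes TAWSS by
  less than 0.1%.

**Calibration.** The mean inlet velocity is the one free scale. It is set
to 0.6 m/s so that pooled surrogate TAWSS over a 100-model population sits
within a 2–20 Pa band (5th–95th percentile, measured 2.1–16 Pa across
seeds) with typical per-model fields of 3–15 Pa, the magnitude range the
method is meant to operate in. This was calibrated once against that band
and is configurable (`surrogate_config(v_mean = ...)`).

What the surrogate does **not** emulate: secondary/Dean flows, flow
separation and recirculation, oscillatory WSS direction (so OSI-type
indices are out of scope), wall compliance, and any dependence of the
waveform shape on morphology. Consequently, passing tests show that the
learning pipeline can recover a smooth, physically plausible
morphology-to-field map from point clouds — they do not certify accuracy
against real CFD or in vivo data.

## Ordering and grid encoding

CNNs need an ordered grid. `pca_order()` centers the cloud, takes the
covariance eigenvectors, and sorts points by their projection on the
leading axis; `axis_order()` sorts on a raw coordinate. Two conventions the
eigendecomposition leaves open are fixed deterministically: the leading
eigenvector is oriented to nonnegative dot product with +x (the LM inflow
direction; if that projection is zero, the largest-magnitude component is
made nonnegative), and ties are broken by the second and third projections,
then input index. The sign convention is resolved per model. Note that it
is frame-dependent by construction: rotations large enough to flip the
+x projection reverse the order, which is the price of a deterministic
convention the package accepts.

`to_grid()` lays consecutive blocks of 64 sorted points into the rows of a
64 x 64 grid (row-major); no space-filling curve is used. `from_grid()`
inverts it exactly, which is what lets predictions be mapped back to the
original point ids.

A property of the comparison between orderings is worth stating plainly:
in the canonical construction frame the LM axis coincides with +x, so a
plain x sort is itself an anatomically coherent sweep and performs on par
with (here, slightly better than) PCA ordering. PCA ordering's purpose is
to impose that coherence *without* a hand-aligned frame. The ordering
ablation therefore poses its dataset in a fixed, generic (non-axis-aligned)
orientation — the regime any axis-agnostic canonicalization is meant for —
and trains all four arms on identical data, seeds and budgets.

## The network

`build_unet()` constructs the regressor: a shared per-point stem (3 -> 8 ->
8, each layer batch-normalized then ReLU), reshape to 64 x 64 x 8, two 3x3
convolutions, then four {max-pool, 2 convolutions} encoder stages
(64 -> 32 -> 16 -> 8 -> 4), four bottleneck convolutions at 4 x 4, and a
decoder of four {2x2 stride-2 transposed convolution, skip concatenation,
2 convolutions} stages, closed by a 1x1 linear head without normalization.
All convolutions are 3x3 with width 8. Batch normalization sits after each
convolution and before its ReLU. The stem is implemented as shared
per-point transforms — the only reading consistent with lifting 4096 x 3
to 4096 x 8 before any reshape. Transposed convolutions use 2x2 kernels
with stride 2 (exact doubling, no output-size ambiguity).

Because the field's deep-learning stacks are not part of this package's
dependency set, the layers (im2col-based convolution, batch norm, pooling,
transposed convolution) and Adam are implemented in the package itself,
with the index-heavy kernels in C++; a finite-difference test validates
the full backward pass.

Training choices left open by the architecture description and adopted
here: MSE loss on min-max-normalized targets (normalization constants are
the dataset-global TAWSS extremes recorded on the split manifest); Adam
with default moments; initial learning rate 1e-3 with staircase decay by
0.9 every 2000 optimizer steps; batch size 16; early stopping on
validation NAME with patience 20 and restoration of the best weights.
Inputs are the canonical-frame coordinates divided by a dataset-global RMS
scale; per-cloud centering is deliberately avoided because the shared
bifurcation origin is a useful anchor. The parameter count implied by
these choices (16,769 at the default configuration) is logged on the
model object; the published figure of 27,339 is not exactly reproducible
because stem widths, transposed-conv kernels and normalization-parameter
accounting are unstated, and no attempt is made to pad parameters to match.

## Error metrics

`mre()` is the mean over points of |y - yhat|/|y| in percent (the square
root of the squared ratio in the printed formula is an absolute value);
denominators below 1e-12 Pa are rejected rather than guarded silently.
`name_metric()` is the mean absolute error normalized by the
dataset-global TAWSS range, in percent; the global max convention is
stated explicitly by the source method and the global min is taken
symmetrically. Headline figures are reported as mean ± sd across test
models (the ± could also be read as across points; across models is
adopted and labeled).

## Problem sizes used by the test suite

The published experiment (1800 models, 4096 points, ~1350 h of CFD plus
GPU training) is replaced by scaled configurations chosen as desk-scale
study conditions:

- Unit and property tests use 8x8–32x32 grids and 3–100 models.
- The end-to-end experiment trains on 1200 models at 16 x 16 (levels 3,
  so the bottleneck keeps the full-scale 16-fold contraction) with batches
  of 200 and a per-batch test quota of 40 — the same 1/5 test fraction and
  10% validation rule as the full-scale protocol, at the largest
  population the suite's runtime allows. A 1800-model, 400-epoch run of
  the same pipeline (~48 CPU-minutes) reaches test NAME 1.53 +/- 0.99%.
- The ordering ablation runs four arms (x, y, z, PCA) on a shared
  200-model dataset in the generic pose described above, with identical
  seeds and budgets.

## Known limitations

- The surrogate's spatial structure is smoother than real CFD fields;
  error levels reached here need not transfer to CFD-labeled data.
- The network is resolution-bound: a model trained at one grid size does
  not accept another (the fixed-point-count limitation of the underlying
  method).
- PCA ordering of near-symmetric clouds has genuinely ambiguous point
  pairs (equal leading projections); the tie-break makes it deterministic
  but not meaningful there.
- On this surrogate benchmark the measured ordering ranking does not favor
  PCA: a fixed x sweep is competitive with or better than PCA ordering in
  both the canonical frame and the generic pose, plausibly because the
  surrogate field is smoother and more morphology-deterministic than CFD
  fields and because per-model PCA axes vary slightly between models,
  which costs the network cross-model consistency. The published advantage
  of canonical ordering should therefore be read as a property of
  CFD-labeled data that this surrogate does not reproduce.
- Predictions are frame-dependent: clouds must be supplied in the
  canonical construction frame.
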