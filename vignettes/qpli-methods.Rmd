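---
title: "qpli: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qpli: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the methods account of `qpli`: what is being modelled,
which knobs matter and why they default the way they do, what the phantom
simulator does and does not emulate, and where the design was genuinely
open and had to be decided. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## 1. Polarization model

Light–specimen interaction is described in the Stokes/Mueller formalism.
A weakly scattering, transparent specimen is modelled per voxel as a
linear retarder (retardance ρ, slow axis ω) composed with an isotropic
transmission/depolarization factor (t, p). Under a five-state acquisition
— right-circular illumination plus four elliptical states of compensatory
retardance χ, detected through a left-circular analyzer — exactly four
Mueller coefficients are retrievable:

$$m = (t,\; t p \sin 2\omega \sin\rho,\; -t p \cos 2\omega \sin\rho,\;
t p \cos\rho),$$

and the measured intensity vector is $I = A(\chi)\,m$ with the 5×4
instrument matrix whose rows correspond to RCP/0°/45°/90°/135°. Everything
the package retrieves rests on three assumptions: (i) the specimen is
mostly transparent (first Born regime); (ii) diattenuation is negligible
(its Mueller entries are not retrievable under this scheme and are not
modelled); (iii) the instrument matrix is known, i.e. the LC is
calibrated. Hardware calibration itself is out of scope.

**Inversion.** With 5 equations and 4 unknowns per voxel, `qpli` solves
ordinary least squares through a Moore–Penrose pseudo-inverse computed
once per χ. On noiseless in-range data this is exact; under additive
zero-mean noise it is the unbiased linear estimator (both are tested).
Voxels with recovered $m_0 \le 0$ are physically meaningless and are
flagged, never silently used.

**Key parameters.**

* `chi` (radians): LC compensatory retardance. The instrument matrix is
  rank-deficient at sin χ = 0, so χ must lie in (0, π). The acquisition
  hardware's actual swing is not published; the package default is
  0.06·π ≈ 0.19 rad (about 3% of a wave), a typical swing for LC universal
  polarizers. The value is configurable everywhere and recorded in run
  outputs. Reconstruction accuracy is insensitive to χ in the noiseless
  regime (the pseudo-inverse is exact for any non-degenerate χ); χ mainly
  shapes noise propagation.
* Channel order RCP, 0°, 45°, 90°, 135° is a validated contract of every
  reader and container, not a convention the user can permute.
* Angles: ω is an axis, reported in [0, π), measured counter-clockwise
  from the camera +x axis. Arrays are (y, x, z, channel), 1-based in R.

## 2. Background correction

Strain and misalignment in the optical train produce a slowly varying
background retardance that masks specimen contrast. Correction operates on
the transformed coefficients $\bar m_1 = m_1/m_3$, $\bar m_2 = m_2/m_3$,
in which two weak retarders compose additively:

* **Round 1** subtracts the transformed coefficients of a measured empty
  field-of-view and forms ρ, ω, BF, DOP.
* **Round 2** estimates the *residual* background (what drifted between
  the background acquisition and the measurement) by median-binning each
  background-subtracted coefficient map into blocks (default 32 px at the
  published 2048² field; shrunk automatically so at least 8×8 bins remain
  on small fields) and fitting a full bivariate polynomial of total order
  2, evaluated back at full resolution and subtracted before property
  extraction.

Median binning is what makes round 2 safe in the presence of specimen:
as long as the specimen is a minority within each bin, the median tracks
the background. Two quantifiable biases come with it. First, the block
median of a polynomial equals its bin-centre value only for affine
surfaces; curvature and cross terms pick up an O(bin²·curvature) offset,
harmless at the scales backgrounds vary but the reason the exactness
tests use planes. Second, a minority outlier block shifts the bin median
by at most (within-bin background variation) × (outlier fraction) — zero
on locally constant backgrounds, negligible on realistic slow ones. The tests quantify both sides: ≥10× suppression of a
synthetic low-order residual ramp, and <5% bias on specimen retardance
when the specimen occupies a minority of the field. The converse failure
mode is real and intended: a specimen that majority-fills bins biases the
fit (use `rounds = 1` there).

Two printed formulas required interpretation, resolved by requiring the
noiseless pipeline to invert the forward model exactly (a property the
suite checks at 1e-8 over a dense (t, p, ρ, ω) grid):

* ρ is printed as a one-argument "arctan2" of
  $\sqrt{\bar m_1^2 + \bar m_2^2}$; since that magnitude equals tan ρ,
  `qpli` implements ρ = arctan of the non-negative magnitude, range
  [0, π/2).
* ω is printed as "½ arctan2(m̄₁ − m̄₂)"; the unique inverse consistent
  with $m_1 \propto \sin 2\omega$, $-m_2 \propto \cos 2\omega$ is
  ω = ½·atan2(m̄₁, −m̄₂), mapped into [0, π), with the tie-break ω = 0 at
  m̄₁ = m̄₂ = 0.
* Only m̄₁ and m̄₂ are refit in round 2; BF and DOP keep the
  measured-background normalization (the description of the second round
  mentions only the transformed retardance-bearing coefficients).

Numerical guards: voxels with $|m_3| < 10^{-6}\,\mathrm{median}|m_3|$
(near half-wave retardance, where the m₁/m₃ parameterization is singular)
or $m_0 \le 0$ are flagged invalid and carry NaN; they are excluded from
all statistics. Edge bins smaller than the bin size still contribute their
median; the polynomial fit is unweighted on bin centres scaled to [−1, 1]
for conditioning.

## 3. Weak-object transfer functions and phase retrieval

The brightfield component m₀ encodes phase through defocus. The cited
transfer-function forms are not printed in full, so `qpli` implements the
standard partially coherent weak-object construction directly: with a
circular incoherent source S (radius NA_ill/λ) and a defocused pupil
$P_z$ (radius NA_det/λ), the source–pupil cross-correlation

$$C(u, z) = \sum_{u'} S(u')\, P_z^*(u')\, P_z(u'+u)
\,/\, \sum S |P|^2$$

yields the absorption and phase transfer functions
$H_\mu = -(C(u) + C^*(-u))$ and $H_\phi = i\,(C(u) - C^*(-u))$, sampled on
the FFT grid of the data. This construction is pinned by tests rather than
taken on faith: $H_\phi(0) = 0$ (no contrast from constant phase),
$H_\phi \approx 0$ at exact focus and antisymmetric in z, $H_\mu$ symmetric
with $H_\mu(0,0) = -2$, agreement with the coherent-limit closed form as
NA_ill → 0 (2% RMS), and — the strongest check — agreement with a
brute-force Abbe partially-coherent image simulation of a weak object to
<2% relative RMS. The 3D volumetric transfer function is the z-DFT of the
defocus stack, consistent with treating the z-convolution circularly on
the acquired grid.

**Inverse problems.** For thick specimens (3D), absorption is dropped and
Tikhonov gives the one-step filter
$\hat\phi = \bar H\,\hat g / (|H|^2 + \tau_\phi)$ on
$g = m_0/m_{0,dc} - 1$. For thin specimens (2D), all z-planes jointly
constrain one phase and one absorption layer: per lateral frequency a
2×2 regularized normal system accumulated over z, solved in closed form;
at least two defocus planes are required (one in-focus plane makes phase
unobservable — enforced as an error).

**TV variant.** The anisotropic-TV problem is solved by alternating
minimization with a quadratic splitting: auxiliary variables
$d_i \approx D_i\phi$ (circular forward differences), penalty β
(default 1.0), shrinkage step $d_i = \mathrm{soft}(D_i\phi, \tau/2\beta)$,
and an exact frequency-domain quadratic solve for φ. Each step minimizes
the splitting objective exactly in one block, so the reported objective is
non-increasing — that is the monotonicity the tests assert. With τ → 0 the
Tikhonov/least-squares solution is a fixed point of the iteration, which
is how the "TV limits to Tikhonov" property is tested (one step from the
Tikhonov solution moves it by <1e-4 relative RMS). Defaults: 50 outer
iterations, zero initialization, deterministic (no randomness consumed).

**Parameters and guards.**

* `tau_phase`, `tau_abs`: non-negative regularization weights; no
  published values exist for the figures, so defaults (1e-3) were chosen
  by the simulation properties (noiseless phantom recovery r > 0.9 with
  τφ = 1e-4·max|Hφ|²) and are fully exposed.
* m₀,dc is estimated as the stack mean by default (median or a provided
  constant are options); the definition m₀′ = m₀ − m₀,dc does not state
  the estimator.
* Frequency-domain denominators are floored at 1e-12× their maximum;
  τ = 0 against transfer-function nulls warns and relies on the floor.
* Sign convention: positive φ means larger optical path than the
  surround, so dense structures reconstruct in positive contrast.
* Grids too coarse for the optics (lateral cutoff (NA_det+NA_ill)/λ above
  Nyquist) warn with the supported cutoff.
* Either raw m₀ or the background-normalized BF ratio may be fed to the
  solvers; m₀ is the default.

The method recovers *local* phase variation, not absolute phase: the dc
component is removed by construction and no interferometric reference
exists.

## 4. The phantom simulator: what a green test establishes

`make_phantom()` produces ground-truth maps (t, p, ρ, ω, φ) for four
scenarios — beads (smooth phase inclusions; cells/nucleoli), a phase star
target, radial anisotropic spokes whose slow axis is perpendicular to the
bar (as for myelinated axon tracts), and layered tissue (strata with
varying transmission, a depolarizing layer, slowly varying birefringence).
`render_polarization_stack()` renders five-channel acquisitions through
exactly the package's forward physics: Mueller coefficients per plane,
intensities through A(χ), defocus phase contrast applied to the
brightfield-bearing intensity through the same WOTFs used for inversion,
optional slowly varying instrument background composed additively in
transformed-coefficient space, and optional Poisson shot noise at a stated
photon budget. Defaults were chosen once to be realistic for transmission
microscopy of tissue slices: ρ amplitudes 0.15–0.3 rad, φ ≤ 0.1 rad
(weak-object regime), photon budgets 10²–10⁴ per pixel, background
retardance ~0.02 rad.

The renderer is deliberately the *only* source of forward simulation and
the inversion code never imports from it, so round-trip tests are
meaningful. Two honest caveats about what green tests establish:

* The anisotropy rendering is thin-specimen: retardance composes
  vectorially over z into one effective layer and defocus carries depth
  information only through m₀. A voxel-wise vectorial diffraction model is
  explicitly not attempted, so tests cannot certify depth-resolved
  anisotropy recovery (the method does not claim it either).
* The simulated noise is shot noise plus the additive background model the
  correction assumes. Real acquisitions add LC calibration error, stray
  birefringence varying with z, registration error between channels, and
  camera artifacts; robustness to those is not certified by this suite.

Paired virtual-staining data uses synthetic fluorescence targets defined
as deterministic functions of the ground-truth maps (retardance, positive
phase, or a two-factor mixture) plus optional blur/noise. Networks are
given the orientation as the continuous pair (ωx, ωy) = ρ(cos 2ω, sin 2ω)
rather than the raw angle, which is discontinuous at π. The 70/15/15
train/val/test split floors the val/test sizes and gives the remainder to
train (20 volumes → 14/3/3); membership is a seeded permutation and
volumes are never shared across splits.

## 5. The residual U-Nets and how the architecture was pinned

Three variants share the block grammar: encoder blocks of two
(convolution → ReLU → batch-norm) repeats with a residual connection from
block input to output, skip concatenations into a decoder that upsamples
by bilinear interpolation, and a single convolution (no activation) as the
output block. Encoder filters are 16/32/64/128/256 (2D, 2.5D) or
16/32/64/128 (3D).

The published description leaves several details unprinted: the decoder
block structure, how residual connections cross channel-count changes, and
the exact z-extent of the 2.5D encoder kernels. The three published
parameter counts (2.0 M, 4.8 M, 1.5 M at two significant figures,
single-channel) are tight constraints; enumerating the design space showed
that the only convention consistent with all three *and* with the printed
downsampling text is:

* residual connections use a 1×1 projection convolution when the channel
  count changes (and identity otherwise), in encoder and 2D/3D decoder;
* 2D downsampling is a full 2×2 stride-2 convolution and 3D a 3×3×3
  stride-2 convolution, as printed; the 2.5D variant downsamples with
  parameter-free N×2×2 average pooling, as printed;
* 2D/3D decoder blocks use a *single* conv-ReLU-BN repeat (with residual);
  the 2.5D decoder uses two repeats without residual;
* 2.5D encoder convolutions are 3×3×3 with same-padding in z (an N×3×3
  encoder at N = 5 alone exceeds 5.8 M parameters, contradicting the
  printed 4.8 M), with the printed N×1×1 valid convolutions collapsing z
  on every skip path including the bottleneck.

This yields 1,965,681 / 4,801,393 / 1,488,433 trainable parameters →
2.0 / 4.8 / 1.5 M. "Trainable" counts convolution weights and biases plus
batch-norm scale/shift; running statistics are excluded. The counts are
recomputed from the actual allocated weight arrays, not from a formula.

Training follows the published recipe: Adam, L1 loss (optionally masked to
foreground pixels), triangular cyclic learning rate between 5e-5 and 6e-3
(half-cycle 2 epochs — only the bounds are published), early stopping
after 20 epochs without validation improvement, minimal-validation-loss
checkpointing, batch sizes 64/16/4 by variant. Inference is fully
convolutional on whole XY planes for 2D/2.5D (reflect-padded to the
encoder-depth multiple, cropped back; the 2.5D N-window slides along z
with reflect padding so output z-extent equals input), and XY-tiled with
32 px overlap and linear blending for 3D. Blend weights ramp linearly
across overlaps and are normalized to an exact partition of unity.

Everything runs on CPU in base R (im2col/offset-sum convolutions over
BLAS); there is no GPU path. Consequently the suite trains only tiny
variants (filters 4/8/16, 16×16 tiles) and asserts *directions* — a tiny
2.5D model overfits a synthetic retardance target to <5% of its initial
loss within 100 epochs; multi-channel input beats single-channel on a
two-factor target (5-seed median); a z-window helps when the target lives
off the centre slice — never the published full-scale correlation values,
which required GPU-weeks and external data and are out of scope here.

## 6. Evaluation metrics

Pearson r and SSIM per XY slice, per XZ slice, and per volume, median
aggregated, with per-slice distributions retained for export. SSIM uses a
uniform 7-wide window (7×7×7 for volumes), c₁ = (0.01 L)², c₂ = (0.03 L)²,
unbiased variance/covariance, mean over fully contained windows — the
convention of the common reference implementations, and the suite checks
agreement with an in-repo brute-force per-window implementation to 1e-6.
L defaults to the *target's* dynamic range per dataset. Since SSIM is
scale-sensitive, predictions must be mapped back to the original intensity
scale before scoring (the prediction path does this automatically when
normalization statistics are attached); Pearson is affine-invariant, and
the contrast between the two behaviours is itself a test. Zero-variance
inputs raise errors rather than returning NaN; zero-variance slices are
skipped and counted in the report. Foreground masks come from Otsu
thresholding (bimodal histograms) or Rosin's unimodal corner rule (256
bins over the data range). Whether the published table metrics were
computed on masked or whole slices is not stated; whole-slice is the
default and masked computation is a flag.

## 7. Known limitations

* Thin-specimen polarization rendering (see §4); no 3D anisotropy
  reconstruction.
* The weak-object linearization breaks down beyond φ ≈ 0.5 rad or strong
  absorption; the simulator stays in the validated regime (φ ≤ 0.1).
* z-convolution is circular on the acquired grid; very thick specimens
  with structure near the stack boundary alias in z.
* The LC swing χ and the regularization weights used for the published
  figures are unreported; defaults here are justified by simulation, not
  by matching figures.
* CPU-scale training only; the architecture is faithful but throughput is
  orders of magnitude below a GPU framework.
* The two-round background correction assumes the specimen is a minority
  of every median bin; dense specimens should use one round.
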