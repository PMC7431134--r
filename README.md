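# qpli — quantitative polarized-light imaging and virtual staining

`qpli` reconstructs the physical contrasts of a transparent specimen —
**phase** φ, **retardance** ρ, **slow-axis orientation** ω, **brightfield**
BF, and **degree of polarization** DOP — from five-state
polarization-resolved brightfield z-stacks acquired with a liquid-crystal
(LC) universal polarizer, and translates those label-free contrasts into
fluorescence-like predictions with a multi-channel residual U-Net. It is
aimed at microscopists and computational imaging researchers who want a
self-contained, CPU-only reference implementation of this reconstruction +
virtual-staining pipeline, testable end to end on synthetic phantoms
without any microscope data.

## The model

**Polarization.** The specimen is a weakly scattering linear retarder with
transmission *t*, depolarization *p*, retardance ρ and slow axis ω. The
retrievable Mueller coefficients are

```
m = ( t,  t p sin 2ω sin ρ,  −t p cos 2ω sin ρ,  t p cos ρ )
```

The microscope illuminates with right-circular plus four elliptical states
(ellipticity set by the LC retardance χ) and detects through a left-circular
analyzer, so the five measured intensities are `I = A m` with the 5×4
instrument matrix `A = A(χ)`. `qpli` inverts this per voxel by least squares
(`invert_intensities()`), applies a measured-background correction and an
optional second round that fits a 2-D polynomial surface to median-binned
transformed coefficients (`correct_background()`), and extracts

```
ρ = arctan √(m̄₁² + m̄₂²),   ω = ½ atan2(m̄₁, −m̄₂),   BF = m₀ˢᵐ/m₀ᵇᵍ,   DOP = DOPˢᵐ/DOPᵇᵍ
```

**Phase.** The brightfield component m₀ carries defocus phase contrast.
`qpli` evaluates the partially coherent weak-object transfer functions
(WOTF) numerically from the source–pupil cross-correlation
(`transfer_functions()`) and solves the regularized deconvolution

```
min_φ Σ‖m₀′ − hφ ⊗ φ‖² + τφ·Reg(φ),   Reg = ‖φ‖² (Tikhonov) or anisotropic TV
```

in 3D (`reconstruct_phase_3d()`) or jointly with absorption for thin
specimens (`reconstruct_phase_2d()`).

**Virtual staining.** 2D / 2.5D / 3D residual U-Nets (built from scratch in
base R, BLAS-backed) translate the label-free channel stack
(BF, φ, ρ, ωx = ρcos2ω, ωy = ρsin2ω) into a fluorescence prediction:
Adam, L1 loss, cyclic learning rate in [5e-5, 6e-3], early stopping on
validation loss, per-dataset foreground median/IQR normalization, and tiled
inference with linear blending. The single-channel variants have 2.0 M
(2D), 4.8 M (2.5D, N=5) and 1.5 M (3D) trainable parameters.

A phantom simulator (`make_phantom()`, `render_polarization_stack()`)
renders ground-truth maps through the same forward physics (plus optional
instrument background fields and Poisson shot noise), so every claim above
is tested end to end in this repository.

## Worked example

```r
library(qpli)

opt <- optics_config(wavelength = 0.532, na_detection = 0.55,
                     na_illumination = 0.4, pixel_size = 0.2, z_step = 0.5)

## a birefringent spoke target in a slightly strained mount, 10^4 photons
ph   <- make_phantom("spokes", shape = c(128, 128, 1),
                     params = list(n_bars = 6, rho_amp = 0.3, bar_width = 3,
                                   r_inner = 20, r_outer = 60), seed = 7)
rend <- render_polarization_stack(ph, background = list(rho = 0.02, omega = pi/3),
                                  photon_budget = 1e4, seed = 7)

A     <- instrument_matrix(chi = 0.06 * pi)
props <- correct_background(invert_intensities(rend$sample, A),
                            invert_intensities(rend$background, A), rounds = 2)
median(props$retardance[ph$rho_map > 0])        # 0.3009 rad (truth 0.300)
median(abs(props$retardance[ph$rho_map == 0]))  # 0.00587 rad residual background

## 3D phase from the brightfield stack of a bead phantom
ph3  <- make_phantom("beads", c(64, 64, 8), params = list(n = 5, phi_amp = 0.1), seed = 2)
tf   <- transfer_functions(opt, c(64, 64, 8), mode = "3D")
m0   <- forward_brightfield(ph3$phi_map, tf)
phi  <- reconstruct_phase_3d(m0, tf, reg_config(tau_phase = 1e-4 * max(Mod(tf$h_phase3)^2)))
pearson(phi, ph3$phi_map)                       # 0.995

## the translation models and their published parameter counts
count_parameters(build_model(model_spec("2D")))                 # 1,965,681  -> 2.0 M
count_parameters(build_model(model_spec("2.5D", n_slices = 5))) # 4,801,393  -> 4.8 M
count_parameters(build_model(model_spec("3D")))                 # 1,488,433  -> 1.5 M
```

The retardance comes back at the ground-truth 0.3 rad on the spokes with a
~6 mrad residual floor off the spokes (shot noise at this photon budget),
the slow axis is perpendicular to each bar as constructed, and the phase
volume correlates with the ground truth at r = 0.995.

## Command line

Every pipeline stage is also a CLI sub-command driven by a JSON config
(flags override file values; one seeded generator drives all randomness):

```sh
Rscript -e 'qpli::qpli_cli()' simulate    --config sim.json  --out runs/sim  --seed 7
Rscript -e 'qpli::qpli_cli()' reconstruct --config rec.json  --out runs/rec
Rscript -e 'qpli::qpli_cli()' phase       --config phase.json
Rscript -e 'qpli::qpli_cli()' train       --config train.json
Rscript -e 'qpli::qpli_cli()' predict     --config pred.json
Rscript -e 'qpli::qpli_cli()' evaluate    --config eval.json
```

Each run writes its resolved config, a structured log, and TIFF/CSV
artifacts into the output directory; reruns with the same config and seed
are bitwise identical.

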