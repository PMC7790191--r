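# cilialign

Motile cilia on multiciliated epithelia — the motivating system is ependymal
cells lining the brain ventricles — beat in a common direction and drive
fluid flow along the tissue surface. The beating direction is itself
flow-sensitive: an external shear stress of the same magnitude that cilia
themselves generate (~0.02–0.8 dyne/cm²) can reorient it, and densely
ciliated tissue reorients less readily than sparse tissue because
neighbouring cilia hydrodynamically screen each other from the external
flow.

`cilialign` is an R package for both halves of this problem, aimed at
quantitative cell biologists and biophysicists:

* **Measurement** — an image-analysis pipeline that turns a high-speed
  bright-field movie and a tracer (fluorescence) movie of the same field of
  view into per-cell records of position, ciliary beat frequency (CBF) and
  beating direction, plus culture-level statistics.
* **Model** — a slender-body-theory (SBT) Stokes solver for arrays of
  tilted rigid rods above a no-slip wall, and a torsional-spring torque
  balance predicting the equilibrium beating angle.

Synthetic-data generators with exact ground truth (planted frequencies,
von Mises–distributed directions, saturating dose-response curves) support
end-to-end recovery testing of every stage.

## The core quantities

For `N` boxes (≈ cells) with unit beating directions `p̂ᵢ` (inferred from
the cilia-driven flow via PIV) and applied-flow direction `ê`:

    Φ = (1/N) Σᵢ p̂ᵢ · ê                       alignment parameter (1 = aligned, 0 = random)
    V̄ = (1/N) Σᵢ vᵢ · ê                       net cilia-driven flow (µm/s)
    ρ = N_box / N_tot,  ρ_cell = ρ / A_box    ciliated area fraction, cells/mm²
    τ(x) = 6ηQ / (h² w(x))                    tapered-channel wall shear (dyne/cm²)
    Φ(τ) = 1 − exp(−τ/τ_c)                   dose response; τ_c = critical shear stress

On the model side, each cilium is coarse-grained (from its beat pattern
ψ(s,t)) into a rigid rod of length L = 1, radius r = 0.02, tilted 53° toward
its beating direction, its base 0.05 above a no-slip wall. In a unit shear
flow at angle θ to the beating direction the rod feels a hydrodynamic
z-torque `T(θ, ρ)` (non-dimensionalised by ηγ̇L³), computed by SBT with a
Blake image system. A linear torsional spring `T_el = k(π/2 − θ)` resists
reorientation; the equilibrium angle `θ*` solves `T(θ*, ρ) = k(π/2 − θ*)`
and yields the model alignment `Φ = cos θ*` as a surface over density and
stiffness.

## Worked example

Analyse a synthetic field of view with known ground truth:

```r
library(cilialign)

spec   <- synthetic_field_spec(fov_px = 256, n_cells = 12, kappa = 4, seed = 11)
layout <- make_field(spec)
bf  <- render_bf_movie(layout)        # 800 frames at 160 fps
fl  <- render_tracer_movie(layout)    # 100 frames at 10 fps, 1 µm beads
fov <- analyze_fov(bf, fl)

head(fov$records, 3)
#>   box_i box_j x_um y_um cbf_hz  vx_um_s    vy_um_s        px         py
#> 1     1     5 34.2  3.8   23.4 3.925646  2.2391115 0.8686351  0.4954524
#> 2     1     6 41.8  3.8   23.4 3.050889  1.5526208 0.8912291  0.4535534
#> 3     2     3 19.0 11.4   17.2 1.642266 -0.3805622 0.9741857 -0.2257481

alignment_parameter(fov$records, e_hat = c(1, 0))
#> Alignment: Phi = 0.918
#>   net flow 3.19 um/s along e_hat; N = 15 boxes (0 excluded)
planted_alignment(4)      # expected Phi for von Mises kappa = 4
#> [1] 0.8635226
```

Each record is one 32-px (7.6 µm) interrogation box containing a segmented
beating cell: its mean beat frequency in Hz, its cilia-driven flow vector in
µm/s, and the unit beating direction. `Φ = 0.918` against a planted
expectation of 0.864 (n = 15 boxes) shows the direction recovery; the
per-cell CBFs match the planted frequencies to the 0.2 Hz spectral bin.

Shear-stress bookkeeping and the dose-response fit:

```r
g <- channel_geometry(q_mm3_s = 8.3)   # 1 mm -> 5 mm taper over 7 mm, h = 1 mm
shear_profile(g, c(0, 7))
#> [1] 0.398 0.080                       # dyne/cm^2: 5x entrance/exit ratio

d <- make_dose_dataset(exp(seq(log(0.02), log(0.8), length.out = 30)),
                       tau_c = 0.1, noise_sd = 0.05, seed = 42)
fit_dose_response(d$tau, d$phi, n_boot = 500, seed = 1)
#> Dose-response fit: tau_c = 0.09814 dyne/cm^2 (68% CI 0.09291 - 0.1028)
#>   Phi at tau_c: 0.632; n = 30 points
```

The hydrodynamic model, from isolated rod to alignment surface:

```r
t0 <- isolated_rod_torque(theta = pi / 2)   # reference torque, ~0.599
tab <- screening_sweep(                      # T(theta, rho) / T0 on a lattice
  d_perp_list = c(0.08, 0.16, 0.24, 0.32, 0.40),
  theta_grid  = c(0, pi / 8, pi / 4, 3 * pi / 8, pi / 2),
  config      = rod_array_config(n_rows = 9, n_cols = 9))
surf <- phi_surface(tab, k_grid = c(0, 0.05, 0.1, 0.2, 0.4))
```

The screening table shows the torque on a cilium in a dense array falling
monotonically with ciliated area fraction — roughly halved at ρ ≈ 0.1 —
and the alignment surface shows Φ decreasing with both anchoring stiffness
and density: densely packed cilia are shielded from the external flow.

The methods vignette (`vignettes/cilia-alignment-methods.Rmd`) documents the
models, defaults, numerical choices and limitations.

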