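---
title: "Quantifying cilia beating alignment with shear flow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cilia beating alignment with shear flow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Multiciliated cells — ependymal cells lining the brain ventricles are the
motivating system — beat their cilia in a common direction and thereby drive
fluid flow along the tissue surface. That beating direction is itself
sensitive to flow: an external shear can reorient it. `cilialign` implements
the two halves of a quantitative treatment of this feedback: an
image-analysis pipeline that measures per-cell beat frequency and beating
direction from microscopy movies, and a hydrodynamic model that explains why
densely ciliated tissue aligns less readily than sparse tissue.

This vignette records the models, the defaults and their units, the numerical
choices, and what the synthetic-data tests do and do not demonstrate.

## The movie pipeline

One field of view is characterised by two recordings: a high-speed
bright-field stack of the beating cilia (nominally 160 frames/s for 5 s) and
a slower fluorescence stack of 1 µm tracer beads advected by the cilia-driven
flow (10 frames/s for 10 s). The pipeline (`analyze_fov()`) proceeds:

1. **Activity map** (`activity_std_map()`): the per-pixel temporal standard
   deviation of intensity, min–max normalised. Beating cilia flicker;
   background does not.
2. **Mask** (`otsu_mask()`): Otsu's threshold (256-bin histogram, maximal
   between-class variance) separates active from inactive pixels.
3. **Beat frequency** (`pixel_cbf()`): for each masked pixel, the frequency
   of the highest magnitude-spectrum peak within 1–50 Hz (DC excluded). The
   spectral resolution is `frame_rate / n_frames` — 0.2 Hz at the nominal
   acquisition. Pixels whose peak is less than 5 times the median in-band
   magnitude are flagged low-confidence.
4. **Segmentation** (`segment_ciliated_cells()`): 8-connected region growing
   over validated pixels, accepting a neighbour only while the component's
   frequency standard deviation stays at or below `sigma_f`. The default
   `sigma_f = 1 Hz` sits above the spectral resolution and below typical
   between-cell frequency differences; components under 20 px are dropped as
   speckle.
5. **PIV** (`piv()`): the tracer stack is tiled with non-overlapping 32 px
   interrogation boxes (7.6 µm at the default 0.2375 µm/px), matching one
   box to roughly one cell. Every consecutive frame pair is cross-correlated
   per box (FFT, normalised); the peak, refined by a 3-point Gaussian fit,
   gives the displacement. By default the correlation planes are
   ensemble-averaged over all frame pairs before the peak is located. For a
   steady flow seeded with a realistic tracer density this is markedly more
   robust than averaging per-pair displacement vectors (also available via
   `average = "displacement"`): single-pair correlation peaks from ~10
   particles per box are noisy, and the stationary-background peak can win.
6. **Records** (`cells_to_boxes()`): a box becomes a cell record when at
   least 10% of its pixels belong to a segmented cell; the record carries
   the box's mean beat frequency, its PIV velocity (µm/s) and the unit
   beating direction inferred from the flow, following the standard
   assumption that cilia-driven flow points along the beating direction.

Bright-field and tracer stacks are different imaging modalities, so
mean-frame cross-correlation between them is not a meaningful registration
check; `estimate_drift()` is provided for same-modality drift estimation and
`analyze_fov(check_drift = TRUE)` enforces a 2 px limit when the caller
knows the check applies. The synthetic fixtures share no texture between the
two movies, so the pipeline tests run with the check off.

## Culture-level statistics

With per-cell unit directions $\hat p_i$ and velocities $v_i$, and the
(previously applied) flow direction $\hat e$:

* alignment parameter $\Phi = \frac{1}{N}\sum_i \hat p_i \cdot \hat e$
  (`alignment_parameter()`): 1 when all cells beat along the flow, 0 for
  random orientations. The mean-projection form is used; the magnitude of
  the mean direction vector is available behind `method = "vector_mean"`.
* net flow $\bar V = \frac{1}{N}\sum_i v_i \cdot \hat e$ in µm/s.
* density: from $N_{box}$ ciliated boxes among $N_{tot}$,
  $\rho = N_{box}/N_{tot}$ (area fraction) and
  $\rho_{cell} = \rho / A_{box}$ in cells/mm² (`density_metrics()`).
* tapered channel: a channel of height $h$ whose width opens linearly from
  $w_0$ carries wall shear $\tau(x) = 6\eta Q / (h^2 w(x))$
  (`shear_profile()`, dyne/cm²); the default geometry (1 mm → 5 mm over
  7 mm) spans a five-fold stress range in a single chip. The near-wall
  stress of a measured flow is $\tau_0 = \eta V / h$
  (`wall_shear_from_flow()`). The medium viscosity defaults to 0.8 mPa s
  (culture medium at 37 °C) and is echoed in outputs.
* dose response: $\Phi(\tau) = 1 - e^{-\tau/\tau_c}$ fitted by nonlinear
  least squares (`fit_dose_response()`). The single parameter makes the SSE
  profile amenable to Brent minimisation on $\log\tau_c$, which is fast and
  has no starting-value failure mode. At $\tau = \tau_c$ the fitted curve is
  $1 - e^{-1} \approx 0.632$, the natural "significant alignment"
  threshold. Confidence intervals are case-resampling bootstrap
  percentiles (68% by default): with ~30 heteroscedastic points an
  asymptotic interval would lean on linearisation that the saturating curve
  does not support.

## Coarse-graining the beat into a tilted rod

A planar beat is stored as the tangent-angle profile $\psi(s, t)$ on an
arclength × phase grid (`beat_pattern()`), with $z(s,t) \ge 0$ enforced.
Averaging the unit tangent $(\cos\psi, \sin\psi)$ uniformly over arclength
and phase (`mean_tangent_angle()`) gives the mean-tangent direction; for
mature ependymal beat patterns this sits at about 53° elevation, leaning
toward the power stroke, and that angle is the default tilt of the rigid-rod
proxy used in the hydrodynamic model. Averaging the tangent *vector* rather
than the tangent *angle* is the default because the mean vector is what the
rod axis replaces; angle-averaging is available for comparison.

`swept_summary()` reduces a beat to the geometry the array model needs. The
stroke-extreme angles are the minimum base-to-tip chord elevations on either
side of the base — the maximum tilts the cilium reaches during the power and
recovery strokes (23° and 18° for the ependymal pattern; the parametric
generator `make_beat_pattern()` can be calibrated to any pair with
`calibrate_beat_extremes()`). A rigid rod of length $L$ at elevation $\beta$
reaches $L\cos\beta$ horizontally, so the beat envelope spans
$d_\parallel^{min} = L(\cos 23^\circ + \cos 18^\circ) \approx 1.87 L$ along
the beating direction. Because the beat is planar, the envelope is one
cilium diameter across laterally, $2r = 0.04 L$, and the per-cilium top-view
footprint defaults to $A_{top} = d_\parallel^{min} \times 0.04 \approx
0.075\,L^2$. The *clearance* between neighbouring cilia perpendicular to the
beat is two body widths, $d_\perp^{min} = 0.08$, so that beat planes cannot
collide. Both widths are arguments, not constants: with the lateral
footprint at one body width, the standard spacing sweep
$d_\perp = 0.08 \ldots 0.40$ maps to area fractions $\rho = 0.5 \ldots 0.1$,
which brackets the ciliated area fractions measured in maturing (≈0.09) and
mature (≈0.17) cultures — the comparison the screening analysis needs. Had
the footprint been taken two body widths across, $\rho \approx 0.1$ would
fall outside the swept spacings entirely.

## Slender-body hydrodynamics with a wall

Cilia-scale flow is Stokes flow. Each cilium is coarse-grained as a static
rigid rod ($L = 1$, $r = 0.02$) tilted 53° toward its beating direction
$\hat e$, its base held 0.05 above a no-slip wall (the offset avoids the
slender-body kernel's wall singularity). The imposed flow is a unit shear
$u_\infty = \dot\gamma z\,\hat y$; $\theta$ is the angle between $\hat e$
and $\hat y$.

`solve_force_density()` discretises each rod into $M$ centreline nodes
(segment midpoints, default $M = 24$) carrying an unknown force density
$g(s)$ and enforces zero total velocity at every node:

* the local slender-body operator
  $[c(I + \hat t\hat t) + 2(I - \hat t\hat t)]\,g / 8\pi\eta$ with
  $c = -\ln(\epsilon^2 e)$ and slenderness $\epsilon = r/L$;
* non-local free-space Stokeslet interactions along and between rods, with
  the standard same-rod local subtraction;
* a Blake image system (image Stokeslet, doublet and source-doublet at the
  reflected points) that cancels every Stokeslet on the wall by
  construction. Tests verify the residual wall velocity is below
  $10^{-6}\dot\gamma L$ (in practice it is at machine precision).

The hydrodynamic torque about the vertical axis through each base
(`rod_torque_z()`, non-dimensionalised by $\eta\dot\gamma L^3$) is the
quantity that can reorient the beating direction. For an isolated rod at
$\theta = \pi/2$ the solver gives $T_0 = 0.599$, stable to under 2% between
$M = 16$ and 32; published slender-body treatments of this geometry report
0.55, and the ±15% band documented for that comparison reflects legitimate
freedom in the image formulation and local-operator constant, not a
convergence problem. The free-space perpendicular drag agrees with the
resistive-force-theory closed form $C_\perp = 4\pi\eta/(\ln(2/\epsilon) +
1/2)$ within 16%, the expected size of the $O(1/\ln\epsilon)$ difference.

`screening_sweep()` assembles the screening table $T(\theta, \rho)/T_0$ over
arrays. Defaults follow the array model: a 9×9 lattice (the reported torque
is the all-rod average; lattice size is configurable and the 5×5 table used
for the alignment surface reproduces the same trends), $d_\parallel$ at its
minimum (increasing it changes torques by well under 5%, so the
perpendicular neighbours dominate, as expected from their smaller
separation), and $d_\perp$ swept over 0.08–0.40. Torques fall monotonically
with density: at $\rho \approx 0.1$ the average torque is roughly half the
isolated value, and at $\rho \approx 0.2$ it is smaller still — hydrodynamic
screening strong enough to explain why mature (denser) cultures need about
twice the shear stress to align.

Solver costs are dominated by the dense linear solve ($3MN_r$ unknowns).
The test suite uses $M = 16$ for array sweeps (per-solve torque within 2% of
$M = 32$) and $M = 24$ for single-rod references; a 9×9 sweep point takes a
few seconds on one core.

## Torque balance and the alignment surface

The anchoring of cilia (the apical actin network, phenomenologically) is
modelled as a linear torsional spring with rest angle $\pi/2$ — beating
initially perpendicular to the flow, the orientation with maximal
hydrodynamic torque. The restoring torque is $T_{el} = k(\pi/2 - \theta)$,
zero at rest and maximal at full alignment; $k$ shares the
$\eta\dot\gamma L^3$ torque scale. The equilibrium beating angle $\theta^*$
solves $T(\theta^*, \rho) = k(\pi/2 - \theta^*)$ (`equilibrium_angle()`):
the sampled torque curve is interpolated with a monotone piecewise-cubic
spline (Hyman filtering; overshoot would fabricate crossings) and the root
is found by bisection to $10^{-10}$ rad. Edge cases: $k = 0$ aligns fully
($\theta^* = 0$); if the spring dominates everywhere the boundary solution
$\theta^* = \pi/2$ is returned flagged; a non-monotone curve with several
crossings returns the smallest root with a warning. The alignment surface
$\Phi(\rho, k) = \cos\theta^*$ (`phi_surface()`) is 1 along $k = 0$ and
non-increasing in both stiffness and density: stiffly anchored or densely
packed cilia align less. Every tabulated equilibrium is cross-checked in the
tests against a $10^4$-point brute-force scan of the same torque balance.

## What the synthetic data emulate — and what they do not

`make_field()` plants non-overlapping disc "cells" with beat frequencies
$\mathcal N(22, 3^2)$ Hz and beating directions drawn von Mises around the
flow direction; the concentration $\kappa$ fixes the expected alignment
exactly, $E[\Phi] = I_1(\kappa)/I_0(\kappa)$, which is what end-to-end
recovery is judged against. `render_bf_movie()` oscillates cell pixels with
independent random phases over Gaussian read noise; `render_tracer_movie()`
advects beads through a superposition of per-cell flow kernels (Gaussian,
width 1.3 cell radii) with Brownian jitter of 1.2 px/frame — the
Stokes–Einstein displacement of a 1 µm bead over a 0.1 s frame — and
resamples 8% of beads per frame to mimic exchange through the focal plane.
The resampling matters: the planted 2-D flow field is compressible, and
without exchange tracers pile up at stagnation zones within a few seconds,
which a real 3-D incompressible flow does not do. Tracer density defaults to
10 beads per interrogation box.

Problem sizes used by the recovery tests, chosen to keep the suite
desk-scale while preserving the nominal acquisition physics: frequency
recovery runs on a 256 px, 12-cell field at the full 800 frames (0.2 Hz
bins); alignment and record-count recovery on a 704 px, 100-cell field
(192 bright-field frames, 40 tracer frames) whose ~120 records match the
100–400 cells per field of view typical of real cultures; the
critical-shear study runs 500 replicates of 30 log-spaced stresses in
0.02–0.8 dyne/cm² at noise 0.05 with planted $\tau_c \in \{0.05, 0.1\}$.
Log spacing reflects how dose-response designs cover a stress range
spanning over an order of magnitude; it also spreads information across
points, where a linear grid concentrates the fit in its two or three
smallest stresses and degrades resampling-based intervals.

The generators do not emulate: photorealistic cilia texture, 3-D flow or
particle defocus, metachronal phase structure, cell-shape irregularity, or
optical aberrations. Passing recovery tests therefore demonstrates the
correctness of the estimators under the stated noise models, not robustness
to every artefact of real microscopy. Conversely the quantities with
physical content — torques, screening, the alignment surface, the shear
formulas — do not depend on the generators at all.

## Known limitations

* The rods are static: time-resolved beating, metachronal coordination and
  flexible-filament elasticity are outside the model, which captures the
  beat only through its mean-tangent tilt and swept footprint.
* The lattice is finite and open (no periodic images); the all-rod average
  over a 9×9 array stands in for the infinite-carpet torque.
* The torsional spring is phenomenological; its stiffness is not derived
  from actin mechanics, only the equilibrium it implies is computed.
* Real alignment measurements carry biological variability (per-cell flow
  strength, cell shape, maturation stage) that enters the synthetic model
  only through direction and frequency dispersion.
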