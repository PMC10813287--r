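---
title: "An anisotropic hyperelastic model for colorectal tissue: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An anisotropic hyperelastic model for colorectal tissue: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonmech)
```

## The constitutive model

Colorectal tissue is a layered, fiber-reinforced soft tissue: markedly
stiffer circumferentially than longitudinally, nonlinear, and essentially
incompressible over physiological strains. `colonmech` models it as a Yeoh
isotropic matrix reinforced by two in-plane fiber families:

$$\Psi = \sum_{i=1}^{3} a_i\,(\bar I_1-3)^i
      + \sum_{j=2}^{4} c_j\,(\bar I_4-1)^j
      + \sum_{k=2}^{4} e_k\,(\bar I_6-1)^k$$

with $\bar I_1 = \operatorname{tr}\bar{\mathbf C}$ and the fiber
pseudo-invariants $\bar I_4 = \mathbf a\cdot\bar{\mathbf C}\mathbf a$,
$\bar I_6 = \mathbf g\cdot\bar{\mathbf C}\mathbf g$, the squared stretches
along the two families. The undeformed fiber directions
$\mathbf a = (\cos\beta_1, \sin\beta_1, 0)$ and
$\mathbf g = (\cos\beta_2, \sin\beta_2, 0)$ lie in the
circumferential–longitudinal plane; $\beta$ angles are stored in degrees
and measured from the circumferential axis. The polynomial orders are fixed
(isotropic powers 1–3, fiber powers 2–4), giving eleven parameters in
total: nine stress-like coefficients in Pa and two angles.

### Uniaxial stress in closed form

Under incompressible uniaxial tension at stretch $\lambda$ the transverse
stretches are $\lambda^{-1/2}$, so
$\bar{\mathbf C} = \mathrm{diag}(\lambda^2, \lambda^{-1}, \lambda^{-1})$
for circumferential loading (and the obvious permutation for longitudinal).
Incompressibility introduces a hydrostatic pressure $p$, which is
eliminated by the traction-free transverse condition. Writing
$\tilde S_{ii} = 2\,\partial\Psi/\partial\bar C_{ii}$, the condition
$S_{33} = -p\,C^{-1}_{33} + \tilde S_{33} = 0$ gives
$p = \lambda\,\tilde S_{33}$ (the transverse entry of $\mathbf C^{-1}$ is
$\lambda$), and substitution into the axial component yields

$$S_{\text{axial}} = \tilde S_{\text{axial}} - \tilde S_{33}\,\lambda^{-3},
\qquad
\sigma = \lambda^2 S_{\text{axial}}, \qquad
P = \lambda\, S_{\text{axial}},$$

with $\sigma$ the Cauchy (true) stress and $P$ the engineering stress.
Because both fiber families are planar, $\tilde S_{33}$ is purely
isotropic. An alternative elimination with denominator $3\lambda^3$
circulates in some accounts of this model; we re-derived the condition
above and found that only the $\lambda^{-3}$ form is consistent with the
pressure-elimination recipe and with reported colorectal stress levels, so
it is the default. The alternative remains available as
`legacy_denominator = TRUE` in `uniaxial_stress()` for sensitivity
analysis, and users comparing against other implementations should check
which convention those use.

### Numerical conventions

* **Power-zero convention.** The $i=1$ isotropic derivative term contains
  $(\bar I_1-3)^0$, which is defined as 1 at the reference state so the
  first Yeoh term behaves as a neo-Hookean term and the model reduces to
  known closed forms.
* **Exact stress-free reference.** The invariant differences
  $\bar I_1 - 3$, $\bar I_4 - 1$, $\bar I_6 - 1$ are computed in difference
  form (e.g. $\cos^2\beta\,(C_{11}-1) + \sin^2\beta\,(C_{22}-1)$) rather
  than by subtracting 1 from the assembled invariant, so the stress at
  $\lambda = 1$ is exactly zero in floating point, not merely small.
* **No tension-only switch by default.** The fiber sums start at power 2,
  so fiber contributions vanish smoothly (value and slope) at
  $\bar I_4 = 1$ and the energy is well defined for mildly compressed
  fibers; the polynomial is therefore evaluated as written. A
  `tension_only` flag is available for users who want a hard fiber
  recruitment cutoff, default off.
* **Angles** are stored and reported in degrees and converted internally;
  `canonicalize()` removes the label-switching degeneracy (families are
  interchangeable and $\beta$ and $\beta \pm 180^\circ$ give the same
  pseudo-invariant) by wrapping angles into $[0^\circ, 180^\circ)$ and
  ordering $\beta_1 \le \beta_2$.

The analytic stress path is verified in the test suite against an
independent oracle that differentiates the summed energy numerically and
solves the traction-free condition for the Lagrange multiplier with a root
finder, over random parameter sets and stretches from 0.9 to 1.3.

## Parameter identification

Fitting both orientations with one parameter set is a genuinely
two-objective problem: the normalized errors

$$E_c = \frac{\sum_l (\sigma^e_{c,l}-\sigma^m_{c,l})^2}{\sum_l (\sigma^e_{c,l})^2},
\qquad
E_t = \frac{\sum_q (\sigma^e_{t,q}-\sigma^m_{t,q})^2}{\sum_q (\sigma^e_{t,q})^2}$$

trade off against each other because the tissue is much stiffer
circumferentially. `fit_material()` minimizes $(E_c, E_t)$ with an elitist
non-dominated-sorting genetic algorithm (NSGA-II style: fast non-dominated
sort, crowding distance, binary tournament, simulated binary crossover,
polynomial mutation), returns the final Pareto front, and selects the
*balanced* solution as the member minimizing $\max(E_c, E_t)$, with ties
broken by smaller $E_c + E_t$ and then input order. Minimax with explicit
tie-breaks was adopted because "the most balanced errors" needs a
reproducible definition.

Defaults and their rationale:

| setting | default | why |
|---|---|---|
| population | 200 | converges on synthetic recovery in minutes on one CPU |
| generations | 300 | as above; the front stabilises well before this |
| coefficient bounds | $\pm 10^7$ Pa | two orders of magnitude around colorectal stiffness scales |
| angle bounds | $[0^\circ, 180^\circ)$ | the full non-degenerate range |
| objective stress | engineering | tensile curves are conventionally reported as engineering stress; a `"true"` mode exists because comparisons against Cauchy-stress outputs are also common |
| aggregation | pooled points | every specimen sample point enters the sums directly; a `mean_curve` mode averages specimens per strain first, for workflows built on averaged curves |

Neither aggregation mode is privileged on scientific grounds; with the
noise model used by the synthetic generator the pooled mode uses more
information, while the mean-curve mode mirrors analyses that publish
averaged curves. The whole-population objective evaluation is a single
block of dense matrix arithmetic, so a 200 x 300 run costs seconds, and
every stochastic step derives from the `seed` in `fit_config()` — no
global random state is consumed or perturbed.

The search space is deliberately overparameterized (higher-order
coefficients of either sign, two free angles), so distinct parameter sets
can produce nearly identical uniaxial curves. Recovery is therefore judged
in curve space — by $(E_c, E_t)$ of the recovered solution — not by
coefficient-wise distance. The packaged reference coefficients
(`colorectal_params()`) are treated the same way: they are a fixture for
verifying the forward model against reported stress levels, not a fitting
target the GA is expected to reproduce coefficient by coefficient.

## The synthetic-data generator

The generator exists so the identification and processing pipelines are
testable end to end without laboratory data. It emulates:

* **Specimen geometry** (`sample_geometry()`): dimensions drawn from
  truncated normal distributions matching the reported per-orientation
  means and standard deviations of fresh porcine colorectal specimens —
  die-cut 20 mm gauge length; circumferential width 10.1 (SD 1.7) mm and
  thickness 1.0 (0.2) mm; longitudinal 8.6 (1.6) mm and 1.1 (0.3) mm;
  post-conditioning lengths 29.0 (2.6) / 29.8 (2.2) mm and widths
  8.9 (2.0) / 8.0 (2.1) mm. Truncation at $\pm 3$ SD (and above the gauge
  length for post-conditioning lengths) keeps every draw physical.
* **Stress–strain curves** (`generate_curves()`): model curves over
  0–20% engineering strain (tissue damage typically starts beyond that,
  so curves are truncated there) with multiplicative Gaussian noise,
  $\sigma_{\text{obs}} = \sigma_{\text{model}}(1+\varepsilon)$,
  $\varepsilon \sim N(0, \text{CV})$ i.i.d. per point, clipped at zero.
  The noise is multiplicative because observed inter-specimen scatter
  grows roughly in proportion to the stress level; the default CV of 0.05
  is a mid-range value for soft-tissue tensile scatter. An exact-curve
  mode (CV = 0) supports noise-free recovery tests.
* **Load histories** (`generate_load_history()`): four triangular
  preconditioning cycles to 7% of the gauge length at 0.05 mm/s, then a
  monotone ramp, sampled at 30 Hz — the standard protocol for this kind of
  test. Force is the model engineering stress at the current stretch times
  the post-conditioning cross-section, with the strain referenced to the
  post-conditioning length (the same normalisation the processing pipeline
  applies). The true ramp-onset index travels with the record as metadata
  so detectors can be scored.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: preconditioning hysteresis and softening
(synthetic cycles trace the same loading curve up and down), load-cell
drift and stepper ripple beyond white noise, inter-specimen correlation
(synthetic specimens are independent), heteroscedasticity beyond the
proportional model, and any damage or tearing above 20% strain. Recovery
results on synthetic data demonstrate the correctness and stability of the
machinery, not the identifiability of the model on noisy laboratory
curves.

## Raw-record processing

`process_record()` chains the pipeline stages:

1. **Smoothing** (`smooth_load()`): a sliding-window local least-squares
   quartic (Savitzky–Golay). A *local* fit is used because a single global
   quartic cannot represent four preconditioning cycles plus a ramp. The
   default window of 31 samples (about one second at 30 Hz) suppresses
   stepper ripple while reproducing any degree-4 polynomial exactly.
2. **Slope filtering** (`slope_filter()`): central-difference
   differentiation followed by a zero-phase (forward–backward) 5th-order
   low-pass Butterworth filter. The cutoff is a *normalized* parameter
   (fraction of Nyquist, default 0.5) rather than a frequency in Hz: at a
   30 Hz sampling rate the Nyquist frequency is 15 Hz, so cutoffs quoted
   in the hundreds of Hz for this kind of rig cannot be realised and are
   treated as non-reproducible. Zero-phase filtering is essential here —
   a causal filter would shift the detected onset by its group delay.
3. **Onset detection** (`detect_onset()`): the first sample after the
   final preconditioning unloading at which the filtered slope stays above
   a threshold for `hold` consecutive samples (defaults: 5% of the peak
   slope, hold 5). Threshold and hold are configuration because no
   universal values exist; the defaults detect the generator's ground
   truth within `hold + 2` samples.
4. **Normalisation** (`engineering_curve()`): strain
   $(d - d_{\text{onset}})/L_{\text{post}}$ and stress
   $(F - F_{\text{onset}})/(w_{\text{ref}}\, t)$, zeroed at the onset so
   every processed curve passes exactly through the origin, and truncated
   at 20% strain by default. The reference width defaults to the
   post-conditioning width and should be the minimum width tracked at the
   onset when video is available.

## Width tracking from frames

`track_width()` implements the video side: Otsu bimodal-histogram
thresholding (`binarize()`, with a polarity flag and a minimum-area speck
filter), boundary extraction, and classification of boundary pixels into
the four specimen edges by the dominant direction of their offset from the
component centroid, normalised by the component half-extents so elongated
silhouettes classify correctly (`extract_edges()`). Width is measured per
image row (the loading axis is assumed vertical; rotate frames first if
not) as the span between the left and right edges, and the per-frame
minimum is reported together with the top-to-bottom extension.
`render_frame()` provides the synthetic counterpart: an
incompressibility-consistent silhouette (length $\times\lambda$, width
$\times\lambda^{-1/2}$) with Gaussian pixel noise and stored ground truth.
Thresholding method, speck area, and the centroid-quadrant rule are
pragmatic defaults, all configurable; there is no digital image
correlation, no lens model, and only a scalar mm/px scale. Extension can
be read either from the images or from the motor displacement; the package
reports both and leaves the choice to the user.

## Problem sizes used by the shipped tests

The test-suite configurations were chosen as the smallest runs that
exercise each claim cleanly: noise-free recovery uses 50 strain points per
direction with a population of 100 for 100 generations; noisy recovery
uses 20 specimens per direction at CV 0.05 with 100 x 120 across three
seeds; oracle agreement sweeps 100 random parameter sets; width tracking
sweeps 50 randomized rendered specimens. Full-size fits
(`fit_config()` defaults) behave the same, only slower.

## Known limitations

* The model is calibrated and verified for uniaxial tension between 0.9
  and ~1.3 stretch; nothing is claimed for biaxial or shear states, large
  compression, or strains beyond the damage threshold.
* Incompressibility is enforced analytically ($J \equiv 1$); there is no
  compressible/volumetric-penalty formulation.
* No viscoelasticity: rate effects and preconditioning softening are
  outside the model.
* Residual stresses in the intact colon are not represented; parameters
  identified from excised flat specimens inherit that simplification.
* The GA provides no uncertainty quantification; the Pareto front spread
  is a sensitivity indication, not a confidence region.
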