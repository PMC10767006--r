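---
title: "Models and methods: biaxial artery mechanics and ECM fiber quantification"
author: "arteryMech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: biaxial artery mechanics and ECM fiber quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arteryMech)
```

# Scope

`arteryMech` analyzes passive carotid-artery mechanics from biaxial
extension–inflation records and quantifies extracellular-matrix (ECM) fiber
microstructure from multiphoton z-stacks. Because raw pressure-myograph and
microscopy data of the kind this pipeline targets are rarely deposited, the
package ships two first-class synthetic-data generators — a membrane
constitutive simulator and a wavy-fiber image renderer — that provide exact
ground truth for every analysis step. Every quantitative claim made by the
test suite is a recovery claim against those generators or an agreement
claim against an independent oracle (hand-derived formulas, quadrature,
finite differences, brute-force enumeration).

# Thin-wall mechanics

A vessel held at fixed axial stretch $\lambda_z$ and inflated stepwise is
treated as a thin-walled incompressible cylinder. With traced unloaded ring
diameters $D_o > D_i$, the deformed inner diameter follows from conservation
of wall volume,

$$d_i = \sqrt{d_o^2 - \frac{D_o^2 - D_i^2}{\lambda_z}},$$

and the mean biaxial Cauchy stresses from equilibrium,

$$\sigma_\theta = \frac{P\,r_i}{h}, \qquad
  \sigma_z = \frac{f + P \pi r_i^2}{\pi h (2 r_i + h)},$$

with $r_i = d_i/2$, $h = (d_o - d_i)/2$, pressure $P$ converted at
1 mmHg = 0.1333224 kPa, forces in mN, stresses in kPa.

Choices where the field leaves room:

* **Circumferential stretch** $\lambda_\theta$ is the mid-wall
  circumference ratio $(d_o + d_i)/(D_o + D_i)$, consistent with the *mean*
  character of the thin-wall stresses. The inner-wall ratio is available via
  `convention = "inner"`. (Which radius published "at MAP" stretches use is
  generally not stated and is unverifiable; the mid-wall default is
  declared in all outputs.)
* **Reference configuration** is the traced unloaded ring; residual stress
  and opening angle are ignored.
* **In vivo axial stretch**: the tested stretch whose axial force stays
  constant during pressurization. The plateau metric is the force *range*
  (max − min) over the sweep — the strictest simple choice; SD is an
  option. A 50 µN (0.05 mN) threshold decides whether the best sweep is a
  genuine plateau. With ≥ 3 sweeps a parabola through the three
  lowest-variation points refines the estimate; the refinement is clamped
  to the tested range.
* **State at MAP** is linearly interpolated in pressure between the two
  bracketing steps; extrapolation is refused. Since physiological MAP can
  exceed the 120 mmHg protocol ceiling, `characterizeSpecimen()` clamps the
  evaluation pressure to the sampled range by default (`mapPolicy`).
* **Tangent modulus** $d\sigma_\theta / d\lambda_\theta$ at the target
  pressure comes from local least-squares quadratics through the 5 states
  nearest in pressure — robust to the 10 mmHg discretization. The default
  estimator is parametric in pressure: it fits $\sigma_\theta(P)$ and
  $\lambda_\theta(P)$ separately against the noise-free pressure and takes
  the ratio of their derivatives. A direct quadratic of stress on stretch
  (`method = "direct"`) is also provided but is an errors-in-variables
  regression: when diameter noise makes per-step stretch increments
  comparable to stretch noise (stiff vessels), it is badly biased, while
  the parametric form stays stable and coincides with it on clean data. A
  central finite difference is available. Degenerate (identical-stretch)
  data raise an ill-conditioned-fit error.
* **Degenerate inputs**: single-sample sweeps are processable into a
  stress state but rejected for tangent modulus (needs ≥ 3 states) and
  plateau analysis (needs ≥ 2 sweeps).

# The membrane simulator and its designed force plateau

The simulator is a plane-stress incompressible membrane with reduced
strain energy (stretches $\lambda_\theta, \lambda_z$; radial stretch
$\lambda_r = 1/(\lambda_\theta\lambda_z)$):

$$W = \frac{c}{2}\left(\lambda_\theta^2 + \lambda_z^2 +
      \frac{1}{\lambda_\theta^2\lambda_z^2} - 3\right)
    + \sum_k \frac{c_{1k}}{4 c_{2k}}
      \left(e^{c_{2k}(\lambda_k^2-1)^2} - 1\right),
  \qquad
  \lambda_k^2 = \lambda_\theta^2 \sin^2\varphi_k +
                \lambda_z^2 \cos^2\varphi_k,$$

giving $\sigma_\theta = \lambda_\theta\, \partial W/\partial\lambda_\theta$
and $\sigma_z = \lambda_z\, \partial W/\partial\lambda_z$ (verified against
finite differences of $W$). Fibers are mechanically active in both tension
and compression — the smooth choice, which keeps the analytic tangent
usable as an oracle; near the operating regime fiber compression is
negligible for the presets. Equilibrium
$\sigma_\theta h / r_i = P$ is solved for $\lambda_\theta$ by vectorized
bisection with mid-wall kinematics $r = \lambda_\theta R_{mid}$,
$h = H/(\lambda_\theta\lambda_z)$, $r_i = r - h/2$. The bracket starts
*below* 1 because an axially prestretched vessel at zero pressure sits at
$\lambda_\theta < 1$. These kinematics satisfy the ring-based
incompressibility relation exactly, so re-processing a zero-noise record
reproduces pressures and forces to solver precision — the round-trip
acceptance test.

**Why the preset fiber angles are not ±45°.** The measured axial force is,
to leading order in $h/r$,
$F \approx \frac{\pi R H}{\lambda_z}(2\sigma_z - \sigma_\theta)$. A force
plateau — $F$ invariant to pressurization at the in vivo stretch, the
property the in vivo stretch estimator relies on — therefore requires
$2\sigma_z - \sigma_\theta$ to stay constant while $\lambda_\theta$ sweeps
its inflation range. A fiber family at angle $\varphi$ contributes to
$\sigma_z$ and $\sigma_\theta$ in the ratio
$(\lambda_z^2/\lambda_\theta^2)\cot^2\varphi$, so families with
$\tan\varphi \approx \sqrt{2}\,\lambda_z/\lambda_\theta$ (about 56–66° for
rat-carotid stretch ranges) add stress in the plateau-neutral ratio 1:2; a
family at exactly 0° contributes a $\lambda_\theta$-independent term to
$\sigma_z$ and thus shifts the force *level* without disturbing the
plateau. The presets — an axial family plus two ± diagonal pairs near
56°/78° — were designed (one-time derivative-free optimization, then
frozen) to realize a genuine plateau (residual force variation
0.004–0.008 mN, an order of magnitude below the 50 µN criterion) at
physiological magnitudes: in vivo stretches ≈ 1.7–2.0, stresses tens to
~150 kPa, tangent moduli ≈ 0.45–0.8 MPa, axial forces ≈ 10–20 mN, with the
hypertensive-like preset stiffer and more prestretched than the
control-like one. A corollary, covered by a test: the force-invariant
stretch is *insensitive* to axial-family stiffness in this model class
(its force contribution has no $\lambda_\theta$ dependence), while
diagonal-pair stiffness moves it.

**Virtual cohorts.** `randomPreset()` emulates within-group biological
variation as (i) a common geometric scale (±8%) — which rescales forces
but leaves the stress–stretch response and the plateau untouched — (ii) a
common wall-stiffness factor (log-normal, CV 15%), and (iii) a small
symmetric per-family jitter (CV 4%). The rationale: littermates share the
wall's constitutive recipe and differ mostly in size and overall
stiffness; it also preserves the designed force invariance, which real
arteries display and which the estimator tests presuppose. Protocol
defaults mirror the emulated experiment: 0–120 mmHg in 10 mmHg steps at
the in vivo stretch ±5%, Gaussian noise of 5 µm on diameter and 0.05 mN
on force, mandatory seeds. Loaders accept and discard sweeps flagged as
preconditioning (0–140 mmHg ×3 is a protocol fact, not analysis input).

What the simulator does **not** emulate: viscoelasticity and hysteresis,
smooth-muscle tone, residual stress, axial force drift, thick-wall stress
gradients (a separate test checks the thin-wall mean against an
integrated thick-wall solution), and operator artifacts. A green recovery
test therefore establishes correctness of the analysis algebra and
estimators on clean-to-moderately-noisy data, not robustness to every
experimental pathology.

# Fiber orientation by FFT

`directionalityHistogram()` mean-subtracts, applies a 2-D Hann window
(suppressing DC leakage and pixel-grid anisotropy), and bins FFT power by
spectral angle over an annulus of 2 cycles/image to 0.9 × Nyquist,
normalizing each angular bin by its pixel count (the frequency grid
samples angles anisotropically, so summed power would bias flat spectra
toward the axes); spectral angles are rotated 90° into fiber space. Convention: 0° = image x axis =
vessel axis; ±90° = circumferential; angles live on [−90°, 90°). For
images ≥ 256 px the estimate averages 50 %-overlapping half-size blocks
(Welch refinement) — interference speckle between overlapping fibers is
the dominant error source in single-FFT estimates, and block averaging
roughly halves the circular-mean error at fixed acquisition settings.
Per-slice distributions are averaged bin-wise and renormalized for stack
summaries (per-slice normalization, so bright slices do not dominate);
depth maps keep one normalized row per slice, depth 0 at the outer
surface. Constant slices raise an undefined-orientation error and are
skipped (with a count) in stack aggregation, because real deep slices are
often nearly empty.

The circumferential-to-axial ratio $Q_C/Q_A$ has no published operational
definition; here $Q_A$ is the orientation mass within ±20° of the axis,
$Q_C$ the mass within 20° of ±90°, both half-widths exposed and recorded
in the output. $Q_A = 0$ yields an undefined-ratio error, not infinity.
For stacks the package reports the ratio of the stack-mean histogram
(per-slice ratios can also be formed from the depth map's rows).

# Fiber straightness

The straightness parameter of a traced fiber is
$P_s = \text{endpoint distance} / \text{arc length}$ (the convention of
fiber-extraction tools in this field), 1 for straight, < 1 for undulated;
closed loops are rejected. Tracing follows the distance-transform recipe:
difference-of-Gaussians band-pass (σ 1 and 6 px) with contrast
normalization — a dependency-light stand-in for curvelet denoising,
validated by the same recovery contracts — with an adaptive noise floor
(3x the pixel-noise SD estimated from neighbor differences, propagated
through the DoG kernel's L2 gain), then binarization at 5% of the image
maximum (Otsu optional; after the noise floor the positive intensities
are near-unimodal fiber pixels, which Otsu's bimodal criterion
oversplits), exact Euclidean distance transform, ridge maxima as nucleation points, and
bidirectional sub-pixel extension that re-centers on the ridge each step,
clamps turning to 35°/step, bridges breaks up to `maxGap` px (4 by
default) along a smoothed pre-gap heading, and stops after running onto
pixels claimed by an earlier fiber. Fibers shorter than 25 µm are
discarded; traced polylines are lightly smoothed (moving average) before
$P_s$ to remove pixel jitter. Per-slice $P_s$ histograms emulate the
3-D-bar-plot view; the per-slice median is taken over raw per-fiber values
(binning first would quantize the summaries), and the stack summary is
the mean ± SD of per-slice medians. Per-fiber equality with any specific
external tracing tool is *not* claimed — the contract is recovery of
known synthetic truth (median $P_s$ within 0.05 of quadrature for
$P_s \in [0.75, 1]$).

# Synthetic fiber images

Fibers are single-harmonic sinusoids (the minimal waviness model with a
closed quadrature for $P_s$) rasterized with a Gaussian transverse profile
(σ 1.2 px) onto a 512 px grid emulating a 425 × 425 µm field of view
(pixel size 425/512 ≈ 0.830 µm; the acquisition's pixel count is not
standardized, so the power-of-two grid was chosen once). Fiber length
defaults to an integer number of waviness periods so the centerline's
chord/arc ratio equals the analytic sinusoid value (truth invariant
≤ 10⁻³). Orientations are von Mises (Best–Fisher sampler); the
`stratified` option replaces iid draws by a jittered systematic quantile
sample, pinning the realized mean direction to the nominal one — used
when a test's target is the nominal mean rather than the realized sample.
Depth stacks switch the orientation distribution at a stated interface
depth, emulating the abrupt axial→circumferential transition at the
adventitia–media border. Noise is additive Gaussian plus optional Poisson
shot noise. Fibers are placed to fit the frame (60 retries), else clipped
with truth restricted to the in-frame portion. Axial stretching of tissue
is emulated by bilinear affine resampling of the rendered image along the
vessel axis.

# Statistics

Group comparisons use classical one-way fixed-effects ANOVA with
Bonferroni-corrected pairwise t tests (equal-variance by default — the
classical Bonferroni-after-ANOVA choice; Welch optional), significance at
p < 0.05. Summaries are mean ± SEM for biomechanical metrics and
mean ± SD for imaging metrics, with the convention recorded in every
table; sample (n−1) SD throughout; n = 1 groups report a flagged zero
dispersion rather than erroring so tables always render. Pooled left/right
vessels are treated as independent specimens (no mixed-effects modeling).

# Numerical choices

* Pressure unit conversion: 1 mmHg = 0.1333224 kPa, applied only where a
  pressure enters a stress formula; units are fixed at the I/O boundary
  (mmHg, mm, mN, µm in; kPa/MPa out).
* Equilibrium bisection: 100 iterations on a bracket guarded for a
  positive inner radius; equilibrium residual < 10⁻⁸ · max(P, 1 kPa).
* Force-invariant stretch search: grid spacing 0.001 with automatic
  bracket widening (warning) when the minimizer hits an edge.
* Fiber exponential overflow (> e⁵⁰⁰) raises a parameter-range error with
  guidance instead of Inf propagation.
* Quadrature for analytic $P_s$: adaptive `integrate` at rel. tol 10⁻¹⁰.
* Distance transform: exact two-pass separable algorithm; Otsu on 256
  bins.
* Seeds: every stochastic stage takes a seed; pipeline stages derive
  seeds from one master seed (FNV-style mixing, kept < 2³¹); generator
  functions save and restore the caller's RNG state.

# Known limitations

The tangent modulus is statistically fragile on noisy sweeps of stiff
vessels: once the per-10-mmHg stretch increment falls below the
stretch-equivalent of the diameter noise (5 µm noise on a ~0.7 mm vessel
is a stretch noise of ~0.004), no local estimator can recover the slope
reliably from 13 discrete steps, and cohort summaries of the modulus
become wide. Real acquisitions integrate continuous readings per step
and are effectively less noisy; for synthetic studies, reduce
`diameterNoiseSD` or average repeated sweeps when the modulus is the
endpoint. The zero-noise recovery contract (within 5% of the analytic
derivative) is the estimator's correctness claim.

2-D analysis only (no 3-D fiber continuity or orientation tensors);
interface *detection* in depth maps is a modal-angle crossing heuristic
intended for abrupt transitions; no constitutive parameter fitting to
experimental curves; no thick-wall transmural stress profiles; axial
stiffness is not estimable from fixed-stretch inflation sweeps and is not
reported. TIFF I/O is not provided in this environment — stacks are
exchanged as in-memory arrays or a plain-text per-slice CSV format with a
JSON sidecar.
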