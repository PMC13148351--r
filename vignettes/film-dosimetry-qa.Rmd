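---
title: "Film dosimetry QA: models, algorithms and design choices"
author: "filmdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Film dosimetry QA: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the science implemented in **filmdose**: the film
response model, the calibration and reconstruction machinery, the
registration and gamma comparison, the synthetic scanner model used for
validation, and — because numerical dosimetry lives and dies by its edge
cases — the numerical choices and their rationale.

## 1. Film response and uncertainty propagation

A flatbed scan of a radiochromic film yields, per pixel and color channel,
an integer pixel value $PV \in [0, 2^{16}-1]$ (48-bit RGB). Transmittance
and optical density are

$$T = \frac{PV}{2^{16}-1}, \qquad OD = -\log_{10} T.$$

A dead pixel ($PV = 0$) is clamped to one count before the logarithm:
infinities would poison every downstream map, while a clamped extreme OD
surfaces visibly in the t-map and noise statistics where it belongs.

Dose is keyed to the *net* change between a post-irradiation and a
pre-irradiation (or unirradiated-reference) measurement,

$$netT = T_f - T_i, \qquad netOD = OD_f - OD_i,$$

with the netOD uncertainty propagated to first order from the pixel-value
scatter inside the ROI:

$$\sigma_{netOD} = \frac{1}{\ln 10}
  \sqrt{\left(\frac{\sigma_{PV_f}}{PV_f}\right)^2 +
        \left(\frac{\sigma_{PV_i}}{PV_i}\right)^2}.$$

The test suite validates this first-order formula against direct
Monte-Carlo simulation ($10^5$ Gaussian draws): the agreement is within 5%
relative for $\sigma_{PV}/PV \le 0.05$, which covers any usable scan.

ROI standard deviations are *population* ($\div n$) rather than sample
($\div (n-1)$): ROIs contain thousands of pixels, the distinction is
physically irrelevant, and the fixed convention makes hand-computed test
values exact. `netT` keeps its literal sign — negative for a darkening
film — and the calibration parameters absorb it; no hidden sign flip.

Replicate films irradiated at the same dose are combined by the
minimum-variance (inverse-variance) weighted average

$$\overline{netOD} = \sum_i \omega_i\,netOD_i,\quad
  \omega_i = \frac{1/\sigma_i^2}{\sum_j 1/\sigma_j^2},\quad
  \sigma_{\rm tot} = \Big(\sum_i \sigma_i^{-2}\Big)^{-1/2}.$$

$\sigma_{\rm tot}$ is the unique choice that makes the weighted mean the
minimum-variance unbiased combination; with $N$ equal-precision replicates
it reduces the uncertainty by exactly $\sqrt{N}$, which the tests assert to
machine precision. All-zero sigmas (an idealized noise-free set) fall back
to the equal-weight mean; *mixed* zero and non-zero sigmas are refused as
ill-posed rather than silently renormalized.

## 2. Calibration models and fitting

Two dose-response families are implemented, both standard for this film
type:

* **rational**, on net transmittance:
  $D = \dfrac{A\,netT}{1 - B\,netT}$ — with $A<0$, $B>0$ it is monotone
  decreasing on $netT \in (-1, 0]$ and inverts in closed form,
  $netT = D/(A + B D)$. Note the inverse has a pole at $D = -A/B$; the
  calibrated dose range must stay below it.
* **polynomial**, on net optical density:
  $D = A\,netOD + B\,netOD^{\,n}$, with $n$ fitted as a free real exponent
  by default (it can be fixed via `fixedN`). Inversion is by bisection on
  the monotone branch through the origin, to $|\Delta D| < 10^{-9}$ Gy.

Fits minimize $\sum_i w_i\,(D_i - f(r_i))^2$ by Levenberg–Marquardt
(`minpack.lm`), with dose as a function of response — the direction the
model families are written in. When response uncertainties are supplied the
weights are $w_i = 1/\sigma_i^2$ directly. A design alternative would
project the response uncertainty through the model slope
($\sigma_D \approx |f'(r)|\,\sigma_r$) before weighting; we rejected it
because it breaks a property we consider more valuable in QA practice:
*equal uncertainties must reproduce the unweighted fit exactly*, so that
weighting can never silently re-balance a homoscedastic calibration set.
The weights are normalized to mean 1 so the reduced chi-square keeps its
Gy² scale.

Starting values matter for rational fits near their pole: $A, B$ are
initialized from an exact two-point solve on the lowest and highest
positive-dose points ($D = A r + B r D$ is linear in $(A, B)$), and the
polynomial from a low-dose slope estimate with $n_0 = 2$. Parameter
uncertainties come from the Jacobian at the optimum scaled by the residual
variance; a singular Jacobian or a non-converged optimizer is an explicit
error, never a silently returned model. During fitting the polynomial power
uses the sign-safe continuation $B\,\mathrm{sign}(r)|r|^n$ so that a noisy
zero-dose replicate with slightly negative $netOD$ cannot abort the
optimizer; the user-facing `polynomialDose` still refuses a negative base
with fractional exponent, as that evaluation is genuinely undefined.

The default calibration range is 0–10 Gy; the stated applicability of the
whole workflow is 0.5–20 Gy, and the synthetic phantoms enforce it.

## 3. Multichannel reconstruction and the t-map

The multichannel method assumes the measured optical density factorizes
into a dose-dependent part and a smooth, dose-*independent* multiplicative
disturbance (film thickness variation, scanner sensitivity). Each channel
predicts a dose $D_i(t) = f_i(OD_i \cdot t)$, and the per-pixel scaling

$$t_{\min} = \arg\min_t \; g(t), \qquad
  g(t) = \sum_{i<j} \left(D_i(t) - D_j(t)\right)^2$$

restores inter-channel consistency; the map of $t_{\min}$ images the
separated non-homogeneities. We use the three unordered pairs: the full
ordered double sum is exactly twice this and has the same argmin.

Because the chosen calibration is a function of $netT$ while the
disturbance model is multiplicative in OD, the scaling is applied in OD
space and the response recomputed: $T_f' = 10^{-OD_f t}$ (and likewise for
the pre-scan OD), then $netT' = T_f' - T_i'$ feeds $f_i$. For `net_od`
models the scaling reduces to $netOD \cdot t$ directly. This is the OD
path; it is the default because the disturbance physics is multiplicative
in absorbance, not transmittance.

**The degenerate root at $t = 0$.** As $t \to 0$ every channel's response
goes to zero and all three predicted doses collapse to 0 — so $g(t) \to 0$
for *every* pixel, regardless of dose. The objective therefore always has a
spurious global minimum at the origin, and the physical solution is only
*locally* identified near $t = 1$. Consequently the solver is a
Newton–Raphson iteration on $g'(t) = 0$ from $t_0 = 1$ (at most 100
iterations, $|\Delta t| < 10^{-6}$) **trust-regioned to $t \in [0.5,
1.5]$**: a Newton step leaving the region triggers a bounded
golden-section fallback, and if that only finds a boundary minimum the
pixel is flagged non-converged and filled with the red-channel
single-channel dose — reported and counted, never a hole in a QA map. In
practice the flagged pixels are the unexposed background, where the
channel ODs are pure quantization noise in inconsistent proportions: below
the 0.5 Gy applicability floor the scaling factor is simply not
identifiable, and the fallback dose there is ≈ 0 Gy anyway.

Derivatives for Newton are 5-point central finite differences of $g$
($h = 10^{-5}$), uniformly for both model families. An analytic derivative
for the rational family was considered and dropped: the finite-difference
path vectorizes across all pixels at once (the whole image iterates
simultaneously on a vector of $t$), is model-agnostic, and matches a dense
$10^{-4}$-step grid search of $g$ within $10^{-4}$ on every tested pixel —
the accuracy that matters, verified in the acceptance suite. Two guards
complete the contract: pixels whose channels already agree at $t=1$
(within $g < 10^{-18}$) converge immediately with $t = 1$, and a final
check resets $t$ to 1 wherever optimization would *worsen* $g$ relative to
the unscaled measurement, so channel agreement is never degraded.

The final dose is the arithmetic mean of the three channel doses at
$t_{\min}$. On a synthetic uniform field with a 5% multiplicative OD
disturbance, the multichannel variance is two to three orders of magnitude
below the red-channel variance, and the t-map correlates with the
reciprocal of the injected field above 0.99 on the plateau — the
noise-suppression property asserted (conservatively, as $\le$) in the
tests. Note the identification is dose-dependent: at the 0.5 Gy floor the
blue channel's OD is ~100 counts, so quantization limits t-recovery there;
t-map quality statements in the tests are therefore made on pixels inside
the applicability range.

## 4. Registration

Scanner orientation: the film is pre-processed by a vertical reflection
followed by a 180° rotation (both individually togglable), matching a
scanner bed that mirrors the planning frame; synthetic films need neither.

The planned map (template), resampled to the film's pixel spacing, is slid
over the dose-converted film and scored at every placement with the
normalized cross-correlation

$$E_{NCC}(u) = \frac{\sum_i (I_0(x_i) - \bar I_0)(I_1(x_i+u) - \bar I_1)}
 {\sqrt{\sum_i (I_0(x_i) - \bar I_0)^2}\sqrt{\sum_i (I_1(x_i+u) - \bar I_1)^2}},$$

where $\bar I_0$ is the template's global mean and $\bar I_1$ the mean of
the film window under the current placement. NCC is invariant to affine
intensity changes of either image, which is what makes matching a *dose*
template against a film robust to residual calibration scale errors.
Matching runs in dose space (not raw PV) so the two intensities are
commensurate; dose conversion happens anyway, so this costs nothing.

Implementation: the cross term is a 2-D FFT correlation (zero-padded to
the image size, so no circular wrap-around can reach the valid region);
window means and variances come from exact integral images. The tests pin
this against a literal double-loop evaluation of the formula to $10^{-10}$
on instances up to 32×32. A zero-variance window (uniform background)
scores 0 rather than erroring — it is a legitimate candidate position that
simply carries no evidence; a zero-variance *template* is refused.

Angular misalignment is absorbed by a sweep: the template is rotated about
its center (bilinear, out-of-bounds filled with the template's edge mean)
by 0, ±1°, ±2°, ±3° by default, and the global (angle, position) maximum
wins. Ties break toward smaller $|$angle$|$, then smaller row, then smaller
column — fully deterministic. The matched region is cropped at the found
offset and inverse-rotated into the plan's frame. Manual fiducial-based
alignment is supported as an explicit offset/angle override, not detected
automatically. Registration recovers synthetic embeddings exactly (offset
error ≤ 1 px, exact angle) at 20 dB additive noise across 20 random trials
in the acceptance suite.

## 5. Gamma analysis

For each reference (plan) pixel above the dose threshold,

$$\Gamma(\vec r_c) = \min_{\vec r_m}
  \sqrt{\frac{|\vec r_c - \vec r_m|^2}{DTA^2} +
        \frac{(D_{ref}(\vec r_c) - D_{meas}(\vec r_m))^2}{\Delta D^2}},$$

with distances in mm via the pixel spacing and the minimum taken over
measured pixel centers. The dose-difference denominator $\Delta D$ is an
explicit *mode*, because the printed local-flavor denominator and a
globally-normalized analysis coexist in common practice: `global` uses
dd% of the reference maximum, `local` dd% of each reference pixel's dose
(zero-dose pixels masked), `absolute` a fixed Gy value. A pixel passes when
$\Gamma \le 1$ (inclusive — the universal clinical convention), and the
pass rate is taken over evaluated pixels only; the default 5% low-dose
threshold excludes the background from the statistics.

The spatial search is cut off at 3×DTA (configurable) and additionally
bounded by the grid size; since reference and measured maps share a grid
after internal resampling, the zero-displacement candidate always exists
and no pixel is ever left without a candidate (no infinities). The
acceptance suite proves the implementation equal (to $10^{-10}$) to an
exhaustive, unlimited-radius double-loop evaluation on 50 random map
pairs, and checks the closed form for uniform maps: 2.00 vs 2.12 Gy at
3%/3 mm global gives $\Gamma = 0.12/(0.03 \cdot 2.00) = 2.00$ exactly,
attained at zero displacement. Monotonicity (relaxing DD or DTA never
lowers the pass rate) and threshold behavior (raising it never grows the
evaluated set) are asserted as properties. There is no sub-pixel
interpolation: the discrete minimum is the definition implemented; finer
agreement is obtained by resampling the measured map first, and pass rates
from interpolating implementations may differ slightly near steep
gradients.

## 6. The synthetic scanner model

The generator replaces physical film irradiation and scanning, and its
defaults are the study conditions the tests run under:

* **Phantoms** (`makeDosePhantom`): a uniform square field
  ($D\,S(x)S(y)$, logistic edge $S$ with scale `penumbraSigmaMm`, default
  2 mm — a realistic linac penumbra at depth) and a pyramid of nested
  squares with increasing level doses (center reaches the last level).
  Doses are restricted to 0.5–20 Gy and field sizes to 50–220 mm, the
  workflow's stated applicability. The validation cases use a 5 Gy /
  100 mm square and a 2/4/6 Gy pyramid.
* **Forward model** (`filmFromDose`): per channel, the calibration inverse
  maps dose to response; the implied OD is multiplied by a smooth quadratic
  disturbance surface of peak amplitude `disturbanceAmplitude` (the
  dose-independent non-homogeneity the multichannel method assumes —
  deliberately matched to that model class); the pixel value is the
  transmittance on the 16-bit scale with Gaussian noise
  ($\sigma = $ `gaussianSigmaFraction` × PV), salt spikes (full-scale
  counts at `spikeProbability`, emulating dust and dead sensor pixels),
  and round-half-even integer quantization. Embedding pastes the
  (optionally rotated) film into a larger unexposed canvas at a known
  offset. Everything is keyed to a single integer seed; equal seeds give
  bit-identical films, and the injected disturbance and embedding truth
  travel in the film's metadata.
* **Calibration truth** (`syntheticCalibrationModels`): rational models
  with R $(A,B) = (-20, 0.5)$, G $(-30, 0.4)$, B $(-50, 0.3)$ — fixture
  constants chosen so the red channel is the most sensitive at low dose
  (mirroring real film's strong red-band response), every channel's $netT$
  stays in $(-1, 0]$ up to 10 Gy, and the three channels are genuinely
  distinct so the multichannel objective is well-conditioned.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real scans: the lateral response artifact (the
position-dependent flatbed response, a *column-structured* multiplicative
effect that is explicitly out of scope here as it is in the modeled
workflow), film-batch and temperature dependence, scan-timing darkening
drift, polarization effects from film rotation on the bed, and real TPS
fluence complexity beyond the two phantom geometries. The synthetic
disturbance is smooth and low-order by construction; real scanner defects
include sharp scratches, which land in the median filter's domain instead.

## 7. Denoising

Two stages, both shape-preserving and constant-exact: a median filter
(default 3×3) removes isolated salt spikes exactly, then a locally adaptive
Wiener filter shrinks each pixel toward its local mean by
$\max(v - \nu, 0)/v$, where $v$ is the local variance (default 5×5 window)
and the noise power $\nu$ is estimated as the mean of the local variances
over the image — the standard adaptive variant when no separate noise
estimate exists. Window size 1 disables a stage; replicate padding keeps
edges unbiased for constants. No installed R package provides this
adaptive Wiener form, so it is implemented here via integral-image local
statistics.

## 8. Geometry, I/O dialects and numerical conventions

* Grids are R matrices indexed `[row, col]`, 1-based, row 1 at the top of
  the scan; the physical center of pixel $(i,j)$ is
  `origin + (i-1, j-1) * spacing` mm. TIFF spacing is `25.4 / dpi`.
* A TIFF without resolution tags requires an explicit `dpi` — spacing is
  never guessed, because a wrong spacing silently corrupts every DTA. The
  bundled TIFF writer does not emit resolution tags, so its outputs always
  take the explicit-`dpi` path on re-read.
* RT Dose files are single-frame, explicit-VR little-endian, 16-bit
  unsigned, with dose-grid scaling `max(dose)/65535` (1e-4 Gy if all
  zero), so the integer range is fully used and the round-trip error is at
  most scaling/2 per pixel. Multi-frame files are rejected, not silently
  sliced: this workflow is strictly planar.
* Resampling is bilinear with edge clamping; constants resample exactly,
  the covered physical area is preserved within one target pixel, and
  interpolation round-off is clamped at zero dose.
* All stochastic tests fix their seeds; the acceptance script derives every
  seed from its `--seed` argument.

Problem sizes in the test and acceptance suites — 16×16 maps for oracle
equivalence, ~40×40 films for multichannel checks, 150×170 canvases for
registration, $10^5$ Monte-Carlo draws, 20-seed repetition for stochastic
recovery — were chosen as the smallest sizes at which each property is
sharply discriminating; each check runs in seconds on one CPU.

One statistical convention: the noisy-calibration check asserts *3-sigma
coverage* of the true parameters across 20 seeds × 2 parameters as a ≥95%
coverage fraction rather than demanding every single draw inside 3σ — with
40 draws, a single legitimate ~0.3%-tail excursion would otherwise fail a
correct implementation.

## 9. Known limitations

No LRA correction (flat-field your scanner or restrict to the bed center);
no sub-pixel gamma interpolation; no 3-D dose grids, DVHs or RT Plan
parsing; no exponential/logistic calibration families; no automatic
fiducial detection (manual override only); multichannel t is unidentifiable
below ~0.5 Gy and those pixels fall back to single-channel dose;
re-calibration and machine-learning-based corrections are out of scope.
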