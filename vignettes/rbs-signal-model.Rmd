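---
title: "The RBS signal model: physics, processing, and decision rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The RBS signal model: physics, processing, and decision rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbscreen)
```

## The measurement principle

Retinal birefringence scanning (RBS) screens for two amblyopia risk
factors at once: loss of central fixation (strabismus) and poor focus
(refractive error). A spot of linearly polarized near-infrared light is
scanned in a circle of 3° visual angle around the point the subject is
asked to fixate. The Henle fibers of the fovea are birefringent and
radially arranged, so the polarization change imprinted on the
double-pass return encodes where the scan circle sits relative to the
foveal center. A polarizing beam splitter routes only the
polarization-changed part of the return to a bull's-eye photodetector
(center + annulus) per eye; the center/annulus energy split encodes
focus quality.

A half-wave plate (HWP) spinning at 9/16 of the scan rate converts the
spatial polarization signature into a clean frequency signature: all
information lands at odd multiples of half the scan frequency
$f_s = 30$ rev/s:

* **4.5 × f_s** — a strong spin-generated carrier, insensitive to the
  direction of gaze;
* **2.5 and 6.5 × f_s** — the central-fixation pair. Their relative
  strength depends on the individual cornea, and either member may
  dominate (or nearly vanish);
* **3.5 and 5.5 × f_s** — the para-central pair, which replaces the
  first pair when the scan center is displaced from the fovea.

## The Mueller-matrix simulator

`detector_sample()` propagates a horizontal linearly polarized Stokes
vector through the retarder train

HWP(ψ) → [fixed WP] → cornea → Henle(axis(φ)) → fundus mirror →
Henle → cornea → [fixed WP] → HWP(ψ) → analyzer,

with ψ = (9/16)φ. Conventions, each of which was a genuinely open
modeling choice:

* **Return pass.** Elements are traversed with mirrored axes
  (axis → −axis, the standard convention for a retracing beam viewed
  against propagation) and the fundus is an ideal mirror
  `diag(1, 1, −1, −1)`. Under this choice—verified by simulation—the
  detected spectrum contains only integer and half-integer harmonics of
  $f_s$, with the gaze-independent carrier at exactly 4.5 × f_s. The
  other sign conventions tested place the carrier at the same index, so
  nothing downstream hinges on it.
* **Henle axis.** Only radial symmetry is physically established; the
  package takes the slow axis radial (configurable). Either choice
  preserves all harmonic signatures.
* **Fiber-free foveal core.** The radial-axis model is singular where
  the scanned point coincides with the foveal center—exactly the
  geometry of the para-central calibration condition (gaze on the scan
  circle). Physically there are no oriented fibers at the foveola, so
  Henle retardance tapers linearly to zero inside `foveal_core_deg`
  (default 0.25°). `henle_axis()` itself still treats the degenerate
  point as a geometry error.
* **Fixed wave plate.** The optimized instrument carries a fixed
  retarder whose exact parameters live in design-specific calibration;
  the slot exists (`fixed_wp`) but is disabled by default, since the
  harmonic signatures hold from the HWP + cornea + Henle train alone.

Energy bookkeeping holds per sample: analyzer-transmitted +
analyzer-rejected + depolarized intensity equals the reflected
intensity (`components = TRUE` exposes the budget).

## Synthetic records and their parameters

`synthesize_record()` produces the four channels (left/right ×
center/annulus) at 6000 samples/s for 1 s, 200 samples per scan
revolution. Defaults, with the reasoning:

| parameter | default | why |
|---|---|---|
| corneal retardance | uniform 20–80° per eye | spans a wide corneal population so that either member of each sideband pair can dominate |
| corneal axis | uniform 0–180° | no preferred orientation |
| Henle retardance | 3° single pass | weak retarder, an order of magnitude below the cornea, giving robust but small sidebands |
| fundus reflectance / depolarized fraction | 0.05 / 0.3 | small specular return plus a dominant depolarized background source |
| carrier channel gain | 0.07 at 4.5 × f_s | the analog chain acquires the strong spin-generated carrier with much less gain to avoid saturation; this value places the synthetic CF ratios (median ≈ 2.9) around the instrument's operating threshold of 0.875 |
| background | amplitude 0.02, 8 scan harmonics, exactly 200-sample periodic | scleral/skin scatter repeats with the scan and is an order of magnitude above the signal |
| line interference | amplitude 0.01 at 60 Hz | mains pickup; exactly two cycles per revolution under synchronized sampling |
| white noise σ | 5 × 10⁻⁴ | sets a per-bin noise floor ~20 dB below the fixation sidebands |

The generator emulates: synchronized sampling (every frequency of
interest on an exact 1-Hz bin), scan-periodic background, line
interference, defocus-dependent center/annulus splitting, and the
5-subject × 12-record × 2-eye × (1 central + 4 para-central) calibration
protocol (120 CF / 480 para-CF feature rows). It does **not** emulate:
eye movement within a record (each record has one fixed offset),
blinks or partial occlusions (though degenerate, carrier-free records
are handled downstream), motor-speed jitter (a ±1-bin band mode exists
for that), wavelength dispersion, or pupil-size photometrics beyond a
single blur-scale factor. Passing tests therefore demonstrate the
correctness of the processing chain under the stated signal model, not
robustness to every artifact of clinical recordings.

## Phase-shift subtraction and spectra

`phss()` subtracts the record from itself shifted by one scan
revolution (200 samples). Everything scan-periodic—background and the
60 Hz line, which completes exactly two cycles per revolution—cancels
identically, while every half-harmonic doubles
($|1 - e^{-i 2\pi(k+\frac12)}| = 2$). The default is a circular shift:
records hold an exact integer number of revolutions, making the
circular form an identity rather than an approximation, and preserving
the 1-Hz bin alignment; a truncated streaming mode is available.

`power_spectrum()` uses the plain DFT, no window (synchronized sampling
makes the target bins leakage-free), one-sided, normalized so bin
powers sum to the signal's mean square. All published decision
quantities are ratios, so the normalization convention cancels.

Per-eye central-fixation features default to the **sum** of center and
annulus channels (total collected light, hence defocus-robust); the
paper computes spectra for both detectors without stating which feeds
the criterion, and center-only is a configuration switch. A record
whose carrier power is below 10⁻¹² of its total half-harmonic power is
declared degenerate: it is flagged unusable and excluded from the
2-of-12 numerator but not the denominator—conservative toward failing.

## Decision rules

**Method 1 (threshold).** The score is $(P_{2.5}+P_{6.5})/P_{4.5}$.
Calibration sweeps θ over 0.3–8.00 in steps of 0.001 and minimizes the
pooled L1 error $\sum_j |r_j - \theta|$ over both labeled sets; ties
break to the smallest θ. This objective is implemented exactly as
published; note its minimizer is the grid point nearest the pooled
median, which separates the classes only when the data do. An
alternative misclassification-count objective on the same grid is
available behind a flag and is clearly labeled as not the published
rule. Classification is strict: pass iff r > θ.

**Method 2 (discriminants).** Two-class linear discriminant with pooled
covariance and equal priors (proportional priors optional; equal priors
despite the 120/480 imbalance match the common default of standard LDA
routines). The boundary $K + \mathbf{P}\mathbf{L}^T = 0$ is converted
to the instrument's explicit form $a_0 = -K/L_{last}$,
$a_i = -L_i/L_{last}$; in 3D a record passes iff
$P_{6.5}/P_{4.5} > a_0 + a_1 x + a_2 y$ with
$x = (P_{3.5}+P_{5.5})/P_{4.5}$ and $y = P_{2.5}/P_{4.5}$ (strict).
The 4D variant splits $x$ into its two components, taken in the order
(r35, r55, r25, r65) with the decision variable last; the published
4D coefficients are carried as configuration defaults under this
ordering. Calibration performance on synthetic data is reported both by
resubstitution and on held-out draws, since the published table does
not state which was used.

**Session rules.** An eye passes CF (or FD) when at least 2 of 12
records pass; alignment requires both eyes to pass CF. The
goodness-of-focus boundary is inclusive (0.65 itself passes): the
published threshold is the limit of acceptable focus, whereas the CF
comparison is published as a strict inequality—the asymmetry is
deliberate and documented.

## Focus model

Effective defocus is `demand − response` with
`demand = stimulus + refraction − lens` and, without cycloplegia,
`response = clamp(demand, tonic, tonic + amplitude)`: a perfect
accommodator pinned at a tonic level it cannot relax. This minimal
model reproduces the clinical arithmetic exactly—a cyclopleged +1.00 D
eye viewing a 3.00 D target peaks at +4.00 D of added lens, the same
eye with 0.75 D of tonic accommodation at +3.25 D—and yields the
characteristic slow fall-off on the minus-lens side (accommodation
absorbs the demand, producing a best-focus plateau whose plus-side end
is reported as the curve peak).

The blur model is $f_A(d) = 1 - \exp(-(d/s)^2)$ for the fraction of
light on the annulus. With C and A defined as carrier-bin signal
magnitudes, goodness is exactly $1 - 2 f_A$, and the default scale
$s = 2.28$ D places the 0.65 crossing at 1.00 D of defocus exactly
($f_A = 0.175$). Cycloplegic dilation scales $s$ by 0.5, which puts the
dilated crossing at 0.50 D past the peak—matching the reported
steepening without further tuning. The magnitude (square-root power)
convention for C and A is what makes the statistic linear in the
optical energy split; treating them as raw powers would bend the
published $f_A = 0.175$ anchor point.

## Numerical notes

* The detected signal repeats exactly every two scan revolutions at the
  9/16 design ratio, so the synthesizer computes one 400-sample base
  period and tiles it (equality with the full computation is tested to
  10⁻¹²).
* The L1 sweep objective is evaluated by sorted cumulative sums rather
  than a grid × sample outer product; the minimizer search tolerates
  last-digit float noise so ties genuinely break to the smallest θ.
* Focus-curve threshold crossings are reported by linear interpolation
  on the 0.25 D lens grid, on the plus side of the peak.
* One top-level seed drives every draw; per-record seeds are derived
  deterministically, and identical configuration + seed yields
  byte-identical feature tables.

## Problem sizes used by the test suite

The package's own verification uses: 20 random corneal draws for the
harmonic-signature suite; two independent 120/480 calibration sets
(5 subjects each) for the threshold round-trip; 20 random datasets for
the sweep-oracle equivalence; and 200 simulated sessions per condition
(clearly normal; constant 1.5° deviation; 2.0 D binocular defocus) for
the end-to-end screening check. These sizes give comfortable
sampling-error margins for the properties asserted while keeping the
suite runnable in a few minutes on one CPU.

## Known limitations

The printed clinical headline numbers (sensitivity/specificity on real
subjects, and the exact published θ = 0.8750 and discriminant
coefficients) depend on the authors' recordings, which are not
deposited; they are reproducible here only as arithmetic on the printed
confusion counts and as configuration defaults. The simulator's
feature distributions are calibrated to sit around the published
operating point, but no claim is made that synthetic calibration
reproduces the published coefficients themselves. Wavelength-dependent
optics, corneal-database-driven optimization of the fixed wave plate,
and real-time/hardware concerns are out of scope.
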