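---
title: "Methods: blast dosimetry, behavior and histology quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blast dosimetry, behavior and histology quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastdose)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical decisions taken where the underlying
procedures are conventionally under-specified, and the limits of what the
synthetic-data tests demonstrate.

# Blast-wave model

A free-field blast pulse is modeled by the modified Friedlander waveform

$$P(t) = P_{max}\left(1 - \frac{\tau}{t_+}\right)e^{-b\,\tau/t_+},
\qquad \tau = t - t_0 \ge 0,$$

with peak overpressure $P_{max}$ (psi), positive-phase duration $t_+$ (ms),
dimensionless decay constant $b \ge 0$ and arrival time $t_0$ (ms). The
waveform rises instantaneously to $P_{max}$ at $t_0$, crosses zero exactly
at $t_0 + t_+$ and is negative (underpressure) beyond it. Its positive
impulse has the closed form

$$I = P_{max}\,t_+\left(\frac{1}{b} - \frac{1 - e^{-b}}{b^2}\right),$$

with the triangular limit $P_{max} t_+/2$ as $b \to 0$ (evaluated by series
below $b = 10^{-6}$ to avoid cancellation). The closed form is the oracle
against which trapezoidal integration of sampled traces is tested.

The decay constant is not a measured quantity here: shock-tube
characterizations report peak, duration and impulse, and $b$ is whatever
value makes those mutually consistent. For the upstream exposure condition
used throughout (19.18 psi, 1.99 ms, impulse 14.03 psi·ms) the impulse
ratio $I/(P_{max} t_+) = 0.366$ solves to $b \approx 1$, which is why the
generators default to $b = 1$ upstream. The adjacent (1.7) and fixture
(2.8) defaults are solved the same way from their respective
peak/duration/impulse triples.

Reflected pressure at a rigid surface facing the wave uses the normal-shock
reflection relation

$$P_{ref} = 2\,\Delta P + \frac{(\gamma + 1)\,\Delta P^2}
{(\gamma - 1)\,\Delta P + 2\gamma P_0},$$

with $\gamma = 1.4$ and $P_0 = 14.7$ psi by default. Implementation note:
the relation is coded in this general-$\gamma$ form and validated by its
limits — the reflection factor $P_{ref}/\Delta P$ must run monotonically
from 2 (acoustic) to 8 (strong shock, air) — rather than against any one
printed rendering of the formula, which in the source literature is often
typeset ambiguously. At $\gamma = 1.4$ it is algebraically
$2\Delta P + 6\Delta P^2/(7P_0 + \Delta P)$.

Measured and calculated reflected pressures are compared by *symmetric*
percent difference $200\,|a-b|/(a+b)$. The symmetric form is chosen because
neither value is privileged as the reference; with the values involved here
the choice of denominator moves the result by well under one percentage
point.

# Trace conditioning

Raw sensor records (nominally 500 kHz) receive exactly two corrections, and
no filtering — digital filtering would attenuate the very wave features
(rise time, peak) being measured:

* **Baseline correction** subtracts the mean of a pre-trigger segment
  (default: the first 10% of samples, which must precede wave arrival; a
  window in ms can be given instead). It is a pure constant shift.
* **Clipping repair.** Saturated spans are detected as runs of at least
  `min_run = 3` consecutive samples within 0.1% of the saturation level
  (the trace maximum when no level is configured). Each span is repaired by
  *two-sided envelope extrapolation*: low-order polynomials are fit by
  least squares to the rising flank and to the decaying flank (each flank
  sized to twice the span, at least 25 samples), and the repaired value is
  the pointwise minimum of the two extrapolations, floored at the
  saturation level. For a pulse whose crest is flattened, the rise and
  decay envelopes intersect near the true peak, so the peak is recovered
  rather than capped. A monotone interpolant across the span was considered
  and rejected: by construction it can never exceed the saturation ceiling,
  so it cannot restore a clipped crest at all.

A trace is **severely clipped** when the clipped samples exceed
`severe_fraction = 0.25` of its positive phase, or when a span touches the
record boundary (no flank to extrapolate from). Severe traces are not
repaired; `exclude_traces()` drops any shot with a severe sensor, with the
reason logged. The 0.25 default is a judgment call — severity is
conventionally left undefined — and is exposed as configuration.

# Wave characterization

* **Onset** $t_0$: walk back from the peak to the crossing of
  `threshold_fraction = 0.05` of the peak, then on to the preceding
  noise-level crossing (noise level = 3 SD of the pre-trigger baseline).
  Walking back from the peak, rather than forward from the start, makes the
  detection immune to isolated baseline noise spikes; the second walk-back
  credits a finite rise ramp to the pulse instead of truncating it at the
  threshold.
* **Peak magnitude** is the raw maximum; **rise time** is peak time minus
  onset.
* **Positive duration** ends at the first zero down-crossing after the
  peak. On a clean trace (baseline SD below $10^{-4}$ of the peak) this is
  the linearly interpolated sign change. On a noisy trace the first
  negative raw sample is systematically *early* (it occurs where the decay
  first dips within noise reach of zero), so the crossing is instead
  located provisionally by a 25-sample centred moving average — used for
  detection only; analyzed samples stay unfiltered — and refined by linear
  regression on the raw samples within ±40 samples, which is unbiased.
* **Positive impulse** is the trapezoidal integral from onset to the
  interpolated crossing on the native grid; at 500 kHz nothing fancier is
  warranted (verified at better than 0.1% against the closed form, and
  0.5% down to 50 kHz).

**Friedlander fitting.** On its positive support the four-parameter form
collapses to $A(c - t)e^{-\beta t}$ — three functional degrees of freedom —
so least squares over $(P_{max}, t_+, b, t_0)$ has an exactly
rank-deficient Jacobian; $t_0$ is identified only by the truncation point.
The fit therefore proceeds in two identifiable steps: (1) nonlinear least
squares (Levenberg–Marquardt) of the three-parameter decay curve from the
measured peak over 1.5 measured durations, initialized from the measured
metrics with $b = 1$; (2) the model clock is placed where a least-squares
line through the rise-ramp samples (15–85% of peak) meets the fitted curve
— or at the detected onset when the rise is unresolved. This recovers the
generating parameters exactly on noiseless pulses and, in the test suite,
to within 2% ($P_{max}$, $t_+$) and 10% ($b$) under 2% multiplicative-scale
noise.

Repeatability tables report per-location mean and sample (n−1) SD, matching
the "mean ± SD" convention of instrument characterizations; group-level
biology uses mean ± SEM instead (below).

# Open-field behavior

The arena is interpreted as an 80 cm × 80 cm square (a "square arena of
80 cm" reading; an 80 cm² floor would be physically implausible for a rat).
The center zone is a concentric square of half the side length (25% of the
area), the common open-field convention; the wall zone is a 10 cm margin,
about one body width. All three are configurable in `arena_spec()`.

Metrics operate on the body-center tracked point by default (nose and tail
base are carried but the center is the conventional locomotion reference).
Per-frame speed is step length × frame rate with no smoothing by default
(`smoothing_window = 1`), since any tracker-side smoothing is unknown; both
maximum and mean velocity are reported, privileging neither. Tracking gaps
up to 5 frames are linearly interpolated; longer gaps split the session —
distance sums within segments and gap-spanning steps are excluded from
velocities. Tarlov scores are validated as integers 0–5 and summarized as
per-group daily medians, appropriate for an ordinal scale.

The trajectory generator is a reflected correlated random walk
(gamma-distributed steps, mean 0.35 cm/frame at 30 fps ≈ 10 cm/s path
speed; heading SD 0.6 rad/frame) with a thigmotaxis weight that drifts the
animal toward the nearest wall each frame. With zero weight its long-run
occupancy is approximately uniform, so the center fraction approaches the
25% area fraction — the property the tests check (within ±0.05 over an
extended 40-minute synthetic session; residual deviation reflects the
walk's finite mixing time, not a bug in the metric, which is verified
exactly against per-frame ground-truth zone labels).

# Histology quantification

Per image: threshold → binary mask → measures.

* **Threshold**: Otsu per image by default, since acquisition settings
  (exposure, gain) vary image to image and the original analyses'
  threshold settings are conventionally unreported; a fixed threshold is
  available for cross-image comparability, and the threshold actually used
  is always recorded in the output. Otsu on a constant image is an error
  directing to the fixed method.
* **Area fraction** = positive pixels / total pixels.
* **Cell count** = 8-connected components with area in
  `[min_area, max_area]`; `min_area = 20 µm²` excludes single-pixel noise
  at a 20X scale (0.65 µm/px default). Labeling uses a 4-connected pass
  plus a union-find merge of diagonal adjacencies. No watershed splitting
  of touching cells by default: plain counts are what the measure reports,
  and splitting would introduce untestable shape assumptions.
* **Integrated density** = sum of *raw* intensities over the region (whole
  image unless a mask is given), satisfying the identity mean intensity ×
  area.
* **Area per cell** = total positive area / count; *undefined* when the
  count is zero (returned as `NA` with a `defined` flag — never 0, never
  infinite).

Per-subject aggregation averages each subject's representative images
(default 6) before group statistics, so the subject — not the image — is
the statistical unit.

The image generator renders cells as flat-topped super-Gaussian disks
(intensity $\propto \exp(-\ln 2\,(d/r)^6)$, half peak at the nominal
radius) placed without overlap by rejection sampling, with Poisson counts,
normal radius (5 ± 0.7 µm, footprint ≈ 80 µm²) and intensity
(180 ± 15 over background 12, noise SD 8). Blast-group effects are
multiplicative on count, radius and intensity; the defaults emulate the
activation patterns of interest — astrocytic (GFAP-like: larger, brighter)
and microglial (Iba1-like: more numerous, smaller, brighter, i.e. count
and integrated density up, area per cell down).

# Group statistics

Two-sided unpaired two-sample t-tests at α = 0.05 with Student
(pooled-variance) form by default, matching the convention of standard
prism-style analyses; Welch is available by flag. No multiple-testing
correction is applied — each marker/metric is tested on its own — and the
report output states this. The implementation delegates to `stats::t.test`
and is verified in the tests against a hand-computed pooled-variance
oracle, against location/scale invariance, and against its nominal type-I
error (rejection rate 0.05 ± 0.01 over 10,000 seeded null simulations at
n = 6 per group).

# Study conditions and problem sizes

The generators' defaults are the characterized study conditions: 7 shots;
upstream 19.18 psi / 1.99 ms / b = 1 with a 0.019 ms rise; adjacent
20.88 psi / 1.56 ms with a damped post-peak ripple (15% of peak, 5 kHz,
0.5 ms decay) standing in for fixture reflections; fixture peak tied to
the adjacent peak through the reflection relation with 8% multiplicative
noise; per-location CVs from the repeatability table; 0.25 psi sensor
noise; baseline offsets in ±0.5 psi; 500 kHz sampling over 8 ms.
Behavioral sessions are 5 min at 30 fps for 6 sham and 7 blast subjects.
The test suite exercises the end-to-end histology comparison at 24 images
per group (4 subjects of 6 images); image size 256 × 256 px keeps a full
study run around a few seconds while leaving dozens of resolvable cells
per field.

# What the synthetic tests do and do not show

The generators share the package's own waveform, geometry and rendering
primitives (with independent ground-truth labels), so passing tests
demonstrate internal consistency, correct algebra and statistical
calibration — not robustness to everything real instruments produce. Not
emulated: sensor ringing and cable artifacts beyond a stylized ripple,
temperature/drift effects, video-tracking identity swaps and reflections,
tissue autofluorescence, uneven illumination, staining-batch variation,
morphologically realistic glial shapes, or colocalization across channels.
Real fixture reflections are also not a damped sinusoid; the adjacent
sensor's "noisier" character is a stand-in. Consequently group-difference
*directions* (and calibrated error rates) are the reproducible structure;
absolute histology magnitudes depend on acquisition settings and are not
portable across laboratories.

# Known limitations

* Negative-phase (underpressure) metrics and frequency-domain analysis are
  out of scope.
* Clipping repair assumes a single dominant crest per span; overlapping
  multi-peak saturation would be flagged severe rather than reconstructed.
* The envelope repair extrapolates polynomials; a span much wider than its
  flanks (beyond the severity threshold) is not trustworthy, which is
  exactly why such traces are excluded.
* Cell counting without watershed undercounts at high densities; the
  generator's rejection-sampled placement sidesteps this, real tissue does
  not.
* Tarlov handling validates and summarizes but deliberately applies no
  parametric statistics to the ordinal scores.
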