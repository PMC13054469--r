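---
title: "Methods: multilateration-based needle-tip tracking in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multilateration-based needle-tip tracking in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `needletrack`, the
parameter choices that matter, what the synthetic-data generator does and
does not emulate, and the numerical decisions behind the solvers. Units are
millimetres, microseconds and MHz throughout the public interface, so that
with a water sound speed of c = 1.48 mm/µs every quantity is O(1–100).

## System model

A 2D matrix-array probe carries 256 active elements arranged on a Fermat
spiral (radius ∝ √k, golden-angle azimuth steps), a low-redundancy sparse
aperture of about 4.8 mm radius — half the footprint of a 32 × 35 element
grid at 0.3 mm pitch. Because the true hardwired element map is proprietary,
`fermat_spiral_layout()` generates a faithful stand-in from the spiral
formula, optionally snapped to a 0.3 mm rectangular grid (a plausible
matrix-array pitch); all downstream validation treats the generated
geometry as self-consistent ground truth, and measured maps can be loaded
from CSV/JSON instead. Sparsification always retains the *outermost* k
elements, ranked by distance from the layout centroid so the rule is
well-defined for loaded geometries too; subsets are therefore nested, and
three elements is the admissible minimum for a 3D solve from absolute
ranges.

Each tracking frame fires the selected elements sequentially; a point-like
omnidirectional hydrophone at the needle tip records one trace per element,
sampled at 26 MHz with t = 0 at the transmit trigger. Two excitations are
modelled: a 5 µs linear chirp swept 1→5 MHz (the tracking waveform; its
time–bandwidth product T·B = 20 gives a matched-filter amplitude SNR gain
of √(T·B) ≈ 4.5) and a four-cycle Gaussian tone burst at 3 MHz (the
comparison waveform, with the cycle count measured between the window's
half-amplitude points).

## The synthetic-data generator

`synthesize_frame()` models, per element: the one-way geometric delay
τᵢ = ‖p − sᵢ‖/c; spherical-spreading amplitude 1/‖p − sᵢ‖ (mm⁻¹, so a
receiver at 1 mm records unit amplitude); optional discrete multipath
echoes (each a delayed, scaled copy of the direct arrival, replicated on
every element); optional frequency-proportional attenuation in dB/(MHz·cm),
off by default to match water-tank conditions; and i.i.d. additive Gaussian
noise under a per-scene seed that leaves the session RNG untouched.

Delays are applied as a frequency-domain phase ramp on a ≥2× zero-padded
grid. This makes the ground-truth arrival time exact by construction —
never quantized to the sample grid — which is what lets the test suite
assert sub-sample round-trip recovery. The alternative (time-domain
interpolation) would have coupled the ground truth to an interpolation
kernel. A consequence worth knowing: a fractionally delayed copy of a
waveform with abrupt edges is band-limited, so trace peaks can overshoot
the nominal 1/r amplitude by a few percent.

The transmit trigger defines t = 0 and the excitation *starts* at t = 0, so
the arrival time is the delay of the excitation's start; the matched-filter
lag axis is calibrated to the same convention (an alternative
centre-referenced convention would merely shift all ranges by a constant,
but mixing the two would bias every range by half the pulse length, so the
convention is fixed once, here).

### Noise calibration

The experimentally relevant regime is a post-compression per-channel
amplitude SNR near 15, reported as nearly constant across channels and
needle positions. A single fixed noise floor cannot reproduce that: with
1/r signal amplitudes it would span SNR ≈ 45 at 10 mm depth down to ≈ 8 at
the deepest offset positions, and at SNR ≈ 5–8 the envelope-peak picker
occasionally locks onto noise maxima that slip through the gates.
`calibrate_noise_sigma()` therefore supports two modes: a global mode (one
noise level, grand-mean SNR equal to the target) and a per-position mode
(one level per scene, each frame at the target), the latter being the
evaluation default because it matches the reported uniform-SNR regime. The
calibration itself is exact up to Monte-Carlo error: the chain is linear,
so one noiseless pass measures the signal peaks and one seeded pure-noise
pass measures the compressed-envelope noise factor.

### What the generator does *not* emulate

No element directivity, lens delays, hydrophone frequency response or
fiber-bending artifacts; no transmit apodization; no sound-speed
heterogeneity or aberration; no stage/registration error. These terms
dominate the error budget of the physical system (see *Limitations*), so
passing the in-silico accuracy checks demonstrates correctness of the
algorithms under the stated propagation model — not the absolute accuracy
to expect on hardware. The 1 kHz PRF and the sequential firing schedule are
not simulated in time; they enter only through the frame-rate model
f = PRF/(N_imaging + N_tracking).

## Receive chain

1. **Bandpass, 1–5 MHz.** A 4th-order Butterworth applied forward–backward
   (`signal::filtfilt`). Zero-phase filtering is a hard requirement: a
   causal filter would shift every envelope peak by its group delay and
   bias all ranges. Band edges sit exactly at the chirp's sweep limits;
   since the filter's −3 dB corners coincide with the band edges and the
   response applies twice, the compressed peak loses ~35 % of amplitude
   relative to an unfiltered matched filter — a pure scale factor that
   cancels in every SNR and gating decision.
2. **Pulse compression.** FFT cross-correlation with the transmitted
   waveform, normalized by template energy so the envelope peak
   approximates the received copy's amplitude. Positive lags only; the lag
   axis equals arrival time of the excitation start.
3. **Envelope.** Magnitude of the analytic signal (one-sided spectrum
   doubling). No sidelobe-suppression taper is applied anywhere.

## Arrival-time gating

For each compressed envelope: σ is the standard deviation over lags below
`baseline_window` (default 5 µs — no arrival is expected there for depths
beyond ~7.4 mm; shallower scenes trigger a simulator warning and the window
should be shortened to fit the scene). The gates run in a fixed order:

* **Noise gate** (default mode `amplitude_gate`): reject as `noisy` when
  the half-maximum level A₅₀ = 0.5·peak is below `sigma_multiplier`·σ
  (default 4, i.e. peak < 8σ). The printed form of this gate compares the
  half-maximum *width* — a time — against 4σ — an amplitude; as stated it
  is dimensionally inconsistent, while its evident intent is to reject
  weak, noise-like peaks. The default preserves that intent; a
  `literal_width` mode (width in samples vs 4σ) is kept only for
  sensitivity analysis.
* **Consistency gate:** reject as `inconsistent` when the amplitude-weighted
  mean lag of *all* supra-A₅₀ samples is farther than `com_delay_limit`
  (default 2 µs) from the peak. Computing the centre of mass over all
  supra-threshold content — not just the main lobe — is what makes the gate
  sensitive to strong late echoes.

Accepted arrivals get a three-point parabolic refinement of the envelope
peak (ties broken toward the earliest lag; the refinement is clamped to
±half a sample). Gating decisions are scale-invariant, and both thresholds
act monotonically. With a 5 µs baseline the σ estimate rests on only ~20
statistically independent envelope samples; on pure-noise traces a few
percent of cases fluctuate past the noise gate and are then caught by the
consistency gate, so pure noise never yields an accepted arrival even
though the rejection *reason* is occasionally `inconsistent`.

## Position solving

Ranges dᵢ = c·tᵢ from accepted elements (at least three, else an
insufficient-observations condition) feed a damped Gauss–Newton minimizer
of Σ(‖p − sᵢ‖ − dᵢ)², Jacobian rows (p − sᵢ)ᵀ/‖p − sᵢ‖. Numerical choices:

* **Initialization.** The objective has mirror minima about the array
  plane, so the start point matters. Differencing squared sphere equations
  against a reference element yields a linear system; with all elements at
  z = 0 it determines (x, y) only, and depth follows from the sphere
  equations averaged over elements, taken positive. This enforces the
  z > 0 half-space (the needle is in front of the probe face) and resolves
  the 3-element mirror ambiguity.
* **Damping.** Steps that would increase the objective are halved (at most
  8 times), so the objective never increases between accepted iterates;
  pure Gauss–Newton is recovered whenever full steps succeed (noiseless
  fixtures converge to machine precision in 2–4 iterations).
* **Tolerances.** Step-norm tolerance 1e-6 mm, iteration cap 50. A frame
  that exhausts the cap returns `converged = FALSE` with diagnostics rather
  than an error.
* **Degeneracies.** Collinear transmitters are reported as degenerate
  geometry; a receiver exactly at a transmitter zeroes that row of the
  Jacobian (its gradient is undefined at the kink) and the remaining rows
  carry the step. No per-element weighting is applied.

`grid_search_position()` is a deliberately independent brute-force
reference (exhaustive 3D grid, compiled loop) used to cross-check the
solver. Near the minimum the objective valley is ~10× shallower laterally
than axially for deep targets, so the best node of a 0.05 mm grid can
legitimately sit a few steps from the continuum minimizer along the valley;
equivalence checks therefore combine per-axis agreement at that resolution
limit, objective dominance of the iterative solution over every grid node,
and RMSE agreement.

## Delay-and-sum baseline

`das_beamform()` sums, per voxel, the complex analytic compressed samples
of every element at the one-way delay ‖v − sᵢ‖/c (linear interpolation) and
takes the magnitude of the sum — envelope after coherent summation, the
standard DAS definition; an envelope-then-sum mode exists for sensitivity
checks. There is no receive beamforming (the receiver is a point) and no
apodization. The default grid is 0.2 mm isotropic over x, y ∈ [−12, 12] mm,
z ∈ [5, 50] mm; the sweep driver restricts the region to the evaluated
positions (±4 mm padding) at the same voxel size for tractability.
`com_localize()` returns the intensity-weighted centroid of voxels within
−6 dB of the maximum.

Two properties of this baseline surprised us and are worth recording.
First, because sparsification keeps the *outermost* ring, the aperture
becomes annular: the main lobe does not broaden as elements are removed —
it narrows slightly while sidelobe energy grows, so PSF degradation
manifests as artefacts, not blur. Second, on noiseless clean frames the
−6 dB centre of mass is accurate to ~0.01 mm at every subset size, with
differences between sizes dominated by voxel/threshold discretization of
the supra-threshold set rather than physics; the DAS accuracy penalty under
sparsification emerges once calibrated noise is present, and the evaluation
asserts it with paired trials (same frames across nested subsets, the same
post-processing sparsification a single acquired dataset would undergo).

## Evaluation protocol and problem sizes

The accuracy protocol places the receiver at depths {10, 20, 30, 40} mm ×
lateral offsets {0, 2, 4} mm in x and y, three noise realizations each —
108 frames per condition. The sparsification sweep evaluates the nested
plan {256, 128, 64, 32, 13, 9} on 108 paired frames with per-position
SNR-15 calibration; the matched-filter gain and pure-noise gate checks use
500 and 200 Monte-Carlo realizations respectively; the solver/grid-search
cross-check uses 50 jittered instances (range jitter σ_t = 0.05 µs). These
sizes were chosen so the full suite completes in minutes on a single CPU
while keeping Monte-Carlo standard errors well below the asserted margins.

## Limitations

* **Absolute accuracy is optimistic.** Under the clean propagation model at
  SNR 15 the noise-limited ToA jitter is ~0.01 µs (near the
  Cramér–Rao bound for the compressed chirp), giving mean 13-element
  localization errors of order 0.05–0.15 mm over the protocol grid — an
  order of magnitude below what physical water-tank systems report, whose
  error budgets are dominated by systematic terms (receiver offset within
  the needle, stage–probe registration, aberration) that the generator
  deliberately omits. In-silico accuracy figures validate the estimator,
  not the hardware.
* **Error growth under sparsification follows information, not hardware
  curves.** For an unbiased noise-limited estimator the error scales like
  the inverse square root of the aperture subset's Fisher information, a
  ~4× growth from 256 to 9 elements here; experimental curves that sit on
  a systematic floor appear much flatter. Comparisons between the two
  should be made on trends, not ratios.
* The hydrophone is ideal (flat response, omnidirectional, noise-free
  optics); multipath is a stylized discrete-echo model; sound speed is
  exact and homogeneous. Tone-burst tracking runs through the same
  compression path with the burst as template, an assumption rather than a
  measured design choice.
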