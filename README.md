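# needletrack

Ultrasound guidance of needle-based procedures (nerve blocks, biopsies) is
limited by poor needle-tip visibility, especially at steep insertion angles
and out of plane. One remedy is an *active* tip: a point-like fiber-optic
hydrophone embedded in the needle receives one-way transmissions from the
imaging probe's elements, and the tip is localized in the probe's own
coordinate frame. `needletrack` implements the signal-processing and
localization chain for such a system built around a sparse Fermat's-spiral
2D matrix array, together with an acoustic simulator that stands in for the
hydrophone hardware, so the whole chain can be exercised and validated in
silico.

The package is aimed at researchers in ultrasonic device tracking and
interventional imaging who want a reference implementation of
multilateration-based tip localization and its delay-and-sum (DAS) baseline.

## The method

Each tracking frame fires a subset of array elements one at a time. For
element *i* at known position **s**ᵢ (mm, array face at z = 0), the received
trace is bandpass filtered (1–5 MHz, zero phase), pulse-compressed by
cross-correlation with the transmitted waveform — a 5 µs linear chirp swept
1→5 MHz, whose time–bandwidth product buys an amplitude SNR gain of about
√(T·B) ≈ 4.5 — and envelope-detected. The envelope peak gives the
time of arrival *t*ᵢ, screened by two reliability gates: a noise gate
(peak must stand far enough above the baseline noise level σ estimated
before any arrival) and a consistency gate (the centre of mass of all
supra-half-maximum envelope content must lie within 2 µs of the peak,
which flags multipath-contaminated traces).

With a constant sound speed *c*, each accepted arrival fixes a range
dᵢ = c·tᵢ, i.e. a sphere around **s**ᵢ. The tip position **p** minimizes the
sum of squared range residuals

    min_p  Σᵢ ( ‖p − sᵢ‖ − c·tᵢ )²

solved by damped Gauss–Newton from a closed-form linearized initialization,
with the z > 0 half-space selecting the physical solution. Three accepted
elements are the minimum; more make the solve overdetermined and more robust.

The baseline localizer reconstructs a volumetric intensity map by one-way
delay-and-sum of the compressed traces and takes the −6 dB centre of mass —
accurate at full aperture but increasingly artefact-prone as elements are
removed, whereas multilateration needs only a handful of elements. Since a
frame spends one transmission per tracking element (plus 9 plane-wave
imaging transmissions) at a 1 kHz PRF, sparsifying the tracking subset from
256 to 13 elements raises the frame rate from 3.77 Hz to 45.45 Hz.

## Worked example

Simulate one tracking frame for a receiver at (2, 4, 30) mm using the 13
outermost spiral elements, with noise calibrated to a post-compression SNR
of 15, then run the full chain:

```r
library(needletrack)

layout   <- fermat_spiral_layout(256)          # full imaging aperture
tracking <- sparsify_layout(layout, 13)        # 13 outermost elements
spec     <- chirp_spec()                       # 1-5 MHz, 5 us @ 26 MHz
sigma    <- calibrate_noise_sigma(tracking, spec,
                                  positions = data.frame(x = 2, y = 4, z = 30))
scene    <- acoustic_scene(c(2, 4, 30), noise_sigma = sigma, rng_seed = 7)
frame    <- synthesize_frame(tracking, scene, spec)
est      <- track_frame(frame, tracking, make_chirp(spec))
print(est)
#> <position_estimate> (1.923, 4.028, 30.013) mm; residual RMS 0.02023 mm; 13 elements; 3 iter (converged)
sqrt(sum((est$position - c(2, 4, 30))^2))      # localization error, mm
#> 0.083
acquisition_frame_rate(13)                     # Hz at PRF 1000, 9 imaging TX
#> 45.45
```

The estimate recovers the receiver to well under a tenth of a millimetre at
this SNR; `attr(est, "decisions")` holds the per-element arrival times and
gate diagnostics. `run_sparsification_sweep()` repeats this over a grid of
depths and lateral offsets for a nested sequence of subsets and compares
multilateration with the DAS baseline.

A thin command-line front end is installed as `exec/needletrack`
(`simulate | track | sweep | frame-rate`), operating on CSV/JSON geometry
and frame containers.

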