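---
title: "Radar-based hallway gait analysis: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radar-based hallway gait analysis: models, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(radargait)
```

`radargait` is a desk-scale re-creation of a hallway gait-monitoring
system: a single 77 GHz FMCW radar, optionally fitted with a dielectric
lens that narrows its beam, watches a subject walk a marked out-and-back
course, and a deliberately simple processing chain recovers per-cycle
spatiotemporal gait parameters. This vignette documents the models, every
tunable that matters, the numerical choices, and — importantly — what a
green test on synthetic data does and does not establish.

## 1. The radar model

A sawtooth FMCW radar transmits linear frequency ramps (slope
$S = 60\,\mathrm{MHz/\mu s}$, ramp $60\,\mu\mathrm{s}$, idle
$250\,\mu\mathrm{s}$). A point reflector at range $R$ returns a fast-time
beat tone at $f_b = 2SR/c$; with 64 complex ADC samples at 2.2 Msps the
range axis has bins every $(f_s/N)\,c/2S = 8.59\,\mathrm{cm}$ out to
5.5 m. Slow-time phase advances by $4\pi R/\lambda$ per chirp, giving
Doppler with $v_{max} = \lambda/4T_c = 3.08$ m/s at the
$T_c = 310\,\mu\mathrm{s}$ chirp interval.

Conventions worth stating:

* **Bandwidth.** The quoted sweep bandwidth is the full-ramp product
  $S\,T_{ramp} = 3600$ MHz. The ADC only samples $29.1\,\mu\mathrm{s}$ of
  the ramp, so the *resolution-bearing* bandwidth is 1745 MHz;
  `sampled_bandwidth()` exposes it separately.
* **Complex sampling.** I/Q sampling is assumed throughout. Real-only
  sampling at 2.2 Msps would halve the unambiguous range to ~2.75 m and
  could not cover the 4.2 m course.
* **Wavelength.** Taken at the centre of the sampled sweep
  (78.47 GHz, $\lambda = 3.82$ mm) and held constant per recording.
* **Frame period.** Not part of the chirp timing; default 100 ms
  (minimum possible is $256 \times 310\,\mu s = 79.4$ ms), configurable.
* $c = 299\,792\,458$ m/s exactly; bins are 0-based everywhere.

## 2. The lens

The lens is plano-hyperbolic: waves from a feed at the focus refract at
the hyperbolic entry face and leave the planar outer face collimated.
Equal optical path length for every ray forces

$$t(r) = \frac{F}{n+1}\left(\sqrt{1 + \frac{n+1}{n-1}
  \left(\frac{r}{F}\right)^2} - 1\right), \qquad n = \sqrt{\varepsilon_r},$$

with $t(0)=0$ and $t$ strictly increasing. Because published renderings of
such formulas are easy to mangle typographically, the package does not
trust the algebra alone: a brute-force ray oracle (tests) checks that
$\sqrt{(F+t)^2+r^2} + n\,(t(R)-t(r))$ is constant across rays to
$10^{-9}F$. Defaults: $R = F = 10\lambda \approx 38$ mm and measured
3D-printed PLA constants $\varepsilon_r = 2.68$, $\sigma = 0.19$ S/m.
Conductivity affects loss, not shape, and is stored as metadata. The
geometric-optics derivation assumes dimensions large against $\lambda$;
`lens_validity_check()` warns below a conservative 5$\lambda$ threshold
(the source design says only "relatively larger", so 5 is a package
choice, configurable).

In the simulator the lens is represented *parametrically*: a
Gaussian-in-angle power pattern. The lens mode gets +14 dB boresight gain
over the bare antenna; its 12° half-power beamwidth is not an independent
knob but derived from that ratio (a 25-fold power gain concentrates the
60° bare beam into roughly $60/\sqrt{25}$ degrees). No full-wave
electromagnetics is attempted or implied.

## 3. The synthetic hallway

`walk_scenario()` states the validation protocol: a 4.2 m course with
0.7 m marked steps walked out-and-back three times (36 steps), radar at
1.2 m height, subject speed 0.87 m/s, 20 dB SNR. Within each step the
torso speed follows a raised cosine,
$v(\tau) = \bar v\,(1 - m\cos 2\pi\tau/T_{step})$, giving exactly one
speed maximum per step (the stance/swing "sawtooth"); depth $m = 0.5$ by
default. The first and last step of each pass use depth 1 so the subject
decelerates smoothly to standstill, dwells `turn_duration` = 1 s, and
re-accelerates. Each step integrates to exactly one step length, so the
ground truth is closed-form.

Choices that deserve justification:

* **Torso sway (6 mm, 0.35 Hz).** At $\lambda = 3.8$ mm a perfectly
  static subject is a perfectly coherent reflector: during turn dwells the
  slow-time-mean clutter filter would then accumulate a residue at the
  dwell bin that out-amplitudes the distant torso (whose return falls as
  $R^{-2}$, a 27× span over the course) and permanently captures the
  argmax. Real torsos breathe and sway at millimetre scale; adding that
  sway is what makes the person distinguishable from true static clutter.
  It is three orders of magnitude below the bin spacing and does not touch
  the gait geometry.
* **Multipath.** Each wall produces a specular mirror ghost at range
  $(|p'| + |p|)/2$ ($p'$ the subject's image). The two reciprocal bounce
  paths have identical length and add in phase, so ghost amplitudes carry
  a factor 2 — without it a ghost can never exceed the torso even off a
  lossless wall, contradicting the observed failure mode. Each static
  reflector additionally spawns a *moving* subject–object bounce ghost at
  $(r_t + |p - c| + r_c)/2$; these are what scatter multipath energy
  across many range bins as the subject walks. Single-bounce only; loss
  defaults 6 dB (painted walls) and 3 dB (object bounce).
* **Cabinets (amplitudes 2, 5, 9 at 1.8/2.8/3.8 m).** Graded so their
  *received* returns are mutually comparable (~0.6 torso-units each) —
  the worst-case contested argmax of a metal-cabinet-lined hallway.
  Chosen once from the radar equation, not fitted to any output.
* **Oblique walks** keep a constant subject–radar azimuth (the course is
  radial at `walk_azimuth`), matching the angle-sweep protocol; arbitrary
  2-D paths are out of scope.
* **Elevation is collapsed.** The 1.2 m mounting height motivates
  torso-dominant amplitude weighting; no explicit elevation pattern.
* **Limbs** (`limbs = TRUE`, off by default) add two weaker scatterers
  oscillating about the torso with larger peak radial speeds — a fidelity
  layer for micro-Doppler experiments, not needed for the parameter path.

What the simulator does **not** emulate: RCS scintillation and body
shadowing, antenna sidelobe structure, TX leakage, intermod/quantisation
effects, multiple people, and real gait variability (asymmetry, limp,
double-support timing). A green test here establishes that the *pipeline*
recovers the stated world's parameters through a physically plausible
radar channel — not that the hardware system achieves those errors.

## 4. The extraction pipeline

1. **Range FFT** per chirp (Hann window by default; `n_fft` = 64).
2. **Clutter filter**: subtract each bin's complex mean over all chirps of
   the recording. This removes zero-Doppler content exactly; a subject
   traversing ~50 bins leaves at most a few percent of their energy in any
   one bin's mean. `mode = "none"` reproduces raw profiles.
3. **Torso track**: per frame, noncoherent mean of chirp magnitudes, then
   the argmax over bins with range ≥ 0.3 m (excludes the leakage region;
   ties to the smaller bin). The reported range is refined within the
   winning bin by 3-point log-parabolic interpolation — the standard
   sub-bin spectral-peak estimate. Refinement matters: bin-centre tracks
   (8.6 cm staircase) produce spurious velocity doublets that inflate the
   step count on slow walks. Frames are timestamped at the centre of the
   chirp burst, not the frame period, since the burst need not fill the
   frame.
4. **Track smoothing**: 5-frame median filter, then a physical gate — any
   frame implying a speed above $v_{max}$ is invalidated and
   interpolated.
5. **Torso velocity**: Savitzky–Golay derivative, window 7 frames,
   polynomial degree 3. Degree matters: the centred *quadratic* derivative
   filter coincides with the straight-line slope filter, whose gain at a
   2–2.5 Hz cadence sampled at 10 Hz is ≈0–0.4 (and sign-flipping), which
   destroys step detection for fast walkers; the cubic filter keeps gains
   of 0.97/0.68 at 1/2 Hz at ~1.6× the noise. Both knobs are exposed.
6. **Segmentation**: frames with $|v|$ below
   $\max(0.05, 0.15\,q_{0.9}(|v|))$ m/s are stationary; stationary runs
   longer than 0.5 s are turns, shorter ones are absorbed into the pass.
   Only the outermost pass boundaries are refined outward to the adjacent
   $|v|$ minimum (the launch/brake tails belong to the walk); expanding
   interior boundaries the same way would swallow whole turns on a smooth
   track.
7. **Step detection**: local maxima of $|v|$ within passes, prominence
   ≥ 0.2× the pass median $|v|$, minimum separation 0.3 s (a 200
   steps/min cadence cap). Step time is the peak-to-peak interval within a
   pass.
8. **Geometry**: the step point is the torso range at the peak instant
   (interpolated); step lengths are successive step-point differences
   within a pass, never across turns; stride length is the sum of two
   successive step lengths (the named quantity is otherwise undefined in
   the source material, so the package defines it explicitly). Step points
   are taken at the $|v|$ peaks rather than troughs for SNR.
9. **Average speed**: summed per-pass range change divided by the elapsed
   time from first pass start to last pass end — turns *included*,
   matching the stopwatch protocol. Interior pass boundaries are measured
   at turn midpoints, where the subject sits at the course extremum.
   Cadence uses pass time only.

The micro-Doppler spectrogram (`micro_doppler_spectrogram()`) is a
diagnostic cross-check on the velocity estimate, not part of the
parameter path.

## 5. Degradation without the lens

With the wide (60°) bare beam, the surviving moving multipath — wall
ghosts and subject–object bounces — contests the range-profile argmax,
the track picks up spurious excursions, and the step count overcounts the
truth while the lens-mode run stays exact. With the clutter filter *also*
disabled, the static cabinets simply pin the argmax and the track (hence
the step count) collapses instead: two distinct failure modes, both
demonstrated in the test suite. The overcount property is therefore
asserted with the filter active in both arms, and the filter-off collapse
is asserted separately.

## 6. Numerical and degenerate-input policy

* All-zero profiles yield invalid frames (`NA`), not errors; empty step
  sets yield an empty but well-formed report.
* Ties in the argmax break toward the smaller bin; parabolic offsets are
  clamped to ±0.5 bin.
* The synthesizer rejects scatterers beyond the unambiguous range by
  label, and walks cannot be simulated closer than the leakage cutoff.
* Noise is generated in a private RNG stream (`rng_seed`); the caller's
  `.Random.seed` is untouched, and equal seeds give bit-identical cubes
  and byte-identical report files (no timestamps in outputs).
* Cube files store complex64; one write/read round trip is exact at
  single precision, subsequent ones bit-exact.

## 7. Known limitations

* The maximum-bin rule is single-subject by construction; MIMO,
  tracking/clustering and multi-person scenes are out of scope.
* At 90° (tangential) walks the radial projection of gait vanishes; the
  pipeline is only claimed for |azimuth| ≤ 60°.
* Step-length errors grow at fast cadence (≥ ~2 Hz) where the 10 Hz frame
  rate undersamples the per-step oscillation; speed remains accurate
  because it depends only on the track endpoints and elapsed time.
* The acceptance envelope (max speed error ≤ 0.045 m/s, mean ≤ 0.013 m/s,
  step length within ±2.33 cm, step-count error ≤ 1.25) is verified on
  synthetic scenes that mirror the validation protocol; hardware-specific
  effects (antenna patterns, gain ripple, SAR) are explicitly not
  modelled.
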