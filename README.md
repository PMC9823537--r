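# radargait

Contactless spatiotemporal gait analysis from a **single FMCW mm-wave
radar** in a cluttered indoor corridor.

Day-to-day changes in walking speed, step length or cadence are early
markers of declining mobility and cognition, especially in older adults,
but mat- or camera-based gait labs are impractical for continuous home or
care-facility monitoring. A 77 GHz frequency-modulated continuous-wave
(FMCW) radar mounted in a hallway can measure gait unobtrusively — *if*
the multipath reflections from walls and furniture can be kept from
masquerading as the walking subject. A dielectric lens that narrows the
antenna beam suppresses that multipath in hardware, after which a very
simple processing chain suffices: take the subject's range bin as the
**maximum of the range profile**, differentiate the torso range track, and
read the gait cycle off the per-step oscillation of the torso speed.

`radargait` implements that whole system at desk scale, in R:

* **Radar configuration** — chirp timing of the reference 77 GHz sensor and
  every derived quantity (range axis `r_k = k (f_s/N) c / 2S`, sweep
  bandwidth `B = S T_ramp`, Doppler limits `v_max = λ/4T_c`).
* **Lens design** — the plano-hyperbolic collimating profile
  `t(r) = F/(n+1) (√(1 + (n+1)/(n−1) (r/F)²) − 1)` with measured printed-PLA
  constants (ε_r = 2.68, σ = 0.19 S/m, R = F = 10λ), CSV/STL export and a
  geometric-optics validity check.
* **Scene simulation** — a point-scatterer synthesizer for a subject walking
  a marked 4.2 m out-and-back course (0.7 m steps, three round trips) past
  the radar: per-step raised-cosine speed modulation, turn dwells,
  wall-mirror and subject–object multipath ghosts, static cabinet clutter,
  and a parametric lens / no-lens beam, with exact ground truth.
* **Gait extraction** — range FFT, slow-time clutter filter, maximum-bin
  torso tracking with sub-bin refinement, Savitzky–Golay torso velocity,
  pass/turn segmentation, step-peak detection, and per-cycle step points,
  step/stride lengths, cadence and turn-inclusive average speed.
* **IO & CLI** — a self-describing binary cube container, raw int16 I/Q
  import, CSV/JSON gait reports and a `simulate | process | evaluate |
  lens-profile` command-line tool.

## Worked example

Simulate the hallway protocol (three out-and-back traversals of the 4.2 m
marked course at 0.87 m/s, lens-mode beam, 20 dB SNR, hallway clutter) and
extract the gait report:

```r
library(radargait)
print(default_config())
#> <chirp_config>
#>   start frequency : 77.00 GHz
#>   slope           : 60.00 MHz/us
#>   ramp / idle     : 60.0 / 250.0 us
#>   ADC             : 64 samples @ 2200 ksps (start 10.0 us)
#>   chirps/frame    : 256, frame period 100.0 ms
#>   bandwidth       : 3600 MHz (sampled 1745 MHz)
#>   range bin       : 0.0859 m, max range 5.50 m
#>   v_max / v_res   : 3.081 / 0.0241 m/s

sim <- simulate_walk_cube(walk_scenario(rng_seed = 1))
rep <- extract_gait(sim$cube)
print(rep)
#> <gait_report>
#>   average speed   : 0.745 m/s (turns included)
#>   step count      : 36
#>   cadence         : 78.5 steps/min
#>   mean step length: 0.707 m (30 lengths)
#>   passes          : 6

sim$ground_truth$true_step_count   # 36: all steps recovered
sim$ground_truth$true_avg_speed    # 0.742 m/s (stopwatch definition,
                                   # turns included): error ~3 mm/s
```

The step count is exact, the mean step length lands within a centimetre of
the 70 cm course marking, and the average speed (distance over elapsed
time *including* the turns, matching a stopwatch reference) is recovered
to a few mm/s. Re-running with `beam_pattern("no_lens")` reproduces the
multipath failure mode: the wide beam lets wall and cabinet ghosts contest
the profile maximum and the pipeline overcounts steps.

The lens that makes this work:

```r
print(default_lens_spec())
#> <lens_spec>
#>   F = 38.20 mm, R = 38.20 mm
#>   eps_r = 2.680 (n = 1.6371), sigma = 0.19 S/m
#>   max thickness t(R) = 18.36 mm
```

## Command line

```sh
Rscript inst/cli/radargait simulate --out walk.rgc --truth truth.json --seed 7
Rscript inst/cli/radargait process  --cube walk.rgc --out report
Rscript inst/cli/radargait evaluate --report report_summary.json \
                                    --truth truth.json --out metrics.json
Rscript inst/cli/radargait lens-profile --out-csv lens.csv --out-stl lens.stl
```

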