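Package: radargait
Title: Spatiotemporal Gait Analysis from FMCW Radar with a Dielectric Lens Beam Model
Version: 0.1.0
Authors@R:
    person("radargait", "developers", email = "radargait@example.org",
           role = c("aut", "cre"))
Description: Tools for contactless gait monitoring with a single
    frequency-modulated continuous-wave (FMCW) millimetre-wave radar in
    cluttered indoor corridors.  Provides a point-scatterer simulator for a
    subject walking a marked hallway course (including wall-mirror multipath
    ghosts and a parametric lens/no-lens antenna beam), fast-time range
    processing with maximum-bin torso tracking, extraction of per-cycle
    spatiotemporal gait parameters (walking speed, step times, step points,
    step and stride lengths, step count, cadence) from the torso velocity
    series, and the hyperbolic dielectric-lens thickness profile used to
    narrow the antenna beam.  Includes binary cube containers, raw I/Q
    import, report writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
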