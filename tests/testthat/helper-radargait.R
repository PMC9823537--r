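# Shared fixtures and oracles.  Everything is generated in code; the
# reduced-chirp configuration keeps unit-test cubes cheap while the
# acceptance tests use the full reference configuration.

# Reference chirp timing with fewer chirps per frame (same fast-time axis).
small_cfg <- function(chirps = 32L, frame_period = 0.1) {
  chirp_config(chirps_per_frame = chirps, frame_period = frame_period)
}

# Tiny config for single-frame synthesis checks.
tiny_cfg <- function(chirps = 4L) {
  chirp_config(chirps_per_frame = chirps,
               frame_period = chirps * 310e-6 + 1e-4)
}

.radargait_cache <- new.env(parent = emptyenv())

# Default hallway walk simulated with the reduced-chirp configuration.
cached_sim_small <- function() {
  if (is.null(.radargait_cache$sim_small)) {
    .radargait_cache$sim_small <-
      simulate_walk_cube(walk_scenario(rng_seed = 7L), cfg = small_cfg())
  }
  .radargait_cache$sim_small
}

cached_report_small <- function() {
  if (is.null(.radargait_cache$rep_small)) {
    .radargait_cache$rep_small <- extract_gait(cached_sim_small()$cube)
  }
  .radargait_cache$rep_small
}

# O(N^2) discrete Fourier transform oracle (independent of stats::fft).
dft_oracle <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  as.vector(W %*% x)
}

# Build a velocity_series directly (bypassing the radar path).
make_velocity_series <- function(times, velocity) {
  structure(list(times = times, velocity = velocity,
                 abs_velocity = abs(velocity)),
            class = "velocity_series")
}

# Build a range_track directly.
make_track <- function(times, ranges, cfg = small_cfg()) {
  structure(list(times = times, torso_range = ranges,
                 torso_bin = as.integer(round(ranges / range_bin_spacing(cfg))),
                 valid = rep(TRUE, length(times)),
                 bin_spacing = range_bin_spacing(cfg), cfg = cfg),
            class = "range_track")
}

# Within-pass speed that yields a prescribed turn-inclusive average speed.
pass_speed_for <- function(v_true, rt = 3, path = 4.2, turn = 1.0) {
  D <- 2 * rt * path
  Tt <- (2 * rt - 1) * turn
  D / (D / v_true - Tt)
}
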