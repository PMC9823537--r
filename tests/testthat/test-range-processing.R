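test_that("range FFT equals the brute-force DFT on a random small cube", {
  cfg <- tiny_cfg()
  set.seed(31)
  n <- cfg$adc_samples * cfg$chirps_per_frame
  data <- array(complex(real = rnorm(n), imaginary = rnorm(n)),
                dim = c(cfg$adc_samples, cfg$chirps_per_frame, 1))
  cube <- structure(list(data = data, cfg = cfg, n_frames = 1L),
                    class = "radar_cube")
  rc <- range_fft(cube, window = "rect")
  for (ch in c(1L, cfg$chirps_per_frame)) {
    expect_equal(rc$bins[, ch, 1], dft_oracle(data[, ch, 1]),
                 tolerance = 1e-10)
  }
  # all-zero cube transforms to all zeros
  zero <- structure(list(data = array(0 + 0i, dim(data)), cfg = cfg,
                         n_frames = 1L), class = "radar_cube")
  expect_true(all(range_fft(zero)$bins == 0))
  expect_error(range_fft(cube, window = "tukey"), "unknown window")
  expect_error(range_fft(cube, n_fft = 32), "n_fft")
})

test_that("Hann window trades mainlobe width for sidelobe level", {
  cfg <- tiny_cfg()
  dr <- range_bin_spacing(cfg)
  sc <- scatterer(20.37 * dr, 0, 1, "static")   # deliberately off-centre
  cube <- synthesize_cube(list(sc), cfg, snr_db = Inf,
                          duration = cfg$frame_period)
  prof_of <- function(w) frame_profile(range_fft(cube, window = w), 1)$magnitudes
  rect <- prof_of("rect"); hann <- prof_of("hann")
  lobe <- 17:25   # bins around the peak (1-based)
  expect_gt(sum(hann[lobe] > max(hann) / 2), sum(rect[lobe] > max(rect) / 2) - 1)
  expect_lt(max(hann[-lobe]) / max(hann), max(rect[-lobe]) / max(rect))
})

test_that("slow-time mean filter removes statics and keeps movers", {
  cfg <- small_cfg()
  static <- scatterer(2.0, 0, 1, "static")
  mover <- scatterer(function(t) 1.2 + 0.9 * t, 0, 1, "torso")
  cube <- synthesize_cube(list(static, mover), cfg, snr_db = Inf,
                          duration = 3)
  rc <- range_fft(cube)
  rcf <- clutter_filter(rc)
  static_bin <- round(2.0 / range_bin_spacing(cfg)) + 1L
  raw_mag <- mean(abs(rc$bins[static_bin, , 1]))
  flt_mag <- mean(abs(rcf$bins[static_bin, , 1]))
  expect_lt(flt_mag, 0.05 * raw_mag)
  # the mover's peak survives within 3 dB in every frame
  for (f in c(1L, 15L, rc$bins |> dim() |> tail(1))) {
    pr <- frame_profile(rc, f)$magnitudes
    pf <- frame_profile(rcf, f)$magnitudes
    mover_bin <- which.max(pf)
    expect_gt(pf[mover_bin], 10^(-3 / 20) * pr[mover_bin])
  }
  # mode none is the identity
  expect_identical(clutter_filter(rc, "none")$bins, rc$bins)
})

test_that("torso_bin applies the max rule with ties toward smaller bins", {
  ax <- range_axis(default_config())
  prof <- structure(list(frame_index = 1L,
                         magnitudes = rep(0, 64), range_axis = ax),
                    class = "range_profile")
  prof$magnitudes[c(10, 20, 30)] <- c(1, 5, 3)
  expect_equal(torso_bin(prof), 19L)          # 0-based index of the max
  prof$magnitudes[] <- 0; prof$magnitudes[c(20, 25)] <- 5
  expect_equal(torso_bin(prof), 19L)          # tie -> smaller bin
  # min_range excludes the leakage region
  prof$magnitudes[] <- 0; prof$magnitudes[c(2, 25)] <- c(9, 5)
  expect_equal(torso_bin(prof, min_range = 0.3), 24L)
  prof$magnitudes[] <- 0
  expect_true(is.na(torso_bin(prof)))         # invalid frame, no error
})

test_that("noiseless mover is tracked within one bin at every frame", {
  cfg <- small_cfg()
  tr <- torso_trajectory(walk_scenario(n_round_trips = 1, rng_seed = 1))
  torso <- scatterer(tr$range_fn, 0, 1, "torso")
  cube <- synthesize_cube(list(torso), cfg, snr_db = Inf,
                          duration = tr$duration)
  rc <- range_fft(cube)          # single mover, no clutter: no filter needed
  track <- range_track(rc, refine = "none")
  truth <- tr$range_fn(track$times)
  expect_true(all(abs(track$torso_range - truth) <= track$bin_spacing + 1e-9))
  # parabolic refinement does at least as well on average
  track2 <- range_track(rc)
  expect_lte(mean(abs(track2$torso_range - truth)),
             mean(abs(track$torso_range - truth)))
})

test_that("track smoothing removes outlier spikes and respects the gate", {
  cfg <- small_cfg()
  times <- (seq_len(60) - 0.5) * cfg$frame_period
  clean <- 1 + 0.8 * times
  spiky <- clean; spiky[30] <- 5.2
  tr <- make_track(times, spiky, cfg)
  sm <- track_smooth(tr)
  expect_equal(sm$torso_range[30], clean[30], tolerance = 0.05)
  vmax <- max_unambiguous_velocity(cfg)
  expect_true(all(abs(diff(sm$torso_range)) / diff(times) <= vmax + 1e-9))
  # a clean ramp passes through except at the very edges
  sm2 <- track_smooth(make_track(times, clean, cfg))
  expect_equal(sm2$torso_range[3:58], clean[3:58], tolerance = 1e-9)
  expect_error(track_smooth(make_track(times[1:2], clean[1:2], cfg)),
               "3 frames")
})

test_that("without the clutter filter, statics capture the argmax", {
  sim <- cached_sim_small()
  cube_nl <- simulate_walk_cube(walk_scenario(rng_seed = 7),
                                cfg = small_cfg(),
                                beam = beam_pattern("no_lens"))$cube
  rc <- range_fft(cube_nl)
  track_raw <- range_track(rc)                      # no filtering
  truth <- sim$trajectory$range_fn(track_raw$times)
  disagree <- sum(abs(track_raw$torso_range - truth) > track_raw$bin_spacing)
  expect_gt(disagree, 0)
})
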