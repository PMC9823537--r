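test_that("velocity of a linear ramp is its slope; constant range gives zero", {
  cfg <- small_cfg()
  times <- (seq_len(80) - 0.5) * cfg$frame_period
  v <- torso_velocity(make_track(times, 0.5 + 0.9 * times, cfg))
  expect_equal(v$velocity, rep(0.9, 80), tolerance = 1e-9)
  expect_equal(v$abs_velocity, abs(v$velocity))
  v0 <- torso_velocity(make_track(times, rep(2.5, 80), cfg))
  expect_equal(v0$velocity, rep(0, 80), tolerance = 1e-12)
  # a cubic range profile is differentiated exactly by the cubic fit
  vc <- torso_velocity(make_track(times, 1 + 0.1 * times^3, cfg))
  expect_equal(vc$velocity, 0.3 * times^2, tolerance = 1e-6)
  expect_error(torso_velocity(make_track(times[1:2], c(1, 2), cfg)),
               "3 valid frames")
})

test_that("pass segmentation partitions a synthetic out-and-back walk", {
  dt <- 0.1
  times <- seq(dt / 2, 30, by = dt)
  # two passes separated by a 2 s standstill, short blips must not split
  vel <- ifelse(times < 10, 1, ifelse(times < 12, 0, -1))
  vel[40:41] <- 0.02    # short in-pass hesitation (0.2 s < min_turn)
  v <- make_velocity_series(times, vel)
  seg <- segment_passes(v, min_turn_duration = 0.5)
  pr <- seg$segments[seg$segments$type == "pass", ]
  tu <- seg$segments[seg$segments$type == "turn", ]
  expect_equal(nrow(pr), 2)
  expect_equal(nrow(tu), 1)
  expect_equal(pr$sign, c(1, -1))
  # every frame labelled exactly once
  expect_length(seg$label, length(times))
  covered <- unlist(Map(seq, seg$segments$start, seg$segments$end))
  expect_equal(sort(covered), seq_along(times))
  # single one-way walk: 1 pass, 0 turns
  v1 <- make_velocity_series(times[times < 10], rep(1, sum(times < 10)))
  seg1 <- segment_passes(v1)
  expect_equal(sum(seg1$segments$type == "pass"), 1)
  expect_equal(sum(seg1$segments$type == "turn"), 0)
  expect_error(segment_passes(make_velocity_series(times, rep(0, length(times)))),
               "no pass")
})

test_that("step peaks are the per-cycle speed maxima", {
  dt <- 0.1
  times <- seq(dt / 2, 6, by = dt)
  # 6 modulated cycles at 1 Hz
  vel <- 1 - 0.5 * cos(2 * pi * times)
  v <- make_velocity_series(times, vel)
  seg <- segment_passes(v)
  ev <- detect_steps(v, seg)
  expect_equal(nrow(ev$events), 6)
  # |v| maxima of 1 - 0.5 cos(2 pi t) sit at t = 0.5 + k
  expect_equal(ev$events$time, c(0.45, 1.45, 2.45, 3.45, 4.45, 5.45),
               tolerance = 0.25)
  # constant-speed pass: no prominence, no steps
  vflat <- make_velocity_series(times, rep(1, length(times)))
  segf <- segment_passes(vflat)
  expect_equal(nrow(detect_steps(vflat, segf)$events), 0)
  # minimum separation suppresses doublets
  vd <- vel + 0.2 * cos(2 * pi * 4 * times)   # 4 Hz ripple
  evd <- detect_steps(make_velocity_series(times, vd), seg,
                      min_step_interval = 0.8)
  expect_lte(nrow(evd$events), 6)
})

test_that("step geometry subtracts successive step points within passes", {
  cfg <- small_cfg()
  times <- (seq_len(50) - 0.5) * 0.1
  track <- make_track(times, 0.7 * times, cfg)   # 0.7 m/s ramp
  ev <- structure(list(events = data.frame(
    index = c(10L, 20L, 30L), time = c(1, 2, 3), pass_id = c(1L, 1L, 1L))),
    class = "step_events")
  geo <- step_geometry(track, ev)
  expect_equal(geo$steps$step_point, c(0.7, 1.4, 2.1))
  expect_equal(geo$steps$step_length, c(0.7, 0.7, NA))
  expect_equal(geo$steps$step_time, c(1, 1, NA))
  expect_equal(geo$stride_lengths, 1.4)
  # pairs never cross passes
  ev2 <- structure(list(events = data.frame(
    index = c(10L, 20L, 30L), time = c(1, 2, 3), pass_id = c(1L, 1L, 2L))),
    class = "step_events")
  geo2 <- step_geometry(track, ev2)
  expect_equal(sum(!is.na(geo2$steps$step_length)), 1)
  ev_bad <- structure(list(events = data.frame(
    index = 1L, time = 99, pass_id = 1L)), class = "step_events")
  expect_error(step_geometry(track, ev_bad), "outside")
})

test_that("average speed is distance over turn-inclusive elapsed time", {
  cfg <- small_cfg()
  times <- seq(0.05, 4.85, by = 0.1)
  track <- make_track(times, 0.8 + (4.2 / 4.83) * (times - 0.05), cfg)
  v <- torso_velocity(track)
  seg <- segment_passes(v)
  expect_equal(average_speed(track, seg), 4.2 / 4.83, tolerance = 0.02)
  # longer turns lower the speed: compare two synthetic two-pass walks
  two_pass <- function(turn_s) {
    tt <- seq(0.05, 10 + turn_s, by = 0.1)
    up <- pmin(tt, 5) * 0.84
    down <- pmax(tt - 5 - turn_s, 0) * 0.84
    make_track(tt, 0.8 + up - down, cfg)
  }
  sp <- function(turn_s) {
    tr <- two_pass(turn_s); vv <- torso_velocity(tr)
    average_speed(tr, segment_passes(vv))
  }
  expect_gt(sp(1), sp(3))
})

test_that("empty step events still produce a coherent report", {
  cfg <- small_cfg()
  times <- (seq_len(60) - 0.5) * 0.1
  track <- make_track(times, 0.8 + 0.7 * times, cfg)
  v <- torso_velocity(track)
  seg <- segment_passes(v)
  ev <- detect_steps(v, seg)        # constant speed -> no peaks
  rep <- build_report(track, v, seg, ev)
  expect_s3_class(rep, "gait_report")
  expect_equal(rep$step_count, 0)
  expect_equal(nrow(rep$steps), 0)
  expect_length(rep$stride_lengths, 0)
})

test_that("full pipeline recovers the default walk (reduced-chirp cube)", {
  sim <- cached_sim_small()
  rep <- cached_report_small()
  gt <- sim$ground_truth
  expect_equal(rep$step_count, gt$true_step_count)
  expect_equal(nrow(rep$steps), rep$step_count)
  expect_equal(rep$mean_step_length, 0.7, tolerance = 0.04)
  expect_lt(abs(rep$avg_speed - gt$true_avg_speed), 0.045)
  # 6 passes of ~4.2 m each, within two bin spacings
  ps <- rep$pass_summary
  expect_equal(nrow(ps), 6)
  track <- attr(rep, "track")
  expect_true(all(abs(ps$distance - 4.2) <= 2 * track$bin_spacing + 0.02))
  # cadence consistency: steps over pass time only
  seg <- attr(rep, "passes")$segments
  pass_time <- sum(seg$t_end[seg$type == "pass"] - seg$t_start[seg$type == "pass"])
  expect_equal(rep$cadence, rep$step_count / pass_time * 60)
})

test_that("micro-Doppler spectrogram shows the expected ridges", {
  cfg <- chirp_config(chirps_per_frame = 64L, frame_period = 0.05)
  vtrue <- 0.9
  mover <- scatterer(function(t) 1.5 + vtrue * t, 0, 1, "torso")
  cube <- synthesize_cube(list(mover), cfg, snr_db = Inf, duration = 1)
  track <- range_track(range_fft(cube))
  sp <- micro_doppler_spectrogram(cube, track)
  ridge <- sp$velocity_axis[apply(sp$magnitude, 2, which.max)]
  dv <- diff(sp$velocity_axis)[1]
  expect_true(all(abs(ridge - vtrue) <= dv + 1e-9))
  # static scatterer: ridge at zero; receding: negative
  for (vv in c(0, -0.9)) {
    sc <- scatterer(function(t) 3.0 + vv * t, 0, 1, "torso")
    cb <- synthesize_cube(list(sc), cfg, snr_db = Inf, duration = 1)
    tk <- range_track(range_fft(cb))
    s2 <- micro_doppler_spectrogram(cb, tk)
    r2 <- s2$velocity_axis[apply(s2$magnitude, 2, which.max)]
    expect_true(all(abs(r2 - vv) <= dv + 1e-9))
  }
  expect_error(micro_doppler_spectrogram(cube, track, stft_window = 1000),
               "stft_window")
})
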